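#' Mean-square displacement
#'
#' Time- and molecule-averaged MSD of the water oxygens on a lag grid.
#' `in_plane = TRUE` restricts to the two in-plane components (dimension
#' `d = 2`, the slab convention); the default infers this from the cell
#' periodicity. Requires unwrapped coordinates (see [unwrap()]).
#'
#' @param traj an unwrapped [wtraj()].
#' @param in_plane logical, or `NULL` for auto (slab -> TRUE).
#' @param lag_grid lags in ps (0 is always included); default 40 lags up to
#'   a quarter of the trajectory.
#' @param origin_stride use every `origin_stride`-th frame as a time origin
#'   (variance changes little beyond the correlation time; the stride keeps
#'   long trajectories affordable).
#' @return object of class `msd_curve`: data.frame `lag` (ps), `msd` (A^2),
#'   `n` (origin-molecule samples), with attribute `d` (dimension).
#' @export
msd <- function(traj, in_plane = NULL, lag_grid = NULL, origin_stride = 1L) {
  stopifnot(inherits(traj, "wtraj"))
  comps <- diffusion_components(traj, in_plane)
  nf <- n_frames(traj)
  dt <- traj$dt
  if (is.null(lag_grid)) {
    lag_grid <- seq(0, (nf - 1) * dt / 4, length.out = 41L)[-1]
  }
  lf <- sort(unique(round(lag_grid / dt)))
  lf <- lf[lf >= 1L]
  if (any(lf > nf - 1L)) stop("lag grid exceeds trajectory length",
                              call. = FALSE)
  x <- o_coords(traj)
  n_mol <- dim(x)[1]
  xcs <- lapply(comps, function(c_) matrix(x[, c_, ], n_mol, nf))
  out_msd <- numeric(length(lf)); out_n <- numeric(length(lf))
  for (k in seq_along(lf)) {
    L <- lf[k]
    orig <- seq(1L, nf - L, by = origin_stride)
    d2 <- 0
    for (xc in xcs) {
      d2 <- d2 + (xc[, orig + L, drop = FALSE] - xc[, orig, drop = FALSE])^2
    }
    out_msd[k] <- mean(d2)
    out_n[k] <- length(d2)
  }
  df <- data.frame(lag = c(0, lf * dt), msd = c(0, out_msd),
                   n = c(n_mol * nf, out_n))
  structure(df, d = length(comps), dt = dt,
            class = c("msd_curve", "data.frame"))
}

#' Diffusion coefficient from an MSD curve (Einstein relation)
#'
#' Least-squares slope of the MSD over `fit_range`, divided by `2 d`. The
#' intercept is free, so constant offsets (ballistic/librational plateaus,
#' bounded rattling) do not bias the estimate. A negative slope yields a
#' diagnostic warning and the raw value is reported.
#'
#' @param msd_curve an `msd_curve` from [msd()] or [frame_msd()].
#' @param fit_range length-2 numeric, lag interval in ps (default 1-5 ps;
#'   keep the lower edge past the ballistic regime).
#' @param d dimension override (default: the curve's).
#' @return `D` in A^2/ps (multiply by 10 for 1e-5 cm^2/s).
#' @export
fit_diffusion <- function(msd_curve, fit_range = c(1, 5), d = NULL) {
  stopifnot(inherits(msd_curve, "msd_curve"))
  if (is.null(d)) d <- attr(msd_curve, "d")
  sel <- msd_curve$lag >= fit_range[1] - 1e-9 &
    msd_curve$lag <= fit_range[2] + 1e-9 & msd_curve$n > 0
  if (sum(sel) < 2L) stop("fit_range must contain at least two sampled lags",
                          call. = FALSE)
  fit <- stats::lm(msd ~ lag, data = msd_curve[sel, ])
  slope <- unname(stats::coef(fit)[2])
  if (slope < 0) warning("negative MSD slope; reporting the raw value")
  slope / (2 * d)
}

#' Frame (intra-shell) mean-square displacement
#'
#' MSD restricted to origin/lag pairs lying inside a single stable-state
#' segment, i.e. displacement accumulated while the solvation-shell
#' composition is unchanged. Every valid (origin, lag) pair is weighted
#' equally (dense origins), matching the convention of the state-dynamics
#' estimators.
#'
#' @param traj an unwrapped [wtraj()].
#' @param segments a `shell_segments`.
#' @param lag_grid lags in ps; default 20 lags up to 1 ps.
#' @param in_plane as in [msd()].
#' @return an `msd_curve`.
#' @export
frame_msd <- function(traj, segments, lag_grid = NULL, in_plane = NULL) {
  stopifnot(inherits(traj, "wtraj"), inherits(segments, "shell_segments"))
  comps <- diffusion_components(traj, in_plane)
  nf <- n_frames(traj)
  dt <- traj$dt
  if (is.null(lag_grid)) lag_grid <- seq(dt, min(1, (nf - 1) * dt / 4),
                                         length.out = 20L)
  lf <- sort(unique(round(lag_grid / dt)))
  lf <- lf[lf >= 1L & lf <= nf - 1L]
  ## segment id per (molecule, frame); NA outside segments
  n_mol <- max(segments$mol)
  sid <- matrix(NA_integer_, n_mol, nf)
  for (i in seq_len(nrow(segments))) {
    sid[segments$mol[i], segments$start_frame[i]:segments$end_frame[i]] <- i
  }
  x <- o_coords(traj)
  if (dim(x)[1] != n_mol) {
    ## molecules without segments simply contribute nothing
    n_mol <- dim(x)[1]
    sid2 <- matrix(NA_integer_, n_mol, nf)
    sid2[seq_len(nrow(sid)), ] <- sid
    sid <- sid2
  }
  xcs <- lapply(comps, function(c_) matrix(x[, c_, ], n_mol, nf))
  out_msd <- rep(NA_real_, length(lf)); out_n <- numeric(length(lf))
  for (k in seq_along(lf)) {
    L <- lf[k]
    same <- sid[, 1:(nf - L), drop = FALSE] ==
      sid[, (1 + L):nf, drop = FALSE]
    same[is.na(same)] <- FALSE
    if (!any(same)) next
    d2 <- 0
    for (xc in xcs) {
      d2 <- d2 + (xc[, (1 + L):nf, drop = FALSE] -
                    xc[, 1:(nf - L), drop = FALSE])^2
    }
    out_msd[k] <- mean(d2[same])
    out_n[k] <- sum(same)
  }
  if (all(is.na(out_msd))) {
    stop("no segment is long enough for the smallest lag", call. = FALSE)
  }
  df <- data.frame(lag = c(0, lf * dt), msd = c(0, out_msd),
                   n = c(sum(!is.na(sid)), out_n))
  df <- df[!is.na(df$msd), , drop = FALSE]
  structure(df, d = length(comps), dt = dt,
            class = c("msd_curve", "data.frame"))
}

#' SWE contribution to diffusion (CTRW model)
#'
#' `D_SWE = delta^2 / (2 d tau)`: a continuous-time random walk with mean
#' squared jump amplitude `delta^2` and waiting time `tau` in `d` dimensions.
#'
#' @param delta_sq mean squared displacement amplitude in A^2.
#' @param tau exchange time in ps (> 0).
#' @param d dimension (2 or 3).
#' @return diffusion coefficient in A^2/ps.
#' @export
d_swe <- function(delta_sq, tau, d) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive", call. = FALSE)
  stopifnot(d %in% c(2, 3))
  delta_sq / (2 * d * tau)
}

#' Kick contribution to diffusion (CTRW model with shell multiplicity)
#'
#' `D_kick = factor * delta^2 / (4 tau)`: the in-plane (d = 2) CTRW formula
#' multiplied by the mean number of H-bonded pairs in the solvation basin
#' (each pair is an independent kick source for the central molecule); the
#' factor comes from [mean_hb_partners()].
#'
#' @param delta_sq mean squared kick displacement of O* in A^2.
#' @param tau kick time in ps (> 0).
#' @param factor shell multiplicity (> 0); `1` reduces to the single-pair
#'   CTRW formula.
#' @return diffusion coefficient in A^2/ps.
#' @export
d_kick <- function(delta_sq, tau, factor) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive", call. = FALSE)
  if (!is.finite(factor) || factor <= 0) stop("factor must be positive",
                                              call. = FALSE)
  factor * delta_sq / (4 * tau)
}

#' Assemble the diffusion decomposition report
#'
#' Collects the total, frame, SWE and kick diffusion coefficients with their
#' CTRW ingredients and computes the additivity residual:
#' `|D_total - (D_SWE + D_kick)| / D_total` in monolayer mode (kick-driven
#' frame motion) and `|D_total - (D_SWE + D_frame)| / D_total` in bulk mode.
#' A zero `D_total` with zero components gives a residual of 0.
#'
#' @param d_total,d_frame,d_swe,d_kick components in A^2/ps (`d_kick` may be
#'   `NA` in bulk mode, `d_frame` may be `NA` if not computed).
#' @param tau_swe,tau_kick waiting times in ps.
#' @param delta_sq_swe,delta_sq_kick amplitudes in A^2.
#' @param kick_factor shell multiplicity used in `d_kick`.
#' @param d dimension (2 monolayer, 3 bulk).
#' @param mode `"monolayer"` or `"bulk"`.
#' @return object of class `diffusion_report` (a list); fields in A^2/ps
#'   plus `*_cm2s` mirrors in 1e-5 cm^2/s (x 10).
#' @export
assemble_report <- function(d_total, d_frame = NA_real_, d_swe, d_kick = NA_real_,
                            tau_swe = NA_real_, tau_kick = NA_real_,
                            delta_sq_swe = NA_real_, delta_sq_kick = NA_real_,
                            kick_factor = NA_real_, d,
                            mode = c("monolayer", "bulk")) {
  mode <- match.arg(mode)
  stopifnot(d %in% c(2, 3))
  need <- if (mode == "monolayer") c(d_total, d_swe, d_kick)
          else c(d_total, d_swe, d_frame)
  if (anyNA(need)) stop("incomplete report: missing diffusion component",
                        call. = FALSE)
  decomp <- if (mode == "monolayer") d_swe + d_kick else d_swe + d_frame
  residual <- if (d_total == 0 && decomp == 0) 0 else
    abs(d_total - decomp) / d_total
  rep_ <- list(
    mode = mode, d = d,
    D_total = d_total, D_frame = d_frame, D_SWE = d_swe, D_kick = d_kick,
    tau_swe = tau_swe, tau_kick = tau_kick,
    delta_sq_swe = delta_sq_swe, delta_sq_kick = delta_sq_kick,
    kick_factor = kick_factor,
    D_decomposed = decomp, additivity_residual = residual,
    D_total_cm2s = 10 * d_total, D_frame_cm2s = 10 * d_frame,
    D_SWE_cm2s = 10 * d_swe, D_kick_cm2s = 10 * d_kick
  )
  structure(rep_, class = "diffusion_report")
}

#' @export
print.diffusion_report <- function(x, ...) {
  cat(sprintf("<diffusion_report> %s (d = %d)\n", x$mode, x$d))
  cat(sprintf("  D_total = %.4g A^2/ps (%.4g x 1e-5 cm^2/s)\n",
              x$D_total, x$D_total_cm2s))
  cat(sprintf("  D_frame = %.4g, D_SWE = %.4g, D_kick = %.4g A^2/ps\n",
              x$D_frame, x$D_SWE, x$D_kick))
  cat(sprintf("  tau_SWE = %.4g ps, tau_kick = %.4g ps, factor = %.3g\n",
              x$tau_swe, x$tau_kick, x$kick_factor))
  cat(sprintf("  decomposition: %.4g; additivity residual = %.3g\n",
              x$D_decomposed, x$additivity_residual))
  invisible(x)
}
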