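## Composition ids: each distinct solvation-shell composition (sorted set of
## partner molecule ids) is interned once; matrices then hold small integers.

intern_comps <- function(keys) {
  uk <- unique(keys)
  defs <- lapply(strsplit(uk, ","), function(v) {
    v <- v[nzchar(v)]
    as.integer(v)
  })
  list(id = match(keys, uk), defs = defs)
}

new_shell_series <- function(comp, comp_defs, dt) {
  structure(list(comp = comp, comp_defs = comp_defs, dt = dt),
            class = "shell_series")
}

#' Solvation-shell composition series
#'
#' Per molecule and frame, the set of solvation-shell partners. In `"hbond"`
#' mode the shell is the union of molecules the tagged water donates an
#' H-bond to and accepts one from (its coordination state); in `"distance"`
#' mode it is all molecules whose O lies within `r_shell` of the tagged O
#' (minimum image, full 3D distance even in slabs).
#'
#' @param bonds a `bond_states` object from [classify_bonds()] (hbond mode).
#' @param mode `"hbond"` or `"distance"`.
#' @param r_shell shell radius in Angstrom (required in distance mode).
#' @param traj a [wtraj()] (required in distance mode).
#' @return an object of class `shell_series`.
#' @export
shell_series <- function(bonds = NULL, mode = c("hbond", "distance"),
                         r_shell = NULL, traj = NULL) {
  mode <- match.arg(mode)
  if (mode == "hbond") {
    stopifnot(inherits(bonds, "bond_states"))
    nf <- ncol(bonds$state)
    n_mol <- bonds$n_mol
    keys <- matrix("", n_mol, nf)
    bm <- bonds$bonds$mol
    for (f in seq_len(nf)) {
      acc <- bonds$acceptor[, f]
      hb <- !is.na(acc)
      partners <- vector("list", n_mol)
      if (any(hb)) {
        dm <- bm[hb]; am <- acc[hb]
        ## donated: partner of donor; accepted: donor is partner of acceptor
        edges_from <- c(dm, am)
        edges_to <- c(am, dm)
        sp <- split(edges_to, edges_from)
        partners[as.integer(names(sp))] <-
          lapply(sp, function(v) sort(unique(v)))
      }
      keys[, f] <- vapply(partners, paste, character(1), collapse = ",")
    }
    dt <- bonds$dt
  } else {
    if (is.null(r_shell)) stop("r_shell is required in distance mode",
                               call. = FALSE)
    stopifnot(inherits(traj, "wtraj"))
    nf <- n_frames(traj)
    n_mol <- n_molecules(traj)
    ro_all <- o_coords(traj)
    keys <- matrix("", n_mol, nf)
    don <- rep(seq_len(n_mol), times = n_mol)
    acc <- rep(seq_len(n_mol), each = n_mol)
    ok <- don < acc
    don <- don[ok]; acc <- acc[ok]
    for (f in seq_len(nf)) {
      ro <- ro_all[, , f, drop = FALSE]; dim(ro) <- c(n_mol, 3L)
      d <- minimum_image_displacement(ro[don, , drop = FALSE],
                                      ro[acc, , drop = FALSE], traj$cell)
      if (is.null(dim(d))) d <- matrix(d, ncol = 3L)
      close_pair <- sqrt(rowSums(d^2)) <= r_shell
      sp <- split(c(acc[close_pair], don[close_pair]),
                  c(don[close_pair], acc[close_pair]))
      partners <- vector("list", n_mol)
      partners[as.integer(names(sp))] <- lapply(sp, function(v) sort(unique(v)))
      keys[, f] <- vapply(partners, paste, character(1), collapse = ",")
    }
    dt <- traj$dt
  }
  ic <- intern_comps(as.vector(keys))
  comp <- matrix(ic$id, n_mol, nf)
  new_shell_series(comp, ic$defs, dt)
}

new_shell_segments <- function(df, comp_defs, dt, nf) {
  rownames(df) <- NULL
  structure(df, comp_defs = comp_defs, dt = dt, n_frames = nf,
            class = c("shell_segments", "data.frame"))
}

#' Filter transient shell fluctuations into stable-state segments
#'
#' Composition changes that revert to the prior composition within
#' `t_filter` are erased (iterated until stable); the remaining runs become
#' stable-state segments. Each segment's composition is the majority
#' composition over its frames.
#'
#' @param shells a `shell_series`.
#' @param t_filter transient filter in ps (>= 0).
#' @return a `shell_segments` data.frame: `mol`, `comp_id`, `start_frame`,
#'   `end_frame`, `t_start`, `t_end` (frame f lives at time (f-1) dt).
#' @export
filter_transients <- function(shells, t_filter = 0.2) {
  stopifnot(inherits(shells, "shell_series"), t_filter >= 0)
  dt <- shells$dt
  fmax <- floor(t_filter / dt + 1e-9)
  nf <- ncol(shells$comp)
  out <- vector("list", nrow(shells$comp))
  for (m in seq_len(nrow(shells$comp))) {
    v <- shells$comp[m, ]
    r <- rle(v)
    repeat {
      k <- length(r$lengths)
      if (k < 2L) break
      ## 1) reverting flickers (A -> x -> A with x shorter than the filter)
      ##    are erased outright, shortest first
      if (k >= 3L) {
        mid <- 2:(k - 1L)
        flick <- mid[r$lengths[mid] <= fmax &
                       r$values[mid - 1L] == r$values[mid + 1L]]
        if (length(flick) > 0L) {
          j <- flick[which.min(r$lengths[flick])]
          r$values[j] <- r$values[j - 1L]
          r <- rle(inverse.rle(r))
          next
        }
      }
      ## 2) any remaining run shorter than the filter is not a stable state;
      ##    absorb it into its longer neighbour (a transient passage between
      ##    two different stable compositions)
      short <- which(r$lengths <= fmax)
      if (length(short) == 0L) break
      j <- short[which.min(r$lengths[short])]
      nb <- c(if (j > 1L) j - 1L, if (j < k) j + 1L)
      nb <- nb[which.max(r$lengths[nb])]
      r$values[j] <- r$values[nb]
      r <- rle(inverse.rle(r))
    }
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ## majority composition over the original frames of each run
    comp_id <- integer(length(starts))
    for (i in seq_along(starts)) {
      tb <- tabulate(v[starts[i]:ends[i]])
      comp_id[i] <- which.max(tb)
    }
    ## merging may make adjacent majorities equal; collapse those
    keep <- c(TRUE, comp_id[-1] != comp_id[-length(comp_id)])
    grp <- cumsum(keep)
    starts <- tapply(starts, grp, min)
    ends <- tapply(ends, grp, max)
    comp_id <- comp_id[keep]
    out[[m]] <- data.frame(mol = m, comp_id = comp_id,
                           start_frame = as.integer(starts),
                           end_frame = as.integer(ends))
  }
  df <- do.call(rbind, out)
  df$t_start <- (df$start_frame - 1) * dt
  df$t_end <- (df$end_frame - 1) * dt
  new_shell_segments(df, shells$comp_defs, dt, nf)
}

new_swe_events <- function(df, segments) {
  rownames(df) <- NULL
  structure(df, segments = segments, class = c("swe_events", "data.frame"))
}

## minimum-image distance between the O atoms of molecules m and p over frames
pair_o_distance <- function(traj, m, p, frames) {
  om <- traj$molecules$o[m]
  op <- traj$molecules$o[p]
  a <- t(traj$coords[om, , frames])
  b <- t(traj$coords[op, , frames])
  d <- minimum_image_displacement(a, b, traj$cell)
  if (is.null(dim(d))) d <- matrix(d, ncol = 3L)
  sqrt(rowSums(d^2))
}

#' Detect solvation-water-exchange (SWE) events
#'
#' Scans consecutive stable-state segments of every molecule. A transition
#' whose compositions differ by a one-out/one-in swap gives a single pairwise
#' event (Wa leaves, Wb arrives); multi-partner changes are decomposed into
#' pairwise swaps by greedy minimal-distance matching of departing and
#' arriving partners at the boundary frame. The time origin `t0` is the
#' linear-interpolated crossing of |O*-Oa| = |O*-Ob| nearest to the segment
#' boundary within `search_window`; events with no crossing are flagged
#' unresolved and excluded from averages downstream.
#'
#' All pairwise records of one segment change share a `transition_id`;
#' amplitude and waiting-time estimators aggregate per transition so that a
#' multi-partner rearrangement is not double-counted.
#'
#' @param segments a `shell_segments` from [filter_transients()].
#' @param traj the [wtraj()] the segments were computed on.
#' @param search_window half-width of the crossing search in ps
#'   (default `max(0.5, 5 dt)`).
#' @return a `swe_events` data.frame: `event_id`, `transition_id`, `mol`,
#'   `w_a`, `w_b`, `boundary_frame`, `t0`, `resolved`.
#' @export
detect_swe <- function(segments, traj, search_window = NULL) {
  stopifnot(inherits(segments, "shell_segments"), inherits(traj, "wtraj"))
  dt <- attr(segments, "dt")
  nf <- attr(segments, "n_frames")
  defs <- attr(segments, "comp_defs")
  if (is.null(search_window)) search_window <- max(0.5, 5 * dt)
  wf <- max(1L, round(search_window / dt))
  rows <- list()
  tid <- 0L
  for (m in unique(segments$mol)) {
    seg <- segments[segments$mol == m, , drop = FALSE]
    if (nrow(seg) < 2L) next
    for (i in seq_len(nrow(seg) - 1L)) {
      pre <- defs[[seg$comp_id[i]]]
      post <- defs[[seg$comp_id[i + 1L]]]
      out_p <- setdiff(pre, post)
      in_p <- setdiff(post, pre)
      if (length(out_p) == 0L && length(in_p) == 0L) next
      tid <- tid + 1L
      bf <- seg$start_frame[i + 1L]  # first frame of the post segment
      ## greedy minimal-distance pairing of departing/arriving partners
      pairs <- list()
      if (length(out_p) > 0L && length(in_p) > 0L) {
        oo <- traj$molecules$o
        ra <- traj$coords[oo[out_p], , bf, drop = FALSE]
        dim(ra) <- c(length(out_p), 3L)
        rb <- traj$coords[oo[in_p], , bf, drop = FALSE]
        dim(rb) <- c(length(in_p), 3L)
        remaining_a <- seq_along(out_p); remaining_b <- seq_along(in_p)
        while (length(remaining_a) > 0L && length(remaining_b) > 0L) {
          dm <- outer(remaining_a, remaining_b, function(ia, ib) {
            d <- minimum_image_displacement(ra[ia, , drop = FALSE],
                                            rb[ib, , drop = FALSE], traj$cell)
            if (is.null(dim(d))) d <- matrix(d, ncol = 3L)
            sqrt(rowSums(d^2))
          })
          k <- arrayInd(which.min(dm), dim(dm))
          pairs[[length(pairs) + 1L]] <-
            c(out_p[remaining_a[k[1]]], in_p[remaining_b[k[2]]])
          remaining_a <- remaining_a[-k[1]]
          remaining_b <- remaining_b[-k[2]]
        }
      }
      if (length(pairs) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          transition_id = tid, mol = m, w_a = NA_integer_, w_b = NA_integer_,
          boundary_frame = bf, t0 = (bf - 1) * dt - dt / 2, resolved = FALSE)
        next
      }
      f_lo <- max(1L, bf - wf)
      f_hi <- min(nf, bf - 1L + wf)
      fr <- f_lo:f_hi
      for (pr in pairs) {
        wa <- pr[1]; wb <- pr[2]
        g <- pair_o_distance(traj, m, wa, fr) - pair_o_distance(traj, m, wb, fr)
        sgn <- sign(g)
        cross <- which(sgn[-1] * sgn[-length(sgn)] < 0 |
                         (sgn[-length(sgn)] == 0))
        if (length(cross) == 0L && sgn[length(sgn)] == 0) {
          cross <- length(sgn) - 1L
        }
        if (length(cross) == 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            transition_id = tid, mol = m, w_a = wa, w_b = wb,
            boundary_frame = bf, t0 = (bf - 1) * dt - dt / 2,
            resolved = FALSE)
          next
        }
        ## crossing nearest the boundary; ties broken toward the boundary
        j <- cross[which.min(abs(fr[cross] + 1L - bf))]
        g1 <- g[j]; g2 <- g[j + 1L]
        fracx <- if (g2 == g1) 0.5 else g1 / (g1 - g2)
        t0 <- ((fr[j] - 1) + fracx) * dt
        rows[[length(rows) + 1L]] <- data.frame(
          transition_id = tid, mol = m, w_a = wa, w_b = wb,
          boundary_frame = bf, t0 = t0, resolved = TRUE)
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transition_id = integer(0), mol = integer(0),
               w_a = integer(0), w_b = integer(0), boundary_frame = integer(0),
               t0 = numeric(0), resolved = logical(0))
  df <- cbind(event_id = seq_len(nrow(df)), df)
  new_swe_events(df, segments)
}

#' Event-averaged O*-Oa and O*-Ob distance traces
#'
#' Averages the distances from the exchanging molecule's O to the departing
#' (Oa) and arriving (Ob) partner over all resolved pairwise SWE events, on a
#' symmetric lag grid around each event's `t0`. The two traces cross at lag 0
#' by the definition of the time origin.
#'
#' @param events a `swe_events` from [detect_swe()].
#' @param traj the [wtraj()].
#' @param half_window half-width of the lag grid in ps.
#' @return data.frame `lag` (ps), `d_oa`, `d_ob` (A), `n` events per lag.
#' @export
swe_distance_traces <- function(events, traj, half_window = 1) {
  ev <- events[events$resolved & !is.na(events$w_a), , drop = FALSE]
  if (nrow(ev) == 0L) stop("no resolved SWE events", call. = FALSE)
  dt <- traj$dt
  nf <- n_frames(traj)
  hw <- max(1L, round(half_window / dt))
  lags <- -hw:hw
  acc_a <- numeric(length(lags)); acc_b <- numeric(length(lags))
  nn <- integer(length(lags))
  for (i in seq_len(nrow(ev))) {
    cf <- round(ev$t0[i] / dt) + 1L
    fr <- cf + lags
    ok <- fr >= 1L & fr <= nf
    if (!any(ok)) next
    da <- pair_o_distance(traj, ev$mol[i], ev$w_a[i], fr[ok])
    db <- pair_o_distance(traj, ev$mol[i], ev$w_b[i], fr[ok])
    acc_a[ok] <- acc_a[ok] + da
    acc_b[ok] <- acc_b[ok] + db
    nn[ok] <- nn[ok] + 1L
  }
  data.frame(lag = lags * dt, d_oa = acc_a / pmax(nn, 1L),
             d_ob = acc_b / pmax(nn, 1L), n = nn)
}

## squared displacement of each molecule's O between two frames, on the
## requested components, from an unwrapped trajectory
window_disp_sq <- function(traj, mol, f1, f2, comps) {
  oo <- traj$molecules$o[mol]
  d2 <- numeric(length(mol))
  for (c_ in comps) {
    d2 <- d2 + (traj$coords[cbind(oo, c_, f2)] -
                  traj$coords[cbind(oo, c_, f1)])^2
  }
  d2
}

diffusion_components <- function(traj, in_plane = NULL) {
  if (is.null(in_plane)) in_plane <- sum(!traj$cell$periodic) == 1L
  if (in_plane) {
    comps <- setdiff(1:3, traj$normal_axis)
    if (sum(traj$cell$periodic) < 2L)
      comps <- which(traj$cell$periodic)
    if (length(comps) == 0L) comps <- 1:2
  } else {
    comps <- 1:3
  }
  comps
}

#' Mean-square displacement amplitude of O* over SWE events
#'
#' For each resolved segment transition, the squared displacement of the
#' exchanging molecule's O. Two conventions:
#' \describe{
#'   \item{window}{`|r(t0+T) - r(t0-T)|^2` with `T = half_window`. With
#'     `baseline = TRUE` (default) the trajectory's mean-square displacement
#'     at lag `2T` is subtracted from the event average, which removes the
#'     contribution of all motion not tied to the tagged event (exact for
#'     superposed independent displacement processes).}
#'   \item{centroid}{squared distance between the mean O* position over the
#'     pre-segment and over the post-segment. Robust to intra-basin rattling
#'     but accumulates any background diffusion over the inter-centroid time;
#'     prefer it only when exchanges are the sole motion.}
#' }
#' Events whose adjacent segments are shorter than 2 frames (centroid) or
#' whose window leaves the trajectory (window) are skipped.
#'
#' @param events a `swe_events`.
#' @param traj unwrapped [wtraj()] (see [unwrap()]).
#' @param convention `"window"` or `"centroid"`.
#' @param half_window window half-width `T` in ps (window convention).
#' @param baseline subtract the lag-`2T` MSD baseline (window convention).
#' @param in_plane use only the two in-plane components (default: auto from
#'   cell periodicity; slab -> TRUE).
#' @return list with `delta_sq` (mean, A^2), `per_event` data.frame,
#'   `baseline` (A^2), `n`.
#' @export
swe_displacement_amplitude <- function(events, traj,
                                       convention = c("window", "centroid"),
                                       half_window = 0.5, baseline = TRUE,
                                       in_plane = NULL) {
  convention <- match.arg(convention)
  segments <- attr(events, "segments")
  comps <- diffusion_components(traj, in_plane)
  dt <- traj$dt
  nf <- n_frames(traj)
  ## one record per transition: all pairwise rows share t0 up to resolution
  ev <- events[events$resolved, , drop = FALSE]
  if (nrow(ev) == 0L) stop("no resolved SWE events", call. = FALSE)
  ev <- ev[!duplicated(ev$transition_id), , drop = FALSE]
  if (convention == "window") {
    hw <- max(1L, round(half_window / dt))
    cf <- round(ev$t0 / dt) + 1L
    f1 <- cf - hw; f2 <- cf + hw
    ok <- f1 >= 1L & f2 <= nf
    ev <- ev[ok, , drop = FALSE]; f1 <- f1[ok]; f2 <- f2[ok]
    if (nrow(ev) == 0L) stop("no SWE events with a full window", call. = FALSE)
    d2 <- window_disp_sq(traj, ev$mol, f1, f2, comps)
    base <- 0
    if (baseline) {
      mm <- msd(traj, lag_grid = (f2[1] - f1[1]) * dt,
                in_plane = length(comps) == 2L)
      base <- mm$msd[mm$lag > 0][1]
    }
    per_event <- data.frame(transition_id = ev$transition_id, mol = ev$mol,
                            t0 = ev$t0, d2_raw = d2)
    list(delta_sq = mean(d2) - base, per_event = per_event,
         baseline = base, n = nrow(ev), convention = convention)
  } else {
    stopifnot(!is.null(segments))
    oo <- traj$molecules$o
    d2 <- rep(NA_real_, nrow(ev))
    for (i in seq_len(nrow(ev))) {
      seg <- segments[segments$mol == ev$mol[i], , drop = FALSE]
      j <- which(seg$start_frame == ev$boundary_frame[i])
      if (length(j) != 1L || j == 1L) next
      pre <- seg[j - 1L, ]; post <- seg[j, ]
      if (pre$end_frame - pre$start_frame < 1L ||
          post$end_frame - post$start_frame < 1L) next
      o <- oo[ev$mol[i]]
      dd <- 0
      for (c_ in comps) {
        dd <- dd + (mean(traj$coords[o, c_, post$start_frame:post$end_frame]) -
                      mean(traj$coords[o, c_, pre$start_frame:pre$end_frame]))^2
      }
      d2[i] <- dd
    }
    ok <- !is.na(d2)
    if (!any(ok)) stop("no SWE events with two usable segments", call. = FALSE)
    per_event <- data.frame(transition_id = ev$transition_id[ok],
                            mol = ev$mol[ok], t0 = ev$t0[ok], d2_raw = d2[ok])
    list(delta_sq = mean(d2[ok]), per_event = per_event, baseline = 0,
         n = sum(ok), convention = convention)
  }
}

#' Solvation-water-exchange time from the jump-time correlation function
#'
#' `tau_SWE` is the time integral of `1 - <p_i(0) p_f(t)>`, where `p_i`
#' indicates the basin occupied at the origin and `p_f` the following basin
#' with an absorbing final state. Operationally this is the survival function
#' of the forward waiting time from every frame (dense origins) to the
#' molecule's next stable-state transition, integrated by the trapezoidal
#' rule. Origins are restricted to `t <= T - max_lag`; origins whose next
#' transition lies beyond the window (or that have none) are censored and
#' keep the survival curve up, so the estimate is unbiased for stationary
#' input and a non-decayed correlation raises a truncation error.
#'
#' @param events a `swe_events` (detected or planted).
#' @param segments the `shell_segments` the events came from (defaults to
#'   the segments attached to `events`).
#' @param max_lag integration window in ps.
#' @param method `"integral"` or `"integral_with_tail"` (exponential tail
#'   fitted to the last decade, as in [lifetime()]).
#' @return list with `tau_swe` (ps), `survival` (a `survival_fn`-shaped
#'   data.frame `lag`, `value`), `n_origins`.
#' @export
swe_time <- function(events, segments = NULL, max_lag = NULL,
                     method = c("integral", "integral_with_tail")) {
  method <- match.arg(method)
  if (is.null(segments)) segments <- attr(events, "segments")
  stopifnot(!is.null(segments))
  dt <- attr(segments, "dt")
  nf <- attr(segments, "n_frames")
  if (is.null(max_lag)) max_lag <- (nf - 1) * dt / 2
  lmax <- min(nf - 1L, round(max_lag / dt))
  t_total <- (nf - 1) * dt
  mols <- unique(segments$mol)
  waits <- numeric(0)
  tr <- events[!duplicated(events$transition_id), c("mol", "t0")]
  for (m in mols) {
    t0s <- sort(tr$t0[tr$mol == m])
    t_or <- (seq_len(nf) - 1) * dt
    t_or <- t_or[t_or <= t_total - lmax * dt + 1e-9]
    if (length(t_or) == 0L) next
    if (length(t0s) == 0L) {
      waits <- c(waits, rep(Inf, length(t_or)))
      next
    }
    idx <- findInterval(t_or, t0s) + 1L  # index of next transition
    w <- ifelse(idx <= length(t0s), t0s[idx] - t_or, Inf)
    ## an origin lying exactly on a transition belongs to the new basin
    w[w <= 0] <- Inf
    waits <- c(waits, w)
  }
  if (length(waits) < 1L) stop("no admissible origins for tau_SWE",
                               call. = FALSE)
  lags <- (0:lmax) * dt
  ws <- sort(waits[is.finite(waits)])
  ## survival of the forward waiting time; censored origins stay in the tail
  surv <- 1 - findInterval(lags, ws, left.open = FALSE) / length(waits)
  tau <- sum(diff(lags) * (surv[-1] + surv[-length(surv)]) / 2)
  tail_val <- surv[length(surv)]
  if (method == "integral") {
    if (tail_val > 0.05) {
      stop(sprintf("jump-time correlation not decayed (%.3f at %g ps)",
                   tail_val, max(lags)), call. = FALSE)
    }
  } else if (tail_val > 0) {
    sel <- which(surv > 0 & surv <= min(10 * tail_val, 0.5))
    if (length(sel) >= 3L) {
      fit <- stats::lm(log(surv[sel]) ~ lags[sel])
      slope <- unname(stats::coef(fit)[2])
      if (is.finite(slope) && slope < 0) tau <- tau + tail_val * (-1 / slope)
    }
  }
  list(tau_swe = tau, survival = data.frame(lag = lags, value = surv),
       n_origins = length(waits))
}
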