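#' Continuous survival correlation function of a bond state
#'
#' Estimates `S(t) = <h(0) H(t)> / <h>`, where `h(t)` is the indicator of a
#' bond occupying the requested state at time `t` and `H(t)` requires
#' continuous occupation from 0 to `t`. Every frame in which a bond occupies
#' the state is a time origin (dense origins), matching the normalisation of
#' the definition. Origins are restricted to `t0 <= T - max_lag` so that all
#' lags share one origin set, which makes the estimate exactly
#' non-increasing with `S(0) = 1`.
#'
#' Interruptions (visits to the complementary state) shorter than
#' `filter_window` do not terminate continuity; `filter_window = 0` is the
#' strict continuous definition.
#'
#' @param bonds a `bond_states` object (or a logical/binary matrix of
#'   occupation, bonds in rows, frames in columns, with attribute `dt` or
#'   with `dt` passed explicitly).
#' @param state `"HB"` or `"DB"`.
#' @param max_lag maximum lag in ps (must be shorter than the trajectory).
#' @param filter_window transient-interruption filter in ps (>= 0).
#' @param dt frame spacing override when `bonds` is a plain matrix.
#' @return object of class `survival_fn`: `lags` (ps), `values`, `counts`.
#' @export
survival_function <- function(bonds, state = c("HB", "DB"), max_lag,
                              filter_window = 0, dt = NULL) {
  state <- match.arg(state)
  if (inherits(bonds, "bond_states")) {
    occ <- bonds$state == 1L
    dt <- bonds$dt
  } else {
    occ <- bonds != 0
    if (is.null(dt)) dt <- attr(bonds, "dt")
    if (is.null(dt)) stop("dt must be supplied for a plain matrix",
                          call. = FALSE)
  }
  if (is.null(dim(occ))) occ <- matrix(occ, nrow = 1L)
  if (state == "DB") occ <- !occ
  nf <- ncol(occ)
  stopifnot(filter_window >= 0)
  lmax <- round(max_lag / dt)
  if (lmax >= nf) stop("max_lag must be shorter than the trajectory",
                       call. = FALSE)
  fw <- floor(filter_window / dt + 1e-9)
  if (!any(occ)) stop(sprintf("state %s is never visited", state),
                      call. = FALSE)
  t_max_origin <- nf - lmax  # last admissible origin frame
  num <- numeric(lmax + 1L)
  n_origins <- 0
  for (b in seq_len(nrow(occ))) {
    v <- occ[b, ]
    r <- rle(v)
    if (fw > 0L) {
      ## interruptions shorter than the filter do not break continuity
      short_gap <- !r$values & r$lengths <= fw
      ## gaps at the very ends have no flanking occupation; keep them
      if (length(short_gap) > 0L) {
        short_gap[1L] <- FALSE
        short_gap[length(short_gap)] <- FALSE
      }
      r$values[short_gap] <- TRUE
      r <- rle(inverse.rle(r))
    }
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & starts <= t_max_origin
    if (!any(keep)) next
    a <- starts[keep]
    bnd <- pmin(ends[keep], t_max_origin)  # admissible origins: a..bnd
    n_origins <- n_origins + sum(bnd - a + 1L)
    e <- ends[keep]
    for (l in 0:lmax) {
      ## origins t0 in [a, bnd] with t0 + l <= episode end
      num[l + 1L] <- num[l + 1L] + sum(pmax(0L, pmin(e - l, bnd) - a + 1L))
    }
  }
  if (n_origins == 0L) stop(sprintf("state %s has no admissible origins",
                                    state), call. = FALSE)
  structure(list(lags = (0:lmax) * dt, values = num / n_origins,
                 counts = rep(n_origins, lmax + 1L), state = state, dt = dt),
            class = "survival_fn")
}

#' @export
print.survival_fn <- function(x, ...) {
  cat(sprintf("<survival_fn> state %s, %d lags up to %g ps, %d origins\n",
              x$state, length(x$lags), max(x$lags), x$counts[1]))
  invisible(x)
}

#' Lifetime from a survival function
#'
#' `tau` is the trapezoidal time integral of `S(t)`. With
#' `method = "integral"` the curve must have decayed below 0.05 within the
#' sampled lags, otherwise a truncation error is raised;
#' `method = "integral_with_tail"` adds an exponential-tail extrapolation
#' fitted to the last decade of the decay.
#'
#' @param surv a `survival_fn`.
#' @param method `"integral"` or `"integral_with_tail"`.
#' @return object of class `lifetime` with fields `tau` (ps) and `method`.
#' @export
lifetime <- function(surv, method = c("integral", "integral_with_tail")) {
  method <- match.arg(method)
  stopifnot(inherits(surv, "survival_fn"))
  s <- surv$values
  lg <- surv$lags
  tau <- sum(diff(lg) * (s[-1] + s[-length(s)]) / 2)
  tail_val <- s[length(s)]
  if (method == "integral") {
    if (tail_val > 0.05) {
      stop(sprintf(
        "survival function has not decayed (S = %.3f at max lag %g ps); %s",
        tail_val, max(lg), "increase max_lag or use integral_with_tail"),
        call. = FALSE)
    }
  } else {
    ## fit log S over the last decade of decay (S in [tail, 10*tail]),
    ## extrapolate the integral beyond the sampled window
    sel <- which(s > 0 & s <= min(10 * max(tail_val, 1e-12), 0.5))
    if (length(sel) >= 3L && tail_val > 0) {
      fit <- stats::lm(log(s[sel]) ~ lg[sel])
      slope <- unname(stats::coef(fit)[2])
      if (is.finite(slope) && slope < 0) {
        tau <- tau + tail_val * (-1 / slope)
      }
    }
  }
  if (tau <= 0) stop("non-positive lifetime", call. = FALSE)
  structure(list(tau = unname(tau), method = method), class = "lifetime")
}

#' @export
print.lifetime <- function(x, ...) {
  cat(sprintf("<lifetime> tau = %g ps (%s)\n", x$tau, x$method))
  invisible(x)
}
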