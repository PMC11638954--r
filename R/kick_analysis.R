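## comp-id per (molecule, frame) lookup built from filtered segments
segment_comp_matrix <- function(segments) {
  nf <- attr(segments, "n_frames")
  n_mol <- max(segments$mol)
  cm <- matrix(NA_integer_, n_mol, nf)
  for (i in seq_len(nrow(segments))) {
    cm[segments$mol[i], segments$start_frame[i]:segments$end_frame[i]] <-
      segments$comp_id[i]
  }
  cm
}

#' Detect intra-shell HB-to-DB "kick" events
#'
#' A kick is an HB-to-DB transition of a tagged O-H bond whose DB episode
#' lasts at least `t_db_min` and whose two molecules remain in each other's
#' filtered solvation shell for at least `t_persist` after the break. The
#' time origin `t0` is the time the tagged H-bond breaks (first DB frame).
#' Transitions where the partner simultaneously leaves the shell are
#' exchanges, not kicks, and are excluded by the persistence requirement.
#'
#' @param bonds a `bond_states` from [classify_bonds()].
#' @param segments a `shell_segments` from [filter_transients()] computed on
#'   the same trajectory.
#' @param t_db_min minimum DB episode duration in ps (suppresses single-frame
#'   librational flickers).
#' @param t_persist shell persistence window in ps after the break.
#' @return a `kick_events` data.frame: `event_id`, `mol` (donor), `h`,
#'   `acceptor`, `bond_row`, `frame0` (first DB frame), `t0` (ps),
#'   `db_frames`.
#' @export
detect_kicks <- function(bonds, segments, t_db_min = 0.05, t_persist = 0.5) {
  stopifnot(inherits(bonds, "bond_states"),
            inherits(segments, "shell_segments"))
  dt <- bonds$dt
  nf <- ncol(bonds$state)
  dbf <- max(1L, round(t_db_min / dt))
  pf <- max(1L, round(t_persist / dt))
  cm <- segment_comp_matrix(segments)
  defs <- attr(segments, "comp_defs")
  ## membership lookup: is molecule q in composition id c?
  member <- function(cid, q) {
    ok <- !is.na(cid)
    res <- logical(length(cid))
    res[ok] <- vapply(cid[ok], function(ci) q %in% defs[[ci]], logical(1))
    res
  }
  rows <- list()
  st <- bonds$state
  for (b in seq_len(nrow(st))) {
    v <- st[b, ]
    breaks <- which(v[-1] == 0L & v[-nf] == 1L) + 1L  # first DB frame
    if (length(breaks) == 0L) next
    r <- rle(v)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    db_len <- integer(nf)
    db_runs <- which(!as.logical(r$values))
    db_len[starts[db_runs]] <- r$lengths[db_runs]
    donor <- bonds$bonds$mol[b]
    for (f0 in breaks) {
      if (db_len[f0] < dbf) next
      partner <- bonds$acceptor[b, f0 - 1L]
      if (is.na(partner)) next
      f_hi <- f0 + pf
      if (f_hi > nf) next
      fr <- f0:f_hi
      if (!all(member(cm[donor, fr], partner))) next
      if (!all(member(cm[partner, fr], donor))) next
      rows[[length(rows) + 1L]] <- data.frame(
        mol = donor, h = bonds$bonds$h[b], acceptor = partner, bond_row = b,
        frame0 = f0, t0 = (f0 - 1) * dt, db_frames = db_len[f0])
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mol = integer(0), h = integer(0), acceptor = integer(0),
               bond_row = integer(0), frame0 = integer(0), t0 = numeric(0),
               db_frames = integer(0))
  df <- cbind(event_id = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  structure(df, dt = dt, class = c("kick_events", "data.frame"))
}

#' Event-synchronised kick traces
#'
#' Averages, over all kick events and on a symmetric lag grid around each
#' break time, (i) the O*-O distance of the kicked pair, (ii) the HB
#' indicator of the tagged bond, and (iii) the angle of the tagged O-H to the
#' surface normal. By construction the HB indicator equals 1 at lag `-dt`
#' and drops at lag 0.
#'
#' @param events a `kick_events` from [detect_kicks()].
#' @param traj the [wtraj()].
#' @param bonds the `bond_states` the events came from.
#' @param half_window half-width of the lag grid in ps.
#' @return data.frame `lag` (ps), `d_oo` (A), `hb` (mean indicator),
#'   `angle` (degrees), `n`.
#' @export
kick_traces <- function(events, traj, bonds, half_window = 1) {
  if (nrow(events) == 0L) stop("no kick events", call. = FALSE)
  dt <- traj$dt
  nf <- n_frames(traj)
  hw <- max(1L, round(half_window / dt))
  lags <- -hw:hw
  acc_d <- numeric(length(lags)); acc_h <- numeric(length(lags))
  acc_a <- numeric(length(lags)); nn <- integer(length(lags))
  for (i in seq_len(nrow(events))) {
    fr <- events$frame0[i] + lags
    ok <- fr >= 1L & fr <= nf
    if (!any(ok)) next
    d <- pair_o_distance(traj, events$mol[i], events$acceptor[i], fr[ok])
    h <- bonds$state[events$bond_row[i], fr[ok]]
    a <- angle_to_normal(traj, events$mol[i], events$h[i],
                         frames = fr[ok])
    acc_d[ok] <- acc_d[ok] + d
    acc_h[ok] <- acc_h[ok] + h
    acc_a[ok] <- acc_a[ok] + a
    nn[ok] <- nn[ok] + 1L
  }
  data.frame(lag = lags * dt, d_oo = acc_d / pmax(nn, 1L),
             hb = acc_h / pmax(nn, 1L), angle = acc_a / pmax(nn, 1L), n = nn)
}

#' Angle between an O-H bond and the surface normal
#'
#' Unsigned convention: `acos(|u_OH . n|) in [0, 90]` degrees, folding the
#' two confining walls together (0 = along the normal, 90 = in-plane). A
#' signed variant (`signed = TRUE`) returns values in `[0, 180]` degrees,
#' distinguishing the two walls.
#'
#' @param traj a [wtraj()].
#' @param molecule molecule index.
#' @param h which O-H bond (1 or 2).
#' @param normal_axis axis index of the surface normal (default from `traj`).
#' @param frames frames to evaluate (default all).
#' @param signed use the signed per-wall convention.
#' @return numeric vector of angles in degrees, one per frame.
#' @export
angle_to_normal <- function(traj, molecule, h, normal_axis = NULL,
                            frames = NULL, signed = FALSE) {
  if (is.null(normal_axis)) normal_axis <- traj$normal_axis
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  o <- traj$molecules$o[molecule]
  ha <- if (h == 1L) traj$molecules$h1[molecule] else traj$molecules$h2[molecule]
  if (is.na(ha)) stop("molecule has no such H atom", call. = FALSE)
  ro <- t(traj$coords[o, , frames, drop = TRUE])
  rh <- t(traj$coords[ha, , frames, drop = TRUE])
  if (length(frames) == 1L) { ro <- matrix(traj$coords[o, , frames], ncol = 3)
                              rh <- matrix(traj$coords[ha, , frames], ncol = 3) }
  u <- minimum_image_displacement(ro, rh, traj$cell)
  if (is.null(dim(u))) u <- matrix(u, ncol = 3L)
  nrm <- sqrt(rowSums(u^2))
  if (any(nrm < 1e-12)) stop("zero-length O-H vector", call. = FALSE)
  cosv <- u[, normal_axis] / nrm
  if (signed) acos(pmin(1, pmax(-1, cosv))) * 180 / pi
  else acos(pmin(1, abs(cosv))) * 180 / pi
}

#' Donor-acceptor recombination statistics after kicks
#'
#' Among kick events whose water pair re-forms any H-bond within
#' `t_rebond_max`, classifies the first re-formed bond by donor-acceptor
#' combination relative to the broken bond: `same` (same donor H, same
#' acceptor), `donor_other_h` (the donor's other H), `reversed_h1` /
#' `reversed_h2` (donor and acceptor roles swapped, with either H of the
#' former acceptor). Fractions sum to 1 over rebonded events.
#'
#' @param events a `kick_events`.
#' @param bonds the `bond_states` the events came from.
#' @param t_rebond_max rebonding window in ps.
#' @return list: `fractions` (named, sums to 1), `n_rebonded`, `n_events`,
#'   `fraction_rebonded`.
#' @export
recombination_stats <- function(events, bonds, t_rebond_max = 1) {
  if (nrow(events) == 0L) stop("no kick events", call. = FALSE)
  dt <- bonds$dt
  nf <- ncol(bonds$state)
  wf <- max(1L, round(t_rebond_max / dt))
  bm <- bonds$bonds$mol
  bh <- bonds$bonds$h
  combos <- c("same", "donor_other_h", "reversed_h1", "reversed_h2")
  counts <- stats::setNames(numeric(4), combos)
  n_reb <- 0L
  for (i in seq_len(nrow(events))) {
    don <- events$mol[i]; acc <- events$acceptor[i]
    f0 <- events$frame0[i]
    fr <- f0:min(nf, f0 + wf)
    ## candidate channels: donor's two bonds toward acc, acceptor's two
    ## bonds toward don
    row_of <- function(mm, hh) {
      r <- which(bm == mm & bh == hh)
      if (length(r) == 1L) r else NA_integer_
    }
    cand_rows <- c(row_of(don, events$h[i]),
                   row_of(don, if (events$h[i] == 1L) 2L else 1L),
                   row_of(acc, 1L), row_of(acc, 2L))
    cand_lab <- combos
    cand_to <- c(acc, acc, don, don)
    first_f <- rep(NA_integer_, length(cand_rows))
    for (k in seq_along(cand_rows)) {
      b <- cand_rows[k]
      if (is.na(b)) next
      hit <- which(bonds$state[b, fr] == 1L &
                     !is.na(bonds$acceptor[b, fr]) &
                     bonds$acceptor[b, fr] == cand_to[k])
      ## for the same channel, skip lag 0 (the bond is DB at f0 by def.)
      if (length(hit) > 0L) first_f[k] <- fr[hit[1]]
    }
    if (all(is.na(first_f))) next
    n_reb <- n_reb + 1L
    k <- which.min(first_f)
    counts[cand_lab[k]] <- counts[cand_lab[k]] + 1
  }
  if (n_reb == 0L) {
    return(list(fractions = counts, n_rebonded = 0L, n_events = nrow(events),
                fraction_rebonded = 0))
  }
  list(fractions = counts / n_reb, n_rebonded = n_reb,
       n_events = nrow(events), fraction_rebonded = n_reb / nrow(events))
}

#' Kick time scale and displacement amplitude
#'
#' `tau_kick` is the integral of the matched survival function: the survival
#' of the forward waiting time from every frame a bond spends in the HB
#' state (dense origins, bonds with at least one kick) to that bond's next
#' kick. For Poisson kicks at rate `lambda` per pair this recovers
#' `1/lambda`. `delta_sq_kick` is the mean squared in-plane displacement of
#' the donor O over the event window `[t0 - T, t0 + T]`; with
#' `baseline = TRUE` the trajectory MSD at lag `2T` is subtracted (see
#' [swe_displacement_amplitude()] for the rationale).
#'
#' @param events a `kick_events`.
#' @param bonds the `bond_states` the events came from.
#' @param traj unwrapped [wtraj()].
#' @param half_window amplitude window half-width `T` in ps.
#' @param max_lag waiting-time integration window in ps.
#' @param baseline subtract the lag-`2T` MSD baseline.
#' @param in_plane restrict displacement components (default auto from cell).
#' @param min_events minimum number of events (statistics guard).
#' @param method `"integral"` (truncation-guarded) or
#'   `"integral_with_tail"` (exponential tail fitted to the last decade).
#' @return list: `tau_kick` (ps), `delta_sq_kick` (A^2), `n_events`,
#'   `n_origins`, `baseline`.
#' @export
kick_time_and_amplitude <- function(events, bonds, traj, half_window = 0.5,
                                    max_lag = NULL, baseline = TRUE,
                                    in_plane = NULL, min_events = 30L,
                                    method = c("integral",
                                               "integral_with_tail")) {
  method <- match.arg(method)
  if (nrow(events) < min_events) {
    stop(sprintf("too few kick events (%d < %d) for stable statistics",
                 nrow(events), min_events), call. = FALSE)
  }
  dt <- bonds$dt
  nf <- ncol(bonds$state)
  if (is.null(max_lag)) max_lag <- (nf - 1) * dt / 2
  lmax <- min(nf - 1L, round(max_lag / dt))
  ## --- tau_kick: forward waiting from dense HB origins to the next kick ---
  waits <- numeric(0)
  for (b in unique(events$bond_row)) {
    kick_f <- sort(events$frame0[events$bond_row == b])
    hb_f <- which(bonds$state[b, ] == 1L)
    hb_f <- hb_f[hb_f <= nf - lmax]
    if (length(hb_f) == 0L) next
    idx <- findInterval(hb_f, kick_f) + 1L
    w <- ifelse(idx <= length(kick_f), (kick_f[idx] - hb_f) * dt, Inf)
    waits <- c(waits, w)
  }
  if (length(waits) == 0L) stop("no HB origins for tau_kick", call. = FALSE)
  lags <- (0:lmax) * dt
  ws <- sort(waits[is.finite(waits)])
  surv <- 1 - findInterval(lags, ws) / length(waits)
  tail_val <- surv[length(surv)]
  tau <- sum(diff(lags) * (surv[-1] + surv[-length(surv)]) / 2)
  if (method == "integral") {
    if (tail_val > 0.05) {
      stop(sprintf("kick waiting-time survival not decayed (%.3f at %g ps)",
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
  ## --- delta_sq_kick: windowed displacement with MSD baseline ------------
  comps <- diffusion_components(traj, in_plane)
  hw <- max(1L, round(half_window / dt))
  f1 <- events$frame0 - hw; f2 <- events$frame0 + hw
  ok <- f1 >= 1L & f2 <= nf
  d2 <- window_disp_sq(traj, events$mol[ok], f1[ok], f2[ok], comps)
  base <- 0
  if (baseline) {
    mm <- msd(traj, lag_grid = 2 * hw * dt, in_plane = length(comps) == 2L)
    base <- mm$msd[mm$lag > 0][1]
  }
  list(tau_kick = tau, delta_sq_kick = mean(d2) - base,
       n_events = nrow(events), n_origins = length(waits), baseline = base,
       survival = data.frame(lag = lags, value = surv))
}
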