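## Independent oracles and tiny fixture builders used across the suite.
## These deliberately re-derive results with the most literal method
## available (exhaustive image search, per-donor loops, closed forms) so the
## package implementations are checked against a separate code path.

## exhaustive 27-image minimum-image displacement (orthorhombic)
mi_brute <- function(r1, r2, box, periodic = c(TRUE, TRUE, TRUE)) {
  shifts <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  shifts[, !periodic] <- 0
  shifts <- unique(shifts)
  d <- t(t(shifts) * box) + matrix(r2 - r1, nrow(shifts), 3, byrow = TRUE)
  d[which.min(rowSums(d^2)), ]
}

## literal per-donor H-bond classification (criterion: R_OO and deviation
## from linearity at H), returning state and acceptor matrices
classify_brute <- function(traj, r_oo_max = 3.5, angle_max = 30) {
  mols <- traj$molecules
  n_mol <- nrow(mols)
  box <- diag(traj$cell$vectors)
  per <- traj$cell$periodic
  nf <- dim(traj$coords)[3]
  nb <- 2L * n_mol
  state <- matrix(0L, nb, nf)
  acceptor <- matrix(NA_integer_, nb, nf)
  for (f in seq_len(nf)) {
    ro <- traj$coords[mols$o, , f]
    for (m in seq_len(n_mol)) {
      for (h in 1:2) {
        hi <- if (h == 1) mols$h1[m] else mols$h2[m]
        rh <- traj$coords[hi, , f]
        best_dev <- Inf; best_roo <- Inf; best_a <- NA_integer_
        for (a in seq_len(n_mol)) {
          if (a == m) next
          d_oo <- mi_brute(ro[m, ], ro[a, ], box, per)
          roo <- sqrt(sum(d_oo^2))
          if (roo > r_oo_max) next
          v1 <- mi_brute(ro[m, ], rh, box, per)      # O_d -> H
          v2 <- mi_brute(rh, ro[a, ], box, per)      # H -> O_a
          dev <- acos(max(-1, min(1, sum(v1 * v2) /
                                    sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
          if (dev > angle_max) next
          if (dev < best_dev - 1e-12 ||
              (abs(dev - best_dev) <= 1e-12 && roo < best_roo)) {
            best_dev <- dev; best_roo <- roo; best_a <- a
          }
        }
        b <- 2L * (m - 1L) + h
        if (!is.na(best_a)) {
          state[b, f] <- 1L
          acceptor[b, f] <- best_a
        }
      }
    }
  }
  list(state = state, acceptor = acceptor)
}

## per-donor oracle with direct orthorhombic component folding; independent
## of the package path (which builds a global candidate pair list and folds
## in fractional coordinates), but fast enough for hundreds of molecules
classify_brute_fast <- function(traj, r_oo_max = 3.5, angle_max = 30) {
  mols <- traj$molecules
  n_mol <- nrow(mols)
  box <- diag(traj$cell$vectors)
  per <- traj$cell$periodic
  fold <- function(d) {
    for (k in which(per)) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    d
  }
  nf <- dim(traj$coords)[3]
  nb <- 2L * n_mol
  state <- matrix(0L, nb, nf)
  acceptor <- matrix(NA_integer_, nb, nf)
  for (f in seq_len(nf)) {
    ro <- traj$coords[mols$o, , f]
    for (m in seq_len(n_mol)) {
      d_oo <- fold(ro - matrix(ro[m, ], n_mol, 3, byrow = TRUE))
      roo <- sqrt(rowSums(d_oo^2))
      cand <- which(roo <= r_oo_max)
      cand <- cand[cand != m]
      if (length(cand) == 0L) next
      for (h in 1:2) {
        hi <- if (h == 1) mols$h1[m] else mols$h2[m]
        rh <- traj$coords[hi, , f]
        v1 <- fold(matrix(rh - ro[m, ], 1, 3))
        v2 <- fold(ro[cand, , drop = FALSE] -
                     matrix(rh, length(cand), 3, byrow = TRUE))
        cosv <- (v2 %*% t(v1 / sqrt(sum(v1^2))))[, 1] / sqrt(rowSums(v2^2))
        dev <- acos(pmax(-1, pmin(1, cosv))) * 180 / pi
        ok <- dev <= angle_max
        if (!any(ok)) next
        sel <- cand[ok][order(dev[ok], roo[cand][ok])[1]]
        b <- 2L * (m - 1L) + h
        state[b, f] <- 1L
        acceptor[b, f] <- sel
      }
    }
  }
  list(state = state, acceptor = acceptor)
}

## build a wtraj from a list of per-frame coordinate matrices
make_traj <- function(frames, dt = 0.01, box = c(20, 20, 20),
                      periodic = c(TRUE, TRUE, TRUE), species = NULL,
                      molecules = NULL, normal_axis = 3L) {
  coords <- array(unlist(frames), c(nrow(frames[[1]]), 3L, length(frames)))
  wtraj(coords, dt = dt, cell = cell(box, periodic), species = species,
        molecules = molecules, normal_axis = normal_axis)
}

## water molecule helper: O at `o`, H1 toward `toward` (unit direction),
## H2 toward `h2_dir`
water_at <- function(o, toward, h2_dir = c(0, 0, 1), oh = 0.97) {
  u1 <- toward / sqrt(sum(toward^2))
  u2 <- h2_dir / sqrt(sum(h2_dir^2))
  rbind(o, o + oh * u1, o + oh * u2)
}

## score detected vs planted events on (molecule, time) within a tolerance;
## one-to-one greedy matching
score_events <- function(det_mol, det_t, pl_mol, pl_t, tol) {
  used <- rep(FALSE, length(det_mol))
  hits <- 0L
  for (i in seq_along(pl_mol)) {
    j <- which(!used & det_mol == pl_mol[i] & abs(det_t - pl_t[i]) <= tol)
    if (length(j)) { used[j[1]] <- TRUE; hits <- hits + 1L }
  }
  list(recall = hits / length(pl_mol),
       matched_detections = sum(used), n_detected = length(det_mol))
}

## bond_states constructed directly from a state matrix (+ acceptors)
make_bonds <- function(state, acceptor = NULL, mol = NULL, h = NULL,
                       dt = 0.01, n_mol = NULL) {
  state <- as.matrix(state)
  if (is.null(acceptor)) acceptor <- matrix(NA_integer_, nrow(state),
                                            ncol(state))
  if (is.null(mol)) mol <- seq_len(nrow(state))
  if (is.null(h)) h <- rep(1L, nrow(state))
  if (is.null(n_mol)) n_mol <- max(mol)
  slitdyn:::new_bond_states(state, acceptor, data.frame(mol = mol, h = h),
                            dt, n_mol)
}

## shell segments constructed directly (planted ground truth in tests)
make_segments <- function(df, comp_defs, dt, nf) {
  df$t_start <- (df$start_frame - 1) * dt
  df$t_end <- (df$end_frame - 1) * dt
  slitdyn:::new_shell_segments(df, comp_defs, dt, nf)
}

make_events <- function(df, segments) {
  slitdyn:::new_swe_events(df, segments)
}
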