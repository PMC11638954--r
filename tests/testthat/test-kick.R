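## two-molecule fixture: bond (mol 1, H1) -> mol 2 breaks at frame f0 with a
## distance step `lead` frames earlier; everything else stays bonded
kick_fixture <- function(f0 = 30L, nf = 60L, lead = 2L, d0 = 2.8, d1 = 3.2,
                         db_len = 6L, dt = 0.01) {
  state <- matrix(1L, 4L, nf)
  state[1, f0:(f0 + db_len - 1L)] <- 0L
  acceptor <- matrix(NA_integer_, 4L, nf)
  acceptor[1, state[1, ] == 1L] <- 2L
  acceptor[3, ] <- 1L   # mol 2 H1 donates back so the pair stays shelled
  bonds <- make_bonds(state, acceptor, mol = c(1L, 1L, 2L, 2L),
                      h = c(1L, 2L, 1L, 2L), dt = dt, n_mol = 2L)
  frames <- lapply(seq_len(nf), function(f) {
    d <- if (f >= f0 - lead) d1 else d0
    o1 <- c(10, 10, 10); o2 <- c(10 + d, 10, 10)
    hb <- state[1, f] == 1L
    h1a <- if (hb) o1 + 0.97 * c(1, 0, 0) else o1 + 0.97 * c(0, 0, 1)
    rbind(o1, h1a, o1 + 0.97 * c(0, 1, 0),
          o2, o2 + 0.97 * c(-1, 0, 0), o2 + 0.97 * c(0, 1, 0))
  })
  traj <- make_traj(frames, dt = dt, box = c(40, 40, 40),
                    periodic = c(TRUE, TRUE, FALSE),
                    species = rep(c("O", "H", "H"), 2))
  segments <- make_segments(
    data.frame(mol = c(1L, 2L), comp_id = c(1L, 2L), start_frame = c(1L, 1L),
               end_frame = c(nf, nf)),
    comp_defs = list(2L, 1L), dt = dt, nf = nf)
  list(bonds = bonds, traj = traj, segments = segments, f0 = f0, dt = dt)
}

test_that("planted HB break inside an intact shell is one kick event", {
  fx <- kick_fixture()
  ev <- detect_kicks(fx$bonds, fx$segments, t_db_min = 0.05, t_persist = 0.1)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$mol, 1L)
  expect_equal(ev$acceptor, 2L)
  expect_equal(ev$t0, (fx$f0 - 1) * fx$dt)
  ## no HB breaks at all: zero events is a valid result
  quiet <- make_bonds(matrix(1L, 2, 30),
                      matrix(c(2L, 1L), 2, 30), mol = c(1L, 2L),
                      h = c(1L, 1L), n_mol = 2L)
  seg <- make_segments(data.frame(mol = 1:2, comp_id = 1:2,
                                  start_frame = 1L, end_frame = 30L),
                       comp_defs = list(2L, 1L), dt = 0.01, nf = 30L)
  expect_equal(nrow(detect_kicks(quiet, seg)), 0L)
})

test_that("a break whose partner leaves the shell is not a kick", {
  fx <- kick_fixture()
  ## partner drops out of the filtered shell at the break: an exchange
  seg2 <- make_segments(
    data.frame(mol = c(1L, 1L, 2L), comp_id = c(1L, 3L, 2L),
               start_frame = c(1L, fx$f0, 1L),
               end_frame = c(fx$f0 - 1L, 60L, 60L)),
    comp_defs = list(2L, 1L, integer(0)), dt = fx$dt, nf = 60L)
  ev <- detect_kicks(fx$bonds, seg2, t_db_min = 0.05, t_persist = 0.1)
  expect_equal(nrow(ev), 0L)
  ## a DB episode shorter than t_db_min is a librational flicker, not a kick
  ev2 <- detect_kicks(fx$bonds, fx$segments, t_db_min = 0.1, t_persist = 0.1)
  expect_equal(nrow(ev2), 0L)
})

test_that("event traces show the distance step leading the indicator drop", {
  fx <- kick_fixture(lead = 2L)
  ev <- detect_kicks(fx$bonds, fx$segments, t_db_min = 0.05, t_persist = 0.1)
  tr <- kick_traces(ev, fx$traj, fx$bonds, half_window = 0.1)
  i0 <- which(tr$lag == 0)
  ## indicator is 1 at all lags < 0 and drops exactly at 0
  expect_true(all(tr$hb[tr$lag < 0] == 1))
  expect_equal(tr$hb[i0], 0)
  ## the distance has already risen two frames before the label change
  expect_equal(tr$d_oo[i0 - 3], 2.8, tolerance = 1e-6)
  expect_equal(tr$d_oo[i0 - 2], 3.2, tolerance = 1e-6)
  expect_equal(tr$d_oo[i0 - 1], 3.2, tolerance = 1e-6)
  ## the tagged O-H reorients from in-plane to along the normal
  expect_equal(tr$angle[i0 - 1], 90, tolerance = 1e-6)
  expect_equal(tr$angle[i0], 0, tolerance = 1e-6)
  ## identical events give zero-variance traces: averaging two copies of the
  ## same event reproduces the single-event trace exactly
  ev2 <- rbind(ev, ev); ev2$event_id <- 1:2
  ev2 <- structure(ev2, dt = fx$dt, class = c("kick_events", "data.frame"))
  tr2 <- kick_traces(ev2, fx$traj, fx$bonds, half_window = 0.1)
  expect_equal(tr2$d_oo, tr$d_oo)
  expect_equal(tr2$hb, tr$hb)
})

test_that("angle to the surface normal has the right closed forms", {
  o <- c(5, 5, 5)
  mk <- function(u) {
    make_traj(list(rbind(o, o + 0.97 * u / sqrt(sum(u^2)),
                         o + 0.97 * c(0, 1, 0))),
              box = c(10, 10, 10), periodic = c(TRUE, TRUE, FALSE),
              species = c("O", "H", "H"))
  }
  expect_equal(angle_to_normal(mk(c(0, 0, 1)), 1, 1), 0)
  expect_equal(angle_to_normal(mk(c(0, 0, -1)), 1, 1), 0)  # unsigned folds
  expect_equal(angle_to_normal(mk(c(1, 0, 0)), 1, 1), 90)
  expect_equal(angle_to_normal(mk(c(1, 0, 1)), 1, 1), 45, tolerance = 1e-9)
  expect_equal(angle_to_normal(mk(c(0, 0, -1)), 1, 1, signed = TRUE), 180)
})

test_that("recombination statistics classify planted rebond channels", {
  dt <- 0.01
  mk_case <- function(channel) {
    ## bond (1, h1) -> 2 breaks at frame 5; the pair rebonds at frame 10
    ## through the requested channel
    state <- matrix(0L, 4, 20); acceptor <- matrix(NA_integer_, 4, 20)
    state[1, 1:4] <- 1L; acceptor[1, 1:4] <- 2L
    row <- c(same = 1L, donor_other_h = 2L, reversed_h1 = 3L,
             reversed_h2 = 4L)[[channel]]
    state[row, 10:20] <- 1L
    acceptor[row, 10:20] <- if (row <= 2L) 2L else 1L
    bonds <- make_bonds(state, acceptor, mol = c(1L, 1L, 2L, 2L),
                        h = c(1L, 2L, 1L, 2L), dt = dt, n_mol = 2L)
    ev <- data.frame(event_id = 1L, mol = 1L, h = 1L, acceptor = 2L,
                     bond_row = 1L, frame0 = 5L, t0 = 4 * dt, db_frames = 5L)
    ev <- structure(ev, dt = dt, class = c("kick_events", "data.frame"))
    recombination_stats(ev, bonds, t_rebond_max = 0.1)
  }
  for (ch in c("same", "donor_other_h", "reversed_h1", "reversed_h2")) {
    rs <- mk_case(ch)
    expect_equal(unname(rs$fractions[ch]), 1)
    expect_equal(sum(rs$fractions), 1)
  }
  ## uniform random recombination over the four channels: each ~ 1/4
  set.seed(40)
  n_ev <- 10000L
  nf <- 12L
  state <- matrix(0L, 4L * n_ev, nf)
  acceptor <- matrix(NA_integer_, 4L * n_ev, nf)
  mols <- rep(seq_len(2L * n_ev), each = 2L)
  hs <- rep(c(1L, 2L), times = 2L * n_ev)
  ev_rows <- vector("list", n_ev)
  for (i in seq_len(n_ev)) {
    b0 <- 4L * (i - 1L)             # rows b0+1..b0+4: pair (2i-1, 2i)
    m1 <- 2L * i - 1L; m2 <- 2L * i
    state[b0 + 1L, 1:2] <- 1L; acceptor[b0 + 1L, 1:2] <- m2
    ch <- sample.int(4L, 1L)
    state[b0 + ch, 8:12] <- 1L
    acceptor[b0 + ch, 8:12] <- if (ch <= 2L) m2 else m1
    ev_rows[[i]] <- data.frame(event_id = i, mol = m1, h = 1L,
                               acceptor = m2, bond_row = b0 + 1L,
                               frame0 = 3L, t0 = 2 * dt, db_frames = 5L)
  }
  bonds <- make_bonds(state, acceptor, mol = mols, h = hs, dt = dt,
                      n_mol = 2L * n_ev)
  ev <- structure(do.call(rbind, ev_rows), dt = dt,
                  class = c("kick_events", "data.frame"))
  rs <- recombination_stats(ev, bonds, t_rebond_max = 0.1)
  expect_equal(rs$n_rebonded, n_ev)
  expect_true(all(abs(rs$fractions - 0.25) < 0.03))
})

test_that("kick time and amplitude recover planted Poisson kinetics", {
  set.seed(23)
  dt <- 0.01; nf <- 4000L; n_bonds <- 60L; lambda <- 2
  state <- matrix(1L, n_bonds, nf)
  kick_list <- vector("list", n_bonds)    # Poisson kick times per bond
  iso_list <- vector("list", n_bonds)     # isolated subset (for amplitudes)
  step <- 0.8
  coords <- array(0, c(n_bonds, 3L, nf))
  x <- matrix(0, n_bonds, nf)
  for (b in seq_len(n_bonds)) {
    kf <- which(stats::runif(nf) < lambda * dt)
    kf <- kf[kf > 10 & kf < nf - 10]
    kick_list[[b]] <- kf
    ## displacements only at isolated kicks so event windows never overlap
    iso <- kf[c(TRUE, diff(kf) > 20L) & c(diff(kf) > 20L, TRUE)]
    iso_list[[b]] <- iso
    if (length(iso)) {
      inc <- numeric(nf); inc[iso] <- step * sample(c(-1, 1), length(iso),
                                                    replace = TRUE)
      x[b, ] <- cumsum(inc)
    }
  }
  coords[, 1, ] <- x
  traj <- wtraj(coords, dt = dt,
                cell = cell(rep(1e5, 3), periodic = c(FALSE, FALSE, FALSE)),
                species = rep("O", n_bonds),
                molecules = data.frame(o = seq_len(n_bonds),
                                       h1 = NA_integer_, h2 = NA_integer_))
  mk_ev <- function(lst) {
    ev <- do.call(rbind, lapply(seq_len(n_bonds), function(b) {
      kf <- lst[[b]]
      if (!length(kf)) return(NULL)
      data.frame(mol = b, h = 1L, acceptor = NA_integer_, bond_row = b,
                 frame0 = kf, t0 = (kf - 1) * dt, db_frames = 1L)
    }))
    structure(cbind(event_id = seq_len(nrow(ev)), ev), dt = dt,
              class = c("kick_events", "data.frame"))
  }
  bonds <- make_bonds(state, mol = seq_len(n_bonds), h = rep(1L, n_bonds),
                      dt = dt, n_mol = n_bonds)
  ## Poisson kicks at rate lambda per pair: tau_kick = 1/lambda
  ke_tau <- kick_time_and_amplitude(mk_ev(kick_list), bonds, traj,
                                    half_window = 0.05, max_lag = 6,
                                    baseline = FALSE, in_plane = FALSE)
  expect_equal(ke_tau$tau_kick, 1 / lambda, tolerance = 0.05)
  ## isolated planted 0.8 A kicks: delta^2 = 0.64 exactly
  ke <- kick_time_and_amplitude(mk_ev(iso_list), bonds, traj,
                                half_window = 0.05, max_lag = 6,
                                baseline = FALSE, in_plane = FALSE)
  expect_equal(ke$delta_sq_kick, 0.64, tolerance = 1e-9)
  ## doubling the displacement quadruples the amplitude
  traj2 <- traj; traj2$coords <- traj$coords * 2
  ke2 <- kick_time_and_amplitude(mk_ev(iso_list), bonds, traj2,
                                 half_window = 0.05, max_lag = 6,
                                 baseline = FALSE, in_plane = FALSE)
  expect_equal(ke2$delta_sq_kick / ke$delta_sq_kick, 4, tolerance = 1e-9)
})
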