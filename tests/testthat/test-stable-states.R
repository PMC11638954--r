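test_that("shell series from bonds and from distances", {
  ## isolated molecule: empty shell in every frame
  w <- water_at(c(10, 10, 10), toward = c(1, 0, 0))
  tr <- make_traj(list(w, w), box = c(20, 20, 20),
                  species = c("O", "H", "H"))
  b <- classify_bonds(tr)
  sh <- shell_series(b, "hbond")
  expect_equal(sh$comp_defs[[sh$comp[1, 1]]], integer(0))
  ## static trimer with W* donating to both neighbours: shell = {2, 3}
  w1 <- water_at(c(5, 5, 5), toward = c(1, 0, 0), h2_dir = c(0, 1, 0))
  w2 <- water_at(c(7.8, 5, 5), toward = c(1, 0.2, 0), h2_dir = c(0, 0, 1))
  w3 <- water_at(c(5, 7.8, 5), toward = c(0.2, 1, 0), h2_dir = c(0, 0, 1))
  tr3 <- make_traj(list(rbind(w1, w2, w3), rbind(w1, w2, w3)),
                   box = c(30, 30, 30), species = rep(c("O", "H", "H"), 3))
  b3 <- classify_bonds(tr3)
  sh3 <- shell_series(b3, "hbond")
  expect_equal(sh3$comp_defs[[sh3$comp[1, 1]]], c(2L, 3L))
  expect_equal(sh3$comp[1, 1], sh3$comp[1, 2])
  ## distance mode with r_shell at the lattice spacing gives the same shells
  shd <- shell_series(mode = "distance", r_shell = 2.9, traj = tr3)
  expect_equal(shd$comp_defs[[shd$comp[1, 1]]],
               sh3$comp_defs[[sh3$comp[1, 1]]])
  ## distance mode without a radius is a config error
  expect_error(shell_series(mode = "distance", traj = tr3), "r_shell")
})

test_that("transient filtering produces stable segments", {
  dt <- 0.01
  mk_shells <- function(v) {
    slitdyn:::new_shell_series(matrix(v, 1), as.list(seq_len(max(v))), dt)
  }
  ## constant shell: one segment spanning the trajectory
  seg <- filter_transients(mk_shells(rep(1L, 100)), t_filter = 0.03)
  expect_equal(nrow(seg), 1L)
  expect_equal(c(seg$start_frame, seg$end_frame), c(1L, 100L))
  ## one-frame flicker with t_filter = 3 dt is erased
  v <- rep(1L, 60); v[30] <- 2L
  seg2 <- filter_transients(mk_shells(v), t_filter = 3 * dt)
  expect_equal(nrow(seg2), 1L)
  ## planted two-segment history with 5 flickers: exactly 2 segments with
  ## the boundary at the planted switch within the filter window
  v3 <- c(rep(1L, 100), rep(2L, 100))
  set.seed(8)
  for (k in sample(setdiff(2:198, 95:105), 5)) {
    v3[k] <- 3L
  }
  seg3 <- filter_transients(mk_shells(v3), t_filter = 0.02)
  expect_equal(nrow(seg3), 2L)
  expect_equal(seg3$comp_id, c(1L, 2L))
  expect_lte(abs(seg3$end_frame[1] - 100L), 2L)
  ## zero filter keeps genuine short states
  seg4 <- filter_transients(mk_shells(v), t_filter = 0)
  expect_equal(nrow(seg4), 3L)
  ## segments tile the trajectory without overlap
  expect_equal(seg3$start_frame[2], seg3$end_frame[1] + 1L)
})

## three point molecules with |O1-O2| and |O1-O3| linear in time, crossing
## between frames 51 and 52 (analytic t0 = 50.5 dt)
crossing_fixture <- function(dt = 0.01, nf = 100L) {
  frames <- lapply(seq_len(nf), function(f) {
    rbind(c(50, 50, 50),
          c(50 + 2 + 0.02 * (f - 1), 50, 50),
          c(50, 50 + 4.02 - 0.02 * (f - 1), 50))
  })
  tr <- make_traj(frames, dt = dt, box = c(100, 100, 100),
                  species = rep("O", 3),
                  molecules = data.frame(o = 1:3, h1 = NA_integer_,
                                         h2 = NA_integer_))
  seg <- make_segments(
    data.frame(mol = c(1L, 1L), comp_id = c(1L, 2L),
               start_frame = c(1L, 52L), end_frame = c(51L, nf)),
    comp_defs = list(2L, 3L), dt = dt, nf = nf)
  list(traj = tr, segments = seg)
}

test_that("SWE detection interpolates the equidistance crossing", {
  fx <- crossing_fixture()
  ev <- detect_swe(fx$segments, fx$traj)
  expect_equal(nrow(ev), 1L)
  expect_true(ev$resolved)
  expect_equal(ev$w_a, 2L)
  expect_equal(ev$w_b, 3L)
  expect_equal(ev$t0, 50.5 * 0.01, tolerance = 0.01 / 2)
  ## a static trajectory yields zero events
  stat <- make_traj(rep(list(rbind(c(1, 1, 1), c(3, 1, 1))), 20),
                    box = c(10, 10, 10), species = c("O", "O"),
                    molecules = data.frame(o = 1:2, h1 = NA_integer_,
                                           h2 = NA_integer_))
  seg1 <- make_segments(data.frame(mol = 1L, comp_id = 1L, start_frame = 1L,
                                   end_frame = 20L),
                        comp_defs = list(2L), dt = 0.01, nf = 20L)
  expect_equal(nrow(detect_swe(seg1, stat)), 0L)
})

test_that("SWE detection is invariant under molecule relabelling", {
  fx <- crossing_fixture()
  ## permutation swapping molecules 2 and 3 (coordinates and compositions)
  perm <- c(1L, 3L, 2L)
  tr2 <- fx$traj
  tr2$coords <- tr2$coords[perm, , , drop = FALSE]
  seg2 <- make_segments(
    data.frame(mol = c(1L, 1L), comp_id = c(1L, 2L),
               start_frame = c(1L, 52L), end_frame = c(51L, 100L)),
    comp_defs = list(3L, 2L), dt = 0.01, nf = 100L)
  ev1 <- detect_swe(fx$segments, fx$traj)
  ev2 <- detect_swe(seg2, tr2)
  expect_equal(ev2$t0, ev1$t0)
  expect_equal(ev2$w_a, 3L)  # relabelled identity of the departing partner
  expect_equal(ev2$w_b, 2L)
})

test_that("distance traces cross at the time origin and reverse in time", {
  fx <- crossing_fixture()
  ev <- detect_swe(fx$segments, fx$traj)
  trc <- swe_distance_traces(ev, fx$traj, half_window = 0.3)
  i0 <- which(trc$lag == 0)
  expect_lt(abs(trc$d_oa[i0] - trc$d_ob[i0]), 0.05)
  ## planted linear distances are recovered along the whole window
  expect_equal(trc$d_oa[i0 + 10], 2 + 0.02 * 60.5, tolerance = 0.03)
  ## reversing time swaps the roles of the departing/arriving partner
  tr_rev <- fx$traj
  tr_rev$coords <- fx$traj$coords[, , 100:1, drop = FALSE]
  seg_rev <- make_segments(
    data.frame(mol = c(1L, 1L), comp_id = c(1L, 2L),
               start_frame = c(1L, 50L), end_frame = c(49L, 100L)),
    comp_defs = list(3L, 2L), dt = 0.01, nf = 100L)
  ev_rev <- detect_swe(seg_rev, tr_rev)
  expect_equal(ev_rev$w_a, 3L)
  expect_equal(ev_rev$w_b, 2L)
  trc_rev <- swe_distance_traces(ev_rev, tr_rev, half_window = 0.3)
  expect_equal(trc_rev$d_oa, rev(trc$d_ob)[seq_len(nrow(trc_rev))],
               tolerance = 0.05)
})

test_that("displacement amplitude on constructed jumps", {
  dt <- 0.01; nf <- 100L
  ## planted 1 A jump between two static basins
  frames <- lapply(seq_len(nf), function(f) {
    matrix(c(if (f <= 50) 5 else 6, 5, 5), 1, 3)
  })
  tr <- make_traj(frames, dt = dt, box = c(50, 50, 50), species = "O",
                  molecules = data.frame(o = 1L, h1 = NA_integer_,
                                         h2 = NA_integer_))
  seg <- make_segments(data.frame(mol = c(1L, 1L), comp_id = c(1L, 2L),
                                  start_frame = c(1L, 51L),
                                  end_frame = c(50L, nf)),
                       comp_defs = list(2L, 3L), dt = dt, nf = nf)
  ev <- make_events(data.frame(event_id = 1L, transition_id = 1L, mol = 1L,
                               w_a = 2L, w_b = 3L, boundary_frame = 51L,
                               t0 = 49.5 * dt, resolved = TRUE), seg)
  for (conv in c("window", "centroid")) {
    amp <- swe_displacement_amplitude(ev, tr, convention = conv,
                                      half_window = 0.05, baseline = FALSE,
                                      in_plane = FALSE)
    expect_equal(amp$delta_sq, 1, tolerance = 1e-9)
  }
  ## a partner change without any O* motion has zero amplitude
  tr0 <- make_traj(rep(frames[1], nf), dt = dt, box = c(50, 50, 50),
                   species = "O",
                   molecules = data.frame(o = 1L, h1 = NA_integer_,
                                          h2 = NA_integer_))
  amp0 <- swe_displacement_amplitude(ev, tr0, half_window = 0.05,
                                     baseline = FALSE, in_plane = FALSE)
  expect_equal(amp0$delta_sq, 0)
})

test_that("exchange time on deterministic waiting times", {
  dt <- 0.01
  nf <- 201L
  T_wait <- 0.5
  n_mol <- 40L
  seg <- do.call(rbind, lapply(seq_len(n_mol), function(m) {
    data.frame(mol = m, comp_id = c(2L * m - 1L, 2L * m),
               start_frame = c(1L, 51L), end_frame = c(50L, nf))
  }))
  segments <- make_segments(seg, comp_defs = as.list(seq_len(2L * n_mol)),
                            dt = dt, nf = nf)
  ev <- make_events(data.frame(
    event_id = seq_len(n_mol), transition_id = seq_len(n_mol),
    mol = seq_len(n_mol), w_a = NA_integer_, w_b = NA_integer_,
    boundary_frame = 51L, t0 = rep(T_wait, n_mol), resolved = TRUE),
    segments)
  ## with max_lag equal to the whole trajectory only t = 0 is an origin, so
  ## every origin waits exactly T
  ts <- swe_time(ev, segments, max_lag = (nf - 1) * dt)
  expect_lt(abs(ts$tau_swe - T_wait), dt)
  ## doubling all waiting times doubles tau
  ev2 <- make_events(within(as.data.frame(ev), t0 <- 2 * t0),
                     make_segments(within(seg, end_frame <- end_frame + 200L),
                                   as.list(seq_len(2L * n_mol)), dt,
                                   nf + 200L))
  ts2 <- swe_time(ev2, attr(ev2, "segments"), max_lag = (nf + 199) * dt)
  expect_lt(abs(ts2$tau_swe - 2 * T_wait), 2 * dt)
})
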