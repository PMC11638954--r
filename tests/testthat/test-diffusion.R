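free_cell <- function() cell(rep(1e5, 3), periodic = c(FALSE, FALSE, FALSE))

point_traj <- function(x, dt = 0.01) {
  ## x: n_mol x n_frames matrix of x-coordinates (y = z = 0)
  coords <- array(0, c(nrow(x), 3L, ncol(x)))
  coords[, 1, ] <- x
  wtraj(coords, dt = dt, cell = free_cell(),
        species = rep("O", nrow(x)),
        molecules = data.frame(o = seq_len(nrow(x)), h1 = NA_integer_,
                               h2 = NA_integer_))
}

test_that("MSD closed forms: static and ballistic motion", {
  tr <- point_traj(matrix(2, 5, 200))
  mm <- msd(tr, in_plane = FALSE, lag_grid = seq(0.05, 0.5, by = 0.05))
  expect_true(all(mm$msd == 0))
  ## deterministic drift v: msd = (v t)^2
  v <- 0.7  # A/ps
  tr2 <- point_traj(matrix((0:199) * v * 0.01, 3, 200, byrow = TRUE))
  mm2 <- msd(tr2, in_plane = FALSE, lag_grid = seq(0.05, 0.5, by = 0.05))
  expect_equal(mm2$msd, (v * mm2$lag)^2, tolerance = 1e-10)
  ## sample counts never increase with the lag
  expect_true(all(diff(mm2$n) <= 0))
  expect_error(msd(tr, lag_grid = 10), "exceeds")
})

test_that("diffusion fit divides the slope by 2d", {
  lag <- seq(0, 6, by = 0.1)
  curve <- structure(data.frame(lag = lag, msd = 4 * 0.25 * lag,
                                n = rep(1000, length(lag))),
                     d = 2, dt = 0.1, class = c("msd_curve", "data.frame"))
  expect_equal(fit_diffusion(curve, c(1, 5)), 0.25)
  ## the same curve read as 3D motion: sensitivity to the dimension
  expect_equal(fit_diffusion(curve, c(1, 5), d = 3), 1 / 6, tolerance = 1e-9)
  ## a decreasing curve warns and reports the raw slope
  curve$msd <- -curve$msd
  expect_warning(D <- fit_diffusion(curve, c(1, 5)), "negative")
  expect_lt(D, 0)
})

test_that("frame MSD restricts displacement to persisting shells", {
  set.seed(77)
  nf <- 400L; n_mol <- 20L; dt <- 0.01
  x <- matrix(0, n_mol, nf)
  for (m in seq_len(n_mol)) x[m, ] <- cumsum(stats::rnorm(nf, sd = 0.1))
  tr <- point_traj(x, dt = dt)
  ## single never-changing shell: frame MSD equals the plain MSD exactly
  seg_all <- make_segments(data.frame(mol = seq_len(n_mol), comp_id = 1L,
                                      start_frame = 1L, end_frame = nf),
                           comp_defs = list(integer(0)), dt = dt, nf = nf)
  lg <- seq(0.02, 0.4, by = 0.02)
  m1 <- msd(tr, in_plane = FALSE, lag_grid = lg)
  m2 <- frame_msd(tr, seg_all, lag_grid = lg, in_plane = FALSE)
  expect_equal(m2$msd, m1$msd, tolerance = 1e-12)
  ## motion only at segment boundaries: frame D ~ 0
  xj <- matrix(0, n_mol, nf)
  xj[, 201:400] <- 3
  trj <- point_traj(xj, dt = dt)
  segj <- make_segments(do.call(rbind, lapply(seq_len(n_mol), function(m) {
    data.frame(mol = m, comp_id = c(2L * m - 1L, 2L * m),
               start_frame = c(1L, 201L), end_frame = c(200L, nf))
  })), comp_defs = as.list(seq_len(2L * n_mol)), dt = dt, nf = nf)
  mj <- frame_msd(trj, segj, lag_grid = lg, in_plane = FALSE)
  expect_true(all(mj$msd == 0))
  ## composite process: frame component recovered within 10%
  g <- gen_ctrw(tau_jump = 1, jump_sigma = 1.5, frame_D = 0.4, d = 2,
                n_walkers = 80, n_steps = 2000, dt = 0.01, seed = 19)
  fm <- frame_msd(g$traj, g$segments, lag_grid = seq(0.02, 0.5, by = 0.02))
  D_f <- fit_diffusion(fm, c(0.1, 0.4), d = 2)
  expect_equal(D_f, 0.4, tolerance = 0.1)
})

test_that("CTRW formulas and their scaling symmetries", {
  expect_equal(d_swe(0, 1, 2), 0)
  expect_equal(d_swe(1, 1, 2), 0.25)
  expect_equal(d_swe(1, 1, 3), 1 / 6)
  expect_error(d_swe(1, 0, 2), "positive")
  expect_equal(d_kick(1, 1, 2.5), 0.625)
  expect_equal(d_kick(1, 1, 1), 0.25)  # factor 1: single-pair CTRW in d = 2
  expect_error(d_kick(1, -1, 2.5), "positive")
  expect_error(d_kick(1, 1, 0), "positive")
  ## homogeneity: coordinates x c -> D x c^2; time x c -> D / c
  c_ <- 1.7
  expect_equal(d_swe(c_^2 * 3, 0.8, 2), c_^2 * d_swe(3, 0.8, 2))
  expect_equal(d_swe(3, c_ * 0.8, 2), d_swe(3, 0.8, 2) / c_)
  expect_equal(d_kick(c_^2 * 3, 0.8, 2.5), c_^2 * d_kick(3, 0.8, 2.5))
  expect_equal(d_kick(3, c_ * 0.8, 2.5), d_kick(3, 0.8, 2.5) / c_)
})

test_that("report assembly computes additivity residuals", {
  r <- assemble_report(d_total = 1, d_frame = 0.1, d_swe = 0.4,
                       d_kick = 0.45, d = 2, mode = "monolayer")
  expect_equal(r$additivity_residual, abs(1 - 0.85) / 1)
  expect_equal(r$D_total_cm2s, 10)
  rb <- assemble_report(d_total = 0.5, d_frame = 0.1, d_swe = 0.38,
                        d_kick = NA_real_, d = 3, mode = "bulk")
  expect_equal(rb$additivity_residual, abs(0.5 - 0.48) / 0.5)
  ## all-zero motion: residual defined as 0
  r0 <- assemble_report(d_total = 0, d_frame = 0, d_swe = 0, d_kick = 0,
                        d = 2, mode = "monolayer")
  expect_equal(r0$additivity_residual, 0)
  expect_error(assemble_report(d_total = 1, d_swe = 0.4, d = 2,
                               mode = "bulk"),
               "incomplete")
})

test_that("full MSD dominates frame MSD when jumps contribute", {
  g <- gen_ctrw(tau_jump = 0.5, jump_sigma = 1, frame_D = 0.2, d = 2,
                n_walkers = 40, n_steps = 1500, dt = 0.01, seed = 29)
  lg <- seq(0.05, 1, by = 0.05)
  m_full <- msd(g$traj, in_plane = FALSE, lag_grid = lg)
  m_frame <- frame_msd(g$traj, g$segments, lag_grid = lg, in_plane = FALSE)
  common <- intersect(round(m_full$lag, 6), round(m_frame$lag, 6))
  common <- setdiff(common, 0)
  expect_true(all(m_full$msd[match(common, round(m_full$lag, 6))] >=
                    m_frame$msd[match(common, round(m_frame$lag, 6))]))
})
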