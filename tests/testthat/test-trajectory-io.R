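test_that("extended-XYZ round trip preserves coordinates and cell", {
  g <- gen_toy_monolayer(n_side = 8, n_steps = 10, kick_sigma = 0,
                         kick_excursion = 0, swe_rate = 0, seed = 2)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_extxyz(g$traj, path)
  back <- read_trajectory(path, "extxyz", dt = g$traj$dt)
  expect_equal(dim(back$coords), dim(g$traj$coords))
  expect_lt(max(abs(back$coords - g$traj$coords)), 1e-6)
  expect_equal(back$cell$vectors, g$traj$cell$vectors)
  expect_equal(back$cell$periodic, g$traj$cell$periodic)
  ## molecules re-inferred by O-H proximity match the writer's topology
  expect_equal(back$molecules$o, g$traj$molecules$o)
  expect_equal(back$molecules$h1, g$traj$molecules$h1)
})

test_that("minimal extended-XYZ input and malformed frames", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c(
    "3", 'Lattice="10 0 0 0 10 0 0 0 10" pbc="T T T"',
    "O 1.0 1.0 1.0", "H 1.8 1.4 1.0", "H 1.0 1.9 1.2",
    "3", 'Lattice="10 0 0 0 10 0 0 0 10" pbc="T T T"',
    "O 1.1 1.0 1.0", "H 1.9 1.4 1.0", "H 1.1 1.9 1.2",
    "3", 'Lattice="10 0 0 0 10 0 0 0 10" pbc="T T T"',
    "O 1.2 1.0 1.0", "H 2.0 1.4 1.0", "H 1.2 1.9 1.2"), path)
  tr <- read_trajectory(path, "extxyz", dt = 0.01)
  expect_equal(nrow(tr$molecules), 1L)
  expect_equal(dim(tr$coords)[3], 3L)
  ## a frame with a missing atom is a format error
  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c(
    "3", 'Lattice="10 0 0 0 10 0 0 0 10"',
    "O 1.0 1.0 1.0", "H 1.8 1.4 1.0", "H 1.0 1.9 1.2",
    "2", 'Lattice="10 0 0 0 10 0 0 0 10"',
    "O 1.1 1.0 1.0", "H 1.9 1.4 1.0"), bad)
  expect_error(read_trajectory(bad, "extxyz", dt = 0.01),
               "inconsistent|truncated")
  ## no Lattice header -> non-periodic, periodic analyses refuse
  nolat <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "comment", "O 1.0 1.0 1.0",
               "1", "comment", "O 1.5 1.0 1.0"), nolat)
  tr2 <- read_trajectory(nolat, "extxyz", dt = 0.01)
  expect_false(any(tr2$cell$periodic))
  expect_error(rdf(tr2), "periodic")
})

test_that("PDB MODEL/ENDMDL frames are read with CRYST1 cell", {
  path <- withr::local_tempfile(fileext = ".pdb")
  at <- function(i, el, x, y, z) {
    sprintf("ATOM  %5d %-4s HOH A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, el, x, y, z, el)
  }
  writeLines(c(
    "CRYST1   10.000   10.000   10.000  90.00  90.00  90.00 P 1",
    "MODEL        1",
    at(1, "O", 1, 1, 1), at(2, "H", 1.8, 1.4, 1), at(3, "H", 1, 1.9, 1.2),
    "ENDMDL",
    "MODEL        2",
    at(1, "O", 1.1, 1, 1), at(2, "H", 1.9, 1.4, 1), at(3, "H", 1.1, 1.9, 1.2),
    "ENDMDL"), path)
  tr <- read_trajectory(path, dt = 0.02)
  expect_equal(dim(tr$coords)[3], 2L)
  expect_equal(nrow(tr$molecules), 1L)
  expect_equal(unname(cell_lengths <- sqrt(rowSums(tr$cell$vectors^2))),
               c(10, 10, 10))
  expect_equal(tr$dt, 0.02)
})

test_that("minimum-image displacement agrees with 27-image brute force", {
  set.seed(71)
  n <- 2000
  for (case in 1:2) {
    box <- c(8, 12, 17) * stats::runif(3, 0.5, 1.5)
    per <- if (case == 1) c(TRUE, TRUE, TRUE) else c(TRUE, TRUE, FALSE)
    cl <- cell(box, per)
    ## points within the primary cell (the 27-image search is exhaustive
    ## only for displacements inside one box length)
    r1 <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
                stats::runif(n, 0, box[3]))
    r2 <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
                stats::runif(n, 0, box[3]))
    d <- minimum_image_displacement(r1, r2, cl)
    for (i in seq(1, n, by = 37)) {
      expect_equal(unname(d[i, ]),
                   unname(mi_brute(r1[i, ], r2[i, ], box, per)),
                   tolerance = 1e-10)
    }
    ## folded components lie in [-L/2, L/2)
    for (k in which(per)) {
      expect_true(all(d[, k] >= -box[k] / 2 - 1e-9 & d[, k] < box[k] / 2 + 1e-9))
    }
  }
  ## identity and wrap cases
  cl <- cell(c(10, 10, 10))
  expect_equal(minimum_image_displacement(c(0, 0, 0), c(0, 0, 0), cl),
               c(0, 0, 0))
  expect_equal(minimum_image_displacement(c(9.5, 0, 0), c(0.5, 0, 0), cl),
               c(1, 0, 0))
  expect_error(minimum_image_displacement(c(0, 0, 0), c(1, 0, 0),
                                          cell(matrix(0, 3, 3))),
               "singular")
})

test_that("unwrap recovers planted drift across box crossings", {
  box <- c(10, 10, 10)
  nf <- 700
  v <- 0.05  # A/frame: 3.5 box lengths over the trajectory
  x <- (seq_len(nf) - 1) * v
  frames <- lapply(seq_len(nf), function(f) {
    matrix(c(x[f] %% 10, 5, 5), 1, 3)
  })
  tr <- make_traj(frames, dt = 0.01, box = box,
                  species = "O",
                  molecules = data.frame(o = 1L, h1 = NA_integer_,
                                         h2 = NA_integer_))
  u <- unwrap(tr)
  xs <- u$coords[1, 1, ]
  expect_true(all(diff(xs) > 0))  # monotone through the crossings
  slope <- stats::coef(stats::lm(xs ~ seq_len(nf)))[2]
  expect_equal(unname(slope), v, tolerance = 1e-9)
  ## stationary input is unchanged
  tr2 <- make_traj(rep(frames[1], 5), box = box, species = "O",
                   molecules = data.frame(o = 1L, h1 = NA_integer_,
                                          h2 = NA_integer_))
  expect_equal(unwrap(tr2)$coords, tr2$coords)
})

test_that("wrap then unwrap preserves minimum-image pair distances", {
  g <- gen_ctrw(tau_jump = 2, jump_sigma = 1, frame_D = 0.2, d = 3,
                n_walkers = 6, n_steps = 200, dt = 0.01, seed = 5)
  tr <- g$traj
  tr$cell <- cell(c(12, 12, 12))
  w <- wrap(tr)
  u <- unwrap(w)
  for (f in c(1L, 100L, 200L)) {
    for (pair in list(c(1, 2), c(3, 5))) {
      d1 <- minimum_image_displacement(tr$coords[pair[1], , f],
                                       tr$coords[pair[2], , f], tr$cell)
      d2 <- minimum_image_displacement(u$coords[pair[1], , f],
                                       u$coords[pair[2], , f], tr$cell)
      expect_equal(sqrt(sum(d1^2)), sqrt(sum(d2^2)), tolerance = 1e-9)
    }
  }
})

test_that("topology inference rejects unassignable hydrogens", {
  frames <- list(rbind(c(1, 1, 1), c(5, 5, 5)))  # H 6+ A from the O
  expect_error(
    make_traj(frames, species = c("O", "H")),
    "cannot be assigned")
})
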