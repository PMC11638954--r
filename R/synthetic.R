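## Run code with a private, restorable RNG stream so generators are
## deterministic (identical seed => identical output) without disturbing the
## caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Two-state telegraph bond-state series
#'
#' Markov HB/DB dynamics: each bond leaves HB at rate `k_off` and returns at
#' rate `k_on` (ps^-1), sampled on the frame grid. The stationary DB
#' fraction is `k_off / (k_on + k_off)` and the continuous HB (DB) survival
#' function is exactly `exp(-k_off t)` (`exp(-k_on t)`) on the grid.
#'
#' @param k_on DB->HB rate in ps^-1.
#' @param k_off HB->DB rate in ps^-1.
#' @param n_episodes approximate total number of state episodes to generate
#'   (sets the trajectory length).
#' @param dt frame spacing in ps; a warning is given when `dt` cannot
#'   resolve the kinetics.
#' @param seed RNG seed.
#' @param n_bonds number of independent bonds.
#' @param n_frames_gen explicit frame count (overrides the episode-based
#'   sizing; useful in the limit of very slow rates).
#' @return a `bond_states` object (acceptor ids are `NA`; there is no
#'   geometry behind a telegraph series).
#' @export
gen_telegraph <- function(k_on, k_off, n_episodes = 1e4, dt = 0.01, seed = 1,
                          n_bonds = 100L, n_frames_gen = NULL) {
  stopifnot(k_on > 0, k_off > 0, dt > 0)
  if (dt >= 1 / (k_on + k_off)) {
    warning("dt is too coarse to resolve the telegraph kinetics")
  }
  cycle <- 1 / k_on + 1 / k_off
  nfr <- if (!is.null(n_frames_gen)) as.integer(n_frames_gen) else
    max(10L, ceiling(n_episodes * cycle / dt / n_bonds / 2) + 1L)
  p_hb <- k_on / (k_on + k_off)
  p_off <- 1 - exp(-k_off * dt)
  p_on <- 1 - exp(-k_on * dt)
  with_seed(seed, {
    B <- matrix(0L, n_bonds, nfr)
    B[, 1] <- stats::rbinom(n_bonds, 1L, p_hb)
    for (f in 2:nfr) {
      prev <- B[, f - 1L]
      r <- stats::runif(n_bonds)
      B[, f] <- ifelse(prev == 1L, ifelse(r < p_off, 0L, 1L),
                       ifelse(r < p_on, 1L, 0L))
    }
    new_bond_states(B, matrix(NA_integer_, n_bonds, nfr),
                    data.frame(mol = seq_len(n_bonds), h = 1L),
                    dt, n_bonds)
  })
}

#' Jump + drift continuous-time random walk trajectories
#'
#' Independent walkers performing Brownian motion with diffusion constant
#' `frame_D` superposed with Poisson jumps (rate `1/tau_jump`) of Gaussian
#' per-component amplitude `jump_sigma` on the first `d` components. The
#' generator's closed-form diffusion constant,
#' `D_total = frame_D + jump_sigma^2 / (2 tau_jump)`, is returned in
#' `$true`. Jumps are logged as planted exchange events; the inter-jump
#' intervals are returned as stable-state segments so the SWE estimators can
#' be run against ground truth.
#'
#' @param tau_jump mean waiting time between jumps in ps (`Inf` for none).
#' @param jump_sigma per-component jump amplitude in Angstrom.
#' @param frame_D Brownian diffusion constant in A^2/ps.
#' @param d dimension of the motion (2 or 3).
#' @param n_walkers,n_steps,dt,seed simulation size and seed.
#' @return list: `traj` (non-periodic [wtraj()] of point particles),
#'   `events` (`swe_events`), `segments` (`shell_segments`), `true`
#'   (closed-form parameters).
#' @export
gen_ctrw <- function(tau_jump = 1, jump_sigma = 1, frame_D = 0, d = 2,
                     n_walkers = 100L, n_steps = 5000L, dt = 0.01, seed = 1) {
  stopifnot(tau_jump > 0, jump_sigma >= 0, frame_D >= 0, d %in% c(2, 3))
  with_seed(seed, {
    p_jump <- if (is.finite(tau_jump)) 1 - exp(-dt / tau_jump) else 0
    coords <- array(0, c(n_walkers, 3L, n_steps))
    sb <- sqrt(2 * frame_D * dt)
    jump_mask <- NULL
    for (c_ in seq_len(d)) {
      inc <- matrix(stats::rnorm(n_walkers * (n_steps - 1L), sd = sb),
                    n_walkers, n_steps - 1L)
      if (c_ == 1L) {
        jump_mask <- if (p_jump > 0) {
          matrix(stats::runif(n_walkers * (n_steps - 1L)) < p_jump,
                 n_walkers, n_steps - 1L)
        } else {
          matrix(FALSE, n_walkers, n_steps - 1L)
        }
      }
      if (p_jump > 0) {
        nj <- sum(jump_mask)
        inc[jump_mask] <- inc[jump_mask] +
          stats::rnorm(nj, sd = jump_sigma)
      }
      coords[, c_, -1L] <- t(apply(inc, 1L, cumsum))
    }
    cl <- cell(rep(1e6, 3L), periodic = c(FALSE, FALSE, FALSE))
    traj <- wtraj(coords, dt = dt, cell = cl,
                  species = rep("O", n_walkers),
                  molecules = data.frame(o = seq_len(n_walkers),
                                         h1 = NA_integer_, h2 = NA_integer_))
    ## planted events and segments (basins between jumps)
    ev_rows <- list(); seg_rows <- list(); cid <- 0L
    for (w in seq_len(n_walkers)) {
      jf <- which(jump_mask[w, ]) + 1L  # jump lands at frame jf
      bounds <- c(1L, jf, n_steps + 1L)
      for (s in seq_len(length(bounds) - 1L)) {
        cid <- cid + 1L
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          mol = w, comp_id = cid, start_frame = bounds[s],
          end_frame = bounds[s + 1L] - 1L)
      }
      if (length(jf)) {
        ev_rows[[length(ev_rows) + 1L]] <- data.frame(
          mol = w, boundary_frame = jf, t0 = (jf - 1.5) * dt)
      }
    }
    seg <- do.call(rbind, seg_rows)
    seg$t_start <- (seg$start_frame - 1) * dt
    seg$t_end <- (seg$end_frame - 1) * dt
    segments <- new_shell_segments(seg, as.list(seq_len(cid)), dt, n_steps)
    ev <- if (length(ev_rows)) do.call(rbind, ev_rows) else
      data.frame(mol = integer(0), boundary_frame = integer(0),
                 t0 = numeric(0))
    ev <- data.frame(event_id = seq_len(nrow(ev)),
                     transition_id = seq_len(nrow(ev)),
                     mol = ev$mol, w_a = rep(NA_integer_, nrow(ev)),
                     w_b = rep(NA_integer_, nrow(ev)),
                     boundary_frame = ev$boundary_frame, t0 = ev$t0,
                     resolved = rep(TRUE, nrow(ev)))
    events <- new_swe_events(ev, segments)
    d_jump <- if (is.finite(tau_jump)) jump_sigma^2 / (2 * tau_jump) else 0
    list(traj = traj, events = events, segments = segments,
         true = list(D_frame = frame_D, D_jump = d_jump,
                     D_total = frame_D + d_jump, tau_jump = tau_jump,
                     delta_sq = d * jump_sigma^2, d = d))
  })
}

## orthogonal-neighbour site indices on an n x n (x n) periodic lattice
lattice_site_index <- function(ij, n_side) {
  ## ij: matrix of 0-based integer lattice coordinates (rows = sites)
  ij <- ((ij %% n_side) + n_side) %% n_side
  if (ncol(ij) == 2L) 1L + ij[, 1] + n_side * ij[, 2]
  else 1L + ij[, 1] + n_side * ij[, 2] + n_side^2 * ij[, 3]
}

#' Toy quasi-2D monolayer water trajectory with planted kicks and exchanges
#'
#' Water oxygens sit on a jittered square lattice in a slab (periodic x/y,
#' confined z). Each molecule donates its two O-H bonds toward the +x and +y
#' neighbouring sites; bonds follow two-state telegraph kinetics with
#' stationary HB occupancy `p_hb` and DB lifetime `tau_db`. Every HB-to-DB
#' transition is a planted kick: the pair separates transiently by
#' `kick_excursion` (starting `kick_lead` before the break, reverting at
#' rebonding) and both molecules take a permanent random in-plane step of
#' per-component amplitude `kick_sigma` at the break. Solvation-water
#' exchanges are planted as diagonal site swaps at per-molecule stable-state
#' transition rate `swe_rate`; a swap moves two molecules by a*sqrt(2) and
#' changes the shell composition of six molecules (the two movers, 2-out/
#' 2-in, and four bystanders, 1-out/1-in). H atoms point at the actual
#' acceptor O when HB and along the +/- surface normal when DB, so the
#' geometric classifier can recover the planted states.
#'
#' The closed-form ground truth is returned in `$true`:
#' `D_kick = 2 p_hb k_off kick_sigma^2` (with `k_off` the HB->DB rate),
#' `D_SWE = swe_rate a^2 / 6`, `D_total = D_kick + D_SWE`.
#'
#' @param n_side lattice side; `n_side^2` molecules.
#' @param a lattice constant in Angstrom.
#' @param slab_height box height along z (non-periodic) in Angstrom.
#' @param dt,n_steps frame spacing (ps) and count.
#' @param p_hb stationary HB occupancy per bond. The default 0.63 is the
#'   compromise between a target DB fraction of 0.35 and a target mean
#'   coordination of 2.5, which the fixed-slot lattice couples as
#'   `coordination = 4 (1 - DB fraction)`.
#' @param tau_db mean DB (rebonding) time in ps.
#' @param kick_sigma per-component permanent kick step in Angstrom.
#' @param kick_excursion transient pair-separation amplitude in Angstrom.
#' @param kick_lead time by which the pair separation precedes the H-bond
#'   break, in ps.
#' @param swe_rate per-molecule stable-state transition rate in ps^-1.
#' @param morph_window swap morph time in ps (positions interpolate).
#' @param jitter per-component thermal position jitter in Angstrom.
#' @param oh_len O-H bond length in Angstrom.
#' @param seed RNG seed.
#' @return list: `traj` (wrapped [wtraj()]), `bonds` (planted
#'   `bond_states`), `segments` (planted `shell_segments`), `swe_events`,
#'   `kick_events`, `true` (closed-form parameters), `params`.
#' @export
gen_toy_monolayer <- function(n_side = 12L, a = 2.8, slab_height = 8,
                              dt = 0.02, n_steps = 2000L,
                              p_hb = 0.63, tau_db = 0.24,
                              kick_sigma = 0.374, kick_excursion = 0.4,
                              kick_lead = 0.04, swe_rate = 0.111,
                              morph_window = 0.08, jitter = 0.03,
                              oh_len = 0.97, seed = 1) {
  gen_toy_lattice(dim3 = FALSE, n_side = n_side, a = a,
                  slab_height = slab_height, dt = dt, n_steps = n_steps,
                  p_hb = p_hb, tau_db = tau_db, kick_sigma = kick_sigma,
                  kick_excursion = kick_excursion, kick_lead = kick_lead,
                  swe_rate = swe_rate, morph_window = morph_window,
                  jitter = jitter, oh_len = oh_len, seed = seed)
}

#' Toy 3D bulk water trajectory with planted exchanges
#'
#' 3D analogue of [gen_toy_monolayer()] on a fully periodic cubic lattice:
#' near-saturated H-bonding (default DB fraction 0.04), very short DB
#' episodes, no kick displacement (H-bond breaks in the bulk do not displace
#' the pair; motion is exchange-dominated), and diagonal-swap exchanges.
#'
#' @inheritParams gen_toy_monolayer
#' @return as [gen_toy_monolayer()].
#' @export
gen_toy_bulk <- function(n_side = 5L, a = 2.9, dt = 0.01, n_steps = 2000L,
                         p_hb = 0.96, tau_db = 0.03, kick_sigma = 0,
                         kick_excursion = 0, kick_lead = 0,
                         swe_rate = 0.2, morph_window = 0.04, jitter = 0.03,
                         oh_len = 0.97, seed = 1) {
  gen_toy_lattice(dim3 = TRUE, n_side = n_side, a = a, slab_height = NA,
                  dt = dt, n_steps = n_steps, p_hb = p_hb, tau_db = tau_db,
                  kick_sigma = kick_sigma, kick_excursion = kick_excursion,
                  kick_lead = kick_lead, swe_rate = swe_rate,
                  morph_window = morph_window, jitter = jitter,
                  oh_len = oh_len, seed = seed)
}

gen_toy_lattice <- function(dim3, n_side, a, slab_height, dt, n_steps,
                            p_hb, tau_db, kick_sigma, kick_excursion,
                            kick_lead, swe_rate, morph_window, jitter,
                            oh_len, seed) {
  stopifnot(p_hb > 0, p_hb < 1, tau_db > 0, n_steps >= 10L)
  n_dim_sites <- if (dim3) 3L else 2L
  N <- n_side^n_dim_sites
  nb <- 2L * N
  nfr <- as.integer(n_steps)
  k_on <- 1 / tau_db
  k_off <- k_on * (1 - p_hb) / p_hb
  lead_f <- round(kick_lead / dt)
  morph_f <- max(1L, round(morph_window / dt))
  with_seed(seed, {
    ## ---- lattice geometry ------------------------------------------------
    if (dim3) {
      grid <- as.matrix(expand.grid(x = 0:(n_side - 1L), y = 0:(n_side - 1L),
                                    z = 0:(n_side - 1L)))
      site_xyz <- (grid + 0.5) * a
      box <- rep(n_side * a, 3L)
      periodic <- c(TRUE, TRUE, TRUE)
    } else {
      grid <- as.matrix(expand.grid(x = 0:(n_side - 1L), y = 0:(n_side - 1L)))
      site_xyz <- cbind((grid + 0.5) * a, slab_height / 2)
      box <- c(n_side * a, n_side * a, slab_height)
      periodic <- c(TRUE, TRUE, FALSE)
    }
    shift_site <- function(sites0, dx, dy) {
      ij <- grid[sites0, , drop = FALSE]
      ij[, 1] <- ij[, 1] + dx
      ij[, 2] <- ij[, 2] + dy
      lattice_site_index(ij, n_side)
    }
    ## orth neighbour sites (x+/-, y+/-) of every site; shells & slots live
    ## in the xy plane in both geometries
    nb_xp <- shift_site(seq_len(N), 1L, 0L)
    nb_xm <- shift_site(seq_len(N), -1L, 0L)
    nb_yp <- shift_site(seq_len(N), 0L, 1L)
    nb_ym <- shift_site(seq_len(N), 0L, -1L)
    orth_nb <- cbind(nb_xp, nb_xm, nb_yp, nb_ym)
    ## ---- bond telegraph --------------------------------------------------
    p_off <- 1 - exp(-k_off * dt)
    p_on <- 1 - exp(-k_on * dt)
    B <- matrix(0L, nb, nfr)
    B[, 1] <- stats::rbinom(nb, 1L, p_hb)
    for (f in 2:nfr) {
      prev <- B[, f - 1L]
      r <- stats::runif(nb)
      B[, f] <- ifelse(prev == 1L, ifelse(r < p_off, 0L, 1L),
                       ifelse(r < p_on, 1L, 0L))
    }
    bond_mol <- rep(seq_len(N), each = 2L)
    bond_h <- rep(c(1L, 2L), times = N)
    ## ---- swaps (solvation water exchanges) -------------------------------
    S_total <- swe_rate * N / 6
    n_sw_frame <- stats::rpois(nfr, S_total * dt)
    n_sw_frame[1] <- 0L
    site_of_mol <- seq_len(N)
    SM <- matrix(0L, N, nfr)
    SM[, 1] <- site_of_mol
    swaps <- list()
    trans <- list()
    diag_dirs <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
    for (f in 2:nfr) {
      k <- n_sw_frame[f]
      while (k > 0L) {
        k <- k - 1L
        i <- sample.int(N, 1L)
        dd <- diag_dirs[sample.int(4L, 1L), ]
        s1 <- site_of_mol[i]
        s2 <- shift_site(s1, dd[1], dd[2])
        mol_of_site <- integer(N); mol_of_site[site_of_mol] <- seq_len(N)
        j <- mol_of_site[s2]
        ## bystander sites that see one shell member replaced
        by_i <- c(shift_site(s1, -dd[1], 0L), shift_site(s1, 0L, -dd[2]))
        by_j <- c(shift_site(s2, dd[1], 0L), shift_site(s2, 0L, dd[2]))
        site_of_mol[i] <- s2
        site_of_mol[j] <- s1
        swaps[[length(swaps) + 1L]] <-
          list(f = f, i = i, j = j, s1 = s1, s2 = s2)
        trans[[length(trans) + 1L]] <- data.frame(
          mol = c(i, j, mol_of_site[by_i], mol_of_site[by_j]),
          w_a = c(NA_integer_, NA_integer_, i, i, j, j),
          w_b = c(NA_integer_, NA_integer_, j, j, i, i),
          boundary_frame = f)
      }
      SM[, f] <- site_of_mol
    }
    ## ---- kick events from the bond series --------------------------------
    kick_rows <- list()
    for (b in seq_len(nb)) {
      v <- B[b, ]
      breaks <- which(v[-1] == 0L & v[-nfr] == 1L) + 1L
      if (length(breaks) == 0L) next
      r <- rle(v); ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      db_end <- integer(nfr)
      dbr <- which(!as.logical(r$values))
      db_end[starts[dbr]] <- ends[dbr]
      kick_rows[[length(kick_rows) + 1L]] <- data.frame(
        bond_row = b, frame0 = breaks, db_end = db_end[breaks])
    }
    kicks <- if (length(kick_rows)) do.call(rbind, kick_rows) else
      data.frame(bond_row = integer(0), frame0 = integer(0),
                 db_end = integer(0))
    ## acceptor of each bond at each frame: occupant of the slot site
    A <- matrix(NA_integer_, nb, nfr)
    for (f in seq_len(nfr)) {
      mol_of_site <- integer(N); mol_of_site[SM[, f]] <- seq_len(N)
      tgt1 <- mol_of_site[nb_xp[SM[, f]]]
      tgt2 <- mol_of_site[nb_yp[SM[, f]]]
      tgt <- rbind(tgt1, tgt2)
      dim(tgt) <- NULL  # interleave: bond order is (mol1 h1, mol1 h2, ...)
      tgt <- as.integer(tgt)
      hb <- B[, f] == 1L
      A[hb, f] <- tgt[hb]
    }
    kicks$mol <- bond_mol[kicks$bond_row]
    kicks$h <- bond_h[kicks$bond_row]
    kicks$acceptor <- A[cbind(kicks$bond_row, pmax(kicks$frame0 - 1L, 1L))]
    ## ---- positions -------------------------------------------------------
    ## permanent kick steps (both pair members), accumulated over time
    inc_x <- matrix(0, N, nfr); inc_y <- matrix(0, N, nfr)
    if (kick_sigma > 0 && nrow(kicks) > 0L) {
      for (i in seq_len(nrow(kicks))) {
        f <- kicks$frame0[i]
        m <- kicks$mol[i]; p <- kicks$acceptor[i]
        st <- stats::rnorm(4L, sd = kick_sigma)
        inc_x[m, f] <- inc_x[m, f] + st[1]
        inc_y[m, f] <- inc_y[m, f] + st[2]
        if (!is.na(p)) {
          inc_x[p, f] <- inc_x[p, f] + st[3]
          inc_y[p, f] <- inc_y[p, f] + st[4]
        }
      }
      inc_x <- t(apply(inc_x, 1L, cumsum))
      inc_y <- t(apply(inc_y, 1L, cumsum))
    }
    ## transient pair-separation excursions (boxcar via differences+cumsum)
    exc_x <- matrix(0, N, nfr); exc_y <- matrix(0, N, nfr)
    if (kick_excursion > 0 && nrow(kicks) > 0L) {
      half <- kick_excursion / 2
      for (i in seq_len(nrow(kicks))) {
        f1 <- max(1L, kicks$frame0[i] - lead_f)
        f2 <- min(nfr, kicks$db_end[i])
        m <- kicks$mol[i]; p <- kicks$acceptor[i]
        if (is.na(p) || f2 < f1) next
        ux <- if (kicks$h[i] == 1L) 1 else 0
        uy <- 1 - ux
        exc_x[m, f1] <- exc_x[m, f1] - half * ux
        exc_y[m, f1] <- exc_y[m, f1] - half * uy
        exc_x[p, f1] <- exc_x[p, f1] + half * ux
        exc_y[p, f1] <- exc_y[p, f1] + half * uy
        if (f2 < nfr) {
          exc_x[m, f2 + 1L] <- exc_x[m, f2 + 1L] + half * ux
          exc_y[m, f2 + 1L] <- exc_y[m, f2 + 1L] + half * uy
          exc_x[p, f2 + 1L] <- exc_x[p, f2 + 1L] - half * ux
          exc_y[p, f2 + 1L] <- exc_y[p, f2 + 1L] - half * uy
        }
      }
      exc_x <- t(apply(exc_x, 1L, cumsum))
      exc_y <- t(apply(exc_y, 1L, cumsum))
    }
    ## base site positions, with swap morphs interpolated
    base_x <- matrix(site_xyz[SM, 1], N, nfr)
    base_y <- matrix(site_xyz[SM, 2], N, nfr)
    for (sw in swaps) {
      for (mp in list(c(sw$i, sw$s1, sw$s2), c(sw$j, sw$s2, sw$s1))) {
        m <- mp[1]
        from <- site_xyz[mp[2], 1:2]; to <- site_xyz[mp[3], 1:2]
        dvec <- minimum_image_displacement(c(from, 0), c(to, 0),
                                           cell(box, periodic))[1:2]
        fr <- sw$f:min(nfr, sw$f + morph_f - 1L)
        frac <- seq_along(fr) / (morph_f + 1L)
        base_x[m, fr] <- from[1] + frac * dvec[1]
        base_y[m, fr] <- from[2] + frac * dvec[2]
      }
    }
    ox <- base_x + inc_x + exc_x +
      matrix(stats::rnorm(N * nfr, sd = jitter), N, nfr)
    oy <- base_y + inc_y + exc_y +
      matrix(stats::rnorm(N * nfr, sd = jitter), N, nfr)
    oz <- matrix(site_xyz[SM, 3], N, nfr) +
      matrix(stats::rnorm(N * nfr, sd = jitter), N, nfr)
    ## DB orientation: along +/- normal (2D) or random (3D); sign fixed per
    ## episode
    db_sign <- matrix(1, nb, nfr)
    for (b in seq_len(nb)) {
      r <- rle(B[b, ])
      sgn <- ifelse(stats::runif(length(r$lengths)) < 0.5, -1, 1)
      db_sign[b, ] <- inverse.rle(list(lengths = r$lengths, values = sgn))
    }
    ## assemble atoms: per molecule O, H1, H2
    n_atoms <- 3L * N
    coords <- array(0, c(n_atoms, 3L, nfr))
    o_rows <- 3L * seq_len(N) - 2L
    coords[o_rows, 1, ] <- ox
    coords[o_rows, 2, ] <- oy
    coords[o_rows, 3, ] <- oz
    cl <- cell(box, periodic)
    for (f in seq_len(nfr)) {
      ro <- cbind(ox[, f], oy[, f], oz[, f])
      for (h in 1:2) {
        bsel <- which(bond_h == h)
        bidx <- bsel
        hb <- B[bidx, f] == 1L
        hv <- matrix(0, N, 3L)
        if (any(hb)) {
          acc <- A[bidx[hb], f]
          v <- minimum_image_displacement(ro[bond_mol[bidx[hb]], , drop = FALSE],
                                          ro[acc, , drop = FALSE], cl)
          if (is.null(dim(v))) v <- matrix(v, ncol = 3L)
          v <- v / sqrt(rowSums(v^2))
          hv[hb, ] <- v
        }
        if (any(!hb)) {
          ndb <- sum(!hb)
          if (dim3) {
            ## cube-diagonal orientations: 54.7 deg from every lattice axis,
            ## so a dangling H never satisfies the angular criterion toward
            ## a neighbouring O
            v <- matrix(sample(c(-1, 1), 3L * ndb, replace = TRUE), ndb, 3L) +
              matrix(stats::rnorm(3L * ndb, sd = 0.08), ndb, 3L)
          } else {
            v <- cbind(stats::rnorm(ndb, sd = 0.1),
                       stats::rnorm(ndb, sd = 0.1),
                       db_sign[bidx[!hb], f])
          }
          v <- v / sqrt(rowSums(v^2))
          hv[!hb, ] <- v
        }
        coords[o_rows + h, , f] <- ro + oh_len * hv
      }
    }
    species <- rep(c("O", "H", "H"), times = N)
    molecules <- data.frame(o = o_rows, h1 = o_rows + 1L, h2 = o_rows + 2L)
    traj <- wrap(wtraj(coords, dt = dt, cell = cl, species = species,
                       molecules = molecules, normal_axis = 3L))
    ## ---- planted analysis objects ---------------------------------------
    bonds <- new_bond_states(B, A, data.frame(mol = bond_mol, h = bond_h),
                             dt, N)
    tr <- if (length(trans)) do.call(rbind, trans) else
      data.frame(mol = integer(0), w_a = integer(0), w_b = integer(0),
                 boundary_frame = integer(0))
    ## segments per molecule from the transition boundaries
    seg_rows <- list(); cid <- 0L; ev_rows <- list(); tid <- 0L
    comp_defs <- list()
    for (m in seq_len(N)) {
      bf <- sort(unique(tr$boundary_frame[tr$mol == m]))
      bf <- bf[bf > 1L & bf <= nfr]
      bounds <- c(1L, bf, nfr + 1L)
      for (s in seq_len(length(bounds) - 1L)) {
        cid <- cid + 1L
        f0 <- bounds[s]
        mol_of_site <- integer(N); mol_of_site[SM[, f0]] <- seq_len(N)
        comp_defs[[cid]] <- sort(mol_of_site[orth_nb[SM[m, f0], ]])
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          mol = m, comp_id = cid, start_frame = bounds[s],
          end_frame = bounds[s + 1L] - 1L)
      }
    }
    seg <- do.call(rbind, seg_rows)
    seg$t_start <- (seg$start_frame - 1) * dt
    seg$t_end <- (seg$end_frame - 1) * dt
    segments <- new_shell_segments(seg, comp_defs, dt, nfr)
    if (nrow(tr)) {
      tr$transition_id <- cumsum(!duplicated(
        paste(tr$mol, tr$boundary_frame)))
      ev <- data.frame(event_id = seq_len(nrow(tr)),
                       transition_id = tr$transition_id, mol = tr$mol,
                       w_a = tr$w_a, w_b = tr$w_b,
                       boundary_frame = tr$boundary_frame,
                       t0 = (tr$boundary_frame - 1.5) * dt,
                       resolved = TRUE)
    } else {
      ev <- data.frame(event_id = integer(0), transition_id = integer(0),
                       mol = integer(0), w_a = integer(0), w_b = integer(0),
                       boundary_frame = integer(0), t0 = numeric(0),
                       resolved = logical(0))
    }
    swe_events <- new_swe_events(ev, segments)
    kick_events <- kicks[, c("mol", "h", "acceptor", "bond_row", "frame0")]
    kick_events$t0 <- (kick_events$frame0 - 1) * dt
    kick_events$db_frames <- kicks$db_end - kicks$frame0 + 1L
    kick_events <- cbind(event_id = seq_len(nrow(kick_events)), kick_events)
    kick_events <- structure(kick_events, dt = dt,
                             class = c("kick_events", "data.frame"))
    d_dim <- if (dim3) 3 else 2
    D_kick_true <- if (dim3) 0 else 2 * p_hb * k_off * kick_sigma^2
    D_swe_true <- swe_rate * a^2 / (if (dim3) 9 else 6)
    list(traj = traj, bonds = bonds, segments = segments,
         swe_events = swe_events, kick_events = kick_events,
         true = list(D_kick = D_kick_true, D_SWE = D_swe_true,
                     D_total = D_kick_true + D_swe_true,
                     p_hb = p_hb, db_fraction = 1 - p_hb,
                     mean_coordination = 4 * p_hb,
                     tau_hb = 1 / k_off, tau_db = tau_db,
                     k_off = k_off, k_on = k_on, d = d_dim),
         params = list(n_side = n_side, a = a, dt = dt, n_steps = nfr,
                       p_hb = p_hb, tau_db = tau_db,
                       kick_sigma = kick_sigma,
                       kick_excursion = kick_excursion,
                       kick_lead = kick_lead, swe_rate = swe_rate,
                       seed = seed))
  })
}

#' Ideal-gas / random-orientation reference configurations
#'
#' Uncorrelated uniform O positions in a periodic box, optionally with two H
#' per O in isotropic random orientations. Used as the null model for RDF
#' normalisation and orientation-distribution checks, and as random input
#' for classifier oracle tests.
#'
#' @param n_mol number of molecules.
#' @param box length-3 box lengths in Angstrom.
#' @param n_frames_gen number of independent frames.
#' @param dt frame spacing in ps.
#' @param with_h place two H per O (random isotropic orientation).
#' @param periodic logical(3) cell periodicity.
#' @param oh_len O-H bond length in Angstrom.
#' @param seed RNG seed.
#' @return a [wtraj()].
#' @export
gen_ideal_gas <- function(n_mol, box = c(20, 20, 20), n_frames_gen = 10L,
                          dt = 0.01, with_h = FALSE,
                          periodic = c(TRUE, TRUE, TRUE), oh_len = 0.97,
                          seed = 1) {
  with_seed(seed, {
    n_at <- if (with_h) 3L * n_mol else n_mol
    coords <- array(0, c(n_at, 3L, n_frames_gen))
    o_rows <- if (with_h) 3L * seq_len(n_mol) - 2L else seq_len(n_mol)
    for (f in seq_len(n_frames_gen)) {
      ro <- cbind(stats::runif(n_mol, 0, box[1]),
                  stats::runif(n_mol, 0, box[2]),
                  stats::runif(n_mol, 0, box[3]))
      coords[o_rows, , f] <- ro
      if (with_h) {
        for (h in 1:2) {
          v <- matrix(stats::rnorm(3L * n_mol), n_mol, 3L)
          v <- v / sqrt(rowSums(v^2))
          coords[o_rows + h, , f] <- ro + oh_len * v
        }
      }
    }
    species <- if (with_h) rep(c("O", "H", "H"), n_mol) else rep("O", n_mol)
    molecules <- if (with_h) {
      data.frame(o = o_rows, h1 = o_rows + 1L, h2 = o_rows + 2L)
    } else {
      data.frame(o = o_rows, h1 = NA_integer_, h2 = NA_integer_)
    }
    wtraj(coords, dt = dt, cell = cell(box, periodic), species = species,
          molecules = molecules)
  })
}
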