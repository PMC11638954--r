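#' Geometric hydrogen-bond criterion
#'
#' An O-H...O pair is hydrogen-bonded when the donor-acceptor O-O distance is
#' at most `r_oo_max` and the angular deviation from linearity is at most
#' `angle_max`. Two angle conventions are supported: `"dha"` measures the
#' deviation of the O_d-H...O_a arrangement from linear at the H position
#' (180 degrees minus the O_d-H-O_a angle), `"hda"` measures the
#' H-O_d...O_a angle at the donor oxygen. The defaults (3.5 A, 30 degrees)
#' are the standard bulk-water choice; both values are fully configurable.
#'
#' @param r_oo_max maximum donor-acceptor O-O distance in Angstrom.
#' @param angle_max maximum angular deviation in degrees (0 < angle <= 90).
#' @param angle_convention `"dha"` or `"hda"`.
#' @param r_oh_max optional maximum H...O_a distance in Angstrom.
#' @return an object of class `hb_criterion`.
#' @export
hb_criterion <- function(r_oo_max = 3.5, angle_max = 30,
                         angle_convention = c("dha", "hda"),
                         r_oh_max = NULL) {
  angle_convention <- match.arg(angle_convention)
  stopifnot(r_oo_max > 0, angle_max > 0, angle_max <= 90,
            is.null(r_oh_max) || r_oh_max > 0)
  structure(list(r_oo_max = r_oo_max, angle_max = angle_max,
                 angle_convention = angle_convention, r_oh_max = r_oh_max),
            class = "hb_criterion")
}

new_bond_states <- function(state, acceptor, bonds, dt, n_mol) {
  structure(list(state = state, acceptor = acceptor, bonds = bonds,
                 dt = dt, n_mol = n_mol),
            class = "bond_states")
}

#' @export
print.bond_states <- function(x, ...) {
  cat(sprintf("<bond_states> %d O-H bonds x %d frames, dt = %g ps; HB fraction %.3f\n",
              nrow(x$state), ncol(x$state), x$dt, mean(x$state)))
  invisible(x)
}

#' Classify every O-H bond per frame as HB or DB
#'
#' Each O-H bond is labelled hydrogen-bonded (HB) when some acceptor oxygen
#' satisfies all clauses of the criterion (minimum image); otherwise it is
#' dangling (DB). When several acceptors qualify, the one with the smallest
#' angular deviation is recorded (ties broken by the smaller O-O distance).
#' Classification is stateless frame-by-frame; persistence filtering belongs
#' to the downstream state-dynamics and event analyses.
#'
#' @param traj a [wtraj()] with water molecules defined.
#' @param crit an [hb_criterion()].
#' @param frames optional integer vector of frames to classify (default all).
#' @return an object of class `bond_states`: binary HB matrix
#'   (`n_bonds x n_frames`), acceptor molecule-id matrix (`NA` when DB), and
#'   a `bonds` table (`mol`, `h`).
#' @export
classify_bonds <- function(traj, crit = hb_criterion(), frames = NULL) {
  mols <- traj$molecules
  if (all(is.na(mols$h1))) {
    stop("trajectory has no hydrogen atoms; cannot classify O-H bonds",
         call. = FALSE)
  }
  if (!any(traj$cell$periodic)) {
    ## still permitted: minimum image degenerates to plain displacement
    cl <- traj$cell
  }
  cl <- traj$cell
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  n_mol <- nrow(mols)
  bonds <- data.frame(
    mol = rep(seq_len(n_mol), each = 2L),
    h = rep(c(1L, 2L), times = n_mol)
  )
  h_atom <- ifelse(bonds$h == 1L, mols$h1[bonds$mol], mols$h2[bonds$mol])
  keep <- !is.na(h_atom)
  bonds <- bonds[keep, , drop = FALSE]
  h_atom <- h_atom[keep]
  rownames(bonds) <- NULL
  nb <- nrow(bonds)
  state <- matrix(0L, nb, length(frames))
  acceptor <- matrix(NA_integer_, nb, length(frames))
  cosmax <- cos(crit$angle_max * pi / 180)

  o_idx <- mols$o
  pair_of_bond <- split(seq_len(nb), bonds$mol)
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    ro <- traj$coords[o_idx, , f, drop = FALSE]; dim(ro) <- c(n_mol, 3L)
    rh <- traj$coords[h_atom, , f, drop = FALSE]; dim(rh) <- c(nb, 3L)
    ## candidate donor-acceptor pairs within the O-O cutoff
    don <- rep(seq_len(n_mol), times = n_mol)
    acc <- rep(seq_len(n_mol), each = n_mol)
    ok <- don != acc
    don <- don[ok]; acc <- acc[ok]
    d_oo_vec <- minimum_image_displacement(ro[don, , drop = FALSE],
                                           ro[acc, , drop = FALSE], cl)
    if (is.null(dim(d_oo_vec))) d_oo_vec <- matrix(d_oo_vec, ncol = 3L)
    r_oo <- sqrt(rowSums(d_oo_vec^2))
    near <- r_oo <= crit$r_oo_max
    don <- don[near]; acc <- acc[near]; r_oo <- r_oo[near]
    if (length(don) == 0L) next
    ## expand to the (up to) two O-H bonds of each donor present in `bonds`
    bsel <- pair_of_bond[as.character(don)]
    reps <- lengths(bsel)
    bidx <- unlist(bsel, use.names = FALSE)
    pacc <- rep(acc, reps)
    proo <- rep(r_oo, reps)
    pdon <- rep(don, reps)
    ## geometry per candidate (bond, acceptor)
    r_don_o <- ro[pdon, , drop = FALSE]
    r_acc_o <- ro[pacc, , drop = FALSE]
    r_h <- rh[bidx, , drop = FALSE]
    v_oh <- minimum_image_displacement(r_don_o, r_h, cl)
    if (is.null(dim(v_oh))) v_oh <- matrix(v_oh, ncol = 3L)
    if (crit$angle_convention == "hda") {
      v_oa <- minimum_image_displacement(r_don_o, r_acc_o, cl)
      if (is.null(dim(v_oa))) v_oa <- matrix(v_oa, ncol = 3L)
      cosv <- rowSums(v_oh * v_oa) /
        (sqrt(rowSums(v_oh^2)) * sqrt(rowSums(v_oa^2)))
    } else {
      ## deviation from linear O_d-H...O_a measured at H:
      ## angle between (H -> O_a) and the extension of (O_d -> H)
      v_ha <- minimum_image_displacement(r_h, r_acc_o, cl)
      if (is.null(dim(v_ha))) v_ha <- matrix(v_ha, ncol = 3L)
      cosv <- rowSums(v_oh * v_ha) /
        (sqrt(rowSums(v_oh^2)) * sqrt(rowSums(v_ha^2)))
    }
    cosv <- pmin(1, pmax(-1, cosv))
    qual <- cosv >= cosmax
    if (!is.null(crit$r_oh_max)) {
      v_ha2 <- minimum_image_displacement(r_h, r_acc_o, cl)
      if (is.null(dim(v_ha2))) v_ha2 <- matrix(v_ha2, ncol = 3L)
      qual <- qual & sqrt(rowSums(v_ha2^2)) <= crit$r_oh_max
    }
    if (!any(qual)) next
    bq <- bidx[qual]; aq <- pacc[qual]; cq <- cosv[qual]; rq <- proo[qual]
    ## best acceptor per bond: max cos (min angle deviation), tie -> min r_oo
    ord <- order(bq, -cq, rq)
    first <- !duplicated(bq[ord])
    sel <- ord[first]
    state[bq[sel], fi] <- 1L
    acceptor[bq[sel], fi] <- aq[sel]
  }
  ## effective frame spacing of the classified series (frames may be strided)
  dt_eff <- traj$dt
  if (length(frames) > 1L) {
    strides <- diff(frames)
    if (length(unique(strides)) > 1L) {
      warning("non-uniform frame subset; downstream time axes assume the ",
              "first stride")
    }
    dt_eff <- traj$dt * strides[1]
  }
  new_bond_states(state, acceptor, bonds, dt_eff, n_mol)
}

#' Per-molecule H-bond coordination series
#'
#' Number of H-bonds (donated plus accepted) per molecule and frame, derived
#' from a [classify_bonds()] result. Partners are counted with multiplicity.
#'
#' @param bonds a `bond_states` object.
#' @return an object of class `coord_series` with a `count` matrix
#'   (`n_mol x n_frames`).
#' @export
coordination_series <- function(bonds) {
  nf <- ncol(bonds$state)
  n_mol <- bonds$n_mol
  donated <- rowsum(bonds$state, bonds$bonds$mol)
  count <- matrix(0L, n_mol, nf)
  count[as.integer(rownames(donated)), ] <- donated
  for (f in seq_len(nf)) {
    acc <- bonds$acceptor[, f]
    acc <- acc[!is.na(acc)]
    if (length(acc)) {
      tb <- tabulate(acc, nbins = n_mol)
      count[, f] <- count[, f] + tb
    }
  }
  structure(list(count = count, dt = bonds$dt), class = "coord_series")
}

#' Coordination-state populations
#'
#' Fraction of (molecule, frame) samples with each H-bond coordination
#' number. Fractions sum to one.
#'
#' @param coord a `coord_series` from [coordination_series()].
#' @return named numeric vector, names are coordination numbers.
#' @export
coordination_populations <- function(coord) {
  stopifnot(inherits(coord, "coord_series"))
  if (length(coord$count) == 0L) stop("empty coordination series",
                                      call. = FALSE)
  tb <- table(as.vector(coord$count))
  p <- as.numeric(tb) / sum(tb)
  names(p) <- names(tb)
  p
}

#' Per-frame dangling-bond fraction
#'
#' @param bonds a `bond_states` object.
#' @return numeric vector, fraction of O-H bonds in the DB state per frame.
#' @export
db_fraction_series <- function(bonds) {
  stopifnot(inherits(bonds, "bond_states"))
  if (length(bonds$state) == 0L) stop("empty bond-state series", call. = FALSE)
  1 - colMeans(bonds$state)
}

#' Mean number of H-bond partners
#'
#' `sum(n * p(n))` over the coordination populations; used as the
#' multiplicity factor of the kick contribution to diffusion (a molecule is
#' kicked by each of its H-bonded pairs).
#'
#' @param pop named numeric vector from [coordination_populations()].
#' @return scalar mean coordination.
#' @export
mean_hb_partners <- function(pop) {
  if (any(pop < 0)) stop("negative fractions", call. = FALSE)
  if (abs(sum(pop) - 1) > 1e-8) stop("fractions must sum to 1", call. = FALSE)
  sum(as.numeric(names(pop)) * pop)
}
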