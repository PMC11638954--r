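#' O-O radial distribution function
#'
#' Pair distribution of the water oxygens, normalised by the ideal-gas
#' expectation. `"bulk3d"` uses 3D minimum-image distances and spherical
#' shells; `"slab2d"` uses in-plane distances and circular annuli against the
#' in-plane area density (the quasi-2D monolayer convention; the observed
#' slab thickness, the 95% density interval along the normal, is reported in
#' the metadata since 2D RDF conventions vary).
#'
#' @param traj a [wtraj()] with a periodic cell.
#' @param r_max histogram range in Angstrom (must be below half the shortest
#'   periodic cell length).
#' @param n_bins number of uniform bins (default r_max / 0.05 A).
#' @param geometry `"bulk3d"` or `"slab2d"`.
#' @param frames frames to accumulate (default all).
#' @return object of class `radial_profile`: data.frame `r` (bin centres,
#'   A), `g`, `pmf` (NA until [pmf()] is called), `count`; attributes
#'   `geometry`, `n_pairs_ideal`, `thickness` (slab only).
#' @export
rdf <- function(traj, r_max = 6, n_bins = NULL,
                geometry = c("bulk3d", "slab2d"), frames = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(inherits(traj, "wtraj"))
  cl <- traj$cell
  if (!any(cl$periodic)) stop("rdf requires a periodic cell", call. = FALSE)
  if (is.null(n_bins)) n_bins <- round(r_max / 0.05)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  len <- cell_lengths(cl)
  if (geometry == "bulk3d") {
    if (!all(cl$periodic)) {
      stop("bulk3d geometry requires a fully periodic cell", call. = FALSE)
    }
    comps <- 1:3
  } else {
    if (sum(!cl$periodic) != 1L) {
      stop("slab2d geometry requires exactly one non-periodic axis",
           call. = FALSE)
    }
    comps <- which(cl$periodic)
  }
  if (r_max >= min(len[cl$periodic]) / 2) {
    stop("r_max must be below half the shortest periodic cell length",
         call. = FALSE)
  }
  n_mol <- n_molecules(traj)
  if (n_mol < 2L) stop("need at least two molecules", call. = FALSE)
  x <- o_coords(traj)
  don <- rep(seq_len(n_mol), times = n_mol)
  acc <- rep(seq_len(n_mol), each = n_mol)
  ok <- don < acc
  don <- don[ok]; acc <- acc[ok]
  edges <- seq(0, r_max, length.out = n_bins + 1L)
  counts <- numeric(n_bins)
  zs <- numeric(0)
  for (f in frames) {
    ro <- x[, , f, drop = FALSE]; dim(ro) <- c(n_mol, 3L)
    d <- minimum_image_displacement(ro[don, , drop = FALSE],
                                    ro[acc, , drop = FALSE], cl)
    if (is.null(dim(d))) d <- matrix(d, ncol = 3L)
    r <- sqrt(rowSums(d[, comps, drop = FALSE]^2))
    h <- graphics::hist(r[r < r_max], breaks = edges, plot = FALSE)
    counts <- counts + h$counts
    if (geometry == "slab2d") zs <- c(zs, ro[, which(!cl$periodic)])
  }
  nfr <- length(frames)
  npair <- n_mol * (n_mol - 1) / 2
  if (geometry == "bulk3d") {
    vol <- abs(det(cl$vectors))
    shell <- 4 / 3 * pi * diff(edges^3)
    ideal <- npair * shell / vol * nfr
    thickness <- NA_real_
  } else {
    area <- prod(len[comps])
    annulus <- pi * diff(edges^2)
    ideal <- npair * annulus / area * nfr
    thickness <- unname(diff(stats::quantile(zs, c(0.025, 0.975))))
  }
  df <- data.frame(r = (edges[-1] + edges[-length(edges)]) / 2,
                   g = counts / ideal, pmf = NA_real_, count = counts)
  structure(df, geometry = geometry, n_pairs_ideal = ideal,
            thickness = thickness, class = c("radial_profile", "data.frame"))
}

#' Potential of mean force from a radial profile
#'
#' `pmf(r) = -ln g(r)` in units of kT; bins with `g = 0` are marked
#' undefined (`NA`).
#'
#' @param profile a `radial_profile` from [rdf()].
#' @return the profile with the `pmf` column filled.
#' @export
pmf <- function(profile) {
  stopifnot(inherits(profile, "radial_profile"))
  profile$pmf <- ifelse(profile$g > 0, -log(profile$g), NA_real_)
  profile
}

#' Orientation distribution of O-H bonds relative to the surface normal
#'
#' Normalised histogram of the unsigned O-H/normal angle (0 = along the
#' normal, 90 = in-plane), optionally split by HB/DB state. Requires a slab
#' geometry (exactly one non-periodic axis).
#'
#' @param traj a [wtraj()] in slab geometry.
#' @param bonds optional `bond_states` for the state split.
#' @param by_state split histograms by HB/DB state (requires `bonds`).
#' @param n_bins histogram bins over [0, 90] degrees.
#' @param frames frames to accumulate (default all).
#' @return data.frame `theta` (bin centres, degrees), `p` (density, 1/deg)
#'   and, with `by_state`, `p_hb`, `p_db`; attribute `mean_angle` (named,
#'   overall and per state).
#' @export
orientation_distribution <- function(traj, bonds = NULL, by_state = FALSE,
                                     n_bins = 18L, frames = NULL) {
  if (sum(!traj$cell$periodic) != 1L) {
    stop("orientation analysis requires a slab geometry", call. = FALSE)
  }
  if (by_state && is.null(bonds)) stop("by_state requires bond states",
                                       call. = FALSE)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  mols <- traj$molecules
  nb_list <- list()
  st_list <- list()
  for (h in 1:2) {
    ha <- if (h == 1L) mols$h1 else mols$h2
    sel <- which(!is.na(ha))
    if (length(sel) == 0L) next
    for (m in sel) {
      ang <- angle_to_normal(traj, m, h, frames = frames)
      nb_list[[length(nb_list) + 1L]] <- ang
      if (by_state) {
        b <- which(bonds$bonds$mol == m & bonds$bonds$h == h)
        st_list[[length(st_list) + 1L]] <- bonds$state[b, frames]
      }
    }
  }
  ang <- unlist(nb_list)
  edges <- seq(0, 90, length.out = n_bins + 1L)
  dens <- function(a) {
    h <- graphics::hist(a, breaks = edges, plot = FALSE)
    h$counts / sum(h$counts) / diff(edges)
  }
  df <- data.frame(theta = (edges[-1] + edges[-length(edges)]) / 2,
                   p = dens(ang))
  means <- c(all = mean(ang))
  if (by_state) {
    st <- unlist(st_list)
    df$p_hb <- dens(ang[st == 1L])
    df$p_db <- dens(ang[st == 0L])
    means <- c(means, hb = mean(ang[st == 1L]), db = mean(ang[st == 0L]))
  }
  structure(df, mean_angle = means, class = c("data.frame"))
}
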