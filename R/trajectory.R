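#' Simulation cell
#'
#' A periodic (or partially periodic) simulation cell. Lengths are in Angstrom.
#'
#' @param vectors 3x3 numeric matrix of cell vectors (rows are lattice
#'   vectors a, b, c) or a length-3 numeric of orthorhombic box lengths.
#' @param periodic logical(3); which axes are periodic. Slab systems have
#'   exactly one non-periodic axis.
#' @return An object of class `cell`.
#' @export
cell <- function(vectors, periodic = c(TRUE, TRUE, TRUE)) {
  if (is.numeric(vectors) && length(vectors) == 3L) {
    vectors <- diag(vectors)
  }
  vectors <- as.matrix(vectors)
  stopifnot(identical(dim(vectors), c(3L, 3L)), length(periodic) == 3L)
  periodic <- as.logical(periodic)
  if (any(periodic) && abs(det(vectors)) < 1e-10) {
    stop("cell vectors are singular", call. = FALSE)
  }
  structure(list(vectors = vectors, periodic = periodic), class = "cell")
}

is_orthorhombic <- function(cl) {
  all(abs(cl$vectors[upper.tri(cl$vectors) | lower.tri(cl$vectors)]) < 1e-10)
}

cell_lengths <- function(cl) sqrt(rowSums(cl$vectors^2))

#' Trajectory container
#'
#' Time-ordered atomic configurations with a fixed frame spacing. Coordinates
#' are stored as an `n_atoms x 3 x n_frames` array in Angstrom; time is in ps.
#' Water topology (one O with its two H per molecule) is held in `molecules`;
#' generators of point-particle walks leave the H columns `NA`.
#'
#' @param coords numeric array `n_atoms x 3 x n_frames` (a matrix is accepted
#'   for a single frame).
#' @param dt frame spacing in ps (> 0).
#' @param cell a [cell()].
#' @param species character vector of element labels, one per atom.
#' @param molecules data.frame with integer columns `o`, `h1`, `h2` (atom
#'   indices); `h1`/`h2` may be `NA` for point particles. If `NULL`, inferred
#'   from `species` by O-H proximity (< 1.3 A, minimum image, first frame).
#' @param wall_atoms integer indices of confining-wall atoms (optional).
#' @param normal_axis axis index perpendicular to the walls (default 3 = z).
#' @return An object of class `wtraj`.
#' @export
wtraj <- function(coords, dt, cell, species = NULL, molecules = NULL,
                  wall_atoms = integer(0), normal_axis = 3L) {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("dt must be a single positive number (ps)", call. = FALSE)
  }
  stopifnot(inherits(cell, "cell"))
  n_atoms <- dim(coords)[1]
  if (is.null(species)) species <- rep("X", n_atoms)
  stopifnot(length(species) == n_atoms)
  if (is.null(molecules)) {
    molecules <- infer_molecules(coords[, , 1, drop = FALSE], species, cell)
  }
  structure(
    list(coords = coords, dt = dt, cell = cell, species = species,
         molecules = molecules, wall_atoms = as.integer(wall_atoms),
         normal_axis = as.integer(normal_axis)),
    class = "wtraj"
  )
}

#' @export
print.wtraj <- function(x, ...) {
  cat(sprintf("<wtraj> %d atoms, %d molecules, %d frames, dt = %g ps\n",
              dim(x$coords)[1], nrow(x$molecules), dim(x$coords)[3], x$dt))
  cat(sprintf("  periodic: %s; cell lengths: %s A\n",
              paste(x$cell$periodic, collapse = " "),
              paste(signif(cell_lengths(x$cell), 4), collapse = " ")))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[3]
n_molecules <- function(traj) nrow(traj$molecules)

#' Frame times in ps (frame f is at (f-1) * dt)
#' @param traj a [wtraj()].
#' @return numeric vector of times.
#' @export
frame_times <- function(traj) (seq_len(n_frames(traj)) - 1) * traj$dt

## Oxygen coordinates as n_mol x 3 x n_frames array
o_coords <- function(traj) {
  traj$coords[traj$molecules$o, , , drop = FALSE]
}

## Assign each H to its nearest O within 1.3 A (minimum image, first frame)
infer_molecules <- function(coords1, species, cl) {
  o_idx <- which(species == "O")
  h_idx <- which(species == "H")
  if (length(o_idx) == 0L) {
    return(data.frame(o = seq_len(dim(coords1)[1]), h1 = NA_integer_,
                      h2 = NA_integer_))
  }
  ro <- coords1[o_idx, , 1, drop = FALSE]; dim(ro) <- c(length(o_idx), 3L)
  assign_h <- vector("list", length(o_idx))
  for (h in h_idx) {
    rh <- matrix(coords1[h, , 1], nrow = length(o_idx), ncol = 3L, byrow = TRUE)
    dm <- minimum_image_displacement(ro, rh, cl)
    if (is.null(dim(dm))) dm <- matrix(dm, ncol = 3L)
    d <- sqrt(rowSums(dm^2))
    j <- which(d < 1.3)
    if (length(j) != 1L) {
      stop(sprintf("H atom %d cannot be assigned to a unique O (matches: %d)",
                   h, length(j)), call. = FALSE)
    }
    assign_h[[j]] <- c(assign_h[[j]], h)
  }
  nh <- lengths(assign_h)
  if (any(nh > 2L)) stop("an O atom has more than two H within 1.3 A",
                         call. = FALSE)
  data.frame(
    o = o_idx,
    h1 = vapply(assign_h, function(v) if (length(v) >= 1L) v[1] else NA_integer_,
                integer(1)),
    h2 = vapply(assign_h, function(v) if (length(v) >= 2L) v[2] else NA_integer_,
                integer(1))
  )
}

#' Minimum-image displacement
#'
#' Displacement `r2 - r1` with each periodic component folded into
#' `[-L/2, L/2)`. Non-periodic axes are left unfolded. Inputs may be single
#' vectors or `n x 3` matrices (recycled against each other).
#'
#' @param r1,r2 numeric length-3 vectors or `n x 3` matrices (Angstrom).
#' @param cell a [cell()].
#' @return displacement vector/matrix in Angstrom.
#' @export
minimum_image_displacement <- function(r1, r2, cell) {
  if (is.null(dim(r1))) r1 <- matrix(r1, ncol = 3L)
  if (is.null(dim(r2))) r2 <- matrix(r2, ncol = 3L)
  n <- max(nrow(r1), nrow(r2))
  if (nrow(r1) == 1L && n > 1L) r1 <- r1[rep(1L, n), , drop = FALSE]
  if (nrow(r2) == 1L && n > 1L) r2 <- r2[rep(1L, n), , drop = FALSE]
  d <- r2 - r1
  if (!any(cell$periodic)) return(drop_if_vector(d))
  if (abs(det(cell$vectors)) < 1e-10) {
    stop("cell vectors are singular", call. = FALSE)
  }
  ## fold in fractional coordinates; exact for orthorhombic cells and for
  ## compact (non-skewed) triclinic cells
  frac <- d %*% solve(cell$vectors)
  shift <- round(frac)
  shift[, !cell$periodic] <- 0
  d <- d - shift %*% cell$vectors
  drop_if_vector(d)
}

drop_if_vector <- function(m) if (nrow(m) == 1L) drop(m) else m

#' Unwrap periodic-boundary jumps
#'
#' Produces continuous coordinates for every atom by accumulating
#' minimum-image inter-frame displacements; non-periodic axes are unchanged.
#' Assumes no atom moves more than half the shortest periodic box length
#' between consecutive frames.
#'
#' @param traj a [wtraj()].
#' @return a [wtraj()] with continuous coordinates.
#' @export
unwrap <- function(traj) {
  cl <- traj$cell
  nf <- n_frames(traj)
  if (!any(cl$periodic) || nf < 2L) return(traj)
  lmin <- min(cell_lengths(cl)[cl$periodic])
  out <- traj$coords
  for (f in 2:nf) {
    prev <- traj$coords[, , f - 1]
    cur <- traj$coords[, , f]
    d <- minimum_image_displacement(prev, cur, cl)
    if (is.null(dim(d))) d <- matrix(d, ncol = 3L)
    if (max(abs(d[, cl$periodic])) > 0.45 * lmin) {
      stop(sprintf(
        "frame %d: inter-frame displacement approaches half the box; %s", f,
        "trajectory output stride is too coarse for unwrapping"),
        call. = FALSE)
    }
    out[, , f] <- out[, , f - 1] + d
  }
  traj$coords <- out
  traj
}

#' Wrap coordinates into the primary cell
#'
#' Folds periodic components into `[0, L)` (fractional `[0, 1)`).
#' @param traj a [wtraj()].
#' @return a wrapped [wtraj()].
#' @export
wrap <- function(traj) {
  cl <- traj$cell
  if (!any(cl$periodic)) return(traj)
  inv <- solve(cl$vectors)
  for (f in seq_len(n_frames(traj))) {
    frac <- traj$coords[, , f] %*% inv
    fl <- floor(frac)
    fl[, !cl$periodic] <- 0
    traj$coords[, , f] <- (frac - fl) %*% cl$vectors
  }
  traj
}

## ---- extended-XYZ and PDB I/O --------------------------------------------

parse_lattice <- function(comment) {
  m <- regmatches(comment,
                  regexpr('Lattice="[^"]*"', comment, ignore.case = TRUE))
  if (length(m) == 0L) return(NULL)
  vals <- as.numeric(strsplit(sub('^[Ll]attice="', "", sub('"$', "", m)),
                              "[[:space:]]+")[[1]])
  if (length(vals) != 9L || anyNA(vals)) {
    stop("malformed Lattice header in extended-XYZ comment line",
         call. = FALSE)
  }
  matrix(vals, nrow = 3L, byrow = TRUE)
}

parse_pbc <- function(comment) {
  m <- regmatches(comment,
                  regexpr('pbc="[^"]*"', comment, ignore.case = TRUE))
  if (length(m) == 0L) return(NULL)
  toks <- strsplit(sub('^[Pp]bc="', "", sub('"$', "", m)), "[[:space:]]+")[[1]]
  toupper(substr(toks, 1, 1)) == "T"
}

read_extxyz <- function(path, dt) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (length(lines) == 0L) stop("empty extended-XYZ file", call. = FALSE)
  frames <- list(); species <- NULL; lat <- NULL; pbc <- NULL
  i <- 1L
  while (i <= length(lines)) {
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na) || na <= 0L) {
      stop(sprintf("line %d: expected an atom count", i), call. = FALSE)
    }
    if (i + 1L + na > length(lines)) {
      stop("truncated extended-XYZ frame", call. = FALSE)
    }
    comment <- lines[i + 1L]
    if (is.null(lat)) { lat <- parse_lattice(comment); pbc <- parse_pbc(comment) }
    block <- lines[(i + 2L):(i + 1L + na)]
    toks <- strsplit(trimws(block), "[[:space:]]+")
    sp <- vapply(toks, `[`, character(1), 1L)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("non-numeric coordinates in extended-XYZ frame",
                         call. = FALSE)
    if (is.null(species)) {
      species <- sp
    } else if (length(sp) != length(species) || any(sp != species)) {
      stop("inconsistent atom count or ordering across extended-XYZ frames",
           call. = FALSE)
    }
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + na
  }
  coords <- array(unlist(frames), c(nrow(frames[[1]]), 3L, length(frames)))
  cl <- if (is.null(lat)) {
    cell(diag(3), periodic = c(FALSE, FALSE, FALSE))
  } else {
    cell(lat, periodic = if (is.null(pbc)) c(TRUE, TRUE, TRUE) else pbc)
  }
  wtraj(coords, dt = dt, cell = cl, species = species)
}

read_pdb_frames <- function(path, dt) {
  lines <- readLines(path)
  cl <- NULL
  cry <- grep("^CRYST1", lines, value = TRUE)
  if (length(cry) > 0L) {
    abc <- as.numeric(c(substr(cry[1], 7, 15), substr(cry[1], 16, 24),
                        substr(cry[1], 25, 33)))
    ang <- as.numeric(c(substr(cry[1], 34, 40), substr(cry[1], 41, 47),
                        substr(cry[1], 48, 54)))
    if (any(abs(ang - 90) > 1e-6)) {
      stop("only orthorhombic CRYST1 records are supported", call. = FALSE)
    }
    cl <- cell(abc)
  }
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  is_end <- grepl("^(ENDMDL|END[[:space:]]*$)", lines)
  frames <- list(); species <- NULL; cur <- list(); cur_sp <- character(0)
  flush_frame <- function() {
    if (length(cur) == 0L) return(invisible())
    xyz <- do.call(rbind, cur)
    if (is.null(species)) {
      species <<- cur_sp
    } else if (length(cur_sp) != length(species) || any(cur_sp != species)) {
      stop("inconsistent atom count or ordering across PDB MODELs",
           call. = FALSE)
    }
    frames[[length(frames) + 1L]] <<- xyz
    cur <<- list(); cur_sp <<- character(0)
  }
  for (k in seq_along(lines)) {
    if (is_atom[k]) {
      ln <- lines[k]
      xyz <- as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                          substr(ln, 47, 54)))
      if (anyNA(xyz)) stop(sprintf("line %d: malformed PDB coordinates", k),
                           call. = FALSE)
      el <- trimws(substr(ln, 77, 78))
      if (!nzchar(el)) el <- trimws(substr(ln, 13, 14))
      el <- sub("^([A-Za-z]).*", "\\1", el)
      cur[[length(cur) + 1L]] <- xyz
      cur_sp <- c(cur_sp, toupper(el))
    } else if (is_end[k]) {
      flush_frame()
    }
  }
  flush_frame()
  if (length(frames) == 0L) stop("no ATOM records found in PDB file",
                                 call. = FALSE)
  coords <- array(unlist(frames), c(nrow(frames[[1]]), 3L, length(frames)))
  if (is.null(cl)) cl <- cell(diag(3), periodic = c(FALSE, FALSE, FALSE))
  wtraj(coords, dt = dt, cell = cl, species = species)
}

#' Read a trajectory
#'
#' Multi-frame extended-XYZ (cell via a `Lattice="..."` header, optional
#' `pbc="..."`) or PDB (MODEL/ENDMDL frame separation, orthorhombic CRYST1).
#' Water molecules are inferred by O-H proximity (< 1.3 A, minimum image);
#' PDB CONECT records are ignored. An extended-XYZ file without a Lattice
#' header yields a non-periodic trajectory on which periodic analyses refuse
#' to run.
#'
#' @param path file path.
#' @param format `"extxyz"` or `"pdb"`; default guessed from the extension.
#' @param dt frame spacing in ps.
#' @return a [wtraj()].
#' @export
read_trajectory <- function(path, format = c("auto", "extxyz", "pdb"), dt) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "extxyz"
  }
  switch(format,
         extxyz = read_extxyz(path, dt),
         pdb = read_pdb_frames(path, dt))
}

#' Write a trajectory as multi-frame extended-XYZ
#'
#' @param traj a [wtraj()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(traj, path) {
  na <- dim(traj$coords)[1]
  lat <- paste(sprintf("%.10g", t(traj$cell$vectors)), collapse = " ")
  pbc <- paste(ifelse(traj$cell$periodic, "T", "F"), collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(as.character(na), con)
    writeLines(sprintf('Lattice="%s" pbc="%s" Properties=species:S:1:pos:R:3',
                       lat, pbc), con)
    writeLines(sprintf("%s %.10f %.10f %.10f", traj$species,
                       traj$coords[, 1, f], traj$coords[, 2, f],
                       traj$coords[, 3, f]), con)
  }
  invisible(path)
}

## TSV writer used by all analysis outputs: one '#' comment line naming units
write_tsv_units <- function(df, path, units_comment) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", units_comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
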