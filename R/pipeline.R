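#' Default pipeline configuration
#'
#' Flat list of every tunable of the end-to-end analysis, with the package
#' defaults. Any subset can be overridden via `...` or read from a flat
#' `key = value` text file with [read_config()].
#'
#' @param ... overrides, e.g. `run_config(t_filter = 0.1)`.
#' @return named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    input = NULL,            # trajectory file path (extxyz or pdb)
    input_format = "auto",
    dt = 0.02,               # ps, frame spacing of the input file
    geometry = "monolayer",  # "monolayer" (slab, d = 2) or "bulk" (d = 3)
    r_oo_max = 3.5,          # A, H-bond O-O cutoff
    angle_max = 30,          # deg, H-bond angular cutoff
    angle_convention = "dha",
    shell_mode = "hbond",    # "hbond" or "distance"
    r_shell = 3.5,           # A, shell radius in distance mode
    t_filter = 0.2,          # ps, stable-state transient filter
    t_db_min = 0.05,         # ps, minimum DB episode for a kick
    t_persist = 0.5,         # ps, shell persistence window for a kick
    t_rebond_max = 1,        # ps, rebonding window for recombination stats
    half_window = 0.5,       # ps, amplitude window half-width T
    max_lag_surv = 3,        # ps, survival-function window
    max_lag_exchange = NULL, # ps, jump-time correlation window (auto)
    fit_range = c(1, 5),     # ps, MSD fit interval
    fit_range_frame = NULL,  # ps, frame-MSD fit interval (auto)
    r_max_rdf = 6,           # A
    out_dir = NULL,          # write TSV/JSON outputs here when set
    seed = 1
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(ov)] <- ov
  structure(cfg, class = "run_config")
}

#' Read a flat key = value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; numeric values are
#' converted, `c(a, b)` ranges are comma-separated pairs.
#'
#' @param path file path.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "[[:space:]]*=[[:space:]]*")
  ov <- list()
  for (p in kv) {
    val <- p[2]
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    ov[[p[1]]] <- if (anyNA(num)) val else num
  }
  do.call(run_config, ov)
}

#' Validate a pipeline configuration
#'
#' @param config a `run_config`.
#' @param traj optional [wtraj()] to cross-check geometry against.
#' @return data.frame of findings (`field`, `reason`); zero rows iff the
#'   configuration is runnable.
#' @export
validate_config <- function(config, traj = NULL) {
  f <- list()
  bad <- function(field, reason) f[[length(f) + 1L]] <<-
    data.frame(field = field, reason = reason)
  if (!is.null(config$input) && !file.exists(config$input)) {
    bad("input", "file does not exist")
  }
  if (config$dt <= 0) bad("dt", "must be > 0")
  for (fld in c("t_filter", "t_db_min", "t_persist", "t_rebond_max",
                "half_window", "max_lag_surv")) {
    if (config[[fld]] < 0) bad(fld, "time window must be >= 0")
  }
  if (!config$geometry %in% c("monolayer", "bulk")) {
    bad("geometry", "must be 'monolayer' or 'bulk'")
  }
  if (config$r_oo_max <= 0) bad("r_oo_max", "must be > 0")
  if (config$angle_max <= 0 || config$angle_max > 90) {
    bad("angle_max", "must be in (0, 90]")
  }
  if (config$shell_mode == "distance" &&
      (is.null(config$r_shell) || config$r_shell <= 0)) {
    bad("r_shell", "distance mode requires a positive shell radius")
  }
  if (diff(config$fit_range) <= 0) bad("fit_range", "must be increasing")
  if (!is.null(traj)) {
    np <- sum(!traj$cell$periodic)
    if (config$geometry == "monolayer" && np != 1L) {
      bad("geometry", "monolayer mode needs exactly one non-periodic axis")
    }
    if (config$geometry == "bulk" && np != 0L) {
      bad("geometry", "bulk mode needs a fully periodic cell")
    }
    if (n_frames(traj) < 10L) bad("input", "trajectory has too few frames")
  }
  if (length(f)) do.call(rbind, f) else
    data.frame(field = character(0), reason = character(0))
}

#' Run the full analysis pipeline
#'
#' Executes classification, state lifetimes, stable-state/SWE analysis, kick
#' analysis, the diffusion decomposition and the structure profiles on one
#' trajectory, writing per-stage TSV tables and one JSON summary when
#' `config$out_dir` is set.
#'
#' @param config a `run_config`; `config$input` names the trajectory unless
#'   `traj` is given directly.
#' @param traj optional [wtraj()] (bypasses file reading).
#' @return the summary list, invisibly when `out_dir` is set.
#' @export
run_all <- function(config = run_config(), traj = NULL) {
  if (is.null(traj)) {
    if (is.null(config$input)) stop("no input trajectory", call. = FALSE)
    traj <- read_trajectory(config$input, config$input_format, dt = config$dt)
  }
  findings <- validate_config(config, traj)
  if (nrow(findings) > 0L) {
    stop("invalid configuration:\n",
         paste(sprintf("  %s: %s", findings$field, findings$reason),
               collapse = "\n"), call. = FALSE)
  }
  mode <- config$geometry
  d_dim <- if (mode == "monolayer") 2L else 3L
  t_total <- (n_frames(traj) - 1) * traj$dt
  msg <- function(...) message(sprintf(...))
  out <- list(config = unclass(config))

  msg("[hbonds] classifying %d molecules x %d frames",
      n_molecules(traj), n_frames(traj))
  crit <- hb_criterion(config$r_oo_max, config$angle_max,
                       config$angle_convention)
  bonds <- classify_bonds(traj, crit)
  coord <- coordination_series(bonds)
  pops <- coordination_populations(coord)
  out$populations <- as.list(pops)
  out$mean_coordination <- mean_hb_partners(pops)
  out$db_fraction <- mean(db_fraction_series(bonds))
  msg("[hbonds] DB fraction %.3f, mean coordination %.2f",
      out$db_fraction, out$mean_coordination)

  msg("[lifetimes] survival functions up to %g ps", config$max_lag_surv)
  ml <- min(config$max_lag_surv, t_total * 0.45)
  s_hb <- survival_function(bonds, "HB", max_lag = ml)
  s_db <- survival_function(bonds, "DB", max_lag = ml)
  out$tau_hb <- lifetime(s_hb, "integral_with_tail")$tau
  out$tau_db <- lifetime(s_db, "integral_with_tail")$tau
  msg("[lifetimes] tau_HB = %.3f ps, tau_DB = %.3f ps",
      out$tau_hb, out$tau_db)

  msg("[swe] stable states (t_filter = %g ps)", config$t_filter)
  shells <- if (config$shell_mode == "hbond") {
    shell_series(bonds, "hbond")
  } else {
    shell_series(mode = "distance", r_shell = config$r_shell, traj = traj)
  }
  segments <- filter_transients(shells, config$t_filter)
  events <- detect_swe(segments, traj)
  n_res <- sum(events$resolved)
  msg("[swe] %d transitions, %d pairwise events resolved, %d unresolved",
      length(unique(events$transition_id)), n_res, sum(!events$resolved))
  utraj <- unwrap(traj)
  mle <- config$max_lag_exchange
  if (is.null(mle)) mle <- t_total * 0.45
  swe_amp <- NULL; tau_swe <- NULL
  if (n_res > 0L) {
    swe_amp <- swe_displacement_amplitude(events, utraj,
                                          half_window = config$half_window)
    tau_swe <- swe_time(events, segments, max_lag = mle,
                        method = "integral_with_tail")
  }

  msg("[kick] detecting intra-shell HB breaks")
  kicks <- detect_kicks(bonds, segments, config$t_db_min, config$t_persist)
  msg("[kick] %d kick events", nrow(kicks))
  kick_est <- NULL; recomb <- NULL
  if (nrow(kicks) >= 30L) {
    kick_est <- kick_time_and_amplitude(kicks, bonds, utraj,
                                        half_window = config$half_window,
                                        max_lag = t_total * 0.45,
                                        method = "integral_with_tail")
    recomb <- recombination_stats(kicks, bonds, config$t_rebond_max)
    out$recombination <- as.list(recomb$fractions)
  }

  msg("[diffusion] MSD and decomposition (d = %d)", d_dim)
  fit_range <- pmin(config$fit_range, t_total * c(0.2, 0.45))
  mm <- msd(utraj, in_plane = mode == "monolayer")
  D_total <- fit_diffusion(mm, fit_range)
  D_frame <- tryCatch({
    frm <- frame_msd(utraj, segments, in_plane = mode == "monolayer")
    fr2 <- config$fit_range_frame
    if (is.null(fr2)) fr2 <- c(max(frm$lag) / 3, max(frm$lag))
    fit_diffusion(frm, fr2)
  }, error = function(e) NA_real_)
  D_swe_v <- if (!is.null(swe_amp)) {
    d_swe(swe_amp$delta_sq, tau_swe$tau_swe, d_dim)
  } else 0
  D_kick_v <- if (!is.null(kick_est)) {
    d_kick(kick_est$delta_sq_kick, kick_est$tau_kick, out$mean_coordination)
  } else 0
  report <- assemble_report(
    d_total = D_total, d_frame = D_frame, d_swe = D_swe_v,
    d_kick = D_kick_v,
    tau_swe = if (is.null(tau_swe)) NA_real_ else tau_swe$tau_swe,
    tau_kick = if (is.null(kick_est)) NA_real_ else kick_est$tau_kick,
    delta_sq_swe = if (is.null(swe_amp)) NA_real_ else swe_amp$delta_sq,
    delta_sq_kick = if (is.null(kick_est)) NA_real_ else
      kick_est$delta_sq_kick,
    kick_factor = out$mean_coordination, d = d_dim,
    mode = if (mode == "monolayer") "monolayer" else "bulk")
  out$diffusion <- unclass(report)
  msg("[diffusion] D_total = %.3g, D_SWE = %.3g, D_kick = %.3g A^2/ps",
      D_total, D_swe_v, D_kick_v)

  msg("[structure] RDF and orientation profiles")
  geom <- if (mode == "monolayer") "slab2d" else "bulk3d"
  r_max <- min(config$r_max_rdf,
               min(cell_lengths(traj$cell)[traj$cell$periodic]) / 2 * 0.99)
  profile <- pmf(rdf(traj, r_max = r_max, geometry = geom))
  orient <- if (mode == "monolayer") {
    orientation_distribution(traj, bonds, by_state = TRUE)
  } else NULL

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    op <- function(x) file.path(config$out_dir, x)
    write_tsv_units(data.frame(frame = seq_along(db_fraction_series(bonds)),
                               db_fraction = db_fraction_series(bonds)),
                    op("db_fraction.tsv"), "frame [-], db_fraction [-]")
    write_tsv_units(data.frame(lag = s_hb$lags, s_hb = s_hb$values,
                               s_db = s_db$values),
                    op("survival.tsv"), "lag [ps], S_HB [-], S_DB [-]")
    write_tsv_units(as.data.frame(events), op("swe_events.tsv"),
                    "t0 [ps], ids [molecule index]")
    write_tsv_units(as.data.frame(kicks), op("kick_events.tsv"),
                    "t0 [ps], ids [molecule index]")
    write_tsv_units(as.data.frame(profile)[, c("r", "g", "pmf")],
                    op("rdf.tsv"), "r [A], g [-], pmf [kT]")
    if (!is.null(orient)) {
      write_tsv_units(orient, op("orientation.tsv"),
                      "theta [deg], densities [1/deg]")
    }
    dfr <- data.frame(key = names(unlist(out$diffusion)),
                      value = unlist(out$diffusion))
    write_tsv_units(dfr, op("diffusion_report.tsv"),
                    "D [A^2/ps], *_cm2s [1e-5 cm^2/s], tau [ps], delta_sq [A^2]")
    jsonlite::write_json(out, op("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    return(invisible(out))
  }
  out
}
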