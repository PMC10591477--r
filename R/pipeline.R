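#' Configuration of a full per-system analysis
#'
#' Bundles everything [run_system()] needs: input topology/trajectory (as
#' file paths or in-memory objects), the metric manifest, interaction
#' cutoffs, distribution-statistics settings and optional externally
#' computed binding free-energy summaries.
#'
#' @param topology A `tn_topology`, or a PDB path.
#' @param trajectories A `tn_trajectory`, or a character vector of
#'   trajectory paths (one per run).
#' @param manifest Metric manifest (default [default_manifest()]).
#' @param cutoffs Interaction cutoffs (default [interaction_cutoffs()]).
#' @param stats Distribution-statistics config (default [stats_config()]).
#' @param chain_map Chain-to-subunit map used when `topology` is a path.
#' @param rmsd_max_frames Frame budget of the representative-structure
#'   RMSD matrix (default 500; the matrix is strided to fit).
#' @param energy Optional named list of binding free-energy inputs (numeric
#'   sample vectors or `list(mean=, sd=, n=)`), e.g.
#'   `list(switch_peptide = ...)`.
#' @param name System label used in outputs.
#' @return A `tn_analysis_config`.
#' @export
analysis_config <- function(topology, trajectories,
                            manifest = default_manifest(),
                            cutoffs = interaction_cutoffs(),
                            stats = stats_config(),
                            chain_map = default_chain_map(),
                            rmsd_max_frames = 500L,
                            energy = NULL, name = "system") {
  structure(list(topology = topology, trajectories = trajectories,
                 manifest = manifest, cutoffs = cutoffs, stats = stats,
                 chain_map = chain_map,
                 rmsd_max_frames = as.integer(rmsd_max_frames),
                 energy = energy, name = name),
            class = "tn_analysis_config")
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else unclass(x)
}

config_fingerprint <- function(config) {
  key <- list(
    manifest = strip_classes(config$manifest),
    cutoffs = unclass(config$cutoffs),
    stats = unclass(config$stats),
    rmsd_max_frames = config$rmsd_max_frames
  )
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(key, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Run the full analysis of one system
#'
#' Executes every pipeline stage on one system and writes the result
#' bundle: per-frame metric series (CSV), per-residue RMSF (CSV),
#' interaction frequency table (CSV), representative structure (single
#' model PDB), distribution summaries (JSON) and a run manifest (JSON,
#' embedding the configuration fingerprint). A stage failure aborts with
#' the stage name.
#'
#' @param config A `tn_analysis_config`.
#' @param out_dir Output directory (created if missing).
#' @return A `tn_bundle`: list with the trajectory, all stage results,
#'   summaries, output paths and the manifest.
#' @export
run_system <- function(config, out_dir) {
  stopifnot(inherits(config, "tn_analysis_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  topology <- stage("topology", {
    if (inherits(config$topology, "tn_topology")) config$topology
    else read_topology(config$topology, chain_map = config$chain_map)
  })
  traj <- stage("trajectory", {
    if (inherits(config$trajectories, "tn_trajectory")) config$trajectories
    else read_trajectory(config$trajectories, topology)
  })

  man <- config$manifest
  metrics <- man[vapply(man, inherits, logical(1), what = "tn_metric")]
  series <- list()
  summaries <- list()
  paths <- list()
  for (nm in names(metrics)) {
    s <- stage(paste0("metric:", nm),
               suppressWarnings(metric_series(traj, metrics[[nm]])))
    series[[nm]] <- s
    thr <- if (nm == "ab_angle" && !is.null(man$ab_open_threshold))
      man$ab_open_threshold else NULL
    summaries[[nm]] <- summarize_distribution(s, config$stats,
                                              threshold = thr)
    paths[[nm]] <- file.path(out_dir, paste0(nm, ".csv"))
    write_series_csv(s, paths[[nm]])
  }

  rmsf_prof <- stage("rmsf", rmsf(traj))
  paths$rmsf <- file.path(out_dir, "rmsf.csv")
  utils::write.csv(data.frame(rmsf_prof[1:2],
                              rmsf = round(rmsf_prof$rmsf, 4)),
                   paths$rmsf, row.names = FALSE, quote = FALSE)

  freq <- stage("interactions",
                profile_interactions(traj, cutoffs = config$cutoffs))
  paths$interactions <- file.path(out_dir, "interactions.csv")
  ft <- as.data.frame(freq)
  ft$percent <- round(ft$percent, 4)
  utils::write.csv(ft, paths$interactions, row.names = FALSE, quote = FALSE)

  rep_mat <- stage("representative",
                   pairwise_rmsd(traj, max_frames = config$rmsd_max_frames))
  rep_str <- representative_structure(rep_mat)
  paths$representative <- file.path(out_dir, "representative.pdb")
  write_frames(traj, paths$representative, format = "pdb",
               frames = rep_str$frame)

  fingerprint <- config_fingerprint(config)
  summary_json <- list(
    system = config$name,
    n_frames = n_frames(traj), n_runs = traj$n_runs,
    config_fingerprint = fingerprint,
    metrics = lapply(summaries, function(s) {
      list(mean = round(s$mean, 4), sd = round(s$sd, 4),
           kde_mode = if (s$degenerate) s$kde_mode else round(s$kde_mode, 4),
           fwhm = if (is.na(s$fwhm)) NULL else round(s$fwhm, 4),
           fraction_above = if (is.na(s$fraction_above)) NULL else
             round(s$fraction_above, 6),
           threshold = s$threshold, n = s$n)
    }),
    representative = rep_str[c("run_id", "frame_index")]
  )
  paths$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary_json, paths$summary, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  manifest <- list(
    system = config$name,
    created_with = paste0("tndyn ",
                          as.character(utils::packageVersion("tndyn"))),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_fingerprint = fingerprint,
    cutoffs = unclass(config$cutoffs),
    stats = unclass(config$stats),
    rmsd_stride = attr(rep_mat, "stride"),
    n_frames = n_frames(traj), n_runs = traj$n_runs
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  structure(list(name = config$name, config = config, trajectory = traj,
                 series = series, summaries = summaries, rmsf = rmsf_prof,
                 interactions = freq, rmsd_matrix = rep_mat,
                 representative = rep_str, energy = config$energy,
                 manifest = manifest, paths = paths, out_dir = out_dir),
            class = "tn_bundle")
}

#' @export
print.tn_bundle <- function(x, ...) {
  cat(sprintf("Analysis bundle '%s': %d frames, %d run(s)\n", x$name,
              n_frames(x$trajectory), x$trajectory$n_runs))
  for (nm in names(x$summaries)) {
    s <- x$summaries[[nm]]
    cat(sprintf("  %-18s mean %8.2f  sd %6.2f\n", nm, s$mean, s$sd))
  }
  cat("  outputs in", x$out_dir, "\n")
  invisible(x)
}

#' Compare two analyzed systems
#'
#' State-comparison report for two bundles produced with identical
#' configurations (verified via the configuration fingerprint): per metric,
#' the mean/sd of both states with delta, KDE-mode delta, FWHM with
#' percent change and Cohen's d (computed from the per-frame series);
#' binding free-energy deltas when both bundles carry energy inputs; and
#' the residue-pair interaction delta table.
#'
#' @param bundle_a,bundle_b `tn_bundle` objects (state A, e.g.
#'   unphosphorylated, and state B, e.g. phosphorylated).
#' @param out_dir Optional output directory for `metrics.csv` (the
#'   summary-table-shaped report) and `interaction_delta.csv`.
#' @return A `tn_report`: list with `metrics` (data.frame), `energy`
#'   (data.frame or NULL), `interaction_delta` (a `tn_delta_table`).
#' @export
compare_systems <- function(bundle_a, bundle_b, out_dir = NULL) {
  stopifnot(inherits(bundle_a, "tn_bundle"), inherits(bundle_b, "tn_bundle"))
  if (bundle_a$manifest$config_fingerprint !=
      bundle_b$manifest$config_fingerprint) {
    stop("bundles were produced with different configurations; ",
         "comparison would not be like-for-like")
  }
  rows <- list()
  for (nm in intersect(names(bundle_a$summaries), names(bundle_b$summaries))) {
    sa <- bundle_a$summaries[[nm]]
    sb <- bundle_b$summaries[[nm]]
    cmp <- state_delta(sa, sb)
    # effect size is meaningless between two (near-)constant series
    d <- if (sa$degenerate && sb$degenerate) NA_real_ else
      cohens_d(bundle_a$series[[nm]]$value, bundle_b$series[[nm]]$value)
    rows[[nm]] <- data.frame(
      metric = nm,
      mean_a = round(sa$mean, 2), sd_a = round(sa$sd, 2),
      mean_b = round(sb$mean, 2), sd_b = round(sb$sd, 2),
      delta_mean = round(cmp$delta_mean, 2),
      kde_a = round(sa$kde_mode, 2), kde_b = round(sb$kde_mode, 2),
      delta_kde = round(cmp$delta_kde_mode, 2),
      fwhm_a = round(sa$fwhm, 2), fwhm_b = round(sb$fwhm, 2),
      fwhm_pct_change = as.integer(cmp$fwhm_percent_change_int),
      frac_above_a = round(sa$fraction_above, 4),
      frac_above_b = round(sb$fraction_above, 4),
      cohens_d = round(d, 3)
    )
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL

  energy <- NULL
  if (!is.null(bundle_a$energy) && !is.null(bundle_b$energy)) {
    nms <- intersect(names(bundle_a$energy), names(bundle_b$energy))
    energy <- do.call(rbind, lapply(nms, function(nm) {
      ed <- energy_delta(bundle_a$energy[[nm]], bundle_b$energy[[nm]])
      data.frame(peptide = nm, mean_a = round(ed$mean_a, 1),
                 mean_b = round(ed$mean_b, 1), ddg = round(ed$ddg, 1))
    }))
  }

  idelta <- compare_states(bundle_a$interactions, bundle_b$interactions)

  report <- structure(list(metrics = metrics, energy = energy,
                           interaction_delta = idelta,
                           system_a = bundle_a$name,
                           system_b = bundle_b$name),
                      class = "tn_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE, quote = FALSE)
    id <- as.data.frame(idelta)
    id$percent_a <- round(id$percent_a, 4)
    id$percent_b <- round(id$percent_b, 4)
    id$delta <- round(id$delta, 4)
    utils::write.csv(id, file.path(out_dir, "interaction_delta.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(energy)) {
      utils::write.csv(energy, file.path(out_dir, "energy.csv"),
                       row.names = FALSE, quote = FALSE)
    }
  }
  report
}

#' @export
print.tn_report <- function(x, ...) {
  cat(sprintf("Comparison %s -> %s\n", x$system_a, x$system_b))
  print(x$metrics, row.names = FALSE)
  if (!is.null(x$energy)) {
    cat("Binding free-energy deltas (kcal/mol):\n")
    print(x$energy, row.names = FALSE)
  }
  big <- x$interaction_delta[abs(x$interaction_delta$delta) >= 10, ]
  if (nrow(big)) {
    cat(sprintf("%d residue-pair interactions changed by >= 10 points\n",
                nrow(big)))
  }
  invisible(x)
}
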