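# Two-condition comparison pipeline: metrics -> interactions -> essential
# dynamics -> free-energy landscape -> DCCM -> residue network, per
# condition, followed by paired difference tables.

#' Analysis configuration
#'
#' Bundles every tunable threshold with its conventional default: H-bond
#' 3.5 A / 30 degrees, salt-bridge 4.0 A, edge threshold `cmin` 0.3, contact
#' cutoff 10 A (off unless `contact_filter = TRUE`), cosine-content ceiling
#' 0.1, high-betweenness cutoff 0.15, betweenness-difference cutoff 0.12,
#' moving-average window 500 frames, 32 x 32 landscape bins at 300 K.
#'
#' @param selection analysis atom selection (default `"name CA"`).
#' @param window optional `c(start, stop)` time window in ps.
#' @param domain_map a [domain_map()].
#' @param hbond an [hbond_criteria()].
#' @param saltbridge_cutoff Angstrom.
#' @param cmin minimum `|C|` for a network edge.
#' @param contact_filter logical; AND a 10 A C-alpha contact filter.
#' @param contact_cutoff Angstrom.
#' @param cosine_threshold cosine-content ceiling for PC selection.
#' @param cb_threshold high-betweenness cutoff.
#' @param dcb_threshold betweenness-difference cutoff.
#' @param smooth_bin moving-average window (frames).
#' @param n_bins landscape bins per axis.
#' @param temperature_K landscape temperature label.
#' @param seed seed recorded in reports.
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(selection = "name CA", window = NULL,
                            domain_map = confdyn::domain_map(),
                            hbond = hbond_criteria(),
                            saltbridge_cutoff = 4.0,
                            cmin = 0.3, contact_filter = FALSE,
                            contact_cutoff = 10,
                            cosine_threshold = 0.1,
                            cb_threshold = 0.15, dcb_threshold = 0.12,
                            smooth_bin = 500L, n_bins = 32L,
                            temperature_K = 300, seed = 1L) {
  stopifnot(cmin >= 0, cmin < 1, cosine_threshold > 0,
            cb_threshold >= 0, dcb_threshold >= 0, n_bins >= 2)
  structure(list(selection = selection, window = window,
                 domain_map = domain_map, hbond = hbond,
                 saltbridge_cutoff = saltbridge_cutoff, cmin = cmin,
                 contact_filter = contact_filter,
                 contact_cutoff = contact_cutoff,
                 cosine_threshold = cosine_threshold,
                 cb_threshold = cb_threshold, dcb_threshold = dcb_threshold,
                 smooth_bin = smooth_bin, n_bins = n_bins,
                 temperature_K = temperature_K, seed = seed),
            class = "analysis_config")
}

.stage <- function(name, expr) {
  t0 <- proc.time()[3]
  out <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("stage %-12s done in %.2f s", name, proc.time()[3] - t0))
  out
}

#' Run the full analysis for one condition
#'
#' Executes metrics, interactions (optional pairs), essential dynamics,
#' free-energy landscape (RMSD vs Rg), DCCM and the residue network in
#' order, returning every product in a single bundle.  Deterministic for a
#' given trajectory and configuration.
#'
#' @param traj a `"trajectory"` object for the condition.
#' @param config an [analysis_config()].
#' @param condition a label (e.g. `"WT"`, `"pS44"`).
#' @param hbond_pairs optional 2-column matrix / list of residue-id pairs to
#'   track H-bond occupancy for.
#' @param saltbridge_pairs optional residue-id pairs for salt-bridge series.
#' @return A list of class `"condition_bundle"` containing `condition`,
#'   `rmsd`, `rg`, `rmsd_distribution`, `rg_distribution`, `rmsf`, `ed`,
#'   `variance_fractions`, `cosine_contents`, `fel`, `basins`, `dccm`,
#'   `network`, `centrality`, `hbonds`, `saltbridges`.
#' @export
run_condition <- function(traj, config = analysis_config(),
                          condition = "condition", hbond_pairs = NULL,
                          saltbridge_pairs = NULL) {
  if (!is.null(config$window))
    traj <- time_window(traj, config$window[1], config$window[2])
  rmsd <- .stage("rmsd", rmsd_series(traj, 1L, config$selection))
  rg <- .stage("rg", rg_series(traj, config$selection))
  nb <- min(100L, max(10L, n_frames(traj) %/% 10L))
  rmsd_dist <- metric_distribution(rmsd, n_bins = nb)
  rg_dist <- metric_distribution(rg, n_bins = nb)
  rmsf <- .stage("rmsf", rmsf_per_residue(traj, config$selection))
  ed <- .stage("pca", essential_dynamics(traj, config$selection))
  nchk <- min(5L, length(ed$eigenvalues))
  projs <- lapply(seq_len(nchk), function(k) project_trajectory(traj, ed, k))
  cc <- vapply(projs, cosine_content, numeric(1))
  if (n_frames(traj) >= 100) {
    fel <- .stage("fel", build_fel(rmsd, rg, config$n_bins,
                                   config$temperature_K, "RMSD (A)", "Rg (A)"))
    basins <- find_basins(fel)
  } else {
    message("fewer than 100 frames: free-energy landscape skipped")
    fel <- NULL; basins <- list()
  }
  dccm <- .stage("dccm", compute_dccm(traj, config$selection))
  net <- .stage("network", build_network(
    dccm, config$cmin,
    contact_coords = if (config$contact_filter)
      frame_coords(subset_trajectory(traj, config$selection), 1L),
    contact_cutoff = config$contact_cutoff))
  centr <- .stage("centrality", centrality_profile(net))
  as_pairs <- function(p) if (is.null(p)) list() else
    if (is.matrix(p)) lapply(seq_len(nrow(p)), function(i) p[i, ]) else p
  hbonds <- lapply(as_pairs(hbond_pairs), function(p)
    hbond_occupancy(traj, p[1], p[2], config$hbond))
  sbs <- lapply(as_pairs(saltbridge_pairs), function(p)
    saltbridge_series(traj, p[1], p[2], config$saltbridge_cutoff))
  structure(list(condition = condition, config = config,
                 rmsd = rmsd, rg = rg,
                 rmsd_distribution = rmsd_dist, rg_distribution = rg_dist,
                 rmsf = rmsf, ed = ed,
                 variance_fractions = c(pc1 = variance_fraction(ed, 1),
                                        pc1_2 = variance_fraction(ed, 2)),
                 cosine_contents = cc, fel = fel, basins = basins,
                 dccm = dccm, network = net, centrality = centr,
                 hbonds = hbonds, saltbridges = sbs),
            class = "condition_bundle")
}

#' @export
print.condition_bundle <- function(x, ...) {
  cat("Condition bundle '", x$condition, "':\n", sep = "")
  cat(sprintf("  mean RMSD %.2f A, mean Rg %.2f A, %d FEL basin(s)\n",
              mean(x$rmsd$values), mean(x$rg$values), length(x$basins)))
  cat(sprintf("  PC1 variance fraction %.2f; %d network edges\n",
              x$variance_fractions["pc1"], nrow(x$network$edges)))
  invisible(x)
}

.basin_table <- function(basins) {
  if (!length(basins))
    return(data.frame(label = integer(0), cv1 = numeric(0),
                      cv2 = numeric(0), min_G = numeric(0),
                      n_frames = integer(0)))
  do.call(rbind, lapply(basins, function(b)
    data.frame(label = b$label, cv1 = b$center[1], cv2 = b$center[2],
               min_G = b$min_G, n_frames = b$n_frames)))
}

#' Compare two analysed conditions
#'
#' @param bundleA,bundleB `"condition_bundle"` objects over the same residue
#'   set (e.g. wild-type and phosphorylated).
#' @param config an [analysis_config()] (thresholds for the difference
#'   selections); defaults to `bundleA$config`.
#' @return A list of class `"comparison_report"` with `schema_version`,
#'   per-condition summaries, the betweenness difference table and selected
#'   residues, high-betweenness residues per condition, basin tables and
#'   centrality correlation matrices.
#' @export
compare_conditions <- function(bundleA, bundleB, config = bundleA$config) {
  if (!identical(bundleA$centrality$residue_id, bundleB$centrality$residue_id))
    stop("conditions cover different residue sets")
  dcb <- centrality_difference(bundleA$centrality, bundleB$centrality,
                               config$dcb_threshold)
  summaries <- lapply(list(bundleA, bundleB), function(b) list(
    condition = b$condition,
    mean_rmsd = mean(b$rmsd$values), mean_rg = mean(b$rg$values),
    rmsd_peaks = b$rmsd_distribution$peaks$location,
    rg_peaks = b$rg_distribution$peaks$location,
    variance_fractions = b$variance_fractions,
    n_basins = length(b$basins),
    basins = .basin_table(b$basins),
    high_betweenness = high_centrality(b$centrality, config$cb_threshold),
    centrality_pearson = centrality_pearson(b$centrality),
    hbond_occupancies = vapply(b$hbonds, `[[`, numeric(1), "occupancy"),
    saltbridge_means = vapply(b$saltbridges, `[[`, numeric(1),
                              "mean_distance")))
  names(summaries) <- c(bundleA$condition, bundleB$condition)
  structure(list(schema_version = "1.0", conditions = summaries,
                 betweenness_difference = dcb$delta,
                 selected_residues = dcb$selected,
                 thresholds = list(cb = config$cb_threshold,
                                   dcb = config$dcb_threshold)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Comparison report (schema", x$schema_version, ")\n")
  for (nm in names(x$conditions)) {
    s <- x$conditions[[nm]]
    cat(sprintf("  %s: mean RMSD %.2f A, mean Rg %.2f A, %d basin(s), %d high-C_B residue(s)\n",
                nm, s$mean_rmsd, s$mean_rg, s$n_basins,
                nrow(s$high_betweenness)))
  }
  cat(sprintf("  |delta C_B| >= %.2f: %d residue(s)\n",
              x$thresholds$dcb, nrow(x$selected_residues)))
  invisible(x)
}

#' Write a comparison report to disk
#'
#' JSON for the full report plus per-table CSVs.
#'
#' @param report a `"comparison_report"`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  utils::write.csv(report$betweenness_difference,
                   file.path(dir, "betweenness_difference.csv"),
                   row.names = FALSE)
  utils::write.csv(report$selected_residues,
                   file.path(dir, "selected_residues.csv"),
                   row.names = FALSE)
  invisible(path)
}
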