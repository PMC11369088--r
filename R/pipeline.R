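# File-to-file stage runners behind the command-line interface. Each stage
# reads tables, runs the corresponding in-memory functions, and writes TSV
# outputs plus a JSON run-metadata sidecar; re-running with the same inputs
# and seed reproduces every output byte for byte.

.write_meta <- function(out_dir, stage, config, extra = list()) {
  meta <- c(list(
    stage = stage,
    package_version = as.character(utils::packageVersion("trip")),
    config = config), extra)
  jsonlite::write_json(meta, file.path(out_dir, paste0(stage, "_meta.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}

#' Run the dataset simulation stage
#'
#' Writes `quant.tsv`, `design.tsv`, `truth.json` and (when a screen config
#' is given) `plates.tsv` under `out_dir`.
#'
#' @param cfg `trip_sim_config` (see [simulation_config()]).
#' @param out_dir output directory (created if needed).
#' @param screen_cfg optional [screen_config()] to emit screen plates too.
#' @return invisibly, the list of written paths.
#' @export
run_simulate <- function(cfg, out_dir, screen_cfg = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- emit_trip_dataset(cfg)
  paths <- c(quant = file.path(out_dir, "quant.tsv"),
             design = file.path(out_dir, "design.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_quant_table(ds$quant, paths["quant"])
  write_design(ds$design, paths["design"])
  jsonlite::write_json(ds$truth, paths["truth"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  if (!is.null(screen_cfg)) {
    sc <- emit_screen_dataset(screen_cfg)
    paths["plates"] <- file.path(out_dir, "plates.tsv")
    write_tsv_precise(sc$plates, paths[["plates"]])
  }
  .write_meta(out_dir, "simulate", cfg[setdiff(names(cfg), "interactors")])
  invisible(paths)
}

#' Run the interactor-calling stage
#'
#' @param quant_path,design_path input tables.
#' @param out_path output enrichment TSV.
#' @param config configuration list.
#' @return invisibly, the enrichment table.
#' @export
run_call_interactors <- function(quant_path, design_path, out_path,
                                 config = default_config()) {
  q <- read_quant_table(quant_path)
  d <- read_design(design_path, grid = config$timepoint_grid)
  e <- run_interactor_calling(q, d, config)
  dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)
  write_tsv_precise(e, out_path)
  .write_meta(dirname(out_path), "call_interactors", config,
              list(sigma = attr(e, "sigma"),
                   fc_threshold = attr(e, "fc_threshold")))
  invisible(e)
}

#' Run the temporal-profiling stage
#'
#' Bait normalization, replicate QC, enrichment over background, unit-
#' interval scaling, pathway aggregation and feature extraction; writes
#' `profiles.tsv`, `qc_report.tsv`, `features.tsv`, `heatmap.tsv` and, with
#' a pathway map, `pathway_aggregates.tsv`.
#'
#' @param quant_path,design_path input tables.
#' @param bait_id bait accession.
#' @param out_dir output directory.
#' @param pathway_path optional pathway map TSV.
#' @param proteins optional protein subset (e.g. called interactors); by
#'   default all non-bait proteins are profiled.
#' @param config configuration list.
#' @return invisibly, a list with the profile set and derived tables.
#' @export
run_profile <- function(quant_path, design_path, bait_id, out_dir,
                        pathway_path = NULL, proteins = NULL,
                        config = default_config()) {
  q <- read_quant_table(quant_path)
  d <- read_design(design_path, grid = config$timepoint_grid)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  qc <- qc_replicates(q, d, bait_id, cv_threshold = config$cv_threshold)
  keep <- qc[!qc$excluded, c("condition", "replicate")]
  qb <- bait_normalize(q, d[paste(d$condition, d$replicate) %in%
                              paste(keep$condition, keep$replicate) |
                              d$role == "booster", , drop = FALSE], bait_id)
  if (is.null(proteins)) proteins <- setdiff(rownames(q), bait_id)
  enr <- compute_enrichment(qb, d, reference = config$reference,
                            proteins = proteins, keep_replicates = keep)
  prof <- scale_profiles(enr, scaling_scope = config$scaling_scope)
  feats <- profile_summary(prof)
  write_tsv_precise(prof$profiles, file.path(out_dir, "profiles.tsv"))
  write_tsv_precise(qc, file.path(out_dir, "qc_report.tsv"))
  write_tsv_precise(feats, file.path(out_dir, "features.tsv"))
  hm <- profiles_heatmap_matrix(prof)
  write_tsv_precise(data.frame(protein_id = rownames(hm), hm,
                               check.names = FALSE),
                    file.path(out_dir, "heatmap.tsv"))
  agg <- NULL
  if (!is.null(pathway_path)) {
    agg <- aggregate_pathways(prof, read_pathway_map(pathway_path))
    write_tsv_precise(agg, file.path(out_dir, "pathway_aggregates.tsv"))
  }
  .write_meta(out_dir, "profile", config,
              list(bait_id = bait_id, quartile_convention = "type-7"))
  invisible(list(profiles = prof, qc = qc, features = feats, aggregates = agg))
}

#' Run the clustering stage
#'
#' Clusters one condition (or a condition pair on the concatenated series),
#' writing `clusters.tsv`, `centroids.tsv`, `cluster_summary.tsv`,
#' `silhouette.tsv` (when k is selected automatically) and, for a pair,
#' `flow.tsv`.
#'
#' @param profiles_path long profiles TSV from [run_profile()].
#' @param conditions condition label or pair.
#' @param out_dir output directory.
#' @param k integer, or `"auto"` for silhouette selection over 2..8.
#' @param seed integer RNG seed.
#' @param n_restarts k-means restarts.
#' @return invisibly, the `trip_clusters` object (for a pair, a list with
#'   the per-condition assignments and flow).
#' @export
run_cluster <- function(profiles_path, conditions, out_dir, k = "auto",
                        seed = 1L, n_restarts = 20L) {
  long <- utils::read.table(profiles_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  prof <- structure(list(profiles = long,
                         grid = sort(unique(long$timepoint_h)),
                         scope = "unknown"), class = "trip_profiles")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  X <- profile_matrix(prof, conditions)
  sil <- NULL
  if (identical(k, "auto")) {
    sel <- choose_k(X, k_range = 2:8, seed = seed, n_restarts = n_restarts)
    k <- sel$selected_k
    sil <- sel$diagnostics
    write_tsv_precise(sil, file.path(out_dir, "silhouette.tsv"))
  }
  a <- cluster_profiles(X, k = as.integer(k), seed = seed,
                        n_restarts = n_restarts)
  write_tsv_precise(a$assignment, file.path(out_dir, "clusters.tsv"))
  write_tsv_precise(data.frame(cluster = rownames(a$centroids), a$centroids,
                               check.names = FALSE),
                    file.path(out_dir, "centroids.tsv"))
  write_tsv_precise(summarize_clusters(a), file.path(out_dir, "cluster_summary.tsv"))
  flow <- NULL
  if (length(conditions) == 2L) {
    a1 <- cluster_profiles(prof, conditions[1L], k = a$k, seed = seed,
                           n_restarts = n_restarts)
    a2 <- cluster_profiles(prof, conditions[2L], k = a$k, seed = seed,
                           n_restarts = n_restarts)
    flow <- cluster_flow(a1, a2)
    write_tsv_precise(flow$long, file.path(out_dir, "flow.tsv"))
  }
  .write_meta(out_dir, "cluster",
              list(conditions = conditions, k = a$k, seed = seed,
                   n_restarts = n_restarts))
  invisible(list(assignment = a, silhouette = sil, flow = flow))
}

#' Run the siRNA screen stage
#'
#' Normalizes plates, calls hits and summarizes controls; writes
#' `screen_results.tsv` and `qc_controls.tsv`.
#'
#' @param plates_path long-format plate TSV.
#' @param out_dir output directory.
#' @param sigma_multiplier hit cutoff in sigma units (default 3).
#' @param min_replicates minimum replicate plates per gene.
#' @return invisibly, the screen result table.
#' @export
run_screen <- function(plates_path, out_dir, sigma_multiplier = 3,
                       min_replicates = 2L) {
  p <- read_screen_plates(plates_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ctrl <- summarize_controls(p)
  pn <- normalize_plate(p)
  res <- call_screen_hits(pn, sigma_multiplier = sigma_multiplier,
                          min_replicates = min_replicates)
  write_tsv_precise(res, file.path(out_dir, "screen_results.tsv"))
  write_tsv_precise(ctrl, file.path(out_dir, "qc_controls.tsv"))
  .write_meta(out_dir, "screen",
              list(sigma_multiplier = sigma_multiplier,
                   min_replicates = min_replicates),
              list(calibration = attr(res, "calibration")))
  invisible(res)
}
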