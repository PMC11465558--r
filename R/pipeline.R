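#' Pipeline configuration
#'
#' Exactly one of `table_path`+`metadata_path` (ingest mode) or
#' `simulation` (a [sim_params()] or list of its arguments) must be
#' given.
#'
#' @param table_path,metadata_path input feature table (TSV, samples as
#'   rows) and metadata TSV
#' @param simulation a [sim_params()] or argument list for it
#' @param rarefaction_depth reads per sample for the dissimilarity
#'   stream (default 5500)
#' @param rarefaction_seed seed of the rarefaction draw
#' @param n_permutations Monte-Carlo permutation count (default 999)
#' @param permutation_seed seed for Monte-Carlo schemes
#' @param alpha significance level for the recovery rules
#' @param simper_k taxa kept per SIMPER comparison (default 100)
#' @param simper_n_perm SIMPER label permutations
#' @param output_dir directory for TSV/JSON outputs, or NULL to skip
#'   writing
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(table_path = NULL, metadata_path = NULL,
                            simulation = NULL,
                            rarefaction_depth = 5500, rarefaction_seed = 1L,
                            n_permutations = 999L, permutation_seed = 1L,
                            alpha = 0.05,
                            simper_k = 100L, simper_n_perm = 999L,
                            output_dir = NULL) {
  has_input <- !is.null(table_path) || !is.null(metadata_path)
  has_sim <- !is.null(simulation)
  if (has_input && has_sim)
    stop("config error: give input paths or a simulation block, not both")
  if (!has_input && !has_sim)
    stop("config error: one of input paths or a simulation block is required")
  if (has_input && (is.null(table_path) || is.null(metadata_path)))
    stop("config error: ingest mode needs both table_path and metadata_path")
  if (has_sim && !inherits(simulation, "sim_params"))
    simulation <- do.call(sim_params, as.list(simulation))
  structure(list(table_path = table_path, metadata_path = metadata_path,
                 simulation = simulation,
                 rarefaction_depth = rarefaction_depth,
                 rarefaction_seed = as.integer(rarefaction_seed),
                 n_permutations = as.integer(n_permutations),
                 permutation_seed = as.integer(permutation_seed),
                 alpha = alpha, simper_k = as.integer(simper_k),
                 simper_n_perm = as.integer(simper_n_perm),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [pipeline_config()] arguments
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full disturbance-response pipeline
#'
#' Simulate or ingest, preprocess along the two streams (rarefied and
#' singleton-filtered counts for dissimilarity analyses; unrarefied
#' relative abundance for SIMPER and the heatmap), then compute: the
#' day-0 treatment test (free within blocks), the split-plot Treatment
#' test (whole-plot error and randomization), the Day and Day:Treatment
#' tests, overall dispersion, the per-treatment day-versus-baseline
#' grid with resistance/resilience summaries, per-plot dissimilarity
#' trajectories with cross-treatment contrasts, SIMPER with the
#' top-contributor union, the day-0 and interaction partial dbRDAs
#' (conditioned on block), and the heatmap matrix of the union taxa.
#'
#' @param config a [pipeline_config()]
#' @return list of class `pipeline_result` (see element names); a
#'   `manifest` element records seeds, scheme levels and attrition
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  if (!is.null(config$simulation)) {
    say("stage simulate: seed %d", config$simulation$seed)
    sim <- simulate_study(config$simulation)
    counts <- sim$counts; design <- sim$design
  } else {
    say("stage ingest: %s", config$table_path)
    counts <- read_count_table(config$table_path)
    design <- read_metadata(config$metadata_path)
    sim <- NULL
  }
  counts <- count_table(unclass(counts)[design$sample_id[
    design$sample_id %in% rownames(counts)], , drop = FALSE])
  design <- study_design(as.data.frame(
    design[design$sample_id %in% rownames(counts), , drop = FALSE]))

  ## dissimilarity stream: rarefy then drop singletons
  rare <- rarefy(counts, depth = config$rarefaction_depth,
                 seed = config$rarefaction_seed)
  dropped <- attr(rare, "dropped")
  say("stage rarefy: depth %d, dropped %d sample(s)",
      as.integer(config$rarefaction_depth), length(dropped))
  rare <- remove_singletons(rare)
  design_r <- study_design(as.data.frame(
    design[design$sample_id %in% rownames(rare), , drop = FALSE]))
  rare <- count_table(unclass(rare)[design_r$sample_id, , drop = FALSE])
  d <- bray_curtis(rare)

  ## taxonomic stream: unrarefied relative abundance
  rel <- to_relative_abundance(counts)

  sch <- function(level) perm_scheme(level,
                                     n_permutations = config$n_permutations,
                                     seed = config$permutation_seed)

  ## day-0 test
  day0 <- design_r$day == 0L
  d0 <- dist_matrix(unclass(d)[day0, day0], metric = "bray")
  des0 <- study_design(as.data.frame(design_r[day0, , drop = FALSE]))
  say("stage day0: %d samples", nrow(des0))
  day0_test <- permutation_test(d0, des0, terms = "Treatment",
                                term = "Treatment",
                                scheme = sch("free_within_block"),
                                denominator = "residual")
  day0_disp <- dispersion_test(
    distances_to_center(pcoa(d0), factor(des0$treatment)))
  day0_dbrda <- partial_dbrda(d0, constraints = data.frame(trt = des0$treatment),
                              conditions = data.frame(block = des0$block))

  ## split-plot tests over the full series
  say("stage permanova: whole-plot Treatment, within-plot Day, interaction")
  trt_test <- permutation_test(d, design_r,
                               terms = c("Treatment", "Plot"),
                               term = "Treatment",
                               scheme = sch("whole_plot"),
                               denominator = "whole_plot")
  day_test <- permutation_test(d, design_r,
                               terms = c("Plot", "Day"), term = "Day",
                               scheme = sch("within_plot"),
                               denominator = "residual")
  int_test <- permutation_test(d, design_r,
                               terms = c("Plot", "Day", "Day:Treatment"),
                               term = "Day:Treatment",
                               scheme = sch("whole_plot"),
                               denominator = "residual")
  overall_disp <- dispersion_test(
    distances_to_center(pcoa(d), factor(design_r$treatment)))

  ## recovery metrics
  say("stage recovery: paired day-versus-baseline grid")
  traj <- trajectory_report(d, design_r, alpha = config$alpha,
                            scheme = sch("paired_within_plot"))

  ## SIMPER on relative abundance
  say("stage simper: %d permutations", config$simper_n_perm)
  simp <- simper_all_pairs(rel, design$treatment,
                           n_perm = config$simper_n_perm,
                           seed = config$permutation_seed)
  k <- min(config$simper_k, ncol(rel))
  union_taxa <- top_contributors(simp, k = k)
  say("stage simper: top-%d union holds %d taxa", k, length(union_taxa))

  ## interaction dbRDA and heatmap
  int_dbrda <- partial_dbrda(
    d, constraints = data.frame(td = interaction(design_r$day,
                                                 design_r$treatment)),
    conditions = data.frame(block = design_r$block))
  centroids <- group_centroids(int_dbrda,
                               paste(design_r$treatment, design_r$day,
                                     sep = "_d"))
  heat <- heatmap_matrix(rel, union_taxa, design)

  manifest <- list(
    mode = if (is.null(sim)) "ingest" else "simulate",
    rarefaction = list(depth = config$rarefaction_depth,
                       seed = config$rarefaction_seed,
                       dropped_samples = dropped),
    permutations = list(n = config$n_permutations,
                        seed = config$permutation_seed),
    alpha = config$alpha,
    simulation_seed = if (is.null(sim)) NULL else config$simulation$seed,
    n_samples = nrow(design_r), n_taxa = ncol(rare))

  res <- structure(list(
    counts = counts, design = design, rarefied = rare, distances = d,
    day0_test = day0_test, day0_dispersion = day0_disp,
    day0_dbrda = day0_dbrda,
    treatment_test = trt_test, day_test = day_test,
    interaction_test = int_test, overall_dispersion = overall_disp,
    trajectory = traj, simper = simp, top_taxa = union_taxa,
    interaction_dbrda = int_dbrda, interaction_centroids = centroids,
    heatmap = heat, manifest = manifest, log = log_lines,
    truth = if (is.null(sim)) NULL else sim$truth),
    class = "pipeline_result")
  if (!is.null(config$output_dir)) write_pipeline_result(res, config$output_dir)
  res
}

write_pipeline_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                         quote = FALSE, row.names = FALSE)
  w(as.data.frame(res$day0_test), "day0_treatment_test.tsv")
  w(as.data.frame(res$treatment_test), "treatment_test.tsv")
  w(as.data.frame(res$day_test), "day_test.tsv")
  w(as.data.frame(res$interaction_test), "interaction_test.tsv")
  grid <- do.call(rbind, lapply(valid_treatments(), function(tr) {
    if (is.null(res$trajectory[[tr]])) return(NULL)
    cbind(treatment = tr, res$trajectory[[tr]]$day_tests)
  }))
  w(grid, "day_vs_baseline_grid.tsv")
  w(res$trajectory$series, "baseline_dissimilarity_series.tsv")
  for (nm in names(res$simper))
    w(res$simper[[nm]], paste0("simper_", gsub("[^A-Za-z0-9_-]", "_", nm), ".tsv"))
  writeLines(res$top_taxa, file.path(dir, "top_taxa_union.txt"))
  w(res$interaction_centroids, "interaction_centroids.tsv")
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  day-0 Treatment: R2 = %.3f, F = %.3g, p = %.4g\n",
              x$day0_test["Treatment", "R2"], x$day0_test["Treatment", "F"],
              x$day0_test["Treatment", "p"]))
  cat(sprintf("  Treatment (whole-plot): F = %.3g, p = %.4g\n",
              x$treatment_test["Treatment", "F"],
              x$treatment_test["Treatment", "p"]))
  cat(sprintf("  Day: F = %.3g, p = %.4g | Day:Treatment: F = %.3g, p = %.4g\n",
              x$day_test["Day", "F"], x$day_test["Day", "p"],
              x$interaction_test["Day:Treatment", "F"],
              x$interaction_test["Day:Treatment", "p"]))
  for (tr in intersect(valid_treatments(), names(x$trajectory)))
    cat(sprintf("  %s: first change day %s, recovery day %s\n", tr,
                x$trajectory[[tr]]$first_change_day,
                x$trajectory[[tr]]$recovery_day))
  cat(sprintf("  SIMPER union: %d taxa\n", length(x$top_taxa)))
  invisible(x)
}
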