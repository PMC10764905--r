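#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end analysis in one list
#' that round-trips through YAML unchanged. Defaults describe a desk-scale
#' simulation (small parcellation, few animals) so a full pipeline run stays
#' fast; the hierarchy of a full study (10 animals x 3 sessions x 4 runs,
#' 542 regions, 500 fit seeds) is reached by overriding the corresponding
#' entries.
#'
#' @param ... Overrides of the default entries (unknown names are an error).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # synthetic design
    n_rois = 40L, k = 3L, overlap = 0.2, n_animals = 3L, n_sessions = 2L,
    n_runs = 2L, n_timepoints = 300L, fs = 1, noise_sd = 0.6,
    animal_sd = 0.1, condition = "bold",
    # preprocessing
    band_low = 0.01, band_high = 0.4, filter_order = 3L, trim = 15L,
    motion_threshold = 0.1, drop_fraction = 0.5,
    # graphs and fit
    density = 0.15, n_seeds = 5L, max_iters = 120L,
    # inference
    bootstrap_iters = 300L, fdr_q = 0.05,
    tier_multipliers = c(0.05, 1, 2, 3.5),
    # gradients
    n_gradients = 2L, sparsify_top = 0.1, diffusion_alpha = 0.5
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return `read_pipeline_config()` returns a `"pipeline_config"`;
#'   `write_pipeline_config()` returns the path invisibly. A config written
#'   and re-read compares identical.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full overlapping-network pipeline on simulated data
#'
#' Executes every stage against a synthetic hierarchical dataset: simulate ->
#' band-pass filter and motion-censor -> correlation matrices -> fixed-density
#' graphs -> per-run mixed-membership fits over several seeds -> seed
#' consensus -> hierarchical aggregation -> node statistics (entropy,
#' belonging, overlap score, degree, participation) -> diffusion-map
#' gradients -> delimited tables plus a machine-readable report. Every random
#' step is seeded from `config$seed`, so a rerun with the same configuration
#' reproduces the report byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; created if needed. `NULL` skips writing.
#' @return Invisibly, a list with the main results (`run_pis`, `group_pi`,
#'   `belonging`, `node_stats`, `gradients`, `report`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- planted_membership(config$n_rois, config$k, overlap = config$overlap,
                              seed = config$seed)
  ds <- generate_hierarchical_dataset(
    truth, n_animals = config$n_animals, n_sessions = config$n_sessions,
    n_runs = config$n_runs, n_timepoints = config$n_timepoints,
    noise_sd = config$noise_sd, fs = config$fs, animal_sd = config$animal_sd,
    condition = config$condition, seed = config$seed)

  prep <- lapply(ds$runs, function(r) {
    r <- bandpass_filter(r, config$band_low, config$band_high,
                         order = config$filter_order, trim = config$trim)
    censor_frames(r, config$motion_threshold, config$drop_fraction)
  })
  kept <- !vapply(prep, function(r) isTRUE(attr(r, "flagged")), logical(1))
  prep <- prep[kept]

  corrs <- lapply(prep, correlation_matrix)
  graphs <- lapply(corrs, threshold_density, d = config$density)

  fit_seeds <- config$seed * 1000L + seq_len(config$n_seeds)
  ctrl <- mmsb_control(max_iters = config$max_iters)
  run_pis <- lapply(seq_along(graphs), function(i) {
    fits <- lapply(fit_seeds + i, function(s)
      fit_mmsb(graphs[[i]], k = config$k, seed = s %% .Machine$integer.max,
               control = ctrl))
    consensus_over_seeds(fits, k = config$k, seed = config$seed)
  })

  index <- dataset_index(fc_dataset(prep))
  agg <- aggregate_hierarchy(run_pis, index)

  # align run-level solutions to the group result before entry-wise stats
  aligned_runs <- lapply(run_pis, function(p) align_to_centroids(p, agg$group)$aligned)
  bs <- hierarchical_bootstrap_matrix(aligned_runs, index,
                                      n_iter = config$bootstrap_iters,
                                      seed = config$seed)
  bel <- belonging_matrix(agg$group, bs$se,
                          belonging_config(mu0 = 1 / config$k))
  tiers <- membership_tiers(agg$group, bs$se,
                            tier_multipliers = config$tier_multipliers)
  entropy_runs <- vapply(aligned_runs, function(p) .entropy_rows(p, config$k),
                         numeric(config$n_rois))
  deg <- lapply(graphs, degree_stats)
  deg_runs <- vapply(deg, function(d) d$normalized_degree, numeric(config$n_rois))
  labels <- disjointify(agg$group)
  pc <- participation_coefficient(graphs[[1]], labels)

  node_stats <- data.frame(
    node = seq_len(config$n_rois) - 1L,
    entropy = rowMeans(entropy_runs),
    entropy_percentile = percentile_map(entropy_runs),
    normalized_degree = rowMeans(deg_runs),
    degree_percentile = percentile_map(deg_runs),
    participation = as.numeric(pc),
    belonging_count = bel$counts,
    disjoint_label = as.integer(labels))

  group_fc <- fisher_group_average(corrs)
  grad <- compute_gradients(group_fc, n_components = config$n_gradients,
                            sparsify_top = config$sparsify_top,
                            diffusion_alpha = config$diffusion_alpha)

  report <- list(
    config = unclass(config),
    n_runs_total = length(ds$runs), n_runs_kept = sum(kept),
    removal_rate_pct = 100 * mean(!kept),
    median_max_membership = stats::median(apply(agg$group, 1, max)),
    overlap_score = bel$overlap_score,
    mean_entropy = mean(node_stats$entropy),
    gradient_variance_fraction = grad$variance_fraction)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_membership(agg$group, file.path(out_dir, "group_membership.tsv"),
                     level = "group", condition = config$condition,
                     seed = config$seed)
    utils::write.table(node_stats, file.path(out_dir, "node_stats.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_gradients(grad, file.path(out_dir, "gradients.tsv"))
    yaml::write_yaml(report, file.path(out_dir, "report.yaml"))
    writeLines(c(sprintf("overnet %s", as.character(utils::packageVersion("overnet"))),
                 sprintf("seed %d", config$seed),
                 sprintf("runs kept %d/%d", sum(kept), length(ds$runs)),
                 "stages: simulate filter censor correlate threshold fit consensus aggregate stats gradients"),
               file.path(out_dir, "pipeline.log"))
  }
  invisible(list(run_pis = run_pis, group_pi = agg$group, belonging = bel,
                 node_stats = node_stats, gradients = grad, report = report))
}

#' Small bundled benchmark fixtures
#'
#' Deterministic, fast-to-build test objects (at most 60 nodes): two disjoint
#' cliques, a sampled mixed-membership benchmark, a small disjoint LFR-style
#' benchmark, and a miniature hierarchical dataset.
#'
#' @param seed Integer seed.
#' @return Named list of fixtures.
#' @export
make_fixtures <- function(seed = 1L) {
  adj <- matrix(0L, 40, 40)
  adj[1:20, 1:20] <- 1L; adj[21:40, 21:40] <- 1L; diag(adj) <- 0L
  two_cliques <- fc_graph(adj)
  mmsb_bench <- sample_mmsb_graph(60, mmsb_hyper(3, alpha = 0.1), seed = seed)
  lfr_small <- generate_lfr_graph(
    lfr_params(n_nodes = 60, avg_degree = 8, mu_topo = 0.1, c_min = 10,
               c_max = 30, on = 0), seed = seed)
  truth <- planted_membership(20, 2, overlap = 0, seed = seed)
  dataset <- generate_hierarchical_dataset(
    truth, n_animals = 2, n_sessions = 2, n_runs = 2, n_timepoints = 200,
    noise_sd = 0.3, seed = seed)
  list(two_cliques = two_cliques, mmsb_bench = mmsb_bench,
       lfr_small = lfr_small, dataset = dataset)
}
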