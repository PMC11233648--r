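#' Configuration for an end-to-end synthetic pipeline run
#'
#' Collects the settings of every stage with the detection constants at
#' their standard values (2 Hz rate filter, 25-bin jitter windows, 12-bin
#' maximum lag, 4-fold significance, 0.9 entropy threshold, minimum module
#' size 4). The surrogate ensemble and Louvain restart counts default to
#' smaller values than [surrogate_spec()]'s 200 so a demo run completes in
#' minutes; raise them for production-quality Z-scores.
#'
#' @param labels Stimulus labels to simulate; each label gets its own set of
#'   planted couplings over a shared population.
#' @param population Settings passed to [make_ground_truth()] (population
#'   part: `n_units`, `areas`, `baseline_hz`, `positions`).
#' @param couplings Coupling settings per label (recycled): `n_couplings`,
#'   `frac_positive`, `lag_range`, `duration_range`, `transmission`,
#'   `modulation`.
#' @param n_trials,n_bins Trials and bins per trial for each label.
#' @param detection A [detection_params()].
#' @param surrogates Ensemble size for motif / modularity Z-scores.
#' @param modularity A [modularity_params()].
#' @param louvain_runs Louvain restarts for empirical networks.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(labels = c("gratings", "movie"),
                       population = list(n_units = 60L, baseline_hz = 20),
                       couplings = list(n_couplings = 10L, frac_positive = 0.6,
                                        transmission = 0.5),
                       n_trials = 100L, n_bins = 2000L,
                       detection = detection_params(),
                       surrogates = 50L,
                       modularity = modularity_params(),
                       louvain_runs = 20L,
                       out_dir = NULL, seed = 1) {
  stopifnot(length(labels) >= 1, n_trials >= 1)
  structure(list(labels = labels, population = population,
                 couplings = couplings, n_trials = as.integer(n_trials),
                 n_bins = as.integer(n_bins), detection = detection,
                 surrogates = as.integer(surrogates), modularity = modularity,
                 louvain_runs = as.integer(louvain_runs),
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Run the full pipeline on synthetic data
#'
#' For each stimulus label: simulate a session from planted ground truth,
#' rate-filter units, build the functional network, score signed motifs and
#' pair states against surrogate ensembles, detect modules and their Z-score,
#' compute module-area agreement (coverage, purity, ARI) and the recovery
#' report against the planted couplings. Across labels, the overlap of
#' pFFLb motif instances is tabulated. All randomness derives from the
#' master seed, so a rerun of the same configuration reproduces the bundle
#' exactly.
#'
#' @param config A [run_config()].
#' @return A list of class `pipeline_result` with one entry per label
#'   (`network`, `metrics`, `motif_z`, `pair_ratios`, `partition`, `Z_Q`,
#'   `module_area`, `recovery`) plus `motif_overlap` and `config`. When
#'   `config$out_dir` is set, tables are also written there as delimited
#'   text.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  per_label <- list()
  instance_sets <- list()
  population_seed <- child_seed(seed, "population")
  for (lab in config$labels) {
    gt_cfg <- c(config$population, config$couplings)
    truth <- make_ground_truth(gt_cfg, seed = child_seed(seed, paste0("truth_", lab)))
    # shared population across labels: regenerate units with a fixed seed
    base_truth <- make_ground_truth(c(config$population, list(n_couplings = 0)),
                                    seed = population_seed)
    truth$units <- base_truth$units
    data <- simulate_session(truth, config$n_trials, config$n_bins,
                             stimulus = lab,
                             seed = child_seed(seed, paste0("sim_", lab)))
    data <- filter_units_by_rate(data, config$detection$min_rate_hz)
    net <- build_network(data, config$detection,
                         seed = child_seed(seed, paste0("net_", lab)))
    metrics <- summary_metrics(net)

    spp <- surrogate_spec("signed_pair_preserving", ensemble = config$surrogates,
                          seed = child_seed(seed, paste0("spp_", lab)))
    er <- surrogate_spec("erdos_renyi", ensemble = config$surrogates,
                         seed = child_seed(seed, paste0("er_", lab)))
    motif_z <- pair_ratios <- partition <- zq <- mod_area <- NULL
    if (nrow(net$edges) >= 2) {
      spp_ens <- surrogate_ensemble(net, spp)
      er_ens <- surrogate_ensemble(net, er)
      motif_z <- motif_zscores(net, spp_ens)
      pair_ratios <- pair_relative_counts(net, er_ens)
      partition <- louvain_signed(net, config$modularity,
                                  seed = child_seed(seed, paste0("louvain_", lab)))
      zq <- modularity_zscore(net, config$modularity, spp_ens,
                              n_runs = config$louvain_runs,
                              seed = child_seed(seed, paste0("zq_", lab)))
      if (any(!is.na(partition$membership))) {
        cp <- coverage_purity(partition$membership, net$nodes$area)
        ari <- adjusted_rand_index(modules = partition$membership,
                                   areas = net$nodes$area)
        mod_area <- list(coverage_purity = cp, ari = as.numeric(ari))
      }
      inst <- attr(motif_intensity_census(net, instances = TRUE), "instances")
      cat_signed <- motif_catalog(3, signed = TRUE)
      instance_sets[[lab]] <-
        inst[inst$signed_label %in% cat_signed$label[cat_signed$pfflb], ,
             drop = FALSE]
    } else {
      instance_sets[[lab]] <- data.frame(i = character(0), j = character(0),
                                         k = character(0),
                                         signed_label = character(0))
    }
    recovery <- evaluate_recovery(truth, net)

    per_label[[lab]] <- list(truth = truth, network = net, metrics = metrics,
                             motif_z = motif_z, pair_ratios = pair_ratios,
                             partition = partition, Z_Q = zq,
                             module_area = mod_area, recovery = recovery)

    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_network(net, config$out_dir, prefix = lab)
      if (!is.null(motif_z))
        write_ccgnet_table(motif_z, file.path(config$out_dir,
                                              paste0(lab, "_motif_z.tsv")),
                           "motif_zscores")
      if (!is.null(pair_ratios))
        write_ccgnet_table(pair_ratios,
                           file.path(config$out_dir, paste0(lab, "_pair_ratios.tsv")),
                           "pair_ratios")
      if (!is.null(partition)) {
        pt <- data.frame(unit = names(partition$membership_full),
                         module = partition$membership_full,
                         assigned = !is.na(partition$membership))
        write_ccgnet_table(pt, file.path(config$out_dir,
                                         paste0(lab, "_modules.tsv")), "modules")
      }
    }
  }
  overlap <- if (length(config$labels) > 1) motif_overlap(instance_sets) else NULL
  if (!is.null(config$out_dir) && !is.null(overlap))
    write_ccgnet_table(overlap, file.path(config$out_dir, "motif_overlap.tsv"),
                       "motif_overlap")
  structure(list(per_label = per_label, motif_overlap = overlap,
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("ccgnet pipeline result\n")
  for (lab in names(x$per_label)) {
    r <- x$per_label[[lab]]
    cat(sprintf("  [%s] %d nodes, %d edges; sensitivity %.2f, precision %s\n",
                lab, nrow(r$network$nodes), nrow(r$network$edges),
                r$recovery$sensitivity,
                ifelse(is.na(r$recovery$precision), "NA",
                       sprintf("%.2f", r$recovery$precision))))
    if (!is.null(r$Z_Q) && !r$Z_Q$flagged)
      cat(sprintf("        Q = %.4f, Z_Q = %.2f\n", r$Z_Q$Q, r$Z_Q$z))
    if (!is.null(r$module_area))
      cat(sprintf("        WA coverage %.3f, WA purity %.3f, ARI %.3f\n",
                  r$module_area$coverage_purity$wa_coverage,
                  r$module_area$coverage_purity$wa_purity, r$module_area$ari))
  }
  invisible(x)
}
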