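# End-to-end pipeline: observed summaries -> reference table -> rejection ->
# scenario choice (optionally staged in two half-batches then a top-6 final
# round) -> parameter estimation -> quality control; plus per-island
# mismatch-distribution analysis.

#' Pipeline configuration
#'
#' Collects and validates every stage's settings before any compute.
#'
#' @param out_dir result directory.
#' @param seed global integer seed.
#' @param design a [sampling_design()].
#' @param priors a [default_priors()].
#' @param scenarios list of scenarios (default: all colonization orders of
#'   [scenario_template()]).
#' @param sumstats summary-statistic configuration.
#' @param n_per_scenario simulations per scenario for the reference table.
#' @param tolerance retained fraction.
#' @param staged if `TRUE`, model choice runs in two half-batches and the
#'   top six scenarios move to a final joint analysis (the default is a
#'   single joint analysis over all scenarios).
#' @param mmd_boot bootstrap replicates for the mismatch analysis (0 skips
#'   the MMD stage).
#' @param mmd_mu_site per-site per-generation mutation rate for dating.
#' @param n_pods pods for the confidence/bias checks (0 skips them).
#' @param island_populations populations given the MMD treatment (default:
#'   islands of the template).
#' @return object of class `coalabc_config`.
#' @export
run_config <- function(out_dir, seed = 1, design = study_design(),
                       priors = default_priors(),
                       scenarios = enumerate_colonization_scenarios(scenario_template()),
                       sumstats = default_sumstat_config(),
                       n_per_scenario = 1000, tolerance = 0.01,
                       staged = FALSE, mmd_boot = 200,
                       mmd_mu_site = 7.6e-8, n_pods = 0,
                       island_populations = c("a", "b", "c", "d")) {
  stopifnot(is.numeric(seed), n_per_scenario >= 1, tolerance > 0,
            tolerance <= 1, mmd_boot >= 0, n_pods >= 0)
  unknown <- setdiff(sumstats, c(PER_POP_STATS, PAIR_STATS))
  if (length(unknown) > 0)
    stop("unknown summary statistics in config: ",
         paste(unknown, collapse = ", "))
  structure(list(out_dir = out_dir, seed = as.integer(seed), design = design,
                 priors = priors, scenarios = scenarios, sumstats = sumstats,
                 n_per_scenario = n_per_scenario, tolerance = tolerance,
                 staged = staged, mmd_boot = mmd_boot,
                 mmd_mu_site = mmd_mu_site, n_pods = n_pods,
                 island_populations = island_populations),
            class = "coalabc_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[setdiff(names(config), "out_dir")], tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full inference pipeline on a dataset bundle
#'
#' Stages: observed summary statistics; reference table over all scenarios;
#' rejection + logistic-regression scenario choice (staged top-6 mode
#' optional); parameter estimation for the winning scenario; PCA
#' pre-evaluation; optional confidence/bias pods; mismatch-distribution
#' analysis per island population. All outputs, the seed and a configuration
#' hash are written to `config$out_dir`; re-running the same configuration
#' reproduces identical statistical outputs.
#'
#' @param bundle the observed [dataset_bundle()].
#' @param config a [run_config()].
#' @return invisibly, a list with `observed`, `table`, `model_choice`,
#'   `posterior`, `pca`, `mmd`, and the output paths.
#' @export
run_pipeline <- function(bundle, config) {
  stopifnot(inherits(config, "coalabc_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  hash <- config_hash(config)

  observed <- summary_vector(bundle, config$sumstats)
  table <- build_reference_table(config$scenarios, config$priors,
                                 config$n_per_scenario, config$design,
                                 config$sumstats)

  scen_ids <- vapply(config$scenarios, function(s) s$scenario_id, integer(1))
  if (config$staged && length(config$scenarios) > 6) {
    half <- split(scen_ids, rep(1:2, length.out = length(scen_ids)))
    stage_post <- numeric(0)
    for (h in half) {
      sub <- subset_table(table, h)
      mc <- scenario_posterior(sub, observed, config$tolerance)
      stage_post <- c(stage_post, mc$posterior)
    }
    top6 <- as.integer(names(sort(stage_post, decreasing = TRUE))[1:6])
    final_table <- subset_table(table, top6)
    model_choice <- scenario_posterior(final_table, observed, config$tolerance)
  } else {
    final_table <- table
    model_choice <- scenario_posterior(table, observed, config$tolerance)
  }
  best_id <- as.integer(names(model_choice$posterior)[
    which.max(model_choice$posterior)])
  best_scenario <- config$scenarios[[match(best_id, scen_ids)]]

  posterior <- tryCatch(
    estimate_parameters(table, observed, best_id, config$tolerance),
    error = function(e) {
      warning("parameter estimation skipped: ", conditionMessage(e))
      NULL
    })
  pca <- pca_preevaluation(final_table, observed)

  qc <- NULL
  if (config$n_pods > 0) {
    qc <- list(confidence = confidence_in_choice(config$scenarios, table,
                                                 config$n_pods,
                                                 config$tolerance),
               bias = if (!is.null(posterior))
                 bias_precision(best_scenario, table, config$n_pods,
                                tolerance = config$tolerance))
  }

  mmd <- NULL
  if (config$mmd_boot > 0 && nrow(bundle$mt) > 0) {
    pops <- copy_populations(rownames(bundle$mt), bundle$popmap)
    keep <- pops %in% config$island_populations
    if (any(keep)) {
      sub_map <- bundle$popmap[bundle$popmap$population %in%
                                 config$island_populations, ]
      mmd <- mmd_table(bundle$mt[keep, , drop = FALSE], sub_map,
                       n_boot = config$mmd_boot,
                       mu_site = config$mmd_mu_site)
    }
  }

  out <- list(seed = config$seed, config_hash = hash,
              observed = as.list(observed),
              posterior_probabilities = as.list(model_choice$posterior),
              best_scenario = best_id,
              best_order = paste(best_scenario$colonization_order,
                                 collapse = ">"),
              pca_inside_hull = pca$inside_hull)
  jsonlite::write_json(out, file.path(config$out_dir, "model_choice.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(posterior))
    write.table(cbind(posterior$summary, config_hash = hash, seed = config$seed),
                file.path(config$out_dir, "parameter_posterior.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(mmd))
    write.table(cbind(mmd, config_hash = hash, seed = config$seed),
                file.path(config$out_dir, "mmd.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(qc)) {
    write.table(qc$confidence, file.path(config$out_dir, "confidence.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(qc$bias))
      write.table(qc$bias, file.path(config$out_dir, "bias_precision.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(observed = observed, table = table,
                 model_choice = model_choice, posterior = posterior,
                 pca = pca, qc = qc, mmd = mmd, config_hash = hash,
                 out_dir = config$out_dir))
}

# restrict a reference table to a set of scenario ids
subset_table <- function(table, scenario_ids) {
  keep <- table$scenario %in% scenario_ids
  out <- table
  out$stats <- table$stats[keep, , drop = FALSE]
  out$params <- table$params[keep, , drop = FALSE]
  out$scenario <- table$scenario[keep]
  out
}
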