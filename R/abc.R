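# Approximate Bayesian computation: reference table, rejection, scenario
# choice by (ridge-regularized) multinomial logistic regression, local-linear
# parameter adjustment, and the four quality-control procedures
# (PCA pre-evaluation, model checking, confidence in scenario choice,
# bias/precision on pseudo-observed datasets).

#' Build an ABC reference table
#'
#' For each scenario, draws `n_per_scenario` parameter sets from the priors,
#' simulates a dataset bundle, and records its summary vector. Per-statistic
#' scale factors (robust SD, 1.4826 x MAD over all rows) are computed after
#' assembly; zero-variance statistics are dropped with a warning.
#'
#' @param scenarios list of `coalabc_scenario`.
#' @param priors a [default_priors()] object.
#' @param n_per_scenario simulations per scenario (>= 1).
#' @param design a [sampling_design()].
#' @param config summary-statistic configuration.
#' @param seed optional integer seed.
#' @return object of class `coalabc_reftable` with elements `stats`
#'   (matrix), `params` (matrix), `scenario` (integer vector), `scales`,
#'   `config`, `seed`.
#' @export
build_reference_table <- function(scenarios, priors, n_per_scenario, design,
                                  config = default_sumstat_config(),
                                  seed = NULL) {
  stopifnot(n_per_scenario >= 1)
  if (!is.null(seed)) set.seed(seed)
  rows_total <- length(scenarios) * n_per_scenario
  stats <- NULL; params <- NULL
  scen_id <- integer(rows_total)
  r <- 0
  for (sc in scenarios) {
    draws <- draw_parameters(sc, priors, n = n_per_scenario)
    if (n_per_scenario == 1) draws <- list(draws)
    for (d in draws) {
      bundle <- simulate_dataset(sc, d, design)
      sv <- summary_vector(bundle, config)
      r <- r + 1
      if (is.null(stats)) {
        stats <- matrix(NA_real_, rows_total, length(sv),
                        dimnames = list(NULL, names(sv)))
        params <- matrix(NA_real_, rows_total, length(d$params),
                         dimnames = list(NULL, names(d$params)))
      }
      stats[r, ] <- sv
      params[r, names(d$params)] <- d$params
      scen_id[r] <- sc$scenario_id
    }
  }
  scales <- apply(stats, 2, function(x) 1.4826 * mad(x, constant = 1))
  dead <- scales <= 0 | !is.finite(scales)
  if (any(dead)) {
    warning("dropping zero-variance statistics: ",
            paste(colnames(stats)[dead], collapse = ", "))
    stats <- stats[, !dead, drop = FALSE]
    scales <- scales[!dead]
  }
  structure(list(stats = stats, params = params, scenario = scen_id,
                 scales = scales, config = config, seed = seed,
                 priors = priors, design = design),
            class = "coalabc_reftable")
}

#' @export
print.coalabc_reftable <- function(x, ...) {
  cat("<coalabc_reftable> ", nrow(x$stats), " simulations, ",
      length(unique(x$scenario)), " scenarios, ", ncol(x$stats),
      " statistics\n", sep = "")
  invisible(x)
}

#' Scaled Euclidean distance between summary vectors
#'
#' sqrt(sum_k ((sim_k - obs_k)/scale_k)^2) over the shared statistic
#' configuration.
#'
#' @param sim,obs named summary vectors with identical names.
#' @param scales named positive scale factors.
#' @return numeric scalar.
#' @export
normalized_distance <- function(sim, obs, scales) {
  if (!identical(names(sim), names(obs)))
    stop("summary vectors have different statistic configurations")
  sqrt(sum(((sim - obs[names(sim)]) / scales[names(sim)])^2))
}

table_distances <- function(table, observed) {
  obs <- observed[colnames(table$stats)]
  if (anyNA(obs)) stop("observed summary vector missing statistics: ",
                       paste(setdiff(colnames(table$stats), names(observed)),
                             collapse = ", "))
  dev <- sweep(table$stats, 2, obs)
  dev <- sweep(dev, 2, table$scales, "/")
  sqrt(rowSums(dev^2))
}

#' Rejection step
#'
#' Retains the `ceiling(tolerance x rows)` reference-table rows closest to
#' the observed vector; ties are broken by row index, so the result is
#' invariant to row permutation up to that documented tie-break.
#'
#' @param table a `coalabc_reftable`.
#' @param observed named summary vector of the observed dataset.
#' @param tolerance retained fraction, in (0, 1].
#' @return list with `index`, `distance`, `scenario`, `stats`, `params`.
#' @export
abc_reject <- function(table, observed, tolerance) {
  if (nrow(table$stats) == 0) stop("empty reference table")
  stopifnot(tolerance > 0, tolerance <= 1)
  d <- table_distances(table, observed)
  keep <- order(d, seq_along(d))[seq_len(ceiling(tolerance * length(d)))]
  list(index = keep, distance = d[keep], scenario = table$scenario[keep],
       stats = table$stats[keep, , drop = FALSE],
       params = table$params[keep, , drop = FALSE])
}

epanechnikov <- function(d) {
  h <- max(d)
  if (h <= 0) return(rep(1, length(d)))
  w <- 1 - (d / h)^2
  w[w < 1e-8] <- 1e-8  # the farthest retained row keeps a vanishing weight
  w
}

#' Scenario posterior probabilities by logistic regression
#'
#' Multinomial logistic regression of the scenario label on the scaled
#' summary deviations over the retained set, evaluated at zero deviation
#' (the observed point). The regression is ridge-regularized (small fixed
#' weight decay) so perfect separation degrades gracefully; rows are
#' weighted by an Epanechnikov kernel on distance.
#'
#' @inheritParams abc_reject
#' @return object of class `coalabc_model_choice`: `posterior` (named
#'   probabilities over every scenario in the table, summing to 1),
#'   `retained` counts, `tolerance`.
#' @export
scenario_posterior <- function(table, observed, tolerance = 0.01) {
  rej <- abc_reject(table, observed, tolerance)
  all_ids <- sort(unique(table$scenario))
  post <- setNames(rep(0, length(all_ids)), all_ids)
  present <- sort(unique(rej$scenario))
  if (length(present) == 1) {
    post[as.character(present)] <- 1
  } else {
    dev <- sweep(rej$stats, 2, observed[colnames(rej$stats)])
    dev <- sweep(dev, 2, table$scales, "/")
    df <- data.frame(dev)
    df$.scenario <- factor(rej$scenario, levels = present)
    w <- epanechnikov(rej$distance)
    fit <- nnet::multinom(.scenario ~ ., data = df, weights = w,
                          decay = 0.01, trace = FALSE, maxit = 500,
                          MaxNWts = 100000)
    zero <- as.data.frame(matrix(0, 1, ncol(dev),
                                 dimnames = list(NULL, colnames(df)[seq_len(ncol(dev))])))
    pr <- predict(fit, newdata = zero, type = "probs")
    if (length(present) == 2) pr <- c(1 - pr, pr)  # binomial case
    post[as.character(present)] <- pr / sum(pr)
  }
  structure(list(posterior = post,
                 retained = table(factor(rej$scenario, levels = all_ids)),
                 tolerance = tolerance, n_retained = length(rej$index)),
            class = "coalabc_model_choice")
}

#' @export
print.coalabc_model_choice <- function(x, ...) {
  cat("<coalabc_model_choice> posterior probabilities:\n")
  print(round(x$posterior, 4))
  invisible(x)
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Posterior parameter estimation with local-linear adjustment
#'
#' Restricts the table to one scenario, retains the closest rows, and
#' adjusts each (log-transformed) parameter by a local-linear regression on
#' the scaled summary deviations with Epanechnikov weights (bandwidth = the
#' largest retained distance), then back-transforms. A singular regression
#' falls back to the unadjusted rejection sample with a warning.
#'
#' @param table a `coalabc_reftable` (only rows of `scenario_id` are used).
#' @param observed named observed summary vector.
#' @param scenario_id scenario whose parameters to estimate.
#' @param tolerance retained fraction of that scenario's rows.
#' @param min_retained minimum retained rows required (default 30).
#' @return object of class `coalabc_posterior`: `adjusted` (matrix of
#'   adjusted draws), `weights`, and a `summary` data.frame with mean,
#'   median, q25, q75 and the central 95% interval per parameter.
#' @export
estimate_parameters <- function(table, observed, scenario_id,
                                tolerance = 0.01, min_retained = 30) {
  sel <- table$scenario == scenario_id
  if (!any(sel)) stop("scenario ", scenario_id, " not present in the table")
  sub <- list(stats = table$stats[sel, , drop = FALSE],
              params = table$params[sel, , drop = FALSE],
              scenario = table$scenario[sel], scales = table$scales)
  class(sub) <- "coalabc_reftable"
  rej <- abc_reject(sub, observed, tolerance)
  if (length(rej$index) < min_retained)
    stop("fewer than ", min_retained, " retained rows; increase tolerance ",
         "or the table size")
  w <- epanechnikov(rej$distance)
  dev <- sweep(rej$stats, 2, observed[colnames(rej$stats)])
  dev <- sweep(dev, 2, table$scales, "/")
  adjusted <- rej$params
  varying <- apply(rej$params, 2, function(x) diff(range(x)) > 0)
  if (all(dev == 0)) varying[] <- FALSE  # nothing to adjust for
  if (any(rej$params[, varying, drop = FALSE] <= 0))
    stop("local-linear adjustment assumes strictly positive parameters")
  X <- cbind(1, dev)
  for (p in colnames(rej$params)[varying]) {
    y <- log(rej$params[, p])
    fit <- tryCatch(lm.wfit(X, y, w), error = function(e) NULL)
    if (is.null(fit) || fit$rank < 2) {
      warning("singular local-linear design for ", p,
              "; using unadjusted rejection sample")
      next
    }
    # aliased (collinear) columns are dropped by the pivoted fit
    beta <- fit$coefficients[-1]
    beta[is.na(beta)] <- 0
    adjusted[, p] <- exp(y - drop(dev %*% beta))
  }
  qs <- t(apply(adjusted, 2, weighted_quantile, w = w,
                probs = c(0.025, 0.25, 0.5, 0.75, 0.975)))
  summary <- data.frame(parameter = colnames(adjusted),
                        mean = apply(adjusted, 2, function(x) sum(x * w) / sum(w)),
                        q025 = qs[, 1], q25 = qs[, 2], median = qs[, 3],
                        q75 = qs[, 4], q975 = qs[, 5],
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(adjusted = adjusted, weights = w, summary = summary,
                 scenario_id = scenario_id, tolerance = tolerance),
            class = "coalabc_posterior")
}

#' @export
print.coalabc_posterior <- function(x, ...) {
  cat("<coalabc_posterior> scenario ", x$scenario_id, "\n", sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Posterior quantiles helper
#'
#' Weighted quantiles of an adjusted posterior sample.
#'
#' @param posterior a `coalabc_posterior`.
#' @param parameter parameter name.
#' @param probs quantile probabilities.
#' @return numeric vector.
#' @export
posterior_quantile <- function(posterior, parameter, probs) {
  weighted_quantile(posterior$adjusted[, parameter], posterior$weights, probs)
}

#' PCA pre-evaluation of scenario-prior combinations
#'
#' Fits a PCA on the scaled simulated summary vectors, projects the observed
#' vector, and reports whether it falls inside the convex hull of the
#' simulated cloud in the first two components.
#'
#' @param table a `coalabc_reftable`.
#' @param observed named observed summary vector.
#' @param n_components components to keep.
#' @return list with `scores`, `observed_scores`, `inside_hull`,
#'   `min_distance` (to the nearest simulation in PC space).
#' @export
pca_preevaluation <- function(table, observed, n_components = 2) {
  if (nrow(table$stats) < n_components)
    stop("need at least as many simulations as components")
  Z <- sweep(table$stats, 2, table$scales, "/")
  pc <- prcomp(Z, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  zobs <- (observed[colnames(table$stats)] / table$scales - pc$center)
  obs_scores <- drop(zobs %*% pc$rotation[, seq_len(k), drop = FALSE])
  hull <- grDevices::chull(scores[, 1], scores[, 2])
  bnd <- scores[c(hull, hull[1]), 1:2]
  inside <- as.logical(mgcv::in.out(bnd, matrix(obs_scores[1:2], 1)))
  dists <- sqrt(rowSums(sweep(scores, 2, obs_scores)^2))
  list(scores = scores, observed_scores = obs_scores,
       inside_hull = inside, min_distance = min(dists))
}

# draw one parameter vector from an adjusted posterior (joint rows,
# weight-proportional), re-validated against the scenario constraints
sample_posterior_draw <- function(posterior, scenario, priors, max_tries = 50) {
  for (i in seq_len(max_tries)) {
    row <- sample.int(nrow(posterior$adjusted), 1,
                      prob = posterior$weights)
    p <- posterior$adjusted[row, ]
    p[p < 1] <- 1  # sizes/times must stay positive and at least 1
    d <- structure(list(params = p, mt_model = priors$mt_model,
                        str_model = priors$str_model),
                   class = "coalabc_draw")
    if (validate_constraints(d, scenario)) return(d)
  }
  # fall back to the unadjusted retained draw closest to the weighted median
  p <- apply(posterior$adjusted, 2, weighted_quantile,
             w = posterior$weights, probs = 0.5)
  structure(list(params = p, mt_model = priors$mt_model,
                 str_model = priors$str_model), class = "coalabc_draw")
}

#' Posterior-predictive model checking
#'
#' Simulates `n_pp` datasets from the fitted posterior of the chosen
#' scenario and reports, per summary statistic, the tail probability
#' (fraction of predictive values <= observed). Values near 0 or 1 flag
#' statistics the fitted model fails to reproduce.
#'
#' @param table a `coalabc_reftable`.
#' @param scenario the chosen `coalabc_scenario`.
#' @param posterior a `coalabc_posterior` for that scenario.
#' @param observed named observed summary vector.
#' @param n_pp posterior-predictive simulations (>= 1).
#' @param flag_level two-sided flagging level (default 0.025 per tail).
#' @return data.frame with statistic, tail probability and flag.
#' @export
model_check <- function(table, scenario, posterior, observed, n_pp,
                        flag_level = 0.025) {
  if (n_pp < 1) stop("n_pp must be at least 1")
  priors <- table$priors
  stats <- colnames(table$stats)
  pred <- matrix(NA_real_, n_pp, length(stats), dimnames = list(NULL, stats))
  for (i in seq_len(n_pp)) {
    d <- sample_posterior_draw(posterior, scenario, priors)
    bundle <- simulate_dataset(scenario, d, table$design)
    pred[i, ] <- summary_vector(bundle, table$config)[stats]
  }
  tail_p <- vapply(stats, function(s)
    mean(pred[, s] <= observed[s]), numeric(1))
  data.frame(statistic = stats, tail_prob = tail_p,
             flagged = tail_p < flag_level | tail_p > 1 - flag_level,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Confidence in scenario choice
#'
#' Simulates pseudo-observed datasets (pods) from each scenario's prior,
#' runs model choice on each against the reference table, and reports type I
#' (true scenario not selected) and type II (scenario selected when another
#' generated the data) error rates.
#'
#' @param scenarios list of `coalabc_scenario` present in the table.
#' @param table a `coalabc_reftable`.
#' @param n_pods pods per scenario (>= 1).
#' @param tolerance retained fraction for each model choice.
#' @param seed optional integer seed.
#' @return data.frame per scenario with `type1`, `type2` and pod counts.
#' @export
confidence_in_choice <- function(scenarios, table, n_pods, tolerance = 0.01,
                                 seed = NULL) {
  if (n_pods < 1) stop("n_pods must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  ids <- vapply(scenarios, function(s) s$scenario_id, integer(1))
  selected <- matrix(0, length(ids), length(ids),
                     dimnames = list(true = ids, chosen = ids))
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    for (k in seq_len(n_pods)) {
      d <- draw_parameters(sc, table$priors)
      bundle <- simulate_dataset(sc, d, table$design)
      mc <- scenario_posterior(table, summary_vector(bundle, table$config),
                               tolerance)
      chosen <- names(mc$posterior)[which.max(mc$posterior)]
      selected[as.character(sc$scenario_id), chosen] <-
        selected[as.character(sc$scenario_id), chosen] + 1
    }
  }
  type1 <- 1 - diag(selected) / n_pods
  type2 <- vapply(seq_along(ids), function(j)
    sum(selected[-j, j]) / (n_pods * (length(ids) - 1)), numeric(1))
  data.frame(scenario_id = ids, type1 = type1, type2 = type2,
             n_pods = n_pods, row.names = NULL)
}

#' Bias and precision of parameter estimation
#'
#' Simulates pods with recorded true parameters from one scenario, estimates
#' each with the posterior median, and reports relative bias
#' mean((estimate - truth)/truth) and relative RMSE.
#'
#' @param scenario the generating `coalabc_scenario`.
#' @param table a `coalabc_reftable` containing that scenario.
#' @param n_pods number of pods (>= 1).
#' @param parameters parameter names to evaluate (default: all time
#'   parameters).
#' @param tolerance retained fraction.
#' @param seed optional integer seed.
#' @return data.frame per parameter with `rel_bias` and `rel_rmse`.
#' @export
bias_precision <- function(scenario, table, n_pods,
                           parameters = NULL, tolerance = 0.01, seed = NULL) {
  if (n_pods < 1) stop("n_pods must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(parameters))
    parameters <- grep("^t[0-9]+$", colnames(table$params), value = TRUE)
  err <- matrix(NA_real_, n_pods, length(parameters),
                dimnames = list(NULL, parameters))
  for (k in seq_len(n_pods)) {
    d <- draw_parameters(scenario, table$priors)
    bundle <- simulate_dataset(scenario, d, table$design)
    post <- estimate_parameters(table, summary_vector(bundle, table$config),
                                scenario$scenario_id, tolerance)
    med <- setNames(post$summary$median, post$summary$parameter)
    err[k, ] <- (med[parameters] - d$params[parameters]) / d$params[parameters]
  }
  data.frame(parameter = parameters,
             rel_bias = colMeans(err),
             rel_rmse = sqrt(colMeans(err^2)),
             n_pods = n_pods, row.names = NULL, stringsAsFactors = FALSE)
}

#' Persist a reference table to a tab-separated file
#'
#' Columnar TSV with a `#`-prefixed header block recording the seed and the
#' statistic configuration; [read_reference_table()] restores the table.
#'
#' @param table a `coalabc_reftable`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_reference_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# coalabc reference table"),
               paste0("# seed: ", if (is.null(table$seed)) "NA" else table$seed),
               paste0("# config: ", paste(table$config, collapse = ",")),
               paste0("# scales: ", paste(signif(table$scales, 15),
                                          collapse = ","))), con)
  df <- data.frame(scenario = table$scenario, table$params, table$stats,
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  field <- function(key) sub(paste0("# ", key, ": "), "",
                             hdr[startsWith(hdr, paste0("# ", key, ":"))])
  seed <- suppressWarnings(as.integer(field("seed")))
  config <- strsplit(field("config"), ",")[[1]]
  scales <- as.numeric(strsplit(field("scales"), ",")[[1]])
  df <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                   sep = "\t", check.names = FALSE)
  stat_cols <- (ncol(df) - length(scales) + 1):ncol(df)
  param_cols <- setdiff(2:ncol(df), stat_cols)
  structure(list(stats = as.matrix(df[, stat_cols, drop = FALSE]),
                 params = as.matrix(df[, param_cols, drop = FALSE]),
                 scenario = df$scenario,
                 scales = setNames(scales, colnames(df)[stat_cols]),
                 config = config,
                 seed = if (is.na(seed)) NULL else seed),
            class = "coalabc_reftable")
}
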