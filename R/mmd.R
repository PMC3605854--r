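# Mismatch-distribution (MMD) demographic analysis: observed distribution of
# pairwise nucleotide differences, sudden-expansion model fit (theta0,
# theta1, tau), SSD and raggedness with parametric-bootstrap p-values, and
# tau -> t dating.

#' Observed mismatch distribution
#'
#' Histogram of Hamming distances over all unordered sequence pairs
#' (non-ACGT sites excluded pairwise, as in the distance statistics).
#'
#' @param aln a [alignment()] with at least 2 sequences.
#' @return object of class `coalabc_mmd`: counts per difference class
#'   0..d, relative frequencies, and the number of pairs.
#' @export
observed_mismatch <- function(aln) {
  if (nrow(aln) < 2) stop("mismatch distribution requires at least 2 sequences")
  d <- pair_diff_cpp(unclass(aln))
  diffs <- d[upper.tri(d)]
  counts <- tabulate(diffs + 1, nbins = max(diffs) + 1)
  mismatch_distribution(counts)
}

mismatch_distribution <- function(counts) {
  structure(list(counts = counts, n_pairs = sum(counts),
                 freq = counts / sum(counts),
                 d_max = length(counts) - 1L),
            class = "coalabc_mmd")
}

#' @export
print.coalabc_mmd <- function(x, ...) {
  cat("<coalabc_mmd> ", x$n_pairs, " pairs, difference classes 0..",
      x$d_max, "\n", sep = "")
  invisible(x)
}

# geometric equilibrium probabilities theta^i/(1+theta)^(i+1), untruncated
fhat_raw <- function(theta, d_max) {
  i <- 0:d_max
  if (theta == 0) return(c(1, rep(0, d_max)))
  exp(i * log(theta) - (i + 1) * log1p(theta))
}

#' Equilibrium mismatch distribution
#'
#' Expected pairwise-difference frequencies for a constant-size population,
#' the geometric F_i(theta) = theta^i/(1+theta)^(i+1), renormalized over the
#' truncated support 0..d_max.
#'
#' @param theta scaled population size 2*N*mu (per locus).
#' @param d_max largest difference class.
#' @return numeric vector of length d_max + 1 summing to 1.
#' @export
equilibrium_mismatch <- function(theta, d_max) {
  stopifnot(theta >= 0)
  f <- fhat_raw(theta, d_max)
  f / sum(f)
}

#' Sudden-expansion mismatch distribution
#'
#' Expected frequencies under a stepwise size change theta0 -> theta1 at
#' scaled time tau = 2*mu*t before present:
#' F_i = Fhat_i(theta1) + exp(-tau (theta1+1)/theta1) *
#'       sum_j (tau^j/j!) (Fhat_{i-j}(theta0) - Fhat_{i-j}(theta1)),
#' truncated at d_max and renormalized. `theta1 = Inf` is supported as the
#' infinite-growth limit (the ancestral geometric convolved with
#' Poisson(tau) mutations).
#'
#' @param theta0,theta1 pre-/post-expansion scaled sizes (>= 0; `theta1`
#'   may be `Inf`).
#' @param tau scaled expansion time (>= 0).
#' @param d_max largest difference class.
#' @return numeric vector of length d_max + 1 summing to 1.
#' @export
expansion_mismatch <- function(theta0, theta1, tau, d_max) {
  if (theta0 < 0 || theta1 < 0 || tau < 0)
    stop("expansion-model parameters must be nonnegative")
  if (is.finite(theta1) && theta1 > 0)
    return(expansion_mismatch_cpp(theta0, theta1, tau, d_max))
  f0 <- fhat_raw(theta0, d_max)
  if (is.infinite(theta1)) {
    f1 <- rep(0, d_max + 1)
    damp <- exp(-tau)
  } else if (theta1 == 0) {
    return(equilibrium_mismatch(0, d_max))
  } else {
    f1 <- fhat_raw(theta1, d_max)
    damp <- exp(-tau * (theta1 + 1) / theta1)
  }
  pois <- exp(-lgamma(0:d_max + 1) + (0:d_max) * log(tau) * (tau > 0))
  if (tau == 0) pois <- c(1, rep(0, d_max))
  delta <- f0 - f1
  conv <- vapply(0:d_max, function(i)
    sum(pois[1:(i + 1)] * delta[(i + 1):1]), numeric(1))
  f <- f1 + damp * conv
  f[f < 0] <- 0
  f / sum(f)
}

ssd_of <- function(par, x) {
  f <- if (par[2] > 0) expansion_mismatch_cpp(par[1], par[2], par[3],
                                              length(x) - 1)
       else expansion_mismatch(par[1], par[2], par[3], length(x) - 1)
  sum((x - f)^2)
}

default_fit_starts <- function(x) {
  # moment start: tau near the mean difference count, plus a fixed grid
  mbar <- sum((seq_along(x) - 1) * x)
  starts <- list(c(0.5, 10, max(mbar, 0.5)),
                 c(0.1, 1, 1), c(1, 5, 2), c(2, 20, 5), c(0.5, 50, 10),
                 c(5, 5, 0.5), c(0.1, 100, 20), c(10, 50, 5),
                 c(0.5, 2, 30), c(1, 100, 3), c(0.01, 30, 8),
                 c(3, 3, 15), c(0.2, 15, 12), c(8, 80, 2),
                 c(0.05, 5, 25), c(1.5, 40, 7), c(0.7, 8, 18),
                 c(4, 60, 1), c(0.3, 25, 4), c(6, 12, 9))
  starts
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Minimizes the sum of squared deviations SSD = sum_i (x_i - F_i)^2 by
#' bounded multi-start optimization (`nlminb`, 20 deterministic starts,
#' theta0/theta1 in `[0, 100]`, tau in `[0, 50]`); ties go to the lowest tau.
#'
#' @param obs a `coalabc_mmd` (see [observed_mismatch()]).
#' @param starts optional list of `c(theta0, theta1, tau)` start points.
#' @return object of class `coalabc_expansion_fit` with elements `theta0`,
#'   `theta1`, `tau`, `ssd`, `raggedness`.
#' @export
fit_expansion <- function(obs, starts = NULL) {
  x <- obs$freq
  if (length(x) < 2) {
    # single difference class: degenerate corner fit
    return(structure(list(theta0 = 0, theta1 = 0, tau = 0,
                          ssd = ssd_of(c(0, 0, 0), x),
                          raggedness = raggedness(obs)),
                     class = "coalabc_expansion_fit"))
  }
  if (is.null(starts)) starts <- default_fit_starts(x)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      nlminb(s, ssd_of, x = x, lower = c(0, 0, 0), upper = c(100, 100, 50)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective - 1e-14 ||
        (abs(fit$objective - best$objective) <= 1e-14 &&
         fit$par[3] < best$par[3]))
      best <- fit
  }
  if (is.null(best)) stop("expansion-model fit failed from every start")
  structure(list(theta0 = best$par[1], theta1 = best$par[2],
                 tau = best$par[3], ssd = best$objective,
                 raggedness = raggedness(obs)),
            class = "coalabc_expansion_fit")
}

#' @export
print.coalabc_expansion_fit <- function(x, ...) {
  cat(sprintf("<expansion fit> theta0 = %.4g, theta1 = %.4g, tau = %.4g, SSD = %.3g\n",
              x$theta0, x$theta1, x$tau, x$ssd))
  invisible(x)
}

#' Harpending's raggedness index
#'
#' r = sum_{i=1..d+1} (x_i - x_{i-1})^2 with x_{d+1} := 0; small values are
#' typical of smoothly unimodal (expansion-like) distributions.
#'
#' @param dist a `coalabc_mmd` or a numeric frequency vector.
#' @return numeric scalar.
#' @export
raggedness <- function(dist) {
  x <- if (inherits(dist, "coalabc_mmd")) dist$freq else dist
  sum(diff(c(x, 0))^2)
}

# Coalescent simulation of one mismatch distribution under the
# sudden-expansion model, in mutation-scaled units: a single population of
# size theta1/(2u) until tau/(2u) generations ago, theta0/(2u) before, with
# infinite-sites Poisson mutations at per-locus rate u.
simulate_mismatch <- function(n, theta0, theta1, tau) {
  u <- 1e-3
  eps <- 1e-9
  N1 <- max(theta1, eps) / (2 * u)
  N0 <- max(theta0, eps) / (2 * u)
  t_exp <- tau / (2 * u)
  sizes <- if (t_exp > 0) matrix(c(0, N1, t_exp, N0), 2, 2, byrow = TRUE)
           else matrix(c(0, N0), 1, 2)
  g <- sim_genealogy_cpp(rep(0L, n), list(sizes), numeric(0), integer(0),
                         integer(0), 1.0)
  nnode <- 2 * n - 1
  nonroot <- seq_len(nnode - 1)
  len <- g$age[g$parent[nonroot] + 1] - g$age[nonroot]
  muts <- rpois(nnode - 1, u * len)
  # tip sets below each node -> each branch adds its mutations to all
  # (inside, outside) pairs
  below <- matrix(FALSE, nnode, n)
  below[cbind(seq_len(n), seq_len(n))] <- TRUE
  for (v in seq_len(nnode - 1))
    below[g$parent[v] + 1, ] <- below[g$parent[v] + 1, ] | below[v, ]
  dm <- matrix(0, n, n)
  for (v in which(muts > 0)) {
    inside <- below[v, ]
    dm[inside, !inside] <- dm[inside, !inside] + muts[v]
  }
  diffs <- (dm + t(dm))[upper.tri(dm)]
  mismatch_distribution(tabulate(diffs + 1, nbins = max(diffs) + 1))
}

#' Parametric-bootstrap p-values for the expansion fit
#'
#' Simulates `n_boot` coalescent replicates under the fitted expansion model
#' (matching the sample size), refits each, and reports the proportion of
#' replicates with a strictly larger SSD than observed (ties count as
#' non-exceedances); analogously for raggedness.
#'
#' @param aln the observed [alignment()] (sets the sample size).
#' @param fit a `coalabc_expansion_fit` for that alignment.
#' @param n_boot number of bootstrap replicates (>= 1).
#' @param seed optional integer seed.
#' @param refit_starts start points for the per-replicate refit (defaults to
#'   the fitted parameters plus two spread starts, for speed).
#' @return list with `p_ssd`, `p_rag`, `n_boot`.
#' @export
bootstrap_pvalues <- function(aln, fit, n_boot, seed = NULL,
                              refit_starts = NULL) {
  if (n_boot < 1) stop("n_boot must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(aln)
  obs <- observed_mismatch(aln)
  rag_obs <- raggedness(obs)
  if (is.null(refit_starts))
    refit_starts <- list(c(fit$theta0, fit$theta1, fit$tau),
                         c(0.5, 10, max(1, fit$tau / 2)),
                         c(2, 50, min(50, 2 * fit$tau + 1)))
  ssd_b <- numeric(n_boot); rag_b <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    rep_dist <- simulate_mismatch(n, fit$theta0, fit$theta1, fit$tau)
    rep_fit <- fit_expansion(rep_dist, starts = refit_starts)
    ssd_b[b] <- rep_fit$ssd
    rag_b[b] <- raggedness(rep_dist)
  }
  list(p_ssd = mean(ssd_b > fit$ssd), p_rag = mean(rag_b > rag_obs),
       n_boot = n_boot)
}

#' Per-locus mutation rate per year
#'
#' mu_locus = mu_site x length / generations-per-year.
#'
#' @param mu_site substitutions per site per generation (> 0).
#' @param length locus length in sites (> 0).
#' @param gens_per_year generations per year (> 0, default 1).
#' @return substitutions per locus per year.
#' @export
locus_rate <- function(mu_site, length, gens_per_year = 1) {
  if (mu_site <= 0 || length <= 0 || gens_per_year <= 0)
    stop("all inputs to locus_rate must be positive")
  mu_site * length / gens_per_year
}

#' Convert tau to time since expansion
#'
#' t = tau / (2 mu_locus) years before present, rounded to the nearest 1,000
#' by default.
#'
#' @param tau scaled expansion time (>= 0).
#' @param mu_locus substitutions per locus per year (> 0).
#' @param rounding `"nearest_1000"` or `"none"`.
#' @return years before present.
#' @export
expansion_time <- function(tau, mu_locus, rounding = c("nearest_1000", "none")) {
  rounding <- match.arg(rounding)
  if (mu_locus <= 0) stop("mu_locus must be positive")
  if (any(tau < 0)) stop("tau must be nonnegative")
  t <- tau / (2 * mu_locus)
  if (rounding == "nearest_1000") round(t / 1000) * 1000 else t
}

#' Mismatch-distribution analysis per population
#'
#' Runs the full mismatch pipeline for each population in the map: observed
#' distribution, expansion fit, bootstrap p-values, and tau -> t dating.
#'
#' @param aln a [alignment()] of all populations.
#' @param popmap population map (`id`, `population`).
#' @param n_boot parametric-bootstrap replicates.
#' @param mu_site,length_bp,gens_per_year dating inputs, see [locus_rate()].
#' @param seed optional integer seed.
#' @return data.frame, one row per population: theta0, theta1, tau, ssd,
#'   p_ssd, raggedness, p_rag, t_years.
#' @export
mmd_table <- function(aln, popmap, n_boot = 1000, mu_site = 7.6e-8,
                      length_bp = ncol(aln), gens_per_year = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu_loc <- locus_rate(mu_site, length_bp, gens_per_year)
  pop <- copy_populations(rownames(aln), popmap)
  rows <- lapply(sort(unique(pop)), function(p) {
    sub <- aln[pop == p, , drop = FALSE]
    fit <- fit_expansion(observed_mismatch(sub))
    pv <- bootstrap_pvalues(sub, fit, n_boot)
    data.frame(population = p, theta0 = fit$theta0, theta1 = fit$theta1,
               tau = fit$tau, ssd = fit$ssd, p_ssd = pv$p_ssd,
               raggedness = fit$raggedness, p_rag = pv$p_rag,
               t_years = expansion_time(fit$tau, mu_loc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
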