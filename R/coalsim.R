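# Structured-coalescent simulation and mutation overlay.

# Piecewise-constant size history per population, plus backward-time merge
# events, assembled from a scenario + parameter draw. Island populations
# inherit their paired lineage's present-day size and drop to their founder
# bottleneck size during the window (t_col - db, t_col) backward from the
# present.
scenario_history <- function(scenario, draw) {
  p <- draw$params
  pops <- scenario$populations
  ev <- scenario$events
  labels <- pops$label
  sizes <- vector("list", length(labels))
  names(sizes) <- labels
  for (i in seq_along(labels)) {
    N <- unname(p[pops$size_param[i]])
    if (is.na(N) || N <= 0) stop("nonpositive size for population ", labels[i])
    sizes[[i]] <- matrix(c(0, N), nrow = 1)
  }
  merges <- data.frame(time = unname(p[ev$time_param]), child = ev$child,
                       parent = ev$parent, stringsAsFactors = FALSE)
  isl <- which(!is.na(ev$bottleneck_size))
  for (i in isl) {
    lab <- ev$child[i]
    t_col <- unname(p[ev$time_param[i]])
    db <- unname(p[ev$bottleneck_duration[i]])
    Nb <- unname(p[ev$bottleneck_size[i]])
    if (db <= 0) stop("bottleneck duration must be positive")
    if (Nb <= 0) stop("nonpositive bottleneck size for population ", lab)
    start <- t_col - db
    if (start <= 0) sizes[[lab]] <- matrix(c(0, Nb), nrow = 1)
    else sizes[[lab]] <- rbind(sizes[[lab]], c(start, Nb))
  }
  merges <- merges[order(merges$time), ]
  list(labels = labels, sizes = sizes, merges = merges)
}

#' Simulate a gene genealogy under a scenario
#'
#' Backward-in-time Kingman coalescent within populations of piecewise
#' constant size: each lineage pair in a population of size N coalesces at
#' rate 1/(cN) with ploidy factor c. At an island's colonization time all its
#' lineages transfer to the parent lineage; at a lineage's coalescence time
#' they transfer to the unsampled source.
#'
#' @param scenario a `coalabc_scenario`.
#' @param draw a `coalabc_draw` satisfying the scenario's constraints.
#' @param sampling named integer vector: gene copies per population label.
#' @param locus_kind `"mt"` (default ploidy factor c = 0.5, the maternally
#'   inherited haploid convention N/4) or `"nuclear"` (c = 2).
#' @param ploidy_c override the ploidy factor.
#' @return `coalabc_genealogy`: ultrametric binary tree as a parent array
#'   with node ages in generations; tips carry (population, copy) labels.
#' @export
simulate_genealogy <- function(scenario, draw, sampling,
                               locus_kind = c("mt", "nuclear"),
                               ploidy_c = NULL) {
  locus_kind <- match.arg(locus_kind)
  if (is.null(ploidy_c)) ploidy_c <- if (locus_kind == "mt") 0.5 else 2
  hist <- scenario_history(scenario, draw)
  sampling <- sampling[sampling > 0]
  if (length(sampling) == 0) stop("empty sampling design")
  bad <- setdiff(names(sampling), hist$labels)
  if (length(bad) > 0) stop("unknown populations in sampling: ",
                            paste(bad, collapse = ", "))
  roles <- scenario$populations$role[match(names(sampling),
                                           scenario$populations$label)]
  if (any(roles == "unsampled_source"))
    stop("cannot sample gene copies from the unsampled source population")
  genealogy_from_history(hist, sampling, ploidy_c)
}

genealogy_from_history <- function(hist, sampling, ploidy_c) {
  tip_pop <- rep(names(sampling), sampling)
  pop_idx <- match(tip_pop, hist$labels) - 1L
  res <- sim_genealogy_cpp(pop_idx, unname(hist$sizes),
                           hist$merges$time,
                           match(hist$merges$child, hist$labels) - 1L,
                           match(hist$merges$parent, hist$labels) - 1L,
                           ploidy_c)
  labels <- unlist(lapply(names(sampling), function(l)
    paste0(l, "_", sprintf("%02d", seq_len(sampling[[l]])))))
  structure(list(parent = res$parent, age = res$age,
                 n_tips = length(tip_pop), tip_pop = tip_pop,
                 tip_label = labels, ploidy_c = ploidy_c),
            class = "coalabc_genealogy")
}

#' @export
print.coalabc_genealogy <- function(x, ...) {
  cat("<coalabc_genealogy> ", x$n_tips, " tips, TMRCA ",
      format(max(x$age), big.mark = ","), " generations\n", sep = "")
  invisible(x)
}

#' Convert a genealogy to an ape phylo tree
#'
#' Branch lengths are in generations; export to newick with
#' [ape::write.tree()].
#'
#' @param genealogy a `coalabc_genealogy`.
#' @return an `ape::phylo` object.
#' @export
as_phylo <- function(genealogy) {
  n <- genealogy$n_tips
  nnode <- 2 * n - 1
  # internal node j (0-based n..2n-2, root last) -> ape number n+1..2n-1
  # with root = n+1
  map <- integer(nnode)
  map[seq_len(n)] <- seq_len(n)
  map[(n + 1):nnode] <- n + (nnode - ((n + 1):nnode)) + 1L
  par <- genealogy$parent
  nonroot <- which(par >= 0)  # 1-based node index with a parent
  edge <- cbind(map[par[nonroot] + 1L], map[nonroot])
  len <- genealogy$age[par[nonroot] + 1L] - genealogy$age[nonroot]
  tr <- structure(list(edge = edge, edge.length = len,
                       tip.label = genealogy$tip_label,
                       Nnode = n - 1L),
                  class = "phylo", order = "cladewise")
  ape::reorder.phylo(tr)
}

# mean relative rate of each of K equal-probability discrete-Gamma slices,
# normalized to mean exactly 1
discrete_gamma_rates <- function(shape, ncat) {
  q <- qgamma(seq(0, 1, length.out = ncat + 1), shape, rate = shape)
  r <- ncat * (pgamma(q[-1], shape + 1, rate = shape) -
                 pgamma(q[-(ncat + 1)], shape + 1, rate = shape))
  r / mean(r)
}

#' Evolve nucleotide sequences along a genealogy (HKY + Gamma + I)
#'
#' The root sequence is drawn from the stationary base frequencies; an exact
#' fraction `prop_invariant` of sites (chosen uniformly at random once per
#' simulation) never mutates; the remaining sites carry relative rates from a
#' discrete Gamma (mean 1). Substitutions follow the HKY rate matrix scaled
#' so a rate-1 site accumulates `mu_site` expected substitutions per
#' generation.
#'
#' @param genealogy a `coalabc_genealogy`.
#' @param model a [mt_model()].
#' @return a [alignment()] with one row per tip.
#' @export
evolve_sequences <- function(genealogy, model) {
  L <- model$length
  n_inv <- round(model$prop_invariant * L)
  site_cat <- sample(rep(1:model$n_categories, length.out = L - n_inv))
  site_cat <- c(rep(0L, n_inv), site_cat)[sample.int(L)]
  rates <- discrete_gamma_rates(model$gamma_shape, model$n_categories)
  m <- evolve_hky_cpp(genealogy$parent, genealogy$age, genealogy$n_tips,
                      as.integer(site_cat), rates, model$kappa,
                      model$base_freqs, model$mu_site)
  alignment(m, labels = genealogy$tip_label)
}

#' Evolve microsatellite loci along independent genealogies
#'
#' One genealogy per locus; the per-locus rate is drawn once per locus from
#' Gamma(shape = `locus_rate_shape`, mean = `mean_rate`); mutation counts on
#' a branch of length L are Poisson(rate x L) and each mutation is a
#' geometric(`p_geom`) multi-step with equiprobable sign.
#'
#' @param genealogies list of `coalabc_genealogy`, one per locus, all with
#'   the same tips.
#' @param model a [str_model()].
#' @return a [str_dataset()], one row per gene copy, one column per locus.
#' @export
evolve_strs <- function(genealogies, model) {
  if (length(genealogies) != model$n_loci)
    stop("need exactly ", model$n_loci, " genealogies, got ",
         length(genealogies))
  if (model$n_loci == 0)
    return(str_dataset(matrix(integer(0), nrow = 0, ncol = 0)))
  n <- genealogies[[1]]$n_tips
  half <- model$clamp_states %/% 2
  lo <- if (model$clamp_states > 0) model$ancestral - half else 1L
  hi <- if (model$clamp_states > 0) model$ancestral + model$clamp_states - half - 1L else 0L
  out <- matrix(NA_integer_, nrow = n, ncol = model$n_loci)
  for (l in seq_len(model$n_loci)) {
    rate <- if (model$mean_rate > 0)
      rgamma(1, shape = model$locus_rate_shape,
             rate = model$locus_rate_shape / model$mean_rate) else 0
    g <- genealogies[[l]]
    out[, l] <- evolve_str_cpp(g$parent, g$age, g$n_tips, rate,
                               model$p_geom, model$ancestral, lo, hi)
  }
  str_dataset(out, labels = genealogies[[1]]$tip_label)
}

#' Simulate a full dataset bundle under a scenario
#'
#' One mtDNA genealogy feeds the sequence alignment; `n_loci` independent
#' nuclear genealogies feed the microsatellite table. In the default
#' `duplicate_haploid` mode one nuclear lineage is simulated per strain and
#' emitted as two identical gene copies (near-isogenic selfing strains).
#'
#' @param scenario a `coalabc_scenario`.
#' @param draw a `coalabc_draw`.
#' @param design a [sampling_design()].
#' @param seed optional integer seed; the bundle is fully reproducible from
#'   (seed, scenario, draw).
#' @return a [dataset_bundle()].
#' @export
simulate_dataset <- function(scenario, draw, design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mt_copies <- design$mt_copies[design$mt_copies > 0]
  aln <- if (length(mt_copies) > 0) {
    g <- simulate_genealogy(scenario, draw, mt_copies, locus_kind = "mt",
                            ploidy_c = design$mt_ploidy_c)
    evolve_sequences(g, design$mt_model)
  } else alignment(character(0))

  strm <- design$str_model
  str_copies <- design$str_copies[design$str_copies > 0]
  if (length(str_copies) > 0 && strm$n_loci > 0) {
    lineages <- if (design$str_mode == "duplicate_haploid")
      str_copies %/% 2L else str_copies
    hist <- scenario_history(scenario, draw)
    gens <- lapply(seq_len(strm$n_loci), function(l)
      genealogy_from_history(hist, lineages, design$nuclear_ploidy_c))
    str <- evolve_strs(gens, strm)
    if (design$str_mode == "duplicate_haploid") {
      idx <- rep(seq_len(nrow(str)), each = 2)
      lab <- paste0(rownames(str)[idx], "/", rep(1:2, nrow(str)))
      str <- str_dataset(unclass(str)[idx, , drop = FALSE], labels = lab)
    }
  } else {
    str <- str_dataset(matrix(integer(0), nrow = 0, ncol = 0))
  }

  ids <- unique(c(rownames(aln), sub("/[12]$", "", rownames(str))))
  pop <- sub("_[0-9]+$", "", ids)
  dataset_bundle(aln, str, data.frame(id = ids, population = pop,
                                      stringsAsFactors = FALSE),
                 provenance = list(seed = seed,
                                   scenario_id = scenario$scenario_id,
                                   draw = draw))
}
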