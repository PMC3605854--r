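# Summary-statistic panel computed identically on observed and simulated
# bundles: mtDNA haplotype/nucleotide diversity, segregating sites, Tajima's
# D and Hudson FST; microsatellite allele counts, allelic range,
# Garza-Williamson M, gene diversity, Weir-Cockerham FST and Goldstein's
# delta-mu-squared.
#
# Missing-data conventions (observed FASTA may carry gaps/ambiguities):
# distance-based statistics exclude non-ACGT sites pairwise; segregating
# sites and Tajima's D use complete deletion.

complete_deletion <- function(aln) {
  if (ncol(aln) == 0) return(aln)
  keep <- colSums(is.na(unclass(aln))) == 0
  aln[, keep, drop = FALSE]
}

#' Haplotype count and diversity
#'
#' Haplotypes are distinct full-length sequences; diversity is the unbiased
#' estimator H = n(1 - sum p_i^2)/(n - 1).
#'
#' @param aln a [alignment()] with at least 2 sequences.
#' @return list with `n_haplotypes` and `haplotype_diversity`.
#' @export
haplotype_stats <- function(aln) {
  n <- nrow(aln)
  if (n < 2) stop("haplotype statistics undefined for fewer than 2 sequences")
  h <- as.character(aln)
  p <- as.numeric(table(h)) / n
  list(n_haplotypes = length(p),
       haplotype_diversity = n * (1 - sum(p^2)) / (n - 1))
}

#' Mean pairwise differences and nucleotide diversity
#'
#' Pi (capital) is the mean Hamming distance over all unordered pairs, with
#' non-ACGT sites excluded pairwise; pi = Pi / alignment length.
#'
#' @param aln a [alignment()] with at least 2 sequences.
#' @return list with `mean_pairwise_differences` and `nucleotide_diversity`.
#' @export
pairwise_diff_stats <- function(aln) {
  n <- nrow(aln)
  if (n < 2) stop("pairwise statistics undefined for fewer than 2 sequences")
  d <- pair_diff_cpp(unclass(aln))
  Pi <- mean(d[upper.tri(d)])
  list(mean_pairwise_differences = Pi,
       nucleotide_diversity = Pi / ncol(aln))
}

segregating_sites <- function(aln) {
  m <- unclass(complete_deletion(aln))
  if (ncol(m) == 0 || nrow(m) == 0) return(0L)
  sum(colSums(m != m[rep.int(1L, nrow(m)), , drop = FALSE]) > 0)
}

#' Tajima's D
#'
#' D = (Pi - S/a1) / sqrt(e1 S + e2 S(S-1)) with the usual constants.
#' Sites with missing data are removed completely before computing both Pi
#' and S. With no segregating sites the statistic is undefined and `NA` is
#' returned (with a warning), never zero.
#'
#' @param aln a [alignment()] with at least 4 sequences.
#' @return numeric scalar, or `NA` if undefined.
#' @export
tajimas_d <- function(aln) {
  n <- nrow(aln)
  if (n < 4) stop("Tajima's D requires at least 4 sequences")
  m <- complete_deletion(aln)
  S <- segregating_sites(m)
  if (S == 0) {
    warning("Tajima's D undefined: no segregating sites")
    return(NA_real_)
  }
  d <- pair_diff_cpp(unclass(m))
  Pi <- mean(d[upper.tri(d)])
  tajd_formula(n, S, Pi)
}

#' Hudson-style pairwise FST from sequences
#'
#' 1 - Hw/Hb where Hw is the mean of the two within-population mean pairwise
#' differences and Hb the mean between-population pairwise difference;
#' returns 0 when Hb = 0.
#'
#' @param aln_a,aln_b alignments for the two populations (>= 2 copies each).
#' @return numeric scalar.
#' @export
pairwise_fst_seq <- function(aln_a, aln_b) {
  if (nrow(aln_a) < 2 || nrow(aln_b) < 2)
    stop("FST requires at least 2 copies per population")
  da <- pair_diff_cpp(unclass(aln_a)); db <- pair_diff_cpp(unclass(aln_b))
  hw <- (mean(da[upper.tri(da)]) + mean(db[upper.tri(db)])) / 2
  both <- pair_diff_cpp(rbind(unclass(aln_a), unclass(aln_b)))
  hb <- mean(both[seq_len(nrow(aln_a)), nrow(aln_a) + seq_len(nrow(aln_b))])
  if (hb == 0) return(0)
  1 - hw / hb
}

str_by_pop <- function(str, popmap) {
  pop <- copy_populations(rownames(str), popmap)
  split(seq_len(nrow(str)), pop)
}

#' Per-population microsatellite statistics
#'
#' Per locus: allele count k, allelic range r = max - min (repeat units),
#' Garza-Williamson M = k/(r + 1), and unbiased gene diversity
#' n(1 - sum p_i^2)/(n - 1). Means and SDs over all loci are reported
#' (`expected_heterozygosity` averages over polymorphic loci only; the
#' polymorphic-locus count is returned alongside).
#'
#' @param str a [str_dataset()].
#' @param popmap population map (data.frame with `id`, `population`).
#' @return data.frame, one row per population.
#' @export
str_locus_stats <- function(str, popmap) {
  groups <- str_by_pop(str, popmap)
  rows <- lapply(names(groups), function(popname) {
    m <- unclass(str)[groups[[popname]], , drop = FALSE]
    per <- apply(m, 2, function(al) {
      al <- al[!is.na(al)]
      if (length(al) < 2) return(c(k = NA, r = NA, M = NA, H = NA))
      p <- as.numeric(table(al)) / length(al)
      c(k = length(p), r = max(al) - min(al),
        M = length(p) / (max(al) - min(al) + 1),
        H = length(al) * (1 - sum(p^2)) / (length(al) - 1))
    })
    per <- per[, !apply(is.na(per), 2, any), drop = FALSE]
    poly <- per["k", ] > 1
    data.frame(population = popname,
               n_loci = ncol(per), n_polymorphic = sum(poly),
               mean_n_alleles = mean(per["k", ]), sd_n_alleles = sd(per["k", ]),
               mean_allelic_range = mean(per["r", ]),
               sd_allelic_range = sd(per["r", ]),
               garza_williamson = mean(per["M", ]),
               sd_garza_williamson = sd(per["M", ]),
               mean_genic_diversity = mean(per["H", ]),
               sd_genic_diversity = sd(per["H", ]),
               expected_heterozygosity =
                 if (any(poly)) mean(per["H", poly]) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Goldstein's delta-mu-squared distance
#'
#' Mean over shared loci of the squared difference in mean allele size.
#'
#' @param str a [str_dataset()].
#' @param popmap population map.
#' @param pair character vector of two population labels.
#' @return numeric scalar.
#' @export
delta_mu_sq <- function(str, popmap, pair) {
  groups <- str_by_pop(str, popmap)
  m1 <- unclass(str)[groups[[pair[1]]], , drop = FALSE]
  m2 <- unclass(str)[groups[[pair[2]]], , drop = FALSE]
  mu1 <- colMeans(m1, na.rm = TRUE); mu2 <- colMeans(m2, na.rm = TRUE)
  ok <- !is.na(mu1) & !is.na(mu2)
  if (!any(ok)) stop("no shared typed loci between populations")
  mean((mu1[ok] - mu2[ok])^2)
}

# Weir-Cockerham variance components for haploid gene copies at one locus:
# returns c(a, a + b) summed over alleles
wc_components <- function(allele_lists) {
  r <- length(allele_lists)
  n_i <- vapply(allele_lists, length, integer(1))
  N <- sum(n_i)
  n_c <- (N - sum(n_i^2) / N) / (r - 1)
  alleles <- sort(unique(unlist(allele_lists)))
  p <- vapply(allele_lists, function(x)
    tabulate(match(x, alleles), length(alleles)) / length(x),
    numeric(length(alleles)))
  p <- matrix(p, nrow = length(alleles))
  pbar <- drop(p %*% n_i) / N
  MSP <- drop((p - pbar)^2 %*% n_i) / (r - 1)
  MSG <- drop((p * (1 - p)) %*% n_i) / sum(n_i - 1)
  a <- (MSP - MSG) / n_c
  c(a = sum(a), b = sum(MSG))
}

#' Weir-Cockerham pairwise FST from microsatellites
#'
#' Variance-components estimator over loci (multi-locus ratio of sums), with
#' gene copies treated as haploid observations; returns 0 when the total
#' variance is 0.
#'
#' @inheritParams delta_mu_sq
#' @return numeric scalar.
#' @export
pairwise_fst_str <- function(str, popmap, pair) {
  groups <- str_by_pop(str, popmap)
  i1 <- groups[[pair[1]]]; i2 <- groups[[pair[2]]]
  if (length(i1) < 2 || length(i2) < 2)
    stop("FST requires at least 2 gene copies per population")
  a_sum <- 0; ab_sum <- 0
  for (l in seq_len(ncol(str))) {
    x1 <- unclass(str)[i1, l]; x1 <- x1[!is.na(x1)]
    x2 <- unclass(str)[i2, l]; x2 <- x2[!is.na(x2)]
    if (length(x1) < 2 || length(x2) < 2) next
    comp <- wc_components(list(x1, x2))
    a_sum <- a_sum + comp["a"]; ab_sum <- ab_sum + comp["a"] + comp["b"]
  }
  if (ab_sum == 0) return(0)
  unname(a_sum / ab_sum)
}

#' Default summary-statistic configuration
#'
#' Per-population: mtDNA haplotype count, mean pairwise differences,
#' segregating sites, Tajima's D; microsatellite mean allele count, expected
#' heterozygosity, mean allelic range, Garza-Williamson M. Pairwise: FST on
#' both markers and delta-mu-squared. Fully configurable by name.
#'
#' @return character vector of statistic names.
#' @export
default_sumstat_config <- function() {
  c("mt_nhap", "mt_mpd", "mt_S", "mt_tajd",
    "str_nall", "str_exphet", "str_range", "str_gw",
    "mt_fst", "str_fst", "str_dmu2")
}

PER_POP_STATS <- c("mt_nhap", "mt_hapdiv", "mt_mpd", "mt_pi", "mt_S",
                   "mt_tajd", "str_nall", "str_exphet", "str_range",
                   "str_gw", "str_gendiv")
PAIR_STATS <- c("mt_fst", "str_fst", "str_dmu2")

#' Summary vector of a dataset bundle
#'
#' Computes the configured statistic panel identically on observed and
#' simulated bundles, concatenated in a deterministic order (per-population
#' statistics over sorted population labels, then pairwise statistics over
#' sorted label pairs). Tajima's D is recorded as 0 when undefined (no
#' segregating sites) so that vectors remain comparable across simulations.
#'
#' @param bundle a [dataset_bundle()].
#' @param config character vector of statistic names (see
#'   [default_sumstat_config()]).
#' @param populations populations to include (default: all in the bundle's
#'   map, sorted).
#' @return named numeric vector.
#' @export
summary_vector <- function(bundle, config = default_sumstat_config(),
                           populations = NULL) {
  unknown <- setdiff(config, c(PER_POP_STATS, PAIR_STATS))
  if (length(unknown) > 0)
    stop("unknown summary statistics: ", paste(unknown, collapse = ", "))
  if (length(config) == 0) return(setNames(numeric(0), character(0)))
  if (is.null(populations)) populations <- sort(unique(bundle$popmap$population))
  want_mt <- any(startsWith(config, "mt_"))
  want_str <- any(startsWith(config, "str_"))

  # shared objects computed once: full mtDNA distance matrix, per-population
  # row indices for both markers
  mtm <- unclass(bundle$mt)
  D <- if (want_mt && nrow(mtm) > 1) pair_diff_cpp(mtm) else NULL
  mt_pop <- if (nrow(mtm) > 0)
    copy_populations(rownames(bundle$mt), bundle$popmap) else character(0)
  mt_idx <- split(seq_len(nrow(mtm)), mt_pop)
  strm <- unclass(bundle$str)
  str_idx <- if (want_str && nrow(strm) > 0)
    split(seq_len(nrow(strm)),
          copy_populations(rownames(bundle$str), bundle$popmap)) else list()
  has_na <- anyNA(mtm)

  pop_mt <- function(p) {
    i <- mt_idx[[p]]
    if (is.null(i) || length(i) < 2)
      stop("population ", p, " has fewer than 2 mtDNA copies")
    i
  }
  mt_block <- function(p) {
    i <- pop_mt(p)
    D[i, i][upper.tri(diag(length(i)))]
  }
  seg_and_pi <- function(p) {
    # complete-deletion segregating sites and (for Tajima's D) matching Pi
    i <- pop_mt(p)
    m <- mtm[i, , drop = FALSE]
    if (has_na) {
      keep <- colSums(is.na(m)) == 0
      m <- m[, keep, drop = FALSE]
    }
    if (ncol(m) == 0) return(c(S = 0, Pi = 0))
    S <- sum(colSums(m != m[rep.int(1L, nrow(m)), , drop = FALSE]) > 0)
    Pi <- if (has_na) {
      d <- pair_diff_cpp(m); mean(d[upper.tri(d)])
    } else mean(mt_block(p))
    c(S = S, Pi = Pi)
  }
  tajd_fast <- function(p) {
    n <- length(pop_mt(p))
    if (n < 4) stop("Tajima's D requires at least 4 sequences")
    sp <- seg_and_pi(p)
    if (sp["S"] == 0) return(0)  # undefined: recorded as 0 in ABC vectors
    tajd_formula(n, sp["S"], sp["Pi"])
  }
  # per-locus microsatellite panel for one population
  str_pop <- function(p) {
    i <- str_idx[[p]]
    if (is.null(i) || length(i) < 2)
      stop("population ", p, " has fewer than 2 STR gene copies")
    k <- r <- H <- numeric(ncol(strm))
    ok <- logical(ncol(strm))
    for (l in seq_len(ncol(strm))) {
      al <- strm[i, l]; al <- al[!is.na(al)]
      if (length(al) < 2) next
      ok[l] <- TRUE
      u <- unique(al)
      pfreq <- tabulate(match(al, u), length(u)) / length(al)
      k[l] <- length(u)
      r[l] <- max(al) - min(al)
      H[l] <- length(al) * (1 - sum(pfreq^2)) / (length(al) - 1)
    }
    k <- k[ok]; r <- r[ok]; H <- H[ok]
    poly <- k > 1
    c(nall = mean(k), range = mean(r), gw = mean(k / (r + 1)),
      gendiv = mean(H), exphet = if (any(poly)) mean(H[poly]) else 0)
  }

  out <- numeric(0)
  per <- intersect(config, PER_POP_STATS)
  str_cache <- list()
  for (p in populations) {
    if (any(per %in% c("str_nall", "str_exphet", "str_range", "str_gw",
                       "str_gendiv")))
      str_cache[[p]] <- str_pop(p)
    # identical sequences have distance 0, so haplotype classes fall out of
    # the shared distance matrix when there is no missing data
    hap_fast <- function(p) {
      if (has_na) return(haplotype_stats(bundle$mt[pop_mt(p), , drop = FALSE]))
      i <- pop_mt(p)
      d <- D[i, i, drop = FALSE]
      n <- length(i)
      first <- vapply(seq_len(n), function(r)
        which(d[r, ] == 0)[1], numeric(1))
      cnt <- tabulate(first, n)
      pfreq <- cnt[cnt > 0] / n
      list(n_haplotypes = length(pfreq),
           haplotype_diversity = n * (1 - sum(pfreq^2)) / (n - 1))
    }
    for (s in per) {
      val <- switch(s,
        mt_nhap = hap_fast(p)$n_haplotypes,
        mt_hapdiv = hap_fast(p)$haplotype_diversity,
        mt_mpd = mean(mt_block(p)),
        mt_pi = mean(mt_block(p)) / ncol(mtm),
        mt_S = unname(seg_and_pi(p)["S"]),
        mt_tajd = unname(tajd_fast(p)),
        str_nall = str_cache[[p]]["nall"],
        str_exphet = str_cache[[p]]["exphet"],
        str_range = str_cache[[p]]["range"],
        str_gw = str_cache[[p]]["gw"],
        str_gendiv = str_cache[[p]]["gendiv"])
      out[paste0(s, "_", p)] <- val
    }
  }
  pairstats <- intersect(config, PAIR_STATS)
  if (length(pairstats) > 0 && length(populations) > 1) {
    prs <- combn(populations, 2)
    for (j in seq_len(ncol(prs))) {
      p1 <- prs[1, j]; p2 <- prs[2, j]
      for (s in pairstats) {
        val <- switch(s,
          mt_fst = {
            i1 <- pop_mt(p1); i2 <- pop_mt(p2)
            hw <- (mean(mt_block(p1)) + mean(mt_block(p2))) / 2
            hb <- mean(D[i1, i2])
            if (hb == 0) 0 else 1 - hw / hb
          },
          str_fst = {
            i1 <- str_idx[[p1]]; i2 <- str_idx[[p2]]
            a_sum <- 0; ab_sum <- 0
            for (l in seq_len(ncol(strm))) {
              x1 <- strm[i1, l]; x1 <- x1[!is.na(x1)]
              x2 <- strm[i2, l]; x2 <- x2[!is.na(x2)]
              if (length(x1) < 2 || length(x2) < 2) next
              comp <- wc_components(list(x1, x2))
              a_sum <- a_sum + comp[1]; ab_sum <- ab_sum + comp[1] + comp[2]
            }
            if (ab_sum == 0) 0 else unname(a_sum / ab_sum)
          },
          str_dmu2 = {
            m1 <- colMeans(strm[str_idx[[p1]], , drop = FALSE], na.rm = TRUE)
            m2 <- colMeans(strm[str_idx[[p2]], , drop = FALSE], na.rm = TRUE)
            ok <- !is.na(m1) & !is.na(m2)
            mean((m1[ok] - m2[ok])^2)
          })
        out[paste0(s, "_", p1, ".", p2)] <- val
      }
    }
  }
  out
}

tajd_formula <- function(n, S, Pi) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (Pi - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}
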