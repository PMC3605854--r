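# Core data containers: nucleotide alignments, microsatellite tables,
# mutation models, sampling designs, dataset bundles.

BASES <- c("A", "C", "G", "T")

#' Nucleotide alignment container
#'
#' Stores an equal-length nucleotide alignment as an integer-coded matrix
#' (0 = A, 1 = C, 2 = G, 3 = T, `NA` = gap/ambiguity), one row per gene copy.
#'
#' @param x character vector of equal-length sequences (names kept as labels),
#'   or an integer matrix already coded 0..3.
#' @param labels optional row labels.
#' @return an object of class `coalabc_alignment`.
#' @export
alignment <- function(x, labels = NULL) {
  if (is.character(x)) {
    if (length(x) == 0) {
      m <- matrix(integer(0), nrow = 0, ncol = 0)
    } else {
      lens <- nchar(x)
      if (length(unique(lens)) > 1) {
        bad <- names(x)[which(lens != lens[1])[1]]
        if (is.null(bad)) bad <- which(lens != lens[1])[1]
        stop("ragged alignment: record '", bad, "' has length ",
             lens[lens != lens[1]][1], ", expected ", lens[1])
      }
      chars <- toupper(do.call(rbind, strsplit(x, "", fixed = TRUE)))
      m <- matrix(match(chars, BASES) - 1L, nrow = length(x))
      if (is.null(labels)) labels <- names(x)
    }
  } else {
    m <- x
  }
  if (is.null(labels) && !is.null(rownames(m))) labels <- rownames(m)
  if (is.null(labels) && nrow(m) > 0) labels <- paste0("seq", seq_len(nrow(m)))
  rownames(m) <- labels
  structure(m, class = c("coalabc_alignment", "matrix", "array"))
}

#' @export
as.character.coalabc_alignment <- function(x, ...) {
  if (nrow(x) == 0) return(character(0))
  ch <- matrix(BASES[unclass(x) + 1L], nrow = nrow(x))
  ch[is.na(ch)] <- "N"
  setNames(apply(ch, 1, paste, collapse = ""), rownames(x))
}

#' @export
print.coalabc_alignment <- function(x, ...) {
  cat("<coalabc_alignment> ", nrow(x), " sequences x ", ncol(x), " sites\n", sep = "")
  invisible(x)
}

# subset keeps class
#' @export
`[.coalabc_alignment` <- function(x, i, j, ..., drop = FALSE) {
  m <- unclass(x)[i, j, drop = FALSE]
  structure(m, class = class(x))
}

#' Microsatellite dataset container
#'
#' Integer allele sizes (repeat units), one row per gene copy, one column per
#' locus; `NA` marks missing alleles.
#'
#' @param mat integer matrix of allele sizes.
#' @param labels optional row labels.
#' @return object of class `coalabc_str`.
#' @export
str_dataset <- function(mat, labels = NULL) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (!is.null(labels)) rownames(mat) <- labels
  if (ncol(mat) > 0 && is.null(colnames(mat)))
    colnames(mat) <- sprintf("L%02d", seq_len(ncol(mat)))
  if (nrow(mat) > 0 && any(mat <= 0, na.rm = TRUE))
    stop("allele sizes must be positive integers")
  structure(mat, class = c("coalabc_str", "matrix", "array"))
}

#' @export
`[.coalabc_str` <- function(x, i, j, ..., drop = FALSE) {
  m <- unclass(x)[i, j, drop = FALSE]
  structure(m, class = class(x))
}

#' @export
print.coalabc_str <- function(x, ...) {
  cat("<coalabc_str> ", nrow(x), " gene copies x ", ncol(x), " loci\n", sep = "")
  invisible(x)
}

#' Mitochondrial substitution model (HKY + Gamma + invariant sites)
#'
#' @param kappa transition/transversion rate ratio.
#' @param base_freqs stationary base frequencies (A, C, G, T), must sum to 1.
#' @param gamma_shape shape of the discrete-Gamma rate heterogeneity (mean 1).
#' @param prop_invariant fraction of sites held constant, in `[0, 1)`.
#' @param mu_site substitutions per site per generation at a rate-1 site.
#' @param length number of sites.
#' @param n_categories discrete-Gamma categories.
#' @return object of class `coalabc_mt_model`.
#' @export
mt_model <- function(kappa = 2, base_freqs = rep(0.25, 4), gamma_shape = 2,
                     prop_invariant = 0.1, mu_site = 7.6e-8, length = 565,
                     n_categories = 4) {
  stopifnot(abs(sum(base_freqs) - 1) < 1e-12, prop_invariant >= 0,
            prop_invariant < 1, gamma_shape > 0, mu_site > 0, length >= 1)
  structure(list(kappa = kappa, base_freqs = base_freqs,
                 gamma_shape = gamma_shape, prop_invariant = prop_invariant,
                 mu_site = mu_site, length = as.integer(length),
                 n_categories = as.integer(n_categories)),
            class = "coalabc_mt_model")
}

#' Microsatellite mutation model (generalized stepwise mutation)
#'
#' Per-locus mean rates are drawn once per locus from a Gamma distribution
#' (shape `locus_rate_shape`, mean `mean_rate`); each mutation moves the
#' allele by a geometric(`p_geom`) number of repeat units with equiprobable
#' sign. Allele sizes are reflected into a contiguous `clamp_states`-state
#' window around the ancestral allele (set `clamp_states = 0` to disable).
#'
#' @param mean_rate mean per-locus mutation rate per generation.
#' @param locus_rate_shape Gamma shape of across-locus rate variation.
#' @param p_geom geometric parameter of the multi-step size distribution;
#'   `p_geom = 1` recovers the strict single-step model.
#' @param n_loci number of independent loci.
#' @param ancestral ancestral allele size (repeat units).
#' @param clamp_states width of the reflecting allele-size window.
#' @return object of class `coalabc_str_model`.
#' @export
str_model <- function(mean_rate = 1e-5, locus_rate_shape = 2, p_geom = 0.22,
                      n_loci = 16, ancestral = 100, clamp_states = 40) {
  stopifnot(mean_rate >= 0, p_geom > 0, p_geom <= 1, n_loci >= 0,
            locus_rate_shape > 0)
  structure(list(mean_rate = mean_rate, locus_rate_shape = locus_rate_shape,
                 p_geom = p_geom, n_loci = as.integer(n_loci),
                 ancestral = as.integer(ancestral),
                 clamp_states = as.integer(clamp_states)),
            class = "coalabc_str_model")
}

#' Sampling design for simulated datasets
#'
#' @param mt_copies named integer vector: mtDNA gene copies (strains) per
#'   population label.
#' @param str_copies named integer vector: microsatellite gene copies per
#'   population; defaults to twice `mt_copies` (two identical gene copies per
#'   near-isogenic haploid strain, the package default) .
#' @param mt_model,str_model mutation models, see [mt_model()], [str_model()].
#' @param str_mode `"duplicate_haploid"` simulates one nuclear lineage per
#'   strain and emits two identical gene copies (selfing, near-isogenic
#'   strains); `"diploid"` simulates every gene copy as its own lineage.
#' @param mt_ploidy_c,nuclear_ploidy_c ploidy factors c in the pair
#'   coalescence rate 1/(c N).
#' @return object of class `coalabc_design`.
#' @export
sampling_design <- function(mt_copies, str_copies = 2L * mt_copies,
                            mt_model = coalabc::mt_model(),
                            str_model = coalabc::str_model(),
                            str_mode = c("duplicate_haploid", "diploid"),
                            mt_ploidy_c = 0.5, nuclear_ploidy_c = 2) {
  str_mode <- match.arg(str_mode)
  stopifnot(!is.null(names(mt_copies)), all(mt_copies >= 0),
            all(str_copies >= 0))
  if (str_mode == "duplicate_haploid" && any(str_copies %% 2 != 0))
    stop("duplicate_haploid mode requires even str_copies")
  structure(list(mt_copies = mt_copies, str_copies = str_copies,
                 mt_model = mt_model, str_model = str_model,
                 str_mode = str_mode, mt_ploidy_c = mt_ploidy_c,
                 nuclear_ploidy_c = nuclear_ploidy_c),
            class = "coalabc_design")
}

#' Paired dataset bundle
#'
#' One (real or simulated) dataset: an mtDNA alignment, a microsatellite
#' table, and the population map tying gene copies to populations.
#'
#' @param mt a [alignment()] (rows labelled by strain).
#' @param str a [str_dataset()] (rows labelled by gene copy; strain labels are
#'   the row label up to the final `/1` or `/2` suffix).
#' @param popmap data.frame with columns `id` (strain) and `population`.
#' @param provenance free-form list (seed, scenario id, generating draw, ...).
#' @return object of class `coalabc_bundle`.
#' @export
dataset_bundle <- function(mt, str, popmap, provenance = list()) {
  stopifnot(is.data.frame(popmap), all(c("id", "population") %in% names(popmap)))
  if (nrow(mt) > 0 && !all(rownames(mt) %in% popmap$id))
    stop("mtDNA copies missing from population map")
  structure(list(mt = mt, str = str, popmap = popmap,
                 provenance = provenance),
            class = "coalabc_bundle")
}

#' @export
print.coalabc_bundle <- function(x, ...) {
  cat("<coalabc_bundle> ", nrow(x$mt), " mt sequences (", ncol(x$mt),
      " bp), ", nrow(x$str), " STR gene copies x ", ncol(x$str),
      " loci, ", length(unique(x$popmap$population)), " populations\n", sep = "")
  invisible(x)
}

# population label of each row of a matrix whose rownames are strain ids or
# strain ids with a /1 /2 gene-copy suffix
copy_populations <- function(labels, popmap) {
  ids <- sub("/[12]$", "", labels)
  pop <- popmap$population[match(ids, popmap$id)]
  if (anyNA(pop)) stop("gene copies missing from population map: ",
                       paste(head(labels[is.na(pop)]), collapse = ", "))
  pop
}
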