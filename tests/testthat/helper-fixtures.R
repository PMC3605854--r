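# Shared builders for the test suite. Everything is generated in code; no
# stored fixtures.

toy_alignment <- function(seqs, labels = NULL) {
  if (is.null(labels)) labels <- paste0("s", seq_along(seqs))
  alignment(setNames(seqs, labels))
}

# hand-built ultrametric genealogy: two tips diverging at `height`
pair_genealogy <- function(height) {
  structure(list(parent = c(2L, 2L, -1L), age = c(0, 0, height),
                 n_tips = 2L, tip_pop = c("x", "x"),
                 tip_label = c("s1", "s2"), ploidy_c = 1),
            class = "coalabc_genealogy")
}

# degenerate genealogy of height 0 (all coalescences at time 0)
flat_genealogy <- function(n) {
  parent <- integer(2 * n - 1)
  avail <- 0:(n - 1)
  for (k in seq_len(n - 1)) {
    node <- n + k - 1
    parent[avail[1] + 1] <- node
    parent[avail[2] + 1] <- node
    avail <- c(avail[-(1:2)], node)
  }
  parent[2 * n - 1] <- -1L
  structure(list(parent = parent, age = rep(0, 2 * n - 1), n_tips = as.integer(n),
                 tip_pop = rep("x", n), tip_label = paste0("s", 1:n),
                 ploidy_c = 1),
            class = "coalabc_genealogy")
}

# the four well-separated colonization orders used as the identifiable toy
# model for ABC self-consistency experiments
toy_abc_setup <- function(n_loci = 16, strains = 12) {
  scens_all <- enumerate_colonization_scenarios(scenario_template())
  orders <- vapply(scens_all, function(s)
    paste(s$colonization_order, collapse = ""), character(1))
  sm <- str_model(mean_rate = 2e-5, n_loci = n_loci)
  list(scenarios = scens_all[match(c("abcd", "bdac", "cabd", "dcba"), orders)],
       priors = default_priors(N_present = c(8e4, 1.2e5), N_A = c(8e4, 1.2e5),
                               N_bottleneck = c(2, 4), str_model = sm),
       design = sampling_design(
         mt_copies = setNames(rep(strains, 4), c("a", "b", "c", "d")),
         str_model = sm),
       config = c("mt_nhap", "mt_mpd", "mt_S",
                  "str_nall", "str_exphet", "str_range"))
}

# small reference table built directly (for regression/rejection unit tests)
synthetic_reftable <- function(stats, params, scenario, scales = NULL) {
  if (is.null(scales)) scales <- apply(stats, 2, function(x) 1.4826 * mad(x, constant = 1))
  structure(list(stats = stats, params = params, scenario = scenario,
                 scales = scales, config = colnames(stats), seed = NULL),
            class = "coalabc_reftable")
}
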