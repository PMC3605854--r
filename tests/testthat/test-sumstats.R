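# Statistic panel: hand-enumerated oracles, frozen independent evaluations,
# and invariances.

test_that("haplotype statistics match hand-enumerated frequencies", {
  a <- toy_alignment(c("AAAA", "AAAA", "AAAT", "AATT"))  # {X, X, Y, Z}
  h <- haplotype_stats(a)
  expect_equal(h$n_haplotypes, 3)
  expect_equal(h$haplotype_diversity, (4 / 3) * (1 - 0.375), tolerance = 1e-12)

  mono <- toy_alignment(rep("ACGT", 5))
  expect_equal(haplotype_stats(mono)$n_haplotypes, 1)
  expect_equal(haplotype_stats(mono)$haplotype_diversity, 0)

  distinct <- toy_alignment(c("AAAA", "AAAT", "AATT", "ATTT", "TTTT"))
  expect_equal(haplotype_stats(distinct)$haplotype_diversity, 1)
  expect_error(haplotype_stats(toy_alignment("AAAA")), "fewer than 2")
})

test_that("pairwise differences and nucleotide diversity match pair enumeration", {
  a <- toy_alignment(c("AAAA", "AAAT", "AATT"))
  pd <- pairwise_diff_stats(a)
  expect_equal(pd$mean_pairwise_differences, 4 / 3, tolerance = 1e-12)
  expect_equal(pd$nucleotide_diversity, 1 / 3, tolerance = 1e-12)
  expect_equal(pairwise_diff_stats(toy_alignment(rep("AAAA", 3)))$mean_pairwise_differences, 0)
  maxd <- pairwise_diff_stats(toy_alignment(c("AAAA", "TTTT")))
  expect_equal(maxd$mean_pairwise_differences, 4)
  expect_equal(maxd$nucleotide_diversity, 1)
})

test_that("Tajima's D matches an independent evaluation and signals S = 0", {
  # frozen value computed with an independent implementation of the 1989
  # constants (n = 5, S = 3, Pi = 1.4)
  a <- toy_alignment(c("AAAAAAAA", "AAAAAAAT", "AAAAAATT", "AAAAAAAA",
                       "AACAAAAA"))
  expect_equal(tajimas_d(a), -0.174748847425, tolerance = 1e-10)
  expect_warning(d0 <- tajimas_d(toy_alignment(rep("AAAA", 4))), "undefined")
  expect_true(is.na(d0))
  expect_error(tajimas_d(toy_alignment(c("AA", "AT", "TA"))), "at least 4")
})

test_that("neutral constant-size data give mean Tajima's D near zero", {
  set.seed(21)
  m <- mt_model(mu_site = 2e-6, prop_invariant = 0, gamma_shape = 100,
                length = 565)
  vals <- replicate(2000, {
    g <- coalabc:::sim_genealogy_cpp(rep(0L, 8), list(matrix(c(0, 2000), 1)),
                                    numeric(0), integer(0), integer(0), 1)
    gg <- structure(list(parent = g$parent, age = g$age, n_tips = 8L,
                         tip_pop = rep("x", 8), tip_label = paste0("s", 1:8),
                         ploidy_c = 1), class = "coalabc_genealogy")
    suppressWarnings(tajimas_d(evolve_sequences(gg, m)))
  })
  expect_lt(abs(mean(vals, na.rm = TRUE)), 0.15)
})

test_that("Hudson FST matches cross-pair enumeration and its conventions", {
  a <- toy_alignment(c("AAAA", "AAAT"))
  b <- toy_alignment(c("TTTT", "TTTA"))
  expect_equal(pairwise_fst_seq(a, b), 1 - 1 / 3.5, tolerance = 1e-12)
  mono <- toy_alignment(c("AAAA", "AAAA"))
  expect_equal(pairwise_fst_seq(mono, mono), 0)  # Hb = 0 convention
  fixed_a <- toy_alignment(c("AAAA", "AAAA"))
  fixed_b <- toy_alignment(c("TTTT", "TTTT"))
  expect_equal(pairwise_fst_seq(fixed_a, fixed_b), 1)
  expect_error(pairwise_fst_seq(toy_alignment("AAAA"), mono), "at least 2")
})

test_that("microsatellite per-locus statistics match direct formulas", {
  # alleles {10,12,14,16,19}: k = 5, range 9, M = 0.5
  str1 <- str_dataset(matrix(c(10L, 12L, 14L, 16L, 19L), ncol = 1),
                      labels = paste0("p_", sprintf("%02d", 1:5)))
  pm <- data.frame(id = rownames(str1), population = "p")
  s <- str_locus_stats(str1, pm)
  expect_equal(s$mean_n_alleles, 5)
  expect_equal(s$mean_allelic_range, 9)
  expect_equal(s$garza_williamson, 0.5)

  mono <- str_dataset(matrix(rep(7L, 4), ncol = 1),
                      labels = paste0("p_", 1:4))
  sm <- str_locus_stats(mono, data.frame(id = rownames(mono), population = "p"))
  expect_equal(sm$mean_n_alleles, 1)
  expect_equal(sm$garza_williamson, 1)   # k = 1, r = 0 is not an error
  expect_equal(sm$mean_genic_diversity, 0)

  het <- str_dataset(matrix(c(10L, 10L, 12L, 12L), ncol = 1),
                     labels = paste0("p_", 1:4))
  sh <- str_locus_stats(het, data.frame(id = rownames(het), population = "p"))
  expect_equal(sh$mean_genic_diversity, (4 / 3) * 0.5, tolerance = 1e-12)
})

test_that("delta-mu-squared matches arithmetic on locus means", {
  mk <- function(vals1, vals2) {
    m <- rbind(vals1, vals2)
    labs <- c(paste0("x_", seq_len(nrow(vals1))), paste0("y_", seq_len(nrow(vals2))))
    str_dataset(matrix(as.integer(m), nrow = nrow(m)), labels = labs)
  }
  s <- mk(matrix(rep(10, 4), 4), matrix(rep(13, 4), 4))
  pm <- data.frame(id = rownames(s), population = rep(c("x", "y"), each = 4))
  expect_equal(delta_mu_sq(s, pm, c("x", "y")), 9)
  expect_equal(delta_mu_sq(s, pm, c("x", "x")), 0)
  two <- mk(cbind(rep(10, 4), rep(20, 4)), cbind(rep(11, 4), rep(23, 4)))
  pm2 <- data.frame(id = rownames(two), population = rep(c("x", "y"), each = 4))
  expect_equal(delta_mu_sq(two, pm2, c("x", "y")), (1 + 9) / 2)
})

test_that("Weir-Cockerham FST matches an independent variance-components evaluation", {
  mk2 <- function(a1, a2) {
    m <- matrix(c(a1, a2), ncol = 1)
    labs <- c(paste0("x_", seq_along(a1)), paste0("y_", seq_along(a2)))
    str_dataset(m, labels = labs)
  }
  pm <- function(s, n1) data.frame(id = rownames(s),
                                   population = rep(c("x", "y"), c(n1, nrow(s) - n1)))
  # frozen value from an independent brute-force evaluation:
  # {10,10,10,12} vs {12,12,12,12} -> 2/3
  s <- mk2(c(10L, 10L, 10L, 12L), c(12L, 12L, 12L, 12L))
  expect_equal(pairwise_fst_str(s, pm(s, 4), c("x", "y")), 2 / 3,
               tolerance = 1e-10)
  fixed <- mk2(c(10L, 10L, 10L), c(12L, 12L, 12L))
  expect_equal(pairwise_fst_str(fixed, pm(fixed, 3), c("x", "y")), 1)
  mono <- mk2(c(10L, 10L), c(10L, 10L))
  expect_equal(pairwise_fst_str(mono, pm(mono, 2), c("x", "y")), 0)
})

test_that("summary vectors are deterministic, configurable, and order-invariant", {
  des <- sampling_design(mt_copies = c(a = 6, b = 6),
                         str_model = str_model(n_loci = 4))
  sc <- enumerate_colonization_scenarios(scenario_template())[[1]]
  b <- simulate_dataset(sc, default_truth_draw(), des, seed = 31)

  expect_length(summary_vector(b, "mt_nhap"), 2)
  expect_length(summary_vector(b, character(0)), 0)
  expect_error(summary_vector(b, "not_a_stat"), "unknown")

  v1 <- summary_vector(b)
  v2 <- summary_vector(b)
  expect_identical(v1, v2)

  # permuting rows of both tables leaves every statistic unchanged
  set.seed(4)
  perm_mt <- sample(nrow(b$mt))
  perm_str <- sample(nrow(b$str))
  b2 <- dataset_bundle(b$mt[perm_mt, ], b$str[perm_str, ], b$popmap)
  expect_equal(summary_vector(b2), v1, tolerance = 1e-12)

  # range contracts
  expect_true(v1["mt_fst_a.b"] <= 1)
  expect_true(all(v1[grep("exphet", names(v1))] >= 0 &
                    v1[grep("exphet", names(v1))] <= 1))
})

test_that("unbiased gene diversity is invariant to sample size in expectation", {
  # the n/(n-1) correction makes the estimator's mean match across sample
  # sizes; compare n = 6 gene copies against n = 40 over replicates
  tmpl <- scenario_template(islands = "a", lineages = "A",
                            lineage_time_params = "t5")
  sc <- enumerate_colonization_scenarios(tmpl)[[1]]
  p <- c(t1 = 2e4, t5 = 5e5, N_A = 2e4, N1 = 2e4, N2 = 1e3, db = 5)
  het_at <- function(n, reps, seed) {
    set.seed(seed)
    d <- structure(list(params = p, mt_model = mt_model(),
                        str_model = str_model(mean_rate = 5e-5, n_loci = 4)),
                   class = "coalabc_draw")
    mean(replicate(reps, {
      gens <- lapply(1:4, function(i)
        simulate_genealogy(sc, d, c(a = n), locus_kind = "nuclear"))
      x <- unclass(evolve_strs(gens, d$str_model))
      mean(apply(x, 2, function(al) {
        pf <- tabulate(match(al, unique(al))) / length(al)
        length(al) * (1 - sum(pf^2)) / (length(al) - 1)
      }))
    }))
  }
  h_small <- het_at(6, 800, 61)
  h_large <- het_at(40, 800, 62)
  expect_lt(abs(h_small - h_large) / h_large, 0.02)
})
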