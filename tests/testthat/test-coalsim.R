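# The simulator core: structured coalescent, HKY sequence evolution,
# generalized stepwise microsatellite mutation.

test_that("pair coalescence time has mean c*N in a constant-size population", {
  set.seed(101)
  for (cc in c(1, 2)) {
    N <- 1000
    t2 <- replicate(10000, {
      g <- coalabc:::sim_genealogy_cpp(c(0L, 0L), list(matrix(c(0, N), 1)),
                                      numeric(0), integer(0), integer(0), cc)
      max(g$age)
    })
    se <- sd(t2) / sqrt(length(t2))
    expect_lt(abs(mean(t2) - cc * N), 3 * se)
  }
})

test_that("cross-population coalescences postdate every colonization", {
  scens <- enumerate_colonization_scenarios(scenario_template())
  sc <- scens[[1]]
  draw <- default_truth_draw()
  set.seed(7)
  for (r in 1:50) {
    g <- simulate_genealogy(sc, draw, c(a = 5, b = 5), locus_kind = "mt")
    # nodes whose descendant tips span both islands
    n <- g$n_tips; nnode <- 2 * n - 1
    below <- matrix(FALSE, nnode, n)
    below[cbind(1:n, 1:n)] <- TRUE
    for (v in seq_len(nnode - 1))
      below[g$parent[v] + 1, ] <- below[g$parent[v] + 1, ] | below[v, ]
    is_a <- g$tip_pop == "a"
    cross <- which(rowSums(below[, is_a, drop = FALSE]) > 0 &
                     rowSums(below[, !is_a, drop = FALSE]) > 0)
    t_cols <- draw$params[c("t4", "t3")]  # a and b colonization times (order abcd)
    expect_gt(min(g$age[cross]), max(t_cols))
  }
})

test_that("a severe founder bottleneck prunes lineages", {
  # one island, colonization at 10,000 generations; compare the number of
  # lineages surviving back past the colonization time with and without a
  # tight bottleneck
  tmpl <- scenario_template(islands = "a", lineages = "A",
                            lineage_time_params = "t5")
  sc <- enumerate_colonization_scenarios(tmpl)[[1]]
  survivors <- function(Nb, db) {
    p <- c(t1 = 10000, t5 = 5e5, N_A = 1e4, N1 = 1e4, N2 = Nb, db = db)
    d <- structure(list(params = p, mt_model = mt_model(),
                        str_model = str_model()), class = "coalabc_draw")
    mean(replicate(3000, {
      g <- simulate_genealogy(sc, d, c(a = 10), locus_kind = "nuclear")
      1 + sum(g$age > 10000)  # lineages left just after the window
    }))
  }
  set.seed(5)
  with_bott <- survivors(Nb = 2, db = 50)
  without <- survivors(Nb = 1e4, db = 50)
  expect_lt(with_bott, without - 0.5)
})

test_that("a zero-height tree yields identical sequences", {
  g <- flat_genealogy(6)
  a <- evolve_sequences(g, mt_model(length = 200))
  expect_equal(length(unique(as.character(a))), 1)
})

test_that("kappa = 1 with equal frequencies reduces HKY to Jukes-Cantor", {
  set.seed(33)
  m <- mt_model(kappa = 1, gamma_shape = 100, prop_invariant = 0,
                mu_site = 1e-3, length = 30000)
  a <- evolve_sequences(pair_genealogy(50), m)
  x <- unclass(a)
  diff <- x[1, ] != x[2, ]
  expect_gt(sum(diff), 1000)
  is_purine <- function(b) b %in% c(0L, 2L)
  transitions <- is_purine(x[1, diff]) == is_purine(x[2, diff])
  p <- mean(transitions)
  se <- sqrt(p * (1 - p) / sum(diff))
  expect_lt(abs(p - 1/3), 4 * se + 0.005)
})

test_that("small-distance pairwise differences match 2*mu*T*(1 - prop_invariant)", {
  set.seed(34)
  m <- mt_model(kappa = 2, prop_invariant = 0.1, mu_site = 1e-4, length = 50000)
  a <- evolve_sequences(pair_genealogy(50), m)  # mu*T = 0.005 per site
  x <- unclass(a)
  p_obs <- mean(x[1, ] != x[2, ])
  expected <- 2 * 0.005 * 0.9
  se <- sqrt(expected * (1 - expected) / ncol(a))
  # small multiple-hit correction keeps the observed value slightly below
  expect_lt(abs(p_obs - expected), 4 * se + 0.1 * expected)
})

test_that("microsatellite mutation follows the generalized stepwise model", {
  g <- pair_genealogy(500)
  # rate 0: every copy stays at the ancestral allele
  set.seed(8)
  quiet <- evolve_strs(list(g, g), str_model(mean_rate = 0, n_loci = 2))
  expect_true(all(unclass(quiet) == 100L))

  # p_geom = 1 (strict single-step), no clamping: displacement across a
  # branch has mean 0 and variance rate*length (each mutation is +/-1)
  sm <- str_model(mean_rate = 1e-3, locus_rate_shape = 1e8, p_geom = 1,
                  n_loci = 1, clamp_states = 0)
  set.seed(9)
  disp <- replicate(8000, {
    x <- evolve_strs(list(pair_genealogy(500)), sm)
    unclass(x)[1, 1] - 100
  })
  rl <- 1e-3 * 500  # expected mutations tip-to-root
  expect_lt(abs(mean(disp)), 3 * sqrt(rl / 8000) + 0.05)
  expect_lt(abs(var(disp) - rl), 5 * rl / sqrt(8000) + 0.05)

  # clamped alleles stay inside the 40-state window
  sm2 <- str_model(mean_rate = 0.05, n_loci = 4, clamp_states = 40)
  set.seed(10)
  x <- evolve_strs(lapply(1:4, function(i) pair_genealogy(5000)), sm2)
  expect_true(all(unclass(x) >= 80 & unclass(x) <= 119))

  expect_error(evolve_strs(list(g), str_model(n_loci = 2)), "genealogies")
})

test_that("mean pairwise mtDNA differences match theta = 2*mu*L*c*N", {
  set.seed(55)
  N <- 2000; mu <- 1e-6; L <- 565; cc <- 1
  m <- mt_model(mu_site = mu, prop_invariant = 0, gamma_shape = 100, length = L)
  diffs <- replicate(8000, {
    g <- coalabc:::sim_genealogy_cpp(c(0L, 0L), list(matrix(c(0, N), 1)),
                                    numeric(0), integer(0), integer(0), cc)
    gg <- structure(list(parent = g$parent, age = g$age, n_tips = 2L,
                         tip_pop = c("x", "x"), tip_label = c("s1", "s2"),
                         ploidy_c = cc), class = "coalabc_genealogy")
    x <- unclass(evolve_sequences(gg, m))
    sum(x[1, ] != x[2, ])
  })
  theta <- 2 * mu * L * cc * N
  expect_lt(abs(mean(diffs) - theta) / theta, 0.05)
})

test_that("constant-size mismatch distributions match the geometric equilibrium", {
  set.seed(56)
  theta <- 3
  pool <- integer(0)
  for (r in 1:4000) {
    mmd <- coalabc:::simulate_mismatch(2, theta, theta, 0)
    pool <- c(pool, rep(0:mmd$d_max, mmd$counts))
  }
  dm <- 25
  obs <- tabulate(pmin(pool, dm) + 1, dm + 1)
  f <- equilibrium_mismatch(theta, 200)
  fe <- c(f[1:dm], sum(f[(dm + 1):201]))
  p <- suppressWarnings(stats::chisq.test(obs, p = fe / sum(fe))$p.value)
  expect_gt(p, 0.01)
})

test_that("microsatellite heterozygosity increases monotonically with mutation rate", {
  tmpl <- scenario_template(islands = "a", lineages = "A",
                            lineage_time_params = "t5")
  sc <- enumerate_colonization_scenarios(tmpl)[[1]]
  p <- c(t1 = 1000, t5 = 5e5, N_A = 1e4, N1 = 1e4, N2 = 100, db = 5)
  set.seed(77)
  rates <- c(1e-6, 1e-5, 1e-4, 1e-3, 1e-2)
  het <- vapply(rates, function(r) {
    d <- structure(list(params = p, mt_model = mt_model(),
                        str_model = str_model(mean_rate = r, n_loci = 2)),
                   class = "coalabc_draw")
    mean(replicate(600, {
      gens <- lapply(1:2, function(i)
        simulate_genealogy(sc, d, c(a = 8), locus_kind = "nuclear"))
      x <- unclass(evolve_strs(gens, d$str_model))
      mean(apply(x, 2, function(al) {
        pf <- tabulate(match(al, unique(al))) / length(al)
        length(al) * (1 - sum(pf^2)) / (length(al) - 1)
      }))
    }))
  }, numeric(1))
  expect_identical(order(het), seq_along(rates))
})

test_that("dataset bundles honor the sampling design and are reproducible", {
  des <- sampling_design(mt_copies = c(a = 22, b = 29, c = 30, d = 16),
                         str_model = str_model(n_loci = 3))
  scens <- enumerate_colonization_scenarios(scenario_template())
  d <- default_truth_draw()
  b1 <- simulate_dataset(scens[[3]], d, des, seed = 99)
  expect_equal(nrow(b1$mt), 97)
  expect_equal(ncol(b1$mt), 565)
  expect_equal(nrow(b1$str), 2 * 97)
  expect_equal(ncol(b1$str), 3)
  # two identical gene copies per strain in duplicate_haploid mode
  expect_equal(unclass(b1$str)[seq(1, 193, 2), ],
               unclass(b1$str)[seq(2, 194, 2), ], ignore_attr = TRUE)
  b2 <- simulate_dataset(scens[[3]], d, des, seed = 99)
  expect_identical(b1$mt, b2$mt)
  expect_identical(b1$str, b2$str)

  des0 <- sampling_design(mt_copies = c(a = 5, b = 5),
                          str_copies = c(a = 0, b = 0))
  b0 <- simulate_dataset(scens[[1]], d, des0, seed = 1)
  expect_equal(nrow(b0$str), 0)
  expect_equal(nrow(b0$mt), 10)

  expect_error(simulate_genealogy(scens[[1]], d, c(U = 2)), "unsampled")
})

test_that("genealogies export to ape trees with branch lengths in generations", {
  set.seed(3)
  g <- simulate_genealogy(enumerate_colonization_scenarios(scenario_template())[[1]],
                          default_truth_draw(), c(a = 4, b = 4))
  tr <- as_phylo(g)
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 8)
  depths <- ape::node.depth.edgelength(tr)
  expect_equal(max(depths[1:8]) , max(g$age), tolerance = 1e-9)
  # tips all at the same depth (ultrametric), to floating-point accuracy
  expect_lt(diff(range(depths[1:8])), 1e-8 * max(depths))
  expect_match(ape::write.tree(tr), "^\\(.*;$")
})
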