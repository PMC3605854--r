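# Study-shaped synthetic datasets: four world lineages (A-D) plus four
# island populations (a-d) of 16-30 strains each (97 island strains), 565-bp
# mtDNA and 16 microsatellite loci, generated under a known colonization
# scenario so every pipeline stage is testable without any download.

#' Study-shaped sampling design
#'
#' Default per-population strain counts: islands a = 22, b = 29, c = 30,
#' d = 16 (97 in total) and world lineages A = 58, B = 29, C = 163, D = 33;
#' microsatellite gene copies are twice the strain counts; 565-bp mtDNA and
#' 16 microsatellite loci.
#'
#' @param island_copies,world_copies named strain counts.
#' @param ... passed to [sampling_design()] (mutation models, ploidy, mode).
#' @return a [sampling_design()].
#' @export
study_design <- function(island_copies = c(a = 22, b = 29, c = 30, d = 16),
                         world_copies = c(A = 58, B = 29, C = 163, D = 33),
                         ...) {
  sampling_design(mt_copies = c(world_copies, island_copies), ...)
}

#' Default generating truth for synthetic fixtures
#'
#' Colonization order c > a > b > d with colonization times spread over
#' 133,000-191,000 generations and lineage coalescences over
#' 391,000-691,000 generations, so fixtures resemble the inferred regime.
#'
#' @param priors a [default_priors()] supplying the mutation models.
#' @return a `coalabc_draw`.
#' @export
default_truth_draw <- function(priors = default_priors()) {
  p <- c(t1 = 133000, t2 = 155000, t3 = 178000, t4 = 191000,
         t5 = 391000, t6 = 465000, t7 = 650000, t8 = 691000,
         N_A = 100000, N1 = 100000, N2 = 100000, N3 = 100000, N4 = 100000,
         N5 = 100, N6 = 100, N7 = 100, N8 = 100, db = 5)
  structure(list(params = p, mt_model = priors$mt_model,
                 str_model = priors$str_model),
            class = "coalabc_draw")
}

#' Generate a study-shaped synthetic dataset
#'
#' Simulates a full bundle under a known scenario and parameter draw
#' (defaults: colonization order c > a > b > d with [default_truth_draw()]);
#' the truth is recorded in the bundle's provenance for recovery tests.
#'
#' @param design a [sampling_design()], default [study_design()].
#' @param scenario generating scenario; default is the c > a > b > d member
#'   of [enumerate_colonization_scenarios()].
#' @param draw generating `coalabc_draw`; default [default_truth_draw()].
#' @param seed integer seed (the bundle is reproducible from it).
#' @return a [dataset_bundle()] with `provenance$truth` filled in.
#' @export
generate_study_like_dataset <- function(design = study_design(),
                                        scenario = NULL, draw = NULL,
                                        seed = 1) {
  if (is.null(scenario)) {
    scens <- enumerate_colonization_scenarios(scenario_template())
    orders <- vapply(scens, function(s)
      paste(s$colonization_order, collapse = ""), character(1))
    scenario <- scens[[which(orders == "cabd")]]
  }
  if (is.null(draw)) draw <- default_truth_draw()
  if (!validate_constraints(draw, scenario))
    stop("generating draw violates the scenario's order constraints")
  bundle <- simulate_dataset(scenario, draw, design, seed = seed)
  bundle$provenance$truth <- list(scenario_id = scenario$scenario_id,
                                  colonization_order = scenario$colonization_order,
                                  params = as.list(draw$params))
  bundle
}

#' Write a dataset bundle to plain-text fixtures
#'
#' Emits a FASTA alignment (70-column wrap), a Genepop file (3-digit allele
#' coding, two gene copies per individual record), a tab-separated
#' population map, and a JSON truth file with explicit units, sufficient to
#' rerun any pipeline stage.
#'
#' @param bundle a [dataset_bundle()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_fixtures <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "mtdna.fasta"),
             genepop = file.path(dir, "str.genepop"),
             popmap = file.path(dir, "popmap.tsv"),
             truth = file.path(dir, "truth.json"))
  write_fasta(bundle$mt, paths["fasta"])
  if (nrow(bundle$str) > 0) {
    write_genepop(bundle$str, bundle$popmap, paths["genepop"])
  } else {
    warning("empty STR dataset: Genepop file omitted")
    paths <- paths[names(paths) != "genepop"]
  }
  write.table(bundle$popmap, paths["popmap"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- bundle$provenance$truth
  if (is.null(truth)) truth <- list()
  truth$units <- list(times = "generations", sizes = "individuals")
  truth$seed <- bundle$provenance$seed
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a fixture directory back into a bundle
#'
#' Inverse of [write_fixtures()]; the round trip restores the alignment,
#' microsatellite table and population map exactly.
#'
#' @param dir directory written by [write_fixtures()].
#' @return a [dataset_bundle()].
#' @export
read_bundle <- function(dir) {
  popmap <- read.table(file.path(dir, "popmap.tsv"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
  aln <- read_fasta(file.path(dir, "mtdna.fasta"))
  gp_path <- file.path(dir, "str.genepop")
  str <- if (file.exists(gp_path)) read_genepop(gp_path)$str
         else str_dataset(matrix(integer(0), 0, 0))
  prov <- list()
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path))
    prov$truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  dataset_bundle(aln, str, popmap, provenance = prov)
}

#' Scaled-down validation configuration for ABC experiments
#'
#' A deliberately identifiable ("well-separated") toy system used by the
#' self-consistency, confidence and coverage experiments: four maximally
#' distinct colonization orders (a>b>c>d, b>d>a>c, c>a>b>d, d>c>b>a) over
#' the full island structure, with each colonization rank drawn from its
#' own disjoint time window (t1 in U(1e3, 5e4), t2 in U(7e4, 1.5e5),
#' t3 in U(1.7e5, 2.5e5), t4 in U(2.7e5, 3.5e5) generations), large
#' present-day sizes U(1.5e5, 2.5e5) so island diversity is still
#' accumulating on the colonization timescale, severe founder bottlenecks
#' U(2, 4), and a 16-locus microsatellite panel (rate 2e-5) typed on 24
#' strains per island; summary statistics are the five per-island
#' microsatellite statistics.
#'
#' @return list with `scenarios`, `priors`, `design`, `config`.
#' @export
toy_validation_setup <- function() {
  scens_all <- enumerate_colonization_scenarios(scenario_template())
  orders <- vapply(scens_all, function(s)
    paste(s$colonization_order, collapse = ""), character(1))
  sm <- str_model(mean_rate = 2e-5, n_loci = 16)
  list(
    scenarios = scens_all[match(c("abcd", "bdac", "cabd", "dcba"), orders)],
    priors = default_priors(
      N_present = c(1.5e5, 2.5e5), N_A = c(1.5e5, 2.5e5),
      N_bottleneck = c(2, 4),
      overrides = list(t1 = c(1e3, 5e4), t2 = c(7e4, 1.5e5),
                       t3 = c(1.7e5, 2.5e5), t4 = c(2.7e5, 3.5e5)),
      str_model = sm),
    design = sampling_design(
      mt_copies = c(a = 4, b = 4, c = 4, d = 4),
      str_copies = c(a = 48, b = 48, c = 48, d = 48),
      str_model = sm),
    config = c("str_nall", "str_exphet", "str_gendiv", "str_range", "str_gw"))
}
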