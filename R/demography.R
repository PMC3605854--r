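# Demographic scenarios: an unsampled source population U, world lineages
# that coalesce into U at times t5..t8 (oldest first, forward in time
# U > D/A > C > B), and island populations founded from their paired lineage
# at order-constrained colonization times t4 > t3 > t2 > t1, each with a
# founder bottleneck (size N5..N8, duration db).

#' Scenario template for island-colonization histories
#'
#' Fixes the lineage-diversification structure shared by every colonization
#' order: each world lineage coalesces into the unsampled source `U` at its
#' own time parameter, and each island population pairs one-to-one with a
#' world lineage. Colonization-order permutations are filled in by
#' [enumerate_colonization_scenarios()].
#'
#' The default reproduces the four-lineage system: lineages A--D merging into
#' U at t7, t5, t6, t8 (so the oldest events are the D and A coalescences),
#' constraint chain `t8 > t6`, `t7 > t6`, `t6 > (oldest colonization)`,
#' `t5 > (oldest colonization)`, leaving the relative order of t8 vs t7 and
#' of t6 vs t5 free.
#'
#' @param islands island population labels, youngest tier (default a--d).
#' @param lineages paired world-lineage labels (default A--D).
#' @param lineage_time_params time parameter of each lineage's coalescence
#'   into U, same order as `lineages`.
#' @param lineage_constraints data.frame(older, younger) of order constraints
#'   among lineage time parameters.
#' @param lineage_floor lineage time parameters required to exceed the oldest
#'   colonization time.
#' @return object of class `coalabc_template`.
#' @export
scenario_template <- function(islands = c("a", "b", "c", "d"),
                              lineages = c("A", "B", "C", "D"),
                              lineage_time_params = c("t7", "t5", "t6", "t8"),
                              lineage_constraints = data.frame(
                                older = c("t8", "t7"), younger = c("t6", "t6"),
                                stringsAsFactors = FALSE),
                              lineage_floor = c("t6", "t5")) {
  k <- length(islands)
  if (k < 1 || length(lineages) != k)
    stop("islands must pair one-to-one with lineages")
  if (length(lineage_time_params) != k)
    stop("one lineage coalescence time parameter per lineage required")
  if (k == 1) { lineage_constraints <- lineage_constraints[0, ]; }
  keep <- lineage_constraints$older %in% lineage_time_params &
    lineage_constraints$younger %in% lineage_time_params
  lineage_constraints <- lineage_constraints[keep, , drop = FALSE]
  lineage_floor <- intersect(lineage_floor, lineage_time_params)
  if (length(lineage_floor) == 0) lineage_floor <- lineage_time_params
  structure(list(islands = islands, lineages = lineages,
                 lineage_time_params = lineage_time_params,
                 lineage_constraints = lineage_constraints,
                 lineage_floor = lineage_floor,
                 coloniz_time_params = paste0("t", seq_len(k)),
                 bottleneck_size_params = paste0("N", k + seq_len(k)),
                 lineage_size_params = paste0("N", seq_len(k))),
            class = "coalabc_template")
}

build_scenario <- function(template, perm, scenario_id) {
  k <- length(template$islands)
  # earliest colonizer takes the oldest colonization parameter (t_k), the
  # latest takes t1
  col_params <- rev(template$coloniz_time_params)  # t_k .. t1
  pops <- data.frame(
    label = c("U", template$lineages, template$islands),
    role = c("unsampled_source", rep("world_lineage", k),
             rep("island_population", k)),
    lineage = c(NA, rep(NA, k), template$lineages),
    size_param = c("N_A", template$lineage_size_params,
                   template$lineage_size_params),
    stringsAsFactors = FALSE)
  lev <- data.frame(time_param = template$lineage_time_params,
                    child = template$lineages, parent = "U",
                    bottleneck_size = NA_character_,
                    bottleneck_duration = NA_character_,
                    stringsAsFactors = FALSE)
  idx <- match(perm, template$islands)
  cev <- data.frame(time_param = col_params,
                    child = perm,
                    parent = template$lineages[idx],
                    bottleneck_size = template$bottleneck_size_params[idx],
                    bottleneck_duration = "db",
                    stringsAsFactors = FALSE)
  # events oldest -> youngest: lineage events (t8..t5 by parameter index
  # descending), then colonizations t_k..t1
  lev <- lev[order(-as.integer(sub("t", "", lev$time_param))), ]
  constraints <- rbind(
    template$lineage_constraints,
    data.frame(older = template$lineage_floor,
               younger = col_params[1], stringsAsFactors = FALSE),
    if (k > 1) data.frame(older = col_params[-k], younger = col_params[-1],
                          stringsAsFactors = FALSE))
  structure(list(scenario_id = as.integer(scenario_id),
                 populations = pops,
                 events = rbind(lev, cev),
                 colonization_order = perm,
                 constraints = constraints),
            class = "coalabc_scenario")
}

#' @export
print.coalabc_scenario <- function(x, ...) {
  cat("<coalabc_scenario> id ", x$scenario_id, ": colonization order ",
      paste(x$colonization_order, collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' Enumerate all colonization-order scenarios
#'
#' Produces one scenario per permutation of the island populations, with the
#' earliest colonizer assigned the oldest colonization time parameter and the
#' latest the youngest. Scenario ids are the lexicographic rank of the
#' permutation, so they are stable across runs.
#'
#' @param template a [scenario_template()].
#' @return list of `coalabc_scenario`, length `factorial(n_islands)`.
#' @export
enumerate_colonization_scenarios <- function(template) {
  if (!inherits(template, "coalabc_template"))
    stop("template must be built by scenario_template()")
  isl <- sort(template$islands)
  perms <- permutations_lex(isl)
  lapply(seq_along(perms), function(i) build_scenario(template, perms[[i]], i))
}

# all permutations of x in lexicographic order
permutations_lex <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    rest <- permutations_lex(x[-i])
    out <- c(out, lapply(rest, function(r) c(x[i], r)))
  }
  out
}

#' Uniform priors for scenario parameters
#'
#' Times are in generations, sizes in individuals. Defaults follow the
#' inferred regime of the motivating island system: colonization times U(1e3, 2.5e5), lineage coalescence times
#' U(1e4, 1e6); present-day and ancestral sizes U(100, 1e5); founder
#' bottleneck sizes U(2, 1e3); bottleneck duration fixed at 5 generations
#' (pass a two-element range, e.g. `db = c(1, 100)`, to draw it).
#'
#' @param t_colonize,t_coalesce,N_present,N_bottleneck,db,N_A ranges
#'   `c(min, max)`; a single value or `c(x, x)` fixes the parameter.
#' @param overrides named list of per-parameter ranges applied last, e.g.
#'   `list(t1 = c(1e3, 5e4))` to give individual time parameters their own
#'   (possibly disjoint) windows.
#' @param mt_model,str_model mutation models attached to every draw.
#' @return object of class `coalabc_priors`: list of `c(min, max)` ranges
#'   keyed by parameter name, plus the mutation models.
#' @export
default_priors <- function(t_colonize = c(1e3, 2.5e5),
                           t_coalesce = c(1e4, 1e6),
                           N_present = c(100, 1e5),
                           N_A = c(100, 1e5),
                           N_bottleneck = c(2, 1e3),
                           db = 5,
                           overrides = list(),
                           mt_model = coalabc::mt_model(),
                           str_model = coalabc::str_model()) {
  rng <- function(x) if (length(x) == 1) c(x, x) else x
  b <- list()
  for (p in paste0("t", 1:4)) b[[p]] <- rng(t_colonize)
  for (p in paste0("t", 5:8)) b[[p]] <- rng(t_coalesce)
  b[["N_A"]] <- rng(N_A)
  for (p in paste0("N", 1:4)) b[[p]] <- rng(N_present)
  for (p in paste0("N", 5:8)) b[[p]] <- rng(N_bottleneck)
  b[["db"]] <- rng(db)
  for (p in names(overrides)) b[[p]] <- rng(overrides[[p]])
  bad <- vapply(b, function(r) r[1] > r[2] || r[1] <= 0, logical(1))
  if (any(bad)) stop("prior bounds must satisfy 0 < min <= max: ",
                     paste(names(b)[bad], collapse = ", "))
  structure(list(bounds = b, mt_model = mt_model, str_model = str_model),
            class = "coalabc_priors")
}

scenario_params <- function(scenario) {
  unique(c(scenario$events$time_param,
           stats::na.omit(c(scenario$populations$size_param,
                            scenario$events$bottleneck_size,
                            scenario$events$bottleneck_duration))))
}

#' Draw scenario parameters from their priors
#'
#' Rejection sampling: all parameters are drawn independently from their
#' uniform priors and the draw is kept only if every order constraint holds,
#' which leaves each accepted marginal uniform on the constraint polytope.
#'
#' @param scenario a `coalabc_scenario`.
#' @param priors a [default_priors()] object covering every parameter the
#'   scenario names.
#' @param n number of accepted draws.
#' @param max_tries rejection cap per requested draw; exceeded caps raise a
#'   configuration error (misordered or disjoint bounds fail fast).
#' @return for `n = 1` a `coalabc_draw` (named parameter list plus mutation
#'   models); otherwise a list of them.
#' @export
draw_parameters <- function(scenario, priors, n = 1, max_tries = 10000) {
  pars <- scenario_params(scenario)
  missing <- setdiff(pars, names(priors$bounds))
  if (length(missing) > 0)
    stop("priors missing parameters: ", paste(missing, collapse = ", "))
  lo <- vapply(priors$bounds[pars], `[`, numeric(1), 1)
  hi <- vapply(priors$bounds[pars], `[`, numeric(1), 2)
  older <- match(scenario$constraints$older, pars)
  younger <- match(scenario$constraints$younger, pars)

  accepted <- matrix(NA_real_, nrow = 0, ncol = length(pars))
  tries <- 0
  block <- max(64, 4 * n)
  while (nrow(accepted) < n) {
    if (tries >= max_tries * n)
      stop("constraint rejection cap exceeded: priors likely incompatible ",
           "with the scenario's order constraints")
    m <- matrix(runif(block * length(pars), rep(lo, each = block),
                      rep(hi, each = block)), nrow = block)
    ok <- rep(TRUE, block)
    for (j in seq_along(older))
      ok <- ok & (m[, older[j]] > m[, younger[j]])
    accepted <- rbind(accepted, m[ok, , drop = FALSE])
    tries <- tries + block
  }
  accepted <- accepted[seq_len(n), , drop = FALSE]
  colnames(accepted) <- pars
  draws <- lapply(seq_len(n), function(i) {
    structure(list(params = accepted[i, ],
                   mt_model = priors$mt_model, str_model = priors$str_model),
              class = "coalabc_draw")
  })
  if (n == 1) draws[[1]] else draws
}

#' Check a parameter draw against a scenario's order constraints
#'
#' Pure predicate: `TRUE` iff every (older, younger) pair satisfies
#' older > younger and every colonization time is younger than every lineage
#' coalescence time.
#'
#' @param draw a `coalabc_draw` or named numeric vector of parameters.
#' @param scenario a `coalabc_scenario`.
#' @return logical scalar.
#' @export
validate_constraints <- function(draw, scenario) {
  p <- if (inherits(draw, "coalabc_draw")) draw$params else draw
  con <- scenario$constraints
  if (nrow(con) > 0 && !all(p[con$older] > p[con$younger])) return(FALSE)
  ev <- scenario$events
  tcol <- p[ev$time_param[!is.na(ev$bottleneck_size)]]
  tlin <- p[ev$time_param[is.na(ev$bottleneck_size)]]
  if (length(tcol) > 0 && length(tlin) > 0 && max(tcol) >= min(tlin))
    return(FALSE)
  TRUE
}

#' Write / read scenarios and priors as YAML
#'
#' Round-trip is lossless: numeric parameter bounds, event tables, and
#' constraint chains are restored exactly.
#'
#' @param scenario,priors objects to serialize.
#' @param file path to a YAML file.
#' @return `read_scenario_yaml()` / `read_priors_yaml()` return the restored
#'   object.
#' @export
write_scenario_yaml <- function(scenario, file) {
  obj <- list(scenario_id = scenario$scenario_id,
              colonization_order = as.list(scenario$colonization_order),
              populations = lapply(seq_len(nrow(scenario$populations)),
                                   function(i) as.list(scenario$populations[i, ])),
              events = lapply(seq_len(nrow(scenario$events)),
                              function(i) as.list(scenario$events[i, ])),
              constraints = lapply(seq_len(nrow(scenario$constraints)),
                                   function(i) as.list(scenario$constraints[i, ])))
  yaml::write_yaml(obj, file, precision = 15)
  invisible(file)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(file) {
  obj <- yaml::read_yaml(file)
  bindrows <- function(l) do.call(rbind, lapply(l, function(r)
    as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                  stringsAsFactors = FALSE)))
  structure(list(scenario_id = as.integer(obj$scenario_id),
                 populations = bindrows(obj$populations),
                 events = bindrows(obj$events),
                 colonization_order = unlist(obj$colonization_order),
                 constraints = bindrows(obj$constraints)),
            class = "coalabc_scenario")
}

#' @rdname write_scenario_yaml
#' @export
write_priors_yaml <- function(priors, file) {
  obj <- list(bounds = lapply(priors$bounds, as.list),
              mt_model = unclass(priors$mt_model),
              str_model = unclass(priors$str_model))
  yaml::write_yaml(obj, file, precision = 15)
  invisible(file)
}

#' @rdname write_scenario_yaml
#' @export
read_priors_yaml <- function(file) {
  obj <- yaml::read_yaml(file)
  mt <- do.call(mt_model, obj$mt_model[setdiff(names(obj$mt_model), NULL)])
  st <- do.call(str_model, obj$str_model)
  structure(list(bounds = lapply(obj$bounds, unlist),
                 mt_model = mt, str_model = st),
            class = "coalabc_priors")
}
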