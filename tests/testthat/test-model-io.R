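# Model containers, file dialects, and model-editing operations.

test_that("models round-trip through both dialects with identical math", {
  for (toy in list(toy_growth_cost(), toy_with_product())) {
    model <- toy$model
    for (dialect in c("bigg-json", "sbml")) {
      f <- tempfile(fileext = if (dialect == "sbml") ".xml" else ".json")
      write_gem(model, f, dialect)
      back <- read_gem(f)
      expect_equal(as.matrix(back$S), as.matrix(model$S))
      expect_equal(back$lb, model$lb)
      expect_equal(back$ub, model$ub)
      expect_identical(back$exchange, model$exchange)
      expect_identical(back$sinks, model$sinks)
      expect_identical(back$biomass, model$biomass)
      expect_identical(model_checksum(back), model_checksum(model))
      unlink(f)
    }
  }
})

test_that("boundary structure drives exchange classification", {
  toy <- toy_with_product()
  nnz <- Matrix::colSums(toy$model$S != 0)
  # every single-entry non-sink column is classified exchange
  singles <- setdiff(which(nnz == 1), toy$model$sinks)
  expect_setequal(toy$model$exchange, singles)
  # partition invariant: internal + exchange + sinks = all reactions
  expect_equal(length(internal_reactions(toy$model)) +
                 length(toy$model$exchange) + length(toy$model$sinks),
               length(toy$model$reactions))
})

test_that("reader errors are explicit", {
  bad <- tempfile(fileext = ".json")
  writeLines("{not valid json", bad)
  expect_error(read_gem(bad), "parse")
  # model with no biomass-like reaction and no objective marker
  noname <- tempfile(fileext = ".json")
  jsonlite::write_json(list(id = "x",
    metabolites = list(list(id = "A", compartment = "c")),
    reactions = list(list(id = "R1", metabolites = list(A = -1),
                          lower_bound = -10, upper_bound = 10),
                     list(id = "R2", metabolites = list(A = 1),
                          lower_bound = 0, upper_bound = 10))),
    noname, auto_unbox = TRUE)
  expect_error(read_gem(noname), "biomass")
  # naming it explicitly fixes the read
  expect_s3_class(read_gem(noname, biomass = "R2"), "metabolic_model")
  expect_error(read_gem(tempfile(fileext = ".json")), "not found")
})

test_that("add_production_reaction appends one column and preserves the rest", {
  toy <- toy_growth_cost()
  recipe <- reaction_recipe(
    "SURFACTIN_SYNTH",
    c(N1 = -1, N2 = -4, surfactin = 1, h2o = 7),
    lower_bound = 0, upper_bound = 1000)
  expect_warning(
    ext <- add_production_reaction(toy$model, recipe, create_missing = TRUE),
    "formulas unavailable")
  expect_equal(length(ext$reactions), length(toy$model$reactions) + 1)
  expect_identical(ext$production, "SURFACTIN_SYNTH")
  # pre-existing columns bit-identical
  old <- as.matrix(toy$model$S)
  expect_identical(as.matrix(ext$S)[rownames(old), colnames(old)], old)
  # duplicate id and unknown metabolite without the create flag are rejected
  expect_error(suppressWarnings(add_production_reaction(ext, recipe, TRUE)),
               "already")
  expect_error(add_production_reaction(toy$model, recipe), "unknown metabolite")
  expect_error(reaction_recipe("r", numeric(0)), "non-empty")
  # add then remove restores the original matrix exactly
  restored <- remove_reaction(ext, "SURFACTIN_SYNTH")
  expect_identical(as.matrix(restored$S), old)
  expect_identical(model_checksum(restored), model_checksum(toy$model))
})

test_that("mass balance is reported when formulas are available", {
  toy <- toy_growth_cost()
  m <- toy$model
  m$formulas <- c(N1 = "C6H12O6", N2 = "NH3", X = "C6H12O6")
  # balanced: isomerization N1 -> X
  m2 <- m
  expect_message(
    add_production_reaction(m2, reaction_recipe("ISO", c(N1 = -1, X = 1)),
                            create_missing = TRUE),
    "balanced")
  expect_message(
    add_production_reaction(m, reaction_recipe("LEAK", c(N1 = -1)),
                            create_missing = TRUE),
    "imbalance")
})

test_that("sinks enforce a production floor and stay out of the medium", {
  toy <- toy_with_product()
  base <- apply_medium(toy$model, c(EX_N1 = 4, EX_N2 = 4))
  model <- remove_reaction(base, "SK_PROD")
  withsink <- add_sink(model, "PROD", lower_bound = 1e-4)
  expect_error(add_sink(withsink, "PROD"), "already present")
  expect_false(which(withsink$reactions == "SK_PROD") %in% withsink$exchange)
  sol <- solve_fba(withsink)
  expect_identical(sol$status, "optimal")
  expect_gte(sol$v_star[["SK_PROD"]], 1e-4 - 1e-12)
  # zero lower bound is a pure relaxation: same optimum as the original
  relaxed <- add_sink(model, "PROD", lower_bound = 0)
  expect_equal(solve_fba(relaxed)$objective_value,
               solve_fba(model)$objective_value, tolerance = 1e-9)
  # a sink on an unproducible metabolite with a positive floor is infeasible
  dead <- add_sink(
    suppressWarnings(add_production_reaction(
      model, reaction_recipe("NOOP", c(ORPHAN = 1, N1 = -1), 0, 0),
      create_missing = TRUE)),
    "ORPHAN", lower_bound = 0.1)
  expect_identical(solve_fba(dead)$status, "infeasible")
})

test_that("run artifacts are internally consistent and round-trip", {
  toy <- toy_growth_cost(box = c(1, 1))
  cfg <- optimization_config(n_init = 6, n_iter = 1, batch_size = 2, seed = 5,
                             raw_samples = 16, acquisition_restarts = 2)
  ds <- quiet_run_mobo(toy$model, toy$medium, toy$prices,
                       objectives = c("growth", "cost"), config = cfg)
  fr <- pareto_front(ds)
  out <- tempfile()
  write_samples(ds, fr, out, config = cfg, model = toy$model)
  expect_error(write_samples(ds, fr, out), "force")
  arts <- read_samples(out)
  expect_equal(nrow(arts$samples), n_samples(ds))
  expect_identical(which(arts$samples$pareto),
                   as.integer(fr$member_indices))
  expect_equal(nrow(arts$front), length(fr$member_indices))
  expect_identical(arts$manifest$model_checksum, model_checksum(toy$model))
  # numerically identical after the CSV round trip (exact, not approximate)
  back <- fluxmedia:::dataset_from_artifacts(arts, toy$medium)
  expect_identical(back$X_raw, ds$X_raw)
  expect_identical(back$Y_raw$growth, ds$Y_raw$growth)
  expect_identical(back$Y_raw$cost, ds$Y_raw$cost)
  # a singleton dataset still yields a one-row front table
  ds1 <- fluxmedia:::new_sample_dataset(
    ds$X_raw[1, , drop = FALSE], ds$Y_raw[1, , drop = FALSE], 0L,
    toy$medium, c("growth", "cost"))
  out1 <- tempfile()
  # a single sample degenerates the cost column (documented 0.5 mapping)
  suppressWarnings(write_samples(ds1, NULL, out1))
  expect_equal(nrow(read_samples(out1)$front), 1)
  unlink(c(out, out1), recursive = TRUE)
})
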