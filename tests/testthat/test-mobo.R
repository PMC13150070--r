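# Outer loop: scalarization, initialization, batch acquisition, budget
# accounting, determinism, and Pareto-seeded restarts.

test_that("augmented Chebyshev scalarization follows its formula", {
  # symmetric point: min_j w_j y_j + rho * sum_j w_j y_j
  expect_equal(chebyshev_scalarize(c(1, 1, 1), rep(1 / 3, 3), rho = 0.05),
               1 / 3 + 0.05, tolerance = 1e-12)
  # rho = 0 reduces to the plain weighted Chebyshev term
  expect_equal(chebyshev_scalarize(c(0.2, 0.9), c(0.7, 0.3), rho = 0),
               min(0.7 * 0.2, 0.3 * 0.9), tolerance = 1e-12)
  expect_error(chebyshev_scalarize(c(1, 1), c(0, 0)), "zero")
  expect_error(chebyshev_scalarize(c(1, 1), c(-1, 2)), "nonnegative")
  # random triples against an independent re-evaluation
  set.seed(9)
  for (k in 1:50) {
    d <- sample(2:4, 1)
    y <- runif(d)
    w <- runif(d); w <- w / sum(w)
    rho <- runif(1, 0, 0.2)
    direct <- min(w * y) + rho * sum(w * y)
    expect_equal(chebyshev_scalarize(y, w, rho), direct, tolerance = 1e-12)
  }
  # matrix input scalarizes row-wise
  Y <- matrix(runif(6), 3, 2)
  w <- c(0.4, 0.6)
  expect_equal(chebyshev_scalarize(Y, w, 0.1),
               apply(Y, 1, chebyshev_scalarize, weights = w, rho = 0.1),
               tolerance = 1e-12)
})

test_that("random initialization is reproducible, boxed, and constrained", {
  toy <- toy_growth_cost()
  X1 <- init_random_media(toy$medium, 50, seed = 42)
  X2 <- init_random_media(toy$medium, 50, seed = 42)
  expect_identical(X1, X2)
  expect_equal(dim(X1), c(50, 2))
  expect_true(all(X1 >= 0))
  expect_true(all(sweep(X1, 2, c(10, 10), "<=")))
  # an equality constraint u1 = 2 u2 is satisfied to 1e-9 after projection
  cons <- list(linear_constraint(c(EX_N1 = 1, EX_N2 = -2), 0, "equality"))
  Xc <- init_random_media(toy$medium, 30, constraints = cons, seed = 7)
  expect_lt(max(abs(Xc[, 1] - 2 * Xc[, 2])), 1e-9 * 10)
  # an empty feasible region errors out after bounded attempts
  impossible <- list(linear_constraint(c(EX_N1 = 1), -5, "inequality-le"))
  expect_error(init_random_media(toy$medium, 5, constraints = impossible,
                                 seed = 1), "empty")
})

test_that("proposed batches have the right size and satisfy constraints", {
  toy <- toy_growth_cost(box = c(1, 1))
  cfg <- optimization_config(n_init = 8, n_iter = 1, batch_size = 4, seed = 4,
                             raw_samples = 16, acquisition_restarts = 2)
  ds <- quiet_run_mobo(toy$model, toy$medium, toy$prices,
                       objectives = c("growth", "cost"), config = cfg)
  sur <- fit_surrogate(ds)
  X <- propose_batch(sur, ds, cfg, iteration = 2L)
  expect_equal(nrow(X), 4)
  expect_true(all(X >= 0 & X <= 1))
  # constraint forcing the first component to zero
  cfg0 <- optimization_config(n_init = 8, n_iter = 1, batch_size = 3, seed = 4,
                              raw_samples = 16, acquisition_restarts = 2,
                              constraints = list(
                                linear_constraint(c(EX_N1 = 1), 0, "equality")))
  X0 <- propose_batch(sur, ds, cfg0, iteration = 2L)
  expect_lt(max(X0[, "EX_N1"]), 1e-6)
})

test_that("the loop honors its budget and is seed-deterministic", {
  toy <- toy_growth_cost(box = c(1, 1))
  cfg <- optimization_config(n_init = 6, n_iter = 3, batch_size = 2, seed = 11,
                             raw_samples = 16, acquisition_restarts = 2)
  ds <- quiet_run_mobo(toy$model, toy$medium, toy$prices,
                       objectives = c("growth", "cost"), config = cfg)
  expect_equal(n_samples(ds), 6 + 3 * 2)
  expect_equal(sort(unique(ds$iteration)), 0:3)
  expect_equal(sum(ds$iteration == 0), 6)
  expect_true(all(table(ds$iteration[ds$iteration > 0]) == 2))
  ds2 <- quiet_run_mobo(toy$model, toy$medium, toy$prices,
                        objectives = c("growth", "cost"), config = cfg)
  expect_identical(ds$X_raw, ds2$X_raw)
  expect_identical(ds$Y_raw, ds2$Y_raw)
  # hypervolume of the accumulated front never decreases with iteration
  cmax <- max(ds$Y_raw$cost) + 1
  hv <- vapply(0:3, function(it) {
    sub <- ds$Y_raw[ds$iteration <= it, ]
    dominated_hypervolume(orient_growth_cost(sub, cmax))
  }, numeric(1))
  expect_true(all(diff(hv) >= -1e-12))
})

test_that("a single interior optimum is located by the acquisition loop", {
  # bypass FBA: 1 active decision variable, synthetic smooth objective with
  # its maximum at x = 0.6; oracle optimum known exactly
  comp <- data.frame(component = c("a", "b"),
                     reaction_id = c("EX_a", "EX_b"),
                     role = c("decision", "fixed"),
                     baseline_value = c(0.5, 1), box_upper = c(1, 1),
                     unit = "flux")
  spec <- medium_spec(comp)
  f <- function(x) exp(-30 * (x - 0.6)^2)
  set.seed(5)
  X <- matrix(runif(5), ncol = 1, dimnames = list(NULL, "EX_a"))
  Y <- data.frame(growth = f(X[, 1]), cost = X[, 1],
                  production = NA_real_, feasible = TRUE, status = "optimal")
  ds <- fluxmedia:::new_sample_dataset(X, Y, rep(0L, 5), spec,
                                       c("growth", "cost"))
  cfg <- optimization_config(n_init = 5, n_iter = 10, batch_size = 1, seed = 8,
                             raw_samples = 24, acquisition_restarts = 2)
  for (it in 1:10) {
    sur <- suppressWarnings(fit_surrogate(ds))
    xq <- suppressWarnings(propose_batch(sur, ds, cfg, iteration = it))
    xr <- xq * 1  # unit box == physical box here
    colnames(xr) <- "EX_a"
    yr <- data.frame(growth = f(xr[, 1]), cost = xr[, 1],
                     production = NA_real_, feasible = TRUE,
                     status = "optimal")
    ds <- fluxmedia:::append_samples(ds, xr, yr, it)
  }
  best <- ds$X_raw[which.max(ds$Y_raw$growth), 1]
  expect_lt(abs(best - 0.6), 0.05)
})

test_that("restarts carry the whole front and pad with fresh media", {
  toy <- toy_growth_cost(box = c(1, 1))
  cfg <- optimization_config(n_init = 6, n_iter = 2, batch_size = 3, seed = 31,
                             raw_samples = 16, acquisition_restarts = 2)
  ds <- quiet_run_mobo(toy$model, toy$medium, toy$prices,
                       objectives = c("growth", "cost"), config = cfg)
  front_n <- sum(pareto_mask(dataset_oriented(ds)))
  init <- restart_from_pareto(ds, cfg)
  expect_s3_class(init, "mobo_init")
  expect_equal(init$n_carried, front_n)
  expect_equal(nrow(init$X), max(cfg$n_init, front_n))
  # carried compositions are exactly the front members
  fr <- pareto_front(ds)
  expect_identical(init$X[seq_len(front_n), , drop = FALSE], fr$X_members)
  # when the front exceeds n_init, nothing is dropped
  cfg_small <- optimization_config(n_init = 2, n_iter = 1, batch_size = 2,
                                   seed = 31)
  init2 <- restart_from_pareto(ds, cfg_small)
  expect_equal(nrow(init2$X), max(2, front_n))
  # chained runs only improve the accumulated front
  ds2 <- quiet_run_mobo(toy$model, toy$medium, toy$prices,
                        objectives = c("growth", "cost"), config = cfg,
                        init = init)
  cmax <- max(ds$Y_raw$cost, ds2$Y_raw$cost) + 1
  expect_gte(dominated_hypervolume(orient_growth_cost(ds2$Y_raw, cmax)),
             dominated_hypervolume(orient_growth_cost(
               ds$Y_raw[ds$Y_raw$feasible, ], cmax)) - 1e-9)
})

test_that("objective and pricing preconditions are enforced", {
  toy <- toy_growth_cost()
  cfg <- optimization_config(n_init = 2, n_iter = 1, batch_size = 1)
  expect_error(run_mobo(toy$model, toy$medium, toy$prices,
                        objectives = c("growth"), config = cfg),
               "2 or 3")
  expect_error(run_mobo(toy$model, toy$medium, toy$prices,
                        objectives = c("growth", "production"), config = cfg),
               "production")
  noprice <- price_table(c(EX_N1 = 1))
  expect_error(run_mobo(toy$model, toy$medium, noprice,
                        objectives = c("growth", "cost"), config = cfg),
               "EX_N2")
})
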