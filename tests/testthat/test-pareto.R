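# Pareto extraction and downstream analyses.

test_that("pareto_mask matches hand checks and keeps duplicates", {
  expect_identical(pareto_mask(matrix(c(1, 2), 1)), TRUE)
  Y <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5), c(0.4, 0.4))
  expect_identical(pareto_mask(Y), c(TRUE, TRUE, TRUE, FALSE))
  # duplicated optimal rows are all retained
  Yd <- rbind(c(1, 1), c(1, 1), c(0, 0))
  expect_identical(pareto_mask(Yd), c(TRUE, TRUE, FALSE))
  expect_error(pareto_mask(matrix(numeric(0), 0, 2)), "empty")
})

test_that("pareto_mask agrees with the pairwise oracle on random data", {
  set.seed(13)
  for (k in 1:20) {
    n <- sample(c(10, 50, 200), 1)
    d <- sample(2:3, 1)
    Y <- matrix(round(runif(n * d), sample(c(1, 6), 1)), n, d)
    expect_identical(pareto_mask(Y), oracle_pareto_mask(Y))
  }
})

test_that("masks are invariant to positive objective rescaling", {
  set.seed(14)
  Y <- matrix(runif(90), 30, 3)
  m0 <- pareto_mask(Y)
  Y2 <- Y
  Y2[, 2] <- Y[, 2] * 57.3
  expect_identical(pareto_mask(Y2), m0)
})

test_that("pareto_front satisfies both defining invariants", {
  toy <- toy_growth_cost(box = c(1, 1))
  cfg <- optimization_config(n_init = 10, n_iter = 1, batch_size = 3,
                             seed = 17, raw_samples = 16,
                             acquisition_restarts = 2)
  ds <- quiet_run_mobo(toy$model, toy$medium, toy$prices,
                       objectives = c("growth", "cost"), config = cfg)
  fr <- pareto_front(ds)
  Y <- dataset_oriented(ds)
  members <- fr$member_indices
  # mutual non-domination among members
  expect_true(all(oracle_pareto_mask(Y[members, , drop = FALSE])))
  # every non-member is dominated by at least one member
  for (i in setdiff(seq_len(nrow(Y)), members)) {
    dominated <- any(apply(Y[members, , drop = FALSE], 1, function(a) {
      all(a >= Y[i, ]) && any(a > Y[i, ])
    }))
    expect_true(dominated)
  }
})

test_that("best-ratio traces are running maxima", {
  toy <- toy_growth_cost(box = c(1, 1))
  Y <- data.frame(growth = c(1, 3, 2), production = NA, cost = c(1, 1, 1),
                  feasible = TRUE, status = "optimal")
  X <- matrix(runif(6), 3, 2, dimnames = list(NULL, c("EX_N1", "EX_N2")))
  ds <- fluxmedia:::new_sample_dataset(X, Y, rep(0L, 3), toy$medium,
                                       c("growth", "cost"))
  tr <- best_ratio_trace(ds, "growth", "cost")
  expect_equal(tr$ratio, c(1, 3, 2))
  expect_equal(tr$best_so_far, c(1, 3, 3))
  # monotone input: trace equals input
  Y2 <- Y; Y2$growth <- c(1, 2, 3)
  ds2 <- fluxmedia:::new_sample_dataset(X, Y2, rep(0L, 3), toy$medium,
                                        c("growth", "cost"))
  expect_equal(best_ratio_trace(ds2)$best_so_far, c(1, 2, 3))
  # random data against a loop oracle
  set.seed(15)
  n <- 100
  Yr <- data.frame(growth = runif(n), production = NA,
                   cost = runif(n, 0.5, 2), feasible = TRUE,
                   status = "optimal")
  Xr <- matrix(runif(2 * n), n, 2, dimnames = list(NULL, c("EX_N1", "EX_N2")))
  dsr <- fluxmedia:::new_sample_dataset(Xr, Yr, rep(0L, n), toy$medium,
                                        c("growth", "cost"))
  trr <- best_ratio_trace(dsr)
  oracle <- numeric(n)
  best <- -Inf
  for (i in 1:n) {
    best <- max(best, Yr$growth[i] / Yr$cost[i])
    oracle[i] <- best
  }
  expect_equal(trr$best_so_far, oracle, tolerance = 1e-12)
  # zero-denominator handling
  Yz <- Yr; Yz$cost <- 0
  dsz <- fluxmedia:::new_sample_dataset(Xr, Yz, rep(0L, n), toy$medium,
                                        c("growth", "cost"))
  expect_error(best_ratio_trace(dsz), "zero")
})

test_that("low-growth filtering is a non-destructive view", {
  toy <- toy_growth_cost(box = c(1, 1))
  Y <- data.frame(growth = c(0.0005, 0.5), production = NA, cost = c(1, 2),
                  feasible = TRUE, status = "optimal")
  X <- matrix(runif(4), 2, 2, dimnames = list(NULL, c("EX_N1", "EX_N2")))
  ds <- fluxmedia:::new_sample_dataset(X, Y, c(0L, 0L), toy$medium,
                                       c("growth", "cost"))
  flt <- filter_low_growth(ds, 0.001)
  expect_equal(n_samples(flt), 1)
  expect_equal(n_samples(ds), 2)           # original untouched
  expect_identical(filter_low_growth(ds, 0)$Y_raw, ds$Y_raw)  # identity view
  # front members above threshold agree whether filtering happens before or
  # after the mask
  set.seed(16)
  n <- 60
  Yr <- data.frame(growth = round(runif(n, 0, 0.01), 4), production = NA,
                   cost = runif(n), feasible = TRUE, status = "optimal")
  Xr <- matrix(runif(2 * n), n, 2, dimnames = list(NULL, c("EX_N1", "EX_N2")))
  dsr <- fluxmedia:::new_sample_dataset(Xr, Yr, rep(0L, n), toy$medium,
                                        c("growth", "cost"))
  thr <- 0.005
  keep <- Yr$growth >= thr
  mask_then_filter <- which(pareto_mask(dataset_oriented(dsr)) & keep)
  filtered <- filter_low_growth(dsr, thr)
  filter_then_mask <- which(keep)[pareto_mask(dataset_oriented(filtered))]
  # filtering first can only promote additional points; every surviving
  # member of the unfiltered front must be retained
  expect_true(all(mask_then_filter %in% filter_then_mask))
})

test_that("composition PCA matches an SVD oracle and its invariances", {
  set.seed(18)
  X <- matrix(runif(50 * 13), 50, 13)
  colnames(X) <- paste0("c", 1:13)
  p <- pca_media(X)
  expect_equal(sum(p$explained), 1, tolerance = 1e-12)
  # oracle: explained-variance fractions from the SVD of the scaled matrix
  Z <- scale(X, center = TRUE, scale = TRUE)
  sv <- svd(Z)$d
  expect_equal(p$explained, sv^2 / sum(sv^2), tolerance = 1e-10)
  # rank-1 data: first component explains everything
  t_ <- runif(30)
  X1 <- cbind(a = 2 * t_, b = -t_)
  p1 <- pca_media(X1, scale. = FALSE)
  expect_gte(p1$explained[1], 0.999)
  # orthogonal rotation leaves the spectrum unchanged (unscaled PCA)
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  X4 <- matrix(runif(80), 20, 4)
  expect_equal(pca_media(X4 %*% Q, scale. = FALSE)$explained,
               pca_media(X4, scale. = FALSE)$explained, tolerance = 1e-9)
  # constant columns are named in the error
  Xc <- cbind(fixed = rep(1, 10), x = runif(10))
  expect_error(pca_media(Xc), "fixed")
})

test_that("component distributions summarize the front against a sort oracle", {
  toy <- toy_growth_cost()
  cfg <- optimization_config(n_init = 12, n_iter = 1, batch_size = 3,
                             seed = 19, raw_samples = 16,
                             acquisition_restarts = 2)
  ds <- quiet_run_mobo(toy$model, toy$medium, toy$prices,
                       objectives = c("growth", "cost"), config = cfg)
  fr <- suppressWarnings(pareto_front(ds))
  cd <- component_distributions(fr, toy$medium)
  Xn <- sweep(fr$X_members, 2, c(10, 10), "/")
  for (j in 1:2) {
    v <- sort(Xn[, j])
    expect_equal(cd$min[j], v[1], tolerance = 1e-12)
    expect_equal(cd$max[j], v[length(v)], tolerance = 1e-12)
    expect_equal(cd$median[j], stats::median(v), tolerance = 1e-12)
  }
  # identical compositions: zero IQR, flagged tight
  fr2 <- fr
  fr2$X_members <- fr$X_members[rep(1, 4), ]
  cd2 <- component_distributions(fr2, toy$medium)
  expect_equal(cd2$iqr, c(0, 0))
  expect_true(all(cd2$tight))
  # a component pinned at the box edge reads median 1, IQR 0
  fr3 <- fr
  fr3$X_members[, 1] <- 10
  cd3 <- component_distributions(fr3, toy$medium)
  expect_equal(cd3$median[1], 1)
  expect_equal(cd3$iqr[1], 0)
})

test_that("perturbation classification is definitionally consistent", {
  fix <- concave_front_fixture()
  oracle <- suppressWarnings(
    brute_force_pareto(fix$model, fix$medium, fix$prices, grid_per_dim = 9))
  ds <- oracle$dataset
  fr <- oracle$front
  evaluator <- function(b) evaluate_objectives(fix$model, fix$medium, b,
                                               fix$prices)
  res <- suppressWarnings(
    perturb_pareto(ds, fr, sigmas = 0.05, n_per_center = 3, evaluator,
                   seed = 2))
  expect_true(all(res$classification %in% c("inward", "outside-envelope")))
  # compositions are clipped to the box
  expect_true(all(res$EX_N1 >= 0 & res$EX_N1 <= 12))
  expect_true(all(res$EX_N2 >= 0 & res$EX_N2 <= 8))
  # definitional check: outside-envelope iff non-dominated in the union
  consts <- attr(suppressWarnings(dataset_oriented(ds)), "constants")
  Yp <- fluxmedia:::apply_orientation(
    res[, c("growth", "cost")], c("growth", "cost"), consts)
  for (i in seq_len(nrow(res))) {
    m <- pareto_mask(rbind(fr$Y_members, Yp[i, ]))
    expect_identical(res$classification[i] == "outside-envelope",
                     unname(m[length(m)]))
  }
  # draws that are dominated by construction classify 100% inward
  inward <- res[res$classification == "inward", ]
  if (nrow(inward) > 0) {
    expect_true(all(!pareto_mask(rbind(fr$Y_members,
                                       Yp[res$classification == "inward", ][1, ]))[
                                         nrow(fr$Y_members) + 1]))
  }
})

test_that("2-d hypervolume matches hand computation", {
  Y <- rbind(c(2, 1), c(1, 2))
  # union of [0,2]x[0,1] and [0,1]x[0,2] = 2 + 2 - 1
  expect_equal(dominated_hypervolume(Y), 3, tolerance = 1e-12)
  # shifted reference: 1.5*0.5 + 0.5*1.5 - 0.5*0.5 overlap
  expect_equal(dominated_hypervolume(Y, ref = c(0.5, 0.5)), 1.25,
               tolerance = 1e-12)
  expect_equal(dominated_hypervolume(rbind(c(-1, -1))), 0)
  # generational distance of a front to itself is zero
  expect_equal(generational_distance(Y, Y), 0, tolerance = 1e-12)
})
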