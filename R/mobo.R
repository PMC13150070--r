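# Outer optimization loop: random-weight augmented Chebyshev scalarization of
# per-objective Gaussian-process surrogates, expected-improvement batch
# acquisition over the unit box, dataset accumulation, and Pareto-seeded
# restarts.

#' Optimization run configuration
#'
#' @param n_init number of random initial media (>= 2).
#' @param n_iter optimization iterations (>= 1).
#' @param batch_size candidates proposed and evaluated per iteration.
#' @param seed master seed; all random substreams (initialization,
#'   scalarization weights, acquisition restarts) are derived from it, so runs
#'   are exactly reproducible.
#' @param rho augmentation coefficient of the Chebyshev scalarization.
#' @param constraints list of [linear_constraint()]s on the decision-variable
#'   bounds (physical units).
#' @param solver inner solver, `"fba"` or `"pfba"`.
#' @param acquisition_restarts local-refinement starts per candidate.
#' @param raw_samples random screening points per candidate before
#'   refinement.
#' @param refit_gp refit GP hyperparameters from scratch each iteration
#'   (default); `FALSE` warm-starts from the previous fit.
#' @return an object of class `optimization_config`.
#' @export
optimization_config <- function(n_init = 50, n_iter = 100, batch_size = 15,
                                seed = 1L, rho = 0.05, constraints = list(),
                                solver = c("fba", "pfba"),
                                acquisition_restarts = 4, raw_samples = 64,
                                refit_gp = TRUE) {
  solver <- match.arg(solver)
  stopifnot(n_init >= 2, n_iter >= 1, batch_size >= 1, rho > 0)
  structure(list(n_init = as.integer(n_init), n_iter = as.integer(n_iter),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 rho = rho, constraints = constraints, solver = solver,
                 acquisition_restarts = as.integer(acquisition_restarts),
                 raw_samples = as.integer(raw_samples), refit_gp = refit_gp),
            class = "optimization_config")
}

#' Linear constraint on medium composition
#'
#' Equality or `<=` inequality among decision-variable bounds, in physical
#' units, e.g. a fixed stoichiometric coupling of two salts in a formulation.
#'
#' @param coefficients named numeric vector (decision-variable reaction id ->
#'   weight), at least one nonzero.
#' @param rhs scalar right-hand side.
#' @param kind `"equality"` or `"inequality-le"`.
#' @return an object of class `linear_constraint`.
#' @export
linear_constraint <- function(coefficients, rhs, kind = c("equality", "inequality-le")) {
  kind <- match.arg(kind)
  if (all(coefficients == 0)) stop("constraint needs a nonzero coefficient")
  if (is.null(names(coefficients))) stop("coefficients must be named by reaction id")
  structure(list(coefficients = coefficients, rhs = rhs, kind = kind),
            class = "linear_constraint")
}

# --- seeded substreams ------------------------------------------------------

substream_seed <- function(seed, name) {
  ints <- utf8ToInt(name)
  h <- sum(ints * seq_along(ints)) %% 1000003
  as.integer((as.numeric(seed) %% 65536 * 32003 + h * 97 + 17) %% 2147483629)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# --- constraints in unit coordinates ----------------------------------------

constraints_unit <- function(constraints, box) {
  lapply(constraints, function(cn) {
    coef <- stats::setNames(numeric(length(box)), names(box))
    unknown <- setdiff(names(cn$coefficients), names(box))
    if (length(unknown)) stop("constraint references non-decision variable(s): ",
                              paste(unknown, collapse = ", "))
    coef[names(cn$coefficients)] <- cn$coefficients * box[names(cn$coefficients)]
    list(coef = coef, rhs = cn$rhs, kind = cn$kind)
  })
}

project_constraints <- function(X, cons_unit, n_pass = 100, tol = 1e-9) {
  eqs <- Filter(function(cn) cn$kind == "equality", cons_unit)
  if (!length(eqs)) return(pmin(pmax(X, 0), 1))
  A <- do.call(rbind, lapply(eqs, `[[`, "coef"))
  b <- vapply(eqs, `[[`, numeric(1), "rhs")
  AAt <- A %*% t(A)
  for (k in seq_len(n_pass)) {
    resid <- A %*% t(X) - b
    if (max(abs(resid)) < tol && all(X >= -tol) && all(X <= 1 + tol)) break
    X <- X - t(t(A) %*% solve(AAt, resid))
    X <- pmin(pmax(X, 0), 1)
  }
  X
}

satisfies_inequalities <- function(X, cons_unit, tol = 1e-6) {
  ineqs <- Filter(function(cn) cn$kind == "inequality-le", cons_unit)
  ok <- rep(TRUE, nrow(X))
  for (cn in ineqs) ok <- ok & (as.numeric(X %*% cn$coef) <= cn$rhs + tol)
  ok
}

#' Draw random initial media
#'
#' Uniform samples on the decision-variable box, projected onto any equality
#' constraints and rejection-filtered on inequalities. Reproducible for a
#' fixed seed.
#'
#' @param spec a [medium_spec()].
#' @param n number of compositions.
#' @param constraints list of [linear_constraint()]s.
#' @param seed integer seed.
#' @return n x d matrix of decision-variable upper bounds (physical units),
#'   columns named by reaction id.
#' @export
init_random_media <- function(spec, n, constraints = list(), seed = 1L) {
  stopifnot(n >= 1)
  box <- decision_box(spec)
  d <- length(box)
  cons <- constraints_unit(constraints, box)
  X <- with_seed(seed, {
    got <- matrix(numeric(0), 0, d)
    for (attempt in seq_len(200L)) {
      cand <- matrix(stats::runif(n * d), n, d)
      cand <- project_constraints(cand, cons)
      cand <- cand[satisfies_inequalities(cand, cons), , drop = FALSE]
      got <- rbind(got, cand)
      if (nrow(got) >= n) break
    }
    if (nrow(got) < n) stop("could not draw ", n, " constraint-satisfying media ",
                            "in 200 rejection rounds; constraint box may be empty")
    got[seq_len(n), , drop = FALSE]
  })
  colnames(X) <- names(box)
  sweep(X, 2, box, "*")
}

#' Fit per-objective Gaussian-process surrogates
#'
#' One independent GP per oriented objective, on unit-box compositions.
#' Hyperparameters are refit from scratch by marginal-likelihood maximization.
#'
#' @param dataset a `sample_dataset` (>= 2 samples).
#' @param previous optional previous `surrogate_model` for warm starts.
#' @param refit refit hyperparameters (default `TRUE`).
#' @return an object of class `surrogate_model`: a list of [gp_fit()]s named
#'   by objective.
#' @export
fit_surrogate <- function(dataset, previous = NULL, refit = TRUE) {
  stopifnot(n_samples(dataset) >= 2)
  Y <- dataset_oriented(dataset)
  gps <- lapply(dataset$objectives, function(obj) {
    init <- if (!is.null(previous)) {
      f <- previous$gps[[obj]]
      list(lengthscales = f$lengthscales, sf2 = f$sf2, sn2 = f$sn2)
    }
    gp_fit(dataset$X_unit, Y[, obj], optimize = refit, init = init)
  })
  names(gps) <- dataset$objectives
  structure(list(gps = gps, objectives = dataset$objectives,
                 constants = attr(Y, "constants"),
                 fingerprint = c(n = n_samples(dataset))),
            class = "surrogate_model")
}

#' Augmented Chebyshev scalarization
#'
#' Collapses an oriented (all-maximized) objective vector to
#' `min_j(w_j y_j) + rho * sum_j(w_j y_j)` with simplex weights `w`.
#'
#' @param y numeric objective vector, or a matrix with one vector per row.
#' @param weights nonnegative weights summing to 1 (normalized if not).
#' @param rho augmentation coefficient (>= 0).
#' @return scalar (or vector, for matrix input).
#' @export
chebyshev_scalarize <- function(y, weights, rho = 0.05) {
  if (any(weights < 0)) stop("weights must be nonnegative")
  s <- sum(weights)
  if (s <= 0) stop("weights must not sum to zero")
  weights <- weights / s
  if (is.matrix(y)) {
    wy <- sweep(y, 2, weights, "*")
    apply(wy, 1, min) + rho * rowSums(wy)
  } else {
    wy <- weights * y
    min(wy) + rho * sum(wy)
  }
}

runif_simplex <- function(d) {
  e <- stats::rexp(d)
  e / sum(e)
}

# log expected improvement of the scalarized posterior (delta-method
# approximation: the scalarization is linearized at the posterior mean)
acq_log_ei <- function(x, gps, weights, rho, best) {
  d <- ncol(gps[[1]]$X)
  x <- pmin(pmax(x, 0), 1)
  mu <- numeric(length(gps)); va <- numeric(length(gps))
  for (j in seq_along(gps)) {
    p <- gp_predict(gps[[j]], matrix(x, 1, d))
    mu[j] <- p$mean; va[j] <- p$var
  }
  wy <- weights * mu
  jstar <- which.min(wy)
  smean <- wy[jstar] + rho * sum(wy)
  g <- weights * rho
  g[jstar] <- g[jstar] + weights[jstar]
  svar <- sum(g^2 * va)
  sd <- sqrt(max(svar, 0))
  if (sd < 1e-12) {
    ei <- max(smean - best, 0)
  } else {
    z <- (smean - best) / sd
    ei <- sd * (z * stats::pnorm(z) + stats::dnorm(z))
  }
  log(max(ei, 1e-300))
}

#' Propose a batch of candidate media
#'
#' Sequential greedy batch acquisition: for each of the `batch_size`
#' candidates an independent simplex weight vector is drawn, the per-objective
#' GP posteriors are collapsed with the augmented Chebyshev scalarization, and
#' a log-expected-improvement criterion is maximized over the unit box
#' (random screen + L-BFGS-B refinement). Earlier candidates condition later
#' ones through fantasy observations at the posterior mean.
#'
#' @param surrogate a [fit_surrogate()] result trained on `dataset`.
#' @param dataset the current `sample_dataset`.
#' @param config an [optimization_config()].
#' @param iteration iteration number (seeds the weight/acquisition streams).
#' @return `batch_size` x d matrix of unit-box candidates.
#' @export
propose_batch <- function(surrogate, dataset, config, iteration = 1L) {
  d <- ncol(dataset$X_unit)
  q <- config$batch_size
  cons <- constraints_unit(config$constraints, dataset$box_upper)
  gps <- surrogate$gps
  Yor <- dataset_oriented(dataset)
  Xfan <- dataset$X_unit
  Yfan <- Yor
  out <- matrix(NA_real_, q, d, dimnames = list(NULL, colnames(dataset$X_unit)))
  sub <- function(what, k) substream_seed(config$seed, sprintf("%s-i%d-c%d", what, iteration, k))
  for (k in seq_len(q)) {
    w <- with_seed(sub("weights", k), runif_simplex(length(gps)))
    best <- max(chebyshev_scalarize(Yfan, w, config$rho))
    raw <- with_seed(sub("acq", k),
                     matrix(stats::runif(config$raw_samples * d), ncol = d))
    raw <- project_constraints(raw, cons)
    ok <- satisfies_inequalities(raw, cons)
    if (any(ok)) raw <- raw[ok, , drop = FALSE]
    vals <- apply(raw, 1, acq_log_ei, gps = gps, weights = w, rho = config$rho, best = best)
    ord <- order(vals, decreasing = TRUE)
    starts <- raw[ord[seq_len(min(config$acquisition_restarts, nrow(raw)))], , drop = FALSE]
    best_x <- raw[ord[1], ]
    best_v <- vals[ord[1]]
    for (s in seq_len(nrow(starts))) {
      opt <- tryCatch(
        stats::optim(starts[s, ],
                     function(x) -acq_log_ei(x, gps, w, config$rho, best),
                     method = "L-BFGS-B", lower = rep(0, d), upper = rep(1, d),
                     control = list(maxit = 60)),
        error = function(e) NULL)
      if (is.null(opt)) next
      xp <- project_constraints(matrix(opt$par, 1), cons)[1, ]
      if (!all(satisfies_inequalities(matrix(xp, 1), cons))) next
      vp <- acq_log_ei(xp, gps, w, config$rho, best)
      if (vp > best_v) { best_v <- vp; best_x <- xp }
    }
    out[k, ] <- best_x
    # fantasy update: condition every GP on its posterior mean at the pick
    yfan <- vapply(gps, function(g) gp_predict(g, matrix(best_x, 1, d))$mean, numeric(1))
    gps <- lapply(seq_along(gps), function(j) gp_condition(gps[[j]], best_x, yfan[j]))
    names(gps) <- surrogate$objectives
    Xfan <- rbind(Xfan, best_x)
    Yfan <- rbind(Yfan, yfan)
  }
  out
}

evaluate_matrix <- function(model, spec, X_raw, prices, fba_objective, config) {
  rows <- lapply(seq_len(nrow(X_raw)), function(i) {
    evaluate_objectives(model, spec, X_raw[i, ], prices, fba_objective,
                        solver = config$solver)
  })
  do.call(rbind, rows)
}

#' Run the full medium-design optimization
#'
#' Executes initialization followed by `n_iter` rounds of surrogate fitting,
#' batch acquisition, FBA evaluation, and dataset accumulation. The total
#' number of evaluated media is exactly `n_init + n_iter * batch_size`, and
#' runs are fully reproducible for a fixed seed and solver configuration.
#'
#' @param model a `metabolic_model`.
#' @param spec a [medium_spec()].
#' @param prices a [price_table()].
#' @param fba_objective inner-loop [flux_objective()]; `NULL` means biomass.
#' @param objectives 2 or 3 of `c("growth", "production", "cost")`.
#' @param config an [optimization_config()].
#' @param init optional initial design from [restart_from_pareto()], or a
#'   plain matrix of physical bounds.
#' @param verbose print one progress line per iteration.
#' @return a `sample_dataset` with per-sample iteration labels (0 =
#'   initialization).
#' @export
run_mobo <- function(model, spec, prices, fba_objective = NULL,
                     objectives = c("growth", "cost"),
                     config = optimization_config(), init = NULL,
                     verbose = FALSE) {
  objectives <- match.arg(objectives, c("growth", "production", "cost"),
                          several.ok = TRUE)
  if (length(objectives) < 2 || length(objectives) > 3) {
    stop("choose 2 or 3 objectives")
  }
  if ("production" %in% objectives && is.null(model$production)) {
    stop("'production' objective requested but the model has no production reaction")
  }
  box <- decision_box(spec)
  missing_price <- setdiff(names(box), names(prices$z))
  if (length(missing_price)) {
    stop("no price for decision variable(s): ", paste(missing_price, collapse = ", "))
  }
  carried_Y <- NULL
  if (is.null(init)) {
    X0 <- init_random_media(spec, config$n_init, config$constraints,
                            seed = substream_seed(config$seed, "init"))
  } else if (inherits(init, "mobo_init")) {
    X0 <- init$X
    carried_Y <- init$Y
  } else {
    X0 <- as.matrix(init)
    colnames(X0) <- names(box)
  }
  if (!is.null(carried_Y) && nrow(carried_Y) > 0) {
    n_car <- nrow(carried_Y)
    Y_new <- if (nrow(X0) > n_car) {
      evaluate_matrix(model, spec, X0[(n_car + 1):nrow(X0), , drop = FALSE],
                      prices, fba_objective, config)
    }
    Y0 <- rbind(carried_Y, Y_new)
  } else {
    Y0 <- evaluate_matrix(model, spec, X0, prices, fba_objective, config)
  }
  dataset <- new_sample_dataset(X0, Y0, rep(0L, nrow(X0)), spec, objectives)
  surrogate <- NULL
  for (it in seq_len(config$n_iter)) {
    surrogate <- fit_surrogate(dataset, previous = surrogate, refit = config$refit_gp)
    Xu <- propose_batch(surrogate, dataset, config, iteration = it)
    Xr <- sweep(Xu, 2, box, "*")
    colnames(Xr) <- names(box)
    Yr <- evaluate_matrix(model, spec, Xr, prices, fba_objective, config)
    dataset <- append_samples(dataset, Xr, Yr, it)
    if (verbose) {
      Yor <- dataset_oriented(dataset)
      message(sprintf("iter %d/%d: n=%d, front=%d, best-scalarized=%.4f",
                      it, config$n_iter, n_samples(dataset),
                      sum(pareto_mask(Yor)),
                      max(chebyshev_scalarize(Yor, rep(1 / ncol(Yor), ncol(Yor)),
                                              config$rho))))
    }
  }
  dataset
}

#' Seed a new run from a previous run's Pareto front
#'
#' The new initialization consists of every Pareto-optimal composition of the
#' previous run (none dropped, even when the front exceeds `n_init`), padded
#' with fresh random media up to `n_init`. Their objective values are carried
#' over, valid as long as the model and medium spec are unchanged.
#'
#' @param previous a `sample_dataset` from a completed run.
#' @param config an [optimization_config()] for the new run.
#' @return a `mobo_init` object to pass as `init` to [run_mobo()].
#' @export
restart_from_pareto <- function(previous, config) {
  stopifnot(n_samples(previous) >= 1)
  mask <- pareto_mask(dataset_oriented(previous))
  Xf <- previous$X_raw[mask, , drop = FALSE]
  Yf <- previous$Y_raw[mask, , drop = FALSE]
  n_pad <- max(config$n_init - nrow(Xf), 0L)
  if (n_pad > 0) {
    Xr <- init_random_media(previous$spec, n_pad, config$constraints,
                            seed = substream_seed(config$seed, "restart-pad"))
    Xf <- rbind(Xf, Xr)
  }
  structure(list(X = Xf, Y = Yf, n_carried = sum(mask)), class = "mobo_init")
}
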