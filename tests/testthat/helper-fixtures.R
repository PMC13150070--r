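# Fixtures and independent oracles shared across the suite. Oracles are
# deliberately naive (enumeration, direct formulas) and never reuse the
# package's computational path.

# standard 2-nutrient toy: growth = min(u1, u2/2), cost = u1 + 0.5*u2
toy_growth_cost <- function(box = c(10, 10)) {
  make_toy_gem(toy_gem_spec(2, demands = c(1, 2), prices = c(1, 0.5),
                            box_upper = box))
}

toy_with_product <- function(box = c(10, 10)) {
  make_toy_gem(toy_gem_spec(2, demands = c(1, 2),
                            product_branch = list(precursor = 1, yield = 1),
                            prices = c(1, 0.5), box_upper = box))
}

# hand-built model with diminishing returns on nutrient 1: pathway P1 has
# yield 1 but capacity 3, P2 has yield 1/2 and no cap, so optimal growth is
# min(conv(u1), u2) with conv(u1) = u1 for u1 <= 3, 3 + (u1 - 3)/2 beyond.
# The growth-cost front is strictly concave piecewise-linear.
concave_front_fixture <- function() {
  mets <- c("N1", "N2", "B")
  rxns <- c("EX_N1", "EX_N2", "P1", "P2", "BIOMASS")
  S <- rbind(c(1, 0, -1, -2, 0),
             c(0, 1, 0, 0, -1),
             c(0, 0, 1, 1, -1))
  model <- metabolic_model(mets, rxns, S, lb = rep(0, 5),
                           ub = c(12, 8, 3, 1000, 1000),
                           biomass = "BIOMASS", exchange = 1:2)
  comp <- data.frame(component = c("N1", "N2"),
                     reaction_id = c("EX_N1", "EX_N2"),
                     role = "decision", baseline_value = c(6, 4),
                     box_upper = c(12, 8), unit = "flux",
                     stringsAsFactors = FALSE)
  list(model = model, medium = medium_spec(comp),
       prices = price_table(c(EX_N1 = 1, EX_N2 = 1)),
       conv = function(u1) ifelse(u1 <= 3, u1, 3 + (u1 - 3) / 2))
}

# brute-force vertex enumeration oracle for max c'v, S v = 0, lb <= v <= ub:
# fix (n - rank) variables at bounds, solve the square system, keep feasible
# basic solutions, return the best objective
vertex_enumerate_opt <- function(cvec, S, lb, ub) {
  S <- as.matrix(S)
  n <- length(cvec)
  r <- qr(S)$rank
  nf <- n - r
  best <- -Inf
  combs <- if (nf > 0) utils::combn(n, nf, simplify = FALSE) else list(integer(0))
  for (fix in combs) {
    free <- setdiff(seq_len(n), fix)
    grid <- if (length(fix)) expand.grid(rep(list(1:2), length(fix)))
            else data.frame(row.names = 1)
    for (g in seq_len(nrow(grid))) {
      vals <- if (length(fix)) {
        ifelse(unlist(grid[g, ]) == 1, lb[fix], ub[fix])
      } else numeric(0)
      if (any(!is.finite(vals))) next
      rhs <- if (length(fix)) -S[, fix, drop = FALSE] %*% vals
             else matrix(0, nrow(S), 1)
      sol <- try(qr.solve(S[, free, drop = FALSE], rhs, tol = 1e-12),
                 silent = TRUE)
      if (inherits(sol, "try-error")) next
      v <- numeric(n)
      v[fix] <- vals
      v[free] <- sol
      if (max(abs(S %*% v)) > 1e-7) next
      if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) next
      best <- max(best, sum(cvec * v))
    }
  }
  best
}

# O(n^2) pairwise dominance oracle, straight from the definition via outer
# comparisons per objective
oracle_pareto_mask <- function(Y) {
  Y <- as.matrix(Y)
  d <- ncol(Y)
  geq <- Reduce(`&`, lapply(seq_len(d), function(k) outer(Y[, k], Y[, k], ">=")))
  gt <- Reduce(`|`, lapply(seq_len(d), function(k) outer(Y[, k], Y[, k], ">")))
  dominates <- geq & gt  # [a, b]: a dominates b
  !apply(dominates, 2, any)
}

# shared raw-objective orientation for comparing fronts on the growth/cost
# toys: growth maximized as-is, cost inverted against a fixed ceiling
orient_growth_cost <- function(Y_raw, cost_ceiling) {
  cbind(growth = Y_raw$growth, inv_cost = cost_ceiling - Y_raw$cost)
}

quiet_run_mobo <- function(...) suppressWarnings(run_mobo(...))
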