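# Inner optimization: standard flux balance analysis and the parsimonious
# variant, under medium-derived bound constraints. The FBA problem is
#   v* = argmax c'v  s.t.  S v = 0,  lb <= v <= ub,
# where c combines the biomass reaction with an optional production flux.

#' Construct a flux objective
#'
#' A sparse per-reaction weight vector for the inner FBA problem.
#'
#' @param model a `metabolic_model`.
#' @param weights named numeric vector, reaction id -> weight; at least one
#'   nonzero weight.
#' @param description free-text label.
#' @return an object of class `flux_objective`.
#' @export
flux_objective <- function(model, weights, description = "") {
  idx <- match(names(weights), model$reactions)
  if (anyNA(idx)) stop("unknown reaction(s) in objective: ",
                       paste(names(weights)[is.na(idx)], collapse = ", "))
  if (all(weights == 0)) stop("flux objective needs at least one nonzero weight")
  structure(list(weights = weights, description = description),
            class = "flux_objective")
}

#' Combined biomass:production objective
#'
#' Weighted average of the biomass reaction and the production reaction, e.g.
#' 99:1 for plasmid-borne antibody-fragment expression or 95:5 for lipopeptide
#' synthesis. Ratios are normalized to sum to one.
#'
#' @param model a `metabolic_model` (with a production reaction when
#'   `production_weight > 0`).
#' @param biomass_weight,production_weight nonnegative ratio parts.
#' @return a [flux_objective()].
#' @export
make_combined_objective <- function(model, biomass_weight, production_weight = 0) {
  if (biomass_weight < 0 || production_weight < 0) stop("weights must be nonnegative")
  s <- biomass_weight + production_weight
  if (s <= 0) stop("weights must not both be zero")
  bw <- biomass_weight / s
  pw <- production_weight / s
  if (pw > 0 && is.null(model$production)) {
    stop("model has no production reaction but production_weight > 0")
  }
  w <- stats::setNames(bw, model$biomass)
  if (pw > 0) w <- c(w, stats::setNames(pw, model$production))
  flux_objective(model, w, sprintf("biomass:production = %g:%g", bw, pw))
}

objective_vector <- function(model, objective = NULL) {
  cvec <- stats::setNames(numeric(length(model$reactions)), model$reactions)
  if (is.null(objective)) {
    cvec[model$biomass] <- 1
  } else {
    stopifnot(inherits(objective, "flux_objective"))
    cvec[names(objective$weights)] <- objective$weights
  }
  cvec
}

#' Constrain a model's imports to a medium
#'
#' Sets the bounds of the listed nutrient-import reactions to `[0, value]`
#' (uptake-positive convention) and closes imports marked absent
#' (`upper bound = 0`). Unlisted imports keep their configured bounds.
#' The input model is not mutated.
#'
#' @param model a `metabolic_model`.
#' @param medium_bounds named numeric vector, exchange reaction id -> maximum
#'   uptake flux (mmol/gDW/h, >= 0).
#' @param absent character vector of exchange reaction ids to close.
#' @return a new model with updated bounds.
#' @export
apply_medium <- function(model, medium_bounds, absent = character()) {
  ex_ids <- exchange_reactions(model)
  keys <- names(medium_bounds)
  bad <- setdiff(c(keys, absent), ex_ids)
  if (length(bad)) stop("not nutrient-import reactions: ", paste(bad, collapse = ", "))
  if (any(medium_bounds < 0)) {
    stop("negative medium bound for: ",
         paste(keys[medium_bounds < 0], collapse = ", "))
  }
  out <- model
  out$lb[keys] <- 0
  out$ub[keys] <- as.numeric(medium_bounds)
  if (length(absent)) {
    out$lb[absent] <- 0
    out$ub[absent] <- 0
  }
  out
}

new_flux_solution <- function(model, status, v = NULL, objective_value = NA_real_,
                              total_flux = NA_real_, ray_var = NA_integer_) {
  if (is.null(v)) v <- stats::setNames(rep(NA_real_, length(model$reactions)), model$reactions)
  structure(list(
    v_star = v,
    objective_value = objective_value,
    status = status,
    total_flux = total_flux,
    growth = if (status == "optimal") v[[model$biomass]] else NA_real_,
    production = if (status == "optimal" && !is.null(model$production))
      v[[model$production]] else NA_real_,
    ray_var = ray_var
  ), class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("flux_solution: status=", x$status, sep = "")
  if (x$status == "optimal") {
    cat(sprintf(", objective=%.6g, growth=%.6g", x$objective_value, x$growth))
    if (!is.na(x$production)) cat(sprintf(", production=%.6g", x$production))
    if (!is.na(x$total_flux)) cat(sprintf(", total_flux=%.6g", x$total_flux))
  }
  cat("\n")
  invisible(x)
}

#' Solve the FBA linear program
#'
#' Maximizes `c'v` subject to steady-state mass balance `S v = 0` and the flux
#' bounds. The returned vertex is whichever the solver reports; FBA optima are
#' generally non-unique, use [solve_pfba()] for a regularized representative.
#'
#' @param model a `metabolic_model`.
#' @param objective a [flux_objective()]; `NULL` means the biomass reaction.
#' @param tol solver feasibility/optimality tolerance.
#' @return a `flux_solution` with `status` in
#'   `"optimal"`/`"infeasible"`/`"unbounded"`.
#' @export
solve_fba <- function(model, objective = NULL, tol = 1e-9) {
  cvec <- objective_vector(model, objective)
  res <- lp_solve(cvec, model$S, rep(0, length(model$metabolites)),
                  model$lb, model$ub, maximize = TRUE, tol = tol)
  if (res$status == "unbounded") {
    rv <- res$ray_var
    warning("FBA unbounded along reaction '",
            if (!is.na(rv)) model$reactions[rv] else "?", "'", call. = FALSE)
    return(new_flux_solution(model, "unbounded", ray_var = rv))
  }
  if (res$status != "optimal") return(new_flux_solution(model, res$status))
  v <- stats::setNames(res$x, model$reactions)
  new_flux_solution(model, "optimal", v, objective_value = sum(cvec * v))
}

#' Parsimonious FBA
#'
#' Two-stage LP: first solve standard FBA, then, holding the achieved
#' objective to within `optimality_tolerance` (as an inequality
#' `c'v >= (1 - tol) * optimum`, avoiding round-off infeasibility), minimize
#' the total absolute flux via reversible-reaction splitting. Selects a unique
#' parsimonious representative among alternate FBA optima.
#'
#' @param model a `metabolic_model`.
#' @param objective a [flux_objective()]; `NULL` means the biomass reaction.
#' @param optimality_tolerance allowed fractional degradation of the FBA
#'   optimum in stage two.
#' @param tol LP tolerance.
#' @return a `flux_solution` with `total_flux` populated.
#' @export
solve_pfba <- function(model, objective = NULL, optimality_tolerance = 1e-6,
                       tol = 1e-9) {
  stage1 <- solve_fba(model, objective, tol = tol)
  if (stage1$status != "optimal") return(stage1)
  cvec <- objective_vector(model, objective)
  n <- length(model$reactions)
  opt <- stage1$objective_value
  floor_val <- (1 - optimality_tolerance) * opt - abs(opt) * 1e-12
  # variables: v+ (n), v- (n), slack t for c'(v+ - v-) - t = floor
  lb2 <- c(pmax(model$lb, 0), pmax(-model$ub, 0), 0)
  ub2 <- c(pmax(model$ub, 0), pmax(-model$lb, 0), Inf)
  A <- cbind(model$S, -model$S, Matrix::Matrix(0, nrow(model$S), 1, sparse = TRUE))
  A <- rbind(A, c(cvec, -cvec, -1))
  b <- c(rep(0, length(model$metabolites)), floor_val)
  obj2 <- c(rep(1, 2 * n), 0)
  res <- lp_solve(obj2, A, b, lb2, ub2, maximize = FALSE, tol = tol)
  if (res$status != "optimal") {
    warning("pFBA stage 2 ", res$status, "; returning the FBA solution", call. = FALSE)
    stage1$total_flux <- sum(abs(stage1$v_star))
    return(stage1)
  }
  v <- stats::setNames(res$x[seq_len(n)] - res$x[n + seq_len(n)], model$reactions)
  new_flux_solution(model, "optimal", v,
                    objective_value = sum(cvec * v),
                    total_flux = sum(abs(v)))
}
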