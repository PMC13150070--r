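# Medium design space: which import bounds are decision variables, how
# laboratory concentrations map to flux bounds, and how a candidate medium is
# scored on the outer objectives (growth, production, cost).

#' Define the medium design space
#'
#' @param components data frame with columns `component` (name), `reaction_id`
#'   (exchange reaction), `role` (`"decision"`, `"fixed"`, or `"absent"`),
#'   `baseline_value` (reference composition, e.g. M9), `box_upper` (search
#'   upper limit for decision variables), and `unit` (`"mM"` or `"flux"`).
#'   Values in mM are converted with `concentration_to_flux()`.
#' @param conversion_factor liters of medium supplied per gram dry weight per
#'   supply period; multiplies mM concentrations to give flux bounds
#'   (mmol/gDW/h). Default 0.5, calibrated so 20 mM glucose maps to an uptake
#'   bound of 10 mmol/gDW/h.
#' @return an object of class `medium_spec`.
#' @export
medium_spec <- function(components, conversion_factor = 0.5) {
  req <- c("component", "reaction_id", "role", "baseline_value", "box_upper", "unit")
  missing <- setdiff(req, names(components))
  if (length(missing)) stop("medium table lacks column(s): ", paste(missing, collapse = ", "))
  if (!all(components$role %in% c("decision", "fixed", "absent"))) {
    stop("role must be one of decision/fixed/absent")
  }
  if (!all(components$unit %in% c("mM", "flux"))) stop("unit must be 'mM' or 'flux'")
  components <- as.data.frame(components, stringsAsFactors = FALSE)
  to_flux <- function(v) ifelse(components$unit == "mM",
                                concentration_to_flux(v, conversion_factor), v)
  components$baseline_flux <- to_flux(components$baseline_value)
  components$box_upper_flux <- to_flux(components$box_upper)
  dec <- components$role == "decision"
  if (!any(dec)) stop("at least one decision variable is required")
  if (any(dec & !(components$box_upper_flux > 0))) {
    stop("box_upper must be > 0 for decision variables: ",
         paste(components$component[dec & !(components$box_upper_flux > 0)], collapse = ", "))
  }
  if (any(components$baseline_flux < 0, na.rm = TRUE)) stop("negative baseline value")
  structure(list(components = components, conversion_factor = conversion_factor),
            class = "medium_spec")
}

#' @export
print.medium_spec <- function(x, ...) {
  tab <- table(x$components$role)
  cat("medium_spec: ", nrow(x$components), " components (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

decision_ids <- function(spec) {
  spec$components$reaction_id[spec$components$role == "decision"]
}

decision_box <- function(spec) {
  with(spec$components[spec$components$role == "decision", ],
       stats::setNames(box_upper_flux, reaction_id))
}

fixed_bounds <- function(spec) {
  with(spec$components[spec$components$role == "fixed", ],
       stats::setNames(baseline_flux, reaction_id))
}

absent_ids <- function(spec) {
  spec$components$reaction_id[spec$components$role == "absent"]
}

baseline_bounds <- function(spec) {
  keep <- spec$components$role != "absent"
  with(spec$components[keep, ], stats::setNames(baseline_flux, reaction_id))
}

#' Price table for medium components
#'
#' @param prices named numeric vector, exchange reaction id -> price per unit
#'   of supplied flux bound (currency per mmol/gDW/h). Zero is allowed (e.g.
#'   oxygen supplied by stirring).
#' @param currency label.
#' @return an object of class `price_table`.
#' @export
price_table <- function(prices, currency = "EUR") {
  if (any(prices < 0)) stop("prices must be nonnegative")
  if (is.null(names(prices))) stop("prices must be named by exchange reaction id")
  structure(list(z = prices, currency = currency), class = "price_table")
}

#' Convert a medium concentration to an uptake flux bound
#'
#' Multiplies a molar concentration by the supply conversion factor
#' (liters of medium per gDW per supply period); the default factor 0.5
#' reproduces the calibration mapping 20 mM glucose in M9 to an uptake bound
#' of 10 mmol/gDW/h.
#'
#' @param concentration mM, >= 0.
#' @param factor conversion factor (l/gDW), > 0.
#' @return flux bound in mmol/gDW/h.
#' @export
concentration_to_flux <- function(concentration, factor = 0.5) {
  if (any(concentration < 0, na.rm = TRUE)) stop("concentration must be >= 0")
  if (factor <= 0) stop("conversion factor must be > 0")
  concentration * factor
}

#' Inverse of [concentration_to_flux()]
#'
#' @param flux mmol/gDW/h, >= 0.
#' @param factor conversion factor (l/gDW), > 0.
#' @return concentration in mM.
#' @export
flux_to_concentration <- function(flux, factor = 0.5) {
  if (any(flux < 0, na.rm = TRUE)) stop("flux must be >= 0")
  if (factor <= 0) stop("conversion factor must be > 0")
  flux / factor
}

#' Convert a doubling time to a specific growth rate
#'
#' `growth rate = ln(2) / doubling time [h]`; e.g. doubling times of 54 and
#' 30 min give 0.77 and 1.39 per hour.
#'
#' @param doubling_time minutes, > 0.
#' @return growth rate in 1/h.
#' @export
doubling_time_to_growth <- function(doubling_time) {
  if (any(doubling_time <= 0)) stop("doubling time must be > 0")
  log(2) / (doubling_time / 60)
}

#' Cost of a medium
#'
#' Linear price-weighted sum of the supplied upper bounds,
#' `f_cost = z' v_max`. Depends only on what is supplied, never on the flux
#' solution.
#'
#' @param bounds named numeric vector of supplied upper bounds (decision
#'   variables).
#' @param prices a [price_table()].
#' @return scalar cost (currency units).
#' @export
medium_cost <- function(bounds, prices) {
  stopifnot(inherits(prices, "price_table"))
  missing <- setdiff(names(bounds), names(prices$z))
  if (length(missing)) stop("no price for component(s): ", paste(missing, collapse = ", "))
  sum(prices$z[names(bounds)] * bounds)
}

#' Evaluate the outer objective vector for a candidate medium
#'
#' Applies the candidate decision-variable bounds (plus the spec's fixed and
#' absent components) to the model, solves the inner FBA (or pFBA) problem,
#' and reads off growth (biomass flux), production (production-reaction flux)
#' and cost (price-weighted supplied bounds). Infeasible or failed solves
#' yield growth = production = 0 while cost is still charged, so the
#' optimizer is penalized for infeasible media; the raw status is retained.
#'
#' @param model a `metabolic_model`.
#' @param spec a [medium_spec()].
#' @param bounds named numeric vector of candidate decision-variable upper
#'   bounds (within `[0, box_upper]`).
#' @param prices a [price_table()].
#' @param fba_objective a [flux_objective()]; `NULL` means biomass.
#' @param solver `"fba"` or `"pfba"`.
#' @param pfba_tolerance stage-two optimality tolerance for pFBA.
#' @return a one-row data frame: `growth`, `production`, `cost`, `feasible`,
#'   `status`.
#' @export
evaluate_objectives <- function(model, spec, bounds, prices, fba_objective = NULL,
                                solver = c("fba", "pfba"), pfba_tolerance = 1e-6) {
  solver <- match.arg(solver)
  ids <- decision_ids(spec)
  if (!all(ids %in% names(bounds))) {
    stop("candidate bounds missing decision variable(s): ",
         paste(setdiff(ids, names(bounds)), collapse = ", "))
  }
  box <- decision_box(spec)
  if (any(bounds[ids] < -1e-12) || any(bounds[ids] > box[ids] * (1 + 1e-9) + 1e-12)) {
    stop("candidate bounds outside [0, box_upper]")
  }
  medium <- c(pmin(pmax(bounds[ids], 0), box[ids]), fixed_bounds(spec))
  constrained <- apply_medium(model, medium, absent = absent_ids(spec))
  sol <- if (solver == "fba") solve_fba(constrained, fba_objective)
         else solve_pfba(constrained, fba_objective, pfba_tolerance)
  if (sol$status == "optimal") {
    growth <- sol$growth
    production <- if (!is.null(model$production)) sol$production else NA_real_
  } else if (sol$status == "infeasible") {
    growth <- 0
    production <- if (!is.null(model$production)) 0 else NA_real_
  } else {
    stop("FBA solve failed (", sol$status, ") for candidate bounds: ",
         paste(sprintf("%s=%.4g", ids, bounds[ids]), collapse = ", "))
  }
  data.frame(growth = growth, production = production,
             cost = medium_cost(bounds[ids], prices),
             feasible = sol$status == "optimal",
             status = sol$status, stringsAsFactors = FALSE)
}

#' Orient and normalize accumulated objective values
#'
#' Production and cost are min-max scaled to `[0, 1]` over the current
#' dataset; cost is then inverted (`1 - scaled`) so that every objective is
#' maximized. Growth passes through unchanged when its observed range lies in
#' `[0, 1]`, otherwise it is min-max scaled with a warning. A degenerate
#' (constant) scaled column maps to 0.5 with a warning, the center of the
#' unit box, so it neither attracts nor repels the Chebyshev scalarization.
#'
#' @param Y_raw data frame with columns among `growth`, `production`, `cost`.
#' @param objectives character subset of `c("growth","production","cost")`
#'   giving the column order of the result.
#' @return a matrix of oriented objectives with attribute `"constants"`
#'   recording the min/max used per column.
#' @export
orient_and_normalize <- function(Y_raw, objectives = c("growth", "cost")) {
  stopifnot(nrow(Y_raw) >= 1, all(objectives %in% c("growth", "production", "cost")))
  out <- matrix(NA_real_, nrow(Y_raw), length(objectives),
                dimnames = list(NULL, objectives))
  consts <- list()
  minmax <- function(v, what) {
    lo <- min(v); hi <- max(v)
    consts[[what]] <<- c(min = lo, max = hi)
    if (hi - lo < 1e-12) {
      warning("constant ", what, " column; mapping to 0.5", call. = FALSE)
      rep(0.5, length(v))
    } else (v - lo) / (hi - lo)
  }
  for (obj in objectives) {
    v <- Y_raw[[obj]]
    if (obj == "growth") {
      if (min(v) >= 0 && max(v) <= 1) {
        consts[["growth"]] <- c(min = 0, max = 1)  # pass-through
        out[, obj] <- v
      } else {
        warning("growth outside [0,1]; min-max scaling applied", call. = FALSE)
        out[, obj] <- minmax(v, "growth")
      }
    } else if (obj == "production") {
      out[, obj] <- minmax(v, "production")
    } else {
      out[, obj] <- 1 - minmax(v, "cost")
    }
  }
  attr(out, "constants") <- consts
  out
}

# re-apply normalization constants from a previous call to new raw values
apply_orientation <- function(Y_raw, objectives, constants) {
  out <- matrix(NA_real_, nrow(Y_raw), length(objectives),
                dimnames = list(NULL, objectives))
  for (obj in objectives) {
    v <- Y_raw[[obj]]
    cc <- constants[[obj]]
    scaled <- if (cc[["max"]] - cc[["min"]] < 1e-12) rep(0.5, length(v))
              else (v - cc[["min"]]) / (cc[["max"]] - cc[["min"]])
    out[, obj] <- if (obj == "cost") 1 - scaled else scaled
  }
  out
}
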