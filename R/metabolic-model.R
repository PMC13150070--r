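# In-memory representation of a constraint-based metabolic model.
#
# Sign convention: nutrient-import (exchange) reactions are stored
# uptake-positive, i.e. positive flux through an exchange reaction creates its
# metabolite inside the network and the medium is encoded purely by upper
# bounds 0 <= v_i <= v_i^max. SBML/BiGG files write the opposite (uptake as
# negative flux through a metabolite-consuming boundary reaction); the readers
# and writers translate between the two conventions so that files round-trip.

#' Construct a metabolic model
#'
#' Builds the container used by all solvers in the package: a stoichiometric
#' matrix, per-reaction flux bounds, and a classification of reactions into
#' internal, exchange (nutrient-import), and sink sets.
#'
#' @param metabolites character vector of metabolite identifiers.
#' @param reactions character vector of reaction identifiers.
#' @param S stoichiometric matrix, metabolites x reactions (coercible to
#'   `Matrix::dgCMatrix`).
#' @param lb,ub numeric flux bounds (mmol/gDW/h), length `length(reactions)`.
#' @param biomass identifier of the biomass reaction.
#' @param production optional identifier of the production reaction.
#' @param exchange indices or identifiers of exchange reactions; if `NULL`
#'   they are detected structurally (single nonzero stoichiometric column
#'   entry, not a sink).
#' @param sinks indices or identifiers of sink reactions (boundary reactions
#'   removing an intracellular metabolite; never medium decision variables).
#' @param formulas optional named character vector of metabolite formulas.
#' @param id model identifier.
#'
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, S, lb, ub, biomass,
                            production = NULL, exchange = NULL, sinks = integer(),
                            formulas = NULL, id = "model") {
  S <- methods::as(methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE),
                                           "dMatrix"), "generalMatrix"), "CsparseMatrix")
  n <- length(reactions)
  m <- length(metabolites)
  stopifnot(nrow(S) == m, ncol(S) == n, length(lb) == n, length(ub) == n)
  dimnames(S) <- list(metabolites, reactions)
  sinks <- resolve_rxn(sinks, reactions)
  if (is.null(exchange)) {
    nnz <- Matrix::colSums(S != 0)
    exchange <- setdiff(which(nnz == 1L), sinks)
  } else {
    exchange <- resolve_rxn(exchange, reactions)
  }
  model <- structure(list(
    id = id,
    metabolites = as.character(metabolites),
    reactions = as.character(reactions),
    S = S,
    lb = stats::setNames(as.numeric(lb), reactions),
    ub = stats::setNames(as.numeric(ub), reactions),
    exchange = sort(as.integer(exchange)),
    sinks = sort(as.integer(sinks)),
    biomass = as.character(biomass),
    production = if (is.null(production)) NULL else as.character(production),
    formulas = formulas,
    objective_direction = "max"
  ), class = "metabolic_model")
  validate_model(model)
  model
}

resolve_rxn <- function(x, reactions) {
  if (is.character(x)) {
    idx <- match(x, reactions)
    if (anyNA(idx)) stop("unknown reaction id(s): ", paste(x[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(x)
}

#' Validate metabolic model invariants
#'
#' Checks bound ordering, the internal/exchange/sink partition, the
#' boundary structure of exchange and sink reactions, and the presence of the
#' biomass reaction. Called by the constructor; exported for use after manual
#' edits.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors on violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  n <- length(model$reactions)
  if (any(model$lb > model$ub)) {
    bad <- model$reactions[model$lb > model$ub]
    stop("lower bound exceeds upper bound for: ", paste(bad, collapse = ", "))
  }
  if (length(intersect(model$exchange, model$sinks))) {
    stop("a reaction cannot be both exchange and sink")
  }
  if (any(model$exchange < 1 | model$exchange > n)) stop("exchange index out of range")
  nnz <- Matrix::colSums(model$S != 0)
  boundary <- c(model$exchange, model$sinks)
  if (length(boundary) && any(nnz[boundary] != 1L)) {
    stop("boundary (exchange/sink) reactions must have exactly one nonzero ",
         "stoichiometric entry: ",
         paste(model$reactions[boundary][nnz[boundary] != 1L], collapse = ", "))
  }
  if (!(model$biomass %in% model$reactions)) {
    stop("biomass reaction '", model$biomass, "' not in the model")
  }
  if (!is.null(model$production) && !(model$production %in% model$reactions)) {
    stop("production reaction '", model$production, "' not in the model")
  }
  if (anyDuplicated(model$reactions)) stop("duplicate reaction ids")
  if (anyDuplicated(model$metabolites)) stop("duplicate metabolite ids")
  invisible(model)
}

#' Internal-reaction index set
#'
#' Reactions that are neither exchange nor sink; together the three sets
#' partition the reaction index set.
#'
#' @param model a `metabolic_model`.
#' @return integer indices.
#' @export
internal_reactions <- function(model) {
  setdiff(seq_along(model$reactions), c(model$exchange, model$sinks))
}

#' Exchange-reaction identifiers
#'
#' @param model a `metabolic_model`.
#' @return character vector of exchange (nutrient-import) reaction ids.
#' @export
exchange_reactions <- function(model) model$reactions[model$exchange]

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model '", x$id, "': ", length(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions (", length(x$exchange), " exchange, ",
      length(x$sinks), " sink)\n", sep = "")
  cat("  biomass: ", x$biomass,
      if (!is.null(x$production)) paste0("; production: ", x$production), "\n", sep = "")
  invisible(x)
}

#' Checksum of a model's mathematical content
#'
#' MD5 of the canonicalized (id-sorted) stoichiometry and bounds, so that
#' dialect round-trips (SBML vs JSON) leave provenance unchanged.
#'
#' @param model a `metabolic_model`.
#' @return a hex digest string.
#' @export
model_checksum <- function(model) {
  mo <- order(model$metabolites)
  ro <- order(model$reactions)
  Sc <- as.matrix(model$S)[mo, ro, drop = FALSE]
  lines <- vapply(seq_along(ro), function(j) {
    nz <- which(Sc[, j] != 0)
    paste0(model$reactions[ro[j]], "|",
           paste0(model$metabolites[mo][nz], ":",
                  format(Sc[nz, j], digits = 15), collapse = ","),
           "|", format(model$lb[ro[j]], digits = 15),
           "|", format(model$ub[ro[j]], digits = 15))
  }, character(1))
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(lines, f)
  unname(tools::md5sum(f))
}

#' Describe a reaction to be added to a model
#'
#' @param id reaction identifier.
#' @param stoichiometry named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed).
#' @param lower_bound,upper_bound flux bounds (mmol/gDW/h).
#' @return an object of class `reaction_recipe`.
#' @export
reaction_recipe <- function(id, stoichiometry, lower_bound = 0, upper_bound = 1000) {
  if (!length(stoichiometry)) stop("recipe stoichiometry must be non-empty")
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry)))) {
    stop("stoichiometry must be a named vector of metabolite coefficients")
  }
  if (lower_bound > upper_bound) stop("lower_bound exceeds upper_bound")
  structure(list(id = as.character(id), stoichiometry = stoichiometry,
                 lower_bound = lower_bound, upper_bound = upper_bound),
            class = "reaction_recipe")
}
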