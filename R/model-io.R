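# Model readers/writers (SBML Level 3 + fbc flux bounds, BiGG-style JSON) and
# model-editing operations. Files use the community convention of
# uptake-negative boundary reactions; in memory we keep exchanges
# uptake-positive (see metabolic-model.R), so both directions translate here.

BIG_BOUND <- 1000

#' Read a genome-scale metabolic model
#'
#' Parses an SBML Level 3 file (with fbc flux-bound annotations) or a
#' BiGG-style JSON file into a [metabolic_model()]. Exchange reactions are
#' identified structurally (single nonzero stoichiometric entry) with id
#' prefixes (`EX_`) as a fallback; reactions prefixed `SK_`/`DM_`/`sink_` are
#' classified as sinks. Exchange columns are re-oriented uptake-positive.
#'
#' @param path file path.
#' @param dialect `"auto"` (by extension), `"sbml"`, or `"bigg-json"`.
#' @param biomass optional biomass reaction id, required when the file does
#'   not mark an objective and no reaction id/name contains "biomass".
#' @return a `metabolic_model`.
#' @export
read_gem <- function(path, dialect = c("auto", "sbml", "bigg-json"), biomass = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "bigg-json" else "sbml"
  }
  raw <- switch(dialect, "bigg-json" = read_bigg_json(path), "sbml" = read_sbml(path))
  build_model_from_raw(raw, biomass = biomass, id = raw$id)
}

read_bigg_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("cannot parse BiGG JSON '", path, "': ",
                                           conditionMessage(e)))
  if (is.null(doc$reactions) || is.null(doc$metabolites)) {
    stop("BiGG JSON '", path, "' lacks a 'reactions' or 'metabolites' element")
  }
  mets <- vapply(doc$metabolites, function(m) m$id, character(1))
  formulas <- vapply(doc$metabolites, function(m) {
    f <- m$formula
    if (is.null(f)) NA_character_ else as.character(f)
  }, character(1))
  names(formulas) <- mets
  rxns <- vapply(doc$reactions, function(r) r$id, character(1))
  lb <- vapply(doc$reactions, function(r) as.numeric(r$lower_bound %||% -BIG_BOUND), numeric(1))
  ub <- vapply(doc$reactions, function(r) as.numeric(r$upper_bound %||% BIG_BOUND), numeric(1))
  obj <- vapply(doc$reactions, function(r) as.numeric(r$objective_coefficient %||% 0), numeric(1))
  trip <- do.call(rbind, lapply(seq_along(doc$reactions), function(j) {
    st <- doc$reactions[[j]]$metabolites
    if (!length(st)) stop("reaction '", rxns[j], "' has empty stoichiometry")
    cbind(match(names(st), mets), j, as.numeric(unlist(st)))
  }))
  if (anyNA(trip[, 1])) stop("reaction references unknown metabolite in '", path, "'")
  S <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                            dims = c(length(mets), length(rxns)))
  list(metabolites = mets, reactions = rxns, S = S, lb = lb, ub = ub,
       objective_coef = obj, formulas = formulas,
       id = as.character(doc$id %||% "model"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML '", path, "': ",
                                           conditionMessage(e)))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model_node, "xml_missing")) stop("SBML '", path, "' has no <model> element")
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(
    vapply(xml2::xml_attr(params, "value"), parse_sbml_double, numeric(1)),
    xml2::xml_attr(params, "id"))
  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- xml2::xml_attr(species, "id")
  if (!length(mets)) stop("SBML '", path, "' declares no species")
  rnodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rnodes)) stop("SBML '", path, "' declares no reactions")
  rxns <- xml2::xml_attr(rnodes, "id")
  nr <- length(rnodes)
  lb <- numeric(nr); ub <- numeric(nr)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  for (j in seq_len(nr)) {
    lo_ref <- xml2::xml_attr(rnodes[[j]], "lowerFluxBound")
    up_ref <- xml2::xml_attr(rnodes[[j]], "upperFluxBound")
    lb[j] <- if (!is.na(lo_ref) && lo_ref %in% names(pvals)) pvals[[lo_ref]] else -BIG_BOUND
    ub[j] <- if (!is.na(up_ref) && up_ref %in% names(pvals)) pvals[[up_ref]] else BIG_BOUND
    for (side in c("listOfReactants", "listOfProducts")) {
      sr <- xml2::xml_find_all(rnodes[[j]], paste0("./s:", side, "/s:speciesReference"), ns)
      if (!length(sr)) next
      idx <- match(xml2::xml_attr(sr, "species"), mets)
      if (anyNA(idx)) {
        stop("reaction '", rxns[j], "' references unknown species '",
             xml2::xml_attr(sr, "species")[is.na(idx)][1], "'")
      }
      st <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      st[is.na(st)] <- 1
      if (side == "listOfReactants") st <- -st
      ti <- c(ti, idx); tj <- c(tj, rep(j, length(idx))); tx <- c(tx, st)
    }
  }
  S <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(length(mets), nr))
  objective_coef <- numeric(nr)
  fo <- xml2::xml_find_all(doc, ".//fbc:fluxObjective", ns)
  if (length(fo)) {
    idx <- match(xml2::xml_attr(fo, "reaction"), rxns)
    co <- as.numeric(xml2::xml_attr(fo, "coefficient"))
    objective_coef[idx[!is.na(idx)]] <- co[!is.na(idx)]
  }
  list(metabolites = mets, reactions = rxns, S = S, lb = lb, ub = ub,
       objective_coef = objective_coef, formulas = NULL,
       id = xml2::xml_attr(model_node, "id") %||% "model")
}

parse_sbml_double <- function(x) {
  if (is.na(x)) return(NA_real_)
  if (x %in% c("INF", "inf")) return(Inf)
  if (x %in% c("-INF", "-inf")) return(-Inf)
  as.numeric(x)
}

build_model_from_raw <- function(raw, biomass = NULL, id = "model") {
  nnz <- Matrix::colSums(raw$S != 0)
  sink_like <- grepl("^(SK_|DM_|sink_)", raw$reactions, ignore.case = TRUE)
  sinks <- which(nnz == 1L & sink_like)
  exchange <- setdiff(which(nnz == 1L), sinks)
  if (!length(exchange)) {  # fallback: id-prefix heuristic
    exchange <- which(grepl("^EX_", raw$reactions) & !sink_like)
  }
  # re-orient exchanges uptake-positive: file columns consuming their
  # metabolite (coefficient < 0) are flipped
  S <- raw$S; lb <- raw$lb; ub <- raw$ub
  for (j in exchange) {
    coef <- S[which(S[, j] != 0), j]
    if (coef < 0) {
      S[, j] <- -S[, j]
      tmp <- lb[j]; lb[j] <- -ub[j]; ub[j] <- -tmp
    }
  }
  if (is.null(biomass)) {
    cand <- which(raw$objective_coef != 0)
    if (length(cand) == 1L) {
      biomass <- raw$reactions[cand]
    } else {
      cand <- which(grepl("biomass", raw$reactions, ignore.case = TRUE))
      if (length(cand) >= 1L) biomass <- raw$reactions[cand[1L]]
      else stop("no biomass-like objective found; pass the biomass reaction id ",
                "explicitly via `biomass=`")
    }
  }
  metabolic_model(raw$metabolites, raw$reactions, S, lb, ub, biomass = biomass,
                  exchange = exchange, sinks = sinks, formulas = raw$formulas,
                  id = id)
}

#' Write a metabolic model to file
#'
#' Writes SBML Level 3 (fbc bounds) or BiGG-style JSON. Exchange reactions are
#' translated back to the file convention (uptake-negative, metabolite
#' consumed), so that [read_gem()] of the output reproduces the input model.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @param dialect `"sbml"` or `"bigg-json"`.
#' @return `path`, invisibly.
#' @export
write_gem <- function(model, path, dialect = c("sbml", "bigg-json")) {
  dialect <- match.arg(dialect)
  # flip exchange columns that are uptake-positive back to file convention
  S <- model$S; lb <- model$lb; ub <- model$ub
  for (j in model$exchange) {
    coef <- S[which(S[, j] != 0), j]
    if (coef > 0) {
      S[, j] <- -S[, j]
      tmp <- lb[j]; lb[j] <- -ub[j]; ub[j] <- -tmp
    }
  }
  if (dialect == "bigg-json") {
    rx <- lapply(seq_along(model$reactions), function(j) {
      nz <- which(S[, j] != 0)
      st <- as.list(S[nz, j])
      names(st) <- model$metabolites[nz]
      list(id = model$reactions[j], metabolites = st,
           lower_bound = lb[[j]], upper_bound = ub[[j]],
           objective_coefficient = if (model$reactions[j] == model$biomass) 1 else 0)
    })
    mets <- lapply(seq_along(model$metabolites), function(i) {
      out <- list(id = model$metabolites[i], compartment = "c")
      if (!is.null(model$formulas) && !is.na(model$formulas[i])) {
        out$formula <- unname(model$formulas[i])
      }
      out
    })
    jsonlite::write_json(list(id = model$id, metabolites = mets, reactions = rx,
                              genes = list(), version = "1"),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    writeLines(sbml_text(model, S, lb, ub), path)
  }
  invisible(path)
}

fmt_num <- function(x) {
  ifelse(is.infinite(x), ifelse(x > 0, "INF", "-INF"), sprintf("%.17g", x))
}

sbml_text <- function(model, S, lb, ub) {
  n <- length(model$reactions)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" fbc:strict="true">', model$id),
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  lines <- c(lines, sprintf(
    '      <species id="%s" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
    model$metabolites))
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  lines <- c(lines,
             sprintf('      <parameter id="fb_%d_lo" value="%s" constant="true"/>',
                     seq_len(n), fmt_num(lb)),
             sprintf('      <parameter id="fb_%d_up" value="%s" constant="true"/>',
                     seq_len(n), fmt_num(ub)))
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (j in seq_len(n)) {
    nz <- which(S[, j] != 0)
    co <- S[nz, j]
    reac <- nz[co < 0]; prod <- nz[co > 0]
    lines <- c(lines, sprintf(
      '      <reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="fb_%d_lo" fbc:upperFluxBound="fb_%d_up">',
      model$reactions[j], tolower(lb[j] < 0), j, j))
    if (length(reac)) {
      lines <- c(lines, '        <listOfReactants>',
                 sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         model$metabolites[reac], fmt_num(-S[reac, j])),
                 '        </listOfReactants>')
    }
    if (length(prod)) {
      lines <- c(lines, '        <listOfProducts>',
                 sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         model$metabolites[prod], fmt_num(S[prod, j])),
                 '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>',
             '    <fbc:listOfObjectives fbc:activeObjective="obj">',
             '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
             '        <fbc:listOfFluxObjectives>',
             sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
                     model$biomass),
             '        </fbc:listOfFluxObjectives>',
             '      </fbc:objective>',
             '    </fbc:listOfObjectives>',
             '  </model>', '</sbml>')
  lines
}

append_column <- function(model, id, stoich, lb, ub, role = c("internal", "exchange", "sink"),
                          create_missing = FALSE) {
  role <- match.arg(role)
  if (id %in% model$reactions) stop("reaction '", id, "' already in the model")
  missing <- setdiff(names(stoich), model$metabolites)
  if (length(missing) && !create_missing) {
    stop("unknown metabolite(s): ", paste(missing, collapse = ", "),
         " (use create_missing = TRUE to add them)")
  }
  mets <- c(model$metabolites, missing)
  S <- model$S
  if (length(missing)) {
    S <- rbind(S, Matrix::Matrix(0, length(missing), ncol(S), sparse = TRUE))
    rownames(S) <- mets
  }
  newcol <- Matrix::sparseMatrix(i = match(names(stoich), mets),
                                 j = rep(1L, length(stoich)),
                                 x = as.numeric(stoich),
                                 dims = c(length(mets), 1L))
  S <- cbind(S, newcol)
  j <- ncol(S)
  forms <- model$formulas
  if (!is.null(forms) && length(missing)) {
    forms <- c(forms, stats::setNames(rep(NA_character_, length(missing)), missing))
  }
  metabolic_model(mets, c(model$reactions, id), S,
                  c(model$lb, lb), c(model$ub, ub), biomass = model$biomass,
                  production = model$production,
                  exchange = if (role == "exchange") c(model$exchange, j) else model$exchange,
                  sinks = if (role == "sink") c(model$sinks, j) else model$sinks,
                  formulas = forms, id = model$id)
}

#' Add a production reaction to a model
#'
#' Appends a reaction assembling a product from precursors (e.g. a lipopeptide
#' from its amino acids and fatty-acyl carrier), marks it as the model's
#' production reaction, and reports the elemental mass balance when metabolite
#' formulas are available.
#'
#' @param model a `metabolic_model`.
#' @param recipe a [reaction_recipe()].
#' @param create_missing create metabolites not present in the model (e.g.
#'   the product species).
#' @return the extended model.
#' @export
add_production_reaction <- function(model, recipe, create_missing = FALSE) {
  stopifnot(inherits(recipe, "reaction_recipe"))
  out <- append_column(model, recipe$id, recipe$stoichiometry,
                       recipe$lower_bound, recipe$upper_bound,
                       role = "internal", create_missing = create_missing)
  out$production <- recipe$id
  report_mass_balance(out, recipe)
  out
}

report_mass_balance <- function(model, recipe) {
  mets <- names(recipe$stoichiometry)
  if (is.null(model$formulas) || any(is.na(model$formulas[mets]))) {
    warning("mass-balance check skipped: metabolite formulas unavailable for '",
            recipe$id, "'", call. = FALSE)
    return(invisible(NULL))
  }
  tot <- list()
  for (k in seq_along(mets)) {
    el <- parse_formula(model$formulas[[mets[k]]])
    for (e in names(el)) tot[[e]] <- (tot[[e]] %||% 0) + recipe$stoichiometry[k] * el[[e]]
  }
  imb <- unlist(tot)
  imb <- imb[abs(imb) > 1e-6]
  if (length(imb)) {
    message("reaction '", recipe$id, "' elemental imbalance: ",
            paste(names(imb), round(imb, 4), collapse = ", "))
  } else {
    message("reaction '", recipe$id, "' is elementally balanced")
  }
  invisible(imb)
}

parse_formula <- function(f) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", f)[[1]]
  parts <- regmatches(f, list(m))[[1]]
  out <- list()
  for (p in parts) {
    el <- sub("^([A-Z][a-z]?).*$", "\\1", p)
    cnt <- sub("^[A-Z][a-z]?", "", p)
    out[[el]] <- (out[[el]] %||% 0) + if (nzchar(cnt)) as.numeric(cnt) else 1
  }
  out
}

#' Add a sink reaction
#'
#' Appends a boundary reaction that removes `metabolite` from the network.
#' Sinks are never medium decision variables; a positive lower bound enforces
#' a minimum production flux (e.g. 0.0001 mmol/gDW/h for a lipopeptide sink).
#'
#' @param model a `metabolic_model`.
#' @param metabolite metabolite identifier.
#' @param lower_bound minimum sink flux (mmol/gDW/h).
#' @param upper_bound maximum sink flux.
#' @return the extended model.
#' @export
add_sink <- function(model, metabolite, lower_bound = 1e-4, upper_bound = BIG_BOUND) {
  if (!(metabolite %in% model$metabolites)) stop("unknown metabolite: ", metabolite)
  id <- paste0("SK_", metabolite)
  existing <- model$reactions[model$sinks]
  if (id %in% existing) stop("sink for '", metabolite, "' already present")
  append_column(model, id, stats::setNames(-1, metabolite),
                lower_bound, upper_bound, role = "sink")
}

#' Remove a reaction from a model
#'
#' Drops the reaction's column; metabolites left without any reaction are
#' dropped too, so `remove_reaction(add_*(model, ...), id)` restores the
#' original stoichiometry.
#'
#' @param model a `metabolic_model`.
#' @param id reaction identifier.
#' @return the reduced model.
#' @export
remove_reaction <- function(model, id) {
  j <- match(id, model$reactions)
  if (is.na(j)) stop("unknown reaction: ", id)
  if (id == model$biomass) stop("refusing to remove the biomass reaction")
  keep <- setdiff(seq_along(model$reactions), j)
  S <- model$S[, keep, drop = FALSE]
  orphan <- which(Matrix::rowSums(S != 0) == 0)
  keep_m <- setdiff(seq_along(model$metabolites), orphan)
  remap <- function(idx) match(model$reactions[setdiff(idx, j)], model$reactions[keep])
  metabolic_model(model$metabolites[keep_m], model$reactions[keep],
                  S[keep_m, , drop = FALSE],
                  model$lb[keep], model$ub[keep], biomass = model$biomass,
                  production = if (identical(model$production, id)) NULL else model$production,
                  exchange = remap(model$exchange), sinks = remap(model$sinks),
                  formulas = model$formulas[model$metabolites[keep_m]],
                  id = model$id)
}
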