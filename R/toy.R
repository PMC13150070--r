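# Small synthetic metabolic models with analytically known
# growth/production/cost trade-offs, plus a grid-enumeration oracle for the
# outer problem. These stand in for full genome-scale reconstructions so the
# whole stack is testable without downloads.

#' Specify a toy genome-scale model
#'
#' The generated network has one import reaction per nutrient and a biomass
#' reaction consuming `demands[i]` units of nutrient i, so optimal growth is
#' `min_i(u_i / demands[i])` over the uptake bounds `u`. An optional product
#' branch diverts the first (or chosen) nutrient into a product metabolite
#' with its own sink, creating a growth/production trade-off on the shared
#' precursor.
#'
#' @param n_nutrients number of import reactions (>= 2).
#' @param demands per-nutrient biomass stoichiometric demand (> 0); recycled
#'   to length `n_nutrients`.
#' @param product_branch `NULL`, or list with `precursor` (nutrient index)
#'   and `yield` (precursor units per product unit, > 0).
#' @param prices per-nutrient price (recycled).
#' @param box_upper per-nutrient search upper bound (recycled).
#' @param seed integer stored for provenance.
#' @return an object of class `toy_gem_spec`.
#' @export
toy_gem_spec <- function(n_nutrients = 2, demands = c(1, 2),
                         product_branch = NULL, prices = 1,
                         box_upper = 10, seed = 1L) {
  stopifnot(n_nutrients >= 2)
  demands <- rep_len(demands, n_nutrients)
  if (any(demands <= 0)) stop("demands must be > 0")
  if (!is.null(product_branch)) {
    stopifnot(product_branch$precursor %in% seq_len(n_nutrients),
              product_branch$yield > 0)
  }
  structure(list(n_nutrients = n_nutrients, demands = demands,
                 product_branch = product_branch,
                 prices = rep_len(prices, n_nutrients),
                 box_upper = rep_len(box_upper, n_nutrients),
                 seed = as.integer(seed)),
            class = "toy_gem_spec")
}

#' Build a toy metabolic model with a closed-form optimum
#'
#' @param spec a [toy_gem_spec()].
#' @return list with `model` (a `metabolic_model`), `medium` (a matching
#'   [medium_spec()]), `prices` (a [price_table()]), and `closed_form`, a
#'   function(uptakes, biomass_weight, production_weight) returning the exact
#'   LP optimum `list(growth, production)` computed independently of the
#'   solver (piecewise-linear analysis of the single trade-off variable).
#' @export
make_toy_gem <- function(spec) {
  stopifnot(inherits(spec, "toy_gem_spec"))
  k <- spec$n_nutrients
  nut <- paste0("N", seq_len(k))
  imp <- paste0("EX_N", seq_len(k))
  mets <- nut
  rxns <- c(imp, "BIOMASS")
  # imports: uptake-positive single-entry columns; biomass consumes demands
  S <- cbind(Matrix::Diagonal(k), -spec$demands)
  lb <- c(rep(0, k), 0)
  ub <- c(spec$box_upper, BIG_BOUND)
  production <- NULL
  sinks <- integer()
  if (!is.null(spec$product_branch)) {
    p <- spec$product_branch$precursor
    b <- spec$product_branch$yield
    mets <- c(nut, "PROD")
    prod_col <- numeric(k + 1)
    prod_col[p] <- -b
    prod_col[k + 1] <- 1
    sink_col <- c(numeric(k), -1)
    S <- rbind(S, Matrix::Matrix(0, 1, ncol(S), sparse = TRUE))
    S <- cbind(S, prod_col, sink_col)
    rxns <- c(rxns, "PRODUCT", "SK_PROD")
    lb <- c(lb, 0, 0)
    ub <- c(ub, BIG_BOUND, BIG_BOUND)
    production <- "PRODUCT"
    sinks <- length(rxns)
  }
  model <- metabolic_model(mets, rxns, S, lb, ub, biomass = "BIOMASS",
                           production = production, exchange = seq_len(k),
                           sinks = sinks, id = "toy")
  comp <- data.frame(component = nut, reaction_id = imp, role = "decision",
                     baseline_value = spec$box_upper / 2,
                     box_upper = spec$box_upper, unit = "flux",
                     stringsAsFactors = FALSE)
  medium <- medium_spec(comp)
  prices <- price_table(stats::setNames(spec$prices, imp))
  a <- spec$demands
  branch <- spec$product_branch
  closed_form <- function(uptakes, biomass_weight = 1, production_weight = 0) {
    u <- as.numeric(uptakes)
    if (is.null(branch)) {
      return(list(growth = min(u / a), production = NA_real_))
    }
    p <- branch$precursor; b <- branch$yield
    other <- setdiff(seq_len(length(u)), p)
    cap_other <- if (length(other)) min(u[other] / a[other]) else Inf
    # growth(vp) = min(cap_other, (u[p] - b*vp)/a[p]); objective piecewise
    # linear in vp on [0, u[p]/b]: evaluate vertices
    vp_breaks <- c(0, u[p] / b)
    kink <- (u[p] - a[p] * cap_other) / b  # where precursor becomes binding
    if (kink > 0 && kink < u[p] / b) vp_breaks <- c(vp_breaks, kink)
    s <- biomass_weight + production_weight
    wB <- biomass_weight / s; wP <- production_weight / s
    vals <- vapply(vp_breaks, function(vp) {
      g <- min(cap_other, (u[p] - b * vp) / a[p])
      wB * g + wP * vp
    }, numeric(1))
    best <- vp_breaks[which.max(vals)]
    # tie-break toward zero production when the production weight is zero
    if (wP == 0) best <- 0
    list(growth = min(cap_other, (u[p] - b * best) / a[p]), production = best)
  }
  list(model = model, medium = medium, prices = prices, closed_form = closed_form)
}

#' Brute-force Pareto front by grid enumeration
#'
#' Evaluates the outer objectives on a full grid over the decision box
#' (inclusive endpoints, so the all-zero and all-max media are always
#' evaluated) and returns the non-dominated subset. Ground-truth oracle for
#' the Bayesian optimizer on problems with few decision variables.
#'
#' @param model a `metabolic_model`.
#' @param spec a [medium_spec()].
#' @param prices a [price_table()].
#' @param fba_objective inner [flux_objective()] or `NULL`.
#' @param grid_per_dim grid points per decision variable.
#' @param objectives objective subset, as in [run_mobo()].
#' @param solver inner solver.
#' @return list with `dataset` (all grid evaluations as a `sample_dataset`)
#'   and `front` (its [pareto_front()]).
#' @export
brute_force_pareto <- function(model, spec, prices, fba_objective = NULL,
                               grid_per_dim = 21, objectives = c("growth", "cost"),
                               solver = c("fba", "pfba")) {
  solver <- match.arg(solver)
  box <- decision_box(spec)
  if (length(box) > 4) {
    stop("grid enumeration supports at most 4 decision variables; ",
         "use run_mobo() for larger spaces")
  }
  grids <- lapply(box, function(b) seq(0, b, length.out = grid_per_dim))
  X <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  colnames(X) <- names(box)
  Y <- do.call(rbind, lapply(seq_len(nrow(X)), function(i) {
    evaluate_objectives(model, spec, X[i, ], prices, fba_objective, solver = solver)
  }))
  dataset <- new_sample_dataset(X, Y, rep(0L, nrow(X)), spec, objectives)
  list(dataset = dataset, front = pareto_front(dataset))
}

#' Editable case-study configuration skeletons
#'
#' Emits medium and price tables for the three published design campaigns:
#' M9-grown wild-type *E. coli* (10 decision variables), antibody-fragment
#' production in *E. coli* (those plus glutamine/arginine/asparagine
#' supplementation at 9.9/9.5/6.1 mM), and surfactin production in
#' *B. subtilis* (13 components, chloride and sodium excluded). Prices are
#' clearly marked placeholders to be replaced with vendor quotes; exchange
#' identifiers follow BiGG naming and may need adjustment for other model
#' versions.
#'
#' @param case one of `"ecoli_m9"`, `"ecoli_antibody"`,
#'   `"bsubtilis_surfactin"`.
#' @return list with `medium` (a [medium_spec()]), `prices` (placeholder
#'   [price_table()]), `fba_ratio` (biomass:production weights), and `notes`.
#' @export
make_case_study_config <- function(case = c("ecoli_m9", "ecoli_antibody",
                                            "bsubtilis_surfactin")) {
  case <- match.arg(case)
  m9 <- data.frame(
    component = c("ammonium", "calcium", "chloride", "glucose", "magnesium",
                  "potassium", "phosphate", "sodium", "sulfate", "oxygen"),
    reaction_id = c("EX_nh4_e", "EX_ca2_e", "EX_cl_e", "EX_glc__D_e",
                    "EX_mg2_e", "EX_k_e", "EX_pi_e", "EX_na1_e",
                    "EX_so4_e", "EX_o2_e"),
    role = "decision",
    baseline_value = c(18.7, 0.1, 18.7, 20, 2, 22, 42, 42, 2, 40),
    box_upper = c(40, 2, 40, 40, 10, 60, 90, 90, 10, 40),
    unit = c("mM", "mM", "mM", "mM", "mM", "mM", "mM", "mM", "mM", "flux"),
    stringsAsFactors = FALSE)
  # oxygen is supplied by stirring: cap 20 mmol/gDW/h, price 0
  m9$baseline_value[m9$component == "oxygen"] <- 20
  m9$box_upper[m9$component == "oxygen"] <- 20
  placeholder_price <- function(components) {
    z <- rep(1, length(components))          # PLACEHOLDER, not vendor prices
    names(z) <- components
    z
  }
  if (case == "ecoli_m9") {
    spec <- medium_spec(m9)
    z <- placeholder_price(m9$reaction_id)
    z["EX_o2_e"] <- 0
    return(list(medium = spec, prices = price_table(z),
                fba_ratio = c(biomass = 1, production = 0),
                notes = paste("Prices are unit placeholders; replace with",
                              "vendor quotes. Glucose baseline 20 mM maps to",
                              "an uptake bound of 10 mmol/gDW/h.")))
  }
  if (case == "ecoli_antibody") {
    aa <- data.frame(
      component = c("glutamine", "arginine", "asparagine"),
      reaction_id = c("EX_gln__L_e", "EX_arg__L_e", "EX_asn__L_e"),
      role = "decision",
      baseline_value = c(9.9, 9.5, 6.1),
      box_upper = c(20, 20, 20),
      unit = "mM", stringsAsFactors = FALSE)
    tab <- rbind(m9, aa)
    spec <- medium_spec(tab)
    z <- placeholder_price(tab$reaction_id)
    z["EX_o2_e"] <- 0
    return(list(medium = spec, prices = price_table(z),
                fba_ratio = c(biomass = 99, production = 1),
                notes = paste("13 decision variables; amino acid baselines",
                              "9.9/9.5/6.1 mM. FBA objective 99:1",
                              "biomass:production. Prices are placeholders.")))
  }
  # surfactin case: M9 minus chloride/sodium, plus iron, protons, water, CO2
  keep <- !(m9$component %in% c("chloride", "sodium"))
  # iron enters as both oxidation states (ferric and ferrous exchanges are
  # separate reactions in these reconstructions), giving 13 decision
  # variables with chloride and sodium excluded
  extra <- data.frame(
    component = c("iron_iii", "iron_ii", "protons", "water", "co2"),
    reaction_id = c("EX_fe3_e", "EX_fe2_e", "EX_h_e", "EX_h2o_e", "EX_co2_e"),
    role = "decision",
    baseline_value = c(0.1, 0.1, 10, 50, 10),
    box_upper = c(2, 2, 40, 100, 40),
    unit = c("mM", "mM", "flux", "flux", "flux"),
    stringsAsFactors = FALSE)
  tab <- rbind(m9[keep, ], extra)
  spec <- medium_spec(tab)
  z <- placeholder_price(tab$reaction_id)
  z[c("EX_o2_e", "EX_h_e", "EX_h2o_e", "EX_co2_e")] <- 0
  list(medium = spec, prices = price_table(z),
       fba_ratio = c(biomass = 95, production = 5),
       notes = paste("13 decision variables (chloride and sodium excluded).",
                     "Add the lipopeptide assembly reaction and a product",
                     "sink with lower bound 0.0001 mmol/gDW/h before",
                     "optimizing; FBA objective 95:5 biomass:production.",
                     "Exchange ids must match the model version in use.",
                     "Prices are placeholders."))
}
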