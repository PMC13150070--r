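# Pareto front extraction and downstream analyses: best-ratio traces,
# composition PCA, per-component distributions, plot filtering, and
# perturbation-based sensitivity around the front.

#' Non-domination mask
#'
#' Row `a` dominates row `b` iff `a >= b` component-wise with at least one
#' strict inequality (all objectives oriented for maximization). Duplicated
#' rows never dominate each other and are all retained as non-dominated.
#'
#' @param Y numeric matrix of oriented objectives, one sample per row.
#' @return logical vector, `TRUE` for non-dominated rows.
#' @export
pareto_mask <- function(Y) {
  Y <- as.matrix(Y)
  if (nrow(Y) == 0) stop("empty objective matrix")
  n <- nrow(Y)
  mask <- rep(TRUE, n)
  ord <- do.call(order, c(lapply(seq_len(ncol(Y)), function(j) -Y[, j])))
  Ys <- Y[ord, , drop = FALSE]
  ms <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!ms[i]) next
    yi <- Ys[i, ]
    if (i < n) {
      js <- which(ms) ; js <- js[js > i]
      if (length(js)) {
        geq <- rowSums(sweep(Ys[js, , drop = FALSE], 2, yi, "<=")) == ncol(Y)
        strict <- rowSums(sweep(Ys[js, , drop = FALSE], 2, yi, "<")) > 0
        ms[js[geq & strict]] <- FALSE
      }
    }
  }
  mask[ord] <- ms
  mask
}

#' Extract the Pareto front of a dataset
#'
#' @param dataset a `sample_dataset`.
#' @return an object of class `pareto_front` with `member_indices`,
#'   `Y_members` (oriented objectives), and `X_members` (raw compositions).
#' @export
pareto_front <- function(dataset) {
  Y <- dataset_oriented(dataset)
  mask <- pareto_mask(Y)
  structure(list(member_indices = which(mask),
                 Y_members = Y[mask, , drop = FALSE],
                 X_members = dataset$X_raw[mask, , drop = FALSE],
                 objectives = dataset$objectives),
            class = "pareto_front")
}

#' @export
print.pareto_front <- function(x, ...) {
  cat("pareto_front: ", length(x$member_indices), " members over objectives ",
      paste(x$objectives, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Running best objective ratio
#'
#' Per-sample ratio of two raw objectives in evaluation order, together with
#' its running maximum (e.g. the best growth-per-cost medium seen so far).
#' Samples with a zero denominator are excluded with a note.
#'
#' @param dataset a `sample_dataset`.
#' @param numerator,denominator objective names.
#' @return data frame: `sample`, `iteration`, `ratio`, `best_so_far`.
#' @export
best_ratio_trace <- function(dataset, numerator = "growth", denominator = "cost") {
  num <- dataset$Y_raw[[numerator]]
  den <- dataset$Y_raw[[denominator]]
  if (is.null(num) || is.null(den)) stop("objective not present in dataset")
  keep <- den > 0
  if (!any(keep)) stop("all '", denominator, "' values are zero")
  if (!all(keep)) message(sum(!keep), " sample(s) with zero ", denominator, " excluded")
  ratio <- num[keep] / den[keep]
  data.frame(sample = which(keep), iteration = dataset$iteration[keep],
             ratio = ratio, best_so_far = cummax(ratio))
}

#' Filter low-growth samples (plot-only view)
#'
#' Returns a filtered copy of the dataset excluding samples with growth below
#' `threshold` (default 0.001 per hour); the input dataset is untouched.
#'
#' @param dataset a `sample_dataset`.
#' @param threshold growth cutoff in 1/h.
#' @return a filtered `sample_dataset`.
#' @export
filter_low_growth <- function(dataset, threshold = 0.001) {
  keep <- dataset$Y_raw$growth >= threshold
  new_sample_dataset(dataset$X_raw[keep, , drop = FALSE],
                     dataset$Y_raw[keep, , drop = FALSE],
                     dataset$iteration[keep], dataset$spec, dataset$objectives)
}

#' PCA of medium compositions
#'
#' Principal component analysis of the composition matrix, by default after
#' centering and unit-scaling each component (components have heterogeneous
#' physical ranges).
#'
#' @param X composition matrix (samples x components).
#' @param scale. unit-scale columns (default `TRUE`).
#' @return list with `scores`, `loadings`, and `explained` (variance
#'   fractions summing to 1).
#' @export
pca_media <- function(X, scale. = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) < 2 || ncol(X) < 2) stop("PCA needs >= 2 samples and >= 2 components")
  sds <- apply(X, 2, stats::sd)
  if (scale. && any(sds < 1e-12)) {
    stop("constant component(s): ",
         paste(colnames(X)[sds < 1e-12], collapse = ", "))
  }
  p <- stats::prcomp(X, center = TRUE, scale. = scale.)
  list(scores = p$x, loadings = p$rotation,
       explained = p$sdev^2 / sum(p$sdev^2))
}

#' Distribution of components across a Pareto front
#'
#' Five-number summary (box-plot statistics) of each decision variable across
#' the front, in box-normalized coordinates (`X / box_upper`), plus a flag
#' for "tight" components whose interquartile range is below a fraction of
#' the box.
#'
#' @param front a [pareto_front()].
#' @param spec the [medium_spec()] of the run.
#' @param tight_fraction IQR threshold (fraction of the unit box) below which
#'   a component counts as tightly optimized.
#' @return data frame, one row per decision variable: `component`,
#'   `min`, `q25`, `median`, `q75`, `max`, `iqr`, `tight`.
#' @export
component_distributions <- function(front, spec, tight_fraction = 0.1) {
  stopifnot(length(front$member_indices) >= 1)
  box <- decision_box(spec)
  Xn <- sweep(front$X_members, 2, box[colnames(front$X_members)], "/")
  qs <- t(apply(Xn, 2, stats::quantile, probs = c(0, 0.25, 0.5, 0.75, 1),
                type = 7))
  out <- data.frame(component = colnames(Xn),
                    min = qs[, 1], q25 = qs[, 2], median = qs[, 3],
                    q75 = qs[, 4], max = qs[, 5],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$iqr <- out$q75 - out$q25
  out$tight <- out$iqr < tight_fraction
  out
}

#' Perturbation sensitivity of a Pareto front
#'
#' Samples media around each front member from an isotropic normal in
#' box-normalized coordinates (standard deviation `sigma`, clipped to the
#' box), evaluates their objectives, and classifies each perturbation as
#' `"inward"` (dominated by the existing front) or `"outside-envelope"`
#' (non-dominated with respect to it). Perturbed objectives are oriented with
#' the normalization constants of the original dataset so the comparison is
#' consistent.
#'
#' @param dataset the originating `sample_dataset`.
#' @param front its [pareto_front()].
#' @param sigmas vector of perturbation scales (fractions of the box).
#' @param n_per_center samples per front member per sigma.
#' @param evaluator function(named bounds vector) -> one-row data frame as
#'   returned by [evaluate_objectives()].
#' @param seed integer seed.
#' @return data frame with one row per perturbation: `sigma`, `center`,
#'   composition columns, objective columns, `classification`.
#' @export
perturb_pareto <- function(dataset, front, sigmas, n_per_center, evaluator,
                           seed = 1L) {
  stopifnot(length(front$member_indices) >= 1, all(sigmas > 0))
  box <- dataset$box_upper
  d <- length(box)
  Yor <- dataset_oriented(dataset)
  consts <- attr(Yor, "constants")
  Yfront <- front$Y_members
  centers_unit <- sweep(front$X_members, 2, box, "/")
  out <- list()
  for (si in seq_along(sigmas)) {
    sg <- sigmas[si]
    pert <- with_seed(substream_seed(seed, paste0("perturb-", si)), {
      do.call(rbind, lapply(seq_len(nrow(centers_unit)), function(ci) {
        Z <- matrix(stats::rnorm(n_per_center * d, 0, sg), n_per_center, d)
        U <- sweep(Z, 2, centers_unit[ci, ], "+")
        cbind(center = ci, pmin(pmax(U, 0), 1))
      }))
    })
    if (is.null(pert) || nrow(pert) == 0) next
    Xr <- sweep(pert[, -1, drop = FALSE], 2, box, "*")
    colnames(Xr) <- names(box)
    Yr <- do.call(rbind, lapply(seq_len(nrow(Xr)), function(i) evaluator(Xr[i, ])))
    Ypert <- apply_orientation(Yr, dataset$objectives, consts)
    cls <- vapply(seq_len(nrow(Ypert)), function(i) {
      m <- pareto_mask(rbind(Yfront, Ypert[i, ]))
      if (m[nrow(Yfront) + 1]) "outside-envelope" else "inward"
    }, character(1))
    out[[si]] <- data.frame(sigma = sg, center = pert[, 1], Xr, Yr,
                            classification = cls, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Dominated hypervolume (diagnostic)
#'
#' Volume of oriented objective space dominated by a point set relative to a
#' reference point (default the origin). Exact sweep for two objectives;
#' deterministic Monte Carlo estimate for three or more. A repository
#' diagnostic for front quality, not a quantity of the underlying method.
#'
#' @param Y oriented objective matrix (maximization).
#' @param ref reference point (default zero vector).
#' @param mc_samples Monte Carlo sample count for d >= 3.
#' @return scalar hypervolume.
#' @export
dominated_hypervolume <- function(Y, ref = NULL, mc_samples = 200000L) {
  Y <- as.matrix(Y)
  d <- ncol(Y)
  if (is.null(ref)) ref <- rep(0, d)
  keep <- rowSums(sweep(Y, 2, ref, ">")) == d
  Y <- Y[keep, , drop = FALSE]
  if (nrow(Y) == 0) return(0)
  Y <- Y[pareto_mask(Y), , drop = FALSE]
  if (d == 2) {
    ord <- order(Y[, 1], decreasing = TRUE)
    Ys <- Y[ord, , drop = FALSE]
    hv <- 0
    y2max <- ref[2]
    for (i in seq_len(nrow(Ys))) {
      if (Ys[i, 2] > y2max) {
        hv <- hv + (Ys[i, 1] - ref[1]) * (Ys[i, 2] - y2max)
        y2max <- Ys[i, 2]
      }
    }
    return(hv)
  }
  hi <- apply(Y, 2, max)
  U <- with_seed(987654L, matrix(stats::runif(mc_samples * d), ncol = d))
  P <- sweep(sweep(U, 2, hi - ref, "*"), 2, ref, "+")
  dominated <- rep(FALSE, nrow(P))
  for (i in seq_len(nrow(Y))) {
    dominated <- dominated | (rowSums(sweep(P, 2, Y[i, ], "<=")) == d)
  }
  mean(dominated) * prod(hi - ref)
}

#' Generational distance between two fronts (diagnostic)
#'
#' Mean Euclidean distance from each point of `front` to its nearest point in
#' `reference`, in oriented objective space.
#'
#' @param front,reference oriented objective matrices.
#' @return scalar distance.
#' @export
generational_distance <- function(front, reference) {
  front <- as.matrix(front); reference <- as.matrix(reference)
  d2 <- outer(rowSums(front^2), rowSums(reference^2), "+") -
    2 * tcrossprod(front, reference)
  mean(sqrt(pmax(apply(d2, 1, min), 0)))
}
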