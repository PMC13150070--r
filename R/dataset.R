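# Accumulated (medium, objective-vector) samples from an optimization run.

new_sample_dataset <- function(X_raw, Y_raw, iteration, spec, objectives) {
  box <- decision_box(spec)
  X_raw <- as.matrix(X_raw)
  colnames(X_raw) <- names(box)
  stopifnot(nrow(X_raw) == nrow(Y_raw), length(iteration) == nrow(X_raw))
  structure(list(
    X_raw = X_raw,
    X_unit = sweep(X_raw, 2, box, "/"),
    Y_raw = Y_raw,
    iteration = as.integer(iteration),
    objectives = objectives,
    box_upper = box,
    spec = spec
  ), class = "sample_dataset")
}

append_samples <- function(dataset, X_new, Y_new, iteration) {
  new_sample_dataset(rbind(dataset$X_raw, X_new),
                     rbind(dataset$Y_raw, Y_new),
                     c(dataset$iteration, rep(iteration, nrow(as.matrix(X_new)))),
                     dataset$spec, dataset$objectives)
}

#' Oriented objective matrix of a dataset
#'
#' Convenience wrapper around [orient_and_normalize()] using the dataset's
#' objective set; constants are recomputed from the full accumulated data.
#'
#' @param dataset a `sample_dataset`.
#' @return oriented objective matrix with a `"constants"` attribute.
#' @export
dataset_oriented <- function(dataset) {
  orient_and_normalize(dataset$Y_raw, dataset$objectives)
}

#' @export
print.sample_dataset <- function(x, ...) {
  cat("sample_dataset: ", nrow(x$X_raw), " samples, ",
      ncol(x$X_raw), " decision variables, objectives: ",
      paste(x$objectives, collapse = "/"), "\n", sep = "")
  cat("  iterations 0..", max(x$iteration), "; feasible: ",
      sum(x$Y_raw$feasible), "/", nrow(x$X_raw), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.sample_dataset <- function(x, ...) {
  Xd <- as.data.frame(x$X_raw)
  names(Xd) <- paste0("bound_", colnames(x$X_raw))
  cbind(sample = seq_len(nrow(Xd)), iteration = x$iteration, Xd, x$Y_raw)
}

#' Number of samples in a dataset
#' @param dataset a `sample_dataset`.
#' @return integer count.
#' @export
n_samples <- function(dataset) nrow(dataset$X_raw)
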