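# Run artifacts: samples table, Pareto front table, machine-readable
# manifest. Tables are CSV with a fixed documented column order; the manifest
# is JSON. Column order of samples.csv:
#   sample, iteration, bound_<rid>... (raw physical bounds),
#   growth/production/cost (raw), oriented_<objective>..., feasible, status,
#   pareto.

#' Write run artifacts
#'
#' Writes `samples.csv` (one row per evaluated medium), `front.csv` (the
#' Pareto-optimal subset), and `manifest.json` (config snapshot, seed, model
#' checksum) into `out_dir`. The manifest contains no timestamps, so two runs
#' with the same seed produce identical artifacts.
#'
#' @param dataset a non-empty `sample_dataset`.
#' @param front its [pareto_front()]; computed from `dataset` when `NULL`.
#' @param out_dir output directory (created if needed).
#' @param config optional [optimization_config()] to record.
#' @param model optional `metabolic_model` whose checksum to record.
#' @param force overwrite existing artifact files.
#' @return invisible character vector of the three file paths.
#' @export
write_samples <- function(dataset, front = NULL, out_dir, config = NULL,
                          model = NULL, force = FALSE) {
  stopifnot(n_samples(dataset) >= 1)
  if (is.null(front)) front <- pareto_front(dataset)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- file.path(out_dir, c("samples.csv", "front.csv", "manifest.json"))
  if (!force && any(file.exists(paths))) {
    stop("artifacts already present in '", out_dir, "'; use force = TRUE")
  }
  Yor <- dataset_oriented(dataset)
  colnames(Yor) <- paste0("oriented_", colnames(Yor))
  tab <- as.data.frame(dataset)
  tab <- cbind(tab[setdiff(names(tab), c("feasible", "status"))], Yor,
               feasible = tab$feasible, status = tab$status,
               pareto = seq_len(nrow(tab)) %in% front$member_indices)
  ok <- tryCatch({
    write_csv_exact(tab, paths[1])
    write_csv_exact(tab[tab$pareto, , drop = FALSE], paths[2])
    TRUE
  }, error = function(e) stop("cannot write artifacts to '", out_dir, "': ",
                              conditionMessage(e)))
  manifest <- list(
    tool = "fluxmedia",
    version = as.character(utils::packageVersion("fluxmedia")),
    objectives = dataset$objectives,
    n_samples = n_samples(dataset),
    n_front = length(front$member_indices),
    decision_variables = colnames(dataset$X_raw),
    box_upper = as.list(dataset$box_upper),
    seed = if (!is.null(config)) config$seed else NULL,
    config = if (!is.null(config)) config[c("n_init", "n_iter", "batch_size",
                                            "seed", "rho", "solver",
                                            "acquisition_restarts",
                                            "raw_samples")] else NULL,
    model_checksum = if (!is.null(model)) model_checksum(model) else NULL
  )
  jsonlite::write_json(manifest[!vapply(manifest, is.null, logical(1))],
                       paths[3], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

# CSV with %.17g doubles so that read.csv restores bit-identical values
# (write.csv prints only 15 significant digits)
write_csv_exact <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
}

#' Read run artifacts back
#'
#' @param out_dir directory written by [write_samples()].
#' @return list with `samples` and `front` data frames and the `manifest`
#'   list.
#' @export
read_samples <- function(out_dir) {
  paths <- file.path(out_dir, c("samples.csv", "front.csv", "manifest.json"))
  if (!all(file.exists(paths))) {
    stop("missing artifact(s) in '", out_dir, "': ",
         paste(basename(paths)[!file.exists(paths)], collapse = ", "))
  }
  samples <- tryCatch(utils::read.csv(paths[1], stringsAsFactors = FALSE),
                      error = function(e) stop("corrupt samples.csv: ",
                                               conditionMessage(e)))
  front <- utils::read.csv(paths[2], stringsAsFactors = FALSE)
  manifest <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  list(samples = samples, front = front, manifest = manifest)
}
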