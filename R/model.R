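# Internal constructor shared by the trainer and the model reader.
new_gps_model <- function(algorithm, clustering_window, clustering_matrix,
                          clusters, sp_fix, calibration_levels, seed,
                          log = NULL) {
  stopifnot(length(clusters) >= 1L)
  check_matrix(clustering_matrix)
  for (cl in clusters) {
    if (!is.null(cl$cutoffs)) {
      co <- cl$cutoffs
      stopifnot(co[["high"]] >= co[["medium"]], co[["medium"]] >= co[["low"]])
    }
    stopifnot(length(cl$weights) == cl$window[[1L]] + 1L + cl$window[[2L]])
  }
  structure(list(algorithm = algorithm,
                 clustering_window = clustering_window,
                 clustering_matrix = clustering_matrix,
                 clusters = clusters,
                 sp_fix = sp_fix,
                 calibration_levels = calibration_levels,
                 seed = seed,
                 log = log),
            class = "gps_model")
}

#' @export
print.gps_model <- function(x, ...) {
  cat("Group-based site predictor (", x$algorithm, "), ",
      length(x$clusters), " cluster(s)\n", sep = "")
  for (cl in x$clusters) {
    cat(sprintf("  cluster %s: NSP(%d, %d), %d reference positives, cutoffs %s\n",
                cl$id, cl$window[[1L]], cl$window[[2L]], length(cl$positives),
                paste(sprintf("%s=%.3f", names(cl$cutoffs), cl$cutoffs),
                      collapse = " ")))
  }
  invisible(x)
}
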