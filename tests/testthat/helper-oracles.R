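# Independent brute-force oracles and fixture builders shared by the suite.
# The oracles deliberately use naive character-by-character loops and stay
# independent of the package's vectorised scoring paths.

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

oracle_pair_score <- function(a, b, mat, weights = NULL) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (is.null(weights)) weights <- rep(1, length(ca))
  s <- 0
  for (i in seq_along(ca)) {
    x <- if (ca[i] %in% rownames(mat)) ca[i] else "*"
    y <- if (cb[i] %in% rownames(mat)) cb[i] else "*"
    s <- s + weights[i] * mat[x, y]
  }
  max(0, s)
}

oracle_similarity <- function(a, b, mat) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  hits <- 0
  for (i in seq_along(ca)) {
    x <- if (ca[i] %in% rownames(mat)) ca[i] else "*"
    y <- if (cb[i] %in% rownames(mat)) cb[i] else "*"
    if (mat[x, y] > 0) hits <- hits + 1
  }
  hits / length(ca)
}

oracle_site_score <- function(query, refs, mat, weights) {
  mean(vapply(refs, function(r) oracle_pair_score(query, r, mat, weights),
              numeric(1)))
}

# AUC as the fraction of correctly ordered positive/negative pairs, ties 1/2.
oracle_auc <- function(scores, labels) {
  p <- scores[labels == "+"]
  n <- scores[labels == "-"]
  tot <- 0
  for (x in p) for (y in n) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(p) * length(n))
}

random_peptide <- function(len, pad_prob = 0.1) {
  paste(sample(c(AA, "*"), len, replace = TRUE,
               prob = c(rep((1 - pad_prob) / 20, 20), pad_prob)),
        collapse = "")
}

# Cysteine-centred random peptide of window (m, n).
random_nsp <- function(m, n) {
  paste0(paste(sample(AA, m, replace = TRUE), collapse = ""), "C",
         paste(sample(AA, n, replace = TRUE), collapse = ""))
}

# Small planted-signal dataset and a reduced-budget training configuration,
# the workhorses of the trainer tests.
small_sim <- function(seed, signal_strength = 0.4, n_proteins = 50,
                      n_pos = 80, n_neg = 400) {
  generate_dataset(simulation_config(
    n_proteins = n_proteins, length_mean = 200, n_pos_sites = n_pos,
    n_neg_sites = n_neg, signal_strength = signal_strength, seed = seed))
}

quick_config <- function(seed = 1, k = 2, ...) {
  args <- list(k = k, ps_max_m = 4, ps_max_n = 4, wt_max_stall = 60,
               mam_max_stall = 120, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(training_config, args)
}

# Hand-built single-cluster model for prediction-path tests.
toy_model <- function(positives, window = c(1L, 1L),
                      cutoffs = c(high = 10, medium = 5, low = 1)) {
  cl <- list(id = "A", window = window,
             weights = rep(1L, window[1] + 1L + window[2]),
             matrix = blosum62(), positives = positives,
             positives_ref = vapply(positives, function(p) {
               # centre the toy peptides in the clustering window by padding
               m <- (nchar(p) - 1L) %/% 2L
               paste0(strrep("*", 7L - m), p, strrep("*", 7L - (nchar(p) - 1L - m)))
             }, character(1), USE.NAMES = FALSE),
             sites = data.frame(protein_id = sprintf("ref%d", seq_along(positives)),
                                position = rep(1L, length(positives))),
             has = 1, cutoffs = cutoffs,
             achieved_sp = c(high = NA_real_, medium = NA_real_,
                             low = NA_real_))
  gpsno:::new_gps_model(algorithm = "gps3", clustering_window = c(7L, 7L),
                        clustering_matrix = blosum62(), clusters = list(cl),
                        sp_fix = 0.8,
                        calibration_levels = c(high = 0.9, medium = 0.85,
                                               low = 0.8),
                        seed = 1L)
}
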