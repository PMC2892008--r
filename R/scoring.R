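#' Substitution score between two equal-length site peptides
#'
#' The score of peptides `A` and `B` is the position-wise sum of substitution
#' scores, floored at zero: `S(A, B) = max(0, sum_i Score(A_i, B_i))`.
#' Padding positions (`*`) and non-standard residues contribute 0.
#'
#' @param a,b Peptide strings of equal length.
#' @param matrix Substitution matrix from [blosum62()] or [read_matrix()].
#' @return Non-negative integer score.
#' @examples
#' pair_score("CCC", "CCC", blosum62())  # 27
#' pair_score("WWW", "GGG", blosum62())  # 0 (raw -6, floored)
#' @export
pair_score <- function(a, b, matrix = blosum62()) {
  if (nchar(a) != nchar(b))
    stop("peptides must have equal length (", nchar(a), " vs ", nchar(b), ")")
  codes <- encode_peptides(c(a, b))
  max(0L, sum(matrix[cbind(codes[1L, ], codes[2L, ])]))
}

#' Position-weighted substitution score between two site peptides
#'
#' Weighted form `S'(A, B) = max(0, sum_i w_i * Score(A_i, B_i))` with one
#' non-negative integer weight per window position.  With all weights 1 it
#' reduces to [pair_score()].
#'
#' @inheritParams pair_score
#' @param weights Numeric vector of non-negative per-position weights, same
#'   length as the peptides.
#' @return Non-negative numeric score.
#' @export
weighted_pair_score <- function(a, b, matrix = blosum62(), weights) {
  if (nchar(a) != nchar(b))
    stop("peptides must have equal length (", nchar(a), " vs ", nchar(b), ")")
  if (length(weights) != nchar(a))
    stop("weights length ", length(weights), " does not match peptide length ",
         nchar(a))
  if (any(weights < 0)) stop("position weights must be non-negative")
  codes <- encode_peptides(c(a, b))
  max(0, sum(weights * matrix[cbind(codes[1L, ], codes[2L, ])]))
}

#' Conserved-substitution similarity between two site peptides
#'
#' The similarity `s(A, B)` is the fraction of aligned positions whose
#' substitution score is positive (a conserved substitution); it ranges from 0
#' to 1.  The companion distance used for clustering is `D(A, B) = 1/s(A, B)`,
#' infinite when `s = 0`; the similarity itself is used directly everywhere,
#' so the infinite distance never needs materialising.
#'
#' @inheritParams pair_score
#' @return Numeric similarity in `[0, 1]`.
#' @examples
#' conserved_similarity("CW", "CG")  # 0.5
#' @export
conserved_similarity <- function(a, b, matrix = blosum62()) {
  if (nchar(a) != nchar(b))
    stop("peptides must have equal length (", nchar(a), " vs ", nchar(b), ")")
  codes <- encode_peptides(c(a, b))
  mean(matrix[cbind(codes[1L, ], codes[2L, ])] > 0)
}

# Pairwise similarity matrix between two peptide code matrices (internal):
# entry (i, j) = fraction of positions where codes_a[i, ] vs codes_b[j, ]
# is a conserved substitution.
similarity_matrix <- function(codes_a, codes_b, matrix) {
  n_pos <- ncol(codes_a)
  acc <- matrix(0, nrow = nrow(codes_a), ncol = nrow(codes_b))
  for (i in seq_len(n_pos)) {
    acc <- acc + (matrix[codes_a[, i], codes_b[, i], drop = FALSE] > 0)
  }
  acc / n_pos
}

# Mean floored weighted pair score of each query row against all reference
# rows (internal fast path behind site_score / LOO scoring).
mean_scores_vs_refs <- function(query_codes, ref_codes, matrix, weights) {
  raw <- matrix(0, nrow = nrow(query_codes), ncol = nrow(ref_codes))
  for (i in seq_len(ncol(query_codes))) {
    raw <- raw + weights[[i]] * matrix[query_codes[, i], ref_codes[, i],
                                       drop = FALSE]
  }
  rowMeans(pmax(raw, 0))
}

#' Score a query peptide against one trained cluster
#'
#' The site score is the arithmetic mean of the weighted pair scores between
#' the query and every reference positive peptide of the cluster, under the
#' cluster's own window, weights and (possibly mutated) matrix.  The mean (not
#' the sum) keeps scores comparable across clusters of different sizes.
#'
#' @param peptide Query peptide extracted with the cluster's window.
#' @param cluster One element of `model$clusters` (fields `positives`,
#'   `weights`, `matrix`).
#' @return Non-negative numeric score.
#' @export
site_score <- function(peptide, cluster) {
  if (length(cluster$positives) == 0L)
    stop("cluster has no reference positives; unusable")
  if (nchar(peptide) != nchar(cluster$positives[[1L]]))
    stop("query length ", nchar(peptide), " does not match cluster window")
  q <- encode_peptides(peptide)
  refs <- encode_peptides(cluster$positives)
  mean_scores_vs_refs(q, refs, cluster$matrix, cluster$weights)[[1L]]
}

#' Assign a clustering-window peptide to the most similar cluster
#'
#' A query peptide (extracted with the model's clustering window, by default
#' NSP(7, 7)) joins the cluster with the highest average conserved-substitution
#' similarity to that cluster's positive members, computed with the unmutated
#' clustering matrix — the same rule used to attach negative sites during
#' training.  Ties break to the lowest cluster index.
#'
#' @param peptide Peptide string in the clustering window.
#' @param model A `gps_model`.
#' @return Integer index into `model$clusters`.
#' @export
assign_cluster <- function(peptide, model) {
  if (length(model$clusters) == 0L) stop("model has no clusters")
  q <- encode_peptides(peptide)
  sims <- vapply(model$clusters, function(cl) {
    refs <- encode_peptides(cl$positives_ref)
    mean(similarity_matrix(q, refs, model$clustering_matrix))
  }, numeric(1))
  which.max(sims)  # which.max returns the first (lowest-index) maximum
}

#' Predict S-nitrosylation sites in protein sequences
#'
#' Every cysteine of every sequence is scored: the clustering-window peptide
#' is extracted and assigned to a cluster, the site is re-extracted with that
#' cluster's window and scored against the cluster's reference positives, and
#' the score is compared with the cluster's calibrated cutoffs.  At a given
#' threshold level only sites with `score >= cutoff[level]` are reported;
#' `level = "all"` reports every cysteine with the most stringent level it
#' passes (`"none"` if below the low cutoff).
#'
#' @param model Trained `gps_model`.
#' @param sequences Named character vector of protein sequences.
#' @param level `"high"`, `"medium"`, `"low"` or `"all"`.
#' @return Data frame with columns `protein_id`, `position`, `peptide`,
#'   `cluster`, `score`, `cutoff_high`, `cutoff_medium`, `cutoff_low`,
#'   `level`, sorted by protein then position.
#' @export
predict_sites <- function(model, sequences,
                          level = c("medium", "high", "low", "all")) {
  level <- match.arg(level)
  for (cl in model$clusters)
    if (is.null(cl$cutoffs)) stop("model is untrained: missing cutoffs")
  cw <- model$clustering_window
  rows <- list()
  for (pid in sort(names(sequences))) {
    seq <- sequences[[pid]]
    for (pos in enumerate_cysteines(seq)) {
      pep77 <- extract_nsp(seq, pos, cw[[1L]], cw[[2L]])
      ci <- assign_cluster(pep77, model)
      cl <- model$clusters[[ci]]
      pep <- extract_nsp(seq, pos, cl$window[[1L]], cl$window[[2L]])
      score <- site_score(pep, cl)
      co <- cl$cutoffs
      best <- if (score >= co[["high"]]) "high"
              else if (score >= co[["medium"]]) "medium"
              else if (score >= co[["low"]]) "low"
              else "none"
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, position = pos, peptide = pep, cluster = cl$id,
        score = score, cutoff_high = co[["high"]],
        cutoff_medium = co[["medium"]], cutoff_low = co[["low"]],
        level = best, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) == 0L) {
    data.frame(protein_id = character(0), position = integer(0),
               peptide = character(0), cluster = character(0),
               score = numeric(0), cutoff_high = numeric(0),
               cutoff_medium = numeric(0), cutoff_low = numeric(0),
               level = character(0), stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  if (level != "all") {
    keep <- switch(level,
                   high = out$level == "high",
                   medium = out$level %in% c("high", "medium"),
                   low = out$level %in% c("high", "medium", "low"))
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
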