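# Average similarity of each member to the other members of one cluster
# (internal).  For a singleton cluster the member is trivially homogeneous
# and its average similarity is defined as 1.
avg_sim_within <- function(sim, members) {
  n <- length(members)
  if (n == 1L) return(stats::setNames(1, NULL))
  sub <- sim[members, members, drop = FALSE]
  (rowSums(sub) - diag(sub)) / (n - 1L)
}

#' Cluster positive site peptides by conserved-substitution similarity
#'
#' A k-medoid variant of k-means under the pairwise conserved-substitution
#' similarity: `k` member peptides are seeded as medoids at random, every
#' peptide is assigned to the medoid of maximal similarity (ties to the
#' lowest medoid index), and each medoid is replaced by the member with the
#' highest average similarity (HAS) to its cluster; assignment and update are
#' repeated until the assignment vector is stable or `max_iter` is reached.
#' Should an update empty a cluster, its medoid is re-seeded with the peptide
#' least similar to its current medoid, so `k` non-empty clusters always
#' survive.  Clustering always runs on clustering-window peptides with unit
#' weights and the unmutated matrix.
#'
#' @param peptides Character vector of equal-length peptides (clustering
#'   window, NSP(7, 7) by default in the trainer).
#' @param k Number of clusters (default 3).
#' @param matrix Substitution matrix (default BLOSUM62).
#' @param seed Optional integer; when given, seeds the medoid draw.  When
#'   `NULL` the current RNG stream is used.
#' @param max_iter Iteration cap (default 100).
#' @return List of class `cluster_assignment`: `k`, `medoids` (indices),
#'   `members_pos` (list of index vectors), `has` (mean intra-cluster
#'   similarity per cluster), `iterations`.
#' @export
kmeans_positives <- function(peptides, k = 3L, matrix = blosum62(),
                             seed = NULL, max_iter = 100L) {
  n <- length(peptides)
  if (n == 0L) stop("no peptides to cluster")
  if (k < 1L || k > n)
    stop("k = ", k, " must be between 1 and the number of peptides (", n, ")")
  if (!is.null(seed)) set.seed(seed)
  codes <- encode_peptides(peptides)
  sim <- similarity_matrix(codes, codes, matrix)
  medoids <- sort(sample.int(n, k))
  assign_step <- function(medoids) {
    # medoid of maximal similarity, ties to the lowest medoid index; a medoid
    # always reaches similarity 1 with itself, so it stays in its own cluster
    # unless an identical peptide serves as an earlier medoid
    max.col(sim[, medoids, drop = FALSE], ties.method = "first")
  }
  assign_vec <- rep(NA_integer_, n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    new_assign <- assign_step(medoids)
    # empty-cluster repair: re-seed the empty cluster's medoid with the
    # peptide least similar to its currently assigned medoid, then re-assign;
    # deterministic, keeps k non-empty clusters
    repairs <- 0L
    while (length(empty <- setdiff(seq_len(k), unique(new_assign))) > 0L &&
           repairs < n) {
      fit <- sim[cbind(seq_len(n), medoids[new_assign])]
      fit[medoids] <- Inf
      medoids[empty[[1L]]] <- which.min(fit)
      new_assign <- assign_step(medoids)
      repairs <- repairs + 1L
    }
    if (identical(new_assign, assign_vec) || iter >= max_iter) {
      assign_vec <- new_assign
      break
    }
    assign_vec <- new_assign
    # medoid update: member with the highest average similarity to its cluster
    for (c in seq_len(k)) {
      members <- which(assign_vec == c)
      avg <- avg_sim_within(sim, members)
      medoids[c] <- members[which.max(avg)]
    }
  }
  members_pos <- lapply(seq_len(k), function(c) which(assign_vec == c))
  has <- vapply(seq_len(k), function(c) {
    mean(avg_sim_within(sim, members_pos[[c]]))
  }, numeric(1))
  # `iterations` counts medoid-update rounds; the final pass that verifies an
  # unchanged assignment is not counted
  structure(list(k = k, medoids = medoids, members_pos = members_pos,
                 members_neg = NULL, has = has, iterations = iter - 1L,
                 peptides = peptides),
            class = "cluster_assignment")
}

#' Attach negative site peptides to the positive clusters
#'
#' Each negative joins the cluster with the highest average
#' conserved-substitution similarity to that cluster's positive members
#' (ties to the lowest cluster index); the positive partition is unchanged.
#'
#' @param assignment A `cluster_assignment` from [kmeans_positives()].
#' @param negatives Character vector of negative peptides in the same window
#'   as the clustered positives.
#' @param matrix Substitution matrix (default BLOSUM62).
#' @return The assignment with `members_neg` filled in (list of index vectors
#'   into `negatives`).
#' @export
attach_negatives <- function(assignment, negatives, matrix = blosum62()) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (length(negatives) > 0L &&
      nchar(negatives[[1L]]) != nchar(assignment$peptides[[1L]]))
    stop("negative peptides must have length ",
         nchar(assignment$peptides[[1L]]), " (the clustering window)")
  neg_codes <- encode_peptides(negatives)
  pos_codes <- encode_peptides(assignment$peptides)
  sim <- similarity_matrix(neg_codes, pos_codes, matrix)
  mean_sims <- vapply(assignment$members_pos, function(members) {
    rowMeans(sim[, members, drop = FALSE])
  }, numeric(length(negatives)))
  mean_sims <- matrix(mean_sims, nrow = length(negatives))
  idx <- if (length(negatives) > 0L) max.col(mean_sims, ties.method = "first")
         else integer(0)
  assignment$members_neg <- lapply(seq_len(assignment$k),
                                   function(c) which(idx == c))
  assignment
}
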