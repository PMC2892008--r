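#' Confusion-matrix performance measures
#'
#' Computes the four standard measures from true/false positive/negative
#' counts: sensitivity `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`,
#' accuracy `Ac = (TP+TN)/(TP+FP+TN+FN)` and the Matthews correlation
#' coefficient `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' with `MCC` defined as 0 when its denominator is 0.
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return Named list with `sn`, `sp`, `ac`, `mcc`.
#' @examples
#' confusion_metrics(9, 1, 9, 1)  # sn = sp = ac = 0.9, mcc = 0.8
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  total <- tp + fp + tn + fn
  if (total == 0) stop("all confusion counts are zero")
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  list(sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       ac = (tp + tn) / total,
       # the factorised denominator can overshoot [-1, 1] by a few ulp
       mcc = min(1, max(-1, mcc)))
}

#' ROC curve and area under it
#'
#' Builds the ROC curve over all distinct score cutoffs (a site is called
#' positive when its score is greater than or equal to the cutoff) and
#' computes the area via the rank-based Mann-Whitney statistic, which equals
#' the trapezoidal area and handles score ties as
#' `P(score+ > score-) + 0.5 * P(score+ = score-)`.
#'
#' @param scores Numeric scores.
#' @param labels Character labels, `"+"` or `"-"`, parallel to `scores`.
#' @return List with `auc` and `points` (data frame of `cutoff`, `fpr`,
#'   `tpr`, including the (0,0) and (1,1) endpoints).
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == "+"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("ROC requires at least one positive and one negative score")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cutoffs <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(cutoffs, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(cutoffs, function(t) mean(scores[!pos] >= t), numeric(1))
  points <- data.frame(cutoff = c(Inf, cutoffs), fpr = c(0, fpr),
                       tpr = c(0, tpr))
  list(auc = auc, points = points)
}

# Smallest representable value strictly above x (internal); used when a
# cutoff must exclude every observed negative score.
just_above <- function(x) {
  if (x == 0) return(.Machine$double.xmin)
  x + max(abs(x) * .Machine$double.eps * 4, .Machine$double.xmin)
}

#' Score cutoff achieving a requested specificity
#'
#' Returns the smallest cutoff `t` such that the fraction of negative scores
#' strictly below `t` is at least `sp_level`, under the decision rule
#' "score >= t predicts positive".  Candidate cutoffs are the observed
#' negative scores plus a value just above the maximum (needed when ties or
#' `sp_level = 1` make every negative fail).  The achieved specificity (the
#' closest achievable at or above the request) is reported alongside.
#'
#' @param negative_scores Non-empty numeric vector.
#' @param sp_level Requested specificity in `(0, 1]`.
#' @return List with `cutoff` and `sp_achieved`.
#' @examples
#' threshold_at_sp(1:100, 0.80)  # cutoff 81, achieved Sp 0.80
#' @export
threshold_at_sp <- function(negative_scores, sp_level) {
  if (length(negative_scores) == 0L) stop("no negative scores")
  if (sp_level <= 0 || sp_level > 1)
    stop("sp_level must be in (0, 1], got ", sp_level)
  s <- sort(negative_scores)
  n <- length(s)
  first <- which(!duplicated(s))
  # for the j-th distinct value, first[j] - 1 negatives lie strictly below it
  candidates <- c(s[first], just_above(s[[n]]))
  below <- c(first - 1L, n)
  ok <- which(below / n >= sp_level - 1e-12)
  list(cutoff = candidates[[ok[[1L]]]], sp_achieved = below[[ok[[1L]]]] / n)
}

#' Pooled sensitivity at a fixed per-cluster specificity
#'
#' For each cluster the cutoff is calibrated on that cluster's own negative
#' scores at `sp_level` (scores of different clusters live on different
#' scales, so specificity is fixed per cluster); confusion counts are then
#' pooled across clusters and summarised.  The pooled sensitivity at fixed
#' specificity is the training objective of the hill-climbing stages.
#'
#' @param scored Per-cluster list; each element a list with numeric vectors
#'   `pos` (positive scores) and `neg` (negative scores).
#' @param sp_level Requested specificity in `(0, 1]`.
#' @return List with `metrics` (from [confusion_metrics()]), `counts`
#'   (tp/fp/tn/fn), and `cutoffs` (per-cluster calibrated cutoff).
#' @export
evaluate_sn_at_sp <- function(scored, sp_level) {
  tp <- fp <- tn <- fn <- 0
  cutoffs <- numeric(length(scored))
  for (i in seq_along(scored)) {
    th <- threshold_at_sp(scored[[i]]$neg, sp_level)
    cutoffs[[i]] <- th$cutoff
    tp <- tp + sum(scored[[i]]$pos >= th$cutoff)
    fn <- fn + sum(scored[[i]]$pos < th$cutoff)
    tn <- tn + sum(scored[[i]]$neg < th$cutoff)
    fp <- fp + sum(scored[[i]]$neg >= th$cutoff)
  }
  list(metrics = confusion_metrics(tp, fp, tn, fn),
       counts = list(tp = tp, fp = fp, tn = tn, fn = fn),
       cutoffs = cutoffs)
}

#' Leave-one-out scores under a trained model's cluster parameters
#'
#' Each positive site is scored against its own cluster's reference positives
#' with itself removed; each negative site is scored once against the full
#' positive reference set of the cluster it attaches to (highest average
#' similarity rule, clustering window, unmutated matrix).  A positive that is
#' the sole member of its cluster has an empty reference set; its score is
#' defined as 0 and flagged.
#'
#' @param dataset An `sno_dataset` whose positive sites are the model's
#'   training positives (matched by protein and position).
#' @param model A `gps_model`.
#' @return Per-cluster list; each element has `pos`, `neg` (score vectors)
#'   and `flagged` (logical vector parallel to `pos`).
#' @export
loo_scores <- function(dataset, model) {
  cw <- model$clustering_window
  sites <- dataset$sites
  neg <- sites[sites$label == "-", , drop = FALSE]
  out <- vector("list", length(model$clusters))
  # attach every negative site by the highest-average-similarity rule
  neg_cluster <- integer(nrow(neg))
  if (nrow(neg) > 0L) {
    neg77 <- extract_nsp_many(dataset$sequences, neg$protein_id, neg$position,
                              cw[[1L]], cw[[2L]])
    codes77 <- encode_peptides(neg77)
    sims <- vapply(model$clusters, function(cl) {
      refs <- encode_peptides(cl$positives_ref)
      rowMeans(similarity_matrix(codes77, refs, model$clustering_matrix))
    }, numeric(nrow(neg)))
    sims <- matrix(sims, nrow = nrow(neg))
    neg_cluster <- max.col(sims, ties.method = "first")
  }
  for (ci in seq_along(model$clusters)) {
    cl <- model$clusters[[ci]]
    np <- length(cl$positives)
    pos_codes <- encode_peptides(cl$positives)
    if (np >= 2L) {
      raw <- matrix(0, np, np)
      for (i in seq_len(ncol(pos_codes)))
        raw <- raw + cl$weights[[i]] * cl$matrix[pos_codes[, i], pos_codes[, i]]
      fl <- pmax(raw, 0)
      pos_scores <- (rowSums(fl) - diag(fl)) / (np - 1L)
      flagged <- rep(FALSE, np)
    } else {
      pos_scores <- rep(0, np)
      flagged <- rep(TRUE, np)
      if (np == 1L)
        warning("cluster ", cl$id, " has a single positive; its ",
                "leave-one-out score is defined as 0")
    }
    idx <- which(neg_cluster == ci)
    neg_scores <- numeric(0)
    if (length(idx) > 0L) {
      pep <- extract_nsp_many(dataset$sequences, neg$protein_id[idx],
                              neg$position[idx], cl$window[[1L]], cl$window[[2L]])
      neg_scores <- mean_scores_vs_refs(encode_peptides(pep), pos_codes,
                                        cl$matrix, cl$weights)
    }
    out[[ci]] <- list(pos = unname(pos_scores), neg = unname(neg_scores),
                      flagged = flagged)
  }
  out
}

#' Stratified k-fold cross-validation of the full training pipeline
#'
#' Sites are partitioned into `folds` folds stratified by label (fold sizes
#' within each label stratum differ by at most one, assignment is seeded).
#' For each fold the model is retrained from scratch on the remaining folds
#' under `config` and the held-out sites are scored through the trained model
#' (cluster assignment followed by site scoring); all held-out scores are
#' pooled into one scored-label set.
#'
#' @param dataset An `sno_dataset`.
#' @param folds Number of folds (>= 2).
#' @param config A [training_config()]; its `seed` also seeds the partition.
#' @param trainer Training function, [train_gps3()] by default (the GPS 2.0
#'   baseline trainer can be substituted).
#' @return List with `scores`, `labels`, `fold` (parallel vectors) and `auc`.
#' @export
kfold_cv <- function(dataset, folds, config = training_config(),
                     trainer = train_gps3) {
  sites <- dataset$sites
  n_pos <- sum(sites$label == "+")
  if (folds < 2L) stop("folds must be >= 2")
  if (folds > n_pos)
    stop("folds (", folds, ") exceeds the number of positive sites (",
         n_pos, ")")
  set.seed(config$seed)
  fold_id <- integer(nrow(sites))
  for (lab in c("+", "-")) {
    idx <- which(sites$label == lab)
    fold_id[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(folds), length(idx))
  }
  scores <- numeric(nrow(sites))
  for (f in seq_len(folds)) {
    test <- fold_id == f
    train_ds <- site_dataset(dataset$sequences,
                             sites[!test, , drop = FALSE])
    model <- trainer(train_ds, config)
    test_sites <- sites[test, , drop = FALSE]
    scores[test] <- score_sites(model, dataset$sequences,
                                test_sites$protein_id, test_sites$position)
  }
  list(scores = scores, labels = sites$label, fold = fold_id,
       auc = roc_auc(scores, sites$label)$auc)
}

#' Score specific cysteine sites through a trained model
#'
#' Runs the prediction scoring path (cluster assignment at the clustering
#' window, then site scoring at the assigned cluster's window) for given
#' sites, without applying any cutoff.
#'
#' @param model Trained `gps_model`.
#' @param sequences Named character vector of protein sequences.
#' @param protein_ids,positions Parallel vectors identifying the sites.
#' @return Numeric score vector.
#' @export
score_sites <- function(model, sequences, protein_ids, positions) {
  cw <- model$clustering_window
  vapply(seq_along(protein_ids), function(i) {
    seq <- sequences[[protein_ids[[i]]]]
    pep77 <- extract_nsp(seq, positions[[i]], cw[[1L]], cw[[2L]])
    cl <- model$clusters[[assign_cluster(pep77, model)]]
    site_score(extract_nsp(seq, positions[[i]], cl$window[[1L]],
                           cl$window[[2L]]), cl)
  }, numeric(1))
}
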