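test_that("confusion metrics match the standard formulas", {
  m <- confusion_metrics(9, 1, 9, 1)
  expect_equal(m$sn, 0.9); expect_equal(m$sp, 0.9)
  expect_equal(m$ac, 0.9); expect_equal(m$mcc, 0.8)
  perfect <- confusion_metrics(5, 0, 7, 0)
  expect_equal(unlist(perfect), c(sn = 1, sp = 1, ac = 1, mcc = 1))
  indep <- confusion_metrics(4, 6, 6, 4)   # tp = fn, tn = fp
  expect_equal(indep$mcc, 0)
  zero_denom <- confusion_metrics(0, 0, 5, 5)   # no predicted positives
  expect_equal(zero_denom$mcc, 0)
  expect_error(confusion_metrics(0, 0, 0, 0), "zero")
})

test_that("ROC area equals the pair-ordering probability", {
  r <- roc_auc(c(3, 1, 2, 0), c("+", "+", "-", "-"))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(5, 6, 1, 2), c("+", "+", "-", "-"))$auc, 1)
  expect_equal(roc_auc(rep(2, 6), c("+", "+", "+", "-", "-", "-"))$auc, 0.5)
  expect_error(roc_auc(1:3, c("+", "+", "+")), "positive and one negative")
  # curve endpoints and monotonicity
  expect_equal(r$points$fpr[1], 0); expect_equal(r$points$tpr[1], 0)
  expect_equal(tail(r$points$fpr, 1), 1); expect_equal(tail(r$points$tpr, 1), 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
})

test_that("specificity-fixed cutoffs behave at boundaries and under ties", {
  th <- threshold_at_sp(1:100, 0.80)
  expect_equal(th$cutoff, 81); expect_equal(th$sp_achieved, 0.80)
  th1 <- threshold_at_sp(1:100, 1.0)
  expect_gt(th1$cutoff, 100); expect_equal(th1$sp_achieved, 1.0)
  expect_equal(sum(1:100 >= th1$cutoff), 0)
  thv <- threshold_at_sp(rep(4, 50), 0.8)
  expect_gt(thv$cutoff, 4); expect_equal(thv$sp_achieved, 1.0)
  expect_error(threshold_at_sp(1:10, 0), "sp_level")
  expect_error(threshold_at_sp(1:10, 1.2), "sp_level")
})

test_that("cutoffs are monotone in the requested specificity", {
  set.seed(8)
  for (rep in 1:20) {
    neg <- round(runif(60, 0, 50), 2)
    levels <- sort(runif(5, 0.5, 1))
    cuts <- vapply(levels, function(l) threshold_at_sp(neg, l)$cutoff,
                   numeric(1))
    expect_true(all(diff(cuts) >= 0))
    achieved <- vapply(levels, function(l) threshold_at_sp(neg, l)$sp_achieved,
                       numeric(1))
    expect_true(all(achieved >= levels))
  }
})

test_that("pooled sensitivity at fixed specificity sums per-cluster counts", {
  scored <- list(list(pos = c(10, 9, 1), neg = c(0:9)),
                 list(pos = c(5, 5), neg = rep(c(1, 4), each = 5)),
                 list(pos = 8, neg = 0:4))
  ev <- evaluate_sn_at_sp(scored, 0.8)
  # manual pooling with per-cluster cutoffs
  manual <- list(tp = 0, fp = 0, tn = 0, fn = 0)
  for (s in scored) {
    t <- threshold_at_sp(s$neg, 0.8)$cutoff
    manual$tp <- manual$tp + sum(s$pos >= t)
    manual$fn <- manual$fn + sum(s$pos < t)
    manual$tn <- manual$tn + sum(s$neg < t)
    manual$fp <- manual$fp + sum(s$neg >= t)
  }
  expect_equal(ev$counts, manual)
  # single-cluster case reduces to threshold + confusion directly
  ev1 <- evaluate_sn_at_sp(scored[1], 0.8)
  t1 <- threshold_at_sp(scored[[1]]$neg, 0.8)$cutoff
  expect_equal(ev1$metrics$sn, mean(scored[[1]]$pos >= t1))
  # a cluster whose positives all clear the cutoff contributes fn = 0
  hi <- list(list(pos = c(100, 90), neg = 0:9))
  expect_equal(evaluate_sn_at_sp(hi, 0.8)$counts$fn, 0)
})

test_that("raising a positive score never lowers Sn at fixed Sp", {
  set.seed(12)
  pos <- runif(30, 0, 10); neg <- runif(100, 0, 10)
  sn0 <- evaluate_sn_at_sp(list(list(pos = pos, neg = neg)), 0.8)$metrics$sn
  pos2 <- pos; pos2[7] <- pos2[7] + 5
  sn1 <- evaluate_sn_at_sp(list(list(pos = pos2, neg = neg)), 0.8)$metrics$sn
  expect_gte(sn1, sn0)
})

test_that("leave-one-out scores equal from-scratch recomputation", {
  ds <- small_sim(4, n_proteins = 25, n_pos = 30, n_neg = 120)
  model <- train_gps3(ds, quick_config(seed = 2, k = 2))
  sc <- loo_scores(ds, model)
  for (ci in seq_along(model$clusters)) {
    cl <- model$clusters[[ci]]
    for (i in seq_along(cl$positives)) {
      refs <- cl$positives[-i]
      expect_equal(sc[[ci]]$pos[i],
                   oracle_site_score(cl$positives[i], refs, cl$matrix,
                                     cl$weights))
    }
  }
})

test_that("two identical positives give each other their self-score in LOO", {
  seqs <- c(p1 = "AAKCDAA", p2 = "AAKCDAA", p3 = "AAACAAAAACAAA")
  sites <- data.frame(protein_id = c("p1", "p2", "p3", "p3"),
                      position = c(4L, 4L, 4L, 10L),
                      label = c("+", "+", "-", "-"))
  ds <- site_dataset(seqs, sites)
  model <- toy_model(c("KCD", "KCD"))
  model$clusters[[1]]$sites <- data.frame(protein_id = c("p1", "p2"),
                                          position = c(4L, 4L))
  sc <- loo_scores(ds, model)
  self <- pair_score("KCD", "KCD")
  expect_equal(sc[[1]]$pos, c(self, self))
})

test_that("a sole positive in a cluster is flagged and scored 0", {
  seqs <- c(p1 = "AAKCDAA", p2 = "AAACAAA")
  ds <- site_dataset(seqs, data.frame(protein_id = c("p1", "p2"),
                                      position = c(4L, 4L),
                                      label = c("+", "-")))
  model <- toy_model("KCD")
  model$clusters[[1]]$sites <- data.frame(protein_id = "p1", position = 4L)
  expect_warning(sc <- loo_scores(ds, model), "single positive")
  expect_equal(sc[[1]]$pos, 0)
  expect_true(sc[[1]]$flagged)
})

test_that("k-fold partitions are stratified, exhaustive and disjoint", {
  ds <- small_sim(6, n_proteins = 30, n_pos = 24, n_neg = 90)
  cfg <- quick_config(seed = 4, k = 1, ps_max_m = 2, ps_max_n = 2,
                      wt_max_stall = 15, mam_max_stall = 20)
  cv <- kfold_cv(ds, 4, cfg)
  expect_equal(length(cv$scores), nrow(ds$sites))
  expect_equal(sort(unique(cv$fold)), 1:4)
  for (lab in c("+", "-")) {
    sizes <- table(cv$fold[ds$sites$label == lab])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_error(kfold_cv(ds, 1, cfg), "folds")
  expect_error(kfold_cv(ds, 25, cfg), "exceeds")
})
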