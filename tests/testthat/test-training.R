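# A small labelled dataset with an informative residue at chosen offsets:
# positives carry K there, everything else is alanine background.
offset_fixture <- function(offsets, n_pos = 12, n_neg = 40) {
  seqs <- character(0); rows <- list()
  for (i in seq_len(n_pos)) {
    s <- strrep("A", 21)
    substr(s, 11, 11) <- "C"
    for (offset in offsets)
      substr(s, 11 + offset, 11 + offset) <- "K"
    seqs[sprintf("pos%02d", i)] <- s
    rows[[length(rows) + 1]] <- data.frame(
      protein_id = sprintf("pos%02d", i), position = 11L, label = "+")
  }
  for (i in seq_len(n_neg)) {
    s <- strrep("A", 21)
    substr(s, 11, 11) <- "C"
    seqs[sprintf("neg%02d", i)] <- s
    rows[[length(rows) + 1]] <- data.frame(
      protein_id = sprintf("neg%02d", i), position = 11L, label = "-")
  }
  site_dataset(seqs, do.call(rbind, rows))
}

test_that("window selection is exhaustive over the grid with declared tie-breaks", {
  # informative K at offset -2 of every positive, alanine background
  ds <- offset_fixture(-2)
  pos <- ds$sites[ds$sites$label == "+", ]
  neg <- ds$sites[ds$sites$label == "-", ]
  # singleton grid
  cfg1 <- training_config(ps_max_m = 1, ps_max_n = 1)
  expect_equal(peptide_selection(ds, pos, neg, config = cfg1)$window, c(1, 1))
  # independent evaluation of every window through the oracle scoring path
  sn_of <- function(m, n) {
    pp <- vapply(seq_len(nrow(pos)), function(i) extract_nsp(
      ds$sequences[[pos$protein_id[i]]], pos$position[i], m, n), character(1))
    np <- vapply(seq_len(nrow(neg)), function(i) extract_nsp(
      ds$sequences[[neg$protein_id[i]]], neg$position[i], m, n), character(1))
    w <- rep(1, m + 1 + n)
    loo <- vapply(seq_along(pp), function(i)
      oracle_site_score(pp[i], pp[-i], blosum62(), w), numeric(1))
    negs <- vapply(np, oracle_site_score, numeric(1), refs = pp,
                   mat = blosum62(), weights = w)
    t <- threshold_at_sp(negs, 0.8)$cutoff
    mean(loo >= t)
  }
  grid <- expand.grid(m = 1:3, n = 1:3)
  grid$sn <- mapply(sn_of, grid$m, grid$n)
  # oracle argmax under the declared tie-break: best Sn, then smallest
  # m + n, then smallest m
  ord <- order(-grid$sn, grid$m + grid$n, grid$m)
  best <- grid[ord[1], ]
  cfg3 <- training_config(ps_max_m = 3, ps_max_n = 3)
  ps <- peptide_selection(ds, pos, neg, config = cfg3)
  expect_equal(ps$window, c(best$m, best$n))
  expect_equal(ps$sn, best$sn)
  # the chosen window must cover the informative offset
  expect_gte(ps$window[1], 2)
})

test_that("uninformative flanks tie every window to the smallest one", {
  # all peptides identical at every offset: every window gives the same Sn
  ds <- offset_fixture(0 + 3)  # K at +3 for positives
  # mask the signal by restricting the grid below the informative offset
  pos <- ds$sites[ds$sites$label == "+", ]
  neg <- ds$sites[ds$sites$label == "-", ]
  cfg <- training_config(ps_max_m = 2, ps_max_n = 2)
  ps <- peptide_selection(ds, pos, neg, config = cfg)
  expect_equal(ps$window, c(1, 1))
})

test_that("weight training only accepts strict improvements", {
  ds <- small_sim(21)
  cfg <- quick_config(seed = 6, k = 1)
  pos <- ds$sites[ds$sites$label == "+", ]
  neg <- ds$sites[ds$sites$label == "-", ]
  set.seed(cfg$seed)
  wt <- weight_training(ds, pos, neg, c(2L, 2L), config = cfg)
  expect_gte(wt$sn, wt$sn_initial)
  if (nrow(wt$trace) > 1) expect_true(all(diff(wt$trace$sn) > 0))
  if (nrow(wt$trace) > 0) expect_gt(wt$trace$sn[1], wt$sn_initial)
  expect_true(all(wt$weights >= 0))
  expect_equal(length(wt$weights), 5)
  # determinism: same RNG state, same data -> identical weights
  set.seed(cfg$seed)
  wt2 <- weight_training(ds, pos, neg, c(2L, 2L), config = cfg)
  expect_identical(wt$weights, wt2$weights)
})

test_that("matrix mutation preserves symmetry and the padding row", {
  ds <- small_sim(22)
  cfg <- quick_config(seed = 7, k = 1)
  pos <- ds$sites[ds$sites$label == "+", ]
  neg <- ds$sites[ds$sites$label == "-", ]
  w <- rep(1L, 5)
  set.seed(cfg$seed)
  mam <- matrix_mutation(ds, pos, neg, c(2L, 2L), w, config = cfg)
  expect_gte(mam$sn, mam$sn_initial)
  if (nrow(mam$trace) > 1) expect_true(all(diff(mam$trace$sn) > 0))
  expect_identical(mam$matrix, t(mam$matrix))
  expect_true(all(mam$matrix["*", ] == 0))
  expect_true(all(mam$matrix[, "*"] == 0))
  set.seed(cfg$seed)
  mam2 <- matrix_mutation(ds, pos, neg, c(2L, 2L), w, config = cfg)
  expect_identical(mam$matrix, mam2$matrix)
})

test_that("the full pipeline is deterministic and freezes cluster membership", {
  ds <- small_sim(23, n_proteins = 40, n_pos = 50, n_neg = 250)
  cfg <- quick_config(seed = 9, k = 2)
  m1 <- train_gps3(ds, cfg)
  m2 <- train_gps3(ds, cfg)
  keep <- setdiff(names(m1), "log")
  expect_identical(m1[keep], m2[keep])
  # membership equals the k-means output run under the same seed
  pos <- ds$sites[ds$sites$label == "+", ]
  pep77 <- vapply(seq_len(nrow(pos)), function(i) extract_nsp(
    ds$sequences[[pos$protein_id[i]]], pos$position[i], 7, 7), character(1))
  set.seed(cfg$seed)
  km <- kmeans_positives(pep77, k = 2)
  for (ci in 1:2) {
    expect_equal(m1$clusters[[ci]]$sites$protein_id,
                 pos$protein_id[km$members_pos[[ci]]])
  }
  # cutoffs ordered high >= medium >= low
  for (cl in m1$clusters) {
    expect_gte(cl$cutoffs[["high"]], cl$cutoffs[["medium"]])
    expect_gte(cl$cutoffs[["medium"]], cl$cutoffs[["low"]])
    expect_gte(cl$achieved_sp[["high"]], 0.9)
  }
})

test_that("the single-group baseline is the k = 1 reduction of the pipeline", {
  ds <- small_sim(24, n_proteins = 30, n_pos = 40, n_neg = 160)
  cfg <- quick_config(seed = 5)
  g2 <- train_gps2_baseline(ds, cfg)
  expect_equal(length(g2$clusters), 1)
  expect_equal(g2$clusters[[1]]$window, c(7L, 7L))
  expect_true(all(g2$clusters[[1]]$weights == 1L))
  cfg1 <- cfg
  cfg1$k <- 1L; cfg1$enable_ps <- FALSE; cfg1$enable_wt <- FALSE
  cfg1$fixed_window <- c(7L, 7L)
  g3 <- train_gps3(ds, cfg1)
  expect_identical(g2$clusters, g3$clusters)
  # hill-climb guarantee: final Sn at fixed Sp >= unmutated-matrix Sn
  tr <- g2$log$traces[[1]]
  expect_gte(tr$stage_sn[["mam_final"]], tr$stage_sn[["mam_initial"]])
})

test_that("degenerate datasets are rejected with instructive errors", {
  ds <- small_sim(25, n_proteins = 10, n_pos = 4, n_neg = 20)
  expect_error(train_gps3(ds, quick_config(k = 5)), "fewer positives")
  seqs <- c(p1 = "AAKCDAAKCDAAKCDAA")
  only_pos <- site_dataset(seqs, data.frame(
    protein_id = "p1", position = c(4L, 9L, 14L), label = "+"))
  expect_error(train_gps3(only_pos, quick_config(k = 1)), "no negative")
})
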