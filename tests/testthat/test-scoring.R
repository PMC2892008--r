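M62 <- blosum62()

test_that("pair scores match hand-derived BLOSUM62 values and the zero floor", {
  expect_equal(pair_score("CCC", "CCC", M62), 27)
  expect_equal(pair_score("WWW", "GGG", M62), 0)   # raw 3 * (-2), floored
  expect_equal(pair_score("**C", "AKC", M62), 9)   # padding contributes 0
  expect_error(pair_score("CC", "C", M62), "equal length")
})

test_that("weighted pair scores reduce to unweighted at unit weights", {
  expect_equal(weighted_pair_score("CC", "CC", M62, c(2, 1)), 27)
  expect_equal(weighted_pair_score("W", "G", M62, 5), 0)
  set.seed(1)
  for (rep in 1:20) {
    a <- random_peptide(9); b <- random_peptide(9)
    expect_equal(weighted_pair_score(a, b, M62, rep(1, 9)),
                 pair_score(a, b, M62))
  }
  expect_error(weighted_pair_score("CC", "CC", M62, c(-1, 1)), "non-negative")
  expect_error(weighted_pair_score("CC", "CC", M62, 1), "length")
})

test_that("conserved similarity is the positive-score fraction in [0, 1]", {
  expect_equal(conserved_similarity("CW", "CG", M62), 0.5)
  expect_equal(conserved_similarity("WWW", "GGG", M62), 0)
  pep <- random_nsp(7, 7)
  expect_equal(conserved_similarity(pep, pep, M62), 1)  # diagonal positivity
})

test_that("scoring agrees with brute-force oracles on random peptide pairs", {
  set.seed(101)
  for (rep in 1:200) {
    len <- sample(3:17, 1)
    a <- random_peptide(len); b <- random_peptide(len)
    w <- sample(0:3, len, replace = TRUE)
    expect_equal(pair_score(a, b, M62), oracle_pair_score(a, b, M62))
    expect_equal(weighted_pair_score(a, b, M62, w),
                 oracle_pair_score(a, b, M62, w))
    expect_equal(conserved_similarity(a, b, M62), oracle_similarity(a, b, M62))
    # symmetry under a symmetric matrix
    expect_equal(pair_score(a, b, M62), pair_score(b, a, M62))
    expect_equal(conserved_similarity(a, b, M62),
                 conserved_similarity(b, a, M62))
  }
})

test_that("raising a matrix entry never decreases an aligned pair score", {
  set.seed(7)
  for (rep in 1:30) {
    a <- random_peptide(9, pad_prob = 0); b <- random_peptide(9, pad_prob = 0)
    i <- sample(9, 1)
    x <- substr(a, i, i); y <- substr(b, i, i)
    m2 <- M62
    m2[x, y] <- m2[x, y] + 3L
    m2[y, x] <- m2[x, y]
    expect_gte(pair_score(a, b, m2), pair_score(a, b, M62))
  }
})

test_that("site scores average over the reference set", {
  p <- random_nsp(1, 1)
  cl <- toy_model(p)$clusters[[1]]
  expect_equal(site_score(p, cl), weighted_pair_score(p, p, M62, rep(1, 3)))

  cl2 <- toy_model(c(p, p))$clusters[[1]]   # duplicate reference
  q <- random_nsp(1, 1)
  expect_equal(site_score(q, cl2), site_score(q, cl))

  set.seed(11)
  refs <- replicate(8, random_nsp(3, 3))
  cl3 <- toy_model(refs, window = c(3L, 3L))$clusters[[1]]
  cl3$weights <- sample(0:3, 7, replace = TRUE)
  q <- random_nsp(3, 3)
  expect_equal(site_score(q, cl3),
               oracle_site_score(q, refs, M62, cl3$weights))
  # permutation invariance of the reference set
  cl4 <- cl3; cl4$positives <- rev(cl4$positives)
  expect_equal(site_score(q, cl4), site_score(q, cl3))
  cl5 <- cl3; cl5$positives <- character(0)
  expect_error(site_score(q, cl5), "no reference positives")
})

test_that("cluster assignment maximises mean conserved similarity", {
  mk_cluster <- function(id, refs77) {
    list(id = id, window = c(1L, 1L), weights = rep(1L, 3), matrix = M62,
         positives = substr(refs77, 7, 9), positives_ref = refs77,
         sites = data.frame(protein_id = "x", position = 1L),
         has = 1, cutoffs = c(high = 3, medium = 2, low = 1),
         achieved_sp = c(high = 1, medium = 1, low = 1))
  }
  pepB <- paste0(strrep("K", 7), "C", strrep("K", 7))
  pepA <- paste0(strrep("W", 7), "C", strrep("W", 7))
  pepC <- paste0(strrep("P", 7), "C", strrep("P", 7))
  model <- gpsno:::new_gps_model(
    algorithm = "gps3", clustering_window = c(7L, 7L),
    clustering_matrix = M62,
    clusters = list(mk_cluster("A", rep(pepA, 3)), mk_cluster("B", rep(pepB, 3)),
                    mk_cluster("C", rep(pepC, 3))),
    sp_fix = 0.8, calibration_levels = c(high = .9, medium = .85, low = .8),
    seed = 1L)
  expect_equal(assign_cluster(pepB, model), 2L)
  # exact tie between clusters A and C breaks to the lower index
  model2 <- model
  model2$clusters[[3]]$positives_ref <- rep(pepA, 3)
  expect_equal(assign_cluster(pepA, model2), 1L)
  # random queries: argmax of exhaustively computed mean similarities
  set.seed(5)
  for (rep in 1:20) {
    q <- random_nsp(7, 7)
    sims <- vapply(model$clusters, function(cl)
      mean(vapply(cl$positives_ref, oracle_similarity, numeric(1), b = q,
                  mat = M62)), numeric(1))
    expect_equal(assign_cluster(q, model), which.max(sims))
  }
})

test_that("prediction respects cutoffs and threshold nesting", {
  model <- toy_model("KCD", cutoffs = c(high = 10, medium = 5, low = 1))
  expect_equal(nrow(predict_sites(model, c(p = "MAKW"), "all")), 0L)

  # self-hit scores 5 + 9 + 6 = 20 >= high; reported at every level
  seqs <- c(p = "AKCDA")
  for (lv in c("high", "medium", "low"))
    expect_equal(nrow(predict_sites(model, seqs, lv)), 1L)

  # a mid-scoring site passes medium and low but not high:
  # query ACA vs reference KCD = -1 + 9 - 2 = 6
  model7 <- toy_model("KCD", cutoffs = c(high = 10, medium = 5, low = 1))
  seqs7 <- c(p = "AACAA")
  expect_equal(predict_sites(model7, seqs7, "all")$score, 6)
  expect_equal(nrow(predict_sites(model7, seqs7, "high")), 0L)
  expect_equal(nrow(predict_sites(model7, seqs7, "medium")), 1L)
  expect_equal(nrow(predict_sites(model7, seqs7, "low")), 1L)

  # nesting on a varied set of sequences
  set.seed(3)
  seqs_many <- setNames(replicate(10, paste(
    sample(c(AA, "C", "D", "K"), 30, replace = TRUE), collapse = "")),
    sprintf("q%02d", 1:10))
  key <- function(df) paste(df$protein_id, df$position)
  hi <- predict_sites(model, seqs_many, "high")
  me <- predict_sites(model, seqs_many, "medium")
  lo <- predict_sites(model, seqs_many, "low")
  expect_true(all(key(hi) %in% key(me)))
  expect_true(all(key(me) %in% key(lo)))

  model_untrained <- model
  model_untrained$clusters[[1]]$cutoffs <- NULL
  expect_error(predict_sites(model_untrained, seqs, "low"), "untrained")
})
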