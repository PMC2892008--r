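#' Training configuration
#'
#' Bundles every tunable of the trainer.  Defaults follow the reference
#' configuration of the algorithm: `k = 3` clusters, NSP(7, 7) clustering
#' window, exhaustive window search over `m, n` in `[1, 30]`, specificity
#' fixed at 80% during optimisation, and high/medium/low prediction cutoffs
#' calibrated at specificity 0.90/0.85/0.80.  The hill climbs stop after a
#' run of consecutive rejected proposals (`wt_max_stall`, `mam_max_stall`):
#' "until the objective no longer increases" is undecidable for stochastic
#' proposals, so a stall counter bounds the run deterministically.
#'
#' @param k Number of clusters.
#' @param clustering_window Length-2 integer vector `c(m, n)` for the
#'   clustering stage.
#' @param ps_max_m,ps_max_n Upper bounds of the window-search grid
#'   (`m` in `1..ps_max_m`, `n` in `1..ps_max_n`).
#' @param sp_fix Specificity level fixed during optimisation.
#' @param calibration_levels Named numeric vector of specificity levels for
#'   the `high`, `medium`, `low` prediction cutoffs.
#' @param wt_max_stall,mam_max_stall Consecutive rejected proposals before
#'   the weight-training / matrix-mutation climbs stop.
#' @param seed Integer seed; a single RNG stream is seeded once and consumed
#'   in documented stage order, so the seed reproduces an entire run.
#' @param enable_ps,enable_wt,enable_mam Stage switches (the GPS 2.0 baseline
#'   disables window search and weight training).
#' @param fixed_window Window used when `enable_ps = FALSE`.
#' @param per_cluster_matrix When `TRUE` (default) matrix mutation operates on
#'   each cluster's own matrix copy; when `FALSE` a single shared matrix is
#'   mutated against the pooled objective.
#' @return List of class `training_config`.
#' @export
training_config <- function(k = 3L,
                            clustering_window = c(7L, 7L),
                            ps_max_m = 30L, ps_max_n = 30L,
                            sp_fix = 0.80,
                            calibration_levels = c(high = 0.90,
                                                   medium = 0.85,
                                                   low = 0.80),
                            wt_max_stall = 500L,
                            mam_max_stall = 2000L,
                            seed = 1L,
                            enable_ps = TRUE,
                            enable_wt = TRUE,
                            enable_mam = TRUE,
                            fixed_window = c(7L, 7L),
                            per_cluster_matrix = TRUE) {
  stopifnot(k >= 1L, sp_fix > 0, sp_fix < 1,
            ps_max_m >= 1L, ps_max_n >= 1L,
            all(calibration_levels > 0), all(calibration_levels <= 1))
  structure(list(k = as.integer(k),
                 clustering_window = as.integer(clustering_window),
                 ps_max_m = as.integer(ps_max_m),
                 ps_max_n = as.integer(ps_max_n),
                 sp_fix = sp_fix,
                 calibration_levels = calibration_levels,
                 wt_max_stall = as.integer(wt_max_stall),
                 mam_max_stall = as.integer(mam_max_stall),
                 seed = as.integer(seed),
                 enable_ps = enable_ps,
                 enable_wt = enable_wt,
                 enable_mam = enable_mam,
                 fixed_window = as.integer(fixed_window),
                 per_cluster_matrix = per_cluster_matrix),
            class = "training_config")
}

# ---- internal per-cluster engine ------------------------------------------

# Per-column pair-contribution matrices between query and reference code
# matrices: Ct[[col]][q, r] = Score(query[q, col], ref[r, col]).
column_contribs <- function(query_codes, ref_codes, matrix) {
  lapply(seq_len(ncol(query_codes)), function(col) {
    matrix[query_codes[, col], ref_codes[, col], drop = FALSE]
  })
}

# Leave-one-out Sn at fixed Sp from raw (unfloored) score matrices.
# raw_pp: np x np raw pairwise scores among positives; raw_np: nn x np raw
# scores of negatives vs positives.  The zero floor applies per pair.
loo_sn_from_raw <- function(raw_pp, raw_np, sp_fix) {
  np <- nrow(raw_pp)
  if (np >= 2L) {
    fl <- pmax(raw_pp, 0)
    pos <- (rowSums(fl) - diag(fl)) / (np - 1L)
  } else {
    pos <- rep(0, np)  # sole positive: empty LOO reference set, score 0
  }
  neg <- rowMeans(pmax(raw_np, 0))
  th <- threshold_at_sp(neg, sp_fix)
  list(sn = mean(pos >= th$cutoff), cutoff = th$cutoff,
       sp_achieved = th$sp_achieved, pos = pos, neg = neg)
}

# Extract integer-coded peptides for a set of sites at window (m, n).
site_codes <- function(dataset, sites, m, n) {
  encode_peptides(extract_nsp_many(dataset$sequences, sites$protein_id,
                                   sites$position, m, n))
}

#' Per-cluster window selection (PS)
#'
#' Exhaustively scans the window grid `m` in `1..ps_max_m`, `n` in
#' `1..ps_max_n`; for each candidate window the cluster's positives and
#' negatives are re-extracted, leave-one-out scores computed with unit
#' weights and the initial matrix, and sensitivity at the fixed specificity
#' evaluated.  The best window wins; ties break to the smallest `m + n`,
#' then the smallest `m`.
#'
#' @param dataset An `sno_dataset`.
#' @param positives,negatives Site data frames (`protein_id`, `position`) of
#'   one cluster.
#' @param matrix Initial substitution matrix.
#' @param config A [training_config()].
#' @return List with `window` (`c(m, n)`) and `sn` at that window.
#' @export
peptide_selection <- function(dataset, positives, negatives,
                              matrix = blosum62(), config = training_config()) {
  max_m <- config$ps_max_m; max_n <- config$ps_max_n
  np <- nrow(positives)
  pos_full <- site_codes(dataset, positives, max_m, max_n)
  neg_full <- site_codes(dataset, negatives, max_m, max_n)
  center <- max_m + 1L
  cpp <- column_contribs(pos_full, pos_full, matrix)
  cnp <- column_contribs(neg_full, pos_full, matrix)
  cum_up_pp <- vector("list", max_m); cum_up_np <- vector("list", max_m)
  acc_p <- 0; acc_n <- 0
  for (m in seq_len(max_m)) {
    acc_p <- acc_p + cpp[[center - m]]; cum_up_pp[[m]] <- acc_p
    acc_n <- acc_n + cnp[[center - m]]; cum_up_np[[m]] <- acc_n
  }
  cum_dn_pp <- vector("list", max_n); cum_dn_np <- vector("list", max_n)
  acc_p <- 0; acc_n <- 0
  for (n in seq_len(max_n)) {
    acc_p <- acc_p + cpp[[center + n]]; cum_dn_pp[[n]] <- acc_p
    acc_n <- acc_n + cnp[[center + n]]; cum_dn_np[[n]] <- acc_n
  }
  best <- NULL
  # visit windows by ascending m + n then ascending m so that, with strict
  # improvement only, the incumbent realises the declared tie-break
  for (total in 2L:(max_m + max_n)) {
    for (m in max(1L, total - max_n):min(max_m, total - 1L)) {
      n <- total - m
      raw_pp <- cpp[[center]] + cum_up_pp[[m]] + cum_dn_pp[[n]]
      raw_np <- cnp[[center]] + cum_up_np[[m]] + cum_dn_np[[n]]
      res <- loo_sn_from_raw(raw_pp, raw_np, config$sp_fix)
      if (is.null(best) || res$sn > best$sn)
        best <- list(window = c(m, n), sn = res$sn)
    }
  }
  best
}

#' Per-cluster position-weight training (WT)
#'
#' Stochastic hill climb over the per-position weights, all initially 1: a
#' position and a step of +1 or -1 are drawn uniformly, proposals driving a
#' weight below 0 are rejected outright, and a proposal is adopted only if
#' the leave-one-out sensitivity at the fixed specificity strictly increases.
#' The climb stops after `wt_max_stall` consecutive rejections.  Consumes the
#' current RNG stream.
#'
#' @inheritParams peptide_selection
#' @param window Length-2 window `c(m, n)` fixed by window selection.
#' @return List with `weights`, `trace` (data frame of accepted steps),
#'   `proposals`, `sn_initial` and `sn`.
#' @export
weight_training <- function(dataset, positives, negatives, window,
                            matrix = blosum62(), config = training_config()) {
  pos_codes <- site_codes(dataset, positives, window[[1L]], window[[2L]])
  neg_codes <- site_codes(dataset, negatives, window[[1L]], window[[2L]])
  len <- window[[1L]] + 1L + window[[2L]]
  cpp <- column_contribs(pos_codes, pos_codes, matrix)
  cnp <- column_contribs(neg_codes, pos_codes, matrix)
  w <- rep(1L, len)
  raw_pp <- Reduce(`+`, cpp)
  raw_np <- Reduce(`+`, cnp)
  cur <- loo_sn_from_raw(raw_pp, raw_np, config$sp_fix)
  sn0 <- cur$sn
  steps <- list(); stall <- 0L; step <- 0L
  while (stall < config$wt_max_stall) {
    step <- step + 1L
    j <- sample.int(len, 1L)
    d <- sample(c(1L, -1L), 1L)
    if (w[[j]] + d < 0L) { stall <- stall + 1L; next }
    new_pp <- raw_pp + d * cpp[[j]]
    new_np <- raw_np + d * cnp[[j]]
    res <- loo_sn_from_raw(new_pp, new_np, config$sp_fix)
    if (res$sn > cur$sn) {
      w[[j]] <- w[[j]] + d
      raw_pp <- new_pp; raw_np <- new_np; cur <- res
      steps[[length(steps) + 1L]] <-
        data.frame(step = step, proposal = sprintf("w[%d]%+d", j, d),
                   accepted = TRUE, sn = res$sn,
                   sp_achieved = res$sp_achieved)
      stall <- 0L
    } else stall <- stall + 1L
  }
  list(weights = w,
       trace = if (length(steps) > 0L) do.call(rbind, steps)
               else data.frame(step = integer(0), proposal = character(0),
                               accepted = logical(0), sn = numeric(0),
                               sp_achieved = numeric(0)),
       proposals = step, sn_initial = sn0, sn = cur$sn)
}

# Sparse index from unordered residue-pair type to the flat score-matrix
# entries it touches, weighted by the position weights (internal, MaM).
# codes_q x codes_r define a (nq x nr) raw-score matrix laid out column-major.
pair_type_index <- function(codes_q, codes_r, weights) {
  nq <- nrow(codes_q); nr <- nrow(codes_r); nf <- nq * nr
  type_all <- numeric(0); flat_all <- numeric(0); w_all <- numeric(0)
  for (col in seq_len(ncol(codes_q))) {
    a <- codes_q[, col][rep(seq_len(nq), times = nr)]
    b <- codes_r[, col][rep(seq_len(nr), each = nq)]
    keep <- a != PAD_CODE & b != PAD_CODE
    if (!any(keep)) next
    lo <- pmin(a, b)[keep]; hi <- pmax(a, b)[keep]
    type_all <- c(type_all, (lo - 1) * 20 + hi)
    flat_all <- c(flat_all, seq_len(nf)[keep])
    w_all <- c(w_all, rep(weights[[col]], sum(keep)))
  }
  if (length(type_all) == 0L) return(vector("list", 400L))
  key <- (type_all - 1) * nf + flat_all
  agg <- rowsum(w_all, group = key)
  key_u <- as.numeric(rownames(agg))
  flat_u <- ((key_u - 1) %% nf) + 1
  type_u <- ((key_u - 1) %/% nf) + 1
  out <- vector("list", 400L)
  for (t in unique(type_u)) {
    sel <- type_u == t
    out[[t]] <- list(flat = flat_u[sel], dw = agg[sel, 1L])
  }
  out
}

#' Per-cluster matrix mutation (MaM)
#'
#' Stochastic hill climb over the substitution-matrix entries, starting from
#' the initial (BLOSUM62) matrix: an unordered residue pair is drawn
#' uniformly from the 20x20 grid together with a step of +1 or -1, applied
#' jointly to `Score(a, b)` and `Score(b, a)` so symmetry is preserved (the
#' padding symbol is never touched), and adopted only if the leave-one-out
#' sensitivity at the fixed specificity strictly increases.  Stops after
#' `mam_max_stall` consecutive rejections.  Consumes the current RNG stream.
#'
#' @inheritParams weight_training
#' @param weights Position weights fixed by weight training.
#' @return List with `matrix`, `trace`, `proposals`, `sn_initial` and `sn`.
#' @export
matrix_mutation <- function(dataset, positives, negatives, window, weights,
                            matrix = blosum62(), config = training_config()) {
  pos_codes <- site_codes(dataset, positives, window[[1L]], window[[2L]])
  neg_codes <- site_codes(dataset, negatives, window[[1L]], window[[2L]])
  m_cur <- matrix
  cpp <- column_contribs(pos_codes, pos_codes, m_cur)
  cnp <- column_contribs(neg_codes, pos_codes, m_cur)
  raw_pp <- Reduce(`+`, Map(`*`, as.list(as.numeric(weights)), cpp))
  raw_np <- Reduce(`+`, Map(`*`, as.list(as.numeric(weights)), cnp))
  idx_pp <- pair_type_index(pos_codes, pos_codes, weights)
  idx_np <- pair_type_index(neg_codes, pos_codes, weights)
  cur <- loo_sn_from_raw(raw_pp, raw_np, config$sp_fix)
  sn0 <- cur$sn
  steps <- list(); stall <- 0L; step <- 0L
  while (stall < config$mam_max_stall) {
    step <- step + 1L
    a <- sample.int(20L, 1L)
    b <- sample.int(20L, 1L)
    d <- sample(c(1L, -1L), 1L)
    t <- (min(a, b) - 1L) * 20L + max(a, b)
    ep <- idx_pp[[t]]; en <- idx_np[[t]]
    if (is.null(ep) && is.null(en)) { stall <- stall + 1L; next }
    if (!is.null(ep)) raw_pp[ep$flat] <- raw_pp[ep$flat] + d * ep$dw
    if (!is.null(en)) raw_np[en$flat] <- raw_np[en$flat] + d * en$dw
    res <- loo_sn_from_raw(raw_pp, raw_np, config$sp_fix)
    if (res$sn > cur$sn) {
      m_cur[a, b] <- m_cur[a, b] + d
      if (a != b) m_cur[b, a] <- m_cur[b, a] + d
      cur <- res
      steps[[length(steps) + 1L]] <-
        data.frame(step = step,
                   proposal = sprintf("Score(%s,%s)%+d", GPS_ALPHABET[[a]],
                                      GPS_ALPHABET[[b]], d),
                   accepted = TRUE, sn = res$sn,
                   sp_achieved = res$sp_achieved)
      stall <- 0L
    } else {
      if (!is.null(ep)) raw_pp[ep$flat] <- raw_pp[ep$flat] - d * ep$dw
      if (!is.null(en)) raw_np[en$flat] <- raw_np[en$flat] - d * en$dw
      stall <- stall + 1L
    }
  }
  list(matrix = m_cur,
       trace = if (length(steps) > 0L) do.call(rbind, steps)
               else data.frame(step = integer(0), proposal = character(0),
                               accepted = logical(0), sn = numeric(0),
                               sp_achieved = numeric(0)),
       proposals = step, sn_initial = sn0, sn = cur$sn)
}

# ---- full pipelines --------------------------------------------------------

train_pipeline <- function(dataset, config, algorithm) {
  sites <- dataset$sites
  pos <- sites[sites$label == "+", , drop = FALSE]
  neg <- sites[sites$label == "-", , drop = FALSE]
  if (nrow(pos) < config$k)
    stop("dataset has fewer positives (", nrow(pos), ") than clusters (",
         config$k, ")")
  if (nrow(neg) < 1L) stop("dataset has no negative sites")
  set.seed(config$seed)
  init_matrix <- blosum62()
  cw <- config$clustering_window
  pos77 <- extract_nsp_many(dataset$sequences, pos$protein_id, pos$position,
                            cw[[1L]], cw[[2L]])
  neg77 <- extract_nsp_many(dataset$sequences, neg$protein_id, neg$position,
                            cw[[1L]], cw[[2L]])
  assignment <- kmeans_positives(pos77, k = config$k, matrix = init_matrix)
  assignment <- attach_negatives(assignment, neg77, matrix = init_matrix)
  clusters <- vector("list", config$k)
  traces <- vector("list", config$k)
  log_rows <- list()
  add_log <- function(cluster, stage, step, proposal, accepted, sn, sp) {
    log_rows[[length(log_rows) + 1L]] <<-
      data.frame(cluster = cluster, stage = stage, step = step,
                 proposal = proposal, accepted = accepted, sn = sn,
                 sp_achieved = sp, stringsAsFactors = FALSE)
  }
  for (ci in seq_len(config$k)) {
    id <- LETTERS[[ci]]
    cl_pos <- pos[assignment$members_pos[[ci]], , drop = FALSE]
    cl_neg <- neg[assignment$members_neg[[ci]], , drop = FALSE]
    if (nrow(cl_neg) == 0L)
      stop("cluster ", id, " attracted no negative sites; ",
           "re-train with a smaller k")
    # 1) window selection
    if (config$enable_ps) {
      ps <- peptide_selection(dataset, cl_pos, cl_neg, init_matrix, config)
      window <- ps$window
      add_log(id, "PS", NA_integer_,
              sprintf("NSP(%d,%d)", window[[1L]], window[[2L]]), TRUE,
              ps$sn, NA_real_)
    } else {
      window <- config$fixed_window
    }
    # 2) weight training
    if (config$enable_wt) {
      wt <- weight_training(dataset, cl_pos, cl_neg, window, init_matrix,
                            config)
      weights <- wt$weights
      if (nrow(wt$trace) > 0L)
        add_log(id, "WT", wt$trace$step, wt$trace$proposal, TRUE,
                wt$trace$sn, wt$trace$sp_achieved)
      add_log(id, "WT", wt$proposals, "final", NA, wt$sn, NA_real_)
      wt_trace <- wt$trace; sn_wt0 <- wt$sn_initial; sn_wt <- wt$sn
    } else {
      weights <- rep(1L, window[[1L]] + 1L + window[[2L]])
      wt_trace <- NULL; sn_wt0 <- NA_real_; sn_wt <- NA_real_
    }
    # 3) matrix mutation
    if (config$enable_mam) {
      mam <- matrix_mutation(dataset, cl_pos, cl_neg, window, weights,
                             init_matrix, config)
      cl_matrix <- mam$matrix
      if (nrow(mam$trace) > 0L)
        add_log(id, "MaM", mam$trace$step, mam$trace$proposal, TRUE,
                mam$trace$sn, mam$trace$sp_achieved)
      add_log(id, "MaM", mam$proposals, "final", NA, mam$sn, NA_real_)
      mam_trace <- mam$trace; sn_mam0 <- mam$sn_initial; sn_mam <- mam$sn
    } else {
      cl_matrix <- init_matrix
      mam_trace <- NULL; sn_mam0 <- NA_real_; sn_mam <- NA_real_
    }
    # final leave-one-out scores under the trained parameters; calibrate the
    # three prediction cutoffs on this cluster's own negative scores
    pos_codes <- site_codes(dataset, cl_pos, window[[1L]], window[[2L]])
    neg_codes <- site_codes(dataset, cl_neg, window[[1L]], window[[2L]])
    cpp <- column_contribs(pos_codes, pos_codes, cl_matrix)
    cnp <- column_contribs(neg_codes, pos_codes, cl_matrix)
    wnum <- as.numeric(weights)
    raw_pp <- Reduce(`+`, Map(`*`, as.list(wnum), cpp))
    raw_np <- Reduce(`+`, Map(`*`, as.list(wnum), cnp))
    final <- loo_sn_from_raw(raw_pp, raw_np, config$sp_fix)
    cuts <- lapply(config$calibration_levels,
                   function(lv) threshold_at_sp(final$neg, lv))
    cutoffs <- vapply(cuts, `[[`, numeric(1), "cutoff")
    achieved <- vapply(cuts, `[[`, numeric(1), "sp_achieved")
    clusters[[ci]] <- list(
      id = id,
      window = window,
      weights = as.integer(weights),
      matrix = cl_matrix,
      positives = extract_nsp_many(dataset$sequences, cl_pos$protein_id,
                                   cl_pos$position, window[[1L]], window[[2L]]),
      positives_ref = pos77[assignment$members_pos[[ci]]],
      sites = data.frame(protein_id = cl_pos$protein_id,
                         position = cl_pos$position,
                         stringsAsFactors = FALSE),
      has = assignment$has[[ci]],
      cutoffs = cutoffs,
      achieved_sp = achieved)
    traces[[ci]] <- list(stage_sn = c(wt_initial = sn_wt0, wt_final = sn_wt,
                                      mam_initial = sn_mam0,
                                      mam_final = sn_mam, final = final$sn),
                         wt = wt_trace, mam = mam_trace)
  }
  log <- list(table = if (length(log_rows) > 0L) do.call(rbind, log_rows)
                      else NULL,
              traces = traces)
  new_gps_model(algorithm = algorithm,
                clustering_window = cw,
                clustering_matrix = init_matrix,
                clusters = clusters,
                sp_fix = config$sp_fix,
                calibration_levels = config$calibration_levels,
                seed = config$seed,
                log = log)
}

#' Train the full group-based predictor (GPS 3.0 pipeline)
#'
#' Runs the four training stages in order: similarity k-means clustering of
#' the positive sites at the clustering window (negatives attached by the
#' highest-average-similarity rule; membership is frozen thereafter), then
#' per cluster: window selection (PS), position-weight training (WT) and
#' matrix mutation (MaM), each maximising leave-one-out sensitivity at the
#' fixed specificity against the cluster's own negatives.  Finally the
#' high/medium/low prediction cutoffs are calibrated per cluster on the
#' final leave-one-out negative scores.
#'
#' @param dataset An `sno_dataset` with at least `k` positives and at least
#'   one negative per resulting cluster.
#' @param config A [training_config()].
#' @return A trained `gps_model` (serializable with [write_model()]), with a
#'   per-stage training log in `$log` and accepted-step traces in each
#'   cluster's `wt_trace` / `mam_trace`.
#' @export
train_gps3 <- function(dataset, config = training_config()) {
  train_pipeline(dataset, config, algorithm = "gps3")
}

#' Train the single-group baseline (GPS 2.0 pipeline)
#'
#' The comparison arm: one group (no clustering), fixed NSP(7, 7) window,
#' unit weights, matrix mutation only, with the same calibration and model
#' container as the full pipeline.
#'
#' @inheritParams train_gps3
#' @export
train_gps2_baseline <- function(dataset, config = training_config()) {
  config$k <- 1L
  config$enable_ps <- FALSE
  config$enable_wt <- FALSE
  config$enable_mam <- TRUE
  config$fixed_window <- c(7L, 7L)
  train_pipeline(dataset, config, algorithm = "gps2")
}
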