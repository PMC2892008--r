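#' Train a position-specific scoring matrix (PSSM) baseline
#'
#' For every window position `i` and residue `a` the log-odds of the
#' positive-class over the negative-class residue probability is estimated
#' with add-`pseudocount` smoothing:
#' `log((c+(i,a)+pc)/(N+ + 20 pc)) - log((c-(i,a)+pc)/(N- + 20 pc))`.
#' The padding symbol and non-standard residues score 0.  Positional
#' (per-column) probabilities are the default; `positional = FALSE` pools
#' the window into a single composition column applied at every position.
#'
#' @param dataset An `sno_dataset`.
#' @param window Length-2 window `c(m, n)` (default NSP(7, 7), the standard
#'   comparison setting).
#' @param pseudocount Positive smoothing constant (default 1, add-one).
#' @param positional Per-column probabilities (default) or composition-only.
#' @return Object of class `pssm_model` with the `log_odds` matrix
#'   (21 symbols x window length; padding row all zero).
#' @export
pssm_train <- function(dataset, window = c(7L, 7L), pseudocount = 1,
                       positional = TRUE) {
  stopifnot(pseudocount > 0)
  sites <- dataset$sites
  pos <- sites[sites$label == "+", , drop = FALSE]
  neg <- sites[sites$label == "-", , drop = FALSE]
  if (nrow(pos) == 0L || nrow(neg) == 0L)
    stop("PSSM training requires at least one positive and one negative")
  len <- window[[1L]] + 1L + window[[2L]]
  count_codes <- function(ss) {
    codes <- site_codes(dataset, ss, window[[1L]], window[[2L]])
    counts <- matrix(0, nrow = 21L, ncol = len,
                     dimnames = list(GPS_ALPHABET, NULL))
    for (col in seq_len(len)) {
      tab <- tabulate(codes[, col], nbins = 21L)
      counts[, col] <- tab
    }
    counts
  }
  cpos <- count_codes(pos)
  cneg <- count_codes(neg)
  if (!positional) {
    cpos <- matrix(rowSums(cpos), nrow = 21L, ncol = len,
                   dimnames = dimnames(cpos))
    cneg <- matrix(rowSums(cneg), nrow = 21L, ncol = len,
                   dimnames = dimnames(cneg))
  }
  # only the 20 standard residues enter the probability model; padding and
  # non-standard residues score 0 by convention
  npos <- colSums(cpos[1:20, , drop = FALSE])
  nneg <- colSums(cneg[1:20, , drop = FALSE])
  lo <- matrix(0, nrow = 21L, ncol = len, dimnames = list(GPS_ALPHABET, NULL))
  for (col in seq_len(len)) {
    p_pos <- (cpos[1:20, col] + pseudocount) / (npos[[col]] + 20 * pseudocount)
    p_neg <- (cneg[1:20, col] + pseudocount) / (nneg[[col]] + 20 * pseudocount)
    lo[1:20, col] <- log(p_pos) - log(p_neg)
  }
  structure(list(window = as.integer(window), log_odds = lo,
                 pseudocount = pseudocount, positional = positional,
                 counts_pos = cpos, counts_neg = cneg),
            class = "pssm_model")
}

#' Score a peptide with a PSSM model
#'
#' The score of a peptide is the sum of its per-position log-odds entries.
#'
#' @param model A `pssm_model` from [pssm_train()].
#' @param peptide Peptide string matching the model window length.
#' @return Numeric score.
#' @export
pssm_score <- function(model, peptide) {
  len <- ncol(model$log_odds)
  if (nchar(peptide) != len)
    stop("peptide length ", nchar(peptide), " does not match PSSM window ",
         len)
  codes <- encode_peptides(peptide)
  sum(model$log_odds[cbind(codes[1L, ], seq_len(len))])
}

# Leave-one-out PSSM scores: each site is scored with its own residue counts
# removed from its class before the log-odds are formed (internal; exact
# because PSSM training is pure counting).
pssm_loo_scores <- function(dataset, window = c(7L, 7L), pseudocount = 1) {
  model <- pssm_train(dataset, window, pseudocount)
  sites <- dataset$sites
  len <- window[[1L]] + 1L + window[[2L]]
  codes <- site_codes(dataset, sites, window[[1L]], window[[2L]])
  npos <- colSums(model$counts_pos[1:20, , drop = FALSE])
  nneg <- colSums(model$counts_neg[1:20, , drop = FALSE])
  vapply(seq_len(nrow(sites)), function(i) {
    cpos <- model$counts_pos; cneg <- model$counts_neg
    if (sites$label[[i]] == "+") {
      cpos[cbind(codes[i, ], seq_len(len))] <-
        cpos[cbind(codes[i, ], seq_len(len))] - 1
      np <- npos - (codes[i, ] != PAD_CODE); nn <- nneg
    } else {
      cneg[cbind(codes[i, ], seq_len(len))] <-
        cneg[cbind(codes[i, ], seq_len(len))] - 1
      np <- npos; nn <- nneg - (codes[i, ] != PAD_CODE)
    }
    s <- 0
    for (col in seq_len(len)) {
      a <- codes[i, col]
      if (a == PAD_CODE) next
      p_pos <- (cpos[a, col] + pseudocount) / (np[[col]] + 20 * pseudocount)
      p_neg <- (cneg[a, col] + pseudocount) / (nn[[col]] + 20 * pseudocount)
      s <- s + log(p_pos) - log(p_neg)
    }
    s
  }, numeric(1))
}

#' Acid-base motif rule
#'
#' `TRUE` when the residue immediately upstream of the central cysteine is
#' one of K/R/H/D/E and the residue immediately downstream is D or E — the
#' classical acid-base recognition pattern K/R/H/D/E-C-D/E.  Terminal padding
#' at either flank never matches.
#'
#' @param peptide Cysteine-centred peptide of odd-positioned centre
#'   `m + 1` for a window `c(m, n)` with `m, n >= 1`.
#' @param m Upstream flank length locating the centre (default: symmetric
#'   window, `(nchar(peptide) - 1) / 2`).
#' @return Logical scalar.
#' @examples
#' motif_match("KCD", m = 1)  # TRUE
#' motif_match("ACA", m = 1)  # FALSE
#' @export
motif_match <- function(peptide, m = (nchar(peptide) - 1L) %/% 2L) {
  stopifnot(m >= 1L, nchar(peptide) >= m + 2L)
  up <- substr(peptide, m, m)
  down <- substr(peptide, m + 2L, m + 2L)
  up %in% c("K", "R", "H", "D", "E") && down %in% c("D", "E")
}
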