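#' Default planted flanking-residue signal profile
#'
#' Per-offset residue distributions planted around positive-site cysteines,
#' emulating the acid-base enrichment reported around S-nitrosylation sites:
#' basic/acidic residues (K/R/H/D/E, uniform) at offsets -2 and -1 and acidic
#' residues (D/E, uniform) at offsets +1 and +2.
#'
#' @return Named list mapping offset (as character, e.g. `"-1"`) to a named
#'   probability vector over residues.
#' @export
default_signal_profile <- function() {
  basic_acidic <- stats::setNames(rep(1 / 5, 5), c("K", "R", "H", "D", "E"))
  acidic <- stats::setNames(rep(1 / 2, 2), c("D", "E"))
  list(`-2` = basic_acidic, `-1` = basic_acidic,
       `1` = acidic, `2` = acidic)
}

#' Simulation configuration for planted-signal benchmark datasets
#'
#' Defaults emulate the shape of a curated S-nitrosylation training set:
#' 200 proteins of mean length 300 carrying 300 positive and 1500 negative
#' cysteine sites (about 1.5 modified and 8 unmodified cysteines per
#' substrate), with a uniform 1/20 background composition (simple nulls and
#' closed-form motif frequencies) and the acid-base signal profile of
#' [default_signal_profile()] planted at full strength.
#'
#' @param n_proteins Number of proteins.
#' @param length_mean Mean protein length (lengths vary around it).
#' @param n_pos_sites,n_neg_sites Total positive / negative site counts.
#' @param signal_profile Per-offset residue distributions (see
#'   [default_signal_profile()]).
#' @param signal_strength Probability in `[0, 1]` that each profiled offset
#'   of a positive site is resampled from the profile (0 = pure background).
#' @param background_freqs Named probability vector over the 20 residues.
#' @param seed Integer seed; the generator is deterministic in it.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 200L,
                              length_mean = 300L,
                              n_pos_sites = 300L,
                              n_neg_sites = 1500L,
                              signal_profile = default_signal_profile(),
                              signal_strength = 1.0,
                              background_freqs = stats::setNames(
                                rep(1 / 20, 20), AA20),
                              seed = 1L) {
  stopifnot(signal_strength >= 0, signal_strength <= 1,
            abs(sum(background_freqs) - 1) < 1e-8,
            all(names(background_freqs) %in% AA20))
  for (p in signal_profile)
    stopifnot(abs(sum(p) - 1) < 1e-8, all(names(p) %in% AA20))
  structure(list(n_proteins = as.integer(n_proteins),
                 length_mean = as.integer(length_mean),
                 n_pos_sites = as.integer(n_pos_sites),
                 n_neg_sites = as.integer(n_neg_sites),
                 signal_profile = signal_profile,
                 signal_strength = signal_strength,
                 background_freqs = background_freqs,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic planted-signal site dataset
#'
#' Proteins are drawn residue-wise from the background composition; cysteines
#' are planted at randomly chosen, well-separated positions and labelled
#' positive or negative.  For positive sites each profiled flanking offset is
#' resampled from the signal profile with probability `signal_strength`;
#' negative sites keep pure background flanks.  Positive and negative sites
#' co-occur on the same proteins, as unmodified cysteines of real substrates
#' do.  Deterministic in `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return An `sno_dataset`.
#' @export
generate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_sites <- config$n_pos_sites + config$n_neg_sites
  lens <- pmax(60L, round(stats::rnorm(config$n_proteins,
                                       config$length_mean,
                                       config$length_mean / 5)))
  ids <- sprintf("SYN%04d", seq_len(config$n_proteins))
  # planted sites are kept >= 5 residues apart so one site's planted flanks
  # cannot overwrite another site's centre or profiled offsets
  slot_gap <- 5L
  capacity <- sum((lens - 2L) %/% slot_gap)
  if (n_sites > capacity)
    stop("requested ", n_sites, " sites but only ", capacity,
         " placeable cysteine slots across ", config$n_proteins, " proteins")
  bg <- config$background_freqs
  seq_chars <- lapply(lens, function(L)
    sample(names(bg), L, replace = TRUE, prob = bg))
  # candidate slots: every slot_gap-th interior position of every protein
  slots <- do.call(rbind, lapply(seq_len(config$n_proteins), function(i) {
    pos <- seq(2L, lens[[i]] - 1L, by = slot_gap)
    cbind(protein = i, position = pos)
  }))
  pick <- slots[sample.int(nrow(slots), n_sites), , drop = FALSE]
  labels <- c(rep("+", config$n_pos_sites), rep("-", config$n_neg_sites))
  offs <- as.integer(names(config$signal_profile))
  for (s in seq_len(n_sites)) {
    i <- pick[s, "protein"]; p <- pick[s, "position"]
    seq_chars[[i]][p] <- "C"
    if (labels[[s]] == "+") {
      for (oi in seq_along(offs)) {
        tp <- p + offs[[oi]]
        if (tp < 1L || tp > lens[[i]]) next
        if (stats::runif(1) < config$signal_strength) {
          prof <- config$signal_profile[[oi]]
          seq_chars[[i]][tp] <- sample(names(prof), 1L, prob = prof)
        }
      }
    }
  }
  sequences <- stats::setNames(vapply(seq_chars, paste, character(1),
                                      collapse = ""), ids)
  sites <- data.frame(protein_id = ids[pick[, "protein"]],
                      position = as.integer(pick[, "position"]),
                      label = labels, stringsAsFactors = FALSE)
  sites <- sites[order(sites$protein_id, sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  site_dataset(sequences, sites)
}

#' Permute site labels (negative control)
#'
#' Uniformly permutes the +/- labels among all sites of the dataset, leaving
#' sequences and site positions untouched — the standard permutation null for
#' recovery experiments: any pipeline trained and evaluated in the permuted
#' world should perform at chance.
#'
#' @param dataset An `sno_dataset`.
#' @param seed Integer seed for the permutation.
#' @return An `sno_dataset` with permuted labels.
#' @export
shuffle_labels <- function(dataset, seed = 1L) {
  set.seed(seed)
  sites <- dataset$sites
  sites$label <- sites$label[sample.int(nrow(sites))]
  site_dataset(dataset$sequences, sites)
}
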