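#' Extract a cysteine-centred site peptide NSP(m, n)
#'
#' A nitrosylation site peptide NSP(m, n) is the cysteine at `position`
#' flanked by `m` residues upstream and `n` residues downstream.  Positions
#' falling outside the protein are filled with the padding symbol `*`, so the
#' result always has length `m + 1 + n`.
#'
#' @param sequence Amino-acid string.
#' @param position 1-based position of the central cysteine.
#' @param m,n Non-negative flank lengths upstream (`m`) and downstream (`n`).
#' @return Character scalar of length `m + 1 + n`.
#' @examples
#' extract_nsp("AKCDE", 3, 2, 2)  # "AKCDE"
#' extract_nsp("CDE", 1, 3, 2)    # "***CDE"
#' @export
extract_nsp <- function(sequence, position, m, n) {
  stopifnot(length(sequence) == 1L, m >= 0, n >= 0)
  len <- nchar(sequence)
  if (position < 1L || position > len)
    stop("position ", position, " out of range [1, ", len, "]")
  if (substr(sequence, position, position) != "C")
    stop("residue at position ", position, " is ",
         substr(sequence, position, position), ", expected C")
  lo <- position - m
  hi <- position + n
  core <- substr(sequence, max(1L, lo), min(len, hi))
  paste0(strrep(PAD_SYMBOL, max(0L, 1L - lo)),
         core,
         strrep(PAD_SYMBOL, max(0L, hi - len)))
}

# Vectorised NSP extraction for many (sequence, position) pairs (internal).
extract_nsp_many <- function(sequences, protein_ids, positions, m, n) {
  vapply(seq_along(protein_ids), function(i) {
    extract_nsp(sequences[[protein_ids[[i]]]], positions[[i]], m, n)
  }, character(1))
}

#' Enumerate cysteine positions in a protein sequence
#'
#' @param sequence Amino-acid string.
#' @return Ascending integer vector of 1-based positions of every `C`
#'   (empty for cysteine-free sequences).
#' @examples
#' enumerate_cysteines("MCKC")  # c(2, 4)
#' @export
enumerate_cysteines <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  which(strsplit(sequence, "", fixed = TRUE)[[1L]] == "C")
}
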