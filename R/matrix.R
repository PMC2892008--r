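#' @keywords internal
"_PACKAGE"

# Residue order used everywhere: the 20 standard amino acids followed by the
# terminal-padding symbol '*'.  Any character outside this set (B, Z, X, U, ...)
# is encoded as the padding index and therefore scores 0 against everything.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
PAD_SYMBOL <- "*"
GPS_ALPHABET <- c(AA20, PAD_SYMBOL)
PAD_CODE <- length(GPS_ALPHABET)

#' BLOSUM62 substitution matrix with a zero-scoring padding symbol
#'
#' Returns the standard BLOSUM62 amino-acid substitution matrix restricted to
#' the 20 standard residues, augmented with the terminal-padding symbol `*`
#' whose row and column are all zero.  Peptide windows that overhang a protein
#' terminus are padded with `*`, so padding positions contribute nothing to any
#' peptide-pair score.  This matrix is the initial matrix for training and the
#' fixed matrix for similarity clustering.
#'
#' @return An integer matrix with dimnames over the 21-symbol alphabet
#'   (20 residues plus `*`), symmetric, with `*` scoring 0 against everything.
#' @examples
#' m <- blosum62()
#' m["C", "C"]  # 9
#' m["*", "W"]  # 0
#' @export
blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  base <- env$BLOSUM62[AA20, AA20]
  out <- matrix(0L, nrow = 21L, ncol = 21L,
                dimnames = list(GPS_ALPHABET, GPS_ALPHABET))
  out[AA20, AA20] <- as.integer(base)
  out
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses a whitespace-delimited substitution matrix file as distributed with
#' BLAST: comment lines starting with `#`, a header row of residue letters,
#' then one labelled row per residue.  The matrix is validated for symmetry,
#' restricted to the package's 21-symbol alphabet, and the padding symbol `*`
#' is forced to score 0 against everything (appended if absent), in keeping
#' with the window-padding convention.
#'
#' @param path Path to a matrix text file.
#' @return An integer matrix as returned by [blosum62()].
#' @export
read_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("matrix file '", path, "' has no data rows")
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  row_names <- vapply(rows, `[[`, character(1), 1L)
  vals <- lapply(rows, function(r) {
    v <- suppressWarnings(as.integer(r[-1L]))
    if (anyNA(v) || length(v) != length(header))
      stop("malformed matrix row for residue '", r[[1L]], "'")
    v
  })
  m <- do.call(rbind, vals)
  dimnames(m) <- list(row_names, header)
  missing_rows <- setdiff(colnames(m), rownames(m))
  if (length(missing_rows) > 0L)
    stop("missing matrix row for residue(s): ",
         paste(missing_rows, collapse = ", "))
  m <- m[colnames(m), , drop = FALSE]
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (m[i, j] != m[j, i])
        stop("matrix is asymmetric at pair (", rownames(m)[i], ", ",
             colnames(m)[j], "): ", m[i, j], " vs ", m[j, i])
    }
  }
  absent <- setdiff(AA20, rownames(m))
  if (length(absent) > 0L)
    stop("missing matrix row for residue(s): ", paste(absent, collapse = ", "))
  out <- matrix(0L, nrow = 21L, ncol = 21L,
                dimnames = list(GPS_ALPHABET, GPS_ALPHABET))
  out[AA20, AA20] <- m[AA20, AA20]
  storage.mode(out) <- "integer"
  out
}

# Validate a 21x21 substitution matrix (internal).
check_matrix <- function(matrix) {
  stopifnot(is.matrix(matrix),
            identical(dim(matrix), c(21L, 21L)),
            identical(rownames(matrix), GPS_ALPHABET),
            identical(colnames(matrix), GPS_ALPHABET))
  if (any(matrix[PAD_CODE, ] != 0) || any(matrix[, PAD_CODE] != 0))
    stop("padding symbol '*' must score 0 against every residue")
  if (!identical(matrix, t(matrix)))
    stop("substitution matrix must be symmetric")
  invisible(matrix)
}

# Encode peptide strings into an integer matrix (rows = peptides, columns =
# window positions); characters outside the alphabet map to the padding code.
encode_peptides <- function(peptides) {
  if (length(peptides) == 0L) return(matrix(integer(0), nrow = 0L, ncol = 0L))
  n <- nchar(peptides)
  if (length(unique(n)) != 1L) stop("peptides must all have the same length")
  chars <- matrix(unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(peptides), byrow = TRUE)
  codes <- match(chars, GPS_ALPHABET)
  codes[is.na(codes)] <- PAD_CODE
  matrix(codes, nrow = length(peptides))
}
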