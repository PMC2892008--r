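#' Read protein sequences from a FASTA file
#'
#' Identifiers are the first whitespace-delimited token of each header line;
#' sequences are upper-cased with whitespace removed.  Residue letters outside
#' the 20 standard amino acids are tolerated with a warning; such residues are
#' kept in the sequence and score 0 against everything (like window padding).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector mapping protein identifier to sequence.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no sequences")
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate identifier in FASTA file: ", paste(dup, collapse = ", "))
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  names(seqs) <- ids
  odd <- setdiff(unique(unlist(strsplit(seqs, "", fixed = TRUE))), AA20)
  if (length(odd) > 0L)
    warning("non-standard residue letter(s) ", paste(odd, collapse = ", "),
            " found; they are kept and will score 0 against everything")
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences Named character vector of amino-acid strings.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Construct and validate a labelled cysteine-site dataset
#'
#' @param sequences Named character vector of protein sequences.
#' @param sites Data frame with columns `protein_id`, `position` (1-based) and
#'   `label` (`"+"` or `"-"`).
#' @return An object of class `sno_dataset` (list with `sequences`, `sites`).
#' @export
site_dataset <- function(sequences, sites) {
  stopifnot(is.character(sequences), !is.null(names(sequences)),
            is.data.frame(sites),
            all(c("protein_id", "position", "label") %in% names(sites)))
  sites <- data.frame(protein_id = as.character(sites$protein_id),
                      position = as.integer(sites$position),
                      label = as.character(sites$label),
                      stringsAsFactors = FALSE)
  bad_label <- setdiff(unique(sites$label), c("+", "-"))
  if (length(bad_label) > 0L)
    stop("unknown label token(s): ", paste(bad_label, collapse = ", "))
  unknown <- setdiff(unique(sites$protein_id), names(sequences))
  if (length(unknown) > 0L)
    stop("site refers to unknown protein(s): ", paste(unknown, collapse = ", "))
  key <- paste(sites$protein_id, sites$position)
  if (anyDuplicated(key))
    stop("duplicate (protein_id, position) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  for (i in seq_len(nrow(sites))) {
    seq <- sequences[[sites$protein_id[[i]]]]
    pos <- sites$position[[i]]
    if (pos < 1L || pos > nchar(seq))
      stop("position ", pos, " out of range for protein ",
           sites$protein_id[[i]], " (length ", nchar(seq), ")")
    res <- substr(seq, pos, pos)
    if (res != "C")
      stop("protein ", sites$protein_id[[i]], ": residue at position ", pos,
           " is ", res, ", expected C")
  }
  structure(list(sequences = sequences, sites = sites), class = "sno_dataset")
}

#' @export
print.sno_dataset <- function(x, ...) {
  cat("sno_dataset:", length(x$sequences), "proteins,",
      sum(x$sites$label == "+"), "positive and",
      sum(x$sites$label == "-"), "negative cysteine sites\n")
  invisible(x)
}

#' Read a cysteine-site annotation table
#'
#' Reads a tab-separated table with a one-line header and columns
#' `protein_id`, `position` (1-based) and `label` (`+` or `-`), binds it to
#' the given sequences and validates every record (position in range, residue
#' is cysteine).  With `auto_negatives = TRUE` every cysteine of every listed
#' protein that is not marked `+` is added as a negative record — the labelling
#' rule under which all non-modified cysteines of a substrate are negatives.
#'
#' @param path Path to the TSV site table.
#' @param sequences Named character vector of protein sequences.
#' @param auto_negatives Add unlisted cysteines of listed proteins as negatives.
#' @return An `sno_dataset`.
#' @export
read_sites <- function(path, sequences, auto_negatives = FALSE) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "")
  need <- c("protein_id", "position", "label")
  if (!all(need %in% names(tab)))
    stop("site table must have columns protein_id, position, label")
  tab$position <- as.integer(tab$position)
  if (auto_negatives) {
    extra <- list()
    for (pid in unique(tab$protein_id)) {
      if (!pid %in% names(sequences)) next
      cys <- enumerate_cysteines(sequences[[pid]])
      listed <- tab$position[tab$protein_id == pid]
      add <- setdiff(cys, listed)
      if (length(add) > 0L)
        extra[[pid]] <- data.frame(protein_id = pid, position = add,
                                   label = "-", stringsAsFactors = FALSE)
    }
    tab <- rbind(tab[, need], do.call(rbind, extra))
  }
  site_dataset(sequences, tab)
}

#' Write a site table to TSV
#'
#' @param dataset An `sno_dataset`.
#' @param path Output path.
#' @export
write_sites <- function(dataset, path) {
  utils::write.table(dataset$sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

MODEL_FORMAT_VERSION <- 1L

matrix_to_list <- function(m) {
  list(alphabet = rownames(m),
       scores = lapply(seq_len(nrow(m)), function(i) unname(m[i, ])))
}

list_to_matrix <- function(x) {
  alphabet <- unlist(x$alphabet)
  m <- do.call(rbind, lapply(x$scores, function(r) as.integer(unlist(r))))
  dimnames(m) <- list(alphabet, alphabet)
  check_matrix(m)
  m
}

#' Serialize a trained model to a JSON file
#'
#' The model file is versioned structured text (JSON) holding the clustering
#' window and matrix plus, per cluster, the window, position weights, mutated
#' substitution matrix, reference positive peptides (both in the cluster's own
#' window and in the clustering window, used for cluster assignment of query
#' sites) and calibrated high/medium/low cutoffs.  `read_model()` reproduces
#' the model field-for-field.
#'
#' @param model A `gps_model` as returned by [train_gps3()].
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "gps_model"))
  for (cl in model$clusters) {
    if (is.null(cl$cutoffs) || is.null(cl$weights) || is.null(cl$matrix) ||
        is.null(cl$window))
      stop("model is not fully trained; refusing to serialize")
  }
  payload <- list(
    format = "gpsno-model",
    version = MODEL_FORMAT_VERSION,
    algorithm = model$algorithm,
    clustering_window = model$clustering_window,
    clustering_matrix = matrix_to_list(model$clustering_matrix),
    sp_fix = model$sp_fix,
    calibration_levels = as.list(model$calibration_levels),
    seed = model$seed,
    clusters = lapply(model$clusters, function(cl) {
      list(id = cl$id,
           window = cl$window,
           weights = cl$weights,
           matrix = matrix_to_list(cl$matrix),
           positives = cl$positives,
           positives_ref = cl$positives_ref,
           sites = cl$sites,
           has = cl$has,
           cutoffs = as.list(cl$cutoffs),
           achieved_sp = as.list(cl$achieved_sp))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a trained model from a JSON file
#'
#' @param path Path to a model file written by [write_model()].
#' @return A `gps_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file '", path, "' does not exist")
  payload <- tryCatch(jsonlite::read_json(path),
                      error = function(e) stop("cannot parse model file '",
                                               path, "': ", conditionMessage(e)))
  if (!identical(payload$format, "gpsno-model"))
    stop("'", path, "' is not a gpsno model file")
  if (!identical(as.integer(payload$version), MODEL_FORMAT_VERSION))
    stop("model file version ", payload$version,
         " not supported by this reader (version ", MODEL_FORMAT_VERSION, ")")
  clusters <- lapply(payload$clusters, function(cl) {
    list(id = cl$id,
         window = as.integer(unlist(cl$window)),
         weights = as.integer(unlist(cl$weights)),
         matrix = list_to_matrix(cl$matrix),
         positives = as.character(unlist(cl$positives)),
         positives_ref = as.character(unlist(cl$positives_ref)),
         sites = data.frame(
           protein_id = vapply(cl$sites, function(r) as.character(r$protein_id),
                               character(1)),
           position = vapply(cl$sites, function(r) as.integer(r$position),
                             integer(1)),
           stringsAsFactors = FALSE),
         has = as.numeric(cl$has),
         cutoffs = unlist(cl$cutoffs),
         achieved_sp = unlist(cl$achieved_sp))
  })
  new_gps_model(algorithm = payload$algorithm,
                clustering_window = as.integer(unlist(payload$clustering_window)),
                clustering_matrix = list_to_matrix(payload$clustering_matrix),
                clusters = clusters,
                sp_fix = as.numeric(payload$sp_fix),
                calibration_levels = unlist(payload$calibration_levels),
                seed = as.integer(payload$seed))
}
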