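#' The 21-letter amino-acid alphabet
#'
#' The 20 canonical amino acids in alphabetical order followed by `"X"`, the
#' token used both for sequence-boundary padding and for any non-canonical
#' letter (B, J, O, U, Z, ...).  Token codes are 0-based: `A = 0`, ...,
#' `Y = 19`, `X = 20`.
#'
#' @format Character vector of length 21.
#' @export
AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and whitespace-stripped; record ids are the first
#' whitespace-delimited token of each header.  Non-canonical letters are kept
#' as read (they are mapped to the missing-residue token only at encoding
#' time).
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` and `sequence`, one row per record,
#'   input order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA ids: ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  if (any(!nzchar(seqs))) stop("empty sequence for id: ", ids[!nzchar(seqs)][1])
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins Data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::BStringSet(proteins$sequence)
  names(set) <- proteins$id
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read / write site-label tables
#'
#' Tab-separated tables with header `protein_id`, `position`, `label` (and
#' optionally `window` when exported from [build_site_dataset()]).
#'
#' @param path Path to the TSV file.
#' @return `read_sites`: data frame with the table's columns, `position`
#'   integer, `label` in \{0, 1\} when present.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position")
  if (!all(need %in% names(x)))
    stop("site table must have columns protein_id and position")
  x$position <- as.integer(x$position)
  if ("label" %in% names(x)) {
    x$label <- as.integer(x$label)
    if (any(!x$label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  }
  x
}

#' @rdname read_sites
#' @param sites Data frame of sites to write.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract a fixed window around a residue
#'
#' Returns the `2 * half_width + 1` residues centred on `position`; positions
#' beyond either end of the sequence are filled with the pad character, which
#' doubles as the missing-residue token of the encoding alphabet.
#'
#' @param sequence Protein sequence (single string).
#' @param position 1-based residue index, the window centre.
#' @param half_width Residues on each side of the centre (default 16, giving
#'   the 33-residue 16-K-16 window).
#' @param pad Padding character (default `"X"`).
#' @return A string of length `2 * half_width + 1`.
#' @export
extract_window <- function(sequence, position, half_width = 16L, pad = "X") {
  n <- nchar(sequence)
  if (position < 1L || position > n)
    stop("position ", position, " out of range for sequence of length ", n)
  lo <- position - half_width
  hi <- position + half_width
  left <- strrep(pad, max(0L, 1L - lo))
  right <- strrep(pad, max(0L, hi - n))
  core <- substr(sequence, max(1L, lo), min(n, hi))
  paste0(left, core, right)
}

#' Encode a window as integer tokens
#'
#' Canonical residues map to 0-19 by alphabetical order
#' (`ACDEFGHIKLMNPQRSTVWY`); `"X"` and every other letter map to 20, the
#' missing-residue token.
#'
#' @param window Window string (any length; dataset windows are 33).
#' @return Integer vector of token codes in `[0, 20]`.
#' @seealso [encode_windows()] for the vectorised matrix form,
#'   [decode_window()] for the inverse.
#' @export
encode_window <- function(window) {
  ch <- strsplit(window, "")[[1]]
  idx <- match(ch, AA_ALPHABET)
  idx[is.na(idx)] <- 21L
  as.integer(idx - 1L)
}

#' Encode many windows into a token matrix
#'
#' @param windows Character vector of equal-length windows, or an integer
#'   token matrix (returned unchanged).
#' @return Integer matrix (n windows x window length) of codes in `[0, 20]`.
#' @export
encode_windows <- function(windows) {
  if (is.matrix(windows)) {
    storage.mode(windows) <- "integer"
    return(windows)
  }
  n <- length(windows)
  L <- nchar(windows[1])
  if (any(nchar(windows) != L)) stop("windows must share one length")
  ch <- matrix(unlist(strsplit(windows, ""), use.names = FALSE), nrow = n, byrow = TRUE)
  idx <- match(ch, AA_ALPHABET)
  idx[is.na(idx)] <- 21L
  matrix(as.integer(idx - 1L), nrow = n)
}

#' Decode integer tokens back to a window string
#'
#' @param tokens Integer vector of codes in `[0, 20]`.
#' @return Window string over the 21-letter alphabet.
#' @export
decode_window <- function(tokens) {
  if (any(tokens < 0L | tokens > 20L)) stop("tokens must lie in [0, 20]")
  paste0(AA_ALPHABET[tokens + 1L], collapse = "")
}

#' Enumerate all candidate lysine sites
#'
#' Builds one labelled record per lysine in every protein: a site is positive
#' iff it appears in `positive_sites`; every other lysine is a negative
#' candidate.  Windows are extracted with [extract_window()].
#'
#' @param proteins Data frame with columns `id`, `sequence`.
#' @param positive_sites Data frame with columns `protein_id`, `position`
#'   (1-based); every listed site must address a `K` residue.
#' @param half_width Window half-width (default 16).
#' @return Data frame with columns `protein_id`, `position`, `label`,
#'   `window`.
#' @export
build_site_dataset <- function(proteins, positive_sites, half_width = 16L) {
  poskey <- character(0)
  if (nrow(positive_sites)) {
    unknown <- setdiff(positive_sites$protein_id, proteins$id)
    if (length(unknown))
      stop("positive sites reference unknown proteins: ",
           paste(unique(unknown), collapse = ", "))
    for (i in seq_len(nrow(positive_sites))) {
      id <- positive_sites$protein_id[i]
      p <- positive_sites$position[i]
      s <- proteins$sequence[match(id, proteins$id)]
      if (p < 1L || p > nchar(s) || substr(s, p, p) != "K")
        stop("positive site is not a lysine: (", id, ", ", p, ")")
    }
    poskey <- paste(positive_sites$protein_id, positive_sites$position)
  }
  out <- vector("list", nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    s <- proteins$sequence[i]
    kpos <- which(strsplit(s, "")[[1]] == "K")
    if (!length(kpos)) next
    wins <- vapply(kpos, function(p) extract_window(s, p, half_width), character(1))
    out[[i]] <- data.frame(
      protein_id = proteins$id[i],
      position = as.integer(kpos),
      label = as.integer(paste(proteins$id[i], kpos) %in% poskey),
      window = wins,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(protein_id = character(0), position = integer(0),
                      label = integer(0), window = character(0))
  rownames(res) <- NULL
  res
}

#' Balance classes by random undersampling
#'
#' Keeps every positive record and randomly subsamples negatives without
#' replacement down to the positive count.  If positives already outnumber
#' negatives, all records are kept with a warning.
#'
#' @param records Site data frame with a `label` column.
#' @param seed Integer seed; the selection is deterministic given it.
#' @return The balanced data frame (positives first, then sampled negatives).
#' @export
balance_undersample <- function(records, seed = 1L) {
  pos <- which(records$label == 1L)
  neg <- which(records$label == 0L)
  if (!length(pos)) stop("no positive records to balance against")
  if (length(pos) > length(neg)) {
    warning("more positives than negatives; keeping all records")
    return(records)
  }
  keep <- with_seed(seed, sample(neg, length(pos)))
  out <- records[c(pos, sort(keep)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratified train/validation split
#'
#' Splits site records into train and validation parts conserving the class
#' ratio (within one record per class), e.g. the 1:9 validation:train split
#' used for model selection.
#'
#' @param records Site data frame with a `label` column.
#' @param validation_fraction Fraction held out for validation, in (0, 1).
#' @param seed Integer seed.
#' @return List with elements `train` and `validation` (data frames).
#' @export
split_stratified <- function(records, validation_fraction = 0.1, seed = 1L) {
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("validation_fraction must be in (0, 1)")
  val_idx <- with_seed(seed, {
    unlist(lapply(unique(records$label), function(cl) {
      ix <- which(records$label == cl)
      sample(ix, round(validation_fraction * length(ix)))
    }))
  })
  val_idx <- sort(val_idx)
  list(
    train = `rownames<-`(records[-val_idx, , drop = FALSE], NULL),
    validation = `rownames<-`(records[val_idx, , drop = FALSE], NULL)
  )
}

#' Build imbalanced validation sets
#'
#' From a balanced validation set, builds `n_sets` imbalanced variants: each
#' keeps all negatives and an independent random fraction
#' `1 - positive_removal` of the positives (rounded up), emulating evaluation
#' under a realistic class skew.
#'
#' @param validation Site data frame with a `label` column.
#' @param n_sets Number of sets to build (default 10).
#' @param positive_removal Fraction of positives removed, in `[0, 1)`
#'   (default 0.9, i.e. 10% of positives retained).
#' @param seed Integer seed.
#' @return List of `n_sets` data frames.
#' @export
make_imbalanced_validation_sets <- function(validation, n_sets = 10L,
                                            positive_removal = 0.9, seed = 1L) {
  if (positive_removal < 0 || positive_removal >= 1)
    stop("positive_removal must be in [0, 1)")
  pos <- which(validation$label == 1L)
  neg <- which(validation$label == 0L)
  keep_n <- ceiling((1 - positive_removal) * length(pos))
  with_seed(seed, {
    lapply(seq_len(n_sets), function(i) {
      keep <- if (keep_n == length(pos)) pos else sample(pos, keep_n)
      out <- validation[sort(c(keep, neg)), , drop = FALSE]
      rownames(out) <- NULL
      out
    })
  })
}

# Stratified fold assignment: per class, a shuffled round-robin over 1..k.
stratified_folds <- function(labels, k, seed = 1L) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      ix <- which(labels == cl)
      if (k > length(ix))
        stop("k = ", k, " exceeds the size of class ", cl)
      fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
  })
  fold
}
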