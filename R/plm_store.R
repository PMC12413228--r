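#' Construct a per-residue embedding table
#'
#' Holds one `L x D` matrix of per-residue protein-language-model embeddings
#' per protein (e.g. D = 1024 for ProtT5).  Embeddings are stored for whole
#' proteins so one table serves every candidate site of a protein.
#'
#' @param entries Named list of numeric matrices, one per protein id; all
#'   matrices must share the same number of columns `D`.
#' @param model Name of the producing model (recorded as provenance).
#' @return An object of class `embedding_table` with fields `entries`,
#'   `width`, `model`.
#' @export
embedding_table <- function(entries, model = "unknown") {
  if (!length(entries)) stop("no entries")
  if (is.null(names(entries)) || any(!nzchar(names(entries))))
    stop("entries must be a named list keyed by protein id")
  widths <- vapply(entries, ncol, integer(1))
  if (length(unique(widths)) != 1L)
    stop("mixed embedding widths: ", paste(unique(widths), collapse = ", "))
  structure(
    list(entries = entries, width = unname(widths[1]), model = model),
    class = "embedding_table"
  )
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("Per-residue embedding table:", length(x$entries), "proteins, width",
      x$width, sprintf("(model: %s)\n", x$model))
  invisible(x)
}

#' Write / read an embedding table
#'
#' The table is written as a keyed-array archive (one named matrix per
#' protein id, RDS container) plus a JSON sidecar `<path>.json` recording the
#' embedding width and producing model.  The round-trip is lossless in ids,
#' shapes and values.
#'
#' @param table An [embedding_table()].
#' @param path Archive path (the sidecar is written next to it).
#' @return `write_embeddings`: `path`, invisibly.  `read_embeddings`: the
#'   reconstructed `embedding_table`.
#' @export
write_embeddings <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  if (!length(table$entries)) stop("no entries")
  saveRDS(table$entries, path)
  jsonlite::write_json(
    list(width = table$width, model = table$model),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  entries <- readRDS(path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list(model = "unknown")
  embedding_table(entries, model = meta$model %||% "unknown")
}

#' Extract the embedding vector of a target site
#'
#' Returns the per-residue embedding row for the residue at `position`
#' (1-based) of the given protein — the vector the MLP branch consumes.
#'
#' @param table An [embedding_table()].
#' @param protein_id Protein id present in the table.
#' @param position 1-based residue index within the protein.
#' @return Numeric vector of length `table$width`.
#' @export
target_embedding <- function(table, protein_id, position) {
  stopifnot(inherits(table, "embedding_table"))
  m <- table$entries[[protein_id]]
  if (is.null(m)) stop("unknown protein id: ", protein_id)
  if (position < 1L || position > nrow(m))
    stop("position ", position, " out of range for ", protein_id,
         " (L = ", nrow(m), ")")
  as.numeric(m[position, ])
}

#' Matrix of target-site embeddings for a site table
#'
#' Stacks [target_embedding()] over every row of a site data frame; errors
#' list every protein missing from the table.
#'
#' @param table An [embedding_table()].
#' @param sites Data frame with columns `protein_id`, `position`.
#' @return Numeric matrix (`nrow(sites)` x `table$width`).
#' @export
site_embedding_matrix <- function(table, sites) {
  missing_ids <- setdiff(unique(sites$protein_id), names(table$entries))
  if (length(missing_ids))
    stop("missing PLM embeddings for: ", paste(missing_ids, collapse = ", "))
  out <- matrix(0, nrow(sites), table$width)
  for (i in seq_len(nrow(sites)))
    out[i, ] <- target_embedding(table, sites$protein_id[i], sites$position[i])
  out
}
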