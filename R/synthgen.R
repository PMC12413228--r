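#' Synthetic-data configuration
#'
#' Parameters of the synthetic benchmark: proteins with i.i.d. uniform
#' residue composition, planted lysine candidate sites, a local compositional
#' motif around positive sites, and class-separable surrogate per-residue
#' embeddings standing in for a protein-language-model.  The defaults define
#' the package's reference fixture: 200 proteins of 80-120 residues with 10
#' planted lysines each, half of them positive (about 1,000 positive and, with
#' background lysines, enough negatives to undersample to a 2,000-site
#' balanced set), motif strength `p = 0.5`, embedding width 64, class shift
#' `delta = 1` and noise `sigma = 1`.
#'
#' @param n_proteins Number of proteins (default 200).
#' @param length_range Min/max protein length (default `c(80, 120)`).
#' @param sites_per_protein Planted lysine sites per protein (default 10;
#'   must be at least 1).
#' @param positive_fraction Fraction of planted sites labelled positive
#'   (default 0.5).
#' @param motif_offsets Window offsets (relative to the site) carrying the
#'   motif (default `c(-3:-1, 1:3)`).
#' @param motif_alphabet Residues the motif draws from (default
#'   `c("E", "D", "G", "A")`).
#' @param motif_p Probability a motif offset carries a motif residue in a
#'   positive window, in `[0, 1]` (default 0.5).
#' @param plm_width Surrogate embedding width D (default 64; set 1024 for
#'   architecture-faithful shapes).
#' @param delta Embedding class shift: positive-site rows are displaced by
#'   `delta` along a fixed unit direction (default 1; must be >= 0).
#' @param sigma Embedding noise standard deviation (default 1; must be > 0).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 200L, length_range = c(80L, 120L),
                         sites_per_protein = 10L, positive_fraction = 0.5,
                         motif_offsets = c(-3:-1, 1:3),
                         motif_alphabet = c("E", "D", "G", "A"),
                         motif_p = 0.5, plm_width = 64L,
                         delta = 1, sigma = 1, seed = 1L) {
  if (sites_per_protein < 1L) stop("at least one lysine site per protein is required")
  if (motif_p < 0 || motif_p > 1) stop("motif_p must be in [0, 1]")
  if (delta < 0) stop("delta must be >= 0")
  if (sigma <= 0) stop("sigma must be > 0")
  structure(
    list(n_proteins = as.integer(n_proteins),
         length_range = as.integer(length_range),
         sites_per_protein = as.integer(sites_per_protein),
         positive_fraction = positive_fraction,
         motif_offsets = as.integer(motif_offsets),
         motif_alphabet = motif_alphabet,
         motif_p = motif_p, plm_width = as.integer(plm_width),
         delta = delta, sigma = sigma, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a synthetic benchmark
#'
#' Builds proteins, labelled lysine sites and surrogate embeddings per the
#' configuration: background residues are i.i.d. uniform over the 20 canonical
#' amino acids; planted site positions (spaced at least 7 apart) are forced to
#' lysine; around each positive site, every motif offset carries a draw from
#' the motif alphabet with probability `motif_p`; per-residue embeddings are
#' `Normal(0, sigma^2 I)`, with positive-site rows shifted by `delta` along a
#' fixed seeded unit vector `u`.
#'
#' @param config A [synth_config()].
#' @param dir Optional output directory; when given, writes
#'   `proteins.fasta`, `sites.tsv`, `embeddings.rds` (+ `.json` sidecar) and
#'   `truth.json` there.
#' @return List with `proteins` (data frame `id`, `sequence`), `positives`
#'   (data frame `protein_id`, `position` of positive sites), `sites` (all
#'   planted sites with labels), `embeddings` (an [embedding_table()]),
#'   `truth` (list with `u`, `delta`, `motif_p`, `motif_offsets`,
#'   `motif_alphabet`), and `paths` when `dir` was given.
#' @export
synth_generate <- function(config = synth_config(), dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  aa20 <- AA_ALPHABET[1:20]
  out <- with_seed(config$seed, {
    u <- stats::rnorm(config$plm_width)
    u <- u / sqrt(sum(u^2))
    proteins <- vector("list", config$n_proteins)
    sites <- vector("list", config$n_proteins)
    entries <- vector("list", config$n_proteins)
    for (i in seq_len(config$n_proteins)) {
      L <- sample(config$length_range[1]:config$length_range[2], 1L)
      s <- sample(aa20, L, replace = TRUE)
      # candidate slots spaced >= 7 so planted motifs never overlap
      slots <- seq(4L, L - 3L, by = 7L)
      if (length(slots) < config$sites_per_protein)
        stop("protein too short for ", config$sites_per_protein, " spaced sites")
      pos <- sort(sample(slots, config$sites_per_protein))
      s[pos] <- "K"
      lab <- integer(length(pos))
      lab[sample(seq_along(pos),
                 round(config$positive_fraction * length(pos)))] <- 1L
      for (j in which(lab == 1L)) {
        for (off in config$motif_offsets) {
          if (stats::runif(1) < config$motif_p)
            s[pos[j] + off] <- sample(config$motif_alphabet, 1L)
        }
      }
      id <- sprintf("synthP%04d", i)
      proteins[[i]] <- data.frame(id = id, sequence = paste0(s, collapse = ""),
                                  stringsAsFactors = FALSE)
      sites[[i]] <- data.frame(protein_id = id, position = pos, label = lab,
                               stringsAsFactors = FALSE)
      emb <- matrix(stats::rnorm(L * config$plm_width, sd = config$sigma),
                    L, config$plm_width)
      ppos <- pos[lab == 1L]
      if (length(ppos))
        emb[ppos, ] <- emb[ppos, , drop = FALSE] +
          matrix(config$delta * u, length(ppos), config$plm_width, byrow = TRUE)
      entries[[i]] <- emb
    }
    proteins <- do.call(rbind, proteins)
    sites <- do.call(rbind, sites)
    names(entries) <- proteins$id
    list(proteins = proteins, sites = sites,
         embeddings = embedding_table(entries, model = "synthetic"),
         truth = list(u = u, delta = config$delta, sigma = config$sigma,
                      motif_p = config$motif_p,
                      motif_offsets = config$motif_offsets,
                      motif_alphabet = config$motif_alphabet))
  })
  out$positives <- out$sites[out$sites$label == 1L, c("protein_id", "position")]
  rownames(out$positives) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fasta = file.path(dir, "proteins.fasta"),
      sites = file.path(dir, "sites.tsv"),
      embeddings = file.path(dir, "embeddings.rds"),
      truth = file.path(dir, "truth.json")
    )
    write_fasta(out$proteins, paths$fasta)
    write_sites(out$sites, paths$sites)
    write_embeddings(out$embeddings, paths$embeddings)
    jsonlite::write_json(out$truth, paths$truth, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}
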