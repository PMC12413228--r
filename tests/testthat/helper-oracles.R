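# Independent oracles and shared fixtures.  Oracles are deliberately written
# as naive enumerations, separate from the package's code paths.

# Brute-force metric panel straight from definitions: confusion by explicit
# loop, AUROC as the mean over all positive/negative score pairs (ties count
# one half), AUPRC as a sweep over unique descending thresholds.
oracle_metrics <- function(labels, scores, threshold = 0.5) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(labels)) {
    pred <- scores[i] >= threshold
    if (labels[i] == 1 && pred) tp <- tp + 1L
    if (labels[i] == 1 && !pred) fn <- fn + 1L
    if (labels[i] == 0 && pred) fp <- fp + 1L
    if (labels[i] == 0 && !pred) tn <- tn + 1L
  }
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  dens <- as.numeric(c(tp + fp, tp + fn, tn + fp, tn + fn))
  mcc <- if (any(dens == 0)) 0 else (tp * tn - fp * fn) / sqrt(prod(dens))
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  auc <- NA_real_
  ap <- NA_real_
  if (length(sp) && length(sn)) {
    tot <- 0
    for (a in sp) for (b in sn)
      tot <- tot + (a > b) + 0.5 * (a == b)
    auc <- tot / (length(sp) * length(sn))
    thr <- sort(unique(scores), decreasing = TRUE)
    prev_r <- 0
    ap <- 0
    for (t in thr) {
      tpt <- sum(sp >= t)
      fpt <- sum(sn >= t)
      r <- tpt / length(sp)
      p <- tpt / (tpt + fpt)
      ap <- ap + (r - prev_r) * p
      prev_r <- r
    }
  }
  list(accuracy = (tp + tn) / length(labels), precision = prec, recall = rec,
       specificity = spec, f1 = f1, mcc = mcc, auroc = auc, auprc = ap)
}

# Closed-form parameter counts, layer by layer, independent of the builders.
oracle_param_count <- function(branch, L = 33, vocab = 21, d = 21,
                               f1 = 32, f2 = 64, kconv = 3,
                               inc_kernels = c(1, 3, 5, 7, 9, 11), incF = 32,
                               plm = 1024, bd = 32, hd = 32, pool = 2) {
  dense <- function(i, o) i * o + o
  conv <- function(k, cin, f) k * cin * f + f
  emb <- vocab * d
  if (branch == "conv") {
    word <- emb + conv(kconv, d, f1) + conv(kconv, f1, f2) +
      dense(((L %/% pool) %/% pool) * f2, bd)
  } else if (branch == "resnet") {
    c1 <- f1 + d
    c2 <- f2 + c1
    word <- emb + conv(kconv, d, f1) + conv(kconv, f1, f1) +
      conv(kconv, c1, f2) + conv(kconv, f2, f2) +
      dense(((L %/% pool) %/% pool) * c2, bd)
  } else if (branch == "inception") {
    word <- emb + sum(vapply(inc_kernels, conv, numeric(1), cin = d, f = incF)) +
      conv(1, d, incF) +
      dense((L %/% pool) * (length(inc_kernels) + 1) * incF, bd)
  } else stop("bad branch")
  word + dense(plm, bd) + dense(2 * bd, hd) + dense(hd, 1)
}

# Exhaustive greedy mRMR oracle sharing only the estimator definition:
# entropies from tabulated equal-width bins, H(a) + H(b) - H(a,b).
oracle_mrmr <- function(pooled, y, k, bins = 10) {
  disc <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) return(rep(1L, length(x)))
    pmin(floor((x - r[1]) / (r[2] - r[1]) * bins) + 1, bins)
  }
  H <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log(p))
  }
  mi <- function(a, b) H(a) + H(b) - H(paste(a, b))
  dm <- apply(pooled, 2, disc)
  p <- ncol(pooled)
  rel <- sapply(seq_len(p), function(j) mi(dm[, j], y))
  sel <- integer(0)
  for (s in seq_len(k)) {
    cand <- setdiff(seq_len(p), sel)
    crit <- sapply(cand, function(j) {
      if (!length(sel)) rel[j]
      else rel[j] - mean(sapply(sel, function(q) mi(dm[, j], dm[, q])))
    })
    sel <- c(sel, cand[which.max(crit)])
  }
  sel
}

random_window <- function(n = 1, L = 33) {
  vapply(seq_len(n), function(i)
    paste0(sample(AA_ALPHABET[1:20], L, TRUE), collapse = ""), character(1))
}

# A small training-ready dataset derived from the synthetic generator.
make_small_data <- function(seed = 7, n_proteins = 60, motif_p = 0.5,
                            delta = 1, plm_width = 32) {
  syn <- synth_generate(synth_config(
    n_proteins = n_proteins, sites_per_protein = 10,
    motif_p = motif_p, delta = delta, plm_width = plm_width, seed = seed))
  ds <- balance_undersample(build_site_dataset(syn$proteins, syn$positives),
                            seed = seed)
  list(syn = syn, ds = ds, plm = site_embedding_matrix(syn$embeddings, ds))
}

# A reduced architecture that trains fast in unit tests.
tiny_config <- function(branch = "conv", plm_width = 32) {
  succnet_config(branch, embed_dim = 8, conv_filters = c(8L, 16L),
                 inception_kernels = c(1L, 3L, 5L), inception_filters = 4L,
                 plm_width = plm_width, branch_dense = 16L, head_dense = 16L)
}

# Memoised small fitted model shared by interpretability tests.
.fixture_env <- new.env(parent = emptyenv())
get_demo_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    d <- make_small_data(seed = 42, n_proteins = 60, motif_p = 0.8, delta = 1)
    fit <- succnet(d$ds$window, d$plm, d$ds$label,
                   config = tiny_config("resnet"), epochs = 50,
                   batch_size = 32, learning_rate = 1e-3, seed = 42)
    .fixture_env$fit <- fit
    .fixture_env$data <- d
  }
  list(fit = .fixture_env$fit, data = .fixture_env$data)
}

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}
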