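# Shapley attribution of window positions.  The game's players are the
# attributed window positions; a coalition keeps those positions at the
# explained instance's residues and fills the rest from background windows
# (the value of a coalition is the mean model output over the background
# set).  Positions outside the attributed subset stay at the instance's
# residues throughout.

# Split windows into a character matrix (n x L).
.win_chars <- function(windows) {
  L <- nchar(windows[1])
  matrix(unlist(strsplit(windows, ""), use.names = FALSE),
         nrow = length(windows), ncol = L, byrow = TRUE)
}

# Evaluate v(S) for each coalition row of `zmat` (ncoal x m 0/1): build all
# composite windows in one batch and average the predictions per coalition.
.coalition_values <- function(predict_fn, inst, bg, positions, zmat) {
  ncoal <- nrow(zmat)
  nb <- nrow(bg)
  # composite block: for each coalition, nb copies of the background with
  # attributed "on" positions overwritten by the instance residues
  comp <- bg[rep(seq_len(nb), ncoal), , drop = FALSE]
  # positions outside the attributed set always take the instance value
  fixed <- setdiff(seq_along(inst), positions)
  if (length(fixed))
    comp[, fixed] <- matrix(inst[fixed], nrow(comp), length(fixed), byrow = TRUE)
  on_rows <- rep(seq_len(ncoal), each = nb)
  for (j in seq_along(positions)) {
    sel <- zmat[on_rows, j] == 1L
    if (any(sel)) comp[sel, positions[j]] <- inst[positions[j]]
  }
  wins <- apply(comp, 1L, paste0, collapse = "")
  preds <- predict_fn(wins)
  as.numeric(rowsum(preds, on_rows) / nb)
}

#' Exact Shapley attribution by subset enumeration
#'
#' Computes classical Shapley values for up to 14 window positions by
#' enumerating all coalitions.  The efficiency axiom holds exactly:
#' `sum(values) + base_value` equals the mean model output with every
#' attributed position taken from the instance.
#'
#' @param predict_fn Function taking a character vector of window strings and
#'   returning one numeric score per window.
#' @param instance_window The window string to explain.
#' @param background_windows Character vector of background windows (same
#'   length as the instance).
#' @param positions 1-based window positions to attribute (default: all);
#'   at most 14 (use [kernel_shapley()] beyond that).
#' @return Object of class `attribution_profile`: `values` (length
#'   `nchar(instance_window)`, zero at non-attributed positions),
#'   `base_value`, `positions`, `instance`, `method`.
#' @export
exact_shapley <- function(predict_fn, instance_window, background_windows,
                          positions = NULL) {
  L <- nchar(instance_window)
  if (any(nchar(background_windows) != L))
    stop("background windows must match the instance length")
  positions <- as.integer(positions %||% seq_len(L))
  m <- length(positions)
  if (m > 14L)
    stop("exact enumeration limited to 14 positions (2^m subsets); ",
         "use kernel_shapley()")
  inst <- strsplit(instance_window, "")[[1]]
  bg <- .win_chars(background_windows)
  # all 2^m coalitions as a 0/1 matrix
  zmat <- as.matrix(expand.grid(rep(list(0:1), m)))
  storage.mode(zmat) <- "integer"
  v <- .coalition_values(predict_fn, inst, bg, positions, zmat)
  sizes <- rowSums(zmat)
  # subset index lookup: binary code of each coalition
  code <- as.integer(zmat %*% (2L^(seq_len(m) - 1L)))
  vv <- numeric(2L^m)
  vv[code + 1L] <- v
  wts <- exp(lfactorial(0:(m - 1L)) + lfactorial(m - 1L - (0:(m - 1L))) -
               lfactorial(m))
  phi <- numeric(m)
  for (i in seq_len(m)) {
    off <- zmat[, i] == 0L
    s_code <- code[off]
    s_size <- sizes[off]
    phi[i] <- sum(wts[s_size + 1L] *
                    (vv[s_code + 2L^(i - 1L) + 1L] - vv[s_code + 1L]))
  }
  values <- numeric(L)
  values[positions] <- phi
  structure(
    list(values = values, base_value = vv[1L], positions = positions,
         instance = instance_window, method = "exact"),
    class = "attribution_profile"
  )
}

#' Kernel Shapley attribution
#'
#' KernelSHAP: coalitions are weighted by the Shapley kernel
#' `(M - 1) / (choose(M, s) * s * (M - s))` and the attributions solve the
#' weighted least-squares problem under the efficiency constraint
#' `sum(values) = f(x) - base_value`.  When `n_samples` covers all
#' `2^M - 2` proper coalitions they are enumerated and the result is exact;
#' otherwise coalitions are sampled (sizes drawn from the kernel mass,
#' members uniformly), deterministically given `seed`.
#'
#' @inheritParams exact_shapley
#' @param n_samples Coalition evaluation budget (must be at least `M + 2`).
#' @param seed Integer seed for coalition sampling.
#' @return An `attribution_profile` (see [exact_shapley()]).
#' @export
kernel_shapley <- function(predict_fn, instance_window, background_windows,
                           n_samples = 4096L, seed = 1L, positions = NULL) {
  L <- nchar(instance_window)
  if (any(nchar(background_windows) != L))
    stop("background windows must match the instance length")
  positions <- as.integer(positions %||% seq_len(L))
  M <- length(positions)
  if (n_samples < M + 2L)
    stop("n_samples must be at least M + 2 = ", M + 2L)
  inst <- strsplit(instance_window, "")[[1]]
  bg <- .win_chars(background_windows)

  base_value <- .coalition_values(predict_fn, inst, bg, positions,
                                  matrix(0L, 1L, M))
  fx <- .coalition_values(predict_fn, inst, bg, positions,
                          matrix(1L, 1L, M))

  full_enum <- M <= 25L && (2^M - 2) <= n_samples
  if (full_enum) {
    zmat <- as.matrix(expand.grid(rep(list(0:1), M)))
    storage.mode(zmat) <- "integer"
    zmat <- zmat[rowSums(zmat) %in% seq_len(M - 1L), , drop = FALSE]
    s <- rowSums(zmat)
    w <- (M - 1) / (choose(M, s) * s * (M - s))
  } else {
    zmat <- with_seed(seed, {
      sz_mass <- (M - 1) / ((1:(M - 1)) * (M - (1:(M - 1))))
      sz <- sample.int(M - 1L, n_samples, replace = TRUE,
                       prob = sz_mass / sum(sz_mass))
      t(vapply(sz, function(s) {
        z <- integer(M)
        z[sample.int(M, s)] <- 1L
        z
      }, integer(M)))
    })
    # sampling already follows the kernel mass over sizes, so rows enter the
    # regression with uniform weight
    w <- rep(1, nrow(zmat))
  }
  v <- .coalition_values(predict_fn, inst, bg, positions, zmat)

  # efficiency via elimination: phi_M = (fx - base) - sum(phi_1..phi_{M-1})
  delta <- fx - base_value
  if (M == 1L) {
    phi <- delta
  } else {
    yreg <- v - base_value - zmat[, M] * delta
    X <- zmat[, -M, drop = FALSE] - zmat[, M]
    sw <- sqrt(w)
    fit <- stats::lm.fit(X * sw, yreg * sw)
    phi <- c(fit$coefficients, delta - sum(fit$coefficients))
    phi[is.na(phi)] <- 0
  }
  values <- numeric(L)
  values[positions] <- phi
  structure(
    list(values = values, base_value = base_value, positions = positions,
         instance = instance_window, method = "kernel"),
    class = "attribution_profile"
  )
}

#' @export
print.attribution_profile <- function(x, ...) {
  cat("Shapley attribution (", x$method, "), base value ",
      format(x$base_value, digits = 4), ", ", length(x$positions),
      " attributed positions\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' Read C-alpha coordinates from a PDB file
#'
#' Extracts one C-alpha coordinate per residue from the ATOM records of a
#' chain; for alternate locations the first is kept.
#'
#' @param pdb_path Path to a PDB file.
#' @param chain Chain identifier (default `"A"`).
#' @return Data frame with columns `resno`, `x`, `y`, `z`, one row per
#'   residue with a C-alpha atom.
#' @export
read_structure_ca <- function(pdb_path, chain = "A") {
  if (!file.exists(pdb_path)) stop("file not found: ", pdb_path)
  pdb <- bio3d::read.pdb(pdb_path)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (!nrow(at)) stop("no C-alpha ATOM records in ", pdb_path)
  if (!chain %in% at$chain)
    stop("chain '", chain, "' not present in ", pdb_path)
  at <- at[at$chain == chain, , drop = FALSE]
  at <- at[!duplicated(at$resno), , drop = FALSE] # first altLoc wins
  data.frame(resno = at$resno, x = at$x, y = at$y, z = at$z)
}

#' C-alpha distances across a window
#'
#' Euclidean C-alpha distance from each window position to the target
#' residue at the window centre.  Positions outside the protein (window
#' padding) or residues without a C-alpha are `NA`.
#'
#' @param coords Data frame from [read_structure_ca()].
#' @param protein_length Length of the protein sequence.
#' @param position 1-based target-residue index.
#' @param half_width Window half-width (default 16).
#' @return Numeric vector of length `2 * half_width + 1` (distance 0 at the
#'   centre offset).
#' @export
window_distances <- function(coords, protein_length, position,
                             half_width = 16L) {
  Lw <- 2L * half_width + 1L
  out <- rep(NA_real_, Lw)
  tgt <- coords[match(position, coords$resno), c("x", "y", "z")]
  if (anyNA(tgt)) stop("target residue ", position, " has no C-alpha")
  for (k in seq_len(Lw)) {
    res <- position + (k - 1L - half_width)
    if (res < 1L || res > protein_length) next
    r <- coords[match(res, coords$resno), c("x", "y", "z")]
    if (anyNA(r)) next
    out[k] <- sqrt(sum((as.numeric(r) - as.numeric(tgt))^2))
  }
  out
}

#' Aggregate attributions by window position
#'
#' Mean absolute Shapley value at each window offset across profiles — the
#' sequence-position view of residue importance.
#'
#' @param profiles List of `attribution_profile` objects (equal window
#'   lengths).
#' @return Numeric vector of mean |value| per window position.
#' @export
aggregate_by_position <- function(profiles) {
  vals <- do.call(rbind, lapply(profiles, function(p) abs(p$values)))
  colMeans(vals)
}

#' Aggregate attributions by structural distance
#'
#' Bins window positions by their C-alpha distance to the target residue
#' (bins `[0, bw)`, `[bw, 2 bw)`, ... with `bw = bin_width` angstroms) and
#' reports the mean absolute Shapley value per bin.  The target position
#' itself (distance 0 by construction) is excluded; positions with missing
#' distances are skipped; empty bins are absent from the output.
#'
#' @param profiles List of `attribution_profile` objects.
#' @param distance_profiles List of numeric distance vectors (from
#'   [window_distances()]), parallel to `profiles`.
#' @param bin_width Bin width in angstroms (default 4).
#' @return Data frame with columns `bin_lo`, `bin_hi`, `mean_abs`, `n`,
#'   sorted by distance.
#' @export
aggregate_by_distance <- function(profiles, distance_profiles, bin_width = 4) {
  stopifnot(length(profiles) == length(distance_profiles))
  vals <- numeric(0)
  bins <- integer(0)
  for (i in seq_along(profiles)) {
    v <- abs(profiles[[i]]$values)
    d <- distance_profiles[[i]]
    centre <- (length(v) + 1L) %/% 2L
    keep <- which(!is.na(d) & seq_along(d) != centre)
    vals <- c(vals, v[keep])
    bins <- c(bins, as.integer(floor(d[keep] / bin_width)))
  }
  if (!length(vals))
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      mean_abs = numeric(0), n = integer(0)))
  agg <- rowsum(cbind(vals, 1), bins)
  b <- as.integer(rownames(agg))
  o <- order(b)
  data.frame(bin_lo = b[o] * bin_width, bin_hi = (b[o] + 1) * bin_width,
             mean_abs = (agg[, 1] / agg[, 2])[o], n = as.integer(agg[, 2])[o])
}

#' Window predictor for a fitted model
#'
#' Builds the scalar predictor used for Shapley attribution of the word
#' branch: windows vary, while the language-model vector is held fixed at
#' the explained instance's value.
#'
#' @param object A fitted [succnet()] model.
#' @param plm_vector The instance's language-model embedding (length
#'   `plm_width`).
#' @return Function mapping a character vector of windows to probabilities.
#' @export
make_window_predictor <- function(object, plm_vector) {
  stopifnot(inherits(object, "succnet"))
  plm_vector <- as.numeric(plm_vector)
  function(windows) {
    tokens <- encode_windows(windows)
    plm <- matrix(plm_vector, nrow(tokens), length(plm_vector), byrow = TRUE)
    predict(object, tokens, plm)
  }
}
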