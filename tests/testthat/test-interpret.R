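# A cheap window predictor used by the attribution tests: additive residue
# effects plus one interaction, so exact Shapley values have a closed form
# for the additive part.
make_toy_predictor <- function(coefs, interaction = 0) {
  force(coefs); force(interaction)
  function(windows) {
    m <- matrix(unlist(strsplit(windows, ""), use.names = FALSE),
                nrow = length(windows), byrow = TRUE)
    out <- rowSums((m == "E") * matrix(coefs, nrow(m), ncol(m), byrow = TRUE))
    if (interaction != 0)
      out <- out + interaction * (m[, 5] == "A") * (m[, 9] == "G")
    out
  }
}

test_that("exact Shapley matches the closed form for additive games", {
  set.seed(1)
  coefs <- rnorm(33)
  pf <- make_toy_predictor(coefs)
  inst <- random_window()
  bg <- random_window(25)
  pos <- c(2, 5, 9, 14, 17, 21, 30)
  prof <- exact_shapley(pf, inst, bg, positions = pos)
  bgm <- matrix(unlist(strsplit(bg, "")), nrow = 25, byrow = TRUE)
  im <- strsplit(inst, "")[[1]]
  for (j in pos) {
    want <- coefs[j] * ((im[j] == "E") - mean(bgm[, j] == "E"))
    expect_equal(prof$values[j], want, tolerance = 1e-12)
  }
  # non-attributed positions report zero
  expect_true(all(prof$values[-pos] == 0))
})

test_that("exact Shapley obeys efficiency, symmetry, and the dummy axiom", {
  set.seed(2)
  pf <- make_toy_predictor(rnorm(33), interaction = 0.8)
  inst <- random_window()
  bg <- random_window(15)
  pos <- c(3, 5, 9, 12, 20)
  prof <- exact_shapley(pf, inst, bg, positions = pos)
  expect_equal(sum(prof$values) + prof$base_value, pf(inst),
               tolerance = 1e-12)
  # dummy: a position with zero coefficient outside the interaction pair
  pf0 <- make_toy_predictor(c(rnorm(10), 0, rnorm(22)))
  prof0 <- exact_shapley(pf0, inst, bg, positions = c(4, 11, 18))
  expect_lt(abs(prof0$values[11]), 1e-12)
  # symmetry: identical coefficients, instance and background columns
  cf <- rep(0, 33); cf[c(7, 8)] <- 1.3
  pfs <- make_toy_predictor(cf)
  inst_s <- paste0(c(rep("A", 6), "E", "E", rep("A", 25)), collapse = "")
  bg_s <- vapply(1:10, function(i) {
    ch <- sample(c("C", "D"), 1)
    paste0(c(rep("A", 6), ch, ch, rep("A", 25)), collapse = "")
  }, character(1))
  ps <- exact_shapley(pfs, inst_s, bg_s, positions = c(7, 8, 15))
  expect_equal(ps$values[7], ps$values[8], tolerance = 1e-12)
})

test_that("a position constant across instance and background attributes zero", {
  set.seed(3)
  pf <- make_toy_predictor(rnorm(33), interaction = 0.5)
  # centre residue is lysine in the instance and every background window
  mk <- function(w) paste0(substr(w, 1, 16), "K", substr(w, 18, 33))
  inst <- mk(random_window())
  bg <- vapply(random_window(20), mk, character(1), USE.NAMES = FALSE)
  prof <- exact_shapley(pf, inst, bg, positions = 13:20)
  expect_identical(prof$values[17], 0)
  kprof <- kernel_shapley(pf, inst, bg, n_samples = 2048, seed = 3,
                          positions = 13:20)
  expect_lt(abs(kprof$values[17]), 1e-9)
})

test_that("kernel Shapley agrees with exact enumeration on 8-position games", {
  set.seed(4)
  for (i in 1:5) {
    pf <- make_toy_predictor(rnorm(33), interaction = runif(1, -1, 1))
    inst <- random_window()
    bg <- random_window(12)
    pos <- sort(sample(33, 8))
    ex <- exact_shapley(pf, inst, bg, positions = pos)
    ke <- kernel_shapley(pf, inst, bg, n_samples = 4096, seed = i,
                         positions = pos)
    expect_lt(max(abs(ex$values - ke$values)), 0.01)
    expect_lt(abs(sum(ke$values) + ke$base_value - pf(inst)), 1e-6)
  }
})

test_that("sampled kernel Shapley is deterministic and efficient at M = 33", {
  set.seed(5)
  pf <- make_toy_predictor(rnorm(33), interaction = 0.4)
  inst <- random_window()
  bg <- random_window(8)
  k1 <- kernel_shapley(pf, inst, bg, n_samples = 500, seed = 11)
  k2 <- kernel_shapley(pf, inst, bg, n_samples = 500, seed = 11)
  expect_identical(k1$values, k2$values)
  expect_lt(abs(sum(k1$values) + k1$base_value - pf(inst)), 1e-6)
  expect_error(kernel_shapley(pf, inst, bg, n_samples = 10), "at least")
  expect_error(exact_shapley(pf, inst, bg), "14")
})

test_that("attribution localises the planted motif around the target site", {
  fx <- get_demo_fit()
  d <- fx$data
  pos_ix <- which(d$ds$label == 1)[1:8]
  motif_pos <- 17 + c(-3:-1, 1:3)
  probe <- c(4, motif_pos, 28) # two remote control positions
  set.seed(6)
  bg <- d$ds$window[sample(nrow(d$ds), 16)]
  profs <- lapply(pos_ix, function(i) {
    pf <- make_window_predictor(fx$fit, d$plm[i, ])
    exact_shapley(pf, d$ds$window[i], bg, positions = probe)
  })
  agg <- aggregate_by_position(profs)
  expect_length(agg, 33)
  expect_gt(mean(agg[motif_pos]), mean(agg[c(4, 28)]))
})

test_that("aggregate_by_position averages absolute values", {
  p1 <- structure(list(values = c(rep(0, 16), 1, rep(0, 16)), base_value = 0),
                  class = "attribution_profile")
  p2 <- structure(list(values = c(-2, rep(0, 32)), base_value = 0),
                  class = "attribution_profile")
  expect_equal(aggregate_by_position(list(p1)), abs(p1$values))
  agg <- aggregate_by_position(list(p1, p2))
  expect_equal(agg[1], 1)
  expect_equal(agg[17], 0.5)
  expect_equal(aggregate_by_position(list(p2, p2))[2:33], rep(0, 32))
})

test_that("C-alpha parsing handles minimal files, altLocs and HETATM-only input", {
  pdb_lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  LYS A   3       7.600   0.000   0.000  1.00  0.00           C",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb_lines, f)
  ca <- read_structure_ca(f)
  expect_equal(nrow(ca), 3)
  expect_equal(ca$resno, 1:3)
  expect_equal(ca$x, c(0, 3.8, 7.6))
  expect_error(read_structure_ca(f, chain = "B"), "chain 'B'")

  alt <- c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.50  0.00           C",
    "END")
  fa <- tempfile(fileext = ".pdb")
  writeLines(alt, fa)
  ca2 <- read_structure_ca(fa)
  expect_equal(nrow(ca2), 1)
  expect_equal(ca2$x, 1) # first altLoc kept

  het <- c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END")
  fh <- tempfile(fileext = ".pdb")
  writeLines(het, fh)
  expect_error(read_structure_ca(fh), "C-alpha")
})

test_that("window distances follow collinear geometry with padding as missing", {
  coords <- data.frame(resno = 1:40, x = 1:40, y = 0, z = 0)
  d <- window_distances(coords, 40, 20)
  expect_equal(d[17], 0)
  for (k in 1:16) {
    expect_equal(d[17 + k], k)
    expect_equal(d[17 - k], k)
  }
  # near the N-terminus the out-of-range offsets are missing
  d2 <- window_distances(coords, 40, 3)
  expect_true(all(is.na(d2[1:14])))
  expect_equal(d2[15], 2)
  # residues without a C-alpha are missing
  gap <- coords[-25, ]
  d3 <- window_distances(gap, 40, 20)
  expect_true(is.na(d3[22]))
})

test_that("distance aggregation bins correctly and omits empty bins", {
  prof <- structure(list(values = rep(1, 33), base_value = 0),
                    class = "attribution_profile")
  near <- rep(1.0, 33) # everything lands in [0, 4)
  agg1 <- aggregate_by_distance(list(prof), list(near))
  expect_equal(nrow(agg1), 1)
  expect_equal(agg1$mean_abs, 1)
  expect_equal(agg1$n, 32L) # target offset excluded

  d <- rep(NA_real_, 33)
  d[17] <- 0
  d[16] <- 1; d[18] <- 2   # bin [0,4)
  d[1] <- 10; d[33] <- 11  # bin [8,12); bin [4,8) left empty
  v <- rep(0, 33); v[c(16, 18)] <- 2; v[c(1, 33)] <- 0.5
  p <- structure(list(values = v, base_value = 0),
                 class = "attribution_profile")
  agg <- aggregate_by_distance(list(p), list(d))
  expect_equal(agg$bin_lo, c(0, 8))
  expect_equal(agg$mean_abs, c(2, 0.5))
  # planted decay: nearer bins carry larger attributions
  expect_true(all(diff(agg$mean_abs) <= 0))
})
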