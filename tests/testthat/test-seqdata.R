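test_that("read_fasta parses records, uppercases, preserves order", {
  f <- write_tmp_fasta(c(">p1", "MKAV"))
  expect_equal(read_fasta(f), data.frame(id = "p1", sequence = "MKAV"))

  f2 <- write_tmp_fasta(c(">a desc", "mkav", ">b", "KK", "PL"))
  r <- read_fasta(f2)
  expect_equal(r$id, c("a", "b"))
  expect_equal(r$sequence, c("MKAV", "KKPL"))
})

test_that("read_fasta rejects empty files and duplicate ids", {
  expect_error(read_fasta(write_tmp_fasta(character(0))), "no records")
  expect_error(read_fasta(write_tmp_fasta(c(">x", "MK", ">x", "AK"))), "x")
})

test_that("extract_window pads, centres, and range-checks", {
  w <- extract_window("AKCDE", 2)
  expect_equal(w, paste0(strrep("X", 15), "AKCDE", strrep("X", 13)))
  expect_equal(nchar(w), 33)
  expect_equal(substr(w, 17, 17), "K")

  s40 <- paste0(rep("ACDE", 10), collapse = "")
  w2 <- extract_window(s40, 20)
  expect_equal(w2, substr(s40, 4, 36))
  expect_false(grepl("X", w2))

  expect_error(extract_window("AKCDE", 9), "out of range")
  expect_error(extract_window("AKCDE", 0), "out of range")
})

test_that("window restricted to non-pad characters is a contiguous substring", {
  set.seed(1)
  for (i in 1:25) {
    s <- paste0(sample(AA_ALPHABET[1:20], sample(5:60, 1), TRUE), collapse = "")
    p <- sample(nchar(s), 1)
    w <- extract_window(s, p)
    core <- gsub("X", "", w)
    expect_true(grepl(core, s, fixed = TRUE))
    expect_equal(substr(w, 17, 17), substr(s, p, p))
  }
})

test_that("encode_window maps the 21-letter alphabet and non-canonical letters", {
  expect_equal(encode_window(strrep("X", 33)), rep(20L, 33))
  expect_equal(encode_window(paste0("A", strrep("X", 32))),
               c(0L, rep(20L, 32)))
  tk <- encode_window(extract_window("AKCDE", 2))
  expect_equal(tk[16:20], c(0L, 8L, 1L, 2L, 3L))
  # B, J, O, U, Z map to the missing token
  expect_equal(encode_window("BJOUZ"), rep(20L, 5))
})

test_that("encode/decode round-trips over the 21-letter alphabet", {
  set.seed(2)
  for (i in 1:20) {
    w <- paste0(sample(AA_ALPHABET, 33, TRUE), collapse = "")
    expect_equal(decode_window(encode_window(w)), w)
  }
  m <- encode_windows(c(strrep("A", 33), strrep("X", 33)))
  expect_equal(dim(m), c(2L, 33L))
  expect_true(all(m >= 0 & m <= 20))
})

test_that("build_site_dataset enumerates every lysine with correct labels", {
  prot <- data.frame(id = "p", sequence = "MKKA")
  ds <- build_site_dataset(prot, data.frame(protein_id = "p", position = 2))
  expect_equal(nrow(ds), 2)
  expect_equal(ds$position, c(2L, 3L))
  expect_equal(ds$label, c(1L, 0L))
  expect_equal(nchar(ds$window), c(33L, 33L))

  nok <- data.frame(id = "q", sequence = "MAAV")
  expect_equal(nrow(build_site_dataset(nok, data.frame(protein_id = character(0),
                                                       position = integer(0)))), 0)
  expect_error(
    build_site_dataset(prot, data.frame(protein_id = "p", position = 1)),
    "\\(p, 1\\)")
})

test_that("site record count equals total lysine count across proteins", {
  set.seed(3)
  prots <- data.frame(
    id = paste0("p", 1:8),
    sequence = vapply(1:8, function(i)
      paste0(sample(AA_ALPHABET[1:20], 50, TRUE), collapse = ""), character(1)))
  ds <- build_site_dataset(prots, data.frame(protein_id = character(0),
                                             position = integer(0)))
  nk <- sum(vapply(prots$sequence,
                   function(s) sum(strsplit(s, "")[[1]] == "K"), numeric(1)))
  expect_equal(nrow(ds), nk)
})

test_that("balance_undersample equalises classes deterministically", {
  rec <- data.frame(protein_id = "p", position = 1:13,
                    label = c(rep(1L, 3), rep(0L, 10)), window = strrep("X", 33))
  b1 <- balance_undersample(rec, seed = 9)
  expect_equal(sum(b1$label == 1), 3)
  expect_equal(sum(b1$label == 0), 3)
  expect_identical(b1, balance_undersample(rec, seed = 9))

  even <- rec[c(1:3, 4:6), ]
  expect_equal(nrow(balance_undersample(even, 1)), 6)

  flipped <- rec
  flipped$label <- 1L - flipped$label
  expect_warning(out <- balance_undersample(flipped, 1), "more positives")
  expect_equal(nrow(out), 13)
})

test_that("split_stratified conserves class ratio within one record per class", {
  rec <- data.frame(label = c(rep(1L, 100), rep(0L, 100)))
  sp <- split_stratified(rec, 0.1, seed = 4)
  expect_equal(sum(sp$validation$label == 1), 10)
  expect_equal(sum(sp$validation$label == 0), 10)
  expect_equal(nrow(sp$train), 180)
  expect_error(split_stratified(rec, 0), "validation_fraction")
  expect_error(split_stratified(rec, 1), "validation_fraction")

  skew <- data.frame(label = c(rep(1L, 90), rep(0L, 10)))
  ss <- split_stratified(skew, 0.2, seed = 4)
  expect_equal(sum(ss$validation$label == 1), 18)
  expect_equal(sum(ss$validation$label == 0), 2)
  # disjoint and exhaustive
  expect_equal(nrow(ss$train) + nrow(ss$validation), 100)
})

test_that("imbalanced validation sets keep all negatives and 10% positives", {
  val <- data.frame(id = seq_len(1000), label = c(rep(1L, 100), rep(0L, 900)))
  sets <- make_imbalanced_validation_sets(val, n_sets = 10,
                                          positive_removal = 0.9, seed = 5)
  expect_length(sets, 10)
  for (s in sets) {
    expect_equal(sum(s$label == 1), 10)
    expect_equal(sum(s$label == 0), 900)
  }
  # independent draws across sets
  expect_false(all(vapply(sets[-1], identical, logical(1), sets[[1]])))

  keep_all <- make_imbalanced_validation_sets(val, n_sets = 2,
                                              positive_removal = 0, seed = 5)
  expect_equal(sum(keep_all[[1]]$label == 1), 100)
  expect_error(make_imbalanced_validation_sets(val, positive_removal = 1),
               "positive_removal")
})

test_that("site tables round-trip through TSV", {
  sites <- data.frame(protein_id = c("a", "b"), position = c(3L, 7L),
                      label = c(1L, 0L))
  f <- tempfile(fileext = ".tsv")
  write_sites(sites, f)
  expect_equal(read_sites(f), sites)
  expect_error(read_sites(tempfile()), "not found")
})
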