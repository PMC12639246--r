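spec <- synthetic_complex_spec(seed = 5)

test_that("the preparation pipeline reproduces planted removal counts", {
  tab <- make_skempi_table(spec, n_clean = 6, n_missing_kd = 2,
                           n_mismatch = 1, n_duplicate = 1)
  ds <- build_dataset(tab$table, tab$sequences, split_fraction = 0.7, seed = 42)
  expect_identical(unname(ds$provenance), unname(tab$expected))
  expect_identical(nrow(ds$records), 6L)
  # floor rule: floor(0.7 * 6) = 4 training, 2 validation
  expect_length(ds$train_idx, 4L)
  expect_length(ds$val_idx, 2L)
})

test_that("removals plus retained records equal the input row count", {
  for (s in 1:5) {
    sp <- synthetic_complex_spec(seed = s)
    tab <- make_skempi_table(sp, n_clean = sample(3:8, 1),
                             n_missing_kd = sample(0:3, 1),
                             n_mismatch = sample(0:2, 1),
                             n_duplicate = sample(0:2, 1))
    ds <- build_dataset(tab$table, tab$sequences)
    p <- ds$provenance
    expect_identical(p[["input"]],
                     p[["missing_affinity"]] + p[["mismatch"]] +
                       p[["duplicate"]] + p[["retained"]])
  }
})

test_that("duplicate-free input reports a zero duplicate count", {
  tab <- make_skempi_table(spec, n_clean = 5, n_missing_kd = 0,
                           n_mismatch = 0, n_duplicate = 0)
  ds <- build_dataset(tab$table, tab$sequences)
  expect_identical(ds$provenance[["duplicate"]], 0L)
  expect_identical(ds$provenance[["retained"]], 5L)
})

test_that("the unordered-pair deduplication key treats (A,B) and (B,A) as one", {
  tab <- data.frame(
    complex = c("SYN1_A_B", "SYN1_B_A"),
    mutations = c("", ""),
    kd = c(1e-8, 1e-8), stringsAsFactors = FALSE)
  seqs <- c(SYN1_A = spec$seq_a, SYN1_B = spec$seq_b)
  ds <- build_dataset(tab, seqs)
  expect_identical(ds$provenance[["duplicate"]], 1L)
  expect_identical(ds$provenance[["retained"]], 1L)
})

test_that("labels come from the record's own dissociation constant", {
  tab <- make_skempi_table(spec, n_clean = 4, n_missing_kd = 0,
                           n_mismatch = 0, n_duplicate = 0)
  ds <- build_dataset(tab$table, tab$sequences)
  expect_equal(ds$records$label, kd_to_affinity_score(ds$records$kd))
})

test_that("splits are reproducible and follow the floor rule", {
  a <- split_indices(101, 0.7, seed = 9)
  b <- split_indices(101, 0.7, seed = 9)
  expect_identical(a, b)
  expect_length(a$train, floor(0.7 * 101))
  expect_length(a$val, 101 - floor(0.7 * 101))
  expect_identical(sort(c(a$train, a$val)), 1:101)
  expect_false(identical(split_indices(101, 0.7, seed = 10)$train, a$train))
})

test_that("retained records are invariant to input row order", {
  tab <- make_skempi_table(spec, shuffle = FALSE)
  shuf <- make_skempi_table(spec, shuffle = TRUE)
  ds1 <- build_dataset(tab$table, tab$sequences)
  ds2 <- build_dataset(shuf$table, shuf$sequences)
  key <- function(d) sort(paste(d$records$seq_a, d$records$seq_b, d$records$kd))
  expect_identical(key(ds1), key(ds2))
})

test_that("tables round-trip through the TSV reader and writer", {
  tab <- make_skempi_table(spec, n_clean = 4, n_missing_kd = 1,
                           n_mismatch = 0, n_duplicate = 0)
  raw <- tab$table
  names(raw) <- c("#Pdb", "Mutation(s)_cleaned", "Affinity_mut (M)")
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(raw, f, sep = "\t", quote = FALSE, row.names = FALSE)
  rt <- read_skempi_table(f)
  expect_equal(rt$kd, tab$table$kd)
  ds <- build_dataset(rt, tab$sequences)
  expect_identical(ds$provenance[["retained"]], 4L)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(ds, out)
  back <- read.delim(out)
  expect_identical(nrow(back), 4L)
  expect_true(file.exists(paste0(out, ".provenance.json")))
})

test_that("an empty retained set is an error", {
  tab <- data.frame(complex = "SYN1_A_B", mutations = "", kd = NA_real_)
  expect_error(build_dataset(tab, c(SYN1_A = "MK", SYN1_B = "WW")),
               "no records retained")
})
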