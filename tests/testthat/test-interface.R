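two_point_structure <- function(d) {
  complex_structure("pair", list(
    A = list(sequence = "G", atoms = data.frame(seq_index = 1, x = 0, y = 0, z = 0)),
    B = list(sequence = "L", atoms = data.frame(seq_index = 1, x = d, y = 0, z = 0))))
}

test_that("single-residue chains are interface iff within the cutoff", {
  near <- extract_interface(two_point_structure(6.0), 6.5)
  expect_identical(near$sets$A, 1L)
  expect_identical(near$sets$B, 1L)
  far <- extract_interface(two_point_structure(7.0), 6.5)
  expect_length(far$sets$A, 0L)
  expect_length(far$sets$B, 0L)
  boundary <- extract_interface(two_point_structure(6.5), 6.5)
  expect_identical(boundary$sets$A, 1L)  # cutoff is inclusive
})

test_that("interface sets equal the brute-force all-atom-pairs oracle", {
  set.seed(31)
  for (case in 1:15) {
    st <- random_toy_structure()
    fast <- extract_interface(st, 6.5)
    slow <- brute_interface(st, 6.5)
    expect_identical(unname(fast$sets[[1]]), slow[[1]])
    expect_identical(unname(fast$sets[[2]]), slow[[2]])
  }
})

test_that("interface sets grow monotonically with the cutoff", {
  set.seed(32)
  for (case in 1:8) {
    st <- random_toy_structure()
    cuts <- c(2, 4, 6.5, 9, 14)
    sets <- lapply(cuts, function(ct) extract_interface(st, ct)$sets)
    for (i in seq_len(length(cuts) - 1)) {
      expect_true(all(sets[[i]][[1]] %in% sets[[i + 1]][[1]]))
      expect_true(all(sets[[i]][[2]] %in% sets[[i + 1]][[2]]))
    }
  }
})

test_that("toy PDB files round-trip through the PDB reader", {
  spec <- synthetic_complex_spec(seed = 13, len_a = 10, len_b = 12,
                                 interface_a = c(3, 7), interface_b = c(5, 9))
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- make_toy_pdb(spec, f)
  cx <- read_complex(f)
  expect_identical(names(cx$chains), c("A", "B"))
  expect_identical(cx$chains$A$sequence, spec$seq_a)
  expect_identical(cx$chains$B$sequence, spec$seq_b)
  # coordinates survive the fixed-width format to 3 decimals
  atom_lines <- grep("^ATOM", lines, value = TRUE)
  xyz <- do.call(rbind, lapply(atom_lines, function(l)
    as.numeric(c(substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54)))))
  parsed <- rbind(as.matrix(cx$chains$A$atoms[, c("x", "y", "z")]),
                  as.matrix(cx$chains$B$atoms[, c("x", "y", "z")]))
  expect_equal(unname(parsed), unname(xyz), tolerance = 1e-9)
})

test_that("the toy geometry plants exactly the designated interface", {
  spec <- synthetic_complex_spec(seed = 14, len_a = 15, len_b = 11,
                                 interface_a = c(2, 8, 13), interface_b = 6)
  f <- withr::local_tempfile(fileext = ".pdb")
  make_toy_pdb(spec, f)
  cx <- read_complex(f)
  is <- extract_interface(cx, 6.5)
  expect_identical(is$sets$A, spec$interface_a)
  expect_identical(is$sets$B, spec$interface_b)
  expect_identical(interface_size(is), 4L)
  # below the planted 5 A gap the interface vanishes
  expect_identical(interface_size(extract_interface(cx, 4)), 0L)
})

test_that("structures without two chains are rejected", {
  st <- complex_structure("solo", list(
    A = list(sequence = "G", atoms = data.frame(seq_index = 1, x = 0, y = 0, z = 0))))
  expect_error(extract_interface(st), "exactly 2 chains")
})

test_that("corpus filtering keeps usable heterodimers and logs removals", {
  mk <- function(id, seqs) list(complex_id = id, chain_seqs = seqs)
  entries <- list(
    mk("ok1", c(A = strrep("K", 100), B = strrep("L", 90))),
    mk("trimer", c(A = "KK", B = "LL", C = "GG")),
    mk("homo", c(A = "KLKL", B = "KLKL")),
    mk("long", c(A = strrep("K", 501), B = "LL")),
    mk("leaky", c(A = "KL", B = "GG")),
    mk("ok2", c(A = strrep("S", 500), B = "GG")))
  out <- corpus_filter(entries, exclude = "leaky")
  expect_identical(vapply(out$retained, `[[`, character(1), "complex_id"),
                   c("ok1", "ok2"))
  expect_identical(out$removal_log,
                   c(not_two_chains = 1L, homodimer = 1L, too_long = 1L,
                     excluded = 1L))
  expect_identical(sum(out$removal_log) + length(out$retained), out$n_input)
})

test_that("interface tables are written with distances and numbering", {
  spec <- synthetic_complex_spec(seed = 15, len_a = 8, len_b = 8,
                                 interface_a = 4, interface_b = 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  make_toy_pdb(spec, f)
  cx <- read_complex(f)
  is <- extract_interface(cx)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_interface(is, out, structure = cx)
  tab <- read.delim(out)
  expect_identical(nrow(tab), 2L)
  expect_true(all(tab$min_distance <= 6.5))
})
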