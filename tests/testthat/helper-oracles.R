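# Independent brute-force oracles used across the tests.

# O(atoms^2) interface oracle: residue in the set iff any heavy-atom pair
# across chains is within the cutoff
brute_interface <- function(structure, cutoff) {
  chs <- structure$chains
  a <- chs[[1]]$atoms; b <- chs[[2]]$atoms
  in_a <- integer(0); in_b <- integer(0)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2)
      if (d <= cutoff) {
        in_a <- c(in_a, a$seq_index[i])
        in_b <- c(in_b, b$seq_index[j])
      }
    }
  }
  list(sort(unique(in_a)), sort(unique(in_b)))
}

# random two-chain toy structure: 1-3 heavy atoms per residue, coordinates
# in a box sized so that cross-chain distances straddle typical cutoffs
random_toy_structure <- function(n_res_max = 25) {
  mk_chain <- function(L) {
    atoms <- do.call(rbind, lapply(seq_len(L), function(r) {
      k <- sample(1:3, 1)
      data.frame(seq_index = rep(r, k),
                 x = runif(k, 0, 15), y = runif(k, 0, 15), z = runif(k, 0, 15))
    }))
    list(sequence = paste(sample(c("G", "L", "K", "S"), L, replace = TRUE),
                          collapse = ""),
         atoms = atoms)
  }
  complex_structure("toy", list(A = mk_chain(sample(1:n_res_max, 1)),
                                B = mk_chain(sample(1:n_res_max, 1))))
}

# brute-force window enumeration oracle for alanine scans
brute_scan <- function(seq, p) {
  L <- nchar(seq)
  vapply(seq_len(L - p + 1L), function(s) {
    ch <- strsplit(seq, "")[[1]]
    ch[s:(s + p - 1L)] <- "A"
    paste(ch, collapse = "")
  }, character(1))
}

# a model stub usable by score_scan: any function(seq_a, seq_b) -> score
constant_model <- function(value) function(seq_a, seq_b) value
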