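#' Specification of a synthetic protein complex with known energetics
#'
#' Defines a reproducible toy dimer whose binding energetics are fully
#' known: a handful of designated "interface" positions on each chain carry
#' additive energetic weights (kcal/mol), and every other position is
#' energetically inert. The same designated positions are used by
#' [make_toy_pdb()] as the geometric interface and by
#' [make_affinity_dataset()] as the energetic determinants of the affinity
#' labels, so a model trained on the labels can be checked against the
#' geometry end-to-end. Background residues are drawn uniformly from the 19
#' non-alanine amino acids so that every alanine-scan position is a genuine
#' substitution.
#'
#' @param seed RNG seed; the spec (sequences, weights) is fully reproducible
#'   from it.
#' @param len_a,len_b chain lengths.
#' @param interface_a,interface_b designated 1-based interface positions per
#'   chain (defaults: 3 positions on A and 2 on B, placed away from the
#'   termini).
#' @param weights_a,weights_b energetic weight per designated position in
#'   kcal/mol; by default drawn uniformly from [1, 3].
#' @param noise_sd Gaussian label noise standard deviation (kcal/mol).
#' @param base_score affinity score of a complex with every designated
#'   position mutated to alanine.
#' @return a `synthetic_complex_spec` with the wild-type sequences attached.
#' @export
synthetic_complex_spec <- function(seed = 1, len_a = 40, len_b = 40,
                                   interface_a = NULL, interface_b = NULL,
                                   weights_a = NULL, weights_b = NULL,
                                   noise_sd = 0.3, base_score = 3) {
  withr_seed(seed, {
    if (is.null(interface_a)) interface_a <- sort(sample(2:(len_a - 1), 3))
    if (is.null(interface_b)) interface_b <- sort(sample(2:(len_b - 1), 2))
    stopifnot(all(interface_a >= 1 & interface_a <= len_a),
              all(interface_b >= 1 & interface_b <= len_b),
              noise_sd >= 0, base_score >= 0)
    if (is.null(weights_a)) weights_a <- runif(length(interface_a), 1, 3)
    if (is.null(weights_b)) weights_b <- runif(length(interface_b), 1, 3)
    stopifnot(length(weights_a) == length(interface_a),
              length(weights_b) == length(interface_b),
              all(is.finite(c(weights_a, weights_b))))
    bg <- setdiff(AA_ALPHABET, "A")
    seq_a <- paste(sample(bg, len_a, replace = TRUE), collapse = "")
    seq_b <- paste(sample(bg, len_b, replace = TRUE), collapse = "")
    structure(list(seed = seed, len_a = len_a, len_b = len_b,
                   interface_a = as.integer(interface_a),
                   interface_b = as.integer(interface_b),
                   weights_a = weights_a, weights_b = weights_b,
                   noise_sd = noise_sd, base_score = base_score,
                   seq_a = seq_a, seq_b = seq_b),
              class = "synthetic_complex_spec")
  })
}

#' @export
print.synthetic_complex_spec <- function(x, ...) {
  cat(sprintf("<synthetic_complex_spec seed %d: %d + %d aa, interface A{%s} B{%s}, sigma=%.2f>\n",
              x$seed, x$len_a, x$len_b,
              paste(x$interface_a, collapse = ","),
              paste(x$interface_b, collapse = ","), x$noise_sd))
  invisible(x)
}

#' Ground-truth affinity oracle of a synthetic complex
#'
#' Noiseless score: `base_score` plus the weight of every designated
#' position whose residue is not alanine. Mutating a designated position to
#' alanine therefore lowers the score by exactly its weight; mutating any
#' other position changes nothing. Optional Gaussian noise (drawn from the
#' caller's RNG stream) emulates experimental measurement error.
#'
#' @param spec a [synthetic_complex_spec()].
#' @param seq_a,seq_b sequences to score (defaults: the wild types).
#' @param noise add `N(0, spec$noise_sd)` noise.
#' @return affinity score in kcal/mol.
#' @export
oracle_affinity <- function(spec, seq_a = spec$seq_a, seq_b = spec$seq_b,
                            noise = FALSE) {
  stopifnot(inherits(spec, "synthetic_complex_spec"),
            nchar(seq_a) == spec$len_a, nchar(seq_b) == spec$len_b)
  on_a <- vapply(spec$interface_a, function(p) substr(seq_a, p, p) != "A", logical(1))
  on_b <- vapply(spec$interface_b, function(p) substr(seq_b, p, p) != "A", logical(1))
  s <- spec$base_score + sum(spec$weights_a[on_a]) + sum(spec$weights_b[on_b])
  if (noise && spec$noise_sd > 0) s <- s + rnorm(1, 0, spec$noise_sd)
  max(s, 0)
}

random_mutation <- function(seq, pos, bg = AA_ALPHABET) {
  wt <- substr(seq, pos, pos)
  repeat {
    mut <- sample(bg, 1)
    if (mut != wt) return(mut)
  }
}

#' Generate a synthetic oracle-labelled affinity dataset
#'
#' Produces a training corpus in the same shape as [build_dataset()]'s
#' output: the wild-type pair plus mutational variants of it (single
#' random substitutions, contiguous alanine patches, and wild-type
#' replicates), each labelled by [oracle_affinity()] with Gaussian noise.
#' Dissociation constants are back-computed from the labels so the records
#' round-trip through [kd_to_affinity_score()].
#'
#' @param spec a [synthetic_complex_spec()].
#' @param n_pairs number of records (>= 2).
#' @param split_fraction,seed forwarded to [split_indices()]; `seed`
#'   defaults to the spec's.
#' @param p_wild,p_single fractions of wild-type replicates and single-site
#'   mutants; the remainder are alanine-patch mutants (patch size drawn
#'   from `patches`).
#' @param patches candidate alanine patch sizes for patch mutants.
#' @return a `processed_dataset`.
#' @export
make_affinity_dataset <- function(spec, n_pairs = 500, split_fraction = 0.7,
                                  seed = spec$seed, p_wild = 0.2,
                                  p_single = 0.4, patches = c(1, 2, 5)) {
  stopifnot(inherits(spec, "synthetic_complex_spec"), n_pairs >= 2,
            p_wild >= 0, p_single >= 0, p_wild + p_single <= 1)
  records <- withr_seed(seed * 7919 + 1, {
    kinds <- sample(c("wild", "single", "patch"), n_pairs, replace = TRUE,
                    prob = c(p_wild, p_single, 1 - p_wild - p_single))
    kinds[1] <- "wild"  # always include at least one wild-type record
    rows <- lapply(seq_len(n_pairs), function(i) {
      sa <- spec$seq_a; sb <- spec$seq_b
      codes <- character(0)
      if (kinds[i] != "wild") {
        side <- sample(c("A", "B"), 1)
        L <- if (side == "A") spec$len_a else spec$len_b
        seq <- if (side == "A") sa else sb
        if (kinds[i] == "single") {
          pos <- sample.int(L, 1)
          mut <- random_mutation(seq, pos)
          codes <- paste0(substr(seq, pos, pos), side, pos, mut)
          seq <- substitute_at(seq, pos, mut)
        } else {
          p <- sample(patches[patches <= L], 1)
          start <- sample.int(L - p + 1L, 1)
          pos <- start:(start + p - 1L)
          codes <- vapply(pos, function(q)
            paste0(substr(seq, q, q), side, q, "A"), character(1))
          for (q in pos) seq <- substitute_at(seq, q, "A")
        }
        if (side == "A") sa <- seq else sb <- seq
      }
      label <- oracle_affinity(spec, sa, sb, noise = TRUE)
      data.frame(complex_id = "SYN1_A_B", seq_a = sa, seq_b = sb,
                 mutations = paste(codes, collapse = ","),
                 kd = affinity_score_to_kd(label), label = label,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  rownames(records) <- NULL
  sp <- split_indices(nrow(records), split_fraction, seed)
  structure(list(records = records, train_idx = sp$train, val_idx = sp$val,
                 provenance = c(input = n_pairs, missing_affinity = 0L,
                                mismatch = 0L, duplicate = 0L,
                                retained = n_pairs),
                 split_fraction = split_fraction, seed = seed,
                 spec = spec),
            class = "processed_dataset")
}

#' Write a toy dimer structure whose interface is the designated positions
#'
#' Emits minimal single-atom (C-alpha) PDB ATOM records for the two chains
#' of a synthetic complex, placed so that the designated interface positions
#' of the two chains sit about 5 angstroms apart (inside the 6.5 A cutoff)
#' while every other cross-chain atom pair is at least 30 A apart. Running
#' [extract_interface()] on the file therefore returns exactly the
#' designated positions. Both chains must have at least one designated
#' position; otherwise the requested geometry is infeasible and an error is
#' raised.
#'
#' @param spec a [synthetic_complex_spec()].
#' @param path optional output file; when `NULL` the PDB text lines are
#'   returned only.
#' @return character vector of PDB lines (invisibly when `path` is given).
#' @export
make_toy_pdb <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "synthetic_complex_spec"))
  ma <- length(spec$interface_a); mb <- length(spec$interface_b)
  if (ma == 0L || mb == 0L)
    stop("infeasible geometry: both chains need at least one designated interface position")
  ncl <- min(ma, mb)
  coords <- function(L, designated, y_far, y_near) {
    xyz <- matrix(NA_real_, L, 3)
    bg <- setdiff(seq_len(L), designated)
    xyz[bg, ] <- cbind(3.8 * bg, y_far, 0)
    for (j in seq_along(designated)) {
      cl <- ((j - 1L) %% ncl) + 1L
      xyz[designated[j], ] <- c(30 * cl, y_near, 0.3 * ((j - 1L) %/% ncl))
    }
    xyz
  }
  xa <- coords(spec$len_a, spec$interface_a, -30, 0)
  xb <- coords(spec$len_b, spec$interface_b, +30, 5)
  fmt <- function(serial, chain, resno, aa1, xyz)
    sprintf("ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            serial, bio3d::aa123(aa1), chain, resno, xyz[1], xyz[2], xyz[3])
  lines <- character(0)
  serial <- 0L
  for (side in list(list("A", spec$seq_a, xa), list("B", spec$seq_b, xb))) {
    for (i in seq_len(nchar(side[[2]]))) {
      serial <- serial + 1L
      lines <- c(lines, fmt(serial, side[[1]], i,
                            substr(side[[2]], i, i), side[[3]][i, ]))
    }
    lines <- c(lines, "TER")
  }
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Generate a SKEMPI-style table with planted defects
#'
#' Builds a raw affinity table for a synthetic complex containing a known
#' number of clean rows, rows lacking affinity data, rows whose mutation
#' code mismatches the sequence, and duplicated rows — the defect classes a
#' real mutation database exhibits. Passing the table through
#' [build_dataset()] reproduces the planted provenance counts exactly.
#'
#' @param spec a [synthetic_complex_spec()].
#' @param n_clean number of well-formed unique rows (the first is the
#'   wild-type pair).
#' @param n_missing_kd rows without a usable dissociation constant.
#' @param n_mismatch rows whose mutation code names the wrong wild-type
#'   residue.
#' @param n_duplicate exact copies of clean rows.
#' @param seed RNG seed; also controls the final row shuffle.
#' @param shuffle shuffle row order (retained records are order-invariant).
#' @return list with `table` (data.frame `complex`, `mutations`, `kd`),
#'   `sequences` (named vector for [build_dataset()]) and `expected`
#'   provenance counts.
#' @export
make_skempi_table <- function(spec, n_clean = 6, n_missing_kd = 2,
                              n_mismatch = 1, n_duplicate = 1,
                              seed = spec$seed, shuffle = TRUE) {
  stopifnot(inherits(spec, "synthetic_complex_spec"), n_clean >= 2,
            n_missing_kd >= 0, n_mismatch >= 0, n_duplicate >= 0,
            n_duplicate <= n_clean - 1)
  withr_seed(seed * 104729 + 2, {
    # distinct single mutations on chain A -> distinct deduplication keys
    stopifnot(n_clean - 1 + n_missing_kd <= spec$len_a)
    pool <- sample.int(spec$len_a, n_clean - 1 + n_missing_kd)
    row_for <- function(pos, kd_ok) {
      wt <- substr(spec$seq_a, pos, pos)
      mut <- random_mutation(spec$seq_a, pos)
      sa <- substitute_at(spec$seq_a, pos, mut)
      label <- oracle_affinity(spec, sa, spec$seq_b, noise = TRUE)
      data.frame(complex = "SYN1_A_B",
                 mutations = paste0(wt, "A", pos, mut),
                 kd = if (kd_ok) affinity_score_to_kd(label) else NA_real_,
                 stringsAsFactors = FALSE)
    }
    wild_label <- oracle_affinity(spec, noise = TRUE)
    clean <- rbind(
      data.frame(complex = "SYN1_A_B", mutations = "",
                 kd = affinity_score_to_kd(wild_label),
                 stringsAsFactors = FALSE),
      do.call(rbind, lapply(pool[seq_len(n_clean - 1)], row_for, kd_ok = TRUE)))
    missing <- if (n_missing_kd > 0)
      do.call(rbind, lapply(pool[n_clean - 1 + seq_len(n_missing_kd)],
                            row_for, kd_ok = FALSE)) else NULL
    mism <- if (n_mismatch > 0) do.call(rbind, lapply(seq_len(n_mismatch), function(i) {
      pos <- sample.int(spec$len_a, 1)
      wt_wrong <- sample(setdiff(AA_ALPHABET, substr(spec$seq_a, pos, pos)), 1)
      mut <- sample(setdiff(AA_ALPHABET, wt_wrong), 1)
      data.frame(complex = "SYN1_A_B",
                 mutations = paste0(wt_wrong, "A", pos, mut),
                 kd = affinity_score_to_kd(wild_label),
                 stringsAsFactors = FALSE)
    })) else NULL
    dup <- if (n_duplicate > 0)
      clean[1 + seq_len(n_duplicate), , drop = FALSE] else NULL
    tab <- rbind(clean, missing, mism, dup)
    if (shuffle) tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
    rownames(tab) <- NULL
    list(table = tab,
         sequences = c(SYN1_A = spec$seq_a, SYN1_B = spec$seq_b),
         expected = c(input = nrow(tab),
                      missing_affinity = as.integer(n_missing_kd),
                      mismatch = as.integer(n_mismatch),
                      duplicate = as.integer(n_duplicate),
                      retained = as.integer(n_clean)))
  })
}
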