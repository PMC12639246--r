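#' Read a dimer structure from a PDB file
#'
#' Parses ATOM records (HETATM ignored by default) into a light-weight
#' per-chain representation: residue sequence in order of appearance, the
#' author residue numbering alongside a consecutive 1-based sequence index,
#' and heavy-atom coordinates. Hydrogens are dropped; for alternate
#' locations only the highest-occupancy conformer of each atom is kept.
#' The author-number to sequence-index map is carried in the result so
#' mutation positions and interface indices share one coordinate system.
#'
#' @param file PDB file path.
#' @param complex_id identifier; defaults to the file basename.
#' @param chains optional character vector restricting which chains to keep.
#' @return a `complex_structure`: list with `complex_id` and `chains`, one
#'   entry per chain holding `sequence`, `resno` (author numbers, parallel
#'   to the sequence) and `atoms` (data.frame: `seq_index`, `x`, `y`, `z`).
#' @export
read_complex <- function(file, complex_id = NULL, chains = NULL) {
  if (is.null(complex_id))
    complex_id <- sub("\\.(pdb|ent)$", "", basename(file), ignore.case = TRUE)
  pdb <- bio3d::read.pdb(file, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop(sprintf("no ATOM records in %s", file))
  elem <- ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                 substr(trimws(at$elety), 1, 1), trimws(at$elesy))
  at <- at[toupper(elem) != "H", , drop = FALSE]
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  if (nrow(at) == 0L) stop("no heavy atoms left after filtering")

  # altloc: keep highest-occupancy conformer per (chain, residue, atom name)
  akey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(akey, -occ)
  keep_rows <- ord[!duplicated(akey[ord])]
  at <- at[sort(keep_rows), , drop = FALSE]

  out <- list()
  for (ch in unique(at$chain)) {
    ca <- at[at$chain == ch, , drop = FALSE]
    rkey <- paste(ca$resno, ifelse(is.na(ca$insert), "", ca$insert))
    first <- !duplicated(rkey)
    seq_index <- as.integer(factor(rkey, levels = unique(rkey)))
    aa3 <- ca$resid[first]
    aa1 <- bio3d::aa321(aa3)
    aa1[is.na(aa1) | !(aa1 %in% AA_ALPHABET)] <- AA_UNKNOWN
    out[[ch]] <- list(
      chain_id = ch,
      sequence = paste(aa1, collapse = ""),
      resno = ca$resno[first],
      atoms = data.frame(seq_index = seq_index,
                         x = ca$x, y = ca$y, z = ca$z))
  }
  structure(list(complex_id = complex_id, chains = out),
            class = "complex_structure")
}

#' Construct a complex structure from in-memory data
#'
#' Programmatic constructor used by the fixture generator and tests; same
#' representation as [read_complex()].
#'
#' @param complex_id identifier.
#' @param chains named list; each element a list with `sequence` and `atoms`
#'   (data.frame with `seq_index`, `x`, `y`, `z`) and optionally `resno`.
#' @return a `complex_structure`.
#' @export
complex_structure <- function(complex_id, chains) {
  for (ch in names(chains)) {
    chains[[ch]]$chain_id <- ch
    if (is.null(chains[[ch]]$resno))
      chains[[ch]]$resno <- seq_len(nchar(chains[[ch]]$sequence))
    stopifnot(all(c("seq_index", "x", "y", "z") %in% names(chains[[ch]]$atoms)))
  }
  structure(list(complex_id = complex_id, chains = chains),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  cat(sprintf("<complex_structure %s: %s>\n", x$complex_id,
              paste(vapply(x$chains, function(ch)
                sprintf("chain %s (%d aa, %d atoms)", ch$chain_id,
                        nchar(ch$sequence), nrow(ch$atoms)),
                character(1)), collapse = ", ")))
  invisible(x)
}

# squared cross-distance matrix between two coordinate matrices
cross_dist2 <- function(A, B) {
  outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
}

#' Extract ground-truth interface residues at a distance cutoff
#'
#' A residue of one chain belongs to the interface iff any of its heavy
#' atoms lies within `cutoff` angstroms of any heavy atom of the partner
#' chain. Construction is symmetric: the chain-A set is determined by chain
#' B and vice versa. Interface sets are monotone in the cutoff.
#'
#' @param structure a `complex_structure` with exactly two chains.
#' @param cutoff distance cutoff in angstroms (default 6.5).
#' @return an `interface_set`: list with `complex_id`, `cutoff`, `sets`
#'   (named list of sorted 1-based sequence indices per chain) and
#'   `min_dist` (per-chain numeric vectors of each residue's minimum
#'   heavy-atom distance to the partner).
#' @export
extract_interface <- function(structure, cutoff = 6.5) {
  stopifnot(inherits(structure, "complex_structure"), cutoff > 0)
  if (length(structure$chains) != 2L)
    stop(sprintf("interface extraction needs exactly 2 chains, got %d",
                 length(structure$chains)))
  chs <- structure$chains
  ids <- names(chs)
  XA <- as.matrix(chs[[1]]$atoms[, c("x", "y", "z")])
  XB <- as.matrix(chs[[2]]$atoms[, c("x", "y", "z")])
  if (nrow(XA) == 0L || nrow(XB) == 0L) stop("chain without coordinates")
  d2 <- cross_dist2(XA, XB)
  d2[d2 < 0] <- 0
  min_per <- function(d2row, idx, L) {
    v <- rep(Inf, L)
    m <- tapply(d2row, idx, min)
    v[as.integer(names(m))] <- m
    sqrt(v)
  }
  La <- nchar(chs[[1]]$sequence); Lb <- nchar(chs[[2]]$sequence)
  mda <- min_per(apply(d2, 1, min), chs[[1]]$atoms$seq_index, La)
  mdb <- min_per(apply(d2, 2, min), chs[[2]]$atoms$seq_index, Lb)
  if (any(!is.finite(mda)) || any(!is.finite(mdb)))
    warning("residues without coordinates were skipped")
  sets <- list(sort(which(mda <= cutoff)), sort(which(mdb <= cutoff)))
  names(sets) <- ids
  md <- list(mda, mdb)
  names(md) <- ids
  structure(list(complex_id = structure$complex_id, cutoff = cutoff,
                 sets = sets, min_dist = md),
            class = "interface_set")
}

#' @export
print.interface_set <- function(x, ...) {
  cat(sprintf("<interface_set %s @ %.1f A: %s (n = %d)>\n", x$complex_id,
              x$cutoff,
              paste(sprintf("chain %s: %d residues", names(x$sets),
                            lengths(x$sets)), collapse = ", "),
              interface_size(x)))
  invisible(x)
}

#' Total number of true interface residues
#'
#' The `n` that parameterizes the N-factor metric: interface residues pooled
#' over both chains.
#' @param x an `interface_set`.
#' @return integer count.
#' @export
interface_size <- function(x) {
  stopifnot(inherits(x, "interface_set"))
  sum(lengths(x$sets))
}

#' Filter an evaluation corpus of complexes
#'
#' Applies the evaluation-corpus rules to a list of candidate complexes and
#' keeps only usable heterodimers: exactly two chain ids, the two chain
#' sequences distinct (homodimers removed), every chain at most
#' `max_residues` residues, and the complex absent from the exclusion list
#' (e.g. complexes present in the training database, to control leakage).
#' Rules are applied in that order and each removal is attributed to the
#' first rule it violates; retained plus removed always equals the input
#' count.
#'
#' @param entries list of `complex_structure` objects, or of lists with
#'   `complex_id` and `chain_seqs` (named character vector of sequences).
#' @param exclude character vector of `complex_id`s to exclude.
#' @param max_residues per-chain residue limit (default 500).
#' @return list with `retained` (the surviving entries), `removal_log`
#'   (named counts: `not_two_chains`, `homodimer`, `too_long`, `excluded`)
#'   and `n_input`.
#' @export
corpus_filter <- function(entries, exclude = character(0), max_residues = 500) {
  log <- c(not_two_chains = 0L, homodimer = 0L, too_long = 0L, excluded = 0L)
  retained <- list()
  for (e in entries) {
    seqs <- if (inherits(e, "complex_structure"))
      vapply(e$chains, `[[`, character(1), "sequence") else e$chain_seqs
    id <- e$complex_id
    rule <- if (length(seqs) != 2L) "not_two_chains"
      else if (seqs[[1]] == seqs[[2]]) "homodimer"
      else if (max(nchar(seqs)) > max_residues) "too_long"
      else if (id %in% exclude) "excluded"
      else NA_character_
    if (is.na(rule)) retained[[length(retained) + 1L]] <- e
    else log[rule] <- log[rule] + 1L
  }
  list(retained = retained, removal_log = log, n_input = length(entries))
}

#' Write an interface set as TSV
#'
#' One row per interface residue: complex, chain, sequence index, author
#' residue number (when known) and minimum heavy-atom distance to the
#' partner chain.
#'
#' @param x an `interface_set`.
#' @param structure optional `complex_structure` supplying author numbering.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_interface <- function(x, path, structure = NULL) {
  rows <- do.call(rbind, lapply(names(x$sets), function(ch) {
    idx <- x$sets[[ch]]
    if (length(idx) == 0L) return(NULL)
    data.frame(complex = x$complex_id, chain = ch, seq_index = idx,
               author_number = if (!is.null(structure))
                 structure$chains[[ch]]$resno[idx] else idx,
               min_distance = round(x$min_dist[[ch]][idx], 3))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
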