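#' Parse a SKEMPI-style mutation code
#'
#' A mutation code such as `"LI38G"` reads: replace `L` at position 38 of
#' chain `I` with `G`. The format is `<wt><chain><position><mut>` where `wt`
#' and `mut` are one-letter amino acids from the 20-residue alphabet, `chain`
#' is a single letter, and `position` is a 1-based index into the chain
#' sequence.
#'
#' @param code character vector of mutation codes.
#' @return for a single code, a `mutation_code` object (list with fields
#'   `wt`, `chain`, `pos`, `mut`); for several codes, a list of them.
#' @examples
#' parse_mutation_code("LI38G")
#' @export
parse_mutation_code <- function(code) {
  if (length(code) > 1L) return(lapply(code, parse_mutation_code))
  stopifnot(is.character(code), length(code) == 1L)
  m <- regmatches(code, regexec("^([A-Z])([A-Za-z])([0-9]+)([A-Z])$", code))[[1]]
  if (length(m) == 0L)
    stop(sprintf("malformed mutation code: '%s'", code))
  wt <- m[2]; chain <- m[3]; pos <- as.integer(m[4]); mut <- m[5]
  if (!(wt %in% AA_ALPHABET))
    stop(sprintf("malformed mutation code '%s': wild-type residue '%s' not a standard amino acid", code, wt))
  if (!(mut %in% AA_ALPHABET))
    stop(sprintf("malformed mutation code '%s': mutant residue '%s' not a standard amino acid", code, mut))
  if (pos < 1L) stop(sprintf("malformed mutation code '%s': position must be >= 1", code))
  if (wt == mut) stop(sprintf("malformed mutation code '%s': wild-type and mutant residues are identical", code))
  structure(list(wt = wt, chain = chain, pos = pos, mut = mut),
            class = "mutation_code")
}

#' @export
format.mutation_code <- function(x, ...) paste0(x$wt, x$chain, x$pos, x$mut)

#' @export
print.mutation_code <- function(x, ...) {
  cat(sprintf("<mutation %s: chain %s position %d, %s -> %s>\n",
              format(x), x$chain, x$pos, x$wt, x$mut))
  invisible(x)
}

#' Construct an affinity record
#'
#' One labelled sequence pair: the two chain sequences of a complex, the
#' mutation codes applied (empty for a wild-type measurement), the measured
#' dissociation constant and, optionally, the derived affinity label.
#'
#' @param complex_id identifier, conventionally `PDBID_chainA_chainB`.
#' @param chain_a,chain_b single-letter chain identifiers.
#' @param seq_a,seq_b amino-acid sequences (20-letter alphabet plus `X`).
#' @param mutations list of [parse_mutation_code()] results, or a character
#'   vector of codes; empty for wild type.
#' @param kd dissociation constant in molar units (`NA` if unmeasured).
#' @param label affinity score in kcal/mol; computed from `kd` via
#'   [kd_to_affinity_score()] when missing.
#' @return an `affinity_record` object.
#' @export
affinity_record <- function(complex_id, chain_a, chain_b, seq_a, seq_b,
                            mutations = list(), kd = NA_real_, label = NULL) {
  if (!is_valid_seq(seq_a) || !is_valid_seq(seq_b))
    stop(sprintf("record '%s': sequences must be non-empty amino-acid strings", complex_id))
  if (is.character(mutations)) {
    mutations <- mutations[nzchar(mutations)]
    mutations <- lapply(mutations, parse_mutation_code)
  }
  if (is.null(label) && is.finite(kd) && kd > 0)
    label <- kd_to_affinity_score(kd, complex_id)
  structure(
    list(complex_id = complex_id, chain_a = chain_a, chain_b = chain_b,
         seq_a = seq_a, seq_b = seq_b, mutations = mutations,
         kd = kd, label = if (is.null(label)) NA_real_ else label),
    class = "affinity_record")
}

#' @export
print.affinity_record <- function(x, ...) {
  cat(sprintf("<affinity_record %s: chains %s (%d aa) / %s (%d aa), %d mutation(s), label %s>\n",
              x$complex_id, x$chain_a, nchar(x$seq_a), x$chain_b, nchar(x$seq_b),
              length(x$mutations),
              if (is.na(x$label)) "NA" else sprintf("%.3f kcal/mol", x$label)))
  invisible(x)
}

substitute_at <- function(seq, pos, aa) {
  substr(seq, pos, pos) <- aa
  seq
}

#' Apply mutation codes to an affinity record
#'
#' Substitutes each mutation into the chain it names, after verifying that
#' the wild-type residue in the code matches the residue actually present at
#' that position. A mismatch (or an out-of-range position, or a chain id not
#' in the record) raises a condition of class `pairbind_mismatch`; the
#' dataset builder counts such records in its mismatch removal class.
#'
#' @param record an [affinity_record()].
#' @return the record with mutated sequences; the `mutations` field is kept
#'   for traceability and a `mutations_applied` flag is set.
#' @export
apply_mutations <- function(record) {
  stopifnot(inherits(record, "affinity_record"))
  if (isTRUE(record$mutations_applied)) return(record)
  for (m in record$mutations) {
    side <-
      if (m$chain == record$chain_a) "seq_a"
      else if (m$chain == record$chain_b) "seq_b"
      else mismatch_error(record$complex_id, sprintf("chain '%s' not in record", m$chain))
    seq <- record[[side]]
    if (m$pos > nchar(seq))
      mismatch_error(record$complex_id,
                     sprintf("position %d beyond chain %s length %d", m$pos, m$chain, nchar(seq)))
    found <- substr(seq, m$pos, m$pos)
    if (found != m$wt)
      mismatch_error(record$complex_id,
                     sprintf("code %s expects %s at %s%d but sequence has %s",
                             format(m), m$wt, m$chain, m$pos, found))
    record[[side]] <- substitute_at(seq, m$pos, m$mut)
  }
  record$mutations_applied <- TRUE
  record
}

mismatch_error <- function(id, detail) {
  stop(structure(
    class = c("pairbind_mismatch", "error", "condition"),
    list(message = sprintf("mismatch in record '%s': %s", id, detail),
         call = NULL)))
}
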