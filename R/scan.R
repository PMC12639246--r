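#' Generate a systematic alanine scan of one sequence
#'
#' Slides a window of `patch_size` consecutive residues along the sequence
#' and replaces every residue in the window with alanine, producing one
#' variant per window start (positions `1 .. L - patch_size + 1`). Windows
#' that are already poly-alanine yield a variant identical to the wild type;
#' these are retained and flagged so downstream scoring can short-circuit
#' them to a zero affinity change.
#'
#' @param seq wild-type amino-acid string.
#' @param patch_size number of consecutive residues replaced per variant
#'   (typically 1, 2, 5 or 10; any value in `1..nchar(seq)` is accepted).
#' @return a `scan_variants` data.frame with columns `start` (1-based window
#'   start), `patch_size`, `mutated_seq` and `identical_to_wild_type`; the
#'   wild-type sequence is kept in the `wild_type` attribute. Covered
#'   positions of a variant are `start .. start + patch_size - 1`.
#' @examples
#' generate_scan("MKV", 1)$mutated_seq  # "AKV" "MAV" "MKA"
#' @export
generate_scan <- function(seq, patch_size) {
  if (!is_valid_seq(seq)) stop("seq must be a non-empty amino-acid string")
  L <- nchar(seq)
  patch_size <- as.integer(patch_size)
  if (patch_size < 1L || patch_size > L)
    stop(sprintf("patch_size must be in 1..%d (sequence length), got %d", L, patch_size))
  starts <- seq_len(L - patch_size + 1L)
  poly_a <- strrep("A", patch_size)
  variants <- vapply(starts, function(s) {
    out <- seq
    substr(out, s, s + patch_size - 1L) <- poly_a
    out
  }, character(1))
  structure(
    data.frame(start = starts, patch_size = patch_size,
               mutated_seq = variants,
               identical_to_wild_type = variants == seq,
               stringsAsFactors = FALSE),
    wild_type = seq, class = c("scan_variants", "data.frame"))
}

#' Plan of alanine scans over a sequence pair
#'
#' @param seq_a,seq_b the wild-type chain sequences.
#' @param chains which partner(s) to scan: `"A"`, `"B"` or `"both"`
#'   (default): while one chain is scanned the other is held fixed.
#' @param patch_sizes integer vector of window sizes.
#' @return a `scan_plan` object.
#' @export
scan_plan <- function(seq_a, seq_b, chains = "both", patch_sizes = c(1, 2, 5, 10)) {
  chains <- match.arg(chains, c("both", "A", "B"))
  stopifnot(is_valid_seq(seq_a), is_valid_seq(seq_b), length(patch_sizes) >= 1)
  patch_sizes <- as.integer(patch_sizes)
  scanned <- if (chains == "both") c("A", "B") else chains
  for (ch in scanned) {
    L <- nchar(if (ch == "A") seq_a else seq_b)
    if (any(patch_sizes > L))
      stop(sprintf("patch size %d exceeds chain %s length %d",
                   max(patch_sizes), ch, L))
  }
  structure(list(seq_a = seq_a, seq_b = seq_b, chains = scanned,
                 patch_sizes = patch_sizes),
            class = "scan_plan")
}

#' Expand a scan plan into scoring jobs
#'
#' Enumerates every (mutated pair, variant) combination the plan implies:
#' for each scanned chain and each patch size, all window starts of
#' [generate_scan()], with the partner chain unaltered. The total number of
#' rows is the sum over scanned chains and patch sizes of
#' `L - patch_size + 1`.
#'
#' @param plan a [scan_plan()] (or a list with `seq_a`, `seq_b`; `chains`
#'   and `patch_sizes` may then be supplied directly).
#' @param ... passed to [scan_plan()] when `plan` is a bare sequence pair.
#' @return data.frame with columns `chain`, `start`, `patch_size`, `seq_a`,
#'   `seq_b` (the pair with the variant substituted in) and
#'   `identical_to_wild_type`.
#' @export
expand_plan <- function(plan, ...) {
  if (!inherits(plan, "scan_plan"))
    plan <- scan_plan(plan$seq_a, plan$seq_b, ...)
  jobs <- list()
  for (ch in plan$chains) {
    wild <- if (ch == "A") plan$seq_a else plan$seq_b
    for (p in plan$patch_sizes) {
      sc <- generate_scan(wild, p)
      jobs[[length(jobs) + 1L]] <- data.frame(
        chain = ch, start = sc$start, patch_size = p,
        seq_a = if (ch == "A") sc$mutated_seq else plan$seq_a,
        seq_b = if (ch == "B") sc$mutated_seq else plan$seq_b,
        identical_to_wild_type = sc$identical_to_wild_type,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, jobs)
  rownames(out) <- NULL
  out
}
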