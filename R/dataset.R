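#' Read a SKEMPI-style affinity table
#'
#' Reads a CSV/TSV mutation table into the standardized three-column form
#' used by [build_dataset()]: `complex` (e.g. `"1CSE_E_I"`), `mutations`
#' (comma-separated mutation codes, empty for wild type) and `kd` (molar).
#' Column names default to the SKEMPI 2.0 headers.
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (`.csv` comma, otherwise tab) unless `sep` is given.
#' @param col_complex,col_mutations,col_kd column names in the input file.
#' @param sep field separator override.
#' @return data.frame with columns `complex`, `mutations`, `kd`.
#' @export
read_skempi_table <- function(path,
                              col_complex = "#Pdb",
                              col_mutations = "Mutation(s)_cleaned",
                              col_kd = "Affinity_mut (M)",
                              sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.delim(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
  for (cn in c(col_complex, col_mutations, col_kd))
    if (!cn %in% names(tab))
      stop(sprintf("column '%s' not found in %s", cn, path))
  data.frame(complex = as.character(tab[[col_complex]]),
             mutations = as.character(tab[[col_mutations]]),
             kd = suppressWarnings(as.numeric(tab[[col_kd]])),
             stringsAsFactors = FALSE)
}

# canonical deduplication key: the pair is unordered (the Siamese model is
# order-symmetric), so each side is serialized as mutated-sequence plus its
# sorted mutation codes and the two sides are sorted before joining
dedup_key <- function(seq_a, seq_b, mutations) {
  codes <- vapply(mutations, format, character(1))
  paste(paste(sort(c(seq_a, seq_b)), collapse = "|"),
        paste(sort(codes), collapse = ","), sep = "|")
}

#' Build the filtered, deduplicated, split training corpus
#'
#' Runs the full preparation pipeline on a raw affinity table:
#' \enumerate{
#'   \item drop rows lacking usable affinity data (`kd` missing, non-finite
#'     or non-positive);
#'   \item resolve chain sequences, parse mutation codes and apply them,
#'     dropping any row whose code does not verify against the sequence
#'     (wrong wild-type residue, out-of-range position, unknown chain,
#'     malformed code) — the "mismatch" class;
#'   \item deduplicate on the unordered pair of mutated sequences plus the
#'     sorted mutation-code set, keeping the first occurrence;
#'   \item compute the affinity label from `kd` via [kd_to_affinity_score()];
#'   \item shuffle with `seed` and split `floor(split_fraction * n)` records
#'     into training, the remainder into validation.
#' }
#' Every removal is counted in the provenance log, and removals plus
#' retained records always sum to the input row count.
#'
#' @param table data.frame from [read_skempi_table()] (columns `complex`,
#'   `mutations`, `kd`), or a path to such a file.
#' @param sequences named character vector of chain sequences keyed
#'   `"PDBID_CHAIN"` (e.g. `"1CSE_E"`), as returned by
#'   [read_chain_sequences()].
#' @param split_fraction fraction of retained records used for training.
#' @param seed RNG seed for the shuffle; identical seeds give identical
#'   splits.
#' @return a `processed_dataset`: list with `records` (data.frame:
#'   `complex_id`, `seq_a`, `seq_b`, `mutations`, `kd`, `label`),
#'   `train_idx`, `val_idx`, and `provenance` (named removal counts).
#' @export
build_dataset <- function(table, sequences, split_fraction = 0.7, seed = 42) {
  if (is.character(table) && length(table) == 1L) table <- read_skempi_table(table)
  stopifnot(is.data.frame(table),
            all(c("complex", "mutations", "kd") %in% names(table)),
            split_fraction > 0, split_fraction < 1)
  n_input <- nrow(table)

  prov <- c(input = n_input, missing_affinity = 0L, mismatch = 0L,
            duplicate = 0L, retained = 0L)
  recs <- vector("list", n_input)
  keys <- character(n_input)
  keep <- logical(n_input)

  for (i in seq_len(n_input)) {
    kd <- table$kd[i]
    if (!is.finite(kd) || kd <= 0) {
      prov["missing_affinity"] <- prov["missing_affinity"] + 1L
      next
    }
    rec <- tryCatch({
      parts <- strsplit(table$complex[i], "_", fixed = TRUE)[[1]]
      if (length(parts) != 3L || nchar(parts[2]) != 1L || nchar(parts[3]) != 1L)
        mismatch_error(table$complex[i], "complex id is not of the form PDB_A_B")
      pdb <- parts[1]; ca <- parts[2]; cb <- parts[3]
      sa <- sequences[paste(pdb, ca, sep = "_")]
      sb <- sequences[paste(pdb, cb, sep = "_")]
      if (is.na(sa) || is.na(sb))
        mismatch_error(table$complex[i], "chain sequence not resolvable")
      codes <- table$mutations[i]
      codes <- if (is.na(codes) || !nzchar(codes)) character(0)
               else strsplit(codes, ",", fixed = TRUE)[[1]]
      muts <- tryCatch(lapply(trimws(codes), parse_mutation_code),
                       error = function(e) mismatch_error(table$complex[i], conditionMessage(e)))
      apply_mutations(affinity_record(table$complex[i], ca, cb,
                                      unname(sa), unname(sb), muts, kd = kd))
    }, pairbind_mismatch = function(e) NULL)
    if (is.null(rec)) {
      prov["mismatch"] <- prov["mismatch"] + 1L
      next
    }
    recs[[i]] <- rec
    keys[i] <- dedup_key(rec$seq_a, rec$seq_b, rec$mutations)
    keep[i] <- TRUE
  }

  idx <- which(keep)
  dup <- duplicated(keys[idx])
  prov["duplicate"] <- sum(dup)
  idx <- idx[!dup]
  prov["retained"] <- length(idx)
  if (length(idx) == 0L) stop("no records retained after filtering")

  records <- do.call(rbind, lapply(recs[idx], function(r) {
    data.frame(complex_id = r$complex_id, seq_a = r$seq_a, seq_b = r$seq_b,
               mutations = paste(vapply(r$mutations, format, character(1)),
                                 collapse = ","),
               kd = r$kd, label = r$label, stringsAsFactors = FALSE)
  }))
  rownames(records) <- NULL

  sp <- split_indices(nrow(records), split_fraction, seed)
  structure(list(records = records, train_idx = sp$train, val_idx = sp$val,
                 provenance = prov, split_fraction = split_fraction, seed = seed),
            class = "processed_dataset")
}

#' Reproducible train/validation split
#'
#' Uniform random shuffle; `floor(fraction * n)` indices go to training and
#' the remainder to validation. No stratification is applied.
#'
#' @param n number of records.
#' @param fraction training fraction in (0, 1).
#' @param seed RNG seed.
#' @return list with sorted integer vectors `train` and `val`.
#' @export
split_indices <- function(n, fraction = 0.7, seed = 42) {
  stopifnot(n >= 1, fraction > 0, fraction < 1)
  n_train <- floor(fraction * n)
  perm <- withr_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[setdiff(seq_len(n), seq_len(n_train))]))
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.processed_dataset <- function(x, ...) {
  cat(sprintf("<processed_dataset: %d records (%d train / %d validation)>\n",
              nrow(x$records), length(x$train_idx), length(x$val_idx)))
  cat("provenance:", paste(names(x$provenance), x$provenance, sep = "=",
                           collapse = ", "), "\n")
  invisible(x)
}

#' Write a processed dataset to disk
#'
#' Writes the records as TSV (with a `split` column marking train/val) and
#' the provenance log as JSON alongside it.
#'
#' @param dataset a `processed_dataset`.
#' @param path output TSV path; the provenance log goes to
#'   `<path>.provenance.json`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "processed_dataset"))
  rec <- dataset$records
  rec$split <- ifelse(seq_len(nrow(rec)) %in% dataset$train_idx, "train", "val")
  write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(dataset$provenance),
                       paste0(path, ".provenance.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read chain sequences from FASTA or PDB files
#'
#' Builds the named sequence vector consumed by [build_dataset()]. FASTA
#' headers must be (or start with) `PDBID_CHAIN` tokens. For PDB files the
#' chain sequences are extracted from the coordinate records in order of
#' residue appearance (one entry per `PDBID_CHAIN`).
#'
#' @param fasta character vector of FASTA paths.
#' @param pdb character vector of PDB paths (basename without extension is
#'   used as the PDB id).
#' @return named character vector of sequences.
#' @export
read_chain_sequences <- function(fasta = character(0), pdb = character(0)) {
  out <- character(0)
  for (f in fasta) {
    fa <- bio3d::read.fasta(f)
    seqs <- apply(fa$ali, 1, function(r) paste(r[r != "-"], collapse = ""))
    ids <- vapply(strsplit(rownames(fa$ali), "\\s+"), `[`, character(1), 1)
    names(seqs) <- ids
    out <- c(out, toupper(seqs))
  }
  for (p in pdb) {
    id <- sub("\\.(pdb|ent)$", "", basename(p), ignore.case = TRUE)
    cx <- read_complex(p, complex_id = id)
    for (ch in names(cx$chains))
      out[paste(id, ch, sep = "_")] <- cx$chains[[ch]]$sequence
  }
  out
}
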