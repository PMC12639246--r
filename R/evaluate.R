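#' Score an alanine scan with a fitted model
#'
#' Predicts the wild-type pair affinity once, predicts every scan variant,
#' and converts the window-level affinity drops into per-residue ddG scores:
#' \deqn{\Delta\Delta G = \hat{y}(\mathrm{wild}) - \hat{y}(\mathrm{variant}),}
#' so positive values mean the mutation weakened predicted binding. For
#' patch sizes above 1 each residue is covered by several windows; its score
#' is the maximum (default) or mean of the covering windows' ddG. Variants
#' flagged identical to the wild type are scored exactly 0 without a model
#' call.
#'
#' @param model an [affinity_model()] fit, or any scoring function
#'   `function(seq_a, seq_b)` returning a single affinity score (useful for
#'   plugging in reference oracles).
#' @param seq_a,seq_b wild-type sequence pair.
#' @param patch_sizes alanine patch sizes to scan (any of 1, 2, 5, 10, ...).
#' @param chains `"both"` (default), `"A"` or `"B"`.
#' @param attribution how window ddG maps to residues for patch > 1:
#'   `"max"` (peak disruption, default) or `"mean"`.
#' @param chunked use [chunked_predict()] for every prediction.
#' @return a `residue_scores` data.frame: `chain`, `position`, `patch_size`,
#'   `ddG`; the wild-type predicted score is kept in the `wild_score`
#'   attribute.
#' @export
score_scan <- function(model, seq_a, seq_b, patch_sizes = 1, chains = "both",
                       attribution = c("max", "mean"), chunked = FALSE) {
  stopifnot(inherits(model, "affinity_model") || is.function(model))
  attribution <- match.arg(attribution)
  predict1 <- if (is.function(model)) model
    else function(sa, sb)
      if (chunked) chunked_predict(model, sa, sb) else predict_pair(model, sa, sb)
  wild <- predict1(seq_a, seq_b)
  jobs <- expand_plan(scan_plan(seq_a, seq_b, chains, patch_sizes))
  jobs$ddG <- 0
  todo <- !jobs$identical_to_wild_type
  jobs$ddG[todo] <- wild - vapply(which(todo), function(i)
    predict1(jobs$seq_a[i], jobs$seq_b[i]), numeric(1))

  out <- list()
  for (ch in unique(jobs$chain)) {
    L <- nchar(if (ch == "A") seq_a else seq_b)
    for (p in unique(jobs$patch_size)) {
      w <- jobs[jobs$chain == ch & jobs$patch_size == p, , drop = FALSE]
      score <- vapply(seq_len(L), function(r) {
        cover <- w$start >= max(1L, r - p + 1L) & w$start <= min(r, L - p + 1L)
        if (attribution == "max") max(w$ddG[cover]) else mean(w$ddG[cover])
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        chain = ch, position = seq_len(L), patch_size = p, ddG = score,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, wild_score = wild,
            class = c("residue_scores", "data.frame"))
}

#' Rank scanned residues by predicted affinity drop
#'
#' Descending ddG ("highest drop in binding energy" first); ties are broken
#' deterministically by chain label then ascending residue position. By
#' default residues of both chains are pooled into one ranking per complex.
#'
#' @param scores a `residue_scores` data.frame (one patch size; subset
#'   first or pass `patch_size`).
#' @param patch_size optional patch size to subset.
#' @param per_chain rank each chain separately instead of pooling.
#' @return the reordered data.frame (or a list of them when `per_chain`).
#' @export
rank_residues <- function(scores, patch_size = NULL, per_chain = FALSE) {
  stopifnot(is.data.frame(scores), nrow(scores) > 0)
  if (!is.null(patch_size)) scores <- scores[scores$patch_size == patch_size, ]
  if (length(unique(scores$patch_size)) > 1L)
    stop("scores contain several patch sizes; pass patch_size to select one")
  if (per_chain)
    return(lapply(split(scores, scores$chain), rank_residues))
  out <- scores[order(-scores$ddG, scores$chain, scores$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

truth_positions <- function(truth, chain_labels = c("A", "B")) {
  if (inherits(truth, "interface_set")) {
    do.call(rbind, lapply(seq_along(truth$sets), function(i) {
      idx <- truth$sets[[i]]
      if (length(idx) == 0L) return(NULL)
      data.frame(chain = chain_labels[i], position = idx,
                 stringsAsFactors = FALSE)
    }))
  } else {
    stopifnot(is.data.frame(truth), all(c("chain", "position") %in% names(truth)))
    truth
  }
}

#' N-factor success of a residue ranking
#'
#' Evaluates how well a ranking recovers the true interface: with `n` true
#' interface residues, the top `k = N * n` ranked positions are examined and
#' every true residue found among them counts as a hit;
#' `success_rate = 100 * hits / n`. For a complex with `n = 20` the rankings
#' examined at N = 1, 2, 3 are the top 20, 40 and 60 positions.
#'
#' @param ranking ranked `residue_scores` from [rank_residues()].
#' @param truth an `interface_set` or a data.frame with `chain` and
#'   `position`; chain labels must match the ranking's (`"A"`/`"B"` scan
#'   labels map to the structure's first/second chain).
#' @param N the multiplier (1, 2, 3, ...).
#' @param complex_id identifier carried into the result.
#' @return an `nfactor_result`: list with `complex_id`, `n`, `N`, `k`,
#'   `hits` and `success_rate` (percent).
#' @export
n_factor_success <- function(ranking, truth, N, complex_id = NULL) {
  stopifnot(N >= 1)
  tp <- truth_positions(truth)
  if (is.null(tp) || nrow(tp) == 0L)
    stop("empty interface truth: the N-factor metric is undefined for n = 0")
  n <- nrow(unique(tp[, c("chain", "position")]))
  k <- as.integer(N * n)
  top <- head(ranking, k)
  hits <- nrow(merge(unique(tp[, c("chain", "position")]),
                     top[, c("chain", "position")]))
  structure(list(complex_id = complex_id, n = n, N = N, k = k, hits = hits,
                 success_rate = 100 * hits / n),
            class = "nfactor_result")
}

#' @export
print.nfactor_result <- function(x, ...) {
  cat(sprintf("<N-factor %g%s: n=%d, k=%d, hits=%d, success %.1f%%>\n",
              x$N, if (is.null(x$complex_id)) "" else paste0(" (", x$complex_id, ")"),
              x$n, x$k, x$hits, x$success_rate))
  invisible(x)
}

#' Classify scan mutations as stabilizing / destabilizing / neutral
#'
#' A mutation is destabilizing when its ddG exceeds `tau` (predicted binding
#' weakened), stabilizing when below `-tau`, neutral otherwise. The
#' threshold `tau` is reported alongside the fractions, which always sum
#' to 1.
#'
#' @param scores a `residue_scores` data.frame (or any data.frame with a
#'   `ddG` column).
#' @param tau neutrality threshold in kcal/mol (default 0.05).
#' @return named numeric vector `stabilizing`, `destabilizing`, `neutral`
#'   (fractions), with `tau` as an attribute.
#' @export
classify_mutations <- function(scores, tau = 0.05) {
  stopifnot(is.data.frame(scores), nrow(scores) > 0, "ddG" %in% names(scores),
            tau >= 0)
  d <- scores$ddG
  out <- c(stabilizing = mean(d < -tau),
           destabilizing = mean(d > tau),
           neutral = mean(abs(d) <= tau))
  attr(out, "tau") <- tau
  out
}

#' Aggregate N-factor results into mean success rates
#'
#' Unweighted mean of per-complex success rates within each group (the
#' per-complex averaging behind a model-by-N heat map summary).
#'
#' @param results list of `nfactor_result` objects or a data.frame with a
#'   `success_rate` column plus grouping columns.
#' @param by character vector of grouping column names (default `"N"`).
#' @return data.frame of group means with column `mean_success_rate`.
#' @export
aggregate_success <- function(results, by = "N") {
  if (!is.data.frame(results)) {
    stopifnot(length(results) > 0)
    results <- do.call(rbind, lapply(results, function(r)
      data.frame(complex_id = if (is.null(r$complex_id)) NA_character_ else r$complex_id,
                 n = r$n, N = r$N, k = r$k, hits = r$hits,
                 success_rate = r$success_rate, stringsAsFactors = FALSE)))
  }
  stopifnot(nrow(results) > 0, all(by %in% names(results)))
  out <- aggregate(results["success_rate"], results[by], mean)
  names(out)[names(out) == "success_rate"] <- "mean_success_rate"
  out
}
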