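#' Convert a dissociation constant to a binding-strength score
#'
#' Maps an equilibrium dissociation constant \eqn{K_D} (molar) to the
#' regression target used throughout the package: the magnitude of the Gibbs
#' free energy of binding in kcal/mol,
#' \deqn{|{-\Delta G}| = |RT \ln K_D| / 1000,}
#' with \eqn{T = 298} K and \eqn{R = 1.9872} cal mol\eqn{^{-1}} K\eqn{^{-1}}.
#' Tighter binders (smaller \eqn{K_D}) receive larger scores; a complex with
#' \eqn{K_D = 1} M scores exactly 0. The positive-magnitude convention keeps
#' the label compatible with the model's rectified (non-negative) output and
#' with the 5-15 kcal/mol range typical of measured complexes.
#'
#' @param kd numeric vector of dissociation constants in molar units; all
#'   values must be finite and strictly positive.
#' @param record_id optional identifier(s) used in error messages when a
#'   value is invalid.
#' @return numeric vector of non-negative scores in kcal/mol.
#' @examples
#' kd_to_affinity_score(1)      # 0
#' kd_to_affinity_score(1e-9)   # ~12.27 kcal/mol, nanomolar binder
#' @export
kd_to_affinity_score <- function(kd, record_id = NULL) {
  if (!is.numeric(kd)) stop("kd must be numeric")
  bad <- !is.finite(kd) | kd <= 0
  if (any(bad)) {
    id <- if (is.null(record_id)) which(bad)[1L] else record_id[which(bad)[1L]]
    stop(sprintf("non-positive or non-finite K_D for record '%s'", id))
  }
  abs(298 * 1.9872 * log(kd) / 1000)
}

# inverse of kd_to_affinity_score on the tight-binding branch (kd <= 1 M);
# used by the synthetic fixture generator so labels round-trip through Eq. 1
affinity_score_to_kd <- function(score) {
  stopifnot(all(is.finite(score)), all(score >= 0))
  exp(-score * 1000 / (298 * 1.9872))
}
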