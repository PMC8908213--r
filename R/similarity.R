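#' Phrase-to-feature similarity measures
#'
#' The degree of association between a candidate phrase and an ontology class
#' is a weighted sum of similarities between the phrase and the class's
#' textual features. Four variants are provided, from plain term overlap to a
#' dependency-level-weighted score, plus a dedicated measure for the entity
#' description feature. All use set semantics on terms: a term is either
#' shared or not, regardless of multiplicity.
#'
#' * `sim_coverage(P, F)`: `|P intersect F| / |F|`.
#' * `sim_length_norm(P, F)`: the overlap count divided by
#'   `|F| + ln(max(1, |P| - |F|))`, damping long phrases that trivially cover
#'   a short feature while reducing exactly to `sim_coverage` whenever
#'   `|P| <= |F|`.
#' * `sim_dependency(...)`: additionally weights each shared term by how
#'   central it is in the phrase's and feature's dependency trees; a term at
#'   dependency level `dl` (depth + 1; level 1 is the head) contributes
#'   `ln(max(k1, |F| + k1 - max(dl_tp, dl_tf)))`, normalized by
#'   `(1 + ln(max(1, |P| - |F|)) / |F|) * ln((|F| + k2)!)`. Heads contribute
#'   more than modifiers; an exact match with chain dependencies scores 1.
#' * `sim_description(...)`: overlap with the pooled description terms of the
#'   entities a class annotates, smoothed by phrase length and by the total
#'   description term count `te_a`, and boosted by how many entities the
#'   class annotates (`te_o`).
#'
#' @param p Character vector: the candidate phrase's terms.
#' @param f Character vector: the feature's terms (must be non-empty).
#' @param dl_tp Integer vector of dependency levels for `p` (parallel to `p`).
#' @param dl_tf Integer vector of dependency levels for `f` (parallel to `f`).
#' @param k1,k2 Integer smoothing constants; `k1 >= 2`, `k2 >= 1`.
#' @param desc_terms Character vector: pooled description terms for a class.
#' @param te_a Total number of description terms appearing with the class.
#' @param te_o Number of entities annotated by the class.
#' @param teo_in_denominator If `TRUE`, the `(1 + ln(1 + te_o))` factor
#'   divides instead of multiplies (the alternative reading of the
#'   description similarity; the default multiplies).
#' @return A non-negative finite numeric scalar.
#' @name similarity
NULL

.check_feature <- function(f) {
  if (length(f) == 0L) {
    stop("feature has no terms; similarity is undefined for |F| == 0", call. = FALSE)
  }
}

#' @rdname similarity
#' @export
sim_coverage <- function(p, f) {
  .check_feature(f)
  length(intersect(p, f)) / length(f)
}

#' @rdname similarity
#' @export
sim_length_norm <- function(p, f) {
  .check_feature(f)
  overlap <- length(intersect(p, f))
  overlap / (length(f) + log(max(1, length(p) - length(f))))
}

#' @rdname similarity
#' @export
sim_dependency <- function(p, f, dl_tp, dl_tf, k1 = 2L, k2 = 1L) {
  .check_feature(f)
  stopifnot(k1 >= 2, k2 >= 1, length(dl_tp) == length(p), length(dl_tf) == length(f))
  shared <- intersect(p, f)
  if (!length(shared)) return(0)
  nf <- length(f)
  np <- length(p)
  denom <- (1 + log(max(1, np - nf)) / nf) * lfactorial(nf + k2)
  total <- 0
  for (t in shared) {
    # a term may occur several times; take its most central occurrence
    dp <- min(dl_tp[p == t])
    df <- min(dl_tf[f == t])
    total <- total + log(max(k1, nf + k1 - max(dp, df)))
  }
  total / denom
}

#' @rdname similarity
#' @export
sim_description <- function(p, desc_terms, te_a, te_o, teo_in_denominator = FALSE) {
  overlap <- length(intersect(p, desc_terms))
  if (!overlap) return(0)
  np <- length(p)
  boost <- 1 + log(1 + te_o)
  base <- (1 + log(np)) * (1 + log(1 + te_a))
  if (teo_in_denominator) overlap / (base * boost) else overlap * boost / base
}
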