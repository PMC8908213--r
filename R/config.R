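#' Annotator configuration
#'
#' Bundles the tunable parameters of the phrase annotator and SPARQL
#' composer. The feature multipliers weight the per-feature similarities in
#' the degree of association: `alpha` (preferred label), `beta` (synonym),
#' `gamma` (definition), `delta` (parent label) and `theta` (entity
#' description). Defaults are the configuration reported to work best on
#' repository-scale data: 3.0, 3.0, 0.0, 0.0, 0.38 with dependency levels on
#' and preferred-label distribution (WPL) on.
#'
#' @param alpha,beta,gamma,delta,theta Non-negative feature multipliers.
#' @param k1 Dependency-level smoothing constant, integer `>= 2`.
#' @param k2 Factorial smoothing constant, integer `>= 1`.
#' @param tau Association filtering threshold (`>= 0`). The default `NULL`
#'   resolves to half the theoretical per-feature maximum under the active
#'   multipliers, i.e. `0.5 * max(alpha, beta, gamma, delta, theta)`, since
#'   every per-feature similarity equals 1 for an exact match.
#' @param wpl Distribute the preferred label into the other features at index
#'   build time (mitigates empty features).
#' @param dep Use dependency-level similarity ([sim_dependency()]); when
#'   `FALSE`, the length-normalized overlap ([sim_length_norm()]) is used.
#' @param parser Name of the parser adapter: `"builtin"` (chunker),
#'   `"builtin-ner"` (mock NER), `"builtin-xner"` (mock NER with context
#'   phrase extension), or any name registered via
#'   [register_parser_adapter()].
#' @param stopwords Terms ignored during matching (empty by default).
#' @param desc_teo_denominator Alternative reading of the description
#'   similarity; see [sim_description()].
#' @param max_combinations Cap on enumerated class combinations in the
#'   composer; lowest-scoring combinations are pruned first.
#' @return An object of class `annotator_config`.
#' @export
annotator_config <- function(alpha = 3.0, beta = 3.0, gamma = 0.0, delta = 0.0,
                             theta = 0.38, k1 = 2L, k2 = 1L, tau = NULL,
                             wpl = TRUE, dep = TRUE, parser = "builtin",
                             stopwords = character(0),
                             desc_teo_denominator = FALSE,
                             max_combinations = 64L) {
  stopifnot(
    alpha >= 0, beta >= 0, gamma >= 0, delta >= 0, theta >= 0,
    k1 >= 2, k2 >= 1, max_combinations >= 1
  )
  if (is.null(tau)) tau <- 0.5 * max(alpha, beta, gamma, delta, theta)
  stopifnot(tau >= 0)
  structure(
    list(
      alpha = alpha, beta = beta, gamma = gamma, delta = delta, theta = theta,
      k1 = as.integer(k1), k2 = as.integer(k2), tau = tau,
      wpl = isTRUE(wpl), dep = isTRUE(dep), parser = parser,
      stopwords = stopwords,
      desc_teo_denominator = isTRUE(desc_teo_denominator),
      max_combinations = as.integer(max_combinations)
    ),
    class = "annotator_config"
  )
}

#' Read an annotator configuration from a YAML key-value file
#'
#' Recognized keys: `alpha`, `beta`, `gamma`, `delta`, `theta`, `k1`, `k2`,
#' `tau`, `wpl`, `dep`, `parser`, `stopwords`, `desc_teo_denominator`,
#' `max_combinations`. Missing keys take the [annotator_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return An `annotator_config`.
#' @export
read_annotator_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(annotator_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(annotator_config, vals)
}

#' @export
print.annotator_config <- function(x, ...) {
  cat("Annotator configuration\n")
  cat(sprintf("  multipliers: alpha=%g beta=%g gamma=%g delta=%g theta=%g\n",
              x$alpha, x$beta, x$gamma, x$delta, x$theta))
  cat(sprintf("  k1=%d k2=%d tau=%g\n", x$k1, x$k2, x$tau))
  cat(sprintf("  wpl=%s dep=%s parser=%s\n", x$wpl, x$dep, x$parser))
  invisible(x)
}
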