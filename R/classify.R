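#' Interaction-call values
#'
#' The four biological interaction types plus two artifact states:
#' * `degradation` — miRNA anti-correlated with its target gene: the bound
#'   transcript is deadenylated and decays. Pairs whose gene and protein are
#'   also anti-correlated are kept in this class, because transcript levels
#'   are known to be imperfect proxies for protein abundance.
#' * `inhibition` — translation inhibition: the transcript persists (miRNA
#'   and gene positively correlated) but protein output drops (gene and
#'   protein anti-correlated). Detectable only with protein data.
#' * `no_interaction` — all profiles positively correlated; no regulatory
#'   signature.
#' * `no_interaction_star` — typing limited by missing protein data (miRNA
#'   and gene positively correlated, no protein assay to separate
#'   inhibition from no interaction).
#' * `no_evidence` — a required association test not significant.
#' * `untestable` — degenerate input (constant profile / too few samples).
#' @export
interaction_calls <- c("degradation", "inhibition", "no_interaction",
                       "no_interaction_star", "no_evidence", "untestable")

#' Classification configuration
#'
#' @param alpha significance threshold on the (possibly adjusted) p-values
#'   (default 0.05).
#' @param mt_correction multiple-testing correction applied per test family
#'   before classification: `"none"` (default) or `"bh"`
#'   (Benjamini-Hochberg).
#' @param require_both_significant when protein data exists, require both
#'   the miRNA-gene and gene-protein tests to pass the gate (default TRUE);
#'   if FALSE a significant miRNA-gene test with a non-significant
#'   gene-protein test falls back to the protein-absent branch.
#' @return list of class `classification_config`.
#' @export
classification_config <- function(alpha = 0.05,
                                  mt_correction = c("none", "bh"),
                                  require_both_significant = TRUE) {
  mt_correction <- match.arg(mt_correction)
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  structure(list(alpha = alpha, mt_correction = mt_correction,
                 require_both_significant = isTRUE(require_both_significant)),
            class = "classification_config")
}

#' Classify one validated pair into an interaction type
#'
#' Maps the signed miRNA-gene (`mg`) and gene-protein (`gp`) association
#' results of a validated pair to an interaction call:
#'
#' | mg sign | gp sign  | call                |
#' |---------|----------|---------------------|
#' | negative| positive | degradation         |
#' | negative| negative | degradation         |
#' | positive| negative | inhibition          |
#' | positive| positive | no_interaction      |
#' | negative| absent   | degradation         |
#' | positive| absent   | no_interaction_star |
#'
#' applied only when the required tests are significant at `alpha`; any
#' required non-significant test gives `no_evidence`, and a degenerate input
#' gives `untestable`. A sign of exactly zero is treated as non-significant.
#'
#' @param mg `pair_association` for gene ~ miRNA (required).
#' @param gp `pair_association` for protein ~ gene, or NULL when no protein
#'   data is available.
#' @param config a [classification_config()].
#' @return One of [interaction_calls].
#' @export
classify_interaction <- function(mg, gp = NULL, config = classification_config()) {
  stopifnot(inherits(mg, "pair_association"))
  if (mg$untestable || (!is.null(gp) && gp$untestable)) return("untestable")
  sig <- function(pa) !is.na(pa$p_value) && pa$p_value <= config$alpha &&
    pa$sign != "zero"
  if (!sig(mg)) return("no_evidence")
  gp_usable <- !is.null(gp)
  if (gp_usable && !sig(gp)) {
    if (config$require_both_significant) return("no_evidence")
    gp_usable <- FALSE
  }
  if (!gp_usable)
    return(if (mg$sign == "negative") "degradation" else "no_interaction_star")
  if (mg$sign == "negative") "degradation"
  else if (gp$sign == "negative") "inhibition"
  else "no_interaction"
}

#' Benjamini-Hochberg adjustment over a family of pair associations
#'
#' Adjusts the p-values of the testable pairs in one family (e.g. all
#' miRNA-gene tests of a run) by the BH step-up procedure; untestable pairs
#' pass through unchanged.
#'
#' @param pairs list of `pair_association` objects.
#' @param method `"none"` (identity) or `"bh"`.
#' @return The list with adjusted `p_value` fields.
#' @export
apply_multiple_testing <- function(pairs, method = c("none", "bh")) {
  method <- match.arg(method)
  stopifnot(length(pairs) >= 1,
            all(vapply(pairs, inherits, logical(1), "pair_association")))
  if (method == "none") return(pairs)
  p <- vapply(pairs, function(x) x$p_value, numeric(1))
  testable <- !is.na(p)
  p[testable] <- stats::p.adjust(p[testable], method = "BH")
  for (i in which(testable)) pairs[[i]]$p_value <- p[i]
  pairs
}
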