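#' The T-LGL leukemia Boolean network and its uncertainty class
#'
#' Returns the 18-gene T-cell large granular lymphocyte (T-LGL) leukemia
#' survival-signaling Boolean network (reduced form), or one of three
#' near-miss variants used as an uncertainty class of candidate regulatory
#' models:
#' \describe{
#'   \item{true}{the published rule set.}
#'   \item{v2}{the NOT-Apoptosis factor removed from the sFas and GPCR rules.}
#'   \item{v3}{the NOT-Apoptosis factor removed from the IAP and P2 rules.}
#'   \item{v4}{the top-level connective of the BID rule swapped
#'     (\code{NOT (MCL1 OR Apoptosis)} becomes \code{NOT (MCL1 AND Apoptosis)}).}
#' }
#' The mutated (cancerous) class freezes the Apoptosis node at OFF: it
#' ignores its regulating function and its noise-free update is always 0.
#'
#' @param variant one of \code{"true"}, \code{"v2"}, \code{"v3"}, \code{"v4"}.
#' @param cls \code{"healthy"} or \code{"mutated"}.
#' @return a \linkS4class{BooleanNetwork} with 18 genes.
#' @examples
#' net <- tlglNetwork("true", "healthy")
#' nGenes(net)
#' @export
tlglNetwork <- function(variant = c("true", "v2", "v3", "v4"),
                        cls = c("healthy", "mutated")) {
  variant <- match.arg(variant)
  cls <- match.arg(cls)
  path <- system.file("extdata", "tlgl",
                      sprintf("tlgl_%s_%s.bn", variant, cls),
                      package = "scPOBDS", mustWork = TRUE)
  readRules(path)
}

#' The default T-LGL uncertainty class
#'
#' Builds the \linkS4class{UncertaintyClass} used in the classification
#' experiments: the first \code{M} T-LGL variants (true, v2, v3, v4) as
#' healthy models for class 0 and their Apoptosis-frozen counterparts for
#' class 1, with uniform model priors and class-0 prior \code{p0}.
#'
#' @param M number of candidate networks per class (1..4).
#' @param p Bernoulli perturbation probability.
#' @param lambda,delta,sigma observation model parameters (scalars are
#'   recycled over the 18 genes).
#' @param noiseFamily observation noise family.
#' @param p0 prior probability of the healthy class.
#' @return an \linkS4class{UncertaintyClass}.
#' @export
tlglUncertaintyClass <- function(M = 4, p = 0.05, lambda = 10, delta = 30,
                                 sigma = 20, noiseFamily = "gaussian", p0 = 0.5) {
  variants <- c("true", "v2", "v3", "v4")
  if (!(M %in% seq_along(variants)))
    stop("M must be between 1 and 4 for the T-LGL uncertainty class")
  mk <- function(v, cls) {
    pobdsModel(tlglNetwork(v, cls), p = p, lambda = lambda, delta = delta,
               sigma = sigma, noiseFamily = noiseFamily,
               modelId = sprintf("tlgl_%s_%s", v, cls))
  }
  uncertaintyClass(models0 = lapply(variants[seq_len(M)], mk, cls = "healthy"),
                   models1 = lapply(variants[seq_len(M)], mk, cls = "mutated"),
                   p0 = p0)
}
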