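#' Closed-form HKY85 transition probabilities (equal base frequencies)
#'
#' With equal base frequencies HKY85 reduces to the two-parameter Kimura
#' model, whose transition probability matrix has three distinct entries:
#' the probability of no net change, of a transition, and of each of the
#' two possible transversions.  `d` is the expected number of
#' substitutions per site and `kappa` the transition/transversion rate
#' ratio (alpha/beta); `kappa = 1` recovers Jukes-Cantor.
#'
#' @param d Branch length(s), expected substitutions/site.
#' @param kappa Transition/transversion rate ratio.
#' @return A list with vectors `same`, `ts`, `tv` (per-target
#'   transversion probability; the total transversion probability is
#'   `2 * tv`).  `same + ts + 2 * tv = 1`.
#' @export
hky_probs <- function(d, kappa) {
  # rate matrix normalized so the expected rate is 1: beta = 2/(kappa+2)
  e1 <- exp(-4 * d / (kappa + 2))
  e2 <- exp(-2 * d * (kappa + 1) / (kappa + 2))
  list(same = 0.25 + 0.25 * e1 + 0.5 * e2,
       ts   = 0.25 + 0.25 * e1 - 0.5 * e2,
       tv   = 0.25 - 0.25 * e1)
}

#' Discrete-Gamma site-rate categories
#'
#' Equal-probability discretization of a Gamma(shape, rate = shape)
#' distribution (mean 1): category rates are the conditional means of the
#' K quantile bins, the standard scheme for among-site rate variation.
#'
#' @param alpha Gamma shape.
#' @param k Number of categories.
#' @return Numeric vector of k rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  stopifnot(alpha > 0, k >= 1)
  if (k == 1) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  # E[X | bin] via the shape+1 identity, times k for equal-probability bins
  p <- stats::pgamma(b, shape = alpha + 1, rate = alpha)
  k * diff(p)
}

# nucleotide coding: 1=A 2=G 3=C 4=T; transitions stay inside {A,G},{C,T}
NUC <- c("a", "g", "c", "t")
ts_partner <- c(2L, 1L, 4L, 3L)
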