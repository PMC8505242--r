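#' Liability-threshold parameters
#'
#' Under the liability-threshold model a binary disorder arises when a
#' standard-normal latent liability exceeds the threshold implied by the
#' population prevalence `K`. This helper bundles the quantities every
#' scale conversion needs: the threshold `t = qnorm(1 - K)`, the normal
#' density at the threshold `z = dnorm(t)`, and the sample case proportion
#' `P` (which differs from `K` in ascertained case-control samples). `t` and
#' `z` are always recomputed from `K`, never stored stale.
#'
#' @param prevalence_k population prevalence `K` in (0, 1).
#' @param case_proportion_p sample case proportion `P` in (0, 1); defaults
#'   to `K` (no ascertainment).
#' @return list of class `liability_params` with `prevalence_k`,
#'   `case_proportion_p`, `threshold_t`, `density_z`.
#' @export
liability_params <- function(prevalence_k, case_proportion_p = prevalence_k) {
  if (!(prevalence_k > 0 && prevalence_k < 1))
    stop("prevalence_k must be strictly inside (0, 1)")
  if (!(case_proportion_p > 0 && case_proportion_p < 1))
    stop("case_proportion_p must be strictly inside (0, 1)")
  t <- stats::qnorm(1 - prevalence_k)
  structure(list(
    prevalence_k = prevalence_k,
    case_proportion_p = case_proportion_p,
    threshold_t = t,
    density_z = stats::dnorm(t)
  ), class = "liability_params")
}

#' Convert observed-scale heritability to the liability scale
#'
#' Case-control samples measure heritability on the observed (0/1) scale,
#' inflated by ascertainment when cases are oversampled. The
#' ascertainment-corrected transformation is
#' \deqn{h^2_{liab} = h^2_{obs} \frac{K^2 (1-K)^2}{z^2 \, P (1-P)}}
#' with `K` the population prevalence, `P` the sample case proportion and
#' `z` the standard-normal density at the liability threshold. With `P = K`
#' it reduces to the classical `K(1-K)/z^2` correction.
#'
#' @param h2_obs observed-scale heritability (non-negative).
#' @param params a [liability_params].
#' @return liability-scale heritability.
#' @seealso [h2_liability_to_observed] for the inverse,
#'   [rescale_h2_liability] to move a liability-scale estimate between
#'   assumed prevalences.
#' @export
h2_observed_to_liability <- function(h2_obs, params) {
  stopifnot(inherits(params, "liability_params"), all(h2_obs >= 0))
  K <- params$prevalence_k
  P <- params$case_proportion_p
  z <- params$density_z
  h2_obs * K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
}

#' Convert liability-scale heritability to the observed scale
#'
#' Exact inverse of [h2_observed_to_liability].
#'
#' @param h2_liab liability-scale heritability (non-negative).
#' @param params a [liability_params].
#' @return observed-scale heritability.
#' @export
h2_liability_to_observed <- function(h2_liab, params) {
  stopifnot(inherits(params, "liability_params"), all(h2_liab >= 0))
  K <- params$prevalence_k
  P <- params$case_proportion_p
  z <- params$density_z
  h2_liab * z^2 * P * (1 - P) / (K^2 * (1 - K)^2)
}

#' Re-express a liability-scale heritability under a different prevalence
#'
#' Published liability-scale estimates depend on the population prevalence
#' assumed in the conversion. Given an estimate computed under `k_from`,
#' this backs out the observed-scale value and re-applies the
#' transformation under `k_to`. The sample case proportion cancels, so only
#' the two prevalences matter.
#'
#' @param h2_liab liability-scale estimate computed assuming `k_from`.
#' @param k_from,k_to assumed population prevalences.
#' @param case_proportion_p sample case proportion (cancels; kept for
#'   transparency).
#' @return the estimate re-expressed under prevalence `k_to`.
#' @export
rescale_h2_liability <- function(h2_liab, k_from, k_to,
                                 case_proportion_p = 0.5) {
  h2_obs <- h2_liability_to_observed(
    h2_liab, liability_params(k_from, case_proportion_p))
  h2_observed_to_liability(
    h2_obs, liability_params(k_to, case_proportion_p))
}

#' Convert observed-scale variance explained by a score to the liability scale
#'
#' Transforms the observed-scale (linear) R-squared of a polygenic score on
#' a binary phenotype to the liability scale, correcting for case-control
#' ascertainment. With threshold `t`, density `z`, mean case liability
#' `m = z/K` and
#' \deqn{C = \frac{K(1-K)}{z^2} \cdot \frac{K(1-K)}{P(1-P)}, \qquad
#'       \theta = m \frac{P-K}{1-K}\left(m \frac{P-K}{1-K} - t\right),}
#' the liability-scale value is
#' \deqn{R^2_{liab} = \frac{C \, R^2_{obs}}{1 + C \, \theta \, R^2_{obs}}.}
#' When `P = K` (no ascertainment) `theta = 0` and the expression reduces
#' to the simple `K(1-K)/z^2` rescaling.
#'
#' @param r2_obs observed-scale R-squared in `[0, 1)` (e.g. the squared
#'   correlation between the 0/1 phenotype and the score).
#' @param params a [liability_params].
#' @return liability-scale R-squared.
#' @export
r2_observed_to_liability <- function(r2_obs, params) {
  stopifnot(inherits(params, "liability_params"),
            all(r2_obs >= 0), all(r2_obs < 1))
  K <- params$prevalence_k
  P <- params$case_proportion_p
  t <- params$threshold_t
  z <- params$density_z
  m <- z / K
  C <- K * (1 - K) / z^2 * K * (1 - K) / (P * (1 - P))
  u <- m * (P - K) / (1 - K)
  theta <- u * (u - t)
  C * r2_obs / (1 + C * theta * r2_obs)
}
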