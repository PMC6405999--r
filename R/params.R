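#' Model parameters
#'
#' Bundles the three parameters of the dynamics: the cooperation benefit `b`
#' (a donor pays 1 unit, the recipient gains `b`), the selection pressure `w`
#' (payoff-to-fitness exponent, `f = exp(w * p)`; `w = 0` is neutral drift,
#' `w = Inf` the deterministic copy-the-best limit), and the mutation
#' probability `mu` per update event.
#'
#' @param b cooperation benefit, dimensionless, must exceed 1.
#' @param w selection pressure, per payoff unit, `>= 0`; `Inf` is allowed and
#'   means deterministic imitation of a maximal-payoff neighbour with uniform
#'   tie-breaking.
#' @param mu mutation probability per event, in `[0, 1]`. On a mutation event
#'   the strategy is resampled uniformly from all four strategies, including
#'   the current one, so the effective change probability is `3 * mu / 4`.
#' @return An object of class `model_params`.
#' @examples
#' model_params(b = 8, w = 1, mu = 0.001)
#' @export
model_params <- function(b, w, mu = 0.001) {
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b), b > 1,
            is.numeric(w), length(w) == 1L, !is.na(w), w >= 0,
            is.numeric(mu), length(mu) == 1L, is.finite(mu), mu >= 0, mu <= 1)
  structure(list(b = as.numeric(b), w = as.numeric(w), mu = as.numeric(mu)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("donation-game parameters: b = %g, w = %g, mu = %g\n",
              x$b, x$w, x$mu))
  invisible(x)
}
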