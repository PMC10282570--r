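#' Annual adult mortality as a function of brood size
#'
#' Having offspring raises adult mortality multiplicatively on survival:
#' `muA(B0) = 1 - (1 - muA0) * exp(-alpha * B0)`. The marginal cost of an
#' extra offspring is largest at small broods and shrinks as broods grow.
#'
#' @param B0 Brood size, non-negative; vectorized.
#' @param params An [adult_params()] object.
#' @return Mortality probability in `[muA0, 1)`, non-decreasing in `B0`.
#' @examples
#' annual_mortality(c(1, 10), adult_params(muA0 = 0.07, alpha = 0.1))
#' @export
annual_mortality <- function(B0, params) {
  stopifnot(inherits(params, "adult_params"), is.numeric(B0))
  if (any(B0 < 0)) stop("'B0' must be non-negative", call. = FALSE)
  1 - (1 - params$muA0) * exp(-params$alpha * B0)
}

#' Expected adult lifespan at a given brood size
#'
#' Survival from one breeding interval to the next is geometric, so the
#' expected number of intervals lived is `1 / muA(B0)`. Reported as a real
#' number of breeding intervals ("years" for annual breeders).
#'
#' @inheritParams annual_mortality
#' @return Expected lifespan in breeding intervals; `Inf` when mortality is 0.
#' @examples
#' expected_lifespan(5, adult_params(muA0 = 0.07, alpha = 0))  # about 14.3
#' @export
expected_lifespan <- function(B0, params) {
  mu <- annual_mortality(B0, params)
  ifelse(mu == 0, Inf, 1 / mu)
}
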