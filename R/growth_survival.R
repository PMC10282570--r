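#' Juvenile size at time t (von Bertalanffy growth)
#'
#' Size follows `dL/dt = r * (1 - L)` with `L(0) = L0`, where size is a
#' fraction of the asymptotic size, giving
#' `L(t) = 1 - (1 - L0) * exp(-r * t)`.
#'
#' @param t Time since birth (same units as `1/r`); non-negative, vectorized.
#' @param r Juvenile growth rate (time^-1), positive.
#' @param L0 Birth size as a fraction of asymptotic size, in (0, 1).
#' @return Size(s) in `[L0, 1)`, strictly increasing in `t`.
#' @examples
#' length_at_time(2, r = 0.5, L0 = 0.01)  # 1 - 0.99 * exp(-1)
#' @export
length_at_time <- function(t, r, L0) {
  stopifnot(is.numeric(t), is.numeric(r), is.numeric(L0))
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  if (any(r <= 0)) stop("'r' must be positive", call. = FALSE)
  if (any(L0 <= 0 | L0 >= 1)) stop("'L0' must lie in (0, 1)", call. = FALSE)
  1 - (1 - L0) * exp(-r * t)
}

#' Surviving juveniles at time t
#'
#' Juveniles die at instantaneous rate `muJ * (1 - L(t))`, which shrinks as
#' they grow. Integrating along the growth curve gives
#' `B(t) = B0 * exp(-muJ * (1 - L0) * (1 - exp(-r t)) / r)`.
#'
#' @param t Time since birth; non-negative, vectorized.
#' @param B0 Initial brood size (expected count), non-negative.
#' @param params A [juvenile_params()] object supplying `muJ` and `L0`.
#' @param r Effective juvenile growth rate for this brood (time^-1). Defaults
#'   to the shared-care rate `params$r0 / B0`.
#' @return Expected surviving juveniles, in `(0, B0]`, non-increasing in `t`.
#' @examples
#' p <- juvenile_params()
#' survivors_at_time(5, B0 = 3, params = p)
#' @export
survivors_at_time <- function(t, B0, params, r = params$r0 / B0) {
  stopifnot(inherits(params, "juvenile_params"), is.numeric(t), is.numeric(B0))
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  if (any(B0 < 0)) stop("'B0' must be non-negative", call. = FALSE)
  if (any(r <= 0)) stop("'r' must be positive", call. = FALSE)
  B0 * exp(-params$muJ * (1 - params$L0) * (1 - exp(-r * t)) / r)
}

#' Expected offspring surviving to maturity
#'
#' The long-time limit of [survivors_at_time()] under shared parental care,
#' where a brood of `B0` grows at rate `r0 / B0`:
#' `Binf(B0) = B0 * exp(-muJ * B0 * (1 - L0) / r0)`.
#' The value at `B0 = 0` is defined as 0 by continuity.
#'
#' @param B0 Brood size (continuous, non-negative); vectorized.
#' @param params A [juvenile_params()] object.
#' @return Expected number of offspring reaching maturity; unimodal in `B0`
#'   when `muJ > 0`.
#' @examples
#' p <- juvenile_params(r0 = 0.5, muJ = 0.2, L0 = 0.01)
#' expected_survivors(c(1, 3, 10), p)  # 0.67, 0.91, 0.19 to 2 dp
#' @export
expected_survivors <- function(B0, params) {
  stopifnot(inherits(params, "juvenile_params"), is.numeric(B0))
  if (any(B0 < 0)) stop("'B0' must be non-negative", call. = FALSE)
  B0 * exp(-params$muJ * B0 * (1 - params$L0) / params$r0)
}

#' Offspring-optimal brood size
#'
#' The brood size maximizing [expected_survivors()], ignoring any cost to
#' the parent. In closed form `B0* = r0 / (muJ * (1 - L0))` with maximum
#' `Binf* = B0* / e`.
#'
#' @param params A [juvenile_params()] object with `muJ > 0`.
#' @return A list with elements `brood_size` and `survivors`.
#' @examples
#' offspring_optimal_brood(juvenile_params())  # about 2.53 and 0.93
#' @export
offspring_optimal_brood <- function(params) {
  stopifnot(inherits(params, "juvenile_params"))
  if (params$muJ == 0)
    stop("no finite optimum: with muJ = 0 expected survivors grow without bound",
         call. = FALSE)
  b <- params$r0 / (params$muJ * (1 - params$L0))
  list(brood_size = b, survivors = b * exp(-1))
}
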