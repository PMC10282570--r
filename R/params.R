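#' Juvenile life-history parameters
#'
#' Bundles the parameters of the juvenile growth-and-survival submodel:
#' the baseline von Bertalanffy growth rate, the size-dependent juvenile
#' mortality coefficient, and birth size. Sizes are measured as a fraction
#' of the asymptotic (maturity) size, which is normalized to 1, so `L0`
#' is dimensionless and lies strictly between 0 and 1.
#'
#' @param r0 Baseline juvenile growth rate (time^-1) conferred on a brood of
#'   one; a brood of size `B0` grows at the shared rate `r0 / B0`.
#' @param muJ Juvenile mortality coefficient (time^-1); instantaneous
#'   mortality is `muJ * (1 - L)` at size `L`.
#' @param L0 Birth size as a fraction of asymptotic size.
#' @return An object of class `"juvenile_params"`.
#' @examples
#' juvenile_params()                   # baseline illustrative values
#' juvenile_params(r0 = 0.2, muJ = 0.1)
#' @export
juvenile_params <- function(r0 = 0.5, muJ = 0.2, L0 = 0.01) {
  stopifnot(is.numeric(r0), length(r0) == 1L, is.finite(r0),
            is.numeric(muJ), length(muJ) == 1L, is.finite(muJ),
            is.numeric(L0), length(L0) == 1L, is.finite(L0))
  if (r0 <= 0) stop("'r0' must be positive", call. = FALSE)
  if (muJ < 0) stop("'muJ' must be non-negative", call. = FALSE)
  if (L0 <= 0 || L0 >= 1) stop("'L0' must lie in (0, 1)", call. = FALSE)
  structure(list(r0 = r0, muJ = muJ, L0 = L0), class = "juvenile_params")
}

#' Adult survival parameters
#'
#' Intrinsic annual adult mortality and the per-offspring brood-cost
#' coefficient of the adult mortality function
#' `muA(B0) = 1 - (1 - muA0) * exp(-alpha * B0)`.
#'
#' @param muA0 Intrinsic adult mortality probability per breeding interval
#'   (the probability of dying in a year with no offspring); in `[0, 1)`.
#' @param alpha Brood-cost mortality coefficient (per offspring), `>= 0`.
#' @return An object of class `"adult_params"`.
#' @examples
#' adult_params(muA0 = 0.07, alpha = 0.1)
#' @export
adult_params <- function(muA0 = 0.07, alpha = 0) {
  stopifnot(is.numeric(muA0), length(muA0) == 1L, is.finite(muA0),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (muA0 < 0 || muA0 >= 1) stop("'muA0' must lie in [0, 1)", call. = FALSE)
  if (alpha < 0) stop("'alpha' must be non-negative", call. = FALSE)
  structure(list(muA0 = muA0, alpha = alpha), class = "adult_params")
}

#' Combined life history
#'
#' A juvenile and an adult parameter set together define the annual
#' population map; see [annual_growth_rate()].
#'
#' @param juvenile A [juvenile_params()] object.
#' @param adult An [adult_params()] object.
#' @return An object of class `"life_history"`.
#' @examples
#' life_history(juvenile_params(), adult_params(alpha = 0.5))
#' @export
life_history <- function(juvenile = juvenile_params(), adult = adult_params()) {
  if (!inherits(juvenile, "juvenile_params"))
    stop("'juvenile' must be a juvenile_params object", call. = FALSE)
  if (!inherits(adult, "adult_params"))
    stop("'adult' must be an adult_params object", call. = FALSE)
  structure(list(juvenile = juvenile, adult = adult), class = "life_history")
}

#' @export
print.juvenile_params <- function(x, ...) {
  cat("Juvenile parameters: r0 =", x$r0, "(time^-1), muJ =", x$muJ,
      "(time^-1), L0 =", x$L0, "\n")
  invisible(x)
}

#' @export
print.adult_params <- function(x, ...) {
  cat("Adult parameters: muA0 =", x$muA0, "(yr^-1), alpha =", x$alpha,
      "(per offspring)\n")
  invisible(x)
}

#' @export
print.life_history <- function(x, ...) {
  print(x$juvenile)
  print(x$adult)
  invisible(x)
}

# replace the brood-cost coefficient (and optionally muA0) without mutating
# the caller's object
.with_alpha <- function(lh, alpha, muA0 = lh$adult$muA0) {
  life_history(lh$juvenile, adult_params(muA0 = muA0, alpha = alpha))
}
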