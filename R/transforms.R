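#' Logit transform of a coverage proportion
#'
#' Maps survey coverage proportions onto the unbounded model scale. Proportions
#' of exactly 0 or 1 (possible in small strata) are clamped to `[eps, 1 - eps]`
#' before the transform so the result is always finite.
#'
#' @param p numeric vector of proportions in `[0, 1]`.
#' @param eps clamp bound, a single value in `(0, 0.5)`. Default `1e-3`.
#' @return `log(p' / (1 - p'))` where `p' = min(max(p, eps), 1 - eps)`.
#' @examples
#' logit_transform(c(0.5, 0.8))
#' logit_transform(1, eps = 0.001) # finite, log(0.999/0.001)
#' @seealso [inverse_logit()]
#' @export
logit_transform <- function(p, eps = 1e-3) {
  if (!is.numeric(p)) stop("`p` must be numeric")
  if (anyNA(p)) stop("`p` contains missing values")
  if (any(p < 0 | p > 1)) {
    stop("proportions outside [0, 1]: ",
         paste(utils::head(signif(p[p < 0 | p > 1], 4), 5L), collapse = ", "))
  }
  if (length(eps) != 1L || !is.finite(eps) || eps <= 0 || eps >= 0.5) {
    stop("`eps` must be a single value in (0, 0.5)")
  }
  pc <- pmin(pmax(p, eps), 1 - eps)
  log(pc / (1 - pc))
}

#' Inverse logit
#'
#' Back-transform from the logit model scale to a proportion in `(0, 1)`.
#'
#' @param y finite numeric vector on the logit scale.
#' @return `1 / (1 + exp(-y))`.
#' @export
inverse_logit <- function(y) {
  if (!is.numeric(y) || anyNA(y) || any(!is.finite(y))) {
    stop("`y` must be finite numeric")
  }
  stats::plogis(y)
}
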