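#' Exponentially weighted moving average smoothing
#'
#' Recursive smoother S_t = alpha * Y_t + (1 - alpha) * S_{t-1}, initialized
#' with S_1 = Y_1. Applied to refined status trajectories as the final
#' smoothing stage before decline-onset detection. `alpha = 1` is permitted as
#' a passthrough edge case.
#'
#' @param y numeric vector of observations.
#' @param alpha smoothing parameter in (0, 1]; default 0.3.
#' @return Numeric vector of smoothed values, same length as `y`.
#' @examples
#' ewma_smooth(c(0, 2), alpha = 0.5)  # -> 0 1
#' @export
ewma_smooth <- function(y, alpha = 0.3) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop("`alpha` must lie in (0, 1]")
  }
  n <- length(y)
  if (n == 0L) stop("`y` must be non-empty")
  if (anyNA(y)) stop("`y` must not contain missing values")
  # recursive filter with S_0 chosen so that S_1 = y_1 exactly
  as.numeric(stats::filter(alpha * y, 1 - alpha, method = "recursive",
                           init = y[1]))
}
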