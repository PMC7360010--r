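#' Simulate well-counter measurements of a plate
#'
#' Emulates a single-sample gamma counter: each well's true activity is
#' perturbed by multiplicative Gaussian error, `measured = truth * (1 + e)`
#' with `e ~ N(0, counter_cv)` truncated at -1 so measurements cannot go
#' negative. `counter_cv = 0` returns the truth exactly, and a true activity
#' of 0 kBq is always measured as 0 kBq.
#'
#' @param plate A [plate_spec()].
#' @param counter_cv Relative standard deviation of the counter measurement.
#' @param seed Integer seed; required when `counter_cv > 0`.
#'
#' @return A tibble with columns `well_id`, `truth_kBq`, `counter_kBq`.
#' @export
simulate_well_counter <- function(plate, counter_cv = 0, seed = NULL) {
  stopifnot(inherits(plate, "plate_spec"))
  if (counter_cv < 0) stop("counter_cv must be >= 0", call. = FALSE)
  n <- nrow(plate)
  if (counter_cv == 0 || n == 0L) {
    eps <- rep(0, n)
  } else {
    if (is.null(seed)) {
      stop("a seed is required when counter_cv > 0 (reproducibility)", call. = FALSE)
    }
    eps <- withr::with_seed(as.integer(seed), stats::rnorm(n, 0, counter_cv))
    eps <- pmax(eps, -1)
  }
  tibble::tibble(
    well_id = plate$well_id,
    truth_kBq = plate$truth_kBq,
    counter_kBq = plate$truth_kBq * (1 + eps)
  )
}
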