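# Quantile regression by exact vertex enumeration.
#
# The tau-th regression quantile minimises the pinball (check) loss
#   sum_k rho_tau(y_k - a - b x_k),  rho_tau(r) = r (tau - 1[r < 0]).
# As a linear program its optimum is attained at a vertex, i.e. at a line
# interpolating at least two data points (when x is non-degenerate). With
# the small n of site-level effect-size data, enumerating all point-pair
# lines and keeping the loss minimiser is exact and dependency-free
# (O(n^3); fine for n up to a few hundred).

#' Pinball (check) loss
#'
#' @param residuals Residuals `y - fitted`.
#' @param tau Quantile level in (0, 1).
#' @return Total pinball loss.
#' @export
pinball_loss <- function(residuals, tau) {
  if (tau <= 0 || tau >= 1) abort("`tau` must be strictly inside (0, 1).")
  sum(residuals * (tau - (residuals < 0)))
}

#' Linear quantile regression at one quantile
#'
#' Fits `y ~ a + b x` minimising the pinball loss at level `tau` by exact
#' enumeration of candidate vertex lines (every line through two data
#' points, plus horizontal lines through each point).
#'
#' @param data A data frame holding the regressor and response.
#' @param x,y Column names (strings) of regressor and response.
#' @param tau Quantile level in (0, 1).
#' @return A `quantile_fit` list: `tau`, `intercept`, `slope`, `loss`, `n`.
#' @examples
#' d <- data.frame(u = 1:5, v = 2 * (1:5))
#' quantile_fit(d, "u", "v", 0.5) # slope 2, intercept 0, loss 0
#' @export
quantile_fit <- function(data, x = "x", y = "y", tau = 0.5) {
  data <- as_tibble(data)
  xs <- data[[x]]; ys <- data[[y]]
  keep <- !is.na(xs) & !is.na(ys)
  xs <- xs[keep]; ys <- ys[keep]
  if (length(xs) < 3) abort("Need at least 3 points for a quantile fit.")
  if (length(unique(xs)) < 2) abort("Degenerate regressor: all x values equal.")
  if (tau <= 0 || tau >= 1) abort("`tau` must be strictly inside (0, 1).")
  n <- length(xs)
  best <- list(intercept = NA_real_, slope = NA_real_, loss = Inf)
  consider <- function(a, b) {
    loss <- pinball_loss(ys - a - b * xs, tau)
    if (loss < best$loss - 1e-12) best <<- list(intercept = a, slope = b, loss = loss)
  }
  # horizontal candidates (slope vertex can be degenerate)
  for (k in seq_len(n)) consider(ys[k], 0)
  idx <- combn(n, 2)
  for (c_i in seq_len(ncol(idx))) {
    i <- idx[1, c_i]; j <- idx[2, c_i]
    if (xs[i] == xs[j]) next
    b <- (ys[j] - ys[i]) / (xs[j] - xs[i])
    consider(ys[i] - b * xs[i], b)
  }
  structure(
    list(tau = tau, intercept = best$intercept, slope = best$slope,
         loss = best$loss, n = n),
    class = "quantile_fit"
  )
}

#' @export
print.quantile_fit <- function(x, ...) {
  cat(sprintf("<quantile_fit> tau=%.2f: y = %.4g + %.4g x (pinball loss %.4g, n=%d)\n",
              x$tau, x$intercept, x$slope, x$loss, x$n))
  invisible(x)
}

#' Predict from a quantile fit
#'
#' @param object A `quantile_fit`.
#' @param newdata Numeric vector of x values.
#' @param ... Ignored.
#' @return Predicted conditional quantiles.
#' @export
predict.quantile_fit <- function(object, newdata, ...) {
  object$intercept + object$slope * newdata
}

#' Quantile fits across a ladder of quantiles
#'
#' Fits [quantile_fit()] at each level of `taus` (default the 10th to 90th
#' percentile in steps of 10, the ladder used to visualise variance
#' convergence).
#'
#' @inheritParams quantile_fit
#' @param taus Quantile levels, strictly inside (0, 1), unique.
#' @return A `quantile_fits` object: list of fits plus the data range.
#' @export
quantile_fits <- function(data, x = "x", y = "y", taus = seq(0.1, 0.9, by = 0.1)) {
  taus <- sort(unique(taus))
  if (any(taus <= 0 | taus >= 1)) abort("All `taus` must be strictly inside (0, 1).")
  fits <- purrr::map(taus, ~ quantile_fit(data, x = x, y = y, tau = .x))
  xs <- data[[x]][!is.na(data[[x]]) & !is.na(data[[y]])]
  structure(
    list(fits = setNames(fits, paste0("tau_", taus)), taus = taus,
         x_range = range(xs), x = x, y = y),
    class = "quantile_fits"
  )
}

#' @export
print.quantile_fits <- function(x, ...) {
  cat(sprintf("<quantile_fits> %d quantile(s) of %s ~ %s over x in [%.3g, %.3g]\n",
              length(x$taus), x$y, x$x, x$x_range[1], x$x_range[2]))
  for (f in x$fits) print(f)
  invisible(x)
}

#' Tidy quantile-fit coefficients
#'
#' @param x A `quantile_fits` object.
#' @param ... Ignored.
#' @return Tibble `(tau, intercept, slope, loss, n)`, one row per quantile.
#' @export
tidy.quantile_fits <- function(x, ...) {
  tibble(
    tau = x$taus,
    intercept = purrr::map_dbl(x$fits, "intercept"),
    slope = purrr::map_dbl(x$fits, "slope"),
    loss = purrr::map_dbl(x$fits, "loss"),
    n = purrr::map_int(x$fits, "n")
  )
}

#' One-row summary of a quantile-fit ladder
#'
#' @param x A `quantile_fits` object.
#' @param ... Ignored.
#' @return One-row tibble with the convergence summary (see
#'   [convergence_summary()]).
#' @export
glance.quantile_fits <- function(x, ...) {
  convergence_summary(x)
}

#' Inter-quantile spread and variance convergence
#'
#' Summarises how the spread between the highest and lowest fitted quantile
#' lines changes over the regressor range: the predicted `q_hi - q_lo`
#' spread at `min(x)` and at `max(x)` and their difference. A positive
#' difference means the quantile lines converge (response variance shrinks)
#' as x increases — the signature of stress responses becoming less
#' variable with baseline network complexity.
#'
#' Raw quantile fits may cross; predictions are monotone-rearranged across
#' the tau ladder at each evaluation point before the spread is taken, so
#' the reported spread is never negative.
#'
#' @param fits A `quantile_fits` object containing at least the lowest and
#'   highest levels of interest (defaults 0.1 and 0.9).
#' @param tau_lo,tau_hi The quantile pair to contrast; defaults 0.1 / 0.9.
#' @return One-row tibble: `tau_lo`, `tau_hi`, `x_min`, `x_max`,
#'   `spread_at_min`, `spread_at_max`, `spread_difference`
#'   (`spread_at_min - spread_at_max`; positive = convergence).
#' @export
convergence_summary <- function(fits, tau_lo = 0.1, tau_hi = 0.9) {
  stopifnot(inherits(fits, "quantile_fits"))
  if (!all(c(tau_lo, tau_hi) %in% fits$taus)) {
    abort("`fits` must contain the requested tau_lo and tau_hi levels.")
  }
  spread_at <- function(x0) {
    preds <- unname(purrr::map_dbl(fits$fits, ~ predict(.x, x0)))
    preds <- sort(preds) # monotone rearrangement across the tau ladder
    preds[match(tau_hi, fits$taus)] - preds[match(tau_lo, fits$taus)]
  }
  x_min <- fits$x_range[1]; x_max <- fits$x_range[2]
  s_min <- spread_at(x_min); s_max <- spread_at(x_max)
  tibble(
    tau_lo = tau_lo, tau_hi = tau_hi, x_min = x_min, x_max = x_max,
    spread_at_min = s_min, spread_at_max = s_max,
    spread_difference = s_min - s_max
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy effect-size test results
#'
#' @param x A `nat_tests` table from [effect_size_tests()].
#' @param ... Ignored.
#' @return The underlying tibble.
#' @export
tidy.nat_tests <- function(x, ...) {
  as_tibble(unclass_first(x))
}

unclass_first <- function(x) {
  class(x) <- setdiff(class(x), c("nat_tests"))
  x
}
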