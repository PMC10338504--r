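#' Polynomial extrapolation of a vector-valued function to zero
#'
#' Neville's scheme evaluated at `x = 0`. Used internally to take the rare-error
#' limit of quantities that are rational (hence locally polynomial) functions of
#' the error rate.
#'
#' @param values numeric matrix with one column per abscissa (a vector input is
#'   treated as a single row).
#' @param x positive abscissae at which `values` were computed.
#' @returns list with `estimate` (extrapolated values), `error` (absolute
#'   difference between the last two extrapolation orders, a convergence
#'   diagnostic).
#' @keywords internal
extrapolate_to_zero <- function(values, x) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  n <- length(x)
  stopifnot(ncol(values) == n, n >= 2)
  tab <- values
  prev <- NULL
  for (m in seq_len(n - 1)) {
    nxt <- matrix(0, nrow(tab), ncol(tab) - 1)
    for (i in seq_len(ncol(tab) - 1)) {
      w <- x[i + m] / (x[i] - x[i + m])
      nxt[, i] <- tab[, i + 1] + w * (tab[, i + 1] - tab[, i])
    }
    prev <- tab
    tab <- nxt
  }
  est <- tab[, 1]
  # compare highest order against the best previous-order estimate
  err <- abs(est - prev[, ncol(prev)])
  list(estimate = est, error = err)
}

# Default error-rate sequence for rare-error limits. Stationary vectors are
# rational in the error rate, so polynomial extrapolation from these points is
# accurate while staying well away from ill-conditioning at eps = 0. Five
# points (rather than three decades) keep the truncation error small even for
# transition vectors with entries comparable to the largest error rate, where
# the rational function varies fastest near zero.
default_eps_sequence <- function() c(1e-3, 3e-4, 1e-4, 3e-5, 1e-5)

assert_probability <- function(x, name, open_left = FALSE, open_right = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!all(is.finite(x) & lo_ok & hi_ok)) {
    stop(sprintf("`%s` must be %s0, 1%s", name,
                 if (open_left) "in (" else "in [",
                 if (open_right) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}
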