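#' @importFrom rlang .data %||% :=
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy posterior draws
#'
#' [tidy()] returns the per-parameter posterior summary (median, central
#' credible interval, mean, effective sample size); [glance()] a one-row
#' overview of the fit.
#'
#' @param x An `nof1_draws` object.
#' @param level Credible-interval level.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.nof1_draws <- function(x, level = 0.95, ...) {
  dplyr::left_join(summarize_draws(x, level), gelman_rubin(x),
                   by = "parameter")
}

#' @rdname tidy.nof1_draws
#' @export
glance.nof1_draws <- function(x, ...) {
  gr <- gelman_rubin(x)
  tibble::tibble(
    chains = length(x$chains),
    draws = nrow(x$chains[[1]]),
    parameters = length(x$par_names),
    max_rhat = max(gr$rhat),
    converged = all(gr$converged),
    seed = x$config$seed
  )
}
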