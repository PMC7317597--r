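#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and summarize fitted model objects
#'
#' `tidy()` returns one row per coefficient (with outcome, estimate, SE,
#' Wald z and p); `glance()` returns a one-row model summary (log
#' likelihood, parameter count, AIC, n, convergence).
#'
#' @param x A `bcs_fit`, `litter_fit`, `model_ranking`, or
#'   `projection_result`.
#' @param ... Unused.
#' @return A tibble.
#' @name icebears-tidiers
NULL

#' @rdname icebears-tidiers
#' @method tidy bcs_fit
#' @export
tidy.bcs_fit <- function(x, ...) x$coefficients

#' @rdname icebears-tidiers
#' @method tidy litter_fit
#' @export
tidy.litter_fit <- function(x, ...) x$coefficients

#' @rdname icebears-tidiers
#' @method glance bcs_fit
#' @export
glance.bcs_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, k = x$k, AIC = x$aic, nobs = x$n,
                 converged = x$converged)
}

#' @rdname icebears-tidiers
#' @method glance litter_fit
#' @export
glance.litter_fit <- glance.bcs_fit

#' @rdname icebears-tidiers
#' @method tidy model_ranking
#' @export
tidy.model_ranking <- function(x, ...) {
  dplyr::left_join(x$averaged,
                   dplyr::rename(x$importance, imp = "importance"),
                   by = "term") |>
    dplyr::rename(importance = "imp")
}

#' @rdname icebears-tidiers
#' @method glance model_ranking
#' @export
glance.model_ranking <- function(x, ...) {
  tibble::tibble(n_models = nrow(x$table),
                 n_averaged = sum(x$table$delta < x$cutoff),
                 best_aic = min(x$table$aic), cutoff = x$cutoff)
}

#' @rdname icebears-tidiers
#' @method tidy projection_result
#' @export
tidy.projection_result <- function(x, ...) x$trajectory
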