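#' Closed-form expected COY litter size
#'
#' The deterministic inner expectation of the stochastic projection chain:
#' `1 + sum_c P(BCS = c) * P(two cubs | BCS = c, covariates)`. Used both
#' directly and as the convergence oracle for [project_litter_size()].
#'
#' @param bcs_probs Numeric length-3 vector of BCS 1/2/3 probabilities
#'   (must sum to 1).
#' @param litter_coefficients Named vector of litter-logit coefficients
#'   (any subset of `intercept`, `springtran`, `ts_springtran`,
#'   `durfree_lag1`, `p2000`, `bcs1`, `bcs3`).
#' @param covariates Named list/vector of covariate values for the
#'   non-BCS terms.
#' @return Expected litter size in `[1, 2]`.
#' @export
expected_litter_size <- function(bcs_probs, litter_coefficients,
                                 covariates = c()) {
  if (any(bcs_probs < 0 | bcs_probs > 1) ||
      abs(sum(bcs_probs) - 1) > 1e-6) {
    stop("`bcs_probs` must be probabilities summing to 1", call. = FALSE)
  }
  p_two <- vapply(1:3, function(cl) {
    cov <- c(intercept = 1, covariates,
             bcs1 = as.numeric(cl == 1), bcs3 = as.numeric(cl == 3))
    miss <- setdiff(names(litter_coefficients), names(cov))
    if (length(miss) > 0) {
      stop("covariates lack term(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    plogis(sum(litter_coefficients * cov[names(litter_coefficients)]))
  }, numeric(1))
  1 + sum(bcs_probs * p_two)
}

#' Project mean COY litter size under a sea-ice scenario
#'
#' Chains the fitted condition and litter-size models through a linear ice
#' scenario. Each bootstrap iteration (1) resamples the condition and
#' litter unit records with replacement, (2) refits the most-supported
#' BCS and COY litter models (fixed term sets, no re-selection) to the
#' resampled data, (3) for each future year computes the scenario
#' covariates, draws a BCS class for each of `cohort` simulated adult
#' females from the multinomial probabilities, (4) draws litter sizes
#' from the binomial probabilities given the drawn BCS, and (5) records
#' the mean litter size. The output is the across-iteration mean and
#' 2.5/97.5 percentile band per year. With `resample = FALSE` the models
#' are fit once to the observed data and only the within-year stochastic
#' draws remain, which converges to [expected_litter_size()] as `B` grows.
#'
#' @param condition_obs Observation tibble (see
#'   [build_condition_design()]).
#' @param litter_records Litter tibble (see [build_litter_design()]).
#' @param ice_metrics Observed ice metrics used for fitting and for the
#'   observed-mean `ts_springtran` covariate.
#' @param scenario An [ice_scenario()].
#' @param horizon Future years to project (defaults to the scenario's).
#' @param B Bootstrap iterations.
#' @param seed Integer seed.
#' @param cohort Simulated AF cohort size per year.
#' @param af_class_profile Class whose BCS distribution drives litter
#'   size; mothers carry dependent young, hence `"AFwC"` by default.
#' @param condition_terms,litter_terms Fixed term sets of the
#'   most-supported models.
#' @param resample Resample-and-refit per iteration (the full bootstrap)
#'   or fit once and keep only within-year stochasticity.
#' @param max_failure_frac Abort when more than this fraction of
#'   iterations fail to refit (failed iterations are redrawn and counted).
#' @return A `projection_result`: tibble `trajectory` (`year`, `mean`,
#'   `lo`, `hi`), plus `B`, `seed`, `scenario`, `n_refit_failures`.
#' @export
project_litter_size <- function(condition_obs, litter_records, ice_metrics,
                                scenario, horizon = NULL, B = 1000,
                                seed = 1, cohort = 500,
                                af_class_profile = "AFwC",
                                condition_terms = bcs_low_aic_terms(),
                                litter_terms = coy_low_aic_terms(),
                                resample = TRUE,
                                max_failure_frac = 0.1) {
  stopifnot(inherits(scenario, "ice_scenario"))
  horizon <- horizon %||% scenario$horizon
  cov_tbl <- scenario_covariates(scenario)[seq_len(horizon), ]
  cd <- build_condition_design(condition_obs, ice_metrics)
  ld <- build_litter_design(litter_records, ice_metrics, stage = "COY")
  ts_mean <- mean(cd$design$ts_springtran)
  set.seed(seed)

  # per-year design rows for the simulated AF profile under the scenario
  future_design <- tibble::tibble(
    afwc = as.numeric(af_class_profile == "AFwC"),
    sub = as.numeric(af_class_profile == "SUB"),
    am = as.numeric(af_class_profile == "AM"),
    p2000 = 1,
    springtran = cov_tbl$springtran,
    ts_springtran = ts_mean,
    durfree_lag1 = cov_tbl$durfree_lag1
  ) |>
    dplyr::mutate(
      afwc_springtran = .data$afwc * .data$springtran,
      afwc_durfree_lag1 = .data$afwc * .data$durfree_lag1,
      sub_springtran = .data$sub * .data$springtran,
      sub_durfree_lag1 = .data$sub * .data$durfree_lag1,
      am_springtran = .data$am * .data$springtran,
      am_durfree_lag1 = .data$am * .data$durfree_lag1
    )

  one_iteration <- function(resample_now) {
    if (resample_now) {
      ci <- sample.int(nrow(cd$design), replace = TRUE)
      li <- sample.int(nrow(ld$design), replace = TRUE)
    } else {
      ci <- seq_len(nrow(cd$design)); li <- seq_len(nrow(ld$design))
    }
    cfit <- fit_multinomial(cd$design[ci, ], cd$response[ci],
                            terms = condition_terms)
    lfit <- fit_binary_logit(ld$design[li, ], ld$response[li],
                             terms = litter_terms)
    if (!cfit$converged) stop("condition refit failed")
    ccoef <- coef_list(cfit)
    lcoef <- coef_vec(lfit)
    probs <- predict_class_probs(ccoef, future_design)
    vapply(seq_len(horizon), function(i) {
      p <- c(probs$p1[i], probs$p2[i], probs$p3[i])
      cls <- sample.int(3, cohort, replace = TRUE, prob = p)
      row <- future_design[i, ]
      eta <- vapply(1:3, function(cl) {
        cov <- c(intercept = 1, unlist(row),
                 bcs1 = as.numeric(cl == 1), bcs3 = as.numeric(cl == 3))
        sum(lcoef * cov[names(lcoef)])
      }, numeric(1))
      two <- rbinom(cohort, 1, plogis(eta)[cls])
      1 + mean(two)
    }, numeric(1))
  }

  draws <- matrix(NA_real_, nrow = B, ncol = horizon)
  failures <- 0
  b <- 1
  while (b <= B) {
    res <- tryCatch(one_iteration(resample), error = function(e) NULL)
    if (is.null(res)) {
      failures <- failures + 1
      if (failures > max_failure_frac * B) {
        stop("more than ", round(100 * max_failure_frac),
             "% of bootstrap refits failed", call. = FALSE)
      }
      next
    }
    draws[b, ] <- res
    b <- b + 1
  }
  trajectory <- tibble::tibble(
    year = cov_tbl$year,
    mean = colMeans(draws),
    lo = apply(draws, 2, stats::quantile, probs = 0.025),
    hi = apply(draws, 2, stats::quantile, probs = 0.975)
  )
  structure(
    list(trajectory = trajectory, B = B, seed = seed, scenario = scenario,
         cohort = cohort, resample = resample,
         n_refit_failures = failures),
    class = "projection_result"
  )
}

# coefficient tibble -> named list of vectors per outcome (bcs1, bcs3)
coef_list <- function(fit) {
  split(fit$coefficients, fit$coefficients$outcome) |>
    purrr::map(~ setNames(.x$estimate, .x$term))
}

# litter fit -> named coefficient vector
coef_vec <- function(fit) {
  setNames(fit$coefficients$estimate, fit$coefficients$term)
}

#' @export
print.projection_result <- function(x, ...) {
  cat("<projection_result>", nrow(x$trajectory), "years, B =", x$B,
      if (!x$resample) "(resampling disabled)", "\n")
  print(utils::head(x$trajectory, 5))
  invisible(x)
}
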