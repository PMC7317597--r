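#' Ground truth for the synthetic body-condition generator
#'
#' Describes the multinomial-logit data-generating process for the
#' three-level body condition score (BCS; reference level BCS = 2).
#' `coefficients` is a list with numeric vectors `bcs1` and `bcs3`, named
#' by design-matrix terms (see [build_condition_design()]); missing terms
#' are treated as zero. The defaults are the point estimates of the
#' most-supported field model for the Baffin Bay subpopulation, so that
#' refitting simulated data recovers published-scale effects.
#'
#' @param coefficients List of named vectors `bcs1`, `bcs3`; `NULL` uses
#'   the published-model defaults.
#' @param class_mix Named proportions over classes
#'   `AF_alone`, `AFwC`, `SUB`, `AM`; must sum to 1.
#' @param n_per_year Observations generated per year (> 0).
#' @return A `condition_truth` object.
#' @export
condition_truth <- function(coefficients = NULL,
                            class_mix = c(AF_alone = 0.12, AFwC = 0.23,
                                          SUB = 0.23, AM = 0.42),
                            n_per_year = 150) {
  if (abs(sum(class_mix) - 1) > 1e-8) {
    stop("`class_mix` must sum to 1", call. = FALSE)
  }
  if (n_per_year <= 0) stop("`n_per_year` must be > 0", call. = FALSE)
  coefficients <- coefficients %||% bb_bcs_coefficients()
  stopifnot(is.list(coefficients), all(c("bcs1", "bcs3") %in% names(coefficients)))
  structure(
    list(coefficients = coefficients, class_mix = class_mix,
         n_per_year = as.integer(n_per_year)),
    class = "condition_truth"
  )
}

#' Ground truth for the synthetic litter-size generator
#'
#' Describes the binomial-logit process for two-cub (vs one-cub) litters.
#' `coefficients` is a named vector over litter design terms (see
#' [build_litter_design()]); missing terms are zero. Whole-litter loss is
#' generated (the litter simply never appears in the sample) but is never
#' part of the fitted model, so observed litters always have size 1 or 2.
#'
#' @param coefficients Named numeric vector; `NULL` uses the published
#'   most-supported COY model point estimates.
#' @param whole_litter_loss_prob Probability in `[0, 1)` that a litter is
#'   lost entirely and therefore unobserved.
#' @return A `litter_truth` object.
#' @export
litter_truth <- function(coefficients = NULL, whole_litter_loss_prob = 0.1) {
  if (whole_litter_loss_prob < 0 || whole_litter_loss_prob >= 1) {
    stop("`whole_litter_loss_prob` must be in [0, 1)", call. = FALSE)
  }
  coefficients <- coefficients %||% bb_coy_coefficients()
  structure(
    list(coefficients = coefficients,
         whole_litter_loss_prob = whole_litter_loss_prob),
    class = "litter_truth"
  )
}

#' Generate bear observations with BCS drawn from a known multinomial truth
#'
#' Samples, for each year, `n_per_year` bears with classes drawn from the
#' truth's class mix and observation dates placed in the on-land season
#' (a uniform lag after the spring transition). BCS values are drawn from
#' the multinomial probabilities implied by the truth coefficients on the
#' exact design matrix that [build_condition_design()] produces, so a
#' refit on the same design is a clean parameter-recovery experiment.
#' A fatness index consistent with the BCS recode is attached.
#'
#' @param truth A [condition_truth()] object.
#' @param ice_metrics Tibble from [season_metrics()]; must cover each
#'   requested year and its preceding year (the lag-1 covariate).
#' @param years Integer years to simulate.
#' @param seed Integer seed.
#' @param obs_lag_range Days after the spring transition within which
#'   observation dates fall (late-summer/fall sampling).
#' @return Tibble of observations: `bear_id`, `date`, `year`, `class`,
#'   `decade`, `fatness_index`, `bcs`, `litter_stage`, `litter_size`.
#' @export
gen_condition_obs <- function(truth, ice_metrics, years, seed = 1,
                              obs_lag_range = c(60, 120)) {
  stopifnot(inherits(truth, "condition_truth"))
  need <- sort(unique(c(years, years - 1)))
  have <- ice_metrics$year[!is.na(ice_metrics$spring_transition)]
  if (!all(need %in% have)) {
    stop("ice metrics missing for year(s): ",
         paste(setdiff(need, have), collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  obs <- purrr::map_dfr(years, function(y) {
    n <- truth$n_per_year
    spring <- ice_metrics$spring_transition[ice_metrics$year == y]
    lag <- runif(n, obs_lag_range[1], obs_lag_range[2])
    tibble::tibble(
      bear_id = sprintf("S%d-%04d", y, seq_len(n)),
      date = date_from_doy(y, round(spring + lag)),
      year = y,
      class = sample(names(truth$class_mix), n, replace = TRUE,
                     prob = truth$class_mix),
      decade = decade_of(y)
    )
  })
  des <- build_condition_design(dplyr::mutate(obs, bcs = 1L), ice_metrics)
  probs <- predict_class_probs(truth$coefficients, des$design)
  u <- runif(nrow(obs))
  bcs <- ifelse(u < probs$p1, 1L,
                ifelse(u < probs$p1 + probs$p2, 2L, 3L))
  fi <- dplyr::case_when(
    bcs == 1L ~ sample(1:2, nrow(obs), replace = TRUE),
    bcs == 2L ~ 3L,
    TRUE ~ sample(4:5, nrow(obs), replace = TRUE)
  )
  dplyr::mutate(obs, fatness_index = fi, bcs = bcs,
                litter_stage = "none", litter_size = NA_integer_)
}

#' Generate litter records from a known binomial-logit truth
#'
#' Takes observed mothers (class `AFwC` with an assigned BCS), computes the
#' litter-size covariates for each, draws two-cub indicators from the
#' truth's logit, and drops whole-litter losses so that output sizes are
#' always 1 or 2. Mothers without a BCS are rejected with a warning.
#'
#' @param truth A [litter_truth()] object.
#' @param mothers Observation tibble (as from [gen_condition_obs()]);
#'   rows with `class == "AFwC"` are used.
#' @param ice_metrics Tibble from [season_metrics()].
#' @param seed Integer seed.
#' @param stage `"COY"` or `"YRL"` stamped on the records.
#' @return Tibble of litter records: `mother_id`, `year`, `date`, `stage`,
#'   `litter_size`, `mother_bcs`, `decade`.
#' @export
gen_litter_obs <- function(truth, mothers, ice_metrics, seed = 1,
                           stage = "COY") {
  stopifnot(inherits(truth, "litter_truth"))
  mom <- dplyr::filter(mothers, .data$class == "AFwC")
  if (anyNA(mom$bcs)) {
    warning(sum(is.na(mom$bcs)), " mother(s) without BCS dropped",
            call. = FALSE)
    mom <- dplyr::filter(mom, !is.na(.data$bcs))
  }
  if (nrow(mom) == 0) stop("no eligible mothers", call. = FALSE)
  set.seed(seed)
  met <- dplyr::select(ice_metrics, "year", springtran = "spring_transition",
                       durfree = "ice_free_duration")
  cov <- mom |>
    dplyr::left_join(met, by = "year") |>
    dplyr::left_join(dplyr::mutate(met, year = .data$year + 1) |>
                       dplyr::select("year", durfree_lag1 = "durfree"),
                     by = "year") |>
    dplyr::mutate(
      ts_springtran = doy_of(.data$date) - .data$springtran,
      p2000 = as.integer(.data$decade == "2000s"),
      bcs1 = as.integer(.data$bcs == 1),
      bcs3 = as.integer(.data$bcs == 3),
      intercept = 1
    )
  beta <- truth$coefficients
  eta <- Reduce(`+`, purrr::map(names(beta), function(nm) {
    if (!nm %in% names(cov)) stop("unknown truth term: ", nm, call. = FALSE)
    beta[[nm]] * cov[[nm]]
  }))
  two <- rbinom(nrow(cov), 1, plogis(eta))
  lost <- runif(nrow(cov)) < truth$whole_litter_loss_prob
  tibble::tibble(
    mother_id = cov$bear_id, year = cov$year, date = cov$date,
    stage = stage, litter_size = 1L + two, mother_bcs = cov$bcs,
    decade = cov$decade
  )[!lost, ]
}
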