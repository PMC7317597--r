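#' Published Baffin Bay reference values
#'
#' Small reference tables for the Baffin Bay polar bear subpopulation
#' (1990s and 2000s sampling periods), entered from the published study of
#' that subpopulation. They serve three purposes: as worked-example inputs
#' (the litter-size and recruitment arithmetic can be reproduced exactly
#' from these counts), as default ground-truth coefficients for the
#' synthetic generators, and as sign/magnitude anchors in tests.
#'
#' @return Each function returns a tibble (or named list/vector):
#' * `bb_bcs_counts()`: body-condition score counts by bear class and
#'   decade (classes as printed, including the litter-bearing female rows).
#' * `bb_litter_counts()`: litter counts by stage, decade, litter size and
#'   maternal BCS, derived from the litter-bearing rows of
#'   `bb_bcs_counts()`.
#' * `bb_recruitment_totals()`: total dependent young and adult females
#'   per decade used for pooled recruitment ratios.
#' * `bb_annual_recruitment()`: published per-year mean COY/AF and YRL/AF.
#' * `bb_bcs_coefficients()`: most-supported multinomial BCS model point
#'   estimates (reference outcome BCS = 2, reference class adult female
#'   without dependent young).
#' * `bb_coy_coefficients()`: most-supported COY litter-size logit point
#'   estimates (reference BCS = 2).
#' @name baffin_reference
NULL

#' @rdname baffin_reference
#' @export
bb_bcs_counts <- function() {
  tibble::tribble(
    ~group,                 ~decade, ~bcs1, ~bcs2, ~bcs3,
    "AF_alone",             "1990s",     8,    39,    19,
    "AF_1COY",              "1990s",    14,    12,     7,
    "AF_2COY",              "1990s",    17,    33,     5,
    "AF_1YRL",              "1990s",     5,    11,     0,
    "AF_2YRL",              "1990s",     7,    15,     7,
    "SUB_female",           "1990s",    19,    38,     3,
    "SUB_male",             "1990s",    25,    43,     5,
    "AM",                   "1990s",    56,   143,   127,
    "AF_alone",             "2000s",    15,    65,    32,
    "AF_1COY",              "2000s",    12,    40,     2,
    "AF_2COY",              "2000s",     1,    49,     3,
    "AF_1YRL",              "2000s",     3,    28,     2,
    "AF_2YRL",              "2000s",     4,    23,     1,
    "SUB_female",           "2000s",    19,   110,     5,
    "SUB_male",             "2000s",    18,    73,     3,
    "AM",                   "2000s",    73,   232,    47
  )
}

#' @rdname baffin_reference
#' @export
bb_litter_counts <- function() {
  bb_bcs_counts() |>
    dplyr::filter(grepl("^AF_[12]", .data$group)) |>
    tidyr::pivot_longer(c("bcs1", "bcs2", "bcs3"), names_to = "bcs",
                        names_prefix = "bcs", values_to = "n") |>
    dplyr::mutate(
      stage = ifelse(grepl("COY$", .data$group), "COY", "YRL"),
      litter_size = as.integer(substr(.data$group, 4, 4)),
      bcs = as.integer(.data$bcs)
    ) |>
    dplyr::select("stage", "decade", "litter_size", "bcs", "n")
}

#' @rdname baffin_reference
#' @export
bb_recruitment_totals <- function() {
  tibble::tribble(
    ~decade, ~stage, ~young, ~af_total,
    "1990s", "COY",  144,    66 + 133,
    "2000s", "COY",  160,    112 + 168,
    "1990s", "YRL",  75,     66 + 133,
    "2000s", "YRL",  89,     112 + 168
  )
}

#' @rdname baffin_reference
#' @export
bb_annual_recruitment <- function() {
  tibble::tribble(
    ~year, ~coy_per_af, ~yrl_per_af,
    1993,  0.80, 0.34,
    1994,  0.82, 0.39,
    1995,  0.69, 0.48,
    1997,  0.63, 0.31,
    2011,  0.60, 0.41,
    2012,  0.55, 0.30,
    2013,  0.57, 0.25
  )
}

#' @rdname baffin_reference
#' @export
bb_bcs_coefficients <- function() {
  list(
    bcs3 = c(intercept = -0.97, afwc = -20.74, sub = -2.10, am = -16.27,
             p2000 = -0.99, springtran = 0.01, ts_springtran = -0.02,
             durfree_lag1 = 0.00, afwc_springtran = 0.12,
             afwc_durfree_lag1 = -0.00, am_springtran = 0.10),
    bcs1 = c(intercept = 12.19, afwc = 7.19, sub = 0.30, am = 10.03,
             p2000 = -2.19, springtran = -0.09, ts_springtran = -0.00,
             durfree_lag1 = 0.01, afwc_springtran = -0.03,
             afwc_durfree_lag1 = -0.02, am_springtran = -0.06)
  )
}

#' @rdname baffin_reference
#' @export
bb_coy_coefficients <- function() {
  c(intercept = -10.17, springtran = 0.07, durfree_lag1 = -0.01,
    bcs1 = -1.24, bcs3 = -1.08)
}
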