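#' Build the litter-size design matrix
#'
#' Stage-appropriate covariates for the binary (two-cub vs one-cub) litter
#' model. For cubs of the year (COY) the candidate terms are the spring
#' transition date of year t, days since the spring transition, the lag-1
#' ice-free duration, the decade indicator and maternal BCS (entered as
#' dummies `bcs1`, `bcs3` against reference BCS 2). For yearlings (YRL)
#' the lag-2 ice-free duration replaces `springtran` as the biological
#' driver; `springtran` is screened out whenever its correlation with
#' `durfree_lag2` reaches the collinearity threshold (as it does in the
#' observed system, r = -0.95). Litter sizes of 3 are recoded to 2 (and
#' counted); rows with missing lag metrics are dropped with a message.
#'
#' @param records Litter tibble: `mother_id`, `year`, `date` (or
#'   `ts_springtran`), `litter_size`, `mother_bcs`, optionally `decade`.
#' @param ice_metrics Tibble from [season_metrics()].
#' @param stage `"COY"` or `"YRL"`.
#' @param collinearity_threshold Absolute correlation at which the
#'   later-listed covariate of a collinear pair is dropped.
#' @return List: `design` (tibble), `response` (0/1 two-cub indicator),
#'   `data`, `n_dropped`, `n_recoded`, `screened_out` (character).
#' @export
build_litter_design <- function(records, ice_metrics,
                                stage = c("COY", "YRL"),
                                collinearity_threshold = 0.9) {
  stage <- match.arg(stage)
  rec <- dplyr::as_tibble(records)
  if (!"decade" %in% names(rec)) rec$decade <- decade_of(rec$year)
  n_recoded <- sum(rec$litter_size > 2, na.rm = TRUE)
  if (n_recoded > 0) {
    message("build_litter_design: recoded ", n_recoded,
            " triplet litter(s) to size 2")
    rec$litter_size <- pmin(rec$litter_size, 2L)
  }
  met <- dplyr::select(ice_metrics, "year",
                       springtran = "spring_transition",
                       durfree = "ice_free_duration")
  rec <- rec |>
    dplyr::left_join(met, by = "year") |>
    dplyr::left_join(dplyr::transmute(met, year = .data$year + 1,
                                      durfree_lag1 = .data$durfree),
                     by = "year")
  if (stage == "YRL") {
    rec <- dplyr::left_join(
      rec,
      dplyr::transmute(met, year = .data$year + 2,
                       durfree_lag2 = .data$durfree),
      by = "year")
  }
  need <- c("springtran", "durfree_lag1",
            if (stage == "YRL") "durfree_lag2")
  keep <- stats::complete.cases(rec[need]) & !is.na(rec$mother_bcs)
  if (any(!keep)) {
    message("build_litter_design: dropped ", sum(!keep),
            " row(s) with missing covariates")
  }
  rec <- rec[keep, ]
  ts <- if ("ts_springtran" %in% names(rec) && !all(is.na(rec$ts_springtran))) {
    rec$ts_springtran
  } else {
    doy_of(rec$date) - rec$springtran
  }
  design <- tibble::tibble(
    springtran = rec$springtran,
    ts_springtran = ts,
    durfree_lag1 = rec$durfree_lag1,
    p2000 = as.numeric(rec$decade == "2000s"),
    bcs1 = as.numeric(rec$mother_bcs == 1),
    bcs3 = as.numeric(rec$mother_bcs == 3)
  )
  screened <- character()
  if (stage == "YRL") {
    design$durfree_lag2 <- rec$durfree_lag2
    r <- stats::cor(design$springtran, design$durfree_lag2)
    if (!is.na(r) && abs(r) >= collinearity_threshold) {
      message(sprintf(
        "build_litter_design: springtran dropped (r = %.2f with durfree_lag2)",
        r))
      design$springtran <- NULL
      screened <- "springtran"
    }
  }
  list(design = design, response = as.integer(rec$litter_size == 2),
       data = rec, n_dropped = sum(!keep), n_recoded = n_recoded,
       screened_out = screened)
}

# most-supported published COY model term set
coy_low_aic_terms <- function() c("springtran", "durfree_lag1", "bcs1", "bcs3")

#' Fit a binomial logistic model for litter size
#'
#' Maximum-likelihood logistic regression of the two-cub indicator on the
#' requested design columns, sharing the AIC ranking machinery of
#' [rank_models()] with the condition module.
#'
#' @param design Design tibble from [build_litter_design()].
#' @param response 0/1 indicator of a two-cub litter.
#' @param terms Design columns to include (default all).
#' @return A `litter_fit` object with the same surface as [fit_multinomial()].
#' @export
fit_binary_logit <- function(design, response, terms = names(design)) {
  stopifnot(length(response) == nrow(design))
  if (length(unique(response)) < 2) {
    stop("both litter sizes must be present", call. = FALSE)
  }
  dat <- as.data.frame(design[, terms, drop = FALSE])
  dat$.two <- response
  fit <- stats::glm(.two ~ ., data = dat, family = stats::binomial())
  separated <- any(abs(stats::coef(fit)) > 15, na.rm = TRUE) ||
    !fit$converged
  sm <- summary(fit)$coefficients
  coefs <- tibble::tibble(
    outcome = "two_cub",
    term = sub("^\\(Intercept\\)$", "intercept", rownames(sm)),
    estimate = unname(sm[, "Estimate"]),
    se = unname(sm[, "Std. Error"]),
    z = unname(sm[, "z value"]),
    p = unname(sm[, "Pr(>|z|)"])
  )
  k <- length(stats::coef(fit))
  ll <- as.numeric(stats::logLik(fit))
  structure(
    list(coefficients = coefs, terms = terms, loglik = ll, k = k,
         aic = 2 * k - 2 * ll, converged = !separated, n = nrow(dat),
         model = fit, response = response),
    class = "litter_fit"
  )
}

#' @export
print.litter_fit <- function(x, ...) {
  cat("<litter_fit> binomial logit (two-cub vs one-cub)\n")
  cat("  n =", x$n, " k =", x$k, " AIC =", round(x$aic, 2),
      if (!x$converged) " (separation suspected)", "\n")
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Expand a litter count table to unit records
#'
#' Inverse of aggregation: one record per counted litter, preserving
#' totals. Counts must be non-negative integers.
#'
#' @param counts Tibble with columns `stage`, `decade`, `litter_size`,
#'   optionally `bcs`, and `n`.
#' @return Tibble of unit litter records (`mother_id` synthesized).
#' @export
litters_from_counts <- function(counts) {
  if (any(counts$n < 0)) stop("counts must be non-negative", call. = FALSE)
  out <- tidyr::uncount(dplyr::as_tibble(counts), weights = .data$n)
  if (nrow(out) == 0) {
    return(dplyr::mutate(out, mother_id = character()))
  }
  out |>
    dplyr::mutate(
      mother_id = sprintf("L%04d", dplyr::row_number()),
      mother_bcs = if ("bcs" %in% names(out)) .data$bcs else NA_integer_
    ) |>
    dplyr::select(dplyr::any_of(c("mother_id", "stage", "decade",
                                  "litter_size", "mother_bcs")))
}

#' Aggregate litter records back to a count table
#'
#' @param records Tibble of unit litter records.
#' @return Count tibble (`stage`, `decade`, `litter_size`, `bcs`, `n`).
#' @export
litters_to_counts <- function(records) {
  records |>
    dplyr::count(.data$stage, .data$decade, .data$litter_size,
                 bcs = .data$mother_bcs, name = "n") |>
    dplyr::arrange(.data$stage, .data$decade, .data$litter_size, .data$bcs)
}

#' Recruitment ratios: dependent young per adult female
#'
#' Per-year ratios (young counted / adult females counted, AFs with and
#' without dependent young) and pooled decade ratios computed as total
#' young over total AFs — not the mean of annual means. Optionally attaches
#' a bootstrap SEM per year, resampling unit observations within year.
#'
#' @param observations Bear-observation tibble: one row per sampled AF
#'   (`class` `"AF_alone"` or `"AFwC"`), with `year`, `litter_stage`
#'   (`"none"`, `"COY"`, `"YRL"`) and `litter_size`.
#' @param stage Which young to count (`"COY"` or `"YRL"`).
#' @param B Bootstrap iterations for per-year SEMs (0 = skip).
#' @param seed Seed for the bootstrap.
#' @return List with tibbles `annual` (`year`, `ratio`, `sem`, `n_af`,
#'   `n_young`) and `pooled` (`decade`, `ratio`, `sem`, `n_af`, `n_young`).
#' @export
recruitment_ratios <- function(observations, stage = "COY", B = 0,
                               seed = 1) {
  af <- dplyr::filter(observations, .data$class %in% c("AF_alone", "AFwC"))
  if (nrow(af) == 0) stop("no adult-female observations", call. = FALSE)
  young_of <- function(df) {
    ifelse(!is.na(df$litter_stage) & df$litter_stage == stage &
             !is.na(df$litter_size), df$litter_size, 0)
  }
  ratio_of <- function(df) sum(young_of(df)) / nrow(df)
  annual <- af |>
    dplyr::group_by(year = .data$year) |>
    dplyr::group_modify(function(df, key) {
      tibble::tibble(ratio = ratio_of(df), n_af = nrow(df),
                     n_young = sum(young_of(df)))
    }) |>
    dplyr::ungroup()
  pooled <- af |>
    dplyr::group_by(decade = decade_of(.data$year)) |>
    dplyr::group_modify(function(df, key) {
      tibble::tibble(ratio = ratio_of(df), n_af = nrow(df),
                     n_young = sum(young_of(df)))
    }) |>
    dplyr::ungroup()
  if (B > 0) {
    annual$sem <- purrr::map_dbl(annual$year, function(y) {
      bootstrap_sem(af[af$year == y, ], ratio_of, B = B, seed = seed)
    })
    pooled$sem <- purrr::map_dbl(pooled$decade, function(d) {
      bootstrap_sem(af[decade_of(af$year) == d, ], ratio_of, B = B,
                    seed = seed)
    })
  }
  list(annual = annual, pooled = pooled)
}

#' Bootstrap standard error of a statistic
#'
#' Resamples unit records (rows) with replacement `B` times and returns
#' the standard deviation of the statistic over the resamples. The
#' resampling unit is the individual bear observation within whatever
#' stratum the caller passes in.
#'
#' @param data A data frame of unit records (>= 2 rows).
#' @param statistic Function of a data frame returning a scalar.
#' @param B Number of bootstrap iterations (default 10000; < 100 warns).
#' @param seed Integer seed.
#' @return The bootstrap SEM (scalar).
#' @export
bootstrap_sem <- function(data, statistic, B = 10000, seed = 1) {
  stopifnot(is.data.frame(data), nrow(data) >= 2)
  if (B < 100) warning("B < 100 gives an unstable SEM", call. = FALSE)
  set.seed(seed)
  n <- nrow(data)
  stats::sd(vapply(seq_len(B), function(b) {
    statistic(data[sample.int(n, n, replace = TRUE), , drop = FALSE])
  }, numeric(1)))
}

#' Kendall rank correlation with exact small-sample p-value
#'
#' Tau-b rank correlation; with few pairs and no ties the p-value is the
#' exact permutation probability.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return One-row tibble: `tau`, `p`, `n`.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("ties-only input; tau undefined", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  tibble::tibble(tau = unname(ct$estimate), p = ct$p.value, n = length(x))
}
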