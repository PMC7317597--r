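#' Recode a 5-point fatness index to a 3-level body condition score
#'
#' Poor (BCS 1) for FI 1-2, fair (BCS 2) for FI 3, good (BCS 3) for FI 4-5.
#'
#' @param fi Integer fatness index values in 1..5.
#' @return Integer BCS values in 1..3.
#' @export
recode_fi_to_bcs <- function(fi) {
  if (any(!is.na(fi) & !fi %in% 1:5)) {
    stop("fatness index must be in 1..5", call. = FALSE)
  }
  out <- rep(NA_integer_, length(fi))
  out[fi %in% 1:2] <- 1L
  out[fi == 3] <- 2L
  out[fi %in% 4:5] <- 3L
  out
}

# the canonical design column names for the condition model
condition_main_terms <- function() {
  c("afwc", "sub", "am", "p2000", "springtran", "ts_springtran",
    "durfree_lag1")
}
condition_interaction_terms <- function() {
  c("afwc_springtran", "afwc_durfree_lag1", "sub_springtran",
    "sub_durfree_lag1", "am_springtran", "am_durfree_lag1")
}

# term set of the most-supported published model (22 parameters over two
# non-reference outcomes once the intercept is counted)
bcs_low_aic_terms <- function() {
  c("afwc", "sub", "am", "p2000", "springtran", "ts_springtran",
    "durfree_lag1", "afwc_springtran", "afwc_durfree_lag1", "am_springtran")
}

#' Build the body-condition design matrix
#'
#' One row per retained observation: class dummies (`afwc`, `sub`, `am`;
#' reference class is the adult female without dependent young), the
#' decade indicator `p2000`, the spring transition date of the observation
#' year (`springtran`), days elapsed since the spring transition
#' (`ts_springtran`), the previous year's ice-free duration
#' (`durfree_lag1`), and the six class x ice interaction products.
#' Continuous covariates are passed through unstandardized. Rows whose
#' lag-year ice metrics are unavailable are dropped with a message;
#' within-year duplicate records of a bear are dropped (repeat
#' observations across years are retained).
#'
#' @param observations Tibble with `bear_id`, `date` (or `ts_springtran`),
#'   `year`, `class` in `{AF_alone, AFwC, SUB, AM}`, `bcs`, and optionally
#'   `decade`.
#' @param ice_metrics Tibble from [season_metrics()].
#' @return A list: `design` (tibble of numeric columns), `response`
#'   (integer BCS vector), `data` (the retained observations), `n_dropped`.
#' @export
build_condition_design <- function(observations, ice_metrics) {
  obs <- observations |>
    dplyr::as_tibble() |>
    dplyr::distinct(.data$bear_id, .data$year, .keep_all = TRUE)
  if (!"decade" %in% names(obs)) obs$decade <- decade_of(obs$year)
  met <- dplyr::select(ice_metrics, "year",
                       springtran = "spring_transition",
                       durfree = "ice_free_duration")
  lag1 <- dplyr::transmute(met, year = .data$year + 1,
                           durfree_lag1 = .data$durfree)
  joined <- obs |>
    dplyr::left_join(met, by = "year") |>
    dplyr::left_join(lag1, by = "year")
  keep <- !is.na(joined$springtran) & !is.na(joined$durfree_lag1)
  if (any(!keep)) {
    message("build_condition_design: dropped ", sum(!keep),
            " row(s) with missing ice metrics")
  }
  joined <- joined[keep, ]
  if ("ts_springtran" %in% names(joined) &&
      !all(is.na(joined$ts_springtran))) {
    ts <- joined$ts_springtran
  } else {
    ts <- doy_of(joined$date) - joined$springtran
  }
  design <- tibble::tibble(
    afwc = as.numeric(joined$class == "AFwC"),
    sub = as.numeric(joined$class == "SUB"),
    am = as.numeric(joined$class == "AM"),
    p2000 = as.numeric(joined$decade == "2000s"),
    springtran = joined$springtran,
    ts_springtran = ts,
    durfree_lag1 = joined$durfree_lag1
  )
  design <- dplyr::mutate(design,
    afwc_springtran = .data$afwc * .data$springtran,
    afwc_durfree_lag1 = .data$afwc * .data$durfree_lag1,
    sub_springtran = .data$sub * .data$springtran,
    sub_durfree_lag1 = .data$sub * .data$durfree_lag1,
    am_springtran = .data$am * .data$springtran,
    am_durfree_lag1 = .data$am * .data$durfree_lag1
  )
  list(design = design, response = as.integer(joined$bcs), data = joined,
       n_dropped = sum(!keep))
}

#' Fit a multinomial logistic model for the 3-level condition score
#'
#' Maximum-likelihood multinomial logit with outcome BCS = 2 as the
#' reference, so coefficients describe the log-odds of poor (BCS 1) and
#' good (BCS 3) condition against fair. Standard errors and Wald z/p come
#' from the observed information.
#'
#' @param design Design tibble from [build_condition_design()].
#' @param response Integer BCS vector (values 1, 2, 3).
#' @param terms Character vector of design columns to include (default all).
#' @param reference Reference outcome level (default `2`).
#' @return A `bcs_fit` object: coefficients tibble (`outcome`, `term`,
#'   `estimate`, `se`, `z`, `p`), `loglik`, `k`, `aic`, `converged`, `n`,
#'   and the underlying `nnet::multinom` fit.
#' @export
fit_multinomial <- function(design, response, terms = names(design),
                            reference = 2) {
  stopifnot(length(response) == nrow(design))
  lev <- sort(unique(response))
  if (length(lev) < 2) stop("response has a single level", call. = FALSE)
  y <- stats::relevel(factor(response), ref = as.character(reference))
  dat <- as.data.frame(design[, terms, drop = FALSE])
  dat$.bcs <- y
  fit <- nnet::multinom(.bcs ~ ., data = dat, trace = FALSE, maxit = 500,
                        Hess = TRUE, reltol = 1e-12)
  converged <- fit$convergence == 0
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                     dimnames = list(setdiff(levels(y),
                                                             as.character(reference)),
                                                     names(cf)))
  # an indefinite Hessian (weakly identified refit) yields NaN SEs; they
  # are kept as the diagnostic rather than warned about per element
  se <- tryCatch({
    s <- suppressWarnings(summary(fit)$standard.errors)
    if (is.null(dim(s))) s <- matrix(s, nrow = 1, dimnames = dimnames(cf))
    s
  }, error = function(e) cf * NA)
  coefs <- purrr::map_dfr(rownames(cf), function(out) {
    tibble::tibble(
      outcome = paste0("bcs", out),
      term = sub("^\\(Intercept\\)$", "intercept", colnames(cf)),
      estimate = unname(cf[out, ]),
      se = unname(se[out, ])
    )
  }) |>
    dplyr::mutate(z = .data$estimate / .data$se,
                  p = 2 * stats::pnorm(-abs(.data$z)))
  ll <- -fit$value
  k <- length(cf)
  structure(
    list(coefficients = coefs, terms = terms, loglik = ll, k = k,
         aic = 2 * k - 2 * ll, converged = converged, n = nrow(dat),
         reference = reference, model = fit, response = as.integer(response),
         fitted_probs = reorder_probs(fit, lev)),
    class = "bcs_fit"
  )
}

# fitted probabilities as a matrix with columns in outcome order 1,2,3
reorder_probs <- function(fit, lev) {
  p <- stats::fitted(fit)
  if (is.null(dim(p))) {  # two-level edge case
    p <- cbind(1 - p, p)
    colnames(p) <- fit$lev
  }
  p[, as.character(lev), drop = FALSE]
}

#' @export
print.bcs_fit <- function(x, ...) {
  cat("<bcs_fit> multinomial logit, reference BCS =", x$reference, "\n")
  cat("  n =", x$n, " k =", x$k, " AIC =", round(x$aic, 2),
      if (!x$converged) " (NOT converged)", "\n")
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Enumerate candidate term sets under a marginality constraint
#'
#' All combinations of main-effect blocks and interaction terms in which
#' every interaction appears only together with both of its parents. The
#' three class dummies enter and leave together as a single main-effect
#' block, while each class-dummy x covariate interaction toggles
#' independently; this is the only reading of "all combinations" that
#' admits a model holding a strict subset of the six interactions.
#'
#' @param main_blocks Named list of main-effect blocks, each a character
#'   vector of design columns.
#' @param interactions Named list of interactions, each a list with
#'   `term` (design column) and `parents` (names of required main blocks).
#' @return A list of character vectors of design columns (the intercept is
#'   implicit); the first element is the empty (intercept-only) model.
#' @export
enumerate_candidates <- function(main_blocks = NULL, interactions = NULL) {
  if (is.null(main_blocks)) {
    main_blocks <- list(class = c("afwc", "sub", "am"), p2000 = "p2000",
                        springtran = "springtran",
                        ts_springtran = "ts_springtran",
                        durfree_lag1 = "durfree_lag1")
    interactions <- purrr::map(condition_interaction_terms(), function(tm) {
      parts <- strsplit(tm, "_", fixed = TRUE)[[1]]
      cov <- paste(parts[-1], collapse = "_")
      list(term = tm, parents = c("class", cov))
    })
  }
  nb <- length(main_blocks)
  out <- list()
  for (mask in 0:(2^nb - 1)) {
    present <- names(main_blocks)[bitwAnd(mask, 2^(seq_len(nb) - 1)) > 0]
    mains <- unlist(main_blocks[present], use.names = FALSE)
    ok_int <- purrr::keep(interactions,
                          ~ all(.x$parents %in% present))
    ni <- length(ok_int)
    for (imask in 0:(max(2^ni - 1, 0))) {
      if (ni == 0 && imask > 0) break
      ints <- purrr::map_chr(
        ok_int[bitwAnd(imask, 2^(seq_len(ni) - 1)) > 0], "term")
      out[[length(out) + 1]] <- c(mains, ints)
    }
  }
  out
}

#' Rank fitted candidate models by AIC
#'
#' Computes each model's AIC difference from the best (delta AIC) and
#' Akaike weight over the full candidate set; model-averages coefficients
#' over the models with delta AIC below `cutoff` using full (zero
#' substitution) averaging with weights renormalized within that set; and
#' scores each term's importance as the sum of the full-set weights of the
#' models containing it.
#'
#' @param fits List of `bcs_fit` / `litter_fit` objects. Non-converged
#'   fits are excluded with a warning.
#' @param cutoff Delta-AIC threshold for the averaging set.
#' @return A `model_ranking` object: `table` (per-model tibble), `averaged`
#'   (tibble `outcome`, `term`, `estimate`), `importance` (tibble `term`,
#'   `importance`), `cutoff`.
#' @export
rank_models <- function(fits, cutoff = 4) {
  conv <- purrr::map_lgl(fits, "converged")
  if (any(!conv)) {
    warning(sum(!conv), " non-converged fit(s) excluded from ranking",
            call. = FALSE)
    fits <- fits[conv]
  }
  if (length(fits) == 0) stop("no converged fits to rank", call. = FALSE)
  aic <- purrr::map_dbl(fits, "aic")
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  tab <- tibble::tibble(
    model_id = seq_along(fits),
    terms = purrr::map(fits, "terms"),
    k = purrr::map_dbl(fits, "k"),
    aic = aic, delta = delta, weight = w
  ) |>
    dplyr::arrange(.data$delta)
  in_avg <- which(delta < cutoff)
  wa <- w[in_avg] / sum(w[in_avg])
  all_coefs <- purrr::imap_dfr(fits[in_avg], function(f, j) {
    dplyr::mutate(f$coefficients, .w = wa[j])
  })
  averaged <- all_coefs |>
    dplyr::group_by(.data$outcome, .data$term) |>
    dplyr::summarise(estimate = sum(.data$estimate * .data$.w),
                     .groups = "drop")  # absent terms contribute 0
  all_terms <- unique(unlist(purrr::map(fits, "terms")))
  importance <- purrr::map_dfr(all_terms, function(tm) {
    has <- purrr::map_lgl(fits, ~ tm %in% .x$terms)
    tibble::tibble(term = tm, importance = sum(w[has]))
  })
  structure(list(table = tab, averaged = averaged, importance = importance,
                 cutoff = cutoff),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, ...) {
  cat("<model_ranking>", nrow(x$table), "models;",
      sum(x$table$delta < x$cutoff), "within delta-AIC <", x$cutoff, "\n")
  print(utils::head(dplyr::mutate(x$table,
                                  terms = purrr::map_chr(.data$terms,
                                                         paste,
                                                         collapse = "+")),
                    5))
  invisible(x)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk test. Binary fits use the classic form: observations
#' are grouped into `groups` bins of the fitted probability and the
#' Pearson chi-square over the group x outcome table has `groups - 2`
#' degrees of freedom. For the three-level condition model the multinomial
#' extension orders observations by the complement of the reference-level
#' probability and uses `(groups - 2) x (levels - 1)` degrees of freedom
#' (16 for ten groups and three outcomes).
#'
#' @param fit A `bcs_fit` or `litter_fit` object.
#' @param groups Number of probability groups (default 10).
#' @return A one-row tibble: `chi2`, `df`, `p`, `groups`.
#' @export
hl_gof <- function(fit, groups = 10) {
  UseMethod("hl_gof")
}

#' @export
hl_gof.bcs_fit <- function(fit, groups = 10) {
  p <- fit$fitted_probs
  lev <- colnames(p)
  yi <- match(as.character(fit$response), lev)
  ref_col <- match(as.character(fit$reference), lev)
  score <- 1 - p[, ref_col]
  hl_core(p, yi, score, groups, df = NULL)
}

#' @export
hl_gof.litter_fit <- function(fit, groups = 10) {
  ph <- stats::fitted(fit$model)
  p <- cbind(1 - ph, ph)
  yi <- fit$model$y + 1L
  hl_core(p, yi, ph, groups, df = NULL)
}

hl_core <- function(p, yi, score, groups, df = NULL) {
  g <- dplyr::ntile(score, groups)
  ng <- length(unique(g))
  if (ng < groups) {
    message("hl_gof: reduced to ", ng, " non-empty groups")
    groups <- ng
  }
  nlev <- ncol(p)
  obs <- matrix(0, groups, nlev)
  expd <- matrix(0, groups, nlev)
  for (j in seq_len(nlev)) {
    obs[, j] <- tapply(as.numeric(yi == j), g, sum)
    expd[, j] <- tapply(p[, j], g, sum)
  }
  chi2 <- sum((obs - expd)^2 / pmax(expd, 1e-12))
  df <- df %||% ((groups - 2) * (nlev - 1))
  tibble::tibble(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 groups = groups)
}

#' Class probabilities from condition-model coefficients
#'
#' Softmax over the two non-reference linear predictors and the implicit
#' zero of the reference outcome (BCS 2). Coefficient vectors may name any
#' subset of design columns plus `intercept`; rows of `design` supply the
#' covariates.
#'
#' @param coefficients List with named numeric vectors `bcs1` and `bcs3`.
#' @param design A tibble/data frame of design columns (one or more rows).
#' @return Tibble with columns `p1`, `p2`, `p3` summing to 1 per row.
#' @export
predict_class_probs <- function(coefficients, design) {
  design <- dplyr::as_tibble(design)
  design$intercept <- 1
  lp <- function(beta) {
    miss <- setdiff(names(beta), names(design))
    if (length(miss) > 0) {
      stop("design lacks term(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    as.numeric(as.matrix(design[names(beta)]) %*% beta)
  }
  e1 <- exp(lp(coefficients$bcs1))
  e3 <- exp(lp(coefficients$bcs3))
  z <- 1 + e1 + e3
  tibble::tibble(p1 = e1 / z, p2 = 1 / z, p3 = e3 / z)
}
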