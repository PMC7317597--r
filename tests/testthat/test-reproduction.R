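test_that("count tables expand to unit records and back (inverse pair)", {
  cnt <- bb_litter_counts()
  rec <- litters_from_counts(cnt)
  expect_equal(nrow(rec), sum(cnt$n))
  # published totals: 107 litters and 160 cubs in the 2000s COY sample
  coy2000 <- dplyr::filter(rec, stage == "COY", decade == "2000s")
  expect_equal(nrow(coy2000), 107)
  expect_equal(sum(coy2000$litter_size), 160)
  back <- litters_to_counts(rec)
  expect_equal(
    dplyr::arrange(dplyr::filter(cnt, n > 0), stage, decade, litter_size,
                   bcs),
    dplyr::arrange(back, stage, decade, litter_size, bcs),
    ignore_attr = TRUE)
  expect_equal(nrow(litters_from_counts(cnt[0, ])), 0)
  expect_error(litters_from_counts(dplyr::mutate(cnt, n = -1)),
               "non-negative")
})

test_that("the two-group decade logistic fit matches its closed form", {
  rec <- litters_from_counts(dplyr::filter(bb_litter_counts(),
                                           stage == "YRL"))
  # 1990s: 16 one-cub, 29 two-cub; 2000s: 33 one-cub, 28 two-cub
  tab <- table(rec$decade, rec$litter_size)
  expect_equal(as.numeric(tab), c(16, 33, 29, 28))
  design <- tibble::tibble(p2000 = as.numeric(rec$decade == "2000s"))
  fit <- fit_binary_logit(design, as.integer(rec$litter_size == 2))
  cf <- tidy(fit)
  beta <- log(28 / 33) - log(29 / 16)
  se <- sqrt(1 / 16 + 1 / 29 + 1 / 33 + 1 / 28)
  expect_equal(cf$estimate[cf$term == "p2000"], beta, tolerance = 1e-6)
  expect_equal(cf$se[cf$term == "p2000"], se, tolerance = 1e-6)
  expect_equal(round(cf$estimate[cf$term == "p2000"], 3), -0.759)
  expect_equal(round(cf$se[cf$term == "p2000"], 3), 0.404)
  # fitted 1990s two-cub probability is the group frequency 29/45
  p90 <- plogis(cf$estimate[cf$term == "intercept"])
  expect_equal(p90, 29 / 45, tolerance = 1e-8)
  expect_equal(round(p90, 2), 0.64)
  # balanced toy data: zero coefficient
  bal <- tibble::tibble(p2000 = rep(c(0, 1), each = 20))
  fb <- fit_binary_logit(bal, rep(c(0, 1), 20))
  expect_equal(tidy(fb)$estimate[2], 0, tolerance = 1e-8)
  expect_error(fit_binary_logit(bal, rep(1, 40)), "both")
})

test_that("litter designs carry stage-appropriate terms and the screen", {
  yrs <- 1990:2013
  m <- tibble::tibble(
    year = yrs,
    spring_transition = as.integer(round(170 - 0.9 * (yrs - 1990))),
    fall_transition = 315L) |>
    dplyr::mutate(ice_free_duration = fall_transition - spring_transition)
  rec <- tibble::tibble(
    mother_id = sprintf("m%d", 1:6),
    year = c(1993, 1994, 1995, 2011, 2012, 2013),
    date = as.Date(sprintf("%d-09-01", c(1993, 1994, 1995, 2011, 2012,
                                         2013))),
    litter_size = c(1L, 2L, 2L, 1L, 1L, 2L),
    mother_bcs = c(1L, 2L, 3L, 2L, 2L, 2L))
  dc <- build_litter_design(rec, m, stage = "COY")
  expect_setequal(names(dc$design),
                  c("springtran", "ts_springtran", "durfree_lag1", "p2000",
                    "bcs1", "bcs3"))
  # BCS 2 mother: both dummies zero
  expect_equal(unlist(dc$design[2, c("bcs1", "bcs3")]),
               c(bcs1 = 0, bcs3 = 0))
  # YRL: springtran is collinear with durfree_lag2 here (|r| = 1) and is
  # screened out; durfree_lag2 enters
  expect_message(dy <- build_litter_design(rec, m, stage = "YRL"),
                 "springtran dropped")
  expect_false("springtran" %in% names(dy$design))
  expect_true("durfree_lag2" %in% names(dy$design))
  expect_equal(dy$screened_out, "springtran")
  # triplets recode to 2 with a message
  rec3 <- dplyr::mutate(rec, litter_size = c(3L, 2L, 1L, 1L, 2L, 1L))
  expect_message(d3 <- build_litter_design(rec3, m, stage = "COY"),
                 "triplet")
  expect_true(all(d3$data$litter_size <= 2))
})

test_that("recruitment ratios reproduce the published pooled arithmetic", {
  tot <- bb_recruitment_totals()
  ratio <- tot$young / tot$af_total
  expect_equal(round(ratio, 2), c(0.72, 0.57, 0.38, 0.32))
  # the same pooled ratios from reconstructed unit observations
  mk_obs <- function(decade, year) {
    lits <- dplyr::filter(bb_litter_counts(), decade == !!decade)
    recs <- litters_from_counts(lits)
    af_young <- dplyr::transmute(
      recs, bear_id = mother_id, year = year, class = "AFwC",
      litter_stage = stage, litter_size = litter_size)
    if (decade == "1990s") {
      # the 1990s sample held one COY and one YRL triplet litter; the
      # two-column count table folds them into the two-cub rows, but cub
      # totals keep them at face value
      for (st in c("COY", "YRL")) {
        i <- which(af_young$litter_stage == st & af_young$litter_size == 2)[1]
        af_young$litter_size[i] <- 3L
      }
    }
    n_young_af <- nrow(af_young)
    n_alone <- ifelse(decade == "1990s", 66, 112)
    total_af <- ifelse(decade == "1990s", 66 + 133, 112 + 168)
    # AFs without dependent young fill the remainder of the printed total
    extra <- total_af - n_young_af - n_alone
    alone <- tibble::tibble(
      bear_id = sprintf("%s-a%03d", decade, seq_len(n_alone + extra)),
      year = year, class = "AF_alone", litter_stage = "none",
      litter_size = NA_integer_)
    dplyr::bind_rows(af_young, alone)
  }
  obs <- dplyr::bind_rows(mk_obs("1990s", 1995), mk_obs("2000s", 2012))
  coy <- recruitment_ratios(obs, stage = "COY")
  yrl <- recruitment_ratios(obs, stage = "YRL")
  expect_equal(round(coy$pooled$ratio[coy$pooled$decade == "1990s"], 2),
               0.72)
  expect_equal(round(coy$pooled$ratio[coy$pooled$decade == "2000s"], 2),
               0.57)
  expect_equal(round(yrl$pooled$ratio[yrl$pooled$decade == "1990s"], 2),
               0.38)
  expect_equal(round(yrl$pooled$ratio[yrl$pooled$decade == "2000s"], 2),
               0.32)
  # one AF with one singleton COY litter: ratio 1
  one <- tibble::tibble(bear_id = "q", year = 1993, class = "AFwC",
                        litter_stage = "COY", litter_size = 1L)
  expect_equal(recruitment_ratios(one)$annual$ratio, 1)
})

test_that("bootstrap SEM matches the analytic SEM of a Bernoulli mean", {
  set.seed(77)
  dat <- tibble::tibble(x = rbinom(200, 1, 0.5))
  sem <- bootstrap_sem(dat, function(d) mean(d$x), B = 2000, seed = 5)
  analytic <- sqrt(mean(dat$x) * (1 - mean(dat$x)) / 200)
  expect_lt(abs(sem - analytic) / analytic, 0.1)
  expect_identical(sem, bootstrap_sem(dat, function(d) mean(d$x),
                                      B = 2000, seed = 5))
  expect_equal(bootstrap_sem(tibble::tibble(x = rep(1, 50)),
                             function(d) mean(d$x), B = 200, seed = 1), 0)
  expect_warning(bootstrap_sem(dat, function(d) mean(d$x), B = 50,
                               seed = 1), "unstable")
})

test_that("Kendall tau matches a brute-force pair count", {
  expect_equal(kendall_tau(1:4, c(2, 3, 5, 9))$tau, 1)
  expect_equal(kendall_tau(1:4, c(9, 5, 3, 2))$tau, -1)
  set.seed(10)
  for (r in 1:10) {
    x <- sample(100, 5); y <- sample(100, 5)
    conc <- 0; disc <- 0
    for (i in 1:4) for (j in (i + 1):5) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1 else disc <- disc + 1
    }
    expect_equal(kendall_tau(x, y)$tau, (conc - disc) / 10)
  }
  # successive-season cohort check on the published annual ratios:
  # COY/AF in year t vs YRL/AF in year t+1 for the four adjacent pairs
  ann <- bb_annual_recruitment()
  pairs <- dplyr::inner_join(
    dplyr::transmute(ann, year = year + 1, coy_t = coy_per_af),
    dplyr::select(ann, year, yrl_next = yrl_per_af), by = "year")
  kt <- kendall_tau(pairs$coy_t, pairs$yrl_next)
  expect_equal(kt$n, 4)
  expect_equal(kt$tau, 1)
  expect_lt(kt$p, 0.1)  # exact two-sided p for n = 4 is 1/12
  expect_error(kendall_tau(c(1, 1, 1), c(1, 2, 3)), "ties")
})

test_that("95% Wald intervals cover the litter truth at nominal rate", {
  m <- toy_metrics(1990:2013) |>
    dplyr::mutate(
      spring_transition = as.integer(round(
        170 - 0.83 * (year - 1990) +
          c(-4, 3, -2, 5, 0, -3, 2, -5, 4, -1)[(year %% 10) + 1])),
      ice_free_duration = fall_transition - spring_transition)
  tr <- condition_truth(class_mix = c(AF_alone = 0.04, AFwC = 0.84,
                                      SUB = 0.04, AM = 0.08),
                        n_per_year = 60)
  truth <- bb_coy_coefficients()
  set.seed(300)
  cover <- replicate(200, {
    s <- sample.int(1e6, 1)
    mothers <- gen_condition_obs(tr, m, c(1993:1995, 1997, 2011:2013),
                                 seed = s)
    lit <- gen_litter_obs(litter_truth(), mothers, m, seed = s + 1)
    ld <- build_litter_design(lit, m, stage = "COY")
    cf <- tidy(fit_binary_logit(ld$design, ld$response,
                                terms = icebears:::coy_low_aic_terms()))
    want <- unname(truth[cf$term])
    abs(cf$estimate - want) <= 1.96 * cf$se
  })
  expect_gte(mean(cover), 0.92)
  expect_lte(mean(cover), 0.98)
})

test_that("litter-truth coefficients are recovered from simulated data", {
  m <- toy_metrics(1990:2013) |>
    dplyr::mutate(
      spring_transition = as.integer(round(
        170 - 0.83 * (year - 1990) +
          c(-4, 3, -2, 5, 0, -3, 2, -5, 4, -1)[(year %% 10) + 1])),
      ice_free_duration = fall_transition - spring_transition)
  tr <- condition_truth(class_mix = c(AF_alone = 0.05, AFwC = 0.8,
                                      SUB = 0.05, AM = 0.1),
                        n_per_year = 340)
  obs <- gen_condition_obs(tr, m, c(1993:1995, 1997, 2011:2013), seed = 61)
  lit <- gen_litter_obs(litter_truth(), obs, m, seed = 62)
  expect_gt(nrow(lit), 1500)
  ld <- build_litter_design(lit, m, stage = "COY")
  fit <- fit_binary_logit(ld$design, ld$response,
                          terms = c("springtran", "durfree_lag1", "bcs1",
                                    "bcs3"))
  cf <- tidy(fit)
  truth <- bb_coy_coefficients()
  for (i in seq_len(nrow(cf))) {
    expect_lt(abs(cf$estimate[i] - truth[[cf$term[i]]]), 3 * cf$se[i])
  }
})
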