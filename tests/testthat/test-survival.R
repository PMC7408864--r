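# scripted small single-covariate instances, with and without ties
cox_instances <- list(
  list(time = c(1, 2, 3, 4), event = c(1, 1, 1, 0), x = c(0, 1, 0, 1)),
  list(time = c(2, 2, 3, 5), event = c(1, 1, 1, 1), x = c(1, 0, 1, 0)),
  list(time = c(1, 1, 1, 2, 3), event = c(1, 1, 0, 1, 1),
       x = c(0.5, -0.2, 1, 0, -1)),
  list(time = c(4, 4, 4, 4, 6, 7), event = c(1, 1, 1, 0, 1, 1),
       x = c(1, 0, 1, 0, -1, 2)),
  list(time = c(1, 2, 2, 3, 3, 3), event = c(0, 1, 1, 1, 1, 1),
       x = c(0.3, -0.7, 1.2, 0.1, -0.4, 0.8)),
  list(time = c(5, 1, 3, 3, 2, 4), event = c(1, 1, 0, 1, 1, 1),
       x = c(-1, 1, 0, 2, -2, 1))
)

test_that("fit_cox matches the brute-force Efron partial-likelihood oracle", {
  for (inst in cox_instances) {
    df <- data.frame(ttt_months = inst$time, ttt_event = inst$event,
                     g = inst$x)
    fit <- fit_cox(df, "g", "ttt")
    expect_true(fit$converged)
    expect_equal(unname(fit$beta),
                 oracle_cox_beta(inst$time, inst$event, inst$x),
                 tolerance = 1e-3)
  }
})

test_that("monotone partial likelihood is flagged, not silently returned", {
  # the covariate perfectly orders the failures: no finite maximizer
  df <- data.frame(ttt_months = c(1, 2, 3, 4), ttt_event = c(1, 1, 1, 0),
                   g = c(0, 0, 1, 1))
  fit <- fit_cox(df, "g", "ttt")
  expect_false(fit$converged)
  expect_false(is.null(fit$diagnostic))
})

test_that("replicating every subject is handled exactly per the Efron oracle", {
  # the Efron tie correction is not replication-invariant (Breslow is);
  # the fitted value must match the brute-force oracle on the tied data
  # and stay close to the untied estimate
  set.seed(31)
  df <- make_ph_cohort(40, c(G1 = 0.5), censor = 40)
  dup <- rbind(df, df)
  b_dup <- fit_cox(dup, "G1", "ttt")$beta
  b_orig <- fit_cox(df, "G1", "ttt")$beta
  expect_equal(unname(b_dup),
               oracle_cox_beta(dup$ttt_months, dup$ttt_event, dup$G1),
               tolerance = 1e-4)
  expect_lt(abs(b_dup - b_orig) / abs(b_orig), 0.05)
})

test_that("fit_cox input contracts", {
  df <- make_ph_cohort(20)
  df$ttt_event <- 0L
  expect_error(fit_cox(df, "G1", "ttt"), "no events")
  df2 <- make_ph_cohort(20)
  df2$flat <- 1
  expect_error(fit_cox(df2, c("G1", "flat"), "ttt"), "flat")
  expect_error(fit_cox(df2, "missing_gene", "ttt"), "missing_gene")
})

test_that("prognostic index is the linear predictor", {
  set.seed(32)
  df <- make_ph_cohort(60, c(G1 = 1.0), censor = 50)
  fit <- fit_cox(df, "G1", "ttt")
  expect_equal(unname(prognostic_index(fit, df)),
               unname(fit$beta) * df$G1)
  # zero coefficients give zero scores
  fit0 <- fit
  fit0$beta[] <- 0
  expect_true(all(prognostic_index(fit0, df) == 0))
  # shifting a covariate shifts every score by a constant: order unchanged
  df2 <- df; df2$G1 <- df2$G1 + 5
  expect_equal(order(prognostic_index(fit, df2)),
               order(prognostic_index(fit, df)))
  expect_error(prognostic_index(fit, df[, "ttt_months", drop = FALSE]),
               "G1")
})

test_that("median split yields equal-sized deterministic groups", {
  lab <- dichotomize_median(1:10)
  expect_equal(as.vector(table(lab)), c(5L, 5L))
  expect_equal(which(lab == "low"), 1:5)
  lab7 <- dichotomize_median(c(3, 1, 4, 1, 5, 9, 2))
  expect_equal(as.vector(table(lab7)), c(4L, 3L))   # extra sample to low
  # permutation of distinct values keeps per-sample assignment
  set.seed(33)
  v <- rnorm(11); ids <- sprintf("s%02d", 1:11)
  perm <- sample(11)
  lab_a <- dichotomize_median(v, ids)
  lab_b <- dichotomize_median(v[perm], ids[perm])
  expect_equal(lab_b[order(perm)], lab_a)
  # ties at the median still split evenly
  lab_t <- dichotomize_median(c(1, 2, 2, 2, 2, 3), letters[1:6])
  expect_equal(as.vector(table(lab_t)), c(3L, 3L))
  expect_error(dichotomize_median(rep(2, 5)), "identical")
  expect_error(dichotomize_median(3), "at least 2")
})

test_that("group hazard ratio inverts when labels swap", {
  set.seed(34)
  df <- make_two_group(60, hr = 3)
  res <- group_hazard_ratio(df, df$labels, "ttt")
  swapped <- factor(ifelse(df$labels == "low", "high", "low"),
                    levels = c("low", "high"))
  res2 <- group_hazard_ratio(df, swapped, "ttt")
  expect_equal(res2$hr, 1 / res$hr, tolerance = 1e-6)
  expect_equal(res2$logrank_p, res$logrank_p)
  expect_true(res$hr > 1)
})

test_that("a group with zero events yields a flagged infinite HR", {
  df <- data.frame(ttt_months = c(1, 2, 3, 10, 11, 12),
                   ttt_event = c(1, 1, 1, 0, 0, 0),
                   os_months = 1, os_event = 1)
  labels <- factor(c("high", "high", "high", "low", "low", "low"),
                   levels = c("low", "high"))
  res <- group_hazard_ratio(df, labels, "ttt")
  expect_true(res$degenerate)
  expect_equal(res$hr, Inf)
})

test_that("Kaplan-Meier estimator matches closed forms", {
  # no events: flat at 1
  km0 <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km0$survival == 1))
  # four distinct events, no censoring: steps of 1/4
  km4 <- km_estimate(1:4, rep(1, 4))
  expect_equal(km4$survival, c(1, 0.75, 0.5, 0.25, 0))
  expect_equal(km4$time, c(0, 1, 2, 3, 4))
  # hand-computed product-limit with interleaved censoring (the curve
  # also carries censoring times; compare at the origin and event times)
  km6 <- km_estimate(1:6, c(1, 0, 1, 1, 0, 1))
  ev <- km6[km6$time %in% c(0, 1, 3, 4, 6), ]
  expect_equal(ev$survival,
               c(1, 5/6, 5/6 * 3/4, 5/6 * 3/4 * 2/3, 0),
               tolerance = 1e-12)
  expect_equal(ev$at_risk, c(6, 6, 4, 3, 1))
  expect_true(all(diff(km6$survival) <= 0))
  # no censoring: equals the empirical survival function
  set.seed(35)
  t <- rexp(40)
  km <- km_estimate(t, rep(1, 40))
  ecdf_surv <- vapply(km$time, function(u) mean(t > u), numeric(1))
  expect_equal(km$survival, ecdf_surv, tolerance = 1e-12)
  expect_error(km_estimate(1:3, c(1, 1, 1),
                           factor(rep("a", 3), levels = c("a", "b"))),
               "empty group")
})

test_that("log-rank statistic is zero for identical group experience", {
  t <- c(1, 3, 5, 7); e <- c(1, 1, 0, 1)
  res <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_error(logrank_test(t, e, rep("a", 4)), "two")
})

test_that("log-rank p agrees with a permutation null on a small cohort", {
  set.seed(36)
  t <- rexp(30); e <- rbinom(30, 1, 0.8)
  g <- rep(c("a", "b"), 15)
  obs <- logrank_test(t, e, g)
  perm <- replicate(2000, logrank_test(t, e, sample(g))$statistic)
  p_perm <- mean(perm >= obs$statistic)
  mc_se <- sqrt(p_perm * (1 - p_perm) / 2000)
  expect_lt(abs(obs$p - p_perm), 4 * mc_se + 0.02)
})

test_that("single-gene and single-gene-signature splits coincide", {
  set.seed(37)
  df <- make_ph_cohort(120, c(G1 = 0.8), censor = 60)
  sg <- single_gene_hr(df, "G1", "ttt")
  sig <- signature_hr(df, "G1", "ttt")
  # with a positive fitted coefficient the PI split is the expression split
  expect_true(sig$fit$beta > 0)
  expect_equal(sig$labels, sg$labels)
  expect_equal(sig$hr, sg$hr)
  expect_error(single_gene_hr(df, "nope", "ttt"), "nope")
  df$flat <- 1
  expect_error(single_gene_hr(df, "flat", "ttt"), "identical")
})

test_that("signature_hr is invariant to gene input order", {
  set.seed(38)
  df <- make_ph_cohort(150, c(G1 = 0.8, G2 = -0.5, G3 = 0.3), censor = 60)
  a <- signature_hr(df, c("G1", "G2", "G3"), "ttt")
  b <- signature_hr(df, c("G3", "G1", "G2"), "ttt")
  expect_equal(a$hr, b$hr)
  expect_equal(a$pi, b$pi)
})

test_that("leave-one-out contributions rank the planted driver first", {
  set.seed(39)
  df <- make_ph_cohort(400, c(DRIVER = 1.2, NOISE = 0), censor = 60)
  res <- leave_one_out_contributions(df, c("NOISE", "DRIVER"), "ttt",
                                     top_k = 1L)
  expect_equal(res$top, "DRIVER")
  expect_gt(res$table$contribution[res$table$gene == "DRIVER"],
            res$table$contribution[res$table$gene == "NOISE"])
  expect_error(
    leave_one_out_contributions(df, c("DRIVER", "NOISE"), "ttt", top_k = 3L),
    "pool")
  expect_error(leave_one_out_contributions(df, "DRIVER", "ttt"), "2 genes")
})

test_that("multivariate model recovers independent planted effects", {
  set.seed(40)
  cfg <- synthetic_config(cohort_n = 1000L,
                          ttt_betas = c(DNPEP = 0.6),
                          os_betas = c(DNPEP = 0.6),
                          ighv_beta = 0, del17p_beta = 0.9,
                          censor_window = 300, seed = 40L)
  cohort <- generate_survival_cohort(cfg)$cohort
  # correctly specified model: both planted effects within 3 SE
  true_fit <- fit_cox(cohort, c("DNPEP", "del17p"), "ttt")
  expect_true(true_fit$converged)
  expect_lt(abs(true_fit$beta[["DNPEP"]] - 0.6), 3 * true_fit$se[["DNPEP"]])
  expect_lt(abs(true_fit$beta[["del17p"]] - 0.9), 3 * true_fit$se[["del17p"]])
  # clinical model with the median-split gene stays prognostic
  res <- multivariate_cox(cohort, "ttt", gene = "DNPEP")
  fit <- res$multivariate
  expect_true(fit$converged)
  expect_lt(fit$wald_p[[paste0("DNPEP", "_high")]], 0.05)
  expect_gt(fit$beta[["del17p"]], 0)
  expect_equal(res$n_used + res$n_excluded, 1000L)
  cohort$del17p <- 0L
  expect_error(multivariate_cox(cohort, "ttt", gene = "DNPEP"), "del17p")
})
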