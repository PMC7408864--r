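# a small configuration that keeps generator tests fast
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_datasets = 4L, samples_range = c(30L, 60L), n_genes = 50L,
         n_planted = 5L, planted_support = 3L, cohort_n = 80L,
         ttt_betas = c(DNPEP = 0.7), os_betas = c(DNPEP = 0.7)),
    list(...))
  do.call(synthetic_config, args)
}

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(synthetic_config(planted_rho = 1.2))
  expect_error(synthetic_config(outlier_fraction = 0.5))
  expect_error(synthetic_config(baseline_hazard = 0), "positive")
  expect_error(synthetic_config(qpcr_sigma = -1))
  expect_error(synthetic_config(rai_sizes = c(20L, 10L, 5L)), "sum")
  expect_error(synthetic_config(drugs = list(A = c(m = -1, dm = 1),
                                             B = c(m = 1, dm = 1))),
               "positive m")
})

test_that("identical seeds reproduce every generator byte for byte", {
  cfg <- small_config(seed = 5L)
  a <- generate_expression_collection(cfg)
  b <- generate_expression_collection(cfg)
  expect_identical(lapply(a$datasets, `[[`, "values"),
                   lapply(b$datasets, `[[`, "values"))
  expect_identical(a$truth, b$truth)
  expect_identical(generate_survival_cohort(cfg),
                   generate_survival_cohort(cfg))
  expect_identical(generate_qpcr_table(cfg), generate_qpcr_table(cfg))
  expect_identical(generate_dose_response(cfg),
                   generate_dose_response(cfg))
  # a different seed changes the data
  expect_false(identical(
    generate_expression_collection(small_config(seed = 6L))$datasets[[1]]$values,
    a$datasets[[1]]$values))
})

test_that("no generated table contains NaN or infinite values", {
  cfg <- small_config(seed = 8L, outlier_fraction = 0.1)
  expr <- generate_expression_collection(cfg)
  for (ds in expr$datasets) expect_true(all(is.finite(ds$values)))
  sc <- generate_survival_cohort(cfg)$cohort
  expect_true(all(is.finite(as.matrix(
    sc[, setdiff(names(sc), c("sample_id", "ighv"))]))))
  expect_true(all(is.finite(generate_qpcr_table(cfg)$records$ct)))
  dr <- generate_dose_response(cfg)
  expect_true(all(is.finite(dr$single$fa)))
  expect_true(all(is.finite(dr$combination$fa)))
})

test_that("planted single-kinase correlation matches its target rho", {
  cfg <- synthetic_config(n_datasets = 1L, samples_range = c(200L, 200L),
                          n_genes = 20L, n_planted = 3L,
                          planted_kinases = 1L, planted_support = 1L,
                          planted_rho = 0.9, seed = 10L)
  x <- generate_expression_collection(cfg)
  ds <- x$datasets[[1]]
  for (g in x$truth$positive_genes) {
    k <- x$truth$support[[g]]$kinases[[1]]
    r <- cor(ds$values[g, ], ds$values[k, ])
    expect_lt(abs(r - 0.9), 0.1)
  }
  # background genes stay uncorrelated
  bg <- cor(ds$values["BG0001", ], ds$values["ZAP70", ])
  expect_lt(abs(bg), 0.25)
})

test_that("planting none yields an empty positive set and collisions error", {
  cfg <- small_config(n_planted = 0L)
  x <- generate_expression_collection(cfg)
  expect_length(x$truth$positive_genes, 0)
  cfg2 <- small_config(planted_names = "ZAP70")
  expect_error(generate_expression_collection(cfg2), "collides")
})

test_that("null survival cohort event times are exponential(h0)", {
  cfg <- synthetic_config(cohort_n = 5000L, ttt_betas = numeric(0),
                          os_betas = numeric(0), ighv_beta = 0,
                          del17p_beta = 0, baseline_hazard = 0.02,
                          censor_window = 1e7, seed = 12L)
  sc <- generate_survival_cohort(cfg, genes = "G1")
  expect_true(all(sc$cohort$ttt_event == 1L))
  ks <- ks.test(sc$cohort$ttt_months, pexp, rate = 0.02)
  expect_gt(ks$p.value, 0.01)
})

test_that("a vanishing censor window censors every sample", {
  cfg <- small_config(censor_window = 0)
  sc <- generate_survival_cohort(cfg)$cohort
  expect_true(all(sc$ttt_event == 0L))
  expect_true(all(sc$os_event == 0L))
})

test_that("a planted log-2 hazard coefficient is recovered by the Cox fit", {
  cfg <- synthetic_config(cohort_n = 1000L,
                          ttt_betas = c(DNPEP = log(2)),
                          os_betas = c(DNPEP = log(2)),
                          ighv_beta = 0, del17p_beta = 0,
                          censor_window = 200, seed = 13L)
  sc <- generate_survival_cohort(cfg)
  fit <- fit_cox(sc$cohort, "DNPEP", "ttt")
  expect_true(fit$converged)
  expect_lt(abs(fit$beta[["DNPEP"]] - log(2)), 3 * fit$se[["DNPEP"]])
})

test_that("generated survival data satisfy proportional hazards", {
  ok <- vapply(1:40, function(s) {
    cfg <- synthetic_config(cohort_n = 300L,
                            ttt_betas = c(DNPEP = 0.7),
                            os_betas = c(DNPEP = 0.7),
                            censor_window = 200, seed = s)
    d <- generate_survival_cohort(cfg)$cohort
    fit <- survival::coxph(survival::Surv(ttt_months, ttt_event) ~ DNPEP,
                           data = d)
    survival::cox.zph(fit)$table["DNPEP", "p"] > 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("qPCR default strata are 20/10/4 with matched Binet labels", {
  q <- generate_qpcr_table(synthetic_config(seed = 14L))
  one <- subset(q$records, gene == "DNPEP")
  expect_equal(as.vector(table(one$rai)[c("0", "I-II", "III-IV")]),
               c(20L, 10L, 4L))
  expect_equal(sum(one$binet != "A"), 5L)
  # advanced Binet stages sit in the highest Rai strata
  expect_true(all(one$rai[one$binet != "A"] %in% c("I-II", "III-IV")))
  expect_true(all(one$ct > 0 & one$ct < 45))
})
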