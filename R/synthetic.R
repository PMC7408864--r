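#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the four generators with defaults emulating
#' the study conditions the pipeline is designed for: a collection of 14
#' B-cell expression datasets screened against a 7-kinase BcR-signaling
#' panel, a 107-sample survival cohort, a 34-sample qPCR table with
#' 20/10/4 Rai strata (29/5 Binet), and median-effect dose-response
#' curves for an inhibitor pair. One pseudo-random stream per generator
#' is split from `seed`, so adding or re-running one generator never
#' perturbs the others, and a given seed fully determines every output.
#'
#' @param n_datasets Number of expression datasets (default 14).
#' @param samples_range Inclusive range of per-dataset sample counts
#'   (default 30 to 200; per-dataset sizes are drawn from this range as
#'   the source collections' sizes are heterogeneous).
#' @param n_genes Number of non-kinase genes per dataset (default 2000).
#' @param kinase_panel BcR-signaling kinase symbols (default ZAP70,
#'   AKT1, AKT2, BTK, MAPK1, MAPK3, PIK3CD).
#' @param kinase_cor Pairwise correlation between panel kinases via a
#'   shared latent signaling-activity factor (default 0.6): BcR kinases
#'   co-express, which is what makes multi-kinase-correlated genes
#'   possible at all.
#' @param n_planted Number of planted positive genes (default 100).
#' @param planted_rho Correlation strength between a planted gene and
#'   its kinase target (default 0.85), in (0, 1).
#' @param planted_kinases Number of kinases (anchor included) each
#'   planted gene tracks (default 3).
#' @param planted_support Number of datasets in which the correlation is
#'   planted (default 6).
#' @param planted_names Optional names for the first planted genes
#'   (default `"DNPEP"`); the rest are `SIG002`, `SIG003`, ...
#' @param outlier_fraction Fraction of samples per dataset replaced by
#'   gross outliers drawn from a 10-fold-wider distribution (default 0;
#'   at most 0.3).
#' @param cohort_n Survival-cohort size (default 107).
#' @param ttt_betas,os_betas Named log-hazard coefficients per gene for
#'   the time-to-treatment and overall-survival endpoints. Defaults
#'   plant `DNPEP` as a dual-endpoint driver plus one favorable and one
#'   adverse single-endpoint driver each.
#' @param ighv_beta Log-hazard of unmutated IGHV status (default 0.4).
#' @param del17p_beta Log-hazard of 17p13 deletion (default 0.9).
#' @param ighv_prevalence Probabilities of mutated / unmutated / unknown
#'   IGHV status (default 0.48 / 0.45 / 0.07).
#' @param del17p_prevalence Probability of 17p13 deletion (default
#'   0.08).
#' @param baseline_hazard Baseline event rate, 1/months (default 0.01).
#' @param censor_window Upper bound of the uniform censoring time in
#'   months (default 120).
#' @param qpcr_n qPCR sample count (default 34).
#' @param rai_sizes Rai stratum sizes, low/intermediate/high risk
#'   (default 20, 10, 4; must sum to `qpcr_n`).
#' @param binet_advanced Number of Binet B/C samples (default 5),
#'   assigned to the highest-risk samples.
#' @param stage_effect Planted log2 expression shift per Rai risk
#'   stratum (default 1, i.e. a 2-fold increase per stratum).
#' @param qpcr_sigma Ct measurement noise SD in cycles (default 0.3;
#'   non-negative).
#' @param qpcr_mu_ref Mean reference-gene Ct (default 25 cycles).
#' @param qpcr_base_log2 Baseline target log2 expression relative to the
#'   reference (default 2).
#' @param qpcr_reference,qpcr_target Gene symbols of the housekeeping
#'   and target genes (defaults ABL1, DNPEP).
#' @param drugs Named list of per-drug median-effect parameters
#'   `c(m = , dm = )`, both positive. Defaults: an aminopeptidase
#'   inhibitor (`DI93293`, m 1.2, Dm 10 uM) and a BH3 mimetic
#'   (`ABT737`, m 1.5, Dm 0.3 uM).
#' @param synergy_factor Dose-sparing factor of the generated
#'   combinations (default 1 = Loewe additive; 0.5 plants two-fold
#'   synergy, i.e. a true CI of 0.5).
#' @param dose_noise SD of multiplicative log-odds noise on generated
#'   fractions affected (default 0 = noise-free).
#' @param seed Master seed (default 1).
#' @return Validated list of class `kinsig_config`.
#' @export
synthetic_config <- function(n_datasets = 14L,
                             samples_range = c(30L, 200L),
                             n_genes = 2000L,
                             kinase_panel = c("ZAP70", "AKT1", "AKT2",
                                              "BTK", "MAPK1", "MAPK3",
                                              "PIK3CD"),
                             kinase_cor = 0.6,
                             n_planted = 100L,
                             planted_rho = 0.85,
                             planted_kinases = 3L,
                             planted_support = 6L,
                             planted_names = "DNPEP",
                             outlier_fraction = 0,
                             cohort_n = 107L,
                             ttt_betas = c(DNPEP = 0.7, SIG002 = 0.5,
                                           SIG003 = -0.5),
                             os_betas = c(DNPEP = 0.7, SIG004 = 0.5,
                                          SIG005 = -0.5),
                             ighv_beta = 0.4,
                             del17p_beta = 0.9,
                             ighv_prevalence = c(mutated = 0.48,
                                                 unmutated = 0.45,
                                                 unknown = 0.07),
                             del17p_prevalence = 0.08,
                             baseline_hazard = 0.01,
                             censor_window = 120,
                             qpcr_n = 34L,
                             rai_sizes = c(20L, 10L, 4L),
                             binet_advanced = 5L,
                             stage_effect = 1,
                             qpcr_sigma = 0.3,
                             qpcr_mu_ref = 25,
                             qpcr_base_log2 = 2,
                             qpcr_reference = "ABL1",
                             qpcr_target = "DNPEP",
                             drugs = list(DI93293 = c(m = 1.2, dm = 10),
                                          ABT737 = c(m = 1.5, dm = 0.3)),
                             synergy_factor = 1,
                             dose_noise = 0,
                             seed = 1L) {
  cfg <- list(
    n_datasets = as.integer(n_datasets),
    samples_range = as.integer(samples_range),
    n_genes = as.integer(n_genes),
    kinase_panel = normalize_panel(kinase_panel),
    kinase_cor = kinase_cor,
    n_planted = as.integer(n_planted),
    planted_rho = planted_rho,
    planted_kinases = as.integer(planted_kinases),
    planted_support = as.integer(planted_support),
    planted_names = as.character(planted_names),
    outlier_fraction = outlier_fraction,
    cohort_n = as.integer(cohort_n),
    ttt_betas = ttt_betas, os_betas = os_betas,
    ighv_beta = ighv_beta, del17p_beta = del17p_beta,
    ighv_prevalence = ighv_prevalence,
    del17p_prevalence = del17p_prevalence,
    baseline_hazard = baseline_hazard,
    censor_window = censor_window,
    qpcr_n = as.integer(qpcr_n),
    rai_sizes = as.integer(rai_sizes),
    binet_advanced = as.integer(binet_advanced),
    stage_effect = stage_effect,
    qpcr_sigma = qpcr_sigma, qpcr_mu_ref = qpcr_mu_ref,
    qpcr_base_log2 = qpcr_base_log2,
    qpcr_reference = qpcr_reference, qpcr_target = qpcr_target,
    drugs = drugs, synergy_factor = synergy_factor,
    dose_noise = dose_noise,
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      n_datasets >= 1L, n_genes >= 1L, cohort_n >= 2L, qpcr_n >= 2L,
      length(samples_range) == 2L, samples_range[1L] >= 2L,
      samples_range[2L] >= samples_range[1L],
      length(kinase_panel) >= 1L,
      kinase_cor >= 0, kinase_cor < 1,
      n_planted >= 0L,
      planted_rho > 0, planted_rho < 1,
      planted_kinases >= 1L, planted_kinases <= length(kinase_panel),
      planted_support >= 1L, planted_support <= n_datasets,
      outlier_fraction >= 0, outlier_fraction <= 0.3,
      censor_window >= 0,
      length(rai_sizes) == 3L, all(rai_sizes >= 0L),
      binet_advanced >= 0L, binet_advanced <= qpcr_n,
      qpcr_sigma >= 0,
      synergy_factor > 0, dose_noise >= 0
    )
  })
  if (cfg$baseline_hazard <= 0) stop("baseline hazard must be positive")
  if (sum(cfg$rai_sizes) != cfg$qpcr_n) {
    stop("Rai stratum sizes must sum to qpcr_n")
  }
  if (abs(sum(cfg$ighv_prevalence) - 1) > 1e-8) {
    stop("IGHV prevalences must sum to 1")
  }
  for (d in names(cfg$drugs)) {
    p <- cfg$drugs[[d]]
    if (!all(c("m", "dm") %in% names(p)) || p[["m"]] <= 0 || p[["dm"]] <= 0) {
      stop("drug '", d, "' needs positive m and dm")
    }
  }
  structure(cfg, class = "kinsig_config")
}

# deterministic sub-stream seeds split from the master seed
substream_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) + stream * 1000003L
}

#' Generate a multi-dataset expression collection with planted truth
#'
#' Emulates the screening input: `n_datasets` log2-scale expression
#' matrices, each holding the kinase panel plus `n_genes` genes.
#' The panel kinases share a latent signaling-activity factor (pairwise
#' correlation `kinase_cor`). Each planted positive gene tracks the
#' anchor (first panel kinase) plus `planted_kinases - 1` randomly chosen
#' other kinases in `planted_support` randomly chosen datasets:
#' in a supported dataset the gene is `rho * target + sqrt(1 - rho^2) *
#' noise` (target = standardized mean of its kinases), then affinely
#' rescaled to a gene-specific baseline and spread. Background genes are
#' independent of the kinases everywhere. Optional outlier samples are
#' redrawn from a 10-fold-wider distribution.
#'
#' @param config A [synthetic_config()].
#' @return List with `datasets` (list of [expression_dataset()]) and
#'   `truth` (planted gene names, per-gene kinase/dataset support, rho).
#' @export
generate_expression_collection <- function(config) {
  stopifnot(inherits(config, "kinsig_config"))
  cfg <- config
  genes <- planted_gene_names(cfg)
  collision <- intersect(genes, cfg$kinase_panel)
  if (length(collision)) {
    stop("kinase panel collides with gene names: ",
         paste(collision, collapse = ", "))
  }
  planted <- utils::head(genes, cfg$n_planted)
  anchor <- cfg$kinase_panel[[1L]]
  others <- cfg$kinase_panel[-1L]

  assign <- withr::with_seed(substream_seed(cfg$seed, 1L), {
    sizes <- sample(seq.int(cfg$samples_range[1L], cfg$samples_range[2L]),
                    cfg$n_datasets, replace = TRUE)
    support <- lapply(planted, function(g) {
      extra <- if (cfg$planted_kinases > 1L) {
        sample(others, cfg$planted_kinases - 1L)
      } else character(0L)
      list(kinases = c(anchor, extra),
           datasets = sort(sample.int(cfg$n_datasets, cfg$planted_support)))
    })
    names(support) <- planted
    list(sizes = sizes, support = support)
  })

  datasets <- lapply(seq_len(cfg$n_datasets), function(d) {
    withr::with_seed(substream_seed(cfg$seed, 100L + d), {
      simulate_dataset(cfg, d, assign$sizes[[d]], genes, assign$support)
    })
  })

  truth <- list(
    positive_genes = planted,
    support = assign$support,
    rho = cfg$planted_rho,
    kinase_panel = cfg$kinase_panel,
    anchor = anchor
  )
  list(datasets = datasets, truth = truth)
}

planted_gene_names <- function(cfg) {
  planted <- character(0L)
  if (cfg$n_planted > 0L) {
    planted <- utils::head(cfg$planted_names, cfg$n_planted)
    if (length(planted) < cfg$n_planted) {
      planted <- c(planted, sprintf("SIG%03d",
                                    seq.int(length(planted) + 1L,
                                            cfg$n_planted)))
    }
  }
  n_bg <- cfg$n_genes - cfg$n_planted
  if (n_bg < 0L) stop("n_planted exceeds n_genes")
  c(planted, sprintf("BG%04d", seq_len(n_bg)))
}

simulate_dataset <- function(cfg, d, n, genes, support) {
  panel <- cfg$kinase_panel
  k <- length(panel)
  latent <- stats::rnorm(n)
  kin_std <- sqrt(cfg$kinase_cor) * matrix(latent, k, n, byrow = TRUE) +
    sqrt(1 - cfg$kinase_cor) * matrix(stats::rnorm(k * n), k, n)
  rownames(kin_std) <- panel
  kin_vals <- 8 + kin_std

  ng <- length(genes)
  mu <- stats::runif(ng, 6, 12)
  sdv <- stats::runif(ng, 0.5, 1.5)
  z <- matrix(stats::rnorm(ng * n), ng, n)
  for (g in names(support)) {
    if (!d %in% support[[g]]$datasets) next
    kset <- support[[g]]$kinases
    s <- length(kset)
    target <- colSums(kin_std[kset, , drop = FALSE]) /
      sqrt(s + s * (s - 1) * cfg$kinase_cor)
    i <- match(g, genes)
    z[i, ] <- cfg$planted_rho * target +
      sqrt(1 - cfg$planted_rho^2) * stats::rnorm(n)
  }
  vals <- mu + sdv * z
  rownames(vals) <- genes

  m <- rbind(kin_vals, vals)
  n_out <- floor(cfg$outlier_fraction * n)
  if (n_out > 0L) {
    out <- sample.int(n, n_out)
    row_mu <- c(rep(8, k), mu)
    row_sd <- c(rep(1, k), sdv)
    m[, out] <- row_mu + 10 * row_sd *
      matrix(stats::rnorm(nrow(m) * n_out), nrow(m), n_out)
  }
  id <- sprintf("DS%02d", d)
  colnames(m) <- sprintf("%s_S%03d", id, seq_len(n))
  expression_dataset(m, id)
}

#' Generate a survival cohort under a proportional-hazards model
#'
#' Per-sample gene expression is standard normal on the log2 scale.
#' Event times for the two endpoints are drawn from exponential hazards
#' `h0 * exp(PI)` with endpoint-specific planted coefficients plus
#' clinical effects of unmutated IGHV status and 17p13 deletion, and
#' censored by independent uniform times on `[0, censor_window]`. The
#' two endpoints share covariates but use independent noise.
#' Proportional hazards hold by construction.
#'
#' @param config A [synthetic_config()].
#' @param genes Gene universe of the cohort; defaults to the planted
#'   coefficient genes plus five noise genes. All coefficient genes must
#'   be included.
#' @return List with `cohort` (data frame: `sample_id`, `ttt_months`,
#'   `ttt_event`, `os_months`, `os_event`, `ighv`, `del17p`, one column
#'   per gene) and `truth` (the planted coefficients and rates).
#' @export
generate_survival_cohort <- function(config, genes = NULL) {
  stopifnot(inherits(config, "kinsig_config"))
  cfg <- config
  if (cfg$baseline_hazard <= 0) stop("baseline hazard must be positive")
  beta_genes <- union(names(cfg$ttt_betas), names(cfg$os_betas))
  if (is.null(genes)) {
    genes <- union(beta_genes, sprintf("NOISE%02d", 1:5))
  }
  missing <- setdiff(beta_genes, genes)
  if (length(missing)) {
    stop("coefficient gene(s) not in gene universe: ",
         paste(missing, collapse = ", "))
  }
  n <- cfg$cohort_n
  withr::with_seed(substream_seed(cfg$seed, 2L), {
    X <- matrix(stats::rnorm(n * length(genes)), n, length(genes),
                dimnames = list(NULL, genes))
    p_mut <- cfg$ighv_prevalence[["mutated"]] /
      (cfg$ighv_prevalence[["mutated"]] + cfg$ighv_prevalence[["unmutated"]])
    unmutated <- stats::rbinom(n, 1L, 1 - p_mut)
    ighv <- ifelse(unmutated == 1L, "unmutated", "mutated")
    ighv[stats::runif(n) < cfg$ighv_prevalence[["unknown"]]] <- "unknown"
    del17p <- stats::rbinom(n, 1L, cfg$del17p_prevalence)
    clinical_lp <- cfg$ighv_beta * unmutated + cfg$del17p_beta * del17p

    draw_endpoint <- function(betas) {
      lp <- clinical_lp
      if (length(betas)) {
        lp <- lp + as.vector(X[, names(betas), drop = FALSE] %*% betas)
      }
      t_event <- stats::rexp(n) / (cfg$baseline_hazard * exp(lp))
      t_cens <- stats::runif(n, 0, cfg$censor_window)
      list(time = pmin(t_event, t_cens),
           event = as.integer(t_event <= t_cens))
    }
    ttt <- draw_endpoint(cfg$ttt_betas)
    os <- draw_endpoint(cfg$os_betas)

    cohort <- data.frame(
      sample_id = sprintf("P%03d", seq_len(n)),
      ttt_months = ttt$time, ttt_event = ttt$event,
      os_months = os$time, os_event = os$event,
      ighv = ighv, del17p = del17p,
      X, check.names = FALSE, stringsAsFactors = FALSE
    )
    list(cohort = cohort,
         truth = list(ttt_betas = cfg$ttt_betas, os_betas = cfg$os_betas,
                      ighv_beta = cfg$ighv_beta,
                      del17p_beta = cfg$del17p_beta,
                      baseline_hazard = cfg$baseline_hazard))
  })
}

#' Generate a qPCR Ct table with stage-dependent expression
#'
#' Samples are assigned Rai strata of the configured sizes (low /
#' intermediate / high risk) and Binet stages (advanced B/C labels go to
#' the highest-risk samples). The target gene's planted log2 expression
#' is `qpcr_base_log2 + stage_effect * risk_level` (levels 0, 1, 2);
#' reference Ct is `Normal(mu_ref, sigma)` and target Ct is
#' `mu_ref - log2(expression) + Normal(0, sigma)`, so with `sigma = 0`
#' the relative expression inverts exactly to the planted fold change.
#'
#' @param config A [synthetic_config()].
#' @return List with `records` (long data frame: `sample_id`, `gene`,
#'   `ct`, `rai`, `binet`) and `truth` (planted per-stratum log2
#'   expression).
#' @export
generate_qpcr_table <- function(config) {
  stopifnot(inherits(config, "kinsig_config"))
  cfg <- config
  if (cfg$qpcr_sigma < 0) stop("Ct noise sigma must be non-negative")
  level <- rep(0:2, cfg$rai_sizes)
  rai <- c("0", "I-II", "III-IV")[level + 1L]
  n <- cfg$qpcr_n
  # advanced Binet labels attach to the highest Rai risk levels
  binet <- rep("A", n)
  if (cfg$binet_advanced > 0L) {
    adv <- order(level, seq_len(n), decreasing = TRUE)[
      seq_len(cfg$binet_advanced)]
    n_c <- floor(cfg$binet_advanced / 2)
    binet[adv] <- rep(c("B", "C"), c(cfg$binet_advanced - n_c, n_c))
  }
  withr::with_seed(substream_seed(cfg$seed, 3L), {
    log2_expr <- cfg$qpcr_base_log2 + cfg$stage_effect * level
    ct_ref <- stats::rnorm(n, cfg$qpcr_mu_ref, cfg$qpcr_sigma)
    ct_tgt <- cfg$qpcr_mu_ref - log2_expr +
      stats::rnorm(n, 0, cfg$qpcr_sigma)
    ids <- sprintf("Q%03d", seq_len(n))
    records <- rbind(
      data.frame(sample_id = ids, gene = cfg$qpcr_reference, ct = ct_ref,
                 rai = rai, binet = binet, stringsAsFactors = FALSE),
      data.frame(sample_id = ids, gene = cfg$qpcr_target, ct = ct_tgt,
                 rai = rai, binet = binet, stringsAsFactors = FALSE)
    )
    list(records = records,
         truth = list(base_log2 = cfg$qpcr_base_log2,
                      stage_effect = cfg$stage_effect,
                      sigma = cfg$qpcr_sigma,
                      rai_sizes = cfg$rai_sizes))
  })
}

#' Generate median-effect dose-response and combination tables
#'
#' Single-agent fractions affected follow the median-effect equation
#' `fa = D^m / (D^m + Dm^m)` on a geometric dose grid around each drug's
#' `Dm`. Combination points for the first two configured drugs are built
#' at a grid of target effects: the dose pair achieving effect `fa` is
#' `(lambda * sf * Dx1(fa), (1 - lambda) * sf * Dx2(fa))` with a sweep
#' of mixing fractions `lambda` (a non-constant-ratio design), so the
#' true combination index equals the synergy factor `sf` at every point
#' (1 = Loewe additive). Optional log-odds noise perturbs the observed
#' fractions.
#'
#' @param config A [synthetic_config()].
#' @return List with `single` (drug, dose, fa), `combination` (drug1,
#'   dose1, drug2, dose2, fa) and `truth` (per-drug `(m, dm)` and the
#'   synergy factor).
#' @export
generate_dose_response <- function(config) {
  stopifnot(inherits(config, "kinsig_config"))
  cfg <- config
  drugs <- cfg$drugs
  if (length(drugs) < 2L) stop("need at least two configured drugs")
  withr::with_seed(substream_seed(cfg$seed, 4L), {
    noisy <- function(fa) {
      if (cfg$dose_noise == 0) return(fa)
      odds <- fa / (1 - fa) * exp(stats::rnorm(length(fa), 0,
                                               cfg$dose_noise))
      odds / (1 + odds)
    }
    single <- do.call(rbind, lapply(names(drugs), function(dn) {
      p <- drugs[[dn]]
      doses <- p[["dm"]] * 2^seq(-3, 3)
      if (any(doses <= 0)) stop("doses must be positive")
      fa <- doses^p[["m"]] / (doses^p[["m"]] + p[["dm"]]^p[["m"]])
      data.frame(drug = dn, dose = doses, fa = noisy(fa),
                 stringsAsFactors = FALSE)
    }))
    pair <- names(drugs)[1:2]
    p1 <- drugs[[pair[[1L]]]]; p2 <- drugs[[pair[[2L]]]]
    fa_targets <- seq(0.3, 0.75, by = 0.05)
    lambda <- seq(0.25, 0.75, length.out = length(fa_targets))
    dx <- function(p, fa) p[["dm"]] * (fa / (1 - fa))^(1 / p[["m"]])
    combination <- data.frame(
      drug1 = pair[[1L]],
      dose1 = lambda * cfg$synergy_factor * dx(p1, fa_targets),
      drug2 = pair[[2L]],
      dose2 = (1 - lambda) * cfg$synergy_factor * dx(p2, fa_targets),
      fa = noisy(fa_targets),
      stringsAsFactors = FALSE
    )
    list(single = single, combination = combination,
         truth = list(params = drugs,
                      synergy_factor = cfg$synergy_factor))
  })
}

#' Write generator outputs to disk
#'
#' Expression datasets go to TSV (see [write_expression_dataset()]);
#' cohort, Ct and dose tables to CSV; planted truth to JSON.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @param truth Planted-truth list from a generator.
#' @export
write_planted_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
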