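#' @importFrom survival Surv coxph coxph.control survfit survdiff
NULL

endpoint_cols <- function(endpoint = c("ttt", "os")) {
  endpoint <- match.arg(endpoint)
  switch(endpoint,
         ttt = c(time = "ttt_months", event = "ttt_event"),
         os  = c(time = "os_months",  event = "os_event"))
}

# extract (time, event) for an endpoint with validation
endpoint_data <- function(cohort, endpoint) {
  cols <- endpoint_cols(endpoint)
  missing <- setdiff(unname(cols), names(cohort))
  if (length(missing)) {
    stop("cohort lacks endpoint column(s): ", paste(missing, collapse = ", "))
  }
  time <- cohort[[cols[["time"]]]]
  event <- cohort[[cols[["event"]]]]
  if (any(time < 0, na.rm = TRUE)) stop("negative survival times")
  if (!all(event %in% c(0, 1))) stop("event indicators must be 0/1")
  list(time = time, event = as.integer(event))
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood with the Efron correction for
#' tied event times (ties at month resolution are common in clinical
#' survival data), iterated to tight convergence. Monotone-likelihood /
#' non-converged fits are returned with `converged = FALSE` rather than
#' silently.
#'
#' @param cohort Data frame with endpoint columns (`ttt_months`,
#'   `ttt_event` or `os_months`, `os_event`) and one column per covariate.
#' @param covariates Character vector of covariate column names; each
#'   must be present and non-constant.
#' @param endpoint `"ttt"` (time to treatment) or `"os"` (overall
#'   survival).
#' @return An object of class `kinsig_coxfit`: list with `covariates`,
#'   `beta` (log-hazard coefficients), `se`, `wald_p`, `loglik`,
#'   `converged`, `n`, `n_events`.
#' @export
fit_cox <- function(cohort, covariates, endpoint = c("ttt", "os")) {
  endpoint <- match.arg(endpoint)
  stopifnot(is.data.frame(cohort), length(covariates) >= 1L)
  missing <- setdiff(covariates, names(cohort))
  if (length(missing)) {
    stop("cohort lacks covariate(s): ", paste(missing, collapse = ", "))
  }
  ed <- endpoint_data(cohort, endpoint)
  if (sum(ed$event) < 1L) stop("no events for endpoint '", endpoint, "'")
  X <- cohort[, covariates, drop = FALSE]
  const <- vapply(X, function(v) length(unique(v[!is.na(v)])) <= 1L,
                  logical(1L))
  if (any(const)) {
    stop("constant covariate(s): ",
         paste(covariates[const], collapse = ", "))
  }
  df <- data.frame(.time = ed$time, .event = ed$event, X,
                   check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  warn <- NULL
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100L)),
    warning = function(w) {
      warn <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  names(beta) <- covariates
  se <- sqrt(diag(stats::vcov(fit)))
  names(se) <- covariates
  converged <- is.null(warn) && all(is.finite(beta))
  structure(
    list(covariates = covariates, beta = beta, se = se,
         wald_p = 2 * stats::pnorm(-abs(beta / se)),
         loglik = unname(fit$loglik[length(fit$loglik)]),
         converged = converged, diagnostic = warn,
         n = fit$n, n_events = fit$nevent, endpoint = endpoint),
    class = "kinsig_coxfit"
  )
}

#' @export
print.kinsig_coxfit <- function(x, ...) {
  cat(sprintf("<kinsig_coxfit> endpoint %s: %d covariates, %d/%d events%s\n",
              x$endpoint, length(x$beta), x$n_events, x$n,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(data.frame(beta = x$beta, se = x$se, p = x$wald_p))
  invisible(x)
}

#' Prognostic index (risk score)
#'
#' Linear predictor of a Cox fit: `PI_i = sum_g beta_g * x_ig`, the term
#' inside the exponent of the proportional-hazards model. Samples are
#' ranked and median-split on this score for combined-gene analyses.
#'
#' @param fit A `kinsig_coxfit`.
#' @param cohort Data frame containing every fit covariate.
#' @return Numeric vector, one score per cohort row, named by
#'   `sample_id` when present.
#' @export
prognostic_index <- function(fit, cohort) {
  stopifnot(inherits(fit, "kinsig_coxfit"))
  missing <- setdiff(fit$covariates, names(cohort))
  if (length(missing)) {
    stop("cohort lacks covariate(s): ", paste(missing, collapse = ", "))
  }
  pi <- as.vector(as.matrix(cohort[, fit$covariates, drop = FALSE]) %*%
                    fit$beta)
  if (!is.null(cohort$sample_id)) names(pi) <- cohort$sample_id
  pi
}

#' Median split into equal-sized risk groups
#'
#' Ranks the values and assigns the first `ceiling(n/2)` ranks to the
#' low group and the rest to the high group, guaranteeing equal group
#' sizes (within one for odd n) even under ties at the median. Ties are
#' resolved by a stable sort on (value, id), so the assignment is a
#' deterministic function of the data, not of input order.
#'
#' @param values Numeric vector (at least 2 values, not all identical).
#' @param ids Optional tie-breaking identifiers (e.g. sample ids);
#'   defaults to input position.
#' @return Factor with levels `low`, `high`, aligned with `values`.
#' @export
dichotomize_median <- function(values, ids = NULL) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values to split")
  if (anyNA(values)) stop("missing values cannot be dichotomized")
  if (length(unique(values)) == 1L) {
    stop("all values identical: no informative split")
  }
  if (is.null(ids)) ids <- seq_len(n)
  ord <- order(values, ids)
  labels <- character(n)
  n_low <- ceiling(n / 2)
  labels[ord[seq_len(n_low)]] <- "low"
  labels[ord[seq.int(n_low + 1L, n)]] <- "high"
  factor(labels, levels = c("low", "high"))
}

#' Hazard ratio between two risk groups
#'
#' Fits a Cox model with the binary group indicator as the only
#' covariate; the hazard ratio is the exponentiated coefficient of the
#' `high` group, with a Wald confidence interval and the log-rank p-value
#' attached. A group with zero events yields a flagged degenerate result
#' (HR `Inf` or 0) instead of an error.
#'
#' @param cohort Cohort data frame (endpoint columns required).
#' @param labels Factor of `low`/`high` group labels, one per row.
#' @param endpoint `"ttt"` or `"os"`.
#' @param conf_level Confidence level for the Wald interval.
#' @return An object of class `kinsig_risk`: list with `hr`, `hr_ci`,
#'   `logrank_p`, `beta`, `se`, `labels`, `n_events` (per group),
#'   `degenerate`.
#' @export
group_hazard_ratio <- function(cohort, labels, endpoint = c("ttt", "os"),
                               conf_level = 0.95) {
  endpoint <- match.arg(endpoint)
  labels <- factor(labels, levels = c("low", "high"))
  if (anyNA(labels)) stop("labels must be 'low' or 'high'")
  ed <- endpoint_data(cohort, endpoint)
  n_events <- tapply(ed$event, labels, sum, default = 0L)
  if (sum(n_events) == 0L) stop("no events in either group")
  lr <- logrank_test(ed$time, ed$event, labels)
  if (any(n_events == 0L)) {
    hr <- if (n_events[["low"]] == 0L) Inf else 0
    res <- list(hr = hr, hr_ci = c(NA_real_, NA_real_),
                logrank_p = lr$p, beta = log(hr), se = NA_real_,
                labels = labels, n_events = n_events, degenerate = TRUE,
                endpoint = endpoint)
    return(structure(res, class = "kinsig_risk"))
  }
  df <- data.frame(ttt_months = ed$time, ttt_event = ed$event,
                   os_months = ed$time, os_event = ed$event,
                   group_high = as.integer(labels == "high"))
  fit <- fit_cox(df, "group_high", endpoint)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(hr = exp(unname(fit$beta)),
         hr_ci = exp(unname(fit$beta) + c(-1, 1) * z * unname(fit$se)),
         logrank_p = lr$p, beta = unname(fit$beta), se = unname(fit$se),
         labels = labels, n_events = n_events,
         degenerate = !fit$converged, endpoint = endpoint),
    class = "kinsig_risk"
  )
}

#' @export
print.kinsig_risk <- function(x, ...) {
  cat(sprintf(
    "<kinsig_risk> %s: HR = %.3f [%.3f, %.3f], log-rank p = %.3g%s\n",
    x$endpoint, x$hr, x$hr_ci[1L], x$hr_ci[2L], x$logrank_p,
    if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Kaplan-Meier product-limit estimate
#'
#' Tidy per-group survival curves with at-risk counts, including the
#' `S(0) = 1` origin, suitable for external plotting.
#'
#' @param times Numeric survival times.
#' @param events 0/1 event indicators.
#' @param labels Optional group labels (single group if `NULL`); empty
#'   groups are an error.
#' @return Data frame with columns `group`, `time`, `survival`,
#'   `at_risk`.
#' @export
km_estimate <- function(times, events, labels = NULL) {
  if (any(times < 0)) stop("negative survival times")
  if (!all(events %in% c(0, 1))) stop("event indicators must be 0/1")
  if (is.null(labels)) labels <- rep("all", length(times))
  labels <- as.factor(labels)
  if (any(table(labels) == 0L)) {
    stop("empty group(s): ",
         paste(levels(labels)[table(labels) == 0L], collapse = ", "))
  }
  out <- lapply(levels(labels), function(g) {
    sel <- labels == g
    sf <- survival::survfit(survival::Surv(times[sel], events[sel]) ~ 1)
    data.frame(group = g,
               time = c(0, sf$time),
               survival = c(1, sf$surv),
               at_risk = c(sum(sel), sf$n.risk),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Two-group log-rank test
#'
#' Standard chi-square log-rank test with one degree of freedom for the
#' equality of two survival curves.
#'
#' @inheritParams km_estimate
#' @param labels Two-group labels, each group non-empty.
#' @return List with `statistic` and `p`.
#' @export
logrank_test <- function(times, events, labels) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) {
    stop("log-rank test needs exactly two non-empty groups")
  }
  sd <- survival::survdiff(
    survival::Surv(times, events) ~ labels, rho = 0)
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' Hazard ratio of a single gene after median split
#'
#' Dichotomizes the cohort at the median expression of one gene and
#' computes the high-vs-low hazard ratio, the per-gene prognostic readout
#' used to rank signature genes individually.
#'
#' @param cohort Cohort data frame.
#' @param gene Gene column name.
#' @param endpoint `"ttt"` or `"os"`.
#' @return A `kinsig_risk` with the `gene` recorded.
#' @export
single_gene_hr <- function(cohort, gene, endpoint = c("ttt", "os")) {
  endpoint <- match.arg(endpoint)
  if (!gene %in% names(cohort)) stop("gene '", gene, "' not in cohort")
  labels <- dichotomize_median(cohort[[gene]], cohort$sample_id)
  res <- group_hazard_ratio(cohort, labels, endpoint)
  res$gene <- gene
  res
}

#' Hazard ratio of a multi-gene signature
#'
#' Fits a Cox model on all signature genes, computes the per-sample
#' prognostic index, median-splits it into equal-sized risk groups, and
#' reports the high-vs-low hazard ratio of the binary group indicator
#' (the single hazard ratio attached to a dichotomized Kaplan-Meier
#' plot).
#'
#' @param cohort Cohort data frame.
#' @param genes Character vector of signature genes (at least 1).
#' @param endpoint `"ttt"` or `"os"`.
#' @return A `kinsig_risk` with elements `pi` (prognostic index), `fit`
#'   (the multi-gene `kinsig_coxfit`) and `genes` added.
#' @export
signature_hr <- function(cohort, genes, endpoint = c("ttt", "os")) {
  endpoint <- match.arg(endpoint)
  if (length(genes) < 1L) stop("need at least one gene")
  genes <- sort(as.character(genes))      # order-invariant by construction
  fit <- fit_cox(cohort, genes, endpoint)
  pi <- prognostic_index(fit, cohort)
  labels <- dichotomize_median(pi, cohort$sample_id)
  res <- group_hazard_ratio(cohort, labels, endpoint)
  res$pi <- pi
  res$fit <- fit
  res$genes <- genes
  res$degenerate <- res$degenerate || !fit$converged
  res
}

#' Leave-one-out gene contributions to the combined hazard ratio
#'
#' Removes each gene in turn from the pool, recomputes the combined
#' signature hazard ratio without it, and defines the gene's contribution
#' as `HR_full - HR_without`. The strongest contributors are the genes
#' whose removal decreases the combined HR the most.
#'
#' @param cohort Cohort data frame.
#' @param genes Gene pool (at least 2 genes).
#' @param endpoint `"ttt"` or `"os"`.
#' @param top_k Number of strongest contributors to extract (default 8);
#'   must not exceed the pool size.
#' @return An object of class `kinsig_contributions`: list with `table`
#'   (gene, hr_without, contribution; descending), `hr_full`, `top`
#'   (top `top_k` genes), `top_k`, `endpoint`.
#' @export
leave_one_out_contributions <- function(cohort, genes,
                                        endpoint = c("ttt", "os"),
                                        top_k = 8L) {
  endpoint <- match.arg(endpoint)
  genes <- as.character(genes)
  if (length(genes) < 2L) stop("need at least 2 genes in the pool")
  if (top_k > length(genes)) {
    stop(sprintf("top_k = %d exceeds the pool size (%d)",
                 top_k, length(genes)))
  }
  hr_full <- signature_hr(cohort, genes, endpoint)$hr
  hr_wo <- vapply(genes, function(g) {
    signature_hr(cohort, setdiff(genes, g), endpoint)$hr
  }, numeric(1L))
  tab <- data.frame(gene = genes, hr_without = unname(hr_wo),
                    contribution = hr_full - unname(hr_wo),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$contribution, tab$gene), ]
  rownames(tab) <- NULL
  structure(
    list(table = tab, hr_full = hr_full,
         top = utils::head(tab$gene, top_k), top_k = top_k,
         endpoint = endpoint),
    class = "kinsig_contributions"
  )
}

#' @export
print.kinsig_contributions <- function(x, ...) {
  cat(sprintf("<kinsig_contributions> %s: full HR %.3f; top %d: %s\n",
              x$endpoint, x$hr_full, x$top_k,
              paste(x$top, collapse = ", ")))
  invisible(x)
}

#' Multivariate Cox model with clinical covariates
#'
#' Tests whether high expression of a gene (median split) remains
#' prognostic after adjusting for IGHV mutational status and 17p13
#' deletion. Samples with unknown IGHV status or missing deletion flag
#' are excluded listwise. Univariate fits of each covariate are emitted
#' alongside the multivariate model for comparison.
#'
#' @param cohort Cohort data frame with `ighv` (values `mutated`,
#'   `unmutated`, `unknown`) and `del17p` (0/1, `NA` allowed) columns.
#' @param endpoint `"ttt"` or `"os"`.
#' @param gene Gene column to dichotomize (default `"DNPEP"`).
#' @return List with `multivariate` (`kinsig_coxfit` with Wald p-values),
#'   `univariate` (named list of single-covariate fits), `n_used`,
#'   `n_excluded`.
#' @export
multivariate_cox <- function(cohort, endpoint = c("ttt", "os"),
                             gene = "DNPEP") {
  endpoint <- match.arg(endpoint)
  need <- c("ighv", "del17p", gene)
  missing <- setdiff(need, names(cohort))
  if (length(missing)) {
    stop("cohort lacks column(s): ", paste(missing, collapse = ", "))
  }
  high <- dichotomize_median(cohort[[gene]], cohort$sample_id)
  keep <- cohort$ighv %in% c("mutated", "unmutated") & !is.na(cohort$del17p)
  sub <- cohort[keep, , drop = FALSE]
  covs <- c(paste0(gene, "_high"), "ighv_unmutated", "del17p")
  sub[[covs[[1L]]]] <- as.integer(high[keep] == "high")
  sub$ighv_unmutated <- as.integer(sub$ighv == "unmutated")
  sub$del17p <- as.integer(sub$del17p)
  multi <- fit_cox(sub, covs, endpoint)
  uni <- lapply(covs, function(cv) fit_cox(sub, cv, endpoint))
  names(uni) <- covs
  list(multivariate = multi, univariate = uni,
       n_used = nrow(sub), n_excluded = sum(!keep))
}
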