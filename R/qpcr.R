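#' Reference-normalized relative expression from Ct values
#'
#' Single-delta Ct under the 100%-amplification-efficiency (doubling)
#' model: `2^(Ct_reference - Ct_target)`. Equal Ct values give 1; each
#' cycle the target crosses earlier than the reference doubles the
#' estimate. No calibrator sample is involved, so values are relative to
#' the housekeeping gene only.
#'
#' @param ct_target,ct_reference Finite Ct values (cycles); vectorized.
#' @return Positive relative expression value(s).
#' @export
#' @examples
#' relative_expression(22, 25)  # 2^3 = 8
relative_expression <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    stop("Ct values must be finite")
  }
  2^(ct_reference - ct_target)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Satterthwaite degrees of freedom,
#' two-sided. Thin wrapper around [stats::t.test()] exposing the
#' quantities used in stage contrasts.
#'
#' @param a,b Numeric samples, each with at least 2 values; at least one
#'   must have nonzero variance.
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least 2 values")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("both samples have zero variance")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

# wide (per-sample) view of a long Ct table for one target/reference pair
qpcr_wide <- function(records, reference, target) {
  need <- c("sample_id", "gene", "ct")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop("Ct table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(records$ct <= 0 | records$ct >= 45, na.rm = TRUE)) {
    stop("Ct values must lie in (0, 45)")
  }
  samples <- unique(records$sample_id)
  ref <- records[records$gene == reference, ]
  tgt <- records[records$gene == target, ]
  if (!all(samples %in% ref$sample_id)) {
    stop("reference gene '", reference, "' missing for some samples")
  }
  if (nrow(tgt) == 0L) stop("target gene '", target, "' not in Ct table")
  idx_r <- match(tgt$sample_id, ref$sample_id)
  out <- data.frame(
    sample_id = tgt$sample_id,
    rel_expr = relative_expression(tgt$ct, ref$ct[idx_r]),
    stringsAsFactors = FALSE
  )
  for (cl in intersect(c("rai", "binet"), names(records))) {
    out[[cl]] <- tgt[[cl]][match(out$sample_id, tgt$sample_id)]
  }
  out
}

#' Stage-group contrasts of relative expression
#'
#' Converts a long Ct table to per-sample reference-normalized relative
#' expression and compares clinical stage groups with Welch t-tests. The
#' default contrasts follow standard risk stratification: for Rai
#' staging, low (0) vs high (III-IV) risk and intermediate (I-II) vs high
#' risk; for Binet staging, early (A) vs advanced (B and C pooled).
#' Other pairs can be requested via `contrasts`.
#'
#' By default the comparison is made on the log2 relative-expression
#' scale (equivalently, on delta-Ct values): Ct noise is additive, so
#' relative expression is lognormal and the t-test is calibrated on the
#' log scale, which is also where qPCR group comparisons are standardly
#' performed. Set `log2_transform = FALSE` to compare raw fold changes.
#'
#' @param records Long data frame with columns `sample_id`, `gene`,
#'   `ct`, and `rai` and/or `binet` stage labels.
#' @param staging `"rai"` or `"binet"`.
#' @param reference Housekeeping gene (default `"ABL1"`).
#' @param target Target gene (default `"DNPEP"`).
#' @param log2_transform Compare log2 relative expression (delta-Ct
#'   scale, default `TRUE`) or raw fold changes (`FALSE`).
#' @param contrasts Optional list of 2-element character vectors of group
#'   labels (Binet groups are `"A"`, `"B-C"`).
#' @return Data frame with one row per contrast: `staging`, `group1`,
#'   `group2`, `n1`, `n2`, `mean1`, `mean2`, `t`, `df`, `p`.
#' @export
stage_comparison <- function(records, staging = c("rai", "binet"),
                             reference = "ABL1", target = "DNPEP",
                             log2_transform = TRUE, contrasts = NULL) {
  staging <- match.arg(staging)
  wide <- qpcr_wide(records, reference, target)
  if (!staging %in% names(wide)) {
    stop("Ct table lacks '", staging, "' stage labels")
  }
  if (staging == "rai") {
    grp <- as.character(wide$rai)
    if (is.null(contrasts)) {
      contrasts <- list(c("0", "III-IV"), c("I-II", "III-IV"))
    }
  } else {
    grp <- ifelse(as.character(wide$binet) == "A", "A", "B-C")
    if (is.null(contrasts)) contrasts <- list(c("A", "B-C"))
  }
  value <- if (log2_transform) log2(wide$rel_expr) else wide$rel_expr
  rows <- lapply(contrasts, function(ct) {
    a <- value[grp == ct[[1L]]]
    b <- value[grp == ct[[2L]]]
    empty <- c(ct[[1L]], ct[[2L]])[c(length(a) == 0L, length(b) == 0L)]
    if (length(empty)) {
      stop("empty stratum(s): ", paste(empty, collapse = ", "))
    }
    w <- welch_t_test(a, b)
    data.frame(staging = staging, group1 = ct[[1L]], group2 = ct[[2L]],
               n1 = length(a), n2 = length(b),
               mean1 = w$mean_a, mean2 = w$mean_b,
               t = w$t, df = w$df, p = w$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
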