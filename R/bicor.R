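#' Biweight midcorrelation
#'
#' Robust correlation using Tukey biweights anchored at the median. For a
#' vector x the deviations are scaled as
#' `u_i = (x_i - median(x)) / (9 * mad(x))` with the unscaled MAD
#' (`constant = 1`); weights `a_i = (1 - u_i^2)^2` vanish outside
#' `|u_i| < 1`, the weighted deviations `(x_i - median(x)) * a_i` are
#' normalized to unit length, and the correlation is the inner product of
#' the two weighted, normalized vectors. Samples far from the median are
#' therefore down-weighted, making the estimate resistant to gross
#' outliers that distort the Pearson correlation.
#'
#' Missing values are removed pairwise; at least `min_overlap` complete
#' pairs are required. If either vector has zero MAD (more than half of
#' its values tied at the median) the Pearson correlation is used for the
#' pair instead and flagged via the `"fallback"` attribute queried by
#' [correlate_collection()]. Constant vectors are an error.
#'
#' @param x,y Numeric vectors of equal length.
#' @param min_overlap Minimum number of complete pairs (default 8;
#'   robust estimates below this are not meaningful).
#' @return Correlation in `[-1, 1]`.
#' @export
#' @examples
#' x <- c(1, 2, 3, 4, 5, 6, 7, 100)  # one gross outlier
#' y <- 1:8
#' bicor(x, y)
#' cor(x, y)   # Pearson is dragged up by the outlier
bicor <- function(x, y, min_overlap = 8L) {
  r <- bicor_pair(x, y, min_overlap)
  r$r
}

# internal: returns list(r, fallback, n_used)
bicor_pair <- function(x, y, min_overlap = 8L) {
  if (!is.numeric(x) || !is.numeric(y)) stop("inputs must be numeric")
  if (length(x) != length(y)) stop("vectors must have equal length")
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < min_overlap) {
    stop(sprintf("only %d complete pairs; minimum overlap is %d",
                 n, min_overlap))
  }
  x <- x[ok]; y <- y[ok]
  wx <- bicor_weights(x)
  wy <- bicor_weights(y)
  fallback <- wx$fallback || wy$fallback
  if (fallback) {
    # zero MAD on either side: Pearson for the whole pair
    r <- stats::cor(x, y)
  } else {
    r <- sum(wx$w * wy$w)
  }
  list(r = max(-1, min(1, r)), fallback = fallback, n_used = n)
}

# weighted, unit-normalized deviations for one vector
bicor_weights <- function(x) {
  if (stats::sd(x) == 0) {
    stop("constant vector: correlation undefined")
  }
  med <- stats::median(x)
  madx <- stats::mad(x, constant = 1)
  if (madx == 0) {
    return(list(w = NULL, fallback = TRUE))
  }
  u <- (x - med) / (9 * madx)
  a <- (1 - u^2)^2 * (abs(u) < 1)
  xt <- (x - med) * a
  nrm <- sqrt(sum(xt^2))
  if (nrm == 0) {
    # all weight collapsed (pathological spread); fall back to Pearson
    return(list(w = NULL, fallback = TRUE))
  }
  list(w = xt / nrm, fallback = FALSE)
}

# matrix version of bicor_weights for complete (no-NA) data: one row per
# gene; returns unit-norm weighted deviations, plus per-row flags
bicor_weights_matrix <- function(m) {
  n <- ncol(m)
  med <- apply(m, 1L, stats::median)
  madv <- apply(m, 1L, stats::mad, constant = 1)
  dev <- m - med
  constant <- apply(dev, 1L, function(d) all(d == 0))
  fallback <- madv == 0 & !constant
  u <- dev / (9 * pmax(madv, .Machine$double.xmin))
  a <- (1 - u^2)^2 * (abs(u) < 1)
  w <- dev * a
  nrm <- sqrt(rowSums(w^2))
  degenerate <- nrm == 0 & !constant & !fallback
  fallback <- fallback | degenerate
  # Pearson-style weights for fallback rows so they can still be combined
  cdev <- m - rowMeans(m)
  cnrm <- sqrt(rowSums(cdev^2))
  w[fallback, ] <- cdev[fallback, , drop = FALSE] / cnrm[fallback]
  ok <- !fallback & !constant
  w[ok, ] <- w[ok, , drop = FALSE] / nrm[ok]
  w[constant, ] <- NA_real_
  list(w = w, fallback = fallback, constant = constant)
}

#' Correlate every gene with every panel kinase across datasets
#'
#' Computes the biweight midcorrelation between each non-kinase gene and
#' each panel kinase present in each dataset, the per-dataset screening
#' step of the consensus selection. Kinase genes themselves are excluded
#' from the candidate side, so panel-internal correlations never enter
#' the gene selection. A kinase missing from a dataset simply yields no
#' records for that dataset; it is an error only if no dataset contains
#' any panel kinase. The panel spelling `PI3KCD` is accepted as an alias
#' of the HGNC symbol `PIK3CD`.
#'
#' Datasets without missing values use a vectorized path; otherwise each
#' pair is computed with pairwise-complete observations. Pairs where a
#' zero-MAD fallback to Pearson occurred are flagged; pairs with fewer
#' than `min_overlap` complete observations or a constant vector yield
#' `NA` correlations (which never pass a consensus threshold).
#'
#' @param datasets List of [expression_dataset()] objects.
#' @param kinase_panel Character vector of kinase gene symbols.
#' @param min_overlap Minimum complete pairs per correlation.
#' @return Data frame with columns `dataset_id`, `gene`, `kinase`, `r`,
#'   `n_used`, `fallback`.
#' @export
correlate_collection <- function(datasets, kinase_panel, min_overlap = 8L) {
  if (inherits(datasets, "kinsig_expression")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1L, length(kinase_panel) >= 1L)
  kinase_panel <- normalize_panel(kinase_panel)
  out <- vector("list", length(datasets))
  any_kinase <- FALSE
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    stopifnot(inherits(ds, "kinsig_expression"))
    kin <- intersect(kinase_panel, ds$gene_ids)
    if (length(kin) == 0L) next
    any_kinase <- TRUE
    genes <- setdiff(ds$gene_ids, kinase_panel)
    if (length(genes) == 0L) next
    out[[i]] <- correlate_one(ds, genes, kin, min_overlap)
  }
  if (!any_kinase) {
    stop("no dataset contains any kinase of the panel: ",
         paste(kinase_panel, collapse = ", "))
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1L))])
}

normalize_panel <- function(panel) {
  panel <- as.character(panel)
  panel[panel == "PI3KCD"] <- "PIK3CD"
  unique(panel)
}

correlate_one <- function(ds, genes, kinases, min_overlap) {
  vals <- ds$values
  gv <- vals[genes, , drop = FALSE]
  kv <- vals[kinases, , drop = FALSE]
  if (!anyNA(gv) && !anyNA(kv)) {
    bg <- bicor_weights_matrix(gv)
    bk <- bicor_weights_matrix(kv)
    r <- bg$w %*% t(bk$w)
    r[] <- pmax(-1, pmin(1, r))
    fb <- outer(bg$fallback, bk$fallback, `|`)
    if (any(fb)) {
      # pair-level Pearson when either side fell back, matching bicor()
      idx <- which(fb, arr.ind = TRUE)
      for (k in seq_len(nrow(idx))) {
        gi <- idx[k, 1L]; ki <- idx[k, 2L]
        if (bg$constant[gi] || bk$constant[ki]) next
        r[gi, ki] <- stats::cor(gv[gi, ], kv[ki, ])
      }
    }
    r[bg$constant, ] <- NA_real_
    r[, bk$constant] <- NA_real_
    data.frame(
      dataset_id = ds$dataset_id,
      gene = rep(genes, times = length(kinases)),
      kinase = rep(kinases, each = length(genes)),
      r = as.vector(r),
      n_used = ncol(vals),
      fallback = as.vector(fb),
      stringsAsFactors = FALSE
    )
  } else {
    recs <- expand.grid(gene = genes, kinase = kinases,
                        stringsAsFactors = FALSE)
    res <- mapply(function(g, k) {
      p <- tryCatch(bicor_pair(gv[g, ], kv[k, ], min_overlap),
                    error = function(e) list(r = NA_real_, fallback = FALSE,
                                             n_used = NA_integer_))
      c(p$r, as.numeric(p$fallback), p$n_used)
    }, recs$gene, recs$kinase)
    data.frame(
      dataset_id = ds$dataset_id,
      gene = recs$gene,
      kinase = recs$kinase,
      r = res[1L, ],
      n_used = as.integer(res[3L, ]),
      fallback = res[2L, ] > 0,
      stringsAsFactors = FALSE
    )
  }
}
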