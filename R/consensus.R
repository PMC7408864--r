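#' Count supporting datasets per gene-kinase pair
#'
#' Applies an absolute correlation threshold to per-dataset correlation
#' records and counts, for every (gene, kinase) pair, the number of
#' datasets in which `|r| >= threshold`. Both correlation signs count.
#' `NA` correlations never pass.
#'
#' @param records Data frame from [correlate_collection()].
#' @param threshold Absolute correlation cutoff in `(0, 1]` (default 0.5).
#' @return An object of class `kinsig_consensus`: list with `counts`
#'   (integer gene x kinase matrix), `records` (with a logical `pass`
#'   column), `threshold`, `n_datasets`, `kinases`, `genes`.
#' @export
build_consensus <- function(records, threshold = 0.5) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("'records' must be a non-empty data frame of correlation records")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("'threshold' must lie in (0, 1]")
  }
  need <- c("dataset_id", "gene", "kinase", "r")
  if (!all(need %in% names(records))) {
    stop("records need columns: ", paste(need, collapse = ", "))
  }
  records$pass <- !is.na(records$r) & abs(records$r) >= threshold
  genes <- sort(unique(records$gene))
  kinases <- sort(unique(records$kinase))
  counts <- matrix(0L, length(genes), length(kinases),
                   dimnames = list(genes, kinases))
  agg <- stats::aggregate(pass ~ gene + kinase, records, sum)
  counts[cbind(match(agg$gene, genes), match(agg$kinase, kinases))] <-
    as.integer(agg$pass)
  structure(
    list(counts = counts,
         records = records[, c("dataset_id", "gene", "kinase", "pass")],
         threshold = threshold,
         n_datasets = length(unique(records$dataset_id)),
         kinases = kinases, genes = genes),
    class = "kinsig_consensus"
  )
}

#' @export
print.kinsig_consensus <- function(x, ...) {
  cat(sprintf(
    "<kinsig_consensus> %d genes x %d kinases over %d datasets (|r| >= %g)\n",
    length(x$genes), length(x$kinases), x$n_datasets, x$threshold))
  invisible(x)
}

# datasets in which `gene` passes for `kinase`
passing_datasets <- function(consensus, gene, kinase) {
  rec <- consensus$records
  rec$dataset_id[rec$gene == gene & rec$kinase == kinase & rec$pass]
}

check_anchor <- function(consensus, anchor) {
  if (!anchor %in% consensus$kinases) {
    stop("anchor kinase '", anchor, "' has no correlation records")
  }
}

# support indicator (count >= min_datasets), optionally requiring the
# supporting datasets to coincide with the anchor's
support_matrix <- function(consensus, anchor, min_datasets, same_datasets) {
  counts <- consensus$counts
  if (!same_datasets) {
    return(counts >= min_datasets)
  }
  sup <- counts >= min_datasets          # anchor column still per-kinase
  rec <- consensus$records
  for (g in rownames(counts)) {
    dsa <- rec$dataset_id[rec$gene == g & rec$kinase == anchor & rec$pass]
    for (k in setdiff(colnames(counts), anchor)) {
      dsk <- rec$dataset_id[rec$gene == g & rec$kinase == k & rec$pass]
      sup[g, k] <- length(intersect(dsa, dsk)) >= min_datasets
    }
  }
  sup
}

#' Stage-1 gene selection: anchor plus one other kinase
#'
#' Selects genes supported in at least `min_datasets` datasets for the
#' anchor kinase and, independently, in at least `min_datasets` datasets
#' for at least one non-anchor kinase. With `same_datasets = TRUE` the
#' non-anchor support is counted only over datasets shared with the
#' anchor's supporting datasets.
#'
#' @param consensus A `kinsig_consensus` object.
#' @param anchor Anchor kinase symbol (default `"ZAP70"`).
#' @param min_datasets Minimum supporting datasets per kinase (default 5).
#' @param same_datasets Require the anchor and the other kinase to be
#'   supported in the same datasets (default `FALSE`).
#' @return Character vector of genes, ordered by [rank_by_support()].
#' @export
select_stage1 <- function(consensus, anchor = "ZAP70", min_datasets = 5L,
                          same_datasets = FALSE) {
  stopifnot(inherits(consensus, "kinsig_consensus"))
  check_anchor(consensus, anchor)
  sup <- support_matrix(consensus, anchor, min_datasets, same_datasets)
  others <- setdiff(colnames(sup), anchor)
  hit <- sup[, anchor] &
    rowSums(sup[, others, drop = FALSE]) >= 1L
  rank_by_support(rownames(sup)[hit], consensus)
}

#' Stage-2 gene selection: anchor plus multiple kinases
#'
#' Refines the selection to genes supported (in at least `min_datasets`
#' datasets) for the anchor kinase and for at least `min_other_kinases`
#' non-anchor kinases, yielding the final signature gene set. Returns the
#' two selection stages, per-gene kinase support, and the kinase-pair
#' overlap matrix.
#'
#' @inheritParams select_stage1
#' @param min_other_kinases Minimum number of supported non-anchor
#'   kinases (default 2). Zero degenerates to the anchor-supported set.
#' @param stage1_genes Optional precomputed stage-1 gene list; computed
#'   if `NULL`.
#' @return An object of class `kinsig_selection`: list with `stage1`,
#'   `stage2` (both ranked), `support` (named list gene -> supported
#'   kinases), `overlap` (kinase x kinase matrix), and the parameters.
#' @export
select_stage2 <- function(consensus, anchor = "ZAP70",
                          min_other_kinases = 2L, min_datasets = 5L,
                          stage1_genes = NULL, same_datasets = FALSE) {
  stopifnot(inherits(consensus, "kinsig_consensus"))
  check_anchor(consensus, anchor)
  if (min_other_kinases > length(consensus$kinases) - 1L) {
    stop(sprintf("min_other_kinases = %d exceeds panel size minus one (%d)",
                 min_other_kinases, length(consensus$kinases) - 1L))
  }
  if (is.null(stage1_genes)) {
    stage1_genes <- select_stage1(consensus, anchor, min_datasets,
                                  same_datasets)
  }
  sup <- support_matrix(consensus, anchor, min_datasets, same_datasets)
  others <- setdiff(colnames(sup), anchor)
  hit <- sup[, anchor] &
    rowSums(sup[, others, drop = FALSE]) >= min_other_kinases
  stage2 <- rank_by_support(rownames(sup)[hit], consensus)
  support <- lapply(stage2, function(g) colnames(sup)[sup[g, ]])
  names(support) <- stage2
  structure(
    list(stage1 = stage1_genes, stage2 = stage2, support = support,
         overlap = kinase_overlap_matrix(consensus, stage2, min_datasets,
                                         same_datasets = same_datasets,
                                         anchor = anchor),
         anchor = anchor, min_datasets = min_datasets,
         min_other_kinases = min_other_kinases,
         threshold = consensus$threshold,
         same_datasets = same_datasets),
    class = "kinsig_selection"
  )
}

#' @export
print.kinsig_selection <- function(x, ...) {
  cat(sprintf(
    "<kinsig_selection> anchor %s: %d stage-1 genes, %d stage-2 genes\n",
    x$anchor, length(x$stage1), length(x$stage2)))
  if (length(x$stage2)) {
    cat("stage-2:", paste(utils::head(x$stage2, 10L), collapse = ", "),
        if (length(x$stage2) > 10L) "..." else "", "\n")
  }
  invisible(x)
}

#' Rank genes by total dataset support
#'
#' Orders genes in descending order of their total supporting-dataset
#' count summed over all panel kinases; ties are broken alphabetically by
#' gene name, so the ordering is deterministic.
#'
#' @param genes Character vector of genes to rank.
#' @param consensus A `kinsig_consensus` object.
#' @return `genes`, reordered.
#' @export
rank_by_support <- function(genes, consensus) {
  stopifnot(inherits(consensus, "kinsig_consensus"))
  genes <- as.character(genes)
  if (length(genes) == 0L) return(character(0L))
  total <- rowSums(consensus$counts[genes, , drop = FALSE])
  genes[order(-total, genes)]
}

#' Kinase-pair overlap matrix of a gene selection
#'
#' Entry (i, j) counts the selected genes supported (at least
#' `min_datasets` datasets) for both kinase i and kinase j; the diagonal
#' holds per-kinase totals. The matrix is symmetric by construction and
#' summarizes how the kinase-specific co-expression programs overlap.
#'
#' @param consensus A `kinsig_consensus` object.
#' @param genes Genes of the selection (e.g. the stage-2 set).
#' @param min_datasets Support cutoff (default 5).
#' @param same_datasets,anchor Passed through to the support definition.
#' @return Symmetric integer kinase x kinase matrix.
#' @export
kinase_overlap_matrix <- function(consensus, genes, min_datasets = 5L,
                                  same_datasets = FALSE, anchor = NULL) {
  stopifnot(inherits(consensus, "kinsig_consensus"))
  kin <- consensus$kinases
  if (length(genes) == 0L) {
    return(matrix(0L, length(kin), length(kin), dimnames = list(kin, kin)))
  }
  if (same_datasets && is.null(anchor)) same_datasets <- FALSE
  sup <- support_matrix(consensus, anchor %||% kin[[1L]], min_datasets,
                        same_datasets)[genes, , drop = FALSE]
  m <- t(sup) %*% sup
  storage.mode(m) <- "integer"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
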