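#' Construct an expression dataset
#'
#' Container for one normalized, log2-scale genes-by-samples expression
#' matrix with a dataset identifier. All downstream correlation and
#' selection functions operate on this class.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#'   Missing values (`NA`) are allowed and handled pairwise in
#'   correlation; infinite values are rejected.
#' @param dataset_id Single string identifying the dataset.
#' @param gene_ids Character vector of row identifiers (defaults to
#'   `rownames(values)`). Duplicates are allowed before probe collapse.
#' @param sample_ids Character vector of column identifiers (defaults to
#'   `colnames(values)`); must be unique.
#'
#' @return An object of class `kinsig_expression`: a list with elements
#'   `dataset_id`, `gene_ids`, `sample_ids` and `values`.
#' @export
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' expression_dataset(m, "toy")
expression_dataset <- function(values, dataset_id,
                               gene_ids = rownames(values),
                               sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (!is.character(dataset_id) || length(dataset_id) != 1L || !nzchar(dataset_id)) {
    stop("'dataset_id' must be a non-empty string")
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample identifiers are required")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("length of 'gene_ids' does not match number of rows")
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length of 'sample_ids' does not match number of columns")
  }
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  }
  if (any(is.infinite(values))) {
    stop("expression matrix contains infinite values")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(dataset_id = dataset_id, gene_ids = gene_ids,
         sample_ids = sample_ids, values = values),
    class = "kinsig_expression"
  )
}

#' @export
print.kinsig_expression <- function(x, ...) {
  cat(sprintf("<kinsig_expression> %s: %d genes x %d samples\n",
              x$dataset_id, length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' @export
dim.kinsig_expression <- function(x) dim(x$values)

#' Read an expression matrix from TSV, CSV or GCT
#'
#' Parses a delimited genes-by-samples matrix into an
#' [expression_dataset()]. The TSV/CSV dialects expect a header row whose
#' first field labels the gene-id column and whose remaining fields are
#' sample ids. The GCT dialect follows the GCT 1.2 convention: a `#1.2`
#' version line, a dimensions line, then a header with `Name` and
#' `Description` columns preceding the sample ids.
#'
#' Ragged rows and non-numeric cells raise errors that name the offending
#' line / cell. Empty fields and the literal `NA` are read as missing.
#'
#' @param path Path to the file.
#' @param dialect One of `"tsv"`, `"csv"`, `"gct"`.
#' @param dataset_id Dataset identifier; defaults to the file name without
#'   extension.
#' @return A `kinsig_expression` object.
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "csv", "gct"),
                                   dataset_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(dataset_id)) {
    dataset_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  sep <- if (dialect == "csv") "," else "\t"
  skip_cols <- 1L
  line_offset <- 0L

  if (dialect == "gct") {
    if (length(lines) < 3L || !startsWith(lines[[1L]], "#1.2")) {
      stop("not a GCT 1.2 file (missing '#1.2' header): ", path)
    }
    dims <- suppressWarnings(as.integer(strsplit(lines[[2L]], "\t")[[1L]]))
    if (length(dims) < 2L || anyNA(dims[1:2])) {
      stop("malformed GCT dimensions line: ", path)
    }
    lines <- lines[-(1:2)]
    line_offset <- 2L
    skip_cols <- 2L
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("no data rows in ", path)

  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1L]]
  n_fields <- length(header)
  lens <- lengths(fields)
  bad <- which(lens != n_fields)[1L]
  if (!is.na(bad)) {
    stop(sprintf("ragged row at line %d: expected %d fields, found %d",
                 bad + line_offset, n_fields, lens[[bad]]))
  }

  sample_ids <- header[-seq_len(skip_cols)]
  body <- fields[-1L]
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  raw <- t(vapply(body, function(f) f[-seq_len(skip_cols)],
                  character(length(sample_ids))))
  if (length(sample_ids) == 1L) raw <- matrix(raw, ncol = 1L)
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad_cell <- which(is.na(vals) & !(raw %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad_cell) > 0L) {
    i <- bad_cell[1L, 1L]; j <- bad_cell[1L, 2L]
    stop(sprintf(
      "non-numeric value '%s' at row '%s' (line %d), column '%s'",
      raw[i, j], gene_ids[[i]], i + 1L + line_offset, sample_ids[[j]]))
  }

  if (dialect == "gct" && (nrow(vals) != dims[[1L]] || ncol(vals) != dims[[2L]])) {
    stop(sprintf("GCT dimensions line promises %d x %d but file holds %d x %d",
                 dims[[1L]], dims[[2L]], nrow(vals), ncol(vals)))
  }
  rownames(vals) <- gene_ids
  colnames(vals) <- sample_ids
  expression_dataset(vals, dataset_id)
}

#' Write an expression dataset as TSV or CSV
#'
#' First column holds gene ids under the header `gene_id`; remaining
#' columns are samples. Inverse of [read_expression_matrix()] for the
#' same dialect.
#'
#' @param x A `kinsig_expression` object.
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_expression_dataset <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "kinsig_expression"))
  sep <- if (dialect == "csv") "," else "\t"
  df <- data.frame(gene_id = x$gene_ids, x$values, check.names = FALSE,
                   row.names = NULL)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene map
#'
#' Two-column TSV (`probe_id`, `gene`), many probes to one gene. Empty
#' gene symbols are rejected.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `probe_id` and `gene`.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("probe map needs two columns (probe_id, gene)")
  names(df)[1:2] <- c("probe_id", "gene")
  validate_probe_map(df[, 1:2])
}

validate_probe_map <- function(map) {
  map <- as.data.frame(map)
  if (!all(c("probe_id", "gene") %in% names(map))) {
    names(map)[1:2] <- c("probe_id", "gene")
  }
  map$probe_id <- as.character(map$probe_id)
  map$gene <- as.character(map$gene)
  if (any(!nzchar(map$gene) | is.na(map$gene))) {
    stop("probe map contains empty gene symbols")
  }
  if (anyDuplicated(map$probe_id)) {
    stop("probe map assigns some probes to multiple genes")
  }
  map
}

#' Collapse probe-level rows to one row per gene
#'
#' For each gene the probe with the highest mean expression (missing
#' values ignored) is retained, the common default in the weighted
#' co-expression ecosystem. Probes absent from the map are dropped with a
#' warning. Row order follows the original position of each retained
#' probe, so the operation is deterministic and idempotent when gene
#' symbols map to themselves.
#'
#' @param dataset A `kinsig_expression` object (probe-level rows).
#' @param probe_map Data frame with columns `probe_id` and `gene`.
#' @return A `kinsig_expression` object with unique gene rows.
#' @export
collapse_probes <- function(dataset, probe_map) {
  stopifnot(inherits(dataset, "kinsig_expression"))
  probe_map <- validate_probe_map(probe_map)
  idx <- match(dataset$gene_ids, probe_map$probe_id)
  keep <- !is.na(idx)
  if (!any(keep)) {
    stop("no probe of dataset '", dataset$dataset_id,
         "' is present in the probe map")
  }
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    warning(sprintf("dropping %d probe(s) of '%s' absent from the probe map",
                    n_drop, dataset$dataset_id))
  }
  vals <- dataset$values[keep, , drop = FALSE]
  genes <- probe_map$gene[idx[keep]]
  means <- rowMeans(vals, na.rm = TRUE)
  # stable: within a gene, the earliest probe wins ties on mean expression
  ord <- order(genes, -means, seq_along(means))
  first <- !duplicated(genes[ord])
  chosen <- sort(ord[first])            # restore original row order
  out <- vals[chosen, , drop = FALSE]
  rownames(out) <- genes[chosen]
  expression_dataset(out, dataset$dataset_id)
}
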