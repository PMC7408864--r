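#' Run the full signature-discovery pipeline on synthetic data
#'
#' Orchestrates the end-to-end analysis under one configuration:
#' generate the expression collection, correlate genes with the kinase
#' panel, apply the two-stage consensus selection, evaluate the selected
#' signature against both survival endpoints (individual hazard ratios,
#' combined signature, top-k refit, leave-one-out contributions,
#' multivariate clinical model), run the qPCR stage contrasts and the
#' drug-combination indices, and write every stage output plus a JSON
#' manifest with parameter echo and per-file checksums. Reruns with the
#' same configuration reproduce the checksums bit for bit.
#'
#' The combined survival analyses use the `signature_size` top-ranked
#' stage-2 genes (default 32) so the multi-gene Cox fit stays
#' well-posed relative to the cohort size, mirroring a 32-gene signature
#' evaluated on ~107 patients.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @param threshold Absolute correlation threshold (default 0.5).
#' @param anchor Anchor kinase (default `"ZAP70"`).
#' @param min_datasets Minimum supporting datasets (default 5).
#' @param min_other_kinases Minimum non-anchor kinases for stage 2
#'   (default 2).
#' @param top_k Size of the strongest-gene lists (default 8).
#' @param signature_size Number of top-ranked stage-2 genes entering the
#'   combined analyses (default 32).
#' @param endpoints Endpoints to evaluate (default both).
#' @param skip Stage names to skip: any of `"survival"`, `"qpcr"`,
#'   `"ci"`.
#' @param same_datasets Consensus support counted over shared datasets
#'   (default `FALSE`).
#' @return The run manifest (list of class `kinsig_manifest`),
#'   invisibly. Any stage failure aborts with an error naming the stage.
#' @export
run_pipeline <- function(config = synthetic_config(),
                         out_dir,
                         threshold = 0.5, anchor = "ZAP70",
                         min_datasets = 5L, min_other_kinases = 2L,
                         top_k = 8L, signature_size = 32L,
                         endpoints = c("ttt", "os"),
                         skip = character(0L),
                         same_datasets = FALSE) {
  stopifnot(inherits(config, "kinsig_config"))
  bad_skip <- setdiff(skip, c("survival", "qpcr", "ci"))
  if (length(bad_skip)) stop("unknown stage(s) in skip: ",
                             paste(bad_skip, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "kinsig",
    version = as.character(utils::packageVersion("kinsig")),
    seed = config$seed,
    parameters = list(threshold = threshold, anchor = anchor,
                      min_datasets = min_datasets,
                      min_other_kinases = min_other_kinases,
                      top_k = top_k, signature_size = signature_size,
                      endpoints = endpoints,
                      same_datasets = same_datasets),
    stages = list()
  )
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  add_stage <- function(name, files, summary) {
    files <- files[file.exists(file.path(out_dir, files))]
    manifest$stages[[name]] <<- list(
      status = "complete", files = files,
      checksums = as.list(unname(tools::md5sum(file.path(out_dir, files)))),
      summary = summary)
  }
  skip_stage <- function(name, reason) {
    manifest$stages[[name]] <<- list(status = "skipped", reason = reason)
  }

  # -- expression -----------------------------------------------------
  expr <- run_stage("expression", function() {
    x <- generate_expression_collection(config)
    for (ds in x$datasets) {
      write_expression_dataset(ds, file.path(out_dir,
                                             paste0(ds$dataset_id, ".tsv")))
    }
    write_planted_truth(x$truth, file.path(out_dir, "planted_truth.json"))
    x
  })
  add_stage("expression",
            c(vapply(expr$datasets,
                     function(d) paste0(d$dataset_id, ".tsv"),
                     character(1L)), "planted_truth.json"),
            list(n_datasets = length(expr$datasets),
                 n_genes = config$n_genes,
                 n_planted = length(expr$truth$positive_genes)))

  # -- correlate ------------------------------------------------------
  records <- run_stage("correlate", function() {
    r <- correlate_collection(expr$datasets, config$kinase_panel)
    utils::write.table(r, file.path(out_dir, "correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    r
  })
  add_stage("correlate", "correlations.tsv",
            list(n_records = nrow(records)))

  # -- select ---------------------------------------------------------
  selection <- run_stage("select", function() {
    consensus <- build_consensus(records, threshold)
    sel <- select_stage2(consensus, anchor = anchor,
                         min_other_kinases = min_other_kinases,
                         min_datasets = min_datasets,
                         same_datasets = same_datasets)
    jsonlite::write_json(
      list(stage1 = sel$stage1, stage2 = sel$stage2,
           support = sel$support, overlap = sel$overlap),
      file.path(out_dir, "selection.json"), auto_unbox = FALSE,
      digits = NA, pretty = TRUE, matrix = "rowmajor")
    sel
  })
  add_stage("select", "selection.json",
            list(stage1_genes = length(selection$stage1),
                 stage2_genes = length(selection$stage2)))

  # -- survival -------------------------------------------------------
  if ("survival" %in% skip) {
    skip_stage("survival", "requested")
  } else if (length(selection$stage2) == 0L) {
    skip_stage("survival", "no genes passed selection")
  } else {
    surv <- run_stage("survival", function() {
      sig_genes <- utils::head(selection$stage2, signature_size)
      beta_genes <- union(names(config$ttt_betas), names(config$os_betas))
      cohort_genes <- union(sig_genes, beta_genes)
      sc <- generate_survival_cohort(config, genes = cohort_genes)
      cohort <- sc$cohort
      write_table_csv(cohort, file.path(out_dir, "cohort.csv"))
      k_eff <- min(top_k, length(sig_genes))
      per_endpoint <- lapply(endpoints, function(ep) {
        indiv <- do.call(rbind, lapply(sig_genes, function(g) {
          r <- single_gene_hr(cohort, g, ep)
          data.frame(gene = g, hr = r$hr, ci_low = r$hr_ci[1L],
                     ci_high = r$hr_ci[2L], logrank_p = r$logrank_p,
                     stringsAsFactors = FALSE)
        }))
        indiv <- indiv[order(-indiv$hr, indiv$gene), ]
        combined <- signature_hr(cohort, sig_genes, ep)
        topk_genes <- utils::head(indiv$gene, k_eff)
        topk <- signature_hr(cohort, topk_genes, ep)
        loo <- if (length(sig_genes) >= 2L) {
          leave_one_out_contributions(cohort, sig_genes, ep, k_eff)
        } else NULL
        km <- km_estimate(cohort[[endpoint_cols(ep)[["time"]]]],
                          cohort[[endpoint_cols(ep)[["event"]]]],
                          combined$labels)
        utils::write.table(
          km, file.path(out_dir, sprintf("km_%s.tsv", ep)),
          sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(
          indiv, file.path(out_dir, sprintf("individual_hr_%s.tsv", ep)),
          sep = "\t", quote = FALSE, row.names = FALSE)
        list(individual = indiv, combined = combined, topk = topk,
             topk_genes = topk_genes, loo = loo)
      })
      names(per_endpoint) <- endpoints
      common_four <- if (all(c("ttt", "os") %in% endpoints) &&
                         !is.null(per_endpoint$ttt$loo)) {
        Reduce(intersect, list(
          per_endpoint$ttt$topk_genes, per_endpoint$os$topk_genes,
          per_endpoint$ttt$loo$top, per_endpoint$os$loo$top))
      } else character(0L)
      multivariate <- if ("DNPEP" %in% cohort_genes) {
        lapply(stats::setNames(endpoints, endpoints), function(ep) {
          fit <- multivariate_cox(cohort, ep, gene = "DNPEP")
          list(p = as.list(fit$multivariate$wald_p),
               n_used = fit$n_used, n_excluded = fit$n_excluded)
        })
      } else NULL
      res <- list(signature_genes = sig_genes,
                  per_endpoint = per_endpoint,
                  common_four = common_four,
                  multivariate = multivariate)
      summary_json <- list(
        signature_genes = sig_genes,
        combined_hr = lapply(per_endpoint, function(x) x$combined$hr),
        topk_hr = lapply(per_endpoint, function(x) x$topk$hr),
        topk_genes = lapply(per_endpoint, function(x) x$topk_genes),
        loo_top = lapply(per_endpoint, function(x) x$loo$top),
        common_four = common_four,
        multivariate = multivariate)
      jsonlite::write_json(summary_json,
                           file.path(out_dir, "survival_summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      res
    })
    add_stage("survival",
              c("cohort.csv", "survival_summary.json",
                sprintf("km_%s.tsv", endpoints),
                sprintf("individual_hr_%s.tsv", endpoints)),
              list(signature_genes = length(surv$signature_genes),
                   combined_hr = lapply(surv$per_endpoint,
                                        function(x) x$combined$hr),
                   topk_hr = lapply(surv$per_endpoint,
                                    function(x) x$topk$hr),
                   common_four = surv$common_four))
  }

  # -- qpcr -----------------------------------------------------------
  if ("qpcr" %in% skip) {
    skip_stage("qpcr", "requested")
  } else {
    qp <- run_stage("qpcr", function() {
      q <- generate_qpcr_table(config)
      write_table_csv(q$records, file.path(out_dir, "qpcr_ct.csv"))
      contrasts <- rbind(
        stage_comparison(q$records, "rai",
                         reference = config$qpcr_reference,
                         target = config$qpcr_target),
        stage_comparison(q$records, "binet",
                         reference = config$qpcr_reference,
                         target = config$qpcr_target))
      utils::write.table(contrasts,
                         file.path(out_dir, "qpcr_contrasts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      contrasts
    })
    add_stage("qpcr", c("qpcr_ct.csv", "qpcr_contrasts.tsv"),
              list(contrasts = nrow(qp),
                   p_values = as.list(stats::setNames(
                     qp$p, paste(qp$group1, "vs", qp$group2)))))
  }

  # -- ci -------------------------------------------------------------
  if ("ci" %in% skip) {
    skip_stage("ci", "requested")
  } else {
    ci_res <- run_stage("ci", function() {
      dr <- generate_dose_response(config)
      write_table_csv(dr$single, file.path(out_dir, "dose_single.csv"))
      write_table_csv(dr$combination,
                      file.path(out_dir, "dose_combination.csv"))
      fits <- lapply(split(dr$single, dr$single$drug), function(df) {
        median_effect_fit(df$dose, df$fa, drug = df$drug[[1L]])
      })
      comb <- dr$combination
      ci <- combination_index(comb$dose1, comb$dose2, comb$fa,
                              fits[[comb$drug1[[1L]]]],
                              fits[[comb$drug2[[1L]]]])
      out <- cbind(comb, ci = ci, call = ci_classify(ci))
      utils::write.table(out, file.path(out_dir, "combination_index.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(table = out, fits = fits)
    })
    add_stage("ci", c("dose_single.csv", "dose_combination.csv",
                      "combination_index.tsv"),
              list(n_points = nrow(ci_res$table),
                   median_ci = stats::median(ci_res$table$ci),
                   fits = lapply(ci_res$fits,
                                 function(f) list(m = f$m, dm = f$dm))))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(structure(manifest, class = "kinsig_manifest"))
}

#' Human-readable summary of a pipeline run
#'
#' Renders the tables a reader of the analysis expects: the selection
#' funnel, combined and top-k hazard ratios per endpoint, the genes
#' common to the four strongest-gene analyses, qPCR contrasts and the
#' combination-index call. Regeneration from the same manifest is
#' idempotent.
#'
#' @param manifest A `kinsig_manifest` (as returned by
#'   [run_pipeline()]) or the path to a written `manifest.json`.
#' @return Character vector of report lines, invisibly; printed to the
#'   console.
#' @export
report <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  }
  if (is.null(manifest$stages)) stop("incomplete manifest: no stages")
  st <- manifest$stages
  lines <- c(
    sprintf("kinsig pipeline run (seed %s)", manifest$seed),
    sprintf("correlation threshold %s, anchor %s, min datasets %s, min other kinases %s",
            manifest$parameters$threshold, manifest$parameters$anchor,
            manifest$parameters$min_datasets,
            manifest$parameters$min_other_kinases))
  if (!is.null(st$select)) {
    lines <- c(lines, sprintf(
      "selection funnel: %s stage-1 genes -> %s stage-2 genes",
      st$select$summary$stage1_genes, st$select$summary$stage2_genes))
  }
  sv <- st$survival
  if (!is.null(sv) && identical(sv$status, "skipped")) {
    lines <- c(lines,
               if (identical(sv$reason, "no genes passed selection"))
                 "survival: no genes passed selection"
               else sprintf("survival: skipped (%s)", sv$reason))
  } else if (!is.null(sv)) {
    for (ep in names(sv$summary$combined_hr)) {
      lines <- c(lines, sprintf(
        "%s: combined signature HR %.3f, top-k HR %.3f",
        ep, as.numeric(sv$summary$combined_hr[[ep]]),
        as.numeric(sv$summary$topk_hr[[ep]])))
    }
    common <- unlist(sv$summary$common_four)
    lines <- c(lines, sprintf(
      "genes common to the four strongest-gene analyses: %s",
      if (length(common)) paste(common, collapse = ", ") else "(none)"))
  }
  qp <- st$qpcr
  if (!is.null(qp) && identical(qp$status, "complete")) {
    ps <- unlist(qp$summary$p_values)
    lines <- c(lines, sprintf("qPCR %s: p = %.4g", names(ps), ps))
  } else if (!is.null(qp)) {
    lines <- c(lines, sprintf("qpcr: skipped (%s)", qp$reason))
  }
  ci <- st$ci
  if (!is.null(ci) && identical(ci$status, "complete")) {
    lines <- c(lines, sprintf(
      "combination index: median CI %.3f over %s dose pairs",
      as.numeric(ci$summary$median_ci), ci$summary$n_points))
  } else if (!is.null(ci)) {
    lines <- c(lines, sprintf("ci: skipped (%s)", ci$reason))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
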