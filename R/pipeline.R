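#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: the simulator configuration
#' (or paths to pre-made input tables), thresholds, report options, and the
#' seed. The full configuration is serialized into the report header so
#' every output records how it was produced.
#'
#' @param sim A [sim_config()]; the cohort is simulated from it unless
#'   `calls` is supplied.
#' @param thresholds A [threshold_config()].
#' @param calls,msi,clinical,regions Optional pre-made tables replacing the
#'   simulated ones (long call table, marker table, clinical table,
#'   additional-region call table).
#' @param significant_genes Optional gene list for the restricted summary.
#' @param exclude_msi Drop non-MSS patients before analysis (the emulated
#'   study enrolled only microsatellite-stable cases)? Default `TRUE`.
#' @param outdir Optional output directory; when given, the report bundle
#'   is written there.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            thresholds = threshold_config(),
                            calls = NULL, msi = NULL, clinical = NULL,
                            regions = NULL,
                            significant_genes = NULL,
                            exclude_msi = TRUE,
                            outdir = NULL) {
  if (!inherits(sim, "sim_config"))
    stop("'sim' must be a sim_config object", call. = FALSE)
  if (!inherits(thresholds, "threshold_config"))
    stop("'thresholds' must be a threshold_config object", call. = FALSE)
  structure(list(sim = sim, thresholds = thresholds, calls = calls,
                 msi = msi, clinical = clinical, regions = regions,
                 significant_genes = significant_genes,
                 exclude_msi = isTRUE(exclude_msi), outdir = outdir),
            class = "pipeline_config")
}

.stage <- function(log, name, n_in, n_out, detail = "") {
  rbind(log, data.frame(stage = name, n_in = n_in, n_out = n_out,
                        detail = detail, stringsAsFactors = FALSE))
}

.run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full concordance pipeline
#'
#' Fixed stage order: simulate (or ingest) -> MSI gate -> retention filter
#' and cross-compartment matching with comparative rescue -> multi-region
#' resolution -> copy-number overlay (when copy events are configured) ->
#' clinical correlates -> report rendering. Any stage failure aborts with
#' the stage name; given a seed the whole bundle is deterministic.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `records`, `summary`,
#'   `summary_significant` (when a gene list was given), `resolution_tally`,
#'   `cnv` (normalized bins and gene calls, or `NULL`), `correlates`,
#'   `matrix`, `msi_classes`, `clinical`, `truth` (when simulated), `log`,
#'   and `config`. When `config$outdir` is set the bundle is also written
#'   as records.tsv, summary.json, cnv.tsv, correlates.json, matrix.tsv and
#'   pipeline.log.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("'config' must be a pipeline_config object", call. = FALSE)
  cfg <- config$thresholds
  log <- data.frame(stage = character(0), n_in = integer(0),
                    n_out = integer(0), detail = character(0),
                    stringsAsFactors = FALSE)

  sim <- NULL
  if (is.null(config$calls)) {
    sim <- .run_stage("simulate", simulate_cohort(config$sim))
    calls <- sim$calls
    msi <- sim$msi
    clinical <- sim$clinical
    regions <- sim$regions
    log <- .stage(log, "simulate", config$sim$n_patients, nrow(sim$truth),
                  sprintf("%d patients, %s regime", config$sim$n_patients,
                          config$sim$regime))
  } else {
    calls <- config$calls
    msi <- config$msi
    clinical <- config$clinical
    regions <- config$regions
    log <- .stage(log, "ingest", NA_integer_, nrow(calls), "external tables")
  }

  msi_classes <- NULL
  if (!is.null(msi)) {
    msi_classes <- .run_stage("msi", classify_msi_cohort(
      msi, cutoff = cfg$msi_unstable_cutoff))
    if (config$exclude_msi) {
      keep <- msi_gate(msi_classes)
      n_before <- length(unique(calls$patient))
      calls <- calls[calls$patient %in% keep, , drop = FALSE]
      if (!is.null(clinical))
        clinical <- clinical[clinical$patient %in% keep, , drop = FALSE]
      if (!is.null(regions))
        regions <- regions[regions$patient %in% keep, , drop = FALSE]
      log <- .stage(log, "msi_gate", n_before, length(unique(calls$patient)),
                    sprintf("excluded %d non-MSS patient(s)",
                            n_before - length(unique(calls$patient))))
    }
  }
  if (nrow(calls) == 0L)
    stop("pipeline stage 'msi_gate' failed: no calls left after gating",
         call. = FALSE)

  filter_mode <- if (config$sim$regime == "wgs" && is.null(config$calls))
    "wgs" else "panel"
  records <- .run_stage("concordance", call_concordance(
    calls, cfg, filter = filter_mode, rescue = TRUE))
  log <- .stage(log, "concordance", nrow(calls), nrow(records),
                sprintf("filter=%s, rescue on", filter_mode))

  region_called <- NULL
  if (!is.null(regions) && nrow(regions) > 0L) {
    rf <- .run_stage("regions", panel_filter(regions, cfg))
    region_called <- rf$retained
  }
  rr <- .run_stage("regions", resolve_with_regions(records, region_called))
  records <- rr$records
  log <- .stage(log, "regions", rr$tally$examined, rr$tally$resolved,
                "multi-region resolution overlay")

  cnv <- NULL
  if (!is.null(config$sim$cnv_events)) {
    cnv <- .run_stage("cnv", {
      targets <- panel_targets(seed = config$sim$seed)
      bins <- simulate_coverage(config$sim, targets)
      bins <- gc_normalize(bins, span = cfg$loess_span)
      calls_by_comp <- cnv_calls(bins, cfg)
      list(bins = bins, calls = calls_by_comp)
    })
    records <- .run_stage("cnv", explain_private_by_deletion(
      records,
      cnv_primary = cnv$calls[cnv$calls$compartment == "primary", ],
      cnv_metastasis = cnv$calls[cnv$calls$compartment == "metastasis", ]))
    log <- .stage(log, "cnv", nrow(cnv$bins),
                  sum(cnv$calls$state != "neutral"),
                  "copy-number overlay on configured events")
  }

  summary <- .run_stage("summary", cohort_summary(records))
  summary_sig <- if (!is.null(config$significant_genes))
    .run_stage("summary", cohort_summary(records, config$significant_genes))
  else NULL
  log <- .stage(log, "summary", nrow(records), summary$n_distinct, "")

  correlates <- NULL
  if (!is.null(clinical)) {
    clin_use <- clinical[clinical$patient %in% unique(records$patient), ,
                         drop = FALSE]
    dropped <- setdiff(clinical$patient, clin_use$patient)
    correlates <- .run_stage("correlates",
                             build_correlate_tables(clin_use, records))
    log <- .stage(log, "correlates", nrow(clinical), nrow(clin_use),
                  if (length(dropped))
                    paste("patients without called mutations excluded:",
                          paste(dropped, collapse = ", "))
                  else "")
  }

  mat <- .run_stage("report", render_matrix(records))
  log <- .stage(log, "report", nrow(records), nrow(mat), "")

  result <- structure(list(
    records = records, summary = summary, summary_significant = summary_sig,
    resolution_tally = rr$tally, cnv = cnv, correlates = correlates,
    matrix = mat, msi_classes = msi_classes, clinical = clinical,
    truth = if (!is.null(sim)) sim$truth else NULL,
    log = log, config = config
  ), class = "pipeline_result")

  if (!is.null(config$outdir)) .write_bundle(result, config$outdir)
  result
}

.serialize_config <- function(config) {
  list(
    sim = unclass(config$sim)[setdiff(names(config$sim),
                                      c("clinical_probs", "cnv_events"))],
    clinical_probs = config$sim$clinical_probs,
    cnv_events = config$sim$cnv_events,
    thresholds = unclass(config$thresholds),
    significant_genes = config$significant_genes,
    exclude_msi = config$exclude_msi
  )
}

.write_bundle <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_report(result$records, p("records.tsv"), "tsv")
  jsonlite::write_json(
    list(config = .serialize_config(result$config),
         summary = unclass(result$summary),
         summary_significant = if (!is.null(result$summary_significant))
           unclass(result$summary_significant) else NULL,
         resolution_tally = result$resolution_tally),
    p("summary.json"), auto_unbox = TRUE, digits = NA, na = "null",
    pretty = TRUE)
  if (!is.null(result$cnv))
    utils::write.table(result$cnv$calls, p("cnv.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(result$correlates))
    jsonlite::write_json(result$correlates, p("correlates.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE, force = TRUE)
  mat_df <- if (nrow(result$matrix))
    cbind(data.frame(patient = rownames(result$matrix),
                     stringsAsFactors = FALSE),
          as.data.frame(result$matrix, stringsAsFactors = FALSE))
  else data.frame(patient = character(0))
  utils::write.table(mat_df, p("matrix.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(result$log, p("pipeline.log"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Concordance pipeline result\n")
  print(x$summary)
  cat(sprintf("  multi-region resolution: %d/%d discordant resolved\n",
              x$resolution_tally$resolved, x$resolution_tally$examined))
  invisible(x)
}

#' Patient-by-gene mutation matrix
#'
#' Renders classified records as a character matrix with one row per
#' patient and one column per gene (genes ordered by cohort mutation
#' frequency, then name). Cell codes: `S` shared, `P` private to primary,
#' `M` private to metastasis, `B` both by comparative analysis; a trailing
#' `*` marks an event that is loss-of-function or COSMIC-recurrent.
#' Multi-hit cells list every event, comma-separated.
#'
#' @param records `concordance_records`.
#' @return Character matrix (patients x genes); empty cohort gives a
#'   0-row, 0-column matrix.
#' @export
render_matrix <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L)
    return(matrix(character(0), nrow = 0, ncol = 0))
  code <- c(shared = "S", private_primary = "P", private_metastasis = "M",
            both_by_comparative = "B")[records$status]
  flag <- ifelse(records$loss_of_function | records$cosmic_recurrent, "*", "")
  cell <- paste0(code, flag)
  gene_freq <- tapply(records$patient, records$gene,
                      function(p) length(unique(p)))
  genes <- names(gene_freq)[order(-gene_freq, names(gene_freq))]
  patients <- sort(unique(records$patient))
  mat <- matrix("", nrow = length(patients), ncol = length(genes),
                dimnames = list(patients, genes))
  ord <- order(records$patient, records$chrom, records$pos, records$alt)
  for (i in ord) {
    r <- records$patient[i]
    g <- records$gene[i]
    mat[r, g] <- if (nzchar(mat[r, g])) paste(mat[r, g], cell[i], sep = ",")
    else cell[i]
  }
  mat
}
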