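#' GC loess normalization of tumor/normal depth ratios
#'
#' Per-target copy number is read off the tumor/normal mean-depth ratio
#' after removing the smooth dependence of coverage on local GC content:
#' a locally weighted regression of the raw ratio on GC is fitted with a
#' robust (symmetric-family) loess — so bins carrying real copy events are
#' downweighted rather than modelled — and each ratio is divided by its
#' fitted value. Ratios are then recentred so the median normalized ratio
#' is 1, which anchors the diploid baseline under the assumption that most
#' of the territory is copy-neutral. Bins with zero normal depth are
#' masked, not imputed, and propagate as `NA`.
#'
#' @param bins A `coverage_bins` data.frame for one tumor/normal pair
#'   (columns `gc`, `tumor_depth`, `normal_depth`; see [read_coverage()]).
#'   If a `compartment` column with several values is present, each
#'   compartment is normalized independently.
#' @param span Loess smoothing span, in (0, 1].
#' @return The input with columns `raw_ratio`, `norm_ratio`, `log2_ratio`,
#'   and logical `masked` added.
#' @export
gc_normalize <- function(bins, span = 0.3) {
  if (!is.numeric(span) || length(span) != 1L || is.na(span) ||
      span <= 0 || span > 1)
    stop("'span' must lie in (0, 1]", call. = FALSE)
  bins <- as.data.frame(bins)
  if ("compartment" %in% names(bins) &&
      length(unique(bins$compartment)) > 1L) {
    parts <- lapply(split(bins, bins$compartment), gc_normalize, span = span)
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    class(out) <- unique(c("coverage_bins", class(out)))
    return(out)
  }
  masked <- is.na(bins$normal_depth) | bins$normal_depth <= 0 |
    is.na(bins$tumor_depth)
  if (all(masked))
    stop("all coverage bins are masked (zero or missing normal depth)",
         call. = FALSE)
  raw <- ifelse(masked, NA_real_, bins$tumor_depth / bins$normal_depth)
  if (sum(!masked) < 50L)
    stop("too few unmasked bins to fit the GC loess (need >= 50, have ",
         sum(!masked), ")", call. = FALSE)
  fit <- stats::loess(raw ~ gc, data = data.frame(raw = raw, gc = bins$gc),
                      span = span, degree = 2, family = "symmetric",
                      na.action = stats::na.exclude)
  fitted_vals <- stats::predict(fit, newdata = data.frame(gc = bins$gc))
  bad_fit <- !is.na(fitted_vals) & fitted_vals <= 0
  masked <- masked | is.na(fitted_vals) | bad_fit
  norm <- ifelse(masked, NA_real_, raw / fitted_vals)
  norm <- norm / stats::median(norm, na.rm = TRUE)
  bins$raw_ratio <- raw
  bins$norm_ratio <- norm
  bins$log2_ratio <- log2(norm)
  bins$masked <- masked
  class(bins) <- unique(c("coverage_bins", class(bins)))
  bins
}

#' Gene-level copy-number call from normalized bins
#'
#' Averages the log2 normalized ratio over a gene's unmasked bins and
#' thresholds it: deletion at or below `cnv_del_log2`, amplification at or
#' above `cnv_amp_log2`, gain at or above `cnv_gain_log2`, otherwise
#' neutral. With fewer than `cnv_min_bins` usable bins the gene is a
#' no-call with a reason, not silently neutral. These cutoffs are package
#' defaults (no published values exist) and live in [threshold_config()].
#'
#' @param bins Normalized `coverage_bins` (after [gc_normalize()]).
#' @param gene Gene symbol to call.
#' @param cfg A [threshold_config()].
#' @return One-row data.frame: `gene`, `state` (`deletion` / `neutral` /
#'   `gain` / `amplification` / `no_call`), `mean_log2`, `n_bins`, `reason`.
#' @export
call_gene_cnv <- function(bins, gene, cfg = threshold_config()) {
  bins <- as.data.frame(bins)
  if (!"log2_ratio" %in% names(bins))
    stop("bins are not normalized; run gc_normalize() first", call. = FALSE)
  sel <- bins$gene == gene & !bins$masked & !is.na(bins$log2_ratio)
  n <- sum(sel)
  if (n < cfg$cnv_min_bins)
    return(data.frame(gene = gene, state = "no_call", mean_log2 = NA_real_,
                      n_bins = n,
                      reason = sprintf("only %d unmasked bins (need >= %d)",
                                       n, cfg$cnv_min_bins),
                      stringsAsFactors = FALSE))
  m <- mean(bins$log2_ratio[sel])
  state <- if (m <= cfg$cnv_del_log2) "deletion"
  else if (m >= cfg$cnv_amp_log2) "amplification"
  else if (m >= cfg$cnv_gain_log2) "gain"
  else "neutral"
  data.frame(gene = gene, state = state, mean_log2 = m, n_bins = n,
             reason = NA_character_, stringsAsFactors = FALSE)
}

#' Copy-number calls for every gene in a normalized bin table
#'
#' @param bins Normalized `coverage_bins`; a `compartment` column, if
#'   present, is carried through (genes are called per compartment).
#' @param cfg A [threshold_config()].
#' @return data.frame of [call_gene_cnv()] rows.
#' @export
cnv_calls <- function(bins, cfg = threshold_config()) {
  bins <- as.data.frame(bins)
  if ("compartment" %in% names(bins) &&
      length(unique(bins$compartment)) > 1L) {
    out <- do.call(rbind, lapply(split(bins, bins$compartment), function(b) {
      calls <- cnv_calls(b, cfg)
      calls$compartment <- b$compartment[1]
      calls
    }))
    rownames(out) <- NULL
    return(out[, c("compartment", setdiff(names(out), "compartment"))])
  }
  out <- do.call(rbind, lapply(sort(unique(bins$gene)), function(g)
    call_gene_cnv(bins, g, cfg)))
  rownames(out) <- NULL
  out
}

#' Explain private mutations by compartment-specific deletions
#'
#' A mutation called only in one compartment need not have arisen there
#' late: if the other compartment deleted the locus, the mutation was lost
#' with the DNA. Any private record whose gene is called `deletion` in the
#' opposite compartment, and whose resolution is still open, receives
#' `resolution = "explained_by_deletion"`. Shared and rescued records are
#' never touched.
#'
#' @param records `concordance_records`.
#' @param cnv_primary,cnv_metastasis Gene-level CNV call tables (as from
#'   [cnv_calls()]) for the two compartments; either may be `NULL`.
#' @return Updated `concordance_records`.
#' @export
explain_private_by_deletion <- function(records, cnv_primary = NULL,
                                        cnv_metastasis = NULL) {
  records <- as.data.frame(records)
  deleted_in <- function(cnv) {
    if (is.null(cnv) || nrow(as.data.frame(cnv)) == 0L) return(character(0))
    cnv <- as.data.frame(cnv)
    cnv$gene[cnv$state == "deletion"]
  }
  del_m <- deleted_in(cnv_metastasis)
  del_p <- deleted_in(cnv_primary)
  hit <- (records$status == "private_primary" & records$gene %in% del_m) |
    (records$status == "private_metastasis" & records$gene %in% del_p)
  hit <- hit & records$resolution == "unresolved"
  records$resolution[hit] <- "explained_by_deletion"
  class(records) <- unique(c("concordance_records", class(records)))
  records
}
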