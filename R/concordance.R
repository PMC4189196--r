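.record_sort <- function(records) {
  if (nrow(records))
    records <- records[order(records$patient, records$chrom, records$pos,
                             records$alt), ]
  rownames(records) <- NULL
  records
}

.match_cohort <- function(primary_calls, metastasis_calls,
                          cfg = threshold_config()) {
  key_cols <- c("patient", "chrom", "pos", "ref", "alt")
  anno_cols <- c("gene", "effect", "protein_change", "cosmic_count")
  take <- function(df) {
    df <- as.data.frame(df)
    if (nrow(df) == 0L) {
      df <- df[, intersect(c(key_cols, anno_cols, "af"), names(df)), drop = FALSE]
      for (col in setdiff(c(key_cols, anno_cols, "af"), names(df)))
        df[[col]] <- vector(mode = if (col %in% c("pos", "cosmic_count", "af"))
          "numeric" else "character")
    }
    df[, c(key_cols, anno_cols, "af")]
  }
  p <- take(primary_calls)
  m <- take(metastasis_calls)
  mg <- merge(p, m, by = key_cols, all = TRUE, suffixes = c("_p", "_m"))
  for (col in anno_cols) {
    cp <- paste0(col, "_p"); cm <- paste0(col, "_m")
    mg[[col]] <- ifelse(is.na(mg[[cp]]), mg[[cm]], mg[[cp]])
    mg[[cp]] <- mg[[cm]] <- NULL
  }
  in_p <- !is.na(mg$af_p)
  in_m <- !is.na(mg$af_m)
  records <- data.frame(
    patient = mg$patient, chrom = mg$chrom, pos = mg$pos,
    ref = mg$ref, alt = mg$alt, gene = mg$gene, effect = mg$effect,
    protein_change = mg$protein_change, cosmic_count = mg$cosmic_count,
    af_primary = mg$af_p, af_metastasis = mg$af_m,
    status = ifelse(in_p & in_m, "shared",
                    ifelse(in_p, "private_primary", "private_metastasis")),
    rescued_from = NA_character_,
    rescue_alt_reads = NA_integer_, rescue_depth = NA_integer_,
    resolution = "unresolved",
    stringsAsFactors = FALSE
  )
  records$loss_of_function <- records$effect %in% cfg$lof_effects
  records$cosmic_recurrent <- !is.na(records$cosmic_count) &
    records$cosmic_count >= cfg$cosmic_recurrent_min
  records <- .record_sort(records)
  class(records) <- c("concordance_records", class(records))
  records
}

#' Match one patient's primary and metastatic call sets
#'
#' The union of the two call sets defines the patient's distinct mutations
#' (each genomic key counted once per patient pair). A variant present in
#' both sets is `shared`; present in exactly one, `private_primary` or
#' `private_metastasis`. Matching identity is the normalized genomic key,
#' never the protein change, so two different mutations in the same gene
#' (convergent evolution) remain distinct events. Loss-of-function and
#' COSMIC-recurrence flags are annotated from the effect class and the
#' catalogue count.
#'
#' @param primary_calls,metastasis_calls Called (post-filter) variant
#'   tables for the two compartments of one patient, with normalized keys
#'   and an `af` column.
#' @param cfg A [threshold_config()] (for the flag definitions).
#' @return A `concordance_records` data.frame with provisional statuses,
#'   `resolution = "unresolved"` and empty rescue evidence.
#' @export
match_pair <- function(primary_calls, metastasis_calls,
                       cfg = threshold_config()) {
  pats <- unique(c(unique(as.character(primary_calls$patient)),
                   unique(as.character(metastasis_calls$patient))))
  if (length(pats) > 1L)
    stop("patient-id mismatch: call sets span patients ",
         paste(pats, collapse = ", "),
         "; match_pair() operates on a single patient pair", call. = FALSE)
  .match_cohort(primary_calls, metastasis_calls, cfg)
}

#' Comparative rescue of private calls
#'
#' For each private record, the mutant-allele pileup of the *other* sample
#' is examined. If the mutant allele is present in at least
#' `rescue_min_reads` reads and at least `rescue_min_af` of all reads
#' there, the event is relabelled `both_by_comparative` and the supporting
#' evidence is recorded; otherwise the record is unchanged. A zero-depth
#' alternate pileup can never rescue and is logged in the `no_rescue_log`
#' attribute of the result.
#'
#' @param records `concordance_records` (any mix of statuses; only
#'   `private_*` records are eligible).
#' @param alternate_obs Pileup observations, a data.frame with columns
#'   `patient`, `chrom`, `pos`, `ref`, `alt`, `role` (`primary` /
#'   `metastasis`), `depth`, `alt_reads` — typically the unfiltered call
#'   table restricted to tumor roles.
#' @param cfg A [threshold_config()].
#' @return Updated `concordance_records`; rescued rows have
#'   `status = "both_by_comparative"`, the original side in `rescued_from`,
#'   and the evidence in `rescue_alt_reads` / `rescue_depth`.
#' @export
rescue_private <- function(records, alternate_obs, cfg = threshold_config()) {
  records <- as.data.frame(records)
  priv <- records$status %in% c("private_primary", "private_metastasis")
  if (!any(priv)) {
    class(records) <- unique(c("concordance_records", class(records)))
    return(.record_sort(records))
  }
  obs <- as.data.frame(alternate_obs)
  need <- c("patient", "chrom", "pos", "ref", "alt", "role", "depth", "alt_reads")
  missing_cols <- setdiff(need, names(obs))
  if (length(missing_cols))
    stop("'alternate_obs' is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  side_needed <- ifelse(records$status == "private_primary",
                        "metastasis", "primary")
  rid <- paste(records$patient, records$chrom, records$pos, records$ref,
               records$alt, side_needed, sep = "\r")
  oid <- paste(obs$patient, obs$chrom, obs$pos, obs$ref, obs$alt, obs$role,
               sep = "\r")
  hit <- match(rid, oid)
  depth <- obs$depth[hit]
  alt <- obs$alt_reads[hit]
  ok <- priv & !is.na(depth) & depth > 0 & alt >= cfg$rescue_min_reads &
    (alt / depth) >= cfg$rescue_min_af
  no_depth <- priv & !is.na(depth) & depth == 0
  records$rescued_from[ok] <- records$status[ok]
  records$status[ok] <- "both_by_comparative"
  records$rescue_alt_reads[ok] <- alt[ok]
  records$rescue_depth[ok] <- depth[ok]
  out <- .record_sort(records)
  class(out) <- unique(c("concordance_records", class(out)))
  attr(out, "no_rescue_log") <- records[no_depth,
                                        c("patient", "chrom", "pos", "ref", "alt")]
  out
}

#' Resolve discordant calls against additional tumor regions
#'
#' A mutation private to one compartment that is found in at least one
#' additional, spatially separate region of the *other* compartment was in
#' truth subclonal there, not absent. Resolution is an overlay: the
#' `resolution` field is set (`resolved_subclonal_in_primary` /
#' `resolved_subclonal_in_metastasis`) while `status` is untouched, so both
#' the as-called and the resolved views remain reportable. Records whose
#' resolution was already assigned (e.g. `explained_by_deletion`) are left
#' alone.
#'
#' @param records `concordance_records`.
#' @param region_calls Called variants from additional regions: data.frame
#'   with `patient`, `compartment` (`primary` / `metastasis`; anything else
#'   is an error), `region_id`, `chrom`, `pos`, `ref`, `alt`. `NULL` or
#'   empty leaves everything unresolved.
#' @return A list: `records` (updated) and `tally` with `examined` (private
#'   records of patients having extra regions), `resolved`, `unresolved`,
#'   and the per-direction resolved counts.
#' @export
resolve_with_regions <- function(records, region_calls) {
  records <- as.data.frame(records)
  empty_tally <- list(examined = 0L, resolved = 0L, unresolved = 0L,
                      resolved_subclonal_in_primary = 0L,
                      resolved_subclonal_in_metastasis = 0L)
  if (is.null(region_calls) || nrow(as.data.frame(region_calls)) == 0L) {
    class(records) <- unique(c("concordance_records", class(records)))
    return(list(records = .record_sort(records), tally = empty_tally))
  }
  reg <- as.data.frame(region_calls)
  bad <- setdiff(unique(reg$compartment), c("primary", "metastasis"))
  if (length(bad))
    stop("region(s) with unknown compartment label: ",
         paste(bad, collapse = ", "), call. = FALSE)
  priv <- records$status %in% c("private_primary", "private_metastasis")
  other <- ifelse(records$status == "private_primary", "metastasis", "primary")
  rid <- paste(records$patient, records$chrom, records$pos, records$ref,
               records$alt, other, sep = "\r")
  oid <- paste(reg$patient, reg$chrom, reg$pos, reg$ref, reg$alt,
               reg$compartment, sep = "\r")
  found <- priv & records$resolution == "unresolved" & (rid %in% oid)
  records$resolution[found] <-
    ifelse(records$status[found] == "private_metastasis",
           "resolved_subclonal_in_primary", "resolved_subclonal_in_metastasis")
  examined <- priv & records$patient %in% unique(reg$patient)
  tally <- list(
    examined = sum(examined),
    resolved = sum(found & examined),
    unresolved = sum(examined) - sum(found & examined),
    resolved_subclonal_in_primary =
      sum(records$resolution[examined] == "resolved_subclonal_in_primary"),
    resolved_subclonal_in_metastasis =
      sum(records$resolution[examined] == "resolved_subclonal_in_metastasis")
  )
  out <- .record_sort(records)
  class(out) <- unique(c("concordance_records", class(out)))
  list(records = out, tally = tally)
}

#' Cohort-level concordance summary
#'
#' Counts distinct mutations (each genomic key once per patient pair) and
#' partitions them into shared and private. Events rescued by comparative
#' analysis (`both_by_comparative`) count toward the shared fraction — the
#' event is, on review, present in both compartments — but the summary also
#' reports `shared_fraction_as_called`, in which rescued events are counted
#' on their originally called private side. The two views bracket the
#' reading of a published shared fraction whose rescue handling is not
#' stated.
#'
#' @param records `concordance_records`.
#' @param significant_genes Optional character vector; when given, the
#'   summary is restricted to records whose gene is in the list (e.g. a
#'   significantly-mutated-gene set supplied by the user).
#' @return An object of class `cohort_summary`: counts, `shared_fraction`
#'   (NA with a note when there are no records), the strict as-called
#'   fraction, and a per-gene breakdown.
#' @export
cohort_summary <- function(records, significant_genes = NULL) {
  records <- as.data.frame(records)
  restricted <- !is.null(significant_genes)
  if (restricted)
    records <- records[records$gene %in% significant_genes, , drop = FALSE]
  n <- nrow(records)
  shared_like <- records$status %in% c("shared", "both_by_comparative")
  n_shared <- sum(shared_like)
  n_both <- sum(records$status == "both_by_comparative")
  n_pp <- sum(records$status == "private_primary")
  n_pm <- sum(records$status == "private_metastasis")
  ## strict view: rescued events revert to their originally called side
  n_pp_strict <- n_pp + sum(records$rescued_from %in% "private_primary")
  n_pm_strict <- n_pm + sum(records$rescued_from %in% "private_metastasis")
  per_gene <- if (n) {
    ag <- stats::aggregate(
      cbind(n_shared = shared_like,
            n_private_primary = records$status == "private_primary",
            n_private_metastasis = records$status == "private_metastasis"),
      by = list(gene = records$gene), FUN = sum)
    ag$n_distinct <- ag$n_shared + ag$n_private_primary + ag$n_private_metastasis
    ag[order(-ag$n_distinct, ag$gene), ]
  } else {
    data.frame(gene = character(0), n_shared = integer(0),
               n_private_primary = integer(0),
               n_private_metastasis = integer(0), n_distinct = integer(0))
  }
  rownames(per_gene) <- NULL
  structure(list(
    n_patients = length(unique(records$patient)),
    n_distinct = n,
    n_shared = n_shared,
    n_both_by_comparative = n_both,
    n_private_primary = n_pp,
    n_private_metastasis = n_pm,
    shared_fraction = if (n > 0) n_shared / n else NA_real_,
    shared_fraction_as_called =
      if (n > 0) (n_shared - n_both) / n else NA_real_,
    n_private_primary_as_called = n_pp_strict,
    n_private_metastasis_as_called = n_pm_strict,
    fraction_note = if (n == 0) "no records: shared fraction undefined" else NULL,
    restricted_to = if (restricted) significant_genes else NULL,
    per_gene = per_gene
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort concordance summary (%d patients, %d distinct mutations%s)\n",
              x$n_patients, x$n_distinct,
              if (!is.null(x$restricted_to)) ", gene-restricted" else ""))
  if (x$n_distinct == 0) {
    cat("  ", x$fraction_note, "\n")
    return(invisible(x))
  }
  cat(sprintf("  shared %d (%.1f%%; as-called %.1f%%), private primary %d, private metastasis %d\n",
              x$n_shared, 100 * x$shared_fraction,
              100 * x$shared_fraction_as_called,
              x$n_private_primary, x$n_private_metastasis))
  if (x$n_both_by_comparative > 0)
    cat(sprintf("  of shared, %d labelled 'both' by comparative analysis\n",
                x$n_both_by_comparative))
  invisible(x)
}

#' Per-gene mutated-patient fractions
#'
#' For each gene, the fraction of patients carrying at least one record in
#' it, optionally with deltas against externally supplied reference
#' frequencies (e.g. a published cohort); reference values are input, never
#' bundled. Genes absent from the cohort but present in the reference are
#' reported with fraction 0.
#'
#' @param records `concordance_records`.
#' @param n_patients Cohort size (> 0); the denominator.
#' @param reference Optional named numeric vector (gene -> fraction).
#' @return data.frame with `gene`, `n_mutated_patients`, `fraction`, and —
#'   when a reference is given — `reference` and `delta`.
#' @export
gene_frequency_table <- function(records, n_patients, reference = NULL) {
  if (!is.numeric(n_patients) || n_patients <= 0)
    stop("'n_patients' must be positive", call. = FALSE)
  records <- as.data.frame(records)
  tab <- if (nrow(records)) {
    counts <- tapply(records$patient, records$gene,
                     function(p) length(unique(p)))
    data.frame(gene = names(counts), n_mutated_patients = as.integer(counts),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(0), n_mutated_patients = integer(0))
  }
  if (!is.null(reference)) {
    extra <- setdiff(names(reference), tab$gene)
    if (length(extra))
      tab <- rbind(tab, data.frame(gene = extra,
                                   n_mutated_patients = 0L))
  }
  tab$fraction <- tab$n_mutated_patients / n_patients
  if (!is.null(reference)) {
    tab$reference <- unname(reference[tab$gene])
    tab$delta <- tab$fraction - ifelse(is.na(tab$reference), 0, tab$reference)
  }
  tab <- tab[order(-tab$fraction, tab$gene), ]
  rownames(tab) <- NULL
  tab
}

#' Full concordance classification from a long call table
#'
#' Convenience orchestrator over one cohort: applies the regime's retention
#' filter per tumor sample, matches each patient's primary and metastatic
#' call sets, and (by default) applies comparative rescue using the
#' unfiltered tumor pileups.
#'
#' @param calls Long `mutation_calls` with roles `normal`, `primary`,
#'   `metastasis` (role `normal` required only for `filter = "wgs"`).
#' @param cfg A [threshold_config()].
#' @param filter `"panel"` (non-synonymous, AF > 5%), `"wgs"` (trio rule),
#'   or `"none"` (calls are taken as already filtered; any row with
#'   `alt_reads > 0` in a tumor counts as called there).
#' @param rescue Apply [rescue_private()] afterwards?
#' @return `concordance_records` for the whole cohort.
#' @export
call_concordance <- function(calls, cfg = threshold_config(),
                             filter = c("panel", "wgs", "none"),
                             rescue = TRUE) {
  filter <- match.arg(filter)
  calls <- as.data.frame(calls)
  if (filter == "wgs") {
    w <- wgs_filter(calls, cfg)$retained
    to_calls <- function(w, side) {
      ok <- w[[paste0("pass_", side)]]
      data.frame(patient = w$patient[ok], chrom = w$chrom[ok], pos = w$pos[ok],
                 ref = w$ref[ok], alt = w$alt[ok], gene = w$gene[ok],
                 effect = w$effect[ok], protein_change = w$protein_change[ok],
                 cosmic_count = w$cosmic_count[ok],
                 af = w[[paste0("af_", side)]][ok],
                 stringsAsFactors = FALSE)
    }
    p <- to_calls(w, "primary")
    m <- to_calls(w, "metastasis")
  } else {
    pick <- function(side) calls[calls$role == side, , drop = FALSE]
    if (filter == "panel") {
      p <- panel_filter(pick("primary"), cfg)$retained
      m <- panel_filter(pick("metastasis"), cfg)$retained
    } else {
      p <- pick("primary")
      p <- p[p$alt_reads > 0, , drop = FALSE]
      m <- pick("metastasis")
      m <- m[m$alt_reads > 0, , drop = FALSE]
    }
  }
  records <- .match_cohort(p, m, cfg)
  if (rescue) {
    obs <- calls[calls$role %in% c("primary", "metastasis"),
                 c("patient", "chrom", "pos", "ref", "alt", "role",
                   "depth", "alt_reads")]
    records <- rescue_private(records, obs, cfg)
  }
  records
}
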