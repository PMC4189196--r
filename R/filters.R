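#' Targeted-panel call retention filter
#'
#' Retains a call iff its effect is non-synonymous (anything but
#' `synonymous` or `noncoding`) and its allele fraction is strictly above
#' `panel_min_af` (the published rule keeps calls "above 5% allele
#' frequency", read here as a strict inequality; a call at exactly 5% is
#' rejected). The allele fraction is recomputed from `alt_reads / depth`.
#' Every rejection is returned with its reason, so a clinical pipeline can
#' audit what was removed and why.
#'
#' @param calls A `mutation_calls` data.frame (any subset of samples; the
#'   filter is applied per row, i.e. per sample under test).
#' @param cfg A [threshold_config()].
#' @return A list with elements `retained` and `rejected`; `rejected`
#'   carries a `reason` column (`"effect"`, `"af"`, or `"effect;af"`).
#' @export
panel_filter <- function(calls, cfg = threshold_config()) {
  calls <- as.data.frame(calls)
  if (nrow(calls) == 0L) {
    rej <- calls
    rej$reason <- character(0)
    return(list(retained = calls, rejected = rej))
  }
  if (any(!(calls$effect %in% MUTATION_EFFECTS)))
    stop("unknown effect class in 'calls'; recognized effects are: ",
         paste(MUTATION_EFFECTS, collapse = ", "), call. = FALSE)
  af <- ifelse(calls$depth > 0, calls$alt_reads / calls$depth, 0)
  effect_ok <- calls$effect %in% NON_SYNONYMOUS_EFFECTS
  af_ok <- af > cfg$panel_min_af
  keep <- effect_ok & af_ok
  retained <- calls[keep, , drop = FALSE]
  retained$af <- af[keep]
  rejected <- calls[!keep, , drop = FALSE]
  rejected$af <- af[!keep]
  rejected$reason <- paste0(ifelse(effect_ok[!keep], "", "effect"),
                            ifelse(!effect_ok[!keep] & !af_ok[!keep], ";", ""),
                            ifelse(af_ok[!keep], "", "af"))
  rownames(retained) <- rownames(rejected) <- NULL
  list(retained = retained, rejected = rejected)
}

.trio_wide <- function(trio_calls) {
  df <- as.data.frame(trio_calls)
  if (!"role" %in% names(df))
    stop("trio calls need a 'role' column (normal/primary/metastasis)",
         call. = FALSE)
  key_cols <- c("patient", "chrom", "pos", "ref", "alt")
  anno_cols <- intersect(c("gene", "effect", "protein_change", "cosmic_count"),
                         names(df))
  pick <- function(role) {
    sub <- df[df$role == role, c(key_cols, anno_cols, "depth", "alt_reads")]
    names(sub)[names(sub) == "depth"] <- paste0("depth_", role)
    names(sub)[names(sub) == "alt_reads"] <- paste0("alt_", role)
    sub
  }
  p <- pick("primary")
  m <- pick("metastasis")
  n <- pick("normal")
  w <- merge(p, m, by = key_cols, all = TRUE, suffixes = c("", ".m"))
  for (col in anno_cols) {
    alt_col <- paste0(col, ".m")
    if (alt_col %in% names(w)) {
      w[[col]][is.na(w[[col]])] <- w[[alt_col]][is.na(w[[col]])]
      w[[alt_col]] <- NULL
    }
  }
  w <- merge(w, n[, c(key_cols, "depth_normal", "alt_normal")],
             by = key_cols, all = TRUE)
  if (any(is.na(w$depth_normal)))
    stop("missing normal observation for ",
         sum(is.na(w$depth_normal)), " variant(s)", call. = FALSE)
  w
}

#' WGS tumor/normal trio call retention filter
#'
#' Implements the whole-genome post-calling rule: a variant is retained iff
#' it reaches at least `wgs_min_reads` mutant reads and `wgs_min_af` allele
#' frequency in at least one of the two tumors, and the best tumor allele
#' frequency is at least `wgs_normal_ratio` times the frequency in the
#' matched normal. A normal frequency of zero passes the ratio test
#' whenever any tumor frequency is positive. Calls failing either clause
#' are removed and logged with the failing clause.
#'
#' @param trio_calls Long `mutation_calls` with `role` in
#'   normal/primary/metastasis; a missing normal observation is an error.
#'   Zero counts are legitimate observations.
#' @param cfg A [threshold_config()].
#' @return A list with `retained` and `rejected` variant tables (wide, one
#'   row per variant with per-role depth/alt columns); `rejected` carries a
#'   `reason` column (`"reads_af"`, `"normal_ratio"`, or both).
#' @export
wgs_filter <- function(trio_calls, cfg = threshold_config()) {
  w <- .trio_wide(trio_calls)
  if (nrow(w) == 0L) {
    w$reason <- character(0)
    return(list(retained = w, rejected = w))
  }
  w$depth_primary[is.na(w$depth_primary)] <- 0L
  w$alt_primary[is.na(w$alt_primary)] <- 0L
  w$depth_metastasis[is.na(w$depth_metastasis)] <- 0L
  w$alt_metastasis[is.na(w$alt_metastasis)] <- 0L
  af_p <- ifelse(w$depth_primary > 0, w$alt_primary / w$depth_primary, 0)
  af_m <- ifelse(w$depth_metastasis > 0, w$alt_metastasis / w$depth_metastasis, 0)
  af_n <- ifelse(w$depth_normal > 0, w$alt_normal / w$depth_normal, 0)
  pass_p <- w$alt_primary >= cfg$wgs_min_reads & af_p >= cfg$wgs_min_af
  pass_m <- w$alt_metastasis >= cfg$wgs_min_reads & af_m >= cfg$wgs_min_af
  tumor_ok <- pass_p | pass_m
  max_af <- pmax(af_p, af_m)
  ratio_ok <- ifelse(af_n == 0, max_af > 0,
                     max_af >= cfg$wgs_normal_ratio * af_n)
  keep <- tumor_ok & ratio_ok
  w$af_primary <- af_p
  w$af_metastasis <- af_m
  w$af_normal <- af_n
  w$pass_primary <- pass_p
  w$pass_metastasis <- pass_m
  retained <- w[keep, , drop = FALSE]
  rejected <- w[!keep, , drop = FALSE]
  rejected$reason <- paste0(ifelse(tumor_ok[!keep], "", "reads_af"),
                            ifelse(!tumor_ok[!keep] & !ratio_ok[!keep], ";", ""),
                            ifelse(ratio_ok[!keep], "", "normal_ratio"))
  rownames(retained) <- rownames(rejected) <- NULL
  list(retained = retained, rejected = rejected)
}
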