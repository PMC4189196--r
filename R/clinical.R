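#' Pearson chi-square test on a 2x2 contingency table
#'
#' Pearson's chi-square with 1 degree of freedom and, by default, *no*
#' continuity correction: with typical clinical-cohort counts the
#' uncorrected statistic is what reproduces published two-digit P values
#' (e.g. rows treated/untreated by discordant yes/no), while the Yates
#' correction roughly doubles them. The correction is available as a flag
#' and the choice is echoed in the result.
#'
#' @param tab 2x2 matrix of non-negative counts (rows = groups,
#'   columns = outcome yes/no).
#' @param correct Apply the Yates continuity correction? Default `FALSE`.
#' @return List with `statistic`, `p_value`, `df`, `fractions` (per-row
#'   proportion of the first column), and `correction`.
#' @examples
#' contingency_test(matrix(c(22, 6, 11, 13), 2, byrow = TRUE))
#' @export
contingency_test <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("'tab' must be a 2x2 table", call. = FALSE)
  if (any(is.na(tab)) || any(tab < 0))
    stop("counts must be non-negative and non-missing", call. = FALSE)
  if (sum(tab) == 0)
    stop("empty table: test undefined", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal: chi-square test undefined", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic),
       p_value = unname(ct$p.value),
       df = unname(ct$parameter),
       fractions = tab[, 1] / rowSums(tab),
       correction = correct)
}

#' Two-sample comparison of group means
#'
#' Two-sided t test of the named variant (`student`: pooled variance, the
#' default; `welch`: unequal variances). Groups with zero variance and
#' equal means are degenerate for the t statistic; by convention the
#' result is then t = 0, p = 1, flagged in `note`.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param variant `"student"` or `"welch"`.
#' @return List with `statistic`, `p_value`, `means` (length 2),
#'   `variant`, and optional `note`.
#' @export
mean_comparison <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y))
    return(list(statistic = 0, p_value = 1, means = c(mean(x), mean(y)),
                variant = variant,
                note = "degenerate: zero variance in both groups, equal means"))
  tt <- stats::t.test(x, y, var.equal = (variant == "student"))
  list(statistic = unname(tt$statistic), p_value = unname(tt$p.value),
       means = c(mean(x), mean(y)), variant = variant)
}

.per_patient_concordance <- function(records) {
  records <- as.data.frame(records)
  priv <- records$status %in% c("private_primary", "private_metastasis")
  pats <- unique(records$patient)
  data.frame(
    patient = pats,
    n_mutations = as.integer(table(records$patient)[pats]),
    discordant = as.logical(tapply(priv, records$patient, any)[pats]),
    primary_only = as.logical(
      tapply(records$status == "private_primary", records$patient, any)[pats]),
    stringsAsFactors = FALSE
  )
}

.ct_or_flag <- function(tab, label, correct = FALSE) {
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  list(label = label, table = tab,
       test = if (degenerate) NULL else contingency_test(tab, correct = correct),
       degenerate = degenerate,
       note = if (degenerate) "degenerate marginal: no test run" else NULL)
}

#' Clinical correlate tables for mutational concordance
#'
#' Builds the contingency tables and group comparisons relating
#' concordance to clinical covariates:
#' (a) among concurrently resected patients, chemonaive vs pre-treated by
#' discordant (>= 1 private mutation) yes/no;
#' (b) pre-treated concurrent resections vs subsequent resections in which
#' only the metastasis was treated, by primary-only mutation yes/no;
#' (c) descriptive splits of burden and discordance by primary location
#' and by resection timing;
#' plus Student-t comparisons of mutation burden and primary tumor size
#' between chemonaive and pre-treated patients. Per-patient discordance
#' and burden are always derived from the concordance records, never
#' free-entered. Tables with a degenerate marginal are emitted flagged,
#' with no test run.
#'
#' @param clinical Clinical table (columns `patient`, `resection`,
#'   `treatment`, `treated_compartment`, `primary_size_cm`, `location`).
#' @param records `concordance_records` for the same patients; patients
#'   present on one side only raise an error listing the ids (patients
#'   with zero distinct mutations must be handled by the caller).
#' @param correct Continuity correction flag passed to
#'   [contingency_test()].
#' @return List with elements `treatment_discordance`,
#'   `resection_primary_only`, `by_location`, `by_resection`,
#'   `burden_comparison`, `size_comparison`, and `per_patient`.
#' @export
build_correlate_tables <- function(clinical, records, correct = FALSE) {
  clinical <- as.data.frame(clinical)
  pp <- .per_patient_concordance(records)
  only_clin <- setdiff(clinical$patient, pp$patient)
  only_rec <- setdiff(pp$patient, clinical$patient)
  if (length(only_clin) || length(only_rec))
    stop("patient sets differ between clinical table and records; ",
         if (length(only_clin)) paste0("clinical only: ",
                                       paste(only_clin, collapse = ", "), ". "),
         if (length(only_rec)) paste0("records only: ",
                                      paste(only_rec, collapse = ", "), "."),
         call. = FALSE)
  d <- merge(clinical, pp, by = "patient")
  chemonaive <- d$treatment == "chemonaive"

  cc <- d[d$resection == "concurrent", ]
  tab_a <- rbind(
    chemonaive = c(sum(cc$discordant[cc$treatment == "chemonaive"]),
                   sum(!cc$discordant[cc$treatment == "chemonaive"])),
    prior_treatment = c(sum(cc$discordant[cc$treatment == "prior_treatment"]),
                        sum(!cc$discordant[cc$treatment == "prior_treatment"]))
  )
  colnames(tab_a) <- c("discordant", "concordant")

  g1 <- d$treatment == "prior_treatment" & d$resection == "concurrent"
  g2 <- d$resection == "subsequent" &
    d$treatment == "prior_treatment" &
    !is.na(d$treated_compartment) & d$treated_compartment == "metastasis_only"
  tab_b <- rbind(
    treated_concurrent = c(sum(d$primary_only[g1]), sum(!d$primary_only[g1])),
    subsequent_met_treated = c(sum(d$primary_only[g2]), sum(!d$primary_only[g2]))
  )
  colnames(tab_b) <- c("primary_only", "none")

  descr <- function(split_col) {
    do.call(rbind, lapply(split(d, d[[split_col]]), function(g)
      data.frame(group = g[[split_col]][1], n = nrow(g),
                 mean_mutations = mean(g$n_mutations),
                 discordant_fraction = mean(g$discordant),
                 stringsAsFactors = FALSE)))
  }

  res <- list(
    treatment_discordance = .ct_or_flag(
      tab_a, "concurrent resections: treatment by discordance", correct),
    resection_primary_only = .ct_or_flag(
      tab_b, "pre-treated: resection timing by primary-only mutations", correct),
    by_location = descr("location"),
    by_resection = descr("resection"),
    burden_comparison = if (sum(chemonaive) >= 2 && sum(!chemonaive) >= 2)
      mean_comparison(d$n_mutations[chemonaive], d$n_mutations[!chemonaive])
    else NULL,
    size_comparison = if (sum(chemonaive) >= 2 && sum(!chemonaive) >= 2)
      mean_comparison(d$primary_size_cm[!chemonaive],
                      d$primary_size_cm[chemonaive])
    else NULL,
    per_patient = pp
  )
  res
}
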