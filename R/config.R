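#' Closed vocabulary of coding-effect classes
#'
#' Every mutation record carries one of these effect labels. The
#' non-synonymous subset (everything except `synonymous` and `noncoding`)
#' is what the panel filter retains.
#'
#' @format Character vector of the seven recognized effect classes.
#' @export
MUTATION_EFFECTS <- c("missense", "nonsense", "frameshift", "splice_site",
                      "synonymous", "inframe_indel", "noncoding")

#' @rdname MUTATION_EFFECTS
#' @format NULL
#' @export
NON_SYNONYMOUS_EFFECTS <- setdiff(MUTATION_EFFECTS, c("synonymous", "noncoding"))

#' Default microsatellite marker panel
#'
#' The five-marker genotyping panel (two mononucleotide, three dinucleotide
#' repeats) used for MSI typing.
#'
#' @format Character vector of marker names.
#' @export
MSI_MARKERS <- c("BAT25", "BAT26", "D17S250", "D2S123", "D5S346")

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", name), call. = FALSE)
  as.numeric(x)
}

.check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

.check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  as.numeric(x)
}

.check_range01 <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) ||
      any(x <= 0) || any(x > 1) || x[1] > x[2])
    stop(sprintf("'%s' must be an increasing interval within (0, 1]", name),
         call. = FALSE)
  as.numeric(x)
}

#' Numeric thresholds for the concordance pipeline
#'
#' Collects every tunable numeric threshold in one configuration object.
#' Defaults encode the published analysis rules: panel calls are retained
#' only above 5% allele frequency; a private call is rescued as present in
#' both compartments when the other sample's pileup shows the mutant allele
#' in at least 3 reads and at least 2% of all reads; WGS trio calls need at
#' least 3 reads and 5% frequency in at least one tumor and at least five
#' times the normal-tissue frequency; MSI-high means >= 30% unstable
#' markers; loss-of-function means nonsense, frameshift, or splice site;
#' COSMIC-recurrent means observed in at least 5 catalogue samples.
#' Copy-number cutoffs and the loess span have no published values and are
#' package defaults (see the methods vignette).
#'
#' @param panel_min_af Panel retention allele-frequency threshold
#'   (strict `>`; default 0.05).
#' @param rescue_min_reads,rescue_min_af Comparative-rescue floor on mutant
#'   reads (`>=`, default 3) and allele fraction (`>=`, default 0.02) in the
#'   alternate sample.
#' @param wgs_min_reads,wgs_min_af Per-tumor WGS retention floors
#'   (`>=`; defaults 3 reads, 0.05).
#' @param wgs_normal_ratio Minimum ratio of the best tumor allele frequency
#'   to the matched-normal allele frequency (default 5).
#' @param msi_unstable_cutoff Unstable-marker fraction at or above which a
#'   case is MSI-high (default 0.30).
#' @param lof_effects Effect classes counted as loss-of-function.
#' @param cosmic_recurrent_min Minimum COSMIC sample count for the
#'   recurrence flag (default 5).
#' @param cnv_del_log2,cnv_gain_log2,cnv_amp_log2 Gene-level mean log2-ratio
#'   cutoffs for deletion (`<=`, default -0.7), gain (`>=`, default 0.4) and
#'   amplification (`>=`, default 1.0).
#' @param cnv_min_bins Minimum unmasked coverage bins required to call a
#'   gene (default 3).
#' @param loess_span Span of the GC loess fit (default 0.3).
#' @return An object of class `threshold_config` (a named list).
#' @examples
#' cfg <- threshold_config()
#' cfg$panel_min_af
#' @export
threshold_config <- function(panel_min_af = 0.05,
                             rescue_min_reads = 3L,
                             rescue_min_af = 0.02,
                             wgs_min_reads = 3L,
                             wgs_min_af = 0.05,
                             wgs_normal_ratio = 5,
                             msi_unstable_cutoff = 0.30,
                             lof_effects = c("nonsense", "frameshift", "splice_site"),
                             cosmic_recurrent_min = 5L,
                             cnv_del_log2 = -0.7,
                             cnv_gain_log2 = 0.4,
                             cnv_amp_log2 = 1.0,
                             cnv_min_bins = 3L,
                             loess_span = 0.3) {
  bad <- setdiff(lof_effects, MUTATION_EFFECTS)
  if (length(bad))
    stop("unknown effect in 'lof_effects': ", paste(bad, collapse = ", "),
         "; recognized effects are: ", paste(MUTATION_EFFECTS, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(loess_span) || length(loess_span) != 1L ||
      is.na(loess_span) || loess_span <= 0 || loess_span > 1)
    stop("'loess_span' must lie in (0, 1]", call. = FALSE)
  cfg <- list(
    panel_min_af = .check_prob(panel_min_af, "panel_min_af"),
    rescue_min_reads = .check_count(rescue_min_reads, "rescue_min_reads"),
    rescue_min_af = .check_prob(rescue_min_af, "rescue_min_af"),
    wgs_min_reads = .check_count(wgs_min_reads, "wgs_min_reads"),
    wgs_min_af = .check_prob(wgs_min_af, "wgs_min_af"),
    wgs_normal_ratio = .check_pos(wgs_normal_ratio, "wgs_normal_ratio"),
    msi_unstable_cutoff = .check_prob(msi_unstable_cutoff, "msi_unstable_cutoff"),
    lof_effects = as.character(lof_effects),
    cosmic_recurrent_min = .check_count(cosmic_recurrent_min, "cosmic_recurrent_min"),
    cnv_del_log2 = as.numeric(cnv_del_log2),
    cnv_gain_log2 = as.numeric(cnv_gain_log2),
    cnv_amp_log2 = as.numeric(cnv_amp_log2),
    cnv_min_bins = .check_count(cnv_min_bins, "cnv_min_bins", min = 1L),
    loess_span = as.numeric(loess_span)
  )
  structure(cfg, class = "threshold_config")
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("Concordance pipeline thresholds:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' Synthetic trio-cohort generator configuration
#'
#' Parameters of the synthetic patient-trio generator. Defaults emulate the
#' study cohort the package was designed around: 69 patient trios, a mean of
#' 6.3 non-synonymous mutations per tumor pair with a 79% truncal (shared)
#' fraction, deep panel coverage (692X) or a WGS regime (87X tumor / 50X
#' normal), tumor purity 0.6-0.9 after macrodissection, private subclones
#' at cancer-cell fractions 0.3-0.9, a treatment-linked reduction of the
#' private-mutation burden (multiplier 0.4), and clinical covariates drawn
#' to the study's marginal distributions (75% concurrent resection, 43.5%
#' chemonaive, ...).
#'
#' @param n_patients Number of patient trios (>= 1).
#' @param mean_mutations_per_patient Expected distinct non-synonymous
#'   mutations per tumor pair.
#' @param shared_fraction Marginal truncal (shared) proportion of mutations,
#'   in `[0, 1]`. Private-mutation rates are normalized over the treatment
#'   marginal so this value is the cohort-wide expectation even when
#'   `treatment_effect < 1`.
#' @param subclonal_fraction_range Interval in (0, 1] for the cancer-cell
#'   fraction of private subclones.
#' @param purity_range Interval in (0, 1] for tumor sample purity.
#' @param panel_depth_mean Mean sequencing depth of every sample in the
#'   panel regime (default 692).
#' @param wgs_tumor_depth_mean,wgs_normal_depth_mean Mean depths in the WGS
#'   regime (defaults 87 and 50).
#' @param regime `"panel"` or `"wgs"`; selects the depth model.
#' @param treatment_effect Multiplier (< 1 shrinks) applied to the expected
#'   private-mutation count of treated patients.
#' @param resolvable_fraction Probability that a private mutation is in
#'   truth subclonally present in the other compartment (detectable in a
#'   spatially separate region but not in the main sample).
#' @param n_extra_regions Additional spatially separate regions simulated
#'   per patient (split between compartments); 0 disables.
#' @param error_rate Per-read background mutant-allele rate in the normal
#'   sample (<= 0.001).
#' @param msi_high_fraction,msi_low_fraction Fractions of patients simulated
#'   as MSI-high / MSI-low (defaults 0: the emulated study enrolled only
#'   microsatellite-stable cases; raise these to exercise the MSI gate).
#' @param cnv_events `NULL`, or a data.frame with columns `gene`, `copies`
#'   (0 = homozygous deletion, 1 = single-copy loss, 2 = neutral, 3 = gain,
#'   larger = amplification) and `compartment` (`"primary"` or
#'   `"metastasis"`), applied by [simulate_coverage()].
#' @param gc_bias_curvature Curvature of the quadratic coverage-vs-GC bias
#'   shared by tumor and normal in [simulate_coverage()]; 0 disables.
#' @param clinical_probs Named list of clinical marginals: `prior_treatment`,
#'   `concurrent`, `treated_compartment` (3 probabilities: both, primary
#'   only, metastasis only), `location` (right/left/rectum), `stage`
#'   (I-IV), `size_mean_chemonaive`, `size_mean_treated`, `size_sd`.
#' @param seed Integer seed; identical seed and configuration give
#'   byte-identical output.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_patients = 5, seed = 42)
#' sim <- simulate_cohort(cfg)
#' head(sim$calls)
#' @export
sim_config <- function(n_patients = 69L,
                       mean_mutations_per_patient = 6.3,
                       shared_fraction = 0.79,
                       subclonal_fraction_range = c(0.3, 0.9),
                       purity_range = c(0.6, 0.9),
                       panel_depth_mean = 692,
                       wgs_tumor_depth_mean = 87,
                       wgs_normal_depth_mean = 50,
                       regime = c("panel", "wgs"),
                       treatment_effect = 0.4,
                       resolvable_fraction = 0.37,
                       n_extra_regions = 0L,
                       error_rate = 5e-4,
                       msi_high_fraction = 0,
                       msi_low_fraction = 0,
                       cnv_events = NULL,
                       gc_bias_curvature = 3,
                       clinical_probs = list(),
                       seed = 1L) {
  regime <- match.arg(regime)
  defaults <- list(
    prior_treatment = 0.565,
    concurrent = 0.75,
    treated_compartment = c(both = 27, primary_only = 1, metastasis_only = 11) / 39,
    location = c(right = 0.40, left = 0.44, rectum = 0.16),
    stage = c(I = 0.0, II = 0.06, III = 0.04, IV = 0.90),
    size_mean_chemonaive = 5.2,
    size_mean_treated = 4.2,
    size_sd = 1.5
  )
  unknown <- setdiff(names(clinical_probs), names(defaults))
  if (length(unknown))
    stop("unknown clinical_probs entries: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cp <- utils::modifyList(defaults, clinical_probs)
  if (!is.null(cnv_events)) {
    cnv_events <- as.data.frame(cnv_events)
    need <- c("gene", "copies", "compartment")
    if (!all(need %in% names(cnv_events)))
      stop("'cnv_events' needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    if (!all(cnv_events$compartment %in% c("primary", "metastasis")))
      stop("cnv_events$compartment must be 'primary' or 'metastasis'",
           call. = FALSE)
    if (any(cnv_events$copies < 0))
      stop("cnv_events$copies must be >= 0", call. = FALSE)
  }
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate > 1e-3)
    stop("'error_rate' must lie in [0, 0.001]", call. = FALSE)
  if (msi_high_fraction + msi_low_fraction > 1)
    stop("msi_high_fraction + msi_low_fraction must not exceed 1", call. = FALSE)
  cfg <- list(
    n_patients = .check_count(n_patients, "n_patients", min = 1L),
    mean_mutations_per_patient = .check_pos(mean_mutations_per_patient,
                                            "mean_mutations_per_patient"),
    shared_fraction = .check_prob(shared_fraction, "shared_fraction"),
    subclonal_fraction_range = .check_range01(subclonal_fraction_range,
                                              "subclonal_fraction_range"),
    purity_range = .check_range01(purity_range, "purity_range"),
    panel_depth_mean = .check_pos(panel_depth_mean, "panel_depth_mean"),
    wgs_tumor_depth_mean = .check_pos(wgs_tumor_depth_mean, "wgs_tumor_depth_mean"),
    wgs_normal_depth_mean = .check_pos(wgs_normal_depth_mean, "wgs_normal_depth_mean"),
    regime = regime,
    treatment_effect = .check_prob(treatment_effect, "treatment_effect"),
    resolvable_fraction = .check_prob(resolvable_fraction, "resolvable_fraction"),
    n_extra_regions = .check_count(n_extra_regions, "n_extra_regions"),
    error_rate = as.numeric(error_rate),
    msi_high_fraction = .check_prob(msi_high_fraction, "msi_high_fraction"),
    msi_low_fraction = .check_prob(msi_low_fraction, "msi_low_fraction"),
    cnv_events = cnv_events,
    gc_bias_curvature = as.numeric(gc_bias_curvature),
    clinical_probs = cp,
    seed = .check_count(seed, "seed")
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Synthetic trio-cohort configuration (%d patients, %s regime, seed %d)\n",
              x$n_patients, x$regime, x$seed))
  cat(sprintf("  mutations/patient %.2f, shared fraction %.2f, treatment effect %.2f\n",
              x$mean_mutations_per_patient, x$shared_fraction, x$treatment_effect))
  invisible(x)
}
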