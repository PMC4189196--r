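#' Gene panel used by the synthetic generator
#'
#' A small colorectal-cancer-flavoured gene set with approximate genomic
#' intervals and per-mutation sampling weights reflecting typical
#' non-hypermutated CRC mutation frequencies (APC and TP53 dominate, then
#' KRAS, PIK3CA, SMAD4, ...). Coordinates are synthetic stand-ins adequate
#' for interval bookkeeping; they are not an annotation resource.
#'
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`, `weight`.
#' @export
panel_genes <- function() {
  data.frame(
    gene  = c("APC", "TP53", "KRAS", "PIK3CA", "SMAD4", "FBXW7", "BRAF",
              "NRAS", "TCF7L2", "SOX9", "ARID1A", "PTEN", "ATM", "AMER1",
              "CTNNB1"),
    chrom = c("5", "17", "12", "3", "18", "4", "7", "1", "10", "17", "1",
              "10", "11", "X", "3"),
    start = c(112043195L, 7565097L, 25357723L, 178866311L, 48556583L,
              153242410L, 140419127L, 115247085L, 114710009L, 70117161L,
              27022522L, 89622870L, 108093211L, 63404506L, 41236328L),
    end   = c(112181936L, 7590856L, 25403870L, 178952497L, 48611412L,
              153456185L, 140624564L, 115259515L, 114927437L, 70122561L,
              27108601L, 89731687L, 108239829L, 63425456L, 41301587L),
    weight = c(0.80, 0.65, 0.45, 0.20, 0.14, 0.10, 0.06, 0.04, 0.05, 0.05,
               0.06, 0.04, 0.05, 0.06, 0.05),
    stringsAsFactors = FALSE
  )
}

.sim_effects <- function(n) {
  sample(c("missense", "nonsense", "frameshift", "splice_site", "inframe_indel"),
         n, replace = TRUE, prob = c(0.62, 0.12, 0.12, 0.06, 0.08))
}

.sim_alleles <- function(effect) {
  n <- length(effect)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- ref
  snv <- !(effect %in% c("frameshift", "inframe_indel"))
  for (i in which(snv)) alt[i] <- sample(setdiff(bases, ref[i]), 1L)
  # indels: multi-base ref deleted down to its anchor base (left-aligned form)
  for (i in which(effect == "frameshift")) {
    k <- sample(1:2, 1L)
    ref[i] <- paste0(ref[i], paste(sample(bases, k, replace = TRUE), collapse = ""))
    alt[i] <- substr(ref[i], 1L, 1L)
  }
  for (i in which(effect == "inframe_indel")) {
    ref[i] <- paste0(ref[i], paste(sample(bases, 3L, replace = TRUE), collapse = ""))
    alt[i] <- substr(ref[i], 1L, 1L)
  }
  list(ref = ref, alt = alt)
}

.sim_depths <- function(config) {
  switch(config$regime,
         panel = c(tumor = config$panel_depth_mean,
                   normal = config$panel_depth_mean),
         wgs = c(tumor = config$wgs_tumor_depth_mean,
                 normal = config$wgs_normal_depth_mean))
}

.draw_obs <- function(n, depth_mean, p_alt) {
  depth <- stats::rpois(n, depth_mean)
  alt <- stats::rbinom(n, depth, pmin(1, p_alt))
  list(depth = depth, alt = alt)
}

#' Simulate a cohort of patient trios with known clonal structure
#'
#' Generates matched normal / primary / metastasis somatic call tables with
#' integer read counts, per-patient MSI marker profiles, a clinical
#' covariate table, and the generator-side ground truth for every variant.
#' Per variant and sample, depth is Poisson with the regime's mean and the
#' mutant read count is binomial with success probability
#' `purity * cancer-cell fraction * 1/2` (heterozygous, diploid); normal
#' samples see mutant reads only at the background error rate. Truncal
#' mutations have cancer-cell fraction 1 in both compartments; private
#' mutations are confined to one compartment at a subclonal fraction, and a
#' configurable proportion of them are additionally present (subclonally)
#' in a spatially separate region of the other compartment, which is what
#' multi-region resolution can recover. Treated patients' expected private
#' burden is `treatment_effect` times the untreated expectation.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `cohort_sim`:
#' \describe{
#'   \item{calls}{long data.frame, one row per variant and sample (roles
#'     `normal`, `primary`, `metastasis`) with read counts and allele
#'     fraction `af`.}
#'   \item{regions}{same layout for additional-region samples (role
#'     `region`, with `region_id` and `compartment`), or `NULL`.}
#'   \item{msi}{per patient and marker stability flags.}
#'   \item{clinical}{per-patient clinical covariates.}
#'   \item{truth}{per-variant ground truth: compartment
#'     (`truncal` / `primary_private` / `metastasis_private`), cancer-cell
#'     fractions, and whether a private variant is resolvable in the other
#'     compartment.}
#'   \item{config}{the configuration used.}
#' }
#' @seealso [simulate_coverage()] for matched coverage tables.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("'config' must be a sim_config object", call. = FALSE)
  set.seed(config$seed)
  n <- config$n_patients
  patients <- sprintf("P%03d", seq_len(n))
  cp <- config$clinical_probs

  ## clinical covariates (Table-1-like marginals)
  treated <- stats::runif(n) < cp$prior_treatment
  resection <- ifelse(stats::runif(n) < cp$concurrent, "concurrent", "subsequent")
  treated_compartment <- rep(NA_character_, n)
  treated_compartment[treated] <- sample(names(cp$treated_compartment),
                                         sum(treated), replace = TRUE,
                                         prob = cp$treated_compartment)
  clinical <- data.frame(
    patient = patients,
    age = round(stats::rnorm(n, 59, 12)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    location = sample(names(cp$location), n, replace = TRUE, prob = cp$location),
    stage = sample(names(cp$stage), n, replace = TRUE, prob = cp$stage),
    resection = resection,
    treatment = ifelse(treated, "prior_treatment", "chemonaive"),
    treated_compartment = treated_compartment,
    primary_size_cm = round(pmax(0.5, stats::rnorm(
      n, ifelse(treated, cp$size_mean_treated, cp$size_mean_chemonaive),
      cp$size_sd)), 1),
    interval_months = ifelse(resection == "subsequent",
                             round(stats::rexp(n, 1 / 15.3), 1), 0),
    stringsAsFactors = FALSE
  )
  purity_primary <- stats::runif(n, config$purity_range[1], config$purity_range[2])
  purity_metastasis <- stats::runif(n, config$purity_range[1], config$purity_range[2])

  ## per-patient mutation counts; private rates normalized over the
  ## treatment marginal so shared_fraction is the cohort-wide expectation
  lam_shared <- config$mean_mutations_per_patient * config$shared_fraction
  denom <- (1 - cp$prior_treatment) + cp$prior_treatment * config$treatment_effect
  lam_priv_base <- config$mean_mutations_per_patient *
    (1 - config$shared_fraction) / denom
  n_shared <- stats::rpois(n, lam_shared)
  n_priv <- stats::rpois(n, lam_priv_base *
                           ifelse(treated, config$treatment_effect, 1))
  m <- sum(n_shared) + sum(n_priv)
  if (m == 0L)
    stop("simulated cohort contains no mutations; increase ",
         "'mean_mutations_per_patient' or 'n_patients'", call. = FALSE)

  pat_idx <- c(rep(seq_len(n), n_shared), rep(seq_len(n), n_priv))
  compartment <- c(rep("truncal", sum(n_shared)),
                   sample(c("primary_private", "metastasis_private"),
                          sum(n_priv), replace = TRUE))
  ord <- order(pat_idx)
  pat_idx <- pat_idx[ord]
  compartment <- compartment[ord]

  pg <- panel_genes()
  gidx <- sample.int(nrow(pg), m, replace = TRUE, prob = pg$weight)
  pos <- floor(stats::runif(m, pg$start[gidx], pg$end[gidx]))
  effect <- .sim_effects(m)
  al <- .sim_alleles(effect)
  hot <- stats::runif(m) < 0.2
  cosmic_count <- ifelse(hot, 5L + stats::rpois(m, 6), stats::rpois(m, 0.3))
  protein_change <- paste0("p.", sample(LETTERS, m, replace = TRUE),
                           sample.int(900L, m, replace = TRUE),
                           ifelse(effect == "nonsense", "*",
                                  sample(LETTERS, m, replace = TRUE)))

  ## cancer-cell fractions per compartment
  sfr <- config$subclonal_fraction_range
  sub_ccf <- stats::runif(m, sfr[1], sfr[2])
  ccf_primary <- ifelse(compartment == "truncal", 1,
                        ifelse(compartment == "primary_private", sub_ccf, 0))
  ccf_metastasis <- ifelse(compartment == "truncal", 1,
                           ifelse(compartment == "metastasis_private", sub_ccf, 0))
  is_private <- compartment != "truncal"
  resolvable <- is_private & stats::runif(m) < config$resolvable_fraction
  ## cancer-cell fraction the variant would have in a spatially separate
  ## region of the opposite compartment (0 if not resolvable)
  ccf_other_region <- ifelse(resolvable, stats::runif(m, sfr[1], sfr[2]), 0)

  truth <- data.frame(
    variant_id = sprintf("V%06d", seq_len(m)),
    patient = patients[pat_idx],
    chrom = pg$chrom[gidx], pos = pos, ref = al$ref, alt = al$alt,
    gene = pg$gene[gidx], compartment = compartment,
    ccf_primary = ccf_primary, ccf_metastasis = ccf_metastasis,
    resolvable = resolvable,
    stringsAsFactors = FALSE
  )

  dm <- .sim_depths(config)
  pur_p <- purity_primary[pat_idx]
  pur_m <- purity_metastasis[pat_idx]
  obs_p <- .draw_obs(m, dm[["tumor"]], pur_p * ccf_primary / 2)
  obs_m <- .draw_obs(m, dm[["tumor"]], pur_m * ccf_metastasis / 2)
  obs_n <- .draw_obs(m, dm[["normal"]], config$error_rate)

  variant_cols <- data.frame(
    patient = patients[pat_idx],
    chrom = pg$chrom[gidx], pos = pos, ref = al$ref, alt = al$alt,
    gene = pg$gene[gidx], effect = effect, protein_change = protein_change,
    cosmic_count = cosmic_count, stringsAsFactors = FALSE
  )
  mk_rows <- function(role, depth, alt) {
    out <- variant_cols
    out$sample <- paste(out$patient, role, sep = "_")
    out$role <- role
    out$depth <- depth
    out$alt_reads <- alt
    out$af <- ifelse(depth > 0, alt / depth, 0)
    out
  }
  calls <- rbind(mk_rows("normal", obs_n$depth, obs_n$alt),
                 mk_rows("primary", obs_p$depth, obs_p$alt),
                 mk_rows("metastasis", obs_m$depth, obs_m$alt))
  calls <- calls[order(calls$patient, calls$chrom, calls$pos, calls$alt,
                       calls$role), ]
  rownames(calls) <- NULL
  class(calls) <- c("mutation_calls", class(calls))

  ## additional spatially separate regions
  regions <- NULL
  if (config$n_extra_regions > 0L) {
    reg_comp <- rep(c("primary", "metastasis"),
                    length.out = config$n_extra_regions)
    grid <- expand.grid(vi = seq_len(m), ri = seq_len(config$n_extra_regions))
    same_comp <- (compartment[grid$vi] == "truncal") |
      (compartment[grid$vi] == "primary_private" & reg_comp[grid$ri] == "primary") |
      (compartment[grid$vi] == "metastasis_private" & reg_comp[grid$ri] == "metastasis")
    ## resolvable private variants surface in one region of the opposite side
    ocomp_v <- ifelse(compartment == "primary_private", "metastasis", "primary")
    chosen_other <- rep(FALSE, nrow(grid))
    for (v in which(resolvable)) {
      cand <- which(reg_comp == ocomp_v[v])
      if (length(cand)) {
        r <- cand[sample.int(length(cand), 1L)]
        chosen_other[grid$vi == v & grid$ri == r] <- TRUE
      }
    }
    present <- same_comp | chosen_other
    gi <- grid[present, , drop = FALSE]
    k <- nrow(gi)
    if (k > 0L) {
      reg_pur <- ifelse(reg_comp[gi$ri] == "primary",
                        purity_primary[pat_idx[gi$vi]],
                        purity_metastasis[pat_idx[gi$vi]])
      reg_ccf <- ifelse(chosen_other[present], ccf_other_region[gi$vi],
                        ifelse(compartment[gi$vi] == "truncal", 1, sub_ccf[gi$vi]))
      ro <- .draw_obs(k, dm[["tumor"]], reg_pur * reg_ccf / 2)
      regions <- variant_cols[gi$vi, ]
      regions$region_id <- sprintf("R%d", gi$ri)
      regions$compartment <- reg_comp[gi$ri]
      regions$sample <- paste(regions$patient, regions$region_id, sep = "_")
      regions$role <- "region"
      regions$depth <- ro$depth
      regions$alt_reads <- ro$alt
      regions$af <- ifelse(ro$depth > 0, ro$alt / ro$depth, 0)
      regions <- regions[order(regions$patient, regions$region_id,
                               regions$chrom, regions$pos, regions$alt), ]
      rownames(regions) <- NULL
    }
  }

  ## MSI marker profiles
  u <- stats::runif(n)
  msi_class <- ifelse(u < config$msi_high_fraction, "MSI-high",
                      ifelse(u < config$msi_high_fraction + config$msi_low_fraction,
                             "MSI-low", "MSS"))
  n_unstable <- ifelse(msi_class == "MSI-high", sample(2:5, n, replace = TRUE),
                       ifelse(msi_class == "MSI-low", 1L, 0L))
  msi <- data.frame(
    patient = rep(patients, each = length(MSI_MARKERS)),
    marker = rep(MSI_MARKERS, n),
    unstable = unlist(lapply(seq_len(n), function(i) {
      flags <- rep(FALSE, length(MSI_MARKERS))
      if (n_unstable[i] > 0)
        flags[sample.int(length(MSI_MARKERS), n_unstable[i])] <- TRUE
      flags
    })),
    stringsAsFactors = FALSE
  )

  structure(list(calls = calls, regions = regions, msi = msi,
                 clinical = clinical, truth = truth, config = config),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("Synthetic trio cohort: %d patients, %d simulated variants (%s regime)\n",
              x$config$n_patients, nrow(x$truth), x$config$regime))
  tab <- table(x$truth$compartment)
  cat("  compartments:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Generate a capture-target table for coverage simulation
#'
#' Tiles each panel gene with fixed-width bins and assigns each bin a GC
#' fraction drawn uniformly from `gc_range`. Bins are non-overlapping,
#' 0-based half-open (BED convention).
#'
#' @param n_per_gene Bins per gene.
#' @param bin_width Width of each bin in bp.
#' @param gc_range Interval for per-bin GC fractions.
#' @param seed Integer seed for the GC draw.
#' @return data.frame with columns `chrom`, `start`, `end`, `gene`, `gc`.
#' @export
panel_targets <- function(n_per_gene = 16L, bin_width = 150L,
                          gc_range = c(0.2, 0.8), seed = 1L) {
  pg <- panel_genes()
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(nrow(pg)), function(i) {
    starts <- pg$start[i] + (seq_len(n_per_gene) - 1L) * bin_width * 4L
    data.frame(chrom = pg$chrom[i], start = starts, end = starts + bin_width,
               gene = pg$gene[i], stringsAsFactors = FALSE)
  }))
  out$gc <- stats::runif(nrow(out), gc_range[1], gc_range[2])
  out
}

#' Simulate per-target tumor/normal coverage with GC bias and copy events
#'
#' Draws Poisson mean depths per capture target for a tumor/normal pair in
#' each compartment. Tumor and normal share a smooth unimodal GC-bias
#' multiplier, quadratic in GC and peaking at GC = 0.45:
#' `b(gc) = max(0.1, 1 - curvature * (gc - 0.45)^2)`.
#' Compartment-specific copy states from `config$cnv_events` (or the
#' `cnv_events` argument) scale the tumor mean by
#' `(purity * copies + (1 - purity) * 2) / 2`, i.e. impure tumors show
#' attenuated ratios.
#'
#' @param config A [sim_config()] object (depth means, regime, GC curvature,
#'   seed).
#' @param targets Target table as from [panel_targets()]; non-overlapping
#'   bins with `gc` in `[0, 1]` required.
#' @param cnv_events Copy events (see [sim_config()]); defaults to the ones
#'   in `config`.
#' @param purity Tumor purity used for the copy-state attenuation
#'   (default 1: pure tumor).
#' @return data.frame of class `coverage_bins` with one row per compartment
#'   and target: `compartment`, `chrom`, `start`, `end`, `gene`, `gc`,
#'   `tumor_depth`, `normal_depth`.
#' @export
simulate_coverage <- function(config, targets, cnv_events = config$cnv_events,
                              purity = 1) {
  if (!inherits(config, "sim_config"))
    stop("'config' must be a sim_config object", call. = FALSE)
  if (is.null(targets) || nrow(targets) == 0L)
    stop("'targets' is empty", call. = FALSE)
  if (any(targets$gc < 0 | targets$gc > 1))
    stop("target GC fractions must lie in [0, 1]", call. = FALSE)
  o <- order(targets$chrom, targets$start)
  tg <- targets[o, ]
  same <- tg$chrom[-1] == tg$chrom[-nrow(tg)]
  if (any(same & tg$start[-1] < tg$end[-nrow(tg)]))
    stop("'targets' must be non-overlapping", call. = FALSE)
  set.seed(config$seed + 1000L)
  dm <- .sim_depths(config)
  bias <- if (config$gc_bias_curvature > 0)
    pmax(0.1, 1 - config$gc_bias_curvature * (targets$gc - 0.45)^2)
  else rep(1, nrow(targets))
  out <- do.call(rbind, lapply(c("primary", "metastasis"), function(comp) {
    copies <- rep(2, nrow(targets))
    if (!is.null(cnv_events)) {
      ev <- cnv_events[cnv_events$compartment == comp, , drop = FALSE]
      for (i in seq_len(nrow(ev))) {
        copies[targets$gene == ev$gene[i]] <- ev$copies[i]
      }
    }
    eff <- (purity * copies + (1 - purity) * 2) / 2
    data.frame(
      compartment = comp, targets[, c("chrom", "start", "end", "gene", "gc")],
      tumor_depth = stats::rpois(nrow(targets), dm[["tumor"]] * bias * eff),
      normal_depth = stats::rpois(nrow(targets), dm[["normal"]] * bias),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  class(out) <- c("coverage_bins", class(out))
  out
}
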