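called <- function(..., patient = "P1") {
  df <- call_row(..., patient = patient)
  df[, c("patient", "chrom", "pos", "ref", "alt", "gene", "effect",
         "protein_change", "cosmic_count", "af")]
}

test_that("match_pair partitions the union into shared and private", {
  # identical single-variant sets
  p <- called(pos = 10L)
  rec <- match_pair(p, p)
  expect_equal(rec$status, "shared")
  # disjoint sets of 2 and 3
  p2 <- rbind(called(pos = 1L), called(pos = 2L))
  m2 <- rbind(called(pos = 11L), called(pos = 12L), called(pos = 13L))
  rec2 <- match_pair(p2, m2)
  expect_equal(sum(rec2$status == "private_primary"), 2L)
  expect_equal(sum(rec2$status == "private_metastasis"), 3L)
  expect_equal(nrow(rec2), 5L)
  # convergent evolution: two different TP53 changes stay distinct events
  r248 <- called(chrom = "17", pos = 7577538L, ref = "C", alt = "T",
                 gene = "TP53", protein_change = "p.R248Q")
  y163 <- called(chrom = "17", pos = 7578442L, ref = "T", alt = "A",
                 gene = "TP53", effect = "nonsense", protein_change = "p.Y163*")
  rec3 <- match_pair(r248, y163)
  expect_equal(nrow(rec3), 2L)
  expect_setequal(rec3$status, c("private_primary", "private_metastasis"))
  # patient mismatch errors
  expect_error(match_pair(called(patient = "P1"), called(patient = "P2")),
               "patient-id mismatch")
})

test_that("comparative rescue applies the 3-read / 2% pileup rule exactly", {
  rec <- match_pair(called(pos = 10L), called(pos = 99L))
  obs <- function(pos, role, depth, alt) {
    data.frame(patient = "P1", chrom = "5", pos = pos, ref = "A", alt = "T",
               role = role, depth = depth, alt_reads = alt)
  }
  # private_primary with metastasis pileup 3/100 (3%): rescued
  out <- rescue_private(rec, obs(10L, "metastasis", 100L, 3L))
  r10 <- out[out$pos == 10L, ]
  expect_equal(r10$status, "both_by_comparative")
  expect_equal(r10$rescued_from, "private_primary")
  expect_equal(r10$rescue_alt_reads, 3L)
  expect_equal(r10$rescue_depth, 100L)
  # 2/50 (4%): reads below 3, unchanged
  out2 <- rescue_private(rec, obs(10L, "metastasis", 50L, 2L))
  expect_equal(out2$status[out2$pos == 10L], "private_primary")
  # 3/200 (1.5%): AF below 2%, unchanged
  out3 <- rescue_private(rec, obs(10L, "metastasis", 200L, 3L))
  expect_equal(out3$status[out3$pos == 10L], "private_primary")
  # zero depth can never rescue and is logged
  out4 <- rescue_private(rec, obs(10L, "metastasis", 0L, 0L))
  expect_equal(out4$status[out4$pos == 10L], "private_primary")
  expect_equal(nrow(attr(out4, "no_rescue_log")), 1L)
  # rescue of the metastasis-private record uses the primary pileup
  out5 <- rescue_private(rec, obs(99L, "primary", 100L, 5L))
  expect_equal(out5$status[out5$pos == 99L], "both_by_comparative")
})

test_that("rescue moves mass between categories without changing the partition", {
  sim <- simulate_cohort(sim_config(n_patients = 30, seed = 101,
                                    subclonal_fraction_range = c(0.02, 0.3)))
  pre <- call_concordance(sim$calls, rescue = FALSE)
  post <- call_concordance(sim$calls, rescue = TRUE)
  expect_identical(nrow(pre), nrow(post))
  s_pre <- cohort_summary(pre)
  s_post <- cohort_summary(post)
  expect_identical(s_pre$n_distinct, s_post$n_distinct)
  for (s in list(s_pre, s_post))
    expect_identical(s$n_shared + s$n_private_primary + s$n_private_metastasis,
                     s$n_distinct)
  expect_gte(s_post$n_shared, s_pre$n_shared)
  # strict as-called view is unchanged by rescue
  expect_equal(s_post$shared_fraction_as_called, s_pre$shared_fraction)
})

test_that("tightening rescue thresholds never increases the shared count", {
  sim <- simulate_cohort(sim_config(n_patients = 40, seed = 111))
  calls <- as.data.frame(sim$calls)
  # depress some truncal variants to trace levels in the metastasis so the
  # panel filter drops them there and rescue eligibility varies by threshold
  set.seed(112)
  trunc_keys <- with(sim$truth[sim$truth$compartment == "truncal", ],
                     paste(patient, chrom, pos, alt))
  met <- calls$role == "metastasis" &
    paste(calls$patient, calls$chrom, calls$pos, calls$alt) %in%
      sample(trunc_keys, 60L)
  calls$depth[met] <- 200L
  calls$alt_reads[met] <- sample(0:9, sum(met), replace = TRUE)
  calls$af[met] <- calls$alt_reads[met] / calls$depth[met]
  shared_at <- function(reads, af) {
    cfg <- threshold_config(rescue_min_reads = reads, rescue_min_af = af)
    cohort_summary(call_concordance(calls, cfg))$n_shared
  }
  expect_gt(shared_at(1L, 0.001), shared_at(30L, 0.30))
  expect_gte(shared_at(1L, 0.001), shared_at(3L, 0.02))
  expect_gte(shared_at(3L, 0.02), shared_at(10L, 0.02))
  expect_gte(shared_at(3L, 0.02), shared_at(3L, 0.10))
  expect_gte(shared_at(3L, 0.10), shared_at(30L, 0.30))
})

test_that("swapping compartment labels swaps the private counts exactly", {
  sim <- simulate_cohort(sim_config(n_patients = 25, seed = 121))
  swapped <- sim$calls
  swapped$role[sim$calls$role == "primary"] <- "metastasis"
  swapped$role[sim$calls$role == "metastasis"] <- "primary"
  s1 <- cohort_summary(call_concordance(sim$calls))
  s2 <- cohort_summary(call_concordance(swapped))
  expect_identical(s1$n_shared, s2$n_shared)
  expect_identical(s1$n_private_primary, s2$n_private_metastasis)
  expect_identical(s1$n_private_metastasis, s2$n_private_primary)
})

test_that("multi-region data resolves private calls as subclonal, as an overlay", {
  rec <- match_pair(called(pos = 10L), called(pos = 99L))
  regions <- data.frame(patient = "P1", compartment = "primary",
                        region_id = "R1", chrom = "5", pos = 99L,
                        ref = "A", alt = "T", stringsAsFactors = FALSE)
  out <- resolve_with_regions(rec, regions)
  r99 <- out$records[out$records$pos == 99L, ]
  expect_equal(r99$resolution, "resolved_subclonal_in_primary")
  expect_equal(r99$status, "private_metastasis")  # status untouched
  expect_equal(out$tally$resolved, 1L)
  expect_equal(out$tally$examined, 2L)
  # no regions supplied: everything unresolved, tally zero
  out0 <- resolve_with_regions(rec, NULL)
  expect_true(all(out0$records$resolution == "unresolved"))
  expect_equal(out0$tally$resolved, 0L)
  # unknown compartment label errors
  bad <- regions; bad$compartment <- "liver"
  expect_error(resolve_with_regions(rec, bad), "unknown compartment")
})

test_that("resolution tally matches the generator truth", {
  cfg <- sim_config(n_patients = 40, n_extra_regions = 4,
                    resolvable_fraction = 0.5, seed = 131)
  sim <- simulate_cohort(cfg)
  rec <- call_concordance(sim$calls)
  region_called <- panel_filter(sim$regions)$retained
  out <- resolve_with_regions(rec, region_called)
  truth_priv <- sim$truth[sim$truth$compartment != "truncal", ]
  # every resolved record is truly resolvable per the generator
  res <- out$records[grepl("^resolved", out$records$resolution), ]
  key <- function(d) paste(d$patient, d$chrom, d$pos, d$alt)
  truth_resolvable <- truth_priv[truth_priv$resolvable, ]
  expect_true(all(key(res) %in% key(truth_resolvable)))
  # and nearly all resolvable privates are recovered (deep coverage)
  called_priv <- out$records[out$records$status %in%
                               c("private_primary", "private_metastasis"), ]
  recoverable <- sum(key(truth_resolvable) %in% key(called_priv))
  expect_gte(out$tally$resolved, floor(0.9 * recoverable))
})

test_that("cohort summary arithmetic and gene restriction", {
  recs <- do.call(rbind, c(
    lapply(1:8, function(i) match_pair(called(pos = i, patient = "P1"),
                                       called(pos = i, patient = "P1"))),
    list(match_pair(called(pos = 100L, gene = "KRAS", patient = "P1"),
                    called(pos = 200L, gene = "SMAD4", patient = "P1")))
  ))
  s <- cohort_summary(recs)
  expect_equal(s$n_distinct, 10L)
  expect_equal(s$shared_fraction, 0.80)
  # restriction changes the denominator
  s2 <- cohort_summary(recs, significant_genes = c("KRAS", "SMAD4"))
  expect_equal(s2$n_distinct, 2L)
  expect_equal(s2$shared_fraction, 0)
  # empty set: zero counts, fraction undefined and said so
  s0 <- cohort_summary(recs[0, ])
  expect_equal(s0$n_distinct, 0L)
  expect_true(is.na(s0$shared_fraction))
  expect_match(s0$fraction_note, "undefined")
})

test_that("gene frequency table computes patient fractions and reference deltas", {
  sim <- simulate_cohort(sim_config(n_patients = 69, seed = 141))
  rec <- call_concordance(sim$calls)
  tab <- gene_frequency_table(rec, n_patients = 69)
  apc <- tab[tab$gene == "APC", ]
  manual <- length(unique(rec$patient[rec$gene == "APC"])) / 69
  expect_equal(apc$fraction, manual)
  # reference deltas, including a gene absent from the cohort
  ref <- c(APC = 0.75, ZZZ9 = 0.10)
  tab2 <- gene_frequency_table(rec, 69, reference = ref)
  expect_equal(tab2$delta[tab2$gene == "APC"], manual - 0.75)
  expect_equal(tab2$fraction[tab2$gene == "ZZZ9"], 0)
  expect_equal(tab2$delta[tab2$gene == "ZZZ9"], -0.10)
  expect_error(gene_frequency_table(rec, 0), "positive")
})

test_that("estimated shared fraction is unbiased across configured fractions", {
  for (sf in c(0.25, 0.5, 0.79, 1.0)) {
    hits <- 0L
    reps <- 30L
    for (r in seq_len(reps)) {
      sim <- simulate_cohort(sim_config(n_patients = 69, shared_fraction = sf,
                                        seed = 1000L + 100L * round(100 * sf) + r))
      s <- cohort_summary(call_concordance(sim$calls))
      half <- 1.96 * sqrt(sf * (1 - sf) / s$n_distinct)
      hits <- hits + (abs(s$shared_fraction - sf) <= half + 1e-12)
    }
    # 95% CI coverage: allow a generous margin at 30 replicates
    expect_gte(hits / reps, 0.85)
  }
})
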