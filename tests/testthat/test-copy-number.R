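# synthetic bin table with a known quadratic GC bias and optional events
make_bins <- function(n = 1000L, depth_t = 600, depth_n = 300, bias = TRUE,
                      del_gene = NULL, del_bins = 30L, del_copies = 1,
                      seed = 1L) {
  set.seed(seed)
  gc <- stats::runif(n, 0.2, 0.8)
  gene <- paste0("G", rep(seq_len(ceiling(n / 10)), each = 10L)[seq_len(n)])
  b <- if (bias) 1 - 2.5 * (gc - 0.45)^2 else rep(1, n)
  copies <- rep(2, n)
  if (!is.null(del_gene)) {
    idx <- which(gene %in% del_gene)[seq_len(del_bins)]
    copies[idx] <- del_copies
  }
  data.frame(
    chrom = "1", start = seq_len(n) * 200L, end = seq_len(n) * 200L + 150L,
    gene = gene, gc = gc,
    tumor_depth = stats::rpois(n, depth_t * b * copies / 2),
    normal_depth = stats::rpois(n, depth_n * b),
    stringsAsFactors = FALSE
  )
}

test_that("normalization is an identity up to centering on bias-free data", {
  bins <- make_bins(bias = FALSE, seed = 2)
  out <- gc_normalize(bins)
  med <- stats::median(out$raw_ratio)
  expect_lt(max(abs(out$norm_ratio - out$raw_ratio / med), na.rm = TRUE), 0.08)
  expect_lt(max(abs(out$log2_ratio), na.rm = TRUE), 0.6)  # Poisson noise only
  expect_equal(stats::median(out$norm_ratio, na.rm = TRUE), 1)
})

test_that("quadratic GC bias is removed: per-decile medians near zero", {
  bins <- make_bins(seed = 3, del_gene = "G5", del_bins = 10L)
  out <- gc_normalize(bins)
  neutral <- out[!(out$gene %in% "G5") & !out$masked, ]
  dec <- cut(neutral$gc, stats::quantile(neutral$gc, 0:10 / 10),
             include.lowest = TRUE)
  med <- tapply(neutral$log2_ratio, dec, stats::median)
  expect_lt(max(abs(med)), 0.05)
  # normalization strictly reduces the GC dependence
  rho_before <- abs(stats::cor(neutral$gc, log2(neutral$raw_ratio),
                               method = "spearman"))
  rho_after <- abs(stats::cor(neutral$gc, neutral$log2_ratio,
                              method = "spearman"))
  expect_lt(rho_after, rho_before)
})

test_that("a planted single-copy loss is recovered near log2 = -1 at purity 1", {
  bins <- make_bins(seed = 4, del_gene = c("G5", "G6", "G7"), del_bins = 30L)
  out <- gc_normalize(bins)
  ev <- out[out$gene %in% c("G5", "G6", "G7") & !out$masked, ]
  expect_lt(abs(mean(ev$log2_ratio) - (-1)), 0.15)
})

test_that("scale invariance: rescaled tumor depths give the same ratios", {
  bins <- make_bins(seed = 5)
  out1 <- gc_normalize(bins)
  bins2 <- bins
  bins2$tumor_depth <- bins2$tumor_depth * 7L
  out2 <- gc_normalize(bins2)
  expect_equal(out2$norm_ratio, out1$norm_ratio, tolerance = 1e-10)
})

test_that("masking and degenerate inputs behave as specified", {
  bins <- make_bins(n = 200L, seed = 6)
  bins$normal_depth[5] <- 0L
  out <- gc_normalize(bins)
  expect_true(out$masked[5])
  expect_true(is.na(out$log2_ratio[5]))
  expect_error(gc_normalize(bins, span = 0), "span")
  expect_error(gc_normalize(bins, span = 1.5), "span")
  expect_error(gc_normalize(make_bins(n = 30L, seed = 7)), "too few")
  all_masked <- bins
  all_masked$normal_depth <- 0L
  expect_error(gc_normalize(all_masked), "masked")
})

test_that("gene-level calls follow the log2 cutoffs and min-bin rule", {
  bins <- make_bins(seed = 8, del_gene = "G3", del_bins = 10L, del_copies = 0)
  out <- gc_normalize(bins)
  expect_equal(call_gene_cnv(out, "G3")$state, "deletion")
  expect_equal(call_gene_cnv(out, "G8")$state, "neutral")
  # direct threshold checks on constructed means
  fake <- data.frame(gene = "X", log2_ratio = rep(-1.2, 12), masked = FALSE)
  expect_equal(call_gene_cnv(fake, "X")$state, "deletion")
  fake$log2_ratio <- rep(0.02, 12)
  expect_equal(call_gene_cnv(fake, "X")$state, "neutral")
  fake$log2_ratio <- rep(0.55, 12)
  expect_equal(call_gene_cnv(fake, "X")$state, "gain")
  fake$log2_ratio <- rep(1.3, 12)
  expect_equal(call_gene_cnv(fake, "X")$state, "amplification")
  # too few bins: no-call with a reason
  nc <- call_gene_cnv(fake[1:2, ], "X")
  expect_equal(nc$state, "no_call")
  expect_match(nc$reason, "unmasked bins")
})

test_that("no-CNV null: false deletion/amplification rate at most 1%", {
  bins <- make_bins(n = 2000L, seed = 9)
  out <- gc_normalize(bins)
  calls <- cnv_calls(out)
  called <- calls[calls$state != "no_call", ]
  bad <- mean(called$state %in% c("deletion", "amplification"))
  expect_lte(bad, 0.01)
})

test_that("compartment-specific gain is called in the metastasis only", {
  cfg <- sim_config(seed = 10, cnv_events = data.frame(
    gene = "BRAF", copies = 3, compartment = "metastasis"))
  bins <- simulate_coverage(cfg, panel_targets(seed = 10))
  out <- gc_normalize(bins)
  calls <- cnv_calls(out)
  expect_equal(calls$state[calls$compartment == "metastasis" &
                             calls$gene == "BRAF"], "gain")
  expect_equal(calls$state[calls$compartment == "primary" &
                             calls$gene == "BRAF"], "neutral")
})

test_that("private mutations in genes deleted on the other side are explained", {
  rec <- match_pair(
    data.frame(patient = "P1", chrom = "5", pos = 1L, ref = "C", alt = "T",
               gene = "APC", effect = "nonsense", protein_change = "p.R1*",
               cosmic_count = 0L, af = 0.4),
    data.frame(patient = "P1", chrom = "17", pos = 2L, ref = "G", alt = "A",
               gene = "TP53", effect = "missense", protein_change = "p.A2V",
               cosmic_count = 0L, af = 0.3))
  shared <- match_pair(
    data.frame(patient = "P1", chrom = "12", pos = 3L, ref = "G", alt = "T",
               gene = "KRAS", effect = "missense", protein_change = "p.G12C",
               cosmic_count = 99L, af = 0.3),
    data.frame(patient = "P1", chrom = "12", pos = 3L, ref = "G", alt = "T",
               gene = "KRAS", effect = "missense", protein_change = "p.G12C",
               cosmic_count = 99L, af = 0.3))
  recs <- rbind(rec, shared)
  cnv_met <- data.frame(gene = c("APC", "KRAS"), state = "deletion")
  out <- explain_private_by_deletion(recs, cnv_metastasis = cnv_met)
  expect_equal(out$resolution[out$gene == "APC"], "explained_by_deletion")
  # copy-neutral gene: unchanged
  expect_equal(out$resolution[out$gene == "TP53"], "unresolved")
  # shared record in a deleted gene: never touched
  expect_equal(out$resolution[out$gene == "KRAS"], "unresolved")
})
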