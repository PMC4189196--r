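test_that("allele fraction is recomputed from counts", {
  tmp <- tempfile(fileext = ".tsv")
  write_calls(call_row(depth = 100L, alt_reads = 8L), tmp)
  calls <- read_calls(tmp)
  expect_equal(calls$af, 0.08)
})

test_that("SNVs pass through normalization unchanged and degenerate input errors", {
  k <- normalize_variant("7", 140453136, "A", "T")
  expect_equal(k, list(chrom = "7", pos = 140453136L, ref = "A", alt = "T"))
  expect_error(normalize_variant("1", 10, "G", "G"), "ref equals alt")
  expect_error(normalize_variant("1", 10, "", "A"), "non-empty")
  expect_error(normalize_variant("1", 10, "N", "A"), "A, C, G, T")
})

test_that("equivalent indel spellings left-align to the same key", {
  # deletion of AG inside the repeat CAGAGA starting at position 100
  flank <- "TTTCAGAGATTT"; flank_start <- 97L
  k1 <- normalize_variant("5", 100, "CAG", "C",
                          flank = flank, flank_start = flank_start)
  k2 <- normalize_variant("5", 101, "AGA", "A",
                          flank = flank, flank_start = flank_start)
  expect_identical(k1, k2)
  # brute-force oracle: both spellings edit the sequence identically
  h1 <- apply_variant(flank, flank_start, 100, "CAG", "C")
  h2 <- apply_variant(flank, flank_start, 101, "AGA", "A")
  expect_identical(h1, h2)
  # and the normalized key reproduces that same haplotype
  h3 <- apply_variant(flank, flank_start, k1$pos, k1$ref, k1$alt)
  expect_identical(h1, h3)
  # enumerate all right-shifted spellings of a 1-base deletion in a homopolymer
  seq <- "GGAAAAAC"; start <- 50L  # AAAAA at 52..56
  keys <- lapply(52:55, function(p)
    normalize_variant("2", p, substr(seq, p - start + 1L, p - start + 2L),
                      substr(seq, p - start + 1L, p - start + 1L),
                      flank = seq, flank_start = start))
  expect_length(unique(keys), 1L)
  expect_equal(keys[[1]]$pos, 51L)
})

test_that("normalization is idempotent", {
  flank <- "TTTCAGAGATTT"; fs <- 97L
  cases <- list(c("5", 101, "AGA", "A"), c("5", 100, "CAGAG", "CAG"),
                c("5", 99, "TC", "TA"))
  for (cs in cases) {
    k1 <- normalize_variant(cs[1], as.integer(cs[2]), cs[3], cs[4],
                            flank = flank, flank_start = fs)
    k2 <- normalize_variant(k1$chrom, k1$pos, k1$ref, k1$alt,
                            flank = flank, flank_start = fs)
    expect_identical(k1, k2)
  }
  # without flank: shared prefix/suffix trimming only, still idempotent
  k1 <- normalize_variant("5", 99, "TCAG", "TC")
  k2 <- normalize_variant(k1$chrom, k1$pos, k1$ref, k1$alt)
  expect_identical(k1, k2)
})

test_that("call tables round-trip through write and read", {
  sim <- simulate_cohort(sim_config(n_patients = 8, seed = 61))
  tmp <- tempfile(fileext = ".tsv")
  write_calls(sim$calls, tmp)
  back <- read_calls(tmp)
  cols <- c("patient", "chrom", "pos", "ref", "alt", "gene", "effect",
            "protein_change", "cosmic_count", "depth", "alt_reads", "af", "role")
  a <- as.data.frame(sim$calls)[, cols]
  a <- a[order(a$patient, a$chrom, a$pos, a$alt, a$role), ]
  rownames(a) <- NULL
  expect_equal(as.data.frame(back)[, cols], a)
})

test_that("malformed tables error with line numbers and the effect vocabulary", {
  good <- call_row()
  tmp <- tempfile(fileext = ".tsv")
  bad <- rbind(good, call_row(pos = 200L, effect = "nonsynonymous"))
  utils::write.table(bad[, setdiff(names(bad), "af")], tmp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_calls(tmp), "line 3.*missense.*synonymous")
  bad2 <- good
  bad2$depth <- NA_integer_
  utils::write.table(bad2[, setdiff(names(bad2), "af")], tmp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_calls(tmp), "depth on line\\(s\\) 2")
  utils::write.table(good[, 1:4], tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_calls(tmp), "missing required columns")
})

test_that("VCF records with AD/DP map onto allele observations", {
  skip_if_not_installed("vcfR")
  tmp <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Effect\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "primary_T", "met_T", "normal_N", sep = "\t"),
    paste("7", "140453136", ".", "A", "T", ".", "PASS",
          "GENE=BRAF;EFFECT=missense", "DP:AD",
          "100:92,8", "80:76,4", "50:50,0", sep = "\t")
  ), tmp)
  calls <- read_calls(tmp, format = "vcf", patient = "P9")
  expect_identical(nrow(calls), 3L)
  p <- calls[calls$role == "primary", ]
  expect_equal(p$depth, 100)
  expect_equal(p$alt_reads, 8L)
  expect_equal(p$af, 0.08)
  expect_equal(p$gene, "BRAF")
  expect_setequal(calls$role, c("primary", "metastasis", "normal"))
})

test_that("record reports round-trip and the JSON report carries the summary", {
  sim <- simulate_cohort(sim_config(n_patients = 10, seed = 71))
  rec <- call_concordance(sim$calls)
  tsv <- tempfile(fileext = ".tsv")
  write_report(rec, tsv, "tsv")
  back <- read_records(tsv)
  expect_identical(nrow(back), nrow(rec))
  expect_equal(back$status, rec$status)
  expect_equal(back$pos, rec$pos)
  # empty record set -> header-only file
  empty <- rec[0, ]
  tsv2 <- tempfile(fileext = ".tsv")
  write_report(empty, tsv2, "tsv")
  expect_length(readLines(tsv2), 2L)  # schema line + column header
  # JSON summary block agrees with cohort_summary on the same records
  js <- tempfile(fileext = ".json")
  write_report(rec, js, "json")
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  s <- cohort_summary(rec)
  expect_equal(parsed$summary$n_shared, s$n_shared)
  expect_equal(parsed$summary$n_distinct, s$n_distinct)
  expect_equal(parsed$summary$shared_fraction, s$shared_fraction)
})
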