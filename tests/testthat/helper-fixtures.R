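# Small in-code fixtures shared across test files.

# one call-table row with sensible defaults
call_row <- function(patient = "P1", role = "primary", chrom = "5",
                     pos = 100L, ref = "A", alt = "T", gene = "APC",
                     effect = "missense", protein_change = "p.X1Y",
                     cosmic_count = 0L, depth = 100L, alt_reads = 30L) {
  data.frame(patient = patient, sample = paste(patient, role, sep = "_"),
             role = role, chrom = chrom, pos = pos, ref = ref, alt = alt,
             gene = gene, effect = effect, protein_change = protein_change,
             cosmic_count = cosmic_count, depth = depth,
             alt_reads = alt_reads, af = ifelse(depth > 0, alt_reads / depth, 0),
             stringsAsFactors = FALSE)
}

calls_table <- function(...) {
  out <- rbind(...)
  class(out) <- c("mutation_calls", class(out))
  out
}

# a full trio (normal/primary/metastasis) for one variant
trio_rows <- function(patient = "P1", chrom = "1", pos = 10L, ref = "A",
                      alt = "G", gene = "TP53", effect = "missense",
                      depth_p = 100L, alt_p = 10L,
                      depth_m = 90L, alt_m = 0L,
                      depth_n = 45L, alt_n = 0L, ...) {
  rbind(
    call_row(patient, "primary", chrom, pos, ref, alt, gene, effect,
             depth = depth_p, alt_reads = alt_p, ...),
    call_row(patient, "metastasis", chrom, pos, ref, alt, gene, effect,
             depth = depth_m, alt_reads = alt_m, ...),
    call_row(patient, "normal", chrom, pos, ref, alt, gene, effect,
             depth = depth_n, alt_reads = alt_n, ...)
  )
}

# brute-force oracle: apply a variant to a reference sequence
apply_variant <- function(seq, seq_start, pos, ref, alt) {
  i <- pos - seq_start + 1L
  stopifnot(substr(seq, i, i + nchar(ref) - 1L) == ref)
  paste0(substr(seq, 1L, i - 1L), alt,
         substr(seq, i + nchar(ref), nchar(seq)))
}

# independent closed-form Pearson chi-square oracle for a 2x2 table
pearson_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  x2 <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = x2, p_value = stats::pchisq(x2, 1, lower.tail = FALSE))
}

# independent MSI rule, straight from the published wording
msi_oracle <- function(flags, cutoff = 0.30) {
  frac <- mean(flags)
  if (frac == 0) "MSS" else if (frac < cutoff) "MSI-low" else "MSI-high"
}
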