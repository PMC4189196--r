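#' Normalize a variant to a parsimonious, left-aligned key
#'
#' Cross-sample matching of mutations is genomic: two calls are the same
#' event iff they normalize to the same (chrom, pos, ref, alt) key.
#' SNVs pass through unchanged. With a flanking reference sequence the
#' representation is fully left-aligned (shared trailing bases are trimmed
#' and the allele is shifted left through repeats, then shared leading
#' bases are trimmed, always keeping an anchor base). Without flanking
#' sequence only shared prefix/suffix trimming is possible, which leaves
#' indels inside repeats at their reported position; this limitation is
#' recorded in output metadata by [write_report()].
#'
#' @param chrom Chromosome name (kept verbatim; no "chr" coercion).
#' @param pos 1-based position of the first `ref` base.
#' @param ref,alt Allele strings over A/C/G/T, `ref != alt`.
#' @param flank Optional reference sequence around the variant.
#' @param flank_start 1-based genomic coordinate of `flank`'s first base.
#' @return A list with elements `chrom`, `pos`, `ref`, `alt`.
#' @examples
#' normalize_variant("7", 140453136, "A", "T")
#' normalize_variant("5", 101, "AGA", "A",
#'                   flank = "TTCAGAGATT", flank_start = 97)
#' @export
normalize_variant <- function(chrom, pos, ref, alt,
                              flank = NULL, flank_start = NULL) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (!nzchar(ref) || !nzchar(alt))
    stop("'ref' and 'alt' must be non-empty", call. = FALSE)
  if (identical(ref, alt))
    stop(sprintf("degenerate variant at %s:%d: ref equals alt ('%s')",
                 chrom, as.integer(pos), ref), call. = FALSE)
  if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt))
    stop("alleles must be strings over A, C, G, T", call. = FALSE)
  pos <- as.integer(pos)
  last <- function(x) substr(x, nchar(x), nchar(x))
  if (!is.null(flank)) {
    if (is.null(flank_start))
      stop("'flank_start' is required when 'flank' is given", call. = FALSE)
    flank <- toupper(flank)
    base_at <- function(p) {
      i <- p - flank_start + 1L
      if (i < 1L || i > nchar(flank)) NA_character_
      else substr(flank, i, i)
    }
    repeat {
      if (nchar(ref) > 0L && nchar(alt) > 0L && last(ref) == last(alt)) {
        ref <- substr(ref, 1L, nchar(ref) - 1L)
        alt <- substr(alt, 1L, nchar(alt) - 1L)
      } else if (nchar(ref) == 0L || nchar(alt) == 0L) {
        b <- base_at(pos - 1L)
        if (is.na(b))
          stop("flanking sequence too short to left-align variant at ",
               chrom, ":", pos, call. = FALSE)
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
        pos <- pos - 1L
      } else break
    }
  } else {
    while (nchar(ref) >= 2L && nchar(alt) >= 2L && last(ref) == last(alt)) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
    }
  }
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(chrom = as.character(chrom), pos = pos, ref = ref, alt = alt)
}

# read.delim would happily coerce an allele column holding only "T" to
# logical; force text columns to character by name
.read_tsv_typed <- function(path) {
  lines <- readLines(path, n = 100L)
  hdr_line <- lines[!startsWith(lines, "#")][1]
  hdr <- strsplit(hdr_line, "\t", fixed = TRUE)[[1]]
  char_cols <- c("patient", "sample", "chrom", "ref", "alt", "gene", "effect",
                 "protein_change", "role", "region_id", "compartment",
                 "marker", "status", "rescued_from", "resolution")
  cc <- ifelse(hdr %in% char_cols, "character", NA)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = cc)
}

.calls_required_cols <- c("patient", "sample", "chrom", "pos", "ref", "alt",
                          "gene", "effect", "protein_change", "cosmic_count",
                          "depth", "alt_reads")

.validate_calls <- function(df, line_offset = 1L) {
  missing_cols <- setdiff(.calls_required_cols, names(df))
  if (length(missing_cols))
    stop("call table is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  line_of <- function(i) i + line_offset
  bad_depth <- which(is.na(df$depth) | df$depth < 0)
  if (length(bad_depth))
    stop("missing or negative depth on line(s) ",
         paste(line_of(bad_depth), collapse = ", "),
         "; records with missing depth are rejected", call. = FALSE)
  bad_alt <- which(is.na(df$alt_reads) | df$alt_reads < 0 |
                     df$alt_reads > df$depth)
  if (length(bad_alt))
    stop("alt_reads missing or outside [0, depth] on line(s) ",
         paste(line_of(bad_alt), collapse = ", "), call. = FALSE)
  bad_eff <- which(!(df$effect %in% MUTATION_EFFECTS))
  if (length(bad_eff))
    stop("unknown effect '", df$effect[bad_eff[1]], "' on line ",
         line_of(bad_eff[1]), "; recognized effects are: ",
         paste(MUTATION_EFFECTS, collapse = ", "), call. = FALSE)
  bad_pos <- which(is.na(df$pos) | df$pos < 1)
  if (length(bad_pos))
    stop("malformed position on line(s) ",
         paste(line_of(bad_pos), collapse = ", "), call. = FALSE)
  invisible(df)
}

.normalize_call_keys <- function(df) {
  df$ref <- toupper(df$ref)
  df$alt <- toupper(df$alt)
  bad <- which(df$ref == df$alt)
  if (length(bad))
    stop("ref equals alt for record(s) at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  needs <- which(nchar(df$ref) > 1L | nchar(df$alt) > 1L)
  for (i in needs) {
    k <- normalize_variant(df$chrom[i], df$pos[i], df$ref[i], df$alt[i])
    df$pos[i] <- k$pos
    df$ref[i] <- k$ref
    df$alt[i] <- k$alt
  }
  df
}

#' Read a somatic mutation call table
#'
#' Reads either the package's tab-delimited MAF-like call table or a
#' VCF 4.2 file carrying per-sample `DP` (total depth) and `AD`
#' (ref,alt depths) FORMAT fields. Variant keys are normalized with
#' [normalize_variant()] and the allele fraction is always recomputed as
#' `alt_reads / depth` (the denominator is all reads at the locus), never
#' trusted from the input. Records with missing depth raise an error
#' naming the offending line rather than being dropped.
#'
#' @param path File to read.
#' @param format `"tsv"` or `"vcf"`.
#' @param patient For VCF input: the patient identifier to assign.
#' @param role_map For VCF input: named character vector mapping VCF sample
#'   names to roles (`normal`, `primary`, `metastasis`, `region`). By
#'   default roles are guessed from sample names.
#' @return A `mutation_calls` data.frame (long layout, one row per variant
#'   and sample).
#' @export
read_calls <- function(path, format = c("tsv", "vcf"), patient = NULL,
                       role_map = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    head_lines <- readLines(path, n = 50L)
    n_comment <- match(FALSE, startsWith(head_lines, "#"), nomatch = 1L) - 1L
    df <- .read_tsv_typed(path)
    ## file line = data row + comment lines + header line
    .validate_calls(df, line_offset = n_comment + 1L)
    df <- .normalize_call_keys(df)
    df$af <- ifelse(df$depth > 0, df$alt_reads / df$depth, 0)
    if (!"role" %in% names(df)) {
      df$role <- sub("^.*_", "", df$sample)
    }
    df <- df[order(df$patient, df$chrom, df$pos, df$alt, df$role), ]
    rownames(df) <- NULL
    class(df) <- c("mutation_calls", class(df))
    return(df)
  }
  .read_calls_vcf(path, patient = patient, role_map = role_map)
}

.read_calls_vcf <- function(path, patient = NULL, role_map = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no records", call. = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    stop("multi-allelic VCF records are not supported; split them first",
         call. = FALSE)
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, "AD")
  if (is.null(dp) || is.null(ad))
    stop("VCF must carry per-sample DP and AD FORMAT fields", call. = FALSE)
  info_field <- function(key) {
    r <- regexpr(paste0("(^|;)", key, "=[^;]*"), fix$INFO)
    out <- rep(NA_character_, nrow(fix))
    hit <- r > 0L
    out[hit] <- sub(paste0("^;?", key, "="), "", regmatches(fix$INFO, r))
    out
  }
  gene <- info_field("GENE")
  effect <- info_field("EFFECT")
  pchg <- info_field("PCHANGE")
  cosmic <- suppressWarnings(as.integer(info_field("COSMIC")))
  samples <- colnames(dp)
  if (is.null(role_map)) {
    role_map <- vapply(samples, function(s) {
      s2 <- tolower(s)
      if (grepl("normal", s2)) "normal"
      else if (grepl("met", s2)) "metastasis"
      else if (grepl("prim", s2)) "primary"
      else stop("cannot guess role of VCF sample '", s,
                "'; supply 'role_map'", call. = FALSE)
    }, character(1))
  }
  if (is.null(patient)) patient <- "VCF_PATIENT"
  out <- do.call(rbind, lapply(samples, function(s) {
    alt_reads <- suppressWarnings(as.integer(sub("^[^,]*,", "", ad[, s])))
    depth <- dp[, s]
    data.frame(
      patient = patient, sample = s, chrom = fix$CHROM,
      pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
      gene = gene,
      effect = ifelse(is.na(effect), "noncoding", effect),
      protein_change = pchg,
      cosmic_count = ifelse(is.na(cosmic), 0L, cosmic),
      depth = depth, alt_reads = alt_reads,
      role = unname(role_map[s]),
      stringsAsFactors = FALSE
    )
  }))
  .validate_calls(out, line_offset = 0L)
  out <- .normalize_call_keys(out)
  out$af <- ifelse(out$depth > 0, out$alt_reads / out$depth, 0)
  out <- out[order(out$patient, out$chrom, out$pos, out$alt, out$role), ]
  rownames(out) <- NULL
  class(out) <- c("mutation_calls", class(out))
  out
}

#' Write a mutation call table
#'
#' Writes the long call table as tab-delimited text with a versioned schema
#' header line, in deterministic (patient, chrom, pos, alt, role) order.
#' Round-trips losslessly through [read_calls()].
#'
#' @param calls A `mutation_calls` data.frame.
#' @param path Output path.
#' @export
write_calls <- function(calls, path) {
  cols <- c(.calls_required_cols, intersect(c("role", "region_id", "compartment"),
                                            names(calls)))
  calls <- as.data.frame(calls)[, cols]
  calls <- calls[do.call(order, calls[intersect(c("patient", "chrom", "pos",
                                                  "alt", "role"), cols)]), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#crcconcord_calls_v1", con)
  utils::write.table(calls, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write classified concordance records
#'
#' Emits the classified record set as tab-delimited text (versioned schema
#' header, deterministic (patient, chrom, pos, alt) order) or as a JSON
#' report that additionally carries the cohort summary block and the
#' normalization convention in its metadata.
#'
#' @param records A `concordance_records` data.frame
#'   (see [call_concordance()]).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  records <- as.data.frame(records)
  if (nrow(records))
    records <- records[order(records$patient, records$chrom, records$pos,
                             records$alt), ]
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#crcconcord_records_v1", con)
    utils::write.table(records, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    summ <- if (nrow(records)) unclass(cohort_summary(records)) else NULL
    payload <- list(
      schema = "crcconcord_records_v1",
      metadata = list(indel_normalization = "left-aligned, parsimonious"),
      summary = summ,
      records = records
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read back a concordance record table written by [write_report()]
#'
#' @param path TSV file written with `write_report(..., format = "tsv")`.
#' @return A `concordance_records` data.frame.
#' @export
read_records <- function(path) {
  df <- .read_tsv_typed(path)
  for (col in c("loss_of_function", "cosmic_recurrent"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  class(df) <- c("concordance_records", class(df))
  df
}

#' Read a per-target coverage table
#'
#' Expects tab-delimited columns `chrom`, `start`, `end` (0-based
#' half-open, BED convention), `gene`, `gc`, `tumor_depth`, `normal_depth`,
#' and optionally `compartment`.
#'
#' @param path File to read.
#' @return A `coverage_bins` data.frame.
#' @export
read_coverage <- function(path) {
  df <- .read_tsv_typed(path)
  need <- c("chrom", "start", "end", "gene", "gc", "tumor_depth", "normal_depth")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("coverage table is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (any(df$gc < 0 | df$gc > 1, na.rm = TRUE))
    stop("GC fractions must lie in [0, 1]", call. = FALSE)
  class(df) <- c("coverage_bins", class(df))
  df
}
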