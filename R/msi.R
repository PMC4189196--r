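#' Classify microsatellite status from marker stability calls
#'
#' Three-class rule over a panel of microsatellite markers (by default the
#' five-marker BAT25/BAT26/D17S250/D2S123/D5S346 panel): microsatellite
#' stable (`MSS`) iff no marker is unstable; `MSI-low` iff the unstable
#' fraction is positive but below the cutoff; `MSI-high` iff the unstable
#' fraction is at or above the cutoff (default 30%). With five markers the
#' boundary cannot be hit exactly, but the rule is implemented for
#' arbitrary marker counts.
#'
#' @param unstable Logical vector of per-marker instability flags (one
#'   patient), length >= 1.
#' @param cutoff MSI-high cutoff on the unstable fraction (default 0.30).
#' @return `"MSS"`, `"MSI-low"`, or `"MSI-high"`.
#' @examples
#' classify_msi(c(FALSE, FALSE, FALSE, FALSE, FALSE)) # MSS
#' classify_msi(c(TRUE, FALSE, FALSE, FALSE, FALSE))  # MSI-low (20%)
#' classify_msi(c(TRUE, TRUE, FALSE, FALSE, FALSE))   # MSI-high (40%)
#' @export
classify_msi <- function(unstable, cutoff = 0.30) {
  if (length(unstable) == 0L)
    stop("empty marker set: MSI status undefined", call. = FALSE)
  if (any(is.na(unstable)))
    stop("marker stability flags must not be NA", call. = FALSE)
  frac <- mean(as.logical(unstable))
  if (frac == 0) "MSS" else if (frac < cutoff) "MSI-low" else "MSI-high"
}

#' Classify MSI status for a whole cohort marker table
#'
#' @param markers data.frame with columns `patient`, `marker`, `unstable`;
#'   marker names must be unique within a patient.
#' @param cutoff MSI-high cutoff (default 0.30).
#' @return data.frame with `patient` and `msi_class`.
#' @export
classify_msi_cohort <- function(markers, cutoff = 0.30) {
  markers <- as.data.frame(markers)
  need <- c("patient", "marker", "unstable")
  missing_cols <- setdiff(need, names(markers))
  if (length(missing_cols))
    stop("marker table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  dup <- duplicated(markers[, c("patient", "marker")])
  if (any(dup))
    stop("duplicated marker(s) within a patient: ",
         paste(unique(markers$marker[dup]), collapse = ", "), call. = FALSE)
  res <- vapply(split(markers$unstable, markers$patient), classify_msi,
                character(1), cutoff = cutoff)
  data.frame(patient = names(res), msi_class = unname(res),
             stringsAsFactors = FALSE)
}

#' Restrict a cohort to microsatellite-stable patients
#'
#' Reproduces the study-inclusion rule "only microsatellite-stable tumors":
#' returns the patient identifiers whose class is `MSS`, with the excluded
#' patients and their classes attached as the `excluded` attribute.
#'
#' @param msi_classes Output of [classify_msi_cohort()].
#' @return Character vector of included (MSS) patient ids.
#' @export
msi_gate <- function(msi_classes) {
  keep <- msi_classes$msi_class == "MSS"
  out <- msi_classes$patient[keep]
  attr(out, "excluded") <- msi_classes[!keep, , drop = FALSE]
  out
}
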