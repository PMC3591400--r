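# Peptide-evidence and protein-report tables.
#
# Evidence rows are single quantified peptide observations: which fraction
# and gel band, the peptide sequence and charge, the protein accession(s) it
# matches, the identification probability, and the light/heavy channel
# intensities. A peptide seen only in the light channel (no heavy signal)
# carries the one-channel sentinel, encoded as +Inf on the log2 scale and
# rendered "+" in reports; the mirrored light-missing case is -Inf.

.EVIDENCE_COLS <- c("fraction", "band_index", "section", "peptide", "charge",
                    "accessions", "probability", "light_intensity",
                    "heavy_intensity")

#' Log2 light/heavy ratio with one-channel sentinels
#'
#' @param light,heavy Non-negative channel intensities (vectors recycle).
#'   `NA` heavy is treated as absent (zero).
#' @return `log2(light/heavy)` where both are positive; `+Inf` when heavy is
#'   absent (light-only, the "+" sentinel of report tables); `-Inf` when
#'   light is absent. Both channels zero is an error.
#' @examples
#' peptide_log_ratio(8, 2)   # 2
#' peptide_log_ratio(7, 0)   # Inf (one-channel)
#' @export
peptide_log_ratio <- function(light, heavy) {
  heavy[is.na(heavy)] <- 0
  light[is.na(light)] <- 0
  if (any(light < 0) || any(heavy < 0))
    stop("intensities must be non-negative", call. = FALSE)
  if (any(light == 0 & heavy == 0))
    stop("both channels zero: no quantification possible", call. = FALSE)
  ifelse(heavy == 0, Inf, ifelse(light == 0, -Inf, log2(light / heavy)))
}

# Internal: validate an evidence data.frame and derive log2_ratio.
# `lines` gives the originating file line per row for diagnostics.
validate_evidence <- function(df, lines = seq_len(nrow(df)) + 1L) {
  missing_cols <- setdiff(.EVIDENCE_COLS, names(df))
  if (length(missing_cols))
    stop("evidence table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  probs <- suppressWarnings(as.numeric(df$probability))
  light <- suppressWarnings(as.numeric(df$light_intensity))
  heavy <- suppressWarnings(as.numeric(df$heavy_intensity))
  heavy[is.na(heavy)] <- 0
  bad <- character(0)
  flag <- function(cond, msg) {
    if (any(cond, na.rm = TRUE) || anyNA(cond))
      bad <<- c(bad, paste0("line ", lines[which(cond | is.na(cond))],
                            ": ", msg))
  }
  flag(is.na(probs) | probs < 0 | probs > 1, "probability outside [0,1]")
  flag(is.na(light) | light < 0, "invalid light_intensity")
  flag(heavy < 0, "negative heavy_intensity")
  flag(!is.na(light) & light == 0 & heavy == 0, "both intensities zero")
  flag(is.na(suppressWarnings(as.integer(df$band_index))) |
         suppressWarnings(as.integer(df$band_index)) < 1,
       "band_index must be a positive integer")
  if (length(bad))
    stop("malformed evidence rows:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  data.frame(
    fraction = as.character(df$fraction),
    band_index = as.integer(df$band_index),
    section = as.character(df$section),
    peptide = as.character(df$peptide),
    charge = as.integer(df$charge),
    accessions = as.character(df$accessions),
    probability = probs,
    light_intensity = light,
    heavy_intensity = heavy,
    log2_ratio = peptide_log_ratio(light, heavy),
    stringsAsFactors = FALSE)
}

#' Read a peptide-evidence table
#'
#' Tab-separated with header columns `fraction`, `band_index`, `section`,
#' `peptide`, `charge`, `accessions` (semicolon-separated when a peptide is
#' shared), `probability`, `light_intensity`, `heavy_intensity` (empty when
#' no heavy-channel signal was detected). Malformed rows are reported with
#' their file line numbers.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of validated evidence with the derived `log2_ratio`
#'   column (`Inf` marks light-only one-channel observations).
#' @export
read_evidence <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          check.names = TRUE, quote = "")
  df$heavy_intensity[df$heavy_intensity == ""] <- NA
  validate_evidence(df)
}

#' Write a peptide-evidence table
#'
#' Inverse of [read_evidence()]: absent heavy intensities are written as
#' empty fields, numbers in full precision, so a read/write cycle is
#' lossless.
#'
#' @param evidence Evidence data.frame (as returned by [read_evidence()] or
#'   [simulate_evidence()]).
#' @param path Output TSV path.
#' @export
write_evidence <- function(evidence, path) {
  out <- evidence[, .EVIDENCE_COLS]
  out$probability <- format(out$probability, digits = 15, trim = TRUE,
                            scientific = FALSE)
  out$light_intensity <- format(out$light_intensity, digits = 15,
                                trim = TRUE, scientific = FALSE)
  out$heavy_intensity <- ifelse(
    evidence$heavy_intensity == 0, "",
    format(out$heavy_intensity, digits = 15, trim = TRUE,
           scientific = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# Render a finite/sentinel log2 value for reports: "+" for light-only,
# "-" for heavy-only, otherwise two decimals.
format_log2 <- function(x) {
  ifelse(is.infinite(x), ifelse(x > 0, "+", "-"), sprintf("%.2f", x))
}

#' Write a protein quantification report
#'
#' One row per protein with the layout of the published differential tables:
#' accession, name, log2 L/H (the string `"+"` for one-channel proteins),
#' p-value to three decimals, coverage to one decimal, evidence tier,
#' fractions seen, and -- when present -- the companion fraction's ratio and
#' p-value (`"ni."` when not identified there). Rows are written in the
#' order supplied; [significant_set()] produces the over-/lower-expressed
#' ordering.
#'
#' @param quants Data.frame with at least `accession`, `log2_lh`, `p_value`;
#'   optional `name`, `coverage`, `tier`, `fractions_seen`, `direction`,
#'   `other_log2`, `other_p`.
#' @param path Output TSV path.
#' @export
write_report <- function(quants, path) {
  n <- nrow(quants)
  grab <- function(col, default = rep(NA, n)) {
    if (col %in% names(quants)) quants[[col]] else default
  }
  out <- data.frame(
    accession = grab("accession", character(0)),
    name = grab("name", rep("", n)),
    log2_lh = if (n) format_log2(quants$log2_lh) else character(0),
    p_value = if (n) sprintf("%.3f", quants$p_value) else character(0),
    coverage = {
      cv <- grab("coverage")
      if (n) ifelse(is.na(cv), "", sprintf("%.1f", cv)) else character(0)
    },
    tier = grab("tier", rep("", n)),
    fractions_seen = grab("fractions_seen", rep("", n)),
    direction = grab("direction", rep("", n)),
    stringsAsFactors = FALSE)
  if (all(c("other_log2", "other_p") %in% names(quants))) {
    out$other_fraction <- ifelse(
      is.na(quants$other_p) & !is.infinite(quants$other_log2),
      "ni.",
      sprintf("%s(%s)", format_log2(quants$other_log2),
              sprintf("%.2f", quants$other_p)))
    # flag non-significant companion values the way italics do in print
    ns <- !is.na(quants$other_p) & quants$other_p >= 0.05 &
      !is.infinite(quants$other_log2)
    out$other_fraction[ns] <- paste0("*", out$other_fraction[ns], "*")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a protein report written by [write_report()]
#'
#' Sentinel `"+"`/`"-"` entries are parsed to `+Inf`/`-Inf`.
#'
#' @param path Report TSV path.
#' @return Data.frame with numeric `log2_lh`, `p_value`, `coverage`.
#' @export
read_report <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          quote = "")
  df$log2_lh <- vapply(df$log2_lh, function(v) {
    if (v == "+") Inf else if (v == "-") -Inf else as.numeric(v)
  }, numeric(1), USE.NAMES = FALSE)
  df$p_value <- as.numeric(df$p_value)
  if ("coverage" %in% names(df))
    df$coverage <- suppressWarnings(as.numeric(df$coverage))
  df
}
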