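# Protein-level quantification: per-band averaging of peptide log2 ratios,
# band-mean-of-means protein ratios with one-channel sentinel handling, and
# band-resolved proteoform quantification.

# Internal: unique-peptide evidence rows for one group.
group_evidence <- function(pg, accession) {
  stopifnot(inherits(pg, "protein_groups"))
  ev <- pg$evidence[pg$evidence$group_accession == accession &
                      pg$evidence$is_unique, , drop = FALSE]
  if (nrow(ev) == 0L)
    stop("no unique quantifiable peptides for '", accession, "'",
         call. = FALSE)
  ev
}

# MAD-based outlier rejection of finite peptide ratios within one band:
# values more than 3 (Gaussian-consistent) MADs from the band median go.
reject_band_outliers <- function(x) {
  m <- stats::median(x)
  s <- stats::mad(x)
  if (s == 0) return(x)
  x[abs(x - m) <= 3 * s]
}

#' Per-band mean log2 ratios for one protein group
#'
#' For every gel band where the group's unique peptides were observed,
#' averages the finite peptide log2 ratios (optionally after MAD-based
#' outlier rejection, the automated stand-in for manual ratio curation)
#' and carries the one-channel sentinel counts through.
#'
#' @param pg A `protein_groups` object.
#' @param accession Group accession.
#' @param reject_outliers Drop peptide ratios more than 3 MAD from the
#'   band median before averaging (off by default).
#' @return Data.frame with `band_index`, `mean_log2` (NA when a band holds
#'   only sentinels), `n_peptides` (finite contributors), `n_one_channel`.
#' @export
band_ratios <- function(pg, accession, reject_outliers = FALSE) {
  ev <- group_evidence(pg, accession)
  per_band <- split(ev$log2_ratio, ev$band_index)
  res <- data.frame(
    band_index = as.integer(names(per_band)),
    mean_log2 = NA_real_,
    n_peptides = 0L,
    n_one_channel = vapply(per_band, function(x)
      sum(is.infinite(x)), integer(1)),
    stringsAsFactors = FALSE)
  for (i in seq_along(per_band)) {
    x <- per_band[[i]][is.finite(per_band[[i]])]
    if (reject_outliers && length(x) >= 3L) x <- reject_band_outliers(x)
    if (length(x)) {
      res$mean_log2[i] <- mean(x)
      res$n_peptides[i] <- length(x)
    }
  }
  res <- res[order(res$band_index), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Protein log2 ratio from per-band ratios
#'
#' Unweighted mean of the per-band mean log2 ratios over bands with finite
#' means (averaging the band-level protein ratios, not the pooled peptide
#' ratios). When every contributing peptide is a one-channel sentinel the
#' protein ratio is the sentinel itself (`+Inf`, rendered "+"); a mixed
#' group reports the finite mean with the sentinel count flagged.
#'
#' @param band_df A [band_ratios()] data.frame.
#' @param mode `"band_mean"` (default) or `"pooled"`; pooled mode weights
#'   each finite peptide equally instead of each band.
#' @return Numeric log2 L/H ratio (possibly `+/-Inf`).
#' @export
protein_ratio <- function(band_df, mode = c("band_mean", "pooled")) {
  mode <- match.arg(mode)
  finite <- !is.na(band_df$mean_log2)
  if (!any(finite)) return(Inf)   # all-sentinel (light-only) protein
  if (mode == "band_mean") {
    mean(band_df$mean_log2[finite])
  } else {
    sum(band_df$mean_log2[finite] * band_df$n_peptides[finite]) /
      sum(band_df$n_peptides[finite])
  }
}

#' Quantify every protein group
#'
#' Applies [band_ratios()] and [protein_ratio()] to each group with at
#' least one unique quantifiable peptide.
#'
#' @param pg A `protein_groups` object.
#' @param reject_outliers Passed to [band_ratios()].
#' @param mode Passed to [protein_ratio()].
#' @return Data.frame with one row per quantified group: `fraction`,
#'   `accession`, `n_unique_peptides`, `tier`, `protein_probability`,
#'   `is_decoy`, `n_bands` (bands with finite means), `n_finite_peptides`,
#'   `n_one_channel`, `one_channel` (all-sentinel flag), `log2_lh`, and
#'   `se_factor` -- the multiplier such that the standard error of
#'   `log2_lh` is `noise_sd * se_factor` for a known peptide-level noise
#'   standard deviation (`sqrt(sum(1/n_band)) / n_bands` for the band-mean
#'   estimator).
#' @export
quantify_groups <- function(pg, reject_outliers = FALSE,
                            mode = c("band_mean", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pg, "protein_groups"))
  g <- pg$groups[pg$groups$n_unique_peptides >= 1L, , drop = FALSE]
  rows <- lapply(seq_len(nrow(g)), function(i) {
    bd <- band_ratios(pg, g$accession[i], reject_outliers = reject_outliers)
    finite <- !is.na(bd$mean_log2)
    nb <- sum(finite)
    se_factor <- if (nb == 0L) NA_real_
      else if (mode == "band_mean") sqrt(sum(1 / bd$n_peptides[finite])) / nb
      else 1 / sqrt(sum(bd$n_peptides[finite]))
    ratio <- protein_ratio(bd, mode = mode)
    data.frame(
      fraction = g$fraction[i],
      accession = g$accession[i],
      n_unique_peptides = g$n_unique_peptides[i],
      tier = g$tier[i],
      protein_probability = g$protein_probability[i],
      is_decoy = g$is_decoy[i],
      n_bands = nb,
      n_finite_peptides = sum(bd$n_peptides),
      n_one_channel = sum(bd$n_one_channel),
      one_channel = is.infinite(ratio),
      log2_lh = ratio,
      se_factor = se_factor,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$accession), , drop = FALSE]
}

#' Band-resolved proteoform quantification
#'
#' Splits a protein's occupied gel bands into contiguous runs (a gap of
#' more than one band starts a new run); runs whose molecular-weight
#' windows come within `mw_tolerance_kda` of each other are merged. Each
#' surviving cluster is a candidate molecular form (for example an intact
#' precursor in the upper gel region and the processed enzyme below it)
#' quantified on its own, and a whole-protein pooled ratio is reported
#' alongside -- pooling across forms can show a clear but diluted,
#' non-significant shift when only one form is regulated.
#'
#' @param pg A `protein_groups` object.
#' @param accession Group accession.
#' @param lane The calibrated [gel_lane()] the evidence came from.
#' @param mw_tolerance_kda Clusters closer than this in MW are merged.
#' @param reject_outliers Passed to [band_ratios()].
#' @return Data.frame with one row per form plus a final `"pooled"` row:
#'   `form`, `band_lo`, `band_hi`, `mw_kda` (peptide-weighted band-midpoint
#'   estimate), `log2_lh`, `n_peptides`, `n_one_channel`, `se` (standard
#'   error from the within-form peptide scatter; NA when fewer than two
#'   finite peptides).
#' @export
proteoform_quant <- function(pg, accession, lane, mw_tolerance_kda = 2,
                             reject_outliers = FALSE) {
  if (!inherits(lane, "gel_lane"))
    stop("lane must be a calibrated gel_lane", call. = FALSE)
  ev <- group_evidence(pg, accession)
  if (max(ev$band_index) > nrow(lane))
    stop("evidence refers to bands beyond the calibrated lane",
         call. = FALSE)
  bd <- band_ratios(pg, accession, reject_outliers = reject_outliers)
  # contiguous runs: a gap of more than one missing band splits
  idx <- bd$band_index
  run_id <- cumsum(c(1L, diff(idx) > 2L))
  # merge runs whose MW windows approach within tolerance
  runs <- split(seq_along(idx), run_id)
  merged <- list(runs[[1L]])
  if (length(runs) > 1L) {
    for (r in runs[-1L]) {
      prev <- merged[[length(merged)]]
      gap_top <- lane$mw_hi_kda[idx[r[1L]]]            # top of lower run
      gap_bottom <- lane$mw_lo_kda[idx[prev[length(prev)]]]
      if (gap_bottom - gap_top < mw_tolerance_kda)
        merged[[length(merged)]] <- c(prev, r)
      else merged <- c(merged, list(r))
    }
  }
  form_row <- function(rows, label) {
    sub <- bd[rows, , drop = FALSE]
    bands <- sub$band_index
    peps <- ev$log2_ratio[ev$band_index %in% bands]
    finite <- peps[is.finite(peps)]
    ratio <- protein_ratio(sub)
    data.frame(
      form = label,
      band_lo = min(bands), band_hi = max(bands),
      mw_kda = sum(band_mw_mid(lane, bands) *
                     (sub$n_peptides + sub$n_one_channel)) /
               sum(sub$n_peptides + sub$n_one_channel),
      log2_lh = ratio,
      n_peptides = length(peps),
      n_one_channel = sum(sub$n_one_channel),
      se = if (length(finite) >= 2L)
        stats::sd(finite) / sqrt(length(finite)) else NA_real_,
      stringsAsFactors = FALSE)
  }
  forms <- do.call(rbind, c(
    lapply(seq_along(merged), function(k)
      form_row(merged[[k]], sprintf("form_%d", k))),
    list(make.row.names = FALSE)))
  pooled <- form_row(seq_len(nrow(bd)), "pooled")
  pooled$mw_kda <- NA_real_
  rbind(forms, pooled)
}
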