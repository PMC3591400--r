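# Median normalization, Gaussian scale fitting, Z-statistic p-values and
# significance calling for protein log2 ratios.
#
# The model: unregulated proteins scatter normally around the log2 mixing
# point of the 1:1 pooled channels. Subtracting the per-fraction median
# centers that bulk at 0; a protein's normalized ratio divided by the
# fitted scale is a standard-normal Z under the null, giving a two-sided
# p-value. One-channel proteins (no heavy signal at all) sit beyond any
# measurable ratio and are significant by convention (p printed "0.000").

#' Median-normalize protein log2 ratios per fraction
#'
#' Subtracts each fraction's median finite log2 ratio, so the unregulated
#' bulk centers at 0 regardless of imperfect 1:1 channel pooling.
#' One-channel sentinels are left untouched and do not enter the median.
#'
#' @param quants Quantification data.frame (see [quantify_groups()]) with
#'   `fraction` and `log2_lh`; at least 3 finite ratios per fraction.
#' @return `quants` with a `norm_log2` column; attribute `"distribution"`
#'   holds a per-fraction data.frame (`fraction`, `n`, `median`).
#' @export
normalize_median <- function(quants) {
  dist <- do.call(rbind, lapply(split(quants, quants$fraction), function(d) {
    fin <- d$log2_lh[is.finite(d$log2_lh)]
    if (length(fin) < 3L)
      stop("fewer than 3 finite ratios in fraction '", d$fraction[1L],
           "': cannot normalize", call. = FALSE)
    data.frame(fraction = d$fraction[1L], n = length(fin),
               median = stats::median(fin), stringsAsFactors = FALSE)
  }))
  rownames(dist) <- NULL
  med <- stats::setNames(dist$median, dist$fraction)
  quants$norm_log2 <- ifelse(is.finite(quants$log2_lh),
                             quants$log2_lh - med[quants$fraction],
                             quants$log2_lh)
  attr(quants, "distribution") <- dist
  quants
}

#' Fit the null scale of normalized log2 ratios
#'
#' @param x Normalized log2 ratios (non-finite values are ignored).
#' @param estimator `"SD"` (sample standard deviation) or `"MAD"`
#'   (Gaussian-consistent 1.4826 x median absolute deviation, robust to a
#'   regulated minority).
#' @return The scale estimate (log2 units).
#' @export
fit_scale <- function(x, estimator = c("SD", "MAD")) {
  estimator <- match.arg(estimator)
  x <- x[is.finite(x)]
  if (length(x) < 3L) stop("need at least 3 finite ratios", call. = FALSE)
  s <- if (estimator == "SD") stats::sd(x) else stats::mad(x)
  if (s <= 0)
    stop("ratio distribution has zero spread: scale undefined",
         call. = FALSE)
  s
}

#' Two-sided Z-statistic p-values for normalized ratios
#'
#' `z = norm_log2 / sigma`; `p = 2 * (1 - Phi(|z|))`. One-channel
#' sentinels get `p = 0` (rendered "0.000") and keep their infinite z.
#'
#' @param quants Data.frame with `norm_log2` (see [normalize_median()]).
#' @param sigma Positive scale estimate (see [fit_scale()]).
#' @return `quants` with `z`, `p_value` and a BH-adjusted `p_adjust_bh`
#'   column (informational; the primary call thresholds the raw p).
#' @export
z_pvalues <- function(quants, sigma) {
  if (!is.numeric(sigma) || sigma <= 0)
    stop("sigma must be positive", call. = FALSE)
  quants$z <- quants$norm_log2 / sigma
  quants$p_value <- ifelse(is.finite(quants$z),
                           2 * stats::pnorm(-abs(quants$z)), 0)
  quants$p_adjust_bh <- stats::p.adjust(quants$p_value, method = "BH")
  quants
}

#' Select significantly regulated proteins
#'
#' Retains proteins with `p_value < alpha` in the required evidence tier
#' and orders them for reporting: over-expressed first (positive
#' normalized ratio or one-channel sentinel, most extreme first, sentinels
#' on top), then lower-expressed by descending magnitude.
#'
#' @param quants Data.frame with `p_value` and a ratio column (`norm_log2`
#'   if present, else `log2_lh`).
#' @param alpha Significance level on the raw p-value.
#' @param require_tier Keep only this tier (`NULL` to keep all tiers).
#' @return The retained rows with a `direction` column
#'   (`"over"`/`"lower"`).
#' @export
significant_set <- function(quants, alpha = 0.05,
                            require_tier = TIER_UNAMBIGUOUS) {
  if (!is.null(require_tier) && "tier" %in% names(quants))
    quants <- quants[quants$tier == require_tier, , drop = FALSE]
  quants <- quants[quants$p_value < alpha, , drop = FALSE]
  ratio <- if ("norm_log2" %in% names(quants)) quants$norm_log2
           else quants$log2_lh
  if (nrow(quants) == 0L) {
    quants$direction <- character(0)
    return(quants)
  }
  quants$direction <- ifelse(ratio > 0 | is.infinite(ratio), "over", "lower")
  key <- abs(ratio)
  ord <- order(quants$direction != "over",  # over-expressed first
               -is.infinite(ratio),         # sentinels on top
               -key)
  out <- quants[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binned counts of normalized ratios (histogram export)
#'
#' @param norm_log2 Normalized log2 ratios (non-finite dropped).
#' @param binwidth Bin width in log2 units.
#' @return Data.frame with `mid` (bin center) and `count`, suitable for a
#'   Gaussian-overlay distribution plot.
#' @export
ratio_histogram <- function(norm_log2, binwidth = 0.2) {
  x <- norm_log2[is.finite(norm_log2)]
  lo <- floor(min(x) / binwidth) * binwidth
  hi <- ceiling(max(x) / binwidth) * binwidth
  breaks <- seq(lo, hi + binwidth / 2, by = binwidth)
  counts <- table(cut(x, breaks, include.lowest = TRUE, right = FALSE))
  data.frame(mid = breaks[-length(breaks)] + binwidth / 2,
             count = as.integer(counts))
}
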