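# Gel lane model: ordered bands with molecular-weight calibration.
#
# A lane is sliced top-down into numbered bands (band 1 = top = highest MW),
# grouped into lettered sections. Calibration is log-linear in MW between the
# top and bottom anchors, the standard migration model for SDS-PAGE.

# Default section boundaries (last band index of each lettered section),
# mirroring a two-fraction design with 65 plugs in 11 sections (F1) and
# 72 plugs in 10 sections (F2).
.DEFAULT_SECTIONS <- list(
  F1 = c(A = 8, B = 14, C = 20, D = 24, E = 29, F = 35,
         G = 41, H = 45, I = 52, J = 60, K = 65),
  F2 = c(A = 6, B = 11, C = 18, D = 25, E = 32, F = 39,
         G = 47, H = 56, I = 65, J = 72)
)

#' Construct a calibrated gel lane
#'
#' @param fraction Lane label, e.g. `"F1"` or `"F2"`.
#' @param n_bands Number of gel bands (plugs); defaults to the fraction's
#'   standard layout (65 for F1, 72 for F2) when available, else 65.
#' @param mw_top,mw_bottom Molecular weights (kDa) at the top of band 1 and
#'   the bottom of the last band. Band windows are log-linear between them.
#' @param section_ends Named integer vector: last band index per lettered
#'   section (top to bottom). Defaults to the fraction's standard layout or
#'   an even split into 10 sections.
#' @return A data.frame of class `gel_lane` with one row per band and
#'   columns `fraction`, `index`, `section`, `mw_hi_kda`, `mw_lo_kda`.
#' @export
gel_lane <- function(fraction = "F1",
                     n_bands = NULL,
                     mw_top = 250, mw_bottom = 10,
                     section_ends = NULL) {
  if (is.null(section_ends) && is.null(n_bands) &&
      fraction %in% names(.DEFAULT_SECTIONS))
    section_ends <- .DEFAULT_SECTIONS[[fraction]]
  if (is.null(n_bands))
    n_bands <- if (!is.null(section_ends)) max(section_ends) else 65L
  n_bands <- as.integer(n_bands)
  if (n_bands < 1L) stop("n_bands must be >= 1", call. = FALSE)
  if (mw_top <= mw_bottom)
    stop("mw_top must exceed mw_bottom", call. = FALSE)
  if (is.null(section_ends)) {
    k <- min(10L, n_bands)
    section_ends <- stats::setNames(
      unique(round(seq_len(k) * n_bands / k)), LETTERS[seq_len(k)])
  }
  if (max(section_ends) != n_bands)
    stop("section_ends must end at n_bands", call. = FALSE)
  breaks <- exp(seq(log(mw_top), log(mw_bottom), length.out = n_bands + 1L))
  section <- character(n_bands)
  prev <- 0L
  for (s in seq_along(section_ends)) {
    section[(prev + 1L):section_ends[[s]]] <- names(section_ends)[[s]]
    prev <- section_ends[[s]]
  }
  structure(
    data.frame(fraction = fraction, index = seq_len(n_bands),
               section = section,
               mw_hi_kda = breaks[-(n_bands + 1L)],
               mw_lo_kda = breaks[-1L],
               stringsAsFactors = FALSE),
    class = c("gel_lane", "data.frame"))
}

#' Band index containing a molecular weight
#'
#' @param lane A [gel_lane()].
#' @param mw_kda Molecular weight(s) in kDa; values outside the calibrated
#'   range clamp to the first/last band.
#' @return Integer band indices.
#' @export
band_for_mw <- function(lane, mw_kda) {
  stopifnot(inherits(lane, "gel_lane"))
  n <- nrow(lane)
  # log-linear calibration: interpolate on log(MW)
  idx <- 1L + floor((log(lane$mw_hi_kda[1L]) - log(mw_kda)) /
                    (log(lane$mw_hi_kda[1L]) - log(lane$mw_lo_kda[n])) * n)
  as.integer(pmin(pmax(idx, 1L), n))
}

#' Midpoint molecular weight of bands (geometric mean of the window)
#'
#' @param lane A [gel_lane()].
#' @param index Band indices.
#' @return Numeric MW estimates in kDa.
#' @export
band_mw_mid <- function(lane, index) {
  stopifnot(inherits(lane, "gel_lane"))
  sqrt(lane$mw_hi_kda[index] * lane$mw_lo_kda[index])
}
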