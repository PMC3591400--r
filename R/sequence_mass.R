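# Sequence-level utilities: tryptic digestion, monoisotopic mass arithmetic
# with SILAC label shifts, decoy shuffling, and sequence coverage.

# Monoisotopic residue masses (Da) for the 20 canonical amino acids.
.RESIDUE_MASSES <- c(
  G = 57.02146374, A = 71.03711381, S = 87.03202841, P = 97.05276385,
  V = 99.06841392, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

.DECOY_PREFIX <- "DECOY_"

#' Mass constants used throughout the package
#'
#' Returns the monoisotopic constants used for peptide mass arithmetic:
#' the SILAC 13C6 label shift applied per labeled lysine or arginine
#' (+6.020129 Da), the propionamide adduct on cysteine (+71.037114 Da,
#' from acrylamide alkylation in-gel), the proton and water masses, and
#' the 20 canonical monoisotopic residue masses.
#'
#' @return A list with elements `label_shift_da`, `propionamide_da`,
#'   `proton_da`, `water_da` and `residue_masses` (named numeric vector).
#' @examples
#' mass_constants()$label_shift_da
#' @export
mass_constants <- function() {
  list(
    label_shift_da  = 6.020129,
    propionamide_da = 71.037114,
    proton_da       = 1.00727646688,
    water_da        = 18.010564684,
    residue_masses  = .RESIDUE_MASSES
  )
}

# Reject sequences containing anything outside the 20 canonical letters
# (B/Z/X/U and lowercase included), naming the first offender.
check_canonical <- function(sequence, what = "sequence") {
  if (length(sequence) != 1L || !is.character(sequence) || is.na(sequence) ||
      nchar(sequence) == 0L)
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), names(.RESIDUE_MASSES))
  if (length(bad))
    stop("non-canonical residue '", bad[[1L]], "' in ", what, call. = FALSE)
  invisible(chars)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Create a protein database entry
#'
#' @param accession Accession string (decoy entries carry the `DECOY_` prefix).
#' @param sequence Uppercase amino-acid sequence over the 20 canonical letters.
#' @param description Free-text description.
#' @param is_decoy Logical; decoy entries are flagged and prefix-checked.
#' @return A list of class `protein_entry` with fields `accession`,
#'   `description`, `sequence`, `is_decoy` and `mw_kda` (monoisotopic chain
#'   mass in kDa, computed from the sequence).
#' @export
protein_entry <- function(accession, sequence, description = "",
                          is_decoy = startsWith(accession, .DECOY_PREFIX)) {
  check_canonical(sequence)
  if (is_decoy && !startsWith(accession, .DECOY_PREFIX))
    accession <- paste0(.DECOY_PREFIX, accession)
  structure(
    list(accession = accession, description = description,
         sequence = sequence, is_decoy = is_decoy,
         mw_kda = peptide_mass(sequence) / 1000),
    class = "protein_entry")
}

#' @export
print.protein_entry <- function(x, ...) {
  cat(sprintf("<protein_entry> %s%s (%d aa, %.3f kDa)\n", x$accession,
              if (x$is_decoy) " [decoy]" else "", nchar(x$sequence), x$mw_kda))
  invisible(x)
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to lysine (K) or arginine (R) except when the next
#' residue is proline (Keil rule), and enumerates every peptide with up to
#' `max_missed` internal missed cleavage sites, in N-to-C order.
#'
#' @param sequence Protein sequence (canonical alphabet) or a
#'   `protein_entry`.
#' @param max_missed Maximum number of internal missed cleavage sites
#'   (non-negative integer; 2 in a typical gel-band workflow).
#' @param min_length,max_length Optional peptide length bounds applied to the
#'   output (defaults keep everything; simulation and search-space uses
#'   typically restrict to 6--40 residues).
#' @return A data.frame with columns `peptide`, `start`, `end`,
#'   `missed_cleavages` and `n_labeled_sites` (count of K plus R residues,
#'   i.e. SILAC-labelable positions).
#' @examples
#' tryptic_digest("AKRGK", max_missed = 0)$peptide  # "AK" "R" "GK"
#' @export
tryptic_digest <- function(sequence, max_missed = 2L,
                           min_length = 1L, max_length = Inf) {
  if (inherits(sequence, "protein_entry")) sequence <- sequence$sequence
  chars <- check_canonical(sequence)
  if (length(max_missed) != 1L || is.na(max_missed) || max_missed < 0)
    stop("max_missed must be a non-negative integer", call. = FALSE)
  max_missed <- as.integer(max_missed)
  n <- length(chars)
  # positions i such that the bond after residue i is cleaved
  kr <- which(chars %in% c("K", "R"))
  kr <- kr[kr < n & chars[kr + 1L] != "P"]
  bounds <- c(0L, kr, n)            # fragment boundaries
  nfrag <- length(bounds) - 1L
  out <- lapply(0:max_missed, function(m) {
    if (nfrag - m < 1L) return(NULL)
    i <- seq_len(nfrag - m)
    data.frame(start = bounds[i] + 1L, end = bounds[i + m + 1L],
               missed_cleavages = m, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  res$peptide <- substring(sequence, res$start, res$end)
  len <- res$end - res$start + 1L
  keep <- len >= min_length & len <= max_length
  res <- res[keep, , drop = FALSE]
  res$n_labeled_sites <- vapply(
    strsplit(res$peptide, "", fixed = TRUE),
    function(ch) sum(ch %in% c("K", "R")), integer(1))
  rownames(res) <- NULL
  res[, c("peptide", "start", "end", "missed_cleavages", "n_labeled_sites")]
}

#' Monoisotopic peptide mass
#'
#' Neutral monoisotopic mass: sum of residue masses plus one water, plus any
#' variable-modification deltas, plus -- for the heavy SILAC channel -- one
#' +6.020129 Da 13C6 label per lysine or arginine residue.
#'
#' @param sequence Peptide sequence (canonical alphabet).
#' @param heavy Logical; if `TRUE` every K and R carries the SILAC label.
#' @param mods Numeric vector of modification mass deltas in Da (for example
#'   `propionamide_mods(sequence)` for alkylated cysteines).
#' @return Neutral mass in Da.
#' @examples
#' peptide_mass("PEPTIDEK", heavy = TRUE) - peptide_mass("PEPTIDEK")  # 6.020129
#' @export
peptide_mass <- function(sequence, heavy = FALSE, mods = numeric(0)) {
  chars <- check_canonical(sequence, "peptide")
  cst <- mass_constants()
  m <- sum(.RESIDUE_MASSES[chars]) + cst$water_da + sum(mods)
  if (isTRUE(heavy))
    m <- m + sum(chars %in% c("K", "R")) * cst$label_shift_da
  m
}

#' Propionamide modification deltas for a peptide
#'
#' One +71.037114 Da delta per cysteine (acrylamide adduct formed during
#' in-gel handling), for use as `mods` in [peptide_mass()].
#'
#' @param sequence Peptide sequence.
#' @return Numeric vector, one element per modified cysteine.
#' @export
propionamide_mods <- function(sequence) {
  chars <- check_canonical(sequence, "peptide")
  rep(mass_constants()$propionamide_da, sum(chars == "C"))
}

#' Precursor m/z from neutral mass and charge
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param charge Positive integer charge state.
#' @return m/z = (mass + charge * proton) / charge.
#' @export
precursor_mz <- function(mass, charge) {
  if (any(charge < 1) || any(charge != as.integer(charge)))
    stop("charge must be a positive integer", call. = FALSE)
  (mass + charge * mass_constants()$proton_da) / charge
}

#' Shuffle a target protein into a decoy entry
#'
#' Produces a decoy with the same length and amino-acid composition by a
#' seeded uniform permutation of the sequence. With `keep_kr = TRUE` the
#' K/R positions (hence the tryptic cleavage pattern) are preserved and only
#' the remaining residues are permuted.
#'
#' @param protein A `protein_entry` (must not already be a decoy).
#' @param seed Integer seed; the same (protein, seed) pair always yields the
#'   same decoy.
#' @param keep_kr Preserve lysine/arginine positions.
#' @return A decoy `protein_entry` whose accession is prefixed `DECOY_`.
#' @export
shuffle_decoy <- function(protein, seed, keep_kr = FALSE) {
  stopifnot(inherits(protein, "protein_entry"))
  if (protein$is_decoy)
    stop("refusing to shuffle an entry that is already a decoy", call. = FALSE)
  chars <- strsplit(protein$sequence, "", fixed = TRUE)[[1L]]
  shuffled <- with_seed(seed, {
    if (keep_kr) {
      idx <- which(!chars %in% c("K", "R"))
      chars[idx] <- chars[sample(idx)]
      chars
    } else chars[sample(length(chars))]
  })
  protein_entry(
    accession = paste0(.DECOY_PREFIX, protein$accession),
    sequence = paste(shuffled, collapse = ""),
    description = paste("decoy of", protein$accession),
    is_decoy = TRUE)
}

#' Sequence coverage of a protein by identified peptides
#'
#' Fraction of residue positions covered by at least one peptide (every
#' occurrence of each peptide counts; overlaps count once), as a percentage
#' reported to one decimal -- the convention used in protein report tables.
#'
#' @param protein A `protein_entry` or plain sequence string.
#' @param peptides Character vector of peptide sequences; each must occur as
#'   a substring of the protein.
#' @return Coverage percentage in \[0, 100\], rounded to one decimal.
#' @export
coverage_percent <- function(protein, peptides) {
  sequence <- if (inherits(protein, "protein_entry")) protein$sequence
              else protein
  check_canonical(sequence)
  n <- nchar(sequence)
  covered <- logical(n)
  for (pep in unique(peptides)) {
    hits <- gregexpr(pep, sequence, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L)
      stop("peptide '", pep, "' not found in protein sequence", call. = FALSE)
    for (h in hits) covered[h:(h + nchar(pep) - 1L)] <- TRUE
  }
  round(100 * sum(covered) / n, 1)
}
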