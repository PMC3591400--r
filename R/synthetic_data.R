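# Ground-truthed synthetic GeLC-SILAC experiments.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: a proteome in which most proteins are unregulated (true log2
# light/heavy ratio 0) plus a regulated minority; a global log2 mixing
# offset standing in for imperfect 1:1 pooling of the two channels (removed
# later by median normalization); peptides landing in the gel band matching
# the protein's molecular weight, with spill-over into adjacent bands;
# multiplicative lognormal intensity noise, i.e. Normal noise on the log2
# ratio scale; heavy-channel dropout for extreme ratios (the one-channel
# "+" case); shuffled-decoy proteins contributing low-probability evidence;
# and two-population identification probabilities (high Beta component for
# targets, low for decoys with a small high-scoring contamination standing
# for chance matches to good spectra).

# Average residue mass used to size random protein sequences (Da).
.AVG_RESIDUE_DA <- 111

# Background amino-acid frequencies for random sequences (uniform over the
# canonical alphabet is adequate here: only the tryptic fragment length
# distribution matters downstream).
.AA_LETTERS <- names(.RESIDUE_MASSES)

random_protein_sequence <- function(length) {
  paste(sample(.AA_LETTERS, length, replace = TRUE), collapse = "")
}

#' Generate a ground-truth protein table for a synthetic experiment
#'
#' @param n_proteins Number of target proteins.
#' @param frac_regulated Fraction of targets carrying a true effect
#'   (each protein is regulated independently with this probability).
#' @param effect_size_range_log2 Length-2 range of regulated effect
#'   magnitudes on the log2 scale (sign random); a scalar `r` means uniform
#'   on `[-r, r]`. The default 0.8--4.5 spans the differential range
#'   typically reported for this design.
#' @param noise_sd Standard deviation of peptide-level log2-ratio noise.
#' @param mixing_offset Global log2 shift emulating imperfect 1:1 channel
#'   pooling; removed downstream by median normalization.
#' @param decoy_fraction Fraction of the concatenated database that is
#'   decoy (0.5 means one decoy per target, the standard construction).
#' @param peptides_per_protein_mean Poisson mean of quantified peptides per
#'   target protein (at least one is always observed).
#' @param one_channel_threshold Proteins with `|true log2| >=` this value
#'   lose the heavy channel entirely (extreme over-expression beyond
#'   measurable ratio).
#' @param seed Mandatory integer seed; the truth table is bit-reproducible.
#' @return A list of class `sim_truth`: `proteins` (data.frame with
#'   `accession`, `mw_kda`, `true_log2_ratio`, `regulated`, `one_channel`,
#'   `n_peptides_expected`, `is_decoy`) and the generator parameters.
#' @export
generate_truth <- function(n_proteins,
                           frac_regulated = 0.05,
                           effect_size_range_log2 = c(0.8, 4.5),
                           noise_sd = 0.3,
                           mixing_offset = 0,
                           decoy_fraction = 0,
                           peptides_per_protein_mean = 6,
                           one_channel_threshold = 5,
                           seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (frac_regulated < 0 || frac_regulated > 1)
    stop("frac_regulated must be in [0,1]", call. = FALSE)
  if (decoy_fraction < 0 || decoy_fraction >= 1)
    stop("decoy_fraction must be in [0,1)", call. = FALSE)
  if (length(effect_size_range_log2) == 1L)
    effect_size_range_log2 <- c(-effect_size_range_log2,
                                effect_size_range_log2)
  proteins <- with_seed(seed, {
    regulated <- stats::runif(n_proteins) < frac_regulated
    effect <- numeric(n_proteins)
    nreg <- sum(regulated)
    if (nreg) {
      if (all(effect_size_range_log2 >= 0)) {
        mag <- stats::runif(nreg, effect_size_range_log2[1L],
                            effect_size_range_log2[2L])
        effect[regulated] <- mag * sample(c(-1, 1), nreg, replace = TRUE)
      } else {
        effect[regulated] <- stats::runif(nreg, effect_size_range_log2[1L],
                                          effect_size_range_log2[2L])
      }
    }
    targets <- data.frame(
      accession = sprintf("SIM%05d", seq_len(n_proteins)),
      mw_kda = stats::runif(n_proteins, 10, 250),
      true_log2_ratio = effect,
      regulated = regulated,
      n_peptides_expected = pmax(1L, stats::rpois(
        n_proteins, peptides_per_protein_mean)),
      is_decoy = FALSE,
      stringsAsFactors = FALSE)
    n_decoys <- round(n_proteins * decoy_fraction / (1 - decoy_fraction))
    if (n_decoys > 0) {
      # decoy identifications are sparse: typically a single chance match
      decoys <- data.frame(
        accession = sprintf("DECOY_SIM%05d", seq_len(n_decoys)),
        mw_kda = stats::runif(n_decoys, 10, 250),
        true_log2_ratio = 0,
        regulated = FALSE,
        n_peptides_expected = 1L + stats::rpois(n_decoys, 0.4),
        is_decoy = TRUE,
        stringsAsFactors = FALSE)
      targets <- rbind(targets, decoys)
    }
    targets
  })
  proteins$one_channel <- !proteins$is_decoy &
    abs(proteins$true_log2_ratio) >= one_channel_threshold
  structure(
    list(proteins = proteins,
         noise_sd = noise_sd,
         mixing_offset = mixing_offset,
         decoy_fraction = decoy_fraction,
         one_channel_threshold = one_channel_threshold,
         seed = seed),
    class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  p <- x$proteins
  cat(sprintf(
    "<sim_truth> %d targets (%d regulated, %d one-channel), %d decoys; noise_sd %.2f, offset %.2f, seed %d\n",
    sum(!p$is_decoy), sum(p$regulated), sum(p$one_channel),
    sum(p$is_decoy), x$noise_sd, x$mixing_offset, x$seed))
  invisible(x)
}

# Identification-probability score model: targets score high, decoys low
# with a small high-scoring contamination (chance matches).
.default_prob_params <- function() {
  list(target = c(20, 2), decoy = c(2, 8), decoy_high_frac = 0.03)
}

#' Simulate peptide evidence from a truth table
#'
#' For every protein a random amino-acid sequence of matching molecular
#' weight is digested in silico (fully tryptic, 6--40 residues) and the
#' requested number of distinct peptides is drawn from the digest. Each
#' peptide observation lands in the gel band whose MW window contains the
#' protein (with probability `spill` it shifts to an adjacent band), and
#' its log2 ratio is `true ratio + mixing_offset + Normal(0, noise_sd)`.
#' Sampled ratios beyond the one-channel threshold lose the corresponding
#' channel. Target peptide probabilities come from the high Beta component,
#' decoy peptides from the low component (with a small high-scoring
#' contamination); decoy proteins produce decoy-only evidence in random
#' bands.
#'
#' @param truth A [generate_truth()] result.
#' @param lane A [gel_lane()] (calibrated; its fraction labels the rows).
#' @param spill Per-peptide probability of migrating into an adjacent band.
#' @param prob_params List with `target` and `decoy` Beta(a, b) parameters
#'   and `decoy_high_frac`.
#' @param peptide_length Length-2 bounds on usable tryptic peptides.
#' @param seed Integer seed.
#' @return Evidence data.frame in the layout of [read_evidence()].
#' @export
simulate_evidence <- function(truth, lane,
                              spill = 0.15,
                              prob_params = .default_prob_params(),
                              peptide_length = c(6, 40),
                              seed) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!inherits(lane, "gel_lane") || nrow(lane) == 0L)
    stop("lane must be a non-empty gel_lane", call. = FALSE)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  p <- truth$proteins
  n_bands <- nrow(lane)
  thr <- truth$one_channel_threshold
  with_seed(seed, {
    rows <- vector("list", nrow(p))
    for (i in seq_len(nrow(p))) {
      npep <- p$n_peptides_expected[i]
      len <- max(90L, round(p$mw_kda[i] * 1000 / .AVG_RESIDUE_DA))
      dig <- tryptic_digest(random_protein_sequence(len), max_missed = 0L,
                            min_length = peptide_length[1L],
                            max_length = peptide_length[2L])
      candidates <- unique(dig$peptide)
      if (!length(candidates)) candidates <- random_protein_sequence(10L)
      peps <- if (length(candidates) >= npep)
        sample(candidates, npep) else candidates
      k <- length(peps)
      if (p$is_decoy[i]) {
        band <- sample.int(n_bands, k, replace = TRUE)
      } else {
        band <- rep.int(band_for_mw(lane, p$mw_kda[i]), k)
        move <- stats::runif(k) < spill
        band[move] <- band[move] + sample(c(-1L, 1L), sum(move),
                                          replace = TRUE)
        band <- pmin(pmax(band, 1L), n_bands)
      }
      ratio <- p$true_log2_ratio[i] + truth$mixing_offset +
        stats::rnorm(k, 0, truth$noise_sd)
      heavy <- stats::rlnorm(k, meanlog = log(1e6), sdlog = 0.5)
      light <- heavy * 2^pmin(pmax(ratio, -thr), thr)
      oc_pos <- p$one_channel[i] && p$true_log2_ratio[i] > 0
      oc_neg <- p$one_channel[i] && p$true_log2_ratio[i] < 0
      drop_heavy <- oc_pos | ratio >= thr
      drop_light <- !drop_heavy & (oc_neg | ratio <= -thr)
      heavy[drop_heavy] <- 0
      light[drop_light] <- 0
      prob <- if (p$is_decoy[i]) {
        high <- stats::runif(k) < prob_params$decoy_high_frac
        ifelse(high,
               stats::rbeta(k, prob_params$target[1L],
                            prob_params$target[2L]),
               stats::rbeta(k, prob_params$decoy[1L],
                            prob_params$decoy[2L]))
      } else {
        stats::rbeta(k, prob_params$target[1L], prob_params$target[2L])
      }
      rows[[i]] <- list(band = band, peptide = peps,
                        charge = sample(2:3, k, replace = TRUE),
                        accession = rep.int(p$accession[i], k),
                        probability = prob, light = light, heavy = heavy)
    }
    band <- unlist(lapply(rows, `[[`, "band"))
    evidence <- data.frame(
      fraction = lane$fraction[1L],
      band_index = band,
      section = lane$section[band],
      peptide = unlist(lapply(rows, `[[`, "peptide")),
      charge = unlist(lapply(rows, `[[`, "charge")),
      accessions = unlist(lapply(rows, `[[`, "accession")),
      probability = unlist(lapply(rows, `[[`, "probability")),
      light_intensity = unlist(lapply(rows, `[[`, "light")),
      heavy_intensity = unlist(lapply(rows, `[[`, "heavy")),
      stringsAsFactors = FALSE)
    evidence$log2_ratio <- peptide_log_ratio(evidence$light_intensity,
                                             evidence$heavy_intensity)
    evidence
  })
}

#' Simulate a two-form proteoform scenario
#'
#' Emits evidence for a single accession occurring as two molecular forms
#' in disjoint gel regions -- an intact precursor in the upper lane and a
#' processed (matured) enzyme lower down -- with distinct true ratios, the
#' situation in which pooled averaging hides form-specific regulation. A
#' configurable fraction of peptide sequences is shared between forms; a
#' small precursor-specific set (propeptide-region peptides) occurs only in
#' the upper bands.
#'
#' @param lane A [gel_lane()].
#' @param accession Accession used for all emitted rows.
#' @param precursor_mw_kda,processed_mw_kda Molecular weights of the two
#'   forms; the precursor must be heavier and the two band clusters must
#'   not touch.
#' @param precursor_ratio,processed_ratio True log2 L/H ratios of the forms.
#' @param shared_peptide_fraction Fraction of each form's peptides drawn
#'   from the shared sequence pool.
#' @param n_peptides_precursor,n_peptides_processed Observations per form.
#' @param n_bands_precursor,n_bands_processed Contiguous bands over which
#'   each form's observations are spread.
#' @param noise_sd Peptide-level log2 noise.
#' @param seed Integer seed.
#' @return Evidence data.frame in the layout of [read_evidence()].
#' @export
simulate_proteoform <- function(lane,
                                accession = "PFORM01",
                                precursor_mw_kda = 37.3,
                                processed_mw_kda = 27.5,
                                precursor_ratio = 1.5,
                                processed_ratio = 0,
                                shared_peptide_fraction = 0.6,
                                n_peptides_precursor = 12,
                                n_peptides_processed = 18,
                                n_bands_precursor = 2,
                                n_bands_processed = 3,
                                noise_sd = 0.3,
                                seed) {
  stopifnot(inherits(lane, "gel_lane"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (precursor_mw_kda <= processed_mw_kda)
    stop("precursor must be heavier than the processed form", call. = FALSE)
  if (shared_peptide_fraction < 0 || shared_peptide_fraction > 1)
    stop("shared_peptide_fraction must be in [0,1]", call. = FALSE)
  n_bands <- nrow(lane)
  centered_bands <- function(mw, nb) {
    home <- band_for_mw(lane, mw)
    start <- min(max(home - (nb - 1L) %/% 2L, 1L), n_bands - nb + 1L)
    start:(start + nb - 1L)
  }
  bands_prec <- centered_bands(precursor_mw_kda, n_bands_precursor)
  bands_proc <- centered_bands(processed_mw_kda, n_bands_processed)
  if (max(bands_prec) >= min(bands_proc) - 1L)
    stop("form MW windows overlap: band clusters must be separated by ",
         "more than one band", call. = FALSE)
  with_seed(seed, {
    # peptide sequence pool from the precursor chain
    len <- max(200L, round(precursor_mw_kda * 1000 / .AVG_RESIDUE_DA))
    pool <- unique(tryptic_digest(random_protein_sequence(len),
                                  max_missed = 0L, min_length = 6,
                                  max_length = 40)$peptide)
    need <- n_peptides_precursor + n_peptides_processed + 3L
    while (length(pool) < need) {
      pool <- unique(c(pool, tryptic_digest(
        random_protein_sequence(len), max_missed = 0L,
        min_length = 6, max_length = 40)$peptide))
    }
    n_shared <- round(shared_peptide_fraction *
                        min(n_peptides_precursor, n_peptides_processed))
    shared <- pool[seq_len(n_shared)]
    rest <- setdiff(pool, shared)
    n_spec_prec <- n_peptides_precursor - n_shared
    spec_prec <- rest[seq_len(n_spec_prec)]
    rest <- setdiff(rest, spec_prec)
    spec_proc <- rest[seq_len(n_peptides_processed - n_shared)]
    form_rows <- function(peps, bands, true_ratio) {
      k <- length(peps)
      band <- rep_len(bands, k)
      ratio <- true_ratio + stats::rnorm(k, 0, noise_sd)
      heavy <- stats::rlnorm(k, meanlog = log(1e6), sdlog = 0.5)
      data.frame(
        fraction = lane$fraction[1L],
        band_index = band,
        section = lane$section[band],
        peptide = peps,
        charge = sample(2:3, k, replace = TRUE),
        accessions = accession,
        probability = stats::rbeta(k, 20, 2),
        light_intensity = heavy * 2^ratio,
        heavy_intensity = heavy,
        stringsAsFactors = FALSE)
    }
    evidence <- rbind(
      form_rows(c(shared, spec_prec), bands_prec, precursor_ratio),
      form_rows(c(shared, spec_proc), bands_proc, processed_ratio))
    evidence$log2_ratio <- peptide_log_ratio(evidence$light_intensity,
                                             evidence$heavy_intensity)
    evidence
  })
}
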