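# Independent oracles and small builders shared across tests.

# Brute-force digestion oracle: enumerate every contiguous substring whose
# ends are cleavage boundaries and whose internal boundary count does not
# exceed the missed-cleavage budget. Independent of the fragment-joining
# implementation in the package.
oracle_digest <- function(sequence, max_missed) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  is_site <- function(i)
    i >= 1L && i < n && ch[i] %in% c("K", "R") && ch[i + 1L] != "P"
  is_boundary <- function(i) i == 0L || i == n || is_site(i)
  out <- character(0)
  for (s in 1:n) for (e in s:n) {
    if (!is_boundary(s - 1L) || !is_boundary(e)) next
    internal <- if (e > s)
      sum(vapply(s:(e - 1L), is_site, logical(1))) else 0L
    if (internal <= max_missed) out <- c(out, substr(sequence, s, e))
  }
  sort(out)
}

random_aa <- function(n, letters = names(gelsilac::mass_constants()$residue_masses)) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Minimal evidence row builder for hand-made scenarios.
make_evidence <- function(peptide, accession, band = 1L, fraction = "F1",
                          probability = 0.99, light = 4, heavy = 2,
                          charge = 2L, section = "A") {
  data.frame(fraction = fraction, band_index = as.integer(band),
             section = section, peptide = peptide, charge = charge,
             accessions = accession, probability = probability,
             light_intensity = light, heavy_intensity = heavy,
             log2_ratio = gelsilac::peptide_log_ratio(light, heavy),
             stringsAsFactors = FALSE)
}

# Run the single-fraction analysis chain used by several tests.
analyze_evidence <- function(evidence, estimator = "SD") {
  pg <- group_proteins(suppressMessages(filter_peptides(evidence)))
  qt <- quantify_groups(pg)
  qt <- qt[!qt$is_decoy, , drop = FALSE]
  nq <- normalize_median(qt)
  sigma <- fit_scale(nq$norm_log2, estimator)
  list(pg = pg, quants = z_pvalues(nq, sigma), sigma = sigma)
}
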