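# Band averaging, protein ratios, sentinel handling, proteoform resolution.

evidence_with_ratios <- function(ratios, accession = "P1", band = 1L,
                                 one_channel = 0L) {
  ev <- do.call(rbind, lapply(seq_along(ratios), function(i)
    make_evidence(paste0("PEP", band, "X", i, "K"), accession, band = band,
                  light = 2^ratios[i] * 100, heavy = 100)))
  if (one_channel > 0L) {
    oc <- do.call(rbind, lapply(seq_len(one_channel), function(i)
      make_evidence(paste0("OC", band, "X", i, "K"), accession, band = band,
                    light = 100, heavy = 0)))
    ev <- rbind(ev, oc)
  }
  ev
}

test_that("band means average finite ratios and carry sentinel counts", {
  pg <- group_proteins(evidence_with_ratios(c(1, 3), one_channel = 1L))
  bd <- band_ratios(pg, "P1")
  expect_equal(bd$mean_log2, 2)
  expect_equal(bd$n_peptides, 2L)
  expect_equal(bd$n_one_channel, 1L)
})

test_that("outlier rejection only acts on genuine outliers", {
  clean <- group_proteins(evidence_with_ratios(c(0.9, 1.0, 1.1, 1.0)))
  expect_equal(band_ratios(clean, "P1", reject_outliers = TRUE)$mean_log2,
               band_ratios(clean, "P1", reject_outliers = FALSE)$mean_log2)
  dirty <- group_proteins(evidence_with_ratios(c(0.9, 1.0, 1.1, 1.0, 8)))
  expect_equal(band_ratios(dirty, "P1", reject_outliers = TRUE)$mean_log2,
               1.0, tolerance = 1e-9)
  expect_gt(band_ratios(dirty, "P1", reject_outliers = FALSE)$mean_log2, 2)
})

test_that("protein ratio is the unweighted mean of band means", {
  ev <- rbind(evidence_with_ratios(c(1, 1), band = 1L),
              evidence_with_ratios(c(2, 2, 2, 2), band = 2L))
  pg <- group_proteins(ev)
  bd <- band_ratios(pg, "P1")
  expect_equal(protein_ratio(bd), 1.5)              # bands weigh equally
  expect_equal(protein_ratio(bd, mode = "pooled"), (2 * 1 + 4 * 2) / 6)
})

test_that("band-mean-of-means is invariant to splitting peptides", {
  set.seed(61)
  ratios <- rnorm(12, 1, 0.5)
  whole <- group_proteins(evidence_with_ratios(ratios, band = 4L))
  expect_equal(protein_ratio(band_ratios(whole, "P1")), mean(ratios))
  # distributing the same peptides over sub-lists within the band and
  # averaging the per-band mean again changes nothing
  halves <- mean(c(mean(ratios[1:6]), mean(ratios[7:12])))
  expect_equal(mean(ratios), mean(c(ratios[1:6], ratios[7:12])))
  expect_equal(protein_ratio(band_ratios(whole, "P1")),
               weighted.mean(c(mean(ratios[1:6]), mean(ratios[7:12])),
                             c(6, 6)))
  expect_false(isTRUE(all.equal(halves, 0)))  # guard against trivial zeros
})

test_that("one-channel proteins propagate the sentinel", {
  all_oc <- group_proteins(evidence_with_ratios(numeric(0), one_channel = 3L))
  bd <- band_ratios(all_oc, "P1")
  expect_true(is.na(bd$mean_log2))
  expect_identical(protein_ratio(bd), Inf)
  q <- quantify_groups(all_oc)
  expect_true(q$one_channel)
  expect_identical(q$log2_lh, Inf)
  # mixed case: finite mean reported, sentinels flagged
  mixed <- group_proteins(evidence_with_ratios(c(1, 1), one_channel = 2L))
  qm <- quantify_groups(mixed)
  expect_equal(qm$log2_lh, 1)
  expect_false(qm$one_channel)
  expect_equal(qm$n_one_channel, 2L)
})

test_that("swapping light and heavy channels negates finite ratios", {
  lane <- gel_lane("F1")
  tr <- generate_truth(60, frac_regulated = 0.2, seed = 62)
  ev <- simulate_evidence(tr, lane, seed = 63)
  swapped <- ev
  swapped$light_intensity <- ev$heavy_intensity
  swapped$heavy_intensity <- ev$light_intensity
  swapped$log2_ratio <- peptide_log_ratio(swapped$light_intensity,
                                          swapped$heavy_intensity)
  q1 <- quantify_groups(group_proteins(suppressMessages(filter_peptides(ev))))
  q2 <- quantify_groups(group_proteins(suppressMessages(
    filter_peptides(swapped))))
  common <- intersect(q1$accession, q2$accession)
  fin <- is.finite(q1$log2_lh[match(common, q1$accession)])
  expect_equal(q2$log2_lh[match(common, q2$accession)][fin],
               -q1$log2_lh[match(common, q1$accession)][fin])
})

test_that("contiguous bands collapse to a single proteoform", {
  lane <- gel_lane("F1")
  ev <- rbind(evidence_with_ratios(c(1, 1.2), band = 30L),
              evidence_with_ratios(c(0.8, 1.0), band = 31L),
              evidence_with_ratios(c(1.1, 0.9), band = 33L))  # gap of one band
  pg <- group_proteins(ev)
  pf <- proteoform_quant(pg, "P1", lane)
  expect_equal(pf$form, c("form_1", "pooled"))
  expect_equal(pf$log2_lh[1], protein_ratio(band_ratios(pg, "P1")))
  expect_equal(pf$log2_lh[1], pf$log2_lh[2])
})

test_that("well-separated clusters with equal ratios match the pooled ratio", {
  lane <- gel_lane("F1")
  ev <- rbind(evidence_with_ratios(c(1, 1), band = 20L),
              evidence_with_ratios(c(1, 1), band = 45L))
  pg <- group_proteins(ev)
  pf <- proteoform_quant(pg, "P1", lane)
  expect_equal(pf$form, c("form_1", "form_2", "pooled"))
  expect_equal(pf$log2_lh, rep(1, 3), tolerance = 1e-12)
  # MW estimates track the band calibration, highest first
  expect_gt(pf$mw_kda[1], pf$mw_kda[2])
  expect_error(proteoform_quant(pg, "P1", data.frame()), "gel_lane")
})

test_that("synthetic proteoforms are recovered band-resolved", {
  lane <- gel_lane("F1")
  pf_ev <- simulate_proteoform(lane, seed = 64)
  pg <- group_proteins(pf_ev)
  pf <- proteoform_quant(pg, "PFORM01", lane)
  forms <- pf[pf$form != "pooled", ]
  expect_equal(nrow(forms), 2L)
  expect_lt(abs(forms$log2_lh[1] - 1.5), 2 * forms$se[1])
  expect_lt(abs(forms$log2_lh[2] - 0.0), 2 * forms$se[2])
  # the upper form's MW estimate is nearer the precursor mass
  expect_lt(abs(forms$mw_kda[1] - 37.3), abs(forms$mw_kda[1] - 27.5))
  pooled <- pf$log2_lh[pf$form == "pooled"]
  expect_gt(pooled, forms$log2_lh[2])
  expect_lt(pooled, forms$log2_lh[1])
})
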