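# Tryptic digestion, mass arithmetic, decoy shuffling, coverage.

test_that("tryptic digestion follows the Keil rule", {
  expect_equal(tryptic_digest("AKRGK", max_missed = 0)$peptide,
               c("AK", "R", "GK"))
  # K before P is not cleaved
  expect_equal(tryptic_digest("AKPGK", max_missed = 0)$peptide, "AKPGK")
  # C-terminal K/R ends the chain without an extra empty fragment
  expect_equal(tryptic_digest("GGK", max_missed = 0)$peptide, "GGK")
  expect_error(tryptic_digest("AKZ", 0), "non-canonical residue 'Z'")
  expect_error(tryptic_digest("AK", -1), "max_missed")
})

test_that("digestion with missed cleavages matches the brute-force oracle", {
  set.seed(401)
  cases <- c(list("AKRGK", "KKKK", "RPRPK"),
             lapply(sample(10:60, 12, replace = TRUE), random_aa))
  for (sq in cases) {
    for (mm in 0:2) {
      got <- sort(tryptic_digest(sq, max_missed = mm)$peptide)
      expect_equal(got, oracle_digest(sq, mm), info = paste(sq, mm))
    }
  }
})

test_that("digestion records missed-cleavage counts and label sites", {
  d <- tryptic_digest("AKRGK", max_missed = 2)
  full <- d[d$peptide == "AKRGK", ]
  expect_equal(full$missed_cleavages, 2L)
  expect_equal(full$n_labeled_sites, 3L)
  # length bounds filter the output
  d2 <- tryptic_digest("AKRGK", max_missed = 0, min_length = 2)
  expect_equal(d2$peptide, c("AK", "GK"))
})

test_that("SILAC and modification mass arithmetic is exact", {
  cst <- mass_constants()
  expect_equal(peptide_mass("PEPTIDEK", heavy = TRUE) -
                 peptide_mass("PEPTIDEK"), 6.020129, tolerance = 1e-9)
  # one label per K or R
  expect_equal(peptide_mass("GKRK", heavy = TRUE) - peptide_mass("GKRK"),
               3 * 6.020129, tolerance = 1e-9)
  # propionamide adds +71.037114 per modified cysteine
  expect_equal(peptide_mass("CC", mods = propionamide_mods("CC")) -
                 peptide_mass("CC"), 142.074228, tolerance = 1e-9)
  # glycine residue plus water, cross-checked elemental value
  expect_equal(peptide_mass("G"), 75.03203, tolerance = 1e-5)
  # the label shift is six 13C-12C neutron-binding differences
  expect_equal(cst$label_shift_da, 6 * 1.0033548378, tolerance = 1e-5)
})

test_that("peptide mass is additive up to one water", {
  set.seed(402)
  for (i in 1:10) {
    p <- random_aa(sample(3:15, 1))
    q <- random_aa(sample(3:15, 1))
    expect_equal(peptide_mass(paste0(p, q)),
                 peptide_mass(p) + peptide_mass(q) -
                   mass_constants()$water_da,
                 tolerance = 1e-9)
  }
})

test_that("precursor m/z follows the charge relation and inverts", {
  cst <- mass_constants()
  expect_equal(precursor_mz(0, 1), cst$proton_da)
  M <- 1827.820556
  expect_equal(precursor_mz(M, 1), 2 * precursor_mz(M, 2) - cst$proton_da,
               tolerance = 1e-9)
  set.seed(403)
  for (z in 1:4) {
    M <- runif(1, 500, 5000)
    mz <- precursor_mz(M, z)
    expect_equal(mz * z - z * cst$proton_da, M, tolerance = 1e-9)
  }
  expect_error(precursor_mz(1000, 0), "charge")
})

test_that("decoy shuffling preserves composition and is seeded", {
  set.seed(404)
  for (i in 1:5) {
    p <- protein_entry(paste0("P", i), random_aa(sample(20:200, 1)))
    d1 <- shuffle_decoy(p, seed = 99)
    d2 <- shuffle_decoy(p, seed = 99)
    d3 <- shuffle_decoy(p, seed = 100)
    expect_identical(d1$sequence, d2$sequence)
    expect_equal(nchar(d1$sequence), nchar(p$sequence))
    expect_equal(sort(strsplit(d1$sequence, "")[[1]]),
                 sort(strsplit(p$sequence, "")[[1]]))
    expect_true(startsWith(d1$accession, "DECOY_"))
    expect_false(identical(d1$sequence, d3$sequence) &&
                   nchar(p$sequence) > 30)  # different seed, different shuffle
  }
  p <- protein_entry("P1", "ACDEFGHIKLMNPQRSTVWY")
  expect_error(shuffle_decoy(shuffle_decoy(p, 1), 2), "already a decoy")
  # K/R-preserving mode keeps the tryptic skeleton
  dk <- shuffle_decoy(p, seed = 5, keep_kr = TRUE)
  kr_pos <- function(s) which(strsplit(s, "")[[1]] %in% c("K", "R"))
  expect_identical(kr_pos(dk$sequence), kr_pos(p$sequence))
})

test_that("coverage counts overlapping positions once and is monotone", {
  prot <- paste(rep("A", 65), collapse = "")
  prot <- paste0(substr(prot, 1, 35), paste(rep("G", 65), collapse = ""))
  prot <- substr(prot, 1, 100)
  expect_equal(coverage_percent(prot, substr(prot, 1, 35)), 35.0)
  # fully overlapping peptides add nothing
  expect_equal(coverage_percent(prot, c(substr(prot, 1, 35),
                                        substr(prot, 5, 20))), 35.0)
  expect_error(coverage_percent(prot, "WWWW"), "'WWWW' not found")
  # adding peptides never lowers coverage
  set.seed(405)
  prot2 <- random_aa(120)
  peps <- lapply(1:8, function(i) {
    s <- sample(1:100, 1); substr(prot2, s, s + sample(5:15, 1))
  })
  cov <- vapply(seq_along(peps), function(k)
    coverage_percent(prot2, unlist(peps[1:k])), numeric(1))
  expect_true(all(diff(cov) >= 0))
  expect_true(all(cov >= 0 & cov <= 100))
})

test_that("protein entries validate sequences and compute chain mass", {
  p <- protein_entry("P1", "ACDEFGHIKLMNPQRSTVWY", "all twenty")
  expect_equal(p$mw_kda, peptide_mass(p$sequence) / 1000, tolerance = 1e-9)
  expect_error(protein_entry("P2", "ACDB"), "non-canonical")
  expect_error(protein_entry("P3", ""), "non-empty")
})

test_that("FASTA round-trips with decoy augmentation", {
  set.seed(406)
  prots <- lapply(1:3, function(i)
    protein_entry(paste0("SP", i), random_aa(40), paste("protein", i)))
  db <- build_decoy_database(prots, seed = 7)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(db, path)
  back <- read_fasta(path)
  expect_length(back, 6L)
  expect_identical(vapply(back, `[[`, character(1), "sequence"),
                   vapply(db, `[[`, character(1), "sequence"))
  expect_identical(vapply(back, `[[`, logical(1), "is_decoy"),
                   rep(c(FALSE, TRUE), each = 3))
})
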