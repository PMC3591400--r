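# Probability filtering, grouping with parsimony, decoy FDR, fraction merge.

test_that("peptide filtering keeps the boundary probability", {
  ev <- rbind(make_evidence("AAAK", "P1", probability = 0.69),
              make_evidence("CCCK", "P1", probability = 0.70),
              make_evidence("DDDK", "P1", probability = 0.71))
  expect_equal(suppressMessages(filter_peptides(ev))$probability,
               c(0.70, 0.71))
  expect_equal(nrow(suppressMessages(filter_peptides(ev, p_min = 0))), 3L)
  expect_message(filter_peptides(ev), "1 of 3")
  expect_error(filter_peptides(ev, p_min = 2), "p_min")
})

test_that("filtering enriches targets over decoys under the score model", {
  lane <- gel_lane("F1")
  tr <- generate_truth(300, frac_regulated = 0, decoy_fraction = 0.4,
                       seed = 51)
  ev <- simulate_evidence(tr, lane, seed = 52)
  keep <- ev$probability >= 0.70
  decoy_share <- function(x) mean(startsWith(x$accessions, "DECOY_"))
  expect_lt(decoy_share(ev[keep, ]), decoy_share(ev[!keep, ]))
})

test_that("redundant identifications pool across adjacent bands", {
  ev <- do.call(rbind, lapply(53:58, function(b)
    make_evidence(paste0("PEP", b, "K"), "CATB", band = b)))
  pg <- group_proteins(ev)
  expect_equal(nrow(pg$groups), 1L)
  expect_equal(pg$groups$bands_seen, "53,54,55,56,57,58")
  expect_equal(pg$groups$n_unique_peptides, 6L)
  expect_equal(pg$groups$tier, "UNAMBIGUOUS")
})

test_that("subset accessions are absorbed by parsimony", {
  ev <- rbind(
    make_evidence("AAAAK", "BIG"), make_evidence("CCCCK", "BIG"),
    make_evidence("DDDDK", "BIG"),
    make_evidence("AAAAK", "SUB"), make_evidence("CCCCK", "SUB"))
  pg <- group_proteins(ev)
  expect_equal(pg$groups$accession, "BIG")
  expect_equal(pg$groups$members, "BIG;SUB")
  # the absorbed accession's peptides count once for the group
  expect_equal(pg$groups$n_unique_peptides, 3L)
  # grouping is idempotent on its own evidence
  pg2 <- group_proteins(pg$evidence[, names(ev)])
  expect_equal(pg2$groups$accession, pg$groups$accession)
  expect_equal(pg2$groups$n_unique_peptides, pg$groups$n_unique_peptides)
})

test_that("charge variants count once; shared peptides are non-unique", {
  ev <- rbind(
    make_evidence("AAAAK", "P1", charge = 2),
    make_evidence("AAAAK", "P1", charge = 3),   # same sequence, new charge
    make_evidence("CCCCK", "P1"), make_evidence("DDDDK", "P1"),
    make_evidence("SHAREDK", "P1;P2"),
    make_evidence("EEEEK", "P2"), make_evidence("FFFFK", "P2"))
  pg <- group_proteins(ev)
  g <- pg$groups[order(pg$groups$accession), ]
  expect_equal(g$n_unique_peptides, c(3L, 2L))
  expect_equal(g$tier, c("UNAMBIGUOUS", "LOW_EVIDENCE"))
  shared_rows <- pg$evidence$peptide == "SHAREDK"
  expect_true(all(!pg$evidence$is_unique[shared_rows]))
})

test_that("low-probability protein groups are dropped", {
  ev <- rbind(make_evidence("AAAAK", "HI", probability = 0.99),
              make_evidence("CCCCK", "LO", probability = 0.80))
  pg <- group_proteins(ev, prob_min = 0.95)
  expect_equal(pg$groups$accession, "HI")
  # boundary retained: 0.95 counts as passing
  ev2 <- make_evidence("AAAAK", "EDGE", probability = 0.95)
  expect_equal(group_proteins(ev2)$groups$accession, "EDGE")
})

test_that("decoy FDR is decoys over targets as a percentage", {
  g <- data.frame(
    accession = c(sprintf("T%02d", 1:50), "DECOY_A", "DECOY_B"),
    tier = "LOW_EVIDENCE",
    is_decoy = c(rep(FALSE, 50), TRUE, TRUE))
  expect_equal(decoy_fdr(g), 4.0)
  expect_equal(decoy_fdr(g[1:50, ]), 0)
  expect_error(decoy_fdr(g[51:52, ]), "FDR undefined")
})

test_that("fraction merging obeys set arithmetic", {
  a <- sprintf("P%03d", 1:40)
  b <- sprintf("P%03d", 26:70)
  m <- merge_fractions(a, b)
  expect_equal(nrow(m), length(union(a, b)))
  expect_equal(sum(m$in_f1 & m$in_f2), length(intersect(a, b)))
  expect_setequal(unique(m$status), c("both", "F1-only", "F2-only"))
  # disjoint and identical edge cases
  expect_equal(nrow(merge_fractions(a, sprintf("Q%03d", 1:10))), 50L)
  expect_equal(nrow(merge_fractions(a, a)), 40L)
  # random pairs against independent set arithmetic
  set.seed(53)
  for (i in 1:10) {
    x <- sample(sprintf("X%03d", 1:60), sample(5:50, 1))
    y <- sample(sprintf("X%03d", 1:60), sample(5:50, 1))
    expect_equal(nrow(merge_fractions(x, y)),
                 length(x) + length(y) - length(intersect(x, y)))
  }
})

test_that("grouping partitions retained accessions by fraction", {
  lane <- gel_lane("F1")
  tr <- generate_truth(120, frac_regulated = 0.1, seed = 54)
  ev <- simulate_evidence(tr, lane, seed = 55)
  pg <- group_proteins(suppressMessages(filter_peptides(ev)))
  expect_false(anyDuplicated(pg$groups$accession) > 0)
  expect_true(all(pg$evidence$group_accession %in% pg$groups$accession))
  expect_true(all(pg$groups$n_unique_peptides >= 1L |
                    pg$groups$tier == "LOW_EVIDENCE"))
})
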