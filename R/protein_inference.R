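# Protein inference: probability filtering, grouping of redundant
# identifications across gel bands, evidence tiers, target-decoy FDR,
# and cross-fraction merging.

TIER_UNAMBIGUOUS <- "UNAMBIGUOUS"
TIER_LOW <- "LOW_EVIDENCE"

#' Filter peptide evidence by identification probability
#'
#' Retains records with probability at or above the threshold (records
#' *below* 0.70 are removed under the default, the usual peptide-level
#' confidence cut).
#'
#' @param evidence Evidence data.frame.
#' @param p_min Minimum retained probability, in \[0,1\].
#' @return Filtered evidence; the number of removed records is reported
#'   via `message()`.
#' @export
filter_peptides <- function(evidence, p_min = 0.70) {
  if (p_min < 0 || p_min > 1) stop("p_min must be in [0,1]", call. = FALSE)
  keep <- evidence$probability >= p_min
  message(sum(!keep), " of ", length(keep),
          " peptide records removed below probability ", p_min)
  evidence[keep, , drop = FALSE]
}

#' Group redundant protein identifications across gel bands
#'
#' Pools, per fraction, all evidence for each accession across bands into
#' one group; accessions whose peptide-sequence set is a strict subset of
#' another accession's set are absorbed into that group (parsimony).
#' Peptide sequences attributable to more than one surviving group are
#' flagged non-unique: they count for identification but are excluded from
#' the unique-peptide tally and from quantification. The group probability
#' is the maximum contributing identification probability (a proxy usable
#' when no external protein-level probability is supplied); groups below
#' `prob_min` are dropped. Groups with at least 3 distinct unique peptide
#' sequences (charge and modification variants counting once) are tier
#' `UNAMBIGUOUS`, others `LOW_EVIDENCE`.
#'
#' @param evidence Filtered evidence data.frame (see [filter_peptides()]).
#' @param prob_min Minimum protein probability to retain a group.
#' @param protein_probabilities Optional named vector of externally
#'   supplied protein probabilities (accession -> probability), used in
#'   place of the max-peptide proxy where available.
#' @return An object of class `protein_groups`: list with `groups` (one
#'   row per group: `fraction`, `accession`, `members`, `bands_seen`,
#'   `n_unique_peptides`, `tier`, `protein_probability`, `is_decoy`) and
#'   `evidence` (the input rows annotated with `group_accession` and
#'   `is_unique`).
#' @export
group_proteins <- function(evidence, prob_min = 0.95,
                           protein_probabilities = NULL) {
  if (prob_min < 0 || prob_min > 1)
    stop("prob_min must be in [0,1]", call. = FALSE)
  per_fraction <- lapply(split(evidence, evidence$fraction),
                         group_one_fraction,
                         prob_min = prob_min,
                         protein_probabilities = protein_probabilities)
  structure(
    list(groups = do.call(rbind, c(lapply(per_fraction, `[[`, "groups"),
                                   list(make.row.names = FALSE))),
         evidence = do.call(rbind, c(lapply(per_fraction, `[[`, "evidence"),
                                     list(make.row.names = FALSE)))),
    class = "protein_groups")
}

group_one_fraction <- function(evidence, prob_min, protein_probabilities) {
  # expand shared-peptide rows (semicolon-separated accessions)
  acc_list <- strsplit(evidence$accessions, ";", fixed = TRUE)
  nacc <- lengths(acc_list)
  long <- evidence[rep(seq_len(nrow(evidence)), nacc), , drop = FALSE]
  long$accession <- unlist(acc_list)

  pepsets <- lapply(split(long$peptide, long$accession), unique)
  accs <- names(pepsets)

  # parsimony: absorb accessions whose peptide set is a strict subset of
  # another accession's set; candidate supersets share at least a peptide
  pep_to_acc <- split(rep(accs, lengths(pepsets)), unlist(pepsets))
  owner <- stats::setNames(accs, accs)
  ord <- order(lengths(pepsets))          # small sets first
  for (a in accs[ord]) {
    set_a <- pepsets[[a]]
    cands <- setdiff(unique(unlist(pep_to_acc[set_a])), a)
    for (b in cands[order(-lengths(pepsets[cands]))]) {
      if (length(pepsets[[b]]) > length(set_a) &&
          all(set_a %in% pepsets[[b]])) {
        owner[[a]] <- b
        break
      }
    }
  }
  # resolve chains (a absorbed by b, b absorbed by c)
  repeat {
    nxt <- owner[owner]
    if (identical(unname(nxt), unname(owner))) break
    owner <- nxt
  }
  long$group_accession <- unname(owner[long$accession])

  # a peptide sequence observed for >1 surviving group is non-unique
  groups_per_pep <- lapply(
    split(long$group_accession, long$peptide), unique)
  long$is_unique <- lengths(groups_per_pep[long$peptide]) == 1L

  g <- split(long, long$group_accession)
  groups <- data.frame(
    fraction = vapply(g, function(d) d$fraction[1L], character(1)),
    accession = names(g),
    members = vapply(g, function(d)
      paste(sort(unique(d$accession)), collapse = ";"), character(1)),
    bands_seen = vapply(g, function(d)
      paste(sort(unique(d$band_index)), collapse = ","), character(1)),
    n_unique_peptides = vapply(g, function(d)
      length(unique(d$peptide[d$is_unique])), integer(1)),
    protein_probability = vapply(g, function(d)
      max(d$probability), numeric(1)),
    stringsAsFactors = FALSE)
  if (!is.null(protein_probabilities)) {
    hit <- groups$accession %in% names(protein_probabilities)
    groups$protein_probability[hit] <-
      protein_probabilities[groups$accession[hit]]
  }
  groups$tier <- ifelse(groups$n_unique_peptides >= 3L,
                        TIER_UNAMBIGUOUS, TIER_LOW)
  groups$is_decoy <- startsWith(groups$accession, .DECOY_PREFIX)
  keep <- groups$protein_probability >= prob_min
  groups <- groups[keep, , drop = FALSE]
  long <- long[long$group_accession %in% groups$accession, , drop = FALSE]
  rownames(groups) <- NULL
  rownames(long) <- NULL
  list(groups = groups, evidence = long)
}

#' @export
print.protein_groups <- function(x, ...) {
  g <- x$groups
  cat(sprintf(
    "<protein_groups> %d groups (%d unambiguous, %d low-evidence, %d decoy) from %d evidence rows\n",
    nrow(g), sum(g$tier == TIER_UNAMBIGUOUS), sum(g$tier == TIER_LOW),
    sum(g$is_decoy), nrow(x$evidence)))
  invisible(x)
}

#' Target-decoy false discovery rate within an evidence tier
#'
#' Simple target-decoy estimate: `100 * n_decoy / n_target` among the
#' groups of the requested tier.
#'
#' @param groups A `protein_groups` object or its `groups` data.frame.
#' @param tier `"UNAMBIGUOUS"`, `"LOW_EVIDENCE"` or `"all"`.
#' @return FDR as a percentage.
#' @export
decoy_fdr <- function(groups, tier = "all") {
  g <- if (inherits(groups, "protein_groups")) groups$groups else groups
  if (tier != "all") g <- g[g$tier == tier, , drop = FALSE]
  n_target <- sum(!g$is_decoy)
  if (n_target == 0L)
    stop("no target groups in tier '", tier, "': FDR undefined",
         call. = FALSE)
  100 * sum(g$is_decoy) / n_target
}

#' Merge protein lists from two fractions
#'
#' Union keyed by accession with per-fraction presence, the bookkeeping
#' behind statements like "651 and 735 proteins, 486 in both, 900 unique".
#'
#' @param f1,f2 Character vectors of accessions, or `protein_groups` /
#'   data.frames with an `accession` column (deduplicated internally).
#' @param labels Fraction labels used in the `status` column.
#' @return Data.frame with `accession`, `in_f1`, `in_f2` and `status`
#'   (`"F1-only"`, `"F2-only"`, `"both"` under default labels).
#' @export
merge_fractions <- function(f1, f2, labels = c("F1", "F2")) {
  as_accessions <- function(x) {
    if (inherits(x, "protein_groups")) x <- x$groups
    if (is.data.frame(x)) x <- x$accession
    unique(as.character(x))
  }
  a <- as_accessions(f1)
  b <- as_accessions(f2)
  accession <- sort(union(a, b))
  in_f1 <- accession %in% a
  in_f2 <- accession %in% b
  data.frame(
    accession = accession, in_f1 = in_f1, in_f2 = in_f2,
    status = ifelse(in_f1 & in_f2, "both",
                    ifelse(in_f1, paste0(labels[1L], "-only"),
                           paste0(labels[2L], "-only"))),
    stringsAsFactors = FALSE)
}
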