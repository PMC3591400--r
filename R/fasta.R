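# FASTA I/O for protein databases, plain or decoy-augmented.

#' Read a protein FASTA database
#'
#' @param path FASTA file. The first whitespace-delimited token of each
#'   header is the accession; the remainder is the description.
#' @return A list of [protein_entry()] objects; entries whose accession
#'   starts with `DECOY_` are flagged as decoys.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  lapply(seq_along(aa), function(i) {
    toks <- strsplit(headers[[i]], "\\s+")[[1L]]
    protein_entry(
      accession = toks[[1L]],
      sequence = as.character(aa[[i]]),
      description = if (length(toks) > 1L)
        paste(toks[-1L], collapse = " ") else "")
  })
}

#' Write protein entries to FASTA
#'
#' @param proteins List of [protein_entry()] objects.
#' @param path Output file.
#' @export
write_fasta <- function(proteins, path) {
  seqs <- vapply(proteins, `[[`, character(1), "sequence")
  aa <- Biostrings::AAStringSet(seqs)
  names(aa) <- vapply(proteins, function(p)
    trimws(paste(p$accession, p$description)), character(1))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Append shuffled decoys to a target database
#'
#' Concatenates the target entries with one shuffled decoy per target,
#' the standard construction for target-decoy FDR estimation.
#'
#' @param proteins List of target [protein_entry()] objects.
#' @param seed Integer seed for the decoy shuffles (one derived seed per
#'   entry, so the result is reproducible and order-independent per entry).
#' @param keep_kr Passed to [shuffle_decoy()].
#' @return List of length `2 * length(proteins)`: targets then decoys.
#' @export
build_decoy_database <- function(proteins, seed, keep_kr = FALSE) {
  decoys <- lapply(seq_along(proteins), function(i)
    shuffle_decoy(proteins[[i]], seed = seed + i, keep_kr = keep_kr))
  c(proteins, decoys)
}
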