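# Category summaries from a user-supplied annotation map.
#
# Each accession maps to exactly one cellular-localization category and one
# biological-function category (a protein with several plausible homes is
# assigned the one it is best known for, a curation step that happens when
# the map is built, not here). No online ontology lookup is performed: the
# map is a plain input table, which keeps runs reproducible.

#' Controlled category vocabularies
#'
#' @return List with `localization` and `biological_function` character
#'   vectors.
#' @export
annotation_categories <- function() {
  list(
    localization = c("plasma membrane", "ER/Golgi", "ribosome",
                     "mitochondrion", "endosome/lysosome", "nucleus",
                     "unknown membrane", "cytoskeleton", "cytosol",
                     "extracellular"),
    biological_function = c("transport", "protein metabolism",
                            "nucleic-acid metabolism",
                            "carbohydrate metabolism", "lipid metabolism",
                            "adhesion/motility/immune", "structural",
                            "other"))
}

#' Read an annotation map
#'
#' @param path TSV with columns `accession`, `localization`,
#'   `biological_function`. Categories outside the controlled vocabularies
#'   are rejected.
#' @return Data.frame annotation map.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  need <- c("accession", "localization", "biological_function")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation map missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  vocab <- annotation_categories()
  bad <- setdiff(unique(df$localization), vocab$localization)
  if (length(bad))
    stop("unknown localization category: ", bad[[1L]], call. = FALSE)
  bad <- setdiff(unique(df$biological_function), vocab$biological_function)
  if (length(bad))
    stop("unknown biological-function category: ", bad[[1L]],
         call. = FALSE)
  if (anyDuplicated(df$accession))
    stop("annotation map has duplicated accessions", call. = FALSE)
  df[, need]
}

#' Summarize accessions by annotation category
#'
#' Counts and display percentages (integer-rounded, over mapped accessions
#' only) per localization and per biological-function category; unmapped
#' accessions are tallied separately so counts always conserve.
#'
#' @param accessions Character vector of protein accessions.
#' @param annotation Annotation map data.frame (see [read_annotation()]).
#' @return List with `localization` and `biological_function` count tables
#'   (`category`, `count`, `pct`), plus `n_total`, `n_mapped`,
#'   `n_unmapped`.
#' @export
categorize <- function(accessions, annotation) {
  accessions <- unique(accessions)
  hit <- match(accessions, annotation$accession)
  mapped <- !is.na(hit)
  vocab <- annotation_categories()
  tally <- function(values, categories) {
    counts <- table(factor(values, levels = categories))
    data.frame(category = categories,
               count = as.integer(counts),
               pct = if (sum(counts) > 0)
                 as.integer(round(100 * as.integer(counts) / sum(counts)))
               else 0L,
               stringsAsFactors = FALSE)
  }
  list(
    localization = tally(annotation$localization[hit[mapped]],
                         vocab$localization),
    biological_function = tally(
      annotation$biological_function[hit[mapped]],
      vocab$biological_function),
    n_total = length(accessions),
    n_mapped = sum(mapped),
    n_unmapped = sum(!mapped))
}
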