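# End-to-end orchestration: filter -> group -> quantify -> normalize ->
# test -> report per fraction, then cross-fraction merging, with a flat
# key=value config and a reproducibility manifest.

#' Default pipeline configuration
#'
#' Thresholds and options of the analysis: the peptide-probability cut
#' (0.70), the protein-probability cut (0.95), the unique-peptide count
#' defining unambiguous identifications (3), the significance level on the
#' raw p-value (0.05), the null-scale estimator, the optional MAD outlier
#' rule for band averaging, the channel orientation labels (ratios are
#' light over heavy throughout), and the seed recorded in the manifest.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    peptide_p_min = 0.70,
    protein_p_min = 0.95,
    min_unique_peptides = 3,
    alpha = 0.05,
    estimator = "SD",
    reject_outliers = FALSE,
    ratio_mode = "band_mean",
    light_label = "sample",
    heavy_label = "reference",
    seed = 1
  )
}

#' Write a configuration as flat key = value text
#'
#' @param config Named list (see [default_config()]).
#' @param path Output file.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    sprintf("%s = %s", k, format(config[[k]], scientific = FALSE)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key = value configuration
#'
#' Values are coerced against the types of [default_config()]; unknown
#' keys are kept as character. A write/read cycle is lossless.
#'
#' @param path Config file.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*?)\\s*$", lines))
  defaults <- default_config()
  config <- list()
  for (m in kv) {
    if (length(m) != 3L) next
    key <- m[[2L]]
    val <- m[[3L]]
    config[[key]] <- if (key %in% names(defaults)) {
      ref <- defaults[[key]]
      if (is.numeric(ref)) as.numeric(val)
      else if (is.logical(ref)) as.logical(val)
      else val
    } else val
  }
  out <- utils::modifyList(defaults, config)
  out
}

# Validate threshold ranges before running.
check_config <- function(config) {
  in01 <- function(x) is.numeric(x) && x >= 0 && x <= 1
  if (!in01(config$peptide_p_min)) stop("peptide_p_min outside [0,1]")
  if (!in01(config$protein_p_min)) stop("protein_p_min outside [0,1]")
  if (!in01(config$alpha)) stop("alpha outside [0,1]")
  if (config$min_unique_peptides < 1) stop("min_unique_peptides < 1")
  if (!config$estimator %in% c("SD", "MAD")) stop("unknown estimator")
  invisible(config)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full quantitative analysis
#'
#' Per fraction: probability filtering, protein grouping, target-decoy FDR
#' per evidence tier, band-wise quantification, median normalization over
#' the unambiguous target proteins, Z-statistic p-values, and significance
#' calling. With two fractions the significant tables carry the companion
#' fraction's ratio and p-value (`"ni."` when not identified there) and
#' the unambiguous identifications are merged into a union table.
#'
#' @param evidence Named list (one element per fraction label) of evidence
#'   data.frames or TSV paths readable by [read_evidence()].
#' @param config Configuration list (see [default_config()]).
#' @param annotation Optional annotation map (data.frame or TSV path) for
#'   category summaries of identified and significant proteins.
#' @param out_dir Optional output directory; when given, writes per-
#'   fraction significance reports (`report_<fraction>.tsv`), full quant
#'   tables, the union table, the config and a run manifest. Re-running
#'   with identical inputs and config reproduces the files byte for byte.
#' @return (Invisibly when writing) list with `quants`, `significant`,
#'   `distributions`, `sigma`, `fdr`, `merged`, `annotation_summary`,
#'   `manifest`.
#' @export
run_pipeline <- function(evidence, config = default_config(),
                         annotation = NULL, out_dir = NULL) {
  check_config(config)
  if (is.null(names(evidence)) || any(!nzchar(names(evidence))))
    stop("evidence must be a named list (one entry per fraction)",
         call. = FALSE)
  counts <- list()
  evidence <- run_stage("read", lapply(evidence, function(e)
    if (is.character(e)) read_evidence(e) else validate_evidence(e)))
  if (is.character(annotation)) annotation <- read_annotation(annotation)

  quants <- list(); sigma <- list(); dists <- list()
  signif <- list(); fdr <- list()
  for (fr in names(evidence)) {
    ev <- evidence[[fr]]
    counts[[paste0("n_evidence_", fr)]] <- nrow(ev)
    filt <- run_stage("filter_peptides",
                      suppressMessages(filter_peptides(
                        ev, config$peptide_p_min)))
    counts[[paste0("n_filtered_", fr)]] <- nrow(filt)
    pg <- run_stage("group_proteins",
                    group_proteins(filt, config$protein_p_min))
    counts[[paste0("n_groups_", fr)]] <- nrow(pg$groups)
    fdr[[fr]] <- c(
      low_evidence = tryCatch(decoy_fdr(pg, TIER_LOW),
                              error = function(e) NA_real_),
      unambiguous = tryCatch(decoy_fdr(pg, TIER_UNAMBIGUOUS),
                             error = function(e) NA_real_))
    qt <- run_stage("quantify",
                    quantify_groups(pg,
                                    reject_outliers = config$reject_outliers,
                                    mode = config$ratio_mode))
    qt <- qt[!qt$is_decoy, , drop = FALSE]
    counts[[paste0("n_quantified_", fr)]] <- nrow(qt)
    # normalization and scale from the unambiguous-tier distribution
    run_stage("normalize", {
      unamb <- qt[qt$n_unique_peptides >= config$min_unique_peptides, ,
                  drop = FALSE]
      nq <- normalize_median(unamb)
      dists[[fr]] <- attr(nq, "distribution")
      med <- dists[[fr]]$median[1L]
      qt$norm_log2 <- ifelse(is.finite(qt$log2_lh),
                             qt$log2_lh - med, qt$log2_lh)
      sigma[[fr]] <- fit_scale(nq$norm_log2, config$estimator)
    })
    qt <- run_stage("test", z_pvalues(qt, sigma[[fr]]))
    quants[[fr]] <- qt
    sg <- run_stage("significant_set", {
      s <- significant_set(
        qt[qt$n_unique_peptides >= config$min_unique_peptides, ,
           drop = FALSE],
        alpha = config$alpha, require_tier = NULL)
      s$fractions_seen <- fr
      s
    })
    signif[[fr]] <- sg
    counts[[paste0("n_significant_", fr)]] <- nrow(sg)
  }

  merged <- NULL
  if (length(evidence) == 2L) {
    frs <- names(evidence)
    run_stage("merge_fractions", {
      unamb_acc <- lapply(quants, function(q)
        q$accession[q$n_unique_peptides >= config$min_unique_peptides])
      merged <- merge_fractions(unamb_acc[[1L]], unamb_acc[[2L]],
                                labels = frs)
      for (i in 1:2) {
        other <- quants[[frs[[3L - i]]]]
        hit <- match(signif[[frs[[i]]]]$accession, other$accession)
        signif[[frs[[i]]]]$other_log2 <- other$log2_lh[hit]
        signif[[frs[[i]]]]$other_p <- other$p_value[hit]
      }
    })
    counts$n_union <- nrow(merged)
    counts$n_both <- sum(merged$in_f1 & merged$in_f2)
  }

  annotation_summary <- NULL
  if (!is.null(annotation)) {
    annotation_summary <- run_stage("annotation", list(
      identified = categorize(
        if (!is.null(merged)) merged$accession
        else unlist(lapply(quants, `[[`, "accession")), annotation),
      significant = categorize(
        unlist(lapply(signif, `[[`, "accession")), annotation)))
  }

  manifest <- c(
    package = "gelsilac",
    version = as.character(utils::packageVersion("gelsilac")),
    unlist(lapply(config, function(v) format(v, scientific = FALSE))),
    ratio_orientation = sprintf("light(%s)/heavy(%s)",
                                config$light_label, config$heavy_label),
    unlist(counts),
    unlist(lapply(sigma, function(s) sprintf("%.6f", s))))

  result <- list(quants = quants, significant = signif,
                 distributions = dists, sigma = sigma, fdr = fdr,
                 merged = merged, annotation_summary = annotation_summary,
                 manifest = manifest)
  if (!is.null(out_dir)) {
    run_stage("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (fr in names(quants)) {
        write_report(signif[[fr]],
                     file.path(out_dir, paste0("report_", fr, ".tsv")))
        utils::write.table(
          quants[[fr]], file.path(out_dir, paste0("quants_", fr, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
      if (!is.null(merged))
        utils::write.table(merged, file.path(out_dir, "union.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      write_config(config, file.path(out_dir, "config.txt"))
      writeLines(sprintf("%s = %s", names(manifest), manifest),
                 file.path(out_dir, "manifest.txt"))
    })
    return(invisible(result))
  }
  result
}
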