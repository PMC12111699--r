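# Orchestration and file I/O: plain-text readers/writers for every input
# and output, and a one-call pipeline with a run manifest.

#' Write / read a gene count matrix as TSV
#'
#' Tab-separated, first column `gene_id`, header row of sample identifiers,
#' integer cells.  The reader validates the matrix and aborts on a negative
#' entry, naming the file, line and offending value.
#'
#' @param counts gene x sample integer matrix with dimnames.
#' @param path file path.
#' @return `writeCountsTSV` returns `path` invisibly; `readCountsTSV`
#'   returns the matrix.
#' @export
writeCountsTSV <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountsTSV
#' @export
readCountsTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative count in ", path, " at line ", bad[1] + 1L,
         " (gene ", rownames(m)[bad[1]], ", sample ",
         colnames(m)[bad[2]], "): ", m[bad[1], bad[2]])
  }
  storage.mode(m) <- "numeric"
  m
}

#' Plain-text table I/O helpers
#'
#' CSV readers/writers for the sample metadata, CBC panel, trait table and
#' long-format body-weight series; metadata factor columns are restored on
#' read.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return readers return a data.frame; writers return `path` invisibly.
#' @export
writeTableCSV <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTableCSV
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.csv(path)
  for (f in c("breed", "pen", "sire")) df[[f]] <- factor(df[[f]])
  df
}

#' @rdname writeTableCSV
#' @export
readTableCSV <- function(path) utils::read.csv(path)

#' Run the full analysis pipeline
#'
#' Simulates a study from `cfg` (or consumes a pre-built
#' `SummarizedExperiment`), writes the raw inputs, preprocesses the counts,
#' runs the hematology scan, and runs differential expression for each of
#' the three traits.  All outputs are plain text under `outdir`, and a
#' `manifest.json` records seeds, stage parameters, and input/output
#' dimensions at every filter step.  A rerun with the same configuration
#' produces byte-identical result files.
#'
#' @param cfg a [SimConfig-class], or a `SummarizedExperiment` as produced
#'   by [simulateStudy()].
#' @param outdir output directory (created if needed).
#' @param fdr differential-expression significance threshold.
#' @param ellipseLevel,meanThresh,zeroFrac,filterLogic,dropFrac
#'   preprocessing parameters, see [prepCounts()].
#' @return invisibly, a list with the prep object, the hematology scan, the
#'   per-trait DE tables and the manifest.
#' @export
runPipeline <- function(cfg = simConfig(), outdir, fdr = 0.1,
                        ellipseLevel = 0.985, meanThresh = 10,
                        zeroFrac = 0.8, filterLogic = "or",
                        dropFrac = 0.10) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  se <- if (is(cfg, "SummarizedExperiment")) cfg
        else stage("simulate", simulateStudy(cfg))
  config <- S4Vectors::metadata(se)$config
  truth <- S4Vectors::metadata(se)$groundTruth
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  meta <- cd[, c("animal_id", "breed", "pen", "sire", "age")]
  cbc <- cd[, c("animal_id", cbcParameterNames())]
  traits <- cd[, c("animal_id", "ADG", "ADFI", "GF")]
  counts <- SummarizedExperiment::assay(se, "counts")

  writeCountsTSV(counts, file.path(outdir, "counts.tsv"))
  writeTableCSV(meta, file.path(outdir, "metadata.csv"))
  writeTableCSV(cbc, file.path(outdir, "cbc.csv"))
  writeTableCSV(traits, file.path(outdir, "traits.csv"))
  writeTableCSV(S4Vectors::metadata(se)$weights,
                file.path(outdir, "weights.csv"))
  if (!is.null(truth))
    jsonlite::write_json(
      list(planted_genes = truth@plantedGenes,
           planted_directions = truth@plantedDirections,
           outlier_samples = truth@outlierSamples),
      file.path(outdir, "ground_truth.json"), auto_unbox = FALSE)

  prep <- stage("prep", prepCounts(counts, meanThresh = meanThresh,
                                   zeroFrac = zeroFrac,
                                   filterLogic = filterLogic,
                                   dropFrac = dropFrac,
                                   ellipseLevel = ellipseLevel))
  utils::write.table(
    data.frame(sample = names(sizeFactors(prep)),
               size_factor = unname(sizeFactors(prep))),
    file.path(outdir, "size_factors.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(prep@keptGenes, file.path(outdir, "kept_genes.txt"))
  utils::write.table(
    data.frame(sample = rownames(prep@pcScores), prep@pcScores,
               outlier = rownames(prep@pcScores) %in% prep@outliers),
    file.path(outdir, "pc_scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  scan <- stage("hema-scan", hemaScan(traits, cbc, meta))
  utils::write.table(format(scan, digits = 6),
                     file.path(outdir, "hematology_scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  de <- list()
  for (tr in c("ADG", "ADFI", "GF")) {
    de[[tr]] <- stage(paste0("de-", tr),
                      runDE(prep, trait = tr, meta = se, cbc = se,
                            fdr = fdr))
    utils::write.table(format(de[[tr]], digits = 6),
                       file.path(outdir, paste0("de_", tolower(tr), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    seed = if (!is.null(config)) config@seed else NA,
    parameters = list(fdr = fdr, ellipse_level = ellipseLevel,
                      mean_thresh = meanThresh, zero_frac = zeroFrac,
                      filter_logic = filterLogic, drop_frac = dropFrac),
    genes_input = nrow(counts),
    genes_after_filter = length(prep@keptGenes),
    samples_input = ncol(counts),
    outliers_removed = length(prep@outliers),
    samples_retained = length(prep@retained),
    hema_scan_rows = nrow(scan),
    de_significant = vapply(de, function(x) sum(x$significant), integer(1)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(prep = prep, scan = scan, de = de, manifest = manifest))
}
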