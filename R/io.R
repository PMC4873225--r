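#' @title TSV and image IO for pipeline artifacts
#' @description Readers and writers for the plain-text and TIFF formats
#'   exchanged between pipeline stages: expression matrix + sample
#'   metadata + auxiliary score tables, long-format qPCR measurements +
#'   clinical table, candidate traces, report tables and 16-bit two-channel
#'   organoid TIFFs.
#' @name prostmark-io
NULL

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write an expression cohort to a directory
#'
#' Emits `matrix.tsv` (rows = genes, first column `gene`), `samples.tsv`,
#' `tissue_scores.tsv`, `citations.tsv` and `truth_genes.tsv`.
#'
#' @param cohort an `expression_cohort`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mat <- data.frame(gene = rownames(cohort$matrix), cohort$matrix,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(mat, file.path(dir, "matrix.tsv"))
  write_tsv(cohort$samples, file.path(dir, "samples.tsv"))
  write_tsv(cohort$tissue_scores, file.path(dir, "tissue_scores.tsv"))
  write_tsv(cohort$citations, file.path(dir, "citations.tsv"))
  write_tsv(cohort$truth$genes, file.path(dir, "truth_genes.tsv"))
  invisible(dir)
}

#' Read an expression cohort from a directory
#'
#' Counterpart of [write_cohort()]; the truth table is attached when
#' present.
#'
#' @param dir directory holding `matrix.tsv`, `samples.tsv`,
#'   `tissue_scores.tsv`, `citations.tsv`.
#' @return an `expression_cohort`.
#' @export
read_cohort <- function(dir) {
  mat_df <- read_tsv(file.path(dir, "matrix.tsv"))
  mat <- as.matrix(mat_df[, -1, drop = FALSE])
  rownames(mat) <- mat_df$gene
  truth_path <- file.path(dir, "truth_genes.tsv")
  structure(
    list(matrix = mat,
         samples = read_tsv(file.path(dir, "samples.tsv")),
         tissue_scores = read_tsv(file.path(dir, "tissue_scores.tsv")),
         citations = read_tsv(file.path(dir, "citations.tsv")),
         truth = if (file.exists(truth_path))
           list(genes = read_tsv(truth_path)) else NULL),
    class = "expression_cohort"
  )
}

#' Write a qPCR dataset (long table + clinical table)
#'
#' @param dataset a `qpcr_dataset`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_qpcr <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(dataset$data, file.path(dir, "qpcr.tsv"))
  write_tsv(dataset$clinical, file.path(dir, "clinical.tsv"))
  if (!is.null(dataset$truth))
    write_tsv(dataset$truth$samples, file.path(dir, "truth_qpcr.tsv"))
  invisible(dir)
}

#' Read a qPCR dataset from its two TSV files
#'
#' @param qpcr_path long-format measurement TSV.
#' @param clinical_path clinical annotation TSV.
#' @return a `qpcr_dataset` (without ground truth).
#' @export
read_qpcr <- function(qpcr_path, clinical_path) {
  dat <- read_tsv(qpcr_path)
  dat$lobe <- as.character(dat$lobe)
  dat$lobe[dat$lobe %in% c("NA", "")] <- NA_character_
  structure(list(data = dat, clinical = read_tsv(clinical_path),
                 truth = NULL),
            class = "qpcr_dataset")
}

#' Write a two-channel organoid image as 16-bit TIFF
#'
#' Channel 1 = live signal, channel 2 = dead signal, stored as two pages.
#'
#' @param image an `organoid_image` or list with `live`, `dead` integer
#'   matrices in the 16-bit range.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_organoid_tiff <- function(image, path) {
  tiff::writeTIFF(list(image$live / 65535, image$dead / 65535), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Read a two-channel 16-bit organoid TIFF
#'
#' @param path file written by [write_organoid_tiff()].
#' @return list with integer matrices `live` and `dead`.
#' @export
read_organoid_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2L) stop("expected a two-page TIFF")
  list(live = round(pages[[1]] * 65535), dead = round(pages[[2]] * 65535))
}

#' Write a candidate trace (TSV + JSON audit log)
#'
#' @param trace a `candidate_trace`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_trace <- function(trace, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(trace$trace, file.path(dir, "candidates.tsv"))
  writeLines(trace$final, file.path(dir, "final_genes.txt"))
  jsonlite::write_json(trace$audit, file.path(dir, "audit.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Write a validation report (three TSVs + combined JSON)
#'
#' @param report a `validation_report`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(report$detection, file.path(dir, "detection.tsv"))
  write_tsv(report$contrasts, file.path(dir, "contrasts.tsv"))
  write_tsv(report$roc, file.path(dir, "roc.tsv"))
  jsonlite::write_json(
    list(detection = report$detection, contrasts = report$contrasts,
         roc = report$roc, problems = report$problems),
    file.path(dir, "report.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(dir)
}
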