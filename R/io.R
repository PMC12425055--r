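# Delimited-text I/O with validation. Everything is flat UTF-8 TSV with a
# header row, first column sample_id, "NA" for missing — desk-scale matrices
# do not justify binary formats.

read_sample_table <- function(path, default_type = readr::col_double()) {
  tbl <- readr::read_tsv(path, na = "NA", show_col_types = FALSE,
                         col_types = readr::cols(
                           sample_id = readr::col_character(),
                           .default = default_type))
  if (!"sample_id" %in% names(tbl)) {
    abort(paste0(path, ": first column must be sample_id"))
  }
  if (anyDuplicated(tbl$sample_id)) {
    dup <- tbl$sample_id[duplicated(tbl$sample_id)][1]
    abort(paste0(path, ": duplicate sample_id '", dup, "'"))
  }
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) {
    abort(paste0(path, ": parse problem at line ", prob$row[1], ": ",
                 prob$expected[1]))
  }
  tbl
}

check_range <- function(tbl, lo, hi, path, tol = 1e-6) {
  vals <- as.matrix(tbl[setdiff(names(tbl), "sample_id")])
  bad <- which(!is.na(vals) & (vals < lo - tol | vals > hi + tol), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("%s: value %.4g out of [%g, %g] at sample '%s', column '%s'",
                  path, vals[bad[1, , drop = FALSE]], lo, hi,
                  tbl$sample_id[bad[1, 1]],
                  setdiff(names(tbl), "sample_id")[bad[1, 2]]))
  }
  invisible(tbl)
}

#' Read and write the pipeline's delimited files
#'
#' Tab-separated, header row, first column `sample_id`, `NA` for missing.
#' `read_methylation()` validates beta values in `[0, 1]` (tolerance 1e-6),
#' `read_dosages()` validates dosages in `[0, 2]`; both error with the
#' offending sample and column named. Row order is preserved.
#'
#' @param path File path.
#' @return A tibble with `sample_id` plus numeric columns.
#' @export
read_methylation <- function(path) {
  check_range(read_sample_table(path), 0, 1, path)
}

#' @rdname read_methylation
#' @export
read_dosages <- function(path) {
  check_range(read_sample_table(path), 0, 2, path)
}

#' @rdname read_methylation
#' @export
read_covariates <- function(path) {
  read_sample_table(path, default_type = readr::col_guess())
}

#' @rdname read_methylation
#' @param tbl Tibble with `sample_id` first column.
#' @export
write_sample_table <- function(tbl, path) {
  readr::write_tsv(tbl, path, na = "NA")
  invisible(path)
}

#' Write or read one cohort as delimited files
#'
#' A cohort is stored as `<cohort>.meth.tsv`, `<cohort>.covar.tsv` and,
#' when present, `<cohort>.geno.tsv` and `<cohort>.truth.tsv` (latent
#' ancestry, simulation only) in one directory.
#'
#' @param dataset A [cohort_dataset()].
#' @param dir Directory.
#' @param cohort_id Cohort label (for `read_cohort()`).
#' @return `write_cohort()` returns the file paths invisibly;
#'   `read_cohort()` returns a [cohort_dataset()].
#' @export
write_cohort <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, dataset$cohort_id)
  paths <- c(meth = paste0(base, ".meth.tsv"), covar = paste0(base, ".covar.tsv"))
  write_sample_table(dataset$methylation, paths["meth"])
  write_sample_table(dataset$covariates, paths["covar"])
  if (!is.null(dataset$genotypes)) {
    paths["geno"] <- paste0(base, ".geno.tsv")
    write_sample_table(dataset$genotypes, paths["geno"])
  }
  if (!is.null(dataset$truth)) {
    paths["truth"] <- paste0(base, ".truth.tsv")
    write_sample_table(dataset$truth, paths["truth"])
  }
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir, cohort_id) {
  base <- file.path(dir, cohort_id)
  geno_path <- paste0(base, ".geno.tsv")
  truth_path <- paste0(base, ".truth.tsv")
  cohort_dataset(
    cohort_id = cohort_id,
    methylation = read_methylation(paste0(base, ".meth.tsv")),
    covariates = read_covariates(paste0(base, ".covar.tsv")),
    genotypes = if (file.exists(geno_path)) read_dosages(geno_path) else NULL,
    truth = if (file.exists(truth_path)) read_covariates(truth_path) else NULL
  )
}
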