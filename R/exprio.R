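#' @importFrom stats median rbinom rexp rnorm runif pt pchisq cor dnorm setNames predict
#' @importFrom utils write.table packageVersion
NULL

# Clinical table column contract (order matters for writers).
CLINICAL_COLUMNS <- c("sample_id", "time_months", "event", "stage", "grade",
                      "n_tumors", "size_gt3cm", "intravesical_therapy")
STAGE_LEVELS   <- c("Ta", "T1")
GRADE_LEVELS   <- c("low", "high")
NTUMOR_LEVELS  <- c("single", "2to7", "ge8")

#' Validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix, features in rows and
#' samples in columns, with unique non-empty identifiers on both axes and
#' (by default) all-finite log2-scale values.
#'
#' @param x numeric matrix with rownames (features) and colnames (samples).
#' @param require_finite error on any non-finite value.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression <- function(x, require_finite = TRUE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression must be a numeric matrix (features x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry feature rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate feature identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (require_finite && !all(is.finite(x)))
    stop("expression matrix contains non-finite values")
  invisible(x)
}

#' Read an expression matrix from tab-separated text
#'
#' Expects a header row `feature_id<TAB>sample1<TAB>...` followed by one
#' numeric row per feature. Ragged rows, duplicate identifiers and
#' non-numeric cells are rejected with the offending line number.
#'
#' @param path path to a TSV file.
#' @return numeric matrix, features x samples.
#' @export
read_expression <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stop("expression file needs a header and at least one feature row: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L) stop("line 1: header must contain a feature-id column and at least one sample")
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids))
    stop("line 1: duplicated sample column header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  ncol_expected <- length(header)
  body <- fields[-1L]
  widths <- lengths(body)
  if (any(widths != ncol_expected)) {
    bad <- which(widths != ncol_expected)[1L] + 1L
    stop("line ", bad, ": expected ", ncol_expected, " fields, found ", widths[bad - 1L])
  }
  feature_ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(feature_ids)) {
    dup <- feature_ids[duplicated(feature_ids)][1L]
    stop("line ", which(feature_ids == dup)[2L] + 1L, ": duplicated feature identifier: ", dup)
  }
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(ncol_expected - 1L)))
  vals <- matrix(vals, ncol = ncol_expected - 1L, byrow = TRUE)
  if (anyNA(vals)) {
    bad_row <- which(rowSums(is.na(vals)) > 0L)[1L]
    stop("line ", bad_row + 1L, ": non-numeric or empty cell in feature ", feature_ids[bad_row])
  }
  dimnames(vals) <- list(feature_ids, sample_ids)
  validate_expression(vals)
  vals
}

#' Write an expression matrix as tab-separated text
#'
#' @param x numeric matrix, features x samples.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read or write a clinical table
#'
#' The clinical TSV carries one row per sample with the exact columns
#' `sample_id, time_months, event, stage, grade, n_tumors, size_gt3cm,
#' intravesical_therapy`. Times are months to progression or censoring
#' (strictly positive); `event` is 1 for progression. Categorical columns
#' are restricted to `stage` in {Ta, T1}, `grade` in {low, high},
#' `n_tumors` in {single, 2to7, ge8}; the remaining two are 0/1 flags.
#'
#' @param path TSV path.
#' @return data.frame with the columns above, categories as factors.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  missing <- setdiff(CLINICAL_COLUMNS, names(df))
  if (length(missing)) stop("clinical table missing columns: ", paste(missing, collapse = ", "))
  df <- df[CLINICAL_COLUMNS]
  df$time_months <- as.numeric(df$time_months)
  df$event <- as.integer(df$event)
  df$size_gt3cm <- as.integer(df$size_gt3cm)
  df$intravesical_therapy <- as.integer(df$intravesical_therapy)
  validate_clinical(df)
}

#' @rdname read_clinical
#' @param clinical data.frame as returned by [read_clinical()] or
#'   [simulate_cohort()].
#' @export
write_clinical <- function(clinical, path) {
  clinical <- validate_clinical(clinical)
  out <- clinical
  out[] <- lapply(out, as.character)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

validate_clinical <- function(df) {
  missing <- setdiff(CLINICAL_COLUMNS, names(df))
  if (length(missing)) stop("clinical table missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical table")
  if (anyNA(df$time_months) || any(df$time_months <= 0)) stop("time_months must be positive")
  if (!all(df$event %in% c(0L, 1L))) stop("event must be 0/1")
  check_levels <- function(x, levels, name) {
    bad <- setdiff(unique(as.character(x)), levels)
    if (length(bad)) stop(name, " has values outside {", paste(levels, collapse = ", "), "}: ",
                          paste(bad, collapse = ", "))
    factor(as.character(x), levels = levels)
  }
  df$stage <- check_levels(df$stage, STAGE_LEVELS, "stage")
  df$grade <- check_levels(df$grade, GRADE_LEVELS, "grade")
  df$n_tumors <- check_levels(df$n_tumors, NTUMOR_LEVELS, "n_tumors")
  if (!all(df$size_gt3cm %in% c(0L, 1L))) stop("size_gt3cm must be 0/1")
  if (!all(df$intravesical_therapy %in% c(0L, 1L))) stop("intravesical_therapy must be 0/1")
  df
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share one empirical distribution: each
#' sample's sorted vector is replaced by the across-sample mean of sorted
#' vectors, and ties within a sample receive the mean of the reference
#' values at their tied ranks. Feature and sample order are unchanged.
#'
#' @param x numeric matrix, features x samples, all finite.
#' @return normalized matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(x) {
  validate_expression(x)
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Log2-transform and median-center an expression matrix
#'
#' Optionally applies log2, then subtracts each feature's median (one row
#' pass) and then each sample's median (one column pass), in that order.
#' After the column pass every sample's median is exactly zero; row medians
#' may shift away from zero again.
#'
#' @param x numeric matrix, features x samples.
#' @param already_log2 if `FALSE`, values must be strictly positive and are
#'   log2-transformed first.
#' @return centered matrix.
#' @export
log2_median_center <- function(x, already_log2 = TRUE) {
  validate_expression(x)
  if (!already_log2) {
    bad <- which(x <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
      show <- utils::head(bad, 5L)
      stop("log2 requested but non-positive values at: ",
           paste(sprintf("[%s,%s]", rownames(x)[show[, 1L]], colnames(x)[show[, 2L]]),
                 collapse = ", "),
           if (nrow(bad) > 5L) sprintf(" (and %d more)", nrow(bad) - 5L) else "")
    }
    x <- log2(x)
  }
  x <- sweep(x, 1L, apply(x, 1L, median), "-")
  x <- sweep(x, 2L, apply(x, 2L, median), "-")
  x
}
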