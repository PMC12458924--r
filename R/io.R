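#' Read a CpG x sample beta-value matrix
#'
#' Reads a delimited text file with a header row of sample identifiers and
#' CpG identifiers in the first column, and validates it as a methylation
#' beta matrix: every value must be numeric and lie in \[0, 1\], and both the
#' CpG and the sample identifiers must be unique.
#'
#' The delimiter is auto-detected from the file extension: `.csv` is read as
#' comma-separated, anything else (`.tsv`, `.txt`, ...) as tab-separated.
#'
#' @param path Path to a delimited text file.
#' @return A numeric matrix with CpG identifiers as row names and sample
#'   identifiers as column names, in file order.
#' @seealso [write_beta_matrix()], [read_reference_library()]
#' @export
read_beta_matrix <- function(path) {
  x <- read_matrix_file(path)
  validate_beta_matrix(x, what = "beta matrix")
  x
}

#' Read a CpG x cell-type reference library
#'
#' Same file layout as [read_beta_matrix()] with cell-type names in the
#' header; requires at least two cell types.
#'
#' @inheritParams read_beta_matrix
#' @return A numeric matrix of mean reference betas, cell types as columns.
#' @export
read_reference_library <- function(path) {
  x <- read_matrix_file(path)
  validate_reference_library(x)
  x
}

#' Write a beta or M-value matrix to delimited text
#'
#' Values are written at 10 significant digits; comma- or tab-delimited by
#' extension as in [read_beta_matrix()].
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  sep <- delim_for(path)
  df <- data.frame(cpg_id = rownames(x),
                   signif(x, 10),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' One row per sample. If `betas` is supplied, sample identifiers must match
#' its columns.
#'
#' @param path Delimited text file with a `sample_id` column.
#' @param betas Optional beta matrix to check sample identifiers against.
#' @return A data frame, one row per sample.
#' @export
read_sample_metadata <- function(path, betas = NULL) {
  sep <- delim_for(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df))
    stop("metadata file must contain a 'sample_id' column")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!is.null(betas) && !setequal(df$sample_id, colnames(betas)))
    stop("metadata sample_ids do not match the beta matrix columns")
  df
}

#' Read a per-CpG annotation table
#'
#' Expects columns `cpg_id`, and any of `chromosome`, `island_context`
#' (Island/Shore/Shelf/OpenSea), `probe_type` (I/II), `genomic_context`
#' (Promoter/5'UTR/3'UTR/Exon/Intron/Intergenic). Category labels outside the
#' closed vocabularies are rejected.
#'
#' @param path Delimited text file.
#' @return A data frame, one row per CpG.
#' @export
read_annotation <- function(path) {
  sep <- delim_for(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_annotation(df)
  df
}

#' Read a TFBS long table (feature, cpg_id) into a named list of CpG sets
#'
#' @param path Two-column delimited text file with columns `feature` and
#'   `cpg_id`.
#' @return Named list mapping feature name to a character vector of CpG ids.
#' @export
read_tfbs_sets <- function(path) {
  sep <- delim_for(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("feature", "cpg_id") %in% names(df)))
    stop("TFBS file must have columns 'feature' and 'cpg_id'")
  lapply(split(df$cpg_id, df$feature), unique)
}

#' Convert beta values to M-values
#'
#' M = log2(beta / (1 - beta)), the log2 odds of methylation. Betas are first
#' clipped to \[`clip_eps`, 1 - `clip_eps`\] so the transform is finite at the
#' boundaries.
#'
#' @param b Numeric matrix or vector of betas in \[0, 1\].
#' @param clip_eps Clipping margin in (0, 0.5); default `1e-6`.
#' @return M-values with the same shape and dimnames as `b`.
#' @export
beta_to_m <- function(b, clip_eps = 1e-6) {
  stopifnot(is.numeric(clip_eps), length(clip_eps) == 1,
            clip_eps > 0, clip_eps < 0.5)
  b <- pmin(pmax(b, clip_eps), 1 - clip_eps)
  log2(b / (1 - b))
}

#' Convert M-values back to beta values
#'
#' beta = 2^M / (1 + 2^M); the exact inverse of [beta_to_m()] away from the
#' clip boundary.
#'
#' @param m Numeric matrix or vector of finite M-values.
#' @return Betas in (0, 1) with the same shape and dimnames as `m`.
#' @export
m_to_beta <- function(m) {
  # 1/(1+2^-M) is stable for large |M| where 2^M overflows
  1 / (1 + 2^(-m))
}

#' Restrict two CpG-indexed matrices to their common CpGs
#'
#' Both inputs are subset to the intersection of their CpG identifiers, in
#' the order the intersection occurs in `a`.
#'
#' @param a,b Matrices with CpG identifiers as row names.
#' @return List with elements `a`, `b` (the aligned matrices) and
#'   `n_common` (intersection size).
#' @export
align_cpgs <- function(a, b) {
  common <- intersect(rownames(a), rownames(b))
  if (length(common) == 0) stop("no CpGs in common between the two matrices")
  list(a = a[common, , drop = FALSE],
       b = b[common, , drop = FALSE],
       n_common = length(common))
}

## ---- internal helpers -----------------------------------------------------

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_matrix_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- delim_for(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  if (ncol(df) < 2) stop("expected an id column plus at least one data column")
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (is.logical(vals[[j]]) && all(is.na(vals[[j]])))
      vals[[j]] <- as.numeric(vals[[j]])  # empty cells only: defer to NA check
    if (!is.numeric(vals[[j]]))
      stop("non-numeric value in column '", names(vals)[j], "' of ", path)
  }
  x <- as.matrix(vals)
  rownames(x) <- ids
  x
}

validate_beta_matrix <- function(x, what = "beta matrix") {
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop(what, ": missing value at CpG '", rownames(x)[bad[1]],
         "', sample '", colnames(x)[bad[2]], "'")
  }
  out <- which(x < 0 | x > 1, arr.ind = TRUE)
  if (nrow(out) > 0) {
    stop(what, ": value ", format(x[out[1, 1], out[1, 2]]),
         " outside [0,1] at CpG '", rownames(x)[out[1, 1]],
         "', column '", colnames(x)[out[1, 2]], "'")
  }
  if (anyDuplicated(rownames(x)))
    stop(what, ": duplicate CpG id '",
         rownames(x)[duplicated(rownames(x))][1], "'")
  if (anyDuplicated(colnames(x)))
    stop(what, ": duplicate column id '",
         colnames(x)[duplicated(colnames(x))][1], "'")
  invisible(x)
}

validate_reference_library <- function(x) {
  validate_beta_matrix(x, what = "reference library")
  if (ncol(x) < 2) stop("reference library needs at least 2 cell types")
  invisible(x)
}

.island_levels  <- c("Island", "Shore", "Shelf", "OpenSea")
.context_levels <- c("Promoter", "5'UTR", "3'UTR", "Exon", "Intron", "Intergenic")

validate_annotation <- function(df) {
  if (!"cpg_id" %in% names(df)) stop("annotation must contain 'cpg_id'")
  if (anyDuplicated(df$cpg_id)) stop("annotation has duplicated cpg_id rows")
  chk <- function(col, levels) {
    if (col %in% names(df)) {
      bad <- setdiff(unique(df[[col]]), levels)
      if (length(bad) > 0)
        stop("annotation column '", col, "' has unknown label(s): ",
             paste(bad, collapse = ", "))
    }
  }
  chk("island_context", .island_levels)
  chk("probe_type", c("I", "II"))
  chk("genomic_context", .context_levels)
  invisible(df)
}
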