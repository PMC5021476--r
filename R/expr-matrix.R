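#' Expression matrix as a tidy tibble
#'
#' `mirlink` stores expression data (miRNA-isoform RPM or gene-level
#' normalized counts) in a tibble whose first column is `feature_id` and whose
#' remaining columns are one numeric column per sample. The object carries a
#' `scale` attribute, either `"linear"` (non-negative RPM / counts) or
#' `"log2"` (after [log2_transform()]). All pipeline verbs
#' ([prevalence_filter()], [quantile_normalize()], [log2_transform()],
#' [remove_batch_effect()], ...) take and return this shape, so stages chain
#' with the pipe.
#'
#' @param x A data frame with a `feature_id` character column and numeric
#'   sample columns, or a numeric matrix with rownames (features) and
#'   colnames (samples).
#' @param scale Value scale, `"linear"` or `"log2"`.
#' @return A tibble of class `expr_matrix`.
#' @examples
#' m <- as_expr_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("f1", "f2"), c("s1", "s2", "s3"))))
#' expr_scale(m)
#' @export
as_expr_matrix <- function(x, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      stop("matrix input needs rownames (features) and colnames (samples)",
           call. = FALSE)
    }
    tbl <- tibble::as_tibble(x, rownames = "feature_id")
  } else if (is.data.frame(x)) {
    if (!"feature_id" %in% names(x)) {
      stop("data frame input needs a `feature_id` column", call. = FALSE)
    }
    tbl <- tibble::as_tibble(x)
    tbl <- dplyr::relocate(tbl, "feature_id")
  } else {
    stop("`x` must be a matrix or data frame", call. = FALSE)
  }
  tbl$feature_id <- as.character(tbl$feature_id)
  out <- structure(tbl, scale = scale,
                   class = c("expr_matrix", class(tbl)))
  validate_expr_matrix(out)
  out
}

#' @rdname as_expr_matrix
#' @export
expr_scale <- function(x) attr(x, "scale") %||% "linear"

#' @rdname as_expr_matrix
#' @export
feature_ids <- function(x) x$feature_id

#' @rdname as_expr_matrix
#' @export
sample_ids <- function(x) setdiff(names(x), "feature_id")

#' Extract the numeric value grid of an `expr_matrix`
#'
#' @param x An `expr_matrix`.
#' @return A numeric matrix, features in rows, samples in columns.
#' @export
expr_values <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), "feature_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$feature_id
  m
}

validate_expr_matrix <- function(x) {
  ids <- x$feature_id
  if (anyDuplicated(ids)) stop("duplicate feature IDs", call. = FALSE)
  sids <- sample_ids(x)
  if (anyDuplicated(sids)) stop("duplicate sample IDs", call. = FALSE)
  if (length(sids) == 0L) stop("expression matrix has no samples", call. = FALSE)
  v <- expr_values(x)
  if (!is.numeric(v)) stop("sample columns must be numeric", call. = FALSE)
  if (identical(expr_scale(x), "linear") && any(v < 0, na.rm = TRUE)) {
    stop("negative values are not allowed on the linear scale", call. = FALSE)
  }
  invisible(x)
}

# rebuild an expr_matrix from a value grid, keeping/overriding the scale tag
rebuild_expr <- function(values, scale) {
  as_expr_matrix(values, scale = scale)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("# expr_matrix: %d features x %d samples [%s scale]\n",
              nrow(x), length(sample_ids(x)), expr_scale(x)))
  NextMethod()
}

#' Read / write an expression matrix as TSV
#'
#' The TSV has a header row, a `feature_id` first column and one column per
#' sample; values round-trip bit-exactly.
#'
#' @param x An `expr_matrix`.
#' @param path File path.
#' @param scale Scale tag to attach on read (`"linear"` or `"log2"`).
#' @return `write_expr_tsv()` returns `x` invisibly; `read_expr_tsv()`
#'   returns an `expr_matrix`.
#' @export
write_expr_tsv <- function(x, path) {
  tbl <- tibble::as_tibble(x)
  # 17 significant digits guarantee exact double round-trip
  for (j in setdiff(names(tbl), "feature_id")) {
    tbl[[j]] <- sprintf("%.17g", tbl[[j]])
  }
  readr::write_tsv(tbl, path)
  invisible(x)
}

#' @rdname write_expr_tsv
#' @export
read_expr_tsv <- function(path, scale = c("linear", "log2")) {
  # values are read as text and converted with strtod so the 17-digit
  # representation written by write_expr_tsv() round-trips bit-exactly
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  for (j in setdiff(names(tbl), "feature_id")) {
    tbl[[j]] <- as.numeric(tbl[[j]])
  }
  as_expr_matrix(tbl, scale = match.arg(scale))
}

#' Sample annotation table
#'
#' One row per sample with its histotype group and batch label. Groups follow
#' the papillary-thyroid-carcinoma histotype vocabulary used throughout the
#' package: `cPTC` (classical), `fvPTC` (follicular variant), `tcPTC`
#' (tall-cell variant) and `other`.
#'
#' @param x A data frame with columns `sample_id`, `group`, `batch`.
#' @return A tibble with character `sample_id`/`batch` and factor `group`.
#' @export
as_sample_annotation <- function(x) {
  need <- c("sample_id", "group", "batch")
  if (!all(need %in% names(x))) {
    stop("annotation needs columns sample_id, group, batch", call. = FALSE)
  }
  tbl <- tibble::as_tibble(x)[, need]
  tbl$sample_id <- as.character(tbl$sample_id)
  tbl$group <- as.character(tbl$group)
  tbl$batch <- as.character(tbl$batch)
  bad <- setdiff(unique(tbl$group), c("cPTC", "fvPTC", "tcPTC", "other"))
  if (length(bad)) {
    stop("unknown histotype group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tbl$sample_id)) stop("duplicate sample IDs", call. = FALSE)
  if (any(!nzchar(tbl$group)) || any(!nzchar(tbl$batch)) ||
      any(is.na(tbl$group)) || any(is.na(tbl$batch))) {
    stop("group and batch must be non-empty for every sample", call. = FALSE)
  }
  tbl
}

#' @rdname as_sample_annotation
#' @param path TSV path with a header row.
#' @export
read_sample_annotation <- function(path) {
  as_sample_annotation(readr::read_tsv(path, show_col_types = FALSE,
                                       progress = FALSE))
}

# annotation rows for the samples of an expr_matrix, in column order
annot_for <- function(x, annot) {
  sids <- sample_ids(x)
  miss <- setdiff(sids, annot$sample_id)
  if (length(miss)) {
    stop("samples missing from annotation: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  annot[match(sids, annot$sample_id), ]
}
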