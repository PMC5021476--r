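#' Prevalence filter: keep features detected in at least half the samples
#'
#' "Detected" means a strictly positive value. With `n` samples a feature is
#' kept when it is detected in at least `ceiling(n / 2)` of them. This is the
#' standard first step against low-abundance isoforms/genes dominating
#' downstream statistics.
#'
#' @param m An `expr_matrix` on the linear scale.
#' @param min_fraction Minimum detected fraction (default 0.5).
#' @return The filtered `expr_matrix`, feature order preserved.
#' @export
prevalence_filter <- function(m, min_fraction = 0.5) {
  stopifnot(inherits(m, "expr_matrix"))
  if (expr_scale(m) != "linear") {
    stop("prevalence_filter() expects linear-scale data", call. = FALSE)
  }
  v <- expr_values(m)
  if (nrow(v) == 0L) stop("empty expression matrix", call. = FALSE)
  need <- ceiling(ncol(v) * min_fraction)
  keep <- rowSums(v > 0) >= need
  out <- m[keep, , drop = FALSE]
  as_expr_matrix(tibble::as_tibble(out), scale = "linear")
}

#' Quantile normalization across samples
#'
#' Forces every sample (column) to share the same empirical distribution:
#' after normalization each column's sorted values equal the cross-column
#' mean of sorted values, with ties receiving the mean of their destination
#' quantiles. Delegates to `limma::normalizeQuantiles(ties = TRUE)`.
#'
#' @param m An `expr_matrix` on the linear scale with at least 2 samples.
#' @return The normalized `expr_matrix` (still tagged linear).
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (expr_scale(m) != "linear") {
    stop("quantile_normalize() expects linear-scale data", call. = FALSE)
  }
  v <- expr_values(m)
  if (ncol(v) < 2L) {
    warning("single sample: quantile normalization is a no-op", call. = FALSE)
    return(m)
  }
  vn <- limma::normalizeQuantiles(v, ties = TRUE)
  dimnames(vn) <- dimnames(v)
  rebuild_expr(vn, scale = "linear")
}

#' Log2 transform with pseudocount
#'
#' `x -> log2(x + offset)`. The default offset of 1 keeps undetected (zero)
#' values at 0 on the log scale.
#'
#' @param m An `expr_matrix` on the linear scale.
#' @param offset Non-negative pseudocount (default 1).
#' @return The `expr_matrix` tagged `log2`.
#' @export
log2_transform <- function(m, offset = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (expr_scale(m) != "linear") {
    stop("log2_transform() expects linear-scale data", call. = FALSE)
  }
  if (offset < 0) stop("offset must be >= 0", call. = FALSE)
  v <- expr_values(m)
  if (any(v + offset <= 0)) {
    stop("value + offset <= 0: log2 undefined", call. = FALSE)
  }
  rebuild_expr(log2(v + offset), scale = "log2")
}

#' Remove batch effects by per-batch mean centering
#'
#' For every feature, the mean over each batch's samples is subtracted from
#' that batch's samples, so per-batch per-feature means of the output are 0.
#' This is plain mean centering, not a model-based correction; it is exact
#' for additive per-batch per-feature offsets and idempotent.
#'
#' @param m An `expr_matrix` on the log2 scale.
#' @param annot Sample annotation ([as_sample_annotation()]) covering every
#'   sample; a sample without a batch label is an error.
#' @return The batch-centered `expr_matrix`.
#' @export
remove_batch_effect <- function(m, annot) {
  stopifnot(inherits(m, "expr_matrix"))
  if (expr_scale(m) != "log2") {
    stop("remove_batch_effect() expects log2-scale data", call. = FALSE)
  }
  ann <- annot_for(m, annot)
  v <- expr_values(m)
  for (b in unique(ann$batch)) {
    idx <- which(ann$batch == b)
    if (length(idx) == 0L) next
    mu <- rowMeans(v[, idx, drop = FALSE])
    v[, idx] <- v[, idx, drop = FALSE] - mu
  }
  rebuild_expr(v, scale = "log2")
}

#' PCA quality-control scores
#'
#' Principal components of the feature-centered matrix with samples as
#' observations and features as variables (no unit-variance scaling). Sign
#' convention: each component is flipped so its largest-magnitude loading is
#' positive, making scores deterministic. Used to visualize batch structure
#' before/after [remove_batch_effect()].
#'
#' @param m An `expr_matrix` on the log2 scale with at least 3 samples.
#' @param annot Sample annotation.
#' @param n_pcs Number of components to return (default 2).
#' @return A tibble `(sample_id, PC1, PC2, ..., group, batch)` of class
#'   `mirlink_pca` with a `var_explained` attribute.
#' @export
pca_qc <- function(m, annot, n_pcs = 2) {
  stopifnot(inherits(m, "expr_matrix"))
  if (expr_scale(m) != "log2") {
    stop("pca_qc() expects log2-scale data", call. = FALSE)
  }
  v <- expr_values(m)
  if (ncol(v) < 3L) stop("PCA QC needs at least 3 samples", call. = FALSE)
  x <- t(v)  # samples x features
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  # deterministic sign: largest-|loading| positive
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ann <- annot_for(m, annot)
  scores <- tibble::as_tibble(pc$x[, seq_len(n_pcs), drop = FALSE])
  out <- dplyr::bind_cols(tibble::tibble(sample_id = sample_ids(m)), scores,
                          ann[, c("group", "batch")])
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(out, var_explained = ve[seq_len(n_pcs)],
            class = c("mirlink_pca", class(out)))
}

#' Mean silhouette of a labelling on PCA scores
#'
#' Average silhouette width of the given labels in (PC1, PC2) space; the
#' batch-QC statistic: planted batch structure raises it, successful batch
#' removal lowers it.
#'
#' @param pca A [pca_qc()] result.
#' @param label Column to evaluate, `"batch"` or `"group"`.
#' @return Mean silhouette width (single number).
#' @export
pca_silhouette <- function(pca, label = c("batch", "group")) {
  label <- match.arg(label)
  lab <- as.integer(factor(pca[[label]]))
  if (length(unique(lab)) < 2L) {
    stop("silhouette needs at least 2 distinct labels", call. = FALSE)
  }
  d <- stats::dist(as.matrix(pca[, c("PC1", "PC2")]))
  mean(cluster::silhouette(lab, d)[, "sil_width"])
}

#' Run the full preprocessing chain
#'
#' Fixed order: [prevalence_filter()] then [quantile_normalize()] then
#' [log2_transform()] then [remove_batch_effect()]. An alternative order
#' placing the log transform before normalization is exposed via `order =
#' "log_then_normalize"` for cohorts processed that way.
#'
#' @param m Linear-scale `expr_matrix`.
#' @param annot Sample annotation.
#' @param order `"normalize_then_log"` (default) or `"log_then_normalize"`.
#' @param log_offset Pseudocount for [log2_transform()].
#' @param min_fraction Detection fraction for [prevalence_filter()].
#' @return A log2-scale, batch-centered `expr_matrix`.
#' @export
preprocess_pipeline <- function(m, annot,
                                order = c("normalize_then_log",
                                          "log_then_normalize"),
                                log_offset = 1, min_fraction = 0.5) {
  order <- match.arg(order)
  m <- prevalence_filter(m, min_fraction = min_fraction)
  if (order == "normalize_then_log") {
    m <- quantile_normalize(m)
    m <- log2_transform(m, offset = log_offset)
  } else {
    # run the log transform first, then renormalize on the linear scale of
    # the transformed values: implemented as QN of 2^log2(x+offset) would be
    # circular, so here QN is applied to the log values directly
    m <- log2_transform(m, offset = log_offset)
    v <- expr_values(m)
    vn <- limma::normalizeQuantiles(v, ties = TRUE)
    dimnames(vn) <- dimnames(v)
    m <- rebuild_expr(vn, scale = "log2")
  }
  remove_batch_effect(m, annot)
}
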