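#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation with average ranks for ties. The two-sided p-value uses
#' the t approximation `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom — the only tractable choice when tens of millions of
#' pairs are screened. `r = +/-1` gives `p = 0`; a constant input gives an
#' `NA` record (flagged, not an error).
#'
#' @param x,y Numeric vectors of equal length `>= 4`.
#' @return A list with `r` and `p_value`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 4L) {
    stop("spearman_cor() needs equal lengths >= 4", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(r = NA_real_, p_value = NA_real_))
  }
  r <- stats::cor(rx, ry)
  list(r = r, p_value = spearman_p(r, n))
}

spearman_p <- function(r, n) {
  p <- rep(NA_real_, length(r))
  edge <- !is.na(r) & abs(r) >= 1
  p[edge] <- 0
  mid <- !is.na(r) & abs(r) < 1
  tt <- r[mid] * sqrt((n - 2) / (1 - r[mid]^2))
  p[mid] <- 2 * stats::pt(-abs(tt), df = n - 2)
  p
}

#' All-pairs Spearman screen within one histotype group
#'
#' Computes the Spearman correlation and t-approximation p-value for every
#' (miRNA feature, gene feature) pair over the samples of one group. Ranks
#' are computed once per feature and standardized; correlations are then
#' chunked matrix products, so peak additional memory is
#' O(chunk_size x n_genes) and results are identical to pairwise
#' [spearman_cor()]. Constant features yield `NA` records; these are
#' excluded from the FDR family downstream.
#'
#' @param mirna,mrna Preprocessed `expr_matrix` objects sharing the same
#'   sample set.
#' @param annot Sample annotation.
#' @param group Histotype group to screen (needs >= 4 samples).
#' @param chunk_size miRNA features per chunk (default 256).
#' @return A tibble of class `mirlink_screen` with columns `mirna_id`,
#'   `gene_id`, `group`, `r`, `p_value`; exactly
#'   `n_mirna * n_gene` rows.
#' @export
all_pairs_screen <- function(mirna, mrna, annot, group, chunk_size = 256) {
  stopifnot(inherits(mirna, "expr_matrix"), inherits(mrna, "expr_matrix"))
  if (!setequal(sample_ids(mirna), sample_ids(mrna))) {
    stop("miRNA and mRNA matrices cover different sample sets", call. = FALSE)
  }
  ann <- annot_for(mirna, annot)
  sel <- sample_ids(mirna)[ann$group == group]
  n <- length(sel)
  if (n < 4L) stop("group '", group, "' has fewer than 4 samples",
                   call. = FALSE)
  vm <- expr_values(mirna)[, sel, drop = FALSE]
  vg <- expr_values(mrna)[, sel, drop = FALSE]
  rm_ <- standardized_ranks(vm)
  rg <- standardized_ranks(vg)
  n_mir <- nrow(vm)
  n_gene <- nrow(vg)
  chunks <- split(seq_len(n_mir),
                  ceiling(seq_len(n_mir) / max(1L, chunk_size)))
  pieces <- purrr::map(chunks, function(idx) {
    rr <- tcrossprod(rm_[idx, , drop = FALSE], rg) / (n - 1)
    # clip tiny numeric excursions beyond [-1, 1]
    rr[rr > 1] <- 1
    rr[rr < -1] <- -1
    tibble::tibble(
      mirna_id = rep(rownames(vm)[idx], each = n_gene),
      gene_id = rep(rownames(vg), times = length(idx)),
      r = as.vector(t(rr))
    )
  })
  out <- dplyr::bind_rows(pieces)
  out$group <- group
  out$p_value <- spearman_p(out$r, n)
  out <- out[, c("mirna_id", "gene_id", "group", "r", "p_value")]
  structure(out, n_samples = n,
            class = c("mirlink_screen", class(out)))
}

# per-row average ranks, centered and scaled to unit variance;
# constant rows become NA rows (propagate to NA correlations)
standardized_ranks <- function(v) {
  r <- t(apply(v, 1L, rank))
  if (nrow(v) == 1L) r <- matrix(rank(v[1L, ]), nrow = 1L)
  mu <- rowMeans(r)
  s <- sqrt(apply(r, 1L, stats::var))
  s[s == 0] <- NA_real_
  (r - mu) / s
}

#' BH adjustment and inverse-correlation filter
#'
#' Adjusts the screen's p-values with Benjamini-Hochberg over all non-NA
#' pairs of the group (the FDR family is the full pair grid of that group),
#' then keeps pairs with `r < threshold` (strict), sorted by `r` ascending.
#'
#' @param records A [all_pairs_screen()] result (one group).
#' @param threshold Inverse-correlation cutoff, must be negative
#'   (default -0.6).
#' @return Filtered records with an `fdr` column, class `mirlink_screen`.
#' @export
fdr_and_filter <- function(records, threshold = -0.6) {
  if (threshold >= 0) {
    stop("threshold must be negative: the screen keeps inverse correlations",
         call. = FALSE)
  }
  ok <- !is.na(records$r)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(n_dropped, " constant-feature pair(s) excluded from FDR family")
  }
  fdr <- rep(NA_real_, nrow(records))
  fdr[ok] <- bh_fdr(records$p_value[ok])
  records$fdr <- fdr
  out <- records[ok & records$r < threshold, , drop = FALSE]
  out <- dplyr::arrange(out, .data$r, .data$mirna_id, .data$gene_id)
  structure(out, n_samples = attr(records, "n_samples"),
            n_family = sum(ok),
            class = unique(c("mirlink_screen", class(out))))
}

#' Group-specific strict correlation thresholds
#'
#' Applies the tighter per-group cutoffs used before the final confirmation
#' stage: by default r < -0.65 for cPTC, < -0.70 for fvPTC, < -0.80 for
#' tcPTC (strict inequalities). The smaller the group, the stricter the
#' cutoff, compensating the higher variance of rank correlations at small n.
#'
#' @param records Filtered records from [fdr_and_filter()].
#' @param thresholds Named numeric vector of per-group cutoffs.
#' @return The records passing their group's strict threshold.
#' @export
strict_threshold <- function(records,
                             thresholds = c(cPTC = -0.65, fvPTC = -0.70,
                                            tcPTC = -0.80)) {
  grp <- unique(records$group)
  unknown <- setdiff(grp, names(thresholds))
  if (length(unknown)) {
    stop("no strict threshold for group(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- records$r < unname(thresholds[records$group])
  out <- records[keep, , drop = FALSE]
  structure(out, n_samples = attr(records, "n_samples"),
            class = unique(c("mirlink_screen", class(out))))
}

#' @export
glance.mirlink_screen <- function(x, ...) {
  tibble::tibble(
    group = if (nrow(x)) x$group[1] else NA_character_,
    n_pairs = nrow(x),
    n_samples = attr(x, "n_samples") %||% NA_integer_,
    min_r = if (nrow(x)) min(x$r, na.rm = TRUE) else NA_real_
  )
}

#' @export
tidy.mirlink_screen <- function(x, ...) tibble::as_tibble(x)
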