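#' Median-based fold change
#'
#' Ratio of group medians, `(median(x1) + eps) / (median(x2) + eps)`, with a
#' small pseudocount `eps` guarding zero medians. The median makes the fold
#' change robust to outliers: any single above-median value can grow without
#' bound without changing the statistic. Inputs are expected on the linear
#' scale; significance bounds used downstream are > 1.25 (up) or < 0.8
#' (down) relative to group 1.
#'
#' @param x1,x2 Numeric vectors of linear-scale expression, one per group.
#' @param eps Pseudocount (default 1e-9).
#' @return The fold change (dimensionless ratio).
#' @export
median_fold_change <- function(x1, x2, eps = 1e-9) {
  if (length(x1) == 0L || length(x2) == 0L) {
    stop("median_fold_change() needs at least one value per group",
         call. = FALSE)
  }
  (stats::median(x1) + eps) / (stats::median(x2) + eps)
}

#' Variance filter: drop the least-variable quarter of features
#'
#' Keeps features whose sample variance is strictly greater than the first
#' quartile (linear-interpolation quantile) of the per-feature variance
#' distribution. If all variances are equal the strict rule would drop
#' everything, so in that degenerate case all features are kept.
#'
#' @param m An `expr_matrix` with at least 4 features.
#' @return The filtered `expr_matrix`.
#' @export
variance_filter <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- expr_values(m)
  if (nrow(v) < 4L) stop("variance_filter() needs >= 4 features", call. = FALSE)
  vars <- apply(v, 1L, stats::var)
  q1 <- stats::quantile(vars, 0.25, type = 7, names = FALSE)
  keep <- vars > q1
  if (!any(keep)) keep <- rep(TRUE, length(vars))  # all variances equal
  out <- m[keep, , drop = FALSE]
  as_expr_matrix(tibble::as_tibble(out), scale = expr_scale(m))
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test (Welch-Satterthwaite degrees of
#' freedom), via [stats::t.test()]. Degenerate inputs (zero variance in both
#' groups) return `t = 0, p = 1` for equal means and `p = 0` flagged
#' degenerate for unequal means.
#'
#' @param x1,x2 Numeric vectors with at least 2 values each.
#' @param var_equal Use the pooled-variance test instead (default FALSE).
#' @return A list with `t_stat`, `p_value`, `degenerate`.
#' @export
welch_t_test <- function(x1, x2, var_equal = FALSE) {
  if (length(x1) < 2L || length(x2) < 2L) {
    stop("welch_t_test() needs >= 2 values per group", call. = FALSE)
  }
  if (stats::var(x1) == 0 && stats::var(x2) == 0) {
    if (mean(x1) == mean(x2)) {
      return(list(t_stat = 0, p_value = 1, degenerate = FALSE))
    }
    return(list(t_stat = sign(mean(x1) - mean(x2)) * Inf, p_value = 0,
                degenerate = TRUE))
  }
  tt <- stats::t.test(x1, x2, var.equal = var_equal)
  list(t_stat = unname(tt$statistic), p_value = tt$p.value,
       degenerate = FALSE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusted values in input order. By default the family size is the number
#' of p-values supplied; `m_total` overrides it with a larger total-feature
#' count (the stricter convention of adjusting with reference to the full
#' platform feature set).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m_total Optional family size `>= length(p)`.
#' @return Adjusted values, same order as `p`.
#' @export
bh_fdr <- function(p, m_total = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  n <- if (is.null(m_total)) length(p) else m_total
  if (n < length(p)) stop("m_total must be >= length(p)", call. = FALSE)
  stats::p.adjust(p, method = "BH", n = n)
}

#' Differential expression table between two histotype groups
#'
#' Applies [variance_filter()] first, then per surviving feature computes
#' the median-based fold change on back-transformed linear values
#' (`pmax(2^x - back_offset, 0)`), a Welch t-test on the log2 values, and a
#' BH-adjusted FDR across the surviving features (or across `m_total`
#' features when given). A feature is called significant when
#' `fdr < fdr_cut` and the fold change is outside `[mbfc_lo, mbfc_hi]`
#' (defaults 0.8 / 1.25).
#'
#' @param m Preprocessed (log2-scale) `expr_matrix`.
#' @param annot Sample annotation.
#' @param group1,group2 Histotype groups to contrast (direction is relative
#'   to `group1`).
#' @param fdr_cut FDR significance cutoff (default 0.05).
#' @param mbfc_hi,mbfc_lo Fold-change significance bounds (default 1.25, 0.8).
#' @param m_total Optional FDR family-size override (see [bh_fdr()]).
#' @param back_offset Pseudocount used at the log2 step, removed before
#'   computing fold changes (default 1).
#' @param var_equal Pooled-variance t-test instead of Welch (default FALSE).
#' @return A tibble of class `mirlink_de` with columns `feature_id`, `mbfc`,
#'   `t_stat`, `p_value`, `fdr`, `significant`, `direction`, sorted by FDR
#'   ascending.
#' @export
differential_table <- function(m, annot, group1, group2,
                               fdr_cut = 0.05, mbfc_hi = 1.25, mbfc_lo = 0.8,
                               m_total = NULL, back_offset = 1,
                               var_equal = FALSE) {
  stopifnot(inherits(m, "expr_matrix"))
  ann <- annot_for(m, annot)
  i1 <- which(ann$group == group1)
  i2 <- which(ann$group == group2)
  if (length(i1) < 2L || length(i2) < 2L) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  mf <- variance_filter(m)
  v <- expr_values(mf)
  lin <- pmax(2^v - back_offset, 0)
  res <- purrr::map(seq_len(nrow(v)), function(i) {
    tt <- welch_t_test(v[i, i1], v[i, i2], var_equal = var_equal)
    tibble::tibble(
      feature_id = rownames(v)[i],
      mbfc = median_fold_change(lin[i, i1], lin[i, i2]),
      t_stat = tt$t_stat, p_value = tt$p_value
    )
  })
  out <- dplyr::bind_rows(res)
  out$fdr <- bh_fdr(out$p_value, m_total = m_total)
  out$significant <- out$fdr < fdr_cut &
    (out$mbfc > mbfc_hi | out$mbfc < mbfc_lo)
  out$direction <- ifelse(out$mbfc >= 1, "up", "down")
  out <- dplyr::arrange(out, .data$fdr, .data$p_value, .data$feature_id)
  structure(out,
            groups = c(group1, group2),
            n_samples = c(length(i1), length(i2)),
            thresholds = c(fdr = fdr_cut, mbfc_hi = mbfc_hi,
                           mbfc_lo = mbfc_lo),
            class = c("mirlink_de", class(out)))
}

#' Select the top differential markers
#'
#' Among significant records, the `k` lowest-FDR features; ties broken by
#' `|log2(mbfc)|` descending, then feature ID. With fewer than `k`
#' significant features all of them are returned with a warning.
#'
#' @param records A [differential_table()] result.
#' @param k Panel size (default 8).
#' @return Character vector of feature IDs.
#' @export
select_top_markers <- function(records, k = 8) {
  sig <- dplyr::filter(records, .data$significant)
  if (nrow(sig) < k) {
    warning(sprintf("only %d significant features (requested %d)",
                    nrow(sig), k), call. = FALSE)
    k <- nrow(sig)
  }
  sig |>
    dplyr::arrange(.data$fdr, dplyr::desc(abs(log2(.data$mbfc))),
                   .data$feature_id) |>
    utils::head(k) |>
    dplyr::pull("feature_id")
}

#' @export
tidy.mirlink_de <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.mirlink_de <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble::tibble(
    group1 = attr(x, "groups")[1], group2 = attr(x, "groups")[2],
    n1 = attr(x, "n_samples")[1], n2 = attr(x, "n_samples")[2],
    n_features = nrow(x), n_significant = sum(x$significant),
    fdr_cut = th[["fdr"]], mbfc_hi = th[["mbfc_hi"]],
    mbfc_lo = th[["mbfc_lo"]]
  )
}
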