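# Sequence utilities. miRNA position 1 = 5' terminus; the seed is
# positions 2-8. T is accepted on input and normalized to U.

norm_rna <- function(seq) {
  s <- toupper(chartr("T", "U", seq))
  if (any(grepl("[^ACGU]", s))) {
    stop("non-RNA characters in sequence", call. = FALSE)
  }
  s
}

revcomp_rna <- function(seq) {
  sapply(strsplit(chartr("ACGU", "UGCA", seq), ""), function(x) {
    paste(rev(x), collapse = "")
  }, USE.NAMES = FALSE)
}

comp_base <- function(b) chartr("ACGU", "UGCA", b)

#' Detect canonical seed-match sites in transcript regions
#'
#' Scans each region 5' to 3' for the four canonical site classes defined by
#' complementarity to the miRNA seed (positions 2-8 from the 5' end):
#' * `6mer` — reverse complement of miRNA positions 2-7;
#' * `7mer-m8` — reverse complement of positions 2-8;
#' * `7mer-A1` — the 6mer followed by an `A` in the mRNA (opposite
#'   position 1);
#' * `8mer` — the 7mer-m8 followed by an `A`.
#'
#' Each match location is reported once, under its most specific class
#' (`8mer > 7mer-m8 > 7mer-A1 > 6mer`). `start` is the 1-based position in
#' the region where the site (including the m8 base, when present) begins.
#'
#' @param mirna A single mature miRNA sequence (character, length >= 8 nt).
#' @param regions A tibble with columns `gene_id`, `utr5`, `cds`, `utr3`
#'   (empty strings for absent regions), e.g. from [read_region_fasta()].
#' @return A tibble with columns `gene_id`, `region`, `start`, `site_type`.
#' @export
find_seed_sites <- function(mirna, regions) {
  if (length(mirna) != 1L || is.na(mirna) || nchar(mirna) == 0L) {
    stop("`mirna` must be a single non-empty sequence", call. = FALSE)
  }
  mir <- norm_rna(mirna)
  if (nchar(mir) < 8L) stop("miRNA shorter than 8 nt", call. = FALSE)
  core6 <- revcomp_rna(substr(mir, 2L, 7L))
  m8c <- comp_base(substr(mir, 8L, 8L))
  out <- purrr::map(c("utr5", "cds", "utr3"), function(rg) {
    s <- regions[[rg]]
    s[is.na(s)] <- ""
    s <- norm_rna(s)
    hits <- gregexpr(core6, s, fixed = TRUE)
    np <- vapply(hits, function(h) if (h[1] == -1L) 0L else length(h),
                 integer(1))
    if (sum(np) == 0L) return(NULL)
    gi <- rep(seq_along(s), np)
    p <- unlist(lapply(hits, function(h) {
      if (h[1] == -1L) integer() else as.integer(h)
    }), use.names = FALSE)
    str <- s[gi]
    has_m8 <- p > 1L & substr(str, p - 1L, p - 1L) == m8c
    has_a1 <- p + 6L <= nchar(str) & substr(str, p + 6L, p + 6L) == "A"
    type <- dplyr::case_when(
      has_m8 & has_a1 ~ "8mer",
      has_m8 ~ "7mer-m8",
      has_a1 ~ "7mer-A1",
      TRUE ~ "6mer"
    )
    tibble::tibble(
      gene_id = regions$gene_id[gi], region = rg,
      start = as.integer(ifelse(has_m8, p - 1L, p)),
      site_type = type
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble::tibble(gene_id = character(), region = character(),
                          start = integer(), site_type = character()))
  }
  dplyr::arrange(res, .data$gene_id, .data$region, .data$start)
}

site_span <- function(site_type) {
  c(`8mer` = 8L, `7mer-m8` = 7L, `7mer-A1` = 7L, `6mer` = 6L)[site_type]
}

#' Duplex alignment score for a miRNA against an mRNA window
#'
#' Best local antiparallel duplex alignment of the miRNA (5' to 3') against
#' the window, scored per base pair: Watson-Crick +5, G:U wobble +1,
#' mismatch -3; gaps cost 8 to open and 2 per additional position.
#' Pair/mismatch contributions at miRNA seed positions 2-8 are doubled.
#' Computed by affine-gap (Gotoh) dynamic programming over the window; the
#' score is invariant under extending the window with non-pairing flanks.
#'
#' @param mirna A single miRNA sequence.
#' @param window The mRNA window (5' to 3'), length >= miRNA length.
#' @param match,wobble,mismatch,gap_open,gap_extend Scoring constants.
#' @param seed_multiplier Factor applied to pair scores at miRNA
#'   positions 2-8 (default 2).
#' @return The maximal local alignment score (>= 0).
#' @export
miranda_like_score <- function(mirna, window, match = 5, wobble = 1,
                               mismatch = -3, gap_open = -8,
                               gap_extend = -2, seed_multiplier = 2) {
  mir <- strsplit(norm_rna(mirna), "")[[1]]
  win <- rev(strsplit(norm_rna(window), "")[[1]])  # window read 3' to 5'
  n <- length(mir)
  m <- length(win)
  if (m < n) stop("window shorter than miRNA", call. = FALSE)
  pair_score <- function(a, b, i) {
    s <- if ((a == "A" && b == "U") || (a == "U" && b == "A") ||
             (a == "G" && b == "C") || (a == "C" && b == "G")) {
      match
    } else if ((a == "G" && b == "U") || (a == "U" && b == "G")) {
      wobble
    } else {
      mismatch
    }
    if (i >= 2L && i <= 8L) s * seed_multiplier else s
  }
  neg <- -1e9
  M <- matrix(0, n + 1L, m + 1L)
  Ix <- matrix(neg, n + 1L, m + 1L)  # gap in window (miRNA base unpaired)
  Iy <- matrix(neg, n + 1L, m + 1L)  # gap in miRNA (window base unpaired)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- pair_score(mir[i], win[j], i)
      M[i + 1L, j + 1L] <- max(0,
        max(M[i, j], Ix[i, j], Iy[i, j]) + sc)
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] + gap_open,
                                Ix[i, j + 1L] + gap_extend)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] + gap_open,
                                Iy[i + 1L, j] + gap_extend)
      if (M[i + 1L, j + 1L] > best) best <- M[i + 1L, j + 1L]
    }
  }
  best
}

#' Run both sequence predictors on one miRNA-gene pair
#'
#' The seed-match (TargetScan-style) verdict is positive when any region
#' carries a site of class `8mer`, `7mer-m8` or `7mer-A1`. The
#' duplex-alignment (miRanda-style) verdict is positive when a window around
#' any site (of class 6mer or better) scores at least `min_score` under
#' [miranda_like_score()]; the window spans the site plus `nchar(mirna) + 5`
#' bases upstream (where the miRNA 3' region pairs) and 5 bases downstream.
#'
#' @param mirna A single miRNA sequence.
#' @param regions One-or-more-row region tibble for the gene(s) to test.
#' @param min_score Duplex-alignment threshold (default 140).
#' @return A list with `predicted_targetscan`, `predicted_miranda`, and the
#'   site tibble annotated with `alignment_score`.
#' @export
predict_pair <- function(mirna, regions, min_score = 140) {
  sites <- find_seed_sites(mirna, regions)
  ts <- any(sites$site_type %in% c("8mer", "7mer-m8", "7mer-A1"))
  if (nrow(sites) == 0L) {
    sites$alignment_score <- numeric()
    return(list(predicted_targetscan = FALSE, predicted_miranda = FALSE,
                sites = sites))
  }
  L <- nchar(norm_rna(mirna))
  scores <- purrr::map_dbl(seq_len(nrow(sites)), function(k) {
    s <- regions[[sites$region[k]]][match(sites$gene_id[k], regions$gene_id)]
    s <- norm_rna(s)
    if (nchar(s) < L) return(0)  # region too short to hold a duplex
    sp <- site_span(sites$site_type[k])
    from <- max(1L, sites$start[k] - (L + 5L))
    to <- min(nchar(s), sites$start[k] + sp - 1L + 5L)
    if (to - from + 1L < L) {  # site near a region edge: widen the window
      to <- min(nchar(s), from + L + 10L)
      from <- max(1L, to - (L + 10L))
    }
    miranda_like_score(mirna, substr(s, from, to))
  })
  sites$alignment_score <- scores
  list(predicted_targetscan = ts,
       predicted_miranda = any(scores >= min_score),
       sites = sites)
}

#' Seed-weighted target ranking over a transcriptome
#'
#' TargetRank-style scoring: per gene, the score is the sum over its 3'UTR
#' sites of a per-class weight (defaults 8mer = 1, 7mer-m8 = 0.75,
#' 7mer-A1 = 0.5, 6mer = 0.25). Genes are ranked per miRNA by score
#' descending (rank 1 = best, ties broken by gene ID); a gene is confirmed
#' when its rank is at most `rank_max` and its score at least `score_min`.
#' Genes without 3'UTR sites score 0 and carry no rank.
#'
#' @param mirna A single miRNA sequence.
#' @param regions Region tibble for the whole transcript set.
#' @param weights Named numeric site-class weights.
#' @param rank_max,score_min Confirmation cutoffs (defaults 100, 0.25).
#' @return A tibble `(gene_id, targetrank_score, targetrank_rank,
#'   targetrank_confirmed)` covering every gene in `regions`.
#' @export
targetrank_like <- function(mirna, regions,
                            weights = c(`8mer` = 1, `7mer-m8` = 0.75,
                                        `7mer-A1` = 0.5, `6mer` = 0.25),
                            rank_max = 100, score_min = 0.25) {
  if (nrow(regions) == 0L) stop("empty transcript set", call. = FALSE)
  sites <- find_seed_sites(mirna, regions)
  utr3 <- dplyr::filter(sites, .data$region == "utr3")
  per_gene <- utr3 |>
    dplyr::mutate(w = unname(weights[.data$site_type])) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(targetrank_score = sum(.data$w), .groups = "drop")
  out <- tibble::tibble(gene_id = regions$gene_id) |>
    dplyr::left_join(per_gene, by = "gene_id") |>
    dplyr::mutate(targetrank_score =
                    dplyr::coalesce(.data$targetrank_score, 0))
  scored <- out |>
    dplyr::filter(.data$targetrank_score > 0) |>
    dplyr::arrange(dplyr::desc(.data$targetrank_score), .data$gene_id) |>
    dplyr::mutate(targetrank_rank = dplyr::row_number())
  out <- out |>
    dplyr::left_join(scored[, c("gene_id", "targetrank_rank")],
                     by = "gene_id") |>
    dplyr::mutate(targetrank_confirmed =
                    !is.na(.data$targetrank_rank) &
                    .data$targetrank_rank <= rank_max &
                    .data$targetrank_score >= score_min)
  out
}

#' Format a TargetRank verdict the way result tables print it
#'
#' `"YES (rank, score)"` when confirmed, otherwise `"NO"`.
#'
#' @param confirmed Logical vector.
#' @param rank,score Rank and score vectors.
#' @return Character vector.
#' @export
format_targetrank <- function(confirmed, rank, score) {
  ifelse(confirmed,
         sprintf("YES (%d, %.2f)", as.integer(rank), score),
         "NO")
}

#' Import externally produced prediction tables
#'
#' Lets real miRanda / TargetScan / TargetRank output stand in for the
#' built-in simplified scorers. The TSV needs columns `mirna_id` and
#' `gene_id`, plus `score` for `tool = "targetrank"`. Duplicate pairs are
#' deduplicated with a message.
#'
#' @param path TSV path.
#' @param tool One of `"miranda"`, `"targetscan"`, `"targetrank"`.
#' @return A tibble of pair-level predictions for the named tool:
#'   flag column `predicted_<tool>` for miranda/targetscan, or
#'   `targetrank_score`/`targetrank_rank`/`targetrank_confirmed` columns.
#' @export
load_external_predictions <- function(path,
                                      tool = c("miranda", "targetscan",
                                               "targetrank")) {
  tool <- match.arg(tool)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("mirna_id", "gene_id") %in% names(tbl))) {
    stop("external prediction table needs mirna_id and gene_id columns",
         call. = FALSE)
  }
  if (nrow(tbl) == 0L) {
    warning("external prediction table is empty: ", path, call. = FALSE)
  }
  ndup <- nrow(tbl) - nrow(dplyr::distinct(tbl, .data$mirna_id, .data$gene_id))
  if (ndup > 0) {
    message(ndup, " duplicate pair row(s) deduplicated in ", path)
    tbl <- dplyr::distinct(tbl, .data$mirna_id, .data$gene_id,
                           .keep_all = TRUE)
  }
  out <- tibble::tibble(mirna_id = as.character(tbl$mirna_id),
                        gene_id = as.character(tbl$gene_id))
  if (tool == "targetrank") {
    if (!"score" %in% names(tbl)) {
      stop("targetrank import needs a score column", call. = FALSE)
    }
    out$targetrank_score <- as.numeric(tbl$score)
    out <- dplyr::arrange(out, dplyr::desc(.data$targetrank_score),
                          .data$gene_id)
    out$targetrank_rank <- seq_len(nrow(out))
    out$targetrank_confirmed <- TRUE
  } else {
    out[[paste0("predicted_", tool)]] <- TRUE
  }
  out
}
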