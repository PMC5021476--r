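#' Run the sequence predictors over a set of candidate pairs
#'
#' Convenience wrapper applying [predict_pair()] to each (miRNA, gene)
#' candidate, typically the pairs surviving the inverse-correlation screen.
#'
#' @param pairs Tibble with columns `mirna_id`, `gene_id` (duplicates
#'   collapsed).
#' @param mirna_seqs Named character vector of mature miRNA sequences.
#' @param regions Transcript-region tibble (see [read_region_fasta()]).
#' @param min_score Duplex-alignment threshold (default 140).
#' @return A tibble `(mirna_id, gene_id, predicted_targetscan,
#'   predicted_miranda, n_sites)`.
#' @export
predict_candidates <- function(pairs, mirna_seqs, regions, min_score = 140) {
  pairs <- dplyr::distinct(pairs, .data$mirna_id, .data$gene_id)
  miss_m <- setdiff(unique(pairs$mirna_id), names(mirna_seqs))
  if (length(miss_m)) {
    stop("no sequence for miRNA(s): ",
         paste(utils::head(miss_m, 5), collapse = ", "), call. = FALSE)
  }
  miss_g <- setdiff(unique(pairs$gene_id), regions$gene_id)
  if (length(miss_g)) {
    stop("no regions for gene(s): ",
         paste(utils::head(miss_g, 5), collapse = ", "), call. = FALSE)
  }
  res <- purrr::map(seq_len(nrow(pairs)), function(k) {
    pp <- predict_pair(mirna_seqs[[pairs$mirna_id[k]]],
                       regions[regions$gene_id == pairs$gene_id[k], ,
                               drop = FALSE],
                       min_score = min_score)
    tibble::tibble(
      mirna_id = pairs$mirna_id[k], gene_id = pairs$gene_id[k],
      predicted_targetscan = pp$predicted_targetscan,
      predicted_miranda = pp$predicted_miranda,
      n_sites = nrow(pp$sites)
    )
  })
  dplyr::bind_rows(res)
}

#' Build the candidate funnel for one histotype group
#'
#' Joins the filtered inverse correlations of one group with per-pair
#' predictor verdicts and records the staged attrition: (a) pairs passing
#' the correlation screen, (b) pairs additionally predicted by at least one
#' sequence tool, (c) pairs predicted by both tools. Pairs at stage (c) are
#' given deterministic names `{group}_{k}` by `r` ascending (ties broken by
#' miRNA then gene ID), mirroring the naming of published candidate tables.
#'
#' @param corr Filtered correlation records (from [fdr_and_filter()]) of a
#'   single group.
#' @param preds Per-pair predictions ([predict_candidates()] or
#'   [load_external_predictions()] output); pairs absent from `preds` count
#'   as predicted by neither tool.
#' @param group The group the records belong to (consistency-checked).
#' @return A list of class `mirlink_funnel` with `candidates` (the stage-(a)
#'   records with predictor flags, `n_predictors` and `regulation_name`) and
#'   `funnel` (tibble of stage counts).
#' @export
build_funnel <- function(corr, preds, group) {
  if (nrow(corr) && !all(corr$group == group)) {
    stop("correlation records are not all from group '", group, "'",
         call. = FALSE)
  }
  keep <- c("mirna_id", "gene_id",
            intersect(c("predicted_targetscan", "predicted_miranda"),
                      names(preds)))
  cand <- dplyr::left_join(tibble::as_tibble(corr),
                           dplyr::distinct(preds[, keep],
                                           .data$mirna_id, .data$gene_id,
                                           .keep_all = TRUE),
                           by = c("mirna_id", "gene_id"))
  for (col in c("predicted_targetscan", "predicted_miranda")) {
    if (!col %in% names(cand)) cand[[col]] <- FALSE
    cand[[col]] <- dplyr::coalesce(cand[[col]], FALSE)
  }
  cand$n_predictors <- as.integer(cand$predicted_targetscan) +
    as.integer(cand$predicted_miranda)
  cand <- dplyr::arrange(cand, .data$r, .data$mirna_id, .data$gene_id)
  cand$regulation_name <- NA_character_
  both <- which(cand$n_predictors == 2L)
  cand$regulation_name[both] <- paste0(group, "_", seq_along(both))
  funnel <- tibble::tibble(
    stage = c("screen", "any_predictor", "both_predictors"),
    count = c(nrow(cand),
              sum(cand$n_predictors >= 1L),
              length(both))
  )
  structure(list(candidates = cand, funnel = funnel, group = group),
            class = "mirlink_funnel")
}

#' @export
print.mirlink_funnel <- function(x, ...) {
  cat(sprintf("# candidate funnel [%s]\n", x$group))
  for (i in seq_len(nrow(x$funnel))) {
    cat(sprintf("  %-16s %d\n", x$funnel$stage[i], x$funnel$count[i]))
  }
  invisible(x)
}

#' @export
glance.mirlink_funnel <- function(x, ...) {
  tibble::tibble(group = x$group,
                 n_screen = x$funnel$count[1],
                 n_any_predictor = x$funnel$count[2],
                 n_both_predictors = x$funnel$count[3])
}

#' Final confirmation of regulation candidates
#'
#' A candidate becomes a final regulation call when it was predicted by both
#' sequence tools, passes its group's strict correlation threshold, and is
#' confirmed by the seed-weighted ranking stage. The ranking stage is
#' evaluated lazily — only candidates already passing the first two rules
#' need rank records.
#'
#' @param funnel A [build_funnel()] result (or its `candidates` tibble with
#'   a `group` column).
#' @param targetrank Per-pair rank records: tibble with `mirna_id`,
#'   `gene_id`, `targetrank_score`, `targetrank_rank`,
#'   `targetrank_confirmed` (e.g. [targetrank_like()] output augmented with
#'   the miRNA ID).
#' @param strict_thresholds Per-group strict cutoffs (see
#'   [strict_threshold()]).
#' @return A tibble of class `mirlink_final`, sorted by `r` ascending, with
#'   the full evidence trail: `regulation_name`, `group`, `mirna_id`,
#'   `gene_id`, `r`, `fdr`, predictor flags, `passed_strict`,
#'   `targetrank_confirmed`, `targetrank` (formatted verdict) and `final`.
#' @export
confirm_final <- function(funnel, targetrank,
                          strict_thresholds = c(cPTC = -0.65, fvPTC = -0.70,
                                                tcPTC = -0.80)) {
  cand <- if (inherits(funnel, "mirlink_funnel")) funnel$candidates else
    tibble::as_tibble(funnel)
  if (nrow(cand) == 0L) {
    out <- cand
    out$passed_strict <- logical(0)
    out$targetrank_confirmed <- logical(0)
    out$targetrank <- character(0)
    out$final <- logical(0)
    return(structure(out, class = c("mirlink_final", class(out))))
  }
  unknown <- setdiff(unique(cand$group), names(strict_thresholds))
  if (length(unknown)) {
    stop("no strict threshold for group(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cand$passed_strict <- cand$r < unname(strict_thresholds[cand$group])
  tr_cols <- c("mirna_id", "gene_id", "targetrank_score", "targetrank_rank",
               "targetrank_confirmed")
  if (is.null(targetrank) || nrow(targetrank) == 0L) {
    cand$targetrank_score <- NA_real_
    cand$targetrank_rank <- NA_integer_
    cand$targetrank_confirmed <- FALSE
  } else {
    cand <- dplyr::left_join(cand, targetrank[, tr_cols],
                             by = c("mirna_id", "gene_id"))
    cand$targetrank_confirmed <-
      dplyr::coalesce(cand$targetrank_confirmed, FALSE)
  }
  eligible <- cand$n_predictors == 2L & cand$passed_strict
  # the ranking verdict only applies to eligible candidates
  cand$targetrank_confirmed[!eligible] <- FALSE
  cand$targetrank <- format_targetrank(cand$targetrank_confirmed,
                                       cand$targetrank_rank,
                                       cand$targetrank_score)
  cand$final <- eligible & cand$targetrank_confirmed
  out <- dplyr::arrange(cand, .data$r, .data$mirna_id, .data$gene_id)
  structure(out, class = c("mirlink_final", class(out)))
}

#' @export
glance.mirlink_final <- function(x, ...) {
  tibble::tibble(n_candidates = nrow(x),
                 n_strict = sum(x$passed_strict),
                 n_final = sum(x$final))
}

#' Run the full discovery pipeline
#'
#' Orchestrates every stage end to end: data (simulated or read from disk),
#' preprocessing of both matrices, the per-group inverse-correlation screen,
#' sequence-based target prediction, and the confirmation funnel. Writes
#' per-stage TSVs, PCA QC tables (and plots), funnel counts as JSON, and a
#' run log carrying the configuration hash and seed, so a rerun with the
#' same configuration and seed is reproducible.
#'
#' @param config A configuration list or path to a YAML file. Recognized
#'   sections (all optional): `simulate` ([sim_config()] arguments),
#'   `inputs` (paths `mirna_tsv`, `mrna_tsv`, `annotations_tsv`,
#'   `mirna_fasta`, `regions_fasta`), `preprocess` (`order`, `log_offset`,
#'   `min_fraction`), `screen` (`threshold`, `strict`, `chunk_size`),
#'   `predict` (`min_score`, `rank_max`, `score_min`, `enabled`), `seed`,
#'   `write_png`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the per-group funnels, the final
#'   regulation table, QC score tables and the output paths.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "qc"), showWarnings = FALSE)
  cfg_hash <- rlang::hash(config)
  seed <- config$seed %||% 1L
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(...)), file = logf, append = TRUE)
  }
  cat(sprintf("mirlink run\nconfig_hash: %s\nseed: %d\n", cfg_hash,
              as.integer(seed)), file = logf)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- data -----------------------------------------------------------
  dat <- stage("ingest", {
    if (!is.null(config$inputs)) {
      inp <- config$inputs
      list(
        mirna = read_expr_tsv(inp$mirna_tsv, scale = "linear"),
        mrna = read_expr_tsv(inp$mrna_tsv, scale = "linear"),
        annot = read_sample_annotation(inp$annotations_tsv),
        seqs = if (!is.null(inp$mirna_fasta)) {
          list(mirna = read_mirna_fasta(inp$mirna_fasta),
               regions = read_region_fasta(inp$regions_fasta))
        },
        truth = NULL
      )
    } else {
      sc <- do.call(sim_config, c(config$simulate, list(seed = seed)))
      sim <- simulate_expression(sc)
      seqs <- simulate_sequences(sim$truth, feature_ids(sim$mirna),
                                 feature_ids(sim$mrna), seed = seed + 1)
      list(mirna = sim$mirna, mrna = sim$mrna, annot = sim$annot,
           seqs = seqs, truth = sim$truth)
    }
  })
  log_line("ingest: %d miRNA x %d samples; %d genes",
           nrow(dat$mirna), length(sample_ids(dat$mirna)), nrow(dat$mrna))

  # --- preprocessing with PCA QC before/after batch removal -----------
  pp <- config$preprocess %||% list()
  prep <- stage("preprocess", {
    lapply(list(mirna = dat$mirna, mrna = dat$mrna), function(m) {
      m <- prevalence_filter(m, min_fraction = pp$min_fraction %||% 0.5)
      m <- quantile_normalize(m)
      m <- log2_transform(m, offset = pp$log_offset %||% 1)
      qc_before <- pca_qc(m, dat$annot)
      m2 <- remove_batch_effect(m, dat$annot)
      qc_after <- pca_qc(m2, dat$annot)
      list(m = m2, qc_before = qc_before, qc_after = qc_after)
    })
  })
  for (nm in names(prep)) {
    readr::write_tsv(tibble::as_tibble(prep[[nm]]$qc_before),
                     file.path(out_dir, "qc",
                               paste0("pca_", nm, "_before.tsv")))
    readr::write_tsv(tibble::as_tibble(prep[[nm]]$qc_after),
                     file.path(out_dir, "qc",
                               paste0("pca_", nm, "_after.tsv")))
    if (isTRUE(config$write_png)) {
      ggplot2::ggsave(
        file.path(out_dir, "qc", paste0("pca_", nm, "_before.png")),
        ggplot2::autoplot(prep[[nm]]$qc_before),
        width = 5, height = 4.5, dpi = 120)
      ggplot2::ggsave(
        file.path(out_dir, "qc", paste0("pca_", nm, "_after.png")),
        ggplot2::autoplot(prep[[nm]]$qc_after),
        width = 5, height = 4.5, dpi = 120)
    }
    log_line("preprocess %s: %d features kept", nm, nrow(prep[[nm]]$m))
  }

  # --- per-group screen + prediction + funnel -------------------------
  scr <- config$screen %||% list()
  prd <- config$predict %||% list()
  strict <- unlist(scr$strict %||%
                     c(cPTC = -0.65, fvPTC = -0.70, tcPTC = -0.80))
  ann <- annot_for(prep$mirna$m, dat$annot)
  groups <- names(which(table(ann$group) >= 4))
  groups <- setdiff(groups, "other")
  predict_enabled <- !isFALSE(prd$enabled) && !is.null(dat$seqs)
  funnels <- list()
  finals <- list()
  for (g in groups) {
    recs <- stage(paste0("screen:", g), {
      all_pairs_screen(prep$mirna$m, prep$mrna$m, dat$annot, g,
                       chunk_size = scr$chunk_size %||% 256) |>
        fdr_and_filter(threshold = scr$threshold %||% -0.6)
    })
    preds <- if (predict_enabled && nrow(recs)) {
      stage(paste0("predict:", g), {
        predict_candidates(recs[, c("mirna_id", "gene_id")],
                           dat$seqs$mirna, dat$seqs$regions,
                           min_score = prd$min_score %||% 140)
      })
    } else {
      tibble::tibble(mirna_id = character(), gene_id = character(),
                     predicted_targetscan = logical(),
                     predicted_miranda = logical())
    }
    fun <- stage(paste0("integrate:", g), build_funnel(recs, preds, g))
    # ranking stage, lazily: only miRNAs of strict+both-tool candidates
    elig <- fun$candidates[fun$candidates$n_predictors == 2L &
                             fun$candidates$r < strict[g], , drop = FALSE]
    tr <- if (predict_enabled && nrow(elig)) {
      dplyr::bind_rows(lapply(unique(elig$mirna_id), function(mid) {
        res <- targetrank_like(dat$seqs$mirna[[mid]], dat$seqs$regions,
                               rank_max = prd$rank_max %||% 100,
                               score_min = prd$score_min %||% 0.25)
        res$mirna_id <- mid
        res
      }))
    } else {
      NULL
    }
    fin <- confirm_final(fun, tr, strict_thresholds = strict)
    funnels[[g]] <- fun
    finals[[g]] <- fin
    readr::write_tsv(fun$candidates,
                     file.path(out_dir, paste0("candidates_", g, ".tsv")))
    log_line("group %s: funnel %s", g,
             paste(fun$funnel$count, collapse = " -> "))
  }

  final_tbl <- dplyr::bind_rows(lapply(finals, function(f) {
    tibble::as_tibble(f)[f$final, , drop = FALSE]
  }))
  if (nrow(final_tbl)) {
    final_tbl <- final_tbl[, c("regulation_name", "group", "r", "fdr",
                               "mirna_id", "targetrank", "gene_id")]
  }
  readr::write_tsv(final_tbl, file.path(out_dir, "final_regulations.tsv"))
  funnel_json <- lapply(funnels, function(f) {
    stats::setNames(as.list(f$funnel$count), f$funnel$stage)
  })
  jsonlite::write_json(funnel_json, file.path(out_dir, "funnel.json"),
                       auto_unbox = TRUE)
  log_line("final regulations: %d", nrow(final_tbl))
  invisible(list(funnels = funnels, finals = finals, final = final_tbl,
                 qc = lapply(prep, function(x)
                   list(before = x$qc_before, after = x$qc_after)),
                 truth = dat$truth, out_dir = out_dir))
}
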