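screen_stub <- function(df, n_samples = 99L) {
  structure(tibble::as_tibble(df), n_samples = n_samples,
            class = c("mirlink_screen", "tbl_df", "tbl", "data.frame"))
}

test_that("the funnel stages are a monotone subset chain with stable names", {
  corr <- screen_stub(tibble::tibble(
    mirna_id = paste0("m", 1:4), gene_id = paste0("g", 1:4), group = "cPTC",
    r = c(-0.70, -0.81, -0.66, -0.62), p_value = 1e-8, fdr = 1e-6))
  preds <- tibble::tibble(
    mirna_id = c("m1", "m2", "m3"), gene_id = c("g1", "g2", "g3"),
    predicted_targetscan = c(TRUE, TRUE, FALSE),
    predicted_miranda = c(TRUE, FALSE, TRUE))
  fun <- build_funnel(corr, preds, "cPTC")
  expect_equal(fun$funnel$count, c(4L, 3L, 1L))
  expect_true(all(diff(fun$funnel$count) <= 0))
  # pair with r = -0.70 but no predictions stays at stage (a)
  m4 <- fun$candidates[fun$candidates$mirna_id == "m4", ]
  expect_equal(m4$n_predictors, 0L)
  # both-predictor candidates are named {group}_{k} by r ascending
  expect_equal(fun$candidates$regulation_name[
    fun$candidates$mirna_id == "m1"], "cPTC_1")
  expect_error(build_funnel(corr, preds, "fvPTC"), "not all from group")
})

test_that("final confirmation requires both tools, strict r and the ranking", {
  cand <- tibble::tibble(
    mirna_id = c("hsa-miR-146b-5p", "hsa-miR-152-3p", "hsa-miR-874-3p",
                 "hsa-miR-21-5p"),
    gene_id = c("PHKB", "TGFA", "ITGB4", "BTBD11"),
    group = c("cPTC", "fvPTC", "cPTC", "cPTC"),
    r = c(-0.750, -0.69, -0.662, -0.670),
    p_value = 1e-12, fdr = 1e-12,
    predicted_targetscan = TRUE,
    predicted_miranda = c(TRUE, TRUE, TRUE, FALSE),
    n_predictors = c(2L, 2L, 2L, 1L),
    regulation_name = c("cPTC_1", "fvPTC_1", "cPTC_2", NA))
  tr <- tibble::tibble(
    mirna_id = c("hsa-miR-146b-5p", "hsa-miR-874-3p"),
    gene_id = c("PHKB", "ITGB4"),
    targetrank_score = c(0.48, 0.39),
    targetrank_rank = c(19L, 36L),
    targetrank_confirmed = c(TRUE, FALSE))
  fin <- confirm_final(cand, tr)
  expect_s3_class(fin, "mirlink_final")
  phkb <- fin[fin$gene_id == "PHKB", ]
  expect_true(phkb$final)  # both tools + r < -0.65 + ranking yes
  expect_equal(phkb$targetrank, "YES (19, 0.48)")
  # fvPTC candidate at -0.69 fails its stricter -0.70 cutoff
  expect_false(fin$final[fin$gene_id == "TGFA"])
  expect_false(fin$passed_strict[fin$gene_id == "TGFA"])
  # ranking said NO
  expect_false(fin$final[fin$gene_id == "ITGB4"])
  expect_equal(fin$targetrank[fin$gene_id == "ITGB4"], "NO")
  # only one tool
  expect_false(fin$final[fin$gene_id == "BTBD11"])
  # every final record sits below its group's strict threshold
  strict <- c(cPTC = -0.65, fvPTC = -0.70, tcPTC = -0.80)
  expect_true(all(fin$r[fin$final] < strict[fin$group[fin$final]]))
  expect_equal(glance(fin)$n_final, 1L)
})

test_that("implanted regulations reach the both-predictors stage", {
  cfg <- sim_config(n_mirna = 25, n_gene = 60, group_sizes = c(cPTC = 80),
                    n_batches = 4, n_regulations = 5, seed = 21)
  sim <- simulate_expression(cfg)
  seqs <- simulate_sequences(sim$truth, feature_ids(sim$mirna),
                             feature_ids(sim$mrna), seed = 22)
  mm <- preprocess_pipeline(sim$mirna, sim$annot)
  mg <- preprocess_pipeline(sim$mrna, sim$annot)
  fl <- fdr_and_filter(all_pairs_screen(mm, mg, sim$annot, "cPTC"))
  preds <- predict_candidates(fl[, c("mirna_id", "gene_id")],
                              seqs$mirna, seqs$regions)
  fun <- build_funnel(fl, preds, "cPTC")
  tr <- sim$truth$regulations
  stage_c <- fun$candidates[fun$candidates$n_predictors == 2L, ]
  planted_in_screen <- paste(fl$mirna_id, fl$gene_id) %in%
    paste(tr$mirna_id, tr$gene_id)
  planted_in_c <- paste(stage_c$mirna_id, stage_c$gene_id) %in%
    paste(tr$mirna_id, tr$gene_id)
  # every planted pair that passed the screen also passes both predictors
  expect_equal(sum(planted_in_c), sum(planted_in_screen))
})

test_that("run_pipeline writes a complete, reproducible result set", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  config <- list(
    simulate = list(n_mirna = 25, n_gene = 60,
                    group_sizes = c(cPTC = 60), n_batches = 4,
                    n_regulations = 4),
    seed = 31
  )
  res1 <- run_pipeline(config, d1)
  expect_true(file.exists(file.path(d1, "final_regulations.tsv")))
  expect_true(file.exists(file.path(d1, "candidates_cPTC.tsv")))
  expect_true(file.exists(file.path(d1, "funnel.json")))
  expect_true(file.exists(file.path(d1, "run.log")))
  expect_true(file.exists(file.path(d1, "qc", "pca_mirna_before.tsv")))
  counts <- unlist(jsonlite::read_json(file.path(d1, "funnel.json"))$cPTC)
  expect_true(all(diff(counts) <= 0))
  # recovered pairs are implanted ones
  fin <- res1$final
  if (nrow(fin)) {
    truth_keys <- paste(res1$truth$regulations$mirna_id,
                        res1$truth$regulations$gene_id)
    expect_true(all(paste(fin$mirna_id, fin$gene_id) %in% truth_keys))
  }
  # rerunning with the same config and seed is byte-identical
  res2 <- run_pipeline(config, d2)
  expect_identical(readLines(file.path(d1, "final_regulations.tsv")),
                   readLines(file.path(d2, "final_regulations.tsv")))
  expect_identical(readLines(file.path(d1, "candidates_cPTC.tsv")),
                   readLines(file.path(d2, "candidates_cPTC.tsv")))
})

test_that("disabling the prediction stage truncates the funnel", {
  d <- withr::local_tempdir()
  config <- list(
    simulate = list(n_mirna = 20, n_gene = 40,
                    group_sizes = c(cPTC = 50), n_batches = 2,
                    n_regulations = 3),
    predict = list(enabled = FALSE),
    seed = 32
  )
  res <- run_pipeline(config, d)
  counts <- res$funnels$cPTC$funnel$count
  expect_gt(counts[1], 0)
  expect_equal(counts[2], 0L)
  expect_equal(counts[3], 0L)
  expect_equal(nrow(res$final), 0L)
})
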