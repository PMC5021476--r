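test_that("median-based fold change matches hand computation and resists outliers", {
  expect_equal(median_fold_change(c(2, 4, 6), c(1, 2, 3)), 2, tolerance = 1e-9)
  expect_equal(median_fold_change(c(1, 2, 3), c(1, 2, 3)), 1, tolerance = 1e-9)
  expect_error(median_fold_change(numeric(), 1:3), "at least one")

  # replacing any single above-median value with an arbitrarily larger one
  # leaves the statistic unchanged (odd group size)
  withr::local_seed(10)
  for (rep in 1:20) {
    x1 <- rexp(5) * 10
    x2 <- rexp(7) * 10
    base <- median_fold_change(x1, x2)
    i <- which(x1 > median(x1))[1]
    x1_out <- x1
    x1_out[i] <- x1[i] * 1e6
    expect_equal(median_fold_change(x1_out, x2), base)
  }

  # the down-regulation bound: a fold change of 0.35 is called down
  expect_true(0.35 < 0.8)
  expect_identical(ifelse(0.35 >= 1, "up", "down"), "down")
})

test_that("variance filter drops the least-variable quarter", {
  # per-feature variances 0, 1, 2, 3 across 5 samples
  v <- rbind(rep(1, 5),
             c(0, 1, 2, 1, 0) * sqrt(1 / var(c(0, 1, 2, 1, 0))),
             c(0, 1, 2, 1, 0) * sqrt(2 / var(c(0, 1, 2, 1, 0))),
             c(0, 1, 2, 1, 0) * sqrt(3 / var(c(0, 1, 2, 1, 0))))
  m <- em(v)
  expect_equal(unname(round(apply(expr_values(m), 1, var), 9)),
               c(0, 1, 2, 3))
  out <- variance_filter(m)  # Q1 = 0.75 by linear interpolation
  expect_equal(feature_ids(out), c("f2", "f3", "f4"))

  # constant feature among varying ones is dropped
  withr::local_seed(20)
  m2 <- em(rbind(rep(2, 6), matrix(rnorm(30), 5, 6)), scale = "log2")
  expect_false("f1" %in% feature_ids(variance_filter(m2)))

  # all-equal variances: strict rule would drop everything; keep all
  m3 <- em(rbind(c(0, 1), c(2, 3), c(4, 5), c(6, 7)))
  expect_equal(nrow(variance_filter(m3)), 4L)
})

test_that("Welch t-test matches the textbook formulas", {
  r <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t_stat, 0)
  expect_equal(r$p_value, 1)

  r2 <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(r2$t_stat), 3.674, tolerance = 1e-3)
  expect_equal(r2$p_value, 0.0213, tolerance = 1e-3)
  r3 <- welch_t_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r3$t_stat, -r2$t_stat)
  expect_equal(r3$p_value, r2$p_value)

  # zero variance in both groups
  expect_equal(welch_t_test(c(2, 2), c(2, 2))$p_value, 1)
  deg <- welch_t_test(c(2, 2), c(5, 5))
  expect_equal(deg$p_value, 0)
  expect_true(deg$degenerate)

  withr::local_seed(30)
  for (i in 1:100) {
    x1 <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    x2 <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2))
    got <- welch_t_test(x1, x2)
    want <- oracle_welch(x1, x2)
    expect_equal(got$t_stat, want$t, tolerance = 1e-9)
    expect_equal(got$p_value, want$p, tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03, 0.002)),
               c(0.02, 0.04, 0.04, 0.008))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, 0.1), m_total = 1), "m_total")

  # family-size override: larger m scales the adjustment up
  expect_equal(bh_fdr(c(0.01, 0.02), m_total = 10),
               oracle_bh(c(0.01, 0.02), m = 10))

  # monotonicity: raising one p never lowers any adjusted value
  withr::local_seed(40)
  p <- runif(50)
  adj <- bh_fdr(p)
  p2 <- p
  p2[7] <- min(1, p[7] + 0.3)
  expect_true(all(bh_fdr(p2) >= adj - 1e-12))
})

test_that("differential table recovers planted shifts with correct direction", {
  cfg <- sim_config(n_mirna = 4, n_gene = 300,
                    group_sizes = c(cPTC = 30, fvPTC = 30), n_batches = 4,
                    n_regulations = 0, de_fraction = 0.1, de_effect = 2,
                    seed = 5)
  sim <- simulate_expression(cfg)
  m <- preprocess_pipeline(sim$mrna, sim$annot)
  de <- differential_table(m, sim$annot, "cPTC", "fvPTC")
  expect_s3_class(de, "mirlink_de")
  # significance flag is exactly the conjunction of the two rules
  expect_equal(de$significant,
               de$fdr < 0.05 & (de$mbfc > 1.25 | de$mbfc < 0.8))
  expect_equal(de$feature_id[order(de$fdr)], de$feature_id)

  planted <- sim$truth$de_features
  found <- de[de$feature_id %in% planted$feature_id, ]
  hit <- merge(found, planted, by.x = "feature_id", by.y = "feature_id")
  # planted "up" features (higher in cPTC = group1) must come out up
  agree <- hit$direction.x == hit$direction.y
  expect_gt(mean(agree[hit$significant]), 0.95)

  g <- glance(de)
  expect_equal(g$n1, 30L)
  expect_equal(g$n_features, nrow(de))
  expect_equal(nrow(tidy(de)), nrow(de))
})

test_that("shuffled group labels produce near-null significance rates", {
  cfg <- sim_config(n_mirna = 4, n_gene = 400,
                    group_sizes = c(cPTC = 30, fvPTC = 30), n_batches = 4,
                    n_regulations = 0, de_fraction = 0, seed = 6)
  sim <- simulate_expression(cfg)
  m <- preprocess_pipeline(sim$mrna, sim$annot)
  a <- sim$annot
  withr::local_seed(61)
  a$group <- sample(a$group)
  de <- differential_table(m, a, "cPTC", "fvPTC")
  expect_lte(mean(de$significant), 0.05)
})

test_that("top-marker selection takes the k best significant features", {
  rec <- tibble::tibble(
    feature_id = paste0("f", 1:12),
    mbfc = c(rep(2, 10), 3, 4),
    t_stat = 1, p_value = 0.001,
    fdr = c(seq(0.001, 0.01, length.out = 10), 0.5, 0.6),
    significant = c(rep(TRUE, 10), FALSE, FALSE),
    direction = "up"
  )
  top <- select_top_markers(rec, k = 8)
  expect_equal(top, paste0("f", 1:8))
  expect_warning(top3 <- select_top_markers(rec[c(1:3, 11:12), ], k = 8),
                 "3 significant")
  expect_equal(length(top3), 3L)
})
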