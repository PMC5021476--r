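test_that("seed sites are detected and classified by the canonical rules", {
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"  # seed (2-8) GAGGUAG
  regions <- tibble::tibble(gene_id = "G1", utr5 = "", cds = "",
                            utr3 = "GGGCUACCUCAGGG")
  sites <- find_seed_sites(mir, regions)
  expect_equal(nrow(sites), 1L)  # one site, reported once (no double count)
  expect_equal(sites$site_type, "8mer")
  expect_equal(sites$start, 4L)
  expect_equal(substr(regions$utr3, sites$start, sites$start + 7),
               "CUACCUCA")

  # exact revcomp of positions 2-8, no trailing A -> 7mer-m8
  r2 <- tibble::tibble(gene_id = "G1", utr5 = "", cds = "",
                       utr3 = "GGCUACCUCGGG")
  s2 <- find_seed_sites(mir, r2)
  expect_equal(s2$site_type, "7mer-m8")

  # 6mer core + A, without the m8 base -> 7mer-A1
  r3 <- tibble::tibble(gene_id = "G1", utr5 = "", cds = "",
                       utr3 = "GGUACCUCAGG")
  s3 <- find_seed_sites(mir, r3)
  expect_equal(s3$site_type, "7mer-A1")

  none <- tibble::tibble(gene_id = "G1", utr5 = "", cds = "",
                         utr3 = "AAAAAAAAAAAA")
  expect_equal(nrow(find_seed_sites(mir, none)), 0L)
  expect_error(find_seed_sites("", regions), "non-empty")

  # sites are found in all three region types and labelled accordingly
  r4 <- tibble::tibble(gene_id = "G1", utr5 = "GGCUACCUCAGG",
                       cds = "GGCUACCUCAGG", utr3 = "GGCUACCUCAGG")
  s4 <- find_seed_sites(mir, r4)
  expect_equal(sort(s4$region), c("cds", "utr3", "utr5"))
})

test_that("seed-site detection equals an exhaustive window scan", {
  withr::local_seed(70)
  for (case in 1:60) {
    mir <- rand_rna(sample(19:23, 1))
    utr <- rand_rna(sample(c(40, 120, 400), 1))
    got <- find_seed_sites(mir, tibble::tibble(gene_id = "G", utr5 = "",
                                               cds = "", utr3 = utr))
    want <- oracle_seed_sites(mir, utr)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$site_type, want$site_type)
    }
  }
})

test_that("duplex score is exact for perfect complements and bounded for junk", {
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"  # 22 nt
  expect_equal(miranda_like_score(mir, rc(mir)), 145)  # 22*5 + 7*5
  expect_equal(miranda_like_score("AAAAAAAAAA", "AAAAAAAAAAAA"), 0)
  expect_error(miranda_like_score(mir, "ACGU"), "shorter")
  expect_error(miranda_like_score(mir, paste0(rc(mir), "X")), "non-RNA")

  # invariant under extension with non-pairing flanks (miRNA has no U:
  # an A flank can neither pair nor wobble)
  m2 <- "GCAGGCAGGCAGGCAGGCAG"
  win <- rc(m2)
  base <- miranda_like_score(m2, win)
  ext <- miranda_like_score(m2, paste0(strrep("A", 12), win, strrep("A", 9)))
  expect_equal(ext, base)
})

test_that("duplex DP equals exhaustive alignment enumeration at toy sizes", {
  withr::local_seed(71)
  for (case in 1:40) {
    mir <- rand_rna(sample(5:8, 1))
    win <- rand_rna(sample(8:12, 1))
    expect_equal(miranda_like_score(mir, win), oracle_duplex(mir, win),
                 info = paste(mir, win))
  }
})

test_that("pair prediction combines the seed and duplex verdicts", {
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"
  planted <- paste0(rc(substr(mir, 2, nchar(mir))), "A")
  regions <- tibble::tibble(
    gene_id = "G1", utr5 = "", cds = "",
    utr3 = paste0(rand_flank <- "GCGCGCGCGCGC", planted, "GCGCGCGCGC"))
  pp <- predict_pair(mir, regions)
  expect_true(pp$predicted_targetscan)
  expect_true(pp$predicted_miranda)
  expect_true(any(pp$sites$alignment_score >= 140))

  # lone 6mer with hostile flanks: seed-only pairing scores 5*2*6 = 60 < 140
  lone <- tibble::tibble(gene_id = "G1", utr5 = "", cds = "",
                         utr3 = paste0(strrep("A", 30),
                                       rc(substr(mir, 2, 7)), "G",
                                       strrep("A", 10)))
  p2 <- predict_pair(mir, lone)
  expect_false(p2$predicted_targetscan)
  expect_false(p2$predicted_miranda)

  empty <- tibble::tibble(gene_id = "G1", utr5 = "", cds = "",
                          utr3 = "CCCCCCCCCCCCCCCCCCCCCCCCCCCC")
  p3 <- predict_pair(mir, empty)
  expect_false(p3$predicted_targetscan)
  expect_false(p3$predicted_miranda)
  expect_equal(nrow(p3$sites), 0L)
})

test_that("seed-weighted ranking orders genes by site-class weights", {
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"
  site8 <- paste0(rc(substr(mir, 2, 8)), "A")       # 8mer, weight 1.0
  site7 <- paste0(rc(substr(mir, 2, 8)), "G")       # 7mer-m8, weight 0.75
  regions <- tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    utr5 = "", cds = "",
    utr3 = c(paste0("CCC", site8, "CCC"),                 # score 1.0
             paste0("CC", site7, "CCCC", site7, "CC"),    # score 1.5
             strrep("C", 30)))                            # score 0
  tr <- targetrank_like(mir, regions)
  expect_equal(tr$targetrank_score[match(c("gA", "gB", "gC"), tr$gene_id)],
               c(1.0, 1.5, 0))
  expect_equal(tr$targetrank_rank[tr$gene_id == "gB"], 1L)
  expect_equal(tr$targetrank_rank[tr$gene_id == "gA"], 2L)
  expect_true(is.na(tr$targetrank_rank[tr$gene_id == "gC"]))
  expect_true(all(tr$targetrank_confirmed[tr$gene_id %in% c("gA", "gB")]))
  expect_false(tr$targetrank_confirmed[tr$gene_id == "gC"])
  expect_error(targetrank_like(mir, regions[0, ]), "empty")

  # published-table verdict format
  expect_equal(format_targetrank(TRUE, 19, 0.48), "YES (19, 0.48)")
  expect_equal(format_targetrank(FALSE, NA, NA), "NO")
})

test_that("external prediction tables import and deduplicate", {
  d <- withr::local_tempdir()
  f <- file.path(d, "ext.tsv")
  readr::write_tsv(tibble::tibble(
    mirna_id = c("m1", "m1", "m2", "m1"),
    gene_id = c("g1", "g2", "g1", "g1")), f)
  expect_message(ext <- load_external_predictions(f, "miranda"),
                 "deduplicated")
  expect_equal(nrow(ext), 3L)
  expect_true(all(ext$predicted_miranda))
  expect_error(load_external_predictions(f, "blastn"), "arg")

  empty <- file.path(d, "empty.tsv")
  readr::write_tsv(tibble::tibble(mirna_id = character(),
                                  gene_id = character()), empty)
  expect_warning(load_external_predictions(empty, "targetscan"), "empty")
})
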