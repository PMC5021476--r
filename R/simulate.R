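#' Simulation configuration
#'
#' Defines the structure of a synthetic paired miRNA/mRNA cohort: grouped
#' samples with batch effects, heterogeneous detection prevalence,
#' differential features between the first two groups, and implanted
#' negative monotone miRNA-gene couplings. Defaults describe a cohort
#' scaled to roughly a third of a 321/99/35 classical / follicular-variant /
#' tall-cell histotype split, sequenced in 16 batches.
#'
#' @param n_mirna,n_gene Feature counts (defaults 200 and 1000).
#' @param group_sizes Named counts of samples per histotype group.
#' @param n_batches Number of sequencing batches (default 16).
#' @param n_regulations Number of implanted miRNA-gene couplings
#'   (default 20); planted on distinct genes.
#' @param regulation_strength Target population Spearman magnitude of the
#'   implanted negative couplings, in (0, 1) (default 0.85).
#' @param dropout_rate Overall fraction of values falling below the
#'   detection limit and recorded as 0, in `[0, 0.5)` (default 0.3).
#'   Detection is abundance-driven: the limit is the `dropout_rate`
#'   quantile of the simulated linear values, so zeros concentrate in
#'   low-abundance features.
#' @param rare_fraction Fraction of unplanted features simulated at
#'   sub-detection abundance (log2 baseline 0-3 instead of 3-12), so the
#'   prevalence filter has real work to do (default 0.3).
#' @param de_fraction Fraction of features differentially expressed between
#'   the first two groups (default 0.1; ignored with a single group).
#' @param de_effect Log2 shift of differential features (default 2).
#' @param batch_sd Standard deviation of per-batch per-feature additive
#'   offsets on the log2 scale (default 1).
#' @param seed RNG seed; all randomness flows from this single stream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_mirna = 200, n_gene = 1000,
                       group_sizes = c(cPTC = 100, fvPTC = 31, tcPTC = 11),
                       n_batches = 16, n_regulations = 20,
                       regulation_strength = 0.85,
                       dropout_rate = 0.3, rare_fraction = 0.3,
                       de_fraction = 0.1, de_effect = 2,
                       batch_sd = 1, seed = 1) {
  cfg <- list(n_mirna = n_mirna, n_gene = n_gene, group_sizes = group_sizes,
              n_batches = n_batches, n_regulations = n_regulations,
              regulation_strength = regulation_strength,
              dropout_rate = dropout_rate, rare_fraction = rare_fraction,
              de_fraction = de_fraction, de_effect = de_effect,
              batch_sd = batch_sd, seed = seed)
  stopifnot(n_mirna >= 1, n_gene >= 1, n_batches >= 1,
            all(group_sizes >= 1), !is.null(names(group_sizes)))
  if (dropout_rate < 0 || dropout_rate >= 0.5) {
    stop("dropout_rate must lie in [0, 0.5)", call. = FALSE)
  }
  if (regulation_strength <= 0 || regulation_strength >= 1) {
    stop("regulation_strength must lie in (0, 1)", call. = FALSE)
  }
  if (n_regulations > n_mirna * n_gene) {
    stop("more regulations requested than miRNA x gene pairs", call. = FALSE)
  }
  if (n_regulations > n_gene) {
    stop("regulations are planted on distinct genes: n_regulations > n_gene",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' The benchmark recovery panel
#'
#' The single-group configuration used to benchmark end-to-end recovery of
#' implanted regulations: 200 miRNAs x 1000 genes, 100 classical-variant
#' samples in 16 batches, 20 implanted couplings at strength 0.85 with
#' planted 8mer sites.
#'
#' @param seed RNG seed.
#' @return A `sim_config`.
#' @export
recovery_panel_config <- function(seed = 1) {
  sim_config(group_sizes = c(cPTC = 100), seed = seed)
}

#' Simulate a paired miRNA / mRNA expression cohort
#'
#' Generates linear-scale expression matrices with the structure the
#' pipeline assumes. On the log2 scale, each feature has a uniform baseline
#' and normal per-sample noise; implanted regulations couple a gene to its
#' miRNA as `gene = mu - sd * (rho * z_mirna + sqrt(1 - rho^2) * eps)` with
#' `rho = 2 * sin(pi * strength / 6)`, so the population Spearman
#' correlation is approximately `-strength` (only the rank structure matters
#' downstream). Per-batch per-feature normal offsets are added and values
#' are exponentiated to the linear scale. Detection is abundance-driven:
#' values below the matrix-wide `dropout_rate` quantile are recorded as 0
#' (undetected), so zeros concentrate in low-abundance features, as they do
#' in sequencing data. A `rare_fraction` subset of unplanted features is
#' simulated at sub-detection baselines and is expected to fail the
#' prevalence filter. Implanted features (regulations and differential
#' features) are drawn from the well-expressed baseline range — a screen
#' can only discover signals among detected features, so the benchmark
#' implants them there. Differential features receive a `de_effect` log2
#' shift between the first two groups.
#'
#' @param cfg A [sim_config()].
#' @return A list with `mirna` and `mrna` (`expr_matrix`, linear scale),
#'   `annot` (sample annotation) and `truth` — a list with tibbles
#'   `regulations` `(mirna_id, gene_id, group, planted_strength,
#'   planted_site_types)` and `de_features` `(feature_id, group_pair,
#'   direction)`.
#' @export
simulate_expression <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, simulate_expression_impl(cfg))
}

simulate_expression_impl <- function(cfg) {
  groups <- names(cfg$group_sizes)
  n <- sum(cfg$group_sizes)
  annot <- tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(n)),
    group = rep(groups, times = cfg$group_sizes),
    batch = sample(rep_len(sprintf("B%02d", seq_len(cfg$n_batches)), n))
  )
  mir_ids <- sprintf("miR-sim-%03d", seq_len(cfg$n_mirna))
  gene_ids <- sprintf("GENE%04d", seq_len(cfg$n_gene))

  reg_genes <- sample(gene_ids, cfg$n_regulations)
  reg_mirs <- if (cfg$n_regulations <= cfg$n_mirna) {
    sample(mir_ids, cfg$n_regulations)
  } else {
    sample(mir_ids, cfg$n_regulations, replace = TRUE)
  }
  reg_group <- groups[which.max(cfg$group_sizes)]

  # differential features between the first two groups, on unplanted features
  de_feats <- tibble::tibble(feature_id = character(),
                             group_pair = character(),
                             direction = character())
  if (length(groups) >= 2L && cfg$de_fraction > 0) {
    pool_m <- setdiff(mir_ids, reg_mirs)
    pool_g <- setdiff(gene_ids, reg_genes)
    de_m <- sample(pool_m, min(length(pool_m),
                               round(cfg$de_fraction * cfg$n_mirna)))
    de_g <- sample(pool_g, min(length(pool_g),
                               round(cfg$de_fraction * cfg$n_gene)))
    de_feats <- tibble::tibble(
      feature_id = c(de_m, de_g),
      group_pair = paste(groups[1], "vs", groups[2]),
      direction = sample(c("up", "down"), length(de_m) + length(de_g),
                         replace = TRUE)
    )
  }

  # baseline abundances: implanted features sit in the well-expressed
  # range, a rare_fraction of the rest below the detection limit
  planted <- c(reg_mirs, reg_genes, de_feats$feature_id)
  sim_grid <- function(ids) {
    k <- length(ids)
    mu <- stats::runif(k, 3, 12)
    is_planted <- ids %in% planted
    mu[is_planted] <- stats::runif(sum(is_planted), 6, 12)
    pool <- which(!is_planted)
    n_rare <- min(floor(cfg$rare_fraction * k), length(pool))
    if (n_rare > 0) {
      rare <- sample(pool, n_rare)
      mu[rare] <- stats::runif(n_rare, 0, 3)
    }
    sdv <- stats::runif(k, 0.8, 2)
    z <- matrix(stats::rnorm(k * n), k, n, dimnames = list(ids, annot$sample_id))
    list(mu = mu, sd = sdv, z = z, log2 = mu + sdv * z)
  }
  gm <- sim_grid(mir_ids)
  gg <- sim_grid(gene_ids)

  # implant negative monotone couplings
  rho <- 2 * sin(pi * cfg$regulation_strength / 6)
  for (k in seq_len(cfg$n_regulations)) {
    gi <- match(reg_genes[k], gene_ids)
    mi <- match(reg_mirs[k], mir_ids)
    eps <- gg$z[gi, ]
    gg$log2[gi, ] <- gg$mu[gi] - gg$sd[gi] *
      (rho * gm$z[mi, ] + sqrt(1 - rho^2) * eps)
  }

  # differential shifts: "up" = higher in the first group of the pair
  if (nrow(de_feats)) {
    g1 <- which(annot$group == groups[1])
    for (k in seq_len(nrow(de_feats))) {
      f <- de_feats$feature_id[k]
      shift <- if (de_feats$direction[k] == "up") cfg$de_effect else
        -cfg$de_effect
      if (f %in% mir_ids) {
        gm$log2[f, g1] <- gm$log2[f, g1] + shift
      } else {
        gg$log2[f, g1] <- gg$log2[f, g1] + shift
      }
    }
  }

  add_batch <- function(lg) {
    bl <- unique(annot$batch)
    off <- matrix(stats::rnorm(nrow(lg) * length(bl), sd = cfg$batch_sd),
                  nrow(lg), length(bl), dimnames = list(NULL, bl))
    lg + off[, annot$batch, drop = FALSE]
  }
  lm_ <- add_batch(gm$log2)
  lg_ <- add_batch(gg$log2)

  # abundance-driven detection: everything below the matrix-wide
  # dropout_rate quantile is below the detection limit and recorded as 0
  apply_detection_limit <- function(lin) {
    if (cfg$dropout_rate <= 0) return(lin)
    tau <- stats::quantile(lin, cfg$dropout_rate, names = FALSE)
    lin[lin < tau] <- 0
    lin
  }
  vm <- apply_detection_limit(2^lm_)
  vg <- apply_detection_limit(2^lg_)

  list(
    mirna = as_expr_matrix(vm, scale = "linear"),
    mrna = as_expr_matrix(vg, scale = "linear"),
    annot = as_sample_annotation_lenient(annot),
    truth = list(
      regulations = tibble::tibble(
        mirna_id = reg_mirs, gene_id = reg_genes, group = reg_group,
        planted_strength = cfg$regulation_strength,
        planted_site_types = "8mer"
      ),
      de_features = de_feats
    )
  )
}

# the simulator may use group labels outside the histotype vocabulary in
# tests; relax the vocabulary check but keep the structural ones
as_sample_annotation_lenient <- function(x) {
  tbl <- tibble::as_tibble(x)[, c("sample_id", "group", "batch")]
  if (anyDuplicated(tbl$sample_id)) stop("duplicate sample IDs", call. = FALSE)
  tbl
}

#' Simulate mature miRNA and transcript-region sequences
#'
#' Random-composition mature miRNA sequences (21-23 nt) and per-gene
#' 5'UTR / CDS / 3'UTR sequences. Each regulated gene's 3'UTR receives one
#' planted site: the reverse complement of its miRNA's positions 2 to end,
#' followed by an A — a canonical 8mer seed site with full 3'-end
#' complementarity, so both sequence predictors can recover it. Regulated
#' miRNAs are given a 5'-terminal U (the dominant base at that position in
#' real mature miRNAs), which lets the planted site pair at position 1 too.
#' Non-regulated genes receive no planted sites; chance seed matches occur
#' at the expected k-mer background rate and must be tolerated downstream.
#'
#' @param truth Ground-truth list from [simulate_expression()].
#' @param mirna_ids,gene_ids Full feature ID sets of the simulated matrices.
#' @param seed RNG seed.
#' @param utr5_len,cds_len,utr3_len Region lengths (defaults 200/900/1000).
#' @return A list with `mirna` (named character vector of RNA sequences) and
#'   `regions` (tibble `gene_id`, `utr5`, `cds`, `utr3`).
#' @export
simulate_sequences <- function(truth, mirna_ids, gene_ids, seed = 1,
                               utr5_len = 200, cds_len = 900,
                               utr3_len = 1000) {
  missing_g <- setdiff(truth$regulations$gene_id, gene_ids)
  if (length(missing_g)) {
    stop("regulated gene(s) missing from gene_ids: ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  }
  missing_m <- setdiff(truth$regulations$mirna_id, mirna_ids)
  if (length(missing_m)) {
    stop("regulating miRNA(s) missing from mirna_ids: ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }
  withr::with_seed(seed, {
    rand_seq <- function(len) {
      paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
            collapse = "")
    }
    mir <- vapply(sample(21:23, length(mirna_ids), replace = TRUE),
                  rand_seq, character(1))
    names(mir) <- mirna_ids
    reg_mirs <- unique(truth$regulations$mirna_id)
    substr(mir[reg_mirs], 1L, 1L) <- "U"
    regions <- tibble::tibble(
      gene_id = gene_ids,
      utr5 = vapply(rep(utr5_len, length(gene_ids)), rand_seq, character(1)),
      cds = vapply(rep(cds_len, length(gene_ids)), rand_seq, character(1)),
      utr3 = vapply(rep(utr3_len, length(gene_ids)), rand_seq, character(1))
    )
    for (k in seq_len(nrow(truth$regulations))) {
      m <- mir[[truth$regulations$mirna_id[k]]]
      site <- paste0(revcomp_rna(substr(m, 2L, nchar(m))), "A")
      gi <- match(truth$regulations$gene_id[k], regions$gene_id)
      pos <- sample.int(utr3_len - nchar(site) + 1L, 1L)
      u <- regions$utr3[gi]
      substr(u, pos, pos + nchar(site) - 1L) <- site
      regions$utr3[gi] <- u
    }
    list(mirna = mir, regions = regions)
  })
}

#' Write a simulated dataset to disk
#'
#' Writes the same plain-text files the ingest step reads: expression TSVs,
#' the sample-annotation TSV, miRNA and transcript-region FASTA, and a
#' ground-truth TSV.
#'
#' @param sim A [simulate_expression()] result.
#' @param seqs A [simulate_sequences()] result (optional).
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, seqs = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_expr_tsv(sim$mirna, file.path(out_dir, "mirna_expression.tsv"))
  write_expr_tsv(sim$mrna, file.path(out_dir, "mrna_expression.tsv"))
  readr::write_tsv(sim$annot, file.path(out_dir, "sample_annotations.tsv"))
  readr::write_tsv(sim$truth$regulations,
                   file.path(out_dir, "ground_truth.tsv"))
  readr::write_tsv(sim$truth$de_features,
                   file.path(out_dir, "ground_truth_de.tsv"))
  if (!is.null(seqs)) {
    write_fasta(seqs$mirna, file.path(out_dir, "mirna.fasta"))
    reg <- seqs$regions
    long <- tidyr::pivot_longer(reg, cols = c("utr5", "cds", "utr3"),
                                names_to = "region", values_to = "seq")
    long <- long[nchar(long$seq) > 0, ]
    rs <- long$seq
    names(rs) <- paste0(long$gene_id, " region=", long$region)
    write_fasta(rs, file.path(out_dir, "regions.fasta"))
  }
  invisible(out_dir)
}
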