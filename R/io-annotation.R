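#' Read per-sample miRNA isoform quantification files
#'
#' Each file is a two-column TSV (header row) with an isoform coordinate
#' string and its expression in reads per million miRNA-mapped reads (RPM),
#' one file per sample — the layout of TCGA miRNA-seq isoform quantification.
#' Isoform IDs are canonical strings `"chrom:start-end:strand"` with 1-based
#' inclusive coordinates. The union of isoforms across all files forms the
#' feature set; an isoform absent from a sample's file is recorded as 0
#' (undetected).
#'
#' @param paths Character vector of file paths, one per sample.
#' @param sample_ids Sample IDs, one per path; defaults to file basenames
#'   without extension.
#' @return An `expr_matrix` on the linear scale.
#' @export
read_isoform_quant <- function(paths, sample_ids = NULL) {
  if (is.null(sample_ids)) {
    sample_ids <- sub("\\.[^.]*$", "", basename(paths))
  }
  stopifnot(length(sample_ids) == length(paths))
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  per_sample <- purrr::map2(paths, sample_ids, function(p, sid) {
    tbl <- readr::read_tsv(p, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(
                             readr::col_character(), readr::col_double()))
    names(tbl)[1:2] <- c("isoform_id", "rpm")
    ok <- grepl("^[^:]+:\\d+-\\d+:[+-]$", tbl$isoform_id)
    if (any(!ok)) {
      stop(sprintf("malformed isoform coordinate in %s at line %d: '%s'",
                   p, which(!ok)[1] + 1L, tbl$isoform_id[which(!ok)[1]]),
           call. = FALSE)
    }
    if (any(tbl$rpm < 0, na.rm = TRUE)) {
      stop(sprintf("negative RPM value in %s", p), call. = FALSE)
    }
    tbl$sample_id <- sid
    tbl
  })
  long <- dplyr::bind_rows(per_sample)
  wide <- tidyr::pivot_wider(long, id_cols = "isoform_id",
                             names_from = "sample_id",
                             values_from = "rpm", values_fill = 0,
                             values_fn = sum)
  names(wide)[1] <- "feature_id"
  # keep requested column order
  wide <- wide[, c("feature_id", sample_ids)]
  as_expr_matrix(wide, scale = "linear")
}

#' Parse an isoform coordinate string
#'
#' @param isoform_id String(s) of the form `"chrom:start-end:strand"`.
#' @return A tibble with columns `isoform_id`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates).
#' @export
parse_isoform_id <- function(isoform_id) {
  m <- stringr::str_match(isoform_id, "^([^:]+):(\\d+)-(\\d+):([+-])$")
  bad <- which(is.na(m[, 1]))
  if (length(bad)) {
    stop("malformed isoform coordinate: '", isoform_id[bad[1]], "'",
         call. = FALSE)
  }
  out <- tibble::tibble(
    isoform_id = isoform_id,
    chrom = m[, 2],
    start = as.integer(m[, 3]),
    end = as.integer(m[, 4]),
    strand = m[, 5]
  )
  if (any(out$start > out$end)) {
    stop("isoform with start > end: '",
         out$isoform_id[which(out$start > out$end)[1]], "'", call. = FALSE)
  }
  out
}

#' Parse mature miRNA loci from a miRBase GFF3 file
#'
#' Extracts records of feature type `miRNA` (mature miRNAs; hairpin
#' `miRNA_primary_transcript` records are ignored) with their `Name`
#' attribute. Coordinates are kept 1-based inclusive as in GFF3.
#'
#' @param path Path to a miRBase-style GFF3 file.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `mature_name` — one row per mature miRNA locus.
#' @export
parse_mirbase_gff3 <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, "##gff-version")) {
    stop("not a GFF3 file (missing '##gff-version' header): ", path,
         call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "miRNA"]
  nm <- as.character(gr$Name)
  drop <- is.na(nm) | !nzchar(nm)
  if (any(drop)) {
    warning(sum(drop), " mature miRNA record(s) without a Name attribute ",
            "were skipped", call. = FALSE)
    gr <- gr[!drop]
    nm <- nm[!drop]
  }
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    mature_name = nm
  )
}

#' Map isoform coordinates to mature miRNA names
#'
#' Assigns each genomic miRNA isoform to the mature miRNA locus it overlaps
#' by the largest number of bases, requiring the same chromosome and strand.
#' Ties are broken by the lexicographically smallest mature name, so the
#' mapping is deterministic. Isoforms overlapping no mature locus map to
#' `NA` (unmapped is a value, not an error).
#'
#' @param isoform_id Character vector of `"chrom:start-end:strand"` IDs.
#' @param loci Mature-locus tibble from [parse_mirbase_gff3()].
#' @return A tibble with columns `isoform_id`, `mature_name` (`NA` when
#'   unmapped) and `overlap` (bases of overlap, 0 when unmapped).
#' @export
map_locus_to_mature <- function(isoform_id, loci) {
  q <- parse_isoform_id(isoform_id)
  if (nrow(loci) == 0L) {
    return(tibble::tibble(isoform_id = q$isoform_id,
                          mature_name = NA_character_, overlap = 0L))
  }
  lev <- union(unique(q$chrom), unique(loci$chrom))
  qr <- GenomicRanges::GRanges(factor(q$chrom, levels = lev),
                               IRanges::IRanges(q$start, q$end),
                               strand = q$strand)
  lr <- GenomicRanges::GRanges(factor(loci$chrom, levels = lev),
                               IRanges::IRanges(loci$start, loci$end),
                               strand = loci$strand)
  hits <- GenomicRanges::findOverlaps(qr, lr, ignore.strand = FALSE)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    qr[S4Vectors::queryHits(hits)], lr[S4Vectors::subjectHits(hits)]))
  cand <- tibble::tibble(
    qi = S4Vectors::queryHits(hits),
    mature_name = loci$mature_name[S4Vectors::subjectHits(hits)],
    overlap = as.integer(ov)
  )
  best <- cand |>
    dplyr::arrange(.data$qi, dplyr::desc(.data$overlap), .data$mature_name) |>
    dplyr::distinct(.data$qi, .keep_all = TRUE)
  out <- tibble::tibble(isoform_id = q$isoform_id,
                        mature_name = NA_character_, overlap = 0L)
  out$mature_name[best$qi] <- best$mature_name
  out$overlap[best$qi] <- best$overlap
  out
}

#' Read / write FASTA sequence sets
#'
#' Thin wrappers around `Biostrings` for the sequence files the target
#' predictors consume. `read_region_fasta()` expects transcript-region
#' records whose description line carries `region=utr5|cds|utr3`
#' (e.g. `>GENE1 region=utr3`) and returns the per-gene region table used by
#' [find_seed_sites()].
#'
#' @param path FASTA path.
#' @return `read_mirna_fasta()`: a named character vector of RNA sequences
#'   (T normalized to U). `read_region_fasta()`: a tibble with columns
#'   `gene_id`, `utr5`, `cds`, `utr3` (empty string when absent).
#' @export
read_mirna_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(chartr("T", "U", as.character(ss)))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' @rdname read_mirna_fasta
#' @export
read_region_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  desc <- names(ss)
  gene <- sub("\\s.*$", "", desc)
  region <- stringr::str_match(desc, "region=(utr5|cds|utr3)")[, 2]
  if (any(is.na(region))) {
    stop("region FASTA description lines must carry region=utr5|cds|utr3",
         call. = FALSE)
  }
  long <- tibble::tibble(
    gene_id = gene, region = region,
    seq = toupper(chartr("T", "U", as.character(ss)))
  )
  wide <- tidyr::pivot_wider(long, names_from = "region",
                             values_from = "seq", values_fill = "")
  for (r in c("utr5", "cds", "utr3")) if (!r %in% names(wide)) wide[[r]] <- ""
  wide[, c("gene_id", "utr5", "cds", "utr3")]
}

#' @rdname read_mirna_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
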