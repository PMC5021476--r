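# Independent reference implementations used to cross-check the package.
# These are deliberately naive (loops, enumeration, closed forms) and share
# no code with the implementation under test.

# Benjamini-Hochberg step-up, literal: sort, p * m / i, cumulative min from
# the largest rank down, clip at 1, back to input order.
oracle_bh <- function(p, m = length(p)) {
  o <- order(p)
  ranked <- p[o] * m / seq_along(p)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(length(p))
  out[o] <- adj
  out
}

# Welch t statistic and two-sided p from the textbook formulas.
oracle_welch <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  v1 <- var(x1); v2 <- var(x2)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x1) - mean(x2)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# Spearman r via base R's cor(); p via the t approximation recomputed here.
oracle_spearman <- function(x, y) {
  r <- cor(x, y, method = "spearman")
  n <- length(x)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = if (abs(r) >= 1) 0 else 2 * pt(-abs(tt), n - 2))
}

rc <- function(s) paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]),
                        collapse = "")

# Exhaustive sliding-window scan for canonical seed sites: test every
# window of the region against the literal definition of each site class,
# most specific class first.
oracle_seed_sites <- function(mir, region_seq) {
  s <- region_seq
  n <- nchar(s)
  m7 <- rc(substr(mir, 2, 8))   # 7mer-m8 match string
  m6 <- rc(substr(mir, 2, 7))   # 6mer match string
  hits <- list()
  for (p in seq_len(max(0, n - 5))) {
    w8 <- substr(s, p, p + 7)
    w7 <- substr(s, p, p + 6)
    w6 <- substr(s, p, p + 5)
    if (nchar(w8) == 8 && w8 == paste0(m7, "A")) {
      hits[[length(hits) + 1]] <- list(start = p, type = "8mer")
    } else if (nchar(w7) == 7 && w7 == m7 &&
               substr(s, p + 7, p + 7) != "A") {
      hits[[length(hits) + 1]] <- list(start = p, type = "7mer-m8")
    } else if (nchar(w7) == 7 && w6 == m6 && substr(s, p + 6, p + 6) == "A" &&
               (p == 1 || substr(s, p - 1, p - 1) != rc(substr(mir, 8, 8)))) {
      hits[[length(hits) + 1]] <- list(start = p, type = "7mer-A1")
    } else if (w6 == m6 && nchar(w6) == 6 &&
               (p == 1 || substr(s, p - 1, p - 1) != rc(substr(mir, 8, 8))) &&
               (p + 6 > n || substr(s, p + 6, p + 6) != "A")) {
      hits[[length(hits) + 1]] <- list(start = p, type = "6mer")
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), site_type = character()))
  }
  data.frame(start = vapply(hits, `[[`, 1L, "start"),
             site_type = vapply(hits, `[[`, "", "type"))
}

# Duplex alignment by memoized top-down enumeration of pair chains:
# an alignment is a chain of pairs strictly increasing in both sequences,
# consecutive pairs separated by a gap run in at most one sequence,
# gap run of length k costing 8 + 2 * (k - 1). Local: chains may start and
# end anywhere; the empty chain scores 0.
oracle_duplex <- function(mir, window, match = 5, wobble = 1, mismatch = -3,
                          gap_open = 8, gap_ext = 2, seed_mult = 2) {
  a <- strsplit(mir, "")[[1]]
  b <- rev(strsplit(window, "")[[1]])
  n <- length(a); m <- length(b)
  sc <- function(i, j) {
    x <- a[i]; y <- b[j]
    s <- if ((x == "A" && y == "U") || (x == "U" && y == "A") ||
             (x == "G" && y == "C") || (x == "C" && y == "G")) match
    else if ((x == "G" && y == "U") || (x == "U" && y == "G")) wobble
    else mismatch
    if (i >= 2 && i <= 8) s * seed_mult else s
  }
  memo <- array(NA_real_, c(n, m))
  f <- function(i, j) {  # best chain score starting with the pair (i, j)
    if (!is.na(memo[i, j])) return(memo[i, j])
    best_cont <- 0
    if (i < n && j < m) {
      best_cont <- max(best_cont, f(i + 1, j + 1))
      for (k in seq_len(n - i - 1)) {  # gap run in the miRNA coordinate
        best_cont <- max(best_cont,
                         f(i + 1 + k, j + 1) - (gap_open + gap_ext * (k - 1)))
      }
      for (k in seq_len(m - j - 1)) {  # gap run in the window coordinate
        best_cont <- max(best_cont,
                         f(i + 1, j + 1 + k) - (gap_open + gap_ext * (k - 1)))
      }
    }
    memo[i, j] <<- sc(i, j) + best_cont
    memo[i, j]
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) best <- max(best, f(i, j))
  best
}

rand_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# tiny expr_matrix builder
em <- function(values, scale = "linear", fprefix = "f", sprefix = "s") {
  v <- as.matrix(values)
  rownames(v) <- paste0(fprefix, seq_len(nrow(v)))
  colnames(v) <- paste0(sprefix, seq_len(ncol(v)))
  as_expr_matrix(v, scale = scale)
}

# annotation for k samples, single group unless given
ann <- function(k, group = "cPTC", batch = "B1", sprefix = "s") {
  tibble::tibble(sample_id = paste0(sprefix, seq_len(k)),
                 group = rep_len(group, k), batch = rep_len(batch, k))
}
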