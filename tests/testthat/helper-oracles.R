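## Independent oracles used throughout the suite. Each is a deliberately
## naive implementation (brute force, quadratic scan, direct summation) kept
## separate from the package code paths it checks.

library(data.table)

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

ham <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

rc <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

## brute-force bridge scan: every offset, both orientations, Hamming
## distance by character comparison; then the documented collapse rule
## (overlapping hits -> fewest mismatches, then leftmost, then forward),
## re-implemented here from scratch.
oracle_bridge_scan <- function(seq, bridge, max_mm) {
  blen <- nchar(bridge)
  slen <- nchar(seq)
  rows <- list()
  if (slen >= blen) {
    for (ori in c("forward", "reverse_complement")) {
      pat <- if (ori == "forward") bridge else rc(bridge)
      for (off in 0:(slen - blen)) {
        mm <- ham(substr(seq, off + 1, off + blen), pat)
        if (mm <= max_mm)
          rows[[length(rows) + 1]] <- data.frame(
            start = off, end = off + blen, orientation = ori,
            mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(),
                      orientation = character(), mismatches = integer()))
  h <- do.call(rbind, rows)
  h <- h[order(h$start), , drop = FALSE]
  ## collapse overlap clusters
  out <- list()
  i <- 1
  while (i <= nrow(h)) {
    j <- i
    hi_end <- h$end[i]
    while (j < nrow(h) && h$start[j + 1] < hi_end) {
      j <- j + 1
      hi_end <- max(hi_end, h$end[j])
    }
    cl <- h[i:j, , drop = FALSE]
    cl <- cl[order(cl$mismatches, cl$start, cl$orientation != "forward"), ,
             drop = FALSE]
    out[[length(out) + 1]] <- cl[1, ]
    i <- j + 1
  }
  h <- do.call(rbind, out)
  h <- h[order(h$start), , drop = FALSE]
  rownames(h) <- NULL
  h
}

## quadratic any-overlap scan for interval filtering
oracle_overlaps <- function(df, iset) {
  hit <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(iset))) {
      if (df$chrom[i] == iset$chrom[j] &&
          df$start[i] < iset$end[j] && iset$start[j] < df$end[i]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  hit
}

## exact upper-tail binomial by direct log-space term summation,
## P[X >= k], X ~ Binomial(n, q)
oracle_binom_tail <- function(k, n, q) {
  if (k <= 0) return(1)
  ks <- k:n
  sum(exp(lchoose(n, ks) + ks * log(q) + (n - ks) * log1p(-q)))
}

## vectorised over k = 0..n: reverse cumulative sum of exact terms
oracle_binom_tail_all <- function(n, q) {
  ks <- 0:n
  terms <- exp(lchoose(n, ks) + ks * log(q) + (n - ks) * log1p(-q))
  rev(cumsum(rev(terms)))
}

## quadratic top-k selection + mean
oracle_topk_mean <- function(values, chrom, start, k) {
  ord <- order(-values, chrom, start)
  mean(values[ord][seq_len(k)])
}

## brute-force per-bin recount of contact midpoints and sites
oracle_bin_value <- function(contacts, sites, chrom, bin_start, bin_end) {
  mids <- (contacts$start + contacts$end) %/% 2L
  n <- sum(contacts$chrom == chrom & mids >= bin_start & mids < bin_end)
  s <- sum(sites >= bin_start & sites < bin_end)
  if (s == 0) return(NA_real_)
  n / s
}

## shared small fixtures ----------------------------------------------------

toy_bridge <- function(...) bridge_spec("ACGGTCATTCGAGGTCCAGTACGC", ...)

## a tiny deterministic simulated dataset, cached per session
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42, n_reads = 3000,
                        chrom_lengths = c(chr2L = 120000L, chr3R = 120000L,
                                          chrX = 60000L),
                        n_genes = 30L)
      cache <<- c(simulate_dataset(cfg), list(cfg = cfg))
    }
    cache
  }
})
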