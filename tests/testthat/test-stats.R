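fake_track <- function(chrom, value, bin_size = 2000L) {
  n <- length(value)
  data.table::data.table(chrom = chrom, start = (seq_len(n) - 1L) * bin_size,
                         end = seq_len(n) * bin_size, raw = value,
                         sites = 1L, value = value, included = TRUE)
}

test_that("cpkm_table computes length- and depth-normalised contact rates", {
  cts <- data.frame(gene_id = rep(c("g1", "g2"), c(500, 5)))
  lens <- c(g1 = 2000, g2 = 1000, g3 = 800)
  s <- cpkm_table(cts, lens, total_contacts = 1e7)
  expect_equal(s$cpkm[s$gene_id == "g1"], 25.0)  # 500/(2kb)/(10M/1e6)
  expect_equal(s$cpkm[s$gene_id == "g3"], 0)     # zero contacts -> 0
  expect_true(s$below_floor[s$gene_id == "g3"])
  expect_false(s$below_floor[s$gene_id == "g1"])

  ## fraction below the floor matches a direct recount
  sim <- small_sim()
  res <- run_pipeline(sim$reads, sim$cfg$bridge, sim$annotations, sim$genome)
  ann <- sim$annotations[sim$annotations$class != "spike", ]
  s <- cpkm_table(res$contacts, setNames(ann$length, ann$gene_id))
  recount <- sapply(s$gene_id, function(g) sum(res$contacts$gene_id == g))
  cp <- recount / (s$transcript_length / 1e3) / (nrow(res$contacts) / 1e6)
  expect_equal(mean(s$below_floor), mean(cp < 10))
  expect_equal(s$cpkm, unname(cp))

  expect_message(cpkm_table(data.frame(gene_id = "nolen"), c(g1 = 100)),
                 "skipped")
})

test_that("select_enriched applies strict floors and recovers planted RNAs", {
  ## boundary strictness: cpkm exactly at the floor is not selected; the
  ## bulk of the catalog has fold ~ 1 so the median scaling is the identity
  set.seed(100)
  bulk <- rlnorm(50, 3, 0.5)
  s <- data.table::data.table(
    gene_id = c(sprintf("bulk%02d", 1:50), "a", "b"),
    cpkm = c(bulk, 100, 200),
    expression = c(bulk, 0.01, 0.01))
  out <- select_enriched(s, cpkm_floor = 100, fold_floor = 10)
  expect_false(out$selected[out$gene_id == "a"])   # 100 is not > 100
  expect_true(out$selected[out$gene_id == "b"])
  expect_false(any(out$selected[grepl("bulk", out$gene_id)]))

  ## planted mixture: 10 chromatin-enriched among 200
  set.seed(101)
  n <- 200
  expr <- rlnorm(n, 3, 0.5)
  cpkm <- expr * rlnorm(n, 0, 0.15)          # fold ~ 1 for the bulk
  planted <- sample(n, 10)
  cpkm[planted] <- pmax(expr[planted] * 60, 150)
  s <- data.table::data.table(gene_id = sprintf("g%03d", 1:n),
                              cpkm = cpkm, expression = expr)
  out <- select_enriched(s)
  expect_setequal(out$gene_id[out$selected], sprintf("g%03d", sort(planted)))
})

test_that("chrom_enrichment fold and p-value match the exact tail oracle", {
  gi <- genome_index(c(chrA = 80000L, chrX = 20000L),
                     list(chrA = integer(), chrX = integer()))
  ## uniform occupancy -> fold 1
  cts <- data.frame(chrom = rep(c("chrA", "chrX"), c(80, 20)))
  r <- chrom_enrichment(cts, "chrX", gi)
  expect_equal(r$fold, 1.0)
  expect_equal(r$expected_fraction, 0.2)

  ## n=100, k=80, q=0.2 -> fold 4, p equals brute-force summation
  cts <- data.frame(chrom = rep(c("chrA", "chrX"), c(20, 80)))
  r <- chrom_enrichment(cts, "chrX", gi)
  expect_equal(r$fold, 4.0)
  expect_equal(r$p_value, oracle_binom_tail(80, 100, 0.2), tolerance = 1e-12)

  ## degenerate tail: no hits -> fold 0, p = 1
  cts <- data.frame(chrom = rep("chrA", 10))
  r <- chrom_enrichment(cts, "chrX", gi)
  expect_equal(r$fold, 0)
  expect_equal(r$p_value, 1.0)

  expect_error(chrom_enrichment(cts, "chrNope", gi), "absent")
  expect_error(chrom_enrichment(cts[0, , drop = FALSE], "chrX", gi),
               "no contacts")
})

test_that("binomial upper tails match exact summation on a sampled grid", {
  set.seed(111)
  gi <- genome_index(c(chrA = 8L, chrX = 2L),
                     list(chrA = integer(), chrX = integer()))
  for (i in 1:50) {
    n <- sample(1000, 1)
    k <- sample(0:n, 1)
    cts <- data.frame(chrom = rep(c("chrX", "chrA"), c(k, n - k)))
    r <- chrom_enrichment(cts, "chrX", gi)
    want <- oracle_binom_tail(k, n, 0.2)
    expect_equal(r$p_value, want, tolerance = 1e-12)
  }
})

test_that("snr equals the quadratic top-k oracle on constructed tracks", {
  ## uniform constant track -> snr 1 for any seed
  tr <- rbind(fake_track("chrX", rep(3, 5000)), fake_track("chr2L", rep(3, 5000)))
  for (s in c(1, 7, 99))
    expect_equal(snr(tr, "chrX", "chr2L", seed = s)$snr, 1.0)

  ## top-300 chrX bins at 10, autosomes at 2 -> snr 5
  set.seed(121)
  xvals <- c(rep(10, 300), rep(1, 4700))[sample(5000)]
  tr <- rbind(fake_track("chrX", xvals), fake_track("chr2L", rep(2, 5000)))
  r <- snr(tr, "chrX", "chr2L", seed = 4)
  expect_equal(r$snr, 5.0)
  expect_equal(r$signal_mean, 10.0)

  ## random track: signal mean equals the quadratic oracle exactly
  vals <- rexp(10000)
  tr <- rbind(fake_track("chrX", vals[1:5000]),
              fake_track("chr3R", vals[5001:10000] + 0.5))
  r <- snr(tr, "chrX", "chr3R", seed = 9)
  xs <- tr[tr$chrom == "chrX", ]
  expect_equal(r$signal_mean,
               oracle_topk_mean(xs$value, xs$chrom, xs$start, 300))

  ## permuting row order changes nothing (same seed, coordinate selection)
  perm <- tr[sample(nrow(tr)), ]
  expect_equal(snr(perm, "chrX", "chr3R", seed = 9), r)

  expect_error(snr(fake_track("chrX", rep(1, 100)), "chrX", "chr2L"),
               "at least")
})

test_that("resolution_curve hits the exact endpoints", {
  gi <- genome_index(c(chr1 = 200000L),
                     list(chr1 = seq(10L, 199000L, by = 200L)))
  set.seed(131)
  mids <- sample(0:199999, 5000, replace = TRUE)
  cts <- data.frame(chrom = "chr1", start = mids, end = mids + 20L)
  rc_ <- resolution_curve(cts, cts, gi, windows = c(200L, 1000L, 5000L))
  expect_equal(rc_$rho, rep(1.0, 3))

  ## anti-ranked toy tracks -> rho = -1
  g2 <- genome_index(c(chr1 = 4000L), list(chr1 = seq(0L, 3996L, by = 100L)))
  a_mid <- rep(seq(50L, 3950L, by = 1000L), times = c(1, 2, 3, 4))
  b_mid <- rep(seq(50L, 3950L, by = 1000L), times = c(4, 3, 2, 1))
  ca <- data.frame(chrom = "chr1", start = a_mid, end = a_mid + 2L)
  cb <- data.frame(chrom = "chr1", start = b_mid, end = b_mid + 2L)
  rcv <- resolution_curve(ca, cb, g2, windows = 1000L)
  expect_equal(rcv$rho, -1.0)

  ## symmetry in the two arguments
  set.seed(132)
  mids2 <- sample(0:199999, 5000, replace = TRUE)
  cts2 <- data.frame(chrom = "chr1", start = mids2, end = mids2 + 20L)
  r1 <- resolution_curve(cts, cts2, gi, windows = c(1000L, 10000L))
  r2 <- resolution_curve(cts2, cts, gi, windows = c(1000L, 10000L))
  expect_equal(r1$rho, r2$rho)

  ## too few bins -> skipped with a message
  expect_message(
    out <- resolution_curve(ca, cb, g2, windows = 4000L), "skipped")
  expect_null(out)
})

test_that("rank correlation rises with window size for nested-noise pairs", {
  L <- 1000000L
  gi <- genome_index(c(chr1 = L), list(chr1 = seq(10L, L - 1000L, by = 200L)))
  windows <- c(50L, 250L, 1000L, 5000L, 25000L, 50000L)
  for (rep_seed in 1:3) {
    set.seed(400 + rep_seed)
    ## shared large-scale intensity over 50 kb blocks, independent fine noise
    blocks <- rexp(L / 50000L) + 0.05
    draw <- function(n) {
      blk <- sample(length(blocks), n, replace = TRUE, prob = blocks)
      pos <- (blk - 1L) * 50000L + sample(0:49999, n, replace = TRUE)
      data.frame(chrom = "chr1", start = pos, end = pos + 20L)
    }
    rcv <- resolution_curve(draw(30000), draw(30000), gi, windows = windows)
    expect_equal(rcv$window, windows)
    expect_true(all(diff(rcv$rho) >= -0.01),
                info = paste("replicate", rep_seed,
                             paste(round(rcv$rho, 3), collapse = " ")))
  }
})

test_that("tad_boundary_test recovers planted enrichment and is reproducible", {
  L <- 40000000L
  set.seed(141)
  sites <- sort(sample(0:(L - 5L), L %/% 200L))
  gi <- genome_index(c(chrA = L), list(chrA = sites))
  tads <- make_tads(gi, width = 80000L)
  expect_equal(nrow(tads), 500L)

  cts <- sample_tad_contacts(gi, 50000L, tads = tads, boundary_factor = 2,
                             seed = 51)
  r <- tad_boundary_test(cts, tads, gi, seed = 61)
  expect_gt(r$fold, 1.8)
  expect_lt(r$fold, 2.2)
  expect_lt(r$p_value, 0.01)

  ## same seed -> identical selection and p-value
  r2 <- tad_boundary_test(cts, tads, gi, seed = 61)
  expect_equal(r2, r)

  ## null: factor 1 -> fold near 1
  cts0 <- sample_tad_contacts(gi, 50000L, tads = tads, boundary_factor = 1,
                              seed = 52)
  r0 <- tad_boundary_test(cts0, tads, gi, seed = 62)
  expect_gt(r0$fold, 0.9)
  expect_lt(r0$fold, 1.1)

  expect_error(tad_boundary_test(cts, tads, gi, target_chroms = "chrZ"),
               "no TADs")
})

test_that("masked-length matching is honoured and cis contacts are excluded", {
  L <- 8000000L
  set.seed(151)
  gi <- genome_index(c(chrA = L), list(chrA = sort(sample(0:(L - 5L), L %/% 200L))))
  tads <- make_tads(gi, width = 80000L)
  masks <- data.frame(chrom = "chrA",
                      start = sort(sample(seq(0L, L - 3000L, by = 40000L), 150)))
  masks$end <- masks$start + sample(200:2500, 150, replace = TRUE)
  cts <- sample_tad_contacts(gi, 20000L, tads = tads, boundary_factor = 1,
                             seed = 53)
  r <- tad_boundary_test(cts, tads, gi, masks = masks, seed = 63)
  expect_gt(r$matching_p, 0.05)

  ## cis exclusion: a contact pile-up at the parent locus (sitting on a TAD
  ## edge) inflates the boundary fold unless the locus is excluded
  edge <- 160000L
  locus <- list(chrom = "chrA", start = edge - 500L, end = edge + 500L)
  clump <- data.frame(read_id = "c", gene_id = "simRNA",
                      rna_category = "ncRNA", sense = TRUE, chrom = "chrA",
                      start = edge + 90L, end = edge + 110L, dna_strand = "+")
  cts_cl <- rbind(cts, clump[rep(1, 4000), ])
  inflated <- tad_boundary_test(cts_cl, tads, gi, seed = 64)
  clean <- tad_boundary_test(cts_cl, tads, gi, parent_locus = locus, seed = 64)
  expect_gt(inflated$fold, clean$fold + 0.2)
  expect_gt(clean$fold, 0.9)
  expect_lt(clean$fold, 1.1)
})

test_that("spike_in_fp_rate reports fraction with Clopper-Pearson CI", {
  cts <- data.frame(gene_id = rep(c("g1", "g2"), c(4990, 10)))
  r <- spike_in_fp_rate(cts, "g2")
  expect_equal(r$fraction, 0.002)
  expect_equal(r$n_spike, 10L)
  want <- binom.test(10, 5000)$conf.int
  expect_equal(c(r$ci_low, r$ci_high), as.numeric(want))

  r0 <- spike_in_fp_rate(data.frame(gene_id = rep("g1", 100)), "sp")
  expect_equal(r0$fraction, 0)
  expect_error(spike_in_fp_rate(data.frame(gene_id = character()), "sp"),
               "no contacts")
})
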