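mk_contacts <- function(chrom, mid, w = 20L) {
  data.frame(read_id = sprintf("r%05d", seq_along(mid)), gene_id = "g",
             rna_category = "ncRNA", sense = TRUE, chrom = chrom,
             start = as.integer(mid - w %/% 2), end = as.integer(mid + w %/% 2),
             dna_strand = "+", stringsAsFactors = FALSE)
}

test_that("dpnII_sites records every GATC occurrence", {
  gi <- dpnII_sites(c(chr1 = "AAAA"))
  expect_equal(gi$sites$chr1, integer(0))

  gi <- dpnII_sites(c(chr1 = "AAGATCAA"))
  expect_equal(gi$sites$chr1, 2L)

  set.seed(71)
  sq <- rand_seq(100000)
  gi <- dpnII_sites(c(chr1 = sq))
  want <- as.integer(gregexpr("GATC", sq, fixed = TRUE)[[1]]) - 1L
  if (length(want) == 1 && want[1] == -2L) want <- integer(0)
  expect_equal(gi$sites$chr1, want)
})

test_that("coverage_track bins, normalises and excludes siteless bins", {
  ## chromosome with sites only in the first bin: 2 sites at 10, 50
  gi <- genome_index(c(chr1 = 400L), list(chr1 = c(10L, 50L)))
  cts <- mk_contacts("chr1", c(20, 60, 100, 150))  # all midpoints in bin 1
  tr <- coverage_track(cts, gi, bin_size = 200L)
  expect_equal(tr$raw, c(4, 0))
  expect_equal(tr$sites, c(2L, 0L))
  expect_equal(tr$value[1], 2.0)          # 4 contacts / 2 sites
  expect_false(tr$included[2])            # no sites -> excluded
  expect_true(is.na(tr$value[2]))

  ## chrX doubling: 3 contacts, 1 site -> 6.0
  gix <- genome_index(c(chrX = 200L), list(chrX = 10L))
  trx <- coverage_track(mk_contacts("chrX", c(20, 60, 100)), gix,
                        bin_size = 200L, male_x_doubling = TRUE)
  expect_equal(trx$value, 6.0)
  trx2 <- coverage_track(mk_contacts("chrX", c(20, 60, 100)), gix,
                         bin_size = 200L, male_x_doubling = FALSE)
  expect_equal(trx2$value, 3.0)

  expect_error(coverage_track(cts, gi, bin_size = 100L, step = 200L),
               "bin_size must be >= step")
})

test_that("raw counts are conserved and doubling is exactly x2", {
  sim <- small_sim()
  res <- run_pipeline(sim$reads, sim$cfg$bridge, sim$annotations, sim$genome)
  tr <- coverage_track(res$contacts, sim$index, bin_size = 200L,
                       normalize = "raw")
  expect_equal(sum(tr$raw), nrow(res$contacts))

  td <- coverage_track(res$contacts, sim$index, bin_size = 200L,
                       normalize = "raw", male_x_doubling = TRUE)
  expect_equal(td$raw[td$chrom == "chrX"], 2 * tr$raw[tr$chrom == "chrX"])
  expect_equal(td$raw[td$chrom != "chrX"], tr$raw[tr$chrom != "chrX"])
})

test_that("normalised values match brute-force recount on random bins", {
  sim <- small_sim()
  res <- run_pipeline(sim$reads, sim$cfg$bridge, sim$annotations, sim$genome)
  tr <- coverage_track(res$contacts, sim$index, bin_size = 200L)
  set.seed(81)
  idx <- sample(nrow(tr), 1000, replace = TRUE)
  for (i in unique(idx)) {
    want <- oracle_bin_value(res$contacts, sim$index$sites[[tr$chrom[i]]],
                             tr$chrom[i], tr$start[i], tr$end[i])
    if (is.na(want)) expect_false(tr$included[i])
    else expect_equal(tr$value[i], want)
  }
})

test_that("sliding track sampled at tile offsets equals the tiled track", {
  sim <- small_sim()
  res <- run_pipeline(sim$reads, sim$cfg$bridge, sim$annotations, sim$genome)
  tiled <- coverage_track(res$contacts, sim$index, bin_size = 200L, step = 200L)
  slid <- coverage_track(res$contacts, sim$index, bin_size = 200L, step = 20L)
  sub <- slid[slid$start %% 200L == 0L, ]
  m <- merge(as.data.frame(tiled), as.data.frame(sub),
             by = c("chrom", "start"))
  expect_gt(nrow(m), 0)
  ## same bin extent -> same raw count (trailing partial bins may differ)
  same <- m$end.x == m$end.y
  expect_equal(m$raw.x[same], m$raw.y[same])
})

test_that("raw/dpnII tracks are additive over contact-set union", {
  sim <- small_sim()
  res <- run_pipeline(sim$reads, sim$cfg$bridge, sim$annotations, sim$genome)
  cts <- res$contacts
  a <- cts[seq_len(nrow(cts)) %% 2 == 0, ]
  b <- cts[seq_len(nrow(cts)) %% 2 == 1, ]
  ta <- coverage_track(a, sim$index, bin_size = 200L)
  tb <- coverage_track(b, sim$index, bin_size = 200L)
  tu <- coverage_track(cts, sim$index, bin_size = 200L)
  expect_equal(tu$raw, ta$raw + tb$raw)
  inc <- tu$included
  expect_equal(tu$value[inc], ta$value[inc] + tb$value[inc])
})

test_that("zscore_track standardises to mean 0, sd 1 and matches a two-pass oracle", {
  sim <- small_sim()
  res <- run_pipeline(sim$reads, sim$cfg$bridge, sim$annotations, sim$genome)
  tr <- coverage_track(res$contacts, sim$index, bin_size = 2000L)
  z <- zscore_track(tr)
  v <- z$value[z$included]
  expect_equal(mean(v), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(v^2)), 1, tolerance = 1e-12)   # population sd

  ## independent two-pass oracle
  inc <- tr$included
  total <- sum(tr$raw[inc]); tsites <- sum(tr$sites[inc])
  expd <- total * tr$sites[inc] / tsites
  lr <- log2((tr$raw[inc] + 1) / (expd + 1))
  mu <- sum(lr) / length(lr)
  sg <- sqrt(sum((lr - mu)^2) / length(lr))
  expect_equal(v, (lr - mu) / sg, tolerance = 1e-12)
})

test_that("zscore arithmetic on a two-bin toy and degenerate error", {
  ## two bins, equal sites; raw chosen so log2 ratios are {0, 2}:
  ## expected = total*1/2 = 2.5 per bin; raw {1.4, 13} with pc 1 gives
  ## log2(2.4/3.5), ... easier: check the standardisation identity directly
  gi <- genome_index(c(chr1 = 400L), list(chr1 = c(10L, 210L)))
  cts <- mk_contacts("chr1", c(rep(20, 6), rep(220, 1)))
  tr <- coverage_track(cts, gi, bin_size = 200L)
  z <- zscore_track(tr)
  v <- z$value[z$included]
  ## two-point z is exactly {+1, -1} under the population sigma
  expect_equal(v, c(1, -1))
  ## log2 ratios {0, 2} map to z {-1, +1}
  lrs <- c(0, 2)
  expect_equal((lrs - mean(lrs)) / sqrt(mean((lrs - mean(lrs))^2)), c(-1, 1))

  ## constant track: sigma = 0 -> explicit error
  ctsu <- mk_contacts("chr1", c(20, 220))
  tru <- coverage_track(ctsu, gi, bin_size = 200L)
  expect_error(zscore_track(tru), "degenerate")
})

test_that("metaprofile normalises to 1 on uniform tracks and detects enrichment", {
  ## uniform synthetic track
  gi <- genome_index(c(chr1 = 100000L),
                     list(chr1 = seq(10L, 99000L, by = 200L)))
  set.seed(91)
  mids <- sample(500:99500, 4000, replace = TRUE)
  tr <- coverage_track(mk_contacts("chr1", mids), gi, bin_size = 200L)
  regions <- data.frame(chrom = "chr1",
                        start = seq(10000L, 80000L, by = 10000L))
  regions$end <- regions$start + 2000L
  rnd <- data.frame(chrom = "chr1", start = seq(5000L, 85000L, by = 8000L))
  rnd$end <- rnd$start + 2000L
  p <- metaprofile(tr, regions, flank = 2000L, n_bins = 10L,
                   random_regions = rnd, n_flank_bins = 5L)
  expect_equal(nrow(p), 20L)
  expect_lt(max(abs(p$value - 1)), 0.5)     # flat within sampling noise

  ## signal only inside regions -> body > 1 > flanks
  mids2 <- unlist(lapply(seq_len(nrow(regions)), function(i)
    sample(regions$start[i]:regions$end[i], 300, replace = TRUE)))
  tr2 <- coverage_track(mk_contacts("chr1", mids2), gi, bin_size = 200L)
  p2 <- metaprofile(tr2, regions, flank = 2000L, n_bins = 10L,
                    random_regions = rnd, n_flank_bins = 5L)
  body <- p2$value[p2$section == "body"]
  flank <- p2$value[p2$section != "body"]
  expect_true(all(body > 1))
  expect_true(mean(flank < 1) > 0.8)
})

test_that("a planted 2x gene-body enrichment is recovered within 10%", {
  L <- 6200000L
  gi <- genome_index(c(chr1 = L), list(chr1 = seq(10L, L - 1000L, by = 200L)))
  set.seed(92)
  ## 500 planted regions on a 12 kb grid; random regions sit in the gaps far
  ## enough that neither they nor their 2 kb flanks touch any planted region,
  ## so the normaliser measures pure background and the plateau reads the
  ## planted fold directly
  regions <- data.frame(chrom = "chr1", start = seq(4000L, by = 12000L,
                                                    length.out = 500L))
  regions$end <- regions$start + 1500L
  bg <- sample(0:(L - 1L), 180000, replace = TRUE)
  inside <- unlist(apply(regions, 1, function(r)
    sample(as.integer(r["start"]):as.integer(r["end"]), 45, replace = TRUE)))
  tr <- coverage_track(mk_contacts("chr1", c(bg, inside)), gi, bin_size = 200L)
  rnd <- data.frame(chrom = "chr1", start = regions$start + 5000L)
  rnd$end <- rnd$start + 1500L
  p <- metaprofile(tr, regions, flank = 2000L, n_bins = 10L,
                   random_regions = rnd, n_flank_bins = 5L)
  plateau <- mean(p$value[p$section == "body"][3:8])
  ## expected fold: bg density 0.06/bp, inside adds 0.06/bp -> 2.0
  expect_gt(plateau, 1.8)
  expect_lt(plateau, 2.2)
})

test_that("ATAC insertion shift follows the +4/-5 convention", {
  ## + strand fragment with 5' end at 100 -> 104
  plus <- data.frame(chrom = "chr1", start = 100L, end = 150L, strand = "+")
  expect_equal(shift_atac_insertions(plus)$pos, 104L)
  ## - strand fragment with 5' end at 200 (end-exclusive 201) -> 195
  minus <- data.frame(chrom = "chr1", start = 150L, end = 201L, strand = "-")
  expect_equal(shift_atac_insertions(minus)$pos, 195L)
  ## strand-flip of the same fragment gives distinct deterministic sites
  frag <- data.frame(chrom = "chr1", start = 100L, end = 201L,
                     strand = c("+", "-"))
  pos <- shift_atac_insertions(frag)$pos
  expect_equal(pos, c(104L, 195L))
  expect_error(shift_atac_insertions(
    data.frame(chrom = "chr1", start = 1L, end = 2L, strand = "*")), "strand")
})
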