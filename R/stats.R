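## Downstream statistics: CPKM summaries and chromatin-enriched RNA
## selection, chromosome enrichment (binomial), signal-to-noise, resolution
## curves, TAD-boundary enrichment testing and the spike-in false-positive
## estimator.

#' Contacts per kilobase per million (CPKM) summary table
#'
#' CPKM = contacts / (transcript kb) / (total contacts in millions): the
#' length- and depth-normalised per-RNA contact metric. RNAs below
#' \code{floor} CPKM are flagged as under the analysis floor.
#'
#' @param contacts contact table with gene_id.
#' @param transcript_lengths named numeric vector (bp) or data.frame with
#'   gene_id and length columns.
#' @param total_contacts denominator depth; defaults to the number of
#'   contacts in the final filtered table passed in.
#' @param expression optional named vector or data.frame (gene_id, value) of
#'   RNA-seq expression, carried through for fold-enrichment.
#' @param floor CPKM analysis floor (default 10).
#' @return data.table: gene_id, contact_count, transcript_length, cpkm,
#'   below_floor, expression (NA when not supplied). RNAs with missing
#'   lengths are skipped with a message.
#' @export
cpkm_table <- function(contacts, transcript_lengths,
                       total_contacts = nrow(contacts), expression = NULL,
                       floor = 10) {
  contacts <- as.data.table(contacts)
  if (is.data.frame(transcript_lengths))
    transcript_lengths <- stats::setNames(transcript_lengths$length,
                                          transcript_lengths$gene_id)
  if (is.data.frame(expression))
    expression <- stats::setNames(expression$value, expression$gene_id)
  if (total_contacts <= 0) stop("total_contacts must be positive", call. = FALSE)
  counts <- contacts[, .(contact_count = .N), by = gene_id]
  ## RNAs with a known length but zero contacts still appear, with CPKM 0
  zero <- setdiff(names(transcript_lengths), counts$gene_id)
  if (length(zero))
    counts <- rbind(counts, data.table(gene_id = zero, contact_count = 0L))
  counts[, transcript_length := transcript_lengths[gene_id]]
  nmiss <- sum(is.na(counts$transcript_length))
  if (nmiss) {
    message(nmiss, " RNA(s) without a transcript length skipped")
    counts <- counts[!is.na(transcript_length)]
  }
  if (any(counts$transcript_length <= 0))
    stop("transcript lengths must be positive", call. = FALSE)
  counts[, cpkm := contact_count / (transcript_length / 1e3) / (total_contacts / 1e6)]
  counts[, below_floor := cpkm < floor]
  counts[, expression := if (is.null(expression)) NA_real_ else
    unname(expression[gene_id])]
  setorder(counts, -cpkm)
  counts[]
}

#' Select chromatin-enriched RNAs
#'
#' Keeps RNAs whose CPKM exceeds \code{cpkm_floor} and whose fold-enrichment
#' of contacts over expression exceeds \code{fold_floor} (both strictly).
#' Because CPKM and expression live in different units, expression is first
#' median-scaled onto the CPKM scale, then a pseudocount is applied to both
#' before the ratio; this cross-unit normalisation is a package choice and
#' is recorded in the returned attributes.
#'
#' @param summaries output of \code{\link{cpkm_table}} with expression
#'   populated.
#' @param cpkm_floor strict lower bound on CPKM (default 100).
#' @param fold_floor strict lower bound on fold enrichment (default 10).
#' @param pseudocount added to numerator and denominator (default 0.1).
#' @return the summaries with fold_enrichment and logical selected columns;
#'   attribute \code{expression_scale} holds the applied scale factor.
#' @export
select_enriched <- function(summaries, cpkm_floor = 100, fold_floor = 10,
                            pseudocount = 0.1) {
  s <- as.data.table(summaries)
  need_cols(s, c("gene_id", "cpkm", "expression"), "summaries")
  if (all(is.na(s$expression)))
    stop("expression column must be populated for enrichment selection",
         call. = FALSE)
  med_c <- stats::median(s$cpkm[s$cpkm > 0], na.rm = TRUE)
  med_e <- stats::median(s$expression[s$expression > 0], na.rm = TRUE)
  scale <- if (is.finite(med_e) && med_e > 0) med_c / med_e else 1
  s[, fold_enrichment := (cpkm + pseudocount) /
        (expression * scale + pseudocount)]
  s[, selected := !is.na(fold_enrichment) & cpkm > cpkm_floor &
        fold_enrichment > fold_floor]
  setattr(s, "expression_scale", scale)
  s[]
}

#' Chromosome enrichment of one RNA's contacts
#'
#' Compares the observed fraction of an RNA's contacts on a target
#' chromosome with the fraction expected if contacts were distributed
#' uniformly over total chromosomal sequence space, and computes a
#' one-tailed cumulative binomial p-value for observing at least that many
#' contacts on the target.
#'
#' @param contacts contacts of a single RNA.
#' @param target_chrom chromosome to test (e.g. \code{"chrX"}).
#' @param index a \code{\link{genome_index}} giving chromosome lengths.
#' @return list: fold, p_value, n_total, n_target, expected_fraction.
#' @export
chrom_enrichment <- function(contacts, target_chrom, index) {
  stopifnot(inherits(index, "genome_index"))
  if (!target_chrom %in% names(index$chrom_lengths))
    stop("target chromosome ", target_chrom, " absent from the genome index",
         call. = FALSE)
  contacts <- as.data.table(contacts)
  n_total <- nrow(contacts)
  if (n_total == 0L) stop("no contacts supplied", call. = FALSE)
  q <- index$chrom_lengths[[target_chrom]] / sum(as.numeric(index$chrom_lengths))
  n_target <- sum(contacts$chrom == target_chrom)
  fold <- (n_target / n_total) / q
  ## upper-tail P[X >= n_target]; pbinom is the numerically stable route
  p <- stats::pbinom(n_target - 1L, n_total, q, lower.tail = FALSE)
  list(fold = fold, p_value = p, n_total = n_total, n_target = n_target,
       expected_fraction = q)
}

#' Signal-to-noise ratio of an X-coating RNA track
#'
#' Signal is the mean of the \code{n_bins} highest-value included bins on
#' the X chromosome (ties at the threshold broken by coordinate order);
#' noise is the mean of \code{n_bins} included autosomal bins sampled
#' uniformly without replacement under \code{seed}. The track should already
#' be restricted to the chromosomes and loci the analysis admits (excluded
#' scaffolds, blacklist, the RNA's own locus).
#'
#' @param track a \code{binned_track} (typically 2 kb, DpnII-normalised).
#' @param x_chrom chromosome carrying the signal.
#' @param autosomes chromosomes to draw noise bins from.
#' @param n_bins bins per class (default 300).
#' @param seed RNG seed for the noise draw.
#' @param exclude_regions optional data.frame of intervals whose bins are
#'   removed before the computation (e.g. the RNA's parent locus).
#' @return list: snr, signal_mean, noise_mean, n_bins, seed.
#' @export
snr <- function(track, x_chrom = "chrX", autosomes, n_bins = 300L, seed = 1L,
                exclude_regions = NULL) {
  tr <- as.data.table(track)[included == TRUE]
  if (!is.null(exclude_regions))
    tr <- tr[!overlaps_any(tr, merge_intervals(exclude_regions))]
  xs <- tr[chrom == x_chrom]
  as_ <- tr[chrom %in% autosomes]
  if (nrow(xs) < n_bins || nrow(as_) < n_bins)
    stop("need at least ", n_bins, " included bins on chrX and on autosomes",
         call. = FALSE)
  setorder(xs, -value, chrom, start)
  signal <- mean(xs$value[seq_len(n_bins)])
  ## noise bins are drawn from coordinate-sorted bins so the selection is a
  ## function of (seed, coordinates), not of input row order
  setorder(as_, chrom, start)
  set.seed(as.integer(seed))
  noise <- mean(as_$value[sample.int(nrow(as_), n_bins)])
  if (noise == 0) stop("degenerate noise: mean of sampled autosome bins is 0",
                       call. = FALSE)
  list(snr = signal / noise, signal_mean = signal, noise_mean = noise,
       n_bins = n_bins, seed = seed)
}

#' Resolution curve: rank correlation versus bin size
#'
#' Re-bins two contact sets at a series of window sizes and reports the
#' Spearman rank correlation of counts-per-bin over the bins both tracks
#' retain (bins with DpnII sites, outside any exclusion set). Rising
#' correlation with window size indicates the scale at which the two assays
#' agree.
#'
#' @param contacts_a,contacts_b two contact tables on the same genome.
#' @param index a \code{\link{genome_index}}.
#' @param windows vector of window sizes in bp.
#' @param exclude_regions optional intervals removed from both tracks.
#' @return data.frame: window, rho, n_bins. Windows with fewer than 3 shared
#'   bins are skipped with a message.
#' @export
resolution_curve <- function(contacts_a, contacts_b, index,
                             windows = c(50L, 200L, 1000L, 5000L, 20000L,
                                         100000L, 1000000L),
                             exclude_regions = NULL) {
  iset <- if (is.null(exclude_regions)) NULL else merge_intervals(exclude_regions)
  rows <- lapply(windows, function(w) {
    ta <- coverage_track(contacts_a, index, bin_size = w, step = w,
                         normalize = "raw")
    tb <- coverage_track(contacts_b, index, bin_size = w, step = w,
                         normalize = "raw")
    keep <- ta$sites > 0L
    if (!is.null(iset)) keep <- keep & !overlaps_any(ta, iset)
    if (sum(keep) < 3L) {
      message("window ", w, ": fewer than 3 shared bins, skipped")
      return(NULL)
    }
    data.frame(window = w,
               rho = stats::cor(ta$raw[keep], tb$raw[keep], method = "spearman"),
               n_bins = sum(keep))
  })
  do.call(rbind, rows)
}

## masked-length stratification: 50 bp bins to 1 kb, 500 bp bins to 20 kb
masked_length_bin <- function(x) {
  breaks <- c(seq(0L, 1000L, by = 50L), seq(1500L, 20000L, by = 500L), Inf)
  findInterval(x, breaks, rightmost.closed = FALSE)
}

#' TAD-boundary enrichment test for one RNA's contacts
#'
#' Boundary regions are the 10 kb on either side of each TAD edge (20 kb
#' total); midpoint control regions are 10 kb either side of the TAD
#' midpoint rounded down to a 10-kb multiple, so both region classes align
#' with the 10-kb bins TADs are called on. Regions overlapping the blacklist
#' are removed; cis contacts (within the RNA's parent locus plus or minus
#' 2 kb) are excluded. Per-region contact counts are DpnII-normalised, the
#' two classes are matched on repeat-masked base pairs by stratified
#' subsampling, and a one-sided Wilcoxon rank-sum test (boundary greater
#' than midpoint) is computed together with the mean fold.
#'
#' @param contacts contacts of one RNA.
#' @param tads data.frame of TAD intervals (chrom/start/end).
#' @param index a \code{\link{genome_index}}.
#' @param masks optional repeat-mask intervals used for the matching.
#' @param blacklist optional intervals; overlapping regions are dropped.
#' @param parent_locus optional list/row (chrom, start, end) of the RNA's
#'   gene; contacts within it plus or minus \code{cis_pad} are removed.
#' @param target_chroms optionally restrict TADs to these chromosomes (an
#'   X-coating RNA is only tested on X-chromosome TADs).
#' @param halfwidth region half-width in bp (default 10 kb).
#' @param cis_pad padding around the parent locus (default 2 kb).
#' @param seed RNG seed for the stratified subsampling.
#' @return list: fold, statistic, p_value, n_per_class, matching_p (Wilcoxon
#'   on masked lengths after matching; should be non-significant), seed.
#' @export
tad_boundary_test <- function(contacts, tads, index, masks = NULL,
                              blacklist = NULL, parent_locus = NULL,
                              target_chroms = NULL, halfwidth = 10000L,
                              cis_pad = 2000L, seed = 1L) {
  stopifnot(inherits(index, "genome_index"))
  tads <- as.data.table(tads)
  if (!is.null(target_chroms)) tads <- tads[chrom %in% target_chroms]
  if (nrow(tads) == 0L) stop("no TADs on the required chromosome(s)", call. = FALSE)
  lens <- index$chrom_lengths
  edges <- unique(rbind(tads[, .(chrom, pos = start)], tads[, .(chrom, pos = end)]))
  bound <- edges[, .(chrom, start = pos - halfwidth, end = pos + halfwidth)]
  mids <- tads[, .(chrom, mp = ((start + end) %/% 2L) %/% 10000L * 10000L)]
  midr <- mids[, .(chrom, start = mp - halfwidth, end = mp + halfwidth)]
  regions <- rbind(cbind(bound, class = "boundary"), cbind(midr, class = "midpoint"))
  regions <- unique(regions)
  regions <- regions[start >= 0L & end <= lens[chrom]]
  if (!is.null(blacklist))
    regions <- regions[!overlaps_any(regions, merge_intervals(blacklist))]
  contacts <- as.data.table(contacts)
  if (!is.null(parent_locus)) {
    cis <- data.frame(chrom = parent_locus$chrom,
                      start = max(0L, parent_locus$start - cis_pad),
                      end = parent_locus$end + cis_pad)
    contacts <- contacts[!overlaps_any(contacts, merge_intervals(cis))]
  }
  ## per-region DpnII-normalised contact counts + masked bp
  mset <- if (is.null(masks)) NULL else merge_intervals(masks)
  regions[, id := .I]
  per <- regions[, {
    ch <- chrom; a <- start; b <- end
    mid <- contacts[chrom == ch & (start + end) %/% 2L >= a &
                      (start + end) %/% 2L < b, .N]
    s <- index$sites[[ch]]
    ns <- if (is.null(s)) 0L else sum(s >= a & s < b)
    mbp <- 0L
    if (!is.null(mset)) {
      mm <- mset[chrom == ch]
      if (nrow(mm))
        mbp <- sum(pmax(0L, pmin(mm$end, b) - pmax(mm$start, a)))
    }
    list(count = mid, sites = ns, masked = mbp)
  }, by = .(id, chrom, start, end, class)]
  per <- per[sites > 0L]
  per[, value := count / sites]
  per[, stratum := masked_length_bin(masked)]
  ## stratified subsampling to the smaller class within each masked-bp bin
  set.seed(as.integer(seed))
  keep <- per[, {
    b <- .I[class == "boundary"]; m <- .I[class == "midpoint"]
    k <- min(length(b), length(m))
    if (k == 0L) integer(0)
    else c(if (length(b) > k) sample(b, k) else b,
           if (length(m) > k) sample(m, k) else m)
  }, by = stratum]$V1
  matched <- per[sort(keep)]
  bv <- matched[class == "boundary", value]
  mv <- matched[class == "midpoint", value]
  if (length(bv) < 3L) stop("too few matched regions for the test", call. = FALSE)
  wt <- if (length(unique(c(bv, mv))) < 2L)
    list(statistic = c(W = length(bv) * length(mv) / 2), p.value = 1)
  else stats::wilcox.test(bv, mv, alternative = "greater", exact = FALSE,
                          correct = TRUE)
  mb <- matched[class == "boundary", masked]
  mm2 <- matched[class == "midpoint", masked]
  match_p <- if (length(unique(c(mb, mm2))) < 2L) 1
             else stats::wilcox.test(mb, mm2, exact = FALSE)$p.value
  list(fold = mean(bv) / mean(mv), statistic = unname(wt$statistic),
       p_value = wt$p.value, n_per_class = length(bv),
       matching_p = match_p, seed = seed)
}

#' Spike-in false-positive contact rate
#'
#' Spike-in RNAs are added after lysis, so any contact they form is a false
#' positive (diffusion or re-ligation). Reports the fraction of contacts
#' involving a spike-in transcript with its Clopper-Pearson 95\% interval.
#'
#' @param contacts contact table.
#' @param spike_gene_ids gene IDs of the spike-in transcripts.
#' @return list: fraction, n_spike, n_total, ci_low, ci_high.
#' @export
spike_in_fp_rate <- function(contacts, spike_gene_ids) {
  contacts <- as.data.table(contacts)
  n <- nrow(contacts)
  if (n == 0L) stop("no contacts supplied", call. = FALSE)
  k <- sum(contacts$gene_id %in% spike_gene_ids)
  ci <- stats::binom.test(k, n)$conf.int
  list(fraction = k / n, n_spike = k, n_total = n,
       ci_low = ci[1], ci_high = ci[2])
}
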