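## Coverage tracks: DpnII site indexing, fixed/sliding-window binned
## coverage with restriction-site normalization, log2 observed/expected
## z-score transforms, region metaprofiles and the ATAC insertion-site
## shift convention.

#' Construct a genome index
#'
#' Chromosome lengths plus the 0-based position of every DpnII (GATC)
#' recognition site, the quantity used to normalise coverage for restriction
#' fragment density.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param sites named list (same names) of sorted 0-based GATC start
#'   positions.
#' @param het_chroms optional heterochromatic scaffold names.
#' @return object of class \code{genome_index}.
#' @export
genome_index <- function(chrom_lengths, sites, het_chroms = character()) {
  stopifnot(!is.null(names(chrom_lengths)), all(names(sites) %in% names(chrom_lengths)))
  sites <- sites[names(chrom_lengths)[names(chrom_lengths) %in% names(sites)]]
  missing <- setdiff(names(chrom_lengths), names(sites))
  for (m in missing) sites[[m]] <- integer(0)
  sites <- sites[names(chrom_lengths)]
  for (ch in names(sites)) {
    s <- as.integer(sort(sites[[ch]]))
    if (length(s) && (s[1] < 0L || s[length(s)] + 4L > chrom_lengths[[ch]]))
      stop("DpnII site outside chromosome bounds on ", ch, call. = FALSE)
    sites[[ch]] <- s
  }
  structure(list(chrom_lengths = chrom_lengths, sites = sites,
                 het_chroms = het_chroms),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("genome_index: %d chromosome(s), %.0f bp, %d DpnII sites\n",
              length(x$chrom_lengths), sum(as.numeric(x$chrom_lengths)),
              sum(lengths(x$sites))))
  invisible(x)
}

#' Locate DpnII (GATC) sites in a genome
#'
#' Records every forward-strand GATC occurrence once; the site is
#' strand-symmetric so the forward scan is complete.
#'
#' @param genome named character vector of chromosome sequences, a
#'   DNAStringSet, or a FASTA path.
#' @param het_chroms passed through to \code{\link{genome_index}}.
#' @return a \code{\link{genome_index}}.
#' @export
dpnII_sites <- function(genome, het_chroms = character()) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  stopifnot(!is.null(names(genome)))
  m <- Biostrings::vmatchPattern("GATC", genome)
  sites <- lapply(m, function(ir) IRanges::start(ir) - 1L)
  names(sites) <- names(genome)
  genome_index(stats::setNames(Biostrings::width(genome), names(genome)),
               sites, het_chroms = het_chroms)
}

bin_starts <- function(len, step) seq.int(0L, by = step, length.out = ceiling(len / step))

#' Binned coverage track from contacts
#'
#' Each contact is assigned to bins by the midpoint of its DNA interval.
#' With \code{step == bin_size} the bins tile the chromosome; with
#' \code{step < bin_size} they slide. When \code{male_x_doubling}, raw
#' counts on the X chromosome (and its heterochromatic scaffold) are doubled
#' before normalization to compensate for the single X in male cells.
#' Restriction-site normalization divides the raw count by the number of
#' GATC sites in the bin; bins without a site are marked excluded and carry
#' no value.
#'
#' @param contacts contact table (chrom/start/end at minimum).
#' @param index a \code{\link{genome_index}}.
#' @param bin_size bin width in bp (display tracks commonly 200, z-score
#'   tracks 2000).
#' @param step distance between bin starts; defaults to \code{bin_size}.
#' @param normalize \code{"dpnii"} (default) or \code{"raw"}.
#' @param male_x_doubling double raw chrX/chrXHet counts first.
#' @param x_chroms chromosome names treated as X for doubling.
#' @return a \code{binned_track}: data.table(chrom, start, end, raw, sites,
#'   value, included) with attributes bin_size, step, normalization.
#' @export
coverage_track <- function(contacts, index, bin_size = 200L, step = bin_size,
                           normalize = c("dpnii", "raw"),
                           male_x_doubling = FALSE,
                           x_chroms = c("chrX", "chrXHet")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(index, "genome_index"))
  bin_size <- as.integer(bin_size); step <- as.integer(step)
  if (bin_size < step) stop("bin_size must be >= step", call. = FALSE)
  contacts <- as.data.table(contacts)
  pieces <- lapply(names(index$chrom_lengths), function(ch) {
    len <- index$chrom_lengths[[ch]]
    st <- bin_starts(len, step)
    en <- pmin(st + bin_size, len)
    bins <- IRanges::IRanges(st + 1L, en)
    mid <- contacts[chrom == ch, (start + end) %/% 2L]
    raw <- IRanges::countOverlaps(bins, IRanges::IRanges(mid + 1L, width = 1L))
    s <- index$sites[[ch]]
    sites <- IRanges::countOverlaps(bins, IRanges::IRanges(s + 1L, width = 1L))
    data.table(chrom = ch, start = st, end = en, raw = as.numeric(raw),
               sites = as.integer(sites))
  })
  tr <- rbindlist(pieces)
  if (male_x_doubling) tr[chrom %in% x_chroms, raw := raw * 2]
  if (normalize == "dpnii") {
    tr[, included := sites > 0L]
    tr[, value := ifelse(included, raw / sites, NA_real_)]
  } else {
    tr[, included := TRUE]
    tr[, value := raw]
  }
  setattr(tr, "bin_size", bin_size)
  setattr(tr, "step", step)
  setattr(tr, "normalization", normalize)
  setattr(tr, "class", c("binned_track", class(tr)))
  tr[]
}

#' Z-score transform of a binned track
#'
#' Computes the expected contacts per bin under a uniform null driven by
#' DpnII site density (expected = total contacts x bin sites / total sites
#' over included bins), takes the log2 observed/expected ratio with a
#' pseudocount, and standardises it by the whole-genome mean and standard
#' deviation over included bins.
#'
#' @param track a tiled \code{binned_track} (step == bin_size) carrying raw
#'   counts.
#' @param pseudocount added to both observed and expected before the log2.
#' @return a \code{binned_track} with normalization \code{"zscore"}; z values
#'   have mean 0 and sd 1 over included bins.
#' @export
zscore_track <- function(track, pseudocount = 1) {
  stopifnot(inherits(track, "binned_track"))
  if (attr(track, "step") != attr(track, "bin_size"))
    stop("z-score transform requires a tiled track (step == bin_size)", call. = FALSE)
  tr <- copy(as.data.table(track))
  tr[, included := sites > 0L]
  total <- sum(tr$raw[tr$included])
  total_sites <- sum(tr$sites[tr$included])
  if (total_sites == 0L) stop("no included bins with DpnII sites", call. = FALSE)
  tr[, expected := ifelse(included, total * sites / total_sites, NA_real_)]
  tr[, ratio := ifelse(included, log2((raw + pseudocount) / (expected + pseudocount)),
                       NA_real_)]
  mu <- mean(tr$ratio[tr$included])
  ## population sigma: the z-score is standardised against the whole-genome
  ## distribution itself, so a two-bin toy with log2 ratios {0,2} gives
  ## z = {-1,+1} exactly
  sig <- sqrt(mean((tr$ratio[tr$included] - mu)^2))
  if (!is.finite(sig) || sig == 0)
    stop("degenerate track: zero variance of log2 ratios, z-score undefined",
         call. = FALSE)
  tr[, value := ifelse(included, (ratio - mu) / sig, NA_real_)]
  tr[, c("expected", "ratio") := NULL]
  setattr(tr, "bin_size", attr(track, "bin_size"))
  setattr(tr, "step", attr(track, "step"))
  setattr(tr, "normalization", "zscore")
  setattr(tr, "zscore_params", list(mu = mu, sigma = sig, pseudocount = pseudocount))
  setattr(tr, "class", c("binned_track", "data.table", "data.frame"))
  tr[]
}

## mean track value over one genomic span [a,b) on chromosome ch
span_means <- function(track_dt, ch, a, b) {
  sel <- track_dt[chrom == ch & included == TRUE]
  if (nrow(sel) == 0L) return(rep(NA_real_, length(a)))
  q <- IRanges::IRanges(a + 1L, b)
  s <- IRanges::IRanges(sel$start + 1L, sel$end)
  ov <- IRanges::findOverlaps(q, s)
  out <- rep(NA_real_, length(a))
  if (length(ov)) {
    dt <- data.table(q = S4Vectors::queryHits(ov),
                     v = sel$value[S4Vectors::subjectHits(ov)])
    agg <- dt[, .(m = mean(v)), by = q]
    out[agg$q] <- agg$m
  }
  out
}

#' Metaprofile of a track over a region set
#'
#' Each region body is length-scaled into \code{n_bins} meta-bins and
#' flanked by fixed-width windows split into \code{n_flank_bins} meta-bins
#' per side. The per-meta-bin mean across regions is divided by the mean of
#' the same profile computed over \code{random_regions}, so a uniform track
#' reads 1.0 everywhere. Regions running past a chromosome end are clipped
#' (with a message); strand, when present, flips the profile so all regions
#' read 5' to 3'.
#'
#' @param track a \code{binned_track}.
#' @param regions data.frame chrom/start/end (optional strand).
#' @param flank flank width in bp on each side (default 2000).
#' @param n_bins meta-bins across the region body.
#' @param random_regions matched random regions used as the normaliser.
#' @param n_flank_bins meta-bins per flank.
#' @return data.frame: meta_bin, section (flank5/body/flank3), value
#'   (fold-change over the random mean), raw_value.
#' @export
metaprofile <- function(track, regions, flank = 2000L, n_bins = 20L,
                        random_regions, n_flank_bins = 10L) {
  regions <- as.data.table(regions)
  if (nrow(regions) == 0L) stop("regions must be non-empty", call. = FALSE)
  prof <- meta_matrix(track, regions, flank, n_bins, n_flank_bins)
  rnd <- meta_matrix(track, as.data.table(random_regions), flank, n_bins, n_flank_bins)
  raw <- colMeans(prof, na.rm = TRUE)
  norm <- mean(colMeans(rnd, na.rm = TRUE), na.rm = TRUE)
  k <- length(raw)
  data.frame(meta_bin = seq_len(k),
             section = rep(c("flank5", "body", "flank3"),
                           c(n_flank_bins, n_bins, n_flank_bins)),
             value = raw / norm, raw_value = raw)
}

meta_matrix <- function(track, regions, flank, n_bins, n_flank_bins) {
  track_dt <- as.data.table(track)
  lens <- track_dt[, .(len = max(end)), by = chrom]
  k <- n_bins + 2L * n_flank_bins
  mat <- matrix(NA_real_, nrow(regions), k)
  clipped <- 0L
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]
    L <- lens[chrom == ch, len]
    if (!length(L)) next
    a <- regions$start[i]; b <- regions$end[i]
    fl <- flank / n_flank_bins
    bw <- (b - a) / n_bins
    starts <- c(a - flank + fl * (seq_len(n_flank_bins) - 1L),
                a + bw * (seq_len(n_bins) - 1L),
                b + fl * (seq_len(n_flank_bins) - 1L))
    ends <- c(starts[seq_len(n_flank_bins)] + fl,
              a + bw * seq_len(n_bins),
              starts[n_bins + n_flank_bins + seq_len(n_flank_bins)] + fl)
    if (starts[1] < 0 || ends[k] > L) clipped <- clipped + 1L
    s2 <- pmax(0, floor(starts)); e2 <- pmin(L, ceiling(ends))
    ok <- e2 > s2
    v <- rep(NA_real_, k)
    v[ok] <- span_means(track_dt, ch, as.integer(s2[ok]), as.integer(e2[ok]))
    if (!is.null(regions$strand) && !is.na(regions$strand[i]) &&
        regions$strand[i] == "-") v <- rev(v)
    mat[i, ] <- v
  }
  if (clipped) message(clipped, " region(s) clipped at chromosome ends")
  mat
}

#' Shift ATAC fragment ends to transposase insertion sites
#'
#' The insertion site is the fragment 5' end shifted +4 bp on the plus
#' strand and -5 bp on the minus strand (the standard Tn5 offset).
#'
#' @param fragments data.frame chrom/start/end/strand (0-based half-open;
#'   strand \code{"+"} or \code{"-"}).
#' @return data.frame chrom, pos (0-based insertion site), strand.
#' @export
shift_atac_insertions <- function(fragments) {
  fragments <- as.data.table(fragments)
  need_cols(fragments, c("chrom", "start", "end", "strand"), "fragments")
  if (any(is.na(fragments$strand) | !fragments$strand %in% c("+", "-")))
    stop("every fragment must have strand '+' or '-'", call. = FALSE)
  five <- ifelse(fragments$strand == "+", fragments$start, fragments$end - 1L)
  pos <- ifelse(fragments$strand == "+", five + 4L, five - 5L)
  data.frame(chrom = fragments$chrom, pos = as.integer(pos),
             strand = fragments$strand, stringsAsFactors = FALSE)
}
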