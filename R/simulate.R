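## Synthetic-data generator: a toy genome with controlled DpnII site
## density, an annotated transcript catalog with three localization classes
## (cis-nascent, genome-wide trans, X-coating), TADs, and chimeric
## RNA-bridge-DNA FASTQ reads with a per-read ground-truth table. Fully
## deterministic under a single seed.

#' Simulation configuration
#'
#' The defaults describe the stated world every generator-backed test runs
#' in: a 3 Mb five-chromosome toy genome whose X carries 10 percent of the
#' sequence, DpnII sites at 5 per kb (median spacing ~200 bp), 152 bp
#' single-end chimeric reads, 85 percent sense RNA capture, a 10 percent
#' PCR duplicate rate and low substitution error. Class mix follows the
#' three observed localization archetypes, dominated by near-locus nascent
#' transcripts.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param chrom_lengths named chromosome lengths (each >= 50 kb).
#' @param x_chrom the chromosome coated by class-III RNAs.
#' @param gatc_per_kb target DpnII site density (sites per kb).
#' @param n_genes number of genomic transcripts.
#' @param gene_length_range uniform range of transcript lengths (bp).
#' @param category_weights sampling weights over the 11 ranked categories.
#' @param class_mix fractions of cis (class I), trans (class II) and xcoat
#'   (class III) RNAs; must sum to 1.
#' @param xcoat_fold planted chrX enrichment fold for class-III RNAs.
#' @param cis_window class-I DNA targets fall within this distance of the
#'   parent locus (bp).
#' @param n_reads reads to emit (before nothing: duplicates are part of
#'   this count).
#' @param read_length maximum read length (bp).
#' @param bridge a \code{\link{bridge_spec}}; the default is a synthetic
#'   24-mer used only by the simulator.
#' @param rna_frag_range RNA-side fragment length range (nt).
#' @param no_bridge_rate,multi_bridge_rate,duplicate_rate,error_rate,antisense_rate,spike_leak_rate
#'   noise knobs, all rates in [0,1].
#' @param n_spikes,spike_length spike-in transcripts (absent from the
#'   genome) and their length.
#' @param rnase_mode when TRUE, emulates the RNase-treated control: no
#'   bridge ligation happens, every read is bridge-less.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr2L = 675000L, chr2R = 675000L,
                                         chr3L = 675000L, chr3R = 675000L,
                                         chrX = 300000L),
                       x_chrom = "chrX",
                       gatc_per_kb = 5,
                       n_genes = 60L,
                       gene_length_range = c(600L, 3000L),
                       category_weights = c(ncRNA = 0.20, transcript = 0.25,
                                            exon = 0.15, intron = 0.10,
                                            gene = 0.10, miRNA = 0.03,
                                            three_prime_UTR = 0.05,
                                            five_prime_UTR = 0.05,
                                            tRNA = 0.03, miscRNA = 0.02,
                                            gene_extended2000 = 0.02),
                       class_mix = c(cis = 0.70, trans = 0.25, xcoat = 0.05),
                       xcoat_fold = 8,
                       cis_window = 10000L,
                       n_reads = 10000L,
                       read_length = 152L,
                       bridge = bridge_spec("AACGCTGGATTCGTCCAACGTGGT"),
                       rna_frag_range = c(20L, 60L),
                       no_bridge_rate = 0.05,
                       multi_bridge_rate = 0.02,
                       duplicate_rate = 0.10,
                       error_rate = 0.002,
                       antisense_rate = 0.15,
                       spike_leak_rate = 0,
                       n_spikes = 3L,
                       spike_length = 200L,
                       rnase_mode = FALSE) {
  stopifnot(inherits(bridge, "bridge_spec"),
            !is.null(names(chrom_lengths)), all(chrom_lengths >= 50000),
            x_chrom %in% names(chrom_lengths))
  rates <- c(no_bridge_rate, multi_bridge_rate, duplicate_rate, error_rate,
             antisense_rate, spike_leak_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0,1]", call. = FALSE)
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix must sum to 1", call. = FALSE)
  if (read_length < nchar(bridge$sequence) + 2L * bridge$min_flank)
    stop("read_length shorter than bridge + 2*min_flank", call. = FALSE)
  if (max(rna_frag_range) > read_length - nchar(bridge$sequence) - bridge$min_flank)
    stop("rna_frag_range leaves no room for a usable DNA flank", call. = FALSE)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

## disrupt every natural GATC by mutating its A; a few passes catch sites
## created by the mutations themselves
disrupt_gatc <- function(vec) {
  for (pass in 1:4) {
    s <- paste(vec, collapse = "")
    m <- gregexpr("GATC", s, fixed = TRUE)[[1]]
    if (m[1] == -1L) break
    vec[m + 1L] <- sample(c("C", "G"), length(m), replace = TRUE)
  }
  vec
}

#' Generate the toy genome
#'
#' Random sequence per chromosome with GATC planted at the target density
#' (within 10 percent): natural GATC occurrences are first disrupted, then
#' sites are planted on a jittered grid. With density 0 the raw random
#' sequence (stochastic background only) is returned. Residual unplanned
#' occurrences are counted and reported.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list: genome (named character), index
#'   (\code{\link{genome_index}}), site_stats (per-chromosome planted /
#'   total / background counts).
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  spacing <- if (config$gatc_per_kb > 0) 1000 / config$gatc_per_kb else Inf
  if (spacing < 8) stop("GATC density infeasible: spacing below 8 bp", call. = FALSE)
  set.seed(derive_seeds(config$seed, 10)[1])
  genome <- character(0)
  planted <- integer(0)
  for (ch in names(config$chrom_lengths)) {
    L <- config$chrom_lengths[[ch]]
    vec <- sample(DNA_BASES, L, replace = TRUE)
    np <- 0L
    if (is.finite(spacing)) {
      vec <- disrupt_gatc(vec)
      grid <- seq(spacing / 2, L - 5, by = spacing)
      pos <- round(grid + stats::runif(length(grid), -spacing / 3, spacing / 3))
      pos <- sort(unique(pmin(pmax(pos, 0), L - 4L)))
      pos <- pos[c(TRUE, diff(pos) >= 4L)]
      idx <- rep(pos, each = 4L) + 0:3 + 1L
      vec[idx] <- rep(c("G", "A", "T", "C"), length(pos))
      np <- length(pos)
    }
    genome[[ch]] <- paste(vec, collapse = "")
    planted[[ch]] <- np
  }
  index <- dpnII_sites(genome)
  site_stats <- data.table(chrom = names(genome),
                           planted = unname(planted),
                           total = unname(lengths(index$sites)))
  site_stats[, background := total - planted]
  list(genome = genome, index = index, site_stats = site_stats[])
}

#' Generate the transcript catalog
#'
#' Places non-overlapping genes on the toy genome with random strand, a
#' ranked-category label, a localization class (class-III genes sit on the
#' X chromosome, as the canonical coating RNAs do), and log-normal
#' expression levels. Spike-in transcripts are extra references whose
#' sequences do not exist in the genome.
#'
#' @param config a \code{\link{sim_config}}.
#' @param genome named character vector from \code{\link{make_genome}}.
#' @return data.table: gene_id, chrom, start, end, strand, category, class,
#'   length, expression, sequence. Spike rows have class \code{"spike"} and
#'   NA coordinates.
#' @export
make_annotations <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seeds(config$seed, 10)[2])
  lens <- config$chrom_lengths
  n <- config$n_genes
  cls <- sample(names(config$class_mix), n, replace = TRUE,
                prob = config$class_mix)
  ## guarantee each positive-weight class is represented
  for (cn in names(config$class_mix)[config$class_mix > 0])
    if (!cn %in% cls) cls[sample.int(n, 1L)] <- cn
  placed <- lapply(names(lens), function(ch) integer(0))
  names(placed) <- names(lens)
  rows <- vector("list", n)
  occupied <- lapply(names(lens), function(ch) data.table(start = integer(), end = integer()))
  names(occupied) <- names(lens)
  for (i in seq_len(n)) {
    glen <- sample(config$gene_length_range[1]:config$gene_length_range[2], 1L)
    for (try in 1:100) {
      ch <- if (cls[i] == "xcoat") config$x_chrom else
        sample(names(lens), 1L, prob = as.numeric(lens))
      st <- sample.int(lens[[ch]] - glen, 1L) - 1L
      occ <- occupied[[ch]]
      if (nrow(occ) == 0L || all(st + glen <= occ$start | st >= occ$end)) {
        occupied[[ch]] <- rbind(occ, data.table(start = st, end = st + glen))
        rows[[i]] <- data.table(gene_id = sprintf("gene%03d", i), chrom = ch,
                                start = st, end = st + glen,
                                strand = sample(c("+", "-"), 1L),
                                category = sample(names(config$category_weights), 1L,
                                                  prob = config$category_weights),
                                class = cls[i], length = glen)
        break
      }
    }
    if (is.null(rows[[i]])) stop("could not place gene ", i, call. = FALSE)
  }
  ann <- rbindlist(rows)
  ann[, expression := stats::rlnorm(.N, meanlog = 4, sdlog = 1)]
  seqs <- substr(genome[ann$chrom], ann$start + 1L, ann$end)
  seqs[ann$strand == "-"] <- revcomp(seqs[ann$strand == "-"])
  ann[, sequence := seqs]
  if (config$n_spikes > 0L) {
    sp <- data.table(gene_id = sprintf("spike%02d", seq_len(config$n_spikes)),
                     chrom = NA_character_, start = NA_integer_, end = NA_integer_,
                     strand = "+", category = "ncRNA", class = "spike",
                     length = config$spike_length,
                     expression = NA_real_,
                     sequence = vapply(seq_len(config$n_spikes),
                                       function(i) random_dna(config$spike_length),
                                       character(1)))
    ann <- rbind(ann, sp)
  }
  ann[]
}

## DpnII fragment table: fragment i runs from site i to site i+1 (+4 so the
## downstream GATC is included), capped at the chromosome end
site_fragments <- function(index) {
  rbindlist(lapply(names(index$sites), function(ch) {
    s <- index$sites[[ch]]
    if (!length(s)) return(NULL)
    nxt <- c(s[-1] + 4L, index$chrom_lengths[[ch]])
    data.table(chrom = ch, pos = s, frag_len = as.integer(nxt - s))
  }))
}

#' Generate chimeric reads and their ground truth
#'
#' Signal reads are RNA fragment + bridge + DNA fragment, the DNA fragment
#' starting at a DpnII site and running to the next one (emulating
#' digestion), the whole chimera presented on a random sequencing strand.
#' Class I RNAs target sites near their own locus, class II any site
#' (optionally with a planted TAD-boundary enrichment), class III chrX
#' sites at the configured fold. Noise reads (bridge-less, double-bridge),
#' PCR duplicates, substitution errors and spike-in leakage are applied per
#' the configured rates. In \code{rnase_mode} every read is bridge-less.
#'
#' @param config a \code{\link{sim_config}}.
#' @param genome,annotations from \code{\link{make_genome}} /
#'   \code{\link{make_annotations}}.
#' @param index the matching \code{\link{genome_index}}.
#' @param tads optional TAD table for boundary-weighted class-II sampling.
#' @param boundary_factor weight multiplier for sites within 10 kb of a TAD
#'   edge (class II only).
#' @return list: reads (read_id, sequence, qualities), truth (read_id,
#'   gene_id, category, sense, chrom, start, end, noise_class).
#' @export
make_reads <- function(config, genome, annotations, index,
                       tads = NULL, boundary_factor = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seeds(config$seed, 10)[3])
  n <- config$n_reads
  ids <- sprintf("read%07d", seq_len(n))
  blen <- nchar(config$bridge$sequence)
  mfl <- config$bridge$min_flank

  if (config$rnase_mode) {
    ch <- sample(names(config$chrom_lengths), n, replace = TRUE,
                 prob = as.numeric(config$chrom_lengths))
    st <- floor(stats::runif(n) * (config$chrom_lengths[ch] - config$read_length))
    sq <- substr(genome[ch], st + 1L, st + config$read_length)
    flip <- stats::runif(n) < 0.5
    sq[flip] <- revcomp(sq[flip])
    reads <- data.table(read_id = ids, sequence = sq,
                        qualities = strrep("I", nchar(sq)))
    truth <- data.table(read_id = ids, gene_id = NA_character_,
                        category = NA_character_, sense = NA,
                        chrom = ch, start = as.integer(st),
                        end = as.integer(st + config$read_length),
                        noise_class = "rnase_no_bridge")
    return(list(reads = reads, truth = truth))
  }

  frags <- site_fragments(index)
  frags <- frags[frag_len >= mfl]          # only fragments long enough to map
  if (nrow(frags) == 0L) stop("no usable DpnII fragments in the genome", call. = FALSE)
  qx <- config$chrom_lengths[[config$x_chrom]] / sum(as.numeric(config$chrom_lengths))
  px <- min(config$xcoat_fold * qx, 0.95)
  ## boundary weights for class-II sampling
  w_trans <- rep(1, nrow(frags))
  if (!is.null(tads) && boundary_factor != 1) {
    td <- as.data.table(tads)
    edges <- unique(rbind(td[, .(chrom, pos = start)], td[, .(chrom, pos = end)]))
    near <- overlaps_any(frags[, .(chrom, start = pos, end = pos + 1L)],
                         merge_intervals(edges[, .(chrom, start = pos - 10000L,
                                                   end = pos + 10000L)]))
    w_trans[near] <- boundary_factor
  }
  x_idx <- which(frags$chrom == config$x_chrom)
  a_idx <- which(frags$chrom != config$x_chrom)

  dup <- stats::runif(n) < config$duplicate_rate
  dup[1] <- FALSE                          # need at least one base read
  nb <- sum(!dup)
  type <- sample(c("signal", "no_bridge", "multi_bridge"), nb, replace = TRUE,
                 prob = c(1 - config$no_bridge_rate - config$multi_bridge_rate,
                          config$no_bridge_rate, config$multi_bridge_rate))

  genes <- annotations[class != "spike"]
  spikes <- annotations[class == "spike"]
  pick_gene <- function(k) {
    gi <- sample(nrow(genes), k, replace = TRUE, prob = genes$expression)
    if (config$spike_leak_rate > 0 && nrow(spikes) > 0L) {
      leak <- stats::runif(k) < config$spike_leak_rate
      gi[leak] <- -sample(nrow(spikes), sum(leak), replace = TRUE)
    }
    gi                                      # negative = spike row
  }
  ## per-gene eligible cis fragment ranges (row indices into frags)
  setkey(frags, chrom, pos)
  cis_rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i]
    which(frags$chrom == g$chrom & frags$pos >= g$start - config$cis_window &
            frags$pos <= g$end + config$cis_window)
  })

  build_signal <- function(k) {
    gi <- pick_gene(k)
    is_spike <- gi < 0
    pick2 <- function(gcol, scol) {
      out <- character(k)
      out[!is_spike] <- gcol[gi[!is_spike]]
      out[is_spike] <- scol[-gi[is_spike]]
      out
    }
    gene_id <- pick2(genes$gene_id, spikes$gene_id)
    category <- pick2(genes$category, spikes$category)
    tseq <- pick2(genes$sequence, spikes$sequence)
    gclass <- character(k)
    gclass[!is_spike] <- genes$class[gi[!is_spike]]
    gclass[is_spike] <- "spike"
    tlen <- nchar(tseq)
    frlen <- pmin(sample(config$rna_frag_range[1]:config$rna_frag_range[2],
                         k, replace = TRUE), tlen)
    fst <- floor(stats::runif(k) * (tlen - frlen + 1)) + 1L
    rna <- substr(tseq, fst, fst + frlen - 1L)
    anti <- stats::runif(k) < config$antisense_rate
    rna[anti] <- revcomp(rna[anti])
    ## DNA target fragment per class
    fi <- integer(k)
    tr <- which(gclass %in% c("trans", "spike"))
    if (length(tr))
      fi[tr] <- sample(nrow(frags), length(tr), replace = TRUE, prob = w_trans)
    xc <- which(gclass == "xcoat")
    if (length(xc)) {
      onx <- stats::runif(length(xc)) < px
      fi[xc[onx]] <- x_idx[sample.int(length(x_idx), sum(onx), replace = TRUE)]
      fi[xc[!onx]] <- a_idx[sample.int(length(a_idx), sum(!onx), replace = TRUE)]
    }
    ci <- which(gclass == "cis")
    if (length(ci)) {
      fi[ci] <- vapply(gi[ci], function(g) {
        r <- cis_rows[[g]]
        if (!length(r)) r <- which(frags$chrom == genes$chrom[g])
        r[sample.int(length(r), 1L)]
      }, integer(1))
    }
    budget <- config$read_length - blen - frlen
    dlen <- pmin(frags$frag_len[fi], budget)
    dna <- substr(genome[frags$chrom[fi]], frags$pos[fi] + 1L,
                  frags$pos[fi] + dlen)
    fwd <- if (config$bridge$rna_end == "left")
      paste0(rna, config$bridge$sequence, dna)
    else paste0(dna, config$bridge$sequence, rna)
    flip <- stats::runif(k) < 0.5
    fwd[flip] <- revcomp(fwd[flip])
    list(seq = fwd,
         truth = data.table(gene_id = gene_id, category = category,
                            sense = !anti, chrom = frags$chrom[fi],
                            start = frags$pos[fi],
                            end = as.integer(frags$pos[fi] + dlen),
                            noise_class = ifelse(is_spike, "spike", "signal")))
  }
  build_no_bridge <- function(k) {
    ch <- sample(names(config$chrom_lengths), k, replace = TRUE,
                 prob = as.numeric(config$chrom_lengths))
    st <- floor(stats::runif(k) * (config$chrom_lengths[ch] - config$read_length))
    sq <- substr(genome[ch], st + 1L, st + config$read_length)
    flip <- stats::runif(k) < 0.5
    sq[flip] <- revcomp(sq[flip])
    list(seq = sq,
         truth = data.table(gene_id = NA_character_, category = NA_character_,
                            sense = NA, chrom = ch, start = as.integer(st),
                            end = as.integer(st + config$read_length),
                            noise_class = "no_bridge"))
  }
  build_multi_bridge <- function(k) {
    gi <- sample(nrow(genes), k, replace = TRUE, prob = genes$expression)
    rna <- substr(genes$sequence[gi], 1L, 20L)
    fi <- sample(nrow(frags), k, replace = TRUE)
    dna <- substr(genome[frags$chrom[fi]], frags$pos[fi] + 1L,
                  frags$pos[fi] + pmin(frags$frag_len[fi], 20L))
    mid <- vapply(seq_len(k), function(i) random_dna(10L), character(1))
    sq <- substr(paste0(rna, config$bridge$sequence, mid,
                        config$bridge$sequence, dna), 1L, config$read_length)
    list(seq = sq,
         truth = data.table(gene_id = genes$gene_id[gi],
                            category = genes$category[gi], sense = TRUE,
                            chrom = frags$chrom[fi], start = frags$pos[fi],
                            end = as.integer(frags$pos[fi] +
                                               pmin(frags$frag_len[fi], 20L)),
                            noise_class = "multi_bridge"))
  }

  base_seq <- character(nb)
  base_truth <- vector("list", 3)
  tpos <- list(signal = which(type == "signal"),
               no_bridge = which(type == "no_bridge"),
               multi_bridge = which(type == "multi_bridge"))
  truth_base <- data.table(gene_id = rep(NA_character_, nb),
                           category = NA_character_, sense = NA,
                           chrom = NA_character_, start = NA_integer_,
                           end = NA_integer_, noise_class = NA_character_)
  for (tt in names(tpos)) {
    idx <- tpos[[tt]]
    if (!length(idx)) next
    res <- switch(tt, signal = build_signal(length(idx)),
                  no_bridge = build_no_bridge(length(idx)),
                  multi_bridge = build_multi_bridge(length(idx)))
    base_seq[idx] <- res$seq
    truth_base[idx, names(res$truth) := res$truth]
  }

  seqs <- character(n)
  truth <- data.table(read_id = ids, gene_id = NA_character_,
                      category = NA_character_, sense = NA,
                      chrom = NA_character_, start = NA_integer_,
                      end = NA_integer_, noise_class = NA_character_)
  base_slots <- which(!dup)
  seqs[base_slots] <- base_seq
  truth[base_slots, names(truth_base) := truth_base]
  if (any(dup)) {
    src <- sample(base_slots, sum(dup), replace = TRUE)
    seqs[dup] <- seqs[src]
    cp <- truth[src, .(gene_id, category, sense, chrom, start, end)]
    truth[which(dup), names(cp) := cp]
    truth[which(dup), noise_class := "duplicate"]
  }
  ## substitution sequencing errors (truth keeps pre-error coordinates)
  if (config$error_rate > 0) {
    nch <- nchar(seqs)
    cum <- cumsum(as.numeric(nch))
    total <- cum[length(cum)]
    k <- stats::rbinom(1L, as.integer(min(total, .Machine$integer.max)),
                       config$error_rate)
    if (k > 0L) {
      at <- sort(sample.int(total, k))
      ri <- findInterval(at - 1, cum) + 1L
      off <- as.integer(at - c(0, cum)[ri])
      for (j in seq_len(k)) {
        cur <- substr(seqs[ri[j]], off[j], off[j])
        substr(seqs[ri[j]], off[j], off[j]) <-
          sample(setdiff(DNA_BASES, cur), 1L)
      }
    }
  }
  list(reads = data.table(read_id = ids, sequence = seqs,
                          qualities = strrep("I", nchar(seqs))),
       truth = truth[])
}

#' Tile chromosomes with TADs
#'
#' Fixed-width TADs tiling each chromosome from coordinate 0; all
#' coordinates are multiples of the width, matching the 10-kb grid TAD
#' callers operate on. Coverage is at least 80 percent whenever the width is
#' at most a fifth of the chromosome.
#'
#' @param index a \code{\link{genome_index}} (only lengths are used).
#' @param width TAD width in bp (multiple of 10 kb recommended; default
#'   10 kb as in the smallest-called domains).
#' @param chroms chromosomes to tile (default all).
#' @return data.table: chrom, start, end.
#' @export
make_tads <- function(index, width = 10000L, chroms = names(index$chrom_lengths)) {
  stopifnot(inherits(index, "genome_index"))
  rbindlist(lapply(chroms, function(ch) {
    L <- index$chrom_lengths[[ch]]
    k <- L %/% width
    if (k < 1L) return(NULL)
    data.table(chrom = ch, start = (seq_len(k) - 1L) * width,
               end = seq_len(k) * width)
  }))
}

#' Sample synthetic contacts with optional TAD-boundary enrichment
#'
#' Draws contact positions at DpnII sites, up-weighting sites within
#' \code{halfwidth} of a TAD edge by \code{boundary_factor}. Used to give
#' the boundary-enrichment test a truth-known input without simulating
#' reads.
#'
#' @param index a \code{\link{genome_index}}.
#' @param n number of contacts.
#' @param tads TAD table (needed when \code{boundary_factor != 1}).
#' @param boundary_factor planted enrichment fold at boundaries.
#' @param halfwidth boundary half-width (default 10 kb).
#' @param chroms restrict sampling to these chromosomes.
#' @param seed RNG seed.
#' @return contact-shaped data.table (read_id, gene_id, rna_category, sense,
#'   chrom, start, end, dna_strand).
#' @export
sample_tad_contacts <- function(index, n, tads = NULL, boundary_factor = 1,
                                halfwidth = 10000L,
                                chroms = names(index$chrom_lengths),
                                seed = 1L) {
  set.seed(as.integer(seed))
  frags <- site_fragments(index)[chrom %in% chroms]
  w <- rep(1, nrow(frags))
  if (!is.null(tads) && boundary_factor != 1) {
    td <- as.data.table(tads)[chrom %in% chroms]
    edges <- unique(rbind(td[, .(chrom, pos = start)], td[, .(chrom, pos = end)]))
    near <- overlaps_any(frags[, .(chrom, start = pos, end = pos + 1L)],
                         merge_intervals(edges[, .(chrom,
                                                   start = pmax(0L, pos - halfwidth),
                                                   end = pos + halfwidth)]))
    w[near] <- boundary_factor
  }
  fi <- sample.int(nrow(frags), n, replace = TRUE, prob = w)
  data.table(read_id = sprintf("sim%07d", seq_len(n)), gene_id = "simRNA",
             rna_category = "ncRNA", sense = TRUE,
             chrom = frags$chrom[fi], start = frags$pos[fi],
             end = frags$pos[fi] + 20L, dna_strand = "+")
}

#' Generate a complete synthetic dataset
#'
#' Runs genome, annotation, TAD and read generation under one seed and
#' optionally writes all artifacts (FASTA, FASTQ, per-category FASTAs, gene
#' and TAD BEDs, expression and truth TSVs, manifest JSON) to a directory.
#'
#' @param config a \code{\link{sim_config}}.
#' @param out_dir optional output directory.
#' @param tad_width TAD width passed to \code{\link{make_tads}}.
#' @return list: config, genome, index, annotations, tads, reads, truth,
#'   site_stats (and \code{out_dir} when written).
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL,
                             tad_width = 10000L) {
  g <- make_genome(config)
  ann <- make_annotations(config, g$genome)
  tads <- make_tads(g$index, width = tad_width)
  rd <- make_reads(config, g$genome, ann, g$index, tads = tads)
  res <- list(config = config, genome = g$genome, index = g$index,
              annotations = ann, tads = tads, reads = rd$reads,
              truth = rd$truth, site_stats = g$site_stats)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(res$genome, file.path(out_dir, "genome.fa"))
    write_fastq(res$reads, file.path(out_dir, "reads.fastq"))
    fwrite(res$truth, file.path(out_dir, "truth.tsv"), sep = "\t")
    fwrite(res$annotations[, .(gene_id, chrom, start, end, strand, category,
                               class, length, expression)],
           file.path(out_dir, "genes.tsv"), sep = "\t")
    write_bed(res$tads, file.path(out_dir, "tads.bed"))
    fwrite(res$annotations[class != "spike",
                           .(gene_id, value = expression)],
           file.path(out_dir, "expression.tsv"), sep = "\t")
    for (cat in unique(res$annotations$category)) {
      sub <- res$annotations[category == cat]
      write_fasta(stats::setNames(sub$sequence, sub$gene_id),
                  file.path(out_dir, paste0("category_", cat, ".fa")))
    }
    manifest <- list(seed = config$seed, n_reads = config$n_reads,
                     chromosomes = as.list(config$chrom_lengths),
                     files = list.files(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    res$out_dir <- out_dir
  }
  res
}
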