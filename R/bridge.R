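## Bridge-adapter handling: deduplication of raw reads, locating the bridge
## oligonucleotide in each read, and splitting reads into RNA and DNA sides
## using the bridge polarity.

#' Describe the bridge oligonucleotide
#'
#' The bridge is the duplex adapter that joins an RNA 3' end to a digested
#' genomic DNA end inside the nucleus. Its polarity is what lets a single
#' sequencing read be split into an RNA side and a DNA side: the flank
#' adjacent to the 5'-adenylated (5'App) end of the bridge is the RNA, the
#' flank adjacent to the restriction-compatible end is the DNA.
#'
#' @param sequence bridge sequence, top strand 5'->3', written with the
#'   RNA-ligation (5'App) end first. At least 10 nt, ACGT only. The concrete
#'   oligo is experiment-specific and always supplied by the user; it is
#'   never hard-coded.
#' @param rna_end which end of \code{sequence} is the 5'App (RNA-ligation)
#'   end; \code{"left"} by the convention above.
#' @param max_mismatches maximum substitutions tolerated when locating the
#'   bridge (no indels). Must stay below a quarter of the bridge length.
#' @param min_flank minimum usable flank length in nt; shorter sides make a
#'   read unmappable and the read is dropped.
#' @return an object of class \code{bridge_spec}.
#' @export
bridge_spec <- function(sequence, rna_end = c("left", "right"),
                        max_mismatches = 1L, min_flank = 15L) {
  rna_end <- match.arg(rna_end)
  sequence <- toupper(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) < 10L)
    stop("bridge sequence must be at least 10 nt", call. = FALSE)
  if (!is_acgt(sequence))
    stop("bridge sequence must contain only A/C/G/T", call. = FALSE)
  max_mismatches <- as.integer(max_mismatches)
  min_flank <- as.integer(min_flank)
  if (max_mismatches < 0L || max_mismatches >= nchar(sequence) / 4)
    stop("max_mismatches must satisfy 0 <= m < bridge length / 4", call. = FALSE)
  if (min_flank < 1L)
    stop("min_flank must be >= 1", call. = FALSE)
  structure(
    list(sequence = sequence, rna_end = rna_end,
         max_mismatches = max_mismatches, min_flank = min_flank),
    class = "bridge_spec")
}

#' @export
print.bridge_spec <- function(x, ...) {
  cat(sprintf("bridge_spec: %s (%d nt), 5'App end: %s, max mismatches: %d, min flank: %d\n",
              x$sequence, nchar(x$sequence), x$rna_end, x$max_mismatches, x$min_flank))
  invisible(x)
}

#' Remove exact PCR duplicates from a read set
#'
#' Duplicates are defined on the entire read sequence; the first occurrence
#' of each distinct sequence is kept. Run before bridge splitting, mirroring
#' the usual dedup-then-trim-then-split order.
#'
#' @param reads data.frame with columns \code{read_id}, \code{sequence} and
#'   optionally \code{qualities}.
#' @return list with \code{reads} (the retained rows) and \code{stats}
#'   (\code{input}, \code{retained}, \code{duplicates}).
#' @export
dedup_reads <- function(reads) {
  need_cols(reads, c("read_id", "sequence"), "reads")
  if (nrow(reads) == 0L)
    return(list(reads = reads,
                stats = list(input = 0L, retained = 0L, duplicates = 0L)))
  keep <- !duplicated(reads$sequence)
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out,
       stats = list(input = nrow(reads), retained = sum(keep),
                    duplicates = nrow(reads) - sum(keep)))
}

## Locate the bridge in many sequences at once.
## Returns a data.table(idx, start, end, orientation, mismatches), start
## 0-based, end exclusive, sorted by (idx, start). Overlapping hits covering
## the same occurrence are collapsed to the best: fewest mismatches, then
## leftmost, then forward orientation.
locate_bridge <- function(seqs, spec) {
  stopifnot(inherits(spec, "bridge_spec"))
  empty <- data.table(idx = integer(), start = integer(), end = integer(),
                      orientation = character(), mismatches = integer())
  if (length(seqs) == 0L) return(empty)
  blen <- nchar(spec$sequence)
  subj <- Biostrings::DNAStringSet(seqs)
  pats <- c(forward = spec$sequence, reverse_complement = revcomp(spec$sequence))
  hits <- lapply(names(pats), function(ori) {
    m <- Biostrings::vmatchPattern(pats[[ori]], subj,
                                   max.mismatch = spec$max_mismatches,
                                   fixed = TRUE)
    n_per <- S4Vectors::elementNROWS(m)
    if (sum(n_per) == 0L) return(NULL)
    ir <- unlist(m)
    data.table(idx = rep(seq_along(seqs), n_per),
               start = IRanges::start(ir) - 1L,   # to 0-based
               end = IRanges::end(ir),
               orientation = ori)
  })
  ht <- rbindlist(hits)
  if (nrow(ht) == 0L) return(empty)
  ## full-bridge requirement: discard anything truncated by the read ends
  ht <- ht[start >= 0L & end <= nchar(seqs)[idx]]
  if (nrow(ht) == 0L) return(empty)
  ## count mismatches by direct character comparison (N never matches)
  frag <- substr(seqs[ht$idx], ht$start + 1L, ht$end)
  pat <- ifelse(ht$orientation == "forward", pats[["forward"]],
                pats[["reverse_complement"]])
  fc <- strsplit(paste(frag, collapse = ""), "", fixed = TRUE)[[1]]
  pc <- strsplit(paste(pat, collapse = ""), "", fixed = TRUE)[[1]]
  mm <- rowsum((fc != pc) + 0L, group = rep(seq_len(nrow(ht)), each = blen))
  ht[, mismatches := as.integer(mm[, 1])]
  ht <- ht[mismatches <= spec$max_mismatches]
  if (nrow(ht) == 0L) return(empty)
  ## collapse overlapping hits of the same occurrence
  setorder(ht, idx, start, mismatches)
  ht[, cluster := {
    cs <- cumsum(c(TRUE, start[-1] >= cummax(end)[-.N]))
    cs
  }, by = idx]
  pref <- ht[, .I[order(mismatches, start, orientation != "forward")][1],
             by = .(idx, cluster)]$V1
  ht <- ht[sort(pref)]
  ht[, cluster := NULL]
  setorder(ht, idx, start)
  ht[]
}

#' Find all bridge occurrences in one read
#'
#' Scans every offset of the read for the bridge and for its reverse
#' complement, allowing up to \code{spec$max_mismatches} substitutions and no
#' indels. Only full-length occurrences count: a bridge truncated by a read
#' end is not a hit. Overlapping hits of the same occurrence are collapsed to
#' the best one (fewest mismatches, then leftmost, then forward).
#'
#' @param read list or data.frame row with \code{read_id} and
#'   \code{sequence}, or a bare character sequence.
#' @param spec a \code{\link{bridge_spec}}.
#' @return data.frame with columns \code{start} (0-based), \code{end}
#'   (exclusive), \code{orientation} (\code{"forward"} or
#'   \code{"reverse_complement"}) and \code{mismatches}, sorted by start.
#'   Empty when the read is shorter than the bridge or carries no bridge.
#' @export
find_bridge <- function(read, spec) {
  seqc <- if (is.character(read)) read[[1]] else read$sequence
  stopifnot(is.character(seqc), length(seqc) == 1L)
  if (nchar(seqc) < nchar(spec$sequence))
    return(data.frame(start = integer(), end = integer(),
                      orientation = character(), mismatches = integer()))
  ht <- locate_bridge(seqc, spec)
  as.data.frame(ht[, .(start, end, orientation, mismatches)])
}

## internal vectorised splitter shared by split_read() and split_reads()
split_engine <- function(seqs, hit_dt, spec) {
  n <- length(seqs)
  out <- data.table(rna_seq = NA_character_, dna_seq = NA_character_,
                    bridge_orientation = NA_character_,
                    drop_reason = NA_character_, i = seq_len(n))
  nh <- integer(n)
  if (nrow(hit_dt)) {
    tab <- hit_dt[, .N, by = idx]
    nh[tab$idx] <- tab$N
  }
  out[nh == 0L, drop_reason := "no_bridge"]
  out[nh >= 2L, drop_reason := "multi_bridge"]
  one <- which(nh == 1L)
  if (length(one)) {
    h1 <- hit_dt[idx %in% one][, .SD[1], by = idx]
    setkey(h1, idx)
    h1 <- h1[J(one)]
    sq <- seqs[one]
    len <- nchar(sq)
    st <- h1$start; en <- h1$end
    if (any(st < 0L | en > len))
      stop("bridge hit coordinates fall outside the read", call. = FALSE)
    rc <- h1$orientation == "reverse_complement"
    ## map the reverse-complement case onto the forward case by flipping the
    ## whole read; this is exactly what makes split results invariant to
    ## sequencing the chimera from the other strand
    sq[rc] <- revcomp(sq[rc])
    st2 <- ifelse(rc, len - en, st)
    en2 <- ifelse(rc, len - st, en)
    left <- substr(sq, 1L, st2)
    right <- substr(sq, en2 + 1L, len)
    if (spec$rna_end == "left") {
      rna <- left; dna <- right
    } else {
      rna <- right; dna <- left
    }
    drop <- rep(NA_character_, length(one))
    short <- nchar(rna) < spec$min_flank | nchar(dna) < spec$min_flank
    drop[short] <- "short_flank"
    drop[nchar(rna) == 0L | nchar(dna) == 0L] <- "one_sided"
    out[one, `:=`(rna_seq = rna, dna_seq = dna,
                  bridge_orientation = h1$orientation,
                  drop_reason = drop)]
    out[one[!is.na(drop)], `:=`(rna_seq = NA_character_, dna_seq = NA_character_)]
  }
  out[, i := NULL]
  out[]
}

#' Split one read at the bridge into RNA and DNA sides
#'
#' With exactly one full bridge hit, the flank adjacent to the bridge's
#' 5'App end becomes the RNA side and the other flank the DNA side. When the
#' bridge is seen in reverse-complement orientation the whole read is flipped
#' first, so \code{rna_seq} is always reported in the transcript-sense
#' convention (a sense RNA aligns to the annotated transcript strand). Reads
#' with no bridge, more than one bridge, or a flank shorter than
#' \code{min_flank} are dropped with an explicit reason.
#'
#' @param read list/row with \code{read_id} and \code{sequence}.
#' @param hits result of \code{\link{find_bridge}} on the same read.
#' @param spec a \code{\link{bridge_spec}}.
#' @return one-row data.frame: \code{read_id}, \code{rna_seq},
#'   \code{dna_seq}, \code{bridge_orientation}, \code{drop_reason}
#'   (\code{NA} when the read is usable; otherwise one of \code{no_bridge},
#'   \code{multi_bridge}, \code{short_flank}, \code{one_sided}).
#' @export
split_read <- function(read, hits, spec) {
  seqc <- if (is.character(read)) read[[1]] else read$sequence
  rid <- if (is.character(read)) NA_character_ else read$read_id
  hd <- as.data.table(hits)
  if (nrow(hd)) hd[, idx := 1L] else hd <- data.table(idx = integer(),
      start = integer(), end = integer(), orientation = character(),
      mismatches = integer())
  res <- split_engine(seqc, hd, spec)
  cbind(data.frame(read_id = rid, stringsAsFactors = FALSE), as.data.frame(res))
}

#' Split a whole read set at the bridge
#'
#' Vectorised equivalent of \code{\link{find_bridge}} +
#' \code{\link{split_read}} over a read table; this is the production path
#' used by \code{\link{run_pipeline}}.
#'
#' @param reads data.frame with \code{read_id} and \code{sequence}.
#' @param spec a \code{\link{bridge_spec}}.
#' @return list with \code{split} (data.table: read_id, rna_seq, dna_seq,
#'   bridge_orientation, drop_reason) and \code{stats} (counts per outcome;
#'   kept + dropped always equals the input count).
#' @export
split_reads <- function(reads, spec) {
  need_cols(reads, c("read_id", "sequence"), "reads")
  hit_dt <- locate_bridge(reads$sequence, spec)
  res <- split_engine(reads$sequence, hit_dt, spec)
  res <- cbind(data.table(read_id = reads$read_id), res)
  st <- table(factor(res$drop_reason,
                     levels = c("no_bridge", "multi_bridge", "short_flank", "one_sided")),
              useNA = "no")
  stats <- c(list(input = nrow(res), kept = sum(is.na(res$drop_reason))),
             as.list(as.integer(st)))
  names(stats)[3:6] <- names(st)
  list(split = res, stats = stats)
}
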