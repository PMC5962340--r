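## RNA-DNA contact assembly: rejoin annotated RNA sides with DNA placements
## by read ID, apply contact-level filters (rRNA, blacklists), and summarise
## strand composition.

#' Merge and sort genomic intervals
#'
#' Normalises a 0-based half-open interval table (or a list of them) into a
#' merged, sorted interval set, the form expected by all overlap-based
#' filters.
#'
#' @param x data.frame with chrom/start/end, or a list of such data.frames.
#' @return data.table(chrom, start, end), merged and sorted.
#' @export
merge_intervals <- function(x) {
  if (is.data.frame(x)) x <- list(x)
  dt <- rbindlist(lapply(x, function(d) {
    need_cols(d, c("chrom", "start", "end"), "interval set")
    as.data.table(d)[, .(chrom, start = as.integer(start), end = as.integer(end))]
  }))
  if (nrow(dt) == 0L)
    return(data.table(chrom = character(), start = integer(), end = integer()))
  dt[, {
    r <- IRanges::reduce(IRanges::IRanges(start + 1L, end))
    list(start = IRanges::start(r) - 1L, end = IRanges::end(r))
  }, by = chrom][order(chrom, start)]
}

## rows of `df` whose [start,end) overlaps >= 1 bp with a merged interval set
overlaps_any <- function(df, iset) {
  hit <- logical(nrow(df))
  if (nrow(df) == 0L || nrow(iset) == 0L) return(hit)
  for (ch in unique(iset$chrom)) {
    sel <- which(df$chrom == ch)
    if (!length(sel)) next
    q <- IRanges::IRanges(df$start[sel] + 1L, df$end[sel])
    s <- IRanges::IRanges(iset[chrom == ch, start] + 1L, iset[chrom == ch, end])
    hit[sel] <- IRanges::overlapsAny(q, s)
  }
  hit
}

#' Join RNA annotations and DNA placements into contacts
#'
#' A contact is made for every read ID that has an assigned RNA annotation
#' AND a unique DNA placement; everything else is tallied in the loss
#' accounting. The two inputs must each have at most one row per read ID.
#'
#' @param rna output of \code{\link{assign_rna_batch}}.
#' @param dna output of \code{\link{assign_dna}}.
#' @return list with \code{contacts} (data.table: read_id, gene_id,
#'   rna_category, sense, chrom, start, end, dna_strand, sorted by
#'   chrom/start) and \code{accounting}.
#' @export
join_contacts <- function(rna, dna) {
  rna <- as.data.table(rna); dna <- as.data.table(dna)
  if (anyDuplicated(rna$read_id) || anyDuplicated(dna$read_id))
    stop("duplicate read_id within an input; deduplicate upstream", call. = FALSE)
  ra <- rna[status == "assigned"]
  dp <- dna[status == "placed"]
  contacts <- merge(
    ra[, .(read_id, gene_id, rna_category = category, sense)],
    dp[, .(read_id, chrom, start, end, dna_strand = strand)],
    by = "read_id")
  setorder(contacts, chrom, start, read_id)
  accounting <- list(
    rna_records = nrow(rna), dna_records = nrow(dna),
    rna_assigned = nrow(ra), dna_placed = nrow(dp),
    contacts = nrow(contacts),
    rna_without_dna = nrow(ra) - nrow(contacts),
    dna_without_rna = nrow(dp) - nrow(contacts))
  list(contacts = contacts[], accounting = accounting)
}

#' Filter contacts by rRNA identity and genomic blacklists
#'
#' Removes contacts whose RNA is in the ribosomal gene list (including any
#' user-supplied list of transcripts re-annotated as rRNA) or whose DNA
#' interval overlaps a blacklist/repeat-mask interval by at least 1 bp. The
#' filter applies to the DNA side only and is idempotent.
#'
#' @param contacts contact table from \code{\link{join_contacts}}.
#' @param rrna_genes character vector of gene IDs to remove.
#' @param blacklists data.frame or list of data.frames (chrom/start/end,
#'   0-based half-open); merged internally.
#' @return list with \code{contacts} (survivors) and \code{stats} (input,
#'   removed_rrna, removed_blacklist, kept).
#' @export
filter_contacts <- function(contacts, rrna_genes = character(),
                            blacklists = list()) {
  contacts <- as.data.table(contacts)
  n0 <- nrow(contacts)
  is_rrna <- contacts$gene_id %in% rrna_genes
  iset <- merge_intervals(blacklists)
  in_bl <- overlaps_any(contacts, iset)
  keep <- !is_rrna & !in_bl
  list(contacts = contacts[keep],
       stats = list(input = n0,
                    removed_rrna = sum(is_rrna),
                    removed_blacklist = sum(in_bl & !is_rrna),
                    kept = sum(keep)))
}

#' Sense/antisense composition per RNA category
#'
#' @param contacts contact table with rna_category and sense columns.
#' @return data.table: rna_category, n, sense_frac, antisense_frac, plus a
#'   final row \code{"(all)"} with the overall composition. Empty input gives
#'   an empty table.
#' @export
strand_composition <- function(contacts) {
  contacts <- as.data.table(contacts)
  if (nrow(contacts) == 0L)
    return(data.table(rna_category = character(), n = integer(),
                      sense_frac = numeric(), antisense_frac = numeric()))
  per <- contacts[, .(n = .N, sense_frac = mean(sense),
                      antisense_frac = mean(!sense)), by = rna_category]
  all <- contacts[, .(rna_category = "(all)", n = .N, sense_frac = mean(sense),
                      antisense_frac = mean(!sense))]
  rbind(per[order(rna_category)], all)
}
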