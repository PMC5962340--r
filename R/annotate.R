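## RNA-side annotation: a toy exact-match aligner (stand-in for an external
## aligner in tests and desk-scale runs), the sense-first priority-ranked
## category resolution for RNA sides, and unique-placement resolution for
## DNA sides.

#' Ranked transcriptome categories
#'
#' When an RNA side aligns with equal score to several transcriptome
#' categories, the highest-priority category wins and contributes the
#' annotation. Reads whose winning category is in \code{removed} (by default
#' tRNA and miscRNA) are discarded from further analysis.
#'
#' @param order character vector of category names, highest priority first.
#' @param removed categories whose winners are discarded.
#' @return object of class \code{priority_order}.
#' @export
priority_order <- function(order = c("tRNA", "miscRNA", "ncRNA", "transcript",
                                     "three_prime_UTR", "five_prime_UTR",
                                     "exon", "intron", "miRNA", "gene",
                                     "gene_extended2000"),
                           removed = c("tRNA", "miscRNA")) {
  stopifnot(is.character(order), !anyDuplicated(order),
            all(removed %in% order))
  structure(list(order = order, removed = removed), class = "priority_order")
}

empty_alignments <- function() {
  data.table(read_id = character(), reference = character(),
             category = character(), start = integer(), end = integer(),
             strand = character(), score = numeric(), unique = logical())
}

#' Exact-match toy aligner
#'
#' Reports every position at which a query occurs verbatim in a reference,
#' on either strand, with score equal to the match length. Minus-strand
#' records mean the reverse complement of the query occurs on the forward
#' reference; coordinates are always forward-reference, 0-based half-open.
#' \code{unique} is TRUE iff the query has exactly one maximal-score
#' location across all references and strands.
#'
#' This is deliberately not a production aligner: it exists so the pipeline
#' can be exercised end-to-end on synthetic data without an external tool.
#' Real data should be aligned externally and fed in through
#' \code{\link{read_sam}}.
#'
#' @param queries named character vector (names are read IDs).
#' @param references named character vector of reference sequences.
#' @param category label stored on each record (e.g. a transcriptome
#'   category, or \code{"genome"}).
#' @return data.table with columns read_id, reference, category, start, end,
#'   strand, score, unique.
#' @export
toy_align <- function(queries, references, category = "genome") {
  if (length(references) == 0L || is.null(names(references)))
    stop("references must be a non-empty named character vector", call. = FALSE)
  out <- empty_alignments()
  if (length(queries) == 0L) return(out)
  if (is.null(names(queries))) stop("queries must be named by read ID", call. = FALSE)
  qlen <- nchar(queries)
  k <- min(15L, min(qlen))
  ## concatenate all references into one subject separated by N runs; the
  ## anchors are ACGT-only so no anchor (or full match) can span a junction
  sep <- strrep("N", max(qlen) + 1L)
  refseq <- unlist(references)
  rlen <- nchar(refseq)
  cat_subject <- paste(refseq, collapse = sep)
  offsets <- cumsum(c(0L, head(rlen + nchar(sep), -1L)))  # 0-based ref starts
  hits <- list()
  for (str in c("+", "-")) {
    qs <- if (str == "+") queries else revcomp(queries)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(substr(qs, 1L, k)))
    m <- Biostrings::matchPDict(pd, Biostrings::DNAString(cat_subject))
    n_per <- S4Vectors::elementNROWS(m)
    if (sum(n_per) == 0L) next
    qidx <- rep(seq_along(queries), n_per)
    gpos <- IRanges::start(unlist(m))       # 1-based position in cat_subject
    ## verify full-length extension of the anchor
    endp <- gpos + qlen[qidx] - 1L
    ok <- substr(rep(cat_subject, length(gpos)), gpos, endp) == qs[qidx]
    if (!any(ok)) next
    qidx <- qidx[ok]; gpos <- gpos[ok]
    ridx <- findInterval(gpos - 1L, offsets)
    local0 <- gpos - 1L - offsets[ridx]     # 0-based start within reference
    hits[[length(hits) + 1L]] <- data.table(
      read_id = names(queries)[qidx],
      reference = names(refseq)[ridx], category = category,
      start = as.integer(local0), end = as.integer(local0 + qlen[qidx]),
      strand = str, score = as.numeric(qlen[qidx]))
  }
  if (!length(hits)) return(out)
  dt <- rbindlist(hits)
  dt[, unique := .N == 1L, by = read_id]
  setorder(dt, read_id, reference, start)
  dt[]
}

## shared engine: resolve RNA-side alignments for one or many reads
resolve_rna <- function(records, priority, all_read_ids = NULL) {
  records <- as.data.table(records)
  empty <- data.table(read_id = character(), gene_id = character(),
                      category = character(), sense = logical(),
                      status = character())
  res <- if (nrow(records)) {
    bad <- setdiff(unique(records$category), priority$order)
    if (length(bad))
      stop("unknown transcriptome categor(ies): ", paste(bad, collapse = ", "),
           call. = FALSE)
    rec <- copy(records)
    rec[, rank := match(category, priority$order)]
    rec[, is_sense := strand == "+"]
    ## sense-first is per read: any sense alignment suppresses all antisense
    rec[, has_sense := any(is_sense), by = read_id]
    pool <- rec[is_sense | !has_sense]
    pool[, smax := max(score), by = read_id]
    pool <- pool[score == smax]
    pool[, rmin := min(rank), by = read_id]
    win <- pool[rank == rmin]
    res0 <- win[, .(n_win = .N, gene_id = reference[1L],
                    category = category[1L], sense = is_sense[1L]),
                by = read_id]
    res0[, status := "assigned"]
    res0[n_win > 1L, `:=`(status = "ambiguous", gene_id = NA_character_,
                          sense = NA)]
    res0[category %in% priority$removed,
         `:=`(status = "removed_category", gene_id = NA_character_, sense = NA)]
    res0[, n_win := NULL]
    res0
  } else empty
  if (!is.null(all_read_ids)) {
    missing <- setdiff(all_read_ids, res$read_id)
    if (length(missing))
      res <- rbind(res, data.table(read_id = missing, gene_id = NA_character_,
                                   category = NA_character_, sense = NA,
                                   status = "unaligned"))
  }
  setorder(res, read_id)
  res[]
}

#' Annotate one RNA-side read from its alignment records
#'
#' Sense alignments (strand \code{"+"} against the transcript, i.e. the read
#' matches the annotated transcript strand) are considered first; antisense
#' alignments are consulted only when no sense alignment exists, because the
#' bridge polarity preserves the RNA strand. Among the maximal-score
#' candidates in the chosen pool, the highest-priority category wins. A
#' winner in a removed category (tRNA/miscRNA by default) gives status
#' \code{removed_category}; an unresolved within-category tie gives
#' \code{ambiguous}; no records at all gives \code{unaligned}.
#'
#' @param records alignment records for a single read (see
#'   \code{\link{toy_align}} / \code{\link{read_sam}}), with a
#'   \code{category} column.
#' @param priority a \code{\link{priority_order}}.
#' @return one-row data.frame: read_id, gene_id, category, sense, status.
#' @export
assign_rna <- function(records, priority = priority_order()) {
  records <- as.data.table(records)
  if (nrow(records) && length(unique(records$read_id)) > 1L)
    stop("assign_rna expects records for a single read; use assign_rna_batch",
         call. = FALSE)
  if (nrow(records) == 0L)
    return(data.frame(read_id = NA_character_, gene_id = NA_character_,
                      category = NA_character_, sense = NA,
                      status = "unaligned", stringsAsFactors = FALSE))
  as.data.frame(resolve_rna(records, priority))
}

#' Annotate many RNA-side reads at once
#'
#' @param records alignment records for any number of reads.
#' @param priority a \code{\link{priority_order}}.
#' @param all_read_ids optional universe of read IDs; IDs with no alignment
#'   records are reported with status \code{unaligned}.
#' @return data.table: read_id, gene_id, category, sense, status (exactly one
#'   row and one status per read).
#' @export
assign_rna_batch <- function(records, priority = priority_order(),
                             all_read_ids = NULL) {
  resolve_rna(records, priority, all_read_ids)
}

#' Resolve DNA-side placements to unique best alignments
#'
#' A read keeps its genomic placement only when a single alignment attains
#' the maximal score; equal-best multimappers are dropped.
#'
#' @param records alignment records (any number of reads, side DNA).
#' @param all_read_ids optional universe of read IDs for unaligned reporting.
#' @return data.table: read_id, chrom, start, end, strand, status in
#'   \{placed, multi, unaligned\}.
#' @export
assign_dna <- function(records, all_read_ids = NULL) {
  records <- as.data.table(records)
  res <- if (nrow(records)) {
    rec <- copy(records)
    rec[, smax := max(score), by = read_id]
    best <- rec[score == smax]
    r <- best[, .(n_best = .N, chrom = reference[1L], start = start[1L],
                  end = end[1L], strand = strand[1L]), by = read_id]
    r[, status := "placed"]
    r[n_best > 1L, `:=`(status = "multi", chrom = NA_character_,
                        start = NA_integer_, end = NA_integer_,
                        strand = NA_character_)]
    r[, n_best := NULL]
    r
  } else {
    data.table(read_id = character(), chrom = character(), start = integer(),
               end = integer(), strand = character(), status = character())
  }
  if (!is.null(all_read_ids)) {
    missing <- setdiff(all_read_ids, res$read_id)
    if (length(missing))
      res <- rbind(res, data.table(read_id = missing, chrom = NA_character_,
                                   start = NA_integer_, end = NA_integer_,
                                   strand = NA_character_, status = "unaligned"))
  }
  setorder(res, read_id)
  res[]
}
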