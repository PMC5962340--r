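## Format readers/writers shared by all stages. Internal coordinates are
## uniformly 0-based half-open; 1-based formats (SAM) are converted at the
## boundary. Gzip is handled transparently on read; paths ending in .gz are
## compressed on write.

out_con <- function(path) if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")

#' Read a FASTA file
#'
#' @param path FASTA path (optionally gzipped).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a FASTA file
#'
#' @param seqs named character vector.
#' @param path destination path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Strict quartet parsing: record count must be a multiple of four, headers
#' must carry their markers, and sequence/quality lengths must agree.
#'
#' @param path FASTQ path (gzip autodetected).
#' @return data.frame: read_id, sequence, qualities.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(data.frame(read_id = character(), sequence = character(),
                      qualities = character(), stringsAsFactors = FALSE))
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: ", length(lines), " lines is not a multiple of 4",
         call. = FALSE)
  i <- seq(1L, length(lines), by = 4L)
  bad <- which(!startsWith(lines[i], "@"))
  if (length(bad))
    stop("malformed FASTQ header at line ", i[bad[1]], call. = FALSE)
  badp <- which(!startsWith(lines[i + 2L], "+"))
  if (length(badp))
    stop("malformed FASTQ separator at line ", i[badp[1]] + 2L, call. = FALSE)
  sq <- lines[i + 1L]; qu <- lines[i + 3L]
  badl <- which(nchar(sq) != nchar(qu))
  if (length(badl))
    stop("sequence/quality length mismatch at line ", i[badl[1]] + 1L,
         call. = FALSE)
  data.frame(read_id = sub("\\s.*$", "", substring(lines[i], 2L)),
             sequence = toupper(sq), qualities = qu, stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param reads data.frame with read_id, sequence and optionally qualities
#'   (constant Phred 40 written when absent).
#' @param path destination path (.gz compresses).
#' @export
write_fastq <- function(reads, path) {
  need_cols(reads, c("read_id", "sequence"), "reads")
  qu <- reads$qualities %||% strrep("I", nchar(reads$sequence))
  con <- out_con(path)
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", qu), con)
  invisible(path)
}

#' Read a BED file (0-based half-open)
#'
#' @param path BED path; 3+ tab-separated columns.
#' @return data.table: chrom, start, end and, when present, name, score,
#'   strand.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L)
    return(data.table(chrom = character(), start = integer(), end = integer()))
  dt <- tryCatch(fread(path, header = FALSE, sep = "\t", fill = TRUE),
                 error = function(e) stop("cannot parse BED ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (nrow(dt) == 0L)
    return(data.table(chrom = character(), start = integer(), end = integer()))
  if (ncol(dt) < 3L) stop("BED needs at least 3 columns: ", path, call. = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  setnames(dt, seq_len(min(ncol(dt), 6L)), cols[seq_len(min(ncol(dt), 6L))])
  if (anyNA(suppressWarnings(as.integer(dt$start))))
    stop("non-numeric start coordinate in ", path, call. = FALSE)
  dt[, `:=`(start = as.integer(start), end = as.integer(end))]
  if (any(dt$end <= dt$start))
    stop("empty or inverted interval in ", path, call. = FALSE)
  dt[]
}

#' Write a BED file
#' @param intervals data.frame with chrom/start/end (+ optional name, score,
#'   strand).
#' @param path destination.
#' @export
write_bed <- function(intervals, path) {
  need_cols(intervals, c("chrom", "start", "end"), "intervals")
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  fwrite(as.data.table(intervals)[, ..cols], path, sep = "\t",
         col.names = FALSE)
  invisible(path)
}

## reference span consumed by a CIGAR string
cigar_ref_len <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^\\d+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read alignment records from a SAM text file
#'
#' Minimal SAM reader for feeding externally aligned reads into
#' \code{\link{assign_rna_batch}} / \code{\link{assign_dna}}. Unmapped and
#' secondary/supplementary records are skipped. Score is the AS tag when
#' present (MAPQ otherwise); a record is unique when no XS tag ties the AS
#' score (single-hit records without tags count as unique).
#'
#' @param path SAM path.
#' @param category category label attached to every record.
#' @return alignment data.table (read_id, reference, category, start, end,
#'   strand, score, unique).
#' @export
read_sam <- function(path, category = "genome") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(empty_alignments())
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L)
      stop("malformed SAM line ", i, ": fewer than 11 fields", call. = FALSE)
    flag <- suppressWarnings(as.integer(f[2]))
    if (is.na(flag)) stop("malformed SAM line ", i, ": bad FLAG", call. = FALSE)
    if (bitwAnd(flag, 4L) > 0L || bitwAnd(flag, 256L) > 0L ||
        bitwAnd(flag, 2048L) > 0L) return(NULL)
    pos <- as.integer(f[4])
    tags <- f[-(1:11)]
    as_ <- grep("^AS:i:", tags, value = TRUE)
    xs_ <- grep("^XS:i:", tags, value = TRUE)
    score <- if (length(as_)) as.numeric(sub("^AS:i:", "", as_[1]))
             else as.numeric(f[5])
    uni <- if (length(as_) && length(xs_))
      score > as.numeric(sub("^XS:i:", "", xs_[1])) else TRUE
    data.table(read_id = f[1], reference = f[3], category = category,
               start = pos - 1L, end = pos - 1L + cigar_ref_len(f[6]),
               strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
               score = score, unique = uni)
  })
  out <- rbindlist(rows)
  if (nrow(out) == 0L) return(empty_alignments())
  out[]
}

#' Export a binned track as bedGraph
#'
#' Excluded bins (no DpnII site under restriction-site normalization) are
#' omitted rather than written as zero, preserving the distinction between
#' "no sites" and "no signal". Only tiled tracks are exportable (bedGraph
#' forbids overlap).
#'
#' @param track a \code{binned_track}.
#' @param path destination path.
#' @param name track name for the header line.
#' @export
write_bedgraph <- function(track, path, name = "charkit") {
  stopifnot(inherits(track, "binned_track"))
  if (attr(track, "step") != attr(track, "bin_size"))
    stop("bedGraph export requires a tiled track", call. = FALSE)
  dt <- as.data.table(track)[included == TRUE]
  con <- out_con(path)
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s"', name), con)
  writeLines(sprintf("%s\t%d\t%d\t%g", dt$chrom, dt$start, dt$end, dt$value), con)
  invisible(path)
}

#' Write a contacts table
#' @param contacts contact table.
#' @param path destination TSV.
#' @export
write_contacts <- function(contacts, path) {
  fwrite(as.data.table(contacts), path, sep = "\t")
  invisible(path)
}

#' Read a contacts table written by \code{\link{write_contacts}}
#' @param path TSV path.
#' @return contact data.table.
#' @export
read_contacts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  fread(path, sep = "\t")
}
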