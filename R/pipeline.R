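## End-to-end orchestration: dedup -> bridge split -> alignment (toy or
## external) -> priority annotation -> DNA placement -> contact join ->
## contact filters, with conservative loss accounting at every stage.

## references per category: gene_id-named sequence vectors
category_references <- function(annotations) {
  ann <- as.data.table(annotations)
  split(stats::setNames(ann$sequence, ann$gene_id), ann$category)
}

#' Run the full contact-mapping pipeline on a read set
#'
#' Uses the bundled exact-match toy aligner, so it is intended for
#' synthetic or desk-scale data; real libraries should be aligned
#' externally and fed through \code{\link{read_sam}} into the individual
#' stages. Every read is accounted for: the accounting partitions the input
#' into duplicates, split drops, RNA-side losses, DNA-side losses, filter
#' removals and surviving contacts.
#'
#' @param reads data.frame (read_id, sequence, qualities) or FASTQ path.
#' @param bridge a \code{\link{bridge_spec}}.
#' @param annotations transcript catalog with gene_id, category and
#'   sequence columns (see \code{\link{make_annotations}}).
#' @param genome named character vector of chromosome sequences.
#' @param priority a \code{\link{priority_order}}.
#' @param rrna_genes gene IDs removed as ribosomal (including re-annotated
#'   rRNAs).
#' @param blacklists optional interval table(s) for DNA-side filtering.
#' @return list: contacts, accounting (named integer vector whose non-input
#'   entries sum exactly to \code{input}), split_stats, filter_stats.
#' @export
run_pipeline <- function(reads, bridge, annotations, genome,
                         priority = priority_order(),
                         rrna_genes = character(), blacklists = list()) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  need_cols(reads, c("read_id", "sequence"), "reads")
  n_input <- nrow(reads)

  dd <- dedup_reads(reads)
  sp <- split_reads(dd$reads, bridge)
  kept <- as.data.table(sp$split)[is.na(drop_reason)]

  refs <- category_references(annotations)
  rna_recs <- rbindlist(lapply(names(refs), function(cat)
    toy_align(stats::setNames(kept$rna_seq, kept$read_id), refs[[cat]],
              category = cat)))
  rna_ann <- assign_rna_batch(rna_recs, priority, all_read_ids = kept$read_id)

  dna_recs <- toy_align(stats::setNames(kept$dna_seq, kept$read_id), genome,
                        category = "genome")
  dna_pl <- assign_dna(dna_recs, all_read_ids = kept$read_id)

  jn <- join_contacts(rna_ann, dna_pl)
  fl <- filter_contacts(jn$contacts, rrna_genes = rrna_genes,
                        blacklists = blacklists)

  ## partition RNA/DNA losses: a read failing both stages counts at the RNA
  ## stage (the first one), keeping the accounting additive
  st <- merge(rna_ann[, .(read_id, rna_status = status)],
              dna_pl[, .(read_id, dna_status = status)], by = "read_id")
  rna_loss <- st[rna_status != "assigned", .N, by = rna_status]
  dna_loss <- st[rna_status == "assigned" & dna_status != "placed", .N,
                 by = dna_status]
  accounting <- c(
    input = n_input,
    duplicates = dd$stats$duplicates,
    no_bridge = sp$stats$no_bridge,
    multi_bridge = sp$stats$multi_bridge,
    short_flank = sp$stats$short_flank,
    one_sided = sp$stats$one_sided,
    rna_unaligned = sum(rna_loss[rna_status == "unaligned", N]),
    rna_removed_category = sum(rna_loss[rna_status == "removed_category", N]),
    rna_ambiguous = sum(rna_loss[rna_status == "ambiguous", N]),
    dna_unaligned = sum(dna_loss[dna_status == "unaligned", N]),
    dna_multi = sum(dna_loss[dna_status == "multi", N]),
    filtered_rrna = fl$stats$removed_rrna,
    filtered_blacklist = fl$stats$removed_blacklist,
    contacts = nrow(fl$contacts))
  list(contacts = fl$contacts, accounting = accounting,
       split_stats = sp$stats, filter_stats = fl$stats)
}
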