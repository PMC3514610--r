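.TAX_RANKS <- c("phylum", "class", "order", "family", "genus")

.BLAST_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Split a contig into consecutive fragments
#'
#' Non-overlapping windows of `window` bases starting at position 1; a
#' terminal remainder of at least `min_keep` bases is kept, a shorter one is
#' dropped. A contig shorter than `window` but at least `min_keep` long
#' yields a single fragment. Fragment ids encode the contig id and 1-based
#' offset as `<contig>|<start>`.
#'
#' @param contig One row of a `contig_set`, or a list/vector with elements
#'   `id` and `seq`.
#' @param window Fragment size in bases (default 500).
#' @param min_keep Minimum fragment size retained (default 200).
#' @return Data.frame: `fragment_id`, `contig_id`, `start`, `length`, `seq`.
#' @export
fragment_contig <- function(contig, window = 500L, min_keep = 200L) {
  id <- as.character(contig$id[1L] %||% contig[["id"]])
  seq <- as.character(contig$seq[1L] %||% contig[["seq"]])
  len <- nchar(seq)
  starts <- seq.int(1L, by = window, length.out = max(len %/% window, 0L))
  rem_start <- length(starts) * window + 1L
  if (len - rem_start + 1L >= min_keep) starts <- c(starts, rem_start)
  if (length(starts) == 0L && len >= min_keep) starts <- 1L
  if (length(starts) == 0L)
    return(data.frame(fragment_id = character(), contig_id = character(),
                      start = integer(), length = integer(),
                      seq = character(), stringsAsFactors = FALSE))
  ends <- pmin(starts + window - 1L, len)
  data.frame(fragment_id = paste0(id, "|", starts), contig_id = id,
             start = starts, length = ends - starts + 1L,
             seq = substring(seq, starts, ends), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fragment every contig of a set
#' @param contigs A `contig_set`.
#' @inheritParams fragment_contig
#' @return Row-bound fragment table (see [fragment_contig()]).
#' @export
fragment_contigs <- function(contigs, window = 500L, min_keep = 200L) {
  do.call(rbind, lapply(seq_len(nrow(contigs)), function(i)
    fragment_contig(contigs[i, , drop = FALSE], window, min_keep)))
}

#' Read BLAST tabular (outfmt 6) hits
#' @param path Path to a 12-column tab-separated hit file without header.
#' @return Data.frame with the standard outfmt-6 column names.
#' @export
read_blast_hits <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 12L) stop("expected 12 tabular columns, got ", ncol(df))
  names(df) <- .BLAST_COLS
  df
}

#' Write hits in BLAST outfmt-6 layout
#' @param hits Hit data.frame with the outfmt-6 columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_hits <- function(hits, path) {
  write.table(hits[, .BLAST_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter alignment hits for taxonomic profiling
#'
#' Keeps hits longer than 200 aligned bases (strict) with at least 25 percent
#' nucleotide identity, then retains only the best hit per query fragment
#' (highest bitscore; ties broken by lowest e-value, then subject id), so
#' each fragment contributes one vote to a profile.
#'
#' @param hits Hit data.frame (outfmt-6 columns).
#' @param min_align_length Exclusive alignment-length cutoff (default 200).
#' @param min_identity Inclusive percent-identity cutoff (default 25).
#' @return Filtered hit data.frame (subset of the input rows).
#' @export
filter_hits <- function(hits, min_align_length = 200L, min_identity = 25) {
  keep <- hits$length > min_align_length & hits$pident >= min_identity
  h <- hits[keep, , drop = FALSE]
  if (nrow(h) == 0L) return(h)
  ord <- order(h$qseqid, -h$bitscore, h$evalue, h$sseqid)
  h <- h[ord, , drop = FALSE]
  h[!duplicated(h$qseqid), , drop = FALSE]
}

#' Read a subject-to-lineage table
#' @param path TSV with columns subject_id, phylum, class, order, family,
#'   genus (header optional but recommended).
#' @return Data.frame with those six columns; empty labels become
#'   "unclassified".
#' @export
read_lineage <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!identical(names(df)[1L], "subject_id"))
    names(df) <- c("subject_id", .TAX_RANKS)
  for (r in .TAX_RANKS) df[[r]][!nzchar(df[[r]]) | is.na(df[[r]])] <-
      "unclassified"
  df
}

# long tally: one row per (retained hit, rank) with its taxon and e-value
.tax_tally <- function(hits, lineage) {
  ix <- match(hits$sseqid, lineage$subject_id)
  if (anyNA(ix)) {
    warning(sum(is.na(ix)), " hit(s) with unresolvable subject id skipped")
    hits <- hits[!is.na(ix), , drop = FALSE]
    ix <- ix[!is.na(ix)]
  }
  if (nrow(hits) == 0L)
    return(data.frame(contig_id = character(), rank = character(),
                      taxon = character(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  contig <- sub("\\|[0-9]+$", "", hits$qseqid)
  do.call(rbind, lapply(.TAX_RANKS, function(r)
    data.frame(contig_id = contig, rank = r, taxon = lineage[[r]][ix],
               evalue = hits$evalue, stringsAsFactors = FALSE)))
}

# reduce tally rows (already restricted to one contig or one bin) to the
# per-rank majority profile
.summarize_tally <- function(tally) {
  out <- lapply(.TAX_RANKS, function(r) {
    tr <- tally[tally$rank == r, , drop = FALSE]
    if (nrow(tr) == 0L)
      return(data.frame(rank = r, taxon = NA_character_, hits = 0L,
                        total_hits = 0L, median_evalue = NA_real_,
                        stringsAsFactors = FALSE))
    tab <- sort(table(tr$taxon), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    maj <- sort(top)[1L] # deterministic tie-break: alphabetical
    data.frame(rank = r, taxon = maj, hits = as.integer(max(tab)),
               total_hits = nrow(tr),
               median_evalue = median(tr$evalue[tr$taxon == maj]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Taxonomic profile of one contig
#'
#' Tallies the filtered best-per-fragment hits of a contig's 500 bp pieces at
#' five ranks (phylum, class, order, family, genus). At each rank the
#' majority taxon is reported with its hit count, the total hits at that
#' rank, and the median e-value of the majority taxon's hits.
#'
#' @param hits Retained hits (after [filter_hits()]) whose `qseqid` are
#'   fragments of this contig.
#' @param lineage Lineage table (see [read_lineage()]).
#' @return Data.frame: `rank`, `taxon`, `hits`, `total_hits`,
#'   `median_evalue`; zero counts and NA taxa when there are no hits.
#' @export
contig_profile <- function(hits, lineage) {
  .summarize_tally(.tax_tally(hits, lineage))
}

#' Taxonomic profiles for all contigs at once
#' @inheritParams contig_profile
#' @return Named list of per-contig profile data.frames.
#' @export
contig_profiles <- function(hits, lineage) {
  tally <- .tax_tally(hits, lineage)
  ids <- unique(tally$contig_id)
  out <- lapply(ids, function(id)
    .summarize_tally(tally[tally$contig_id == id, , drop = FALSE]))
  names(out) <- ids
  out
}

#' Taxonomic profile of a bin
#'
#' Member contig tallies are summed per taxon at each rank; the majority
#' taxon of the summed tally is reported with the median e-value over the
#' pooled hits of that taxon. A single-contig bin's profile equals the
#' contig's own profile; members without hits contribute nothing.
#'
#' @param member_ids Contig ids belonging to the bin.
#' @param hits Retained hits (after [filter_hits()]) for the whole sample.
#' @param lineage Lineage table.
#' @return Profile data.frame as in [contig_profile()].
#' @export
bin_profile <- function(member_ids, hits, lineage) {
  tally <- .tax_tally(hits, lineage)
  .summarize_tally(tally[tally$contig_id %in% member_ids, , drop = FALSE])
}

#' Cross-validate bins against another sample at high identity
#'
#' For every query contig, the best hit with at least `min_identity` percent
#' identity (highest bitscore) is located in a reference bin; the contig's
#' full length is credited to that bin. Contigs without a qualifying hit are
#' recovered to no bin.
#'
#' @param query_contigs A `contig_set` (queries; `qseqid` = contig id).
#' @param reference_bins Data.frame mapping reference contig id (`id`) to
#'   `bin`, or a `binning_result` whose assignments provide that mapping.
#' @param hits Hit table of query contigs vs reference contigs.
#' @param min_identity Identity cutoff in percent (default 98).
#' @return Data.frame: `bin`, `recovered_nt`, `n_contigs`.
#' @export
crossvalidate <- function(query_contigs, reference_bins, hits,
                          min_identity = 98) {
  if (inherits(reference_bins, "binning_result"))
    reference_bins <- reference_bins$assignments[, c("id", "bin")]
  h <- hits[hits$pident >= min_identity, , drop = FALSE]
  if (nrow(h)) {
    ord <- order(h$qseqid, -h$bitscore, h$evalue, h$sseqid)
    h <- h[ord, , drop = FALSE]
    h <- h[!duplicated(h$qseqid), , drop = FALSE]
  }
  h$bin <- reference_bins$bin[match(h$sseqid, reference_bins$id)]
  h <- h[!is.na(h$bin), , drop = FALSE]
  qlen <- setNames(query_contigs$length, query_contigs$id)
  if (nrow(h) == 0L)
    return(data.frame(bin = integer(), recovered_nt = numeric(),
                      n_contigs = integer(), stringsAsFactors = FALSE))
  agg <- tapply(qlen[h$qseqid], h$bin, sum)
  cnt <- tapply(h$qseqid, h$bin, length)
  data.frame(bin = as.integer(names(agg)), recovered_nt = as.numeric(agg),
             n_contigs = as.integer(cnt), stringsAsFactors = FALSE)
}

#' Write a lineage table
#' @param lineage Data.frame with subject_id and the five rank columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lineage <- function(lineage, path) {
  write.table(lineage[, c("subject_id", .TAX_RANKS)], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
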