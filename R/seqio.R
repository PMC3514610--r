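#' Read assembled contigs from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file into a contig table. Sequences
#' are upper-cased; the full header line (without the leading `>`) is kept
#' verbatim, and the identifier is the first whitespace-delimited token.
#' Per-contig sequencing coverage is extracted from the header with
#' [parse_coverage()].
#'
#' @param path Path to a FASTA file.
#' @param mean_read_length Optional mean read length (bases) used to estimate
#'   coverage from a `numreads` header field when no explicit coverage field
#'   is present.
#' @return A `contig_set`: a data.frame with columns `id`, `header`, `seq`,
#'   `length`, `coverage` (NA when absent) and `truth_label` (NA unless the
#'   contigs are simulated).
#' @export
read_fasta <- function(path, mean_read_length = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path)
  # tolerate trailing blank lines; reject text before the first '>'
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    return(contig_set(character(), character(), character()))
  first <- nonblank[1L]
  if (!startsWith(lines[first], ">"))
    stop("malformed FASTA: sequence or text before first '>' at line ", first)
  hdr_idx <- which(startsWith(lines, ">"))
  ends <- c(hdr_idx[-1L] - 1L, length(lines))
  headers <- sub("^>", "", lines[hdr_idx])
  seqs <- vapply(seq_along(hdr_idx), function(i) {
    if (ends[i] < hdr_idx[i] + 1L) return("")
    paste0(lines[(hdr_idx[i] + 1L):ends[i]], collapse = "")
  }, character(1))
  seqs <- toupper(gsub("[ \t]", "", seqs))
  empty <- which(!nzchar(seqs))
  if (length(empty))
    stop("malformed FASTA: empty sequence for entry at line ",
         hdr_idx[empty[1L]], " (", headers[empty[1L]], ")")
  ids <- sub("\\s.*$", "", headers)
  cov <- vapply(seq_along(headers), function(i)
    parse_coverage(headers[i], mean_read_length = mean_read_length,
                   contig_length = nchar(seqs[i])),
    numeric(1))
  contig_set(ids, seqs, headers, coverage = cov)
}

#' Construct a contig table
#'
#' @param id Character vector of contig identifiers.
#' @param seq Character vector of nucleotide sequences (upper-cased).
#' @param header Full original header text; defaults to `id`.
#' @param coverage Per-contig coverage, NA when unknown.
#' @param truth_label Source genome of each contig (simulations only).
#' @return A data.frame of class `contig_set`.
#' @export
contig_set <- function(id, seq, header = id, coverage = NA_real_,
                       truth_label = NA_character_) {
  seq <- toupper(seq)
  n <- length(id)
  df <- data.frame(id = as.character(id), header = as.character(header),
                   seq = seq, length = nchar(seq),
                   coverage = rep_len(as.numeric(coverage), n),
                   truth_label = rep_len(as.character(truth_label), n),
                   stringsAsFactors = FALSE)
  bad <- which(!is.na(df$coverage) & df$coverage <= 0)
  if (length(bad)) stop("coverage must be > 0 when present (contig ",
                        df$id[bad[1L]], ")")
  class(df) <- c("contig_set", "data.frame")
  df
}

#' Write contigs to FASTA
#'
#' Sequences are wrapped at 70 columns; the stored header is written verbatim.
#'
#' @param contigs A `contig_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path) {
  x <- Biostrings::DNAStringSet(contigs$seq)
  names(x) <- contigs$header
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Parse sequencing coverage from an assembler FASTA header
#'
#' Two header dialects are recognized, in order of precedence:
#' an explicit coverage field matching `cov[a-z]*?[=_]([\d.]+)` (matched
#' against the lower-cased header, so `Cov=12`, `coverage_12` and
#' `..._cov_22.7` all work), and a read-count field matching
#' `numreads *= *(\d+)`, from which coverage is estimated as
#' `numreads * mean_read_length / contig_length`.
#'
#' @param header Header text (without or with the leading `>`).
#' @param mean_read_length Mean read length in bases, required for the
#'   read-count fallback; if absent and only `numreads` matches, NA is
#'   returned with a warning.
#' @param contig_length Contig length in bases (read-count fallback only).
#' @return Coverage as a number, or `NA_real_` when no pattern matches.
#' @export
#' @examples
#' parse_coverage("node_3_length_5021_cov_22.715717")
#' parse_coverage("contig00042 numreads=360",
#'                mean_read_length = 100, contig_length = 6000)
parse_coverage <- function(header, mean_read_length = NULL,
                           contig_length = NULL) {
  stopifnot(is.character(header), length(header) == 1L, nzchar(header))
  h <- tolower(header)
  m <- regmatches(h, regexec("cov[a-z]*?[=_]([0-9.]+)", h))[[1L]]
  if (length(m) == 2L) {
    v <- suppressWarnings(as.numeric(m[2L]))
    if (!is.na(v)) return(v)
  }
  m <- regmatches(h, regexec("numreads *= *([0-9]+)", h))[[1L]]
  if (length(m) == 2L) {
    if (is.null(mean_read_length) || is.null(contig_length) ||
        is.na(mean_read_length) || is.na(contig_length)) {
      warning("header carries a read count but mean_read_length/contig_length",
              " not supplied; coverage left undefined: ", header)
      return(NA_real_)
    }
    return(as.numeric(m[2L]) * mean_read_length / contig_length)
  }
  NA_real_
}
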