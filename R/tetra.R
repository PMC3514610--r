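#' Canonical tetranucleotide classes
#'
#' Under the assumption that both DNA strands are sampled equally, a 4-mer and
#' its reverse complement carry the same information, so the 256
#' tetranucleotides collapse into 136 canonical classes: 120 two-member pairs
#' plus 16 palindromes (4-mers equal to their own reverse complement). Classes
#' are ordered by the lexicographically smallest member so vectors are
#' comparable across runs.
#'
#' @return A list with `class_of` (integer vector of length 256 mapping the
#'   lexicographic 4-mer index to a class index in 1..136), `class_names`
#'   (the smallest member of each class), `palindromic` (logical per class)
#'   and `class_count` (136).
#' @export
build_canonical_map <- function() {
  if (!is.null(.tetrabin_env$canonical_map)) return(.tetrabin_env$canonical_map)
  idx <- 0:255
  b <- cbind(idx %/% 64L, (idx %/% 16L) %% 4L, (idx %/% 4L) %% 4L, idx %% 4L)
  # reverse complement: reverse base order, complement each (code -> 3 - code)
  rc <- (3L - b[, 4L]) * 64L + (3L - b[, 3L]) * 16L +
        (3L - b[, 2L]) * 4L + (3L - b[, 1L])
  canon <- pmin(idx, rc)
  members <- sort(unique(canon))
  class_of <- match(canon, members)
  bases <- c("A", "C", "G", "T")
  nm <- apply(cbind(members %/% 64L, (members %/% 16L) %% 4L,
                    (members %/% 4L) %% 4L, members %% 4L) + 1L, 1L,
              function(r) paste0(bases[r], collapse = ""))
  map <- list(class_of = class_of, class_names = nm,
              palindromic = members == rc[members + 1L],
              class_count = length(members))
  .tetrabin_env$canonical_map <- map
  map
}

# encode a nucleotide string as integer codes 0..3 (A,C,G,T), NA otherwise
.encode_seq <- function(seq) {
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("T")] <- 3L
  lut[utf8ToInt("a")] <- 0L; lut[utf8ToInt("c")] <- 1L
  lut[utf8ToInt("g")] <- 2L; lut[utf8ToInt("t")] <- 3L
  ints <- utf8ToInt(seq)
  ints[ints > 128L] <- 1L
  lut[ints]
}

.decode_codes <- function(codes) {
  paste(c("A", "C", "G", "T")[codes + 1L], collapse = "")
}

# canonical class index per sliding 4-base window (NA where the window
# contains a non-ACGT character); length(seq) - 3 entries
.window_classes <- function(codes, map = build_canonical_map()) {
  n <- length(codes)
  if (n < 4L) return(integer(0))
  k <- n - 3L
  idx <- codes[1:k] * 64L + codes[2:(k + 1L)] * 16L +
         codes[3:(k + 2L)] * 4L + codes[4:(k + 3L)]
  map$class_of[idx + 1L]
}

#' Normalized canonical tetranucleotide frequency vector
#'
#' Slides a 4-base window along the sequence in steps of one; windows
#' containing any non-ACGT character are skipped and excluded from the
#' denominator. The count of each canonical class is divided by the number of
#' matched windows and scaled by 136, so the 136 entries sum to 136 (mean 1).
#'
#' @param seq A nucleotide string, or a vector of integer base codes as
#'   produced internally.
#' @param map Canonical class map from [build_canonical_map()].
#' @return A list of class `tetra_freq` with `values` (numeric, length 136,
#'   named by class), `matched_windows` (valid window count) and `valid`
#'   (FALSE when no window was matched; `values` are then all NA).
#' @export
frequency_vector <- function(seq, map = build_canonical_map()) {
  codes <- if (is.character(seq)) .encode_seq(seq) else seq
  cls <- .window_classes(codes, map)
  cls <- cls[!is.na(cls)]
  matched <- length(cls)
  if (matched == 0L) {
    v <- rep(NA_real_, map$class_count)
  } else {
    v <- tabulate(cls, nbins = map$class_count) / matched * map$class_count
  }
  names(v) <- map$class_names
  structure(list(values = v, matched_windows = matched, valid = matched > 0L),
            class = "tetra_freq")
}

#' Frequency vectors for a set of sequences
#'
#' @param seqs Character vector of sequences (e.g. `contigs$seq`).
#' @param map Canonical class map.
#' @return A list with `values` (matrix, one row per sequence, 136 columns;
#'   NA rows where no window matched) and `matched_windows` (integer vector).
#' @export
frequency_matrix <- function(seqs, map = build_canonical_map()) {
  n <- length(seqs)
  vals <- matrix(NA_real_, nrow = n, ncol = map$class_count,
                 dimnames = list(names(seqs), map$class_names))
  matched <- integer(n)
  for (i in seq_len(n)) {
    fv <- frequency_vector(seqs[[i]], map)
    vals[i, ] <- fv$values
    matched[i] <- fv$matched_windows
  }
  list(values = vals, matched_windows = matched)
}

.as_freq_values <- function(v) {
  if (inherits(v, "tetra_freq")) {
    if (!v$valid) stop("undefined frequency vector (no matched windows)")
    return(v$values)
  }
  stopifnot(is.numeric(v), length(v) == 136L)
  if (anyNA(v)) stop("undefined frequency vector (NA values)")
  v
}

#' Export frequency vectors as a tab-separated table
#'
#' One row per sequence: identifier followed by the 136 class frequencies,
#' with class names as column headers. [read_frequency_table()] reads it back.
#'
#' @param mat Result of [frequency_matrix()].
#' @param ids Sequence identifiers (row order of `mat$values`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(mat, ids, path) {
  df <- data.frame(id = ids, mat$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frequency_table
#' @export
read_frequency_table <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$id
  vals
}

# reverse complement on a code vector
.revcomp_codes <- function(codes) rev(3L - codes)

#' Reverse complement of a nucleotide string
#' @param seq Nucleotide string (A/C/G/T/N and IUPAC codes).
#' @return The reverse complement string.
#' @export
reverse_complement <- function(seq) {
  chartr("ACGTMRWSYKVHDBNacgtmrwsykvhdbn",
         "TGCAKYWSRMBDHVNtgcakywsrmbdhvn",
         paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}
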