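#' Default fragment length grid (bases)
#'
#' The 38 fragment lengths, from 0.3 to 100 kb, at which dispersion and
#' probability thresholds are calibrated.
#'
#' @return Integer vector of 38 lengths in bases.
#' @export
default_length_grid <- function() {
  as.integer(1000 * c(0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0, 1.1, 1.2, 1.3,
                      1.4, 1.5, 1.75, 2, 2.25, 2.5, 2.75, 3, 4, 5, 6, 7, 8,
                      10, 12, 14, 16, 18, 20, 25, 30, 40, 50, 60, 70, 80, 100))
}

# run expr with a locally-seeded RNG, restoring global state afterwards
.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

.fragment_starts <- function(genome_len, l, n) {
  sample.int(genome_len - l + 1L, n, replace = TRUE)
}

#' Sample fragments of fixed lengths from a genome
#'
#' Draws `n_per_length` substrings at uniformly random start positions for
#' each requested length. Deterministic for a given seed. Lengths exceeding
#' the genome are skipped with a warning.
#'
#' @param genome A nucleotide string (or a `synthetic_genome`).
#' @param lengths Fragment lengths in bases.
#' @param n_per_length Fragments per length (default 100).
#' @param seed Integer seed.
#' @return A named list (one element per usable length, named by the length)
#'   of character vectors of fragments.
#' @export
sample_fragments <- function(genome, lengths, n_per_length = 100L, seed) {
  if (is.list(genome) && !is.null(genome$seq)) genome <- genome$seq
  glen <- nchar(genome)
  usable <- lengths[lengths <= glen]
  if (length(usable) < length(lengths))
    warning("genome shorter than requested length(s): ",
            paste(setdiff(lengths, usable), collapse = ", "), "; skipped")
  .with_seed(seed, {
    out <- lapply(usable, function(l) {
      s <- .fragment_starts(glen, l, n_per_length)
      substring(genome, s, s + l - 1L)
    })
    names(out) <- usable
    out
  })
}

# per-fragment canonical-class frequency matrix from a precomputed
# window-class vector of the source genome (fast path used by calibration)
.fragment_freqs <- function(classvec, starts, l, n_classes = 136L) {
  n <- length(starts)
  out <- matrix(0, nrow = n, ncol = n_classes)
  nw <- l - 3L
  for (i in seq_len(n)) {
    cl <- classvec[starts[i]:(starts[i] + nw - 1L)]
    cl <- cl[!is.na(cl)]
    out[i, ] <- tabulate(cl, nbins = n_classes) / length(cl) * n_classes
  }
  out
}

#' Calibrate dispersion and probability-threshold lookup tables
#'
#' Builds the two empirical relationships that drive the Gaussian contig
#' membership model. For every reference genome and every fragment length,
#' `n_per_length` fragments are sampled and their canonical tetranucleotide
#' frequency vectors computed. For each class the standard deviation of the
#' fragment frequencies (s) is paired with the genome's mean frequency (m);
#' pooling these (m, s) points over all genomes and classes, binning m, and
#' averaging s per cell yields the dispersion table s = f(m, l). Each
#' fragment's log-probability against its own source genome is then computed
#' under that table, and the (100 - recall)-th percentile of the pooled
#' log-probabilities at each length gives the acceptance threshold for the
#' 90 / 95 / 98 percent recall levels.
#'
#' @param genomes Named character vector of genome sequences, a list of
#'   `synthetic_genome` objects, or a `contig_set`.
#' @param lengths Fragment length grid; default [default_length_grid()].
#' @param n_per_length Fragments sampled per genome per length (default 100).
#' @param seed Integer seed (required: calibration is a sampling procedure).
#' @param m_breaks Mean-frequency bin breaks; default width 0.05 over [0, 4],
#'   values above 4 clamped into the last bin.
#' @param sigma_floor Lower bound on any interpolated sigma (default 1e-3),
#'   preventing infinite log-densities for never-observed classes.
#' @return A `calibration_tables` object: list with `sigma`
#'   (`length_grid`, `m_centers`, `values` matrix m x l, `counts`),
#'   `thresholds` (matrix, rows "90","95","98" by length), `sigma_floor`, and
#'   `provenance` (genome count, n_per_length, seed).
#' @export
build_tables <- function(genomes, lengths = default_length_grid(),
                         n_per_length = 100L, seed,
                         m_breaks = seq(0, 4, by = 0.05),
                         sigma_floor = 1e-3) {
  seqs <- .as_genome_seqs(genomes)
  map <- build_canonical_map()
  nc <- map$class_count
  keep <- vapply(seqs, function(s) {
    fv <- frequency_vector(s, map)
    fv$valid
  }, logical(1))
  if (any(!keep))
    warning("excluding ", sum(!keep), " genome(s) with undefined vectors")
  seqs <- seqs[keep]
  if (length(seqs) < 2L)
    stop("calibration requires at least 2 usable genomes")
  glens <- nchar(seqs)
  lengths <- sort(unique(as.integer(lengths)))
  usable_l <- lengths[lengths <= min(glens)]
  if (length(usable_l) < length(lengths))
    warning("length(s) exceeding the shortest genome skipped: ",
            paste(setdiff(lengths, usable_l), collapse = ", "))
  lengths <- usable_l

  centers <- head(m_breaks, -1L) + diff(m_breaks) / 2
  nb <- length(centers)
  nl <- length(lengths)

  # per-genome window-class vectors and mean vectors
  gdata <- .with_seed(seed, lapply(seq_along(seqs), function(g) {
    codes <- .encode_seq(seqs[[g]])
    classvec <- .window_classes(codes, map)
    valid <- classvec[!is.na(classvec)]
    mvec <- tabulate(valid, nbins = nc) / length(valid) * nc
    frag <- lapply(lengths, function(l) {
      starts <- .fragment_starts(glens[g], l, n_per_length)
      .fragment_freqs(classvec, starts, l, nc)
    })
    names(frag) <- lengths
    list(mean = mvec, frag = frag)
  }))

  # dispersion table: pool (m, s) points per length, bin m, average s
  sig <- matrix(NA_real_, nrow = nb, ncol = nl,
                dimnames = list(NULL, lengths))
  cnt <- matrix(0L, nrow = nb, ncol = nl, dimnames = list(NULL, lengths))
  for (j in seq_len(nl)) {
    m_all <- unlist(lapply(gdata, function(gd) gd$mean))
    s_all <- unlist(lapply(gdata, function(gd) {
      F <- gd$frag[[j]]
      sqrt(colSums(sweep(F, 2L, colMeans(F))^2) / (nrow(F) - 1L))
    }))
    bin <- findInterval(pmin(m_all, max(m_breaks) - 1e-12), m_breaks,
                        rightmost.closed = TRUE)
    bin[bin < 1L] <- 1L
    sums <- tapply(s_all, bin, sum)
    ns <- tapply(s_all, bin, length)
    ix <- as.integer(names(sums))
    sig[ix, j] <- sums / ns
    cnt[ix, j] <- as.integer(ns)
  }
  # fill empty mean-frequency cells from the nearest populated cell along m
  for (j in seq_len(nl)) {
    filled <- which(!is.na(sig[, j]))
    if (length(filled) == 0L) stop("no dispersion observations at length ",
                                   lengths[j])
    empty <- which(is.na(sig[, j]))
    if (length(empty))
      sig[empty, j] <- sig[filled[vapply(empty, function(e)
        which.min(abs(filled - e)), integer(1))], j]
  }
  sig <- pmax(sig, sigma_floor)

  tables <- list(sigma = list(length_grid = lengths, m_centers = centers,
                              values = sig, counts = cnt),
                 thresholds = NULL, sigma_floor = sigma_floor,
                 provenance = list(n_genomes = length(seqs),
                                   n_per_length = n_per_length, seed = seed))
  class(tables) <- "calibration_tables"

  # thresholds: percentiles of pooled same-genome fragment log-probabilities
  conf <- c(90, 95, 98)
  thr <- matrix(NA_real_, nrow = 3L, ncol = nl,
                dimnames = list(as.character(conf), lengths))
  for (j in seq_len(nl)) {
    lp <- unlist(lapply(gdata, function(gd) {
      .log_probability_rows(gd$frag[[j]], gd$mean, lengths[j], tables)
    }))
    thr[, j] <- quantile(lp, probs = (100 - conf) / 100, names = FALSE)
  }
  tables$thresholds <- thr
  tables
}

.as_genome_seqs <- function(genomes) {
  if (inherits(genomes, "contig_set")) {
    s <- genomes$seq; names(s) <- genomes$id; return(s)
  }
  if (is.list(genomes)) {
    s <- vapply(genomes, function(g)
      if (is.list(g)) g$seq else g, character(1))
    ids <- vapply(seq_along(genomes), function(i) {
      g <- genomes[[i]]
      if (is.list(g) && !is.null(g$id)) g$id else paste0("genome_", i)
    }, character(1))
    names(s) <- ids
    return(s)
  }
  stopifnot(is.character(genomes))
  if (is.null(names(genomes)))
    names(genomes) <- paste0("genome_", seq_along(genomes))
  genomes
}

#' Interpolated dispersion lookup
#'
#' Bilinear interpolation of the calibrated dispersion table: linear in the
#' mean frequency m and linear in log fragment length. Queries outside the
#' grid are clamped to its edge; the result is floored at the calibration
#' `sigma_floor`.
#'
#' @param tables A `calibration_tables` object.
#' @param m Mean frequency (vectorized).
#' @param l Fragment length in bases (scalar).
#' @return Standard deviation(s), same length as `m`.
#' @export
lookup_sigma <- function(tables, m, l) {
  st <- tables$sigma
  lg <- st$length_grid
  l <- min(max(l, lg[1L]), lg[length(lg)])
  j <- findInterval(l, lg, all.inside = TRUE)
  col_lo <- .interp_m(st, m, j)
  if (lg[j] == l) {
    s <- col_lo
  } else {
    col_hi <- .interp_m(st, m, j + 1L)
    w <- (log(l) - log(lg[j])) / (log(lg[j + 1L]) - log(lg[j]))
    s <- (1 - w) * col_lo + w * col_hi
  }
  pmax(s, tables$sigma_floor)
}

.interp_m <- function(st, m, j) {
  ctr <- st$m_centers
  col <- st$values[, j]
  m <- pmin(pmax(m, ctr[1L]), ctr[length(ctr)])
  i <- findInterval(m, ctr, all.inside = TRUE)
  w <- (m - ctr[i]) / (ctr[i + 1L] - ctr[i])
  (1 - w) * col[i] + w * col[i + 1L]
}

#' Threshold lookup at a confidence level and length
#'
#' Linear interpolation in log length of the calibrated log-probability
#' cutoff; lengths outside the grid are clamped.
#'
#' @param tables A `calibration_tables` object.
#' @param confidence One of 90, 95, 98 (percent recall).
#' @param l Contig length in bases.
#' @return Log-probability threshold.
#' @export
lookup_threshold <- function(tables, confidence, l) {
  row <- tables$thresholds[as.character(confidence), ]
  lg <- tables$sigma$length_grid
  stats::approx(log(lg), row, xout = log(min(max(l, lg[1L]),
                                             lg[length(lg)])),
                rule = 2)$y
}

#' Gaussian log-probability of contig membership
#'
#' Log of the 136-dimensional product of independent Gaussian densities: for
#' each canonical class x, the contig's frequency v_x is scored against the
#' candidate source's mean m_x with dispersion s_x = f(m_x, l) from the
#' calibrated lookup table. All arithmetic is in log space (the raw product
#' underflows at 136 dimensions).
#'
#' When `abort_below` is given, evaluation stops early as soon as the partial
#' sum plus an upper bound on all remaining terms (suffix sums of the
#' per-class maxima -log(sqrt(2*pi)*s_x)) falls below the cutoff; an aborted
#' call returns a value guaranteed to be <= `abort_below`, flagged with
#' attribute `aborted = TRUE`. Accept/reject decisions against `abort_below`
#' are identical to the full sum.
#'
#' @param v Contig frequency vector (`tetra_freq` or numeric of length 136).
#' @param m Candidate source mean vector (same forms).
#' @param l Contig length in bases.
#' @param tables A `calibration_tables` object.
#' @param abort_below Optional log-probability cutoff enabling early abort.
#' @return Log-probability (numeric scalar), with attribute `aborted`.
#' @export
log_probability <- function(v, m, l, tables, abort_below = NULL) {
  v <- .as_freq_values(v)
  m <- .as_freq_values(m)
  s <- lookup_sigma(tables, m, l)
  const <- -log(sqrt(2 * pi) * s)
  terms <- const - (v - m)^2 / (2 * s^2)
  if (is.null(abort_below)) {
    return(structure(sum(terms), aborted = FALSE))
  }
  # bound for terms after position i: each term_x <= const_x
  suffix <- rev(cumsum(rev(const))) # suffix[i] = sum(const[i:136])
  partial <- 0
  n <- length(terms)
  for (i in seq_len(n)) {
    partial <- partial + terms[i]
    bound <- if (i < n) partial + suffix[i + 1L] else partial
    if (bound < abort_below)
      return(structure(bound, aborted = i < n))
  }
  structure(partial, aborted = FALSE)
}

# vectorized full-sum log-probabilities of fragment rows vs one mean vector
.log_probability_rows <- function(F, m, l, tables) {
  s <- lookup_sigma(tables, m, l)
  const_sum <- -sum(log(sqrt(2 * pi) * s))
  dev <- sweep(F, 2L, m)
  const_sum - rowSums(sweep(dev^2, 2L, 2 * s^2, "/"))
}

#' Serialize calibration tables to a plain-text file
#'
#' Versioned tab-separated format: a provenance header, the dispersion matrix
#' (rows = mean-frequency bin centers), the per-cell observation counts and
#' the threshold matrix. Values are written at full double precision so a
#' read/write round trip is bit-identical.
#'
#' @param tables A `calibration_tables` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(tables, path) {
  con <- file(path, "w")
  on.exit(close(con))
  pv <- tables$provenance
  fmt <- function(x) sprintf("%.17g", x)
  writeLines(c("#tetrabin-calibration\tv1",
               sprintf("#provenance\tn_genomes=%d\tn_per_length=%d\tseed=%d\tsigma_floor=%s",
                       pv$n_genomes, pv$n_per_length, pv$seed,
                       fmt(tables$sigma_floor))), con)
  st <- tables$sigma
  writeLines(paste0("#lengths\t", paste(st$length_grid, collapse = "\t")), con)
  writeLines(paste0("#m_centers\t", paste(fmt(st$m_centers), collapse = "\t")),
             con)
  writeLines("#sigma", con)
  writeLines(apply(st$values, 1L, function(r) paste(fmt(r), collapse = "\t")),
             con)
  writeLines("#counts", con)
  writeLines(apply(st$counts, 1L, function(r) paste(r, collapse = "\t")), con)
  writeLines("#thresholds", con)
  writeLines(vapply(rownames(tables$thresholds), function(cf)
    paste(c(cf, fmt(tables$thresholds[cf, ])), collapse = "\t"),
    character(1)), con)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "#tetrabin-calibration"))
    stop("not a calibration file: ", path)
  kv <- strsplit(sub("^#provenance\t", "", lines[2L]), "\t")[[1L]]
  kvl <- setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
  lengths <- as.integer(strsplit(sub("^#lengths\t", "", lines[3L]),
                                 "\t")[[1L]])
  centers <- as.numeric(strsplit(sub("^#m_centers\t", "", lines[4L]),
                                 "\t")[[1L]])
  sec <- function(tag) which(lines == tag)
  i_sig <- sec("#sigma"); i_cnt <- sec("#counts"); i_thr <- sec("#thresholds")
  parse_block <- function(from, to)
    do.call(rbind, lapply(lines[from:to], function(x)
      as.numeric(strsplit(x, "\t")[[1L]])))
  sig <- parse_block(i_sig + 1L, i_cnt - 1L)
  cnt <- parse_block(i_cnt + 1L, i_thr - 1L)
  colnames(sig) <- colnames(cnt) <- lengths
  thr_rows <- lapply(lines[(i_thr + 1L):length(lines)],
                     function(x) strsplit(x, "\t")[[1L]])
  thr <- do.call(rbind, lapply(thr_rows, function(r) as.numeric(r[-1L])))
  rownames(thr) <- vapply(thr_rows, `[[`, character(1), 1L)
  colnames(thr) <- lengths
  structure(list(sigma = list(length_grid = lengths, m_centers = centers,
                              values = sig,
                              counts = matrix(as.integer(cnt), nrow(cnt),
                                              dimnames = dimnames(cnt))),
                 thresholds = thr,
                 sigma_floor = as.numeric(kvl[["sigma_floor"]]),
                 provenance = list(n_genomes = as.integer(kvl[["n_genomes"]]),
                                   n_per_length = as.integer(kvl[["n_per_length"]]),
                                   seed = as.integer(kvl[["seed"]]))),
            class = "calibration_tables")
}
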