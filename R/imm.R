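# k-mer counts (width w) over valid windows of a code vector
.kmer_counts <- function(codes, w) {
  n <- length(codes)
  if (n < w) return(integer(4L^w))
  k <- n - w + 1L
  idx <- codes[1:k]
  if (w > 1L) for (p in 2:w) idx <- idx * 4L + codes[p:(k + p - 1L)]
  tabulate(idx[!is.na(idx)] + 1L, nbins = 4L^w)
}

#' Train an interpolated Markov model
#'
#' Counts (context, next base) occurrences for context orders 0..`max_order`
#' over all training sequences and their reverse complements (strand
#' symmetry), then precomputes interpolated conditional probabilities. At
#' order k the probability blends the maximum-likelihood estimate with the
#' order k-1 probability of the context suffix:
#' `P_k = lambda_k * MLE_k + (1 - lambda_k) * P_{k-1}` with
#' `lambda_k = min(1, count(context) / interpolation_threshold)`, so contexts
#' seen at least `interpolation_threshold` times are fully trusted. The
#' order-0 distribution is the pseudocount-smoothed base composition.
#' Non-ACGT characters break contexts; no background (negative) model is
#' involved.
#'
#' @param sequences Character vector of training sequences.
#' @param max_order Longest context length K (default 8).
#' @param interpolation_threshold Context count at which the MLE is fully
#'   trusted (default 400).
#' @param pseudocount Order-0 smoothing constant (default 1).
#' @return An `imm_model`: list with `max_order`,
#'   `interpolation_threshold`, `pseudocount`, `counts` (per-order k-mer
#'   count vectors), `probs` (per-order matrices, 4^k x 4, rows summing to
#'   1) and `train_nt` (total training bases).
#' @export
imm_train <- function(sequences, max_order = 8L,
                      interpolation_threshold = 400L, pseudocount = 1) {
  sequences <- sequences[nzchar(sequences)]
  if (length(sequences) == 0L) stop("empty training set")
  K <- as.integer(max_order)
  stopifnot(K >= 1L)
  counts <- vector("list", K + 1L)
  for (k in 0:K) counts[[k + 1L]] <- integer(4L^(k + 1L))
  total_nt <- 0
  for (s in sequences) {
    codes <- .encode_seq(s)
    total_nt <- total_nt + sum(!is.na(codes))
    rc <- .revcomp_codes(codes)
    for (k in 0:K) {
      counts[[k + 1L]] <- counts[[k + 1L]] + .kmer_counts(codes, k + 1L) +
        .kmer_counts(rc, k + 1L)
    }
  }
  model <- .imm_from_counts(counts, K, interpolation_threshold, pseudocount)
  model$train_nt <- total_nt
  model
}

#' Score a sequence under an interpolated Markov model
#'
#' Sum over positions of `log P(base | context)` using the interpolated
#' conditional probabilities. The context of a position is the longest run
#' of valid bases immediately preceding it, capped at the model's
#' `max_order`; positions at the start of the sequence (or just after a
#' non-ACGT character, which resets the context) use correspondingly shorter
#' orders. Non-ACGT positions contribute zero.
#'
#' @param model An `imm_model`.
#' @param seq Nucleotide string.
#' @return Log-likelihood (finite numeric scalar).
#' @export
imm_score <- function(model, seq) {
  codes <- if (is.character(seq)) .encode_seq(seq) else seq
  info <- .imm_context(codes, model$max_order)
  .imm_score_ctx(model, info)
}

# precompute, once per sequence, everything scoring needs: per-order context
# indices and the usable context length at every position
.imm_context <- function(codes, K) {
  n <- length(codes)
  if (n == 0L)
    return(list(n = 0L, K = K))
  valid <- !is.na(codes)
  # index of the last invalid position at or before i (0 when none)
  lastbad <- cummax(seq_len(n) * !valid)
  avail <- pmin(K, seq_len(n) - 1L - c(0L, lastbad[-n]))
  avail[!valid] <- -1L # excluded below
  # ctx[[k+1]][i] = base-4 context of length k ending just before position i
  ctx <- vector("list", K + 1L)
  ctx[[1L]] <- integer(n)
  pow <- 1L
  for (k in seq_len(K)) {
    shifted <- c(rep(NA_integer_, k), codes[seq_len(n - k)])
    ctx[[k + 1L]] <- shifted * pow + ctx[[k]]
    pow <- pow * 4L
  }
  sel <- lapply(0:K, function(c_ord) which(avail == c_ord))
  idx <- lapply(0:K, function(c_ord) {
    s <- sel[[c_ord + 1L]]
    cbind(ctx[[c_ord + 1L]][s] + 1L, codes[s] + 1L)
  })
  list(n = n, K = K, idx = idx)
}

.imm_score_ctx <- function(model, info) {
  if (info$n == 0L) return(0)
  stopifnot(info$K == model$max_order)
  logp <- 0
  for (c_ord in 0:model$max_order) {
    ix <- info$idx[[c_ord + 1L]]
    if (nrow(ix) == 0L) next
    logp <- logp + sum(log(model$probs[[c_ord + 1L]][ix]))
  }
  logp
}

#' Assign contigs to the highest-scoring model
#'
#' Scores every contig under every model and assigns it to the arg-max. Ties
#' go to the model trained on more nucleotides, then to the lowest bin id.
#' Assignment is invariant to the ordering of `models`.
#'
#' @param models Named list of `imm_model` objects (names = bin labels).
#' @param contigs A `contig_set`.
#' @return Data.frame: `id`, `length`, `bin` (integer index into the sorted
#'   unique model names), `model` (model name), `score`.
#' @export
imm_assign <- function(models, contigs) {
  stopifnot(length(models) >= 1L)
  if (is.null(names(models))) names(models) <- seq_along(models)
  mnames <- names(models)
  train_nt <- vapply(models, `[[`, numeric(1), "train_nt")
  S <- matrix(NA_real_, nrow = nrow(contigs), ncol = length(models),
              dimnames = list(contigs$id, mnames))
  K <- models[[1L]]$max_order
  for (i in seq_len(nrow(contigs))) {
    info <- .imm_context(.encode_seq(contigs$seq[i]), K)
    S[i, ] <- vapply(models, .imm_score_ctx, numeric(1), info = info)
  }
  pick <- apply(S, 1L, function(r) {
    best <- which(r == max(r))
    if (length(best) > 1L) {
      best <- best[order(-train_nt[best], best)][1L]
    }
    best
  })
  data.frame(id = contigs$id, length = contigs$length,
             bin = as.integer(pick), model = mnames[pick],
             score = S[cbind(seq_len(nrow(S)), pick)],
             stringsAsFactors = FALSE)
}

#' Rank seed-bin candidates for model training
#'
#' Applies the three "good bin" heuristics — long bins, homogeneous
#' sequencing coverage, consistent taxonomic profile — as explicit gates and
#' emits a diagnostic report. The tool never auto-trains from this report;
#' the bin list is for the user to accept or override.
#'
#' @param result A `binning_result`.
#' @param profiles Optional named list of bin profiles (names = bin ids, as
#'   from [bin_profile()]); when absent the taxonomy gate passes with NA
#'   diagnostics.
#' @param min_bin_length Minimum bin total length in bases (default 2e5).
#' @param max_coverage_cv Maximum coefficient of variation of member
#'   coverages (default 0.5); bins without coverage get NA and pass.
#' @param min_majority_fraction Minimum fraction of genus-rank hits on the
#'   majority genus (default 0.5).
#' @return Data.frame: `bin`, `total_length`, `coverage_cv`,
#'   `majority_fraction`, `pass_length`, `pass_coverage`, `pass_taxonomy`,
#'   `candidate`, ordered by decreasing total length.
#' @export
select_seed_bins <- function(result, profiles = NULL, min_bin_length = 2e5,
                             max_coverage_cv = 0.5,
                             min_majority_fraction = 0.5) {
  rows <- lapply(result$bins, function(b) {
    cv <- NA_real_
    cov <- b$coverage_values[!is.na(b$coverage_values)]
    if (length(cov) >= 1L)
      cv <- if (length(cov) == 1L) 0 else sd(cov) / mean(cov)
    mf <- NA_real_
    if (!is.null(profiles) && as.character(b$id) %in% names(profiles)) {
      pr <- profiles[[as.character(b$id)]]
      g <- pr[pr$rank == "genus", , drop = FALSE]
      if (nrow(g) == 1L && g$total_hits > 0L) mf <- g$hits / g$total_hits
    }
    data.frame(bin = b$id, total_length = b$total_length, coverage_cv = cv,
               majority_fraction = mf, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$pass_length <- df$total_length >= min_bin_length
  df$pass_coverage <- is.na(df$coverage_cv) | df$coverage_cv <= max_coverage_cv
  df$pass_taxonomy <- is.na(df$majority_fraction) |
    df$majority_fraction >= min_majority_fraction
  df$candidate <- df$pass_length & df$pass_coverage & df$pass_taxonomy
  df[order(-df$total_length), , drop = FALSE]
}

#' Serialize an interpolated Markov model to text
#'
#' Versioned plain-text format: parameters, then per order the non-zero
#' k-mer counts. Probabilities are recomputed on load, so the round trip is
#' exact.
#'
#' @param model An `imm_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imm <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#tetrabin-imm\tv1",
               sprintf("#params\tmax_order=%d\tinterpolation_threshold=%d\tpseudocount=%.17g\ttrain_nt=%.17g",
                       model$max_order, model$interpolation_threshold,
                       model$pseudocount, model$train_nt)), con)
  for (k in 0:model$max_order) {
    cc <- model$counts[[k + 1L]]
    nz <- which(cc > 0L)
    writeLines(sprintf("#order\t%d", k), con)
    if (length(nz))
      writeLines(paste(nz - 1L, cc[nz], sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_imm
#' @export
read_imm <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "#tetrabin-imm")) stop("not an IMM file: ", path)
  kv <- strsplit(sub("^#params\t", "", lines[2L]), "\t")[[1L]]
  kvl <- setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
  K <- as.integer(kvl[["max_order"]])
  C <- as.integer(kvl[["interpolation_threshold"]])
  ps <- as.numeric(kvl[["pseudocount"]])
  counts <- vector("list", K + 1L)
  order_at <- which(startsWith(lines, "#order"))
  bounds <- c(order_at, length(lines) + 1L)
  for (b in seq_along(order_at)) {
    k <- as.integer(strsplit(lines[order_at[b]], "\t")[[1L]][2L])
    cc <- integer(4L^(k + 1L))
    from <- order_at[b] + 1L; to <- bounds[b + 1L] - 1L
    if (to >= from) {
      parts <- do.call(rbind, strsplit(lines[from:to], "\t"))
      cc[as.integer(parts[, 1L]) + 1L] <- as.integer(parts[, 2L])
    }
    counts[[k + 1L]] <- cc
  }
  # rebuild probabilities via the training recursion
  model <- .imm_from_counts(counts, K, C, ps)
  model$train_nt <- as.numeric(kvl[["train_nt"]])
  model
}

.imm_from_counts <- function(counts, K, interpolation_threshold, pseudocount) {
  probs <- vector("list", K + 1L)
  c0 <- counts[[1L]]
  probs[[1L]] <- matrix((c0 + pseudocount) / (sum(c0) + 4 * pseudocount),
                        nrow = 1L)
  for (k in 1:K) {
    cm <- matrix(counts[[k + 1L]], ncol = 4L, byrow = TRUE)
    ctx_tot <- rowSums(cm)
    mle <- cm / ifelse(ctx_tot > 0, ctx_tot, 1)
    mle[ctx_tot == 0, ] <- 0.25
    lam <- pmin(1, ctx_tot / interpolation_threshold)
    suffix <- (seq_len(nrow(cm)) - 1L) %% (4L^(k - 1L))
    probs[[k + 1L]] <- lam * mle + (1 - lam) *
      probs[[k]][suffix + 1L, , drop = FALSE]
  }
  structure(list(max_order = K,
                 interpolation_threshold = interpolation_threshold,
                 pseudocount = pseudocount, counts = counts, probs = probs,
                 train_nt = NA_real_),
            class = "imm_model")
}
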