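#' Greedy composition-based priming of bins
#'
#' Contigs are sorted by decreasing length (ties by identifier) and processed
#' in order. The longest contig seeds the first bin. Each subsequent contig is
#' scored with [log_probability()] (early abort at the threshold for the
#' contig's length) against the length-weighted mean vector of every existing
#' bin; it joins the highest-scoring bin whose score reaches the
#' recall-calibrated threshold, updating that bin's weighted mean. A contig
#' matching no bin seeds a new one only if it is at least `min_seed_length`
#' bases long (short contigs estimate the source composition too poorly to
#' seed); otherwise it is left unassigned, or, with `force_assign = TRUE`,
#' placed in its best-scoring bin without updating the bin mean.
#'
#' @param contigs A `contig_set`.
#' @param tables A `calibration_tables` object.
#' @param confidence Recall level: 90 (high confidence), 95 (medium) or
#'   98 (low).
#' @param min_seed_length Minimum length (bases) for a contig to seed a new
#'   bin; default 1000.
#' @param force_assign Place below-threshold contigs in their best-scoring
#'   bin instead of leaving them unassigned (bin means are not updated for
#'   forced assignments).
#' @return A `binning_result`: list with `confidence`, `bins` (each with
#'   `id`, `members`, `total_length`, `mean_vector`, `coverage_values`),
#'   `unassigned` (contig ids) and `assignments` (data.frame: `id`, `length`,
#'   `bin` (NA if unassigned), `score`, `forced`).
#' @export
greedy_bin <- function(contigs, tables, confidence = 95,
                       min_seed_length = 1000L, force_assign = FALSE) {
  stopifnot(inherits(contigs, "contig_set"), nrow(contigs) >= 1L)
  fm <- frequency_matrix(setNames(contigs$seq, contigs$id))
  ord <- order(-contigs$length, contigs$id)

  bin_means <- list()
  bin_totals <- numeric(0)
  bin_members <- list()
  assign_bin <- rep(NA_integer_, nrow(contigs))
  assign_score <- rep(NA_real_, nrow(contigs))
  assign_forced <- rep(FALSE, nrow(contigs))
  unassigned <- integer(0)

  for (i in ord) {
    if (fm$matched_windows[i] == 0L) {
      warning("contig ", contigs$id[i],
              " has no valid tetranucleotide window; left unassigned")
      unassigned <- c(unassigned, i)
      next
    }
    v <- fm$values[i, ]
    len <- contigs$length[i]
    thr <- lookup_threshold(tables, confidence, len)
    nb <- length(bin_means)
    if (nb > 0L) {
      scores <- vapply(seq_len(nb), function(b)
        as.numeric(log_probability(v, bin_means[[b]], len, tables,
                                   abort_below = thr)), numeric(1))
      best <- which.max(scores) # ties -> lowest bin id (earliest seeded)
      if (scores[best] >= thr) {
        w_old <- bin_totals[best]
        bin_means[[best]] <- (bin_means[[best]] * w_old + v * len) /
          (w_old + len)
        bin_totals[best] <- w_old + len
        bin_members[[best]] <- c(bin_members[[best]], i)
        assign_bin[i] <- best
        assign_score[i] <- scores[best]
        next
      }
    }
    if (len >= min_seed_length) {
      bin_means[[nb + 1L]] <- v
      bin_totals[nb + 1L] <- len
      bin_members[[nb + 1L]] <- i
      assign_bin[i] <- nb + 1L
      next
    }
    if (force_assign && nb > 0L) {
      full <- vapply(seq_len(nb), function(b)
        as.numeric(log_probability(v, bin_means[[b]], len, tables)),
        numeric(1))
      best <- which.max(full)
      bin_members[[best]] <- c(bin_members[[best]], i)
      assign_bin[i] <- best
      assign_score[i] <- full[best]
      assign_forced[i] <- TRUE
      next
    }
    unassigned <- c(unassigned, i)
  }

  bins <- lapply(seq_along(bin_means), function(b) {
    mem <- bin_members[[b]]
    list(id = b, members = contigs$id[mem],
         total_length = sum(contigs$length[mem]),
         mean_vector = bin_means[[b]],
         coverage_values = contigs$coverage[mem])
  })
  structure(list(confidence = confidence, bins = bins,
                 unassigned = contigs$id[unassigned],
                 assignments = data.frame(id = contigs$id,
                                          length = contigs$length,
                                          bin = assign_bin,
                                          score = assign_score,
                                          forced = assign_forced,
                                          stringsAsFactors = FALSE)),
            class = "binning_result")
}

#' Run the priming binner at all three confidence levels
#'
#' Three independent [greedy_bin()] runs at 90, 95 and 98 percent recall. A
#' more stringent threshold (90, high confidence) tends to produce at least
#' as many bins as a permissive one (98, low confidence).
#'
#' @inheritParams greedy_bin
#' @param ... Passed to [greedy_bin()].
#' @return Named list of three `binning_result` objects ("90", "95", "98").
#' @export
run_all_confidences <- function(contigs, tables, ...) {
  res <- lapply(c(90, 95, 98), function(cf)
    greedy_bin(contigs, tables, confidence = cf, ...))
  names(res) <- c("90", "95", "98")
  res
}

#' Nucleotide-weighted accuracy and recall of a partition
#'
#' Each bin is matched to the source genome contributing the most nucleotides
#' to it; bin accuracy is the correctly binned nucleotides divided by the bin
#' total (x 100). Each source is matched to the bin holding the largest share
#' of its nucleotides; recall is that share divided by the source total
#' (x 100). Unassigned contigs count against recall but not against bin
#' accuracy.
#'
#' @param result A `binning_result`, or a data.frame with columns `id`,
#'   `length`, `bin` (NA allowed) as produced by [imm_assign()].
#' @param truth Named character vector mapping contig id to source genome,
#'   or a data.frame with columns `id` and `genome` (or `truth_label`).
#' @return List with `bins` (per-bin data.frame: `bin`, `dominant_source`,
#'   `total_nt`, `correct_nt`, `accuracy`), `sources` (per-source: `source`,
#'   `total_nt`, `best_bin`, `recall`) and `overall_accuracy` (percent of
#'   assigned nucleotides binned correctly).
#' @export
evaluate_partition <- function(result, truth) {
  asg <- if (inherits(result, "binning_result")) result$assignments else result
  stopifnot(all(c("id", "length", "bin") %in% names(asg)))
  truth <- .as_truth_map(truth)
  if (!all(asg$id %in% names(truth)))
    stop("truth labels missing for some contigs")
  asg$source <- truth[asg$id]

  binned <- asg[!is.na(asg$bin) & nzchar(asg$source), , drop = FALSE]
  nt <- tapply(binned$length, list(binned$bin, binned$source), sum,
               default = 0)
  bins <- data.frame(bin = as.integer(rownames(nt)),
                     dominant_source = colnames(nt)[max.col(nt, "first")],
                     total_nt = rowSums(nt), stringsAsFactors = FALSE)
  bins$correct_nt <- nt[cbind(seq_len(nrow(nt)),
                              match(bins$dominant_source, colnames(nt)))]
  bins$accuracy <- bins$correct_nt / bins$total_nt * 100

  src_tot <- tapply(asg$length, asg$source, sum)
  sources <- data.frame(source = names(src_tot),
                        total_nt = as.numeric(src_tot),
                        stringsAsFactors = FALSE)
  sources$best_bin <- NA_integer_
  sources$recall <- 0
  for (k in seq_len(nrow(sources))) {
    s <- sources$source[k]
    if (s %in% colnames(nt) && any(nt[, s] > 0)) {
      b <- which.max(nt[, s])
      sources$best_bin[k] <- as.integer(rownames(nt)[b])
      sources$recall[k] <- nt[b, s] / sources$total_nt[k] * 100
    }
  }
  list(bins = bins[order(bins$bin), , drop = FALSE],
       sources = sources,
       overall_accuracy = sum(bins$correct_nt) / sum(bins$total_nt) * 100)
}

.as_truth_map <- function(truth) {
  if (is.data.frame(truth)) {
    lab <- if ("genome" %in% names(truth)) truth$genome else truth$truth_label
    return(setNames(as.character(lab), truth$id))
  }
  stopifnot(!is.null(names(truth)))
  truth
}
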