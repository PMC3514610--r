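# stationary base composition of an order-k chain given a (4^k x 4)
# conditional probability matrix (power iteration on the context chain)
.stationary_composition <- function(P, iters = 200L) {
  nctx <- nrow(P)
  ctx <- seq_len(nctx) - 1L
  # dense context-transition matrix: state -> next state
  Tm <- matrix(0, nctx, nctx)
  for (b in 0:3) {
    to <- ((ctx * 4L + b) %% nctx) + 1L
    Tm[cbind(seq_len(nctx), to)] <- Tm[cbind(seq_len(nctx), to)] + P[, b + 1L]
  }
  pi_ctx <- rep(1 / nctx, nctx)
  for (it in seq_len(iters)) {
    nxt <- as.numeric(pi_ctx %*% Tm)
    if (max(abs(nxt - pi_ctx)) < 1e-13) { pi_ctx <- nxt; break }
    pi_ctx <- nxt
  }
  colSums(pi_ctx * P)
}

# tilt G/C columns by factor t and renormalize rows
.tilt_gc <- function(P, t) {
  Q <- P
  Q[, 2:3] <- Q[, 2:3] * t
  Q / rowSums(Q)
}

#' Generate a synthetic genome from a random order-k Markov chain
#'
#' Transition probabilities for each of the 4^order contexts are drawn from a
#' Dirichlet centered on the target composition, giving each genome its own
#' compositional signature (the way real genomes differ), then exponentially
#' tilted so the stationary GC content matches `gc` (bisection on the tilt
#' factor). The sequence is sampled from the chain; deterministic by seed.
#'
#' @param length Genome length in bases (at least 10 kb).
#' @param gc Target GC fraction in (0, 1); default 0.5.
#' @param order Markov context length (default 3).
#' @param seed Integer seed.
#' @param id Genome identifier; default derived from the seed.
#' @param concentration Dirichlet concentration (default 8); smaller values
#'   give more idiosyncratic, easier-to-separate genomes.
#' @return A `synthetic_genome`: list with `id`, `seq`, `gc_target`,
#'   `order`, `seed` and the tilted transition matrix `transitions`.
#' @export
make_genome <- function(length, gc = 0.5, order = 3L, seed,
                        id = sprintf("genome_s%d", seed),
                        concentration = 8) {
  stopifnot(length >= 1e4)
  if (!(gc > 0 && gc < 1)) stop("GC target must lie strictly in (0, 1)")
  order <- as.integer(order)
  nctx <- 4L^order
  .with_seed(seed, {
    base_w <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    P <- matrix(rgamma(nctx * 4L, shape = concentration *
                         rep(base_w * 4, each = nctx)), nrow = nctx)
    P <- P / rowSums(P)
    # bisect a GC tilt so the stationary composition hits the target
    lo <- -4; hi <- 4
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      comp <- .stationary_composition(.tilt_gc(P, exp(mid)))
      if (comp[2] + comp[3] < gc) lo <- mid else hi <- mid
    }
    P <- .tilt_gc(P, exp((lo + hi) / 2))
    cum <- t(apply(P, 1L, cumsum))
    init <- sample.int(4L, order, replace = TRUE) - 1L
    codes <- markov_sample_cpp(as.integer(length), cum, order, init)
    structure(list(id = id, seq = .decode_codes(codes), gc_target = gc,
                   order = order, seed = seed, transitions = P),
              class = "synthetic_genome")
  })
}

#' Simulate a metagenomic community with known truth labels
#'
#' Generates `n_genomes` synthetic genomes with GC contents spread over
#' `gc_range`, samples contigs from each at random positions with log-normal
#' lengths clipped to `contig_length_range`, assigns each genome a sequencing
#' coverage, and writes assembler-style headers
#' (`<genome>_contig_<i>_length_<L>_cov_<x>`) so coverage round-trips through
#' [parse_coverage()]. Contig counts per genome scale with `abundances`.
#'
#' @param n_genomes Number of source genomes (default 3).
#' @param genome_length Genome length in bases (default 2e6).
#' @param contigs_per_genome Contigs sampled per unit relative abundance
#'   (default 100).
#' @param contig_length_range Min and max contig length in bases
#'   (default c(500, 1e5)).
#' @param contig_meanlog,contig_sdlog Log-normal contig length parameters
#'   (defaults log(8000) and 0.7, echoing typical short-read assemblies).
#' @param gc_range GC contents assigned evenly across genomes
#'   (default c(0.35, 0.65)).
#' @param abundances Relative abundances, recycled to `n_genomes`
#'   (default equal).
#' @param coverages Per-genome coverage values; default drawn uniformly from
#'   [5, 80] with 10 percent per-contig jitter.
#' @param order Markov order of the genome generator (default 3).
#' @param seed Integer seed.
#' @return A `synthetic_community`: list with `contigs` (a `contig_set`
#'   carrying `truth_label` and `coverage`), `genomes` (list of
#'   `synthetic_genome`), `truth` (data.frame `id`, `genome`) and
#'   `coverages`.
#' @export
make_community <- function(n_genomes = 3L, genome_length = 2e6,
                           contigs_per_genome = 100L,
                           contig_length_range = c(500, 1e5),
                           contig_meanlog = log(8000), contig_sdlog = 0.7,
                           gc_range = c(0.35, 0.65), abundances = 1,
                           coverages = NULL, order = 3L, seed) {
  stopifnot(n_genomes >= 1L, genome_length > max(contig_length_range))
  gcs <- if (n_genomes == 1L) mean(gc_range) else
    seq(gc_range[1L], gc_range[2L], length.out = n_genomes)
  abundances <- rep_len(abundances, n_genomes)
  genomes <- lapply(seq_len(n_genomes), function(g)
    make_genome(genome_length, gc = gcs[g], order = order,
                seed = seed * 1000L + g, id = sprintf("g%02d", g)))
  .with_seed(seed, {
    if (is.null(coverages)) coverages <- round(runif(n_genomes, 5, 80), 1)
    rows <- lapply(seq_len(n_genomes), function(g) {
      n_i <- max(1L, round(contigs_per_genome * abundances[g] /
                             mean(abundances)))
      len <- round(pmin(pmax(rlnorm(n_i, contig_meanlog, contig_sdlog),
                             contig_length_range[1L]),
                        contig_length_range[2L]))
      s <- vapply(len, function(l)
        sample.int(genome_length - l + 1L, 1L), integer(1))
      cov <- round(coverages[g] * runif(n_i, 0.9, 1.1), 4)
      data.frame(genome = genomes[[g]]$id,
                 seq = substring(genomes[[g]]$seq, s, s + len - 1L),
                 length = len, coverage = cov, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    # velvet-style headers: the id token itself carries length and coverage,
    # so ids survive a FASTA round trip unchanged
    ids <- sprintf("%s_contig_%04d_length_%d_cov_%s",
                   df$genome,
                   unlist(lapply(rows, function(r) seq_len(nrow(r)))),
                   df$length,
                   format(df$coverage, trim = TRUE, scientific = FALSE,
                          digits = 12))
    headers <- ids
    contigs <- contig_set(ids, df$seq, header = headers,
                          coverage = df$coverage, truth_label = df$genome)
    structure(list(contigs = contigs, genomes = genomes,
                   truth = data.frame(id = ids, genome = df$genome,
                                      stringsAsFactors = FALSE),
                   coverages = setNames(coverages,
                                        vapply(genomes, `[[`, character(1),
                                               "id"))),
              class = "synthetic_community")
  })
}

#' Simulate BLAST-style hits and a lineage table for a community
#'
#' Each contig is fragmented into 500 bp pieces; every fragment receives one
#' on-target hit against its own genome's reference subject (high identity,
#' small e-value), and with probability `noise` an additional off-target hit
#' with a higher bitscore, so the off-target lineage wins the
#' best-hit-per-fragment vote for that fragment. The default lineage gives
#' every genome its own taxon at all five ranks.
#'
#' @param community A `synthetic_community`.
#' @param noise Off-target hit rate in [0, 1] (default 0).
#' @param off_target_subject Subject id receiving the off-target hits;
#'   default a random other genome per fragment.
#' @param lineage Optional lineage data.frame overriding the default.
#' @param seed Integer seed.
#' @return List with `hits` (12-column outfmt-6 data.frame) and `lineage`.
#' @export
make_hits <- function(community, noise = 0, off_target_subject = NULL,
                      lineage = NULL, seed) {
  frags <- fragment_contigs(community$contigs)
  gids <- vapply(community$genomes, `[[`, character(1), "id")
  subjects <- paste0(gids, "_ref")
  if (is.null(lineage))
    lineage <- data.frame(subject_id = subjects,
                          phylum = paste0("Phylum_", gids),
                          class = paste0("Class_", gids),
                          order = paste0("Order_", gids),
                          family = paste0("Family_", gids),
                          genus = paste0("Genus_", gids),
                          stringsAsFactors = FALSE)
  truth <- setNames(community$truth$genome, community$truth$id)
  .with_seed(seed, {
    n <- nrow(frags)
    src <- truth[frags$contig_id]
    on_target <- data.frame(qseqid = frags$fragment_id,
                            sseqid = paste0(src, "_ref"),
                            pident = round(runif(n, 92, 99.9), 2),
                            length = frags$length, mismatch = 0L,
                            gapopen = 0L, qstart = 1L, qend = frags$length,
                            sstart = 1L, send = frags$length,
                            evalue = signif(10^-runif(n, 30, 180), 3),
                            bitscore = round(1.9 * frags$length, 1),
                            stringsAsFactors = FALSE)
    hits <- on_target
    off <- which(runif(n) < noise)
    if (length(off)) {
      off_subj <- if (!is.null(off_target_subject)) {
        rep(off_target_subject, length(off))
      } else {
        vapply(src[off], function(g) {
          pool <- subjects[subjects != paste0(g, "_ref")]
          if (length(pool) == 0L) paste0(g, "_ref") else
            pool[sample.int(length(pool), 1L)]
        }, character(1))
      }
      off_hits <- on_target[off, , drop = FALSE]
      off_hits$sseqid <- off_subj
      off_hits$bitscore <- off_hits$bitscore + 5
      hits <- rbind(hits, off_hits)
      if (!is.null(off_target_subject) &&
          !off_target_subject %in% lineage$subject_id)
        lineage <- rbind(lineage,
                         data.frame(subject_id = off_target_subject,
                                    phylum = "Phylum_off", class = "Class_off",
                                    order = "Order_off", family = "Family_off",
                                    genus = "Genus_off",
                                    stringsAsFactors = FALSE))
    }
    rownames(hits) <- NULL
    list(hits = hits, lineage = lineage)
  })
}
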