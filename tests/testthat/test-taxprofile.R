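test_that("fragment_contig tiles with a kept terminal remainder", {
  c1250 <- list(id = "c", seq = tb_random_seq(1250, seed = 1))
  fr <- fragment_contig(c1250)
  expect_equal(fr$length, c(500L, 500L, 250L))
  expect_equal(fr$start, c(1L, 501L, 1001L))
  expect_equal(fr$fragment_id, c("c|1", "c|501", "c|1001"))

  expect_equal(nrow(fragment_contig(list(id = "s", seq = strrep("A", 150)))),
               0L)
  f500 <- fragment_contig(list(id = "e", seq = tb_random_seq(500, seed = 2)))
  expect_equal(nrow(f500), 1L)
  expect_equal(f500$length, 500L)
  # remainder below min_keep is dropped
  expect_equal(fragment_contig(list(id = "r",
                                    seq = tb_random_seq(1150, 3)))$length,
               c(500L, 500L))
})

test_that("fragments tile the contig without overlap", {
  set.seed(5)
  for (len in sample(200:5000, 20)) {
    fr <- fragment_contig(list(id = "x", seq = tb_random_seq(len)))
    if (nrow(fr) == 0) { expect_lt(len, 200); next }
    expect_true(all(diff(fr$start) == 500L))
    expect_lte(sum(fr$length), len)
    expect_true(all(fr$start + fr$length - 1L <= len))
    expect_equal(nchar(fr$seq), fr$length)
  }
})

tb_toy_hits <- function() {
  # 5 hits on 2 fragments; hand enumeration: f1 keeps h2 (h1 too short,
  # h3 loses on bitscore), f2 keeps h4 (h5 below identity)
  data.frame(qseqid = c("c|1", "c|1", "c|1", "c|501", "c|501"),
             sseqid = c("s1", "s2", "s3", "s1", "s3"),
             pident = c(90, 85, 88, 70, 20),
             length = c(200, 450, 450, 300, 400),
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 1L,
             sstart = 1L, send = 1L,
             evalue = c(1e-50, 1e-80, 1e-70, 1e-30, 1e-90),
             bitscore = c(400, 800, 700, 500, 600),
             stringsAsFactors = FALSE)
}

test_that("filter_hits applies the length/identity cutoffs and best-per-fragment", {
  h <- tb_toy_hits()
  kept <- filter_hits(h)
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$sseqid[kept$qseqid == "c|1"], "s2")
  expect_equal(kept$sseqid[kept$qseqid == "c|501"], "s1")
  # strict > 200: an exactly-200 bp hit is dropped, 250 retained
  h2 <- h[1:2, ]; h2$length <- c(200, 250); h2$pident <- 80
  expect_equal(filter_hits(h2)$length, 250)
  # idempotent and a subset of the input
  expect_identical(filter_hits(kept), kept)
  expect_true(all(kept$bitscore %in% h$bitscore))
  # bitscore tie broken by lower e-value (s2 at 1e-80 beats s3 at 1e-70)
  h3 <- h[2:3, ]; h3$bitscore <- 700
  expect_equal(filter_hits(h3)$sseqid, "s2")
  # and by subject id when e-values tie as well
  h4 <- h3; h4$evalue <- 1e-70
  expect_equal(filter_hits(h4)$sseqid, "s2")
})

tb_toy_lineage <- function() {
  data.frame(subject_id = c("s1", "s2", "s3"),
             phylum = c("P1", "P1", "P2"), class = c("C1", "C1", "C2"),
             order = c("O1", "O1", "O2"), family = c("F1", "F2", "F3"),
             genus = c("X", "X", "Y"), stringsAsFactors = FALSE)
}

test_that("contig_profile tallies majorities with counts and median e-value", {
  lin <- tb_toy_lineage()
  # genus tally {X:3, Y:2} -> majority X with 3 of 5 hits
  h <- data.frame(qseqid = paste0("c|", c(1, 501, 1001, 1501, 2001)),
                  sseqid = c("s1", "s2", "s1", "s3", "s3"),
                  pident = 90, length = 450, mismatch = 0L, gapopen = 0L,
                  qstart = 1L, qend = 1L, sstart = 1L, send = 1L,
                  evalue = c(1e-10, 1e-20, 1e-30, 1e-40, 1e-50),
                  bitscore = 500, stringsAsFactors = FALSE)
  pr <- contig_profile(h, lin)
  g <- pr[pr$rank == "genus", ]
  expect_equal(g$taxon, "X")
  expect_equal(g$hits, 3L)
  expect_equal(g$total_hits, 5L)
  expect_equal(g$median_evalue, 1e-20) # median of {1e-10,1e-20,1e-30}
  # all five ranks reported
  expect_equal(pr$rank, c("phylum", "class", "order", "family", "genus"))
  # phylum majority pools s1+s2 (P1: 3 hits) vs s3 (P2: 2)
  expect_equal(pr$taxon[pr$rank == "phylum"], "P1")
  # zero hits -> empty profile at all ranks
  empty <- contig_profile(h[0, ], lin)
  expect_true(all(empty$hits == 0L))
  expect_true(all(is.na(empty$taxon)))
  # unresolvable subject is skipped with a warning
  h$sseqid[1] <- "unknown_subject"
  expect_warning(contig_profile(h, lin), "unresolvable")
})

test_that("bin_profile sums member tallies; singleton equals the contig", {
  lin <- tb_toy_lineage()
  mk <- function(contig, subjects, evalues) {
    n <- length(subjects)
    data.frame(qseqid = paste0(contig, "|", seq_len(n) * 500 - 499),
               sseqid = subjects, pident = 90, length = 450,
               mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 1L,
               sstart = 1L, send = 1L, evalue = evalues, bitscore = 500,
               stringsAsFactors = FALSE)
  }
  # contig a: genus X x3; contig b: genus Y x5
  hits <- rbind(mk("a", c("s1", "s2", "s1"), 1e-10),
                mk("b", rep("s3", 5), 1e-60))
  bp <- bin_profile(c("a", "b"), hits, lin)
  g <- bp[bp$rank == "genus", ]
  expect_equal(g$taxon, "Y")
  expect_equal(g$hits, 5L)
  expect_equal(g$total_hits, 8L)
  # single-member bin equals the contig's own profile
  expect_equal(bin_profile("a", hits, lin), contig_profile(hits[1:3, ], lin))
  # members without hits contribute nothing
  expect_equal(bin_profile(c("a", "zzz"), hits, lin),
               bin_profile("a", hits, lin))
})

test_that("crossvalidate recovers nucleotides by best high-identity hit", {
  q <- contig_set(c("q1", "q2", "q3"),
                  c(tb_random_seq(1000, 1), tb_random_seq(2000, 2),
                    tb_random_seq(500, 3)))
  refbins <- data.frame(id = c("r1", "r2", "r3"), bin = c(1L, 1L, 2L))
  hits <- data.frame(qseqid = c("q1", "q2", "q2", "q3"),
                     sseqid = c("r1", "r3", "r2", "r1"),
                     pident = c(100, 99, 98.5, 90),
                     length = 400, mismatch = 0L, gapopen = 0L,
                     qstart = 1L, qend = 1L, sstart = 1L, send = 1L,
                     evalue = 1e-100,
                     bitscore = c(800, 700, 650, 900),
                     stringsAsFactors = FALSE)
  cv <- crossvalidate(q, refbins, hits)
  # q1 (1000 nt) -> bin 1; q2's best >=98% hit is r3 -> bin 2;
  # q3's only hit is below 98% identity -> recovered to none
  expect_equal(cv$recovered_nt[cv$bin == 1], 1000)
  expect_equal(cv$recovered_nt[cv$bin == 2], 2000)
  expect_equal(sum(cv$n_contigs), 2L)
})

test_that("hit and lineage tables round-trip through files", {
  h <- tb_toy_hits()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_blast_hits(h, f)
  back <- read_blast_hits(f)
  expect_equal(back$qseqid, h$qseqid)
  expect_equal(back$bitscore, h$bitscore)
  lin <- tb_toy_lineage()
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_lineage(lin, f2)
  expect_equal(read_lineage(f2), lin)
})
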