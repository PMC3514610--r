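---
title: "tetrabin: models, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tetrabin: models, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
statistical model behind the tetranucleotide priming stage, how the lookup
tables are calibrated, what the interpolated Markov refinement adds, the
numerical choices that were genuinely open, and what the synthetic
benchmarks do and do not establish.

## 1. The composition signal

Oligonucleotide usage is a genome-level signature: 4-mer frequencies are
fairly constant along a prokaryotic chromosome and differ between taxa.
Under the assumption that sequencing samples both strands equally, a 4-mer
carries the same information as its reverse complement, so the 256
tetranucleotides collapse into 136 canonical classes — 120 two-member pairs
plus 16 palindromes (classes are indexed by their lexicographically smallest
member, making vectors stable across runs and serializable). A contig is
summarized by the vector

$$f_x = \frac{\mathrm{count}(x)}{W} \times 136,$$

where $W$ is the number of 4-base windows consisting solely of A/C/G/T
(windows touching an N are dropped from numerator *and* denominator), so
$\sum_x f_x = 136$ and the vector mean is exactly 1. Counting is
single-stranded with reverse-complement canonicalization — equivalent to
counting both strands, and half the work. A sequence with no valid window
yields a flagged undefined vector rather than an error; such contigs are
routed to the unassigned pool downstream.

The covariance structure of the 136 classes is not modeled. The true number
of degrees of freedom is smaller (103), but the method operates in the full
136-dimensional space and treats classes as independent; the calibrated
thresholds absorb the resulting miscalibration of the joint density because
they are percentiles of the *empirical* score distribution, not of a
theoretical chi-square.

## 2. The dispersion surface and the membership probability

When fragments of length $l$ are sampled from one genome, the standard
deviation $s$ of a class frequency across fragments is predicted well by
just two quantities: the genome's mean frequency $m$ for that class and $l$.
No satisfactory closed form exists for $s = f(m, l)$, so it is tabulated
empirically: for each reference genome and each grid length (38 lengths,
0.3–100 kb), 100 random fragments are drawn, the per-class $(m, s)$ pairs
from all genomes and classes are pooled into mean-frequency bins of width
0.05 spanning $[0, 4]$, and $s$ is averaged per cell. Lookup is bilinear —
linear in $m$, linear in $\log l$ — with out-of-range queries clamped to the
grid edge.

Membership of a contig (vector $v$, length $l$) in a source with mean vector
$m$ is scored as a product of independent Gaussians, evaluated in log space
(the raw 136-term product underflows double precision):

$$\log P = \sum_{x=1}^{136} \log\!\left[
  \frac{1}{\sqrt{2\pi}\,s_x} e^{-\frac{(v_x - m_x)^2}{2 s_x^2}}
\right], \qquad s_x = f(m_x, l).$$

Acceptance thresholds come from the same sampling run: each calibration
fragment is scored against its own source genome's mean, the scores are
pooled over genomes per length, and the threshold at recall level
$r \in \{90, 95, 98\}$ percent is the $(100 - r)$-th percentile
(linear-interpolated empirical percentile — standard and deterministic).
Thresholds are interpolated linearly in $\log l$ between grid lengths. By
construction, a fresh same-genome fragment scored against its true source
mean passes the $r\%$ threshold with probability $\approx r\%$ — this is the
self-consistency property the acceptance suite re-measures.

Numerical safeguards, chosen once:

* $\sigma$ floor of $10^{-3}$, preventing infinite log-densities for classes
  never observed in a sparse mean-frequency cell; realistic cells are far
  above it.
* Empty $(m, l)$ cells inherit the nearest populated cell along the $m$
  axis (extreme mean frequencies are rare; nearest-neighbor fill avoids
  undefined $\sigma$).
* The mean-frequency grid spans $[0, 4]$; larger means are clamped into the
  last bin.

**Early abort.** The original formulation aborts the 136-term comparison as
soon as the running product falls below the threshold, which silently
assumes every factor is $\le 1$. That is false whenever
$\sqrt{2\pi}\,s_x < 1$ (i.e. $s_x \lesssim 0.4$, which is the common case
for long contigs), so a literal implementation could abort a computation
that would have recovered. `log_probability()` instead precomputes suffix
sums of the per-class maxima $-\log(\sqrt{2\pi}\,s_x)$ and aborts only when
the partial sum plus the bound on all remaining terms is already below the
cutoff. An aborted call returns a value $\le$ the cutoff and a flag; its
accept/reject decision is provably identical to the full sum's, which the
test suite checks on a thousand random triples.

## 3. Greedy priming and its failure modes

Contigs are sorted by decreasing length (ties by identifier, making the
partition independent of input order); the longest seeds bin 1. Each
subsequent contig is scored against every bin's length-weighted mean vector
with the abort cutoff set to the threshold at the contig's length, joins the
highest-scoring bin at or above threshold (ties to the earliest-seeded,
i.e. longest-seeded, bin), and updates that bin's mean; otherwise it seeds a
new bin if it is at least `min_seed_length` (default 1000) bases, else it is
left unassigned. An optional `force_assign` places such leftovers in their
best-scoring bin without moving the bin mean — means stay anchored to
contigs that passed the threshold on their own merits.

The method's central approximation is that a bin's mean vector stands in
for the source genome's mean. This is poor exactly when a bin is young: a
single-contig bin's mean carries the full per-fragment sampling variance,
so the deviation of the next same-genome contig has roughly *twice* the
calibrated variance and routinely fails the threshold. The practical
consequence — observed in our simulations and worth stating plainly — is
that each source genome is typically spread over a few *pure* parallel bins
rather than collected into one, with a dominant bin emerging as means
sharpen. This is why the workflow runs at all three recall levels (the
permissive 98% run merges most aggressively and yields the largest seed
bins) and why the refinement stage exists. Collapse of a multi-contig
single-genome input to literally one bin should not be expected, and the
package does not promise it.

## 4. Interpolated Markov refinement

Seed bins are chosen by three explicit gates mirroring the "good bin"
heuristics — total length, coefficient of variation of member coverages,
and the fraction of genus-rank hits on the majority genus
(`select_seed_bins()`, defaults 200 kb / 0.5 / 0.5; all three are
parameters because the choice is ultimately the scientist's, and the tool
never auto-trains without an explicit list).

One interpolated Markov model is trained per seed bin on both strands of
its member contigs. The model keeps (context, next base) counts for context
orders $0..K$ (default $K = 8$) and blends maximum-likelihood estimates
across orders with count-based trust weights applied recursively:

$$P_k = \lambda_k\,\mathrm{MLE}_k + (1 - \lambda_k) P_{k-1}, \qquad
\lambda_k = \min(1, \mathrm{count}(\mathrm{context}_k)/C),$$

with $C = 400$ and a pseudocount-smoothed base composition at order 0.
Scoring sums $\log P(\mathrm{base}\mid\mathrm{context})$ over positions;
non-ACGT positions contribute zero and reset the context, and positions too
close to the start (or to an N) use correspondingly shorter orders. No
background model is subtracted. Every contig is assigned to the arg-max
model (ties: more training nucleotides, then lowest bin id).

This is the standard count-threshold interpolated-context formulation, not
Glimmer's $\chi^2$-weighted ICM; $K = 8$ and $C = 400$ are conventional
ICM-scale settings, exposed as parameters because the original tool's
settings are unstated. A corollary of count-based trust worth knowing:
training on duplicated data is *not* a no-op (counts double, so $\lambda$
rises toward 1); only saturated contexts are invariant.

With $\ge$ 500 kb of training material per model the IMM separates even
closely related compositions and outperforms the Gaussian classifier; with
only ~10 kb the tetranucleotide classifier is the safer of the two. The
acceptance suite checks both directions of that crossover.

## 5. Taxonomic profiling and coverage

For profiling, contigs are cut into non-overlapping 500 bp pieces (a
terminal remainder $\ge 200$ bp is kept — 200 mirrors the hit-length
cutoff; the choice is ours, the original is silent on remainders). Hits in
standard 12-column tabular format are filtered to alignment length
$> 200$ bp (strict) and identity $\ge 25\%$ (implemented exactly as
specified, though unusually permissive), then reduced to the best hit per
fragment (highest bitscore, ties by e-value then subject id) so one
fragment contributes one vote regardless of how many database paralogs it
hits. Profiles report, at each of five ranks (phylum through genus), the
majority taxon, its hit count, the total hits, and the median e-value of
the majority taxon's hits (an exact zero e-value is kept as 0). Bin
profiles sum member tallies before taking the majority. Cross-sample
validation credits each query contig's full length to the reference bin
holding its best $\ge 98\%$-identity hit.

Sequencing coverage is parsed from assembler headers with
`cov[a-z]*?[=_](number)` against the lower-cased header (so `Cov=12`,
`coverage_12` and Velvet's `..._cov_22.7` all match), falling back to
`numreads = (count)` $\times$ mean read length / contig length; the
explicit coverage field wins when both match, being the direct measurement.

## 6. The synthetic world

Everything is testable offline because the simulator generates the inputs:

* **Genomes** are order-3 Markov chains with per-context Dirichlet-drawn
  transitions (concentration 8) exponentially tilted so the stationary GC
  matches a target — order-3 rather than i.i.d. precisely so that genomes
  carry distinct tetranucleotide signatures, as real genomes do; i.i.d.
  genomes would make binning degenerate. Sequential sampling is a small
  Rcpp kernel using R's RNG, so everything is reproducible from seeds.
* **Communities** draw contigs at uniform positions with log-normal lengths
  (meanlog $\log 8000$, sdlog 0.7, clipped to a requested range — a
  realistic short-read assembly spread; the shape parameters are our
  choice, made once), assign per-genome GC evenly across 0.35–0.65 and
  per-genome coverages with 10% per-contig jitter, and write
  `..._length_L_cov_x` headers so coverage round-trips through the parser.
* **Hit tables** give every fragment one on-target hit and, at a chosen
  noise rate, an off-target hit with a higher bitscore, so profile
  majorities flip exactly when noise saturates.

What a green test establishes — and what it does not: synthetic order-3
genomes are compositionally *homogeneous*, with no rRNA operons, mobile
elements, horizontally transferred islands or strain mixtures, and the
GC spread (35–65%) makes sources well separated. Accuracy numbers from this
world are upper bounds on real-community behavior, and the
classifier-crossover comparison saturates at 100% on both sides at the
10-species scale (the inequalities hold, but with equality). The
calibration self-consistency result, by contrast, is internal to the method
and transfers: thresholds are percentiles of the same score distribution
they are later applied to.

## 7. Scale of the shipped experiments

The acceptance experiments run at the stated scale (10 calibration genomes
of 2 Mb, 100 fragments per grid length; a 3-genome community of 300
contigs; ten 10-species crossover replicates with 1 Mb and 10 kb training
and 100 8-kb test fragments per species); the whole test suite, acceptance
experiments included, completes in roughly five minutes on one CPU.
Unit tests run against a reduced fixture (3 genomes of 400 kb, a 7-length
grid, 50 fragments per length) purely for speed; nothing about the reduced
world is tuned to pass.

## 8. Known limitations

* The Gaussian treats the 136 classes as independent; correlations are
  absorbed into empirical thresholds but not modeled.
* Fragmentation of young bins (section 3) means bin counts are not
  interpretable as population counts; use the refinement stage and the
  per-bin report before drawing conclusions.
* No automatic choice of confidence level is attempted — there is no
  general rule; run all three and inspect.
* The IMM is an approximation of the original ICM formulation; scores are
  not comparable to Glimmer's.
* Coverage parsing knows the two stated header dialects only; other
  assemblers need the read-count fallback or pre-parsed headers.
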