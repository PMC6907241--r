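---
title: "Dynamic reference learning: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic reference learning: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(nucleolearn)
```

## The problem

Reference-guided assembly of short reads breaks down when the only
available reference is phylogenetically distant from the sequenced
organism: conventional mappers place few reads, and the unmapped reads'
information is lost. `nucleolearn` treats the reference not as a fixed
string but as a *learned* object: each read is aligned to the current
reference by dynamic programming, and the reference is immediately pulled
a little toward the read. As reads accumulate, the reference converges
toward the read population, so later reads align better than earlier
ones. The intended scale is amplicons and small (e.g. organellar)
genomes — the full alignment matrix is held in memory per read.

## The model

**Encoding.** A reference of length $l$ is a sequence of probability
vectors $F = f_1 \dots f_l$ over the bases (A, C, G, T), initialised
one-hot from the reference sequence. A read $R = r_1 \dots r_n$ is
encoded from its calls and Phred qualities: a base $b$ called with error
probability $q = 10^{-Q/10}$ gets $r_{yb} = 1 - q$ and each alternative
$q/3$. An `N` becomes the uniform vector in either sequence; other IUPAC
codes are rejected rather than guessed at. All vectors are indexed in the
fixed order A, C, G, T.

**Distance.** Only the read's most probable base matters:
$d(f_x, r_y) = |f_{xi} - r_{yi}|$ with $i = \arg\max_j r_{yj}$ (ties to
the first base in alphabet order). The distance is asymmetric by
construction; the reference is always the first argument.

**Alignment.** A free-ends (semi-global) recurrence with linear gap cost
$c = 1$ — the maximum possible vector distance:

$$M(x,0) = 0,\qquad M(0,y) = c\,y,$$
$$M(x,y) = \min\{\,M(x-1,y-1) + d(f_x, r_y),\; M(x-1,y) + c,\; M(x,y-1) + c\,\}.$$

The read must be consumed in full; the reference's flanks are free:
$e = \min_{1 \le x \le l} M(x,n)$, and the *edit rate* is
$\hat e = e / n$. The printed recurrence indexes $d(f_{x-1}, r_{y-1})$
relative to 0-based vector storage; we follow the standard convention
that the diagonal move into $(x,y)$ pays the distance between reference
position $x$ and read position $y$ in 1-based symbol counting. Tie-breaks
are fixed for reproducibility: match/substitution over deletion-from-read
over insertion-from-read, and the smallest end row. A read-side free end
is *not* granted — the formula above is taken literally.

**Learning-rate schedule.** The retention weight is
$w = \mathrm{clamp}(3\hat e - 0.1,\; 0.05,\; 0.95)$ and the learning rate
is $1 - w$. A read within sequencing-error distance of the reference
($\hat e \le 0.05$) updates at rate 0.95; a read more distant than
roughly 70% identity ($\hat e \ge 0.35$) at 0.05. The two terms are used
inconsistently in informal descriptions of such schemes; here the
semantics are fixed so both prose anchors hold: low edit rate means high
learning rate.

**Update.** Walking the optimal path in read order:

* match/substitution at $(x, y)$: $f_x \leftarrow w f_x + (1-w) r_y$ — a
  convex combination, so probability mass is conserved;
* insertion-from-read at locus $x$: persistence $p_x \leftarrow p_x + (1-w)$;
* deletion-from-read at $x$: $p_x \leftarrow p_x - (1-w)$.

After the walk (once per read, at most one structural edit per locus),
any touched locus with $p_x > 1 + w$ receives an inserted position
initialised to the aligned read vector, and any with $p_x < 1 - w$ is
deleted. Because the threshold offset equals $w$, a poorly aligned read
(large $w$) nudges persistence by only $1 - w$ and can never trigger a
structural edit on its own, while a well-aligned read can. The offset is
exposed as `indel_threshold_offset` for experimentation.

**Assembly.** Reads stream in a seeded random permutation per epoch
(default one epoch). Coverage counts each read's aligned footprint
`[ref_start, ref_end)`; after the last epoch, zero-coverage runs at the
reference ends are trimmed (interior gaps are kept) and the per-position
argmax consensus is emitted. Every read is applied — there is no
rejection threshold by default; distant reads simply learn at 0.05. An
optional `max_edit_rate` skip and per-epoch resampling fraction exist for
experiments. Coverage accumulates across epochs by default (an option
resets it per epoch). With a SAM hint file and a `window_size`, each
hinted read is aligned only within `hint ± window_size`, the memory
mitigation appropriate for longer references; hints go stale as
structural edits shift coordinates, which is tolerable because the
window must be generous (at least a read length) anyway.

## Decisions taken where the design was open

* **Update timing.** Substitution updates are applied during the path
  walk, in path order, so later steps of the same read see earlier
  updates. The choice is isolated in `apply_update()` and has no effect
  on one-hot/error-free fixed points.
* **Persistence bookkeeping.** An insertion's evidence is tracked at the
  existing position before which the read base would insert (clamped to
  the last position for end insertions). After a triggered edit the
  persistence at the locus resets to 1 — without a reset, one locus
  could fire repeatedly off stale evidence. Inserted positions start
  with persistence 1 and coverage 0.
* **Strand.** Real FASTQ reads have unknown orientation, so
  `assemble()` aligns both the read and its reverse complement by
  default and keeps the smaller edit rate (ties prefer forward);
  `strand = "forward"` recovers the literal single-orientation
  behaviour and is what the simulations use, since the simulator emits
  forward reads only.
* **Consensus ties** go to the first base in alphabet order; exact ties
  essentially occur only in synthetic constructions.

## The simulator: what it emulates and what it does not

`random_sequence()` draws i.i.d. bases at 50% GC; `mutate_sequence()`
applies independent per-position substitutions and single-base indels
(an indel event is an insertion or deletion with equal probability —
the rate is read as per-position, both choices parameterised);
`simulate_reads()` draws 150 bp reads at uniform start positions with a
uniform 1% error rate and constant qualities
$Q = \mathrm{round}(-10\log_{10}\epsilon)$, capped at 42 (so "error-free"
reads carry Q42, and a residual edit rate of $\sim 6\times 10^{-5}$
remains — zero up to the quality cap). None of this emulates real
Illumina behaviour: no quality decay along the read, no indel
sequencing errors, no PCR duplicates, no strand mixture. Passing tests
therefore demonstrate the learning mechanics under the stated error
model, not robustness to platform-specific artefacts.

`edit_distance_calibration()` reproduces the schedule-calibration
design: per replicate, a truth of length $U(500, 5000)$, one read,
references mutated at substitution rates 1–50% (each also carrying 10%
single-base indels) plus a fresh random sequence. Its output justifies
the 0.05/0.35 thresholds: the "own" condition concentrates well below
0.05 and the mutated conditions' medians increase with divergence. The
test suite and acceptance script run 200 replicates rather than the
reference design's 1000; 200 is ample to order seven medians.

**Tiled reads for recovery experiments.** `reference_recovery()` streams
*tiled* error-free reads (starts every `read_length / coverage` bases)
rather than uniform random starts. With uniform starts the first and
last reference positions are each covered with probability only
$\approx 0.25$ at 30× (a terminal position is covered only by a read
starting exactly on it), so end trimming would shorten most assemblies
for reasons unrelated to the learning mechanism under test. Tiling makes
end coverage deterministic while keeping interior coverage at the
nominal 30×; the stream order remains a seeded random permutation, which
is the randomness the learner is actually sensitive to.

## Evaluation

`evaluate_assembly()` follows the standard recipe: global alignment with
affine gaps (a gap of length $k$ costs $\mathrm{open} + k \cdot
\mathrm{extend}$), the full NUC.4.4 matrix, and free end gaps; the
unaligned columns at the ends are discarded, the remaining column count
is the aligned length, and the errors are the Hamming distance over the
retained columns, counting retained internal gap columns as errors (a
flag ignores them instead). Gap parameters default to open 10, extend
0.5 — the EMBOSS needle defaults; near-identical sequences, the regime
in which the statistic is used, are insensitive to the exact values.
The engine is `Biostrings::pairwiseAlignment()`, which implements
exactly this convention (verified against exhaustive alignment
enumeration in the test suite; note Biostrings accumulates scores in
single precision, so scores agree to $\sim 10^{-6}$, not exactly).

## Numerical and degenerate-input conventions

* Probability vectors must sum to 1 within $10^{-9}$; convex updates
  preserve this exactly up to floating point.
* Traceback compares recomputed sums for exact double equality — safe
  because the identical operations produced the stored minimum.
* Empty reads, empty references, windows outside the reference, and
  stale alignments (coordinates that no longer fit after structural
  edits) raise errors; an assembly with no covered position returns an
  empty consensus with a warning, not an error.
* Persistence stays in $(0, 2)$ after every update: untriggered loci are
  within $w$ of 1, and triggered loci reset.

## Problem sizes used by the tests

The suite exercises: oracle equivalence on 200 random instances with
$l \le 12$, $n \le 8$ (top-down memoized evaluation of the recurrence as
the independent route); recovery of a 500 bp truth from a reference
corrupted by 5 substitutions + 1 insertion + 1 deletion at 30× over 10
seeds; the 200-replicate calibration; evaluator agreement with
exhaustive alignment enumeration on strings up to length 7; and the
coverage arithmetic of a 5× experiment on a 5,130 bp amplicon
($\lceil 5 \cdot 5130 / 150 \rceil = 171$ reads, 25,650 read-bases).
These sizes keep a full run around a minute on one core while leaving
every quantitative claim computed, not asserted.

## Known limitations

* Memory is $O(l \cdot n)$ per alignment; genome-scale references need
  the hint/window mechanism or an external seeding step.
* One epoch over randomly ordered reads gives no convergence guarantee;
  different seeds can yield different assemblies where coverage is thin.
  Multiple epochs (`epochs > 1`) trade time for stability.
* The learner's gap model is linear; affine gaps exist only in the
  evaluator.
* Indel evidence is tracked per locus with single-base granularity;
  long indels are acquired one base per read pass.
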