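---
title: "The readmerge model: MAP fragment-length inference for read merging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The readmerge model: MAP fragment-length inference for read merging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readmerge)
```

## The problem

Sequencing libraries built from degraded DNA — ancient remains,
forensic traces, cell-free DNA — contain molecules that are frequently
shorter than the read length. A 100 bp paired-end run over a 45 bp
fragment produces two reads that each contain the whole fragment
followed by adaptor sequence, and whose fragment parts overlap
completely. Three things must then happen before mapping or assembly:
the adaptor must be removed, the two observations of the same fragment
should be collapsed into one, and the collapsed bases should carry
quality scores that reflect the double observation. Doing these as
separate, cutoff-driven steps discards information; `readmerge` treats
them as one inference over a single latent variable, the original
molecule length $i$.

## The model

Let $r_1, r_2$ be the two reads (lengths $l_1, l_2$), $q_1, q_2$ their
PHRED qualities, and $a_1, a_2$ the adaptors expected after the
fragment on each strand. Write $\bar r_2$ for the reverse complement of
$r_2$. A PHRED score $q$ encodes the error probability
$p_e(q) = 10^{-q/10}$.

For each candidate molecule length $i \in \{0, \dots, l_1+l_2\}$ the
likelihood factorises over positions under an independent-errors
assumption. The geometry (0-based, half-open) is: read 1 covers
molecule positions $[0, \min(l_1, i))$ and $\bar r_2$ covers
$[\max(0, i-l_2), i)$. Then:

* **Adaptor terms.** Read positions past the fragment are compared to
  the adaptor base expected there: probability $1 - p_e(q)$ on a
  match, $p_e(q)/3$ on a mismatch (a sequencing error is assumed
  equally likely to produce each of the three other bases), and $1/4$
  for positions past the adaptor's end, where the template is unknown.
  Insertions and deletions are not modelled, so the comparison is a
  straight positional walk.
* **Overlap terms.** A molecule position covered by both reads
  contributes the probability that the two observations share a
  template, marginalised over the unknown template base $n$:
  $\sum_{n} \frac{1}{4} P(b_1 \mid n)\, P(b_2 \mid n)$ with
  $P(b \mid n)$ as above.
* **Single-coverage terms.** A molecule position seen by exactly one
  read contributes $1/4$: one observation of an a-priori uniform base.
  This keeps hypotheses with different data decompositions comparable —
  every hypothesis explains exactly $l_1 + l_2$ observed bases.
* **Prior.** $P(i)$ is either uniform or log-normal,
  $P(i) = \frac{1}{i\sqrt{2\pi}\,\sigma}
  e^{-(\ln i - \mu)^2 / 2\sigma^2}$, with $\mu, \sigma$ on the
  log-length scale. Degraded libraries have small $\mu$ and small
  $\sigma$; `fit_length_prior()` estimates both by the closed-form
  maximum-likelihood identities $\hat\mu = \overline{\ln x}$,
  $\hat\sigma^2 = \overline{(\ln x - \hat\mu)^2}$ (the $1/n$ variance,
  since the estimator is the MLE, not the unbiased variant).

$i = 0$ is the adaptor-dimer hypothesis: both reads are pure adaptor.
In addition to the $l_1+l_2+1$ length hypotheses, a **no-merge**
hypothesis — the molecule is longer than $l_1+l_2$, so no adaptor is
present and the reads cannot overlap — is scored as
$(1 - \mathrm{cdf}(l_1+l_2)) \cdot (1/4)^{l_1+l_2}$. Because it
competes in the same posterior, no hard overlap or adaptor-match
cutoff is needed anywhere; long-insert libraries simply see this
hypothesis win.

`posterior_profile()` evaluates all hypotheses (internally as diagonal
sums over pairwise score matrices, one `rowsum()` per term, which makes
a 100 bp pair cost a few milliseconds in pure R) and `decide()` applies
the **ambiguity guard**: if the second-best hypothesis is within a
likelihood ratio of $1/20$ of the best, the call is deemed ambiguous
and the pair is passed through unmerged. The guard threshold is
exposed (`ratio_threshold`, CLI `--ratio`); at its default a merge
must be at least 20-fold better supported than any alternative,
including the no-merge hypothesis, which we deliberately include in
the second-best search.

## Consensus calling

For a doubly covered position with observations $(b_1, q_1)$ and
$(b_2, q_2)$, the posterior of each nucleotide $n$ is
$p(n \mid b_1, b_2) \propto p(b_1 \mid n)\, p(b_2 \mid n) \cdot
\tfrac14$, and the reported quality is the PHRED scaling of the
posterior error probability

$$p(\neg n \mid b_1, b_2) =
  \frac{\sum_{m \ne n} p(b_1, b_2 \mid m)}{\sum_m p(b_1, b_2 \mid m)}.$$

Two agreeing observations therefore reinforce each other (the
consensus quality is never below either input), and a conflict is
resolved in favour of the higher-quality base with a sharply reduced
quality. Positions covered by one read keep their original base and
quality unchanged.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `ratio_threshold` | 0.05 | ambiguity guard; merges must beat the runner-up 20-fold |
| prior | uniform | fragment-length prior; fit a log-normal when library data exist |
| `qual_cap` | 60 | ceiling on consensus qualities (two agreeing Q40 bases would otherwise exceed the encodable FASTQ range) |
| adaptors | TruSeq read-through pair | override for other library preparations |
| `offset` | 33 | FASTQ PHRED encoding (64 supported) |

A prior should be used whenever the library's insert-size distribution
is known (e.g. fitted from previously merged data): it is what
distinguishes a few chance adaptor-like bases at a read end from a
genuinely short fragment, and it suppresses spurious merges of
long-insert pairs that happen to share a short overlap by chance. With
no such knowledge the uniform prior assigns every hypothesis, including
no-merge, mass $1/(l_1+l_2+2)$.

## Numerical choices

* **Log space.** All products are computed as sums of logs; with that,
  no further underflow guards are required. The test suite checks the
  log-space path against a direct probability-product evaluation on
  short reads, where the products are representable.
* **Quality floor.** Qualities below 2 are floored at 2 before
  entering the model, so that $1 - p_e > p_e/3$ always holds and a
  matching base is always evidence *for* a match (at $p_e \ge 3/4$ the
  inequality would invert).
* **`N` policy.** An `N` anywhere is an uninformative observation: it
  scores $1/4$ against any adaptor base and contributes a constant to
  the overlap marginal; it never counts as a match. In consensus, an
  `N` defers to the other read's base and quality; two `N`s produce
  `N` with quality 2.
* **Length 0 under a log-normal prior.** The density is undefined at
  0; the adaptor-dimer hypothesis evaluates it at 0.5 (continuity
  correction).
* **Ties.** Exact floating-point ties in the argmax resolve to the
  smallest length (and a length hypothesis before no-merge); in
  practice ties are caught by the ambiguity guard long before the
  tie-break matters. A consensus tie (conflicting bases, equal
  qualities) deterministically emits the read-1 base with the — low —
  posterior quality.
* **Single-end reads.** The same model without overlap terms:
  candidate trim points $i \le l$ score
  $P(i)\,(1/4)^i\,P(a \approx r[i..])$ against a
  molecule-longer-than-read hypothesis. A winning trim point yields
  decision `trimmed_single`; a winning no-trim hypothesis is reported
  with the pass-through decision code `kept_as_pair`, the package's
  single keep-as-is category.

## The simulator, and what it does not emulate

`simulate_pairs()` reproduces the generative process the model assumes:
fragment lengths drawn from a log-normal (default $\mu = 3.8$,
$\sigma = 0.3$: median ≈ 45 bp, essentially all mass below 100 bp — a
typical degraded library) or from an explicit length list; fragments
taken from a reference FASTA (windows containing `N` are rejected and
redrawn) or generated uniformly at random with configurable GC;
reads built as fragment + adaptor + random post-adaptor padding,
truncated to the read length (default 100 bp); substitution errors
injected independently per base, uniformly over the three
alternatives; qualities drawn from separate distributions for correct
(default ≈ N(37, 2)) and erroneous (≈ N(18, 5)) calls, clamped to
[2, 41], or from a user-supplied empirical profile table. Everything
derives from one seed through R's Mersenne–Twister stream, so output
is byte-identical across runs and platforms.

Real data differ in ways the simulator deliberately ignores: errors
are not independent of position or context, quality scores are only
approximately calibrated, indels occur (rarely, on Illumina),
ancient-DNA damage inflates C→T/G→A mismatches at fragment ends, and
adaptor sequences can themselves be read with errors *and* truncated
by quality trimming upstream. Passing the simulation-based tests
therefore demonstrates correctness of the inference under its own
model assumptions — not performance on any particular instrument's
error process.

The test suite runs the full loop at sizes chosen to exercise the
statistics without waste: 200 random short pairs against the
brute-force oracle, 1,000 pairs per condition for recovery and
error-rate sweeps ({0, 2, 5, 10}% substitutions), 1,000 long-molecule
pairs for the false-merge comparison of uniform versus matched prior,
and 400 pairs at 1% error for the merged-versus-trimmed mismatch
comparison. `scripts/acceptance.R` re-runs the same computations from
a caller-supplied seed.

## Known limitations

* Indel-tolerant adaptor alignment is out of scope; a single indel in
  the adaptor region shifts the whole comparison frame.
* Substitution errors are modelled as uniform over the three
  alternative bases; damage-aware (asymmetric) substitution priors are
  not implemented.
* Quality scores are trusted as calibrated error probabilities; no
  recalibration is attempted.
* Adaptor sequences must be supplied (defaults are TruSeq-style);
  there is no adaptor discovery.
* Processing is single-threaded; throughput is adequate for
  method-validation workloads rather than production-scale lanes.
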