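# readmerge

Bayesian adaptor trimming and merging of overlapping Illumina read
pairs, for libraries whose molecules are shorter than the read length —
the typical situation in ancient-DNA, forensic and cell-free DNA work.

When a DNA fragment of length *i* is shorter than the read length,
read 1 runs through the fragment into adaptor 1, read 2 runs through
the reverse-complement strand into adaptor 2, and the two reads overlap
over the whole fragment. `readmerge` treats trimming and merging as a
single inference problem: for every candidate fragment length
*i* ∈ {0, …, l₁+l₂} it computes

    P(i | r1, r2, a1, a2)  ∝  P(a1 ≈ r1[i..]) · P(r1[0..i) ≈ rc(r2)[0..i)) · P(a2 ≈ r2[i..]) · P(i)

where the adaptor terms score each base as 1 − p_e(q) on a match and
p_e(q)/3 on a mismatch (p_e(q) = 10^(−q/10) from the PHRED score, 1/4
past the adaptor's end), the overlap term marginalises each doubly
covered position over the unknown template base, positions covered by
one read only contribute 1/4, and the prior *P(i)* is uniform or
log-normal (the distribution that fits sequencing-library insert sizes;
fit it from data with `fit_length_prior()`). The hypothesis that the
molecule is *longer* than l₁+l₂ — no adaptor, no overlap — is scored
alongside, with prior mass 1 − cdf(l₁+l₂), so no hard cut-off is ever
applied. The maximum-a-posteriori length wins unless the second-best
hypothesis is within a factor of 1/20 (the ambiguity guard), in which
case the pair is passed through untouched.

Doubly covered positions are collapsed by Bayes' rule into a consensus
base whose quality is the PHRED scaling of its posterior error
probability, so merged bases in the overlap are *more* reliable than
either read alone ("cross-correction"). Single-end reads are handled by
the same model without the overlap term (`trim` mode).

The package also ships a read-pair simulator with configurable
substitution error rates and quality profiles plus truth-table scoring,
used throughout the test suite to validate the inference end to end.

## Worked example

```r
library(readmerge)

## simulate an ancient-DNA-like library: 500 pairs, 100 bp reads,
## log-normal fragment lengths (median ~45 bp), 2% error
sim <- simulate_pairs(sim_config(
  n_pairs = 500, read_len = 100, error_rate = 0.02,
  length_dist = list(kind = "lognormal", mu = 3.8, sigma = 0.3),
  seed = 7))

## fit the fragment-length prior from known lengths
prior <- fit_length_prior(sim$truth$true_length)
#> <length_prior> log-normal, mu = 3.8133, sigma = 0.2998 (log-length scale)
#>   median length 45.3 bp, mass below 100 bp: 0.996

## merge
batch <- merge_reads(sim$r1, sim$r2, prior = prior)
#> <merge_batch> 500 records
#>   merged          500
#>   ambiguous       0
#>   kept_as_pair    0
#>   trimmed_single  0

## score against the simulation truth
sc <- score_reconstruction(sim$truth, batch)
#> perfect: 0.986  correct length: 1.000  false merges: 0

## inspect one pair's posterior landscape
posterior_profile(sim$r1[[1]], sim$r2[[1]], adaptor_pair(), prior)
#> <length_posterior> (pair mode, 202 hypotheses)
#>   MAP molecule length: 89 bp
#>   log-odds best vs second best: 143.739 (ratio 3.76e-63)
```

All 500 pairs merge, every merged read has the true fragment length,
and 98.6% are reconstructed without a single mismatch despite the 2%
per-base error rate — the consensus step corrects most injected errors
in the overlap. `plot()` on a `length_posterior` draws the
log-likelihood landscape; the dashed line is the no-merge hypothesis.

## Command line

The installed package provides an executable script
(`system.file("exec", "readmerge", package = "readmerge")`; R places it
under the package's `exec/` directory):

```sh
readmerge merge --fq1 R1.fq.gz --fq2 R2.fq.gz --out merged.fq.gz \
    --prior lognormal --loc 3.8 --scale 0.3
readmerge trim  --fq1 single.fq.gz --out trimmed.fq.gz    # single-end
readmerge fit-prior --lengths lengths.txt
readmerge simulate --n 1000 --error-rate 0.02 --seed 1 --out-prefix sim
readmerge score --truth sim_truth.tsv --merged merged.fq --read-len 100
```

Inputs can be paired FASTQ (`--fq1/--fq2`), interleaved FASTQ
(`--fqi`) or unaligned BAM (`--bam-in`); output is FASTQ or a
decision-tagged unaligned BAM (`--bam-out`, `dc` aux tag). See
`readmerge merge --help` for all flags (`--ratio`, `--qual-cap`,
`--phred-offset`, …).

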