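---
title: "TXTLseq methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TXTLseq methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the quantities it
computes, the assumptions behind them, the parameters that matter, and the
choices made where the design was genuinely open. The companion README shows
a worked run; here we explain *why* the pipeline is built the way it is.

## The measurement model

A pooled reporter library contains constructs, each a regulatory sequence
(by default 165 nt) placed immediately upstream of a reporter ATG and
identified by a unique N-terminal barcode. Sequencing the input DNA pool
and the 3'-adaptor-ligated reporter cDNA pool yields per-construct read
counts. Because both pools are sequenced from the same reaction, the
relative RNA abundance of a construct normalized by its relative DNA
abundance estimates transcriptional output per template:

$$\mathrm{Tx}_i \;=\; \frac{\mathrm{RNA}_i / \sum_j \mathrm{RNA}_j}
                          {\mathrm{DNA}_i / \sum_j \mathrm{DNA}_j}.$$

The assumptions are those of any ratio-of-multinomials estimator: reads are
assigned to the correct construct (guaranteed here by exact barcode
matching against a designed index with unique barcodes), the sample totals
are large, and composition is comparable across pools (we therefore
normalize by totals of assigned reads only). Replicate counts are **summed
before** the ratio rather than averaged after it: pooling counts keeps the
estimator a ratio of sufficient statistics and does not overweight the
shallower replicate.

Constructs must reach **15 summed DNA reads** to enter downstream analysis;
below that the denominator is too noisy to interpret. The cutoff is a
count, not a rate, so it tightens automatically at low depth. log10 Tx over
passing constructs with nonzero RNA is converted to Z-scores per sample
(population SD, divisor $n$); the Z-transform is what makes profiles
comparable across lysates whose absolute transcriptional yield differs by
orders of magnitude. Constructs passing the DNA filter with *zero* RNA are
reported as "inactive" rather than assigned an arbitrary floor value; an
optional RNA pseudocount (default off) exists for modeling uses that need a
complete response vector.

Two open points were fixed and documented rather than guessed per run:
Z-scores are computed over **passing constructs only** (not all detected
barcodes), and RNA abundance is counted by **barcode identity** (reads
whose regulatory segment fails the 1-mismatch suffix check still count
toward abundance but are excluded from 5'-end pileups; set
`countsFrom = "match"` to require the full match).

## Read processing

Merged reads are expected to end in the common adaptor preceded by the two
random ligation bases; trimming scans for the adaptor from the 3' end
(rightmost acceptable placement wins, `maxMismatches = 0` by default) and
removes both. The built-in pair merger scores candidate overlaps as
$o - 2m$ (overlap length minus twice the mismatches), requires a minimum
overlap and a maximum mismatch fraction, resolves overlap disagreements by
base quality, and rejects ties outright — ambiguity is counted, not
guessed. Output of an external merger can be supplied directly.

Demultiplexing is exact by default. A Hamming-1 rescue exists but refuses
to run unless the library's pairwise barcode distance is at least 3, the
minimum at which single-error rescue cannot cross assignments. Every run
satisfies the conservation identity
`assigned + unassigned + rejected = total`, asserted internally.

For RNA reads, the 5' end of the trimmed payload is the inferred mRNA 5'
end; after removing the constant context and barcode from the 3' side, the
remaining segment is matched against the construct's regulatory-sequence
suffix (at most one mismatch) and its length gives the transcription start
position in ATG coordinates (+1 = first base of ATG; upstream negative; no
zero). Reads that would map upstream of the regulatory sequence are
impossible under this geometry and fail QC.

## TSS calling

Per-construct pileups of 5'-end positions are clustered in one dimension,
positions weighted by read counts. The procedure starts from 16 clusters
(capped at the number of distinct positions) and repeatedly decrements the
cluster count — re-clustering each time — while any two cluster
representatives lie within 10 bp of each other or any cluster holds less
than 1% of reads (strictly less: a cluster at exactly 1% survives). A
primary TSS is called when a unique cluster holds more than 70% of 5'-end
reads *and* more than 200 reads (both strict); other clusters above 10%
yield secondary TSSs. The representative of a cluster is its modal
position, ties broken toward the most upstream (most negative) position,
matching single-nucleotide TSS biology.

The clustering step itself solves the weighted 1D k-means objective
**exactly**, by dynamic programming over contiguous partitions (the
optimal-1D-clustering approach familiar from `Ckmeans.1d.dp`). We chose
exactness over iterative centroid refinement deliberately: in one dimension
the exact solution costs little more than Lloyd iteration, it removes all
dependence on initialization, and — decisively — the decrement loop makes
the *procedure* sensitive to clustering quality. We found pileups where a
locally optimal Lloyd partition at some k happens to satisfy the merge
rule while the globally optimal partition at the same k does not, sending
the two procedures down different k's and changing the final calls. With
exact clustering the whole pipeline is byte-deterministic, and the test
suite cross-checks it against an independently implemented top-down
dynamic program plus brute-force enumeration at small sizes. The DP tables
are computed once per pileup and backtracked at every k, so the decrement
loop costs one pass.

The 200-read primary threshold is applied after replicate pooling,
consistent with pooled-count quantification.

## Promoter features and models

Eight features are extracted for every construct with a primary TSS:

| feature | definition | units / range |
|---|---|---|
| f1 | best −35 hexamer log-odds within the joint scan | bits |
| f2 | best −10 hexamer log-odds | bits |
| f3 | product of standardized f1 and f2 | — |
| f4 | spacer penalty, $-\lvert s - 17\rvert$ for $s \in [15, 19]$ | {0, −1, −2} |
| f5 | GC fraction of the annotated spacer | [0, 1] |
| f6 | log-odds of the 8 bp downstream of the TSS | bits |
| f7 | folding pseudo-energy of the first 50 nt of transcript | ≤ 0 |
| f8 | GC fraction of the full regulatory sequence | [0, 1] |

The −35/−10 matrices are discovered de novo by one-occurrence-per-sequence
expectation-maximization on the top 10% most active promoters, within the
45 bp upstream of each primary TSS (a distal sub-window for the −35, the
proximal 15 bp for the −10; the downstream matrix uses the 8 bp from the
TSS). EM initialization is deterministic — the most frequent window k-mer,
alphabetical tie-break, seeded at probability 0.7 — and iterates to a
1e-6 max-change tolerance with a 0.5 pseudocount; all-identical input
degenerates gracefully to that k-mer's profile. Annotation scans all
placements of both hexamers inside the 45-bp window with spacers of
17 ± 2 bp, maximizing combined log-odds plus the spacer penalty; the
penalty scale (−1 bit-equivalent per bp of deviation) is the package's
choice — the existence of a suboptimal-spacer penalty is biologically
motivated, its magnitude is not published, so it is a configurable default.
Eight features rather than seven: "spacer sequence" contributes both a
length penalty (f4) and a composition term (f5), which fixes the count
while keeping each column interpretable.

The folding term (f7) defaults to Nussinov maximum base pairing
(Watson-Crick + G:U, minimum hairpin loop 3, −1 per pair): a deterministic,
dependency-free pseudo-energy that orders sequences by structure-forming
propensity. It is *not* a thermodynamic free energy; when kcal/mol matters,
pass a folder adapter (e.g. `viennaFolder()`, which shells out to RNAfold)
to the `external` backend. The two backends agree in rank, not in value.

Models are ordinary least squares of activity Z-scores on standardized
features (constant columns get zero coefficients; rank-deficient designs
fall back to a 1e-8 ridge with a warning). Cross-validation repeats random
10%/90% train/test splits 10 times under a caller-supplied seed; the
within-one-log metric back-transforms predictions to log10 using the
training set's mean and SD, because a Z-scale residual has no natural
"one log" unit. Validation on an independent library reuses the training
PWMs — re-discovering motifs on the validation set would leak.

## Comparative analytics

Profile matrices take the constructs active (passing filter, nonzero RNA)
in **every** included sample; correlation, PCA (samples as observations,
column-centered SVD, component signs fixed by the largest-magnitude
loading) and average-linkage clustering on $1 - r$ operate on that matrix.
Species-selective promoters require strictly more than 10-fold higher raw
activity than the best other sample. Depletion screening tests each
construct's output count against its input fraction with a one-sided
binomial test (BH-corrected, q < 0.05 *and* fold change < 0.5 — the exact
test and level are the package's documented defaults, chosen because the
per-construct null is a binomial draw under stable composition), then
ranks degenerate 5-mers (at most one N — a space of 2,304 patterns,
sufficient to express restriction sites like CCNGG) by fold-enrichment in
depleted vs retained constructs under hypergeometric presence/absence
tests.

## The simulator: what it emulates, and what it does not

`generateLibrary` plants sigma70-consensus-degraded −35/−10 pairs (spacer
15–19 bp, TSS 7 bp downstream of the −10 start, per-construct strength
0.6–1) in a configurable fraction of otherwise random constructs, with
barcodes at pairwise Hamming ≥ 3. `assignTruth` makes true log10 activity
an exact linear function of the true features plus Gaussian noise, and
`simulateReads` renders FASTQ: Dirichlet-perturbed input abundances
(gamma shape 10 — moderate, library-prep-like inhomogeneity), multinomial
counts per replicate, RNA weights proportional to abundance times
$10^{\text{activity}}$, per-read 5' ends jittered by a discretized
Gaussian (sd 0.5, leaving roughly 92% of reads exactly on the TSS — the
scale of observed single-bp concordance), and optional motif-driven
depletion and per-base substitution error. All randomness flows from one
seed and output is byte-stable.

What the simulator does **not** emulate: sequence-dependent
reverse-transcription or ligation bias, PCR duplicates and chimeras,
quality-score structure, indels, RNA degradation profiles, fitness
coupling of in vivo libraries (a log-normal abundance multiplier exists
but defaults off), or any biochemistry of the lysate itself. Passing the
simulation-based tests therefore demonstrates algorithmic correctness —
that the pipeline recovers what the assay design encodes — not robustness
to every artifact of real sequencing data.

The test suite and acceptance script run at sizes chosen to exercise the
statistics without waste: 1,000 constructs at one million reads per kind
per replicate for end-to-end recovery, 150–600 constructs at 10^5-scale
depths for module tests, 200 fuzzed pileups for the clustering oracle,
n = 5,000 for model recovery. At those sizes the end-to-end activity
recovery correlation is ~0.98 and TSS recovery within 1 bp is ~100% for
constructs with ≥ 300 reads; both are recomputed, not asserted constants.

## Known limitations

* Exact barcode demultiplexing discards reads with barcode errors
  (conservative counts at realistic error rates); the Hamming-1 rescue is
  opt-in.
* The suffix-match 5'-end inference assumes constructs are exact: it
  tolerates one substitution but no indels, appropriate for synthesized
  libraries, not for mutagenized ones.
* The Nussinov pseudo-energy ignores stacking thermodynamics; use the
  external backend for energies.
* EM motif discovery assumes exactly one occurrence per window and a fixed
  width of 6; promoters recognized by other sigma factors, or elements at
  unusual distances, will be mis-annotated rather than skipped.
* The depletion screen's binomial null ignores overdispersion between
  library preparations; with replicated input pools a beta-binomial would
  be stricter.
* With fewer than two samples the comparative-analytics functions
  deliberately refuse to run rather than degenerate.
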