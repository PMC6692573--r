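# TXTLseq

Multiplexed transcriptional profiling of barcoded regulatory sequences in
cell-free (TXTL) and in vivo expression systems.

## What this package is for

Massively parallel reporter assays measure thousands of promoters at once by
sequencing instead of fluorescence: a pooled library of uniquely barcoded
constructs — each a regulatory sequence (typically the 165 bp immediately
upstream of a reporter ATG) — is incubated in a cell-free lysate (or
transformed into cells), and both the input DNA pool and the reporter mRNA
pool are deep-sequenced. TXTLseq implements the complete computational side
of such an experiment for people running or reanalyzing these assays:

* **Read processing** — overlap-merging of read pairs, trimming of the
  3'-ligated common adaptor and its two random ligation bases, and exact
  barcode demultiplexing of DNA and cDNA reads against the designed library.
* **Activity quantification** — for construct *i*, the transcriptional
  activity is the relative-abundance ratio

  Tx_i = (RNA_i / Σ RNA) / (DNA_i / Σ DNA)

  with DNA and RNA counts summed over replicates, a 15-DNA-read abundance
  cutoff, and log10 Tx converted to Z-scores across the passing constructs
  of each sample for cross-sample comparison.
* **Transcription start site (TSS) calling** — the 5' end of each cDNA read
  is mapped back onto its construct (the adaptor-ligation design means the
  cDNA 3' end is the mRNA 5' end); per-construct 5'-end pileups are
  clustered by exact weighted one-dimensional k-means starting from 16
  seeds, with clusters merged when their representatives lie within 10 bp
  and pruned below 1% of reads. A primary TSS requires > 70% of 5'-end
  reads and > 200 reads; secondary TSSs hold > 10%. Positions are reported
  in bp from the ATG (+1 = first base of ATG, upstream negative).
* **Promoter sequence features** — within the 45 bp upstream of each primary
  TSS, −35 and −10 hexamer matrices are discovered de novo (OOPS
  expectation-maximization on the top 10% most active promoters) and
  scanned jointly with a spacer constraint of 17 ± 2 bp (penalty −1 per bp
  of deviation). Eight features feed the activity models: −35 and −10
  log-odds scores, their interaction, spacer penalty, spacer GC, the
  composition score of the 8 bp downstream of the TSS, the folding
  pseudo-energy of the first 50 nt of transcript (Nussinov maximum base
  pairing, or a thermodynamic folder via an adapter), and the GC content of
  the full regulatory sequence.
* **Activity models** — ordinary least squares on standardized features with
  repeated random-subsampling cross-validation (default 10% train / 90%
  test, 10 repeats) and a within-one-log10 prediction metric.
* **Comparative analytics** — pairwise Pearson profiles over universally
  active constructs, PCA with deterministic sign convention, average-linkage
  clustering on correlation distance (newick output), species-selective
  promoter calls (> 10-fold, strict), and restriction-motif depletion
  screening (per-construct binomial tests, then hypergeometric enrichment of
  degenerate 5-mers such as CCNGG over depleted vs retained constructs).
* **A read simulator** — generates libraries with planted sigma70 promoters,
  assigns ground-truth activities as a linear function of the true features,
  and renders error-free (optionally error-prone) FASTQ with known per-read
  5' ends, so every pipeline stage can be validated against truth.

## Worked example

Simulate a 300-member library, run the pipeline, and inspect the results:

```r
library(TXTLseq)

gl    <- generateLibrary(300, motifPlantFrac = 0.6, seed = 7)
truth <- assignTruth(gl$library, gl$truth,
                     beta = c(0.6, 0.9, 0.1, 0.3, -0.2, 0.2, 0.15, -0.8),
                     sigma = 0.25, seed = 8)
sim   <- simulateReads(gl$library, truth, depthDna = 3e5, depthRna = 3e5,
                       dir = tempdir(), seed = 9)
res   <- runPipeline(gl$library, sim$dnaFiles, sim$rnaFiles,
                     file.path(tempdir(), "out"),
                     config = list(trainFrac = 0.5, cvRepeats = 5))

res$tss
#> TssCallSet: 300 constructs, 72 with a primary TSS
res$pwms$pwm10
#> PWMatrix: width 6, consensus TATAAT
res$pwms$pwm35
#> PWMatrix: width 6, consensus TTGACA
res$model
#> PromoterModel: 8 features, r_train = 0.903, r_test = NA
mean(res$cv$r_test)
#> [1] 0.827
head(as.data.frame(res$tss@calls), 3)
#>   construct_id primary_tss primary_fraction primary_count total_reads secondaries
#> 1        c0001         -56                1           202         202
#> 2        c0002         -55                1           932         932
#> 3        c0003          NA               NA            NA          13         -63
```

Reading the output: 72 constructs received enough 5'-end reads to satisfy
the > 70% / > 200-read primary rule (c0003, at 13 reads, does not — its
minor cluster at −63 bp still surfaces as a secondary candidate). The
motif matrices discovered from the most active promoters recover the
canonical sigma70 hexamers, and a model trained on half the constructs
predicts held-out activity Z-scores at mean Pearson r ≈ 0.83. Comparing
estimated log10 activities against the simulation's truth gives r ≈ 0.98
at this depth. All outputs (count, activity, TSS, feature tables; PWM and
model files; a manifest with input hashes and the full configuration) are
written to the output directory as plain TSV/JSON.

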