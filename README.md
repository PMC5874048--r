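# txReadthrough

Strand-specific meta-gene analysis of RNA polymerase II transcription
termination failure ("read-through") from bulk RNA-seq coverage.

When termination fails — for example when the 5'→3' "torpedo" exonuclease
XRN2 is catalytically inactive — polymerase continues past the transcription
end site (TES) and RNA accumulates downstream of annotated 3' ends.
`txReadthrough` quantifies this from stranded per-base coverage: it is aimed
at anyone with a transcript annotation (GTF) and strand-specific coverage
(bedGraph pair per library, or a dUTP-protocol BAM) who wants a reproducible
read-through profile and a statistical contrast between conditions, without
hand-rolled interval arithmetic.

## The statistic

For every highly expressed (TPM > 10), spliced transcript *t* whose
downstream region is free of other same-strand transcripts, the signal is
summed in *K* contiguous genomic windows of *W* = 250 nt placed directly
downstream of the TES, and normalized to the signal in the last 250 nt of
the gene body:

```
r_t(k) = S_t(window k downstream) / S_t(terminal 250 nt),   k = 1..K
```

The meta-gene profile is the per-window aggregate across transcripts, either
as the mean of the per-transcript ratios (`mean_of_ratios`, default; every
transcript weighs equally) or as the ratio of pooled sums (`pooled_ratio`;
a cumulative-signal reading). Conditions are compared per window by the
difference of means with a 95% bootstrap confidence interval (resampling
transcripts within each condition).

The package also ships a seeded simulator with known ground truth: uniform
expected coverage `c_t` on exons and a read-through component
`alpha * c_t * exp(-d / lambda)` at distance *d* downstream of the TES, with
per-base Poisson noise. Its closed-form expectation,

```
E[r(k)] = alpha * (lambda/W) * exp(-(k-1) W / lambda) * (1 - exp(-W/lambda)),
```

makes every stage verifiable at desk scale, including recovery of `alpha`
from a fitted meta-gene via `estimateReadthroughFraction()`.

## Worked example

Simulated wild-type (alpha = 0.05) versus termination-deficient
(alpha = 0.6) libraries over 100 transcripts:

```r
library(txReadthrough)

params <- simulationParams(nTranscripts = 100, seed = 7)
sim <- simulateAnnotation(params)
wt  <- simulateCoverage(sim$annotation, sim$truth, alpha = 0.05, seed = 8)
mut <- simulateCoverage(sim$annotation, sim$truth, alpha = 0.60, seed = 9)

cfg  <- pipelineConfig()                      # W=250, K=20, TPM>10, spliced
tpm  <- computeTpm(sim$annotation, mut)
filt <- filterTranscripts(sim$annotation, tpm, cfg)
keep <- sim$annotation[filt$transcript_id[filt$retained]]   # 89 of 100
                                              # (11 excluded: monoexonic)

psW <- transcriptProfiles(keep, wt,  cfg, "wildtype", "rep1")
psM <- transcriptProfiles(keep, mut, cfg, "mutant",   "rep1")
metageneProfile(psM)
#> MetaGeneProfile [mutant/rep1] mode=mean_of_ratios, n=89 transcript(s)
#>  window distance_nt      mean          sd  n
#>       1           0 0.5335241 0.017314955 89
#>       2         250 0.4125067 0.012658162 89
#>       3         500 0.3193144 0.011530430 89
#>       4         750 0.2497162 0.008359366 89
#>       5        1000 0.1947730 0.007777517 89
#>   ...
```

The window-1 mean of 0.53 says that, in the mutant, the first 250 nt past
the TES still carry about half the gene-body signal — read-through — decaying
with the simulated 1-kb length scale. The contrast confirms the difference
is real at every window:

```r
head(compareConditions(psW, psM, cfg), 3)
#>   window distance_nt  diff ratio ci_lo ci_hi n_boot seed
#> 1      1           0 0.489  12.0 0.485 0.493   1000    1
#> 2      2         250 0.378  11.8 0.375 0.381   1000    1
#> 3      3         500 0.292  11.9 0.290 0.295   1000    1

estimateReadthroughFraction(metageneProfile(psM), decayLength = 1000)
#> [1] 0.603      # true value: 0.6
```

The same analysis runs from the shell on file inputs (GTF + bedGraph pairs)
via a YAML config:

```sh
Rscript inst/scripts/txreadthrough.R simulate --out fixtures --seed 42
Rscript inst/scripts/txreadthrough.R run-all --config fixtures/config.yaml
```

producing `transcripts.tsv` (filter audit), `profiles.tsv`, `metagene.tsv`,
`comparison.tsv` and a run manifest; outputs are byte-identical across
reruns with the same config and seed.

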