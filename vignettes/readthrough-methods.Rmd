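---
title: "Quantifying transcriptional read-through: model and methods"
author: "txReadthrough"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcriptional read-through: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txReadthrough)
```

## The question and the measurement

Termination of RNA polymerase II transcription depends on 5'→3'
exonucleolytic degradation of the nascent downstream RNA (the torpedo
mechanism, in human cells carried out by XRN2). When this activity is lost,
polymerase runs past the transcription end site (TES) and steady-state RNA
accumulates downstream of annotated 3' ends. In stranded RNA-seq this is
visible as strand-specific coverage decaying away from the TES.

The measurement implemented here anchors every analyzable transcript at its
TES, sums coverage in $K$ contiguous genomic windows of width $W$ placed
directly downstream (window $k$ spans distances $[(k-1)W, kW)$ from the
TES, following transcription direction: increasing coordinates on `+`,
decreasing on `-`), and normalizes each transcript's window sums to the
signal in its *terminal window* — the last $W$ nt of the gene body adjacent
to the TES:

$$ r_t(k) = \frac{S_t(\text{downstream window } k)}{S_t(\text{terminal } W\text{ nt})}. $$

Self-normalization is what makes profiles comparable across transcripts and
libraries: it cancels expression level and sequencing depth exactly (the
test suite asserts bit-level invariance under scaling all coverage by a
constant), so condition curves can only separate downstream of the TES —
gene-body levels coincide by construction.

## Transcript selection

Only transcripts for which the statistic is meaningful enter the meta-gene:

* **expression** — coverage-based TPM strictly greater than the threshold
  (default 10). TPM is computed from per-base exonic coverage (summed
  exonic signal over exonic length, rescaled so all transcripts sum to
  $10^6$), not from read counts; with coverage as the pipeline's canonical
  input this is self-consistent, and the normalization identity
  $\sum \mathrm{TPM} = 10^6$ holds whenever any signal is present. The
  threshold is applied strictly (`>`), so a transcript at exactly the
  threshold is excluded. Filtering is done on coverage pooled across a
  condition's replicates, so one retained set serves all replicates of that
  condition.
* **splicing** — at least two exons (default on). Spliced structure is
  evidence of a genuine processed transcript rather than an assembly
  artifact or an unresolved precursor.
* **clearance** — no other same-strand transcript may overlap the region of
  length `clearance` (default $K \cdot W$ = 5 kb) immediately downstream of
  the TES; otherwise downstream windows would read a neighbour's gene-body
  signal rather than read-through. Isoforms of the same gene sharing the
  identical TES are exempt, as their downstream region is the same.
  Opposite-strand neighbours never matter because the signal is
  strand-specific. Whether such exclusion is strictly necessary is not
  settled; it is configurable (set `clearance = 0` to disable) and on by
  default as the conservative choice.

Every transcript is accounted for in the output table as retained or
excluded with all failed rules recorded (semicolon-joined), so filter
behaviour is auditable.

At the profile stage three more per-transcript validity rules apply,
all-or-none across windows so the meta-gene has a constant $n$: a terminal
signal below a floor $\epsilon$ (default 1 signal unit) invalidates the
profile rather than producing an exploding or undefined ratio
(`terminal-floor`); a transcript span shorter than $W$ has no terminal
window (`short-span`); windows running below position 1 or past a known
chromosome end are not measurable (`out-of-bounds`).

## Windows are genomic, and two aggregation modes

Windows — including the terminal reference — are placed on the genomic
span, ignoring exon structure. This matches the windowed-density reading of
the measurement and keeps window arithmetic exact; the cost is that a
terminal exon shorter than $W$ dilutes the reference with intronic
positions. Such transcripts are flagged (`terminalExonShort`) but still
measured, preserving auditability without changing the definition.

Aggregation across transcripts is genuinely ambiguous — averaging
per-transcript ratios and pooling cumulative signal are both defensible and
differ exactly when expression and read-through are correlated across
transcripts (the test suite pins the worked example: terminal signals
100 and 300 with window-1 signals 100 and 0 give 0.5 under
`mean_of_ratios` but 0.25 under `pooled_ratio`). Both are implemented and
tagged in every output; `mean_of_ratios` is the default because equal
per-transcript weighting is the more robust meta-gene convention, and every
profile it averages is already self-normalized.

Replicates are kept separate through profiling; meta-genes are reported per
replicate and for the concatenated profiles of all replicates
(`combined`).

## Condition contrast

The comparison between conditions is a per-window difference of
`mean_of_ratios` means (contrast minus reference) with a 95% percentile
bootstrap interval obtained by resampling transcripts (transcript ×
replicate units) with replacement within each condition, 1000 resamples by
default. A bootstrap was chosen over a parametric test because the
per-transcript ratios are heavily right-skewed and no distributional claim
is warranted. The bootstrap is seeded from the pipeline seed and restores
the caller's RNG state, so identical configurations give identical output.

## The simulator and its oracle

The generator emulates the statistical structure of a stranded (dUTP
protocol) RNA-seq termination experiment: non-overlapping transcripts on
one synthetic chromosome, triplicate libraries per condition, and a
condition-dependent read-through component. Expected per-base coverage is

$$ \mu(p) = c_t \text{ on exons of } t, \qquad
   \mu(\mathrm{TES} + d) = \alpha \, c_t \, e^{-d/\lambda}
   \ \ (0 \le d < D_{\max}), \qquad \beta \text{ elsewhere}, $$

with per-base Poisson noise (or none, for analytic checks). Exponential
decay is the simplest monotone model for post-TES signal loss, and it
admits a closed form: the noiseless normalized window value is

$$ E[r(k)] = \alpha \frac{\lambda}{W} e^{-(k-1)W/\lambda}
   \left(1 - e^{-W/\lambda}\right), $$

the continuous approximation of the discrete per-base sum (they agree
within 0.5% for $\lambda \ge 500$, $W = 250$; a brute-force summation test
verifies this). Inverting the $k = 1$ case yields the estimator
`estimateReadthroughFraction()`, whose recovery of the true $\alpha$ is a
standing test.

Default parameters, chosen once to be realistic for this kind of
experiment: per-base expression $c_t$ log-normal with meanlog 3 and sdlog 1
(median ≈ 20 read-bases per position, i.e. well-expressed genes with a
spread of one order of magnitude); decay length $\lambda$ = 1000 nt and
extent $D_{\max}$ = 5000 nt (kilobase-scale read-through); 90% spliced
transcripts of 1–5 exons; exons 300–800 nt — the minimum is kept above
$W = 250$ so the terminal reference window is always fully exonic, which
the uniform-coverage model assumes when it equates the terminal window with
gene-body level; introns 100–1000 nt; background $\beta = 0$; intergenic
gaps of at least 6000 nt, which exceed both $D_{\max}$ and the default
clearance so that windows and read-through regions never touch a
neighbouring transcript; three replicates; read-through fractions 0.05
(wild-type-like leakage) versus 0.6 (termination-deficient) for the shipped
two-condition bundle.

What the simulator deliberately does **not** model: splice-junction reads
and 3' coverage bias, overdispersion beyond Poisson, antisense or
overlapping transcription, multi-chromosome genomes, and read-level
artifacts (duplicates, mapping ambiguity). Passing tests therefore
demonstrate correctness of the windowing, normalization, filtering and
aggregation machinery under a known generative model — not robustness to
every feature of real libraries. On real data the same machinery applies,
but $\lambda$ is not known and the recovered $\alpha$ should be read as a
model-based summary, not a physical fraction.

## Numerical and degenerate-input choices

* Interval sums are exact per-base sums over run-length-encoded coverage —
  no binning or interpolation; positions without data contribute zero.
  Equality with a per-base brute-force oracle over random intervals is
  asserted bitwise.
* All-zero coverage yields all-zero TPM (no division by zero); an all-zero
  condition aborts the pipeline with the exclusion tally rather than
  producing an empty meta-gene.
* GTF coordinates (1-based inclusive) pass through unchanged into
  GRanges-based containers; bedGraph (0-based half-open) is shifted at the
  boundary. Overlapping exons within one transcript are merged with a
  warning (tolerant of assembler output); overlapping bedGraph intervals
  are an error naming file and line.
* Writers are deterministic: fixed column formats, no timestamps in any
  TSV (the run manifest carries the timestamp). Pipeline stages communicate
  through their TSV files, so running `quantify`, `metagene` and `compare`
  separately is *definitionally* identical to `run-all`.
* Seeds: one pipeline seed drives the bootstrap; the simulator derives
  per-replicate seeds deterministically from its own seed. Seeded sections
  restore the caller's RNG state.

## Problem sizes

The shipped tests and the acceptance script run entirely on simulated
data: 100–200 transcripts per dataset on a ~2–3 Mb synthetic chromosome,
up to 20 windows of 250 nt, 10 repetitions for recovery checks and 20 for
null-coverage checks, 400–1000 bootstrap resamples. These sizes give
standard errors far below the asserted tolerances while keeping any single
check in seconds.

## Known limitations

* Coverage-based TPM diverges from count-based TPM (no effective-length or
  fragment-model corrections); the strict threshold therefore selects a
  slightly different set than a count-based pipeline would.
* The genomic terminal window understates gene-body density for
  transcripts with short terminal exons (flagged, not corrected).
* The bootstrap contrast treats transcripts as exchangeable units and does
  not model replicate-level variance components.
* The BAM adapter implements only the dUTP ("reverse", read 2 carries the
  transcript strand) convention and flag-based exclusion; no duplicate
  marking or mapping-quality policy of its own.
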