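---
title: "Characterizing marker-assisted backcross lines from whole-genome variant data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing marker-assisted backcross lines from whole-genome variant data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mabcr)
```

## The problem

Marker-assisted backcrossing (MABC) transfers a single target allele from a
donor cultivar into an elite recurrent parent: the donor is crossed to the
recurrent parent, the progeny are repeatedly backcrossed to the recurrent
parent while selecting carriers of the target allele (foreground selection),
and a final self-fertilization fixes the target homozygous. The question a
breeder then asks is *how much of the recurrent-parent genome came back*.
Whole-genome sequencing of the two parents and one advanced progeny answers
it at nucleotide resolution: every site where the parents are homozygous for
different alleles is an informative marker whose progeny genotype reads out
parental origin.

`mabcr` implements that analysis as a pipeline over a three-sample VCF:

1. **Site filtering** — reduce raw multi-sample calls to reliable markers.
2. **Classification** — assign each informative marker a parental-origin
   class (recurrent-homozygous, heterozygous, donor-homozygous,
   non-parental).
3. **Recovery rate** — the recurrent-parent allele frequency among
   classified markers, with its theoretical expectation.
4. **Graphical genotyping** — window densities and contiguous genotype
   blocks along chromosomes.
5. **Effect annotation** — a minimal codon-level consequence caller and
   trait-gene cross-reference for the donor-derived variants that remain.

A forward-time breeding simulator generates complete synthetic studies
(parents, meioses, selection, noisy VCFs) with known truth, so every stage
is testable without any external data.

## Filtering model

A site survives filtering iff it passes all of, in order:

| filter | rule | default |
|---|---|---|
| missing | no sample call may be missing | on |
| multiallelic | exactly one ALT allele; records dropped whole, never decomposed | on |
| parental het | both parents homozygous | on |
| depth | per-sample DP at or above threshold, all three samples | 6 reads |
| quality | site QUAL at or above threshold | 20 |
| progeny balance | heterozygous progeny alt-allele fraction inside a closed band | [0.40, 0.60] |

Removals are attributed to the *first* failing filter, so tallies are
deterministic, order-independent and conserve the input count. Two choices
deserve comment. The depth rule is applied per sample rather than to a
site-level DP: a marker is only as reliable as its weakest call, and the
per-sample reading is the stricter of the two interpretations. Allele
balance is computed from the AD field (`alt / (ref + alt)` over the first
two entries); when a heterozygous call carries no AD the balance filter is
skipped for that site and the skip is counted rather than silently ignored.
The band endpoints are inclusive: a balance of exactly 0.40 or 0.60 is kept.

## Recovery rate

With `YY`, `YK`, `KK` the counts of recurrent-homozygous, heterozygous and
donor-homozygous markers, the genome recovery rate is the recurrent-parent
allele frequency

$$R = \frac{YY + YK/2}{YY + YK + KK},$$

equivalently the mean per-marker recurrent-allele dosage divided by 2.
Non-parental sites (an allele matching neither parent — genotyping error or
residual multiallelism) are excluded from the denominator and reported
separately. Percentages in the profile table are rounded half-up to one
decimal, matching how such tables are printed.

```{r}
recovery_rate(106288, 9009, 3157)
```

The no-selection expectations after $n$ backcrosses and $m$ selfings are

$$E[R] = 1 - 2^{-(n+1)}, \qquad
  E[\text{het fraction}] = 2^{-(n+m)}.$$

The allele frequency is unchanged by selfing; heterozygosity starts at 1 in
the F1 and halves every generation thereafter, backcross or selfing alike.
`expected_recovery(3, 1)` therefore gives 0.9375 and 0.0625 for a BC3F2.
(Some presentations write the het expectation with an extra factor of two;
the form used here is the one that satisfies both boundary conditions —
an F1 heterozygous everywhere and a halving per generation — and it is
verified against the simulator in the test suite.)

## Blocks and windows

Graphical genotypes are drawn from two reductions of the classified marker
list. *Window densities* count markers per class in fixed windows (default
10 kb tiling; set `step < window_size` to slide) and report the dominant
class, with ties resolved as `NONE` rather than by any class order. *Blocks*
are maximal runs of consecutive same-class markers, broken when the
inter-marker gap exceeds `max_gap` (default 1 Mb, respecting marker deserts)
and required to contain at least `min_markers` markers (default 3,
suppressing single-marker noise). Shorter runs are flagged as candidate
micro-blocks — real double-recombination segments do occur inside larger
blocks and should stay visible — and flanking same-class runs are rejoined
across them. Block extent is first-to-last supporting marker, not window
edges. Internally positions are 1-based (VCF convention); BED output is
0-based half-open, converted only at the writer boundary, so 1-based
position $p$ occupies 0-based coordinate $p-1$ and window $[0, 10000)$
holds positions 1–10000.

## Effect annotation

The annotator is a deliberately minimal stand-in for a full consequence
predictor: enough to separate protein-altering from silent variants and to
cross-reference candidate genes, not a reimplementation of SnpEff. Gene
models come from GFF3 (`mRNA`/`transcript` with `exon` and `CDS` children;
phase honored from the file), sequence from a genome FASTA. For each
variant and overlapping transcript the region is resolved as splice site
(the canonical 2 nt at each intron end, strand-aware donor/acceptor), CDS,
UTR, intron or intergenic; a variant spanning several regions takes the
most severe. Coding variants are evaluated by rebuilding the spliced CDS,
applying the allele, and translating both sequences: a length change not
divisible by 3 is a frameshift (HIGH); an in-frame indel is MODERATE; SNPs
are classified synonymous / missense / stop-gained / stop-lost / start-lost
by the amino-acid change. One most-severe term is kept per variant across
transcripts (severity order fixed and total; see `so_severity_table()`),
and "protein-altering" means impact HIGH or MODERATE. Indels that run from
CDS into non-coding sequence are classified from the net length change
alone; variants touching a splice site are splice variants regardless of
their coding overlap.

## The simulator

The simulator is the package's source of ground truth and defines the
conditions under which the pipeline is validated:

* **Genome** — 12 chromosomes with rice-like lengths (~373 Mb total) and a
  uniform genetic map of 1 cM per 400 kb; both configurable.
* **Markers** — positions uniform per chromosome, apportioned by physical
  length; parents homozygous for opposite alleles at every marker; 80%
  SNPs, 20% short (1–3 nt) indels, echoing the roughly 4:1 SNP:indel ratio
  whole-genome comparisons of related cultivars yield.
* **Meiosis** — crossover counts Poisson with mean the genetic length in
  Morgans, positions uniform, no interference (Haldane), starting
  chromatid fair; an F1 gamete is therefore donor-derived over half its
  length in expectation.
* **Scheme** — the default is BC3F2 with foreground selection: progeny
  heterozygous at the target locus through BC3F1 (gametes redrawn until
  the donor allele transmits, with a bounded attempt count), the first
  selfing product donor-homozygous at the target. The target defaults to
  chromosome 6 at 5 Mb; its physical position is a free parameter.
* **Noise** — per-site missing calls, low-depth and low-quality spikes,
  spurious third alleles, genotype errors, and forced heterozygote
  allele-balance skew, each at a configurable rate; depths Poisson
  (mean 30) or constant; heterozygote AD split exactly or binomially. The
  `"none"` preset (constant depth 30, exact AD, QUAL 60, all rates zero)
  is the oracle setting under which pipeline output equals truth exactly.

What the simulator does *not* emulate: reference-biased mapping artifacts,
locally clustered marker density, crossover interference and hotspots, and
segregation distortion. Passing tests therefore demonstrate correctness of
the accounting and estimation machinery under a clean generative model, not
robustness to every artifact of real short-read data.

One empirical point the simulator makes sharply: foreground selection drags
linked donor chromatin along (linkage drag), and on a ~930 cM genome the
depression of the genome-wide mean recovery below the no-selection
expectation of $1 - 2^{-4}$ is on the order of several percentage points,
concentrated around the target. The closed-form expectation above is the
*no-selection* value, and the package's validation of it runs the scheme
with `select_target = FALSE`; the selected scheme is validated
qualitatively (target fixed donor-homozygous, recovery depressed nearby).

## Problem sizes and numerical choices

The shipped validation uses marker counts of 2,000–50,000 and replicate
counts of 60–2,000, chosen so each statistical check has the power its
tolerance needs (binomial and Poisson checks at 3 SE; the Monte-Carlo mean
over 2,000 BC3F2 genomes has a standard error below 0.1 percentage points).
Determinism is end-to-end under a single seed: identical seeds produce
byte-identical VCFs and reports. Degenerate inputs are defined, not
accidental: allele balance on zero reads is undefined (`NA`) and fails the
band test; an empty VCF yields an empty table; all-zero class counts are an
error for the recovery rate; tied window classes dominate as `NONE`.

## Limitations

* Recovery is marker-averaged, not cM-weighted; with markers apportioned by
  physical length this approximates physical-genome recovery.
* The annotator assumes well-formed gene models (CDS within exons,
  canonical splice sites) and does not model NMD, regulatory features or
  loss-of-function curation.
* Block calling is rule-based (runs and gaps), not an HMM; it will not
  smooth genotyping error beyond the micro-block flagging already built in.
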