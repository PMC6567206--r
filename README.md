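# mabcr

Genome characterization for marker-assisted backcross (MABC) breeding
programs, from whole-genome variant calls.

When a target allele is introgressed from a donor cultivar into an elite
recurrent parent by repeated backcrossing, sequencing the two parents and an
advanced progeny turns every parentally divergent homozygous site into an
informative marker: the progeny genotype at such a site reads out parental
origin. `mabcr` takes a three-sample VCF (donor, recurrent parent, progeny)
and

* filters sites to reliable markers (missing data, multiallelic records,
  heterozygous parents, per-sample depth < 6, QUAL < 20, and heterozygous
  progeny calls with alt-allele balance outside the closed 40–60% band);
* classifies each informative marker as recurrent-homozygous (`YY`),
  heterozygous (`YK`), donor-homozygous (`KK`) or non-parental;
* computes the **genome recovery rate**

  ```
  R = (YY + YK/2) / (YY + YK + KK)
  ```

  together with its theoretical no-selection expectation
  `1 − 2^−(n_backcross+1)` and the expected heterozygous fraction
  `2^−(n_backcross+n_self)`;
* segments chromosomes into window densities and contiguous genotype blocks
  (graphical genotyping, BED output);
* annotates remaining donor-derived variants with a minimal codon-level
  consequence caller (Sequence Ontology terms, HIGH/MODERATE/LOW/MODIFIER
  impact) and cross-references trait-gene lists.

A forward-time breeding simulator (Haldane meioses, BCnFm schemes with
foreground selection at a target locus, configurable sequencing noise)
generates complete synthetic studies with known truth; it is how the package
validates itself and a convenient source of test data.

## Worked example

Simulate a BC3F2 introgression line (three backcrosses, one selfing,
foreground selection at chr06:5,000,000), emit a noisy VCF, and run the
pipeline:

```r
library(mabcr)

p     <- make_parental_genomes(sim_config(n_markers = 20000), seed = 101)
ind   <- run_scheme(scheme_spec(), p, seed = 102)
sites <- genotype_markers(ind, p$map,
                          noise_model(missing_rate = 0.01,
                                      low_depth_rate = 0.01), seed = 103)
emit_vcf(sites, "example.vcf", p$map$chrom_lengths)

cfg <- pipeline_config("example.vcf", donor = "donor",
                       recurrent = "recurrent", progeny = "progeny",
                       chrom_lengths = p$map$chrom_lengths,
                       out_dir = "example_out")
run_pipeline(cfg)
```

```
Genotype         SNPs   Indels  Total  Genome %
Recurrent (hom)  13308  3353    16661  84.9
Donor (hom)      735    187     922    4.7
Hetero           1657   384     2041   10.4
Total            15700  3924    19624  100.0
Genome recovery rate: 90.1%
Blocks: 20 (12 recurrent-hom, 3 donor-hom, 5 het)
```

The table is the classified-marker accounting: of 19,624 markers surviving
the filters (199 removed as missing, 176 for low depth at these noise
settings), 84.9% are recurrent-parent homozygous and the recovery rate —
recurrent-allele frequency — is 90.1%, exactly matching the simulator's
haplotype-level truth (`true_recovery(ind, p$map)` = 0.9011). It sits below
the no-selection expectation of 93.75% because foreground selection drags
linked donor chromatin along: per-chromosome recovery
(`recovery_by_chromosome`) shows chr06, which carries the selected target,
recovered only 72.9%, while unlinked chromosomes are fully recovered.
`example_out/` holds the per-site classified table, filter tally, window
densities, block BED and the rendered summary.

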