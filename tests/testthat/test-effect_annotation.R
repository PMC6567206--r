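# All effect-annotation tests run on the toy two-exon gene (see
# helper-fixtures.R): CDS = ATG GCT GCA GGA AAA CCC TTC TAC GAT TAA,
# protein MAAGKPFYD*.

toy <- write_toy_annotation()
genome <- read_genome(toy$fasta)
models <- read_gene_models(toy$gff)
tx <- models[["tx1"]]

test_that("gene models load with exons, CDS and strand", {
  expect_equal(length(models), 1L)
  expect_equal(tx$gene_id, "gene1")
  expect_equal(tx$strand, "+")
  expect_equal(tx$exons$start, c(101, 199))
  expect_equal(tx$cds$end, c(138, 210))
  expect_equal(tx$cds$phase, c(0L, 0L))
})

test_that("variants are located in the right transcript region", {
  expect_equal(locate_variant("chrT", 130, "G", models)$region, "CDS")
  expect_equal(locate_variant("chrT", 110, "A", models)$region, "UTR")
  expect_equal(locate_variant("chrT", 160, "T", models)$region, "intron")
  expect_equal(locate_variant("chrT", 139, "G", models)$region,
               "splice_donor_variant")
  expect_equal(locate_variant("chrT", 140, "T", models)$region,
               "splice_donor_variant")
  expect_equal(locate_variant("chrT", 198, "G", models)$region,
               "splice_acceptor_variant")
  expect_equal(nrow(locate_variant("chrT", 20, "A", models)), 0L)
})

test_that("coding SNPs classify by their amino-acid change", {
  cc <- function(pos, ref, alt)
    coding_consequence("chrT", pos, ref, alt, tx, genome)
  # GGA -> GGG, Gly4Gly
  syn <- cc(132, "A", "G")
  expect_equal(syn$so_term, "synonymous_variant")
  expect_equal(syn$impact, "LOW")
  # GCT -> GTT, Ala2Val
  mis <- cc(125, "C", "T")
  expect_equal(mis$so_term, "missense_variant")
  expect_equal(mis$impact, "MODERATE")
  expect_equal(mis$protein_change, "p.A2V")
  # TAC -> TAA, Tyr8* (spans the intron: codon 8 sits in exon 2)
  expect_equal(cc(204, "C", "A")$so_term, "stop_gained")
  # terminal TAA -> CAA
  expect_equal(cc(208, "T", "C")$so_term, "stop_lost")
  # ATG -> ACG
  expect_equal(cc(122, "T", "C")$so_term, "start_lost")
})

test_that("CDS indels are frameshift iff length change mod 3 != 0", {
  cc <- function(pos, ref, alt)
    coding_consequence("chrT", pos, ref, alt, tx, genome)
  seq <- toy$seq
  # deletions of 1..6 nt anchored at genomic 123 (inside CDS exon 1)
  for (k in 1:6) {
    ref <- substr(seq, 123, 123 + k)
    eff <- cc(123, ref, substr(seq, 123, 123))
    if (k %% 3 == 0) {
      expect_equal(eff$so_term, "inframe_deletion")
      expect_equal(eff$impact, "MODERATE")
    } else {
      expect_equal(eff$so_term, "frameshift_variant")
      expect_equal(eff$impact, "HIGH")
    }
  }
  # insertions of 1..6 nt
  for (k in 1:6) {
    anchor <- substr(seq, 123, 123)
    eff <- cc(123, anchor, paste0(anchor,
                                  paste(rep("A", k), collapse = "")))
    expect_equal(eff$so_term,
                 if (k %% 3 == 0) "inframe_insertion" else
                   "frameshift_variant")
  }
})

test_that("a reference mismatch is reported as an error", {
  wrong_ref <- if (substr(toy$seq, 125, 125) == "A") "T" else "A"
  expect_error(coding_consequence("chrT", 125, wrong_ref, "G", tx, genome),
               "reference mismatch")
})

test_that("annotating the reference allele against itself is a no-op", {
  sites <- make_sites(make_site(chrom = "chrT", pos = 125L,
                                ref = substr(toy$seq, 125, 125),
                                alt = substr(toy$seq, 125, 125)))
  ann <- annotate_variants(sites, models, genome)
  expect_equal(nrow(ann), 0L)
})

test_that("mirrored gene models give identical terms for mirrored variants", {
  mir <- write_toy_annotation_mirror()
  genome_m <- read_genome(mir$fasta)
  models_m <- read_gene_models(mir$gff)
  cases <- list(
    list(pos = 132, ref = "A", alt = "G"),                       # synonymous
    list(pos = 125, ref = "C", alt = "T"),                       # missense
    list(pos = 204, ref = "C", alt = "A"),                       # stop gained
    list(pos = 123, ref = substr(toy$seq, 123, 124),
         alt = substr(toy$seq, 123, 123)),                       # frameshift
    list(pos = 123, ref = substr(toy$seq, 123, 126),
         alt = substr(toy$seq, 123, 123)),                       # inframe del
    list(pos = 139, ref = "G", alt = "C"),                       # splice donor
    list(pos = 160, ref = substr(toy$seq, 160, 160), alt = "A")  # intron
  )
  for (v in cases) {
    fwd <- annotate_variants(
      make_sites(make_site(chrom = "chrT", pos = as.integer(v$pos),
                           ref = v$ref, alt = v$alt)), models, genome)
    m <- mirror_variant(v$pos, v$ref, v$alt)
    rev <- annotate_variants(
      make_sites(make_site(chrom = "chrT", pos = as.integer(m$pos),
                           ref = m$ref, alt = m$alt)), models_m, genome_m)
    expect_equal(rev$so_term, fwd$so_term, info = paste("pos", v$pos))
  }
})

test_that("one most-severe term survives when transcripts overlap", {
  # duplicate the transcript so the variant hits two models; count once
  models2 <- models
  tx2 <- tx; tx2$tx_id <- "tx1b"
  models2[["tx1b"]] <- tx2
  class(models2) <- class(models)
  sites <- make_sites(make_site(chrom = "chrT", pos = 125L, ref = "C",
                                alt = "T"))
  ann <- annotate_variants(sites, models2, genome)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$so_term, "missense_variant")

  # severity order is total and fixed
  sev <- so_severity_table()
  expect_true(which(sev$so_term == "stop_gained") <
                which(sev$so_term == "missense_variant"))
  expect_true(which(sev$so_term == "frameshift_variant") <
                which(sev$so_term == "inframe_deletion"))
  expect_true(which(sev$so_term == "missense_variant") <
                which(sev$so_term == "synonymous_variant"))
  expect_true(which(sev$so_term == "synonymous_variant") <
                which(sev$so_term == "intron_variant"))
  expect_equal(sort(unique(sev$impact)),
               c("HIGH", "LOW", "MODERATE", "MODIFIER"))
})

test_that("effect tallies count protein-altering variants per class", {
  sites <- make_sites(
    make_site(chrom = "chrT", pos = 125L, ref = "C", alt = "T",
              progeny_gt = "1/1"),                         # missense, donor
    make_site(chrom = "chrT", pos = 204L, ref = "C", alt = "A",
              progeny_gt = "1/1"),                         # stop, donor
    make_site(chrom = "chrT", pos = 132L, ref = "A", alt = "G",
              progeny_gt = "1/1"),                         # synonymous, donor
    make_site(chrom = "chrT", pos = 110L, ref = "A", alt = "C",
              progeny_gt = "0/1", progeny_ad = "15,15")    # UTR, het
  )
  cls <- classify_sites(select_informative_sites(sites))
  ann <- annotate_variants(cls, models, genome)
  tal <- summarize_effects(ann, cls)
  pa <- attr(tal, "protein_altering")
  expect_equal(unname(pa["DONOR_HOM"]), 2L)   # missense + stop, not syn
  expect_equal(unname(pa["HET"]), 0L)
  expect_equal(tal$n[tal$class == "DONOR_HOM" &
                       tal$so_term == "synonymous_variant" &
                       tal$variant_class == "SNP"], 1L)

  none <- summarize_effects(ann[0, ], cls)
  expect_equal(sum(none$n), 0L)
})

test_that("trait-gene cross-reference keeps HIGH/MODERATE hits only", {
  tt_file <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ttrait\tdataset",
               "gene1\tCold tolerance\tdataset1",
               "geneX\tBlast resistance\tdataset2"), tt_file)
  tt <- read_trait_genes(tt_file)

  sites <- make_sites(
    make_site(chrom = "chrT", pos = 125L, ref = "C", alt = "T",
              progeny_gt = "1/1"),   # missense in gene1 -> reported
    make_site(chrom = "chrT", pos = 132L, ref = "A", alt = "G",
              progeny_gt = "1/1")    # synonymous in gene1 -> excluded
  )
  cls <- classify_sites(select_informative_sites(sites))
  ann <- annotate_variants(cls, models, genome)
  rep <- crossref_trait_genes(ann, tt, cls)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$gene_id, "gene1")
  expect_equal(rep$trait, "Cold tolerance")
  expect_equal(rep$class, "DONOR_HOM")

  # variant in an unlisted gene is excluded
  ann_other <- ann
  ann_other$gene_id <- "geneZ"
  expect_equal(nrow(crossref_trait_genes(ann_other, tt, cls)), 0L)
})
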