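# Fixtures built in code: hand-written VCF text, site-table constructors,
# and a toy two-exon gene model with genome FASTA + GFF3.

# A site-table row with passing defaults; override any field.
make_site <- function(chrom = "chr01", pos = 100L, ref = "G", alt = "A",
                      qual = 60, donor_gt = "1/1", recurrent_gt = "0/0",
                      progeny_gt = "0/0", donor_dp = 30L, recurrent_dp = 30L,
                      progeny_dp = 30L, donor_ad = "0,30",
                      recurrent_ad = "30,0", progeny_ad = "30,0") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, qual = qual,
             variant_class = ifelse(grepl(",", alt) | nchar(ref) > 1 |
                                      nchar(alt) > 1, "INDEL", "SNP"),
             donor_gt = donor_gt, recurrent_gt = recurrent_gt,
             progeny_gt = progeny_gt, donor_dp = donor_dp,
             recurrent_dp = recurrent_dp, progeny_dp = progeny_dp,
             donor_ad = donor_ad, recurrent_ad = recurrent_ad,
             progeny_ad = progeny_ad, stringsAsFactors = FALSE)
}

make_sites <- function(...) variant_sites(do.call(rbind, list(...)))

# A classified-site table from bare vectors (for segmentation tests).
make_classified <- function(chrom, pos, class, variant_class = "SNP") {
  df <- make_site()[rep(1L, length(pos)), ]
  df$chrom <- chrom; df$pos <- as.integer(pos)
  df$variant_class <- rep_len(variant_class, length(pos))
  df$class <- factor(class, levels = c("RECURRENT_HOM", "HET", "DONOR_HOM",
                                       "NON_PARENTAL"))
  rownames(df) <- NULL
  df
}

# Write a minimal three-sample VCF with given body lines.
write_test_vcf <- function(body, file = tempfile(fileext = ".vcf"),
                           samples = c("KJ", "YM", "BC")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr01,length=1000000>",
    "##contig=<ID=chr06,length=31000000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body
  ), file)
  file
}

vcf_record <- function(chrom = "chr01", pos = 100, ref = "G", alt = "A",
                       qual = 60, donor = "1/1:0,30:30",
                       recurrent = "0/0:30,0:30", progeny = "0/0:30,0:30") {
  paste(chrom, pos, ".", ref, alt, qual, "PASS", ".", "GT:AD:DP",
        donor, recurrent, progeny, sep = "\t")
}

TEST_ROLES <- c(donor = "KJ", recurrent = "YM", progeny = "BC")

# --- toy gene model ---------------------------------------------------------
# chrT, 300 nt, plus-strand gene:
#   exon1 101-138 (UTR 101-120, CDS 121-138), intron 139-198 (GT..AG),
#   exon2 199-230 (CDS 199-210, UTR 211-230)
# CDS (30 nt): ATG GCT GCA GGA AAA CCC TTC TAC GAT TAA -> protein MAAGKPFYD*
toy_cds <- "ATGGCTGCAGGAAAACCCTTCTACGATTAA"

toy_genome_seq <- function() {
  base <- strsplit(paste(rep("ACGTTGCA", 38), collapse = ""), "")[[1]][1:300]
  base[121:138] <- strsplit(substr(toy_cds, 1, 18), "")[[1]]
  intron <- strsplit(paste(rep("TTCA", 15), collapse = ""), "")[[1]]
  intron[1:2] <- c("G", "T"); intron[59:60] <- c("A", "G")
  base[139:198] <- intron
  base[199:210] <- strsplit(substr(toy_cds, 19, 30), "")[[1]]
  paste(base, collapse = "")
}

write_toy_annotation <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  seq <- toy_genome_seq()
  fasta <- file.path(dir, "toy.fa")
  writeLines(c(">chrT", seq), fasta)
  gff <- file.path(dir, "toy.gff3")
  writeLines(c(
    "##gff-version 3",
    "chrT\ttest\tgene\t101\t230\t.\t+\t.\tID=gene1",
    "chrT\ttest\tmRNA\t101\t230\t.\t+\t.\tID=tx1;Parent=gene1",
    "chrT\ttest\texon\t101\t138\t.\t+\t.\tID=ex1;Parent=tx1",
    "chrT\ttest\texon\t199\t230\t.\t+\t.\tID=ex2;Parent=tx1",
    "chrT\ttest\tCDS\t121\t138\t.\t+\t0\tID=cds1;Parent=tx1",
    "chrT\ttest\tCDS\t199\t210\t.\t+\t0\tID=cds2;Parent=tx1"
  ), gff)
  list(fasta = fasta, gff = gff, seq = seq)
}

# Mirror of the toy annotation: reverse-complemented genome, gene on the
# minus strand at mirrored coordinates (length 300: pos' = 301 - pos).
write_toy_annotation_mirror <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(toy_genome_seq())))
  fasta <- file.path(dir, "mirror.fa")
  writeLines(c(">chrT", seq), fasta)
  gff <- file.path(dir, "mirror.gff3")
  m <- function(a, b) c(301 - b, 301 - a)
  lines <- c("##gff-version 3",
    sprintf("chrT\ttest\tgene\t%d\t%d\t.\t-\t.\tID=gene1", m(101, 230)[1], m(101, 230)[2]),
    sprintf("chrT\ttest\tmRNA\t%d\t%d\t.\t-\t.\tID=tx1;Parent=gene1", m(101, 230)[1], m(101, 230)[2]),
    sprintf("chrT\ttest\texon\t%d\t%d\t.\t-\t.\tID=ex1;Parent=tx1", m(101, 138)[1], m(101, 138)[2]),
    sprintf("chrT\ttest\texon\t%d\t%d\t.\t-\t.\tID=ex2;Parent=tx1", m(199, 230)[1], m(199, 230)[2]),
    sprintf("chrT\ttest\tCDS\t%d\t%d\t.\t-\t0\tID=cds1;Parent=tx1", m(121, 138)[1], m(121, 138)[2]),
    sprintf("chrT\ttest\tCDS\t%d\t%d\t.\t-\t0\tID=cds2;Parent=tx1", m(199, 210)[1], m(199, 210)[2]))
  writeLines(lines, gff)
  list(fasta = fasta, gff = gff, seq = seq)
}

# Mirror a variant into the reverse-complemented toy genome.
mirror_variant <- function(pos, ref, alt, len = 300L) {
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  list(pos = len - (pos + nchar(ref) - 1L) + 1L, ref = rc(ref), alt = rc(alt))
}

# Small simulated genome config used across simulator tests.
small_config <- function(n_markers = 2000)
  sim_config(chrom_lengths = c(chr01 = 40e6, chr02 = 30e6, chr03 = 25e6),
             n_markers = n_markers)
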