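# Minimal codon-level variant-effect annotation against GFF3 gene models
# and a genome FASTA, with Sequence Ontology terms, impact tiers and
# trait-gene cross-referencing.
#
# The annotator is deliberately small: one most-severe consequence per
# variant, canonical 2-nt splice sites, and codon-table translation of the
# reference and mutant CDS.  It is not a general-purpose effect predictor;
# it covers the consequence classes a backcross characterization needs
# (frameshift / in-frame indels, missense / synonymous / stop-affecting
# SNPs, splice-site hits) over well-formed gene models.

.SO_SEVERITY <- c(
  "stop_gained", "stop_lost", "start_lost", "frameshift_variant",
  "splice_donor_variant", "splice_acceptor_variant",
  "missense_variant", "inframe_insertion", "inframe_deletion",
  "coding_sequence_variant",
  "synonymous_variant", "UTR_variant", "intron_variant",
  "intergenic_variant"
)

.SO_IMPACT <- c(
  stop_gained = "HIGH", stop_lost = "HIGH", start_lost = "HIGH",
  frameshift_variant = "HIGH", splice_donor_variant = "HIGH",
  splice_acceptor_variant = "HIGH",
  missense_variant = "MODERATE", inframe_insertion = "MODERATE",
  inframe_deletion = "MODERATE", coding_sequence_variant = "MODERATE",
  synonymous_variant = "LOW",
  UTR_variant = "MODIFIER", intron_variant = "MODIFIER",
  intergenic_variant = "MODIFIER"
)

#' Severity-ordered Sequence Ontology terms and impact map
#'
#' @return data.frame of SO terms in decreasing severity with their impact
#'   tier (`HIGH`, `MODERATE`, `LOW`, `MODIFIER`).
#' @export
so_severity_table <- function() {
  data.frame(so_term = .SO_SEVERITY,
             impact = unname(.SO_IMPACT[.SO_SEVERITY]),
             stringsAsFactors = FALSE)
}

#' Read a genome FASTA
#'
#' @param file FASTA path; sequence names are truncated at the first
#'   whitespace, matching chromosome identifiers in VCF/GFF3.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_genome <- function(file) {
  g <- Biostrings::readDNAStringSet(file)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read gene models from a GFF3 file
#'
#' Builds per-transcript gene models (exons, CDS intervals with phase,
#' strand, parent gene) from GFF3 `mRNA`/`transcript`, `exon` and `CDS`
#' features linked by `Parent` attributes.  Intervals are 1-based inclusive
#' as in GFF3.
#'
#' @param file GFF3 path.
#' @return list of class `mabc_gene_models`; one element per transcript
#'   with fields `tx_id`, `gene_id`, `chrom`, `strand`, `exons`, `cds`
#'   (data.frames with `start`, `end`, sorted by position; `cds` also has
#'   `phase`).
#' @export
read_gene_models <- function(file) {
  gr <- rtracklayer::import(file, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$type <- as.character(df$type)
  df$Parent <- vapply(as.list(df$Parent), function(p)
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]]), "")
  tx_rows <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  models <- lapply(seq_len(nrow(tx_rows)), function(i) {
    tx <- tx_rows[i, ]
    tx_id <- tx$ID
    kids <- df[!is.na(df$Parent) & df$Parent == tx_id, , drop = FALSE]
    take <- function(type) {
      k <- kids[kids$type == type, , drop = FALSE]
      k <- k[order(k$start), , drop = FALSE]
      out <- data.frame(start = k$start, end = k$end)
      if (type == "CDS")
        out$phase <- if (!is.null(k$phase)) as.integer(as.character(k$phase))
                     else rep(NA_integer_, nrow(k))
      out
    }
    list(tx_id = tx_id,
         gene_id = if (!is.na(tx$Parent)) tx$Parent else tx_id,
         chrom = as.character(tx$seqnames),
         strand = as.character(tx$strand),
         exons = take("exon"),
         cds = take("CDS"))
  })
  names(models) <- vapply(models, `[[`, "", "tx_id")
  structure(models, class = "mabc_gene_models")
}

# Splice-site intervals (first and last 2 nt of each intron) for a
# transcript, labelled donor/acceptor strand-aware.
.splice_sites <- function(tx) {
  ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
  if (nrow(ex) < 2L)
    return(data.frame(start = integer(0), end = integer(0),
                      side = character(0)))
  istart <- ex$end[-nrow(ex)] + 1L   # intron starts (left end, genomic)
  iend <- ex$start[-1L] - 1L         # intron ends
  keep <- iend >= istart
  istart <- istart[keep]; iend <- iend[keep]
  left <- data.frame(start = istart, end = pmin(istart + 1L, iend))
  right <- data.frame(start = pmax(iend - 1L, istart), end = iend)
  if (tx$strand == "-") {
    left$side <- "splice_acceptor_variant"
    right$side <- "splice_donor_variant"
  } else {
    left$side <- "splice_donor_variant"
    right$side <- "splice_acceptor_variant"
  }
  rbind(left, right)
}

.overlaps <- function(qstart, qend, start, end) {
  any(qstart <= end & qend >= start)
}

#' Locate a variant relative to gene models
#'
#' Region resolution for a single variant against every overlapping
#' transcript: `CDS`, `splice_donor`/`splice_acceptor` (within the first or
#' last 2 nt of an intron, strand-aware), `intron`, `UTR` (exonic,
#' non-coding) or `intergenic`.  A variant whose span touches several
#' regions reports the most severe (splice over CDS over the rest).
#'
#' @param chrom,pos chromosome and 1-based position.
#' @param ref reference allele (its length defines the affected span).
#' @param models gene models from [read_gene_models()].
#' @return data.frame with one row per overlapping transcript (`tx_id`,
#'   `gene_id`, `region`); zero rows means intergenic.
#' @export
locate_variant <- function(chrom, pos, ref, models) {
  span_end <- pos + nchar(ref) - 1L
  hits <- lapply(models, function(tx) {
    if (tx$chrom != chrom) return(NULL)
    tx_start <- min(tx$exons$start, tx$cds$start)
    tx_end <- max(tx$exons$end, tx$cds$end)
    if (!.overlaps(pos, span_end, tx_start, tx_end)) return(NULL)
    ss <- .splice_sites(tx)
    region <- NULL
    for (i in seq_len(nrow(ss)))
      if (.overlaps(pos, span_end, ss$start[i], ss$end[i])) {
        region <- ss$side[i]; break
      }
    if (is.null(region)) {
      if (nrow(tx$cds) > 0L &&
          .overlaps(pos, span_end, tx$cds$start, tx$cds$end) &&
          any(pos <= tx$cds$end & span_end >= tx$cds$start)) {
        region <- "CDS"
      } else if (any(pos <= tx$exons$end & span_end >= tx$exons$start)) {
        region <- "UTR"
      } else {
        region <- "intron"
      }
    }
    data.frame(tx_id = tx$tx_id, gene_id = tx$gene_id, region = region,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    hits <- data.frame(tx_id = character(0), gene_id = character(0),
                       region = character(0), stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  hits
}

# Spliced CDS in genomic (plus-strand) orientation plus a map from genomic
# position to index in that spliced sequence.
.spliced_cds <- function(tx, genome) {
  cds <- tx$cds[order(tx$cds$start), , drop = FALSE]
  chrom_seq <- genome[[tx$chrom]]
  pieces <- lapply(seq_len(nrow(cds)), function(i)
    as.character(Biostrings::subseq(chrom_seq, cds$start[i], cds$end[i])))
  seq_plus <- paste(pieces, collapse = "")
  gpos <- unlist(lapply(seq_len(nrow(cds)), function(i)
    seq.int(cds$start[i], cds$end[i])))
  list(seq = seq_plus, gpos = gpos)
}

# Trim GFF3 phase from the 5' end of an oriented CDS, then pad to a codon
# multiple for translation.
.orient_cds <- function(seq_plus, tx) {
  s <- if (tx$strand == "-") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_plus)))
  } else seq_plus
  cds <- tx$cds
  phase <- if (tx$strand == "-") cds$phase[which.max(cds$end)]
           else cds$phase[which.min(cds$start)]
  if (!is.na(phase) && phase > 0L) s <- substring(s, phase + 1L)
  s
}

.translate_cds <- function(s) {
  n <- nchar(s) - nchar(s) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(s, 1L, n)),
                                     if.fuzzy.codon = "solve"))
}

#' Codon-level consequence of a coding variant
#'
#' Rebuilds the spliced CDS from the genome, applies the variant, translates
#' reference and mutant coding sequences, and classifies the consequence:
#' length change not divisible by 3 is a frameshift (HIGH); an in-frame
#' indel is `inframe_insertion`/`inframe_deletion` (MODERATE); a SNP is
#' classified by the amino-acid change (`synonymous_variant`,
#' `missense_variant`, `stop_gained`, `stop_lost`, `start_lost`).
#' Minus-strand transcripts are handled by reverse complement.
#'
#' @param chrom,pos,ref,alt the variant (1-based; `ref`/`alt` are VCF-style
#'   allele strings).
#' @param tx one transcript model (an element of [read_gene_models()]).
#' @param genome a [Biostrings::DNAStringSet].
#' @return one-row data.frame: `so_term`, `impact`, `protein_change`.
#' @export
coding_consequence <- function(chrom, pos, ref, alt, tx, genome) {
  sp <- .spliced_cds(tx, genome)
  span_end <- pos + nchar(ref) - 1L
  idx <- match(seq.int(pos, span_end), sp$gpos)
  if (anyNA(idx)) {
    # partial CDS overlap (e.g. indel running into an intron): classify by
    # net length change over the CDS portion alone
    dlen <- nchar(alt) - nchar(ref)
    term <- if (dlen %% 3L != 0L) "frameshift_variant"
            else "coding_sequence_variant"
    return(data.frame(so_term = term, impact = unname(.SO_IMPACT[term]),
                      protein_change = NA_character_,
                      stringsAsFactors = FALSE))
  }
  observed <- substr(sp$seq, idx[1L], idx[length(idx)])
  if (!identical(observed, ref))
    stop(sprintf("reference mismatch at %s:%d: VCF says '%s', genome has '%s'",
                 chrom, pos, ref, observed))
  mutant_plus <- paste0(substr(sp$seq, 1L, idx[1L] - 1L), alt,
                        substr(sp$seq, idx[length(idx)] + 1L, nchar(sp$seq)))
  ref_cds <- .orient_cds(sp$seq, tx)
  alt_cds <- .orient_cds(mutant_plus, tx)
  ref_aa <- .translate_cds(ref_cds)
  alt_aa <- .translate_cds(alt_cds)

  dlen <- nchar(alt) - nchar(ref)
  if (dlen %% 3L != 0L) {
    aa_pos <- .first_aa_diff(ref_aa, alt_aa)
    return(.eff("frameshift_variant",
                sprintf("p.%s%dfs", substr(ref_aa, aa_pos, aa_pos), aa_pos)))
  }
  if (dlen != 0L) {
    term <- if (dlen < 0L) "inframe_deletion" else "inframe_insertion"
    return(.eff(term, sprintf("p.%d_%s", .first_aa_diff(ref_aa, alt_aa),
                              if (dlen < 0L) "del" else "ins")))
  }
  # substitution (possibly MNP); compare proteins codon by codon
  aa_pos <- .first_aa_diff(ref_aa, alt_aa)
  if (is.na(aa_pos))
    return(.eff("synonymous_variant", "p.(=)"))
  ref_aa1 <- substr(ref_aa, aa_pos, aa_pos)
  alt_aa1 <- substr(alt_aa, aa_pos, aa_pos)
  change <- sprintf("p.%s%d%s", ref_aa1, aa_pos, alt_aa1)
  if (aa_pos == 1L && ref_aa1 == "M" && alt_aa1 != "M")
    return(.eff("start_lost", change))
  if (alt_aa1 == "*" && ref_aa1 != "*") return(.eff("stop_gained", change))
  if (ref_aa1 == "*" && alt_aa1 != "*") return(.eff("stop_lost", change))
  .eff("missense_variant", change)
}

.eff <- function(term, change) {
  data.frame(so_term = term, impact = unname(.SO_IMPACT[term]),
             protein_change = change, stringsAsFactors = FALSE)
}

.first_aa_diff <- function(a, b) {
  n <- max(nchar(a), nchar(b))
  if (n == 0L) return(NA_integer_)
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  length(av) <- n; length(bv) <- n
  d <- which(is.na(av) | is.na(bv) | av != bv)
  if (length(d) == 0L) NA_integer_ else d[1L]
}

#' Annotate variants with their most severe consequence
#'
#' Runs [locate_variant()] and, where coding, [coding_consequence()] for
#' every site and keeps exactly one most-severe annotation per variant
#' across transcripts (ties broken by transcript order).  The reference
#' allele annotated against itself yields no consequence and is skipped.
#' Variants on chromosomes absent from the annotation are reported
#' intergenic with a warning.
#'
#' @param sites a site table (biallelic; `alt` single allele).
#' @param models gene models from [read_gene_models()].
#' @param genome a [Biostrings::DNAStringSet].
#' @return data.frame: `chrom`, `pos`, `ref`, `alt`, `gene_id`, `tx_id`,
#'   `so_term`, `impact`, `protein_change`; one row per variant.
#' @export
annotate_variants <- function(sites, models, genome) {
  known_chroms <- unique(vapply(models, `[[`, "", "chrom"))
  unknown <- setdiff(unique(sites$chrom), known_chroms)
  if (length(unknown) > 0L)
    warning("chromosomes absent from annotation, reported intergenic: ",
            paste(unknown, collapse = ", "))
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    chrom <- sites$chrom[i]; pos <- sites$pos[i]
    ref <- sites$ref[i]; alt <- sites$alt[i]
    base <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                       stringsAsFactors = FALSE)
    if (identical(ref, alt)) return(NULL)  # identity: no consequence
    hits <- locate_variant(chrom, pos, ref, models)
    if (nrow(hits) == 0L)
      return(cbind(base, gene_id = NA_character_, tx_id = NA_character_,
                   .eff("intergenic_variant", NA_character_)[, 1:2],
                   protein_change = NA_character_))
    anns <- lapply(seq_len(nrow(hits)), function(j) {
      region <- hits$region[j]
      eff <- if (region == "CDS") {
        coding_consequence(chrom, pos, ref, alt, models[[hits$tx_id[j]]],
                           genome)
      } else if (region %in% c("splice_donor_variant",
                               "splice_acceptor_variant")) {
        .eff(region, NA_character_)
      } else if (region == "UTR") {
        .eff("UTR_variant", NA_character_)
      } else {
        .eff("intron_variant", NA_character_)
      }
      cbind(base, gene_id = hits$gene_id[j], tx_id = hits$tx_id[j], eff)
    })
    anns <- do.call(rbind, anns)
    anns[order(match(anns$so_term, .SO_SEVERITY))[1L], , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gene_id = character(0), tx_id = character(0),
                      so_term = character(0), impact = character(0),
                      protein_change = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Tally effects by genotype class, SO term and variant class
#'
#' Joins annotations to classified sites by position and cross-tabulates,
#' counting each variant once at its most severe term.  "Protein-altering"
#' means impact HIGH or MODERATE.
#'
#' @param annotations output of [annotate_variants()].
#' @param sites a classified site table.
#' @return data.frame of counts (`class` x `so_term` x `variant_class`),
#'   with attribute `protein_altering`: per-class counts of HIGH/MODERATE
#'   variants.
#' @export
summarize_effects <- function(annotations, sites) {
  key_a <- paste(annotations$chrom, annotations$pos, annotations$alt)
  key_s <- paste(sites$chrom, sites$pos, sites$alt)
  m <- match(key_a, key_s)
  ann <- annotations[!is.na(m), , drop = FALSE]
  idx <- m[!is.na(m)]
  ann$class <- as.character(sites$class[idx])
  ann$variant_class <- sites$variant_class[idx]
  tab <- as.data.frame(table(
    class = factor(ann$class, levels = .GENOTYPE_CLASSES),
    so_term = factor(ann$so_term, levels = .SO_SEVERITY),
    variant_class = factor(ann$variant_class, levels = c("SNP", "INDEL"))),
    stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "n"
  altering <- ann$impact %in% c("HIGH", "MODERATE")
  pa <- vapply(.GENOTYPE_CLASSES, function(cl)
    sum(altering & ann$class == cl), 0L)
  attr(tab, "protein_altering") <- pa
  tab
}

#' Read a trait-gene table
#'
#' @param file TSV with columns `gene_id`, `trait`, `dataset` (a tag naming
#'   the source gene list).
#' @return data.frame; gene IDs must be unique within a dataset.
#' @export
read_trait_genes <- function(file) {
  tt <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("gene_id", "trait", "dataset")
  if (!all(need %in% names(tt)))
    stop("trait table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tt[, c("gene_id", "dataset")]))
    stop("gene IDs must be unique within a dataset")
  tt
}

#' Cross-reference protein-altering variants with trait genes
#'
#' Selects HIGH/MODERATE-impact annotated variants whose gene appears in a
#' trait-gene table and reports them with their genotype class and
#' alteration type (the layout of a candidate-gene report).
#'
#' @param annotations output of [annotate_variants()].
#' @param trait_table data.frame from [read_trait_genes()].
#' @param sites optional classified site table supplying genotype classes.
#' @return data.frame: `chrom`, `pos`, `ref`, `alt`, `class`, `so_term`,
#'   `impact`, `gene_id`, `trait`, `dataset`.
#' @export
crossref_trait_genes <- function(annotations, trait_table, sites = NULL) {
  keep <- annotations$impact %in% c("HIGH", "MODERATE") &
    !is.na(annotations$gene_id) &
    annotations$gene_id %in% trait_table$gene_id
  ann <- annotations[keep, , drop = FALSE]
  cls <- rep(NA_character_, nrow(ann))
  if (!is.null(sites) && nrow(ann) > 0L) {
    m <- match(paste(ann$chrom, ann$pos, ann$alt),
               paste(sites$chrom, sites$pos, sites$alt))
    cls <- as.character(sites$class[m])
  }
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    tg <- trait_table[trait_table$gene_id == ann$gene_id[i], , drop = FALSE]
    data.frame(chrom = ann$chrom[i], pos = ann$pos[i], ref = ann$ref[i],
               alt = ann$alt[i], class = cls[i], so_term = ann$so_term[i],
               impact = ann$impact[i], gene_id = ann$gene_id[i],
               trait = tg$trait, dataset = tg$dataset,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      class = character(0), so_term = character(0),
                      impact = character(0), gene_id = character(0),
                      trait = character(0), dataset = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
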