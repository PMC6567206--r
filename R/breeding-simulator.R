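# Forward-time backcross simulator: parental marker maps, Haldane meioses,
# the BCnFm scheme with foreground selection at a target locus, and noisy
# three-sample VCF emission with known truth.
#
# Haplotypes are parent-of-origin mosaics stored per chromosome as segment
# end positions plus origins ("D" donor / "R" recurrent); the segments tile
# [0, length).  All randomness flows through R's global RNG; seed arguments
# call set.seed() so identical seeds give byte-identical output.

# Approximate rice (IRGSP-1.0) chromosome lengths, nt.
.RICE_CHROM_LENGTHS <- c(
  chr01 = 43270923, chr02 = 35937250, chr03 = 36413819, chr04 = 35502694,
  chr05 = 29958434, chr06 = 31248787, chr07 = 29697621, chr08 = 28443022,
  chr09 = 23012720, chr10 = 23207287, chr11 = 29021106, chr12 = 27531856
)

#' Simulator genome configuration
#'
#' Defaults emulate a 12-chromosome rice-like genome (~373 Mb) with a
#' uniform genetic map of 1 cM per 400 kb and an 80:20 SNP:indel marker
#' mix, mirroring the marker composition whole-genome sequencing yields
#' between two divergent cultivars.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (nt).
#' @param cm_per_mb genetic map density (cM per Mb; 2.5 = 1 cM/400 kb).
#' @param n_markers total number of parental-divergent markers, apportioned
#'   to chromosomes by physical length.
#' @param snp_fraction fraction of markers that are SNPs (rest are 1-3 nt
#'   indels).
#' @return list of class `mabc_sim_config`.
#' @export
sim_config <- function(chrom_lengths = .RICE_CHROM_LENGTHS,
                       cm_per_mb = 2.5, n_markers = 50000,
                       snp_fraction = 0.8) {
  stopifnot(all(chrom_lengths > 0), cm_per_mb >= 0,
            n_markers >= 0, snp_fraction >= 0, snp_fraction <= 1)
  structure(list(chrom_lengths = chrom_lengths,
                 genetic_lengths = chrom_lengths / 1e6 * cm_per_mb,
                 n_markers = n_markers, snp_fraction = snp_fraction),
            class = "mabc_sim_config")
}

#' Breeding-scheme specification
#'
#' The default is the BC3F2 scheme: donor crossed to the recurrent parent,
#' three backcrosses with heterozygote selection at the target locus, then
#' one self-fertilization selecting a donor-homozygote at the target
#' (foreground selection only; no background marker selection).
#'
#' @param n_backcross number of backcross generations.
#' @param n_self number of self-fertilization rounds.
#' @param target_chrom,target_pos the foreground-selection locus; the
#'   default sits mid-arm on chromosome 6 (the physical position of the
#'   target is a free parameter of the simulation).
#' @param select_target apply foreground selection (heterozygous at the
#'   target through the backcrosses, donor-homozygous from the first
#'   selfing on)?  With `FALSE` the scheme advances without selection,
#'   giving the no-selection theoretical expectations.
#' @param max_attempts bound on gamete redraws per selection step before
#'   failing.
#' @return list of class `mabc_scheme`.
#' @export
scheme_spec <- function(n_backcross = 3L, n_self = 1L,
                        target_chrom = "chr06", target_pos = 5e6,
                        select_target = TRUE, max_attempts = 10000L) {
  stopifnot(n_backcross >= 0, n_self >= 0, max_attempts >= 1)
  structure(list(n_backcross = as.integer(n_backcross),
                 n_self = as.integer(n_self),
                 target_chrom = target_chrom, target_pos = target_pos,
                 select_target = isTRUE(select_target),
                 max_attempts = as.integer(max_attempts)),
            class = "mabc_scheme")
}

#' Sequencing-noise model for VCF emission
#'
#' @param mean_depth mean per-sample read depth.
#' @param depth_dist `"poisson"` (depth ~ Poisson(mean)) or `"constant"`.
#' @param het_ab `"exact"` (heterozygote allele depths split as evenly as
#'   the depth allows) or `"binomial"` (alt reads ~ Binomial(DP, 0.5)).
#' @param missing_rate per-site probability the progeny call is missing.
#' @param low_depth_rate per-site probability one random sample's depth is
#'   replaced by a draw from 0..5 reads.
#' @param low_qual_rate per-site probability the site QUAL drops below 20.
#' @param multiallelic_rate per-site probability a spurious third allele is
#'   appended.
#' @param genotype_error_rate per-site probability the progeny genotype is
#'   replaced by a random different one.
#' @param ab_skew_rate fraction of heterozygous progeny sites whose allele
#'   balance is forced to `ab_skew_value`.
#' @param ab_skew_value the forced alternate-allele balance.
#' @return list of class `mabc_noise`; `noise_model(preset = "none")`
#'   switches every rate to 0 with constant depth 30 and exact allele
#'   depths (the noiseless oracle setting).
#' @export
noise_model <- function(mean_depth = 30, depth_dist = c("poisson", "constant"),
                        het_ab = c("exact", "binomial"),
                        missing_rate = 0, low_depth_rate = 0,
                        low_qual_rate = 0, multiallelic_rate = 0,
                        genotype_error_rate = 0,
                        ab_skew_rate = 0, ab_skew_value = 0.30,
                        preset = NULL) {
  if (identical(preset, "none"))
    return(noise_model(mean_depth = 30, depth_dist = "constant",
                       het_ab = "exact"))
  depth_dist <- match.arg(depth_dist)
  het_ab <- match.arg(het_ab)
  rates <- c(missing_rate, low_depth_rate, low_qual_rate, multiallelic_rate,
             genotype_error_rate, ab_skew_rate)
  stopifnot(all(rates >= 0 & rates <= 1), mean_depth >= 0,
            ab_skew_value >= 0, ab_skew_value <= 1)
  structure(list(mean_depth = mean_depth, depth_dist = depth_dist,
                 het_ab = het_ab, missing_rate = missing_rate,
                 low_depth_rate = low_depth_rate,
                 low_qual_rate = low_qual_rate,
                 multiallelic_rate = multiallelic_rate,
                 genotype_error_rate = genotype_error_rate,
                 ab_skew_rate = ab_skew_rate, ab_skew_value = ab_skew_value),
            class = "mabc_noise")
}

# A pure-parent haplotype: one segment per chromosome.
.pure_haplotype <- function(chrom_lengths, origin) {
  lapply(chrom_lengths, function(len)
    list(bp = as.numeric(len), origin = origin))
}

#' Simulate parental genomes and a marker map
#'
#' Draws marker positions uniformly per chromosome (apportioned by physical
#' length), assigns each marker divergent parental alleles (the recurrent
#' allele is the VCF REF, the donor allele the ALT) and a SNP/indel flag,
#' and returns both fully homozygous parents.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed (sets the RNG).
#' @return list: `map` (list with `chrom_lengths`, `genetic_lengths`,
#'   `markers` data.frame of `chrom`, `pos`, `ref`, `alt`,
#'   `variant_class`), `donor`, `recurrent` (individuals: lists with
#'   haplotypes `hap1`, `hap2`).
#' @export
make_parental_genomes <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- config$chrom_lengths
  n_per <- round(config$n_markers * lens / sum(lens))
  if (any(n_per == 0L))
    warning("chromosomes with zero markers: ",
            paste(names(lens)[n_per == 0L], collapse = ", "))
  bases <- c("A", "C", "G", "T")
  markers <- do.call(rbind, lapply(names(lens), function(ch) {
    n <- n_per[[ch]]
    if (n == 0L)
      return(data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        variant_class = character(0),
                        stringsAsFactors = FALSE))
    pos <- sort(sample.int(lens[[ch]], n))
    is_snp <- stats::runif(n) < config$snp_fraction
    ref_base <- sample(bases, n, replace = TRUE)
    alt_base <- vapply(ref_base, function(b)
      sample(setdiff(bases, b), 1L), "")
    ref <- ref_base
    alt <- alt_base
    indel <- which(!is_snp)
    if (length(indel) > 0L) {
      ins <- stats::runif(length(indel)) < 0.5
      extra <- vapply(sample(1:3, length(indel), replace = TRUE),
                      function(k) paste(sample(bases, k, replace = TRUE),
                                        collapse = ""), "")
      # insertion: ALT gains bases; deletion: REF gains bases
      alt[indel[ins]] <- paste0(ref_base[indel[ins]], extra[ins])
      ref[indel[!ins]] <- paste0(ref_base[indel[!ins]], extra[!ins])
      alt[indel[!ins]] <- ref_base[indel[!ins]]
    }
    data.frame(chrom = ch, pos = as.integer(pos), ref = ref, alt = alt,
               variant_class = ifelse(is_snp, "SNP", "INDEL"),
               stringsAsFactors = FALSE)
  }))
  rownames(markers) <- NULL
  map <- list(chrom_lengths = lens, genetic_lengths = config$genetic_lengths,
              markers = markers)
  list(map = map,
       donor = list(hap1 = .pure_haplotype(lens, "D"),
                    hap2 = .pure_haplotype(lens, "D")),
       recurrent = list(hap1 = .pure_haplotype(lens, "R"),
                        hap2 = .pure_haplotype(lens, "R")))
}

# Origin of a haplotype at given positions on one chromosome.
.origin_at <- function(hap_chrom, pos) {
  hap_chrom$origin[findInterval(pos - 1e-9, c(0, hap_chrom$bp),
                                rightmost.closed = FALSE)]
}

# Recombine two single-chromosome haplotypes at crossover positions,
# starting from hap A or B, and compress equal-origin neighbours.
.recombine_chrom <- function(hapA, hapB, co, start_first) {
  len <- hapA$bp[length(hapA$bp)]
  if (length(co) == 0L) return(if (start_first) hapA else hapB)
  ends <- sort(unique(c(co, hapA$bp, hapB$bp, len)))
  ends <- ends[ends > 0 & ends <= len]
  mids <- (c(0, ends[-length(ends)]) + ends) / 2
  use_a <- (findInterval(mids, sort(co)) %% 2L == 0L) == start_first
  origin <- ifelse(use_a, .origin_at(hapA, mids), .origin_at(hapB, mids))
  keep <- c(origin[-length(origin)] != origin[-1L], TRUE)
  list(bp = ends[keep], origin = origin[keep])
}

#' One meiosis: produce a gamete haplotype
#'
#' Crossover counts per chromosome are Poisson with mean equal to the
#' genetic length in Morgans (Haldane's no-interference model); crossover
#' positions are uniform on the physical map (uniform cM/Mb); the starting
#' chromatid is chosen with probability 1/2 per chromosome.
#'
#' @param individual a diploid (list with `hap1`, `hap2`).
#' @param map marker map (for chromosome and genetic lengths).
#' @return a gamete haplotype (per-chromosome segment lists).
#' @export
meiosis <- function(individual, map) {
  chroms <- names(map$chrom_lengths)
  gam <- lapply(chroms, function(ch) {
    gl <- map$genetic_lengths[[ch]]
    n_co <- stats::rpois(1L, gl / 100)
    co <- if (n_co > 0L) stats::runif(n_co, 0, map$chrom_lengths[[ch]])
          else numeric(0)
    .recombine_chrom(individual$hap1[[ch]], individual$hap2[[ch]],
                     co, stats::runif(1L) < 0.5)
  })
  names(gam) <- chroms
  gam
}

.gamete_origin_at_target <- function(gamete, scheme) {
  .origin_at(gamete[[scheme$target_chrom]], scheme$target_pos)
}

.draw_gamete <- function(parent, map, scheme, want_donor_at_target) {
  if (!want_donor_at_target) return(meiosis(parent, map))
  for (i in seq_len(scheme$max_attempts)) {
    g <- meiosis(parent, map)
    if (.gamete_origin_at_target(g, scheme) == "D") return(g)
  }
  stop("selection rule unsatisfiable: no gamete carried the donor allele ",
       "at the target locus after ", scheme$max_attempts, " attempts")
}

#' Run a backcross-and-selfing breeding scheme
#'
#' Advances an F1 through `n_backcross` backcrosses to the recurrent parent
#' and `n_self` self-fertilizations.  With foreground selection on, every
#' backcross progeny is required to be heterozygous at the target locus
#' (gametes redrawn until the donor allele is transmitted) and the first
#' selfing product must be donor-homozygous at the target; later selfings
#' preserve it automatically.
#'
#' @param scheme a [scheme_spec()].
#' @param parents output of [make_parental_genomes()].
#' @param seed optional integer seed.
#' @return a simulated individual: list with haplotypes `hap1`, `hap2` and
#'   a `pedigree` data.frame logging each generation.
#' @export
run_scheme <- function(scheme = scheme_spec(), parents, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- parents$map
  if (!scheme$target_chrom %in% names(map$chrom_lengths))
    stop("target locus chromosome not in simulated genome: ",
         scheme$target_chrom)
  ped <- list()
  cur <- list(hap1 = meiosis(parents$donor, map),
              hap2 = meiosis(parents$recurrent, map))
  ped[[1L]] <- data.frame(generation = "F1", selected = "none")
  for (b in seq_len(scheme$n_backcross)) {
    g <- .draw_gamete(cur, map, scheme, scheme$select_target)
    cur <- list(hap1 = g, hap2 = meiosis(parents$recurrent, map))
    ped[[length(ped) + 1L]] <-
      data.frame(generation = sprintf("BC%dF1", b),
                 selected = if (scheme$select_target) "HET_AT_TARGET"
                            else "none")
  }
  for (s in seq_len(scheme$n_self)) {
    want <- scheme$select_target && s == 1L
    g1 <- .draw_gamete(cur, map, scheme, want)
    g2 <- .draw_gamete(cur, map, scheme, want)
    cur <- list(hap1 = g1, hap2 = g2)
    ped[[length(ped) + 1L]] <-
      data.frame(generation = sprintf("BC%dF%d", scheme$n_backcross, s + 1L),
                 selected = if (want) "DONOR_HOM_AT_TARGET" else "none")
  }
  cur$pedigree <- do.call(rbind, ped)
  cur
}

#' True recurrent-genome recovery of a simulated individual
#'
#' Recurrent-allele dosage averaged over the marker map, computed from the
#' noiseless parent-of-origin haplotypes — the oracle against which the
#' pipeline estimate is checked.
#'
#' @param individual a simulated individual.
#' @param map the marker map it was simulated on.
#' @return fraction in `[0, 1]`.
#' @export
true_recovery <- function(individual, map) {
  mk <- map$markers
  dosage <- 0
  for (ch in unique(mk$chrom)) {
    pos <- mk$pos[mk$chrom == ch]
    o1 <- .origin_at(individual$hap1[[ch]], pos)
    o2 <- .origin_at(individual$hap2[[ch]], pos)
    dosage <- dosage + sum(o1 == "R") + sum(o2 == "R")
  }
  dosage / (2 * nrow(mk))
}

#' True parent-of-origin segments of a simulated individual
#'
#' @param individual a simulated individual.
#' @param map the marker map (for chromosome names).
#' @param origin which parent, `"D"` or `"R"`.
#' @param zygosity `"hom"` for segments where both haplotypes carry
#'   `origin`, `"any"` for segments where at least one does.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open).
#' @export
donor_segments <- function(individual, map, origin = "D",
                           zygosity = c("hom", "any")) {
  zygosity <- match.arg(zygosity)
  out <- lapply(names(map$chrom_lengths), function(ch) {
    h1 <- individual$hap1[[ch]]; h2 <- individual$hap2[[ch]]
    ends <- sort(unique(c(h1$bp, h2$bp)))
    starts <- c(0, ends[-length(ends)])
    mids <- (starts + ends) / 2
    o1 <- .origin_at(h1, mids); o2 <- .origin_at(h2, mids)
    hit <- if (zygosity == "hom") o1 == origin & o2 == origin
           else o1 == origin | o2 == origin
    if (!any(hit)) return(NULL)
    runs <- rle(hit)
    stops <- cumsum(runs$lengths)
    firsts <- stops - runs$lengths + 1L
    data.frame(chrom = ch, start = starts[firsts[runs$values]],
               end = ends[stops[runs$values]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Genotype a simulated individual at the marker map
#'
#' Builds the three-sample site table (donor `1/1`, recurrent `0/0`,
#' progeny from its parent-of-origin haplotypes) and injects sequencing
#' noise per the noise model.  This is the in-memory form of the VCF
#' [emit_vcf()] serializes; reading the emitted VCF back with
#' [read_multisample_variants()] reproduces this table.
#'
#' @param individual a simulated individual.
#' @param map the marker map.
#' @param noise a [noise_model()].
#' @param seed optional integer seed.
#' @return a site table; attribute `noise_log` is a data.frame of injected
#'   events (`row`, `event`).
#' @export
genotype_markers <- function(individual, map, noise = noise_model(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mk <- map$markers
  n <- nrow(mk)
  dosage <- integer(n)   # donor-allele dosage per marker
  for (ch in unique(mk$chrom)) {
    i <- which(mk$chrom == ch)
    o1 <- .origin_at(individual$hap1[[ch]], mk$pos[i])
    o2 <- .origin_at(individual$hap2[[ch]], mk$pos[i])
    dosage[i] <- (o1 == "D") + (o2 == "D")
  }
  progeny_gt <- c("0/0", "0/1", "1/1")[dosage + 1L]

  draw_dp <- function() {
    if (noise$depth_dist == "poisson") stats::rpois(n, noise$mean_depth)
    else rep.int(as.integer(round(noise$mean_depth)), n)
  }
  dp_d <- draw_dp(); dp_r <- draw_dp(); dp_p <- draw_dp()
  qual <- rep(60, n)

  events <- list()
  log_event <- function(rows, event) {
    if (length(rows) > 0L)
      events[[length(events) + 1L]] <<-
        data.frame(row = rows, event = event, stringsAsFactors = FALSE)
  }

  # genotype errors first (they alter the truth the pipeline sees)
  if (noise$genotype_error_rate > 0) {
    hit <- which(stats::runif(n) < noise$genotype_error_rate)
    if (length(hit) > 0L) {
      progeny_gt[hit] <- vapply(progeny_gt[hit], function(g)
        sample(setdiff(c("0/0", "0/1", "1/1"), g), 1L), "")
      log_event(hit, "genotype_error")
    }
  }

  het <- progeny_gt == "0/1"
  alt_p <- integer(n)
  alt_p[progeny_gt == "1/1"] <- dp_p[progeny_gt == "1/1"]
  if (noise$het_ab == "binomial") {
    alt_p[het] <- stats::rbinom(sum(het), dp_p[het], 0.5)
  } else {
    alt_p[het] <- dp_p[het] %/% 2L
  }

  # forced allele-balance skew at a sample of het sites
  if (noise$ab_skew_rate > 0) {
    cand <- which(het)
    hit <- cand[stats::runif(length(cand)) < noise$ab_skew_rate]
    if (length(hit) > 0L) {
      dp_p[hit] <- pmax(dp_p[hit], 10L)  # enough reads to express the skew
      alt_p[hit] <- as.integer(round(dp_p[hit] * noise$ab_skew_value))
      log_event(hit, "ab_skew")
    }
  }

  if (noise$low_depth_rate > 0) {
    hit <- which(stats::runif(n) < noise$low_depth_rate)
    if (length(hit) > 0L) {
      who <- sample(3L, length(hit), replace = TRUE)
      low <- sample(0:5, length(hit), replace = TRUE)
      dp_d[hit[who == 1L]] <- low[who == 1L]
      dp_r[hit[who == 2L]] <- low[who == 2L]
      dp_p[hit[who == 3L]] <- low[who == 3L]
      alt_p[hit[who == 3L] [progeny_gt[hit[who == 3L]] == "1/1"]] <-
        dp_p[hit[who == 3L] [progeny_gt[hit[who == 3L]] == "1/1"]]
      i3 <- hit[who == 3L]
      alt_p[i3[progeny_gt[i3] == "0/1"]] <- dp_p[i3[progeny_gt[i3] == "0/1"]] %/% 2L
      log_event(hit, "low_depth")
    }
  }

  if (noise$low_qual_rate > 0) {
    hit <- which(stats::runif(n) < noise$low_qual_rate)
    qual[hit] <- round(stats::runif(length(hit), 0, 19.9), 1)
    log_event(hit, "low_qual")
  }

  alt <- mk$alt
  if (noise$multiallelic_rate > 0) {
    hit <- which(stats::runif(n) < noise$multiallelic_rate)
    if (length(hit) > 0L) {
      bases <- c("A", "C", "G", "T")
      third <- vapply(hit, function(i)
        sample(setdiff(bases, c(substr(mk$ref[i], 1L, 1L), alt[i])), 1L), "")
      alt[hit] <- paste(alt[hit], third, sep = ",")
      log_event(hit, "multiallelic")
    }
  }

  if (noise$missing_rate > 0) {
    hit <- which(stats::runif(n) < noise$missing_rate)
    progeny_gt[hit] <- "./."
    log_event(hit, "missing")
  }

  ad <- function(dp, altn) paste0(dp - altn, ",", altn)
  df <- data.frame(
    chrom = mk$chrom, pos = mk$pos, ref = mk$ref, alt = alt,
    qual = qual,
    variant_class = .variant_class(mk$ref, alt),
    donor_gt = rep.int("1/1", n), recurrent_gt = rep.int("0/0", n),
    progeny_gt = progeny_gt,
    donor_dp = as.integer(dp_d), recurrent_dp = as.integer(dp_r),
    progeny_dp = as.integer(dp_p),
    donor_ad = ad(dp_d, dp_d), recurrent_ad = ad(dp_r, 0L),
    progeny_ad = ad(dp_p, alt_p),
    stringsAsFactors = FALSE
  )
  out <- variant_sites(df)
  attr(out, "noise_log") <- if (length(events) > 0L) do.call(rbind, events)
    else data.frame(row = integer(0), event = character(0))
  out
}

#' Write a site table as a three-sample VCF
#'
#' Emits a VCF v4.2 text file with samples `donor`, `recurrent`, `progeny`
#' (FORMAT `GT:AD:DP`), contig header lines from the chromosome lengths,
#' and the provenance recorded in header comments.
#'
#' @param sites a site table.
#' @param file output path (plain text).
#' @param chrom_lengths named vector for the contig header lines.
#' @param source_info optional character string recorded in the header
#'   (e.g. simulation seed and parameters).
#' @return the path, invisibly.
#' @export
emit_vcf <- function(sites, file, chrom_lengths = NULL, source_info = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(source_info)) paste0("##source=", source_info),
    if (!is.null(chrom_lengths))
      sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
              as.integer(chrom_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "donor", "recurrent", "progeny", sep = "\t")
  )
  fmt <- function(gt, ad, dp) paste(gt, ad, dp, sep = ":")
  body <- if (nrow(sites) > 0L) {
    paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt,
          format(sites$qual, trim = TRUE), "PASS", ".", "GT:AD:DP",
          fmt(sites$donor_gt, sites$donor_ad, sites$donor_dp),
          fmt(sites$recurrent_gt, sites$recurrent_ad, sites$recurrent_dp),
          fmt(sites$progeny_gt, sites$progeny_ad, sites$progeny_dp),
          sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' Simulated recovery study
#'
#' Repeats the breeding scheme `n` times on one simulated parental genome
#' and runs the classification pipeline (site filters, informative-site
#' selection, parental-origin classification, recovery rate) on the
#' noiseless genotypes of each replicate.
#'
#' @param n number of simulated individuals.
#' @param config a [sim_config()].
#' @param scheme a [scheme_spec()].
#' @param seed integer seed governing the whole study.
#' @return data.frame with one row per replicate: `estimated` (pipeline
#'   recovery) and `true` (haplotype-level recovery).
#' @export
simulate_recovery_study <- function(n, config = sim_config(),
                                    scheme = scheme_spec(), seed = 1L) {
  set.seed(seed)
  parents <- make_parental_genomes(config)
  noiseless <- noise_model(preset = "none")
  est <- numeric(n); tru <- numeric(n)
  for (i in seq_len(n)) {
    ind <- run_scheme(scheme, parents)
    sites <- genotype_markers(ind, parents$map, noise = noiseless)
    flt <- apply_site_filters(sites)
    cls <- classify_sites(select_informative_sites(flt$sites))
    est[i] <- recovery_rate(yy = sum(cls$class == "RECURRENT_HOM"),
                            yk = sum(cls$class == "HET"),
                            kk = sum(cls$class == "DONOR_HOM"))
    tru[i] <- true_recovery(ind, parents$map)
  }
  data.frame(estimated = est, true = tru)
}
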