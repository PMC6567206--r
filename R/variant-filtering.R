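# Multi-sample VCF ingestion and the site-level marker filters.
#
# The central data structure of the package is the "site table": a plain
# data.frame with one row per variant record and fixed columns for the three
# breeding roles (donor parent, recurrent parent, progeny).  All downstream
# modules (classification, profiling, block segmentation, annotation) consume
# this table, whether it came from a real VCF or from the simulator.

.MABC_ROLES <- c("donor", "recurrent", "progeny")

.SITE_COLS <- c(
  "chrom", "pos", "ref", "alt", "qual", "variant_class",
  "donor_gt", "recurrent_gt", "progeny_gt",
  "donor_dp", "recurrent_dp", "progeny_dp",
  "donor_ad", "recurrent_ad", "progeny_ad"
)

# Filters are applied, and removals attributed, in this fixed order.
.FILTER_ORDER <- c("missing", "multiallelic", "parental_het",
                   "low_depth", "low_quality", "progeny_af")

#' Construct or validate a site table
#'
#' A site table is a `data.frame` with one row per biallelic (or
#' yet-unfiltered multiallelic) variant and per-role genotype (`GT`), total
#' depth (`DP`) and allele-depth (`AD`, comma-separated string) columns for
#' the roles `donor`, `recurrent` and `progeny`.  Positions are 1-based VCF
#' coordinates; `alt` holds comma-separated alternate alleles until
#' multiallelic records are filtered out.
#'
#' @param df data.frame carrying at least the site-table columns.
#' @return `df` with class `mabc_sites` prepended, columns ordered.
#' @export
variant_sites <- function(df) {
  missing_cols <- setdiff(.SITE_COLS, names(df))
  if (length(missing_cols) > 0L)
    stop("site table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(df) > 0L && any(df$pos < 1L, na.rm = TRUE))
    stop("site positions must be >= 1 (1-based VCF coordinates)")
  df <- df[, c(.SITE_COLS, setdiff(names(df), .SITE_COLS)), drop = FALSE]
  class(df) <- unique(c("mabc_sites", class(df)))
  df
}

#' Read a three-sample VCF into a site table
#'
#' Reads a multi-sample VCF (plain or bgzip) and extracts the three samples
#' named in `role_map` into the fixed-role site-table layout.  Records are
#' passed through unfiltered: multiallelic sites, missing calls and records
#' on contigs absent from the header are all retained for the downstream
#' filters to count.
#'
#' @param file path to a VCF (v4.x) with per-sample GT, AD and DP fields.
#' @param role_map named character vector mapping roles to VCF sample names,
#'   e.g. `c(donor = "Kaijin", recurrent = "WT", progeny = "BC3F2")`.
#'   Names must be `donor`, `recurrent`, `progeny`.
#' @return a site table (see [variant_sites()]).
#' @export
read_multisample_variants <- function(file, role_map) {
  if (!all(.MABC_ROLES %in% names(role_map)))
    stop("role_map must name all of: ", paste(.MABC_ROLES, collapse = ", "))
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  samples <- colnames(v@gt)[-1L]
  absent <- setdiff(unname(role_map[.MABC_ROLES]), samples)
  if (length(absent) > 0L)
    stop("samples not in VCF header: ", paste(absent, collapse = ", "))

  fix <- v@fix
  n <- nrow(fix)
  grab <- function(field, fun = identity) {
    if (n == 0L) return(fun(character(0)))
    m <- vcfR::extract.gt(v, element = field, as.numeric = FALSE)
    fun(m[, unname(role_map[.MABC_ROLES]), drop = FALSE])
  }
  gt <- grab("GT")
  dp <- grab("DP", function(m) { storage.mode(m) <- "integer"; m })
  ad <- grab("AD")

  col <- function(m, j) if (n == 0L) m else m[, j]
  df <- data.frame(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    variant_class = rep(NA_character_, n),
    donor_gt = col(gt, 1L), recurrent_gt = col(gt, 2L), progeny_gt = col(gt, 3L),
    donor_dp = col(dp, 1L), recurrent_dp = col(dp, 2L), progeny_dp = col(dp, 3L),
    donor_ad = col(ad, 1L), recurrent_ad = col(ad, 2L), progeny_ad = col(ad, 3L),
    stringsAsFactors = FALSE
  )
  df$variant_class <- .variant_class(df$ref, df$alt)
  variant_sites(df)
}

# SNP iff ref and the single alt are both 1 nt; NA while multiallelic.
.variant_class <- function(ref, alt) {
  multi <- grepl(",", alt, fixed = TRUE) | is.na(alt) | alt == "."
  ifelse(multi, NA_character_,
         ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "INDEL"))
}

# Parse diploid GT strings into two integer allele columns.  Only the unique
# strings are split, so the cost is independent of table length for the
# handful of GT values real data contains.  Unphased and phased separators
# are treated alike; haploid or malformed calls come back as missing.
.gt_alleles <- function(gt) {
  u <- unique(gt)
  parts <- strsplit(sub("|", "/", u, fixed = TRUE), "/", fixed = TRUE)
  ua <- suppressWarnings(vapply(parts, function(p) {
    if (length(p) != 2L) c(NA_integer_, NA_integer_)
    else as.integer(p)
  }, integer(2)))
  i <- match(gt, u)
  list(a1 = ua[1L, i], a2 = ua[2L, i])
}

.gt_is_missing <- function(gt) {
  al <- .gt_alleles(gt)
  is.na(al$a1) | is.na(al$a2)
}

.gt_is_het <- function(gt) {
  al <- .gt_alleles(gt)
  !is.na(al$a1) & !is.na(al$a2) & al$a1 != al$a2
}

#' Alternate-allele balance of a sample call
#'
#' Fraction of reads supporting the alternate allele, computed from the AD
#' field as `alt / (ref + alt)` using the first two AD entries.  Returns
#' `NA` (the undefined value) when AD is absent or when no reads support
#' either allele.
#'
#' @param ad character vector of comma-separated allele depths (`"13,7"`),
#'   or a two-column numeric matrix of (ref, alt) read counts.
#' @return numeric vector of fractions in `[0, 1]`, `NA` where undefined.
#' @examples
#' allele_balance(c("10,10", "13,7", "0,0"))  # 0.50 0.35 NA
#' @export
allele_balance <- function(ad) {
  if (is.matrix(ad)) {
    ref <- as.numeric(ad[, 1L]); alt <- as.numeric(ad[, 2L])
  } else {
    u <- unique(as.character(ad))
    parts <- strsplit(u, ",", fixed = TRUE)
    uref <- suppressWarnings(vapply(parts, function(p)
      if (length(p) >= 1L) as.numeric(p[1L]) else NA_real_, 0))
    ualt <- suppressWarnings(vapply(parts, function(p)
      if (length(p) >= 2L) as.numeric(p[2L]) else NA_real_, 0))
    i <- match(as.character(ad), u)
    ref <- uref[i]; alt <- ualt[i]
  }
  tot <- ref + alt
  ifelse(is.na(tot) | tot == 0, NA_real_, alt / tot)
}

#' Site-filter configuration
#'
#' Thresholds for [apply_site_filters()].  Defaults follow a conservative
#' short-read multi-sample calling workflow: drop sites with any missing
#' call, multiallelic records, heterozygous parents, per-sample depth below
#' 6 reads, site quality below 20, and progeny heterozygotes whose allele
#' balance falls outside the closed 40--60% band.
#'
#' @param min_depth minimum per-sample read depth (every role must satisfy).
#' @param min_quality minimum phred-scaled site QUAL.
#' @param het_af_band closed interval of acceptable alternate-allele
#'   fraction for heterozygous progeny calls.
#' @param drop_missing,drop_multiallelic,drop_parental_het logical switches
#'   for the corresponding filters.
#' @return list of class `mabc_filter_config`.
#' @export
filter_config <- function(min_depth = 6, min_quality = 20,
                          het_af_band = c(0.40, 0.60),
                          drop_missing = TRUE, drop_multiallelic = TRUE,
                          drop_parental_het = TRUE) {
  stopifnot(min_depth >= 0, length(het_af_band) == 2L,
            het_af_band[1] >= 0, het_af_band[1] <= het_af_band[2],
            het_af_band[2] <= 1)
  structure(list(min_depth = min_depth, min_quality = min_quality,
                 het_af_band = het_af_band, drop_missing = drop_missing,
                 drop_multiallelic = drop_multiallelic,
                 drop_parental_het = drop_parental_het),
            class = "mabc_filter_config")
}

#' Apply site-level marker filters
#'
#' Applies, in a fixed order, the filters that reduce a raw multi-sample
#' call set to reliable markers: missing data in any sample; multiallelic
#' records (dropped whole, never decomposed); heterozygous calls in either
#' parent; per-sample depth below `min_depth`; site quality below
#' `min_quality`; and, for heterozygous progeny calls, alternate-allele
#' balance outside `het_af_band` (endpoints included).  Each removed site
#' is attributed to the first filter it fails, so the tally is deterministic
#' and sums to the input count.
#'
#' Allele balance is computed from AD; when a heterozygous progeny call has
#' no AD the balance filter is skipped for that site and the skip counted
#' (`n_af_skipped`).
#'
#' @param sites a site table.
#' @param config a [filter_config()].
#' @return list with elements `sites` (passing subset, `variant_class`
#'   filled in), `tally` (data.frame of per-filter removal counts),
#'   `n_input`, `n_passing`, `n_af_skipped`.
#' @export
apply_site_filters <- function(sites, config = filter_config()) {
  n <- nrow(sites)
  fail <- matrix(FALSE, nrow = n, ncol = length(.FILTER_ORDER),
                 dimnames = list(NULL, .FILTER_ORDER))
  if (n > 0L) {
    if (config$drop_missing)
      fail[, "missing"] <- .gt_is_missing(sites$donor_gt) |
        .gt_is_missing(sites$recurrent_gt) | .gt_is_missing(sites$progeny_gt)
    if (config$drop_multiallelic)
      fail[, "multiallelic"] <- grepl(",", sites$alt, fixed = TRUE) |
        is.na(sites$alt) | sites$alt == "."
    if (config$drop_parental_het)
      fail[, "parental_het"] <- .gt_is_het(sites$donor_gt) |
        .gt_is_het(sites$recurrent_gt)
    dp_bad <- function(dp) is.na(dp) | dp < config$min_depth
    fail[, "low_depth"] <- dp_bad(sites$donor_dp) |
      dp_bad(sites$recurrent_dp) | dp_bad(sites$progeny_dp)
    fail[, "low_quality"] <- is.na(sites$qual) | sites$qual < config$min_quality
  }

  n_af_skipped <- 0L
  if (n > 0L) {
    het <- .gt_is_het(sites$progeny_gt)
    has_ad <- !is.na(sites$progeny_ad) & sites$progeny_ad != "." &
      sites$progeny_ad != ""
    n_af_skipped <- sum(het & !has_ad)
    idx <- which(het & has_ad)
    if (length(idx) > 0L) {
      ab <- allele_balance(sites$progeny_ad[idx])
      band <- config$het_af_band
      out_of_band <- is.na(ab) | ab < band[1] | ab > band[2]
      fail[idx, "progeny_af"] <- out_of_band
    }
  }

  if (n > 0L) {
    first_fail <- max.col(fail, ties.method = "first")
    first_fail[!fail[cbind(seq_len(n), first_fail)]] <- NA_integer_
  } else {
    first_fail <- integer(0)
  }
  removed <- tabulate(first_fail, nbins = length(.FILTER_ORDER))
  keep <- is.na(first_fail)

  passing <- sites[keep, , drop = FALSE]
  rownames(passing) <- NULL
  passing$variant_class <- .variant_class(passing$ref, passing$alt)

  list(
    sites = variant_sites(passing),
    tally = data.frame(filter = .FILTER_ORDER, removed = removed,
                       stringsAsFactors = FALSE),
    n_input = n,
    n_passing = sum(keep),
    n_af_skipped = n_af_skipped
  )
}

#' Keep only parentally informative sites
#'
#' An informative marker is a site where the two parents are homozygous for
#' different alleles, so the progeny genotype decodes parental origin.
#' Sites where the parents share an allele are dropped and counted in the
#' `n_uninformative` attribute.  The retained table gains integer columns
#' `donor_allele` and `recurrent_allele` (allele indices into REF/ALT).
#'
#' @param sites a filtered site table (parents homozygous).
#' @return site table of informative markers, with attribute
#'   `n_uninformative`.
#' @export
select_informative_sites <- function(sites) {
  d <- .gt_alleles(sites$donor_gt)
  r <- .gt_alleles(sites$recurrent_gt)
  d_hom <- !is.na(d$a1) & !is.na(d$a2) & d$a1 == d$a2
  r_hom <- !is.na(r$a1) & !is.na(r$a2) & r$a1 == r$a2
  keep <- d_hom & r_hom & d$a1 != r$a1
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$donor_allele <- d$a1[keep]
  out$recurrent_allele <- r$a1[keep]
  out <- variant_sites(out)
  attr(out, "n_uninformative") <- sum(!keep)
  out
}
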