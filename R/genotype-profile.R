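# Parent-of-origin classification of progeny genotypes and the
# recurrent-parent genome recovery rate.

.GENOTYPE_CLASSES <- c("RECURRENT_HOM", "HET", "DONOR_HOM", "NON_PARENTAL")

#' Classify informative sites by parental origin
#'
#' At an informative marker both parents are homozygous for different
#' alleles, so a progeny call decodes to: homozygous for the recurrent
#' allele (`RECURRENT_HOM`), homozygous for the donor allele (`DONOR_HOM`),
#' one allele from each parent (`HET`), or carrying an allele matching
#' neither parent (`NON_PARENTAL`).
#'
#' @param sites an informative site table from
#'   [select_informative_sites()] (must carry `donor_allele` and
#'   `recurrent_allele`; they are recomputed from the parental genotypes if
#'   absent).
#' @return the site table with a `class` factor column added (levels
#'   `RECURRENT_HOM`, `HET`, `DONOR_HOM`, `NON_PARENTAL`).
#' @export
classify_sites <- function(sites) {
  if (is.null(sites$donor_allele) || is.null(sites$recurrent_allele)) {
    sites <- select_informative_sites(sites)
    if (attr(sites, "n_uninformative") > 0L)
      stop("classify_sites() requires informative sites ",
           "(parents homozygous for different alleles)")
  }
  p <- .gt_alleles(sites$progeny_gt)
  if (nrow(sites) > 0L && any(is.na(p$a1) | is.na(p$a2)))
    stop("classify_sites(): missing progeny genotypes; filter first")
  d <- sites$donor_allele
  r <- sites$recurrent_allele
  from_parents <- (p$a1 == d | p$a1 == r) & (p$a2 == d | p$a2 == r)
  cls <- ifelse(!from_parents, "NON_PARENTAL",
         ifelse(p$a1 == r & p$a2 == r, "RECURRENT_HOM",
         ifelse(p$a1 == d & p$a2 == d, "DONOR_HOM", "HET")))
  sites$class <- factor(cls, levels = .GENOTYPE_CLASSES)
  sites
}

#' Recurrent-parent genome recovery rate
#'
#' The recurrent-parent allele frequency among classified markers,
#' `(YY + YK/2) / (YY + YK + KK)`, where `YY`, `YK` and `KK` are the counts
#' of recurrent-homozygous, heterozygous and donor-homozygous markers.
#'
#' @param yy count of recurrent-parent homozygous markers.
#' @param yk count of heterozygous markers.
#' @param kk count of donor-parent homozygous markers.
#' @return recovery rate as a fraction in `[0, 1]`.
#' @examples
#' recovery_rate(106288, 9009, 3157)  # 0.9353...
#' @export
recovery_rate <- function(yy, yk, kk) {
  stopifnot(yy >= 0, yk >= 0, kk >= 0)
  total <- yy + yk + kk
  if (total == 0) stop("recovery_rate() undefined for all-zero counts")
  (yy + yk / 2) / total
}

# Round half away from zero to `digits` decimals (the convention of printed
# percentage tables; R's round() would round half to even).
.round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Genotype profile summary
#'
#' Cross-tabulates classified markers by genotype class and variant class
#' (SNP vs indel), computes per-class genome percentages (rounded half-up to
#' one decimal, on the classified total excluding non-parental sites) and
#' the genome recovery rate.
#'
#' @param x either a classified site table (from [classify_sites()]) or a
#'   3x2 count matrix with rownames `RECURRENT_HOM`, `HET`, `DONOR_HOM` and
#'   colnames `SNP`, `INDEL`.
#' @param non_parental count of non-parental sites (only used for matrix
#'   input; taken from the table otherwise).
#' @return list of class `mabc_profile` with elements `counts` (3x2
#'   matrix), `totals` (per-class totals), `percent` (per-class genome
#'   percentages), `n_classified`, `n_non_parental`, `recovery_rate`.
#' @export
profile_summary <- function(x, non_parental = 0L) {
  if (is.data.frame(x)) {
    cls <- factor(as.character(x$class),
                  levels = c("RECURRENT_HOM", "HET", "DONOR_HOM"))
    vc <- factor(x$variant_class, levels = c("SNP", "INDEL"))
    counts <- table(cls, vc, useNA = "no")
    counts <- matrix(as.integer(counts), nrow = 3L,
                     dimnames = list(c("RECURRENT_HOM", "HET", "DONOR_HOM"),
                                     c("SNP", "INDEL")))
    non_parental <- sum(x$class == "NON_PARENTAL", na.rm = TRUE)
  } else {
    counts <- as.matrix(x)
    if (!all(c("RECURRENT_HOM", "HET", "DONOR_HOM") %in% rownames(counts)) ||
        !all(c("SNP", "INDEL") %in% colnames(counts)))
      stop("count matrix needs rows RECURRENT_HOM/HET/DONOR_HOM ",
           "and columns SNP/INDEL")
    counts <- counts[c("RECURRENT_HOM", "HET", "DONOR_HOM"),
                     c("SNP", "INDEL"), drop = FALSE]
  }
  totals <- rowSums(counts)
  n_classified <- sum(totals)
  if (n_classified == 0) stop("no classified sites to summarize")
  percent <- .round_half_up(100 * totals / n_classified, 1L)
  rate <- recovery_rate(yy = totals[["RECURRENT_HOM"]],
                        yk = totals[["HET"]],
                        kk = totals[["DONOR_HOM"]])
  structure(list(counts = counts, totals = totals, percent = percent,
                 n_classified = n_classified,
                 n_non_parental = as.integer(non_parental),
                 recovery_rate = rate),
            class = "mabc_profile")
}

#' @export
print.mabc_profile <- function(x, ...) {
  cat(render_summary(x), sep = "\n")
  invisible(x)
}

#' Per-chromosome recovery rates
#'
#' @param sites a classified site table.
#' @return data.frame with one row per chromosome: counts `yy`, `yk`, `kk`
#'   and the chromosome-wise `recovery` fraction.
#' @export
recovery_by_chromosome <- function(sites) {
  keep <- sites$class != "NON_PARENTAL"
  s <- sites[keep, , drop = FALSE]
  chroms <- unique(s$chrom)
  out <- do.call(rbind, lapply(chroms, function(ch) {
    cl <- s$class[s$chrom == ch]
    yy <- sum(cl == "RECURRENT_HOM"); yk <- sum(cl == "HET")
    kk <- sum(cl == "DONOR_HOM")
    data.frame(chrom = ch, yy = yy, yk = yk, kk = kk,
               recovery = recovery_rate(yy, yk, kk),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Theoretical recovery under backcrossing and selfing
#'
#' No-selection expectations for a BCnFm individual: after `n_backcross`
#' backcrosses to the recurrent parent the expected recurrent-allele
#' fraction is `1 - 2^-(n_backcross + 1)`; self-fertilization does not
#' change allele frequencies but halves the expected heterozygous fraction
#' each round, giving `2^-(n_backcross + n_self)` (the F1 is heterozygous at
#' every informative marker).
#'
#' @param n_backcross number of backcross generations (>= 0).
#' @param n_self number of self-fertilization rounds after the last
#'   backcross (>= 0).
#' @return list with `recurrent_allele_fraction` and `het_fraction`.
#' @examples
#' expected_recovery(3, 1)  # 0.9375, 0.0625
#' @export
expected_recovery <- function(n_backcross, n_self) {
  if (n_backcross < 0 || n_self < 0)
    stop("generation counts must be non-negative")
  list(
    recurrent_allele_fraction = 1 - 2^-(n_backcross + 1),
    het_fraction = 2^-(n_backcross + n_self)
  )
}
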