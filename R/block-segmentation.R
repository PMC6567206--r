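# Graphical genotyping: window densities and contiguous genotype blocks
# along chromosomes.
#
# Site positions are 1-based (VCF convention) everywhere inside the
# package; windows, blocks and BED output use 0-based half-open intervals,
# converted only at this module's boundary (position p occupies the 0-based
# coordinate p - 1).

#' Per-window marker densities by genotype class
#'
#' Counts classified markers in fixed-size windows along each chromosome
#' and reports the dominant class per window (`NONE` on ties or empty
#' windows, never an arbitrary class order).  With `step < window_size` the
#' windows slide and overlap; the default is a non-overlapping tiling.
#'
#' @param sites a classified site table (sorted internally).
#' @param chrom_lengths named numeric vector of chromosome lengths (nt),
#'   covering every chromosome present in `sites`.
#' @param window_size window width in nt.
#' @param step distance between window starts in nt.
#' @return data.frame: `chrom`, `start`, `end` (0-based half-open; the
#'   terminal window is truncated at the chromosome end), one count column
#'   per genotype class (`n_recurrent_hom`, `n_het`, `n_donor_hom`,
#'   `n_non_parental`), and `dominant`.
#' @export
window_density <- function(sites, chrom_lengths, window_size = 10000,
                           step = window_size) {
  stopifnot(window_size >= 1, step >= 1)
  miss <- setdiff(unique(sites$chrom), names(chrom_lengths))
  if (length(miss) > 0L)
    stop("chrom_lengths missing chromosomes: ", paste(miss, collapse = ", "))
  beyond <- sites$pos > chrom_lengths[sites$chrom]
  if (any(beyond)) {
    i <- which(beyond)[1L]
    stop(sprintf("site %s:%d lies beyond the stated chromosome length (%d)",
                 sites$chrom[i], sites$pos[i],
                 as.integer(chrom_lengths[sites$chrom[i]])))
  }
  class_cols <- c(RECURRENT_HOM = "n_recurrent_hom", HET = "n_het",
                  DONOR_HOM = "n_donor_hom", NON_PARENTAL = "n_non_parental")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, max(0, len - 1), by = step)
    ends <- pmin(starts + window_size, len)
    w <- data.frame(chrom = ch, start = starts, end = ends,
                    stringsAsFactors = FALSE)
    on_ch <- sites[sites$chrom == ch, , drop = FALSE]
    for (cl in names(class_cols)) {
      pos0 <- sort(on_ch$pos[on_ch$class == cl]) - 1L
      # count of pos0 in [s, e): positions strictly below e minus below s
      w[[class_cols[[cl]]]] <-
        findInterval(ends - 0.5, pos0) - findInterval(starts - 0.5, pos0)
    }
    w
  })
  out <- do.call(rbind, out)
  cnt <- as.matrix(out[, unname(class_cols), drop = FALSE])
  top <- apply(cnt, 1L, max)
  n_top <- rowSums(cnt == top)
  dominant <- names(class_cols)[max.col(cnt, ties.method = "first")]
  dominant[top == 0 | n_top > 1L] <- "NONE"
  out$dominant <- dominant
  rownames(out) <- NULL
  out
}

#' Call contiguous genotype blocks
#'
#' Segments each chromosome into maximal runs of consecutive markers
#' sharing one genotype class, breaking a run when the gap between adjacent
#' markers exceeds `max_gap`.  Runs supported by fewer than `min_markers`
#' markers are flagged as candidate micro-blocks (the short
#' double-recombination segments seen inside larger blocks) rather than
#' merged away; flanking same-class runs separated only by flagged
#' micro-blocks are rejoined into one block, provided the joined gap does
#' not exceed `max_gap`.
#'
#' Block extent is first-to-last supporting marker, reported 0-based
#' half-open (`start = first_pos - 1`, `end = last_pos`).
#'
#' @param sites a classified site table.
#' @param min_markers minimum markers for an unflagged block.
#' @param max_gap maximum intra-block gap between adjacent markers (nt).
#' @return data.frame: `chrom`, `start`, `end`, `class`, `n_markers`,
#'   `first_pos`, `last_pos` (1-based marker positions), `flagged`.
#' @export
call_blocks <- function(sites, min_markers = 3L, max_gap = 1e6) {
  stopifnot(min_markers >= 1, max_gap >= 0)
  s <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  out <- lapply(unique(s$chrom), function(ch) {
    on_ch <- s[s$chrom == ch, , drop = FALSE]
    pos <- on_ch$pos
    cls <- as.character(on_ch$class)
    n <- length(pos)
    if (n == 0L) return(NULL)
    new_run <- c(TRUE, cls[-1L] != cls[-n] | diff(pos) > max_gap)
    run_id <- cumsum(new_run)
    runs <- data.frame(
      class = cls[new_run],
      n_markers = as.integer(tabulate(run_id)),
      first_pos = pos[new_run],
      last_pos = pos[rev(!duplicated(rev(run_id)))],
      stringsAsFactors = FALSE
    )
    runs$flagged <- runs$n_markers < min_markers

    # rejoin unflagged same-class neighbours across flagged micro-blocks
    merged <- list()
    for (i in seq_len(nrow(runs))) {
      r <- runs[i, ]
      if (r$flagged) { merged[[length(merged) + 1L]] <- r; next }
      j <- length(merged)
      prev <- NULL
      while (j >= 1L) {             # nearest earlier unflagged run
        if (!merged[[j]]$flagged) { prev <- j; break }
        j <- j - 1L
      }
      if (!is.null(prev) && merged[[prev]]$class == r$class &&
          all(vapply(merged[seq_len(length(merged)) > prev],
                     function(m) m$flagged, TRUE)) &&
          (r$first_pos - merged[[prev]]$last_pos) <= max_gap) {
        merged[[prev]]$n_markers <- merged[[prev]]$n_markers + r$n_markers
        merged[[prev]]$last_pos <- r$last_pos
      } else {
        merged[[length(merged) + 1L]] <- r
      }
    }
    res <- do.call(rbind, merged)
    data.frame(chrom = ch, start = res$first_pos - 1L, end = res$last_pos,
               class = res$class, n_markers = res$n_markers,
               first_pos = res$first_pos, last_pos = res$last_pos,
               flagged = res$flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write genotype blocks as BED6
#'
#' One BED line per block: 0-based half-open coordinates, `name` = genotype
#' class, `score` = number of supporting markers, strand `"."`.
#'
#' @param blocks a block table from [call_blocks()]; pass
#'   `blocks[!blocks$flagged, ]` to export only resolved blocks.
#' @param file output path.
#' @return the path, invisibly.
#' @export
blocks_to_bed <- function(blocks, file) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.",
                   blocks$chrom, as.integer(blocks$start),
                   as.integer(blocks$end), blocks$class,
                   as.integer(blocks$n_markers))
  writeLines(lines, file)
  invisible(file)
}

#' Read a BED6 block file back into a block table
#'
#' @param file a BED file written by [blocks_to_bed()].
#' @return data.frame with `chrom`, `start`, `end`, `class`, `n_markers`.
#' @export
read_blocks_bed <- function(file) {
  raw <- readLines(file)
  if (length(raw) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), class = character(0),
                      n_markers = integer(0), stringsAsFactors = FALSE))
  f <- strsplit(raw, "\t", fixed = TRUE)
  data.frame(
    chrom = vapply(f, `[`, "", 1L),
    start = as.integer(vapply(f, `[`, "", 2L)),
    end = as.integer(vapply(f, `[`, "", 3L)),
    class = vapply(f, `[`, "", 4L),
    n_markers = as.integer(vapply(f, `[`, "", 5L)),
    stringsAsFactors = FALSE
  )
}

#' Jaccard overlap of two interval sets
#'
#' Base-pair Jaccard index (intersection / union) between two sets of
#' genomic intervals given as data.frames with `chrom`, `start`, `end`
#' (0-based half-open).  Used to compare called blocks against true
#' simulated segments.
#'
#' @param x,y interval data.frames.
#' @return Jaccard index in `[0, 1]` (1 when both sets are empty).
#' @export
interval_jaccard <- function(x, y) {
  to_gr <- function(d) {
    if (nrow(d) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(GenomicRanges::GRanges(
      seqnames = d$chrom,
      ranges = IRanges::IRanges(start = d$start + 1L, end = d$end)))
  }
  gx <- to_gr(x); gy <- to_gr(y)
  # disjoint chromosome sets are a legitimate comparison (Jaccard 0), not
  # a seqlevel mismatch worth warning about
  inter <- suppressWarnings(sum(as.numeric(GenomicRanges::width(
    GenomicRanges::intersect(gx, gy, ignore.strand = TRUE)))))
  uni <- suppressWarnings(sum(as.numeric(GenomicRanges::width(
    GenomicRanges::union(gx, gy, ignore.strand = TRUE)))))
  if (uni == 0) return(1)
  inter / uni
}

#' Plot a simple genotype map
#'
#' Chromosome ideograms with blocks coloured by genotype class
#' (recurrent-homozygous black, heterozygous blue, donor-homozygous red,
#' following the usual graphical-genotype convention).
#'
#' @param blocks a block table from [call_blocks()].
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param ... passed to [graphics::plot()].
#' @return invisible `NULL`; draws on the active device.
#' @export
plot_genotype_map <- function(blocks, chrom_lengths, ...) {
  cols <- c(RECURRENT_HOM = "black", HET = "blue", DONOR_HOM = "red",
            NON_PARENTAL = "grey60")
  chroms <- names(chrom_lengths)
  nc <- length(chroms)
  graphics::plot(NULL, xlim = c(0, max(chrom_lengths)),
                 ylim = c(0.5, nc + 0.5), yaxt = "n",
                 xlab = "position (nt)", ylab = "", ...)
  graphics::axis(2, at = rev(seq_len(nc)), labels = chroms, las = 1)
  for (i in seq_len(nc)) {
    y <- nc - i + 1
    graphics::rect(0, y - 0.3, chrom_lengths[[i]], y + 0.3, border = "grey40")
    b <- blocks[blocks$chrom == chroms[i] & !blocks$flagged, , drop = FALSE]
    if (nrow(b) > 0L)
      graphics::rect(b$start, y - 0.3, b$end, y + 0.3,
                     col = cols[b$class], border = NA)
  }
  invisible(NULL)
}
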