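# Apparent microhomology at the rejoined sites of deletions (>= 2 bp).
#
# The microhomology length is defined as the number of distinct equal-length
# deletion placements yielding the identical derived sequence, minus one.
# It is computed as the sum of the leftward and rightward longest common
# extensions of the junction: repeatedly shifting the deleted segment by one
# base is valid exactly when the next flanking base matches across the
# junction, so the total placement ambiguity is mh_left + mh_right. The
# extension is not capped at the deletion length, so tandem-repeat deletions
# can report microhomology longer than the deletion itself.

MH_BINS <- c("0", "1", "2", "3-4", "5-9", ">=10")

#' Apparent microhomology of a deletion junction
#'
#' @param ref A [reference_genome()].
#' @param chrom Chromosome name.
#' @param del_start,del_end 1-based inclusive bounds of the deleted segment
#'   (any equivalent placement; the result is placement-invariant).
#' @return Integer microhomology length, or `NA_integer_` when the junction
#'   is undefined because an `N` base occurs in the deleted segment or
#'   within one deletion length of either flank. Deletions shorter than 2 bp
#'   or outside the chromosome are contract violations and raise an error.
#' @export
#' @examples
#' ref <- reference_genome(c(chr = "GGACGTACGTT"))
#' compute_microhomology(ref, "chr", 3, 6)  # 4
compute_microhomology <- function(ref, chrom, del_start, del_end) {
  if (del_end < del_start) stop("del_end must be >= del_start")
  d <- del_end - del_start + 1L
  if (d < 2L) stop("microhomology is defined for deletions >= 2 bp")
  len <- chrom_length(ref, chrom)
  if (del_start < 1L || del_end > len)
    stop("deletion [", del_start, ", ", del_end, "] outside ", chrom)
  sq <- ref$sequences[[chrom]]
  window <- substr(sq, max(1L, del_start - d), min(len, del_end + d))
  if (grepl("N", window, fixed = TRUE)) return(NA_integer_)
  base <- function(i) substr(sq, i, i)
  # rightward extension: shift chain condition ref[s+k] == ref[e+1+k]
  r <- 0L
  while (del_end + 1L + r <= len) {
    b1 <- base(del_start + r); b2 <- base(del_end + 1L + r)
    if (b1 == "N" || b2 == "N" || b1 != b2) break
    r <- r + 1L
  }
  # leftward extension: shift chain condition ref[s-k] == ref[e+1-k]
  l <- 0L
  while (del_start - 1L - l >= 1L) {
    b1 <- base(del_start - 1L - l); b2 <- base(del_end - l)
    if (b1 == "N" || b2 == "N" || b1 != b2) break
    l <- l + 1L
  }
  l + r
}

#' Bin a microhomology length
#'
#' Bins are `0, 1, 2, 3-4, 5-9, >=10`, chosen so the named peaks of typical
#' end-joining spectra (2 bp for NHEJ-proficient, 3-4 bp for
#' NHEJ-deficient material) fall in separate bins.
#'
#' @param mh_length Integer vector of microhomology lengths (`NA` allowed).
#' @return A factor with levels `r paste(MH_BINS, collapse = ", ")`.
#' @export
bin_microhomology <- function(mh_length) {
  if (any(mh_length < 0, na.rm = TRUE))
    stop("mh_length must be non-negative")
  cut(mh_length, breaks = c(-0.5, 0.5, 1.5, 2.5, 4.5, 9.5, Inf),
      labels = MH_BINS)
}

#' Deletion junction table for Del >= 2 bp events
#'
#' Computes the junction description (deleted sequence, flanks,
#' microhomology and bin) for every simple Del >= 2 bp event. Deletions are
#' reported at their leftmost-normalized placement; flanks are clipped at
#' chromosome ends.
#'
#' @param events Classified events (see [classify_events()]); only category
#'   `DelGE2` rows are used.
#' @param ref A [reference_genome()].
#' @param flank Reported flank length in bp (default 30).
#' @return A `data.frame`: `sample_id`, `chrom`, `del_start`, `del_end`,
#'   `length`, `deleted_seq`, `left_flank`, `right_flank`, `mh_length`
#'   (`NA` when undefined), `bin`.
#' @export
deletion_junctions <- function(events, ref, flank = 30L) {
  del <- events[events$category == "DelGE2", , drop = FALSE]
  n <- nrow(del)
  out <- data.frame(sample_id = character(n), chrom = character(n),
                    del_start = integer(n), del_end = integer(n),
                    length = integer(n), deleted_seq = character(n),
                    left_flank = character(n), right_flank = character(n),
                    mh_length = integer(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    x <- del[i, ]
    len <- chrom_length(ref, x$chrom)
    out$sample_id[i] <- x$sample_id
    out$chrom[i] <- x$chrom
    out$del_start[i] <- x$start
    out$del_end[i] <- x$end
    out$length[i] <- x$end - x$start + 1L
    out$deleted_seq[i] <- ref_segment(ref, x$chrom, x$start, x$end)
    out$left_flank[i] <-
      if (x$start > 1L)
        ref_segment(ref, x$chrom, max(1L, x$start - flank), x$start - 1L)
      else ""
    out$right_flank[i] <-
      if (x$end < len)
        ref_segment(ref, x$chrom, x$end + 1L, min(len, x$end + flank))
      else ""
    out$mh_length[i] <- compute_microhomology(ref, x$chrom, x$start, x$end)
  }
  out$bin <- as.character(bin_microhomology(out$mh_length))
  out
}

#' Microhomology distribution of a set of deletion junctions
#'
#' @param junctions Output of [deletion_junctions()] (one strain).
#' @return A list with `counts` and `fractions` (named by bin; fractions
#'   sum to 1 over junctions with defined microhomology), `zero_fraction`
#'   (proportion of defined junctions with no apparent microhomology,
#'   reported separately), `n_defined` and `n_undefined`.
#' @export
microhomology_distribution <- function(junctions) {
  mh <- junctions$mh_length
  def <- mh[!is.na(mh)]
  counts <- table(factor(as.character(bin_microhomology(def)),
                         levels = MH_BINS))
  counts <- setNames(as.integer(counts), MH_BINS)
  n <- length(def)
  fractions <- if (n > 0) counts / n else setNames(rep(NA_real_, 6),
                                                   MH_BINS)
  list(counts = counts, fractions = fractions,
       zero_fraction = if (n > 0) sum(def == 0) / n else NA_real_,
       n_defined = n, n_undefined = sum(is.na(mh)))
}
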