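#' Shared haplotype regions between two cases by IBS window scan
#'
#' Scans each chromosome over sites at which both cases are fully
#' called, in sliding windows of `window_size` consecutive informative
#' sites. A window passes when the fraction of sites with zero
#' identity-by-state (the two genotypes share no allele, e.g. 0/0 vs
#' 1/1) is at most `max_mismatch_frac`; overlapping passing windows are
#' merged into maximal regions. This approximates identity-by-descent
#' sharing between affected relatives from genotype data alone.
#'
#' @param vs a [variant_set()].
#' @param case_ids exactly two individual ids.
#' @param config a [funnel_config()] carrying `window_size` and
#'   `max_mismatch_frac`.
#' @return Data frame of class `shared_regions` with columns `chrom`,
#'   `start`, `end` (1-based inclusive) and `n_sites`; per chromosome
#'   the regions are sorted and non-overlapping. Chromosomes with fewer
#'   informative sites than `window_size` yield no regions (with a
#'   warning).
#' @export
shared_regions <- function(vs, case_ids, config = funnel_config()) {
  if (length(case_ids) != 2L)
    stop_input("shared_regions expects exactly two case ids")
  if (!all(case_ids %in% vs$individuals))
    stop_input("case ids not present in call set")
  w <- config$window_size
  out <- list()
  for (chr in unique(vs$variants$chrom)) {
    rows <- which(vs$variants$chrom == chr)
    rows <- rows[order(vs$variants$pos[rows])]
    g1 <- vs$gt[rows, case_ids[1]]
    g2 <- vs$gt[rows, case_ids[2]]
    inf <- !gt_has_missing(g1) & !gt_has_missing(g2)
    rows <- rows[inf]
    if (length(rows) < w) {
      warning(sprintf("chromosome %s: %d informative sites < window %d",
                      chr, length(rows), w))
      next
    }
    a1 <- gt_split(vs$gt[rows, case_ids[1]])
    a2 <- gt_split(vs$gt[rows, case_ids[2]])
    zero_ibs <- as.numeric(a1[, 1] != a2[, 1] & a1[, 1] != a2[, 2] &
                             a1[, 2] != a2[, 1] & a1[, 2] != a2[, 2])
    mism <- data.table::frollsum(zero_ibs, w)      # window ends at i
    pass_end <- which(!is.na(mism) & mism / w <= config$max_mismatch_frac)
    if (length(pass_end) == 0L) next
    # union of [end - w + 1, end] site-index intervals, merged
    covered <- rep(FALSE, length(rows))
    for (e in pass_end) covered[(e - w + 1L):e] <- TRUE
    r <- rle(covered)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (j in which(r$values)) {
      s <- idx_start[j]; e <- idx_end[j]
      out[[length(out) + 1L]] <-
        data.frame(chrom = chr,
                   start = vs$variants$pos[rows[s]],
                   end = vs$variants$pos[rows[e]],
                   n_sites = e - s + 1L)
    }
  }
  res <- if (length(out) == 0L)
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_sites = integer())
  else do.call(rbind, out)
  class(res) <- c("shared_regions", "data.frame")
  res
}
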