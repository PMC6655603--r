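#' Squared allelic correlation between two sites
#'
#' Classic haplotype-based `r^2`: with haplotype frequencies `p_AB`, `p_A`,
#' `p_B` estimated from haplotypes non-missing at both sites,
#' `r^2 = (p_AB - p_A p_B)^2 / (p_A (1-p_A) p_B (1-p_B))`. `NA` when either
#' site is monomorphic among the complete haplotypes.
#'
#' @param h a [haplotype_matrix()].
#' @param site_i,site_j row indices of the two sites.
#' @return a single `r^2` value in `[0, 1]`, or `NA`.
#' @export
pair_r2 <- function(h, site_i, site_j) {
  a <- h$haps[site_i, ]; b <- h$haps[site_j, ]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  pA <- mean(a); pB <- mean(b); pAB <- mean(a & b)
  den <- pA * (1 - pA) * pB * (1 - pB)
  if (den == 0) return(NA_real_)
  (pAB - pA * pB)^2 / den
}

#' LD decay curve over distance bins
#'
#' Computes `r^2` for every intra-chromosomal site pair within
#' `max_dist_bp`, pools the pairs genome-wide into non-overlapping distance
#' bins of `bin_bp`, and reports the per-bin mean. Distance is the
#' difference of 1-based bp positions. The threshold-crossing distance is
#' the midpoint of the first bin at which a running-mean-smoothed curve
#' falls below `threshold` (raw 1-kb bins are noisy).
#'
#' @param h a [haplotype_matrix()].
#' @param max_dist_bp maximum pair distance (default 1 Mb).
#' @param bin_bp bin width (default 1 kb).
#' @param threshold `r^2` level whose crossing distance is reported
#'   (default 0.2).
#' @param smooth_bins width of the running mean used for the crossing
#'   (default 5 bins).
#' @return list with `bins` (data.frame `bin_start_bp`, `bin_end_bp`,
#'   `mean_r2`, `n_pairs`) and `crossing_bp` (`NA` when the curve never
#'   falls below the threshold).
#' @export
decay_curve <- function(h, max_dist_bp = 1e6, bin_bp = 1000,
                        threshold = 0.2, smooth_bins = 5) {
  n_bins <- ceiling(max_dist_bp / bin_bp)
  sums <- numeric(n_bins); counts <- numeric(n_bins)
  H <- h$haps
  for (ch in unique(h$variants$chrom)) {
    sel <- which(h$variants$chrom == ch)
    pos <- h$variants$pos[sel]
    if (length(sel) < 2) next
    for (ii in seq_len(length(sel) - 1)) {
      jmax <- findInterval(pos[ii] + max_dist_bp, pos)
      if (jmax <= ii) next
      js <- (ii + 1):jmax
      a <- H[sel[ii], ]
      B <- H[sel[js], , drop = FALSE]
      va <- !is.na(a)
      a0 <- ifelse(va, a, 0L)
      valid <- !is.na(B) & rep(va, each = length(js))
      B0 <- B; B0[is.na(B0)] <- 0L
      n <- rowSums(valid)
      sa <- as.vector(valid %*% a0)
      sb <- rowSums(B0 * valid)
      sab <- rowSums(B0 * rep(a0, each = length(js)) * valid)
      pA <- sa / n; pB <- sb / n; pAB <- sab / n
      den <- pA * (1 - pA) * pB * (1 - pB)
      r2 <- (pAB - pA * pB)^2 / den
      keep <- n > 0 & den > 0
      if (!any(keep)) next
      bin <- pmin(floor((pos[js] - pos[ii]) / bin_bp) + 1L, n_bins)[keep]
      r2 <- r2[keep]
      bs <- tapply(r2, bin, sum)
      bc <- table(bin)
      idx <- as.integer(names(bs))
      sums[idx] <- sums[idx] + as.numeric(bs)
      counts[idx] <- counts[idx] + as.numeric(bc)
    }
  }
  bins <- data.frame(bin_start_bp = (seq_len(n_bins) - 1) * bin_bp,
                     bin_end_bp = seq_len(n_bins) * bin_bp,
                     mean_r2 = ifelse(counts > 0, sums / counts, NA_real_),
                     n_pairs = as.integer(counts))
  crossing <- NA_real_
  defined <- which(!is.na(bins$mean_r2))
  if (length(defined)) {
    sm <- stats::filter(bins$mean_r2, rep(1 / smooth_bins, smooth_bins),
                        sides = 2)
    below <- which(!is.na(sm) & sm < threshold)
    if (length(below))
      crossing <- (bins$bin_start_bp[below[1]] + bins$bin_end_bp[below[1]]) / 2
  }
  list(bins = bins, crossing_bp = crossing)
}
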