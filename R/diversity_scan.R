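#' Per-site expected heterozygosity
#'
#' For each site, the alternate-allele frequency `p` is estimated from the
#' non-missing calls of the chosen sample subset and the heterozygosity is
#' `2p(1-p)` (expected, the default) or the observed fraction of
#' heterozygous genotypes. Averaged over the fixed array site set this is
#' the "conditional nucleotide diversity" of array studies. Sites with no
#' non-missing call in the subset are `NA`.
#'
#' @param g a [genotype_matrix()].
#' @param subset sample IDs to use (default: all samples).
#' @param observed use the observed heterozygote fraction instead of
#'   `2p(1-p)`.
#' @param corrected apply the small-sample factor `n/(n-1)` (on haplotype
#'   count `n`) to the expected heterozygosity.
#' @return numeric vector, one value per site.
#' @export
site_heterozygosity <- function(g, subset = NULL, observed = FALSE,
                                corrected = FALSE) {
  d <- subset_dosage(g, subset)
  if (ncol(d) == 0) stop("empty sample subset")
  if (observed)
    return(rowMeans(d == 1, na.rm = TRUE))
  n_hap <- 2 * rowSums(!is.na(d))
  p <- rowSums(d, na.rm = TRUE) / n_hap
  het <- 2 * p * (1 - p)
  if (corrected) het <- het * n_hap / (n_hap - 1)
  het[n_hap == 0] <- NA_real_
  het
}

#' Tile chromosomes with sliding windows
#'
#' Windows are `[k * step, k * step + window)` in 0-based half-open bp,
#' anchored at position 0 of each chromosome, for `k = 0, 1, ...` while the
#' start lies inside the chromosome; the final window is truncated at the
#' chromosome end.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param window_bp window size (default 1 Mb).
#' @param step_bp increment (default 200 kb); must not exceed `window_bp`.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
make_windows <- function(chrom_lengths, window_bp = 1e6, step_bp = 2e5) {
  stopifnot(window_bp > 0, step_bp > 0, step_bp <= window_bp)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- as.character(seq_along(chrom_lengths))
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    if (len <= 0) return(NULL)
    starts <- seq(0, len - 1, by = step_bp)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_bp, len))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(chrom = character(), start = numeric(),
                                      end = numeric())
  rownames(out) <- NULL
  out
}

## Sums of per-site values over (possibly overlapping) windows, via
## cumulative sums on the position-sorted sites of each chromosome.
## `values` may be a matrix (one column per statistic); NA values are
## excluded per column, with per-column n in attr "n".
window_sums <- function(variants, values, windows) {
  values <- as.matrix(values)
  sums <- matrix(0, nrow(windows), ncol(values),
                 dimnames = list(NULL, colnames(values)))
  ns <- matrix(0L, nrow(windows), ncol(values))
  for (ch in unique(windows$chrom)) {
    sel <- which(variants$chrom == ch)
    wi <- which(windows$chrom == ch)
    if (!length(wi)) next
    x0 <- variants$pos[sel] - 1
    for (j in seq_len(ncol(values))) {
      v <- values[sel, j]
      ok <- !is.na(v)
      xs <- x0[ok]
      cs <- c(0, cumsum(v[ok]))
      lo <- findInterval(windows$start[wi] - 1, xs)
      hi <- findInterval(windows$end[wi] - 1, xs)
      sums[wi, j] <- cs[hi + 1] - cs[lo + 1]
      ns[wi, j] <- hi - lo
    }
  }
  attr(sums, "n") <- ns
  sums
}

#' Average per-site values over sliding windows
#'
#' A window's value is the mean of the defined per-site values at sites
#' whose 0-based position falls in `[start, end)`. Windows with fewer than
#' `min_sites` contributing sites are reported `NA`.
#'
#' @param values numeric vector aligned with `variants` (NA = undefined).
#' @param variants variant table.
#' @param windows window data.frame from [make_windows()].
#' @param min_sites minimum contributing sites per window (default 10).
#' @return data.frame: `chrom`, `start`, `end`, `n_sites`, `value`.
#' @export
window_mean <- function(values, variants, windows, min_sites = 10) {
  s <- window_sums(variants, values, windows)
  n <- attr(s, "n")[, 1]
  val <- ifelse(n >= max(min_sites, 1L), s[, 1] / n, NA_real_)
  data.frame(chrom = windows$chrom, start = windows$start,
             end = windows$end, n_sites = n, value = val)
}

#' Per-chromosome average of window statistics
#'
#' Mean of the defined window values on each chromosome (the dotted
#' horizontal baseline of genome-wide diversity plots).
#'
#' @param stats data.frame from [window_mean()] (or any window table with a
#'   `value` column).
#' @return data.frame with `chrom` and `mean_value` (`NA` when every window
#'   on the chromosome is undefined).
#' @export
chromosome_average <- function(stats) {
  out <- aggregate(value ~ chrom, data = stats, FUN = mean,
                   na.action = stats::na.pass, na.rm = TRUE)
  names(out)[2] <- "mean_value"
  out$mean_value[is.nan(out$mean_value)] <- NA_real_
  out[order(out$chrom), , drop = FALSE]
}
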