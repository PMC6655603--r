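## Per-site Hudson FST components. p-hat and haplotype counts from
## non-missing diploid calls; sites where either group has fewer than 2
## haplotypes are NA.
hudson_site_components <- function(g, popA, popB) {
  if (length(intersect(popA, popB)))
    stop("overlapping sample groups")
  dA <- subset_dosage(g, popA)
  dB <- subset_dosage(g, popB)
  nA <- 2 * rowSums(!is.na(dA))
  nB <- 2 * rowSums(!is.na(dB))
  pA <- rowSums(dA, na.rm = TRUE) / nA
  pB <- rowSums(dB, na.rm = TRUE) / nB
  bad <- nA < 2 | nB < 2
  num <- (pA - pB)^2 - pA * (1 - pA) / (nA - 1) - pB * (1 - pB) / (nB - 1)
  den <- pA * (1 - pB) + pB * (1 - pA)
  num[bad] <- NA_real_
  den[bad] <- NA_real_
  list(num = num, den = den)
}

## Weir-Cockerham (1984) two-population per-site variance components,
## available behind the estimator switch; a and (a+b+c) summed per window.
wc_site_components <- function(g, popA, popB) {
  dA <- subset_dosage(g, popA); dB <- subset_dosage(g, popB)
  n1 <- rowSums(!is.na(dA)); n2 <- rowSums(!is.na(dB))
  p1 <- rowSums(dA, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(dB, na.rm = TRUE) / (2 * n2)
  h1 <- rowMeans(dA == 1, na.rm = TRUE)
  h2 <- rowMeans(dB == 1, na.rm = TRUE)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- n1 < 2 | n2 < 2
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  list(num = a, den = a + b + cc)
}

#' Windowed pairwise FST
#'
#' Hudson's estimator (default) with ratio-of-averages aggregation: the
#' per-site numerator `(pA - pB)^2 - pA(1-pA)/(nA-1) - pB(1-pB)/(nB-1)` and
#' denominator `pA(1-pB) + pB(1-pA)` are summed over the sites of each
#' window and then divided (`nA`, `nB` are non-missing haplotype counts).
#' This aggregation is the standard recommendation for windowed FST and is
#' unbiased under symmetric drift, so simulations with a known drift
#' parameter can check recovery. Weir-Cockerham is available via
#' `estimator = "wc"`.
#'
#' @param g a [genotype_matrix()].
#' @param popA,popB disjoint character vectors of sample IDs.
#' @param windows window data.frame from [make_windows()].
#' @param min_sites minimum contributing sites per window.
#' @param estimator `"hudson"` (default) or `"wc"`.
#' @return data.frame: `chrom`, `start`, `end`, `n_sites`, `fst` (`NA` where
#'   undefined).
#' @export
window_fst <- function(g, popA, popB, windows, min_sites = 10,
                       estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  comp <- switch(estimator,
                 hudson = hudson_site_components(g, popA, popB),
                 wc = wc_site_components(g, popA, popB))
  ok <- !is.na(comp$num) & !is.na(comp$den)
  num <- ifelse(ok, comp$num, NA_real_)
  den <- ifelse(ok, comp$den, NA_real_)
  s <- window_sums(g$variants, cbind(num = num, den = den), windows)
  n <- attr(s, "n")[, 1]
  fst <- ifelse(n >= max(min_sites, 1L) & s[, "den"] > 0,
                s[, "num"] / s[, "den"], NA_real_)
  data.frame(chrom = windows$chrom, start = windows$start,
             end = windows$end, n_sites = n, fst = fst)
}

#' Genome-wide FST (single ratio of averages over all sites)
#'
#' @inheritParams window_fst
#' @return a single FST value.
#' @export
genome_fst <- function(g, popA, popB, estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  comp <- switch(estimator,
                 hudson = hudson_site_components(g, popA, popB),
                 wc = wc_site_components(g, popA, popB))
  sum(comp$num, na.rm = TRUE) / sum(comp$den, na.rm = TRUE)
}

#' Transform FST to a divergence-time branch length
#'
#' `T = -log(1 - FST)`, the divergence time in population-size-scaled units.
#' FST is clipped to `[0, 1 - 1e-12]` first, so small negative finite-sample
#' estimates map to 0 and complete fixation stays finite. `NA` propagates.
#'
#' @param fst numeric vector of FST values.
#' @return numeric vector of branch lengths `T >= 0`.
#' @export
divergence_time <- function(fst) {
  t <- -log(1 - pmin(pmax(fst, 0), 1 - 1e-12))
  t[is.na(fst)] <- NA_real_
  t
}

#' Population branch statistic from three branch lengths
#'
#' `PBS = (t_fs + t_fo - t_so) / 2`: the branch length of the focal
#' population since its divergence from the sister group, with the
#' focal-sister, focal-outgroup and sister-outgroup divergence times.
#' Negative values are reported as-is; `NA` in any input gives `NA`.
#'
#' @param t_fs,t_fo,t_so numeric vectors of divergence times.
#' @return numeric vector of PBS values.
#' @export
pbs <- function(t_fs, t_fo, t_so) {
  (t_fs + t_fo - t_so) / 2
}

#' Genome-wide PBS selection scan
#'
#' Computes windowed pairwise Hudson FST for the three population pairs,
#' transforms each to a divergence time `T = -log(1 - FST)`, combines them
#' into the focal-branch PBS per window, and reports the top regions.
#' Because sliding windows overlap, a "region" is a maximal run of
#' overlapping windows whose PBS is in the top `1 - top_quantile` fraction,
#' scored by its maximum PBS.
#'
#' @param g a [genotype_matrix()].
#' @param samples sample metadata with `sample_id` and `population` in
#'   `{FOCAL, SISTER, OUTGROUP}`.
#' @param windows window data.frame.
#' @param min_sites minimum contributing sites per window.
#' @param top_k number of regions to report (default 10).
#' @param top_quantile PBS quantile defining candidate windows for region
#'   merging (default 0.99).
#' @param estimator FST estimator, see [window_fst()].
#' @return list with `windows` (coordinate-sorted data.frame: window, pair
#'   FSTs `fst_fs`, `fst_fo`, `fst_so`, times `t_fs`, `t_fo`, `t_so`, `pbs`)
#'   and `top_regions` (data.frame: `rank`, `chrom`, `start`, `end`,
#'   `max_pbs`, `n_windows`).
#' @export
pbs_scan <- function(g, samples, windows, min_sites = 10, top_k = 10,
                     top_quantile = 0.99, estimator = "hudson") {
  pops <- c("FOCAL", "SISTER", "OUTGROUP")
  missing_p <- setdiff(pops, unique(samples$population))
  if (length(missing_p))
    stop("missing population label(s): ", paste(missing_p, collapse = ", "))
  ids <- lapply(pops, function(p)
    intersect(samples$sample_id[samples$population == p], g$samples))
  names(ids) <- pops
  fs <- window_fst(g, ids$FOCAL, ids$SISTER, windows, min_sites, estimator)
  fo <- window_fst(g, ids$FOCAL, ids$OUTGROUP, windows, min_sites, estimator)
  so <- window_fst(g, ids$SISTER, ids$OUTGROUP, windows, min_sites, estimator)
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, n_sites = fs$n_sites,
                    fst_fs = fs$fst, fst_fo = fo$fst, fst_so = so$fst)
  out$t_fs <- divergence_time(out$fst_fs)
  out$t_fo <- divergence_time(out$fst_fo)
  out$t_so <- divergence_time(out$fst_so)
  out$pbs <- pbs(out$t_fs, out$t_fo, out$t_so)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  list(windows = out,
       top_regions = top_pbs_regions(out, top_k, top_quantile))
}

#' Merge top-PBS windows into ranked regions
#'
#' @param pbs_windows window table with a `pbs` column, coordinate sorted.
#' @param top_k number of regions to return.
#' @param top_quantile PBS quantile above which windows enter a region.
#' @return data.frame of ranked regions.
#' @export
top_pbs_regions <- function(pbs_windows, top_k = 10, top_quantile = 0.99) {
  w <- pbs_windows[!is.na(pbs_windows$pbs), , drop = FALSE]
  empty <- data.frame(rank = integer(), chrom = character(),
                      start = numeric(), end = numeric(),
                      max_pbs = numeric(), n_windows = integer())
  if (nrow(w) == 0) return(empty)
  thr <- quantile(w$pbs, top_quantile, names = FALSE)
  w <- w[w$pbs >= thr, , drop = FALSE]
  if (nrow(w) == 0) return(empty)
  w <- w[order(w$chrom, w$start), , drop = FALSE]
  ## group windows into maximal overlapping runs
  grp <- integer(nrow(w)); grp[1] <- 1L
  cur_end <- w$end[1]
  for (i in seq_len(nrow(w))[-1]) {
    if (w$chrom[i] == w$chrom[i - 1] && w$start[i] < cur_end) {
      grp[i] <- grp[i - 1]
      cur_end <- max(cur_end, w$end[i])
    } else {
      grp[i] <- grp[i - 1] + 1L
      cur_end <- w$end[i]
    }
  }
  reg <- data.frame(
    chrom = tapply(w$chrom, grp, `[`, 1),
    start = tapply(w$start, grp, min),
    end = tapply(w$end, grp, max),
    max_pbs = tapply(w$pbs, grp, max),
    n_windows = as.integer(table(grp)))
  reg <- reg[order(-reg$max_pbs), , drop = FALSE]
  reg <- head(reg, top_k)
  reg <- cbind(rank = seq_len(nrow(reg)), reg)
  rownames(reg) <- NULL
  reg
}
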