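#' ROH detection rule set
#'
#' The segment-level rules used for runs-of-homozygosity calling: a segment
#' is a run of consecutive array SNPs containing at most `max_het`
#' heterozygous and `max_missing` missing calls, with every inter-SNP gap at
#' most `max_gap_bp`, spanning at least `min_length_bp`, containing at least
#' `min_snps` homozygous SNPs, at an average density of at least one SNP per
#' `max_bp_per_snp`. Only sites with minor-allele frequency at least
#' `min_maf` (in the whole panel) are considered.
#'
#' @param min_snps minimum homozygous SNPs per segment (default 80).
#' @param min_length_bp minimum segment span (default 0.5 Mb).
#' @param max_gap_bp maximum gap between consecutive SNPs (default 100 kb).
#' @param max_het heterozygous calls permitted per segment (default 1).
#' @param max_missing missing calls permitted per segment (default 2).
#' @param max_bp_per_snp maximum average spacing (default 50 kb).
#' @param min_maf minimum MAF for a site to enter the scan (default 0.01).
#' @return list of class `roh_rules`.
#' @export
roh_rules <- function(min_snps = 80, min_length_bp = 5e5, max_gap_bp = 1e5,
                      max_het = 1, max_missing = 2, max_bp_per_snp = 5e4,
                      min_maf = 0.01) {
  structure(list(min_snps = min_snps, min_length_bp = min_length_bp,
                 max_gap_bp = max_gap_bp, max_het = max_het,
                 max_missing = max_missing, max_bp_per_snp = max_bp_per_snp,
                 min_maf = min_maf),
            class = "roh_rules")
}

## Segment scan of one chromosome. The chromosome is first split at
## inter-SNP gaps above the cap; within each block a cursor sweeps left to
## right, each candidate being the longest run starting at the cursor that
## respects the heterozygote/missing allowances (hereditary constraints, so
## a single forward-only two-pointer suffices). Candidates are trimmed to
## homozygous endpoints, reported when they satisfy the span, homozygous
## count and density rules, and the cursor jumps past the candidate's end,
## so reported segments are disjoint by construction.
roh_scan_chrom <- function(pos, call, rules) {
  ## call: 0 = homozygous, 1 = het, 2 = missing
  n <- length(pos)
  if (n == 0) return(NULL)
  blocks <- if (n == 1) cbind(1, 1) else {
    cut <- which(diff(pos) > rules$max_gap_bp)
    cbind(c(1, cut + 1), c(cut, n))
  }
  segs <- list()
  for (b in seq_len(nrow(blocks))) {
    lo <- blocks[b, 1]; hi <- blocks[b, 2]
    het <- c(0L, cumsum(call[lo:hi] == 1))
    mis <- c(0L, cumsum(call[lo:hi] == 2))
    m <- hi - lo + 1
    c_ <- 1L
    j <- 0L
    while (c_ <= m) {
      if (j < c_) j <- c_
      while (j < m &&
             het[j + 2] - het[c_] <= rules$max_het &&
             mis[j + 2] - mis[c_] <= rules$max_missing)
        j <- j + 1L
      ## trim to homozygous endpoints
      ii <- lo + c_ - 1L; jj <- lo + j - 1L
      while (ii <= jj && call[ii] != 0) ii <- ii + 1L
      while (jj >= ii && call[jj] != 0) jj <- jj - 1L
      if (ii <= jj)
        segs[[length(segs) + 1]] <- c(ii, jj)
      c_ <- j + 1L
    }
  }
  if (!length(segs)) return(NULL)
  segs <- do.call(rbind, segs)
  i <- segs[, 1]; j <- segs[, 2]
  span <- pos[j] - pos[i] + 1
  n_snps <- j - i + 1
  n_het <- vapply(seq_along(i), function(k) sum(call[i[k]:j[k]] == 1), 0L)
  n_mis <- vapply(seq_along(i), function(k) sum(call[i[k]:j[k]] == 2), 0L)
  n_hom <- n_snps - n_het - n_mis
  keep <- span >= rules$min_length_bp & n_hom >= rules$min_snps &
    span / n_snps <= rules$max_bp_per_snp
  if (!any(keep)) return(NULL)
  out <- data.frame(start = pos[i[keep]] - 1, end = pos[j[keep]],
                    n_snps = n_snps[keep], n_het = n_het[keep],
                    n_missing = n_mis[keep])
  rownames(out) <- NULL
  out
}

#' Detect runs of homozygosity for one sample
#'
#' Scans each chromosome of the sample's genotype calls for maximal runs
#' satisfying the segment rules (see [roh_rules()]). Candidate runs are
#' maximal with respect to the heterozygote/missing allowances and the gap
#' cap; the span, homozygous-count and density rules are then applied, the
#' run endpoints are trimmed to homozygous SNPs, and overlapping survivors
#' are resolved greedily left-to-right (ties to the earlier start).
#'
#' @param g a [genotype_matrix()]; the MAF rule of `rules` is applied to the
#'   whole panel before scanning.
#' @param sample_id sample to scan.
#' @param rules a [roh_rules()] object.
#' @return data.frame of segments: `sample_id`, `chrom`, `start`, `end`
#'   (0-based half-open bp spanning the outermost SNPs), `n_snps`, `n_het`,
#'   `n_missing`.
#' @export
detect_roh <- function(g, sample_id, rules = roh_rules()) {
  if (!sample_id %in% g$samples)
    stop("unknown sample: ", sample_id)
  if (rules$min_maf > 0) {
    maf <- site_stats(g)$maf
    keep <- !is.na(maf) & maf >= rules$min_maf
    g <- genotype_matrix(g$variants[keep, , drop = FALSE], g$samples,
                         g$dosage[keep, , drop = FALSE])
  }
  d <- g$dosage[, match(sample_id, g$samples)]
  call <- ifelse(is.na(d), 2L, ifelse(d == 1L, 1L, 0L))
  out <- list()
  for (ch in unique(g$variants$chrom)) {
    sel <- g$variants$chrom == ch
    segs <- roh_scan_chrom(g$variants$pos[sel], call[sel], rules)
    if (!is.null(segs) && nrow(segs))
      out[[length(out) + 1]] <- cbind(
        data.frame(sample_id = sample_id, chrom = ch), segs)
  }
  if (!length(out))
    return(data.frame(sample_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_snps = integer(), n_het = integer(),
                      n_missing = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' F_ROH summaries from ROH segments
#'
#' For each sample and each length threshold, sums the lengths of segments
#' longer than the threshold (`L_ROH`, kb), counts them (`n_ROH`), and
#' divides by the genome length to obtain the ROH-based inbreeding
#' coefficient `F_ROH`.
#'
#' @param segments segment data.frame from [detect_roh()] (any number of
#'   samples; segments must not overlap within a sample).
#' @param genome_length_kb autosomal genome length in kb
#'   (default 2,243,000 kb, the equine autosome scale).
#' @param thresholds_bp segment-length thresholds in bp
#'   (default >0.5 Mb and >5 Mb).
#' @param sample_ids samples to summarize (default: those present in
#'   `segments`); samples with no qualifying segment get `f_roh = 0`.
#' @return data.frame: `sample_id`, `threshold_bp`, `l_roh_kb`, `n_roh`,
#'   `f_roh`.
#' @export
f_roh <- function(segments, genome_length_kb = 2243000,
                  thresholds_bp = c(5e5, 5e6), sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- unique(segments$sample_id)
  if (nrow(segments)) {
    for (sid in unique(segments$sample_id)) {
      s <- segments[segments$sample_id == sid, , drop = FALSE]
      for (ch in unique(s$chrom)) {
        sc <- s[s$chrom == ch, , drop = FALSE]
        sc <- sc[order(sc$start), , drop = FALSE]
        if (nrow(sc) > 1 && any(sc$start[-1] < sc$end[-nrow(sc)]))
          stop("overlapping ROH segments for sample ", sid)
      }
    }
  }
  out <- expand.grid(sample_id = sample_ids, threshold_bp = thresholds_bp,
                     stringsAsFactors = FALSE)
  out$l_roh_kb <- 0; out$n_roh <- 0L
  for (k in seq_len(nrow(out))) {
    s <- segments[segments$sample_id == out$sample_id[k] &
                    (segments$end - segments$start) > out$threshold_bp[k], ,
                  drop = FALSE]
    out$l_roh_kb[k] <- sum(s$end - s$start) / 1000
    out$n_roh[k] <- nrow(s)
  }
  out$f_roh <- out$l_roh_kb / genome_length_kb
  out
}

## ---------------------------------------------------------------------------
## Pedigree inbreeding
## ---------------------------------------------------------------------------

## Generation depth of every individual (founders = 0), for recursion order.
ped_depth <- function(ped) {
  depth <- setNames(rep(NA_real_, nrow(ped)), ped$id)
  get_depth <- function(id) {
    if (id == MISSING_PARENT) return(-1)
    if (!is.na(depth[[id]])) return(depth[[id]])
    rec <- ped[match(id, ped$id), ]
    d <- 1 + max(get_depth(rec$sire), get_depth(rec$dam))
    depth[[id]] <<- d
    d
  }
  for (id in ped$id) get_depth(id)
  depth
}

#' Pedigree inbreeding coefficient, truncated at a generation horizon
#'
#' Wright's coefficient computed as the kinship of the individual's parents
#' by the recursive definition: `phi(x, x) = (1 + F_x) / 2`,
#' `phi(x, y) = (phi(sire_x, y) + phi(dam_x, y)) / 2` (recursing on the
#' individual of greater generation depth), with unknown parents and
#' founders treated as unrelated and non-inbred. Before computing, the
#' pedigree is pruned to ancestors reachable within `max_generations`
#' meioses of the sample (parents are generation 1); ancestors at the
#' horizon become founders, so loops through deeper common ancestors
#' contribute nothing.
#'
#' @param ped a `pedigree`.
#' @param sample_id individual whose coefficient is wanted.
#' @param max_generations truncation depth (default `Inf` = full pedigree).
#' @return A single inbreeding coefficient in `[0, 1)`.
#' @export
pedigree_f <- function(ped, sample_id, max_generations = Inf) {
  if (!sample_id %in% ped$id)
    stop("sample not in pedigree: ", sample_id)
  ## prune to the generation horizon (minimum path depth)
  if (is.finite(max_generations)) {
    depth <- setNames(0, sample_id)
    frontier <- sample_id
    g <- 0
    while (length(frontier) && g < max_generations) {
      g <- g + 1
      recs <- ped[match(frontier, ped$id), , drop = FALSE]
      nxt <- setdiff(unique(c(recs$sire, recs$dam)),
                     c(MISSING_PARENT, names(depth)))
      nxt <- nxt[nxt %in% ped$id]
      depth[nxt] <- g
      frontier <- nxt
    }
    keep <- ped$id %in% names(depth)
    sub <- ped[keep, , drop = FALSE]
    horizon <- names(depth)[depth == max_generations]
    sub$sire[sub$id %in% horizon] <- MISSING_PARENT
    sub$dam[sub$id %in% horizon] <- MISSING_PARENT
    sub$sire[!(sub$sire %in% sub$id)] <- MISSING_PARENT
    sub$dam[!(sub$dam %in% sub$id)] <- MISSING_PARENT
    ped <- sub
  }
  depth <- ped_depth(ped)
  memo <- new.env(parent = emptyenv())
  parents <- function(id) unlist(ped[match(id, ped$id), c("sire", "dam")])
  phi <- function(a, b) {
    if (a == MISSING_PARENT || b == MISSING_PARENT) return(0)
    key <- paste(sort(c(a, b)), collapse = "\r")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (a == b) {
      pr <- parents(a)
      (1 + phi(pr[1], pr[2])) / 2
    } else {
      ## recurse on the deeper individual; it cannot be the other's ancestor
      if (depth[[a]] < depth[[b]]) { tmp <- a; a <- b; b <- tmp }
      pr <- parents(a)
      (phi(pr[1], b) + phi(pr[2], b)) / 2
    }
    memo[[key]] <- val
    val
  }
  pr <- parents(sample_id)
  phi(pr[1], pr[2])
}

#' Pedigree F for many samples at several depths
#'
#' @param ped a `pedigree`.
#' @param sample_ids individuals to evaluate.
#' @param generations truncation depths (default 5 and 10).
#' @return data.frame: `sample_id`, `generations`, `f_ped`.
#' @export
pedigree_f_table <- function(ped, sample_ids, generations = c(5, 10)) {
  out <- expand.grid(sample_id = sample_ids, generations = generations,
                     stringsAsFactors = FALSE)
  out$f_ped <- mapply(function(s, gn) pedigree_f(ped, s, gn),
                      out$sample_id, out$generations)
  out
}

#' Correlation between ROH-based and pedigree-based inbreeding
#'
#' Pearson correlation of `F_ROH` and `F_PED` over the samples present in
#' both tables, for every combination of ROH length threshold and pedigree
#' truncation depth, plus a binned four-way histogram summary of the F
#' distributions.
#'
#' @param roh_summary data.frame from [f_roh()].
#' @param ped_f data.frame from [pedigree_f_table()].
#' @param breaks histogram bin breaks on the F scale.
#' @return list with `correlations` (data.frame `threshold_bp`,
#'   `generations`, `n`, `r`; `r` is `NA` when either vector is constant)
#'   and `histogram` (long data.frame of bin counts per measure).
#' @export
f_correlation <- function(roh_summary, ped_f,
                          breaks = seq(0, 1, by = 0.02)) {
  common <- intersect(roh_summary$sample_id, ped_f$sample_id)
  if (length(common) < 3)
    stop("need at least 3 samples present in both tables")
  combos <- expand.grid(threshold_bp = unique(roh_summary$threshold_bp),
                        generations = unique(ped_f$generations))
  combos$n <- NA_integer_; combos$r <- NA_real_
  for (k in seq_len(nrow(combos))) {
    a <- roh_summary[roh_summary$threshold_bp == combos$threshold_bp[k], ]
    b <- ped_f[ped_f$generations == combos$generations[k], ]
    x <- a$f_roh[match(common, a$sample_id)]
    y <- b$f_ped[match(common, b$sample_id)]
    combos$n[k] <- length(common)
    if (stats::sd(x) > 0 && stats::sd(y) > 0)
      combos$r[k] <- cor(x, y)
  }
  hists <- list()
  for (th in unique(roh_summary$threshold_bp)) {
    a <- roh_summary[roh_summary$threshold_bp == th, ]
    h <- hist(pmin(a$f_roh, max(breaks)), breaks = breaks, plot = FALSE)
    hists[[length(hists) + 1]] <- data.frame(
      measure = sprintf("F_ROH>%gMb", th / 1e6),
      bin_lo = head(breaks, -1), bin_hi = breaks[-1], count = h$counts)
  }
  for (gn in unique(ped_f$generations)) {
    b <- ped_f[ped_f$generations == gn, ]
    h <- hist(pmin(b$f_ped, max(breaks)), breaks = breaks, plot = FALSE)
    hists[[length(hists) + 1]] <- data.frame(
      measure = sprintf("F_PED%g", gn),
      bin_lo = head(breaks, -1), bin_hi = breaks[-1], count = h$counts)
  }
  list(correlations = combos, histogram = do.call(rbind, hists))
}
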