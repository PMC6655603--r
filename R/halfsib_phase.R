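#' Detect half-sib families from sample metadata
#'
#' Groups genotyped samples by shared `sire_id`; families with at least
#' `min_family_size` offspring become phasing units (the sires themselves
#' are typically ungenotyped).
#'
#' @param g a [genotype_matrix()].
#' @param samples metadata data.frame with `sample_id` and `sire_id`.
#' @param min_family_size minimum offspring per family (default 10).
#' @return list of `halfsib_family` objects (`sire_id`, `offspring`,
#'   `geno` restricted to the offspring), one per qualifying sire.
#' @export
detect_families <- function(g, samples, min_family_size = 10) {
  if (!"sire_id" %in% names(samples))
    stop("sample table has no sire_id column")
  sam <- samples[!is.na(samples$sire_id) & samples$sire_id != "" &
                   samples$sample_id %in% g$samples, , drop = FALSE]
  if (nrow(sam) == 0) return(list())
  fams <- split(sam$sample_id, sam$sire_id)
  fams <- fams[vapply(fams, length, 0L) >= min_family_size]
  fams <- fams[order(-vapply(fams, length, 0L))]
  lapply(names(fams), function(sire) {
    off <- fams[[sire]]
    structure(list(sire_id = sire, offspring = off,
                   geno = genotype_matrix(
                     g$variants, off,
                     g$dosage[, match(off, g$samples), drop = FALSE])),
              class = "halfsib_family")
  })
}

#' @export
print.halfsib_family <- function(x, ...) {
  cat(sprintf("halfsib_family: sire %s, %d offspring, %d sites\n",
              x$sire_id, length(x$offspring), nrow(x$geno$variants)))
  invisible(x)
}

## Scan one chromosome of one family. tmat: informative-site x offspring
## matrix of transmitted sire alleles (0/1/NA). Returns per-offspring strand
## block boundaries (indices into the informative sites) and initial strands.
scan_strands <- function(tmat, support_k) {
  n_sites <- nrow(tmat); n_off <- ncol(tmat)
  strand <- rep(NA_integer_, n_off)        # current strand per offspring
  run <- integer(n_off)                    # consecutive-conflict counter
  run_start <- integer(n_off)              # site index where the run began
  last_ok <- integer(n_off)                # last concordant site index
  flips <- vector("list", n_off)           # conflict-site index of each flip
  first_strand <- rep(NA_integer_, n_off)
  hap0 <- rep(NA_integer_, n_sites)        # online estimate of strand-0 allele
  for (s in seq_len(n_sites)) {
    t <- tmat[s, ]
    det <- which(!is.na(t))
    if (!length(det)) next
    seeded <- det[!is.na(strand[det])]
    ## online vote for the strand-0 allele at this site
    h <- NA_integer_
    if (length(seeded)) {
      votes <- ifelse(strand[seeded] == 0L, t[seeded], 1L - t[seeded])
      n1 <- sum(votes); n0 <- length(votes) - n1
      if (n1 != n0) h <- as.integer(n1 > n0)
    } else {
      ## seed the first determinable offspring onto strand 0
      first <- det[1]
      strand[first] <- 0L
      first_strand[first] <- 0L
      last_ok[first] <- s
      h <- t[first]
      seeded <- first
    }
    if (is.na(h)) next                     # tied vote: site uninformative
    hap0[s] <- h
    for (o in det) {
      if (is.na(strand[o])) {              # late seeding
        strand[o] <- if (t[o] == h) 0L else 1L
        first_strand[o] <- strand[o]
        last_ok[o] <- s
        next
      }
      expected <- if (strand[o] == 0L) h else 1L - h
      if (t[o] == expected) {
        run[o] <- 0L
        last_ok[o] <- s
      } else {
        if (run[o] == 0L) run_start[o] <- s
        run[o] <- run[o] + 1L
        if (run[o] >= support_k) {         # recombination confirmed
          flips[[o]] <- c(flips[[o]],
                          c(prev = last_ok[o], conflict = run_start[o]))
          strand[o] <- 1L - strand[o]
          run[o] <- 0L
          last_ok[o] <- s
        }
      }
    }
  }
  list(flips = flips, first_strand = first_strand)
}

#' Reconstruct the haplotypes of an ungenotyped sire from half-sibs
#'
#' At a biallelic site, the sire must be heterozygous whenever both
#' homozygote classes occur among the offspring (each offspring carries one
#' sire allele); such sites are *informative*. A homozygous offspring's
#' transmitted sire allele at an informative site is its own allele;
#' heterozygous or missing offspring are uninformative there. Offspring are
#' then assigned to the sire's two strands by a left-to-right scan per
#' chromosome: an offspring keeps its current strand until `support_k`
#' consecutive determinable informative sites all conflict with it, at which
#' point a recombination is placed at the midpoint between the last
#' concordant and the first conflicting informative site; shorter conflict
#' runs are treated as genotyping error and ignored. Finally the sire's two
#' allele sequences are voted per site from the offspring assigned to each
#' strand (majority, `NA` on ties).
#'
#' @param fam a `halfsib_family` from [detect_families()].
#' @param support_k consecutive conflicting sites required to accept a
#'   strand switch (default 3).
#' @param chrom_lengths optional named chromosome lengths (bp); blocks then
#'   span whole chromosomes instead of the informative-site range.
#' @param min_family_size guard re-checked here (default 10).
#' @return An object of class `sire_phase`: `sire_id`,
#'   `informative_sites` (variant table subset), `sire_hap0`/`sire_hap1`
#'   (0/1/NA over informative sites), `blocks` (data.frame `sample_id`,
#'   `chrom`, `start`, `end`, `strand`), `recombinations` (data.frame
#'   `sample_id`, `chrom`, `n_recomb`).
#' @export
infer_sire_phase <- function(fam, support_k = 3, chrom_lengths = NULL,
                             min_family_size = 10) {
  stopifnot(inherits(fam, "halfsib_family"))
  if (length(fam$offspring) < min_family_size)
    stop("family below minimum size: ", length(fam$offspring))
  g <- fam$geno
  n_off <- length(fam$offspring)
  has0 <- rowSums(g$dosage == 0L, na.rm = TRUE) > 0
  has2 <- rowSums(g$dosage == 2L, na.rm = TRUE) > 0
  info <- has0 & has2
  vt <- g$variants[info, , drop = FALSE]
  d <- g$dosage[info, , drop = FALSE]
  tmat <- matrix(NA_integer_, nrow(d), ncol(d))
  tmat[d == 0L] <- 0L
  tmat[d == 2L] <- 1L

  blocks <- list(); recomb <- list()
  hap0 <- rep(NA_integer_, nrow(vt)); hap1 <- rep(NA_integer_, nrow(vt))
  strand_at <- matrix(NA_integer_, nrow(vt), n_off)
  for (ch in unique(g$variants$chrom)) {
    sel <- which(vt$chrom == ch)
    pos <- vt$pos[sel]
    lo_bp <- if (!is.null(chrom_lengths)) 0 else
      if (length(sel)) pos[1] - 1 else 0
    hi_bp <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else
      if (length(sel)) pos[length(sel)] else 0
    if (length(sel) < support_k) {
      if (length(sel))
        warning("chromosome ", ch, ": fewer than support_k informative sites")
      for (o in seq_len(n_off)) {
        blocks[[length(blocks) + 1]] <- data.frame(
          sample_id = fam$offspring[o], chrom = ch, start = lo_bp,
          end = hi_bp, strand = 0L)
        recomb[[length(recomb) + 1]] <- data.frame(
          sample_id = fam$offspring[o], chrom = ch, n_recomb = 0L)
      }
      if (length(sel)) strand_at[sel, ] <- 0L
      next
    }
    sc <- scan_strands(tmat[sel, , drop = FALSE], support_k)
    for (o in seq_len(n_off)) {
      fl <- sc$flips[[o]]
      s0 <- sc$first_strand[o]
      if (is.na(s0)) s0 <- 0L              # never determinable: one block
      n_flip <- length(fl) / 2
      bps <- numeric(0)
      if (n_flip > 0) {
        prev <- fl[seq(1, length(fl), by = 2)]
        conf <- fl[seq(2, length(fl), by = 2)]
        bps <- (pos[prev] + pos[conf]) / 2
      }
      strands <- (s0 + seq_len(n_flip + 1) - 1) %% 2L
      starts <- c(lo_bp, bps); ends <- c(bps, hi_bp)
      blocks[[length(blocks) + 1]] <- data.frame(
        sample_id = fam$offspring[o], chrom = ch, start = starts,
        end = ends, strand = as.integer(strands))
      recomb[[length(recomb) + 1]] <- data.frame(
        sample_id = fam$offspring[o], chrom = ch,
        n_recomb = as.integer(n_flip))
      ## per-site strand for the final haplotype vote
      strand_at[sel, o] <- as.integer(strands[
        findInterval(pos - 0.5, c(starts[1], ends)) ])
    }
  }
  ## majority vote per strand
  for (s in seq_len(nrow(vt))) {
    t <- tmat[s, ]
    for (st in 0:1) {
      v <- t[!is.na(t) & !is.na(strand_at[s, ]) & strand_at[s, ] == st]
      if (!length(v)) next
      n1 <- sum(v); n0 <- length(v) - n1
      allele <- if (n1 > n0) 1L else if (n0 > n1) 0L else NA_integer_
      if (st == 0) hap0[s] <- allele else hap1[s] <- allele
    }
  }
  bl <- do.call(rbind, blocks); rownames(bl) <- NULL
  rc <- do.call(rbind, recomb); rownames(rc) <- NULL
  structure(list(sire_id = fam$sire_id, offspring = fam$offspring,
                 informative_sites = vt, sire_hap0 = hap0, sire_hap1 = hap1,
                 blocks = bl, recombinations = rc),
            class = "sire_phase")
}

#' @export
print.sire_phase <- function(x, ...) {
  cat(sprintf(
    "sire_phase: sire %s, %d offspring, %d informative sites, %.2f recomb/offspring\n",
    x$sire_id, length(x$offspring), nrow(x$informative_sites),
    mean(tapply(x$recombinations$n_recomb, x$recombinations$sample_id, sum))))
  invisible(x)
}

#' Summarize recombination across half-sib families
#'
#' Per family: the genome-wide mean recombination count per offspring. Per
#' chromosome (pooled over families): mean count and the proportion of
#' offspring with zero recombinations, paired with chromosome length when
#' given.
#'
#' @param phases list of `sire_phase` objects.
#' @param chrom_lengths optional named chromosome lengths in bp.
#' @return list with `families` (data.frame `sire_id`, `n_half_sibs`,
#'   `mean_recomb`) and `per_chrom` (data.frame `chrom`, `length_bp`,
#'   `mean_recomb`, `prop_zero`).
#' @export
summarize_recombination <- function(phases, chrom_lengths = NULL) {
  stopifnot(length(phases) >= 1)
  fam <- do.call(rbind, lapply(phases, function(p) {
    tot <- tapply(p$recombinations$n_recomb, p$recombinations$sample_id, sum)
    data.frame(sire_id = p$sire_id, n_half_sibs = length(p$offspring),
               mean_recomb = mean(tot))
  }))
  allrc <- do.call(rbind, lapply(phases, `[[`, "recombinations"))
  per <- aggregate(n_recomb ~ chrom, data = allrc, FUN = mean)
  names(per)[2] <- "mean_recomb"
  pz <- aggregate(n_recomb ~ chrom, data = allrc,
                  FUN = function(x) mean(x == 0))
  per$prop_zero <- pz$n_recomb[match(per$chrom, pz$chrom)]
  per$length_bp <- if (!is.null(chrom_lengths))
    unname(chrom_lengths[per$chrom]) else NA_real_
  per <- per[, c("chrom", "length_bp", "mean_recomb", "prop_zero")]
  list(families = fam, per_chrom = per[order(per$chrom), , drop = FALSE])
}
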