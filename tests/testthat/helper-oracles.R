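# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately written as direct, unoptimized transcriptions of
# the definitions (explicit enumeration / explicit count tables), so they
# share no code path with the package implementations they check.

toy_geno <- function(pos, dosage, chrom = "1", samples = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(dosage)))
  vt <- data.frame(chrom = chrom, pos = pos,
                   id = paste0("m", seq_along(pos)), ref = "A", alt = "G")
  genotype_matrix(vt, samples, dosage)
}

toy_haps <- function(pos, haps, chrom = "1") {
  haps <- as.matrix(haps)
  vt <- data.frame(chrom = chrom, pos = pos,
                   id = paste0("m", seq_along(pos)), ref = "A", alt = "G")
  haplotype_matrix(vt, paste0("s", seq_len(ncol(haps) / 2)), haps)
}

# One-sample genotype matrix from a call vector (0 = hom, 1 = het,
# 2 = missing), for ROH tests; panel MAF is made irrelevant by disabling
# the MAF rule via rules_nomaf().
roh_geno <- function(pos, call) {
  d <- ifelse(call == 2L, NA_integer_, ifelse(call == 1L, 1L, 0L))
  toy_geno(pos, matrix(d, ncol = 1))
}
rules_nomaf <- function(...) roh_rules(min_maf = 0, ...)

# Brute-force ROH enumerator: explicit O(n^2) scan. A window [i, j] is
# admissible when every inter-SNP gap is <= max_gap_bp and it contains at
# most max_het heterozygous and max_missing missing calls (checked by
# slicing and counting each time). The cursor takes the longest admissible
# window starting at its position, trims to homozygous endpoints, applies
# the span / homozygous-count / density rules, and jumps past the window.
brute_roh <- function(pos, call, rules) {
  n <- length(pos)
  res <- list()
  i <- 1L
  while (i <= n) {
    jbest <- NA_integer_
    for (j in i:n) {
      w <- call[i:j]
      gaps_ok <- j == i || all(diff(pos[i:j]) <= rules$max_gap_bp)
      if (gaps_ok && sum(w == 1) <= rules$max_het &&
          sum(w == 2) <= rules$max_missing) {
        jbest <- j
      } else break   # every constraint is monotone in j: no recovery
    }
    if (is.na(jbest)) { i <- i + 1L; next }
    ii <- i; jj <- jbest
    while (ii <= jj && call[ii] != 0) ii <- ii + 1L
    while (jj >= ii && call[jj] != 0) jj <- jj - 1L
    if (ii <= jj) {
      w <- call[ii:jj]
      span <- pos[jj] - pos[ii] + 1
      n_snps <- jj - ii + 1
      n_hom <- sum(w == 0)
      if (span >= rules$min_length_bp && n_hom >= rules$min_snps &&
          span / n_snps <= rules$max_bp_per_snp)
        res[[length(res) + 1]] <- data.frame(
          start = pos[ii] - 1, end = pos[jj], n_snps = n_snps,
          n_het = sum(w == 1), n_missing = sum(w == 2))
    }
    i <- jbest + 1L
  }
  if (!length(res))
    return(data.frame(start = numeric(), end = numeric(),
                      n_snps = integer(), n_het = integer(),
                      n_missing = integer()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Random 500-SNP test chromosome mixing homozygosity-rich and
# heterozygosity-rich blocks, with variable spacing so the gap and density
# rules are exercised.
random_roh_chrom <- function(n = 500) {
  pos <- cumsum(sample(c(rep(5000:20000, 3), 40000:120000), n,
                       replace = TRUE))
  n_blocks <- sample(6:14, 1)
  cuts <- sort(sample(seq_len(n - 1), n_blocks - 1))
  sizes <- diff(c(0, cuts, n))
  call <- unlist(lapply(sizes, function(m) {
    if (runif(1) < 0.5)
      sample(0:2, m, replace = TRUE, prob = c(0.985, 0.005, 0.01))
    else
      sample(0:2, m, replace = TRUE, prob = c(0.65, 0.3, 0.05))
  }))
  list(pos = pos, call = as.integer(call))
}

# Brute-force r^2 from the explicit 2x2 haplotype count table.
brute_r2 <- function(h, i, j) {
  a <- h$haps[i, ]; b <- h$haps[j, ]
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
  n <- n11 + n10 + n01 + n00
  pA <- (n11 + n10) / n; pB <- (n11 + n01) / n
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  D <- n11 / n - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Brute-force windowed Hudson FST: per-site terms from explicit allele
# counting over individual genotypes, summed with an explicit loop.
brute_window_fst <- function(g, popA, popB) {
  num <- 0; den <- 0; used <- 0L
  for (s in seq_len(nrow(g$variants))) {
    terms <- lapply(list(popA, popB), function(ids) {
      d <- g$dosage[s, match(ids, g$samples)]
      d <- d[!is.na(d)]
      list(n = 2 * length(d), p = sum(d) / (2 * length(d)))
    })
    nA <- terms[[1]]$n; pA <- terms[[1]]$p
    nB <- terms[[2]]$n; pB <- terms[[2]]$p
    if (nA < 2 || nB < 2) next
    num <- num + (pA - pB)^2 - pA * (1 - pA) / (nA - 1) -
      pB * (1 - pB) / (nB - 1)
    den <- den + pA * (1 - pB) + pB * (1 - pA)
    used <- used + 1L
  }
  if (used == 0 || den == 0) return(NA_real_)
  num / den
}

# Small phased panel simulated from given per-haplotype allele frequency.
random_panel_haps <- function(n_sites, n_samples, p = 0.5, pos_step = 1000) {
  toy_haps(pos = seq(pos_step, by = pos_step, length.out = n_sites),
           haps = matrix(rbinom(n_sites * 2 * n_samples, 1, p), n_sites))
}

write_lines_vcf <- function(lines, file = tempfile(fileext = ".vcf")) {
  writeLines(lines, file)
  file
}

minimal_vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}
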