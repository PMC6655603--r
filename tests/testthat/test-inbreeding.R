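test_that("a run tolerating one heterozygote forms a single segment", {
  ## 100 SNPs every 10 kb; hom at 1..90, then alternating het/hom
  pos <- seq(10001, by = 10000, length.out = 100)
  call <- c(rep(0L, 90), rep(c(1L, 0L), 5))
  segs <- detect_roh(roh_geno(pos, call), "s1", rules_nomaf())
  expect_equal(nrow(segs), 1)
  ## the run absorbs the first het (site 91) and ends on hom site 92
  expect_equal(segs$start, pos[1] - 1)
  expect_equal(segs$end, pos[92])
  expect_equal(segs$n_het, 1L)
  expect_equal(segs$n_snps - segs$n_het - segs$n_missing, 91L)
  ## agreement with the independent enumerator
  bf <- brute_roh(pos, call, rules_nomaf())
  expect_equal(segs[, names(bf)], bf, ignore_attr = TRUE)
})

test_that("fewer than 80 homozygous SNPs yields no segment", {
  pos <- seq(10001, by = 10000, length.out = 80)
  call <- c(rep(0L, 70), rep(c(1L, 1L), 5))
  segs <- detect_roh(roh_geno(pos, call), "s1", rules_nomaf())
  expect_equal(nrow(segs), 0)
})

test_that("a gap above 100 kb splits an otherwise perfect run", {
  pos <- c(seq(10001, by = 10000, length.out = 100),
           seq(10001 + 99 * 10000 + 120000, by = 10000, length.out = 100))
  call <- rep(0L, 200)
  segs <- detect_roh(roh_geno(pos, call), "s1", rules_nomaf())
  expect_equal(nrow(segs), 2)
  expect_equal(segs$end[1], pos[100])
  expect_equal(segs$start[2], pos[101] - 1)
  bf <- brute_roh(pos, call, rules_nomaf())
  expect_equal(segs$start, bf$start)
  expect_equal(segs$end, bf$end)
})

test_that("the scanner matches the brute-force enumerator exactly", {
  set.seed(50)
  rules <- rules_nomaf()
  for (rep in 1:60) {
    rc <- random_roh_chrom(500)
    got <- detect_roh(roh_geno(rc$pos, rc$call), "s1", rules)
    want <- brute_roh(rc$pos, rc$call, rules)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_snps, want$n_snps)
      expect_equal(got$n_het, want$n_het)
      expect_equal(got$n_missing, want$n_missing)
    }
  }
})

test_that("the MAF rule removes rare sites before scanning", {
  ## 100 informative SNPs; every 10th site is panel-monomorphic
  pos <- seq(10001, by = 10000, length.out = 100)
  d1 <- rep(0L, 100)
  d2 <- rep(c(1L, 2L), 50); d2[seq(10, 100, 10)] <- 0L
  d3 <- rep(c(1L, 0L), 50); d3[seq(10, 100, 10)] <- 0L
  g <- toy_geno(pos, cbind(d1, d2, d3))
  segs <- detect_roh(g, "s1", roh_rules(min_maf = 0.01))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snps, 90L)           # the rare sites are gone
  expect_error(detect_roh(g, "sX"), "unknown sample")
})

test_that("f_roh reproduces ratios, nests thresholds, rejects overlap", {
  segs <- data.frame(sample_id = "a", chrom = c("1", "2"),
                     start = c(0, 0), end = c(6e6, 8e5),
                     n_snps = c(600L, 80L), n_het = 0L, n_missing = 0L)
  out <- f_roh(segs, genome_length_kb = 10000)
  expect_equal(out$l_roh_kb[out$threshold_bp == 5e5], 6800)
  expect_equal(out$n_roh[out$threshold_bp == 5e5], 2L)
  expect_equal(out$l_roh_kb[out$threshold_bp == 5e6], 6000)
  expect_equal(out$f_roh, c(0.68, 0.60))
  ## every >5 Mb segment is also a >0.5 Mb segment
  expect_true(all(out$f_roh[out$threshold_bp == 5e6] <=
                    out$f_roh[out$threshold_bp == 5e5]))
  expect_equal(f_roh(segs[0, ], sample_ids = "a")$f_roh, c(0, 0))
  bad <- rbind(segs, data.frame(sample_id = "a", chrom = "1", start = 5e6,
                                end = 7e6, n_snps = 100L, n_het = 0L,
                                n_missing = 0L))
  expect_error(f_roh(bad), "overlapping")
})

test_that("textbook consanguineous matings give exact F values", {
  pd <- build_pedigree(loops = c("fullsib", "halfsib", "cousin"))
  expect_equal(pedigree_f(pd$ped, "L01X"), 0.25)
  expect_equal(pedigree_f(pd$ped, "L02X"), 0.125)
  expect_equal(pedigree_f(pd$ped, "L03X"), 0.0625)
  ## founders and non-inbred individuals
  expect_equal(pedigree_f(pd$ped, "L01F1"), 0)
  expect_equal(pedigree_f(pd$ped, "L01C1"), 0)
  expect_error(pedigree_f(pd$ped, "nobody"), "not in pedigree")
})

test_that("generation truncation zeroes loops deeper than the horizon", {
  pd <- build_pedigree(loops = "deep6")
  full <- pedigree_f(pd$ped, "L01X")
  ## single common ancestor at depth 6 on both sides: F = (1/2)^11
  ## (its founder parents add nothing: Wright paths may not revisit it)
  expect_equal(full, 2^-11)
  expect_equal(pedigree_f(pd$ped, "L01X", max_generations = 5), 0)
  expect_equal(pedigree_f(pd$ped, "L01X", max_generations = 10), full)
  ## monotone in depth
  f5 <- pedigree_f(pd$ped, "L01X", 5)
  f10 <- pedigree_f(pd$ped, "L01X", 10)
  expect_lte(f5, f10)
})

test_that("truncated F is monotone in depth across loop pedigrees", {
  pd <- build_pedigree(loops = c("fullsib", "halfsib", "cousin", "deep6"))
  for (x in c("L01X", "L02X", "L03X", "L04X")) {
    fs <- vapply(c(2, 5, 10, Inf), function(gn)
      pedigree_f(pd$ped, x, gn), 0)
    expect_true(all(diff(fs) >= -1e-12))
  }
})

test_that("realized autozygosity of loop offspring matches pedigree F", {
  set.seed(51)
  for (tpl in c("halfsib", "cousin")) {
    pd <- build_pedigree(loops = tpl)
    f_exp <- pedigree_f(pd$ped, "L01X")
    fracs <- replicate(150, {
      vt <- data.frame(chrom = as.character(1:4), pos = rep(1e6, 4),
                       id = paste0("m", 1:4), ref = "A", alt = "G")
      fh <- sample_haplotypes(rep(.5, 4), vt, pd$ped$id[pd$ped$sire == "0"])
      gd <- gene_drop(pd$ped, fh, rep(1e8, 4))
      tr <- gd$ibd_tracts[gd$ibd_tracts$id == "L01X", ]
      sum(tr$end - tr$start) / 4e8
    })
    se <- stats::sd(fracs) / sqrt(length(fracs))
    expect_lt(abs(mean(fracs) - f_exp), 4 * se + 0.005)
  }
})

test_that("planted autozygous tracts are recovered by the ROH caller", {
  set.seed(52)
  ## full-sib mating, 5 kb grid, engineered founder haplotypes (below)
  pd <- build_pedigree(loops = "fullsib")
  n <- 8000; len <- 4e7
  vt <- data.frame(chrom = "1", pos = 5000 * seq_len(n),
                   id = paste0("m", seq_len(n)), ref = "A", alt = "G")
  ## balanced allele patterns cycling with period 3: any two distinct
  ## founder haplotypes agree at exactly every third site, so runs of
  ## chance homozygosity outside true tracts are single isolated sites
  pat <- rbind(c(0, 1, 0, 1), c(0, 0, 1, 1), c(0, 1, 1, 0))
  H <- pat[rep(1:3, length.out = n), ]
  fh <- haplotype_matrix(vt, c("L01F1", "L01F2"), H)
  gd <- gene_drop(pd$ped, fh, len)
  g <- genotypes_from_haplotypes(gd$haps)
  segs <- detect_roh(g, "L01X", roh_rules(max_het = 0, min_maf = 0))
  truth <- gd$ibd_tracts[gd$ibd_tracts$id == "L01X", ]
  big <- truth[truth$end - truth$start >= 8e5, ]
  for (k in seq_len(nrow(big))) {
    hit <- segs[segs$start < big$end[k] & segs$end > big$start[k], ]
    expect_equal(nrow(hit), 1)
    expect_lte(abs(hit$start - big$start[k]), 5000)
    expect_lte(abs(hit$end - big$end[k]), 5000)
  }
  ## no false positives: every called segment sits inside a true tract
  for (k in seq_len(nrow(segs)))
    expect_true(any(truth$start - 5000 <= segs$start[k] &
                      truth$end + 5000 >= segs$end[k]))
})

test_that("f_correlation handles perfect, constant and undersized input", {
  roh <- data.frame(sample_id = c("a", "b", "c", "d"),
                    threshold_bp = 5e5,
                    l_roh_kb = c(100, 200, 300, 400), n_roh = 1:4,
                    f_roh = c(0.1, 0.2, 0.3, 0.4))
  ped <- data.frame(sample_id = c("a", "b", "c", "d"), generations = 5,
                    f_ped = c(0.1, 0.2, 0.3, 0.4))
  fc <- f_correlation(roh, ped)
  expect_equal(fc$correlations$r, 1)
  expect_true(all(c("F_ROH>0.5Mb", "F_PED5") %in% fc$histogram$measure))

  ped$f_ped <- 0.1
  fc2 <- f_correlation(roh, ped)
  expect_true(is.na(fc2$correlations$r))

  expect_error(f_correlation(roh[1:2, ], ped[1:2, ]), "at least 3")
})

test_that("shallow pedigrees understate F when deep loops dominate", {
  set.seed(53)
  ## genotyped cohort: offspring of deep loops plus recent loops
  pd <- build_pedigree(loops = c("deep6", "deep6", "deep6", "fullsib",
                                 "cousin", "halfsib"))
  ids <- pd$samples$sample_id[pd$samples$genotyped]
  f5 <- vapply(ids, function(s) pedigree_f(pd$ped, s, 5), 0)
  ffull <- vapply(ids, function(s) pedigree_f(pd$ped, s, Inf), 0)
  expect_true(all(f5 <= ffull))
  expect_gt(sum(ffull > f5), 0)
})
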