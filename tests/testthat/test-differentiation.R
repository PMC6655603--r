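one_window <- data.frame(chrom = "1", start = 0, end = 1e6)

test_that("single-site Hudson FST matches the hand-worked value", {
  ## popA: 10 haplotypes with 6 alt copies (p = 0.6); popB: 2/10 (p = 0.2)
  g <- toy_geno(pos = 100,
                dosage = matrix(c(2L, 2L, 1L, 1L, 0L,   # A: 5 diploids
                                  1L, 1L, 0L, 0L, 0L),  # B: 5 diploids
                                1))
  fst <- window_fst(g, paste0("s", 1:5), paste0("s", 6:10), one_window,
                    min_sites = 1)$fst
  num <- 0.16 - 0.6 * 0.4 / 9 - 0.2 * 0.8 / 9
  den <- 0.6 * 0.8 + 0.2 * 0.4
  expect_equal(fst, num / den)
  expect_equal(round(fst, 4), 0.2063)
})

test_that("FST hits the boundaries for fixed or identical populations", {
  ## fixed difference -> 1
  g <- toy_geno(pos = c(100, 200),
                dosage = rbind(rep(c(2L, 0L), each = 20),
                               rep(c(2L, 0L), each = 20)))
  fst <- window_fst(g, paste0("s", 1:20), paste0("s", 21:40), one_window,
                    min_sites = 1)$fst
  expect_equal(fst, 1)
  ## identical allele frequencies -> ~0 (small negative allowed)
  set.seed(40)
  d <- matrix(rbinom(200 * 100, 2, 0.4), 200)
  g2 <- toy_geno(pos = sort(sample(9e5, 200)), dosage = d)
  fst2 <- window_fst(g2, paste0("s", 1:50), paste0("s", 51:100), one_window,
                     min_sites = 1)$fst
  expect_lt(abs(fst2), 0.01)
  expect_error(window_fst(g2, paste0("s", 1:50), paste0("s", 50:100),
                          one_window), "overlapping")
})

test_that("windowed FST equals the brute-force per-site summation", {
  for (seed in 1:20) {
    set.seed(seed)
    n_sites <- sample(1:5, 1)
    g <- toy_geno(pos = sort(sample(9e5, n_sites)),
                  dosage = matrix(sample(c(0:2, NA), n_sites * 12,
                                         replace = TRUE), n_sites))
    got <- window_fst(g, paste0("s", 1:6), paste0("s", 7:12), one_window,
                      min_sites = 1)$fst
    want <- brute_window_fst(g, paste0("s", 1:6), paste0("s", 7:12))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("divergence-time transform clips and maps correctly", {
  expect_equal(divergence_time(0), 0)
  expect_equal(divergence_time(-0.01), 0)
  expect_equal(divergence_time(0.2), 0.223144, tolerance = 1e-5)
  expect_true(is.finite(divergence_time(1)))
  expect_true(is.na(divergence_time(NA)))
})

test_that("PBS combines branch lengths as half the focal excess", {
  expect_equal(pbs(0, 0, 0), 0)
  t <- 0.37
  expect_equal(pbs(t, t, t), t / 2)
  expect_equal(pbs(0.223144, 0.223144, 0.105361), 0.170464,
               tolerance = 1e-5)
  ## negative values are not floored
  expect_lt(pbs(0, 0, 0.4), 0)
})

test_that("three-taxon additivity: focal plus sister branch equals t_fs", {
  set.seed(41)
  cfg <- sim_config(n_chrom = 1, chrom_length_bp = 1e7,
                    n_sites_per_chrom = 1000,
                    n_pop = c(FOCAL = 15, SISTER = 15, OUTGROUP = 15),
                    families = integer(),
                    drift_F = c(FOCAL = .1, SISTER = .05, OUTGROUP = .2),
                    miss_rate = 0, seed = 41)
  p <- simulate_panel(cfg)
  w <- make_windows(c(`1` = 1e7), 1e6, 1e6)
  s1 <- pbs_scan(p$geno, p$samples, w)$windows
  swapped <- p$samples
  swapped$population[p$samples$population == "FOCAL"] <- "SISTER"
  swapped$population[p$samples$population == "SISTER"] <- "FOCAL"
  s2 <- pbs_scan(p$geno, swapped, w)$windows
  expect_equal(s1$pbs + s2$pbs, s1$t_fs, tolerance = 1e-10)
  expect_equal(s1$t_fs, s2$t_fs, tolerance = 1e-10)
})

test_that("PBS is invariant to which allele is labelled alternate", {
  set.seed(42)
  cfg <- sim_config(n_chrom = 1, chrom_length_bp = 5e6,
                    n_sites_per_chrom = 500,
                    n_pop = c(FOCAL = 10, SISTER = 10, OUTGROUP = 10),
                    families = integer(), miss_rate = 0, seed = 42)
  p <- simulate_panel(cfg)
  w <- make_windows(c(`1` = 5e6), 1e6, 2e5)
  s1 <- pbs_scan(p$geno, p$samples, w)$windows
  flip <- sample(c(TRUE, FALSE), nrow(p$geno$variants), replace = TRUE)
  d <- p$geno$dosage
  d[flip, ] <- 2L - d[flip, ]
  g2 <- genotype_matrix(p$geno$variants, p$geno$samples, d)
  s2 <- pbs_scan(g2, p$samples, w)$windows
  expect_equal(s1$pbs, s2$pbs, tolerance = 1e-12)
})

test_that("Hudson ratio-of-averages recovers the drift parameter", {
  for (F in c(0.05, 0.1, 0.2)) {
    set.seed(round(1000 * F))
    p <- runif(5e4, 0.05, 0.95)
    pA <- rbeta(5e4, p * (1 - F) / F, (1 - p) * (1 - F) / F)
    pB <- rbeta(5e4, p * (1 - F) / F, (1 - p) * (1 - F) / F)
    vt <- data.frame(chrom = "1", pos = seq_len(5e4) * 100,
                     id = paste0("m", seq_len(5e4)), ref = "A", alt = "G")
    dos <- cbind(matrix(rbinom(5e4 * 50, 2, pA), 5e4),
                 matrix(rbinom(5e4 * 50, 2, pB), 5e4))
    g <- genotype_matrix(vt, paste0("s", 1:100), dos)
    fst <- genome_fst(g, paste0("s", 1:50), paste0("s", 51:100))
    expect_lt(abs(fst - F), 0.01)
  }
})

test_that("the Weir-Cockerham switch gives a similar genome-wide value", {
  set.seed(43)
  p <- runif(2e4, 0.05, 0.95)
  F <- 0.1
  pA <- rbeta(2e4, p * (1 - F) / F, (1 - p) * (1 - F) / F)
  pB <- rbeta(2e4, p * (1 - F) / F, (1 - p) * (1 - F) / F)
  vt <- data.frame(chrom = "1", pos = seq_len(2e4) * 100,
                   id = paste0("m", seq_len(2e4)), ref = "A", alt = "G")
  dos <- cbind(matrix(rbinom(2e4 * 30, 2, pA), 2e4),
               matrix(rbinom(2e4 * 30, 2, pB), 2e4))
  g <- genotype_matrix(vt, paste0("s", 1:60), dos)
  h <- genome_fst(g, paste0("s", 1:30), paste0("s", 31:60))
  wc <- genome_fst(g, paste0("s", 1:30), paste0("s", 31:60),
                   estimator = "wc")
  expect_lt(abs(h - wc), 0.02)
})

test_that("a planted focal sweep tops the merged PBS regions", {
  cfg <- sim_config(n_chrom = 3, chrom_length_bp = 3e7,
                    n_sites_per_chrom = 3000,
                    n_pop = c(FOCAL = 40, SISTER = 20, OUTGROUP = 20),
                    families = integer(),
                    drift_F = c(FOCAL = .1, SISTER = .1, OUTGROUP = .1),
                    sweep_specs = list(list(population = "FOCAL",
                                            chrom = "2", start = 1.2e7,
                                            end = 1.4e7)),
                    miss_rate = 0, seed = 44)
  p <- simulate_panel(cfg)
  w <- make_windows(setNames(cfg$chrom_length_bp, as.character(1:3)),
                    1e6, 2e5)
  scan <- pbs_scan(p$geno, p$samples, w)
  top <- scan$top_regions[1, ]
  expect_equal(top$chrom, "2")
  expect_lt(top$start, 1.4e7)
  expect_gt(top$end, 1.2e7)
})

test_that("a sweep in the outgroup does not elevate the focal branch", {
  cfg <- sim_config(n_chrom = 2, chrom_length_bp = 3e7,
                    n_sites_per_chrom = 3000,
                    n_pop = c(FOCAL = 30, SISTER = 15, OUTGROUP = 30),
                    families = integer(),
                    drift_F = c(FOCAL = .1, SISTER = .1, OUTGROUP = .1),
                    sweep_specs = list(list(population = "OUTGROUP",
                                            chrom = "2", start = 1.2e7,
                                            end = 1.4e7)),
                    miss_rate = 0, seed = 45)
  p <- simulate_panel(cfg)
  w <- make_windows(setNames(cfg$chrom_length_bp, as.character(1:2)),
                    1e6, 2e5)
  scan <- pbs_scan(p$geno, p$samples, w)
  sw <- scan$windows
  inside <- sw$chrom == "2" & sw$start < 1.4e7 & sw$end > 1.2e7
  thr <- quantile(sw$pbs[!inside], 0.99, na.rm = TRUE)
  expect_lt(max(sw$pbs[inside], na.rm = TRUE), thr)
})

test_that("PBS is near zero without differentiation, positive under drift", {
  ## true null: all three groups sample the same (ancestral) frequencies
  cfg <- sim_config(n_chrom = 2, chrom_length_bp = 2e7,
                    n_sites_per_chrom = 2000,
                    n_pop = c(FOCAL = 25, SISTER = 25, OUTGROUP = 25),
                    families = integer(),
                    drift_F = c(FOCAL = 0, SISTER = 0, OUTGROUP = 0),
                    miss_rate = 0, seed = 46)
  p <- simulate_panel(cfg)
  w <- make_windows(setNames(cfg$chrom_length_bp, as.character(1:2)),
                    1e6, 2e5)
  sw <- pbs_scan(p$geno, p$samples, w)$windows
  expect_lt(abs(mean(sw$pbs, na.rm = TRUE)), 0.01)
  expect_lt(max(sw$pbs, na.rm = TRUE), 0.1)

  ## symmetric drift F gives each population its own branch of length
  ## -log(1 - F) / 2, so the PBS track centres near that, not near zero
  cfg2 <- sim_config(n_chrom = 2, chrom_length_bp = 2e7,
                     n_sites_per_chrom = 2000,
                     n_pop = c(FOCAL = 25, SISTER = 25, OUTGROUP = 25),
                     families = integer(),
                     drift_F = c(FOCAL = .1, SISTER = .1, OUTGROUP = .1),
                     miss_rate = 0, seed = 47)
  p2 <- simulate_panel(cfg2)
  sw2 <- pbs_scan(p2$geno, p2$samples, w)$windows
  branch <- -log(1 - 0.1) / 2
  expect_lt(abs(mean(sw2$pbs, na.rm = TRUE) - branch), 0.03)
})

test_that("pbs_scan demands all three population labels", {
  g <- toy_geno(pos = c(100, 200), dosage = matrix(0L, 2, 4))
  sm <- data.frame(sample_id = paste0("s", 1:4),
                   population = c("FOCAL", "FOCAL", "SISTER", "SISTER"))
  expect_error(pbs_scan(g, sm, one_window), "OUTGROUP")
})
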