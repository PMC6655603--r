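## Approximate autosome lengths (Mb) of the equCab2 horse assembly, used as
## the default simulated genome so chromosome-count statistics are on the
## scale of the real array data.
EQUINE_AUTOSOME_MB <- c(186, 121, 119, 109, 100, 85, 99, 94, 84, 84, 61, 33,
                        43, 94, 92, 87, 81, 82, 60, 64, 58, 50, 56, 47, 40,
                        42, 40, 46, 34, 30, 25)

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-panel generator. The defaults emulate
#' the study design the package targets: ~31 autosomes at equine lengths, an
#' array-ascertained common-SNP site grid, three population groups under
#' Balding-Nichols drift (two closely related breeds plus a pooled outgroup),
#' half-sib families of 31/25/19/17/15/10 offspring from ungenotyped sires,
#' and the remainder as unrelated focal samples.
#'
#' @param n_chrom number of autosomes.
#' @param chrom_length_bp chromosome lengths in bp (recycled to `n_chrom`).
#' @param n_sites_per_chrom array sites per chromosome (recycled); sites are
#'   laid out on an even grid, mimicking array spacing.
#' @param map_cM_per_Mb recombination rate (default 1 cM/Mb).
#' @param maf_window ancestral allele-frequency window `[min, max]`; the
#'   uniform draw is a proxy for common-SNP array ascertainment.
#' @param drift_F named Balding-Nichols drift parameter per population.
#' @param n_pop named number of genotyped diploids per population; the
#'   `FOCAL` entry is the number of *unrelated* focal samples added on top of
#'   the pedigreed half-sib offspring.
#' @param families half-sib family sizes (offspring per ungenotyped sire).
#' @param loops character vector of consanguineous-loop templates to insert
#'   (`"fullsib"`, `"halfsib"`, `"cousin"`, `"deep6"`), see [build_pedigree()].
#' @param sweep_specs list of sweeps, each
#'   `list(population=, chrom=, start=, end=)` (0-based half-open bp).
#' @param miss_rate,err_rate per-call missingness and genotyping-error rates.
#' @param seed integer seed from which all randomness flows.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 31,
                       chrom_length_bp = EQUINE_AUTOSOME_MB * 1e6,
                       n_sites_per_chrom = round(chrom_length_bp / 4000),
                       map_cM_per_Mb = 1,
                       maf_window = c(0.05, 0.95),
                       drift_F = c(FOCAL = 0.05, SISTER = 0.05,
                                   OUTGROUP = 0.2),
                       n_pop = c(FOCAL = 253, SISTER = 24, OUTGROUP = 287),
                       families = c(31, 25, 19, 17, 15, 10),
                       loops = character(),
                       sweep_specs = list(),
                       miss_rate = 0.002,
                       err_rate = 0,
                       seed = 1L) {
  chrom_length_bp <- rep_len(chrom_length_bp, n_chrom)
  n_sites_per_chrom <- rep_len(n_sites_per_chrom, n_chrom)
  stopifnot(all(drift_F >= 0), all(drift_F < 1),
            length(maf_window) == 2, maf_window[1] <= maf_window[2],
            miss_rate >= 0, miss_rate < 1, err_rate >= 0, err_rate < 1)
  for (sw in sweep_specs) {
    stopifnot(all(c("population", "chrom", "start", "end") %in% names(sw)))
    ci <- match(as.character(sw$chrom), as.character(seq_len(n_chrom)))
    if (is.na(ci) || sw$start < 0 || sw$end > chrom_length_bp[ci])
      stop("sweep interval outside chromosome bounds")
  }
  structure(list(n_chrom = n_chrom, chrom_length_bp = chrom_length_bp,
                 n_sites_per_chrom = n_sites_per_chrom,
                 map_cM_per_Mb = map_cM_per_Mb, maf_window = maf_window,
                 drift_F = drift_F, n_pop = n_pop, families = families,
                 loops = loops, sweep_specs = sweep_specs,
                 miss_rate = miss_rate, err_rate = err_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Variant grid implied by a simulation configuration
#'
#' Sites are evenly spaced along each chromosome, so the inter-SNP spacing is
#' `chrom_length_bp / n_sites` exactly (useful when reasoning about ROH
#' boundary resolution).
#'
#' @param cfg a [sim_config()].
#' @return A variant table data.frame (`chrom`, `pos`, `id`, `ref`, `alt`).
#' @export
variant_grid <- function(cfg) {
  out <- lapply(seq_len(cfg$n_chrom), function(ci) {
    n <- cfg$n_sites_per_chrom[ci]
    spacing <- floor(cfg$chrom_length_bp[ci] / (n + 1))
    pos <- spacing * seq_len(n)
    data.frame(chrom = as.character(ci), pos = pos,
               id = sprintf("snp_%d_%d", ci, seq_len(n)),
               ref = "A", alt = "G")
  })
  do.call(rbind, out)
}

#' Simulate ancestral and per-population allele frequencies
#'
#' Ancestral frequency per site is Uniform over `cfg$maf_window` (a proxy for
#' common-SNP array ascertainment). Each population's frequency is drawn
#' independently from the Balding-Nichols distribution
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose mean is the ancestral `p` and whose
#' FST relative to the ancestor equals `F`. `F = 0` degenerates to the
#' ancestral frequency itself. Sweep intervals then overwrite the swept
#' population's frequencies with near-fixation (0.99) of the ancestrally
#' major allele.
#'
#' @param cfg a [sim_config()].
#' @param variants optional variant table (defaults to [variant_grid()]).
#' @return list with `variants`, `ancestral` (numeric per site) and `pop`
#'   (site x population matrix).
#' @export
simulate_frequencies <- function(cfg, variants = variant_grid(cfg)) {
  n <- nrow(variants)
  p <- runif(n, cfg$maf_window[1], cfg$maf_window[2])
  pops <- names(cfg$drift_F)
  pm <- matrix(NA_real_, n, length(pops), dimnames = list(NULL, pops))
  for (k in pops) {
    F <- cfg$drift_F[[k]]
    pm[, k] <- if (F == 0) p else
      rbeta(n, p * (1 - F) / F, (1 - p) * (1 - F) / F)
  }
  for (sw in cfg$sweep_specs) {
    idx <- variants$chrom == as.character(sw$chrom) &
      variants$pos - 1 >= sw$start & variants$pos - 1 < sw$end
    pm[idx, sw$population] <- ifelse(p[idx] >= 0.5, 0.99, 0.01)
  }
  list(variants = variants, ancestral = p, pop = pm)
}

#' Sample unrelated diploid genotypes from population frequencies
#'
#' @param freq numeric vector of per-site alternate-allele frequencies.
#' @param variants variant table aligned with `freq`.
#' @param ids sample IDs to create.
#' @return A [genotype_matrix()] with Hardy-Weinberg genotypes.
#' @export
sample_genotypes <- function(freq, variants, ids) {
  d <- matrix(rbinom(length(freq) * length(ids), 2, rep(freq, length(ids))),
              nrow = length(freq))
  genotype_matrix(variants, ids, d)
}

#' Sample unrelated phased haplotypes from population frequencies
#'
#' @inheritParams sample_genotypes
#' @return A [haplotype_matrix()].
#' @export
sample_haplotypes <- function(freq, variants, ids) {
  h <- matrix(rbinom(length(freq) * 2 * length(ids), 1,
                     rep(freq, 2 * length(ids))),
              nrow = length(freq))
  haplotype_matrix(variants, ids, h)
}

## ---------------------------------------------------------------------------
## Pedigree construction
## ---------------------------------------------------------------------------

loop_template <- function(kind, tag) {
  id <- function(x) paste0(tag, x)
  F0 <- MISSING_PARENT
  rows <- switch(
    kind,
    fullsib = rbind(
      c(id("F1"), F0, F0), c(id("F2"), F0, F0),
      c(id("C1"), id("F1"), id("F2")), c(id("C2"), id("F1"), id("F2")),
      c(id("X"), id("C1"), id("C2"))),
    halfsib = rbind(
      c(id("F1"), F0, F0), c(id("F2"), F0, F0), c(id("F3"), F0, F0),
      c(id("C1"), id("F1"), id("F2")), c(id("C2"), id("F1"), id("F3")),
      c(id("X"), id("C1"), id("C2"))),
    cousin = rbind(
      c(id("F1"), F0, F0), c(id("F2"), F0, F0),
      c(id("S1"), F0, F0), c(id("S2"), F0, F0),
      c(id("P1"), id("F1"), id("F2")), c(id("P2"), id("F1"), id("F2")),
      c(id("K1"), id("P1"), id("S1")), c(id("K2"), id("P2"), id("S2")),
      c(id("X"), id("K1"), id("K2"))),
    deep6 = {
      ## common ancestor B sits 6 generations above X on both sides
      m <- rbind(c(id("A1"), F0, F0), c(id("A2"), F0, F0),
                 c(id("B"), id("A1"), id("A2")))
      for (side in c("L", "R")) {
        prev <- id("B")
        for (g in 1:5) {
          u <- id(paste0("U", side, g)); v <- id(paste0(side, g))
          m <- rbind(m, c(u, F0, F0), c(v, prev, u))
          prev <- v
        }
      }
      rbind(m, c(id("X"), id("L5"), id("R5")))
    },
    stop("unknown loop template: ", kind))
  data.frame(id = rows[, 1], sire = rows[, 2], dam = rows[, 3],
             stringsAsFactors = FALSE)
}

#' Build a pedigree of half-sib families and consanguineous loops
#'
#' Half-sib families share one ungenotyped sire with distinct unrelated dams
#' (the structure of sire-centred horse breeding). Loop templates insert
#' textbook consanguineous matings whose offspring carry known expected
#' inbreeding: `"fullsib"` (F = 0.25), `"halfsib"` (F = 0.125), `"cousin"`
#' (first cousins, F = 0.0625) and `"deep6"` (the only common ancestor sits
#' six generations deep, so a 5-generation truncated coefficient is 0).
#'
#' @param families integer vector of half-sib family sizes.
#' @param loops character vector of template names (repeats allowed).
#' @param n_unrelated number of additional unrelated genotyped founders.
#' @return list with `ped` (a validated `pedigree`) and `samples`, a
#'   data.frame with `sample_id`, `population` (`FOCAL`), `sire_id`, `sex`,
#'   `role` and `genotyped` (half-sib offspring, loop offspring and unrelated
#'   founders are genotyped; sires, dams and internal loop members are not).
#' @export
build_pedigree <- function(families = integer(), loops = character(),
                           n_unrelated = 0) {
  stopifnot(all(families >= 1))
  rows <- list(); meta <- list()
  add <- function(id, sire, dam, role, genotyped, sire_id = NA_character_) {
    rows[[length(rows) + 1]] <<- data.frame(id = id, sire = sire, dam = dam)
    meta[[length(meta) + 1]] <<- data.frame(
      sample_id = id, population = "FOCAL", sire_id = sire_id,
      sex = NA_character_, role = role, genotyped = genotyped)
  }
  for (i in seq_along(families)) {
    s <- sprintf("S%02d", i)
    add(s, MISSING_PARENT, MISSING_PARENT, "sire", FALSE)
    for (j in seq_len(families[i])) {
      dm <- sprintf("D%02d_%02d", i, j)
      off <- sprintf("O%02d_%02d", i, j)
      add(dm, MISSING_PARENT, MISSING_PARENT, "dam", FALSE)
      add(off, s, dm, "halfsib_offspring", TRUE, sire_id = s)
    }
  }
  for (i in seq_along(loops)) {
    tpl <- loop_template(loops[i], sprintf("L%02d", i))
    for (r in seq_len(nrow(tpl))) {
      is_x <- grepl("X$", tpl$id[r])
      add(tpl$id[r], tpl$sire[r], tpl$dam[r],
          role = if (is_x) paste0("loop_", loops[i]) else "loop_internal",
          genotyped = is_x,
          sire_id = if (is_x) tpl$sire[r] else NA_character_)
    }
  }
  for (j in seq_len(n_unrelated)) {
    add(sprintf("U%03d", j), MISSING_PARENT, MISSING_PARENT,
        "unrelated", TRUE)
  }
  ped_df <- do.call(rbind, rows)
  if (is.null(ped_df))
    return(list(ped = pedigree_table(character(), character(), character()),
                samples = do.call(rbind, meta)))
  list(ped = pedigree_table(ped_df$id, ped_df$sire, ped_df$dam),
       samples = do.call(rbind, meta))
}

## ---------------------------------------------------------------------------
## Gene dropping
## ---------------------------------------------------------------------------

## An ancestry track is, per chromosome, a data.frame(start, end, hap) of
## 0-based half-open bp intervals labelled with the founder-haplotype column
## they descend from. Meioses operate on these intervals, so crossover and
## autozygosity truth is exact in bp, independent of the site grid.

slice_track <- function(track, s, e) {
  keep <- track$end > s & track$start < e
  out <- track[keep, , drop = FALSE]
  if (nrow(out)) {
    out$start <- pmax(out$start, s)
    out$end <- pmin(out$end, e)
  }
  out
}

meiose <- function(gam1, gam2, chrom_length_bp, morgans_per_bp) {
  n_chr <- length(chrom_length_bp)
  out <- vector("list", n_chr)
  breaks <- vector("list", n_chr)
  for (ci in seq_len(n_chr)) {
    len <- chrom_length_bp[ci]
    k <- rpois(1, len * morgans_per_bp)
    bp <- sort(runif(k, 0, len))
    bp <- bp[bp > 0 & bp < len]           # breakpoints strictly inside
    strand <- sample(1:2, 1)
    bounds <- c(0, bp, len)
    pieces <- vector("list", length(bounds) - 1)
    for (seg in seq_len(length(bounds) - 1)) {
      src <- if ((seg + strand) %% 2 == 0) gam1[[ci]] else gam2[[ci]]
      pieces[[seg]] <- slice_track(src, bounds[seg], bounds[seg + 1])
    }
    tr <- do.call(rbind, pieces)
    ## merge touching intervals with identical origin
    if (nrow(tr) > 1) {
      same <- tr$hap[-1] == tr$hap[-nrow(tr)] &
        tr$start[-1] == tr$end[-nrow(tr)]
      grp <- cumsum(c(TRUE, !same))
      tr <- data.frame(start = tapply(tr$start, grp, min),
                       end = tapply(tr$end, grp, max),
                       hap = tr$hap[!duplicated(grp)])
    }
    rownames(tr) <- NULL
    out[[ci]] <- tr
    breaks[[ci]] <- bp
  }
  list(track = out, breaks = breaks)
}

autozygous_tracts <- function(t1, t2, chrom_length_bp) {
  res <- list()
  for (ci in seq_along(chrom_length_bp)) {
    cuts <- sort(unique(c(0, t1[[ci]]$end, t2[[ci]]$end,
                          chrom_length_bp[ci])))
    s <- cuts[-length(cuts)]; e <- cuts[-1]
    mid <- (s + e) / 2
    h1 <- t1[[ci]]$hap[findInterval(mid, t1[[ci]]$start)]
    h2 <- t2[[ci]]$hap[findInterval(mid, t2[[ci]]$start)]
    auto <- h1 == h2
    if (!any(auto)) next
    grp <- cumsum(c(TRUE, diff(auto) != 0))[auto]
    res[[length(res) + 1]] <- data.frame(
      chrom = as.character(ci),
      start = tapply(s[auto], grp, min),
      end = tapply(e[auto], grp, max))
  }
  if (!length(res))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  out <- do.call(rbind, res); rownames(out) <- NULL; out
}

#' Drop founder haplotypes through a pedigree
#'
#' Simulates every meiosis in the pedigree: crossover counts are Poisson
#' with mean equal to the chromosome's genetic length in Morgans (no
#' interference), breakpoints uniform, and the transmitted gamete is a
#' mosaic of the parent's two haplotypes. Returns the realized haplotypes of
#' all individuals plus the full ground truth: every crossover breakpoint
#' and every autozygous (identical founder-haplotype) tract.
#'
#' @param ped a `pedigree`; every individual must either be a founder (both
#'   parents unknown) or have both parents in the pedigree.
#' @param founder_haps a [haplotype_matrix()] whose samples are exactly the
#'   pedigree founders.
#' @param chrom_length_bp named or ordered chromosome lengths in bp, matching
#'   the chromosomes in `founder_haps$variants` (labelled "1", "2", ...).
#' @param map_cM_per_Mb recombination rate.
#' @return list with `haps` (haplotype_matrix over all pedigree members),
#'   `crossovers` (data.frame child, parent, chrom, pos_bp), `ibd_tracts`
#'   (data.frame id, chrom, start, end; 0-based half-open).
#' @export
gene_drop <- function(ped, founder_haps, chrom_length_bp, map_cM_per_Mb = 1) {
  stopifnot(inherits(ped, "pedigree"), inherits(founder_haps, "hap_matrix"))
  founders <- ped$id[ped$sire == MISSING_PARENT & ped$dam == MISSING_PARENT]
  half <- ped$id[xor(ped$sire == MISSING_PARENT, ped$dam == MISSING_PARENT)]
  if (length(half))
    stop("individual with exactly one known parent: ", half[1])
  missing_f <- setdiff(founders, founder_haps$samples)
  if (length(missing_f))
    stop("missing founder haplotypes for: ",
         paste(head(missing_f, 5), collapse = ", "))
  chroms <- unique(founder_haps$variants$chrom)
  stopifnot(length(chrom_length_bp) == length(chroms))
  morgans_per_bp <- map_cM_per_Mb / 100 / 1e6

  tracks <- new.env(parent = emptyenv())
  whole <- function(hapcol) {
    lapply(seq_along(chroms), function(ci)
      data.frame(start = 0, end = chrom_length_bp[ci], hap = hapcol))
  }
  for (f in founders) {
    i <- match(f, founder_haps$samples)
    assign(f, list(whole(2L * i - 1L), whole(2L * i)), envir = tracks)
  }
  ## topological order
  order_ids <- character(0)
  remaining <- ped[!(ped$id %in% founders), , drop = FALSE]
  done <- founders
  while (nrow(remaining) > 0) {
    ready <- remaining$sire %in% done & remaining$dam %in% done
    if (!any(ready)) stop("pedigree is not acyclic")
    order_ids <- c(order_ids, remaining$id[ready])
    done <- c(done, remaining$id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  xov <- list()
  for (id in order_ids) {
    rec <- ped[ped$id == id, ]
    gam <- vector("list", 2)
    for (pi in 1:2) {
      parent <- if (pi == 1) rec$sire else rec$dam
      ptr <- get(parent, envir = tracks)
      m <- meiose(ptr[[1]], ptr[[2]], chrom_length_bp, morgans_per_bp)
      gam[[pi]] <- m$track
      for (ci in seq_along(chroms)) {
        if (length(m$breaks[[ci]]))
          xov[[length(xov) + 1]] <- data.frame(
            child = id, parent = parent, chrom = chroms[ci],
            pos_bp = m$breaks[[ci]])
      }
    }
    assign(id, gam, envir = tracks)
  }
  crossovers <- if (length(xov)) do.call(rbind, xov) else
    data.frame(child = character(), parent = character(),
               chrom = character(), pos_bp = numeric())

  ## realized haplotypes at the site grid
  vt <- founder_haps$variants
  pos0 <- vt$pos - 1
  chrom_idx <- match(vt$chrom, chroms)
  all_ids <- ped$id
  H <- matrix(NA_integer_, nrow(vt), 2L * length(all_ids))
  tract_rows <- list()
  for (k in seq_along(all_ids)) {
    tr <- get(all_ids[k], envir = tracks)
    for (g in 1:2) {
      src <- integer(nrow(vt))
      for (ci in seq_along(chroms)) {
        sel <- chrom_idx == ci
        t <- tr[[g]][[ci]]
        src[sel] <- t$hap[findInterval(pos0[sel], t$start)]
      }
      H[, 2L * k - 2L + g] <- founder_haps$haps[cbind(seq_len(nrow(vt)), src)]
    }
    tct <- autozygous_tracts(tr[[1]], tr[[2]], chrom_length_bp)
    if (nrow(tct))
      tract_rows[[length(tract_rows) + 1]] <-
        cbind(data.frame(id = all_ids[k]), tct)
  }
  ibd <- if (length(tract_rows)) do.call(rbind, tract_rows) else
    data.frame(id = character(), chrom = character(), start = numeric(),
               end = numeric())
  rownames(ibd) <- NULL
  list(haps = haplotype_matrix(vt, all_ids, H),
       crossovers = crossovers, ibd_tracts = ibd)
}

#' Degrade phased haplotypes into array-like genotype calls
#'
#' Dosage is the haplotype sum; each call is independently perturbed to one
#' of the two other dosage values with probability `err_rate`, then set
#' missing with probability `miss_rate` (missingness wins).
#'
#' @param h a [haplotype_matrix()].
#' @param miss_rate,err_rate per-call rates in `[0, 1)` (`miss_rate = 1`
#'   allowed: everything missing).
#' @param seed optional integer seed.
#' @return A [genotype_matrix()].
#' @export
genotypes_from_haplotypes <- function(h, miss_rate = 0, err_rate = 0,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- as_geno_matrix(h)
  d <- g$dosage
  if (err_rate > 0) {
    hit <- which(!is.na(d) & runif(length(d)) < err_rate)
    if (length(hit)) {
      shift <- sample(1:2, length(hit), replace = TRUE)
      d[hit] <- (d[hit] + shift) %% 3L
    }
  }
  if (miss_rate > 0)
    d[runif(length(d)) < miss_rate] <- NA_integer_
  genotype_matrix(g$variants, g$samples, d)
}

## ---------------------------------------------------------------------------
## Full panel
## ---------------------------------------------------------------------------

#' Simulate a complete multi-population pedigreed SNP panel
#'
#' End-to-end generator: draws the site grid and population frequencies,
#' builds the focal-breed pedigree (half-sib families, loops, unrelated
#' samples), drops founder haplotypes through it, samples unrelated phased
#' diploids for the sister and outgroup populations, and degrades the
#' combined haplotypes into genotype calls. All randomness flows from
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `geno` (genotype_matrix of all genotyped samples),
#'   `haps` (true phased haplotypes for the same samples), `samples`
#'   (metadata with `population`, `sire_id`, `genotyped`), `ped` (focal
#'   pedigree), and `truth` (list: `freqs`, `crossovers`, `ibd_tracts`,
#'   `sweep_specs`, `chrom_length_bp`).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  variants <- variant_grid(cfg)
  fq <- simulate_frequencies(cfg, variants)

  pd <- build_pedigree(cfg$families, cfg$loops,
                       n_unrelated = cfg$n_pop[["FOCAL"]])
  founders <- pd$ped$id[pd$ped$sire == MISSING_PARENT &
                          pd$ped$dam == MISSING_PARENT]
  fh <- sample_haplotypes(fq$pop[, "FOCAL"], variants, founders)
  gd <- gene_drop(pd$ped, fh, cfg$chrom_length_bp, cfg$map_cM_per_Mb)

  focal_ids <- pd$samples$sample_id[pd$samples$genotyped]
  keep <- match(focal_ids, gd$haps$samples)
  cols <- as.vector(rbind(2L * keep - 1L, 2L * keep))
  focal_h <- haplotype_matrix(variants, focal_ids,
                              gd$haps$haps[, cols, drop = FALSE])

  sister_ids <- sprintf("ST%03d", seq_len(cfg$n_pop[["SISTER"]]))
  out_ids <- sprintf("NT%03d", seq_len(cfg$n_pop[["OUTGROUP"]]))
  sh <- sample_haplotypes(fq$pop[, "SISTER"], variants, sister_ids)
  oh <- sample_haplotypes(fq$pop[, "OUTGROUP"], variants, out_ids)

  all_ids <- c(focal_ids, sister_ids, out_ids)
  haps <- haplotype_matrix(variants, all_ids,
                           cbind(focal_h$haps, sh$haps, oh$haps))
  geno <- genotypes_from_haplotypes(haps, cfg$miss_rate, cfg$err_rate)

  samples <- rbind(
    pd$samples,
    data.frame(sample_id = c(sister_ids, out_ids),
               population = rep(c("SISTER", "OUTGROUP"),
                                c(length(sister_ids), length(out_ids))),
               sire_id = NA_character_, sex = NA_character_,
               role = "unrelated", genotyped = TRUE))

  list(geno = geno, haps = haps, samples = samples, ped = pd$ped,
       truth = list(freqs = fq, crossovers = gd$crossovers,
                    ibd_tracts = gd$ibd_tracts,
                    sweep_specs = cfg$sweep_specs,
                    chrom_length_bp = cfg$chrom_length_bp))
}
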