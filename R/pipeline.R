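#' Pipeline run configuration
#'
#' A single configuration object shared by every [run_stage()] stage, with
#' defaults mirroring the standard analysis parameters: 1 Mb windows with
#' 200 kb increments, ROH thresholds of 0.5 and 5 Mb, pedigree depths of 5
#' and 10 generations, and 1 Mb / 1 kb LD binning.
#'
#' @param vcf,pedigree,samples input file paths (VCF genotypes, 3-column
#'   pedigree, sample metadata TSV). Stages that need a missing input fail
#'   naming the path.
#' @param out_dir output directory (created if needed).
#' @param window_bp,step_bp sliding-window geometry.
#' @param min_sites minimum sites per window.
#' @param roh a [roh_rules()] list.
#' @param roh_thresholds_bp F_ROH length thresholds.
#' @param genome_length_kb genome length for F_ROH.
#' @param generations pedigree truncation depths.
#' @param support_k half-sib phasing conflict support.
#' @param min_family_size minimum half-sib family size.
#' @param ld_max_dist_bp,ld_bin_bp LD decay geometry.
#' @param fst_estimator `"hudson"` or `"wc"`.
#' @param sim a [sim_config()] used by the `simulate` stage.
#' @param seed integer seed recorded in every output header.
#' @return list of class `run_config`.
#' @export
run_config <- function(vcf = NULL, pedigree = NULL, samples = NULL,
                       out_dir = "eqpopgen_run",
                       window_bp = 1e6, step_bp = 2e5, min_sites = 10,
                       roh = roh_rules(), roh_thresholds_bp = c(5e5, 5e6),
                       genome_length_kb = 2243000, generations = c(5, 10),
                       support_k = 3, min_family_size = 10,
                       ld_max_dist_bp = 1e6, ld_bin_bp = 1000,
                       fst_estimator = "hudson",
                       sim = sim_config(), seed = 1L) {
  structure(list(vcf = vcf, pedigree = pedigree, samples = samples,
                 out_dir = out_dir, window_bp = window_bp, step_bp = step_bp,
                 min_sites = min_sites, roh = roh,
                 roh_thresholds_bp = roh_thresholds_bp,
                 genome_length_kb = genome_length_kb,
                 generations = generations, support_k = support_k,
                 min_family_size = min_family_size,
                 ld_max_dist_bp = ld_max_dist_bp, ld_bin_bp = ld_bin_bp,
                 fst_estimator = fst_estimator, sim = sim,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys override [run_config()] defaults; `roh:` and `sim:`
#' sub-maps override [roh_rules()] and [sim_config()] fields.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  roh <- do.call(roh_rules, y$roh %||% list())
  sim <- do.call(sim_config, y$sim %||% list())
  y$roh <- NULL; y$sim <- NULL
  do.call(run_config, c(y, list(roh = roh, sim = sim)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cfg_inputs <- function(cfg, needed) {
  for (nm in needed) {
    p <- cfg[[nm]]
    if (is.null(p) || !file.exists(p))
      stop("stage input missing: ", nm, " (", p %||% "unset", ")")
  }
}

stage_header <- function(cfg, stage) {
  sprintf("eqpopgen %s stage=%s seed=%d config_hash=%s",
          as.character(utils::packageVersion("eqpopgen")), stage, cfg$seed,
          substr(tools::md5sum(
            files = write_tmp_cfg(cfg))[[1]], 1, 8))
}

write_tmp_cfg <- function(cfg) {
  f <- file.path(tempdir(), "eqpopgen_cfg_echo.txt")
  writeLines(utils::capture.output(utils::str(cfg)), f)
  f
}

write_manifest <- function(cfg, stage, inputs, outputs) {
  man <- list(tool = "eqpopgen",
              version = as.character(utils::packageVersion("eqpopgen")),
              stage = stage, seed = cfg$seed,
              config = cfg[setdiff(names(cfg), c("roh", "sim"))],
              roh_rules = unclass(cfg$roh),
              inputs = lapply(inputs, function(p)
                list(path = p, md5 = unname(tools::md5sum(p)))),
              outputs = outputs)
  path <- file.path(cfg$out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  path
}

#' Run one pipeline stage (or all of them)
#'
#' Stages: `simulate` (write a synthetic panel: VCF, pedigree, sample TSV
#' and truth tracks), `diversity` (per-population sliding-window
#' heterozygosity), `fst-pbs` (windowed pairwise FST, divergence times and
#' the PBS scan with top regions), `roh` (ROH segments and F_ROH
#' summaries), `pedf` (truncated pedigree inbreeding and the F_ROH/F_PED
#' correlations), `phase-halfsib` (sire haplotypes, offspring blocks and
#' recombination summaries), `ld-decay` (binned r-squared decay curve), or
#' `all` (everything in dependency order, simulating first when no VCF is
#' configured). Each stage writes its outputs plus a JSON manifest with the
#' package version, a config echo and input checksums; reruns with the same
#' config and seed are identical for the deterministic stages.
#'
#' @param stage stage name.
#' @param cfg a [run_config()].
#' @return character vector of written file paths, invisibly.
#' @export
run_stage <- function(stage = c("simulate", "phase-halfsib", "diversity",
                                "fst-pbs", "roh", "pedf", "ld-decay", "all"),
                      cfg = run_config()) {
  stage <- match.arg(stage)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    if (is.null(cfg$vcf)) {
      run_stage("simulate", cfg)
      cfg$vcf <- file.path(cfg$out_dir, "panel.vcf")
      cfg$pedigree <- file.path(cfg$out_dir, "pedigree.tsv")
      cfg$samples <- file.path(cfg$out_dir, "samples.tsv")
    }
    for (s in c("phase-halfsib", "diversity", "fst-pbs", "roh", "pedf",
                "ld-decay"))
      run_stage(s, cfg)
    return(invisible(list.files(cfg$out_dir, full.names = TRUE)))
  }
  t0 <- Sys.time()
  message("[eqpopgen] stage ", stage, " started")
  hdr <- stage_header(cfg, stage)
  out <- switch(stage,
    simulate = stage_simulate(cfg, hdr),
    diversity = stage_diversity(cfg, hdr),
    `fst-pbs` = stage_fst_pbs(cfg, hdr),
    roh = stage_roh(cfg, hdr),
    pedf = stage_pedf(cfg, hdr),
    `phase-halfsib` = stage_phase(cfg, hdr),
    `ld-decay` = stage_ld(cfg, hdr))
  man <- write_manifest(cfg, stage, out$inputs, out$outputs)
  message(sprintf("[eqpopgen] stage %s done in %.1fs", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(c(out$outputs, man))
}

out_path <- function(cfg, name) file.path(cfg$out_dir, name)

write_tsv <- function(df, path, hdr) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

stage_simulate <- function(cfg, hdr) {
  panel <- simulate_panel(cfg$sim)
  paths <- c(
    write_vcf(panel$geno, out_path(cfg, "panel.vcf"),
              header_lines = paste0("##", hdr)),
    write_vcf(panel$haps, out_path(cfg, "panel_phased.vcf"),
              header_lines = paste0("##", hdr)),
    { write_pedigree(panel$ped, out_path(cfg, "pedigree.tsv")) },
    write_sample_table(panel$samples, out_path(cfg, "samples.tsv")),
    write_tsv(panel$truth$crossovers, out_path(cfg, "truth_crossovers.tsv"),
              hdr),
    write_tsv(panel$truth$ibd_tracts, out_path(cfg, "truth_ibd_tracts.tsv"),
              hdr),
    write_tsv(data.frame(
      chrom = as.character(seq_along(cfg$sim$chrom_length_bp)),
      length_bp = cfg$sim$chrom_length_bp),
      out_path(cfg, "chrom_lengths.tsv"), hdr))
  if (length(cfg$sim$sweep_specs)) {
    sw <- do.call(rbind, lapply(cfg$sim$sweep_specs, as.data.frame))
    paths <- c(paths, write_tsv(sw, out_path(cfg, "truth_sweeps.tsv"), hdr))
  }
  list(inputs = character(), outputs = paths)
}

load_panel <- function(cfg) {
  cfg_inputs(cfg, c("vcf", "samples"))
  v <- read_vcf(cfg$vcf)
  samples <- read_sample_table(cfg$samples)
  list(geno = v$geno, haps = v$haps, samples = samples)
}

panel_chrom_lengths <- function(cfg, vt) {
  f <- out_path(cfg, "chrom_lengths.tsv")
  if (file.exists(f)) {
    t <- read_window_stats(f)
    setNames(t$length_bp, t$chrom)
  } else {
    tapply(vt$pos, vt$chrom, max)
  }
}

stage_diversity <- function(cfg, hdr) {
  p <- load_panel(cfg)
  windows <- make_windows(panel_chrom_lengths(cfg, p$geno$variants),
                          cfg$window_bp, cfg$step_bp)
  paths <- character()
  for (pop in unique(p$samples$population)) {
    ids <- intersect(p$samples$sample_id[p$samples$population == pop],
                     p$geno$samples)
    if (length(ids) == 0) next
    het <- site_heterozygosity(p$geno, ids)
    wm <- window_mean(het, p$geno$variants, windows, cfg$min_sites)
    f <- out_path(cfg, sprintf("diversity_%s.tsv", tolower(pop)))
    write_window_stats(wm, f, comment = hdr)
    paths <- c(paths, f)
  }
  list(inputs = c(cfg$vcf, cfg$samples), outputs = paths)
}

stage_fst_pbs <- function(cfg, hdr) {
  p <- load_panel(cfg)
  windows <- make_windows(panel_chrom_lengths(cfg, p$geno$variants),
                          cfg$window_bp, cfg$step_bp)
  scan <- pbs_scan(p$geno, p$samples, windows, cfg$min_sites,
                   estimator = cfg$fst_estimator)
  f1 <- out_path(cfg, "pbs_windows.tsv")
  write_window_stats(scan$windows, f1, comment = hdr)
  f2 <- write_tsv(scan$top_regions, out_path(cfg, "pbs_top_regions.tsv"),
                  hdr)
  list(inputs = c(cfg$vcf, cfg$samples), outputs = c(f1, f2))
}

stage_roh <- function(cfg, hdr) {
  p <- load_panel(cfg)
  ids <- p$samples$sample_id[p$samples$population == "FOCAL" &
                               p$samples$sample_id %in% p$geno$samples]
  segs <- do.call(rbind, lapply(ids, function(s)
    detect_roh(p$geno, s, cfg$roh)))
  summ <- f_roh(segs, cfg$genome_length_kb, cfg$roh_thresholds_bp,
                sample_ids = ids)
  f1 <- write_tsv(segs, out_path(cfg, "roh_segments.tsv"), hdr)
  f2 <- write_tsv(summ, out_path(cfg, "roh_summary.tsv"), hdr)
  list(inputs = c(cfg$vcf, cfg$samples), outputs = c(f1, f2))
}

stage_pedf <- function(cfg, hdr) {
  cfg_inputs(cfg, c("pedigree", "samples"))
  ped <- read_pedigree(cfg$pedigree)
  samples <- read_sample_table(cfg$samples)
  ids <- intersect(samples$sample_id, ped$id)
  fp <- pedigree_f_table(ped, ids, cfg$generations)
  f1 <- write_tsv(fp, out_path(cfg, "fped.tsv"), hdr)
  paths <- f1
  roh_file <- out_path(cfg, "roh_summary.tsv")
  if (file.exists(roh_file)) {
    roh <- read_window_stats(roh_file)
    fc <- tryCatch(f_correlation(roh, fp), error = function(e) NULL)
    if (!is.null(fc))
      paths <- c(paths, write_tsv(fc$correlations,
                                  out_path(cfg, "f_correlations.tsv"), hdr))
  }
  list(inputs = c(cfg$pedigree, cfg$samples), outputs = paths)
}

stage_phase <- function(cfg, hdr) {
  p <- load_panel(cfg)
  fams <- detect_families(p$geno, p$samples, cfg$min_family_size)
  paths <- character()
  if (length(fams)) {
    lens <- panel_chrom_lengths(cfg, p$geno$variants)
    phases <- lapply(fams, infer_sire_phase, support_k = cfg$support_k,
                     chrom_lengths = lens,
                     min_family_size = cfg$min_family_size)
    for (ph in phases) {
      hm <- haplotype_matrix(ph$informative_sites, ph$sire_id,
                             cbind(ph$sire_hap0, ph$sire_hap1))
      fv <- out_path(cfg, sprintf("sire_phase_%s.vcf", ph$sire_id))
      write_vcf(hm, fv, header_lines = paste0("##", hdr))
      fb <- write_tsv(ph$blocks,
                      out_path(cfg, sprintf("sire_blocks_%s.tsv",
                                            ph$sire_id)), hdr)
      paths <- c(paths, fv, fb)
    }
    sm <- summarize_recombination(phases, lens)
    paths <- c(paths,
               write_tsv(sm$families,
                         out_path(cfg, "recomb_families.tsv"), hdr),
               write_tsv(sm$per_chrom,
                         out_path(cfg, "recomb_per_chrom.tsv"), hdr))
  }
  list(inputs = c(cfg$vcf, cfg$samples), outputs = paths)
}

stage_ld <- function(cfg, hdr) {
  p <- load_panel(cfg)
  if (is.null(p$haps)) {
    alt <- out_path(cfg, "panel_phased.vcf")
    if (file.exists(alt)) p$haps <- read_vcf(alt)$haps
  }
  if (is.null(p$haps))
    stop("ld-decay needs a phased VCF (| separators): ", cfg$vcf)
  dc <- decay_curve(p$haps, cfg$ld_max_dist_bp, cfg$ld_bin_bp)
  f <- write_tsv(dc$bins, out_path(cfg, "ld_decay.tsv"), hdr)
  list(inputs = cfg$vcf, outputs = f)
}
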