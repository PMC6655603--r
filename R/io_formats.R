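#' eqpopgen: population genomics for pedigreed SNP-array panels
#'
#' See the package README and the methods vignette
#' (`vignette("thoroughbred-popgen")`) for the scientific background and a
#' worked end-to-end example.
#'
#' @importFrom stats rbeta rbinom rpois runif cor quantile aggregate setNames
#' @importFrom utils read.table write.table head tail
#' @importFrom graphics hist
#' @keywords internal
"_PACKAGE"

MISSING_PARENT <- "0"

## ---------------------------------------------------------------------------
## Containers
## ---------------------------------------------------------------------------

#' Construct a genotype matrix
#'
#' The central container of the package: a biallelic variant table plus a
#' sites x samples dosage matrix counting copies of the alternate allele
#' (0, 1, 2; `NA` = missing call).
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based bp),
#'   `id`, `ref`, `alt`. Positions must be strictly increasing within each
#'   chromosome.
#' @param samples character vector of unique sample IDs.
#' @param dosage integer matrix, `nrow(variants)` x `length(samples)`,
#'   values in `{0, 1, 2, NA}`.
#' @return An object of class `geno_matrix`.
#' @export
genotype_matrix <- function(variants, samples, dosage) {
  variants <- as.data.frame(variants)
  stopifnot(all(c("chrom", "pos", "id", "ref", "alt") %in% names(variants)))
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != nrow(variants) || ncol(dosage) != length(samples))
    stop("dosage dimensions do not match variants x samples")
  if (anyDuplicated(samples))
    stop("duplicate sample IDs")
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad))
    stop("dosage values must be 0, 1, 2 or NA")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  colnames(dosage) <- samples
  structure(list(variants = variants, samples = as.character(samples),
                 dosage = dosage),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d sites x %d samples on %d chromosome(s)\n",
              nrow(x$variants), length(x$samples),
              length(unique(x$variants$chrom))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) c(nrow(x$variants), length(x$samples))

#' Construct a haplotype matrix
#'
#' Phased companion of [genotype_matrix()]: per site, `2 * n_samples` binary
#' allele codes. Columns `2i - 1` and `2i` are the two haplotypes of sample
#' `i`; at every non-missing site they sum to the sample's dosage.
#'
#' @param variants variant table as in [genotype_matrix()].
#' @param samples character vector of sample IDs.
#' @param haps integer matrix of 0/1/NA, sites x (2 * samples).
#' @return An object of class `hap_matrix`.
#' @export
haplotype_matrix <- function(variants, samples, haps) {
  variants <- as.data.frame(variants)
  haps <- as.matrix(haps)
  if (ncol(haps) != 2L * length(samples))
    stop("haps must have 2 columns per sample")
  if (nrow(haps) != nrow(variants))
    stop("haps rows must match variants")
  if (!all(haps %in% c(0L, 1L) | is.na(haps)))
    stop("haplotype codes must be 0, 1 or NA")
  colnames(haps) <- paste(rep(samples, each = 2), c("a", "b"), sep = "_")
  structure(list(variants = variants, samples = as.character(samples),
                 haps = haps),
            class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("hap_matrix: %d sites x %d haplotypes (%d samples)\n",
              nrow(x$variants), ncol(x$haps), length(x$samples)))
  invisible(x)
}

#' Collapse a haplotype matrix to genotype dosages
#'
#' @param h a `hap_matrix`.
#' @return A `geno_matrix` whose dosage at each site is the haplotype sum
#'   (NA where either haplotype is missing).
#' @export
as_geno_matrix <- function(h) {
  stopifnot(inherits(h, "hap_matrix"))
  n <- length(h$samples)
  d <- h$haps[, 2L * seq_len(n) - 1L, drop = FALSE] +
    h$haps[, 2L * seq_len(n), drop = FALSE]
  genotype_matrix(h$variants, h$samples, d)
}

#' Per-site summary statistics of a genotype matrix
#'
#' @param g a `geno_matrix`.
#' @param subset optional character vector of sample IDs to restrict to.
#' @return data.frame with `call_rate`, `p_alt` (alternate-allele frequency
#'   among non-missing calls) and `maf` per site; `p_alt`/`maf` are `NA` at
#'   all-missing sites.
#' @export
site_stats <- function(g, subset = NULL) {
  d <- subset_dosage(g, subset)
  n_called <- rowSums(!is.na(d))
  p <- rowSums(d, na.rm = TRUE) / (2 * n_called)
  p[n_called == 0] <- NA_real_
  data.frame(call_rate = n_called / ncol(d),
             p_alt = p,
             maf = pmin(p, 1 - p))
}

subset_dosage <- function(g, subset = NULL) {
  if (is.null(subset)) return(g$dosage)
  miss <- setdiff(subset, g$samples)
  if (length(miss))
    stop("unknown sample ID(s): ", paste(head(miss, 5), collapse = ", "))
  g$dosage[, match(subset, g$samples), drop = FALSE]
}

## ---------------------------------------------------------------------------
## VCF
## ---------------------------------------------------------------------------

#' Read genotypes (and phased haplotypes) from a VCF file
#'
#' Parses the GT field of a VCF v4.x file via \pkg{vcfR}. Non-biallelic
#' records are skipped with a warning (default) or raise an error in strict
#' mode. If every non-missing genotype uses the `|` phase separator the
#' phased haplotypes are returned alongside the dosages.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file.
#' @param strict error (rather than warn-and-skip) on non-biallelic sites.
#' @return A list with elements `geno` (a [genotype_matrix()]) and `haps`
#'   (a [haplotype_matrix()] when the file is fully phased, otherwise `NULL`).
#' @export
read_vcf <- function(path, strict = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  samples <- colnames(v@gt)[-1]
  if (n_rec == 0) {
    vt <- data.frame(chrom = character(), pos = numeric(), id = character(),
                     ref = character(), alt = character())
    g <- genotype_matrix(vt, samples,
                         matrix(integer(), 0, length(samples)))
    return(list(geno = g, haps = NULL))
  }
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) & alt != "."
  if (any(!biallelic)) {
    msg <- sprintf("%d non-biallelic site(s)", sum(!biallelic))
    if (strict) stop(msg) else warning(msg, " skipped")
  }
  gt <- v@gt[, -1, drop = FALSE]
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  ## strip any trailing FORMAT subfields; GT is always first
  gt[] <- sub(":.*$", "", gt)
  id <- fix[, "ID"]
  noid <- is.na(id) | id == "."
  id[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  vt <- data.frame(chrom = fix[, "CHROM"],
                   pos = as.numeric(fix[, "POS"]),
                   id = id,
                   ref = fix[, "REF"],
                   alt = fix[, "ALT"])
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  sep <- substr(gt, 2, 2)
  tomiss <- a1 == "." | a2 == "." | is.na(gt)
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt))
  ok <- !tomiss
  dose[ok] <- as.integer(a1[ok]) + as.integer(a2[ok])
  g <- genotype_matrix(vt, samples, dose)
  phased <- all(sep[ok] == "|") && any(ok)
  haps <- NULL
  if (phased) {
    hm <- matrix(NA_integer_, nrow(gt), 2L * ncol(gt))
    hm[, seq(1, ncol(hm), by = 2)][ok] <- as.integer(a1[ok])
    hm[, seq(2, ncol(hm), by = 2)][ok] <- as.integer(a2[ok])
    haps <- haplotype_matrix(vt, samples, hm)
  }
  list(geno = g, haps = haps)
}

#' Write genotypes to a VCF file
#'
#' Serializes a genotype matrix (or a haplotype matrix, in which case the
#' genotypes are written phased with `|`) as a minimal plain-text VCF v4.2
#' with GT-only FORMAT. Readable back with [read_vcf()].
#'
#' @param x a `geno_matrix` or `hap_matrix`.
#' @param path output file path.
#' @param header_lines optional extra `##` meta lines (e.g. run provenance).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, header_lines = character()) {
  phased <- inherits(x, "hap_matrix")
  vt <- x$variants
  samples <- x$samples
  if (phased) {
    n <- length(samples)
    h1 <- x$haps[, 2L * seq_len(n) - 1L, drop = FALSE]
    h2 <- x$haps[, 2L * seq_len(n), drop = FALSE]
    gt <- matrix(paste0(ifelse(is.na(h1), ".", h1), "|",
                        ifelse(is.na(h2), ".", h2)),
                 nrow = nrow(vt))
    gt[is.na(h1) | is.na(h2)] <- ".|."
  } else {
    code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix("./.", nrow(x$dosage), ncol(x$dosage))
    ok <- !is.na(x$dosage)
    gt[ok] <- code[as.character(x$dosage[ok])]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=eqpopgen_", utils::packageVersion("eqpopgen")),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               header_lines,
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  if (nrow(vt) > 0) {
    body <- cbind(vt$chrom, format(vt$pos, scientific = FALSE, trim = TRUE),
                  vt$id, vt$ref, vt$alt, ".", ".", ".", "GT", gt)
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## Site QC filters
## ---------------------------------------------------------------------------

#' Filter sites on call rate, MAF and autosomes
#'
#' Standard array-QC filter: minor-allele frequency is computed per site from
#' non-missing genotypes only, after which the call-rate and MAF thresholds
#' are applied jointly. Sample order is unchanged.
#'
#' @param g a `geno_matrix`.
#' @param min_call_rate minimum fraction of non-missing genotypes in `[0,1]`.
#' @param min_maf minimum minor-allele frequency in `[0,0.5]`.
#' @param autosomes_only drop chromosomes whose label looks non-autosomal
#'   (X, Y, MT, with or without a "chr" prefix).
#' @return The filtered `geno_matrix` (possibly with zero sites, with a
#'   warning).
#' @export
filter_sites <- function(g, min_call_rate = 0, min_maf = 0,
                         autosomes_only = FALSE) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1)
  st <- site_stats(g)
  keep <- st$call_rate >= min_call_rate &
    (min_maf == 0 | (!is.na(st$maf) & st$maf >= min_maf))
  if (autosomes_only) {
    sexchr <- grepl("^(chr)?(x|y|mt?|m)$", tolower(g$variants$chrom))
    keep <- keep & !sexchr
  }
  if (!any(keep))
    warning("all sites removed by filters")
  vt <- g$variants[keep, , drop = FALSE]
  rownames(vt) <- NULL
  genotype_matrix(vt, g$samples, g$dosage[keep, , drop = FALSE])
}

## ---------------------------------------------------------------------------
## Pedigree and sample tables
## ---------------------------------------------------------------------------

#' Read a three-column pedigree file
#'
#' Tab- or comma-separated `individual, sire, dam` records; unknown parents
#' coded `"0"` or empty (PLINK convention). Individuals referenced only as
#' parents are appended as founders. Acyclicity is validated.
#'
#' @param path path to the pedigree file.
#' @param header does the file carry a header line?
#' @return A `pedigree` data.frame with columns `id`, `sire`, `dam`
#'   (`"0"` = unknown).
#' @export
read_pedigree <- function(path, header = TRUE) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else "\t"
  df <- read.table(path, sep = sep, header = header,
                   colClasses = "character", comment.char = "#",
                   blank.lines.skip = TRUE)
  if (ncol(df) < 3) stop("pedigree file needs 3 columns: id, sire, dam")
  pedigree_table(df[[1]], df[[2]], df[[3]])
}

#' Build and validate a pedigree table
#'
#' @param id,sire,dam character vectors; unknown parents as `"0"`, `""` or
#'   `NA`.
#' @return A validated `pedigree` data.frame (founders auto-appended).
#' @export
pedigree_table <- function(id, sire, dam) {
  norm <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == ""] <- MISSING_PARENT
    x
  }
  df <- data.frame(id = as.character(id), sire = norm(sire), dam = norm(dam),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id))
    stop("duplicate individual in pedigree: ",
         df$id[duplicated(df$id)][1])
  parents <- setdiff(unique(c(df$sire, df$dam)), c(MISSING_PARENT, df$id))
  if (length(parents))
    df <- rbind(df, data.frame(id = parents, sire = MISSING_PARENT,
                               dam = MISSING_PARENT))
  rownames(df) <- NULL
  ## cycle check by iterative founder-stripping (Kahn)
  remaining <- df
  repeat {
    known <- c(MISSING_PARENT, setdiff(df$id, remaining$id))
    ready <- remaining$sire %in% known & remaining$dam %in% known
    if (!any(ready)) break
    remaining <- remaining[!ready, , drop = FALSE]
  }
  if (nrow(remaining) > 0)
    stop("pedigree cycle detected involving individual ", remaining$id[1])
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Write a pedigree table as TSV
#' @param ped a `pedigree` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with at least `sample_id` and `population` columns; optional
#' `sire_id` and `sex`. Population labels are the analysis groups
#' (e.g. `FOCAL`, `SISTER`, `OUTGROUP`).
#'
#' @param path path to the TSV file.
#' @return data.frame of sample metadata.
#' @export
read_sample_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = "character", comment.char = "#")
  if (!all(c("sample_id", "population") %in% names(df)))
    stop("sample table needs sample_id and population columns")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id")
  df
}

#' Write a sample metadata table as TSV
#' @param samples sample metadata data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Window-statistic tables
## ---------------------------------------------------------------------------

#' Write window statistics as BED-like TSV
#'
#' Columns `chrom`, `start` (0-based), `end` (half-open), `n_sites`, then one
#' column per statistic. Input must be sorted by (chrom, start).
#'
#' @param stats data.frame with at least `chrom`, `start`, `end`, `n_sites`.
#' @param path output path.
#' @param comment optional `#`-prefixed header comment lines.
#' @return `path`, invisibly.
#' @export
write_window_stats <- function(stats, path, comment = character()) {
  stopifnot(all(c("chrom", "start", "end", "n_sites") %in% names(stats)))
  if (nrow(stats) > 1) {
    o <- order(stats$chrom, stats$start)
    if (!identical(o, seq_len(nrow(stats))))
      stop("windows must be sorted by (chrom, start)")
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment))
    writeLines(paste0("# ", comment), con)
  write.table(stats, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a window-statistic TSV written by [write_window_stats()]
#' @param path input path.
#' @return data.frame of window statistics.
#' @export
read_window_stats <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             colClasses = NA, stringsAsFactors = FALSE)
}
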