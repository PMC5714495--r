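#' Construct a site table
#'
#' A site table is the in-memory form of a multi-sample SNP call set: one row
#' per biallelic SNP with a genotype dosage matrix (number of alternate
#' alleles, 0/1/2, \code{NA} = missing) and a read-depth matrix of identical
#' shape. Sample order is fixed and shared by both matrices.
#'
#' @param sites data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}.
#' @param gt integer matrix, sites x samples, values 0/1/2 or \code{NA}.
#' @param dp non-negative integer matrix, sites x samples.
#' @param samples character vector of sample names (column order of \code{gt}).
#' @return object of class \code{site_table}.
#' @export
site_table <- function(sites, gt, dp, samples = colnames(gt)) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            nrow(gt) == nrow(sites), nrow(dp) == nrow(sites),
            ncol(gt) == ncol(dp))
  if (is.null(samples)) stop("sample names are required")
  gt <- as.matrix(gt); dp <- as.matrix(dp)
  storage.mode(gt) <- "integer"; storage.mode(dp) <- "integer"
  dimnames(gt) <- list(NULL, samples); dimnames(dp) <- list(NULL, samples)
  if (any(dp < 0, na.rm = TRUE)) stop("negative depth")
  bad <- !(gt %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype dosages must be 0, 1, 2 or NA")
  # strictly increasing positions within each chromosome
  ord_ok <- tapply(sites$pos, sites$chrom, function(p) all(diff(p) > 0))
  if (!all(unlist(ord_ok)))
    stop("positions must be strictly increasing within each chromosome")
  structure(list(sites = sites, gt = gt, dp = dp,
                 samples = as.character(samples)),
            class = "site_table")
}

#' @export
print.site_table <- function(x, ...) {
  cat(sprintf("site_table: %d SNPs, %d samples, %d chromosome(s)\n",
              nrow(x$sites), length(x$samples),
              length(unique(x$sites$chrom))))
  invisible(x)
}

#' Number of sites in a site table
#' @param x a \code{site_table}.
#' @return integer count of SNP records.
#' @export
n_sites <- function(x) nrow(x$sites)

#' Subset a site table by row index
#' @param x a \code{site_table}.
#' @param i integer or logical row index.
#' @return a \code{site_table} with the selected sites.
#' @export
subset_sites <- function(x, i) {
  site_table(x$sites[i, , drop = FALSE],
             x$gt[i, , drop = FALSE],
             x$dp[i, , drop = FALSE],
             x$samples)
}

#' Construct a population map
#'
#' Maps each sample to a population and each population to a species. The
#' canonical four-population design contrasts an allopatric and a sympatric
#' pair: \code{allo_A}, \code{allo_B}, \code{sym_A}, \code{sym_B} with species
#' \code{A} and \code{B}.
#'
#' @param sample character vector of sample names.
#' @param population population assignment per sample.
#' @param species species assignment per sample (constant within population).
#' @return data.frame of class \code{population_map}.
#' @export
population_map <- function(sample, population, species) {
  df <- data.frame(sample = as.character(sample),
                   population = as.character(population),
                   species = as.character(species),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample)) stop("duplicated sample names")
  sp <- tapply(df$species, df$population, function(s) length(unique(s)))
  if (any(sp != 1)) stop("species must be constant within a population")
  class(df) <- c("population_map", "data.frame")
  df
}

#' Samples belonging to a population
#' @param pop_map a \code{population_map}.
#' @param pop population name.
#' @return character vector of sample names.
#' @export
pop_samples <- function(pop_map, pop) {
  s <- pop_map$sample[pop_map$population == pop]
  if (length(s) == 0) stop("no samples in population '", pop, "'")
  s
}

#' Construct a genome layout
#' @param chrom chromosome names (unique).
#' @param length chromosome lengths in bp (> 0).
#' @param class chromosome class, \code{"autosome"} or \code{"Z"}.
#' @return data.frame of class \code{genome_layout}.
#' @export
genome_layout <- function(chrom, length, class) {
  if (anyDuplicated(chrom)) stop("duplicated chromosome names")
  if (any(length <= 0)) stop("chromosome lengths must be positive")
  if (!all(class %in% c("autosome", "Z")))
    stop("chromosome class must be 'autosome' or 'Z'")
  df <- data.frame(chrom = as.character(chrom),
                   length = as.numeric(length),
                   class = as.character(class), stringsAsFactors = FALSE)
  class(df) <- c("genome_layout", "data.frame")
  df
}
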