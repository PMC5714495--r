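#' Read a multi-sample VCF into a site table
#'
#' Parses a VCF 4.2 file with per-sample \code{GT} and \code{DP} fields.
#' Only biallelic SNPs are retained; multi-allelic records and indels are
#' skipped with a reported count. A missing \code{GT} or \code{DP} yields a
#' missing genotype; missing \code{DP} is stored as depth 0.
#'
#' @param path path to a VCF file (plain text).
#' @param pop_map optional \code{\link{population_map}}; when supplied every
#'   VCF sample must be assigned, otherwise an error names the offender.
#' @return a \code{\link{site_table}}.
#' @export
read_vcf <- function(path, pop_map = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0)
    message(n_skip, " non-SNP or multi-allelic record(s) skipped")
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp_raw <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gt_raw <- gt_raw[snp, , drop = FALSE]
  dp_raw <- dp_raw[snp, , drop = FALSE]
  chrom <- chrom[snp]; pos <- pos[snp]; ref <- ref[snp]; alt <- alt[snp]
  for (cn in unique(chrom)) {
    p <- pos[chrom == cn]
    if (any(diff(p) <= 0)) stop("VCF not sorted within chromosome ", cn)
  }
  samples <- colnames(gt_raw)
  if (!is.null(pop_map)) {
    unknown <- setdiff(samples, pop_map$sample)
    if (length(unknown) > 0)
      stop("sample(s) absent from population map: ",
           paste(unknown, collapse = ", "))
  }
  gt <- matrix(NA_integer_, nrow = length(pos), ncol = length(samples),
               dimnames = list(NULL, samples))
  g <- gsub("|", "/", gt_raw, fixed = TRUE)
  gt[g == "0/0"] <- 0L
  gt[g == "0/1" | g == "1/0"] <- 1L
  gt[g == "1/1"] <- 2L
  dp <- dp_raw
  dp[is.na(dp)] <- 0
  gt[is.na(dp_raw)] <- NA_integer_
  site_table(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                        stringsAsFactors = FALSE),
             gt, dp, samples)
}

#' Write a site table as VCF 4.2
#'
#' Emits a minimal sorted VCF with \code{FORMAT GT:DP} and one \code{##contig}
#' line per chromosome of the layout.
#'
#' @param st a \code{\link{site_table}}.
#' @param path output path.
#' @param layout optional \code{\link{genome_layout}} for contig headers.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(st, path, layout = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=divscan",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  if (!is.null(layout))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          layout$chrom, as.integer(layout$length)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", st$samples),
                      collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[st$gt + 1L],
                   nrow = nrow(st$gt))
  gt_str[is.na(st$gt)] <- "./."
  cells <- matrix(paste0(gt_str, ":", st$dp), nrow = nrow(st$gt))
  body <- paste(st$sites$chrom, st$sites$pos, ".", st$sites$ref,
                st$sites$alt, ".", "PASS", ".", "GT:DP",
                apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a sample-to-population map from TSV
#'
#' Expects a header row with columns \code{sample}, \code{population},
#' \code{species}.
#'
#' @param path TSV path.
#' @return a \code{\link{population_map}}.
#' @export
read_population_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  population_map(df$sample, df$population, df$species)
}

#' Read a genome layout from TSV
#'
#' Expects a header row with columns \code{chrom}, \code{length},
#' \code{class}.
#'
#' @param path TSV path.
#' @return a \code{\link{genome_layout}}.
#' @export
read_genome_layout <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  genome_layout(df$chrom, df$length, df$class)
}

#' Read a callable-site mask from BED3
#'
#' Intervals are 0-based half-open, as in BED.
#'
#' @param path BED path.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}.
#' @export
read_callable_mask <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write a callable mask as BED3
#' @param mask data.frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_callable_mask <- function(mask, path) {
  writeLines(paste(mask$chrom, format(mask$start, scientific = FALSE,
                                      trim = TRUE),
                   format(mask$end, scientific = FALSE, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}

#' Tile the genome into non-overlapping windows
#'
#' Builds consecutive windows of \code{size} bp per chromosome (0-based
#' half-open coordinates). A shorter terminal window is kept and flagged
#' \code{partial}. \code{callable_bp} is the overlap of each window with the
#' callable mask; downstream per-bp statistics are normalized by it.
#'
#' @param layout a \code{\link{genome_layout}}.
#' @param mask callable mask data.frame (\code{chrom}, \code{start},
#'   \code{end}), or \code{NULL} for an empty mask.
#' @param size window size in bp (default 10 kb).
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{class}, \code{callable_bp}, \code{partial}.
#' @export
make_windows <- function(layout, mask, size = 10000) {
  if (size <= 0) stop("window size must be positive")
  out <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    len <- layout$length[i]
    starts <- seq(0, len - 1, by = size)
    ends <- pmin(starts + size, len)
    w <- data.frame(chrom = layout$chrom[i], start = starts, end = ends,
                    class = layout$class[i],
                    callable_bp = 0, partial = ends - starts < size,
                    stringsAsFactors = FALSE)
    if (!is.null(mask)) {
      m <- mask[mask$chrom == layout$chrom[i], , drop = FALSE]
      if (nrow(m) > 0) {
        if (any(m$start < 0) || any(m$end > len))
          stop("mask interval outside chromosome ", layout$chrom[i])
        mr <- IRanges::reduce(IRanges::IRanges(m$start + 1L, m$end))
        wr <- IRanges::IRanges(starts + 1L, ends)
        ov <- IRanges::findOverlaps(wr, mr)
        if (length(ov) > 0) {
          piece <- IRanges::pintersect(wr[S4Vectors::queryHits(ov)],
                                       mr[S4Vectors::subjectHits(ov)])
          cb <- tapply(IRanges::width(piece), S4Vectors::queryHits(ov), sum)
          w$callable_bp[as.integer(names(cb))] <- as.numeric(cb)
        }
      }
    }
    out[[i]] <- w
  }
  do.call(rbind, out)
}

# window index of a 1-based position for a given window size
.window_index <- function(pos, size) (pos - 1L) %/% size

# key matching sites to rows of a windows data.frame
.window_key <- function(chrom, start) paste(chrom, start, sep = ":")
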