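#' Z-standardize window FST per chromosome class
#'
#' Standardizes each window's FST by the mean and sample standard deviation
#' (ddof = 1) of the defined, full (non-partial) windows of the same
#' chromosome class. Autosomes and the Z chromosome are standardized
#' separately because their baseline differentiation differs. Windows with
#' undefined FST, and partial terminal windows, get no score.
#'
#' @param win_stats data.frame of window statistics.
#' @param fst_col name of the FST column to standardize.
#' @return \code{win_stats} with an appended \code{fst_z} column.
#' @export
zscore_fst <- function(win_stats, fst_col) {
  fst <- win_stats[[fst_col]]
  if (is.null(fst)) stop("no column '", fst_col, "'")
  usable <- !is.na(fst) & !win_stats$partial
  z <- rep(NA_real_, nrow(win_stats))
  for (cl in unique(win_stats$class)) {
    sel <- usable & win_stats$class == cl
    if (sum(sel) < 2) next
    s <- stats::sd(fst[sel])
    if (s == 0) stop("zero FST standard deviation in class '", cl, "'")
    z[sel] <- (fst[sel] - mean(fst[sel])) / s
  }
  win_stats$fst_z <- z
  win_stats
}

#' Call percentile outliers per chromosome class
#'
#' The class threshold is the nearest-rank percentile: the value at rank
#' \code{ceiling(q/100 * N)} of the sorted defined scores. A window is an
#' outlier when its score is strictly greater than the threshold, so with N
#' distinct scores exactly \code{N - ceiling(q/100 * N)} outliers are
#' called.
#'
#' @param win_stats data.frame with an \code{fst_z} column (see
#'   \code{\link{zscore_fst}}).
#' @param percentile percentile in (0, 100); default 99.
#' @return \code{win_stats} with an appended logical \code{is_outlier}
#'   column (\code{FALSE} for unscored windows).
#' @export
call_outliers <- function(win_stats, percentile = 99) {
  z <- win_stats$fst_z
  if (is.null(z)) stop("run zscore_fst first")
  out <- rep(FALSE, nrow(win_stats))
  for (cl in unique(win_stats$class)) {
    sel <- which(!is.na(z) & win_stats$class == cl)
    N <- length(sel)
    if (N == 0) next
    if (N < 100)
      warning("only ", N, " scored windows in class '", cl,
              "'; percentile threshold is unstable")
    thr <- sort(z[sel])[ceiling(percentile / 100 * N)]
    out[sel] <- z[sel] > thr
  }
  win_stats$is_outlier <- out
  win_stats
}

#' Upper-tail binomial probability of outlier clustering
#'
#' Exact probability that a block of \code{n} windows contains \code{k} or
#' more outliers when outliers fall independently with probability \code{p},
#' i.e. \code{P(X >= k)} for \code{X ~ Binomial(n, p)}.
#'
#' @param n block size in windows.
#' @param p genome-wide outlier fraction.
#' @param k minimum outlier count.
#' @return probability in [0, 1].
#' @export
binom_tail <- function(n, p, k) {
  if (length(n) != 1 || length(p) != 1 || length(k) != 1)
    stop("scalar arguments required")
  if (is.na(p) || p < 0 || p > 1) stop("p must be in [0, 1]")
  if (is.na(k) || k < 0 || k > n) stop("k must be in [0, n]")
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Scan for blocks enriched in outlier windows
#'
#' Slides a block of \code{block} consecutive full windows (step 1, within
#' chromosome, ordered by position) and reports blocks containing at least
#' \code{min_outliers} outliers, each annotated with the binomial tail
#' probability of that level of clustering under the genome-wide outlier
#' fraction.
#'
#' @param win_stats data.frame with \code{is_outlier} (see
#'   \code{\link{call_outliers}}).
#' @param block block size in windows (default 50, i.e. 0.5 Mb of 10-kb
#'   windows).
#' @param min_outliers minimum outliers per significant block (default 10).
#' @param p_global outlier probability for the binomial; default the
#'   realized outlier fraction over usable windows.
#' @return data.frame of significant blocks: \code{chrom}, \code{start},
#'   \code{end}, \code{n_outliers}, \code{p_binomial}, plus a list column
#'   \code{outlier_starts} of member outlier window starts.
#' @export
scan_blocks <- function(win_stats, block = 50, min_outliers = 10,
                        p_global = NULL) {
  if (is.null(win_stats$is_outlier)) stop("run call_outliers first")
  usable <- !win_stats$partial & !is.na(win_stats$fst_z)
  if (is.null(p_global))
    p_global <- sum(win_stats$is_outlier[usable]) / sum(usable)
  res <- list()
  for (cn in unique(win_stats$chrom)) {
    sel <- which(win_stats$chrom == cn & usable)
    if (length(sel) < block) {
      message("chromosome ", cn, " has fewer than ", block,
              " usable windows; skipped")
      next
    }
    sel <- sel[order(win_stats$start[sel])]
    flags <- as.numeric(win_stats$is_outlier[sel])
    cs <- c(0, cumsum(flags))
    n_blk <- length(sel) - block + 1L
    counts <- cs[(block + 1):(block + n_blk)] - cs[1:n_blk]
    hit <- which(counts >= min_outliers)
    for (h in hit) {
      idx <- sel[h:(h + block - 1L)]
      res[[length(res) + 1L]] <- data.frame(
        chrom = cn,
        start = win_stats$start[idx[1]],
        end = win_stats$end[idx[length(idx)]],
        n_outliers = counts[h],
        p_binomial = binom_tail(block, p_global, counts[h]),
        stringsAsFactors = FALSE)
      res[[length(res)]]$outlier_starts <-
        list(win_stats$start[idx][win_stats$is_outlier[idx]])
    }
  }
  if (length(res) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_outliers = numeric(),
                      p_binomial = numeric()))
  do.call(rbind, res)
}

#' Merge overlapping significant blocks into outlier regions
#'
#' Overlapping or bookended blocks on the same chromosome are merged
#' transitively. A region's p-value is the minimum member-block p, and its
#' outlier windows are counted once.
#'
#' @param blocks data.frame from \code{\link{scan_blocks}}.
#' @param window_size window size in bp, used to report the region's span in
#'   windows.
#' @return data.frame of regions: \code{chrom}, \code{start}, \code{end},
#'   \code{n_windows}, \code{n_outliers}, \code{p_binomial}, list column
#'   \code{outlier_starts}.
#' @export
merge_blocks <- function(blocks, window_size = 10000) {
  if (nrow(blocks) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_windows = numeric(),
                      n_outliers = numeric(), p_binomial = numeric()))
  res <- list()
  for (cn in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == cn, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(b$start + 1, b$end))
    ov <- IRanges::findOverlaps(IRanges::IRanges(b$start + 1, b$end), ir)
    grp <- S4Vectors::subjectHits(ov)
    for (g in unique(grp)) {
      mem <- which(grp == g)
      starts <- sort(unique(unlist(b$outlier_starts[mem])))
      reg <- data.frame(chrom = cn,
                        start = min(b$start[mem]),
                        end = max(b$end[mem]),
                        n_outliers = length(starts),
                        p_binomial = min(b$p_binomial[mem]),
                        stringsAsFactors = FALSE)
      reg$outlier_starts <- list(starts)
      res[[length(res) + 1L]] <- reg
    }
  }
  out <- do.call(rbind, res)
  out$n_windows <- (out$end - out$start) / window_size
  out[order(out$chrom, out$start),
      c("chrom", "start", "end", "n_windows", "n_outliers", "p_binomial",
        "outlier_starts")]
}

#' Full differentiation-island scan
#'
#' Convenience wrapper: Z-standardize, call percentile outliers, scan
#' sliding blocks and merge them into regions.
#'
#' @param win_stats window statistics data.frame.
#' @param fst_col FST column to scan.
#' @param percentile outlier percentile (default 99).
#' @param block block size in windows.
#' @param min_outliers minimum outliers per significant block.
#' @return list with \code{windows} (scored), \code{blocks}, \code{regions}.
#' @export
outlier_scan <- function(win_stats, fst_col, percentile = 99, block = 50,
                         min_outliers = 10) {
  w <- call_outliers(zscore_fst(win_stats, fst_col), percentile)
  blocks <- scan_blocks(w, block = block, min_outliers = min_outliers)
  list(windows = w, blocks = blocks, regions = merge_blocks(blocks))
}
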