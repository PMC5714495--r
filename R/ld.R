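#' Composite LD between two loci
#'
#' Squared Pearson correlation of unphased genotype dosages (0/1/2) over the
#' individuals with a non-missing genotype at both loci.
#'
#' @param x,y dosage vectors of equal length.
#' @return r-squared in [0, 1]; \code{NA} when fewer than 2 complete pairs or
#'   when either locus has zero dosage variance.
#' @export
ld_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Window-mean composite LD for one population
#'
#' Considers SNP pairs less than \code{max_dist} bp apart on the same
#' chromosome, where both loci have minor allele frequency strictly above
#' \code{maf_min} among retained genotypes (depth >= \code{min_depth},
#' non-missing). Each qualifying pair is assigned to the window containing
#' its left locus; the window value is the mean r-squared over assigned
#' pairs.
#'
#' @param st a \code{\link{site_table}}.
#' @param pop_map a \code{\link{population_map}}.
#' @param windows data.frame from \code{\link{make_windows}}.
#' @param pop population whose genotypes are used.
#' @param max_dist maximum pair distance in bp (exclusive; default 100 kb).
#' @param maf_min minor-allele-frequency threshold (exclusive; default 0.2).
#' @param min_depth minimum read depth for a genotype to be retained.
#' @return numeric vector parallel to \code{windows}: mean r-squared, or
#'   \code{NA} for windows without qualifying pairs.
#' @export
window_mean_ld <- function(st, pop_map, windows, pop,
                           max_dist = 100000, maf_min = 0.2,
                           min_depth = 5) {
  cols <- match(pop_samples(pop_map, pop), st$samples)
  gt <- st$gt[, cols, drop = FALSE]
  gt[st$dp[, cols, drop = FALSE] < min_depth] <- NA_integer_

  obs <- !is.na(gt)
  n_all <- 2 * rowSums(obs)
  alt <- rowSums(gt, na.rm = TRUE)
  p <- ifelse(n_all > 0, alt / n_all, NA_real_)
  pass <- !is.na(p) & pmin(p, 1 - p) > maf_min

  size <- max(windows$end - windows$start)
  wkey <- .window_key(windows$chrom, windows$start)
  sums <- rep(0, nrow(windows))
  counts <- rep(0L, nrow(windows))

  D0 <- gt
  D0[!obs] <- 0L
  for (cn in unique(st$sites$chrom)) {
    sel <- which(st$sites$chrom == cn & pass)
    if (length(sel) < 2) next
    pos <- st$sites$pos[sel]
    Dm <- D0[sel, , drop = FALSE]
    Om <- obs[sel, , drop = FALSE]
    widx <- match(.window_key(cn, .window_index(pos, size) * size), wkey)
    jmax <- 1L
    for (i in seq_len(length(sel) - 1L)) {
      if (jmax < i + 1L) jmax <- i + 1L
      while (jmax < length(sel) && pos[jmax + 1L] - pos[i] < max_dist)
        jmax <- jmax + 1L
      if (pos[jmax] - pos[i] >= max_dist) next
      J <- (i + 1L):jmax
      M <- Om[J, , drop = FALSE] &
        matrix(Om[i, ], nrow = length(J), ncol = ncol(Om), byrow = TRUE)
      nn <- rowSums(M)
      Xi <- matrix(Dm[i, ], nrow = length(J), ncol = ncol(Dm), byrow = TRUE)
      Yj <- Dm[J, , drop = FALSE]
      Sx <- rowSums(Xi * M); Sy <- rowSums(Yj * M)
      Sxx <- rowSums(Xi * Xi * M); Syy <- rowSums(Yj * Yj * M)
      Sxy <- rowSums(Xi * Yj * M)
      vx <- Sxx - Sx^2 / nn
      vy <- Syy - Sy^2 / nn
      cv <- Sxy - Sx * Sy / nn
      r2 <- ifelse(nn >= 2 & vx > 0 & vy > 0, cv^2 / (vx * vy), NA_real_)
      good <- !is.na(r2)
      if (any(good)) {
        w <- widx[i]
        sums[w] <- sums[w] + sum(r2[good])
        counts[w] <- counts[w] + sum(good)
      }
    }
  }
  ifelse(counts > 0, sums / counts, NA_real_)
}
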