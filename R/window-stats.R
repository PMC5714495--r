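# cumulative harmonic sums; .a1(n) = sum_{i=1}^{n-1} 1/i, elementwise
.a1 <- function(n) {
  H <- cumsum(1 / seq_len(max(c(n, 2)) - 1))
  out <- rep(NA_real_, length(n))
  ok <- n >= 2
  out[ok] <- H[n[ok] - 1]
  out
}
.a2 <- function(n) {
  H2 <- cumsum(1 / seq_len(max(c(n, 2)) - 1)^2)
  out <- rep(NA_real_, length(n))
  ok <- n >= 2
  out[ok] <- H2[n[ok] - 1]
  out
}

#' Per-site pairwise diversity
#'
#' Mean number of differences among all pairs of the \code{n} sampled
#' alleles at one site with \code{k} alternate alleles:
#' \code{k (n - k) / choose(n, 2)}. Equals \code{(n/(n-1)) 2 p (1 - p)} with
#' \code{p = k/n}.
#'
#' @param n retained allele count (>= 2 for a defined value).
#' @param k alternate allele count.
#' @return numeric vector; \code{NA} where \code{n < 2}.
#' @export
site_pi <- function(n, k) {
  out <- ifelse(n >= 2, k * (n - k) / (n * (n - 1) / 2), NA_real_)
  as.numeric(out)
}

#' Window diversity estimators
#'
#' Sums per-site pairwise diversity and Watterson's per-site contributions
#' over the sites of one window and normalizes by the callable length.
#' Watterson's theta uses the site-specific allele count:
#' \code{theta_w = sum_seg 1/a1(n_site) / callable_bp}.
#'
#' @param n,k vectors of retained allele counts and alternate counts for the
#'   sites in the window.
#' @param callable_bp callable length of the window in bp.
#' @return list with \code{theta_pi}, \code{theta_w}, \code{S}
#'   (segregating-site count) and \code{pi_sum} (unnormalized).
#' @export
window_theta <- function(n, k, callable_bp) {
  if (is.na(callable_bp) || callable_bp <= 0)
    return(list(theta_pi = NA_real_, theta_w = NA_real_, S = NA_integer_,
                pi_sum = NA_real_))
  if (length(n) == 0)
    return(list(theta_pi = 0, theta_w = 0, S = 0L, pi_sum = 0))
  seg <- k > 0 & k < n
  pi_sum <- sum(site_pi(n, k), na.rm = TRUE)
  list(theta_pi = pi_sum / callable_bp,
       theta_w = sum(1 / .a1(n[seg]), na.rm = TRUE) / callable_bp,
       S = sum(seg), pi_sum = pi_sum)
}

#' Tajima's D from window summaries
#'
#' Classical normalized difference between mean pairwise diversity and the
#' scaled segregating-site count, with the standard variance constants for a
#' fixed sample size \code{n} alleles.
#'
#' @param n representative allele count for the window (>= 4).
#' @param S number of segregating sites (>= 1).
#' @param pi_sum sum of per-site pairwise diversities over the window.
#' @return numeric; \code{NA} when \code{S < 1} or \code{n < 4}.
#' @export
tajima_d <- function(n, S, pi_sum) {
  n <- as.numeric(n); S <- as.numeric(S)
  a1 <- .a1(n); a2 <- .a2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  d <- (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  d[S < 1 | n < 4] <- NA_real_
  d
}

#' Hudson FST components for one site
#'
#' Sample-size-corrected numerator and between-population heterozygosity
#' denominator of the Hudson-type estimator. Window and global FST are
#' ratios of the summed components (ratio of sums), which is unbiased for
#' the drift coefficient under a Balding-Nichols model and robust to
#' low-information sites.
#'
#' @param p1,p2 sample alternate-allele frequencies in the two populations.
#' @param n1,n2 retained allele counts (> 1 for a defined value).
#' @return list of vectors \code{num}, \code{den}; \code{NA} where
#'   \code{n <= 1}.
#' @export
hudson_fst_components <- function(p1, n1, p2, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  bad <- n1 <= 1 | n2 <= 1
  num[bad] <- NA_real_
  den[bad] <- NA_real_
  list(num = num, den = den)
}

#' Window FST as a ratio of sums
#' @param num,den per-site Hudson components (\code{NA}s dropped pairwise).
#' @return numeric FST; \code{NA} when the summed denominator is 0.
#' @export
window_fst <- function(num, den) {
  ok <- !is.na(num) & !is.na(den)
  d <- sum(den[ok])
  if (length(num) == 0 || d == 0) return(NA_real_)
  sum(num[ok]) / d
}

#' Window absolute divergence DXY
#'
#' Mean between-population pairwise difference per callable bp:
#' \code{sum_sites [p1 (1-p2) + p2 (1-p1)] / callable_bp}.
#'
#' @param p1,p2 sample frequencies at the window's sites.
#' @param callable_bp callable window length (> 0).
#' @return numeric; \code{NA} when \code{callable_bp <= 0}.
#' @export
window_dxy <- function(p1, p2, callable_bp) {
  if (is.na(callable_bp) || callable_bp <= 0) return(NA_real_)
  if (length(p1) == 0) return(0)
  sum(p1 * (1 - p2) + p2 * (1 - p1), na.rm = TRUE) / callable_bp
}

#' Windowed summary statistics for populations and species pairs
#'
#' Applies the genotype filter once, then computes per 10-kb window and per
#' population the diversity statistics (theta_pi, theta_w, Tajima's D; the
#' representative n for Tajima's D is the floored median retained allele
#' count across the window's segregating sites), and per species pair the
#' Hudson FST (ratio of sums), DXY and fixed-difference count. All per-bp
#' quantities are normalized by the window's callable length; windows with
#' zero callable length get \code{NA}.
#'
#' @param st a \code{\link{site_table}}.
#' @param pop_map a \code{\link{population_map}}.
#' @param windows data.frame from \code{\link{make_windows}}.
#' @param profile a \code{\link{filter_profile}} (default standard).
#' @param pops populations for which diversity columns are computed.
#' @param pairs named list of length-2 population vectors for FST/DXY
#'   columns.
#' @return the \code{windows} data.frame with appended columns
#'   \code{theta_pi_<pop>}, \code{theta_w_<pop>}, \code{tajima_d_<pop>},
#'   \code{S_<pop>}, and \code{fst_<pair>}, \code{dxy_<pair>},
#'   \code{n_fixed_<pair>}, \code{n_snps_<pair>}.
#' @export
compute_window_stats <- function(st, pop_map, windows,
                                 profile = filter_profile("standard"),
                                 pops = unique(pop_map$population),
                                 pairs = list(
                                   allopatric = c("allo_A", "allo_B"),
                                   sympatric = c("sym_A", "sym_B"))) {
  fl <- pass_filter(st, pop_map, profile)
  keep <- which(fl$pass)
  size <- max(windows$end - windows$start)
  wkey <- .window_key(windows$chrom, windows$start)
  skey <- .window_key(st$sites$chrom[keep],
                      .window_index(st$sites$pos[keep], size) * size)
  widx <- match(skey, wkey)
  out <- windows

  agg <- function(v, f = sum) {
    r <- rep(0, nrow(windows))
    if (length(v) > 0) {
      t <- tapply(v, widx, f, na.rm = TRUE)
      r[as.integer(names(t))] <- as.numeric(t)
    }
    r
  }

  for (p in pops) {
    n <- fl$n[keep, p]; k <- fl$alt[keep, p]
    seg <- n >= 2 & k > 0 & k < n
    pi_site <- site_pi(n, k)
    pi_sum <- agg(ifelse(is.na(pi_site), 0, pi_site))
    S <- agg(as.numeric(seg))
    thw_sum <- agg(ifelse(seg, 1 / .a1(n), 0))
    # representative n for Tajima's D: floored median over segregating sites
    n_rep <- rep(NA_real_, nrow(windows))
    if (any(seg)) {
      t <- tapply(n[seg], widx[seg], function(x) floor(stats::median(x)))
      n_rep[as.integer(names(t))] <- as.numeric(t)
    }
    cb <- out$callable_bp
    defined <- !is.na(cb) & cb > 0
    out[[paste0("theta_pi_", p)]] <- ifelse(defined, pi_sum / cb, NA_real_)
    out[[paste0("theta_w_", p)]] <- ifelse(defined, thw_sum / cb, NA_real_)
    out[[paste0("S_", p)]] <- ifelse(defined, S, NA_real_)
    td <- tajima_d(ifelse(is.na(n_rep), 0, n_rep), S, pi_sum)
    td[!defined | is.na(n_rep)] <- NA_real_
    out[[paste0("tajima_d_", p)]] <- td
  }

  for (pr in names(pairs)) {
    pa <- pairs[[pr]][1]; pb <- pairs[[pr]][2]
    n1 <- fl$n[keep, pa]; n2 <- fl$n[keep, pb]
    p1 <- ifelse(n1 > 0, fl$alt[keep, pa] / n1, NA_real_)
    p2 <- ifelse(n2 > 0, fl$alt[keep, pb] / n2, NA_real_)
    hc <- hudson_fst_components(p1, n1, p2, n2)
    num_s <- agg(ifelse(is.na(hc$num), 0, hc$num))
    den_s <- agg(ifelse(is.na(hc$den), 0, hc$den))
    dxy_sum <- agg(ifelse(is.na(p1) | is.na(p2), 0,
                          p1 * (1 - p2) + p2 * (1 - p1)))
    fixed <- !is.na(p1) & !is.na(p2) &
      ((p1 == 0 & p2 == 1) | (p1 == 1 & p2 == 0))
    nsnp <- agg(as.numeric(!is.na(p1) & !is.na(p2)))
    cb <- out$callable_bp
    defined <- !is.na(cb) & cb > 0
    out[[paste0("fst_", pr)]] <- ifelse(den_s > 0, num_s / den_s, NA_real_)
    out[[paste0("dxy_", pr)]] <- ifelse(defined, dxy_sum / cb, NA_real_)
    out[[paste0("n_fixed_", pr)]] <- agg(as.numeric(fixed))
    out[[paste0("n_snps_", pr)]] <- nsnp
  }
  out
}
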