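#' Configuration for the divergence-with-secondary-contact simulator
#'
#' The simulator emulates two species that diverged in allopatry under
#' genetic drift and later formed a sympatric hybrid zone. Per 10-kb window
#' a Balding-Nichols drift coefficient is assigned: a genome-wide baseline
#' \code{F_base}, contiguous islands of elevated drift \code{F_peak} covering
#' a fraction \code{peak_fraction} of autosomal windows, and a homogeneous
#' (island-free) \code{F_z} on the Z chromosome whose effective population
#' size is reduced. Sympatric individuals are admixed: each carries an
#' ancestry proportion q toward species B drawn once from a Beta
#' distribution, and genotypes are sampled from the mixture allele frequency
#' q*pB + (1-q)*pA.
#'
#' @param n_per_pop diploid individuals per population.
#' @param chrom_spec data.frame with \code{chrom}, \code{length}, \code{class}
#'   (\code{"autosome"}/\code{"Z"}).
#' @param theta_auto per-bp ancestral diversity for autosomes; the expected
#'   SNP density is \code{theta_auto * a1(4*n_per_pop)} per callable bp.
#' @param theta_z_factor multiplier (0,1] applied to \code{theta_auto} on the
#'   Z class, reflecting its reduced effective population size.
#' @param F_base baseline drift coefficient in [0,1).
#' @param F_peak drift coefficient inside elevated islands;
#'   \code{F_base <= F_peak < 1}.
#' @param F_z drift coefficient for all Z-class windows.
#' @param peak_fraction fraction of autosomal windows inside elevated islands.
#' @param peak_len island length in windows (contiguous windows per island).
#' @param admix_alpha_A,admix_alpha_B Beta(shape1, shape2) parameters of the
#'   per-individual ancestry proportion toward species B in the two sympatric
#'   populations.
#' @param mean_depth Poisson mean per-genotype read depth.
#' @param callable_frac fraction of each chromosome covered by the callable
#'   mask (dropped in 50-kb chunks).
#' @param window_size window size in bp.
#' @param seed integer RNG seed; identical seeds give identical datasets.
#' @return a \code{simulation_config} list.
#' @export
simulation_config <- function(n_per_pop = 10,
                              chrom_spec = data.frame(
                                chrom = c("chr1", "chr2", "chrZ"),
                                length = c(3e6, 2e6, 1e6),
                                class = c("autosome", "autosome", "Z"),
                                stringsAsFactors = FALSE),
                              theta_auto = 0.005,
                              theta_z_factor = 0.5,
                              F_base = 0.2,
                              F_peak = 0.6,
                              F_z = 0.3,
                              peak_fraction = 0.05,
                              peak_len = 15,
                              admix_alpha_A = c(1, 1),
                              admix_alpha_B = c(8, 2),
                              mean_depth = 8,
                              callable_frac = 0.9,
                              window_size = 10000,
                              seed = 1) {
  if (!(F_base >= 0 && F_base <= F_peak && F_peak < 1))
    stop("need 0 <= F_base <= F_peak < 1")
  if (!(F_z >= 0 && F_z < 1)) stop("need 0 <= F_z < 1")
  if (!(theta_z_factor > 0 && theta_z_factor <= 1))
    stop("need 0 < theta_z_factor <= 1")
  if (any(chrom_spec$length <= 0)) stop("non-positive chromosome length")
  if (any(chrom_spec$length < window_size))
    stop("all chromosome lengths must be >= window_size")
  if (!(peak_fraction >= 0 && peak_fraction < 1))
    stop("peak_fraction must be in [0,1)")
  if (n_per_pop < 1) stop("n_per_pop must be >= 1")
  structure(list(n_per_pop = n_per_pop, chrom_spec = chrom_spec,
                 theta_auto = theta_auto, theta_z_factor = theta_z_factor,
                 F_base = F_base, F_peak = F_peak, F_z = F_z,
                 peak_fraction = peak_fraction, peak_len = peak_len,
                 admix_alpha_A = admix_alpha_A,
                 admix_alpha_B = admix_alpha_B,
                 mean_depth = mean_depth, callable_frac = callable_frac,
                 window_size = window_size, seed = as.integer(seed)),
            class = "simulation_config")
}

# folded neutral-SFS frequency grid for a pool of m chromosomes:
# frequencies i/m, i = 1..m-1, density proportional to 1/i (equivalent to the
# folded 1/x density with random allele orientation)
.sfs_grid <- function(m) {
  i <- seq_len(m - 1)
  list(p = i / m, w = (1 / i) / sum(1 / i))
}

# Balding-Nichols draw of a population frequency around p0 with drift F;
# the F -> 0 limit is pA = p0 (no drift)
.bn_draw <- function(p0, F) {
  out <- p0
  pos <- F > 0
  if (any(pos)) {
    f <- F[pos]; p <- p0[pos]
    out[pos] <- stats::rbeta(sum(pos), p * (1 - f) / f,
                             (1 - p) * (1 - f) / f)
  }
  out
}

# place non-overlapping islands of `len` consecutive windows among `n`
# full windows so that approximately `frac * n` windows are elevated
.place_islands <- function(n, frac, len) {
  elevated <- logical(n)
  n_isl <- round(frac * n / len)
  if (n_isl == 0 || n < len) return(elevated)
  free <- rep(TRUE, n)
  placed <- 0
  guard <- 0
  while (placed < n_isl && guard < 50 * n_isl) {
    guard <- guard + 1
    s <- sample.int(n - len + 1L, 1L)
    idx <- s:(s + len - 1L)
    # keep islands separated by at least one baseline window
    lo <- max(1L, s - 1L); hi <- min(n, s + len)
    if (all(free[lo:hi])) {
      elevated[idx] <- TRUE
      free[lo:hi] <- FALSE
      placed <- placed + 1
    }
  }
  elevated
}

#' Simulate a two-species allopatry/sympatry dataset
#'
#' Generates a \code{\link{site_table}} plus population map, genome layout,
#' callable mask and ground truth under the scenario described in
#' \code{\link{simulation_config}}. Per polymorphic site an ancestral
#' frequency p0 is drawn from a folded neutral-SFS grid; the two species'
#' frequencies pA, pB are independent Balding-Nichols draws around p0 with
#' the window's drift coefficient. Allopatric genotypes are Binomial(2, p)
#' draws from the species frequency, sympatric genotypes from the
#' individual's admixture-mixture frequency. Depth is Poisson; genotypes with
#' zero depth are missing, and low-depth genotypes are emitted (not dropped)
#' so that downstream filters are exercised. Sites at which no alternate
#' allele was sampled in any individual are not emitted (a variant caller
#' would not report them).
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with elements \code{sites} (\code{site_table}),
#'   \code{pop_map}, \code{layout}, \code{mask}, \code{truth} (list with
#'   \code{window_F}, \code{ancestry_q}, \code{site_p0}) and \code{config}.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_per_pop
  pops <- c("allo_A", "allo_B", "sym_A", "sym_B")
  species <- c(allo_A = "A", allo_B = "B", sym_A = "A", sym_B = "B")
  samples <- unlist(lapply(pops, function(p) sprintf("%s_%02d", p, 1:n)))
  pop_of <- rep(pops, each = n)
  pop_map <- population_map(samples, pop_of, species[pop_of])

  set.seed(config$seed)
  q <- c(rep(0, n), rep(1, n),
         stats::rbeta(n, config$admix_alpha_A[1], config$admix_alpha_A[2]),
         stats::rbeta(n, config$admix_alpha_B[1], config$admix_alpha_B[2]))
  names(q) <- samples

  grid <- .sfs_grid(4 * n)
  a1 <- sum(1 / seq_len(4 * n - 1))
  wsize <- config$window_size
  nucs <- c("A", "C", "G", "T")

  layout <- genome_layout(config$chrom_spec$chrom, config$chrom_spec$length,
                          config$chrom_spec$class)
  site_list <- list(); gt_list <- list(); dp_list <- list()
  mask_list <- list(); winF_list <- list(); p0_list <- list()

  for (ci in seq_len(nrow(layout))) {
    # fixed per-chromosome offset of the seed keeps chromosomes independent
    # and the whole dataset reproducible
    set.seed(config$seed + 7919L * ci)
    cn <- layout$chrom[ci]; len <- layout$length[ci]
    is_z <- layout$class[ci] == "Z"

    # callable mask: drop 50-kb chunks at random
    chunk <- 50000
    cs <- seq(0, len - 1, by = chunk)
    ce <- pmin(cs + chunk, len)
    keep <- stats::runif(length(cs)) < config$callable_frac
    mask_list[[ci]] <- data.frame(chrom = cn, start = cs[keep],
                                  end = ce[keep], stringsAsFactors = FALSE)

    # per-window drift
    starts <- seq(0, len - 1, by = wsize)
    ends <- pmin(starts + wsize, len)
    n_win <- length(starts)
    if (is_z) {
      winF <- rep(config$F_z, n_win)
    } else {
      winF <- rep(config$F_base, n_win)
      winF[.place_islands(n_win, config$peak_fraction, config$peak_len)] <-
        config$F_peak
    }
    winF_list[[ci]] <- data.frame(chrom = cn, start = starts, end = ends,
                                  F = winF, stringsAsFactors = FALSE)

    # site positions: uniform within callable intervals at the class density
    m <- mask_list[[ci]]
    callable_bp <- sum(m$end - m$start)
    theta <- config$theta_auto * if (is_z) config$theta_z_factor else 1
    n_sites <- stats::rpois(1, callable_bp * theta * a1)
    if (n_sites == 0 || callable_bp == 0) next
    off <- sort(sample.int(callable_bp, min(n_sites, callable_bp)))
    cum <- cumsum(m$end - m$start)
    iv <- findInterval(off - 1L, c(0, cum[-length(cum)]))
    pos <- as.integer(m$start[iv] + (off - c(0, cum)[iv])) # 1-based

    p0 <- sample(grid$p, length(pos), replace = TRUE, prob = grid$w)
    Fs <- winF[.window_index(pos, wsize) + 1L]
    pA <- .bn_draw(p0, Fs)
    pB <- .bn_draw(p0, Fs)

    # per-individual sampling frequency: mixture by ancestry toward B
    P <- outer(pA, 1 - q) + outer(pB, q)
    gt <- matrix(stats::rbinom(length(P), 2L, P), nrow = nrow(P),
                 dimnames = list(NULL, samples))
    dp <- matrix(stats::rpois(length(P), config$mean_depth), nrow = nrow(P),
                 dimnames = list(NULL, samples))
    gt[dp == 0] <- NA_integer_

    # drop sites with no observed alternate allele
    seen <- rowSums(gt, na.rm = TRUE) > 0
    gt <- gt[seen, , drop = FALSE]; dp <- dp[seen, , drop = FALSE]
    pos <- pos[seen]; p0 <- p0[seen]

    ref <- sample(nucs, length(pos), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nucs, r), 1L), "")
    site_list[[ci]] <- data.frame(chrom = cn, pos = pos, ref = ref,
                                  alt = unname(alt),
                                  stringsAsFactors = FALSE)
    gt_list[[ci]] <- gt; dp_list[[ci]] <- dp
    p0_list[[ci]] <- data.frame(chrom = cn, pos = pos, p0 = p0,
                                stringsAsFactors = FALSE)
  }

  length(site_list) <- nrow(layout)
  length(gt_list) <- nrow(layout)
  length(dp_list) <- nrow(layout)
  length(p0_list) <- nrow(layout)
  keep_ci <- !vapply(site_list, is.null, TRUE)
  sites <- do.call(rbind, site_list[keep_ci])
  rownames(sites) <- NULL
  st <- site_table(sites, do.call(rbind, gt_list[keep_ci]),
                   do.call(rbind, dp_list[keep_ci]), samples)
  truth <- list(window_F = do.call(rbind, winF_list),
                ancestry_q = data.frame(sample = samples, q = unname(q),
                                        stringsAsFactors = FALSE),
                site_p0 = do.call(rbind, p0_list[keep_ci]))
  rownames(truth$window_F) <- rownames(truth$site_p0) <- NULL
  list(sites = st, pop_map = pop_map, layout = layout,
       mask = do.call(rbind, mask_list), truth = truth, config = config)
}
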