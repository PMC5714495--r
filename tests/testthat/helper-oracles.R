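# Brute-force oracles: O(n^2 * L) pairwise-difference counts computed
# directly from allele multisets, independent of the estimator formulas.

# per-population alleles at one site: retained genotypes only
.site_alleles <- function(gt_row, dp_row, cols, min_depth = 5) {
  g <- gt_row[cols]
  d <- dp_row[cols]
  g <- g[!is.na(g) & d >= min_depth]
  unlist(lapply(g, function(x) c(rep(1L, x), rep(0L, 2L - x))))
}

# mean pairwise difference within a population, summed over sites
brute_pi_sum <- function(st, cols, min_depth = 5) {
  total <- 0
  for (i in seq_len(n_sites(st))) {
    al <- .site_alleles(st$gt[i, ], st$dp[i, ], cols, min_depth)
    n <- length(al)
    if (n < 2) next
    diffs <- 0; pairs <- 0
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      diffs <- diffs + (al[a] != al[b])
      pairs <- pairs + 1
    }
    total <- total + diffs / pairs
  }
  unname(total)
}

# mean between-population pairwise difference, summed over sites
brute_dxy_sum <- function(st, colsA, colsB, min_depth = 5) {
  total <- 0
  for (i in seq_len(n_sites(st))) {
    a <- .site_alleles(st$gt[i, ], st$dp[i, ], colsA, min_depth)
    b <- .site_alleles(st$gt[i, ], st$dp[i, ], colsB, min_depth)
    if (length(a) == 0 || length(b) == 0) next
    diffs <- 0
    for (x in a) for (y in b) diffs <- diffs + (x != y)
    total <- total + diffs / (length(a) * length(b))
  }
  unname(total)
}

# full-CDS retranslation oracle for coding effects
retranslate_effect <- function(model, g, pos, alt) {
  s <- model$seqs[[g$chrom]]
  protein <- function(sq) {
    pieces <- lapply(seq_len(nrow(g$cds)), function(i)
      Biostrings::subseq(sq, g$cds$start[i], g$cds$end[i]))
    cs <- do.call(Biostrings::xscat, pieces)
    if (g$strand == "-") cs <- Biostrings::reverseComplement(cs)
    ph0 <- if (g$strand == "+") g$cds$phase[1] else g$cds$phase[nrow(g$cds)]
    cs <- Biostrings::subseq(cs, ph0 + 1)
    as.character(Biostrings::translate(
      Biostrings::DNAString(as.character(cs)), if.fuzzy.codon = "X"))
  }
  mut <- Biostrings::replaceLetterAt(s, pos, alt)
  if (protein(s) == protein(mut)) "synonymous" else "nonsynonymous"
}

# a small random site table with missingness, for oracle comparisons
random_site_table <- function(n_site = 80, n_per_pop = 5, seed = 1,
                              chrom = "c1") {
  set.seed(seed)
  n_samp <- 2 * n_per_pop
  samples <- sprintf("s%02d", seq_len(n_samp))
  gt <- matrix(sample(0:2, n_site * n_samp, replace = TRUE,
                      prob = c(0.5, 0.3, 0.2)),
               nrow = n_site, dimnames = list(NULL, samples))
  dp <- matrix(rpois(n_site * n_samp, 8), nrow = n_site,
               dimnames = list(NULL, samples))
  gt[dp == 0] <- NA_integer_
  sites <- data.frame(chrom = chrom,
                      pos = sort(sample.int(9000, n_site)),
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  list(st = site_table(sites, gt, dp, samples),
       pop_map = population_map(samples,
                                rep(c("allo_A", "allo_B"), each = n_per_pop),
                                rep(c("A", "B"), each = n_per_pop)))
}

# hand-buildable site table from per-population allele count specs:
# each row of `spec` is c(nA_ind, altA, nB_ind, altB) with full depth
count_site_table <- function(spec, n_per_pop = 10, chrom = "c1") {
  n_samp <- 2 * n_per_pop
  samples <- sprintf("s%02d", seq_len(n_samp))
  gt <- matrix(0L, nrow = nrow(spec), ncol = n_samp,
               dimnames = list(NULL, samples))
  fill <- function(alt, n_ind) {
    # dosage vector with `alt` alternate alleles among n_ind diploids
    g <- integer(n_ind)
    full <- alt %/% 2
    g[seq_len(full)] <- 2L
    if (alt %% 2 == 1) g[full + 1] <- 1L
    g
  }
  for (i in seq_len(nrow(spec))) {
    gt[i, 1:n_per_pop] <- fill(spec[i, 2], n_per_pop)
    gt[i, (n_per_pop + 1):n_samp] <- fill(spec[i, 4], n_per_pop)
  }
  dp <- matrix(10L, nrow = nrow(spec), ncol = n_samp,
               dimnames = list(NULL, samples))
  sites <- data.frame(chrom = chrom, pos = seq_len(nrow(spec)) * 100,
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  list(st = site_table(sites, gt, dp, samples),
       pop_map = population_map(samples,
                                rep(c("allo_A", "allo_B"), each = n_per_pop),
                                rep(c("A", "B"), each = n_per_pop)))
}
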