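#' Pearson chi-square statistic for a contingency table
#'
#' Plain Pearson statistic \code{sum((obs - exp)^2 / exp)} with expected
#' counts from the product of the marginals; no continuity correction.
#'
#' @param table numeric matrix of non-negative counts, at least 2 x 2.
#' @return list with \code{statistic} and \code{df} = (r-1)(c-1).
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("need at least a 2 x 2 table")
  if (any(table < 0)) stop("negative counts")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal total")
  expd <- outer(rs, cs) / sum(table)
  list(statistic = sum((table - expd)^2 / expd),
       df = (nrow(table) - 1) * (ncol(table) - 1))
}

#' Two-sample distribution comparison statistics
#'
#' Kolmogorov-Smirnov statistic \code{D = sup |ECDF_x - ECDF_y|} and the
#' rank-sum statistic \code{W} = sum of the (mid-)ranks of \code{x} in the
#' pooled ranking. \code{W} lies between \code{n_x(n_x+1)/2} and
#' \code{n_x(n_x + 2 n_y + 1)/2}.
#'
#' @param x,y non-empty numeric samples.
#' @return list with \code{D} and \code{W}.
#' @export
compare_distributions <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  pts <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(pts)
  Fy <- stats::ecdf(y)(pts)
  ranks <- rank(c(x, y))   # midranks for ties
  list(D = max(abs(Fx - Fy)), W = sum(ranks[seq_along(x)]))
}

#' Pearson correlation between two window-statistic columns
#'
#' Windows where either field is undefined are dropped pairwise.
#'
#' @param win_stats window statistics data.frame.
#' @param field_x,field_y column names.
#' @return Pearson r; \code{NA} with a warning when fewer than 3 complete
#'   windows or zero variance.
#' @export
window_correlation <- function(win_stats, field_x, field_y) {
  x <- win_stats[[field_x]]; y <- win_stats[[field_y]]
  if (is.null(x) || is.null(y)) stop("unknown field")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) {
    warning("fewer than 3 complete windows")
    return(NA_real_)
  }
  if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
    warning("zero variance")
    return(NA_real_)
  }
  stats::cor(x[ok], y[ok])
}

#' Published SNP category counts for the chiffchaff species pair
#'
#' Counts of shared, private and fixed SNPs between common (*abietinus*) and
#' Siberian (*tristis*) chiffchaff population pairs sampled in allopatry and
#' sympatry, stratified by chromosome class, as published for this study
#' system. Shipped as a plain-text table; used as input for the
#' contingency-table statistics.
#'
#' @return data.frame with columns \code{comparison}, \code{chrom_class},
#'   \code{shared}, \code{private_A}, \code{private_B}, \code{fixed},
#'   \code{total}.
#' @export
snp_category_counts <- function() {
  path <- system.file("extdata", "chiffchaff_snp_counts.tsv",
                      package = "divscan")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

# fixed significant-digit formatting so regenerated reports are
# byte-identical
.fmt <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 4), format = "g", digits = 4))
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], .fmt)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# mean +/- sd summary of a window column within a chromosome-class stratum
.mean_sd <- function(v, sel) {
  v <- v[sel & !is.na(v)]
  c(mean = mean(v), sd = stats::sd(v))
}

#' Assemble the genome-scan report
#'
#' Writes the standard result tables of the analysis to \code{out_dir}:
#' per-comparison SNP category tables, per-population window-mean diversity
#' summaries (autosome / Z / all), per-comparison FST and DXY summaries
#' (with SD estimated across windows), the scored window table, outlier
#' regions as TSV and BED, and (optionally) a Manhattan-style plot of
#' standardized FST with region shading.
#'
#' @param out_dir output directory.
#' @param win_stats window statistics (see
#'   \code{\link{compute_window_stats}}), scored by
#'   \code{\link{zscore_fst}}/\code{\link{call_outliers}} if available.
#' @param partitions named list of data.frames from
#'   \code{\link{partition_table}} (one per comparison).
#' @param regions outlier regions data.frame (may be empty).
#' @param pops populations with diversity columns in \code{win_stats}.
#' @param pairs named list of comparisons with FST/DXY columns.
#' @param make_plots write PNG plots (requires a working png device).
#' @return named vector of written file paths, invisibly.
#' @export
assemble_report <- function(out_dir, win_stats, partitions, regions,
                            pops = c("allo_A", "allo_B", "sym_A", "sym_B"),
                            pairs = c("allopatric", "sympatric"),
                            make_plots = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  for (nm in names(partitions)) {
    f <- file.path(out_dir, paste0("categories_", nm, ".tsv"))
    .write_tsv(partitions[[nm]], f)
    files[paste0("categories_", nm)] <- f
  }
  strata <- list(autosome = win_stats$class == "autosome",
                 Z = win_stats$class == "Z",
                 all = rep(TRUE, nrow(win_stats)))
  rows <- list()
  for (p in pops) for (s in names(strata)) {
    pi_ <- .mean_sd(win_stats[[paste0("theta_pi_", p)]], strata[[s]])
    tw <- .mean_sd(win_stats[[paste0("theta_w_", p)]], strata[[s]])
    td <- .mean_sd(win_stats[[paste0("tajima_d_", p)]], strata[[s]])
    r2c <- win_stats[[paste0("mean_r2_", p)]]
    r2 <- if (is.null(r2c)) c(mean = NA_real_, sd = NA_real_)
          else .mean_sd(r2c, strata[[s]])
    rows[[length(rows) + 1L]] <- data.frame(
      population = p, stratum = s,
      theta_pi = pi_["mean"], theta_pi_sd = pi_["sd"],
      theta_w = tw["mean"], theta_w_sd = tw["sd"],
      tajima_d = td["mean"], tajima_d_sd = td["sd"],
      mean_r2 = r2["mean"], mean_r2_sd = r2["sd"],
      stringsAsFactors = FALSE)
  }
  div_tab <- do.call(rbind, rows); rownames(div_tab) <- NULL
  f <- file.path(out_dir, "diversity_summary.tsv")
  .write_tsv(div_tab, f); files["diversity_summary"] <- f

  rows <- list()
  for (pr in pairs) for (s in names(strata)) {
    fs <- .mean_sd(win_stats[[paste0("fst_", pr)]], strata[[s]])
    dx <- .mean_sd(win_stats[[paste0("dxy_", pr)]], strata[[s]])
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = pr, stratum = s,
      fst = fs["mean"], fst_sd = fs["sd"],
      dxy = dx["mean"], dxy_sd = dx["sd"], stringsAsFactors = FALSE)
  }
  diff_tab <- do.call(rbind, rows); rownames(diff_tab) <- NULL
  f <- file.path(out_dir, "differentiation_summary.tsv")
  .write_tsv(diff_tab, f); files["differentiation_summary"] <- f

  f <- file.path(out_dir, "windows.tsv")
  .write_tsv(win_stats, f); files["windows"] <- f

  reg <- regions
  if (!is.null(reg$outlier_starts)) reg$outlier_starts <- NULL
  f <- file.path(out_dir, "regions.tsv")
  .write_tsv(reg, f); files["regions"] <- f
  f <- file.path(out_dir, "regions.bed")
  writeLines(if (nrow(reg) > 0)
    paste(reg$chrom, format(reg$start, scientific = FALSE, trim = TRUE),
          format(reg$end, scientific = FALSE, trim = TRUE), sep = "\t")
    else character(0), f)
  files["regions_bed"] <- f

  if (make_plots && !is.null(win_stats$fst_z) &&
      capabilities("png")) {
    dat <- win_stats[!is.na(win_stats$fst_z), , drop = FALSE]
    dat$mid <- (dat$start + dat$end) / 2
    gp <- ggplot2::ggplot(dat, ggplot2::aes(x = mid, y = fst_z)) +
      ggplot2::geom_point(size = 0.3, alpha = 0.6) +
      ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
      ggplot2::labs(x = "position (bp)", y = expression(F[ST]^Z)) +
      ggplot2::theme_bw()
    if (nrow(reg) > 0)
      gp <- gp + ggplot2::geom_rect(
        data = reg, inherit.aes = FALSE,
        ggplot2::aes(xmin = start, xmax = end),
        ymin = -Inf, ymax = Inf, fill = "red", alpha = 0.2)
    f <- file.path(out_dir, "fst_z_manhattan.png")
    suppressMessages(ggplot2::ggsave(f, gp, width = 10, height = 3,
                                     dpi = 120))
    files["manhattan"] <- f
  }
  invisible(files)
}
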