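#' Per-population genotype filter profiles
#'
#' The \code{standard} profile keeps a site when at least 7 individuals per
#' population have a called genotype covered by at least 5 reads, in all four
#' populations. The \code{strict} profile, used for the fixed-difference
#' effect analysis, requires at least 9 such individuals but only in the two
#' allopatric populations.
#'
#' @param profile \code{"standard"}, \code{"strict"}, or \code{"custom"}.
#' @param min_individuals genotypes retained per required population
#'   (overrides the profile default).
#' @param min_depth minimum reads per genotype (default 5).
#' @param populations_required populations in which the threshold must hold.
#' @return a \code{filter_profile} list.
#' @export
filter_profile <- function(profile = c("standard", "strict", "custom"),
                           min_individuals = NULL, min_depth = 5,
                           populations_required = NULL) {
  profile <- match.arg(profile)
  if (profile == "standard") {
    if (is.null(min_individuals)) min_individuals <- 7
    if (is.null(populations_required))
      populations_required <- c("allo_A", "allo_B", "sym_A", "sym_B")
  } else if (profile == "strict") {
    if (is.null(min_individuals)) min_individuals <- 9
    if (is.null(populations_required))
      populations_required <- c("allo_A", "allo_B")
  } else {
    if (is.null(min_individuals) || is.null(populations_required))
      stop("custom profile needs min_individuals and populations_required")
  }
  if (min_depth < 1) stop("min_depth must be >= 1")
  structure(list(name = profile, min_individuals = min_individuals,
                 min_depth = min_depth,
                 populations_required = populations_required),
            class = "filter_profile")
}

#' Apply a depth/completeness filter and count retained alleles
#'
#' A genotype counts toward its population only when it is non-missing and
#' covered by at least \code{min_depth} reads. A site passes when every
#' required population retains at least \code{min_individuals} genotypes.
#'
#' @param st a \code{\link{site_table}}.
#' @param pop_map a \code{\link{population_map}} covering all samples.
#' @param profile a \code{\link{filter_profile}}.
#' @return list with \code{pass} (logical per site), \code{n} (matrix of
#'   retained allele counts, sites x populations; 2 alleles per retained
#'   diploid genotype) and \code{alt} (matrix of retained alternate-allele
#'   counts).
#' @export
pass_filter <- function(st, pop_map, profile) {
  stopifnot(inherits(st, "site_table"), inherits(profile, "filter_profile"))
  pops <- unique(pop_map$population)
  retained <- !is.na(st$gt) & st$dp >= profile$min_depth
  n <- matrix(0L, nrow = n_sites(st), ncol = length(pops),
              dimnames = list(NULL, pops))
  alt <- n
  for (p in pops) {
    cols <- match(pop_samples(pop_map, p), st$samples)
    if (anyNA(cols)) stop("population map sample missing from site table")
    r <- retained[, cols, drop = FALSE]
    n[, p] <- 2L * rowSums(r)
    g <- st$gt[, cols, drop = FALSE]
    g[!r] <- 0L
    alt[, p] <- rowSums(g, na.rm = TRUE)
  }
  req <- profile$populations_required
  missing_pop <- setdiff(req, pops)
  if (length(missing_pop) > 0)
    stop("required population(s) not in map: ",
         paste(missing_pop, collapse = ", "))
  pass <- rowSums(n[, req, drop = FALSE] >=
                    2L * profile$min_individuals) == length(req)
  list(pass = pass, n = n, alt = alt)
}

#' Classify sites as shared, private or fixed between two groups
#'
#' A group is polymorphic at a site when its retained alternate-allele count
#' is strictly between 0 and its retained allele count. Categories:
#' \code{fixed} (both monomorphic, different alleles), \code{shared} (both
#' polymorphic), \code{private_A}/\code{private_B} (exactly one polymorphic),
#' \code{monomorphic} (both monomorphic, same allele).
#'
#' @param nA,altA retained allele counts and alternate counts in group A
#'   (vectors).
#' @param nB,altB the same for group B.
#' @return character vector of categories.
#' @export
classify_site <- function(nA, altA, nB, altB) {
  if (any(nA == 0) || any(nB == 0))
    stop("zero retained alleles; filter sites before classification")
  polyA <- altA > 0 & altA < nA
  polyB <- altB > 0 & altB < nB
  monoA <- ifelse(polyA, NA, altA > 0)   # TRUE = fixed alt, FALSE = fixed ref
  monoB <- ifelse(polyB, NA, altB > 0)
  out <- character(length(nA))
  out[polyA & polyB] <- "shared"
  out[polyA & !polyB] <- "private_A"
  out[!polyA & polyB] <- "private_B"
  both_mono <- !polyA & !polyB
  out[both_mono & monoA != monoB] <- "fixed"
  out[both_mono & monoA == monoB] <- "monomorphic"
  out
}

#' Tabulate SNP categories for a species-pair comparison
#'
#' Applies the filter, classifies every passing site for the given pair of
#' populations, and tabulates counts and proportions stratified by
#' chromosome class (autosome / Z / all). Proportions use the
#' shared + private + fixed total as denominator; monomorphic and filtered
#' sites are excluded.
#'
#' @param st a \code{\link{site_table}}.
#' @param pop_map a \code{\link{population_map}}.
#' @param profile a \code{\link{filter_profile}}.
#' @param layout a \code{\link{genome_layout}}.
#' @param pair length-2 character vector: the population compared as group A
#'   and as group B (e.g. \code{c("allo_A", "allo_B")}).
#' @return data.frame with one row per stratum (\code{autosome}, \code{Z},
#'   \code{all}): counts \code{shared}, \code{private_A}, \code{private_B},
#'   \code{fixed}, \code{total} and matching \code{prop_*} columns.
#' @export
partition_table <- function(st, pop_map, profile, layout,
                            pair = c("allo_A", "allo_B")) {
  fl <- pass_filter(st, pop_map, profile)
  keep <- fl$pass
  cat_all <- rep(NA_character_, n_sites(st))
  cat_all[keep] <- classify_site(fl$n[keep, pair[1]], fl$alt[keep, pair[1]],
                                 fl$n[keep, pair[2]], fl$alt[keep, pair[2]])
  cls <- layout$class[match(st$sites$chrom, layout$chrom)]
  strata <- list(autosome = cls == "autosome", Z = cls == "Z",
                 all = rep(TRUE, length(cls)))
  cats <- c("shared", "private_A", "private_B", "fixed")
  rows <- lapply(names(strata), function(s) {
    x <- cat_all[strata[[s]] & keep]
    counts <- vapply(cats, function(k) sum(x == k, na.rm = TRUE), 0)
    tot <- sum(counts)
    if (tot == 0) {
      warning("no polymorphic sites in stratum '", s, "'")
      props <- rep(0, length(cats))
    } else props <- counts / tot
    data.frame(stratum = s, t(counts), total = tot,
               t(stats::setNames(props, paste0("prop_", cats))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
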