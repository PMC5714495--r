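#' Read gene models from GFF3 plus reference FASTA
#'
#' Builds an annotation model with one transcript per gene (the first mRNA
#' encountered). Genes whose CDS length, after removing the leading phase,
#' is not a multiple of 3 are flagged non-coding for effect calls (with a
#' warning) but still contribute to location classification.
#'
#' @param gff_path GFF3 file with gene/mRNA/exon/CDS features.
#' @param fasta_path reference FASTA covering all CDS coordinates.
#' @return object of class \code{annotation_model}: list with \code{genes}
#'   (per-gene records), \code{gene_table} (summary data.frame) and
#'   \code{seqs} (DNAStringSet).
#' @export
read_gene_models <- function(gff_path, fasta_path) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  typ <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(as.list(gr$Parent),
                    function(p) if (length(p)) p[[1]] else NA_character_, "")
  genes <- which(typ == "gene")
  model_genes <- list()
  for (gi in genes) {
    gid <- ids[gi]
    mrnas <- which(typ == "mRNA" & parents == gid)
    if (length(mrnas) == 0) next
    tid <- ids[mrnas[1]]   # first transcript only
    ex_i <- which(typ == "exon" & parents == tid)
    cds_i <- which(typ == "CDS" & parents == tid)
    ex <- data.frame(start = GenomicRanges::start(gr)[ex_i],
                     end = GenomicRanges::end(gr)[ex_i])
    ex <- ex[order(ex$start), , drop = FALSE]
    cds <- data.frame(start = GenomicRanges::start(gr)[cds_i],
                      end = GenomicRanges::end(gr)[cds_i],
                      phase = suppressWarnings(
                        as.integer(as.character(gr$phase[cds_i]))))
    cds <- cds[order(cds$start), , drop = FALSE]
    strand <- as.character(GenomicRanges::strand(gr)[gi])
    coding_ok <- FALSE
    if (nrow(cds) > 0) {
      ph0 <- if (strand == "+") cds$phase[1] else cds$phase[nrow(cds)]
      if (is.na(ph0)) ph0 <- 0L
      total <- sum(cds$end - cds$start + 1L)
      coding_ok <- (total - ph0) %% 3L == 0L
      if (!coding_ok)
        warning("gene ", gid,
                ": CDS length not a multiple of 3 after phase; ",
                "excluded from coding-effect calls")
    }
    model_genes[[gid]] <- list(
      id = gid, chrom = as.character(GenomicRanges::seqnames(gr)[gi]),
      strand = strand,
      start = GenomicRanges::start(gr)[gi],
      end = GenomicRanges::end(gr)[gi],
      exons = ex, cds = cds, coding_ok = coding_ok)
  }
  gene_table <- do.call(rbind, lapply(model_genes, function(g)
    data.frame(id = g$id, chrom = g$chrom, start = g$start, end = g$end,
               strand = g$strand, coding_ok = g$coding_ok,
               stringsAsFactors = FALSE)))
  rownames(gene_table) <- NULL
  structure(list(genes = model_genes, gene_table = gene_table, seqs = seqs),
            class = "annotation_model")
}

# feature ranges (1-based inclusive) of one kind across all genes
.model_ranges <- function(model, kind, flank = 5000, splice_bp = 2) {
  rows <- list()
  for (g in model$genes) {
    r <- switch(kind,
      cds = g$cds[, c("start", "end"), drop = FALSE],
      exon = g$exons,
      intron = {
        ex <- g$exons
        if (nrow(ex) < 2) NULL else
          data.frame(start = ex$end[-nrow(ex)] + 1L,
                     end = ex$start[-1] - 1L)
      },
      splice = {
        ex <- g$exons
        if (nrow(ex) < 2) NULL else {
          is_ <- ex$end[-nrow(ex)] + 1L
          ie_ <- ex$start[-1] - 1L
          keep <- ie_ >= is_
          is_ <- is_[keep]; ie_ <- ie_[keep]
          data.frame(start = c(is_, pmax(is_, ie_ - splice_bp + 1L)),
                     end = c(pmin(ie_, is_ + splice_bp - 1L), ie_))
        }
      },
      upstream = {
        if (g$strand == "+")
          data.frame(start = max(1L, g$start - flank), end = g$start - 1L)
        else
          data.frame(start = g$end + 1L, end = g$end + flank)
      },
      downstream = {
        if (g$strand == "+")
          data.frame(start = g$end + 1L, end = g$end + flank)
        else
          data.frame(start = max(1L, g$start - flank), end = g$start - 1L)
      })
    if (!is.null(r) && nrow(r) > 0) {
      r <- r[r$end >= r$start, , drop = FALSE]
      if (nrow(r) > 0)
        rows[[length(rows) + 1L]] <- data.frame(chrom = g$chrom, r,
                                                stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(GenomicRanges::GRanges())
  df <- do.call(rbind, rows)
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}

#' Classify SNP locations relative to gene models
#'
#' Assigns each SNP exactly one location class with precedence
#' exon (CDS) > other (UTR or splice) > intron > upstream > downstream >
#' intergenic. UTRs are exonic positions outside the CDS; splice positions
#' are the first/last \code{splice_bp} bases of an intron. Upstream and
#' downstream are strand-aware within \code{flank} bp of the gene.
#'
#' @param model an \code{annotation_model}.
#' @param chrom,pos SNP coordinates (1-based).
#' @param flank flank distance in bp (default 5000).
#' @param splice_bp intronic splice-region width at each boundary.
#' @return character vector of classes: \code{"exon"}, \code{"other"},
#'   \code{"intron"}, \code{"upstream"}, \code{"downstream"},
#'   \code{"intergenic"}.
#' @export
classify_location <- function(model, chrom, pos, flank = 5000,
                              splice_bp = 2) {
  unknown <- setdiff(unique(chrom), names(model$seqs))
  if (length(unknown) > 0)
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  snp <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  out <- rep("intergenic", length(pos))
  layers <- list(
    downstream = .model_ranges(model, "downstream", flank, splice_bp),
    upstream = .model_ranges(model, "upstream", flank, splice_bp),
    intron = .model_ranges(model, "intron", flank, splice_bp),
    other_splice = .model_ranges(model, "splice", flank, splice_bp),
    other_utr = .model_ranges(model, "exon", flank, splice_bp),
    exon = .model_ranges(model, "cds", flank, splice_bp))
  labels <- c(downstream = "downstream", upstream = "upstream",
              intron = "intron", other_splice = "other",
              other_utr = "other", exon = "exon")
  for (nm in names(layers)) {
    gr <- layers[[nm]]
    if (length(gr) == 0) next
    hit <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(snp, gr)))
    out[hit] <- labels[[nm]]
  }
  # exonic non-CDS positions are UTR -> "other"; the layering above already
  # paints exon over UTR last, so repaint UTR-only hits
  out
}

# 5'->3' CDS sequence of a gene and bookkeeping for codon lookup
.gene_cds_seq <- function(model, g) {
  pieces <- lapply(seq_len(nrow(g$cds)), function(i)
    Biostrings::subseq(model$seqs[[g$chrom]], g$cds$start[i], g$cds$end[i]))
  s <- do.call(Biostrings::xscat, pieces)
  if (g$strand == "-") s <- Biostrings::reverseComplement(s)
  s
}

#' Coding effect of SNPs
#'
#' For SNPs inside a CDS, rebuilds the affected codon (strand- and
#' phase-aware) and compares the translated amino acids:
#' \code{"synonymous"} when unchanged, \code{"nonsynonymous"} otherwise.
#' SNPs within \code{splice_bp} intronic bases of an exon boundary of a
#' coding gene are \code{"splice"}. Everything else, including SNPs in genes
#' with invalid CDS, is \code{"none"}.
#'
#' @param model an \code{annotation_model}.
#' @param chrom,pos,ref,alt SNP records (1-based positions, single bases).
#' @param splice_bp intronic splice-region width.
#' @return character vector of effects.
#' @export
coding_effect <- function(model, chrom, pos, ref, alt, splice_bp = 2) {
  code <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- rep("none", length(pos))
  for (i in seq_along(pos)) {
    hit_gene <- NULL; kind <- NULL
    for (g in model$genes) {
      if (g$chrom != chrom[i]) next
      if (nrow(g$cds) > 0 &&
          any(pos[i] >= g$cds$start & pos[i] <= g$cds$end)) {
        hit_gene <- g; kind <- "cds"; break
      }
      ex <- g$exons
      if (nrow(ex) >= 2) {
        is_ <- ex$end[-nrow(ex)] + 1L
        ie_ <- ex$start[-1] - 1L
        in_splice <- any((pos[i] >= is_ & pos[i] <= pmin(ie_, is_ + splice_bp - 1L)) |
                         (pos[i] >= pmax(is_, ie_ - splice_bp + 1L) & pos[i] <= ie_))
        if (in_splice && nrow(g$cds) > 0) { hit_gene <- g; kind <- "splice"; break }
      }
    }
    if (is.null(hit_gene)) next
    if (kind == "splice") { out[i] <- "splice"; next }
    g <- hit_gene
    if (!g$coding_ok) { warning("gene ", g$id, " has invalid CDS"); next }
    ref_base <- as.character(Biostrings::subseq(model$seqs[[g$chrom]],
                                                pos[i], pos[i]))
    if (ref_base != ref[i])
      stop("REF allele disagrees with reference at ", chrom[i], ":", pos[i])
    widths <- g$cds$end - g$cds$start + 1L
    before <- cumsum(c(0L, widths[-length(widths)]))
    ci <- which(pos[i] >= g$cds$start & pos[i] <= g$cds$end)[1]
    off <- before[ci] + (pos[i] - g$cds$start[ci])   # 0-based, ascending
    total <- sum(widths)
    ph0 <- if (g$strand == "+") g$cds$phase[1] else g$cds$phase[nrow(g$cds)]
    if (is.na(ph0)) ph0 <- 0L
    orient <- if (g$strand == "+") off else total - 1L - off
    cpos <- orient - ph0
    if (cpos < 0) next                       # inside the trimmed phase bases
    codon_i <- cpos %/% 3L
    within <- cpos %% 3L
    s <- as.character(.gene_cds_seq(model, g))
    from <- ph0 + codon_i * 3L + 1L
    if (from + 2L > nchar(s)) next           # incomplete terminal codon
    codon <- substr(s, from, from + 2L)
    mut_base <- if (g$strand == "+") alt[i] else comp[[alt[i]]]
    mcodon <- codon
    substr(mcodon, within + 1L, within + 1L) <- mut_base
    out[i] <- if (code[[codon]] == code[[mcodon]]) "synonymous"
              else "nonsynonymous"
  }
  out
}

#' Genes overlapping outlier regions
#'
#' Lists every gene whose span overlaps any region by at least one bp
#' (half-open region coordinates), once, with the overlapping region(s).
#'
#' @param regions data.frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open, e.g. from \code{\link{merge_blocks}}).
#' @param model an \code{annotation_model}.
#' @return data.frame with \code{gene}, \code{chrom}, \code{start},
#'   \code{end}, \code{regions} (comma-separated \code{start-end} labels).
#' @export
regions_to_genes <- function(regions, model) {
  gt <- model$gene_table
  if (is.null(gt) || nrow(gt) == 0 || nrow(regions) == 0)
    return(data.frame(gene = character(), chrom = character(),
                      start = integer(), end = integer(),
                      regions = character()))
  gr_gene <- GenomicRanges::GRanges(gt$chrom,
                                    IRanges::IRanges(gt$start, gt$end))
  gr_reg <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start + 1,
                                                    regions$end))
  ov <- GenomicRanges::findOverlaps(gr_gene, gr_reg)
  if (length(ov) == 0)
    return(data.frame(gene = character(), chrom = character(),
                      start = integer(), end = integer(),
                      regions = character()))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  lab <- paste0(regions$chrom[sh], ":", regions$start[sh], "-",
                regions$end[sh])
  agg <- tapply(lab, qh, paste, collapse = ",")
  idx <- as.integer(names(agg))
  data.frame(gene = gt$id[idx], chrom = gt$chrom[idx],
             start = gt$start[idx], end = gt$end[idx],
             regions = as.character(agg), stringsAsFactors = FALSE)
}

#' Location-class frequency table by SNP category
#'
#' For each SNP category and chromosome class, the proportion of SNPs in
#' each location class. Rows sum to 1; empty strata give a zero row with a
#' warning.
#'
#' @param model an \code{annotation_model}.
#' @param chrom,pos SNP coordinates.
#' @param category SNP category per site (e.g. from
#'   \code{\link{classify_site}}); \code{NA} sites are ignored.
#' @param layout a \code{\link{genome_layout}}.
#' @param flank,splice_bp passed to \code{\link{classify_location}}.
#' @return data.frame: \code{category}, \code{chrom_class}, \code{n}, one
#'   proportion column per location class.
#' @export
category_effect_table <- function(model, chrom, pos, category, layout,
                                  flank = 5000, splice_bp = 2) {
  loc <- classify_location(model, chrom, pos, flank, splice_bp)
  cls <- layout$class[match(chrom, layout$chrom)]
  classes <- c("exon", "intron", "upstream", "downstream", "intergenic",
               "other")
  cats <- sort(unique(stats::na.omit(category)))
  rows <- list()
  for (cc in unique(layout$class)) for (k in cats) {
    sel <- !is.na(category) & category == k & cls == cc
    nn <- sum(sel)
    if (nn == 0) {
      warning("no SNPs for category '", k, "' on class ", cc)
      props <- stats::setNames(rep(0, length(classes)), classes)
    } else {
      props <- vapply(classes, function(l) mean(loc[sel] == l), 0)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(category = k, chrom_class = cc, n = nn, t(props),
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
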