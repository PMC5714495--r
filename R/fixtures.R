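# Synthetic gene models for the effect-annotation module. Each gene has
# three exons (widths 301/299/300 so that CDS phases are exercised); every
# second gene carries 5'/3' UTRs (CDS trimmed inside the terminal exons,
# still a multiple of 3). Strand alternates. Offsets are relative to a
# 0-based gene start.
.gene_template <- function(with_utr) {
  ex <- cbind(start = c(0L, 401L, 800L), end = c(301L, 700L, 1100L))
  if (with_utr) {
    cds <- cbind(start = c(60L, 401L, 800L), end = c(301L, 700L, 1040L))
  } else {
    cds <- ex
  }
  list(exons = ex, cds = cds, span = c(0L, 1100L))
}

# phases in translation order: bases to skip to reach the next codon start
.cds_phases <- function(widths) {
  before <- cumsum(c(0L, widths[-length(widths)]))
  as.integer((3L - before %% 3L) %% 3L)
}

# Place genes on each chromosome: one inside an elevated-drift window when
# the chromosome has any, the rest in baseline windows.
.plan_genes <- function(layout, window_F, genes_per_chrom, wsize) {
  plan <- list()
  gid <- 0L
  for (ci in seq_len(nrow(layout))) {
    cn <- layout$chrom[ci]
    wf <- window_F[window_F$chrom == cn, , drop = FALSE]
    base_F <- min(wf$F)
    peaks <- which(wf$F > base_F)
    base <- which(wf$F == base_F & !seq_len(nrow(wf)) %in% peaks)
    slots <- integer(0)
    if (length(peaks) > 0) slots <- peaks[ceiling(length(peaks) / 2)]
    n_base <- genes_per_chrom - length(slots)
    if (n_base > 0 && length(base) > 0)
      slots <- c(slots, base[unique(pmax(1L, round(
        seq(1, length(base), length.out = min(n_base, length(base))))))])
    for (k in seq_along(slots)) {
      gs <- wf$start[slots[k]] + 100L
      if (gs + 1100L > layout$length[ci]) next
      gid <- gid + 1L
      tpl <- .gene_template(with_utr = gid %% 2L == 0L)
      plan[[gid]] <- list(id = sprintf("gene%03d", gid), chrom = cn,
                          offset = gs,
                          strand = if (gid %% 2L == 0L) "-" else "+",
                          tpl = tpl,
                          in_peak = slots[k] %in% peaks)
    }
  }
  plan
}

.write_gff3 <- function(plan, path) {
  lines <- "##gff-version 3"
  for (g in plan) {
    s1 <- g$offset + 1L
    span <- g$tpl$span + g$offset
    tid <- paste0(g$id, ".t1")
    lines <- c(lines,
      paste(g$chrom, "divscan_sim", "gene", span[1] + 1L, span[2], ".",
            g$strand, ".", paste0("ID=", g$id), sep = "\t"),
      paste(g$chrom, "divscan_sim", "mRNA", span[1] + 1L, span[2], ".",
            g$strand, ".", paste0("ID=", tid, ";Parent=", g$id), sep = "\t"))
    ex <- g$tpl$exons + g$offset
    for (i in seq_len(nrow(ex)))
      lines <- c(lines,
        paste(g$chrom, "divscan_sim", "exon", ex[i, 1] + 1L, ex[i, 2], ".",
              g$strand, ".", paste0("Parent=", tid), sep = "\t"))
    cds <- g$tpl$cds + g$offset
    widths <- cds[, 2] - cds[, 1]
    ord <- if (g$strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
    ph <- integer(nrow(cds))
    ph[ord] <- .cds_phases(widths[ord])
    for (i in seq_len(nrow(cds)))
      lines <- c(lines,
        paste(g$chrom, "divscan_sim", "CDS", cds[i, 1] + 1L, cds[i, 2], ".",
              g$strand, ph[i], paste0("Parent=", tid), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated dataset to disk as standard-format fixtures
#'
#' Emits \code{sites.vcf}, \code{samples.tsv}, \code{layout.tsv},
#' \code{callable.bed}, \code{genes.gff3}, \code{ref.fasta} and
#' \code{truth.json} in \code{out_dir}. The reference FASTA is a random
#' sequence whose bases at variant positions equal the VCF REF alleles, so
#' VCF and FASTA are mutually consistent. Synthetic gene models are placed
#' with at least one gene inside an elevated-drift window (when present) and
#' the rest in baseline windows.
#'
#' @param dataset result of \code{\link{simulate_dataset}}.
#' @param out_dir output directory (created if needed).
#' @param genes_per_chrom gene models per chromosome.
#' @return named character vector of the seven file paths, invisibly.
#' @export
write_fixtures <- function(dataset, out_dir, genes_per_chrom = 4) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  st <- dataset$sites
  write_vcf(st, p("sites.vcf"), dataset$layout)
  utils::write.table(dataset$pop_map, p("samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$layout, p("layout.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_callable_mask(dataset$mask, p("callable.bed"))

  # gene models and reference sequence are derived from the dataset's seed
  # so write_fixtures is deterministic regardless of call order
  set.seed(dataset$config$seed + 104729L)
  plan <- .plan_genes(dataset$layout, dataset$truth$window_F,
                      genes_per_chrom, dataset$config$window_size)
  .write_gff3(plan, p("genes.gff3"))

  seqs <- lapply(seq_len(nrow(dataset$layout)), function(ci) {
    len <- dataset$layout$length[ci]
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    idx <- st$sites$chrom == dataset$layout$chrom[ci]
    s[st$sites$pos[idx]] <- st$sites$ref[idx]
    paste(s, collapse = "")
  })
  dna <- Biostrings::DNAStringSet(unlist(seqs))
  names(dna) <- dataset$layout$chrom
  Biostrings::writeXStringSet(dna, p("ref.fasta"))

  jsonlite::write_json(dataset$truth, p("truth.json"), digits = NA)
  files <- c(vcf = p("sites.vcf"), samples = p("samples.tsv"),
             layout = p("layout.tsv"), mask = p("callable.bed"),
             gff = p("genes.gff3"), fasta = p("ref.fasta"),
             truth = p("truth.json"))
  invisible(files)
}
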