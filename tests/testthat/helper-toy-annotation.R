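# Builds a tiny two-gene annotation fixture on one 1-kb chromosome,
# written to temp files and read back through the package's own readers.
#
# geneP (+ strand): exons [101,106] and [201,206], CDS = exons
#   (sequence at 101..106 is fixed to ATGGCC so codon arithmetic is known).
# geneM (- strand): exons [501,506] and [601,606], CDS = exons.
# geneO overlaps geneP's intron with an exon (intron/exon precedence).
toy_annotation <- function(seed = 42, with_overlap = TRUE) {
  set.seed(seed)
  s <- sample(c("A", "C", "G", "T"), 1000, replace = TRUE)
  s[101:106] <- c("A", "T", "G", "G", "C", "C")
  s[201:206] <- c("G", "A", "A", "T", "T", "C")
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">toy", paste(s, collapse = "")), fa)

  gff <- tempfile(fileext = ".gff3")
  lines <- c("##gff-version 3",
    "toy\tt\tgene\t101\t206\t.\t+\t.\tID=geneP",
    "toy\tt\tmRNA\t101\t206\t.\t+\t.\tID=geneP.t1;Parent=geneP",
    "toy\tt\texon\t101\t106\t.\t+\t.\tParent=geneP.t1",
    "toy\tt\texon\t201\t206\t.\t+\t.\tParent=geneP.t1",
    "toy\tt\tCDS\t101\t106\t.\t+\t0\tParent=geneP.t1",
    "toy\tt\tCDS\t201\t206\t.\t+\t0\tParent=geneP.t1",
    "toy\tt\tgene\t501\t606\t.\t-\t.\tID=geneM",
    "toy\tt\tmRNA\t501\t606\t.\t-\t.\tID=geneM.t1;Parent=geneM",
    "toy\tt\texon\t501\t506\t.\t-\t.\tParent=geneM.t1",
    "toy\tt\texon\t601\t606\t.\t-\t.\tParent=geneM.t1",
    "toy\tt\tCDS\t501\t506\t.\t-\t0\tParent=geneM.t1",
    "toy\tt\tCDS\t601\t606\t.\t-\t0\tParent=geneM.t1")
  if (with_overlap)
    lines <- c(lines,
      "toy\tt\tgene\t140\t180\t.\t+\t.\tID=geneO",
      "toy\tt\tmRNA\t140\t180\t.\t+\t.\tID=geneO.t1;Parent=geneO",
      "toy\tt\texon\t140\t180\t.\t+\t.\tParent=geneO.t1",
      "toy\tt\tCDS\t140\t178\t.\t+\t0\tParent=geneO.t1")
  writeLines(lines, gff)
  suppressWarnings(read_gene_models(gff, fa))
}
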