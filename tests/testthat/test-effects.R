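test_that("location classes follow the documented precedence", {
  model <- toy_annotation()
  # geneP: exons [101,106], [201,206]; intron 107..200; geneO exon 140..180
  expect_equal(classify_location(model, "toy", 103), "exon")
  expect_equal(classify_location(model, "toy", 150), "exon")  # geneO CDS wins
  expect_equal(classify_location(model, "toy", 130), "intron")
  expect_equal(classify_location(model, "toy", 107), "other")  # splice donor
  expect_equal(classify_location(model, "toy", 200), "other")  # acceptor
  expect_equal(classify_location(model, "toy", 179), "other")  # geneO 3' UTR
  expect_equal(classify_location(model, "toy", 98), "upstream")
  expect_equal(classify_location(model, "toy", 210), "downstream")
  # geneM is on -, so downstream of it lies at lower coordinates
  expect_equal(classify_location(model, "toy", 490), "downstream")
  expect_equal(classify_location(model, "toy", 620), "upstream")
  expect_error(classify_location(model, "nope", 10), "unknown chromosome")
})

test_that("a distant SNP is intergenic beyond the flank", {
  model <- toy_annotation(with_overlap = FALSE)
  # with flank 100 the gap between geneP (ends 206) and geneM (starts 501)
  # leaves 307..400 intergenic
  expect_equal(classify_location(model, "toy", 350, flank = 100),
               "intergenic")
  expect_equal(classify_location(model, "toy", 300, flank = 100),
               "downstream")
})

test_that("coding effects resolve codon changes on the plus strand", {
  model <- toy_annotation()
  # CDS starts ATG GCC: position 106 is codon 2 pos 3 (GCC -> GCA, Ala=Ala)
  expect_equal(coding_effect(model, "toy", 106, "C", "A"), "synonymous")
  # position 104 is codon 2 pos 1 (GCC -> ACC, Ala -> Thr)
  expect_equal(coding_effect(model, "toy", 104, "G", "A"), "nonsynonymous")
  # intronic base 2 bp from the exon boundary is a splice call
  expect_equal(coding_effect(model, "toy", 108, "N", "A"), "splice")
  expect_equal(coding_effect(model, "toy", 199, "N", "A"), "splice")
  expect_equal(coding_effect(model, "toy", 130, "N", "A"), "none")
  # REF disagreement is an error naming the position
  expect_error(coding_effect(model, "toy", 104, "T", "A"), "toy:104")
})

test_that("reverse-strand genes give calls consistent with their + twin", {
  # chromosome B is the reverse complement of chromosome A with the gene
  # annotated on the opposite strand at mirrored coordinates
  set.seed(7)
  L <- 400
  sA <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  sA[101:103] <- c("A", "T", "G")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  sB <- rev(unname(comp[sA]))
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">chrA", paste(sA, collapse = ""),
               ">chrB", paste(sB, collapse = "")), fa)
  # + gene on chrA at [101, 160] (60 bp CDS), - twin on chrB mirrored
  bs <- L - 160 + 1; be <- L - 101 + 1
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "chrA\tt\tgene\t101\t160\t.\t+\t.\tID=gA",
    "chrA\tt\tmRNA\t101\t160\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chrA\tt\texon\t101\t160\t.\t+\t.\tParent=gA.t1",
    "chrA\tt\tCDS\t101\t160\t.\t+\t0\tParent=gA.t1",
    sprintf("chrB\tt\tgene\t%d\t%d\t.\t-\t.\tID=gB", bs, be),
    sprintf("chrB\tt\tmRNA\t%d\t%d\t.\t-\t.\tID=gB.t1;Parent=gB", bs, be),
    sprintf("chrB\tt\texon\t%d\t%d\t.\t-\t.\tParent=gB.t1", bs, be),
    sprintf("chrB\tt\tCDS\t%d\t%d\t.\t-\t0\tParent=gB.t1", bs, be)), gff)
  model <- read_gene_models(gff, fa)
  for (rep in 1:50) {
    pos <- sample(101:160, 1)
    ref <- sA[pos]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    mpos <- L - pos + 1
    eA <- coding_effect(model, "chrA", pos, ref, alt)
    eB <- coding_effect(model, "chrB", mpos, unname(comp[ref]),
                        unname(comp[alt]))
    expect_identical(eA, eB)
  }
})

test_that("effect calls agree with full-CDS retranslation on fixtures", {
  ds <- simulate_dataset(simulation_config(seed = 23, chrom_spec = data.frame(
    chrom = "c1", length = 2e5, class = "autosome")))
  d <- file.path(tempdir(), "eff")
  files <- write_fixtures(ds, d)
  model <- read_gene_models(files[["gff"]], files[["fasta"]])
  set.seed(99)
  for (rep in 1:200) {
    g <- model$genes[[sample(length(model$genes), 1)]]
    if (!g$coding_ok) next
    ci <- sample(nrow(g$cds), 1)
    pos <- sample(g$cds$start[ci]:g$cds$end[ci], 1)
    ref <- as.character(Biostrings::subseq(model$seqs[[g$chrom]], pos, pos))
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    expect_identical(coding_effect(model, g$chrom, pos, ref, alt),
                     retranslate_effect(model, g, pos, alt))
  }
})

test_that("regions_to_genes applies half-open 1-bp overlap", {
  model <- toy_annotation(with_overlap = FALSE)
  # geneP spans 101..206 (1-based)
  hit <- regions_to_genes(data.frame(chrom = "toy", start = 0, end = 300),
                          model)
  expect_true("geneP" %in% hit$gene)
  # overlap by exactly 1 bp at the gene start (region [90, 101) covers 101)
  hit2 <- regions_to_genes(data.frame(chrom = "toy", start = 90, end = 101),
                           model)
  expect_true("geneP" %in% hit2$gene)
  # region ending where the gene starts (half-open) does not overlap
  hit3 <- regions_to_genes(data.frame(chrom = "toy", start = 90, end = 100),
                           model)
  expect_false("geneP" %in% hit3$gene)
  # gene listed once with both regions
  hit4 <- regions_to_genes(data.frame(chrom = "toy", start = c(90, 150),
                                      end = c(120, 180)), model)
  expect_equal(sum(hit4$gene == "geneP"), 1)
})

test_that("category-by-location tables are row-normalized", {
  model <- toy_annotation(with_overlap = FALSE)
  lay <- genome_layout("toy", 1000, "autosome")
  chrom <- rep("toy", 4)
  pos <- c(103, 350, 820, 900)        # exon, intergenic-ish, far, far
  category <- c("fixed", "shared", "shared", "shared")
  tab <- suppressWarnings(category_effect_table(model, chrom, pos, category,
                                                lay, flank = 100))
  fixed_row <- tab[tab$category == "fixed", ]
  expect_equal(fixed_row$exon, 1)
  shared_row <- tab[tab$category == "shared", ]
  expect_equal(sum(shared_row[, c("exon", "intron", "upstream", "downstream",
                                  "intergenic", "other")]), 1,
               tolerance = 1e-12)
})
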