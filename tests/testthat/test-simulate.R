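small_spec <- data.frame(chrom = c("c1", "cZ"), length = c(4e5, 2e5),
                         class = c("autosome", "Z"), stringsAsFactors = FALSE)

test_that("config validation rejects inconsistent parameters", {
  expect_error(simulation_config(F_base = 0.5, F_peak = 0.2), "F_base")
  expect_error(simulation_config(theta_z_factor = 0), "theta_z_factor")
  expect_error(simulation_config(
    chrom_spec = data.frame(chrom = "c1", length = -5, class = "autosome")),
    "chromosome length")
  expect_error(simulation_config(
    chrom_spec = data.frame(chrom = "c1", length = 5000, class = "autosome")),
    "window_size")
})

test_that("identical seed gives byte-identical fixtures", {
  cfg <- simulation_config(seed = 77, chrom_spec = small_spec)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_fixtures(simulate_dataset(cfg), d1)
  write_fixtures(simulate_dataset(cfg), d2)
  for (f in c("sites.vcf", "callable.bed", "genes.gff3", "ref.fasta",
              "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # and a different seed changes the data
  d3 <- file.path(tempdir(), "det3")
  write_fixtures(simulate_dataset(simulation_config(seed = 78,
                                                    chrom_spec = small_spec)),
                 d3)
  expect_false(identical(readLines(file.path(d1, "sites.vcf")),
                         readLines(file.path(d3, "sites.vcf"))))
})

test_that("simulation truth covers every window and sympatric sample once", {
  ds <- simulate_dataset(simulation_config(seed = 5, chrom_spec = small_spec))
  win <- make_windows(ds$layout, ds$mask)
  expect_identical(nrow(ds$truth$window_F), nrow(win))
  expect_false(anyDuplicated(with(ds$truth$window_F,
                                  paste(chrom, start))) > 0)
  q <- ds$truth$ancestry_q
  expect_setequal(q$sample, ds$pop_map$sample)
  expect_true(all(q$q >= 0 & q$q <= 1))
  # allopatric samples are unadmixed by construction
  expect_true(all(q$q[grepl("^allo_A", q$sample)] == 0))
  expect_true(all(q$q[grepl("^allo_B", q$sample)] == 1))
})

test_that("no-drift limit gives FST near zero and neutral Tajima's D", {
  cfg <- simulation_config(seed = 3, F_base = 0, F_peak = 0, F_z = 0,
                           peak_fraction = 0,
                           chrom_spec = data.frame(chrom = "c1", length = 3e6,
                                                   class = "autosome"))
  ds <- simulate_dataset(cfg)
  expect_gt(n_sites(ds$sites), 20000)
  win <- make_windows(ds$layout, ds$mask)
  ws <- compute_window_stats(ds$sites, ds$pop_map, win)
  expect_lt(abs(mean(ws$fst_allopatric, na.rm = TRUE)), 0.01)
  expect_lt(abs(mean(ws$tajima_d_allo_A, na.rm = TRUE)), 0.3)
  expect_lt(abs(mean(ws$tajima_d_sym_B, na.rm = TRUE)), 0.3)
})

test_that("Balding-Nichols drift is recovered by window-mean Hudson FST", {
  cfg <- simulation_config(seed = 19, F_base = 0.2, F_peak = 0.2,
                           peak_fraction = 0, theta_auto = 0.002,
                           chrom_spec = data.frame(
                             chrom = c("c1", "c2"), length = c(1e7, 1e7),
                             class = "autosome"))
  ds <- simulate_dataset(cfg)
  win <- make_windows(ds$layout, ds$mask)
  expect_gte(sum(!win$partial), 2000)
  ws <- compute_window_stats(ds$sites, ds$pop_map, win,
                             pairs = list(allo = c("allo_A", "allo_B")))
  expect_lt(abs(mean(ws$fst_allo, na.rm = TRUE) - 0.2), 0.02)
})

test_that("Z-class diversity is reduced when theta_z_factor < 1", {
  cfg <- simulation_config(seed = 8, theta_z_factor = 0.5, F_z = 0.2,
                           peak_fraction = 0,
                           chrom_spec = data.frame(
                             chrom = c("c1", "cZ"), length = c(6e6, 6e6),
                             class = c("autosome", "Z")))
  ds <- simulate_dataset(cfg)
  win <- make_windows(ds$layout, ds$mask)
  ws <- compute_window_stats(ds$sites, ds$pop_map, win,
                             pops = "allo_A", pairs = list())
  z <- ws$class == "Z"
  expect_gte(sum(z & !is.na(ws$theta_pi_allo_A)), 500)
  tt <- t.test(ws$theta_pi_allo_A[z], ws$theta_pi_allo_A[!z],
               alternative = "less")
  expect_lt(tt$p.value, 1e-6)
})

test_that("identical admixture in both sympatric populations erases FST", {
  cfg <- simulation_config(seed = 21, admix_alpha_A = c(4, 4),
                           admix_alpha_B = c(4, 4),
                           chrom_spec = data.frame(chrom = "c1",
                                                   length = 3e6,
                                                   class = "autosome"))
  ds <- simulate_dataset(cfg)
  expect_gt(n_sites(ds$sites), 20000)
  win <- make_windows(ds$layout, ds$mask)
  ws <- compute_window_stats(ds$sites, ds$pop_map, win,
                             pairs = list(sym = c("sym_A", "sym_B")))
  expect_lt(abs(mean(ws$fst_sym, na.rm = TRUE)), 0.01)
})

test_that("admixture overlap lowers the sympatric fixed-difference fraction", {
  ds <- simulate_dataset(simulation_config(seed = 2))
  prof <- filter_profile("standard")
  pa <- partition_table(ds$sites, ds$pop_map, prof, ds$layout,
                        c("allo_A", "allo_B"))
  ps <- partition_table(ds$sites, ds$pop_map, prof, ds$layout,
                        c("sym_A", "sym_B"))
  fa <- pa$prop_fixed[pa$stratum == "all"]
  fs <- ps$prop_fixed[ps$stratum == "all"]
  expect_gt(fa, 0)
  expect_lt(fs, fa)
})

test_that("fixtures round-trip and respect coordinate bounds", {
  cfg <- simulation_config(seed = 9, chrom_spec = data.frame(
    chrom = "c1", length = 30000, class = "autosome"))
  ds <- simulate_dataset(cfg)
  d <- file.path(tempdir(), "rt")
  files <- write_fixtures(ds, d)
  expect_length(files, 7)
  expect_true(all(file.exists(files)))
  st2 <- read_vcf(files[["vcf"]], read_population_map(files[["samples"]]))
  expect_identical(st2$gt, ds$sites$gt)
  expect_identical(st2$dp, ds$sites$dp)
  expect_identical(st2$sites, ds$sites$sites)
  expect_true(all(st2$sites$pos >= 1 & st2$sites$pos <= 30000))
  # FASTA agrees with the VCF REF column at every site
  fa <- Biostrings::readDNAStringSet(files[["fasta"]])
  bases <- strsplit(as.character(fa[[1]]), "")[[1]]
  expect_identical(bases[st2$sites$pos], st2$sites$ref)
})

test_that("gene fixtures land in both elevated and baseline windows", {
  cfg <- simulation_config(seed = 13, peak_fraction = 0.1, peak_len = 5,
                           chrom_spec = data.frame(chrom = "c1",
                                                   length = 1e6,
                                                   class = "autosome"))
  ds <- simulate_dataset(cfg)
  d <- file.path(tempdir(), "genes")
  files <- write_fixtures(ds, d)
  model <- read_gene_models(files[["gff"]], files[["fasta"]])
  wf <- ds$truth$window_F
  gene_F <- wf$F[findInterval(model$gene_table$start - 1, wf$start)]
  expect_true(any(gene_F > min(wf$F)))
  expect_true(any(gene_F == min(wf$F)))
})
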