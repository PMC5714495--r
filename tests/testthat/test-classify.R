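test_that("filter profiles carry the documented thresholds", {
  std <- filter_profile("standard")
  expect_equal(std$min_individuals, 7)
  expect_equal(std$min_depth, 5)
  expect_length(std$populations_required, 4)
  strict <- filter_profile("strict")
  expect_equal(strict$min_individuals, 9)
  expect_setequal(strict$populations_required, c("allo_A", "allo_B"))
  expect_error(filter_profile("standard", min_depth = 0), "min_depth")
})

std2 <- filter_profile("custom", min_individuals = 7, min_depth = 5,
                       populations_required = c("allo_A", "allo_B"))

test_that("genotypes below the depth threshold are not retained", {
  tt <- count_site_table(matrix(c(10, 5, 10, 5), nrow = 1), n_per_pop = 10)
  # push 3 allo_A genotypes to depth 4: 7 retained -> still passes 7@5x
  tt$st$dp[1, 1:3] <- 4L
  fl <- pass_filter(tt$st, tt$pop_map, std2)
  expect_equal(fl$n[1, "allo_A"], c(allo_A = 14L))
  expect_true(fl$pass[1])
  # one more low-depth genotype -> 6 retained -> fails (needs 7)
  tt$st$dp[1, 4] <- 4L
  fl <- pass_filter(tt$st, tt$pop_map, std2)
  expect_equal(fl$n[1, "allo_A"], c(allo_A = 12L))
  expect_false(fl$pass[1])
})

test_that("all full-depth called genotypes are retained", {
  tt <- count_site_table(matrix(c(10, 3, 10, 0), nrow = 1), n_per_pop = 10)
  fl <- pass_filter(tt$st, tt$pop_map, std2)
  expect_equal(unname(fl$n[1, ]), c(20L, 20L))
  expect_equal(unname(fl$alt[1, ]), c(3L, 0L))
})

test_that("site categories follow the fixed/shared/private definitions", {
  expect_equal(classify_site(18, 0, 18, 18), "fixed")
  expect_equal(classify_site(20, 7, 18, 0), "private_A")
  expect_equal(classify_site(20, 0, 18, 3), "private_B")
  expect_equal(classify_site(20, 7, 18, 3), "shared")
  expect_equal(classify_site(20, 0, 18, 0), "monomorphic")
  expect_equal(classify_site(20, 20, 18, 18), "monomorphic")
  expect_error(classify_site(0, 0, 18, 3), "zero retained")
})

test_that("partition_table reproduces a hand count", {
  spec <- rbind(c(10, 0, 10, 20),  # fixed
                c(10, 20, 10, 0),  # fixed
                c(10, 5, 10, 9),   # shared
                c(10, 1, 10, 19),  # shared
                c(10, 7, 10, 0),   # private_A
                c(10, 0, 10, 3))   # private_B
  tt <- count_site_table(spec, n_per_pop = 10)
  lay <- genome_layout("c1", 1e4, "autosome")
  pt <- partition_table(tt$st, tt$pop_map, std2, lay,
                        c("allo_A", "allo_B"))
  all_row <- pt[pt$stratum == "all", ]
  expect_equal(all_row$fixed, 2)
  expect_equal(all_row$shared, 2)
  expect_equal(all_row$private_A, 1)
  expect_equal(all_row$private_B, 1)
  expect_equal(all_row$prop_fixed, 1 / 3)
  expect_equal(all_row$prop_shared, 1 / 3)
  expect_equal(all_row$prop_private_A, 1 / 6)
  expect_equal(all_row$prop_private_B, 1 / 6)
})

test_that("an all-monomorphic table degenerates to zeros with a warning", {
  tt <- count_site_table(rbind(c(10, 0, 10, 0), c(10, 20, 10, 20)))
  lay <- genome_layout("c1", 1e4, "autosome")
  expect_warning(pt <- partition_table(tt$st, tt$pop_map, std2, lay,
                                       c("allo_A", "allo_B")),
                 "no polymorphic")
  expect_true(all(pt$total == 0))
  expect_true(all(pt$prop_fixed == 0))
})

test_that("category counts partition the polymorphic sites", {
  rt <- random_site_table(n_site = 120, n_per_pop = 8, seed = 7)
  prof <- filter_profile("custom", min_individuals = 5,
                         populations_required = c("allo_A", "allo_B"))
  fl <- pass_filter(rt$st, rt$pop_map, prof)
  k <- which(fl$pass)
  cats <- classify_site(fl$n[k, "allo_A"], fl$alt[k, "allo_A"],
                        fl$n[k, "allo_B"], fl$alt[k, "allo_B"])
  expect_equal(sum(cats %in% c("shared", "private_A", "private_B", "fixed",
                               "monomorphic")), length(k))
})

test_that("tightening min_individuals never admits more sites", {
  rt <- random_site_table(n_site = 200, n_per_pop = 10, seed = 3)
  passes <- vapply(4:10, function(mi) {
    prof <- filter_profile("custom", min_individuals = mi,
                           populations_required = c("allo_A", "allo_B"))
    sum(pass_filter(rt$st, rt$pop_map, prof)$pass)
  }, 0)
  expect_true(all(diff(passes) <= 0))
})

test_that("the strict profile never finds more fixed differences", {
  ds <- simulate_dataset(simulation_config(seed = 31, chrom_spec = data.frame(
    chrom = "c1", length = 5e5, class = "autosome")))
  count_fixed <- function(prof) {
    fl <- pass_filter(ds$sites, ds$pop_map, prof)
    k <- which(fl$pass)
    sum(classify_site(fl$n[k, "allo_A"], fl$alt[k, "allo_A"],
                      fl$n[k, "allo_B"], fl$alt[k, "allo_B"]) == "fixed")
  }
  lax <- filter_profile("custom", min_individuals = 7,
                        populations_required = c("allo_A", "allo_B"))
  expect_lte(count_fixed(filter_profile("strict")), count_fixed(lax))
})
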