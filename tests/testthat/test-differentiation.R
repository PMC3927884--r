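test_that("Weir-Cockerham theta hits its analytic boundaries", {
  fixA <- one_locus_collection(n_aa = 30, river = "A")
  fixB <- one_locus_collection(n_bb = 30, river = "B")
  loci <- locus_table("L1")
  ds <- genotype_dataset(loci, list(fixA, fixB))
  expect_equal(wc_theta(ds)$theta, 1)

  set.seed(61)
  co <- hwe_collection(100, c(0.5, 0.3, 0.2), river = "A")
  dup <- collection("B", 2010L, co$alleles[sample(100), ])
  ds2 <- genotype_dataset(loci, list(co, dup))
  expect_lt(abs(wc_theta(ds2)$theta), 0.02)

  mono <- genotype_dataset(loci, list(one_locus_collection(n_aa = 10, river = "A"),
                                      one_locus_collection(n_aa = 10, river = "B")))
  expect_error(wc_theta(mono), "monomorphic")
})

test_that("island-model simulation recovers its target FST", {
  sim <- simulate_genotypes(n_stocks = 20, rivers_per_stock = 1,
                            individuals_per_river = 50, n_loci = 12,
                            alleles_per_locus = 8, f_stock = 0.05,
                            f_river = 0, seed = 62)
  th <- wc_theta(sim$dataset)$theta
  expect_gte(th, 0.04)
  expect_lte(th, 0.06)
})

test_that("standardized F'ST behaves as a maximum-scaled theta", {
  loci <- locus_table("L1")
  ds <- genotype_dataset(loci, list(one_locus_collection(n_aa = 30, river = "A"),
                                    one_locus_collection(n_bb = 30, river = "B")))
  fs <- fst_standardized(ds)
  expect_equal(fs$theta, 1)
  expect_equal(fs$theta_prime, 1)

  set.seed(63)
  co <- hwe_collection(80, c(0.5, 0.3, 0.2), river = "A")
  ds2 <- genotype_dataset(loci, list(co, collection("B", 2010L, co$alleles)))
  fs2 <- fst_standardized(ds2)
  expect_lt(abs(fs2$theta), 0.02)
  expect_lt(abs(fs2$theta_prime), 0.06)

  ## diverse pair: theta' strictly exceeds theta since theta_max < 1
  sim <- simulate_genotypes(n_stocks = 2, rivers_per_stock = 1,
                            individuals_per_river = 50, n_loci = 8,
                            f_stock = 0.08, seed = 64)
  fs3 <- fst_standardized(sim$dataset)
  expect_gt(fs3$theta, 0)
  expect_gt(fs3$theta_prime, fs3$theta)
  expect_lte(fs3$theta_prime, 1 + 1e-9)
  ## internal consistency: theta on the recoded data is theta_max
  expect_equal(wc_theta(stockpriority:::recode_disjoint(sim$dataset))$theta,
               fs3$theta_max)
})

test_that("genic test: null, signal and Fisher combination", {
  loci <- locus_table(c("L1", "L2"))
  co <- one_locus_collection(n_aa = 10, n_ab = 10, n_bb = 10, river = "A")
  m2 <- cbind(co$alleles, co$alleles[sample(30), ])
  A <- collection("A", 2010L, m2)
  B <- collection("B", 2010L, m2)        # identical allele counts
  ds <- genotype_dataset(loci, list(A, B))
  set.seed(65)
  g <- genic_test(ds, n_perm = 199)
  expect_true(all(g$per_locus == 1))
  expect_equal(g$p, 1)

  sim <- simulate_genotypes(n_stocks = 2, rivers_per_stock = 1,
                            individuals_per_river = 50, n_loci = 8,
                            f_stock = 0.1, seed = 66)
  expect_lt(genic_test(sim$dataset, n_perm = 999)$p, 0.001)

  fc <- fisher_combine(c(0.5, 0.5))
  expect_equal(fc$chisq, -2 * log(0.25), tolerance = 1e-9)   # 2.7726
  expect_equal(fc$df, 4L)
  expect_equal(fc$p, pchisq(2.772589, 4, lower.tail = FALSE), tolerance = 1e-4)
  expect_equal(round(fc$p, 3), 0.597)
})

test_that("Nei's DA matches hand calculations and bounds", {
  loci <- locus_table("L1")
  x <- one_locus_collection(n_ab = 10, river = "X")        # p = (0.5, 0.5)
  y <- one_locus_collection(n_aa = 10, river = "Y")        # p = (1, 0)
  ds <- genotype_dataset(loci, list(x, y))
  expect_equal(nei_da(ds, "X", "Y"), 1 - sqrt(0.5), tolerance = 1e-12)
  ## identical profiles -> 0
  ds2 <- genotype_dataset(loci, list(x, collection("Z", 2010L, x$alleles)))
  expect_equal(nei_da(ds2, "X", "Z"), 0)
  ## disjoint allele sets -> 1
  ds3 <- genotype_dataset(loci, list(one_locus_collection(n_aa = 5, river = "X"),
                                     one_locus_collection(n_aa = 5, a = 201L,
                                                          river = "Y")))
  expect_equal(nei_da(ds3, "X", "Y"), 1)
  m <- nei_da_matrix(ds)
  expect_true(isSymmetric(m))
  expect_equal(diag(m), setNames(c(0, 0), c("X", "Y")))
})

test_that("AMOVA closes to 100% and orders variance by design", {
  sim <- simulate_genotypes(n_stocks = 3, rivers_per_stock = 3,
                            individuals_per_river = 15, n_loci = 8,
                            f_stock = 0.15, f_river = 0.01, seed = 67)
  grouping <- setNames(sim$truth$stock, sim$truth$river)
  set.seed(68)
  am <- amova3(sim$dataset, grouping, n_perm = 99)
  expect_equal(sum(am$percent), 100, tolerance = 1e-6)
  expect_gt(am$percent[1], am$percent[2])   # among stocks > among rivers
  expect_lte(am$p_values[["CT"]], 0.05)
  expect_error(amova3(sim$dataset, setNames(rep("one", 9), sim$truth$river)),
               "degenerate")

  ## identical populations: among-level percentages near zero
  set.seed(69)
  co <- hwe_collection(30, c(0.5, 0.3, 0.2))
  cols <- lapply(c("A", "B", "C", "D"), function(r)
    collection(r, 2010L, co$alleles[sample(30, 30, TRUE), ]))
  ds0 <- genotype_dataset(locus_table("L1"), cols)
  am0 <- amova3(ds0, setNames(c("G1", "G1", "G2", "G2"), c("A", "B", "C", "D")),
                n_perm = 49)
  expect_lt(abs(am0$percent[1]) + abs(am0$percent[2]), 10)
})

test_that("AMOVA group-level p is roughly uniform under random grouping", {
  sim <- simulate_genotypes(n_stocks = 1, rivers_per_stock = 6,
                            individuals_per_river = 12, n_loci = 6,
                            f_stock = 0, f_river = 0.02, seed = 70)
  set.seed(71)
  ps <- replicate(20, {
    grouping <- setNames(sample(rep(c("G1", "G2"), 3)), sim$truth$river)
    amova3(sim$dataset, grouping, n_perm = 49)$p_values[["CT"]]
  })
  expect_gt(mean(ps), 0.2)
  expect_lt(mean(ps), 0.85)
})

test_that("power simulation calibrates alpha and rises with FST", {
  base <- replicate(8, c(0.4, 0.3, 0.2, 0.1), simplify = FALSE)
  set.seed(72)
  p0 <- power_simulation(base, 0, n_pops = 6, sample_n = 40, n_reps = 300)
  expect_equal(p0$t_generations, 0L)
  expect_gte(p0$power, 0.03)
  expect_lte(p0$power, 0.07)
  p_strong <- power_simulation(base, 0.05, n_pops = 6, sample_n = 40,
                               n_reps = 60)
  expect_gte(p_strong$power, 0.99)
  expect_error(power_simulation(list(1, 1), 0.01), "monomorphic")
})
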