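test_that("admixture sampler: K = 1 forces full assignment, seeds reproduce", {
  sim <- simulate_genotypes(n_stocks = 2, rivers_per_stock = 2,
                            individuals_per_river = 10, n_loci = 5, seed = 81)
  ds <- sim$dataset
  f1 <- admixture_gibbs(ds, 1, burn_in = 50, reps = 200, seed = 1)
  expect_true(all(f1$q == 1))
  expect_true(is.finite(f1$lnP))

  fa <- admixture_gibbs(ds, 2, burn_in = 50, reps = 200, seed = 9)
  fb <- admixture_gibbs(ds, 2, burn_in = 50, reps = 200, seed = 9)
  expect_identical(fa$q, fb$q)
  expect_identical(fa$lnP, fb$lnP)

  ## q rows are proper admixture proportions
  expect_true(all(abs(rowSums(fa$q) - 1) < 1e-9))
  expect_error(admixture_gibbs(ds, 100), "exceeds")
})

test_that("correlated-frequency model runs and returns valid output", {
  sim <- simulate_genotypes(n_stocks = 2, rivers_per_stock = 1,
                            individuals_per_river = 15, n_loci = 4, seed = 82)
  f <- admixture_gibbs(sim$dataset, 2, burn_in = 100, reps = 300,
                       model = "correlated", seed = 3)
  expect_true(all(abs(rowSums(f$q) - 1) < 1e-9))
  expect_true(is.finite(f$lnP))
})

test_that("K selection demands enough replicates and K values", {
  sim <- simulate_genotypes(n_stocks = 2, rivers_per_stock = 1,
                            individuals_per_river = 8, n_loci = 3, seed = 83)
  expect_error(select_k(sim$dataset, 1:2), "at least 3")
  expect_error(select_k(sim$dataset, 1:4, n_replicates = 2), "replicates")
})

test_that("hierarchical scan: no-op for K = 1, finds planted substructure", {
  sim <- simulate_genotypes(n_stocks = 2, rivers_per_stock = 2,
                            individuals_per_river = 10, n_loci = 5, seed = 84)
  top1 <- admixture_gibbs(sim$dataset, 1, burn_in = 50, reps = 150, seed = 1)
  expect_message(out <- hierarchical_scan(sim$dataset, top1), "nothing to scan")
  expect_length(out, 0L)

  ## stock A carries two sub-demes (F = 0.08); stock B is homogeneous
  subA <- simulate_genotypes(n_stocks = 2, rivers_per_stock = 2,
                             individuals_per_river = 15, n_loci = 10,
                             f_stock = 0.08, f_river = 0.005, seed = 85)
  subB <- simulate_genotypes(n_stocks = 1, rivers_per_stock = 4,
                             individuals_per_river = 15, n_loci = 10,
                             f_stock = 0.30, f_river = 0.005, seed = 86)
  colsA <- lapply(seq_along(subA$dataset$collections), function(i) {
    co <- subA$dataset$collections[[i]]
    collection(paste0("A", i), 2010L, co$alleles)
  })
  colsB <- lapply(seq_along(subB$dataset$collections), function(i) {
    co <- subB$dataset$collections[[i]]
    collection(paste0("B", i), 2010L, co$alleles)
  })
  ds <- genotype_dataset(subA$dataset$loci, c(colsA, colsB))
  top <- admixture_gibbs(ds, 2, burn_in = 400, reps = 1200, seed = 87)
  scans <- hierarchical_scan(ds, top, K_range = 1:3, n_replicates = 3,
                             seed = 88, burn_in = 300, reps = 900)
  subK <- vapply(scans, `[[`, 0L, "sub_K")
  rivA <- vapply(scans, function(s) any(grepl("^A", s$rivers)), logical(1))
  expect_equal(unname(subK[rivA]), 2L)        # planted split recovered
  expect_equal(unname(subK[!rivA]), 1L)       # homogeneous stock stays K = 1
})

test_that("cluster alignment solves the label permutation", {
  q <- rbind(c(0.9, 0.05, 0.05), c(0.1, 0.1, 0.8), c(0.05, 0.9, 0.05))
  truth <- c("g1", "g2", "g3")
  perm <- align_clusters(q, truth)
  expect_equal(as.integer(perm), c(1L, 3L, 2L))
  expect_equal(attr(perm, "match_fraction"), 1)
})

test_that("PCoA reproduces geometry and regresses Axis 1 on latitude", {
  ## 3 collinear points: one positive axis carries all variation
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  p <- pcoa(d)
  expect_equal(p$percent[1], 100, tolerance = 1e-8)

  ## Euclidean input: coordinates reproduce the distances exactly
  set.seed(89)
  pts <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(LETTERS[1:6], LETTERS[1:6])
  pr <- pcoa(D)
  Dr <- as.matrix(dist(pr$coords))
  expect_equal(unname(Dr), unname(D), tolerance = 1e-8)
  expect_true(all(diff(pr$percent) <= 1e-9))

  ## latitude gradient drives Axis 1
  lat <- seq(34, 44, length.out = 8)
  Dg <- as.matrix(dist(cbind(lat, 0.05 * rnorm(8))))
  dimnames(Dg) <- list(paste0("R", 1:8), paste0("R", 1:8))
  pg <- pcoa(Dg, latitudes = setNames(lat, paste0("R", 1:8)))
  expect_gte(pg$r_squared, 0.95)
  expect_lt(pg$p_value, 0.001)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_warning(p0 <- pcoa(matrix(0, 4, 4)), "degenerate")
  expect_true(is.na(p0$percent))
})
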