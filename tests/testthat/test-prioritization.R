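test_that("slope classification follows the published thresholds", {
  th <- priority_thresholds()
  expect_equal(classify_variable(-0.80, "mean_length", th), "high")
  expect_equal(classify_variable(-0.04, "run_count", th), "medium")
  expect_equal(classify_variable(0.2, "mean_length", th), "low")
  expect_equal(classify_variable(-0.75, "mean_length", th), "high")  # boundary
  expect_equal(classify_variable(-0.05, "run_cpue", th), "high")
  expect_error(classify_variable(0.1, "age_at_maturity", th), "unknown")
  expect_error(classify_variable(Inf, "mean_length", th), "finite")
  expect_error(priority_thresholds(length_cut = 0.5), "below")

  ## monotone step function: higher slope never raises priority
  grid <- seq(-2, 1, by = 0.01)
  ranks <- match(vapply(grid, classify_variable, "", variable = "mean_length",
                        thresholds = th), c("high", "medium", "low"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("precautionary merge is a join on the low<medium<high lattice", {
  expect_equal(merge_designations("medium", "high"), "high")
  expect_equal(merge_designations("low", "low"), "low")
  expect_equal(merge_designations("medium", NA), "medium")
  expect_error(merge_designations(NA, NA), "no designation")
  lv <- c("low", "medium", "high")
  for (a in lv) for (b in lv) {
    expect_equal(merge_designations(a, b), merge_designations(b, a))
    expect_equal(merge_designations(a, a), a)
    for (cc in lv)
      expect_equal(merge_designations(merge_designations(a, b), cc),
                   merge_designations(a, merge_designations(b, cc)))
  }
})

test_that("stock designation averages member slopes per variable then merges", {
  expect_equal(stock_designation(length_slopes = c(-1.0, -0.9)), "high")
  expect_equal(stock_designation(runsize_slopes = c(0.1, 0.3)), "low")
  ## mixed: length mean -0.2 (medium), run mean -0.06 (high) -> high
  expect_equal(stock_designation(length_slopes = c(-0.2),
                                 runsize_slopes = c(-0.06)), "high")
  expect_error(stock_designation(), "no member slopes")
})

test_that("stock extension honours own data, proximity and overrides", {
  rivers <- data.frame(
    river = c("MON", "UNM", "FAR", "TIE"),
    stock = c("SNE", "SNE", NA, NA),
    lat = c(41.7, 41.7, 41.701, 41.7),
    lon = c(-70.6, -70.8, -70.601, -70.7))
  own <- c(MON = "low")
  stock_des <- c(SNE = "high")
  ## exact distance ties are constructed through an explicit matrix
  dk <- matrix(50, 4, 4, dimnames = list(rivers$river, rivers$river))
  diag(dk) <- 0
  dk["FAR", "MON"] <- dk["MON", "FAR"] <- 1        # FAR is nearest to MON
  expect_warning(pt <- extend_to_unmonitored(rivers, own, stock_des,
                                             dist_km = dk),
                 "equidistant")
  expect_equal(pt$designation[pt$river == "MON"], "low")      # own data wins
  expect_equal(pt$provenance[pt$river == "MON"], "own_data")
  expect_equal(pt$designation[pt$river == "UNM"], "high")
  expect_equal(pt$provenance[pt$river == "UNM"], "stock_extended")
  expect_equal(pt$stock[pt$river == "FAR"], "SNE")            # proximity

  ov <- data.frame(river = "UNM", designation = "medium",
                   reason = "agency request")
  pt2 <- suppressWarnings(
    extend_to_unmonitored(rivers, own, stock_des, dist_km = dk,
                          overrides = ov))
  expect_equal(pt2$designation[pt2$river == "UNM"], "medium")
  expect_match(pt2$provenance[pt2$river == "UNM"], "override")

  ## determinism: identical inputs give identical tables
  pt3 <- suppressWarnings(extend_to_unmonitored(rivers, own, stock_des,
                                                dist_km = dk))
  expect_identical(pt, pt3)
  ## coordinate route also works for proximity assignment
  pt4 <- extend_to_unmonitored(rivers[1:3, ], own, stock_des)
  expect_equal(pt4$stock[pt4$river == "FAR"], "SNE")
})

test_that("tallies of the published priority table match the printed counts", {
  blu <- tally_report(herring_priority_table("blueback"))
  expect_equal(unname(blu$counts),
               c(0L, 26L, 29L, 55L))
  ale <- tally_report(herring_priority_table("alewife"))
  expect_equal(unname(ale$counts[c("low", "medium", "total")]),
               c(6L, 23L, 45L))
  ## direct tally of the table gives 16 high (the accompanying text prints
  ## 15); both are surfaced rather than reconciled
  expect_equal(unname(ale$counts[["high"]]), 16L)
  empty <- tally_report(data.frame(designation = character(0)))
  expect_equal(unname(empty$counts), c(0L, 0L, 0L, 0L))
})
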