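## Data-conformance screens: Hardy-Weinberg and linkage-disequilibrium
## Monte-Carlo exact tests, sequential Bonferroni (Holm) correction, and the
## lnRV/lnRH microsatellite neutrality screen.

new_test_result <- function(unit, statistic, p, n_perm, status = "ok") {
  structure(list(unit = unit, statistic = statistic, p_value = p,
                 n_permutations = n_perm, status = status),
            class = "conformance_test")
}

#' @export
print.conformance_test <- function(x, ...) {
  cat(x$unit, ": p =", format(x$p_value, digits = 4),
      "(", x$n_permutations, "permutations,", x$status, ")\n")
  invisible(x)
}

## Levene conditional-probability statistic up to the (fixed) allele-count
## terms: h*log(2) - sum(lfactorial(genotype counts)).  Larger = more
## probable array; the probability test accumulates arrays at most as
## probable as the observed one.
hwe_stat <- function(a1, a2, k) {
  het <- sum(a1 != a2)
  gcode <- pmin(a1, a2) * k + pmax(a1, a2)
  het * log(2) - sum(lfactorial(tabulate(gcode, nbins = k * k + k)))
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Permutes gene copies among individuals within a locus (Fisher-Levene
#' conditioning on allele counts) and compares either the conditional
#' probability of the genotype array (`statistic = "probability"`) or the
#' heterozygote count one-sided for deficit (`statistic = "deficit"`).
#' The p-value uses add-one smoothing, \eqn{p = (b+1)/(n_{perm}+1)}.
#'
#' @param col a [collection()].
#' @param l locus index.
#' @param n_perm number of permutations (default 9999).
#' @param statistic "probability" (two-sided exact) or "deficit".
#' @return a `conformance_test`; monomorphic loci return status
#'   "untestable" with p = NA.
#' @export
hwe_exact_test <- function(col, l, n_perm = 9999L,
                           statistic = c("probability", "deficit")) {
  statistic <- match.arg(statistic)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  m <- locus_genotypes(col, l)
  unit <- paste0(col$river_code, ":", l)
  if (nrow(m) < 5L) stop("need >= 5 genotyped individuals")
  genes <- c(t(m))
  lev <- sort(unique(genes))
  if (length(lev) < 2L)
    return(new_test_result(unit, NA, NA, n_perm, status = "untestable"))
  gi <- match(genes, lev)
  k <- length(lev)
  i1 <- seq(1L, length(gi), 2L); i2 <- i1 + 1L
  if (statistic == "probability") {
    obs <- hwe_stat(gi[i1], gi[i2], k)
    b <- 0L
    for (r in seq_len(n_perm)) {
      g <- sample(gi)
      if (hwe_stat(g[i1], g[i2], k) <= obs + 1e-9) b <- b + 1L
    }
  } else {
    obs <- sum(gi[i1] != gi[i2])
    b <- 0L
    for (r in seq_len(n_perm)) {
      g <- sample(gi)
      if (sum(g[i1] != g[i2]) <= obs) b <- b + 1L
    }
  }
  new_test_result(unit, obs, (b + 1) / (n_perm + 1), n_perm)
}

## G (log-likelihood ratio) of a contingency table given fixed margins.
g_stat <- function(obs, expected) {
  keep <- obs > 0
  2 * sum(obs[keep] * log(obs[keep] / expected[keep]))
}

#' Monte-Carlo exact test of linkage disequilibrium between two loci
#'
#' Permutes one locus's genotypes across individuals and compares the
#' log-likelihood-ratio (G) statistic of the two-locus genotype contingency
#' table.  Only individuals genotyped at both loci enter the test.
#'
#' @param col a [collection()].
#' @param la,lb locus indices.
#' @param n_perm number of permutations.
#' @return a `conformance_test`; monomorphic or all-missing overlap gives
#'   status "untestable".
#' @export
ld_test <- function(col, la, lb, n_perm = 9999L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  A <- col$alleles[, locus_cols(la), drop = FALSE]
  B <- col$alleles[, locus_cols(lb), drop = FALSE]
  keep <- !is.na(A[, 1L]) & !is.na(B[, 1L])
  unit <- paste0(col$river_code, ":", la, "x", lb)
  if (sum(keep) < 5L)
    return(new_test_result(unit, NA, NA, n_perm, status = "untestable"))
  ga <- genotype_codes(A[keep, , drop = FALSE])
  gb <- genotype_codes(B[keep, , drop = FALSE])
  if (max(ga) < 2L || max(gb) < 2L)
    return(new_test_result(unit, NA, NA, n_perm, status = "untestable"))
  n <- length(ga)
  ka <- max(ga); kb <- max(gb)
  rowm <- tabulate(ga, ka); colm <- tabulate(gb, kb)
  expected <- outer(rowm, colm) / n
  joint <- function(b) matrix(tabulate((ga - 1L) * kb + b, ka * kb), ka, kb,
                              byrow = TRUE)
  obs <- g_stat(joint(gb), expected)
  bcount <- 0L
  for (r in seq_len(n_perm))
    if (g_stat(joint(sample(gb)), expected) >= obs - 1e-9) bcount <- bcount + 1L
  new_test_result(unit, obs, (bcount + 1) / (n_perm + 1), n_perm)
}

## distinct genotype codes 1..k for a two-column allele matrix
genotype_codes <- function(m) {
  key <- paste(pmin(m[, 1L], m[, 2L]), pmax(m[, 1L], m[, 2L]))
  match(key, unique(key))
}

#' Sequential Bonferroni (Holm) correction
#'
#' Step-down procedure: order the m p-values increasingly and reject while
#' \eqn{p_{(i)} \le \alpha/(m-i+1)}; the first failure stops all further
#' rejections.  Rejections are mapped back to the input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param alpha family-wise error level.
#' @return logical vector, TRUE = significant after correction.
#' @export
holm_correction <- function(p, alpha = 0.05) {
  if (length(p) == 0L) return(logical(0))
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "holm") <= alpha
}

#' lnRV / lnRH neutrality screen
#'
#' For every population pair and locus, computes the log-ratio of repeat-
#' number variances (lnRV) and of the heterozygosity transform
#' \eqn{\ln[((1/(1-H_1))^2 - 1)/((1/(1-H_2))^2 - 1)]} (lnRH), averages over
#' pairs, standardizes across loci and flags |z| > 1.96 as outliers.  Pairs
#' where a variance is 0 (lnRV) or H = 1 (lnRH) are excluded for that locus.
#'
#' Fragment lengths are converted to repeat numbers as
#' (length - min observed length) / repeat_unit_length.
#'
#' @param ds a [genotype_dataset()] (one collection per population).
#' @return list with per-locus table (`lnRV`, `lnRH`, `zRV`, `zRH`,
#'   `outlier`) and the number of usable pairs per locus.
#' @export
lnrv_lnrh_screen <- function(ds) {
  L <- n_loci(ds)
  P <- length(ds$collections)
  if (P < 2L) stop("need at least two populations")
  pairs <- combn(P, 2L)
  lnrv <- lnrh <- numeric(L)
  used_rv <- used_rh <- integer(L)
  for (l in seq_len(L)) {
    ## repeat-number conversion shared across populations
    all_genes <- unlist(lapply(ds$collections, locus_genes, l = l))
    minlen <- min(all_genes)
    ru <- ds$loci$repeat_unit_length[l]
    rv_vals <- rh_vals <- numeric(0)
    for (j in seq_len(ncol(pairs))) {
      c1 <- ds$collections[[pairs[1L, j]]]
      c2 <- ds$collections[[pairs[2L, j]]]
      r1 <- (locus_genes(c1, l) - minlen) / ru
      r2 <- (locus_genes(c2, l) - minlen) / ru
      v1 <- var(r1); v2 <- var(r2)
      if (isTRUE(v1 > 0) && isTRUE(v2 > 0))
        rv_vals <- c(rv_vals, log(v1 / v2))
      h1 <- unbiased_expected_heterozygosity(c1, l)
      h2 <- unbiased_expected_heterozygosity(c2, l)
      if (h1 < 1 && h2 < 1 && h1 > 0 && h2 > 0) {
        t1 <- (1 / (1 - h1))^2 - 1
        t2 <- (1 / (1 - h2))^2 - 1
        rh_vals <- c(rh_vals, log(t1 / t2))
      }
    }
    lnrv[l] <- if (length(rv_vals)) mean(rv_vals) else NA_real_
    lnrh[l] <- if (length(rh_vals)) mean(rh_vals) else NA_real_
    used_rv[l] <- length(rv_vals); used_rh[l] <- length(rh_vals)
  }
  zrv <- standardize_across(lnrv)
  zrh <- standardize_across(lnrh)
  data.frame(locus = ds$loci$name, lnRV = lnrv, lnRH = lnrh,
             zRV = zrv, zRH = zrh,
             pairs_RV = used_rv, pairs_RH = used_rh,
             outlier = (abs(zrv) > 1.96) | (abs(zrh) > 1.96))
}

standardize_across <- function(x) {
  s <- sd(x, na.rm = TRUE)
  if (!isTRUE(s > 0)) return(rep(0, length(x)))
  (x - mean(x, na.rm = TRUE)) / s
}
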