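## Per-river, per-locus genetic diversity statistics.

#' Allele frequencies at one locus (gene counting, missing excluded)
#'
#' @param col a [collection()].
#' @param l locus index.
#' @return named numeric vector of frequencies summing to 1.
#' @export
allele_frequencies <- function(col, l) {
  g <- locus_genes(col, l)
  if (length(g) == 0L)
    stop("locus ", l, " is entirely missing in river ", col$river_code)
  tab <- table(g)
  setNames(as.numeric(tab) / length(g), names(tab))
}

#' Observed heterozygosity
#'
#' Fraction of non-missing individuals carrying two distinct alleles.
#'
#' @inheritParams allele_frequencies
#' @export
observed_heterozygosity <- function(col, l) {
  m <- locus_genotypes(col, l)
  if (nrow(m) == 0L)
    stop("locus ", l, " is entirely missing in river ", col$river_code)
  mean(m[, 1L] != m[, 2L])
}

#' Unbiased expected heterozygosity (Nei 1978)
#'
#' \eqn{H_E = \frac{2n}{2n-1}\,(1 - \sum_a p_a^2)} with n the number of
#' genotyped individuals; 0 for monomorphic loci.
#'
#' @inheritParams allele_frequencies
#' @export
unbiased_expected_heterozygosity <- function(col, l) {
  m <- locus_genotypes(col, l)
  n <- nrow(m)
  if (n == 0L)
    stop("locus ", l, " is entirely missing in river ", col$river_code)
  p <- allele_frequencies(col, l)
  (2 * n / (2 * n - 1)) * (1 - sum(p^2))
}

## Weir-Cockerham single-population variance components (b, c) per allele.
## Returns the summed components across alleles; f = 1 - c/(b+c).
wc_single_pop_components <- function(col, l) {
  m <- locus_genotypes(col, l)
  n <- nrow(m)
  genes <- c(m[, 1L], m[, 2L])
  alleles <- unique(genes)
  b <- c <- 0
  for (a in alleles) {
    p <- mean(genes == a)
    h <- mean((m[, 1L] == a) != (m[, 2L] == a))  # het for allele a
    b <- b + (n / (n - 1)) * (p * (1 - p) - h * (2 * n - 1) / (4 * n))
    c <- c + h / 2
  }
  c(b = b, c = c, n = n)
}

#' Weir-Cockerham inbreeding coefficient f (single population)
#'
#' Computed from the within-population variance components; undefined
#' (returned as NA) for monomorphic loci.
#'
#' @inheritParams allele_frequencies
#' @export
f_is <- function(col, l) {
  m <- locus_genotypes(col, l)
  if (nrow(m) < 2L) stop("need at least 2 genotyped individuals")
  if (length(unique(c(m[, 1L], m[, 2L]))) < 2L) return(NA_real_)
  comp <- wc_single_pop_components(col, l)
  unname(1 - comp["c"] / (comp["b"] + comp["c"]))
}

#' Multilocus FIS by summed variance components
#'
#' @param col a [collection()].
#' @param loci locus indices (default all).
#' @export
f_is_multilocus <- function(col, loci = seq_len(ncol(col$alleles) / 2L)) {
  bs <- cs <- 0
  for (l in loci) {
    m <- locus_genotypes(col, l)
    if (nrow(m) < 2L || length(unique(c(m[, 1L], m[, 2L]))) < 2L) next
    comp <- wc_single_pop_components(col, l)
    bs <- bs + comp["b"]; cs <- cs + comp["c"]
  }
  unname(1 - cs / (bs + cs))
}

#' Rarefied allelic richness
#'
#' Expected number of alleles in a standardized subsample of `g` diploid
#' individuals (2g genes), by the hypergeometric rarefaction
#' \eqn{R = \sum_a [1 - C(N - N_a, 2g) / C(N, 2g)]} where N is the number of
#' sampled genes and N_a the copies of allele a.  Evaluated with
#' log-binomials to avoid overflow.
#'
#' @inheritParams allele_frequencies
#' @param g standard sample size in diploid individuals.
#' @export
allelic_richness_rarefied <- function(col, l, g) {
  genes <- locus_genes(col, l)
  N <- length(genes)
  if (2L * g > N)
    stop("rarefaction size 2g = ", 2L * g, " exceeds the ", N,
         " sampled genes at locus ", l, " in river ", col$river_code)
  counts <- table(genes)
  sum(1 - exp(lchoose(N - as.numeric(counts), 2 * g) - lchoose(N, 2 * g)))
}

#' Diversity table for a dataset (Tables S1/S2 layout)
#'
#' Per (river, locus): genotyped n, allele count, observed and unbiased
#' expected heterozygosity, FIS and rarefied richness; per-river means are
#' taken over the loci genotyped in that river.
#'
#' @param ds a [genotype_dataset()], usually pooled per river.
#' @param g rarefaction standard (diploid individuals); default the smallest
#'   per-river minimum across loci.
#' @return list with `per_locus` (long data.frame) and `river_means`.
#' @export
diversity_table <- function(ds, g = NULL) {
  L <- n_loci(ds)
  if (is.null(g)) {
    g <- min(vapply(ds$collections, function(co)
      min(vapply(seq_len(L), function(l) nrow(locus_genotypes(co, l)), 0L)),
      0L))
    g <- max(g, 1L)
  }
  rows <- list()
  for (co in ds$collections) {
    for (l in seq_len(L)) {
      m <- locus_genotypes(co, l)
      n <- nrow(m)
      if (n == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          river = co$river_code, locus = ds$loci$name[l], n = 0L,
          Na = NA, Ho = NA, He = NA, Fis = NA, R = NA)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        river = co$river_code, locus = ds$loci$name[l], n = n,
        Na = length(unique(c(m[, 1L], m[, 2L]))),
        Ho = observed_heterozygosity(co, l),
        He = unbiased_expected_heterozygosity(co, l),
        Fis = if (n >= 2L) f_is(co, l) else NA_real_,
        R = if (n >= g) allelic_richness_rarefied(co, l, g) else NA_real_)
    }
  }
  per_locus <- do.call(rbind, rows)
  means <- do.call(rbind, lapply(split(per_locus, per_locus$river), function(d)
    data.frame(river = d$river[1L],
               Na = mean(d$Na, na.rm = TRUE), Ho = mean(d$Ho, na.rm = TRUE),
               He = mean(d$He, na.rm = TRUE), Fis = mean(d$Fis, na.rm = TRUE),
               R = mean(d$R, na.rm = TRUE))))
  list(per_locus = per_locus, river_means = means, g = g)
}
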