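## Among-river differentiation: Weir-Cockerham theta, Hedrick-standardized
## F'ST, genic heterogeneity tests with Fisher combination, hierarchical
## AMOVA on allele-identity distances, Nei's DA, and POWSIM-style power
## assessment.

## Per-locus Weir-Cockerham variance components (a, b, c) summed over
## alleles.  Populations with < 2 genotyped individuals at the locus are
## dropped for that locus.
wc_components_locus <- function(cols, l) {
  mats <- lapply(cols, locus_genotypes, l = l)
  mats <- mats[vapply(mats, nrow, 0L) >= 2L]
  r <- length(mats)
  if (r < 2L) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  ni <- vapply(mats, nrow, 0L)
  genes <- lapply(mats, function(m) c(m[, 1L], m[, 2L]))
  alleles <- sort(unique(unlist(genes)))
  if (length(alleles) < 2L) return(c(a = 0, b = 0, c = 0))
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  A <- B <- C <- 0
  for (al in alleles) {
    pi <- vapply(genes, function(g) mean(g == al), 0)
    hi <- vapply(mats, function(m) mean((m[, 1L] == al) != (m[, 2L] == al)), 0)
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  c(a = A, b = B, c = C)
}

#' Weir-Cockerham theta (FST)
#'
#' Multilocus theta from summed variance components,
#' \eqn{\theta = \sum_l a_l / \sum_l (a_l + b_l + c_l)}, with per-locus
#' estimates also returned.  Small negative estimates are retained.
#'
#' @param ds a [genotype_dataset()] with one collection per population.
#' @param rivers optional subset of river codes.
#' @return list with `theta` (multilocus), `per_locus`, and the summed
#'   components.
#' @export
wc_theta <- function(ds, rivers = NULL) {
  cols <- ds$collections
  if (!is.null(rivers)) {
    keep <- vapply(cols, function(co) co$river_code %in% rivers, logical(1))
    cols <- cols[keep]
  }
  if (length(cols) < 2L) stop("need at least two populations")
  L <- n_loci(ds)
  comp <- t(vapply(seq_len(L), function(l) wc_components_locus(cols, l),
                   numeric(3)))
  ok <- complete.cases(comp)
  if (!any(ok)) stop("theta undefined: no usable locus")
  denom_l <- rowSums(comp)
  per_locus <- ifelse(ok & abs(denom_l) > 0, comp[, 1L] / denom_l, NA_real_)
  tot <- colSums(comp[ok, , drop = FALSE])
  if (sum(tot) == 0) stop("theta undefined: all loci monomorphic")
  list(theta = tot[["a"]] / sum(tot),
       per_locus = setNames(per_locus, ds$loci$name),
       components = tot)
}

## Recode allele codes so no allele is shared between populations, while
## preserving within-population frequencies and the missing pattern
## (Meirmans RECODEDATA behaviour).
recode_disjoint <- function(ds, rivers = NULL) {
  cols <- ds$collections
  if (!is.null(rivers))
    cols <- cols[vapply(cols, function(co) co$river_code %in% rivers, logical(1))]
  offset <- 0L
  newcols <- vector("list", length(cols))
  for (i in seq_along(cols)) {
    co <- cols[[i]]
    a <- co$alleles + offset
    newcols[[i]] <- collection(co$river_code, co$year, a, ids = co$ids)
    offset <- offset + max(co$alleles, na.rm = TRUE) + 1L
  }
  genotype_dataset(ds$loci, newcols, species_label = ds$species_label)
}

#' Hedrick-standardized differentiation F'ST
#'
#' \eqn{\theta' = \theta / \theta_{max}}, where \eqn{\theta_{max}} is the
#' Weir-Cockerham estimate after recoding the data so that no allele is
#' shared between populations (preserving within-population frequencies).
#'
#' @param ds a [genotype_dataset()].
#' @param rivers optional subset (e.g. a pair) of river codes; default all
#'   populations (global standardization by whole-dataset recoding).
#' @return list with `theta`, `theta_max`, `theta_prime`.
#' @export
fst_standardized <- function(ds, rivers = NULL) {
  th <- wc_theta(ds, rivers)$theta
  thmax <- wc_theta(recode_disjoint(ds, rivers))$theta
  if (!isTRUE(thmax > 0))
    stop("theta_max is not positive (populations effectively monomorphic)")
  list(theta = th, theta_max = thmax, theta_prime = th / thmax)
}

#' Pairwise matrices of theta and F'ST
#'
#' @param ds a [genotype_dataset()] with one collection per river.
#' @return list of symmetric matrices `theta` and `theta_prime` with river
#'   codes as labels.
#' @export
pairwise_fst <- function(ds) {
  rivers <- vapply(ds$collections, `[[`, "", "river_code")
  P <- length(rivers)
  th <- thp <- matrix(NA_real_, P, P, dimnames = list(rivers, rivers))
  diag(th) <- diag(thp) <- 0
  for (i in seq_len(P - 1L)) for (j in (i + 1L):P) {
    fs <- fst_standardized(ds, rivers[c(i, j)])
    th[i, j] <- th[j, i] <- fs$theta
    thp[i, j] <- thp[j, i] <- fs$theta_prime
  }
  list(theta = th, theta_prime = thp)
}

## allele-count x population contingency table for one locus
allele_count_table <- function(cols, l) {
  genes <- lapply(cols, locus_genes, l = l)
  alleles <- sort(unique(unlist(genes)))
  tab <- vapply(genes, function(g) tabulate(match(g, alleles),
                                            length(alleles)),
                integer(length(alleles)))
  matrix(tab, nrow = length(alleles))
}

#' Genic (allelic heterogeneity) test
#'
#' Per locus, an exact test of allele-frequency homogeneity on the
#' alleles x populations contingency table: Monte-Carlo permutation of
#' population labels among gene copies with a G (log-likelihood-ratio)
#' statistic (`method = "exact"`), or the asymptotic chi-square test
#' (`method = "chisq"`).  Per-locus p-values are combined over testable
#' loci by Fisher's method, \eqn{\chi^2 = -2\sum_l \ln p_l} with 2L df.
#'
#' @param ds a [genotype_dataset()].
#' @param rivers optional subset of river codes.
#' @param n_perm permutations for the exact method.
#' @param method "exact" or "chisq".
#' @return list with `per_locus` p-values (NA = untestable), `chisq`, `df`,
#'   and the Fisher-combined `p`.
#' @export
genic_test <- function(ds, rivers = NULL, n_perm = 999L,
                       method = c("exact", "chisq")) {
  method <- match.arg(method)
  cols <- ds$collections
  if (!is.null(rivers))
    cols <- cols[vapply(cols, function(co) co$river_code %in% rivers, logical(1))]
  if (length(cols) < 2L) stop("need at least two populations")
  L <- n_loci(ds)
  pl <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    tab <- allele_count_table(cols, l)
    if (nrow(tab) < 2L) next   # monomorphic across the subset: untestable
    pl[l] <- if (method == "exact") genic_perm_p(tab, n_perm)
             else genic_chisq_p(tab)
  }
  ok <- !is.na(pl)
  if (!any(ok)) stop("no testable locus")
  chi <- -2 * sum(log(pl[ok]))
  df <- 2L * sum(ok)
  list(per_locus = setNames(pl, ds$loci$name), chisq = chi, df = df,
       p = pchisq(chi, df, lower.tail = FALSE))
}

genic_perm_p <- function(tab, n_perm) {
  k <- nrow(tab); r <- ncol(tab)
  n <- sum(tab)
  pop <- rep.int(seq_len(r), colSums(tab))
  gene <- rep.int(rep(seq_len(k), r), as.vector(tab))
  expected <- outer(rowSums(tab), colSums(tab)) / n
  obs <- g_stat(tab, expected)
  b <- 0L
  for (i in seq_len(n_perm)) {
    t2 <- matrix(tabulate((sample(pop) - 1L) * k + gene, r * k), k, r)
    if (g_stat(t2, expected) >= obs - 1e-9) b <- b + 1L
  }
  (b + 1) / (n_perm + 1)
}

genic_chisq_p <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  pchisq(stat, (nrow(tab) - 1L) * (ncol(tab) - 1L), lower.tail = FALSE)
}

#' Fisher's method for combining independent p-values
#'
#' @param p vector of p-values in (0, 1].
#' @return list with `chisq`, `df`, `p`.
#' @export
fisher_combine <- function(p) {
  p <- p[!is.na(p)]
  chi <- -2 * sum(log(p))
  list(chisq = chi, df = 2L * length(p),
       p = pchisq(chi, 2L * length(p), lower.tail = FALSE))
}

#' Nei's DA genetic distance
#'
#' \eqn{D_A = 1 - \frac{1}{L}\sum_l \sum_a \sqrt{x_{la} y_{la}}} over the
#' loci genotyped in both populations.
#'
#' @param ds a [genotype_dataset()].
#' @param river_x,river_y river codes.
#' @export
nei_da <- function(ds, river_x, river_y) {
  cx <- ds$collections[[which(vapply(ds$collections, `[[`, "", "river_code")
                              == river_x)[1L]]]
  cy <- ds$collections[[which(vapply(ds$collections, `[[`, "", "river_code")
                              == river_y)[1L]]]
  L <- n_loci(ds)
  tot <- 0; used <- 0L
  for (l in seq_len(L)) {
    if (nrow(locus_genotypes(cx, l)) == 0L ||
        nrow(locus_genotypes(cy, l)) == 0L) next
    px <- allele_frequencies(cx, l)
    py <- allele_frequencies(cy, l)
    alleles <- union(names(px), names(py))
    xs <- ifelse(alleles %in% names(px), px[alleles], 0)
    ys <- ifelse(alleles %in% names(py), py[alleles], 0)
    tot <- tot + sum(sqrt(xs * ys))
    used <- used + 1L
  }
  if (used == 0L) stop("no shared genotyped loci between ", river_x,
                       " and ", river_y)
  1 - tot / used
}

#' Pairwise DA distance matrix
#'
#' @param ds a [genotype_dataset()] with one collection per river.
#' @return symmetric matrix with river-code labels and zero diagonal.
#' @export
nei_da_matrix <- function(ds) {
  rivers <- vapply(ds$collections, `[[`, "", "river_code")
  P <- length(rivers)
  m <- matrix(0, P, P, dimnames = list(rivers, rivers))
  for (i in seq_len(P - 1L)) for (j in (i + 1L):P)
    m[i, j] <- m[j, i] <- nei_da(ds, rivers[i], rivers[j])
  m
}

## ---------------------------------------------------------------------------
## AMOVA on allele-identity distances
## ---------------------------------------------------------------------------

## Squared inter-individual distance = number of non-shared alleles between
## the two diploid single-locus genotypes (0/1/2), summed over the loci
## genotyped in both individuals (Arlequin's default for unordered alleles).
allele_identity_dist2 <- function(cols) {
  A <- do.call(rbind, lapply(cols, `[[`, "alleles"))
  N <- nrow(A)
  L <- ncol(A) / 2L
  d2 <- matrix(0, N, N)
  for (l in seq_len(L)) {
    a1 <- A[, 2L * l - 1L]; a2 <- A[, 2L * l]
    ok <- !is.na(a1)
    ## shared alleles between genotypes {a1,a2} and {b1,b2}: best pairing
    e11 <- outer(a1, a1, "=="); e22 <- outer(a2, a2, "==")
    e12 <- outer(a1, a2, "=="); e21 <- outer(a2, a1, "==")
    shared <- pmax(e11 + e22, e12 + e21)
    miss <- !ok | rep(!ok, each = N)
    contrib <- 2 - shared
    contrib[miss] <- 0
    d2 <- d2 + contrib
  }
  d2
}

ssd_within <- function(d2, idx_list) {
  sum(vapply(idx_list, function(ix)
    sum(d2[ix, ix]) / (2 * length(ix)), 0))
}

amova_components <- function(d2, pop, grp_of_pop) {
  N <- nrow(d2)
  pops <- split(seq_len(N), pop)
  P <- length(pops)
  grp <- grp_of_pop[names(pops)]
  groups <- split(names(pops), grp)
  G <- length(groups)
  grp_ind <- lapply(groups, function(ps) unlist(pops[ps], use.names = FALSE))
  np <- vapply(pops, length, 0L)
  ng <- vapply(grp_ind, length, 0L)

  ss_total <- sum(d2) / (2 * N)
  ss_wp <- ssd_within(d2, pops)
  ss_wg <- ssd_within(d2, grp_ind)
  ss_ag <- ss_total - ss_wg
  ss_ap <- ss_wg - ss_wp

  df_ag <- G - 1L; df_ap <- P - G; df_wp <- N - P
  ms_wp <- ss_wp / df_wp
  sum_np2_by_g <- vapply(groups, function(ps) sum(np[ps]^2) / sum(np[ps]), 0)
  n1 <- (N - sum(sum_np2_by_g)) / df_ap
  n2 <- (sum(sum_np2_by_g) - sum(np^2) / N) / df_ag
  n3 <- (N - sum(ng^2) / N) / df_ag
  sc <- ms_wp
  sb <- (ss_ap / df_ap - sc) / n1
  sa <- (ss_ag / df_ag - sc - n2 * sb) / n3
  c(a = sa, b = sb, c = sc)
}

#' Three-level hierarchical AMOVA
#'
#' Partitions genetic variance among groups (stocks), among populations
#' within groups, and within populations, using the number of non-shared
#' alleles between diploid genotypes as the squared inter-individual
#' distance.  Permutation tests: populations among groups (Phi_CT),
#' individuals among populations within groups (Phi_SC), and individuals
#' among all populations (Phi_ST).
#'
#' @param ds a [genotype_dataset()] with one collection per population.
#' @param grouping named character vector mapping river code to group label.
#' @param n_perm permutations per level.
#' @return object of class `amova_result` with components, percentages
#'   (summing to 100), Phi statistics, and p-values.
#' @export
amova3 <- function(ds, grouping, n_perm = 999L) {
  cols <- ds$collections
  rivers <- vapply(cols, `[[`, "", "river_code")
  if (!all(rivers %in% names(grouping)))
    stop("grouping must cover every river")
  grp_of_pop <- grouping[rivers]
  names(grp_of_pop) <- rivers
  if (length(unique(grp_of_pop)) < 2L)
    stop("degenerate grouping: need at least two groups")
  d2 <- allele_identity_dist2(cols)
  pop <- rep.int(rivers, vapply(cols, function(co) nrow(co$alleles), 0L))
  comp <- amova_components(d2, pop, grp_of_pop)
  tot <- sum(comp)
  phi <- c(CT = comp[["a"]] / tot,
           SC = comp[["b"]] / (comp[["b"]] + comp[["c"]]),
           ST = (comp[["a"]] + comp[["b"]]) / tot)

  ## permutation tests
  ge_ct <- ge_sc <- ge_st <- 0L
  pop_f <- factor(pop, levels = rivers)
  for (i in seq_len(n_perm)) {
    g_perm <- setNames(sample(unname(grp_of_pop)), rivers)
    cc <- amova_components(d2, pop, g_perm)
    if (cc[["a"]] / sum(cc) >= phi[["CT"]] - 1e-12) ge_ct <- ge_ct + 1L

    ## individuals among pops within groups
    pop_sc <- pop
    for (g in unique(grp_of_pop)) {
      ix <- which(grp_of_pop[pop] == g)
      pop_sc[ix] <- sample(pop[ix])
    }
    cc <- amova_components(d2, pop_sc, grp_of_pop)
    sc_stat <- cc[["b"]] / (cc[["b"]] + cc[["c"]])
    if (sc_stat >= phi[["SC"]] - 1e-12) ge_sc <- ge_sc + 1L

    ## individuals among all pops
    cc <- amova_components(d2, sample(pop), grp_of_pop)
    if ((cc[["a"]] + cc[["b"]]) / sum(cc) >= phi[["ST"]] - 1e-12)
      ge_st <- ge_st + 1L
  }
  pvals <- (c(ge_ct, ge_sc, ge_st) + 1) / (n_perm + 1)
  structure(list(
    components = comp,
    percent = 100 * comp / tot,
    phi = phi,
    p_values = setNames(pvals, c("CT", "SC", "ST")),
    n_perm = n_perm),
    class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA variance components (percent of total):\n")
  lv <- c("among groups", "among pops within groups", "within pops")
  for (i in 1:3)
    cat(sprintf("  %-26s %8.3f  (%6.2f%%)\n", lv[i], x$components[i],
                x$percent[i]))
  cat("Phi: CT =", round(x$phi[["CT"]], 4), " SC =", round(x$phi[["SC"]], 4),
      " ST =", round(x$phi[["ST"]], 4), "\n")
  cat("p (perm):", paste(names(x$p_values), format(x$p_values, digits = 3),
                         collapse = "  "), "\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## POWSIM-style power assessment
## ---------------------------------------------------------------------------

#' Power simulation for detecting weak differentiation
#'
#' Simulates independent drift of `n_pops` populations from common base
#' allele frequencies for t generations with
#' \eqn{F_{ST} = 1 - (1 - 1/(2N_e))^t} (t solved from the target, rounded to
#' the nearest integer), draws genotype samples, runs the genic test
#' combined over loci, and reports the rejection rate at the 0.05 level.
#' At `target_fst = 0` (t = 0) the rejection rate is the realized
#' alpha-error.
#'
#' @param base_freqs list of per-locus allele-frequency vectors.
#' @param target_fst desired expected FST (>= 0).
#' @param ne effective size per population during drift.
#' @param n_pops number of populations.
#' @param sample_n diploid individuals sampled per population.
#' @param n_reps simulation replicates.
#' @param method test method passed to [genic_test()] ("chisq" default,
#'   matching the large-sample contingency test).
#' @param alpha nominal level.
#' @return list with `power`, `t_generations`, `realized_fst_expected`, and
#'   the replicate p-values.
#' @export
power_simulation <- function(base_freqs, target_fst, ne = 1000L,
                             n_pops = 10L, sample_n = 50L, n_reps = 200L,
                             method = "chisq", alpha = 0.05) {
  if (target_fst < 0) stop("target_fst must be >= 0")
  if (all(vapply(base_freqs, length, 0L) < 2L))
    stop("base frequencies are monomorphic")
  t_gen <- if (target_fst == 0) 0L else
    max(0L, as.integer(round(log(1 - target_fst) / log(1 - 1 / (2 * ne)))))
  realized <- 1 - (1 - 1 / (2 * ne))^t_gen
  L <- length(base_freqs)
  pvals <- numeric(n_reps)
  for (rep in seq_len(n_reps)) {
    ## drift then sample: allele-count table per locus
    chis <- dfs <- numeric(0)
    for (l in seq_len(L)) {
      p0 <- base_freqs[[l]]
      if (length(p0) < 2L) next
      tab <- matrix(0L, length(p0), n_pops)
      for (j in seq_len(n_pops)) {
        p <- p0
        for (g in seq_len(t_gen))
          p <- as.vector(rmultinom(1L, 2L * ne, p)) / (2 * ne)
        tab[, j] <- as.vector(rmultinom(1L, 2L * sample_n, p))
      }
      tab <- tab[rowSums(tab) > 0L, , drop = FALSE]
      if (nrow(tab) < 2L) next
      pl <- genic_chisq_p(tab)
      chis <- c(chis, -2 * log(max(pl, 1e-300)))
      dfs <- c(dfs, 2)
    }
    pvals[rep] <- if (length(chis) == 0L) 1 else
      pchisq(sum(chis), sum(dfs), lower.tail = FALSE)
  }
  list(power = mean(pvals < alpha), t_generations = t_gen,
       realized_fst_expected = realized, p_values = pvals)
}
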