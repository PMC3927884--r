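## Model-based clustering (admixture Gibbs sampler), K selection by
## lnPr(X|K) and the Evanno delta-K statistic, hierarchical re-scanning
## within clusters, and PCoA ordination of a genetic distance matrix.

## dataset -> N x 2L matrix of per-locus allele indices (0 = missing),
## plus per-locus allele counts and individual/river labels
encode_alleles <- function(ds) {
  cols <- ds$collections
  A <- do.call(rbind, lapply(cols, `[[`, "alleles"))
  L <- n_loci(ds)
  out <- matrix(0L, nrow(A), 2L * L)
  n_alleles <- integer(L)
  for (l in seq_len(L)) {
    cc <- locus_cols(l)
    lev <- sort(unique(as.vector(A[, cc])))
    n_alleles[l] <- max(length(lev), 1L)
    idx <- match(A[, cc], lev)
    idx[is.na(idx)] <- 0L
    out[, cc] <- idx
  }
  list(geno = out, n_alleles = n_alleles,
       river = rep.int(vapply(cols, `[[`, "", "river_code"),
                       vapply(cols, function(co) nrow(co$alleles), 0L)),
       ids = unlist(lapply(cols, `[[`, "ids")))
}

#' Admixture-model Gibbs sampler
#'
#' Bayesian clustering of multilocus genotypes under the admixture model:
#' each gene copy originates in one of K clusters; cluster allele
#' frequencies get a Dirichlet prior (independent model) or the correlated
#' F-model prior linking them to ancestral frequencies through per-cluster
#' drift parameters; individual admixture proportions get a symmetric
#' Dirichlet(alpha) prior with alpha updated by Metropolis.
#'
#' The marginal-likelihood estimate follows the usual penalized form
#' \eqn{\widehat{\ln\Pr(X|K)} = \overline{\ln L} - \mathrm{var}(\ln L)/2}
#' over post-burn-in sweeps.
#'
#' @param ds a [genotype_dataset()] (collections are concatenated; pool
#'   temporal replicates first if desired).
#' @param K number of clusters (>= 1).
#' @param burn_in burn-in sweeps.
#' @param reps post-burn-in sweeps.
#' @param model "independent" or "correlated" allele-frequency prior.
#' @param alpha initial admixture Dirichlet parameter.
#' @param update_alpha Metropolis-update alpha?
#' @param seed optional integer seed (set before sampling).
#' @return object of class `cluster_result`: posterior-mean `q` (N x K),
#'   per-cluster allele frequencies `P`, `lnP` estimate, the lnL trace
#'   summary, and labels.
#' @export
admixture_gibbs <- function(ds, K, burn_in = 5000L, reps = 25000L,
                            model = c("independent", "correlated"),
                            alpha = 1, update_alpha = TRUE, seed = NULL) {
  model <- match.arg(model)
  enc <- encode_alleles(ds)
  N <- nrow(enc$geno)
  if (K < 1L) stop("K must be >= 1")
  if (K > N) stop("K exceeds the number of individuals")
  if (reps < 1L || burn_in < 0L) stop("need reps > burn_in >= 0")
  if (!is.null(seed)) set.seed(seed)
  fit <- .admixture_gibbs_cpp(enc$geno, enc$n_alleles, as.integer(K),
                              as.integer(burn_in), as.integer(reps),
                              alpha, update_alpha && K > 1L,
                              model == "correlated")
  lnl <- fit$lnl
  ## crude non-mixing diagnostic: strong monotone trend in the lnL trace
  if (length(lnl) >= 20L) {
    tr <- cor(seq_along(lnl), lnl)
    if (is.finite(tr) && abs(tr) > 0.8)
      warning("lnL trace is strongly trending (r = ", round(tr, 2),
              "); the chain may not have converged")
  }
  structure(list(K = K, q = fit$q, P = fit$P,
                 lnP = mean(lnl) - var(lnl) / 2,
                 lnl_mean = mean(lnl), lnl_var = var(lnl),
                 alpha = fit$alpha, model = model, seed = seed,
                 river = enc$river, ids = enc$ids),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result: K =", x$K, " lnPr(X|K) =", round(x$lnP, 2),
      " (", x$model, "model )\n")
  tab <- table(x$river, max.col(x$q))
  print(tab)
  invisible(x)
}

#' Stacked-bar plot of admixture proportions
#'
#' @param x a `cluster_result`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.cluster_result <- function(x, ...) {
  ord <- order(x$river, -apply(x$q, 1L, max))
  graphics::barplot(t(x$q[ord, , drop = FALSE]), col = seq_len(x$K) + 1L,
                    border = NA, space = 0, xlab = "individuals (by river)",
                    ylab = "admixture proportion q", ...)
  invisible(x)
}

#' Select K by lnPr(X|K) and the Evanno delta-K statistic
#'
#' Runs `n_replicates` independent chains per K.  Delta-K at an interior K
#' is the mean over replicates of the absolute second difference
#' |L(K+1) - 2 L(K) + L(K-1)| divided by the SD of L(K) across replicates.
#' `chosen_K` is the argmax of delta-K; the lnP plateau diagnostics
#' (mean, SD per K, and the K maximizing mean lnP) are reported alongside,
#' and a disagreement flag is raised when the two criteria point to
#' different K rather than silently auto-selecting.
#'
#' @param ds a [genotype_dataset()].
#' @param K_range integer vector of K values (length >= 3, contiguous).
#' @param n_replicates chains per K (>= 3: delta-K needs an SD).
#' @param seed base seed; replicate r at K uses `seed + 1000*K + r`.
#' @param ... passed to [admixture_gibbs()].
#' @return object of class `k_selection`.
#' @export
select_k <- function(ds, K_range = 1:5, n_replicates = 3L, seed = 1L, ...) {
  K_range <- sort(unique(as.integer(K_range)))
  if (length(K_range) < 3L) stop("K_range must contain at least 3 values")
  if (n_replicates < 3L) stop("delta-K needs >= 3 replicates per K")
  lnp <- matrix(NA_real_, length(K_range), n_replicates,
                dimnames = list(K_range, NULL))
  runs <- list()
  for (i in seq_along(K_range)) {
    for (r in seq_len(n_replicates)) {
      fit <- admixture_gibbs(ds, K_range[i],
                             seed = seed + 1000L * K_range[i] + r, ...)
      lnp[i, r] <- fit$lnP
      runs[[paste0("K", K_range[i], "_r", r)]] <- fit
    }
  }
  mean_lnp <- rowMeans(lnp)
  sd_lnp <- apply(lnp, 1L, sd)
  dk <- rep(NA_real_, length(K_range))
  for (i in seq_along(K_range)) {
    if (i == 1L || i == length(K_range)) next
    if (sd_lnp[i] == 0) {
      warning("zero SD of lnP at K = ", K_range[i], "; delta-K is infinite")
      dk[i] <- Inf
      next
    }
    dk[i] <- mean(abs(lnp[i + 1L, ] - 2 * lnp[i, ] + lnp[i - 1L, ])) / sd_lnp[i]
  }
  chosen <- if (all(is.na(dk))) NA_integer_ else K_range[which.max(dk)]
  best_lnp <- K_range[which.max(mean_lnp)]
  structure(list(K_range = K_range, lnP = lnp, mean_lnP = mean_lnp,
                 sd_lnP = sd_lnp, delta_K = setNames(dk, K_range),
                 chosen_K = chosen, best_by_lnP = best_lnp,
                 criteria_disagree = !is.na(chosen) && chosen != best_lnp,
                 runs = runs),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  df <- data.frame(K = x$K_range, mean_lnP = round(x$mean_lnP, 2),
                   sd_lnP = round(x$sd_lnP, 3),
                   delta_K = round(x$delta_K, 2))
  print(df, row.names = FALSE)
  cat("delta-K argmax:", x$chosen_K, "; lnP plateau argmax:", x$best_by_lnP,
      if (x$criteria_disagree) " [criteria disagree]" else "", "\n")
  invisible(x)
}

#' Hierarchical re-scan within clusters
#'
#' Assigns each river to the cluster holding the majority of its
#' individuals' maximum-q assignments, then re-runs K selection
#' independently inside each cluster with >= 2 rivers.  Within a cluster
#' the sub-K is read from the lnP plateau (argmax of mean lnPr(X|K)),
#' which, unlike delta-K, can select K = 1.
#'
#' @param ds a [genotype_dataset()].
#' @param top a `cluster_result` from the top-level analysis (K >= 2).
#' @param K_range sub-scan K values.
#' @param ... passed to [select_k()].
#' @return list per cluster: member rivers and the sub-scan `k_selection`
#'   (NULL for skipped single-river clusters), plus `sub_K` summary.
#' @export
hierarchical_scan <- function(ds, top, K_range = 1:3, ...) {
  if (top$K < 2L) {
    message("single-cluster input: nothing to scan")
    return(list())
  }
  river_cluster <- vapply(split(max.col(top$q), top$river), function(v)
    as.integer(names(which.max(table(v)))), 0L)
  out <- list()
  for (k in sort(unique(river_cluster))) {
    members <- names(river_cluster)[river_cluster == k]
    if (length(members) < 2L) {
      message("cluster ", k, " has < 2 rivers; skipped")
      out[[paste0("cluster", k)]] <- list(rivers = members, scan = NULL,
                                          sub_K = NA_integer_)
      next
    }
    sub <- subset_rivers(ds, members)
    sel <- select_k(sub, K_range = K_range, ...)
    out[[paste0("cluster", k)]] <- list(rivers = members, scan = sel,
                                        sub_K = sel$best_by_lnP)
  }
  out
}

#' Subset a dataset to a set of rivers
#'
#' @param ds a [genotype_dataset()].
#' @param rivers river codes to keep.
#' @export
subset_rivers <- function(ds, rivers) {
  keep <- vapply(ds$collections, function(co) co$river_code %in% rivers,
                 logical(1))
  if (!any(keep)) stop("no collection matches the requested rivers")
  genotype_dataset(ds$loci, ds$collections[keep], ds$species_label)
}

#' Align cluster labels to reference labels
#'
#' Exhaustive assignment matching (K <= 8) maximizing the summed q mass
#' that each reference group places on its matched cluster.
#'
#' @param q N x K admixture matrix.
#' @param truth factor/character of reference group per individual (with at
#'   most K levels).
#' @return integer vector `perm` such that cluster `perm[g]` corresponds to
#'   reference level g, with the achieved match fraction as attribute.
#' @export
align_clusters <- function(q, truth) {
  truth <- factor(truth)
  G <- nlevels(truth)
  K <- ncol(q)
  if (G > K) stop("more reference groups than clusters")
  if (K > 8L) stop("exhaustive alignment supports K <= 8")
  mass <- t(vapply(levels(truth), function(g)
    colSums(q[truth == g, , drop = FALSE]), numeric(K)))
  perms <- all_permutations(K)
  best <- NULL; best_val <- -Inf
  for (i in seq_len(nrow(perms))) {
    pm <- perms[i, ]
    val <- sum(mass[cbind(seq_len(G), pm[seq_len(G)])])
    if (val > best_val) { best_val <- val; best <- pm }
  }
  hard <- max.col(q)
  correct <- mean(hard == best[as.integer(truth)])
  structure(best[seq_len(G)], match_fraction = correct)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L  # insert n into every position of every (n-1)-permutation
  for (i in seq_len(nrow(sub))) for (pos in seq_len(n)) {
    r <- r + 1L
    out[r, ] <- append(sub[i, ], n, after = pos - 1L)
  }
  out
}

## ---------------------------------------------------------------------------
## PCoA
## ---------------------------------------------------------------------------

#' Principal coordinates analysis of a genetic distance matrix
#'
#' Double-centres \eqn{-D^2/2}, eigendecomposes, and reports axis
#' coordinates with percent variation computed from the positive
#' eigenvalues.  Optionally regresses Axis 1 on latitude (OLS).
#'
#' @param dist square symmetric distance matrix with labels.
#' @param latitudes optional named numeric vector (by matrix label).
#' @return object of class `pcoa_result` with `coords`, `eig`, `percent`,
#'   and (if latitudes given) `r_squared` and `p_value` of Axis 1 ~ latitude.
#' @export
pcoa <- function(dist, latitudes = NULL) {
  d <- as.matrix(dist)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8))
    stop("distance matrix must be square and symmetric")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 populations")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  ee <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- ee$values > 1e-10
  if (!any(pos)) {
    warning("all eigenvalues are zero: degenerate configuration")
    return(structure(list(coords = matrix(0, n, 1,
                                          dimnames = list(rownames(d), "Axis1")),
                          eig = ee$values, percent = NA_real_,
                          r_squared = NA_real_, p_value = NA_real_),
                     class = "pcoa_result"))
  }
  coords <- ee$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(ee$values[pos]), sum(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  percent <- 100 * ee$values[pos] / sum(ee$values[pos])
  r2 <- p <- NA_real_
  if (!is.null(latitudes)) {
    lat <- latitudes[rownames(coords)]
    fit <- summary(lm(coords[, 1L] ~ lat))
    r2 <- fit$r.squared
    p <- fit$coefficients["lat", "Pr(>|t|)"]
  }
  structure(list(coords = coords, eig = ee$values, percent = percent,
                 r_squared = r2, p_value = p),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- min(3L, length(x$percent))
  cat("PCoA:", paste0("Axis", seq_len(k), " = ",
                      round(x$percent[seq_len(k)], 2), "%", collapse = ", "),
      "\n")
  if (!is.na(x$r_squared))
    cat("Axis1 ~ latitude: r^2 =", round(x$r_squared, 3),
        " p =", format(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' @export
plot.pcoa_result <- function(x, ...) {
  graphics::plot(x$coords[, 1L], x$coords[, 2L],
                 xlab = sprintf("Axis 1 (%.1f%%)", x$percent[1L]),
                 ylab = sprintf("Axis 2 (%.1f%%)", x$percent[2L]), ...)
  graphics::text(x$coords[, 1L], x$coords[, 2L], rownames(x$coords),
                 pos = 3, cex = 0.7)
  invisible(x)
}
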