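## Isolation by distance: along-ocean (least-cost) distances between river
## mouths on a rasterized land/ocean grid, Rousset linearization, and the
## Mantel permutation test.

#' Construct an ocean grid
#'
#' @param mask logical matrix, TRUE = ocean (passable).  Row i, column j is
#'   the cell centred at `lat_origin + (i-1)*cell`, `lon_origin + (j-1)*cell`.
#' @param lat_origin,lon_origin coordinates of cell (1, 1), decimal degrees.
#' @param cell cell size in degrees.
#' @return object of class `ocean_grid`.
#' @export
ocean_grid <- function(mask, lat_origin, lon_origin, cell) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, lat_origin = lat_origin,
                 lon_origin = lon_origin, cell = cell),
            class = "ocean_grid")
}

grid_latlon <- function(grid, i, j) {
  cbind(lon = grid$lon_origin + (j - 1) * grid$cell,
        lat = grid$lat_origin + (i - 1) * grid$cell)
}

## snap a point to the nearest passable cell within `radius` cells
snap_to_ocean <- function(grid, lat, lon, radius = 3L) {
  i0 <- round((lat - grid$lat_origin) / grid$cell) + 1
  j0 <- round((lon - grid$lon_origin) / grid$cell) + 1
  nr <- nrow(grid$mask); nc <- ncol(grid$mask)
  best <- NULL; bestd <- Inf
  for (di in -radius:radius) for (dj in -radius:radius) {
    i <- i0 + di; j <- j0 + dj
    if (i < 1 || i > nr || j < 1 || j > nc || !grid$mask[i, j]) next
    d <- di^2 + dj^2
    if (d < bestd) { bestd <- d; best <- c(i, j) }
  }
  if (is.null(best))
    stop("point (", lat, ", ", lon, ") has no passable cell within ",
         radius, " cells")
  best
}

#' Along-ocean distance matrix between river mouths
#'
#' Builds an 8-neighbour graph over ocean cells with per-step great-circle
#' edge lengths (so east-west steps shrink with latitude) and returns the
#' shortest-path distance in kilometres between every pair of river mouths,
#' each snapped to the nearest passable cell within `snap_radius` cells.
#'
#' @param grid an [ocean_grid()].
#' @param mouths data.frame with columns `code`, `lat`, `lon`.
#' @param snap_radius snapping tolerance in cells.
#' @return symmetric matrix (km) with zero diagonal, labelled by river code.
#' @export
marine_distance_matrix <- function(grid, mouths, snap_radius = 3L) {
  nr <- nrow(grid$mask); nc <- ncol(grid$mask)
  idx <- matrix(0L, nr, nc)
  ocean <- which(grid$mask)
  idx[ocean] <- seq_along(ocean)
  oc_ij <- arrayInd(ocean, c(nr, nc))

  ## 8-neighbour edges (each counted once: E, S, SE, SW offsets)
  offs <- rbind(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  from <- to <- integer(0)
  w <- numeric(0)
  for (o in seq_len(nrow(offs))) {
    i2 <- oc_ij[, 1L] + offs[o, 1L]
    j2 <- oc_ij[, 2L] + offs[o, 2L]
    ok <- i2 >= 1L & i2 <= nr & j2 >= 1L & j2 <= nc
    ok[ok] <- grid$mask[cbind(i2[ok], j2[ok])]
    if (!any(ok)) next
    a <- idx[cbind(oc_ij[ok, 1L], oc_ij[ok, 2L])]
    b <- idx[cbind(i2[ok], j2[ok])]
    p1 <- grid_latlon(grid, oc_ij[ok, 1L], oc_ij[ok, 2L])
    p2 <- grid_latlon(grid, i2[ok], j2[ok])
    from <- c(from, a); to <- c(to, b)
    w <- c(w, geosphere::distHaversine(p1, p2) / 1000)
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(ocean) - igraph::vcount(g)))

  snapped <- vapply(seq_len(nrow(mouths)), function(r) {
    ij <- snap_to_ocean(grid, mouths$lat[r], mouths$lon[r], snap_radius)
    idx[ij[1L], ij[2L]]
  }, 0L)
  uniq <- unique(snapped)   # mouths may snap to the same cell
  Du <- igraph::distances(g, v = uniq, to = uniq, weights = w)
  D <- Du[match(snapped, uniq), match(snapped, uniq), drop = FALSE]
  dimnames(D) <- list(mouths$code, mouths$code)
  if (any(!is.finite(D))) {
    bad <- which(!is.finite(D), arr.ind = TRUE)[1L, ]
    stop("no ocean path between ", mouths$code[bad[1L]], " and ",
         mouths$code[bad[2L]])
  }
  D
}

#' Rousset linearization of differentiation
#'
#' Transforms every off-diagonal value x to x/(1-x).  Values equal to 1
#' become NA with a warning (the transform diverges); negative estimates
#' pass through unchanged in sign.
#'
#' @param m symmetric matrix of differentiation estimates (< 1).
#' @export
linearize <- function(m) {
  m <- as.matrix(m)
  at_one <- abs(m - 1) < 1e-12
  if (any(at_one)) {
    warning(sum(at_one), " value(s) equal to 1 excluded (infinite transform)")
    m[at_one] <- NA_real_
  }
  out <- m / (1 - m)
  diag(out) <- 0
  out
}

#' Mantel test between two symmetric matrices
#'
#' r is the Pearson correlation of the off-diagonal lower triangles; the
#' p-value comes from simultaneous row/column permutation of the second
#' matrix.  The default alternative is one-tailed for positive association
#' (the isolation-by-distance hypothesis).  The OLS slope and intercept of
#' `gen ~ dist` over pairs are also returned.
#'
#' @param dist,gen symmetric matrices with matching labels (gen is
#'   reordered to dist's labels when both are labelled).
#' @param n_perm number of permutations (>= 1).
#' @param alternative "greater" (default) or "two.sided".
#' @return object of class `mantel_result` with `r`, `p`, `slope`,
#'   `intercept`, `n_perm`.
#' @export
mantel <- function(dist, gen, n_perm = 9999L,
                   alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  d <- as.matrix(dist); g <- as.matrix(gen)
  if (!is.null(rownames(d)) && !is.null(rownames(g)))
    g <- g[rownames(d), rownames(d)]
  n <- nrow(d)
  if (n < 4L) stop("need at least 4 populations")
  lt <- lower.tri(d)
  x <- d[lt]; y <- g[lt]
  keep <- is.finite(x) & is.finite(y)
  if (sd(x[keep]) == 0 || sd(y[keep]) == 0)
    stop("constant matrix: Mantel r undefined")
  r_obs <- cor(x[keep], y[keep])
  fit <- lm(y[keep] ~ x[keep])
  ge <- 0L
  for (i in seq_len(n_perm)) {
    pm <- sample(n)
    yp <- g[pm, pm][lt]
    rp <- cor(x[keep], yp[keep])
    hit <- if (alternative == "greater") rp >= r_obs - 1e-12
           else abs(rp) >= abs(r_obs) - 1e-12
    if (hit) ge <- ge + 1L
  }
  structure(list(r = r_obs, p = (ge + 1) / (n_perm + 1),
                 slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 n_perm = n_perm, alternative = alternative),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat("Mantel: r =", round(x$r, 3), " p =", format(x$p, digits = 3),
      "(", x$alternative, ",", x$n_perm, "permutations )\n")
  cat("IBD slope =", signif(x$slope, 3), " intercept =",
      signif(x$intercept, 3), "\n")
  invisible(x)
}
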