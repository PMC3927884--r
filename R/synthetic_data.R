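## Generators producing inputs with the statistical structure the pipeline
## assumes: hierarchically structured allele frequencies (stocks containing
## weakly differentiated rivers), AR(1) time series with trends and missing
## years, and a rasterized coastline for along-ocean distances.

rdirichlet_one <- function(par) {
  x <- rgamma(length(par), pmax(par, 1e-8))
  x <- pmax(x, 1e-300)
  x / sum(x)
}

#' Simulate hierarchically structured genotypes
#'
#' Hierarchical F-model: ancestral frequencies ~ symmetric Dirichlet(1);
#' stock frequencies ~ Dirichlet(p_anc (1-F_stock)/F_stock); river
#' frequencies ~ Dirichlet(p_stock (1-F_river)/F_river); genotypes drawn
#' under Hardy-Weinberg within rivers.  F = 0 copies the parent
#' frequencies, so F_stock = F_river = 0 gives panmixia.  Allele codes are
#' fragment lengths 100, 102, 104, ... (dinucleotide spacing).
#'
#' @param n_stocks,rivers_per_stock,individuals_per_river design sizes.
#' @param n_loci,alleles_per_locus marker panel.
#' @param f_stock,f_river stock-vs-ancestral and river-vs-stock divergence
#'   (each in [0, 1)).
#' @param missing_rate per-genotype missing probability (in [0, 0.5]).
#' @param seed optional integer seed.
#' @param species_label dataset tag.
#' @return list: `dataset` (a [genotype_dataset()], one collection per
#'   river), `truth` (data.frame river, stock), `stock_freqs`.
#' @export
simulate_genotypes <- function(n_stocks = 3L, rivers_per_stock = 5L,
                               individuals_per_river = 30L, n_loci = 12L,
                               alleles_per_locus = 8L, f_stock = 0.10,
                               f_river = 0.01, missing_rate = 0,
                               seed = NULL, species_label = "synthetic") {
  if (alleles_per_locus < 2L) stop("need at least 2 alleles per locus")
  if (f_stock < 0 || f_stock >= 1 || f_river < 0 || f_river >= 1)
    stop("F values must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate > 0.5)
    stop("missing_rate must lie in [0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  codes <- 100L + 2L * (seq_len(alleles_per_locus) - 1L)
  descend <- function(p, f) {
    if (f == 0) p else rdirichlet_one(p * (1 - f) / f)
  }
  anc <- replicate(n_loci, rdirichlet_one(rep(1, alleles_per_locus)),
                   simplify = FALSE)
  collections <- list()
  truth <- data.frame(river = character(0), stock = character(0))
  stock_freqs <- list()
  for (s in seq_len(n_stocks)) {
    sf <- lapply(anc, descend, f = f_stock)
    stock_freqs[[paste0("S", s)]] <- sf
    for (r in seq_len(rivers_per_stock)) {
      rf <- lapply(sf, descend, f = f_river)
      n <- individuals_per_river
      m <- matrix(NA_integer_, n, 2L * n_loci)
      for (l in seq_len(n_loci)) {
        g <- sample(codes, 2L * n, replace = TRUE, prob = rf[[l]])
        m[, 2L * l - 1L] <- g[seq_len(n)]
        m[, 2L * l] <- g[n + seq_len(n)]
        if (missing_rate > 0) {
          drop <- runif(n) < missing_rate
          m[drop, c(2L * l - 1L, 2L * l)] <- NA_integer_
        }
      }
      code <- sprintf("S%dR%d", s, r)
      collections[[code]] <- collection(code, 2010L, m)
      truth <- rbind(truth, data.frame(river = code, stock = paste0("S", s)))
    }
  }
  ds <- genotype_dataset(locus_table(sprintf("L%02d", seq_len(n_loci)), 2L),
                         collections, species_label = species_label)
  list(dataset = ds, truth = truth, stock_freqs = stock_freqs)
}

#' Simulate a demographic time series with trend and AR(1) noise
#'
#' \eqn{v_t = intercept + slope (t - t_0) + e_t},
#' \eqn{e_t = \phi e_{t-1} + N(0, \sigma^2)}; years are then thinned
#' independently with `missing_year_prob` (at least 3 records kept).
#'
#' @param n_years series length before thinning (>= 3).
#' @param start_year first year.
#' @param intercept,slope trend parameters (value units, units/yr).
#' @param ar1 AR(1) coefficient (|ar1| < 1).
#' @param noise_sd innovation SD (>= 0).
#' @param missing_year_prob probability a year is unobserved.
#' @param river_code,variable,sex series labels.
#' @param seed optional integer seed.
#' @return a [time_series()].
#' @export
simulate_series <- function(n_years, start_year = 1980L, intercept = 0,
                            slope = 0, ar1 = 0, noise_sd = 1,
                            missing_year_prob = 0,
                            river_code = "SIM", variable = "run_count",
                            sex = "pooled", seed = NULL) {
  if (n_years < 3L) stop("need at least 3 years")
  if (abs(ar1) >= 1) stop("|ar1| must be < 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  e <- numeric(n_years)
  for (t in seq_len(n_years))
    e[t] <- (if (t > 1L) ar1 * e[t - 1L] else 0) + rnorm(1L, 0, noise_sd)
  years <- start_year + seq_len(n_years) - 1L
  values <- intercept + slope * (years - start_year) + e
  keep <- runif(n_years) >= missing_year_prob
  if (sum(keep) < 3L) keep[sample(which(!keep), 3L - sum(keep))] <- TRUE
  time_series(river_code, variable, sex, years[keep], values[keep])
}

#' Simulate a coastline grid with river mouths
#'
#' Builds a synthetic north-south coast: land occupies the western columns
#' up to an irregular (random-walk) coast column per row, ocean lies east
#' of it.  `n_rivers` mouths are placed on the first ocean cell of evenly
#' spaced rows, so along-coast distance ordering matches the mouth
#' (latitude) ordering.
#'
#' @param n_rivers number of river mouths.
#' @param grid_size grid rows/columns (>= 20).
#' @param cell cell size in degrees.
#' @param lat_origin,lon_origin registration of cell (1, 1).
#' @param seed optional integer seed.
#' @return list: `grid` (an [ocean_grid()]) and `mouths` (data.frame code,
#'   lat, lon, state).
#' @export
simulate_coastline <- function(n_rivers, grid_size = 40L, cell = 0.1,
                               lat_origin = 35, lon_origin = -75,
                               seed = NULL) {
  if (grid_size < 20L) stop("grid_size must be >= 20")
  if (!is.null(seed)) set.seed(seed)
  coast <- numeric(grid_size)
  coast[1L] <- grid_size %/% 4L
  for (i in 2:grid_size)
    coast[i] <- min(max(coast[i - 1L] + sample(-1:1, 1L), 2L),
                    grid_size %/% 2L)
  mask <- matrix(TRUE, grid_size, grid_size)
  for (i in seq_len(grid_size)) mask[i, seq_len(coast[i])] <- FALSE
  grid <- ocean_grid(mask, lat_origin, lon_origin, cell)
  rows <- unique(round(seq(2L, grid_size - 1L, length.out = n_rivers)))
  while (length(rows) < n_rivers)
    rows <- sort(unique(c(rows, sample(2:(grid_size - 1L), 1L))))
  rows <- rows[seq_len(n_rivers)]
  mouths <- data.frame(
    code = sprintf("RIV%02d", seq_len(n_rivers)),
    lat = lat_origin + (rows - 1L) * cell,
    lon = lon_origin + (coast[rows]) * cell,  # first ocean column
    state = "XX", stringsAsFactors = FALSE)
  list(grid = grid, mouths = mouths)
}
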