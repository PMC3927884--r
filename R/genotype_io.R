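#' @useDynLib stockpriority, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var sd median lm pchisq pnorm qnorm rbinom rnorm runif
#'   rmultinom pf aov TukeyHSD anova complete.cases cor rgamma coef
#'   setNames
#' @importFrom utils read.csv write.csv combn head tail
NULL

## ---------------------------------------------------------------------------
## Data model
##
## A genotype_dataset holds diploid multilocus genotypes grouped into
## collections (one spawning river in one sample year).  Alleles are integer
## fragment lengths; a missing call is NA in both columns of the locus pair.
## The allele matrix of a collection is n x 2L, columns (locus1.a, locus1.b,
## locus2.a, ...), so locus l occupies columns 2l-1 and 2l.
## ---------------------------------------------------------------------------

#' Construct a set of microsatellite locus descriptors
#'
#' @param names character vector of unique locus names.
#' @param repeat_unit_length integer vector (length 1 or `length(names)`) of
#'   repeat-motif lengths in base pairs, used to convert fragment lengths to
#'   repeat numbers for the lnRV neutrality screen.
#' @return data.frame with columns `name` and `repeat_unit_length`.
#' @export
locus_table <- function(names, repeat_unit_length = 2L) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("locus names must be unique")
  ru <- as.integer(rep_len(repeat_unit_length, length(names)))
  if (any(ru < 1L)) stop("repeat_unit_length must be >= 1")
  data.frame(name = names, repeat_unit_length = ru, stringsAsFactors = FALSE)
}

#' Construct a collection (one river x year sample)
#'
#' @param river_code short river code (e.g. "EMA").
#' @param year sample year (integer, or NA for pooled collections).
#' @param alleles integer matrix, n individuals x 2*L columns; allele codes
#'   are positive integers, missing calls NA.  An individual missing one
#'   allele at a locus is treated as missing the whole locus.
#' @param ids optional individual labels.
#' @return object of class `collection`.
#' @export
collection <- function(river_code, year, alleles, ids = NULL) {
  if (!nzchar(river_code)) stop("river_code must be nonempty")
  alleles <- as.matrix(alleles)
  if (ncol(alleles) %% 2L != 0L) stop("allele matrix needs 2 columns per locus")
  storage.mode(alleles) <- "integer"
  if (any(alleles <= 0L, na.rm = TRUE)) stop("allele codes must be positive")
  ## half-missing genotypes become wholly missing at that locus
  for (l in seq_len(ncol(alleles) / 2L)) {
    cols <- c(2L * l - 1L, 2L * l)
    bad <- is.na(alleles[, cols[1L]]) | is.na(alleles[, cols[2L]])
    alleles[bad, cols] <- NA_integer_
  }
  if (is.null(ids)) {
    ids <- sprintf("%s_%s_%03d", river_code,
                   ifelse(is.na(year), "pooled", year), seq_len(nrow(alleles)))
  }
  structure(list(river_code = river_code, year = as.integer(year),
                 ids = as.character(ids), alleles = alleles),
            class = "collection")
}

#' Assemble a genotype dataset
#'
#' @param loci data.frame from [locus_table()].
#' @param collections list of [collection()] objects sharing the locus order.
#' @param species_label free-text species tag.
#' @return object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(loci, collections, species_label = "") {
  if (length(collections) < 1L) stop("need at least one collection")
  L <- nrow(loci)
  for (col in collections) {
    if (!inherits(col, "collection")) stop("collections must be 'collection' objects")
    if (ncol(col$alleles) != 2L * L)
      stop("collection ", col$river_code, " does not match the locus table")
  }
  names(collections) <- vapply(collections, function(co)
    paste0(co$river_code, if (!is.na(co$year)) paste0("_", co$year) else ""),
    character(1))
  structure(list(loci = loci, collections = collections,
                 species_label = species_label),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", x$species_label, "\n")
  cat(" ", nrow(x$loci), "loci;", length(x$collections), "collections;",
      sum(vapply(x$collections, function(co) nrow(co$alleles), 0)),
      "individuals\n")
  invisible(x)
}

#' @export
print.collection <- function(x, ...) {
  cat("collection", x$river_code,
      if (!is.na(x$year)) x$year else "(pooled)",
      ":", nrow(x$alleles), "individuals\n")
  invisible(x)
}

n_loci <- function(ds) nrow(ds$loci)

locus_cols <- function(l) c(2L * l - 1L, 2L * l)

#' Alleles of one locus in one collection
#'
#' @param col a `collection`.
#' @param l locus index.
#' @param drop_missing drop NA gene copies.
#' @return integer vector of 2n (or fewer) gene copies.
#' @keywords internal
locus_genes <- function(col, l, drop_missing = TRUE) {
  g <- as.vector(t(col$alleles[, locus_cols(l), drop = FALSE]))
  if (drop_missing) g <- g[!is.na(g)]
  g
}

locus_genotypes <- function(col, l) {
  m <- col$alleles[, locus_cols(l), drop = FALSE]
  m[!is.na(m[, 1L]), , drop = FALSE]
}

## ---------------------------------------------------------------------------
## GENEPOP text format
## ---------------------------------------------------------------------------

#' Read a GENEPOP file
#'
#' Parses the classic GENEPOP dialect: a title line, locus names (one per
#' line or comma-separated on one line), `POP` separators, then individual
#' lines `id , a1a2 a1a2 ...` with fixed-width 2- or 3-digit allele codes.
#' `00`/`000` denote a missing allele.  The code width is auto-detected from
#' the first genotype token; mixed widths are rejected.
#'
#' River code and year are recovered from individual labels of the form
#' `CODE_YEAR_xxx`; labels without a parsable year give `year = NA`.
#'
#' @param path file path.
#' @param repeat_unit_length repeat-motif length(s) attached to the loci.
#' @param species_label species tag for the dataset.
#' @return a [genotype_dataset()].
#' @export
read_genepop <- function(path, repeat_unit_length = 2L, species_label = "") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3L) stop("not a GENEPOP file: too few lines")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) stop("not a GENEPOP file: no POP separator")
  header <- lines[2:(first_pop - 1L)]
  locus_names <- trimws(unlist(strsplit(header, ",")))
  locus_names <- locus_names[nzchar(locus_names)]
  L <- length(locus_names)
  if (L < 1L) stop("no locus names found")

  ## detect allele-code width from the first genotype token
  body <- lines[(first_pop + 1L):length(lines)]
  first_ind <- body[!grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)][1L]
  tok <- strsplit(sub("^[^,]*,", "", first_ind), "\\s+")[[1L]]
  tok <- tok[nzchar(tok)][1L]
  width <- nchar(tok) / 2L
  if (!width %in% c(2L, 3L))
    stop("unknown allele-code width (token '", tok, "')")

  pop_breaks <- c(first_pop, which(is_pop)[which(is_pop) > first_pop],
                  length(lines) + 1L)
  pop_breaks <- sort(unique(c(which(is_pop), length(lines) + 1L)))
  collections <- list()
  for (p in seq_len(length(pop_breaks) - 1L)) {
    rows <- lines[(pop_breaks[p] + 1L):(pop_breaks[p + 1L] - 1L)]
    if (length(rows) < 1L) stop("empty POP block ", p)
    ids <- character(length(rows))
    mat <- matrix(NA_integer_, length(rows), 2L * L)
    for (i in seq_along(rows)) {
      parts <- strsplit(rows[i], ",")[[1L]]
      if (length(parts) < 2L)
        stop("malformed individual line: '", rows[i], "'")
      ids[i] <- trimws(parts[1L])
      toks <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "\\s+")[[1L]]
      toks <- toks[nzchar(toks)]
      if (length(toks) != L)
        stop("ragged genotype row for individual '", ids[i], "': ",
             length(toks), " loci, expected ", L)
      if (any(nchar(toks) != 2L * width))
        stop("mixed allele-code widths at individual '", ids[i], "'")
      a1 <- as.integer(substr(toks, 1L, width))
      a2 <- as.integer(substr(toks, width + 1L, 2L * width))
      a1[a1 == 0L] <- NA_integer_
      a2[a2 == 0L] <- NA_integer_
      mat[i, seq(1L, 2L * L, by = 2L)] <- a1
      mat[i, seq(2L, 2L * L, by = 2L)] <- a2
    }
    info <- parse_sample_id(ids[1L])
    collections[[p]] <- collection(info$river, info$year, mat, ids = ids)
  }
  genotype_dataset(locus_table(locus_names, repeat_unit_length),
                   collections, species_label = species_label)
}

parse_sample_id <- function(id) {
  parts <- strsplit(id, "_")[[1L]]
  year <- NA_integer_
  if (length(parts) >= 2L && grepl("^[0-9]{4}$", parts[2L]))
    year <- as.integer(parts[2L])
  list(river = parts[1L], year = year)
}

#' Write a GENEPOP file
#'
#' Emits a file that re-parses (via [read_genepop()]) to an equal dataset:
#' same allele codes, population order and missing pattern.  The code width
#' (2 or 3 digits) is chosen from the largest allele code.
#'
#' @param ds a [genotype_dataset()].
#' @param path output file path.
#' @param title first (comment) line of the file.
#' @export
write_genepop <- function(ds, path, title = ds$species_label) {
  for (co in ds$collections)
    if (nrow(co$alleles) == 0L)
      stop("empty collection '", co$river_code, "': GENEPOP POP blocks cannot be empty")
  amax <- suppressWarnings(max(unlist(lapply(ds$collections,
                                             function(co) co$alleles)), na.rm = TRUE))
  if (!is.finite(amax)) amax <- 1L
  if (amax > 999L) stop("allele code ", amax, " exceeds 3 digits")
  width <- if (amax > 99L) 3L else 2L
  fmt <- paste0("%0", width, "d")
  out <- c(if (nzchar(title)) title else "stockpriority export",
           ds$loci$name)
  for (co in ds$collections) {
    out <- c(out, "POP")
    for (i in seq_len(nrow(co$alleles))) {
      a <- co$alleles[i, ]
      a[is.na(a)] <- 0L
      toks <- paste0(sprintf(fmt, a[seq(1L, length(a), 2L)]),
                     sprintf(fmt, a[seq(2L, length(a), 2L)]))
      out <- c(out, paste0(co$ids[i], " , ", paste(toks, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Collection management
## ---------------------------------------------------------------------------

#' Pool temporal replicates of one river
#'
#' Merges all collections sharing a river code into a single collection,
#' appropriate once temporal homogeneity has been established (e.g. by a
#' hierarchical AMOVA showing nonsignificant variation among years).
#'
#' @param ds a [genotype_dataset()].
#' @param river_code river to pool.
#' @return a single pooled [collection()] (year = NA, `years` attribute).
#' @export
pool_temporal_replicates <- function(ds, river_code) {
  keep <- vapply(ds$collections, function(co) co$river_code == river_code,
                 logical(1))
  if (!any(keep)) stop("unknown river code '", river_code, "'")
  cols <- ds$collections[keep]
  merged <- collection(river_code, NA_integer_,
                       do.call(rbind, lapply(cols, `[[`, "alleles")),
                       ids = unlist(lapply(cols, `[[`, "ids")))
  attr(merged, "years") <- sort(unique(vapply(cols, `[[`, 0L, "year")))
  merged
}

#' Pool every river's temporal replicates
#'
#' @param ds a [genotype_dataset()].
#' @return a [genotype_dataset()] with one collection per river, in order of
#'   first appearance.
#' @export
pool_all_rivers <- function(ds) {
  rivers <- unique(vapply(ds$collections, `[[`, "", "river_code"))
  genotype_dataset(ds$loci,
                   lapply(rivers, function(r) pool_temporal_replicates(ds, r)),
                   species_label = ds$species_label)
}

#' Per-river sample summary
#'
#' @param ds a [genotype_dataset()], or NULL/empty.
#' @return data.frame (river, years, n) with a `total` attribute holding the
#'   grand specimen total.
#' @export
summarize_dataset <- function(ds) {
  if (is.null(ds) || length(ds$collections) == 0L) {
    out <- data.frame(river = character(), years = character(), n = integer())
    attr(out, "total") <- 0L
    return(out)
  }
  rivers <- unique(vapply(ds$collections, `[[`, "", "river_code"))
  rows <- lapply(rivers, function(r) {
    cols <- ds$collections[vapply(ds$collections,
                                  function(co) co$river_code == r, logical(1))]
    yrs <- vapply(cols, `[[`, 0L, "year")
    data.frame(river = r,
               years = paste(sort(yrs[!is.na(yrs)]), collapse = ","),
               n = sum(vapply(cols, function(co) nrow(co$alleles), 0L)))
  })
  out <- do.call(rbind, rows)
  attr(out, "total") <- sum(out$n)
  out
}

#' Read river metadata (code, coordinates, state, optional stock)
#'
#' @param path CSV with columns `code,lat,lon,state` and optionally `stock`.
#' @return data.frame with validated coordinates.
#' @export
read_river_metadata <- function(path) {
  md <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("code", "lat", "lon", "state")
  if (!all(need %in% names(md)))
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  if (any(md$lat < -90 | md$lat > 90)) stop("latitude out of [-90, 90]")
  if (any(md$lon < -180 | md$lon > 180)) stop("longitude out of [-180, 180]")
  if (is.null(md$stock)) md$stock <- NA_character_
  md
}

#' Read demographic time series from delimited text
#'
#' @param path CSV with columns `river,variable,sex,year,value`.
#' @return list of [time_series()] objects, one per river x variable x sex.
#' @export
read_time_series_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("river", "variable", "sex", "year", "value")
  if (!all(need %in% names(df)))
    stop("time-series file needs columns: ", paste(need, collapse = ", "))
  key <- interaction(df$river, df$variable, df$sex, drop = TRUE)
  lapply(split(df, key), function(d)
    time_series(d$river[1L], d$variable[1L], d$sex[1L], d$year, d$value))
}
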