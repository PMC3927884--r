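## Bundled reference tables for the two river herring species: the genetic
## sample register (collections, years, sample sizes) and the published
## river-level conservation prioritization table.  These small plain-text
## tables let the bookkeeping operations (pooling, summaries, tallies) be
## exercised without access to the genotype data themselves.

#' Genetic sample register for alewife and blueback herring
#'
#' One row per (river, year) genetic collection: species, river name, code,
#' state, sample year, and the number of specimens.
#'
#' @param species optional "alewife" or "blueback".
#' @return data.frame.
#' @export
herring_sample_register <- function(species = NULL) {
  df <- read.csv(system.file("extdata", "sample_collections.csv",
                             package = "stockpriority"),
                 stringsAsFactors = FALSE)
  if (!is.null(species)) df <- df[df$species == species, ]
  df
}

#' Build a register-only genotype dataset
#'
#' Expands the sample register into a [genotype_dataset()] whose
#' collections have the registered sizes but no genotype calls (a single
#' all-missing placeholder locus), so the pooling and summary plumbing
#' operates on the published collection structure.
#'
#' @param species "alewife" or "blueback".
#' @return a [genotype_dataset()].
#' @export
register_dataset <- function(species) {
  reg <- herring_sample_register(species)
  cols <- lapply(seq_len(nrow(reg)), function(i)
    collection(reg$code[i], reg$year[i],
               matrix(NA_integer_, reg$n[i], 2L)))
  genotype_dataset(locus_table("placeholder"), cols, species_label = species)
}

#' Published river-level conservation prioritizations
#'
#' @param species "alewife" or "blueback".
#' @return a `priority_table` data.frame (river, stock, designation,
#'   demographic_data), restricted to rivers inside the species' assessed
#'   range.
#' @export
herring_priority_table <- function(species = c("alewife", "blueback")) {
  species <- match.arg(species)
  df <- read.csv(system.file("extdata", "priority_table.csv",
                             package = "stockpriority"),
                 stringsAsFactors = FALSE)
  pre <- if (species == "alewife") "alewife" else "blueback"
  out <- data.frame(river = df$river, state = df$state,
                    stock = df[[paste0(pre, "_stock")]],
                    designation = df[[paste0(pre, "_priority")]],
                    demographic_data = df[[paste0(pre, "_demog")]] == "Y",
                    stringsAsFactors = FALSE)
  out <- out[out$designation != "-", ]
  rownames(out) <- NULL
  class(out) <- c("priority_table", "data.frame")
  out
}
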