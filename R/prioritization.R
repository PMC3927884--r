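## Conservation-prioritization rules: per-population classification from
## trend slopes, precautionary merging across variables, stock-level
## averaging, and extension to demographically unmonitored rivers.

PRIORITY_LEVELS <- c("low", "medium", "high")

#' Default prioritization thresholds
#'
#' Slopes above 0 are low priority; slopes at or below the variable's cut
#' (-0.75 mm/yr for mean length, -0.05 SD/yr for normalized run size) are
#' high priority; in between is medium.
#'
#' @param length_cut medium/high threshold for mean-length slopes.
#' @param runsize_cut medium/high threshold for normalized run-size slopes.
#' @export
priority_thresholds <- function(length_cut = -0.75, runsize_cut = -0.05) {
  if (length_cut >= 0 || runsize_cut >= 0)
    stop("cuts must be below the low-priority boundary (0)")
  list(length_cut = length_cut, runsize_cut = runsize_cut, low_cut = 0)
}

#' Classify one slope into a priority designation
#'
#' @param slope finite trend slope.
#' @param variable "mean_length", "run_count", "run_cpue" (the run-size
#'   variables share the run-size cut).
#' @param thresholds from [priority_thresholds()].
#' @return "low", "medium" or "high".
#' @export
classify_variable <- function(slope, variable,
                              thresholds = priority_thresholds()) {
  if (!is.finite(slope)) stop("slope must be finite")
  cut <- switch(variable,
                mean_length = thresholds$length_cut,
                run_count = ,
                run_cpue = ,
                run_size = thresholds$runsize_cut,
                stop("unknown variable '", variable, "'"))
  if (slope > thresholds$low_cut) "low"
  else if (slope > cut) "medium"
  else "high"
}

#' Precautionary merge of designations
#'
#' Join on the ordered lattice low < medium < high: the more conservative
#' (higher-risk) designation wins.  Absent designations (NULL/NA) pass
#' through; both absent is an error (the caller must fall back to the
#' stock-level designation).
#'
#' @param d_length,d_runsize designations or NA/NULL.
#' @export
merge_designations <- function(d_length = NULL, d_runsize = NULL) {
  ds <- c(d_length, d_runsize)
  ds <- ds[!is.na(ds)]
  if (length(ds) == 0L)
    stop("no designation available: use the stock-level extension")
  if (!all(ds %in% PRIORITY_LEVELS)) stop("unknown designation")
  PRIORITY_LEVELS[max(match(ds, PRIORITY_LEVELS))]
}

#' Stock-level designation from member slopes
#'
#' Averages the member time-series slopes per variable, classifies each
#' mean, and merges the per-variable designations conservatively.
#'
#' @param length_slopes,runsize_slopes numeric vectors (possibly empty) of
#'   member slopes; run-size slopes are expected in normalized units.
#' @param thresholds from [priority_thresholds()].
#' @export
stock_designation <- function(length_slopes = numeric(0),
                              runsize_slopes = numeric(0),
                              thresholds = priority_thresholds()) {
  if (length(length_slopes) + length(runsize_slopes) == 0L)
    stop("no member slopes for this stock")
  dl <- if (length(length_slopes))
    classify_variable(mean(length_slopes), "mean_length", thresholds) else NA
  dr <- if (length(runsize_slopes))
    classify_variable(mean(runsize_slopes), "run_count", thresholds) else NA
  merge_designations(dl, dr)
}

#' River-level designation from a trend table
#'
#' For each river with demographic data, classifies every series slope
#' (male/female mean-length series separately) and merges all of the
#' river's designations conservatively.
#'
#' @param per_series data.frame from [trend_table()]`$per_series`.
#' @param thresholds from [priority_thresholds()].
#' @return named character vector of designations by river.
#' @export
river_designations <- function(per_series, thresholds = priority_thresholds()) {
  vapply(split(per_series, per_series$river), function(d) {
    des <- mapply(classify_variable, d$slope, d$variable,
                  MoreArgs = list(thresholds = thresholds))
    Reduce(function(a, b) merge_designations(a, b), des)
  }, character(1))
}

#' Extend designations to unmonitored rivers
#'
#' Monitored rivers keep their own-data designation; demographically
#' unmonitored rivers inherit their stock's designation.  Rivers without a
#' stock label (not genetically sampled) are first assigned to the stock of
#' the nearest stock-bearing river — by the supplied along-coast distance
#' matrix if given, else by great-circle distance from coordinates; exact
#' ties go to the more northern neighbour with a warning.  Manual overrides
#' are applied last and flagged in the provenance column.
#'
#' @param rivers data.frame with columns `river`, `stock` (NA = unassigned),
#'   `lat`, `lon`.
#' @param own named designation vector from [river_designations()] (rivers
#'   absent from it count as unmonitored).
#' @param stock_des named designation vector by stock.
#' @param dist_km optional along-coast distance matrix labelled by river.
#' @param overrides optional data.frame (`river`, `designation`, `reason`).
#' @return `priority_table` data.frame: river, stock, designation,
#'   provenance (own_data / stock_extended / override).
#' @export
extend_to_unmonitored <- function(rivers, own, stock_des, dist_km = NULL,
                                  overrides = NULL) {
  rivers$stock <- as.character(rivers$stock)
  unassigned <- which(is.na(rivers$stock))
  anchors <- which(!is.na(rivers$stock))
  for (i in unassigned) {
    if (length(anchors) == 0L) stop("no stock-bearing river to assign from")
    d <- if (!is.null(dist_km)) {
      dist_km[rivers$river[i], rivers$river[anchors]]
    } else {
      if (is.na(rivers$lat[i]))
        stop("river ", rivers$river[i], " has no stock and no coordinates")
      geosphere::distHaversine(cbind(rivers$lon[i], rivers$lat[i]),
                               cbind(rivers$lon[anchors],
                                     rivers$lat[anchors])) / 1000
    }
    near <- which(d == min(d))
    if (length(near) > 1L) {
      warning("river ", rivers$river[i], " equidistant from ",
              length(near), " rivers; assigned to the northern neighbour")
      near <- near[which.max(rivers$lat[anchors][near])]
    }
    rivers$stock[i] <- rivers$stock[anchors[near]]
  }
  designation <- character(nrow(rivers))
  provenance <- character(nrow(rivers))
  for (i in seq_len(nrow(rivers))) {
    r <- rivers$river[i]
    if (r %in% names(own)) {
      designation[i] <- own[[r]]
      provenance[i] <- "own_data"
    } else {
      st <- rivers$stock[i]
      if (!st %in% names(stock_des))
        stop("no stock designation for stock '", st, "'")
      designation[i] <- stock_des[[st]]
      provenance[i] <- "stock_extended"
    }
  }
  out <- data.frame(river = rivers$river, stock = rivers$stock,
                    designation = designation, provenance = provenance,
                    stringsAsFactors = FALSE)
  if (!is.null(overrides)) {
    for (j in seq_len(nrow(overrides))) {
      i <- match(overrides$river[j], out$river)
      if (is.na(i)) stop("override names unknown river ", overrides$river[j])
      out$designation[i] <- overrides$designation[j]
      out$provenance[i] <- paste0("override: ", overrides$reason[j])
    }
  }
  class(out) <- c("priority_table", "data.frame")
  out
}

#' Tally a priority table
#'
#' @param pt a `priority_table` (or any data.frame with `designation` and
#'   optionally `stock`).
#' @return list with `counts` (low/medium/high + total) and `by_stock`.
#' @export
tally_report <- function(pt) {
  counts <- setNames(integer(3L), PRIORITY_LEVELS)
  if (nrow(pt) > 0L) {
    tab <- table(factor(pt$designation, levels = PRIORITY_LEVELS))
    counts[] <- as.integer(tab)
  }
  by_stock <- if (!is.null(pt$stock) && nrow(pt) > 0L)
    table(pt$stock, factor(pt$designation, levels = PRIORITY_LEVELS))
  else NULL
  list(counts = c(counts, total = sum(counts)), by_stock = by_stock)
}
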