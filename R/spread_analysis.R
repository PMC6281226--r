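# Spread-of-signal profiles: origin wells, relative expression, and the
# within-cross / outside-cross partition of detections.

#' Find the origin well of a marker
#'
#' The origin of a marker in a batch is the non-control well with the highest
#' expression, provided the marker is detected in at least three wells (fewer
#' detections carry too little evidence of spreading).  Control wells are
#' excluded before both the detection count and the maximum.
#'
#' @param marker Marker token (a rowname of the table).
#' @param table A \code{\link{marker_table}}.
#' @param space The batch's \code{batch_space}.
#' @param floor Detection floor: a marker is detected in a well iff its TPM
#'   exceeds this value (default 0).
#' @return The origin well label, or \code{NA_character_} when the marker is
#'   detected in fewer than three non-control wells.  An exact tie at the
#'   maximum resolves to the lexicographically smallest well label with a
#'   warning.
#' @export
find_origin_well <- function(marker, table, space, floor = 0) {
  x <- marker_tpm(marker, table)
  x <- x[!space$wells$is_control[match(names(x), space$wells$well)]]
  det <- names(x)[x > floor]
  if (length(det) < 3L) return(NA_character_)
  mx <- max(x)
  top <- sort(names(x)[x == mx])
  if (length(top) > 1L)
    warning("tie at maximum TPM for marker '", marker,
            "'; taking lexicographically smallest well ", top[1])
  top[1]
}

marker_tpm <- function(marker, table) {
  i <- match(marker, rownames(table$tpm))
  if (is.na(i)) stop("marker not in table: '", marker, "'")
  table$tpm[i, ]
}

#' Profile the spread of a marker around its origin well
#'
#' Computes the relative expression (TPM in each well over TPM in the origin)
#' of a marker across all non-control wells, splits detections into
#' within-cross and outside-cross sets, and flags wells whose relative
#' expression reaches the clonal threshold as possible in vivo clonal
#' expansion rather than index switching.
#'
#' @inheritParams find_origin_well
#' @param origin Origin well label, normally from
#'   \code{\link{find_origin_well}}.
#' @param clonal_threshold Relative expression at or above which a recipient
#'   well is flagged as a possible independent clonal source (default 0.1,
#'   matching the empirical separation between switching artefacts, almost
#'   all below 0.05, and true duplications at 0.1-0.99).
#' @return Object of class \code{spread_profile}: the marker, origin,
#'   relative-expression vector over non-control wells, the detected
#'   within-cross and outside-cross well sets, and the clonal-flagged wells.
#' @export
spread_profile <- function(marker, origin, table, space, floor = 0,
                           clonal_threshold = 0.1) {
  origin <- resolve_well(origin, space)
  x <- marker_tpm(marker, table)
  x <- x[!space$wells$is_control[match(names(x), space$wells$well)]]
  if (!origin %in% names(x)) stop("origin is a control well or not in space")
  if (x[origin] <= 0) stop("origin TPM is 0 for marker '", marker,
                           "': cannot normalize")
  relexp <- x / x[origin]
  cross <- cross_of(origin, space)
  outside <- outside_cross(origin, space)
  det <- names(relexp)[x > floor]
  structure(list(marker = marker, origin = origin, relexp = relexp,
                 cross = cross, outside = outside,
                 detected_within = intersect(det, cross),
                 detected_outside = intersect(det, outside),
                 clonal_flagged = setdiff(names(relexp)[relexp >= clonal_threshold],
                                          origin),
                 floor = floor, clonal_threshold = clonal_threshold),
            class = "spread_profile")
}

#' @export
print.spread_profile <- function(x, ...) {
  cat("Spread profile of '", x$marker, "' from origin ", x$origin, "\n",
      sep = "")
  cat("  detected within cross: ", length(x$detected_within), "/",
      length(x$cross), ";  outside: ", length(x$detected_outside), "/",
      length(x$outside), "\n", sep = "")
  if (length(x$clonal_flagged))
    cat("  clonal-flagged wells:", paste(x$clonal_flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate within/outside-cross detection counts over markers
#'
#' Accumulates, over a set of spread profiles, how many within-cross and
#' outside-cross wells exist (per origin) and how many of each carried the
#' marker, reproducing the counting behind proportions such as "320 of 1104
#' within-cross wells".
#'
#' @param profiles List of \code{\link{spread_profile}} objects.
#' @return List of class \code{partition_counts} with
#'   \code{n_within_detected}, \code{n_within_total},
#'   \code{n_outside_detected}, \code{n_outside_total}.
#' @export
partition_counts <- function(profiles) {
  if (inherits(profiles, "spread_profile")) profiles <- list(profiles)
  counts <- list(n_within_detected = 0L, n_within_total = 0L,
                 n_outside_detected = 0L, n_outside_total = 0L)
  for (p in profiles) {
    counts$n_within_detected <- counts$n_within_detected + length(p$detected_within)
    counts$n_within_total <- counts$n_within_total + length(p$cross)
    counts$n_outside_detected <- counts$n_outside_detected + length(p$detected_outside)
    counts$n_outside_total <- counts$n_outside_total + length(p$outside)
  }
  structure(counts, class = "partition_counts")
}

#' Normalized within-cross fraction
#'
#' The proportion of spread signal attributable to single-index switching,
#' after normalizing the raw detection counts for the very different numbers
#' of wells within and outside a cross pattern: with within-cross detection
#' rate r_w and outside rate r_o, returns r_w / (r_w + r_o).
#'
#' @param counts A \code{\link{partition_counts}} object, or
#'   \code{n_within_detected} given all four counts positionally.
#' @param n_within_total,n_outside_detected,n_outside_total Counts when not
#'   passing a \code{partition_counts}.
#' @return A fraction in [0, 1].
#' @examples
#' normalized_within_fraction(320, 1104, 13, 6820)  # 0.9935
#' @export
normalized_within_fraction <- function(counts, n_within_total = NULL,
                                       n_outside_detected = NULL,
                                       n_outside_total = NULL) {
  if (inherits(counts, "partition_counts")) {
    c4 <- counts
  } else {
    c4 <- list(n_within_detected = counts, n_within_total = n_within_total,
               n_outside_detected = n_outside_detected,
               n_outside_total = n_outside_total)
  }
  if (c4$n_within_total <= 0 || c4$n_outside_total <= 0)
    stop("zero within/outside totals")
  r_w <- c4$n_within_detected / c4$n_within_total
  r_o <- c4$n_outside_detected / c4$n_outside_total
  if (r_w + r_o == 0) return(NaN)
  r_w / (r_w + r_o)
}

#' Spread profiles for every origin-bearing marker of a batch
#'
#' Runs \code{\link{find_origin_well}} and \code{\link{spread_profile}} over
#' all markers of a table.  Markers without an origin (detected in fewer than
#' three wells) are returned separately with summary statistics, mirroring
#' the low-evidence report of markers that never enter estimation.
#'
#' @inheritParams spread_profile
#' @return List with \code{profiles} (named list of spread profiles) and
#'   \code{low_evidence} (data frame: marker, wells detected, max and median
#'   TPM among detections).
#' @export
batch_profiles <- function(table, space, floor = 0, clonal_threshold = 0.1) {
  profiles <- list()
  low <- list()
  for (m in rownames(table$tpm)) {
    o <- find_origin_well(m, table, space, floor)
    if (is.na(o)) {
      x <- marker_tpm(m, table)
      x <- x[x > floor]
      low[[length(low) + 1L]] <- data.frame(
        marker = m, n_wells = length(x),
        max_tpm = if (length(x)) max(x) else 0,
        median_tpm = if (length(x)) stats::median(x) else 0,
        stringsAsFactors = FALSE)
      next
    }
    profiles[[m]] <- spread_profile(m, o, table, space, floor, clonal_threshold)
  }
  list(profiles = profiles,
       low_evidence = if (length(low)) do.call(rbind, low)
                      else data.frame(marker = character(0), n_wells = integer(0),
                                      max_tpm = numeric(0), median_tpm = numeric(0)))
}
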