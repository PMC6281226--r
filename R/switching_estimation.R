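# Misassignment estimation: per-marker summed recipient relative expression,
# dual-source allocation, per-index switching propensities, and the
# contamination and platform tests.

#' Allocate a marker's signal between two clonal source wells
#'
#' When a marker has two accepted sources (a clone present twice), recipient
#' wells lying in both sources' crosses received switched reads from both.
#' Their TPM is split between the sources in proportion to the source
#' expressions; wells in exactly one cross attach wholly to that source.
#' Allocation conserves per-well TPM exactly.  With a single source the
#' allocation is the identity.
#'
#' @param marker Marker token.
#' @param sources Character vector of 1 or 2 source well labels.
#' @param table A \code{\link{marker_table}}.
#' @param space The batch's \code{batch_space}.
#' @return Named list (by source well), each element a list with the
#'   source's \code{tpm} allocation over wells and \code{relexp} (allocated
#'   TPM over the source's own TPM).
#' @export
allocate_dual_source <- function(marker, sources, table, space) {
  sources <- resolve_well(sources, space)
  if (length(sources) > 2L) stop("more than two sources (should be filtered)")
  x <- marker_tpm(marker, table)
  w <- space$wells
  x <- x[!w$is_control[match(names(x), w$well)]]
  src_tpm <- x[sources]
  if (sum(src_tpm) <= 0) stop("source expressions are all 0")
  crosses <- lapply(sources, cross_of, space = space)
  share <- src_tpm / sum(src_tpm)
  both <- if (length(sources) == 2L) intersect(crosses[[1]], crosses[[2]])
          else character(0)
  out <- lapply(seq_along(sources), function(i) {
    alloc <- stats::setNames(numeric(length(x)), names(x))
    own <- setdiff(crosses[[i]], unlist(crosses[-i]))
    alloc[own] <- x[own]
    # second share as the complement so per-well conservation is exact
    alloc[both] <- if (i == 1L) x[both] * share[1] else x[both] - x[both] * share[1]
    alloc[sources[i]] <- x[sources[i]]
    list(source = sources[i], tpm = alloc, relexp = alloc / x[sources[i]])
  })
  stats::setNames(out, sources)
}

#' Per-marker misassignment estimate from one source
#'
#' Sums the relative expression of a marker over the recipient wells of its
#' source's cross, decomposed into the row arm (wells sharing the source's
#' row index, reached by a column-index switch) and the column arm (shared
#' column index, row-index switch).  Outside-cross signal is reported as a
#' separate diagnostic, never added to the misassigned fraction.
#'
#' @param source Source well label.
#' @param relexp Named relative-expression vector over non-control wells
#'   (from \code{\link{spread_profile}} or \code{\link{allocate_dual_source}}).
#' @param space The \code{batch_space}.
#' @param marker Marker token (carried through to the output).
#' @return One-row data frame: marker, source, batch, platform,
#'   \code{sum_relexp_row_arm}, \code{sum_relexp_col_arm},
#'   \code{misassigned_fraction} (their sum) and
#'   \code{sum_relexp_outside}.
#' @export
per_marker_misassignment <- function(marker, source, relexp, space) {
  source <- resolve_well(source, space)
  s <- well_row(source, space)
  cross <- cross_of(source, space)
  info <- well_row(cross, space)
  row_arm <- cross[info$row_index == s$row_index]
  col_arm <- cross[info$col_index == s$col_index]
  outside <- outside_cross(source, space)
  data.frame(marker = marker, source = source, batch_id = space$batch_id,
             platform = space$platform,
             sum_relexp_row_arm = sum(relexp[row_arm]),
             sum_relexp_col_arm = sum(relexp[col_arm]),
             misassigned_fraction = sum(relexp[row_arm]) + sum(relexp[col_arm]),
             sum_relexp_outside = sum(relexp[outside]),
             stringsAsFactors = FALSE)
}

#' Summarize misassignment estimates
#'
#' Median and interquartile range of the misassigned fraction, overall, per
#' platform, and per source well (markers of one well averaged first, since
#' one cell can source both an alpha and a beta marker).  Quantiles use
#' linear interpolation (\code{stats::quantile} type 7).
#'
#' @param estimates Data frame of \code{\link{per_marker_misassignment}} rows.
#' @return List of class \code{switch_summary}: \code{n_markers},
#'   \code{n_source_wells}, \code{overall} (median/q1/q3), \code{by_platform},
#'   \code{by_well} and the quantile convention used.
#' @export
batch_summary <- function(estimates) {
  if (!nrow(estimates)) stop("no estimates to summarize")
  qs <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    list(median = q[2], q1 = q[1], q3 = q[3], n = length(x))
  }
  per_well <- tapply(estimates$misassigned_fraction,
                     paste(estimates$batch_id, estimates$source),
                     mean)
  by_platform <- lapply(split(estimates$misassigned_fraction,
                              estimates$platform), qs)
  structure(list(n_markers = nrow(estimates),
                 n_source_wells = length(per_well),
                 overall = qs(estimates$misassigned_fraction),
                 by_platform = by_platform,
                 by_well = qs(as.numeric(per_well)),
                 quantile_type = 7L),
            class = "switch_summary")
}

#' @export
print.switch_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf("Misassignment over %d markers in %d source wells:\n",
              x$n_markers, x$n_source_wells))
  cat(sprintf("  median %.1f%% (IQR %.1f%%-%.1f%%)\n",
              100 * o$median, 100 * o$q1, 100 * o$q3))
  for (p in names(x$by_platform)) {
    b <- x$by_platform[[p]]
    cat(sprintf("  %s: median %.3f (n = %d)\n", p, b$median, b$n))
  }
  invisible(x)
}

#' Per-index switching propensities
#'
#' For each column index c, accumulates over curated markers (whose source
#' does not use c) the relative expression of the single well reachable from
#' the source by one column switch into c — the well with the source's row
#' index and column index c — and divides by the number of such markers (the
#' index's exposures).  Row indices analogous.  Under uniform switching all
#' propensities share one expectation.
#'
#' @param estimates Accepted estimates (to know the markers and sources).
#' @param relexps Named list: for each (marker, source) key
#'   \code{"marker|source"} the relative-expression vector used for that
#'   estimate.
#' @param space The \code{batch_space}.
#' @return Data frame: \code{index}, \code{role} (\code{row}/\code{column}),
#'   \code{accumulated_relexp}, \code{n_exposures}, \code{propensity}
#'   (\code{NA} when never exposed).
#' @export
index_propensities <- function(estimates, relexps, space) {
  w <- space$wells
  acc <- list(row = stats::setNames(numeric(length(space$row_indices)),
                                    space$row_indices),
              column = stats::setNames(numeric(length(space$col_indices)),
                                       space$col_indices))
  n_exp <- lapply(acc, function(a) stats::setNames(integer(length(a)), names(a)))
  for (i in seq_len(nrow(estimates))) {
    src <- well_row(estimates$source[i], space)
    re <- relexps[[paste0(estimates$marker[i], "|", estimates$source[i])]]
    for (cc in setdiff(space$col_indices, src$col_index)) {
      tgt <- w$well[w$row_index == src$row_index & w$col_index == cc]
      n_exp$column[cc] <- n_exp$column[cc] + 1L
      if (!w$is_control[match(tgt, w$well)])
        acc$column[cc] <- acc$column[cc] + (re[tgt] %|NA|% 0)
    }
    for (rr in setdiff(space$row_indices, src$row_index)) {
      tgt <- w$well[w$row_index == rr & w$col_index == src$col_index]
      n_exp$row[rr] <- n_exp$row[rr] + 1L
      if (!w$is_control[match(tgt, w$well)])
        acc$row[rr] <- acc$row[rr] + (re[tgt] %|NA|% 0)
    }
  }
  rbind(
    data.frame(index = names(acc$row), role = "row",
               accumulated_relexp = as.numeric(acc$row),
               n_exposures = as.integer(n_exp$row),
               propensity = ifelse(n_exp$row > 0, acc$row / n_exp$row, NA),
               stringsAsFactors = FALSE),
    data.frame(index = names(acc$column), role = "column",
               accumulated_relexp = as.numeric(acc$column),
               n_exposures = as.integer(n_exp$column),
               propensity = ifelse(n_exp$column > 0, acc$column / n_exp$column, NA),
               stringsAsFactors = FALSE))
}

`%|NA|%` <- function(a, b) if (length(a) != 1L || is.na(a)) b else a

#' Paired test for plate-local contamination
#'
#' In a two-plate batch, column-arm recipients split into wells on the
#' source's own plate and wells on the other plate.  Index switching reaches
#' both equally; physical contamination only the source plate.  Per marker
#' the mean relative expression in each group forms a pair; a one-sided
#' paired t-test (alternative: source plate higher) detects contamination.
#'
#' @param same_plate,other_plate Numeric vectors of per-marker mean relative
#'   expression in source-plate and other-plate column-arm wells.
#' @return List of class \code{switch_test}: statistic, df, p_value,
#'   sidedness, group means, and \code{degenerate = TRUE} (with
#'   \code{p_value = NA}) when the paired differences have zero variance.
#' @export
contamination_paired_test <- function(same_plate, other_plate) {
  stopifnot(length(same_plate) == length(other_plate))
  if (length(same_plate) < 2L) stop("need at least 2 pairs")
  d <- same_plate - other_plate
  if (stats::sd(d) == 0)
    return(structure(list(statistic = NA_real_, df = length(d) - 1L,
                          p_value = NA_real_, sidedness = "one_sided",
                          degenerate = TRUE,
                          group_means = c(same_plate = mean(same_plate),
                                          other_plate = mean(other_plate))),
                     class = "switch_test"))
  tt <- stats::t.test(same_plate, other_plate, paired = TRUE,
                      alternative = "greater")
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, sidedness = "one_sided",
                 degenerate = FALSE,
                 group_means = c(same_plate = mean(same_plate),
                                 other_plate = mean(other_plate))),
            class = "switch_test")
}

#' Compare misassignment between sequencing platforms
#'
#' Two-sided equal-variance (Student's) two-sample t-test on the misassigned
#' fractions of two platform groups, with group medians reported.
#'
#' @param estimates Data frame of estimates from two or more batches with
#'   exactly two distinct platforms, or a list of two numeric vectors.
#' @return A \code{switch_test} (two-sided) with per-group medians.
#' @export
platform_compare <- function(estimates) {
  if (is.data.frame(estimates))
    groups <- split(estimates$misassigned_fraction, estimates$platform)
  else groups <- estimates
  groups <- groups[lengths(groups) > 0]
  if (length(groups) != 2L) stop("need exactly two platform groups")
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 estimates")
  tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE,
                      alternative = "two.sided")
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, sidedness = "two_sided",
                 degenerate = FALSE,
                 group_medians = vapply(groups, stats::median, numeric(1))),
            class = "switch_test")
}

#' @export
print.switch_test <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Degenerate test: all paired differences zero; no p-value\n")
    return(invisible(x))
  }
  cat(sprintf("t = %.3f, df = %g, %s p = %.4g\n", x$statistic, x$df,
              sub("_", "-", x$sidedness), x$p_value))
  g <- x$group_means %||% x$group_medians
  cat("  groups:", paste(names(g), signif(g, 4), sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}

# Per-marker (same-plate mean, other-plate mean) pairs over the column arm,
# for the contamination test.
contamination_pairs <- function(estimates, relexps, space) {
  w <- space$wells
  if (length(unique(w$plate)) < 2L) return(NULL)
  same <- other <- numeric(0)
  for (i in seq_len(nrow(estimates))) {
    src <- well_row(estimates$source[i], space)
    re <- relexps[[paste0(estimates$marker[i], "|", estimates$source[i])]]
    arm <- w[w$col_index == src$col_index & w$well != src$well & !w$is_control, ]
    sp <- re[arm$well[arm$plate == src$plate]]
    op <- re[arm$well[arm$plate != src$plate]]
    if (!length(sp) || !length(op)) next
    same <- c(same, mean(sp)); other <- c(other, mean(op))
  }
  list(same_plate = same, other_plate = other)
}
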