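# Source-well identification and marker curation.
#
# A well is called the source of a marker's spread if it (1) sits at the
# centre of a cross (the marker is detected elsewhere on its row or column),
# (2) expresses the marker at least five-fold higher than any other well on
# either arm, (3) hosts a cell of the matching type (T cell for TR markers,
# plasma cell for IG markers), and (4) carries this marker as its top
# same-family same-chain marker.  Markers are then filtered: too few
# detections, too many outside-cross detections, or more than two sources
# disqualify a marker from rate estimation.

#' Identify candidate source wells of a marker
#'
#' Evaluates the four source criteria for every well in which the marker is
#' detected and reports the per-criterion booleans.
#'
#' @inheritParams spread_profile
#' @param fivefold Dominance factor for criterion 2 (default 5); the
#'   comparison is non-strict (candidate TPM >= factor x arm maximum).
#' @return Data frame with one row per candidate well: \code{well},
#'   \code{tpm}, the four criterion columns \code{cross_center},
#'   \code{fivefold_dominance}, \code{cell_type_match},
#'   \code{top_marker_in_well}, and \code{is_source} (all four true).
#' @export
identify_sources <- function(marker, table, space, floor = 0, fivefold = 5) {
  x <- marker_tpm(marker, table)
  w <- space$wells
  x <- x[!w$is_control[match(names(x), w$well)]]
  det <- names(x)[x > floor]
  mk <- table$markers[table$markers$raw_id == marker, ]
  fam_ok_type <- if (mk$receptor_family == "TR") "T" else "P"
  same <- table$markers$raw_id[table$markers$receptor_family == mk$receptor_family &
                               table$markers$chain == mk$chain]
  wi <- w[match(names(x), w$well), ]  # geometry of the non-control wells
  n <- length(det)
  c1 <- c2 <- c3 <- c4 <- logical(n)
  top_same <- apply(table$tpm[same, det, drop = FALSE], 2, max)
  for (i in seq_len(n)) {
    k <- match(det[i], names(x))
    on_arm <- (wi$row_index == wi$row_index[k] | wi$col_index == wi$col_index[k])
    on_arm[k] <- FALSE
    arm_tpm <- x[on_arm]
    c1[i] <- any(arm_tpm > floor)
    c2[i] <- x[k] >= fivefold * max(arm_tpm, 0)
    c3[i] <- wi$cell_type[k] == fam_ok_type
    c4[i] <- x[k] >= top_same[i]
  }
  out <- data.frame(well = det, tpm = unname(x[det]),
                    cross_center = c1, fivefold_dominance = c2,
                    cell_type_match = c3, top_marker_in_well = c4,
                    stringsAsFactors = FALSE)
  out$is_source <- out$cross_center & out$fivefold_dominance &
    out$cell_type_match & out$top_marker_in_well
  out
}

#' Filter markers for rate estimation
#'
#' Applies the three rejection rules to candidate markers: detected in fewer
#' than three wells (\code{too_few_wells}), detected in more than three
#' outside-cross wells (\code{too_many_outside}), or more than two source
#' wells in the batch (\code{too_many_sources}).  Markers passing all three
#' but without any well meeting the four source criteria are rejected as
#' \code{no_source}, since a rate estimate needs an identified source.  The
#' rules are order-independent.
#'
#' @param candidates Named list, one entry per marker, each a list with
#'   \code{n_detected} (integer), \code{n_outside} (outside-cross detections)
#'   and \code{sources} (character vector of source wells).
#' @return List of class \code{curated_markers} with data frames
#'   \code{accepted} (marker, sources, n_sources) and \code{rejected}
#'   (marker, reason).
#' @export
filter_markers <- function(candidates) {
  acc <- list(); rej <- list()
  for (m in names(candidates)) {
    cand <- candidates[[m]]
    reason <- NULL
    if (cand$n_detected < 3L) reason <- "too_few_wells"
    else if (cand$n_outside > 3L) reason <- "too_many_outside"
    else if (length(cand$sources) > 2L) reason <- "too_many_sources"
    else if (length(cand$sources) == 0L) reason <- "no_source"
    if (is.null(reason)) {
      acc[[length(acc) + 1L]] <- data.frame(
        marker = m, sources = paste(sort(cand$sources), collapse = ","),
        n_sources = length(cand$sources), stringsAsFactors = FALSE)
    } else {
      rej[[length(rej) + 1L]] <- data.frame(marker = m, reason = reason,
                                            stringsAsFactors = FALSE)
    }
  }
  empty_acc <- data.frame(marker = character(0), sources = character(0),
                          n_sources = integer(0))
  empty_rej <- data.frame(marker = character(0), reason = character(0))
  structure(list(accepted = if (length(acc)) do.call(rbind, acc) else empty_acc,
                 rejected = if (length(rej)) do.call(rbind, rej) else empty_rej),
            class = "curated_markers")
}

#' Choose between V-gene and full-length receptor markers
#'
#' V gene segments are preferred as markers because they are more readily
#' detected, but a V gene shared by several receptors (or by a clone present
#' twice) spreads signal from multiple cells at once.  For each V gene with
#' both marker levels available: keep the V-gene marker unless it is detected
#' in more than one well outside its cross or has more than two identified
#' source wells, in which case every full-length receptor using that V gene
#' substitutes for it.
#'
#' @param v_profiles Named list of \code{\link{spread_profile}}s for V-gene
#'   markers.
#' @param receptor_of_v Named list mapping each V gene to the character
#'   vector of full-length receptor markers using it.
#' @param v_sources Named list mapping each V-gene marker to its source wells
#'   (character vectors, as from \code{\link{identify_sources}}).
#' @return Data frame: \code{v_gene}, \code{level} (\code{"V_GENE"} or
#'   \code{"FULL_RECEPTOR"}), \code{n_outside}, \code{n_sources},
#'   \code{substitutes} (comma-joined receptor markers when substituted).
#' @export
choose_marker_level <- function(v_profiles, receptor_of_v, v_sources) {
  rows <- lapply(names(v_profiles), function(v) {
    p <- v_profiles[[v]]
    n_out <- length(p$detected_outside)
    n_src <- length(v_sources[[v]] %||% character(0))
    substitute <- n_out > 1L || n_src > 2L
    data.frame(v_gene = v,
               level = if (substitute) "FULL_RECEPTOR" else "V_GENE",
               n_outside = n_out, n_sources = n_src,
               substitutes = if (substitute)
                 paste(receptor_of_v[[v]] %||% character(0), collapse = ",")
               else "",
               stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows)
  else data.frame(v_gene = character(0), level = character(0),
                  n_outside = integer(0), n_sources = integer(0),
                  substitutes = character(0))
}

#' Curate all markers of a batch
#'
#' End-to-end curation: profiles every marker, identifies sources, applies
#' the marker-level choice where both V-gene and full-length markers exist
#' for a V gene, applies the three rejection filters, and (by default)
#' excludes IG/BCR markers from the accepted estimation set because their
#' extreme expression makes assemblies from index-switched reads likely.
#'
#' @inheritParams identify_sources
#' @param clonal_threshold Passed to \code{\link{spread_profile}}.
#' @param include_bcr Keep IG-family markers in the accepted set (default
#'   \code{FALSE}).
#' @return List of class \code{curation} with the accepted/rejected frames,
#'   per-marker source calls, level decisions, spread profiles and the
#'   low-evidence report.
#' @export
curate_markers <- function(table, space, floor = 0, fivefold = 5,
                           clonal_threshold = 0.1, include_bcr = FALSE) {
  bp <- batch_profiles(table, space, floor, clonal_threshold)
  profiles <- bp$profiles

  source_calls <- lapply(names(profiles), function(m)
    identify_sources(m, table, space, floor, fivefold))
  names(source_calls) <- names(profiles)
  sources <- lapply(source_calls, function(df) df$well[df$is_source])

  # marker-level choice per V gene having both levels profiled
  mk <- table$markers
  v_named <- intersect(names(profiles), mk$raw_id[mk$marker_class == "V_GENE"])
  recs <- mk[mk$marker_class == "FULL_RECEPTOR", ]
  receptor_of_v <- split(recs$raw_id, recs$v_gene)
  v_both <- v_named[v_named %in% names(receptor_of_v)]
  levels <- choose_marker_level(profiles[v_both], receptor_of_v[v_both],
                                sources[v_both])
  drop <- character(0)
  if (nrow(levels)) {
    for (i in seq_len(nrow(levels))) {
      if (levels$level[i] == "FULL_RECEPTOR")
        drop <- c(drop, levels$v_gene[i])            # V gene replaced
      else
        drop <- c(drop, receptor_of_v[[levels$v_gene[i]]])  # receptors folded in
    }
  }
  use <- setdiff(names(profiles), drop)

  candidates <- lapply(use, function(m) {
    p <- profiles[[m]]
    list(n_detected = 1L + length(p$detected_within) + length(p$detected_outside),
         n_outside = length(p$detected_outside),
         sources = sources[[m]])
  })
  names(candidates) <- use
  cur <- filter_markers(candidates)

  if (!include_bcr && nrow(cur$accepted)) {
    fam <- mk$receptor_family[match(cur$accepted$marker, mk$raw_id)]
    bcr <- cur$accepted[fam == "IG", , drop = FALSE]
    cur$accepted <- cur$accepted[fam == "TR", , drop = FALSE]
    if (nrow(bcr))
      cur$rejected <- rbind(cur$rejected,
                            data.frame(marker = bcr$marker, reason = "bcr_excluded",
                                       stringsAsFactors = FALSE))
  }
  structure(list(accepted = cur$accepted, rejected = cur$rejected,
                 source_calls = source_calls, levels = levels,
                 profiles = profiles, low_evidence = bp$low_evidence),
            class = "curation")
}

#' @export
print.curation <- function(x, ...) {
  cat("Marker curation: ", nrow(x$accepted), " accepted, ",
      nrow(x$rejected), " rejected, ", nrow(x$low_evidence),
      " low-evidence\n", sep = "")
  if (nrow(x$rejected)) {
    tab <- table(x$rejected$reason)
    cat("  rejections:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
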