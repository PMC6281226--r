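# Plate / batch geometry: dual-index well spaces and cross patterns.
#
# A "batch" is the set of plates pooled on one sequencing lane and sharing an
# index space.  Every well is identified by a (row index, column index) pair;
# within a batch the pairs are in bijection with physical wells.  In two-plate
# batches the plates share the column indices and use disjoint row indices, so
# the combined space is a 16 x 12 virtual grid stacked from two 8 x 12 plates.

CELL_TYPE_CODES <- c("T" = "T", "P" = "P", "0" = "empty",
                     "50" = "multi_cell_control", "X" = "unknown")

#' Build a batch well space from a layout description
#'
#' Constructs the virtual grid of all (row index, column index) combinations
#' used on one sequencing lane and maps each combination to a physical well
#' with its annotation.  Index switching moves reads between wells of this
#' space, so all cross-pattern geometry is defined on it.
#'
#' @param config A list describing one batch:
#'   \describe{
#'     \item{batch_id}{character scalar.}
#'     \item{platform}{one of \code{"HiSeq3000"}, \code{"HiSeq4000"},
#'       \code{"other"}.}
#'     \item{column_indices}{character vector of column index labels, shared
#'       by every plate of the batch.}
#'     \item{plates}{list of plates, each a list with \code{plate_id},
#'       \code{row_indices} (disjoint across plates) and \code{cell_types},
#'       a character vector with one whitespace-separated string per row
#'       using the codes \code{T} (T cell), \code{P} (plasma cell), \code{0}
#'       (empty), \code{50} (multi-cell control), \code{X} (unknown).}
#'     \item{control_wells}{optional character vector of well labels to flag
#'       as controls in addition to every \code{50}-coded well.}
#'     \item{exclude_wells}{optional character vector of failed wells to drop
#'       from analysis (treated like controls for partitioning).}
#'   }
#' @return An object of class \code{batch_space}: the ordered index labels,
#'   and a \code{wells} data frame with one row per (row index, column index)
#'   combination giving plate, display coordinates, indices, cell type and
#'   control flag.
#' @examples
#' space <- build_batch_space(example_layout_config())
#' nrow(space$wells)  # 192 wells for a two-plate batch
#' @export
build_batch_space <- function(config) {
  stopifnot(is.list(config))
  batch_id <- as.character(config$batch_id %||% "batch")
  platform <- match.arg(config$platform %||% "other",
                        c("HiSeq3000", "HiSeq4000", "other"))
  col_indices <- as.character(config$column_indices)
  if (length(col_indices) == 0L || anyNA(col_indices) || any(!nzchar(col_indices)))
    stop("column_indices must be non-empty strings")
  if (anyDuplicated(col_indices))
    stop("duplicate column index label in batch '", batch_id, "'")
  plates <- config$plates
  if (length(plates) == 0L) stop("layout must list at least one plate")

  all_rows <- list()
  row_indices <- character(0)
  for (p in seq_along(plates)) {
    pl <- plates[[p]]
    plate_id <- as.character(pl$plate_id %||% paste0("Plate", p))
    ri <- as.character(pl$row_indices)
    if (length(ri) == 0L || any(!nzchar(ri)))
      stop("plate '", plate_id, "' has empty row index labels")
    if (any(ri %in% row_indices))
      stop("row index label reused across plates in batch '", batch_id,
           "': ", paste(intersect(ri, row_indices), collapse = ", "))
    if (anyDuplicated(ri))
      stop("duplicate row index label within plate '", plate_id, "'")
    row_indices <- c(row_indices, ri)
    row_labels <- LETTERS[seq_along(ri)]
    star <- if (p > 1L) "*" else ""
    ct <- pl$cell_types
    if (is.null(ct)) ct <- rep(paste(rep("X", length(col_indices)), collapse = " "),
                               length(ri))
    if (length(ct) != length(ri))
      stop("plate '", plate_id, "': need one cell-type row string per row")
    for (r in seq_along(ri)) {
      codes <- strsplit(trimws(ct[[r]]), "[[:space:]]+")[[1]]
      if (length(codes) != length(col_indices))
        stop("plate '", plate_id, "' row ", row_labels[r], ": expected ",
             length(col_indices), " cell-type codes, got ", length(codes))
      bad <- setdiff(codes, names(CELL_TYPE_CODES))
      if (length(bad))
        stop("unknown cell-type code(s): ", paste(unique(bad), collapse = ", "))
      all_rows[[length(all_rows) + 1L]] <- data.frame(
        plate = plate_id,
        row_label = row_labels[r],
        row_disp = paste0(row_labels[r], star),
        col = seq_along(col_indices),
        row_index = ri[r],
        col_index = col_indices,
        cell_type = unname(CELL_TYPE_CODES[codes]),
        stringsAsFactors = FALSE)
    }
  }
  wells <- do.call(rbind, all_rows)
  wells$well <- paste0(wells$plate, ":", wells$row_label, wells$col)
  if (anyDuplicated(wells$well))
    stop("well coordinate collision in batch '", batch_id, "'")
  if (anyDuplicated(paste(wells$row_index, wells$col_index)))
    stop("index-pair collision in batch '", batch_id, "'")

  wells$is_control <- wells$cell_type == "multi_cell_control"
  space <- structure(
    list(batch_id = batch_id, platform = platform,
         row_indices = row_indices, col_indices = col_indices,
         wells = wells[, c("well", "plate", "row_label", "row_disp", "col",
                           "row_index", "col_index", "cell_type", "is_control")]),
    class = "batch_space")
  extra <- as.character(config$control_wells %||% character(0))
  excl <- as.character(config$exclude_wells %||% character(0))
  for (w in c(extra, excl)) {
    i <- match(resolve_well(w, space), space$wells$well)
    space$wells$is_control[i] <- TRUE
  }
  space
}

#' Read a multi-batch plate layout from a YAML file
#'
#' The file has a top-level \code{batches} list; each entry follows the schema
#' of \code{\link{build_batch_space}}.  A checked example ships with the
#' package (\code{system.file("extdata", "example_layout.yaml", package =
#' "crossbleed")}).
#'
#' @param path Path to the YAML layout file.
#' @return Named list of \code{batch_space} objects, one per batch.
#' @export
read_layout <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$batches)) stop("layout file has no 'batches' key: ", path)
  spaces <- lapply(cfg$batches, build_batch_space)
  names(spaces) <- vapply(spaces, function(s) s$batch_id, character(1))
  spaces
}

# Resolve a well label to canonical "plate:RowCol" form.  Accepts the
# canonical form and the display dialect "D5" / "D*5" (star marks the second
# plate of a two-plate batch).
resolve_well <- function(label, space) {
  label <- as.character(label)
  out <- character(length(label))
  for (i in seq_along(label)) {
    lab <- label[i]
    if (lab %in% space$wells$well) { out[i] <- lab; next }
    m <- regmatches(lab, regexec("^([A-Za-z0-9_.-]+):([A-H])([0-9]+)$", lab))[[1]]
    if (length(m) == 4L) {
      w <- paste0(m[2], ":", m[3], as.integer(m[4]))
      if (!w %in% space$wells$well)
        stop("unknown well label '", lab, "' in batch '", space$batch_id, "'")
      out[i] <- w
      next
    }
    m <- regmatches(lab, regexec("^([A-H])(\\*?)([0-9]+)$", lab))[[1]]
    if (length(m) == 4L) {
      hit <- space$wells$well[space$wells$row_disp == paste0(m[2], m[3]) &
                              space$wells$col == as.integer(m[4])]
      if (length(hit) == 1L) { out[i] <- hit; next }
    }
    stop("unknown well label '", lab, "' in batch '", space$batch_id, "'")
  }
  out
}

well_row <- function(well, space) {
  i <- match(well, space$wells$well)
  if (anyNA(i)) stop("well not in batch space: ",
                     paste(well[is.na(i)], collapse = ", "))
  space$wells[i, , drop = FALSE]
}

#' Wells sharing an index with an origin well (the cross pattern)
#'
#' A single-index switch relocates a read to a well sharing the origin's row
#' index or column index; the union of those wells is the origin's "cross".
#' The column arm (shared column index) spans all plates of the batch, while
#' the row arm stays on the origin's plate because row indices are
#' plate-specific.  Control wells are never part of the cross.
#'
#' @param origin Well label (canonical or display dialect).
#' @param space A \code{batch_space}.
#' @return Character vector of well labels in the cross, origin excluded.
#' @examples
#' sp <- build_batch_space(example_layout_config())
#' length(cross_of("Plate4:D5", sp))  # 26 in a 16 x 12 space (A1 controls off-arm)
#' @export
cross_of <- function(origin, space) {
  o <- well_row(resolve_well(origin, space), space)
  if (o$is_control) stop("origin '", o$well, "' is a control well")
  w <- space$wells
  hit <- (w$row_index == o$row_index | w$col_index == o$col_index) &
    w$well != o$well & !w$is_control
  w$well[hit]
}

#' Wells outside an origin's cross pattern
#'
#' The non-control wells that share neither index with the origin.  Together
#' with \code{{origin}}, \code{\link{cross_of}} and the control wells these
#' partition the batch space.
#'
#' @inheritParams cross_of
#' @return Character vector of well labels.
#' @export
outside_cross <- function(origin, space) {
  o <- resolve_well(origin, space)
  cross <- cross_of(o, space)
  w <- space$wells
  setdiff(w$well[!w$is_control], c(o, cross))
}

#' @export
print.batch_space <- function(x, ...) {
  w <- x$wells
  cat("Batch well space '", x$batch_id, "' (", x$platform, ")\n", sep = "")
  cat("  ", length(x$row_indices), " row x ", length(x$col_indices),
      " column indices = ", nrow(w), " wells on ",
      length(unique(w$plate)), " plate(s)\n", sep = "")
  tab <- table(w$cell_type)
  cat("  cell types:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  control wells:", sum(w$is_control), "\n")
  invisible(x)
}

#' A ready-made two-plate layout configuration
#'
#' Returns the layout description of a typical two-plate batch: 16 row
#' indices split over two 8 x 12 plates bound by 12 shared column indices,
#' with the A1 well of each plate a multi-cell control.  Cell types other
#' than the controls default to unknown; the simulator overwrites them.
#'
#' @param batch_id,platform Batch identity fields.
#' @param plate_ids Character vector of 1 or 2 plate names.
#' @param n_rows,n_cols Plate dimensions (per plate).
#' @return A layout config list accepted by \code{\link{build_batch_space}}.
#' @export
example_layout_config <- function(batch_id = "Batch3", platform = "HiSeq4000",
                                  plate_ids = c("Plate4", "Plate5"),
                                  n_rows = 8, n_cols = 12) {
  stopifnot(length(plate_ids) %in% 1:2, n_rows <= 8)
  row_of <- function(codes) paste(codes, collapse = " ")
  plates <- lapply(seq_along(plate_ids), function(p) {
    ct <- matrix("X", n_rows, n_cols)
    ct[1, 1] <- "50"  # A1 multi-cell control
    list(plate_id = plate_ids[p],
         row_indices = sprintf("R%02d", (p - 1L) * n_rows + seq_len(n_rows)),
         cell_types = apply(ct, 1, row_of))
  })
  list(batch_id = batch_id, platform = platform,
       column_indices = sprintf("C%02d", seq_len(n_cols)),
       plates = plates)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Serialize a batch_space back into a layout config (inverse of
# build_batch_space up to display details); used to persist simulated
# layouts with their realized cell-type annotations.
space_to_config <- function(space) {
  w <- space$wells
  inv <- stats::setNames(names(CELL_TYPE_CODES), CELL_TYPE_CODES)
  plates <- lapply(unique(w$plate), function(p) {
    pw <- w[w$plate == p, ]
    rows <- unique(pw$row_index)
    ct <- vapply(rows, function(r) {
      pr <- pw[pw$row_index == r, ]
      paste(inv[pr$cell_type[order(pr$col)]], collapse = " ")
    }, character(1))
    list(plate_id = p, row_indices = as.list(rows),
         cell_types = as.list(unname(ct)))
  })
  extra <- w$well[w$is_control & w$cell_type != "multi_cell_control"]
  cfg <- list(batch_id = space$batch_id, platform = space$platform,
              column_indices = as.list(space$col_indices), plates = plates)
  if (length(extra)) cfg$control_wells <- as.list(extra)
  cfg
}
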