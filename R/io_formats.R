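# Marker identifiers and external tables.
#
# Markers follow the V_junction_J naming convention of single-cell receptor
# assemblers: either a bare V gene segment ("TRBV5-6") or a full-length
# receptor "V_junction_J" ("TRBV11-3_CTTAGTAGGGAACATGAAC_TRBJ1-1").  The V
# gene prefix determines receptor family (TR vs IG) and chain.

CHAIN_OF_PREFIX <- c(TRAV = "alpha", TRBV = "beta", TRGV = "unknown",
                     TRDV = "unknown", IGHV = "heavy", IGKV = "kappa",
                     IGLV = "lambda")

#' Parse receptor marker identifiers
#'
#' Splits marker tokens into their V gene, junction and J gene parts and
#' classifies each as a bare V-gene segment or a full-length receptor, with
#' receptor family (TR/IG) and chain inferred from the V gene prefix.
#'
#' @param raw Character vector of marker tokens.
#' @return Data frame with columns \code{raw_id}, \code{marker_class}
#'   (\code{"V_GENE"} or \code{"FULL_RECEPTOR"}), \code{receptor_family}
#'   (\code{"TR"}/\code{"IG"}), \code{chain}, \code{v_gene}, \code{junction},
#'   \code{j_gene} (the last two \code{NA} for bare V genes).
#' @examples
#' parse_marker_id("TRBV11-3_CTTAGTAGGGAACATGAAC_TRBJ1-1")
#' parse_marker_id("TRBV5-6")
#' @export
parse_marker_id <- function(raw) {
  raw <- as.character(raw)
  if (length(raw) == 0L)
    return(data.frame(raw_id = character(0), marker_class = character(0),
                      receptor_family = character(0), chain = character(0),
                      v_gene = character(0), junction = character(0),
                      j_gene = character(0), stringsAsFactors = FALSE))
  if (anyNA(raw) || any(!nzchar(raw))) stop("empty marker token")
  v_re <- "(TRAV|TRBV|TRGV|TRDV|IGHV|IGKV|IGLV)[A-Za-z0-9./-]*"
  full_re <- paste0("^(", v_re, ")_([ACGTN]+)_([A-Za-z0-9./-]+)$")
  vonly_re <- paste0("^", v_re, "$")
  out <- lapply(raw, function(tok) {
    m <- regmatches(tok, regexec(full_re, tok))[[1]]
    if (length(m) == 5L)
      return(list(class = "FULL_RECEPTOR", v = m[2], junction = m[4], j = m[5]))
    if (grepl(vonly_re, tok))
      return(list(class = "V_GENE", v = tok, junction = NA_character_,
                  j = NA_character_))
    stop("unparseable marker token: '", tok, "'")
  })
  v <- vapply(out, `[[`, character(1), "v")
  prefix <- substr(v, 1, 4)
  data.frame(
    raw_id = raw,
    marker_class = vapply(out, `[[`, character(1), "class"),
    receptor_family = ifelse(startsWith(prefix, "TR"), "TR", "IG"),
    chain = unname(CHAIN_OF_PREFIX[prefix]),
    v_gene = v,
    junction = vapply(out, `[[`, character(1), "junction"),
    j_gene = vapply(out, `[[`, character(1), "j"),
    stringsAsFactors = FALSE)
}

#' Construct a marker expression table
#'
#' @param tpm Numeric matrix of TPM values, markers in rows (rownames are
#'   marker tokens), wells in columns (colnames are well labels of
#'   \code{space}; the display dialect \code{"D*5"} is accepted).
#' @param space The \code{batch_space} the wells belong to.
#' @return Object of class \code{marker_table}: the batch id, the parsed
#'   marker identities, and a markers x wells TPM matrix whose columns cover
#'   every well of the space (wells absent from the input are zero-filled).
#' @export
marker_table <- function(tpm, space) {
  stopifnot(is.matrix(tpm))
  if (nrow(tpm) > 0 && is.null(rownames(tpm)))
    stop("tpm matrix needs marker rownames")
  if (anyDuplicated(rownames(tpm)))
    stop("duplicate marker rows: ",
         paste(unique(rownames(tpm)[duplicated(rownames(tpm))]), collapse = ", "))
  storage.mode(tpm) <- "double"
  tpm[is.na(tpm)] <- 0
  if (any(tpm < 0)) stop("negative TPM values")
  colnames(tpm) <- resolve_well(colnames(tpm), space)
  full <- matrix(0, nrow(tpm), nrow(space$wells),
                 dimnames = list(rownames(tpm), space$wells$well))
  full[, colnames(tpm)] <- tpm
  structure(list(batch_id = space$batch_id,
                 markers = parse_marker_id(rownames(tpm)),
                 tpm = full),
            class = "marker_table")
}

#' @export
print.marker_table <- function(x, ...) {
  cat("Marker table for batch '", x$batch_id, "': ", nrow(x$tpm),
      " markers x ", ncol(x$tpm), " wells\n", sep = "")
  tab <- table(x$markers$marker_class)
  if (length(tab)) cat("  ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a markers-by-wells expression matrix
#'
#' Tab-separated file: first column the marker token, remaining columns TPM
#' values under well-label headers (\code{"Plate4:D5"} canonical or
#' \code{"D*5"} display dialect).  Missing cells read as 0.
#'
#' @param path File path.
#' @param space The \code{batch_space} whose wells the columns reference.
#' @return A \code{\link{marker_table}}.
#' @export
read_expression_matrix <- function(path, space) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop("empty expression file: ", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) && !is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- ids
  marker_table(m, space)
}

#' Write a marker table as a canonical TSV
#'
#' Columns are the wells of the batch space in layout order, labels in
#' canonical \code{plate:rowcol} form; values are formatted with 6
#' significant digits so that write-read round-trips are exact.
#'
#' @param table A \code{marker_table}.
#' @param path Output path.
#' @export
write_expression_matrix <- function(table, path) {
  m <- table$tpm
  df <- data.frame(marker = rownames(m),
                   signif(m, 6), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a marker table from per-well Kallisto abundance files
#'
#' Each abundance file is the standard 5-column Kallisto output
#' (\code{target_id length eff_length est_counts tpm}).  Rows whose
#' \code{target_id} is not parseable as a receptor marker are skipped (their
#' count is reported via \code{message}); target ids collapsing to the same
#' marker identity (e.g. alleles of one V gene) have their TPM summed.
#'
#' @param files Named character vector: names are well labels of
#'   \code{space}, values are abundance file paths.
#' @param space The batch's \code{batch_space}.
#' @return A \code{\link{marker_table}}.
#' @export
read_kallisto_abundance <- function(files, space) {
  if (is.null(names(files)) || any(!nzchar(names(files))))
    stop("'files' must be a named vector mapping well label -> path")
  wells <- resolve_well(names(files), space)
  acc <- list()  # marker -> named numeric per well
  n_skipped <- 0L
  for (i in seq_along(files)) {
    ab <- utils::read.delim(files[[i]], stringsAsFactors = FALSE)
    if (!all(c("target_id", "tpm") %in% names(ab)))
      stop("not a Kallisto abundance file (need target_id and tpm columns): ",
           files[[i]])
    ok <- vapply(ab$target_id, function(t)
      !inherits(try(parse_marker_id(t), silent = TRUE), "try-error"),
      logical(1))
    n_skipped <- n_skipped + sum(!ok)
    ab <- ab[ok, , drop = FALSE]
    if (!nrow(ab)) next
    agg <- tapply(ab$tpm, ab$target_id, sum)
    for (id in names(agg)) {
      if (is.null(acc[[id]])) acc[[id]] <- numeric(0)
      acc[[id]][wells[i]] <- agg[[id]]
    }
  }
  if (n_skipped) message(n_skipped, " non-marker target_id rows skipped")
  ids <- sort(names(acc))
  m <- matrix(0, length(ids), length(wells), dimnames = list(ids, wells))
  for (id in ids) m[id, names(acc[[id]])] <- acc[[id]]
  marker_table(m, space)
}

#' Collapse full-length receptor markers to V-gene level
#'
#' Sums TPM over all full-length receptors sharing a V gene, emulating
#' pseudoalignment quantification of the V segments themselves.  Useful for
#' exercising the V-gene vs full-length marker level choice on data that only
#' carries receptor-level markers.
#'
#' @param table A \code{marker_table}.
#' @return A \code{marker_table} containing both the original markers and one
#'   added \code{V_GENE} row per V gene (only where not already present).
#' @export
aggregate_v_genes <- function(table) {
  mk <- table$markers
  fr <- mk$marker_class == "FULL_RECEPTOR"
  vg <- unique(mk$v_gene[fr])
  vg <- setdiff(vg, mk$raw_id)  # don't duplicate existing V-gene rows
  if (!length(vg)) return(table)
  add <- t(vapply(vg, function(v)
    colSums(table$tpm[mk$raw_id[fr & mk$v_gene == v], , drop = FALSE]),
    numeric(ncol(table$tpm))))
  out <- rbind(table$tpm, add)
  tb <- table
  tb$tpm <- out
  tb$markers <- parse_marker_id(rownames(out))
  tb
}
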