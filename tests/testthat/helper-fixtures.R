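# In-code fixture builders shared across the test files.

# A layout config for one or two plates with a uniform cell-type grid.
# cell_codes: single code for every well, or a list of per-plate character
# matrices (n_rows x n_cols of codes).  control_a1 marks A1 wells "50".
mini_config <- function(batch_id = "B", platform = "other", n_plates = 1,
                        n_rows = 8, n_cols = 12, cell_codes = "T",
                        control_a1 = FALSE) {
  plates <- lapply(seq_len(n_plates), function(p) {
    ct <- if (is.list(cell_codes)) cell_codes[[p]]
          else matrix(cell_codes, n_rows, n_cols)
    if (control_a1) ct[1, 1] <- "50"
    list(plate_id = paste0("P", p),
         row_indices = sprintf("R%02d", (p - 1L) * n_rows + seq_len(n_rows)),
         cell_types = apply(ct, 1, paste, collapse = " "))
  })
  list(batch_id = batch_id, platform = platform,
       column_indices = sprintf("C%02d", seq_len(n_cols)), plates = plates)
}

mini_space <- function(...) build_batch_space(mini_config(...))

# marker_table from (marker, well, tpm) triples; all other cells 0.
tab_from_triples <- function(space, triples) {
  ids <- unique(triples$marker)
  m <- matrix(0, length(ids), nrow(space$wells),
              dimnames = list(ids, space$wells$well))
  for (i in seq_len(nrow(triples)))
    m[triples$marker[i], resolve_label(triples$well[i], space)] <-
      m[triples$marker[i], resolve_label(triples$well[i], space)] + triples$tpm[i]
  marker_table(m, space)
}

resolve_label <- function(lab, space) {
  vapply(lab, function(l) {
    if (l %in% space$wells$well) return(l)
    # accept bare "D5" on single-plate helpers
    space$wells$well[paste0(space$wells$row_label, space$wells$col) == l &
                       space$wells$plate == space$wells$plate[1]][1]
  }, character(1), USE.NAMES = FALSE)
}

tr_id <- function(n = 1) sprintf("TRBV%d-1_%s_TRBJ1-%d", seq_len(n) + 4,
                                 strrep("ACGT", 4), (seq_len(n) - 1) %% 6 + 1)
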