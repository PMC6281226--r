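test_that("source criteria pass and fail on the textbook cases", {
  sp <- mini_space()                       # all T cells
  id <- tr_id()
  tab <- tab_from_triples(sp, data.frame(
    marker = id, well = c("D5", "D6", "E5"), tpm = c(9000, 300, 100)))
  calls <- identify_sources(id, tab, sp)
  d5 <- calls[calls$well == resolve_label("D5", sp), ]
  expect_true(d5$cross_center)
  expect_true(d5$fivefold_dominance)       # 9000 >= 5 * 300
  expect_true(d5$is_source)
  d6 <- calls[calls$well == resolve_label("D6", sp), ]
  expect_false(d6$fivefold_dominance)      # D5 sits on D6's row arm
  expect_false(d6$is_source)

  # a fourfold-dominant candidate fails criterion 2
  weak <- tab_from_triples(sp, data.frame(
    marker = id, well = c("D5", "D6"), tpm = c(1200, 300)))
  wc <- identify_sources(id, weak, sp)
  expect_false(wc$fivefold_dominance[wc$well == resolve_label("D5", sp)])
})

test_that("a plasma-cell well never sources a TR marker", {
  ct <- matrix("T", 8, 12); ct[4, 5] <- "P"   # D5 holds a plasma cell
  sp <- build_batch_space(mini_config(cell_codes = list(ct)))
  id <- tr_id()
  tab <- tab_from_triples(sp, data.frame(
    marker = id, well = c("D5", "D6"), tpm = c(9000, 100)))
  calls <- identify_sources(id, tab, sp)
  d5 <- calls[calls$well == resolve_label("D5", sp), ]
  expect_false(d5$cell_type_match)
  expect_false(d5$is_source)
  # the same geometry with an IG marker is a valid source
  igid <- "IGKV1-5_ACGTACGTACGT_IGKJ2"
  igtab <- tab_from_triples(sp, data.frame(
    marker = igid, well = c("D5", "D6"), tpm = c(9000, 100)))
  ig <- identify_sources(igid, igtab, sp)
  expect_true(ig$is_source[ig$well == resolve_label("D5", sp)])
})

test_that("two wells dominating their own crosses give two sources", {
  sp <- mini_space()
  id <- tr_id()
  tab <- tab_from_triples(sp, data.frame(
    marker = id,
    well = c("B2", "B3", "C2", "F7", "F8", "E7"),
    tpm = c(8000, 90, 80, 2000, 30, 25)))
  calls <- identify_sources(id, tab, sp)
  expect_setequal(calls$well[calls$is_source],
                  resolve_label(c("B2", "F7"), sp))
})

test_that("a cell's top marker wins criterion 4 per chain", {
  sp <- mini_space()
  beta1 <- "TRBV5-1_ACGTACGT_TRBJ1-1"
  beta2 <- "TRBV9-1_TTGGCCAA_TRBJ2-2"
  alpha <- "TRAV8-4_ACGTTGCA_TRAJ23"
  tab <- tab_from_triples(sp, data.frame(
    marker = c(beta1, beta1, beta2, beta2, alpha, alpha),
    well = c("D5", "D6", "D5", "D7", "D5", "D8"),
    tpm = c(9000, 100, 4000, 60, 800, 20)))
  # beta2 is not D5's top beta marker; the alpha ranks separately and passes
  c_beta2 <- identify_sources(beta2, tab, sp)
  expect_false(c_beta2$top_marker_in_well[c_beta2$well == resolve_label("D5", sp)])
  c_alpha <- identify_sources(alpha, tab, sp)
  expect_true(c_alpha$top_marker_in_well[c_alpha$well == resolve_label("D5", sp)])
  expect_true(c_alpha$is_source[c_alpha$well == resolve_label("D5", sp)])
})

test_that("the three rejection rules fire on their defining cases", {
  cand <- list(
    ok         = list(n_detected = 5L, n_outside = 1L, sources = "P1:B2"),
    few        = list(n_detected = 2L, n_outside = 0L, sources = "P1:B3"),
    outside    = list(n_detected = 8L, n_outside = 4L, sources = "P1:B4"),
    manysrc    = list(n_detected = 9L, n_outside = 0L,
                      sources = c("P1:B5", "P1:C5", "P1:D5")),
    clone      = list(n_detected = 7L, n_outside = 2L,
                      sources = c("P1:B6", "P1:E6")),
    sourceless = list(n_detected = 4L, n_outside = 0L, sources = character(0)))
  cur <- filter_markers(cand)
  expect_setequal(cur$accepted$marker, c("ok", "clone"))
  expect_equal(cur$accepted$n_sources[cur$accepted$marker == "clone"], 2L)
  rej <- setNames(cur$rejected$reason, cur$rejected$marker)
  expect_equal(rej[["few"]], "too_few_wells")
  expect_equal(rej[["outside"]], "too_many_outside")
  expect_equal(rej[["manysrc"]], "too_many_sources")
  expect_equal(rej[["sourceless"]], "no_source")
  # boundary: exactly 3 detected, exactly 3 outside, exactly 2 sources pass
  edge <- filter_markers(list(e = list(n_detected = 3L, n_outside = 3L,
                                       sources = c("a", "b"))))
  expect_equal(edge$accepted$marker, "e")
})

test_that("filtering is order-independent", {
  cand <- list(
    a = list(n_detected = 5L, n_outside = 1L, sources = "w1"),
    b = list(n_detected = 2L, n_outside = 0L, sources = "w2"),
    c = list(n_detected = 8L, n_outside = 4L, sources = "w3"),
    d = list(n_detected = 6L, n_outside = 0L, sources = c("w4", "w5", "w6")))
  r1 <- filter_markers(cand)
  r2 <- filter_markers(cand[c(3, 1, 4, 2)])
  sort_df <- function(d) d[order(d$marker), , drop = FALSE]
  expect_equal(sort_df(r1$accepted)$marker, sort_df(r2$accepted)$marker)
  expect_equal(sort_df(r1$rejected)[, c("marker", "reason")],
               sort_df(r2$rejected)[, c("marker", "reason")],
               ignore_attr = TRUE)
})

test_that("marker level prefers V genes unless they smear outside the cross", {
  clean <- structure(list(detected_outside = character(0)),
                     class = "spread_profile")
  dirty <- structure(list(detected_outside = c("w1", "w2")),
                     class = "spread_profile")
  dec <- choose_marker_level(
    list("TRBV5-6" = clean, "TRBV20-1" = dirty),
    list("TRBV5-6" = "TRBV5-6_AAAA_TRBJ1-1",
         "TRBV20-1" = c("TRBV20-1_CCCC_TRBJ1-1", "TRBV20-1_GGGG_TRBJ2-7")),
    list("TRBV5-6" = "P1:B2", "TRBV20-1" = "P1:E7"))
  expect_equal(dec$level[dec$v_gene == "TRBV5-6"], "V_GENE")
  expect_equal(dec$level[dec$v_gene == "TRBV20-1"], "FULL_RECEPTOR")
  expect_match(dec$substitutes[dec$v_gene == "TRBV20-1"], "TRBV20-1_CCCC")
  # three source wells also force substitution
  dec2 <- choose_marker_level(
    list(v = clean), list(v = "x"),
    list(v = c("w1", "w2", "w3")))
  expect_equal(dec2$level, "FULL_RECEPTOR")
})

test_that("a shared V gene is replaced by its receptors during curation", {
  sp <- mini_space()
  r1 <- "TRBV20-1_ACGTACGTACGTACGT_TRBJ1-1"
  r2 <- "TRBV20-1_TTGGCCAATTGGCCAA_TRBJ2-7"
  tab <- tab_from_triples(sp, data.frame(
    marker = c(r1, r1, r1, r2, r2, r2),
    well = c("B2", "B3", "C2", "E7", "E8", "F7"),
    tpm = c(8000, 90, 70, 6000, 80, 60)))
  agg <- aggregate_v_genes(tab)
  cur <- curate_markers(agg, sp)
  expect_setequal(cur$accepted$marker, c(r1, r2))
  expect_equal(cur$levels$level[cur$levels$v_gene == "TRBV20-1"],
               "FULL_RECEPTOR")
  # and when one receptor equals the whole V gene signal, the V gene is kept
  solo <- tab_from_triples(sp, data.frame(
    marker = c(r1, r1, r1), well = c("B2", "B3", "C2"),
    tpm = c(8000, 90, 70)))
  cur2 <- curate_markers(aggregate_v_genes(solo), sp)
  expect_equal(cur2$accepted$marker, "TRBV20-1")
})

test_that("curation of a fixed table is bit-for-bit reproducible", {
  b <- generate_batch(sim_params(n_t_cells = 30, n_plasma_cells = 10, seed = 17))
  c1 <- curate_markers(b$table, b$space)
  c2 <- curate_markers(b$table, b$space)
  expect_identical(c1$accepted, c2$accepted)
  expect_identical(c1$rejected, c2$rejected)
})

test_that("true sources are recovered on moderate-switching simulations", {
  hits <- 0L; total <- 0L; false_sources <- 0L
  for (seed in 1:2) {
    b <- generate_batch(sim_params(n_t_cells = 50, n_plasma_cells = 0,
                                   p_clone = 0, s_row = 0.03, s_col = 0.03,
                                   seed = seed))
    cur <- curate_markers(b$table, b$space)
    truth_src <- names(b$truth$marker_of_well)
    for (m in names(cur$source_calls)) {
      calls <- cur$source_calls[[m]]
      true_well <- names(b$truth$marker_of_well)[b$truth$marker_of_well == m]
      total <- total + 1L
      if (true_well %in% calls$well[calls$is_source]) hits <- hits + 1L
      false_sources <- false_sources +
        sum(!calls$well[calls$is_source] %in% true_well)
    }
  }
  expect_gte(hits / total, 0.95)
  expect_equal(false_sources, 0L)
})
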