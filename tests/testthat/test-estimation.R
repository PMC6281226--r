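test_that("dual-source allocation splits overlap proportionally and conserves TPM", {
  sp <- mini_space()
  id <- tr_id()
  s1 <- resolve_label("B2", sp); s2 <- resolve_label("E7", sp)
  overlap <- resolve_label("B7", sp)    # row of s1, column of s2
  tab <- tab_from_triples(sp, data.frame(
    marker = id,
    well = c("B2", "E7", "B7", "B3", "E8"),
    tpm = c(8000, 2000, 100, 40, 10)))
  alloc <- allocate_dual_source(id, c(s1, s2), tab, sp)
  expect_equal(unname(alloc[[s1]]$tpm[overlap]), 80)
  expect_equal(unname(alloc[[s2]]$tpm[overlap]), 20)
  # wells in exactly one cross attach wholly
  expect_equal(unname(alloc[[s1]]$tpm[resolve_label("B3", sp)]), 40)
  expect_equal(unname(alloc[[s2]]$tpm[resolve_label("B3", sp)]), 0)
  # conservation at every recipient well
  tot <- alloc[[s1]]$tpm + alloc[[s2]]$tpm
  x <- tab$tpm[id, names(tot)]
  recip <- setdiff(names(tot), c(s1, s2))
  expect_equal(tot[recip], x[recip])
  # relative expression is against each source's own level
  expect_equal(unname(alloc[[s1]]$relexp[overlap]), 80 / 8000)
  expect_equal(unname(alloc[[s2]]$relexp[overlap]), 20 / 2000)

  single <- allocate_dual_source(id, s1, tab, sp)
  expect_equal(unname(single[[s1]]$tpm[overlap]), 100)   # identity
  expect_error(allocate_dual_source(id, c(s1, s2, overlap), tab, sp),
               "more than two")
})

test_that("misassignment is the summed recipient relative expression by arm", {
  sp <- mini_space()
  src <- resolve_label("D5", sp)
  relexp <- setNames(numeric(nrow(sp$wells)), sp$wells$well)
  relexp[src] <- 1
  relexp[resolve_label("D6", sp)] <- 0.02     # row arm
  relexp[resolve_label("D9", sp)] <- 0.01     # row arm
  relexp[resolve_label("F5", sp)] <- 0.005    # column arm
  relexp[resolve_label("G8", sp)] <- 0.003    # outside
  est <- per_marker_misassignment("m", src, relexp, sp)
  expect_equal(est$sum_relexp_row_arm, 0.03)
  expect_equal(est$sum_relexp_col_arm, 0.005)
  expect_equal(est$misassigned_fraction, 0.035)
  expect_equal(est$sum_relexp_outside, 0.003)
})

test_that("misassignment is invariant to rescaling the marker", {
  sp <- mini_space()
  id <- tr_id()
  df <- data.frame(marker = id, well = c("D5", "D6", "F5"),
                   tpm = c(5000, 100, 50))
  for (k in c(1, 250)) {
    d <- df; d$tpm <- d$tpm * k
    tab <- tab_from_triples(sp, d)
    p <- spread_profile(id, resolve_label("D5", sp), tab, sp)
    est <- per_marker_misassignment(id, p$origin, p$relexp, sp)
    expect_equal(est$misassigned_fraction, 0.03)
  }
})

test_that("batch summaries use interpolated quantiles over markers and wells", {
  one <- data.frame(marker = "m", source = "w", batch_id = "b",
                    platform = "other", sum_relexp_row_arm = 0.04,
                    sum_relexp_col_arm = 0, misassigned_fraction = 0.04,
                    sum_relexp_outside = 0)
  s1 <- batch_summary(one)
  expect_equal(s1$overall$median, 0.04)
  expect_equal(s1$overall$q1, 0.04)
  expect_equal(s1$overall$q3, 0.04)

  four <- do.call(rbind, lapply(1:4, function(i) {
    d <- one; d$marker <- paste0("m", i); d$source <- paste0("w", i)
    d$misassigned_fraction <- i / 100; d
  }))
  s4 <- batch_summary(four)
  expect_equal(s4$overall$median, 0.025)
  expect_equal(s4$n_source_wells, 4)
  expect_error(batch_summary(four[0, ]), "no estimates")
})

test_that("index propensities are zero without switching and track weights", {
  b0 <- generate_batch(sim_params(n_t_cells = 25, n_plasma_cells = 0,
                                  p_clone = 0, s_row = 0, s_col = 0, seed = 2))
  f0 <- fit_switching(b0$table, b0$space)
  expect_true(all(f0$propensities$accumulated_relexp == 0))

  # one column index weighted 5x as a switch target dominates the propensities
  w <- setNames(rep(1, 12), sprintf("C%02d", 1:12)); w["C09"] <- 5
  bw <- generate_batch(sim_params(n_t_cells = 80, n_plasma_cells = 0,
                                  p_clone = 0, s_row = 0.02, s_col = 0.05,
                                  switch_weights_col = w, seed = 8))
  fw <- fit_switching(bw$table, bw$space)
  cols <- fw$propensities[fw$propensities$role == "column", ]
  expect_equal(cols$index[which.max(cols$propensity)], "C09")
})

test_that("propensities are homogeneous under uniform switching", {
  b <- generate_batch(sim_params(n_t_cells = 100, n_plasma_cells = 0,
                                 p_clone = 0, s_row = 0.03, s_col = 0.03,
                                 seed = 31))
  f <- fit_switching(b$table, b$space)
  pr <- f$propensities[f$propensities$role == "column", ]
  # rescale accumulated relexp to effective switch-event counts and test
  # goodness of fit against exposure-proportional expectation
  per_evt <- expected_spread(sim_params(s_col = 0.03))$per_recipient_row_arm
  counts <- pr$accumulated_relexp / per_evt
  p <- suppressWarnings(stats::chisq.test(counts,
                                          p = pr$n_exposures / sum(pr$n_exposures)))$p.value
  expect_gt(p, 0.01)
})

test_that("the paired contamination test matches the closed form", {
  # difference vector {0.01, 0.02, 0.03}: t = mean/ (sd/sqrt(3)) = 3.464
  res <- contamination_paired_test(c(0.02, 0.04, 0.06), c(0.01, 0.02, 0.03))
  expect_equal(res$statistic, 0.02 / (0.01 / sqrt(3)), tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, stats::pt(3.4641016, 2, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(res$sidedness, "one_sided")

  deg <- contamination_paired_test(c(0.01, 0.02), c(0.01, 0.02))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p_value))
  expect_error(contamination_paired_test(0.01, 0.02), "2 pairs")
})

test_that("contamination inflates the source-plate arm and the test sees it", {
  # pairs built from generator truth so the comparison is not entangled with
  # the outside-cross filter, which contamination trips by design
  pairs_from_truth <- function(rate, seed = 12) {
    b <- generate_batch(sim_params(n_t_cells = 60, n_plasma_cells = 0,
                                   p_clone = 0, s_row = 0.02, s_col = 0.02,
                                   contamination_rate = rate, seed = seed))
    w <- b$space$wells
    same <- other <- numeric(0)
    for (src in names(b$truth$marker_of_well)) {
      m <- b$truth$marker_of_well[[src]]
      tpm <- b$table$tpm[m, ]
      k <- match(src, w$well)
      arm <- w[w$col_index == w$col_index[k] & w$well != src & !w$is_control, ]
      same <- c(same, mean(tpm[arm$well[arm$plate == w$plate[k]]] / tpm[src]))
      other <- c(other, mean(tpm[arm$well[arm$plate != w$plate[k]]] / tpm[src]))
    }
    list(same = same, other = other)
  }
  p0 <- pairs_from_truth(0)
  pc <- pairs_from_truth(0.05)
  res <- contamination_paired_test(pc$same, pc$other)
  expect_lt(res$p_value, 0.01)
  expect_gt(mean(pc$same - pc$other), mean(p0$same - p0$other))
})

test_that("the platform comparison is two-sided Student's t with medians", {
  g <- list(a = c(0.01, 0.02, 0.03), b = c(0.01, 0.02, 0.03))
  res <- platform_compare(g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(unname(res$group_medians), c(0.02, 0.02))
  expect_error(platform_compare(list(a = 1:3 / 100)), "two platform")
  expect_error(platform_compare(list(a = 1:3 / 100, b = 0.01)), ">= 2")
  # clearly separated switching levels are detected
  b1 <- generate_batch(sim_params(n_t_cells = 40, n_plasma_cells = 0,
                                  p_clone = 0, s_row = 0.01, s_col = 0.01,
                                  layout = example_layout_config(
                                    "BA", "HiSeq3000", c("p1", "p2")),
                                  seed = 4))
  b2 <- generate_batch(sim_params(n_t_cells = 40, n_plasma_cells = 0,
                                  p_clone = 0, s_row = 0.04, s_col = 0.04,
                                  layout = example_layout_config(
                                    "BB", "HiSeq4000", c("p3", "p4")),
                                  seed = 5))
  est <- rbind(fit_switching(b1$table, b1$space)$estimates,
               fit_switching(b2$table, b2$space)$estimates)
  res2 <- platform_compare(est)
  expect_lt(res2$p_value, 0.001)
  expect_lt(res2$group_medians[["HiSeq3000"]],
            res2$group_medians[["HiSeq4000"]])
})
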