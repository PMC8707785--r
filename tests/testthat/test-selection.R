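test_that("the grid flags a planted responder at high doses and gates on elevation", {
  cfg <- small_config(seed = 5, n_donors = 10,
                      responses = dose_response_spec("zymosan", "IL-8",
                                                     emax_log = 4,
                                                     ec50 = 3.2e5))
  means <- average_replicates(apply_censoring(generate_study(cfg)$study))
  g <- significance_grid(means, mode = "paired")
  il8 <- g[g$stimulus == "zymosan" & g$cytokine == "IL-8", ]
  il8 <- il8[order(il8$dose_rank), ]
  expect_true(all(il8$significant[3:4]))   # two top doses
  # grid is complete over design x panel
  expect_equal(nrow(g), 3 * 4 * 6)
  # alpha = 0 admits nothing
  g0 <- significance_grid(means, alpha = 0, mode = "paired")
  expect_false(any(g0$significant))
})

test_that("suppressed cytokines are never called significant", {
  panel <- cytokine_panel(c("IL-6", "IL-8"))
  rec <- do.call(rbind, lapply(1:8, function(i) {
    data.frame(donor = sprintf("D%d", i), cohort = "fresh",
               stimulus = c("NC", "zymosan"), concentration = c(0, 1e4),
               co_exposure = "", role = c("negative_control", "treatment"),
               cytokine = "IL-8", replicate = 0,
               value = c(100 + i, 10 + i),  # strong suppression
               censor = "none", stringsAsFactors = FALSE)
  }))
  des <- iirmi_design(); des <- des[des$stimulus == "zymosan", ]
  st <- study_table(rec, des, data.frame(), panel)
  g <- significance_grid(average_replicates(st), mode = "paired")
  cell <- g[g$cytokine == "IL-8" & g$dose_rank == 1, ]
  expect_lt(cell$p, 0.05)
  expect_false(cell$elevated)
  expect_false(cell$significant)
})

test_that("signature selection picks the lowest qualifying dose and min p, with panel-order ties", {
  panel <- default_cytokine_panel()
  # a grid shaped like a realistic zymosan outcome:
  # at the lowest dose MIP-1a wins at p = 0.001 with 13 co-induced cytokines
  others <- setdiff(panel$name, c("MIP-1a", "IL-2", "IL-17"))
  cells <- c(
    lapply(others, function(k)
      grid_cell("zymosan", 1, 1e4, k, p = 0.01)),
    list(grid_cell("zymosan", 1, 1e4, "MIP-1a", p = 0.001),
         grid_cell("zymosan", 1, 1e4, "IL-2", p = 0.4),
         grid_cell("zymosan", 1, 1e4, "IL-17", p = 0.6)))
  g <- make_grid_fixture(cells, panel)
  cl <- select_signature(g, "zymosan")
  expect_equal(cl$signature_cytokine, "MIP-1a")
  expect_equal(cl$concentration, 1e4)
  expect_equal(length(cl$co_induced), 13)

  # tie at the first qualifying dose: earlier panel_order wins
  g2 <- make_grid_fixture(list(
    grid_cell("LPS", 1, 1, "IL-6", p = 0.3),
    grid_cell("LPS", 2, 10, "MCP-1", p = 0.01),
    grid_cell("LPS", 2, 10, "IL-1a", p = 0.01)), panel)
  cl2 <- select_signature(g2, "LPS")
  expect_equal(cl2$signature_cytokine, "IL-1a")   # order 3 beats order 15
  expect_equal(cl2$dose_rank, 2)

  # nothing significant anywhere -> no call
  g3 <- make_grid_fixture(list(grid_cell("MDP", 1, 1e4, "IL-8", p = 0.9)),
                          panel)
  expect_null(select_signature(g3, "MDP"))
  expect_error(select_signature(g3, "not-a-stimulus"), "not present")
})

test_that("dose-monotonicity: a lower all-null dose never changes the call", {
  panel <- default_cytokine_panel()
  base <- list(grid_cell("MDP", 2, 1e5, "IL-8", p = 0.002),
               grid_cell("MDP", 2, 1e5, "IL-6", p = 0.01))
  g <- make_grid_fixture(base, panel)
  with_null_low <- make_grid_fixture(
    c(list(grid_cell("MDP", 1, 1e4, "IL-8", p = 0.7),
           grid_cell("MDP", 1, 1e4, "IL-6", p = 0.9)), base), panel)
  expect_equal(select_signature(g, "MDP")$signature_cytokine,
               select_signature(with_null_low, "MDP")$signature_cytokine)
  expect_equal(select_top_k(g, "MDP", k = 2)$selected,
               select_top_k(with_null_low, "MDP", k = 2)$selected)
})

test_that("top-k selection scans doses until k cytokines qualify and flags short designs", {
  panel <- default_cytokine_panel()
  cells <- list(
    grid_cell("CLO75", 1, 1e4, "IL-10", p = 0.01),       # only 1 sig here
    grid_cell("CLO75", 2, 1e5, "IL-10", p = 0.001),
    grid_cell("CLO75", 2, 1e5, "IL-6", p = 0.002),
    grid_cell("CLO75", 2, 1e5, "IL-8", p = 0.04),
    grid_cell("CLO75", 2, 1e5, "TNFa", p = 0.045))
  g <- make_grid_fixture(cells, panel)
  tk <- select_top_k(g, "CLO75", k = 3)
  expect_equal(tk$selected, c("IL-10", "IL-6", "IL-8"))
  expect_equal(tk$dose_rank, 2)
  expect_false(tk$short)
  # k = 1 agrees with the signature rule under the same grid
  expect_equal(select_top_k(g, "CLO75", k = 1)$selected,
               select_signature(g, "CLO75")$signature_cytokine)
  # design exhausted without k significant: all sig at top dose, short
  g2 <- make_grid_fixture(list(
    grid_cell("MDP", 1, 1e4, "IL-8", p = 0.01),
    grid_cell("MDP", 2, 1e5, "IL-8", p = 0.01),
    grid_cell("MDP", 2, 1e5, "IL-6", p = 0.03)), panel)
  tk2 <- select_top_k(g2, "MDP", k = 3)
  expect_true(tk2$short)
  expect_equal(sort(tk2$selected), c("IL-6", "IL-8"))
  # nothing significant anywhere: empty flagged selection
  g3 <- make_grid_fixture(list(grid_cell("MDP", 1, 1e4, "IL-8", p = 0.9)),
                          panel)
  tk3 <- select_top_k(g3, "MDP", k = 3)
  expect_true(tk3$short)
  expect_equal(length(tk3$selected), 0)
})

test_that("planted co-exposure effects are called with the right direction", {
  cfg <- generator_config(seed = 17)
  gs <- generate_study(cfg)
  means <- average_replicates(apply_censoring(gs$study))
  calls <- modulation_calls(means, co_label = "TP")
  truth <- gs$truth$modulation
  # the planted zymosan signature suppression
  z <- calls[calls$stimulus == "zymosan" & calls$cytokine == "MIP-1a", ]
  expect_equal(nrow(z), 1)
  expect_equal(z$direction, "inhibited")
  # the planted PGE-2 enhancement mirrors the asterisk convention
  p <- calls[calls$stimulus == "zymosan" & calls$cytokine == "PGE-2", ]
  expect_equal(nrow(p), 1)
  expect_equal(p$direction, "enhanced")
  # every call that matches a planted effect has the planted direction
  merged <- merge(calls, truth, by = c("stimulus", "cytokine"))
  expect_true(all(merged$direction.x == merged$direction.y))
  # a study with no co-exposed arms cannot be tested
  cfg0 <- small_config(seed = 18)
  means0 <- average_replicates(apply_censoring(generate_study(cfg0)$study))
  expect_error(modulation_calls(means0, co_label = "TP"), "matched arms")
})
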