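test_that("the reference induction matrix has the expected shape", {
  m <- iirmi_reference_matrix()
  expect_equal(dim(m), c(10, 16))
  expect_true(all(rowSums(m) == 3))
  expect_equal(sort(colnames(m)[m["zymosan", ]]),
               c("IL-1a", "MCP-1", "MIP-1a"))
  expect_identical(attr(m, "provenance"), "from_fixture")
  # membrane-tethered-PRR stimuli consistently induce IL-1a and MIP-1a
  membrane <- c("flagellin", "FSL-1", "zymosan", "LPS")
  shared <- colnames(m)[colSums(m[membrane, ]) == length(membrane)]
  expect_equal(sort(shared), c("IL-1a", "MIP-1a"))
})

test_that("panel verification counts covered stimuli", {
  m <- iirmi_reference_matrix()
  four <- verify_panel(m, c("MCP-1", "MIP-1a", "IL-8", "IL-6"))
  expect_true(four$is_cover)
  expect_equal(length(four$covered), 10)
  three <- verify_panel(m, c("IL-1a", "IP-10", "IL-8"))
  expect_true(three$is_cover)
  empty <- verify_panel(m, character(0))
  expect_false(empty$is_cover)
  expect_equal(length(empty$uncovered), 10)
  expect_error(verify_panel(m, "IL-99"), "unknown")
})

test_that("minimum covers are found exhaustively and deterministically", {
  m <- iirmi_reference_matrix()
  cov <- minimal_covers(m)
  expect_equal(cov$min_size, 3)
  sets <- lapply(cov$covers, sort)
  expect_true(any(sapply(sets, identical, c("IL-1a", "IL-8", "IP-10"))))
  expect_true(any(sapply(sets, identical, c("IL-1a", "IL-8", "MCP-1"))))
  # every returned cover is a cover and is minimal (no subset covers)
  for (cv in cov$covers) {
    expect_true(verify_panel(m, cv)$is_cover)
    for (drop_i in seq_along(cv)) {
      expect_false(verify_panel(m, cv[-drop_i])$is_cover)
    }
  }
  # trivial cases
  one <- induction_matrix(matrix(TRUE, 3, 1,
                                 dimnames = list(letters[1:3], "IL-6")))
  expect_equal(minimal_covers(one)$min_size, 1)
  eye <- induction_matrix(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2,
                                 dimnames = list(c("s1", "s2"),
                                                 c("c1", "c2"))))
  cov2 <- minimal_covers(eye)
  expect_equal(cov2$min_size, 2)
  expect_equal(cov2$n_covers, 1)
  # an all-FALSE row names the uncoverable stimulus
  bad <- induction_matrix(matrix(c(TRUE, FALSE), 2, 1,
                                 dimnames = list(c("ok", "dead"), "IL-6")))
  expect_error(minimal_covers(bad), "dead")
})

test_that("exhaustive search agrees with a brute-force subset oracle", {
  set.seed(71)
  for (rep_i in 1:25) {
    nr <- sample(2:8, 1); nc <- sample(2:10, 1)
    m <- matrix(runif(nr * nc) < 0.3, nr, nc,
                dimnames = list(paste0("s", seq_len(nr)),
                                paste0("c", seq_len(nc))))
    if (any(rowSums(m) == 0)) next
    im <- induction_matrix(m)
    got <- minimal_covers(im)
    want <- oracle_min_cover(m)
    expect_equal(got$min_size, want$min_size)
    canon <- function(covs) sort(sapply(lapply(covs, sort), paste,
                                        collapse = "|"))
    expect_equal(canon(got$covers), canon(want$covers))
  }
})

test_that("adding TRUE cells never increases the minimum cover size", {
  set.seed(72)
  for (rep_i in 1:10) {
    m <- matrix(runif(24) < 0.35, 4, 6,
                dimnames = list(paste0("s", 1:4), paste0("c", 1:6)))
    if (any(rowSums(m) == 0)) next
    base <- minimal_covers(induction_matrix(m))$min_size
    m2 <- m
    off <- which(!m2)
    if (length(off) == 0) next
    m2[sample(off, 1)] <- TRUE
    expect_lte(minimal_covers(induction_matrix(m2))$min_size, base)
  }
})

test_that("top-k calls assemble into an induction matrix", {
  panel <- default_cytokine_panel()
  mk <- function(s, sel) structure(list(stimulus = s, selected = sel,
                                        p_values = rep(0.01, length(sel)),
                                        concentration_used = 1e4,
                                        dose_rank = 1L,
                                        short = length(sel) == 0),
                                   class = "topk_call")
  calls <- list(mk("zymosan", c("IL-1a", "MCP-1", "MIP-1a")),
                mk("MDP", c("IL-6", "IL-8", "IP-10")))
  m <- matrix_from_topk(calls, panel)
  expect_equal(rowSums(m), c(zymosan = 3, MDP = 3))
  expect_identical(attr(m, "provenance"), "from_grid")
  expect_warning(matrix_from_topk(c(calls, list(mk("LPS", character(0)))),
                                  panel), "all-FALSE")
  expect_error(matrix_from_topk(c(calls, calls[1]), panel), "duplicate")
})
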