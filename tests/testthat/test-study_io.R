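test_that("a minimal well-formed study reads, validates and round-trips", {
  dir <- withr::local_tempdir()
  paths <- tiny_study_files(dir)
  st <- read_study(paths[1], paths[2], paths[3])
  expect_s3_class(st, "study_table")
  expect_equal(nrow(st$records), 4L)
  expect_equal(unique(st$records$cohort), "fresh")

  out <- file.path(dir, c("m2.csv", "d2.csv", "l2.csv"))
  write_study(st, out[1], out[2], out[3])
  st2 <- read_study(out[1], out[2], out[3])
  expect_equal(st2$records, st$records)
  expect_equal(st2$design, st$design)
  expect_equal(st2$limits, st$limits)
})

test_that("stimulus dose units are normalized to pg/mL on read", {
  dir <- withr::local_tempdir()
  paths <- tiny_study_files(dir, unit_mix = TRUE)   # 10 ug/mL == 1e7 pg/mL
  st <- read_study(paths[1], paths[2], paths[3])
  expect_equal(unique(st$records$concentration[st$records$role == "treatment"]),
               1e7)
  expect_equal(convert_dose(1, "ug/mL"), 1e6)
  expect_equal(convert_dose(10, "ng"), 1e4)
})

test_that("validation rejects malformed studies with named offenders", {
  dir <- withr::local_tempdir()
  paths <- tiny_study_files(dir)
  meas <- read.csv(paths[1])

  m <- meas; m$cytokine <- NULL
  write.csv(m, file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(read_study(file.path(dir, "bad.csv"), paths[2], paths[3]),
               "cytokine")

  # 7 ug/mL zymosan is not a catalogued dose
  m <- meas; m$concentration[3:4] <- 7; m$unit[3:4] <- "ug/mL"
  write.csv(m, file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(read_study(file.path(dir, "bad.csv"), paths[2], paths[3]),
               "design catalogue")

  m <- meas; m$stimulus[3:4] <- "mystery"
  write.csv(m, file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(read_study(file.path(dir, "bad.csv"), paths[2], paths[3]),
               "mystery")

  m <- rbind(meas, meas[1, ])
  write.csv(m, file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(read_study(file.path(dir, "bad.csv"), paths[2], paths[3]),
               "duplicate")
})

test_that("censoring substitution follows the ADL/ULOQ and BDL/zero policy", {
  rec <- data.frame(
    donor = "D1", cohort = "fresh", stimulus = c("NC", "NC", "NC"),
    concentration = 0, co_exposure = "", role = "negative_control",
    cytokine = c("IL-6", "IL-2", "IL-6"), replicate = c(0, 0, 1),
    value = c(NA, NA, 7), censor = c("ADL", "BDL", "none"),
    stringsAsFactors = FALSE)
  lim <- data.frame(cytokine = c("IL-6", "IL-2"), lloq = c(1, 1),
                    uloq = c(5000, 4000))
  st <- study_table(rec, iirmi_design(), lim,
                    cytokine_panel(c("IL-6", "IL-2")))
  cen <- apply_censoring(st)
  expect_equal(cen$records$value, c(5000, 0, 7))
  # idempotent
  expect_identical(apply_censoring(cen)$records, cen$records)
  # censored cytokine without limits is a configuration error
  st$limits <- lim[1, , drop = FALSE]
  expect_error(apply_censoring(st), "IL-2")
  # no censored records: identity
  st2 <- st; st2$records <- st$records[3, , drop = FALSE]
  expect_identical(apply_censoring(st2)$records, st2$records)
})

test_that("replicate averaging is the arithmetic mean and keeps counts", {
  rec <- data.frame(
    donor = "D1", cohort = "fresh",
    stimulus = c("NC", "NC", "zymosan", "NC"), concentration = c(0, 0, 1e4, 0),
    co_exposure = "", role = c("negative_control", "negative_control",
                               "treatment", "negative_control"),
    cytokine = c("IL-6", "IL-6", "IL-6", "IL-2"), replicate = c(0, 1, 0, 0),
    value = c(100, 120, 7, 0), censor = "none", stringsAsFactors = FALSE)
  st <- study_table(rec, iirmi_design(), data.frame(),
                    cytokine_panel(c("IL-6", "IL-2")))
  mm <- average_replicates(st)
  expect_equal(mm$value[mm$cytokine == "IL-6" & mm$stimulus == "NC"], 110)
  expect_equal(mm$n_replicates[mm$cytokine == "IL-6" & mm$stimulus == "NC"], 2L)
  expect_equal(mm$value[mm$stimulus == "zymosan"], 7)   # single replicate
  expect_equal(mm$value[mm$cytokine == "IL-2"], 0)
})

test_that("permuting input rows leaves downstream results identical", {
  cfg <- small_config(seed = 7,
                      responses = dose_response_spec("zymosan", "IL-8", 3,
                                                     3e5))
  st <- generate_study(cfg)$study
  perm <- st
  set.seed(1)
  perm$records <- perm$records[sample(nrow(perm$records)), , drop = FALSE]
  rownames(perm$records) <- NULL
  g1 <- significance_grid(average_replicates(apply_censoring(st)))
  g2 <- significance_grid(average_replicates(apply_censoring(perm)))
  expect_identical(as.data.frame(g1), as.data.frame(g2))
})
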