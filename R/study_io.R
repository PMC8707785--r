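#' @keywords internal
"_PACKAGE"

.CENSOR_LEVELS <- c("none", "BDL", "ADL")
.ROLE_LEVELS <- c("negative_control", "positive_control", "treatment")

# canonical key identifying a treatment arm within a record table
.condition_key <- function(rec) {
  co <- rec$co_exposure
  co[is.na(co)] <- ""
  paste(rec$stimulus, rec$concentration, co, sep = "\r")
}

# human-readable arm label for matrices and reports
.condition_label <- function(stimulus, concentration, co_exposure) {
  lab <- ifelse(stimulus %in% c("NC", "PC"), stimulus,
                paste0(stimulus, " @", signif(concentration, 3)))
  co <- ifelse(is.na(co_exposure) | co_exposure == "", "",
               paste0(" +", co_exposure))
  paste0(lab, co)
}

#' Construct and validate a study table
#'
#' The container for one immunostimulation study: well-level measurement
#' records, the stimulus dose catalogue, per-cytokine assay quantification
#' limits, and the ordered cytokine panel.
#'
#' @param records data.frame with columns `donor`, `cohort`, `stimulus`,
#'   `concentration` (pg/mL), `co_exposure` (`NA`/`""` when absent), `role`,
#'   `cytokine`, `replicate`, `value` (pg/mL, `NA` when censored), `censor`
#'   (`"none"`, `"BDL"`, `"ADL"`).
#' @param design Dose catalogue as from [iirmi_design()]; must contain
#'   `stimulus` and `concentration`.
#' @param limits data.frame with columns `cytokine`, `lloq`, `uloq` (pg/mL).
#' @param panel A [cytokine_panel()].
#' @return An object of class `"study_table"`.
#' @export
study_table <- function(records, design, limits, panel) {
  stopifnot(is.data.frame(records), is.data.frame(design),
            is.data.frame(limits))
  if (!inherits(panel, "cytokine_panel")) panel <- cytokine_panel(panel)
  if (!"cohort" %in% names(records)) records$cohort <- "fresh"
  records$cohort[is.na(records$cohort) | records$cohort == ""] <- "fresh"
  if (!"co_exposure" %in% names(records)) records$co_exposure <- ""
  records$co_exposure[is.na(records$co_exposure)] <- ""
  need <- c("donor", "stimulus", "concentration", "role", "cytokine",
            "replicate", "value", "censor")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records are missing column(s): ",
                         paste(miss, collapse = ", "))
  records$concentration <- as.numeric(records$concentration)
  records$value <- as.numeric(records$value)

  bad <- setdiff(unique(records$censor), .CENSOR_LEVELS)
  if (length(bad)) stop("unknown censor flag(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(records$role), .ROLE_LEVELS)
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))

  unk <- setdiff(unique(records$cytokine), panel$name)
  if (length(unk)) stop("cytokine(s) not in panel: ",
                        paste(unk, collapse = ", "))
  trt <- records[records$role == "treatment", , drop = FALSE]
  unk <- setdiff(unique(trt$stimulus), unique(design$stimulus))
  if (length(unk)) stop("stimulus(es) not in design catalogue: ",
                        paste(unk, collapse = ", "))
  dkey <- paste(design$stimulus, signif(design$concentration, 6))
  tkey <- paste(trt$stimulus, signif(trt$concentration, 6))
  unk <- unique(tkey[!tkey %in% dkey])
  if (length(unk)) stop("treatment dose(s) absent from design catalogue: ",
                        paste(unk, collapse = "; "))
  nc <- records$role == "negative_control"
  if (!any(nc)) stop("study contains no negative-control records")
  if (any(records$concentration[nc] != 0)) {
    stop("negative-control records must have zero concentration")
  }

  key <- paste(records$donor, records$cohort, .condition_key(records),
               records$cytokine, records$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (donor, condition, cytokine, replicate, cohort) key(s), e.g. ",
         gsub("\r", " / ", key[duplicated(key)][1]))
  }
  ok <- records$censor == "none"
  if (any(ok & (is.na(records$value) | records$value < 0))) {
    stop("uncensored records must carry a non-negative value")
  }
  if (any(!ok & !is.na(records$value))) {
    stop("censored records must have an absent value (use apply_censoring)")
  }
  if (nrow(limits)) {
    if (!all(c("cytokine", "lloq", "uloq") %in% names(limits))) {
      stop("limits need columns cytokine, lloq, uloq")
    }
    if (any(limits$lloq <= 0 | limits$uloq <= limits$lloq)) {
      stop("limits must satisfy 0 < lloq < uloq")
    }
  }
  structure(list(records = records, design = design, limits = limits,
                 panel = panel),
            class = "study_table")
}

#' @export
print.study_table <- function(x, ...) {
  r <- x$records
  cat("Immunostimulation study table\n")
  cat(sprintf("  %d well-level records | %d donors | %d cytokines | %d conditions\n",
              nrow(r), length(unique(r$donor)), nrow(x$panel),
              length(unique(.condition_key(r)))))
  cat(sprintf("  cohorts: %s\n", paste(unique(r$cohort), collapse = ", ")))
  cens <- table(factor(r$censor, .CENSOR_LEVELS))
  cat(sprintf("  censoring: %d none, %d BDL, %d ADL\n",
              cens[["none"]], cens[["BDL"]], cens[["ADL"]]))
  invisible(x)
}

#' Read a study from its three CSV files
#'
#' Measurements are long-format, one row per well-level cytokine reading,
#' with explicit censor flags (never inferred from sentinel values). The
#' `concentration`/`unit` pair is normalized to pg/mL on read; cytokine
#' readings themselves must already be pg/mL.
#'
#' @param measurements_path CSV with header `donor, cohort, stimulus,
#'   concentration, unit, co_exposure, role, cytokine, replicate, value,
#'   censor` (`cohort` may be omitted and defaults to `"fresh"`).
#' @param design_path CSV with `stimulus, prr, localization, concentration,
#'   unit` rows (one per tested dose), or with `concentration` already in
#'   pg/mL when `unit` is omitted.
#' @param limits_path CSV with `cytokine, lloq, uloq` in pg/mL.
#' @param panel Cytokine panel; defaults to the measured cytokines in file
#'   order of first appearance.
#' @return A validated [study_table()].
#' @export
read_study <- function(measurements_path, design_path, limits_path,
                       panel = NULL) {
  for (p in c(measurements_path, design_path, limits_path)) {
    if (!file.exists(p)) stop("no such file: ", p)
  }
  meas <- utils::read.csv(measurements_path, stringsAsFactors = FALSE)
  need <- c("donor", "stimulus", "concentration", "role", "cytokine",
            "replicate", "value", "censor")
  miss <- setdiff(need, names(meas))
  if (length(miss)) stop("measurements file is missing column(s): ",
                         paste(miss, collapse = ", "))
  if ("unit" %in% names(meas)) {
    has <- !is.na(meas$unit) & meas$unit != "" & meas$concentration != 0
    meas$concentration[has] <- convert_dose(meas$concentration[has],
                                            meas$unit[has])
    meas$unit <- NULL
  }
  meas$value[meas$censor != "none"] <- NA_real_

  des <- utils::read.csv(design_path, stringsAsFactors = FALSE)
  if (!all(c("stimulus", "concentration") %in% names(des))) {
    stop("design file needs columns stimulus, concentration")
  }
  if ("unit" %in% names(des)) {
    des$concentration <- convert_dose(des$concentration, des$unit)
    des$unit <- NULL
  }
  if (!"dose_rank" %in% names(des)) {
    des <- des[order(des$stimulus, des$concentration), , drop = FALSE]
    des$dose_rank <- stats::ave(des$concentration, des$stimulus,
                                FUN = seq_along)
  }
  lim <- utils::read.csv(limits_path, stringsAsFactors = FALSE)
  if (is.null(panel)) panel <- cytokine_panel(unique(meas$cytokine))
  study_table(meas, des, lim, panel)
}

#' Write a study back to its three CSV files
#'
#' Inverse of [read_study()]: a written study reads back equal.
#'
#' @param table A [study_table()].
#' @param measurements_path,design_path,limits_path Output CSV paths.
#' @return Invisibly, the paths written.
#' @export
write_study <- function(table, measurements_path, design_path, limits_path) {
  stopifnot(inherits(table, "study_table"))
  utils::write.csv(table$records, measurements_path, row.names = FALSE,
                   na = "")
  utils::write.csv(table$design, design_path, row.names = FALSE)
  utils::write.csv(table$limits, limits_path, row.names = FALSE)
  invisible(c(measurements_path, design_path, limits_path))
}

#' Substitute censored readings by the study's censoring policy
#'
#' Readings above the upper limit of quantification (`ADL`) are set to the
#' cytokine's ULOQ; readings below the lower limit (`BDL`) are set to zero.
#' Uncensored values are untouched. Idempotent.
#'
#' @param table A [study_table()].
#' @return The table with all values present; censor flags are retained for
#'   audit.
#' @export
apply_censoring <- function(table) {
  stopifnot(inherits(table, "study_table"))
  r <- table$records
  cens <- r$censor != "none"
  if (any(cens)) {
    need <- unique(r$cytokine[cens])
    have <- if (nrow(table$limits)) table$limits$cytokine else character()
    miss <- setdiff(need, have)
    if (length(miss)) {
      stop("censored records but no assay limits configured for: ",
           paste(miss, collapse = ", "))
    }
    adl <- r$censor == "ADL"
    r$value[adl] <- table$limits$uloq[match(r$cytokine[adl],
                                            table$limits$cytokine)]
    r$value[r$censor == "BDL"] <- 0
  }
  table$records <- r
  table
}

#' Average duplicate wells
#'
#' Arithmetic mean over replicates per (donor, cohort, condition, cytokine),
#' after censoring substitution. Single replicates pass through.
#'
#' @param table A censored [study_table()] (no absent values).
#' @return A data.frame of class `"cytokine_means"` with one row per key and
#'   columns `value` (mean) and `n_replicates`; the design and panel travel
#'   as attributes.
#' @export
average_replicates <- function(table) {
  stopifnot(inherits(table, "study_table"))
  r <- table$records
  if (anyNA(r$value)) {
    stop("absent values present; run apply_censoring() first")
  }
  key <- paste(r$donor, r$cohort, r$stimulus, r$concentration,
               r$co_exposure, r$role, r$cytokine, sep = "\r")
  first <- !duplicated(key)
  sums <- rowsum(r$value, key)
  cnts <- rowsum(rep(1L, nrow(r)), key)
  agg <- r[first, c("donor", "cohort", "stimulus", "concentration",
                    "co_exposure", "role", "cytokine"), drop = FALSE]
  idx <- match(key[first], rownames(sums))
  agg$value <- sums[idx, 1] / cnts[idx, 1]
  agg$n_replicates <- as.integer(cnts[idx, 1])
  # fixed row order so downstream results never depend on input row order
  agg <- agg[order(agg$cohort, agg$stimulus, agg$concentration,
                   agg$co_exposure, agg$cytokine, agg$donor), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "design") <- table$design
  attr(agg, "panel") <- table$panel
  class(agg) <- c("cytokine_means", "data.frame")
  agg
}
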