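# Synthetic immunostimulation studies with planted ground truth.
#
# The generative model is log-normal throughout: for donor i, cytokine c,
# treatment arm (s, d),
#
#   log value = baseline_log(c) + donor_offset(i, c)
#             + emax_log(s, c) * d^h / (d^h + ec50^h)     [planted response]
#             + co_exposure_effect(s, c)                  [when co-exposed]
#             + biological noise (per donor x arm x cytokine)
#             + replicate noise (per well)
#
# exponentiated and then censored at the assay limits (below LLOQ -> BDL,
# above ULOQ -> ADL). Donor offsets model stable inter-donor heterogeneity
# ("high responders"); rank tests downstream are invariant to the monotone
# log link.

#' Planted dose-response specification
#'
#' @param stimulus Stimulus name (must exist in the design catalogue).
#' @param cytokine Responsive cytokine.
#' @param emax_log Maximum log-fold induction at saturating dose (natural
#'   log).
#' @param ec50 Dose of half-maximal induction, pg/mL.
#' @param hill Hill coefficient (> 0); shallow slopes (< 1) reflect the
#'   heterogeneous responder mix of a PBMC culture.
#' @return A one-row data.frame.
#' @export
dose_response_spec <- function(stimulus, cytokine, emax_log, ec50,
                               hill = 0.5) {
  stopifnot(emax_log >= 0, ec50 > 0, hill > 0)
  data.frame(stimulus = stimulus, cytokine = cytokine,
             emax_log = emax_log, ec50 = ec50, hill = hill,
             stringsAsFactors = FALSE)
}

# geometric mid-point of a stimulus's tested doses
.mid_dose <- function(design, stimulus) {
  d <- design$concentration[design$stimulus == stimulus]
  exp(mean(log(range(d))))
}

#' Default planted responses: one signature cytokine per IIRMI
#'
#' One responsive cytokine per stimulus — the signature reported for each
#' IIRMI in the 16-plex study — at `emax_log` induction, half-maximal at
#' the geometric mid-dose of the stimulus's tested range.
#'
#' @param design The dose catalogue (default [iirmi_design()]).
#' @param emax_log Planted maximum log-fold induction.
#' @param hill Hill coefficient.
#' @return A data.frame of [dose_response_spec()] rows.
#' @export
default_planted_responses <- function(design = iirmi_design(),
                                      emax_log = 3, hill = 0.5) {
  sig <- c("flagellin" = "IL-1b", "FSL-1" = "IL-1a", "ODN2006" = "IFNa",
           "poly(I:C) HMW" = "IP-10", "poly(I:C) LMW" = "MCP-1",
           "zymosan" = "MIP-1a", "CLO75" = "IL-10", "MDP" = "IL-8",
           "ODN2216" = "IL-6", "LPS" = "IL-1a")
  sig <- sig[names(sig) %in% unique(design$stimulus)]
  do.call(rbind, lapply(names(sig), function(s) {
    dose_response_spec(s, sig[[s]], emax_log, .mid_dose(design, s), hill)
  }))
}

#' Generator configuration
#'
#' Defaults emulate the study conditions: 10 donors, duplicate wells, the
#' full IIRMI dose catalogue with and without drug co-exposure, NC/PC
#' controls, log-normal noise with large stable donor effects, one planted
#' signature cytokine per stimulus, drug co-exposure suppressing each
#' planted signature and enhancing PGE-2, and a strong uniform
#' positive-control induction.
#'
#' @param n_donors Number of donors.
#' @param n_replicates Wells per condition (duplicates by default).
#' @param panel A [cytokine_panel()].
#' @param baseline_log Named per-cytokine baseline log-mean (pg/mL scale);
#'   default spreads geometrically from 50 to 1000 pg/mL over the panel.
#' @param baseline_log_sd Condition-level biological log-SD (within donor,
#'   between conditions).
#' @param donor_sd Log-SD of the per-(donor, cytokine) offsets.
#' @param replicate_cv Coefficient of variation of replicate noise on the
#'   natural scale.
#' @param limits Assay limits data.frame (`cytokine`, `lloq`, `uloq`).
#' @param design Dose catalogue.
#' @param responses Planted [dose_response_spec()] rows.
#' @param co_exposure_effects data.frame (`stimulus`, `cytokine`,
#'   `log_effect`): additive log modulation applied under co-exposure
#'   (negative = suppression). Default: -2 on each planted signature, +2
#'   on PGE-2 for every stimulus.
#' @param co_label Co-exposure label (`"TP"`).
#' @param include_co_exposure Generate the co-exposed arms?
#' @param pc_effect Uniform positive-control log induction.
#' @param cohort Cohort tag stamped on the records.
#' @param seed Integer seed; identical seeds give bit-identical studies.
#' @return A validated list of class `"generator_config"`.
#' @export
generator_config <- function(n_donors = 10L, n_replicates = 2L,
                             panel = default_cytokine_panel(),
                             baseline_log = NULL, baseline_log_sd = 0.1,
                             donor_sd = 0.8, replicate_cv = 0.15,
                             limits = NULL, design = iirmi_design(),
                             responses = default_planted_responses(design),
                             co_exposure_effects = NULL, co_label = "TP",
                             include_co_exposure = TRUE, pc_effect = 4,
                             cohort = "fresh", seed = 1L) {
  if (!inherits(panel, "cytokine_panel")) panel <- cytokine_panel(panel)
  k <- nrow(panel)
  if (is.null(baseline_log)) {
    baseline_log <- stats::setNames(seq(log(50), log(1000), length.out = k),
                                    panel$name)
  }
  if (is.null(limits)) {
    limits <- data.frame(cytokine = panel$name, lloq = 5, uloq = 5e4,
                         stringsAsFactors = FALSE)
  }
  if (is.null(co_exposure_effects)) {
    co_exposure_effects <- rbind(
      if (!is.null(responses) && nrow(responses))
        data.frame(stimulus = responses$stimulus,
                   cytokine = responses$cytokine, log_effect = -2,
                   stringsAsFactors = FALSE),
      if ("PGE-2" %in% panel$name)
        data.frame(stimulus = unique(design$stimulus), cytokine = "PGE-2",
                   log_effect = 2, stringsAsFactors = FALSE))
    # a planted PGE-2 signature would otherwise get two rows
    co_exposure_effects <-
      co_exposure_effects[!duplicated(co_exposure_effects[1:2]), ,
                          drop = FALSE]
  }
  cfg <- list(n_donors = as.integer(n_donors),
              n_replicates = as.integer(n_replicates), panel = panel,
              baseline_log = baseline_log,
              baseline_log_sd = baseline_log_sd, donor_sd = donor_sd,
              replicate_cv = replicate_cv, limits = limits, design = design,
              responses = responses,
              co_exposure_effects = co_exposure_effects,
              co_label = co_label,
              include_co_exposure = include_co_exposure,
              pc_effect = pc_effect, cohort = cohort,
              seed = as.integer(seed))
  .validate_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

.validate_config <- function(cfg) {
  if (cfg$n_donors < 2L) stop("n_donors must be >= 2")
  if (cfg$n_replicates < 1L) stop("n_replicates must be >= 1")
  if (cfg$replicate_cv <= 0) stop("replicate_cv must be > 0")
  if (cfg$baseline_log_sd < 0 || cfg$donor_sd < 0) {
    stop("noise SDs must be non-negative")
  }
  if (!all(names(cfg$baseline_log) %in% cfg$panel$name) ||
      !all(cfg$panel$name %in% names(cfg$baseline_log))) {
    stop("baseline_log must be named by exactly the panel cytokines")
  }
  if (any(cfg$limits$lloq <= 0 | cfg$limits$uloq <= cfg$limits$lloq)) {
    stop("limits must satisfy 0 < lloq < uloq")
  }
  r <- cfg$responses
  if (!is.null(r) && nrow(r)) {
    if (!all(r$stimulus %in% unique(cfg$design$stimulus))) {
      stop("planted response references a stimulus not in the design")
    }
    if (!all(r$cytokine %in% cfg$panel$name)) {
      stop("planted response references a cytokine not in the panel")
    }
    if (any(r$emax_log < 0) || any(r$ec50 <= 0) || any(r$hill <= 0)) {
      stop("invalid planted response parameters")
    }
  }
  invisible(cfg)
}

# run code with a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic study with planted ground truth
#'
#' @param config A [generator_config()].
#' @return A list with elements `study` (a censored-flag [study_table()];
#'   censored wells carry `NA` values until [apply_censoring()]) and
#'   `truth` (class `"planted_truth"`: the planted `responses` and the
#'   expected co-exposure `modulation` directions).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  .validate_config(config)
  cfg <- config
  panel <- cfg$panel
  K <- nrow(panel); D <- cfg$n_donors; R <- cfg$n_replicates
  donors <- sprintf("D%02d", seq_len(D))

  arms <- unique(cfg$design[c("stimulus", "concentration")])
  conds <- data.frame(stimulus = c("NC", "PC", arms$stimulus),
                      concentration = c(0, 0, arms$concentration),
                      co_exposure = "",
                      role = c("negative_control", "positive_control",
                               rep("treatment", nrow(arms))),
                      stringsAsFactors = FALSE)
  if (cfg$include_co_exposure) {
    co <- conds[conds$role == "treatment", , drop = FALSE]
    co$co_exposure <- cfg$co_label
    conds <- rbind(conds, co)
  }
  C <- nrow(conds)

  # fixed-effect grid (condition x cytokine)
  eff <- matrix(0, nrow = C, ncol = K, dimnames = list(NULL, panel$name))
  eff[conds$role == "positive_control", ] <- cfg$pc_effect
  resp <- cfg$responses
  if (!is.null(resp)) for (j in seq_len(nrow(resp))) {
    rows <- conds$role == "treatment" & conds$stimulus == resp$stimulus[j]
    d <- conds$concentration[rows]
    eff[rows, resp$cytokine[j]] <- eff[rows, resp$cytokine[j]] +
      resp$emax_log[j] * d^resp$hill[j] /
        (d^resp$hill[j] + resp$ec50[j]^resp$hill[j])
  }
  ce <- cfg$co_exposure_effects
  if (!is.null(ce) && cfg$include_co_exposure) for (j in seq_len(nrow(ce))) {
    rows <- conds$role == "treatment" &
      conds$stimulus == ce$stimulus[j] & conds$co_exposure == cfg$co_label
    eff[rows, ce$cytokine[j]] <- eff[rows, ce$cytokine[j]] + ce$log_effect[j]
  }

  rep_sd <- sqrt(log(1 + cfg$replicate_cv^2))
  grid <- expand.grid(donor = seq_len(D), cyt = seq_len(K),
                      cond = seq_len(C), KEEP.OUT.ATTRS = FALSE)
  n_cells <- nrow(grid)

  records <- .with_seed(cfg$seed, {
    donor_off <- matrix(stats::rnorm(D * K, sd = cfg$donor_sd), D, K)
    bio <- stats::rnorm(n_cells, sd = cfg$baseline_log_sd)
    mu <- cfg$baseline_log[panel$name[grid$cyt]] +
      donor_off[cbind(grid$donor, grid$cyt)] +
      eff[cbind(grid$cond, grid$cyt)] + bio
    do.call(rbind, lapply(seq_len(R) - 1L, function(rep_i) {
      val <- exp(mu + stats::rnorm(n_cells, sd = rep_sd))
      data.frame(donor = donors[grid$donor], cohort = cfg$cohort,
                 stimulus = conds$stimulus[grid$cond],
                 concentration = conds$concentration[grid$cond],
                 co_exposure = conds$co_exposure[grid$cond],
                 role = conds$role[grid$cond],
                 cytokine = panel$name[grid$cyt], replicate = rep_i,
                 value = val, censor = "none", stringsAsFactors = FALSE)
    }))
  })
  lim <- cfg$limits[match(records$cytokine, cfg$limits$cytokine), ]
  bdl <- records$value < lim$lloq
  adl <- records$value > lim$uloq
  records$censor[bdl] <- "BDL"
  records$censor[adl] <- "ADL"
  records$value[bdl | adl] <- NA_real_

  design <- cfg$design
  study <- study_table(records, design, cfg$limits, panel)

  modulation <- if (!is.null(ce) && nrow(ce)) {
    data.frame(stimulus = ce$stimulus, cytokine = ce$cytokine,
               direction = ifelse(ce$log_effect > 0, "enhanced",
                                  "inhibited"),
               log_effect = ce$log_effect, stringsAsFactors = FALSE)
  } else NULL
  truth <- structure(list(responses = resp, modulation = modulation),
                     class = "planted_truth")
  list(study = study, truth = truth)
}

#' @export
print.planted_truth <- function(x, ...) {
  nr <- if (is.null(x$responses)) 0L else nrow(x$responses)
  nm <- if (is.null(x$modulation)) 0L else nrow(x$modulation)
  cat(sprintf("Planted truth: %d responsive (stimulus, cytokine) pairs, %d co-exposure effects\n",
              nr, nm))
  invisible(x)
}
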