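#' Define an ordered cytokine panel
#'
#' A panel is the ordered list of analytes measured on one multiplex plate.
#' The order (`panel_order`) is the deterministic tie-break used everywhere a
#' selection rule must choose between cytokines with identical p-values.
#'
#' @param names Character vector of unique cytokine labels.
#' @return A data.frame with columns `name` and `panel_order`
#'   (0-based rank), classed `"cytokine_panel"`.
#' @examples
#' cytokine_panel(c("IL-6", "IL-8", "TNFa"))
#' @export
cytokine_panel <- function(names) {
  names <- as.character(names)
  if (length(names) == 0L) stop("panel must contain at least one cytokine")
  if (anyDuplicated(names)) {
    stop("duplicate cytokine names in panel: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  out <- data.frame(name = names, panel_order = seq_along(names) - 1L,
                    stringsAsFactors = FALSE)
  class(out) <- c("cytokine_panel", "data.frame")
  out
}

#' The default 16-plex cytokine panel
#'
#' The 16 analytes of the PBMC immunostimulation assay: the three interferon
#' classes, seven interleukins, IP-10, TNFa, PGE-2 and the chemokines MIP-1a
#' and MCP-1. Greek letters are transliterated to ASCII (IFNa = IFN-alpha,
#' etc.).
#'
#' @return A `cytokine_panel` of 16 cytokines.
#' @export
default_cytokine_panel <- function() {
  cytokine_panel(c("IFNa", "IFNg", "IFNl", "IL-1a", "IL-1b", "IL-2",
                   "IL-6", "IL-8", "IL-10", "IL-12", "IL-17", "IP-10",
                   "TNFa", "PGE-2", "MIP-1a", "MCP-1"))
}

# dose unit -> pg multiplier (per mL)
.unit_factor <- function(unit) {
  f <- c("pg" = 1, "ng" = 1e3, "ug" = 1e6, "µg" = 1e6, "mg" = 1e9)
  u <- sub("/m[lL]$", "", trimws(unit))
  out <- unname(f[u])
  if (anyNA(out)) {
    stop("unknown concentration unit(s): ",
         paste(unique(unit[is.na(out)]), collapse = ", "))
  }
  out
}

#' Convert a stimulus dose to pg/mL
#'
#' @param value Numeric amount per mL.
#' @param unit One of `"pg"`, `"ng"`, `"ug"` (or the micro sign form),
#'   `"mg"`; a trailing `"/mL"` is tolerated.
#' @return Dose in pg/mL.
#' @export
convert_dose <- function(value, unit) {
  as.numeric(value) * .unit_factor(unit)
}

#' The IIRMI stimulus design catalogue
#'
#' The ten innate immune response modulating impurities of the study, their
#' cognate pattern-recognition receptors and receptor localization, and the
#' four tested final concentrations per mL of each. Doses are stored in
#' pg/mL; the display unit used on plate maps is kept alongside.
#'
#' @return A data.frame with one row per (stimulus, dose): columns
#'   `stimulus`, `prr`, `localization` (membrane/endosome/cytosol),
#'   `concentration` (pg/mL), `dose_rank` (1 = lowest), `display` (the
#'   human-readable dose label).
#' @export
iirmi_design <- function() {
  spec <- list(
    list("flagellin",      "TLR5",         "membrane", c(1e4, 1e5, 1e6, 1e7),
         c("10 ng/mL", "100 ng/mL", "1 ug/mL", "10 ug/mL")),
    list("FSL-1",          "TLR2/TLR6",    "membrane", c(1e1, 1e2, 1e3, 1e4),
         c("10 pg/mL", "100 pg/mL", "1 ng/mL", "10 ng/mL")),
    list("ODN2006",        "TLR9",         "endosome", c(1e4, 1e5, 1e6, 1e7),
         c("10 ng/mL", "100 ng/mL", "1 ug/mL", "10 ug/mL")),
    list("poly(I:C) HMW",  "TLR3",         "endosome", c(1e4, 1e5, 1e6, 1e7),
         c("10 ng/mL", "100 ng/mL", "1 ug/mL", "10 ug/mL")),
    list("poly(I:C) LMW",  "TLR3",         "endosome", c(1e4, 1e5, 1e6, 1e7),
         c("10 ng/mL", "100 ng/mL", "1 ug/mL", "10 ug/mL")),
    list("zymosan",        "TLR2/Dectin-1", "membrane", c(1e4, 1e5, 1e6, 1e7),
         c("10 ng/mL", "100 ng/mL", "1 ug/mL", "10 ug/mL")),
    list("CLO75",          "TLR8",         "endosome", c(1e4, 1e5, 1e6, 1e7),
         c("10 ng/mL", "100 ng/mL", "1 ug/mL", "10 ug/mL")),
    list("MDP",            "NOD2",         "cytosol",  c(1e4, 1e5, 1e6, 1e7),
         c("10 ng/mL", "100 ng/mL", "1 ug/mL", "10 ug/mL")),
    list("ODN2216",        "TLR9",         "endosome", c(5e3, 5e4, 5e5, 5e6),
         c("5 ng/mL", "50 ng/mL", "500 ng/mL", "5 ug/mL")),
    list("LPS",            "TLR4",         "membrane", c(1e0, 1e1, 1e2, 1e3),
         c("1 pg/mL", "10 pg/mL", "100 pg/mL", "1 ng/mL"))
  )
  do.call(rbind, lapply(spec, function(s) {
    data.frame(stimulus = s[[1]], prr = s[[2]], localization = s[[3]],
               concentration = s[[4]], dose_rank = seq_along(s[[4]]),
               display = s[[5]], stringsAsFactors = FALSE)
  }))
}

#' Reference top-3 induction matrix for the ten IIRMIs
#'
#' The boolean stimuli-by-cytokines induction matrix of the 16-plex study:
#' each row marks, for one IIRMI, the three cytokines selected by the
#' top-3 rule (unpaired two-sided Wilcoxon vs pooled negative control,
#' ascending dose scan). Shipped as a built-in example for panel-design
#' work; every row has exactly three TRUE cells.
#'
#' @return An [induction_matrix()] of dimension 10 x 16, provenance
#'   `"from_fixture"`.
#' @export
iirmi_reference_matrix <- function() {
  cyt <- c("IFNa", "IFNg", "IFNl", "IL-10", "IL-12", "IL-17", "IL-1a",
           "IL-1b", "IL-2", "IL-6", "IL-8", "IP-10", "MCP-1", "MIP-1a",
           "TNFa", "PGE-2")
  rows <- list(
    "flagellin"     = c("IL-1a", "IL-1b", "MIP-1a"),
    "FSL-1"         = c("IL-1a", "IL-1b", "MIP-1a"),
    "zymosan"       = c("IL-1a", "MCP-1", "MIP-1a"),
    "LPS"           = c("IL-1a", "IL-1b", "MIP-1a"),
    "ODN2006"       = c("IFNa", "IL-8", "MCP-1"),
    "poly(I:C) HMW" = c("IL-6", "IP-10", "MCP-1"),
    "poly(I:C) LMW" = c("IFNg", "IP-10", "MCP-1"),
    "CLO75"         = c("IL-10", "IL-6", "IL-8"),
    "ODN2216"       = c("IFNa", "IP-10", "MCP-1"),
    "MDP"           = c("IL-6", "IL-8", "IP-10")
  )
  m <- matrix(FALSE, nrow = length(rows), ncol = length(cyt),
              dimnames = list(names(rows), cyt))
  for (s in names(rows)) m[s, rows[[s]]] <- TRUE
  induction_matrix(m, provenance = "from_fixture")
}
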