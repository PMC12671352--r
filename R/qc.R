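#' Certified reference material recovery
#'
#' Recovery of a certified reference material (CRM) analysis, in percent:
#' `100 * measured / certified`. Used to validate instrument accuracy; a
#' digestion/measurement chain is conventionally accepted when recovery is
#' within roughly 90--110 %.
#'
#' @param measured Measured concentration, mg/kg (>= 0).
#' @param certified Certified concentration, mg/kg (> 0).
#' @param digits Rounding for reporting; `NULL` returns full precision.
#'   Integer rounding reproduces "round number" recoveries quoted in survey
#'   reports (0.46/0.48 -> 95.83 -> 96).
#'
#' @return Recovery in percent.
#' @export
#' @examples
#' crm_recovery(0.46, 0.48)             # 95.83...
#' crm_recovery(0.46, 0.48, digits = 0) # 96
crm_recovery <- function(measured, certified, digits = NULL) {
  if (!is.numeric(certified) || any(certified <= 0)) {
    stop_named("vegrisk_domain_error", "`certified` must be > 0")
  }
  if (!is.numeric(measured) || any(measured < 0)) {
    stop_named("vegrisk_domain_error", "`measured` must be >= 0")
  }
  r <- 100 * measured / certified
  if (!is.null(digits)) r <- round(r, digits) else r
}

#' Flag below-detection-limit cells
#'
#' Per-cell logical mask over a concentration table: `TRUE` where the stored
#' concentration is strictly below the metal's limit of detection. The
#' boundary counts as detected (values are printed at or above LOD), and
#' metals with no LOD entry are never flagged.
#'
#' @param table A [concentration_table()] carrying an `lod` attribute.
#' @return Logical matrix, rows named by sample, columns by metal.
#' @export
flag_below_lod <- function(table) {
  lod <- attr(table, "lod")
  if (is.null(lod)) {
    stop_named("vegrisk_qc_error", "table carries no LOD map")
  }
  metals <- table_metals(table)
  mask <- matrix(FALSE, nrow(table), length(metals),
                 dimnames = list(table$sample, metals))
  for (m in intersect(metals, names(lod))) {
    mask[, m] <- table[[m]] < lod[[m]]
  }
  mask
}

#' Build a CRM quality-control report
#'
#' One row per metal with measured and certified values, percent recovery,
#' and a pass flag at a configurable acceptance threshold.
#'
#' @param measured Named numeric vector, mg/kg.
#' @param certified Named numeric vector over the same metals, mg/kg.
#' @param threshold Minimum acceptable recovery, percent (default 90).
#' @return A data.frame with columns `metal`, `measured`, `certified`,
#'   `recovery_pct` (one decimal), `pass`.
#' @export
qc_report <- function(measured, certified, threshold = 90) {
  metals <- intersect(names(measured), names(certified))
  if (!length(metals)) {
    stop_named("vegrisk_qc_error", "no metals shared between measured and certified")
  }
  rec <- crm_recovery(measured[metals], certified[metals])
  data.frame(metal = metals,
             measured = as.numeric(measured[metals]),
             certified = as.numeric(certified[metals]),
             recovery_pct = round(rec, 1),
             pass = rec >= threshold,
             row.names = NULL)
}
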