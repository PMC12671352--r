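#' Estimated daily intake (EDI)
#'
#' Chronic daily intake of a contaminant through the foodstuff,
#' `EDI = C * DIR / BW`, where `C` is the concentration in mg/kg dry weight,
#' `DIR` the daily ingestion rate in g/day and `BW` the body weight in kg.
#' The mg/kg x g/day / kg combination lands directly on ug per kg body
#' weight per day, so no explicit unit factor appears here; the single
#' ug-to-mg conversion of the pipeline lives inside
#' [target_hazard_quotient()].
#'
#' @param c Concentration(s), mg/kg dry weight; vectorised.
#' @param scenario An [exposure_scenario()].
#' @return EDI in ug/kg bw/day.
#' @export
#' @examples
#' estimated_daily_intake(519.24, exposure_scenario()) # 537.14...
estimated_daily_intake <- function(c, scenario = exposure_scenario()) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  if (!is.numeric(c) || anyNA(c) || any(c < 0)) {
    stop_named("vegrisk_domain_error", "concentration must be numeric and >= 0")
  }
  c * scenario$dir / scenario$bw
}

#' Target hazard quotient (THQ)
#'
#' Non-carcinogenic hazard quotient
#' `THQ = EDI * EF * ED / (RfD * AT) * 1e-3`,
#' with EDI in ug/kg bw/day and the oral reference dose RfD in mg/kg bw/day;
#' the `1e-3` converts the intake to mg. Under the default lifetime scenario
#' `EF * ED = AT`, so the time terms cancel and `THQ = EDI * 1e-3 / RfD`.
#' THQ > 1 flags potential non-carcinogenic risk.
#'
#' @param edi Estimated daily intake, ug/kg bw/day; vectorised.
#' @param rfd Oral reference dose, mg/kg bw/day (> 0).
#' @param scenario An [exposure_scenario()] supplying EF, ED, AT.
#' @param metal Optional metal name used in error messages.
#' @return Dimensionless hazard quotient.
#' @export
#' @examples
#' target_hazard_quotient(88.36, rfd = 0.04) # 2.209
target_hazard_quotient <- function(edi, rfd, scenario = exposure_scenario(),
                                   metal = NULL) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  if (is.null(rfd) || is.na(rfd) || !is.numeric(rfd) || rfd <= 0) {
    stop_named("vegrisk_missing_rfd_error",
               "no positive oral reference dose",
               if (!is.null(metal)) paste0(" for metal ", metal) else "")
  }
  if (!is.numeric(edi) || anyNA(edi) || any(edi < 0)) {
    stop_named("vegrisk_domain_error", "`edi` must be numeric and >= 0")
  }
  edi * scenario$ef * scenario$ed / (rfd * scenario$at) * 1e-3
}

#' Hazard index (HI)
#'
#' Cumulative non-carcinogenic risk: the sum of target hazard quotients over
#' co-occurring contaminants. HI > 1 indicates that adverse health effects
#' from combined exposure are likely.
#'
#' @param thqs Named numeric vector of THQs (>= 1 entry).
#' @return A list with `hi` (the sum) and `exceeds` (`hi > 1`).
#' @export
hazard_index <- function(thqs) {
  if (!is.numeric(thqs) || length(thqs) == 0L) {
    stop_named("vegrisk_domain_error", "at least one THQ is required")
  }
  hi <- sum(thqs)
  list(hi = hi, exceeds = hi > 1)
}

# The seven elements for which the survey computes hazard quotients.
HI_METALS <- c("Mn", "Fe", "Cu", "Zn", "As", "Cd", "Pb")

#' Compute the full deterministic risk table
#'
#' Per sample and metal, the estimated daily intake and target hazard
#' quotient; per sample, the hazard index over `metals`. By default the
#' metal set is the seven elements with USEPA oral reference doses
#' (Mn, Fe, Cu, Zn, As, Cd, Pb).
#'
#' All arithmetic is carried at full precision. Published risk tables often
#' sum hazard quotients that were rounded to two decimals for display;
#' `round_thq` reproduces that convention (the HI is then the sum of the
#' rounded THQs) and is `NULL` (off) by default.
#'
#' @param table A [concentration_table()].
#' @param registry A metal registry supplying oral reference doses.
#' @param scenario An [exposure_scenario()].
#' @param metals Metals entering THQ/HI; all must carry an RfD and be
#'   present in `table`.
#' @param round_thq `NULL`, or the number of decimals THQs are rounded to
#'   before the HI summation.
#'
#' @return A list of class `"risk_table"`: `edi` and `thq` are sample x
#'   metal matrices, `hi` a named vector, plus `hi_exceeds`, `scenario` and
#'   `metals`.
#' @export
#' @examples
#' risk <- compute_risk_table(table1_fixture())
#' round(risk$hi[["LS4A"]], 2) # 12.15
compute_risk_table <- function(table, registry = builtin_registry(),
                               scenario = exposure_scenario(),
                               metals = HI_METALS, round_thq = NULL) {
  stopifnot(inherits(table, "concentration_table"))
  missing_m <- setdiff(metals, table_metals(table))
  if (length(missing_m)) {
    stop_named("vegrisk_missing_metal_error",
               "metal(s) not in table: ", paste(missing_m, collapse = ", "))
  }
  missing_r <- setdiff(metals, names(registry))
  if (length(missing_r)) {
    stop_named("vegrisk_missing_metal_error",
               "metal(s) not in registry: ", paste(missing_r, collapse = ", "))
  }
  edi <- sapply(metals, function(m) {
    estimated_daily_intake(table[[m]], scenario)
  })
  edi <- matrix(edi, nrow = nrow(table),
                dimnames = list(table$sample, metals))
  thq <- sapply(metals, function(m) {
    target_hazard_quotient(edi[, m], registry[[m]]$rfd, scenario, metal = m)
  })
  thq <- matrix(thq, nrow = nrow(table),
                dimnames = list(table$sample, metals))
  thq_for_hi <- if (is.null(round_thq)) thq else round(thq, round_thq)
  hi <- rowSums(thq_for_hi)
  structure(list(edi = edi, thq = thq, hi = hi, hi_exceeds = hi > 1,
                 site = setNames(table$site, table$sample),
                 scenario = scenario, metals = metals,
                 round_thq = round_thq),
            class = "risk_table")
}

#' @export
print.risk_table <- function(x, ...) {
  cat("Risk table: ", nrow(x$edi), " samples x ", length(x$metals),
      " metals (", paste(x$metals, collapse = ", "), ")\n", sep = "")
  cat("HI range: ", round(min(x$hi), 2), "-", round(max(x$hi), 2),
      "; samples with HI > 1: ", sum(x$hi_exceeds), "/", length(x$hi),
      "\n", sep = "")
  invisible(x)
}

#' Flatten a risk table for export
#'
#' Long format mirroring the survey's published layout: one row per sample
#' and metal with EDI and THQ (full precision rounded to `digits`), the
#' per-sample HI repeated on each row.
#'
#' @param x A `"risk_table"`.
#' @param digits Decimals for the exported values (default 2).
#' @param ... Unused.
#' @return A data.frame with columns `sample`, `site`, `metal`, `edi`,
#'   `thq`, `hi`.
#' @export
as.data.frame.risk_table <- function(x, digits = 2, ...) {
  rows <- expand.grid(metal = x$metals, sample = rownames(x$edi),
                      stringsAsFactors = FALSE)[, 2:1]
  data.frame(sample = rows$sample,
             site = unname(x$site[rows$sample]),
             metal = rows$metal,
             edi = round(x$edi[cbind(rows$sample, rows$metal)], digits),
             thq = round(x$thq[cbind(rows$sample, rows$metal)], digits),
             hi = round(unname(x$hi[rows$sample]), digits),
             row.names = NULL)
}

#' Screen site-maximum concentrations against food limits
#'
#' For every registry metal carrying a maximum permissible concentration,
#' the maximum concentration over the selected samples, the fold ratio
#' (maximum / limit) and whether the limit is exceeded (fold > 1, strict).
#'
#' @param table A [concentration_table()].
#' @param registry A metal registry with `food_limit` entries.
#' @param site Optional site label to restrict the sample set.
#' @return A data.frame of class `"exceedance_report"` with columns `metal`,
#'   `max_conc`, `food_limit`, `fold`, `exceeds`.
#' @export
#' @examples
#' rep <- exceedance_report(table1_fixture())
#' rep[rep$metal == "Cd", "fold"] # 29.5
exceedance_report <- function(table, registry = builtin_registry(),
                              site = NULL) {
  stopifnot(inherits(table, "concentration_table"))
  if (!is.null(site)) table <- table[table$site %in% site, , drop = FALSE]
  if (nrow(table) == 0L) {
    stop_named("vegrisk_domain_error", "no samples selected")
  }
  limits <- registry_field(registry, "food_limit")
  metals <- intersect(table_metals(table), names(limits))
  if (!length(metals)) {
    stop_named("vegrisk_domain_error", "no table metal carries a food limit")
  }
  mx <- vapply(metals, function(m) max(table[[m]]), numeric(1))
  fold <- mx / limits[metals]
  out <- data.frame(metal = metals, max_conc = unname(mx),
                    food_limit = unname(limits[metals]),
                    fold = unname(fold), exceeds = unname(fold > 1),
                    row.names = NULL)
  class(out) <- c("exceedance_report", "data.frame")
  out
}

#' Per-site hazard-index summary
#'
#' @param risk A `"risk_table"`.
#' @param site Site label present in the risk table.
#' @return A list with `min`, `max`, `mean`, `n` over that site's HI values.
#' @export
#' @examples
#' risk <- compute_risk_table(table1_fixture())
#' site_summary(risk, "Lutendele")$min # 4.84...
site_summary <- function(risk, site) {
  stopifnot(inherits(risk, "risk_table"))
  hi <- risk$hi[risk$site == site]
  if (!length(hi)) {
    stop_named("vegrisk_unknown_site_error", "no samples for site '", site, "'")
  }
  list(min = min(hi), max = max(hi), mean = mean(hi), n = length(hi))
}
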