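#' Concentration table
#'
#' The central data container: one row per foodstuff sample, one numeric
#' column per metal, concentrations in mg/kg dry weight, plus a sample
#' identifier and a site label. An optional per-metal limit-of-detection
#' (LOD) map travels with the table as an attribute; values printed as 0.0
#' in the source survey are below-LOD reports and are stored as 0.0.
#'
#' @param samples Character vector of unique sample identifiers.
#' @param site Character vector of site labels, recycled if length 1.
#' @param concentrations Numeric matrix or data.frame, one column per metal
#'   (named), one row per sample; all values finite and >= 0.
#' @param lod Optional named numeric vector of detection limits, mg/kg.
#'
#' @return A data.frame of class `"concentration_table"` with columns
#'   `sample`, `site`, then one column per metal, and attribute `lod`.
#' @export
concentration_table <- function(samples, site, concentrations, lod = NULL) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) {
    stop_named("vegrisk_duplicate_sample_error", "duplicate sample ids: ",
               paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  conc <- as.data.frame(concentrations, check.names = FALSE)
  if (nrow(conc) != length(samples)) {
    stop_named("vegrisk_table_error", "concentrations must have one row per sample")
  }
  if (is.null(names(conc)) || !all(nzchar(names(conc)))) {
    stop_named("vegrisk_table_error", "every metal column must be named")
  }
  for (m in names(conc)) {
    x <- conc[[m]]
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
      stop_named("vegrisk_parse_error", "non-numeric concentration in column ", m)
    }
    if (any(x < 0)) {
      bad <- samples[which(x < 0)[1]]
      stop_named("vegrisk_negative_concentration_error",
                 "negative concentration at sample ", bad, ", metal ", m)
    }
  }
  if (!is.null(lod)) {
    if (is.null(names(lod)) || !is.numeric(lod)) {
      stop_named("vegrisk_table_error", "`lod` must be a named numeric vector")
    }
    lod <- lod[!is.na(lod)]
  }
  out <- cbind(data.frame(sample = samples,
                          site = rep_len(as.character(site), length(samples)),
                          stringsAsFactors = FALSE),
               conc)
  attr(out, "lod") <- lod
  class(out) <- c("concentration_table", "data.frame")
  out
}

#' @export
print.concentration_table <- function(x, ...) {
  cat("Concentration table: ", nrow(x), " samples, ",
      length(table_metals(x)), " metals; sites: ",
      paste(sprintf("%s (n=%d)", names(table(x$site)), as.integer(table(x$site))),
            collapse = ", "), "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Metals present in a concentration table
#' @param table A `concentration_table`.
#' @return Character vector of metal column names, in column order.
#' @export
table_metals <- function(table) {
  setdiff(names(table), c("sample", "site"))
}

#' Read a concentration table from delimited text
#'
#' Expects a header row with a sample-identifier column, an optional site
#' column, and one numeric column per metal. When no site column is present
#' the site is inferred from the sample-id prefix through `site_prefixes`
#' (default: ids starting `CS` are Cecomaf, `LS` Lutendele), so survey tables
#' can be stored verbatim without an extra column. A column literally named
#' `site` is always treated as the site column, so tables written by
#' [write_concentration_table()] read back unchanged.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator (default comma).
#' @param dec Decimal mark; set `","` for comma-decimal files.
#' @param sample_col Name of the sample-identifier column (default
#'   `"sample"`).
#' @param site_col Name of the site column if one exists, else `NULL` to
#'   infer from prefixes.
#' @param site_prefixes Named character vector mapping id prefix to site
#'   label, used when `site_col` is `NULL`.
#' @param lod Optional named numeric vector of detection limits to attach.
#'
#' @return A [concentration_table()].
#' @export
read_concentration_table <- function(path, sep = ",", dec = ".",
                                     sample_col = "sample", site_col = NULL,
                                     site_prefixes = c(CS = "Cecomaf", LS = "Lutendele"),
                                     lod = NULL) {
  raw <- read.csv(path, sep = sep, dec = dec, check.names = FALSE,
                  colClasses = "character", strip.white = TRUE)
  if (!sample_col %in% names(raw)) {
    stop_named("vegrisk_missing_sample_col_error",
               "no sample-identifier column '", sample_col, "' in ", path)
  }
  samples <- raw[[sample_col]]
  if (is.null(site_col) && "site" %in% names(raw)) site_col <- "site"
  if (!is.null(site_col)) {
    if (!site_col %in% names(raw)) {
      stop_named("vegrisk_table_error", "site column '", site_col, "' not found")
    }
    site <- raw[[site_col]]
    metal_cols <- setdiff(names(raw), c(sample_col, site_col))
  } else {
    site <- rep(NA_character_, length(samples))
    for (p in names(site_prefixes)) {
      site[startsWith(samples, p)] <- site_prefixes[[p]]
    }
    site[is.na(site)] <- "unknown"
    metal_cols <- setdiff(names(raw), sample_col)
  }
  conc <- lapply(metal_cols, function(m) {
    txt <- raw[[m]]
    if (dec != ".") txt <- gsub(dec, ".", txt, fixed = TRUE)
    x <- suppressWarnings(as.numeric(txt))
    if (anyNA(x)) {
      i <- which(is.na(x))[1]
      stop_named("vegrisk_parse_error", "non-numeric value '", txt[i],
                 "' at row ", i, " (sample ", samples[i], "), column ", m)
    }
    if (any(x < 0)) {
      i <- which(x < 0)[1]
      stop_named("vegrisk_negative_concentration_error",
                 "negative concentration at row ", i, ", column ", m)
    }
    x
  })
  names(conc) <- metal_cols
  concentration_table(samples, site, as.data.frame(conc, check.names = FALSE),
                      lod = lod)
}

#' Write a concentration table to CSV
#'
#' Inverse of [read_concentration_table()]: a written table reads back
#' field-for-field identical (the site column is written explicitly).
#'
#' @param table A `concentration_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged survey dataset: trace elements in Brassica pekinensis leaves
#'
#' The full 19-sample x 19-metal concentration table (mg/kg dry weight) from
#' a survey of two urban gardening sites in Kinshasa: 11 samples from
#' Cecomaf (ids `CS*`) and 8 from Lutendele (ids `LS*`), together with the
#' instrument limits of detection reported for the first 13 elements.
#' Below-LOD measurements are stored as 0.0, exactly as published.
#'
#' @return A [concentration_table()] with 19 rows, metals Ti, V, Cr, Mn, Fe,
#'   Co, Ni, Cu, Zn, As, Se, Mo, Ag, Cd, Sn, Sb, Ba, Pb, Hg, and an `lod`
#'   attribute.
#' @export
#' @examples
#' tab <- table1_fixture()
#' tab[tab$sample == "CS2P", "Cu"] # 115.39
table1_fixture <- function() {
  conc_path <- system.file("extdata", "table1_concentrations.csv",
                           package = "vegrisk", mustWork = TRUE)
  lod_path <- system.file("extdata", "table1_lod.csv",
                          package = "vegrisk", mustWork = TRUE)
  lod_df <- read.csv(lod_path)
  read_concentration_table(conc_path,
                           lod = setNames(lod_df$lod, lod_df$metal))
}

#' Exposure scenario
#'
#' The deterministic intake parameters: daily ingestion rate of the
#' foodstuff, consumer body weight, and the chronic-exposure time terms of
#' the hazard-quotient formula. Defaults describe an adult resident of the
#' surveyed area eating 60 g/day at 58 kg body weight over a 70-year
#' lifetime (exposure frequency 365 d/y, averaging time 25550 d), under
#' which the time terms cancel.
#'
#' @param dir Daily ingestion rate, g/day.
#' @param bw Body weight, kg.
#' @param ef Exposure frequency, days/year (<= 366).
#' @param ed Exposure duration, years.
#' @param at Averaging time, days.
#'
#' @return A list of class `"exposure_scenario"`.
#' @export
exposure_scenario <- function(dir = 60, bw = 58, ef = 365, ed = 70,
                              at = 25550) {
  for (nm in c("dir", "bw", "ef", "ed", "at")) {
    check_positive_scalar(get(nm), nm)
  }
  if (ef > 366) {
    stop_named("vegrisk_domain_error", "`ef` cannot exceed 366 days/year")
  }
  structure(list(dir = dir, bw = bw, ef = ef, ed = ed, at = at),
            class = "exposure_scenario")
}

#' Read an exposure scenario from a YAML config file
#'
#' Keys `dir`, `bw`, `ef`, `ed`, `at`; absent keys keep their defaults.
#'
#' @param path YAML file path.
#' @return An [exposure_scenario()].
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  keep <- intersect(names(cfg), c("dir", "bw", "ef", "ed", "at"))
  do.call(exposure_scenario, cfg[keep])
}
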