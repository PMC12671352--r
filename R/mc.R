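#' Distribution specification
#'
#' A small declarative description of a sampling distribution used by the
#' Monte Carlo exposure module, optionally truncated by rejection.
#' Families and their parameters:
#' \describe{
#'   \item{lognormal}{`meanlog`, `sdlog` (log-scale mean and sd, `sdlog >= 0`)}
#'   \item{normal}{`mean`, `sd` (`sd >= 0`)}
#'   \item{triangular}{`min`, `mode`, `max` (`min <= mode <= max`, `min < max`)}
#'   \item{point}{`value` (a degenerate point mass)}
#'   \item{empirical}{`values` (resampled with replacement)}
#' }
#'
#' @param family One of `"lognormal"`, `"normal"`, `"triangular"`,
#'   `"point"`, `"empirical"`.
#' @param ... Family parameters, named as above.
#' @param lower,upper Optional truncation bounds in the variable's units.
#' @return A list of class `"dist_spec"`.
#' @export
#' @examples
#' dist_spec("lognormal", meanlog = 0, sdlog = 1)
#' dist_spec("normal", mean = 58, sd = 10, lower = 20)
dist_spec <- function(family = c("lognormal", "normal", "triangular",
                                "point", "empirical"),
                      ..., lower = -Inf, upper = Inf) {
  family <- match.arg(family)
  pars <- list(...)
  bad <- function(msg) stop_named("vegrisk_config_error",
                                  family, " spec invalid: ", msg)
  need <- function(nms) {
    if (!all(nms %in% names(pars))) {
      bad(paste("needs parameters", paste(nms, collapse = ", ")))
    }
  }
  switch(family,
    lognormal = { need(c("meanlog", "sdlog"))
                  if (pars$sdlog < 0) bad("sdlog < 0") },
    normal = { need(c("mean", "sd")); if (pars$sd < 0) bad("sd < 0") },
    triangular = { need(c("min", "mode", "max"))
                   if (!(pars$min <= pars$mode && pars$mode <= pars$max &&
                         pars$min < pars$max)) bad("min <= mode <= max violated") },
    point = need("value"),
    empirical = { need("values")
                  if (!length(pars$values)) bad("empty value set") })
  if (lower >= upper) bad("truncation bounds not ordered")
  structure(list(family = family, pars = pars, lower = lower, upper = upper),
            class = "dist_spec")
}

# Draw n values from a dist_spec; truncation by rejection (resample the
# rejected positions until all accepted). Deterministic under a fixed RNG
# state.
draw_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$pars
  raw <- function(k) switch(spec$family,
    lognormal = exp(rnorm(k, p$meanlog, p$sdlog)),
    normal = rnorm(k, p$mean, p$sd),
    triangular = {
      u <- runif(k)
      fc <- (p$mode - p$min) / (p$max - p$min)
      ifelse(u < fc,
             p$min + sqrt(u * (p$max - p$min) * (p$mode - p$min)),
             p$max - sqrt((1 - u) * (p$max - p$min) * (p$max - p$mode)))
    },
    point = rep(p$value, k),
    empirical = p$values[sample.int(length(p$values), k, replace = TRUE)])
  x <- raw(n)
  if (is.finite(spec$lower) || is.finite(spec$upper)) {
    for (it in seq_len(10000)) {
      reject <- which(x <= spec$lower | x >= spec$upper)
      if (!length(reject)) break
      if (spec$family == "point") {
        stop_named("vegrisk_config_error",
                   "point mass lies outside its truncation bounds")
      }
      x[reject] <- raw(length(reject))
    }
    if (any(x <= spec$lower | x >= spec$upper)) {
      stop_named("vegrisk_config_error",
                 "rejection sampling failed to satisfy truncation bounds")
    }
  }
  x
}

#' Population model for exposure simulation
#'
#' A mixture of consumer strata (e.g. age/sex groups), each with its own
#' body-weight and ingestion-rate distributions. Proportions must sum to 1.
#'
#' @param strata A list; each element a list with `label`, `proportion`,
#'   `bw_dist` (a [dist_spec()], kg) and `dir_dist` (a [dist_spec()], g/day).
#' @return A list of class `"population_model"`.
#' @export
population_model <- function(strata) {
  if (!length(strata)) stop_named("vegrisk_config_error", "no strata")
  props <- vapply(strata, `[[`, numeric(1), "proportion")
  if (any(props <= 0) || abs(sum(props) - 1) > 1e-9) {
    stop_named("vegrisk_config_error",
               "stratum proportions must be positive and sum to 1")
  }
  for (s in strata) {
    if (!inherits(s$bw_dist, "dist_spec") || !inherits(s$dir_dist, "dist_spec")) {
      stop_named("vegrisk_config_error",
                 "every stratum needs bw_dist and dir_dist dist_spec objects")
    }
  }
  structure(list(strata = strata), class = "population_model")
}

#' Default illustrative consumer population
#'
#' Three strata: adult men (35 %, body weight normal(65, 10) kg), adult
#' women (40 %, normal(58, 10) kg) and children (25 %, normal(25, 8) kg),
#' with leafy-vegetable ingestion normal(60, 15) g/day for adults and
#' normal(40, 12) g/day for children, truncated to physical ranges
#' (adult bw > 20 kg, child bw > 5 kg, intake > 0). These are illustrative
#' defaults for a population whose survey did not publish its
#' distributional assumptions; override for any real assessment.
#'
#' @return A [population_model()].
#' @export
default_population_model <- function() {
  population_model(list(
    list(label = "adult_male", proportion = 0.35,
         bw_dist = dist_spec("normal", mean = 65, sd = 10, lower = 20),
         dir_dist = dist_spec("normal", mean = 60, sd = 15, lower = 0)),
    list(label = "adult_female", proportion = 0.40,
         bw_dist = dist_spec("normal", mean = 58, sd = 10, lower = 20),
         dir_dist = dist_spec("normal", mean = 60, sd = 15, lower = 0)),
    list(label = "child", proportion = 0.25,
         bw_dist = dist_spec("normal", mean = 25, sd = 8, lower = 5),
         dir_dist = dist_spec("normal", mean = 40, sd = 12, lower = 0))
  ))
}

#' Monte Carlo configuration
#'
#' @param conc_dist Named list (by metal) of [dist_spec()] objects for
#'   concentrations, mg/kg.
#' @param limits Named numeric vector of intake limits, ug/kg bw/day; every
#'   simulated metal must have one.
#' @param population A [population_model()].
#' @param n_iter Iteration count (>= 1, default 10000).
#' @param seed Integer seed.
#' @return A list of class `"mc_config"`.
#' @export
mc_config <- function(conc_dist, limits, population = default_population_model(),
                      n_iter = 10000, seed = 1) {
  if (!length(conc_dist) || is.null(names(conc_dist))) {
    stop_named("vegrisk_config_error", "conc_dist must be a named list")
  }
  for (m in names(conc_dist)) {
    if (!inherits(conc_dist[[m]], "dist_spec")) {
      stop_named("vegrisk_config_error", "conc_dist[['", m, "']] is not a dist_spec")
    }
  }
  missing_l <- setdiff(names(conc_dist), names(limits))
  if (length(missing_l)) {
    stop_named("vegrisk_config_error", "no intake limit for: ",
               paste(missing_l, collapse = ", "))
  }
  if (!is.numeric(n_iter) || n_iter < 1) {
    stop_named("vegrisk_config_error", "n_iter must be >= 1")
  }
  structure(list(conc_dist = conc_dist,
                 limits = limits[names(conc_dist)],
                 population = population,
                 n_iter = as.integer(n_iter), seed = seed),
            class = "mc_config")
}

#' Fit lognormal concentration distributions from survey data
#'
#' Per metal, a lognormal spec from the mean and standard deviation of the
#' log observations. Zeros (below-LOD reports) are replaced by LOD/2 before
#' log-fitting when the table carries an LOD for that metal; metals with
#' fewer than 3 positive observations after substitution are skipped with a
#' warning. A metal whose observations are all identical degenerates to a
#' point spec.
#'
#' @param table A [concentration_table()].
#' @param metals Metals to fit (default [HI_METALS]).
#' @param site Optional site restriction; default pools all samples.
#' @return Named list of [dist_spec()] objects.
#' @export
fit_concentration_dists <- function(table, metals = HI_METALS, site = NULL) {
  stopifnot(inherits(table, "concentration_table"))
  if (!is.null(site)) table <- table[table$site %in% site, , drop = FALSE]
  lod <- attr(table, "lod")
  out <- list()
  for (m in metals) {
    if (!m %in% table_metals(table)) {
      stop_named("vegrisk_missing_metal_error", "metal not in table: ", m)
    }
    x <- table[[m]]
    if (any(x == 0) && !is.null(lod) && m %in% names(lod) && lod[[m]] > 0) {
      x[x == 0] <- lod[[m]] / 2
    }
    x <- x[x > 0]
    if (length(x) < 3) {
      warning("metal ", m, " skipped: fewer than 3 positive observations",
              call. = FALSE)
      next
    }
    lx <- log(x)
    if (sd(lx) == 0) {
      out[[m]] <- dist_spec("point", value = x[1])
    } else {
      out[[m]] <- dist_spec("lognormal", meanlog = mean(lx), sdlog = sd(lx))
    }
  }
  out
}

#' Run the Monte Carlo dietary-exposure simulation
#'
#' Each iteration draws a consumer stratum by its population proportion, a
#' body weight and ingestion rate from that stratum, and one concentration
#' per metal; the estimated daily intake `EDI = C * DIR / BW` is then
#' compared with the metal's intake limit. The exceedance probability is
#' the fraction of iterations with `EDI > limit`, with binomial Monte Carlo
#' standard error `sqrt(p (1 - p) / n_iter)`.
#'
#' One RNG stream keyed by `config$seed` is used, with a fixed draw order
#' (stratum assignments, then per-stratum body weights and ingestion rates
#' in stratum order, then each metal in config order), so identical configs
#' give bit-identical results.
#'
#' @param config An [mc_config()].
#' @return A list of class `"mc_result"`: `summary` (data.frame per metal:
#'   mean, sd, 2.5/50/97.5 % quantiles of simulated EDI, `exceedance_prob`,
#'   `mc_se`), `edi` (the draw matrix), `strata` (labels per iteration),
#'   `config`.
#' @export
#' @examples
#' cfg <- mc_config(
#'   conc_dist = list(Cd = dist_spec("lognormal", meanlog = 0, sdlog = 1)),
#'   limits = c(Cd = 1), n_iter = 2000, seed = 42)
#' run_simulation(cfg)$summary
run_simulation <- function(config) {
  stopifnot(inherits(config, "mc_config"))
  n <- config$n_iter
  strata <- config$population$strata
  props <- vapply(strata, `[[`, numeric(1), "proportion")
  labels <- vapply(strata, `[[`, character(1), "label")
  metals <- names(config$conc_dist)
  res <- with_seed(config$seed, {
    idx <- sample.int(length(strata), n, replace = TRUE, prob = props)
    bw <- numeric(n)
    dir <- numeric(n)
    for (s in seq_along(strata)) {
      pos <- which(idx == s)
      if (!length(pos)) next
      bw[pos] <- draw_dist(strata[[s]]$bw_dist, length(pos))
      dir[pos] <- draw_dist(strata[[s]]$dir_dist, length(pos))
    }
    conc <- sapply(metals, function(m) draw_dist(config$conc_dist[[m]], n))
    conc <- matrix(conc, nrow = n, dimnames = list(NULL, metals))
    list(idx = idx, bw = bw, dir = dir, conc = conc)
  })
  scen_per_draw <- res$conc * res$dir / res$bw  # vectorised EDI, ug/kg bw/day
  edi <- matrix(scen_per_draw, nrow = n, dimnames = list(NULL, metals))
  summ <- do.call(rbind, lapply(metals, function(m) {
    x <- edi[, m]
    p <- mean(x > config$limits[[m]])
    data.frame(metal = m, limit = config$limits[[m]],
               mean = mean(x), sd = sd(x),
               q2.5 = unname(quantile(x, 0.025)),
               median = unname(quantile(x, 0.5)),
               q97.5 = unname(quantile(x, 0.975)),
               exceedance_prob = p,
               mc_se = sqrt(p * (1 - p) / n))
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, edi = edi,
                 strata = labels[res$idx], config = config),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat("Monte Carlo exposure simulation: ", x$config$n_iter,
      " iterations, seed ", x$config$seed, "\n", sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Exceedance report rows from a simulation result
#'
#' One row per metal with the intake limit and the exceedance probability
#' formatted as a percentage at one decimal. Rows follow the conventional
#' reporting order Mn, Fe, Cu, Zn, As, Cd, Pb where those metals are
#' present; any others follow in config order.
#'
#' @param result An `"mc_result"`.
#' @return A data.frame with columns `metal`, `limit`, `probability_pct`,
#'   `probability_label`.
#' @export
exceedance_table <- function(result) {
  stopifnot(inherits(result, "mc_result"))
  s <- result$summary
  ord <- order(match(s$metal, HI_METALS, nomatch = length(HI_METALS) + 1))
  s <- s[ord, ]
  pct <- round(100 * s$exceedance_prob, 1)
  data.frame(metal = s$metal, limit = s$limit, probability_pct = pct,
             probability_label = paste0(formatC(pct, format = "fg"), " %"),
             row.names = NULL)
}

#' Histogram data of simulated intakes for one metal
#'
#' Bin the simulated EDI draws for export (`bin_left`, `bin_right`,
#' `count`), mirroring the usual published exposure histograms.
#'
#' @param result An `"mc_result"`.
#' @param metal Metal symbol present in the result.
#' @param breaks Number of bins (default 40).
#' @return A data.frame with columns `bin_left`, `bin_right`, `count`.
#' @export
mc_histogram <- function(result, metal, breaks = 40) {
  stopifnot(inherits(result, "mc_result"))
  if (!metal %in% colnames(result$edi)) {
    stop_named("vegrisk_missing_metal_error", "metal not simulated: ", metal)
  }
  h <- graphics::hist(result$edi[, metal], breaks = breaks, plot = FALSE)
  data.frame(bin_left = h$breaks[-length(h$breaks)],
             bin_right = h$breaks[-1], count = h$counts)
}

#' Read a Monte Carlo configuration from YAML
#'
#' Expected keys: `n_iter`, `seed`, `limits` (map metal -> ug/kg bw/day),
#' `distributions` (map metal -> `{family, <parameters>, lower, upper}`),
#' optional `strata` (list of `{label, proportion, bw: {...}, dir: {...}}`).
#'
#' @param path YAML file path.
#' @return An [mc_config()].
#' @export
read_mc_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_spec <- function(d) {
    fam <- d$family
    d$family <- NULL
    lower <- if (!is.null(d$lower)) d$lower else -Inf
    upper <- if (!is.null(d$upper)) d$upper else Inf
    d$lower <- NULL; d$upper <- NULL
    do.call(dist_spec, c(list(family = fam), d, list(lower = lower, upper = upper)))
  }
  conc <- lapply(cfg$distributions, as_spec)
  pop <- if (is.null(cfg$strata)) default_population_model() else {
    population_model(lapply(cfg$strata, function(s) {
      list(label = s$label, proportion = s$proportion,
           bw_dist = as_spec(s$bw), dir_dist = as_spec(s$dir))
    }))
  }
  mc_config(conc_dist = conc, limits = unlist(cfg$limits), population = pop,
            n_iter = if (is.null(cfg$n_iter)) 10000 else cfg$n_iter,
            seed = if (is.null(cfg$seed)) 1 else cfg$seed)
}
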