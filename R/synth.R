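#' Synthetic survey specification
#'
#' Describes a ground-truth generative model for concentration tables:
#' per-site sample counts, lognormal marginals per metal (log-scale mean and
#' sd), and optional pairwise rank-correlation targets realised through a
#' joint latent Gaussian (a Gaussian copula). The latent correlation matrix
#' is built from the targets with the standard conversion
#' `r_latent = 2 sin(pi rho_s / 6)` so the resulting sample Spearman
#' correlation approximates each target, and must be positive definite.
#'
#' @param sites A named integer vector: site label -> number of samples.
#' @param metals A data.frame with columns `symbol`, `log_mean`, `log_sd`
#'   (`log_sd >= 0`), applied at every site; or a named list of such frames
#'   keyed by site label for site-specific marginals.
#' @param rank_dependence Optional data.frame with columns `metal_a`,
#'   `metal_b`, `rho` (`|rho| < 1`): target Spearman correlations.
#' @param lod Optional named numeric vector; generated values below a
#'   metal's LOD are reported as 0.0, matching survey convention.
#' @param seed Integer seed.
#' @return A list of class `"synth_spec"`.
#' @export
#' @examples
#' synth_spec(sites = c(SA = 10),
#'            metals = data.frame(symbol = c("Cr", "As"),
#'                                log_mean = c(0.5, -2), log_sd = c(0.6, 0.5)),
#'            rank_dependence = data.frame(metal_a = "Cr", metal_b = "As",
#'                                         rho = 0.9))
synth_spec <- function(sites, metals, rank_dependence = NULL, lod = NULL,
                       seed = 1) {
  if (is.null(names(sites)) || any(sites < 1)) {
    stop_named("vegrisk_config_error",
               "`sites` must be a named vector of counts >= 1")
  }
  site_metals <- if (is.data.frame(metals)) {
    setNames(rep(list(metals), length(sites)), names(sites))
  } else metals
  if (!setequal(names(site_metals), names(sites))) {
    stop_named("vegrisk_config_error", "metals list must cover every site")
  }
  symbols <- unique(unlist(lapply(site_metals, `[[`, "symbol")))
  for (mdf in site_metals) {
    if (!all(c("symbol", "log_mean", "log_sd") %in% names(mdf)) ||
        any(mdf$log_sd < 0)) {
      stop_named("vegrisk_config_error",
                 "metals need columns symbol, log_mean, log_sd (log_sd >= 0)")
    }
  }
  sigma <- diag(length(symbols))
  dimnames(sigma) <- list(symbols, symbols)
  if (!is.null(rank_dependence)) {
    for (i in seq_len(nrow(rank_dependence))) {
      a <- rank_dependence$metal_a[i]
      b <- rank_dependence$metal_b[i]
      rho <- rank_dependence$rho[i]
      if (abs(rho) >= 1 || !all(c(a, b) %in% symbols)) {
        stop_named("vegrisk_config_error",
                   "rank_dependence rows need known metals and |rho| < 1")
      }
      sigma[a, b] <- sigma[b, a] <- 2 * sin(pi * rho / 6)
    }
    pd <- tryCatch({ chol(sigma); TRUE }, error = function(e) FALSE)
    if (!pd) {
      stop_named("vegrisk_copula_error",
                 "latent correlation matrix is not positive definite")
    }
  }
  structure(list(sites = sites, site_metals = site_metals,
                 symbols = symbols, latent_sigma = sigma,
                 rank_dependence = rank_dependence, lod = lod, seed = seed),
            class = "synth_spec")
}

#' Generate a synthetic concentration table
#'
#' Draws each site's samples as `exp(mu + sigma * Z)` per metal, where `Z`
#' is a latent standard Gaussian vector correlated according to the spec's
#' copula. Sample ids are `<SITE><k>`. Values below the spec's LOD map are
#' reported as 0.0, and the LOD map is attached to the table. Identical
#' spec (including seed) gives an identical table.
#'
#' @param spec A [synth_spec()].
#' @return A [concentration_table()].
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  L <- chol(spec$latent_sigma)
  with_seed(spec$seed, {
    blocks <- lapply(names(spec$sites), function(site) {
      n <- spec$sites[[site]]
      mdf <- spec$site_metals[[site]]
      z <- matrix(rnorm(n * length(spec$symbols)), n) %*% L
      colnames(z) <- spec$symbols
      conc <- sapply(seq_len(nrow(mdf)), function(j) {
        exp(mdf$log_mean[j] + mdf$log_sd[j] * z[, mdf$symbol[j]])
      })
      conc <- matrix(conc, nrow = n, dimnames = list(NULL, mdf$symbol))
      list(samples = paste0(site, seq_len(n)), site = site, conc = conc)
    })
    conc <- do.call(rbind, lapply(blocks, `[[`, "conc"))
    if (!is.null(spec$lod)) {
      for (m in intersect(colnames(conc), names(spec$lod))) {
        conc[conc[, m] < spec$lod[[m]], m] <- 0
      }
    }
    concentration_table(unlist(lapply(blocks, `[[`, "samples")),
                        rep(names(spec$sites), spec$sites),
                        conc, lod = spec$lod)
  })
}

#' Generate a synthetic consumer population
#'
#' Draws `n` consumers from a [population_model()]: a stratum by its
#' proportion, then body weight and ingestion rate from that stratum's
#' truncated distributions.
#'
#' @param model A [population_model()].
#' @param n Number of consumers.
#' @param seed Integer seed.
#' @return A data.frame with columns `stratum`, `bw` (kg), `dir` (g/day).
#' @export
generate_population <- function(model, n, seed = 1) {
  stopifnot(inherits(model, "population_model"))
  strata <- model$strata
  props <- vapply(strata, `[[`, numeric(1), "proportion")
  labels <- vapply(strata, `[[`, character(1), "label")
  with_seed(seed, {
    idx <- sample.int(length(strata), n, replace = TRUE, prob = props)
    bw <- numeric(n)
    dir <- numeric(n)
    for (s in seq_along(strata)) {
      pos <- which(idx == s)
      if (!length(pos)) next
      bw[pos] <- draw_dist(strata[[s]]$bw_dist, length(pos))
      dir[pos] <- draw_dist(strata[[s]]$dir_dist, length(pos))
    }
    data.frame(stratum = labels[idx], bw = bw, dir = dir)
  })
}
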