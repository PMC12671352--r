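#' Mid-ranks (fractional ranks)
#'
#' Ranks a numeric vector with ties assigned the mean of the rank positions
#' they span, the convention required for tie-corrected Spearman
#' correlation. Delegates to `rank(ties.method = "average")` after checking
#' finiteness; ranks always sum to `n(n+1)/2`.
#'
#' @param x Numeric vector, all finite, length >= 1.
#' @return Numeric rank vector.
#' @export
#' @examples
#' midranks(c(1, 2, 2, 3)) # 1 2.5 2.5 4
midranks <- function(x) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) || any(!is.finite(x))) {
    stop_named("vegrisk_domain_error", "input must be finite numeric, length >= 1")
  }
  rank(x, ties.method = "average")
}

#' Tie-corrected Spearman rank correlation
#'
#' The product-moment correlation of the mid-rank vectors of `x` and `y`.
#' With no ties this equals the classical `1 - 6 * sum(d^2) / (n (n^2 - 1))`
#' formula; with ties the product-moment form is the correct (tie-corrected)
#' coefficient, and the shortcut formula is biased.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return Correlation in `[-1, 1]`.
#' @export
#' @examples
#' spearman_rho(c(1, 2, 2, 3), c(1, 2, 3, 4)) # 0.9486...
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop_named("vegrisk_domain_error", "x and y must have equal length >= 3")
  }
  rx <- midranks(x)
  ry <- midranks(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    stop_named("vegrisk_constant_input_error",
               "rank correlation undefined for a constant vector")
  }
  cor(rx, ry)
}

# All permutations of 1..n as a matrix (n! rows); used for exact tests.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Two-sided p-value for a Spearman coefficient
#'
#' Either the classical t approximation,
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom,
#' or a permutation test of the rank statistic: full enumeration of all
#' `n!` relabelings when `n <= 7`, otherwise seeded Monte Carlo sampling.
#'
#' @param rho Observed coefficient (for `method = "t-approx"`), or `NULL`
#'   when `x`/`y` are supplied for the permutation method.
#' @param n Sample size (>= 4); taken from `x` when data are given.
#' @param method `"t-approx"` (default) or `"permutation"`.
#' @param x,y Data vectors, required for `method = "permutation"`.
#' @param n_perm Monte Carlo permutation count (default 10000).
#' @param seed Seed for Monte Carlo permutations.
#' @return p-value in `[0, 1]`.
#' @export
spearman_pvalue <- function(rho = NULL, n = NULL, method = c("t-approx", "permutation"),
                            x = NULL, y = NULL, n_perm = 10000, seed = 1) {
  method <- match.arg(method)
  if (method == "t-approx") {
    if (is.null(n) && !is.null(x)) n <- length(x)
    if (is.null(rho)) rho <- spearman_rho(x, y)
    if (is.null(n) || n < 4) {
      stop_named("vegrisk_domain_error", "n >= 4 required for a p-value")
    }
    if (abs(rho) >= 1) return(0)
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    return(2 * pt(-abs(tstat), df = n - 2))
  }
  if (is.null(x) || is.null(y)) {
    stop_named("vegrisk_domain_error", "permutation method needs x and y")
  }
  n <- length(x)
  if (n < 4) stop_named("vegrisk_domain_error", "n >= 4 required for a p-value")
  rx <- midranks(x)
  ry <- midranks(y)
  obs <- abs(cor(rx, ry))
  if (n <= 7) {
    perms <- all_permutations(n)
    stat <- apply(perms, 1, function(p) abs(cor(rx, ry[p])))
    # exact: observed identity permutation is one of the n!
    mean(stat >= obs - 1e-12)
  } else {
    with_seed(seed, {
      hits <- sum(vapply(seq_len(n_perm), function(i) {
        abs(cor(rx, ry[sample.int(n)])) >= obs - 1e-12
      }, logical(1)))
      (1 + hits) / (1 + n_perm)
    })
  }
}

#' Pairwise rank-correlation matrix for one site
#'
#' Tie-corrected Spearman coefficients and two-sided p-values over all metal
#' pairs of one site's samples, with a significance mask at `alpha`.
#' Below-LOD zeros participate in ranking as zeros (ties among them get
#' mid-ranks); constant columns yield `NA` coefficients with a warning.
#'
#' @param table A [concentration_table()].
#' @param site Site label; that site must have >= 4 samples.
#' @param metals Metals to correlate (default: all table metals).
#' @param alpha Significance level for the mask (default 0.05).
#' @param method p-value method, see [spearman_pvalue()].
#' @param seed Seed used when `method = "permutation"`.
#' @return A list of class `"correlation_matrix"`: `site`, `metals`, `rho`,
#'   `p`, `significant`, `n`, `alpha`.
#' @export
#' @examples
#' cm <- correlation_matrix(table1_fixture(), "Lutendele")
#' round(cm$rho["Cr", "As"], 3) # 0.910
correlation_matrix <- function(table, site, metals = table_metals(table),
                               alpha = 0.05, method = "t-approx", seed = 1) {
  stopifnot(inherits(table, "concentration_table"))
  sub <- table[table$site == site, , drop = FALSE]
  if (nrow(sub) < 4L) {
    stop_named("vegrisk_domain_error", "site '", site, "' has fewer than 4 samples")
  }
  k <- length(metals)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(metals, metals))
  diag(rho) <- 1
  diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      xi <- sub[[metals[i]]]
      xj <- sub[[metals[j]]]
      if (sd(xi) == 0 || sd(xj) == 0) {
        warning("constant column ", metals[if (sd(xi) == 0) i else j],
                " at site ", site, "; coefficient set to NA", call. = FALSE)
        next
      }
      r <- spearman_rho(xi, xj)
      rho[i, j] <- rho[j, i] <- r
      pv <- if (method == "permutation") {
        spearman_pvalue(method = "permutation", x = xi, y = xj, seed = seed)
      } else {
        spearman_pvalue(rho = r, n = nrow(sub))
      }
      p[i, j] <- p[j, i] <- pv
    }
  }
  structure(list(site = site, metals = metals, rho = rho, p = p,
                 significant = !is.na(p) & p < alpha, n = nrow(sub),
                 alpha = alpha),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("Spearman rank-correlation matrix, site ", x$site, " (n = ", x$n,
      "), ", length(x$metals), " metals; ",
      sum(x$significant[upper.tri(x$significant)]),
      " pairs significant at alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Long-format export of a correlation matrix
#'
#' @param x A `"correlation_matrix"`.
#' @param ... Unused.
#' @return A data.frame with one row per unordered metal pair: `metal_a`,
#'   `metal_b`, `rho`, `p`, `significant`.
#' @export
as.data.frame.correlation_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  data.frame(metal_a = x$metals[idx[, 1]],
             metal_b = x$metals[idx[, 2]],
             rho = x$rho[idx],
             p = x$p[idx],
             significant = x$significant[idx],
             row.names = NULL)
}
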