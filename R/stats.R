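#' Mann-Whitney U test (rank-sum) with exact and approximate p-values
#'
#' Computes the U statistic from midranks and a two-sided p-value: by exact
#' enumeration over all group assignments of the pooled (mid)ranks when
#' `n1 + n2 <= exact_limit`, otherwise by the normal approximation with tie
#' correction and continuity correction. The exact route handles ties
#' correctly because it permutes the observed midranks themselves.
#'
#' @param x,y Numeric samples (each of length >= 1).
#' @param exact_limit Total sample size up to which exact enumeration is
#'   used (default 20).
#' @return A list of class `mann_whitney` with elements `u` (U statistic of
#'   the first sample), `p_value` (two-sided), `method` (`"exact"` or
#'   `"normal_approx"`), `degenerate` (TRUE when all pooled values are
#'   identical, in which case p = 1).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, exact_limit = 20) {
  stopifnot(length(x) >= 1, length(y) >= 1,
            all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  if (diff(range(pooled)) == 0) {
    return(structure(list(u = n1 * n2 / 2, p_value = 1,
                          method = "degenerate", degenerate = TRUE),
                     class = "mann_whitney"))
  }
  r <- rank(pooled)  # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  if (n <= exact_limit) {
    # enumerate all assignments of the observed midranks to group 1
    combs <- utils::combn(n, n1)
    r1 <- colSums(matrix(r[combs], nrow = n1))
    us <- r1 - n1 * (n1 + 1) / 2
    center <- n1 * n2 / 2
    p <- mean(abs(us - center) >= abs(u - center) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    mu <- n1 * n2 / 2
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)  # continuity correction
    p <- min(1, 2 * pnorm(z, lower.tail = FALSE))
    method <- "normal_approx"
  }
  structure(list(u = u, p_value = p, method = method, degenerate = FALSE),
            class = "mann_whitney")
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f, two-sided p = %.4g (%s)\n",
              x$u, x$p_value, x$method))
  invisible(x)
}

#' Significance tier for a p-value
#'
#' Tier mapping: `***` for p < 0.0001, `**` for p < 0.001, `*` for p < 0.01,
#' `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  dplyr::case_when(
    p < 1e-4 ~ "***",
    p < 1e-3 ~ "**",
    p < 1e-2 ~ "*",
    TRUE ~ "ns")
}

#' Compare morphometric parameters between genotype groups
#'
#' For every numeric parameter column, reports group sizes, means and sds and
#' the Mann-Whitney U test between the two genotypes, with the significance
#' tier. Observations are per-cell, pooled across patients (no clustering
#' adjustment, matching the source analysis; treat tiers accordingly).
#'
#' @param morpho Tibble of per-cell measurements (e.g. from
#'   [measure_phantom_batch()] or [measure_cell()] rows).
#' @param genotype Either a character vector aligned with `morpho` rows, or
#'   the name of a column in `morpho` holding the genotype labels.
#' @param parameters Optional character vector of parameter columns; default:
#'   all numeric columns.
#' @return A tibble with one row per parameter: n, mean, sd per group,
#'   `u`, `p_value`, `tier`.
#' @export
compare_groups <- function(morpho, genotype = "genotype",
                           parameters = NULL) {
  if (length(genotype) == 1 && genotype %in% names(morpho)) {
    glab <- as.character(morpho[[genotype]])
    morpho <- dplyr::select(morpho, -dplyr::all_of(genotype))
  } else {
    glab <- as.character(genotype)
  }
  stopifnot(length(glab) == nrow(morpho))
  lv <- unique(glab)
  if (length(lv) != 2)
    stop("exactly two genotype groups are required, got: ",
         paste(lv, collapse = ", "))
  lv <- sort(lv)  # e.g. MUT, WT
  if (is.null(parameters))
    parameters <- names(morpho)[vapply(morpho, is.numeric, TRUE)]
  rows <- lapply(parameters, function(p) {
    v <- morpho[[p]]
    x <- v[glab == lv[1] & !is.na(v)]
    y <- v[glab == lv[2] & !is.na(v)]
    if (length(x) == 0 || length(y) == 0)
      stop("a group is empty for parameter: ", p)
    mw <- mann_whitney_u(x, y)
    tibble::tibble(
      parameter = p,
      n_1 = length(x), mean_1 = mean(x), sd_1 = sd(x),
      n_2 = length(y), mean_2 = mean(y), sd_2 = sd(y),
      u = mw$u, p_value = mw$p_value, tier = significance_tier(mw$p_value))
  })
  out <- dplyr::bind_rows(rows)
  names(out) <- sub("_1$", paste0("_", lv[1]), names(out))
  names(out) <- sub("_2$", paste0("_", lv[2]), names(out))
  attr(out, "groups") <- lv
  out
}
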