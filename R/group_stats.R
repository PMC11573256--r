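#' Percent change between group means
#'
#' Signed percent change of a test group's mean relative to a reference
#' group's mean: `100 * (test - reference) / reference`.
#'
#' @param reference_mean Reference group mean (non-zero).
#' @param test_mean Test group mean.
#' @return Percent change.
#' @examples
#' percent_change(1.00, 1.44) # +44
#' @export
percent_change <- function(reference_mean, test_mean) {
  if (reference_mean == 0) stop("reference mean is zero; percent change undefined")
  100 * (test_mean - reference_mean) / reference_mean
}

#' Brown-Forsythe heteroscedastic one-way ANOVA
#'
#' Equal-means test robust to unequal group variances:
#' `F* = sum n_i (m_i - m)^2 / sum (1 - n_i/N) s_i^2`, referred to an F
#' distribution with `k - 1` and Satterthwaite-approximated (fractional)
#' denominator degrees of freedom. For two groups it reduces exactly to
#' Welch's t-test (`F* = t^2` with the Welch df).
#'
#' @param values Named list of numeric vectors, one per group (each with at
#'   least 2 observations).
#' @return List with `statistic`, `df1`, `df2`, `p.value`, `method`.
#' @export
brown_forsythe_test <- function(values) {
  values <- lapply(values, function(x) x[!is.na(x)])
  k <- length(values)
  if (k < 2) stop("need at least 2 groups")
  n <- vapply(values, length, numeric(1))
  if (any(n < 2)) stop("each group needs at least 2 observations")
  m <- vapply(values, mean, numeric(1))
  v <- vapply(values, var, numeric(1))
  N <- sum(n)
  grand <- sum(n * m) / N
  num <- sum(n * (m - grand)^2)
  ci <- (1 - n / N) * v
  den <- sum(ci)
  if (den == 0) {
    equal_means <- max(m) - min(m) == 0
    return(list(
      statistic = if (equal_means) 0 else Inf,
      df1 = k - 1, df2 = NA_real_,
      p.value = if (equal_means) 1 else 0,
      method = "Brown-Forsythe equal-means ANOVA"
    ))
  }
  fstat <- num / den
  w <- ci / den
  df2 <- 1 / sum(w^2 / (n - 1))
  list(
    statistic = fstat, df1 = k - 1, df2 = df2,
    p.value = pf(fstat, k - 1, df2, lower.tail = FALSE),
    method = "Brown-Forsythe equal-means ANOVA"
  )
}

# KS normality screen with estimated mean/sd; NA for degenerate samples.
ks_normality_p <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || sd(x) == 0) {
    return(NA_real_)
  }
  suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x))$p.value)
}

# Two-sided Mann-Whitney U. Exact for n <= 20 per group without ties,
# normal approximation with tie correction otherwise. Fully degenerate
# input (all values identical across both groups) gets p = 1 by convention.
mann_whitney <- function(x, y, exact_max = 20) {
  if (max(c(x, y)) == min(c(x, y))) {
    return(list(statistic = length(x) * length(y) / 2, p.value = 1))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) <= exact_max && length(y) <= exact_max && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}

#' Compare a metric across experimental groups
#'
#' The statistical layer applied to every per-site metric: per-group
#' Kolmogorov-Smirnov normality screening, then either the nonparametric
#' family (Kruskal-Wallis omnibus over all groups plus all pairwise
#' two-sided Mann-Whitney U tests) or the Brown-Forsythe heteroscedastic
#' ANOVA family used for receptive-field properties.
#'
#' Pairwise p values are uncorrected by default (set `p_adjust = "holm"`
#' for the conservative option).
#'
#' @param values Named list of numeric vectors, one per group, each with at
#'   least 3 non-missing observations.
#' @param metric Metric name carried into the report.
#' @param family `"nonparametric"` or `"brown_forsythe"`.
#' @param p_adjust `"none"` or `"holm"` (pairwise tests only).
#' @return An object of class `group_comparison`: list with `metric`,
#'   `family`, `groups` (n / median / mean / sd / se per group),
#'   `normality` (per-group KS p), `omnibus` (test, statistic, df, p) and,
#'   for the nonparametric family, `pairwise` (group pair, U, p).
#' @export
compare_groups <- function(values, metric = "value",
                           family = c("nonparametric", "brown_forsythe"),
                           p_adjust = c("none", "holm")) {
  family <- match.arg(family)
  p_adjust <- match.arg(p_adjust)
  if (is.null(names(values)) || any(names(values) == "")) {
    stop("values must be a named list of groups")
  }
  values <- lapply(values, function(x) x[!is.na(x)])
  n <- vapply(values, length, numeric(1))
  if (length(values) < 2) stop("need at least 2 groups")
  if (any(n < 3)) {
    stop(
      "insufficient observations in group(s): ",
      paste(names(values)[n < 3], collapse = ", ")
    )
  }
  groups <- data.frame(
    group = names(values),
    n = as.integer(n),
    median = vapply(values, median, numeric(1)),
    mean = vapply(values, mean, numeric(1)),
    sd = vapply(values, sd, numeric(1)),
    se = vapply(values, function(x) sd(x) / sqrt(length(x)), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  normality <- data.frame(
    group = names(values),
    ks_p = vapply(values, ks_normality_p, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (family == "nonparametric") {
    kw <- kruskal.test(values)
    omnibus <- list(
      test = "Kruskal-Wallis",
      statistic = unname(kw$statistic),
      df = unname(kw$parameter),
      p.value = kw$p.value
    )
    pairs <- combn(names(values), 2)
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]
      b <- pairs[2, k]
      mw <- mann_whitney(values[[a]], values[[b]])
      data.frame(
        group_a = a, group_b = b,
        U = mw$statistic, p.value = mw$p.value,
        stringsAsFactors = FALSE
      )
    })
    pairwise <- do.call(rbind, rows)
    if (p_adjust == "holm") {
      pairwise$p.adjusted <- p.adjust(pairwise$p.value, method = "holm")
    }
  } else {
    bf <- brown_forsythe_test(values)
    omnibus <- list(
      test = bf$method,
      statistic = bf$statistic,
      df = c(bf$df1, bf$df2),
      p.value = bf$p.value
    )
    pairwise <- NULL
  }
  structure(
    list(
      metric = metric, family = family, groups = groups,
      normality = normality, omnibus = omnibus, pairwise = pairwise
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("Group comparison: %s (%s family)\n", x$metric, x$family))
  print(cbind(
    x$groups[c("group", "n")],
    round(x$groups[c("median", "mean", "se")], digits)
  ), row.names = FALSE)
  df_txt <- paste(signif(x$omnibus$df, 4), collapse = ", ")
  cat(sprintf(
    "Omnibus %s: statistic = %.4g, df = %s, p = %.4g\n",
    x$omnibus$test, x$omnibus$statistic, df_txt, x$omnibus$p.value
  ))
  if (!is.null(x$pairwise)) {
    cat("Pairwise Mann-Whitney U (two-sided):\n")
    pw <- x$pairwise
    pw$p.value <- signif(pw$p.value, 3)
    print(pw, row.names = FALSE)
  }
  invisible(x)
}
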