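#' Pearson correlation with a t-based p-value
#'
#' Standard product-moment correlation; the two-sided p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @param predictor,response Optional labels carried into the result.
#' @return A one-row tibble: `predictor`, `response`, `r`, `n`, `p_value`.
#' @export
pearson <- function(x, y, predictor = "x", response = "y") {
  check_pairs(x, y)
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(predictor = predictor, response = response,
         r = unname(ct$estimate), n = length(x), p_value = ct$p.value)
}

#' Simple least-squares regression with R-squared
#'
#' @param x,y Numeric vectors of equal length >= 3; `x` non-constant.
#' @return A one-row tibble: `slope`, `intercept`, `r_squared` (defined as
#'   `1 - SS_res / SS_tot`; equals the squared Pearson correlation).
#' @export
regress <- function(x, y) {
  check_pairs(x, y, require_y_varying = FALSE)
  if (sd(y) == 0) {
    return(tibble(slope = 0, intercept = y[1], r_squared = 0))
  }
  fit <- lm(y ~ x)
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit)$r.squared)
  )
}

check_pairs <- function(x, y, require_y_varying = TRUE) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) abort("missing values not allowed")
  if (sd(x) == 0) abort("x is constant; correlation/regression undefined")
  if (require_y_varying && sd(y) == 0) {
    abort("y is constant; correlation undefined")
  }
  invisible(TRUE)
}

#' Compare two sets of correlation coefficients across strata
#'
#' Paired t-test on per-stratum differences of correlation coefficients,
#' optionally Fisher-z transformed (`atanh`) first, to test whether one
#' predictor correlates with the response more strongly than another across
#' repeated strata (e.g. locations x heterosis types).
#'
#' @param r1,r2 Numeric vectors of correlation coefficients, paired by
#'   stratum; length >= 2.
#' @param transform `"fisher_z"` (default) or `"none"`.
#' @param alternative `"two.sided"` (default), `"greater"` (`r1 > r2`) or
#'   `"less"`.
#' @return A one-row tibble: `t_statistic`, `df`, `p_value`, `mean_diff`
#'   (mean per-stratum difference on the transformed scale), `transform`.
#' @export
compare_correlations <- function(r1, r2, transform = c("fisher_z", "none"),
                                 alternative = c("two.sided", "greater", "less")) {
  transform <- match.arg(transform)
  alternative <- match.arg(alternative)
  if (length(r1) != length(r2)) abort("r1 and r2 must be paired")
  if (length(r1) < 2) abort("need at least 2 strata pairs")
  if (any(abs(c(r1, r2)) > 1)) abort("correlations must lie in [-1, 1]")
  z1 <- if (transform == "fisher_z") atanh(r1) else r1
  z2 <- if (transform == "fisher_z") atanh(r2) else r2
  d <- z1 - z2
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    t_stat <- if (m == 0) 0 else sign(m) * Inf
  } else {
    t_stat <- m / (s / sqrt(n))
  }
  p <- switch(alternative,
    two.sided = 2 * pt(-abs(t_stat), n - 1),
    greater = pt(t_stat, n - 1, lower.tail = FALSE),
    less = pt(t_stat, n - 1)
  )
  tibble(t_statistic = t_stat, df = n - 1, p_value = p, mean_diff = m,
         transform = transform)
}

#' Parent membership among the top-k crosses
#'
#' Ranks crosses by a response (yield or heterosis), takes the `k` best and
#' counts how often each parent appears among them — the breeder's check
#' that high-scoring parents dominate the best crosses.
#'
#' @param tbl Tibble keyed by `female`, `male` with the response column.
#' @param response Name of the column to rank by (default `"f1_mean"`).
#' @param k Number of top crosses.
#' @return A list with `top` (the k top rows, best first) and `parents`
#'   (tibble `parent`, `role`, `n_top` sorted by `n_top`). Ties at the
#'   cut are broken by table order, with a warning.
#' @export
top_crosses <- function(tbl, response = "f1_mean", k = 10) {
  tbl <- as_tibble(tbl)
  stopifnot(all(c("female", "male", response) %in% names(tbl)))
  if (k > nrow(tbl)) abort("k exceeds the number of crosses")
  v <- tbl[[response]]
  ord <- order(-v)
  cutoff <- v[ord][k]
  if (k < nrow(tbl) && sum(v == cutoff) > 1 && v[ord][k + 1] == cutoff) {
    warn("ties at the top-k boundary broken by table order")
  }
  top <- tbl[ord[seq_len(k)], ]
  parents <- bind_rows(
    top |> dplyr::count(parent = .data$female, name = "n_top") |>
      mutate(role = "line"),
    top |> dplyr::count(parent = .data$male, name = "n_top") |>
      mutate(role = "tester")
  ) |>
    arrange(dplyr::desc(.data$n_top)) |>
    select("parent", "role", "n_top")
  list(top = top, parents = parents)
}

#' Correlations of PEUS heterozygosity and genetic distance with heterosis
#'
#' Assembles the predictor-response correlation table: each predictor
#' (`n_het_peus`, `gd`) against each response (`mph`, `bph`), either over
#' individual crosses (`by = "none"`) or over parent means after
#' [aggregate_by_parent()] (`by = "female"` / `"male"` / `"group"`).
#'
#' @param scores [score_all()] output.
#' @param heterosis [compute_heterosis()] output (scope `"across"`), or a
#'   per-location subset already reduced to one row per cross.
#' @param by Aggregation key; `"none"` correlates over crosses directly.
#' @param parents Parent table (required for `by = "group"`).
#' @return A tibble of [pearson()] rows, one per predictor-response pair,
#'   plus [regress()] slope/intercept/R-squared columns.
#' @export
predictor_correlations <- function(scores, heterosis,
                                   by = c("none", "female", "male", "group"),
                                   parents = NULL) {
  by <- match.arg(by)
  joined <- as_tibble(scores) |>
    inner_join(select(as_tibble(heterosis), "female", "male", "mph", "bph"),
               by = c("female", "male"))
  if (nrow(joined) == 0L) abort("scores and heterosis tables share no cross")
  dat <- if (by == "none") joined else {
    aggregate_by_parent(joined, by = by, parents = parents)
  }
  grid <- tidyr::expand_grid(predictor = c("n_het_peus", "gd"),
                             response = c("mph", "bph"))
  purrr::pmap(grid, function(predictor, response) {
    x <- dat[[predictor]]
    y <- dat[[response]]
    ok <- complete.cases(x, y)
    bind_cols(
      pearson(x[ok], y[ok], predictor = predictor, response = response),
      regress(x[ok], y[ok])
    )
  }) |> bind_rows()
}
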