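#' Entry identifier for a cross
#'
#' Plot tables identify F1 entries by a single string; this is the canonical
#' encoding used throughout the package and by the simulator.
#'
#' @param female,male Parent sample identifiers.
#' @return Character vector `"female x male"`.
#' @export
cross_entry_id <- function(female, male) paste(female, male, sep = " x ")

#' Mid-parent and better-parent heterosis from plot yields
#'
#' For each cross, F1 and parent means are taken over replications (and over
#' locations when `scope = "across"`), then
#' `MPH = 100 * (F1 - MP) / MP` with `MP = (P1 + P2) / 2`, and
#' `BPH = 100 * (F1 - BP) / BP` with `BP = max(P1, P2)`.
#'
#' A cross whose mid- or better-parent mean is not positive has undefined
#' heterosis: `mph`/`bph` are `NA` and the row is flagged, never fabricated.
#'
#' @param plots Plot table: `entry_id`, `entry_type` (`F1`, `parent`,
#'   `check`), `location`, `replication`, `gy` (grain yield, t/ha).
#' @param crosses Tibble with columns `female`, `male`.
#' @param scope `"across"` (means over all locations, one row per cross) or
#'   `"per_location"` (one row per cross and location).
#' @return A tibble with `female`, `male`, `entry_id`, (`location`,)
#'   `f1_mean`, `p1_mean`, `p2_mean`, `mp`, `bp`, `mph`, `bph`, `undefined`.
#' @export
compute_heterosis <- function(plots, crosses,
                              scope = c("across", "per_location")) {
  scope <- match.arg(scope)
  plots <- as_tibble(plots)
  crosses <- as_tibble(crosses)
  stopifnot(all(c("entry_id", "entry_type", "location", "replication", "gy") %in%
                  names(plots)),
            all(c("female", "male") %in% names(crosses)))

  keys <- if (scope == "across") "entry_id" else c("entry_id", "location")
  means <- plots |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(mean_gy = mean(.data$gy), .groups = "drop")

  crosses <- crosses |> mutate(entry_id = cross_entry_id(.data$female, .data$male))
  needed <- unique(c(crosses$entry_id, crosses$female, crosses$male))
  absent <- setdiff(needed, means$entry_id)
  if (length(absent)) {
    abort(paste0("entries without plot data in requested scope: ",
                 paste(head(absent, 5), collapse = ", "),
                 if (length(absent) > 5) ", ..."))
  }

  loc_key <- if (scope == "per_location") "location" else character()
  out <- crosses |>
    left_join(rename(means, f1_mean = "mean_gy"), by = "entry_id") |>
    left_join(rename(means, p1_mean = "mean_gy"),
              by = c(c(female = "entry_id"), loc_key)) |>
    left_join(rename(means, p2_mean = "mean_gy"),
              by = c(c(male = "entry_id"), loc_key))

  out <- out |>
    mutate(
      mp = (.data$p1_mean + .data$p2_mean) / 2,
      bp = pmax(.data$p1_mean, .data$p2_mean),
      undefined = .data$mp <= 0 | .data$bp <= 0,
      mph = ifelse(.data$undefined, NA_real_, 100 * (.data$f1_mean - .data$mp) / .data$mp),
      bph = ifelse(.data$undefined, NA_real_, 100 * (.data$f1_mean - .data$bp) / .data$bp)
    )
  if (any(out$undefined)) {
    warn(paste0("heterosis undefined (non-positive parent mean) for ",
                sum(out$undefined), " cross(es)"))
  }
  cols <- c("female", "male", "entry_id",
            if (scope == "per_location") "location",
            "f1_mean", "p1_mean", "p2_mean", "mp", "bp", "mph", "bph",
            "undefined")
  out[, cols]
}

LT_SOURCES <- c("Locations (Loc)", "Replications:Loc", "Lines", "Testers (T)",
                "Lines x T", "Lines x Loc", "T x Loc", "Lines x T x Loc",
                "Error")

#' Line-by-tester analysis of variance for grain yield
#'
#' Fixed-effects decomposition of F1 plot yields from a balanced
#' line-by-tester trial grown in randomized complete blocks at several
#' locations:
#' locations, replications within locations, lines, testers, line x tester,
#' and the interactions of lines/testers/crosses with locations, against a
#' single pooled error. Every F statistic uses the Error mean square as
#' denominator (lines and testers are deliberately chosen, not sampled, so
#' no interaction term serves as a denominator).
#'
#' Sums of squares are sequential; on the balanced orthogonal designs this
#' function accepts they coincide with marginal sums of squares. Unbalanced
#' data are rejected.
#'
#' @param plots Plot table (see [compute_heterosis()]); only `F1` entries
#'   matching `crosses` enter the model.
#' @param crosses Tibble with columns `female` (line), `male` (tester).
#' @return An `lt_anova` object: a tibble with `source`, `df`, `sum_sq`,
#'   `mean_sq`, `f_value`, `p_value` in the canonical source order.
#' @export
anova_line_tester <- function(plots, crosses) {
  plots <- as_tibble(plots)
  crosses <- as_tibble(crosses) |>
    mutate(entry_id = cross_entry_id(.data$female, .data$male))
  dat <- plots |>
    filter(.data$entry_type == "F1") |>
    select("entry_id", "location", "replication", "gy") |>
    inner_join(crosses, by = "entry_id")
  if (nrow(dat) == 0L) abort("no F1 plots matching the cross design")

  counts <- dat |> dplyr::count(.data$female, .data$male, .data$location)
  n_cells <- nrow(crosses) * dplyr::n_distinct(dat$location)
  if (nrow(counts) != n_cells || dplyr::n_distinct(counts$n) != 1L) {
    abort("unbalanced design: equal replication of every cross at every location is required")
  }

  dat <- dat |>
    mutate(
      location = factor(.data$location),
      replication = factor(.data$replication),
      line = factor(.data$female),
      tester = factor(.data$male)
    )
  fit <- lm(gy ~ location + location:replication + line + tester +
              line:tester + line:location + tester:location +
              line:tester:location, data = dat)
  a <- anova(fit)
  lab <- rownames(a)
  pick <- function(term) which(lab == term)
  ord <- c(pick("location"), pick("location:replication"), pick("line"),
           pick("tester"), pick("line:tester"), pick("location:line"),
           pick("location:tester"), pick("location:line:tester"),
           pick("Residuals"))
  tbl <- tibble(
    source = LT_SOURCES,
    df = as.integer(a$Df[ord]),
    sum_sq = a$`Sum Sq`[ord],
    mean_sq = a$`Mean Sq`[ord],
    f_value = a$`F value`[ord],
    p_value = a$`Pr(>F)`[ord]
  )
  structure(tbl, class = c("lt_anova", class(tbl)),
            n_obs = nrow(dat),
            n_lines = nlevels(dat$line), n_testers = nlevels(dat$tester),
            n_locations = nlevels(dat$location),
            n_reps = counts$n[1])
}

#' @export
tidy.lt_anova <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.lt_anova <- function(x, ...) {
  err <- x[x$source == "Error", ]
  tibble(
    n_obs = attr(x, "n_obs"),
    df_error = err$df,
    ms_error = err$mean_sq,
    n_lines = attr(x, "n_lines"),
    n_testers = attr(x, "n_testers"),
    n_locations = attr(x, "n_locations"),
    n_reps = attr(x, "n_reps")
  )
}

#' Fisher's least significant difference
#'
#' `LSD = t(1 - alpha/2, df_error) * sqrt(2 * MS_error / n)`, for separating
#' means each based on `n` plots, using the pooled error of the
#' line-by-tester ANOVA.
#'
#' @param anova An [anova_line_tester()] result (or any tibble with an
#'   `Error` row carrying `df` and `mean_sq`).
#' @param n_per_mean Number of observations behind each compared mean.
#' @param alpha Significance level.
#' @return The least significant difference (same units as the trait).
#' @export
lsd <- function(anova, n_per_mean, alpha = 0.05) {
  if (n_per_mean <= 0) abort("`n_per_mean` must be positive")
  err <- anova[anova$source == "Error", ]
  if (nrow(err) != 1L) abort("ANOVA table lacks an Error row")
  qt(1 - alpha / 2, err$df) * sqrt(2 * err$mean_sq / n_per_mean)
}

#' Kempthorne combining-ability decomposition
#'
#' On the balanced line-by-tester table of cross means, the general
#' combining ability (GCA) of a line is its mean over testers minus the
#' grand mean (symmetrically for testers), and the specific combining
#' ability (SCA) of a cross is its mean minus grand mean and both GCAs.
#' Each effect set sums to zero and
#' `cross mean = grand + gca_line + gca_tester + sca` exactly.
#'
#' @param plots Plot table (see [compute_heterosis()]).
#' @param crosses Tibble with columns `female` (line), `male` (tester).
#' @return A `combining_ability` object: list with `grand_mean`, `gca_line`,
#'   `gca_tester`, `sca` tibbles.
#' @export
combining_ability <- function(plots, crosses) {
  plots <- as_tibble(plots)
  crosses <- as_tibble(crosses) |>
    mutate(entry_id = cross_entry_id(.data$female, .data$male))
  dat <- plots |>
    filter(.data$entry_type == "F1") |>
    select("entry_id", "location", "replication", "gy") |>
    inner_join(crosses, by = "entry_id")
  if (nrow(dat) == 0L) abort("no F1 plots matching the cross design")
  counts <- dat |> dplyr::count(.data$female, .data$male)
  if (nrow(counts) != nrow(crosses) || dplyr::n_distinct(counts$n) != 1L) {
    abort("unbalanced design: every cross needs the same number of plots")
  }
  cell <- dat |>
    group_by(.data$female, .data$male) |>
    summarise(mean_gy = mean(.data$gy), .groups = "drop")
  grand <- mean(cell$mean_gy)
  gl <- cell |> group_by(.data$female) |>
    summarise(gca = mean(.data$mean_gy) - grand, .groups = "drop") |>
    rename(line = "female")
  gt_ <- cell |> group_by(.data$male) |>
    summarise(gca = mean(.data$mean_gy) - grand, .groups = "drop") |>
    rename(tester = "male")
  sca <- cell |>
    left_join(rename(gl, female = "line", gca_line = "gca"), by = "female") |>
    left_join(rename(gt_, male = "tester", gca_tester = "gca"), by = "male") |>
    mutate(sca = .data$mean_gy - grand - .data$gca_line - .data$gca_tester) |>
    select(line = "female", tester = "male", "sca")
  structure(
    list(grand_mean = grand, gca_line = gl, gca_tester = gt_, sca = sca),
    class = "combining_ability"
  )
}

#' @export
#' @method print combining_ability
print.combining_ability <- function(x, ...) {
  cat("<combining_ability> grand mean ", sprintf("%.3f", x$grand_mean), "\n",
      sep = "")
  cat("GCA, lines:\n"); print(x$gca_line, n = 5)
  cat("GCA, testers:\n"); print(x$gca_tester, n = 5)
  invisible(x)
}

#' @export
tidy.combining_ability <- function(x, ...) {
  bind_rows(
    x$gca_line |> transmute(term = "gca_line", level = .data$line,
                            estimate = .data$gca),
    x$gca_tester |> transmute(term = "gca_tester", level = .data$tester,
                              estimate = .data$gca),
    x$sca |> transmute(term = "sca",
                       level = cross_entry_id(.data$line, .data$tester),
                       estimate = .data$sca)
  )
}
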