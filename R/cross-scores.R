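#' Heterozygous/homozygous PEUS SNP counts for one cross
#'
#' Applies the inbred-cross classification rule over PEUS sites only: where
#' both parents are homozygous, equal dosages make the F1 homozygous at that
#' locus and different dosages make it heterozygous. A locus where either
#' parent is missing, or carries a residual heterozygous call (dosage 1, an
#' ambiguous state in an inbred), is excluded from both counts.
#'
#' @param gm A [genotype_matrix()].
#' @param ann Annotation from [annotate_matrix()] on the same matrix.
#' @param female,male Sample identifiers of the two parents.
#' @return A one-row tibble: `n_het_peus`, `n_hom_peus`, `n_excluded`. The
#'   three always sum to the number of PEUS sites.
#' @export
count_peus <- function(gm, ann, female, male) {
  stopifnot(inherits(gm, "genotype_matrix"))
  check_samples(gm, c(female, male))
  if (nrow(ann) != nrow(gm$sites)) abort("annotation does not match matrix sites")
  peus <- ann$is_peus
  df <- gm$dosage[peus, female]
  dm <- gm$dosage[peus, male]
  usable <- !is.na(df) & !is.na(dm) & df != 1L & dm != 1L
  het <- sum(usable & df != dm)
  hom <- sum(usable & df == dm)
  tibble(
    n_het_peus = het,
    n_hom_peus = hom,
    n_excluded = sum(peus) - het - hom
  )
}

#' Identity-by-state genetic distance between two parents
#'
#' Per site, the shared-allele fraction is `(2 - |dosage_a - dosage_b|) / 2`;
#' IBS is its mean over sites genotyped in both samples and GD = 1 - IBS.
#' Computed over all sites of the (filtered) matrix, not only PEUS sites.
#'
#' @param gm A [genotype_matrix()].
#' @param a,b Sample identifiers.
#' @return Genetic distance in `[0, 1]`.
#' @export
ibs_distance <- function(gm, a, b) {
  stopifnot(inherits(gm, "genotype_matrix"))
  check_samples(gm, c(a, b))
  da <- gm$dosage[, a]
  db <- gm$dosage[, b]
  ok <- !is.na(da) & !is.na(db)
  if (!any(ok)) abort(paste0("no jointly genotyped site between ", a, " and ", b))
  ibs <- mean((2 - abs(da[ok] - db[ok])) / 2)
  1 - ibs
}

check_samples <- function(gm, ids) {
  missing_ids <- setdiff(ids, gm$samples)
  if (length(missing_ids)) {
    abort(paste0("sample(s) not in genotype matrix: ",
                 paste(missing_ids, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Score every cross of a line-by-tester design
#'
#' For each (female, male) cross: heterozygous/homozygous/excluded PEUS SNP
#' counts ([count_peus()]) and genome-wide genetic distance
#' ([ibs_distance()]). Output rows follow the design order.
#'
#' @param gm A filtered [genotype_matrix()].
#' @param ann Annotation from [annotate_matrix()].
#' @param crosses Tibble with columns `female`, `male`; rows must be unique.
#' @return A tibble with columns `female`, `male`, `n_het_peus`,
#'   `n_hom_peus`, `n_excluded`, `gd`.
#' @export
score_all <- function(gm, ann, crosses) {
  crosses <- as_tibble(crosses)
  stopifnot(all(c("female", "male") %in% names(crosses)))
  if (anyDuplicated(crosses[, c("female", "male")])) {
    abort("duplicate crosses in design")
  }
  if (nrow(crosses) == 0L) {
    return(tibble(female = character(), male = character(),
                  n_het_peus = integer(), n_hom_peus = integer(),
                  n_excluded = integer(), gd = double()))
  }
  check_samples(gm, unique(c(crosses$female, crosses$male)))

  peus <- ann$is_peus
  n_peus <- sum(peus)
  dos <- gm$dosage
  dos_p <- dos[peus, , drop = FALSE]
  score_one <- function(female, male) {
    df <- dos_p[, female]
    dm <- dos_p[, male]
    usable <- !is.na(df) & !is.na(dm) & df != 1L & dm != 1L
    het <- sum(usable & df != dm)
    hom <- sum(usable & df == dm)
    da <- dos[, female]; db <- dos[, male]
    ok <- !is.na(da) & !is.na(db)
    if (!any(ok)) abort(paste0("no jointly genotyped site for ", female, " x ", male))
    tibble(
      female = female, male = male,
      n_het_peus = het, n_hom_peus = hom, n_excluded = n_peus - het - hom,
      gd = 1 - mean((2 - abs(da[ok] - db[ok])) / 2)
    )
  }
  purrr::pmap(list(crosses$female, crosses$male), score_one) |> bind_rows()
}

#' Mean cross scores per parent or heterotic group
#'
#' Averages `n_het_peus`, `n_hom_peus` and `gd` over all crosses sharing a
#' key: the female parent (line), the male parent (tester), or the female
#' parent's heterotic group.
#'
#' @param scores Output of [score_all()], optionally joined with extra
#'   numeric columns (e.g. heterosis), which are averaged too.
#' @param by `"female"`, `"male"`, or `"group"`.
#' @param parents For `by = "group"`: tibble with columns `sample`, `group`
#'   mapping the female parents to heterotic groups.
#' @return A tibble keyed by the grouping variable with `n_crosses` and the
#'   mean of every numeric score column.
#' @export
aggregate_by_parent <- function(scores, by = c("female", "male", "group"),
                                parents = NULL) {
  by <- match.arg(by)
  scores <- as_tibble(scores)
  if (nrow(scores) == 0L) abort("no cross scores to aggregate")
  if (by == "group") {
    if (is.null(parents)) abort('`parents` is required for by = "group"')
    scores <- scores |>
      left_join(select(as_tibble(parents), sample = "sample", group = "group"),
                by = c(female = "sample"))
    if (anyNA(scores$group)) abort("some female parents have no heterotic group")
  }
  key <- switch(by, female = "female", male = "male", group = "group")
  scores |>
    group_by(.data[[key]]) |>
    summarise(
      across(where(is.numeric), mean),
      n_crosses = dplyr::n(),
      .groups = "drop"
    ) |>
    relocate("n_crosses", .after = 1L)
}
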