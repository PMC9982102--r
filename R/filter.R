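#' Quality-filter settings for SNP calls
#'
#' Defaults follow standard resequencing practice for inbred panels: per-call
#' read depth >= 3 and genotype quality >= 5 (failing calls are masked to
#' missing, not dropped), site quality >= 30, and a per-site missing rate of
#' at most 0.2 after masking.
#'
#' @param min_depth Minimum per-call read depth.
#' @param min_site_quality Minimum phred-scaled site QUAL.
#' @param min_genotype_quality Minimum per-call genotype quality.
#' @param max_missing_rate Maximum fraction of missing calls per site, with
#'   the number of samples in the (possibly subset) matrix as denominator.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_depth = 3, min_site_quality = 30,
                          min_genotype_quality = 5, max_missing_rate = 0.2) {
  stopifnot(min_depth >= 0, min_site_quality >= 0, min_genotype_quality >= 0,
            max_missing_rate >= 0, max_missing_rate <= 1)
  structure(
    list(
      min_depth = min_depth,
      min_site_quality = min_site_quality,
      min_genotype_quality = min_genotype_quality,
      max_missing_rate = max_missing_rate
    ),
    class = "filter_config"
  )
}

#' Apply per-call and per-site quality filters
#'
#' Two-stage filter. First, calls with depth below `min_depth` or genotype
#' quality below `min_genotype_quality` are masked to missing (the site is
#' kept). Second, sites with QUAL below `min_site_quality`, or whose missing
#' fraction after masking exceeds `max_missing_rate`, are removed. Sites with
#' no recorded QUAL pass the site-quality test; matrices without depth or GQ
#' skip the corresponding masking.
#'
#' The operation is idempotent and never modifies its input.
#'
#' @param gm A [genotype_matrix()].
#' @param cfg A [filter_config()].
#' @return A new, possibly empty, `genotype_matrix`.
#' @export
filter_variants <- function(gm, cfg = filter_config()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(cfg, "filter_config"))
  dosage <- gm$dosage
  depth <- gm$depth
  gq <- gm$gq
  if (!is.null(depth)) {
    dosage[!is.na(depth) & depth < cfg$min_depth] <- NA_integer_
  }
  if (!is.null(gq)) {
    dosage[!is.na(gq) & gq < cfg$min_genotype_quality] <- NA_integer_
  }
  miss_rate <- rowMeans(is.na(dosage))
  qual_ok <- is.na(gm$sites$qual) | gm$sites$qual >= cfg$min_site_quality
  keep <- qual_ok & miss_rate <= cfg$max_missing_rate
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    inform(paste0("filter_variants: removed ", n_drop, " of ", length(keep),
                  " site(s) (QUAL < ", cfg$min_site_quality,
                  " or missing rate > ", cfg$max_missing_rate, ")"))
  }
  genotype_matrix(
    gm$sites[keep, , drop = FALSE],
    dosage[keep, , drop = FALSE],
    depth = if (!is.null(depth)) depth[keep, , drop = FALSE],
    gq = if (!is.null(gq)) gq[keep, , drop = FALSE]
  )
}
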