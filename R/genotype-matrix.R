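#' Construct a genotype matrix for a panel of inbred parents
#'
#' Container for biallelic SNP calls on a set of samples: a site table
#' (chromosome, 1-based position, REF/ALT alleles, site quality) plus
#' per-sample allele-dosage calls and optional per-call read depth and
#' genotype quality.
#'
#' Dosage is the count of ALT alleles: 0 (homozygous REF), 1 (heterozygous),
#' 2 (homozygous ALT), or `NA` for a missing call. Fully inbred parents are
#' expected to carry dosages 0/2 almost everywhere; residual heterozygous
#' calls are tolerated here and handled downstream.
#'
#' @param sites Tibble with columns `chrom`, `pos`, `ref`, `alt`, `qual`.
#'   Sites must be biallelic SNPs (single-base `ref` and `alt`, `ref != alt`).
#' @param dosage Integer matrix, sites in rows and samples in columns
#'   (column names are the sample identifiers); values in `{0, 1, 2, NA}`.
#' @param depth,gq Optional numeric matrices of the same shape: per-call read
#'   depth and phred-scaled genotype quality. `NULL` means unavailable, and
#'   quality filters treat the calls as passing.
#' @return An object of class `genotype_matrix`.
#' @seealso [read_vcf()], [filter_variants()], [ibs_distance()]
#' @export
genotype_matrix <- function(sites, dosage, depth = NULL, gq = NULL) {
  sites <- as_tibble(sites)
  required <- c("chrom", "pos", "ref", "alt", "qual")
  if (!all(required %in% names(sites))) {
    abort(paste0("`sites` must have columns: ", paste(required, collapse = ", ")))
  }
  dosage <- as.matrix(dosage)
  if (is.null(colnames(dosage))) {
    abort("`dosage` must carry sample identifiers as column names")
  }
  if (nrow(dosage) != nrow(sites)) {
    abort("`dosage` rows must match `sites` rows")
  }
  storage.mode(dosage) <- "integer"
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% 0:2)) {
    abort("dosages must be 0, 1, 2 or NA")
  }
  if (any(sites$pos < 1)) abort("positions must be >= 1")
  if (any(nchar(sites$ref) != 1L | nchar(sites$alt) != 1L)) {
    abort("only biallelic SNPs are supported (single-base ref and alt)")
  }
  if (any(sites$ref == sites$alt)) abort("ref and alt must differ")
  key <- paste(sites$chrom, sites$pos)
  if (anyDuplicated(key)) abort("duplicate (chrom, pos) sites")
  ord <- order(sites$chrom, sites$pos)
  if (is.unsorted(ord)) {
    sites <- sites[ord, ]
    dosage <- dosage[ord, , drop = FALSE]
    if (!is.null(depth)) depth <- depth[ord, , drop = FALSE]
    if (!is.null(gq)) gq <- gq[ord, , drop = FALSE]
  }
  check_aux <- function(m, what) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (!identical(dim(m), dim(dosage))) abort(paste0("`", what, "` must match `dosage` dimensions"))
    m
  }
  structure(
    list(
      samples = colnames(dosage),
      sites = sites,
      dosage = dosage,
      depth = check_aux(depth, "depth"),
      gq = check_aux(gq, "gq")
    ),
    class = "genotype_matrix"
  )
}

#' @export
#' @method print genotype_matrix
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$sites), " sites x ", length(x$samples),
      " samples\n", sep = "")
  cat("  samples: ", paste(head(x$samples, 6), collapse = ", "),
      if (length(x$samples) > 6) ", ..." else "", "\n", sep = "")
  cat("  chromosomes: ", paste(unique(x$sites$chrom), collapse = ", "), "\n", sep = "")
  miss <- mean(is.na(x$dosage))
  cat("  missing calls: ", sprintf("%.2f%%", 100 * miss), "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$sites), length(x$samples))

#' Subset a genotype matrix by sample
#'
#' @param gm A [genotype_matrix()].
#' @param samples Character vector of sample identifiers to keep, in the
#'   requested order. Site order is preserved.
#' @return A `genotype_matrix` restricted to `samples`.
#' @export
subset_samples <- function(gm, samples) {
  stopifnot(inherits(gm, "genotype_matrix"))
  missing_ids <- setdiff(samples, gm$samples)
  if (length(missing_ids)) {
    abort(paste0("samples not in matrix: ", paste(missing_ids, collapse = ", ")))
  }
  genotype_matrix(
    gm$sites,
    gm$dosage[, samples, drop = FALSE],
    depth = if (!is.null(gm$depth)) gm$depth[, samples, drop = FALSE],
    gq = if (!is.null(gm$gq)) gm$gq[, samples, drop = FALSE]
  )
}

#' Tidy a genotype matrix into long format
#'
#' @param x A [genotype_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per (site, sample) call: `chrom`, `pos`,
#'   `ref`, `alt`, `sample`, `dosage`.
#' @export
tidy.genotype_matrix <- function(x, ...) {
  d <- as_tibble(x$dosage)
  out <- bind_cols(x$sites[, c("chrom", "pos", "ref", "alt")], d)
  tidyr::pivot_longer(out, cols = dplyr::all_of(x$samples),
                      names_to = "sample", values_to = "dosage")
}
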