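#' Read a multi-sample VCF into a genotype matrix
#'
#' Loads GT (and, when present, per-sample DP and GQ) from a VCF and returns a
#' [genotype_matrix()]. Only biallelic SNP records are retained: indels and
#' multiallelic records are skipped and their count reported. Records sharing
#' a (chromosome, position) key after that filter keep the first occurrence.
#'
#' @param path Path to a VCF (plain text or bgzip/gzip).
#' @param samples Optional character vector: keep only these samples, in this
#'   order. All must be present in the VCF header.
#' @return A [genotype_matrix()]. When the VCF carries no DP or GQ FORMAT
#'   field the corresponding slot is `NULL` and downstream quality filters
#'   treat those calls as passing.
#' @export
read_vcf <- function(path, samples = NULL) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  n_in <- nrow(fix)
  if (n_in == 0L) {
    hdr_samples <- colnames(vcf@gt)[-1] %||% character()
    keep <- samples %||% hdr_samples
    return(genotype_matrix(
      tibble(chrom = character(), pos = integer(), ref = character(),
             alt = character(), qual = double()),
      matrix(integer(), 0, length(keep), dimnames = list(NULL, keep))
    ))
  }

  snp <- !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0) {
    inform(paste0("read_vcf: skipped ", n_skip,
                  " non-biallelic-SNP record(s) (indel/multiallelic)"))
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  hdr_samples <- colnames(gt)
  if (!is.null(samples)) {
    missing_ids <- setdiff(samples, hdr_samples)
    if (length(missing_ids)) {
      abort(paste0("samples absent from VCF header: ",
                   paste(missing_ids, collapse = ", ")))
    }
  } else {
    samples <- hdr_samples
  }

  has_fmt <- function(tag) {
    any(grepl(paste0("(^|:)", tag, "(:|$)"), vcf@gt[, "FORMAT"]))
  }
  dp <- if (has_fmt("DP")) vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)
  gq <- if (has_fmt("GQ")) vcfR::extract.gt(vcf, "GQ", as.numeric = TRUE)

  take <- function(m) {
    if (is.null(m)) return(NULL)
    m[snp, samples, drop = FALSE]
  }
  gt <- take(gt)
  dp <- take(dp)
  gq <- take(gq)
  fix <- fix[snp, , drop = FALSE]

  dosage <- gt_to_dosage(gt)

  key <- paste(fix$CHROM, fix$POS)
  dup <- duplicated(key)
  if (any(dup)) {
    inform(paste0("read_vcf: dropped ", sum(dup),
                  " duplicate (chrom, pos) record(s), kept first"))
    fix <- fix[!dup, , drop = FALSE]
    dosage <- dosage[!dup, , drop = FALSE]
    if (!is.null(dp)) dp <- dp[!dup, , drop = FALSE]
    if (!is.null(gq)) gq <- gq[!dup, , drop = FALSE]
  }

  rownames(dosage) <- NULL
  if (!is.null(dp)) rownames(dp) <- NULL
  if (!is.null(gq)) rownames(gq) <- NULL
  sites <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL))
  )
  genotype_matrix(sites, dosage, depth = dp, gq = gq)
}

# GT strings -> alt-allele dosage; anything unparseable is missing
gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  d[gt %in% c("0/0", "0|0")] <- 0L
  d[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  d[gt %in% c("1/1", "1|1")] <- 2L
  d
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Emits a minimal VCF v4.2 with GT calls (plus DP and GQ when the matrix
#' carries them). Missing dosages are written as `./.`. Reading the file back
#' with [read_vcf()] reproduces dosages, positions, alleles and site
#' qualities.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(paste0("cannot write VCF: ", path))
  })
  on.exit(close(con))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=heteropeus",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  with_aux <- !is.null(gm$depth) && !is.null(gm$gq)
  if (with_aux) {
    header <- c(
      header,
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
      '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">'
    )
  }
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", gm$samples),
                            collapse = "\t"))
  writeLines(header, con)
  if (nrow(gm$sites) == 0L) return(invisible(path))

  gt_chr <- matrix(c("0/0", "0/1", "1/1")[gm$dosage + 1L],
                   nrow(gm$dosage), ncol(gm$dosage))
  gt_chr[is.na(gm$dosage)] <- "./."
  if (with_aux) {
    fmt <- "GT:DP:GQ"
    dp <- ifelse(is.na(gm$depth), ".", format(gm$depth, trim = TRUE, scientific = FALSE))
    gq <- ifelse(is.na(gm$gq), ".", format(gm$gq, trim = TRUE, scientific = FALSE))
    cells <- matrix(paste(gt_chr, dp, gq, sep = ":"),
                    nrow(gt_chr), ncol(gt_chr))
  } else {
    fmt <- "GT"
    cells <- gt_chr
  }
  qual <- ifelse(is.na(gm$sites$qual), ".",
                 format(gm$sites$qual, trim = TRUE, scientific = FALSE))
  body <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref,
                gm$sites$alt, qual, "PASS", ".", fmt, sep = "\t")
  body <- paste(body, apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}
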