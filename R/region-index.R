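PEUS_CATEGORIES <- c("PROMOTER", "EXON", "UTR", "STOP_CODON")

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS/five_prime_UTR/three_prime_UTR features into a
#' tidy feature table with one row per interval. Coordinates are 1-based
#' inclusive genomic, as in GFF3.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `chrom`, `type`, `start`, `end`, `strand`,
#'   `transcript_id`, `gene_id`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) abort(paste0("GFF3 not found: ", path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  df$type <- as.character(df$type)
  df$Parent <- vapply(df$Parent %||% list(),
                      function(p) if (length(p)) p[[1]] else NA_character_,
                      character(1))
  tx <- df |>
    filter(.data$type %in% c("mRNA", "transcript")) |>
    select(transcript_id = "ID", gene_id = "Parent")
  feats <- df |>
    filter(.data$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")) |>
    transmute(
      chrom = as.character(.data$seqnames),
      type = .data$type,
      start = as.integer(.data$start),
      end = as.integer(.data$end),
      strand = as.character(.data$strand),
      transcript_id = .data$Parent
    ) |>
    left_join(tx, by = "transcript_id")
  feats$gene_id[is.na(feats$gene_id)] <- feats$transcript_id[is.na(feats$gene_id)]
  feats
}

# last `n` coding bases in transcript orientation; may span two CDS intervals
stop_codon_intervals <- function(starts, ends, strand, n = 3L) {
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  out_s <- integer(); out_e <- integer()
  need <- n
  if (strand == "-") {
    # transcript 3' end is the genomic minimum
    for (i in seq_along(starts)) {
      if (need <= 0) break
      take <- min(need, ends[i] - starts[i] + 1L)
      out_s <- c(out_s, starts[i])
      out_e <- c(out_e, starts[i] + take - 1L)
      need <- need - take
    }
  } else {
    for (i in rev(seq_along(starts))) {
      if (need <= 0) break
      take <- min(need, ends[i] - starts[i] + 1L)
      out_s <- c(out_s, ends[i] - take + 1L)
      out_e <- c(out_e, ends[i])
      need <- need - take
    }
  }
  tibble(start = out_s, end = out_e)
}

#' Build a strand-aware PEUS region index from gene models
#'
#' Derives the four PEUS categories from each transcript's intervals:
#' `PROMOTER` is `promoter_len` bases 5' of the start codon (the CDS start in
#' strand orientation, truncated at the chromosome start), `EXON` all exon
#' intervals, `UTR` the 5' and 3' UTR intervals, and `STOP_CODON` the final 3
#' coding bases in transcript orientation (split across CDS intervals when
#' the stop codon spans an intron). Categories are unioned over transcripts
#' and genes, so one position may carry several.
#'
#' Transcripts without CDS contribute exon/UTR intervals only and are
#' reported.
#'
#' @param features Feature tibble as returned by [read_gene_models()] (or the
#'   simulator), or a path to a GFF3 file.
#' @param promoter_len Promoter length in bp upstream of the start codon.
#' @return An object of class `region_index` wrapping per-category genomic
#'   ranges.
#' @export
build_region_index <- function(features, promoter_len = 1000) {
  if (is.character(features) && length(features) == 1L) {
    features <- read_gene_models(features)
  }
  features <- as_tibble(features)
  stopifnot(all(c("chrom", "type", "start", "end", "strand", "transcript_id") %in%
                  names(features)))
  if (any(features$end < features$start)) abort("feature end < start")

  rows <- list()
  add <- function(chrom, start, end, category) {
    rows[[length(rows) + 1L]] <<- tibble(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      category = category
    )
  }

  ex <- features[features$type == "exon", ]
  if (nrow(ex)) add(ex$chrom, ex$start, ex$end, "EXON")
  utr <- features[features$type %in% c("five_prime_UTR", "three_prime_UTR"), ]
  if (nrow(utr)) add(utr$chrom, utr$start, utr$end, "UTR")

  cds <- features[features$type == "CDS", ]
  no_cds <- setdiff(unique(features$transcript_id), unique(cds$transcript_id))
  if (length(no_cds)) {
    inform(paste0("build_region_index: ", length(no_cds),
                  " transcript(s) without CDS contribute exon/UTR only"))
  }
  for (txid in unique(cds$transcript_id)) {
    tx <- cds[cds$transcript_id == txid, ]
    chrom <- tx$chrom[1]
    strand <- tx$strand[1]
    if (strand == "+") {
      cds_start <- min(tx$start)
      p_start <- max(1L, cds_start - as.integer(promoter_len))
      p_end <- cds_start - 1L
      if (p_end >= p_start) add(chrom, p_start, p_end, "PROMOTER")
    } else {
      cds_end <- max(tx$end)
      add(chrom, cds_end + 1L, cds_end + as.integer(promoter_len), "PROMOTER")
    }
    sc <- stop_codon_intervals(tx$start, tx$end, strand)
    if (nrow(sc)) add(chrom, sc$start, sc$end, "STOP_CODON")
  }

  tbl <- if (length(rows)) bind_rows(rows) else {
    tibble(chrom = character(), start = integer(), end = integer(),
           category = character())
  }
  gr <- GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(start = tbl$start, end = tbl$end),
    category = tbl$category
  )
  structure(
    list(gr = gr, intervals = tbl, promoter_len = promoter_len),
    class = "region_index"
  )
}

#' @export
#' @method print region_index
print.region_index <- function(x, ...) {
  cat("<region_index> ", nrow(x$intervals), " intervals, promoter ",
      x$promoter_len, " bp\n", sep = "")
  print(dplyr::count(x$intervals, .data$category))
  invisible(x)
}

#' Categories covering a single genomic position
#'
#' @param idx A [build_region_index()] result.
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @return Character vector (possibly empty) drawn from
#'   `PROMOTER`, `EXON`, `UTR`, `STOP_CODON`, in that fixed order.
#' @export
classify_position <- function(idx, chrom, pos) {
  stopifnot(inherits(idx, "region_index"))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, idx$gr))
  cats <- unique(idx$gr$category[S4Vectors::subjectHits(hits)])
  PEUS_CATEGORIES[PEUS_CATEGORIES %in% cats]
}

#' Flag PEUS SNPs in a genotype matrix
#'
#' Classifies every site of the matrix against the region index. A site is a
#' PEUS SNP when it falls in at least one category; each category a site
#' carries is flagged separately, so a 5'UTR position inside an exon counts
#' in both `EXON` and `UTR`, but only once in `is_peus`.
#'
#' @param gm A [genotype_matrix()].
#' @param idx A [build_region_index()] result.
#' @return A tibble with one row per site: `chrom`, `pos`, one logical column
#'   per category (`promoter`, `exon`, `utr`, `stop_codon`), and `is_peus`.
#' @seealso [peus_category_counts()]
#' @export
annotate_matrix <- function(gm, idx) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(idx, "region_index"))
  ann <- tibble(
    chrom = gm$sites$chrom,
    pos = gm$sites$pos,
    promoter = FALSE, exon = FALSE, utr = FALSE, stop_codon = FALSE
  )
  if (nrow(ann) && length(idx$gr)) {
    q <- GenomicRanges::GRanges(ann$chrom, IRanges::IRanges(ann$pos, ann$pos))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(q, idx$gr))
    i <- S4Vectors::queryHits(hits)
    cat <- idx$gr$category[S4Vectors::subjectHits(hits)]
    col <- c(PROMOTER = "promoter", EXON = "exon", UTR = "utr",
             STOP_CODON = "stop_codon")
    for (cc in names(col)) {
      ann[[col[[cc]]]][unique(i[cat == cc])] <- TRUE
    }
  }
  ann$is_peus <- ann$promoter | ann$exon | ann$utr | ann$stop_codon
  ann
}

#' Per-category PEUS SNP counts
#'
#' One site increments every category it carries; `is_peus` counts each site
#' once.
#'
#' @param ann Annotation tibble from [annotate_matrix()].
#' @return A tibble with columns `category` and `n_snps`.
#' @export
peus_category_counts <- function(ann) {
  tibble(
    category = c(PEUS_CATEGORIES, "is_peus"),
    n_snps = c(sum(ann$promoter), sum(ann$exon), sum(ann$utr),
               sum(ann$stop_codon), sum(ann$is_peus))
  )
}

#' Export PEUS intervals as BED
#'
#' Writes the index intervals in BED format (0-based half-open) with the
#' category in the name column, for inspection in genome browsers.
#'
#' @param idx A [build_region_index()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peus_bed <- function(idx, path) {
  stopifnot(inherits(idx, "region_index"))
  tbl <- idx$intervals
  readr::write_tsv(
    tibble(chrom = tbl$chrom, start = tbl$start - 1L, end = tbl$end,
           name = tbl$category),
    path, col_names = FALSE
  )
  invisible(path)
}
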