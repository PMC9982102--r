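# Builders and independent oracles shared across the suite.

# genotype matrix from a dosage matrix (sites x samples); sites autogenerated
toy_gm <- function(dosage, qual = NULL, depth = NULL, gq = NULL,
                   chrom = "chr1", pos = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- paste0("S", seq_len(ncol(dosage)))
  }
  sites <- tibble::tibble(
    chrom = rep(chrom, length.out = n),
    pos = pos %||% seq(100L, by = 100L, length.out = n),
    ref = rep("A", n),
    alt = rep("G", n),
    qual = qual %||% rep(50, n)
  )
  genotype_matrix(sites, dosage, depth = depth, gq = gq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-transcript gene feature table in the package schema
toy_gene <- function(gene_id, chrom, strand, exons, cds,
                     utr5 = NULL, utr3 = NULL) {
  mk <- function(ivs, type) {
    if (is.null(ivs)) return(NULL)
    tibble::tibble(type = type,
                   start = vapply(ivs, `[`, 0, 1),
                   end = vapply(ivs, `[`, 0, 2))
  }
  dplyr::bind_rows(
    mk(exons, "exon"), mk(cds, "CDS"),
    mk(utr5, "five_prime_UTR"), mk(utr3, "three_prime_UTR")
  ) |>
    dplyr::mutate(chrom = chrom, strand = strand,
                  transcript_id = paste0(gene_id, ".t1"), gene_id = gene_id)
}

# balanced F1 + parent plot table built from a cell-mean function
toy_plots <- function(crosses, parent_means, cross_means,
                      n_locations = 2, n_reps = 2, noise = 0,
                      loc_shift = NULL) {
  locs <- paste0("L", seq_len(n_locations))
  loc_shift <- loc_shift %||% stats::setNames(rep(0, n_locations), locs)
  entries <- dplyr::bind_rows(
    tibble::tibble(entry_id = names(parent_means), entry_type = "parent",
                   mu = unname(parent_means)),
    tibble::tibble(entry_id = cross_entry_id(crosses$female, crosses$male),
                   entry_type = "F1", mu = unname(cross_means))
  )
  out <- tidyr::expand_grid(entries, location = locs,
                            replication = seq_len(n_reps))
  out$gy <- out$mu + loc_shift[out$location] +
    if (noise > 0) stats::rnorm(nrow(out), 0, noise) else 0
  out$mu <- NULL
  out
}

# --- independent oracles -----------------------------------------------------

# IBS by explicit enumeration of the 2x2 allele pairings at each locus
oracle_gd <- function(da, db) {
  ok <- !is.na(da) & !is.na(db)
  stopifnot(any(ok))
  shared <- vapply(which(ok), function(i) {
    a <- c(rep("R", 2 - da[i]), rep("A", da[i]))
    b <- c(rep("R", 2 - db[i]), rep("A", db[i]))
    # maximum one-to-one matching between the two allele multisets
    min(sum(a == "R"), sum(b == "R")) + min(sum(a == "A"), sum(b == "A"))
  }, numeric(1))
  1 - mean(shared / 2)
}

# sequential sums of squares for the line x tester model by explicit
# cell-mean projections (balanced data only); Error by subtraction
oracle_lt_ss <- function(dat) {
  g <- mean(dat$gy)
  m <- function(...) {
    dplyr::summarise(dplyr::group_by(dat, ...), m = mean(gy), n = dplyr::n(),
                     .groups = "drop")
  }
  ss <- function(tab, expected) sum(tab$n * (tab$m - expected)^2)
  ml <- m(location); mi <- m(line); mj <- m(tester)
  mlk <- m(location, replication)
  mij <- m(line, tester); mil <- m(line, location); mjl <- m(tester, location)
  mijl <- m(line, tester, location)
  lk <- dplyr::left_join(mlk, dplyr::rename(ml, ml = m, nl = n), by = "location")
  ij <- mij |>
    dplyr::left_join(dplyr::rename(mi[, c("line", "m")], mi = m), by = "line") |>
    dplyr::left_join(dplyr::rename(mj[, c("tester", "m")], mj = m), by = "tester")
  il <- mil |>
    dplyr::left_join(dplyr::rename(mi[, c("line", "m")], mi = m), by = "line") |>
    dplyr::left_join(dplyr::rename(ml[, c("location", "m")], ml = m), by = "location")
  jl <- mjl |>
    dplyr::left_join(dplyr::rename(mj[, c("tester", "m")], mj = m), by = "tester") |>
    dplyr::left_join(dplyr::rename(ml[, c("location", "m")], ml = m), by = "location")
  ijl <- mijl |>
    dplyr::left_join(dplyr::rename(mij[, c("line", "tester", "m")], mij = m),
                     by = c("line", "tester")) |>
    dplyr::left_join(dplyr::rename(mil[, c("line", "location", "m")], mil = m),
                     by = c("line", "location")) |>
    dplyr::left_join(dplyr::rename(mjl[, c("tester", "location", "m")], mjl = m),
                     by = c("tester", "location")) |>
    dplyr::left_join(dplyr::rename(mi[, c("line", "m")], mi = m), by = "line") |>
    dplyr::left_join(dplyr::rename(mj[, c("tester", "m")], mj = m), by = "tester") |>
    dplyr::left_join(dplyr::rename(ml[, c("location", "m")], ml = m), by = "location")
  out <- c(
    loc = ss(ml, g),
    rep_loc = sum(lk$n * (lk$m - lk$ml)^2),
    lines = ss(mi, g),
    testers = ss(mj, g),
    lxt = sum(ij$n * (ij$m - ij$mi - ij$mj + g)^2),
    lxloc = sum(il$n * (il$m - il$mi - il$ml + g)^2),
    txloc = sum(jl$n * (jl$m - jl$mj - jl$ml + g)^2),
    lxtxloc = sum(ijl$n * (ijl$m - ijl$mij - ijl$mil - ijl$mjl +
                             ijl$mi + ijl$mj + ijl$ml - g)^2)
  )
  c(out, error = sum((dat$gy - g)^2) - sum(out))
}

# brute-force region lookup: linear scan over every interval
oracle_classify <- function(intervals, chrom, pos) {
  hit <- intervals$chrom == chrom & intervals$start <= pos & intervals$end >= pos
  sort(unique(intervals$category[hit]))
}

# write a small VCF by hand (text lines), returning the path
write_vcf_text <- function(lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

vcf_header <- function(samples, fmt_extra = character()) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    fmt_extra,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}
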