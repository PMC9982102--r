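small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_snps = 2000, n_genes = 10, chrom_length = 5e5),
    list(...)
  )
  do.call(sim_config, args)
}

test_that("simulated gene models satisfy the gene-model invariants", {
  feats <- simulate_annotation(small_cfg())
  expect_equal(dplyr::n_distinct(feats$gene_id), 10L)
  for (tx in unique(feats$transcript_id)) {
    f <- feats[feats$transcript_id == tx, ]
    exons <- f[f$type == "exon", ]
    cds <- f[f$type == "CDS", ]
    utr <- f[f$type %in% c("five_prime_UTR", "three_prime_UTR"), ]
    expect_gte(nrow(exons), 1)
    expect_gte(nrow(cds), 1)
    # CDS and UTR bases all inside the exon union
    in_exons <- function(iv) {
      any(exons$start <= iv[1] & exons$end >= iv[2])
    }
    expect_true(all(apply(cds[, c("start", "end")], 1, in_exons)))
    expect_true(all(apply(utr[, c("start", "end")], 1, in_exons)))
    expect_true(all(f$chrom == f$chrom[1]))
    expect_true(all(f$start <= f$end))
  }
  # genes do not overlap each other (promoter space is reserved)
  spans <- feats |>
    dplyr::group_by(chrom, gene_id) |>
    dplyr::summarise(start = min(start), end = max(end), .groups = "drop") |>
    dplyr::arrange(chrom, start)
  by_chrom <- split(spans, spans$chrom)
  for (s in by_chrom) {
    if (nrow(s) > 1) expect_true(all(s$start[-1] > s$end[-nrow(s)] + 1000))
  }
})

test_that("a fixed seed reproduces the GFF3 byte for byte", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.gff3"); f2 <- file.path(dir, "b.gff3")
  write_gff3(simulate_annotation(small_cfg(seed = 42)), f1)
  write_gff3(simulate_annotation(small_cfg(seed = 42)), f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- file.path(dir, "c.gff3")
  write_gff3(simulate_annotation(small_cfg(seed = 43)), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("minus-strand genes get their promoter space on the 3' genomic side", {
  feats <- simulate_annotation(small_cfg())
  idx <- build_region_index(feats)
  minus <- unique(feats$transcript_id[feats$strand == "-"])
  for (tx in minus) {
    cds <- feats[feats$transcript_id == tx & feats$type == "CDS", ]
    prom <- idx$intervals[idx$intervals$category == "PROMOTER" &
                            idx$intervals$start == max(cds$end) + 1L, ]
    expect_equal(nrow(prom), 1L)
    expect_gt(prom$start, max(cds$end))
  }
})

test_that("simulated inbreds are homozygous, high-quality and reproducible", {
  out <- simulate_inbreds(small_cfg(seed = 9))
  expect_equal(length(out$gm$samples), 24L)
  expect_false(any(out$gm$dosage == 1L, na.rm = TRUE))
  expect_false(anyNA(out$gm$dosage))
  expect_true(all(out$gm$depth >= 3))
  expect_true(all(out$gm$gq >= 5))
  expect_true(all(out$gm$sites$qual >= 30))
  expect_equal(sum(out$parents$role == "tester"), 5L)
  expect_equal(sum(out$parents$role == "line"), 19L)
  expect_equal(as.integer(table(out$parents$group)[c("nonReid", "Reid", "Suwan1")]),
               c(13L, 8L, 3L))
  # filtering the simulated panel is a no-op under defaults
  kept <- suppressMessages(filter_variants(out$gm))
  expect_equal(nrow(kept$sites), nrow(out$gm$sites))

  again <- simulate_inbreds(small_cfg(seed = 9))
  expect_identical(again$gm$dosage, out$gm$dosage)
  other <- simulate_inbreds(small_cfg(seed = 10))
  expect_false(identical(other$gm$dosage, out$gm$dosage))
})

test_that("within-group heterozygosity matches the 2p(1-p) expectation", {
  out <- simulate_inbreds(small_cfg(seed = 21, n_snps = 4000))
  grp <- "nonReid"
  ids <- out$parents$sample[out$parents$group == grp]
  p <- out$group_freq[, grp]
  expected <- sum(2 * p * (1 - p))
  pairs <- utils::combn(ids, 2)
  observed <- apply(pairs, 2, function(pr) {
    sum(out$gm$dosage[, pr[1]] != out$gm$dosage[, pr[2]])
  })
  expect_gte(ncol(pairs), 50)
  expect_equal(mean(observed), expected, tolerance = 0.03)
})

test_that("low divergence erases the between-group distance excess", {
  gd_gap <- function(fst, seed) {
    out <- simulate_inbreds(small_cfg(seed = seed, fst = fst))
    within <- ibs_distance(out$gm, "NO_01", "NO_02")
    between <- ibs_distance(out$gm, "NO_01", "RE_01")
    between - within
  }
  hi <- mean(vapply(1:3, function(s) gd_gap(0.25, s), numeric(1)))
  lo <- mean(vapply(1:3, function(s) gd_gap(0.01, s), numeric(1)))
  expect_gt(hi, 0.05)
  expect_lt(abs(lo), 0.02)
})

test_that("without dominance there is no heterosis; with zero noise BPH <= 0", {
  cfg <- small_cfg(seed = 13, dominance_effect_mean = 1e-12,
                   location_effect_sd = 0, rep_effect_sd = 0, gxe_sd = 0,
                   plot_noise_sd = 0)
  sim <- simulate_experiment(cfg)
  het <- compute_heterosis(sim$plots, sim$crosses)
  # F1 = MP exactly, so MPH = 0 and BPH <= 0 for every cross
  expect_equal(het$mph, rep(0, 95), tolerance = 1e-6)
  expect_true(all(het$bph <= 1e-8))

  # with field noise back on, mean MPH stays near zero
  cfg2 <- small_cfg(seed = 13, dominance_effect_mean = 1e-12)
  sim2 <- simulate_experiment(cfg2)
  het2 <- compute_heterosis(sim2$plots, sim2$crosses)
  expect_lt(abs(mean(het2$mph)), 5)
})

test_that("a single causal locus with zero noise gives MPH = 100 d / MP exactly", {
  # two homozygous parents differing at the only PEUS SNP
  dosage <- cbind(P1 = c(0L, 0L, 2L), P2 = c(2L, 0L, 2L))
  gm <- toy_gm(dosage, pos = c(1000L, 2000L, 3000L))
  ann <- tibble::tibble(chrom = "chr1", pos = c(1000L, 2000L, 3000L),
                        promoter = c(TRUE, FALSE, FALSE), exon = FALSE,
                        utr = FALSE, stop_codon = FALSE,
                        is_peus = c(TRUE, FALSE, FALSE))
  parents <- tibble::tibble(sample = c("P1", "P2"),
                            group = "G", role = c("line", "tester"))
  crosses <- tibble::tibble(female = "P1", male = "P2")
  cfg <- sim_config(seed = 5, causal_fraction_of_peus = 1,
                    location_effect_sd = 0, rep_effect_sd = 0, gxe_sd = 0,
                    plot_noise_sd = 0)
  ph <- simulate_phenotypes(gm, ann, parents, crosses, cfg)
  expect_equal(nrow(ph$truth$causal), 1L)
  d <- ph$truth$causal$d
  het <- compute_heterosis(ph$plots, crosses)
  expect_equal(het$mph, 100 * d / het$mp, tolerance = 1e-10)
})

test_that("phenotype records are reproducible and complete", {
  cfg <- small_cfg(seed = 3)
  sim <- simulate_experiment(cfg)
  expect_equal(nrow(sim$plots), (95 + 24) * 9)
  expect_setequal(unique(sim$plots$entry_type), c("F1", "parent"))
  sim_again <- simulate_experiment(cfg)
  expect_identical(sim$plots, sim_again$plots)
  expect_true(all(sim$truth$causal$is_peus))
  expect_true(all(sim$truth$causal$locus %in% which(sim$ann$is_peus)))
})

test_that("full_experiment writes a self-sufficient file bundle", {
  dir <- withr::local_tempdir()
  sim <- full_experiment(small_cfg(seed = 6), dir)
  for (p in sim$paths) expect_true(file.exists(p))
  design <- readr::read_csv(sim$paths$design, show_col_types = FALSE)
  expect_equal(nrow(design), 95L)
  expect_equal(dplyr::n_distinct(c(design$female, design$male)), 24L)
  plots <- readr::read_csv(sim$paths$plots, show_col_types = FALSE)
  expect_equal(nrow(plots), (95 + 24) * 9)
  gm <- read_vcf(sim$paths$vcf)
  expect_identical(gm$dosage, sim$gm$dosage)
  truth <- jsonlite::read_json(sim$paths$truth, simplifyVector = TRUE)
  expect_equal(nrow(truth$causal), nrow(sim$truth$causal))
})
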