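test_that("promoter is 1 kb upstream of the start codon in strand orientation", {
  plus <- toy_gene("gP", "chr1", "+",
                   exons = list(c(4900, 6100)), cds = list(c(5001, 6000)))
  minus <- toy_gene("gM", "chr2", "-",
                    exons = list(c(6900, 8100)), cds = list(c(7001, 8000)))
  idx <- build_region_index(dplyr::bind_rows(plus, minus))
  # + strand: CDS starts at 5001 -> promoter [4001, 5000]
  expect_true("PROMOTER" %in% classify_position(idx, "chr1", 4001))
  expect_true("PROMOTER" %in% classify_position(idx, "chr1", 4500))
  expect_true("PROMOTER" %in% classify_position(idx, "chr1", 5000))
  expect_false("PROMOTER" %in% classify_position(idx, "chr1", 4000))
  # - strand: CDS genomic maximum 8000 -> promoter [8001, 9000]
  expect_true("PROMOTER" %in% classify_position(idx, "chr2", 8001))
  expect_true("PROMOTER" %in% classify_position(idx, "chr2", 9000))
  expect_false("PROMOTER" %in% classify_position(idx, "chr2", 9001))
  # truncated at the chromosome start
  near_start <- toy_gene("gS", "chr3", "+",
                         exons = list(c(1, 900)), cds = list(c(401, 900)))
  idx2 <- build_region_index(near_start)
  prom <- idx2$intervals[idx2$intervals$category == "PROMOTER", ]
  expect_equal(c(prom$start, prom$end), c(1L, 400L))
})

test_that("stop codon is the last 3 coding bases, split across CDS intervals", {
  plus <- toy_gene("gP", "chr1", "+",
                   exons = list(c(5001, 6000)), cds = list(c(5001, 6000)))
  idx <- build_region_index(plus)
  expect_true("STOP_CODON" %in% classify_position(idx, "chr1", 5998))
  expect_true("STOP_CODON" %in% classify_position(idx, "chr1", 6000))
  expect_false("STOP_CODON" %in% classify_position(idx, "chr1", 5997))

  # stop codon spanning an intron: CDS [100,198] + [300,301] on + strand
  split_p <- toy_gene("gX", "chr1", "+",
                      exons = list(c(100, 198), c(300, 301)),
                      cds = list(c(100, 198), c(300, 301)))
  sc <- build_region_index(split_p)$intervals
  sc <- sc[sc$category == "STOP_CODON", ]
  covered <- sort(unlist(Map(seq, sc$start, sc$end)))
  expect_equal(covered, c(198L, 300L, 301L))

  # minus strand: transcript 3' end is the genomic minimum
  split_m <- toy_gene("gY", "chr2", "-",
                      cds = list(c(500, 501), c(600, 700)),
                      exons = list(c(500, 501), c(600, 700)))
  sc <- build_region_index(split_m)$intervals
  sc <- sc[sc$category == "STOP_CODON", ]
  covered <- sort(unlist(Map(seq, sc$start, sc$end)))
  expect_equal(covered, c(500L, 501L, 600L))
})

test_that("positions collect every category covering them", {
  g <- toy_gene("g1", "chr1", "+",
                exons = list(c(1000, 1399), c(1800, 2599)),
                cds = list(c(1200, 1399), c(1800, 2399)),
                utr5 = list(c(1000, 1199)), utr3 = list(c(2400, 2599)))
  idx <- build_region_index(g)
  expect_equal(classify_position(idx, "chr1", 2450), c("EXON", "UTR"))
  expect_equal(classify_position(idx, "chr1", 1500), character(0))  # intron
  expect_equal(classify_position(idx, "chr1", 999), c("PROMOTER"))
  expect_equal(classify_position(idx, "chr1", 2399),
               c("EXON", "STOP_CODON"))
  expect_equal(classify_position(idx, "chrX", 1100), character(0))
  # promoter [200,1199] overlaps the 5'UTR -> both recorded
  expect_equal(classify_position(idx, "chr1", 1150),
               c("PROMOTER", "EXON", "UTR"))
})

test_that("annotate_matrix counts each PEUS site once, categories separately", {
  g <- toy_gene("g1", "chr1", "+",
                exons = list(c(1000, 1399)), cds = list(c(1200, 1399)),
                utr5 = list(c(1000, 1199)))
  idx <- build_region_index(g)
  gm <- toy_gm(matrix(0L, 5, 2), pos = c(500L, 900L, 1100L, 1250L, 5000L))
  ann <- annotate_matrix(gm, idx)
  # promoter [200,1199] covers 500, 900 and 1100; 5000 is intergenic
  expect_equal(sum(ann$is_peus), 4)
  counts <- peus_category_counts(ann)
  expect_equal(counts$n_snps[counts$category == "PROMOTER"], 3)
  expect_equal(counts$n_snps[counts$category == "EXON"], 2)
  expect_equal(counts$n_snps[counts$category == "UTR"], 1)
  expect_equal(ann$is_peus, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(counts$n_snps[counts$category == "is_peus"], 4)
})

test_that("empty index flags nothing", {
  idx <- build_region_index(toy_gene("g", "chr9", "+",
                                     exons = list(c(10, 20)),
                                     cds = list(c(10, 20))))
  gm <- toy_gm(matrix(0L, 3, 2), chrom = "chr1")
  ann <- annotate_matrix(gm, idx)
  expect_false(any(ann$is_peus))
})

test_that("index query agrees with a brute-force scan over all intervals", {
  cfg <- sim_config(seed = 11, n_genes = 30, n_snps = 500,
                    chrom_length = 3e5)
  feats <- simulate_annotation(cfg)
  idx <- build_region_index(feats)
  set.seed(7)
  pos <- sample.int(3e5, 400)
  chroms <- sample(c("chr1", "chr2"), 400, replace = TRUE)
  for (i in seq_along(pos)) {
    expect_identical(sort(classify_position(idx, chroms[i], pos[i])),
                     oracle_classify(idx$intervals, chroms[i], pos[i]))
  }
})

test_that("reverse-complementing a chromosome mirrors promoters and stop codons", {
  L <- 10000L
  fwd <- toy_gene("g1", "chr1", "+",
                  exons = list(c(3000, 3499), c(3800, 4599)),
                  cds = list(c(3200, 3499), c(3800, 4399)),
                  utr5 = list(c(3000, 3199)), utr3 = list(c(4400, 4599)))
  mirror_iv <- function(s, e) c(L + 1L - e, L + 1L - s)
  rev <- toy_gene("g1", "chr1", "-",
                  exons = list(mirror_iv(3000, 3499), mirror_iv(3800, 4599)),
                  cds = list(mirror_iv(3200, 3499), mirror_iv(3800, 4399)),
                  utr5 = list(mirror_iv(3000, 3199)),
                  utr3 = list(mirror_iv(4400, 4599)))
  iv_f <- build_region_index(fwd)$intervals
  iv_r <- build_region_index(rev)$intervals
  for (cat in c("PROMOTER", "STOP_CODON", "EXON", "UTR")) {
    f <- iv_f[iv_f$category == cat, ]
    r <- iv_r[iv_r$category == cat, ]
    mirrored <- tibble::tibble(start = L + 1L - r$end, end = L + 1L - r$start)
    expect_setequal(paste(f$start, f$end),
                    paste(mirrored$start, mirrored$end))
  }
})

test_that("a promoter never overlaps its own transcript's CDS", {
  feats <- simulate_annotation(sim_config(seed = 3, n_genes = 40,
                                          chrom_length = 5e5))
  iv <- build_region_index(feats)$intervals
  prom <- iv[iv$category == "PROMOTER", ]
  cds <- feats[feats$type == "CDS", ]
  for (i in seq_len(nrow(prom))) {
    same <- cds[cds$chrom == prom$chrom[i], ]
    overlap <- same$start <= prom$end[i] & same$end >= prom$start[i]
    expect_false(any(overlap))
  }
})

test_that("transcripts without CDS contribute exon/UTR only, with a note", {
  nc <- toy_gene("gNC", "chr1", "+", exons = list(c(100, 200)), cds = NULL)
  expect_message(idx <- build_region_index(nc), "without CDS")
  expect_equal(sort(unique(idx$intervals$category)), "EXON")
})

test_that("gene models round-trip through GFF3", {
  feats <- simulate_annotation(sim_config(seed = 5, n_genes = 8,
                                          chrom_length = 2e5))
  path <- file.path(withr::local_tempdir(), "genes.gff3")
  write_gff3(feats, path)
  back <- read_gene_models(path)
  key <- function(d) dplyr::arrange(
    d[, c("chrom", "type", "start", "end", "strand", "transcript_id")],
    chrom, start, type)
  expect_equal(key(back), key(feats))
  idx_a <- build_region_index(feats)
  idx_b <- build_region_index(path)
  expect_equal(dplyr::arrange(idx_a$intervals, chrom, start, category),
               dplyr::arrange(idx_b$intervals, chrom, start, category))
})
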