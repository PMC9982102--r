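#' Simulation settings for a synthetic line-by-tester experiment
#'
#' Defaults mirror the study design the package analyses: 24 fully
#' homozygous inbreds in three heterotic groups (nonReid 13, Reid 8, Suwan1
#' 3), the five testers drawn from the Reid group and crossed to the
#' remaining 19 lines (95 crosses), grown at 3 locations in randomized
#' complete blocks with 3 replications. The genome is desk-scale: 2
#' chromosomes of 2 Mb carrying a sparse panel of 20 genes and 24,000 SNPs,
#' so the PEUS compartment is a small slice of the genome-wide panel, as in
#' a real genome. Heterosis is generated by dominance effects at causal
#' loci drawn from the PEUS SNPs; effect sizes are calibrated so the
#' per-cross correlation between heterozygous PEUS SNP count and mid-parent
#' heterosis is of the magnitude line-by-tester yield trials report
#' (about 0.3) with mean mid-parent heterosis around 35%.
#'
#' @param seed Master seed; component streams (annotation, genotypes,
#'   effects, phenotypes) are derived from it so that, e.g., changing the
#'   phenotype stream leaves genotypes fixed.
#' @param group_sizes Named integer vector of inbreds per heterotic group.
#' @param n_testers Number of testers, taken from the first group_sizes
#'   group that has at least that many members (Reid by default).
#' @param fst Divergence of group allele frequencies around the ancestral
#'   frequency (Balding-Nichols beta model).
#' @param n_chromosomes,chrom_length,n_genes,n_snps Genome scale.
#' @param ancestral_freq_range Range of ancestral allele frequencies.
#' @param causal_fraction_of_peus Fraction of PEUS SNPs that are causal.
#' @param off_peus_effect_fraction Fraction of causal loci relocated to
#'   non-PEUS SNPs (0 = the dominance architecture sits entirely in PEUS
#'   regions; 1 = entirely outside).
#' @param additive_effect_mean,dominance_effect_mean Mean additive effect
#'   `a` (t/ha per allele) and mean dominance effect `d` (t/ha at a
#'   heterozygous locus); `a ~ Normal(mean, mean/2)`, `d ~ Gamma(shape = 6, mean)`
#'   (mildly dispersed positive effects, so an unweighted heterozygous-locus
#'   count is close to the optimal linear predictor).
#' @param n_locations,n_reps Trial dimensions.
#' @param location_effect_sd,rep_effect_sd,gxe_sd,plot_noise_sd Standard
#'   deviations (t/ha) of location, replication-within-location,
#'   entry-by-location and plot-residual effects.
#' @param grand_mean_gy Population mean grain yield, t/ha.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       group_sizes = c(nonReid = 13, Reid = 8, Suwan1 = 3),
                       n_testers = 5,
                       fst = 0.15,
                       n_chromosomes = 2,
                       chrom_length = 2e6,
                       n_genes = 20,
                       n_snps = 24000,
                       ancestral_freq_range = c(0.05, 0.95),
                       causal_fraction_of_peus = 0.6,
                       off_peus_effect_fraction = 0,
                       additive_effect_mean = 0.02,
                       dominance_effect_mean = 0.057,
                       n_locations = 3,
                       n_reps = 3,
                       location_effect_sd = 1.5,
                       rep_effect_sd = 0.3,
                       gxe_sd = 0.6,
                       plot_noise_sd = 1.6,
                       grand_mean_gy = 6) {
  stopifnot(fst > 0, fst < 1,
            causal_fraction_of_peus >= 0, causal_fraction_of_peus <= 1,
            off_peus_effect_fraction >= 0, off_peus_effect_fraction <= 1,
            location_effect_sd >= 0, rep_effect_sd >= 0, gxe_sd >= 0,
            plot_noise_sd >= 0,
            !is.null(names(group_sizes)), all(group_sizes >= 1))
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

# evaluate `code` under `seed`, restoring the caller's RNG state
with_sim_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

sub_seed <- function(seed, offset) {
  s <- (as.double(seed) * 48271 + offset * 2654435) %% 2147483647
  as.integer(max(1, s))
}

#' Simulate gene models
#'
#' Places `n_genes` non-overlapping two-exon genes on alternating strands,
#' each with 5'/3' UTRs, intron-split CDS and upstream promoter space.
#'
#' @param cfg A [sim_config()].
#' @return Feature tibble with the [read_gene_models()] schema.
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  gene_span <- 1600L
  slot <- gene_span + 2500L   # promoter + margin on either strand
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chromosomes)
  spacing <- floor(cfg$chrom_length / per_chrom)
  if (spacing < slot + 200L) {
    abort("infeasible packing: too many genes for the chromosome length")
  }
  with_sim_seed(sub_seed(cfg$seed, 1L), {
    rows <- vector("list", cfg$n_genes)
    for (g in seq_len(cfg$n_genes)) {
      chrom_i <- ((g - 1L) %% cfg$n_chromosomes) + 1L
      slot_i <- (g - 1L) %/% cfg$n_chromosomes
      jitter <- sample.int(max(1L, spacing - slot - 200L), 1L)
      s <- slot_i * spacing + 1200L + jitter
      strand <- if (g %% 2L == 1L) "+" else "-"
      chrom <- paste0("chr", chrom_i)
      gid <- sprintf("gene%03d", g)
      tid <- sprintf("mRNA%03d", g)
      f <- if (strand == "+") {
        tibble(
          type = c("exon", "five_prime_UTR", "CDS",
                   "exon", "CDS", "three_prime_UTR"),
          start = s + c(0L, 0L, 200L, 800L, 800L, 1400L),
          end = s + c(399L, 199L, 399L, 1599L, 1399L, 1599L)
        )
      } else {
        tibble(
          type = c("exon", "five_prime_UTR", "CDS",
                   "exon", "CDS", "three_prime_UTR"),
          start = s + c(1200L, 1400L, 1200L, 0L, 200L, 0L),
          end = s + c(1599L, 1599L, 1399L, 799L, 799L, 199L)
        )
      }
      rows[[g]] <- f |>
        mutate(chrom = chrom, strand = strand,
               transcript_id = tid, gene_id = gid)
    }
    bind_rows(rows) |>
      select("chrom", "type", "start", "end", "strand",
             "transcript_id", "gene_id") |>
      arrange(.data$chrom, .data$start, .data$type)
  })
}

#' Write gene models as GFF3
#'
#' Emits gene and mRNA parent records plus the exon/CDS/UTR features with
#' `ID`/`Parent` attributes; [read_gene_models()] round-trips the table.
#'
#' @param features Feature tibble ([simulate_annotation()] schema).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  features <- as_tibble(features)
  spans <- features |>
    group_by(.data$gene_id, .data$transcript_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    arrange(.data$chrom, .data$start)
  lines_out <- c("##gff-version 3")
  fmt <- function(chrom, type, start, end, strand, attr) {
    paste(chrom, "heteropeus", type, start, end, ".", strand, ".", attr,
          sep = "\t")
  }
  gene_lines <- fmt(spans$chrom, "gene", spans$start, spans$end, spans$strand,
                    paste0("ID=", spans$gene_id))
  mrna_lines <- fmt(spans$chrom, "mRNA", spans$start, spans$end, spans$strand,
                    paste0("ID=", spans$transcript_id, ";Parent=", spans$gene_id))
  feat_lines <- fmt(features$chrom, features$type, features$start,
                    features$end, features$strand,
                    paste0("ID=", features$transcript_id, ":", features$type,
                           ":", features$start,
                           ";Parent=", features$transcript_id))
  writeLines(c(lines_out, gene_lines, mrna_lines, feat_lines), path)
  invisible(path)
}

#' Simulate a panel of fully homozygous inbred parents
#'
#' Ancestral allele frequencies are uniform on `ancestral_freq_range`; each
#' heterotic group's frequency is drawn from the Balding-Nichols beta model
#' `Beta(p(1-Fst)/Fst, (1-p)(1-Fst)/Fst)`. Each inbred is fully homozygous:
#' dosage 2 with the group frequency, else 0. All calls carry depth and
#' genotype quality above the default filters.
#'
#' @param cfg A [sim_config()].
#' @return List with `gm` (a [genotype_matrix()]), `parents` (tibble
#'   `sample`, `role`, `group`) and `group_freq` (loci x groups matrix).
#' @export
simulate_inbreds <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  groups <- names(cfg$group_sizes)
  tester_group <- if ("Reid" %in% groups &&
                      cfg$group_sizes[["Reid"]] >= cfg$n_testers) {
    "Reid"
  } else {
    groups[which(cfg$group_sizes >= cfg$n_testers)[1]]
  }
  if (is.na(tester_group)) abort("no heterotic group is large enough to supply the testers")
  with_sim_seed(sub_seed(cfg$seed, 2L), {
    per_chrom <- table(sort(rep(seq_len(cfg$n_chromosomes),
                                length.out = cfg$n_snps)))
    sites <- purrr::map_dfr(seq_len(cfg$n_chromosomes), function(ci) {
      n <- as.integer(per_chrom[[ci]])
      pos <- sort(sample.int(cfg$chrom_length, n))
      ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                    character(1))
      tibble(chrom = paste0("chr", ci), pos = pos, ref = ref, alt = unname(alt),
             qual = round(runif(n, 35, 60), 1))
    })
    n_loci <- nrow(sites)
    p_anc <- runif(n_loci, cfg$ancestral_freq_range[1], cfg$ancestral_freq_range[2])
    group_freq <- vapply(groups, function(g) {
      rbeta(n_loci,
            p_anc * (1 - cfg$fst) / cfg$fst,
            (1 - p_anc) * (1 - cfg$fst) / cfg$fst)
    }, numeric(n_loci))

    samples <- unname(unlist(purrr::imap(as.list(cfg$group_sizes), function(n, g) {
      sprintf("%s_%02d", substr(toupper(g), 1, 2), seq_len(n))
    })))
    sample_group <- rep(groups, cfg$group_sizes)
    dosage <- vapply(seq_along(samples), function(i) {
      2L * rbinom(n_loci, 1L, group_freq[, sample_group[i]])
    }, integer(n_loci))
    colnames(dosage) <- samples

    testers <- samples[sample_group == tester_group][seq_len(cfg$n_testers)]
    parents <- tibble(
      sample = samples,
      group = sample_group,
      role = ifelse(samples %in% testers, "tester", "line")
    )
    depth <- matrix(10L, n_loci, length(samples))
    gq <- matrix(99L, n_loci, length(samples))
    list(
      gm = genotype_matrix(sites, dosage, depth = depth, gq = gq),
      parents = parents,
      group_freq = group_freq
    )
  })
}

#' Line-by-tester cross design from a parent table
#'
#' Every line (female) is crossed to every tester (male).
#'
#' @param parents Tibble with `sample`, `role` (`line`/`tester`).
#' @return Tibble with columns `female`, `male`.
#' @export
make_design <- function(parents) {
  parents <- as_tibble(parents)
  tidyr::expand_grid(
    female = parents$sample[parents$role == "line"],
    male = parents$sample[parents$role == "tester"]
  )
}

#' Simulate multi-location replicated grain yields
#'
#' Draws causal loci from the PEUS SNPs (a fraction may be relocated off
#' PEUS via `off_peus_effect_fraction`), assigns additive and dominance
#' effects, and builds plot records for every parent and F1 entry:
#' `gy = grand mean + location + rep(location) + genetic value +
#' entry-by-location + plot noise`, truncated at zero. The F1 dosage at a
#' locus is the parental mean; the locus is heterozygous iff the (homozygous)
#' parents differ.
#'
#' @param gm Parent [genotype_matrix()].
#' @param ann Annotation from [annotate_matrix()].
#' @param parents,crosses Design tables (see [simulate_inbreds()],
#'   [make_design()]).
#' @param cfg A [sim_config()].
#' @return List with `plots` (plot tibble) and `truth` (causal loci/effects
#'   and per-entry genetic values).
#' @export
simulate_phenotypes <- function(gm, ann, parents, crosses, cfg) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(cfg, "sim_config"))
  peus_idx <- which(ann$is_peus)
  off_idx <- which(!ann$is_peus)
  n_causal <- round(cfg$causal_fraction_of_peus * length(peus_idx))
  if (n_causal == 0L) abort("no causal loci available: increase causal_fraction_of_peus")
  n_off <- round(cfg$off_peus_effect_fraction * n_causal)
  n_on <- n_causal - n_off
  if (n_off > length(off_idx)) abort("not enough non-PEUS loci for requested off-PEUS fraction")

  effects <- with_sim_seed(sub_seed(cfg$seed, 3L), {
    causal <- c(
      if (n_on > 0) sample(peus_idx, n_on),
      if (n_off > 0) sample(off_idx, n_off)
    )
    tibble(
      locus = causal,
      chrom = gm$sites$chrom[causal],
      pos = gm$sites$pos[causal],
      is_peus = ann$is_peus[causal],
      a = rnorm(n_causal, cfg$additive_effect_mean, cfg$additive_effect_mean / 2),
      d = rgamma(n_causal, shape = 6, rate = 6 / cfg$dominance_effect_mean)
    )
  })

  dos_c <- gm$dosage[effects$locus, , drop = FALSE]
  gv_parent <- colSums(effects$a * (dos_c - 1))
  entries <- tibble(entry_id = parents$sample, entry_type = "parent",
                    gv = gv_parent[parents$sample])
  f1 <- as_tibble(crosses) |>
    mutate(entry_id = cross_entry_id(.data$female, .data$male))
  gv_f1 <- purrr::map2_dbl(f1$female, f1$male, function(fe, ma) {
    df <- dos_c[, fe]; dm <- dos_c[, ma]
    dos <- (df + dm) / 2
    het <- df != dm
    sum(effects$a * (dos - 1) + effects$d * het)
  })
  entries <- bind_rows(entries,
                       tibble(entry_id = f1$entry_id, entry_type = "F1",
                              gv = gv_f1))

  plots <- with_sim_seed(sub_seed(cfg$seed, 4L), {
    locs <- paste0("loc", seq_len(cfg$n_locations))
    loc_eff <- setNames(rnorm(cfg$n_locations, 0, cfg$location_effect_sd), locs)
    reps <- tidyr::expand_grid(location = locs, replication = seq_len(cfg$n_reps)) |>
      mutate(rep_eff = rnorm(dplyr::n(), 0, cfg$rep_effect_sd))
    gxe <- tidyr::expand_grid(entry_id = entries$entry_id, location = locs) |>
      mutate(gxe = rnorm(dplyr::n(), 0, cfg$gxe_sd))
    out <- tidyr::expand_grid(entries, location = locs,
                              replication = seq_len(cfg$n_reps)) |>
      left_join(reps, by = c("location", "replication")) |>
      left_join(gxe, by = c("entry_id", "location")) |>
      mutate(
        gy = cfg$grand_mean_gy + loc_eff[.data$location] + .data$rep_eff +
          .data$gv + .data$gxe + rnorm(dplyr::n(), 0, cfg$plot_noise_sd)
      )
    n_trunc <- sum(out$gy < 0)
    if (n_trunc > 0) {
      inform(paste0("simulate_phenotypes: truncated ", n_trunc,
                    " negative plot yield(s) at 0"))
      out$gy <- pmax(out$gy, 0)
    }
    out |> select("entry_id", "entry_type", "location", "replication", "gy")
  })

  truth <- list(
    causal = effects,
    genetic_values = entries,
    config = cfg
  )
  list(plots = plots, truth = truth)
}

#' Simulate a complete line-by-tester experiment in memory
#'
#' Runs [simulate_annotation()], [simulate_inbreds()], [make_design()] and
#' [simulate_phenotypes()] under one configuration.
#'
#' @param cfg A [sim_config()].
#' @return List: `features`, `gm`, `parents`, `crosses`, `plots`, `truth`,
#'   `ann` (annotation of the simulated matrix), `index`.
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  features <- simulate_annotation(cfg)
  inb <- simulate_inbreds(cfg)
  idx <- build_region_index(features)
  ann <- annotate_matrix(inb$gm, idx)
  crosses <- make_design(inb$parents)
  ph <- simulate_phenotypes(inb$gm, ann, inb$parents, crosses, cfg)
  list(features = features, gm = inb$gm, parents = inb$parents,
       group_freq = inb$group_freq, crosses = crosses, plots = ph$plots,
       truth = ph$truth, ann = ann, index = idx)
}

#' Simulate an experiment and write its files
#'
#' Produces everything the pipeline needs as files: VCF, GFF3, design and
#' parent CSVs, plot-level phenotype CSV and a ground-truth JSON.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the [simulate_experiment()] bundle plus a `paths`
#'   element.
#' @export
full_experiment <- function(cfg = sim_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_experiment(cfg)
  paths <- list(
    vcf = file.path(dir, "parents.vcf"),
    gff = file.path(dir, "genes.gff3"),
    design = file.path(dir, "design.csv"),
    parents = file.path(dir, "parents.csv"),
    plots = file.path(dir, "plots.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_vcf(sim$gm, paths$vcf)
  write_gff3(sim$features, paths$gff)
  readr::write_csv(sim$crosses, paths$design)
  readr::write_csv(sim$parents, paths$parents)
  readr::write_csv(sim$plots, paths$plots)
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  sim$paths <- paths
  invisible(sim)
}

#' Replicate-seed recovery comparison of the two heterosis predictors
#'
#' For each seed, simulates a full experiment, runs the analysis pipeline in
#' memory (filter, annotate, score, heterosis) and records the Pearson
#' correlations of `n_het_peus` and `gd` with mid-parent heterosis over the
#' simulated crosses, plus which predictor wins.
#'
#' @param cfg A [sim_config()]; its `seed` is replaced by each element of
#'   `seeds` in turn.
#' @param seeds Integer vector of replicate seeds.
#' @return Tibble: `seed`, `r_het_peus`, `r_gd`, `het_wins`.
#' @export
recovery_experiment <- function(cfg = sim_config(), seeds = 1:50) {
  purrr::map_dfr(seeds, function(s) {
    cfg$seed <- s
    sim <- simulate_experiment(cfg)
    gm <- filter_variants(sim$gm)
    ann <- annotate_matrix(gm, sim$index)
    scores <- score_all(gm, ann, sim$crosses)
    het <- compute_heterosis(sim$plots, sim$crosses, scope = "across")
    dat <- inner_join(scores, het, by = c("female", "male"))
    r_het <- cor(dat$n_het_peus, dat$mph)
    r_gd <- cor(dat$gd, dat$mph)
    tibble(seed = s, r_het_peus = r_het, r_gd = r_gd,
           het_wins = r_het > r_gd)
  })
}
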