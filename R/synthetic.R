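#' Synthetic cohort configuration
#'
#' Study conditions for the planted-truth cohort: three tumour groups
#' (A/B/C) whose chromatin accessibility differs in known ways. Group B
#' carries reduced accessibility at oestrogen-responsive-element (ERE)
#' and FOXA1-motif CREs while its planted "expression" of the ER and
#' FOXA1 genes is unchanged (the dissociation the pipeline must
#' recover); group C is TNBC-like, with elevated immune TME-CRE
#' accessibility and its own ETS-motif CRE program. Fragment lengths
#' follow a sub-nucleosomal + mono-nucleosomal mixture; insertions
#' concentrate at the planted regions and at TSSs. A separate validation
#' expression cohort carries a minority of marker-high samples with a
#' planted hazard effect on survival.
#'
#' @param n_samples_per_group ATAC samples per group (3 groups).
#' @param genome_length bp per synthetic chromosome.
#' @param n_chroms number of chromosomes.
#' @param n_true_regions number of planted accessible regions.
#' @param motif_plant_fraction fraction of regions carrying each planted
#'   motif (ERE, FOXA1, ETS).
#' @param ere_reduction_factor multiplicative accessibility reduction of
#'   ERE/FOXA1-motif regions in group B; in (0, 1].
#' @param tme_fraction fraction of regions assigned to each TME
#'   reference set.
#' @param fragments_per_sample sequenced fragments per sample.
#' @param nfr_length_mean,mono_length_mean fragment-length mixture
#'   component means (bp); sds 15/25, weights 0.55/0.45.
#' @param survival_hazard_ratio hazard multiplier of marker-high
#'   validation samples.
#' @param n_validation validation (expression + survival) cohort size.
#' @param n_high_validation planted marker-high validation samples.
#' @param promoter_fraction fraction of regions placed at TSSs.
#' @param group_specific_fraction fraction of regions forming the
#'   C-specific (ETS) program.
#' @param group_effect accessibility multiplier of C-specific regions in
#'   group C (and immune TME regions in group C).
#' @param marker_effect log-scale expression elevation of marker genes
#'   in group-B / marker-high samples.
#' @param n_genes genes in the expression matrices.
#' @param n_marker_genes planted surrogate marker genes.
#' @param seed master seed; fixes all randomness end to end.
#' @return validated config list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples_per_group = 8,
                          genome_length = 1e7,
                          n_chroms = 5,
                          n_true_regions = 20000,
                          motif_plant_fraction = 0.08,
                          ere_reduction_factor = 0.4,
                          tme_fraction = 0.02,
                          fragments_per_sample = 200000,
                          nfr_length_mean = 60,
                          mono_length_mean = 200,
                          survival_hazard_ratio = 3,
                          n_validation = 436,
                          n_high_validation = 45,
                          promoter_fraction = 0.15,
                          group_specific_fraction = 0.08,
                          group_effect = 2.5,
                          marker_effect = 2.5,
                          n_genes = 200,
                          n_marker_genes = 30,
                          seed = 1) {
  cfg <- list(
    n_samples_per_group = check_count(n_samples_per_group, "n_samples_per_group"),
    genome_length = check_count(genome_length, "genome_length", min = 1e5),
    n_chroms = check_count(n_chroms, "n_chroms"),
    n_true_regions = check_count(n_true_regions, "n_true_regions"),
    motif_plant_fraction = check_fraction(motif_plant_fraction, "motif_plant_fraction"),
    ere_reduction_factor = check_fraction(ere_reduction_factor, "ere_reduction_factor",
                                          lo = 1e-9, hi = 1),
    tme_fraction = check_fraction(tme_fraction, "tme_fraction"),
    fragments_per_sample = check_count(fragments_per_sample, "fragments_per_sample"),
    nfr_length_mean = check_count(nfr_length_mean, "nfr_length_mean"),
    mono_length_mean = check_count(mono_length_mean, "mono_length_mean"),
    survival_hazard_ratio = check_fraction(survival_hazard_ratio,
                                           "survival_hazard_ratio", lo = 1e-9, hi = Inf),
    n_validation = check_count(n_validation, "n_validation", min = 2),
    n_high_validation = check_count(n_high_validation, "n_high_validation"),
    promoter_fraction = check_fraction(promoter_fraction, "promoter_fraction"),
    group_specific_fraction = check_fraction(group_specific_fraction,
                                             "group_specific_fraction"),
    group_effect = check_fraction(group_effect, "group_effect", lo = 1e-9, hi = Inf),
    marker_effect = check_fraction(marker_effect, "marker_effect", lo = 0, hi = Inf),
    n_genes = check_count(n_genes, "n_genes", min = 10),
    n_marker_genes = check_count(n_marker_genes, "n_marker_genes"),
    seed = check_count(seed, "seed", min = 0)
  )
  cfg$region_step <- 2400L
  cfg$region_margin <- 2000L
  # the last 12 kb of each chromosome stay region-free (blacklist zone)
  capacity <- cfg$n_chroms *
    floor((cfg$genome_length - cfg$region_margin - 12000) / cfg$region_step)
  if (capacity < cfg$n_true_regions) {
    stop_config("n_true_regions",
                sprintf("exceeds genome capacity (%d regions at %d bp spacing)",
                        capacity, cfg$region_step))
  }
  if (cfg$n_high_validation >= cfg$n_validation) {
    stop_config("n_high_validation", "must be smaller than n_validation")
  }
  if (cfg$n_marker_genes + 2 > cfg$n_genes) {
    stop_config("n_marker_genes", "must leave room for non-marker genes")
  }
  class(cfg) <- "cohort_config"
  cfg
}

TME_SET_NAMES <- c("endothelial", "fibroblast", "tcell", "bcell", "plasma", "myeloid")
IMMUNE_SETS <- c("tcell", "bcell", "plasma", "myeloid")

consensus_pfm <- function(consensus, total = 100, conc = 0.85) {
  bases <- strsplit(consensus, "")[[1]]
  m <- vapply(bases, function(b) {
    if (b == "N") return(rep(total / 4, 4))
    col <- rep(total * (1 - conc) / 3, 4)
    col[match(b, DNA_BASES)] <- total * conc
    col
  }, numeric(4))
  matrix(m, nrow = 4, dimnames = list(DNA_BASES, NULL))
}

cohort_pfms <- function() {
  list(
    ERE = consensus_pfm("GGTCANNNTGACC"),
    FOXA1 = consensus_pfm("TGTTTACA"),
    ETS = consensus_pfm("ACAGGAAGTG")
  )
}

sample_motif_instance <- function(pfm) {
  probs <- sweep(pfm, 2, colSums(pfm), "/")
  paste(apply(probs, 2, function(p) sample(DNA_BASES, 1, prob = p)), collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Generate a synthetic ATAC cohort with planted truth
#'
#' Emits everything the pipeline consumes — per-sample fragment tables
#' and summit calls, a TSS catalog, a blacklist (with planted decoy
#' summits inside it), TME reference CRE sets, motif PFMs, a synthetic
#' genome and region FASTA, expression matrices and a survival table —
#' together with the planted ground truth used as the acceptance oracle.
#' Every artifact draws from its own RNG stream derived from the master
#' seed, so outputs are byte-identical across runs and adding an
#' artifact does not perturb the others.
#'
#' @param config a [cohort_config()].
#' @return a list with elements `config`, `samples`, `fragments`,
#'   `summits`, `tss`, `blacklist`, `tme_sets`, `pfms`, `motifs`,
#'   `genome`, `region_seqs`, `expression`, `validation` (expression,
#'   survival), `chrom_sizes`, and `truth`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  seeds <- derive_seeds(config$seed, 12)
  n_grp <- config$n_samples_per_group
  n_samples <- 3L * n_grp
  groups <- rep(c("A", "B", "C"), each = n_grp)
  sample_ids <- sprintf("S%02d_%s", seq_len(n_samples), groups)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  chrom_sizes <- setNames(rep(config$genome_length, config$n_chroms), chroms)

  ## region layout and roles -------------------------------------------------
  layout <- with_seed(seeds[2], {
    per_chrom <- floor((config$genome_length - 2 * config$region_margin) /
                         config$region_step)
    counts <- rep(floor(config$n_true_regions / config$n_chroms), config$n_chroms)
    rem <- config$n_true_regions - sum(counts)
    if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
    summit <- unlist(lapply(seq_len(config$n_chroms), function(i) {
      config$region_margin + config$region_step * (seq_len(counts[i]) - 1L)
    }))
    regions <- tibble(
      chrom = rep(chroms, counts),
      summit = as.integer(summit)
    )
    regions$start <- regions$summit - 250L
    regions$end <- regions$summit + 251L
    regions$region_id <- peak_ids(regions)
    n <- nrow(regions)
    role <- rep("baseline", n)
    idx <- sample.int(n)  # random role assignment, disjoint slices
    take <- function(k) {
      if (k < 1) return(integer(0))
      out <- idx[seq_len(k)]
      idx <<- idx[-seq_len(k)]
      out
    }
    role[take(round(config$promoter_fraction * n))] <- "promoter"
    tme_set <- rep(NA_character_, n)
    for (s in TME_SET_NAMES) {
      i <- take(round(config$tme_fraction * n))
      role[i] <- "tme"
      tme_set[i] <- s
    }
    motif <- rep(NA_character_, n)
    i <- take(round(config$motif_plant_fraction * n)); role[i] <- "motif"; motif[i] <- "ERE"
    i <- take(round(config$motif_plant_fraction * n)); role[i] <- "motif"; motif[i] <- "FOXA1"
    i <- take(round(config$group_specific_fraction * n))
    role[i] <- "c_specific"; motif[i] <- "ETS"
    regions$role <- role
    regions$tme_set <- tme_set
    regions$motif <- motif
    # baseline weight of each region (relative accessibility)
    regions$weight <- stats::rgamma(n, shape = 6, rate = 6)
    regions
  })
  n_regions <- nrow(layout)

  ## group multipliers -------------------------------------------------------
  mult <- matrix(1, nrow = n_regions, ncol = 3, dimnames = list(NULL, c("A", "B", "C")))
  reduced <- layout$role == "motif" & layout$motif %in% c("ERE", "FOXA1")
  mult[reduced, "B"] <- config$ere_reduction_factor
  mult[layout$role == "c_specific", "C"] <- config$group_effect
  immune <- layout$role == "tme" & layout$tme_set %in% IMMUNE_SETS
  mult[immune, "C"] <- config$group_effect

  ## TSS catalog -------------------------------------------------------------
  tss <- with_seed(seeds[12], {
    prom <- layout[layout$role == "promoter", , drop = FALSE]
    extra_from <- layout[layout$role == "baseline", , drop = FALSE]
    extra <- extra_from[sample.int(nrow(extra_from), min(300L, nrow(extra_from))), ]
    out <- tibble(
      chrom = c(prom$chrom, extra$chrom),
      position = c(prom$summit, extra$summit + 1200L),
      strand = sample(c("+", "-"), nrow(prom) + nrow(extra), replace = TRUE),
      gene_name = sprintf("GENE%05d", seq_len(nrow(prom) + nrow(extra)))
    )
    out[radix_order(out$chrom, out$position), , drop = FALSE]
  })

  ## blacklist (in the region-free chromosome tails) -------------------------
  blacklist <- local({
    starts <- round(seq(config$genome_length - 10000,
                        config$genome_length - 2800, length.out = 8))
    tibble(
      chrom = rep(chroms, each = 8),
      start = as.integer(rep(starts, config$n_chroms)),
      end = as.integer(rep(starts, config$n_chroms)) + 800L
    )
  })

  ## genome + region sequences with planted motifs ---------------------------
  pfms <- cohort_pfms()
  genome <- with_seed(seeds[1], {
    g <- lapply(chroms, function(ch) {
      sample(DNA_BASES, config$genome_length, replace = TRUE,
             prob = c(0.30, 0.20, 0.20, 0.30))
    })
    names(g) <- chroms
    g
  })
  genome <- with_seed(seeds[3], {
    # per-region GC structure so GC matching has signal
    for (r in seq_len(n_regions)) {
      gc <- stats::rbeta(1, 15, 22)
      w <- layout$end[r] - layout$start[r]
      genome[[layout$chrom[r]]][(layout$start[r] + 1L):layout$end[r]] <-
        sample(DNA_BASES, w, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    }
    genome
  })
  genome <- with_seed(seeds[4], {
    planted <- which(!is.na(layout$motif))
    for (r in planted) {
      pfm <- pfms[[layout$motif[r]]]
      wid <- ncol(pfm)
      for (k in 1:2) {
        inst <- sample_motif_instance(pfm)
        if (runif(1) < 0.5) inst <- revcomp_chr(inst)
        off <- sample(seq(-180L, 180L - wid), 1)
        at <- layout$summit[r] + off
        genome[[layout$chrom[r]]][(at + 1L):(at + wid)] <- strsplit(inst, "")[[1]]
      }
    }
    genome
  })
  genome <- Biostrings::DNAStringSet(vapply(genome, paste, "", collapse = ""))
  region_seqs <- get_peak_sequences(
    tibble(chrom = layout$chrom, start = layout$start, end = layout$end,
           peak_id = layout$region_id),
    genome
  )

  ## per-sample accessibility intensities ------------------------------------
  lam <- layout$weight * mult[, groups, drop = FALSE]  # regions x samples
  depth <- with_seed(seeds[5], exp(rnorm(n_samples, 0, 0.08)))
  probs <- sweep(lam, 2, colSums(lam), "/")

  ## per-sample summit calls (+ blacklist decoys) ----------------------------
  exp_insertions <- sweep(probs, 2, 2 * config$fragments_per_sample * 0.8 * depth, "*")
  summits <- with_seed(seeds[6], {
    out <- vector("list", n_samples)
    for (j in seq_len(n_samples)) {
      score <- rpois(n_regions, exp_insertions[, j])
      keep <- score > 0
      obs <- layout$summit[keep] + as.integer(round(rnorm(sum(keep), 0, 8)))
      obs <- pmin(pmax(obs, 251L), config$genome_length - 252L)
      out[[j]] <- tibble(
        chrom = layout$chrom[keep], summit = obs,
        score = as.numeric(score[keep]), sample_id = sample_ids[j]
      )
    }
    decoys <- with_seed(seeds[11], {
      nb <- nrow(blacklist)
      lapply(seq_len(n_samples), function(j) {
        pick <- sample.int(nb, 40L, replace = TRUE)
        tibble(
          chrom = blacklist$chrom[pick],
          summit = as.integer(blacklist$start[pick] +
                                sample(100:700, 40L, replace = TRUE)),
          score = as.numeric(rpois(40L, 40)),
          sample_id = sample_ids[j]
        )
      })
    })
    bind_rows(purrr::map2(out, decoys, bind_rows))
  })

  ## fragments ---------------------------------------------------------------
  fragments <- with_seed(seeds[7], {
    nf <- config$fragments_per_sample
    n_reg <- round(0.8 * nf)
    n_tss <- round(0.1 * nf)
    n_bg <- nf - n_reg - n_tss
    out <- vector("list", n_samples)
    for (j in seq_len(n_samples)) {
      reg <- sample.int(n_regions, n_reg, replace = TRUE, prob = probs[, j])
      tss_pick <- sample.int(nrow(tss), n_tss, replace = TRUE)
      center <- c(
        layout$summit[reg] + round(rnorm(n_reg, 0, 70)),
        tss$position[tss_pick] + round(rnorm(n_tss, 0, 25)),
        round(runif(n_bg, 0, config$genome_length - 1))
      )
      chrom <- c(layout$chrom[reg], tss$chrom[tss_pick],
                 sample(chroms, n_bg, replace = TRUE))
      is_mono <- runif(nf) < 0.45
      len <- ifelse(is_mono,
                    round(rnorm(nf, config$mono_length_mean, 25)),
                    round(rnorm(nf, config$nfr_length_mean, 15)))
      len <- pmax(len, 15L)
      start <- as.integer(center - floor(len / 2))
      start <- pmax(start, 0L)
      end <- as.integer(pmin(start + len, config$genome_length))
      out[[j]] <- tibble(chrom = chrom, start = start, end = end,
                         sample_id = sample_ids[j])
    }
    bind_rows(out)
  })

  ## expression matrices ------------------------------------------------------
  marker_genes <- sprintf("MKG%03d", seq_len(config$n_marker_genes))
  other <- sprintf("BGG%03d", seq_len(config$n_genes - config$n_marker_genes - 2))
  gene_names <- c("ESR1", "FOXA1", marker_genes, other)
  cohort_expr <- with_seed(seeds[8], {
    mu <- setNames(rnorm(config$n_genes, 8, 1.5), gene_names)
    m <- matrix(rnorm(config$n_genes * n_samples, mu, 1),
                nrow = config$n_genes,
                dimnames = list(gene_names, sample_ids))
    m[marker_genes, groups == "B"] <- m[marker_genes, groups == "B"] + config$marker_effect
    list(mu = mu, m = m)
  })
  base_mu <- cohort_expr$mu
  expression <- cohort_expr$m
  validation <- with_seed(seeds[9], {
    vid <- sprintf("V%03d", seq_len(config$n_validation))
    high <- sample.int(config$n_validation, config$n_high_validation)
    m <- matrix(rnorm(config$n_genes * config$n_validation, base_mu, 1),
                nrow = config$n_genes, dimnames = list(gene_names, vid))
    m[marker_genes, high] <- m[marker_genes, high] + config$marker_effect
    surv <- with_seed(seeds[10], {
      rate <- 0.1 * config$survival_hazard_ratio^(seq_len(config$n_validation) %in% high)
      t_raw <- rexp(config$n_validation, rate)
      tibble(
        sample = vid,
        time = pmin(t_raw, 15),
        event = as.integer(t_raw <= 15)
      )
    })
    list(expression = m, survival = surv,
         labels = tibble(sample = vid,
                         marker_high = seq_len(config$n_validation) %in% high))
  })

  ## planted truth ------------------------------------------------------------
  differential <- bind_rows(
    tibble(region_id = layout$region_id[reduced], contrast = "B_vs_A",
           direction = "down"),
    tibble(region_id = layout$region_id[layout$role == "c_specific"],
           contrast = "C_vs_A", direction = "up")
  )
  truth <- list(
    groups = tibble(sample_id = sample_ids, group = groups),
    regions = layout[, c("region_id", "chrom", "start", "end", "summit",
                         "role", "tme_set", "motif")],
    marker_genes = marker_genes,
    differential = differential,
    survival_effect = config$survival_hazard_ratio,
    validation_labels = validation$labels
  )

  list(
    config = config,
    samples = truth$groups,
    fragments = fragments,
    summits = summits,
    tss = tss,
    blacklist = blacklist,
    tme_sets = setNames(lapply(TME_SET_NAMES, function(s) {
      layout[layout$role == "tme" & layout$tme_set == s,
             c("chrom", "start", "end")]
    }), TME_SET_NAMES),
    pfms = pfms,
    motifs = setNames(lapply(names(pfms), function(n) motif_model(n, pfms[[n]])),
                      names(pfms)),
    genome = genome,
    region_seqs = region_seqs,
    expression = expression,
    validation = validation,
    chrom_sizes = chrom_sizes,
    truth = truth
  )
}

#' Null counts matrix (no group effect)
#'
#' i.i.d. negative-binomial counts with common mean and dispersion
#' (Poisson at dispersion 0): `Var = mu + dispersion * mu^2`. Used for
#' type-I-error and FDR calibration of the differential test.
#'
#' @param n_regions,n_samples matrix dimensions (both >= 2).
#' @param dispersion NB dispersion (>= 0).
#' @param mu common mean count.
#' @param seed RNG seed.
#' @return a raw `accessibility_matrix`.
#' @export
generate_null_counts <- function(n_regions, n_samples, dispersion, mu = 50,
                                 seed = 1) {
  n_regions <- check_count(n_regions, "n_regions", min = 2)
  n_samples <- check_count(n_samples, "n_samples", min = 2)
  if (dispersion < 0) stop_config("dispersion", "must be >= 0")
  values <- with_seed(seed, {
    n <- n_regions * n_samples
    x <- if (dispersion == 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
    matrix(x, nrow = n_regions,
           dimnames = list(sprintf("r%05d", seq_len(n_regions)),
                           sprintf("s%02d", seq_len(n_samples))))
  })
  accessibility_matrix(values, state = "raw")
}

random_seq <- function(n, length, gc) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }, "")
}

#' Labelled target/background sequences with planted motif occurrences
#'
#' Generates random sequences at the requested GC and plants PWM-sampled
#' motif instances (random position and strand) into a `plant_rate`
#' fraction of each set — the ground truth for validating the motif
#' enrichment test.
#'
#' @param motif a [motif_model()].
#' @param n_target,n_background sequence counts.
#' @param plant_rate_target,plant_rate_background planting probabilities.
#' @param length sequence length, bp (must be >= the motif width).
#' @param gc background GC fraction.
#' @param seed RNG seed.
#' @return list with `target` and `background` `DNAStringSet`s and
#'   logical planting indicators `target_planted`, `background_planted`.
#' @export
generate_motif_sequences <- function(motif, n_target, n_background,
                                     plant_rate_target, plant_rate_background,
                                     length = 200, gc = 0.5, seed = 1) {
  stopifnot(inherits(motif, "motif_model"))
  check_fraction(plant_rate_target, "plant_rate_target")
  check_fraction(plant_rate_background, "plant_rate_background")
  if (length < motif$width) stop_config("length", "must be >= the motif width")
  with_seed(seed, {
    make_set <- function(n, rate, prefix) {
      seqs <- random_seq(n, length, gc)
      planted <- runif(n) < rate
      for (i in which(planted)) {
        inst <- sample_motif_instance(motif$pfm)
        if (runif(1) < 0.5) inst <- revcomp_chr(inst)
        at <- sample.int(length - motif$width + 1L, 1)
        substr(seqs[i], at, at + motif$width - 1L) <- inst
      }
      set <- Biostrings::DNAStringSet(seqs)
      names(set) <- sprintf("%s%04d", prefix, seq_len(n))
      list(set = set, planted = planted)
    }
    tgt <- make_set(n_target, plant_rate_target, "target_")
    bg <- make_set(n_background, plant_rate_background, "bg_")
    list(target = tgt$set, background = bg$set,
         target_planted = tgt$planted, background_planted = bg$planted)
  })
}

#' Map harmonized peaks onto planted truth regions
#'
#' Associates each merged peak with the planted region whose true summit
#' it contains (if any), so pipeline results can be compared with the
#' planted roles/motifs.
#'
#' @param peaks merged peak tibble with `peak_id`.
#' @param truth_regions the `truth$regions` tibble of a generated cohort.
#' @return `peaks` with added `region_id`, `role`, `motif`, `tme_set`
#'   columns (`NA` where no planted region matches).
#' @export
match_truth_regions <- function(peaks, truth_regions) {
  gr_pk <- intervals_to_gr(peaks)
  gr_tr <- positions_to_gr(truth_regions$chrom, truth_regions$summit)
  h <- GenomicRanges::findOverlaps(gr_tr, gr_pk, select = "first")
  out <- peaks
  out$region_id <- NA_character_
  out$role <- NA_character_
  out$motif <- NA_character_
  out$tme_set <- NA_character_
  ok <- !is.na(h)
  out$region_id[h[ok]] <- truth_regions$region_id[ok]
  out$role[h[ok]] <- truth_regions$role[ok]
  out$motif[h[ok]] <- truth_regions$motif[ok]
  out$tme_set[h[ok]] <- truth_regions$tme_set[ok]
  out
}
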