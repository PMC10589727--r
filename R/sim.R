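# Synthetic-data generators. These emulate the statistical structure the
# analysis assumes -- many peak sets sharing biotype-specific source loci
# with summit jitter, negative-binomial counts with library-size variation
# and biotype/tumor effects, and proportional-hazards survival linked to
# planted regions -- so that every downstream stage can be exercised and
# its ground truth recovered without external downloads.

#' Configuration for the synthetic-data generators
#'
#' All generators are pure functions of this configuration: the single
#' global `seed` is expanded into independent per-generator streams (see
#' [stream_seed()]), so adding one generator never shifts another's draws.
#'
#' @param seed integer global seed.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_biotypes number of tissue/cell-of-origin labels.
#' @param n_source_loci number of true intergenic transcribed loci shared
#'   across datasets.
#' @param loci_biotype_specificity probability in \[0,1\] that a dataset's
#'   peak is anchored on a locus of its own biotype (0 = no association).
#' @param n_datasets number of ChIP-seq datasets.
#' @param peaks_per_dataset called peaks per dataset.
#' @param summit_jitter_sd standard deviation (bp) of Gaussian summit noise
#'   around the source locus.
#' @param peak_halfwidth half-width (bp) of emitted peak intervals.
#' @param q_fail_frac fraction of peaks drawn with a q-value failing the
#'   1e-5 significance filter.
#' @param n_samples_per_biotype RNA-seq samples per biotype.
#' @param nb_mean_range range (length-2) of per-region base means; drawn
#'   log-uniformly.
#' @param nb_overdispersion NB overdispersion alpha in V(mu)=mu+alpha*mu^2.
#' @param libsize_lognormal_sd sd of log library-size factors.
#' @param effect_log2fc log2 fold change planted on marker regions in their
#'   own biotype's samples.
#' @param marker_frac fraction of regions planted as markers per biotype.
#' @param blacklist_frac fraction of the genome covered by the simulated
#'   blacklist.
#' @param n_survival_regions number of regions planted with a survival
#'   effect.
#' @param hazard_log_hr log hazard ratio per unit Pearson residual at the
#'   planted regions.
#' @param censor_frac fraction of samples independently censored.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 1e6,
                       n_biotypes = 6L,
                       n_source_loci = 300L,
                       loci_biotype_specificity = 0.8,
                       n_datasets = 60L,
                       peaks_per_dataset = 150L,
                       summit_jitter_sd = 30,
                       peak_halfwidth = 150L,
                       q_fail_frac = 0.1,
                       n_samples_per_biotype = 30L,
                       nb_mean_range = c(2, 50),
                       nb_overdispersion = 0.3,
                       libsize_lognormal_sd = 0.3,
                       effect_log2fc = 2,
                       marker_frac = 0.05,
                       blacklist_frac = 0.01,
                       n_survival_regions = 1L,
                       hazard_log_hr = 1,
                       censor_frac = 0.3) {
  cfg <- list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length), n_biotypes = as.integer(n_biotypes),
    n_source_loci = as.integer(n_source_loci),
    loci_biotype_specificity = loci_biotype_specificity,
    n_datasets = as.integer(n_datasets),
    peaks_per_dataset = as.integer(peaks_per_dataset),
    summit_jitter_sd = summit_jitter_sd,
    peak_halfwidth = as.integer(peak_halfwidth),
    q_fail_frac = q_fail_frac,
    n_samples_per_biotype = as.integer(n_samples_per_biotype),
    nb_mean_range = nb_mean_range,
    nb_overdispersion = nb_overdispersion,
    libsize_lognormal_sd = libsize_lognormal_sd,
    effect_log2fc = effect_log2fc,
    marker_frac = marker_frac,
    blacklist_frac = blacklist_frac,
    n_survival_regions = as.integer(n_survival_regions),
    hazard_log_hr = hazard_log_hr,
    censor_frac = censor_frac
  )
  counts <- c("n_chromosomes", "n_biotypes", "n_source_loci", "n_datasets",
              "peaks_per_dataset", "peak_halfwidth", "n_samples_per_biotype",
              "n_survival_regions")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L) stop("`", f, "` must be >= 0")
  }
  for (f in c("loci_biotype_specificity", "q_fail_frac", "marker_frac",
              "blacklist_frac", "censor_frac")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("`", f, "` must be in [0,1]")
  }
  if (cfg$chrom_length <= 2L * cfg$peak_halfwidth)
    stop("chrom_length must exceed 2*peak_halfwidth")
  if (any(cfg$nb_mean_range <= 0) || cfg$nb_overdispersion <= 0 ||
      cfg$libsize_lognormal_sd < 0)
    stop("NB parameters must be positive")
  class(cfg) <- "sim_config"
  cfg
}

sim_chrom_names <- function(cfg) sprintf("chr%d", seq_len(cfg$n_chromosomes))

sim_biotype_names <- function(cfg) sprintf("biotype%02d", seq_len(cfg$n_biotypes))

# Reserved intergenic zone on each chromosome ([0.3L, 0.7L)); source loci
# live here, gene models are placed outside it.
sim_zone <- function(cfg) {
  c(start = floor(0.3 * cfg$chrom_length), end = floor(0.7 * cfg$chrom_length))
}

# Source loci: deterministic function of cfg via the "loci" stream. Loci are
# laid out on evenly spaced slots inside the reserved zone (with a margin so
# peaks stay clear of the zone edges) and jittered within their slot, which
# guarantees a minimum inter-locus spacing.
sim_source_loci <- function(cfg) {
  if (cfg$n_source_loci == 0L || cfg$n_chromosomes == 0L) {
    return(data.frame(locus_id = character(), chrom = character(),
                      pos = integer(), biotype = character()))
  }
  zone <- sim_zone(cfg)
  margin <- cfg$peak_halfwidth + max(1000, 8 * cfg$summit_jitter_sd)
  lo <- zone["start"] + margin
  hi <- zone["end"] - margin
  if (hi <= lo) stop("chromosome too short for the reserved intergenic zone")
  chroms <- sim_chrom_names(cfg)
  chrom_of <- rep(chroms, length.out = cfg$n_source_loci)
  with_seed(stream_seed(cfg$seed, "loci"), {
    per <- table(factor(chrom_of, levels = chroms))
    pos <- integer(cfg$n_source_loci)
    for (ci in seq_along(chroms)) {
      k <- per[[ci]]
      if (k == 0L) next
      slot <- (hi - lo) / k
      centers <- lo + slot * (seq_len(k) - 0.5)
      jit <- stats::runif(k, -slot / 6, slot / 6)
      pos[chrom_of == chroms[ci]] <- as.integer(round(centers + jit))
    }
    biotype <- sample(rep(sim_biotype_names(cfg), length.out = cfg$n_source_loci))
    data.frame(
      locus_id = sprintf("locus%04d", seq_len(cfg$n_source_loci)),
      chrom = chrom_of, pos = pos, biotype = biotype,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate ChIP-seq peak datasets anchored on shared source loci
#'
#' Each dataset carries a biotype label; each of its peaks is anchored on a
#' source locus chosen with probability `loci_biotype_specificity` from the
#' loci of the dataset's own biotype (otherwise uniformly from all loci).
#' The summit is the locus position plus Gaussian jitter (rounded to bp);
#' the interval is summit +/- `peak_halfwidth`, clipped to the chromosome.
#' A fraction `q_fail_frac` of peaks is drawn with a -log10 q-value below 5
#' (i.e. failing the q < 1e-5 filter).
#'
#' @param cfg a [sim_config()].
#' @return list with `datasets` (dataset_id, biotype), `peaks` (0-based
#'   half-open peak table with summit, qvalue, dataset_id, peak_id, and the
#'   generating locus_id), and `truth` (the locus -> biotype map).
#' @export
simulate_peak_datasets <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$peaks_per_dataset > 10L * max(cfg$n_source_loci, 0L))
    stop("peaks_per_dataset exceeds 10x n_source_loci (degenerate oversampling)")
  loci <- sim_source_loci(cfg)
  if (cfg$n_datasets == 0L) {
    return(list(
      datasets = data.frame(dataset_id = character(), biotype = character()),
      peaks = data.frame(chrom = character(), start = integer(),
                         end = integer(), summit = integer(),
                         qvalue = numeric(), dataset_id = character(),
                         peak_id = character(), locus_id = character()),
      truth = loci
    ))
  }
  biotypes <- sim_biotype_names(cfg)
  datasets <- data.frame(
    dataset_id = sprintf("ds%03d", seq_len(cfg$n_datasets)),
    biotype = rep(biotypes, length.out = cfg$n_datasets),
    stringsAsFactors = FALSE
  )
  L <- cfg$chrom_length
  hw <- cfg$peak_halfwidth
  with_seed(stream_seed(cfg$seed, "peaks"), {
    out <- vector("list", cfg$n_datasets)
    for (d in seq_len(cfg$n_datasets)) {
      bt <- datasets$biotype[d]
      own <- which(loci$biotype == bt)
      npk <- cfg$peaks_per_dataset
      use_own <- stats::runif(npk) < cfg$loci_biotype_specificity &
        length(own) > 0L
      idx <- integer(npk)
      idx[use_own] <- own[sample.int(length(own), sum(use_own), replace = TRUE)]
      idx[!use_own] <- sample.int(nrow(loci), sum(!use_own), replace = TRUE)
      summit <- loci$pos[idx] +
        as.integer(round(stats::rnorm(npk, 0, cfg$summit_jitter_sd)))
      summit <- pmin(pmax(summit, 0L), L - 1L)
      start <- pmax(summit - hw, 0L)
      end <- pmin(summit + hw, L)
      fails <- stats::runif(npk) < cfg$q_fail_frac
      qv <- ifelse(fails, stats::runif(npk, 2, 5), stats::runif(npk, 5.001, 12))
      out[[d]] <- data.frame(
        chrom = loci$chrom[idx], start = start, end = end, summit = summit,
        qvalue = qv, dataset_id = datasets$dataset_id[d],
        locus_id = loci$locus_id[idx], stringsAsFactors = FALSE
      )
    }
    peaks <- do.call(rbind, out)
    peaks$peak_id <- sprintf("pk%06d", seq_len(nrow(peaks)))
    rownames(peaks) <- NULL
    list(datasets = datasets, peaks = peaks, truth = loci)
  })
}

#' Simulate a transcript annotation and blacklist
#'
#' Gene models are placed only outside the reserved intergenic zone that
#' holds the source loci, with a 2-kb buffer, so by construction no locus
#' overlaps a transcript +/- 1 kb. The blacklist is a set of non-overlapping
#' 500-bp intervals in the flanks covering `blacklist_frac` of the genome.
#'
#' @param cfg a [sim_config()].
#' @return list with `transcripts` (stranded GRanges with `gene_id`) and
#'   `blacklist` (GRanges); both empty for an empty genome.
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_chromosomes == 0L) {
    return(list(transcripts = GenomicRanges::GRanges(),
                blacklist = GenomicRanges::GRanges()))
  }
  zone <- sim_zone(cfg)
  L <- cfg$chrom_length
  chroms <- sim_chrom_names(cfg)
  buffer <- 2000L
  # gene slots in the two flanks, 15 kb apart, genes 2-10 kb long
  slot_w <- 15000L
  with_seed(stream_seed(cfg$seed, "annotation"), {
    tx <- list(); gid <- 0L
    for (ch in chroms) {
      flanks <- rbind(c(buffer, zone["start"] - buffer),
                      c(zone["end"] + buffer, L - buffer))
      for (f in 1:2) {
        lo <- flanks[f, 1]; hi <- flanks[f, 2]
        nslot <- max(0L, floor((hi - lo) / slot_w))
        if (nslot == 0L) next
        for (sl in seq_len(nslot)) {
          gid <- gid + 1L
          gstart <- lo + (sl - 1L) * slot_w +
            as.integer(stats::runif(1, 0, 2000))
          glen <- as.integer(stats::runif(1, 2000, 10000))
          tx[[length(tx) + 1L]] <- data.frame(
            chrom = ch, start = gstart, end = min(gstart + glen, hi),
            strand = sample(c("+", "-"), 1L),
            gene_id = sprintf("gene%04d", gid), stringsAsFactors = FALSE
          )
        }
      }
    }
    txdf <- if (length(tx)) do.call(rbind, tx) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), gene_id = character())
    # blacklist: distinct 500-bp grid slots inside the flanks
    bl_w <- 500L
    n_bl <- round(cfg$blacklist_frac * cfg$n_chromosomes * L / bl_w)
    bl <- list()
    if (n_bl > 0L) {
      grid <- list()
      for (ch in chroms) {
        s1 <- seq(0L, zone["start"] - bl_w, by = bl_w)
        s2 <- seq(zone["end"], L - bl_w, by = bl_w)
        grid[[ch]] <- data.frame(chrom = ch, start = c(s1, s2),
                                 stringsAsFactors = FALSE)
      }
      grid <- do.call(rbind, grid)
      pick <- grid[sample.int(nrow(grid), min(n_bl, nrow(grid))), , drop = FALSE]
      bl <- data.frame(chrom = pick$chrom, start = pick$start,
                       end = pick$start + bl_w, stringsAsFactors = FALSE)
    } else {
      bl <- data.frame(chrom = character(), start = integer(), end = integer())
    }
    list(transcripts = gr_from_bed0(txdf), blacklist = gr_from_bed0(bl))
  })
}

#' Simulate an NB count matrix at consensus regions
#'
#' Counts follow NB(mean = base_r * libsize_s * 2^(effect_log2fc * I),
#' overdispersion = `nb_overdispersion`) where I indicates that region r is
#' a planted marker for the biotype of sample s. Region base means are drawn
#' log-uniformly from `nb_mean_range`; library-size factors are log-normal.
#'
#' @param regions character vector of region ids (or a consensus table with
#'   a `region_id` column).
#' @param cfg a [sim_config()].
#' @param region_biotype optional named character vector mapping region ids
#'   to biotypes. When given, the planted markers of each biotype are
#'   exactly its regions (shared biotype structure with the peak layer,
#'   as when regions descend from biotype-specific source loci); when
#'   NULL, disjoint random blocks of `marker_frac` regions are planted.
#' @return list with `counts` (regions x samples integer matrix),
#'   `sample_meta` (sample_id, biotype, libsize) and `truth_markers`
#'   (biotype -> region ids planted as markers).
#' @export
simulate_count_matrix <- function(regions, cfg, region_biotype = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.data.frame(regions)) regions <- regions$region_id
  regions <- as.character(regions)
  biotypes <- sim_biotype_names(cfg)
  ns <- cfg$n_samples_per_biotype * cfg$n_biotypes
  if (ns < 2L) stop("need at least 2 samples")
  meta <- data.frame(
    sample_id = sprintf("s%04d", seq_len(ns)),
    biotype = rep(biotypes, each = cfg$n_samples_per_biotype),
    stringsAsFactors = FALSE
  )
  nr <- length(regions)
  with_seed(stream_seed(cfg$seed, "counts"), {
    meta$libsize <- exp(stats::rnorm(ns, 0, cfg$libsize_lognormal_sd))
    if (any(meta$libsize <= 0)) stop("non-positive library size")
    if (nr == 0L) {
      cm <- matrix(0L, 0L, ns, dimnames = list(character(), meta$sample_id))
      return(list(counts = cm, sample_meta = meta,
                  truth_markers = stats::setNames(
                    rep(list(character()), cfg$n_biotypes), biotypes)))
    }
    base <- exp(stats::runif(nr, log(cfg$nb_mean_range[1]),
                             log(cfg$nb_mean_range[2])))
    if (!is.null(region_biotype)) {
      truth <- lapply(stats::setNames(biotypes, biotypes), function(b) {
        intersect(regions, names(region_biotype)[region_biotype == b])
      })
    } else {
      # disjoint marker blocks per biotype
      n_mark <- floor(cfg$marker_frac * nr)
      shuffled <- sample(regions)
      truth <- stats::setNames(vector("list", cfg$n_biotypes), biotypes)
      for (b in seq_len(cfg$n_biotypes)) {
        lo <- (b - 1L) * n_mark + 1L
        hi <- min(b * n_mark, nr)
        truth[[b]] <- if (lo <= hi) shuffled[lo:hi] else character()
      }
    }
    is_marker <- matrix(FALSE, nr, cfg$n_biotypes,
                        dimnames = list(regions, biotypes))
    for (b in biotypes) is_marker[truth[[b]], b] <- TRUE
    mu <- outer(base, meta$libsize)
    bump <- 2^(cfg$effect_log2fc * is_marker[, meta$biotype, drop = FALSE])
    mu <- mu * bump
    cm <- matrix(
      stats::rnbinom(nr * ns, size = 1 / cfg$nb_overdispersion, mu = mu),
      nrow = nr, dimnames = list(regions, meta$sample_id)
    )
    list(counts = cm, sample_meta = meta, truth_markers = truth)
  })
}

#' Simulate proportional-hazards survival linked to planted regions
#'
#' Event times are exponential with hazard h0 * exp(hazard_log_hr * r) where
#' r is the sum of the Pearson residuals of the planted regions in each
#' sample. A fraction `censor_frac` of samples is independently censored at
#' a uniform fraction of its event time.
#'
#' @param samples character sample ids (columns of `residuals`).
#' @param planted_regions region ids (rows of `residuals`) carrying the
#'   hazard effect; may be empty for a global null.
#' @param residuals matrix regions x samples of Pearson residuals.
#' @param cfg a [sim_config()].
#' @param baseline_hazard baseline exponential hazard (events per day).
#' @return data.frame `sample_id`, `time` (> 0), `event` (0/1).
#' @export
simulate_survival <- function(samples, planted_regions, residuals, cfg,
                              baseline_hazard = 0.01) {
  stopifnot(inherits(cfg, "sim_config"))
  stopifnot(all(planted_regions %in% rownames(residuals)))
  stopifnot(all(samples %in% colnames(residuals)))
  lp <- if (length(planted_regions)) {
    cfg$hazard_log_hr *
      colSums(residuals[planted_regions, samples, drop = FALSE])
  } else {
    rep(0, length(samples))
  }
  with_seed(stream_seed(cfg$seed, "survival"), {
    t_event <- stats::rexp(length(samples), rate = baseline_hazard * exp(lp))
    censored <- stats::runif(length(samples)) < cfg$censor_frac
    time <- ifelse(censored, t_event * stats::runif(length(samples)), t_event)
    time <- pmax(time, 1e-8)
    data.frame(sample_id = samples, time = time,
               event = as.integer(!censored), stringsAsFactors = FALSE)
  })
}

#' Simulate per-base read coverage over standardized regions
#'
#' Two profile shapes are generated, mirroring the two transcriptional
#' patterns seen at consensus regions: a narrow central bump ("spike") and a
#' broad central plateau ("plateau"). Coverage is Poisson around the shaped
#' intensity.
#'
#' @param n_regions number of regions.
#' @param n_samples number of samples.
#' @param length region length in bp.
#' @param shape "spike" or "plateau" (recycled over regions).
#' @param depth mean reads per bp at the profile maximum.
#' @param seed integer seed.
#' @return 3-d array `[region, sample, position]` of integer coverage.
#' @export
simulate_region_coverage <- function(n_regions, n_samples, length = 1000L,
                                     shape = c("spike", "plateau"),
                                     depth = 2, seed = 1L) {
  shape <- rep(shape, length.out = n_regions)
  pos <- seq_len(length)
  center <- length / 2
  shapes <- list(
    spike = exp(-((pos - center)^2) / (2 * 60^2)),
    plateau = as.numeric(abs(pos - center) < 0.3 * length)
  )
  with_seed(stream_seed(seed, "coverage"), {
    arr <- array(0L, dim = c(n_regions, n_samples, length))
    for (r in seq_len(n_regions)) {
      lambda <- depth * shapes[[shape[r]]]
      for (s in seq_len(n_samples)) {
        arr[r, s, ] <- stats::rpois(length, lambda)
      }
    }
    arr
  })
}
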