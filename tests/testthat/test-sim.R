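# Synthetic-data generators: determinism, planted structure, ground truth.

test_that("peak-set generation is deterministic and respects contracts", {
  cfg <- sim_config(seed = 11, n_datasets = 8, peaks_per_dataset = 40,
                    n_source_loci = 50, n_biotypes = 3)
  a <- simulate_peak_datasets(cfg)
  b <- simulate_peak_datasets(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$peaks), 8 * 40)
  expect_true(all(a$peaks$start < a$peaks$end))
  expect_true(all(a$peaks$start <= a$peaks$summit &
                    a$peaks$summit < a$peaks$end))
  # q-value failure fraction is as configured (binomial tolerance)
  frac_fail <- mean(a$peaks$qvalue <= 5)
  expect_lt(abs(frac_fail - cfg$q_fail_frac), 0.06)
  # empty case
  e <- simulate_peak_datasets(sim_config(seed = 1, n_datasets = 0))
  expect_equal(nrow(e$peaks), 0)
  expect_equal(nrow(e$datasets), 0)
  # degenerate oversampling rejected
  expect_error(simulate_peak_datasets(
    sim_config(seed = 1, n_source_loci = 5, peaks_per_dataset = 51)),
    "oversampling")
})

test_that("zero specificity decouples locus usage from dataset biotype", {
  # chi-square independence test on the biotype x locus usage table,
  # repeated over replicates: non-significant at alpha = 0.01 in nearly all
  pvals <- vapply(1:20, function(r) {
    cfg <- sim_config(seed = 100 + r, n_datasets = 12, n_biotypes = 3,
                      peaks_per_dataset = 60, n_source_loci = 12,
                      loci_biotype_specificity = 0)
    ps <- simulate_peak_datasets(cfg)
    bt <- ps$datasets$biotype[match(ps$peaks$dataset_id,
                                    ps$datasets$dataset_id)]
    suppressWarnings(stats::chisq.test(table(bt, ps$peaks$locus_id))$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.9)
})

test_that("high specificity concentrates peaks on own-biotype loci", {
  cfg <- sim_config(seed = 5, loci_biotype_specificity = 0.9,
                    n_datasets = 12, n_biotypes = 3, n_source_loci = 30,
                    peaks_per_dataset = 50)
  ps <- simulate_peak_datasets(cfg)
  bt_ds <- ps$datasets$biotype[match(ps$peaks$dataset_id,
                                     ps$datasets$dataset_id)]
  bt_locus <- ps$truth$biotype[match(ps$peaks$locus_id, ps$truth$locus_id)]
  expect_gt(mean(bt_ds == bt_locus), 0.85)
})

test_that("annotation keeps source loci intergenic and hits the blacklist fraction", {
  cfg <- sim_config(seed = 3)
  ann <- simulate_annotation(cfg)
  loci <- simulate_peak_datasets(cfg)$truth
  pad <- GenomicRanges::resize(ann$transcripts,
                               GenomicRanges::width(ann$transcripts) + 2000,
                               fix = "center")
  pts <- gr_from_bed0(data.frame(chrom = loci$chrom, start = loci$pos,
                                 end = loci$pos + 1L))
  expect_equal(sum(GenomicRanges::countOverlaps(pts, pad)), 0)
  cov_bl <- sum(GenomicRanges::width(GenomicRanges::reduce(ann$blacklist)))
  genome <- cfg$n_chromosomes * cfg$chrom_length
  expect_lt(abs(cov_bl / genome - cfg$blacklist_frac),
            0.2 * cfg$blacklist_frac)
  empty <- simulate_annotation(sim_config(seed = 1, n_chromosomes = 0))
  expect_length(empty$transcripts, 0)
  expect_length(empty$blacklist, 0)
})

test_that("count generation matches its NB mean structure", {
  # no planted effect: per-region means equal across biotypes
  cfg0 <- sim_config(seed = 21, effect_log2fc = 0, n_biotypes = 2,
                     n_samples_per_biotype = 60, nb_overdispersion = 0.2)
  cm0 <- simulate_count_matrix(sprintf("r%03d", 1:150), cfg0)
  g <- cm0$sample_meta$biotype == cm0$sample_meta$biotype[1]
  pv <- vapply(seq_len(nrow(cm0$counts)), function(i) {
    stats::t.test(cm0$counts[i, g], cm0$counts[i, !g])$p.value
  }, numeric(1))
  expect_gte(mean(pv > 0.01), 0.95)
  # library-size factors scale empirical means proportionally
  cfgL <- sim_config(seed = 22, effect_log2fc = 0, n_biotypes = 2,
                     n_samples_per_biotype = 1, libsize_lognormal_sd = 0.6,
                     nb_overdispersion = 0.1)
  cmL <- simulate_count_matrix(sprintf("r%04d", 1:5000), cfgL)
  ls <- cmL$sample_meta$libsize
  emp <- colMeans(cmL$counts)
  expect_lt(abs((emp[1] / emp[2]) / (ls[1] / ls[2]) - 1), 0.1)
  # empty region list keeps a valid header
  cmE <- simulate_count_matrix(character(), cfg0)
  expect_equal(dim(cmE$counts), c(0L, ncol(cm0$counts)))
  expect_equal(colnames(cmE$counts), cm0$sample_meta$sample_id)
})

test_that("planted survival effects are recoverable and nulls are clean", {
  make_res <- function(seed, nr = 200, ns = 300) {
    set.seed(seed)
    matrix(rnorm(nr * ns), nr, ns,
           dimnames = list(sprintf("r%03d", 1:nr), sprintf("s%03d", 1:ns)))
  }
  # null: no hazard association -> flagged regions are rare
  fp <- vapply(1:10, function(sd) {
    res <- make_res(sd)
    cfg <- sim_config(seed = sd, hazard_log_hr = 0, censor_frac = 0.2)
    sv <- simulate_survival(colnames(res), character(), res, cfg)
    sum(cox_screen(res, sv)$flagged)
  }, numeric(1))
  expect_lte(mean(fp), 1)
  # planted effect at one region recovered with HR > 1
  hits <- vapply(1:10, function(sd) {
    res <- make_res(sd, nr = 50, ns = 500)
    cfg <- sim_config(seed = sd, hazard_log_hr = 1, censor_frac = 0.2)
    sv <- simulate_survival(colnames(res), "r001", res, cfg)
    scr <- cox_screen(res, sv)
    scr$flagged[1] && scr$log_hr[1] > 0
  }, logical(1))
  expect_gte(sum(hits), 9)
  # full censoring leaves no events to screen
  cfgC <- sim_config(seed = 9, censor_frac = 1)
  res <- make_res(9, nr = 5, ns = 50)
  sv <- simulate_survival(colnames(res), "r001", res, cfgC)
  expect_true(all(sv$event == 0))
  expect_error(cox_screen(res, sv), "events")
})

test_that("simulation outputs round-trip through the on-disk formats", {
  cfg <- sim_config(seed = 2, n_datasets = 4, peaks_per_dataset = 20,
                    n_source_loci = 30, n_biotypes = 2,
                    n_samples_per_biotype = 3)
  ps <- simulate_peak_datasets(cfg)
  ann <- simulate_annotation(cfg)
  cm <- simulate_count_matrix(sprintf("r%02d", 1:10), cfg)
  sv <- simulate_survival(cm$sample_meta$sample_id, character(),
                          matrix(0, 1, nrow(cm$sample_meta),
                                 dimnames = list("r01",
                                                 cm$sample_meta$sample_id)),
                          cfg)
  dir <- withr::local_tempdir()
  man <- write_simulation(list(peaksets = ps, annotation = ann,
                               expression = cm, survival = sv), cfg, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  ds1 <- ps$datasets$dataset_id[1]
  back <- read_narrowpeak(file.path(dir, paste0(ds1, ".narrowPeak")),
                          dataset_id = ds1)
  orig <- ps$peaks[ps$peaks$dataset_id == ds1, ]
  expect_equal(back$start, orig$start)
  expect_equal(back$summit, orig$summit)
  expect_equal(back$qvalue, orig$qvalue, tolerance = 1e-6)
  tx <- read_gff3_transcripts(file.path(dir, "annotation.gff3"))
  expect_equal(length(tx), length(ann$transcripts))
})
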