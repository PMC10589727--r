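# Biotype scores / Gini-Simpson, enrichment tests, category cascade,
# epigenome-state proportions, eQTL enrichment.

test_that("biotype scores normalize contributions and compute diversity", {
  # one biotype only at a consensus -> lambda = 0
  ds <- data.frame(dataset_id = c("d1", "d2", "d3", "d4"),
                   biotype = c("A", "A", "B", "B"))
  M <- matrix(c(TRUE, TRUE, FALSE, FALSE), 4, 1,
              dimnames = list(ds$dataset_id, "c1"))
  bs <- biotype_scores(M, ds)
  expect_equal(unname(bs$lambda), 0)
  expect_equal(unname(bs$dominant_biotype), "A")
  # R equally weighted biotypes -> lambda = 1 - R*(1/R)^2
  R <- 16
  dsr <- data.frame(dataset_id = sprintf("d%02d", 1:R),
                    biotype = sprintf("b%02d", 1:R))
  Mr <- matrix(TRUE, R, 1, dimnames = list(dsr$dataset_id, "c1"))
  expect_equal(unname(biotype_scores(Mr, dsr)$lambda), 1 - 16 * (1 / 16)^2)
  # normalization is anti-dominance: a small biotype with the same local
  # contribution outranks a peak-rich one
  ds2 <- data.frame(dataset_id = c("a1", "b1"), biotype = c("A", "B"))
  M2 <- matrix(FALSE, 2, 110, dimnames = list(ds2$dataset_id,
                                              sprintf("c%03d", 1:110)))
  M2["a1", 1:10] <- TRUE            # A: 10 total, incl. consensus c001
  M2["b1", 1:100] <- TRUE           # B: 100 total, incl. consensus c001
  bs2 <- biotype_scores(M2, ds2)
  expect_equal(bs2$n["A", "c001"], 0.1)
  expect_equal(bs2$n["B", "c001"], 0.01)
  expect_equal(unname(bs2$dominant_biotype[1]), "A")
  # all-zero column flagged as undefined
  bs3 <- biotype_scores(M2, ds2)
  expect_true(is.na(bs3$lambda["c110"]))
  # proportions sum to one where defined
  ok <- !is.na(bs2$lambda)
  expect_equal(unname(colSums(bs2$p[, ok])), rep(1, sum(ok)))
})

test_that("biotype scores are invariant to dataset order and duplication", {
  set.seed(1)
  ds <- data.frame(dataset_id = sprintf("d%02d", 1:12),
                   biotype = rep(c("A", "B", "C"), each = 4))
  M <- matrix(runif(12 * 30) < 0.4, 12, 30,
              dimnames = list(ds$dataset_id, sprintf("c%02d", 1:30)))
  bs <- biotype_scores(M, ds)
  perm <- sample(12)
  bs_p <- biotype_scores(M[perm, ], ds[perm, ])
  expect_equal(bs_p$n, bs$n)
  expect_equal(bs_p$lambda, bs$lambda)
  # duplicating every dataset of one biotype leaves n unchanged
  dup_rows <- which(ds$biotype == "A")
  M_dup <- rbind(M, M[dup_rows, , drop = FALSE])
  rownames(M_dup) <- c(rownames(M), sprintf("dupe%d", dup_rows))
  ds_dup <- rbind(ds, data.frame(dataset_id = sprintf("dupe%d", dup_rows),
                                 biotype = "A"))
  bs_d <- biotype_scores(M_dup, ds_dup)
  expect_equal(bs_d$n, bs$n)
  expect_equal(bs_d$lambda, bs$lambda)
  expect_equal(bs_d$dominant_biotype, bs$dominant_biotype)
})

test_that("binomial overlap test matches the exact tail and fold definition", {
  r <- binomial_overlap_test(4, 4, 50, 100)
  expect_equal(r$p_value, 1 / 16)
  expect_equal(r$fold, 2)
  # k at expectation -> fold 1
  r2 <- binomial_overlap_test(5, 10, 50, 100)
  expect_equal(r2$fold, 1)
  # no hits
  r3 <- binomial_overlap_test(0, 10, 50, 100)
  expect_equal(r3$p_value, 1)
  expect_equal(r3$fold, 0)
  expect_error(binomial_overlap_test(1, 2, 10, 0), "universe")
  expect_error(binomial_overlap_test(1, 2, 11, 10), "exceeds")
})

test_that("hypergeometric test matches exhaustive enumeration", {
  # closed case: all 4 draws hit among 5/10 -> C(5,4)/C(10,4)
  r <- hypergeom_subset_test(10, 5, 4, 4)
  expect_equal(r$p_value, choose(5, 4) / choose(10, 4), tolerance = 1e-12)
  # enumeration oracle over all draw outcomes for random parameters
  set.seed(8)
  for (rep in 1:10) {
    N <- sample(8:25, 1); K <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
    k <- sample(0:min(n, K), 1)
    want <- sum(vapply(k:min(n, K), function(j) {
      choose(K, j) * choose(N - K, n - j) / choose(N, n)
    }, numeric(1)))
    expect_equal(hypergeom_subset_test(N, K, n, k)$p_value, want,
                 tolerance = 1e-9)
  }
  # expectation -> fold 1 (integer case)
  expect_equal(hypergeom_subset_test(10, 5, 4, 2)$fold, 1)
  expect_error(hypergeom_subset_test(10, 5, 4, 5), "bounds")
})

test_that("hypergeometric converges to binomial for large populations", {
  p <- 0.3; n <- 12; k <- 7
  pb <- stats::pbinom(k - 1, n, p, lower.tail = FALSE)
  for (N in c(1e4, 1e6)) {
    ph <- hypergeom_subset_test(N, round(p * N), n, k)$p_value
    expect_equal(ph, pb, tolerance = 10 / sqrt(N))
  }
})

test_that("category cascade applies priorities in order", {
  cons <- data.frame(chrom = "chr1",
                     centroid = c(100L, 500L, 15500L, 900L, 1200L))
  mk <- function(s, e) gr_from_bed0(data.frame(chrom = "chr1", start = s,
                                               end = e))
  genes <- gr_from_bed0(data.frame(chrom = "chr1", start = 10000,
                                   end = 10500, strand = "+"))
  cats <- classify_consensus(
    cons,
    promoter_sets = list(PLS = mk(50, 150)),
    lnc_sets = list(lnc = mk(450, 550)),
    enhancer_sets = list(ELS = mk(50, 150)),       # overlaps the PLS hit
    regulatory_sets = list(DNase = mk(850, 950)),
    genes = genes
  )
  # PLS+ELS double hit resolves to Promoter-like (cascade priority)
  expect_equal(cats, c("Promoter-like", "LNC-body", "Gene-tail",
                       "Regulatory-like", "Unannotated"))
  # centroid 5 kb downstream of the gene end -> Gene-tail window [1k, 9k)
  expect_equal(classify_consensus(data.frame(chrom = "chr1",
                                             centroid = 15500L),
                                  genes = genes), "Gene-tail")
  # minus-strand gene: downstream is leftward
  gneg <- gr_from_bed0(data.frame(chrom = "chr1", start = 10000,
                                  end = 10500, strand = "-"))
  expect_equal(classify_consensus(data.frame(chrom = "chr1",
                                             centroid = 5500L),
                                  genes = gneg), "Gene-tail")
  # no hits anywhere
  expect_equal(classify_consensus(data.frame(chrom = "chr1",
                                             centroid = 42L)),
               "Unannotated")
})

test_that("epigenome-state proportions sum to one and tests behave", {
  set.seed(4)
  n_cons <- 200; n_epi <- 10
  states <- sprintf("S%02d", 1:5)
  calls <- matrix(sample(states, n_cons * n_epi, TRUE), n_cons, n_epi,
                  dimnames = list(NULL, sprintf("E%02d", 1:n_epi)))
  memb <- rep(c(TRUE, FALSE), each = n_cons / 2)
  ep <- epistate_proportions(memb, calls)
  sums <- tapply(ep$proportions$prop_subset,
                 ep$proportions$epigenome, sum)
  expect_equal(as.numeric(sums), rep(1, n_epi), tolerance = 1e-9)
  # identical subsets -> t = 0, p = 1
  ep_same <- epistate_proportions(memb, calls, membership_b = memb)
  expect_true(all(ep_same$tests$t == 0))
  expect_true(all(ep_same$tests$p == 1))
  # a 3x planted state enrichment in the subset is detected
  calls2 <- calls
  hot <- which(memb)[1:60]
  calls2[hot, ] <- "S01"
  ep2 <- epistate_proportions(memb, calls2)
  expect_lt(ep2$tests$p[ep2$tests$state == "S01"], 0.01)
  # single epigenome: proportions only
  ep1 <- epistate_proportions(memb, calls[, 1, drop = FALSE])
  expect_null(ep1$tests)
})

test_that("eQTL enrichment filters and favors the matched tissue", {
  set.seed(12)
  n_reg <- 600
  tissues <- c("T1", "T2", "T3")
  ids <- sprintf("r%04d", 1:n_reg)
  regions <- gr_from_bed0(data.frame(
    chrom = "chr1", start = (seq_len(n_reg) - 1) * 2000,
    end = (seq_len(n_reg) - 1) * 2000 + 1000, region_id = ids
  ))
  mm <- matrix(FALSE, n_reg, 3, dimnames = list(ids, tissues))
  blocks <- split(1:180, rep(1:3, each = 60))
  for (b in 1:3) mm[blocks[[b]], b] <- TRUE
  # eQTLs planted inside each tissue's own marker regions
  eqtls <- lapply(1:3, function(b) {
    idx <- blocks[[b]][1:40]
    data.frame(chrom = "chr1", pos = (idx - 1) * 2000 + 500)
  })
  names(eqtls) <- tissues
  P <- eqtl_enrichment(mm, eqtls, regions, tissue_frac_cap = 1 / 3,
                       min_markers = 20)
  expect_true(all(diag(P) < P[upper.tri(P)] + 1e-12))
  expect_true(all(diag(P) < 1e-4))
  # a tissue short of markers disappears from the output columns
  mm2 <- mm; mm2[blocks[[3]][21:60], 3] <- FALSE
  P2 <- eqtl_enrichment(mm2, eqtls, regions, tissue_frac_cap = 1 / 3,
                        min_markers = 21)
  expect_false("T3" %in% colnames(P2))
  # no eQTLs at all -> p = 1 everywhere
  P3 <- eqtl_enrichment(mm, lapply(eqtls, function(d) d[0, ]), regions,
                        tissue_frac_cap = 1 / 3, min_markers = 20)
  expect_true(all(P3 == 1))
})
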