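# Marker calling, differential regions, meta-clustering, pan-cancer
# threshold.

# Small labeled residual/count pair with planted up-regulated regions in
# one group.
planted_expression <- function(seed, n_regions = 300, n_per = 30,
                               n_up = 30, lfc = 1) {
  set.seed(seed)
  labels <- rep(c("grp", "rest1", "rest2"), each = n_per)
  base <- exp(runif(n_regions, log(5), log(50)))
  mu <- outer(base, rep(1, length(labels)))
  up <- sprintf("r%04d", seq_len(n_up))
  rownames(mu) <- sprintf("r%04d", seq_len(n_regions))
  mu[up, labels == "grp"] <- mu[up, labels == "grp"] * 2^lfc
  counts <- matrix(rnbinom(length(mu), size = 1 / 0.05, mu = mu),
                   nrow = n_regions, dimnames = list(rownames(mu), NULL))
  colnames(counts) <- sprintf("s%03d", seq_along(labels))
  s <- rep(1, length(labels))
  model <- fit_regularized_nb(counts, s, seed = 1)
  res <- pearson_residuals(counts, model)
  list(res = res, counts = counts, labels = labels, s = s, up = up)
}

test_that("expression markers recover planted signal with controlled FDR", {
  recall <- numeric(5); fdp <- numeric(5)
  for (i in 1:5) {
    px <- planted_expression(600 + i)
    em <- expression_markers(px$res, px$counts, px$labels, px$s)
    called <- colnames(em$markers)[em$markers["grp", ]]
    recall[i] <- mean(px$up %in% called)
    fdp[i] <- if (length(called)) mean(!(called %in% px$up)) else 0
  }
  expect_gte(mean(recall), 0.9)
  expect_lte(mean(fdp), 0.1)
})

test_that("a region detected in one group sample is never a marker", {
  px <- planted_expression(11)
  # forge a region: zero in the group except one sample, huge there
  hot <- "r0150"
  px$counts[hot, px$labels == "grp"] <- 0L
  px$counts[hot, which(px$labels == "grp")[1]] <- 1000L
  px$res[hot, px$labels == "grp"] <- 0
  px$res[hot, which(px$labels == "grp")[1]] <- 5
  em <- expression_markers(px$res, px$counts, px$labels, px$s)
  expect_false(em$markers["grp", hot])
})

test_that("null groups yield marker rates at or below the nominal FDR", {
  rates <- vapply(1:5, function(sd) {
    px <- planted_expression(700 + sd, n_up = 0)
    em <- expression_markers(px$res, px$counts, px$labels, px$s)
    mean(em$markers["grp", ])
  }, numeric(1))
  expect_lte(mean(rates), 0.05)
})

test_that("occupancy markers match exhaustive hypergeometric enumeration", {
  # 5 datasets of biotype A among 50; a consensus bound by exactly those 5
  ds_bt <- c(rep("A", 5), rep("B", 45))
  names(ds_bt) <- sprintf("d%02d", 1:50)
  M <- matrix(FALSE, 50, 3, dimnames = list(names(ds_bt), c("c1", "c2", "c3")))
  M[1:5, "c1"] <- TRUE          # pure biotype-A consensus
  M[, "c2"] <- TRUE             # bound by everyone
  M[c(1, 6, 7), "c3"] <- TRUE   # mixed
  om <- occupancy_markers(M, ds_bt)
  N <- sum(M); K <- sum(M[1:5, ])
  p_manual <- sum(vapply(5:5, function(j) {
    choose(K, j) * choose(N - K, 5 - j) / choose(N, 5)
  }, numeric(1)))
  expect_equal(om$p["A", "c1"], p_manual, tolerance = 1e-12)
  expect_true(om$markers["A", "c1"])
  # with a balanced background, a consensus bound by every dataset is
  # enriched for no biotype
  Mb <- matrix(TRUE, 10, 4,
               dimnames = list(sprintf("e%02d", 1:10), sprintf("c%d", 1:4)))
  btb <- c(rep("A", 3), rep("B", 7))
  names(btb) <- rownames(Mb)
  omb <- occupancy_markers(Mb, btb)
  expect_gt(min(omb$p), 0.3)
  expect_false(any(omb$markers))
})

test_that("occupancy marker p-values agree with a shuffle-based null", {
  set.seed(20)
  for (rep in 1:3) {
    n_ds <- sample(20:40, 1)
    bt <- sample(c("A", "B", "C"), n_ds, TRUE)
    names(bt) <- sprintf("d%02d", seq_len(n_ds))
    M <- matrix(runif(n_ds * 4) < 0.4, n_ds, 4,
                dimnames = list(names(bt), sprintf("c%d", 1:4)))
    om <- occupancy_markers(M, bt)
    # Monte-Carlo: draw n memberships from the N-peak pool, count biotype-A
    N <- sum(M); K <- sum(M[bt == "A", ]); n <- sum(M[, 1])
    k <- sum(M[bt == "A", 1])
    pool <- c(rep(1L, K), rep(0L, N - K))
    draws <- replicate(20000, sum(sample(pool, n)))
    p_mc <- mean(draws >= k)
    se <- sqrt(p_mc * (1 - p_mc) / 20000)
    expect_lt(abs(om$p["A", "c1"] - p_mc), 3 * max(se, 1e-3))
  }
})

test_that("differential regions are signed and antisymmetric", {
  px <- planted_expression(42, n_up = 20, lfc = 1.5)
  cond <- ifelse(px$labels == "grp", "tumor", "normal")
  dr <- differential_regions(px$res, px$counts, cond, px$s,
                             cond_a = "tumor")
  called <- dr$region_id[dr$selected]
  expect_gte(mean(px$up %in% called), 0.8)
  expect_true(all(dr$sign[dr$region_id %in% px$up] == 1))
  # swapping the reference condition flips every sign
  dr2 <- differential_regions(px$res, px$counts, cond, px$s,
                              cond_a = "normal")
  expect_equal(dr2$lfc, -dr$lfc, tolerance = 1e-12)
  expect_equal(dr2$selected, dr$selected)
  # identical groups stay near-silent
  cond_null <- rep(c("a", "b"), length.out = length(px$labels))
  drn <- differential_regions(px$res[!rownames(px$res) %in% px$up, ],
                              px$counts[!rownames(px$counts) %in% px$up, ],
                              cond_null, px$s, cond_a = "a")
  expect_lte(mean(drn$selected), 0.05)
})

test_that("meta-clustering distances follow the Yule formula and filters", {
  mk <- rbind(
    src1.A = c(1, 1, 1, 0, 0, 0, 1),
    src2.A = c(1, 1, 1, 0, 0, 0, 1),
    src1.B = c(0, 0, 0, 1, 1, 1, 1),
    src2.B = c(0, 0, 0, 1, 1, 1, 1)
  ) == 1
  colnames(mk) <- sprintf("r%d", 1:7)
  # r7 is a marker in all 4 rows (> 10% of rows); singletons dropped too
  mc <- meta_cluster(mk, max_frac = 0.6, min_rows = 2)
  expect_false("r7" %in% mc$kept_regions)
  expect_equal(mc$dist["src1.A", "src2.A"], 0)
  expect_equal(mc$dist["src1.A", "src1.B"], 2) # complementary rows
  # identical rows merge first
  expect_equal(sort(mc$hc$merge[1, ]), c(-2, -1))
  expect_error(meta_cluster(mk, max_frac = 0.01), "dropped")
})

test_that("matching-biotype marker sets sit closer than non-matching ones", {
  set.seed(33)
  n_reg <- 400; biotypes <- sprintf("b%d", 1:5)
  blocks <- split(seq_len(250), rep(1:5, each = 50))
  mk <- list()
  for (src in c("chip", "rna")) {
    for (b in 1:5) {
      v <- runif(n_reg) < 0.02
      v[blocks[[b]]] <- runif(50) < 0.7
      mk[[paste(src, biotypes[b], sep = ".")]] <- v
    }
  }
  mk <- do.call(rbind, mk)
  colnames(mk) <- sprintf("r%04d", seq_len(n_reg))
  mc <- meta_cluster(mk, max_frac = 0.5, min_rows = 2)
  bt_of <- sub("^[a-z]+\\.", "", rownames(mc$dist))
  same <- outer(bt_of, bt_of, "==") & upper.tri(mc$dist)
  diff_ <- !outer(bt_of, bt_of, "==") & upper.tri(mc$dist)
  wt <- suppressWarnings(stats::wilcox.test(mc$dist[same], mc$dist[diff_],
                                            alternative = "less"))
  expect_lt(wt$p.value, 0.01)
})

test_that("pan-cancer threshold separates planted sharing from the null", {
  universe <- sprintf("r%05d", 1:10000)
  # planted: 100 regions marker in all 8 cancers, the rest random
  set.seed(3)
  shared <- universe[1:100]
  sets <- lapply(1:8, function(i) {
    unique(c(shared, sample(universe, 400)))
  })
  names(sets) <- sprintf("cancer%d", 1:8)
  pc <- pancancer_threshold(sets, universe, seed = 1)
  expect_lte(pc$threshold, 8)
  expect_true(all(shared %in% pc$regions))
  # self-null: random marker sets yield (almost) no calls
  false_frac <- vapply(1:10, function(sd) {
    set.seed(sd)
    nullsets <- lapply(1:8, function(i) sample(universe, 400))
    names(nullsets) <- sprintf("cancer%d", 1:8)
    pcn <- pancancer_threshold(nullsets, universe, seed = sd)
    length(pcn$regions) / sum(pcn$observed_counts >= 1)
  }, numeric(1))
  expect_lte(mean(false_frac), 0.05)
  expect_error(pancancer_threshold(list(a = universe[1:5]), universe),
               "2 cancers")
})
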