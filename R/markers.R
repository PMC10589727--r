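# Marker calling (expression and occupancy), tumor/normal differential
# regions, cross-source meta-clustering, and the resampling pan-cancer
# threshold.

# Detectability requirement: >= 1 read in at least max(ceil(frac*n), 2)
# samples of a group.
detected_in_group <- function(counts, group, min_frac = 0.10) {
  need <- max(ceiling(min_frac * sum(group)), 2L)
  rowSums(counts[, group, drop = FALSE] >= 1L) >= need
}

# log2 fold change of size-factor-normalized mean counts with pseudocount 1.
log2fc_norm <- function(counts, s, group) {
  norm <- sweep(counts, 2, s, "/")
  log2((rowMeans(norm[, group, drop = FALSE]) + 1) /
         (rowMeans(norm[, !group, drop = FALSE]) + 1))
}

#' Expression markers per biotype (group versus rest)
#'
#' A region is a marker of a biotype if (a) a one-sided Welch t-test on the
#' Pearson residuals (group > rest) passes a Benjamini-Hochberg FDR of
#' `fdr`, (b) the log2 fold change of size-factor-normalized mean counts
#' (pseudocount 1) exceeds `lfc_min`, and (c) the region is detectable
#' (>= 1 read) in at least max(10% of the group, 2) group samples. All
#' three are required.
#'
#' @param residuals regions x samples Pearson residuals.
#' @param counts matching raw count matrix.
#' @param labels sample -> biotype labels (length = columns).
#' @param s per-sample size factors.
#' @param fdr FDR threshold (default 0.05).
#' @param lfc_min minimum log2 fold change (default 0.25).
#' @param min_frac detectability fraction (default 0.10).
#' @return list with `markers` (logical biotypes x regions matrix) and
#'   `detail` (per-biotype data.frames with t, q, lfc, detected).
#' @export
expression_markers <- function(residuals, counts, labels, s, fdr = 0.05,
                               lfc_min = 0.25, min_frac = 0.10) {
  stopifnot(ncol(residuals) == length(labels),
            all(dim(residuals) == dim(counts)))
  biotypes <- sort(unique(labels))
  ids <- rownames(residuals)
  mk <- matrix(FALSE, length(biotypes), nrow(residuals),
               dimnames = list(biotypes, ids))
  detail <- list()
  for (b in biotypes) {
    g <- labels == b
    if (sum(g) < 2L || sum(!g) < 2L) {
      message("biotype ", b, " skipped: fewer than 2 samples in a group")
      next
    }
    tt <- row_welch_t(residuals, g, alternative = "greater")
    q <- stats::p.adjust(tt$p, method = "BH")
    lfc <- log2fc_norm(counts, s, g)
    det <- detected_in_group(counts, g, min_frac)
    mk[b, ] <- q <= fdr & lfc > lfc_min & det
    detail[[b]] <- data.frame(region_id = ids, t = tt$statistic, q = q,
                              lfc = lfc, detected = det,
                              stringsAsFactors = FALSE)
  }
  list(markers = mk, detail = detail)
}

#' Occupancy markers per biotype from the binary matrix
#'
#' For each consensus region and biotype, an upper-tail hypergeometric test
#' with N = total peak memberships across all experiments, K = memberships
#' from datasets of the biotype, n = experiments with a peak at the region,
#' and k = biotype experiments with a peak there. Benjamini-Hochberg FDR is
#' applied within each biotype.
#'
#' @param M logical occupancy matrix (datasets x regions).
#' @param dataset_biotypes biotype per dataset (named by dataset or in row
#'   order of `M`).
#' @param fdr FDR threshold (default 0.05).
#' @return list with `markers` (logical biotypes x regions), `p` and `q`
#'   matrices of the same shape.
#' @export
occupancy_markers <- function(M, dataset_biotypes, fdr = 0.05) {
  if (!is.null(names(dataset_biotypes)))
    dataset_biotypes <- dataset_biotypes[rownames(M)]
  stopifnot(length(dataset_biotypes) == nrow(M))
  biotypes <- sort(unique(dataset_biotypes))
  N <- sum(M)
  n_j <- colSums(M)
  P <- matrix(NA_real_, length(biotypes), ncol(M),
              dimnames = list(biotypes, colnames(M)))
  for (b in biotypes) {
    rows <- dataset_biotypes == b
    K <- sum(M[rows, , drop = FALSE])
    k_j <- colSums(M[rows, , drop = FALSE])
    P[b, ] <- stats::phyper(k_j - 1, K, N - K, n_j, lower.tail = FALSE)
  }
  Q <- t(apply(P, 1, stats::p.adjust, method = "BH"))
  list(markers = Q <= fdr, p = P, q = Q)
}

#' Differential regions between two conditions
#'
#' Two-sided Welch t-test on the Pearson residuals (BH FDR `fdr`),
#' absolute log2 fold change above `lfc_min`, and detectability in at
#' least max(10%, 2 samples) of either condition. The sign follows the
#' first condition level minus the second (positive = up in `cond_a`).
#'
#' @param residuals regions x samples Pearson residuals.
#' @param counts matching raw counts.
#' @param condition two-level labels per sample (e.g. tumor/normal).
#' @param s size factors.
#' @param cond_a the level treated as the "up" direction; defaults to the
#'   first level encountered.
#' @param fdr,lfc_min,min_frac thresholds as in [expression_markers()].
#' @return data.frame region_id, t, q, lfc, sign, selected.
#' @export
differential_regions <- function(residuals, counts, condition, s,
                                 cond_a = NULL, fdr = 0.05,
                                 lfc_min = 0.25, min_frac = 0.10) {
  lv <- unique(condition)
  stopifnot(length(lv) == 2L)
  if (is.null(cond_a)) cond_a <- lv[1]
  g <- condition == cond_a
  stopifnot(sum(g) >= 2L, sum(!g) >= 2L)
  tt <- row_welch_t(residuals, g, alternative = "two.sided")
  q <- stats::p.adjust(tt$p, method = "BH")
  lfc <- log2fc_norm(counts, s, g)
  det <- detected_in_group(counts, g, min_frac) |
    detected_in_group(counts, !g, min_frac)
  sel <- q <= fdr & abs(lfc) > lfc_min & det
  ids <- rownames(residuals)
  data.frame(region_id = ids, t = tt$statistic, q = q, lfc = lfc,
             sign = ifelse(lfc >= 0, 1L, -1L), selected = sel,
             stringsAsFactors = FALSE)
}

#' Meta-cluster (source, biotype) marker sets under Yule dissimilarity
#'
#' Regions that are markers in more than `max_frac` of the rows (ubiquitous)
#' or in fewer than `min_rows` rows (private) are dropped; the remaining
#' binary rows are compared with the Yule dissimilarity
#' d = 2 c10 c01 / (c11 c00 + c10 c01) (0/0 -> 0) and clustered with
#' average linkage. Matching biotypes from different sources are expected
#' to pair up.
#'
#' @param markers logical matrix, rows = (source, biotype) combinations,
#'   columns = regions.
#' @param max_frac ubiquity cap (default 0.10).
#' @param min_rows minimum rows a region must mark (default 2).
#' @return list with `dist` (matrix), `hc` (average-linkage hclust) and
#'   `kept_regions`.
#' @export
meta_cluster <- function(markers, max_frac = 0.10, min_rows = 2L) {
  stopifnot(nrow(markers) >= 2L)
  cs <- colSums(markers)
  keep <- cs >= min_rows & cs <= max_frac * nrow(markers)
  if (!any(keep)) stop("all regions dropped by the marker-frequency filters")
  x <- markers[, keep, drop = FALSE]
  d <- yule_dist(x)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  list(dist = d, hc = hc, kept_regions = colnames(markers)[keep])
}

#' Resampling threshold for pan-cancer markers
#'
#' The observed statistic per region is the number of cancers calling it a
#' marker. The null preserves each cancer's marker count exactly: in each
#' of `n_iter` iterations, each cancer draws |markers_c| regions uniformly
#' without replacement from the universe. The threshold T is the smallest
#' count at which the expected null tail is less than `fdr` times the
#' observed tail; regions with observed count >= T are the pan-cancer set.
#'
#' @param marker_sets list cancer -> character vector of marker region ids.
#' @param universe character vector of all region ids.
#' @param n_iter number of null iterations (default 100).
#' @param fdr FDR bound (default 0.05).
#' @param seed integer seed.
#' @return list with `threshold` (Inf if unattainable, with a message),
#'   `regions` (the pan-cancer set), `observed_counts`, `null_tail_mean`,
#'   `null_tail_se` (per candidate threshold).
#' @export
pancancer_threshold <- function(marker_sets, universe, n_iter = 100L,
                                fdr = 0.05, seed = 1L) {
  if (length(marker_sets) < 2L) stop("need at least 2 cancers")
  stopifnot(all(unlist(marker_sets) %in% universe))
  sizes <- lengths(marker_sets)
  obs <- table(factor(unlist(lapply(marker_sets, unique)), levels = universe))
  obs <- as.integer(obs)
  names(obs) <- universe
  tmax <- length(marker_sets)
  obs_tail <- vapply(seq_len(tmax), function(T) sum(obs >= T), numeric(1))
  null_tails <- with_seed(stream_seed(seed, "pancancer"), {
    acc <- matrix(0, n_iter, tmax)
    nuniv <- length(universe)
    for (it in seq_len(n_iter)) {
      cnt <- integer(nuniv)
      for (sz in sizes) {
        draw <- sample.int(nuniv, sz)
        cnt[draw] <- cnt[draw] + 1L
      }
      acc[it, ] <- vapply(seq_len(tmax), function(T) sum(cnt >= T), numeric(1))
    }
    acc
  })
  null_mean <- colMeans(null_tails)
  null_se <- apply(null_tails, 2, stats::sd) / sqrt(n_iter)
  ratio <- ifelse(obs_tail > 0, null_mean / obs_tail, Inf)
  ok <- which(ratio < fdr)
  if (!length(ok)) {
    message("no threshold satisfies the FDR bound; returning empty set")
    return(list(threshold = Inf, regions = character(),
                observed_counts = obs, null_tail_mean = null_mean,
                null_tail_se = null_se))
  }
  T_star <- min(ok)
  list(threshold = T_star, regions = universe[obs >= T_star],
       observed_counts = obs, null_tail_mean = null_mean,
       null_tail_se = null_se)
}
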