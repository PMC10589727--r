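# Biotype contribution scores, Gini-Simpson diversity, the category
# cascade, and the overlap/epigenome/eQTL enrichment tests.

#' Biotype contribution scores and Gini-Simpson diversity
#'
#' For biotype i and consensus j, the raw contribution is
#' s_ij = sum over datasets of biotype i of M_kj. Each biotype row is then
#' normalized by its total contribution across all consensus
#' (n_ij = s_ij / sum_j' s_ij'), which prevents over-represented biotypes
#' (or biotypes with peak-rich datasets) from dominating the labels. The
#' per-consensus proportions p_ij = n_ij / sum_i' n_i'j sum to one, the
#' dominant biotype is argmax_i n_ij, and the Gini-Simpson index is
#' lambda_j = 1 - sum_i p_ij^2 (0 for a fully biotype-specific consensus,
#' up to 1 - 1/R for an equidistributed one).
#'
#' @param M logical occupancy matrix (datasets x consensus), or a numeric
#'   peak-count matrix when `use_counts = TRUE`.
#' @param datasets data.frame with `dataset_id` and `biotype` covering the
#'   rows of `M`.
#' @param use_counts if TRUE, `M` is interpreted as per-dataset peak counts
#'   instead of binary membership.
#' @return list with matrices `s`, `n`, `p` (biotypes x consensus),
#'   `lambda` (per consensus; NA where the column is all-zero), and
#'   `dominant_biotype` (per consensus; NA where undefined).
#' @export
biotype_scores <- function(M, datasets, use_counts = FALSE) {
  stopifnot(all(rownames(M) %in% datasets$dataset_id))
  bt <- datasets$biotype[match(rownames(M), datasets$dataset_id)]
  if (any(is.na(bt) | bt == "")) stop("every dataset needs a biotype")
  X <- if (use_counts) M * 1 else (M != 0) * 1
  s <- rowsum(X, group = bt)
  tot <- rowSums(s)
  n <- s / ifelse(tot > 0, tot, 1)
  ctot <- colSums(n)
  p <- sweep(n, 2, ifelse(ctot > 0, ctot, 1), "/")
  lambda <- 1 - colSums(p^2)
  dominant <- rownames(n)[max.col(t(n), ties.method = "first")]
  zero <- ctot == 0
  lambda[zero] <- NA_real_
  dominant[zero] <- NA_character_
  p[, zero] <- NA_real_
  list(s = s, n = n, p = p, lambda = lambda, dominant_biotype = dominant)
}

#' Binomial overlap enrichment against a coverage-based expectation
#'
#' Tests whether `k` of `n_trials` consensus centroids hitting a feature
#' exceeds the expectation under a per-trial hit probability equal to the
#' feature's share of the universe coverage. The p-value is the upper-tail
#' binomial probability P(X >= k); the fold change is k / (n * p).
#'
#' @param k observed number of hits.
#' @param n_trials total number of consensus regions.
#' @param feature_coverage feature coverage in bp.
#' @param universe_coverage universe (intergenic space) coverage in bp.
#' @param feature_name label carried into the result.
#' @return one-row data.frame (feature, test, k, n, p_param, p_value, fold).
#' @export
binomial_overlap_test <- function(k, n_trials, feature_coverage,
                                  universe_coverage,
                                  feature_name = "feature") {
  if (universe_coverage <= 0) stop("universe_coverage must be > 0")
  if (feature_coverage > universe_coverage)
    stop("feature_coverage exceeds universe_coverage")
  stopifnot(k >= 0, k <= n_trials)
  p_param <- feature_coverage / universe_coverage
  p_value <- stats::pbinom(k - 1, n_trials, p_param, lower.tail = FALSE)
  fold <- if (n_trials * p_param > 0) k / (n_trials * p_param) else NA_real_
  data.frame(feature = feature_name, test = "binomial", k = k, n = n_trials,
             p_param = p_param, p_value = p_value, fold = fold,
             stringsAsFactors = FALSE)
}

#' Hypergeometric subset enrichment
#'
#' Tests whether a subset of consensus regions hits a feature more often
#' than the whole atlas does, removing the atlas-wide intersection bias:
#' P(X >= k) under Hypergeometric(N, K, n). Fold change is (k/n)/(K/N).
#'
#' @param N population size (all consensus regions).
#' @param K population successes (consensus hitting the feature).
#' @param n draws (subset size).
#' @param k observed subset successes.
#' @param feature_name label carried into the result.
#' @return one-row data.frame (feature, test, N, K, n, k, p_value, fold).
#' @export
hypergeom_subset_test <- function(N, K, n, k, feature_name = "feature") {
  if (k > min(n, K) || n > N || K > N || any(c(N, K, n, k) < 0))
    stop("invalid hypergeometric bounds")
  p_value <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
  data.frame(feature = feature_name, test = "hypergeometric",
             N = N, K = K, n = n, k = k, p_value = p_value, fold = fold,
             stringsAsFactors = FALSE)
}

#' Categorize consensus regions by a priority cascade
#'
#' Each centroid is tested against reference sets in a fixed priority
#' order; the first matching category wins:
#' Promoter-like, LNC-body, Enhancer-like, Regulatory-like, Gene-tail,
#' Unannotated. Gene-tail means the centroid lies 1-9 kb downstream of a
#' gene end, strand-aware.
#'
#' @param consensus consensus table with `chrom` and `centroid`.
#' @param promoter_sets list of GRanges whose union defines Promoter-like
#'   evidence (e.g. promoter-like cCREs, H3K4me3 cCREs, CAGE TSS, lncRNA
#'   promoters as TSS +/- 1 kb).
#' @param lnc_sets list of GRanges of lncRNA transcript bodies (already
#'   extended as desired).
#' @param enhancer_sets list of GRanges of enhancer evidence.
#' @param regulatory_sets list of GRanges of other regulatory evidence
#'   (CRMs, DNase).
#' @param genes stranded GRanges of genes for the Gene-tail window.
#' @param tail_from downstream window start offset in bp (default 1000).
#' @param tail_to downstream window end offset in bp (default 9000).
#' @return character vector of categories, one per consensus.
#' @export
classify_consensus <- function(consensus,
                               promoter_sets = list(),
                               lnc_sets = list(),
                               enhancer_sets = list(),
                               regulatory_sets = list(),
                               genes = GenomicRanges::GRanges(),
                               tail_from = 1000L, tail_to = 9000L) {
  pts <- data.frame(chrom = consensus$chrom, pos = consensus$centroid)
  hit_any <- function(sets) {
    if (!length(sets)) return(rep(FALSE, nrow(pts)))
    Reduce(`|`, lapply(sets, function(g) intersect_centroids(pts, g)))
  }
  cat <- rep("Unannotated", nrow(pts))
  if (length(genes)) {
    plus <- as.character(GenomicRanges::strand(genes)) != "-"
    tail_start <- ifelse(plus, GenomicRanges::end(genes) + tail_from,
                         GenomicRanges::start(genes) - tail_to)
    tail_end <- ifelse(plus, GenomicRanges::end(genes) + tail_to,
                       GenomicRanges::start(genes) - tail_from)
    tails <- GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(genes),
      ranges = IRanges::IRanges(start = pmax(tail_start, 1), end = pmax(tail_end, 1))
    )
    cat[intersect_centroids(pts, tails)] <- "Gene-tail"
  }
  cat[hit_any(regulatory_sets)] <- "Regulatory-like"
  cat[hit_any(enhancer_sets)] <- "Enhancer-like"
  cat[hit_any(lnc_sets)] <- "LNC-body"
  cat[hit_any(promoter_sets)] <- "Promoter-like"
  cat
}

#' Epigenetic-state proportions of a consensus subset, with paired tests
#'
#' For each epigenome, computes the proportion of each chromatin state
#' among the consensus of a subset (proportions sum to one within an
#' epigenome), and likewise for a comparison subset (by default the
#' complement). A paired t-test across epigenomes assesses, per state,
#' whether the subset's proportion differs from the comparison's.
#'
#' @param membership logical vector over consensus (the subset/cluster).
#' @param state_calls matrix consensus x epigenomes of state labels.
#' @param membership_b optional second subset; default is `!membership`.
#' @param states state vocabulary; defaults to the labels present.
#' @return list with `proportions` (data.frame: epigenome, state, subset
#'   proportion, comparison proportion) and `tests` (per state: t, p; NULL
#'   with a single epigenome).
#' @export
epistate_proportions <- function(membership, state_calls,
                                 membership_b = NULL, states = NULL) {
  stopifnot(length(membership) == nrow(state_calls))
  if (is.null(membership_b)) membership_b <- !membership
  if (is.null(states)) states <- sort(unique(as.vector(state_calls)))
  epis <- colnames(state_calls)
  if (is.null(epis)) epis <- sprintf("epi%02d", seq_len(ncol(state_calls)))
  prop_of <- function(memb) {
    sapply(seq_len(ncol(state_calls)), function(e) {
      tab <- table(factor(state_calls[memb, e], levels = states))
      as.numeric(tab) / max(sum(tab), 1L)
    }) # states x epigenomes
  }
  pa <- prop_of(membership)
  pb <- prop_of(membership_b)
  rownames(pa) <- rownames(pb) <- states
  props <- do.call(rbind, lapply(seq_along(epis), function(e) {
    data.frame(epigenome = epis[e], state = states,
               prop_subset = pa[, e], prop_comparison = pb[, e],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  tests <- NULL
  if (ncol(state_calls) >= 2L) {
    tests <- do.call(rbind, lapply(states, function(st) {
      d <- pa[st, ] - pb[st, ]
      if (all(abs(d - 0) < 1e-15)) {
        data.frame(state = st, t = 0, p = 1, stringsAsFactors = FALSE)
      } else {
        tt <- stats::t.test(d)
        data.frame(state = st, t = unname(tt$statistic), p = tt$p.value,
                   stringsAsFactors = FALSE)
      }
    }))
  }
  list(proportions = props, tests = tests)
}

#' Pairwise tissue-specific eQTL enrichment of marker regions
#'
#' SNPs that are eQTLs in more than `tissue_frac_cap` of the tissues are
#' removed (they are unlikely to sit in tissue-specific regulatory
#' regions); regions that are markers in more than `tissue_frac_cap` of
#' the tissues, or markers of no tissue, are removed; marker tissues with
#' fewer than `min_markers` surviving markers are dropped. Each
#' (eQTL tissue, marker tissue) pair is then scored with
#' [hypergeom_subset_test()] over the surviving regions.
#'
#' @param marker_matrix logical matrix regions x tissues (marker status).
#' @param eqtl_snps list tissue -> data.frame(chrom, pos) of eQTL SNPs
#'   (0-based positions); SNP identity across tissues is chrom:pos.
#' @param regions GRanges of the (standardized) regions, with `region_id`
#'   matching the rownames of `marker_matrix`; SNPs are intersected
#'   against the whole region.
#' @param tissue_frac_cap ubiquity cap (default 0.10).
#' @param min_markers minimum surviving markers per tissue (default 50).
#' @return matrix of p-values, eQTL tissues x marker tissues.
#' @export
eqtl_enrichment <- function(marker_matrix, eqtl_snps, regions,
                            tissue_frac_cap = 0.10, min_markers = 50L) {
  tissues <- colnames(marker_matrix)
  stopifnot(!is.null(tissues), all(names(eqtl_snps) %in% tissues) || TRUE)
  # SNP ubiquity filter
  all_snps <- unique(do.call(rbind, lapply(eqtl_snps, function(d)
    d[c("chrom", "pos")])))
  if (is.null(all_snps) || nrow(all_snps) == 0L) {
    keep_key <- character(0)
  } else {
    key_of <- function(d) paste(d$chrom, d$pos, sep = ":")
    ub <- Reduce(`+`, lapply(eqtl_snps, function(d)
      key_of(all_snps) %in% key_of(d)))
    keep_key <- key_of(all_snps)[ub <= tissue_frac_cap * length(eqtl_snps)]
  }
  # region marker-frequency filter: markers of >=1 and <= cap tissues
  nmark <- rowSums(marker_matrix)
  keep_r <- nmark >= 1L & nmark <= tissue_frac_cap * ncol(marker_matrix)
  mm <- marker_matrix[keep_r, , drop = FALSE]
  N <- nrow(mm)
  if (N == 0L)
    stop("no region survives the marker-frequency filter; ",
         "check tissue_frac_cap against the number of tissues")
  reg <- regions[match(rownames(mm), S4Vectors::mcols(regions)$region_id)]
  marker_tissues <- tissues[colSums(mm) >= min_markers]
  # region x eqtl-tissue hit matrix (surviving SNPs vs whole regions)
  hit <- vapply(names(eqtl_snps), function(tn) {
    d <- eqtl_snps[[tn]]
    if (nrow(d)) d <- d[paste(d$chrom, d$pos, sep = ":") %in% keep_key, ,
                        drop = FALSE]
    if (nrow(d) == 0L) return(rep(FALSE, N))
    snp_gr <- GenomicRanges::GRanges(d$chrom,
                                     IRanges::IRanges(d$pos + 1L, width = 1L))
    IRanges::overlapsAny(reg, snp_gr)
  }, logical(N))
  if (is.null(dim(hit))) hit <- matrix(hit, nrow = N,
                                       dimnames = list(NULL, names(eqtl_snps)))
  P <- matrix(NA_real_, length(eqtl_snps), length(marker_tissues),
              dimnames = list(names(eqtl_snps), marker_tissues))
  for (ti in names(eqtl_snps)) {
    K <- sum(hit[, ti])
    for (tj in marker_tissues) {
      n <- sum(mm[, tj])
      k <- sum(hit[, ti] & mm[, tj])
      P[ti, tj] <- hypergeom_subset_test(N, K, n, k)$p_value
    }
  }
  P
}
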