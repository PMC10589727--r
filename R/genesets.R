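# Region-to-gene assignment via regulatory domains, gene-set enrichment
# with a negative-binomial GLM corrected by expected hits, and
# term-redundancy reduction.

#' GREAT-style regulatory domains
#'
#' Each gene gets a basal domain of 5 kb upstream / 1 kb downstream of its
#' TSS (strand-aware), extended on each side up to `max_ext` bp or to the
#' nearest other gene's basal domain, whichever is closer; the extension
#' never shrinks below the basal domain.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `strand` ("+"/"-"),
#'   `tss` (0-based position), or a stranded GRanges with `gene_id` (the
#'   TSS is then the strand-aware 5' end).
#' @param basal_up,basal_down basal extents in bp (defaults 5000 / 1000).
#' @param max_ext maximum extension per side in bp (default 1e6).
#' @return data.frame gene_id, chrom, strand, tss, basal_start, basal_end,
#'   ext_start, ext_end (0-based half-open).
#' @export
regulatory_domains <- function(genes, basal_up = 5000L, basal_down = 1000L,
                               max_ext = 1e6) {
  if (inherits(genes, "GRanges")) {
    plus <- as.character(GenomicRanges::strand(genes)) != "-"
    genes <- data.frame(
      gene_id = S4Vectors::mcols(genes)$gene_id,
      chrom = as.character(GenomicRanges::seqnames(genes)),
      strand = ifelse(plus, "+", "-"),
      tss = ifelse(plus, GenomicRanges::start(genes) - 1L,
                   GenomicRanges::end(genes) - 1L),
      stringsAsFactors = FALSE
    )
  }
  plus <- genes$strand != "-"
  basal_start <- ifelse(plus, genes$tss - basal_up, genes$tss - basal_down + 1L)
  basal_end <- ifelse(plus, genes$tss + basal_down, genes$tss + basal_up + 1L)
  basal_start <- pmax(basal_start, 0)
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    strand = genes$strand, tss = genes$tss,
                    basal_start = basal_start, basal_end = basal_end,
                    ext_start = NA_real_, ext_end = NA_real_,
                    stringsAsFactors = FALSE)
  for (ch in unique(out$chrom)) {
    i <- which(out$chrom == ch)
    o <- i[order(out$basal_start[i], out$basal_end[i])]
    bs <- out$basal_start[o]; be <- out$basal_end[o]
    n <- length(o)
    # nearest other basal edge on each side (running extrema excluding self)
    left_lim <- rep(-Inf, n); right_lim <- rep(Inf, n)
    if (n > 1L) {
      left_lim <- c(-Inf, cummax(be[-n]))
      right_lim <- c(rev(cummin(rev(bs[-1]))), Inf)
    }
    ext_s <- pmin(bs, pmax(bs - max_ext, left_lim, 0))
    ext_e <- pmax(be, pmin(be + max_ext, right_lim))
    out$ext_start[o] <- ext_s
    out$ext_end[o] <- ext_e
  }
  out
}

#' Count consensus regions in each gene's regulatory domain
#'
#' Centroid-in-domain intersection: n_g counts all universe centroids in
#' the gene's extended domain, k_g the subset's centroids. The expected
#' number of subset hits is E_g = n_g * K / N with K the subset size and N
#' the universe size.
#'
#' @param domains output of [regulatory_domains()].
#' @param universe data.frame with `region_id`, `chrom`, `pos` (centroids).
#' @param subset_ids region ids forming the subset (must be in universe).
#' @return list with `genes` (data.frame gene_id, n, k, E) and globals
#'   `K`, `N`.
#' @export
count_hits <- function(domains, universe, subset_ids) {
  stopifnot(all(subset_ids %in% universe$region_id))
  N <- nrow(universe)
  K <- length(unique(subset_ids))
  dom_gr <- gr_from_bed0(data.frame(
    chrom = domains$chrom, start = domains$ext_start, end = domains$ext_end,
    gene_id = domains$gene_id
  ))
  pts <- GenomicRanges::GRanges(universe$chrom,
                                IRanges::IRanges(universe$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(dom_gr, pts)
  in_sub <- universe$region_id %in% subset_ids
  n_g <- integer(nrow(domains)); k_g <- integer(nrow(domains))
  tab_all <- table(factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(domains))))
  n_g <- as.integer(tab_all)
  sel <- in_sub[S4Vectors::subjectHits(hits)]
  tab_sub <- table(factor(S4Vectors::queryHits(hits)[sel],
                          levels = seq_len(nrow(domains))))
  k_g <- as.integer(tab_sub)
  genes <- data.frame(gene_id = domains$gene_id, n = n_g, k = k_g,
                      E = n_g * K / N, stringsAsFactors = FALSE)
  list(genes = genes, K = K, N = N)
}

#' Gene-set enrichment by negative-binomial regression on gene hit counts
#'
#' Models the per-gene subset hit count k_g with an NB GLM,
#' ln(mu_g) = b0 + b1 * G_g + ln(E_g + eps), where G indicates gene-set
#' membership and the log expected hits enter as an offset, correcting the
#' intersection bias of gene-wise region counts. The one-sided Wald test
#' asks whether b1 > 0. Genes with no regions in their domain are excluded
#' (their expectation is zero); sets are tested only when, after
#' intersection with the measured genes, they hold more than `min_genes-1`
#' and fewer than `max_genes+1` genes.
#'
#' @param hits output of [count_hits()].
#' @param gene_sets named list of gene-id vectors (GMT-like).
#' @param min_genes minimum set size after intersection (default 4).
#' @param max_genes maximum set size (default 999).
#' @param eps offset guard (default 1e-8).
#' @return data.frame: set, n_genes, beta1, p (one-sided Wald), fold
#'   (exp(beta1)), q (BH across tested sets), fallback (TRUE where the NB
#'   fit failed and a Poisson GLM was used).
#' @export
nb_glm_geneset_test <- function(hits, gene_sets, min_genes = 4L,
                                max_genes = 999L, eps = 1e-8) {
  g <- hits$genes[hits$genes$n > 0L, , drop = FALSE]
  off <- log(g$E + eps)
  rows <- lapply(names(gene_sets), function(nm) {
    G <- as.integer(g$gene_id %in% gene_sets[[nm]])
    sz <- sum(G)
    if (sz < min_genes || sz > max_genes) return(NULL)
    fallback <- FALSE
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(g$k ~ G + offset(off))),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) {
      fallback <- TRUE
      fit <- stats::glm(g$k ~ G + offset(off), family = stats::poisson())
    }
    cf <- summary(fit)$coefficients
    b1 <- cf["G", "Estimate"]
    se <- cf["G", "Std. Error"]
    p <- stats::pnorm(b1 / se, lower.tail = FALSE)
    data.frame(set = nm, n_genes = sz, beta1 = b1, p = p,
               fold = exp(b1), fallback = fallback, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(set = character(), n_genes = integer(),
                      beta1 = numeric(), p = numeric(), fold = numeric(),
                      fallback = logical(), q = numeric()))
  }
  res$q <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Reduce redundant significant terms by graph clustering
#'
#' Builds a k-nearest-neighbor graph of terms under the Yule dissimilarity
#' of their gene memberships, partitions it with Leiden, and picks the
#' smallest-p term (ties broken lexicographically by id) as each cluster's
#' representative.
#'
#' @param term_genes logical matrix, terms x genes.
#' @param pvals p-value per term (named or in row order).
#' @param k_neighbors neighborhood size (default 10).
#' @param seed integer seed.
#' @return data.frame term, cluster, p, representative.
#' @export
reduce_terms <- function(term_genes, pvals, k_neighbors = 10L, seed = 1L) {
  terms <- rownames(term_genes)
  if (is.null(terms)) terms <- as.character(seq_len(nrow(term_genes)))
  if (!is.null(names(pvals))) pvals <- pvals[terms]
  if (nrow(term_genes) == 1L) {
    return(data.frame(term = terms, cluster = 0L, p = pvals,
                      representative = TRUE, stringsAsFactors = FALSE))
  }
  d <- yule_dist(term_genes)
  nn <- knn_from_dist(d, min(k_neighbors, nrow(d) - 1L))
  n <- nrow(d)
  adj <- matrix(FALSE, n, n)
  adj[cbind(rep(seq_len(n), each = ncol(nn)), as.vector(t(nn)))] <- TRUE
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cl <- with_seed(stream_seed(seed, "terms"), {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           n_iterations = 5L)
  })
  memb <- as.integer(igraph::membership(cl)) - 1L
  rep_flag <- logical(n)
  for (cc in unique(memb)) {
    i <- which(memb == cc)
    best <- i[order(pvals[i], terms[i])][1]
    rep_flag[best] <- TRUE
  }
  data.frame(term = terms, cluster = memb, p = as.numeric(pvals),
             representative = rep_flag, stringsAsFactors = FALSE)
}

#' Read a GMT-like TSV of gene sets
#' @param path file with one set per line: name, description, genes...
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1], "")
  sets
}
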