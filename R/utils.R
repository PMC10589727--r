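# Shared helpers: seeding, coordinate conversion, binary distances.

#' Derive a per-stream RNG seed from a global seed
#'
#' Each generator in the package draws from its own stream so that adding a
#' generator (or calling them in a different order) does not shift the draws
#' of the others. The stream seed is a deterministic hash of the global seed
#' and a stream label, kept below 2^31.
#'
#' @param seed integer global seed.
#' @param stream character stream label.
#' @return An integer seed.
#' @export
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  v <- utf8ToInt(stream)
  h <- sum(v * seq_along(v)) %% 100003L
  as.integer((abs(as.integer(seed)) %% 1000003L) * 2011L + h * 7919L) %% 2147483587L
}

# Run code under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Convert a 0-based half-open interval table to GRanges
#'
#' The package stores peak and region tables in BED convention (0-based,
#' half-open); interval arithmetic is done on 1-based closed GRanges.
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `strand`; other columns become metadata.
#' @return A [GenomicRanges::GRanges] object.
#' @export
gr_from_bed0 <- function(df) {
  if (nrow(df) == 0L) return(GenomicRanges::GRanges())
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  extra <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  if (length(extra)) S4Vectors::mcols(gr) <- df[extra]
  gr
}

#' Convert GRanges back to a 0-based half-open interval table
#' @param gr a GRanges object.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, plus metadata columns.
#' @export
bed0_from_gr <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  mc <- S4Vectors::mcols(gr)
  if (ncol(mc)) df <- cbind(df, as.data.frame(mc))
  df
}

# Pairwise binary contingency counts between rows of a 0/1 matrix.
binary_counts <- function(x) {
  x <- matrix(as.numeric(x != 0), nrow = nrow(x), dimnames = dimnames(x))
  c11 <- tcrossprod(x)
  c10 <- tcrossprod(x, 1 - x)
  list(c11 = c11, c10 = c10, c01 = t(c10), c00 = tcrossprod(1 - x))
}

#' Pairwise Yule dissimilarity between binary rows
#'
#' d = 2*c10*c01 / (c11*c00 + c10*c01), with 0/0 defined as 0. Identical
#' rows give 0, complementary rows give 2.
#'
#' @param x logical or 0/1 matrix, items in rows.
#' @return symmetric numeric matrix of dissimilarities.
#' @export
yule_dist <- function(x) {
  cc <- binary_counts(x)
  num <- 2 * cc$c10 * cc$c01
  den <- cc$c11 * cc$c00 + cc$c10 * cc$c01
  d <- num / den
  d[den == 0] <- 0
  diag(d) <- 0
  d
}

#' Pairwise Sorensen-Dice dissimilarity between binary rows
#' @param x logical or 0/1 matrix, items in rows.
#' @return symmetric numeric matrix; 1 - 2*c11/(2*c11 + c10 + c01).
#' @export
dice_dist <- function(x) {
  cc <- binary_counts(x)
  den <- 2 * cc$c11 + cc$c10 + cc$c01
  d <- 1 - 2 * cc$c11 / den
  d[den == 0] <- 0
  diag(d) <- 0
  d
}

# Distance matrix under one of the metrics used by the clustering stages.
metric_dist <- function(x, metric = c("euclidean", "pearson-correlation",
                                      "yule", "sorensen-dice")) {
  metric <- match.arg(metric)
  switch(metric,
    "euclidean" = as.matrix(stats::dist(x)),
    "pearson-correlation" = {
      d <- 1 - stats::cor(t(x))
      d[is.na(d)] <- 0
      diag(d) <- 0
      d
    },
    "yule" = yule_dist(x),
    "sorensen-dice" = dice_dist(x)
  )
}

# Vectorized Welch t-test of group vs rest on matrix rows.
# alternative: "greater" (group mean larger) or "two.sided".
row_welch_t <- function(x, group, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is.logical(group), length(group) == ncol(x))
  n1 <- sum(group); n2 <- sum(!group)
  stopifnot(n1 >= 2L, n2 >= 2L)
  m1 <- rowMeans(x[, group, drop = FALSE])
  m2 <- rowMeans(x[, !group, drop = FALSE])
  v1 <- matrixStats::rowVars(x[, group, drop = FALSE])
  v2 <- matrixStats::rowVars(x[, !group, drop = FALSE])
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  bad <- !is.finite(tt) | !is.finite(df)
  tt[bad] <- 0
  df[bad] <- n1 + n2 - 2
  p <- if (alternative == "greater") {
    stats::pt(tt, df, lower.tail = FALSE)
  } else {
    2 * stats::pt(-abs(tt), df)
  }
  list(statistic = tt, df = df, p = p, mean_diff = m1 - m2)
}
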