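# Consensus-region construction: pooled peak summits are turned into a
# smoothed per-bp density, segmented at its strict local minima, and each
# segment supported by enough distinct datasets becomes a consensus region.

#' Gaussian-smoothed summit density on a 1-bp grid
#'
#' The density is the 1-bp summit histogram convolved with a Gaussian
#' kernel truncated at +/- 4 sigma and renormalized to unit mass, evaluated
#' on the grid `[min(summit) - 4 sigma, max(summit) + 4 sigma]`. Total mass
#' equals the number of summits (to within floating-point error).
#'
#' @param summits integer summit positions on one chromosome.
#' @param sigma kernel standard deviation in bp (> 0).
#' @return list with `grid` (integer positions) and `density`.
#' @export
summit_density <- function(summits, sigma) {
  stopifnot(length(summits) >= 1L)
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  halfw <- as.integer(ceiling(4 * sigma))
  offs <- -halfw:halfw
  w <- stats::dnorm(offs, 0, sigma)
  w <- w / sum(w)
  g0 <- min(summits) - halfw
  grid <- g0:(max(summits) + halfw)
  dens <- numeric(length(grid))
  for (s in summits) {
    idx <- (s - g0) + 1L + offs
    dens[idx] <- dens[idx] + w
  }
  list(grid = grid, density = dens)
}

# Strict local minima of a discrete series; an equal-valued plateau that is
# a minimum contributes its leftmost grid index. Endpoints are not minima.
local_minima_idx <- function(d) {
  r <- rle(d)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-k]))
  inner <- 2:(k - 1L)
  is_min <- r$values[inner] < r$values[inner - 1L] &
    r$values[inner] < r$values[inner + 1L]
  starts[inner][is_min]
}

#' Average peak width divided by eight
#'
#' The default kernel bandwidth: one eighth of the average peak size of the
#' post-filter intergenic peaks, computed genome-wide.
#'
#' @param peaks peak data.frame (0-based half-open).
#' @return numeric sigma in bp.
#' @export
auto_sigma <- function(peaks) {
  stopifnot(nrow(peaks) >= 1L)
  mean(peaks$end - peaks$start) / 8
}

#' Segment pooled summits into consensus regions
#'
#' Per chromosome, the smoothed summit density is computed and cut at its
#' strict local minima; every summit between two flanking minima belongs to
#' the same candidate (a summit lying exactly on a minimum goes to the left
#' segment). Candidates with peaks from at least `min_datasets` distinct
#' datasets become consensus regions; boundaries are those of the farthest
#' member peaks and the centroid is the mean member-summit position
#' (rounded half-to-even for output; the exact value is kept).
#'
#' @param peaks filtered intergenic peak data.frame with `chrom`, `start`,
#'   `end`, `summit`, `dataset_id` and optionally `peak_id`.
#' @param sigma kernel sd in bp, or "auto" for [auto_sigma()].
#' @param min_datasets minimum number of distinct contributing datasets.
#' @return data.frame of consensus regions with columns `region_id`,
#'   `chrom`, `start`, `end`, `centroid`, `centroid_exact`, `n_peaks`,
#'   `n_datasets`, plus list columns `member_peak_ids` and `dataset_ids`.
#' @export
segment_consensus <- function(peaks, sigma = "auto", min_datasets = 2L) {
  empty <- data.frame(
    region_id = character(), chrom = character(), start = integer(),
    end = integer(), centroid = integer(), centroid_exact = numeric(),
    n_peaks = integer(), n_datasets = integer(), stringsAsFactors = FALSE
  )
  empty$member_peak_ids <- list()
  empty$dataset_ids <- list()
  if (is.null(peaks) || nrow(peaks) == 0L) return(empty)
  if (identical(sigma, "auto")) sigma <- auto_sigma(peaks)
  if (is.null(peaks$peak_id)) peaks$peak_id <- sprintf("pk%06d", seq_len(nrow(peaks)))
  out <- list()
  for (ch in unique(peaks$chrom)) {
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    sd_ <- summit_density(pk$summit, sigma)
    mins <- sd_$grid[local_minima_idx(sd_$density)]
    # segment index: summits strictly greater than a minimum fall right of
    # it; a summit equal to a minimum position stays in the left segment
    seg <- findInterval(pk$summit, mins + 0.5) # p <= m -> left
    for (sg in unique(seg)) {
      m <- pk[seg == sg, , drop = FALSE]
      nds <- length(unique(m$dataset_id))
      if (nds < min_datasets) next
      ce <- mean(m$summit)
      row <- data.frame(
        region_id = NA_character_, chrom = ch,
        start = min(m$start), end = max(m$end),
        centroid = as.integer(round(ce)), centroid_exact = ce,
        n_peaks = nrow(m), n_datasets = nds, stringsAsFactors = FALSE
      )
      row$member_peak_ids <- list(m$peak_id)
      row$dataset_ids <- list(sort(unique(m$dataset_id)))
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res$region_id <- sprintf("cr%05d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

#' Build the binary dataset-by-consensus occupancy matrix
#'
#' Entry (k, j) is TRUE iff dataset k contributed at least one member peak
#' to consensus j, regardless of how many.
#'
#' @param consensus consensus table from [segment_consensus()].
#' @param datasets data.frame with a `dataset_id` column (row universe).
#' @return logical matrix, datasets x consensus regions.
#' @export
build_occupancy_matrix <- function(consensus, datasets) {
  ids <- datasets$dataset_id
  M <- matrix(FALSE, nrow = length(ids), ncol = nrow(consensus),
              dimnames = list(ids, consensus$region_id))
  for (j in seq_len(nrow(consensus))) {
    dsj <- consensus$dataset_ids[[j]]
    if (!all(dsj %in% ids)) {
      stop("unknown dataset_id in consensus ", consensus$region_id[j], ": ",
           paste(setdiff(dsj, ids), collapse = ", "))
    }
    M[dsj, j] <- TRUE
  }
  M
}

#' Standardize consensus regions to a fixed width around their centroids
#'
#' Each region becomes `[centroid - width/2, centroid + width/2)`; a region
#' running off a chromosome end is shifted inward so its length is
#' preserved.
#'
#' @param consensus consensus table with `chrom` and `centroid`.
#' @param width target width in bp (must be even).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return GRanges with a `region_id` metadata column.
#' @export
standardize_regions <- function(consensus, width = 1000L, chrom_lengths) {
  if (width %% 2L != 0L) stop("width must be even")
  if (nrow(consensus) == 0L) return(GenomicRanges::GRanges())
  L <- chrom_lengths[consensus$chrom]
  if (any(is.na(L))) stop("missing chromosome length")
  if (any(L < width)) stop("chromosome shorter than the target width")
  half <- width %/% 2L
  start <- consensus$centroid - half
  start <- pmax(start, 0L)
  start <- pmin(start, L - width)
  df <- data.frame(chrom = consensus$chrom, start = as.integer(start),
                   end = as.integer(start + width),
                   region_id = consensus$region_id, stringsAsFactors = FALSE)
  gr_from_bed0(df)
}

#' Write consensus regions as BED6 with atlas columns
#' @param consensus consensus table.
#' @param path output file.
#' @export
write_consensus_bed <- function(consensus, path) {
  out <- data.frame(
    chrom = consensus$chrom, start = consensus$start, end = consensus$end,
    name = consensus$region_id, score = 0L, strand = ".",
    centroid = consensus$centroid, n_peaks = consensus$n_peaks,
    n_datasets = consensus$n_datasets
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read the occupancy matrix as TSV
#' @param M logical occupancy matrix.
#' @param path file path.
#' @export
write_occupancy_tsv <- function(M, path) {
  utils::write.table(M * 1L, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_occupancy_tsv
#' @export
read_occupancy_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", check.names = FALSE))
  m != 0
}
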