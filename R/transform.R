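# Count filtering, detectability-restricted pooling size factors, the
# regularized negative-binomial model, clipped Pearson residuals, and
# read-profile matrices.

#' Drop regions without minimal support
#'
#' Keeps regions with at least `min_reads` reads in at least `min_samples`
#' samples. Idempotent.
#'
#' @param counts regions x samples integer matrix.
#' @param min_reads minimum read count (default 1).
#' @param min_samples minimum number of samples (default 3).
#' @return the filtered count matrix.
#' @export
filter_low_counts <- function(counts, min_reads = 1L, min_samples = 3L) {
  keep <- rowSums(counts >= min_reads) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Rank regions by detectability
#'
#' Detectability of a region is the number of samples with at least one
#' read there; ties are broken successively by the number of samples with
#' at least 2, 3, 4 and 5 reads, and any remaining ties by region id, so
#' the ordering is deterministic. The top 5% (ceiling) feed the size-factor
#' computation: this keeps non-expressed or single-condition regions out of
#' the normalization.
#'
#' @param counts regions x samples matrix with rownames.
#' @param top_frac fraction of regions returned as the top subset.
#' @return list with `order` (region ids, best first), `top` (the top
#'   subset ids) and `detectability` (the primary key).
#' @export
detectability_rank <- function(counts, top_frac = 0.05) {
  stopifnot(ncol(counts) >= 1L)
  ids <- rownames(counts)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(counts)))
  keys <- sapply(1:5, function(k) rowSums(counts >= k))
  if (nrow(counts) == 1L) keys <- matrix(keys, nrow = 1L)
  o <- order(-keys[, 1], -keys[, 2], -keys[, 3], -keys[, 4], -keys[, 5], ids)
  n_top <- ceiling(top_frac * nrow(counts))
  list(order = ids[o], top = ids[o][seq_len(n_top)],
       detectability = stats::setNames(keys[, 1], ids))
}

#' Pooling-and-deconvolution size factors on the most detectable regions
#'
#' Computes per-sample normalization factors by summing counts over pools
#' of samples arranged on a library-size-ordered ring, comparing each pool
#' to an average reference, and deconvolving the per-sample factors by
#' least squares (the scran pooling estimator). Run on the
#' detectability-restricted top subset of regions; factors are scaled to
#' mean one. If any solved factor is non-positive the function warns and
#' falls back to median-of-ratios on the same subset.
#'
#' @param counts_top counts restricted to the top detectable regions.
#' @param sizes pool sizes (default c(11, 21, 31), reduced when there are
#'   few samples).
#' @return numeric vector of positive per-sample factors, mean 1.
#' @export
pooling_size_factors <- function(counts_top, sizes = c(11L, 21L, 31L)) {
  ns <- ncol(counts_top)
  if (ns < 8L) stop("need at least 8 samples for pooled size factors")
  sizes <- sort(unique(pmin(sizes, ns)))
  sizes <- sizes[sizes >= 2L]
  sf <- tryCatch(
    scran::calculateSumFactors(as.matrix(counts_top), sizes = sizes,
                               min.mean = 0.1, positive = FALSE),
    error = function(e) rep(-1, ns)
  )
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    warning("non-positive pooled size factor; falling back to median-of-ratios")
    sf <- median_of_ratios(counts_top)
  }
  sf <- sf / mean(sf)
  stats::setNames(sf, colnames(counts_top))
}

# DESeq-style median-of-ratios on rows with an all-positive geometric mean.
median_of_ratios <- function(counts) {
  lg <- log(counts)
  use <- rowSums(!is.finite(lg)) == 0
  if (!any(use)) stop("no region with all-positive counts for median-of-ratios")
  ref <- exp(rowMeans(lg[use, , drop = FALSE]))
  sf <- apply(counts[use, , drop = FALSE], 2, function(x) stats::median(x / ref))
  sf / mean(sf)
}

# Negative log-likelihood of an intercept NB model with exposure s.
nb_nll <- function(par, x, s) {
  mu <- exp(par[1]) * s
  alpha <- exp(par[2])
  -sum(stats::dnbinom(x, size = 1 / alpha, mu = mu, log = TRUE))
}

# ML fit of (log mu_base, log alpha) for one region via Nelder-Mead.
fit_nb_region <- function(x, s) {
  m <- sum(x) / sum(s)
  if (m <= 0) return(list(b0 = -Inf, alpha = NA_real_, converged = FALSE))
  v <- stats::var(x / s)
  a0 <- max((v - m) / m^2, 1e-3)
  fit <- stats::optim(c(log(m), log(a0)), nb_nll, x = x, s = s,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  alpha <- exp(fit$par[2])
  conv <- fit$convergence == 0 && alpha > 1e-8 && alpha < 1e4
  list(b0 = fit$par[1], alpha = alpha, converged = conv)
}

# ML intercept given a fixed alpha (1-d, used after regularization).
refit_b0 <- function(x, s, alpha) {
  m <- sum(x) / sum(s)
  if (m <= 0) return(-Inf)
  f <- function(b0) -sum(stats::dnbinom(x, size = 1 / alpha,
                                        mu = exp(b0) * s, log = TRUE))
  stats::optimize(f, interval = log(m) + c(-3, 3))$minimum
}

#' Fit the regularized negative-binomial model
#'
#' Each region gets an intercept-only NB model with the log size factors as
#' exposure, ln(mu) = b0 + ln(s), variance V(mu) = mu + alpha * mu^2,
#' fitted by maximum likelihood with a Nelder-Mead search. The
#' overdispersion is then regularized: up to `n_trend` regions (seeded
#' subsample) are binned into `nbins` groups by quantile of mean
#' expression, the modal per-bin alpha is located with a kernel density
#' estimate on log(alpha) (Silverman's bandwidth rule), and the trend is
#' linearly interpolated between bin centers (flat beyond the outer bins).
#' The trend alpha is re-assigned to every region and the intercept refitted
#' under it, so the final variance depends on the mean only.
#'
#' @param counts filtered regions x samples matrix.
#' @param s per-sample size factors.
#' @param nbins number of mean-quantile bins (default 20).
#' @param n_trend maximum number of regions used to fit the trend.
#' @param seed seed for the trend subsample.
#' @return an `nb_model` list: `mu_base` (= exp(b0), per region), `alpha`
#'   (regularized, per region), `alpha_raw` (per sampled region), `trend`
#'   (bin centers and values on log scales), `converged`, `s`.
#' @export
fit_regularized_nb <- function(counts, s, nbins = 20L, n_trend = 5000L,
                               seed = 1L) {
  stopifnot(ncol(counts) == length(s), all(s > 0))
  nr <- nrow(counts)
  ids <- rownames(counts)
  mean_expr <- as.numeric(counts %*% (1 / length(s) / s)) # mean of x/s
  mean_expr <- pmax(mean_expr, 1e-10)
  sub <- with_seed(stream_seed(seed, "nb_trend"), {
    if (nr > n_trend) sort(sample.int(nr, n_trend)) else seq_len(nr)
  })
  fits <- lapply(sub, function(i) fit_nb_region(counts[i, ], s))
  alpha_raw <- vapply(fits, `[[`, numeric(1), "alpha")
  converged <- vapply(fits, `[[`, logical(1), "converged")
  ok <- converged & is.finite(alpha_raw) & alpha_raw > 0
  if (sum(ok) < 2L) stop("too few converged NB fits to build a trend")
  lm_ok <- log(mean_expr[sub][ok])
  la_ok <- log(alpha_raw[ok])
  nb <- max(1L, min(nbins, floor(sum(ok) / 2)))
  qs <- stats::quantile(lm_ok, probs = seq(0, 1, length.out = nb + 1L))
  bin <- cut(lm_ok, unique(qs), include.lowest = TRUE)
  centers <- tapply(lm_ok, bin, mean)
  modes <- tapply(la_ok, bin, function(v) {
    if (length(v) < 2L) return(mean(v))
    de <- stats::density(v, bw = "nrd0")
    de$x[which.max(de$y)]
  })
  keep <- !is.na(centers) & !is.na(modes)
  centers <- centers[keep]; modes <- modes[keep]
  if (length(centers) == 1L) {
    alpha_hat <- rep(exp(modes), nr)
  } else {
    o <- order(centers)
    alpha_hat <- exp(stats::approx(centers[o], modes[o],
                                   xout = log(mean_expr), rule = 2)$y)
  }
  b0 <- vapply(seq_len(nr), function(i) refit_b0(counts[i, ], s, alpha_hat[i]),
               numeric(1))
  model <- list(
    mu_base = stats::setNames(exp(b0), ids),
    alpha = stats::setNames(alpha_hat, ids),
    alpha_raw = stats::setNames(alpha_raw, ids[sub]),
    converged = stats::setNames(converged, ids[sub]),
    trend = list(log_mean = as.numeric(centers), log_alpha = as.numeric(modes)),
    s = s
  )
  class(model) <- "nb_model"
  model
}

#' Evaluate the regularized overdispersion trend at given means
#' @param model an `nb_model`.
#' @param mu mean expression values.
#' @return alpha values from the trend (flat extrapolation).
#' @export
trend_alpha <- function(model, mu) {
  tr <- model$trend
  if (length(tr$log_mean) == 1L) return(rep(exp(tr$log_alpha), length(mu)))
  o <- order(tr$log_mean)
  exp(stats::approx(tr$log_mean[o], tr$log_alpha[o], xout = log(mu),
                    rule = 2)$y)
}

#' Clipped NB Pearson residuals
#'
#' r = (x - mu) / sqrt(mu + alpha mu^2) with mu = mu_base * s, clipped
#' symmetrically at c = sqrt(9 + n/4) where n is the number of samples --
#' wider than the sqrt(n/4)-style bound at small n without changing the
#' large-sample behavior.
#'
#' @param counts the count matrix used to fit `model`.
#' @param model an `nb_model` from [fit_regularized_nb()].
#' @param clip clip bound; default `sqrt(9 + ncol(counts)/4)`.
#' @return residual matrix with attribute `clip`.
#' @export
pearson_residuals <- function(counts, model, clip = NULL) {
  stopifnot(inherits(model, "nb_model"))
  n <- ncol(counts)
  if (is.null(clip)) clip <- sqrt(9 + n / 4)
  mu <- outer(model$mu_base[rownames(counts)], model$s)
  alpha <- model$alpha[rownames(counts)]
  r <- (counts - mu) / sqrt(mu + alpha * mu^2)
  r[!is.finite(r)] <- 0
  r <- pmin(pmax(r, -clip), clip)
  attr(r, "clip") <- clip
  r
}

#' Windowed, max-normalized read-profile matrix
#'
#' Per-sample coverage is depth-normalized (divided by the sample's total
#' reads), summed into a pooled meta-sample, aggregated in fixed windows,
#' and each region's row divided by its maximum window value, giving
#' profiles in \[0, 1\] with rowwise maximum 1. All-zero regions are
#' dropped with a message.
#'
#' @param coverage 3-d array `[region, sample, position]` as produced by
#'   [simulate_region_coverage()].
#' @param window window width in bp; must divide the region length.
#' @return list with `profiles` (regions x windows), `mean_profile`
#'   (column means) and `dropped` (ids of all-zero regions).
#' @export
profile_matrix <- function(coverage, window = 10L) {
  stopifnot(length(dim(coverage)) == 3L)
  len <- dim(coverage)[3]
  if (len %% window != 0L) stop("region length must be divisible by window")
  totals <- apply(coverage, 2, sum)
  totals[totals == 0] <- 1
  nwin <- len %/% window
  win_of <- rep(seq_len(nwin), each = window)
  nr <- dim(coverage)[1]
  pooled <- matrix(0, nr, nwin)
  for (s in seq_len(dim(coverage)[2])) {
    sl <- coverage[, s, , drop = FALSE]
    dim(sl) <- c(nr, len)
    pooled <- pooled + t(rowsum(t(sl), win_of)) / totals[s]
  }
  dimnames(pooled) <- NULL
  mx <- matrixStats::rowMaxs(pooled)
  zero <- mx == 0
  if (any(zero)) message(sum(zero), " all-zero region(s) dropped from profile")
  prof <- pooled[!zero, , drop = FALSE] / mx[!zero]
  list(profiles = prof, mean_profile = colMeans(prof),
       dropped = which(zero))
}
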