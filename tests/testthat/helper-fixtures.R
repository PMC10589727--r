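# Shared fixtures and small independent oracles used across test files.

# Adjusted Rand index between two labelings (closed-form contingency sum).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_ <- si * sj / n
  mx <- (si + sj) / 2
  if (mx == exp_) return(1)
  (sij - exp_) / (mx - exp_)
}

# Brute-force per-bp summit density: for each grid point, sum the
# truncated, renormalized Gaussian kernel over summits (O(G*n) scan).
brute_density <- function(summits, sigma) {
  halfw <- as.integer(ceiling(4 * sigma))
  offs <- -halfw:halfw
  w <- stats::dnorm(offs, 0, sigma)
  w <- w / sum(w)
  g0 <- min(summits) - halfw
  grid <- g0:(max(summits) + halfw)
  dens <- vapply(grid, function(g) {
    o <- g - summits
    keep <- abs(o) <= halfw
    sum(w[o[keep] + halfw + 1L])
  }, numeric(1))
  list(grid = grid, density = dens)
}

# Exhaustive strict-minima scan on a discrete series (plateau -> leftmost).
brute_minima <- function(d) {
  out <- integer(0)
  i <- 2L
  n <- length(d)
  while (i < n) {
    if (d[i] < d[i - 1L]) {
      j <- i
      while (j < n && d[j + 1L] == d[i]) j <- j + 1L
      if (j < n && d[j + 1L] > d[i]) out <- c(out, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# Brute-force consensus segmentation: explicit density, exhaustive minima,
# linear-search membership, then the same support/boundary/centroid rules.
brute_consensus <- function(peaks, sigma, min_datasets = 2L) {
  res <- list()
  for (ch in sort(unique(peaks$chrom))) {
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    bd <- brute_density(pk$summit, sigma)
    mins <- bd$grid[brute_minima(bd$density)]
    seg <- vapply(pk$summit, function(p) sum(mins < p), numeric(1))
    for (sg in sort(unique(seg))) {
      m <- pk[seg == sg, , drop = FALSE]
      if (length(unique(m$dataset_id)) < min_datasets) next
      res[[length(res) + 1L]] <- list(
        chrom = ch, start = min(m$start), end = max(m$end),
        centroid = as.integer(round(mean(m$summit))),
        members = sort(m$peak_id)
      )
    }
  }
  res
}

# Random peak instance on one or more chromosomes for oracle checks.
random_peak_instance <- function(n_summits, n_datasets, seed,
                                 span = 20000L, halfwidth = 100L) {
  set.seed(seed)
  n_chrom <- sample(1:2, 1)
  chrom <- sample(sprintf("chr%d", seq_len(n_chrom)), n_summits, replace = TRUE)
  summit <- as.integer(sample(500:span, n_summits, replace = TRUE))
  data.frame(
    chrom = chrom, start = summit - halfwidth, end = summit + halfwidth,
    summit = summit, qvalue = 10,
    dataset_id = sprintf("ds%02d", sample.int(n_datasets, n_summits,
                                              replace = TRUE)),
    peak_id = sprintf("pk%04d", seq_len(n_summits)),
    stringsAsFactors = FALSE
  )
}

# NB counts with a known overdispersion trend alpha(mu), for transform
# recovery tests.
nb_trend_counts <- function(n_regions, n_samples, seed,
                            mean_range = c(1, 100),
                            alpha_fun = function(mu) 0.1 + 2 / mu,
                            libsize_sd = 0.2) {
  set.seed(seed)
  base <- exp(runif(n_regions, log(mean_range[1]), log(mean_range[2])))
  s <- exp(rnorm(n_samples, 0, libsize_sd))
  s <- s / mean(s)
  mu <- outer(base, s)
  alpha <- alpha_fun(base)
  x <- matrix(rnbinom(n_regions * n_samples, size = rep(1 / alpha, n_samples),
                      mu = mu), nrow = n_regions)
  dimnames(x) <- list(sprintf("r%04d", seq_len(n_regions)),
                      sprintf("s%04d", seq_len(n_samples)))
  list(counts = x, s_true = s, base = base, alpha = alpha)
}
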