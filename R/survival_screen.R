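# Per-region Cox proportional-hazards screening and maximally selected
# log-rank cutpoints.

#' Per-region Cox proportional-hazards screen on Pearson residuals
#'
#' Fits a univariate Cox model per region (partial likelihood, Efron tie
#' handling) of survival on the region's Pearson residuals. A positive log
#' hazard ratio means overexpression is associated with worse survival.
#' Regions with a Benjamini-Hochberg q-value at or below `fdr` are flagged.
#'
#' @param residuals regions x samples Pearson residual matrix.
#' @param survival data.frame with `sample_id`, `time` (> 0), `event`
#'   (0/1), covering the residual columns.
#' @param fdr FDR threshold (default 0.05).
#' @return data.frame region_id, log_hr, se, p, q, flagged, skipped
#'   (constant covariate).
#' @export
cox_screen <- function(residuals, survival, fdr = 0.05) {
  stopifnot(all(c("sample_id", "time", "event") %in% names(survival)))
  stopifnot(all(survival$time > 0), !anyDuplicated(survival$sample_id))
  surv <- survival[match(colnames(residuals), survival$sample_id), ]
  if (any(is.na(surv$sample_id))) stop("survival table misses samples")
  if (sum(surv$event) < 2L) stop("need at least 2 observed events")
  y <- survival::Surv(surv$time, surv$event)
  ids <- rownames(residuals)
  res <- data.frame(region_id = ids, log_hr = NA_real_, se = NA_real_,
                    p = NA_real_, q = NA_real_, flagged = FALSE,
                    skipped = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(residuals))) {
    x <- residuals[i, ]
    if (stats::sd(x) == 0) {
      res$skipped[i] <- TRUE
      next
    }
    fit <- tryCatch(
      survival::coxph(y ~ x, ties = "efron"),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(survival::coxph(y ~ x, ties = "efron"))
      }
    )
    if (is.null(fit) || !is.finite(fit$coefficients[1])) {
      res$skipped[i] <- TRUE
      next
    }
    sm <- summary(fit)$coefficients
    res$log_hr[i] <- sm[1, "coef"]
    res$se[i] <- sm[1, "se(coef)"]
    res$p[i] <- sm[1, "Pr(>|z|)"]
  }
  tested <- !res$skipped & is.finite(res$p)
  res$q[tested] <- stats::p.adjust(res$p[tested], method = "BH")
  res$flagged <- !is.na(res$q) & res$q <= fdr
  res
}

# Standardized two-group log-rank statistics for many cutpoints at once.
# Returns a vector of |Z| per cutpoint (group = expression > cut).
logrank_z_all <- function(x, time, event, cuts) {
  dt <- sort(unique(time[event == 1]))
  A <- outer(dt, time, function(a, b) as.numeric(b >= a)) # at risk
  E <- outer(dt, time, "==") * rep(event, each = length(dt)) # died at t
  H <- outer(x, cuts, ">") * 1 # samples x cuts, high group
  Y <- rowSums(A)
  D <- rowSums(E)
  Y1 <- A %*% H
  D1 <- E %*% H
  U <- colSums(D1 - D * Y1 / Y)
  vterm <- D * (Y - D) / pmax(Y - 1, 1)
  V <- colSums(vterm * (Y1 / Y) * (1 - Y1 / Y))
  z <- abs(U) / sqrt(pmax(V, 1e-300))
  z[V <= 0] <- 0
  z
}

#' Maximally selected log-rank cutpoint
#'
#' Scans candidate expression cutpoints inside the inner quantile range,
#' computing the standardized two-group log-rank statistic for each split,
#' and reports the cutpoint maximizing |Z|. Because the maximum over many
#' correlated splits is not chi-square distributed, the p-value is
#' estimated by permuting the expression values across samples and
#' recomputing the maximal statistic (a Monte-Carlo approximation to the
#' conditional-Monte-Carlo approach of the maximally-selected-rank
#' literature).
#'
#' @param x per-sample expression (or residual) values.
#' @param survival data.frame with `time` and `event` aligned to `x`.
#' @param probs inner quantile range for candidate cutpoints.
#' @param n_perm number of permutations for the p-value (default 10000).
#' @param seed integer seed.
#' @return list with `cutpoint`, `statistic` (max |Z|), `p`, and
#'   `candidates` (cutpoint, z per candidate).
#' @export
maxstat_cutpoint <- function(x, survival, probs = c(0.1, 0.9),
                             n_perm = 10000L, seed = 1L) {
  stopifnot(length(x) == nrow(survival))
  if (length(x) < 10L) stop("need at least 10 samples")
  qs <- stats::quantile(x, probs)
  cuts <- sort(unique(x[x >= qs[1] & x <= qs[2]]))
  cuts <- cuts[cuts < max(x)] # a split must leave both groups non-empty
  if (!length(cuts)) stop("no usable cutpoint (values all tied?)")
  z <- logrank_z_all(x, survival$time, survival$event, cuts)
  best <- which.max(z)
  obs <- z[best]
  perm_max <- with_seed(stream_seed(seed, "maxstat"), {
    vapply(seq_len(n_perm), function(b) {
      xp <- sample(x)
      max(logrank_z_all(xp, survival$time, survival$event, cuts))
    }, numeric(1))
  })
  p <- (1 + sum(perm_max >= obs)) / (n_perm + 1)
  list(cutpoint = cuts[best], statistic = obs, p = p,
       candidates = data.frame(cutpoint = cuts, z = z))
}

#' Kaplan-Meier table for grouped samples
#'
#' @param survival data.frame with `time` and `event`.
#' @param group group labels per sample.
#' @return data.frame time, n_risk, n_event, survival, group.
#' @export
km_table <- function(survival, group) {
  fit <- survival::survfit(
    survival::Surv(survival$time, survival$event) ~ group
  )
  sm <- summary(fit)
  strata <- if (is.null(sm$strata)) rep("all", length(sm$time)) else
    as.character(sm$strata)
  data.frame(time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
             survival = sm$surv, group = strata, stringsAsFactors = FALSE)
}
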