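# First-order feature families: intensity statistics, intensity histogram,
# intensity-volume histogram. All moments use population (n) denominators per
# the IBSI reference; degenerate inputs (zero variance, zero denominators)
# yield 0 rather than NA, a documented convention.

pop_moments <- function(x) {
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  list(mu = mu, m2 = m2, m3 = mean(d^3), m4 = mean(d^4))
}

safe_div <- function(num, den) if (isTRUE(den == 0) || !is.finite(den)) 0 else num / den

#' Intensity statistical features
#'
#' The 18 `stat.*` features computed on raw (undiscretized) ROI intensities:
#' moments with population denominators, order statistics, and dispersion
#' measures. `stat.skew` is `m3 / m2^(3/2)` and `stat.kurt` is excess
#' kurtosis `m4 / m2^2 - 3`; both are defined as 0 for zero-variance input.
#' `stat.cov` is the coefficient of variation sigma/mu (0 when mu = 0) and
#' `stat.qcod` the quartile coefficient of dispersion.
#'
#' @param values Numeric vector of ROI intensities (non-empty).
#' @return Named numeric vector of length 18.
#' @export
#' @examples
#' statistical_features(c(1, 1, 4))[["stat.skew"]]  # 1/sqrt(2)
statistical_features <- function(values) {
  if (length(values) == 0) stopf("`values` must be non-empty")
  m <- pop_moments(values)
  q <- unname(quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7))
  p10 <- q[1]; p25 <- q[2]; med <- q[3]; p75 <- q[4]; p90 <- q[5]
  inner <- values[values >= p10 & values <= p90]
  rmad <- if (length(inner)) mean(abs(inner - mean(inner))) else 0
  sigma <- sqrt(m$m2)
  c(
    stat.mean   = m$mu,
    stat.var    = m$m2,
    stat.skew   = if (m$m2 > 0) m$m3 / m$m2^1.5 else 0,
    stat.kurt   = if (m$m2 > 0) m$m4 / m$m2^2 - 3 else 0,
    stat.median = med,
    stat.min    = min(values),
    stat.p10    = p10,
    stat.p90    = p90,
    stat.max    = max(values),
    stat.iqr    = p75 - p25,
    stat.range  = max(values) - min(values),
    stat.mad    = mean(abs(values - m$mu)),
    stat.rmad   = rmad,
    stat.medad  = mean(abs(values - med)),
    stat.cov    = safe_div(sigma, m$mu),
    stat.qcod   = safe_div(p75 - p25, p75 + p25),
    stat.energy = sum(values^2),
    stat.rms    = sqrt(mean(values^2))
  )
}

#' Intensity histogram features
#'
#' The 23 `ih.*` features computed on discretized grey levels `1..Ng`.
#' Moment-type features reuse the intensity-statistics definitions on the
#' level values; in addition the histogram mode, Shannon entropy (log2),
#' uniformity, and histogram-gradient features are computed. The gradient of
#' the level-count histogram `n_1..n_Ng` is `grad_1 = n_2 - n_1`,
#' `grad_i = (n_(i+1) - n_(i-1)) / 2`, `grad_Ng = n_Ng - n_(Ng-1)`;
#' `ih.max.grad`/`ih.min.grad` are its extrema and `ih.max.grad.g`/
#' `ih.min.grad.g` the (first) levels attaining them. A single-level
#' histogram has zero gradients by convention.
#'
#' @param levels Integer grey levels from [discretize()].
#' @param Ng Number of grey levels; defaults to the `Ng` attribute of
#'   `levels`.
#' @return Named numeric vector of length 23.
#' @export
intensity_histogram_features <- function(levels, Ng = attr(levels, "Ng")) {
  if (length(levels) == 0) stopf("`levels` must be non-empty")
  Ng <- as.integer(Ng %||% max(levels))
  x <- as.numeric(levels)
  st <- statistical_features(x)
  counts <- tabulate(levels, nbins = Ng)
  p <- counts / sum(counts)
  pp <- p[p > 0]
  if (Ng >= 2) {
    grad <- c(counts[2] - counts[1],
              if (Ng > 2) (counts[3:Ng] - counts[1:(Ng - 2)]) / 2,
              counts[Ng] - counts[Ng - 1])
  } else {
    grad <- 0
  }
  c(
    ih.mean   = unname(st["stat.mean"]),
    ih.var    = unname(st["stat.var"]),
    ih.skew   = unname(st["stat.skew"]),
    ih.kurt   = unname(st["stat.kurt"]),
    ih.median = unname(st["stat.median"]),
    ih.min    = min(x),
    ih.p10    = unname(st["stat.p10"]),
    ih.p90    = unname(st["stat.p90"]),
    ih.max    = max(x),
    ih.mode   = which.max(counts),
    ih.iqr    = unname(st["stat.iqr"]),
    ih.range  = unname(st["stat.range"]),
    ih.mad    = unname(st["stat.mad"]),
    ih.rmad   = unname(st["stat.rmad"]),
    ih.medad  = unname(st["stat.medad"]),
    ih.cov    = unname(st["stat.cov"]),
    ih.qcod   = unname(st["stat.qcod"]),
    ih.entropy    = -sum(pp * log2(pp)),
    ih.uniformity = sum(pp^2),
    ih.max.grad   = max(grad),
    ih.max.grad.g = which.max(grad),
    ih.min.grad   = min(grad),
    ih.min.grad.g = which.min(grad)
  )
}

#' Intensity-volume histogram features
#'
#' Fractional-volume/intensity summaries over the ROI. For intensity
#' fraction `f`, `V(f)` is the fraction of ROI voxels with intensity at or
#' above `min + f * range`. `ivh.v10`/`ivh.v90` are `V(0.10)`/`V(0.90)`;
#' `ivh.i10`/`ivh.i90` are the intensities above which 10% resp. 90% of the
#' volume lies (the 90th and 10th intensity percentiles); the two `diff`
#' features are their differences, and `ivh.auc` is the area under `V(f)`
#' over `f` in \[0, 1\]. A constant ROI has `V(f) = 1` everywhere.
#'
#' @param values Numeric ROI intensities (non-empty).
#' @return Named numeric vector of length 7.
#' @export
ivh_features <- function(values) {
  if (length(values) == 0) stopf("`values` must be non-empty")
  lo <- min(values); rng <- max(values) - lo
  vol_at <- function(f) mean(values >= lo + f * rng)
  v10 <- vol_at(0.10); v90 <- vol_at(0.90)
  i10 <- unname(quantile(values, 0.90, type = 7))
  i90 <- unname(quantile(values, 0.10, type = 7))
  fs <- seq(0, 1, by = 0.01)
  auc <- mean(vapply(fs, vol_at, numeric(1)))
  c(ivh.v10 = v10, ivh.v90 = v90, ivh.i10 = i10, ivh.i90 = i90,
    ivh.diff.v10.v90 = v10 - v90, ivh.diff.i10.i90 = i10 - i90,
    ivh.auc = auc)
}
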