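#' Grey-level discretization configuration
#'
#' Settings controlling how continuous SUV (or TBR) values are binned into
#' integer grey levels before histogram and texture feature computation.
#'
#' With `method = "fixed_bin_size"` a voxel with value `x` gets level
#' `floor((x - xmin) / bin_width) + 1`, where `xmin` is the ROI minimum
#' (`min_policy = "roi_min"`) or `fixed_min`. With
#' `method = "fixed_bin_number"` levels are
#' `min(floor(n_bins * (x - min) / (max - min)) + 1, n_bins)`; a constant
#' input maps entirely to level 1.
#'
#' The default (fixed bin size, width 0.1 SUV, ROI-minimum anchoring) makes
#' histogram and texture features sensitive to the intensity scale, so SUV
#' and TBR runs of the same lesion may differ slightly — the behaviour seen
#' in clinical SUV/TBR feature tables — whereas fixed-bin-number
#' discretization is invariant under positive rescaling.
#'
#' @param method `"fixed_bin_size"` or `"fixed_bin_number"`.
#' @param bin_width Bin width in intensity units (fixed bin size only).
#' @param n_bins Number of bins (fixed bin number only), at least 2.
#' @param min_policy `"roi_min"` or `"fixed_value"` anchoring for fixed bin
#'   size.
#' @param fixed_min Lower edge used when `min_policy = "fixed_value"`.
#' @return A `discretization_config` list.
#' @export
discretization_config <- function(method = c("fixed_bin_size", "fixed_bin_number"),
                                  bin_width = 0.1,
                                  n_bins = 32L,
                                  min_policy = c("roi_min", "fixed_value"),
                                  fixed_min = 0) {
  method <- match.arg(method)
  min_policy <- match.arg(min_policy)
  if (method == "fixed_bin_size" && (!is.numeric(bin_width) || bin_width <= 0))
    stopf("`bin_width` must be a positive number, got %s", format(bin_width))
  if (method == "fixed_bin_number" && (!is.numeric(n_bins) || n_bins < 2))
    stopf("`n_bins` must be >= 2, got %s", format(n_bins))
  structure(
    list(method = method, bin_width = bin_width, n_bins = as.integer(n_bins),
         min_policy = min_policy, fixed_min = fixed_min),
    class = "discretization_config"
  )
}

#' Discretize intensities into grey levels
#'
#' @param values Numeric vector of voxel intensities (non-empty).
#' @param config A [discretization_config()].
#' @return Integer vector of grey levels in `1..Ng`, with attribute `Ng`
#'   (the number of levels spanned: the maximum occupied level for fixed bin
#'   size, `n_bins` for fixed bin number).
#' @export
#' @examples
#' discretize(c(1.00, 1.05, 1.23), discretization_config(bin_width = 0.1))
discretize <- function(values, config = discretization_config()) {
  if (length(values) == 0) stopf("`values` must be non-empty")
  if (!inherits(config, "discretization_config"))
    stopf("`config` must be a discretization_config")
  if (config$method == "fixed_bin_size") {
    xmin <- if (config$min_policy == "roi_min") min(values) else config$fixed_min
    lev <- as.integer(floor((values - xmin) / config$bin_width)) + 1L
    ng <- max(lev)
  } else {
    rng <- max(values) - min(values)
    ng <- config$n_bins
    if (rng == 0) {
      lev <- rep(1L, length(values))
    } else {
      lev <- pmin(as.integer(floor(ng * (values - min(values)) / rng)) + 1L, ng)
    }
  }
  attr(lev, "Ng") <- as.integer(ng)
  lev
}
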