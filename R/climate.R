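#' Bin a time series into fixed-width age intervals
#'
#' Half-open bins `[k w, (k+1) w)` from age 0 (the first bin is 0-`w` Ma),
#' each summarised by its sample mean, sample (n-1) standard deviation and
#' point count. The sd is `NA` (flagged) for bins with fewer than 2 points;
#' empty bins are kept with `n = 0` so the binned axis is contiguous.
#'
#' @param series a `"sealevel_series"` (or data.frame with `age_ma`,
#'   `value`).
#' @param width bin width in Myr (default 1).
#' @return a `data.frame` of class `"binned_series"` with columns
#'   `bin_start`, `bin_end`, `mid`, `mean`, `sd`, `n`.
#' @export
bin_time_series <- function(series, width = 1) {
  stopifnot(width > 0)
  if (nrow(series) == 0L) stop("empty series")
  k <- floor(series$age_ma / width)
  nbin <- max(k) + 1L
  idx <- factor(k, levels = 0:(nbin - 1L))
  n <- as.integer(table(idx))
  mean_ <- tapply(series$value, idx, mean)
  sd_ <- tapply(series$value, idx, function(v) if (length(v) >= 2L) stats::sd(v) else NA_real_)
  out <- data.frame(bin_start = (0:(nbin - 1L)) * width,
                    bin_end = (1:nbin) * width,
                    mid = ((0:(nbin - 1L)) + 0.5) * width,
                    mean = as.numeric(mean_), sd = as.numeric(sd_), n = n)
  structure(out, class = c("binned_series", "data.frame"), width = width)
}

#' Joint lineage-accumulation / climate report
#'
#' Merges an LTT curve with a binned climate series on the bin midpoints:
#' for every bin the lineage count is the step-function value of the LTT
#' curve at the bin midpoint (NA outside the tree's age span), next to the
#' bin's climate mean and sd. Disjoint age ranges produce an empty table
#' with a warning.
#'
#' @param ltt_curve an [ltt()] curve.
#' @param binned a [bin_time_series()] result.
#' @return `data.frame` with columns `age`, `lineages`, `climate_mean`,
#'   `climate_sd`.
#' @export
overlay_report <- function(ltt_curve, binned) {
  stopifnot(inherits(ltt_curve, "ltt_curve"), inherits(binned, "binned_series"))
  lin <- ltt_at(ltt_curve, binned$mid)
  out <- data.frame(age = binned$mid, lineages = lin,
                    climate_mean = binned$mean, climate_sd = binned$sd)
  if (all(is.na(out$lineages))) {
    warning("LTT curve and climate series have disjoint age ranges")
    return(out[0, ])
  }
  out
}
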