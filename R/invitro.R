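# In vitro dilution-series analysis: maximum-intensity projections,
# 2-D condensate detection, saturation-concentration bracketing, and
# turbidity (A340) summaries.

#' Maximum-intensity projection of a stack over z
#'
#' @param stack an [image_stack] (or a bare 3-D array).
#' @param channel channel selector (default first channel).
#' @return 2-D matrix with attribute `pixel_size` (um, `(y, x)`).
#'   Projecting a projection (a single-plane stack) returns it unchanged.
#' @export
max_projection <- function(stack, channel = 1L) {
  if (inherits(stack, "image_stack")) {
    vol <- stack_channel(stack, channel)
    px <- stack$voxel_size[2:3]
  } else {
    stopifnot(length(dim(stack)) == 3L)
    vol <- stack
    px <- attr(stack, "pixel_size")
  }
  d <- dim(vol)
  proj <- vol[1, , ]
  if (d[1] > 1) for (z in 2:d[1]) proj <- pmax(proj, vol[z, , ])
  proj <- matrix(proj, d[2], d[3])
  attr(proj, "pixel_size") <- px
  proj
}

#' Count condensates in a 2-D field
#'
#' Thresholds the image and counts connected bright components with area
#' at least `min_area`. The default `"robust"` policy thresholds at
#' median + 6 MAD of the field, which stays quiet on condensate-free
#' fields where a bimodal split would hallucinate foreground; `"otsu"`,
#' `"quantile"` and `"absolute"` policies are available as in
#' [detect_puncta()].
#'
#' @param projection 2-D matrix (e.g. from [max_projection()]) with a
#'   `pixel_size` attribute, or supply `pixel_size`.
#' @param threshold_policy list with `$method`; for `"robust"` optionally
#'   `$k` (MAD multiplier, default 6).
#' @param min_area minimum condensate area, um^2 (default 0.05:
#'   submicron-size objects).
#' @param pixel_size `(y, x)` pixel size in um if the attribute is
#'   absent.
#' @return integer condensate count; attribute `"threshold"` records the
#'   intensity cut used.
#' @export
detect_condensates_2d <- function(projection,
                                  threshold_policy = list(method = "robust"),
                                  min_area = 0.05, pixel_size = NULL) {
  px <- attr(projection, "pixel_size")
  if (is.null(px)) px <- pixel_size
  if (is.null(px)) stop("pixel size unknown: supply pixel_size")
  if (length(px) == 1) px <- c(px, px)
  v <- as.vector(projection)
  method <- if (is.list(threshold_policy)) threshold_policy$method else threshold_policy
  thr <- if (identical(method, "robust")) {
    k <- if (is.list(threshold_policy) && !is.null(threshold_policy$k)) threshold_policy$k else 6
    stats::median(v) + k * max(stats::mad(v), 1e-9)
  } else {
    resolve_threshold(v, threshold_policy)
  }
  m <- projection > thr
  cnt <- 0L
  if (any(m)) {
    lab <- EBImage::bwlabel(m * 1)
    sizes <- tabulate(lab[lab > 0])
    min_px <- max(1L, round(min_area / prod(px)))
    cnt <- sum(sizes >= min_px)
  }
  structure(as.integer(cnt), threshold = thr)
}

#' Bracket the saturation concentration from a dilution series
#'
#' Runs condensate detection on the maximum-intensity projection of each
#' concentration's stack; a sample is phase-separated when its condensate
#' count reaches `min_count` (default 3, resisting single-speck false
#' positives). The bracket is `(lower, upper)` where `lower` is the
#' highest condensate-free concentration (0 when condensates appear at
#' every concentration, read "C_sat < upper") and `upper` the lowest
#' condensate-positive one (`Inf` when none is positive). A non-monotone
#' detection pattern is flagged and the bracket is taken from the first
#' positive with a warning.
#'
#' @param series a `dilution_series` (see [generate_dilution_series()])
#'   or a list with `concentrations` and `stacks`.
#' @param threshold_policy,min_area passed to [detect_condensates_2d()].
#' @param min_count minimum objects per field for a positive call.
#' @return object of class `csat_bracket`: list with `lower`, `upper`,
#'   `counts`, `positive`, `flagged`.
#' @export
csat_bracket <- function(series, threshold_policy = list(method = "robust"),
                         min_area = 0.05, min_count = 3L) {
  conc <- series$concentrations
  if (length(conc) == 0) stop("empty dilution series")
  counts <- vapply(series$stacks, function(s) {
    as.integer(detect_condensates_2d(max_projection(s),
                                     threshold_policy = threshold_policy,
                                     min_area = min_area))
  }, integer(1))
  positive <- counts >= min_count
  flagged <- FALSE
  if (any(positive)) {
    first_pos <- which(positive)[1]
    if (any(!positive[seq_along(positive) > first_pos])) {
      warning("non-monotone detection pattern; bracketing from first positive")
      flagged <- TRUE
    }
    upper <- conc[first_pos]
    below <- conc[!positive & conc < upper]
    lower <- if (length(below)) max(below) else 0
  } else {
    upper <- Inf
    lower <- max(conc)
  }
  structure(list(lower = lower, upper = upper, counts = counts,
                 positive = positive, flagged = flagged),
            class = "csat_bracket")
}

#' @export
print.csat_bracket <- function(x, ...) {
  if (is.infinite(x$upper)) {
    cat(sprintf("<csat_bracket> no condensates up to %g (C_sat > %g)\n",
                x$lower, x$lower))
  } else if (x$lower == 0) {
    cat(sprintf("<csat_bracket> C_sat < %g\n", x$upper))
  } else {
    cat(sprintf("<csat_bracket> C_sat between %g and %g\n", x$lower, x$upper))
  }
  invisible(x)
}

#' Summarize a turbidity (A340) series
#'
#' Buffer-only absorbance is subtracted from every protein reading; the
#' per-concentration mean and SD over replicates are reported. Fewer than
#' 2 replicates leaves the SD undefined and flags the row.
#'
#' @param series data.frame with columns `concentration`, `a340`,
#'   `buffer_a340` (constant per series or per row).
#' @return data.frame with `concentration`, `mean_a340` (background
#'   subtracted), `sd_a340`, `n`, `flagged`.
#' @export
turbidity_summary <- function(series) {
  stopifnot(all(c("concentration", "a340", "buffer_a340") %in% names(series)))
  corrected <- series$a340 - series$buffer_a340
  out <- do.call(rbind, lapply(split(seq_len(nrow(series)), series$concentration),
    function(ix) {
      v <- corrected[ix]
      data.frame(concentration = series$concentration[ix[1]],
                 mean_a340 = mean(v),
                 sd_a340 = if (length(v) >= 2) sd(v) else NA_real_,
                 n = length(v),
                 flagged = length(v) < 2)
    }))
  out <- out[order(out$concentration), , drop = FALSE]
  rownames(out) <- NULL
  out
}
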