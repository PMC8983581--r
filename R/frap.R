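# FRAP normalization and single-exponential recovery fitting.
#
# Model: I(t) = I0 + M_f (1 - I0) (1 - 2^(-t / T_half)), on the doubly
# normalized scale where the prebleach intensity is 1 and I0 is the
# post-bleach floor. T_half is the recovery half-time (the fitted curve
# reaches half of its plateau rise at t = T_half) and M_f the mobile
# fraction: the recovered share of the bleached fluorescence.

#' FRAP time series container
#'
#' @param time sampling times in seconds, strictly increasing, bleach at
#'   t = 0.
#' @param roi bleached-ROI intensity, a.u.
#' @param background background intensity, a.u.
#' @param reference unbleached reference (punctum/condensate) intensity,
#'   a.u.; carries acquisition photobleaching.
#' @param prebleach scalar prebleach ROI intensity, a.u.
#' @return object of class `frap_trace`.
#' @export
frap_trace <- function(time, roi, background, reference, prebleach) {
  n <- length(time)
  stopifnot(length(roi) == n, length(background) == n, length(reference) == n,
            length(prebleach) == 1)
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing")
  structure(list(time = as.numeric(time), roi = as.numeric(roi),
                 background = as.numeric(background),
                 reference = as.numeric(reference),
                 prebleach = as.numeric(prebleach)),
            class = "frap_trace")
}

#' Normalize a FRAP trace against background and an unbleached reference
#'
#' Double normalization: background-subtracted ROI divided by the
#' background-subtracted reference (cancelling acquisition
#' photobleaching), rescaled so that the prebleach level maps to 1; the
#' first post-bleach point then sits at its bleached fraction.
#'
#' @param trace a [frap_trace].
#' @return data.frame (class `frap_norm`) with columns `time`, `value`.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  denom <- trace$reference - trace$background
  if (any(denom <= 0)) stop("reference must exceed background at all points")
  v <- (trace$roi - trace$background) / denom
  pre <- (trace$prebleach - trace$background[1]) / denom[1]
  if (pre <= 0) stop("prebleach must exceed background")
  out <- data.frame(time = trace$time, value = v / pre)
  class(out) <- c("frap_norm", "data.frame")
  out
}

#' Fit single-exponential FRAP recovery
#'
#' Bounded Levenberg-Marquardt least squares of
#' `I(t) = I0 + M_f (1 - I0) (1 - 2^(-t/T_half))` on a normalized trace.
#' The rate is initialized from a log-linear fit of the plateau gap;
#' bounds are `M_f` in (0, 1.05] (soft cap above 1 for noise) and
#' `T_half` in (0, 10 t_max]. A fit whose mobile fraction collapses onto
#' the lower boundary (flat trace) or that fails to converge is flagged
#' `converged = FALSE` — no silent fallback.
#'
#' @param norm normalized trace from [normalize_trace()], or any
#'   data.frame with `time` (s) and `value` columns; at least 8
#'   post-bleach points.
#' @return object of class `frap_fit`: list with `t_half` (s), `m_f`,
#'   `i0`, `rss`, `converged`, `diagnostics`, and the fitted curve
#'   accessor via `predict`.
#' @export
fit_recovery <- function(norm) {
  stopifnot(is.data.frame(norm), all(c("time", "value") %in% names(norm)))
  post <- norm[norm$time >= 0, , drop = FALSE]
  if (nrow(post) < 8) stop("need at least 8 post-bleach points")
  t <- post$time
  y <- post$value
  t_max <- max(t)

  # initialization by exact profiling: for fixed T_half the model is
  # linear in (i0, amplitude), so a coarse log-spaced T_half grid with
  # closed-form linear fits locates the global least-squares basin
  # (a log-linear rate guess alone often strands the optimizer in a
  # local optimum on noisy traces)
  ths <- exp(seq(log(t_max / 200), log(2 * t_max), length.out = 60))
  prof_rss <- vapply(ths, function(th) {
    X <- cbind(1, 1 - 2^(-t / th))
    sum(lm.fit(X, y)$residuals^2)
  }, numeric(1))
  th_init <- ths[which.min(prof_rss)]
  Xb <- cbind(1, 1 - 2^(-t / th_init))
  cf0 <- lm.fit(Xb, y)$coefficients
  i0_init <- min(max(cf0[1], 0), 0.99)
  mf_init <- min(max(cf0[2] / max(1 - i0_init, 1e-6), 1e-3), 1.05)

  model <- function(par) par[1] + par[2] * (1 - par[1]) * (1 - 2^(-t / par[3]))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(i0 = i0_init, m_f = mf_init, t_half = th_init),
      fn = function(par) y - model(par),
      lower = c(0, 1e-4, 1e-9),
      upper = c(1, 1.05, 10 * t_max),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )

  if (inherits(fit, "error")) {
    return(structure(list(t_half = NA_real_, m_f = NA_real_, i0 = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          diagnostics = conditionMessage(fit)),
                     class = "frap_fit"))
  }
  cf <- coef(fit)
  rss <- fit$deviance
  # honest convergence: optimizer converged AND the recovery is actually
  # identified (mobile fraction not collapsed to the boundary, finite rise)
  ok <- fit$info %in% 1:3
  amp <- cf[["m_f"]] * (1 - cf[["i0"]])
  resid_sd <- sd(y)
  identified <- amp > max(2e-3, 0.05 * resid_sd) && cf[["m_f"]] > 2e-3
  diag <- if (!identified) "flat or unidentified recovery (m_f at boundary)" else ""
  structure(list(t_half = unname(cf[["t_half"]]), m_f = unname(cf[["m_f"]]),
                 i0 = unname(cf[["i0"]]), rss = rss,
                 converged = ok && identified, diagnostics = diag),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> T_1/2 = %.4g s, M_f = %.4g, rss = %.3g, converged = %s\n",
              x$t_half, x$m_f, x$rss, x$converged))
  invisible(x)
}

#' Group mean and SD recovery curve over multiple normalized traces
#'
#' Mirrors the standard presentation of FRAP data as mean +/- SD over n
#' traces sampled on a common time base.
#'
#' @param norms list of normalized traces (equal time grids).
#' @return data.frame with `time`, `mean`, `sd`, `n`.
#' @export
frap_group_curve <- function(norms) {
  stopifnot(length(norms) >= 1)
  tm <- norms[[1]]$time
  for (nm in norms) stopifnot(isTRUE(all.equal(nm$time, tm)))
  vals <- sapply(norms, function(nm) nm$value)
  data.frame(time = tm,
             mean = rowMeans(vals),
             sd = apply(vals, 1, sd),
             n = length(norms))
}
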