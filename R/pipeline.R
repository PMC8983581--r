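# End-to-end orchestration: stacks -> per-punctum and per-cell tables ->
# per-construct summaries and group statistics, with deterministic
# outputs and a provenance record.

#' Quantify one stack end to end
#'
#' Segments nuclei, computes the LoG response, detects and measures
#' puncta, and derives per-cell metrics for every nucleus.
#'
#' @param stack a two-channel [image_stack].
#' @param nuclei_args,puncta_args,log_args named lists of overrides for
#'   [segment_nuclei()], [detect_puncta()] and [log_response()].
#' @param calib,thermo calibration and thermodynamic parameters.
#' @param periphery_cutoff um.
#' @param nuclear_only restrict puncta to nuclei (default TRUE).
#' @return list with `nuclei`, `puncta`, `cells` data.frames and the two
#'   label volumes.
#' @export
quantify_stack <- function(stack, nuclei_args = list(), puncta_args = list(),
                           log_args = list(), calib = calibration_model(),
                           thermo = thermo_params(), periphery_cutoff = 0.5,
                           nuclear_only = TRUE) {
  nuc_lab <- do.call(segment_nuclei, c(list(stack = stack), nuclei_args))
  resp <- do.call(log_response, c(list(stack = stack), log_args))
  pun_lab <- do.call(detect_puncta,
                     c(list(response = resp, stack = stack,
                            nuclei_labels = nuc_lab,
                            nuclear_only = nuclear_only), puncta_args))
  nuclei <- measure_nuclei(nuc_lab, stack)
  puncta <- measure_puncta(pun_lab, stack, nuc_lab, nuclear_only = nuclear_only)
  cells <- do.call(rbind, lapply(seq_len(nrow(nuclei)), function(i) {
    cell_metrics(nuclei[i, , drop = FALSE], puncta, nuc_lab, pun_lab, stack,
                 calib = calib, thermo = thermo,
                 periphery_cutoff = periphery_cutoff)
  }))
  if (is.null(cells)) cells <- data.frame()
  list(nuclei = nuclei, puncta = puncta, cells = cells,
       nuclei_labels = nuc_lab, puncta_labels = pun_lab)
}

# metrics defined for every cell (zero-punctum cells included) vs. only
# for cells with puncta (zero-punctum cells excluded)
.metrics_all_cells <- c("puncta_density", "lp", "total_concentration", "pcc")
.metrics_puncta_cells <- c("v_p", "dp", "k_p", "delta_g_tr")

#' Summarize per-cell metrics by construct
#'
#' Applies the zero-punctum conventions: density-style metrics (puncta
#' density, [LP], total concentration, PCC) are summarized over all
#' cells; distribution metrics (V_p, [DP], K_p, free energy of transfer)
#' only over cells with at least one punctum.
#'
#' @param cells per-cell table with a `construct` column.
#' @return data.frame with `construct`, `metric`, `n`, `mean`, `se`,
#'   `zero_punctum_cells` (`"included"`/`"excluded"`).
#' @export
summarize_cells <- function(cells) {
  stopifnot("construct" %in% names(cells))
  rows <- list()
  for (grp in split(cells, cells$construct)) {
    cons <- grp$construct[1]
    for (m in .metrics_all_cells) {
      v <- grp[[m]]
      v <- v[!is.na(v)]
      rows[[length(rows) + 1]] <- data.frame(
        construct = cons, metric = m, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        se = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
        zero_punctum_cells = "included")
    }
    withp <- grp[grp$n_puncta > 0, , drop = FALSE]
    for (m in .metrics_puncta_cells) {
      v <- withp[[m]]
      v <- v[!is.na(v)]
      rows[[length(rows) + 1]] <- data.frame(
        construct = cons, metric = m, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        se = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
        zero_punctum_cells = "excluded")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full imaging pipeline over a manifest of stacks
#'
#' Input stacks come either from `config$stacks` (a list of entries with
#' `stack` = [image_stack] and `construct` label) or from
#' `config$manifest` (data.frame with `path` and `construct`; stacks are
#' read with [read_stack()]). Every stack is quantified with
#' [quantify_stack()]; per-punctum, per-cell and per-construct tables are
#' returned and, when `config$output_dir` is set, written as CSV together
#' with a provenance YAML (config hash, package version, seed). Outputs
#' are deterministic: rerunning the same config yields byte-identical
#' tables.
#'
#' @param config list: `stacks` or `manifest`, optional `params` (named
#'   lists `nuclei`, `puncta`, `log`, `calibration`, `thermo`,
#'   `periphery_cutoff`, `nuclear_only`), optional `seed` (recorded),
#'   optional `output_dir`.
#' @return list with `puncta`, `cells`, `summary` data.frames and
#'   `provenance`.
#' @export
run_pipeline <- function(config) {
  entries <- if (!is.null(config$stacks)) {
    config$stacks
  } else if (!is.null(config$manifest)) {
    mf <- config$manifest
    missing <- !file.exists(mf$path)
    if (any(missing)) stop("manifest paths not found: ",
                           paste(mf$path[missing], collapse = ", "))
    lapply(seq_len(nrow(mf)), function(i) {
      list(stack = read_stack(mf$path[i]), construct = mf$construct[i],
           id = basename(mf$path[i]))
    })
  } else {
    stop("config must provide $stacks or $manifest")
  }

  prm <- config$params
  calib <- if (!is.null(prm$calibration)) prm$calibration else calibration_model()
  thermo <- if (!is.null(prm$thermo)) prm$thermo else thermo_params()
  cutoff <- if (!is.null(prm$periphery_cutoff)) prm$periphery_cutoff else 0.5
  nuc_only <- if (!is.null(prm$nuclear_only)) prm$nuclear_only else TRUE

  all_cells <- list()
  all_puncta <- list()
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    sid <- if (!is.null(e$id)) e$id else paste0("stack", i)
    res <- tryCatch(
      quantify_stack(e$stack,
                     nuclei_args = if (is.null(prm$nuclei)) list() else prm$nuclei,
                     puncta_args = if (is.null(prm$puncta)) list() else prm$puncta,
                     log_args = if (is.null(prm$log)) list() else prm$log,
                     calib = calib, thermo = thermo,
                     periphery_cutoff = cutoff, nuclear_only = nuc_only),
      error = function(err) {
        stop(sprintf("stage 'quantify' failed for input '%s': %s",
                     sid, conditionMessage(err)), call. = FALSE)
      })
    if (nrow(res$cells)) {
      res$cells$stack_id <- sid
      res$cells$construct <- e$construct
      all_cells[[length(all_cells) + 1]] <- res$cells
    }
    if (nrow(res$puncta)) {
      res$puncta$stack_id <- sid
      res$puncta$construct <- e$construct
      all_puncta[[length(all_puncta) + 1]] <- res$puncta
    }
  }
  cells <- if (length(all_cells)) do.call(rbind, all_cells) else data.frame()
  puncta <- if (length(all_puncta)) do.call(rbind, all_puncta) else data.frame()
  summary <- if (nrow(cells)) summarize_cells(cells) else data.frame()

  cfg_for_hash <- config[setdiff(names(config), "stacks")]
  provenance <- list(
    package = "punctakit",
    version = as.character(utils::packageVersion("punctakit")),
    seed = if (is.null(config$seed)) NA else config$seed,
    n_inputs = length(entries),
    config_hash = rlang::hash(cfg_for_hash)
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_tables(cells, file.path(config$output_dir, "cells.csv"), empty_ok = TRUE)
    write_tables(puncta, file.path(config$output_dir, "puncta.csv"), empty_ok = TRUE)
    write_tables(summary, file.path(config$output_dir, "summary.csv"), empty_ok = TRUE)
    yaml::write_yaml(provenance, file.path(config$output_dir, "provenance.yaml"))
  }
  list(puncta = puncta, cells = cells, summary = summary,
       provenance = provenance)
}

#' Two-group comparison of a per-cell metric
#'
#' Default test is the two-sided Mann-Whitney U (per-cell condensate
#' metrics are typically right-skewed); Welch's t test is available.
#'
#' @param a,b numeric metric values for the two groups (each >= 3
#'   values).
#' @param test `"wilcox"` (default) or `"t"`.
#' @param metric label for the output row.
#' @return one-row data.frame: `metric`, `test`, `statistic`, `p_value`,
#'   `n_a`, `n_b`, `degenerate` (TRUE when either group is constant).
#' @export
compare_groups <- function(a, b, test = c("wilcox", "t"), metric = "") {
  test <- match.arg(test)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) stop("each group needs at least 3 values")
  degenerate <- sd(a) == 0 || sd(b) == 0
  ht <- if (test == "wilcox") {
    wilcox.test(a, b, alternative = "two.sided", exact = FALSE, correct = TRUE)
  } else {
    t.test(a, b, alternative = "two.sided")
  }
  data.frame(metric = metric, test = test,
             statistic = unname(ht$statistic), p_value = ht$p.value,
             n_a = length(a), n_b = length(b), degenerate = degenerate)
}

#' Descriptive linear trend with pointwise confidence band
#'
#' Ordinary least squares of metric vs. concentration, with a pointwise
#' confidence band — a visualization aid, not a mechanistic model. The
#' `log10_y` option reproduces semi-log presentation by fitting and
#' banding on log10(y).
#'
#' @param x,y numeric vectors (>= 3 points; `x` must vary).
#' @param level confidence level (default 0.95).
#' @param log10_y fit log10(y) instead of y.
#' @param n_grid number of band evaluation points.
#' @return list: `slope`, `intercept`, `band` (data.frame `x`, `fit`,
#'   `lwr`, `upr` on the fitted scale), `log10_y`.
#' @export
linear_trend <- function(x, y, level = 0.95, log10_y = FALSE, n_grid = 50L) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 points")
  if (sd(x) == 0) stop("constant x: singular fit")
  yy <- if (log10_y) log10(y) else y
  fit <- lm(yy ~ x)
  grid <- data.frame(x = seq(min(x), max(x), length.out = n_grid))
  band <- cbind(grid, predict(fit, newdata = grid, interval = "confidence",
                              level = level))
  names(band) <- c("x", "fit", "lwr", "upr")
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       band = band, log10_y = log10_y)
}
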