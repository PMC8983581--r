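#' Generate a synthetic FRAP trace with known recovery parameters
#'
#' The noiseless recovery fraction follows the single-exponential model
#' `f(t) = m_f * (1 - 2^(-t / t_half))`, so the trace passes through
#' `m_f / 2` at `t = t_half` and plateaus at `m_f`. The returned object
#' carries raw ROI, background and unbleached-reference channels with an
#' optional multiplicative acquisition-photobleaching drift, so that
#' [normalize_trace()] must reconstruct the model curve.
#'
#' @param t_half recovery half-time, s (> 0).
#' @param m_f mobile fraction in (0, 1].
#' @param noise_sd additive noise sd on the normalized scale (fraction).
#' @param n_points number of post-bleach samples.
#' @param seed RNG seed.
#' @param t_max last sampled time, s (default `8 * t_half`).
#' @param bleach_depth normalized intensity immediately after bleaching
#'   (default 0.5: bleached to 50% intensity).
#' @param background constant background level, a.u.
#' @param reference0 unbleached-reference intensity at t = 0, a.u.
#' @param drift_rate fractional linear decay per second of the reference
#'   (overall acquisition photobleaching); 0 disables it.
#' @return a [frap_trace] object; attributes `t_half_true`, `m_f_true`.
#' @export
generate_frap_trace <- function(t_half, m_f, noise_sd = 0, n_points = 50L,
                                seed = 1L, t_max = 8 * t_half,
                                bleach_depth = 0.5, background = 20,
                                reference0 = 520, drift_rate = 0) {
  if (t_half <= 0) stop("t_half must be positive")
  if (m_f <= 0 || m_f > 1) stop("m_f must lie in (0, 1]")
  withr::with_seed(seed, {
    time <- seq(0, t_max, length.out = n_points)
    f <- m_f * (1 - 2^(-time / t_half))
    ideal <- bleach_depth + f * (1 - bleach_depth)  # normalized intensity
    drift <- pmax(1 - drift_rate * time, 0.2)
    reference <- background + (reference0 - background) * drift
    noisy <- ideal + if (noise_sd > 0) rnorm(n_points, 0, noise_sd) else 0
    roi <- background + (reference - background) * noisy
    tr <- frap_trace(time = time, roi = roi, background = rep(background, n_points),
                     reference = reference, prebleach = reference0)
    attr(tr, "t_half_true") <- t_half
    attr(tr, "m_f_true") <- m_f
    tr
  })
}

#' Generate an in vitro dilution series with a known saturation concentration
#'
#' Emulates dilution-ladder condensate imaging: for each concentration a
#' small image stack is produced; below `csat_true` the field contains
#' only background, at or above it the field contains bright condensate
#' spots whose number grows with concentration (at least `min_spots`
#' whenever the sample is phase-separated, so an error-free detector
#' brackets `csat_true` exactly).
#'
#' @param csat_true saturation concentration, nmol/L.
#' @param concentrations ascending concentrations, nmol/L.
#' @param seed RNG seed.
#' @param pixel_size lateral pixel size, um.
#' @param n_planes number of z planes (default 13: a 6-um range at 0.5-um
#'   spacing, endpoints included).
#' @param z_step z spacing, um.
#' @param field_px lateral field size in pixels.
#' @param min_spots condensate count at the first phase-separated
#'   concentration.
#' @param max_spots cap on the per-field condensate count (placement in
#'   a finite field saturates at high supersaturation).
#' @param background,spot_intensity,noise_sd image formation parameters
#'   (a.u.).
#' @return object of class `dilution_series`: list with `concentrations`
#'   and `stacks` (one single-channel [image_stack] per concentration),
#'   plus `csat_true` and the true per-concentration spot counts.
#' @export
generate_dilution_series <- function(csat_true, concentrations, seed = 1L,
                                     pixel_size = 0.1, n_planes = 13L,
                                     z_step = 0.5, field_px = 128L,
                                     min_spots = 6L, max_spots = 40L,
                                     background = 10,
                                     spot_intensity = 200, noise_sd = 2) {
  if (length(concentrations) < 1) stop("empty concentration list")
  if (is.unsorted(concentrations, strictly = TRUE)) {
    stop("concentrations must be sorted strictly ascending")
  }
  withr::with_seed(seed, {
    stacks <- vector("list", length(concentrations))
    n_true <- integer(length(concentrations))
    vs <- c(z_step, pixel_size, pixel_size)
    shape <- c(n_planes, field_px, field_px)
    extent <- (shape - 1) * vs
    for (k in seq_along(concentrations)) {
      conc <- concentrations[k]
      vol <- array(background, shape)
      n_spots <- 0L
      if (conc >= csat_true) {
        # grows with supersaturation, capped at what one field can hold
        n_spots <- min(min_spots + as.integer(round(6 * log2(conc / csat_true))),
                       max_spots)
        r <- 0.35
        centers <- matrix(NA_real_, n_spots, 3)
        for (i in seq_len(n_spots)) {
          for (try in 1:500) {
            cand <- c(runif(1, r, extent[1] - r),
                      runif(2, r + 0.3, extent[2:3] - r - 0.3))
            if (i > 1) {
              # separation enforced laterally: detection happens on the
              # z-projection, where axially stacked spots would merge
              prev <- centers[seq_len(i - 1), 2:3, drop = FALSE]
              dd <- sqrt(colSums((t(prev) - cand[2:3])^2))
              if (any(dd < 2 * r + 0.3)) next
            }
            centers[i, ] <- cand
            break
          }
          if (anyNA(centers[i, ])) stop("could not place condensate spot")
          vol <- paint_sphere(vol, vs, centers[i, ], r, spot_intensity)
        }
      }
      if (noise_sd > 0) {
        vol <- pmax(vol + rnorm(length(vol), 0, noise_sd), 0)
        dim(vol) <- shape
      }
      stacks[[k]] <- image_stack(array(vol, c(1L, shape)), vs, "protein")
      n_true[k] <- n_spots
    }
    structure(list(concentrations = concentrations, stacks = stacks,
                   csat_true = csat_true, n_spots_true = n_true),
              class = "dilution_series")
  })
}

#' Generate a synthetic turbidity series with known sigmoidal mean
#'
#' A340 responses follow a logistic curve in log-concentration above the
#' saturation point, plus replicate Gaussian noise and a constant buffer
#' absorbance.
#'
#' @param concentrations protein concentrations, umol/L.
#' @param csat_true onset concentration, umol/L.
#' @param a340_max plateau absorbance above background.
#' @param n_replicates replicates per concentration (>= 3 by default,
#'   mirroring standard practice).
#' @param noise_sd replicate noise sd.
#' @param buffer_a340 buffer-only absorbance.
#' @param seed RNG seed.
#' @return a data.frame with columns `concentration`, `replicate`,
#'   `a340`, `buffer_a340`; attribute `mean_true` holds the noiseless
#'   background-subtracted means.
#' @export
generate_turbidity_series <- function(concentrations, csat_true = 0.5,
                                      a340_max = 0.4, n_replicates = 3L,
                                      noise_sd = 0.01, buffer_a340 = 0.05,
                                      seed = 1L) {
  withr::with_seed(seed, {
    mu <- a340_max / (1 + exp(-4 * (log10(pmax(concentrations, 1e-9)) - log10(csat_true))))
    mu[concentrations <= 0] <- 0
    df <- do.call(rbind, lapply(seq_along(concentrations), function(k) {
      data.frame(concentration = concentrations[k],
                 replicate = seq_len(n_replicates),
                 a340 = buffer_a340 + mu[k] + rnorm(n_replicates, 0, noise_sd),
                 buffer_a340 = buffer_a340)
    }))
    attr(df, "mean_true") <- mu
    df
  })
}

# spacer alphabet for synthetic IDR sequences: no F (prevents accidental
# FG) and no L (prevents a trailing "GL" upgrading a plain FG to GLFG);
# weighted toward N/Q/S/T/G/A to mimic NUP98-style disordered composition
.spacer_alphabet <- c(N = 4, Q = 4, S = 5, T = 4, G = 4, A = 3, P = 2,
                      V = 1, E = 1, K = 1, R = 1, D = 1, H = 1, M = 1)

#' Generate a synthetic FG-repeat construct sequence
#'
#' Emits a two-region disordered sequence with exactly the requested
#' numbers of FG and GLFG motifs per region (each GLFG contains, and is
#' counted once as, an FG). Spacers avoid phenylalanine and leucine so no
#' accidental motifs arise, and are compositionally biased toward
#' N/Q/S/T. Region annotations (`nterm`, `cterm`) are 1-based inclusive
#' intervals; per-motif positions are recorded for building mutation
#' specs.
#'
#' @param n_fg_nterm,n_fg_cterm total FG valence per region (GLFG
#'   included).
#' @param n_glfg_nterm,n_glfg_cterm GLFG count per region; must not
#'   exceed the corresponding FG count.
#' @param seed RNG seed.
#' @param spacer_range min/max spacer length between motifs (residues).
#' @return a [protein_sequence] whose `motifs` attribute is a data.frame
#'   with columns `region`, `kind` (`FG`/`GLFG`), `start` (motif start)
#'   and `f_pos` (position of the motif's F, i.e. the FG dipeptide
#'   start).
#' @export
generate_construct_sequence <- function(n_fg_nterm, n_fg_cterm,
                                        n_glfg_nterm = 0L, n_glfg_cterm = 0L,
                                        seed = 1L, spacer_range = c(4L, 12L)) {
  counts <- c(n_fg_nterm, n_fg_cterm, n_glfg_nterm, n_glfg_cterm)
  if (any(counts < 0)) stop("motif counts must be non-negative")
  if (n_glfg_nterm > n_fg_nterm || n_glfg_cterm > n_fg_cterm) {
    stop("GLFG counts cannot exceed FG counts in a region")
  }
  withr::with_seed(seed, {
    spacer <- function() {
      len <- sample(spacer_range[1]:spacer_range[2], 1)
      paste(sample(names(.spacer_alphabet), len, replace = TRUE,
                   prob = .spacer_alphabet), collapse = "")
    }
    build_region <- function(n_fg, n_glfg) {
      kinds <- c(rep("GLFG", n_glfg), rep("FG", n_fg - n_glfg))
      if (length(kinds) > 1) kinds <- sample(kinds)
      pieces <- character(0)
      motif_kind <- character(0)
      motif_start <- integer(0)
      pos <- 0L
      for (k in kinds) {
        sp <- spacer()
        pieces <- c(pieces, sp)
        pos <- pos + nchar(sp)
        pieces <- c(pieces, k)
        motif_kind <- c(motif_kind, k)
        motif_start <- c(motif_start, pos + 1L)
        pos <- pos + nchar(k)
      }
      sp <- spacer()
      pieces <- c(pieces, sp)
      pos <- pos + nchar(sp)
      list(seq = paste(pieces, collapse = ""), len = pos,
           kind = motif_kind, start = motif_start)
    }
    nt <- build_region(n_fg_nterm, n_glfg_nterm)
    ct <- build_region(n_fg_cterm, n_glfg_cterm)
    residues <- paste0(nt$seq, ct$seq)
    regions <- list(nterm = c(1L, nt$len),
                    cterm = c(nt$len + 1L, nt$len + ct$len))
    motifs <- data.frame(
      region = c(rep("nterm", length(nt$kind)), rep("cterm", length(ct$kind))),
      kind = c(nt$kind, ct$kind),
      start = c(nt$start, ct$start + nt$len),
      stringsAsFactors = FALSE
    )
    # the F of an FG motif: at start for FG, at start + 2 for GLFG
    motifs$f_pos <- motifs$start + ifelse(motifs$kind == "GLFG", 2L, 0L)
    seq <- protein_sequence(id = "synthetic_construct", residues = residues,
                            regions = regions)
    attr(seq, "motifs") <- motifs
    seq
  })
}
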