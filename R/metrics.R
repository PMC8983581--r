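# Per-cell phase-separation metrics: puncta number density, average
# punctum volume V_p, light/dense-phase concentrations [LP]/[DP], the
# partition coefficient K_p = [DP]/[LP], the Gibbs free energy of
# transfer -RT ln K_p, Pearson colocalization with the DNA channel, and
# nuclear-periphery statistics.

#' Linear intensity-to-concentration calibration
#'
#' Maps arbitrary-unit fluorescence intensity to concentration as
#' `conc = offset + slope * intensity`. The identity default reports
#' concentrations in a.u.; ratio metrics (K_p, and hence the free energy
#' of transfer) are independent of `slope` and, with `offset = 0`, of the
#' calibration altogether.
#'
#' @param slope umol/L per intensity unit (> 0).
#' @param offset umol/L.
#' @return object of class `calibration_model`.
#' @export
calibration_model <- function(slope = 1, offset = 0) {
  stopifnot(slope > 0)
  structure(list(slope = slope, offset = offset), class = "calibration_model")
}

apply_calibration <- function(calib, intensity) {
  calib$offset + calib$slope * intensity
}

#' Thermodynamic constants for free-energy conversion
#'
#' @param temperature Kelvin (> 0); default 310.15 K (37 degrees C, live-cell
#'   imaging temperature).
#' @return object of class `thermo_params` with the gas constant
#'   `R = 1.987e-3` kcal mol^-1 K^-1.
#' @export
thermo_params <- function(temperature = 310.15) {
  stopifnot(temperature > 0)
  structure(list(R = 1.987e-3, temperature = temperature),
            class = "thermo_params")
}

#' Partition coefficient K_p = [DP] / [LP]
#'
#' @param dp dense-phase concentration (inside puncta).
#' @param lp light-phase concentration (nucleoplasm outside puncta).
#' @return `dp / lp`; `NA` with a warning when either phase is
#'   non-positive (undefined metric, not zero).
#' @export
partition_coefficient <- function(dp, lp) {
  out <- dp / lp
  bad <- !is.na(lp) & !is.na(dp) & (lp <= 0 | dp <= 0)
  if (any(bad)) {
    warning("non-positive phase concentration: K_p undefined")
    out[bad] <- NA_real_
  }
  out
}

#' Gibbs free energy of transfer into the dense phase
#'
#' `dG_Tr = -R T ln(K_p)`, in kcal/mol: negative when partitioning into
#' puncta is favourable (K_p > 1), positive when unfavourable.
#'
#' @param k_p partition coefficient(s), > 0.
#' @param thermo a [thermo_params] object.
#' @return free energy of transfer, kcal/mol.
#' @export
delta_g_transfer <- function(k_p, thermo = thermo_params()) {
  if (any(!is.na(k_p) & k_p <= 0)) stop("k_p must be positive")
  -thermo$R * thermo$temperature * log(k_p)
}

#' Pearson colocalization of protein and DNA over a nucleus mask
#'
#' @param stack two-channel [image_stack].
#' @param mask logical array selecting nuclear voxels (>= 2 TRUE).
#' @param protein_channel,dna_channel channel selectors.
#' @return Pearson correlation coefficient in `[-1, 1]`; `NA` with a
#'   warning when either channel is constant within the mask.
#' @export
pearson_colocalization <- function(stack, mask, protein_channel = "protein",
                                   dna_channel = "dna") {
  stopifnot(inherits(stack, "image_stack"))
  if (sum(mask) < 2) stop("mask must contain at least 2 voxels")
  p <- stack_channel(stack, protein_channel)[mask]
  d <- stack_channel(stack, dna_channel)[mask]
  if (sd(p) == 0 || sd(d) == 0) {
    warning("constant channel within mask: PCC undefined")
    return(NA_real_)
  }
  cor(p, d)
}

#' Nuclear-periphery statistics of puncta
#'
#' @param puncta per-punctum records from [measure_puncta()] (must carry
#'   `boundary_distance`).
#' @param cutoff periphery distance cutoff, um (default 0.5).
#' @return list with `periphery_fraction` (fraction of puncta closer than
#'   `cutoff` to the nuclear boundary; `NA` for an empty record list) and
#'   `interior_puncta` (records at >= `cutoff`).
#' @export
periphery_stats <- function(puncta, cutoff = 0.5) {
  stopifnot(cutoff >= 0)
  if (nrow(puncta) == 0) {
    return(list(periphery_fraction = NA_real_,
                interior_puncta = puncta))
  }
  if (!"boundary_distance" %in% names(puncta)) {
    stop("records lack boundary_distance")
  }
  near <- puncta$boundary_distance < cutoff
  list(periphery_fraction = mean(near),
       interior_puncta = puncta[!near, , drop = FALSE])
}

#' Per-cell condensate metrics
#'
#' Combines one nucleus record with its puncta into the per-cell
#' quantities: puncta number density (count per 10^3 um^3 nuclear
#' volume), average punctum volume V_p, calibrated light-phase ([LP]:
#' mean protein intensity over nuclear voxels outside all puncta),
#' dense-phase ([DP]: pooled mean over all punctum voxels of the
#' nucleus), K_p, free energy of transfer, total nuclear concentration,
#' and Pearson colocalization. Zero-punctum cells get a defined density
#' (0), [LP], total concentration and PCC, but undefined (`NA`) V_p,
#' [DP], K_p and free energy — such cells belong in density summaries and
#' are excluded from V_p/K_p summaries.
#'
#' @param nucleus one-row data.frame from [measure_nuclei()].
#' @param puncta per-punctum records of this nucleus.
#' @param nuclei_labels,puncta_labels aligned [label_volume]s.
#' @param stack source [image_stack].
#' @param calib a [calibration_model].
#' @param thermo a [thermo_params].
#' @param protein_channel,dna_channel channel selectors.
#' @param periphery_cutoff um; periphery fraction cutoff.
#' @param boundary_margin um (default 0.3): concentration metrics
#'   ([LP], [DP] support intersection, total) are computed over nuclear
#'   voxels at least this far inside the segmented boundary, excluding
#'   partial-volume rim voxels that would otherwise dilute them.
#' @return one-row data.frame of class metrics.
#' @export
cell_metrics <- function(nucleus, puncta, nuclei_labels, puncta_labels,
                         stack, calib = calibration_model(),
                         thermo = thermo_params(),
                         protein_channel = "protein", dna_channel = "dna",
                         periphery_cutoff = 0.5, boundary_margin = 0.3) {
  stopifnot(nrow(nucleus) == 1, nucleus$volume > 0)
  check_aligned(nuclei_labels, stack)
  nid <- nucleus$nucleus_id
  pt <- puncta[puncta$nucleus_id == nid, , drop = FALSE]
  n_p <- nrow(pt)

  nuc_mask <- nuclei_labels$labels == nid
  if (boundary_margin > 0) {
    bd <- .edt_3d(nuc_mask, as.integer(dim(nuc_mask)),
                  as.numeric(nuclei_labels$voxel_size))
    interior <- nuc_mask & bd >= boundary_margin
    # degenerate thin nuclei: fall back to the full mask
    if (sum(interior) >= 100) nuc_mask <- interior
  }
  pun_mask <- nuc_mask & (puncta_labels$labels > 0) &
    array(puncta_labels$labels %in% pt$punctum_id, dim(puncta_labels$labels))
  # exclude punctum halos (detection foreground beyond the refined
  # regions) from the light phase: they are phase-boundary voxels
  excl <- attr(puncta_labels, "exclusion_mask")
  lp_mask <- if (!is.null(excl)) nuc_mask & !excl & !pun_mask else nuc_mask & !pun_mask

  prot <- stack_channel(stack, protein_channel)
  lp <- if (any(lp_mask)) apply_calibration(calib, mean(prot[lp_mask])) else NA_real_
  if (!any(lp_mask)) warning("nucleus has no non-punctum voxel: [LP] undefined")
  dp <- if (n_p > 0) apply_calibration(calib, mean(prot[pun_mask])) else NA_real_
  total <- apply_calibration(calib, mean(prot[nuc_mask]))
  k_p <- if (n_p > 0 && !is.na(lp)) partition_coefficient(dp, lp) else NA_real_
  dg <- if (!is.na(k_p)) delta_g_transfer(k_p, thermo) else NA_real_

  has_dna <- (is.character(dna_channel) && dna_channel %in% stack$channel_names) ||
    (is.numeric(dna_channel) && dna_channel <= dim(stack$voxels)[1])
  pcc <- if (has_dna) {
    pearson_colocalization(stack, nuc_mask, protein_channel, dna_channel)
  } else NA_real_

  peri <- periphery_stats(pt, periphery_cutoff)

  data.frame(
    nucleus_id = nid,
    n_puncta = n_p,
    puncta_density = 1000 * n_p / nucleus$volume,
    v_p = if (n_p > 0) mean(pt$volume) else NA_real_,
    lp = lp,
    dp = dp,
    k_p = k_p,
    delta_g_tr = dg,
    total_concentration = total,
    pcc = pcc,
    periphery_fraction = peri$periphery_fraction,
    nucleus_volume = nucleus$volume,
    touches_stack_boundary = nucleus$touches_stack_boundary
  )
}
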