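# Puncta detection: threshold the multi-scale LoG response, seed at its
# local maxima (minimum physical separation, deterministic tie-breaks),
# and split touching blobs by watershed flooding of the response.

resolve_threshold <- function(vals, policy) {
  if (is.numeric(policy)) return(as.numeric(policy))
  method <- if (is.list(policy)) policy$method else policy
  switch(method,
         otsu = otsu_threshold(vals),
         quantile = quantile(vals, if (is.list(policy) && !is.null(policy$prob)) policy$prob else 0.99),
         absolute = {
           if (!is.list(policy) || is.null(policy$value)) stop("absolute policy needs $value")
           policy$value
         },
         stop("unknown threshold policy: ", method))
}

#' Detect and segment puncta from a LoG response grid
#'
#' Foreground is the response above a threshold (default: Otsu on the
#' positive response restricted to nuclear voxels, hence invariant to
#' positive intensity rescaling); seeds are its 26-neighbourhood local
#' maxima, greedily filtered so accepted seeds are at least
#' `min_seed_separation` apart (anisotropic physical distance; candidates
#' ranked by response, exact ties broken by lexicographic voxel order);
#' each seed grows into one punctum by watershed flooding of the inverted
#' response within the foreground.
#'
#' @param response LoG response array from [log_response()].
#' @param stack the source [image_stack] (for voxel sizes).
#' @param nuclei_labels nuclei [label_volume]; with `nuclear_only` the
#'   search is restricted to labelled nuclear voxels.
#' @param threshold_policy `list(method = "otsu")` (default),
#'   `list(method = "quantile", prob = ...)`,
#'   `list(method = "absolute", value = ...)`, or a bare number.
#' @param min_seed_separation minimum seed spacing, um (default 0.3,
#'   about the lateral resolution limit).
#' @param nuclear_only restrict detection to nuclear voxels (default
#'   TRUE); disable to also segment cytoplasmic condensates.
#' @param seed_margin um (default 0.3): watershed seeds must lie at
#'   least this far inside the nucleus, keeping the LoG response of the
#'   bright nucleus/background edge itself from seeding phantom puncta.
#' @param min_contrast minimum fractional rise of a punctum's peak above
#'   the nucleoplasm level (default 0.1); regions without dense-phase
#'   contrast (e.g. residual rim-ring responses in punctum-free nuclei)
#'   are discarded.
#' @param refine_fraction after watershed, each region is refined to its
#'   half-maximum support: voxels whose protein intensity reaches the
#'   surrounding light-phase level plus `refine_fraction` of the
#'   punctum's peak rise above it. For blurred spherical puncta the
#'   half-height contour sits at the true boundary, so refined regions
#'   track true punctum volume and their pooled mean tracks the
#'   dense-phase intensity. `NULL` disables refinement (raw watershed
#'   regions of the LoG foreground, which over-fill blobs).
#' @param protein_channel channel used for refinement.
#' @return a [label_volume] of kind `"puncta"`; no foreground yields an
#'   empty (all-zero) label volume. Attribute `"threshold"` records the
#'   response threshold used.
#' @export
detect_puncta <- function(response, stack, nuclei_labels,
                          threshold_policy = list(method = "otsu"),
                          min_seed_separation = 0.3, nuclear_only = TRUE,
                          refine_fraction = 0.5, protein_channel = "protein",
                          seed_margin = 0.3, min_contrast = 0.1) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(response)
  vs <- stack$voxel_size
  region <- if (nuclear_only) {
    check_aligned(nuclei_labels, stack)
    nuclei_labels$labels > 0
  } else {
    array(TRUE, d)
  }
  vals <- response[region & response > 0]
  if (length(vals) < 2) {
    out <- label_volume(array(0L, d), vs, "puncta")
    attr(out, "threshold") <- Inf
    return(out)
  }
  thr <- resolve_threshold(vals, threshold_policy)
  fg <- region & response > thr
  if (!any(fg)) {
    out <- label_volume(array(0L, d), vs, "puncta")
    attr(out, "threshold") <- thr
    return(out)
  }

  seed_ok <- fg
  if (seed_margin > 0) {
    nuc_mask <- nuclei_labels$labels > 0
    if (any(nuc_mask)) {
      bd <- .edt_3d(nuc_mask, as.integer(d), as.numeric(vs))
      # inside a nucleus, seeds keep clear of the rim; outside (only
      # reachable when nuclear_only = FALSE) no margin applies
      seed_ok <- fg & (!nuc_mask | bd >= seed_margin)
    }
  }
  is_max <- local_maxima_3d(response, seed_ok)
  cand <- which(is_max)
  # rank: descending response, then lexicographic (column-major) order
  ord <- order(-response[cand], cand)
  cand <- cand[ord]
  ci <- arrayInd(cand, d)
  pos <- cbind((ci[, 1] - 1) * vs[1], (ci[, 2] - 1) * vs[2], (ci[, 3] - 1) * vs[3])

  # ridge-connectivity check: does the response along the voxel line from
  # candidate c to seed a stay at c's own level (no saddle)? If so, c is
  # a plateau/shoulder of the same blob, not a separate punctum.
  same_ridge <- function(vc, va, resp_c) {
    nstep <- max(3L, ceiling(max(abs(va - vc))) * 2L)
    tt <- seq(0, 1, length.out = nstep)
    mn <- Inf
    for (t in tt) {
      v <- round(vc + t * (va - vc))
      mn <- min(mn, response[v[1], v[2], v[3]])
    }
    (resp_c - mn) <= 0.01 * abs(resp_c)
  }

  acc <- logical(length(cand))
  acc_idx <- integer(0)
  for (i in seq_along(cand)) {
    reject <- FALSE
    if (length(acc_idx) > 0) {
      dd <- sqrt(colSums((t(pos[acc_idx, , drop = FALSE]) - pos[i, ])^2))
      if (any(dd < min_seed_separation)) {
        reject <- TRUE
      } else {
        near <- acc_idx[dd < 1.5]
        for (j in near) {
          if (same_ridge(ci[i, ], ci[j, ], response[cand[i]])) {
            reject <- TRUE
            break
          }
        }
      }
    }
    if (!reject) {
      acc[i] <- TRUE
      acc_idx <- c(acc_idx, i)
    }
  }
  seeds <- array(0L, d)
  seeds[cand[acc]] <- seq_len(sum(acc))

  lab <- .watershed_3d(as.numeric(response), seeds, fg, as.integer(d))

  # all foreground (labelled or not) is excluded from [LP] support
  exclusion <- fg
  prot <- stack_channel(stack, protein_channel)
  bg_mask <- region & !fg
  bg <- if (any(bg_mask)) median(prot[bg_mask]) else 0
  idx <- which(lab > 0)
  if (length(idx)) {
    lv <- lab[idx]
    pk <- tapply(prot[idx], lv, max)
    if (min_contrast > 0 && bg > 0) {
      flat <- as.integer(names(pk))[pk < bg * (1 + min_contrast)]
      if (length(flat)) {
        lab[idx[lv %in% flat]] <- 0L
        keep_ids <- !(lv %in% flat)
        idx <- idx[keep_ids]
        lv <- lv[keep_ids]
      }
    }
    if (!is.null(refine_fraction) && length(idx)) {
      cut <- bg + refine_fraction * (pk - bg)
      keep <- prot[idx] >= cut[as.character(lv)]
      lab[idx[!keep]] <- 0L
    }
  }
  out <- label_volume(lab, vs, "puncta")
  # halo voxels -- the detection foreground plus a dilation margin
  # (sub-threshold punctum rim and blur tail; wider axially, where both
  # the PSF and the z-sampling are coarser) -- belong to neither phase
  # cleanly; [LP] estimation excludes them
  if (any(exclusion)) {
    margin <- c(0.45, 0.25, 0.25)
    dist_scaled <- .edt_3d(!exclusion, as.integer(d), as.numeric(vs / margin))
    exclusion <- exclusion | (dist_scaled <= 1)
  }
  attr(out, "exclusion_mask") <- exclusion
  attr(out, "threshold") <- thr
  attr(out, "n_seeds") <- sum(acc)
  out
}

#' Measure per-punctum features
#'
#' Volume, mean and integrated protein intensity (the sum over member
#' voxels), voxel-centred centroid in um, parent nucleus by centroid
#' membership, and distance from the centroid to the nuclear boundary via
#' an anisotropy-aware Euclidean distance transform of the parent nucleus
#' mask.
#'
#' @param puncta_labels puncta [label_volume] from [detect_puncta()].
#' @param stack source [image_stack].
#' @param nuclei_labels nuclei [label_volume].
#' @param protein_channel channel selector.
#' @param nuclear_only when TRUE (default) puncta whose centroid falls
#'   outside every nucleus are dropped (their count is reported in the
#'   `"n_excluded"` attribute and a message); when FALSE they are kept
#'   with `nucleus_id = 0` and `boundary_distance = NA`.
#' @return data.frame with one row per punctum: `punctum_id`,
#'   `nucleus_id`, `volume` (um^3), `mean_intensity`,
#'   `integrated_intensity`, `centroid_z/y/x` (um), `boundary_distance`
#'   (um).
#' @export
measure_puncta <- function(puncta_labels, stack, nuclei_labels,
                           protein_channel = "protein", nuclear_only = TRUE) {
  stopifnot(inherits(puncta_labels, "label_volume"),
            puncta_labels$kind == "puncta")
  check_aligned(puncta_labels, stack)
  check_aligned(nuclei_labels, stack)
  lab <- puncta_labels$labels
  d <- dim(lab)
  vs <- puncta_labels$voxel_size
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  empty <- data.frame(punctum_id = integer(0), nucleus_id = integer(0),
                      volume = numeric(0), mean_intensity = numeric(0),
                      integrated_intensity = numeric(0),
                      centroid_z = numeric(0), centroid_y = numeric(0),
                      centroid_x = numeric(0), boundary_distance = numeric(0))
  if (length(ids) == 0) return(empty)

  prot <- stack_channel(stack, protein_channel)
  vol_vox <- voxel_volume(vs)
  idx <- which(lab > 0)
  lv <- lab[idx]
  ai <- arrayInd(idx, d)
  counts <- tabulate(lv, nbins = max(ids))
  sum_int <- tapply(prot[idx], lv, sum)
  cz <- tapply((ai[, 1] - 1) * vs[1], lv, mean)
  cy <- tapply((ai[, 2] - 1) * vs[2], lv, mean)
  cx <- tapply((ai[, 3] - 1) * vs[3], lv, mean)

  rec <- data.frame(
    punctum_id = ids,
    volume = counts[ids] * vol_vox,
    integrated_intensity = as.numeric(sum_int[as.character(ids)]),
    centroid_z = as.numeric(cz[as.character(ids)]),
    centroid_y = as.numeric(cy[as.character(ids)]),
    centroid_x = as.numeric(cx[as.character(ids)])
  )
  rec$mean_intensity <- rec$integrated_intensity / counts[ids]

  cvox <- cbind(pmin(pmax(round(rec$centroid_z / vs[1]) + 1, 1), d[1]),
                pmin(pmax(round(rec$centroid_y / vs[2]) + 1, 1), d[2]),
                pmin(pmax(round(rec$centroid_x / vs[3]) + 1, 1), d[3]))
  rec$nucleus_id <- nuclei_labels$labels[cvox]
  # rim puncta: centroid voxel can fall just outside the (conservatively
  # segmented) nucleus; assign by majority nuclear label of member voxels
  zero <- which(rec$nucleus_id == 0L)
  for (i in zero) {
    nl <- nuclei_labels$labels[idx[lv == rec$punctum_id[i]]]
    nl <- nl[nl > 0]
    if (length(nl)) rec$nucleus_id[i] <- as.integer(names(which.max(table(nl))))
  }

  rec$boundary_distance <- NA_real_
  for (nid in setdiff(unique(rec$nucleus_id), 0L)) {
    edt <- .edt_3d(as.logical(nuclei_labels$labels == nid), as.integer(d),
                   as.numeric(vs))
    sel <- rec$nucleus_id == nid
    rec$boundary_distance[sel] <- edt[cvox[sel, , drop = FALSE]]
  }

  n_out <- sum(rec$nucleus_id == 0L)
  if (nuclear_only && n_out > 0) {
    message(sprintf("excluding %d punctum/a with centroid outside all nuclei", n_out))
    rec <- rec[rec$nucleus_id != 0L, , drop = FALSE]
  }
  rec <- rec[, c("punctum_id", "nucleus_id", "volume", "mean_intensity",
                 "integrated_intensity", "centroid_z", "centroid_y",
                 "centroid_x", "boundary_distance")]
  rownames(rec) <- NULL
  attr(rec, "n_excluded") <- if (nuclear_only) n_out else 0L
  rec
}
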