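#' Normalise a volume by total intracranial volume
#'
#' Head size varies substantially between subjects (and between sexes), so
#' regional and tissue volumes are expressed as unitless fractions of total
#' intracranial volume (TIV). Report layers may multiply by 100 for display
#' in percent; this function always returns the raw fraction.
#'
#' @param volume volume(s) in mm3, >= 0.
#' @param tiv total intracranial volume(s) in mm3, > 0.
#' @return volume / tiv.
#' @export
tiv_normalize <- function(volume, tiv) {
  if (any(tiv <= 0)) stop("tiv must be positive", call. = FALSE)
  if (any(volume < 0)) stop("volume must be non-negative", call. = FALSE)
  volume / tiv
}

#' Brain parenchymal fraction
#'
#' (gray matter + white matter) / TIV, a global atrophy measure.
#'
#' @param gm,wm gray and white matter volumes in mm3.
#' @inheritParams tiv_normalize
#' @return unitless parenchymal fraction.
#' @export
parenchymal_fraction <- function(gm, wm, tiv) {
  tiv_normalize(gm, tiv) + tiv_normalize(wm, tiv)
}

wml_classes <- c("periventricular", "juxtacortical", "deep_white")

#' Aggregate white-matter-lesion records per subject
#'
#' Sums per-lesion volumes into a total and per anatomical class
#' (periventricular, juxtacortical, deep white), normalised by TIV, and
#' counts lesions. Classes absent from the input get zero volume.
#'
#' @param lesions data.frame with one row per lesion: \code{subject_id},
#'   \code{lesion_class} (one of the three class labels) and \code{volume}
#'   (mm3, > 0). May be empty. May contain several subjects.
#' @param tiv named numeric vector of TIV per subject (names are subject
#'   ids), or a single value when \code{lesions} holds one subject.
#' @param subject_ids optional character vector of subjects to report
#'   (defaults to \code{names(tiv)}, or the subjects present in
#'   \code{lesions}); subjects without lesions get zero rows.
#' @return data.frame: \code{subject_id}, \code{total_lesion_count},
#'   \code{total_lesion_volume_frac}, \code{periventricular_frac},
#'   \code{juxtacortical_frac}, \code{deep_white_frac}. The total fraction
#'   equals the sum of the three class fractions.
#' @export
aggregate_wml <- function(lesions, tiv, subject_ids = NULL) {
  if (nrow(lesions)) {
    bad <- setdiff(unique(lesions$lesion_class), wml_classes)
    if (length(bad))
      stop("unknown lesion class: ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (any(lesions$volume <= 0))
      stop("lesion volumes must be positive", call. = FALSE)
  }
  if (is.null(names(tiv))) {
    ids <- unique(as.character(lesions$subject_id))
    if (length(tiv) == 1 && length(ids) <= 1) {
      if (!length(ids)) ids <- if (is.null(subject_ids)) "subject" else subject_ids
      names(tiv) <- ids[1]
      if (length(ids) > 1) stop("tiv must be named per subject", call. = FALSE)
    } else stop("tiv must be a named vector (names = subject ids)",
                call. = FALSE)
  }
  if (any(tiv <= 0)) stop("tiv must be positive", call. = FALSE)
  if (is.null(subject_ids)) subject_ids <- names(tiv)
  unknown <- setdiff(unique(as.character(lesions$subject_id)), subject_ids)
  if (nrow(lesions) && length(unknown))
    stop("lesions for subjects without TIV: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  out <- data.frame(subject_id = subject_ids,
                    total_lesion_count = 0L,
                    total_lesion_volume_frac = 0,
                    periventricular_frac = 0,
                    juxtacortical_frac = 0,
                    deep_white_frac = 0,
                    stringsAsFactors = FALSE)
  if (nrow(lesions)) {
    sid <- factor(as.character(lesions$subject_id), levels = subject_ids)
    cls <- factor(lesions$lesion_class, levels = wml_classes)
    vol_by <- tapply(lesions$volume, list(sid, cls), sum, default = 0)
    cnt <- as.integer(table(sid))
    out$total_lesion_count <- cnt
    frac <- vol_by / tiv[subject_ids]
    out$periventricular_frac <- frac[, "periventricular"]
    out$juxtacortical_frac <- frac[, "juxtacortical"]
    out$deep_white_frac <- frac[, "deep_white"]
    out$total_lesion_volume_frac <- rowSums(frac)
  }
  rownames(out) <- NULL
  out
}

#' Derived volumetric measures for a cohort
#'
#' Joins TIV-normalised tissue and regional volumes with the white-matter
#' lesion summary into the single table the baseline analyses consume.
#'
#' @param volumes data.frame with one row per subject: \code{subject_id},
#'   \code{tiv}, \code{gm_volume}, \code{wm_volume}, \code{csf_volume},
#'   \code{hippocampus_left}, \code{hippocampus_right} (mm3), plus any
#'   cortical thickness columns (mm), which are passed through unchanged.
#' @param lesions per-lesion records as for \code{\link{aggregate_wml}};
#'   may be NULL for a cohort without lesion segmentation.
#' @return data.frame keyed by \code{subject_id} with fraction columns
#'   (\code{gm_frac}, \code{wm_frac}, \code{csf_frac},
#'   \code{hippocampus_left_frac}, \code{hippocampus_right_frac},
#'   \code{parenchymal_frac}), the pass-through thickness columns, and the
#'   WML summary columns.
#' @export
derive_volumetrics <- function(volumes, lesions = NULL) {
  req <- c("subject_id", "tiv", "gm_volume", "wm_volume", "csf_volume",
           "hippocampus_left", "hippocampus_right")
  miss <- setdiff(req, names(volumes))
  if (length(miss))
    stop("volumetrics columns not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  with_tot <- volumes$gm_volume + volumes$wm_volume + volumes$csf_volume
  if (any(with_tot > volumes$tiv * 1.05))
    stop("gm + wm + csf exceeds 1.05 * tiv for some subjects", call. = FALSE)
  out <- data.frame(
    subject_id = as.character(volumes$subject_id),
    tiv = volumes$tiv,
    gm_frac = tiv_normalize(volumes$gm_volume, volumes$tiv),
    wm_frac = tiv_normalize(volumes$wm_volume, volumes$tiv),
    csf_frac = tiv_normalize(volumes$csf_volume, volumes$tiv),
    hippocampus_left_frac = tiv_normalize(volumes$hippocampus_left,
                                          volumes$tiv),
    hippocampus_right_frac = tiv_normalize(volumes$hippocampus_right,
                                           volumes$tiv),
    stringsAsFactors = FALSE)
  out$parenchymal_frac <- parenchymal_fraction(volumes$gm_volume,
                                               volumes$wm_volume,
                                               volumes$tiv)
  extra <- setdiff(names(volumes), req)
  for (cc in extra) out[[cc]] <- volumes[[cc]]
  if (!is.null(lesions)) {
    tiv <- stats::setNames(volumes$tiv, as.character(volumes$subject_id))
    wml <- aggregate_wml(lesions, tiv)
    out <- merge(out, wml, by = "subject_id", sort = FALSE)
  }
  out
}
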