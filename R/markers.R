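#' Individual-level neural markers from parcel-constrained fROIs
#'
#' For each subject and each parcel, a functional ROI (fROI) is defined as
#' the top fraction of parcel voxels by the localizer contrast statistic;
#' the markers are (i) the cross-validated contrast effect size within the
#' fROI, (ii) the number of individually significant voxels in the parcel,
#' and (iii) the split-half spatial correlation of the contrast topography
#' within the parcel. Per-hemisphere aggregates are unweighted means over
#' that hemisphere's parcels, and lateralization is computed from the
#' hemisphere voxel counts.
#'
#' @name markers
NULL

as_parcel_mask <- function(parcel, domain) {
  if (inherits(parcel, "binary_map")) {
    stop_if_incompatible(domain, parcel$domain, "map and parcel")
    parcel$membership
  } else {
    m <- as.logical(parcel)
    if (length(m) != n_sites(domain)) stop("parcel mask length mismatch", call. = FALSE)
    m
  }
}

#' Define a subject fROI within a parcel
#'
#' Top `round-half-up(fraction * |parcel|)` parcel voxels by map value, ties
#' broken by ascending linear voxel index.
#'
#' @param map a `stat_map` (typically the localizer t-map).
#' @param parcel a `binary_map` or logical mask.
#' @param fraction fraction of the parcel's voxels to select, default 0.10.
#' @export
define_froi <- function(map, parcel, fraction = 0.10) {
  mem <- as_parcel_mask(parcel, map$domain)
  top_fraction_binarize(map, binary_map(mem, map$domain), fraction = fraction)
}

# fold statistic for fROI definition from the held-in runs: across-run t
# when >= 2 runs are held in, else the single held-in run's contrast
fold_statistic <- function(cm, held_in) {
  x <- cm[, held_in, drop = FALSE]
  if (ncol(x) >= 2L) {
    mu <- rowMeans(x)
    sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
    ifelse(sdv > 0, mu / (sdv / sqrt(ncol(x))), 0)
  } else {
    x[, 1]
  }
}

#' Leave-one-run-out cross-validated effect size
#'
#' For each run r, the fROI is defined on the contrast statistic computed
#' from all runs except r; the language-minus-control response of the
#' left-out run r is then averaged over the fROI voxels. The per-fold
#' estimates are averaged. Defining the fROI and estimating its response on
#' disjoint runs keeps the estimate free of selection bias.
#'
#' @param session a [subject_session()] with >= 2 runs.
#' @param parcel parcel mask within which the fROI is defined.
#' @param contrast `c(language_condition, control_condition)`.
#' @param fraction fROI fraction of the parcel, default 0.10.
#' @return The cross-validated effect size, in the units of the input maps.
#' @export
crossval_effect_size <- function(session, parcel, contrast, fraction = 0.10) {
  if (n_runs(session) < 2L) {
    stop(sprintf("%s/%s: cross-validation requires >= 2 runs",
                 session$subject, session$session), call. = FALSE)
  }
  mem <- as_parcel_mask(parcel, session$domain)
  cm <- run_contrasts(session, contrast)
  folds <- vapply(seq_len(ncol(cm)), function(r) {
    stat <- fold_statistic(cm, setdiff(seq_len(ncol(cm)), r))
    froi <- define_froi(stat_map(stat, session$domain, subject = session$subject,
                                 kind = "contrast"),
                        mem, fraction = fraction)
    mean(cm[froi$membership, r])
  }, numeric(1))
  mean(folds)
}

#' Count individually significant voxels in a parcel
#'
#' Number of parcel voxels whose t-value exceeds the one-sided critical
#' value at the uncorrected threshold `p`.
#'
#' @param map a `stat_map` of kind `"t"` with dof set.
#' @param parcel parcel mask.
#' @param p uncorrected one-sided threshold, default 0.001.
#' @export
voxel_count <- function(map, parcel, p = 0.001) {
  mem <- as_parcel_mask(parcel, map$domain)
  sum(threshold_binarize(map, binary_map(mem, map$domain), p)$membership)
}

#' Split-half spatial-correlation stability marker
#'
#' Fisher-transformed Pearson correlation of the contrast map between odd-
#' and even-numbered runs, within each parcel, plus per-hemisphere means
#' over each hemisphere's parcels (both z and raw r aggregates are
#' returned).
#'
#' @inheritParams crossval_effect_size
#' @param parcels a [parcel_set()].
#' @param subset `"all"` or `"positive"` voxel subset.
#' @return list with `parcel_z`, `parcel_r`, `hemi_z`, `hemi_r`.
#' @export
spatial_correlation_marker <- function(session, parcels, contrast,
                                       subset = "all") {
  rec <- qc_session(session, parcels, contrast, subset = subset)
  hemi <- vapply(parcels$parcels, `[[`, "", "hemi")
  agg <- function(v) c(L = mean(v[hemi == "L"], na.rm = TRUE),
                       R = mean(v[hemi == "R"], na.rm = TRUE))
  list(parcel_z = rec$parcel_z, parcel_r = rec$parcel_r,
       hemi_z = agg(rec$parcel_z), hemi_r = agg(rec$parcel_r))
}

#' Hemispheric lateralization index from voxel counts
#'
#' `(LH - RH) / (LH + RH)`, in \[-1, 1\]; defined as 0 (with a warning) when
#' both counts are zero.
#'
#' @param lh_count,rh_count nonnegative voxel counts.
#' @export
lateralization_index <- function(lh_count, rh_count) {
  stopifnot(lh_count >= 0, rh_count >= 0)
  if (lh_count + rh_count == 0) {
    warning("both hemisphere counts are 0; lateralization index set to 0",
            call. = FALSE)
    return(0)
  }
  (lh_count - rh_count) / (lh_count + rh_count)
}

#' Per-subject marker table and cohort quantile summary
#'
#' Computes, for every session in the cohort, all three markers per parcel,
#' the per-hemisphere aggregates (unweighted means over each hemisphere's
#' parcels), and the lateralization index from the summed hemisphere voxel
#' counts. Sessions with fewer than 2 runs contribute voxel counts only
#' (when a precomputed t-map is available) and `NA` for the run-dependent
#' markers. The summary reports min / 25% / median / 75% / max per
#' hemisphere aggregate, using type-7 (linear-interpolation) quantiles.
#'
#' @param cohort list of [subject_session()]s.
#' @param parcels a [parcel_set()].
#' @param contrast `c(language_condition, control_condition)`.
#' @param fraction fROI fraction, default 0.10.
#' @param p voxel-count threshold, default 0.001.
#' @param subset voxel subset for the spatial-correlation marker.
#' @return list with `table` (one row per subject) and `summary` (quantile
#'   rows per marker and hemisphere).
#' @export
marker_table <- function(cohort, parcels, contrast, fraction = 0.10,
                         p = 0.001, subset = "all") {
  stopifnot(length(cohort) >= 1L)
  tab <- do.call(rbind, lapply(cohort, marker_record, parcels = parcels,
                               contrast = contrast, fraction = fraction,
                               p = p, subset = subset))
  rownames(tab) <- NULL
  list(table = tab, summary = marker_summary(tab))
}

#' @rdname marker_table
#' @param session a single [subject_session()].
#' @return `marker_record()`: a one-row data.frame of that subject's markers.
#' @export
marker_record <- function(session, parcels, contrast, fraction = 0.10,
                          p = 0.001, subset = "all") {
  keys <- names(parcels$parcels)
  hemi <- vapply(parcels$parcels, `[[`, "", "hemi")
  ses <- session
  multi <- n_runs(ses) >= 2L
  tm <- tryCatch(session_tmap(ses, contrast), error = function(e) NULL)
  es <- zs <- vc <- stats::setNames(rep(NA_real_, length(keys)), keys)
  if (multi) {
    for (k in keys) {
      es[k] <- crossval_effect_size(ses, parcels$parcels[[k]]$mask,
                                    contrast, fraction)
    }
    zs <- spatial_correlation_marker(ses, parcels, contrast, subset)$parcel_z
  }
  if (!is.null(tm) && !is.null(tm$dof)) {
    for (k in keys) vc[k] <- voxel_count(tm, parcels$parcels[[k]]$mask, p)
  }
  lh_ct <- sum(vc[hemi == "L"], na.rm = TRUE)
  rh_ct <- sum(vc[hemi == "R"], na.rm = TRUE)
  li <- if (all(is.na(vc))) NA_real_
        else suppressWarnings(lateralization_index(lh_ct, rh_ct))
  out <- c(list(subject = ses$subject, session = ses$session,
                n_runs = n_runs(ses)),
           stats::setNames(as.list(es), paste0(keys, "_effect_size")),
           stats::setNames(as.list(vc), paste0(keys, "_voxel_count")),
           stats::setNames(as.list(zs), paste0(keys, "_spcorr_z")),
           list(LH_effect_size = mean(es[hemi == "L"]),
                RH_effect_size = mean(es[hemi == "R"]),
                LH_voxel_count = mean(vc[hemi == "L"]),
                RH_voxel_count = mean(vc[hemi == "R"]),
                LH_spcorr_z = mean(zs[hemi == "L"]),
                RH_spcorr_z = mean(zs[hemi == "R"]),
                lat_index = li))
  as.data.frame(out, check.names = FALSE)
}

#' @rdname marker_table
#' @param table a marker table (rows from [marker_record()]).
#' @return `marker_summary()`: long data.frame of min / 25% / median / 75% /
#'   max per hemisphere-aggregate marker.
#' @export
marker_summary <- function(table) {
  qnames <- c("min", "q25", "median", "q75", "max")
  scols <- c("LH_effect_size", "RH_effect_size", "LH_voxel_count",
             "RH_voxel_count", "LH_spcorr_z", "RH_spcorr_z")
  do.call(rbind, lapply(scols, function(cn) {
    v <- table[[cn]][is.finite(table[[cn]])]
    q <- if (length(v)) stats::quantile(v, c(0, .25, .5, .75, 1),
                                        type = 7, names = FALSE)
         else rep(NA_real_, 5)
    data.frame(marker = cn, stat = qnames, value = q)
  }))
}
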