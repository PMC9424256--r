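#' Split-half activation-stability QC
#'
#' Session quality is quantified by the spatial correlation of the contrast
#' topography between the odd- and even-numbered runs, computed within a set
#' of parcels and averaged. Sessions with a negative mean correlation are
#' excluded; among a subject's remaining sessions the one with the highest
#' mean correlation is kept.
#'
#' @name qc
NULL

# clamp before atanh so identical halves give a finite Fisher z
R_CLAMP <- 1 - 1e-7

fisher_z <- function(r) atanh(pmin(pmax(r, -R_CLAMP), R_CLAMP))

#' Split a session into odd-run and even-run contrast maps
#'
#' Averages the per-run language-minus-control contrast over the
#' odd-numbered and the even-numbered runs (run numbering from 1), yielding
#' the two half-session maps whose spatial correlation measures activation
#' stability.
#'
#' @param session a [subject_session()] with at least 2 runs.
#' @param contrast length-2 character vector
#'   `c(language_condition, control_condition)`.
#' @return list of two `stat_map`s, `odd` and `even`.
#' @export
split_half_maps <- function(session, contrast) {
  if (n_runs(session) < 2L) {
    stop(sprintf("single-run session %s/%s: split-half QC undefined, mark for visual review",
                 session$subject, session$session), call. = FALSE)
  }
  cm <- run_contrasts(session, contrast)
  idx <- vapply(session$runs, function(r) as.integer(r$run), integer(1))
  odd <- idx %% 2L == 1L
  if (!any(odd) || all(odd)) {
    stop(sprintf("session %s/%s has runs only of one parity", session$subject,
                 session$session), call. = FALSE)
  }
  mk <- function(cols, lab) stat_map(rowMeans(cm[, cols, drop = FALSE]),
                                     session$domain, subject = session$subject,
                                     kind = "contrast", fold = lab)
  list(odd = mk(odd, "odd"), even = mk(!odd, "even"))
}

#' Parcel-wise spatial correlation between two half-session maps
#'
#' Pearson r of the two maps within each parcel (optionally restricted to
#' voxels where both halves are positive), the per-parcel Fisher z, and
#' their unweighted means across parcels. Parcels with fewer than 2 usable
#' voxels, or with zero variance in either half, are omitted from the means
#' with a warning. The session status is `excluded_negative` when the mean
#' raw r is negative, else `kept`.
#'
#' @param a,b grid-compatible `stat_map`s (the two halves).
#' @param parcels a [parcel_set()] on the same grid.
#' @param subset `"all"` voxels, or `"positive"` (both halves > 0).
#' @param subject,session identifiers recorded on the result (default from `a`).
#' @return A `qc_record`: list with `subject`, `session`, `parcel_r`,
#'   `parcel_z` (named numeric), `mean_r`, `mean_z`, `subset`, `status`.
#' @export
parcelwise_spatial_correlation <- function(a, b, parcels,
                                           subset = c("all", "positive"),
                                           subject = a$subject,
                                           session = NA_character_) {
  subset <- match.arg(subset)
  stop_if_incompatible(a$domain, b$domain, "the two halves")
  stop_if_incompatible(a$domain, parcels$domain, "maps and parcels")
  rs <- vapply(parcels$parcels, function(p) {
    use <- p$mask & is.finite(a$values) & is.finite(b$values)
    if (subset == "positive") use <- use & a$values > 0 & b$values > 0
    x <- a$values[use]; y <- b$values[use]
    if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning(sprintf("parcel '%s' has <2 usable voxels or zero variance; omitted",
                      p$name), call. = FALSE)
      return(NA_real_)
    }
    stats::cor(x, y)
  }, numeric(1))
  zs <- fisher_z(rs)
  mean_r <- mean(rs, na.rm = TRUE)
  mean_z <- mean(zs, na.rm = TRUE)
  status <- if (is.nan(mean_r)) "needs_review"
            else if (mean_r < 0) "excluded_negative" else "kept"
  structure(list(subject = subject, session = session,
                 parcel_r = rs, parcel_z = zs,
                 mean_r = mean_r, mean_z = mean_z,
                 subset = subset, scheme = "odd_even", status = status),
            class = "qc_record")
}

#' Split-half QC for one session
#'
#' Convenience wrapper: [split_half_maps()] then
#' [parcelwise_spatial_correlation()]. Single-run sessions yield a
#' `needs_review` record with `NA` correlations instead of an error.
#'
#' @inheritParams split_half_maps
#' @inheritParams parcelwise_spatial_correlation
#' @export
qc_session <- function(session, parcels, contrast, subset = "all") {
  if (n_runs(session) < 2L) {
    np <- length(parcels$parcels)
    rs <- stats::setNames(rep(NA_real_, np), names(parcels$parcels))
    return(structure(list(subject = session$subject, session = session$session,
                          parcel_r = rs, parcel_z = rs,
                          mean_r = NA_real_, mean_z = NA_real_,
                          subset = subset, scheme = "odd_even",
                          status = "needs_review"),
                     class = "qc_record"))
  }
  halves <- split_half_maps(session, contrast)
  parcelwise_spatial_correlation(halves$odd, halves$even, parcels,
                                 subset = subset, subject = session$subject,
                                 session = session$session)
}

#' Select one session per subject from QC records
#'
#' Drops `excluded_negative` sessions; among each subject's remaining
#' records picks the session with the highest mean r (ties broken by the
#' lexicographically earliest session id, deterministically). Subjects whose
#' only sessions are `needs_review` are passed through flagged for visual
#' inspection; subjects whose sessions are all excluded are dropped.
#'
#' @param records list of `qc_record`s (from [qc_session()]).
#' @return list with data.frames `chosen` (subject, session, mean_r, mean_z,
#'   status), `excluded`, and `flagged`.
#' @export
select_sessions <- function(records) {
  stopifnot(length(records) >= 1L)
  tab <- do.call(rbind, lapply(records, function(r) {
    data.frame(subject = r$subject, session = r$session,
               mean_r = r$mean_r, mean_z = r$mean_z, status = r$status,
               stringsAsFactors = FALSE)
  }))
  excluded <- tab[tab$status == "excluded_negative", ]
  chosen <- NULL; flagged <- NULL
  for (sub in unique(tab$subject)) {
    st <- tab[tab$subject == sub, ]
    ok <- st[st$status == "kept", ]
    if (nrow(ok) > 0L) {
      ok <- ok[order(-ok$mean_r, ok$session), ]
      if (nrow(ok) > 1L && ok$mean_r[1] == ok$mean_r[2]) {
        message(sprintf("select_sessions: tie for subject %s broken by earliest session id (%s)",
                        sub, ok$session[1]))
      }
      chosen <- rbind(chosen, ok[1, ])
    } else if (any(st$status == "needs_review")) {
      nr <- st[st$status == "needs_review", ]
      flagged <- rbind(flagged, nr[order(nr$session)[1], ])
    }
  }
  empty <- tab[0, ]
  list(chosen = if (is.null(chosen)) empty else chosen,
       excluded = excluded,
       flagged = if (is.null(flagged)) empty else flagged)
}

#' Write QC records to CSV (one row per session)
#' @param records list of `qc_record`s.
#' @param path output CSV path.
#' @export
write_qc_csv <- function(records, path) {
  rows <- lapply(records, function(r) {
    c(list(subject = r$subject, session = r$session),
      as.list(r$parcel_r),
      list(mean_r = r$mean_r, mean_z = r$mean_z,
           subset = r$subset, status = r$status))
  })
  tab <- do.call(rbind, lapply(rows, function(x) as.data.frame(x, check.names = FALSE)))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
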