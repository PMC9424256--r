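#' Per-subject session of multi-run condition effect maps
#'
#' The unit on which QC and individual markers are computed: one scanning
#' session holding, for each run, the per-condition effect maps (and
#' optionally a precomputed contrast t-map for the whole session).
#'
#' @param subject,session identifiers.
#' @param runs list of entries `list(run=, effects=)` where `run` is the
#'   1-based run index and `effects` a named list of `stat_map`s (one per
#'   condition).
#' @param tmap optional session-level `stat_map` of kind `"t"` (with dof).
#' @export
subject_session <- function(subject, session, runs, tmap = NULL) {
  stopifnot(length(runs) >= 1L)
  idx <- vapply(runs, function(r) as.integer(r$run), integer(1))
  if (anyDuplicated(idx) || any(idx < 1L)) {
    stop("run indices must be unique and >= 1", call. = FALSE)
  }
  dom <- runs[[1]]$effects[[1]]$domain
  for (r in runs) for (m in r$effects) stop_if_incompatible(dom, m$domain, "run maps")
  if (!is.null(tmap)) stop_if_incompatible(dom, tmap$domain, "t-map and run maps")
  runs <- runs[order(idx)]
  structure(list(subject = subject, session = session, runs = runs,
                 tmap = tmap, domain = dom),
            class = "subject_session")
}

#' @export
print.subject_session <- function(x, ...) {
  cat(sprintf("<subject_session> %s/%s: %d runs, conditions %s%s\n",
              x$subject, x$session, length(x$runs),
              paste(names(x$runs[[1]]$effects), collapse = ","),
              if (!is.null(x$tmap)) " + t-map" else ""))
  invisible(x)
}

n_runs <- function(session) length(session$runs)

# per-run contrast (language - control) value matrix, one column per run
run_contrasts <- function(session, contrast) {
  lang <- contrast[[1]]; ctrl <- contrast[[2]]
  cm <- vapply(session$runs, function(r) {
    if (!all(c(lang, ctrl) %in% names(r$effects))) {
      stop(sprintf("run %d of %s/%s lacks condition '%s' or '%s'",
                   r$run, session$subject, session$session, lang, ctrl),
           call. = FALSE)
    }
    r$effects[[lang]]$values - r$effects[[ctrl]]$values
  }, numeric(n_sites(session$domain)))
  dim(cm) <- c(n_sites(session$domain), length(session$runs))
  cm
}

#' Across-run contrast t-map for a session
#'
#' One-sample t of the per-run language-minus-control contrasts across the
#' session's runs (dof = runs - 1): the per-subject ranking statistic used
#' for binarization when no first-level GLM t-map is supplied. Sessions
#' carrying a precomputed `tmap` return it unchanged.
#'
#' @param session a [subject_session()].
#' @param contrast `c(language_condition, control_condition)`.
#' @return A `stat_map` of kind `"t"`.
#' @export
session_tmap <- function(session, contrast) {
  if (n_runs(session) < 2L) {
    if (!is.null(session$tmap)) return(session$tmap)
    stop(sprintf("%s/%s has a single run and no precomputed t-map",
                 session$subject, session$session), call. = FALSE)
  }
  if (!is.null(session$tmap)) return(session$tmap)
  cm <- run_contrasts(session, contrast)
  n <- ncol(cm)
  mu <- rowMeans(cm)
  sdv <- sqrt(rowSums((cm - mu)^2) / (n - 1))
  t <- ifelse(sdv > 0, mu / (sdv / sqrt(n)), NA_real_)
  stat_map(t, session$domain, subject = session$subject, kind = "t",
           dof = n - 1)
}

#' Read a cohort manifest / metadata table
#'
#' The manifest CSV has one row per (subject, session, run, condition) with
#' the path to the corresponding effect map; optional demographic columns
#' (age, gender, handedness, native, localizer_version) are carried through
#' untouched. Paths are resolved relative to the CSV's directory.
#'
#' @param path CSV file with at least columns
#'   `subject, session, run, condition, path`.
#' @param check_paths verify that every referenced file exists.
#' @return data.frame with resolved paths.
#' @export
read_cohort_table <- function(path, check_paths = TRUE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "session", "run", "condition", "path")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop(sprintf("manifest lacks columns: %s",
                                 paste(miss, collapse = ", ")), call. = FALSE)
  key <- with(tab, paste(subject, session, run, condition))
  if (anyDuplicated(key)) stop("duplicate (subject, session, run, condition) rows", call. = FALSE)
  base <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", tab$path), tab$path,
                file.path(base, tab$path))
  if (check_paths) {
    bad <- abs[!file.exists(abs)]
    if (length(bad)) stop(sprintf("missing map files, e.g. '%s' (%d total)",
                                  bad[1], length(bad)), call. = FALSE)
  }
  tab$path <- abs
  tab
}

#' Load `subject_session` objects from a cohort manifest
#'
#' @param manifest data.frame from [read_cohort_table()] (or a path to one).
#' @param expect optional `vol_grid` all maps must match.
#' @return named list of `subject_session`s, one per (subject, session).
#' @export
load_sessions <- function(manifest, expect = NULL) {
  if (is.character(manifest)) manifest <- read_cohort_table(manifest)
  keys <- unique(manifest[, c("subject", "session")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- keys$subject[i]; ses <- keys$session[i]
    rows <- manifest[manifest$subject == sub & manifest$session == ses, ]
    runs <- lapply(sort(unique(rows$run)), function(ri) {
      rr <- rows[rows$run == ri, ]
      eff <- stats::setNames(lapply(seq_len(nrow(rr)), function(j) {
        read_stat_map(rr$path[j], expect = expect, subject = sub,
                      kind = "condition-effect")
      }), rr$condition)
      list(run = ri, effects = eff)
    })
    out[[i]] <- subject_session(sub, ses, runs)
  }
  names(out) <- paste(keys$subject, keys$session, sep = "/")
  out
}
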