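#' Synthetic localizer cohorts with known ground truth
#'
#' The generator emulates the structure of a multi-run functional localizer
#' cohort: a fixed population activation landscape (a sum of 3-D Gaussian
#' blobs placed at canonical language-network locations, with weaker
#' right-hemisphere homologues), per-subject spatial jitter of the blob
#' centres, per-subject multiplicative amplitude scaling, and additive
#' i.i.d. Gaussian noise per run. The "control" condition is a zero-mean
#' baseline, so the language-minus-control contrast equals the (scaled,
#' jittered) landscape plus noise. Every downstream quantity — selection
#' probabilities, atlas values, effect sizes, voxel counts — has a known or
#' Monte-Carlo-computable ground truth.
#'
#' @name simulate
NULL

default_language_blobs <- function() {
  # canonical LH language-network foci (MNI mm): IFG, posterior temporal,
  # anterior temporal
  data.frame(name = c("IFG", "PostTemp", "AntTemp"),
             x = c(-50, -54, -56), y = c(20, -40, -10), z = c(8, 2, -6),
             sd_mm = 12, peak = 2)
}

#' Ground-truth activation landscape
#'
#' @param grid a [vol_grid()]; default the 4 mm MNI bounding box.
#' @param blobs data.frame of left-hemisphere Gaussian blobs with columns
#'   name, x, y, z (centre, mm), sd_mm, peak (amplitude).
#' @param asymmetry right-hemisphere amplitude multiplier in \[0, 1\]: each
#'   LH blob gets a mirrored RH homologue with peak scaled by this factor.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(grid = mni_grid(4), blobs = default_language_blobs(),
                         asymmetry = 0.5) {
  stopifnot(asymmetry >= 0, asymmetry <= 1)
  rh <- blobs
  rh$x <- -rh$x
  rh$peak <- rh$peak * asymmetry
  rh$name <- paste0(rh$name, "_R")
  blobs$name <- paste0(blobs$name, "_L")
  all_blobs <- rbind(blobs, rh)
  structure(list(grid = grid, blobs = all_blobs, asymmetry = asymmetry),
            class = "ground_truth")
}

#' Evaluate the amplitude landscape A(v), optionally jittered and scaled
#'
#' @param truth a `ground_truth`.
#' @param offsets optional numeric matrix (n_blobs x 3) of per-blob centre
#'   offsets in mm.
#' @param scale multiplicative amplitude factor.
#' @export
amplitude_landscape <- function(truth, offsets = NULL, scale = 1) {
  xyz <- voxel_world(truth$grid)
  b <- truth$blobs
  if (is.null(offsets)) offsets <- matrix(0, nrow(b), 3)
  v <- numeric(nrow(xyz))
  for (i in seq_len(nrow(b))) {
    d2 <- (xyz[, 1] - (b$x[i] + offsets[i, 1]))^2 +
          (xyz[, 2] - (b$y[i] + offsets[i, 2]))^2 +
          (xyz[, 3] - (b$z[i] + offsets[i, 3]))^2
    v <- v + scale * b$peak[i] * exp(-d2 / (2 * b$sd_mm[i]^2))
  }
  v
}

#' Simulation configuration
#'
#' Defaults describe the study conditions exercised throughout the package:
#' 200 subjects, 6 runs each, 6 mm isotropic centre jitter, lognormal
#' amplitude scale (meanlog 0, sdlog 0.3), and additive noise with sd equal
#' to a quarter of the blob peak amplitude.
#'
#' @param n_subjects cohort size.
#' @param runs_per_subject runs per session.
#' @param jitter_sd isotropic per-blob centre jitter sd, mm.
#' @param scale_meanlog,scale_sdlog lognormal parameters of the per-subject
#'   amplitude scale.
#' @param noise_sd additive Gaussian noise sd per condition map, in
#'   amplitude units.
#' @param seed master integer seed (mandatory).
#' @export
sim_config <- function(n_subjects = 200, runs_per_subject = 6,
                       jitter_sd = 6, scale_meanlog = 0, scale_sdlog = 0.3,
                       noise_sd = 0.5, seed) {
  if (missing(seed)) stop("a master seed is required", call. = FALSE)
  stopifnot(n_subjects >= 1, runs_per_subject >= 1, jitter_sd >= 0,
            scale_sdlog >= 0, noise_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 runs_per_subject = as.integer(runs_per_subject),
                 jitter_sd = jitter_sd, scale_meanlog = scale_meanlog,
                 scale_sdlog = scale_sdlog, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

subject_seed <- function(master, index) {
  as.integer((as.numeric(master) + 7919 * as.numeric(index)) %% 2147483647)
}

#' Simulate one subject's session
#'
#' Draws per-blob centre offsets (isotropic normal with the configured
#' jitter sd) and a lognormal amplitude scale, then per run emits a
#' "language" map (scaled jittered landscape plus noise) and a "control"
#' map (noise only), together with a pooled across-run t-map of the
#' contrast (dof = runs - 1) when the session has >= 2 runs.
#'
#' @param truth a [ground_truth()].
#' @param cfg a [sim_config()].
#' @param seed integer seed for this subject.
#' @param subject,session identifiers.
#' @return A [subject_session()].
#' @export
simulate_subject <- function(truth, cfg, seed, subject = "sub01",
                             session = "ses1") {
  if (cfg$runs_per_subject < 1L) stop("runs_per_subject must be >= 1", call. = FALSE)
  set.seed(seed)
  nb <- nrow(truth$blobs)
  offsets <- matrix(stats::rnorm(3 * nb, 0, cfg$jitter_sd), nb, 3)
  scale <- stats::rlnorm(1, cfg$scale_meanlog, cfg$scale_sdlog)
  A <- amplitude_landscape(truth, offsets, scale)
  n <- length(A)
  runs <- lapply(seq_len(cfg$runs_per_subject), function(r) {
    lang <- A + stats::rnorm(n, 0, cfg$noise_sd)
    ctrl <- stats::rnorm(n, 0, cfg$noise_sd)
    list(run = r, effects = list(
      language = stat_map(lang, truth$grid, subject = subject,
                          kind = "condition-effect", fold = sprintf("run%d", r)),
      control = stat_map(ctrl, truth$grid, subject = subject,
                         kind = "condition-effect", fold = sprintf("run%d", r))))
  })
  ses <- subject_session(subject, session, runs)
  if (cfg$runs_per_subject >= 2L) {
    ses$tmap <- session_tmap(ses, c("language", "control"))
  }
  ses
}

#' Simulate a cohort (optionally writing NIfTI maps and a manifest)
#'
#' Per-subject seeds are derived deterministically from the master seed and
#' the subject index, so any subject can be regenerated in isolation and
#' identical configurations yield bitwise-identical cohorts. When `out_dir`
#' is given, every per-run condition map is written as NIfTI and a manifest
#' CSV (readable by [read_cohort_table()]) is written alongside.
#'
#' @inheritParams simulate_subject
#' @param out_dir optional output directory.
#' @return list with `sessions` (list of [subject_session()]) and
#'   `manifest` (data.frame; paths filled when `out_dir` is given).
#' @export
simulate_cohort <- function(truth, cfg, out_dir = NULL) {
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sessions <- vector("list", cfg$n_subjects)
  rows <- list()
  for (i in seq_len(cfg$n_subjects)) {
    sub <- sprintf("sub%03d", i)
    ses <- simulate_subject(truth, cfg, subject_seed(cfg$seed, i),
                            subject = sub, session = "ses1")
    sessions[[i]] <- ses
    for (r in ses$runs) {
      for (cond in names(r$effects)) {
        p <- if (is.null(out_dir)) NA_character_ else {
          f <- file.path(out_dir, sprintf("%s_run%d_%s.nii.gz", sub, r$run, cond))
          write_nifti_map(r$effects[[cond]], path = f)
          f
        }
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sub, session = "ses1", run = r$run,
          condition = cond, path = p, stringsAsFactors = FALSE)
      }
    }
  }
  names(sessions) <- vapply(sessions, function(s) paste(s$subject, s$session, sep = "/"), "")
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(sessions = sessions, manifest = manifest)
}

#' Monte-Carlo per-voxel selection probability q(v)
#'
#' Estimates, by simulating independent subjects from the generative model,
#' the probability that each voxel falls in the top `fraction` of a
#' subject's t-map (or contrast map for single-run configurations) — the
#' quantity a top-fraction probabilistic atlas estimates.
#'
#' @inheritParams simulate_subject
#' @param fraction top-fraction selection rule.
#' @param n_mc number of Monte-Carlo subjects.
#' @param seed seed for the Monte-Carlo draw (independent of any cohort).
#' @param mask optional analysis mask; default all voxels.
#' @return numeric vector of selection probabilities over the grid.
#' @export
selection_probability <- function(truth, cfg, fraction = 0.10, n_mc = 1000,
                                  seed, mask = NULL) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (is.null(mask)) mask <- binary_map(rep(TRUE, n_sites(truth$grid)), truth$grid)
  counts <- numeric(n_sites(truth$grid))
  for (i in seq_len(n_mc)) {
    ses <- simulate_subject(truth, cfg, subject_seed(seed, i),
                            subject = sprintf("mc%06d", i))
    stat <- if (!is.null(ses$tmap)) ses$tmap
            else stat_map(run_contrasts(ses, c("language", "control"))[, 1],
                          truth$grid, kind = "contrast")
    counts <- counts + top_fraction_binarize(stat, mask, fraction)$membership
  }
  counts / n_mc
}
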