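#' End-to-end pipeline: QC -> session selection -> binarize -> atlas
#'
#' @name pipeline
NULL

pipeline_defaults <- function() {
  list(manifest = NULL, parcels = NULL, mask = NULL, out_dir = NULL,
       mode = "top_fraction", fraction = 0.10, p = NULL,
       language = "language", control = "control",
       qc_subset = "all", run_qc = TRUE,
       run_markers = FALSE, marker_fraction = 0.10, marker_p = 0.001,
       stability_sizes = NULL, stability_boot = 20,
       seed = 1L)
}

#' Signal a configuration/validation error (condition class
#' `validation_error`), distinguished from data errors by the CLI's exit
#' codes.
#' @param msg error message.
#' @export
validation_error <- function(msg) {
  stop(structure(class = c("validation_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Read and validate a pipeline configuration
#'
#' YAML file with keys among: manifest, parcels, mask, out_dir, mode,
#' fraction, p, language, control, qc_subset, run_qc, run_markers,
#' marker_fraction, marker_p, stability_sizes, stability_boot, seed.
#' Unknown keys are rejected.
#'
#' @param path YAML file path, or a named list of overrides.
#' @param overrides named list merged over the file's values.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- pipeline_defaults()
  user <- if (is.null(path)) list()
          else if (is.list(path)) path
          else yaml::read_yaml(path)
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    validation_error(sprintf("unknown config keys: %s",
                             paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(cfg, user)
  if (is.null(cfg$manifest)) validation_error("config requires 'manifest'")
  if (!cfg$mode %in% c("top_fraction", "fixed_p")) {
    validation_error("mode must be top_fraction or fixed_p")
  }
  if (cfg$mode == "fixed_p" && is.null(cfg$p)) validation_error("fixed_p mode requires 'p'")
  if (isTRUE(cfg$run_qc) && is.null(cfg$parcels)) {
    validation_error("QC requires 'parcels' (or set run_qc: false)")
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full atlas pipeline
#'
#' Loads the cohort manifest, runs split-half QC and session selection
#' (when parcels are provided), computes per-session t-maps, binarizes each
#' by the configured rule inside the analysis mask, aggregates into a
#' probabilistic atlas, and writes the atlas, QC table, optional marker
#' table, summary, and a run log to `out_dir`. Outputs are a pure function
#' of (inputs, config, seed).
#'
#' @param config a config list or YAML path (see [read_pipeline_config()]).
#' @return (invisibly) list with `atlas`, `summary`, `qc`, `selection`,
#'   `markers`, `stability`, `mask`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  set.seed(cfg$seed)
  contrast <- c(cfg$language, cfg$control)

  sessions <- load_sessions(cfg$manifest)
  stage_log("load", "%d sessions from %s", length(sessions), cfg$manifest)

  parcels <- NULL
  if (!is.null(cfg$parcels)) parcels <- read_parcels(cfg$parcels)

  qc_records <- NULL; selection <- NULL
  if (isTRUE(cfg$run_qc)) {
    qc_records <- lapply(sessions, qc_session, parcels = parcels,
                         contrast = contrast, subset = cfg$qc_subset)
    selection <- select_sessions(qc_records)
    kept_keys <- paste(selection$chosen$subject, selection$chosen$session, sep = "/")
    stage_log("qc", "%d sessions kept, %d excluded (negative r), %d flagged for review",
              nrow(selection$chosen), nrow(selection$excluded),
              nrow(selection$flagged))
    sessions <- sessions[names(sessions) %in% kept_keys]
  }
  if (length(sessions) == 0L) stop("no sessions survived QC", call. = FALSE)

  tmaps <- lapply(sessions, session_tmap, contrast = contrast)
  mask <- if (is.null(cfg$mask)) {
    analysis_mask(tmaps, "auto")
  } else {
    mm <- read_stat_map(cfg$mask, expect = tmaps[[1]]$domain)
    analysis_mask(tmaps, "explicit",
                  mask = is.finite(mm$values) & mm$values != 0)
  }
  stage_log("mask", "%d voxels in analysis mask (%s)", sum(mask$membership),
            if (is.null(cfg$mask)) "auto-intersection" else cfg$mask)

  members <- lapply(tmaps, function(tm) {
    if (cfg$mode == "top_fraction") top_fraction_binarize(tm, mask, cfg$fraction)
    else threshold_binarize(tm, mask, cfg$p)
  })
  atlas <- build_atlas(members)
  summ <- atlas_summary(atlas, mask)
  stage_log("atlas", "n=%d, LH max %.3f, RH max %.3f, mask mean %.4f",
            atlas$n_subjects, summ$lh_range["max"], summ$rh_range["max"],
            summ$mask_mean)

  markers <- NULL
  if (isTRUE(cfg$run_markers)) {
    markers <- marker_table(sessions, parcels, contrast,
                            fraction = cfg$marker_fraction, p = cfg$marker_p)
    stage_log("markers", "%d subjects", nrow(markers$table))
  }

  stability <- NULL
  if (!is.null(cfg$stability_sizes)) {
    stability <- stability_curve(tmaps, mask, cfg$stability_sizes,
                                 n_boot = cfg$stability_boot, seed = cfg$seed,
                                 fraction = cfg$fraction)
    stage_log("stability", "sizes %s", paste(cfg$stability_sizes, collapse = ","))
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_nifti_map(atlas, path = file.path(cfg$out_dir, "atlas.nii.gz"))
    write_nifti_map(mask, path = file.path(cfg$out_dir, "analysis_mask.nii.gz"))
    if (!is.null(qc_records)) {
      write_qc_csv(qc_records, file.path(cfg$out_dir, "qc.csv"))
    }
    utils::write.csv(atlas$laterality,
                     file.path(cfg$out_dir, "laterality.csv"), row.names = FALSE)
    sumtab <- data.frame(
      stat = c("n_subjects", "mask_voxels", "mask_mean", "lh_min", "lh_max",
               "rh_min", "rh_max", "lh_fraction_mean", "lh_fraction_median"),
      value = c(atlas$n_subjects, sum(mask$membership), summ$mask_mean,
                summ$lh_range["min"], summ$lh_range["max"],
                summ$rh_range["min"], summ$rh_range["max"],
                summ$lh_fraction_mean, summ$lh_fraction_median))
    utils::write.csv(sumtab, file.path(cfg$out_dir, "summary.csv"),
                     row.names = FALSE)
    if (!is.null(markers)) {
      utils::write.csv(markers$table, file.path(cfg$out_dir, "markers.csv"),
                       row.names = FALSE)
      utils::write.csv(markers$summary,
                       file.path(cfg$out_dir, "markers_summary.csv"),
                       row.names = FALSE)
    }
    if (!is.null(stability)) {
      utils::write.csv(stability, file.path(cfg$out_dir, "stability.csv"),
                       row.names = FALSE)
    }
    writeLines(c(sprintf("probatlas %s", as.character(utils::packageVersion("probatlas"))),
                 sprintf("R %s", R.version.string),
                 sprintf("seed %d", cfg$seed),
                 sprintf("mode %s fraction %s p %s", cfg$mode,
                         format(cfg$fraction), format(cfg$p)),
                 sprintf("mask %s (%d voxels)",
                         if (is.null(cfg$mask)) "auto-intersection" else cfg$mask,
                         sum(mask$membership)),
                 sprintf("sessions %d", atlas$n_subjects)),
               file.path(cfg$out_dir, "run_log.txt"))
  }

  invisible(list(atlas = atlas, summary = summ, qc = qc_records,
                 selection = selection, markers = markers,
                 stability = stability, mask = mask))
}
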