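# Shared fixtures: tiny grids, hand-built sessions, and miniature synthetic
# cohorts. Everything is generated in code; no binary files.

# grid symmetric about world x = 0 (odd shapes put voxel centres on x = 0)
sym_grid <- function(shape = c(5, 5, 5), spacing = 2) {
  aff <- diag(c(spacing, spacing, spacing, 1))
  aff[1:3, 4] <- -(shape - 1) / 2 * spacing
  vol_grid(shape, aff, space = "test-sym")
}

# grid strictly left/right split (even x extent, no midline voxels)
offset_grid <- function(shape = c(4, 4, 4), spacing = 2) {
  aff <- diag(c(spacing, spacing, spacing, 1))
  aff[1:3, 4] <- c(-(shape[1]) * spacing / 2 + spacing / 2,
                   -(shape[2] - 1) / 2 * spacing,
                   -(shape[3] - 1) / 2 * spacing)
  vol_grid(shape, aff, space = "test-offset")
}

map_on <- function(values, grid, kind = "t", dof = NULL, subject = "s1") {
  stat_map(values, grid, subject = subject, kind = kind, dof = dof)
}

full_mask <- function(grid) binary_map(rep(TRUE, n_sites(grid)), grid)

# session from per-run (language, control) value matrices (columns = runs)
session_from_values <- function(lang, ctrl, grid, subject = "s1",
                                session = "ses1") {
  runs <- lapply(seq_len(ncol(lang)), function(r) {
    list(run = r, effects = list(
      language = stat_map(lang[, r], grid, subject = subject,
                          kind = "condition-effect"),
      control = stat_map(ctrl[, r], grid, subject = subject,
                         kind = "condition-effect")))
  })
  subject_session(subject, session, runs)
}

# session whose per-run contrast is signal + noise_sd * N(0,1)
noisy_session <- function(signal, grid, n_runs = 2, noise_sd = 1,
                          subject = "s1", session = "ses1") {
  n <- n_sites(grid)
  lang <- vapply(seq_len(n_runs),
                 function(r) signal + rnorm(n, 0, noise_sd), numeric(n))
  ctrl <- vapply(seq_len(n_runs),
                 function(r) rnorm(n, 0, noise_sd), numeric(n))
  session_from_values(lang, ctrl, grid, subject, session)
}

# miniature ground truth on a small symmetric grid, blobs well inside
mini_truth <- function(shape = c(20, 24, 20), spacing = 2, asymmetry = 0.5,
                       peak = 2, sd_mm = 6) {
  grid <- sym_grid(shape, spacing)
  blobs <- data.frame(name = c("front", "back"),
                      x = c(-10, -12), y = c(8, -10), z = c(0, 2),
                      sd_mm = sd_mm, peak = peak)
  ground_truth(grid = grid, blobs = blobs, asymmetry = asymmetry)
}

# two-pass textbook Pearson correlation (independent oracle)
oracle_cor <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# exhaustive sort-based top-k selection (independent oracle): returns the
# selected linear indices, ties at the cut resolved by ascending index
oracle_top_k <- function(values, idx, k) {
  o <- idx[order(-values[idx], idx)]
  sort(o[seq_len(k)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
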