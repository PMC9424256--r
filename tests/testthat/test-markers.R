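contrast <- c("language", "control")

test_that("fROI definition selects the top parcel voxels", {
  grid <- vol_grid(c(20, 1, 1), diag(c(2, 2, 2, 1)))
  parcel <- rep(TRUE, 20)
  set.seed(20)
  v <- rnorm(20)
  froi <- define_froi(map_on(v, grid), parcel, 0.10)
  expect_equal(sum(froi$membership), 2)
  expect_setequal(which(froi$membership), order(-v)[1:2])
  # strictly decreasing values: fROI = first k indices
  dec <- map_on(seq(20, 1), grid)
  expect_identical(which(define_froi(dec, parcel, 0.25)$membership), 1:5)
  # sort-based oracle on random 500-voxel parcels
  g2 <- vol_grid(c(10, 10, 10), diag(c(2, 2, 2, 1)))
  for (seed in 1:3) {
    set.seed(seed)
    vals <- round(rnorm(1000), 1)
    pidx <- sort(sample(1000, 500))
    pm <- rep(FALSE, 1000); pm[pidx] <- TRUE
    got <- which(define_froi(map_on(vals, g2), pm, 0.1)$membership)
    expect_identical(got, oracle_top_k(vals, pidx, 50))
  }
})

test_that("cross-validated effect size reproduces the two-run hand computation", {
  grid <- vol_grid(c(10, 1, 1), diag(c(2, 2, 2, 1)))
  lang <- cbind(rep(2, 10), rep(4, 10))
  ctrl <- cbind(rep(1, 10), rep(1, 10))
  ses <- session_from_values(lang, ctrl, grid)
  # folds give (2-1) = 1 and (4-1) = 3; average 2
  expect_equal(crossval_effect_size(ses, rep(TRUE, 10), contrast), 2)
  # noise-free recovery: identical runs with contrast c over a subregion
  sig <- c(rep(3.5, 4), rep(0, 6))
  ses2 <- session_from_values(cbind(sig, sig, sig), matrix(0, 10, 3), grid)
  expect_equal(crossval_effect_size(ses2, rep(TRUE, 10), contrast, 0.4), 3.5)
  expect_error(crossval_effect_size(
    session_from_values(lang[, 1, drop = FALSE], ctrl[, 1, drop = FALSE], grid),
    rep(TRUE, 10), contrast), ">= 2 runs")
})

test_that("cross-validation leaves the effect estimate unbiased", {
  # selection on held-in runs, estimation on the left-out run: under pure
  # noise the estimate must average to zero despite selecting maxima
  grid <- vol_grid(c(7, 7, 6), diag(c(2, 2, 2, 1))); n <- n_sites(grid)
  parcel <- c(rep(TRUE, 120), rep(FALSE, n - 120))
  set.seed(21)
  null_es <- replicate(300, {
    ses <- noisy_session(rep(0, n), grid, n_runs = 3, noise_sd = 1)
    crossval_effect_size(ses, parcel, contrast)
  })
  se <- sd(null_es) / sqrt(length(null_es))
  expect_lt(abs(mean(null_es)), 3 * se)
  # with a true effect beta over the parcel, the estimate recovers beta
  beta <- 0.8
  sig <- rep(0, n); sig[parcel] <- beta
  set.seed(22)
  sig_es <- replicate(200, {
    ses <- noisy_session(sig, grid, n_runs = 3, noise_sd = 1)
    crossval_effect_size(ses, parcel, contrast)
  })
  expect_lt(abs(mean(sig_es) - beta), 2 * sd(sig_es) / sqrt(length(sig_es)))
})

test_that("voxel counts threshold at the one-sided critical t and nest in p", {
  grid <- vol_grid(c(4, 1, 1), diag(c(2, 2, 2, 1)))
  parcel <- rep(TRUE, 4)
  expect_equal(voxel_count(map_on(rep(0, 4), grid, dof = 100), parcel), 0)
  m <- map_on(c(1, 2, 3.5, 4), grid, dof = 100)
  expect_equal(voxel_count(m, parcel, 0.001), 2)
  # nested thresholds: count nonincreasing as p decreases
  g2 <- vol_grid(c(10, 10, 5), diag(c(2, 2, 2, 1)))
  set.seed(23)
  m2 <- map_on(rnorm(500, 1), g2, dof = 50)
  ps <- c(0.2, 0.05, 0.01, 0.001, 1e-5)
  counts <- vapply(ps, function(p) voxel_count(m2, rep(TRUE, 500), p), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("split-half stability marker aggregates z by hemisphere", {
  grid <- sym_grid(c(8, 6, 6)); n <- n_sites(grid)
  hl <- hemi_labels(grid)
  parcels <- parcel_set(grid, c(
    lapply(1:3, function(i) {
      m <- rep(FALSE, n); m[which(hl == "L")[(20 * i - 19):(20 * i)]] <- TRUE
      list(name = paste0("P", i), hemi = "L", mask = m)
    }),
    lapply(1:3, function(i) {
      m <- rep(FALSE, n); m[which(hl == "R")[(20 * i - 19):(20 * i)]] <- TRUE
      list(name = paste0("P", i), hemi = "R", mask = m)
    })))
  set.seed(24)
  ses <- noisy_session(rnorm(n, 0, 2), grid, n_runs = 4, noise_sd = 1)
  sm <- spatial_correlation_marker(ses, parcels, contrast)
  hemi <- vapply(parcels$parcels, `[[`, "", "hemi")
  expect_equal(sm$hemi_z[["L"]], mean(sm$parcel_z[hemi == "L"]))
  expect_equal(sm$hemi_z[["R"]], mean(sm$parcel_z[hemi == "R"]))
  # identical halves sit at the clamp value
  ses_id <- session_from_values(matrix(rnorm(n * 2), n)[, c(1, 1)],
                                matrix(0, n, 2), grid)
  sm_id <- spatial_correlation_marker(ses_id, parcels, contrast)
  expect_true(all(sm_id$parcel_z == atanh(1 - 1e-7)))
  # independent-noise halves: cohort mean |z| stays small
  set.seed(25)
  zs <- replicate(50, {
    s <- noisy_session(rep(0, n), grid, n_runs = 2, noise_sd = 1)
    mean(spatial_correlation_marker(s, parcels, contrast)$parcel_z)
  })
  expect_lt(abs(mean(zs)), 0.1)
})

test_that("lateralization index follows (LH-RH)/(LH+RH)", {
  expect_equal(lateralization_index(100, 50), 1 / 3)
  expect_equal(lateralization_index(7, 0), 1)
  expect_equal(lateralization_index(0, 7), -1)
  expect_warning(li <- lateralization_index(0, 0), "set to 0")
  expect_equal(li, 0)
})

test_that("marker table scales linearly and summarizes with type-7 quantiles", {
  grid <- sym_grid(c(8, 6, 6)); n <- n_sites(grid)
  hl <- hemi_labels(grid)
  mk_parcel <- function(h, i) {
    m <- rep(FALSE, n); m[which(hl == h)[(30 * i - 29):(30 * i)]] <- TRUE
    list(name = paste0("P", i), hemi = h, mask = m)
  }
  parcels <- parcel_set(grid, list(mk_parcel("L", 1), mk_parcel("L", 2),
                                   mk_parcel("R", 1), mk_parcel("R", 2)))
  set.seed(26)
  sig <- abs(rnorm(n))
  cohort <- lapply(1:6, function(i) {
    noisy_session(sig, grid, n_runs = 3, noise_sd = 0.5,
                  subject = sprintf("s%02d", i))
  })
  mt <- marker_table(cohort, parcels, contrast)
  expect_equal(nrow(mt$table), 6)
  # hemisphere aggregates are unweighted means of the parcel values
  expect_equal(mt$table$LH_effect_size,
               rowMeans(mt$table[, c("L_P1_effect_size", "L_P2_effect_size")]))
  # scaling every map by c scales effect sizes by c, leaves z and counts alone
  cohort2x <- lapply(cohort, function(ses) {
    runs <- lapply(ses$runs, function(r) {
      list(run = r$run, effects = lapply(r$effects, function(m)
        stat_map(2 * m$values, m$domain, subject = m$subject, kind = m$kind)))
    })
    subject_session(ses$subject, ses$session, runs)
  })
  mt2 <- marker_table(cohort2x, parcels, contrast)
  expect_equal(mt2$table$LH_effect_size, 2 * mt$table$LH_effect_size)
  expect_equal(mt2$table$LH_spcorr_z, mt$table$LH_spcorr_z)
  expect_equal(mt2$table$lat_index, mt$table$lat_index)
  # quantile summary matches a direct interpolation oracle
  v <- sort(mt$table$LH_effect_size)
  interp <- function(p) {
    h <- (length(v) - 1) * p
    v[floor(h) + 1] + (h - floor(h)) * (v[pmin(floor(h) + 2, length(v))] -
                                          v[floor(h) + 1])
  }
  got <- mt$summary[mt$summary$marker == "LH_effect_size", "value"]
  expect_equal(got, vapply(c(0, .25, .5, .75, 1), interp, numeric(1)))
})

test_that("single-run subjects contribute voxel counts only", {
  grid <- sym_grid(c(6, 5, 5)); n <- n_sites(grid)
  parcels <- parcel_set(grid, list(
    list(name = "P", hemi = "L", mask = c(rep(TRUE, 40), rep(FALSE, n - 40))),
    list(name = "P", hemi = "R", mask = c(rep(FALSE, n - 40), rep(TRUE, 40)))))
  set.seed(27)
  one_run <- session_from_values(matrix(rnorm(n), n), matrix(0, n), grid,
                                 subject = "solo")
  one_run$tmap <- map_on(rnorm(n, 2), grid, dof = 90, subject = "solo")
  multi <- noisy_session(rnorm(n), grid, n_runs = 2, subject = "full")
  mt <- marker_table(list(multi, one_run), parcels, contrast)
  solo <- mt$table[mt$table$subject == "solo", ]
  expect_true(is.na(solo$LH_effect_size))
  expect_true(is.na(solo$LH_spcorr_z))
  expect_false(is.na(solo$LH_voxel_count))
})
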