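contrast <- c("language", "control")

test_that("split halves average odd- and even-numbered run contrasts", {
  grid <- sym_grid(c(3, 3, 3)); n <- n_sites(grid)
  set.seed(1)
  lang <- matrix(rnorm(n * 4), n, 4); ctrl <- matrix(rnorm(n * 4), n, 4)
  ses <- session_from_values(lang, ctrl, grid)
  halves <- split_half_maps(ses, contrast)
  cm <- lang - ctrl
  expect_equal(halves$odd$values, rowMeans(cm[, c(1, 3)]))
  expect_equal(halves$even$values, rowMeans(cm[, c(2, 4)]))
  # two identical runs give identical halves
  ses2 <- session_from_values(lang[, c(1, 1)], ctrl[, c(1, 1)], grid)
  h2 <- split_half_maps(ses2, contrast)
  expect_identical(h2$odd$values, h2$even$values)
  # a single run cannot be split; qc_session flags it for review
  ses1 <- session_from_values(lang[, 1, drop = FALSE], ctrl[, 1, drop = FALSE], grid)
  expect_error(split_half_maps(ses1, contrast), "single-run")
  parcels <- parcel_set(grid, list(list(name = "P", hemi = "L",
                                        mask = rep(TRUE, n))))
  expect_identical(qc_session(ses1, parcels, contrast)$status, "needs_review")
})

test_that("parcelwise correlation matches a two-pass oracle and clamps z", {
  grid <- sym_grid(c(5, 4, 4)); n <- n_sites(grid)
  set.seed(2)
  a <- map_on(rnorm(n), grid); b <- map_on(rnorm(n) + 0.4 * a$values, grid)
  masks <- list(seq_len(30), 31:75, 50:80)  # <= 100 voxels, overlapping
  parcels <- parcel_set(grid, lapply(seq_along(masks), function(i) {
    m <- rep(FALSE, n); m[masks[[i]]] <- TRUE
    list(name = paste0("P", i), hemi = if (i < 3) "L" else "R", mask = m)
  }))
  rec <- parcelwise_spatial_correlation(a, b, parcels)
  for (i in seq_along(masks)) {
    expect_equal(rec$parcel_r[[i]],
                 oracle_cor(a$values[masks[[i]]], b$values[masks[[i]]]),
                 tolerance = 1e-12)
  }
  expect_equal(rec$mean_r, mean(rec$parcel_r))
  expect_equal(rec$parcel_z, atanh(pmin(pmax(rec$parcel_r, -(1 - 1e-7)),
                                        1 - 1e-7)))
  # self-correlation: every r = 1, z at the clamp value, status kept
  self <- parcelwise_spatial_correlation(a, a, parcels)
  expect_equal(unname(self$parcel_r), rep(1, 3))
  expect_equal(unname(self$parcel_z), rep(atanh(1 - 1e-7), 3))
  expect_identical(self$status, "kept")
  # anti-correlation: every r = -1 and the session is excluded
  anti <- parcelwise_spatial_correlation(a, map_on(-a$values, grid), parcels)
  expect_equal(unname(anti$parcel_r), rep(-1, 3))
  expect_identical(anti$status, "excluded_negative")
})

test_that("correlation is invariant to affine rescaling and handles degenerate parcels", {
  grid <- sym_grid(c(5, 5, 4)); n <- n_sites(grid)
  set.seed(3)
  a <- map_on(rnorm(n), grid); b <- map_on(rnorm(n), grid)
  parcels <- parcel_set(grid, list(list(name = "P", hemi = "L",
                                        mask = rep(TRUE, n))))
  r1 <- parcelwise_spatial_correlation(a, b, parcels)$mean_r
  r2 <- parcelwise_spatial_correlation(a, map_on(2 * b$values + 3, grid),
                                       parcels)$mean_r
  expect_equal(r1, r2, tolerance = 1e-12)
  # constant half in one parcel: omitted with a warning, mean over the rest
  two <- parcel_set(grid, list(
    list(name = "ok", hemi = "L", mask = c(rep(TRUE, 50), rep(FALSE, n - 50))),
    list(name = "flat", hemi = "R", mask = c(rep(FALSE, 50), rep(TRUE, n - 50)))))
  aflat <- a$values; aflat[51:n] <- 7
  expect_warning(rec <- parcelwise_spatial_correlation(map_on(aflat, grid), b, two),
                 "omitted")
  expect_true(is.na(rec$parcel_r[["R_flat"]]))
  expect_equal(rec$mean_r, rec$parcel_r[["L_ok"]])
})

test_that("independent-noise halves correlate near zero in a large parcel", {
  grid <- vol_grid(c(10, 10, 10), diag(c(2, 2, 2, 1)))
  parcels <- parcel_set(grid, list(list(name = "P", hemi = "R",
                                        mask = rep(TRUE, 1000))))
  set.seed(4)
  rs <- replicate(20, {
    parcelwise_spatial_correlation(map_on(rnorm(1000), grid),
                                   map_on(rnorm(1000), grid),
                                   parcels)$mean_r
  })
  expect_lt(max(abs(rs)), 0.1)
})

test_that("mean split-half z decreases as run noise grows", {
  grid <- sym_grid(c(8, 8, 6)); n <- n_sites(grid)
  xyz <- voxel_world(grid)
  signal <- 2 * exp(-((xyz[, 1] + 4)^2 + xyz[, 2]^2 + xyz[, 3]^2) / (2 * 36))
  parcels <- parcel_set(grid, list(list(name = "P", hemi = "L",
                                        mask = rep(TRUE, n))))
  set.seed(5)
  mean_z <- vapply(c(0.25, 0.5, 1, 2, 4), function(sd) {
    mean(replicate(30, {
      ses <- noisy_session(signal, grid, n_runs = 2, noise_sd = sd)
      qc_session(ses, parcels, contrast)$mean_z
    }))
  }, numeric(1))
  expect_true(all(diff(mean_z) < 0))
})

test_that("session selection keeps the best non-negative session per subject", {
  mk <- function(sub, ses, r, status = if (is.na(r)) "needs_review"
                 else if (r < 0) "excluded_negative" else "kept") {
    structure(list(subject = sub, session = ses, parcel_r = r, parcel_z = r,
                   mean_r = r, mean_z = r, subset = "all",
                   scheme = "odd_even", status = status),
              class = "qc_record")
  }
  out <- select_sessions(list(
    mk("s1", "a", 0.3), mk("s1", "b", 0.7),
    mk("s2", "a", -0.05),
    mk("s3", "a", 0.5), mk("s3", "b", 0.5),
    mk("s4", "a", NA)))
  expect_identical(out$chosen$session[out$chosen$subject == "s1"], "b")
  expect_false("s2" %in% out$chosen$subject)       # only session negative
  expect_identical(out$excluded$subject, "s2")
  expect_identical(out$chosen$session[out$chosen$subject == "s3"], "a")  # tie
  expect_identical(out$flagged$subject, "s4")      # single-run passthrough
})

test_that("QC CSV export has one row per session with parcel columns", {
  grid <- sym_grid(c(4, 4, 4)); n <- n_sites(grid)
  set.seed(6)
  parcels <- parcel_set(grid, list(
    list(name = "A", hemi = "L", mask = c(rep(TRUE, 32), rep(FALSE, 32))),
    list(name = "A", hemi = "R", mask = c(rep(FALSE, 32), rep(TRUE, 32)))))
  recs <- lapply(1:3, function(i) {
    ses <- noisy_session(rnorm(n), grid, subject = paste0("s", i))
    qc_session(ses, parcels, contrast)
  })
  f <- tempfile(fileext = ".csv")
  write_qc_csv(recs, f)
  tab <- read.csv(f, check.names = FALSE)
  expect_equal(nrow(tab), 3)
  expect_true(all(c("subject", "session", "L_A", "R_A", "mean_r", "mean_z",
                    "status") %in% names(tab)))
})
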