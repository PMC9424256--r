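#' Probabilistic atlas construction
#'
#' Each subject's statistical map is binarized by a [selection_rule()] and
#' the binary maps are averaged voxelwise: the atlas value at a voxel is the
#' proportion of subjects whose selected set contains that voxel.
#'
#' @name atlas_build
NULL

# round-half-up, used for the per-subject selected-voxel count k
round_half_up <- function(x) floor(x + 0.5)

#' Binarize a map by selecting the top fraction of mask voxels
#'
#' Selects `k = round-half-up(fraction * |mask|)` voxels with the largest
#' values inside the mask, pooling both hemispheres. Ties at the k-th order
#' statistic are broken by ascending linear voxel index so exactly `k`
#' voxels are always selected.
#'
#' @param map a `stat_map`.
#' @param mask a `binary_map` (the in-brain analysis mask); must contain no
#'   missing map values.
#' @param fraction selection fraction in (0, 1], default 0.10.
#' @return A `binary_map` carrying the top-fraction [selection_rule()].
#' @export
top_fraction_binarize <- function(map, mask, fraction = 0.10) {
  stop_if_incompatible(map$domain, mask$domain, "map and mask")
  stopifnot(fraction > 0, fraction <= 1)
  idx <- which(mask$membership)
  m <- length(idx)
  if (m == 0L) stop("mask is empty", call. = FALSE)
  v <- map$values[idx]
  if (any(!is.finite(v))) {
    stop("missing values inside the analysis mask; the mask must exclude them",
         call. = FALSE)
  }
  k <- round_half_up(fraction * m)
  if (k < 1) stop(sprintf("fraction %g of %d mask voxels selects 0 voxels",
                          fraction, m), call. = FALSE)
  # order() is stable, so equal values keep ascending-index order
  sel <- idx[order(v, decreasing = TRUE)[seq_len(k)]]
  mem <- rep(FALSE, n_sites(map$domain))
  mem[sel] <- TRUE
  binary_map(mem, map$domain,
             rule = selection_rule("top_fraction", fraction = fraction),
             subject = map$subject)
}

#' One-sided critical t-value for an uncorrected p threshold
#' @param p upper-tail p-value threshold.
#' @param dof degrees of freedom.
#' @export
t_critical <- function(p, dof) stats::qt(p, df = dof, lower.tail = FALSE)

#' Binarize a t-map at a fixed uncorrected p threshold
#'
#' Selects mask voxels whose t-value exceeds the one-sided positive-tail
#' Student-t critical value at `p` with the map's degrees of freedom. Unlike
#' top-fraction selection, an empty result is allowed. Missing values are
#' never selected.
#'
#' @param map a `stat_map` of kind `"t"` with `dof` set.
#' @param mask a `binary_map`.
#' @param p uncorrected one-sided p threshold in (0, 1).
#' @export
threshold_binarize <- function(map, mask, p) {
  stop_if_incompatible(map$domain, mask$domain, "map and mask")
  if (is.null(map$dof)) stop("p-based thresholding requires the map's dof", call. = FALSE)
  stopifnot(p > 0, p < 1)
  tc <- t_critical(p, map$dof)
  mem <- mask$membership & !is.na(map$values) & map$values > tc
  binary_map(mem, map$domain, rule = selection_rule("fixed_p", p = p),
             subject = map$subject)
}

#' Aggregate per-subject binary maps into a probabilistic atlas
#'
#' The atlas value at each voxel is the number of subjects whose binary map
#' selects it, divided by the number of subjects; a per-subject laterality
#' table records the fraction of each subject's selected voxels falling in
#' the left hemisphere.
#'
#' @param members list of `binary_map`s with identical domains and rules.
#' @return A `prob_atlas`: list with `domain`, `values` (in \[0,1\]),
#'   `n_subjects`, `rule`, `laterality` (data.frame subject, lh_fraction,
#'   n_selected).
#' @export
build_atlas <- function(members) {
  stopifnot(length(members) >= 1L)
  dom <- members[[1]]$domain
  rule <- members[[1]]$rule
  hl <- hemi_labels(dom)
  counts <- numeric(n_sites(dom))
  lat <- data.frame(subject = character(0), lh_fraction = numeric(0),
                    n_selected = integer(0))
  for (m in members) {
    stop_if_incompatible(dom, m$domain)
    if (!same_rule(rule, m$rule)) stop("mixed selection rules in atlas members", call. = FALSE)
    counts <- counts + m$membership
    ns <- sum(m$membership)
    lat <- rbind(lat, data.frame(
      subject = m$subject,
      lh_fraction = if (ns > 0) sum(hl[m$membership] == "L") / ns else NA_real_,
      n_selected = ns))
  }
  structure(list(domain = dom, values = counts / length(members),
                 n_subjects = length(members), rule = rule,
                 laterality = lat),
            class = "prob_atlas")
}

#' @export
print.prob_atlas <- function(x, ...) {
  cat(sprintf("<prob_atlas> n=%d subjects, %d sites, max overlap %.3f\n",
              x$n_subjects, length(x$values), max(x$values)))
  invisible(x)
}

#' Summarize a probabilistic atlas
#'
#' Per-hemisphere minimum and maximum overlap values, the cohort mean and
#' median of the per-subject left-hemisphere selection fraction, and a
#' histogram of the overlap values.
#'
#' @param atlas a `prob_atlas`.
#' @param mask optional `binary_map`; summaries restricted to it.
#' @param breaks histogram breaks passed to [hist()].
#' @export
atlas_summary <- function(atlas, mask = NULL, breaks = seq(0, 1, 0.05)) {
  use <- if (is.null(mask)) rep(TRUE, length(atlas$values)) else mask$membership
  hl <- hemi_labels(atlas$domain)
  rng <- function(h) {
    v <- atlas$values[use & hl == h]
    if (length(v) == 0L) c(min = NA_real_, max = NA_real_)
    else c(min = min(v), max = max(v))
  }
  lf <- atlas$laterality$lh_fraction
  list(lh_range = rng("L"), rh_range = rng("R"),
       lh_fraction_mean = mean(lf, na.rm = TRUE),
       lh_fraction_median = stats::median(lf, na.rm = TRUE),
       mask_mean = mean(atlas$values[use]),
       n_subjects = atlas$n_subjects,
       histogram = graphics::hist(atlas$values[use], breaks = breaks,
                                  plot = FALSE))
}

#' Atlas stability as a function of sample size
#'
#' For each sample size n, draws `n_boot` subject subsamples without
#' replacement, builds the subsample atlas, and Pearson-correlates it with
#' the full-cohort atlas over the mask. The resulting curve shows the sample
#' size at which the atlas stabilizes.
#'
#' @param maps list of subject `stat_map`s.
#' @param mask analysis `binary_map`.
#' @param sizes integer vector of subsample sizes (each <= cohort size).
#' @param n_boot subsamples per size.
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @param fraction top-fraction used to binarize each map.
#' @return data.frame with columns n, mean_r, sd_r.
#' @export
stability_curve <- function(maps, mask, sizes, n_boot = 20, seed,
                            fraction = 0.10) {
  stopifnot(n_boot >= 1L, all(sizes >= 1L), all(sizes <= length(maps)))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  members <- lapply(maps, top_fraction_binarize, mask = mask, fraction = fraction)
  full <- build_atlas(members)
  fv <- full$values[mask$membership]
  if (stats::sd(fv) == 0) stop("full-cohort atlas is constant over the mask; stability undefined", call. = FALSE)
  set.seed(seed)
  out <- lapply(sizes, function(n) {
    rs <- vapply(seq_len(n_boot), function(b) {
      sub <- sample.int(length(members), n)
      av <- build_atlas(members[sub])$values[mask$membership]
      if (stats::sd(av) == 0) return(NA_real_)
      stats::cor(av, fv)
    }, numeric(1))
    data.frame(n = n, mean_r = mean(rs, na.rm = TRUE),
               sd_r = stats::sd(rs))
  })
  do.call(rbind, out)
}
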