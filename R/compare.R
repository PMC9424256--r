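#' Atlas and map comparison utilities
#' @name compare
NULL

mask_indices <- function(domain, mask = NULL) {
  if (is.null(mask)) return(seq_len(n_sites(domain)))
  m <- if (inherits(mask, "binary_map")) {
    stop_if_incompatible(domain, mask$domain, "object and mask")
    mask$membership
  } else as.logical(mask)
  which(m)
}

#' Pearson correlation between two probabilistic atlases
#'
#' @param a,b `prob_atlas` objects on the same domain.
#' @param mask optional mask restricting the correlation.
#' @export
atlas_correlation <- function(a, b, mask = NULL) {
  stop_if_incompatible(a$domain, b$domain, "atlases")
  idx <- mask_indices(a$domain, mask)
  stats::cor(a$values[idx], b$values[idx])
}

#' Voxelwise correlation between a t-map and its contrast map
#'
#' @param t,c grid-compatible `stat_map`s for the same subject.
#' @param mask optional mask; only voxels finite in both maps are used.
#' @export
map_pair_correlation <- function(t, c, mask = NULL) {
  stop_if_incompatible(t$domain, c$domain, "t-map and contrast map")
  idx <- mask_indices(t$domain, mask)
  ok <- is.finite(t$values[idx]) & is.finite(c$values[idx])
  stats::cor(t$values[idx][ok], c$values[idx][ok])
}

#' Cohort aggregate of per-subject t-vs-contrast correlations
#'
#' @param tmaps,cmaps parallel lists of per-subject maps.
#' @param mask optional mask.
#' @return list with `r` (per subject), `mean`, `sd`.
#' @export
cohort_map_pair_correlation <- function(tmaps, cmaps, mask = NULL) {
  stopifnot(length(tmaps) == length(cmaps), length(tmaps) >= 1L)
  r <- mapply(map_pair_correlation, tmaps, cmaps,
              MoreArgs = list(mask = mask))
  list(r = r, mean = mean(r), sd = stats::sd(r))
}

#' Random-effects group t-map from per-subject contrast maps
#'
#' Voxelwise one-sample t-test across subjects: t = mean / (sd / sqrt(n)),
#' dof = n - 1. Voxels with zero across-subject variance get a missing
#' value (their count is reported via `message()`) rather than an infinite
#' t, so downstream correlations stay well defined.
#'
#' @param maps list of >= 2 grid-compatible contrast `stat_map`s.
#' @return A `stat_map` of kind `"t"` with dof n - 1.
#' @export
group_t_map <- function(maps) {
  stopifnot(length(maps) >= 2L)
  dom <- maps[[1]]$domain
  for (m in maps) stop_if_incompatible(dom, m$domain)
  vm <- vapply(maps, `[[`, numeric(n_sites(dom)), "values")
  dim(vm) <- c(n_sites(dom), length(maps))
  n <- ncol(vm)
  mu <- rowMeans(vm)
  sdv <- sqrt(rowSums((vm - mu)^2) / (n - 1))
  zero <- sdv == 0
  t <- ifelse(zero, NA_real_, mu / (sdv / sqrt(n)))
  if (any(zero)) message(sprintf("group_t_map: %d zero-variance voxels set to NA", sum(zero)))
  stat_map(t, dom, subject = "group", kind = "t", dof = n - 1)
}

#' Group-level ROI from the highest-overlap atlas voxels
#'
#' The `n_top` voxels with the largest atlas values (within the parcel mask
#' when given), ties broken by ascending linear voxel index.
#'
#' @param atlas a `prob_atlas`.
#' @param within optional parcel mask restricting the candidates.
#' @param n_top number of voxels to select.
#' @export
atlas_group_roi <- function(atlas, within = NULL, n_top) {
  idx <- mask_indices(atlas$domain, within)
  if (n_top < 1L || n_top > length(idx)) {
    stop(sprintf("n_top = %d but %d candidate voxels", n_top, length(idx)),
         call. = FALSE)
  }
  sel <- idx[order(atlas$values[idx], decreasing = TRUE)[seq_len(n_top)]]
  mem <- rep(FALSE, n_sites(atlas$domain))
  mem[sel] <- TRUE
  binary_map(mem, atlas$domain, subject = "group_roi")
}
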