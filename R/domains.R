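#' Spatial domains: voxel grids and surface vertex sets
#'
#' A `vol_grid` describes a regular 3-D voxel grid embedded in world (mm)
#' space through a 4x4 affine that maps 0-based voxel indices to world
#' coordinates. A `surf_domain` describes a pair of per-hemisphere vertex
#' vectors (left vertices first, then right); no mesh geometry is carried
#' because none of the supported computations needs it.
#'
#' @param shape integer vector of length 3, voxel counts per axis.
#' @param affine 4x4 numeric matrix, voxel (0-based) to world mm transform.
#'   Must be invertible.
#' @param space free-text label for the template space (e.g. `"MNI-IXI549"`).
#' @return An object of class `vol_grid`.
#' @export
vol_grid <- function(shape, affine, space = "unknown") {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps) {
    stop("grid affine is singular", call. = FALSE)
  }
  structure(list(shape = shape, affine = affine, space = space),
            class = "vol_grid")
}

#' @rdname vol_grid
#' @param nv_left,nv_right vertex counts for the left and right hemisphere.
#' @export
surf_domain <- function(nv_left, nv_right) {
  nv_left <- as.integer(nv_left); nv_right <- as.integer(nv_right)
  stopifnot(nv_left >= 1L, nv_right >= 1L)
  structure(list(nvertices = c(L = nv_left, R = nv_right)),
            class = "surf_domain")
}

#' Number of sites (voxels or vertices) in a domain
#' @param domain a `vol_grid` or `surf_domain`.
#' @export
n_sites <- function(domain) {
  if (inherits(domain, "vol_grid")) return(as.integer(prod(domain$shape)))
  if (inherits(domain, "surf_domain")) return(as.integer(sum(domain$nvertices)))
  stop("not a spatial domain", call. = FALSE)
}

#' Test whether two domains are compatible
#'
#' Two voxel grids are compatible iff their shapes match and their affines
#' agree elementwise within `tol` mm. Two surface domains are compatible iff
#' their per-hemisphere vertex counts match.
#'
#' @param a,b domains.
#' @param tol absolute tolerance on affine entries, in mm.
#' @export
domain_compatible <- function(a, b, tol = 1e-4) {
  if (inherits(a, "vol_grid") && inherits(b, "vol_grid")) {
    return(all(a$shape == b$shape) && all(abs(a$affine - b$affine) <= tol))
  }
  if (inherits(a, "surf_domain") && inherits(b, "surf_domain")) {
    return(all(a$nvertices == b$nvertices))
  }
  FALSE
}

stop_if_incompatible <- function(a, b, what = "maps") {
  if (!domain_compatible(a, b)) {
    da <- if (inherits(a, "vol_grid")) paste(deparse(round(a$affine, 4)), collapse = " ") else "surface"
    db <- if (inherits(b, "vol_grid")) paste(deparse(round(b$affine, 4)), collapse = " ") else "surface"
    stop(sprintf("grid mismatch between %s:\n  first:  %s\n  second: %s",
                 what, da, db), call. = FALSE)
  }
  invisible(TRUE)
}

# 0-based (i,j,k) index triples for linear voxel indices (R column-major order)
voxel_ijk <- function(grid, linear = seq_len(prod(grid$shape))) {
  s <- grid$shape
  l0 <- linear - 1L
  i <- l0 %% s[1]
  j <- (l0 %/% s[1]) %% s[2]
  k <- l0 %/% (s[1] * s[2])
  cbind(i, j, k)
}

#' World-space coordinates of voxel centres
#'
#' @param grid a `vol_grid`.
#' @param linear linear voxel indices (1-based, column-major); defaults to all.
#' @return numeric matrix with columns x, y, z in mm.
#' @export
voxel_world <- function(grid, linear = seq_len(prod(grid$shape))) {
  ijk <- voxel_ijk(grid, linear)
  xyz <- cbind(ijk, 1) %*% t(grid$affine[1:3, , drop = FALSE])
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

# nearest linear voxel index for world coordinates; NA when outside the grid
world_to_voxel <- function(grid, xyz) {
  inv <- solve(grid$affine)
  ijk <- round(cbind(xyz, 1) %*% t(inv[1:3, , drop = FALSE]))
  s <- grid$shape
  ok <- ijk[, 1] >= 0 & ijk[, 1] < s[1] &
        ijk[, 2] >= 0 & ijk[, 2] < s[2] &
        ijk[, 3] >= 0 & ijk[, 3] < s[3]
  lin <- ijk[, 1] + s[1] * (ijk[, 2] + s[2] * ijk[, 3]) + 1
  lin[!ok] <- NA_integer_
  as.integer(lin)
}

#' Hemisphere labels for every site of a domain
#'
#' Volume grids are split in world coordinates: a voxel is left iff its centre
#' has world x < 0, right iff x > 0, and midline iff |x| < 1e-6 (midline
#' voxels belong to neither hemisphere summary). Surface domains label the
#' first block of vertices "L" and the rest "R".
#'
#' @param domain a `vol_grid` or `surf_domain`.
#' @return character vector over sites with values "L", "R", "M".
#' @export
hemi_labels <- function(domain) {
  if (inherits(domain, "surf_domain")) {
    return(rep(c("L", "R"), domain$nvertices))
  }
  x <- voxel_world(domain)[, "x"]
  out <- rep("M", length(x))
  out[x < -1e-6] <- "L"
  out[x > 1e-6] <- "R"
  out
}

#' Hemisphere partition masks
#'
#' @param grid a `vol_grid` (or `surf_domain`).
#' @return list of three [binary_map]s `left`, `right`, `midline` that
#'   partition the domain.
#' @export
hemisphere_masks <- function(grid) {
  h <- hemi_labels(grid)
  list(left    = binary_map(h == "L", grid, rule = NULL, subject = "hemi_L"),
       right   = binary_map(h == "R", grid, rule = NULL, subject = "hemi_R"),
       midline = binary_map(h == "M", grid, rule = NULL, subject = "hemi_M"))
}

#' The 2 mm MNI bounding-box grid used by common volume pipelines
#'
#' Bounding box (-90, -126, -72) to (90, 90, 108) mm at 2 mm isotropic
#' resolution: a 91 x 109 x 91 grid.
#' @param spacing voxel size in mm (2 for the standard box; 4 halves each axis).
#' @export
mni_grid <- function(spacing = 2) {
  lo <- c(-90, -126, -72); hi <- c(90, 90, 108)
  shape <- (hi - lo) / spacing + 1
  if (any(shape != round(shape))) stop("spacing does not tile the MNI box", call. = FALSE)
  aff <- diag(c(spacing, spacing, spacing, 1))
  aff[1:3, 4] <- lo
  vol_grid(round(shape), aff, space = sprintf("MNI-boundingbox-%gmm", spacing))
}

#' @export
print.vol_grid <- function(x, ...) {
  cat(sprintf("<vol_grid> %s  shape %s  %d voxels\n", x$space,
              paste(x$shape, collapse = "x"), prod(x$shape)))
  invisible(x)
}

#' @export
print.surf_domain <- function(x, ...) {
  cat(sprintf("<surf_domain> L=%d R=%d vertices\n",
              x$nvertices["L"], x$nvertices["R"]))
  invisible(x)
}
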