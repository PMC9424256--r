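#' Statistical maps and binary membership maps
#'
#' A `stat_map` holds one scalar per voxel/vertex of a domain together with
#' the subject it came from, the kind of statistic (`"t"`, `"contrast"` or
#' `"condition-effect"`), the degrees of freedom when the values are
#' t-statistics (required for p-based thresholding), and an optional fold
#' label (e.g. `"odd"`, `"run2-leftout"`).
#'
#' @param values numeric vector, one value per site; `NA` allowed.
#' @param domain a [vol_grid()] or [surf_domain()].
#' @param subject subject identifier.
#' @param kind one of `"t"`, `"contrast"`, `"condition-effect"`.
#' @param dof degrees of freedom (positive), required for `kind = "t"` maps
#'   that will be thresholded by p-value.
#' @param fold optional fold label.
#' @return A `stat_map`.
#' @export
stat_map <- function(values, domain, subject = NA_character_,
                     kind = c("t", "contrast", "condition-effect"),
                     dof = NULL, fold = NULL) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) != n_sites(domain)) {
    stop(sprintf("values length %d does not match domain size %d",
                 length(values), n_sites(domain)), call. = FALSE)
  }
  if (!is.null(dof)) stopifnot(is.numeric(dof), dof > 0)
  structure(list(subject = subject, domain = domain, values = values,
                 kind = kind, dof = dof, fold = fold),
            class = "stat_map")
}

#' @rdname stat_map
#' @param membership logical vector over sites.
#' @param rule the [selection_rule()] that produced the map (may be `NULL`
#'   for plain masks).
#' @export
binary_map <- function(membership, domain, rule = NULL,
                       subject = NA_character_) {
  membership <- as.logical(membership)
  membership[is.na(membership)] <- FALSE
  if (length(membership) != n_sites(domain)) {
    stop("membership length does not match domain size", call. = FALSE)
  }
  structure(list(subject = subject, domain = domain,
                 membership = membership, rule = rule),
            class = "binary_map")
}

#' Voxel/vertex selection rule
#'
#' Either `top_fraction` (select the fraction of mask sites with the largest
#' values, pooled across both hemispheres) or `fixed_p` (select sites whose
#' one-sided positive-tail p-value beats a threshold).
#'
#' @param mode `"top_fraction"` or `"fixed_p"`.
#' @param fraction selection fraction in (0, 1], default 0.10; only for
#'   `top_fraction`.
#' @param p p-value threshold in (0, 1); only for `fixed_p`.
#' @export
selection_rule <- function(mode = c("top_fraction", "fixed_p"),
                           fraction = NULL, p = NULL) {
  mode <- match.arg(mode)
  if (mode == "top_fraction") {
    if (!is.null(p)) stop("p is only valid for fixed_p rules", call. = FALSE)
    if (is.null(fraction)) fraction <- 0.10
    stopifnot(fraction > 0, fraction <= 1)
  } else {
    if (!is.null(fraction)) stop("fraction is only valid for top_fraction rules", call. = FALSE)
    if (is.null(p)) stop("fixed_p rule requires p", call. = FALSE)
    stopifnot(p > 0, p < 1)
  }
  structure(list(mode = mode, fraction = fraction, p = p,
                 tail = "one_sided_positive"),
            class = "selection_rule")
}

same_rule <- function(a, b) {
  if (is.null(a) || is.null(b)) return(is.null(a) && is.null(b))
  identical(a$mode, b$mode) && identical(a$fraction, b$fraction) &&
    identical(a$p, b$p)
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> subject=%s kind=%s%s  %d sites, %d finite\n",
              x$subject, x$kind,
              if (!is.null(x$dof)) sprintf(" dof=%g", x$dof) else "",
              length(x$values), sum(is.finite(x$values))))
  invisible(x)
}

#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf("<binary_map> subject=%s  %d of %d sites selected\n",
              x$subject, sum(x$membership), length(x$membership)))
  invisible(x)
}

grid_from_nifti <- function(img, space = "from-header") {
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  vol_grid(dim(img)[1:3], unclass(aff)[1:4, 1:4], space = space)
}

#' Read a statistical map from a NIfTI file
#'
#' Reads a NIfTI-1/2 volume (3-D) as a `stat_map` on the grid described by
#' its header (sform preferred, qform fallback). If `expect` is supplied the
#' file's grid is checked for compatibility and a grid-mismatch error naming
#' both affines is raised on disagreement.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param expect optional `vol_grid` the file must match.
#' @inheritParams stat_map
#' @return A `stat_map`.
#' @export
read_stat_map <- function(path, expect = NULL, subject = NA_character_,
                          kind = "t", dof = NULL, fold = NULL) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("cannot read NIfTI '%s': %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  d <- dim(img)
  if (length(d) > 3 && any(d[-(1:3)] != 1)) {
    stop(sprintf("'%s' is not a 3-D volume (dims %s)", path,
                 paste(d, collapse = "x")), call. = FALSE)
  }
  grid <- grid_from_nifti(img)
  if (!is.null(expect)) stop_if_incompatible(grid, expect,
                                             sprintf("'%s' and expected grid", path))
  stat_map(as.vector(img), grid, subject = subject, kind = kind,
           dof = dof, fold = fold)
}

#' Write values on a grid to a NIfTI file
#'
#' @param values numeric vector (length = grid voxel count) or a `stat_map`,
#'   `binary_map` or `prob_atlas` (their values are used).
#' @param grid the `vol_grid`; taken from the object when omitted.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_nifti_map <- function(values, grid = NULL, path) {
  if (inherits(values, "stat_map")) { grid <- values$domain; values <- values$values }
  else if (inherits(values, "binary_map")) { grid <- values$domain; values <- as.numeric(values$membership) }
  else if (inherits(values, "prob_atlas")) { grid <- values$domain; values <- values$values }
  if (!inherits(grid, "vol_grid")) stop("a vol_grid is required to write a volume", call. = FALSE)
  arr <- array(as.numeric(values), dim = grid$shape)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(grid$affine, code = 2L)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a surface statistical map from two per-hemisphere overlay files
#'
#' Each overlay is a 1-D NIfTI whose voxels are vertex values; the two
#' hemispheres are concatenated (left first) into a single value vector so
#' that pooled operations (top-fraction selection, overlap aggregation)
#' treat both hemispheres together.
#'
#' @param path_left,path_right per-hemisphere overlay files.
#' @inheritParams stat_map
#' @export
read_surf_stat_map <- function(path_left, path_right,
                               subject = NA_character_, kind = "t",
                               dof = NULL, fold = NULL) {
  vl <- as.vector(RNifti::readNifti(path_left))
  vr <- as.vector(RNifti::readNifti(path_right))
  stat_map(c(vl, vr), surf_domain(length(vl), length(vr)),
           subject = subject, kind = kind, dof = dof, fold = fold)
}

#' In-brain analysis mask from a collection of maps
#'
#' The `auto` policy intersects the maps: a site is in the mask iff its value
#' is finite and nonzero in every map. This yields a reproducible stand-in
#' for "the brain" when no explicit template mask is provided (zero-padded
#' margins and missing voxels drop out). The `explicit` policy validates a
#' caller-supplied mask against the maps' common grid and returns it.
#'
#' @param maps list of grid-compatible `stat_map`s.
#' @param policy `"auto"` or `"explicit"`.
#' @param mask a `binary_map` (or logical vector), required for `explicit`.
#' @return A `binary_map`.
#' @export
analysis_mask <- function(maps, policy = c("auto", "explicit"), mask = NULL) {
  policy <- match.arg(policy)
  stopifnot(length(maps) >= 1L)
  dom <- maps[[1]]$domain
  for (m in maps) stop_if_incompatible(dom, m$domain)
  if (policy == "explicit") {
    if (is.null(mask)) stop("explicit policy requires a mask", call. = FALSE)
    mem <- if (inherits(mask, "binary_map")) {
      stop_if_incompatible(dom, mask$domain, "mask and maps")
      mask$membership
    } else as.logical(mask)
    if (length(mem) != n_sites(dom)) stop("mask length does not match maps", call. = FALSE)
  } else {
    mem <- rep(TRUE, n_sites(dom))
    for (m in maps) mem <- mem & is.finite(m$values) & m$values != 0
  }
  if (!any(mem)) stop("analysis mask is empty", call. = FALSE)
  binary_map(mem, dom, subject = "analysis_mask")
}
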