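#' Parcel sets: named, hemisphere-tagged spatial masks
#'
#' Parcels denote the typical locations of functional regions; subject-level
#' fROIs are defined within them and QC correlations are computed within
#' them. Parcels may overlap each other; each must be nonempty and the
#' (hemisphere, name) pairs must be unique.
#'
#' @param domain a [vol_grid()] or [surf_domain()].
#' @param parcels list of entries `list(name=, hemi=, mask=)` with `hemi`
#'   `"L"` or `"R"` and `mask` a logical vector over sites.
#' @param provenance free-text note on where the parcels came from.
#' @export
parcel_set <- function(domain, parcels, provenance = "") {
  stopifnot(length(parcels) >= 1L)
  keys <- character(0)
  for (p in parcels) {
    stopifnot(is.character(p$name), p$hemi %in% c("L", "R"))
    if (length(p$mask) != n_sites(domain)) {
      stop(sprintf("parcel '%s' mask length mismatch", p$name), call. = FALSE)
    }
    if (!any(p$mask)) stop(sprintf("parcel '%s' is empty", p$name), call. = FALSE)
    keys <- c(keys, paste(p$hemi, p$name, sep = "_"))
  }
  if (anyDuplicated(keys)) stop("duplicate (hemisphere, name) parcel keys", call. = FALSE)
  parcels <- lapply(parcels, function(p) {
    m <- as.logical(p$mask); m[is.na(m)] <- FALSE
    list(name = p$name, hemi = p$hemi, mask = m)
  })
  names(parcels) <- keys
  structure(list(domain = domain, parcels = parcels, provenance = provenance),
            class = "parcel_set")
}

#' @export
print.parcel_set <- function(x, ...) {
  sizes <- vapply(x$parcels, function(p) sum(p$mask), integer(1))
  cat(sprintf("<parcel_set> %d parcels (%s)\n", length(x$parcels),
              paste(sprintf("%s:%d", names(x$parcels), sizes), collapse = ", ")))
  invisible(x)
}

#' Canonical language-network parcel names
#'
#' The six left-hemisphere frontal/temporal/parietal regions within which
#' language fROIs are conventionally defined: inferior frontal gyrus (IFG),
#' its orbital part (IFGorb), middle frontal gyrus (MFG), anterior and
#' posterior temporal cortex (AntTemp, PostTemp) and the angular gyrus
#' (AngG). With their right-hemisphere mirrors this gives 12 parcels.
#' @export
language_parcel_names <- function() {
  c("IFG", "IFGorb", "MFG", "AntTemp", "PostTemp", "AngG")
}

#' Read a parcel set from a NIfTI label volume
#'
#' Non-zero integer labels become parcels; `labels` maps label value to
#' parcel name. Hemisphere tags are derived from the world-x sign of each
#' parcel's centre of mass unless given.
#'
#' @param path NIfTI label volume.
#' @param labels optional named character vector: `names()` are label values,
#'   values are parcel names.
#' @param hemi optional named character vector of hemisphere tags per label.
#' @export
read_parcels <- function(path, labels = NULL, hemi = NULL) {
  img <- RNifti::readNifti(path)
  grid <- grid_from_nifti(img)
  v <- as.vector(img)
  lv <- sort(unique(v[is.finite(v) & v != 0]))
  hl <- hemi_labels(grid)
  parcels <- lapply(lv, function(l) {
    mask <- is.finite(v) & v == l
    nm <- if (!is.null(labels) && as.character(l) %in% names(labels))
      labels[[as.character(l)]] else sprintf("parcel%g", l)
    hm <- if (!is.null(hemi) && as.character(l) %in% names(hemi))
      hemi[[as.character(l)]]
    else if (sum(hl[mask] == "L") >= sum(hl[mask] == "R")) "L" else "R"
    list(name = nm, hemi = hm, mask = mask)
  })
  parcel_set(grid, parcels, provenance = path)
}

#' Mirror left-hemisphere parcels onto the right hemisphere
#'
#' For every L-tagged parcel, adds an R-tagged parcel whose members are the
#' nearest-voxel images of the original members under the world-coordinate
#' reflection x -> -x. Mirrored voxels that fall outside the grid are
#' dropped (a count is reported via `message()`).
#'
#' @param parcels a `parcel_set` on a `vol_grid`, containing L-tagged parcels.
#' @return A `parcel_set` with the original parcels plus the mirrored ones.
#' @export
mirror_parcels <- function(parcels) {
  grid <- parcels$domain
  if (!inherits(grid, "vol_grid")) stop("mirroring requires a volume grid", call. = FALSE)
  lefts <- Filter(function(p) p$hemi == "L", parcels$parcels)
  if (length(lefts) == 0L) stop("no L-tagged parcels to mirror", call. = FALSE)
  dropped <- 0L
  mirrored <- lapply(lefts, function(p) {
    xyz <- voxel_world(grid, which(p$mask))
    xyz[, "x"] <- -xyz[, "x"]
    lin <- world_to_voxel(grid, xyz)
    dropped <<- dropped + sum(is.na(lin))
    mask <- rep(FALSE, n_sites(grid))
    mask[lin[!is.na(lin)]] <- TRUE
    list(name = p$name, hemi = "R", mask = mask)
  })
  if (dropped > 0L) message(sprintf("mirror_parcels: %d mirrored voxels fell outside the grid and were dropped", dropped))
  keep <- Filter(function(p) p$hemi != "R", parcels$parcels)
  parcel_set(grid, c(unname(keep), unname(mirrored)),
             provenance = paste0(parcels$provenance, " + x-mirror"))
}

#' Build a parcel set from world-space boxes (testing/simulation helper)
#'
#' @param grid a `vol_grid`.
#' @param boxes data.frame with columns name, hemi, and world-mm bounds
#'   xmin,xmax,ymin,ymax,zmin,zmax.
#' @export
parcels_from_boxes <- function(grid, boxes) {
  xyz <- voxel_world(grid)
  parcels <- lapply(seq_len(nrow(boxes)), function(i) {
    b <- boxes[i, ]
    mask <- xyz[, "x"] >= b$xmin & xyz[, "x"] <= b$xmax &
            xyz[, "y"] >= b$ymin & xyz[, "y"] <= b$ymax &
            xyz[, "z"] >= b$zmin & xyz[, "z"] <= b$zmax
    list(name = b$name, hemi = b$hemi, mask = mask)
  })
  parcel_set(grid, parcels, provenance = "boxes")
}

#' Write a parcel set as a NIfTI label volume plus a label table CSV
#' @param parcels a `parcel_set` on a volume grid.
#' @param path output NIfTI path; the label table is written alongside with
#'   extension `.labels.csv`.
#' @export
write_parcels <- function(parcels, path) {
  grid <- parcels$domain
  v <- numeric(n_sites(grid))
  for (i in seq_along(parcels$parcels)) v[parcels$parcels[[i]]$mask] <- i
  write_nifti_map(v, grid, path)
  tab <- data.frame(label = seq_along(parcels$parcels),
                    name = vapply(parcels$parcels, `[[`, "", "name"),
                    hemi = vapply(parcels$parcels, `[[`, "", "hemi"))
  utils::write.csv(tab, sub("\\.nii(\\.gz)?$", ".labels.csv", path),
                   row.names = FALSE)
  invisible(path)
}
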