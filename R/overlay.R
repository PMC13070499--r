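#' Bundle co-registered binary masks on a common voxel grid
#'
#' Validates that every mask shares the same 3-D grid (and affine, when
#' given) and is binary. Registration to a common template space is assumed
#' to have been done upstream; this container only checks consistency.
#'
#' @param masks named list (by subject id) of 3-D arrays with values in
#'   \{0, 1\}.
#' @param group named character vector of group labels, one per mask.
#' @param affine optional 4x4 voxel-to-world affine shared by all masks.
#' @return A `mask_set` list.
#' @export
mask_set <- function(masks, group, affine = NULL) {
  if (!length(masks)) stop("mask set is empty")
  if (is.null(names(masks))) names(masks) <- sprintf("s%03d", seq_along(masks))
  dims <- dim(masks[[1]])
  if (length(dims) != 3) stop("masks must be 3-D arrays")
  for (id in names(masks)) {
    m <- masks[[id]]
    if (!identical(dim(m), dims))
      stop("mask grid mismatch for subject '", id, "': expected ",
           paste(dims, collapse = "x"), ", got ",
           paste(dim(m), collapse = "x"))
    if (!all(m %in% c(0, 1)))
      stop("non-binary mask for subject '", id, "'")
  }
  group <- group[names(masks)]
  if (anyNA(group)) stop("missing group label for some masks")
  structure(list(masks = masks, group = group, grid = dims, affine = affine),
            class = "mask_set")
}

#' Read binary masks from NIfTI files
#'
#' @param paths named character vector of NIfTI paths (names become subject
#'   ids).
#' @param group named group labels per subject.
#' @param threshold values above this are set to 1 (default 0.5).
#' @return A [mask_set()].
#' @export
read_masks <- function(paths, group, threshold = 0.5) {
  imgs <- lapply(paths, RNifti::readNifti)
  masks <- lapply(imgs, function(im) {
    arr <- array(as.integer(as.array(im) > threshold), dim = dim(im))
    arr
  })
  affine <- RNifti::xform(imgs[[1]])
  mask_set(masks, group, affine = affine)
}

#' Voxelwise tumour overlap map for one group
#'
#' Adds the binary masks of one group voxel by voxel. The total of the
#' resulting counts equals the sum of the individual mask volumes
#' (conservation), and the per-group maximum count is retained for
#' normalisation.
#'
#' @param maskset a [mask_set()].
#' @param group group label to sum over.
#' @return `overlay_map` list: `counts` (integer array), `group_max`,
#'   `n_masks`, `grid`, `affine`.
#' @export
build_overlay <- function(maskset, group) {
  ids <- names(maskset$masks)[maskset$group == group]
  if (!length(ids)) stop("no masks in group '", group, "'")
  counts <- Reduce(`+`, maskset$masks[ids])
  structure(list(counts = counts, group_max = max(counts),
                 n_masks = length(ids), grid = maskset$grid,
                 affine = maskset$affine, group = group),
            class = "overlay_map")
}

#' Normalise an overlay to its own group maximum
#'
#' Divides the counts by the group's maximal overlap so each group's map
#' spans `[0, 1]` with maximum exactly 1 — groups of different sizes are
#' displayed on their own scale, not a shared one.
#'
#' @param map an `overlay_map`.
#' @return numeric array in `[0, 1]`.
#' @export
normalize_overlay <- function(map) {
  if (map$group_max < 1)
    stop("empty overlay (group maximum is 0); nothing to normalise")
  map$counts / map$group_max
}

#' Mirror left and right hemispheres
#'
#' Reflects a mask, overlay or raw array across the midsagittal plane
#' (first voxel axis). The reflection is about the grid centre, so counts
#' are conserved and mirroring twice is the identity. If an affine is
#' present, its midsagittal plane must coincide with the grid centre within
#' half a voxel; otherwise supply `midline` explicitly (in voxel units,
#' must equal the grid centre `(dim1 + 1) / 2` on an unresampled grid).
#'
#' @param x a `mask_set`, `overlay_map`, or 3-D array.
#' @param midline optional explicit midline voxel coordinate on axis 1.
#' @return object of the same type, left-right flipped.
#' @export
mirror_hemispheres <- function(x, midline = NULL) {
  flip <- function(arr) arr[rev(seq_len(dim(arr)[1])), , , drop = FALSE]
  check_mid <- function(d1, affine) {
    centre <- (d1 + 1) / 2
    if (!is.null(midline) && abs(midline - centre) > 0.5)
      stop("reflection is only supported about the grid centre (",
           centre, "); resample the volume or adjust the grid")
    if (is.null(midline) && !is.null(affine)) {
      # world x = 0 plane in voxel coordinates (assumes axis 1 ~ left-right)
      if (abs(affine[1, 1]) > 1e-8) {
        vox_mid <- -affine[1, 4] / affine[1, 1] + 1  # 1-based voxels
        if (abs(vox_mid - centre) > 0.5)
          stop("affine midsagittal plane (voxel ", round(vox_mid, 2),
               ") is not at the grid centre (", centre, "); pass an ",
               "explicit midline")
      }
    }
  }
  if (inherits(x, "mask_set")) {
    check_mid(x$grid[1], x$affine)
    x$masks <- lapply(x$masks, flip)
    x
  } else if (inherits(x, "overlay_map")) {
    check_mid(x$grid[1], x$affine)
    x$counts <- flip(x$counts)
    x
  } else if (is.array(x) && length(dim(x)) == 3) {
    check_mid(dim(x)[1], NULL)
    flip(x)
  } else stop("cannot mirror object of class ", paste(class(x), collapse = "/"))
}

#' Paired overlap maps for declined versus non-declined patients
#'
#' Partitions the mask subjects by their reliable-change classification on
#' one test (or domain), builds an overlay per side, and normalises each to
#' its own maximum. Every mask subject must have a classification for the
#' requested test/domain, and both sides must be non-empty.
#'
#' @param maskset a [mask_set()] (group labels are ignored; the partition
#'   comes from `classes`).
#' @param change a `change_results` data frame (or a [domain_change()]
#'   table).
#' @param test_or_domain the `test_id` (or `domain`) whose classification
#'   partitions the subjects.
#' @param mirror if `TRUE`, mirror hemispheres before normalising.
#' @return list with `declined` and `non_declined`, each containing the
#'   `overlay_map` and its `normalized` array.
#' @export
group_compare_maps <- function(maskset, change, test_or_domain,
                               mirror = FALSE) {
  unit_col <- if ("test_id" %in% names(change)) "test_id" else "domain"
  cls_col <- if ("rci_class" %in% names(change)) "rci_class" else "class"
  sub <- change[change[[unit_col]] == test_or_domain, , drop = FALSE]
  if (!nrow(sub)) stop("no change results for '", test_or_domain, "'")
  cls <- sub[[cls_col]][match(names(maskset$masks), sub$subject_id)]
  if (anyNA(cls))
    stop("missing change classification for mask subject(s): ",
         paste(names(maskset$masks)[is.na(cls)], collapse = ", "))
  part <- ifelse(cls == "declined", "declined", "non_declined")
  if (!any(part == "declined"))
    stop("empty comparison side: no declined subjects for '",
         test_or_domain, "'")
  if (!any(part == "non_declined"))
    stop("empty comparison side: no non-declined subjects for '",
         test_or_domain, "'")
  ms <- mask_set(maskset$masks, stats::setNames(part, names(maskset$masks)),
                 affine = maskset$affine)
  if (mirror) ms <- mirror_hemispheres(ms)
  out <- lapply(c(declined = "declined", non_declined = "non_declined"),
                function(g) {
    ov <- build_overlay(ms, g)
    list(overlay = ov, normalized = normalize_overlay(ov))
  })
  out
}

#' Write an overlay map to NIfTI
#'
#' Writes the integer count volume and, optionally, the normalised float
#' volume alongside it (suffix `_norm`).
#'
#' @param map an `overlay_map`.
#' @param path output `.nii`/`.nii.gz` path for the counts.
#' @param normalized also write the normalised volume.
#' @return invisibly, the path(s) written.
#' @export
write_overlay_nifti <- function(map, path, normalized = TRUE) {
  img <- RNifti::asNifti(map$counts)
  RNifti::writeNifti(img, path)
  paths <- path
  if (normalized) {
    npath <- sub("(\\.nii(\\.gz)?)$", "_norm\\1", path)
    if (npath == path) npath <- paste0(path, "_norm.nii")
    RNifti::writeNifti(RNifti::asNifti(normalize_overlay(map)), npath)
    paths <- c(paths, npath)
  }
  invisible(paths)
}
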