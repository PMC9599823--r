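#' Canonical names of the eleven visual ROIs
#'
#' The fixed ordering used for every matrix row/column index in the package:
#' dorsal/ventral V1-V3, then V4, LOC, FFA, PPA, and HVC (the voxel-wise union
#' of LOC, FFA and PPA treated as an eleventh region).
#'
#' @return character vector of length 11.
#' @export
roi_names <- function() {
  c("V1d", "V1v", "V2d", "V2v", "V3d", "V3v",
    "V4", "LOC", "FFA", "PPA", "HVC")
}

#' Group membership of the eleven ROIs
#'
#' V1-V3 subregions form the low-level group; V4, LOC, FFA, PPA and HVC the
#' medium/high-level group. The grouping decides which adjacency entries get
#' the stronger within-group weight.
#'
#' @return named character vector mapping ROI name to
#'   `"low_level"` or `"mid_high_level"`.
#' @export
roi_groups <- function() {
  g <- c(rep("low_level", 6L), rep("mid_high_level", 5L))
  names(g) <- roi_names()
  g
}

#' @rdname roi_names
#' @param name ROI name(s).
#' @return `roi_index()`: integer position(s) in the canonical order.
#' @export
roi_index <- function(name) {
  i <- match(name, roi_names())
  if (anyNA(i)) stopf("unknown ROI name: %s", paste(name[is.na(i)], collapse = ", "))
  i
}

#' Construct an ROI template
#'
#' @param masks named list of 11 binary 3D arrays (0/1), one per ROI in any
#'   order; names must be exactly [roi_names()]. All masks must share one
#'   grid, be non-empty, and HVC must equal the voxel-wise union of LOC, FFA
#'   and PPA.
#' @param voxel_dim voxel size in mm, length 3 (default 3 mm isotropic).
#' @return an object of class `roi_template` with fields `masks` (in
#'   canonical order), `grid`, `voxel_dim`, `groups`.
#' @export
roi_template <- function(masks, voxel_dim = c(3, 3, 3)) {
  tpl <- structure(
    list(masks = masks[roi_names()],
         grid = dim(masks[[1]]),
         voxel_dim = voxel_dim,
         groups = roi_groups()),
    class = "roi_template")
  validate_roi_template(tpl)
  tpl
}

validate_roi_template <- function(tpl) {
  if (!setequal(names(tpl$masks), roi_names()))
    stopf("template must contain exactly the 11 canonical ROIs")
  grid <- tpl$grid
  for (nm in roi_names()) {
    m <- tpl$masks[[nm]]
    if (!identical(dim(m), as.integer(grid)) && !identical(dim(m), grid))
      stopf("grid mismatch: ROI %s has dims %s, expected %s", nm,
            paste(dim(m), collapse = "x"), paste(grid, collapse = "x"))
    if (!all(m %in% c(0, 1)))
      stopf("non-binary mask values in ROI %s", nm)
    if (sum(m) < 1)
      stopf("empty mask: ROI %s has no voxels", nm)
  }
  hvc <- tpl$masks$HVC > 0
  un <- (tpl$masks$LOC > 0) | (tpl$masks$FFA > 0) | (tpl$masks$PPA > 0)
  if (!identical(as.vector(hvc), as.vector(un)))
    stopf("HVC union violation: HVC mask must equal union(LOC, FFA, PPA)")
  invisible(tpl)
}

#' @export
print.roi_template <- function(x, ...) {
  cat(sprintf("ROI template: grid %s, voxel %s mm\n",
              paste(x$grid, collapse = " x "),
              paste(x$voxel_dim, collapse = " x ")))
  sizes <- vapply(x$masks, sum, numeric(1))
  for (nm in roi_names())
    cat(sprintf("  %-4s %-15s %6d voxels\n", nm, x$groups[[nm]], as.integer(sizes[[nm]])))
  invisible(x)
}

#' Construct a single-block fMRI volume sequence
#'
#' @param data 4D numeric array `(X, Y, Z, 3)`: three whole-brain volumes
#'   (one per TR of the stimulus block) on the template grid.
#' @param subject subject identifier (integer).
#' @param label stimulus class in `1..n_classes` (or `NA` when unknown).
#' @param n_classes number of stimulus classes (default 10).
#' @return object of class `volume_sequence`.
#' @export
volume_sequence <- function(data, subject, label = NA_integer_, n_classes = 10L) {
  d <- dim(data)
  if (length(d) != 4L) stopf("scan data must be a 4D array, got %d dims", length(d))
  if (d[4] != 3L) stopf("scan must have exactly 3 time frames, got %d", d[4])
  if (!is.na(label) && (label < 1L || label > n_classes))
    stopf("label %s outside 1..%d", label, n_classes)
  structure(list(data = data, subject = as.integer(subject),
                 label = as.integer(label)),
            class = "volume_sequence")
}

#' @export
print.volume_sequence <- function(x, ...) {
  cat(sprintf("volume_sequence: grid %s, 3 frames, subject %d, label %s\n",
              paste(dim(x$data)[1:3], collapse = " x "), x$subject,
              ifelse(is.na(x$label), "?", x$label)))
  invisible(x)
}

check_scan_grid <- function(scan, template) {
  if (!identical(as.integer(dim(scan$data)[1:3]), as.integer(template$grid)))
    stopf("grid mismatch: scan %s vs template %s",
          paste(dim(scan$data)[1:3], collapse = "x"),
          paste(template$grid, collapse = "x"))
  invisible(TRUE)
}

#' Mask a scan down to one ROI
#'
#' Zeroes every voxel outside the ROI mask in all three frames; voxels inside
#' pass through unchanged (element-wise product with the mask, broadcast over
#' time). This is how the non-visual areas of the brain are removed before a
#' scan enters a per-ROI CNN stream.
#'
#' @param scan a [volume_sequence()].
#' @param roi ROI name (one of [roi_names()]).
#' @param template an [roi_template()].
#' @return a masked [volume_sequence()] of identical shape.
#' @export
apply_mask <- function(scan, roi, template) {
  check_scan_grid(scan, template)
  m <- template$masks[[match.arg(roi, roi_names())]]
  out <- scan$data * as.vector(m) # mask recycles over the 3 frames
  volume_sequence(out, scan$subject, scan$label)
}

#' Mean ROI time course of a scan
#'
#' Element `t` is the mean intensity of frame `t` over the ROI's voxels. These
#' per-ROI signals, concatenated across training scans, are what the
#' functional-connectivity adjacency is computed from.
#'
#' @inheritParams apply_mask
#' @return numeric vector of length 3.
#' @export
roi_mean_timecourse <- function(scan, roi, template) {
  check_scan_grid(scan, template)
  m <- template$masks[[match.arg(roi, roi_names())]]
  keep <- which(m > 0)
  if (length(keep) == 0) stopf("degenerate ROI: %s has an empty mask", roi)
  vapply(1:3, function(t) mean(scan$data[, , , t][keep]), numeric(1))
}

#' Write an ROI template to disk
#'
#' One NIfTI volume per ROI plus a JSON manifest (the source of truth: ROI
#' name, filename, group). A combined integer-labelled volume over the ten
#' disjoint ROIs is written as a convenience; it cannot encode HVC, which
#' overlaps its constituents.
#'
#' @param template an [roi_template()].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
write_template <- function(template, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rois <- lapply(roi_names(), function(nm) {
    file <- paste0("roi_", nm, ".nii.gz")
    img <- RNifti::asNifti(array(as.numeric(template$masks[[nm]]),
                                 dim = template$grid),
                           pixdim = template$voxel_dim)
    RNifti::writeNifti(img, file.path(dir, file))
    list(name = nm, file = file, group = unname(template$groups[[nm]]))
  })
  combined <- array(0, dim = template$grid)
  for (i in 1:10) combined[template$masks[[roi_names()[i]]] > 0] <- i
  RNifti::writeNifti(RNifti::asNifti(combined, pixdim = template$voxel_dim),
                     file.path(dir, "combined_labels.nii.gz"))
  manifest <- list(grid = as.integer(template$grid),
                   voxel_dim = template$voxel_dim,
                   rois = rois)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load and validate an ROI template
#'
#' Reads the JSON manifest written by [write_template()] (or a directory
#' containing `manifest.json`), loads each ROI NIfTI, and enforces the
#' template invariants: binary masks, one shared grid, non-empty ROIs, and
#' HVC equal to the union of LOC, FFA and PPA.
#'
#' @param path manifest file or its directory.
#' @return an [roi_template()].
#' @export
load_template <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  if (!file.exists(path)) stopf("template manifest not found: %s", path)
  manifest <- jsonlite::read_json(path, simplifyVector = TRUE)
  dir <- dirname(path)
  grid <- as.integer(manifest$grid)
  masks <- list()
  for (i in seq_len(nrow(manifest$rois))) {
    nm <- manifest$rois$name[i]
    img <- RNifti::readNifti(file.path(dir, manifest$rois$file[i]))
    arr <- array(as.numeric(img), dim = dim(img))
    if (!all(arr %in% c(0, 1)))
      stopf("non-binary voxel values in ROI %s", nm)
    if (!identical(as.integer(dim(arr)), grid))
      stopf("grid mismatch: ROI %s is %s, manifest says %s", nm,
            paste(dim(arr), collapse = "x"), paste(grid, collapse = "x"))
    masks[[nm]] <- arr
  }
  roi_template(masks, voxel_dim = as.numeric(manifest$voxel_dim))
}
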