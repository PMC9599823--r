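#' Configuration for the synthetic fMRI generator
#'
#' The generator emulates the statistical structure the decoder assumes:
#' per-class spatial activation patterns injected into the ROI masks, a
#' hemodynamic-like ramp over the three frames of a block, multiplicative
#' subject-level gain differences, and i.i.d. Gaussian voxel noise.
#'
#' @param n_subjects simulated subjects (>= 2 for any split experiment).
#' @param scans_per_class_per_subject repetitions of each class per subject.
#' @param n_classes stimulus categories (default 10).
#' @param effect_size mean class-signal amplitude in units of `noise_sd`.
#' @param noise_sd SD of the additive voxel noise (intensity units).
#' @param subject_gain_sd SD of the log-normal per-subject gain.
#' @param pattern_sd relative SD of per-voxel amplitudes around
#'   `effect_size * noise_sd` (makes patterns class-specific voxel by voxel).
#' @param baseline baseline tissue intensity before gain and noise.
#' @param grid spatial grid, default `c(64, 64, 50)`.
#' @param seed master seed; every scan derives its own sub-seed from it.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 5L,
                             scans_per_class_per_subject = 20L,
                             n_classes = 10L,
                             effect_size = 2,
                             noise_sd = 1,
                             subject_gain_sd = 0.1,
                             pattern_sd = 1,
                             baseline = 100,
                             grid = c(64L, 64L, 50L),
                             seed = 1L) {
  stopifnot(is_count(n_subjects), n_subjects >= 2,
            is_count(scans_per_class_per_subject),
            is_count(n_classes), n_classes >= 2,
            effect_size >= 0, noise_sd > 0, subject_gain_sd >= 0,
            length(grid) == 3)
  structure(list(n_subjects = as.integer(n_subjects),
                 scans_per_class_per_subject = as.integer(scans_per_class_per_subject),
                 n_classes = as.integer(n_classes),
                 effect_size = effect_size, noise_sd = noise_sd,
                 subject_gain_sd = subject_gain_sd, pattern_sd = pattern_sd,
                 baseline = baseline, grid = as.integer(grid),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# frame gains emulating a hemodynamic ramp over the three TRs of a block
hemodynamic_ramp <- function() c(0.8, 1.0, 0.9)

#' Generate a synthetic ROI template
#'
#' Places the ten disjoint ROIs (V1d..V3v, V4, LOC, FFA, PPA) as compact
#' ellipsoidal blobs in separate compartments of the grid, then sets HVC to
#' the voxel-wise union of LOC, FFA and PPA. On the reference 64 x 64 x 50
#' grid each blob holds roughly 100-600 voxels; on smaller grids the target
#' volume scales with grid volume (minimum 8 voxels). Stands in for a
#' manually delineated anatomical template.
#'
#' @param seed integer seed; the same seed always yields the same template.
#' @param grid spatial grid (default `c(64, 64, 50)`).
#' @param voxel_dim voxel size in mm.
#' @return an [roi_template()].
#' @export
generate_template <- function(seed = 1L, grid = c(64L, 64L, 50L),
                              voxel_dim = c(3, 3, 3)) {
  grid <- as.integer(grid)
  set.seed(derive_seed(seed, 11L))
  # 3 x 2 x 2 lattice of disjoint compartments; one blob per compartment
  nc <- c(3L, 2L, 2L)
  lo <- lapply(1:3, function(a) floor(seq(0, grid[a], length.out = nc[a] + 1)))
  cells <- list()
  for (k in 0:(nc[3] - 1)) for (j in 0:(nc[2] - 1)) for (i in 0:(nc[1] - 1))
    cells[[length(cells) + 1L]] <- rbind(
      c(lo[[1]][i + 1] + 1, lo[[1]][i + 2]),
      c(lo[[2]][j + 1] + 1, lo[[2]][j + 2]),
      c(lo[[3]][k + 1] + 1, lo[[3]][k + 2]))
  scale <- prod(grid) / (64 * 64 * 50)
  masks <- list()
  for (r in 1:10) {
    cell <- cells[[r]]
    half <- (cell[, 2] - cell[, 1]) / 2
    centre <- (cell[, 1] + cell[, 2]) / 2 + runif(3, -0.2, 0.2) * half
    target <- max(8, runif(1, 100, 600) * scale)
    f <- runif(3, 0.7, 1.3)
    r0 <- (3 * target / (4 * pi * prod(f)))^(1 / 3)
    radii <- pmin(pmax(r0 * f, 1.0), half - 0.51)
    radii <- pmax(radii, 0.9) # never thinner than one voxel
    m <- array(0, dim = grid)
    xs <- cell[1, 1]:cell[1, 2]; ys <- cell[2, 1]:cell[2, 2]; zs <- cell[3, 1]:cell[3, 2]
    for (z in zs) {
      dz2 <- ((z - centre[3]) / radii[3])^2
      if (dz2 > 1) next
      dy2 <- ((ys - centre[2]) / radii[2])^2
      dx2 <- ((xs - centre[1]) / radii[1])^2
      inside <- outer(dx2, dy2, "+") + dz2 <= 1
      m[xs, ys, z][inside] <- 1
    }
    if (sum(m) == 0) m[round(centre[1]), round(centre[2]), round(centre[3])] <- 1
    masks[[roi_names()[r]]] <- m
  }
  masks$HVC <- pmin(masks$LOC + masks$FFA + masks$PPA, 1)
  roi_template(masks, voxel_dim = voxel_dim)
}

# per-class activation patterns over the ten disjoint ROIs, as a full-volume
# array per class; HVC inherits its constituents' voxels
class_patterns <- function(config, template) {
  amp <- config$effect_size * config$noise_sd
  set.seed(derive_seed(config$seed, 7L))
  lapply(seq_len(config$n_classes), function(cl) {
    p <- array(0, dim = template$grid)
    for (r in 1:10) {
      idx <- which(template$masks[[roi_names()[r]]] > 0)
      p[idx] <- amp * (1 + rnorm(length(idx), 0, config$pattern_sd))
    }
    p
  })
}

#' Generate a seeded synthetic dataset
#'
#' For every (subject, class, repetition) a scan is drawn as
#' `gain_s * (baseline + ramp_t * P_c) + noise`, where `P_c` is the class's
#' fixed spatial pattern (mean amplitude `effect_size * noise_sd` inside the
#' ROI masks, zero outside), `ramp` is the frame-wise hemodynamic ramp
#' (0.8, 1.0, 0.9), `gain_s` is a per-subject log-normal gain, and the noise
#' is i.i.d. Gaussian per voxel. Identical `(config, seed)` regenerate the
#' dataset bit-identically.
#'
#' @param config a [generator_config()].
#' @param template an [roi_template()] on the same grid.
#' @return object of class `synthetic_dataset`: `template`, `scans` (list of
#'   [volume_sequence()]), `index` (data.frame scan/subject/label), `config`.
#' @export
generate_dataset <- function(config, template) {
  if (!identical(as.integer(template$grid), config$grid))
    stopf("template grid %s does not match config grid %s",
          paste(template$grid, collapse = "x"), paste(config$grid, collapse = "x"))
  patterns <- class_patterns(config, template)
  set.seed(derive_seed(config$seed, 5L))
  gains <- exp(rnorm(config$n_subjects, 0, config$subject_gain_sd))
  ramp <- hemodynamic_ramp()
  nvox <- prod(config$grid)
  scans <- list()
  rows <- list()
  for (s in seq_len(config$n_subjects)) {
    for (cl in seq_len(config$n_classes)) {
      for (rep in seq_len(config$scans_per_class_per_subject)) {
        set.seed(derive_seed(config$seed, s, cl, rep))
        dat <- array(0, dim = c(config$grid, 3L))
        for (t in 1:3) {
          dat[, , , t] <- gains[s] * (config$baseline + ramp[t] * patterns[[cl]]) +
            rnorm(nvox, 0, config$noise_sd)
        }
        scans[[length(scans) + 1L]] <- volume_sequence(dat, s, cl,
                                                       config$n_classes)
        rows[[length(rows) + 1L]] <- data.frame(scan = length(scans),
                                                subject = s, label = cl)
      }
    }
  }
  structure(list(template = template, scans = scans,
                 index = do.call(rbind, rows), config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d scans (%d subjects x %d classes x %d reps), grid %s\n",
              length(x$scans), x$config$n_subjects, x$config$n_classes,
              x$config$scans_per_class_per_subject,
              paste(x$config$grid, collapse = " x ")))
  invisible(x)
}

#' Normalise scans subject by subject
#'
#' Different subjects show different overall signal levels; before any
#' training or inference each subject's scans are brought to a common range
#' using only that subject's own statistics (no cross-subject leakage).
#' `"zscore"` (default) z-scores every voxel intensity with the subject's
#' global mean and SD over all its scans and frames; `"minmax"` maps the
#' subject's global range to `[0, 1]`.
#'
#' @param scans list of [volume_sequence()].
#' @param method `"zscore"` or `"minmax"`.
#' @return list of normalised [volume_sequence()] in the same order.
#' @export
normalize_by_subject <- function(scans, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  subjects <- vapply(scans, function(s) s$subject, integer(1))
  out <- scans
  for (s in unique(subjects)) {
    idx <- which(subjects == s)
    all_vals <- unlist(lapply(scans[idx], function(x) as.vector(x$data)),
                       use.names = FALSE)
    if (method == "zscore") {
      mu <- mean(all_vals)
      sdv <- sqrt(mean((all_vals - mu)^2))
      if (sdv <= 0) stopf("normalization error: subject %d has zero variance", s)
      for (i in idx) out[[i]]$data <- (scans[[i]]$data - mu) / sdv
    } else {
      rng <- range(all_vals)
      if (diff(rng) <= 0) stopf("normalization error: subject %d has zero range", s)
      for (i in idx) out[[i]]$data <- (scans[[i]]$data - rng[1]) / diff(rng)
    }
  }
  out
}

#' Write a synthetic dataset to disk
#'
#' NIfTI scan volumes, the ROI template (via [write_template()]), a CSV index
#' (file, subject, label) and a JSON provenance record (config + seed).
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "scans"), recursive = TRUE, showWarnings = FALSE)
  write_template(dataset$template, file.path(dir, "template"))
  files <- character(length(dataset$scans))
  for (i in seq_along(dataset$scans)) {
    files[i] <- sprintf("scans/scan_%04d.nii.gz", i)
    img <- RNifti::asNifti(dataset$scans[[i]]$data,
                           pixdim = dataset$template$voxel_dim)
    RNifti::writeNifti(img, file.path(dir, files[i]))
  }
  index <- cbind(file = files, dataset$index[c("subject", "label")])
  write.csv(index, file.path(dir, "index.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(dataset$config),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return a `synthetic_dataset`-shaped list (template, scans, index, config).
#' @export
read_dataset <- function(dir) {
  template <- load_template(file.path(dir, "template"))
  index <- read.csv(file.path(dir, "index.csv"))
  cfg <- jsonlite::read_json(file.path(dir, "provenance.json"),
                             simplifyVector = TRUE)
  scans <- lapply(seq_len(nrow(index)), function(i) {
    img <- RNifti::readNifti(file.path(dir, index$file[i]))
    volume_sequence(array(as.numeric(img), dim = dim(img)),
                    index$subject[i], index$label[i],
                    cfg$n_classes %||% 10L)
  })
  structure(list(template = template, scans = scans,
                 index = data.frame(scan = seq_len(nrow(index)),
                                    subject = index$subject,
                                    label = index$label),
                 config = cfg),
            class = "synthetic_dataset")
}
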