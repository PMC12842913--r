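# Synthetic chest phantoms with voxel-exact ground truth: two lung
# cylinders (subdivided into five lobe bands), a candy-cane aorta
# (ascending limb, arch, descending limb) with a configurable wall, a soft-
# tissue body, empty cranial/caudal scan margins, and additive Gaussian
# noise of known standard deviation. Every pipeline stage can be verified
# against the returned truth masks without any clinical data.

#' Specification of a synthetic chest phantom
#'
#' Geometry is given in millimetres in the canonical patient frame (axis 1
#' left, axis 2 posterior, axis 3 cranial); the lung occupies exactly the
#' slices between the two gap margins, so the ground-truth overscan
#' distances are `gap_slices * dz` by construction. Defaults emulate a
#' small-FOV screening chest: lung tube radius 19 mm, aortic lumen radius
#' 9 mm with a 1.9 mm wall (the population mean wall thickness), and an
#' arch connecting the limbs above the lung apex.
#'
#' @param shape Integer grid size `(nx, ny, nz)`.
#' @param spacing Voxel spacing `(dx, dy, dz)` in mm.
#' @param caudal_gap_slices,cranial_gap_slices Number of lung-free slices at
#'   the caudal/cranial ends; 0 produces a truth underscan.
#' @param lung List: `center_right`, `center_left` (in-plane mm),
#'   `radius_mm`.
#' @param aorta List: `x_mm`, `ascending_y_mm`, `descending_y_mm`,
#'   `lumen_radius_mm`, `wall_thickness_mm`, `arch` (logical),
#'   `descending_caudal_slice` (the descending limb starts below the lung so
#'   the trim step has something to cut).
#' @param body List: `center`, `semi` (in-plane ellipse, mm).
#' @param hu List of tissue attenuations (HU): `lung`, `blood`, `wall`,
#'   `soft`, `air`.
#' @param noise_sigma Standard deviation (HU) of the additive Gaussian noise.
#' @param mas,pitch Optional acquisition metadata copied into the volume.
#' @param seed Optional RNG seed making the voxel noise reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 100),
                         spacing = c(1.25, 1.25, 1.5),
                         caudal_gap_slices = 14,
                         cranial_gap_slices = 18,
                         lung = list(),
                         aorta = list(),
                         body = list(),
                         hu = list(),
                         noise_sigma = 15,
                         mas = NULL, pitch = NULL, seed = NULL) {
  lung <- modifyList(list(center_right = c(36, 40), center_left = c(84, 40),
                          radius_mm = 19), lung)
  aorta <- modifyList(list(x_mm = 60, ascending_y_mm = 64,
                           descending_y_mm = 92, lumen_radius_mm = 9,
                           wall_thickness_mm = 1.9, arch = TRUE,
                           descending_caudal_slice = 4), aorta)
  body <- modifyList(list(center = c(60, 60), semi = c(56, 52)), body)
  hu <- modifyList(list(lung = -800, blood = 40, wall = 50, soft = 30,
                        air = -1000), hu)
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(shape) != 3L || any(shape < 8L))
    stop_ldctqa("'shape' must be three integers >= 8", "ldctqa_invalid_input")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_ldctqa("'spacing' must be three positive numbers",
                "ldctqa_invalid_input")
  if (caudal_gap_slices < 0 || cranial_gap_slices < 0 ||
      caudal_gap_slices + cranial_gap_slices > shape[3] - 5L)
    stop_ldctqa("gap slices must be >= 0 and leave at least 5 lung slices",
                "ldctqa_invalid_input")
  if (aorta$lumen_radius_mm <= 0 || aorta$wall_thickness_mm < 0)
    stop_ldctqa("aorta must have lumen_radius_mm > 0 and wall >= 0",
                "ldctqa_invalid_input")
  if (noise_sigma < 0)
    stop_ldctqa("'noise_sigma' must be >= 0", "ldctqa_invalid_input")
  structure(list(shape = shape, spacing = spacing,
                 caudal_gap_slices = as.integer(caudal_gap_slices),
                 cranial_gap_slices = as.integer(cranial_gap_slices),
                 lung = lung, aorta = aorta, body = body, hu = hu,
                 noise_sigma = noise_sigma, mas = mas, pitch = pitch,
                 seed = seed),
            class = "phantom_spec")
}

disk2d <- function(xs, ys, center, radius) {
  outer((xs - center[1])^2, (ys - center[2])^2, "+") <= radius^2
}

#' Generate a synthetic chest phantom with ground truth
#'
#' Deterministic given `spec$seed`: the voxel HU values are the noise-free
#' tissue map plus `N(0, noise_sigma)` noise, while the truth masks describe
#' the noise-free geometry. Infeasible geometry (organs overlapping or
#' leaving the body outline, an arch without cranial headroom) is an error.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `volume` (a [ct_volume()]) and `truth` (class
#'   `phantom_truth`: the five `lobes`, the `aorta` mask including wall, the
#'   blood-only `lumen`, the `descending` and `ascending` limb blood,
#'   `wall`, the ground-truth `margins_mm`, `underscan` flags, and
#'   `noise_sigma`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  sp <- spec$spacing
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  xs <- (seq_len(nx) - 0.5) * sp[1]
  ys <- (seq_len(ny) - 0.5) * sp[2]
  zs <- (seq_len(nz) - 0.5) * sp[3]

  z_lung_lo <- spec$caudal_gap_slices + 1L
  z_lung_hi <- nz - spec$cranial_gap_slices
  lung_slices <- z_lung_lo:z_lung_hi

  body2 <- outer(((xs - spec$body$center[1]) / spec$body$semi[1])^2,
                 ((ys - spec$body$center[2]) / spec$body$semi[2])^2,
                 "+") <= 1
  rlung2 <- disk2d(xs, ys, spec$lung$center_right, spec$lung$radius_mm)
  llung2 <- disk2d(xs, ys, spec$lung$center_left, spec$lung$radius_mm)

  ao <- spec$aorta
  r_out <- ao$lumen_radius_mm + ao$wall_thickness_mm
  asc2_out <- disk2d(xs, ys, c(ao$x_mm, ao$ascending_y_mm), r_out)
  asc2_in <- disk2d(xs, ys, c(ao$x_mm, ao$ascending_y_mm), ao$lumen_radius_mm)
  desc2_out <- disk2d(xs, ys, c(ao$x_mm, ao$descending_y_mm), r_out)
  desc2_in <- disk2d(xs, ys, c(ao$x_mm, ao$descending_y_mm), ao$lumen_radius_mm)

  zmask <- function(slices) {
    sel <- rep(FALSE, nz); sel[slices] <- TRUE
    array(rep(sel, each = nx * ny), dim = d)
  }
  inplane3 <- function(m2) array(m2, dim = d)

  lung_z3 <- zmask(lung_slices)
  rlung3 <- inplane3(rlung2) & lung_z3
  llung3 <- inplane3(llung2) & lung_z3
  lung3 <- rlung3 | llung3

  # aorta: descending limb from below the lung up to the arch (or to the
  # lung apex for straight-tube phantoms), plus optional ascending limb
  # and half-torus arch above the lung apex
  desc_lo <- min(ao$descending_caudal_slice, z_lung_lo)
  if (ao$arch) {
    arch_R <- (ao$descending_y_mm - ao$ascending_y_mm) / 2
    y_mid <- (ao$descending_y_mm + ao$ascending_y_mm) / 2
    z_arch <- (z_lung_hi + 0.5) * sp[3]  # just above the lung apex
    if (z_arch + arch_R + r_out > nz * sp[3])
      stop_ldctqa("arch does not fit above the lung apex; increase cranial gap",
                  "ldctqa_infeasible_geometry")
    limb_hi <- max(which(zs <= z_arch))
    asc_lo <- max(1L, floor((z_lung_lo + z_lung_hi) / 2))
    desc3_out <- inplane3(desc2_out) & zmask(desc_lo:limb_hi)
    desc3_in <- inplane3(desc2_in) & zmask(desc_lo:limb_hi)
    asc3_out <- inplane3(asc2_out) & zmask(asc_lo:limb_hi)
    asc3_in <- inplane3(asc2_in) & zmask(asc_lo:limb_hi)
    arch_sl <- which(zs >= z_arch)
    torus3 <- function(r) {
      a2 <- (sqrt(outer((ys - y_mid)^2, (zs[arch_sl] - z_arch)^2, "+")) - arch_R)^2
      m <- outer((xs - ao$x_mm)^2, a2, "+") <= r^2
      dim(m) <- c(nx, ny, length(arch_sl))
      full <- array(FALSE, dim = d)
      full[, , arch_sl] <- m
      full
    }
    arch3_out <- torus3(r_out)
    arch3_in <- torus3(ao$lumen_radius_mm)
  } else {
    limb_hi <- z_lung_hi
    desc3_out <- inplane3(desc2_out) & zmask(desc_lo:limb_hi)
    desc3_in <- inplane3(desc2_in) & zmask(desc_lo:limb_hi)
    asc3_out <- asc3_in <- arch3_out <- arch3_in <- array(FALSE, dim = d)
  }

  aorta3 <- desc3_out | asc3_out | arch3_out
  lumen3 <- desc3_in | asc3_in | arch3_in
  wall3 <- aorta3 & !lumen3

  body3 <- inplane3(body2)
  if (any(lung3 & aorta3))
    stop_ldctqa("lung and aorta geometry overlap", "ldctqa_infeasible_geometry")
  if (any(aorta3 & !body3) || any(lung3 & !body3))
    stop_ldctqa("organ geometry extends outside the body outline",
                "ldctqa_infeasible_geometry")

  hu <- array(spec$hu$air, dim = d)
  hu[body3] <- spec$hu$soft
  hu[lung3] <- spec$hu$lung
  hu[wall3] <- spec$hu$wall
  hu[lumen3] <- spec$hu$blood
  if (spec$noise_sigma > 0)
    hu <- hu + with_preserved_seed(spec$seed,
            array(rnorm(length(hu), 0, spec$noise_sigma), dim = d))

  # lobe subdivision: planar z-bands of each lung tube (three right, two
  # left); no anatomical fidelity intended beyond exercising the merge step
  n_lung <- length(lung_slices)
  cut3 <- lung_slices[ceiling(n_lung * c(0.35, 0.60))]
  cut2 <- lung_slices[ceiling(n_lung * 0.55)]
  lobes <- list(
    right_lower  = rlung3 & zmask(z_lung_lo:cut3[1]),
    right_middle = rlung3 & zmask((cut3[1] + 1L):cut3[2]),
    right_upper  = rlung3 & zmask((cut3[2] + 1L):z_lung_hi),
    left_lower   = llung3 & zmask(z_lung_lo:cut2),
    left_upper   = llung3 & zmask((cut2 + 1L):z_lung_hi)
  )[LOBE_LABELS]
  lobes <- lapply(lobes, binary_mask, spacing = sp)

  truth <- structure(list(
    lobes = lobes,
    aorta = binary_mask(aorta3, sp),
    lumen = binary_mask(lumen3, sp),
    descending = binary_mask(desc3_in, sp),
    ascending = binary_mask(asc3_in, sp),
    wall = binary_mask(wall3, sp),
    lung = binary_mask(lung3, sp),
    margins_mm = c(caudal = spec$caudal_gap_slices * sp[3],
                   cranial = spec$cranial_gap_slices * sp[3]),
    gap_slices = c(caudal = spec$caudal_gap_slices,
                   cranial = spec$cranial_gap_slices),
    underscan = c(caudal = spec$caudal_gap_slices == 0L,
                  cranial = spec$cranial_gap_slices == 0L),
    noise_sigma = spec$noise_sigma,
    spec = spec
  ), class = "phantom_truth")

  vol <- ct_volume(hu, sp,
                   acquisition = acquisition_meta(mas = spec$mas,
                                                  pitch = spec$pitch,
                                                  source_format = "synthetic"))
  list(volume = vol, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> margins %.1f mm caudal / %.1f mm cranial; sigma = %.1f HU\n",
              x$margins_mm["caudal"], x$margins_mm["cranial"], x$noise_sigma))
  invisible(x)
}

#' Generate a randomized phantom cohort
#'
#' Draws `n` phantom specifications with randomized z-extent, slice spacing,
#' scan margins and noise level, forcing a stated fraction of them to touch
#' a scan edge (truth underscan) so cohort-level underscan rates have an
#' exact expected value: with `underscan_fraction = f`, exactly
#' `round(n * f)` phantoms carry a truth underscan flag. Phantoms are
#' reproducible: the i-th phantom depends only on `seed` and `i`.
#'
#' @param n Number of phantoms (>= 1).
#' @param seed Integer seed for the cohort.
#' @param underscan_fraction Fraction of phantoms forced to underscan
#'   (caudal; half of those additionally cranial).
#' @param shape In-plane grid size; `nz` is sampled per phantom.
#' @param spacing_inplane In-plane spacing (mm).
#' @param nz_range Range of slice counts to sample from.
#' @param dz_choices Slice spacings (mm) to sample from.
#' @param gap_range Range of gap slice counts to sample from (non-forced
#'   phantoms sample from `max(1, gap_range[1])` so their flags stay FALSE).
#' @param noise_range Range of noise sigmas (HU) to sample from.
#' @param arch Whether phantoms carry an aortic arch; arch phantoms need
#'   cranial headroom, so the cranial gap is raised to fit and cranial
#'   underscan is never forced.
#' @return For `generate_cohort`, a list of `n` results of
#'   [generate_phantom()]; for `sample_cohort_specs`, the list of `n`
#'   [phantom_spec()] objects it would realize. Use the spec sampler plus
#'   [generate_phantom()] to stream large cohorts one phantom at a time
#'   instead of holding them all in memory.
#' @export
generate_cohort <- function(n, seed = 1, underscan_fraction = 0.1,
                            shape = c(64, 64), spacing_inplane = c(1.8, 1.8),
                            nz_range = c(70, 110),
                            dz_choices = c(1, 1.5, 2, 2.5),
                            gap_range = c(0, 20), noise_range = c(5, 40),
                            arch = FALSE) {
  specs <- sample_cohort_specs(n, seed = seed,
                               underscan_fraction = underscan_fraction,
                               shape = shape,
                               spacing_inplane = spacing_inplane,
                               nz_range = nz_range, dz_choices = dz_choices,
                               gap_range = gap_range,
                               noise_range = noise_range, arch = arch)
  lapply(specs, generate_phantom)
}

#' @rdname generate_cohort
#' @export
sample_cohort_specs <- function(n, seed = 1, underscan_fraction = 0.1,
                                shape = c(64, 64),
                                spacing_inplane = c(1.8, 1.8),
                                nz_range = c(70, 110),
                                dz_choices = c(1, 1.5, 2, 2.5),
                                gap_range = c(0, 20), noise_range = c(5, 40),
                                arch = FALSE) {
  if (n < 1) stop_ldctqa("'n' must be >= 1", "ldctqa_invalid_input")
  n_forced <- round(n * underscan_fraction)
  with_preserved_seed(seed, {
    forced <- rep(FALSE, n)
    if (n_forced > 0) forced[sample.int(n, n_forced)] <- TRUE
    lapply(seq_len(n), function(i) {
      nz <- sample(nz_range[1]:nz_range[2], 1)
      dz <- sample(dz_choices, 1)
      r_out <- 9 + 1.9
      arch_min_gap <- if (arch) ceiling(((92 - 64) / 2 + r_out + dz) / dz) + 1L else 0L
      samp_gap <- function(lo) {
        vals <- lo:max(gap_range[2], lo)
        vals[sample.int(length(vals), 1)]
      }
      if (forced[i]) {
        caudal <- 0L
        cranial <- if (!arch && stats::runif(1) < 0.5) 0L else
          samp_gap(max(1L, gap_range[1], arch_min_gap))
      } else {
        caudal <- samp_gap(max(1L, gap_range[1]))
        cranial <- samp_gap(max(1L, gap_range[1], arch_min_gap))
      }
      if (caudal + cranial > nz - 20L) {
        cranial <- min(cranial, max(arch_min_gap, nz - 20L - caudal))
        caudal <- min(caudal, nz - 20L - cranial)
      }
      phantom_spec(shape = c(shape, nz),
                   spacing = c(spacing_inplane, dz),
                   caudal_gap_slices = caudal,
                   cranial_gap_slices = cranial,
                   aorta = list(arch = arch),
                   noise_sigma = stats::runif(1, noise_range[1],
                                              noise_range[2]),
                   seed = sample.int(.Machine$integer.max, 1))
    })
  })
}

#' Write a phantom to disk
#'
#' Writes the volume, the six organ masks, the blood-only lumen mask, and a
#' JSON ground-truth record into `dir`.
#'
#' @param phantom A result of [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(volume = file.path(dir, "volume.nii.gz"))
  write_volume(phantom$volume, paths[["volume"]])
  for (nm in LOBE_LABELS) {
    paths[[nm]] <- file.path(dir, paste0(nm, ".nii.gz"))
    write_mask(phantom$truth$lobes[[nm]], paths[[nm]])
  }
  for (nm in c("aorta", "lumen")) {
    paths[[nm]] <- file.path(dir, paste0(nm, ".nii.gz"))
    write_mask(phantom$truth[[nm]], paths[[nm]])
  }
  paths[["truth"]] <- file.path(dir, "truth.json")
  truth <- phantom$truth
  jsonlite::write_json(list(margins_mm = as.list(truth$margins_mm),
                            gap_slices = as.list(truth$gap_slices),
                            underscan = as.list(truth$underscan),
                            noise_sigma = truth$noise_sigma),
                       paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
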