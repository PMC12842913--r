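#' Compute raw and volume-normalized image noise from aortic blood
#'
#' Blood is homogeneous at CT scale, so any spread of HU values inside a
#' pure blood mask reflects quantum noise and artefacts rather than anatomy.
#' The raw estimate is the sample mean and standard deviation (n - 1
#' denominator) over exactly the masked voxels. Because the raw standard
#' deviation depends on voxel size (averaging larger voxels pools more
#' photons), it is normalized to the noise that would theoretically occur at
#' a reference voxel volume of 1 mm^3:
#' \deqn{\sigma_{norm} = \sigma_{raw} \sqrt{v_{raw} / v_{norm}},\quad
#'       v_{norm} = 1\,\mathrm{mm}^3,}
#' where \eqn{v_{raw} = dx \cdot dy \cdot dz} comes from the volume's
#' spacing metadata. \eqn{\sigma_{norm}} is therefore comparable across
#' reconstructions with different voxel sizes (within one reconstruction
#' kernel).
#'
#' @param vol The [ct_volume()] the mask refers to.
#' @param lumen The extracted blood [binary_mask()] on the same grid.
#' @param min_voxels Minimum mask size; fewer voxels raise an error so a
#'   degenerate lumen is reported as "noise unavailable" rather than as an
#'   unstable number.
#' @return An object of class `noise_result` with fields `mu_raw`,
#'   `sigma_raw`, `v_raw` (mm^3), `sigma_norm`, and `n_voxels`.
#' @export
compute_noise <- function(vol, lumen, min_voxels = 100) {
  stopifnot(inherits(vol, "ct_volume"), inherits(lumen, "binary_mask"))
  assert_same_grid(vol, lumen, "volume and lumen mask")
  vals <- vol$voxels[lumen$voxels]
  if (length(vals) < min_voxels)
    stop_ldctqa(sprintf("only %d lumen voxels (minimum %d); noise unavailable",
                        length(vals), min_voxels), "ldctqa_noise_unavailable")
  v_raw <- prod(vol$spacing)
  sigma_raw <- sd(vals)
  structure(list(mu_raw = mean(vals), sigma_raw = sigma_raw, v_raw = v_raw,
                 sigma_norm = sigma_raw * sqrt(v_raw / 1),
                 n_voxels = length(vals)),
            class = "noise_result")
}

#' @export
print.noise_result <- function(x, ...) {
  cat(sprintf("<noise_result> n = %d voxels (v_raw = %.4g mm^3)\n",
              x$n_voxels, x$v_raw))
  cat(sprintf("  mu_raw = %.2f HU, sigma_raw = %.2f HU, sigma_norm = %.2f HU\n",
              x$mu_raw, x$sigma_raw, x$sigma_norm))
  invisible(x)
}

#' Effective tube current-time product
#'
#' For helical CT the exposure per z-position is the tube current-time
#' product divided by the pitch: `effective mAs = mAs / pitch`.
#'
#' @param mas Tube current-time product in mAs (> 0).
#' @param pitch Helical pitch, dimensionless (> 0).
#' @return Effective mAs.
#' @export
effective_mas <- function(mas, pitch) {
  if (!is.numeric(mas) || any(mas <= 0))
    stop_ldctqa("'mas' must be positive", "ldctqa_invalid_input")
  if (!is.numeric(pitch) || any(pitch <= 0))
    stop_ldctqa("'pitch' must be positive", "ldctqa_invalid_input")
  mas / pitch
}

#' Map exposure to an expected noise level
#'
#' In an ideal CT the detected photon count is Poisson and proportional to
#' the effective mAs, so noise scales as `1 / sqrt(effective mAs)`. Given a
#' reference pair (`sigma_ref` at `mas_ref`, `pitch_ref`), this returns the
#' noise expected at another exposure. Used by the phantom generator to
#' express the dose law as an injectable noise level.
#'
#' @param mas,pitch Exposure of interest.
#' @param sigma_ref Noise (HU) measured or assumed at the reference exposure.
#' @param mas_ref,pitch_ref Reference exposure.
#' @return Expected noise standard deviation in HU.
#' @export
noise_sigma_from_mas <- function(mas, pitch = 1, sigma_ref, mas_ref,
                                 pitch_ref = 1) {
  sigma_ref * sqrt(effective_mas(mas_ref, pitch_ref) / effective_mas(mas, pitch))
}
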