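# Synthetic micro-CT phantoms of osteochondral tissue: a dense plate over a
# porous trabecular region, used to exercise the image -> segmentation ->
# labelling -> mesh path that real scans would follow. The trabecular
# microstructure model (thresholded correlated Gaussian field) is a
# deliberately simple stand-in and makes no claim of histomorphometric
# realism.

#' Phantom generation parameters
#'
#' @param voxel_size Isotropic voxel size in micrometres (default 18).
#' @param plate_thickness Dense plate thickness in mm (default 0.3).
#' @param dims Integer length-3 volume dimensions in voxels.
#' @param bone_volume_fraction Target trabecular BV/TV in (0, 1).
#' @param correlation_length Trabecular structure correlation length in mm
#'   (Gaussian smoothing scale; default 0.1, i.e. strut-scale).
#' @param noise_std Additive Gaussian noise standard deviation in intensity
#'   units (bone sits at 1, marrow at 0).
#' @param seed Integer seed; fixes all randomness.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(voxel_size = 18, plate_thickness = 0.3,
                           dims = c(64, 64, 64),
                           bone_volume_fraction = 0.3,
                           correlation_length = 0.1,
                           noise_std = 0, seed = 1) {
  stopifnot(voxel_size > 0, plate_thickness >= 0,
            length(dims) == 3L, all(dims >= 1),
            bone_volume_fraction > 0, bone_volume_fraction < 1,
            correlation_length > 0, noise_std >= 0)
  structure(list(voxel_size = as.numeric(voxel_size),
                 plate_thickness = as.numeric(plate_thickness),
                 dims = as.integer(dims),
                 bone_volume_fraction = as.numeric(bone_volume_fraction),
                 correlation_length = as.numeric(correlation_length),
                 noise_std = as.numeric(noise_std),
                 seed = as.integer(seed),
                 # scanner settings recorded as metadata only
                 scanner = list(voltage_kVp = 40, current_uA = 200,
                                integration_ms = 200,
                                filter = "0.5 mm aluminium")),
            class = "phantom_params")
}

# periodic Gaussian smoothing of a 3-D array by FFT; sigma in voxels
gaussian_smooth3 <- function(a, sigma) {
  d <- dim(a)
  kern1 <- function(n, s) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) # fft frequencies as offsets
    k <- exp(-0.5 * (x / s)^2)
    k / sum(k)
  }
  Kf <- outer(outer(fft(kern1(d[1], sigma[1])), fft(kern1(d[2], sigma[2]))),
              fft(kern1(d[3], sigma[3])))
  dim(Kf) <- d
  Re(fft(fft(a) * Kf, inverse = TRUE)) / prod(d)
}

#' Generate a synthetic micro-CT phantom
#'
#' A grayscale volume: intensity 1 for bone, 0 for marrow/background, plus
#' optional additive Gaussian noise. The top `plate_thickness` of the
#' volume is fully dense (the subchondral plate); below it, trabecular bone
#' is drawn as a correlated Gaussian random field thresholded at the
#' quantile that realises the target bone volume fraction, so the realised
#' BV/TV matches the target up to voxel-count discreteness. The same seed
#' always yields a bit-identical volume (the caller's RNG state is left
#' untouched).
#'
#' @param params A [phantom_params()].
#' @return A grayscale [voxel_grid()] (voxel size in mm).
#' @export
generate_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  d <- params$dims
  if (any(d < 1L)) stop("degenerate volume dimensions")
  vs_mm <- params$voxel_size / 1000
  n_plate <- min(d[3], round(params$plate_thickness / vs_mm))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(params$seed)
  vol <- array(0, dim = d)
  n_trab <- d[3] - n_plate
  if (n_trab > 0) {
    g <- array(stats::rnorm(d[1] * d[2] * n_trab), dim = c(d[1], d[2], n_trab))
    sigma_vox <- rep(params$correlation_length / vs_mm, 3)
    if (min(dim(g)) >= 4) g <- gaussian_smooth3(g, sigma_vox)
    thr <- stats::quantile(g, 1 - params$bone_volume_fraction, names = FALSE)
    vol[, , n_plate + seq_len(n_trab)] <- as.numeric(g >= thr)
  }
  if (n_plate > 0) vol[, , seq_len(n_plate)] <- 1
  if (params$noise_std > 0)
    vol <- vol + array(stats::rnorm(prod(d), sd = params$noise_std), dim = d)
  voxel_grid(vol, rep(vs_mm, 3), kind = "grayscale")
}

#' Threshold segmentation of a grayscale volume
#'
#' Voxels with intensity at or above the threshold are labelled bone
#' (trabecular code), the rest background — the binarisation step a
#' segmentation package applies to CT data. Layer identities are assigned
#' separately by [label_layers()].
#'
#' @param volume A grayscale [voxel_grid()].
#' @param threshold Intensity threshold.
#' @return A labelled [voxel_grid()] (0 background, 1 bone).
#' @export
segment_volume <- function(volume, threshold) {
  stopifnot(inherits(volume, "voxel_grid"), volume$kind == "grayscale")
  lab <- array(ifelse(volume$data >= threshold, LABEL_TRABECULAR,
                      LABEL_BACKGROUND), dim = volume$dims)
  voxel_grid(lab, volume$voxel_size, kind = "labels")
}

#' Split a bone mask into plate and trabecular layers
#'
#' For each lateral column, bone voxels within `plate_thickness` below the
#' topmost bone voxel of that column are relabelled as plate; deeper bone
#' stays trabecular. Columns containing no bone are left as background
#' (counted in a warning).
#'
#' @param mask A labelled [voxel_grid()] from [segment_volume()].
#' @param plate_thickness Plate thickness in mm.
#' @return A labelled [voxel_grid()] with plate/trabecular codes.
#' @export
label_layers <- function(mask, plate_thickness) {
  stopifnot(inherits(mask, "voxel_grid"), mask$kind == "labels")
  if (!any(mask$data != LABEL_BACKGROUND)) stop("mask is empty")
  d <- mask$dims
  vz <- mask$voxel_size[3]
  n_plate_vox <- round(plate_thickness / vz)
  lab <- mask$data
  bone <- lab != LABEL_BACKGROUND
  # topmost bone voxel per lateral column (z index increases downward)
  flat <- matrix(bone, nrow = d[1] * d[2], ncol = d[3])
  top_k <- apply(flat, 1, function(col) {
    w <- which(col)
    if (length(w)) w[1] else NA_integer_
  })
  n_empty <- sum(is.na(top_k))
  if (n_empty > 0)
    warning(sprintf("%d lateral columns contain no bone", n_empty))
  if (n_plate_vox > 0) {
    kmat <- matrix(rep(seq_len(d[3]), each = d[1] * d[2]), nrow = d[1] * d[2])
    in_plate <- !is.na(top_k) & kmat >= top_k & kmat < top_k + n_plate_vox
    sel <- as.vector(in_plate) & as.vector(flat)
    lab[sel] <- LABEL_PLATE
  }
  voxel_grid(lab, mask$voxel_size, kind = "labels")
}
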