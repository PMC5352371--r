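#' Phantom shape specification
#'
#' Describes a synthetic tumor phantom: a sphere, an axis-aligned ellipsoid,
#' or a "sea-urchin" spiky shape (a sphere carrying radial Gaussian bumps in
#' seeded random directions). Phantoms span the compact-to-spiculated shape
#' range that drives tumor compactness.
#'
#' @param family One of `"sphere"`, `"ellipsoid"`, `"spiky"`.
#' @param radius_mm Sphere/spiky base radius in mm.
#' @param semiaxes_mm Length-3 semi-axes in mm (ellipsoid only).
#' @param spike_count Number of radial bumps (spiky only, >= 0).
#' @param spike_amplitude_mm Radial bump amplitude in mm (spiky only, >= 0).
#' @param spike_width_rad Angular half-width of each bump in radians.
#' @param spacing Per-axis voxel size in mm.
#' @param seed Integer seed controlling the bump directions.
#' @return A `shape_spec` list.
#' @export
shape_spec <- function(family = c("sphere", "ellipsoid", "spiky"),
                       radius_mm = 15,
                       semiaxes_mm = NULL,
                       spike_count = 0L,
                       spike_amplitude_mm = 0,
                       spike_width_rad = 0.25,
                       spacing = c(1, 1, 1),
                       seed = 1L) {
  family <- match.arg(family)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive voxel sizes in mm", call. = FALSE)
  }
  if (family == "ellipsoid") {
    if (is.null(semiaxes_mm)) semiaxes_mm <- c(radius_mm, radius_mm, radius_mm)
    if (length(semiaxes_mm) != 3L || any(semiaxes_mm <= 0)) {
      stop("`semiaxes_mm` must be 3 positive lengths", call. = FALSE)
    }
    if (any(semiaxes_mm <= 2 * max(spacing))) {
      stop("degenerate shape: semi-axes must exceed 2 x max(spacing)",
        call. = FALSE
      )
    }
  } else {
    if (!is.numeric(radius_mm) || radius_mm <= 0) {
      stop("`radius_mm` must be positive", call. = FALSE)
    }
    if (radius_mm <= 2 * max(spacing)) {
      stop("degenerate shape: radius must exceed 2 x max(spacing)",
        call. = FALSE
      )
    }
  }
  if (family != "spiky" && (spike_count != 0L || spike_amplitude_mm != 0)) {
    stop("spike parameters must be 0 for non-spiky families", call. = FALSE)
  }
  if (spike_count < 0L || spike_amplitude_mm < 0) {
    stop("spike parameters must be non-negative", call. = FALSE)
  }
  structure(
    list(
      family = family, radius_mm = radius_mm, semiaxes_mm = semiaxes_mm,
      spike_count = as.integer(spike_count),
      spike_amplitude_mm = spike_amplitude_mm,
      spike_width_rad = spike_width_rad,
      spacing = spacing, seed = as.integer(seed)
    ),
    class = "shape_spec"
  )
}

#' Digitize a phantom tumor to a segmentation mask
#'
#' Voxel centers falling inside the analytic shape become foreground. The
#' grid is sized to enclose the shape with a one-voxel background margin on
#' every side, so contraction behaves identically to a clinical mask.
#' Deterministic for a given spec (the seed fixes the spike directions).
#'
#' @param spec A [shape_spec()].
#' @return A [seg_mask()].
#' @examples
#' ph <- make_phantom(shape_spec("sphere", radius_mm = 15))
#' compute_rtv(ph) # close to 4/3 pi 1.5^3 = 14.14 cm^3
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "shape_spec")) stop("`spec` must be a shape_spec", call. = FALSE)
  sp <- spec$spacing
  half <- switch(spec$family,
    sphere = rep(spec$radius_mm, 3),
    ellipsoid = spec$semiaxes_mm,
    spiky = rep(spec$radius_mm + spec$spike_amplitude_mm, 3)
  )
  n <- 2L * (as.integer(ceiling(half / sp)) + 2L) + 1L # odd: center voxel
  centers <- lapply(1:3, function(ax) ((seq_len(n[ax]) - 1) - (n[ax] - 1) / 2) * sp[ax])

  cx <- centers[[1]][slice.index(array(0, n), 1)]
  cy <- centers[[2]][slice.index(array(0, n), 2)]
  cz <- centers[[3]][slice.index(array(0, n), 3)]

  inside <- switch(spec$family,
    sphere = (cx^2 + cy^2 + cz^2) <= spec$radius_mm^2,
    ellipsoid = {
      a <- spec$semiaxes_mm
      (cx / a[1])^2 + (cy / a[2])^2 + (cz / a[3])^2 <= 1
    },
    spiky = {
      r <- sqrt(cx^2 + cy^2 + cz^2)
      rad <- spiky_radius(cx, cy, cz, r, spec)
      r <= rad
    }
  )
  dim(inside) <- n
  if (!any(inside)) stop("degenerate shape: digitizes to an empty mask", call. = FALSE)
  thin <- vapply(1:3, function(ax) {
    rng <- range(slice.index(array(0, n), ax)[inside])
    rng[2] - rng[1] + 1L
  }, numeric(1))
  if (any(thin < 2)) {
    stop("degenerate shape: thinner than one voxel along an axis", call. = FALSE)
  }
  seg_mask(inside, spacing = sp, origin = -half - 2 * sp)
}

# radius of the spiky shape along each voxel direction: base sphere plus
# Gaussian angular bumps with seeded uniform directions
spiky_radius <- function(cx, cy, cz, r, spec) {
  rad <- rep(spec$radius_mm, length(r))
  if (spec$spike_count > 0L && spec$spike_amplitude_mm > 0) {
    dirs <- withr::with_seed(spec$seed, {
      u <- stats::runif(spec$spike_count, -1, 1)
      th <- stats::runif(spec$spike_count, 0, 2 * pi)
      s <- sqrt(1 - u^2)
      cbind(s * cos(th), s * sin(th), u)
    })
    nz <- r > 0
    ux <- cx[nz] / r[nz]; uy <- cy[nz] / r[nz]; uz <- cz[nz] / r[nz]
    bump <- rep(0, sum(nz))
    for (k in seq_len(spec$spike_count)) {
      cosang <- pmin(pmax(ux * dirs[k, 1] + uy * dirs[k, 2] + uz * dirs[k, 3], -1), 1)
      ang <- acos(cosang)
      bump <- bump + spec$spike_amplitude_mm * exp(-(ang / spec$spike_width_rad)^2)
    }
    rad[nz] <- rad[nz] + bump
  }
  rad
}

#' Closed-form volumetry of an ideal sphere
#'
#' The analytic oracle for the digitized-sphere features: volume
#' 4/3 pi r^3, shell volume 4/3 pi (r^3 - (r - t)^3), compactness from their
#' ratio, axes 2r, and the cylinder volume of the bounding cylinder.
#'
#' @param radius_mm Sphere radius in mm (> `shell_mm`).
#' @param shell_mm Shell (contraction) depth in mm, default 1.
#' @return A one-row tibble shaped like [extract_features()] output.
#' @export
analytic_sphere_features <- function(radius_mm, shell_mm = 1) {
  if (!is.numeric(radius_mm) || radius_mm <= shell_mm) {
    stop("`radius_mm` must exceed `shell_mm`", call. = FALSE)
  }
  r <- radius_mm / 10 # cm
  t <- shell_mm / 10
  rtv <- 4 / 3 * pi * r^3
  sa <- 4 / 3 * pi * (r^3 - (r - t)^3)
  compactness <- rtv / sa^1.5
  tibble::tibble(
    id = NA_character_,
    rtv_cm3 = rtv,
    sa_rtv_cm3 = sa,
    compactness = compactness,
    long_axis_cm = 2 * r,
    diameter_cm = 2 * r,
    catv_cm3 = pi * r^2 * (2 * r),
    tctv_cm3 = rtv / compactness,
    n_components = 1L,
    flags = ""
  )
}

#' Perturb a mask boundary to emulate a second reader
#'
#' Adds a smooth random field (a sum of seeded random plane waves, rescaled
#' so its maximum magnitude equals `boundary_noise_mm`) to the signed
#' distance of the contour and re-thresholds. The contour therefore moves in
#' or out by at most `boundary_noise_mm` in physical units, emulating
#' inter-observer contouring variability without changing topology in ways a
#' reader would not.
#'
#' @inheritParams mask_spacing
#' @param boundary_noise_mm Maximum boundary displacement in mm (>= 0); 0
#'   returns the input unchanged.
#' @param seed Integer seed for the random field.
#' @param n_waves Number of plane waves in the field.
#' @return A [seg_mask()] on the same grid.
#' @export
simulate_reader <- function(mask, boundary_noise_mm, seed = 1L, n_waves = 8L) {
  assert_nonempty(mask, "reader simulation")
  if (!is.numeric(boundary_noise_mm) || boundary_noise_mm < 0) {
    stop("`boundary_noise_mm` must be >= 0", call. = FALSE)
  }
  if (boundary_noise_mm == 0) {
    return(mask)
  }
  sp <- mask_spacing(mask)
  d <- dim(mask)
  # signed distance to the mask surface: center distances are offset by half
  # a voxel so boundary voxels sit near zero rather than at a full voxel
  h <- mean(sp) / 2
  sdist <- ifelse(mask,
    pmax(sqrt(distance_to_background_sq(mask)) - h, 0),
    -pmax(sqrt(distance_to_foreground_sq(mask)) - h, 0)
  )
  dim(sdist) <- d

  field <- withr::with_seed(as.integer(seed), {
    # wavelengths of ~15-60 mm: smooth on the tumor scale
    kmag <- stats::runif(n_waves, 2 * pi / 60, 2 * pi / 15)
    u <- stats::runif(n_waves, -1, 1)
    th <- stats::runif(n_waves, 0, 2 * pi)
    ph <- stats::runif(n_waves, 0, 2 * pi)
    amp <- stats::runif(n_waves, 0.5, 1)
    s <- sqrt(1 - u^2)
    dirs <- cbind(s * cos(th), s * sin(th), u) * kmag
    cx <- ((slice.index(array(0, d), 1)) - 1) * sp[1]
    cy <- ((slice.index(array(0, d), 2)) - 1) * sp[2]
    cz <- ((slice.index(array(0, d), 3)) - 1) * sp[3]
    f <- 0
    for (k in seq_len(n_waves)) {
      f <- f + amp[k] * cos(dirs[k, 1] * cx + dirs[k, 2] * cy + dirs[k, 3] * cz + ph[k])
    }
    f
  })
  field <- field / max(abs(field)) * boundary_noise_mm
  out <- array(sdist + field > 0, dim = d)
  seg_mask(out, spacing = sp, origin = attr(mask, "origin"))
}
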