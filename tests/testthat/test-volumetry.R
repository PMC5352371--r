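test_that("RTV is voxel count times physical voxel volume", {
  expect_equal(compute_rtv(single_voxel_mask()), 0.001)
  expect_equal(compute_rtv(tiny_box_mask(10, spacing = c(2, 2, 2))), 8)
  # digitized sphere against the closed form
  ph <- make_phantom(shape_spec("sphere", radius_mm = 18.8, spacing = rep(0.5, 3)))
  expect_lt(abs(compute_rtv(ph) / (4 / 3 * pi * 1.88^3) - 1), 0.01)
})

test_that("contraction matches the brute-force smoothed-interface oracle", {
  # depths chosen so no lattice distance lands exactly on the threshold,
  # where the transform and the exhaustive search could round differently
  cases <- list(
    list(sp = c(1, 1, 1), depth = 1),
    list(sp = c(0.8, 1.2, 2), depth = 0.9)
  )
  for (cs in cases) {
    masks <- list(
      tiny_box_mask(6, spacing = cs$sp),
      make_phantom(shape_spec("sphere", radius_mm = 4.5, spacing = cs$sp, seed = 2)),
      {
        a <- array(0L, c(8, 7, 6))
        a[2:6, 2:6, 2:5] <- 1L
        a[3, 3, 3] <- 0L # internal dent
        seg_mask(a, spacing = cs$sp)
      }
    )
    for (m in masks) {
      got <- contract_mask(m, cs$depth)
      want <- brute_force_contract(m, cs$depth)
      expect_identical(
        as.logical(got), as.logical(want),
        label = paste("contraction vs oracle, spacing", paste(cs$sp, collapse = "x"))
      )
    }
  }
})

test_that("box and degenerate contraction examples are exact", {
  box <- tiny_box_mask(20) # 20 mm cube at 1 mm
  inner <- contract_mask(box, 1)
  expect_equal(sum(inner), 5832L) # 18 mm interior cube
  expect_equal(compute_sa_surrogate(box), (8000 - 5832) / 1000)

  expect_false(any(contract_mask(single_voxel_mask(), 1)))
  # thin slab dissolves: shell equals full volume, compactness = RTV^-0.5
  slab <- seg_mask(array(1L, c(10, 10, 1)))
  expect_equal(compute_sa_surrogate(slab), compute_rtv(slab))
  expect_equal(compute_compactness(slab), compute_rtv(slab)^-0.5)
})

test_that("contraction rejects non-positive depth", {
  expect_error(contract_mask(tiny_box_mask(), 0), "positive")
  expect_error(contract_mask(tiny_box_mask(), -1), "positive")
})

test_that("digitized-sphere features converge to closed forms", {
  # at 0.5 mm isotropic: rtv, shell and compactness all within 5%
  for (r in c(15, 18.8)) {
    f <- extract_features(make_phantom(shape_spec("sphere",
      radius_mm = r, spacing = rep(0.5, 3)
    )))
    an <- analytic_sphere_features(r)
    expect_lt(abs(f$rtv_cm3 / an$rtv_cm3 - 1), 0.05)
    expect_lt(abs(f$sa_rtv_cm3 / an$sa_rtv_cm3 - 1), 0.05)
    expect_lt(abs(f$compactness / an$compactness - 1), 0.05)
  }
  # error shrinks as the grid refines
  f1 <- extract_features(make_phantom(shape_spec("sphere",
    radius_mm = 15, spacing = rep(1, 3)
  )))
  f05 <- extract_features(make_phantom(shape_spec("sphere",
    radius_mm = 15, spacing = rep(0.5, 3)
  )))
  an <- analytic_sphere_features(15)
  expect_lt(
    abs(f05$sa_rtv_cm3 - an$sa_rtv_cm3),
    abs(f1$sa_rtv_cm3 - an$sa_rtv_cm3)
  )
})

test_that("shell volume is bounded by the full volume on varied masks", {
  specs <- list(
    shape_spec("sphere", radius_mm = 8, spacing = c(1, 1, 2)),
    shape_spec("ellipsoid", semiaxes_mm = c(14, 7, 7), spacing = rep(1, 3)),
    shape_spec("spiky",
      radius_mm = 8, spike_count = 12, spike_amplitude_mm = 4, seed = 5
    )
  )
  for (s in specs) {
    m <- make_phantom(s)
    rtv <- compute_rtv(m)
    sa <- compute_sa_surrogate(m)
    expect_gt(sa, 0)
    expect_lte(sa, rtv + 1e-12)
  }
})

test_that("axes: degenerate, box-diagonal and sphere cases", {
  ax <- measure_axes(single_voxel_mask())
  expect_equal(ax$long_axis_cm, 0)
  expect_equal(ax$diameter_cm, 0)

  # 50 x 20 x 20 mm box: long axis is the 3D diagonal between extreme
  # voxel centers, diameter the in-plane diagonal
  box <- seg_mask(array(1L, c(50, 20, 20)))
  ax <- measure_axes(box)
  expect_equal(ax$long_axis_cm, sqrt(49^2 + 19^2 + 19^2) / 10, tolerance = 1e-10)
  expect_equal(ax$diameter_cm, sqrt(49^2 + 19^2) / 10, tolerance = 1e-10)

  # brute-force pairwise oracle on a small irregular mask
  a <- array(0L, c(6, 6, 6))
  set.seed(42)
  a[sample(length(a), 25)] <- 1L
  m <- seg_mask(a, spacing = c(1.1, 0.9, 2))
  co <- foreground_coords(m)
  expect_equal(measure_axes(m)$long_axis_cm, max(stats::dist(co)) / 10)

  ph <- make_phantom(shape_spec("sphere", radius_mm = 21, spacing = rep(1, 3)))
  ax <- measure_axes(ph)
  expect_equal(ax$long_axis_cm, 4.2, tolerance = 0.05)
  expect_equal(ax$diameter_cm, 4.2, tolerance = 0.05)
})

test_that("CATV follows the cylinder formula and its scalings", {
  expect_equal(compute_catv(2, 1), pi)
  expect_equal(compute_catv(4.2, 5), pi * 2.1^2 * 5)
  expect_equal(compute_catv(2.4, 3), 4 * compute_catv(1.2, 3))
  expect_error(compute_catv(0, 1), "positive")
  expect_error(compute_catv(1, -2), "positive")
})

test_that("TCTV is RTV over compactness and equals shell^1.5 from a mask", {
  expect_equal(compute_tctv(5, 1), 5)
  expect_equal(compute_tctv(27.75, 1.84), 27.75 / 1.84)
  expect_error(compute_tctv(5, 0), "positive")

  for (spec in list(
    shape_spec("sphere", radius_mm = 9),
    shape_spec("spiky", radius_mm = 7, spike_count = 8, spike_amplitude_mm = 3, seed = 3)
  )) {
    f <- extract_features(make_phantom(spec))
    expect_equal(f$tctv_cm3, f$sa_rtv_cm3^1.5, tolerance = 1e-9)
    expect_equal(f$tctv_cm3, compute_tctv(f$rtv_cm3, f$compactness), tolerance = 1e-12)
  }
})

test_that("extract_features is consistent with the individual operations", {
  m <- make_phantom(shape_spec("ellipsoid", semiaxes_mm = c(12, 8, 8)))
  f <- extract_features(m)
  expect_equal(f$rtv_cm3, compute_rtv(m))
  expect_equal(f$sa_rtv_cm3, compute_sa_surrogate(m))
  expect_equal(f$compactness, compute_compactness(m))
  ax <- measure_axes(m)
  expect_equal(f$long_axis_cm, ax$long_axis_cm)
  expect_equal(f$catv_cm3, compute_catv(ax$diameter_cm, ax$long_axis_cm))
  expect_identical(f$flags, "")
})

test_that("multi-component masks warn and carry a flag", {
  a <- array(0L, c(10, 10, 10))
  a[2:4, 2:4, 2:4] <- 1L
  a[7:9, 7:9, 7:9] <- 1L
  m <- seg_mask(a)
  expect_warning(f <- extract_features(m), "disconnected")
  expect_equal(f$n_components, 2L)
  expect_match(f$flags, "multi_component")
})

test_that("sphere compactness is nearly scale-invariant at fixed shell depth", {
  f15 <- extract_features(make_phantom(shape_spec("sphere", radius_mm = 15)))
  f25 <- extract_features(make_phantom(shape_spec("sphere", radius_mm = 25)))
  expect_lt(abs(f15$compactness / f25$compactness - 1), 0.1)
})

test_that("compactness orders sphere > ellipsoid > spiky at comparable volume", {
  sph <- extract_features(make_phantom(shape_spec("sphere", radius_mm = 12)))
  # 3:1 ellipsoid with the same volume: (a, b, b), a = 3b, 3 b^3 = r^3
  b <- 12 / 3^(1 / 3)
  ell <- extract_features(make_phantom(shape_spec("ellipsoid",
    semiaxes_mm = c(3 * b, b, b)
  )))
  spk <- extract_features(make_phantom(shape_spec("spiky",
    radius_mm = 9.5, spike_count = 40, spike_amplitude_mm = 7,
    spike_width_rad = 0.2, seed = 7
  )))
  expect_gt(sph$compactness, ell$compactness)
  expect_gt(ell$compactness, spk$compactness)
})

test_that("rtv agrees between isotropic and anisotropic digitizations", {
  iso <- make_phantom(shape_spec("sphere", radius_mm = 15, spacing = rep(1, 3)))
  ani <- make_phantom(shape_spec("sphere",
    radius_mm = 15,
    spacing = c(0.78, 1.14, 5)
  ))
  rel <- abs(compute_rtv(ani) / compute_rtv(iso) - 1)
  # discretization bound: one voxel layer over the sphere surface
  bound <- 4 * pi * 1.5^2 * (5 / 2 / 10) / (4 / 3 * pi * 1.5^3)
  expect_lt(rel, bound)
})
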