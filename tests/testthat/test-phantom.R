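test_that("phantom generation is deterministic under a fixed seed", {
  a <- small_phantom(fill = 0.37, seed = 99)
  b <- small_phantom(fill = 0.37, seed = 99)
  expect_identical(a$ct$voxels, b$ct$voxels)
  expect_identical(a$truth$cavities, b$truth$cavities)
  c2 <- small_phantom(fill = 0.37, seed = 100)
  expect_false(identical(a$ct$voxels, c2$ct$voxels))
})

test_that("fill extremes give soft fraction exactly 0 and 1", {
  empty <- small_phantom(fill = 0)
  expect_identical(empty$truth$overall$pabcd, 0)
  expect_true(all(empty$truth$cavities$n_soft == 0))
  full <- small_phantom(fill = 1)
  expect_identical(full$truth$overall$pabcd, 1)
  expect_true(all(full$truth$cavities$n_air == 0))
})

test_that("realized fill is the closest achievable to nominal and recorded exactly", {
  # one large ellipsoid (>= 1e4 voxels) at fill 0.5
  cav <- data.frame(name = "maxillary", side = "left",
                    cx = 16, cy = 16, cz = 16, ax = 14, ay = 14, az = 14,
                    shape = "ellipsoid", type = "sinus")
  sp <- phantom_spec(fill = 0.5, grid_dim = 64, spacing = 0.5,
                     cavities = cav, seed = 1)
  ph <- generate_phantom(sp)
  tr <- ph$truth$cavities
  expect_gt(tr$n_total, 1e4)
  expect_lt(abs(tr$realized_fill - 0.5), 0.01)
  expect_identical(tr$realized_fill, tr$n_soft / tr$n_total)
  # counted in the noise-free label volume, not nominal
  expect_identical(sum(ph$truth$labels == 2L), tr$n_soft)
  expect_identical(sum(ph$truth$labels == 1L), tr$n_air)
})

test_that("cavity volumes conserve: n_air + n_soft equals cavity voxel count", {
  ph <- small_phantom(fill = 0.31, seed = 8)
  cav <- ph$truth$cavities
  expect_identical(cav$n_air + cav$n_soft, cav$n_total)
  mask_counts <- c(vapply(ph$truth$masks$sinus, n_foreground, integer(1)),
                   vapply(ph$truth$masks$omc, n_foreground, integer(1)))
  expect_setequal(mask_counts, cav$n_total)
  expect_equal(n_foreground(ph$truth$masks$total), sum(cav$n_total))
})

test_that("gravity fill places soft tissue below air within each cavity", {
  ph <- small_phantom(fill = 0.5, seed = 4)
  lab <- ph$truth$labels
  for (nm in names(ph$truth$masks$sinus)) {
    m <- ph$truth$masks$sinus[[nm]]
    z_of <- function(code) {
      w <- which(m & lab == code, arr.ind = TRUE)
      if (nrow(w) == 0) return(NULL)
      w[, 3]
    }
    zs <- z_of(2L); za <- z_of(1L)
    if (!is.null(zs) && !is.null(za))
      expect_lte(min(zs), min(za))
  }
})

test_that("clipped HU noise keeps every voxel inside its class band", {
  ph <- small_phantom(fill = 0.5, seed = 21)
  hu <- ph$ct$voxels; lab <- ph$truth$labels
  expect_true(all(hu[lab == 1L] >= -2000 & hu[lab == 1L] <= -250))
  expect_true(all(hu[lab == 2L] >= -249 & hu[lab == 2L] <= 250))
  expect_true(all(hu[lab == 3L] >= 251 & hu[lab == 3L] <= 2000))
  # hence classification recovers the noise-free labels exactly
  all_mask <- voi_mask(array(TRUE, dim(hu)), reference = ph$ct)
  got <- classify_voxels(ph$ct, all_mask)
  expect_identical(as.vector(unclass(got)), as.vector(lab))
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(fill = 1.2), "\\[0, 1\\]")
  expect_error(phantom_spec(fill = -0.1), "\\[0, 1\\]")
  expect_error(hu_model(air = c(100, 10)), "air HU mean")
  expect_error(hu_model(soft = c(400, 10)), "soft-tissue HU mean")
  # cavity poking out of the grid
  cav <- data.frame(name = "maxillary", side = "left",
                    cx = 2, cy = 16, cz = 16, ax = 5, ay = 5, az = 5,
                    shape = "ellipsoid", type = "sinus")
  expect_error(phantom_spec(fill = .5, grid_dim = 64, cavities = cav),
               "inside the grid")
  # overlapping cavities
  cav2 <- data.frame(name = c("maxillary", "maxillary"),
                     side = c("left", "right"),
                     cx = c(14, 18), cy = 16, cz = 16, ax = 6, ay = 6, az = 6,
                     shape = "ellipsoid", type = "sinus")
  expect_error(generate_phantom(
    phantom_spec(fill = .5, grid_dim = 64, cavities = cav2)), "overlap")
  # sub-voxel cavity between voxel centres rasterizes to zero voxels
  cav3 <- data.frame(name = "maxillary", side = "left",
                     cx = 16.5, cy = 16.5, cz = 16.5,
                     ax = 0.1, ay = 0.1, az = 0.1,
                     shape = "ellipsoid", type = "sinus")
  expect_error(generate_phantom(
    phantom_spec(fill = .5, grid_dim = 64, spacing = 0.5, cavities = cav3)),
    "unachievable")
})

test_that("phantom spec config files round-trip through JSON and YAML", {
  sp <- phantom_spec(fill = c(rep(0.4, 10), 0.8, 0.8), grid_dim = 32,
                     seed = 5)
  for (ext in c(".json", ".yaml")) {
    f <- withr::local_tempfile(fileext = ext)
    write_phantom_spec(sp, f)
    sp2 <- read_phantom_spec(f)
    expect_equal(sp2$grid_dim, sp$grid_dim)
    expect_equal(sp2$cavities$fill, sp$cavities$fill)
    expect_equal(sp2$cavities$cx, sp$cavities$cx)
    a <- generate_phantom(sp); b <- generate_phantom(sp2)
    expect_identical(a$ct$voxels, b$ct$voxels)
  }
})

test_that("paired cohort generator hits the requested effect and is seeded", {
  co <- default_cohort(200, seed = 31)
  f <- cohort_fills(co)
  expect_equal(nrow(f), 200L)
  expect_lt(abs(mean(f$pre) - 0.68), 0.04)
  expect_lt(abs(mean(f$post) - 0.52), 0.04)
  expect_true(all(f$pre >= 0 & f$pre <= 1 & f$post >= 0 & f$post <= 1))

  expect_identical(cohort_fills(default_cohort(20, seed = 3)),
                   cohort_fills(default_cohort(20, seed = 3)))

  one <- default_cohort(1, seed = 2)
  expect_length(one, 1L)
  expect_s3_class(one[[1]]$pre, "phantom_spec")
  expect_s3_class(one[[1]]$post, "phantom_spec")

  expect_error(default_cohort(5, effect = c(1.2, 0.5)), "\\[0, 1\\]")
  expect_error(default_cohort(0), ">= 1")
})

test_that("cohort phantom specs reproduce their nominal fills when rendered", {
  co <- default_cohort(2, seed = 12, grid_dim = 32)
  for (pt in co) {
    ph <- generate_phantom(pt$pre)
    expect_lt(abs(ph$truth$overall$pabcd - pt$fill_pre), 0.02)
    ph2 <- generate_phantom(pt$post)
    expect_lt(abs(ph2$truth$overall$pabcd - pt$fill_post), 0.02)
  }
})
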