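test_that("grid_integral is the Riemann sum times voxel volume", {
  # uniform value 2.0 on a box of total volume 3 bohr^3 (8 voxels of 0.375)
  u <- density_grid(c(0, 0, 0), diag((3 / 8)^(1 / 3) * c(1, 1, 1)),
                    array(2, dim = c(2, 2, 2)))
  expect_equal(grid_integral(u), 6, tolerance = 1e-12)
  z <- density_grid(c(0, 0, 0), diag(3), array(0, dim = c(4, 4, 4)))
  expect_equal(grid_integral(z), 0)
})

test_that("single Gaussian normalized to 5 electrons integrates to 5", {
  tr <- gen_density_triplet(shape = 40, box_len = 16,
                            centers = rbind(c(8, 8, 8)), sigma = 1.2,
                            n_electrons = 5, anion_add = 1, cation_remove = 1)
  expect_equal(grid_integral(tr$neutral), 5, tolerance = 1e-3)
})

test_that("Fukui grids from synthetic densities satisfy their normalizations", {
  tr <- gen_density_triplet(shape = 32, box_len = 24,
                            centers = rbind(c(9, 12, 12), c(15, 12, 12)),
                            n_electrons = c(6, 4),
                            anion_add = c(0, 1), cation_remove = c(1, 0))
  f <- fukui_from_densities(tr$neutral, tr$cation, tr$anion)
  expect_equal(unname(f$integrals[["f_plus"]]), 1, tolerance = 1e-2)
  expect_equal(unname(f$integrals[["f_minus"]]), 1, tolerance = 1e-2)
  expect_equal(unname(f$integrals[["dual"]]), 0, tolerance = 2e-2)
  # dual is exactly f+ - f- voxelwise
  expect_identical(f$dual$values, f$f_plus$values - f$f_minus$values)
  # the added electron went to atom 2 (x = 15): f+ mass sits in x > 12
  xcoord <- tr$neutral$origin[1] +
    (seq_len(32) - 1) * tr$neutral$axes[1, 1]
  right <- xcoord > 12
  vv <- voxel_volume(f$f_plus)
  mass_right <- sum(f$f_plus$values[right, , ]) * vv
  expect_gt(mass_right, 0.95)
})

test_that("identical neutral and anion densities give a zero f+ with warning", {
  tr <- gen_density_triplet(shape = 24, box_len = 24,
                            centers = rbind(c(12, 12, 12)), n_electrons = 8,
                            anion_add = 1, cation_remove = 1)
  w <- testthat::capture_warnings(
    f <- fukui_from_densities(tr$neutral, tr$cation, tr$neutral))
  expect_true(any(grepl("f\\+ integrates to 0", w)))
  expect_true(all(f$f_plus$values == 0))
})

test_that("geometry mismatches are rejected with the differing field named", {
  tr <- gen_density_triplet(shape = 16, box_len = 20,
                            centers = rbind(c(10, 10, 10)), n_electrons = 4,
                            anion_add = 1, cation_remove = 1)
  shifted <- density_grid(tr$anion$origin + 0.5, tr$anion$axes, tr$anion$values)
  expect_error(fukui_from_densities(tr$neutral, tr$cation, shifted),
               "differing origin")
  small <- density_grid(tr$anion$origin, tr$anion$axes,
                        tr$anion$values[1:8, 1:8, 1:8])
  expect_error(fukui_from_densities(tr$neutral, tr$cation, small),
               "differing shape")
})

test_that("Fukui differences are linear in the density perturbation", {
  tr <- gen_density_triplet(shape = 24, box_len = 24,
                            centers = rbind(c(9, 12, 12), c(15, 12, 12)),
                            n_electrons = c(6, 4))
  f1 <- fukui_from_densities(tr$neutral, tr$cation, tr$anion)
  # scale the density differences by 2 (breaks normalization, hence warnings)
  anion2 <- density_grid(tr$neutral$origin, tr$neutral$axes,
                         tr$neutral$values + 2 * (tr$anion$values - tr$neutral$values))
  cation2 <- density_grid(tr$neutral$origin, tr$neutral$axes,
                          tr$neutral$values + 2 * (tr$cation$values - tr$neutral$values))
  f2 <- suppressWarnings(fukui_from_densities(tr$neutral, cation2, anion2))
  expect_equal(f2$f_plus$values, 2 * f1$f_plus$values, tolerance = 1e-12)
  expect_equal(f2$f_minus$values, 2 * f1$f_minus$values, tolerance = 1e-12)
})

test_that("quadrature error of the f+ norm shrinks as the grid is refined", {
  err <- vapply(c(16, 32, 64), function(s) {
    tr <- gen_density_triplet(shape = s, box_len = 24,
                              centers = rbind(c(9, 12, 12), c(15, 12, 12)),
                              n_electrons = c(6, 4))
    f <- suppressWarnings(fukui_from_densities(tr$neutral, tr$cation, tr$anion))
    abs(f$integrals[["f_plus"]] - 1)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("condensed Fukui indices follow the charge-difference formulas", {
  cf <- condensed_fukui(charges_n = c(0.1, -0.1),
                        charges_cation = c(0.9, 0.1),
                        charges_anion = c(-0.4, -0.6))
  expect_equal(cf$f_plus_k, c(0.5, 0.5))
  expect_equal(cf$f_minus_k, c(0.8, 0.2))
  expect_equal(sum(cf$f_plus_k), 1)
  expect_error(condensed_fukui(c(0, 0), c(1, 0), c(0, 0, -1)), "length")
  expect_error(condensed_fukui(c(0, 0), c(0.5, 0), c(0, -1)),
               "cation total charge")
})

test_that("condensed column sums are exact under charge conservation", {
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    qn <- rnorm(n)
    qc <- qn + as.numeric(stats::rmultinom(1, 1000, rep(1, n))) / 1000
    qa <- qn - as.numeric(stats::rmultinom(1, 1000, rep(1, n))) / 1000
    cf <- condensed_fukui(qn, qc, qa)
    s <- attr(cf, "sums")
    # independent summation oracle
    expect_equal(unname(s[["f_plus"]]), sum(qn - qa), tolerance = 1e-10)
    expect_equal(unname(s[["f_plus"]]), 1, tolerance = 1e-10)
    expect_equal(unname(s[["f_minus"]]), 1, tolerance = 1e-10)
    expect_equal(unname(s[["dual"]]), 0, tolerance = 1e-10)
  }
})

test_that("dual-descriptor sign regions count both lobes symmetrically", {
  z <- density_grid(c(0, 0, 0), diag(0.5, 3), array(0, dim = c(8, 8, 8)))
  r0 <- dual_sign_regions(z, threshold = 0.001)
  expect_equal(r0$positive$n_voxels, 0)
  expect_equal(r0$negative$n_voxels, 0)

  # antisymmetric grid: mirror-image positive and negative blobs
  tr <- gen_density_triplet(shape = 32, box_len = 24,
                            centers = rbind(c(9, 12, 12), c(15, 12, 12)),
                            n_electrons = c(5, 5),
                            anion_add = c(1, 0), cation_remove = c(0, 1))
  f <- fukui_from_densities(tr$neutral, tr$cation, tr$anion)
  r <- dual_sign_regions(f$dual, threshold = 1e-4)
  expect_lte(abs(r$positive$n_voxels - r$negative$n_voxels), 1)
  expect_equal(r$positive$mass, -r$negative$mass, tolerance = 1e-6)

  rbig <- dual_sign_regions(f$dual, threshold = max(abs(f$dual$values)) * 1.01)
  expect_equal(rbig$positive$n_voxels + rbig$negative$n_voxels, 0)
})
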