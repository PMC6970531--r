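test_that("superposition recovers exact transforms and never reflects", {
  set.seed(10)
  B <- matrix(rnorm(60, sd = 5), ncol = 3)
  sp0 <- superpose(B, B)
  expect_equal(sp0$rmsd, 0)
  expect_equal(sp0$transform$rotation, diag(3), tolerance = 1e-9)

  R <- rnapdyn:::rotation_about_axis(c(0, 0, 1), 37)
  A <- t(R %*% t(B)) + matrix(c(1, -2, 3), nrow(B), 3, byrow = TRUE)
  sp <- superpose(A, B)
  expect_lt(sp$rmsd, 1e-9)
  aa <- axis_angle_decompose(sp$transform$rotation)
  expect_equal(aa$angle, 37, tolerance = 1e-6)
  expect_equal(det(sp$transform$rotation), 1, tolerance = 1e-9)
  expect_error(superpose(A[1:2, ], B[1:2, ]), "at least 3")
})

test_that("SVD superposition matches the quaternion oracle on noisy clouds", {
  set.seed(11)
  for (i in 1:200) {
    B <- matrix(rnorm(150, sd = 4), ncol = 3)
    R <- random_rotation()
    A <- t(R %*% t(B)) + matrix(rnorm(3, sd = 10), 50, 3, byrow = TRUE) +
      matrix(rnorm(150, sd = 0.1), ncol = 3)
    expect_equal(superpose(A, B)$rmsd, quat_superpose_oracle(A, B)$rmsd,
                 tolerance = 1e-9)
  }
})

test_that("rmsd is invariant under rigid motion of either input and symmetric", {
  set.seed(12)
  B <- matrix(rnorm(90, sd = 6), ncol = 3)
  A <- B + matrix(rnorm(90, sd = 0.3), ncol = 3)
  base <- superpose(A, B)$rmsd
  for (i in 1:10) {
    R <- random_rotation(); t1 <- rnorm(3, sd = 20)
    A2 <- t(R %*% t(A)) + matrix(t1, nrow(A), 3, byrow = TRUE)
    expect_equal(superpose(A2, B)$rmsd, base, tolerance = 1e-9)
    expect_equal(superpose(B, A2)$rmsd, base, tolerance = 1e-9)
  }
})

test_that("pairing matches atoms by identity and reports the unmatched", {
  m <- make_ideal_helix(30)
  full <- pair_common_atoms(m, m)
  expect_equal(full$n, 30L)

  keep <- m$atoms$resno < 5 | m$atoms$resno > 10
  m2 <- atom_model(m$atoms[keep, ], "truncated")
  pr <- pair_common_atoms(m, m2)
  expect_equal(pr$n, 24L)
  expect_length(pr$unmatched_a, 6L)
  expect_length(pr$unmatched_b, 0L)
  expect_error(pair_common_atoms(m, atom_model(m$atoms[1, , drop = FALSE])),
               "insufficient")
})

test_that("rmsd_between is zero against itself and honors exclusions", {
  td <- make_two_domain_model(angle = 25, seed = 4)
  self <- rmsd_between(td$reference, td$reference)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)

  ## moving domain inflates global rmsd; excluding it restores ~0
  both <- rmsd_between(td$reference, td$moved)
  expect_gt(both$rmsd, 1)
  core_only <- rmsd_between(td$reference, td$moved,
                            exclude = parse_selection("B:1-60"))
  expect_lt(core_only$rmsd, 1e-9)
  expect_equal(core_only$n_atoms, 60L)
  ## symmetry of the reported rmsd
  expect_equal(rmsd_between(td$moved, td$reference)$rmsd, both$rmsd,
               tolerance = 1e-9)
})

test_that("axis-angle decomposition handles canonical and random rotations", {
  id <- axis_angle_decompose(diag(3))
  expect_equal(id$angle, 0)
  expect_false(id$reliable)

  z90 <- axis_angle_decompose(rnapdyn:::rotation_about_axis(c(0, 0, 1), 90))
  expect_equal(z90$angle, 90, tolerance = 1e-9)
  expect_equal(z90$axis, c(0, 0, 1), tolerance = 1e-9)

  expect_error(axis_angle_decompose(diag(c(1, 1, -1))), "determinant")
  expect_error(axis_angle_decompose(matrix(rnorm(9), 3)), "orthonormal")

  set.seed(13)
  for (i in 1:2000) {
    R <- random_rotation()
    aa <- axis_angle_decompose(R)
    oracle <- quat_axis_angle_oracle(R)
    expect_equal(aa$angle, oracle$angle, tolerance = 1e-9)
    ## round trip for well-conditioned angles
    if (aa$angle > 0.1 && aa$angle < 179.9)
      expect_equal(rnapdyn:::rotation_about_axis(aa$axis, aa$angle), R,
                   tolerance = 1e-6)
  }
})

test_that("screw decomposition recovers pivot and translation along the axis", {
  axis <- c(0, 0, 1)
  pivot <- c(5, -3, 2)
  R <- rnapdyn:::rotation_about_axis(axis, 50)
  t_vec <- as.numeric(pivot - R %*% pivot) + 1.25 * axis   # screw of 1.25 A
  aa <- screw_decompose(list(rotation = R, translation = t_vec),
                        reference_point = pivot)
  expect_equal(aa$angle, 50, tolerance = 1e-9)
  expect_equal(abs(sum(aa$axis * axis)), 1, tolerance = 1e-9)
  expect_equal(abs(aa$screw_translation), 1.25, tolerance = 1e-9)
  expect_equal(aa$pivot, pivot, tolerance = 1e-6)
})

test_that("domain rotation recovers constructed motions and flags degeneracy", {
  core <- parse_selection("A:1-60"); dom <- parse_selection("B:1-60")
  td <- make_two_domain_model(angle = 121, axis = c(2, -1, 0.5), seed = 21)
  aa <- domain_rotation(td$reference, td$moved, core, dom)
  expect_equal(aa$angle, 121, tolerance = 1e-6)
  expect_gte(abs(sum(aa$axis * td$truth$parameters$axis)), 0.999999)

  ## zero rotation: angle ~0 and axis flagged unreliable
  td0 <- make_two_domain_model(angle = 0, seed = 22)
  aa0 <- domain_rotation(td0$reference, td0$moved, core, dom)
  expect_lt(aa0$angle, 0.1)
  expect_false(aa0$reliable)

  expect_error(domain_rotation(td$reference, td$moved,
                               parse_selection("A:1-60;B:1-5"), dom),
               "overlap")
})

test_that("kink angle is ~0 on a straight helix and recovers applied bends", {
  straight <- make_ideal_helix(30)
  k0 <- kink_angle(straight, parse_selection("A:1-30"), 15)
  expect_lt(k0$angle, 2)

  kh <- make_kinked_helix(30, 15, 30)
  k30 <- kink_angle(kh$model, parse_selection("A:1-30"), 15)
  expect_equal(k30$angle, 30, tolerance = 1)
  expect_equal(k30$kink_residue, 15)

  ## flank window too short
  expect_error(kink_angle(straight, parse_selection("A:12-18"), 15),
               "at least 6")
})

test_that("minimum distance matches hand values and the brute-force oracle", {
  two <- atom_model(data.frame(
    chain = c("A", "B"), resno = c(1, 1), insert = NA, resid = "ALA",
    elety = "CA", elesy = "C", x = c(0, 3), y = c(0, 4), z = 0, o = 1,
    alt = NA))
  d <- min_distance(two, parse_selection("A:1"), parse_selection("B:1"))
  expect_equal(d$distance, 5)

  set.seed(14)
  n <- 80
  m <- atom_model(data.frame(
    chain = rep(c("A", "B"), each = n), resno = rep(1:n, 2), insert = NA,
    resid = "ALA", elety = "CA", elesy = "C",
    x = rnorm(2 * n, sd = 15), y = rnorm(2 * n, sd = 15),
    z = rnorm(2 * n, sd = 15), o = 1, alt = NA))
  got <- min_distance(m, parse_selection(sprintf("A:1-%d", n)),
                      parse_selection(sprintf("B:1-%d", n)))
  xa <- coords(m)[m$atoms$chain == "A", ]; xb <- coords(m)[m$atoms$chain == "B", ]
  expect_equal(got$distance, min_distance_bruteforce(xa, xb),
               tolerance = 1e-12)
  expect_error(min_distance(m, parse_selection("Z:1"), parse_selection("B:1")),
               "empty")
})

test_that("interface area matches the two-sphere analytic value and vanishes with distance", {
  two_atoms <- function(d) atom_model(data.frame(
    chain = "A", resno = c(1, 2), insert = NA, resid = "ALA",
    elety = "CA", elesy = "C", x = c(0, d), y = 0, z = 0, o = 1, alt = NA))
  sa <- parse_selection("A:1"); sb <- parse_selection("A:2")

  ## overlapping equal spheres: buried area = 2 pi R^2 (1 - d / 2R) each
  R <- 1.70 + 1.4
  for (d in c(2.0, 3.5, 5.0)) {
    analytic <- 2 * pi * R^2 * (1 - d / (2 * R))
    expect_equal(interface_area(two_atoms(d), sa, sb), analytic,
                 tolerance = 0.02 * analytic + 1e-9)
  }
  ## beyond contact distance the interface is exactly zero
  expect_equal(interface_area(two_atoms(2 * R + 0.1), sa, sb), 0)

  ## monotone decrease toward zero with separation
  areas <- vapply(c(2, 3, 4, 5, 6), function(d)
    interface_area(two_atoms(d), sa, sb), numeric(1))
  expect_true(all(diff(areas) < 0))
  expect_error(interface_area(two_atoms(3), sa, sa), "overlap")
})
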