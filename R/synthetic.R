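## synthetic: deterministic generators with known ground truth
##
## Every generator returns (or attaches) a ground_truth record so the
## analysis pipeline can be checked end-to-end against known parameters.
## Coordinate noise is isotropic Gaussian per atom; eigenvalue ensembles
## are exactly Gaussian (the distribution observed for clamp components).

ground_truth <- function(kind, ...) {
  structure(list(kind = kind, parameters = list(...)), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s: %s\n", x$kind,
              paste(names(x$parameters), collapse = ", ")))
  invisible(x)
}

helix_coords <- function(n_res, rise, twist, radius) {
  i <- seq_len(n_res) - 1L
  th <- deg2rad(twist) * i
  cbind(radius * cos(th), radius * sin(th), rise * i)
}

ca_model <- function(xyz, chain = "A", resno = seq_len(nrow(xyz)),
                     source_id = "synthetic") {
  atom_model(data.frame(chain = chain, resno = resno, insert = NA_character_,
                        resid = "ALA", elety = "CA", elesy = "C",
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        o = 1, alt = NA_character_,
                        stringsAsFactors = FALSE),
             source_id = source_id)
}

#' Ideal alpha-helix (alpha carbons only)
#'
#' Deterministic Calpha trace of an ideal helix along +z: radius 2.3
#' Angstrom, 1.5 Angstrom rise and 100 degree twist per residue (the
#' canonical alpha-helix parameters; consecutive Calpha are then about 3.8
#' Angstrom apart).
#'
#' @param n_res number of residues (>= 6).
#' @param rise rise per residue, Angstrom.
#' @param twist twist per residue, degrees.
#' @param radius helix radius, Angstrom.
#' @param chain chain id.
#' @return an [atom_model()] of `n_res` CA atoms.
#' @export
make_ideal_helix <- function(n_res, rise = 1.5, twist = 100, radius = 2.3,
                             chain = "A") {
  if (n_res < 6L) stopf("need at least 6 residues for a helix, got %d", n_res)
  ca_model(helix_coords(n_res, rise, twist, radius), chain = chain,
           source_id = "synthetic ideal helix")
}

#' Ideal helix with a known kink
#'
#' Builds an ideal helix and rotates the downstream half by `kink_angle`
#' about `kink_axis` through the Calpha of the kink residue.
#'
#' @param n_res residues (kink must have >= 6 residues on each side).
#' @param kink_pos kink residue index.
#' @param kink_angle applied rotation, degrees.
#' @param kink_axis rotation axis (default x, perpendicular to the helix
#'   axis, so the applied rotation equals the bend between the two helix
#'   axes).
#' @inheritParams make_ideal_helix
#' @return list with `model` ([atom_model()]) and `truth`
#'   (ground-truth record of the applied kink).
#' @export
make_kinked_helix <- function(n_res, kink_pos, kink_angle,
                              kink_axis = c(1, 0, 0),
                              rise = 1.5, twist = 100, radius = 2.3) {
  if (kink_pos < 6L || kink_pos > n_res - 6L)
    stopf("kink_pos %d leaves fewer than 6 residues on one side", kink_pos)
  xyz <- helix_coords(n_res, rise, twist, radius)
  if (kink_angle != 0) {
    R <- rotation_about_axis(kink_axis, kink_angle)
    pivot <- xyz[kink_pos, ]
    down <- (kink_pos + 1L):n_res
    xyz[down, ] <- t(R %*% (t(xyz[down, , drop = FALSE]) - pivot)) +
      matrix(pivot, length(down), 3, byrow = TRUE)
  }
  list(model = ca_model(xyz, source_id = "synthetic kinked helix"),
       truth = ground_truth("kink", angle = kink_angle,
                            axis = unit3(kink_axis), residue = kink_pos))
}

#' Two-domain model pair with a known rigid rotation
#'
#' Builds two rigid Calpha clusters on distinct chains (core on chain A,
#' domain on chain B) and a moved copy in which the domain chain is rotated
#' by a known angle about a known axis through the domain centroid.
#' Optional isotropic Gaussian noise is added to the moved copy only,
#' emulating independent coordinate error in the second model.
#'
#' @param core_n,domain_n atoms per cluster (>= 10).
#' @param angle applied rotation, degrees.
#' @param axis rotation axis (any non-zero 3-vector; normalized).
#' @param noise_sd per-coordinate Gaussian noise on the moved copy,
#'   Angstrom.
#' @param spread cluster standard deviation, Angstrom (controls lever
#'   arm).
#' @param seed RNG seed (generators are deterministic given the seed).
#' @return list with `reference`, `moved` ([atom_model()]s) and `truth`
#'   (applied angle, unit axis, pivot).
#' @export
make_two_domain_model <- function(core_n = 60L, domain_n = 60L, angle = 10,
                                  axis = c(0, 0, 1), noise_sd = 0,
                                  spread = 8, seed = 0L) {
  if (core_n < 10L || domain_n < 10L)
    stopf("core_n and domain_n must each be >= 10")
  axis <- unit3(as.numeric(axis))
  with_seed(seed, {
    core <- matrix(stats::rnorm(core_n * 3, sd = spread), ncol = 3)
    dom <- matrix(stats::rnorm(domain_n * 3, sd = spread), ncol = 3)
    dom <- sweep(dom, 2, c(30, 0, 0), "+")
    pivot <- colMeans(dom)
    R <- rotation_about_axis(axis, angle)
    dom_moved <- t(R %*% (t(dom) - pivot)) +
      matrix(pivot, domain_n, 3, byrow = TRUE)
    noise <- function(m) if (noise_sd > 0)
      m + matrix(stats::rnorm(length(m), sd = noise_sd), ncol = 3) else m
    build <- function(core_xyz, dom_xyz, tag) {
      at <- rbind(
        ca_model(core_xyz, chain = "A")$atoms,
        ca_model(dom_xyz, chain = "B")$atoms)
      atom_model(at, source_id = paste("synthetic two-domain", tag))
    }
    list(reference = build(core, dom, "reference"),
         moved = build(noise(core), noise(dom_moved), "moved"),
         truth = ground_truth("rotation", angle = angle, axis = axis,
                              pivot = pivot, noise_sd = noise_sd,
                              seed = seed))
  })
}

#' Gaussian per-particle eigenvalue ensemble with a known angle map
#'
#' Draws `n` eigenvalues from `N(mu, sigma^2)` and records the linear
#' eigenvalue-to-rotation map, so the tercile rotation (theta_bin) and the
#' 98 percent range (theta_98) have analytic targets: for Gaussian data
#' the outer-tercile means sit `2 * 3 * dnorm(qnorm(2/3)) * sigma` apart
#' (about 2.18 sigma) and the 98 percent range is `2 * qnorm(0.99) *
#' sigma` (about 4.65 sigma).
#'
#' @param n particles (>= 100).
#' @param mu,sigma Gaussian parameters (eigenvalue units).
#' @param degrees_per_unit linear map from eigenvalue units to rotation
#'   degrees.
#' @param seed RNG seed.
#' @return list with `series` ([eigenvalue_series()]) and `truth`
#'   (parameters plus `expected_theta_bin` / `expected_theta_98` in the
#'   large-n limit).
#' @export
simulate_eigenvalues <- function(n, mu = 0, sigma = 1, degrees_per_unit = 1,
                                 seed = 0L) {
  if (n < 100L) stopf("need at least 100 particles, got %d", n)
  stopifnot(sigma > 0)
  vals <- with_seed(seed, stats::rnorm(n, mu, sigma))
  tercile_gap <- 2 * 3 * stats::dnorm(stats::qnorm(2 / 3))   # in sigma units
  list(series = eigenvalue_series(vals, source = "synthetic"),
       truth = ground_truth("eigen_map", mu = mu, sigma = sigma,
                            degrees_per_unit = degrees_per_unit, seed = seed,
                            expected_theta_bin =
                              degrees_per_unit * tercile_gap * sigma,
                            expected_theta_98 =
                              degrees_per_unit * 2 * stats::qnorm(0.99) * sigma))
}

#' Preset promoter energy landscapes
#'
#' Package-defined four-step landscapes for a hypothetical inhibited and a
#' hypothetical activated promoter. The exact energies are package
#' choices, not published values; they encode the qualitative kinetic
#' signatures of the two promoter classes:
#' \describe{
#'   \item{inhibited_hypothetical}{low barriers throughout (the open
#'     complex forms fast) and a shallow RPo well, so RPo stays in
#'     equilibrium with earlier intermediates and escape into RNA
#'     synthesis is the slow step.}
#'   \item{activated_hypothetical}{a high RP2 -> RPo barrier (open-complex
#'     formation is slow and rate-limiting) and a very deep RPo well (the
#'     open complex, once formed, is stable for hours).}
#' }
#'
#' @return named list of [energy_landscape()] objects.
#' @export
preset_landscapes <- function() {
  list(
    inhibited_hypothetical = energy_landscape(
      state_G = c(0, -0.5, -1.0, -2.0),
      barrier_G = c(2.0, 1.5, 2.5),
      final_barrier_G = 8.0),
    activated_hypothetical = energy_landscape(
      state_G = c(0, -0.5, -1.0, -8.0),
      barrier_G = c(2.0, 1.5, 6.0),
      final_barrier_G = -5.0)
  )
}
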