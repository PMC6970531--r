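## geometry: superposition, RMSD, domain rotation, kink, distances, interface

#' Pair atoms common to two models
#'
#' Matches atoms sharing (chain, residue number, insertion code, atom name)
#' inside a selection. Residue numbering is assumed comparable across models
#' of the same protein (author numbering); no sequence alignment is done.
#'
#' @param model_a,model_b [atom_model()] objects.
#' @param sel optional `selection` restricting the pairing.
#' @param atom_name atom name to pair on (default `"CA"`, the alpha carbon;
#'   `NULL` pairs every atom name).
#' @return list with `xyz_a`, `xyz_b` (N x 3 matrices in identical pairing
#'   order), `n`, and `unmatched_a` / `unmatched_b` (atom keys present in
#'   only one model).
#' @export
pair_common_atoms <- function(model_a, model_b, sel = NULL, atom_name = "CA") {
  if (n_atoms(model_a) == 0L || n_atoms(model_b) == 0L)
    stopf("cannot pair atoms of an empty model")
  grab <- function(m) {
    at <- m$atoms[selection_indices(m, sel), , drop = FALSE]
    if (!is.null(atom_name)) at <- at[at$elety == atom_name, , drop = FALSE]
    at
  }
  a <- grab(model_a); b <- grab(model_b)
  key <- function(at) paste(at$chain, at$resno,
                            ifelse(is.na(at$insert), "", at$insert),
                            at$elety, sep = "\r")
  ka <- key(a); kb <- key(b)
  common <- intersect(ka, kb)
  if (length(common) < 3L)
    stopf("insufficient common atoms for pairing (%d < 3)", length(common))
  ia <- match(common, ka); ib <- match(common, kb)
  ## preserve the order of model_a
  ord <- order(ia)
  ia <- ia[ord]; ib <- ib[ord]
  list(xyz_a = as.matrix(a[ia, c("x", "y", "z")]),
       xyz_b = as.matrix(b[ib, c("x", "y", "z")]),
       n = length(ia),
       unmatched_a = setdiff(ka, kb),
       unmatched_b = setdiff(kb, ka))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Closed-form least-squares superposition of `coords_b` onto `coords_a`
#' via singular value decomposition of the covariance matrix, with a
#' determinant guard so a reflection is never returned.
#'
#' @param coords_a,coords_b N x 3 coordinate matrices in pairing order.
#' @param weights optional per-atom non-negative weights.
#' @return Object of class `superposition`: `transform` (list with 3x3
#'   `rotation` and length-3 `translation`, mapping b onto a as
#'   `R x + t`), `rmsd` (Angstrom, after transformation), `n_atoms`.
#' @export
superpose <- function(coords_a, coords_b, weights = NULL) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  stopifnot(ncol(coords_a) == 3, ncol(coords_b) == 3,
            nrow(coords_a) == nrow(coords_b))
  n <- nrow(coords_a)
  if (n < 3L) stopf("superposition requires at least 3 atom pairs, got %d", n)
  if (any(!is.finite(coords_a)) || any(!is.finite(coords_b)))
    stopf("coordinates contain non-finite values")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  wn <- w / sum(w)
  ca <- colSums(coords_a * wn); cb <- colSums(coords_b * wn)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  H <- t(B * wn) %*% A                      # covariance, b -> a
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d < 0 && sv$d[3] < 1e-10 * max(sv$d[1], 1))
    warning("near-degenerate (planar/collinear) point set; superposition may be ill-conditioned")
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- ca - as.numeric(R %*% cb)
  fitted <- t(R %*% t(coords_b)) + matrix(t_vec, n, 3, byrow = TRUE)
  rmsd <- sqrt(sum(wn * rowSums((coords_a - fitted)^2)))
  structure(list(transform = list(rotation = R, translation = t_vec),
                 rmsd = rmsd, n_atoms = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f Angstrom over %d atoms\n",
              x$rmsd, x$n_atoms))
  invisible(x)
}

apply_transform <- function(xyz, transform) {
  t(transform$rotation %*% t(xyz)) +
    matrix(transform$translation, nrow(xyz), 3, byrow = TRUE)
}

#' RMSD between two models after optimal superposition
#'
#' Pairs common alpha carbons (or another atom name) within `include` minus
#' `exclude`, superposes, and reports the post-fit RMSD.
#'
#' @param model_a,model_b [atom_model()] objects.
#' @param include optional `selection` of atoms to use (default: all).
#' @param exclude optional `selection` of atoms to leave out.
#' @param atom_name atom name to pair (default alpha carbons).
#' @return list with `rmsd` (Angstrom), `n_atoms`, and the full
#'   `superposition`.
#' @export
rmsd_between <- function(model_a, model_b, include = NULL, exclude = NULL,
                         atom_name = "CA") {
  if (!is.null(exclude)) {
    drop_sub <- function(m) {
      keep <- setdiff(selection_indices(m, include),
                      selection_indices(m, exclude))
      atom_model(m$atoms[keep, , drop = FALSE], m$source_id, m$model_number)
    }
    model_a <- drop_sub(model_a); model_b <- drop_sub(model_b)
    include <- NULL
  }
  pr <- pair_common_atoms(model_a, model_b, include, atom_name)
  sp <- superpose(pr$xyz_a, pr$xyz_b)
  list(rmsd = sp$rmsd, n_atoms = pr$n, superposition = sp)
}

#' Decompose a rotation matrix into axis and angle
#'
#' The angle is `acos((trace - 1)/2)` in degrees, restricted to
#' `[0, 180]`. The axis comes from the antisymmetric part of the matrix,
#' with a stable symmetric-part branch near 180 degrees. Below 0.1 degree
#' the axis is numerically undefined and flagged unreliable.
#'
#' @param rotation orthonormal 3x3 matrix with determinant +1 (validated).
#' @return Object of class `axis_angle`: `axis` (unit 3-vector),
#'   `angle` (degrees), `reliable` (logical).
#' @export
axis_angle_decompose <- function(rotation) {
  check_rotation(rotation)
  tr <- sum(diag(rotation))
  angle <- rad2deg(acos(max(-1, min(1, (tr - 1) / 2))))
  v <- c(rotation[3, 2] - rotation[2, 3],
         rotation[1, 3] - rotation[3, 1],
         rotation[2, 1] - rotation[1, 2])
  nv <- sqrt(sum(v^2))
  if (angle < 0.1) {
    axis <- c(0, 0, 1)                      # undefined; flagged
    reliable <- FALSE
  } else if (angle > 135 || nv < 1e-8) {
    ## large angles: the antisymmetric part shrinks with sin(angle); use the
    ## exact symmetric-part identity (R + R^T)/2 = cos(t) I + (1-cos(t)) a a^T
    ct <- (tr - 1) / 2
    S <- (rotation + t(rotation)) / 2 - diag(ct, 3)
    j <- which.max(diag(S))
    axis <- unit3(S[, j])
    if (nv > 1e-12 && sum(axis * v) < 0) axis <- -axis
    reliable <- TRUE
  } else {
    axis <- v / nv
    reliable <- TRUE
  }
  structure(list(axis = axis, angle = angle, reliable = reliable),
            class = "axis_angle")
}

#' @export
print.axis_angle <- function(x, ...) {
  cat(sprintf("<axis_angle> %.3f deg about (%.4f, %.4f, %.4f)%s\n",
              x$angle, x$axis[1], x$axis[2], x$axis[3],
              if (isTRUE(x$reliable)) "" else " [axis unreliable]"))
  if (!is.null(x$screw_translation))
    cat(sprintf("  screw translation %.3f Angstrom; pivot (%.2f, %.2f, %.2f)\n",
                x$screw_translation, x$pivot[1], x$pivot[2], x$pivot[3]))
  invisible(x)
}

#' Axis-angle with screw component and pivot for a full rigid transform
#'
#' Decomposes `x -> R x + t` into a screw motion: rotation angle/axis,
#' translation along the axis, and a pivot point on the axis chosen
#' nearest `reference_point`.
#'
#' @param transform list with `rotation` and `translation` (see
#'   [superpose()]).
#' @param reference_point 3-vector; the returned pivot is the axis point
#'   closest to it (typically a domain centroid).
#' @return `axis_angle` object with `screw_translation` (Angstrom) and
#'   `pivot` fields added.
#' @export
screw_decompose <- function(transform, reference_point = c(0, 0, 0)) {
  aa <- axis_angle_decompose(transform$rotation)
  t_vec <- transform$translation
  a <- aa$axis
  screw <- sum(t_vec * a)
  t_perp <- t_vec - screw * a
  ## points p on the axis satisfy (I - R) p = t_perp; solve by pseudo-inverse
  M <- diag(3) - transform$rotation
  sv <- svd(M)
  pos <- sv$d > 1e-9 * max(sv$d, 1)
  p0 <- if (any(pos))
    sv$v[, pos, drop = FALSE] %*% ((t(sv$u[, pos, drop = FALSE]) %*% t_perp) / sv$d[pos])
  else matrix(0, 3, 1)
  p0 <- as.numeric(p0)
  pivot <- p0 + sum((reference_point - p0) * a) * a
  aa$screw_translation <- screw
  aa$pivot <- pivot
  aa
}

#' Rigid-body rotation of a domain between two conformational states
#'
#' Two-stage "core-then-domain" protocol: superpose `model_b` onto
#' `model_a` using the core selection, then fit the residual rigid
#' transform carrying the domain of `model_a` onto the (core-aligned)
#' domain of `model_b`, and decompose it into a screw motion. The pivot is
#' reported on the rotation axis nearest the domain centroid.
#'
#' @param model_a,model_b [atom_model()] objects of the two states.
#' @param core_sel `selection` for the structural core used as the fixed
#'   reference frame.
#' @param domain_sel `selection` for the moving domain; must be disjoint
#'   from the core.
#' @param atom_name atom name used for pairing (default alpha carbons).
#' @return `axis_angle` object (angle degrees, unit axis, screw
#'   translation, pivot) with extra fields `core_rmsd`, `domain_rmsd`,
#'   `n_core`, `n_domain`.
#' @export
domain_rotation <- function(model_a, model_b, core_sel, domain_sel,
                            atom_name = "CA") {
  ci_a <- selection_indices(model_a, core_sel)
  di_a <- selection_indices(model_a, domain_sel)
  if (length(intersect(ci_a, di_a)))
    stopf("core and domain selections overlap (%d shared atoms)",
          length(intersect(ci_a, di_a)))
  core <- pair_common_atoms(model_a, model_b, core_sel, atom_name)
  sp_core <- superpose(core$xyz_a, core$xyz_b)
  dom <- pair_common_atoms(model_a, model_b, domain_sel, atom_name)
  dom_b_aligned <- apply_transform(dom$xyz_b, sp_core$transform)
  ## residual transform carrying the domain of a onto the domain of b
  sp_dom <- superpose(dom_b_aligned, dom$xyz_a)
  centroid <- colMeans(dom$xyz_a)
  aa <- screw_decompose(sp_dom$transform, reference_point = centroid)
  aa$core_rmsd <- sp_core$rmsd
  aa$domain_rmsd <- sp_dom$rmsd
  aa$n_core <- core$n
  aa$n_domain <- dom$n
  aa
}

## helix axis of consecutive Calpha positions, oriented from first toward
## last residue. Uses the second-difference construction: for points on a
## regular helix the vectors p[i] - 2 p[i+1] + p[i+2] are exactly
## perpendicular to the helix axis (they point at it), so the axis is the
## null direction of their covariance. Unlike a principal-component fit of
## the raw coordinates, this is unbiased for windows covering a
## non-integer number of helical turns.
helix_axis <- function(xyz) {
  n <- nrow(xyz)
  d2 <- xyz[1:(n - 2), , drop = FALSE] - 2 * xyz[2:(n - 1), , drop = FALSE] +
    xyz[3:n, , drop = FALSE]
  ev <- eigen(crossprod(d2), symmetric = TRUE)
  ax <- ev$vectors[, 3]                     # smallest-variance direction
  direction <- xyz[n, ] - xyz[1, ]
  if (sum(ax * direction) < 0) ax <- -ax
  unit3(ax)
}

#' Helix kink angle at a residue
#'
#' Fits a helix axis to the alpha carbons of the upstream and downstream
#' flanks (second-difference axis construction, oriented N to C; unbiased
#' for windows spanning a non-integer number of turns) and returns the
#' angle between the two axes. A straight helix gives an angle near zero.
#' Kink values depend on the flank window; the default is 12 residues.
#'
#' @param model an [atom_model()].
#' @param helix_sel `selection` covering the helix (alpha carbons are
#'   extracted from it).
#' @param kink_residue residue number of the kink (on the helix chain); if
#'   the selection spans several chains, a list `list(chain=, resno=)`.
#' @param flank number of residues fitted on each side (default 12; at
#'   least 6 must be available on each side).
#' @return Object of class `kink_result`: `angle` (degrees),
#'   `upstream_axis`, `downstream_axis` (unit vectors), `kink_residue`.
#' @export
kink_angle <- function(model, helix_sel, kink_residue, flank = 12L) {
  helix <- apply_selection(model, helix_sel)
  at <- helix$atoms[helix$atoms$elety == "CA", , drop = FALSE]
  if (is.list(kink_residue)) {
    at <- at[at$chain == kink_residue$chain, , drop = FALSE]
    kres <- kink_residue$resno
  } else kres <- kink_residue
  at <- at[order(at$resno), , drop = FALSE]
  up <- at[at$resno >= kres - flank & at$resno < kres, , drop = FALSE]
  down <- at[at$resno > kres & at$resno <= kres + flank, , drop = FALSE]
  if (nrow(up) < 6L || nrow(down) < 6L)
    stopf("need at least 6 alpha carbons on each side of residue %s (have %d up, %d down)",
          kres, nrow(up), nrow(down))
  ax_up <- helix_axis(as.matrix(up[, c("x", "y", "z")]))
  ax_down <- helix_axis(as.matrix(down[, c("x", "y", "z")]))
  ang <- rad2deg(acos(max(-1, min(1, sum(ax_up * ax_down)))))
  structure(list(angle = ang, upstream_axis = ax_up,
                 downstream_axis = ax_down, kink_residue = kres),
            class = "kink_result")
}

#' @export
print.kink_result <- function(x, ...) {
  cat(sprintf("<kink_result> %.2f deg at residue %s\n", x$angle, x$kink_residue))
  invisible(x)
}

#' Minimum interatomic distance between two selections
#'
#' @param model an [atom_model()].
#' @param sel_a,sel_b `selection` objects; both must match at least one
#'   atom.
#' @return list with `distance` (Angstrom) and `pair` (two-row data.frame
#'   of the achieving atoms).
#' @export
min_distance <- function(model, sel_a, sel_b) {
  a <- apply_selection(model, sel_a)
  b <- apply_selection(model, sel_b)
  if (n_atoms(a) == 0L || n_atoms(b) == 0L)
    stopf("min_distance: empty selection (%d and %d atoms matched)",
          n_atoms(a), n_atoms(b))
  xa <- coords(a); xb <- coords(b)
  ## squared cross distances via the expansion |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  ij <- arrayInd(which.min(d2), dim(d2))
  list(distance = sqrt(max(0, d2[ij])),
       pair = rbind(a$atoms[ij[1], ], b$atoms[ij[2], ]))
}

## ---- solvent-accessible surface and interface area --------------------

## van der Waals radii (Angstrom) by element symbol
vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               MG = 1.73, ZN = 1.39, FE = 1.40, "NA" = 2.27, K = 2.75,
               CL = 1.75, CA = 2.31, MN = 1.39, CU = 1.40)
vdw_default <- 1.70

atom_radii <- function(model) {
  sy <- toupper(trimws(model$atoms$elesy))
  r <- unname(vdw_radii[sy])
  r[is.na(r)] <- vdw_default
  r
}

## near-uniform points on the unit sphere (golden-section spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with test points on a golden-section spiral. A point on
#' the probe-expanded sphere of an atom counts as accessible if it lies
#' outside every neighbour's probe-expanded sphere.
#'
#' @param model an [atom_model()].
#' @param probe probe radius, Angstrom (default 1.4, water).
#' @param n_points test points per atom (default 960).
#' @return total SASA in square Angstrom; per-atom areas in attribute
#'   `per_atom`.
#' @export
sasa <- function(model, probe = 1.4, n_points = 960L) {
  xyz <- coords(model)
  n <- nrow(xyz)
  if (n == 0L) return(structure(0, per_atom = numeric(0)))
  r <- atom_radii(model) + probe
  pts <- sphere_points(n_points)
  max_r <- max(r)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(di < r[i] + max_r & seq_len(n) != i)
    nb <- nb[di[nb] < r[i] + r[nb]]
    surf <- pts * r[i] + matrix(xyz[i, ], n_points, 3, byrow = TRUE)
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        d2 <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
          (surf[, 3] - xyz[j, 3])^2
        free <- free & d2 > r[j]^2
        if (!any(free)) break
      }
      frac <- sum(free) / n_points
    } else frac <- 1
    per_atom[i] <- 4 * pi * r[i]^2 * frac
  }
  structure(sum(per_atom), per_atom = per_atom)
}

#' Buried interface area between two selections
#'
#' One-sided buried surface area,
#' `(SASA(a) + SASA(b) - SASA(a U b)) / 2`, the usual deposition
#' convention, computed by Shrake-Rupley sampling. Numerical sampling makes
#' cross-implementation agreement approximate (about 10 percent).
#'
#' @param model an [atom_model()].
#' @param sel_a,sel_b disjoint, non-empty `selection` objects.
#' @param probe probe radius, Angstrom.
#' @param n_points Shrake-Rupley points per atom.
#' @return interface area, square Angstrom.
#' @export
interface_area <- function(model, sel_a, sel_b, probe = 1.4, n_points = 960L) {
  ia <- selection_indices(model, sel_a)
  ib <- selection_indices(model, sel_b)
  if (!length(ia) || !length(ib))
    stopf("interface_area: empty selection")
  if (length(intersect(ia, ib)))
    stopf("interface_area: selections overlap (%d shared atoms)",
          length(intersect(ia, ib)))
  sub <- function(idx) atom_model(model$atoms[idx, , drop = FALSE],
                                  model$source_id, model$model_number)
  s_a <- sasa(sub(ia), probe, n_points)
  s_b <- sasa(sub(ib), probe, n_points)
  s_ab <- sasa(sub(sort(c(ia, ib))), probe, n_points)
  max(0, (as.numeric(s_a) + as.numeric(s_b) - as.numeric(s_ab)) / 2)
}
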