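## Independent numerical oracles, deliberately implemented with different
## algorithms than the package (quaternion methods vs SVD; brute force vs
## vectorized) so the two routes can disagree.

## quaternion (w, x, y, z) -> rotation matrix
quat_to_mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

## Horn's closed-form absolute orientation: optimal rigid fit of B onto A.
## Returns list(rotation, translation, rmsd).
quat_superpose_oracle <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  S <- t(Bc) %*% Ac
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  R <- quat_to_mat(q)
  t_vec <- ca - as.numeric(R %*% cb)
  fitted <- t(R %*% t(B)) + matrix(t_vec, nrow(B), 3, byrow = TRUE)
  list(rotation = R, translation = t_vec,
       rmsd = sqrt(mean(rowSums((A - fitted)^2))))
}

## axis-angle extraction via quaternion components
quat_axis_angle_oracle <- function(R) {
  tr <- sum(diag(R))
  ## robust quaternion from matrix (largest-component branch)
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3,2]-R[2,3])/s, (R[1,3]-R[3,1])/s, (R[2,1]-R[1,2])/s)
  } else {
    i <- which.max(diag(R))
    if (i == 1) {
      s <- sqrt(1 + R[1,1] - R[2,2] - R[3,3]) * 2
      q <- c((R[3,2]-R[2,3])/s, s/4, (R[1,2]+R[2,1])/s, (R[1,3]+R[3,1])/s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2,2] - R[1,1] - R[3,3]) * 2
      q <- c((R[1,3]-R[3,1])/s, (R[1,2]+R[2,1])/s, s/4, (R[2,3]+R[3,2])/s)
    } else {
      s <- sqrt(1 + R[3,3] - R[1,1] - R[2,2]) * 2
      q <- c((R[2,1]-R[1,2])/s, (R[1,3]+R[3,1])/s, (R[2,3]+R[3,2])/s, s/4)
    }
  }
  if (q[1] < 0) q <- -q
  angle <- 2 * atan2(sqrt(sum(q[2:4]^2)), q[1]) * 180 / pi
  nxyz <- sqrt(sum(q[2:4]^2))
  axis <- if (nxyz > 1e-12) q[2:4] / nxyz else c(0, 0, 1)
  list(angle = angle, axis = axis)
}

## uniform random rotation from a random quaternion
random_rotation <- function() quat_to_mat(stats::rnorm(4))

## exhaustive double-loop minimum cross distance
min_distance_bruteforce <- function(xa, xb) {
  best <- Inf
  for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb))) {
    d <- sqrt(sum((xa[i, ] - xb[j, ])^2))
    if (d < best) best <- d
  }
  best
}

## union of inclusive integer ranges by enumeration
range_union_oracle <- function(ranges) {
  sort(unique(unlist(lapply(ranges, function(r) seq(r[1], r[2])))))
}
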