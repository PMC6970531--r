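## heterogeneity: per-particle eigenvalue analysis of continuous domain motion
##
## Multibody refinement of cryo-EM particle images yields, per particle, an
## amplitude (eigenvalue) along each principal component of relative body
## motion. These amplitudes are a proxy for a continuous conformational
## coordinate (e.g. clamp opening). This module fits their distribution,
## bins particles into equal-count terciles, calibrates eigenvalue units to
## degrees using an externally measured rotation between the outer-bin mean
## conformations, and extrapolates the rotation range covering 98% of
## particles under a Gaussian model.

#' Construct an eigenvalue series
#' @param values numeric vector, one amplitude per particle.
#' @param component_index which principal component the values belong to.
#' @param source free-text provenance.
#' @return object of class `eigenvalue_series`.
#' @export
eigenvalue_series <- function(values, component_index = 1L, source = "") {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stopf("eigenvalues contain non-finite entries")
  structure(list(values = values, component_index = as.integer(component_index),
                 n_particles = length(values), source = source),
            class = "eigenvalue_series")
}

#' @export
print.eigenvalue_series <- function(x, ...) {
  cat(sprintf("<eigenvalue_series> component %d, %d particles (mean %.4g, sd %.4g)\n",
              x$component_index, x$n_particles, mean(x$values),
              stats::sd(x$values)))
  invisible(x)
}

#' Load per-particle eigenvalues from a delimited text table
#'
#' Accepts whitespace- or comma-delimited numeric tables, one row per
#' particle and one column per principal component. Lines starting with
#' `#` are skipped.
#'
#' @param path file path.
#' @param component column to extract (1-based).
#' @return an [eigenvalue_series()].
#' @export
load_eigenvalues <- function(path, component = 1L) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  if (!length(lines)) stopf("no data rows in '%s'", path)
  sep <- if (grepl(",", lines[1], fixed = TRUE)) "," else ""
  tab <- utils::read.table(text = lines, sep = sep, header = FALSE,
                           colClasses = "character",
                           strip.white = TRUE, blank.lines.skip = TRUE)
  if (component < 1L || component > ncol(tab))
    stopf("component column %d not present (table has %d column(s))",
          component, ncol(tab))
  col <- suppressWarnings(as.numeric(tab[[component]]))
  if (anyNA(col))
    stopf("non-numeric value in column %d at data row %d of '%s'",
          component, which(is.na(col))[1], path)
  eigenvalue_series(col, component_index = component, source = basename(path))
}

#' Write an eigenvalue table
#' @param values numeric vector or matrix (one column per component).
#' @param path output path.
#' @param header optional `#`-prefixed header line.
#' @return `path`, invisibly.
#' @export
write_eigenvalues <- function(values, path, header = NULL) {
  m <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Fit a Gaussian to an eigenvalue distribution
#'
#' `mle` uses the sample moments (population standard deviation, dividing
#' by n, since the fit describes the observed particle ensemble; set
#' `sd_type = "sample"` for the n-1 convention). `histogram_ls` fits a
#' Gaussian density to the normalized histogram by least squares. Both
#' report the sum of squared residuals against the normalized histogram as
#' `goodness`.
#'
#' @param series an [eigenvalue_series()] (n >= 30, positive variance).
#' @param method `"mle"` or `"histogram_ls"`.
#' @param n_bins histogram bins (equal width over mean +/- 4 sd).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return object of class `gaussian_fit` with `mu`, `sigma`, `method`,
#'   `goodness`.
#' @export
fit_gaussian <- function(series, method = c("mle", "histogram_ls"),
                         n_bins = 60L, sd_type = c("population", "sample")) {
  method <- match.arg(method)
  sd_type <- match.arg(sd_type)
  x <- series$values
  n <- length(x)
  if (n < 30L) stopf("need at least 30 particles to fit, got %d", n)
  mu0 <- mean(x)
  var_pop <- mean((x - mu0)^2)
  if (var_pop <= 0) stopf("degenerate eigenvalue series: zero variance")
  sig0 <- sqrt(if (sd_type == "population") var_pop else var_pop * n / (n - 1))
  breaks <- seq(mu0 - 4 * sig0, mu0 + 4 * sig0, length.out = n_bins + 1L)
  inside <- x[x >= breaks[1] & x <= breaks[n_bins + 1L]]
  h <- graphics::hist(inside, breaks = breaks, plot = FALSE)
  if (method == "mle") {
    mu <- mu0; sigma <- sig0
  } else {
    df <- data.frame(mid = h$mids, dens = h$density)
    fit <- minpack.lm::nlsLM(dens ~ stats::dnorm(mid, mu, sigma), data = df,
                             start = list(mu = mu0, sigma = sig0),
                             lower = c(-Inf, 1e-12))
    cf <- stats::coef(fit)
    mu <- unname(cf["mu"]); sigma <- unname(cf["sigma"])
  }
  goodness <- sum((h$density - stats::dnorm(h$mids, mu, sigma))^2)
  structure(list(mu = mu, sigma = sigma, method = method, goodness = goodness),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> mu %.5g, sigma %.5g (%s; SSR %.3g)\n",
              x$mu, x$sigma, x$method, x$goodness))
  invisible(x)
}

#' Divide particles into three equal-count eigenvalue bins
#'
#' Particles are stably sorted by eigenvalue (ties keep input order) and
#' split into low / mid / high terciles. When n is not divisible by 3 the
#' remainder is distributed low, then mid, then high, so bin counts never
#' differ by more than one.
#'
#' @param series an [eigenvalue_series()] with n >= 3.
#' @return object of class `bin_assignment`: `labels` (factor
#'   low/mid/high per particle, input order) and `counts`.
#' @export
equal_count_bins <- function(series) {
  x <- series$values
  n <- length(x)
  if (n < 3L) stopf("need at least 3 particles to bin, got %d", n)
  q <- n %/% 3L; r <- n %% 3L
  counts <- c(low = q + (r >= 1L), mid = q + (r >= 2L), high = q)
  ord <- order(x)                           # stable in R
  lab <- rep(c("low", "mid", "high"), counts)
  labels <- character(n)
  labels[ord] <- lab
  structure(list(labels = factor(labels, levels = c("low", "mid", "high")),
                 counts = counts),
            class = "bin_assignment")
}

#' @export
print.bin_assignment <- function(x, ...) {
  cat(sprintf("<bin_assignment> low %d / mid %d / high %d\n",
              x$counts["low"], x$counts["mid"], x$counts["high"]))
  invisible(x)
}

#' Calibrate eigenvalue units to rotation degrees
#'
#' Given the rotation angle between the mean conformations of the low and
#' high eigenvalue terciles (measured externally, e.g. with
#' [domain_rotation()] on the per-bin reconstructions), derives degrees per
#' eigenvalue unit, assuming the rotation is linear in the eigenvalue (the
#' middle tercile sits half-way between the outer two under this
#' assumption).
#'
#' @param theta_bin rotation between low-bin and high-bin mean
#'   conformations, degrees (>= 0).
#' @param series the [eigenvalue_series()].
#' @param bins its [equal_count_bins()] assignment.
#' @return object of class `motion_calibration`: `theta_bin`,
#'   `eigen_gap` (mean(high) - mean(low)), `degrees_per_unit`.
#' @export
calibrate_rotation <- function(theta_bin, series, bins) {
  stopifnot(is_number(theta_bin), theta_bin >= 0)
  gap <- mean(series$values[bins$labels == "high"]) -
    mean(series$values[bins$labels == "low"])
  if (gap <= 0) stopf("eigenvalue gap between outer bins is not positive (%g)", gap)
  structure(list(theta_bin = theta_bin, eigen_gap = gap,
                 degrees_per_unit = theta_bin / gap),
            class = "motion_calibration")
}

#' Rotation range covering 98 percent of particles
#'
#' Extrapolates, from the Gaussian fit and the calibration, the rotation
#' range containing 98% of the particles (1% excluded from each tail):
#' `theta_98 = degrees_per_unit * (q(1 - tail) - q(tail)) * sigma`, i.e.
#' `2 * 2.3263 * sigma * degrees_per_unit` at the default 1% tails.
#'
#' @param fit a [fit_gaussian()] result.
#' @param calibration a [calibrate_rotation()] result.
#' @param tail fraction excluded from each tail (default 0.01).
#' @param component_label optional text, e.g. "opening/closing".
#' @return object of class `range_estimate`: `theta_bin`, `theta_98`
#'   (degrees), `z_tail`, `component_label`.
#' @export
estimate_range98 <- function(fit, calibration, tail = 0.01,
                             component_label = "") {
  stopifnot(tail > 0, tail < 0.5)
  z <- stats::qnorm(1 - tail)
  theta_98 <- calibration$degrees_per_unit * 2 * z * fit$sigma
  structure(list(theta_bin = calibration$theta_bin, theta_98 = theta_98,
                 z_tail = z, component_label = component_label),
            class = "range_estimate")
}

#' @export
print.range_estimate <- function(x, ...) {
  cat(sprintf("<range_estimate>%s theta_bin %.3f deg, theta_98 %.3f deg (z %.4f)\n",
              if (nzchar(x$component_label)) paste0(" ", x$component_label, ":") else "",
              x$theta_bin, x$theta_98, x$z_tail))
  invisible(x)
}

#' Tabulate clamp-range estimates across complexes and components
#'
#' Runs the full pipeline (Gaussian fit, tercile binning, calibration, 98%
#' range) for each row and returns a tidy table analogous to a bar-chart of
#' tercile (theta_bin) vs extrapolated 98% (theta_98) rotation ranges per
#' complex and motion component.
#'
#' @param rows list of lists with fields `complex` (text), `component`
#'   (text label, e.g. "opening/closing"), `series`
#'   ([eigenvalue_series()]), `theta_bin` (degrees).
#' @param method Gaussian fit method, see [fit_gaussian()].
#' @return data.frame with columns complex, component, n_particles,
#'   theta_bin, theta_98, mu, sigma, goodness.
#' @export
clamp_range_report <- function(rows, method = "mle") {
  cols <- c("complex", "component", "n_particles", "theta_bin", "theta_98",
            "mu", "sigma", "goodness")
  if (!length(rows)) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), 2), cols[1:2]))
    for (cl in cols[3:8]) out[[cl]] <- numeric(0)
    return(out)
  }
  do.call(rbind, lapply(rows, function(r) {
    fit <- fit_gaussian(r$series, method = method)
    bins <- equal_count_bins(r$series)
    cal <- calibrate_rotation(r$theta_bin, r$series, bins)
    rng <- estimate_range98(fit, cal, component_label = r$component)
    data.frame(complex = r$complex, component = r$component,
               n_particles = r$series$n_particles,
               theta_bin = rng$theta_bin, theta_98 = rng$theta_98,
               mu = fit$mu, sigma = fit$sigma, goodness = fit$goodness,
               stringsAsFactors = FALSE)
  }))
}
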