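## kinetics: four-step initiation scheme driven by a free-energy landscape
##
## The promoter cycles through R+P <-> RP1 <-> RP2 <-> RPo -> RP_ITC, the
## last step irreversible (RNA synthesis has begun) and regenerating free
## promoter, the minimal closure admitting a steady-state flux. Energies
## are in units of thermal energy kBT (dimensionless); rates in units of a
## single prefactor, so absolute time is not interpretable -- only ratios
## and fold changes are.

#' Construct a free-energy landscape for initiation
#'
#' @param state_G free energies of the states (kBT), by convention
#'   starting at the free promoter.
#' @param barrier_G transition-state energies between consecutive states
#'   (length `length(state_G) - 1`); every barrier must sit at or above
#'   both flanking wells.
#' @param final_barrier_G transition-state energy of the irreversible
#'   final step (from the last state to the initially transcribing
#'   complex); must be at or above the last well.
#' @param state_names state labels; defaults to the four-step initiation
#'   scheme for four states, generic labels otherwise.
#' @return object of class `energy_landscape`.
#' @export
energy_landscape <- function(state_G, barrier_G, final_barrier_G,
                             state_names = NULL) {
  state_G <- as.numeric(state_G); barrier_G <- as.numeric(barrier_G)
  ns <- length(state_G)
  if (is.null(state_names))
    state_names <- if (ns == 4L) c("R+P", "RP1", "RP2", "RPo") else
      c("R+P", paste0("I", seq_len(max(0, ns - 2L))),
        "RPo")[seq_len(ns)]
  if (ns < 2L) stopf("a landscape needs at least 2 states")
  if (length(barrier_G) != ns - 1L)
    stopf("barrier_G must have length %d (one per transition), got %d",
          ns - 1L, length(barrier_G))
  if (length(state_names) != ns)
    stopf("state_names length (%d) does not match state_G (%d)",
          length(state_names), ns)
  if (!is_number(final_barrier_G)) stopf("final_barrier_G must be a number")
  bad <- which(barrier_G < pmax(state_G[-ns], state_G[-1]) - 1e-12)
  if (length(bad))
    stopf("barrier %d (%s <-> %s) lies below a flanking well",
          bad[1], state_names[bad[1]], state_names[bad[1] + 1L])
  if (final_barrier_G < state_G[ns] - 1e-12)
    stopf("final barrier lies below the %s well", state_names[ns])
  structure(list(state_names = state_names, state_G = state_G,
                 barrier_G = barrier_G, final_barrier_G = final_barrier_G),
            class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat("<energy_landscape> (kBT)\n")
  for (i in seq_along(x$state_G)) {
    cat(sprintf("  %-5s %7.2f\n", x$state_names[i], x$state_G[i]))
    if (i < length(x$state_G))
      cat(sprintf("    barrier %7.2f\n", x$barrier_G[i]))
  }
  cat(sprintf("    final barrier %7.2f (irreversible)\n", x$final_barrier_G))
  invisible(x)
}

#' Transition-state rates from an energy landscape
#'
#' Arrhenius-type mapping: `k_fwd[i] = A exp(-(B[i] - G[i]))`,
#' `k_rev[i] = A exp(-(B[i] - G[i+1]))`,
#' `k_cat = A exp(-(B_final - G[last]))`. The first forward rate is
#' additionally multiplied by `rnap_activity` (pseudo-first-order binding).
#' Detailed balance `k_fwd/k_rev = exp(G[i] - G[i+1])` holds by
#' construction.
#'
#' @param landscape an [energy_landscape()].
#' @param prefactor rate prefactor A (default 1; sets the time unit).
#' @param rnap_activity dimensionless factor on the initial binding step.
#' @return object of class `rate_scheme` with `k_fwd`, `k_rev`, `k_cat`,
#'   `K_B` (equilibrium constant of the initial binding step including
#'   `rnap_activity`), `state_names`.
#' @export
rates_from_landscape <- function(landscape, prefactor = 1, rnap_activity = 1) {
  stopifnot(inherits(landscape, "energy_landscape"),
            is_number(prefactor), prefactor > 0,
            is_number(rnap_activity), rnap_activity > 0)
  G <- landscape$state_G; B <- landscape$barrier_G
  ns <- length(G)
  k_fwd <- prefactor * exp(-(B - G[-ns]))
  k_rev <- prefactor * exp(-(B - G[-1]))
  k_fwd[1] <- k_fwd[1] * rnap_activity
  k_cat <- prefactor * exp(-(landscape$final_barrier_G - G[ns]))
  structure(list(k_fwd = k_fwd, k_rev = k_rev, k_cat = k_cat,
                 K_B = k_fwd[1] / k_rev[1],
                 state_names = landscape$state_names),
            class = "rate_scheme")
}

#' @export
print.rate_scheme <- function(x, ...) {
  cat("<rate_scheme>\n")
  for (i in seq_along(x$k_fwd))
    cat(sprintf("  %s <-> %s: k_fwd %.4g, k_rev %.4g\n",
                x$state_names[i], x$state_names[i + 1], x$k_fwd[i], x$k_rev[i]))
  cat(sprintf("  %s -> output: k_cat %.4g (irreversible)\n",
              x$state_names[length(x$state_names)], x$k_cat))
  invisible(x)
}

## rate matrix of the unicyclic promoter scheme: dp/dt = K p
scheme_matrix <- function(scheme) {
  kf <- scheme$k_fwd; kr <- scheme$k_rev; kc <- scheme$k_cat
  ns <- length(kf) + 1L
  K <- matrix(0, ns, ns)
  for (i in seq_along(kf)) {
    K[i, i] <- K[i, i] - kf[i];     K[i + 1, i] <- K[i + 1, i] + kf[i]
    K[i + 1, i + 1] <- K[i + 1, i + 1] - kr[i]; K[i, i + 1] <- K[i, i + 1] + kr[i]
  }
  K[ns, ns] <- K[ns, ns] - kc
  K[1, ns] <- K[1, ns] + kc                 # output regenerates free promoter
  K
}

new_flux_result <- function(p, scheme) {
  names(p) <- scheme$state_names
  structure(list(occupancies = p,
                 flux_J = scheme$k_cat * p[[length(p)]],
                 fold_change_vs_reference = NULL),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat("<flux_result>\n  occupancies:",
      paste(sprintf("%s %.4f", names(x$occupancies), x$occupancies),
            collapse = ", "),
      sprintf("\n  flux %.6g per promoter per unit time\n", x$flux_J))
  if (!is.null(x$fold_change_vs_reference))
    cat(sprintf("  fold change vs reference: %.4g\n",
                x$fold_change_vs_reference))
  invisible(x)
}

#' Steady-state occupancies and transcription flux (exact linear solve)
#'
#' Solves `K p = 0` with `sum(p) = 1` for the unicyclic promoter scheme in
#' which output regenerates the free promoter, and reports the flux
#' `J = k_cat * p(last state)`.
#'
#' @param scheme a [rates_from_landscape()] result.
#' @return object of class `flux_result`: `occupancies` (sum 1),
#'   `flux_J`.
#' @export
steady_state_flux <- function(scheme) {
  stopifnot(inherits(scheme, "rate_scheme"))
  if (all(c(scheme$k_fwd, scheme$k_rev, scheme$k_cat) == 0))
    stopf("degenerate scheme: all rates are zero")
  K <- scheme_matrix(scheme)
  ns <- nrow(K)
  A <- rbind(K[-ns, , drop = FALSE], rep(1, ns))
  p <- tryCatch(solve(A, c(rep(0, ns - 1L), 1)),
                error = function(e) stopf("singular steady-state system: %s",
                                          conditionMessage(e)))
  if (any(p < -1e-10)) stopf("negative occupancy in steady-state solution")
  p <- pmax(p, 0); p <- p / sum(p)
  new_flux_result(p, scheme)
}

#' Steady state by integrating the master equation (independent oracle)
#'
#' Integrates `dp/dt = K p` with a stiff solver until
#' `max |dp/dt| < tol`, as an independent check on
#' [steady_state_flux()].
#'
#' @param scheme a [rates_from_landscape()] result.
#' @param init initial occupancies (sum 1; default all mass on the free
#'   promoter).
#' @param t_end maximum integration time (prefactor units).
#' @param tol convergence tolerance on `max |dp/dt|`.
#' @return `flux_result`, as [steady_state_flux()].
#' @export
ode_steady_state <- function(scheme, init = NULL, t_end = 1e10, tol = 1e-12) {
  stopifnot(inherits(scheme, "rate_scheme"))
  K <- scheme_matrix(scheme)
  ns <- nrow(K)
  if (is.null(init)) init <- c(1, rep(0, ns - 1L))
  if (abs(sum(init) - 1) > 1e-8) stopf("initial occupancies must sum to 1")
  deriv <- function(t, p, parms) list(as.numeric(K %*% p))
  p <- init
  t0 <- 1 / max(abs(diag(K)), 1e-12)        # fastest relaxation scale
  t_now <- 0
  repeat {
    span <- min(1e4 * t0, t_end - t_now)
    sol <- deSolve::lsoda(p, c(0, span), deriv, parms = NULL,
                          rtol = 1e-12, atol = 1e-14, maxsteps = 100000)
    p <- as.numeric(sol[nrow(sol), -1])
    t_now <- t_now + span
    if (max(abs(K %*% p)) < tol) break
    if (t_now >= t_end)
      stopf("master equation did not reach steady state by t = %g (residual %g)",
            t_end, max(abs(K %*% p)))
  }
  p <- pmax(p, 0); p <- p / sum(p)
  new_flux_result(p, scheme)
}

#' Perturb an energy landscape
#'
#' Adds energy changes to selected barriers and/or wells and re-validates.
#' Negative deltas lower a barrier (accelerating both directions of the
#' transition equally, leaving its equilibrium fixed) or stabilize a state.
#'
#' @param landscape an [energy_landscape()].
#' @param delta_barrier named or indexed numeric vector of barrier changes
#'   (index = transition number, kBT).
#' @param delta_state numeric vector of state changes (index = state
#'   number, kBT).
#' @param delta_final change to the final irreversible barrier.
#' @param label optional text label.
#' @return a new `energy_landscape`; the input is unchanged.
#' @export
apply_perturbation <- function(landscape, delta_barrier = NULL,
                               delta_state = NULL, delta_final = 0,
                               label = "") {
  stopifnot(inherits(landscape, "energy_landscape"))
  G <- landscape$state_G; B <- landscape$barrier_G
  add_deltas <- function(vec, deltas, what) {
    if (is.null(deltas)) return(vec)
    idx <- if (!is.null(names(deltas)) && any(nzchar(names(deltas))))
      as.integer(names(deltas)) else seq_along(deltas)
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > length(vec)))
      stopf("invalid %s index in perturbation", what)
    vec[idx] <- vec[idx] + as.numeric(deltas)
    vec
  }
  B <- add_deltas(B, delta_barrier, "barrier")
  G <- add_deltas(G, delta_state, "state")
  out <- energy_landscape(G, B, landscape$final_barrier_G + delta_final,
                          landscape$state_names)
  attr(out, "label") <- label
  out
}

## common driver for the two shipped scenarios
run_scenario <- function(landscape, perturbed, prefactor, rnap_activity,
                         f_dissoc = 1) {
  basal <- steady_state_flux(
    rates_from_landscape(landscape, prefactor, rnap_activity))
  sch <- rates_from_landscape(perturbed, prefactor, rnap_activity)
  sch$k_cat <- sch$k_cat * f_dissoc
  mut <- steady_state_flux(sch)
  fold <- mut$flux_J / basal$flux_J
  mut$fold_change_vs_reference <- fold
  list(basal = basal, perturbed = mut, fold_change = fold,
       regulation = if (fold < 1) "inhibition" else
         if (fold > 1) "activation" else "none")
}

#' Effect of deleting sigma70 region 1.1
#'
#' Region 1.1 occupies the DNA channel of free holoenzyme and must be
#' ejected late on the path to the open complex; its deletion is modeled
#' as lowering the kinetic barrier separating RP2 and RPo, leaving
#' everything else unchanged.
#'
#' @param landscape basal promoter [energy_landscape()] (four states).
#' @param delta barrier change, kBT (<= 0). The default -3.5 gives an
#'   e^3.5 (about 32-fold) acceleration of the RP2 -> RPo step.
#' @param prefactor,rnap_activity passed to [rates_from_landscape()].
#' @return list with `basal` and `perturbed` [steady_state_flux()]
#'   results, `fold_change`, and a `regulation` label.
#' @export
sigma11_deletion_scenario <- function(landscape, delta = -3.5,
                                      prefactor = 1, rnap_activity = 1) {
  stopifnot(inherits(landscape, "energy_landscape"),
            length(landscape$state_G) == 4L, is_number(delta), delta <= 0)
  pert <- apply_perturbation(landscape, delta_barrier = c("3" = delta),
                             label = "sigma70_1.1 deletion")
  run_scenario(landscape, pert, prefactor, rnap_activity)
}

#' Effect of TraR binding on initiation output
#'
#' TraR is modeled as the same composite landscape perturbation at every
#' promoter: lowering the RP1 <-> RP2 barrier, lowering the free energy of
#' RP2 relative to RPo, and lowering the RP2 <-> RPo barrier. The initial
#' binding step is never modified. Whether the promoter is activated or
#' inhibited is then decided by its basal landscape, not by the
#' perturbation. Optionally, `f_dissoc` in (0, 1] scales the final
#' irreversible rate in the TraR-bound scheme (TraR must dissociate before
#' RNA synthesis can begin); the default 1 models the pure landscape
#' perturbation.
#'
#' @param landscape basal promoter [energy_landscape()] (four states).
#' @param d_barrier_12 change to the RP1 <-> RP2 barrier, kBT (<= 0).
#' @param d_state_RP2 change to the RP2 well, kBT (<= 0).
#' @param d_barrier_2o change to the RP2 <-> RPo barrier, kBT (<= 0).
#' @param f_dissoc multiplicative factor in (0, 1] on the final rate.
#' @param prefactor,rnap_activity passed to [rates_from_landscape()].
#' @return as [sigma11_deletion_scenario()].
#' @export
traR_scenario <- function(landscape, d_barrier_12 = -1.5, d_state_RP2 = -1.0,
                          d_barrier_2o = -2.5, f_dissoc = 1,
                          prefactor = 1, rnap_activity = 1) {
  stopifnot(inherits(landscape, "energy_landscape"),
            length(landscape$state_G) == 4L,
            d_barrier_12 <= 0, d_state_RP2 <= 0, d_barrier_2o <= 0,
            is_number(f_dissoc), f_dissoc > 0, f_dissoc <= 1)
  pert <- apply_perturbation(landscape,
                             delta_barrier = c("2" = d_barrier_12,
                                               "3" = d_barrier_2o),
                             delta_state = c("3" = d_state_RP2),
                             label = "TraR")
  run_scenario(landscape, pert, prefactor, rnap_activity,
               f_dissoc = f_dissoc)
}

## ---- plain-text landscape config --------------------------------------

#' Read an energy landscape from a plain-text config
#'
#' Format, one `key: values` pair per line (`#` comments allowed):
#' \preformatted{
#' states: R+P RP1 RP2 RPo
#' state_G: 0 -0.5 -1 -2
#' barrier_G: 2 1.5 2.5
#' final_barrier_G: 8
#' }
#'
#' @param path file path, or a string `"presets:<label>"` referring to
#'   [preset_landscapes()].
#' @return an [energy_landscape()].
#' @export
read_landscape_config <- function(path) {
  if (grepl("^presets:", path)) {
    label <- sub("^presets:", "", path)
    presets <- preset_landscapes()
    if (!label %in% names(presets))
      stopf("unknown preset '%s' (have: %s)", label,
            paste(names(presets), collapse = ", "))
    return(presets[[label]])
  }
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stopf("malformed landscape config line: '%s'", ln)
    kv[[m[2]]] <- strsplit(trimws(m[3]), "\\s+")[[1]]
  }
  need <- c("state_G", "barrier_G", "final_barrier_G")
  miss <- setdiff(need, names(kv))
  if (length(miss)) stopf("landscape config missing key(s): %s",
                          paste(miss, collapse = ", "))
  energy_landscape(as.numeric(kv$state_G), as.numeric(kv$barrier_G),
                   as.numeric(kv$final_barrier_G),
                   state_names = kv$states %||%
                     c("R+P", "RP1", "RP2", "RPo"))
}

#' Write an energy landscape to a plain-text config
#' @param landscape an [energy_landscape()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landscape_config <- function(landscape, path) {
  writeLines(c(
    paste("states:", paste(landscape$state_names, collapse = " ")),
    paste("state_G:", paste(format(landscape$state_G, digits = 17),
                            collapse = " ")),
    paste("barrier_G:", paste(format(landscape$barrier_G, digits = 17),
                              collapse = " ")),
    paste("final_barrier_G:", format(landscape$final_barrier_G, digits = 17))
  ), path)
  invisible(path)
}
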