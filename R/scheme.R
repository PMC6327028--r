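#' Kinetic scheme of electron relaxation and attachment
#'
#' Parameterizes the multi-species scheme used throughout the package.  An
#' ionizing picosecond pulse creates quasi-free electrons; within the pulse a
#' fraction `1 - exp(-concentration/c37)` is captured by the solute into an
#' excited anion radical, the remainder enters the relaxation cascade
#'
#' \deqn{e_{IR} \xrightarrow{\tau_1} e_{vis} \xrightarrow{\tau_2} e_{sol}
#'       \xrightarrow{1/\tau_{esol} + k_{attach} C} \textrm{ground anion}}
#'
#' while the excited anion decays with `tau_tni` to non-absorbing products
#' (dissociation).  Time constants are in ps except `tau_esol` (microseconds)
#' and `k_esol_attach` (L mol^-1 s^-1).
#'
#' @param tau1 Near-IR ("p-like") state lifetime, ps.
#' @param tau2 Hot-visible-state relaxation time (also the blue-shift time
#'   constant in shifting-mode simulation), ps.
#' @param tau_tni Excited-anion (TNI*) lifetime, ps.
#' @param tau_esol Intrinsic solvated-electron lifetime, microseconds.
#' @param k_esol_attach Rate constant of the slow solvated-electron + solute
#'   attachment step, L mol^-1 s^-1.
#' @param lambda_initial,lambda_final Visible-band shift endpoints, nm
#'   (initial > final).
#' @param c37 Scavenging capacity, mol/L: concentration at which the
#'   unscavenged electron fraction is 1/e.
#' @param concentration Solute concentration, mol/L.
#' @return Object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(tau1 = 45, tau2 = 80, tau_tni = 350,
                           tau_esol = 5, k_esol_attach = 5e7,
                           lambda_initial = 750, lambda_final = 630,
                           c37 = 0.37, concentration = 0) {
  for (nm in c("tau1", "tau2", "tau_tni", "tau_esol", "c37")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a positive number", nm), call. = FALSE)
  }
  if (!is.finite(k_esol_attach) || k_esol_attach < 0)
    stop("`k_esol_attach` must be >= 0", call. = FALSE)
  if (lambda_initial <= lambda_final)
    stop("`lambda_initial` must exceed `lambda_final`", call. = FALSE)
  if (!is.finite(concentration) || concentration < 0)
    stop("`concentration` must be >= 0", call. = FALSE)
  structure(list(tau1 = tau1, tau2 = tau2, tau_tni = tau_tni,
                 tau_esol = tau_esol, k_esol_attach = k_esol_attach,
                 lambda_initial = lambda_initial, lambda_final = lambda_final,
                 c37 = c37, concentration = concentration),
            class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("<kinetic_scheme>\n")
  cat(sprintf("  tau1 %.3g ps | tau2 %.3g ps | tau_tni %.3g ps | tau_esol %.3g us\n",
              x$tau1, x$tau2, x$tau_tni, x$tau_esol))
  cat(sprintf("  k_esol_attach %.3g /M/s | c37 %.3g M | C %.3g M | shift %g -> %g nm\n",
              x$k_esol_attach, x$c37, x$concentration,
              x$lambda_initial, x$lambda_final))
  invisible(x)
}

#' Solvent metadata
#'
#' Dielectric constant and viscosity are carried as experiment metadata only;
#' they do not enter any kinetic equation.
#'
#' @param name Solvent name.
#' @param dielectric_constant Relative permittivity (> 1).
#' @param viscosity Dynamic viscosity in cP (> 0).
#' @return Object of class `solvent_spec`.
#' @export
solvent_spec <- function(name = "diethylene glycol",
                         dielectric_constant = 31.69, viscosity = 35.7) {
  if (!is.finite(dielectric_constant) || dielectric_constant <= 1)
    stop("`dielectric_constant` must exceed 1", call. = FALSE)
  if (!is.finite(viscosity) || viscosity <= 0)
    stop("`viscosity` must be positive", call. = FALSE)
  structure(list(name = name, dielectric_constant = dielectric_constant,
                 viscosity = viscosity), class = "solvent_spec")
}

#' Species order used by the simulator
#'
#' @return Character vector naming the population rows, in fixed order.
#' @export
species_names <- function() {
  c("e_ir", "e_vis", "e_sol", "rt_excited", "rt_ground")
}

# Cascade rates in 1/ps; k3 combines intrinsic solvated-electron decay with
# the slow attachment channel (k_esol_attach converted from /M/s to /M/ps).
.scheme_rates <- function(scheme) {
  list(k1 = 1 / scheme$tau1,
       k2 = 1 / scheme$tau2,
       k3 = 1 / (scheme$tau_esol * 1e6) +
         scheme$k_esol_attach * 1e-12 * scheme$concentration)
}

#' Simulate species populations of the kinetic scheme
#'
#' Evaluates the closed-form solution of the linear relaxation/attachment
#' cascade on a delay grid, without instrument-response broadening.  All
#' populations are fractions of the initial electron yield; at t = 0 the
#' surviving fraction `exp(-C/c37)` sits entirely in the near-IR state and the
#' scavenged fraction `1 - exp(-C/c37)` in the excited anion.  Populations are
#' zero for negative delays.
#'
#' @param scheme A [kinetic_scheme()].
#' @param delays Strictly ascending delay grid, ps.
#' @return Matrix (5 species x delays) with rownames [species_names()].
#' @export
simulate_populations <- function(scheme, delays) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (any(diff(delays) <= 0))
    stop("delay grid must be strictly ascending", call. = FALSE)
  r <- .scheme_rates(scheme)
  k1 <- r$k1; k2 <- r$k2; k3 <- r$k3
  if (min(abs(c(k1 - k2, k1 - k3, k2 - k3))) < 1e-9 * max(k1, k2))
    stop("cascade rates are degenerate (two time constants coincide); ",
         "perturb one of tau1, tau2, tau_esol", call. = FALSE)
  u0 <- exp(-scheme$concentration / scheme$c37)
  f_cap <- 1 - u0
  t <- pmax(delays, 0)
  on_ <- as.numeric(delays >= 0)

  e1 <- exp(-k1 * t); e2 <- exp(-k2 * t); e3 <- exp(-k3 * t)
  e_ir <- u0 * e1
  e_vis <- u0 * k1 / (k2 - k1) * (e1 - e2)
  # Bateman solution for the third member of the chain.
  e_sol <- u0 * k1 * k2 * (e1 / ((k2 - k1) * (k3 - k1)) +
                           e2 / ((k1 - k2) * (k3 - k2)) +
                           e3 / ((k1 - k3) * (k2 - k3)))
  rt_exc <- f_cap * exp(-t / scheme$tau_tni)
  kc <- scheme$k_esol_attach * 1e-12 * scheme$concentration
  rt_gnd <- if (kc == 0) numeric(length(t)) else
    kc * u0 * k1 * k2 * ((1 - e1) / (k1 * (k2 - k1) * (k3 - k1)) +
                         (1 - e2) / (k2 * (k1 - k2) * (k3 - k2)) +
                         (1 - e3) / (k3 * (k1 - k3) * (k2 - k3)))
  pop <- rbind(e_ir, e_vis, e_sol, rt_exc, rt_gnd) *
    rep(on_, each = 5)
  pop[pop < 0 & pop > -1e-12] <- 0  # clip numerical negatives
  rownames(pop) <- species_names()
  pop
}
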