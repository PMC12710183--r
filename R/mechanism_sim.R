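# Mechanistic simulator: two-step electrophilic aromatic substitution
# (addition to a Wheland-type sigma-complex, then re-aromatization) under
# pseudo-first-order, pH-controlled conditions, emitting noisy stopped-flow
# absorbance traces with known ground truth.

#' Fraction of nucleophile present as the reactive free base
#'
#' For a nucleophile whose conjugate acid has the given `pKa`, the fraction
#' of the total concentration that is unprotonated at a given pH is
#' `f = 1 / (1 + 10^(pKa - pH))` (Henderson-Hasselbalch).  Only this free
#' base reacts with the electrophile, so apparent second-order rate
#' constants measured against total concentration must be divided by `f` to
#' obtain the pH-independent constant.
#'
#' @param pH Solution pH (finite numeric, vectorised).
#' @param pKa Conjugate-acid pKa of the nucleophile (default 3.38, the
#'   value for 3-aminothiophene).
#' @return Fraction in (0, 1].
#' @export
free_base_fraction <- function(pH, pKa = 3.38) {
  stopifnot(is.numeric(pH), is.numeric(pKa), all(is.finite(pH)),
            all(is.finite(pKa)))
  1 / (1 + 10^(pKa - pH))
}

#' Ground-truth mechanism parameters
#'
#' Bundles the elementary rate constants of the two-step substitution
#' pathway: bimolecular addition `k1` (M^-1 s^-1) of the electrophile to the
#' free-base nucleophile, and the unimolecular decomposition channels of the
#' cationic intermediate — reversion `k_minus1` (s^-1) and re-aromatization
#' `k2` (s^-1) — plus the nucleophile's conjugate-acid `pKa`.
#'
#' @param k1 Addition rate constant, M^-1 s^-1 (> 0).
#' @param k_minus1 Reversion rate constant, s^-1 (> 0).
#' @param k2 Re-aromatization rate constant, s^-1 (> 0).
#' @param pKa Conjugate-acid pKa (default 3.38).
#' @return An object of class `mechanism_params`.
#' @export
mechanism_params <- function(k1, k_minus1, k2, pKa = 3.38) {
  stopifnot(is.numeric(k1), k1 > 0, is.numeric(k_minus1), k_minus1 >= 0,
            is.numeric(k2), k2 > 0, is.finite(pKa))
  structure(list(k1 = k1, k_minus1 = k_minus1, k2 = k2, pKa = pKa),
            class = "mechanism_params")
}

#' Steady-state pseudo-first-order rate constant
#'
#' Applies the quasi-steady-state approximation to the cationic
#' intermediate: `kobsd = k1 * k2 / (k_minus1 + k2) * f * [Nu]_tot`, where
#' `f` is the free-base fraction at the working pH.  When re-aromatization
#' dominates (`k2 >> k_minus1`) this reduces to `kobsd = k1 * f * [Nu]_tot`,
#' the regime established experimentally by the absence of a kinetic
#' isotope effect.
#'
#' @param params A [mechanism_params()] object.
#' @param conc Total nucleophile concentration, mol L^-1 (> 0).
#' @param pH Solution pH.
#' @return `kobsd` in s^-1.
#' @export
steady_state_kobsd <- function(params, conc, pH) {
  stopifnot(inherits(params, "mechanism_params"))
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("nucleophile concentration must be strictly positive", call. = FALSE)
  }
  partition <- params$k2 / (params$k_minus1 + params$k2)
  params$k1 * partition * free_base_fraction(pH, params$pKa) * conc
}

#' Experiment design for a simulated stopped-flow campaign
#'
#' Describes the conditions of a concentration series at one pH: the total
#' nucleophile concentrations, the (much smaller) electrophile
#' concentration, absorbance endpoints, noise level and sampling grid.
#' Defaults mirror the study conditions: nucleophile 1.0e-3 to 2.8e-2
#' mol L^-1, electrophile 5e-5 mol L^-1, Gaussian absorbance noise of
#' 0.002 AU.  The pseudo-first-order requirement (every nucleophile
#' concentration at least 20-fold above the electrophile) is enforced.
#'
#' @param nucleophile_total_concs Total nucleophile concentrations,
#'   mol L^-1.
#' @param electrophile_conc Initial electrophile concentration, mol L^-1.
#' @param pH Solution pH.
#' @param time_grid Optional strictly increasing sampling times (s).  When
#'   `NULL`, each trace uses 200 points spanning `5 / kobsd`, capturing over
#'   99% of the relaxation.
#' @param A0,A_inf Absorbance at time zero and at equilibrium (AU).
#' @param noise_sd Standard deviation of i.i.d. Gaussian absorbance noise
#'   (AU, >= 0).
#' @param seed Integer random seed for the design.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(nucleophile_total_concs =
                                seq(1.0e-3, 2.8e-2, length.out = 7),
                              electrophile_conc = 5e-5,
                              pH = 1,
                              time_grid = NULL,
                              A0 = 0.05, A_inf = 0.80,
                              noise_sd = 0.002,
                              seed = 1L) {
  stopifnot(length(nucleophile_total_concs) >= 1,
            all(nucleophile_total_concs > 0),
            electrophile_conc > 0, noise_sd >= 0)
  if (any(nucleophile_total_concs < 20 * electrophile_conc)) {
    stop("pseudo-first-order regime requires every nucleophile ",
         "concentration to be at least 20x the electrophile concentration",
         call. = FALSE)
  }
  if (!is.null(time_grid)) {
    stopifnot(length(time_grid) >= 2, all(diff(time_grid) > 0))
  }
  structure(list(nucleophile_total_concs = nucleophile_total_concs,
                 electrophile_conc = electrophile_conc,
                 pH = pH, time_grid = time_grid,
                 A0 = A0, A_inf = A_inf, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

.default_time_grid <- function(kobsd, n = 200L) {
  seq(0, 5 / kobsd, length.out = n)
}

#' Integrate the two-step mechanism
#'
#' Numerically integrates the mass-action system for electrophile `E`,
#' intermediate `I` and product `P` with the nucleophile clamped at its
#' free-base concentration (pseudo-first-order excess):
#' `dE/dt = -k1 f Nu E + k_minus1 I`,
#' `dI/dt =  k1 f Nu E - (k_minus1 + k2) I`,
#' `dP/dt =  k2 I`.
#' Mass balance `E + I + P = E0` is preserved to integrator tolerance.
#'
#' @param params A [mechanism_params()] object.
#' @param conc Total nucleophile concentration, mol L^-1.
#' @param pH Solution pH.
#' @param electrophile_conc Initial electrophile concentration, mol L^-1.
#' @param times Output time points (s); default spans 5 relaxation times of
#'   the steady-state rate.
#' @param rtol,atol Integrator tolerances passed to [deSolve::lsoda()].
#' @return A data frame with columns `time`, `E`, `I`, `P`.
#' @export
simulate_mechanism_ode <- function(params, conc, pH,
                                   electrophile_conc = 5e-5,
                                   times = NULL,
                                   rtol = 1e-10, atol = 1e-14) {
  stopifnot(inherits(params, "mechanism_params"), conc > 0,
            electrophile_conc > 0)
  nu_free <- conc * free_base_fraction(pH, params$pKa)
  if (is.null(times)) {
    times <- .default_time_grid(steady_state_kobsd(params, conc, pH))
  }
  rhs <- function(t, y, p) {
    add <- p$k1 * nu_free * y[["E"]]
    list(c(E = -add + p$k_minus1 * y[["I"]],
           I = add - (p$k_minus1 + p$k2) * y[["I"]],
           P = p$k2 * y[["I"]]))
  }
  sol <- deSolve::lsoda(y = c(E = electrophile_conc, I = 0, P = 0),
                        times = times, func = rhs, parms = params,
                        rtol = rtol, atol = atol)
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0) {
    stop("ODE integration failed: lsoda istate = ",
         attr(sol, "istate")[1], call. = FALSE)
  }
  as.data.frame(sol)
}

#' Generate one stopped-flow absorbance trace
#'
#' Produces a single-exponential relaxation
#' `A(t) = A_inf - (A_inf - A0) * exp(-kobsd * t)` sampled on the design's
#' time grid, with i.i.d. Gaussian noise added.  The generating `kobsd` is
#' recorded in the trace for recovery tests.  Deterministic for a fixed
#' seed.
#'
#' @param kobsd Pseudo-first-order rate constant, s^-1 (> 0).
#' @param time_grid Sampling times (s); default 200 points over `5/kobsd`.
#' @param A0,A_inf Absorbance endpoints (AU); must differ.
#' @param noise_sd Gaussian noise standard deviation (AU).
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @param pH,nucleophile_total_conc Optional condition labels carried on
#'   the trace.
#' @return An object of class `absorbance_trace`: a list with `times`,
#'   `absorbances`, `A0`, `A_inf`, `pH`, `nucleophile_total_conc`,
#'   `true_kobsd`.
#' @export
generate_trace <- function(kobsd, time_grid = NULL, A0 = 0.05, A_inf = 0.80,
                           noise_sd = 0.002, seed = NULL,
                           pH = NA_real_, nucleophile_total_conc = NA_real_) {
  stopifnot(is.numeric(kobsd), kobsd > 0)
  if (isTRUE(all.equal(A0, A_inf))) {
    stop("degenerate trace: A_inf equals A0, no relaxation amplitude",
         call. = FALSE)
  }
  if (is.null(time_grid)) time_grid <- .default_time_grid(kobsd)
  stopifnot(all(diff(time_grid) > 0) || length(time_grid) == 1)
  clean <- A_inf - (A_inf - A0) * exp(-kobsd * time_grid)
  if (!is.null(seed)) set.seed(as.integer(seed))
  noise <- if (noise_sd > 0) stats::rnorm(length(time_grid), 0, noise_sd)
           else rep(0, length(time_grid))
  structure(list(times = time_grid, absorbances = clean + noise,
                 A0 = A0, A_inf = A_inf, pH = pH,
                 nucleophile_total_conc = nucleophile_total_conc,
                 true_kobsd = kobsd),
            class = "absorbance_trace")
}

# Deterministic per-trace substream seed derived from one campaign seed.
# Kept below 2^31 - 1 so it is always a valid R integer.
.trace_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 1000003) * 2011 + 7919 * (as.numeric(index) %% 1000003)
  as.integer(s %% 2147483629)
}

#' Generate a full synthetic coupling study
#'
#' Builds the complete synthetic analogue of the kinetic study: for every
#' electrophile in `truth$E` the ground-truth pH-independent rate constant
#' is computed from the reactivity relation `log10 k1 = sN_true * (E +
#' N_true)`, converted to the apparent constant at each pH through the
#' free-base fraction, and one noisy trace is generated per (electrophile,
#' pH, concentration) cell.  A manifest records all ground truth so that
#' every downstream stage can be scored by parameter recovery.
#'
#' @param truth List with `N_true`, `sN_true`, numeric `E` (named by
#'   electrophile label, or `labels` supplied separately), and optionally
#'   `pKa` (default 3.38).
#' @param design An [experiment_design()]; its `pH` field is ignored in
#'   favour of `ph_values`.
#' @param seed Integer campaign seed; per-trace substreams are derived from
#'   it deterministically.
#' @param ph_values Numeric vector of working pH values (default `c(1, 2)`).
#' @return An object of class `campaign`: list with `traces` (list of
#'   [generate_trace()] objects, each annotated with `label`) and
#'   `manifest` (design, seed, per-electrophile ground truth `k1_true`,
#'   `k_true` per pH, and the generating `N_true`, `sN_true`, `pKa`).
#' @export
generate_campaign <- function(truth, design = experiment_design(),
                              seed = 1L, ph_values = c(1, 2)) {
  stopifnot(is.list(truth), length(truth$E) >= 1,
            is.numeric(truth$N_true), is.numeric(truth$sN_true),
            inherits(design, "experiment_design"))
  pKa <- if (is.null(truth$pKa)) 3.38 else truth$pKa
  labels <- if (!is.null(truth$labels)) truth$labels
            else if (!is.null(names(truth$E))) names(truth$E)
            else sprintf("E%02d", seq_along(truth$E))
  k1_true <- 10^(truth$sN_true * (truth$E + truth$N_true))
  traces <- list()
  idx <- 0L
  for (i in seq_along(truth$E)) {
    for (ph in ph_values) {
      k_app <- unname(k1_true[i]) * free_base_fraction(ph, pKa)
      for (conc in design$nucleophile_total_concs) {
        idx <- idx + 1L
        tr <- generate_trace(kobsd = k_app * conc,
                             time_grid = design$time_grid,
                             A0 = design$A0, A_inf = design$A_inf,
                             noise_sd = design$noise_sd,
                             seed = .trace_seed(seed, idx),
                             pH = ph, nucleophile_total_conc = conc)
        tr$label <- labels[i]
        traces[[idx]] <- tr
      }
    }
  }
  manifest <- list(seed = as.integer(seed),
                   N_true = truth$N_true, sN_true = truth$sN_true,
                   pKa = pKa, ph_values = ph_values,
                   labels = labels, E = unname(truth$E),
                   k1_true = stats::setNames(k1_true, labels),
                   design = unclass(design))
  structure(list(traces = traces, manifest = manifest), class = "campaign")
}

#' @export
print.campaign <- function(x, ...) {
  m <- x$manifest
  cat("Synthetic coupling campaign:", length(m$labels), "electrophiles x",
      length(m$ph_values), "pH x",
      length(m$design$nucleophile_total_concs), "concentrations =",
      length(x$traces), "traces\n")
  cat("  ground truth: N =", m$N_true, ", s_N =", m$sN_true,
      ", pKa =", m$pKa, ", seed =", m$seed, "\n")
  invisible(x)
}

#' @export
print.absorbance_trace <- function(x, ...) {
  cat("Stopped-flow trace:", length(x$times), "points, t in [",
      min(x$times), ",", max(x$times), "] s\n")
  if (!is.na(x$true_kobsd)) cat("  generating kobsd =", x$true_kobsd, "s^-1\n")
  invisible(x)
}
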