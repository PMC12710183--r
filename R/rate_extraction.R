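# Recovery of kobsd from single-exponential absorbance traces, of the
# apparent bimolecular constant k from concentration series, of the
# speciation-corrected k1, and of kinetic isotope effect ratios.

#' Fit the pseudo-first-order rate constant of a relaxation trace
#'
#' Two estimators for the observed rate constant of a single-exponential
#' absorbance relaxation:
#'
#' * `"guggenheim-linear"` — the classical log-linear treatment: regress
#'   `ln(A_inf - A_t)` on `t`; the slope is `-kobsd`.  Points on or past the
#'   equilibrium absorbance (log of a non-positive amplitude) are dropped
#'   with a warning.
#' * `"exp-nonlinear"` — direct least-squares fit of
#'   `A(t) = A_inf - (A_inf - A0) * exp(-kobsd t)` with all three
#'   parameters free (Levenberg-Marquardt), which avoids the noise
#'   distortion the log transform introduces near `A_inf`.
#'
#' @param trace An `absorbance_trace`, or a list/data frame with `times`
#'   and `absorbances` (plus `A0`, `A_inf` when available).
#' @param method `"guggenheim-linear"` (default) or `"exp-nonlinear"`.
#' @param A_inf Equilibrium absorbance.  Defaults to the trace's recorded
#'   value; set `A_inf = "tail"` to estimate it as the mean of the final 5%
#'   of points.
#' @return List with `kobsd` (s^-1), `fit_r2` (determination coefficient of
#'   the regression actually performed), `method`, and `n_used`.
#' @export
fit_kobsd <- function(trace, method = c("guggenheim-linear", "exp-nonlinear"),
                      A_inf = NULL) {
  method <- match.arg(method)
  t <- trace$times
  A <- trace$absorbances
  stopifnot(length(t) == length(A))
  if (length(t) < 5) stop("need at least 5 points to fit kobsd", call. = FALSE)
  if (is.null(A_inf)) {
    A_inf <- trace$A_inf
    if (is.null(A_inf)) A_inf <- "tail"
  }
  if (identical(A_inf, "tail")) {
    n_tail <- max(1L, ceiling(0.05 * length(A)))
    A_inf <- mean(utils::tail(A, n_tail))
  }
  A0 <- if (!is.null(trace$A0)) trace$A0 else A[1]
  rising <- A_inf >= A0
  amp <- if (rising) A_inf - A else A - A_inf

  if (method == "guggenheim-linear") {
    usable <- amp > 0
    if (!all(usable)) {
      warning(sum(!usable), " point(s) at or beyond A_inf dropped from ",
              "log-linear fit", call. = FALSE)
    }
    if (sum(usable) < 5) {
      stop("fewer than 5 usable points for log-linear fit", call. = FALSE)
    }
    fit <- stats::lm(log(amp[usable]) ~ t[usable])
    kobsd <- -unname(stats::coef(fit)[2])
    r2 <- .r_squared(fit)
    # a real relaxation must progress measurably over the observed window
    if (!is.finite(kobsd) || kobsd <= 0 ||
        kobsd * diff(range(t)) < 1e-10) {
      stop("no relaxation detected: fitted kobsd is not positive",
           call. = FALSE)
    }
    return(list(kobsd = kobsd, fit_r2 = r2, method = method,
                n_used = sum(usable)))
  }

  # exp-nonlinear: start from the log-linear estimate where possible
  start_k <- tryCatch(
    suppressWarnings(
      fit_kobsd(trace, method = "guggenheim-linear", A_inf = A_inf)$kobsd),
    error = function(e) 1 / stats::median(t[t > 0]))
  dat <- data.frame(t = t, A = A)
  fit <- minpack.lm::nlsLM(
    A ~ Ainf - (Ainf - A0) * exp(-k * t), data = dat,
    start = list(Ainf = A_inf, A0 = A0, k = start_k),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  kobsd <- unname(co[["k"]])
  if (!is.finite(kobsd) || kobsd <= 0) {
    stop("no relaxation detected: fitted kobsd is not positive", call. = FALSE)
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((A - mean(A))^2)
  list(kobsd = kobsd, fit_r2 = 1 - ss_res / ss_tot, method = method,
       n_used = length(t))
}

#' Second-order rate constant from a concentration series
#'
#' Ordinary least-squares fit of the observed pseudo-first-order rate
#' constants against total nucleophile concentration at one pH.  The slope
#' is the apparent second-order rate constant `k` at that pH; the intercept
#' is a mechanistic diagnostic expected to be zero for an irreversible
#' pathway and is fitted, not forced.
#'
#' @param measurements Data frame with columns `conc` (mol L^-1), `kobsd`
#'   (s^-1) and `pH`; all rows must share one pH.
#' @return An object of class `bimolecular_fit`: list with `k` (slope,
#'   M^-1 s^-1), `intercept` (s^-1), `r2`, `pH`, `n`.
#' @export
fit_bimolecular <- function(measurements) {
  stopifnot(is.data.frame(measurements),
            all(c("conc", "kobsd", "pH") %in% names(measurements)))
  ph <- unique(measurements$pH)
  if (length(ph) != 1) {
    stop("measurements mix pH values (", paste(ph, collapse = ", "),
         "); fit one pH at a time", call. = FALSE)
  }
  if (length(unique(measurements$conc)) < 3) {
    stop("need at least 3 distinct concentrations", call. = FALSE)
  }
  fit <- stats::lm(kobsd ~ conc, data = measurements)
  structure(list(k = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = .r_squared(fit),
                 pH = ph, n = nrow(measurements)),
            class = "bimolecular_fit")
}

#' @export
print.bimolecular_fit <- function(x, ...) {
  cat(sprintf("Bimolecular fit (pH %g, n = %d): k = %.4g M^-1 s^-1, intercept = %.3g s^-1, R^2 = %.4f\n",
              x$pH, x$n, x$k, x$intercept, x$r2))
  invisible(x)
}

#' Speciation-correct an apparent rate constant
#'
#' Converts the apparent second-order constant `k`, referred to total
#' nucleophile concentration at the working pH, into the pH-independent
#' constant `k1` referred to the free base:
#' `k1 = k * (1 + 10^(pKa - pH)) = k / free_base_fraction(pH, pKa)`.
#'
#' @param k Apparent second-order rate constant, M^-1 s^-1 (> 0,
#'   vectorised).
#' @param pH Working pH.
#' @param pKa Conjugate-acid pKa of the nucleophile (default 3.38).
#' @return `k1` in M^-1 s^-1.
#' @export
to_k1 <- function(k, pH, pKa = 3.38) {
  stopifnot(is.numeric(k), all(k[!is.na(k)] > 0))
  k / free_base_fraction(pH, pKa)
}

#' Kinetic isotope effect ratios
#'
#' Pairs protio and deuterio speciation-corrected rate constants on the key
#' (`label`, `pH`) and returns the elementwise `kH/kD` ratios with their
#' range.  Ratios near unity indicate that the C-H bond is not broken in
#' the rate-determining step.
#'
#' @param protio,deuterio Data frames with columns `label`, `pH`, `k1`.
#'   Every deuterio entry must have a protio partner.
#' @return Data frame with `label`, `pH`, `k1_H`, `k1_D`, `ratio`;
#'   attributes `kie_min` and `kie_max` carry the range.
#' @export
kie_ratios <- function(protio, deuterio) {
  need <- c("label", "pH", "k1")
  stopifnot(all(need %in% names(protio)), all(need %in% names(deuterio)))
  key_p <- paste(protio$label, protio$pH)
  key_d <- paste(deuterio$label, deuterio$pH)
  missing <- setdiff(key_d, key_p)
  if (length(missing) > 0) {
    stop("deuterio entry without protio partner: (",
         paste(missing, collapse = "), ("), ")", call. = FALSE)
  }
  idx <- match(key_d, key_p)
  out <- data.frame(label = deuterio$label, pH = deuterio$pH,
                    k1_H = protio$k1[idx], k1_D = deuterio$k1,
                    ratio = protio$k1[idx] / deuterio$k1)
  attr(out, "kie_min") <- min(out$ratio)
  attr(out, "kie_max") <- max(out$ratio)
  out
}

#' Extract second-order rate constants from a synthetic campaign
#'
#' Runs the full trace-level pipeline over a [generate_campaign()] result:
#' fits `kobsd` for every trace, regresses `kobsd` on concentration per
#' (electrophile, pH), and speciation-corrects the slopes to `k1`.
#'
#' @param campaign A `campaign` object.
#' @param method Trace fitting method passed to [fit_kobsd()].
#' @param pKa Conjugate-acid pKa used for speciation correction; default is
#'   the campaign's generating value.
#' @return Data frame with one row per (label, pH): `label`, `pH`, `k`,
#'   `intercept`, `r2`, `k1`.
#' @export
extract_campaign_rates <- function(campaign,
                                   method = c("guggenheim-linear",
                                              "exp-nonlinear"),
                                   pKa = NULL) {
  stopifnot(inherits(campaign, "campaign"))
  method <- match.arg(method)
  if (is.null(pKa)) pKa <- campaign$manifest$pKa
  meas <- do.call(rbind, lapply(campaign$traces, function(tr) {
    fit <- fit_kobsd(tr, method = method)
    data.frame(label = tr$label, pH = tr$pH,
               conc = tr$nucleophile_total_conc,
               kobsd = fit$kobsd, fit_r2 = fit$fit_r2)
  }))
  groups <- split(meas, list(meas$label, meas$pH), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    bf <- fit_bimolecular(g[, c("conc", "kobsd", "pH")])
    data.frame(label = g$label[1], pH = bf$pH, k = bf$k,
               intercept = bf$intercept, r2 = bf$r2,
               k1 = to_k1(bf$k, bf$pH, pKa))
  }))
  rownames(out) <- NULL
  out[order(out$label, out$pH), ]
}
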