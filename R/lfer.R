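# Linear free-energy relationship analyses: Hammett, Yukawa-Tsuno,
# Mayr-Patz nucleophilicity fitting, and the sigma-plus predictive model.
# All logarithms are base 10 (LFER convention); all regressions are
# unweighted ordinary least squares.

#' pH-averaged logarithmic rate constant
#'
#' The speciation-corrected constant `k1` is pH-independent by
#' construction, so measurements at several pH values are replicates; the
#' analyses use the arithmetic mean of the available `log10 k1` values.
#' `NA` entries are skipped; a record with no `k1` at all is an error.
#'
#' @param k1_pH1,k1_pH2 Speciation-corrected rate constants (M^-1 s^-1) at
#'   the two working pH values; vectorised, `NA` allowed.
#' @return Mean of the available `log10 k1` per record.
#' @export
average_log_rate <- function(k1_pH1, k1_pH2 = NA_real_) {
  m <- cbind(log10(k1_pH1), log10(k1_pH2))
  if (any(rowSums(!is.na(m)) == 0)) {
    stop("record with no k1 value at any pH", call. = FALSE)
  }
  rowMeans(m, na.rm = TRUE)
}

.check_xy <- function(x, y, min_n, what) {
  if (length(x) != length(y)) {
    stop(what, ": predictor and response lengths differ", call. = FALSE)
  }
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < min_n) {
    stop(what, ": need at least ", min_n, " complete points, have ",
         sum(keep), call. = FALSE)
  }
  keep
}

#' Hammett correlation of rate constants
#'
#' Ordinary least-squares fit of `log10 k` against a Hammett substituent
#' scale: `log k = intercept + rho * sigma`.  The reaction constant `rho`
#' measures the sensitivity of the rate to the substituent's electronic
#' effect; large positive `rho` signals substantial positive charge
#' development on the nucleophilic partner in the transition state.
#'
#' @param log_k Base-10 logarithms of rate constants.
#' @param sigma Substituent constants (`sigma_p` or `sigma_p_plus` values,
#'   matching `scale`).
#' @param scale Which scale `sigma` is on: `"sigma"` or `"sigma_plus"`
#'   (label only; values are supplied by the caller).
#' @return An object of class `hammett_fit`: `rho`, `intercept`, `r2`,
#'   `scale_used`, `n`, `residuals`.
#' @export
hammett_fit <- function(log_k, sigma, scale = c("sigma", "sigma_plus")) {
  scale <- match.arg(scale)
  keep <- .check_xy(sigma, log_k, 3, "hammett_fit")
  fit <- stats::lm(log_k[keep] ~ sigma[keep])
  structure(list(rho = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = .r_squared(fit),
                 scale_used = scale, n = sum(keep),
                 residuals = unname(stats::residuals(fit))),
            class = "hammett_fit")
}

#' @export
print.hammett_fit <- function(x, ...) {
  cat(sprintf("Hammett fit (%s, n = %d): log k = %.3f %+.3f sigma, R^2 = %.4f\n",
              x$scale_used, x$n, x$intercept, x$rho, x$r2))
  invisible(x)
}

#' Yukawa-Tsuno correlation
#'
#' Fits the extended Hammett model
#' `log k = intercept + rho * (sigma + r * (sigma_plus - sigma))`,
#' where the resonance demand parameter `r` weights the enhanced
#' through-resonance component of the substituent effect; `r = 0` recovers
#' the plain `sigma` correlation and `r = 1` the `sigma_plus` correlation.
#'
#' Two estimators:
#' * `"joint-bilinear"` (default) — two-regressor OLS on `sigma` and
#'   `(sigma_plus - sigma)` giving `b1 = rho` and `b2 = rho * r`, then
#'   `r = b2 / b1`.  This is the global least-squares optimum of the
#'   three-parameter model.
#' * `"grid-conditional"` — scans `r` over \[-1, 3\] in steps of 0.01,
#'   fitting a one-regressor OLS on the effective constant
#'   `sigma_eff = sigma + r * (sigma_plus - sigma)` at each `r`, and
#'   returns the `r` minimising the residual sum of squares.
#'
#' When `sigma_plus` equals `sigma` for every point the resonance term
#' vanishes and `r` is unidentifiable: the joint method errors, the grid
#' method returns the plain Hammett fit flagged `r_identifiable = FALSE`.
#'
#' @param log_k Base-10 logarithms of rate constants.
#' @param sigma,sigma_plus Substituent constants per point.
#' @param method `"joint-bilinear"` or `"grid-conditional"`.
#' @return An object of class `yukawa_tsuno_fit`: `rho`, `r`, `intercept`,
#'   `r2`, `sse`, `method`, `n`, `r_identifiable`.
#' @export
yukawa_tsuno_fit <- function(log_k, sigma, sigma_plus,
                             method = c("joint-bilinear", "grid-conditional")) {
  method <- match.arg(method)
  stopifnot(length(sigma) == length(sigma_plus))
  keep <- .check_xy(sigma, log_k, 4, "yukawa_tsuno_fit") &
    !is.na(sigma_plus)
  if (sum(keep) < 4) {
    stop("yukawa_tsuno_fit: need at least 4 complete points", call. = FALSE)
  }
  y <- log_k[keep]; s <- sigma[keep]; sp <- sigma_plus[keep]
  resonance <- sp - s
  degenerate <- all(abs(resonance) < 1e-12)

  if (method == "joint-bilinear") {
    if (degenerate) {
      stop("sigma_plus equals sigma for every point: resonance term is ",
           "identically zero and r is undefined", call. = FALSE)
    }
    fit <- stats::lm(y ~ s + resonance)
    b1 <- unname(stats::coef(fit)[2])
    b2 <- unname(stats::coef(fit)[3])
    if (!is.finite(b1) || abs(b1) < 1e-12) {
      stop("rho estimate is zero; resonance parameter r is undefined",
           call. = FALSE)
    }
    return(structure(list(rho = b1, r = b2 / b1,
                          intercept = unname(stats::coef(fit)[1]),
                          r2 = .r_squared(fit),
                          sse = sum(stats::residuals(fit)^2),
                          method = method, n = sum(keep),
                          r_identifiable = TRUE),
                     class = "yukawa_tsuno_fit"))
  }

  if (degenerate) {
    h <- hammett_fit(y, s, "sigma")
    return(structure(list(rho = h$rho, r = NA_real_,
                          intercept = h$intercept, r2 = h$r2,
                          sse = sum(h$residuals^2),
                          method = method, n = sum(keep),
                          r_identifiable = FALSE),
                     class = "yukawa_tsuno_fit"))
  }
  r_grid <- seq(-1, 3, by = 0.01)
  best <- NULL
  for (r in r_grid) {
    sigma_eff <- s + r * resonance
    fit <- stats::lm(y ~ sigma_eff)
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(rho = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]),
                   r2 = .r_squared(fit), r = r, sse = sse)
    }
  }
  structure(list(rho = best$rho, r = best$r, intercept = best$intercept,
                 r2 = best$r2, sse = best$sse, method = method,
                 n = sum(keep), r_identifiable = TRUE),
            class = "yukawa_tsuno_fit")
}

#' @export
print.yukawa_tsuno_fit <- function(x, ...) {
  cat(sprintf("Yukawa-Tsuno fit (%s, n = %d): rho = %.3f, r = %.3f, intercept = %.3f, R^2 = %.4f\n",
              x$method, x$n, x$rho, x$r, x$intercept, x$r2))
  if (!x$r_identifiable) cat("  (r unidentifiable: sigma_plus == sigma)\n")
  invisible(x)
}

#' Mayr-Patz nucleophilicity fit
#'
#' Fits the reactivity relation `log10 k = s_N * (E + N)` by OLS of
#' `log10 k1` on the electrophilicity parameters `E` of the reaction
#' partners: the slope is the nucleophile-specific sensitivity `s_N` and
#' the intercept is `s_N * N`, so `N = intercept / s_N`.
#'
#' @param log_k1 Base-10 logarithms of pH-independent rate constants.
#' @param E Mayr electrophilicity parameters; points with `NA` are dropped.
#' @return An object of class `mayr_fit`: `s_N`, `N`, `intercept`, `r2`,
#'   `n`, `residuals`.
#' @export
mayr_fit <- function(log_k1, E) {
  keep <- .check_xy(E, log_k1, 3, "mayr_fit")
  fit <- stats::lm(log_k1[keep] ~ E[keep])
  s_N <- unname(stats::coef(fit)[2])
  if (!is.finite(s_N) || s_N <= 0) {
    stop("nucleophile-electrophile scale inverted: fitted slope s_N <= 0",
         call. = FALSE)
  }
  intercept <- unname(stats::coef(fit)[1])
  structure(list(s_N = s_N, N = intercept / s_N, intercept = intercept,
                 r2 = .r_squared(fit), n = sum(keep),
                 residuals = unname(stats::residuals(fit))),
            class = "mayr_fit")
}

#' @export
print.mayr_fit <- function(x, ...) {
  cat(sprintf("Mayr-Patz fit (n = %d): log k1 = %.3f %+.3f E  =>  s_N = %.3f, N = %.3f (R^2 = %.4f)\n",
              x$n, x$intercept, x$s_N, x$s_N, x$N, x$r2))
  invisible(x)
}

#' Nucleophilicity from a single reference rate
#'
#' Inverts the reactivity relation for one measured rate constant toward an
#' electrophile of known `E`: `N = log10(k) / s_N - E`.  With the
#' conventional approximation `s_N = 1` this is the standard one-point
#' calibration against a reference electrophile.
#'
#' @param k Second-order rate constant, M^-1 s^-1 (> 0, vectorised).
#' @param E Electrophilicity of the reference electrophile.
#' @param s_N Sensitivity parameter (default 1).
#' @return Nucleophilicity parameter `N`.
#' @export
n_from_single_rate <- function(k, E, s_N = 1) {
  stopifnot(all(k[!is.na(k)] > 0), s_N > 0)
  log10(k) / s_N - E
}

#' Linear model of nucleophilicity against sigma-plus
#'
#' OLS fit of measured nucleophilicity parameters `N` against the
#' sigma-plus constants of the ring substituent:
#' `N = intercept + slope * sigma_plus`.  A strongly negative slope
#' quantifies how electron-donating substituents, acting through the pi
#' system, amplify nucleophilicity.
#'
#' @param N Nucleophilicity parameters.
#' @param sigma_plus Substituent sigma-plus constants.
#' @return An object of class `sigma_plus_model`: `slope`, `intercept`,
#'   `r2`, `n`.
#' @export
fit_sigma_plus_model <- function(N, sigma_plus) {
  keep <- .check_xy(sigma_plus, N, 3, "fit_sigma_plus_model")
  x <- sigma_plus[keep]
  if (length(unique(x)) < 2) {
    stop("design is rank deficient: all sigma_plus values coincide",
         call. = FALSE)
  }
  fit <- stats::lm(N[keep] ~ x)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = .r_squared(fit), n = sum(keep)),
            class = "sigma_plus_model")
}

#' @export
print.sigma_plus_model <- function(x, ...) {
  cat(sprintf("N-sigma+ model (n = %d): N = %.3f %+.3f sigma+ (R^2 = %.4f)\n",
              x$n, x$intercept, x$slope, x$r2))
  invisible(x)
}

#' Predict a nucleophilicity parameter from sigma-plus
#'
#' @param model A fitted [fit_sigma_plus_model()] object.
#' @param sigma_plus Sigma-plus constant(s) of the substituent(s).
#' @return Predicted `N`.
#' @export
predict_N <- function(model, sigma_plus) {
  stopifnot(inherits(model, "sigma_plus_model"))
  model$intercept + model$slope * sigma_plus
}

#' Predict a rate constant from reactivity parameters
#'
#' Forward evaluation of the reactivity relation:
#' `k = 10^(s_N * (E + N))`.
#'
#' @param N Nucleophilicity parameter.
#' @param s_N Sensitivity parameter (default 1).
#' @param E Electrophilicity parameter.
#' @return Predicted second-order rate constant, M^-1 s^-1.
#' @export
predict_rate <- function(N, s_N = 1, E) {
  stopifnot(all(is.finite(N)), all(is.finite(s_N)), all(is.finite(E)))
  10^(s_N * (E + N))
}

#' Compare predicted with experimental rate constants
#'
#' Forms the ratio `k_exp / k_calc` per pair and flags whether every
#' deviation factor (the ratio or its reciprocal, whichever is >= 1) stays
#' within the stated confidence factor — conventionally 100 (two orders of
#' magnitude) for reactivity-scale predictions.
#'
#' @param k_exp,k_calc Positive experimental and calculated rate constants
#'   (paired).
#' @param names Optional names per pair.
#' @param confidence_factor Maximum acceptable deviation factor
#'   (default 100).
#' @return Data frame with `name`, `k_exp`, `k_calc`, `ratio`,
#'   `deviation_factor`; attribute `within_confidence` is the overall flag.
#' @export
validate_predictions <- function(k_exp, k_calc, names = NULL,
                                 confidence_factor = 100) {
  stopifnot(length(k_exp) == length(k_calc))
  if (any(k_exp <= 0) || any(k_calc <= 0)) {
    stop("rate constants must be strictly positive", call. = FALSE)
  }
  if (is.null(names)) names <- as.character(seq_along(k_exp))
  ratio <- k_exp / k_calc
  dev <- pmax(ratio, 1 / ratio)
  out <- data.frame(name = names, k_exp = k_exp, k_calc = k_calc,
                    ratio = ratio, deviation_factor = dev)
  attr(out, "within_confidence") <- all(dev <= confidence_factor)
  out
}
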