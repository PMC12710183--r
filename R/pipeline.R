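# Orchestration: campaign export/import and the one-call reproduction of
# the study's derived quantities from the packaged tables.

#' Write a synthetic campaign to disk
#'
#' Exports each trace as a CSV (columns `time_s`, `absorbance`) and the
#' campaign manifest (design, seed, ground truth) as a JSON sidecar.
#' Deterministic: the same campaign always produces byte-identical files.
#'
#' @param campaign A [generate_campaign()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  stopifnot(inherits(campaign, "campaign"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir,
                             call. = FALSE)
  for (i in seq_along(campaign$traces)) {
    tr <- campaign$traces[[i]]
    df <- data.frame(time_s = tr$times, absorbance = tr$absorbances)
    write_rate_table(df, file.path(dir, sprintf("trace_%04d.csv", i)))
  }
  index <- lapply(seq_along(campaign$traces), function(i) {
    tr <- campaign$traces[[i]]
    list(file = sprintf("trace_%04d.csv", i), label = tr$label,
         pH = tr$pH, conc = tr$nucleophile_total_conc,
         A0 = tr$A0, A_inf = tr$A_inf, true_kobsd = tr$true_kobsd)
  })
  jsonlite::write_json(list(manifest = campaign$manifest, traces = index),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a campaign written by [write_campaign()]
#'
#' @param dir Directory containing `manifest.json` and trace CSVs.
#' @return A `campaign` object equivalent to the one written.
#' @export
read_campaign <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("no manifest.json in ", dir, call. = FALSE)
  }
  meta <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  traces <- lapply(seq_len(nrow(meta$traces)), function(i) {
    row <- meta$traces[i, ]
    df <- read_rate_table(file.path(dir, row$file),
                          required = c("time_s", "absorbance"))
    structure(list(times = df$time_s, absorbances = df$absorbance,
                   A0 = row$A0, A_inf = row$A_inf, pH = row$pH,
                   nucleophile_total_conc = row$conc,
                   true_kobsd = row$true_kobsd, label = row$label),
              class = "absorbance_trace")
  })
  manifest <- meta$manifest
  manifest$k1_true <- stats::setNames(unlist(manifest$k1_true),
                                      manifest$labels)
  structure(list(traces = traces, manifest = manifest), class = "campaign")
}

#' Reproduce the study's derived quantities from the packaged tables
#'
#' Runs the complete fixture-driven analysis chain:
#' speciation-consistency check of the tabulated `k`/`k1` pairs, kinetic
#' isotope effect summary, Hammett fits on both substituent scales,
#' Yukawa-Tsuno fits by both estimators, the Mayr-Patz nucleophilicity
#' fit (excluding the one electrophile without a tabulated `E`), one-point
#' `N` estimates for the reference nucleophile set, the `N`-sigma-plus
#' model with its predictions for the unmeasured thiophenes, and the
#' rate-constant validation against the second electrophile.
#'
#' @param pKa Conjugate-acid pKa used in the speciation check
#'   (default 3.38).
#' @return An object of class `study_report`; see the elements of the
#'   returned list.  Use [write_study_report()] to serialise it.
#' @export
reproduce_study <- function(pKa = 3.38) {
  t1 <- load_table1()
  t2 <- load_table2()
  t3 <- load_table3()

  # speciation consistency of the printed k/k1 pairs
  spec_check <- data.frame(
    label = rep(t1$label, 2),
    pH = rep(c(2, 1), each = nrow(t1)),
    k = c(t1$k_pH2, t1$k_pH1),
    k1_printed = c(t1$k1_pH2, t1$k1_pH1))
  spec_check$k1_recomputed <- to_k1(spec_check$k, spec_check$pH, pKa)
  spec_check$rel_err <- abs(spec_check$k1_recomputed / spec_check$k1_printed - 1)

  # kinetic isotope effect on the speciation-corrected constants
  protio <- data.frame(label = rep(t1$label, 2),
                       pH = rep(c(2, 1), each = nrow(t1)),
                       k1 = c(t1$k1_pH2, t1$k1_pH1))
  has_d <- !is.na(t1$k1_deuterio_pH2)
  deuterio <- data.frame(label = rep(t1$label[has_d], 2),
                         pH = rep(c(2, 1), each = sum(has_d)),
                         k1 = c(t1$k1_deuterio_pH2[has_d],
                                t1$k1_deuterio_pH1[has_d]))
  kie <- kie_ratios(protio, deuterio)

  # LFER fits on the pH-averaged log10 k1
  log_k1 <- average_log_rate(t1$k1_pH1, t1$k1_pH2)
  hammett_sigma <- hammett_fit(log_k1, t1$sigma_p, "sigma")
  hammett_sigma_plus <- hammett_fit(log_k1, t1$sigma_p_plus, "sigma_plus")
  yt_joint <- yukawa_tsuno_fit(log_k1, t1$sigma_p, t1$sigma_p_plus,
                               "joint-bilinear")
  yt_grid <- yukawa_tsuno_fit(log_k1, t1$sigma_p, t1$sigma_p_plus,
                              "grid-conditional")
  mayr <- mayr_fit(log_k1, t1$E)  # record without E dropped inside

  # one-point N estimates for the reference nucleophile panel
  t2$N_recomputed <- n_from_single_rate(t2$k_ref, t2$E_ref, s_N = 1)

  # N-sigma+ model on the experimentally fitted N of the aminothiophenes
  # (the parent compound's tabulated N_exp is the Mayr-fit N to the
  # reported precision; mayr$N here rounds to the same value)
  amino <- !is.na(t2$sigma_plus_C3)
  sp_model <- fit_sigma_plus_model(t2$N_exp[amino], t2$sigma_plus_C3[amino])
  predicted_N <- predict_N(sp_model, t3$sigma_plus)
  names(predicted_N) <- t3$nucleophile_name

  # forward prediction and validation against the printed N values
  k_calc <- predict_rate(t3$N_pred, s_N = 1, E = t3$E)
  validation <- validate_predictions(t3$k_exp, k_calc,
                                     names = t3$nucleophile_name)

  structure(list(
    pKa = pKa,
    speciation = spec_check,
    kie = kie,
    kie_range = c(min = attr(kie, "kie_min"), max = attr(kie, "kie_max")),
    log_k1 = stats::setNames(log_k1, t1$label),
    hammett_sigma = hammett_sigma,
    hammett_sigma_plus = hammett_sigma_plus,
    yukawa_tsuno_joint = yt_joint,
    yukawa_tsuno_grid = yt_grid,
    mayr = mayr,
    table2 = t2,
    sigma_plus_model = sp_model,
    predicted_N = predicted_N,
    validation = validation), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("== Diazonium coupling study report ==\n")
  cat(sprintf("Speciation check (pKa %.2f): max |k1 recomputed/printed - 1| = %.3g\n",
              x$pKa, max(x$speciation$rel_err)))
  cat(sprintf("KIE kH/kD range: %.2f - %.2f over %d pairs\n",
              x$kie_range["min"], x$kie_range["max"], nrow(x$kie)))
  print(x$hammett_sigma)
  print(x$hammett_sigma_plus)
  print(x$yukawa_tsuno_joint)
  print(x$yukawa_tsuno_grid)
  print(x$mayr)
  print(x$sigma_plus_model)
  cat("Predicted N:",
      paste(sprintf("%s = %.2f", names(x$predicted_N), x$predicted_N),
            collapse = ", "), "\n")
  cat(sprintf("Prediction validation: deviation factors %.1f - %.1f (within factor 100: %s)\n",
              min(x$validation$deviation_factor),
              max(x$validation$deviation_factor),
              attr(x$validation, "within_confidence")))
  invisible(x)
}

#' Serialise a study report to JSON
#'
#' @param report A [reproduce_study()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_study_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  flat <- list(
    pKa = report$pKa,
    speciation_max_rel_err = max(report$speciation$rel_err),
    kie_min = unname(report$kie_range["min"]),
    kie_max = unname(report$kie_range["max"]),
    hammett_sigma = unclass(report$hammett_sigma),
    hammett_sigma_plus = unclass(report$hammett_sigma_plus),
    yukawa_tsuno_joint = unclass(report$yukawa_tsuno_joint),
    yukawa_tsuno_grid = unclass(report$yukawa_tsuno_grid),
    mayr = unclass(report$mayr),
    sigma_plus_model = unclass(report$sigma_plus_model),
    predicted_N = as.list(report$predicted_N),
    validation = report$validation,
    within_confidence = attr(report$validation, "within_confidence"))
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
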