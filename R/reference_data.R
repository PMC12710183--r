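# Packaged kinetic tables and the CSV vocabulary shared by the whole pipeline.

# Canonical column vocabulary for kinetic rate tables.  Matching is
# case-insensitive; canonical (lower-case) spellings are restored on read.
.rate_table_numeric_cols <- c(
  "sigma_p", "sigma_p_plus", "e", "k_ph2", "k1_ph2", "k_ph1", "k1_ph1",
  "k_deuterio_ph2", "k1_deuterio_ph2", "k_deuterio_ph1", "k1_deuterio_ph1",
  "k", "k1", "kobsd", "conc", "ph", "intercept", "r2",
  "sigma_plus", "sigma_plus_c3", "k_ref", "e_ref", "n", "n_exp", "n_pred",
  "s_n", "k_exp", "k_calc", "ratio", "time_s", "absorbance"
)

.canonical_names <- function(nms) {
  # Case-insensitive mapping onto the canonical vocabulary; unknown columns
  # are kept verbatim (lower-cased) so user extensions survive a round trip.
  low <- tolower(nms)
  # restore conventional capitalisation for a few display columns
  low[low == "e"] <- "E"
  low[low == "e_ref"] <- "E_ref"
  low[low == "n"] <- "N"
  low[low == "n_exp"] <- "N_exp"
  low[low == "n_pred"] <- "N_pred"
  low[low == "s_n"] <- "s_N"
  low[low == "sigma_plus_c3"] <- "sigma_plus_C3"
  gsub("_ph([12])$", "_pH\\1", low)
}

#' Read a kinetic rate table from CSV
#'
#' Reads an RFC-4180 CSV ("." decimal separator, scientific notation allowed)
#' into a data frame using the package's fixed column vocabulary.  Column
#' names are matched case-insensitively and normalised to their canonical
#' spelling (e.g. `K_PH2` becomes `k_pH2`).  Empty cells become `NA`, the
#' explicit not-available marker used throughout the package.
#'
#' @param path Path to a CSV file with a header row.
#' @param required Character vector of canonical column names that must be
#'   present; a missing column is an error naming that column.
#' @return A data frame with canonical column names; numeric columns parsed
#'   as doubles.
#' @seealso [write_rate_table()] for the inverse operation.
#' @export
read_rate_table <- function(path, required = character()) {
  if (!file.exists(path)) {
    stop("rate table not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  names(raw) <- .canonical_names(names(raw))
  missing <- setdiff(.canonical_names(required), names(raw))
  if (length(missing) > 0) {
    stop("rate table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in names(raw)) {
    if (!tolower(col) %in% .rate_table_numeric_cols) next
    vals <- raw[[col]]
    vals[vals == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(num))
    if (length(bad) > 0) {
      stop("non-numeric value ", dQuote(vals[bad[1]]), " in column ", col,
           " of ", path, " (row ", bad[1], ")", call. = FALSE)
    }
    raw[[col]] <- num
  }
  raw
}

#' Write a kinetic rate table to CSV
#'
#' Writes records in the package's tabular vocabulary to an RFC-4180 CSV.
#' Values are written at full precision (15 significant digits) so that a
#' write/read round trip reproduces the stored numbers exactly; `NA` becomes
#' an empty cell.
#'
#' @param records A data frame of kinetic records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), "",
                           formatC(out[[col]], digits = 15, format = "g"))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

.fixture_path <- function(name) {
  path <- system.file("extdata", name, package = "diazokin")
  if (identical(path, "") || !file.exists(path)) {
    stop("packaged fixture ", name, " is missing or the package is not ",
         "installed correctly", call. = FALSE)
  }
  path
}

#' Measured rate constants for the diazonium coupling series
#'
#' Loads the packaged table of apparent second-order rate constants `k` and
#' speciation-corrected constants `k1` (both in M^-1 s^-1) for the coupling
#' of 3-aminothiophene with eight para-substituted benzenediazonium cations
#' (labels `7a`-`7h`) at pH 1 and pH 2, together with the Hammett
#' `sigma_p` / `sigma_p_plus` constants of the para substituent and the Mayr
#' electrophilicity `E` of each cation.  Deuterio columns hold the
#' corresponding values measured with 2-deuterio-3-aminothiophene where
#' available (`7a`, `7c`, `7g`); all other cells are `NA`.  `7d` (R = F) has
#' no tabulated `E`.
#'
#' @return A data frame with 8 rows and the columns described above.
#' @export
load_table1 <- function() {
  tab <- read_rate_table(.fixture_path("table1_rates.csv"),
                         required = c("label", "substituent", "k_pH2",
                                      "k1_pH2", "k_pH1", "k1_pH1"))
  stopifnot(nrow(tab) == 8, !anyDuplicated(tab$label))
  tab
}

#' Reference nucleophiles and their N parameters
#'
#' Loads the packaged comparison table of pi-activated carbon nucleophiles
#' (aminothiophenes, pyrroles, indoles): second-order rate constant `k_ref`
#' toward the reference superelectrophile 4,6-dinitrobenzofuroxan
#' (`E_ref` = -5.06), the nucleophilicity `N` estimated from that single rate
#' with `s_N` = 1, the experimentally fitted `N_exp` where one exists, and
#' the sigma-plus constant of the C-3 substituent for the aminothiophene
#' subset.
#'
#' @return A data frame with 7 rows.
#' @export
load_table2 <- function() {
  read_rate_table(.fixture_path("table2_nucleophiles.csv"),
                  required = c("name", "k_ref", "E_ref", "N"))
}

#' Predicted versus measured rates for the thiophene validation set
#'
#' Loads the packaged validation table: rate constants of three thiophenes
#' toward 4,6-dinitrobenzotriazole (`E` = -9.56), the nucleophilicity
#' `N_pred` predicted from the sigma-plus model, the rate `k_calc` computed
#' from it, and the experimental/calculated ratio.
#'
#' @return A data frame with 3 rows.
#' @export
load_table3 <- function() {
  read_rate_table(.fixture_path("table3_predictions.csv"),
                  required = c("nucleophile_name", "N_pred", "E",
                               "k_exp", "k_calc", "ratio"))
}

#' Hammett substituent constants used by the analyses
#'
#' @return A data frame with columns `substituent`, `position` (`para` for
#'   the diazonium para substituents, `C3` for thiophene ring substituents),
#'   `sigma_p` and `sigma_p_plus`.
#' @export
load_substituent_constants <- function() {
  read_rate_table(.fixture_path("substituent_constants.csv"),
                  required = c("substituent", "position", "sigma_p_plus"))
}
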