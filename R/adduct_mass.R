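#' Ligand specification for covalent-adduct calling
#'
#' Under \code{full_addition} chemistry (epoxide ring-opening by a
#' protein nucleophile) the entire ligand mass is added to the protein
#' with no leaving group, so a 1:1 adduct appears at the protein mass
#' plus the ligand mass (596 Da for excavatolide B).
#'
#' @param name Ligand token.
#' @param mass Ligand mass in Da (> 0).
#' @param addition_chemistry Currently only \code{"full_addition"}.
#' @return A \code{ligand_spec} list.
#' @export
ligand_spec <- function(name, mass, addition_chemistry = "full_addition") {
  stopifnot(is.numeric(mass), length(mass) == 1, mass > 0)
  addition_chemistry <- match.arg(addition_chemistry, "full_addition")
  structure(list(name = name, mass = mass,
                 addition_chemistry = addition_chemistry),
            class = "ligand_spec")
}

#' Construct a deconvoluted intact-mass spectrum
#'
#' Peaks closer than 0.01 Da are merged (intensities summed at the mass
#' of the most intense member).
#'
#' @param mass Numeric vector of peak masses in Da (> 0).
#' @param intensity Nonnegative intensities, parallel to \code{mass}.
#' @param label Free-text label (protein/treatment).
#' @return A \code{deconvoluted_spectrum} tibble with attributes.
#' @export
deconvoluted_spectrum <- function(mass, intensity, label = "spectrum") {
  if (length(mass) == 0) {
    rlang::abort("a spectrum needs at least one peak",
                 class = "competeMS_input_error")
  }
  stopifnot(length(mass) == length(intensity),
            all(mass > 0), all(intensity >= 0))
  ord <- order(mass)
  mass <- mass[ord]; intensity <- intensity[ord]
  # merge peaks within 0.01 Da
  grp <- cumsum(c(TRUE, diff(mass) >= 0.01))
  m <- tapply(seq_along(mass), grp, function(i) mass[i][which.max(intensity[i])])
  it <- tapply(intensity, grp, sum)
  out <- tibble::tibble(mass = as.numeric(m), intensity = as.numeric(it))
  attr(out, "label") <- label
  class(out) <- c("deconvoluted_spectrum", class(out))
  out
}

#' Read a two-column (mass, intensity) peak list
#' @param path Tab-separated file with header columns \code{mass},
#'   \code{intensity}.
#' @param label Spectrum label; defaults to the file base name.
#' @return A \code{\link{deconvoluted_spectrum}}.
#' @export
read_spectrum <- function(path, label = sub("\\.[^.]*$", "", basename(path))) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  deconvoluted_spectrum(df$mass, df$intensity, label = label)
}

#' Expected adduct mass for a given stoichiometry
#'
#' @param protein_mass Unmodified protein mass in Da.
#' @param ligand A \code{\link{ligand_spec}}.
#' @param stoichiometry Number of ligand additions (>= 0).
#' @return \code{protein_mass + stoichiometry * ligand$mass}.
#' @export
expected_adduct_mass <- function(protein_mass, ligand, stoichiometry) {
  stopifnot(inherits(ligand, "ligand_spec"), all(protein_mass > 0))
  if (any(stoichiometry < 0)) {
    rlang::abort("stoichiometry must be nonnegative",
                 class = "competeMS_input_error")
  }
  protein_mass + stoichiometry * ligand$mass
}

#' Call covalent ligand additions in a deconvoluted spectrum
#'
#' The base (unmodified) peak is the most intense peak unless overridden.
#' For each stoichiometry k = 1..\code{max_stoichiometry}, the peak
#' nearest to base + k x ligand mass within \code{tolerance_da} (ties
#' toward higher intensity) is called a k:1 adduct; no peak is assigned
#' twice. Modified fractions are each matched peak's intensity over the
#' base plus all matched-adduct intensities.
#'
#' @param spectrum A \code{\link{deconvoluted_spectrum}}.
#' @param ligand A \code{\link{ligand_spec}}.
#' @param tolerance_da Match tolerance in Da (default 2.0, suited to
#'   average-mass deconvolution of intact proteins).
#' @param max_stoichiometry Highest ligand stoichiometry considered.
#' @param base_mass Optional override of the unmodified mass; the nearest
#'   peak to it is used as base.
#' @return Tibble of adduct calls (possibly zero rows) with columns
#'   \code{base_mass}, \code{adduct_mass}, \code{delta},
#'   \code{stoichiometry}, \code{mass_error}, \code{modified_fraction}.
#' @export
call_adducts <- function(spectrum, ligand, tolerance_da = 2.0,
                         max_stoichiometry = 3L, base_mass = NULL) {
  stopifnot(inherits(ligand, "ligand_spec"), tolerance_da > 0,
            max_stoichiometry >= 1)
  if (!inherits(spectrum, "deconvoluted_spectrum")) {
    spectrum <- deconvoluted_spectrum(spectrum$mass, spectrum$intensity)
  }
  if (nrow(spectrum) == 0) {
    rlang::abort("empty spectrum", class = "competeMS_input_error")
  }
  if (is.null(base_mass)) {
    base_i <- which.max(spectrum$intensity)
  } else {
    base_i <- which.min(abs(spectrum$mass - base_mass))
  }
  b_mass <- spectrum$mass[base_i]
  b_int <- spectrum$intensity[base_i]

  assigned <- base_i
  calls <- list()
  for (k in seq_len(max_stoichiometry)) {
    target <- b_mass + k * ligand$mass
    free <- setdiff(seq_len(nrow(spectrum)), assigned)
    if (length(free) == 0) break
    d <- abs(spectrum$mass[free] - target)
    within <- free[d <= tolerance_da]
    if (length(within) == 0) next
    dd <- abs(spectrum$mass[within] - target)
    best <- within[order(dd, -spectrum$intensity[within])][1]
    assigned <- c(assigned, best)
    calls[[length(calls) + 1L]] <- tibble::tibble(
      base_mass = b_mass,
      adduct_mass = spectrum$mass[best],
      delta = spectrum$mass[best] - b_mass,
      stoichiometry = k,
      mass_error = spectrum$mass[best] - target,
      intensity = spectrum$intensity[best])
  }
  if (length(calls) == 0) {
    return(tibble::tibble(base_mass = numeric(0), adduct_mass = numeric(0),
                          delta = numeric(0), stoichiometry = integer(0),
                          mass_error = numeric(0),
                          modified_fraction = numeric(0)))
  }
  calls <- dplyr::bind_rows(calls)
  total <- b_int + sum(calls$intensity)
  calls$modified_fraction <- if (total > 0) calls$intensity / total else 0
  calls$intensity <- NULL
  calls
}

#' Compare adduct calls between a treated and a control spectrum
#'
#' @param spectrum_treated,spectrum_control
#'   \code{\link{deconvoluted_spectrum}} objects (e.g. compound-treated
#'   vs vehicle).
#' @param ligand A \code{\link{ligand_spec}}.
#' @param tolerance_da Match tolerance in Da.
#' @return \code{"adduct_gained"} when the treated spectrum carries an
#'   adduct call (stoichiometry and delta, within tolerance) absent from
#'   the control; \code{"adduct_lost"} for the converse;
#'   \code{"no_change"} otherwise.
#' @export
compare_conditions <- function(spectrum_treated, spectrum_control, ligand,
                               tolerance_da = 2.0) {
  ct <- call_adducts(spectrum_treated, ligand, tolerance_da)
  cc <- call_adducts(spectrum_control, ligand, tolerance_da)
  in_other <- function(row, other) {
    any(other$stoichiometry == row$stoichiometry &
          abs(other$delta - row$delta) <= tolerance_da)
  }
  gained <- nrow(ct) > 0 &&
    any(vapply(seq_len(nrow(ct)),
               function(i) !in_other(ct[i, ], cc), logical(1)))
  lost <- nrow(cc) > 0 &&
    any(vapply(seq_len(nrow(cc)),
               function(i) !in_other(cc[i, ], ct), logical(1)))
  if (gained) "adduct_gained" else if (lost) "adduct_lost" else "no_change"
}
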