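# Chemical-formula arithmetic for silver-adduct product-ion annotation.
# A formula is a named integer vector of element counts with class
# "chem_formula"; "Ag" always denotes monoisotopic 107Ag.

new_chem_formula <- function(counts) {
  counts <- counts[counts != 0]
  if (any(counts < 0)) {
    abort("chemical formula has negative element counts")
  }
  structure(counts[order(hill_rank(names(counts)))], class = "chem_formula")
}

# Hill order: C first, H second, all other elements alphabetical.
hill_rank <- function(el) {
  match(el, c("C", "H", sort(setdiff(names(.pg_masses), c("C", "H")))))
}

#' Parse a chemical formula string
#'
#' Parses element symbols with optional counts into an element-count map.
#' Monoisotopic silver may be written `Ag` or bracketed as `[107Ag]`;
#' deuterium as `D` or `[2H]`. The empty string is the empty formula
#' (mass zero, the identity of formula addition).
#'
#' @param text A formula string, e.g. `"C20H32O5"` (the shared composition of
#'   PGE2, PGD2 and delta12-PGD2) or `"C20H32O5[107Ag]"`.
#' @return A `chem_formula`: a named integer vector of element counts in
#'   Hill order.
#' @examples
#' parse_formula("C20H32O5")
#' parse_formula("C8H14O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- gsub("\\[107Ag\\]", "Ag", text)
  text <- gsub("\\[2H\\]", "D", text)
  if (!nzchar(text)) {
    return(new_chem_formula(stats::setNames(integer(0), character(0))))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    abort(paste0("malformed formula string: '", text, "'"))
  }
  el <- sub("[0-9]*$", "", tokens)
  n <- sub("^[A-Z][a-z]?", "", tokens)
  n <- ifelse(nzchar(n), as.integer(n), 1L)
  bad <- setdiff(el, names(.pg_masses))
  if (length(bad)) {
    abort(paste0("unknown element symbol(s): ", paste(bad, collapse = ", ")))
  }
  counts <- tapply(n, el, sum)
  new_chem_formula(stats::setNames(as.integer(counts), names(counts)))
}

as_formula_obj <- function(f) {
  if (inherits(f, "chem_formula")) f else parse_formula(f)
}

#' Render a formula in canonical (Hill) order
#'
#' @param f A `chem_formula` or formula string.
#' @param isotope_brackets Render silver as `[107Ag]` and deuterium as `[2H]`
#'   instead of the shorthand `Ag`/`D` symbols.
#' @return A single string; parsing it back gives the same formula.
#' @examples
#' format_formula(parse_formula("H32O5C20"))
#' @export
format_formula <- function(f, isotope_brackets = FALSE) {
  f <- as_formula_obj(f)
  if (!length(f)) return("")
  el <- names(f)
  if (isotope_brackets) {
    el[el == "Ag"] <- "[107Ag]"
    el[el == "D"] <- "[2H]"
  }
  paste0(el, ifelse(f == 1L, "", f), collapse = "")
}

#' @export
format.chem_formula <- function(x, ...) format_formula(x, ...)

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

formula_add <- function(a, b) {
  a <- as_formula_obj(a); b <- as_formula_obj(b)
  el <- union(names(a), names(b))
  new_chem_formula(stats::setNames(
    as.integer(ifelse(is.na(a[el]), 0L, a[el]) + ifelse(is.na(b[el]), 0L, b[el])),
    el
  ))
}

# Subtraction of a loss from a precursor; NULL when any count would go negative.
formula_subtract <- function(a, b) {
  a <- as_formula_obj(a); b <- as_formula_obj(b)
  el <- union(names(a), names(b))
  d <- ifelse(is.na(a[el]), 0L, a[el]) - ifelse(is.na(b[el]), 0L, b[el])
  if (any(d < 0)) return(NULL)
  new_chem_formula(stats::setNames(as.integer(d), el))
}

#' @export
`+.chem_formula` <- function(e1, e2) formula_add(e1, e2)

#' @export
`-.chem_formula` <- function(e1, e2) {
  out <- formula_subtract(e1, e2)
  if (is.null(out)) abort("formula subtraction yields a negative element count")
  out
}

#' Monoisotopic mass of a neutral formula
#'
#' Sum of per-element monoisotopic masses from the pinned constants table
#' ([pg_atomic_masses()]). Electron mass is never included here; charged
#' species are handled by [adduct_mz()].
#'
#' @param f A `chem_formula` or formula string.
#' @return Mass in Da (0 for the empty formula).
#' @examples
#' monoisotopic_mass("H2O")
#' monoisotopic_mass("C20H32O5")
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula_obj(f)
  if (!length(f)) return(0)
  sum(.pg_masses[names(f)] * as.numeric(f))
}

.adducts <- list(
  "107Ag" = list(formula = "Ag", charge = 1L),
  "Na"    = list(formula = "Na", charge = 1L),
  "H"     = list(formula = "H",  charge = 1L),
  "-H"    = list(formula = "H",  charge = -1L)
)

#' m/z of a singly charged adduct ion
#'
#' Computes `(neutral mass + adduct mass - charge x electron mass) / |charge|`.
#' The electron-mass correction is always applied to charged species; at
#' m/z 459 it amounts to about 1.2 ppm and is required to reproduce the
#' silver-adduct values to within 0.1 ppm.
#'
#' @param neutral Neutral-species formula (`chem_formula` or string); may be
#'   the empty formula, e.g. for the bare silver cation.
#' @param adduct One of `"107Ag"`, `"Na"`, `"H"` (cationization, charge +1) or
#'   `"-H"` (deprotonation, charge -1).
#' @return Theoretical m/z.
#' @examples
#' adduct_mz("C20H32O5", "107Ag") # 459.1295, the shared PG precursor
#' adduct_mz("", "107Ag")         # bare 107Ag+
#' @export
adduct_mz <- function(neutral, adduct = "107Ag") {
  adduct <- as.character(adduct)
  if (!adduct %in% names(.adducts)) {
    abort(paste0("unsupported adduct species: '", adduct, "'"))
  }
  a <- .adducts[[adduct]]
  m <- monoisotopic_mass(neutral)
  if (a$charge > 0) {
    (m + monoisotopic_mass(a$formula) - a$charge * .electron_mass) / abs(a$charge)
  } else {
    (m - monoisotopic_mass(a$formula) - a$charge * .electron_mass) / abs(a$charge)
  }
}

#' Mass error in parts per million
#'
#' @param measured,theoretical Positive m/z values (vectorized).
#' @return `(measured - theoretical) / theoretical * 1e6`.
#' @examples
#' ppm_error(331.0096, adduct_mz("C12H16O4", "107Ag"))
#' @export
ppm_error <- function(measured, theoretical) {
  if (any(measured <= 0) || any(theoretical <= 0)) {
    abort("m/z values must be positive")
  }
  (measured - theoretical) / theoretical * 1e6
}

# m/z of a product ion of [M+Ag]+ after a neutral loss: the charge stays +1
# whether or not the silver leaves with the loss (as AgH).
product_ion_mz <- function(precursor_ion, loss) {
  monoisotopic_mass(precursor_ion) - monoisotopic_mass(loss) - .electron_mass
}

#' Assign neutral-loss formulas to a product ion
#'
#' Enumerates candidate neutral losses of a singly charged silver-adduct
#' precursor and returns all assignments within a ppm tolerance, ranked by
#' absolute mass error. Losses are element-bounded subformulas of the
#' precursor ion composition over C/H/O; when `allow_metal_losses` is `TRUE`
#' the silver may leave as part of the loss (neutral AgH together with
#' further C/H/O), shifting the charge onto the organic fragment, as seen
#' for the m/z 333.2060 ion (loss of H2O + AgH).
#'
#' Ties in |ppm| are broken by fewer heavy (non-H) atoms in the loss, i.e.
#' the simplest loss ranks first. The identity assignment (empty loss) is
#' returned when the measured value matches the precursor itself.
#'
#' @param measured Measured product-ion m/z (scalar).
#' @param precursor Neutral precursor formula (default the prostaglandin
#'   composition `"C20H32O5"`).
#' @param adduct Adduct species of the precursor ion (default `"107Ag"`).
#' @param tol_ppm Mass tolerance in ppm (> 0).
#' @param allow_metal_losses Also enumerate AgH-containing losses.
#' @return A tibble with columns `measured_mz`, `ion_formula`, `loss_formula`,
#'   `theoretical_mz`, `ppm_error`, `rank`; zero rows when nothing matches.
#' @examples
#' assign_product_ion(397.1291)            # loss CH2O3 (CO2 + H2O)
#' assign_product_ion(333.2060)            # loss H2O + AgH
#' @export
assign_product_ion <- function(measured, precursor = "C20H32O5",
                               adduct = "107Ag", tol_ppm = 5,
                               allow_metal_losses = TRUE) {
  stopifnot(length(measured) == 1L, measured > 0, tol_ppm > 0)
  prec_ion <- formula_add(precursor, .adducts[[adduct]]$formula)
  cnt <- function(el) if (el %in% names(prec_ion)) as.integer(prec_ion[el]) else 0L
  nC <- cnt("C"); nH <- cnt("H"); nO <- cnt("O"); nAg <- cnt("Ag")
  prec_mass <- monoisotopic_mass(prec_ion)
  half_width <- measured * tol_ppm * 1e-6

  # For each (C, O, Ag) loss combination, solve directly for the H counts
  # whose product-ion m/z falls inside the tolerance window.
  out <- list()
  ag_range <- if (allow_metal_losses && nAg > 0) 0:nAg else 0L
  for (ag in ag_range) for (c_ in 0:nC) for (o in 0:nO) {
    base <- c_ * .pg_masses["C"] + o * .pg_masses["O"] + ag * .pg_masses["Ag"]
    # mz = prec_mass - base - h*mH - me ; want |mz - measured| <= half_width
    target_h <- (prec_mass - base - .electron_mass - measured) / .pg_masses["H"]
    h_lo <- max(if (ag > 0) 1L else 0L,
                ceiling(target_h - half_width / .pg_masses["H"]))
    h_hi <- min(nH, floor(target_h + half_width / .pg_masses["H"]))
    if (h_hi < h_lo) next
    for (h in h_lo:h_hi) {
      loss <- new_chem_formula(stats::setNames(as.integer(c(c_, h, o, ag)),
                                               c("C", "H", "O", "Ag")))
      ion <- formula_subtract(prec_ion, loss)
      if (is.null(ion)) next
      mz <- product_ion_mz(prec_ion, loss)
      if (abs(mz - measured) > half_width) next
      out[[length(out) + 1L]] <- tibble::tibble(
        measured_mz = measured,
        ion_formula = format_formula(ion),
        loss_formula = format_formula(loss),
        theoretical_mz = mz,
        ppm_error = ppm_error(measured, mz),
        heavy_atoms = sum(loss[names(loss) != "H"])
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(measured_mz = numeric(), ion_formula = character(),
                          loss_formula = character(), theoretical_mz = numeric(),
                          ppm_error = numeric(), rank = integer()))
  }
  res <- dplyr::bind_rows(out)
  res <- dplyr::arrange(res, abs(.data$ppm_error), .data$heavy_atoms)
  res$rank <- seq_len(nrow(res))
  dplyr::select(res, -"heavy_atoms")
}

#' Annotate a table of measured product ions
#'
#' Tidy wrapper over [assign_product_ion()]: takes a data frame of measured
#' m/z values and returns the best-ranked assignment per ion (or all
#' candidates), in the style of a product-ion summary table.
#'
#' @param data A data frame with a numeric m/z column.
#' @param mz_col Name of the m/z column (default `"mz"`).
#' @param top_only Keep only the rank-1 assignment per measured ion.
#' @inheritParams assign_product_ion
#' @return The input joined with assignment columns (`ion_formula`,
#'   `loss_formula`, `theoretical_mz`, `ppm_error`, `rank`); unassigned ions
#'   keep `NA` in those columns.
#' @export
annotate_ions <- function(data, mz_col = "mz", precursor = "C20H32O5",
                          adduct = "107Ag", tol_ppm = 5,
                          allow_metal_losses = TRUE, top_only = TRUE) {
  stopifnot(is.data.frame(data), mz_col %in% names(data))
  res <- purrr::map(data[[mz_col]], function(m) {
    a <- assign_product_ion(m, precursor, adduct, tol_ppm, allow_metal_losses)
    if (!nrow(a)) {
      a <- tibble::tibble(measured_mz = m, ion_formula = NA_character_,
                          loss_formula = NA_character_,
                          theoretical_mz = NA_real_, ppm_error = NA_real_,
                          rank = NA_integer_)
    } else if (top_only) {
      a <- a[1L, ]
    }
    a
  })
  ann <- dplyr::bind_rows(res)
  if (top_only) {
    dplyr::bind_cols(data, dplyr::select(ann, -"measured_mz"))
  } else {
    dplyr::left_join(data, ann, by = stats::setNames("measured_mz", mz_col))
  }
}

#' Published silver-adduct product ions of the PG isomers
#'
#' Reference table of the MS2/MS3 product ions of PGE2, PGD2 and
#' delta12-PGD2 cationized with 107Ag: measured m/z, assigned ion
#' composition, neutral loss from the [C20H32O5 + 107Ag]+ precursor, the
#' published mass error, and in which isomers each ion is observed. The
#' three diagnostic MS3 channels are 331.0096 (PGE2-specific), 333.2060
#' (common, abundance-graded) and 341.0301 (delta12-PGD2-specific).
#'
#' @return A tibble with columns `measured_mz`, `ion_formula`,
#'   `published_ppm`, `loss_formula`, `pge2`, `pgd2`, `d12pgd2`.
#' @export
pg_product_ions <- function() {
  tibble::tribble(
    ~measured_mz, ~ion_formula,  ~published_ppm, ~loss_formula, ~pge2,        ~pgd2,        ~d12pgd2,
    313.0352,  "C13H18AgO2",  0.07,  "C7H14O3",  "no",         "MS3",        "MS3",
    315.1953,  "C20H27O3",   -0.45,  "H5AgO2",   "no",         "MS3",        "MS2+MS3",
    331.0096,  "C12H16AgO4",  0.60,  "C8H16O",   "MS3",        "no",         "no",
    331.1905,  "C20H27O4",    0.33,  "H5AgO",    "MS2+MS3",    "MS2+MS3",    "MS2+MS3",
    333.0252,  "C12H18AgO4",  0.12,  "C8H14O",   "no",         "MS2",        "no",
    333.2060,  "C20H29O4",   -0.03,  "H3AgO",    "MS3",        "MS2+MS3",    "MS2+MS3",
    341.0301,  "C14H18AgO3", -0.23,  "C6H14O2",  "no",         "no",         "MS2+MS3",
    343.0094,  "C13H16AgO4", -0.06,  "C7H16O",   "no",         "no",         "MS3",
    359.0410,  "C14H20AgO4",  0.95,  "C6H12O",   "no",         "no",         "MS2",
    397.1291,  "C19H30AgO2",  0.30,  "CH2O3",    "MS3",        "MS3",        "no",
    413.1245,  "C19H30AgO3", -0.11,  "CH2O2",    "MS3",        "MS3",        "MS3",
    423.1084,  "C20H28AgO3",  0.02,  "H4O2",     "MS2+MS3",    "MS2+MS3",    "MS2+MS3",
    441.1190,  "C20H30AgO4", -0.06,  "H2O",      "MS2",        "MS2",        "MS2+MS3"
  )
}

#' Theoretical m/z of the PG precursor ion
#'
#' The silver adduct of the shared C20H32O5 composition, m/z 459.1295.
#' @return A single m/z value.
#' @export
pg_precursor_mz <- function() adduct_mz("C20H32O5", "107Ag")

#' Theoretical m/z of the PGD2-d9 internal standard ion
#'
#' The silver adduct of the nine-fold deuterated PGD2 (C20H23D9O5) doped
#' into the nano-DESI solvent for one-point quantitation.
#' @return A single m/z value.
#' @export
pg_internal_standard_mz <- function() adduct_mz("C20H23D9O5", "107Ag")
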