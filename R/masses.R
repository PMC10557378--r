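# Pinned monoisotopic mass constants. All mass arithmetic in the package
# routes through this one table so that adduct m/z values are reproducible
# to < 0.1 ppm. "Ag" here always means the monoisotopic 107Ag isotope used
# for cationization; it is also accepted spelled "[107Ag]" in formulas.
.pg_masses <- c(
  H    = 1.0078250319,
  D    = 2.0141017780, # 2H, for deuterated internal standards
  C    = 12.0,
  N    = 14.0030740052,
  O    = 15.9949146221,
  Na   = 22.9897692820,
  P    = 30.97376151,
  S    = 31.97207069,
  Ag   = 106.905092    # 107Ag
)

.electron_mass <- 0.00054857990907

#' Pinned monoisotopic atomic masses
#'
#' The versioned table of monoisotopic atomic masses (in Da) used by every
#' mass computation in the package. `Ag` is the monoisotopic 107Ag isotope
#' (106.905092 Da) used for silver cationization; `D` is deuterium.
#'
#' @return A tibble with columns `element` and `mass` (Da), plus one row
#'   `electron` holding the electron mass used for charge correction.
#' @examples
#' pg_atomic_masses()
#' @export
pg_atomic_masses <- function() {
  tibble::tibble(
    element = c(names(.pg_masses), "electron"),
    mass = c(unname(.pg_masses), .electron_mass)
  )
}
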