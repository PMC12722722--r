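#' Physical constants and unit helpers
#'
#' All energies in the package are kJ/mol, lengths in Angstrom (A), times in
#' ns, temperatures in K. Umbrella spring constants are accepted in
#' kJ/mol/nm^2 (the unit conventionally printed in MD methods sections) and
#' converted internally to kJ/mol/A^2; the conversion lives here so it is
#' done exactly once.
#'
#' @name units
NULL

#' Boltzmann constant in kJ/mol/K
#' @export
KB_KJ_PER_MOL_K <- 0.0083145

#' Thermal energy kT in kJ/mol at a given temperature
#'
#' @param temperature_K temperature in Kelvin (default 300).
#' @return kT in kJ/mol (2.494 kJ/mol at 300 K).
#' @export
kT_at <- function(temperature_K = 300) {
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  KB_KJ_PER_MOL_K * temperature_K
}

#' Convert a spring constant from kJ/mol/nm^2 to kJ/mol/A^2
#'
#' @param k_nm2 spring constant in kJ/mol/nm^2.
#' @return spring constant in kJ/mol/A^2 (1 nm^2 = 100 A^2).
#' @export
spring_nm2_to_A2 <- function(k_nm2) {
  stopifnot(is.numeric(k_nm2))
  k_nm2 / 100
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}
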