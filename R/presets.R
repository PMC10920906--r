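#' Condition presets used by the synthetic generators
#'
#' The generators encode published effect directions and magnitudes as named
#' presets so that the whole quantification stack can be exercised without
#' any primary data. Magnitudes are preset constants, inspectable here, not
#' hard-coded inside the generators:
#'
#' * Imaging presets scale the reporter-spot amplitude (`spot_factor`) or the
#'   diffuse nuclear 5mC-stain level (`nuclear_factor`) relative to the
#'   untreated/sparse baseline. Dense cultures and 5-aza-dC-treated cells show
#'   dimmer methylation-reporter spots; TET-inhibitor (Bobcat339) treatment
#'   raises global nuclear 5mC staining by 1.5x.
#' * qPCR presets fix the true methylated fraction of the MSRE amplicon and
#'   the true alpha-satellite transcript fold change per condition.
#'   5-aza-dC halves the methylated fraction in both the MCF10A and MCF7
#'   settings; dense cultures carry a lower methylated fraction and a higher
#'   transcript level than sparse cultures (the dense/sparse magnitude is a
#'   documented free choice of 0.75x, the direction being the constrained
#'   part).
#' * Motion presets fix the apparent diffusion coefficient of reporter spots;
#'   chromatin at methylated repeats moves slower in dense cultures (0.5x).
#'
#' @param name preset name.
#' @return A named list of preset constants.
#' @export
#' @examples
#' scene_preset("dense")
#' qpcr_preset("mcf10a_aza")
scene_preset <- function(name = c("none", "sparse", "dense", "aza_treated",
                                  "bobcat_treated")) {
  name <- match.arg(name)
  switch(name,
    none           = list(name = name, spot_factor = 1.0, nuclear_factor = 1.0),
    sparse         = list(name = name, spot_factor = 1.0, nuclear_factor = 1.0),
    dense          = list(name = name, spot_factor = 0.6, nuclear_factor = 1.0),
    aza_treated    = list(name = name, spot_factor = 0.5, nuclear_factor = 1.0),
    bobcat_treated = list(name = name, spot_factor = 1.0, nuclear_factor = 1.5)
  )
}

#' @rdname scene_preset
#' @export
qpcr_preset <- function(name = c("mcf10a_aza", "mcf7_aza", "sparse_dense",
                                 "null_pair")) {
  name <- match.arg(name)
  conditions <- switch(name,
    mcf10a_aza = tibble::tibble(
      condition = c("mock", "aza"),
      methylated_fraction = c(0.80, 0.40),
      expression_fold = c(1.0, 2.0)
    ),
    mcf7_aza = tibble::tibble(
      condition = c("mock", "aza"),
      methylated_fraction = c(0.70, 0.35),
      expression_fold = c(1.0, 2.0)
    ),
    sparse_dense = tibble::tibble(
      condition = c("sparse", "dense"),
      methylated_fraction = c(0.80, 0.60),
      expression_fold = c(1.0, 2.0)
    ),
    null_pair = tibble::tibble(
      condition = c("a", "b"),
      methylated_fraction = c(0.60, 0.60),
      expression_fold = c(1.0, 1.0)
    )
  )
  list(name = name, conditions = conditions)
}

#' @rdname scene_preset
#' @export
motion_preset <- function(name = c("sparse", "dense")) {
  name <- match.arg(name)
  switch(name,
    sparse = list(name = name, diffusion_coefficient = 0.010),
    dense  = list(name = name, diffusion_coefficient = 0.005)
  )
}
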