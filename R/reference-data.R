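#' Reference anion-binding and transport characterisation data
#'
#' Published characterisation of the trimeric carbazole-urea macrocycle
#' whose analysis workflow this package implements: association constants
#' in DMSO-d6/0.5% H2O, in C12E8 micelles and in POPC vesicles (the
#' micelle/vesicle values at 0.2 M ionic strength and
#' surface-potential-corrected where competition titrations were used),
#' literature constants of the acyclic bis-urea reference receptor in
#' DMSO, and H+/anion symport rates at 20 mM anion. Entries reported only
#' as bounds carry a `qualifier` of `">"` or `"<"`; `NA` values were not
#' determined.
#'
#' These values serve as generating ground truths for the synthetic
#' recovery studies and as the arithmetic inputs of the worked examples.
#'
#' @return A data.frame with columns `anion`, `medium`, `receptor`,
#'   `ka` (M^-1) or `rate` (anions s^-1 carrier^-1 for
#'   `medium == "transport"`), `sd`, `qualifier`.
#' @export
reference_binding_constants <- function() {
  rbind(
    data.frame(
      anion = c("SO4", "H2PO4", "Cl", "Br", "NO3", "I", "ClO4"),
      medium = "DMSO", receptor = "macrocycle",
      ka = c(7.4e9, 1e5, 2000, 200, 340, 6.1, 1),
      sd = c(1.1e9, NA, 100, 10, 10, 0.6, NA),
      qualifier = c("=", ">", "=", "=", "=", "=", "<")
    ),
    data.frame(
      anion = c("SO4", "H2PO4", "Cl", "Br", "NO3", "I", "ClO4"),
      medium = "DMSO", receptor = "bis-urea",
      ka = c(1e5, 46000, 670, 70, 10, 3, NA),
      sd = NA_real_,
      qualifier = c(">", "=", "=", "=", "=", "=", NA)
    ),
    data.frame(
      anion = c("SO4", "H2PO4", "Cl", "Br", "NO3", "I", "ClO4"),
      medium = "C12E8", receptor = "macrocycle",
      ka = c(54000, 140, 19, 29, 210, 200, 32),
      sd = c(3000, 20, 1, 1, 10, 10, 1),
      qualifier = "="
    ),
    data.frame(
      anion = c("SO4", "H2PO4", "Cl", "Br", "NO3", "I", "ClO4"),
      medium = "POPC", receptor = "macrocycle",
      ka = c(370, 1, 1, 2.6, 24, 24, 45),
      sd = c(10, NA, NA, 0.6, 4, 2, 9),
      qualifier = c("=", "<", "<", "=", "=", "=", "=")
    ),
    data.frame(
      anion = c("SO4", "H2PO4", "Cl", "Br", "NO3", "I", "ClO4"),
      medium = "transport", receptor = "macrocycle",
      ka = c(0.042, 0.031, 0.082, 0.097, 2.1, 2.0, 0.83),
      sd = c(0.006, 0.010, 0.016, 0.018, 0.1, 0.4, 0.10),
      qualifier = "="
    )
  )
}

#' Reference bilayer penetration depths of the macrocycle
#'
#' Most probable distances of the macrocycle's fluorophore from the POPC
#' bilayer centre determined by spin-label quenching: at the headgroup
#' region when anion-free or sulfate-bound, and deeper in the
#' carbonyl/glycerol region when perchlorate-bound.
#'
#' @return A data.frame with columns `state` and `depth` (Angstrom from
#'   the bilayer centre).
#' @export
reference_depths <- function() {
  data.frame(
    state = c("anion-free", "ClO4-bound"),
    depth = c(19, 16)
  )
}
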