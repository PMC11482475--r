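# Bundled case study: published characterization and potency tables for a
# panel of eight zinc oxide particles - six ZnO nanoforms (three uncoated,
# UC-1/UC-2/UC-3, and three coated: AM = (3-aminopropyl) triethoxysilane,
# SA = stearic acid, SO = silicone oil), micron-sized bulk ZnO and ionic
# ZnCl2 - screened in A549 (human lung epithelial) and J774 (mouse
# monocyte/macrophage) cells.

# transition metals reported in the elemental panel (Zn itself, the bulk
# constituent, is excluded from the contaminant sum)
.transition_metals <- c("Cd", "Co", "Cr", "Cu", "Fe", "Hf", "La", "Mn",
                        "Mo", "Nb", "Ni", "Sc", "Ta", "Ti", "V", "Zr")

.zno_file <- function(name) {
  path <- system.file("extdata", name, package = "nanopotency")
  if (path == "") {
    # source-tree fallback for devtools-style loads
    path <- file.path("inst", "extdata", name)
  }
  path
}

#' Physicochemical descriptor table of the ZnO case-study particles
#'
#' One row per particle with primary size (TEM, nm), BET specific surface
#' area (m2/g), hydrodynamic size (DLS, nm), polydispersity index, zeta
#' potential (mV), and derived elemental contents: `zn_ppm`,
#' `transition_metals_ppm` (sum of the contaminant transition-metal
#' elements, Zn excluded) and `total_metals_ppm` (sum over the full
#' elemental panel). Descriptors that could not be measured for a particle
#' (e.g. DLS for the silicone-oil-coated nanoform) are `NA` and handled by
#' listwise deletion downstream.
#'
#' @return a `data.frame` with one row per particle.
#' @seealso [zno_elements()], [zno_potency()], [pairwise_associations()]
#' @export
#' @examples
#' zno_descriptors()[, c("particle", "betsa_m2_g", "dls_nm")]
zno_descriptors <- function() {
  props <- read.csv(.zno_file("zno_properties.csv"),
                    stringsAsFactors = FALSE)
  el <- zno_elements()
  m <- as.matrix(el[, -1L])
  rownames(m) <- el$element
  derived <- data.frame(
    particle = colnames(m),
    zn_ppm = m["Zn", ],
    transition_metals_ppm = colSums(m[.transition_metals, , drop = FALSE]),
    total_metals_ppm = colSums(m),
    stringsAsFactors = FALSE)
  out <- merge(props, derived, by = "particle", sort = FALSE)
  rownames(out) <- NULL
  out
}

#' Elemental contents (ppm) of the ZnO case-study particles
#'
#' ICP-MS/ES elemental panel, one row per element and one column per
#' particle; values below the detection limit are recorded as 0.
#'
#' @return a `data.frame` with an `element` column and per-particle ppm
#'   columns.
#' @export
zno_elements <- function() {
  read.csv(.zno_file("zno_elements.csv"), check.names = FALSE,
           stringsAsFactors = FALSE)
}

#' Published potency exponents of the ZnO case-study particles
#'
#' Absolute power-law potency exponents (3-decimal published precision)
#' per particle, cell type (A549, J774) and cytotoxicity endpoint (ATP,
#' LDH, CTB). Feed through [consensus_potency()] to regenerate consensus
#' average potencies and ranks, or through [signed_beta()] to recover the
#' sign convention for descriptor associations.
#'
#' @return a long `data.frame` with columns `particle`, `cell_type`,
#'   `endpoint`, `beta_abs`.
#' @export
#' @examples
#' consensus_potency(zno_potency())
zno_potency <- function() {
  read.csv(.zno_file("zno_potency.csv"), stringsAsFactors = FALSE)
}
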