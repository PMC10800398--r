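# Material properties of the lumbar FE model (linear elastic; truss
# cross-section areas in mm^2).  Values are the standard lumbar FE material
# card used by the modelled study.

#' Material table for the finite-element model
#'
#' @param nucleus_nu_cap cap applied to the nucleus Poisson ratio.  The
#'   nominal value 0.499 locks constant-strain tetrahedra; the default cap
#'   0.495 is the documented near-incompressibility treatment.  Set to
#'   0.499 to disable the cap.
#' @return data frame with columns `name`, `E` (MPa), `nu`, `area` (mm^2,
#'   truss materials only, NA otherwise)
#' @export
material_table <- function(nucleus_nu_cap = 0.495) {
  mt <- data.frame(
    name = c("cortical", "cancellous", "endplate", "cartilage",
             "annulus_matrix", "nucleus", "annulus_fiber",
             "ALL", "PLL", "LF", "ISL", "SSL", "ITL", "CL"),
    E = c(12000, 100, 23.8, 10, 4.2, 0.4, 455,
          7.8, 10, 15, 10, 8, 10, 7.5),
    nu = c(0.3, 0.2, 0.4, 0.4, 0.45, 0.499, 0.3,
           0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3),
    area = c(NA, NA, NA, NA, NA, NA, 1.35,
             63.7, 20, 40, 40, 30, 1.8, 30))
  mt$nu[mt$name == "nucleus"] <- min(mt$nu[mt$name == "nucleus"], nucleus_nu_cap)
  mt
}

#' Validate a material table
#'
#' Rejects non-physical entries (E <= 0, nu outside [0, 0.5), missing
#' areas for truss materials).
#' @param mt a material table as from [material_table()]
#' @export
validate_materials <- function(mt) {
  if (any(mt$E <= 0)) stop("Young's modulus must be positive")
  if (any(mt$nu < 0 | mt$nu >= 0.5)) stop("Poisson ratio must lie in [0, 0.5)")
  truss <- mt$name %in% c("annulus_fiber", "ALL", "PLL", "LF", "ISL", "SSL",
                          "ITL", "CL")
  if (any(truss & (is.na(mt$area) | mt$area <= 0)))
    stop("truss materials need a positive cross-sectional area")
  invisible(TRUE)
}

# solid region name -> material name
region_material <- function(region) {
  out <- rep(NA_character_, length(region))
  out[grepl("_cortical$", region)] <- "cortical"
  out[grepl("_cancellous$", region)] <- "cancellous"
  # posterior elements carry cortical properties (single-material posterior
  # arch, a common simplification when only two bone materials are given)
  out[grepl("_posterior_elements$", region)] <- "cortical"
  out[grepl("^endplate_", region)] <- "endplate"
  out[grepl("^facet_cartilage_", region)] <- "cartilage"
  out[grepl("_annulus$", region)] <- "annulus_matrix"
  out[grepl("_nucleus$", region)] <- "nucleus"
  if (anyNA(out)) stop("unmapped region(s): ",
                       paste(unique(region[is.na(out)]), collapse = ", "))
  out
}
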