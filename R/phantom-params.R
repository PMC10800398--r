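# Subject parameters and cohort sampling.
#
# The phantom is a parametric stand-in for a patient CT reconstruction of
# L3-L5.  Dimensional defaults are taken from adult lumbar morphometry
# (vertebral body ~46 x 33 x 28 mm at L4, disc space ~10 mm, pedicles
# ~10 x 13 mm, laminae ~5 mm thick, facet joints ~15 mm lateral and ~13 mm
# behind the posterior vertebral wall, articular planes near 45 degrees to
# the sagittal plane); the disc-complex specifications (cortical shell
# 1 mm, disc complex 95% of the vertebral cross-section, nucleus 40% of the
# disc with an anterior/posterior offset ratio of 1.62, facet cartilage
# under 1 mm) are explicit construction targets of the modelled procedure.

.param_defaults <- list(
  body_width = 46, body_depth = 33, body_height = 28,
  se_exponent = 2.4,
  disc_height = 10,
  cortical_thickness = 1.0,
  endplate_thickness = 0.8,
  nucleus_area_fraction = 0.40,
  disc_to_vertebra_area_fraction = 0.95,
  ap_offset_ratio = 1.62,
  lordosis_l3l4 = 6, lordosis_l4l5 = 8,
  canal_width = 18, canal_depth = 14,
  pedicle_width = 10, pedicle_height = 13, pedicle_length = 9,
  lamina_thickness = 5, lamina_height = 17, interlaminar_arch = 4,
  spinous_process_length = 25, spinous_thickness = 6, spinous_height = 16,
  facet_angle = 45, facet_gap = 0.4, cartilage_thickness = 0.8,
  facet_width = 11, facet_height = 16,
  facet_lateral_offset = 15, facet_posterior_offset = 13,
  process_thickness = 7,
  rng_seed = 42L
)

# parameters eligible for inter-subject jitter (positive lengths/angles)
.jitter_params <- c(
  "body_width", "body_depth", "body_height", "disc_height",
  "canal_width", "canal_depth", "pedicle_width", "pedicle_height",
  "pedicle_length", "lamina_thickness", "lamina_height",
  "spinous_process_length", "spinous_thickness", "spinous_height",
  "facet_angle", "facet_width", "facet_height",
  "facet_lateral_offset", "facet_posterior_offset",
  "lordosis_l3l4", "lordosis_l4l5")

#' Parameters of one synthetic subject
#'
#' All lengths in mm, angles in degrees.  Unspecified fields take the
#' package defaults; see the methods vignette for the provenance of each
#' default.
#'
#' @param ... named parameter overrides (see `lumbosim:::.param_defaults`
#'   for the full list).
#' @return validated list of class `subject_params`
#' @export
subject_params <- function(...) {
  over <- list(...)
  bad <- setdiff(names(over), names(.param_defaults))
  if (length(bad)) stop("unknown subject parameters: ", paste(bad, collapse = ", "))
  p <- utils::modifyList(.param_defaults, over)
  validate_subject_params(p)
  structure(p, class = "subject_params")
}

validate_subject_params <- function(p) {
  lens <- setdiff(names(.param_defaults),
                  c("nucleus_area_fraction", "disc_to_vertebra_area_fraction",
                    "ap_offset_ratio", "rng_seed", "lordosis_l3l4",
                    "lordosis_l4l5"))
  for (nm in lens)
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
      stop("parameter '", nm, "' must be a positive number")
  if (p$nucleus_area_fraction <= 0 || p$nucleus_area_fraction >= 1)
    stop("nucleus_area_fraction must lie in (0, 1)")
  if (p$disc_to_vertebra_area_fraction <= 0 || p$disc_to_vertebra_area_fraction > 1)
    stop("disc_to_vertebra_area_fraction must lie in (0, 1]")
  if (p$cartilage_thickness >= 1)
    stop("cartilage_thickness must be below 1 mm")
  if (p$ap_offset_ratio <= 0) stop("ap_offset_ratio must be positive")
  # geometric feasibility: would the regions self-intersect?
  b_d <- p$body_depth / 2 * sqrt(p$disc_to_vertebra_area_fraction)
  y_nc <- -b_d * (p$ap_offset_ratio - 1) / (p$ap_offset_ratio + 1)
  b_n <- b_d * sqrt(p$nucleus_area_fraction)
  if (y_nc - b_n <= -b_d + 0.2 || y_nc + b_n >= b_d - 0.2)
    stop("degenerate geometry: nucleus would intersect the annulus outer ",
         "boundary (region 'nucleus')")
  if (2 * p$cortical_thickness >= min(p$body_width, p$body_depth) / 2)
    stop("degenerate geometry: cortical shell thicker than the vertebral ",
         "body (region 'cortical')")
  if (2 * p$endplate_thickness >= p$disc_height)
    stop("degenerate geometry: endplates consume the whole disc space ",
         "(region 'endplate')")
  if (p$canal_width / 2 + p$pedicle_width >= p$body_width / 2 + p$pedicle_length)
    stop("degenerate geometry: pedicles wider than the posterior arch ",
         "(region 'posterior_elements')")
  invisible(TRUE)
}

#' @export
print.subject_params <- function(x, ...) {
  cat("<subject_params>\n")
  for (nm in names(x)) cat(sprintf("  %-32s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Cohort specification
#'
#' @param n_subjects number of synthetic subjects (>= 2)
#' @param jitter either a single coefficient of variation applied to every
#'   jitterable dimensional parameter, or a named vector/list of per-parameter
#'   CVs (unnamed parameters get 0).
#' @param master_seed integer seed controlling the whole cohort draw.
#' @return list of class `cohort_spec`
#' @export
cohort_spec <- function(n_subjects = 25, jitter = 0.05, master_seed = 20240101) {
  if (!is.numeric(n_subjects) || n_subjects < 2)
    stop("n_subjects must be at least 2")
  if (is.numeric(jitter) && is.null(names(jitter)) && length(jitter) == 1) {
    jit <- stats::setNames(rep(jitter, length(.jitter_params)), .jitter_params)
  } else {
    jit <- stats::setNames(rep(0, length(.jitter_params)), .jitter_params)
    jitter <- unlist(jitter)
    bad <- setdiff(names(jitter), .jitter_params)
    if (length(bad)) stop("not a jitterable parameter: ", paste(bad, collapse = ", "))
    jit[names(jitter)] <- jitter
  }
  if (any(jit < 0)) stop("jitter CVs must be non-negative")
  structure(list(n_subjects = as.integer(n_subjects), jitter = jit,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

#' Draw a cohort of subject parameter sets
#'
#' Each jitterable parameter is drawn independently from a normal
#' distribution centred on its default with the requested coefficient of
#' variation, truncated at 2.5 standard deviations; parameter sets that fail
#' geometric validation are redrawn (bounded retries).  The draw is fully
#' deterministic under `master_seed`.
#'
#' @param spec a [cohort_spec()]
#' @param base optional [subject_params()] supplying the cohort means
#' @param max_retries resampling budget per subject
#' @return list of `subject_params`, one per subject
#' @export
sample_cohort <- function(spec, base = subject_params(), max_retries = 100) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$master_seed)
  out <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      p <- unclass(base)
      for (nm in names(spec$jitter)) {
        cv <- spec$jitter[[nm]]
        if (cv == 0) next
        mu <- base[[nm]]
        repeat {
          v <- stats::rnorm(1, mu, cv * abs(mu))
          if (abs(v - mu) <= 2.5 * cv * abs(mu)) break
        }
        p[[nm]] <- v
      }
      p$rng_seed <- spec$master_seed %% 1000003L + i
      res <- try(
        { validate_subject_params(p); structure(p, class = "subject_params") },
        silent = TRUE)
      if (!inherits(res, "try-error")) { out[[i]] <- res; ok <- TRUE; break }
    }
    if (!ok) stop("could not draw a valid parameter set for subject ", i,
                  " within ", max_retries, " retries")
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
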