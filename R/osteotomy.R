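# Resected-volume computation: Boolean intersection of the trephine tool
# with bone (and facet cartilage), with a Monte Carlo point-classification
# oracle, plus resection of anatomy models for the surgical variants.

# groups of an anatomy model that count towards osteotomy volume
.volume_group_names <- function(include_cartilage = TRUE) {
  c("lamina", "facet_L4_inferior", "facet_L5_superior", "other",
    if (include_cartilage) "cartilage")
}

#' Boolean intersection volume of tool and bone
#'
#' Computes the volume of `tool` intersected with bone by extracting the
#' watertight boundary of the CSG intersection (marching tetrahedra) and
#' applying the divergence theorem.  When `bone` is an `anatomy_model` the
#' volume is attributed to the posterior arch (lamina/pedicles/spinous and
#' the non-operated joint processes), the L4 inferior and L5 superior
#' articular processes, the vertebral bodies (`other`) and, optionally,
#' facet cartilage.
#'
#' @param bone an `anatomy_model`, a named list of `ls_solid`, or a single
#'   `ls_solid`
#' @param tool an `ls_solid` (e.g. `plan_tool(...)$solid`) or
#'   `trephine_tool`
#' @param pitch integration lattice pitch (mm)
#' @param include_cartilage count facet cartilage in the total (default
#'   TRUE)
#' @return for an `anatomy_model`: list with `total` (mm^3) and `breakdown`
#'   (named vector); otherwise the volume (named vector for a list input)
#' @export
intersect_volume <- function(bone, tool, pitch = 0.3, include_cartilage = TRUE) {
  if (inherits(tool, "trephine_tool")) tool <- tool$solid
  one <- function(region) {
    sol <- solid_intersection(tool, region)
    if (sol$empty) 0 else solid_volume(sol, pitch = pitch)
  }
  if (inherits(bone, "anatomy_model")) {
    grps <- bone$volume_groups[.volume_group_names(include_cartilage)]
    breakdown <- vapply(grps, one, 0)
    return(list(total = sum(breakdown), breakdown = breakdown))
  }
  if (inherits(bone, "ls_solid")) return(one(bone))
  vapply(bone, one, 0)
}

#' Monte Carlo volume oracle
#'
#' Samples points uniformly in the tool's bounding box and classifies each
#' point (inside tool AND inside any bone region); the estimate is the box
#' volume times the hit fraction with a binomial standard error.  This is
#' the independent check on the surface-extraction Boolean.
#'
#' @param bone as in [intersect_volume()]; meshes (`ls_mesh`) are also
#'   accepted and classified by ray casting
#' @param tool `ls_solid`, `trephine_tool` or `ls_mesh`
#' @param n_samples number of sample points (>= 1e4)
#' @param seed RNG seed (deterministic output)
#' @param include_cartilage as in [intersect_volume()]
#' @return list with `estimate` and `stderr` (mm^3)
#' @export
monte_carlo_volume <- function(bone, tool, n_samples = 1e6, seed = 1,
                               include_cartilage = TRUE) {
  if (n_samples < 1e4) stop("n_samples must be at least 1e4")
  if (inherits(tool, "trephine_tool")) tool <- tool$solid
  if (inherits(tool, "ls_mesh")) tool <- solid_from_mesh(tool)
  solids <- if (inherits(bone, "anatomy_model")) {
    unname(bone$volume_groups[.volume_group_names(include_cartilage)])
  } else if (inherits(bone, "ls_solid") || inherits(bone, "ls_mesh")) {
    list(bone)
  } else bone
  solids <- lapply(solids, function(s) if (inherits(s, "ls_mesh")) solid_from_mesh(s) else s)

  bb <- tool$bbox
  vbox <- bbox_volume(bb)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  hits <- 0
  chunk <- 2e5
  done <- 0
  while (done < n_samples) {
    n <- min(chunk, n_samples - done)
    P <- cbind(stats::runif(n, bb[1, 1], bb[2, 1]),
               stats::runif(n, bb[1, 2], bb[2, 2]),
               stats::runif(n, bb[1, 3], bb[2, 3]))
    intool <- solid_contains(tool, P)
    inbone <- rep(FALSE, n)
    if (any(intool)) {
      sub <- P[intool, , drop = FALSE]
      hit <- rep(FALSE, nrow(sub))
      for (s in solids) {
        todo <- which(!hit)
        if (!length(todo)) break
        hit[todo] <- solid_contains(s, sub[todo, , drop = FALSE])
      }
      inbone[intool] <- hit
    }
    hits <- hits + sum(intool & inbone)
    done <- done + n
  }
  p <- hits / n_samples
  list(estimate = vbox * p,
       stderr = vbox * sqrt(p * (1 - p) / n_samples))
}

#' Resect an anatomy model with a tool
#'
#' Replaces every bone/cartilage region by `region` minus `tool`.  Regions
#' whose bounding box is disjoint from the tool are returned untouched
#' (bit-identical); regions consumed entirely are dropped and listed in the
#' removal report.
#'
#' @param model an `anatomy_model`
#' @param tool `ls_solid` or `trephine_tool`
#' @param pitch lattice pitch for removed-volume quantification (mm)
#' @param regions region names subject to resection (defaults to bone and
#'   facet cartilage)
#' @return the resected `anatomy_model`; `attr(, "removal_report")` is a
#'   data frame with per-region removed volume and drop status
#' @export
resect <- function(model, tool, pitch = 0.4, regions = NULL) {
  if (inherits(tool, "trephine_tool")) tool <- tool$solid
  if (is.null(regions))
    regions <- grep("cortical|cancellous|posterior_elements|facet_cartilage",
                    names(model$regions), value = TRUE)
  out <- model
  out$mesh_cache <- new.env(parent = emptyenv())
  report <- list()
  resected <- character(0)
  dropped <- character(0)
  for (nm in names(model$regions)) {
    reg <- model$regions[[nm]]
    touched <- nm %in% regions && !is.null(bbox_intersect(reg$bbox, tool$bbox))
    removed <- 0
    drop <- FALSE
    if (touched) {
      removed <- solid_volume(solid_intersection(tool, reg), pitch = pitch)
      if (removed > 1e-9) {
        newreg <- solid_difference(reg, tool, label = reg$label)
        # emptiness probe: coarse lattice over the region bounding box
        bb <- reg$bbox
        step <- max(1, pitch)
        gx <- seq(bb[1, 1], bb[2, 1], by = step)
        gy <- seq(bb[1, 2], bb[2, 2], by = step)
        gz <- seq(bb[1, 3], bb[2, 3], by = step)
        f <- eval_field_grid(newreg, gx, gy, gz)
        if (!any(f < 0)) {
          drop <- TRUE
          dropped <- c(dropped, nm)
        } else {
          out$regions[[nm]] <- newreg
          resected <- c(resected, nm)
        }
      } else touched <- FALSE
    }
    if (!touched || (!drop && removed <= 1e-9)) {
      # untouched: carry over any cached mesh so output is bit-identical
      cached <- model$mesh_cache[[nm]]
      if (!is.null(cached)) out$mesh_cache[[nm]] <- cached
    }
    report[[nm]] <- data.frame(region = nm, removed_volume = removed,
                               dropped = drop)
  }
  out$regions[dropped] <- NULL
  out$resected <- union(model$resected %||% character(0), resected)
  # volume groups must reflect the resection for downstream accounting
  out$volume_groups <- lapply(model$volume_groups, function(g)
    if (is.null(bbox_intersect(g$bbox, tool$bbox))) g
    else solid_difference(g, tool, label = g$label))
  rep_df <- do.call(rbind, report)
  rownames(rep_df) <- NULL
  attr(out, "removal_report") <- rep_df
  out
}

#' Full-factorial osteotomy volume experiment over a cohort
#'
#' One row per subject x angle x diameter x attempts.  Each subject's
#' interspace frame is built from its endplate planes and posterior-edge
#' landmarks; tools follow the planned fan of angles with the 5 degree
#' second-attempt offset.
#'
#' @param cohort a `cohort_spec`, or a list of `subject_params`
#' @param angles entry angles (degrees)
#' @param diameters tool diameters (mm)
#' @param attempts attempt counts
#' @param pitch integration pitch (mm); 0.5 keeps the 900-row factorial
#'   tractable while staying well inside the Monte Carlo oracle's
#'   uncertainty
#' @param include_cartilage count facet cartilage in totals
#' @param progress print per-subject progress
#' @return data frame of class `osteotomy_table`; failures (if any) are
#'   recorded in `attr(, "errors")`
#' @export
run_volume_experiment <- function(cohort, angles = c(20, 30, 40, 50, 60, 70),
                                  diameters = c(7, 8, 9), attempts = c(1, 2),
                                  pitch = 0.5, include_cartilage = TRUE,
                                  progress = FALSE) {
  subjects <- if (inherits(cohort, "cohort_spec")) sample_cohort(cohort) else cohort
  rows <- list()
  errors <- list()
  for (i in seq_along(subjects)) {
    if (progress) message(sprintf("subject %d/%d", i, length(subjects)))
    res <- tryCatch({
      model <- generate_phantom(subjects[[i]])
      frame <- build_interspace_frame(model, model$planes$L4_inferior,
                                      model$planes$L5_superior)
      sub_rows <- list()
      for (ang in angles) for (dia in diameters) for (att in attempts) {
        plan <- trephine_plan(ang, dia, att)
        tool <- plan_tool(frame, plan)
        iv <- intersect_volume(model, tool$solid, pitch = pitch,
                               include_cartilage = include_cartilage)
        sub_rows[[length(sub_rows) + 1]] <- data.frame(
          subject = i, group = plan$group, angle_deg = ang,
          diameter_mm = dia, attempts = att,
          removed_volume = iv$total,
          vol_lamina = iv$breakdown[["lamina"]],
          vol_facet_L4_inferior = iv$breakdown[["facet_L4_inferior"]],
          vol_facet_L5_superior = iv$breakdown[["facet_L5_superior"]],
          vol_other = iv$breakdown[["other"]],
          vol_cartilage = if (include_cartilage) iv$breakdown[["cartilage"]] else 0)
      }
      do.call(rbind, sub_rows)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[as.character(i)]] <- conditionMessage(res)
      warning("subject ", i, " failed and was excluded: ", conditionMessage(res))
    } else rows[[length(rows) + 1]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("osteotomy_table", class(out))
  attr(out, "errors") <- errors
  out
}
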