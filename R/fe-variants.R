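# Surgical variants M1-M6 and the biomechanical experiment.
#
# M1 is the intact segment.  M2-M6 resect bone/cartilage along the planned
# trephine corridor (element removal by centroid containment, voxel-FE
# style) and remove capsular/flavum trusses:
#   M2: 8 mm, 60 deg, 1 attempt, 1/4 of the capsular trusses
#   M3: 8 mm, 30 deg, 1 attempt, right ligamentum flavum
#   M4: 8 mm, 50 deg, 1 attempt, 1/2 capsular
#   M5: 8 mm, 50 deg, 2 attempts, 1/2 capsular (larger cartilage footprint)
#   M6: 9 mm, 50 deg, 1 attempt, 3/4 capsular, extensive cartilage removal

#' Surgical variant definition
#' @param id one of "M1".."M6"
#' @return list of class `surgical_variant`
#' @export
surgical_variant <- function(id = c("M1", "M2", "M3", "M4", "M5", "M6")) {
  id <- match.arg(id)
  spec <- switch(id,
    M1 = list(plan = NULL, cl_fraction = 0, flavum = "none",
              cartilage_removal = "none"),
    M2 = list(plan = trephine_plan(60, 8, 1), cl_fraction = 1 / 4,
              flavum = "none", cartilage_removal = "small"),
    M3 = list(plan = trephine_plan(30, 8, 1), cl_fraction = 0,
              flavum = "right", cartilage_removal = "none"),
    M4 = list(plan = trephine_plan(50, 8, 1), cl_fraction = 1 / 2,
              flavum = "none", cartilage_removal = "moderate"),
    M5 = list(plan = trephine_plan(50, 8, 2), cl_fraction = 1 / 2,
              flavum = "none", cartilage_removal = "large"),
    M6 = list(plan = trephine_plan(50, 9, 1), cl_fraction = 3 / 4,
              flavum = "none", cartilage_removal = "extensive"))
  structure(c(list(id = id), spec), class = "surgical_variant")
}

# Mechanical connectivity of a tet mesh: components over shared faces,
# then components sharing >= 3 nodes are merged (block interfaces with
# mismatched face diagonals are stable connections, a single shared node
# or edge is a mechanism).
tet_components <- function(nnodes, tets) {
  m <- nrow(tets)
  fidx <- rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
                tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
  fs <- t(apply(fidx, 1, sort))
  key <- (fs[, 1] * (nnodes + 1) + fs[, 2]) * (nnodes + 1) + fs[, 3]
  tid <- rep(seq_len(m), 4)
  ord <- order(key)
  key_s <- key[ord]; tid_s <- tid[ord]
  same <- which(key_s[-1] == key_s[-length(key_s)])
  e <- cbind(tid_s[same], tid_s[same + 1])
  # label propagation on the tet adjacency
  comp <- seq_len(m)
  if (nrow(e)) {
    ee <- rbind(e, e[, 2:1])
    repeat {
      mm <- tapply(comp[ee[, 2]], ee[, 1], min)
      idx <- as.integer(names(mm))
      new <- comp
      new[idx] <- pmin(new[idx], mm)
      new <- new[new]
      if (identical(new, comp)) break
      comp <- new
    }
  }
  # merge face-components that share at least 3 nodes
  nodecomp <- unique(data.frame(node = as.vector(tets),
                                comp = rep(comp, 4)))
  dup <- nodecomp$node[duplicated(nodecomp$node)]
  if (length(dup)) {
    sub <- nodecomp[nodecomp$node %in% dup, ]
    pairs <- do.call(rbind, lapply(split(sub$comp, sub$node), function(cs) {
      cs <- sort(unique(cs))
      if (length(cs) < 2) return(NULL)
      t(utils::combn(cs, 2))
    }))
    if (!is.null(pairs) && nrow(pairs)) {
      pk <- paste(pairs[, 1], pairs[, 2])
      tab <- table(pk)
      strong <- names(tab)[tab >= 3]
      if (length(strong)) {
        reps <- sort(unique(comp))
        lab <- stats::setNames(reps, reps)
        findr <- function(x) { while (lab[[as.character(x)]] != x) x <- lab[[as.character(x)]]; x }
        for (s in strong) {
          ab <- as.integer(strsplit(s, " ")[[1]])
          ra <- findr(ab[1]); rb <- findr(ab[2])
          if (ra != rb) lab[[as.character(max(ra, rb))]] <- min(ra, rb)
        }
        comp <- vapply(comp, findr, 0)
      }
    }
  }
  comp
}

# connected components over tet-sharing nodes (label propagation)
node_components <- function(nnodes, tets) {
  e <- rbind(tets[, c(1, 2)], tets[, c(1, 3)], tets[, c(1, 4)],
             tets[, c(2, 3)], tets[, c(2, 4)], tets[, c(3, 4)])
  e <- rbind(e, e[, 2:1])
  comp <- seq_len(nnodes)
  repeat {
    m <- tapply(comp[e[, 2]], e[, 1], min)
    idx <- as.integer(names(m))
    new <- comp
    new[idx] <- pmin(new[idx], m)
    # propagate through the representative chain
    new <- new[new]
    if (identical(new, comp)) break
    comp <- new
  }
  comp
}

#' Apply a surgical variant to an FE model
#'
#' M1 is returned unchanged (identical node and element sets).  Otherwise
#' the variant's trephine corridor is resected by removing every bone and
#' facet-cartilage element whose centroid lies inside the tool; capsular
#' trusses of the operated (right) L4/5 joint are removed in order of
#' increasing distance from the tool axis; M3 removes the right L4/5
#' ligamentum flavum trusses.
#'
#' @param fem solver-ready `fe_model` of the intact segment
#' @param model the `anatomy_model`
#' @param variant a [surgical_variant()]
#' @return modified `fe_model`; removed element/truss counts are in
#'   `attr(, "resection")`
#' @export
apply_variant <- function(fem, model, variant) {
  if (variant$id == "M1" && is.null(variant$plan) && variant$cl_fraction == 0 &&
      variant$flavum == "none") return(fem)
  out <- fem
  removed_elems <- 0L
  if (!is.null(variant$plan)) {
    frame <- build_interspace_frame(model, model$planes$L4_inferior,
                                    model$planes$L5_superior)
    tool <- plan_tool(frame, variant$plan)
    resectable <- grepl("cortical|cancellous|posterior_elements|facet_cartilage",
                        fem$region)
    ctr <- (fem$nodes[fem$tets[, 1], ] + fem$nodes[fem$tets[, 2], ] +
              fem$nodes[fem$tets[, 3], ] + fem$nodes[fem$tets[, 4], ]) / 4
    inside <- solid_contains(tool$solid, ctr) & resectable
    # "extensive" cartilage removal (M6): the large trephine destroys the
    # whole articular cartilage of the operated joint, beyond the nominal
    # cylinder footprint
    if (identical(variant$cartilage_removal, "extensive"))
      inside <- inside | (fem$region == "facet_cartilage_L4L5_right")
    removed_elems <- sum(inside)
    out$tets <- fem$tets[!inside, , drop = FALSE]
    out$region <- fem$region[!inside]
    # floating fragments: components that lose contact with the anchored
    # column.  Small islands (loose slivers at the cut surface) come out
    # with the trephine core and are removed; a large disconnected fragment
    # invalidates the model.
    el_comp <- tet_components(nrow(out$nodes), out$tets)
    has_fixed <- unique(el_comp[rowSums(matrix(out$tets %in% out$fixed_nodes,
                                               ncol = 4)) > 0])
    has_load <- unique(el_comp[rowSums(matrix(out$tets %in% out$load_nodes,
                                              ncol = 4)) > 0])
    anchored <- union(has_fixed, has_load)
    loose_el <- !(el_comp %in% anchored)
    if (any(loose_el)) {
      if (mean(loose_el) > 0.05)
        stop("resection disconnected a major bone fragment (variant ",
             variant$id, ")")
      removed_elems <- removed_elems + sum(loose_el)
      out$tets <- out$tets[!loose_el, , drop = FALSE]
      out$region <- out$region[!loose_el]
    }
  }
  # capsular truss removal on the operated side, nearest-to-tool-axis first
  if (variant$cl_fraction > 0) {
    tr <- out$trusses
    sel <- which(tr$group == "CL" & tr$level == "L4L5" & tr$side == "right")
    nrem <- round(variant$cl_fraction * length(sel))
    if (nrem > 0) {
      if (!is.null(variant$plan)) {
        frame <- build_interspace_frame(model, model$planes$L4_inferior,
                                        model$planes$L5_superior)
        ax <- trephine_axis(frame, variant$plan$angle_deg, 1, variant$plan$side)
        mid <- (out$nodes[tr$n1[sel], , drop = FALSE] +
                  out$nodes[tr$n2[sel], , drop = FALSE]) / 2
        rel <- sweep(mid, 2, ax$point)
        t_par <- as.numeric(rel %*% ax$direction)
        dist <- sqrt(pmax(0, rowSums(rel^2) - t_par^2))
        sel <- sel[order(dist)]
      }
      out$trusses <- tr[-sel[seq_len(nrem)], , drop = FALSE]
    }
  }
  if (variant$flavum != "none") {
    tr <- out$trusses
    drop <- tr$group == "LF" & tr$level == "L4L5" & tr$side == variant$flavum
    out$trusses <- tr[!drop, , drop = FALSE]
  }
  # drop springs whose cartilage nodes lost all their elements
  if (!is.null(out$springs) && nrow(out$springs)) {
    used <- unique(as.vector(out$tets))
    keep <- out$springs$a %in% used & out$springs$b %in% used
    out$springs <- out$springs[keep, , drop = FALSE]
  }
  # re-anchor trusses whose endpoint lost all its elements: the ligament
  # attaches over an area, so it moves to the nearest surviving bone node;
  # it is removed only when no bone remains within reach
  if (!is.null(out$trusses) && nrow(out$trusses)) {
    used <- unique(as.vector(out$tets))
    usedset <- rep(FALSE, nrow(out$nodes)); usedset[used] <- TRUE
    reanchor <- function(nid) {
      if (usedset[nid]) return(nid)
      d2 <- rowSums(sweep(out$nodes[used, , drop = FALSE], 2,
                          out$nodes[nid, ], `-`)^2)
      j <- which.min(d2)
      if (d2[j] > 25) return(NA_integer_)
      used[j]
    }
    tr <- out$trusses
    tr$n1 <- vapply(tr$n1, reanchor, 0L)
    tr$n2 <- vapply(tr$n2, reanchor, 0L)
    tr <- tr[!is.na(tr$n1) & !is.na(tr$n2) & tr$n1 != tr$n2, , drop = FALSE]
    out$trusses <- tr
  }
  attr(out, "resection") <- list(removed_elements = removed_elems,
                                 trusses_remaining = nrow(out$trusses))
  out
}

#' Run the biomechanical experiment
#'
#' Solves every requested variant under the six load directions and
#' reports L4-L5 and L3-L4 range of motion plus maximum von Mises stress
#' in the L4/5 annulus and the adjacent endplates.
#'
#' @param model an `anatomy_model`
#' @param variants character vector of variant ids (default M1..M6)
#' @param directions load directions (default all six)
#' @param target_edge FE mesh edge length (mm)
#' @param follower_load,moment load protocol (N, N m)
#' @param materials material table
#' @param progress print progress
#' @return data frame with one row per variant x direction
#' @export
run_fe_experiment <- function(model, variants = paste0("M", 1:6),
                              directions = c("flexion", "extension",
                                             "left_bending", "right_bending",
                                             "left_rotation", "right_rotation"),
                              target_edge = 3, follower_load = 400, moment = 10,
                              materials = material_table(), progress = FALSE) {
  fem0 <- build_fe_model(model, target_edge, materials)
  rows <- list()
  for (vid in variants) {
    if (progress) message("variant ", vid)
    var <- surgical_variant(vid)
    fem <- apply_variant(fem0, model, var)
    K <- assemble_stiffness(fem)
    for (dir in directions) {
      sol <- assemble_and_solve(fem, load_case(dir, follower_load, moment), K = K)
      vm <- compute_von_mises(fem, sol$u)
      rows[[length(rows) + 1]] <- data.frame(
        variant = vid, direction = dir,
        rom_L4L5 = compute_rom(fem, sol$u, "L4L5"),
        rom_L3L4 = compute_rom(fem, sol$u, "L3L4"),
        vm_annulus_L4L5 = vm$max_by_region[["disc_L4L5_annulus"]],
        vm_endplate_L5_superior = vm$max_by_region[["endplate_L5_superior"]],
        vm_endplate_L4_inferior = vm$max_by_region[["endplate_L4_inferior"]],
        residual = sol$residual, engaged_springs = sol$engaged)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
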