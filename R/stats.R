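# Cohort statistics over the osteotomy volume table: per-condition
# summaries (mean +- SD), paired/unpaired two-sample t-tests and one-way
# ANOVA across angle groups, with the */** significance convention.

#' Per-condition summary of an osteotomy volume table
#'
#' @param volumes an `osteotomy_table` from [run_volume_experiment()] (or
#'   any data frame with `group`, `angle_deg`, `diameter_mm`, `attempts`,
#'   `removed_volume`, `subject`)
#' @return data frame keyed by (group, angle, diameter, attempts) with n,
#'   mean and unbiased SD (mm^3)
#' @export
summarize_volumes <- function(volumes) {
  key <- interaction(volumes$group, volumes$angle_deg, volumes$diameter_mm,
                     volumes$attempts, drop = TRUE)
  parts <- split(volumes, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    if (nrow(d) < 2)
      warning("condition with fewer than 2 subjects omitted: ",
              d$angle_deg[1], "/", d$diameter_mm[1], "/", d$attempts[1])
    data.frame(group = d$group[1], angle_deg = d$angle_deg[1],
               diameter_mm = d$diameter_mm[1], attempts = d$attempts[1],
               n = nrow(d), mean = mean(d$removed_volume),
               sd = stats::sd(d$removed_volume))
  }))
  out <- out[out$n >= 2, ]
  out <- out[order(out$diameter_mm, out$attempts, out$angle_deg), ]
  rownames(out) <- NULL
  out
}

signif_flag <- function(p) {
  if (is.na(p)) "" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Two-sample comparison of osteotomy volumes
#'
#' Two-sided t-test between two conditions.  Within-cohort angle contrasts
#' are paired by subject by default (every synthetic subject contributes
#' all conditions).
#'
#' @param x,y numeric vectors of volumes for the two conditions (aligned
#'   by subject when `paired`)
#' @param paired paired by subject (default TRUE)
#' @return list of class `comparison_result`: statistic, p_value,
#'   significance flags at 0.05 and 0.01
#' @export
pairwise_test <- function(x, y, paired = TRUE) {
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 values per group")
  if (paired && length(x) != length(y))
    stop("paired comparison needs equal group sizes")
  degenerate <- if (paired) stats::sd(x - y) == 0
  else stats::sd(x) == 0 && stats::sd(y) == 0
  if (degenerate && isTRUE(all.equal(mean(x), mean(y)))) {
    res <- list(statistic = 0, p_value = 1, degenerate = TRUE)
  } else {
    tt <- stats::t.test(x, y, paired = paired)
    res <- list(statistic = unname(tt$statistic), p_value = unname(tt$p.value),
                degenerate = FALSE)
  }
  res$significant_05 <- res$p_value < 0.05
  res$significant_01 <- res$p_value < 0.01
  res$flag <- signif_flag(res$p_value)
  res$paired <- paired
  structure(res, class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("t = %.3f, p = %.4g %s%s\n", x$statistic, x$p_value, x$flag,
              if (isTRUE(x$degenerate)) " (degenerate: zero variance)" else ""))
  invisible(x)
}

#' One-way ANOVA across three or more conditions
#'
#' @param ... numeric vectors, one per condition (at least 3), or a single
#'   list of them
#' @return `comparison_result` with the F statistic and p value
#' @export
anova_volumes <- function(...) {
  gs <- list(...)
  if (length(gs) == 1 && is.list(gs[[1]]) && !is.numeric(gs[[1]])) gs <- gs[[1]]
  if (length(gs) < 3)
    stop("one-way ANOVA needs at least 3 groups; use pairwise_test for 2")
  vals <- unlist(gs)
  fac <- factor(rep(seq_along(gs), vapply(gs, length, 0L)))
  fit <- stats::aov(vals ~ fac)
  sm <- summary(fit)[[1]]
  res <- list(statistic = sm[["F value"]][1], p_value = sm[["Pr(>F)"]][1],
              degenerate = FALSE)
  if (is.na(res$statistic)) { res$statistic <- 0; res$p_value <- 1 }
  res$significant_05 <- res$p_value < 0.05
  res$significant_01 <- res$p_value < 0.01
  res$flag <- signif_flag(res$p_value)
  structure(res, class = "comparison_result")
}

#' Angle-contrast table for a volume experiment
#'
#' Reproduces the reported contrast structure: paired t-tests between
#' angle pairs within each diameter x attempts cell, plus the per-cell
#' one-way ANOVA across the three angles of each approach group.
#'
#' @param volumes an `osteotomy_table`
#' @param contrasts list of angle pairs to test
#' @param paired paired by subject
#' @return data frame of contrasts with statistics, p values and flags
#' @export
angle_contrasts <- function(volumes,
                            contrasts = list(c(20, 30), c(20, 40), c(30, 40),
                                             c(40, 50), c(50, 60), c(50, 70),
                                             c(60, 70)),
                            paired = TRUE) {
  rows <- list()
  for (dia in sort(unique(volumes$diameter_mm)))
    for (att in sort(unique(volumes$attempts))) {
      cell <- volumes[volumes$diameter_mm == dia & volumes$attempts == att, ]
      cell <- cell[order(cell$subject), ]
      for (cp in contrasts) {
        x <- cell$removed_volume[cell$angle_deg == cp[1]]
        y <- cell$removed_volume[cell$angle_deg == cp[2]]
        if (length(x) < 2 || length(y) < 2) next
        ct <- pairwise_test(x, y, paired = paired)
        rows[[length(rows) + 1]] <- data.frame(
          diameter_mm = dia, attempts = att,
          angle_a = cp[1], angle_b = cp[2],
          statistic = ct$statistic, p_value = ct$p_value, flag = ct$flag)
      }
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
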