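# Phenol-oxidase (PO) microplate kinetics and microbe inhibition-zone
# statistics. PO activity is the Vmax of the linear phase of a DOPA
# conversion trace read at 490 nm every 2 min for 90 min, after
# subtracting the substrate self-darkening measured in blank wells.

#' Subtract the (mean) blank trace from a kinetic trace
#'
#' Blank wells carry only substrate self-darkening; subtracting their
#' mean pointwise leaves the enzymatic signal. All traces must share the
#' same time grid.
#'
#' @param od numeric absorbance trace.
#' @param blanks numeric vector (one blank) or matrix with one blank per
#'   row, same number of timepoints as `od`.
#' @return corrected absorbance trace.
#' @export
blank_correct <- function(od, blanks) {
  if (is.matrix(blanks)) {
    if (ncol(blanks) != length(od)) stop("time grid mismatch with blanks")
    blanks <- colMeans(blanks)
  }
  if (length(blanks) != length(od)) stop("time grid mismatch with blanks")
  od - blanks
}

#' Vmax of the linear phase of a kinetic trace
#'
#' The maximal least-squares slope over all contiguous windows of
#' `window_points` readings, clipped at zero. On a lag / linear /
#' plateau shaped trace any window fully inside the linear phase
#' recovers the true slope, so the maximum over windows estimates the
#' linear-phase Vmax without locating the phase explicitly. The result
#' is invariant to adding a constant to the whole trace.
#'
#' @param od blank-corrected absorbance trace.
#' @param minutes timepoints in minutes (default an equally spaced
#'   0-90 min grid matching `od`).
#' @param window_points window width in readings (default 10, i.e.
#'   20 min at 2-min intervals); at least 3 and at most `length(od)`.
#' @return list with `vmax` (OD/min, >= 0), `window_start` and
#'   `window_end` (minutes of the best window).
#' @export
po_vmax <- function(od, minutes = seq(0, by = 2, length.out = length(od)),
                    window_points = 10) {
  n <- length(od)
  if (length(minutes) != n) stop("minutes and od differ in length")
  if (window_points < 3) stop("window_points must be >= 3")
  if (window_points > n) stop("window longer than trace")
  best <- -Inf; best_i <- 1L
  for (i in seq_len(n - window_points + 1L)) {
    idx <- i:(i + window_points - 1L)
    x <- minutes[idx]; y <- od[idx]
    slope <- stats::cov(x, y) / stats::var(x)
    if (slope > best) { best <- slope; best_i <- i }
  }
  list(vmax = max(best, 0),
       window_start = minutes[best_i],
       window_end = minutes[best_i + window_points - 1L])
}

#' Per-well Vmax from a long-format kinetic plate
#'
#' Averages all blank wells, blank-corrects every signal well and
#' estimates its linear-phase Vmax — the plate-level pipeline from raw
#' readings to the per-well activities consumed by [po_group_stats].
#'
#' @param traces data.frame with columns `well`, `minute`, `od490`,
#'   `is_blank` (and optionally `group`, carried through).
#' @param window_points see [po_vmax].
#' @return data.frame per signal well: `well` (, `group`), `vmax`,
#'   `window_start`, `window_end`.
#' @export
po_vmax_table <- function(traces, window_points = 10) {
  stopifnot(all(c("well", "minute", "od490", "is_blank") %in% names(traces)))
  traces <- traces[order(traces$well, traces$minute), ]
  minutes <- sort(unique(traces$minute))
  get_trace <- function(w) {
    d <- traces[traces$well == w, ]
    if (!identical(d$minute, minutes)) stop("time grid mismatch across wells")
    d$od490
  }
  blank_wells <- unique(traces$well[traces$is_blank])
  if (length(blank_wells) == 0L) stop("no blank wells on the plate")
  blank_mean <- rowMeans(sapply(blank_wells, get_trace))
  signal_wells <- setdiff(unique(traces$well), blank_wells)
  rows <- lapply(signal_wells, function(w) {
    fit <- po_vmax(blank_correct(get_trace(w), blank_mean), minutes,
                   window_points)
    out <- data.frame(well = w, vmax = fit$vmax,
                      window_start = fit$window_start,
                      window_end = fit$window_end,
                      stringsAsFactors = FALSE)
    if ("group" %in% names(traces))
      out$group <- traces$group[match(w, traces$well)]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group statistics of PO activity on the square-root scale
#'
#' Summarises per-well Vmax values per group on the square-root scale
#' (the variance-stabilising scale the assay is reported on) and runs
#' Welch's t-test of every group against the reference (wild-type)
#' group, annotated with significance stars. Groups of fewer than two
#' wells are summarised but not tested.
#'
#' @param vmax data.frame with columns `group` and `vmax`.
#' @param reference name of the reference group (default `"wild-type"`).
#' @return data.frame per group: `n`, `mean_sqrt_vmax`, `sd_sqrt_vmax`,
#'   `median_sqrt_vmax`, `q1`, `q3`, `p_vs_reference` (`NA` for the
#'   reference itself and for untestable groups), `stars`.
#' @export
po_group_stats <- function(vmax, reference = "wild-type") {
  stopifnot(all(c("group", "vmax") %in% names(vmax)))
  if (!reference %in% vmax$group)
    stop("reference group '", reference, "' not present")
  if (any(vmax$vmax < 0)) stop("vmax must be >= 0")
  vmax$sqrt_vmax <- sqrt(vmax$vmax)
  ref <- vmax$sqrt_vmax[vmax$group == reference]
  groups <- unique(vmax$group)
  rows <- lapply(groups, function(g) {
    v <- vmax$sqrt_vmax[vmax$group == g]
    p <- NA_real_
    if (!identical(g, reference)) {
      if (length(v) < 2L || length(ref) < 2L) {
        warning("group '", g, "' not tested (need n >= 2 in both groups)")
      } else if (stats::sd(v) == 0 && stats::sd(ref) == 0) {
        p <- 1
      } else {
        p <- stats::t.test(v, ref)$p.value
      }
    }
    data.frame(group = g, n = length(v),
               mean_sqrt_vmax = mean(v), sd_sqrt_vmax = stats::sd(v),
               median_sqrt_vmax = stats::median(v),
               q1 = unname(stats::quantile(v, 0.25)),
               q3 = unname(stats::quantile(v, 0.75)),
               p_vs_reference = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$stars <- significance_stars(out$p_vs_reference)
  rownames(out) <- NULL
  out
}

#' Rank-sum comparison of inhibition-zone areas
#'
#' For each microbe, sex and knock-down group, compares the inhibition
#' zone areas (cm^2) against the same-sex wild-type group with the
#' two-sided Mann-Whitney-Wilcoxon test ([rank_sum_test]).
#'
#' @param zones data.frame with columns `microbe`, `sex`, `group`,
#'   `area` (cm^2, >= 0).
#' @param reference wild-type group label (default `"wt"`).
#' @return data.frame per (microbe, sex, group): group sizes, medians,
#'   `p`, `stars`.
#' @export
zone_compare <- function(zones, reference = "wt") {
  stopifnot(all(c("microbe", "sex", "group", "area") %in% names(zones)))
  if (any(zones$area < 0)) stop("areas must be >= 0")
  cells <- unique(zones[zones$group != reference,
                        c("microbe", "sex", "group")])
  if (nrow(cells) == 0L) stop("no knock-down groups to compare")
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel_kd <- zones$microbe == cells$microbe[i] &
      zones$sex == cells$sex[i] & zones$group == cells$group[i]
    sel_wt <- zones$microbe == cells$microbe[i] &
      zones$sex == cells$sex[i] & zones$group == reference
    if (!any(sel_wt))
      stop("no same-sex wild-type measurements for ",
           cells$microbe[i], "/", cells$sex[i])
    ts <- rank_sum_test(zones$area[sel_kd], zones$area[sel_wt])
    data.frame(microbe = cells$microbe[i], sex = cells$sex[i],
               group = cells$group[i],
               n_kd = sum(sel_kd), n_wt = sum(sel_wt),
               median_kd = stats::median(zones$area[sel_kd]),
               median_wt = stats::median(zones$area[sel_wt]),
               p = ts$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$stars <- significance_stars(out$p)
  rownames(out) <- NULL
  out
}
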