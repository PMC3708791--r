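# GC-MS quantification: external-standard calibration, retention-index
# peak matching, mass back-calculation (with "equivalents" through a
# surrogate curve for compounds lacking authentic standards), molar
# totals and compositional statistics.

#' Fit a linear calibration curve
#'
#' Ordinary least squares of peak area on analyte amount for an external
#' standard series (typically five points). The curve is used untransformed
#' and with a free intercept.
#'
#' @param amount_ng standard amounts (ng).
#' @param area integrated peak areas.
#' @param compound optional compound code carried in the result.
#' @return object of class `calibration_curve`: list with `compound`,
#'   `slope` (area per ng), `intercept`, `r_squared`, `n_points`.
#' @export
fit_calibration <- function(amount_ng, area, compound = NA_character_) {
  if (length(amount_ng) != length(area))
    stop("amount_ng and area differ in length")
  if (length(amount_ng) < 2L || length(unique(amount_ng)) < 2L)
    stop("calibration needs at least two distinct amounts")
  fit <- stats::lm(area ~ amount_ng)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((area - mean(area))^2)
  structure(list(compound = compound,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 n_points = length(amount_ng)),
            class = "calibration_curve")
}

#' Fit calibration curves for a whole standard series table
#'
#' @param standards data.frame with columns `compound`, `amount_ng`,
#'   `area`; one five-point series per standard compound.
#' @return named list of `calibration_curve` objects.
#' @export
fit_calibration_set <- function(standards) {
  stopifnot(all(c("compound", "amount_ng", "area") %in% names(standards)))
  sp <- split(standards, standards$compound)
  lapply(sp, function(d) fit_calibration(d$amount_ng, d$area, d$compound[1L]))
}

#' Match retention indices to registry compounds
#'
#' Nearest-neighbour matching against all retention-index aliases in the
#' registry (a compound observed at two elution positions has two
#' aliases). Indices farther than `tolerance` from every alias, or
#' exactly equidistant from two different compounds, are left unmatched.
#'
#' @param retention_index numeric vector of Kovats indices.
#' @param registry compound registry, see [compound_registry].
#' @param tolerance maximal absolute index distance (default 5).
#' @return character vector of compound codes, `NA` where unmatched.
#' @export
match_peak <- function(retention_index, registry = compound_registry(),
                       tolerance = 5) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  aliases <- rbind(
    data.frame(compound = registry$compound, ri = registry$ri1),
    data.frame(compound = registry$compound, ri = registry$ri2))
  aliases <- aliases[!is.na(aliases$ri), ]
  vapply(retention_index, function(ri) {
    d <- abs(aliases$ri - ri)
    dmin <- min(d)
    if (dmin > tolerance) return(NA_character_)
    hits <- unique(aliases$compound[d == dmin])
    if (length(hits) > 1L) {
      warning("retention index ", ri, " ties between ",
              paste(hits, collapse = " and "), "; left unmatched")
      return(NA_character_)
    }
    hits
  }, character(1))
}

#' Back-calculate analyte mass from a peak area
#'
#' Inverts the calibration line: `(area - intercept) / slope`, clipped at
#' zero (a peak smaller than the blank response reports 0 ng). Compounds
#' without an authentic standard are quantified as equivalents by passing
#' the surrogate's curve.
#'
#' @param area integrated peak area(s).
#' @param curve a `calibration_curve`.
#' @return mass in ng (vectorised).
#' @export
quantify_mass <- function(area, curve) {
  if (!inherits(curve, "calibration_curve")) stop("curve must be fitted")
  if (!is.finite(curve$slope) || curve$slope <= 0)
    stop("calibration slope must be > 0")
  pmax((area - curve$intercept) / curve$slope, 0)
}

# Molecular weights used for molar conversion of the five-component
# profile: summed quinones (benzoquinone + hydroquinone precursor) are
# converted with the benzoquinone MW.
profile_mw <- function() {
  reg <- compound_registry()
  mw <- function(code) reg$mw[match(code, reg$compound)]
  c(MBQ_sum = mw("MBQ"), EBQ_sum = mw("EBQ"),
    `15ene` = mw("15ene"), `17diene` = mw("17diene"),
    `17ene` = mw("17ene"))
}

#' Molar totals of quinones and alkenes
#'
#' Converts the five-component masses to nanomoles and sums the quinone
#' pool (`MBQ_sum + EBQ_sum`, converted with the benzoquinone molecular
#' weights) and the alkene pool (`15ene + 17diene + 17ene`).
#'
#' @param masses named numeric vector (or one-row data.frame) with
#'   elements `MBQ_sum`, `EBQ_sum`, `15ene`, `17diene`, `17ene`.
#' @param unit `"ug"` (default) or `"ng"`.
#' @return list with `quinones_nmol` and `alkenes_nmol`.
#' @export
molar_totals <- function(masses, unit = c("ug", "ng")) {
  unit <- match.arg(unit)
  absent <- setdiff(names(profile_mw()), names(masses))
  if (length(absent) > 0L)
    stop("missing component mass: ", paste(absent, collapse = ", "))
  masses <- unlist(masses[names(profile_mw())])
  if (anyNA(masses)) stop("missing component mass")
  if (any(masses < 0)) stop("masses must be >= 0")
  scale <- if (unit == "ug") 1000 else 1
  nmol <- scale * masses / profile_mw()
  list(quinones_nmol = unname(nmol["MBQ_sum"] + nmol["EBQ_sum"]),
       alkenes_nmol = unname(sum(nmol[c("15ene", "17diene", "17ene")])))
}

#' Molar fractions of the three alkenes
#'
#' @inheritParams molar_totals
#' @return named numeric vector (`15ene`, `17diene`, `17ene`) summing to
#'   1, or all-`NA` with a warning when no alkenes are present.
#' @export
alkene_fractions <- function(masses, unit = c("ug", "ng")) {
  unit <- match.arg(unit)
  mw <- profile_mw()[c("15ene", "17diene", "17ene")]
  m <- unlist(masses[names(mw)])
  nmol <- m / mw
  tot <- sum(nmol)
  if (!is.finite(tot) || tot <= 0) {
    warning("no alkenes present; fractions undefined")
    return(stats::setNames(rep(NA_real_, 3L), names(mw)))
  }
  nmol / tot
}

#' Quantify a GC-MS peak table into volatile profiles
#'
#' Full path from integrated areas to per-sample masses: peaks are
#' matched to compounds (by retention index unless a `compound` column is
#' already present), areas are back-calculated through each compound's
#' surrogate calibration curve, hydroquinones are summed with their
#' benzoquinones into `MBQ_sum`/`EBQ_sum`, and molar pool totals are
#' appended. Compounds flagged unquantified in the registry are dropped.
#'
#' @param peaks data.frame with columns `sample_id`, `sex`, `gland`,
#'   `area`, and either `compound` or `retention_index`.
#' @param standards standard-series table for [fit_calibration_set].
#' @param registry see [compound_registry].
#' @param ri_tolerance retention-index tolerance for [match_peak].
#' @return data.frame (class `volatile_profile`), one row per sample:
#'   `sample_id`, `sex`, `gland`, the five component masses in ng,
#'   `quinones_nmol`, `alkenes_nmol`.
#' @export
quantify_peaks <- function(peaks, standards, registry = compound_registry(),
                           ri_tolerance = 5) {
  stopifnot(all(c("sample_id", "sex", "gland", "area") %in% names(peaks)))
  if (!"compound" %in% names(peaks)) {
    if (!"retention_index" %in% names(peaks))
      stop("peaks need a compound or retention_index column")
    peaks$compound <- match_peak(peaks$retention_index, registry,
                                 ri_tolerance)
  }
  curves <- fit_calibration_set(standards)
  quant <- registry[registry$quantified, ]
  need <- unique(quant$surrogate)
  if (!all(need %in% names(curves)))
    stop("missing standard curve for: ",
         paste(setdiff(need, names(curves)), collapse = ", "))
  peaks <- peaks[!is.na(peaks$compound) &
                   peaks$compound %in% quant$compound, ]
  peaks$mass_ng <- NA_real_
  for (i in seq_len(nrow(peaks))) {
    surr <- quant$surrogate[match(peaks$compound[i], quant$compound)]
    peaks$mass_ng[i] <- quantify_mass(peaks$area[i], curves[[surr]])
  }
  samples <- unique(peaks[, c("sample_id", "sex", "gland")])
  comp_mass <- function(s, code) {
    sel <- peaks$sample_id == s & peaks$compound == code
    if (any(sel)) sum(peaks$mass_ng[sel]) else 0
  }
  out <- samples
  out$MBQ_sum <- mapply(function(s) comp_mass(s, "MBQ") + comp_mass(s, "MHQ"),
                        samples$sample_id)
  out$EBQ_sum <- mapply(function(s) comp_mass(s, "EBQ") + comp_mass(s, "EHQ"),
                        samples$sample_id)
  out$`15ene` <- vapply(samples$sample_id, comp_mass, numeric(1), "15ene")
  out$`17diene` <- vapply(samples$sample_id, comp_mass, numeric(1), "17diene")
  out$`17ene` <- vapply(samples$sample_id, comp_mass, numeric(1), "17ene")
  mol <- t(apply(out[, names(profile_mw())], 1L, function(m)
    unlist(molar_totals(as.list(m), unit = "ng"))))
  out$quinones_nmol <- mol[, "quinones_nmol"]
  out$alkenes_nmol <- mol[, "alkenes_nmol"]
  rownames(out) <- NULL
  class(out) <- unique(c("volatile_profile", class(out)))
  out
}

#' Compositional statistics of a set of gland mass means
#'
#' Given mean component masses for one sex/gland cell, reports the
#' MBQ/EBQ molar ratio, the quinone-to-alkene molar ratio, the alkene
#' molar fractions, and the quinone weight fraction of the total
#' secretion.
#'
#' @inheritParams molar_totals
#' @return list with `mbq_ebq_molar_ratio`, `quinone_alkene_molar_ratio`,
#'   `alkene_fractions`, `quinone_weight_fraction`, `quinones_nmol`,
#'   `alkenes_nmol`.
#' @export
composition_stats <- function(masses, unit = c("ug", "ng")) {
  unit <- match.arg(unit)
  mw <- profile_mw()
  m <- unlist(masses[names(mw)])
  tot <- molar_totals(as.list(m), unit)
  list(
    mbq_ebq_molar_ratio = (m["MBQ_sum"] / mw["MBQ_sum"]) /
      (m["EBQ_sum"] / mw["EBQ_sum"]),
    quinone_alkene_molar_ratio = tot$quinones_nmol / tot$alkenes_nmol,
    alkene_fractions = alkene_fractions(as.list(m), unit),
    quinone_weight_fraction = (m["MBQ_sum"] + m["EBQ_sum"]) / sum(m),
    quinones_nmol = tot$quinones_nmol,
    alkenes_nmol = tot$alkenes_nmol
  )
}

#' Per-cell compositional report for a profile table
#'
#' Averages per-beetle volatile profiles within each sex-by-gland cell
#' and derives the compositional statistics of [composition_stats] per
#' cell, plus each gland's share of the whole-beetle molar totals.
#'
#' @param profiles a `volatile_profile` data.frame (masses in ng).
#' @return data.frame with one row per sex-by-gland cell and columns
#'   `n`, the mean component masses, `quinones_nmol`, `alkenes_nmol`,
#'   `mbq_ebq_molar_ratio`, `quinone_alkene_molar_ratio`, the three
#'   alkene fractions, `quinone_weight_fraction`, and the gland's
#'   `share_quinones` / `share_alkenes` of the sex's whole-beetle totals.
#' @export
compositional_report <- function(profiles) {
  comps <- names(profile_mw())
  cells <- unique(profiles[, c("sex", "gland")])
  if (nrow(cells) == 0L) stop("empty profile set")
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- profiles$sex == cells$sex[i] & profiles$gland == cells$gland[i]
    means <- colMeans(profiles[sel, comps, drop = FALSE])
    st <- composition_stats(as.list(means), unit = "ng")
    data.frame(sex = cells$sex[i], gland = cells$gland[i], n = sum(sel),
               as.list(means),
               quinones_nmol = st$quinones_nmol,
               alkenes_nmol = st$alkenes_nmol,
               mbq_ebq_molar_ratio = unname(st$mbq_ebq_molar_ratio),
               quinone_alkene_molar_ratio =
                 unname(st$quinone_alkene_molar_ratio),
               frac_15ene = unname(st$alkene_fractions["15ene"]),
               frac_17diene = unname(st$alkene_fractions["17diene"]),
               frac_17ene = unname(st$alkene_fractions["17ene"]),
               quinone_weight_fraction =
                 unname(st$quinone_weight_fraction),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$share_quinones <- NA_real_
  out$share_alkenes <- NA_real_
  for (sx in unique(out$sex)) {
    sel <- out$sex == sx
    out$share_quinones[sel] <-
      out$quinones_nmol[sel] / sum(out$quinones_nmol[sel])
    out$share_alkenes[sel] <-
      out$alkenes_nmol[sel] / sum(out$alkenes_nmol[sel])
  }
  rownames(out) <- NULL
  out
}

#' Group and sex comparisons of volatile amounts
#'
#' `compare_volatile_groups` runs the two-sided rank-sum test
#' ([rank_sum_test]) per component between two profile groups (e.g.
#' wild-type vs an RNAi knock-down); `compare_volatile_sexes` runs
#' Welch's t-test per component between the sexes.
#'
#' @param x,y two `volatile_profile` data.frames (or any data.frames
#'   carrying the five component columns).
#' @param components component columns to compare (default the five main
#'   components).
#' @return named numeric vector of two-sided p-values.
#' @export
compare_volatile_groups <- function(x, y,
                                    components = names(profile_mw())) {
  vapply(components, function(cc)
    rank_sum_test(x[[cc]], y[[cc]])$p.value, numeric(1))
}

#' @rdname compare_volatile_groups
#' @export
compare_volatile_sexes <- function(x, y,
                                   components = names(profile_mw())) {
  vapply(components, function(cc) {
    a <- x[[cc]]; b <- y[[cc]]
    if (length(a) < 2L || length(b) < 2L)
      stop("t-test needs n >= 2 per group")
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      stop("zero variance in both groups")
    stats::t.test(a, b)$p.value
  }, numeric(1))
}
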