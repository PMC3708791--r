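# Compound registry and bundled reference tables for the gland-volatile
# pipeline. Molecular weights are the monoisotopic-style values used
# throughout the quantification (g/mol); retention indices are Kovats
# indices, with up to two aliases per compound where two elution
# positions are observed.

#' Registry of the main stink-gland volatiles
#'
#' The benzoquinones (MBQ, EBQ), their hydroquinone precursors (MHQ,
#' EHQ), and the defensive alkenes of tenebrionid stink glands, with
#' molecular weight, Kovats retention index aliases, the calibration
#' surrogate whose standard curve quantifies each compound, and whether
#' the compound enters the five-component quantification.
#'
#' EBQ and 1,8-heptadecadiene lack commercial authentic standards and are
#' quantified as equivalents through the EHQ and 1-heptadecene curves
#' respectively. Minor components (1,6-pentadecadiene, 1-hexadecene,
#' 1,2-dimethoxy-4-n-propylbenzene) are registered so peaks match, but
#' are excluded from quantification.
#'
#' @param quantified_only if `TRUE`, drop the registered-but-unquantified
#'   minor components.
#' @return data.frame with columns `compound` (short code), `name`,
#'   `mw` (g/mol), `ri1`, `ri2` (retention-index aliases, `ri2` may be
#'   `NA`), `surrogate` (standard curve used), `class`
#'   (quinone/hydroquinone/alkene/other), `quantified` (logical).
#' @export
compound_registry <- function(quantified_only = FALSE) {
  reg <- data.frame(
    compound = c("MBQ", "EBQ", "MHQ", "EHQ",
                 "15diene", "15ene", "DMPB", "16ene", "17diene", "17ene"),
    name = c("methyl-1,4-benzoquinone", "ethyl-1,4-benzoquinone",
             "methyl-1,4-hydroquinone", "ethyl-1,4-hydroquinone",
             "1,6-pentadecadiene", "1-pentadecene",
             "1,2-dimethoxy-4-n-propylbenzene", "1-hexadecene",
             "1,8-heptadecadiene", "1-heptadecene"),
    mw = c(122.04, 136.05, 124.05, 138.07,
           208.38, 210.24, 180.12, 224.25, 236.25, 238.27),
    ri1 = c(1011, 1098, 1350, 1432, 1477, 1492, 1552, 1593, 1663, 1693),
    ri2 = c(1018, 1109, 1367, NA, NA, NA, NA, NA, 1672, NA),
    surrogate = c("MBQ", "EHQ", "MHQ", "EHQ",
                  NA, "15ene", NA, NA, "17ene", "17ene"),
    class = c("quinone", "quinone", "hydroquinone", "hydroquinone",
              "alkene", "alkene", "other", "alkene", "alkene", "alkene"),
    quantified = c(TRUE, TRUE, TRUE, TRUE,
                   FALSE, TRUE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  if (quantified_only) reg <- reg[reg$quantified, ]
  reg
}

#' Reference sequencing statistics of the six gland libraries
#'
#' Raw per-library totals for the six-sample stink-gland mRNA-seq
#' experiment (anterior-abdomen control, tar-mutant prothoracic glands,
#' wild-type male/female prothoracic and abdominal glands): total and
#' mapped 38-base reads, bases of the reference transcript set covered,
#' and the reference size. Feed to [library_metrics] to derive mapping
#' ratios, average depth and relative totals.
#'
#' @return data.frame with one row per sample, columns `sample`,
#'   `total_reads`, `mapped_reads`, `covered_total_base`,
#'   `reference_total_base`.
#' @export
reference_sequencing_stats <- function() {
  data.frame(
    sample = GLAND_SAMPLES,
    total_reads = c(29527715, 29690989, 28544764,
                    29350110, 27929437, 27786784),
    mapped_reads = c(14727172, 15773797, 14605945,
                     15590528, 14327863, 16955288),
    covered_total_base = c(15746380, 13768019, 13279109,
                           12151610, 13943411, 13272086),
    reference_total_base = rep(23149063, 6L),
    stringsAsFactors = FALSE
  )
}

#' Reference wild-type gland volatile amounts
#'
#' Mean (and SD) microgram amounts of the five main secretion components
#' per sex and gland type in wild-type adults: summed
#' methyl-benzoquinone/-hydroquinone (`MBQ_sum`), summed
#' ethyl-benzoquinone/-hydroquinone (`EBQ_sum`), 1-pentadecene,
#' 1,8-heptadecadiene and 1-heptadecene. `thr_abd` rows are whole-beetle
#' (thoracic + abdominal) totals. Used as a realistic baseline by the
#' synthetic generators and by the compositional-statistics validation.
#'
#' @return data.frame with columns `sex`, `gland`, and for each component
#'   `<comp>` and `<comp>_sd` in micrograms.
#' @export
reference_gland_volatiles <- function() {
  data.frame(
    sex = rep(c("male", "female"), 3L),
    gland = rep(c("thr", "abd", "thr_abd"), each = 2L),
    MBQ_sum = c(5.39, 5.66, 8.43, 7.51, 13.82, 13.20),
    MBQ_sum_sd = c(1.63, 2.15, 2.53, 1.75, 3.61, 3.18),
    EBQ_sum = c(7.08, 7.41, 10.63, 10.84, 17.71, 18.25),
    EBQ_sum_sd = c(2.15, 1.93, 3.05, 2.79, 4.60, 4.17),
    `15ene` = c(4.71, 4.80, 9.91, 9.58, 14.62, 14.31),
    `15ene_sd` = c(1.20, 1.21, 2.61, 1.95, 3.17, 2.65),
    `17diene` = c(2.39, 2.74, 0.51, 0.66, 2.90, 3.36),
    `17diene_sd` = c(0.64, 0.68, 0.17, 0.16, 0.71, 0.73),
    `17ene` = c(1.08, 1.06, 1.06, 0.94, 2.14, 1.97),
    `17ene_sd` = c(0.27, 0.25, 0.28, 0.18, 0.46, 0.34),
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
}
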