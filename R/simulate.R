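# Seeded synthetic-data generators. Every pipeline stage gets an input
# generator with known ground truth, so classification, calibration,
# kinetics and phenotype scoring are testable without external data.

#' Configuration for the synthetic expression library
#'
#' The defaults state the world the subtraction pipeline was designed
#' for: ten planted subtraction groups with the observed per-group sizes
#' (62, 23, 40, 0, 4, 0, 299, 0, 39, 44 genes), a background of
#' exchangeable genes, 38-base reads, a 64-fold planted signal with a
#' 2x safety margin over the classification cutoff, and near-Poisson
#' count noise (the libraries emulate single technical sequencing runs
#' of deeply pooled RNA, not biological replicates).
#'
#' @param seed RNG seed (integer).
#' @param n_background_genes exchangeable background genes (default
#'   1000).
#' @param group_sizes integer vector of 10 planted group sizes.
#' @param baseline_reads mean background/low-side read count (default
#'   50).
#' @param planted_fc fold multiplier of the planted signal (default 64,
#'   matching a log2 cutoff of 6).
#' @param margin extra fold factor above `planted_fc` so recovery is
#'   robust to count noise (default 2).
#' @param read_length read length in bases (default 38).
#' @param noise_model `"nbinom"`, `"poisson"` or `"none"`
#'   (deterministic means).
#' @param dispersion negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`; default 0.001, near-Poisson technical
#'   noise).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_background_genes = 1000L,
                       group_sizes = c(62L, 23L, 40L, 0L, 4L,
                                       0L, 299L, 0L, 39L, 44L),
                       baseline_reads = 50,
                       planted_fc = 64,
                       margin = 2,
                       read_length = 38,
                       noise_model = c("nbinom", "poisson", "none"),
                       dispersion = 0.001) {
  noise_model <- match.arg(noise_model)
  if (length(group_sizes) != 10L) stop("group_sizes must have length 10")
  if (any(group_sizes < 0) || any(!is.finite(group_sizes)))
    stop("group_sizes must be non-negative and finite")
  if (!is.finite(baseline_reads) || baseline_reads <= 0)
    stop("baseline_reads must be > 0")
  if (!is.finite(planted_fc) || planted_fc < 2)
    stop("planted_fc must be >= 2")
  if (margin < 1) stop("margin must be >= 1")
  if (dispersion < 0) stop("dispersion must be >= 0")
  structure(list(seed = as.integer(seed),
                 n_background_genes = as.integer(n_background_genes),
                 group_sizes = as.integer(group_sizes),
                 baseline_reads = baseline_reads,
                 planted_fc = planted_fc,
                 margin = margin,
                 read_length = read_length,
                 noise_model = noise_model,
                 dispersion = dispersion),
            class = "sim_config")
}

# Which samples carry the planted high signal, per group. G10 genes are
# regulated in the tar-mutant sample in either direction: "up" plants
# high reads in s2 only; "down" plants high reads everywhere except s2,
# so s2 is low relative to s3/s4 while no wild-type contrast fires.
planted_high_samples <- function(group, direction = "up") {
  s <- GLAND_SAMPLES
  switch(group,
         `1` = s[3:6], `2` = s[3:4], `3` = s[5:6],
         `4` = s[c(3, 5)], `5` = s[c(4, 6)],
         `6` = s[3], `7` = s[5], `8` = s[4], `9` = s[6],
         `10` = if (direction == "up") s[2] else s[-2])
}

draw_counts <- function(mu, model, dispersion) {
  if (model == "none") return(round(mu))
  if (model == "poisson" || dispersion == 0) return(stats::rpois(length(mu), mu))
  stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Generate a synthetic six-sample expression library with ground truth
#'
#' Background genes draw exchangeable counts around `baseline_reads` in
#' all six samples. Planted genes carry
#' `baseline_reads * planted_fc * margin` expected reads in their
#' group's defining samples and baseline reads elsewhere, so the
#' subtraction classifier recovers the planted labels; genes planted for
#' the tar-mutant group alternate between up- and down-regulation in s2.
#' All samples share one library-size scalar (no normalisation step is
#' simulated).
#'
#' @param cfg a [sim_config].
#' @return list with `library` (an `expression_library`, rows shuffled)
#'   and `truth` (data.frame `gene_id`, `group` with `NA` for
#'   background).
#' @export
simulate_expression_library <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_planted <- sum(cfg$group_sizes)
  n <- cfg$n_background_genes + n_planted
  group <- c(rep(NA_integer_, cfg$n_background_genes),
             rep(1:10, cfg$group_sizes))
  gene_id <- sprintf("gene%05d", seq_len(n))
  high <- cfg$baseline_reads * cfg$planted_fc * cfg$margin
  mu <- matrix(cfg$baseline_reads, nrow = n, ncol = 6,
               dimnames = list(NULL, GLAND_SAMPLES))
  g10_dir <- "up"
  for (i in which(!is.na(group))) {
    dir <- "up"
    if (group[i] == 10L) {          # alternate regulation direction
      dir <- g10_dir
      g10_dir <- if (g10_dir == "up") "down" else "up"
    }
    mu[i, planted_high_samples(as.character(group[i]), dir)] <- high
  }
  counts <- matrix(draw_counts(as.vector(mu), cfg$noise_model,
                               cfg$dispersion),
                   nrow = n, dimnames = dimnames(mu))
  lib <- data.frame(gene_id = gene_id,
                    transcript_length = sample(200:5000, n, replace = TRUE),
                    counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  ord <- sample.int(n)
  lib <- lib[ord, ]
  rownames(lib) <- NULL
  list(library = as_expression_library(lib),
       truth = data.frame(gene_id = gene_id[ord], group = group[ord],
                          stringsAsFactors = FALSE))
}

#' Simulate a GC-MS run: peak table plus standard series
#'
#' Peak areas follow each compound's surrogate calibration line
#' (`area = slope * mass + intercept`), with optional multiplicative
#' Gaussian noise; compounds with zero true mass produce no peak.
#' Retention indices are drawn near the registry values (uniform
#' +/- 2 index units). Each standard compound gets a five-point series
#' with known amounts on its own line.
#'
#' @param true_masses named vector of true masses in ng (names are
#'   registry compound codes).
#' @param curve_params data.frame `compound`, `slope` (> 0),
#'   `intercept`; one row per standard compound.
#' @param noise_sd relative (multiplicative) noise SD (default 0).
#' @param seed RNG seed.
#' @param registry see [compound_registry].
#' @param standard_amounts amounts of the standard series in ng
#'   (default 10, 25, 50, 100, 200).
#' @param sample_id,sex,gland sample annotation copied into the peak
#'   table.
#' @return list with `peaks` (`sample_id`, `sex`, `gland`,
#'   `retention_index`, `area`) and `standards` (`compound`,
#'   `amount_ng`, `area`).
#' @export
simulate_gcms_run <- function(true_masses, curve_params, noise_sd = 0,
                              seed = 1L, registry = compound_registry(),
                              standard_amounts = c(10, 25, 50, 100, 200),
                              sample_id = "sample1", sex = "male",
                              gland = "thr") {
  stopifnot(all(c("compound", "slope", "intercept") %in% names(curve_params)))
  if (any(curve_params$slope <= 0)) stop("calibration slopes must be > 0")
  set.seed(seed)
  unknown <- setdiff(names(true_masses), registry$compound)
  if (length(unknown) > 0L)
    stop("compounds not in registry: ", paste(unknown, collapse = ", "))
  surrogate_of <- function(code)
    registry$surrogate[match(code, registry$compound)]
  present <- names(true_masses)[true_masses > 0]
  needed <- unique(stats::na.omit(surrogate_of(present)))
  missing <- setdiff(needed, curve_params$compound)
  if (length(missing) > 0L)
    stop("missing curve for required standard: ",
         paste(missing, collapse = ", "))
  noisy <- function(a)
    if (noise_sd > 0) a * (1 + stats::rnorm(length(a), 0, noise_sd)) else a

  standards <- do.call(rbind, lapply(seq_len(nrow(curve_params)), function(i)
    data.frame(compound = curve_params$compound[i],
               amount_ng = standard_amounts,
               area = noisy(curve_params$slope[i] * standard_amounts +
                              curve_params$intercept[i]),
               stringsAsFactors = FALSE)))

  peaks <- do.call(rbind, lapply(present, function(code) {
    ci <- match(surrogate_of(code), curve_params$compound)
    ri <- registry$ri1[match(code, registry$compound)] +
      stats::runif(1, -2, 2)
    data.frame(sample_id = sample_id, sex = sex, gland = gland,
               retention_index = ri,
               area = noisy(curve_params$slope[ci] * true_masses[[code]] +
                              curve_params$intercept[ci]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(peaks))
    peaks <- data.frame(sample_id = character(), sex = character(),
                        gland = character(), retention_index = numeric(),
                        area = numeric(), stringsAsFactors = FALSE)
  rownames(peaks) <- NULL
  list(peaks = peaks, standards = standards)
}

#' Simulate PO kinetic traces with paired blanks
#'
#' Blank wells carry only a linear substrate self-darkening drift;
#' signal wells add a lag / linear / plateau piecewise-linear enzymatic
#' signal with the given true Vmax. Readings are every 2 minutes from 0
#' to 90 (46 timepoints).
#'
#' @param true_vmax named numeric vector of true slopes (OD/min, > 0),
#'   one per signal well.
#' @param lag_min lag before the linear phase starts (default 10 min).
#' @param plateau_od absorbance at which the signal saturates (`NULL`
#'   for no plateau).
#' @param blank_drift substrate self-darkening slope (OD/min, default
#'   0.001).
#' @param noise_sd additive Gaussian noise SD on every reading
#'   (default 0).
#' @param n_blanks number of blank wells (default 3).
#' @param seed RNG seed.
#' @return data.frame with columns `well`, `minute`, `od490`,
#'   `is_blank`; attribute `true_vmax` carries the ground truth.
#' @export
simulate_po_traces <- function(true_vmax, lag_min = 10, plateau_od = NULL,
                               blank_drift = 0.001, noise_sd = 0,
                               n_blanks = 3L, seed = 1L) {
  if (any(!is.finite(true_vmax)) || any(true_vmax <= 0))
    stop("true_vmax must be > 0 for signal traces")
  if (is.null(names(true_vmax)))
    names(true_vmax) <- paste0("well", seq_along(true_vmax))
  set.seed(seed)
  minutes <- seq(0, 90, by = 2)
  noisy <- function(y)
    if (noise_sd > 0) y + stats::rnorm(length(y), 0, noise_sd) else y
  signal <- function(vmax) {
    s <- pmax(minutes - lag_min, 0) * vmax
    if (!is.null(plateau_od)) s <- pmin(s, plateau_od)
    s
  }
  rows <- c(
    lapply(seq_len(n_blanks), function(j)
      data.frame(well = paste0("blank", j), minute = minutes,
                 od490 = noisy(blank_drift * minutes), is_blank = TRUE,
                 stringsAsFactors = FALSE)),
    lapply(names(true_vmax), function(w)
      data.frame(well = w, minute = minutes,
                 od490 = noisy(blank_drift * minutes +
                                 signal(true_vmax[[w]])),
                 is_blank = FALSE, stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "true_vmax") <- true_vmax
  out
}

#' Simulate an RNAi knock-down cohort with intended phenotype strengths
#'
#' For each gene, draws per-beetle gland component amounts such that
#' [classify_strength] recovers the intended strength class: class 1
#' plants a near-complete loss of one component in every beetle, class 2
#' a 77-93% reduction, class 3 the same strong effect in a strict subset
#' of beetles only, class 4 a 30-70% reduction in every beetle, and
#' class 5 changes below 25% everywhere. Strength 6 (uncloned/untested)
#' has no data and cannot be simulated.
#'
#' @param strengths named integer vector of intended strengths (1-5),
#'   one per knock-down gene.
#' @param n_beetles beetles per gene (>= 2).
#' @param seed RNG seed.
#' @param control_means data.frame `gland`, `compound`, `mean_ng` of
#'   wild-type control means (default: the bundled wild-type reference
#'   amounts, male rows, converted to ng).
#' @return list with `knockdown` (data.frame `gene`, `beetle`, `gland`,
#'   `compound`, `amount_ng`), `control_means`, and `truth` (the input
#'   strengths).
#' @export
simulate_phenotype_cohort <- function(strengths, n_beetles = 5L, seed = 1L,
                                      control_means = NULL) {
  if (any(!strengths %in% 1:5))
    stop("strength 6 (uncloned/untested) cannot be simulated as data")
  if (n_beetles < 2L) stop("n_beetles must be >= 2")
  if (is.null(names(strengths)))
    names(strengths) <- paste0("GT", seq_along(strengths))
  set.seed(seed)
  comps <- names(profile_mw())
  if (is.null(control_means)) {
    ref <- reference_gland_volatiles()
    ref <- ref[ref$sex == "male" & ref$gland %in% c("thr", "abd"), ]
    control_means <- do.call(rbind, lapply(seq_len(nrow(ref)), function(i)
      data.frame(gland = ref$gland[i], compound = comps,
                 mean_ng = 1000 * as.numeric(ref[i, comps]),
                 stringsAsFactors = FALSE)))
  }
  glands <- unique(control_means$gland)
  rows <- list()
  for (g in names(strengths)) {
    target <- sample(comps, 1L)
    cls <- strengths[[g]]
    strong_beetles <- if (cls == 3L)
      seq_len(max(1L, floor(n_beetles / 2))) else seq_len(n_beetles)
    for (b in seq_len(n_beetles)) {
      for (gl in glands) {
        for (cc in comps) {
          base <- control_means$mean_ng[control_means$gland == gl &
                                          control_means$compound == cc]
          change <- stats::runif(1, -0.1, 0.1)
          if (cc == target) {
            change <- switch(as.character(cls),
              `1` = stats::runif(1, -1, -0.96),
              `2` = stats::runif(1, -0.93, -0.77),
              `3` = if (b %in% strong_beetles)
                      stats::runif(1, -0.93, -0.77)
                    else stats::runif(1, -0.2, 0.2),
              `4` = stats::runif(1, -0.70, -0.30),
              `5` = stats::runif(1, -0.2, 0.2))
          }
          rows[[length(rows) + 1L]] <-
            data.frame(gene = g, beetle = b, gland = gl, compound = cc,
                       amount_ng = base * (1 + change),
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(knockdown = out, control_means = control_means, truth = strengths)
}

#' Relative changes of a knock-down cohort against control means
#'
#' Joins per-beetle knock-down amounts with the control means and
#' computes the signed relative change per beetle, gland and component —
#' the input of [classify_strength].
#'
#' @param knockdown data.frame `gene`, `beetle`, `gland`, `compound`,
#'   `amount_ng`.
#' @param control_means data.frame `gland`, `compound`, `mean_ng`.
#' @return data.frame `gene`, `beetle`, `gland`, `compound`, `change`.
#' @export
knockdown_changes <- function(knockdown, control_means) {
  m <- merge(knockdown, control_means, by = c("gland", "compound"))
  m$change <- component_change(m$amount_ng, m$mean_ng)
  m[, c("gene", "beetle", "gland", "compound", "change")]
}
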