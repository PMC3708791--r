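#' Sample codes of a six-library stink-gland experiment
#'
#' The six mRNA-seq libraries compared by the subtraction pipeline:
#' anterior-abdomen control, tar-mutant prothoracic glands, and wild-type
#' male/female prothoracic and abdominal glands.
#'
#' @format Character vector of the six sample column names, in order:
#'   `s1_ctl`, `s2_tthr`, `s3_mthr`, `s4_fthr`, `s5_mabd`, `s6_fabd`.
#' @export
GLAND_SAMPLES <- c("s1_ctl", "s2_tthr", "s3_mthr", "s4_fthr",
                   "s5_mabd", "s6_fabd")

#' Construct and validate an expression library
#'
#' An expression library is a plain `data.frame` with one row per gene:
#' a `gene_id`, the transcript length in bases, and the mapped read count
#' of that gene in each of the six samples (see [GLAND_SAMPLES]).
#'
#' @param x data.frame with columns `gene_id`, `transcript_length` and the
#'   six sample read-count columns.
#' @return `x` with class `expression_library` prepended.
#' @export
as_expression_library <- function(x) {
  stopifnot(is.data.frame(x))
  needed <- c("gene_id", "transcript_length", GLAND_SAMPLES)
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0L)
    stop("expression library is missing columns: ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(x$gene_id))
    stop("duplicated gene_id in expression library")
  if (any(!is.finite(x$transcript_length)) || any(x$transcript_length <= 0))
    stop("transcript_length must be finite and > 0")
  counts <- as.matrix(x[, GLAND_SAMPLES])
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("read counts must be finite and >= 0")
  class(x) <- unique(c("expression_library", class(x)))
  x
}

#' Read / write an expression library as tab-separated text
#'
#' The on-disk format is a TSV with header
#' `gene_id  transcript_length  s1_ctl ... s6_fabd`.
#'
#' @param path file path.
#' @return `read_expression_library` returns a validated
#'   `expression_library`; `write_expression_library` returns `path`
#'   invisibly.
#' @export
read_expression_library <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_expression_library(x)
}

#' @rdname read_expression_library
#' @param library an `expression_library`.
#' @export
write_expression_library <- function(library, path) {
  utils::write.table(library, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-gene read coverage (depth)
#'
#' Coverage of a transcript is the total sequenced bases mapped to it
#' divided by its length: `reads * read_length / transcript_length`.
#' With 38-base reads a gene of length 38 covered by 100 reads has
#' coverage 100.
#'
#' @param reads mapped read count(s), >= 0.
#' @param transcript_length transcript length(s) in bases, > 0.
#' @param read_length read length in bases (default 38).
#' @return numeric coverage, vectorised over the inputs.
#' @export
coverage_depth <- function(reads, transcript_length, read_length = 38) {
  if (any(!is.finite(transcript_length)) || any(transcript_length <= 0))
    stop("transcript_length must be finite and > 0")
  if (any(!is.finite(reads)) || any(reads < 0))
    stop("reads must be finite and >= 0")
  reads * read_length / transcript_length
}

#' Sequencing-library summary metrics
#'
#' Derives, for each library, the mapping ratio, total mapped bases
#' (`mapped_reads * read_length`), average depth over the reference,
#' covered-region ratio, and total reads relative to the first (control)
#' sample.
#'
#' @param stats data.frame with one row per sample and columns `sample`,
#'   `total_reads`, `mapped_reads`, `covered_total_base`,
#'   `reference_total_base`.
#' @param read_length read length in bases (default 38).
#' @param reference_sample sample whose total reads is the denominator of
#'   `relative_total_reads` (default the first row).
#' @return the input with columns `mapping_ratio`, `total_mapped_bases`,
#'   `average_depth`, `covered_ratio`, `relative_total_reads` appended.
#' @export
library_metrics <- function(stats, read_length = 38,
                            reference_sample = stats$sample[1L]) {
  needed <- c("sample", "total_reads", "mapped_reads",
              "covered_total_base", "reference_total_base")
  missing <- setdiff(needed, names(stats))
  if (length(missing) > 0L)
    stop("missing columns: ", paste(missing, collapse = ", "))
  if (any(stats$total_reads <= 0) || any(stats$reference_total_base <= 0))
    stop("zero denominator in library metrics")
  if (any(stats$mapped_reads > stats$total_reads))
    stop("mapped_reads must not exceed total_reads")
  if (any(stats$covered_total_base > stats$reference_total_base))
    stop("covered_total_base must not exceed reference_total_base")
  ref <- stats$total_reads[match(reference_sample, stats$sample)]
  if (is.na(ref)) stop("unknown reference_sample: ", reference_sample)
  stats$mapping_ratio <- stats$mapped_reads / stats$total_reads
  stats$total_mapped_bases <- stats$mapped_reads * read_length
  stats$average_depth <- stats$total_mapped_bases / stats$reference_total_base
  stats$covered_ratio <- stats$covered_total_base / stats$reference_total_base
  stats$relative_total_reads <- stats$total_reads / ref
  stats
}

#' Log2 fold change between two read counts
#'
#' `log2((a + pseudocount) / (b + pseudocount))`. The pseudocount keeps
#' the ratio finite when one side is zero; the function is antisymmetric
#' under swapping `a` and `b`.
#'
#' @param reads_a,reads_b non-negative read counts (vectorised).
#' @param pseudocount value added to both counts before the ratio
#'   (default 1). Must be > 0 unless both counts are positive.
#' @return numeric log2 fold change(s).
#' @export
log2_fc <- function(reads_a, reads_b, pseudocount = 1) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && any(reads_a == 0 | reads_b == 0))
    stop("zero counts require a positive pseudocount")
  log2((reads_a + pseudocount) / (reads_b + pseudocount))
}

#' Genes abundantly expressed in glands or control
#'
#' A gene is abundant when its coverage exceeds the threshold (strictly;
#' default 50, about twice the genome-wide sequencing depth) in all four
#' wild-type gland samples (`scope = "glands"`) or in the
#' anterior-abdomen control (`scope = "control"`).
#'
#' @param library an `expression_library`.
#' @param threshold coverage cutoff, exceeded strictly (default 50).
#' @param scope `"glands"` (all of s3-s6) or `"control"` (s1).
#' @param read_length read length in bases (default 38).
#' @return character vector of gene ids.
#' @export
abundant_genes <- function(library, threshold = 50,
                           scope = c("glands", "control"),
                           read_length = 38) {
  scope <- match.arg(scope)
  if (threshold <= 0) stop("threshold must be > 0")
  samples <- if (scope == "glands")
    c("s3_mthr", "s4_fthr", "s5_mabd", "s6_fabd") else "s1_ctl"
  cov <- sapply(samples, function(s)
    coverage_depth(library[[s]], library$transcript_length, read_length))
  cov <- matrix(cov, nrow = nrow(library))
  keep <- rowSums(cov > threshold) == length(samples)
  library$gene_id[keep]
}

# The ten subtraction groups as (high, low) sample pairs; every pair must
# satisfy log2FC(high, low) >= cutoff. G10 is special-cased (two-sided
# tar-mutant comparison) and handled in classify_subtraction_groups().
subtraction_group_pairs <- function() {
  s1 <- "s1_ctl"; s3 <- "s3_mthr"; s4 <- "s4_fthr"
  s5 <- "s5_mabd"; s6 <- "s6_fabd"
  pairs <- function(highs, lows)
    do.call(rbind, lapply(highs, function(h)
      data.frame(high = h, low = lows, stringsAsFactors = FALSE)))
  list(
    G1 = pairs(c(s3, s4, s5, s6), s1),          # all glands vs control
    G2 = pairs(c(s3, s4), c(s5, s6, s1)),       # thoracic-specific
    G3 = pairs(c(s5, s6), c(s3, s4, s1)),       # abdominal-specific
    G4 = pairs(c(s3, s5), c(s4, s6, s1)),       # male-specific
    G5 = pairs(c(s4, s6), c(s3, s5)),           # female-specific (no s1)
    G6 = pairs(s3, c(s4, s1)),                  # male thoracic
    G7 = pairs(s5, c(s6, s1)),                  # male abdominal
    G8 = pairs(s4, c(s3, s1)),                  # female thoracic
    G9 = pairs(s6, c(s5, s1))                   # female abdominal
  )
}

#' Classify genes into the ten gland-specificity subtraction groups
#'
#' Each gene is tested against ten mutually exclusive subtraction groups
#' defined by log2 fold-change inequalities at a common cutoff (default 6,
#' i.e. a 64-fold read difference):
#' \describe{
#'   \item{G1}{highly expressed in all four wild-type gland samples
#'     (s3-s6) relative to the control s1 (gland-specific).}
#'   \item{G2}{s3 and s4 above s5, s6 and s1 (thoracic-gland-specific).}
#'   \item{G3}{s5 and s6 above s3, s4 and s1 (abdominal-gland-specific).}
#'   \item{G4}{s3 and s5 above s4, s6 and s1 (male-gland-specific).}
#'   \item{G5}{s4 and s6 above s3 and s5 (female-gland-specific; no
#'     control comparison).}
#'   \item{G6}{s3 above s4 and s1 (male thoracic).}
#'   \item{G7}{s5 above s6 and s1 (male abdominal).}
#'   \item{G8}{s4 above s3 and s1 (female thoracic).}
#'   \item{G9}{s6 above s5 and s1 (female abdominal).}
#'   \item{G10}{absolute log2 fold change of the tar-mutant prothoracic
#'     sample s2 against both s3 and s4 at or above the cutoff (up- or
#'     down-regulated in the mutant).}
#' }
#' A gene can satisfy the inequalities of several groups; assignment is
#' first-match in the order G1..G10 so that every gene carries at most one
#' label. The diagnostic column `passing_groups` lists all groups whose
#' conditions held.
#'
#' A minimum-expression floor (default 64 reads) is additionally required
#' of the high side of every comparison, so genes whose "signal" is noise
#' over a zero background do not enter a group. Set `min_reads = 0` to
#' disable.
#'
#' @param library an `expression_library`.
#' @param cutoff log2 fold-change cutoff (default 6).
#' @param pseudocount pseudocount for [log2_fc] (default 1).
#' @param min_reads read floor applied to the high side of each
#'   comparison (default 64; 0 disables).
#' @return data.frame with columns `gene_id`, `group` (integer 1-10 or
#'   `NA` when unassigned) and `passing_groups` (comma-separated
#'   diagnostic string).
#' @export
classify_subtraction_groups <- function(library, cutoff = 6,
                                        pseudocount = 1, min_reads = 64) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  library <- as_expression_library(library)
  n <- nrow(library)
  reads <- lapply(GLAND_SAMPLES, function(s) library[[s]])
  names(reads) <- GLAND_SAMPLES

  holds <- function(high, low) {
    ok <- log2_fc(reads[[high]], reads[[low]], pseudocount) >= cutoff
    if (min_reads > 0) ok <- ok & reads[[high]] >= min_reads
    ok
  }
  group_pass <- matrix(FALSE, n, 10L,
                       dimnames = list(NULL, paste0("G", 1:10)))
  pair_sets <- subtraction_group_pairs()
  for (g in names(pair_sets)) {
    ps <- pair_sets[[g]]
    ok <- rep(TRUE, n)
    for (i in seq_len(nrow(ps))) ok <- ok & holds(ps$high[i], ps$low[i])
    group_pass[, g] <- ok
  }
  # G10: |log2FC| >= cutoff for s2 against both s3 and s4; the floor
  # applies to the larger side of each comparison.
  g10 <- rep(TRUE, n)
  for (other in c("s3_mthr", "s4_fthr")) {
    fc <- log2_fc(reads[["s2_tthr"]], reads[[other]], pseudocount)
    ok <- abs(fc) >= cutoff
    if (min_reads > 0)
      ok <- ok & pmax(reads[["s2_tthr"]], reads[[other]]) >= min_reads
    g10 <- g10 & ok
  }
  group_pass[, "G10"] <- g10

  first <- apply(group_pass, 1L, function(p) {
    w <- which(p)
    if (length(w) == 0L) NA_integer_ else w[1L]
  })
  passing <- apply(group_pass, 1L, function(p)
    paste(paste0("G", which(p)), collapse = ","))
  data.frame(gene_id = library$gene_id,
             group = as.integer(first),
             passing_groups = passing,
             stringsAsFactors = FALSE)
}

#' Summarise a group assignment
#'
#' Counts assigned genes per subtraction group with percentages of the
#' assigned total (the numbers behind a pie-chart style screening
#' summary).
#'
#' @param assignment result of [classify_subtraction_groups].
#' @return data.frame with columns `group`, `n`, `percent`.
#' @export
subtraction_summary <- function(assignment) {
  counts <- vapply(1:10, function(g)
    sum(assignment$group == g, na.rm = TRUE), integer(1))
  total <- sum(counts)
  data.frame(group = paste0("G", 1:10), n = counts,
             percent = if (total > 0) 100 * counts / total else rep(0, 10))
}

#' Log2 fold-change profile of candidate genes against the control
#'
#' For each requested gene, the log2 fold change of each gland sample
#' (s3, s4, s5, s6, and the tar-mutant s2) against the anterior-abdomen
#' control s1 — the screening profile used for candidate genes and
#' homologs.
#'
#' @param library an `expression_library`.
#' @param gene_ids genes to profile; must all exist in `library`.
#' @param pseudocount pseudocount for [log2_fc] (default 1).
#' @return numeric matrix, one row per gene (rownames = gene ids),
#'   columns `s3_mthr`, `s4_fthr`, `s5_mabd`, `s6_fabd`, `s2_tthr`.
#' @export
fold_change_profile <- function(library, gene_ids, pseudocount = 1) {
  library <- as_expression_library(library)
  idx <- match(gene_ids, library$gene_id)
  if (anyNA(idx))
    stop("unknown gene_id: ",
         paste(gene_ids[is.na(idx)], collapse = ", "))
  cols <- c("s3_mthr", "s4_fthr", "s5_mabd", "s6_fabd", "s2_tthr")
  out <- sapply(cols, function(s)
    log2_fc(library[[s]][idx], library[["s1_ctl"]][idx], pseudocount))
  out <- matrix(out, nrow = length(idx), dimnames = list(gene_ids, cols))
  out
}
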