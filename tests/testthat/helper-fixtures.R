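# Small in-code fixtures shared across test files.

# Build a tiny expression library from a named list of per-gene count
# vectors (length 6, sample order s1..s6).
make_library <- function(counts, transcript_length = 1000) {
  m <- do.call(rbind, counts)
  colnames(m) <- GLAND_SAMPLES
  as_expression_library(data.frame(
    gene_id = names(counts),
    transcript_length = transcript_length,
    m, check.names = FALSE, stringsAsFactors = FALSE))
}

# Brute-force rank-sum oracle: enumerate every assignment of the pooled
# observations to the two groups and count rank sums as or more extreme
# than observed (two-sided).
enumerate_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  splits <- utils::combn(length(pooled), n1)
  ws <- apply(splits, 2, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# A random small library over a modest count range, for property tests.
random_library <- function(n_genes, seed, max_count = 20000) {
  set.seed(seed)
  counts <- matrix(stats::rpois(n_genes * 6,
                                lambda = stats::runif(n_genes * 6, 0,
                                                      max_count / 10)),
                   ncol = 6, dimnames = list(NULL, GLAND_SAMPLES))
  as_expression_library(data.frame(
    gene_id = sprintf("rg%03d", seq_len(n_genes)),
    transcript_length = sample(200:3000, n_genes, replace = TRUE),
    counts, check.names = FALSE, stringsAsFactors = FALSE))
}
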