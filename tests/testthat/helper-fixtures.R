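## Shared fixtures and independent oracles, built in code at test time.

## small simulated experiment reused by several files (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_experiment(sim_config(n_genes = 300, seed = 42))
    }
    cache
  }
})

small_norm <- function() {
  upper_quartile_normalize(filter_low_expressed(small_sim()$experiment))
}

## a normalized_matrix built directly from a log2 value matrix (noise-free
## fits): values chosen so log2(values + 1) equals `log2mat` exactly
norm_from_log2 <- function(log2mat, design) {
  structure(list(values = 2^log2mat - 1,
                 size_factors = rep(1, ncol(log2mat)),
                 log2 = log2mat,
                 design = design),
            class = c("normalized_matrix"))
}

## design table for one genotype, two conditions over given weeks/replicates
two_condition_design <- function(weeks = 1:17, reps = 1:3,
                                 conditions = c("control", "preflowering"),
                                 genotype = "RTx430") {
  grid <- expand.grid(replicate = reps, week = weeks, condition = conditions,
                      stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_%s_w%02d_r%d", genotype, grid$condition,
                                 grid$week, grid$replicate),
             genotype = genotype, tissue = "leaf",
             condition = grid$condition, week = grid$week,
             replicate = grid$replicate, stringsAsFactors = FALSE)
}

## independent brute-force BH step-up oracle (textbook definition)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

## independent pooled two-sample t oracle (textbook formula)
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}
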