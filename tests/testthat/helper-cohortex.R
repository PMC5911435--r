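# Shared fixtures. Everything is generated in code; the default cohort
# simulation and its pipeline run are cached because several files score
# different aspects of the same run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

default_sim <- function() cached("sim", simulate_counts(simulation_spec(seed = 101)))

default_run <- function() cached("run", {
  sim <- default_sim()
  run_pipeline(pipeline_config(seed = 101), sim$counts, sim$samples,
               sim$variants)
})

# factor-model expression blocks: `sizes` module sizes followed by
# n_noise unstructured genes; per-gene loadings optionally jittered with
# a block-specific sub-seed so two draws (different `seed`) share loadings
make_block_expr <- function(sizes, loading, n, n_noise = 0, seed = 1,
                            jitter = 0) {
  set.seed(seed)
  g <- sum(sizes) + n_noise
  expr <- matrix(rnorm(g * n), g, n,
                 dimnames = list(sprintf("G%04d", seq_len(g)),
                                 sprintf("S%d_%03d", seed, seq_len(n))))
  labels <- rep(0L, g)
  start <- 1
  loading <- rep_len(loading, length(sizes))
  for (i in seq_along(sizes)) {
    idx <- start:(start + sizes[i] - 1)
    start <- start + sizes[i]
    l <- loading[i]
    if (jitter > 0) {
      set.seed(7000 + i)
      l <- pmin(0.99, pmax(0.05,
                           l + runif(sizes[i], -jitter, jitter)))
    }
    set.seed(seed * 1000 + i)
    expr <- inject_module(expr, rownames(expr)[idx], l)$expr
    labels[idx] <- i
  }
  list(expr = expr, labels = labels)
}

# two-group design matrix with the contrast column named as run_de expects
group_design <- function(n_a, n_b) {
  d <- cbind(1, rep(c(0, 1), c(n_a, n_b)))
  colnames(d) <- c("(Intercept)", "groupcase")
  d
}

tiny_counts <- function() {
  m <- matrix(c(10L, 0L, 5L,
                2L, 7L, 1L), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  count_matrix(m)
}
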