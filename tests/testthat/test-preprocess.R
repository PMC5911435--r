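test_that("CPM follows its definition and conserves column totals", {
  m <- matrix(c(10, 1999990, 500000, 500000), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  out <- cpm(m)
  expect_equal(out["g1", "s1"], 5)           # 10 in a 2e6 library
  expect_equal(out["g1", "s2"], 5e5)         # library 1e6: CPM == counts
  set.seed(1)
  r <- matrix(rpois(20, 50) + 1, 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expect_equal(unname(colSums(cpm(r))), rep(1e6, 4), tolerance = 1e-6)
  z <- r; z[, 2] <- 0
  expect_error(cpm(z), "s2")
})

test_that("robust filter uses strict CPM > threshold and >= sample count", {
  n <- 10
  cpm_m <- matrix(5, 3, n, dimnames = list(c("at5", "at6", "lo"),
                                           paste0("s", 1:n)))
  cpm_m["at6", 1:4] <- 6       # above threshold in exactly 4 samples
  cpm_m["lo", ] <- 1
  expect_identical(filter_robust(cpm_m, min_cpm = 5, min_samples = 4),
                   "at6")
  # a gene at exactly the CPM threshold everywhere is removed
  expect_false("at5" %in% filter_robust(cpm_m, min_cpm = 5,
                                        min_samples = 1))
  expect_error(filter_robust(cpm_m, min_cpm = 100, min_samples = 1),
               "no gene passes")
  expect_error(filter_robust(cpm_m, min_samples = n + 1), "exceeds")
})

test_that("robust filter matches a two-loop recount and ignores ordering", {
  sim <- default_sim()
  cpm_m <- cpm(sim$counts)
  min_samples <- as.integer(ceiling(120 / 302 * ncol(cpm_m)))
  kept <- filter_robust(cpm_m, min_cpm = 5, min_samples = min_samples)
  # independent brute-force recount
  slow <- character()
  for (g in rownames(cpm_m)) {
    n_over <- 0L
    for (s in colnames(cpm_m)) if (cpm_m[g, s] > 5) n_over <- n_over + 1L
    if (n_over >= min_samples) slow <- c(slow, g)
  }
  expect_identical(kept, slow)
  expect_gt(length(kept), 0)
  # permutation invariance
  set.seed(2)
  perm <- cpm_m[sample(nrow(cpm_m)), sample(ncol(cpm_m))]
  expect_setequal(filter_robust(perm, min_cpm = 5,
                                min_samples = min_samples), kept)
})

test_that("log2 transform is exact, monotone, and guards negatives", {
  expect_equal(log2_transform(matrix(0), 1)[1, 1], 0)
  expect_equal(log2_transform(matrix(7), 1)[1, 1], 3)
  set.seed(3)
  x <- matrix(runif(50, 0, 100), 10, 5)
  y <- log2_transform(x, 1)
  ord <- order(x)
  expect_true(all(diff(y[ord]) > 0))
  expect_error(log2_transform(matrix(-1), 1), "negative")
  expect_true("log2(+1)" %in% attr(y, "provenance"))
})

test_that("batch adjustment matches the reference EB implementation", {
  set.seed(42)
  g <- 150; n <- 60
  expr <- matrix(rnorm(g * n, 8, 1), g, n,
                 dimnames = list(paste0("G", 1:g), paste0("S", 1:n)))
  batch <- rep(c("A", "B"), each = n / 2)
  expr[, batch == "B"] <- expr[, batch == "B"] + rnorm(g, 2, 0.3)
  sex <- rep(c("M", "F"), n / 2)
  got <- combat_adjust(expr, batch, covariates = data.frame(sex = sex))
  ref <- sva::ComBat(expr, batch = batch, mod = model.matrix(~sex),
                     par.prior = TRUE)
  expect_lt(max(abs(got$expr - ref)), 1e-4)
  # BatchModel contents are coherent
  expect_true(all(got$model$delta2_star > 0))
  expect_identical(dim(got$model$gamma_star), c(2L, as.integer(g)))
})

test_that("a planted additive batch shift is removed", {
  set.seed(11)
  g <- 100; n <- 120
  prof <- rnorm(g, 8, 2)
  batch <- rep(c("A", "B"), each = 60)
  expr <- matrix(rnorm(g * n, 0, 0.5), g, n,
                 dimnames = list(paste0("G", 1:g), paste0("S", 1:n))) + prof
  expr[, batch == "B"] <- expr[, batch == "B"] + rnorm(g, 2, 0.5)
  pre_diff <- rowMeans(expr[, batch == "B"]) -
    rowMeans(expr[, batch == "A"])
  expect_gt(mean(abs(pre_diff)), 1.5)
  adj <- combat_adjust(expr, batch)$expr
  post_diff <- rowMeans(adj[, batch == "B"]) -
    rowMeans(adj[, batch == "A"])
  expect_lt(max(abs(post_diff)), 0.1)
  # second adjustment changes less than the first (idempotence in
  # expectation)
  adj2 <- combat_adjust(adj, batch)$expr
  expect_lt(mean(abs(adj2 - adj)), mean(abs(adj - expr)) / 10)
})

test_that("a planted batch scale effect is equalised", {
  set.seed(12)
  g <- 100; n <- 120
  batch <- rep(c("A", "B"), each = 60)
  expr <- matrix(rnorm(g * n, 8, 1), g, n,
                 dimnames = list(paste0("G", 1:g), paste0("S", 1:n)))
  expr[, batch == "B"] <- 8 + (expr[, batch == "B"] - 8) * 2
  adj <- combat_adjust(expr, batch)$expr
  ratio <- apply(adj[, batch == "B"], 1, var) /
    apply(adj[, batch == "A"], 1, var)
  expect_gt(median(ratio), 0.8)
  expect_lt(median(ratio), 1.25)
})

test_that("null batches are barely touched and errors fire on bad designs", {
  set.seed(13)
  g <- 80; n <- 60
  expr <- matrix(rnorm(g * n, 8, 1), g, n,
                 dimnames = list(paste0("G", 1:g), paste0("S", 1:n)))
  batch <- rep(c("A", "B"), each = 30)
  adj <- combat_adjust(expr, batch)$expr
  expect_lt(mean(abs(adj - expr)), 0.1)
  d_pre <- rowMeans(expr[, 31:60]) - rowMeans(expr[, 1:30])
  d_post <- rowMeans(adj[, 31:60]) - rowMeans(adj[, 1:30])
  expect_lte(sd(d_post), sd(d_pre))
  # confounded covariate and singleton batch are hard errors
  expect_error(
    combat_adjust(expr, batch,
                  covariates = data.frame(group = batch)),
    "confounded")
  expect_error(combat_adjust(expr, c("A", rep("B", n - 1))),
               "singleton")
  expect_error(combat_adjust(expr, rep("A", n)), "2 batches")
})

test_that("MDS silhouette detects a batch split and its removal", {
  set.seed(14)
  g <- 100; n <- 120
  prof <- rnorm(g, 8, 2)
  batch <- rep(c("A", "B"), each = 60)
  expr <- matrix(rnorm(g * n, 0, 0.5), g, n,
                 dimnames = list(paste0("G", 1:g), paste0("S", 1:n))) + prof
  expr[, batch == "B"] <- expr[, batch == "B"] + rnorm(g, 2, 0.5)
  before <- mds_check(expr, batch)
  expect_gt(before$silhouette, 0.5)
  after <- mds_check(combat_adjust(expr, batch)$expr, batch)
  expect_lt(after$silhouette, 0.1)
  # identical duplicated samples sit at zero distance
  dup <- cbind(expr, dup1 = expr[, 1])
  cd <- mds_check(dup, c(batch, "A"))$coords
  expect_equal(cd["dup1", ], cd[colnames(expr)[1], ], tolerance = 1e-8)
  const <- expr; const[, 2] <- 5
  expect_error(mds_check(const, batch), "constant")
})

test_that("preprocessing keeps planted signal genes at default settings", {
  sim <- default_sim()
  pre <- preprocess_counts(sim$counts, sim$samples,
                           pipeline_config(seed = 101))
  expect_gt(length(pre$kept_genes), 0)
  planted <- c(sim$truth$de$gene,
               unlist(lapply(sim$truth$modules, `[[`, "genes")))
  expect_true(all(planted %in% pre$kept_genes))
  expect_true(all(is.finite(pre$expr)))
  expect_true(all(c("cpm") %in% attr(cpm(sim$counts), "provenance")))
})
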