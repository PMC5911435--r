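test_that("quality filter reaches the brute-force fixed point", {
  set.seed(50)
  expr <- matrix(rnorm(20 * 10), 20, 10,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  expect_identical(quality_filter_genes(expr)$expr, expr)
  expr2 <- expr; expr2["g3", ] <- 2
  expect_identical(quality_filter_genes(expr2)$genes_removed, "g3")
  # crossing missingness: dropping a bad sample rescues genes, dropping
  # bad genes rescues samples; compare with an independent iteration
  expr3 <- expr
  expr3["g1", 1:6] <- NA
  expr3[5:20, "s2"] <- NA
  got <- quality_filter_genes(expr3)
  brute <- expr3
  repeat {
    gi <- rowMeans(is.na(brute)) > 0.5 |
      apply(brute, 1, function(x) is.na(var(x, na.rm = TRUE)) ||
              var(x, na.rm = TRUE) == 0)
    brute <- brute[!gi, , drop = FALSE]
    si <- colMeans(is.na(brute)) > 0.5
    brute <- brute[, !si, drop = FALSE]
    if (!any(gi) && !any(si)) break
  }
  expect_identical(got$expr, brute)
})

test_that("unsigned adjacency is |cor|^6 with guarded inputs", {
  n <- 50
  set.seed(51)
  base <- rnorm(n)
  x <- rbind(a = base, b = 2 * base + 3, c = -base,
             d = rnorm(n))
  colnames(x) <- paste0("s", 1:n)
  # make d exactly orthogonal to a
  x["d", ] <- residuals(lm(x["d", ] ~ base))
  a <- wgcna_adjacency(x, power = 6)
  expect_equal(a["a", "b"], 1)          # perfectly correlated
  expect_equal(a["a", "c"], 1)          # anti-correlated, unsigned
  expect_equal(a["a", "d"], 0, tolerance = 1e-12)
  # |r| = 0.5 maps to 0.5^6
  y <- rbind(p = base, q = 0.5 * scale(base)[, 1] +
               sqrt(0.75) * scale(x["d", ])[, 1])
  colnames(y) <- paste0("s", 1:n)
  r <- abs(cor(y["p", ], y["q", ]))
  expect_equal(wgcna_adjacency(y, 6)["p", "q"], r^6)
  expect_equal(0.5^6, 0.015625)
  xz <- rbind(x, e = 1)
  expect_error(wgcna_adjacency(xz), "zero-variance")
})

test_that("TOM equals the naive triple-loop reference", {
  set.seed(52)
  for (g in c(8, 50)) {
    r <- matrix(runif(g * g), g, g)
    adj <- (r + t(r)) / 2
    diag(adj) <- 1
    dimnames(adj) <- list(paste0("g", 1:g), paste0("g", 1:g))
    got <- tom_similarity(adj)$sim
    k <- colSums(adj) - 1
    ref <- diag(g)
    for (i in 1:g) for (j in 1:g) {
      if (i == j) next
      l <- 0
      for (u in 1:g) if (u != i && u != j) l <- l + adj[i, u] * adj[u, j]
      ref[i, j] <- (l + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
    }
    expect_lt(max(abs(got - ref)), 1e-12)
  }
  # two perfectly adjacent genes have TOM 1; empty adjacency gives 0
  a2 <- matrix(c(1, 1, 1, 1), 2, 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(tom_similarity(a2)$sim["x", "y"], 1)
  a0 <- diag(3); dimnames(a0) <- list(letters[1:3], letters[1:3])
  expect_true(all(tom_similarity(a0)$sim[upper.tri(a0)] == 0))
})

test_that("two planted blocks are recovered as exactly two modules", {
  b <- make_block_expr(c(60, 60), sqrt(0.8), 100, seed = 2)
  tm <- tom_similarity(wgcna_adjacency(b$expr))
  det <- detect_modules(tm$diss, b$expr, min_size = 40)
  expect_length(det$modules, 2)
  got <- det$labels[rownames(b$expr)]
  acc <- max(mean((got == got[1]) == (b$labels == 1)),
             mean((got == got[1]) == (b$labels == 2)))
  expect_gte(acc, 0.95)
  # invariance to gene order (same partition up to label names)
  set.seed(3)
  perm <- sample(nrow(b$expr))
  tm2 <- tom_similarity(wgcna_adjacency(b$expr[perm, ]))
  det2 <- detect_modules(tm2$diss, b$expr[perm, ], min_size = 40)
  common <- rownames(b$expr)
  expect_equal(mclust::adjustedRandIndex(det$labels[common],
                                         det2$labels[common]), 1)
})

test_that("noise yields no modules and sub-minimum blocks are not reported", {
  set.seed(53)
  noise <- matrix(rnorm(300 * 100), 300, 100,
                  dimnames = list(paste0("g", 1:300), paste0("s", 1:100)))
  tm <- tom_similarity(wgcna_adjacency(noise))
  det <- detect_modules(tm$diss, noise, min_size = 40)
  expect_gte(mean(det$labels == "grey"), 0.9)
  # a coherent 30-gene block stays below the 40-gene floor
  b30 <- make_block_expr(30, 0.9, 100, n_noise = 170, seed = 3)
  tm30 <- tom_similarity(wgcna_adjacency(b30$expr))
  det30 <- detect_modules(tm30$diss, b30$expr, min_size = 40)
  expect_true(all(det30$labels[b30$labels == 1] == "grey"))
})

test_that("module eigengene is the sign-aligned first PC", {
  set.seed(54)
  n <- 120
  shared <- rnorm(n)
  same <- matrix(rep(shared, 5), 5, n, byrow = TRUE) +
    matrix(rnorm(5), 5, n)          # identical profiles, shifted means
  dimnames(same) <- list(paste0("g", 1:5), paste0("s", 1:n))
  eg <- module_eigengene(same)
  expect_equal(eg$var_explained, 1, tolerance = 1e-12)
  expect_equal(abs(cor(eg$eigengene, shared)), 1, tolerance = 1e-12)
  expect_equal(sum(eg$eigengene^2), 1, tolerance = 1e-12)  # unit norm
  expect_true(all(cor(t(same), eg$eigengene) > 0))
  # sign contract: negating all members still correlates positively
  egn <- module_eigengene(-same)
  expect_true(mean(cor(t(-same), egn$eigengene)) > 0)
  # factor model at loading 0.8: variance explained near 0.64
  b <- make_block_expr(100, 0.8, 200, seed = 4)
  egf <- module_eigengene(b$expr[b$labels == 1, ])
  expect_equal(egf$var_explained, 0.64, tolerance = 0.05)
  expect_error(module_eigengene(same[1, , drop = FALSE]), "at least 2")
  expect_error(module_eigengene(matrix(1, 3, 4)), "degenerate")
})

test_that("eigengene variance explained dominates mean squared kME", {
  for (seed in 1:3) {
    b <- make_block_expr(40, 0.7, 80, seed = seed)
    sub <- b$expr[b$labels == 1, ]
    eg <- module_eigengene(sub)
    kme <- drop(cor(t(sub), eg$eigengene))
    expect_gte(eg$var_explained + 1e-8, mean(kme^2))
  }
})

test_that("kME assignment is strict at the threshold with grey fallback", {
  kme <- matrix(c(0.9, 0.7, 0.2,
                  0.1, 0.2, 0.75), 3, 2,
                dimnames = list(c("hub", "edge", "other"),
                                c("blue", "red")))
  got <- assign_by_kme(kme, threshold = 0.7)
  expect_identical(got$primary[["hub"]], "blue")
  # kME exactly 0.7 does not qualify
  expect_identical(got$primary[["edge"]], "grey")
  expect_identical(got$primary[["other"]], "red")
  expect_identical(got$modules$blue, "hub")
  # overlapping membership is allowed
  kme2 <- matrix(c(0.9, 0.8), 1, 2,
                 dimnames = list("shared", c("blue", "red")))
  got2 <- assign_by_kme(kme2)
  expect_true(all(got2$membership["shared", ]))
  expect_identical(got2$primary[["shared"]], "blue")
})

test_that("an unrelated gene is assigned at about the correlation null rate", {
  set.seed(55)
  n <- 60
  eg <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "blue"))
  x <- matrix(rnorm(2000 * n), 2000, n,
              dimnames = list(paste0("g", 1:2000), paste0("s", 1:n)))
  kme <- module_kme(x, eg)
  # P(|r| > 0.7) at n = 60 under the null, via the t transform
  r <- 0.7
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p_null <- 2 * pt(tval, df = n - 2, lower.tail = FALSE)
  got <- mean(kme > 0.7)
  expect_lt(abs(got - p_null / 2), 3 * sqrt(p_null / 2000) + 2e-3)
  expect_lt(max(abs(kme)), 0.99)
})

test_that("kME merging joins duplicates, keeps orthogonal, absorbs mixtures", {
  set.seed(21)
  n <- 150
  f1 <- rnorm(n); f2 <- rnorm(n)
  mk <- function(f, g, loading = 0.9)
    t(vapply(seq_len(g), function(i)
      loading * f + sqrt(1 - loading^2) * rnorm(n), numeric(n)))
  # duplicates on one factor must merge
  e <- rbind(mk(f1, 50), mk(f1, 40))
  dimnames(e) <- list(paste0("G", 1:90), paste0("S", 1:n))
  r <- merge_by_kme(e, list(m1 = paste0("G", 1:50),
                            m2 = paste0("G", 51:90)))
  expect_length(r$modules, 1)
  # orthogonal factors must not merge
  e2 <- rbind(mk(f1, 50), mk(f2, 40))
  dimnames(e2) <- list(paste0("G", 1:90), paste0("S", 1:n))
  r2 <- merge_by_kme(e2, list(m1 = paste0("G", 1:50),
                              m2 = paste0("G", 51:90)))
  expect_length(r2$modules, 2)
  # a module composed half-and-half of the two factors is absorbed and
  # its genes end up with their true modules
  e3 <- rbind(mk(f1, 60), mk(f2, 60), mk(f1, 20), mk(f2, 20))
  dimnames(e3) <- list(paste0("G", 1:160), paste0("S", 1:n))
  r3 <- merge_by_kme(e3, list(m1 = paste0("G", 1:60),
                              m2 = paste0("G", 61:120),
                              m3 = paste0("G", 121:160)))
  expect_length(r3$modules, 2)
  f1_genes <- c(paste0("G", 1:60), paste0("G", 121:140))
  sizes <- vapply(r3$modules, function(m) sum(m %in% f1_genes), 0L)
  expect_setequal(unname(sizes), c(80L, 0L))
})

test_that("eigengene significance reports the right statistic per trait type", {
  set.seed(56)
  n <- 80
  e <- rnorm(n)
  samples <- data.frame(
    sample_id = paste0("s", 1:n),
    group = rep(c("case", "control"), each = n / 2),
    age = rnorm(n, 30, 10), sex = sample(c("M", "F"), n, TRUE),
    batch = "b1")
  eg <- cbind(blue = e)
  rownames(eg) <- samples$sample_id
  # trait identical to the eigengene: r = 1, p ~ 0
  samples$age <- e
  res <- eigengene_significance(eg, samples,
                                traits = c("group", "age"))
  age_row <- res[res$trait == "age", ]
  expect_equal(age_row$statistic, 1, tolerance = 1e-12)
  expect_lt(age_row$p, 1e-100)
  expect_identical(age_row$type, "continuous")
  expect_identical(res$type[res$trait == "group"], "binary")
  expect_true(all(res$p_bonferroni >= res$p))
  # constant traits are skipped with a warning
  samples$sex <- "M"
  expect_warning(eigengene_significance(eg, samples, traits = "sex"),
                 "skipped")
})

test_that("a case-shifted module factor is detected; a permuted label is not", {
  set.seed(57)
  n <- 300
  group <- rep(c("case", "control"), c(180, 120))
  e <- rnorm(n) + (group == "case") * 1   # +1 SD shift in cases
  samples <- data.frame(sample_id = paste0("s", 1:n), group = group,
                        age = rnorm(n, 30, 5),
                        sex = sample(c("M", "F"), n, TRUE), batch = "b")
  eg <- cbind(blue = e); rownames(eg) <- samples$sample_id
  res <- eigengene_significance(eg, samples, traits = "group")
  expect_lt(res$p_bonferroni, 0.05)
  # calibration under permuted labels
  reps <- replicate(200, {
    samples$group <- sample(samples$group)
    eigengene_significance(eg, samples, traits = "group")$p
  })
  expect_lt(abs(mean(reps < 0.05) - 0.05), 0.035)
})

test_that("the full network build recovers planted modules end to end", {
  b <- make_block_expr(c(80, 80, 80), 0.8, 150, n_noise = 120,
                       seed = 6)
  net <- build_network(b$expr, pipeline_config())
  expect_length(net$modules, 3)
  pl <- net$primary[rownames(b$expr)]
  ari <- mclust::adjustedRandIndex(pl[b$labels > 0], b$labels[b$labels > 0])
  expect_gte(ari, 0.9)
  expect_gte(mean(pl[b$labels == 0] == "grey"), 0.9)
  # module names come from the colour palette, grey reserved
  expect_false("grey" %in% names(net$modules))
})
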