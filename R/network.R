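# Unsigned weighted co-expression network analysis.
#
# adjacency a_ij = |cor(x_i, x_j)|^beta (beta = 6), topological overlap
# TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij), average-linkage
# clustering of the TOM dissimilarity, dynamic branch cutting (minimum
# module size 40), an initial eigengene merge at dissimilarity < 0.1,
# kME-based module merging (threshPercent 50 / mergePercent 25 /
# reassignScale 0.6) and final overlapping assignment at kME > 0.7 with
# a grey fallback. Preservation between two datasets is scored by the
# permutation Z-summary of module density and connectivity.

#' Iterative quality filter for network input
#'
#' Repeatedly drops genes with more than \code{max_missing} missing
#' values or zero variance, then samples with more than
#' \code{max_missing} missing values, until the matrix is stable.
#'
#' @param expr expression matrix (genes x samples), may contain NA.
#' @param max_missing maximum tolerated missing fraction (default 0.5).
#' @return list with the filtered \code{expr}, \code{genes_removed} and
#'   \code{samples_removed}.
#' @export
quality_filter_genes <- function(expr, max_missing = 0.5) {
  genes_removed <- character(); samples_removed <- character()
  repeat {
    gm <- rowMeans(is.na(expr))
    gv <- apply(expr, 1, function(x) var(x, na.rm = TRUE))
    bad_g <- gm > max_missing | is.na(gv) | gv == 0
    if (any(bad_g)) {
      genes_removed <- c(genes_removed, rownames(expr)[bad_g])
      expr <- expr[!bad_g, , drop = FALSE]
    }
    if (!nrow(expr)) stop("quality filter removed every gene")
    sm <- colMeans(is.na(expr))
    bad_s <- sm > max_missing
    if (any(bad_s)) {
      samples_removed <- c(samples_removed, colnames(expr)[bad_s])
      expr <- expr[, !bad_s, drop = FALSE]
    }
    if (!ncol(expr)) stop("quality filter removed every sample")
    if (!any(bad_g) && !any(bad_s)) break
  }
  list(expr = expr, genes_removed = genes_removed,
       samples_removed = samples_removed)
}

#' Unsigned soft-threshold adjacency
#'
#' \code{a_ij = |pearson(x_i, x_j)|^power}. The diagonal is stored as 1
#' by convention but excluded from connectivity sums downstream.
#'
#' @param expr expression matrix (genes x samples), >= 3 samples,
#'   quality-filtered (zero-variance genes are an error).
#' @param power soft-threshold exponent (default 6).
#' @return symmetric adjacency matrix in [0, 1].
#' @export
wgcna_adjacency <- function(expr, power = 6) {
  if (ncol(expr) < 3) stop("need at least 3 samples")
  sds <- apply(expr, 1, function(x) sd(x, na.rm = TRUE))
  if (any(is.na(sds) | sds == 0))
    stop("zero-variance gene(s) must be filtered first: ",
         paste(head(rownames(expr)[is.na(sds) | sds == 0], 3),
               collapse = ", "))
  a <- abs(cor(t(expr), use = "pairwise.complete.obs"))^power
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' \code{TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)} with
#' \code{l_ij = sum_u a_iu a_uj} over u distinct from i and j, and
#' \code{k_i = sum_{u != i} a_iu}; \code{TOM_ii = 1}.
#'
#' @param adj adjacency matrix from \code{\link{wgcna_adjacency}}.
#' @return list with \code{sim} (TOM) and \code{diss} (1 - TOM).
#' @export
tom_similarity <- function(adj) {
  a <- adj
  diag(a) <- 0
  l <- a %*% a            # zero diagonal makes this exactly l_ij
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  sim <- (l + a) / (kmin + 1 - a)
  diag(sim) <- 1
  list(sim = sim, diss = 1 - sim)
}

# ---- dynamic branch cutting -------------------------------------------

# per-node leaf sets and heights for an hclust tree
.tree_nodes <- function(tree) {
  m <- tree$merge
  leaves <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    a <- m[i, 1]; b <- m[i, 2]
    la <- if (a < 0) -a else leaves[[a]]
    lb <- if (b < 0) -b else leaves[[b]]
    leaves[[i]] <- c(la, lb)
  }
  leaves
}

# recursively split node i while both children satisfy min_size and the
# height gap criterion; returns a list of leaf-index vectors
.split_branch <- function(i, tree, leaves, min_size, min_gap) {
  m <- tree$merge; h <- tree$height
  node_h <- h[i]
  a <- m[i, 1]; b <- m[i, 2]
  size_a <- if (a < 0) 1L else length(leaves[[a]])
  size_b <- if (b < 0) 1L else length(leaves[[b]])
  h_a <- if (a < 0) 0 else h[a]
  h_b <- if (b < 0) 0 else h[b]
  if (size_a >= min_size && size_b >= min_size &&
      (node_h - max(h_a, h_b)) >= min_gap) {
    c(.split_branch(a, tree, leaves, min_size, min_gap),
      .split_branch(b, tree, leaves, min_size, min_gap))
  } else {
    list(leaves[[i]])
  }
}

#' Detect modules by dynamic branch cutting
#'
#' Approximation of hybrid dynamic tree cutting on the average-linkage
#' tree of the TOM dissimilarity: (a) a static cut at \code{cut_height}
#' (absolute on the unit TOM-dissimilarity scale, so featureless trees
#' whose merges all sit above it yield no modules); (b) recursive
#' splitting of each branch while both children hold at least
#' \code{min_size} genes and are separated from the parent merge by at
#' least \code{min_gap}; (c) PAM-like assignment of leftover genes to the
#' module with the smallest mean dissimilarity, capped at
#' \code{cut_height}; (d) an eigengene merge pass joining modules whose
#' eigengene dissimilarity (1 - cor) is below \code{merge_height}.
#'
#' @param diss TOM dissimilarity matrix.
#' @param expr expression matrix (genes x samples) used for eigengenes.
#' @param min_size minimum module size (default 40).
#' @param merge_height eigengene-dissimilarity merge threshold
#'   (default 0.1, i.e. eigengene correlation > 0.9 merges).
#' @param cut_height static cut height (default 0.995).
#' @param min_gap minimum branch height gap for recursive splits.
#' @return list with \code{labels} (named vector, "grey" = unassigned),
#'   \code{modules} (named list of gene vectors, size-ordered colour
#'   names), \code{tree} (the hclust object) and \code{merge_history}.
#' @export
detect_modules <- function(diss, expr, min_size = 40, merge_height = 0.1,
                           cut_height = 0.995, min_gap = 0.02) {
  genes <- rownames(diss)
  n <- length(genes)
  tree <- hclust(as.dist(diss), method = "average")
  if (n < min_size) {
    warning("fewer genes (", n, ") than min_size (", min_size,
            "); everything is grey")
    labels <- setNames(rep("grey", n), genes)
    return(list(labels = labels, modules = list(), tree = tree,
                merge_history = character()))
  }
  static <- cutree(tree, h = cut_height)
  leaves <- .tree_nodes(tree)
  modules <- list()
  for (cl in unique(static)) {
    idx <- which(static == cl)
    if (length(idx) < min_size) next
    # top node of this branch: highest merge fully inside the branch
    inside <- vapply(seq_along(leaves),
                     function(i) all(leaves[[i]] %in% idx), TRUE)
    top <- which(inside)[which.max(tree$height[inside])]
    modules <- c(modules, .split_branch(top, tree, leaves, min_size,
                                        min_gap))
  }
  labels <- setNames(rep("grey", n), genes)
  if (length(modules)) {
    # PAM-like rescue of unassigned genes
    assigned <- unlist(modules)
    stray <- setdiff(seq_len(n), assigned)
    if (length(stray)) {
      mean_d <- vapply(modules, function(mod)
        rowMeans(diss[stray, mod, drop = FALSE]), numeric(length(stray)))
      mean_d <- matrix(mean_d, nrow = length(stray))
      best <- max.col(-mean_d, ties.method = "first")
      ok <- mean_d[cbind(seq_along(stray), best)] <= cut_height
      for (j in which(ok))
        modules[[best[j]]] <- c(modules[[best[j]]], stray[j])
    }
    # eigengene merge pass
    mods <- lapply(modules, function(i) genes[i])
    merge_history <- character()
    repeat {
      if (length(mods) < 2) break
      eg <- vapply(mods, function(g)
        module_eigengene(expr[g, , drop = FALSE])$eigengene,
        numeric(ncol(expr)))
      dd <- 1 - abs(cor(eg))
      diag(dd) <- Inf
      mn <- which(dd == min(dd), arr.ind = TRUE)[1, ]
      if (dd[mn[1], mn[2]] >= merge_height) break
      merge_history <- c(merge_history,
                         sprintf("merged modules of %d and %d genes (eigengene diss %.3f)",
                                 length(mods[[mn[1]]]), length(mods[[mn[2]]]),
                                 dd[mn[1], mn[2]]))
      mods[[mn[1]]] <- c(mods[[mn[1]]], mods[[mn[2]]])
      mods[[mn[2]]] <- NULL
    }
    mods <- mods[order(-lengths(mods))]
    names(mods) <- .module_names(length(mods))
    for (nm in names(mods)) labels[mods[[nm]]] <- nm
    return(list(labels = labels, modules = mods, tree = tree,
                merge_history = merge_history))
  }
  list(labels = labels, modules = list(), tree = tree,
       merge_history = character())
}

#' Module eigengene
#'
#' First principal component of the gene-standardised (zero mean, unit
#' SD per gene) module submatrix, expressed as a unit-norm per-sample
#' score, sign-aligned so its mean correlation with member genes is
#' positive.
#'
#' @param expr expression matrix restricted to the module's member genes
#'   (>= 2 rows).
#' @return list with \code{eigengene} (length = samples, unit norm) and
#'   \code{var_explained}.
#' @export
module_eigengene <- function(expr) {
  if (nrow(expr) < 2) stop("module needs at least 2 member genes")
  sds <- apply(expr, 1, sd)
  if (all(sds == 0)) stop("degenerate (rank-0) module submatrix")
  x <- (expr - rowMeans(expr)) / ifelse(sds > 0, sds, 1)
  sv <- svd(x, nu = 0, nv = 1)
  e <- sv$v[, 1]
  if (mean(cor(t(expr), e)) < 0) e <- -e
  list(eigengene = e, var_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Module membership (kME)
#'
#' \code{kME_gm = pearson(x_g, eigengene_m)} for every gene and module.
#'
#' @param expr expression matrix (genes x samples).
#' @param eigengenes samples x modules matrix of eigengene scores.
#' @return genes x modules kME matrix.
#' @export
module_kme <- function(expr, eigengenes) {
  cor(t(expr), eigengenes)
}

#' Assign genes to modules by kME
#'
#' A gene joins every module for which its kME strictly exceeds
#' \code{threshold} (so membership may overlap); genes failing the
#' criterion for all modules are grey.
#'
#' @param kme genes x modules kME matrix.
#' @param threshold strict kME lower bound (default 0.7).
#' @return list with \code{membership} (logical genes x modules),
#'   \code{primary} (named vector: module of maximal kME among assigned,
#'   or "grey") and \code{modules} (named list of member vectors).
#' @export
assign_by_kme <- function(kme, threshold = 0.7) {
  membership <- kme > threshold
  primary <- rep("grey", nrow(kme))
  names(primary) <- rownames(kme)
  any_m <- rowSums(membership) > 0
  if (any(any_m)) {
    km <- kme
    km[!membership] <- -Inf
    primary[any_m] <- colnames(kme)[max.col(km[any_m, , drop = FALSE],
                                            ties.method = "first")]
  }
  modules <- lapply(setNames(colnames(kme), colnames(kme)),
                    function(m) rownames(kme)[membership[, m]])
  list(membership = membership, primary = primary, modules = modules)
}

# own-module kME with the gene's own contribution to the eigengene
# removed (rank-one leave-one-out correction): without it a module's
# eigengene overfits its members and even identical-factor duplicate
# modules fail the "prefers the other module" comparison
.kme_own_loo <- function(expr, members) {
  x <- expr[members, , drop = FALSE]
  sds <- apply(x, 1, sd)
  xs <- (x - rowMeans(x)) / ifelse(sds > 0, sds, 1)
  sv <- svd(xs, nu = 1, nv = 1)
  u <- sv$u[, 1]
  score <- sv$d[1] * sv$v[, 1]
  if (mean(u) < 0) {        # sign-align with the member genes
    u <- -u
    score <- -score
  }
  vapply(seq_along(members), function(i)
    cor(xs[i, ], score - u[i] * xs[i, ]), 0)
}

#' Merge modules by kME structure
#'
#' For each ordered module pair (smaller first): take the top
#' \code{thresh_percent}\% of the smaller module's genes ranked by kME to
#' their own module; if more than \code{merge_percent}\% of them have a
#' higher kME to the other module than to their own (own-module kME taken
#' with a leave-one-out correction so a gene's self-contribution to the
#' eigengene does not bias the comparison), merge the smaller into the
#' larger.
#' After each merge pass, every gene whose best foreign kME exceeds
#' \code{reassign_scale} times its home-module kME moves to its
#' maximal-kME module. Eigengenes are recomputed and the procedure
#' iterates to a fixed point (bounded by twice the initial module
#' count).
#'
#' @param expr expression matrix (genes x samples).
#' @param modules named list of member-gene vectors (disjoint primary
#'   assignment).
#' @param thresh_percent,merge_percent,reassign_scale merge parameters
#'   (defaults 50, 25, 0.6).
#' @return list with the merged \code{modules}, final \code{eigengenes},
#'   \code{kme}, and \code{history}.
#' @export
merge_by_kme <- function(expr, modules, thresh_percent = 50,
                         merge_percent = 25, reassign_scale = 0.6) {
  history <- character()
  if (length(modules) < 1)
    return(list(modules = modules, eigengenes = NULL, kme = NULL,
                history = history))
  max_iter <- max(2 * length(modules), 4)
  iter <- 0
  repeat {
    iter <- iter + 1
    if (iter > max_iter)
      stop("kME merge failed to reach a fixed point after ", max_iter,
           " iterations (", length(modules), " modules remain)")
    eg <- vapply(modules, function(g)
      module_eigengene(expr[g, , drop = FALSE])$eigengene,
      numeric(ncol(expr)))
    colnames(eg) <- names(modules)
    kme <- module_kme(expr, eg)
    changed <- FALSE
    if (length(modules) >= 2) {
      ord <- order(lengths(modules))
      for (i in ord) {
        m <- names(modules)[i]
        members <- modules[[m]]
        k_home <- setNames(.kme_own_loo(expr, members), members)
        n_top <- max(1L, ceiling(thresh_percent / 100 * length(members)))
        top <- members[order(-k_home)][seq_len(n_top)]
        for (o in setdiff(names(modules), m)) {
          if (length(modules[[o]]) < length(members)) next
          frac <- mean(kme[top, o] > k_home[top])
          if (frac > merge_percent / 100) {
            modules[[o]] <- c(modules[[o]], members)
            modules[[m]] <- NULL
            history <- c(history, sprintf("merged %s into %s (%.0f%% of top genes prefer it)",
                                          m, o, 100 * frac))
            changed <- TRUE
            break
          }
        }
        if (changed) break
      }
    }
    if (changed) next
    # reassignment pass on the current eigengene set
    moved <- FALSE
    if (length(modules) >= 2) {
      assignment <- rep(names(modules), lengths(modules))
      names(assignment) <- unlist(modules)
      for (g in names(assignment)) {
        home <- assignment[g]
        foreign <- setdiff(names(modules), home)
        kf <- kme[g, foreign]
        best <- foreign[which.max(kf)]
        if (max(kf) > reassign_scale * kme[g, home] &&
            max(kf) > kme[g, home]) {
          modules[[home]] <- setdiff(modules[[home]], g)
          modules[[best]] <- c(modules[[best]], g)
          moved <- TRUE
        }
      }
      small <- lengths(modules) < 2
      if (any(small)) {
        history <- c(history, sprintf("dropped emptied module(s): %s",
                                      paste(names(modules)[small],
                                            collapse = ", ")))
        modules <- modules[!small]
        moved <- TRUE
      }
      if (moved) {
        history <- c(history, "reassigned genes to maximal-kME modules")
        next
      }
    }
    break
  }
  eg <- vapply(modules, function(g)
    module_eigengene(expr[g, , drop = FALSE])$eigengene,
    numeric(ncol(expr)))
  colnames(eg) <- names(modules)
  rownames(eg) <- colnames(expr)
  list(modules = modules, eigengenes = eg, kme = module_kme(expr, eg),
       history = history)
}

#' Build the full co-expression network
#'
#' Quality filter, adjacency at \code{soft_power}, TOM, dynamic branch
#' cutting with eigengene merging, kME-based module merging, and final
#' overlapping assignment at \code{kme_threshold} with grey fallback.
#'
#' @param expr expression matrix (genes x samples).
#' @param config a \code{\link{pipeline_config}}.
#' @return a ModuleSet: list with \code{modules} (overlapping final
#'   membership), \code{primary} (one label per gene, "grey" =
#'   unassigned), \code{eigengenes} (samples x modules), \code{kme},
#'   \code{var_explained}, \code{tree}, \code{merge_history}, and the
#'   filtered \code{genes}.
#' @export
build_network <- function(expr, config = pipeline_config()) {
  qf <- quality_filter_genes(expr)
  expr <- qf$expr
  adj <- wgcna_adjacency(expr, power = config$soft_power)
  tomres <- tom_similarity(adj)
  det <- detect_modules(tomres$diss, expr,
                        min_size = config$min_module_size,
                        merge_height = config$merge_height,
                        cut_height = config$cut_height,
                        min_gap = config$min_gap)
  merged <- merge_by_kme(expr, det$modules,
                         thresh_percent = config$thresh_percent,
                         merge_percent = config$merge_percent,
                         reassign_scale = config$reassign_scale)
  if (!length(merged$modules))
    return(list(modules = list(), primary = setNames(
      rep("grey", nrow(expr)), rownames(expr)),
      eigengenes = NULL, kme = NULL, var_explained = numeric(),
      tree = det$tree, merge_history = det$merge_history,
      genes = rownames(expr)))
  # size-ordered colour names for the final module set
  mods <- merged$modules[order(-lengths(merged$modules))]
  names(mods) <- .module_names(length(mods))
  eg <- vapply(mods, function(g)
    module_eigengene(expr[g, , drop = FALSE])$eigengene,
    numeric(ncol(expr)))
  colnames(eg) <- names(mods)
  rownames(eg) <- colnames(expr)
  ve <- vapply(mods, function(g)
    module_eigengene(expr[g, , drop = FALSE])$var_explained, 0)
  kme <- module_kme(expr, eg)
  assign <- assign_by_kme(kme, threshold = config$kme_threshold)
  list(modules = assign$modules, primary = assign$primary,
       eigengenes = eg, kme = kme, var_explained = ve,
       tree = det$tree,
       merge_history = c(det$merge_history, merged$history),
       genes = rownames(expr))
}

#' Module eigengene significance against sample traits
#'
#' Binary traits: Welch two-sample t-test of the eigengene between
#' levels; continuous traits: Pearson correlation with the Student
#' asymptotic p value. Bonferroni correction across all module x trait
#' tests performed. Constant or all-missing traits are skipped with a
#' warning.
#'
#' @param eigengenes samples x modules matrix.
#' @param samples sample table (rows matching the eigengene rows by
#'   \code{sample_id}).
#' @param traits column names of \code{samples} to test.
#' @return data.frame: module, trait, type, statistic, p, p_bonferroni.
#' @export
eigengene_significance <- function(eigengenes, samples,
                                   traits = c("group", "age", "sex",
                                              "gestation_weeks",
                                              "comorbidity",
                                              "risk_factor")) {
  stopifnot(!is.null(rownames(eigengenes)))
  samples <- samples[match(rownames(eigengenes), samples$sample_id), ,
                     drop = FALSE]
  traits <- intersect(traits, names(samples))
  rows <- list()
  for (tr in traits) {
    v <- samples[[tr]]
    ok <- !is.na(v)
    if (sum(ok) < 3 || length(unique(v[ok])) < 2) {
      warning("trait '", tr, "' constant or too sparse; skipped")
      next
    }
    binary <- is.logical(v) || is.factor(v) || is.character(v)
    for (m in colnames(eigengenes)) {
      e <- eigengenes[ok, m]
      if (binary) {
        f <- factor(v[ok])
        if (nlevels(f) != 2) {
          warning("trait '", tr, "' is not binary; skipped")
          break
        }
        tt <- t.test(e ~ f)
        rows[[length(rows) + 1]] <- data.frame(
          module = m, trait = tr, type = "binary",
          statistic = unname(tt$statistic), p = tt$p.value,
          stringsAsFactors = FALSE)
      } else {
        ct <- cor.test(e, v[ok], method = "pearson")
        rows[[length(rows) + 1]] <- data.frame(
          module = m, trait = tr, type = "continuous",
          statistic = unname(ct$estimate), p = ct$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}

# density and connectivity statistics of a gene set in one dataset pair
.preservation_stats <- function(ref_expr, test_expr, genes, power) {
  a_ref <- abs(cor(t(ref_expr[genes, , drop = FALSE])))^power
  a_test <- abs(cor(t(test_expr[genes, , drop = FALSE])))^power
  off <- row(a_test) != col(a_test)
  density <- mean(a_test[off])
  kim_ref <- rowSums(a_ref) - 1
  kim_test <- rowSums(a_test) - 1
  conn <- suppressWarnings(cor(kim_ref, kim_test))
  if (is.na(conn)) conn <- 0
  c(density = density, connectivity = conn)
}

#' Permutation module preservation (Z-summary)
#'
#' For each module, the observed statistics are the mean intramodular
#' adjacency in the test data (density) and the correlation of
#' intramodular connectivities between reference and test data
#' (connectivity). The null distribution is obtained from
#' \code{n_perm} random gene sets of equal size drawn (without
#' replacement) from the shared gene universe excluding every module of
#' the tested set, so the null reflects unstructured background genes
#' (when that leaves too small a pool, only the tested module is
#' excluded); \code{Z = (obs - mean_null) / sd_null} and \code{Z_summary}
#' is the mean of the density and connectivity Z scores. Modules are
#' conventionally called preserved when Z-summary exceeds 10.
#'
#' @param ref_expr,test_expr expression matrices sharing a gene universe.
#' @param modules named list of member-gene vectors.
#' @param power adjacency exponent (default 6).
#' @param n_perm number of permutations (default 100).
#' @param seed mandatory integer seed for the permutation draws.
#' @return data.frame: module, n_genes, Z_density, Z_connectivity,
#'   Z_summary, n_permutations, seed.
#' @export
preservation_zsummary <- function(ref_expr, test_expr, modules,
                                  power = 6, n_perm = 100, seed) {
  if (missing(seed)) stop("seed is mandatory")
  universe <- intersect(rownames(ref_expr), rownames(test_expr))
  if (length(universe) < 10) stop("shared gene universe too small")
  ref_expr <- ref_expr[universe, , drop = FALSE]
  test_expr <- test_expr[universe, , drop = FALSE]
  with_seed(seed, {
    rows <- list()
    for (m in names(modules)) {
      genes <- intersect(modules[[m]], universe)
      if (length(genes) < 3) {
        warning("module '", m, "' has fewer than 3 shared genes; skipped")
        next
      }
      obs <- .preservation_stats(ref_expr, test_expr, genes, power)
      pool <- setdiff(universe, unique(unlist(modules)))
      if (length(pool) < length(genes)) pool <- setdiff(universe, genes)
      if (length(pool) < length(genes))
        stop("gene universe too small for permutation null of module ", m)
      null <- vapply(seq_len(n_perm), function(i) {
        rnd <- sample(pool, length(genes))
        .preservation_stats(ref_expr, test_expr, rnd, power)
      }, c(density = 0, connectivity = 0))
      zs <- vapply(c("density", "connectivity"), function(stat) {
        mu <- mean(null[stat, ]); sdev <- sd(null[stat, ])
        if (sdev == 0) return(0)
        (obs[stat] - mu) / sdev
      }, 0)
      rows[[m]] <- data.frame(
        module = m, n_genes = length(genes),
        Z_density = unname(zs["density"]),
        Z_connectivity = unname(zs["connectivity"]),
        Z_summary = mean(zs),
        n_permutations = n_perm, seed = seed,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
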