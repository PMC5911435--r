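# Preprocessing: library-size normalisation, robust-expression filter,
# log2 transform, parametric empirical-Bayes batch adjustment, and the
# MDS batch-removal check.
#
# Expression matrices are plain numeric matrices (genes x samples) with a
# "provenance" attribute listing the transforms applied in order.

add_provenance <- function(m, tag) {
  attr(m, "provenance") <- c(attr(m, "provenance"), tag)
  m
}

#' Counts per million
#'
#' \code{cpm_gs = counts_gs / libsize_s * 1e6} with the library size taken
#' as the total column sum over all genes (computed before any filtering).
#'
#' @param counts count matrix (genes x samples).
#' @param lib_sizes optional per-sample library sizes; defaults to the
#'   column sums of \code{counts}.
#' @return CPM matrix; every column sums to 1e6 (up to float rounding)
#'   when \code{lib_sizes} is the default.
#' @export
cpm <- function(counts, lib_sizes = NULL) {
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0))
    stop("zero library size for sample: ",
         paste(colnames(counts)[lib_sizes <= 0], collapse = ", "))
  out <- t(t(counts) / lib_sizes) * 1e6
  add_provenance(out, "cpm")
}

#' Robust-expression filter
#'
#' Keeps gene g iff its CPM exceeds \code{min_cpm} (strictly) in at least
#' \code{min_samples} samples. With the default thresholds this is the
#' "more than five counts per million in at least 120 of 302 samples"
#' rule, expressed as a fraction so other cohort sizes scale.
#'
#' @param cpm_matrix CPM matrix.
#' @param min_cpm CPM threshold (strict >).
#' @param min_samples minimum number of samples; if \code{NULL}, computed
#'   as \code{ceiling(min_fraction * ncol)}.
#' @param min_fraction fraction of samples used when \code{min_samples}
#'   is \code{NULL}.
#' @return character vector of kept gene identifiers (input order).
#' @export
filter_robust <- function(cpm_matrix, min_cpm = 5, min_samples = NULL,
                          min_fraction = 120 / 302) {
  if (is.null(min_samples))
    min_samples <- as.integer(ceiling(min_fraction * ncol(cpm_matrix)))
  if (min_samples > ncol(cpm_matrix))
    stop("min_samples (", min_samples, ") exceeds sample count (",
         ncol(cpm_matrix), ")")
  keep <- rowSums(cpm_matrix > min_cpm) >= min_samples
  if (!any(keep))
    stop("no gene passes the robust-expression filter; ",
         "review min_cpm/min_samples")
  rownames(cpm_matrix)[keep]
}

#' Log2 transform with pseudocount
#'
#' @param m non-negative matrix.
#' @param pseudocount added before the log (default 1).
#' @return log2(m + pseudocount) with provenance recording the
#'   pseudocount.
#' @export
log2_transform <- function(m, pseudocount = 1) {
  if (any(m < 0)) stop("negative values cannot be log-transformed")
  out <- log2(m + pseudocount)
  attr(out, "provenance") <- attr(m, "provenance")
  attr(out, "pseudocount") <- pseudocount
  add_provenance(out, sprintf("log2(+%g)", pseudocount))
}

#' Parametric empirical-Bayes batch adjustment
#'
#' Per-gene location/scale batch adjustment: (1) gene-wise
#' standardisation removing covariate effects and pooled variance, (2)
#' per-batch location (gamma) and scale (delta^2) estimates shrunk toward
#' batch-level priors (normal prior on gamma, inverse-gamma on delta^2,
#' hyper-parameters by method of moments, iterative posterior solve), (3)
#' reconstruction without batch terms, covariate effects restored. This
#' is the parametric location/scale model popularised by the ComBat
#' function; \code{conv} is the maximum relative change at which the
#' posterior iteration stops.
#'
#' @param expr expression matrix (genes x samples), typically log2 scale.
#' @param batch per-sample batch labels (>= 2 batches, each >= 2 samples).
#' @param covariates optional per-sample data.frame of covariates to
#'   protect (e.g. sex, group); must not be confounded with batch.
#' @param conv convergence tolerance of the posterior iteration.
#' @return list with \code{expr} (adjusted matrix, provenance extended)
#'   and \code{model} (per-batch gamma/delta^2 estimates, their shrunken
#'   counterparts, prior hyper-parameters, and the design used).
#' @export
combat_adjust <- function(expr, batch, covariates = NULL, conv = 1e-4) {
  batch <- droplevels(factor(batch))
  if (nlevels(batch) < 2) stop("need at least 2 batches")
  nb <- table(batch)
  if (any(nb < 2))
    stop("singleton (or near-singleton) batch: ",
         paste(names(nb)[nb < 2], collapse = ", "))
  n_array <- ncol(expr)
  n_batch <- nlevels(batch)
  batch_design <- model.matrix(~ -1 + batch)
  cov_mm <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cov_mm <- model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  }
  design <- cbind(batch_design, cov_mm)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    aliased <- colnames(design)[qrd$pivot[-seq_len(qrd$rank)]]
    stop("covariate(s) confounded with batch: ",
         paste(aliased, collapse = ", "))
  }

  dat <- expr
  B_hat <- solve(crossprod(design), t(design) %*% t(dat))
  grand_mean <- crossprod(as.numeric(nb) / n_array,
                          B_hat[seq_len(n_batch), , drop = FALSE])
  resid <- dat - t(design %*% B_hat)
  var_pooled <- rowMeans(resid^2)
  if (any(var_pooled <= 0))
    stop("zero pooled variance for gene(s): ",
         paste(head(rownames(dat)[var_pooled <= 0], 3), collapse = ", "))
  stand_mean <- matrix(grand_mean, nrow(dat), n_array)
  if (!is.null(cov_mm)) {
    tmp <- design
    tmp[, seq_len(n_batch)] <- 0
    stand_mean <- stand_mean + t(tmp %*% B_hat)
  }
  s_data <- (dat - stand_mean) / sqrt(var_pooled)

  gamma_hat <- matrix(NA_real_, n_batch, nrow(dat))
  delta2_hat <- matrix(NA_real_, n_batch, nrow(dat))
  gamma_star <- gamma_hat; delta2_star <- delta2_hat
  gamma_bar <- t2 <- a_prior <- b_prior <- numeric(n_batch)
  for (b in seq_len(n_batch)) {
    idx <- which(batch == levels(batch)[b])
    sb <- s_data[, idx, drop = FALSE]
    gamma_hat[b, ] <- rowMeans(sb)
    delta2_hat[b, ] <- apply(sb, 1, var)
    gamma_bar[b] <- mean(gamma_hat[b, ])
    t2[b] <- var(gamma_hat[b, ])
    m <- mean(delta2_hat[b, ]); s2 <- var(delta2_hat[b, ])
    a_prior[b] <- (2 * s2 + m^2) / s2
    b_prior[b] <- (m * s2 + m^3) / s2
    # iterative posterior solve for gamma*, delta2*
    g_old <- gamma_hat[b, ]; d_old <- delta2_hat[b, ]
    nbb <- length(idx)
    repeat {
      g_new <- (nbb * t2[b] * gamma_hat[b, ] + d_old * gamma_bar[b]) /
        (nbb * t2[b] + d_old)
      sum2 <- rowSums((sb - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[b]) / (nbb / 2 + a_prior[b] - 1)
      change <- max(abs(g_new - g_old) / abs(g_old),
                    abs(d_new - d_old) / abs(d_old))
      g_old <- g_new; d_old <- d_new
      if (change < conv) break
    }
    gamma_star[b, ] <- g_old
    delta2_star[b, ] <- d_old
  }

  adj <- s_data
  for (b in seq_len(n_batch)) {
    idx <- which(batch == levels(batch)[b])
    adj[, idx] <- (s_data[, idx, drop = FALSE] - gamma_star[b, ]) /
      sqrt(delta2_star[b, ])
  }
  adj <- adj * sqrt(var_pooled) + stand_mean
  attr(adj, "provenance") <- attr(expr, "provenance")
  adj <- add_provenance(adj, "combat")

  model <- list(
    batches = levels(batch), n_per_batch = as.integer(nb),
    gamma_hat = gamma_hat, delta2_hat = delta2_hat,
    gamma_star = gamma_star, delta2_star = delta2_star,
    gamma_bar = gamma_bar, tau2_bar = t2,
    a_prior = a_prior, b_prior = b_prior,
    design = design, var_pooled = var_pooled)
  list(expr = adj, model = model)
}

#' MDS batch/group separation check
#'
#' Classical metric MDS of samples on the (1 - Pearson correlation)
#' distance, with the silhouette width of a label partition in the 2-D
#' embedding as a separation score. After successful batch adjustment
#' batch labels should score near zero.
#'
#' @param expr expression matrix (genes x samples), >= 3 samples.
#' @param labels per-sample labels (e.g. batch).
#' @return list with \code{coords} (samples x 2), \code{silhouette}
#'   (mean silhouette width; NA when labels are constant), and
#'   \code{labels}.
#' @export
mds_check <- function(expr, labels) {
  if (ncol(expr) < 3) stop("need at least 3 samples for MDS")
  sds <- apply(expr, 2, sd)
  if (any(sds == 0))
    stop("constant sample(s): ",
         paste(colnames(expr)[sds == 0], collapse = ", "))
  d <- 1 - cor(expr)
  d[d < 0] <- 0
  coords <- cmdscale(as.dist(d), k = 2)
  colnames(coords) <- c("MDS1", "MDS2")
  lab <- factor(labels)
  sil <- NA_real_
  if (nlevels(lab) >= 2) {
    sw <- cluster::silhouette(as.integer(lab), dist(coords))
    sil <- mean(sw[, "sil_width"])
  }
  list(coords = coords, silhouette = sil, labels = lab)
}
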