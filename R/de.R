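# Dual-analysis moderated-t differential expression.
#
# Two arms: a "primary" analysis of all samples on batch-adjusted
# expression, and a "secondary" analysis of cases against in-house
# controls only with age and sex in the model. Genes are reported as
# differentially expressed when they pass both arms with consistent sign
# (intersect_de).

#' Per-gene ordinary least squares fit
#'
#' Fits the same linear model to every gene (row) of the expression
#' matrix. The case/control contrast column of the design yields the
#' log2 fold change when the expression is on the log2 scale.
#'
#' @param expr expression matrix (genes x samples).
#' @param design model matrix (samples x coefficients), full rank, with
#'   residual df >= 1.
#' @return list with \code{beta} (genes x coefficients),
#'   \code{stdev_unscaled}, \code{s2} (residual variances), \code{df}
#'   (residual df), and \code{design}.
#' @export
fit_linear_model <- function(expr, design) {
  design <- as.matrix(design)
  stopifnot(nrow(design) == ncol(expr))
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    aliased <- colnames(design)[qrd$pivot[-seq_len(qrd$rank)]]
    stop("design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  if (nrow(design) - ncol(design) < 1)
    stop("residual degrees of freedom < 1")
  fit <- limma::lmFit(expr, design)
  list(beta = fit$coefficients,
       stdev_unscaled = fit$stdev.unscaled,
       s2 = fit$sigma^2,
       df = fit$df.residual,
       design = design)
}

#' Empirical-Bayes variance moderation and moderated t
#'
#' Shrinks per-gene residual variances toward a pooled prior under a
#' scaled-inverse-chi-squared model: \code{s2_post = (d0 s02 + d s2) /
#' (d0 + d)}, with the prior df \code{d0} and prior variance \code{s02}
#' estimated by moment matching on the log variances unless supplied.
#' The moderated t for the chosen coefficient is \code{beta /
#' (stdev_unscaled * sqrt(s2_post))} with \code{d0 + d} degrees of
#' freedom. Closed-form limits: \code{d0 = 0} leaves \code{s2_post = s2}
#' (ordinary t); \code{d0 = Inf} gives \code{s2_post = s02} for every
#' gene (and must not crash when all variances are equal).
#'
#' @param fit result of \code{\link{fit_linear_model}}.
#' @param coef name or index of the tested coefficient.
#' @param d0,s02 optional explicit prior df and prior variance; both must
#'   be given together. Estimated from the data when \code{NULL}.
#' @return list with \code{d0}, \code{s02}, \code{s2_post}, \code{t},
#'   \code{p} (two-sided, df = d0 + d), \code{df_total}, and \code{lfc}
#'   (the tested coefficient).
#' @export
ebayes_moderate <- function(fit, coef = 2, d0 = NULL, s02 = NULL) {
  s2 <- fit$s2
  d <- fit$df
  if (length(s2) < 10 && is.null(d0))
    stop("need at least 10 genes to estimate the variance prior")
  if (is.null(d0) != is.null(s02))
    stop("d0 and s02 must be supplied together")
  if (is.null(d0)) {
    sq <- limma::squeezeVar(s2, d)
    d0 <- sq$df.prior
    s02 <- sq$var.prior
    s2_post <- sq$var.post
  } else if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
  } else if (d0 == 0) {
    s2_post <- s2
  } else {
    s2_post <- (d0 * s02 + d * s2) / (d0 + d)
  }
  beta <- fit$beta[, coef]
  su <- fit$stdev_unscaled[, coef]
  tstat <- beta / (su * sqrt(s2_post))
  df_total <- d + d0
  p <- 2 * pt(-abs(tstat), df = df_total)
  list(d0 = d0, s02 = s02, s2_post = s2_post, t = tstat, p = p,
       df_total = df_total, lfc = beta)
}

#' Run one differential-expression arm
#'
#' \code{mode = "primary"}: all samples, model \code{~ group} (expression
#' is expected to be batch-adjusted already). \code{mode = "secondary"}:
#' cases plus in-house controls only (controls sharing a batch with at
#' least one case), model \code{~ group + age + sex}. P values are
#' Bonferroni-corrected across the tested genes.
#'
#' @param expr log2 expression matrix (genes x samples).
#' @param samples sample table.
#' @param mode \code{"primary"} or \code{"secondary"}.
#' @return data.frame: gene, log2FC (case - control), t, p, p_adjusted,
#'   analysis_id.
#' @export
run_de <- function(expr, samples, mode = c("primary", "secondary")) {
  mode <- match.arg(mode)
  samples <- validate_samples(samples, expr)
  if (mode == "secondary") {
    case_batches <- unique(samples$batch[samples$group == "case"])
    keep <- samples$group == "case" |
      (samples$group == "control" & samples$batch %in% case_batches)
    if (sum(keep & samples$group == "control") < 3)
      stop("secondary analysis needs at least 3 in-house controls")
    samples <- samples[keep, , drop = FALSE]
    expr <- expr[, samples$sample_id, drop = FALSE]
    design <- model.matrix(~ group + age + sex, data = samples)
  } else {
    design <- model.matrix(~ group, data = samples)
  }
  fit <- fit_linear_model(expr, design)
  mod <- ebayes_moderate(fit, coef = "groupcase")
  data.frame(gene = rownames(expr),
             log2FC = unname(mod$lfc),
             moderated_t = unname(mod$t),
             p = unname(mod$p),
             p_adjusted = p.adjust(unname(mod$p), method = "bonferroni"),
             analysis_id = mode,
             stringsAsFactors = FALSE)
}

#' Intersect the two differential-expression arms
#'
#' A gene is reported iff |log2FC| exceeds \code{lfc} in both arms with
#' agreeing sign, its Bonferroni-corrected p is below \code{p1} in the
#' primary arm, and its p value is below \code{p2} in the secondary arm
#' (unadjusted by default, matching how the two thresholds are stated;
#' set \code{secondary_adjusted = TRUE} to use the Bonferroni-corrected
#' value there too). Genes excluded only because the two arms disagree
#' in sign are recorded in the \code{"sign_disagreement"} attribute.
#'
#' @param primary,secondary DE result data.frames sharing a gene universe.
#' @param lfc,p1,p2 thresholds (defaults 0.5, 0.001, 0.05).
#' @param secondary_adjusted whether \code{p2} applies to the secondary
#'   arm's Bonferroni-corrected p (default \code{FALSE}: raw p).
#' @return data.frame: gene, direction (up/down), per-arm log2FC and
#'   adjusted p.
#' @export
intersect_de <- function(primary, secondary, lfc = 0.5, p1 = 0.001,
                         p2 = 0.05, secondary_adjusted = FALSE) {
  m <- merge(primary, secondary, by = "gene",
             suffixes = c("_primary", "_secondary"))
  p_sec <- if (secondary_adjusted) m$p_adjusted_secondary else
    m$p_secondary
  size_ok <- abs(m$log2FC_primary) > lfc & abs(m$log2FC_secondary) > lfc &
    m$p_adjusted_primary < p1 & p_sec < p2
  sign_ok <- sign(m$log2FC_primary) == sign(m$log2FC_secondary)
  out <- m[size_ok & sign_ok,
           c("gene", "log2FC_primary", "log2FC_secondary",
             "p_adjusted_primary", "p_adjusted_secondary"),
           drop = FALSE]
  out$direction <- ifelse(out$log2FC_primary > 0, "up", "down")
  out <- out[order(out$p_adjusted_primary), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sign_disagreement") <- m$gene[size_ok & !sign_ok]
  out
}
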