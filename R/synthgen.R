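# Synthetic cohort generator.
#
# Emulates a case/control lymphoblastoid-cell-line RNA-seq cohort:
# negative-binomial counts with log-normal library sizes and baseline
# abundances, a two-batch structure (cases + in-house controls vs an
# external control set), planted differential expression, planted
# per-sample expression outliers with or without a supporting variant
# annotation, and planted co-expression modules driven by latent factors
# that may correlate with a sample trait. Every planted signal is
# recorded in a GroundTruth object sufficient to score recovery exactly.

# run code under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specify a synthetic cohort
#'
#' Defaults mirror the study design the pipeline targets: 182 cases and 20
#' in-house controls in one batch, 100 external controls in a second
#' batch, ~2000 genes with log-normal baseline abundance and per-gene
#' negative-binomial dispersion, library sizes log-normal around 1e7 with
#' CV 0.3 (so the counts-per-million filter has realistic bite), 50
#' planted differentially expressed genes at |log2FC| = 1, planted case
#' outliers (loss-of-function-supported at 2.5-4 SD, missense-supported at
#' 2.5-4 SD, variant-free at 4.5-6 SD), and three planted 80-gene
#' co-expression modules at factor loading 0.8, the first correlated with
#' case status.
#'
#' @param n_genes number of genes.
#' @param n_cases,n_controls_inhouse,n_controls_external cohort arms; the
#'   external controls form their own batch.
#' @param baseline_meanlog2,baseline_sdlog2 normal parameters of baseline
#'   abundance on the log2-CPM scale.
#' @param dispersion_meanlog,dispersion_sdlog log-normal parameters of the
#'   per-gene NB dispersion phi (var = mu + phi mu^2); set
#'   \code{dispersion_meanlog = -Inf} for the Poisson limit.
#' @param libsize_mean,libsize_cv library-size log-normal mean and CV.
#' @param batch_shift_sd SD of the per-gene additive log2 location effect
#'   of the external batch (0 disables).
#' @param batch_scale_sd SD (log scale) of the per-gene dispersion
#'   inflation in the external batch (0 disables).
#' @param n_de,de_lfc planted DE genes (half up, half down) and |log2FC|.
#' @param n_outlier_lof,n_outlier_missense,n_outlier_novariant planted
#'   case outliers by supporting-variant status; each occupies a distinct
#'   case sample and a distinct gene.
#' @param shift_variant,shift_novariant length-2 ranges (in within-case
#'   SD units) for the planted shifts of variant-supported and
#'   variant-free outliers; signs alternate.
#' @param n_background_variants random benign variant rows (missense or
#'   other, no expression effect) added to the variant table.
#' @param modules list of planted modules, each
#'   \code{list(n_genes =, loading =, trait_cor =)}; \code{trait_cor} is
#'   the correlation of the module's latent factor with case status.
#' @param seed mandatory integer seed.
#' @return object of class \code{cohortex_simspec}.
#' @export
simulation_spec <- function(n_genes = 2000,
                            n_cases = 182,
                            n_controls_inhouse = 20,
                            n_controls_external = 100,
                            baseline_meanlog2 = 4,
                            baseline_sdlog2 = 2,
                            dispersion_meanlog = log(0.1),
                            dispersion_sdlog = 0.5,
                            libsize_mean = 1e7,
                            libsize_cv = 0.3,
                            batch_shift_sd = 0.5,
                            batch_scale_sd = 0.1,
                            n_de = 50,
                            de_lfc = 1,
                            n_outlier_lof = 9,
                            n_outlier_missense = 6,
                            n_outlier_novariant = 10,
                            shift_variant = c(2.5, 4),
                            shift_novariant = c(4.5, 6),
                            n_background_variants = 200,
                            modules = list(
                              list(n_genes = 80, loading = 0.8,
                                   trait_cor = 0.5),
                              list(n_genes = 80, loading = 0.8,
                                   trait_cor = 0),
                              list(n_genes = 80, loading = 0.8,
                                   trait_cor = 0)),
                            seed = 1L) {
  spec <- as.list(environment())
  stopifnot(n_genes >= 10, n_cases >= 3,
            n_controls_inhouse + n_controls_external >= 3,
            length(seed) == 1, is.finite(seed),
            all(is.finite(unlist(shift_variant))),
            all(is.finite(unlist(shift_novariant))))
  n_planted <- n_de +
    sum(vapply(modules, `[[`, 0, "n_genes")) +
    n_outlier_lof + n_outlier_missense + n_outlier_novariant
  if (n_planted > 0.45 * n_genes)
    stop("too many planted genes (", n_planted, ") for n_genes = ", n_genes,
         "; planted sets must fit in the mid-abundance band")
  spec$seed <- as.integer(seed)
  class(spec) <- "cohortex_simspec"
  spec
}

#' Generate a synthetic cohort
#'
#' Counts are drawn as
#' \code{NB(mean = lib_s q_g 2^(batch_g b(s)) 2^(lfc_g case(s)),
#' dispersion = phi_g)}; planted co-expression modules are imposed on the
#' log2 scale through \code{\link{inject_module}} and back-transformed to
#' counts; planted outliers shift the target sample's log2 expression by
#' the requested number of within-case SDs and are likewise rounded back
#' to counts, so the planted shift is directly interpretable in the
#' outlier caller's Z units.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return list with \code{counts} (gene x sample matrix), \code{samples}
#'   (sample table), \code{variants} (variant table), and \code{truth}
#'   (GroundTruth: \code{de}, \code{outliers}, \code{modules},
#'   \code{batch}, \code{warnings}).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "cohortex_simspec"))
  with_seed(spec$seed, {
    n_ctrl <- spec$n_controls_inhouse + spec$n_controls_external
    n <- spec$n_cases + n_ctrl
    genes <- sprintf("G%04d", seq_len(spec$n_genes))
    samples_id <- c(sprintf("case_%03d", seq_len(spec$n_cases)),
                    sprintf("ctrl_ih_%03d", seq_len(spec$n_controls_inhouse)),
                    sprintf("ctrl_ex_%03d", seq_len(spec$n_controls_external)))
    group <- c(rep("case", spec$n_cases), rep("control", n_ctrl))
    batch <- c(rep("b1", spec$n_cases + spec$n_controls_inhouse),
               rep("b2", spec$n_controls_external))
    samples <- data.frame(
      sample_id = samples_id, group = group,
      age = round(ifelse(group == "case", runif(n, 2, 20),
                         runif(n, 18, 60)), 1),
      sex = sample(c("M", "F"), n, replace = TRUE),
      batch = batch,
      gestation_weeks = ifelse(group == "case",
                               round(runif(n, 26, 41), 1), NA),
      comorbidity = group == "case" & runif(n) < 0.3,
      risk_factor = group == "case" & runif(n) < 0.5,
      stringsAsFactors = FALSE)

    # baseline abundance (log2 CPM scale) and NB dispersion
    level <- rnorm(spec$n_genes, spec$baseline_meanlog2, spec$baseline_sdlog2)
    rel <- 2^level / sum(2^level)
    phi <- if (is.finite(spec$dispersion_meanlog))
      rlnorm(spec$n_genes, spec$dispersion_meanlog, spec$dispersion_sdlog)
    else rep(0, spec$n_genes)
    sdlog_lib <- sqrt(log(1 + spec$libsize_cv^2))
    lib <- rlnorm(n, log(spec$libsize_mean) - sdlog_lib^2 / 2, sdlog_lib)

    # partition the mid-abundance band into disjoint planted sets
    mid <- which(level > quantile(level, 0.25) &
                   level < quantile(level, 0.75))
    mid <- sample(mid)
    take <- function(k) {
      if (k > length(mid)) stop("not enough mid-abundance genes to plant")
      out <- mid[seq_len(k)]
      if (k > 0) mid <<- mid[-seq_len(k)]
      out
    }
    de_idx <- take(spec$n_de)
    de_lfc <- rep_len(c(spec$de_lfc, -spec$de_lfc), spec$n_de)
    mod_idx <- lapply(spec$modules, function(m) take(m$n_genes))
    n_out <- spec$n_outlier_lof + spec$n_outlier_missense +
      spec$n_outlier_novariant
    out_idx <- take(n_out)

    # mean model and NB draw
    is_case <- group == "case"
    b2 <- batch == "b2"
    batch_shift <- rnorm(spec$n_genes, 0, spec$batch_shift_sd)
    scale_fac <- exp(rnorm(spec$n_genes, 0, spec$batch_scale_sd))
    lfc_vec <- numeric(spec$n_genes)
    lfc_vec[de_idx] <- de_lfc
    log2mu <- outer(log2(rel), log2(lib), `+`) +
      outer(lfc_vec, as.numeric(is_case)) +
      outer(batch_shift, as.numeric(b2))
    mu <- 2^log2mu
    counts <- matrix(0L, spec$n_genes, n, dimnames = list(genes, samples_id))
    for (s in seq_len(n)) {
      ph <- phi * if (b2[s]) scale_fac^2 else 1
      counts[, s] <- ifelse(ph > 0,
                            rnbinom(spec$n_genes, mu = mu[, s],
                                    size = 1 / pmax(ph, 1e-12)),
                            rpois(spec$n_genes, mu[, s]))
    }

    warnings <- character()

    # planted modules: impose latent factors on the log2 scale
    trait <- as.numeric(is_case)
    trait_std <- (trait - mean(trait)) / sd(trait)
    y <- log2(counts + 1)
    mod_truth <- list()
    for (i in seq_along(spec$modules)) {
      m <- spec$modules[[i]]
      rho <- m$trait_cor
      f <- rho * trait_std + sqrt(max(0, 1 - rho^2)) * rnorm(n)
      jit <- if (is.null(m$loading_jitter)) 0.15 else m$loading_jitter
      inj <- inject_module(y, genes[mod_idx[[i]]], m$loading, factor = f,
                           loading_jitter = jit)
      y <- inj$expr
      mod_truth[[i]] <- list(genes = genes[mod_idx[[i]]],
                             loading = m$loading, trait_cor = rho,
                             loadings = inj$loadings, factor = inj$factor)
      if (length(intersect(mod_idx[[i]], de_idx)))
        warnings <- c(warnings, sprintf(
          "module %d overlaps planted DE genes", i))
    }
    if (length(spec$modules)) {
      newc <- pmax(round(2^y - 1), 0)
      touched <- unlist(mod_idx)
      counts[touched, ] <- newc[touched, ]
    }

    # planted outliers on case samples: one sample, one gene each
    out_samples <- sample(which(is_case), n_out)
    shift_mag <- c(
      runif(spec$n_outlier_lof, spec$shift_variant[1], spec$shift_variant[2]),
      runif(spec$n_outlier_missense, spec$shift_variant[1],
            spec$shift_variant[2]),
      runif(spec$n_outlier_novariant, spec$shift_novariant[1],
            spec$shift_novariant[2]))
    shift <- shift_mag * rep_len(c(1, -1), n_out)
    vclass <- c(sample(.lof_classes, spec$n_outlier_lof, replace = TRUE),
                rep("missense", spec$n_outlier_missense),
                rep(NA_character_, spec$n_outlier_novariant))
    cpm_now <- t(t(counts) / colSums(counts)) * 1e6
    ycpm <- log2(cpm_now + 1)
    out_rows <- data.frame(sample_id = samples_id[out_samples],
                           gene = genes[out_idx], shift = shift,
                           has_variant = !is.na(vclass),
                           variant_class = vclass,
                           stringsAsFactors = FALSE)
    for (j in seq_len(n_out)) {
      g <- out_idx[j]; s <- out_samples[j]
      base_cpm <- cpm_now[g, is_case]
      if (median(base_cpm) < 1)
        stop("planted outlier requested on a near-zero gene: ", genes[g])
      mu_g <- mean(ycpm[g, is_case]); sd_g <- sd(ycpm[g, is_case])
      target <- mu_g + shift[j] * sd_g
      counts[g, s] <- max(round((2^target - 1) * colSums(counts)[s] / 1e6), 0)
    }

    # variant table: rows for variant-supported outliers plus benign noise
    v_out <- out_rows[out_rows$has_variant, , drop = FALSE]
    variants <- data.frame(
      sample_id = v_out$sample_id, gene = v_out$gene,
      variant_class = v_out$variant_class,
      zygosity = rep("het", nrow(v_out)), stringsAsFactors = FALSE)
    if (spec$n_background_variants > 0) {
      bg <- data.frame(
        sample_id = sample(samples_id[is_case], spec$n_background_variants,
                           replace = TRUE),
        gene = sample(genes, spec$n_background_variants, replace = TRUE),
        variant_class = sample(c("missense", "other", "splice"),
                               spec$n_background_variants, replace = TRUE),
        zygosity = sample(c("het", "hom"), spec$n_background_variants,
                          replace = TRUE, prob = c(0.9, 0.1)),
        stringsAsFactors = FALSE)
      # never let background variants land on planted outlier pairs
      clash <- paste(bg$sample_id, bg$gene) %in%
        paste(out_rows$sample_id, out_rows$gene)
      variants <- rbind(variants, bg[!clash, , drop = FALSE])
    }
    variants <- validate_variants(variants)

    truth <- list(
      de = data.frame(gene = genes[de_idx], lfc = de_lfc,
                      stringsAsFactors = FALSE),
      outliers = out_rows,
      modules = mod_truth,
      batch = data.frame(gene = genes, shift_b2 = batch_shift,
                         scale_b2 = scale_fac, stringsAsFactors = FALSE),
      dispersion = data.frame(gene = genes, phi = phi,
                              stringsAsFactors = FALSE),
      warnings = warnings,
      seed = spec$seed)

    list(counts = count_matrix(counts),
         samples = validate_samples(samples, counts),
         variants = variants,
         truth = truth)
  })
}

#' Impose a latent co-expression factor on a set of genes
#'
#' Each member gene's (log-scale) profile is rewritten as
#' \code{mean_g + sd_g (loading * f + sqrt(1 - loading^2) * z_g)} where
#' \code{z_g} is the gene's own standardised residual profile and \code{f}
#' the shared factor, so the expected pairwise correlation among members
#' is \code{loading^2} and gene-level means and SDs are preserved.
#'
#' Co-expression modules in real data have hub structure: members differ
#' in how strongly they follow the shared factor. \code{loading} may
#' therefore be a per-gene vector, or \code{loading_jitter} can spread a
#' scalar loading uniformly by up to that amount around its value.
#'
#' @param expr numeric matrix (genes x samples) on a log scale.
#' @param gene_set member gene identifiers (at least 2, all in expr).
#' @param loading factor loading in (0, 1]; scalar or one per member
#'   gene.
#' @param factor optional length-\code{ncol(expr)} factor values; drawn
#'   standard normal if \code{NULL}.
#' @param loading_jitter half-width of uniform per-gene jitter applied
#'   to a scalar \code{loading} (default 0, i.e. a common loading).
#' @return list with the modified \code{expr}, the \code{factor} used,
#'   and the per-gene \code{loadings}.
#' @export
inject_module <- function(expr, gene_set, loading, factor = NULL,
                          loading_jitter = 0) {
  stopifnot(is.matrix(expr), all(loading > 0), all(loading <= 1))
  if (length(gene_set) < 2) stop("gene_set must contain at least 2 genes")
  missing_g <- setdiff(gene_set, rownames(expr))
  if (length(missing_g))
    stop("gene_set not in matrix: ", paste(head(missing_g, 3), collapse = ", "))
  n <- ncol(expr)
  if (is.null(factor)) factor <- rnorm(n)
  f <- (factor - mean(factor)) / sd(factor)
  if (length(loading) == 1 && loading_jitter > 0)
    loading <- pmin(0.99, pmax(0.05,
      loading + runif(length(gene_set), -loading_jitter, loading_jitter)))
  loading <- rep_len(loading, length(gene_set))
  sub <- expr[gene_set, , drop = FALSE]
  mu <- rowMeans(sub)
  sdev <- apply(sub, 1, sd)
  z <- (sub - mu) / ifelse(sdev > 0, sdev, 1)
  mixed <- loading * matrix(f, nrow(sub), n, byrow = TRUE) +
    sqrt(1 - loading^2) * z
  expr[gene_set, ] <- mu + sdev * mixed
  list(expr = expr, factor = f, loadings = setNames(loading, gene_set))
}
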