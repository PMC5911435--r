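# Pipeline orchestration: preprocess -> outliers -> differential
# expression -> enrichment -> network -> preservation, with per-stage
# result tables and a machine-readable summary.

#' Preprocess a count matrix
#'
#' CPM normalisation (library size = total column sum before any
#' filtering), robust-expression filter, log2 transform and
#' empirical-Bayes batch adjustment protecting sex. The default order is
#' log2 then batch adjustment; \code{config$paper_order = TRUE} adjusts
#' un-logged CPM first and log-transforms afterwards (see the methods
#' vignette for the rationale).
#'
#' @param counts count matrix.
#' @param samples sample table.
#' @param config a \code{\link{pipeline_config}}.
#' @return list: \code{expr} (filtered, adjusted log2 matrix),
#'   \code{expr_unadjusted} (filtered log2 CPM, no batch adjustment),
#'   \code{kept_genes}, \code{batch_model}, \code{mds_before},
#'   \code{mds_after}.
#' @export
preprocess_counts <- function(counts, samples, config = pipeline_config()) {
  samples <- validate_samples(samples, counts)
  cpm_mat <- cpm(counts)
  kept <- filter_robust(cpm_mat, min_cpm = config$min_cpm,
                        min_samples = resolve_min_samples(config,
                                                          ncol(counts)))
  cpm_f <- cpm_mat[kept, , drop = FALSE]
  # protect the biological contrast and sex while estimating batch
  # effects; with cases concentrated in one batch, leaving group out
  # would let the adjustment absorb most of the case/control signal
  covars <- samples[, c("group", "sex"), drop = FALSE]
  single_batch <- length(unique(samples$batch)) < 2
  if (config$paper_order) {
    if (single_batch) {
      adj <- cpm_f; model <- NULL
    } else {
      cb <- combat_adjust(cpm_f, samples$batch, covariates = covars)
      adj <- cb$expr; model <- cb$model
      adj[adj < 0] <- 0  # EB adjustment can push low counts below zero
    }
    expr <- log2_transform(adj, config$pseudocount)
    expr_un <- log2_transform(cpm_f, config$pseudocount)
  } else {
    expr_un <- log2_transform(cpm_f, config$pseudocount)
    if (single_batch) {
      expr <- expr_un; model <- NULL
    } else {
      cb <- combat_adjust(expr_un, samples$batch, covariates = covars)
      expr <- cb$expr; model <- cb$model
    }
  }
  # batch check on control samples when both batches hold controls:
  # with every case in one batch, the protected case/control signal
  # would otherwise masquerade as residual batch separation
  ctrl <- samples$group == "control"
  chk <- if (length(unique(samples$batch[ctrl])) >= 2 && sum(ctrl) >= 6)
    ctrl else rep(TRUE, nrow(samples))
  mds_before <- mds_check(expr_un[, chk, drop = FALSE],
                          samples$batch[chk])
  mds_after <- mds_check(expr[, chk, drop = FALSE], samples$batch[chk])
  list(expr = expr, expr_unadjusted = expr_un, kept_genes = kept,
       batch_model = model, mds_before = mds_before,
       mds_after = mds_after)
}

#' Run the full cohort analysis pipeline
#'
#' Executes preprocess, outlier calling with case resolution,
#' dual-analysis differential expression with intersection, gene-list
#' enrichment, co-expression network construction on the control
#' samples with eigengene-trait association, and permutation module
#' preservation of the control modules in the cases. Any stage failure
#' aborts with the stage name; when \code{out_dir} is given, per-stage
#' TSV tables (each carrying the config hash), a Newick export of the
#' gene dendrogram and a JSON summary are written.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param counts count matrix.
#' @param samples sample table.
#' @param variants variant table (may be NULL or empty).
#' @param gene_lists optional named list of gene sets for enrichment.
#' @param out_dir optional output directory.
#' @return list of stage results plus \code{summary} (config, seed,
#'   versions, per-stage counts, determinism checksum).
#' @export
run_pipeline <- function(config, counts, samples, variants = NULL,
                         gene_lists = NULL, out_dir = NULL) {
  validate_config(config)
  samples <- validate_samples(samples, counts)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  pre <- stage("preprocess", preprocess_counts(counts, samples, config))

  out <- stage("outliers", {
    zm <- zscore_matrix(pre$expr, samples, reference = config$z_reference)
    calls <- call_outliers(zm, samples, variants,
                           t_variant = config$z_with_variant,
                           t_novariant = config$z_without_variant)
    res <- resolve_cases(calls, n_cases = sum(samples$group == "case"))
    list(z = zm, calls = calls, resolution = res)
  })

  de <- stage("de", {
    primary <- run_de(pre$expr, samples, mode = "primary")
    secondary <- run_de(pre$expr_unadjusted, samples, mode = "secondary")
    intersection <- intersect_de(primary, secondary,
                                 lfc = config$lfc_threshold,
                                 p1 = config$p_primary,
                                 p2 = config$p_secondary)
    list(primary = primary, secondary = secondary,
         intersection = intersection)
  })

  enrich <- stage("enrich", {
    if (is.null(gene_lists) || !length(gene_lists) ||
        !nrow(de$intersection)) NULL
    else overlap_gene_lists(de$intersection$gene, gene_lists,
                            background = pre$kept_genes)
  })

  ctrl <- samples$sample_id[samples$group == "control"]
  case <- samples$sample_id[samples$group == "case"]
  net <- stage("network", {
    ns <- build_network(pre$expr[, ctrl, drop = FALSE], config)
    trait_assoc <- NULL
    if (length(ns$modules)) {
      # eigengenes for all samples with modules as defined on controls
      eg_all <- vapply(ns$modules, function(g) {
        g <- intersect(g, rownames(pre$expr))
        if (length(g) < 2) return(rep(NA_real_, ncol(pre$expr)))
        module_eigengene(pre$expr[g, , drop = FALSE])$eigengene
      }, numeric(ncol(pre$expr)))
      rownames(eg_all) <- colnames(pre$expr)
      keep_m <- colSums(is.na(eg_all)) == 0
      eg_all <- eg_all[, keep_m, drop = FALSE]
      if (ncol(eg_all))
        trait_assoc <- eigengene_significance(eg_all, samples)
      ns$eigengenes_all <- eg_all
    }
    ns$trait_association <- trait_assoc
    ns
  })

  pres <- stage("preserve", {
    if (!length(net$modules)) NULL
    else preservation_zsummary(
      pre$expr[net$genes, ctrl, drop = FALSE],
      pre$expr[net$genes, case, drop = FALSE],
      net$modules, power = config$soft_power,
      n_perm = config$n_permutations, seed = config$seed)
  })

  summary <- list(
    config = unclass(config),
    config_hash = attr(config, "hash"),
    seed = config$seed,
    versions = list(R = as.character(getRversion()),
                    cohortex = as.character(packageVersion("cohortex"))),
    stages = list(
      preprocess = list(
        status = "complete",
        n_genes_in = nrow(counts), n_genes_kept = length(pre$kept_genes),
        n_samples = ncol(counts),
        mds_silhouette_before = pre$mds_before$silhouette,
        mds_silhouette_after = pre$mds_after$silhouette),
      outliers = list(
        status = "complete",
        n_calls = nrow(out$calls),
        n_variant_supported = sum(out$calls$tier == "variant_supported"),
        n_resolved = out$resolution$n_resolved,
        resolved_percent = out$resolution$percent),
      de = list(
        status = "complete",
        n_significant_primary = sum(
          de$primary$p_adjusted < config$p_primary &
            abs(de$primary$log2FC) > config$lfc_threshold),
        n_intersection = nrow(de$intersection),
        n_up = sum(de$intersection$direction == "up"),
        n_down = sum(de$intersection$direction == "down")),
      enrich = list(
        status = "complete",
        n_lists = if (is.null(enrich)) 0L else nrow(enrich)),
      network = list(
        status = "complete",
        n_modules = length(net$modules),
        n_grey = sum(net$primary == "grey")),
      preserve = list(
        status = "complete",
        n_modules_tested = if (is.null(pres)) 0L else nrow(pres),
        n_preserved = if (is.null(pres)) 0L
        else sum(pres$Z_summary > config$preservation_z))))
  summary$checksum <- digest::digest(list(
    out$calls, out$resolution$resolved, de$intersection,
    net$primary, pres))

  result <- list(preprocess = pre, outliers = out, de = de,
                 enrich = enrich, network = net, preservation = pres,
                 summary = summary)
  if (!is.null(out_dir)) write_pipeline_outputs(result, config, out_dir)
  result
}

#' Write pipeline result tables
#'
#' One TSV per stage (each prefixed with a config-hash comment line), a
#' Newick export of the gene dendrogram, and \code{summary.json}.
#'
#' @param result value of \code{\link{run_pipeline}}.
#' @param config the config that produced it.
#' @param out_dir output directory (created if absent).
#' @return \code{out_dir}, invisibly.
#' @export
write_pipeline_outputs <- function(result, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- attr(config, "hash")
  wt <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(paste0("# config_hash: ", hash), con)
    close(con)
    suppressWarnings(
      write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                  na = "NA", append = TRUE))
  }
  wt(result$outliers$calls, "outlier_calls.tsv")
  wt(result$outliers$resolution$resolved, "resolved_cases.tsv")
  wt(result$de$primary, "de_primary.tsv")
  wt(result$de$secondary, "de_secondary.tsv")
  wt(result$de$intersection, "de_intersection.tsv")
  if (!is.null(result$enrich)) wt(result$enrich, "overlap_results.tsv")
  net <- result$network
  wt(data.frame(gene = names(net$primary), module = net$primary,
                stringsAsFactors = FALSE), "modules.tsv")
  if (!is.null(net$eigengenes))
    wt(data.frame(sample_id = rownames(net$eigengenes), net$eigengenes,
                  check.names = FALSE), "eigengenes.tsv")
  if (!is.null(net$trait_association))
    wt(net$trait_association, "module_trait.tsv")
  if (!is.null(result$preservation))
    wt(result$preservation, "preservation.tsv")
  if (!is.null(net$tree) && requireNamespace("ape", quietly = TRUE))
    ape::write.tree(ape::as.phylo(net$tree),
                    file.path(out_dir, "gene_dendrogram.nwk"))
  mds <- data.frame(sample_id = rownames(result$preprocess$mds_after$coords),
                    result$preprocess$mds_after$coords)
  wt(mds, "mds_coordinates.tsv")
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
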