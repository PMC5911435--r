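# Variant-stratified expression-outlier analysis.
#
# A gene is an outlier in a sample when its expression lies at least
# z_with_variant SDs from the reference mean and a potentially
# dysregulating variant was detected in that gene in that sample, or at
# least z_without_variant SDs from the mean with no variant. A case is
# "resolved" when at least one of its outlier genes carries a
# loss-of-function variant (deletion, stop-gain or frameshift).

#' Per-gene Z statistic
#'
#' \code{z_gs = (x_gs - mean_g,ref) / sd_g,ref} with the sample SD (n-1).
#' In \code{"within_group"} mode the mean and SD are computed for cases
#' and controls separately and each sample is referenced against its own
#' group; \code{"all_samples"} uses the whole cohort. Genes whose
#' reference SD is zero are flagged degenerate and get Z = 0.
#'
#' @param expr expression matrix (genes x samples), log2 scale.
#' @param samples sample table covering every column of \code{expr}.
#' @param reference \code{"within_group"} or \code{"all_samples"}.
#' @return list with \code{z} (matrix), \code{reference} (per-sample
#'   group used), and \code{degenerate} (per-group list of zero-SD
#'   genes).
#' @export
zscore_matrix <- function(expr, samples,
                          reference = c("within_group", "all_samples")) {
  reference <- match.arg(reference)
  samples <- validate_samples(samples, expr)
  z <- expr * NA_real_
  degenerate <- list()
  groups <- if (reference == "within_group")
    Filter(length, split(seq_len(ncol(expr)), samples$group))
  else list(all_samples = seq_len(ncol(expr)))
  for (gname in names(groups)) {
    idx <- groups[[gname]]
    if (length(idx) < 3)
      stop("reference group '", gname, "' has fewer than 3 samples")
    mu <- rowMeans(expr[, idx, drop = FALSE])
    sdev <- apply(expr[, idx, drop = FALSE], 1, sd)
    deg <- sdev == 0
    degenerate[[gname]] <- rownames(expr)[deg]
    sdev[deg] <- 1
    zg <- (expr[, idx, drop = FALSE] - mu) / sdev
    zg[deg, ] <- 0
    z[, idx] <- zg
  }
  ref_group <- setNames(rep(names(groups), lengths(groups)),
                        colnames(expr)[unlist(groups)])
  list(z = z, reference = ref_group[colnames(expr)],
       degenerate = degenerate)
}

#' Call expression outliers with variant stratification
#'
#' A (sample, gene) pair is called iff |Z| >= \code{t_variant} and a
#' variant of any class exists for that sample and gene, or |Z| >=
#' \code{t_novariant} regardless of variant status. Thresholds are
#' inclusive ("at least k SD"). When both conditions hold the
#' variant-supported tier takes precedence; each pair yields at most one
#' call. By default calls are restricted to case samples.
#'
#' @param zmat result of \code{\link{zscore_matrix}} (or a bare Z matrix).
#' @param samples sample table.
#' @param variants variant table (may be empty).
#' @param t_variant,t_novariant |Z| thresholds (t_variant < t_novariant).
#' @param groups sample groups eligible for calls (default "case").
#' @return data.frame of calls: sample_id, gene, z, direction (up/down),
#'   tier (variant_supported / expression_only), variant_class.
#' @export
call_outliers <- function(zmat, samples, variants,
                          t_variant = 2, t_novariant = 4,
                          groups = "case") {
  if (is.list(zmat) && !is.null(zmat$z)) zmat <- zmat$z
  stopifnot(t_variant < t_novariant, t_variant > 0)
  samples <- validate_samples(samples, zmat)
  keep <- samples$sample_id[samples$group %in% groups]
  z <- zmat[, colnames(zmat) %in% keep, drop = FALSE]

  vkey <- character(0)
  vclass <- character(0)
  if (!is.null(variants) && nrow(variants)) {
    variants <- validate_variants(variants)
    vkey <- paste(variants$sample_id, variants$gene, sep = "\r")
    # one class per pair: keep the first after LoF-first ordering so the
    # reported class is the most consequential one
    ord <- order(match(variants$variant_class,
                       c(.lof_classes,
                         setdiff(.variant_classes, .lof_classes))))
    vv <- variants[ord, ]
    vkey2 <- paste(vv$sample_id, vv$gene, sep = "\r")
    first <- !duplicated(vkey2)
    vclass <- setNames(vv$variant_class[first], vkey2[first])
  }

  hits <- which(abs(z) >= t_variant, arr.ind = TRUE)
  if (!nrow(hits))
    return(data.frame(sample_id = character(), gene = character(),
                      z = numeric(), direction = character(),
                      tier = character(), variant_class = character(),
                      stringsAsFactors = FALSE))
  gene <- rownames(z)[hits[, 1]]
  sample_id <- colnames(z)[hits[, 2]]
  zval <- z[hits]
  key <- paste(sample_id, gene, sep = "\r")
  has_var <- key %in% names(vclass)
  tier <- ifelse(has_var, "variant_supported",
                 ifelse(abs(zval) >= t_novariant, "expression_only", NA))
  keep_call <- !is.na(tier)
  calls <- data.frame(
    sample_id = sample_id[keep_call], gene = gene[keep_call],
    z = zval[keep_call],
    direction = ifelse(zval[keep_call] > 0, "up", "down"),
    tier = tier[keep_call],
    variant_class = ifelse(has_var[keep_call],
                           vclass[key[keep_call]], NA_character_),
    stringsAsFactors = FALSE)
  calls[order(-abs(calls$z)), , drop = FALSE]
}

#' Resolve cases through loss-of-function-supported outliers
#'
#' A case is resolved when it has at least one outlier call whose
#' same-sample, same-gene variant belongs to \code{resolving_classes}
#' (conservatively: deletion, stop-gain, frameshift). Each case counts
#' once however many such calls it has.
#'
#' @param calls outlier calls from \code{\link{call_outliers}}.
#' @param n_cases case-cohort size used for the summary percentage.
#' @param resolving_classes variant classes accepted as resolving.
#' @return list with \code{resolved} (data.frame sample_id, gene,
#'   variant_class, z — one row per resolving call), \code{n_resolved},
#'   \code{n_cases}, and \code{percent} (rounded to the nearest whole
#'   percent, e.g. 9 of 182 gives 5).
#' @export
resolve_cases <- function(calls, n_cases,
                          resolving_classes = c("deletion", "stop_gain",
                                                "frameshift")) {
  stopifnot(n_cases >= 1)
  res <- calls[!is.na(calls$variant_class) &
                 calls$variant_class %in% resolving_classes,
               c("sample_id", "gene", "variant_class", "z"),
               drop = FALSE]
  rownames(res) <- NULL
  n_resolved <- length(unique(res$sample_id))
  list(resolved = res,
       n_resolved = n_resolved,
       n_cases = as.integer(n_cases),
       percent = percent(n_resolved, n_cases))
}
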