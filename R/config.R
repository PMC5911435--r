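#' Pipeline configuration
#'
#' Collects every stage parameter with defaults equal to the values used
#' throughout the workflow: robust-expression filter (CPM > 5 in at least
#' a 120/302 fraction of samples), variant-stratified outlier thresholds
#' (2 SD with a variant, 4 SD without), dual-analysis differential
#' expression thresholds (|log2FC| > 0.5, Bonferroni p < 0.001 primary,
#' p < 0.05 secondary), unsigned network soft power 6, minimum module size
#' 40, eigengene merge height 0.1, kME-based merge parameters
#' (threshPercent 50, mergePercent 25, reassignScale 0.6), kME assignment
#' threshold 0.7, and the preservation bar Z-summary > 10.
#'
#' @param min_cpm robust-expression CPM threshold (strictly greater than).
#' @param min_sample_fraction minimum fraction of samples that must exceed
#'   \code{min_cpm} for a gene to be kept. May instead be given as an
#'   absolute sample count via \code{min_samples}.
#' @param min_samples absolute minimum sample count for the filter;
#'   overrides \code{min_sample_fraction} when not \code{NULL}.
#' @param pseudocount added before the log2 transform.
#' @param paper_order if \code{TRUE}, run the empirical-Bayes batch
#'   adjustment on un-logged CPM and log-transform afterwards; default is
#'   log2 first (see the methods vignette).
#' @param z_with_variant,z_without_variant outlier |Z| thresholds with and
#'   without a same-gene variant.
#' @param z_reference \code{"within_group"} (mean/SD per group) or
#'   \code{"all_samples"}.
#' @param lfc_threshold,p_primary,p_secondary dual-analysis intersection
#'   thresholds.
#' @param soft_power unsigned adjacency exponent.
#' @param min_module_size minimum genes per module.
#' @param merge_height eigengene dissimilarity (1 - cor) below which
#'   modules are merged in the initial pass.
#' @param cut_height static tree-cut height on the TOM dissimilarity scale.
#' @param min_gap minimum height gap for recursive branch splitting.
#' @param thresh_percent,merge_percent,reassign_scale kME-based module
#'   merge parameters.
#' @param kme_threshold strict lower bound on kME for module assignment.
#' @param preservation_z Z-summary above which a module counts as
#'   preserved.
#' @param n_permutations permutations for the preservation null.
#' @param seed integer seed recorded in every output.
#' @return object of class \code{cohortex_config} (a validated list with a
#'   \code{hash} attribute).
#' @export
pipeline_config <- function(min_cpm = 5,
                            min_sample_fraction = 120 / 302,
                            min_samples = NULL,
                            pseudocount = 1,
                            paper_order = FALSE,
                            z_with_variant = 2,
                            z_without_variant = 4,
                            z_reference = c("within_group", "all_samples"),
                            lfc_threshold = 0.5,
                            p_primary = 0.001,
                            p_secondary = 0.05,
                            soft_power = 6,
                            min_module_size = 40,
                            merge_height = 0.1,
                            cut_height = 0.995,
                            min_gap = 0.02,
                            thresh_percent = 50,
                            merge_percent = 25,
                            reassign_scale = 0.6,
                            kme_threshold = 0.7,
                            preservation_z = 10,
                            n_permutations = 100,
                            seed = 1L) {
  z_reference <- match.arg(z_reference)
  cfg <- list(
    min_cpm = min_cpm, min_sample_fraction = min_sample_fraction,
    min_samples = min_samples, pseudocount = pseudocount,
    paper_order = isTRUE(paper_order),
    z_with_variant = z_with_variant,
    z_without_variant = z_without_variant,
    z_reference = z_reference,
    lfc_threshold = lfc_threshold,
    p_primary = p_primary, p_secondary = p_secondary,
    soft_power = soft_power, min_module_size = min_module_size,
    merge_height = merge_height, cut_height = cut_height,
    min_gap = min_gap,
    thresh_percent = thresh_percent, merge_percent = merge_percent,
    reassign_scale = reassign_scale, kme_threshold = kme_threshold,
    preservation_z = preservation_z,
    n_permutations = as.integer(n_permutations),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  attr(cfg, "hash") <- config_hash(cfg)
  class(cfg) <- "cohortex_config"
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg,
                                         call. = FALSE)
  chk(cfg$min_cpm > 0, "min_cpm must be positive")
  chk(cfg$min_sample_fraction > 0 && cfg$min_sample_fraction <= 1,
      "min_sample_fraction must be in (0, 1]")
  chk(is.null(cfg$min_samples) ||
        (cfg$min_samples >= 1 && cfg$min_samples == round(cfg$min_samples)),
      "min_samples must be a positive integer or NULL")
  chk(cfg$pseudocount > 0, "pseudocount must be positive")
  chk(cfg$z_with_variant > 0 && cfg$z_without_variant > 0,
      "z thresholds must be positive")
  chk(cfg$z_with_variant < cfg$z_without_variant,
      "z_with_variant must be below z_without_variant")
  chk(cfg$lfc_threshold > 0, "lfc_threshold must be positive")
  chk(cfg$p_primary > 0 && cfg$p_primary <= 1, "p_primary must be in (0, 1]")
  chk(cfg$p_secondary > 0 && cfg$p_secondary <= 1,
      "p_secondary must be in (0, 1]")
  chk(cfg$soft_power > 0, "soft_power must be positive")
  chk(cfg$min_module_size >= 2, "min_module_size must be at least 2")
  chk(cfg$merge_height > 0 && cfg$merge_height < 1,
      "merge_height must be in (0, 1)")
  chk(cfg$cut_height > 0 && cfg$cut_height <= 1,
      "cut_height must be in (0, 1]")
  chk(cfg$thresh_percent > 0 && cfg$thresh_percent <= 100,
      "thresh_percent must be in (0, 100]")
  chk(cfg$merge_percent > 0 && cfg$merge_percent <= 100,
      "merge_percent must be in (0, 100]")
  chk(cfg$reassign_scale > 0, "reassign_scale must be positive")
  chk(cfg$kme_threshold > 0 && cfg$kme_threshold < 1,
      "kme_threshold must be in (0, 1)")
  chk(cfg$preservation_z > 0, "preservation_z must be positive")
  chk(cfg$n_permutations >= 10, "n_permutations must be at least 10")
  chk(length(cfg$seed) == 1 && !is.na(cfg$seed), "seed is mandatory")
  invisible(TRUE)
}

#' @rdname pipeline_config
#' @param cfg a \code{cohortex_config}.
#' @export
config_hash <- function(cfg) {
  digest::digest(unclass(cfg)[order(names(unclass(cfg)))], algo = "sha256")
}

# resolve the filter's min_samples for a concrete cohort size
resolve_min_samples <- function(cfg, n_samples) {
  if (!is.null(cfg$min_samples)) return(as.integer(cfg$min_samples))
  as.integer(ceiling(cfg$min_sample_fraction * n_samples))
}
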