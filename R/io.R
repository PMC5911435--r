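# Tabular I/O for the pipeline's domain objects.
#
# CountMatrix    : non-negative integer matrix, genes x samples, dimnames
#                  carry the identifiers.
# SampleTable    : data.frame keyed by sample_id with group/age/sex/batch
#                  and optional gestation/comorbidity/risk-factor columns.
# VariantTable   : data.frame of (sample_id, gene, variant_class, zygosity)
#                  with a controlled variant-class vocabulary.
#
# TSV dialect: tab-separated, UTF-8, missing written as "NA" (empty string
# also accepted on read). Gene and sample identifiers are opaque
# case-sensitive strings; no symbol/ID mapping is attempted.

.variant_classes <- c("stop_gain", "frameshift", "deletion", "insertion",
                      "missense", "splice", "cnv", "other")
.lof_classes <- c("deletion", "stop_gain", "frameshift")
.zygosities <- c("het", "hom", "hemi", "compound_het", "unknown")

# aliases seen in variant annotation exports
.variant_aliases <- c(
  "del" = "deletion", "ins" = "insertion",
  "f/shift" = "frameshift", "fshift" = "frameshift",
  "frame_shift" = "frameshift", "stopgain" = "stop_gain",
  "stop-gain" = "stop_gain", "nonsense" = "stop_gain",
  "copy_number" = "cnv", "copy-number" = "cnv", "mis" = "missense"
)

#' Construct and validate a count matrix
#'
#' @param counts non-negative numeric matrix, genes in rows, samples in
#'   columns, with rownames (gene identifiers) and colnames (sample
#'   identifiers).
#' @return the validated matrix (storage mode integer-compatible numeric).
#' @export
count_matrix <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  genes <- rownames(counts)
  samples <- colnames(counts)
  if (is.null(genes) || is.null(samples))
    stop("counts must carry gene rownames and sample colnames")
  if (anyDuplicated(genes))
    stop("duplicate gene identifier: ", genes[duplicated(genes)][1])
  if (anyDuplicated(samples))
    stop("duplicate sample identifier: ", samples[duplicated(samples)][1])
  if (any(!is.finite(counts))) {
    idx <- which(!is.finite(counts), arr.ind = TRUE)[1, ]
    stop("non-numeric count at gene ", genes[idx[1]],
         ", sample ", samples[idx[2]])
  }
  if (any(counts < 0)) {
    idx <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop("negative count at gene ", genes[idx[1]],
         ", sample ", samples[idx[2]])
  }
  counts
}

#' Read a gene-level count matrix
#'
#' TSV layout: first column gene identifiers, header row sample
#' identifiers. MTX layout: MatrixMarket triplet file with `genes.txt` /
#' `samples.txt` sidecars (one identifier per line) next to it.
#'
#' @param path file path (the .mtx file itself for \code{format = "mtx"}).
#' @param format \code{"tsv"} or \code{"mtx"}.
#' @return validated count matrix with file order preserved.
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))),
                   arr.ind = TRUE)
      stop("non-numeric count at row ", bad[1, 1], ", column ", bad[1, 2])
    }
    rownames(m) <- genes
  } else {
    d <- dirname(path)
    gf <- file.path(d, "genes.txt")
    sf <- file.path(d, "samples.txt")
    if (!file.exists(gf) || !file.exists(sf))
      stop("mtx sidecar files genes.txt/samples.txt not found in ", d)
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(gf)
    colnames(m) <- readLines(sf)
  }
  count_matrix(m)
}

#' Write a count matrix
#'
#' @param counts validated count matrix.
#' @param path output path (for \code{"mtx"} the .mtx path; sidecars are
#'   written next to it).
#' @param format \code{"tsv"} or \code{"mtx"}.
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  counts <- count_matrix(counts)
  if (format == "tsv") {
    df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    d <- dirname(path)
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), file.path(d, "genes.txt"))
    writeLines(colnames(counts), file.path(d, "samples.txt"))
  }
  invisible(path)
}

#' Read the per-sample phenotype table
#'
#' Required columns: \code{sample_id}, \code{group} (case/control),
#' \code{age}, \code{sex} (M/F), \code{batch}. Optional:
#' \code{gestation_weeks}, \code{comorbidity}, \code{risk_factor}
#' (logical flags), and any further covariates. Missing values are encoded
#' as "NA" or empty.
#'
#' @param path TSV path.
#' @param counts optional count matrix; if given, every count sample must
#'   appear exactly once in the table (hard error otherwise).
#' @return data.frame with \code{group} as a case/control factor.
#' @export
read_samples <- function(path, counts = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  validate_samples(df, counts)
}

#' @rdname read_samples
#' @param samples a candidate sample table (data.frame).
#' @export
validate_samples <- function(samples, counts = NULL) {
  req <- c("sample_id", "group", "age", "sex", "batch")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols))
    stop("sample table missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample table: ",
         samples$sample_id[duplicated(samples$sample_id)][1])
  if (!all(samples$group %in% c("case", "control")))
    stop("group must be 'case' or 'control'")
  samples$group <- factor(samples$group, levels = c("control", "case"))
  if (!all(samples$sex %in% c("M", "F", NA)))
    stop("sex must be 'M' or 'F'")
  for (fl in c("comorbidity", "risk_factor"))
    if (fl %in% names(samples)) samples[[fl]] <- as.logical(samples[[fl]])
  if (!is.null(counts)) {
    absent <- setdiff(colnames(counts), samples$sample_id)
    if (length(absent))
      stop("samples in counts missing from sample table: ",
           paste(head(absent, 5), collapse = ", "))
    samples <- samples[match(colnames(counts), samples$sample_id), ,
                       drop = FALSE]
    rownames(samples) <- NULL
  }
  samples
}

#' Read the per-sample variant table
#'
#' Required columns: \code{sample_id}, \code{gene}, \code{variant_class},
#' \code{zygosity}. Class labels are normalised through an alias map (e.g.
#' "del" to "deletion", "f/shift" to "frameshift"); classes outside the
#' controlled vocabulary are mapped to \code{"other"} with a warning.
#' Duplicate (sample, gene, class) rows are dropped with a warning.
#'
#' @param path TSV path.
#' @return validated variant data.frame.
#' @export
read_variants <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  validate_variants(df)
}

#' @rdname read_variants
#' @param variants candidate variant table (data.frame).
#' @export
validate_variants <- function(variants) {
  req <- c("sample_id", "gene", "variant_class", "zygosity")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols))
    stop("variant table missing columns: ",
         paste(missing_cols, collapse = ", "))
  cls <- tolower(variants$variant_class)
  ali <- !is.na(.variant_aliases[cls])
  cls[ali] <- .variant_aliases[cls[ali]]
  unknown <- !(cls %in% .variant_classes)
  if (any(unknown)) {
    warning(sum(unknown), " variant row(s) with unknown class (",
            paste(unique(variants$variant_class[unknown]), collapse = ", "),
            ") mapped to 'other'")
    cls[unknown] <- "other"
  }
  variants$variant_class <- cls
  variants$zygosity <- ifelse(variants$zygosity %in% .zygosities,
                              variants$zygosity, "unknown")
  key <- paste(variants$sample_id, variants$gene, variants$variant_class,
               sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)),
            " duplicate (sample, gene, class) variant row(s) removed")
    variants <- variants[!duplicated(key), , drop = FALSE]
  }
  rownames(variants) <- NULL
  variants
}

#' Read gene lists
#'
#' Plain-text format: one gene per line, a single set named after the file
#' (without extension). GMT format: one set per line —
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}.
#'
#' @param path file path.
#' @param format \code{"txt"} or \code{"gmt"} (default guessed from the
#'   extension).
#' @return named list of character vectors (unique, order preserved).
#' @export
read_gene_list <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format))
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "txt"
  format <- match.arg(format, c("txt", "gmt"))
  if (format == "txt") {
    genes <- trimws(readLines(path))
    genes <- unique(genes[nzchar(genes)])
    if (!length(genes)) stop("empty gene list: ", path)
    sets <- list(genes)
    names(sets) <- sub("\\.[^.]*$", "", basename(path))
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty gene list: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(fields, function(f) {
      g <- unique(trimws(f[-(1:2)]))
      g[nzchar(g)]
    })
    names(sets) <- vapply(fields, `[[`, "", 1)
    if (any(!lengths(sets)))
      stop("empty gene set in GMT: ",
           paste(names(sets)[!lengths(sets)], collapse = ", "))
  }
  sets
}

# write a result data.frame as TSV with NA encoded as "NA"
write_result_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
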