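# Hypergeometric gene-list overlap with representation factor.

#' Hypergeometric gene-list overlap
#'
#' Both lists are intersected with the background universe before
#' testing (genes outside it are dropped and counted). With N background
#' genes, |A| and |B| list sizes and k = |A intersect B|, the expected
#' overlap is |A||B|/N, the representation factor is k / expected, and
#' the exact tail probabilities are P(X >= k) and P(X <= k) under
#' Hypergeometric(N, |A|, |B|). The headline p value is the
#' over-representation tail unless the representation factor is below 1,
#' in which case the under-representation tail is reported.
#'
#' @param list_a,list_b character vectors of gene identifiers.
#' @param background background universe (e.g. all robustly expressed
#'   genes).
#' @return list: \code{n_background}, \code{size_a}, \code{size_b},
#'   \code{overlap}, \code{expected}, \code{representation_factor},
#'   \code{p_over}, \code{p_under}, \code{p} (headline),
#'   \code{dropped_a}, \code{dropped_b}.
#' @export
hypergeom_overlap <- function(list_a, list_b, background) {
  background <- unique(background)
  N <- length(background)
  if (N < 1) stop("empty background")
  a0 <- unique(list_a); b0 <- unique(list_b)
  a <- intersect(a0, background)
  b <- intersect(b0, background)
  if (!length(a) || !length(b))
    stop("a gene list is empty after intersection with the background")
  k <- length(intersect(a, b))
  nA <- length(a); nB <- length(b)
  expected <- nA * nB / N
  p_over <- phyper(k - 1, nA, N - nA, nB, lower.tail = FALSE)
  p_under <- phyper(k, nA, N - nA, nB, lower.tail = TRUE)
  rf <- k / expected
  list(n_background = N, size_a = nA, size_b = nB, overlap = k,
       expected = expected, representation_factor = rf,
       p_over = p_over, p_under = p_under,
       p = if (rf < 1) p_under else p_over,
       dropped_a = length(a0) - nA, dropped_b = length(b0) - nB)
}

#' Overlap a set of gene lists against one query list
#'
#' Convenience wrapper applying \code{\link{hypergeom_overlap}} of each
#' named list against the same query (e.g. the differentially expressed
#' genes, or a network module) over a common background.
#'
#' @param query character vector (e.g. DE genes).
#' @param gene_lists named list of character vectors.
#' @param background background universe.
#' @return data.frame, one row per list.
#' @export
overlap_gene_lists <- function(query, gene_lists, background) {
  rows <- lapply(names(gene_lists), function(nm) {
    ov <- hypergeom_overlap(query, gene_lists[[nm]], background)
    data.frame(list = nm, size_list = ov$size_b, size_query = ov$size_a,
               overlap = ov$overlap, expected = ov$expected,
               representation_factor = ov$representation_factor,
               p_over = ov$p_over, p_under = ov$p_under, p = ov$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
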