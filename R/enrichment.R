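#' One-sided Fisher exact over-representation p-value
#'
#' Upper-tail hypergeometric probability of drawing at least `k` genes
#' with the term when `n` genes are drawn from a background of `N` genes
#' of which `K` carry the term:
#' `p = sum_{i=k}^{min(K,n)} C(K,i) C(N-K, n-i) / C(N,n)`.
#' Over-representation only (the DAVID-style one-sided Fisher test).
#'
#' @param k genes in the list carrying the term.
#' @param K background genes carrying the term.
#' @param n list size.
#' @param N background size.
#' @param ease apply the conservative EASE adjustment (test `k - 1`
#'   successes instead of `k`); default off.
#' @return the one-sided p-value.
#' @examples
#' fisher_overrep(5, 5, 10, 20)  # C(15,5)/C(20,10) ~ 0.0163
#' @export
fisher_overrep <- function(k, K, n, N, ease = FALSE) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent counts: need 0 <= k <= min(K, n), K <= N, n <= N")
  if (ease) k <- max(k - 1, 0)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term over-representation analysis of a gene list
#'
#' Scores every annotation term against the gene list with the one-sided
#' Fisher exact test, Benjamini-Hochberg-corrects across the tested
#' terms, and flags terms with adjusted p below `q_cut` (default 0.05,
#' the corrected cut-off of the DAVID-style analysis). The background is
#' the full set of mapped genes of the platform; annotation genes
#' outside the background are ignored, terms with no background gene are
#' skipped, and background genes carrying no term still count in `N`.
#'
#' @param gene_list character vector of genes, a subset of `background`.
#' @param background character vector, the gene universe.
#' @param annotation named list, term id -> character vector of genes
#'   (as from [read_gmt()] or [simulate_annotation()]).
#' @param q_cut significance threshold on the adjusted p-value.
#' @param ease use the EASE-adjusted variant of the test (default off).
#' @return data.frame sorted by p-value with columns `term`, `k`, `K`,
#'   `n`, `N`, `odds_ratio`, `p`, `q`, `significant`.
#' @export
enrich <- function(gene_list, background, annotation, q_cut = 0.05,
                   ease = FALSE) {
  background <- unique(as.character(background))
  if (!length(background)) stop("empty background")
  gene_list <- unique(as.character(gene_list))
  stray <- setdiff(gene_list, background)
  if (length(stray))
    stop("gene_list members missing from background: ",
         paste(utils::head(stray, 5), collapse = ", "),
         if (length(stray) > 5) ", ..." else "")
  n <- length(gene_list)
  N <- length(background)
  rows <- list()
  for (tm in names(annotation)) {
    term_genes <- intersect(unique(annotation[[tm]]), background)
    K <- length(term_genes)
    if (K == 0) next
    k <- length(intersect(term_genes, gene_list))
    p <- fisher_overrep(k, K, n, N, ease = ease)
    or <- (k * (N - K - n + k)) / ((K - k) * (n - k))
    rows[[length(rows) + 1L]] <- data.frame(
      term = tm, k = k, K = K, n = n, N = N, odds_ratio = or, p = p,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), odds_ratio = numeric(),
                      p = numeric(), q = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < q_cut
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
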