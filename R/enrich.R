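#' Annotation set: gene-set membership over a background universe
#'
#' @param term_map named list mapping term name to a character vector of gene
#'   symbols.
#' @param universe background gene symbols; defaults to the union of all
#'   annotated genes. Every term must be a subset of the universe.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(term_map, universe = NULL) {
  term_map <- lapply(term_map, function(g) sort(unique(as.character(g))))
  if (is.null(universe)) universe <- sort(unique(unlist(term_map)))
  universe <- sort(unique(as.character(universe)))
  outside <- setdiff(unlist(term_map), universe)
  if (length(outside))
    stop_validation("term gene(s) outside the universe: %s",
                    paste(utils::head(outside, 5), collapse = ", "))
  if (length(universe) < 1L && length(term_map) > 0L)
    stop_argument("annotation universe is empty")
  structure(list(term_map = term_map, universe = universe),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d terms over %d universe genes\n",
              length(x$term_map), length(x$universe)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line — term name, description, then the member
#' gene symbols — tab-separated (whitespace-separated accepted). Duplicate
#' genes within a line are deduplicated; a line with fewer than 3 fields is a
#' format error. The universe defaults to the union of all genes.
#'
#' @param path GMT file.
#' @param universe optional explicit background gene set.
#' @return An [annotation_set()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(annotation_set(list(), universe))
  fields <- lapply(lines, function(l) {
    f <- if (grepl("\t", l)) strsplit(l, "\t", fixed = TRUE)[[1L]]
         else strsplit(trimws(l), "[[:space:]]+")[[1L]]
    f[nzchar(f)]
  })
  short <- vapply(fields, length, 0L) < 3L
  if (any(short))
    stop_format("GMT line %d has fewer than 3 fields", which(short)[1L])
  term_map <- stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                              vapply(fields, `[`, "", 1L))
  annotation_set(term_map, universe)
}

#' Right-tailed hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` annotated genes when drawing `n` from a universe of `N` genes
#' of which `K` are annotated. Identical to the one-sided (right-tail)
#' Fisher exact test on the corresponding 2x2 table. Computed via the
#' numerically stable upper-tail of [stats::phyper()].
#'
#' @param k observed overlap; `K` term size; `n` draw (hit-list) size;
#'   `N` universe size.
#' @param K,n,N see above.
#' @return p in (0, 1].
#' @examples
#' hypergeom_right_tail(2, 3, 4, 10)  # 1/3
#' @export
hypergeom_right_tail <- function(k, K, n, N) {
  if (any(N < 1 | K < 0 | n < 0 | K > N | n > N))
    stop_argument("need 0 <= K <= N, 0 <= n <= N, N >= 1")
  if (any(k < 0 | k > pmin(K, n)))
    stop_argument("need 0 <= k <= min(K, n)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment controlling the expected proportion of false
#' discoveries among rejections, with monotonicity enforcement; output order
#' matches input order.
#'
#' @param p raw p-values, all in (0, 1].
#' @return Adjusted p-values, elementwise >= `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p) | p <= 0 | p > 1))
    stop_argument("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Coverage of a term by the hit list, as a floored integer percentage
#'
#' `floor(100 * k / K)`: the share of a term's genes that are hits.
#'
#' @param k hits annotated to the term; `K` term size (>= 1).
#' @param K see above.
#' @return Integer percent.
#' @examples
#' coverage_percent(2, 7)    # 28
#' coverage_percent(4, 140)  # 2
#' @export
coverage_percent <- function(k, K) {
  if (any(K < 1)) stop_argument("K must be >= 1")
  if (any(k < 0 | k > K)) stop_argument("need 0 <= k <= K")
  as.integer(floor(100 * k / K))
}

#' Term overrepresentation of a hit list
#'
#' For every annotation term of size at least `min_term_size`, tests whether
#' the hit list overlaps the term more than expected under random drawing
#' from the universe (right-tailed hypergeometric / one-sided Fisher test),
#' adjusts over all tested terms by Benjamini-Hochberg, and reports the
#' floored coverage percentage. Hits outside the universe are dropped with a
#' warning. Terms with no hit overlap are tested (they enter the FDR
#' adjustment) but not reported.
#'
#' @param hits character vector of hit gene symbols.
#' @param annotation an [annotation_set()].
#' @param min_term_size smallest term size tested (default 1).
#' @return A data.frame of class `enrichment_table`, sorted by adjusted
#'   p-value: columns `term`, `k`, `K`, `n`, `N`, `coverage_percent`,
#'   `genes`, `p_raw`, `p_adjusted`.
#' @export
enrich_hits <- function(hits, annotation, min_term_size = 1) {
  stopifnot(inherits(annotation, "annotation_set"))
  if (length(annotation$term_map) == 0L) {
    out <- data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(),
                      coverage_percent = integer(), genes = character(),
                      p_raw = numeric(), p_adjusted = numeric(),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("enrichment_table", "data.frame")))
  }
  N <- length(annotation$universe)
  if (N < 1L) stop_argument("annotation universe is empty")
  hits <- unique(as.character(hits))
  outside <- setdiff(hits, annotation$universe)
  if (length(outside)) {
    warning(sprintf("%d hit gene(s) outside the annotation universe dropped: %s",
                    length(outside),
                    paste(utils::head(outside, 5), collapse = ", ")))
    hits <- intersect(hits, annotation$universe)
  }
  n <- length(hits)
  sizes <- vapply(annotation$term_map, length, 0L)
  tested <- annotation$term_map[sizes >= min_term_size]
  if (length(tested) == 0L)
    return(enrich_hits(character(), annotation_set(list()), min_term_size))
  overlap <- lapply(tested, intersect, x = hits)
  k <- vapply(overlap, length, 0L)
  K <- vapply(tested, length, 0L)
  p_raw <- hypergeom_right_tail(k, K, n, N)
  p_adj <- bh_fdr(p_raw)
  keep <- k >= 1L
  out <- data.frame(term = names(tested)[keep],
                    k = k[keep], K = K[keep], n = n, N = N,
                    coverage_percent = coverage_percent(k[keep], K[keep]),
                    genes = vapply(overlap[keep], function(g)
                      paste(sort(g), collapse = ";"), ""),
                    p_raw = unname(p_raw[keep]),
                    p_adjusted = unname(p_adj[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_adjusted, out$p_raw, out$term, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_table", "data.frame"))
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("<enrichment_table> %d enriched term(s)\n", nrow(x)))
  if (nrow(x)) {
    show <- as.data.frame(x)[c("term", "k", "K", "coverage_percent",
                               "p_raw", "p_adjusted")]
    show$p_raw <- signif(show$p_raw, 3)
    show$p_adjusted <- signif(show$p_adjusted, 3)
    print(utils::head(show, 10))
  }
  invisible(x)
}
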