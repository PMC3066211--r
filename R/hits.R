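#' Flag siRNAs whose density z-score marks a viability confound
#'
#' An siRNA whose cell-density robust z is large in magnitude (|z_mb| >= c)
#' changed cell number, so its reporter reading is confounded; such siRNAs
#' are removed from hit candidacy before ranking. Missing `z_mb` is not
#' flagged.
#'
#' @param z_mb numeric vector of summarized density z-scores.
#' @param c threshold in robust-z units (default 2).
#' @return Logical vector of flags.
#' @export
viability_filter <- function(z_mb, c = 2.0) {
  !is.na(z_mb) & abs(z_mb) >= c
}

#' Rank siRNAs and flag top-k membership
#'
#' siRNAs are sorted by decreasing z (reduction-positive, so the strongest
#' reducers come first) with ties broken lexicographically by siRNA
#' identifier, and the first `top_k` are flagged as selected. With fewer
#' scored siRNAs than `top_k` a warning is raised and all are selected.
#'
#' @param sirnas data.frame with columns `sirna_id` and `z` (rows with
#'   missing z are dropped).
#' @param top_k selection size k.
#' @return The data.frame sorted by rank, with added columns `rank` and
#'   `in_top_k`.
#' @export
rank_sirnas <- function(sirnas, top_k = 150) {
  s <- sirnas[!is.na(sirnas$z), , drop = FALSE]
  ord <- order(-s$z, s$sirna_id, method = "radix")
  s <- s[ord, , drop = FALSE]
  s$rank <- seq_len(nrow(s))
  if (nrow(s) < top_k) {
    warning(sprintf("only %d scored siRNAs for top_k = %d; selecting all",
                    nrow(s), top_k))
    s$in_top_k <- TRUE
  } else {
    s$in_top_k <- s$rank <= top_k
  }
  rownames(s) <- NULL
  s
}

#' Gene-level hit calling by siRNA concordance
#'
#' Implements the screen's hit rule: flagged viability confounds are removed,
#' the remaining siRNAs are ranked by decreasing z and the top k selected,
#' and a gene is a hit when at least m of its r siRNAs are among the
#' selected. Requiring concordance across independent siRNA sequences guards
#' against single-siRNA off-target effects; the hit count can never exceed
#' `floor(top_k / m)`.
#'
#' @param sirnas a `scored_screen` (its `$sirnas` table is used) or a
#'   data.frame with columns `sirna_id`, `gene`, `z` and optionally `z_mb`.
#' @param config a [screen_config()].
#' @param apply_viability_filter apply the density-confound filter before
#'   ranking (default `TRUE`; the single-channel density analysis disables
#'   it).
#' @return A data.frame of class `hit_table`, one row per gene, sorted by
#'   decreasing mean z (ties broken by symbol): columns `gene`, `mean_z`,
#'   `n_in_top_k`, `n_scored`, `hit`, `viability_flagged`, `sirna_z`
#'   (comma-joined per-siRNA z) and `sirna_ranks`. Attributes carry `top_k`,
#'   `min_concordant`, `direction`, `n_hits` and `hit_rate_percent`.
#' @examples
#' tab <- data.frame(sirna_id = c("g1_a", "g1_b", "g1_c"),
#'                   gene = "g1", z = c(3, 2.5, 0.1))
#' call_gene_hits(tab, screen_config(top_k = 2))
#' @export
call_gene_hits <- function(sirnas, config = screen_config(),
                           apply_viability_filter = TRUE) {
  if (inherits(sirnas, "scored_screen")) sirnas <- sirnas$sirnas
  need <- c("sirna_id", "gene", "z")
  miss <- setdiff(need, names(sirnas))
  if (length(miss))
    stop_format("siRNA score table lacks column(s): %s",
                paste(miss, collapse = ", "))
  if (is.null(sirnas$z_mb)) sirnas$z_mb <- NA_real_

  flagged <- if (apply_viability_filter)
    viability_filter(sirnas$z_mb, config$viability_z_threshold)
  else rep(FALSE, nrow(sirnas))
  candidates <- sirnas[!flagged, , drop = FALSE]
  ranked <- rank_sirnas(candidates, config$top_k)

  sirnas$rank <- ranked$rank[match(sirnas$sirna_id, ranked$sirna_id)]
  sirnas$in_top_k <- sirnas$sirna_id %in% ranked$sirna_id[ranked$in_top_k]
  sirnas$flagged <- flagged

  genes <- sort(unique(sirnas$gene), method = "radix")
  gi <- match(sirnas$gene, genes)
  scored <- !is.na(sirnas$z)
  n_scored <- tabulate(gi[scored], length(genes))
  n_top <- tabulate(gi[sirnas$in_top_k], length(genes))
  sum_z <- rep(0, length(genes))
  sz <- sirnas[scored, ]
  sum_z <- vapply(split(sz$z, factor(sz$gene, levels = genes)),
                  function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1))
  flag_any <- vapply(split(flagged, factor(sirnas$gene, levels = genes)),
                     any, logical(1))
  per_gene_z <- vapply(split(sirnas, factor(sirnas$gene, levels = genes)),
                       function(d) {
                         d <- d[order(d$sirna_id, method = "radix"), ]
                         paste(sprintf("%.4f", d$z), collapse = ",")
                       }, character(1))
  per_gene_rank <- vapply(split(sirnas, factor(sirnas$gene, levels = genes)),
                          function(d) {
                            d <- d[order(d$sirna_id, method = "radix"), ]
                            paste(ifelse(is.na(d$rank), "NA", d$rank),
                                  collapse = ",")
                          }, character(1))

  r <- config$sirnas_per_gene
  if (any(n_scored != r))
    warning(sprintf("%d gene(s) with a number of scored siRNAs != %d; %s",
                    sum(n_scored != r), r,
                    "concordance applied to the available siRNAs"))

  ht <- data.frame(gene = genes,
                   mean_z = unname(sum_z),
                   n_in_top_k = n_top,
                   n_scored = n_scored,
                   hit = n_top >= config$min_concordant,
                   viability_flagged = unname(flag_any),
                   sirna_z = unname(per_gene_z),
                   sirna_ranks = unname(per_gene_rank),
                   stringsAsFactors = FALSE)
  ht <- ht[order(-ht$mean_z, ht$gene, method = "radix"), , drop = FALSE]
  rownames(ht) <- NULL
  n_hits <- sum(ht$hit)
  structure(ht,
            top_k = config$top_k, min_concordant = config$min_concordant,
            direction = config$direction, n_hits = n_hits,
            hit_rate_percent = hit_rate_percent(n_hits, length(genes)),
            class = c("hit_table", "data.frame"))
}

#' Hit rate as a nearest-integer percentage
#'
#' @param n_hits number of hit genes.
#' @param n_genes number of genes screened.
#' @return Nearest-integer percent (ties rounded up).
#' @examples
#' hit_rate_percent(22, 712)  # 3
#' @export
hit_rate_percent <- function(n_hits, n_genes) {
  if (n_genes < 1) stop_argument("n_genes must be >= 1")
  as.integer(floor(100 * n_hits / n_genes + 0.5))
}

#' Single-channel cell-density hit analysis
#'
#' The same top-k / at-least-m-of-r machinery applied to the density channel
#' alone (reduction-positive density z), identifying genes whose knockdown
#' reduces cell density. No viability filter applies — density is the
#' phenotype here.
#'
#' @param scored a `scored_screen` (its per-siRNA `z_mb` is used) or a
#'   data.frame with `sirna_id`, `gene`, `z_mb`.
#' @param config a [screen_config()].
#' @return A `hit_table` on the density channel.
#' @export
density_hit_analysis <- function(scored, config = screen_config()) {
  tab <- if (inherits(scored, "scored_screen")) scored$sirnas else scored
  if (is.null(tab$z_mb))
    stop_format("density analysis needs a z_mb column")
  tab2 <- data.frame(sirna_id = tab$sirna_id, gene = tab$gene, z = tab$z_mb,
                     stringsAsFactors = FALSE)
  out <- call_gene_hits(tab2, config, apply_viability_filter = FALSE)
  attr(out, "channel") <- "MB"
  out
}

#' @export
print.hit_table <- function(x, ...) {
  cat(sprintf("<hit_table> %d genes, %d hits (top_k = %d, m = %d, rate = %d%%)\n",
              nrow(x), attr(x, "n_hits"), attr(x, "top_k"),
              attr(x, "min_concordant"), attr(x, "hit_rate_percent")))
  print(utils::head(as.data.frame(x)[c("gene", "mean_z", "n_in_top_k",
                                       "hit", "viability_flagged")], 10))
  invisible(x)
}

#' Hit genes of a hit table
#' @param hits a `hit_table`.
#' @return Character vector of hit gene symbols (in table order).
#' @export
hit_genes <- function(hits) hits$gene[hits$hit]
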