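# One-class rank-product calling of constitutively expressed genes from
# replicated intensity arrays, with a pooled within-sample label-permutation
# null for p-values and an estimated percentage of false positives (pfp).

#' Collapse probe rows to gene rows
#'
#' Replaces probe-level rows by one row per gene, the arithmetic mean of the
#' gene's probes in each sample.  Probes absent from the map are dropped.
#'
#' @param matrix Numeric matrix, probes in rows (rownames), samples in
#'   columns.
#' @param probe_map Named character vector mapping probe id to gene id.
#' @return Numeric matrix with one row per gene.
#' @export
collapse_probes <- function(matrix, probe_map) {
  keep <- rownames(matrix) %in% names(probe_map)
  if (!any(keep))
    stop_hb("hb_empty_result", "no probes map to genes")
  m <- matrix[keep, , drop = FALSE]
  gene <- unname(probe_map[rownames(m)])
  collapsed <- rowsum(m, group = gene) / as.vector(table(gene)[sort(unique(gene))])
  collapsed[sort(unique(gene)), , drop = FALSE]
}

# within-column ranks, descending intensity (rank 1 = highest), midranks on ties
.desc_ranks <- function(matrix) {
  apply(matrix, 2L, function(col) rank(-col, ties.method = "average"))
}

#' Rank product of within-array intensity ranks
#'
#' Within each sample genes are ranked by descending intensity (rank 1 =
#' highest, ties get the average rank); a gene's rank product is the
#' geometric mean of its ranks across samples.  Small values flag genes
#' consistently at the top of every array, i.e. constitutively abundant
#' transcripts.
#'
#' @param matrix Numeric matrix, genes in rows (rownames), >= 2 samples in
#'   columns.
#' @return Named numeric vector of rank products, in \[1, n_genes\].
#' @export
rank_product <- function(matrix) {
  if (ncol(matrix) < 2L)
    stop_hb("hb_bad_argument", "rank_product needs >= 2 samples")
  if (any(apply(matrix, 2L, function(col) length(unique(col)) == 1L)))
    warning("constant sample column: all ranks tied at (n+1)/2", call. = FALSE)
  r <- .desc_ranks(matrix)
  rp <- exp(rowMeans(log(r)))
  stats::setNames(as.vector(rp), rownames(matrix))
}

#' Rank-product significance by within-sample label permutation
#'
#' The null distribution is built by independently permuting the gene
#' labels within each sample `n_perm` times and recomputing every rank
#' product; since within-column ranks are a fixed multiset, this amounts to
#' drawing independent random rank assignments per column.  The p-value is
#' the smoothed pooled-null tail probability
#' `p = (1 + #\{null rp <= observed\}) / (1 + n_perm * n_genes)`, and
#' `pfp = p * n_genes / rank(p)` estimates the percentage of false
#' positives at each gene's cut.  A gene is called expressed when its
#' p-value (or, optionally, its pfp) is at most `alpha`.
#'
#' @param matrix Numeric matrix, genes in rows, >= 2 samples in columns.
#' @param n_perm Number of label permutations (>= 1; use >= 100 for real
#'   analyses).
#' @param seed Optional integer seed for the permutation stream.
#' @param alpha Significance threshold (default 0.01).
#' @param call_on Apply the threshold to `"p"` (default) or `"pfp"`.
#' @return Data.frame of class `rp_result` with columns `gene`, `rp`,
#'   `p_value`, `pfp`, `called`, ordered as the input genes.
#' @export
rp_significance <- function(matrix, n_perm = 1000L, seed = NULL,
                            alpha = 0.01, call_on = c("p", "pfp")) {
  call_on <- match.arg(call_on)
  if (!is.numeric(n_perm) || n_perm < 1)
    stop_hb("hb_bad_argument", "n_perm must be >= 1")
  n_perm <- as.integer(n_perm)
  n <- nrow(matrix); k <- ncol(matrix)
  rp_obs <- rank_product(matrix)

  draw_null <- function() {
    # one permutation: each column's ranks are a fresh random assignment
    logr <- matrix(log(replicate(k, sample.int(n))), nrow = n)
    exp(rowMeans(logr))
  }
  null_rp <- if (is.null(seed)) {
    as.vector(replicate(n_perm, draw_null()))
  } else {
    with_seed(seed, as.vector(replicate(n_perm, draw_null())))
  }
  null_sorted <- sort(null_rp)
  cnt <- findInterval(rp_obs, null_sorted)  # #{null <= observed}
  p <- (1 + cnt) / (1 + n_perm * n)
  pfp <- p * n / rank(p, ties.method = "max")
  called <- if (call_on == "p") p <= alpha else pfp <= alpha
  out <- data.frame(gene = names(rp_obs), rp = unname(rp_obs),
                    p_value = p, pfp = pfp, called = called,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_perm") <- n_perm
  attr(out, "alpha") <- alpha
  attr(out, "call_on") <- call_on
  class(out) <- c("rp_result", "data.frame")
  out
}

#' @export
print.rp_result <- function(x, ...) {
  cat(sprintf(
    "Rank-product expression call: %d/%d genes called (%s <= %g, %d permutations)\n",
    sum(x$called), nrow(x), attr(x, "call_on"), attr(x, "alpha"),
    attr(x, "n_perm")))
  print.data.frame(utils::head(x[order(x$p_value), ], 10L), ...)
  invisible(x)
}

#' Genes called expressed across several datasets
#'
#' The screening workflow pools several replicated series; each is called
#' separately and the per-series calls are combined by union (default) or
#' intersection.
#'
#' @param results List of `rp_result` objects.
#' @param combine `"union"` (default) or `"intersection"`.
#' @return Character vector of called gene ids.
#' @export
combine_calls <- function(results, combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  sets <- lapply(results, function(r) r$gene[r$called])
  out <- Reduce(if (combine == "union") union else intersect, sets)
  sort(out)
}
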