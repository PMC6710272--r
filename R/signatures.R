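#' Rank genes by Pearson correlation with an anchor gene
#'
#' Correlates every other gene with the anchor across spheroids and sorts
#' descending.  Zero-variance genes get `NA` correlations and rank last;
#' ties are broken by gene identifier for determinism.
#'
#' @param matrix Expression matrix, genes x spheroids (>= 3 spheroids).
#' @param anchor Anchor gene identifier (must be present, non-constant).
#' @return data.frame with columns `gene` and `r`, ranked.
#' @export
correlate_with_anchor <- function(matrix, anchor) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 3L)
  if (!anchor %in% rownames(matrix))
    stop("anchor gene not found: ", anchor, call. = FALSE)
  a <- matrix[anchor, ]
  if (stats::sd(a) == 0)
    stop("anchor gene has zero variance: ", anchor, call. = FALSE)
  others <- setdiff(rownames(matrix), anchor)
  r <- vapply(others, function(g) {
    x <- matrix[g, ]
    if (stats::sd(x) == 0) NA_real_ else stats::cor(x, a)
  }, 0)
  ord <- order(-r, others, na.last = TRUE)
  data.frame(gene = others[ord], r = unname(r[ord]))
}

#' Construct a gene signature
#'
#' @param name Signature name.
#' @param genes Unique gene identifiers.
#' @param anchor Optional anchor gene; must not be a member of `genes`.
#' @param source One of `"anchor_correlation"`, `"fixed_list"`,
#'   `"deconvolution"`.
#' @return List of class `signature`.
#' @export
gene_signature <- function(name, genes,  anchor = NULL,
                      source = c("fixed_list", "anchor_correlation",
                                 "deconvolution")) {
  source <- match.arg(source)
  if (anyDuplicated(genes))
    stop("signature genes must be unique", call. = FALSE)
  if (!is.null(anchor) && anchor %in% genes)
    stop("anchor gene must not be a member of its own signature",
         call. = FALSE)
  structure(list(name = name, genes = as.character(genes), anchor = anchor,
                 source = source), class = "signature")
}

#' Build a signature from the top anchor-correlated genes
#'
#' The lineage-signature construction used for stem (PROX1-like) and
#' terminally differentiated (TFF3-like) programs: the `top_k` genes most
#' highly correlated with the anchor, anchor excluded.
#'
#' @param matrix Expression matrix, genes x spheroids.
#' @param anchor Anchor gene identifier.
#' @param top_k Number of genes to take (default 20).
#' @return A [gene_signature()] with `source = "anchor_correlation"`.
#' @export
build_anchor_signature <- function(matrix, anchor, top_k = 20L) {
  ranked <- correlate_with_anchor(matrix, anchor)
  defined <- ranked[!is.na(ranked$r), ]
  if (nrow(defined) < top_k)
    stop(sprintf("only %d genes with defined correlation (need %d)",
                 nrow(defined), top_k), call. = FALSE)
  gene_signature(name = paste0(anchor, "_top", top_k),
            genes = defined$gene[seq_len(top_k)], anchor = anchor,
            source = "anchor_correlation")
}

#' Score spheroids for a signature against matched random controls
#'
#' Non-signature ("background") genes are binned into `n_bins` equal-size
#' bins by mean expression across spheroids; each signature gene is mapped
#' to the bin covering its own mean, and `controls_per_gene` control genes
#' are sampled from that bin (with replacement).  The score of a spheroid
#' is the mean expression of the signature genes minus the mean expression
#' of all sampled controls, which cancels technical per-spheroid offsets.
#' Signature genes are excluded from the control pools: a coordinated
#' expression program must not serve as its own background.
#'
#' @param matrix Log-expression matrix, genes x spheroids (at least
#'   `n_bins` genes).
#' @param sig A [gene_signature()]; all member genes must be present.
#' @param n_bins Number of expression bins (default 25).
#' @param controls_per_gene Control genes sampled per signature gene
#'   (default 100).
#' @param seed Integer seed.
#' @return data.frame of class `score_table` with columns `spheroid_id`,
#'   `score`; attributes record the signature name, bins, controls, seed.
#' @export
score_signature <- function(matrix, sig, n_bins = 25L,
                            controls_per_gene = 100L, seed = 1L) {
  stopifnot(is.matrix(matrix), inherits(sig, "signature"),
            nrow(matrix) >= n_bins)
  missing <- setdiff(sig$genes, rownames(matrix))
  if (length(missing))
    stop("signature gene(s) absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  set.seed(check_seed(seed))
  means <- rowMeans(matrix)
  bg <- setdiff(rownames(matrix), sig$genes)
  if (length(bg) < n_bins)
    stop("not enough background genes to build ", n_bins, " bins",
         call. = FALSE)
  ord <- bg[order(means[bg], bg)]             # deterministic tie-break
  bin <- integer(length(bg))
  bin[match(ord, bg)] <- ceiling(seq_along(bg) / (length(bg) / n_bins))
  names(bin) <- bg
  # upper mean boundary of each background bin, for mapping signature genes
  upper <- vapply(seq_len(n_bins),
                  function(b) max(means[names(bin)[bin == b]]), 0)
  controls <- unlist(lapply(sig$genes, function(g) {
    b <- min(findInterval(means[g], upper, left.open = TRUE) + 1L, n_bins)
    sample(names(bin)[bin == b], controls_per_gene, replace = TRUE)
  }), use.names = FALSE)
  sig_mean <- colMeans(matrix[sig$genes, , drop = FALSE])
  ctrl_mean <- colMeans(matrix[controls, , drop = FALSE])
  out <- data.frame(spheroid_id = colnames(matrix),
                    score = unname(sig_mean - ctrl_mean))
  attr(out, "signature") <- sig$name
  attr(out, "n_bins") <- n_bins
  attr(out, "controls_per_gene") <- controls_per_gene
  attr(out, "seed") <- seed
  class(out) <- c("score_table", "data.frame")
  out
}

#' Compare signature scores between two clusters
#'
#' Classic equal-variance unpaired two-tailed Student's t-test on the
#' per-spheroid scores of two phenotype clusters.
#'
#' @param scores A [score_signature()] table (or data.frame with columns
#'   `spheroid_id` and `score`).
#' @param labels Two-level cluster assignment, named by spheroid_id or
#'   aligned with `scores` rows.
#' @return List: `t` (first cluster minus second, in sorted label order),
#'   `df`, `p_value`, `cluster_means`.
#' @export
compare_cluster_scores <- function(scores, labels) {
  if (!is.null(names(labels)))
    labels <- labels[scores$spheroid_id]
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2L)
    stop("labels must define exactly two clusters", call. = FALSE)
  x <- scores$score[labels == lv[1]]
  y <- scores$score[labels == lv[2]]
  if (length(x) < 2L || length(y) < 2L)
    stop("each cluster needs at least 2 members", call. = FALSE)
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2L
  list(t = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df),
       cluster_means = stats::setNames(c(mean(x), mean(y)), lv))
}

#' Reconstruct pseudobulk profiles from single-cell data
#'
#' Emulates pooled spheroid profiles from single cells: per randomization,
#' the cells of each class are shuffled and partitioned into `n_groups`
#' near-equal groups (sizes differ by at most 1), and each group's profile
#' is the per-gene mean of its cells' counts.
#'
#' @param sc_matrix Single-cell count matrix, genes x cells.
#' @param class_labels Per-cell class labels (named by cell or aligned
#'   with columns).
#' @param n_groups Groups per class (default 4).
#' @param n_randomizations Independent partitions (default 4).
#' @param seed Integer seed; reproduces all randomizations.
#' @return List of `n_randomizations` matrices; columns are named
#'   `<class>_<group>_<randomization>`.
#' @export
make_pseudobulk <- function(sc_matrix, class_labels, n_groups = 4L,
                            n_randomizations = 4L, seed = 1L) {
  stopifnot(is.matrix(sc_matrix))
  if (!is.null(names(class_labels)))
    class_labels <- class_labels[colnames(sc_matrix)]
  class_labels <- as.character(class_labels)
  stopifnot(length(class_labels) == ncol(sc_matrix))
  classes <- sort(unique(class_labels))
  for (cl in classes)
    if (sum(class_labels == cl) < n_groups)
      stop(sprintf("class '%s' has fewer cells than groups (%d < %d)",
                   cl, sum(class_labels == cl), n_groups), call. = FALSE)
  set.seed(check_seed(seed))
  lapply(seq_len(n_randomizations), function(r) {
    profiles <- list()
    for (cl in classes) {
      cells <- which(class_labels == cl)
      shuffled <- sample(cells)
      grp <- rep(seq_len(n_groups), length.out = length(shuffled))
      for (g in seq_len(n_groups)) {
        member <- shuffled[grp == g]
        profiles[[sprintf("%s_%d_%d", cl, g, r)]] <-
          rowMeans(sc_matrix[, member, drop = FALSE])
      }
    }
    do.call(cbind, profiles)
  })
}

#' Hypergeometric overlap enrichment against gene sets
#'
#' For each gene set, tests whether its overlap with the query is larger
#' than expected by chance: upper-tail hypergeometric probability
#' `P[X >= overlap]` drawing `|query|` genes from the universe, with the
#' set's universe-restricted members as successes.  P-values are adjusted
#' by Benjamini-Hochberg across the tested sets and results are ranked by
#' `q` then `p`.
#'
#' @param query_genes Character vector; must be a subset of `universe`.
#' @param gene_sets Named list of gene identifier vectors (e.g., from
#'   [read_gmt()]); each set is intersected with the universe before
#'   testing.
#' @param universe Character vector of all considered genes.
#' @return data.frame: `gene_set`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p`, `q`, ranked by significance.
#' @export
overlap_enrichment <- function(query_genes, gene_sets, universe) {
  universe <- unique(as.character(universe))
  query_genes <- unique(as.character(query_genes))
  if (!length(universe) || !length(query_genes))
    stop("universe and query must be non-empty", call. = FALSE)
  if (length(setdiff(query_genes, universe)))
    stop("query genes must be a subset of the universe", call. = FALSE)
  N <- length(universe); n <- length(query_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(set, query_genes))
    p <- stats::phyper(k - 1, length(set), N - length(set), n,
                       lower.tail = FALSE)
    data.frame(gene_set = nm, overlap = k, set_size = length(set),
               query_size = n, universe_size = N, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$q, out$p, out$gene_set), , drop = FALSE]
}
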