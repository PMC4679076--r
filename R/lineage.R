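# Lineage trajectories: the ordered series of per-term PP-scores at every
# node on the path from the tree root down to one extant genome, combining
# the extant count matrix (leaf) with the ancestral matrix (internal
# nodes).

#' Root-to-leaf path of node ids
#'
#' @param phy a validated `phylo`.
#' @param leaf a leaf label.
#' @return character vector of node ids from the root (first) to the leaf
#'   (last), consecutive entries being parent and child.
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' root_to_leaf_path(tr, "A")
#' @export
root_to_leaf_path <- function(phy, leaf) {
  if (!leaf %in% phy$tip.label) stop("unknown leaf: ", sQuote(leaf))
  par <- parent_vector(phy)
  v <- match(leaf, phy$tip.label)
  path <- v
  while (par[v] != 0L) {
    v <- par[v]
    path <- c(v, path)
  }
  node_labels(phy)[path]
}

#' PP-score trajectory of terms along a lineage
#'
#' Scores every term at every node on the root-to-leaf path: internal
#' nodes against the ancestral count matrix, the leaf against the extant
#' matrix. Each node is scored against its own annotatable universe, so a
#' term's trajectory reflects both the changing architecture counts of its
#' member domains and the changing background repertoire.
#'
#' @param terms a `term_set`.
#' @param phy a validated `phylo`.
#' @param extant an `arch_count_matrix` over (at least) the path's leaf.
#' @param ancestral an `arch_count_matrix` over the internal nodes
#'   (typically from [ancestral_count_matrix()]).
#' @param leaf target leaf label.
#' @param cfg a [score_config()]; `fdr_family = "global"` pools the whole
#'   trajectory into one BH family, the default adjusts per node.
#' @return a `data.frame` of class `lineage_trajectory`: the
#'   [score_terms()] columns plus `node_id` (= `genome_id`) and `depth`
#'   (0 at the root).
#' @export
score_lineage <- function(terms, phy, extant, ancestral, leaf,
                          cfg = score_config()) {
  path <- root_to_leaf_path(phy, leaf)
  tabs <- vector("list", length(path))
  for (i in seq_along(path)) {
    node <- path[i]
    m <- if (node %in% colnames(ancestral)) ancestral
         else if (node %in% colnames(extant)) extant
         else stop("node ", sQuote(node), " missing from both count matrices")
    tab <- score_terms(terms, node, m, cfg)
    tab$node_id <- node
    tab$depth <- i - 1L
    tabs[[i]] <- tab
  }
  out <- do.call(rbind, tabs)
  if (cfg$fdr_family == "global") out <- apply_global_fdr(out)
  rownames(out) <- NULL
  class(out) <- c("lineage_trajectory", "data.frame")
  out
}

#' Write a lineage trajectory as TSV
#'
#' Long format, one row per (node, term):
#' `node_id depth term_id pp pp_score p_value fdr status` plus the
#' remaining score columns.
#'
#' @param trajectory output of [score_lineage()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lineage <- function(trajectory, path) {
  lead <- c("node_id", "depth", "term_id", "term_name", "k", "pp",
            "null_mu", "null_sigma", "pp_score", "p_value", "fdr", "status")
  out <- trajectory[, lead, drop = FALSE]
  for (col in c("pp", "null_mu", "null_sigma", "pp_score", "p_value", "fdr")) {
    out[[col]] <- signif(out[[col]], 6)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a term-by-node PP-score heatmap of a trajectory
#'
#' A thin convenience wrapper around [graphics::image()] with a symmetric
#' diverging scale centred at zero; the tested surface of the package is
#' the trajectory table, not this rendering.
#'
#' @param trajectory output of [score_lineage()].
#' @param ... passed to [graphics::image()].
#' @return the score matrix (terms x nodes), invisibly.
#' @export
plot_lineage <- function(trajectory, ...) {
  nodes <- unique(trajectory$node_id[order(trajectory$depth)])
  terms <- unique(trajectory$term_id)
  z <- matrix(NA_real_, length(terms), length(nodes),
              dimnames = list(terms, nodes))
  z[cbind(match(trajectory$term_id, terms),
          match(trajectory$node_id, nodes))] <- trajectory$pp_score
  lim <- max(abs(z), na.rm = TRUE)
  if (!is.finite(lim) || lim == 0) lim <- 1
  cols <- grDevices::hcl.colors(51, "Blue-Red 3")
  graphics::image(x = seq_along(nodes), y = seq_along(terms), z = t(z),
                  zlim = c(-lim, lim), col = cols, xlab = "node (root to leaf)",
                  ylab = "", axes = FALSE, ...)
  graphics::axis(1, at = seq_along(nodes), labels = nodes, las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_along(terms), labels = terms, las = 1, cex.axis = 0.7)
  invisible(z)
}
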