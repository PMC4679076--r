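# Dollo parsimony on a rooted, fully resolved binary species tree.
# Convergent evolution of domain architectures is rare, so each
# architecture is modelled as gained exactly once and lost any number of
# times; under that model the minimum-loss reconstruction places the gain
# at the MRCA of the possessing leaves and marks present every node on a
# path from that MRCA to a possessing leaf. Branch lengths play no role.

#' Parse a rooted binary species tree
#'
#' Reads Newick text (or a file) into an `ape` `phylo` object and
#' validates the structural contract: rooted, fully resolved (every
#' internal node has exactly two children), unique leaf labels.
#' Polytomies are rejected rather than arbitrarily resolved, since an
#' arbitrary resolution would silently change ancestral counts. Unlabeled
#' internal nodes receive deterministic identifiers `N1, N2, ...` in
#' postorder, so outputs are reproducible across runs.
#'
#' @param source Newick string, or path to a Newick file.
#' @return a `phylo` object with all tip and internal node labels set.
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' tr$Nnode  # 3 internal nodes
#' @export
parse_newick <- function(source) {
  txt <- if (length(source) == 1L && !grepl("(", source, fixed = TRUE) &&
             file.exists(source)) {
    paste(readLines(source, warn = FALSE), collapse = "")
  } else {
    paste(source, collapse = "")
  }
  phy <- ape::read.tree(text = txt)
  if (is.null(phy)) stop("could not parse Newick input")
  validate_phylogeny(phy)
}

#' Validate and label a phylogeny
#'
#' @param phy a `phylo` object.
#' @return `phy` with internal node labels filled in.
#' @keywords internal
#' @export
validate_phylogeny <- function(phy) {
  if (!inherits(phy, "phylo")) stop("expected a 'phylo' object")
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf label(s): ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  }
  if (ape::Ntip(phy) < 2L) stop("tree must have at least 2 leaves")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (!ape::is.binary(phy)) {
    stop("not-binary tree: polytomies are rejected, not silently resolved")
  }
  ntip <- ape::Ntip(phy)
  labs <- phy$node.label
  need <- is.null(labs) || any(is.na(labs)) || any(!nzchar(labs)) ||
    anyDuplicated(c(phy$tip.label, labs))
  if (need) {
    po <- postorder_internal(phy)
    labs <- character(phy$Nnode)
    labs[po - ntip] <- paste0("N", seq_along(po))
    phy$node.label <- labs
  }
  phy
}

# internal node numbers in postorder (children before parents,
# left subtree first, following the edge matrix)
postorder_internal <- function(phy) {
  ntip <- ape::Ntip(phy)
  children <- split(phy$edge[, 2L], phy$edge[, 1L])
  out <- integer(0)
  # iterative DFS with explicit visit marks
  stack <- ntip + 1L  # root
  state <- integer(0)
  visited <- logical(ntip + phy$Nnode)
  expanded <- logical(ntip + phy$Nnode)
  while (length(stack)) {
    v <- stack[length(stack)]
    if (!expanded[v]) {
      expanded[v] <- TRUE
      kids <- children[[as.character(v)]]
      kids <- kids[kids > ntip]
      if (length(kids)) stack <- c(stack, rev(kids))
    } else {
      stack <- stack[-length(stack)]
      if (!visited[v]) {
        visited[v] <- TRUE
        out <- c(out, v)
      }
    }
  }
  out
}

# label <-> node-number helpers (tips then internals, ape numbering)
node_labels <- function(phy) c(phy$tip.label, phy$node.label)

node_number <- function(phy, ids) {
  labs <- node_labels(phy)
  idx <- match(ids, labs)
  if (anyNA(idx)) stop("unknown node id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  idx
}

# parent vector indexed by node number; 0 for the root
parent_vector <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  par <- integer(n)
  par[phy$edge[, 2L]] <- phy$edge[, 1L]
  par
}

#' Dollo presence set of an architecture
#'
#' Given the leaves possessing an architecture, returns every node at
#' which the architecture is reconstructed present under single-gain
#' minimum-loss (Dollo) parsimony: the nodes of the minimal spanning
#' subtree connecting the possessing leaves, i.e. the MRCA and every node
#' on a path from the MRCA down to a possessing leaf. An architecture seen
#' in a single leaf is gained at that leaf and present nowhere else.
#'
#' @param phy a validated `phylo` (see [parse_newick()]).
#' @param leaves_with character vector of leaf labels possessing the
#'   architecture (non-empty subset of the tips).
#' @return character vector of present node ids (tips and internal
#'   labels), sorted.
#' @export
dollo_presence <- function(phy, leaves_with) {
  if (length(leaves_with) == 0L) stop("leaves_with must be non-empty")
  leaves_with <- unique(leaves_with)
  unknown <- setdiff(leaves_with, phy$tip.label)
  if (length(unknown)) {
    stop("unknown leaf label(s): ", paste(unknown, collapse = ", "))
  }
  tips <- match(leaves_with, phy$tip.label)
  if (length(tips) == 1L) {
    return(phy$tip.label[tips])
  }
  par <- parent_vector(phy)
  # walk each possessing tip towards the root, marking; the MRCA is the
  # first node reached by all tips, and the union of tip->MRCA paths is
  # the spanning subtree
  n <- length(par)
  hits <- integer(n)
  paths <- vector("list", length(tips))
  for (i in seq_along(tips)) {
    v <- tips[i]
    path <- v
    while (par[v] != 0L) {
      v <- par[v]
      path <- c(path, v)
    }
    paths[[i]] <- path
    hits[path] <- hits[path] + 1L
  }
  k <- length(tips)
  present <- logical(n)
  for (path in paths) {
    shared <- which(hits[path] == k)[1L]  # first ancestor common to all
    present[path[seq_len(shared)]] <- TRUE
  }
  sort(node_labels(phy)[present])
}

#' Dollo gain and loss events of an architecture
#'
#' @param phy a validated `phylo`.
#' @param leaves_with leaf labels possessing the architecture.
#' @return list: `presence` (node ids), `gain` (the MRCA node id), and
#'   `losses` (ids of the roots of maximal absent subtrees below present
#'   nodes).
#' @export
dollo_events <- function(phy, leaves_with) {
  presence <- dollo_presence(phy, leaves_with)
  pres_num <- node_number(phy, presence)
  par <- parent_vector(phy)
  n <- length(par)
  in_s <- logical(n)
  in_s[pres_num] <- TRUE
  gain <- pres_num[which(par[pres_num] == 0L | !in_s[pmax(par[pres_num], 1L)])]
  loss <- which(!in_s & par != 0L & in_s[pmax(par, 1L)])
  labs <- node_labels(phy)
  list(presence = presence, gain = labs[gain], losses = sort(labs[loss]))
}

#' Brute-force Dollo oracle
#'
#' Independent check of [dollo_presence()] for small trees: enumerates
#' every subset of nodes, keeps those that are valid single-gain
#' configurations (leaf states match the observed pattern; the present set
#' is connected with a unique highest node), counts each configuration's
#' losses (absent children of present nodes), and returns the minimum-loss
#' solutions.
#'
#' @param phy a validated `phylo` with at most 8 leaves.
#' @param leaves_with leaf labels possessing the architecture.
#' @return list: `losses` (the minimum), `solutions` (list of presence id
#'   vectors attaining it).
#' @export
brute_force_dollo <- function(phy, leaves_with) {
  ntip <- ape::Ntip(phy)
  if (ntip > 8L) stop("brute-force oracle capped at 8 leaves")
  leaves_with <- unique(leaves_with)
  unknown <- setdiff(leaves_with, phy$tip.label)
  if (length(unknown)) stop("unknown leaf label(s): ", paste(unknown, collapse = ", "))
  if (length(leaves_with) == 0L) stop("leaves_with must be non-empty")
  n <- ntip + phy$Nnode
  par <- parent_vector(phy)
  masks <- 0:(2^n - 1L)
  in_s <- matrix(FALSE, length(masks), n)
  for (v in seq_len(n)) {
    in_s[, v] <- bitwAnd(masks, bitwShiftL(1L, v - 1L)) != 0L
  }
  want <- phy$tip.label %in% leaves_with
  ok <- rep(TRUE, length(masks))
  for (t in seq_len(ntip)) ok <- ok & (in_s[, t] == want[t])
  # unique highest present node (also forces connectivity)
  tops <- integer(length(masks))
  losses <- integer(length(masks))
  for (v in seq_len(n)) {
    parent_in <- if (par[v] == 0L) FALSE else in_s[, par[v]]
    tops <- tops + (in_s[, v] & !parent_in)
    losses <- losses + (!in_s[, v] & parent_in)
  }
  ok <- ok & tops == 1L
  if (!any(ok)) stop("no valid single-gain configuration")  # unreachable
  best <- min(losses[ok])
  sols <- which(ok & losses == best)
  labs <- node_labels(phy)
  list(losses = best,
       solutions = lapply(sols, function(i) sort(labs[in_s[i, ]])))
}

#' Ancestral architecture count matrix
#'
#' Runs the Dollo reconstruction for every distinct architecture observed
#' across the leaf genomes and counts, at each internal node `v`, the
#' number of reconstructed-present architectures containing each
#' superfamily: the ancestral counterpart of
#' [build_arch_count_matrix()]. An architecture confined to a single leaf
#' contributes to no internal node.
#'
#' @param table a `genome_assignments` data frame whose `genome_id` values
#'   are the tree's leaf labels.
#' @param phy a validated `phylo`.
#' @return an `arch_count_matrix` with internal node ids as columns and
#'   attribute `genome_type = "ancestral"`.
#' @export
ancestral_count_matrix <- function(table, phy) {
  missing <- setdiff(phy$tip.label, unique(table$genome_id))
  if (length(missing)) {
    stop("leaf genome(s) without assignments: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(unique(table$genome_id), phy$tip.label)
  if (length(extra)) {
    stop("assignment genome(s) not in the tree: ", paste(extra, collapse = ", "))
  }
  ga <- unique(data.frame(genome_id = table$genome_id,
                          architecture = table$architecture,
                          stringsAsFactors = FALSE))
  archs <- unique(ga$architecture)
  leaves_of <- split(ga$genome_id, ga$architecture)
  internal <- sort(phy$node.label)
  doms_all <- sort(unique(unlist(lapply(archs, arch_domains), use.names = FALSE)))
  m <- matrix(0L, length(doms_all), length(internal),
              dimnames = list(doms_all, internal))
  for (a in archs) {
    present <- dollo_presence(phy, leaves_of[[a]])
    nodes <- intersect(present, internal)
    if (length(nodes) == 0L) next
    d <- arch_domains(a)
    m[d, nodes] <- m[d, nodes] + 1L
  }
  as_arch_count_matrix(m, "ancestral")
}

#' Write per-architecture Dollo events as TSV
#'
#' Columns: `architecture`, `gain_node`, `loss_nodes` (comma-separated).
#'
#' @param table a `genome_assignments` data frame over the tree's leaves.
#' @param phy a validated `phylo`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dollo_events <- function(table, phy, path) {
  ga <- unique(data.frame(genome_id = table$genome_id,
                          architecture = table$architecture,
                          stringsAsFactors = FALSE))
  leaves_of <- split(ga$genome_id, ga$architecture)
  archs <- sort(names(leaves_of))
  rows <- lapply(archs, function(a) {
    ev <- dollo_events(phy, leaves_of[[a]])
    data.frame(architecture = a, gain_node = ev$gain,
               loss_nodes = paste(ev$losses, collapse = ","),
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
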