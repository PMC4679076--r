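# Synthetic data with the statistical structure the method assumes:
# power-law architecture diversity across superfamilies, single-gain /
# multi-loss architecture evolution on a pure-birth tree, and annotation
# terms planted with known high or low plasticity.

#' Simulation configuration
#'
#' @param n_superfamilies number of superfamilies in the root genome.
#' @param zipf_exponent exponent `s > 1` of the discrete power law
#'   (`P(N) ~ N^-s`) that architecture counts per superfamily are drawn
#'   from. Steep exponents (~3) concentrate mass at a single architecture
#'   per superfamily, as seen across extant genomes; shallow exponents
#'   (~1.1-1.5) produce the flatter, more diversified regime.
#' @param max_count support truncation of the power law.
#' @param n_leaves number of leaves of the simulated species tree.
#' @param loss_prob per-branch probability that an architecture present at
#'   the parent is lost, in `[0, 1)`.
#' @param gain_rule where architectures are gained: `"root"` (all present
#'   in the root genome) or `"uniform"` (each gained at a node drawn
#'   uniformly).
#' @param planted_k size of each planted term.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_superfamilies = 1000L, zipf_exponent = 3,
                       max_count = 1000L, n_leaves = 16L, loss_prob = 0.3,
                       gain_rule = c("root", "uniform"), planted_k = 10L,
                       seed = 1L) {
  if (zipf_exponent <= 1) stop("zipf_exponent must be > 1")
  if (loss_prob < 0 || loss_prob >= 1) stop("loss_prob must be in [0, 1)")
  if (planted_k > n_superfamilies) stop("planted_k exceeds n_superfamilies")
  structure(list(n_superfamilies = as.integer(n_superfamilies),
                 zipf_exponent = zipf_exponent,
                 max_count = as.integer(max_count),
                 n_leaves = as.integer(n_leaves),
                 loss_prob = loss_prob,
                 gain_rule = match.arg(gain_rule),
                 planted_k = as.integer(planted_k),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Sample per-superfamily architecture diversity targets
#'
#' Draws one target architecture count per superfamily from a truncated
#' discrete power law (`P(N = x) ~ x^-s`, `x = 1 .. max_count`): most
#' superfamilies occur in a single architecture, a few in many, matching
#' the heavy-tailed diversity profile of real proteomes.
#'
#' @param n number of superfamilies (named `SF00001, ...`).
#' @param exponent power-law exponent, `> 1`.
#' @param max_count support truncation.
#' @return named integer vector of counts.
#' @export
sample_superfamily_diversity <- function(n, exponent = 3, max_count = 1000L) {
  if (exponent <= 1) stop("zipf exponent must be > 1")
  n <- as.integer(n)
  if (n == 0L) return(setNames(integer(0), character(0)))
  support <- seq_len(max_count)
  w <- support^(-exponent)
  counts <- sample(support, n, replace = TRUE, prob = w)
  setNames(as.integer(counts), sprintf("SF%05d", seq_len(n)))
}

#' Realize a genome from target architecture counts
#'
#' For each superfamily `d` with target count `N_d`, emits `N_d` distinct
#' architectures built as tandem repeats of `d` of lengths `1 .. N_d`.
#' Tandem-repeat construction keeps superfamilies from sharing
#' architectures, so the rebuilt count matrix reproduces the targets
#' exactly -- the round-trip oracle for [build_arch_count_matrix()].
#' Combinatorial realism (multi-domain architectures) necessarily trades
#' off against that exact control and is left to the tree simulation.
#'
#' @param counts named non-negative integer vector (superfamily -> target
#'   count). Zero-count superfamilies are omitted from the genome.
#' @param genome_id genome identifier for the emitted rows.
#' @return a `genome_assignments` data frame, one protein per
#'   architecture.
#' @examples
#' build_genome_from_counts(c(A = 3))  # architectures A; A,A; A,A,A
#' @export
build_genome_from_counts <- function(counts, genome_id = "G1") {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  counts <- counts[counts > 0]
  archs <- unlist(lapply(names(counts), function(d) {
    vapply(seq_len(counts[[d]]), function(r) paste(rep(d, r), collapse = ","),
           character(1L))
  }), use.names = FALSE)
  if (length(archs) == 0L) {
    return(as_genome_assignments(data.frame(genome_id = character(0),
                                            protein_id = character(0),
                                            architecture = character(0),
                                            stringsAsFactors = FALSE)))
  }
  as_genome_assignments(data.frame(
    genome_id = genome_id,
    protein_id = sprintf("p%05d", seq_along(archs)),
    architecture = archs,
    stringsAsFactors = FALSE))
}

#' Simulate single-gain / multi-loss architecture evolution on a tree
#'
#' Each architecture is gained at exactly one node (the root, a uniformly
#' drawn node, or a supplied gain node) and, on every branch below the
#' gain, is lost independently with probability `loss_prob`; once lost it
#' never reappears. Leaves inherit the surviving architectures. The true
#' node-by-architecture presence matrix is returned so reconstructions
#' can be checked against the generating history.
#'
#' @param phy a validated `phylo`.
#' @param architectures character vector of canonical architecture
#'   strings.
#' @param loss_prob per-branch loss probability in `[0, 1)`.
#' @param gain `"root"`, `"uniform"`, or a character vector of node ids
#'   (one per architecture).
#' @return list: `tables` (a `genome_assignments` data frame over all
#'   leaves), `presence` (logical matrix architectures x node ids, the
#'   true history), `gain` (named character vector of gain nodes).
#' @export
evolve_architectures_on_tree <- function(phy, architectures, loss_prob = 0.3,
                                         gain = "root") {
  stopifnot(loss_prob >= 0, loss_prob < 1)
  architectures <- unique(architectures)
  na <- length(architectures)
  labs <- node_labels(phy)
  ntip <- ape::Ntip(phy)
  nnode <- length(labs)
  root <- ntip + 1L
  if (identical(gain, "root")) {
    gain_num <- rep(root, na)
  } else if (identical(gain, "uniform")) {
    gain_num <- sample.int(nnode, na, replace = TRUE)
  } else {
    stopifnot(length(gain) == na)
    gain_num <- node_number(phy, gain)
  }
  # preorder edge traversal: parent presence decided before children
  edge <- phy$edge[preorder_edges(phy), , drop = FALSE]
  presence <- matrix(FALSE, na, nnode, dimnames = list(architectures, labs))
  presence[cbind(seq_len(na), gain_num)] <- TRUE
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1L]; child <- edge[e, 2L]
    inherit <- presence[, par]
    if (any(inherit)) {
      survive <- inherit & (stats::runif(na) >= loss_prob)
      presence[, child] <- presence[, child] | survive
    }
  }
  tabs <- lapply(seq_len(ntip), function(t) {
    archs <- architectures[presence[, t]]
    if (length(archs) == 0L) {
      return(data.frame(genome_id = character(0), protein_id = character(0),
                        architecture = character(0), stringsAsFactors = FALSE))
    }
    data.frame(genome_id = phy$tip.label[t],
               protein_id = sprintf("p%05d", seq_along(archs)),
               architecture = archs, stringsAsFactors = FALSE)
  })
  list(tables = as_genome_assignments(do.call(rbind, tabs)),
       presence = presence,
       gain = setNames(labs[gain_num], architectures))
}

# edge row order such that each parent is visited before its children
preorder_edges <- function(phy) {
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    rows <- kids[[as.character(v)]]
    if (is.null(rows)) next
    out <- c(out, rows)
    stack <- c(stack, rev(phy$edge[rows, 2L]))
  }
  out
}

#' Plant an annotation term with a known plasticity direction
#'
#' `direction = "high"` takes the `k` most architecture-diverse domains
#' of the counts map (expected positive PP-score), `"low"` the `k` least
#' diverse among those present (expected negative). Ties break by
#' superfamily id for determinism.
#'
#' @param counts named integer vector of architecture counts (> 0 entries
#'   are eligible).
#' @param direction `"high"` or `"low"`.
#' @param k term size, `1 <= k <=` number of eligible domains.
#' @param term_id identifier for the planted term.
#' @return list: `term_id`, `term_name`, `level`, `members`,
#'   `expected_sign` (+1 or -1).
#' @export
plant_term <- function(counts, direction = c("high", "low"), k,
                       term_id = NULL) {
  direction <- match.arg(direction)
  if (k < 1L) stop("k must be >= 1")
  eligible <- counts[counts > 0]
  if (k > length(eligible)) stop("k exceeds the number of present domains")
  ord <- order(eligible, names(eligible),
               decreasing = (direction == "high"), method = "radix")
  members <- names(eligible)[ord[seq_len(k)]]
  if (is.null(term_id)) term_id <- paste0("PLANT:", toupper(direction))
  list(term_id = term_id,
       term_name = paste("planted", direction, "plasticity term"),
       level = "specific",
       members = members,
       expected_sign = if (direction == "high") 1L else -1L)
}

#' Simulate a complete input dataset
#'
#' End-to-end fixture generator: draws per-superfamily diversity targets
#' from the configured power law, realizes the root genome, simulates a
#' pure-birth (Yule) species tree topology with single-gain / multi-loss
#' architecture evolution, plants one high- and one low-plasticity term
#' (plus one broad background term covering every superfamily, so the
#' annotatable universe spans the genome), and returns the three standard
#' inputs with the generating truth.
#'
#' @param cfg a [sim_config()].
#' @return list: `assignments` (leaf `genome_assignments`), `annotations`
#'   (`term_set`), `tree` (`phylo`), `truth` (list: root `counts`, true
#'   `presence` matrix, `gain` nodes, `planted` data frame of term_id /
#'   direction / expected_sign).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  counts <- sample_superfamily_diversity(cfg$n_superfamilies,
                                         cfg$zipf_exponent, cfg$max_count)
  root_genome <- build_genome_from_counts(counts, genome_id = "ROOT")
  phy <- ape::rphylo(cfg$n_leaves, birth = 1, death = 0)
  phy$tip.label <- sprintf("G%03d", seq_len(cfg$n_leaves))
  phy <- validate_phylogeny(phy)
  evo <- evolve_architectures_on_tree(phy, root_genome$architecture,
                                      loss_prob = cfg$loss_prob,
                                      gain = cfg$gain_rule)
  hi <- plant_term(counts, "high", cfg$planted_k, term_id = "PLANT:HIGH")
  lo <- plant_term(counts, "low", cfg$planted_k, term_id = "PLANT:LOW")
  bg <- list(term_id = "BG:ALL", term_name = "background (all superfamilies)",
             level = "highly-general", members = names(counts))
  annotations <- make_term_set(list(hi, lo, bg))
  planted <- data.frame(term_id = c(hi$term_id, lo$term_id),
                        direction = c("high", "low"),
                        expected_sign = c(hi$expected_sign, lo$expected_sign),
                        stringsAsFactors = FALSE)
  list(assignments = evo$tables, annotations = annotations, tree = phy,
       truth = list(counts = counts, presence = evo$presence,
                    gain = evo$gain, planted = planted))
}
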