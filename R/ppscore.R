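# The core statistic. The plasticity potential (PP) of a domain set in a
# genome is the median architecture count over its member domains. The
# PP-score standardizes the observed PP against a Monte Carlo null built
# by resampling equal-size domain sets from the genome's annotatable
# universe:
#
#   PP_ds(g)  = MED_{d in ds} N_d(g)
#   mu, sigma = mean and (B-1)-denominator SD of B null replicate medians
#   PP-score  = (PP - mu) / sigma
#
# Significance is empirical: the p-value is the fraction of null replicates
# at least as extreme as the observed PP, in the direction of the score.

#' Scoring configuration
#'
#' @param B number of null replicates (default 2000).
#' @param seed integer master seed; per-term streams are derived from
#'   `(seed, term_id, genome_id)` so results do not depend on term
#'   iteration order.
#' @param p_correction `"add-one"` (default) maps a null-exceedance count
#'   `c` to `(1 + c) / (1 + B)`, keeping p in (0, 1] and the FDR step
#'   well-defined; `"raw"` uses the literal fraction `c / B`, which can be
#'   zero at resolution `1/B`.
#' @param fdr_family `"per-genome"` (default) adjusts p-values across the
#'   scored terms of one genome; `"global"` pools all (term, genome) pairs,
#'   e.g. when scoring every node of a tree.
#' @param shared_null reuse one null per `(genome, k)` across terms of
#'   equal effective size instead of one stream per term. A legitimate
#'   optimization; default off.
#' @return a list of class `score_config`.
#' @export
score_config <- function(B = 2000L, seed = 1L,
                         p_correction = c("add-one", "raw"),
                         fdr_family = c("per-genome", "global"),
                         shared_null = FALSE) {
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("B must be an integer >= 1")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  structure(list(B = B, seed = seed,
                 p_correction = match.arg(p_correction),
                 fdr_family = match.arg(fdr_family),
                 shared_null = isTRUE(shared_null)),
            class = "score_config")
}

# Polynomial rolling hash of the concatenated arguments, folded into a
# positive seed below 2^31; used to derive independent per-term RNG
# streams. Exact in double arithmetic (31 * h < 2^53).
derive_seed <- function(seed, ...) {
  bytes <- utf8ToInt(paste(c(seed, ...), collapse = "\x1f"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h) + 1L
}

#' Median plasticity potential of a domain set
#'
#' The median of the architecture counts `N_d(g)` over the effective
#' domain set; the median (rather than the mean) keeps the estimate
#' insensitive to the extreme counts of highly plastic superfamilies.
#' Even-sized sets take the midpoint of the two central values.
#'
#' @param domains character vector of superfamily ids (the effective set;
#'   all must be present in the genome).
#' @param genome genome/node id, a column of `m`.
#' @param m an `arch_count_matrix`.
#' @return the median count, or `NA_real_` with a warning if `domains` is
#'   empty (not-scoreable).
#' @examples
#' m <- build_arch_count_matrix(data.frame(
#'   genome_id = "G", protein_id = paste0("p", 1:3),
#'   architecture = c("A", "A,B", "B,A,B")))
#' pp_median(c("A", "B"), "G", m)
#' @export
pp_median <- function(domains, genome, m) {
  if (length(domains) == 0L) {
    warning("empty domain set: not scoreable")
    return(NA_real_)
  }
  counts <- arch_counts(m, genome)
  missing <- setdiff(domains, names(counts))
  if (length(missing)) {
    stop("domain(s) absent from the count matrix: ", paste(missing, collapse = ", "))
  }
  vals <- counts[domains]
  if (any(vals == 0L)) {
    stop("domain(s) with zero architectures in ", genome,
         ": effective sets must be resolved against the genome first")
  }
  median(as.numeric(vals))
}

#' Monte Carlo null for a domain set size
#'
#' Draws `B` domain sets of size `k` uniformly without replacement from
#' the genome's annotatable universe and records the median architecture
#' count of each. Returns the replicate medians together with their mean
#' and standard deviation (sample, `B - 1` denominator). Bit-reproducible
#' under a fixed RNG state.
#'
#' @param k domain set size, `1 <= k <= |universe|`.
#' @param universe an `annotatable_universe`.
#' @param cfg a [score_config()].
#' @return list of class `null_summary`: `mu`, `sigma`, `samples` (length
#'   `B`), `k`.
#' @export
sample_null <- function(k, universe, cfg = score_config()) {
  stopifnot(inherits(universe, "annotatable_universe"))
  n <- length(universe$domains)
  if (k < 1L) stop("k must be >= 1 (empty sets are not scoreable)")
  if (k > n) {
    stop("infeasible null: k = ", k, " exceeds universe size ", n)
  }
  if (k == n) {
    # only one subset exists: every replicate is the universe median
    samples <- rep(median(as.numeric(universe$counts)), cfg$B)
    return(new_null_summary(samples, k))
  }
  samples <- null_pp_medians(as.numeric(universe$counts), as.integer(k), cfg$B)
  new_null_summary(samples, k)
}

new_null_summary <- function(samples, k) {
  structure(list(mu = mean(samples),
                 sigma = if (length(samples) > 1L) stats::sd(samples) else 0,
                 samples = samples,
                 k = as.integer(k)),
            class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf("null_summary: k = %d, B = %d, mu = %.4g, sigma = %.4g\n",
              x$k, length(x$samples), x$mu, x$sigma))
  invisible(x)
}

#' Exact null by exhaustive subset enumeration
#'
#' Enumerates every size-`k` subset of the universe with equal weight and
#' returns the population mean and standard deviation of the subset
#' medians, plus exact tail mass at an observed median. Feasible only for
#' small `choose(|universe|, k)`; intended as an independent oracle for the
#' Monte Carlo null.
#'
#' @param k subset size.
#' @param universe an `annotatable_universe`.
#' @param cap refuse enumeration beyond this many subsets (default 1e6).
#' @return list: `mu`, `sigma` (population, `N` denominator), `medians`
#'   (one per subset), and `tail(pp)` returning
#'   `list(upper = P(M >= pp), lower = P(M <= pp))`.
#' @export
exact_null <- function(k, universe, cap = 1e6) {
  stopifnot(inherits(universe, "annotatable_universe"))
  n <- length(universe$domains)
  if (k < 1L || k > n) stop("k must be in [1, |universe|]")
  n_subsets <- choose(n, k)
  if (n_subsets > cap) {
    stop("exact null refused: choose(", n, ", ", k, ") = ", n_subsets,
         " exceeds enumeration cap ", cap)
  }
  vals <- as.numeric(universe$counts)
  medians <- combn(vals, k, FUN = median)
  mu <- mean(medians)
  sigma <- sqrt(mean((medians - mu)^2))
  list(mu = mu, sigma = sigma, medians = medians,
       tail = function(pp) list(upper = mean(medians >= pp),
                                lower = mean(medians <= pp)))
}

#' Standardized plasticity potential score
#'
#' `(pp - mu) / sigma` against the null summary. Zero means the set forms
#' distinct architectures no more and no less readily than a random
#' equal-size set from the universe; positive/negative scores mean more /
#' fewer distinct architectures than chance.
#'
#' @param pp observed median from [pp_median()].
#' @param null a `null_summary`.
#' @return the score, or `NA_real_` (degenerate null) when `sigma == 0`.
#' @export
pp_score <- function(pp, null) {
  stopifnot(inherits(null, "null_summary"))
  if (null$sigma == 0) return(NA_real_)
  (pp - null$mu) / null$sigma
}

#' Directional empirical p-value
#'
#' For a positive score, the fraction of null replicate medians `>=` the
#' observed median (inclusive); for a negative score, the fraction `<=`.
#' A zero score is assigned p = 1 (maximally conservative). With the
#' default add-one correction the exceedance count `c` maps to
#' `(1 + c) / (1 + B)` so p never reaches exactly zero.
#'
#' @param pp observed median.
#' @param null a `null_summary` holding the same `B` replicates used for
#'   `mu`/`sigma`.
#' @param score the PP-score (its sign selects the tail). `NA` or 0 gives
#'   p = 1.
#' @param p_correction `"add-one"` or `"raw"`.
#' @return p-value in (0, 1] (add-one) or [0, 1] (raw).
#' @export
empirical_pvalue <- function(pp, null, score,
                             p_correction = c("add-one", "raw")) {
  stopifnot(inherits(null, "null_summary"))
  p_correction <- match.arg(p_correction)
  if (is.na(score) || score == 0) return(1)
  count <- if (score > 0) sum(null$samples >= pp) else sum(null$samples <= pp)
  B <- length(null$samples)
  if (p_correction == "add-one") (1 + count) / (1 + B) else count / B
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Standard BH step-up: order the m p-values ascending, set
#' `q_(i) = min_{j >= i} p_(j) * m / j`, and restore the original order.
#' Delegates to [stats::p.adjust()] after validating the domain.
#'
#' @param p numeric vector of p-values in [0, 1]; `NA`s propagate.
#' @return adjusted values (q-values), same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) stop("p-values outside [0, 1]: ", paste(p[bad], collapse = ", "))
  p.adjust(p, method = "BH")
}

#' Score every term of an annotation set in one genome
#'
#' The full per-genome pipeline: resolve each term's effective domain set
#' against the genome's annotatable universe, compute the observed median
#' (PP), draw the Monte Carlo null, standardize (PP-score), attach the
#' directional empirical p-value, and adjust across the genome's scored
#' terms by BH-FDR. Terms whose effective set is empty are reported with
#' status `not-scoreable`; terms whose null is degenerate (zero null SD,
#' e.g. the effective set is the whole universe) with status
#' `degenerate-null`.
#'
#' Each term draws from its own RNG stream derived from
#' `(seed, term_id, genome_id)`, so the table is invariant to term order
#' and byte-identical across runs with the same configuration.
#'
#' @param terms a `term_set` from [parse_annotations()].
#' @param genome genome/node id, a column of `m`.
#' @param m an `arch_count_matrix`.
#' @param cfg a [score_config()].
#' @param universe optionally a precomputed [annotatable_universe()] for
#'   `genome` (computed from `terms` otherwise).
#' @return a `data.frame` with one row per term: `term_id`, `term_name`,
#'   `genome_id`, `k`, `pp`, `null_mu`, `null_sigma`, `pp_score`,
#'   `p_value`, `fdr`, `status`.
#' @export
score_terms <- function(terms, genome, m, cfg = score_config(),
                        universe = NULL) {
  stopifnot(inherits(cfg, "score_config"))
  if (is.null(universe)) {
    universe <- annotatable_universe(genome, m, terms)
  }
  ids <- unique(terms$term_id)
  names_of <- terms$term_name[match(ids, terms$term_id)]
  n <- length(ids)
  res <- data.frame(
    term_id = ids, term_name = names_of, genome_id = rep(genome, n),
    k = integer(n), pp = rep(NA_real_, n),
    null_mu = rep(NA_real_, n), null_sigma = rep(NA_real_, n),
    pp_score = rep(NA_real_, n), p_value = rep(NA_real_, n),
    fdr = rep(NA_real_, n), status = rep("not-scoreable", n),
    stringsAsFactors = FALSE)
  null_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    eff <- resolve_domain_set(term_members(terms, ids[i]), universe)
    res$k[i] <- eff$k
    if (eff$k == 0L) next
    res$pp[i] <- pp_median(eff$domains, genome, m)
    if (cfg$shared_null) {
      key <- as.character(eff$k)
      if (is.null(null_cache[[key]])) {
        set.seed(derive_seed(cfg$seed, "k", eff$k, genome))
        null_cache[[key]] <- sample_null(eff$k, universe, cfg)
      }
      null <- null_cache[[key]]
    } else {
      set.seed(derive_seed(cfg$seed, ids[i], genome))
      null <- sample_null(eff$k, universe, cfg)
    }
    res$null_mu[i] <- null$mu
    res$null_sigma[i] <- null$sigma
    if (null$sigma == 0) {
      res$status[i] <- "degenerate-null"
      next
    }
    res$pp_score[i] <- pp_score(res$pp[i], null)
    res$p_value[i] <- empirical_pvalue(res$pp[i], null, res$pp_score[i],
                                       p_correction = cfg$p_correction)
    res$status[i] <- "scored"
  }
  scored <- res$status == "scored"
  if (!any(scored)) {
    warning("no scoreable terms in genome ", genome)
  }
  if (cfg$fdr_family == "per-genome") {
    res$fdr[scored] <- bh_fdr(res$p_value[scored])
  }
  # fdr_family == "global": left NA here; apply_global_fdr() pools tables
  res
}

#' Pool several score tables into one global FDR family
#'
#' Recomputes the BH adjustment over the scored rows of all tables at
#' once, e.g. across every node of a tree.
#'
#' @param results a `data.frame` of stacked [score_terms()] outputs.
#' @return `results` with `fdr` recomputed over all scored rows.
#' @export
apply_global_fdr <- function(results) {
  scored <- results$status == "scored"
  results$fdr[scored] <- bh_fdr(results$p_value[scored])
  results
}

#' Write a score table as TSV
#'
#' Tab-separated with one header row; floating point columns at 6
#' significant digits.
#'
#' @param results output of [score_terms()] (or stacked outputs).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pp_results <- function(results, path) {
  out <- results
  for (col in c("pp", "null_mu", "null_sigma", "pp_score", "p_value", "fdr")) {
    if (col %in% names(out)) out[[col]] <- signif(out[[col]], 6)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
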