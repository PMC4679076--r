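# Domain-centric ontology annotations (dcGO-style): terms annotate sets of
# superfamilies at one of four specificity levels. A term is scored through
# its "domain set" -- the superfamilies it annotates -- restricted to the
# annotatable universe of the genome under study.

TERM_LEVELS <- c("highly-general", "general", "specific", "highly-specific")

#' Parse a domain-centric annotation table
#'
#' Reads a TSV with header `term_id`, `term_name`, `level`,
#' `superfamily_id`, one row per (term, superfamily) annotation. The level
#' vocabulary is closed: `highly-general`, `general`, `specific`,
#' `highly-specific`. The file is taken as already propagated along the
#' ontology graph; no true-path propagation is performed here.
#'
#' @param path path to the TSV file, or a connection.
#' @return a `data.frame` of class `term_set` with one row per
#'   (term, superfamily) pair; duplicated member rows are dropped.
#' @export
parse_annotations <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character", check.names = FALSE,
                   stringsAsFactors = FALSE)
  required <- c("term_id", "term_name", "level", "superfamily_id")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("annotation table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[required]
  bad <- setdiff(unique(df$level), TERM_LEVELS)
  if (length(bad)) {
    stop("unknown specificity level(s): ", paste(sQuote(bad), collapse = ", "),
         "; expected one of: ", paste(TERM_LEVELS, collapse = ", "))
  }
  df <- unique(df)
  rownames(df) <- NULL
  class(df) <- c("term_set", "data.frame")
  df
}

# build a term_set from term descriptors given as a list of
# list(term_id, term_name, level, members)
make_term_set <- function(terms) {
  rows <- lapply(terms, function(t) {
    data.frame(term_id = t$term_id,
               term_name = if (is.null(t$term_name)) t$term_id else t$term_name,
               level = if (is.null(t$level)) "specific" else t$level,
               superfamily_id = t$members,
               stringsAsFactors = FALSE)
  })
  df <- unique(do.call(rbind, rows))
  bad <- setdiff(unique(df$level), TERM_LEVELS)
  if (length(bad)) stop("unknown specificity level(s): ", paste(bad, collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("term_set", "data.frame")
  df
}

# member superfamilies of one term
term_members <- function(terms, term_id) {
  unique(terms$superfamily_id[terms$term_id == term_id])
}

#' The annotatable domain universe of a genome
#'
#' The randomization null samples domain sets from the domains that are
#' both present in the genome (architecture count > 0) and annotated by at
#' least one term. Restricting the universe this way keeps the observed set
#' and the null sets on the same support. Annotations from all namespaces
#' and levels are pooled by default; `levels` restricts the pool.
#'
#' @param genome genome (or ancestral node) identifier, a column of `m`.
#' @param m an `arch_count_matrix`.
#' @param terms a `term_set` from [parse_annotations()].
#' @param levels optional subset of specificity levels to draw the
#'   annotated pool from.
#' @return an object of class `annotatable_universe`: list with
#'   `genome_id`, `domains` (sorted superfamily ids) and `counts` (named
#'   integer vector of architecture counts over `domains`).
#' @export
annotatable_universe <- function(genome, m, terms, levels = NULL) {
  counts <- arch_counts(m, genome)
  ann <- terms
  if (!is.null(levels)) {
    stopifnot(all(levels %in% TERM_LEVELS))
    ann <- ann[ann$level %in% levels, , drop = FALSE]
  }
  annotated <- unique(ann$superfamily_id)
  domains <- sort(intersect(names(counts)[counts > 0L], annotated))
  structure(list(genome_id = genome,
                 domains = domains,
                 counts = counts[domains]),
            class = "annotatable_universe")
}

#' @export
print.annotatable_universe <- function(x, ...) {
  cat(sprintf("annotatable_universe: genome %s, %d domains\n",
              x$genome_id, length(x$domains)))
  invisible(x)
}

#' Resolve the effective domain set of a term within a genome
#'
#' The effective set is the intersection of the term's member superfamilies
#' with the genome's annotatable universe. Members annotated to the term
#' but absent from the genome are excluded (not scored as zero-count), so
#' that the observed median and the null medians are computed over the same
#' support. An empty intersection is a valid outcome, handled downstream as
#' not-scoreable.
#'
#' @param members character vector of the term's member superfamily ids.
#' @param universe an `annotatable_universe`.
#' @return list with `domains` (the effective set, sorted) and `k` (its
#'   size).
#' @export
resolve_domain_set <- function(members, universe) {
  stopifnot(inherits(universe, "annotatable_universe"))
  eff <- sort(intersect(unique(members), universe$domains))
  list(domains = eff, k = length(eff))
}
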