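# Domain assignment tables and the superfamily x genome architecture count
# matrix. An architecture is the N-to-C ordered sequence of SCOP superfamily
# tokens and gap tokens along one protein; its identity is exact token-
# sequence equality.

#' Canonicalize a domain architecture token sequence
#'
#' Splits a SUPERFAMILY-style architecture string (comma-separated
#' superfamily identifiers and `_gap_` tokens) into its canonical token
#' sequence: whitespace around tokens is stripped, runs of consecutive gap
#' tokens collapse to a single gap (the length of an unassigned region is
#' not informative at this level), and superfamily tokens are preserved
#' verbatim and in order, including repeats. Leading and trailing gaps are
#' retained.
#'
#' @param raw a single architecture string, or a character vector of tokens.
#' @param ignore_gaps drop gap tokens entirely before canonicalization, so
#'   that architectures differing only in gap placement compare equal.
#' @return character vector of tokens (N-terminus first), at least one of
#'   which is a superfamily identifier.
#' @examples
#' canonicalize_architecture("A,_gap_,_gap_,B")  # "A" "_gap_" "B"
#' canonicalize_architecture("A,C,A")            # repeats preserved
#' @export
canonicalize_architecture <- function(raw, ignore_gaps = FALSE) {
  if (length(raw) == 1L && is.character(raw)) {
    tokens <- strsplit(raw, ",", fixed = TRUE)[[1L]]
  } else {
    tokens <- as.character(raw)
  }
  tokens <- trimws(tokens)
  if (length(tokens) == 0L || any(!nzchar(tokens))) {
    stop("malformed architecture: empty token in ", sQuote(paste(raw, collapse = ",")))
  }
  if (ignore_gaps) {
    tokens <- tokens[tokens != GAP_TOKEN]
  } else {
    is_gap <- tokens == GAP_TOKEN
    drop <- is_gap & c(FALSE, is_gap[-length(is_gap)])
    tokens <- tokens[!drop]
  }
  if (length(tokens) == 0L || all(tokens == GAP_TOKEN)) {
    stop("malformed architecture: no superfamily token in ",
         sQuote(paste(raw, collapse = ",")))
  }
  tokens
}

# canonical string form used as the architecture identity key
arch_key <- function(tokens) paste(tokens, collapse = ",")

#' Parse a genome domain-assignment table
#'
#' Reads a UTF-8 TSV with header columns `genome_id`, `protein_id` and
#' `architecture` (comma-separated tokens, gap token `_gap_`). Every row is
#' canonicalized with [canonicalize_architecture()]. Duplicate
#' `(genome_id, protein_id)` pairs are an error rather than last-wins:
#' silent overwrite would hide upstream corruption.
#'
#' @param path path to the TSV file, or a connection.
#' @param ignore_gaps passed to [canonicalize_architecture()].
#' @return a `data.frame` of class `genome_assignments` with columns
#'   `genome_id`, `protein_id`, `architecture` (canonical string form).
#' @export
parse_assignments <- function(path, ignore_gaps = FALSE) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character", check.names = FALSE,
                   stringsAsFactors = FALSE)
  required <- c("genome_id", "protein_id", "architecture")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("assignment table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[required]
  key <- paste(df$genome_id, df$protein_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate (genome_id, protein_id) record: (",
         dup$genome_id, ", ", dup$protein_id, ")")
  }
  df$architecture <- vapply(
    df$architecture,
    function(a) arch_key(canonicalize_architecture(a, ignore_gaps = ignore_gaps)),
    character(1L), USE.NAMES = FALSE)
  as_genome_assignments(df)
}

as_genome_assignments <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("genome_assignments", "data.frame")
  df
}

# tokens of a canonical architecture string that are superfamily ids
arch_domains <- function(key) {
  tokens <- strsplit(key, ",", fixed = TRUE)[[1L]]
  unique(tokens[tokens != GAP_TOKEN])
}

#' Build the superfamily x genome architecture count matrix
#'
#' For each superfamily `d` and genome `g`, `N_d(g)` is the number of
#' distinct architectures among `g`'s proteins that contain `d` at least
#' once. A domain repeated within one architecture counts that architecture
#' once; identical architectures carried by several proteins count once.
#' Counting runs over every protein row as given, with no length, e-value
#' or isoform filtering.
#'
#' @param table a `genome_assignments` data frame from [parse_assignments()]
#'   (or any data frame with `genome_id`, `protein_id`, `architecture`
#'   columns holding canonical architecture strings).
#' @return an integer matrix of class `arch_count_matrix`, superfamilies in
#'   rows, genomes in columns, with attribute `genome_type = "extant"`.
#'   Zero means the superfamily occurs in no architecture of that genome.
#' @examples
#' tab <- data.frame(genome_id = "G1", protein_id = paste0("p", 1:4),
#'                   architecture = c("A,B", "A,B", "B", "A,_gap_,C"))
#' build_arch_count_matrix(tab)  # N_A = 2, N_B = 2, N_C = 1
#' @export
build_arch_count_matrix <- function(table) {
  stopifnot(all(c("genome_id", "protein_id", "architecture") %in% names(table)))
  genomes <- sort(unique(table$genome_id))
  if (length(genomes) == 0L) {
    m <- matrix(integer(0), nrow = 0, ncol = 0)
    return(as_arch_count_matrix(m, "extant"))
  }
  # one row per distinct (genome, architecture), then explode to domains
  ga <- unique(data.frame(genome_id = table$genome_id,
                          architecture = table$architecture,
                          stringsAsFactors = FALSE))
  doms <- lapply(ga$architecture, arch_domains)
  long <- data.frame(
    genome_id = rep(ga$genome_id, lengths(doms)),
    domain = unlist(doms, use.names = FALSE),
    stringsAsFactors = FALSE)
  sfs <- sort(unique(long$domain))
  m <- matrix(0L, nrow = length(sfs), ncol = length(genomes),
              dimnames = list(sfs, genomes))
  tab <- table(factor(long$domain, levels = sfs),
               factor(long$genome_id, levels = genomes))
  m[, ] <- as.integer(tab)
  as_arch_count_matrix(m, "extant")
}

as_arch_count_matrix <- function(m, genome_type) {
  storage.mode(m) <- "integer"
  attr(m, "genome_type") <- genome_type
  class(m) <- c("arch_count_matrix", class(m))
  m
}

#' @export
print.arch_count_matrix <- function(x, ...) {
  cat(sprintf("arch_count_matrix: %d superfamilies x %d %s genomes\n",
              nrow(x), ncol(x), attr(x, "genome_type")))
  y <- x
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  print(utils::head(y[, seq_len(min(ncol(y), 8L)), drop = FALSE]), ...)
  invisible(x)
}

# architecture counts of one genome as a named vector; errors if unknown
arch_counts <- function(m, genome) {
  if (!genome %in% colnames(m)) {
    stop("unknown genome: ", sQuote(genome))
  }
  setNames(as.integer(m[, genome]), rownames(m))
}

#' Export an architecture count matrix as long-format TSV
#'
#' Writes `superfamily_id<TAB>genome_id<TAB>n_architectures` (the genome
#' column is named `node_id` for ancestral matrices). Zero entries are
#' omitted.
#'
#' @param m an `arch_count_matrix`.
#' @param path output file path.
#' @param keep_zeros also write zero counts.
#' @return `path`, invisibly.
#' @export
write_arch_count_matrix <- function(m, path, keep_zeros = FALSE) {
  gcol <- if (identical(attr(m, "genome_type"), "ancestral")) "node_id" else "genome_id"
  long <- data.frame(
    superfamily_id = rep(rownames(m), times = ncol(m)),
    g = rep(colnames(m), each = nrow(m)),
    n_architectures = as.integer(m),
    stringsAsFactors = FALSE)
  names(long)[2L] <- gcol
  if (!keep_zeros) long <- long[long$n_architectures > 0L, , drop = FALSE]
  long <- long[order(long$superfamily_id, long[[gcol]]), , drop = FALSE]
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format architecture count matrix TSV
#'
#' Inverse of [write_arch_count_matrix()].
#'
#' @param path TSV with columns `superfamily_id`, `genome_id` (or
#'   `node_id`), `n_architectures`.
#' @return an `arch_count_matrix`.
#' @export
read_arch_count_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE)
  gcol <- if ("node_id" %in% names(df)) "node_id" else "genome_id"
  stopifnot(all(c("superfamily_id", gcol, "n_architectures") %in% names(df)))
  sfs <- sort(unique(df$superfamily_id))
  gs <- sort(unique(df[[gcol]]))
  m <- matrix(0L, length(sfs), length(gs), dimnames = list(sfs, gs))
  m[cbind(match(df$superfamily_id, sfs), match(df[[gcol]], gs))] <-
    as.integer(df$n_architectures)
  as_arch_count_matrix(m, if (gcol == "node_id") "ancestral" else "extant")
}
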