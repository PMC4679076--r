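# Shared fixture builders; everything is generated in code.

# assignment data frame from genome -> architecture strings
assignments_df <- function(..., genome_id = "G1") {
  archs <- c(...)
  if (length(archs) == 0L) {
    return(data.frame(genome_id = character(0), protein_id = character(0),
                      architecture = character(0), stringsAsFactors = FALSE))
  }
  data.frame(genome_id = genome_id,
             protein_id = sprintf("p%03d", seq_along(archs)),
             architecture = archs,
             stringsAsFactors = FALSE)
}

# write an assignments TSV and return its path
write_assignments_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# count matrix realizing exact per-domain counts in one genome
counts_matrix <- function(counts, genome_id = "G1") {
  build_arch_count_matrix(build_genome_from_counts(counts, genome_id))
}

# term_set from named list: term_id -> members
terms_of <- function(members_by_term, level = "specific") {
  archpp:::make_term_set(lapply(names(members_by_term), function(id) {
    list(term_id = id, members = members_by_term[[id]], level = level)
  }))
}

# annotations TSV
write_annotations_tsv <- function(terms, path = tempfile(fileext = ".tsv")) {
  write.table(as.data.frame(terms), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  path
}

# tip labels at or below a node id (tips and internal labels both allowed)
descendant_tips <- function(phy, id) {
  v <- archpp:::node_number(phy, id)
  if (v <= ape::Ntip(phy)) return(phy$tip.label[v])
  ape::extract.clade(phy, v)$tip.label
}

# all unlabeled rooted binary tree shapes with n leaves, as Newick strings
# with leaves labelled t1..tn left to right
all_tree_shapes <- function(n) {
  shapes <- function(m) {
    if (m == 1L) return("x")
    out <- character(0)
    for (i in seq_len(m %/% 2)) {
      left <- shapes(i)
      right <- shapes(m - i)
      for (a in seq_along(left)) {
        bs <- if (2L * i == m) seq(a, length(right)) else seq_along(right)
        for (b in bs) {
          out <- c(out, paste0("(", left[a], ",", right[b], ")"))
        }
      }
    }
    out
  }
  vapply(shapes(n), function(s) {
    for (i in seq_len(n)) s <- sub("x", paste0("t", i), s, fixed = TRUE)
    paste0(s, ";")
  }, character(1L), USE.NAMES = FALSE)
}
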