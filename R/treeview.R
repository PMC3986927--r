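#' Write Cluster 3.0 / TreeView CDT and GTR files
#'
#' Exports a clustered log-ratio matrix in the tab-delimited dialect that
#' Java TreeView and Cluster 3.0 read: a `.gtr` tree file with one line per
#' merge (`NODEkX  child1  child2  similarity`), children named `GENEiX`
#' for leaves (0-based, input row order) and `NODEjX` for earlier merges,
#' and a `.cdt` data table with header `GID  UNIQID  NAME  <conditions>`
#' and rows in dendrogram leaf order. Because the tree is built on a
#' correlation-based distance, similarity is stored as 1 - merge height.
#'
#' @param dend A `pm_dendrogram` whose leaves are the matrix rows.
#' @param mat Numeric matrix (strains x conditions) with row and column
#'   names; typically a [log_ratio_matrix()].
#' @param basename Output path without extension; `.cdt` and `.gtr` are
#'   appended.
#' @return Character vector of the two paths, invisibly.
#' @export
write_cdt_gtr <- function(dend, mat, basename) {
  stopifnot(inherits(dend, "pm_dendrogram"))
  mat <- unclass(mat)
  if (!setequal(rownames(mat), dend$labels) ||
      nrow(mat) != length(dend$labels))
    stop("dendrogram leaves and matrix rows do not match")
  leaf_id <- setNames(sprintf("GENE%dX", seq_len(dend$n) - 1L), dend$labels)
  node_name <- function(node)
    if (node < 0L) leaf_id[[dend$labels[-node]]] else sprintf("NODE%dX", node)
  gtr_path <- paste0(basename, ".gtr")
  cdt_path <- paste0(basename, ".cdt")
  gtr <- vapply(seq_len(nrow(dend$merge)), function(m) {
    paste(sprintf("NODE%dX", m),
          node_name(dend$merge[m, 1L]),
          node_name(dend$merge[m, 2L]),
          fmt_num(1 - dend$height[m]),
          sep = "\t")
  }, character(1L))
  writeLines(gtr, con <- file(gtr_path, "wb"), sep = "\n"); close(con)
  ord <- leaf_order(dend)
  header <- paste(c("GID", "UNIQID", "NAME", colnames(mat)), collapse = "\t")
  body <- vapply(ord, function(id) {
    vals <- vapply(mat[id, ], function(v)
      if (is.na(v)) "" else fmt_num(v), character(1L))
    paste(c(leaf_id[[id]], id, id, vals), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), con <- file(cdt_path, "wb"), sep = "\n")
  close(con)
  invisible(c(cdt = cdt_path, gtr = gtr_path))
}

fmt_num <- function(x) format(signif(x, 6), digits = 15, trim = TRUE,
                              scientific = FALSE)

#' Write a dendrogram as a rooted Newick tree
#'
#' Branch lengths follow the ultrametric convention for average-linkage
#' trees: each internal node sits at half its merge height, so every leaf
#' lies at depth (root height)/2 and two leaves' path length equals their
#' cophenetic distance.
#'
#' @param dend A `pm_dendrogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dend, path) {
  stopifnot(inherits(dend, "pm_dendrogram"))
  build <- function(node) {
    if (node < 0L)
      return(list(str = dend$labels[-node], age = 0))
    kids <- lapply(dend$merge[node, ], build)
    age <- dend$height[node] / 2
    parts <- vapply(kids, function(k)
      paste0(k$str, ":", fmt_num(age - k$age)), character(1L))
    list(str = paste0("(", paste(parts, collapse = ","), ")"), age = age)
  }
  nwk <- paste0(build(nrow(dend$merge))$str, ";")
  writeLines(nwk, con <- file(path, "wb"), sep = "\n")
  close(con)
  invisible(path)
}
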