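# Gene-age assignment: simplified Dollo phylostratigraphy on a dated tree.
# A gene's origin is placed at the MRCA of the focal species and every
# species carrying an ortholog; its age A_i is that node's age (time before
# present), the quantity the transcriptome age index weights by expression.

#' Node ages of a dated ultrametric tree
#'
#' Leaf ages are 0; an internal node's age is its distance to any descendant
#' leaf; the root is oldest.  The tree must be ultrametric: the worst
#' deviation of leaf depths is checked against `tol` (relative to tree
#' height).
#'
#' @param tree an [ape::read.tree()] `phylo` object with branch lengths in
#'   time units
#' @param tol relative ultrametricity tolerance (default 1e-6)
#' @return named numeric vector of ages, one per node (leaves first, named by
#'   leaf label; internal nodes named by their node label or `node<k>`)
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' node_ages_from_tree(tr)
node_ages_from_tree <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) invalid_parameter("tree must be a 'phylo' object")
  depth <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  height <- max(depth[seq_len(ntip)])
  dev <- max(abs(depth[seq_len(ntip)] - height))
  if (height > 0 && dev > tol * height) {
    stop_evoindex("evoindex_not_ultrametric",
                  "tree is not ultrametric: worst leaf-depth deviation %.6g (tolerance %.3g of height %.6g)",
                  dev, tol, height)
  }
  ages <- height - depth
  ages[seq_len(ntip)] <- 0  # clamp leaf ages exactly
  nn <- tree$Nnode
  inner_names <- if (!is.null(tree$node.label) &&
                     length(tree$node.label) == nn &&
                     all(nzchar(tree$node.label))) {
    tree$node.label
  } else {
    paste0("node", ntip + seq_len(nn))
  }
  names(ages) <- c(tree$tip.label, inner_names)
  ages
}

# indices of the nodes on the path focal leaf -> root (including both ends)
focal_path_nodes <- function(tree, focal) {
  ntip <- length(tree$tip.label)
  tip <- match(focal, tree$tip.label)
  if (is.na(tip)) {
    stop_evoindex("evoindex_validation",
                  "focal species '%s' is not a leaf of the tree", focal)
  }
  root <- ntip + 1L
  path <- tip
  node <- tip
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  while (node != root) {
    node <- parent[match(node, child)]
    path <- c(path, node)
  }
  path
}

#' Ages of the nodes on the focal-to-root path
#'
#' These are the only ages a Dollo assignment can produce (plus 0 for
#' focal-only genes); the synthetic generator draws true gene ages from this
#' set.
#'
#' @inheritParams assign_gene_ages
#' @param tol passed to [node_ages_from_tree()]
#' @return named numeric vector, youngest (the focal leaf, age 0) first
#' @export
focal_path_ages <- function(tree, focal = default_focal_species(), tol = 1e-6) {
  ages <- node_ages_from_tree(tree, tol = tol)
  path <- focal_path_nodes(tree, focal)
  ages[path]
}

#' Assign gene ages by Dollo parsimony on a dated species tree
#'
#' For each gene, the origin node is the most recent common ancestor of the
#' focal species and all carrier species (the deepest node on the
#' focal-to-root path subtending any carrier); the gene's age is that node's
#' age.  Genes present only in the focal species are assigned the focal leaf
#' itself, age 0 (the youngest stratum).  Under loss-only evolution this rule
#' can only under-date: inferred age <= true origin age.
#'
#' @param pa logical or 0/1 matrix, genes x species; rownames are gene ids,
#'   colnames are tree leaf names.  The focal column must be all `TRUE`.
#' @param tree dated ultrametric `phylo` tree
#' @param focal focal species leaf name
#' @param tol ultrametricity tolerance, see [node_ages_from_tree()]
#' @return data.frame with columns `gene_id`, `origin_node`, `age`
#' @export
#' @examples
#' tr <- default_species_tree()
#' pa <- matrix(TRUE, 1, 2,
#'              dimnames = list("g1", c("Homo_sapiens", "Tarsius_syrichta")))
#' assign_gene_ages(pa, tr)  # deepest carrier forces a root origin
assign_gene_ages <- function(pa, tree, focal = default_focal_species(),
                             tol = 1e-6) {
  if (is.null(rownames(pa)) || is.null(colnames(pa))) {
    stop_evoindex("evoindex_validation",
                  "presence/absence matrix needs gene rownames and species colnames")
  }
  mode(pa) <- "logical"
  unknown <- setdiff(colnames(pa), tree$tip.label)
  if (length(unknown)) {
    stop_evoindex("evoindex_validation",
                  "species not in tree: %s", paste(unknown, collapse = ", "))
  }
  if (!focal %in% colnames(pa)) {
    stop_evoindex("evoindex_validation",
                  "focal species '%s' missing from presence/absence matrix", focal)
  }
  if (!all(pa[, focal])) {
    bad <- rownames(pa)[!pa[, focal]]
    stop_evoindex("evoindex_validation",
                  "gene(s) absent from focal species: %s",
                  paste(head(bad, 5), collapse = ", "))
  }
  ages <- node_ages_from_tree(tree, tol = tol)
  path <- focal_path_nodes(tree, focal)
  path_ages <- unname(ages[path])
  # age of MRCA(focal, leaf) for every leaf, precomputed once
  ntip <- length(tree$tip.label)
  mrca_age <- numeric(ntip)
  names(mrca_age) <- tree$tip.label
  mrca_age[focal] <- 0
  others <- setdiff(tree$tip.label, focal)
  if (length(others)) {
    for (sp in others) {
      node <- ape::getMRCA(tree, c(focal, sp))
      mrca_age[sp] <- ages[node]
    }
  }
  leaf_ages <- mrca_age[colnames(pa)]
  gene_age <- apply(pa, 1L, function(row) max(0, leaf_ages[row]))
  origin_idx <- vapply(gene_age,
                       function(a) path[which.min(abs(path_ages - a))],
                       integer(1))
  origin_lab <- names(ages)[origin_idx]
  data.frame(gene_id = rownames(pa),
             origin_node = unname(origin_lab),
             age = unname(gene_age),
             stringsAsFactors = FALSE,
             row.names = NULL)
}
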