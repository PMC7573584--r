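# Build an ape "phylo" object from an edge list with arbitrary internal ids.
# Tips are 1..n already; internal nodes are renumbered n+1, n+2, ... in
# preorder from `root`.
make_phylo <- function(edges, lengths, tip_labels, root) {
  n <- length(tip_labels)
  kids <- split(seq_len(nrow(edges)), edges[, 1])
  new_id <- integer(0)
  nxt <- n
  renumber <- function(node) {
    nxt <<- nxt + 1L
    new_id[as.character(node)] <<- nxt
    for (e in kids[[as.character(node)]]) {
      ch <- edges[e, 2]
      if (ch > n) renumber(ch)
    }
  }
  renumber(root)
  e2 <- edges
  for (i in seq_len(nrow(edges))) {
    if (e2[i, 1] > n) e2[i, 1] <- new_id[as.character(edges[i, 1])]
    if (e2[i, 2] > n) e2[i, 2] <- new_id[as.character(edges[i, 2])]
  }
  phy <- list(edge = e2, edge.length = lengths, tip.label = tip_labels,
              Nnode = length(new_id))
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomerative algorithm: repeatedly join the pair of
#' active nodes minimizing the Q criterion, compute the two branch lengths
#' by the standard rate-corrected formulas, and reduce the distance matrix,
#' until three nodes remain and are joined in a final trifurcation. NJ is
#' exact on additive distances: if the input is a tree metric the generating
#' topology and branch lengths are recovered. Ties in Q are broken by the
#' lowest (row, column) index pair; negative branch lengths are clamped to
#' zero without redistribution.
#'
#' @param dm symmetric non-negative matrix with zero diagonal and row/column
#'   names (the leaf labels), at least 3 x 3
#' @return an unrooted `phylo` tree (trifurcating root node)
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("neighbor joining needs at least 3 labels")
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <-
      paste0("t", seq_len(n))
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(!is.finite(dm)) || any(dm < 0)) stop("distances must be finite and >= 0")
  labels <- rownames(dm)
  active <- seq_len(n)          # node ids of active rows
  d <- dm
  next_id <- n
  edges <- matrix(0L, 0, 2); lens <- numeric(0)
  while (length(active) > 3) {
    r <- length(active)
    R <- rowSums(d)
    best <- c(NA, NA); bestq <- Inf
    for (i in seq_len(r - 1)) for (j in (i + 1):r) {
      q <- (r - 2) * d[i, j] - R[i] - R[j]
      if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    next_id <- next_id + 1L
    bi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- d[i, j] - bi
    edges <- rbind(edges, c(next_id, active[i]), c(next_id, active[j]))
    lens <- c(lens, max(0, bi), max(0, bj))
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    d <- rbind(cbind(d[-c(i, j), -c(i, j), drop = FALSE],
                     du[-c(i, j)]),
               c(du[-c(i, j)], 0))
    active <- c(active[-c(i, j)], next_id)
  }
  # final trifurcation
  next_id <- next_id + 1L
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  edges <- rbind(edges, c(next_id, active[1]), c(next_id, active[2]),
                 c(next_id, active[3]))
  lens <- c(lens, max(0, b1), max(0, b2), max(0, b3))
  make_phylo(edges, lens, labels, next_id)
}

# Tips below each node; returns list indexed by node id.
tips_below <- function(phy) {
  n <- length(phy$tip.label)
  post <- ape::reorder.phylo(phy, "postorder")
  below <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) below[[i]] <- i
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the leaves into two sets; the split is encoded
#' as the sorted comma-joined labels of the side not containing the
#' alphabetically first leaf, making keys comparable across trees on the
#' same leaf set regardless of rooting.
#'
#' @param phy a `phylo` tree
#' @return named character vector of split keys; names are the internal
#'   (child) node ids of the corresponding edges
#' @export
tree_bipartitions <- function(phy) {
  n <- length(phy$tip.label)
  ref <- sort(phy$tip.label)[1]
  below <- tips_below(phy)
  keys <- character(0)
  for (e in seq_len(nrow(phy$edge))) {
    ch <- phy$edge[e, 2]
    if (ch <= n) next
    side <- phy$tip.label[below[[ch]]]
    if (length(side) < 2 || length(side) > n - 2) next
    if (ref %in% side) side <- setdiff(phy$tip.label, side)
    keys[as.character(ch)] <- paste(sort(side), collapse = ",")
  }
  keys
}

#' Mahalanobis distance matrix between group mean shapes
#'
#' Convenience builder for morphometric trees: runs [cva()] and returns its
#' Mahalanobis distance matrix between group means.
#'
#' @inheritParams cva
#' @return symmetric `g x g` distance matrix
#' @export
mahalanobis_distances <- function(shapes, labels) cva(shapes, labels)$mahalanobis

#' Bootstrap support for a distance-based tree
#'
#' Builds the tree on the full dataset, then resamples specimens with
#' replacement within each group, rebuilds the distance matrix and the NJ
#' tree per replicate, and reports for each internal edge of the full tree
#' the percentage of replicate trees containing the same leaf bipartition.
#' Resampling specimens (rather than, say, coordinates) propagates sampling
#' variance of the group means into the tree.
#'
#' @param shapes `n x p` shape matrix
#' @param labels group labels, length n; every group needs >= 2 members
#' @param builder function(shapes, labels) returning a labelled distance
#'   matrix; default [mahalanobis_distances()]
#' @param n_reps bootstrap replicates (default 1000)
#' @param seed optional integer seed
#' @return the full-data `phylo` tree with `node.label` holding supports
#'   (percentages, `""` for the root); attributes `n_effective` (replicates
#'   that succeeded) and `n_failed`
#' @export
bootstrap_support <- function(shapes, labels, builder = mahalanobis_distances,
                              n_reps = 1000, seed = NULL) {
  shapes <- as.matrix(shapes)
  labels <- factor(labels)
  full_dm <- builder(shapes, labels)
  full_tree <- neighbor_joining(full_dm)
  full_splits <- tree_bipartitions(full_tree)
  counts <- stats::setNames(numeric(length(full_splits)), full_splits)
  idx_by_group <- split(seq_along(labels), labels)
  n_fail <- 0L
  n_ok <- 0L
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      take <- unlist(lapply(idx_by_group, function(ii)
        sample(ii, length(ii), replace = TRUE)), use.names = FALSE)
      rep_splits <- tryCatch(
        tree_bipartitions(neighbor_joining(
          builder(shapes[take, , drop = FALSE], labels[take]))),
        error = function(e) NULL)
      if (is.null(rep_splits)) { n_fail <- n_fail + 1L; next }
      n_ok <- n_ok + 1L
      hit <- names(counts) %in% rep_splits
      counts[hit] <- counts[hit] + 1
    }
  })
  if (n_fail > 0)
    warning(n_fail, " bootstrap replicate(s) failed and were skipped")
  if (n_ok == 0) stop("all bootstrap replicates failed")
  n <- length(full_tree$tip.label)
  node_lab <- rep("", full_tree$Nnode)
  for (node_chr in names(full_splits)) {
    v <- as.integer(node_chr)
    node_lab[v - n] <- sprintf("%.0f", 100 * counts[[full_splits[[node_chr]]]] /
                                 n_ok)
  }
  full_tree$node.label <- node_lab
  attr(full_tree, "n_effective") <- n_ok
  attr(full_tree, "n_failed") <- n_fail
  full_tree
}

#' Serialize a tree to a Newick string
#' @param tree a `phylo` object (optionally with `node.label` supports)
#' @return single Newick string terminated by `;`
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Parse a Newick string into a tree
#'
#' Parenthesis balance is checked up front so that malformed input is
#' reported with the character position of the first offending bracket.
#'
#' @param text a Newick string
#' @return a `phylo` object
#' @export
parse_newick <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced ')' at position ", i, " in Newick string")
    }
  }
  if (depth != 0L)
    stop("unbalanced '(' in Newick string: ", depth, " unclosed at end")
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("malformed Newick string")
  phy
}
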