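#' Dated species trees
#'
#' A dated species tree is an [ape::phylo] object that is rooted, binary,
#' and carries non-negative branch lengths in millions of years (My).
#' Every branch is identified by the label of its child node: tip labels
#' for terminal branches, node labels (auto-filled as `"n<number>"` when
#' absent) for internal branches.
#'
#' @param tree an [ape::phylo] object, a newick string, or a path to a
#'   newick file.
#' @return a validated `phylo` object with node labels filled in.
#' @examples
#' tr <- as_dated_tree("((A:100,B:100):50,C:150);")
#' branch_ids(tr)
#' @export
as_dated_tree <- function(tree) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree[1]) && length(tree) == 1L && !grepl("\\(", tree)) {
      ape::read.tree(file = tree)
    } else {
      ape::read.tree(text = paste(tree, collapse = ""))
    }
  }
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object or newick")
  if (is.null(tree$edge.length)) stop("tree is not dated: no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) stop("tree must be binary")
  root <- length(tree$tip.label) + 1L
  if (sum(tree$edge[, 1] == root) != 2L) stop("root must have exactly two children")
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label)) || anyNA(tree$node.label)) {
    lab <- tree$node.label
    if (is.null(lab)) lab <- rep("", tree$Nnode)
    fill <- !nzchar(lab) | is.na(lab)
    lab[fill] <- paste0("n", (seq_len(tree$Nnode) + length(tree$tip.label))[fill])
    tree$node.label <- lab
  }
  nl <- node_labels(tree)
  if (anyDuplicated(nl)) stop("branch ids (node labels) must be unique")
  tree
}

#' @rdname as_dated_tree
#' @export
node_labels <- function(tree) c(tree$tip.label, tree$node.label)

#' @rdname as_dated_tree
#' @export
branch_ids <- function(tree) node_labels(tree)[tree$edge[, 2]]

# node number for a branch id (the child node carrying the label)
branch_node <- function(tree, id) {
  i <- match(id, node_labels(tree))
  if (anyNA(i)) stop("unknown branch id(s): ", paste(id[is.na(i)], collapse = ", "))
  i
}

#' Leaf sets of the two clades stemming from the root
#'
#' @param tree a dated species tree (see [as_dated_tree()]).
#' @return list of two character vectors of tip labels.
#' @export
root_clades <- function(tree) {
  tree <- as_dated_tree(tree)
  root <- length(tree$tip.label) + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  lapply(kids, function(k) {
    if (k <= length(tree$tip.label)) tree$tip.label[k]
    else ape::extract.clade(tree, k)$tip.label
  })
}

#' Specify a whole-genome duplication hypothesis on a species-tree branch
#'
#' @param branch branch id (see [branch_ids()]): the label of the node at
#'   the lower (recent) end of the branch.
#' @param age placement of the WGD on the branch, in My before the
#'   branch's child node. `NA` places it at the branch midpoint when the
#'   hypothesis is resolved against a tree.
#' @param q retention rate in `[0, 1]`: the probability that a gene copy
#'   created at the WGD survives to the present. Used by the simulator;
#'   in inference q is a free parameter and this value is ignored.
#' @param name optional label for reporting.
#' @return a one-row data.frame of class `wgd_hypothesis`.
#' @export
wgd_hypothesis <- function(branch, age = NA_real_, q = NA_real_, name = branch) {
  stopifnot(is.character(branch), length(branch) == 1L)
  if (!is.na(q) && (q < 0 || q > 1)) stop("q must lie in [0, 1]")
  out <- data.frame(branch = branch, age = as.numeric(age), q = as.numeric(q),
                    name = name, stringsAsFactors = FALSE)
  class(out) <- c("wgd_hypothesis", class(out))
  out
}

# normalize a list/data.frame of hypotheses against a tree: resolve midpoint
# ages and check that each age lies strictly inside its branch
resolve_wgds <- function(wgds, tree) {
  if (is.null(wgds) || (is.data.frame(wgds) && nrow(wgds) == 0L)) {
    return(data.frame(branch = character(), age = numeric(), q = numeric(),
                      name = character(), stringsAsFactors = FALSE))
  }
  if (inherits(wgds, "wgd_hypothesis") || is.data.frame(wgds)) wgds <- list(wgds)
  wgds <- do.call(rbind, lapply(wgds, function(w) as.data.frame(w)[, c("branch", "age", "q", "name")]))
  nodes <- branch_node(tree, wgds$branch)
  blen <- tree$edge.length[match(nodes, tree$edge[, 2])]
  if (anyNA(blen)) stop("WGD placed on the root, which has no branch")
  mid <- is.na(wgds$age)
  wgds$age[mid] <- blen[mid] / 2
  bad <- wgds$age <= 0 | wgds$age >= blen
  if (any(bad)) stop("WGD age must lie strictly inside its branch interval")
  wgds
}
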