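# ensure a rooted tree has unique node labels; branches are keyed by the
# label of the edge's child node, the root's incoming stem is "root"
ensureNodeLabels <- function(tree) {
  if (is.null(tree$node.label) || anyDuplicated(tree$node.label) ||
      any(tree$node.label == ""))
    tree$node.label <- sprintf("n%d", seq_len(tree$Nnode) + ape::Ntip(tree))
  tree
}

nodeLabel <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  ifelse(node <= ntip, tree$tip.label[node],
         tree$node.label[node - ntip])
}

#' Dollo-parsimony reconstruction of family histories
#'
#' Under Dollo parsimony a family is gained exactly once and may only be
#' lost afterwards. The unique minimum-loss single-gain reconstruction
#' places the gain on the branch subtending the most recent common ancestor
#' of the leaves carrying the family (the root's incoming stem for families
#' spanning the root); below the gain, a node is present iff some descendant
#' leaf is present, and one loss is charged on every branch from a present
#' parent to a child whose entire subtree lacks the family.
#'
#' @param tree rooted `phylo` (binary or multifurcating); unrooted trees are
#'   rejected
#' @param leaf_presence either a [PAMatrix-class] (columns = leaf labels) or
#'   a named list mapping family id -> character vector of leaves carrying it
#' @return named list of family histories, each a list with `gain_branch`
#'   (child-node label of the gain edge, `"root"` for the stem),
#'   `gain_clade` (tips below the gain edge), `loss_branches` (child-node
#'   labels) and `ancestral_states` (named logical over all node labels).
#'   Families observed in no leaf raise an error.
#' @export
dolloReconstruct <- function(tree, leaf_presence) {
  if (!ape::is.rooted(tree))
    stop("Dollo reconstruction requires a rooted tree")
  tree <- ensureNodeLabels(tree)
  if (is(leaf_presence, "PAMatrix")) {
    b <- binary(leaf_presence)
    leaf_presence <- lapply(setNames(rownames(b), rownames(b)),
                            function(f) colnames(b)[b[f, ] > 0])
  }
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  desc <- phangorn::Descendants(tree, type = "tips")
  all_labels <- vapply(seq_len(nnode), function(v) nodeLabel(tree, v), "")
  edges <- tree$edge
  out <- vector("list", length(leaf_presence))
  names(out) <- names(leaf_presence)
  for (f in names(leaf_presence)) {
    P <- leaf_presence[[f]]
    if (!length(P))
      stop("family ", f, " observed in no leaf: no history")
    bad <- setdiff(P, tree$tip.label)
    if (length(bad))
      stop("family ", f, ": leaf ", bad[1], " not in tree")
    tipidx <- match(P, tree$tip.label)
    mrca <- if (length(tipidx) == 1) tipidx
            else ape::getMRCA(tree, tipidx)
    # present iff under (or equal to) the MRCA and carrying >= 1 present leaf
    under <- c(if (mrca > ntip) phangorn::Descendants(tree, mrca, "all"),
               mrca)
    states <- setNames(rep(FALSE, nnode), all_labels)
    for (v in under)
      states[v] <- any(tree$tip.label[desc[[v]]] %in% P)
    gain_branch <- if (mrca == ntip + 1L) "root" else nodeLabel(tree, mrca)
    losses <- character(0)
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1]; chl <- edges[e, 2]
      if (states[par] && !states[chl] && chl %in% under)
        losses <- c(losses, nodeLabel(tree, chl))
    }
    out[[f]] <- list(gain_branch = gain_branch,
                     gain_clade = sort(tree$tip.label[desc[[mrca]]]),
                     loss_branches = sort(losses),
                     ancestral_states = states)
  }
  out
}

#' Per-branch gain and loss counts
#'
#' Aggregates family histories into counts of gains and losses on every
#' branch (keyed by the child-node label, plus the `"root"` stem), optionally
#' restricted to a family subset -- e.g. the GH-annotated families, or the
#' host-glycan families ([HOST_GLYCAN_GH]).
#'
#' @param histories output of [dolloReconstruct()]
#' @param tree the (rooted) tree the histories were reconstructed on
#' @param subset optional character vector of family ids; unknown ids raise
#'   a warning and are ignored
#' @return data.frame with `branch`, `n_gains`, `n_losses`
#' @export
branchEvents <- function(histories, tree, subset = NULL) {
  tree <- ensureNodeLabels(tree)
  branches <- c("root", vapply(tree$edge[, 2],
                               function(v) nodeLabel(tree, v), ""))
  if (!is.null(subset)) {
    unknown <- setdiff(subset, names(histories))
    if (length(unknown))
      warning("unknown families ignored: ",
              paste(unknown, collapse = ", "))
    histories <- histories[intersect(subset, names(histories))]
  }
  gains <- setNames(integer(length(branches)), branches)
  losses <- setNames(integer(length(branches)), branches)
  for (h in histories) {
    gains[h$gain_branch] <- gains[h$gain_branch] + 1L
    for (b in h$loss_branches) losses[b] <- losses[b] + 1L
  }
  data.frame(branch = branches, n_gains = as.integer(gains),
             n_losses = as.integer(losses), row.names = NULL)
}

#' Per-leaf GH gene counts attached to a tree
#'
#' Counts GH-annotated genes per genome and returns them in the order of the
#' tree's tips, for rendering next to the leaves.
#'
#' @param gs a [GenomeSet-class] with annotations
#' @param tree `phylo` whose tip labels are genome ids
#' @return named integer vector over tree tips
#' @export
leafGhCounts <- function(gs, tree) {
  tal <- labelTally(gs, "gh_family")
  miss <- setdiff(tree$tip.label, tal$genome_id)
  if (length(miss))
    stop("tree leaf not found among genomes: ", miss[1])
  setNames(tal$count[match(tree$tip.label, tal$genome_id)],
           tree$tip.label)
}

#' Write per-branch events and an annotated tree
#'
#' Writes the [branchEvents()] table as TSV and, when `newick_path` is
#' given, a Newick file whose internal-node labels carry the gain/loss
#' counts as `label|g<gains>_l<losses>`.
#'
#' @param events data.frame from [branchEvents()]
#' @param path output TSV
#' @param tree optional tree for the annotated Newick
#' @param newick_path optional Newick output path
#' @return invisibly, `path`
#' @export
writeBranchEvents <- function(events, path, tree = NULL,
                              newick_path = NULL) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(tree) && !is.null(newick_path)) {
    tree <- ensureNodeLabels(tree)
    key <- setNames(sprintf("g%d_l%d", events$n_gains, events$n_losses),
                    events$branch)
    tree$node.label <- paste0(tree$node.label, "|",
                              key[tree$node.label])
    writeNewick(tree, newick_path)
  }
  invisible(path)
}
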