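#' Single-copy core families
#'
#' Core families with exactly one member in every genome -- the families
#' concatenated into the supertree alignment (paralog-containing core
#' families are excluded).
#'
#' @param pam a [PAMatrix-class]
#' @return character vector of family ids
#' @export
selectSingleCopyCore <- function(pam) {
  m <- counts(pam)
  rownames(m)[rowSums(m == 1) == ncol(m)]
}

# ---- progressive multiple alignment -------------------------------------

# frequency profile of an alignment: (20 AA + gap) x columns
profileOf <- function(alnChars) {
  lv <- c(AA20, "-")
  apply(alnChars, 2, function(col) {
    col[col == "X"] <- NA  # X scores as nothing in either direction
    tabulate(factor(col, levels = lv), nbins = 21)
  }) / nrow(alnChars)
}

# global profile-profile alignment with affine gaps; returns the two gapped
# index vectors mapping merged columns back to input columns (0 = gap)
alignProfilePair <- function(PA, PB, S21, open, ext) {
  la <- ncol(PA); lb <- ncol(PB)
  SM <- t(PA) %*% S21 %*% PB          # column-vs-column match scores
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, la + 1, lb + 1)
  M[1, 1] <- 0
  Ix[, 1] <- c(NEG, -(open + ext * seq_len(la)))  # gaps in B (consume A)
  Iy[1, ] <- c(NEG, -(open + ext * seq_len(lb)))
  jj <- seq_len(lb)
  for (i in seq_len(la)) {
    prevM <- M[i, ]; prevX <- Ix[i, ]; prevY <- Iy[i, ]
    # match state: best of the three at (i-1, j-1) plus the column score
    best_prev <- pmax(prevM[jj], prevX[jj], prevY[jj])
    Mrow <- c(NEG, best_prev + SM[i, ])
    Mrow[1] <- M[i + 1, 1]
    # gap-in-B state: vertical moves only
    Xrow <- pmax(prevM - open - ext, prevX - ext)
    Xrow[1] <- Ix[i + 1, 1]
    # gap-in-A state: horizontal running max within the current row
    cm <- cummax(Mrow + (0:lb) * ext)
    Yrow <- c(NEG, cm[jj] - open - (jj) * ext)
    M[i + 1, ] <- Mrow; Ix[i + 1, ] <- Xrow; Iy[i + 1, ] <- Yrow
  }
  fin <- c(M[la + 1, lb + 1], Ix[la + 1, lb + 1], Iy[la + 1, lb + 1])
  state <- which.max(fin)
  score <- fin[state]
  tol <- 1e-9
  ia <- integer(0); ib <- integer(0)
  i <- la; j <- lb
  while (i > 0 || j > 0) {
    if (state == 1) {
      ia <- c(i, ia); ib <- c(j, ib)
      prev <- c(M[i, j], Ix[i, j], Iy[i, j])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      ia <- c(i, ia); ib <- c(0L, ib)
      state <- if (abs(Ix[i + 1, j + 1] - (M[i, j + 1] - open - ext)) < tol)
        1L else 2L
      i <- i - 1
    } else {
      ia <- c(0L, ia); ib <- c(j, ib)
      state <- if (abs(Iy[i + 1, j + 1] - (M[i + 1, j] - open - ext)) < tol)
        1L else 3L
      j <- j - 1
    }
  }
  list(ia = ia, ib = ib, score = score)
}

mergeAln <- function(A, B, map) {
  # A, B: character matrices (rows seqs); map from alignProfilePair
  ncols <- length(map$ia)
  out <- matrix("-", nrow(A) + nrow(B), ncols)
  rownames(out) <- c(rownames(A), rownames(B))
  out[seq_len(nrow(A)), map$ia > 0] <- A[, map$ia[map$ia > 0], drop = FALSE]
  out[nrow(A) + seq_len(nrow(B)), map$ib > 0] <-
    B[, map$ib[map$ib > 0], drop = FALSE]
  out
}

alnToMatrix <- function(aln) {
  chars <- strsplit(as.character(aln), "")
  m <- do.call(rbind, chars)
  rownames(m) <- names(aln)
  m
}

matrixToAln <- function(m) {
  AAStringSet(setNames(apply(m, 1, paste, collapse = ""), rownames(m)))
}

#' Progressive multiple sequence alignment
#'
#' Deterministic progressive alignment: a neighbor-joining guide tree from
#' pairwise global-alignment distances, then profile-profile global
#' alignment with affine gap penalties merged up the (midpoint-rooted) guide
#' tree. Intended for the moderate divergences of single-copy core families;
#' a pre-aligned `AAStringSet` (equal widths) is accepted unchanged, which
#' is the hook for externally aligned families in full-scale runs.
#'
#' @param seqs named [Biostrings::AAStringSet] (one per taxon)
#' @param scoring list with `matrix`, `gap_open`, `gap_extend`
#' @return aligned [Biostrings::AAStringSet] (equal widths, `-` gaps), same
#'   name order as the input
#' @export
progressiveAlign <- function(seqs, scoring = defaultScoring()) {
  if (length(seqs) < 2) stop("need at least two sequences")
  if (any(width(seqs) == 0)) stop("empty sequence")
  if (length(unique(width(seqs))) == 1 &&
      any(grepl("-", as.character(seqs), fixed = TRUE)))
    return(seqs)  # already aligned
  S21 <- matrix(0, 21, 21, dimnames = list(c(AA20, "-"), c(AA20, "-")))
  S21[AA20, AA20] <- scoring$matrix[AA20, AA20]
  open <- scoring$gap_open; ext <- scoring$gap_extend

  n <- length(seqs)
  nm <- names(seqs)
  mats <- lapply(seq_len(n), function(i) {
    m <- matrix(strsplit(as.character(seqs[[i]]), "")[[1]], nrow = 1)
    rownames(m) <- nm[i]
    m
  })
  if (n == 2) {
    map <- alignProfilePair(profileOf(mats[[1]]), profileOf(mats[[2]]),
                            S21, open, ext)
    return(matrixToAln(mergeAln(mats[[1]], mats[[2]], map)))
  }
  # guide tree from pairwise global-alignment p-distances
  D <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) {
    pa <- pairwiseAlignment(seqs[seq.int(i + 1, n)], seqs[[i]],
                            substitutionMatrix = scoring$matrix,
                            gapOpening = open, gapExtension = ext,
                            type = "global")
    p <- 1 - nmatch(pa) / alnCols(pa)
    D[i, seq.int(i + 1, n)] <- D[seq.int(i + 1, n), i] <- p
  }
  guide <- phangorn::midpoint(njTree(D))
  merged <- stats::setNames(mats, nm)
  alignNode <- function(node) {
    kids <- guide$edge[guide$edge[, 1] == node, 2]
    if (!length(kids)) return(merged[[guide$tip.label[node]]])
    pieces <- lapply(kids, alignNode)
    acc <- pieces[[1]]
    for (k in seq.int(2, length(pieces))) {
      map <- alignProfilePair(profileOf(acc), profileOf(pieces[[k]]),
                              S21, open, ext)
      acc <- mergeAln(acc, pieces[[k]], map)
    }
    acc
  }
  res <- alignNode(ape::Ntip(guide) + 1L)
  matrixToAln(res[nm, , drop = FALSE])
}

#' Concatenate per-family alignments
#'
#' Row-wise concatenation in the given (fixed) family order; every alignment
#' must contain exactly one row per taxon.
#'
#' @param alignments named list of aligned [Biostrings::AAStringSet]
#' @param taxa character vector of taxon names fixing the row order
#' @return one concatenated aligned [Biostrings::AAStringSet]
#' @export
concatenateAlignments <- function(alignments, taxa) {
  rows <- setNames(rep("", length(taxa)), taxa)
  for (f in names(alignments)) {
    aln <- alignments[[f]]
    miss <- setdiff(taxa, names(aln))
    if (length(miss))
      stop("family ", f, " is missing taxon ", miss[1])
    if (length(aln) != length(taxa))
      stop("family ", f, " must have exactly one row per taxon")
    rows <- paste0(rows, as.character(aln)[taxa])
  }
  AAStringSet(setNames(rows, taxa))
}

#' Pairwise distances from an alignment
#'
#' Proportion of differing columns over columns where neither row has a gap
#' (`p_distance`), or its Poisson correction `-ln(1 - p)`.
#'
#' @param alignment aligned [Biostrings::AAStringSet]
#' @param model `"p_distance"` (default) or `"poisson"`
#' @return symmetric distance matrix with zero diagonal
#' @export
alignmentDistances <- function(alignment,
                               model = c("p_distance", "poisson")) {
  model <- match.arg(model)
  if (length(alignment) < 2) stop("need at least two rows")
  m <- alnToMatrix(alignment)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok))
      stop("no comparable columns between ", rownames(m)[i], " and ",
           rownames(m)[j], ": distance undefined")
    p <- mean(m[i, ok] != m[j, ok])
    if (model == "poisson") {
      if (p >= 1) stop("saturated distance: Poisson correction undefined")
      p <- -log(1 - p)
    }
    D[i, j] <- D[j, i] <- p
  }
  D
}

#' Neighbor-joining tree
#'
#' Classical agglomeration minimizing the Q criterion, with
#' a deterministic tie-break: among minimizing pairs, the one whose
#' (lexicographically smallest member label, then the other label) sorts
#' first is joined. Output is an unrooted `phylo`; negative branch-length
#' estimates are clamped to zero. Ties encountered are counted in
#' `attr(tree, "tie_count")`.
#'
#' @param d symmetric distance matrix with taxon dimnames (>= 3 taxa)
#' @return an unrooted `ape::phylo`
#' @export
njTree <- function(d) {
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  n0 <- nrow(d)
  if (n0 < 3) stop("need at least three taxa")
  labels <- rownames(d)
  # active node bookkeeping: ids 1..n0 tips, internals n0+1 ...
  ids <- seq_len(n0)
  rep_lab <- labels            # representative (smallest leaf) label
  D <- d
  next_id <- n0 + 1L
  edges <- matrix(0L, 0, 2)
  elen <- numeric(0)
  tie_count <- 0L
  while (length(ids) > 3) {
    n <- length(ids)
    rs <- rowSums(D)
    Q <- (n - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= abs(qmin) * 1e-12 + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) > 1) {
      tie_count <- tie_count + 1L
      keys <- apply(cand, 1, function(ij) {
        p <- sort(c(rep_lab[ij[1]], rep_lab[ij[2]]))
        paste(p, collapse = "\r")
      })
      cand <- cand[order(keys)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    bi <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    new_d <- (D[i, ] + D[j, ] - D[i, j]) / 2
    edges <- rbind(edges, c(next_id, ids[i]), c(next_id, ids[j]))
    elen <- c(elen, max(bi, 0), max(bj, 0))
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], new_d[keep]),
               c(new_d[keep], 0))
    new_rep <- min(rep_lab[c(i, j)])
    rep_lab <- c(rep_lab[keep], new_rep)
    ids <- c(ids[keep], next_id)
    rownames(D) <- colnames(D) <- rep_lab
    next_id <- next_id + 1L
  }
  # final three-way join: exact three-point branch lengths
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  edges <- rbind(edges, c(next_id, ids[1]), c(next_id, ids[2]),
                 c(next_id, ids[3]))
  elen <- c(elen, max(v1, 0), max(v2, 0), max(v3, 0))
  # renumber internals: ape wants tips 1..n0, root-ish first internal n0+1
  n_int <- next_id - n0
  old_int <- seq.int(n0 + 1L, next_id)
  new_int <- setNames(rev(seq.int(n0 + 1L, next_id)), old_int)
  e2 <- edges
  for (k in seq_along(e2)) {
    if (e2[k] > n0) e2[k] <- new_int[as.character(e2[k])]
  }
  tree <- list(edge = e2, edge.length = elen, tip.label = labels,
               Nnode = n_int)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  # normalize node numbering to ape's canonical preorder layout
  tree <- ape::read.tree(text = ape::write.tree(tree, digits = 12))
  attr(tree, "tie_count") <- tie_count
  tree
}

#' Midpoint rooting
#'
#' Roots an unrooted tree at the midpoint of its longest leaf-to-leaf path
#' (the display/rooting default), or on a user-specified outgroup.
#'
#' @param tree an `ape::phylo`
#' @param outgroup optional tip label(s); when given, roots on their branch
#' @return rooted `phylo`
#' @export
rootTree <- function(tree, outgroup = NULL) {
  if (!is.null(outgroup))
    return(ape::root(tree, outgroup = outgroup, resolve.root = TRUE))
  phangorn::midpoint(tree)
}

# canonical bipartition keys of a tree's internal edges: the tip-set side
# not containing the reference tip, sorted and pasted
treeSplits <- function(tree, ref = NULL) {
  tips <- sort(tree$tip.label)
  if (is.null(ref)) ref <- tips[1]
  ntip <- ape::Ntip(tree)
  out <- character(0)
  desc <- phangorn::Descendants(tree, type = "tips")
  for (node in seq.int(ntip + 1L, ntip + tree$Nnode)) {
    grp <- tree$tip.label[desc[[node]]]
    if (length(grp) <= 1 || length(grp) >= ntip - 1) next
    if (ref %in% grp) grp <- setdiff(tree$tip.label, grp)
    out <- c(out, paste(sort(grp), collapse = "\r"))
  }
  unique(out)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal bipartition of the full-data
#' tree the percentage of replicates containing it. Supports are attached as
#' internal node labels.
#'
#' @param alignment aligned [Biostrings::AAStringSet]
#' @param n_reps bootstrap replicates (default 100)
#' @param seed integer seed
#' @param model distance model passed to [alignmentDistances()]
#' @return the full-data NJ `phylo` with `node.label` percentages (root
#'   label empty)
#' @export
bootstrapSupport <- function(alignment, n_reps = 100, seed = 1,
                             model = "p_distance") {
  stopifnot(n_reps >= 1)
  full <- njTree(alignmentDistances(alignment, model))
  m <- alnToMatrix(alignment)
  hits <- new.env()
  withr::with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rep_aln <- matrixToAln(m[, cols, drop = FALSE])
      rt <- try(njTree(alignmentDistances(rep_aln, model)), silent = TRUE)
      if (inherits(rt, "try-error")) next
      for (s in treeSplits(rt))
        assign(s, (if (exists(s, hits)) get(s, hits) else 0) + 1, hits)
    }
  })
  ntip <- ape::Ntip(full)
  desc <- phangorn::Descendants(full, type = "tips")
  ref <- sort(full$tip.label)[1]
  labs <- character(full$Nnode)
  for (k in seq_len(full$Nnode)) {
    node <- ntip + k
    grp <- full$tip.label[desc[[node]]]
    if (length(grp) <= 1 || length(grp) >= ntip - 1) { labs[k] <- ""; next }
    if (ref %in% grp) grp <- setdiff(full$tip.label, grp)
    key <- paste(sort(grp), collapse = "\r")
    cnt <- if (exists(key, hits)) get(key, hits) else 0
    labs[k] <- as.character(round(100 * cnt / n_reps))
  }
  full$node.label <- labs
  full
}

#' Newick read/write
#'
#' Thin wrappers with lossless round-trip (write -> read -> write is
#' byte-stable).
#'
#' @param tree a `phylo`
#' @param path file path
#' @return `readNewick` returns a `phylo`; `writeNewick` the path, invisibly
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) ape::read.tree(path)
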