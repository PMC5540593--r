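# Independent oracles used across the suite. These are deliberately naive
# (plain loops, exhaustive enumeration) and share no code with the package
# implementations they check.

AA <- c("A","R","N","D","C","Q","E","G","H","I",
        "L","K","M","F","P","S","T","W","Y","V")

blosum62 <- local({
  e <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

randProt <- function(len) paste(sample(AA, len, replace = TRUE),
                                collapse = "")

mutateProt <- function(seq, frac) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), round(frac * length(ch)))
  for (p in pos) ch[p] <- sample(setdiff(AA, ch[p]), 1)
  paste(ch, collapse = "")
}

# Smith-Waterman with affine gaps (gap of length k costs open + k*ext),
# score only
oracleLocalScore <- function(a, b, mat = blosum62, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  FF <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    E[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, E[i + 1, j] - ext)
    FF[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, FF[i, j + 1] - ext)
    H[i + 1, j + 1] <- max(0, H[i, j] + mat[A[i], B[j]],
                           E[i + 1, j + 1], FF[i + 1, j + 1])
    best <- max(best, H[i + 1, j + 1])
  }
  best
}

# Needleman-Wunsch global score with the same gap convention
oracleGlobalScore <- function(a, b, mat = blosum62, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(-Inf, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  FF <- matrix(-Inf, n + 1, m + 1)
  H[1, 1] <- 0
  for (j in seq_len(m)) E[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) FF[i + 1, 1] <- -(open + ext * i)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    E[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, E[i + 1, j] - ext)
    FF[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, FF[i, j + 1] - ext)
    H[i + 1, j + 1] <- max(H[i, j], E[i, j], FF[i, j]) + mat[A[i], B[j]]
  }
  max(H[n + 1, m + 1], E[n + 1, m + 1], FF[n + 1, m + 1])
}

# connected components of an undirected edge list (cluster oracle)
oracleComponents <- function(nodes, from, to) {
  comp <- setNames(seq_along(nodes), nodes)
  # repeated relabeling (small graphs only)
  repeat {
    changed <- FALSE
    for (k in seq_along(from)) {
      a <- comp[from[k]]; b <- comp[to[k]]
      if (a != b) { comp[comp == max(a, b)] <- min(a, b); changed <- TRUE }
    }
    if (!changed) break
  }
  split(nodes, comp)
}

# exhaustive minimum-loss single-gain reconstruction on a rooted tree
oracleDollo <- function(tree, present) {
  ntip <- ape::Ntip(tree)
  nn <- tree$Nnode
  labs <- c(tree$tip.label,
            if (is.null(tree$node.label))
              sprintf("n%d", ntip + seq_len(nn)) else tree$node.label)
  edges <- tree$edge
  root <- ntip + 1L
  leaf_state <- tree$tip.label %in% present
  best <- NULL
  for (mask in 0:(2^nn - 1)) {
    st <- c(leaf_state,
            as.logical(bitwAnd(rep(mask, nn), 2^(seq_len(nn) - 1))))
    gains <- sum(st[edges[, 2]] & !st[edges[, 1]]) + st[root]
    if (gains != 1) next
    loss_edges <- which(st[edges[, 1]] & !st[edges[, 2]])
    nl <- length(loss_edges)
    if (is.null(best) || nl < best$losses) {
      gain_branch <- if (st[root]) "root"
        else labs[edges[which(st[edges[, 2]] & !st[edges[, 1]]), 2]]
      best <- list(losses = nl, gain_branch = gain_branch,
                   loss_branches = sort(labs[edges[loss_edges, 2]]))
    }
  }
  best
}

# all permutations of 1..n (small n)
allPerms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in allPerms(n - 1)) for (k in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = k - 1)
  }
  out
}

# exhaustive mean pan/core curve over all genome orderings
oraclePanCurve <- function(bin) {
  ng <- ncol(bin)
  perms <- allPerms(ng)
  pan <- core <- matrix(0, length(perms), ng)
  for (r in seq_along(perms)) {
    ord <- perms[[r]]
    seen <- rep(FALSE, nrow(bin)); inall <- rep(TRUE, nrow(bin))
    for (k in seq_len(ng)) {
      pres <- bin[, ord[k]] > 0
      seen <- seen | pres; inall <- inall & pres
      pan[r, k] <- sum(seen); core[r, k] <- sum(inall)
    }
  }
  list(pan = colMeans(pan), core = colMeans(core))
}

# map recovered families to the simulator's true families for ARI
truthFamilyVector <- function(truth) {
  rows <- do.call(rbind, lapply(names(truth$leaf_membership), function(f) {
    m <- truth$leaf_membership[[f]]
    if (nrow(m)) data.frame(key = paste0(m$genome, "|", m$gene), fam = f)
    else NULL
  }))
  setNames(rows$fam, rows$key)
}

recoveredVsTruthARI <- function(famset, truth) {
  tv <- truthFamilyVector(truth)
  rec <- familyOf(famset)
  mclust::adjustedRandIndex(unname(tv[names(rec)]), unname(rec))
}

# concatenated single-copy-core supertree from a clustering
supertreeFromFamilies <- function(gs, famset, pam,
                                  model = "p_distance") {
  scc <- selectSingleCopyCore(pam)
  gg <- famset@geneGenome
  prots <- do.call(c, unname(lapply(genomeIds(gs), function(g) {
    p <- proteins(gs, g); names(p) <- paste0(g, "|", names(p)); p
  })))
  alns <- lapply(setNames(scc, scc), function(f) {
    ids <- families(famset)[[f]]
    seqs <- prots[ids]
    names(seqs) <- gg[ids]
    progressiveAlign(seqs)
  })
  concat <- concatenateAlignments(alns, genomeIds(gs))
  njTree(alignmentDistances(concat, model))
}
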