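#' Configuration for the genome-family simulator
#'
#' Defines the study conditions emulated by [simulateGenomes()]: a rooted
#' tree relating the genomes, gene families gained once on a branch and lost
#' independently below it, protein sequences diverging by substitutions in
#' proportion to path length, and single-contig nucleotide genomes with a
#' controlled per-branch substitution fraction.
#'
#' @param n_leaves number of genomes (>= 2)
#' @param tree optional user-supplied rooted `phylo`; generated when `NULL`
#' @param root_family_count families present at the root
#' @param gain_rate expected number of new families gained per branch
#'   (Poisson)
#' @param loss_rate per-branch per-family loss probability in `[0,1]`
#' @param dup_prob per-family per-leaf probability of an extra paralog copy
#' @param prot_sub_rate protein substitutions per site per unit branch length
#' @param nuc_divergence per-branch nucleotide substitution fraction
#' @param mean_prot_len mean ancestral protein length (Poisson around it)
#' @param genome_len nucleotide genome length (bp)
#' @param gc genomic GC fraction used to draw the root genome
#' @param gh_fraction fraction of families carrying a GH-family label
#' @param seed integer seed; fully determines the output
#' @return a list of class `sim_config`
#' @export
simConfig <- function(n_leaves = 8, tree = NULL, root_family_count = 20,
                      gain_rate = 2, loss_rate = 0.05, dup_prob = 0,
                      prot_sub_rate = 0.05, nuc_divergence = 0.02,
                      mean_prot_len = 120, genome_len = 12000, gc = 0.6,
                      gh_fraction = 0.3, seed = 1) {
  stopifnot(n_leaves >= 2, root_family_count >= 0, gain_rate >= 0,
            loss_rate >= 0, loss_rate <= 1, dup_prob >= 0, dup_prob <= 1,
            prot_sub_rate >= 0, nuc_divergence >= 0, nuc_divergence < 0.75,
            mean_prot_len > 0, genome_len > 0, gc > 0, gc < 1,
            gh_fraction >= 0, gh_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# GH labels sampled for simulated families: common families plus the
# host-glycan set so subset-restricted event summaries are exercised
SIM_GH_POOL <- c("GH13", "GH3", "GH43", "GH23", "GH32", "GH25",
                 "GH20", "GH29", "GH33", "GH38", "GH95", "GH101",
                 "GH112", "GH125", "GH129")

#' GH families implicated in host-glycan degradation
#'
#' The family labels used to restrict gain/loss summaries to host-glycan
#' degrading enzymes.
#' @export
HOST_GLYCAN_GH <- c("GH20", "GH29", "GH33", "GH38", "GH95",
                    "GH101", "GH112", "GH125", "GH129")

randomRootedTree <- function(n) {
  tr <- ape::rtree(n, rooted = TRUE,
                   tip.label = sprintf("g%02d", seq_len(n)))
  # branch lengths ~ U(0.5, 1.5) so one unit of rate is one expected unit
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.5, 1.5)
  tr
}

# preorder edge indices of a rooted phylo (parents before children)
preorderEdges <- function(tree) {
  root <- ape::Ntip(tree) + 1L
  ord <- integer(0)
  stack <- which(tree$edge[, 1] == root)
  while (length(stack)) {
    e <- stack[1]; stack <- stack[-1]
    ord <- c(ord, e)
    stack <- c(which(tree$edge[, 1] == tree$edge[e, 2]), stack)
  }
  ord
}

# node label helper: tips keep tip.label, internal nodes "n<k>"
nodeLabels <- function(tree) {
  c(tree$tip.label, sprintf("n%d", seq_len(tree$Nnode) + ape::Ntip(tree)))
}

mutateProtein <- function(seq_chars, n_sub, exch) {
  if (n_sub == 0) return(seq_chars)
  pos <- sample.int(length(seq_chars), min(n_sub, length(seq_chars)))
  for (p in pos) {
    probs <- exch[seq_chars[p], ]
    probs[seq_chars[p]] <- 0
    seq_chars[p] <- sample(colnames(exch), 1, prob = probs)
  }
  seq_chars
}

mutateNucleotide <- function(seq_chars, frac) {
  n <- round(frac * length(seq_chars))
  if (n == 0) return(list(seq = seq_chars, pos = integer(0)))
  pos <- sample.int(length(seq_chars), n)
  bases <- c("A", "C", "G", "T")
  for (p in pos)
    seq_chars[p] <- sample(setdiff(bases, seq_chars[p]), 1)
  list(seq = seq_chars, pos = pos)
}

# amino-acid exchangeability weights: positive BLOSUM62 entries,
# so simulated substitutions stay detectable by the alignment stage
blosumExchange <- function() {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())[AA20, AA20]
  W <- pmax(B, 0) + 0.1   # keep all moves possible, favour conservative ones
  diag(W) <- 0
  W
}

#' Simulate a family of genomes with full ground truth
#'
#' Realizes the generative model that the downstream pipeline is designed to
#' invert: a rooted tree; families gained exactly once on a branch (root
#' families on the root stem) and lost with a fixed per-branch probability
#' below the gain; protein sequences evolving by substitutions only, counts
#' Poisson in `rate x length x branch length`, replacements drawn
#' proportional to positive BLOSUM62 exchangeabilities; and one nucleotide
#' contig per genome accumulating a fixed substitution fraction per branch.
#'
#' @param config a [simConfig()] object
#' @return list with `genomes` (a [GenomeSet-class]) and `truth`, a list of
#'   class `sim_truth` with elements `tree` (rooted `phylo`, node-labelled),
#'   `family_origin` (family -> branch id, `"root"` for the root stem),
#'   `family_losses` (family -> character vector of branch ids),
#'   `leaf_membership` (family -> data.frame genome/gene),
#'   `family_gh` (family -> GH label or NA) and `pairwise_nuc_identity`
#'   (expected identity fractions, leaf x leaf). Branch ids are the label of
#'   the child node of the edge.
#' @examples
#' sim <- simulateGenomes(simConfig(n_leaves = 4, seed = 42))
#' sim$genomes
#' @export
simulateGenomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulateGenomesImpl(config))
}

simulateGenomesImpl <- function(cfg) {
  tree <- if (is.null(cfg$tree)) randomRootedTree(cfg$n_leaves) else cfg$tree
  if (!ape::is.rooted(tree)) stop("simulator tree must be rooted")
  ntip <- ape::Ntip(tree)
  labs <- nodeLabels(tree)
  if (is.null(tree$node.label)) tree$node.label <- labs[-seq_len(ntip)]
  edges <- tree$edge
  elen <- tree$edge.length
  pre <- preorderEdges(tree)
  root <- ntip + 1L

  exch <- blosumExchange()
  fam_counter <- 0L
  newFamily <- function() {
    fam_counter <<- fam_counter + 1L
    sprintf("F%04d", fam_counter)
  }

  # per-node family presence and sequences: presence[[node]] = named list
  # family -> character vector of residues
  seqs <- vector("list", ntip + tree$Nnode)
  origin <- character(0); losses <- list()

  rootFam <- function() {
    len <- max(30L, stats::rpois(1, cfg$mean_prot_len))
    sample(AA20, len, replace = TRUE)
  }
  seqs[[root]] <- list()
  for (i in seq_len(cfg$root_family_count)) {
    f <- newFamily()
    seqs[[root]][[f]] <- rootFam()
    origin[f] <- "root"
    losses[[f]] <- character(0)
  }

  for (e in pre) {
    par <- edges[e, 1]; chl <- edges[e, 2]; bl <- elen[e]
    inherited <- seqs[[par]]
    kept <- list()
    for (f in names(inherited)) {
      if (stats::runif(1) < cfg$loss_rate) {
        losses[[f]] <- c(losses[[f]], labs[chl])
      } else {
        s <- inherited[[f]]
        nsub <- stats::rpois(1, cfg$prot_sub_rate * length(s) * bl)
        kept[[f]] <- mutateProtein(s, nsub, exch)
      }
    }
    ngain <- stats::rpois(1, cfg$gain_rate)
    for (i in seq_len(ngain)) {
      f <- newFamily()
      kept[[f]] <- rootFam()
      origin[f] <- labs[chl]
      losses[[f]] <- character(0)
    }
    seqs[[chl]] <- kept
  }

  # nucleotide genomes: root sequence, then substitutions along each edge
  bases <- c("A", "C", "G", "T")
  pbase <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
  gseq <- vector("list", ntip + tree$Nnode)
  gseq[[root]] <- sample(bases, cfg$genome_len, replace = TRUE, prob = pbase)
  for (e in pre) {
    m <- mutateNucleotide(gseq[[edges[e, 1]]], cfg$nuc_divergence)
    gseq[[edges[e, 2]]] <- m$seq
  }

  # expected pairwise identity: product of (1 - d) over the connecting path
  nEdgesPath <- matrix(0, ntip, ntip)
  anc <- lapply(seq_len(ntip), function(i)
    c(i, phangorn::Ancestors(tree, i, "all")))
  for (i in seq_len(ntip)) for (j in seq_len(ntip)) if (i != j) {
    common <- max(intersect(anc[[i]], anc[[j]]))
    nEdgesPath[i, j] <- (length(anc[[i]]) - match(common, anc[[i]])) +
      (length(anc[[j]]) - match(common, anc[[j]])) + 2
  }
  expId <- (1 - cfg$nuc_divergence)^nEdgesPath
  diag(expId) <- 1
  dimnames(expId) <- list(tree$tip.label, tree$tip.label)

  # assemble leaf genomes
  proteins <- list(); contigs <- list(); ann <- list()
  membership <- lapply(setNames(names(origin), names(origin)),
                       function(f) data.frame(genome = character(0),
                                              gene = character(0)))
  fam_gh <- setNames(rep(NA_character_, length(origin)), names(origin))
  ghfam <- names(origin)[stats::runif(length(origin)) < cfg$gh_fraction]
  fam_gh[ghfam] <- sample(SIM_GH_POOL, length(ghfam), replace = TRUE)
  fam_cat <- setNames(sample(c(LETTERS[1:17], "R", "S"),
                             length(origin), replace = TRUE), names(origin))

  for (i in seq_len(ntip)) {
    g <- tree$tip.label[i]
    fams <- names(seqs[[i]])
    gene_seqs <- character(0); gene_ids <- character(0)
    rows <- list()
    k <- 0L
    for (f in fams) {
      copies <- 1L + (cfg$dup_prob > 0 && stats::runif(1) < cfg$dup_prob)
      for (cp in seq_len(copies)) {
        k <- k + 1L
        gid <- sprintf("%s_g%04d", g, k)
        s <- seqs[[i]][[f]]
        if (cp > 1)  # paralog: a lightly diverged extra copy
          s <- mutateProtein(s, max(1L, stats::rpois(1, 0.02 * length(s))),
                             exch)
        gene_seqs <- c(gene_seqs, paste(s, collapse = ""))
        gene_ids <- c(gene_ids, gid)
        membership[[f]] <- rbind(membership[[f]],
                                 data.frame(genome = g, gene = gid))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gid, genome_id = g, gh_family = fam_gh[[f]],
          cog_category = fam_cat[[f]],
          mobile_element = FALSE, family_truth = f,
          stringsAsFactors = FALSE)
      }
    }
    proteins[[g]] <- AAStringSet(setNames(gene_seqs, gene_ids))
    contigs[[g]] <- DNAStringSet(setNames(
      paste(gseq[[i]], collapse = ""), paste0(g, "_contig1")))
    ann[[g]] <- do.call(rbind, rows)
  }

  genomes <- GenomeSet(
    data.frame(genome_id = tree$tip.label, label = tree$tip.label,
               group = "bifidobacterium", rrna_loci = NA, trna_count = NA),
    contigs = contigs, proteins = proteins,
    annotations = {
      a <- do.call(rbind, ann); rownames(a) <- NULL; a
    })

  truth <- structure(list(
    tree = tree, family_origin = origin, family_losses = losses,
    leaf_membership = membership, family_gh = fam_gh,
    pairwise_nuc_identity = expId, config = cfg), class = "sim_truth")
  list(genomes = genomes, truth = truth)
}

#' Presence/absence matrix implied by simulator ground truth
#'
#' Builds the family-by-genome count matrix directly from the recorded leaf
#' membership (not from the origin/loss events), so it can be compared
#' against an independent traversal of those events.
#'
#' @param truth the `truth` element of [simulateGenomes()] output
#' @return a [PAMatrix-class]
#' @export
truthPresenceMatrix <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  leaves <- truth$tree$tip.label
  fams <- names(truth$family_origin)
  m <- matrix(0L, length(fams), length(leaves),
              dimnames = list(fams, leaves))
  for (f in fams) {
    mem <- truth$leaf_membership[[f]]
    if (nrow(mem)) {
      t0 <- table(mem$genome)
      m[f, names(t0)] <- as.integer(t0)
    }
  }
  m <- m[rowSums(m) > 0, , drop = FALSE]
  new("PAMatrix", counts = m)
}

#' Write simulator output to disk
#'
#' Emits per-genome protein and nucleotide FASTA, the annotation TSV, the
#' true tree as Newick and the remaining ground truth as JSON.
#'
#' @param sim output of [simulateGenomes()]
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gs <- sim$genomes
  for (g in genomeIds(gs)) {
    writeXStringSet(proteins(gs, g), file.path(dir, paste0(g, "_prot.faa")))
    writeXStringSet(contigs(gs, g), file.path(dir, paste0(g, "_genome.fna")))
  }
  write.table(annotations(gs), file.path(dir, "annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(sim$truth$tree, file.path(dir, "true_tree.nwk"))
  tr <- sim$truth
  jsonlite::write_json(
    list(family_origin = as.list(tr$family_origin),
         family_losses = tr$family_losses,
         family_gh = as.list(tr$family_gh),
         pairwise_nuc_identity = tr$pairwise_nuc_identity),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
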