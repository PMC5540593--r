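# Gapped Karlin-Altschul parameters for BLOSUM62 with affine gaps 11/1,
# used to scale raw local-alignment scores into e-values. The search space
# is the plain length product n x m; the identity and coverage filters
# dominate edge selection, the e-value mainly removes short spurious hits.
KA_LAMBDA <- 0.267
KA_K <- 0.041

defaultScoring <- function() {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  list(matrix = get("BLOSUM62", envir = environment()),
       gap_open = 11, gap_extend = 1)
}

# number of alignment columns (match + mismatch + gap positions) without
# materializing the gapped strings
alnCols <- function(pa) {
  nd <- Biostrings::nindel(pa)
  nmatch(pa) + Biostrings::nmismatch(pa) +
    Biostrings::insertion(nd)[, "WidthSum"] +
    Biostrings::deletion(nd)[, "WidthSum"]
}

evalueFromScore <- function(score, n, m,
                            lambda = KA_LAMBDA, K = KA_K) {
  K * as.numeric(n) * as.numeric(m) * exp(-lambda * score)
}

bitScore <- function(score, lambda = KA_LAMBDA, K = KA_K) {
  (lambda * score - log(K)) / log(2)
}

#' Optimal local alignment of two proteins
#'
#' Exact Smith-Waterman alignment with affine gap penalties (no heuristic
#' seeding), as used for the all-vs-all similarity search. Identity is
#' computed over aligned columns (internal gaps included); coverage is the
#' aligned span on each sequence divided by its full length; the e-value is
#' a Karlin-Altschul scaling of the raw score against the length product.
#'
#' @param a,b protein sequences (character or `AAString`)
#' @param scoring list with `matrix` (a substitution matrix), `gap_open`
#'   and `gap_extend`; defaults to BLOSUM62 with 11/1. A gap of length k
#'   costs `gap_open + k * gap_extend`.
#' @return list with `score`, `identity_pct`, `coverage_q`, `coverage_s`,
#'   `evalue`, `bitscore`, and the aligned span coordinates; `NULL` when no
#'   positive-scoring local alignment exists.
#' @examples
#' alignPair("HEAGAWGHEE", "PAWHEAE")$score
#' @export
alignPair <- function(a, b, scoring = defaultScoring()) {
  a <- as.character(a); b <- as.character(b)
  if (!nchar(a) || !nchar(b)) stop("empty sequence")
  ok <- paste0(c(AA20, "X"), collapse = "")
  if (grepl(sprintf("[^%s]", ok), a) || grepl(sprintf("[^%s]", ok), b))
    stop("invalid residues: alphabet is the 20 amino acids plus X")
  pa <- pairwiseAlignment(AAStringSet(a), AAStringSet(b),
                          substitutionMatrix = scoring$matrix,
                          gapOpening = scoring$gap_open,
                          gapExtension = scoring$gap_extend,
                          type = "local")
  s <- Biostrings::score(pa)
  if (s <= 0) return(NULL)
  hitStats(s, nmatch(pa), alnCols(pa),
           start(Biostrings::pattern(pa)), end(Biostrings::pattern(pa)),
           start(Biostrings::subject(pa)), end(Biostrings::subject(pa)),
           nchar(a), nchar(b))
}

hitStats <- function(score, nid, ncol_aln, qs, qe, ss, se, qlen, slen) {
  list(score = score,
       identity_pct = 100 * nid / ncol_aln,
       n_aligned_cols = ncol_aln,
       coverage_q = (qe - qs + 1) / qlen,
       coverage_s = (se - ss + 1) / slen,
       qstart = qs, qend = qe, sstart = ss, send = se,
       evalue = evalueFromScore(score, qlen, slen),
       bitscore = bitScore(score))
}

#' All-vs-all similarity graph over a genome set
#'
#' Compares every protein against every other protein (within-genome pairs
#' included, so paralog edges exist) by exact local alignment and keeps an
#' edge when the hit passes all three filters: e-value at most `max_evalue`,
#' identity at least `min_identity` percent, and aligned span covering at
#' least `min_coverage` of *both* sequences. Edge weight is `-log10(evalue)`
#' capped at `weight_cap`.
#'
#' @param gs a [GenomeSet-class] with proteomes
#' @param max_evalue e-value cutoff (default `1e-5`)
#' @param min_identity identity cutoff in percent (default `50`)
#' @param min_coverage coverage cutoff on both sequences (default `0.5`)
#' @param weight_cap maximum edge weight (default `200`)
#' @param scoring as in [alignPair()]
#' @return a [SimilarityGraph-class]; gene ids are `genome|gene` keys
#' @export
allVsAll <- function(gs, max_evalue = 1e-5, min_identity = 50,
                     min_coverage = 0.5, weight_cap = 200,
                     scoring = defaultScoring()) {
  prot <- proteins(gs)
  if (!length(prot)) stop("genome set carries no proteomes")
  all <- do.call(c, unname(lapply(names(prot), function(g) {
    p <- prot[[g]]
    names(p) <- paste0(g, "|", names(p))
    p
  })))
  if (length(all) < 2) stop("need at least two genes")
  all <- all[order(names(all))]
  n <- length(all)
  lens <- width(all)
  rows <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    idx <- seq.int(i + 1, n)
    pa <- pairwiseAlignment(all[idx], all[[i]],
                            substitutionMatrix = scoring$matrix,
                            gapOpening = scoring$gap_open,
                            gapExtension = scoring$gap_extend,
                            type = "local")
    sc <- Biostrings::score(pa)
    ev <- evalueFromScore(sc, lens[idx], lens[i])
    idn <- 100 * nmatch(pa) / alnCols(pa)
    covq <- (end(Biostrings::pattern(pa)) -
             start(Biostrings::pattern(pa)) + 1) / lens[idx]
    covs <- (end(Biostrings::subject(pa)) -
             start(Biostrings::subject(pa)) + 1) / lens[i]
    keep <- sc > 0 & ev <= max_evalue & idn >= min_identity &
      pmin(covq, covs) >= min_coverage
    if (any(keep))
      rows[[i]] <- data.frame(
        from = names(all)[i], to = names(all)[idx][keep],
        weight = pmin(-log10(ev[keep]), weight_cap),
        identity_pct = idn[keep], evalue = ev[keep],
        coverage_min = pmin(covq, covs)[keep],
        score = sc[keep],
        stringsAsFactors = FALSE)
  }
  edges <- if (any(!vapply(rows, is.null, TRUE)))
    do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  else data.frame(from = character(0), to = character(0),
                  weight = numeric(0), identity_pct = numeric(0),
                  evalue = numeric(0), coverage_min = numeric(0),
                  score = numeric(0))
  rownames(edges) <- NULL
  new("SimilarityGraph", nodes = names(all), edges = edges)
}

#' Markov clustering of a similarity graph into ortholog families
#'
#' Runs MCL on the column-stochastic matrix of the weighted graph:
#' alternating expansion (matrix squaring) and inflation (entrywise power
#' followed by column renormalization), pruning entries below a small
#' threshold, until the matrix change falls under `tol`. Clusters are read
#' off as the connected components of the converged matrix's nonzero
#' pattern. Isolated genes become singleton families. Node order (and hence
#' family numbering) is lexicographic in gene id, so the result is
#' deterministic.
#'
#' @param graph a [SimilarityGraph-class]
#' @param inflation inflation exponent (> 1); 1.5 is the conventional
#'   coarse-clustering default
#' @param self_loop diagonal weight added before normalization; the default
#'   `NULL` uses each node's maximum incident edge weight (at least 1),
#'   which damps the flow oscillations that otherwise shatter small
#'   components
#' @param prune entries below this are zeroed each iteration
#' @param tol convergence threshold on the max absolute change
#' @param max_iter iteration cap; non-convergence raises a warning and the
#'   partial result is flagged with `attr(, "converged") = FALSE`
#' @return a [CogFamilySet-class]; families are named `COG0001`, ... in
#'   decreasing size order
#' @export
mclCluster <- function(graph, inflation = 1.5, self_loop = NULL,
                       prune = 1e-5, tol = 1e-6, max_iter = 100) {
  stopifnot(inflation > 1)
  nodes <- sort(graph@nodes)
  n <- length(nodes)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- graph@edges
  if (nrow(e)) {
    i <- match(e$from, nodes); j <- match(e$to, nodes)
    M[cbind(i, j)] <- e$weight
    M[cbind(j, i)] <- e$weight
  }
  if (is.null(self_loop)) self_loop <- pmax(apply(M, 1, max), 1)
  diag(M) <- diag(M) + self_loop
  normalize <- function(X) sweep(X, 2, colSums(X), "/")
  M <- normalize(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M          # expansion
    M2 <- M2^inflation     # inflation
    M2[M2 < prune] <- 0
    M2 <- normalize(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge after ", max_iter,
            " iterations; returning partial clustering")
  # components of the nonzero pattern (symmetrized)
  adj <- (M > tol) | t(M > tol)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v]) next
      comp[v] <- cur
      nb <- which(adj[v, ] & comp == 0L)
      stack <- c(stack, nb)
    }
  }
  fam <- split(nodes, comp)
  fam <- fam[order(-lengths(fam),
                   vapply(fam, function(x) sort(x)[1], ""))]
  names(fam) <- sprintf("COG%04d", seq_along(fam))
  fam <- lapply(fam, sort)
  gg <- setNames(sub("\\|.*$", "", nodes), nodes)
  out <- new("CogFamilySet", families = fam, geneGenome = gg)
  attr(out, "converged") <- converged
  out
}

#' Write similarity hits in 12-column tabular format
#'
#' Classic tabular layout: query, subject, identity, alignment length,
#' mismatches, gap openings, query/subject start/end, e-value, bit score.
#' Mismatch and gap-opening counts are not retained in the graph and are
#' written as `NA`.
#'
#' @param graph a [SimilarityGraph-class]
#' @param path output TSV
#' @return invisibly, the path
#' @export
writeHitsTable <- function(graph, path) {
  e <- graph@edges
  na <- rep(NA, nrow(e))
  tab <- data.frame(query = e$from, subject = e$to,
                    identity = round(e$identity_pct, 2),
                    length = na, mismatches = na, gaps = na,
                    qstart = na, qend = na, sstart = na, send = na,
                    evalue = signif(e$evalue, 3),
                    bitscore = round(bitScore(e$score), 1))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write families as TSV
#'
#' @param famset a [CogFamilySet-class]
#' @param path output TSV (`family_id`, tab, comma-separated members)
#' @return invisibly, the path
#' @export
writeFamilies <- function(famset, path) {
  tab <- data.frame(family_id = names(families(famset)),
                    members = vapply(families(famset),
                                     paste, "", collapse = ","))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
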