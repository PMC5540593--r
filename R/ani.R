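# blastn-style nucleotide scoring used for fragment alignment
aniScoring <- function() {
  list(matrix = nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                             baseOnly = TRUE),
       gap_open = 5, gap_extend = 2)
}

#' Cut a genome into consecutive fragments
#'
#' Non-overlapping windows of fixed size per contig; a terminal remnant
#' shorter than the window is discarded. Fragment names record the origin as
#' `contig:start-end` with 0-based half-open coordinates.
#'
#' @param contigs a [Biostrings::DNAStringSet] (or character vector)
#' @param size window size in bp (1020 by default, the fragment-based ANI
#'   convention)
#' @return a [Biostrings::DNAStringSet] of fragments (possibly empty)
#' @examples
#' length(fragmentGenome(Biostrings::DNAStringSet(
#'   setNames(paste(rep("ACGT", 765), collapse = ""), "c1"))))  # 3060 bp -> 3
#' @export
fragmentGenome <- function(contigs, size = 1020) {
  if (is.character(contigs)) contigs <- DNAStringSet(contigs)
  if (is.null(names(contigs)))
    names(contigs) <- sprintf("contig%d", seq_along(contigs))
  frags <- character(0); ids <- character(0)
  for (k in seq_along(contigs)) {
    len <- width(contigs)[k]
    nfrag <- len %/% size
    if (nfrag == 0) next
    starts <- (seq_len(nfrag) - 1L) * size + 1L
    frags <- c(frags, vapply(starts, function(s)
      as.character(Biostrings::subseq(contigs[[k]], s, s + size - 1L)), ""))
    ids <- c(ids, sprintf("%s:%d-%d", names(contigs)[k], starts - 1L,
                          starts - 1L + size))
  }
  DNAStringSet(setNames(frags, ids))
}

bestFragmentHit <- function(frag, subject_contigs, scoring) {
  best <- NULL
  for (k in seq_along(subject_contigs)) {
    for (strand in 1:2) {
      subj <- if (strand == 1) subject_contigs[[k]]
              else reverseComplement(subject_contigs[[k]])
      pa <- pairwiseAlignment(frag, subj,
                              substitutionMatrix = scoring$matrix,
                              gapOpening = scoring$gap_open,
                              gapExtension = scoring$gap_extend,
                              type = "local")
      s <- Biostrings::score(pa)
      if (is.null(best) || s > best$score) {
        ncols <- alnCols(pa)
        best <- list(score = s,
                     identity = 100 * nmatch(pa) / ncols,
                     frag_cov = (end(Biostrings::pattern(pa)) -
                                 start(Biostrings::pattern(pa)) + 1) /
                       length(frag))
      }
    }
  }
  best
}

#' Fragment-based average nucleotide identity between two genomes
#'
#' Each fixed-size fragment of the query genome is locally aligned against
#' every contig of the subject (both strands, best score kept). Hits are
#' retained when identity (computed over alignment columns, gaps counting as
#' mismatches) is at least `min_identity` percent over at least
#' `min_coverage` of the fragment length; the one-directional ANI is the
#' mean identity of retained hits. The symmetric ANI is the mean of the two
#' directions, and a pair is called a distinct species when it falls below
#' `species_boundary` (95 by convention).
#'
#' @param a,b [Biostrings::DNAStringSet] contigs of the two genomes
#' @param fragment_size window size in bp (default 1020)
#' @param min_identity retained-hit identity threshold, percent (default 30)
#' @param min_coverage retained-hit fragment-coverage threshold (default 0.7)
#' @param species_boundary symmetric-ANI species cutoff, percent (default 95)
#' @param scoring nucleotide scoring scheme (match 2 / mismatch -3, affine
#'   gaps 5/2 by default)
#' @return list with `ani_pct` (symmetric mean; `NA` when no hits pass in
#'   either direction), `ani_ab`, `ani_ba`, `n_fragments_a`, `n_fragments_b`,
#'   `n_hits_ab`, `n_hits_ba`, `distinct_species`
#' @export
aniPair <- function(a, b, fragment_size = 1020, min_identity = 30,
                    min_coverage = 0.7, species_boundary = 95,
                    scoring = aniScoring()) {
  if (is.character(a)) a <- DNAStringSet(a)
  if (is.character(b)) b <- DNAStringSet(b)
  if (!length(a) || !length(b)) stop("both genomes must be non-empty")
  oneDir <- function(q, s) {
    frags <- fragmentGenome(q, fragment_size)
    ids <- numeric(0)
    for (i in seq_along(frags)) {
      hit <- bestFragmentHit(frags[[i]], s, scoring)
      if (!is.null(hit) && hit$identity >= min_identity &&
          hit$frag_cov >= min_coverage)
        ids <- c(ids, hit$identity)
    }
    list(n_fragments = length(frags), n_hits = length(ids),
         ani = if (length(ids)) mean(ids) else NA_real_)
  }
  ab <- oneDir(a, b)
  ba <- oneDir(b, a)
  both <- c(ab$ani, ba$ani)
  ani <- if (all(is.na(both))) NA_real_ else mean(both, na.rm = TRUE)
  list(ani_pct = ani, ani_ab = ab$ani, ani_ba = ba$ani,
       n_fragments_a = ab$n_fragments, n_fragments_b = ba$n_fragments,
       n_hits_ab = ab$n_hits, n_hits_ba = ba$n_hits,
       distinct_species = if (is.na(ani)) NA else ani < species_boundary)
}

#' Pairwise ANI matrix over a genome set
#'
#' @param gs a [GenomeSet-class] with contigs
#' @param ... passed to [aniPair()]
#' @return symmetric matrix of symmetric ANI percentages (diagonal 100)
#' @export
aniMatrix <- function(gs, ...) {
  ids <- names(contigs(gs))
  M <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(ids, ids))
  diag(M) <- 100
  if (length(ids) > 1)
    for (i in seq_len(length(ids) - 1)) for (j in seq.int(i + 1, length(ids))) {
      r <- aniPair(contigs(gs, ids[i]), contigs(gs, ids[j]), ...)
      M[i, j] <- M[j, i] <- r$ani_pct
    }
  M
}
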