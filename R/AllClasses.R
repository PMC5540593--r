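#' @import methods
#' @importFrom Biostrings DNAStringSet AAStringSet readDNAStringSet
#'   readAAStringSet writeXStringSet alphabetFrequency pairwiseAlignment
#'   nmatch pid reverseComplement nucleotideSubstitutionMatrix
#' @importFrom IRanges start end width
#' @importFrom stats lm coef rpois runif rbinom setNames
#' @importFrom utils read.delim write.table
NULL

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

#' Container for a set of annotated genomes
#'
#' A `GenomeSet` holds, for each genome in a comparative analysis, its
#' assembled contigs (nucleotide), its predicted proteome (amino acid), an
#' optional per-gene annotation table, and a per-genome summary row
#' (size, GC content, ORF count, rRNA/tRNA counts, group membership).
#' Contigs and proteins may be absent (e.g. when only printed summary
#' statistics are analysed); when present they must agree with the stored
#' summary statistics.
#'
#' @slot info data.frame with one row per genome; columns `genome_id`,
#'   `label`, `group` (one of `"bifidobacterium"`, `"other_genus"`),
#'   `size_bp`, `gc_percent`, `orf_count`, `rrna_loci`, `trna_count`.
#' @slot contigs named list of [Biostrings::DNAStringSet], one per genome
#'   (possibly empty list).
#' @slot proteins named list of [Biostrings::AAStringSet], one per genome;
#'   element names are gene ids, unique within the genome.
#' @slot annotations data.frame with columns `gene_id`, `genome_id` and any
#'   of `gh_family`, `cog_category`, `mobile_element`, `gene_name`.
#'
#' @seealso [GenomeSet()] for the constructor, [readGenomeSet()] for
#'   building one from FASTA/TSV files.
#' @export
setClass("GenomeSet",
  representation(info = "data.frame", contigs = "list",
                 proteins = "list", annotations = "data.frame"))

setValidity("GenomeSet", function(object) {
  msg <- character()
  need <- c("genome_id", "label", "group", "size_bp", "gc_percent",
            "orf_count", "rrna_loci", "trna_count")
  miss <- setdiff(need, colnames(object@info))
  if (length(miss))
    msg <- c(msg, paste("info lacks columns:", paste(miss, collapse = ", ")))
  ids <- object@info$genome_id
  if (anyDuplicated(ids)) msg <- c(msg, "duplicated genome_id in info")
  if (length(object@contigs) &&
      !all(names(object@contigs) %in% ids))
    msg <- c(msg, "contigs named by unknown genome ids")
  if (length(object@proteins) &&
      !all(names(object@proteins) %in% ids))
    msg <- c(msg, "proteins named by unknown genome ids")
  for (g in names(object@proteins)) {
    aa <- object@proteins[[g]]
    if (anyDuplicated(names(aa)))
      msg <- c(msg, paste0("duplicated gene ids in genome ", g))
    freq <- alphabetFrequency(aa)
    bad <- rowSums(freq[, setdiff(colnames(freq), c(AA20, "X")),
                        drop = FALSE])
    if (any(bad > 0))
      msg <- c(msg, paste0("non amino-acid residues in proteins of ", g))
    if (any(width(aa) == 0))
      msg <- c(msg, paste0("empty protein sequence in ", g))
    n <- object@info$orf_count[match(g, ids)]
    if (!is.na(n) && n != length(aa))
      msg <- c(msg, paste0("orf_count disagrees with proteome size for ", g))
  }
  for (g in names(object@contigs)) {
    dn <- object@contigs[[g]]
    freq <- alphabetFrequency(dn)
    bad <- rowSums(freq[, setdiff(colnames(freq), c("A","C","G","T","N")),
                        drop = FALSE])
    if (any(bad > 0))
      msg <- c(msg, paste0("non-nucleotide characters in contigs of ", g))
    i <- match(g, ids)
    if (!is.na(object@info$size_bp[i]) &&
        object@info$size_bp[i] != sum(width(dn)))
      msg <- c(msg, paste0("size_bp disagrees with contig lengths for ", g))
    if (!is.na(object@info$gc_percent[i])) {
      gc <- computeGenomeStats(dn)$gc_percent
      if (abs(gc - object@info$gc_percent[i]) > 0.01)
        msg <- c(msg, paste0("gc_percent disagrees with contigs for ", g))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Clusters of orthologous groups over a set of genomes
#'
#' Result of Markov clustering of the all-vs-all protein similarity graph:
#' a partition of every gene into families (COGs). Genes that fall in no
#' multi-member cluster are kept as singleton families.
#'
#' @slot families named list; each element is a character vector of gene ids
#'   (ids are `genome|gene` keys, globally unique).
#' @slot geneGenome named character vector mapping each gene id to its
#'   genome id.
#' @export
setClass("CogFamilySet",
  representation(families = "list", geneGenome = "character"))

setValidity("CogFamilySet", function(object) {
  genes <- unlist(object@families, use.names = FALSE)
  if (anyDuplicated(genes))
    return("families do not partition genes: duplicated membership")
  if (!all(genes %in% names(object@geneGenome)))
    return("family members missing from geneGenome map")
  if (is.null(names(object@families)) || anyDuplicated(names(object@families)))
    return("families must be uniquely named")
  TRUE
})

#' Family-by-genome presence/absence (count) matrix
#'
#' Integer matrix of per-family member counts per genome; the binary view
#' underlies pan/core/unique-gene partitioning and gain/loss reconstruction.
#'
#' @slot counts integer matrix, rows = families, columns = genomes, with
#'   dimnames set; every row has at least one positive entry.
#' @export
setClass("PAMatrix", representation(counts = "matrix"))

setValidity("PAMatrix", function(object) {
  m <- object@counts
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("counts must carry family and genome dimnames")
  if (any(m < 0)) return("negative counts")
  if (nrow(m) && any(rowSums(m) < 1))
    return("every family must be present in at least one genome")
  TRUE
})

#' Filtered protein similarity graph
#'
#' Undirected weighted graph over gene ids, built from reciprocal local
#' alignment hits that pass the e-value/identity/coverage thresholds.
#' Edge weights are `-log10(evalue)` capped at a maximum.
#'
#' @slot nodes character vector of gene ids (lexicographically sorted).
#' @slot edges data.frame with columns `from`, `to`, `weight`,
#'   `identity_pct`, `evalue`, `coverage_min` (one row per unordered pair).
#' @export
setClass("SimilarityGraph",
  representation(nodes = "character", edges = "data.frame"))

setValidity("SimilarityGraph", function(object) {
  e <- object@edges
  if (nrow(e)) {
    if (any(e$from == e$to)) return("self-loops are not allowed")
    if (any(e$weight <= 0)) return("edge weights must be positive")
    if (!all(c(e$from, e$to) %in% object@nodes))
      return("edge endpoints missing from node set")
  }
  TRUE
})
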