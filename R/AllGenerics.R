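#' @rdname GenomeSet-accessors
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))

#' @rdname GenomeSet-accessors
#' @export
setGeneric("genomeInfo", function(x) standardGeneric("genomeInfo"))

#' @rdname GenomeSet-accessors
#' @export
setGeneric("contigs", function(x, genome) standardGeneric("contigs"))

#' @rdname GenomeSet-accessors
#' @export
setGeneric("proteins", function(x, genome) standardGeneric("proteins"))

#' @rdname GenomeSet-accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname CogFamilySet-accessors
#' @export
setGeneric("families", function(x) standardGeneric("families"))

#' @rdname CogFamilySet-accessors
#' @export
setGeneric("familyOf", function(x) standardGeneric("familyOf"))

#' @rdname PAMatrix-accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname PAMatrix-accessors
#' @export
setGeneric("binary", function(object) standardGeneric("binary"))

#' Accessors for GenomeSet
#'
#' `genomeIds` returns the genome identifiers; `genomeInfo` the per-genome
#' summary data.frame; `contigs`/`proteins` the sequence sets of one genome
#' (or the full named list when `genome` is missing); `annotations` the
#' per-gene annotation table.
#'
#' @param x a [GenomeSet-class]
#' @param genome a genome id; when missing, the full named list is returned
#' @name GenomeSet-accessors
NULL

#' @rdname GenomeSet-accessors
setMethod("genomeIds", "GenomeSet", function(x) x@info$genome_id)

#' @rdname GenomeSet-accessors
setMethod("genomeInfo", "GenomeSet", function(x) x@info)

#' @rdname GenomeSet-accessors
setMethod("contigs", "GenomeSet", function(x, genome) {
  if (missing(genome)) return(x@contigs)
  x@contigs[[genome]]
})

#' @rdname GenomeSet-accessors
setMethod("proteins", "GenomeSet", function(x, genome) {
  if (missing(genome)) return(x@proteins)
  x@proteins[[genome]]
})

#' @rdname GenomeSet-accessors
setMethod("annotations", "GenomeSet", function(x) x@annotations)

setMethod("show", "GenomeSet", function(object) {
  cat("GenomeSet with", nrow(object@info), "genomes\n")
  ng <- table(object@info$group)
  cat("  groups:", paste(names(ng), ng, sep = "=", collapse = ", "), "\n")
  cat("  contigs for", length(object@contigs), "genomes; proteomes for",
      length(object@proteins), "genomes\n")
  if (nrow(object@annotations))
    cat("  annotations:", nrow(object@annotations), "gene records\n")
})

#' Accessors for CogFamilySet
#'
#' `families` returns the named list of member gene ids; `familyOf` the
#' inverse map (named character vector gene id -> family id).
#'
#' @param x a [CogFamilySet-class]
#' @name CogFamilySet-accessors
NULL

#' @rdname CogFamilySet-accessors
setMethod("families", "CogFamilySet", function(x) x@families)

#' @rdname CogFamilySet-accessors
setMethod("familyOf", "CogFamilySet", function(x) {
  fam <- rep(names(x@families), lengths(x@families))
  setNames(fam, unlist(x@families, use.names = FALSE))
})

setMethod("show", "CogFamilySet", function(object) {
  sz <- lengths(object@families)
  cat("CogFamilySet:", length(sz), "families over", sum(sz), "genes\n")
  cat("  family sizes: min", min(sz), "median", stats::median(sz),
      "max", max(sz), "\n")
})

#' Accessors for PAMatrix
#'
#' `counts` returns the integer family-by-genome member-count matrix;
#' `binary` the 0/1 presence view.
#'
#' @param object a [PAMatrix-class]
#' @name PAMatrix-accessors
NULL

#' @rdname PAMatrix-accessors
setMethod("counts", "PAMatrix", function(object) object@counts)

#' @rdname PAMatrix-accessors
setMethod("binary", "PAMatrix", function(object) {
  b <- object@counts
  b[b > 0] <- 1L
  storage.mode(b) <- "integer"
  b
})

setMethod("show", "PAMatrix", function(object) {
  m <- object@counts
  cat("PAMatrix:", nrow(m), "families x", ncol(m), "genomes\n")
  core <- sum(rowSums(m > 0) == ncol(m))
  uni <- sum(rowSums(m > 0) == 1)
  cat("  core families:", core, "; single-genome families:", uni, "\n")
})

setMethod("show", "SimilarityGraph", function(object) {
  cat("SimilarityGraph:", length(object@nodes), "genes,",
      nrow(object@edges), "edges\n")
})
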