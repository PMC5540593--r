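#' Build the family-by-genome presence/absence matrix
#'
#' @param famset a [CogFamilySet-class]
#' @param genomes character vector fixing the genome (column) order; defaults
#'   to the sorted set of genomes seen in the families
#' @return a [PAMatrix-class] of member counts
#' @export
buildMatrix <- function(famset, genomes = NULL) {
  gg <- famset@geneGenome
  if (is.null(genomes)) genomes <- sort(unique(unname(gg)))
  unknown <- setdiff(unique(unname(gg)), genomes)
  if (length(unknown))
    stop("genes reference unknown genomes: ", paste(unknown, collapse = ", "))
  fam <- families(famset)
  m <- matrix(0L, length(fam), length(genomes),
              dimnames = list(names(fam), genomes))
  for (f in names(fam)) {
    t0 <- table(gg[fam[[f]]])
    m[f, names(t0)] <- as.integer(t0)
  }
  new("PAMatrix", counts = m)
}

#' Core families: present in every genome
#'
#' The core genome is the set of families with at least one member in each
#' genome of the analysis.
#'
#' @param pam a [PAMatrix-class]
#' @return character vector of family ids
#' @export
coreFamilies <- function(pam) {
  b <- binary(pam)
  if (!nrow(b)) stop("empty matrix")
  rownames(b)[rowSums(b) == ncol(b)]
}

#' Truly unique genes (TUGs) per genome
#'
#' A TUG is any member gene of a family confined to exactly one genome;
#' single-genome paralog families contribute all their members.
#'
#' @param pam a [PAMatrix-class]
#' @param famset the [CogFamilySet-class] the matrix was built from
#' @return named list per genome: character vectors of gene ids, with a
#'   `counts` attribute (named integer vector)
#' @export
uniqueGenes <- function(pam, famset) {
  b <- binary(pam)
  gg <- famset@geneGenome
  fam <- families(famset)
  out <- setNames(vector("list", ncol(b)), colnames(b))
  for (g in colnames(b)) out[[g]] <- character(0)
  uniq <- rownames(b)[rowSums(b) == 1]
  for (f in uniq) {
    g <- colnames(b)[which(b[f, ] == 1)]
    out[[g]] <- c(out[[g]], fam[[f]])
  }
  attr(out, "counts") <- vapply(out, length, 0L)
  out
}

#' Pan/core accumulation curves over random genome orderings
#'
#' For each random permutation of genomes, tracks the cumulative pan-genome
#' size (union of families), core size (intersection) and number of new
#' families contributed at each step; reports per-step means and standard
#' deviations across permutations.
#'
#' @param pam a [PAMatrix-class]
#' @param n_orderings number of random permutations (default 100)
#' @param seed integer seed
#' @return data.frame of class `pan_curve` with columns `step`, `pan_mean`,
#'   `pan_sd`, `core_mean`, `core_sd`, `new_mean`
#' @export
panCurve <- function(pam, n_orderings = 100, seed = 1) {
  stopifnot(n_orderings >= 1)
  b <- binary(pam)
  ng <- ncol(b)
  pan <- core <- new <- matrix(0, n_orderings, ng)
  withr::with_seed(seed, {
    for (r in seq_len(n_orderings)) {
      ord <- sample.int(ng)
      seen <- rep(FALSE, nrow(b))
      inall <- rep(TRUE, nrow(b))
      for (k in seq_len(ng)) {
        pres <- b[, ord[k]] > 0
        new[r, k] <- sum(pres & !seen)
        seen <- seen | pres
        inall <- inall & pres
        pan[r, k] <- sum(seen)
        core[r, k] <- sum(inall)
      }
    }
  })
  out <- data.frame(step = seq_len(ng),
                    pan_mean = colMeans(pan),
                    pan_sd = apply(pan, 2, stats::sd),
                    core_mean = colMeans(core),
                    core_sd = apply(core, 2, stats::sd),
                    new_mean = colMeans(new))
  class(out) <- c("pan_curve", "data.frame")
  out
}

#' Open/closed pan-genome assessment
#'
#' Fits the decay of the mean number of new families per added genome as a
#' power law `k * N^(-alpha)` by least squares on the log-log scale (steps
#' `N >= 2`). The pan-genome is called open when `alpha <= 1` (the new-gene
#' stream diverges as genomes accumulate) and closed otherwise.
#'
#' @param curve output of [panCurve()]
#' @return list with `k`, `alpha`, `open` (logical) and the fitted values;
#'   an all-zero new-family stream is flagged closed with a degenerate fit
#' @export
fitOpenness <- function(curve) {
  stopifnot(nrow(curve) >= 4)
  d <- curve[curve$step >= 2, ]
  if (all(d$new_mean == 0))
    return(list(k = 0, alpha = Inf, open = FALSE, degenerate = TRUE))
  d <- d[d$new_mean > 0, ]
  fit <- lm(log(new_mean) ~ log(step), data = d)
  alpha <- -unname(coef(fit)[2])
  k <- exp(unname(coef(fit)[1]))
  list(k = k, alpha = alpha, open = alpha <= 1, degenerate = FALSE,
       fitted = data.frame(step = d$step,
                           fitted_new = k * d$step^(-alpha)))
}

#' Functional-category tally over a gene set
#'
#' Counts one-letter functional categories among the given genes; genes
#' without a category are reported separately as `unannotated`.
#'
#' @param gene_ids character vector of gene ids (`genome|gene` keys or raw
#'   ids matching the annotation table)
#' @param annotations data.frame with `gene_id`, `genome_id`, `cog_category`
#' @return list with `counts` (named integer per letter), `percent`
#'   (of annotated genes) and `unannotated`
#' @export
categoryTally <- function(gene_ids, annotations) {
  key <- paste0(annotations$genome_id, "|", annotations$gene_id)
  idx <- match(gene_ids, key)
  idx[is.na(idx)] <- match(gene_ids[is.na(idx)], annotations$gene_id)
  cat <- annotations$cog_category[idx]
  ann <- !is.na(cat) & cat != ""
  counts <- table(factor(cat[ann], levels = sort(unique(cat[ann]))))
  counts <- setNames(as.integer(counts), names(counts))
  pct <- if (sum(counts)) 100 * counts / sum(counts) else counts * 0
  list(counts = counts, percent = pct,
       unannotated = sum(!ann))
}

#' Write a presence/absence matrix as TSV
#'
#' @param pam a [PAMatrix-class]
#' @param path output TSV (dense); a sparse triplet file is written next to
#'   it when `sparse = TRUE`
#' @param sparse also emit `<path>.triplets.tsv`
#' @return invisibly, the path
#' @export
writeMatrix <- function(pam, path, sparse = FALSE) {
  m <- counts(pam)
  write.table(data.frame(family_id = rownames(m), m, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (sparse) {
    idx <- which(m > 0, arr.ind = TRUE)
    trip <- data.frame(family_id = rownames(m)[idx[, 1]],
                       genome_id = colnames(m)[idx[, 2]],
                       count = m[idx])
    write.table(trip, paste0(path, ".triplets.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
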