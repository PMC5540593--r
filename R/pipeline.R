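#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end analysis with the documented
#' defaults: similarity thresholds 1e-5 e-value / 50% identity / 50%
#' coverage, MCL inflation 1.5, p-distance NJ with midpoint rooting and 100
#' bootstrap replicates, 1020-bp ANI fragments with the 30%/70% hit filters
#' and the 95% species boundary, 100 pan-genome permutations.
#'
#' @param genomes a [GenomeSet-class] (or a manifest data.frame accepted by
#'   [readGenomeSet()])
#' @param outdir output directory
#' @param max_evalue,min_identity,min_coverage similarity-graph thresholds
#' @param inflation MCL inflation
#' @param distance_model `"p_distance"` or `"poisson"`
#' @param outgroup optional outgroup tips (midpoint rooting otherwise)
#' @param bootstrap_reps bootstrap replicates (0 disables bootstrap)
#' @param ani_fragment,ani_min_identity,ani_min_coverage,ani_boundary ANI
#'   stage options
#' @param run_ani run the (quadratic, alignment-heavy) ANI stage
#' @param n_orderings pan-curve permutations
#' @param seed integer seed propagated to every stochastic stage
#' @return list of class `run_config`
#' @export
runConfig <- function(genomes, outdir, max_evalue = 1e-5,
                      min_identity = 50, min_coverage = 0.5,
                      inflation = 1.5,
                      distance_model = "p_distance", outgroup = NULL,
                      bootstrap_reps = 100,
                      ani_fragment = 1020, ani_min_identity = 30,
                      ani_min_coverage = 0.7, ani_boundary = 95,
                      run_ani = TRUE, n_orderings = 100, seed = 1) {
  if (is.data.frame(genomes)) genomes <- readGenomeSet(genomes)
  stopifnot(is(genomes, "GenomeSet"))
  structure(as.list(environment()), class = "run_config")
}

tsvHeader <- function(path, cfg, stage) {
  cat(sprintf("# panphylo %s | seed=%d evalue<=%g identity>=%g coverage>=%g inflation=%g\n",
              stage, cfg$seed, cfg$max_evalue, cfg$min_identity,
              cfg$min_coverage, cfg$inflation), file = path)
  path
}

appendTable <- function(tab, path) {
  suppressWarnings(write.table(tab, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Run the full analysis end to end
#'
#' Genomes -> similarity graph -> MCL families -> presence/absence matrix ->
#' pan/core/unique partition with openness fit -> single-copy core supertree
#' with bootstrap -> ANI matrix -> Dollo gain/loss mapping, writing the
#' complete report bundle into `outdir`. Every file is deterministic for a
#' fixed config and seed; each table carries a `#` header recording seed and
#' thresholds. Stages that cannot run (fewer than 3 genomes for the tree, no
#' contigs for ANI) are skipped with an entry in `skipped`.
#'
#' @param config a [runConfig()] object
#' @return invisibly, a list with the in-memory stage results and `skipped`
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  gs <- cfg$genomes
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list(skipped = character(0))
  pth <- function(f) file.path(cfg$outdir, f)

  graph <- allVsAll(gs, max_evalue = cfg$max_evalue,
                    min_identity = cfg$min_identity,
                    min_coverage = cfg$min_coverage)
  writeHitsTable(graph, tsvHeader(pth("similarity.tsv"), cfg, "similarity"))
  fams <- mclCluster(graph, inflation = cfg$inflation)
  writeFamilies(fams, tsvHeader(pth("families.tsv"), cfg, "families"))
  pam <- buildMatrix(fams, genomes = genomeIds(gs))
  writeMatrix(pam, pth("matrix.tsv"), sparse = TRUE)
  out$graph <- graph; out$families <- fams; out$matrix <- pam

  curve <- panCurve(pam, n_orderings = cfg$n_orderings, seed = cfg$seed)
  appendTable(curve, tsvHeader(pth("pan_curve.tsv"), cfg, "pan_curve"))
  if (nrow(curve) >= 4) {
    open <- fitOpenness(curve)
  } else {
    open <- list(k = NA, alpha = NA, open = NA, degenerate = TRUE)
    out$skipped <- c(out$skipped, "openness: fewer than 4 genomes")
  }
  jsonlite::write_json(open[c("k", "alpha", "open", "degenerate")],
                       pth("openness.json"), auto_unbox = TRUE, digits = NA)
  core <- coreFamilies(pam)
  writeLines(core, pth("core_families.txt"))
  tugs <- uniqueGenes(pam, fams)
  tug_tab <- data.frame(genome_id = names(tugs),
                        n_tugs = attr(tugs, "counts"),
                        genes = vapply(tugs, paste, "", collapse = ","))
  appendTable(tug_tab, tsvHeader(pth("unique_genes.tsv"), cfg, "tugs"))
  out$pan_curve <- curve; out$openness <- open
  out$core <- core; out$tugs <- tugs

  if (length(genomeIds(gs)) < 3) {
    out$skipped <- c(out$skipped,
                     "supertree: fewer than 3 genomes")
  } else {
    scc <- selectSingleCopyCore(pam)
    if (length(scc) == 0) {
      out$skipped <- c(out$skipped, "supertree: no single-copy core family")
    } else {
      fmap <- familyOf(fams)
      gg <- fams@geneGenome
      prots <- do.call(c, unname(lapply(genomeIds(gs), function(g) {
        p <- proteins(gs, g); names(p) <- paste0(g, "|", names(p)); p
      })))
      alns <- lapply(setNames(scc, scc), function(f) {
        ids <- families(fams)[[f]]
        seqs <- prots[ids]
        names(seqs) <- gg[ids]
        progressiveAlign(seqs)
      })
      concat <- concatenateAlignments(alns, genomeIds(gs))
      writeXStringSet(concat, pth("core_concat_alignment.faa"))
      tree <- if (cfg$bootstrap_reps > 0)
        bootstrapSupport(concat, n_reps = cfg$bootstrap_reps,
                         seed = cfg$seed, model = cfg$distance_model)
      else njTree(alignmentDistances(concat, cfg$distance_model))
      rooted <- rootTree(tree, outgroup = cfg$outgroup)
      writeNewick(tree, pth("supertree_unrooted.nwk"))
      writeNewick(rooted, pth("supertree_rooted.nwk"))
      out$tree <- tree; out$rooted_tree <- rooted

      hist <- dolloReconstruct(rooted, pam)
      ev <- branchEvents(hist, rooted)
      writeBranchEvents(ev, pth("branch_events.tsv"), tree = rooted,
                        newick_path = pth("supertree_events.nwk"))
      ann <- annotations(gs)
      if (nrow(ann) && "gh_family" %in% colnames(ann)) {
        fam_gh <- familyGhLabels(fams, ann)
        gh_fams <- names(fam_gh)[!is.na(fam_gh)]
        ev_gh <- branchEvents(hist, rooted, subset = gh_fams)
        appendTable(ev_gh, tsvHeader(pth("branch_events_gh.tsv"), cfg,
                                     "gh_events"))
        hg <- names(fam_gh)[fam_gh %in% HOST_GLYCAN_GH]
        ev_hg <- branchEvents(hist, rooted, subset = hg)
        appendTable(ev_hg, tsvHeader(pth("branch_events_hostglycan.tsv"),
                                     cfg, "hostglycan_events"))
        out$gh_events <- ev_gh; out$hostglycan_events <- ev_hg
      }
      out$histories <- hist; out$branch_events <- ev
    }
  }

  if (!cfg$run_ani || length(contigs(gs)) < 2) {
    out$skipped <- c(out$skipped, "ani: disabled or fewer than 2 genomes with contigs")
  } else {
    M <- aniMatrix(gs, fragment_size = cfg$ani_fragment,
                   min_identity = cfg$ani_min_identity,
                   min_coverage = cfg$ani_min_coverage,
                   species_boundary = cfg$ani_boundary)
    appendTable(data.frame(genome_id = rownames(M), M, check.names = FALSE),
                tsvHeader(pth("ani_matrix.tsv"), cfg, "ani"))
    out$ani <- M
  }

  stab <- summaryTable(gs)
  writeSummaryTable(stab, pth("genome_summary.tsv"))
  summary <- list(
    seed = cfg$seed, n_genomes = length(genomeIds(gs)),
    n_families = length(families(fams)),
    n_core = length(core),
    n_single_copy_core = if (!is.null(out$tree))
      length(selectSingleCopyCore(pam)) else 0L,
    n_tugs = sum(attr(tugs, "counts")),
    pan_open = open$open, openness_alpha = open$alpha,
    mean_genome_size_bp = mean(stab$size_bp),
    mean_gc_percent = mean(stab$gc_percent),
    skipped = out$skipped)
  jsonlite::write_json(summary, pth("summary.json"),
                       auto_unbox = TRUE, digits = NA)
  out$summary <- summary
  invisible(out)
}

#' Majority GH label per family
#'
#' Assigns each family the most frequent non-missing `gh_family` annotation
#' among its member genes (`NA` when none is annotated); ties resolve to the
#' alphabetically first label.
#'
#' @param famset a [CogFamilySet-class]
#' @param ann annotation data.frame with `gene_id`, `genome_id`, `gh_family`
#' @return named character vector over families
#' @export
familyGhLabels <- function(famset, ann) {
  key <- paste0(ann$genome_id, "|", ann$gene_id)
  gh <- setNames(ann$gh_family, key)
  vapply(families(famset), function(genes) {
    v <- gh[genes]
    v <- v[!is.na(v) & v != ""]
    if (!length(v)) return(NA_character_)
    t0 <- sort(table(v), decreasing = TRUE)
    names(t0)[1]
  }, "")
}
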