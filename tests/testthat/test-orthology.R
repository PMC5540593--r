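test_that("self-alignment has full identity and coverage", {
  withr::with_seed(1, p <- randProt(80))
  h <- alignPair(p, p)
  expect_equal(h$identity_pct, 100, ignore_attr = TRUE)
  expect_equal(h$coverage_q, 1)
  expect_equal(h$coverage_s, 1)
  expect_error(alignPair("", "MKL"), "empty")
  expect_error(alignPair("MK1L", "MKL"), "invalid residues")
})

test_that("local alignment scores match an independent DP oracle", {
  expect_equal(alignPair("HEAGAWGHEE", "PAWHEAE")$score,
               oracleLocalScore("HEAGAWGHEE", "PAWHEAE"))
  withr::with_seed(20, {
    for (k in 1:12) {
      a <- randProt(sample(20:60, 1))
      b <- if (k %% 2) mutateProt(a, 0.3) else randProt(sample(20:60, 1))
      h <- alignPair(a, b)
      got <- if (is.null(h)) 0 else h$score
      expect_equal(got, oracleLocalScore(a, b), info = paste("pair", k))
    }
  })
})

test_that("ortholog identity tracks the substitution load", {
  withr::with_seed(8, {
    a <- randProt(150)
    b <- mutateProt(a, 0.2)
  })
  h <- alignPair(a, b)
  expect_lt(abs(h$identity_pct - 80), 3)
})

test_that("the similarity graph applies all three filters", {
  withr::with_seed(30, {
    base <- randProt(200)
    near <- mutateProt(base, 0.40)   # ~60% identity: passes
    far <- mutateProt(base, 0.60)    # ~40% identity: fails
  })
  gs <- GenomeSet(data.frame(genome_id = c("gA", "gB")),
                  proteins = list(
                    gA = Biostrings::AAStringSet(c(x1 = base)),
                    gB = Biostrings::AAStringSet(c(y1 = near, y2 = far))))
  g <- allVsAll(gs)
  pairs <- paste(g@edges$from, g@edges$to)
  expect_true("gA|x1 gB|y1" %in% pairs)
  expect_false(any(grepl("y2", pairs)))
})

test_that("identical proteomes connect gene-for-gene at capped weight", {
  withr::with_seed(40, prots <- vapply(1:5, function(i) randProt(400), ""))
  aa <- Biostrings::AAStringSet(setNames(prots, sprintf("p%d", 1:5)))
  gs <- GenomeSet(data.frame(genome_id = c("gA", "gB")),
                  proteins = list(gA = aa, gB = aa))
  g <- allVsAll(gs)
  cross <- g@edges[g@edges$identity_pct == 100, ]
  expect_equal(nrow(cross), 5)
  expect_true(all(cross$weight == 200))
})

test_that("the graph equals brute-force filtering of every pair", {
  sim <- simulateGenomes(simConfig(n_leaves = 4, root_family_count = 8,
                                   gain_rate = 1, loss_rate = 0.1,
                                   prot_sub_rate = 0.03, mean_prot_len = 70,
                                   genome_len = 1200, seed = 55))
  gs <- sim$genomes
  g <- allVsAll(gs)
  got <- sort(paste(pmin(g@edges$from, g@edges$to),
                    pmax(g@edges$from, g@edges$to)))
  ids <- unlist(lapply(genomeIds(gs), function(gg)
    paste0(gg, "|", names(proteins(gs, gg)))))
  seqs <- setNames(unlist(lapply(genomeIds(gs), function(gg)
    as.character(proteins(gs, gg)))), ids)
  want <- character(0)
  for (i in seq_len(length(ids) - 1)) for (j in seq.int(i + 1, length(ids))) {
    h <- alignPair(seqs[[i]], seqs[[j]])
    if (!is.null(h) && h$evalue <= 1e-5 && h$identity_pct >= 50 &&
        min(h$coverage_q, h$coverage_s) >= 0.5)
      want <- c(want, paste(min(ids[i], ids[j]), max(ids[i], ids[j])))
  }
  expect_setequal(got, sort(want))
})

test_that("MCL recovers disconnected cliques and preserves singletons", {
  cl <- function(p, w) {
    e <- t(combn(p, 2))
    data.frame(from = e[, 1], to = e[, 2], weight = w)
  }
  edges <- rbind(cl(paste0("a", 1:4), 10), cl(paste0("b", 1:4), 10))
  nodes <- c(paste0("a", 1:4), paste0("b", 1:4), "solo")
  g <- new("SimilarityGraph", nodes = nodes, edges = edges)
  fams <- mclCluster(g)
  got <- unname(lapply(families(fams), sort))
  expect_setequal(got, list(paste0("a", 1:4), paste0("b", 1:4), "solo"))
  # matches the connected-component oracle on disconnected structures
  orc <- oracleComponents(nodes, edges$from, edges$to)
  expect_setequal(got, unname(lapply(orc, sort)))
})

test_that("MCL severs a weak bridge between cliques at inflation 1.5", {
  cl <- function(p, w) {
    e <- t(combn(p, 2))
    data.frame(from = e[, 1], to = e[, 2], weight = w)
  }
  edges <- rbind(cl(paste0("a", 1:4), 10), cl(paste0("b", 1:4), 10),
                 data.frame(from = "a1", to = "b1", weight = 1))
  g <- new("SimilarityGraph", nodes = c(paste0("a", 1:4), paste0("b", 1:4)),
           edges = edges)
  fams <- mclCluster(g, inflation = 1.5)
  expect_setequal(unname(lapply(families(fams), sort)),
                  list(paste0("a", 1:4), paste0("b", 1:4)))
})

test_that("families partition the gene universe", {
  sim <- simulateGenomes(simConfig(n_leaves = 5, root_family_count = 10,
                                   gain_rate = 2, loss_rate = 0.1,
                                   mean_prot_len = 60, genome_len = 1200,
                                   seed = 66))
  fams <- mclCluster(allVsAll(sim$genomes))
  genes <- unlist(families(fams))
  expect_equal(length(genes),
               sum(vapply(proteins(sim$genomes), length, 0L)))
  expect_false(anyDuplicated(genes) > 0)
})

test_that("clustering is invariant under gene relabeling", {
  cl <- function(p, w) {
    e <- t(combn(p, 2))
    data.frame(from = e[, 1], to = e[, 2], weight = w)
  }
  nodes <- c(paste0("a", 1:3), paste0("b", 1:3))
  edges <- rbind(cl(paste0("a", 1:3), 8), cl(paste0("b", 1:3), 12))
  g1 <- new("SimilarityGraph", nodes = nodes, edges = edges)
  # relabel: z-prefix reverses the lexicographic processing order
  map <- setNames(paste0("z", rev(seq_along(nodes))), nodes)
  g2 <- new("SimilarityGraph", nodes = unname(map[nodes]),
            edges = transform(edges, from = unname(map[from]),
                              to = unname(map[to])))
  f1 <- lapply(families(mclCluster(g1)), function(x) sort(unname(map[x])))
  f2 <- lapply(families(mclCluster(g2)), sort)
  expect_setequal(unname(f1), unname(f2))
})

test_that("hit tables and family tables are written in tabular layout", {
  withr::with_seed(70, p <- randProt(80))
  gs <- GenomeSet(data.frame(genome_id = c("gA", "gB")),
                  proteins = list(
                    gA = Biostrings::AAStringSet(c(x = p)),
                    gB = Biostrings::AAStringSet(c(y = mutateProt(p, 0.1)))))
  g <- allVsAll(gs)
  hp <- tempfile(fileext = ".tsv")
  writeHitsTable(g, hp)
  tab <- read.delim(hp)
  expect_equal(ncol(tab), 12)
  expect_equal(tab$query, "gA|x")
  fams <- mclCluster(g)
  fp <- tempfile(fileext = ".tsv")
  writeFamilies(fams, fp)
  expect_equal(read.delim(fp)$members, "gA|x,gB|y")
})
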