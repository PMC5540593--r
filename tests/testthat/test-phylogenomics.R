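test_that("single-copy core selection keeps exactly-one-per-genome rows", {
  m <- matrix(c(1, 1, 1,
                2, 1, 1,
                1, 0, 1), ncol = 3, byrow = TRUE,
              dimnames = list(c("F1", "F2", "F3"), c("a", "b", "c")))
  pam <- new("PAMatrix", counts = m)
  expect_equal(selectSingleCopyCore(pam), "F1")
  withr::with_seed(4, {
    r <- matrix(rpois(80, 0.9), nrow = 20,
                dimnames = list(sprintf("F%02d", 1:20), paste0("g", 1:4)))
  })
  r <- r[rowSums(r) > 0, ]
  pam2 <- new("PAMatrix", counts = r)
  oracle <- rownames(r)[apply(r, 1, function(x) all(x == 1))]
  expect_equal(selectSingleCopyCore(pam2), oracle)
})

test_that("progressive alignment handles identity and single-gap cases", {
  same <- Biostrings::AAStringSet(c(a = "MKLV", b = "MKLV", c = "MKLV"))
  aln <- progressiveAlign(same)
  expect_false(any(grepl("-", as.character(aln))))
  two <- progressiveAlign(Biostrings::AAStringSet(c(a = "ACDE", b = "ACE")))
  expect_equal(unname(nchar(as.character(two))), c(4L, 4L))
  expect_equal(sum(strsplit(paste(as.character(two), collapse = ""),
                            "")[[1]] == "-"), 1)
  # ungapped rows reproduce the inputs
  expect_equal(gsub("-", "", as.character(two)[["b"]]), "ACE")
})

test_that("pairwise progressive alignment scores match the global DP oracle", {
  scoreAln <- function(aln, open = 11, ext = 1) {
    a <- strsplit(as.character(aln)[1], "")[[1]]
    b <- strsplit(as.character(aln)[2], "")[[1]]
    s <- 0
    for (k in seq_along(a))
      if (a[k] != "-" && b[k] != "-") s <- s + blosum62[a[k], b[k]]
    for (row in list(a, b)) {
      r <- rle(row == "-")
      gaps <- r$lengths[r$values]
      s <- s - sum(open + ext * gaps)
    }
    s
  }
  withr::with_seed(61, {
    for (k in 1:6) {
      a <- randProt(30)
      b <- mutateProt(a, 0.2)
      if (k > 3) b <- paste0(substr(b, 1, 12), substr(b, 16, 30))  # deletion
      aln <- progressiveAlign(Biostrings::AAStringSet(c(x = a, y = b)))
      expect_equal(scoreAln(aln), oracleGlobalScore(a, b),
                   info = paste("pair", k))
    }
  })
})

test_that("low-divergence families align nearly column-identical", {
  sim <- simulateGenomes(simConfig(n_leaves = 6, root_family_count = 5,
                                   gain_rate = 0, loss_rate = 0,
                                   prot_sub_rate = 0.02, genome_len = 1200,
                                   seed = 19))
  gs <- sim$genomes
  f <- names(sim$truth$leaf_membership)[1]
  mem <- sim$truth$leaf_membership[[f]]
  seqs <- Biostrings::AAStringSet(vapply(seq_len(nrow(mem)), function(i)
    as.character(proteins(gs, mem$genome[i])[[mem$gene[i]]]), ""))
  names(seqs) <- mem$genome
  aln <- progressiveAlign(seqs)
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  col_ident <- mean(apply(m, 2, function(col) length(unique(col)) == 1))
  expect_gte(col_ident, 0.6)  # ~2% per unit branch over <= ~8 units of path
})

test_that("concatenation is row-wise in fixed order and checks taxa", {
  a1 <- Biostrings::AAStringSet(c(x = "AAAAA", y = "CCCCC"))
  a2 <- Biostrings::AAStringSet(c(y = "DD-DD", x = "EEEEE"))
  cc <- concatenateAlignments(list(F1 = a1, F2 = a2), c("x", "y"))
  expect_equal(as.character(cc),
               c(x = "AAAAAEEEEE", y = "CCCCCDD-DD"))
  expect_equal(as.character(concatenateAlignments(list(F1 = a1),
                                                  c("x", "y"))),
               as.character(a1))
  expect_error(concatenateAlignments(list(F1 = a1[1]), c("x", "y")),
               "missing taxon y")
  # family order permutes columns but not the distances
  d1 <- alignmentDistances(cc)
  d2 <- alignmentDistances(
    concatenateAlignments(list(F2 = a2, F1 = a1), c("x", "y")))
  expect_equal(d1, d2)
})

test_that("alignment distances use gap-free columns and closed forms", {
  aln <- Biostrings::AAStringSet(c(a = paste(rep("A", 100), collapse = ""),
                                   b = paste(c(rep("A", 95), rep("C", 5)),
                                             collapse = "")))
  D <- alignmentDistances(aln)
  expect_equal(D["a", "b"], 0.05)
  Dp <- alignmentDistances(aln, model = "poisson")
  expect_equal(Dp["a", "b"], -log(0.95))
  expect_equal(round(Dp["a", "b"], 4), 0.0513)
  same <- Biostrings::AAStringSet(c(a = "MKL", b = "MKL"))
  expect_true(all(alignmentDistances(same) == 0))
  gappy <- Biostrings::AAStringSet(c(a = "AA--", b = "--AA"))
  expect_error(alignmentDistances(gappy), "no comparable columns")
})

test_that("three-taxon NJ solves the three-point equations exactly", {
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, dimnames = list(c("a", "b", "c"),
                                             c("a", "b", "c")))
  tr <- njTree(d)
  expect_equal(ape::Ntip(tr), 3)
  # v_a = (3+4-5)/2 = 1, v_b = 2, v_c = 3
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("a", "b", "c")], c(a = 1, b = 2, c = 3))
  expect_error(njTree(matrix(c(0, 1, 1, 0), 2, 2,
                             dimnames = list(c("a", "b"), c("a", "b")))),
               "three taxa")
  asym <- d; asym[1, 2] <- 9
  expect_error(njTree(asym), "symmetric")
})

test_that("NJ recovers random additive trees exactly", {
  withr::with_seed(100, {
    for (k in 1:25) {
      n <- sample(5:12, 1)
      true <- ape::rtree(n)
      true$edge.length <- runif(nrow(true$edge), 0.1, 2)
      D <- cophenetic(true)
      est <- njTree(D)
      expect_equal(phangorn::RF.dist(ape::unroot(true), est), 0,
                   info = paste("tree", k))
      expect_lt(max(abs(cophenetic(est)[rownames(D), colnames(D)] - D)),
                1e-6)
    }
  })
})

test_that("NJ agrees with an independent implementation on noisy input", {
  withr::with_seed(101, {
    true <- ape::rtree(9)
    D <- cophenetic(true) + matrix(runif(81, 0, 0.01), 9)
  })
  D <- (D + t(D)) / 2; diag(D) <- 0
  expect_equal(phangorn::RF.dist(njTree(D), ape::nj(D)), 0)
})

test_that("equidistant taxa resolve deterministically and flag the tie", {
  d <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  t1 <- njTree(d)
  t2 <- njTree(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_gte(attr(t1, "tie_count"), 1)
})

test_that("Newick write-read-write is byte-stable", {
  withr::with_seed(102, tr <- ape::rtree(12))
  p1 <- tempfile(fileext = ".nwk"); p2 <- tempfile(fileext = ".nwk")
  writeNewick(tr, p1)
  writeNewick(readNewick(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- readNewick(p1)
  expect_setequal(back$tip.label, tr$tip.label)
})

test_that("bootstrap saturates on clean signal and is binary at one rep", {
  withr::with_seed(103, {
    a <- randProt(120)
    b <- mutateProt(a, 0.05)
    c2 <- randProt(120)
    d2 <- mutateProt(c2, 0.05)
  })
  aln <- progressiveAlign(Biostrings::AAStringSet(
    c(t1 = a, t2 = b, t3 = c2, t4 = d2)))
  tr <- bootstrapSupport(aln, n_reps = 30, seed = 5)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
  one <- bootstrapSupport(aln, n_reps = 1, seed = 6)
  s1 <- suppressWarnings(as.numeric(one$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))
})

test_that("perfectly conflicting signal yields weak supports", {
  # two column blocks supporting incompatible splits of four taxa: each
  # bootstrap replicate is decided by the sampled block majority, so the
  # internal split cannot approach full support
  blk <- function(x) paste(rep(x, 40), collapse = "")
  aln <- Biostrings::AAStringSet(c(
    t1 = paste0(blk("A"), blk("G")),
    t2 = paste0(blk("A"), blk("T")),
    t3 = paste0(blk("C"), blk("G")),
    t4 = paste0(blk("C"), blk("T"))))
  tr <- bootstrapSupport(aln, n_reps = 50, seed = 7)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] < 90))
})

test_that("midpoint rooting and outgroup rooting both root the tree", {
  withr::with_seed(105, tr <- ape::unroot(ape::rtree(6)))
  expect_true(ape::is.rooted(rootTree(tr)))
  out <- rootTree(tr, outgroup = "t1")
  expect_true(ape::is.rooted(out))
  kids <- out$edge[out$edge[, 1] == ape::Ntip(out) + 1, 2]
  expect_true(match("t1", out$tip.label) %in% kids)
})
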