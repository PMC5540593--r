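labTree <- function(txt) {
  tr <- ape::read.tree(text = txt)
  tr$node.label <- sprintf("n%d", ape::Ntip(tr) + seq_len(tr$Nnode))
  tr
}

test_that("trivial presence patterns reconstruct as expected", {
  tr <- labTree("((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
  h <- dolloReconstruct(tr, list(
    all = c("A", "B", "C", "D", "E"),
    one = "D",
    cherry = c("A", "B")))
  expect_equal(h$all$gain_branch, "root")
  expect_length(h$all$loss_branches, 0)
  expect_equal(h$one$gain_branch, "D")
  expect_length(h$one$loss_branches, 0)
  expect_equal(h$cherry$gain_branch, "n7")
  expect_length(h$cherry$loss_branches, 0)
  expect_error(dolloReconstruct(tr, list(bad = character(0))), "no leaf")
  expect_error(dolloReconstruct(tr, list(bad = "Z")), "not in tree")
  expect_error(dolloReconstruct(ape::unroot(tr), list(f = "A")), "rooted")
})

test_that("the worked five-leaf case matches the exhaustive oracle", {
  tr <- labTree("((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
  h <- dolloReconstruct(tr, list(f = c("A", "B", "D")))[["f"]]
  orc <- oracleDollo(tr, c("A", "B", "D"))
  expect_equal(h$gain_branch, orc$gain_branch)
  expect_equal(sort(h$loss_branches), orc$loss_branches)
  expect_equal(length(h$loss_branches), orc$losses)
})

test_that("reconstruction equals exhaustive minimum-loss search", {
  withr::with_seed(50, {
    for (rep in 1:10) {
      n <- sample(4:7, 1)
      tr <- ape::rtree(n, tip.label = LETTERS[1:n])
      tr$node.label <- sprintf("n%d", n + seq_len(tr$Nnode))
      for (p in 1:10) {
        pres <- LETTERS[1:n][runif(n) < 0.5]
        if (!length(pres)) next
        h <- dolloReconstruct(tr, list(f = pres))[["f"]]
        orc <- oracleDollo(tr, pres)
        expect_equal(h$gain_branch, orc$gain_branch,
                     info = paste(rep, p))
        expect_equal(sort(h$loss_branches), orc$loss_branches,
                     info = paste(rep, p))
      }
    }
  })
})

test_that("monophyletic presence yields zero losses", {
  withr::with_seed(51, tr <- ape::rtree(8))
  tr$node.label <- sprintf("n%d", 8 + seq_len(tr$Nnode))
  desc <- phangorn::Descendants(tr, type = "tips")
  for (node in (ape::Ntip(tr) + 1):(ape::Ntip(tr) + tr$Nnode)) {
    clade <- tr$tip.label[desc[[node]]]
    h <- dolloReconstruct(tr, list(f = clade))[["f"]]
    expect_length(h$loss_branches, 0)
  }
})

test_that("states are Dollo-consistent: no loss above the gain, one gain", {
  withr::with_seed(52, tr <- ape::rtree(7))
  tr$node.label <- sprintf("n%d", 7 + seq_len(tr$Nnode))
  pres <- c("t1", "t3", "t5")
  h <- dolloReconstruct(tr, list(f = intersect(pres, tr$tip.label)))[["f"]]
  st <- h$ancestral_states
  # losses only on branches whose parent is present
  edges <- tr$edge
  labs <- c(tr$tip.label, tr$node.label)
  for (b in h$loss_branches) {
    e <- which(labs[edges[, 2]] == b)
    expect_true(st[labs[edges[e, 1]]])
    expect_false(st[b])
  }
  # leaves match observations
  expect_setequal(names(st[tr$tip.label])[st[tr$tip.label]],
                  intersect(pres, tr$tip.label))
})

test_that("branch events aggregate gains and losses per branch", {
  tr <- labTree("((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
  pres <- list(f1 = c("A", "B", "D"), f2 = "C", f3 = LETTERS[1:5])
  h <- dolloReconstruct(tr, pres)
  ev <- branchEvents(h, tr)
  expect_equal(sum(ev$n_gains), 3)  # one gain per family
  expect_equal(ev$n_gains[ev$branch == "root"], 2)
  expect_equal(ev$n_gains[ev$branch == "C"], 1)
  expect_equal(sum(ev$n_losses), 2)  # f1 loses C and E
  # disjoint one-per-leaf families put one gain on every terminal branch
  solo <- dolloReconstruct(tr, setNames(as.list(LETTERS[1:5]),
                                        paste0("u", 1:5)))
  evs <- branchEvents(solo, tr)
  expect_true(all(evs$n_gains[evs$branch %in% LETTERS[1:5]] == 1))
  # subsets restrict, unknown names warn, empty subset zeroes out
  ev_sub <- branchEvents(h, tr, subset = c("f2"))
  expect_equal(sum(ev_sub$n_gains), 1)
  expect_warning(branchEvents(h, tr, subset = c("f2", "ghost")), "unknown")
  ev_none <- branchEvents(h, tr, subset = character(0))
  expect_equal(sum(ev_none$n_gains) + sum(ev_none$n_losses), 0)
})

test_that("without losses every reconstructed gain sits on the true branch", {
  sim <- simulateGenomes(simConfig(n_leaves = 7, root_family_count = 10,
                                   gain_rate = 3, loss_rate = 0,
                                   genome_len = 1200, seed = 53))
  truth <- sim$truth
  h <- dolloReconstruct(truth$tree, truthPresenceMatrix(truth))
  for (f in names(h)) {
    expect_equal(h[[f]]$gain_branch, unname(truth$family_origin[f]),
                 info = f)
    expect_length(h[[f]]$loss_branches, 0)
  }
})

test_that("with losses, gains are recovered for all Dollo-recoverable families", {
  sim <- simulateGenomes(simConfig(n_leaves = 8, root_family_count = 15,
                                   gain_rate = 2, loss_rate = 0.15,
                                   genome_len = 1200, seed = 54))
  truth <- sim$truth
  tree <- truth$tree
  pam <- truthPresenceMatrix(truth)
  h <- dolloReconstruct(tree, pam)
  labs <- c(tree$tip.label, tree$node.label)
  bin <- binary(pam)
  n_checked <- 0
  for (f in rownames(bin)) {
    org <- truth$family_origin[[f]]
    present <- colnames(bin)[bin[f, ] > 0]
    # recoverable: surviving leaves still span the origin's full clade MRCA
    org_node <- if (org == "root") ape::Ntip(tree) + 1 else match(org, labs)
    mrca <- if (length(present) == 1) match(present, tree$tip.label)
            else ape::getMRCA(tree, present)
    if (mrca == org_node) {
      n_checked <- n_checked + 1
      expect_equal(h[[f]]$gain_branch, org, info = f)
    }
  }
  expect_gt(n_checked, 5)
})

test_that("leaf GH counts mirror the annotation table", {
  sim <- simulateGenomes(simConfig(n_leaves = 5, root_family_count = 10,
                                   gain_rate = 1, loss_rate = 0,
                                   gh_fraction = 0.4, genome_len = 1200,
                                   seed = 55))
  counts <- leafGhCounts(sim$genomes, sim$truth$tree)
  ann <- annotations(sim$genomes)
  for (g in names(counts))
    expect_equal(unname(counts[g]),
                 sum(!is.na(ann$gh_family[ann$genome_id == g])))
  other <- sim$truth$tree
  other$tip.label[1] <- "missing_genome"
  expect_error(leafGhCounts(sim$genomes, other), "not found")
})

test_that("branch events serialize with an annotated tree", {
  tr <- labTree("((A:1,B:1):1,C:1);")
  h <- dolloReconstruct(tr, list(f1 = c("A", "B"), f2 = "C"))
  ev <- branchEvents(h, tr)
  tp <- tempfile(fileext = ".tsv"); np <- tempfile(fileext = ".nwk")
  writeBranchEvents(ev, tp, tree = tr, newick_path = np)
  back <- read.delim(tp)
  expect_equal(sum(back$n_gains), 2)
  expect_true(any(grepl("\\|g", readLines(np))))
})
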