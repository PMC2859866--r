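# Tree building, rooting, jackknife support, MGR-like ancestors, event
# placement and partial orders.

random_additive_matrix <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, rooted = FALSE,
                   tip.label = paste0("t", seq_len(ntaxa)))
  tr$edge.length <- runif(nrow(tr$edge), 0.5, 3)
  list(tree = tr, D = cophenetic(tr))
}

test_that("BIONJ recovers the generating topology from additive matrices", {
  set.seed(81)
  for (r in 1:8) {
    ntaxa <- sample(6:10, 1)
    ad <- random_additive_matrix(ntaxa)
    tr <- bionj_tree(ad$D)
    expect_setequal(tree_splits(tr), tree_splits(ad$tree))
  }
  # three taxa: unique topology, three-point branch lengths
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- bionj_tree(D)
  expect_equal(sort(tr3$tip.label), c("a", "b", "c"))
  expect_equal(sum(tr3$edge.length), (3 + 4 + 5) / 2)
  expect_error(bionj_tree(D[1:2, 1:2]), "3 taxa")
})

test_that("outgroup rooting works for clades and warns otherwise", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
  utr <- ape::unroot(tr)
  rooted <- root_with_outgroup(utr, c("D", "E"))
  expect_true(ape::is.rooted(rooted))
  expect_true(ape::is.monophyletic(rooted, c("D", "E")))
  expect_warning(root_with_outgroup(utr, c("A", "C")), "not a clade")
})

test_that("jackknife with keep_fraction 1 gives 100% everywhere", {
  set.seed(82)
  sim <- simulate_history(sim_params(n_blocks = 20,
                                     mix = c(1, 0, 0)), seed = 83)
  js <- jackknife_support(sim$leaves_final, keep_fraction = 1,
                          replicates = 10, seed = 1)
  expect_true(all(js$supports$support == 100))
  expect_error(jackknife_support(sim$leaves_final, keep_fraction = 0),
               "keep_fraction")
})

test_that("jackknife supports are reproducible and input-order invariant", {
  set.seed(84)
  sim <- simulate_history(sim_params(n_blocks = 30, mix = c(1, 0, 0)),
                          seed = 85)
  s <- sim$leaves_final
  j1 <- jackknife_support(s, replicates = 30, seed = 9)
  j2 <- jackknife_support(s, replicates = 30, seed = 9)
  expect_equal(j1$supports, j2$supports)
  perm <- s[sample(length(s))]
  j3 <- jackknife_support(perm, replicates = 30, seed = 9,
                          tree = j1$tree)
  expect_equal(j3$supports[order(j3$supports$split), ],
               j1$supports[order(j1$supports$split), ],
               ignore_attr = TRUE)
})

test_that("the MGR heuristic solves trivial medians exactly", {
  # two genomes: score equals the pairwise distance
  p <- c(1L, 2L, 3L, 4L, 5L, 6L)
  q <- c(1L, -4L, -3L, -2L, 5L, 6L)
  m2 <- mgr_like_ancestors(list(a = p, b = q))
  expect_equal(m2$score, inversion_distance(p, q)$distance)
  # identity, identity, one-inversion: median = identity, score 1
  m3 <- mgr_like_ancestors(list(a = p, b = p, c = q))
  expect_equal(m3$score, 1L)
  expect_equal(m3$ancestors[["A1"]], p)
  expect_setequal(m3$tree$tip.label, c("a", "b", "c"))
})

test_that("the MGR heuristic stays near the true event count on simulations", {
  set.seed(86)
  ratios <- numeric(0)
  for (r in 1:5) {
    tr <- ape::read.tree(text = "((A:2,B:2):2,(C:2,D:2):2);")
    sim <- simulate_history(sim_params(n_blocks = 15, tree = tr,
                                       mix = c(1, 0, 0)), seed = 860 + r)
    true_k <- sum(sim$n_events)
    if (true_k == 0) next
    m <- mgr_like_ancestors(sim$leaves_final)
    ratios <- c(ratios, m$score / true_k)
    expect_lte(m$score, true_k * 1.5)
  }
  expect_true(length(ratios) > 0)
})

test_that("topology-constrained MGR merges along the given tree", {
  set.seed(87)
  topo <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  p <- 1:8
  mk <- function(...) apply_inversion(p, ...)
  perms <- list(a = p, b = mk(2, 3), c = mk(5, 7), d = mk(5, 6))
  m <- mgr_like_ancestors(perms, topology = topo)
  expect_setequal(m$tree$tip.label, c("a", "b", "c", "d"))
  # (a,b) and (c,d) are cherries of the result
  sp <- tree_splits(m$tree)
  expect_true("c|d" %in% sp || "a|b" %in% sp)
})

test_that("duplications are placed at the MRCA of both-copy genomes", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,(D:1,E:1):1);")
  # final GSSs: anchor 5 split into 5a/5b; D and E carry virtual copies
  base <- c("1", "2", "3", "4", "5a", "5b", "6")
  s <- gss_set(lapply(c("A", "B", "C", "D", "E"), function(id)
    gss(id, base, stage = "final")))
  res <- list(gss = s,
              rename_log = data.frame(),
              removed = character(0),
              virtual = data.frame(genome = c("D", "E"),
                                   label = c("5a", "5a"),
                                   inserted = c("5b", "5b"),
                                   stringsAsFactors = FALSE),
              tdpl_records = list())
  sc <- place_duplication_events(tr, res)
  # TD above the MRCA of A,B,C; loss of 5b on the stem of (D,E)
  td_branch <- names(Filter(function(evs)
    any(vapply(evs, function(e) e$type == "TD", logical(1))),
    sc$branches))
  l_branch <- names(Filter(function(evs)
    any(vapply(evs, function(e) e$type == "L", logical(1))),
    sc$branches))
  abc_mrca <- ape::getMRCA(tr, c("A", "B", "C"))
  de_mrca <- ape::getMRCA(tr, c("D", "E"))
  expect_equal(td_branch, paste0("N", abc_mrca))
  expect_equal(l_branch, paste0("N", de_mrca))
  # all-genome duplication lands on the root branch
  res2 <- res
  res2$virtual <- data.frame(genome = character(0), label = character(0),
                             inserted = character(0))
  sc2 <- place_duplication_events(tr, res2)
  root_node <- length(tr$tip.label) + 1L
  expect_true(paste0("N", root_node) %in% names(sc2$branches))
})

test_that("non-monophyletic duplication patterns warn and use the MRCA", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,D:1);")
  base <- c("1", "2a", "2b", "3")
  s <- gss_set(lapply(c("A", "B", "C", "D"), function(id)
    gss(id, base, stage = "final")))
  res <- list(gss = s, rename_log = data.frame(), removed = character(0),
              virtual = data.frame(genome = c("B"), label = "2a",
                                   inserted = "2b",
                                   stringsAsFactors = FALSE),
              tdpl_records = list())
  # real copies in A, C, D: not a clade
  expect_warning(place_duplication_events(tr, res), "not monophyletic")
})

test_that("genome-specific collapsed regions expand on terminal branches", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  s <- gss_set(lapply(c("A", "B", "C"), function(id)
    gss(id, as.character(1:6), stage = "final")))
  reg <- structure(list(genome_id = "A", span_idx = 2:5,
                        copyA = list(lab = c("2", "3"), sg = c(1L, 1L)),
                        copyB = list(lab = c("2", "3"), sg = c(1L, 1L)),
                        shared = c("2", "3"), lost_in_A = character(0),
                        lost_in_B = "4", inverted_b = FALSE,
                        internal_inversions = NULL,
                        irreconcilable = FALSE,
                        boundary_ambiguous = FALSE),
                   class = "tandem_region")
  res <- list(gss = s, rename_log = data.frame(), removed = character(0),
              virtual = data.frame(genome = character(0),
                                   label = character(0),
                                   inserted = character(0)),
              tdpl_records = list(reg))
  sc <- place_duplication_events(tr, res)
  expect_true("A" %in% names(sc$branches))
  types <- vapply(sc$branches[["A"]], `[[`, character(1), "type")
  expect_true("TDPL" %in% types)
})

test_that("inversion events from ancestors replay along each branch", {
  set.seed(88)
  sim <- simulate_history(sim_params(n_blocks = 12, mix = c(1, 0, 0),
                                     tree = ape::read.tree(
                                       text = "((A:2,B:2):2,C:2);")),
                          seed = 89)
  m <- mgr_like_ancestors(sim$leaves_final)
  perms <- sim_perms(sim)
  res <- list(gss = sim$leaves_final, rename_log = data.frame(),
              removed = character(0),
              virtual = data.frame(genome = character(0),
                                   label = character(0),
                                   inserted = character(0)),
              tdpl_records = list())
  sc <- place_duplication_events(m$tree, res, ancestors = m$ancestors,
                                 perms = lapply(perms, as.integer))
  # replay: parent permutation + I events = child permutation
  all_perms <- c(m$ancestors, lapply(perms, as.integer))
  ntip <- length(m$tree$tip.label)
  node_lab <- function(v) if (v <= ntip) m$tree$tip.label[v] else
    m$tree$node.label[v - ntip]
  for (ei in seq_len(nrow(m$tree$edge))) {
    pv <- node_lab(m$tree$edge[ei, 1]); cv <- node_lab(m$tree$edge[ei, 2])
    evs <- sc$branches[[cv]]
    if (is.null(evs)) evs <- list()
    cur <- all_perms[[pv]]
    for (e in evs) if (e$type == "I") cur <- apply_inversion(cur, e$i, e$j)
    expect_equal(cur, all_perms[[cv]])
  }
})

test_that("the event partial order frees disjoint inversions only", {
  evs <- list(list(type = "I", labels = c("1", "2")),
              list(type = "I", labels = c("4", "5")),
              list(type = "I", labels = c("2", "3")))
  po <- event_partial_order(evs)
  expect_true(nrow(po[po$from == 1 & po$to == 3, ]) == 1)
  expect_false(any(po$from == 1 & po$to == 2))
  evs2 <- list(list(type = "TDPL", labels = c("2", "3")),
               list(type = "I", labels = c("3", "4")))
  po2 <- event_partial_order(evs2)
  expect_equal(nrow(po2), 1L)
})

test_that("all linear extensions of a branch partial order replay equally", {
  p <- 1:6
  evs <- list(list(type = "I", labels = c("2", "3")),
              list(type = "I", labels = c("5", "6")))
  po <- event_partial_order(evs)
  expect_equal(nrow(po), 0L)
  r1 <- apply_labeled_events(p, evs)
  r2 <- apply_labeled_events(p, rev(evs))
  expect_equal(r1, r2)
  expect_equal(r1, c(1L, -3L, -2L, 4L, -6L, -5L))
})
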