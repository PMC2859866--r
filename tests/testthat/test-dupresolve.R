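# The duplicate framework: neighborhood graph, weight clusters, tandem
# region detection/collapse, paralog disambiguation, virtual copies and
# label bookkeeping.

test_that("neighborhood weights match the brute-force pair enumerator", {
  cases <- list(
    list(c("1", "2", "3"), c("1", "2", "3"), c("1", "2", "3")),
    list(c("1", "2")),
    list(c("1", "2", "3", "4", "5")),
    list(c("1", "2", "3", "2", "3", "4")))
  for (tk in cases) {
    gs <- gss_set(lapply(seq_along(tk), function(i)
      gss(paste0("g", i), tk[[i]])))
    ng <- build_neighborhood_graph(gs)
    oracle <- brute_neighbor_weights(tk)
    for (key in names(oracle)) {
      ab <- strsplit(key, "~", fixed = TRUE)[[1]]
      expect_equal(ng$w[ab[1], ab[2]], oracle[[key]],
                   info = paste("pair", key))
    }
    expect_equal(sum(ng$w) / 2, sum(unlist(oracle)))
    expect_equal(ng$w, t(ng$w))
    expect_true(all(diag(ng$w) == 0))
  }
  # spec'd canonical counts: three genomes "1 2 3" -> all pairs weight 3
  ng3 <- build_neighborhood_graph(gss_set(list(
    gss("a", c("1", "2", "3")), gss("b", c("1", "2", "3")),
    gss("c", c("1", "2", "3")))))
  expect_true(all(ng3$w[upper.tri(ng3$w)] == 3))
})

test_that("clusters honor the weight-threshold definition", {
  # chain A-B (w=8), B-C (w=3), via constructed occurrence counts
  g <- structure(list(labels = c("A", "B", "C"),
                      w = matrix(c(0L, 8L, 0L, 8L, 0L, 3L, 0L, 3L, 0L), 3,
                                 dimnames = list(c("A", "B", "C"),
                                                 c("A", "B", "C")))),
                 class = "neighborhood_graph")
  c4 <- clusters_at_weight(g, 4)
  expect_equal(length(c4), 1L)
  expect_setequal(c4[[1]], c("A", "B"))
  c3 <- clusters_at_weight(g, 3)
  expect_setequal(c3[[1]], c("A", "B", "C"))
  expect_equal(clusters_at_weight(g, 9), list())
  expect_error(clusters_at_weight(g, 0), ">= 1")
  hc <- hierarchical_clusters(g)
  expect_equal(hc[[1]]$w, 8)
  expect_equal(hc[[length(hc)]]$w, 1)
})

test_that("exact tandem duplicates are detected and collapsed", {
  g <- gss("t", c("1", "2", "3", "2", "3", "4"))
  regs <- detect_tandem_regions(g)
  expect_length(regs, 1)
  r <- regs[[1]]
  expect_setequal(r$shared, c("2", "3"))
  expect_equal(r$copyA$lab, c("2", "3"))
  expect_equal(r$copyB$lab, c("2", "3"))
  expect_length(r$lost_in_A, 0)
  cc <- collapse_tandem_region(g, r)
  expect_equal(canonicalize(cc, origin = "1"),
               canonicalize(gss("t", as.character(1:4)), origin = "1"),
               ignore_attr = TRUE)
  expect_true(attr(cc, "unique_merge"))
})

test_that("partial loss is reintroduced at its positional slot", {
  g <- gss("t", c("1", "2", "3", "4", "2", "4", "5"))
  regs <- detect_tandem_regions(g)
  expect_length(regs, 1)
  r <- regs[[1]]
  expect_setequal(r$shared, c("2", "4"))
  expect_equal(r$lost_in_B, "3")
  cc <- collapse_tandem_region(g, r)
  expect_equal(canonicalize(cc, origin = "1"),
               canonicalize(gss("t", as.character(1:5)), origin = "1"),
               ignore_attr = TRUE)
})

test_that("a copy inverted as a unit is recognized and collapsed", {
  g <- gss("t", c("1", "2", "3", "-3", "-2", "4"))
  regs <- detect_tandem_regions(g)
  expect_length(regs, 1)
  expect_true(regs[[1]]$inverted_b)
  cc <- collapse_tandem_region(g, regs[[1]])
  expect_equal(canonicalize(cc, origin = "1"),
               canonicalize(gss("t", as.character(1:4)), origin = "1"),
               ignore_attr = TRUE)
})

test_that("three copies are out of model and reported as excluded", {
  g <- gss("t", c("1", "2", "2", "2", "3"))
  regs <- detect_tandem_regions(g)
  expect_equal(attr(regs, "excluded"), "2")
  expect_length(regs, 0)
})

test_that("collapse recovers the pre-duplication order on simulated TDPLs", {
  set.seed(71)
  n <- 30L
  for (r in 1:25) {
    q <- sample(c(0, 0.3), 1)
    len <- sample(3:8, 1)
    start <- sample(n, 1)
    lossA <- runif(len) < q
    lossB <- runif(len) < q
    both <- lossA & lossB
    lossA[both] <- FALSE
    st <- list(base = 1:n, sign = rep(1L, n), copy = rep("", n))
    st2 <- mitorearr:::.apply_event(st, list(type = "tdpl", start = start,
                                             len = len, lossA = lossA,
                                             lossB = lossB))
    g <- gss("s", ifelse(st2$sign < 0, paste0("-", st2$base),
                         as.character(st2$base)), stage = "bpisac")
    regs <- detect_tandem_regions(g)
    if (length(regs) == 0) {
      # all anchors singleton (TDRL-like outcome): nothing to collapse
      expect_equal(anyDuplicated(gss_labels(g)), 0L)
      next
    }
    cc <- collapse_tandem_region(g, regs[[1]])
    expect_equal(sort(as.integer(gss_labels(cc))), 1:n)
    if (isTRUE(attr(cc, "unique_merge"))) {
      expect_equal(as.integer(canonicalize(cc, origin = "1")), 1:n)
    }
  }
})

test_that("paralogs are renamed by neighborhood and virtual copies added", {
  # two genomes carry {20 21 22} twice; the copy next to {23} gets "a";
  # a third genome has one copy and receives a virtual tandem copy
  t1 <- c("23", "20", "21", "22", "30", "31", "20", "21", "22", "40")
  t2 <- c("23", "20", "21", "22", "31", "30", "20", "21", "22", "40")
  t3 <- c("23", "20", "21", "22", "30", "31", "40")
  s <- gss_set(list(gss("x", t1), gss("y", t2), gss("z", t3)))
  res <- disambiguate_paralogs(s, collapse = FALSE)
  labs <- sort_gss_labels(gss_labels(res$gss[[1]]))
  expect_true(all(c("20a", "20b", "21a", "21b", "22a", "22b") %in% labs))
  for (g in res$gss) expect_setequal(gss_labels(g), labs)
  # genome z got the virtual copies
  expect_true(all(res$virtual$genome == "z"))
  # the first occurrence (next to 23) carries the "a" suffix in x
  xb <- gss_labels(res$gss[["x"]])
  expect_lt(which(xb == "20a"), which(xb == "20b"))
})

test_that("symmetric duplicates are deleted from every genome", {
  # palindromic context: both copies of "5" see identical neighborhoods
  t1 <- c("1", "5", "2", "3", "2", "5", "1", "9")
  s <- gss_set(list(gss("x", t1),
                    gss("y", c("1", "5", "2", "3", "2", "5", "1", "9"))))
  res <- suppressWarnings(disambiguate_paralogs(s, collapse = FALSE))
  for (g in res$gss) {
    expect_false(any(grepl("^5", gss_labels(g))))
  }
  expect_true(length(res$removed) >= 1)
})

test_that("virtual copies never change pairwise distances (property)", {
  set.seed(72)
  for (r in 1:30) {
    n <- sample(8:40, 1)
    p <- rand_signed_perm(n)
    q <- rand_signed_perm(n)
    gp <- gss("p", ifelse(p < 0, paste0("-", abs(p)), as.character(p)))
    gq <- gss("q", ifelse(q < 0, paste0("-", abs(q)), as.character(q)))
    lbl <- as.character(sample(n, 1))
    gp2 <- add_virtual_copy(gp, lbl, paste0(lbl, "v"))
    gq2 <- add_virtual_copy(gq, lbl, paste0(lbl, "v"))
    d0 <- distance_matrix(gss_set(list(gp, gq)))["p", "q"]
    d1 <- distance_matrix(gss_set(list(gp2, gq2)))["p", "q"]
    expect_equal(d1, d0)
    b0 <- distance_matrix(gss_set(list(gp, gq)), "breakpoint")["p", "q"]
    b1 <- distance_matrix(gss_set(list(gp2, gq2)), "breakpoint")["p", "q"]
    expect_equal(b1, b0)
  }
})

test_that("the printed deletion and rename lists leave 72 final labels", {
  labs <- gss_label_bookkeeping(
    69, deleted = c(2, 60, 61, 62, 68),
    duplicated = c(20, 21, 22, 27, 24, 26, 67, 35))
  expect_length(labs, 72)
  expect_false(any(c("2", "60", "61", "62", "68") %in% labs))
  expect_true(all(c("20a", "20b", "27a", "27b", "24a", "24b", "35a",
                    "35b", "67a", "67b", "26a", "26b") %in% labs))
})

test_that("end-to-end resolution of a simulated history yields final GSSs", {
  tr <- ape::read.tree(text = "(((A:2,B:2):1,C:2):1,D:2);")
  sim <- simulate_history(sim_params(n_blocks = 25, tree = tr,
                                     mix = c(0.75, 0.15, 0.1)), seed = 73)
  res <- tryCatch(disambiguate_paralogs(sim$leaves_bpisac),
                  error = function(e) NULL)
  # resolution can legitimately delete unresolvable anchors, but when it
  # completes, the postcondition must hold: one occurrence of each label
  if (!is.null(res)) {
    ref <- sort_gss_labels(gss_labels(res$gss[[1]]))
    for (g in res$gss) {
      expect_setequal(gss_labels(g), ref)
      expect_equal(anyDuplicated(gss_labels(g)), 0L)
    }
  } else {
    succeed("resolution reported an unresolvable configuration")
  }
})
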