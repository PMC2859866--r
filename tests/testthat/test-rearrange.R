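# Signed-permutation machinery: exact inversion distance against the BFS
# oracle, scenario replay, breakpoint distance against an adjacency
# enumerator, circular canonicalization, distance matrices.

test_that("inversion distance matches the BFS oracle exhaustively (n <= 5)", {
  for (n in 1:5) {
    tab <- bfs_distance_table(n)
    id <- seq_len(n)
    ok <- vapply(all_signed_perms(n), function(p)
      inversion_distance(p, id)$distance == bfs_table_lookup(tab, p, id),
      logical(1))
    expect_true(all(ok))
  }
})

test_that("breakpoint-graph decomposition satisfies d = b - c + h + f", {
  set.seed(21)
  for (r in 1:200) {
    n <- sample(2:40, 1)
    st <- inversion_distance(rand_signed_perm(n), rand_signed_perm(n))
    expect_identical(st$distance,
                     st$breakpoints - st$cycles + st$hurdles + st$fortress)
    expect_gte(st$distance, 0L)
  }
  expect_identical(inversion_distance(1:7, 1:7)$distance, 0L)
})

test_that("distance is symmetric and zero only for equal permutations", {
  set.seed(22)
  for (r in 1:50) {
    n <- sample(2:30, 1)
    p <- rand_signed_perm(n); q <- rand_signed_perm(n)
    d <- inversion_distance(p, q)$distance
    expect_identical(d, inversion_distance(q, p)$distance)
    expect_identical(d == 0L, identical(p, q))
  }
})

test_that("classic small cases: single inversion and hurdle permutation", {
  expect_identical(inversion_distance(c(1L, -2L, 3L), 1:3)$distance, 1L)
  # frozen from the BFS oracle
  expect_identical(inversion_distance(c(3L, -1L, 2L), 1:3)$distance, 3L)
  st <- inversion_distance(c(2L, 1L), 1:2)  # unoriented component: hurdle
  expect_identical(st$distance, 3L)
  expect_identical(st$hurdles, 1L)
})

test_that("sorting scenarios replay to the target with parsimonious length", {
  set.seed(23)
  for (r in 1:40) {
    n <- sample(5:40, 1)
    p <- rand_signed_perm(n); q <- rand_signed_perm(n)
    d <- inversion_distance(p, q)$distance
    sc <- sorting_scenario(p, q)
    expect_identical(nrow(sc), d)
    expect_identical(apply_scenario(p, sc), q)
    # every prefix reduces the remaining distance by exactly one
    cur <- p
    for (s in seq_len(min(5, nrow(sc)))) {
      cur <- apply_inversion(cur, sc$i[s], sc$j[s])
      expect_identical(inversion_distance(cur, q)$distance, d - s)
    }
  }
  expect_identical(nrow(sorting_scenario(1:6, 1:6)), 0L)
})

test_that("d <= k for k random inversions and often equals k for small k", {
  set.seed(24)
  n <- 40L
  hits <- 0; total <- 0
  for (r in 1:60) {
    k <- sample(1:(n / 4), 1)
    p <- seq_len(n)
    for (e in seq_len(k)) {
      ij <- sort(sample(n, 2))
      p <- apply_inversion(p, ij[1], ij[2])
    }
    d <- inversion_distance(p, seq_len(n))$distance
    expect_lte(d, k)
    total <- total + 1
    if (d == k) hits <- hits + 1
  }
  expect_gt(hits / total, 0.8)
})

test_that("breakpoint distance agrees with direct adjacency enumeration", {
  adj_set <- function(p) {
    n <- length(p)
    keys <- character(n)
    for (i in seq_len(n)) {
      x <- p[i]; y <- p[if (i == n) 1 else i + 1]
      a <- c(x, y); b <- c(-y, -x)
      keys[i] <- if (b[1] < a[1] || (b[1] == a[1] && b[2] < a[2]))
        paste(b, collapse = ",") else paste(a, collapse = ",")
    }
    keys
  }
  set.seed(25)
  for (r in 1:50) {
    n <- sample(3:25, 1)
    p <- rand_signed_perm(n); q <- rand_signed_perm(n)
    expect_identical(breakpoint_distance(p, q),
                     sum(!(adj_set(p) %in% adj_set(q))))
    expect_identical(breakpoint_distance(p, q), breakpoint_distance(q, p))
  }
  expect_identical(breakpoint_distance(1:5, 1:5), 0L)
  # circular single-element sign flip: frozen from the enumerator
  expect_identical(breakpoint_distance(c(1L, -2L, 3L), 1:3), 2L)
})

test_that("canonicalization is invariant to rotation and reflection", {
  set.seed(26)
  for (r in 1:20) {
    n <- sample(4:15, 1)
    toks <- sample(ifelse(runif(n) < 0.5, paste0("-", 1:n),
                          as.character(1:n)))
    g <- gss("x", toks)
    ref <- canonicalize(g)
    k <- sample(n, 1)
    rot <- gss("x", toks[c(k:n, seq_len(k - 1))])
    expect_equal(as.integer(canonicalize(rot)), as.integer(ref))
    refl <- gss("x", rev(ifelse(startsWith(toks, "-"),
                                sub("^-", "", toks),
                                paste0("-", toks))))
    expect_equal(as.integer(canonicalize(refl)), as.integer(ref))
  }
  expect_equal(as.integer(canonicalize(gss("x", c("3", "1", "2")),
                                       origin = "1")), 1:3)
  expect_error(canonicalize(gss("x", c("1", "2")), origin = "9"), "absent")
})

test_that("distance matrices are symmetric, zero-diagonal and label-checked", {
  g1 <- gss("a", c("1", "2", "3", "4"))
  g2 <- gss("b", c("2", "3", "4", "1"))    # same circle
  g3 <- gss("c", c("1", "-3", "-2", "4"))
  s <- gss_set(list(g1, g2, g3))
  D <- distance_matrix(s)
  expect_equal(diag(D), c(a = 0, b = 0, c = 0))
  expect_equal(D, t(D))
  expect_equal(D["a", "b"], 0)
  expect_gt(D["a", "c"], 0)
  B <- distance_matrix(s, metric = "breakpoint")
  expect_equal(B["a", "b"], 0)
  bad <- gss_set(list(g1, gss("d", c("1", "2", "3", "5"))))
  expect_error(distance_matrix(bad), "label sets")
  # reordering genomes permutes rows/columns only
  D2 <- distance_matrix(s[c(3, 1, 2)])
  expect_equal(D2[rownames(D), colnames(D)], D)
})

test_that("choice of reference relabeling leaves pairwise distances unchanged", {
  set.seed(27)
  for (r in 1:10) {
    n <- 12
    base <- lapply(1:4, function(i) rand_signed_perm(n))
    s1 <- gss_set(lapply(seq_along(base), function(i)
      gss(paste0("g", i), as.character(base[[i]]))))
    # consistent relabeling: rename label l -> pi(l), keep signs
    pi <- sample(n)
    relab <- gss_set(lapply(seq_along(base), function(i) {
      p <- base[[i]]
      ap <- abs(p)
      gss(paste0("g", i), ifelse(p < 0, paste0("-", pi[ap]),
                                 as.character(pi[ap])))
    }))
    expect_equal(distance_matrix(s1), distance_matrix(relab))
    expect_equal(distance_matrix(s1, "breakpoint"),
                 distance_matrix(relab, "breakpoint"))
  }
})

test_that("brute-force BFS distance is symmetric and respects max_d", {
  set.seed(28)
  for (r in 1:10) {
    p <- rand_signed_perm(6); q <- rand_signed_perm(6)
    expect_identical(brute_force_distance(p, q), brute_force_distance(q, p))
  }
  expect_identical(brute_force_distance(1:5, 1:5), 0L)
  expect_true(is.na(brute_force_distance(c(-5L, 4L, -3L, 2L, -1L), 1:5,
                                         max_d = 1L)))
})
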