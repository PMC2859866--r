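# Signed-permutation rearrangement measures: exact Hannenhalli-Pevzner
# inversion distance with its breakpoint-graph decomposition, parsimonious
# sorting scenarios, breakpoint distance, distance matrices, and a BFS
# brute-force oracle.

check_perm_pair <- function(p, q) {
  p <- check_perm(p, "p")
  q <- check_perm(q, "q")
  if (length(p) != length(q))
    stop("permutations differ in length (", length(p), " vs ", length(q), ")")
  list(p = p, q = q)
}

#' Inversion (reversal) distance between signed permutations
#'
#' Exact minimal number of signed reversals transforming `p` into `q`,
#' computed from the breakpoint graph as `d = b - c + h + f` (breakpoints,
#' non-trivial cycles, hurdles, fortress).
#'
#' @param p,q signed integer permutations over the same labels, each label
#'   exactly once (e.g. from [canonicalize()]).
#' @return Object of class `inversion_distance`: a list with elements
#'   `distance`, `breakpoints`, `cycles`, `hurdles`, `fortress`.
#' @examples
#' inversion_distance(c(3L, -1L, 2L), 1:3)
#' @export
inversion_distance <- function(p, q = seq_along(p)) {
  pq <- check_perm_pair(p, q)
  st <- cpp_inversion_stats(pq$p, pq$q)
  structure(as.list(st), class = "inversion_distance")
}

#' @export
print.inversion_distance <- function(x, ...) {
  cat("inversion distance:", x$distance,
      sprintf("(b = %d, c = %d, h = %d, f = %d)\n",
              x$breakpoints, x$cycles, x$hurdles, x$fortress))
  invisible(x)
}

#' Parsimonious inversion scenario
#'
#' An ordered list of reversals of length exactly
#' `inversion_distance(p, q)$distance` transforming `p` into `q`. Every
#' prefix decreases the remaining distance by one. Among distance-reducing
#' reversals the lexicographically smallest interval is chosen, so scenarios
#' are reproducible.
#'
#' @inheritParams inversion_distance
#' @return data.frame with columns `step`, `i`, `j` (1-based inclusive
#'   interval reversed at that step) and `result` (the permutation after the
#'   step, space-separated).
#' @export
sorting_scenario <- function(p, q) {
  pq <- check_perm_pair(p, q)
  steps <- cpp_sorting_scenario(pq$p, pq$q)
  k <- nrow(steps)
  res <- character(k)
  cur <- pq$p
  if (k > 0) {
    for (r in seq_len(k)) {
      cur <- apply_inversion(cur, steps[r, 1], steps[r, 2])
      res[r] <- paste(cur, collapse = " ")
    }
  }
  data.frame(step = seq_len(k),
             i = if (k) steps[, 1] else integer(0),
             j = if (k) steps[, 2] else integer(0),
             result = res, stringsAsFactors = FALSE)
}

#' Apply one signed reversal
#' @param p signed permutation.
#' @param i,j 1-based inclusive interval; elements are reversed and
#'   sign-flipped.
#' @export
apply_inversion <- function(p, i, j) {
  p <- as_perm(p)
  stopifnot(i >= 1, j >= i, j <= length(p))
  p[i:j] <- -rev(p[i:j])
  p
}

#' Replay a scenario
#' @param p signed permutation.
#' @param scenario data.frame with columns `i`, `j` as from
#'   [sorting_scenario()].
#' @export
apply_scenario <- function(p, scenario) {
  p <- as_perm(p)
  for (r in seq_len(nrow(scenario)))
    p <- apply_inversion(p, scenario$i[r], scenario$j[r])
  p
}

# canonical key of a signed adjacency (x,y) == (-y,-x)
.adj_keys <- function(p) {
  n <- length(p)
  x <- p
  y <- p[c(2:n, 1)]
  a1 <- x; b1 <- y
  a2 <- -y; b2 <- -x
  swap <- (a2 < a1) | (a2 == a1 & b2 < b1)
  paste(ifelse(swap, a2, a1), ifelse(swap, b2, b1))
}

#' Breakpoint distance between circular signed permutations
#'
#' Counts the signed adjacencies of `p` (circular, wrapping last to first)
#' that are absent from `q`; the adjacency `(x, y)` is identified with
#' `(-y, -x)`.
#'
#' @inheritParams inversion_distance
#' @export
breakpoint_distance <- function(p, q) {
  pq <- check_perm_pair(p, q)
  sum(!(.adj_keys(pq$p) %in% .adj_keys(pq$q)))
}

#' Brute-force inversion distance by breadth-first search
#'
#' Independent oracle: explores the reversal graph from `p` outwards with no
#' breakpoint-graph theory. Only practical for `n <= 8`.
#'
#' @inheritParams inversion_distance
#' @param max_d search horizon; returns `NA` when `q` is not reached.
#' @export
brute_force_distance <- function(p, q, max_d = 20L) {
  pq <- check_perm_pair(p, q)
  d <- cpp_brute_force_distance(pq$p, pq$q, as.integer(max_d))
  if (d < 0) NA_integer_ else d
}

#' Exhaustive BFS distance table from the identity
#'
#' Independent oracle for the inversion distance: breadth-first search over
#' the whole reversal graph of signed permutations of size `n` (`n <= 7`),
#' with no breakpoint-graph theory. `bfs_table_lookup` returns the distance
#' between two permutations via the left-invariance
#' `d(p, q) = d(identity, rename(p by q))`.
#'
#' @param n permutation size (1..7).
#' @return Integer vector of distances indexed by an internal permutation
#'   rank; query it with [bfs_table_lookup()].
#' @export
bfs_distance_table <- function(n) {
  cpp_bfs_distance_table(as.integer(n))
}

#' @param tab table from [bfs_distance_table()].
#' @inheritParams inversion_distance
#' @rdname bfs_distance_table
#' @export
bfs_table_lookup <- function(tab, p, q) {
  pq <- check_perm_pair(p, q)
  tab[cpp_perm_table_index(pq$p, pq$q) + 1]
}

#' Pairwise rearrangement distance matrix for a GSS set
#'
#' All genomes must share one label alphabet with every label exactly once.
#' Each genome is canonicalized (origin pinned at the smallest label) before
#' the distance computation.
#'
#' @param x a `gss_set` of final (duplicate-free) GSSs, or a list of signed
#'   permutations over a common alphabet.
#' @param metric `"inversion"` or `"breakpoint"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(x, metric = c("inversion", "breakpoint")) {
  metric <- match.arg(metric)
  if (inherits(x, "gss_set")) {
    if (length(x) < 2) stop("need at least two genomes")
    alph <- sort_gss_labels(gss_labels(x[[1]]))
    perms <- lapply(x, function(g) {
      if (!setequal(gss_labels(g), alph))
        stop("genomes carry different label sets (genome ", g$id, ")")
      canonicalize(g, origin = alph[1], labels = alph)
    })
  } else {
    perms <- lapply(x, check_perm)
  }
  k <- length(perms)
  ids <- names(perms)
  if (is.null(ids)) ids <- paste0("g", seq_len(k))
  M <- do.call(rbind, lapply(perms, as_perm))
  if (metric == "inversion") {
    D <- cpp_distance_matrix(M)
  } else {
    D <- matrix(0, k, k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      D[i, j] <- D[j, i] <- breakpoint_distance(M[i, ], M[j, ])
    }
  }
  dimnames(D) <- list(ids, ids)
  D
}

#' Write a distance matrix in square PHYLIP format
#' @param D symmetric matrix with dimnames.
#' @param path output file.
#' @export
write_phylip_dist <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    writeLines(paste0(formatC(rownames(D)[i], width = -10),
                      paste(sprintf("%.6f", D[i, ]), collapse = "  ")), con)
  }
  invisible(path)
}
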