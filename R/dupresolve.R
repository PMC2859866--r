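# Resolution of duplicated synteny anchors under the tandem-duplication-
# with-partial-loss (TDPL) model: neighborhood graph, weight-threshold
# anchor clusters, detection and collapsing of tandem regions, paralog /
# ortholog disambiguation with virtual tandem copies, and removal of
# unresolvable anchors. Turns GSS bpisac into duplicate-free final GSS.

.parse_gss <- function(g) {
  list(lab = gss_labels(g), sg = gss_signs(g))
}

.make_tokens <- function(lab, sg) ifelse(sg < 0, paste0("-", lab), lab)

#' Neighborhood graph of synteny anchors
#'
#' Two anchors are neighbors when they are separated by at most one anchor
#' on the circular GSS; the edge weight counts, over all genomes and all
#' occurrence pairs (duplicates each contribute), how often the two anchors
#' are neighbors. Position pairs at circular distance 1 or 2 are each
#' counted once; there are no self edges.
#'
#' @param x a `gss_set` (stage bpisac or final).
#' @return Object of class `neighborhood_graph`: list with `labels` and the
#'   symmetric integer weight matrix `w`.
#' @export
build_neighborhood_graph <- function(x) {
  stopifnot(inherits(x, "gss_set"))
  labels <- sort_gss_labels(unique(unlist(lapply(x, gss_labels))))
  k <- length(labels)
  w <- matrix(0L, k, k, dimnames = list(labels, labels))
  for (g in x) {
    lab <- gss_labels(g)
    L <- length(lab)
    if (L < 2) next
    for (i in seq_len(L - 1)) {
      for (j in (i + 1):L) {
        d <- min(j - i, L - (j - i))
        if (d >= 1 && d <= 2 && lab[i] != lab[j]) {
          a <- lab[i]; b <- lab[j]
          w[a, b] <- w[a, b] + 1L
          w[b, a] <- w[b, a] + 1L
        }
      }
    }
  }
  structure(list(labels = labels, w = w), class = "neighborhood_graph")
}

#' @export
print.neighborhood_graph <- function(x, ...) {
  cat("<neighborhood_graph>", length(x$labels), "anchors,",
      sum(x$w > 0) / 2, "weighted edges\n")
  invisible(x)
}

#' Anchor clusters at a weight threshold
#'
#' Connected components of the subgraph keeping edges of weight at least
#' `w`, restricted to anchors incident to at least one such edge.
#'
#' @param graph a [build_neighborhood_graph()] result.
#' @param w positive integer weight threshold.
#' @return List of character vectors (clusters).
#' @export
clusters_at_weight <- function(graph, w) {
  if (w < 1) stop("w must be >= 1")
  keep <- graph$w >= w
  deg <- rowSums(keep)
  nodes <- graph$labels[deg > 0]
  if (length(nodes) == 0) return(list())
  sub <- keep[nodes, nodes, drop = FALSE]
  ig <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
  comp <- igraph::components(ig)
  split(nodes, comp$membership)
}

#' Hierarchical anchor clustering over decreasing weight
#'
#' The nesting of [clusters_at_weight()] components as the threshold
#' decreases from the maximal observed weight down to 1.
#'
#' @param graph a [build_neighborhood_graph()] result.
#' @return List of levels, each with elements `w` and `clusters`.
#' @export
hierarchical_clusters <- function(graph) {
  wmax <- max(graph$w)
  if (wmax < 1) return(list())
  lapply(seq(wmax, 1), function(wt)
    list(w = wt, clusters = clusters_at_weight(graph, wt)))
}

# highest threshold at which two labels share a cluster (0 if never)
.cluster_affinity <- function(graph, a, b) {
  if (!(a %in% graph$labels) || !(b %in% graph$labels)) return(0L)
  # affinity via direct neighborhood weight; cluster-level ties are broken
  # upstream with this same quantity
  graph$w[a, b]
}

#' Detect candidate tandem-duplication regions in one GSS
#'
#' Labels occurring exactly twice are grouped into regions; each region is
#' split into two copies whose boundaries maximize shared content, with
#' ambiguous flanking singletons assigned by neighborhood-graph affinity.
#' Whole-copy inversions of the second copy are recognized; other internal
#' sign-flipped sub-runs are reported (via the shared-anchor sorting
#' scenario) but leave the region irreconcilable for collapsing. Labels
#' occurring three or more times are out of model and reported as excluded.
#'
#' @param g a `gss` (stage bpisac).
#' @param graph optional [build_neighborhood_graph()] used for boundary
#'   ties.
#' @return List of `tandem_region` objects; attribute `excluded` carries
#'   labels with 3+ copies.
#' @export
detect_tandem_regions <- function(g, graph = NULL) {
  p <- .parse_gss(g)
  lab <- p$lab; sg <- p$sg
  L <- length(lab)
  cnt <- table(lab)
  over <- names(cnt)[cnt > 2]
  dups <- names(cnt)[cnt == 2]
  dups <- setdiff(dups, over)
  out <- list()
  if (length(dups) > 0) {
    didx <- sort(which(lab %in% dups))
    # rotate so the largest duplicate-free circular gap precedes index 1
    gaps <- diff(c(didx, didx[1] + L))
    rot <- (didx[which.max(gaps)] %% L) + 1L
    idx <- ((seq_len(L) + rot - 2L) %% L) + 1L
    rlab <- lab[idx]; rsg <- sg[idx]
    # group duplicated labels by overlapping [first, second] intervals
    ivs <- t(vapply(dups, function(d) which(rlab == d), integer(2)))
    ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
    grp <- cumsum(c(1, as.integer(ivs[-nrow(ivs), 2] <
                                    ivs[-1, 1]))) # overlap chain
    for (gi in unique(grp)) {
      rows <- which(grp == gi)
      if (length(rows) == 0) next
      gd <- rownames(ivs)[rows]
      firsts <- ivs[rows, 1]; seconds <- ivs[rows, 2]
      w0 <- min(firsts); w1 <- max(seconds)
      tA <- max(firsts); tB <- min(seconds)
      if (tA >= tB) next  # interleaved beyond the 2-copy tandem model
      # assign ambiguous singletons between the copies
      zone <- if (tB - tA >= 2)
        setdiff(seq(tA + 1, tB - 1), c(firsts, seconds)) else integer(0)
      split_at <- tA
      boundary_ambiguous <- length(zone) > 0
      if (length(zone) > 0 && !is.null(graph)) {
        prefs <- vapply(zone, function(z) {
          wa <- .cluster_affinity(graph, rlab[z], rlab[tA])
          wb <- .cluster_affinity(graph, rlab[z], rlab[tB])
          sign(wa - wb)
        }, numeric(1))
        scores <- vapply(seq(tA, tB - 1), function(t)
          sum(prefs[zone <= t]) - sum(prefs[zone > t]), numeric(1))
        split_at <- seq(tA, tB - 1)[which.max(scores)]
      }
      ai <- seq(w0, split_at)
      bi <- seq(split_at + 1, w1)
      shared_a <- rlab[ai][rlab[ai] %in% gd]
      shared_b <- rlab[bi][rlab[bi] %in% gd]
      sgn_a <- rsg[ai][rlab[ai] %in% gd]
      sgn_b <- rsg[bi][rlab[bi] %in% gd]
      inverted_b <- FALSE
      internal_inv <- NULL
      if (!identical(shared_a, shared_b) || !identical(sgn_a, sgn_b)) {
        if (identical(shared_a, rev(shared_b)) &&
            identical(sgn_a, rev(-sgn_b))) {
          inverted_b <- TRUE
        } else {
          # report the sub-run inversions separating the two copies
          pa <- match(shared_b, shared_a) * sgn_b *
            sgn_a[match(shared_b, shared_a)]
          internal_inv <- tryCatch(
            sorting_scenario(as.integer(pa), seq_along(shared_a)),
            error = function(e) NULL)
        }
      }
      region <- structure(list(
        genome_id = g$id,
        span_idx = idx[seq(w0, w1)],
        copyA = list(lab = rlab[ai], sg = rsg[ai]),
        copyB = list(lab = rlab[bi], sg = rsg[bi]),
        shared = gd,
        lost_in_A = setdiff(rlab[bi], c(gd, rlab[ai])),
        lost_in_B = setdiff(rlab[ai], c(gd, rlab[bi])),
        inverted_b = inverted_b,
        internal_inversions = internal_inv,
        irreconcilable = !inverted_b && !is.null(internal_inv),
        boundary_ambiguous = boundary_ambiguous),
        class = "tandem_region")
      out[[length(out) + 1]] <- region
    }
  }
  attr(out, "excluded") <- over
  out
}

#' @export
print.tandem_region <- function(x, ...) {
  cat("<tandem_region> ", x$genome_id, ": copies [",
      paste(.make_tokens(x$copyA$lab, x$copyA$sg), collapse = " "), "] / [",
      paste(.make_tokens(x$copyB$lab, x$copyB$sg), collapse = " "), "]",
      if (x$inverted_b) " (copy B inverted)", "\n", sep = "")
  invisible(x)
}

#' Collapse a tandem region into one copy
#'
#' Replaces the two copies by their minimal common supersequence on the
#' shared-anchor scaffold: anchors lost in one copy are reintroduced at
#' their positional slot; where several minimal supersequences exist, copy
#' A's content is placed first within a slot. Copies whose shared anchors
#' disagree in order (beyond a whole-copy inversion) raise an
#' "irreconcilable region" error carrying both orders.
#'
#' @param g the `gss` the region was detected in.
#' @param region a `tandem_region`.
#' @return New `gss` with the region collapsed; attributes `merged`
#'   (the merged tokens) and `unique_merge` (TRUE when the minimal common
#'   supersequence is unique, in which case the pre-duplication order is
#'   provably recovered).
#' @export
collapse_tandem_region <- function(g, region) {
  A <- region$copyA; B <- region$copyB
  if (region$inverted_b) {
    B <- list(lab = rev(B$lab), sg = rev(-B$sg))
  }
  shA <- A$lab[A$lab %in% region$shared]
  shB <- B$lab[B$lab %in% region$shared]
  if (!identical(shA, shB))
    stop("irreconcilable region: copy orders [",
         paste(.make_tokens(A$lab, A$sg), collapse = " "), "] vs [",
         paste(.make_tokens(B$lab, B$sg), collapse = " "),
         "] admit no common linear extension")
  # slot decomposition keyed by the shared scaffold
  slot_of <- function(cp) {
    ks <- cumsum(cp$lab %in% region$shared)
    # slot s collects private anchors preceding shared anchor s+1
    split(seq_along(cp$lab)[!(cp$lab %in% region$shared)],
          ks[!(cp$lab %in% region$shared)])
  }
  sa <- slot_of(A); sb <- slot_of(B)
  shared_idx_a <- which(A$lab %in% region$shared)
  merged_lab <- character(0); merged_sg <- integer(0)
  mixed <- FALSE
  nsh <- length(shA)
  for (s in 0:nsh) {
    ia <- sa[[as.character(s)]]
    ib <- sb[[as.character(s)]]
    if (!is.null(ia) && !is.null(ib) && length(ia) && length(ib))
      mixed <- TRUE
    if (length(ia)) {
      merged_lab <- c(merged_lab, A$lab[ia])
      merged_sg <- c(merged_sg, A$sg[ia])
    }
    if (length(ib)) {
      merged_lab <- c(merged_lab, B$lab[ib])
      merged_sg <- c(merged_sg, B$sg[ib])
    }
    if (s < nsh) {
      merged_lab <- c(merged_lab, shA[s + 1])
      merged_sg <- c(merged_sg, A$sg[shared_idx_a[s + 1]])
    }
  }
  toks_all <- g$blocks
  L <- length(toks_all)
  rest <- setdiff(seq_len(L), region$span_idx)
  # keep circular order starting right after the region
  after <- region$span_idx[length(region$span_idx)]
  ord <- ((seq_len(L) + after - 1L) %% L) + 1L
  rest_ord <- ord[ord %in% rest]
  new_blocks <- c(.make_tokens(merged_lab, merged_sg), toks_all[rest_ord])
  out <- gss(g$id, new_blocks, stage = "bpisac")
  attr(out, "merged") <- .make_tokens(merged_lab, merged_sg)
  attr(out, "unique_merge") <- !region$boundary_ambiguous && !mixed
  out
}

#' Insert a virtual tandem copy of an anchor
#'
#' Adds `new_label` in tandem with the existing occurrence of `label`,
#' downstream in the anchor's own reading direction (after it on the plus
#' strand, before it on the minus strand) and with the same sign. The new
#' adjacency is then conserved across genomes, so pairwise inversion and
#' breakpoint distances are unchanged.
#'
#' @param g a `gss` carrying `label` exactly once.
#' @param label existing anchor label.
#' @param new_label label of the virtual copy. A label ending in "a" is
#'   placed upstream (the a-copy precedes the b-copy in reading
#'   direction), anything else downstream.
#' @export
add_virtual_copy <- function(g, label, new_label) {
  p <- .parse_gss(g)
  i <- which(p$lab == label)
  if (length(i) != 1) stop("label ", label, " must occur exactly once in ",
                           g$id)
  downstream <- !grepl("a$", new_label)
  at <- if (downstream == (p$sg[i] > 0)) i else i - 1L
  lab <- append(p$lab, new_label, after = at)
  sg <- append(p$sg, p$sg[i], after = at)
  gss(g$id, .make_tokens(lab, sg), stage = g$stage)
}

# neighbor labels within circular distance 2 of occurrence index i
.flanks <- function(lab, i) {
  L <- length(lab)
  off <- c(-2, -1, 1, 2)
  unique(lab[((i - 1 + off) %% L) + 1])
}

#' Disambiguate remaining paralogous anchors and finalize GSSs
#'
#' Implements the duplicate framework end to end: (i) detect and collapse
#' genome-specific tandem regions; (ii) for anchors still duplicated,
#' assign suffixes a/b by neighborhood (the copy adjacent to the anchor's
#' strongest neighborhood partner gets "a", remaining genomes by flanking
#' agreement); (iii) insert virtual tandem copies in genomes carrying a
#' single copy; (iv) delete, in all genomes, anchors whose copies cannot be
#' disambiguated; and verify that the final GSSs share one occurrence of
#' every label.
#'
#' @param x a `gss_set` (stage bpisac).
#' @param graph optional precomputed [build_neighborhood_graph()].
#' @param collapse collapse detectable tandem regions first.
#' @return List with `gss` (final `gss_set`), `rename_log`, `removed`,
#'   `virtual` and `tdpl_records`.
#' @export
disambiguate_paralogs <- function(x, graph = NULL, collapse = TRUE) {
  stopifnot(inherits(x, "gss_set"))
  if (is.null(graph)) graph <- build_neighborhood_graph(x)
  log_rows <- list()
  tdpl_records <- list()
  cur <- as.list(x)

  if (collapse) {
    for (gid in names(cur)) {
      repeat {
        regs <- detect_tandem_regions(cur[[gid]], graph)
        regs <- Filter(function(r) !r$irreconcilable, regs)
        if (length(regs) == 0) break
        r <- regs[[1]]
        res <- tryCatch(collapse_tandem_region(cur[[gid]], r),
                        error = function(e) NULL)
        if (is.null(res)) break
        cur[[gid]] <- res
        tdpl_records[[length(tdpl_records) + 1]] <- r
        log_rows[[length(log_rows) + 1]] <- data.frame(
          genome = gid, old = paste(r$shared, collapse = ","),
          new = paste(r$shared, collapse = ","), reason = "tdpl_collapsed",
          stringsAsFactors = FALSE)
      }
    }
  }

  # remaining duplicated labels over the whole set
  all_cnt <- lapply(cur, function(g) table(gss_labels(g)))
  labels <- unique(unlist(lapply(cur, gss_labels)))
  removed <- character(0)
  virtual <- list()
  dup_labels <- Filter(function(l)
    any(vapply(all_cnt, function(ct) isTRUE(ct[l] >= 2), logical(1))),
    labels)

  for (dl in dup_labels) {
    counts <- vapply(all_cnt, function(ct)
      if (is.na(ct[dl])) 0L else as.integer(ct[dl]), integer(1))
    if (any(counts > 2)) { removed <- c(removed, dl); next }
    # strongest neighborhood partner: a unique (non-duplicated) anchor,
    # since a duplicated partner flanks both copies
    cand <- setdiff(graph$labels, c(dl, dup_labels))
    if (length(cand) == 0) cand <- setdiff(graph$labels, dl)
    wrow <- graph$w[dl, cand]
    partner <- names(sort(wrow, decreasing = TRUE))[1]
    a_flanks <- NULL; b_flanks <- NULL
    assign_ok <- TRUE
    plan <- list()
    for (gid in names(cur)) {
      if (counts[gid] < 2) next
      p <- .parse_gss(cur[[gid]])
      occ <- which(p$lab == dl)
      near <- vapply(occ, function(i) partner %in% .flanks(p$lab, i),
                     logical(1))
      if (sum(near) == 1) {
        a_i <- occ[near]; b_i <- occ[!near]
      } else if (!is.null(a_flanks)) {
        ov_a <- vapply(occ, function(i)
          length(intersect(.flanks(p$lab, i), a_flanks)), integer(1))
        ov_b <- vapply(occ, function(i)
          length(intersect(.flanks(p$lab, i), b_flanks)), integer(1))
        pref <- ov_a - ov_b
        if (pref[1] == pref[2]) { assign_ok <- FALSE; break }
        a_i <- occ[which.max(pref)]; b_i <- occ[which.min(pref)]
      } else { assign_ok <- FALSE; break }
      if (is.null(a_flanks)) {
        a_flanks <- setdiff(.flanks(p$lab, a_i), dl)
        b_flanks <- setdiff(.flanks(p$lab, b_i), dl)
      }
      plan[[gid]] <- c(a = a_i, b = b_i)
    }
    if (!assign_ok) { removed <- c(removed, dl); next }
    # apply suffixes, then complete single-copy genomes with virtual copies
    for (gid in names(cur)) {
      p <- .parse_gss(cur[[gid]])
      if (counts[gid] >= 2) {
        p$lab[plan[[gid]]["a"]] <- paste0(dl, "a")
        p$lab[plan[[gid]]["b"]] <- paste0(dl, "b")
        cur[[gid]] <- gss(gid, .make_tokens(p$lab, p$sg), stage = "bpisac")
        log_rows[[length(log_rows) + 1]] <- data.frame(
          genome = gid, old = dl, new = paste0(dl, "a/", dl, "b"),
          reason = "paralogs_distinguished", stringsAsFactors = FALSE)
      } else if (counts[gid] == 1) {
        i <- which(p$lab == dl)
        fl <- .flanks(p$lab, i)
        suff <- if (!is.null(b_flanks) &&
                    length(intersect(fl, b_flanks)) >
                    length(intersect(fl, a_flanks))) "b" else "a"
        other <- setdiff(c("a", "b"), suff)
        p$lab[i] <- paste0(dl, suff)
        cur[[gid]] <- add_virtual_copy(
          gss(gid, .make_tokens(p$lab, p$sg), stage = "bpisac"),
          paste0(dl, suff), paste0(dl, other))
        virtual[[length(virtual) + 1]] <- data.frame(
          genome = gid, label = paste0(dl, suff),
          inserted = paste0(dl, other), stringsAsFactors = FALSE)
        log_rows[[length(log_rows) + 1]] <- data.frame(
          genome = gid, old = dl, new = paste0(dl, suff),
          reason = "virtual_copy_added", stringsAsFactors = FALSE)
      }
    }
  }

  # deletion of unresolvable anchors, in every genome
  for (dl in unique(removed)) {
    for (gid in names(cur)) {
      p <- .parse_gss(cur[[gid]])
      keep <- p$lab != dl
      cur[[gid]] <- gss(gid, .make_tokens(p$lab[keep], p$sg[keep]),
                        stage = "bpisac")
    }
    log_rows[[length(log_rows) + 1]] <- data.frame(
      genome = "*", old = dl, new = "", reason = "unresolvable_removed",
      stringsAsFactors = FALSE)
  }

  final <- lapply(cur, function(g) {
    labs <- gss_labels(g)
    if (anyDuplicated(labs))
      stop("internal error: labels still duplicated in ", g$id, ": ",
           paste(unique(labs[duplicated(labs)]), collapse = ", "))
    gss(g$id, g$blocks, stage = "final")
  })
  ref <- sort_gss_labels(gss_labels(final[[1]]))
  for (g in final) {
    if (!setequal(gss_labels(g), ref))
      stop("internal error: final GSSs do not share one occurrence of ",
           "each label (genome ", g$id, ")")
  }
  list(gss = gss_set(final),
       rename_log = if (length(log_rows)) do.call(rbind, log_rows)
                    else data.frame(genome = character(0),
                                    old = character(0), new = character(0),
                                    reason = character(0)),
       removed = unique(removed),
       virtual = if (length(virtual)) do.call(rbind, virtual)
                 else data.frame(genome = character(0), label = character(0),
                                 inserted = character(0)),
       tdpl_records = tdpl_records)
}

#' Label bookkeeping from bpisac anchors to final GSS blocks
#'
#' Applies a deletion list and a list of duplicated anchors that are split
#' into a/b copies to the 1..n anchor alphabet, returning the final label
#' set (deleted anchors dropped; each split anchor contributes two suffixed
#' labels).
#'
#' @param n_anchors number of bpisac anchors.
#' @param deleted integer anchors removed entirely.
#' @param duplicated integer anchors split into a/b pairs (including
#'   single-copy genomes completed with virtual copies).
#' @return Character vector of final labels.
#' @export
gss_label_bookkeeping <- function(n_anchors, deleted = integer(0),
                                  duplicated = integer(0)) {
  base <- setdiff(seq_len(n_anchors), c(deleted, duplicated))
  c(as.character(base),
    paste0(rep(duplicated, each = 2), c("a", "b")))
}
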