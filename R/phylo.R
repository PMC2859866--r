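# Tree inference and event placement: BIONJ on rearrangement distance
# matrices, outgroup rooting, block-jackknife support, an MGR-like greedy
# reconstruction of ancestral gene orders, and assembly of per-branch event
# scenarios with duplications reintroduced.

#' BIONJ tree from a distance matrix
#'
#' @param D symmetric matrix with zero diagonal and dimnames (at least 3
#'   taxa).
#' @return Unrooted `phylo` tree.
#' @export
bionj_tree <- function(D) {
  if (nrow(D) < 3) stop("need at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-9) stop("matrix must be symmetric")
  ape::bionj(D)
}

#' Root a tree on the edge separating an outgroup
#'
#' When the outgroup is not monophyletic in the unrooted tree, the tree is
#' rooted at the outgroup's most recent common ancestor with a warning.
#'
#' @param tree `phylo`.
#' @param outgroup character vector of leaf names.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  stopifnot(all(outgroup %in% tree$tip.label))
  mono <- ape::is.monophyletic(tree, outgroup)
  if (mono) {
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  } else {
    warning("outgroup is not a clade; rooting at its MRCA")
    node <- ape::getMRCA(tree, outgroup)
    tryCatch(ape::root(tree, node = node, resolve.root = TRUE),
             error = function(e) ape::root(tree, node = node))
  }
}

#' Non-trivial bipartitions of an unrooted tree as canonical keys
#'
#' @param tree `phylo`.
#' @return Character vector; each key lists the sorted tips of the side not
#'   containing the alphabetically first tip, separated by `|`.
#' @export
tree_splits <- function(tree) {
  tr <- ape::unroot(tree)
  pp <- ape::prop.part(tr)
  tips <- attr(pp, "labels")
  anchor <- sort(tips)[1]
  sz <- vapply(pp, length, integer(1))
  keep <- sz >= 2 & sz <= length(tips) - 2
  unique(vapply(pp[keep], function(s) {
    side <- tips[s]
    if (anchor %in% side) side <- setdiff(tips, side)
    paste(sort(side), collapse = "|")
  }, character(1)))
}

#' Block-jackknife support for a rearrangement tree
#'
#' Per replicate, a random `1 - keep_fraction` subset of GSS blocks is
#' deleted from all genomes, the distance matrix and BIONJ tree are
#' recomputed, and the recurrence of each reference bipartition recorded.
#' Virtual tandem copies participate as ordinary blocks.
#'
#' @param x a `gss_set` of final GSSs over a common label set.
#' @param keep_fraction fraction of blocks kept per replicate (in (0, 1]).
#' @param replicates number of jackknife replicates.
#' @param seed integer seed (reproducible, invariant to genome order).
#' @param tree reference tree whose splits are scored; defaults to the
#'   full-data BIONJ tree.
#' @param metric distance metric (see [distance_matrix()]).
#' @return List with `tree` (reference), `supports` (data.frame `split`,
#'   `support` in percent) and `replicates`.
#' @export
jackknife_support <- function(x, keep_fraction = 0.9, replicates = 1000,
                              seed = NULL, tree = NULL,
                              metric = "inversion") {
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]")
  labels <- sort_gss_labels(gss_labels(x[[1]]))
  n <- length(labels)
  n_drop <- round((1 - keep_fraction) * n)
  if (n - n_drop < 4) stop("too few blocks kept per replicate")
  if (is.null(tree)) tree <- bionj_tree(distance_matrix(x, metric))
  ref <- tree_splits(tree)
  counts <- setNames(numeric(length(ref)), ref)
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      drop <- if (n_drop > 0) sample(labels, n_drop) else character(0)
      sub <- gss_set(lapply(x, function(g) {
        keep <- !(gss_labels(g) %in% drop)
        gss(g$id, g$blocks[keep], stage = "final")
      }))
      tr <- bionj_tree(distance_matrix(sub, metric))
      hit <- ref %in% tree_splits(tr)
      counts[hit] <- counts[hit] + 1
    }
  })
  list(tree = tree,
       supports = data.frame(split = ref,
                             support = 100 * unname(counts) / replicates),
       replicates = replicates)
}

# clade tip-sets of a rooted tree
.clade_sets <- function(tree) {
  pp <- ape::prop.part(tree)
  tips <- attr(pp, "labels")
  lapply(pp, function(s) sort(tips[s]))
}

#' MGR-like greedy reconstruction of ancestral gene orders
#'
#' Heuristic for the parsimonious-tree problem: repeatedly apply to some
#' genome the inversion that most decreases the sum of its inversion
#' distances to all others (ties: smallest interval, then lexicographic);
#' genomes that become identical merge into an ancestor node. When no
#' single inversion lowers the total, the closest (allowed) pair is merged
#' by sorting one genome into the other. With a `topology`, merges are
#' constrained to its cherries.
#'
#' @param x a `gss_set` of final GSSs (3 or more genomes), or a named list
#'   of signed permutations over a common alphabet.
#' @param topology optional rooted `phylo` constraining the merge order.
#' @return List with `tree` (rooted `phylo`, internal nodes labelled
#'   A1..Ak, branch lengths = inversions), `ancestors` (named list of
#'   signed permutations), `score` (total inversions) and `labels` (the
#'   label alphabet of the permutations).
#' @export
mgr_like_ancestors <- function(x, topology = NULL) {
  if (inherits(x, "gss_set")) {
    alph <- sort_gss_labels(gss_labels(x[[1]]))
    perms <- lapply(x, function(g)
      as_perm(canonicalize(g, origin = alph[1], labels = alph)))
  } else {
    alph <- NULL
    perms <- lapply(x, check_perm)
  }
  ids <- names(perms)
  stopifnot(length(perms) >= 2)
  clades <- if (!is.null(topology)) .clade_sets(topology) else NULL
  active <- perms
  leafset <- lapply(ids, function(i) i)
  names(leafset) <- ids
  nwk <- setNames(as.list(ids), ids)
  events <- setNames(rep(0L, length(ids)), ids)
  ancestors <- list()
  score <- 0L
  anc_i <- 0L

  allowed_pair <- function(a, b) {
    if (is.null(clades)) return(TRUE)
    u <- sort(c(leafset[[a]], leafset[[b]]))
    any(vapply(clades, function(cl) identical(cl, u), logical(1)))
  }
  merge_pair <- function(a, b) {
    anc_i <<- anc_i + 1L
    nm <- paste0("A", anc_i)
    ancestors[[nm]] <<- active[[a]]
    nwk[[nm]] <<- paste0("(", nwk[[a]], ":", events[[a]], ",", nwk[[b]],
                         ":", events[[b]], ")", nm)
    leafset[[nm]] <<- sort(c(leafset[[a]], leafset[[b]]))
    active[[nm]] <<- active[[a]]
    events[[nm]] <<- 0L
    for (z in c(a, b)) {
      active[[z]] <<- NULL
      nwk[[z]] <<- NULL
      leafset[[z]] <<- NULL
      events <<- events[names(events) != z]
    }
  }

  while (length(active) > 1) {
    nm <- names(active)
    # merge identical allowed pairs first
    merged <- FALSE
    for (a in nm) {
      for (b in nm) {
        if (a >= b || !allowed_pair(a, b)) next
        if (identical(active[[a]], active[[b]])) {
          merge_pair(a, b)
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (merged) next
    if (length(active) == 1) break
    # greedy: best single reversal over all genomes
    best <- NULL
    for (a in names(active)) {
      others <- do.call(rbind, active[names(active) != a])
      cur_tot <- sum(cpp_distance_matrix(
        do.call(rbind, c(active[a], active[names(active) != a])))[1, -1])
      br <- cpp_best_reversal(active[[a]], others)
      delta <- br[["total"]] - cur_tot
      if (is.null(best) || delta < best$delta)
        best <- list(a = a, i = br[["i"]], j = br[["j"]], delta = delta)
    }
    if (!is.null(best) && best$delta < 0) {
      active[[best$a]] <- apply_inversion(active[[best$a]], best$i, best$j)
      events[[best$a]] <- events[[best$a]] + 1L
      score <- score + 1L
    } else {
      # local optimum: sort the closest allowed pair into each other
      nm <- names(active)
      bestp <- NULL
      for (a in nm) for (b in nm) {
        if (a >= b || !allowed_pair(a, b)) next
        d <- cpp_inversion_distance(active[[a]], active[[b]])
        if (is.null(bestp) || d < bestp$d) bestp <- list(a = a, b = b,
                                                         d = d)
      }
      if (is.null(bestp)) stop("no allowed merge pair under the topology")
      sc <- cpp_sorting_scenario(active[[bestp$a]], active[[bestp$b]])
      for (r in seq_len(nrow(sc))) {
        active[[bestp$a]] <- apply_inversion(active[[bestp$a]],
                                             sc[r, 1], sc[r, 2])
        events[[bestp$a]] <- events[[bestp$a]] + 1L
        score <- score + 1L
      }
    }
  }
  root_nm <- names(active)[1]
  txt <- paste0(nwk[[root_nm]], ";")
  tree <- ape::read.tree(text = txt)
  if (!(root_nm %in% names(ancestors)))
    ancestors[[root_nm]] <- active[[root_nm]]
  list(tree = tree, ancestors = ancestors, score = score, labels = alph)
}

#' Place duplication and loss events on a rooted tree
#'
#' Each shared tandem duplication is assigned to the branch above the most
#' recent common ancestor of the genomes retaining both real copies
#' (genome-specific duplications land on terminal branches); per-copy
#' losses are placed below the duplication on the stems of the maximal
#' clades lacking that copy. Genome-specific collapsed tandem regions are
#' re-expanded into TD + L event pairs on their terminal branch. Inversion
#' events are added per branch when ancestral permutations are supplied.
#'
#' @param tree rooted `phylo` whose tips are genome ids; internal node
#'   labels (e.g. A1..Ak from [mgr_like_ancestors()]) name the branches.
#' @param resolution result of [disambiguate_paralogs()] (uses the
#'   `virtual` table and `tdpl_records`).
#' @param ancestors optional named list of signed permutations for internal
#'   nodes (plus the leaf permutations), as from [mgr_like_ancestors()];
#'   when given, per-branch inversion events are computed with
#'   [sorting_scenario()].
#' @param perms optional named list of leaf permutations (required with
#'   `ancestors`).
#' @return Object of class `rearrangement_scenario`: list with `tree` and
#'   `branches` (named by child node; ordered event lists, each event a
#'   list with `type` in I/TD/TDPL/L, `labels`, and for inversions the
#'   interval applied).
#' @export
place_duplication_events <- function(tree, resolution, ancestors = NULL,
                                     perms = NULL) {
  tips <- tree$tip.label
  ntip <- length(tips)
  node_lab <- function(v) {
    if (v <= ntip) tips[v]
    else if (!is.null(tree$node.label) &&
             nzchar(tree$node.label[v - ntip])) tree$node.label[v - ntip]
    else paste0("N", v)
  }
  branches <- list()
  add_event <- function(child, ev) {
    key <- node_lab(child)
    branches[[key]] <<- c(branches[[key]], list(ev))
  }
  final_labels <- sort_gss_labels(gss_labels(resolution$gss[[1]]))
  suffixed <- grep("[ab]$", final_labels, value = TRUE)
  dup_bases <- unique(sub("[ab]$", "", suffixed))
  virt <- resolution$virtual

  clade_node <- function(leaves) {
    if (length(leaves) == 1) return(match(leaves, tips))
    ape::getMRCA(tree, leaves)
  }
  for (db in dup_bases) {
    la <- paste0(db, "a"); lb <- paste0(db, "b")
    virt_genomes <- unique(virt$genome[sub("[ab]$", "", virt$inserted) ==
                                         db])
    real_genomes <- setdiff(tips, virt_genomes)
    if (length(real_genomes) == 0) next
    mrca <- clade_node(real_genomes)
    homoplasy <- length(real_genomes) > 1 &&
      !ape::is.monophyletic(tree, real_genomes)
    if (homoplasy)
      warning("duplication of anchor ", db,
              " is not monophyletic; placed at the MRCA")
    add_event(mrca, list(type = "TD", labels = c(la, lb),
                         homoplasy = homoplasy))
    # losses: maximal clades of virtual-carrying genomes, per lost copy
    for (suffix in c("a", "b")) {
      lost <- paste0(db, suffix)
      lackers <- unique(virt$genome[virt$inserted == lost])
      if (length(lackers) == 0) next
      remaining <- lackers
      while (length(remaining) > 0) {
        # grow the largest clade consisting solely of lacking genomes
        cl <- remaining[1]
        repeat {
          anc <- clade_node(cl)
          up <- tree$edge[tree$edge[, 2] == anc, 1]
          if (length(up) == 0) break
          below <- ape::extract.clade(tree, up)$tip.label
          if (all(below %in% lackers)) cl <- below else break
        }
        add_event(clade_node(cl), list(type = "L", labels = lost))
        remaining <- setdiff(remaining, cl)
      }
    }
  }
  # genome-specific collapsed tandem regions: TD followed by per-copy L
  for (r in resolution$tdpl_records) {
    child <- match(r$genome_id, tips)
    labs <- unique(c(r$copyA$lab, r$copyB$lab))
    add_event(child, list(type = "TDPL", labels = labs,
                          lost_in_A = r$lost_in_A,
                          lost_in_B = r$lost_in_B))
  }
  # inversions from ancestral permutations
  if (!is.null(ancestors)) {
    all_perms <- c(ancestors, perms)
    for (ei in seq_len(nrow(tree$edge))) {
      pv <- node_lab(tree$edge[ei, 1]); cv <- node_lab(tree$edge[ei, 2])
      if (is.null(all_perms[[pv]]) || is.null(all_perms[[cv]])) next
      p <- all_perms[[pv]]; q <- all_perms[[cv]]
      sc <- sorting_scenario(p, q)
      cur <- as_perm(p)
      for (s in seq_len(nrow(sc))) {
        seg <- abs(cur[sc$i[s]:sc$j[s]])
        labs <- if (!is.null(final_labels) &&
                    max(seg) <= length(final_labels))
          final_labels[seg] else as.character(seg)
        add_event(tree$edge[ei, 2],
                  list(type = "I", labels = labs, i = sc$i[s], j = sc$j[s]))
        cur <- apply_inversion(cur, sc$i[s], sc$j[s])
      }
    }
  }
  structure(list(tree = tree, branches = branches),
            class = "rearrangement_scenario")
}

#' @export
print.rearrangement_scenario <- function(x, ...) {
  cat("<rearrangement_scenario> over", length(x$branches), "branches\n")
  for (b in names(x$branches)) {
    evs <- vapply(x$branches[[b]], function(e)
      paste0(e$type, "{", paste(e$labels, collapse = " "), "}"),
      character(1))
    cat("  ", b, ": ", paste(evs, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Precedence constraints among the events of one branch
#'
#' Two inversions are ordered iff their label contents overlap; a tandem
#' duplication (TD/TDPL) precedes any later event touching its duplicated
#' labels. Events not connected by a constraint may be permuted freely.
#'
#' @param events ordered event list for one branch (from a
#'   `rearrangement_scenario`).
#' @return data.frame with columns `from`, `to` (indices into `events`).
#' @export
event_partial_order <- function(events) {
  n <- length(events)
  out <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      ei <- events[[i]]; ej <- events[[j]]
      overlap <- length(intersect(ei$labels, ej$labels)) > 0
      constrained <-
        (ei$type == "I" && ej$type == "I" && overlap) ||
        (ei$type %in% c("TD", "TDPL") && overlap) ||
        (ej$type %in% c("TD", "TDPL") && overlap)
      if (constrained)
        out[[length(out) + 1]] <- data.frame(from = i, to = j)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(from = integer(0), to = integer(0))
}

#' Apply label-anchored inversion events to a signed permutation
#'
#' Each inversion is located by its label content (which must be
#' contiguous) rather than fixed positions, so independent events commute;
#' used to replay linear extensions of a branch partial order.
#'
#' @param p signed permutation.
#' @param events list of events with `type == "I"` and `labels` (label
#'   ranks are `abs` values of `p`'s alphabet indices when `labels` is
#'   numeric-like, otherwise matched through `alphabet`).
#' @param alphabet label alphabet giving rank of each label.
#' @export
apply_labeled_events <- function(p, events, alphabet = NULL) {
  p <- as_perm(p)
  for (ev in events) {
    if (ev$type != "I") next
    ranks <- if (is.null(alphabet)) as.integer(ev$labels)
             else match(ev$labels, alphabet)
    pos <- sort(match(ranks, abs(p)))
    if (any(is.na(pos)) || !identical(pos, seq(pos[1],
                                               pos[1] + length(pos) - 1)))
      stop("inversion labels are not contiguous; cannot replay")
    p <- apply_inversion(p, pos[1], pos[length(pos)])
  }
  p
}
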