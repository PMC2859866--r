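# Synthetic-history generator: circular signed-block genomes evolving along
# a rooted tree by inversions, tandem duplications with per-copy partial
# loss (TDPL) and duplicate-copy losses, with a replayable event log; plus
# nucleotide-level generators (markers rendered into annotated genomes, and
# substitution-only sequence evolution) so the whole pipeline runs offline.

#' Simulation parameters
#'
#' Defaults emulate the study conditions of the eight-maize/teosinte-genome
#' setting: ~69 anchors on a circle, an 8-leaf rooted tree with 2-6
#' structural events per branch, mostly inversions with occasional tandem
#' duplications (segment length 1-12 anchors, per-copy anchor-loss
#' probability 0.3) and duplicate losses.
#'
#' @param n_blocks number of synteny anchors at the root.
#' @param tree rooted `phylo` with branch lengths = expected event counts;
#'   `NULL` draws a random 8-leaf rooted topology with branch lengths
#'   uniform in `branch_range` when the history is simulated.
#' @param mix event-type probabilities `c(inv, tdpl, loss)`; must sum to 1.
#' @param tdpl_len_max maximal duplicated segment length (anchors).
#' @param q per-copy anchor-loss probability after a tandem duplication
#'   (every anchor retains at least one copy).
#' @param branch_range branch-length range for a randomly drawn tree.
#' @param branch_model `"poisson"` draws Poisson(branch length) events from
#'   `mix`; `"uniform"` applies exactly `round(branch length)` inversions
#'   per branch plus, with probability `p_tdpl_branch`, one tandem
#'   duplication (no separate loss events) - the regime of a known number
#'   of inversions per branch with at most one duplication.
#' @param p_tdpl_branch per-branch tandem-duplication probability under the
#'   `"uniform"` branch model.
#' @export
sim_params <- function(n_blocks = 69, tree = NULL,
                       mix = c(inv = 0.8, tdpl = 0.1, loss = 0.1),
                       tdpl_len_max = 12, q = 0.3,
                       branch_range = c(2, 6),
                       branch_model = c("poisson", "uniform"),
                       p_tdpl_branch = 0.5) {
  branch_model <- match.arg(branch_model)
  stopifnot(n_blocks >= 4, length(mix) == 3, all(mix >= 0),
            abs(sum(mix) - 1) < 1e-9, q >= 0, q <= 1)
  structure(list(n_blocks = n_blocks, tree = tree, mix = mix,
                 tdpl_len_max = tdpl_len_max, q = q,
                 branch_range = branch_range, branch_model = branch_model,
                 p_tdpl_branch = p_tdpl_branch), class = "sim_params")
}

# state: list(base = int, sign = int, copy = chr "" / "a" / "b")
.state_rotate <- function(st, k) {
  L <- length(st$base)
  idx <- ((seq_len(L) + k - 2L) %% L) + 1L
  list(base = st$base[idx], sign = st$sign[idx], copy = st$copy[idx])
}

.apply_event <- function(st, ev) {
  L <- length(st$base)
  if (ev$type == "inv") {
    st <- .state_rotate(st, ev$start)
    r <- seq_len(ev$len)
    st$base[r] <- rev(st$base[r])
    st$sign[r] <- -rev(st$sign[r])
    st$copy[r] <- rev(st$copy[r])
  } else if (ev$type == "tdpl") {
    st <- .state_rotate(st, ev$start)
    seg <- seq_len(ev$len)
    a <- list(base = st$base[seg], sign = st$sign[seg],
              copy = rep("a", ev$len))
    b <- list(base = st$base[seg], sign = st$sign[seg],
              copy = rep("b", ev$len))
    keepA <- !ev$lossA; keepB <- !ev$lossB
    rest <- setdiff(seq_len(L), seg)
    st <- list(base = c(a$base[keepA], b$base[keepB], st$base[rest]),
               sign = c(a$sign[keepA], b$sign[keepB], st$sign[rest]),
               copy = c(a$copy[keepA], b$copy[keepB], st$copy[rest]))
  } else if (ev$type == "loss") {
    st <- list(base = st$base[-ev$occ], sign = st$sign[-ev$occ],
               copy = st$copy[-ev$occ])
  }
  st
}

.sample_branch_events <- function(st, lambda, params) {
  if (identical(params$branch_model, "uniform")) {
    types <- rep("inv", max(0L, round(lambda)))
    if (runif(1) < params$p_tdpl_branch) {
      at <- sample.int(length(types) + 1L, 1)
      types <- append(types, "tdpl", after = at - 1L)
    }
  } else {
    types <- character(rpois(1, lambda))
  }
  k <- length(types)
  evs <- list()
  for (e in seq_len(k)) {
    L <- length(st$base)
    ty <- if (nzchar(types[e])) types[e] else
      sample(c("inv", "tdpl", "loss"), 1, prob = params$mix)
    ev <- NULL
    if (ty == "inv") {
      len <- sample.int(max(1L, floor(L / 2)), 1)
      ev <- list(type = "inv", start = sample.int(L, 1), len = len)
    } else if (ty == "tdpl") {
      cnt <- table(st$base)
      for (try in 1:30) {
        len <- sample.int(min(params$tdpl_len_max, L - 1L), 1)
        start <- sample.int(L, 1)
        seg <- ((start - 1L + seq_len(len) - 1L) %% L) + 1L
        bases <- st$base[seg]
        if (anyDuplicated(bases) == 0 && all(cnt[as.character(bases)] == 1)
            && all(st$copy[seg] == "")) {
          lossA <- runif(len) < params$q
          lossB <- runif(len) < params$q
          both <- lossA & lossB
          if (any(both)) {
            flip <- runif(sum(both)) < 0.5
            lossA[both][flip] <- FALSE
            lossB[both][!flip] <- FALSE
          }
          ev <- list(type = "tdpl", start = start, len = len,
                     lossA = lossA, lossB = lossB)
          break
        }
      }
    } else {
      cnt <- table(st$base)
      dup <- names(cnt)[cnt >= 2]
      if (length(dup) > 0) {
        db <- as.integer(sample(dup, 1))
        occ <- which(st$base == db)
        ev <- list(type = "loss", occ = occ[sample.int(length(occ), 1)])
      }
    }
    if (!is.null(ev)) {
      st <- .apply_event(st, ev)
      evs[[length(evs) + 1]] <- ev
    }
  }
  list(state = st, events = evs)
}

.random_rooted_tree <- function(n_leaves, branch_range) {
  tr <- ape::rtree(n_leaves, rooted = TRUE,
                   tip.label = paste0("G", seq_len(n_leaves)))
  tr$edge.length <- runif(nrow(tr$edge), branch_range[1], branch_range[2])
  tr
}

#' Simulate a rearrangement history along a rooted tree
#'
#' The root is the identity circle `1..n_blocks` (all positive). On each
#' branch, a Poisson(branch length) number of events is drawn from the
#' event mix: inversions of uniform circular intervals (at most half the
#' genome), tandem duplications with independent per-copy anchor loss
#' (every anchor keeps at least one copy), and losses of one random
#' duplicated-copy anchor. Seeded and reproducible; the event log replays
#' to the leaves exactly.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed.
#' @return List with `tree`, `leaves_bpisac` (a `gss_set` of signed base
#'   labels with duplicates), `leaves_final` (ground-truth-resolved
#'   `gss_set` with a/b suffixes and virtual copies completing single-copy
#'   genomes), `event_log` (per-branch ordered events), `states` (raw leaf
#'   states) and `n_events` per branch.
#' @export
simulate_history <- function(params = sim_params(), seed = NULL) {
  with_seed(seed, {
    tree <- params$tree
    if (is.null(tree))
      tree <- .random_rooted_tree(8, params$branch_range)
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    st0 <- list(base = seq_len(params$n_blocks),
                sign = rep(1L, params$n_blocks),
                copy = rep("", params$n_blocks))
    states <- list()
    states[[root]] <- st0
    log <- list()
    ord <- ape::reorder.phylo(tree, "cladewise")
    node_name <- function(v) {
      if (v <= ntip) tree$tip.label[v] else paste0("N", v)
    }
    for (ei in seq_len(nrow(ord$edge))) {
      par <- ord$edge[ei, 1]; chi <- ord$edge[ei, 2]
      res <- .sample_branch_events(states[[par]], ord$edge.length[ei],
                                   params)
      states[[chi]] <- res$state
      log[[node_name(chi)]] <- res$events
    }
    leaf_states <- setNames(lapply(seq_len(ntip), function(v) states[[v]]),
                            tree$tip.label)
    leaves_bpisac <- gss_set(lapply(names(leaf_states), function(nm) {
      st <- leaf_states[[nm]]
      gss(nm, .make_tokens(as.character(st$base), st$sign),
          stage = "bpisac")
    }))
    leaves_final <- .resolve_truth(leaf_states)
    list(tree = tree, leaves_bpisac = leaves_bpisac,
         leaves_final = leaves_final, event_log = log,
         states = leaf_states,
         n_events = vapply(log, length, integer(1)))
  })
}

# ground-truth paralog resolution: suffix tagged copies, complete
# single-copy genomes with a virtual tandem copy
.resolve_truth <- function(leaf_states) {
  dup_bases <- sort(unique(unlist(lapply(leaf_states, function(st)
    st$base[duplicated(st$base)]))))
  out <- lapply(names(leaf_states), function(nm) {
    st <- leaf_states[[nm]]
    basev <- st$base
    lab <- as.character(st$base)
    sg <- st$sign
    copyv <- st$copy
    for (db in dup_bases) {
      occ <- which(basev == db)
      if (length(occ) == 2) {
        tags <- copyv[occ]
        if (anyDuplicated(tags) || any(tags == "")) tags <- c("a", "b")
        lab[occ] <- paste0(db, tags)
      } else if (length(occ) == 1) {
        tag <- if (copyv[occ] %in% c("a", "b")) copyv[occ] else "a"
        other <- setdiff(c("a", "b"), tag)
        lab[occ] <- paste0(db, tag)
        # tandem insertion follows the anchor's own reading direction
        # (and a precedes b) so the created adjacency is conserved
        at <- if ((other == "b") == (sg[occ] > 0)) occ else occ - 1L
        lab <- append(lab, paste0(db, other), after = at)
        sg <- append(sg, sg[occ], after = at)
        basev <- append(basev, db, after = at)
        copyv <- append(copyv, other, after = at)
      }
    }
    gss(nm, .make_tokens(lab, sg), stage = "final")
  })
  gss_set(out)
}

#' Replay an event log from the root
#'
#' @param sim result of [simulate_history()].
#' @return Named list of leaf states; replaying must reproduce
#'   `sim$states` exactly (log-replay identity).
#' @export
replay_event_log <- function(sim) {
  tree <- sim$tree
  ntip <- length(tree$tip.label)
  st0 <- NULL
  n <- max(unlist(lapply(sim$states, function(s) s$base)))
  st0 <- list(base = seq_len(n), sign = rep(1L, n), copy = rep("", n))
  states <- list()
  states[[ntip + 1L]] <- st0
  ord <- ape::reorder.phylo(tree, "cladewise")
  node_name <- function(v) if (v <= ntip) tree$tip.label[v] else
    paste0("N", v)
  for (ei in seq_len(nrow(ord$edge))) {
    par <- ord$edge[ei, 1]; chi <- ord$edge[ei, 2]
    st <- states[[par]]
    for (ev in sim$event_log[[node_name(chi)]]) st <- .apply_event(st, ev)
    states[[chi]] <- st
  }
  setNames(lapply(seq_len(ntip), function(v) states[[v]]), tree$tip.label)
}

#' Simulate nucleotide sequences (substitutions only) along a tree
#'
#' Jukes-Cantor-style evolution: each branch substitutes every site
#' independently with probability `rate * branch length`, drawing uniformly
#' among the three other bases. No indels, so the leaf sequences form a
#' gap-free multiple alignment.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param length alignment length (bp).
#' @param rate per-site substitution probability per unit branch length.
#' @param seed integer seed.
#' @return Named character vector of leaf sequences.
#' @export
simulate_sequences <- function(tree, length = 10000, rate = 0.002,
                               seed = NULL) {
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    ntip <- base::length(tree$tip.label)
    seqs <- list()
    seqs[[ntip + 1L]] <- sample(bases, length, replace = TRUE)
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (ei in seq_len(nrow(ord$edge))) {
      par <- ord$edge[ei, 1]; chi <- ord$edge[ei, 2]
      s <- seqs[[par]]
      p <- min(1, rate * ord$edge.length[ei])
      hit <- which(runif(length) < p)
      if (base::length(hit) > 0) {
        s[hit] <- vapply(s[hit], function(b)
          sample(setdiff(bases, b), 1), character(1))
      }
      seqs[[chi]] <- s
    }
    setNames(vapply(seq_len(ntip), function(v)
      paste(seqs[[v]], collapse = ""), character(1)), tree$tip.label)
  })
}

#' Render a simulated history into annotated nucleotide genomes
#'
#' Each synteny anchor becomes a unique random marker sequence shared
#' ancestrally (protein-gene-like, 400-1500 bp, or tRNA-like, 60-90 bp)
#' and mutated along the tree at `subs_rate` per site per branch;
#' duplicate copies within a genome are identical, as in real
#' mitogenomes. Markers are separated by genome-specific random intergenic
#' spacers. Annotations follow GenBank conventions via [genome_record()].
#'
#' @param sim result of [simulate_history()].
#' @param subs_rate per-site substitution probability per branch.
#' @param intergenic_range intergenic spacer length range (bp).
#' @param p_gene probability that an anchor is protein-gene-like.
#' @param seed integer seed.
#' @return List with `records` (named list of [genome_record()]) and
#'   `truth` (data.frame: genome, position index, base label, copy tag,
#'   marker label, start, end, strand).
#' @export
simulate_marker_genomes <- function(sim, subs_rate = 0.002,
                                    intergenic_range = c(50, 300),
                                    p_gene = 0.7, seed = NULL) {
  with_seed(seed, {
    tree <- sim$tree
    ntip <- length(tree$tip.label)
    n <- max(unlist(lapply(sim$states, function(s) s$base)))
    bases4 <- c("A", "C", "G", "T")
    is_gene <- runif(n) < p_gene
    root_markers <- lapply(seq_len(n), function(b) {
      len <- if (is_gene[b]) sample(400:1500, 1) else sample(60:90, 1)
      sample(bases4, len, replace = TRUE)
    })
    marker_sets <- list()
    marker_sets[[ntip + 1L]] <- root_markers
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (ei in seq_len(nrow(ord$edge))) {
      par <- ord$edge[ei, 1]; chi <- ord$edge[ei, 2]
      ms <- marker_sets[[par]]
      if (subs_rate > 0) {
        ms <- lapply(ms, function(s) {
          hit <- which(runif(length(s)) < subs_rate)
          if (length(hit) > 0)
            s[hit] <- vapply(s[hit], function(b)
              sample(setdiff(bases4, b), 1), character(1))
          s
        })
      }
      marker_sets[[chi]] <- ms
    }
    records <- list()
    truth <- list()
    for (v in seq_len(ntip)) {
      nm <- tree$tip.label[v]
      st <- sim$states[[nm]]
      ms <- marker_sets[[v]]
      parts <- character(0)
      feats <- list()
      pos <- 0L
      for (i in seq_along(st$base)) {
        ig <- paste(sample(bases4, sample(intergenic_range[1]:
                                            intergenic_range[2], 1),
                           replace = TRUE), collapse = "")
        parts <- c(parts, ig)
        pos <- pos + nchar(ig)
        b <- st$base[i]
        mk <- paste(ms[[b]], collapse = "")
        seq_i <- if (st$sign[i] < 0) revcomp(mk) else mk
        start <- pos
        end <- pos + nchar(mk)
        lbl <- if (is_gene[b]) paste0("gene", b) else paste0("trn", b)
        kind <- if (is_gene[b]) "protein_gene" else "tRNA"
        feats[[length(feats) + 1]] <-
          feature_annotation(lbl, kind, list(c(start, end)), st$sign[i])
        truth[[length(truth) + 1]] <- data.frame(
          genome = nm, index = i, base = b, tag = st$copy[i], label = lbl,
          start = start, end = end, strand = st$sign[i],
          stringsAsFactors = FALSE)
        parts <- c(parts, seq_i)
        pos <- end
      }
      records[[nm]] <- genome_record(nm, paste(parts, collapse = ""),
                                     feats)
    }
    list(records = records, truth = do.call(rbind, truth))
  })
}
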