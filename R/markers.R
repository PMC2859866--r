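# Marker construction: annotated coding markers, reciprocal-best-hit
# ortholog families with length-class E-value thresholds, a simplified
# co-linear backbone builder (unique k-mer anchors chained across genomes),
# and non-coding markers from backbone fragments.

#' Extract annotated markers from a genome record
#'
#' One row per feature (protein genes, tRNAs, rRNAs, ORFs, pseudogenes);
#' the sequence is spliced over exons and reverse-complemented on the minus
#' strand.
#'
#' @param record a [genome_record()].
#' @return data.frame with columns `genome_id`, `label`, `kind`, `start`,
#'   `end` (0-based half-open span), `strand`, `sequence`.
#' @export
extract_markers <- function(record) {
  if (length(record$features) == 0)
    return(data.frame(genome_id = character(0), label = character(0),
                      kind = character(0), start = integer(0),
                      end = integer(0), strand = integer(0),
                      sequence = character(0)))
  rows <- lapply(record$features, function(f) {
    span <- range(unlist(f$exons))
    data.frame(genome_id = record$id, label = f$label, kind = f$kind,
               start = min(vapply(f$exons, `[`, integer(1), 1)),
               end = max(vapply(f$exons, `[`, integer(1), 2)),
               strand = f$strand, sequence = feature_sequence(record, f),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.rbh_pass <- function(score, len1, len2, evalue_long = 1e-170,
                      evalue_short = 1e-26, len_class = 100,
                      max_len_diff = 0.08, params = karlin_parameters()) {
  cut <- if (min(len1, len2) < len_class) log10(evalue_short)
         else log10(evalue_long)
  l10 <- log10_evalue(score, len1, len2, params)
  (l10 < cut) && (abs(len1 - len2) / max(len1, len2) < max_len_diff)
}

#' Reciprocal-best-hit marker families across genomes
#'
#' For every marker, the best local-alignment hit in each other genome's
#' marker set is determined; families are grown from mutual best pairs that
#' pass the length-class E-value thresholds (`evalue_long` for sequences of
#' at least `len_class` bp, `evalue_short` below) and whose sequence lengths
#' differ by less than `max_len_diff`. Best hits tied in score and subject
#' length are flagged indistinguishable. A family absent from some genome
#' triggers a rescue search of its representative against that genome's full
#' sequence; if the rescue also fails, the family is excluded and all its
#' members dropped.
#'
#' @param markers named list (by genome id) of marker data.frames as from
#'   [extract_markers()]; duplicated markers may appear twice per genome.
#' @param genome_seqs optional named character vector of full genome
#'   sequences used for the rescue search.
#' @param evalue_long,evalue_short,len_class,max_len_diff thresholds.
#' @return List with `families` (data.frame: `family_id`, `genome_id`,
#'   `label`, `row` index into the genome's marker table, `tie`, `rescued`)
#'   and `excluded` (data.frame of excluded families and the genomes that
#'   caused the exclusion).
#' @export
reciprocal_best_hits <- function(markers, genome_seqs = NULL,
                                 evalue_long = 1e-170,
                                 evalue_short = 1e-26, len_class = 100,
                                 max_len_diff = 0.08) {
  gids <- names(markers)
  if (is.null(gids) || length(gids) < 2)
    stop("need a named list of marker tables for at least two genomes")
  for (g in gids) if (nrow(markers[[g]]) == 0)
    stop("empty marker set for genome ", g)
  kp <- karlin_parameters()

  node_id <- function(g, i) paste0(g, "#", i)
  # best hit of each marker of g in h: index, plus tie flag
  best <- list()
  for (g in gids) for (h in setdiff(gids, g)) {
    mg <- markers[[g]]; mh <- markers[[h]]
    bi <- integer(nrow(mg)); tie <- logical(nrow(mg))
    for (i in seq_len(nrow(mg))) {
      sc <- .align_scores(mg$sequence[i], mh$sequence)
      top <- max(sc)
      cand <- which(sc == top)
      # ties: equal score and equal subject length are indistinguishable
      if (length(cand) > 1) {
        lens <- nchar(mh$sequence[cand])
        tie[i] <- anyDuplicated(lens) > 0
        cand <- cand[order(-lens)]
      }
      bi[i] <- cand[1]
    }
    best[[paste(g, h)]] <- list(idx = bi, tie = tie)
  }

  # union-find over mutual best pairs passing thresholds
  nodes <- unlist(lapply(gids, function(g)
    vapply(seq_len(nrow(markers[[g]])), node_id, character(1), g = g)))
  parent <- setNames(nodes, nodes)
  findp <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  tie_flag <- setNames(rep(FALSE, length(nodes)), nodes)
  for (g in gids) for (h in setdiff(gids, g)) {
    if (match(g, gids) > match(h, gids)) next
    bg <- best[[paste(g, h)]]; bh <- best[[paste(h, g)]]
    for (i in seq_along(bg$idx)) {
      j <- bg$idx[i]
      if (bh$idx[j] != i) next
      a <- markers[[g]]$sequence[i]; b <- markers[[h]]$sequence[j]
      sc <- .align_scores(a, b)
      if (!.rbh_pass(sc, nchar(a), nchar(b), evalue_long, evalue_short,
                     len_class, max_len_diff, kp)) next
      ni <- node_id(g, i); nj <- node_id(h, j)
      if (bg$tie[i] || bh$tie[j]) {
        tie_flag[ni] <- TRUE; tie_flag[nj] <- TRUE
      }
      parent[[findp(ni)]] <- findp(nj)
    }
  }

  roots <- vapply(nodes, findp, character(1))
  # attach markers left in singleton components (typically the second,
  # identical copy of a duplicated marker: only one copy can be the mutual
  # best) to the family of their best hit when the pair passes thresholds
  sizes <- table(roots)
  for (g in gids) {
    for (i in seq_len(nrow(markers[[g]]))) {
      ni <- node_id(g, i)
      if (sizes[[roots[[ni]]]] > 1) next
      for (h in setdiff(gids, g)) {
        j <- best[[paste(g, h)]]$idx[i]
        nj <- node_id(h, j)
        if (sizes[[roots[[nj]]]] <= 1) next
        a <- markers[[g]]$sequence[i]; b <- markers[[h]]$sequence[j]
        sc <- .align_scores(a, b)
        if (.rbh_pass(sc, nchar(a), nchar(b), evalue_long, evalue_short,
                      len_class, max_len_diff, kp)) {
          parent[[findp(ni)]] <- findp(nj)
          tie_flag[ni] <- TRUE  # homologous copy, orthology undecided
          break
        }
      }
    }
  }
  roots <- vapply(nodes, findp, character(1))
  fam_of <- match(roots, unique(roots))
  fam_rows <- data.frame(
    family_id = fam_of,
    genome_id = sub("#.*$", "", nodes),
    row = as.integer(sub("^.*#", "", nodes)),
    tie = unname(tie_flag), stringsAsFactors = FALSE)
  fam_rows$label <- vapply(seq_len(nrow(fam_rows)), function(r)
    markers[[fam_rows$genome_id[r]]]$label[fam_rows$row[r]], character(1))
  fam_rows$rescued <- FALSE

  # completeness: every genome must carry the family (rescue or exclude)
  keep <- logical(max(fam_rows$family_id))
  excluded <- list()
  for (fid in seq_len(max(fam_rows$family_id))) {
    sub <- fam_rows[fam_rows$family_id == fid, ]
    # singleton components are unmatched markers, not families
    if (length(unique(sub$genome_id)) < 2) next
    missing <- setdiff(gids, unique(sub$genome_id))
    ok <- TRUE
    if (length(missing) > 0) {
      rep_seq <- markers[[sub$genome_id[1]]]$sequence[sub$row[1]]
      for (mg in missing) {
        found <- FALSE
        if (!is.null(genome_seqs) && mg %in% names(genome_seqs)) {
          la <- local_align(rep_seq, genome_seqs[[mg]])
          cut <- if (nchar(rep_seq) < len_class) log10(evalue_short)
                 else log10(evalue_long)
          found <- la$log10_evalue < cut
        }
        if (found) {
          fam_rows <- rbind(fam_rows, data.frame(
            family_id = fid, genome_id = mg, row = NA_integer_,
            tie = FALSE, label = sub$label[1], rescued = TRUE,
            stringsAsFactors = FALSE))
        } else {
          ok <- FALSE
          excluded[[length(excluded) + 1]] <-
            data.frame(family_id = fid, label = sub$label[1],
                       missing_genome = mg, stringsAsFactors = FALSE)
        }
      }
    }
    keep[fid] <- ok
  }
  fams <- fam_rows[keep[fam_rows$family_id], , drop = FALSE]
  fams$family_id <- match(fams$family_id, unique(fams$family_id))
  rownames(fams) <- NULL
  list(families = fams,
       excluded = if (length(excluded)) do.call(rbind, excluded)
                  else data.frame(family_id = integer(0),
                                  label = character(0),
                                  missing_genome = character(0)))
}

# -- backbone ----------------------------------------------------------------

.kmer_catalog <- function(s, k) {
  n <- nchar(s)
  starts <- seq_len(n - k + 1)
  fw <- substring(s, starts, starts + k - 1)
  rc <- vapply(fw, .revcomp, character(1), USE.NAMES = FALSE)
  canon <- ifelse(fw <= rc, fw, rc)
  keep <- !grepl("N", fw, fixed = TRUE) & fw != rc  # drop palindromes
  canon <- canon[keep]; starts <- starts[keep]
  strand <- ifelse(fw[keep] <= rc[keep], 1L, -1L)
  cnt <- table(canon)
  uniq <- names(cnt)[cnt == 1]
  sel <- canon %in% uniq
  data.frame(kmer = canon[sel], pos = starts[sel], strand = strand[sel],
             stringsAsFactors = FALSE)
}

#' Build co-linear backbone fragments across genomes
#'
#' Simplified co-linear block finder: k-mers occurring exactly once in every
#' genome (canonical over both strands) serve as anchors; anchors are walked
#' in reference-genome order and chained while order, orientation and
#' inter-anchor spacing stay consistent in every genome. A spacing
#' discrepancy larger than `max_gap` in any genome splits the chain; blocks
#' shorter than `min_block` in any genome are discarded.
#'
#' @param seqs named character vector of (duplicate-masked) genome
#'   sequences, one per genome.
#' @param seed_weight anchor k-mer length.
#' @param min_island minimum genome-specific insertion treated as a real
#'   island (absorbed into the `max_gap` spacing test in this simplified
#'   chainer).
#' @param max_gap maximal tolerated inter-anchor spacing difference (bp).
#' @param min_block minimal fragment length (bp).
#' @param reference reference genome id (fragment order and numbering).
#' @return List with `fragments` (long data.frame: `fragment_id`,
#'   `genome_id`, `start`, `end`, `strand`, `length`) and `backbone`
#'   (named character vector: per-genome concatenation of fragments in
#'   reference order, minus-strand fragments reverse-complemented).
#' @export
build_backbone <- function(seqs, seed_weight = 9, min_island = 15,
                           max_gap = 15, min_block = 50,
                           reference = names(seqs)[1]) {
  if (length(seqs) < 2) stop("need at least two genomes")
  gids <- names(seqs)
  stopifnot(reference %in% gids)
  k <- seed_weight
  cats <- lapply(seqs, .kmer_catalog, k = k)
  shared <- Reduce(intersect, lapply(cats, function(d) d$kmer))
  if (length(shared) == 0)
    return(list(fragments = data.frame(), backbone = setNames(
      rep("", length(gids)), gids)))
  pos <- lapply(cats, function(d) {
    i <- match(shared, d$kmer)
    list(pos = d$pos[i], strand = d$strand[i])
  })
  ref <- pos[[reference]]
  ord <- order(ref$pos)
  # per-genome positions/strands in reference order; rel strand vs reference
  P <- lapply(gids, function(g) pos[[g]]$pos[ord])
  S <- lapply(gids, function(g) pos[[g]]$strand[ord] * ref$strand[ord])
  names(P) <- names(S) <- gids
  m <- length(ord)
  split_after <- logical(m - 1)
  if (m > 1) {
    dref <- diff(P[[reference]])
    for (g in gids) {
      dg <- diff(P[[g]])
      rel <- S[[g]]
      same_rel <- rel[-m] == rel[-1]
      dg_rel <- dg * rel[-m]
      split_after <- split_after | !same_rel | dg_rel <= 0 |
        abs(dg_rel - dref) > max_gap
    }
  }
  block_id <- cumsum(c(1, as.integer(split_after)))
  frag_rows <- list()
  backbone <- setNames(rep("", length(gids)), gids)
  fid <- 0
  for (b in unique(block_id)) {
    sel <- which(block_id == b)
    ok <- TRUE
    rows <- list()
    for (g in gids) {
      p <- P[[g]][sel]
      st <- S[[g]][sel][1]
      s0 <- min(p) - 1L
      e0 <- max(p) + k - 1L
      if (e0 - s0 < min_block) { ok <- FALSE; break }
      rows[[g]] <- c(s0, e0, st)
    }
    if (!ok) next
    fid <- fid + 1
    for (g in gids) {
      r <- rows[[g]]
      frag <- substr(seqs[[g]], r[1] + 1, r[2])
      if (r[3] < 0) frag <- revcomp(frag)
      backbone[g] <- paste0(backbone[g], frag)
      frag_rows[[length(frag_rows) + 1]] <- data.frame(
        fragment_id = fid, genome_id = g, start = r[1], end = r[2],
        strand = as.integer(r[3]), length = r[2] - r[1],
        stringsAsFactors = FALSE)
    }
  }
  list(fragments = if (length(frag_rows)) do.call(rbind, frag_rows)
                   else data.frame(),
       backbone = backbone)
}

#' Non-coding markers from backbone fragments
#'
#' Backbone fragments longer than `min_len` bp in every genome become
#' non-coding markers, excluding fragments fully contained in an annotated
#' coding region in any genome (they would be counted twice).
#'
#' @param backbone result of [build_backbone()].
#' @param records named list of [genome_record()] (for feature spans and
#'   sequences).
#' @param min_len minimal fragment length.
#' @return data.frame in the layout of [extract_markers()] with
#'   `kind = "noncoding"` and labels `nc<fragment_id>`.
#' @export
extract_noncoding_markers <- function(backbone, records, min_len = 100) {
  fr <- backbone$fragments
  out <- list()
  if (is.null(fr) || nrow(fr) == 0) return(data.frame())
  for (fid in unique(fr$fragment_id)) {
    sub <- fr[fr$fragment_id == fid, ]
    if (any(sub$length <= min_len)) next
    contained <- FALSE
    for (r in seq_len(nrow(sub))) {
      rec <- records[[sub$genome_id[r]]]
      for (f in rec$features) {
        span <- range(unlist(f$exons))
        if (sub$start[r] >= span[1] && sub$end[r] <= span[2]) {
          contained <- TRUE
          break
        }
      }
      if (contained) break
    }
    if (contained) next
    for (r in seq_len(nrow(sub))) {
      rec <- records[[sub$genome_id[r]]]
      s <- substr(rec$sequence, sub$start[r] + 1, sub$end[r])
      if (sub$strand[r] < 0) s <- revcomp(s)
      out[[length(out) + 1]] <- data.frame(
        genome_id = sub$genome_id[r], label = paste0("nc", fid),
        kind = "noncoding", start = sub$start[r], end = sub$end[r],
        strand = sub$strand[r], sequence = s, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else data.frame()
}

#' Concatenated per-fragment global alignment of two genomes' backbones
#'
#' Aligns each backbone fragment of the two genomes globally (match/mismatch
#' with affine gaps) and concatenates the alignments in reference order.
#'
#' @param backbone result of [build_backbone()].
#' @param records named list of [genome_record()].
#' @param g1,g2 genome ids.
#' @return An `aligned_pair`: list with gapped strings `a`, `b` and
#'   `source = "backbone"`.
#' @export
backbone_alignment <- function(backbone, records, g1, g2) {
  fr <- backbone$fragments
  a_all <- character(0); b_all <- character(0)
  for (fid in unique(fr$fragment_id)) {
    sub <- fr[fr$fragment_id == fid, ]
    r1 <- sub[sub$genome_id == g1, ]; r2 <- sub[sub$genome_id == g2, ]
    if (nrow(r1) != 1 || nrow(r2) != 1) next
    s1 <- substr(records[[g1]]$sequence, r1$start + 1, r1$end)
    if (r1$strand < 0) s1 <- revcomp(s1)
    s2 <- substr(records[[g2]]$sequence, r2$start + 1, r2$end)
    if (r2$strand < 0) s2 <- revcomp(s2)
    ga <- global_align(s1, s2)
    a_all <- c(a_all, ga$a); b_all <- c(b_all, ga$b)
  }
  structure(list(a = paste(a_all, collapse = ""),
                 b = paste(b_all, collapse = ""), source = "backbone"),
            class = "aligned_pair")
}
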