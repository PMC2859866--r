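# From ordered common markers to signed Genome Structure Sequences:
# markers that are contiguous, co-ordered and co-oriented as a unit in every
# occurrence in every genome are grouped into synteny anchors; anchors are
# numbered along a reference genome and signed by strand relative to it.

#' Ordered marker occurrences per genome from RBH families
#'
#' @param rbh result of [reciprocal_best_hits()].
#' @param markers the marker tables passed to [reciprocal_best_hits()].
#' @return Named list (per genome) of data.frames `label` (family label),
#'   `pos`, `strand`, ordered by position; rescued members without
#'   coordinates are dropped.
#' @export
family_marker_orders <- function(rbh, markers) {
  fams <- rbh$families
  out <- list()
  for (g in names(markers)) {
    sub <- fams[fams$genome_id == g & !is.na(fams$row), ]
    mt <- markers[[g]][sub$row, ]
    d <- data.frame(label = paste0("f", sub$family_id), pos = mt$start,
                    strand = mt$strand, stringsAsFactors = FALSE)
    out[[g]] <- d[order(d$pos), ]
  }
  out
}

.check_orders <- function(orders) {
  gids <- names(orders)
  if (is.null(gids) || length(gids) < 1) stop("need named marker orders")
  labs <- lapply(orders, function(d) unique(d$label))
  common <- Reduce(intersect, labs)
  for (g in gids) {
    miss <- setdiff(unique(unlist(labs)), labs[[g]])
    if (length(miss) > 0)
      stop("marker(s) missing from genome ", g, ": ",
           paste(head(miss, 5), collapse = ", "),
           " (filter to common markers upstream)")
  }
  invisible(common)
}

# does every occurrence of x and y in every genome realize the signed
# adjacency (x sx) -> (y sy) as a unit (allowing whole-unit reversal)?
.always_adjacent <- function(orders, x, y, sx, sy) {
  for (d in orders) {
    lab <- d$label; sg <- d$strand
    L <- length(lab)
    nx <- which(lab == x); ny <- which(lab == y)
    if (length(nx) != length(ny)) return(FALSE)
    claimed <- integer(0)
    for (i in nx) {
      nxt <- if (i == L) 1L else i + 1L
      prv <- if (i == 1L) L else i - 1L
      if (sg[i] == sx && lab[nxt] == y && sg[nxt] == sy) {
        j <- nxt
      } else if (sg[i] == -sx && lab[prv] == y && sg[prv] == -sy) {
        j <- prv
      } else return(FALSE)
      if (j %in% claimed) return(FALSE)
      claimed <- c(claimed, j)
    }
    # every y occurrence must be claimed by exactly one x occurrence
    if (!setequal(claimed, ny)) return(FALSE)
  }
  TRUE
}

#' Group co-ordered common markers into synteny anchors
#'
#' Maximal runs of markers that are adjacent (no intervening common
#' marker), co-ordered and co-oriented as a unit in every occurrence in
#' every genome are merged into one anchor; all other markers become
#' singleton anchors.
#'
#' @param orders named list (per genome) of data.frames with columns
#'   `label`, `pos`, `strand`, ordered by position; circular adjacency
#'   (last to first) counts. Every label must occur in every genome.
#' @return List of anchors; each anchor is a list with `members` (ordered
#'   labels) and `signs` (member strands in canonical anchor orientation).
#' @export
group_markers_into_anchors <- function(orders) {
  .check_orders(orders)
  orders <- lapply(orders, function(d) d[order(d$pos), ])
  # candidate pairs: adjacencies observed in the first genome
  d1 <- orders[[1]]
  L <- nrow(d1)
  parent <- setNames(unique(d1$label), unique(d1$label))
  findp <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  merged_rel <- list()
  for (i in seq_len(L)) {
    j <- if (i == L) 1L else i + 1L
    x <- d1$label[i]; y <- d1$label[j]
    if (x == y) next
    sx <- d1$strand[i]; sy <- d1$strand[j]
    if (.always_adjacent(orders, x, y, sx, sy)) {
      parent[[findp(x)]] <- findp(y)
      merged_rel[[length(merged_rel) + 1]] <- list(x = x, y = y, sx = sx,
                                                   sy = sy)
    }
  }
  comp <- vapply(names(parent), findp, character(1))
  anchors <- list()
  for (r in unique(comp)) {
    members <- names(comp)[comp == r]
    # order members and record canonical signs from their first run in the
    # first genome
    first_idx <- match(members, d1$label)
    ord <- order(first_idx)
    members <- members[ord]
    # canonical orientation: as the unit appears at its first occurrence
    signs <- d1$strand[match(members, d1$label)]
    ref_sign <- signs[1]
    anchors[[length(anchors) + 1]] <-
      list(members = members, signs = as.integer(signs * ref_sign))
  }
  anchors
}

# one anchor occurrence: forward unit (orientation +/-1) or reversed unit
.match_unit <- function(mlabs, msgs, a) {
  k <- length(a$members)
  if (identical(mlabs, a$members) && all(msgs == msgs[1] * a$signs))
    return(as.integer(msgs[1]))
  flipped <- rev(-msgs)
  if (identical(rev(mlabs), a$members) &&
      all(flipped == flipped[1] * a$signs))
    return(as.integer(-flipped[1]))
  NA_integer_
}

# locate anchor occurrences in one genome's marker order
.anchor_occurrences <- function(d, anchors) {
  lab <- d$label; sg <- d$strand; ps <- d$pos
  L <- length(lab)
  member_of <- integer(0)
  size_of <- integer(length(anchors))
  for (ai in seq_along(anchors)) {
    member_of[anchors[[ai]]$members] <- ai
    size_of[ai] <- length(anchors[[ai]]$members)
  }
  aidx <- unname(member_of[lab])
  # rotate so index 1 starts a fresh run (avoids splitting across the wrap)
  rot <- 1L
  for (s in seq_len(L)) {
    prev <- if (s == 1) L else s - 1
    if (aidx[s] != aidx[prev]) { rot <- s; break }
  }
  idx <- ((seq_len(L) + rot - 2L) %% L) + 1L
  albs <- aidx[idx]
  brk <- c(which(diff(albs) != 0), L)
  start <- 1
  occ <- list()
  for (e in brk) {
    sel <- idx[start:e]
    start <- e + 1
    ai <- aidx[sel[1]]
    a <- anchors[[ai]]
    k <- size_of[ai]
    if (length(sel) %% k != 0)
      stop("anchor occurrence inconsistent with grouping for anchor ",
           paste(a$members, collapse = "+"))
    # tandem occurrences of the same anchor parse as consecutive chunks
    for (c0 in seq(1, length(sel), by = k)) {
      chunk <- sel[c0:(c0 + k - 1)]
      orient <- .match_unit(lab[chunk], sg[chunk], a)
      if (is.na(orient))
        stop("anchor occurrence inconsistent with grouping for anchor ",
             paste(a$members, collapse = "+"))
      occ[[length(occ) + 1]] <- data.frame(anchor = ai, pos = ps[chunk[1]],
                                           orient = orient)
    }
  }
  d2 <- do.call(rbind, occ)
  d2[order(d2$pos), ]
}

#' Number synteny anchors along a reference genome
#'
#' The reference genome's anchors receive labels 1..n in ascending position
#' of their first occurrence, all positive; other genomes inherit the labels
#' with sign -1 when an occurrence lies on the opposite strand relative to
#' the reference.
#'
#' @param orders as for [group_markers_into_anchors()].
#' @param anchors result of [group_markers_into_anchors()].
#' @param reference reference genome id (defaults to the first).
#' @return Named list (per genome) of data.frames `number`, `pos`, `sign`,
#'   plus attribute `anchor_table` mapping numbers to member markers.
#' @export
assign_numbers <- function(orders, anchors,
                           reference = names(orders)[1]) {
  stopifnot(reference %in% names(orders))
  occ <- lapply(orders, .anchor_occurrences, anchors = anchors)
  refocc <- occ[[reference]]
  first <- refocc[!duplicated(refocc$anchor), ]
  first <- first[order(first$pos), ]
  number_of <- integer(length(anchors))
  ref_orient <- integer(length(anchors))
  number_of[first$anchor] <- seq_len(nrow(first))
  ref_orient[first$anchor] <- first$orient
  out <- lapply(occ, function(d) {
    data.frame(number = number_of[d$anchor], pos = d$pos,
               sign = d$orient * ref_orient[d$anchor])
  })
  tab <- data.frame(
    number = number_of,
    members = vapply(anchors, function(a)
      paste(a$members, collapse = ","), character(1)))
  attr(out, "anchor_table") <- tab[order(tab$number), ]
  out
}

#' Build GSS bpisac sequences from numbered anchors
#'
#' @param numbered result of [assign_numbers()].
#' @return A `gss_set` (stage bpisac): per genome, the circular order of
#'   signed anchor labels including duplicate occurrences.
#' @export
build_gss_bpisac <- function(numbered) {
  gss_set(lapply(names(numbered), function(g) {
    d <- numbered[[g]][order(numbered[[g]]$pos), ]
    if (any(d$number == 0)) stop("anchor with no reference occurrence in ",
                                 g)
    gss(g, ifelse(d$sign < 0, paste0("-", d$number),
                  as.character(d$number)), stage = "bpisac")
  }))
}
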