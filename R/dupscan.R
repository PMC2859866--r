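# Detection of large intra-genome duplicated segments by seed-and-extend
# self-comparison under +1/-3 scoring, plus Table-1-style duplication
# statistics and masking of one copy per duplicate for backbone building.
#
# Circularity: the genome is doubled (sequence + sequence) for scanning and
# hits are normalized back to [0, n). Ungapped X-drop extension; exact-match
# seeds; hits merged per diagonal. N symbols never match.

.seed_positions <- function(s, k) {
  # named list kmer -> integer positions (1-based); kmers containing N skipped
  n <- nchar(s)
  if (n < k) return(list())
  starts <- seq_len(n - k + 1)
  kms <- substring(s, starts, starts + k - 1)
  keep <- !grepl("N", kms, fixed = TRUE)
  split(starts[keep], kms[keep])
}

# X-drop maximal-scoring extension along one diagonal.
# step: per-position scores (match/mismatch; NA = never extend through)
.xdrop_extend <- function(step, from, to, xdrop) {
  # returns c(lo, hi) of the maximal-scoring run containing [from, to]
  n <- length(step)
  lo <- from; hi <- to
  # right
  if (hi < n) {
    seg <- step[(hi + 1):n]
    seg[is.na(seg)] <- -Inf
    sc <- cumsum(seg)
    run_max <- cummax(sc)
    stop_at <- which(run_max - sc > xdrop)
    lim <- if (length(stop_at)) stop_at[1] - 1 else length(sc)
    if (lim > 0) {
      best <- which.max(sc[seq_len(lim)])
      if (sc[best] > 0) hi <- hi + best
    }
  }
  # left
  if (lo > 1) {
    seg <- rev(step[1:(lo - 1)])
    seg[is.na(seg)] <- -Inf
    sc <- cumsum(seg)
    run_max <- cummax(sc)
    stop_at <- which(run_max - sc > xdrop)
    lim <- if (length(stop_at)) stop_at[1] - 1 else length(sc)
    if (lim > 0) {
      best <- which.max(sc[seq_len(lim)])
      if (sc[best] > 0) lo <- lo - best
    }
  }
  c(lo, hi)
}

.circ_positions <- function(start0, end0, n) {
  # 0-based half-open, end0 may exceed n (wrap); returns 1-based positions
  (seq.int(start0, end0 - 1) %% n) + 1L
}

#' Find large duplicated segments within one genome
#'
#' Self-comparison of the genome (both strands) with exact-match seeds and
#' ungapped X-drop extension under the stated scoring; overlapping hits are
#' merged into maximal segments. The trivial full-length self-hit is
#' excluded. Only segments of at least `min_len` bases whose Karlin-Altschul
#' E-value (search space n^2) does not exceed `evalue_max` are returned.
#'
#' @param genome a [genome_record()] or a nucleotide string.
#' @param min_len minimal segment length in bases.
#' @param match,mismatch alignment scores.
#' @param evalue_max E-value cutoff (compared in log10 space).
#' @param seed_len exact-match seed length.
#' @param xdrop ungapped extension termination threshold.
#' @param band diagonal band within which overlapping segments are merged.
#' @return data.frame with columns `start_a`, `end_a`, `start_b`, `end_b`
#'   (0-based half-open; `end` may exceed the genome length when a copy
#'   spans the origin), `orientation` ("direct"/"inverted"), `length`,
#'   `score`, `log10_evalue`, `overlapping` (flag: the two copies overlap).
#' @export
find_duplicated_segments <- function(genome, min_len = 500, match = 1,
                                     mismatch = -3, evalue_max = 1e-300,
                                     seed_len = 12, xdrop = 20, band = 10) {
  s <- if (inherits(genome, "genome_record")) genome$sequence else
    toupper(genome)
  n <- nchar(s)
  empty <- data.frame(start_a = integer(0), end_a = integer(0),
                      start_b = integer(0), end_b = integer(0),
                      orientation = character(0), length = integer(0),
                      score = numeric(0), log10_evalue = numeric(0),
                      overlapping = logical(0))
  if (n < min_len || n < seed_len) return(empty)
  doubled <- paste0(s, s)
  dchars <- strsplit(doubled, "")[[1]]
  kp <- karlin_parameters(match, mismatch)
  log10_cut <- log10(evalue_max)

  segs <- list()
  scan_strand <- function(qseq, inverted) {
    qchars <- strsplit(qseq, "")[[1]]
    nq <- nchar(qseq)
    qpos <- .seed_positions(qseq, seed_len)
    dpos <- .seed_positions(doubled, seed_len)
    shared <- intersect(names(qpos), names(dpos))
    hits_q <- integer(0); hits_d <- integer(0)
    for (km in shared) {
      qs <- qpos[[km]]; ds <- dpos[[km]]
      grid <- expand.grid(q = qs, d = ds)
      if (!inverted) {
        keep <- grid$d > grid$q & ((grid$d - grid$q) %% n) != 0
      } else {
        keep <- rep(TRUE, nrow(grid))
      }
      hits_q <- c(hits_q, grid$q[keep]); hits_d <- c(hits_d, grid$d[keep])
    }
    if (length(hits_q) == 0) return(invisible(NULL))
    diag <- hits_d - hits_q
    for (dg in unique(diag)) {
      qs <- sort(hits_q[diag == dg])
      # per-position step scores along this diagonal (NA outside range)
      q_lo <- max(1L, 1L - dg)
      q_hi <- min(nq, 2L * n - dg)
      if (q_hi - q_lo + 1 < seed_len) next
      step <- rep(NA_real_, nq)
      qi <- q_lo:q_hi
      mvec <- qchars[qi] == dchars[qi + dg] & qchars[qi] != "N" &
        dchars[qi + dg] != "N"
      step[qi] <- ifelse(mvec, match, mismatch)
      # cluster seeds with small gaps, extend each cluster
      brk <- c(0, which(diff(qs) > 4 * seed_len), length(qs))
      for (ci in seq_len(length(brk) - 1)) {
        cl <- qs[(brk[ci] + 1):brk[ci + 1]]
        from <- min(cl); to <- min(max(cl) + seed_len - 1, q_hi)
        ext <- .xdrop_extend(step, from, to, xdrop)
        lo <- ext[1]; hi <- ext[2]
        len <- hi - lo + 1
        if (len < min_len) next
        score <- sum(step[lo:hi])
        l10 <- log10_evalue(score, n, n, kp)
        if (l10 > log10_cut) next
        if (!inverted) {
          a0 <- lo - 1L; a1 <- hi
          b0 <- lo + dg - 1L; b1 <- hi + dg
        } else {
          # query coords are on the reverse complement: map back
          a0 <- nq - hi; a1 <- nq - lo + 1L
          b0 <- lo + dg - 1L; b1 <- hi + dg
        }
        segs[[length(segs) + 1]] <<- list(a0 = a0, a1 = a1, b0 = b0,
                                          b1 = b1, inverted = inverted,
                                          len = len, score = score,
                                          l10 = l10)
      }
    }
    invisible(NULL)
  }

  scan_strand(s, inverted = FALSE)
  scan_strand(revcomp(s), inverted = TRUE)
  if (length(segs) == 0) return(empty)

  # normalize to [0, n), order the two copies, drop the mirrored duplicates
  rows <- lapply(segs, function(x) {
    a0 <- x$a0 %% n; a1 <- a0 + (x$a1 - x$a0)
    b0 <- x$b0 %% n; b1 <- b0 + (x$b1 - x$b0)
    if (b0 < a0) { t0 <- a0; t1 <- a1; a0 <- b0; a1 <- b1; b0 <- t0; b1 <- t1 }
    c(a0, a1, b0, b1, as.integer(x$inverted), x$len, x$score, x$l10)
  })
  m <- do.call(rbind, rows)
  # self-pair from palindromic/degenerate mapping
  m <- m[!(m[, 1] == m[, 3] & m[, 2] == m[, 4]), , drop = FALSE]
  if (nrow(m) == 0) return(empty)
  # merge segments whose copies overlap on both intervals (same orientation)
  merged <- list()
  used <- rep(FALSE, nrow(m))
  ivl_overlap <- function(s1, e1, s2, e2) (s1 < e2) && (s2 < e1)
  for (i in seq_len(nrow(m))) {
    if (used[i]) next
    cur <- m[i, ]
    repeat {
      grew <- FALSE
      for (j in seq_len(nrow(m))) {
        if (used[j] || j == i) next
        if (m[j, 5] != cur[5]) next
        if (ivl_overlap(cur[1], cur[2], m[j, 1], m[j, 2]) &&
            ivl_overlap(cur[3], cur[4], m[j, 3], m[j, 4]) &&
            abs((m[j, 3] - m[j, 1]) - (cur[3] - cur[1])) <= band) {
          cur[1] <- min(cur[1], m[j, 1]); cur[2] <- max(cur[2], m[j, 2])
          cur[3] <- min(cur[3], m[j, 3]); cur[4] <- max(cur[4], m[j, 4])
          cur[6] <- cur[2] - cur[1]
          cur[7] <- max(cur[7], m[j, 7]); cur[8] <- min(cur[8], m[j, 8])
          used[j] <- TRUE
          grew <- TRUE
        }
      }
      if (!grew) break
    }
    used[i] <- TRUE
    merged[[length(merged) + 1]] <- cur
  }
  m <- unique(do.call(rbind, merged))
  m <- m[m[, 6] >= min_len, , drop = FALSE]
  if (nrow(m) == 0) return(empty)
  ovl <- vapply(seq_len(nrow(m)), function(i) {
    pa <- .circ_positions(m[i, 1], m[i, 2], n)
    pb <- .circ_positions(m[i, 3], m[i, 4], n)
    length(intersect(pa, pb)) > 0
  }, logical(1))
  out <- data.frame(start_a = as.integer(m[, 1]), end_a = as.integer(m[, 2]),
                    start_b = as.integer(m[, 3]), end_b = as.integer(m[, 4]),
                    orientation = ifelse(m[, 5] == 1, "inverted", "direct"),
                    length = as.integer(m[, 6]), score = m[, 7],
                    log10_evalue = m[, 8], overlapping = ovl)
  out[order(out$start_a, out$start_b), , drop = FALSE]
}

#' Duplication statistics in the layout of a per-genome summary table
#'
#' Each duplicated fragment is counted once: `total_duplicated_kbp` is the
#' sum of per-pair copy lengths, `percent_duplicated` relates it to the
#' genome length, and `length_without_duplication_kbp` removes one copy of
#' each duplicate from the genome.
#'
#' @param segments data.frame from [find_duplicated_segments()].
#' @param genome_length genome length in bases.
#' @return One-row data.frame with kbp-scaled columns.
#' @export
duplication_stats <- function(segments, genome_length) {
  if (genome_length <= 0) stop("genome_length must be positive")
  lens <- segments$length / 1000
  total <- sum(lens)
  data.frame(
    genome_length_kbp = genome_length / 1000,
    total_duplicated_kbp = total,
    percent_duplicated = 100 * total / (genome_length / 1000),
    min_dup_kbp = if (length(lens)) min(lens) else NA_real_,
    max_dup_kbp = if (length(lens)) max(lens) else NA_real_,
    median_dup_kbp = if (length(lens)) median(lens) else NA_real_,
    n_fragments = length(lens),
    length_without_duplication_kbp = genome_length / 1000 - total)
}

#' Shortest circular gap between the two copies of a duplicated segment
#'
#' @param segment one row of [find_duplicated_segments()] output (or a list
#'   with `start_a`, `end_a`, `start_b`, `end_b`).
#' @param genome_length genome length in bases.
#' @return Gap in bases; 0 when the copies are adjacent or overlap.
#' @export
tandem_gap <- function(segment, genome_length) {
  n <- genome_length
  a0 <- segment$start_a %% n; a1 <- a0 + (segment$end_a - segment$start_a)
  b0 <- segment$start_b %% n; b1 <- b0 + (segment$end_b - segment$start_b)
  pa <- .circ_positions(a0, a1, n)
  pb <- .circ_positions(b0, b1, n)
  if (length(intersect(pa, pb)) > 0) return(0L)
  g1 <- (b0 - a1) %% n
  g2 <- (a0 - b1) %% n
  as.integer(min(g1, g2))
}

#' Mask one copy of each duplicated segment with N
#'
#' The copy with the greater start coordinate (after normalizing to the
#' origin) is replaced by N; first copies are untouched. Masking is
#' idempotent because N never seeds or extends a match.
#'
#' @param genome a [genome_record()] or nucleotide string.
#' @param segments data.frame from [find_duplicated_segments()].
#' @return Same type as `genome`, with the masked sequence.
#' @export
mask_one_copy <- function(genome, segments) {
  rec <- inherits(genome, "genome_record")
  s <- if (rec) genome$sequence else toupper(genome)
  n <- nchar(s)
  chars <- strsplit(s, "")[[1]]
  for (i in seq_len(nrow(segments))) {
    sg <- segments[i, ]
    # second copy = greater normalized start
    if ((sg$start_b %% n) >= (sg$start_a %% n)) {
      pos <- .circ_positions(sg$start_b, sg$end_b, n)
    } else {
      pos <- .circ_positions(sg$start_a, sg$end_a, n)
    }
    chars[pos] <- "N"
  }
  out <- paste(chars, collapse = "")
  if (rec) genome_record(genome$id, out, genome$features) else out
}
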