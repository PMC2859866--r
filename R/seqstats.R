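# Sequence-level divergence: substitution counts on pairwise alignments,
# per-10 kb substitution rates, backbone/gene rate ratios, Kimura
# two-parameter distances and a bootstrapped BIONJ sequence tree.

#' Count substitutions in a pairwise alignment
#'
#' Columns containing a gap or N are excluded from the effective length L;
#' transitions (A<->G, C<->T) and transversions are tallied separately.
#'
#' @param a,b gapped aligned sequences of equal length (or an
#'   `aligned_pair` as `a`).
#' @return List with `L` (non-gap sites), `s` (substitutions), `P`
#'   (transition proportion), `Q` (transversion proportion), `transitions`,
#'   `transversions`.
#' @export
count_substitutions <- function(a, b = NULL) {
  if (inherits(a, "aligned_pair")) { b <- a$b; a <- a$a }
  if (nchar(a) != nchar(b))
    stop("aligned sequences differ in length (", nchar(a), " vs ",
         nchar(b), ")")
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  x <- x[ok]; y <- y[ok]
  L <- length(x)
  diff <- x != y
  purine <- function(z) z %in% c("A", "G")
  ts <- sum(diff & (purine(x) == purine(y)))
  tv <- sum(diff) - ts
  list(L = L, s = ts + tv, P = if (L > 0) ts / L else 0,
       Q = if (L > 0) tv / L else 0, transitions = ts, transversions = tv)
}

#' Substitution rate per 10 kb
#'
#' `rate = s / L * 10000`: substitutions per aligned non-gap site, scaled
#' to 10 kb.
#'
#' @param counts result of [count_substitutions()].
#' @export
substitution_rate_per10kb <- function(counts) {
  if (counts$L <= 0) stop("no aligned non-gap sites")
  counts$s / counts$L * 10000
}

#' Elementwise backbone/gene substitution-rate ratio table
#'
#' @param backbone_rates,gene_rates symmetric rate matrices over the same
#'   genomes.
#' @return Matrix with the upper triangle filled; a zero gene rate against
#'   a positive backbone rate yields `Inf` with a warning.
#' @export
rate_ratio_table <- function(backbone_rates, gene_rates) {
  stopifnot(identical(dimnames(backbone_rates), dimnames(gene_rates)))
  k <- nrow(backbone_rates)
  out <- matrix(NA_real_, k, k, dimnames = dimnames(backbone_rates))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    g <- gene_rates[i, j]; bb <- backbone_rates[i, j]
    if (g == 0 && bb > 0) {
      warning("zero gene rate with positive backbone rate for pair ",
              rownames(out)[i], "-", colnames(out)[j])
      out[i, j] <- Inf
    } else if (g == 0) {
      out[i, j] <- NA_real_
    } else out[i, j] <- bb / g
  }
  out
}

#' Kimura two-parameter distance
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` from transition and
#' transversion proportions.
#'
#' @param counts result of [count_substitutions()], or a transition
#'   proportion `P` (then `Q` must be given).
#' @param Q transversion proportion when `counts` is numeric.
#' @export
k2p_distance <- function(counts, Q = NULL) {
  if (is.list(counts)) { P <- counts$P; Q <- counts$Q } else P <- counts
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0)
    stop("saturated alignment: K2P distance undefined (1-2P-Q = ",
         signif(a1, 3), ", 1-2Q = ", signif(a2, 3), ")")
  -0.5 * log(a1) - 0.25 * log(a2)
}

.k2p_matrix <- function(aln) {
  ids <- names(aln)
  k <- length(ids)
  D <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    D[i, j] <- D[j, i] <- k2p_distance(count_substitutions(aln[[i]],
                                                           aln[[j]]))
  }
  D
}

#' Sequence-divergence BIONJ tree with bootstrap support
#'
#' Pairwise K2P distances are computed from a joint (gap-free columns
#' shared) multiple alignment; bootstrap resamples alignment columns with
#' replacement and records the recurrence of the full-data bipartitions.
#'
#' @param aln named character vector of aligned sequences of equal length.
#' @param bootstrap number of bootstrap replicates.
#' @param seed integer seed.
#' @param outgroup optional leaf set for rooting the returned tree.
#' @return List with `tree` (rooted when `outgroup` given), `supports`
#'   (data.frame `split`, `support` percent) and the K2P `distances`.
#' @export
sequence_tree <- function(aln, bootstrap = 1000, seed = NULL,
                          outgroup = NULL) {
  aln <- as.list(aln)
  lens <- vapply(aln, nchar, integer(1))
  if (length(unique(lens)) != 1)
    stop("aligned sequences must share one length")
  D <- .k2p_matrix(aln)
  tree <- bionj_tree(D)
  ref <- tree_splits(tree)
  counts <- setNames(numeric(length(ref)), ref)
  mat <- do.call(rbind, strsplit(unlist(aln), ""))
  rownames(mat) <- names(aln)
  L <- ncol(mat)
  with_seed(seed, {
    for (r in seq_len(bootstrap)) {
      cols <- sample.int(L, L, replace = TRUE)
      sub <- setNames(apply(mat[, cols, drop = FALSE], 1, paste,
                            collapse = ""), rownames(mat))
      tr <- bionj_tree(.k2p_matrix(as.list(sub)))
      hit <- ref %in% tree_splits(tr)
      counts[hit] <- counts[hit] + 1
    }
  })
  if (!is.null(outgroup)) tree <- root_with_outgroup(tree, outgroup)
  list(tree = tree,
       supports = data.frame(split = ref,
                             support = if (bootstrap > 0)
                               100 * unname(counts) / bootstrap
                             else rep(NA_real_, length(ref))),
       distances = D)
}
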