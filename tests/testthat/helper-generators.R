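# shared generators for property-style tests

rand_signed_perm <- function(n) {
  as.integer(sample(n) * sample(c(-1L, 1L), n, replace = TRUE))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

rc_dna <- function(s) chartr("ACGT", "TGCA",
                             paste(rev(strsplit(s, "")[[1]]),
                                   collapse = ""))

# all signed permutations of 1..n (list of integer vectors)
all_signed_perms <- function(n) {
  perms <- list(seq_len(1))
  if (n == 1) {
    idx <- matrix(1L, 1, 1)
  } else {
    idx <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    idx <- idx[apply(idx, 1, function(r) length(unique(r)) == n), ,
               drop = FALSE]
  }
  signs <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
  out <- vector("list", nrow(idx) * nrow(signs))
  k <- 1
  for (i in seq_len(nrow(idx))) {
    for (j in seq_len(nrow(signs))) {
      out[[k]] <- as.integer(idx[i, ] * signs[j, ])
      k <- k + 1
    }
  }
  out
}

# independent enumerator for circular neighborhood pair counting:
# unordered position pairs at circular distance 1 or 2, each counted once
brute_neighbor_weights <- function(token_lists) {
  w <- list()
  add <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "~")
    w[[key]] <<- (if (is.null(w[[key]])) 0 else w[[key]]) + 1
  }
  for (toks in token_lists) {
    lab <- sub("^-", "", toks)
    L <- length(lab)
    if (L < 2) next
    for (i in seq_len(L - 1)) {
      for (j in (i + 1):L) {
        d <- min(j - i, L - (j - i))
        if (d %in% c(1, 2) && lab[i] != lab[j]) add(lab[i], lab[j])
      }
    }
  }
  w
}

# linearized leaf permutations of a simulated history, over the common
# final label alphabet
sim_perms <- function(sim) {
  alph <- sort_gss_labels(gss_labels(sim$leaves_final[[1]]))
  lapply(sim$leaves_final, function(g)
    canonicalize(g, origin = alph[1], labels = alph))
}
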