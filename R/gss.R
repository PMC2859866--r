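# Genome Structure Sequences: a genome abstracted as a circular ordered list
# of signed synteny-anchor labels. Labels are positive integers with an
# optional single-letter suffix distinguishing resolved paralogs ("20a").

.token_re <- "^-?[0-9]+[a-z]?$"

#' Create a Genome Structure Sequence
#'
#' A GSS represents one circular genome as an ordered sequence of signed
#' synteny-anchor labels. Before paralog resolution (`stage = "bpisac"`)
#' labels may occur more than once; a final GSS carries every label exactly
#' once.
#'
#' @param id genome identifier.
#' @param blocks character vector of signed tokens, e.g. `c("1","-3","20a")`.
#'   Integer vectors are accepted and converted.
#' @param stage `"bpisac"` (duplicates allowed) or `"final"`.
#' @return An object of class `gss`.
#' @export
gss <- function(id, blocks, stage = c("bpisac", "final")) {
  stage <- match.arg(stage)
  blocks <- as.character(blocks)
  if (length(blocks) == 0) stop("GSS must contain at least one block")
  bad <- blocks[!grepl(.token_re, blocks)]
  if (length(bad) > 0)
    stop("invalid GSS token(s): ", paste(unique(bad), collapse = ", "))
  labs <- gss_labels_of(blocks)
  if (stage == "final" && anyDuplicated(labs))
    stop("final GSS must carry each label exactly once (genome ", id, ")")
  structure(list(id = as.character(id), blocks = blocks, stage = stage),
            class = "gss")
}

#' @export
print.gss <- function(x, ...) {
  cat("<gss> ", x$id, " (", x$stage, "): ",
      paste(x$blocks, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
length.gss <- function(x) length(x$blocks)

gss_labels_of <- function(blocks) sub("^-", "", blocks)
gss_signs_of <- function(blocks) ifelse(startsWith(blocks, "-"), -1L, 1L)

#' Unsigned labels / signs of a GSS
#' @param g a `gss` object.
#' @return Character vector of labels, or integer vector of +1/-1 signs.
#' @export
gss_labels <- function(g) gss_labels_of(g$blocks)

#' @rdname gss_labels
#' @export
gss_signs <- function(g) gss_signs_of(g$blocks)

#' Bundle several GSSs into a set
#'
#' @param x list of `gss` objects (or a single `gss`).
#' @return Named list of class `gss_set`.
#' @export
gss_set <- function(x) {
  if (inherits(x, "gss")) x <- list(x)
  stopifnot(all(vapply(x, inherits, logical(1), "gss")))
  ids <- vapply(x, function(g) g$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome id: ",
                               ids[duplicated(ids)][1])
  names(x) <- ids
  structure(x, class = "gss_set")
}

#' @export
print.gss_set <- function(x, ...) {
  cat("<gss_set> of", length(x), "genomes\n")
  for (g in x) print(g)
  invisible(x)
}

#' @export
`[.gss_set` <- function(x, i) {
  structure(unclass(x)[i], class = "gss_set")
}

# order labels by integer base then suffix ("2" < "10" < "10a" < "10b")
sort_gss_labels <- function(labels) {
  labels <- unique(labels)
  base <- as.integer(sub("[a-z]$", "", labels))
  suf <- ifelse(grepl("[a-z]$", labels), substring(labels, nchar(labels)), "")
  labels[order(base, suf)]
}

#' Read / write GSS files
#'
#' One genome per line: `<genome_id><TAB><space-separated signed tokens>`;
#' `#` starts a comment line. Circularity is implicit.
#'
#' @param path file path.
#' @return `read_gss` returns a `gss_set`.
#' @export
read_gss <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("malformed GSS line (expected id<TAB>tokens): ", ln)
    toks <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    if (parts[1] %in% vapply(out, function(g) g$id, character(1)))
      stop("duplicate genome id in GSS file: ", parts[1])
    out[[length(out) + 1]] <- gss(parts[1], toks)
  }
  gss_set(out)
}

#' @param x a `gss_set` (or single `gss`).
#' @rdname read_gss
#' @export
write_gss <- function(x, path) {
  if (inherits(x, "gss")) x <- gss_set(list(x))
  lines <- vapply(x, function(g)
    paste0(g$id, "\t", paste(g$blocks, collapse = " ")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Linearize a circular GSS into a canonical signed permutation
#'
#' Rotates the circle so the origin label comes first with positive sign
#' (reverse-complementing the whole circle first when the origin occurs on
#' the minus strand), then maps labels to integer ranks. Any rotation or
#' whole-circle reflection of the same circular GSS yields the identical
#' canonical form.
#'
#' @param g a `gss` with every label occurring exactly once.
#' @param origin origin label; default is the smallest label.
#' @param labels label alphabet defining integer ranks; defaults to the
#'   sorted labels of `g`. All genomes of a set must share one alphabet.
#' @return Integer vector of signed ranks (class `signed_permutation`) with
#'   attributes `labels`, `id` and `origin`.
#' @export
canonicalize <- function(g, origin = NULL, labels = NULL) {
  stopifnot(inherits(g, "gss"))
  labs <- gss_labels(g)
  if (anyDuplicated(labs))
    stop("cannot canonicalize a GSS with duplicated labels (genome ",
         g$id, "); resolve duplicates first")
  if (is.null(labels)) labels <- sort_gss_labels(labs)
  if (!setequal(labs, labels))
    stop("label alphabet mismatch for genome ", g$id)
  if (is.null(origin)) origin <- labels[1]
  idx <- match(origin, labs)
  if (is.na(idx)) stop("origin label '", origin, "' absent from genome ", g$id)
  blocks <- g$blocks
  signs <- gss_signs_of(blocks)
  if (signs[idx] < 0) {
    blocks <- rev(ifelse(startsWith(blocks, "-"),
                         sub("^-", "", blocks), paste0("-", blocks)))
    idx <- length(blocks) - idx + 1L
  }
  if (idx > 1) blocks <- c(blocks[idx:length(blocks)], blocks[1:(idx - 1)])
  perm <- match(gss_labels_of(blocks), labels) * gss_signs_of(blocks)
  structure(as.integer(perm), labels = labels, id = g$id, origin = origin,
            class = "signed_permutation")
}

#' @export
print.signed_permutation <- function(x, ...) {
  cat("<signed_permutation> ", attr(x, "id"), ": ",
      paste(unclass(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

# strip attributes for arithmetic use
as_perm <- function(p) {
  if (inherits(p, "signed_permutation")) as.integer(unclass(p))
  else as.integer(p)
}

check_perm <- function(p, arg = "p") {
  p <- as_perm(p)
  n <- length(p)
  if (n == 0 || any(p == 0) || anyNA(p))
    stop(arg, " is not a signed permutation")
  if (!identical(sort(abs(p)), seq_len(n)))
    stop(arg, " must contain each of 1..n exactly once (signed)")
  p
}
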