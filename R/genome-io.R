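# Annotated genome records and flat-file I/O. All internal coordinates are
# 0-based half-open; GenBank's 1-based inclusive convention is converted at
# the boundary. The GenBank reader is deliberately restricted to the dialect
# used for plant mitogenome records (LOCUS/FEATURES/ORIGIN; CDS, tRNA, rRNA
# and gene features; join/complement locations; the pseudo qualifier).

.feature_kinds <- c("protein_gene", "tRNA", "rRNA", "ORF", "pseudogene",
                    "noncoding")

#' Feature annotation
#'
#' @param label locus name.
#' @param kind one of `"protein_gene"`, `"tRNA"`, `"rRNA"`, `"ORF"`,
#'   `"pseudogene"`, `"noncoding"`.
#' @param exons list of `c(start, end)` 0-based half-open intervals in
#'   genome coordinates, in transcription order.
#' @param strand +1 or -1.
#' @export
feature_annotation <- function(label, kind, exons, strand = 1L) {
  kind <- match.arg(kind, .feature_kinds)
  if (length(exons) == 0) stop("feature ", label, " has no exons")
  exons <- lapply(exons, function(e) {
    e <- as.integer(e)
    if (length(e) != 2 || e[1] >= e[2])
      stop("feature ", label, ": exon must satisfy start < end")
    e
  })
  if (!strand %in% c(1L, -1L)) stop("strand must be +1 or -1")
  structure(list(label = as.character(label), kind = kind, exons = exons,
                 strand = as.integer(strand)), class = "feature_annotation")
}

#' Annotated circular genome record
#'
#' @param id text identifier.
#' @param sequence nucleotide string (A/C/G/T/N, uppercased).
#' @param features list of [feature_annotation()] objects.
#' @export
genome_record <- function(id, sequence, features = list()) {
  sequence <- toupper(as.character(sequence))
  n <- nchar(sequence)
  if (n == 0) stop("empty sequence")
  if (grepl("[^ACGTN]", sequence)) stop("sequence contains non-ACGTN symbols")
  for (f in features) {
    stopifnot(inherits(f, "feature_annotation"))
    for (e in f$exons) {
      if (e[1] < 0 || e[2] > n)
        stop("feature '", f$label, "' has coordinates outside [0, ", n, ")")
    }
  }
  structure(list(id = as.character(id), sequence = sequence, length = n,
                 features = features), class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record>", x$id, "-", x$length, "bp,",
      length(x$features), "features\n")
  invisible(x)
}

.revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

revcomp <- function(s) vapply(s, .revcomp, character(1), USE.NAMES = FALSE)

#' Extract the (spliced) nucleotide sequence of a feature
#' @param record a [genome_record()].
#' @param feature a [feature_annotation()] of that record.
#' @export
feature_sequence <- function(record, feature) {
  parts <- vapply(feature$exons, function(e)
    substr(record$sequence, e[1] + 1, e[2]), character(1))
  s <- paste(parts, collapse = "")
  if (feature$strand < 0) revcomp(s) else s
}

# -- GenBank location strings ------------------------------------------------

parse_gb_location <- function(loc, label = "?") {
  loc <- gsub("\\s", "", loc)
  strand <- 1L
  # peel complement() wrappers (outermost or around the whole join)
  while (grepl("^complement\\(.*\\)$", loc)) {
    loc <- sub("^complement\\(", "", loc)
    loc <- sub("\\)$", "", loc)
    strand <- -strand
  }
  parts <- if (grepl("^join\\(.*\\)$", loc)) {
    strsplit(sub("\\)$", "", sub("^join\\(", "", loc)), ",")[[1]]
  } else loc
  exons <- lapply(parts, function(p) {
    st <- 1L
    while (grepl("^complement\\(.*\\)$", p)) {
      p <- sub("\\)$", "", sub("^complement\\(", "", p))
      st <- -st
    }
    if (st != 1L)
      stop("feature '", label, "': per-exon complement is not supported")
    p <- gsub("[<>]", "", p)
    if (grepl("^[0-9]+$", p)) {
      a <- as.integer(p); b <- a
    } else if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "\\.\\.")[[1]])
      a <- ab[1]; b <- ab[2]
    } else stop("feature '", label, "': unsupported location '", p, "'")
    c(a - 1L, b)  # 1-based inclusive -> 0-based half-open
  })
  if (strand < 0) exons <- rev(exons)
  list(exons = exons, strand = strand)
}

# -- GenBank flat file reader ------------------------------------------------

#' Read an annotated genome from a GenBank flat file
#'
#' Parses the sequence (ORIGIN block) and one [feature_annotation()] per
#' CDS/tRNA/rRNA/gene feature. Multi-exon `join(...)` locations are kept as
#' ordered exon lists; `complement(...)` features get strand -1. Features
#' whose gene/locus_tag starts with "orf" (case-insensitive) are classed as
#' ORFs; features carrying the `/pseudo` qualifier as pseudogenes. `gene`
#' features are only retained when they denote an ORF or pseudogene (to
#' avoid duplicating their CDS).
#'
#' @param path GenBank flat file.
#' @return A [genome_record()].
#' @export
read_genome_annotation <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(trimws(locus[1]), "\\s+")[[1]][2]
        else basename(path)
  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) == 0) stop("GenBank parse error: no ORIGIN block in ",
                                path)
  # sequence
  seq_lines <- lines[(ostart[1] + 1):length(lines)]
  end <- grep("^//", seq_lines)
  if (length(end)) seq_lines <- seq_lines[seq_len(end[1] - 1)]
  sequence <- toupper(gsub("[^acgtnACGTN]", "", paste(seq_lines,
                                                      collapse = "")))
  # features
  features <- list()
  if (length(fstart)) {
    flines <- lines[(fstart[1] + 1):(ostart[1] - 1)]
    entries <- list()
    cur <- NULL
    for (ln in flines) {
      if (grepl("^ {5}\\S", ln)) {
        if (!is.null(cur)) entries[[length(entries) + 1]] <- cur
        key <- trimws(substr(ln, 1, 21))
        cur <- list(key = key, text = trimws(substring(ln, 22)))
      } else if (!is.null(cur)) {
        cur$text <- paste0(cur$text, "\n", trimws(ln))
      }
    }
    if (!is.null(cur)) entries[[length(entries) + 1]] <- cur
    for (e in entries) {
      if (!e$key %in% c("CDS", "tRNA", "rRNA", "gene")) next
      txt <- strsplit(e$text, "\n")[[1]]
      qstart <- grep("^/", txt)
      loc <- paste(txt[seq_len(if (length(qstart)) qstart[1] - 1
                               else length(txt))], collapse = "")
      quals <- txt[grepl("^/", txt)]
      getq <- function(name) {
        m <- grep(paste0("^/", name, "="), quals, value = TRUE)
        if (length(m) == 0) return(NA_character_)
        gsub('"', "", sub(paste0("^/", name, "="), "", m[1]))
      }
      label <- getq("gene")
      if (is.na(label)) label <- getq("locus_tag")
      if (is.na(label)) label <- getq("product")
      if (is.na(label)) label <- paste0(e$key, length(features) + 1)
      pseudo <- any(grepl("^/pseudo\\b", quals))
      is_orf <- grepl("^orf", label, ignore.case = TRUE)
      kind <- if (pseudo) "pseudogene"
        else if (e$key == "tRNA") "tRNA"
        else if (e$key == "rRNA") "rRNA"
        else if (is_orf) "ORF"
        else if (e$key == "CDS") "protein_gene"
        else NA_character_
      if (is.na(kind)) next  # plain gene feature shadowing its CDS
      pl <- parse_gb_location(loc, label)
      n <- nchar(sequence)
      for (ex in pl$exons) {
        if (ex[1] < 0 || ex[2] > n)
          stop("feature '", label, "' has coordinates beyond sequence ",
               "length ", n)
      }
      features[[length(features) + 1]] <-
        feature_annotation(label, kind, pl$exons, pl$strand)
    }
  }
  genome_record(id, sequence, features)
}

#' Write a minimal GenBank flat file
#'
#' Emits LOCUS/FEATURES/ORIGIN in the restricted dialect that
#' [read_genome_annotation()] parses; round-trips coordinates, strands and
#' exon structure.
#'
#' @param record a [genome_record()].
#' @param path output file.
#' @export
write_genbank <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     circular PLN",
                     record$id, record$length), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  for (f in record$features) {
    key <- switch(f$kind, tRNA = "tRNA", rRNA = "rRNA", "CDS")
    spans <- vapply(f$exons, function(e)
      paste0(e[1] + 1, "..", e[2]), character(1))
    loc <- if (length(spans) > 1) paste0("join(", paste(spans,
                                                        collapse = ","), ")")
           else spans
    if (f$strand < 0) loc <- paste0("complement(", loc, ")")
    writeLines(sprintf("     %-16s%s", key, loc), con)
    writeLines(sprintf('                     /gene="%s"', f$label), con)
    if (f$kind == "pseudogene")
      writeLines("                     /pseudo", con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(record$sequence)
  pos <- 1
  while (pos <= nchar(s)) {
    chunk <- substr(s, pos, min(pos + 59, nchar(s)))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", pos, paste(tens, collapse = " ")), con)
    pos <- pos + 60
  }
  writeLines("//", con)
  invisible(path)
}

# -- FASTA -------------------------------------------------------------------

#' Read / write FASTA
#' @param path file path.
#' @return `read_fasta` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("no FASTA records in ", path)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  starts <- hdr + 1
  ends <- c(hdr[-1] - 1, length(lines))
  seqs <- vapply(seq_along(hdr), function(i)
    toupper(paste(lines[starts[i]:ends[i]], collapse = "")), character(1))
  setNames(gsub("\\s", "", seqs), ids)
}

#' @param seqs named character vector of sequences.
#' @param width line width.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    writeLines(substring(s, seq(1, nchar(s), width),
                         pmin(seq(width, nchar(s) + width - 1, width),
                              nchar(s))), con)
  }
  invisible(path)
}

#' Write a phylogenetic tree in newick format
#'
#' Internal-node support values are emitted as node labels; branch lengths
#' keep at least six significant digits. Leaves must be named.
#'
#' @param tree an `ape::phylo` object (optionally with `node.label`).
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("all leaves must be named")
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}
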