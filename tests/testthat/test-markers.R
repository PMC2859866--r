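# Marker extraction, reciprocal-best-hit families, backbone construction
# and non-coding markers.

test_that("local alignment scores and identities behave as expected", {
  set.seed(41)
  s <- rand_dna(300)
  la <- local_align(s, s)
  expect_equal(la$score, 300)
  expect_equal(la$identity, 1)
  expect_equal(la$aligned_length, 300)
  expect_lt(la$log10_evalue, -170)
  # unrelated sequences never approach the homology thresholds
  lr <- local_align(rand_dna(300), rand_dna(300))
  expect_gt(lr$log10_evalue, -26)
  expect_equal(local_align("ACGT", "ACGT")$score, 4)
})

make_marker_tables <- function(seqs_by_genome) {
  lapply(seqs_by_genome, function(seqs) {
    data.frame(genome_id = "x", label = names(seqs),
               kind = "protein_gene", start = 0L,
               end = nchar(seqs), strand = 1L, sequence = unname(seqs),
               stringsAsFactors = FALSE)
  })
}

test_that("identical genes across genomes form one complete family", {
  set.seed(42)
  gseq <- rand_dna(500)
  mk <- make_marker_tables(list(A = c(g1 = gseq), B = c(g1 = gseq),
                                C = c(g1 = gseq)))
  rbh <- reciprocal_best_hits(mk)
  expect_equal(length(unique(rbh$families$family_id)), 1L)
  expect_equal(nrow(rbh$families), 3L)
})

test_that("pairs with >= 8% aligned-length difference are rejected", {
  set.seed(43)
  core <- rand_dna(500)
  long <- paste0(core, rand_dna(60))  # 10.7% longer
  mk <- make_marker_tables(list(A = c(g1 = core), B = c(g1 = long)))
  rbh <- reciprocal_best_hits(mk)
  expect_equal(nrow(rbh$families), 0L)
  # under the threshold it passes
  long2 <- paste0(core, rand_dna(20))  # 3.8% longer
  mk2 <- make_marker_tables(list(A = c(g1 = core), B = c(g1 = long2)))
  rbh2 <- reciprocal_best_hits(mk2)
  expect_equal(length(unique(rbh2$families$family_id)), 1L)
})

test_that("families absent from a genome are rescued or excluded", {
  set.seed(44)
  shared <- rand_dna(600)
  extra <- rand_dna(600)
  mk <- list(A = data.frame(genome_id = "A",
                            label = c("s", "e"), kind = "protein_gene",
                            start = 0L, end = 600L, strand = 1L,
                            sequence = c(shared, extra),
                            stringsAsFactors = FALSE),
             B = make_marker_tables(list(B = c(s = shared)))$B,
             C = make_marker_tables(list(C = c(s = shared)))$C)
  # no rescue sequences: family of `extra` never forms (singleton),
  # family of `shared` is complete
  rbh <- reciprocal_best_hits(mk)
  expect_equal(length(unique(rbh$families$family_id)), 1L)
  # with genome sequences carrying the marker, the family is rescued
  seqs <- c(A = paste0(rand_dna(200), shared, extra, rand_dna(200)),
            B = paste0(rand_dna(150), shared, extra, rand_dna(100)),
            C = paste0(shared, rand_dna(300)))
  mkB <- mk
  rbh2 <- reciprocal_best_hits(
    list(A = mk$A, B = mk$B, C = mk$C), genome_seqs = seqs)
  expect_equal(length(unique(rbh2$families$family_id)), 1L)
})

test_that("duplicated identical markers join their family as extra copies", {
  set.seed(45)
  gseq <- rand_dna(500)
  mkA <- data.frame(genome_id = "A", label = c("g1", "g1"),
                    kind = "protein_gene", start = c(0L, 1000L),
                    end = c(500L, 1500L), strand = 1L,
                    sequence = c(gseq, gseq), stringsAsFactors = FALSE)
  mk <- list(A = mkA, B = make_marker_tables(list(B = c(g1 = gseq)))$B)
  rbh <- reciprocal_best_hits(mk)
  expect_equal(length(unique(rbh$families$family_id)), 1L)
  expect_equal(sum(rbh$families$genome_id == "A"), 2L)
})

test_that("identical genomes give one backbone fragment covering everything", {
  set.seed(46)
  s <- rand_dna(3000)
  bb <- build_backbone(c(A = s, B = s, C = s))
  expect_equal(length(unique(bb$fragments$fragment_id)), 1L)
  fr <- bb$fragments[bb$fragments$genome_id == "A", ]
  expect_lt(fr$start, 20)
  expect_gt(fr$end, 2980)
  expect_equal(unname(nchar(bb$backbone["A"])), fr$length)
})

test_that("an inverted internal segment splits the backbone into 3 fragments", {
  set.seed(47)
  s <- rand_dna(4000)
  inv <- paste0(substr(s, 1, 1500), rc_dna(substr(s, 1501, 2500)),
                substr(s, 2501, 4000))
  bb <- build_backbone(c(A = s, B = inv))
  expect_equal(length(unique(bb$fragments$fragment_id)), 3L)
  strands <- bb$fragments$strand[bb$fragments$genome_id == "B"]
  expect_equal(sort(strands), c(-1L, 1L, 1L))
})

test_that("fragments below min_block are dropped", {
  set.seed(48)
  s <- rand_dna(2000)
  # genome B shares only a 40 bp island inside otherwise unrelated sequence
  isl <- substr(s, 1000, 1039)
  b <- paste0(rand_dna(900), isl, rand_dna(900))
  bb <- build_backbone(c(A = s, B = b))
  expect_true(is.null(bb$fragments$length) ||
                all(bb$fragments$length >= 50))
  expect_error(build_backbone(c(A = s)), "two genomes")
})

test_that("non-coding markers come from long fragments outside coding regions", {
  set.seed(49)
  s <- rand_dna(1200)
  recA <- genome_record("A", s, list(
    feature_annotation("gene1", "protein_gene", list(c(100L, 700L)), 1L)))
  recB <- genome_record("B", s, recA$features)
  fragments <- data.frame(
    fragment_id = c(1L, 1L, 2L, 2L, 3L, 3L),
    genome_id = rep(c("A", "B"), 3),
    start = c(150L, 150L, 800L, 800L, 1000L, 1000L),
    end = c(400L, 400L, 950L, 950L, 1090L, 1090L),
    strand = 1L,
    length = c(250L, 250L, 150L, 150L, 90L, 90L))
  bb <- list(fragments = fragments)
  nc <- extract_noncoding_markers(bb, list(A = recA, B = recB))
  # fragment 1 inside the CDS, fragment 3 below 100 bp: only fragment 2
  expect_equal(unique(nc$label), "nc2")
  expect_equal(nrow(nc), 2L)
  expect_equal(nc$sequence[1], substr(s, 801, 950))
})

test_that("backbone alignments concatenate per-fragment global alignments", {
  set.seed(50)
  s <- rand_dna(2500)
  # one substitution and nothing else
  s2 <- s
  substr(s2, 1200, 1200) <- setdiff(c("A", "C", "G", "T"),
                                    substr(s, 1200, 1200))[1]
  recs <- list(A = genome_record("A", s), B = genome_record("B", s2))
  bb <- build_backbone(c(A = s, B = s2))
  ap <- backbone_alignment(bb, recs, "A", "B")
  cs <- count_substitutions(ap)
  expect_equal(cs$s, 1L)
  expect_gt(cs$L, 2300)
  # identical fragments give a gap-free alignment
  bb2 <- build_backbone(c(A = s, B = s))
  ap2 <- backbone_alignment(bb2, list(A = recs$A, B = recs$A), "A", "B")
  expect_false(grepl("-", ap2$a, fixed = TRUE))
  expect_identical(ap2$a, ap2$b)
})
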