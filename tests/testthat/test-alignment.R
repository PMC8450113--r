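test_that("reference databases parse deflines and fetch spans", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">loc1 chr6:100-340", "ACGTACGTAA", ">loc2", "GGGGCCCC"), fa)
  db <- reference_db(fa)
  expect_equal(db$name, c("loc1", "loc2"))
  expect_equal(db$coords[1], "chr6:100-340")
  expect_equal(fetch_reference_span(db, "loc1", 1, 10), "ACGTACGTAA")
  expect_equal(fetch_reference_span(db, "loc1", 3, 3), "G")
  expect_equal(paste0(fetch_reference_span(db, "loc1", 1, 4),
                      fetch_reference_span(db, "loc1", 5, 10)),
               fetch_reference_span(db, "loc1", 1, 10))
  expect_error(fetch_reference_span(db, "loc1", 0, 5), "out of range")
  expect_error(fetch_reference_span(db, "loc1", 5, 11), "out of range")
  expect_error(fetch_reference_span(db, "nope", 1, 2), "unknown locus")
})

test_that("an identical query aligns full-span with an all-match midline", {
  fx <- fix_locus()
  h <- local_align(fx$seq, fx$db)
  expect_false(h$no_hits)
  expect_length(h$hsps, 1)
  hsp <- h$hsps[[1]]
  expect_equal(c(hsp$qstart, hsp$qend, hsp$sstart, hsp$send), c(1, 240, 1, 240))
  expect_equal(hsp$score, 480)
  expect_false(grepl(" ", hsp$midline))
})

test_that("single-fragment scores match an independent affine-gap oracle", {
  fx <- fix_locus()
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  oracle_score <- function(q) {
    Biostrings::pairwiseAlignment(Biostrings::DNAString(q),
                                  Biostrings::DNAString(fx$seq),
                                  type = "local", substitutionMatrix = mat,
                                  gapOpening = 5, gapExtension = 2) |>
      Biostrings::score()
  }
  set.seed(99)
  for (k in c(0, 3, 8, 21)) {
    at <- sample(60:140, 1)
    q <- paste0(substr(fx$seq, 1, at), substr(fx$seq, at + k + 1, 240))
    h <- local_align(q, fx$db)
    expect_length(h$hsps, 1)
    expect_equal(h$hsps[[1]]$score, oracle_score(q))
  }
  # substitutions as well as deletions
  q <- fx$seq
  substr(q, 120, 120) <- setdiff(c("A", "C", "G", "T"),
                                 substr(q, 120, 120))[1]
  h <- local_align(q, fx$db)
  expect_equal(h$hsps[[1]]$score, oracle_score(q))
})

test_that("aligning the reverse complement mirrors strand and score", {
  fx <- fix_locus()
  q <- paste0(substr(fx$seq, 1, 100), substr(fx$seq, 109, 240))
  hp <- local_align(q, fx$db)
  hm <- local_align(reverse_complement(q), fx$db)
  expect_equal(hp$strand, "+")
  expect_equal(hm$strand, "-")
  expect_equal(hm$hsps[[1]]$score, hp$hsps[[1]]$score)
  expect_equal(hm$hsps[[1]]$sstart, hp$hsps[[1]]$sstart)
  expect_equal(hm$query_oriented, q)
})

test_that("indels up to 60 bp stay inside one fragment with exact size", {
  fx <- fix_locus()
  for (k in c(1, 2, 5, 13, 27, 41, 60)) {
    q <- paste0(substr(fx$seq, 1, 100), substr(fx$seq, 101 + k, 240))
    h <- local_align(q, fx$db)
    expect_length(h$hsps, 1)
    cl <- classify_allele(h$hsps[[1]], nchar(q))
    expect_equal(cl$allele_class, "deletion")
    expect_equal(cl$size_bp, k)
  }
  # insertions too
  set.seed(7)
  ins <- paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
               collapse = "")
  q <- paste0(substr(fx$seq, 1, 100), ins, substr(fx$seq, 101, 240))
  h <- local_align(q, fx$db)
  cl <- classify_allele(h$hsps[[1]], nchar(q))
  expect_length(h$hsps, 1)
  expect_equal(cl$allele_class, "insertion")
  expect_equal(cl$size_bp, 12)
})

test_that("long deletions split into fragments that chain to the exact size", {
  fx <- fix_big_locus()
  for (k in c(61, 75, 150, 400, 900)) {
    q <- paste0(substr(fx$seq, 1, 40), substr(fx$seq, 41 + k, 1000))
    h <- local_align(q, fx$db)
    expect_gte(length(h$hsps), 2)
    chain <- chain_hsps(h$hsps)
    expect_s3_class(chain, "chained_alignment")
    expect_equal(chain$bridged_subject_gap, k)
    rec <- reconstitute_allele(chain, fx$db, h$query_oriented)
    cl <- classify_allele(rec, nchar(q))
    expect_equal(cl$allele_class, "deletion")
    expect_equal(cl$size_bp, k)
    # the reconstituted alignment shows one contiguous k-column gap run
    expect_true(grepl(strrep("-", k), rec$q_aln, fixed = TRUE))
  }
})

test_that("chains violating colinearity or the 1 kb rule are deprecated", {
  two <- list(make_hsp(qstart = 1, qend = 100, sstart = 1, send = 100),
              make_hsp(qstart = 101, qend = 180, sstart = 301, send = 380))
  ch <- chain_hsps(two)
  expect_s3_class(ch, "chained_alignment")
  expect_equal(ch$bridged_subject_gap, 200)
  expect_equal(ch$subject_span, 380)

  over <- list(make_hsp(qstart = 1, qend = 100, sstart = 1, send = 100),
               make_hsp(qstart = 101, qend = 180, sstart = 91, send = 170))
  expect_equal(chain_hsps(over)$reason, "overlap")

  wide <- list(make_hsp(qstart = 1, qend = 100, sstart = 1, send = 100),
               make_hsp(qstart = 101, qend = 180, sstart = 1422, send = 1501))
  expect_equal(chain_hsps(wide)$reason, "span_exceeded")

  disc <- list(make_hsp(qstart = 1, qend = 100, sstart = 301, send = 400),
               make_hsp(qstart = 101, qend = 180, sstart = 1, send = 80))
  expect_equal(chain_hsps(disc)$reason, "discordant")

  mixed <- list(make_hsp(qstart = 1, qend = 100, sstart = 1, send = 100),
                make_hsp(qstart = 101, qend = 180, sstart = 301, send = 380,
                         strand = "-"))
  expect_equal(chain_hsps(mixed)$reason, "discordant")
})

test_that("a >1 kb deletion is deprecated end to end", {
  set.seed(77)
  big <- paste(sample(c("A", "C", "G", "T"), 1300, replace = TRUE),
               collapse = "")
  db <- reference_db(c(b = big))
  q <- paste0(substr(big, 1, 60), substr(big, 1161, 1300))
  h <- local_align(q, db)
  expect_gte(length(h$hsps), 2)
  ch <- chain_hsps(h$hsps)
  expect_s3_class(ch, "deprecated_chain")
  expect_equal(ch$reason, "span_exceeded")
  # the pipeline surfaces it as a deprecated allele call
  cl <- ampliclone:::call_one_allele(q, db)
  expect_equal(cl$deprecated_reason, "chain_overlap_or_span")
})

test_that("degenerate chains with adjacent fragments reconstitute cleanly", {
  h1 <- make_hsp(qstart = 1, qend = 50, sstart = 1, send = 50)
  h2 <- make_hsp(qstart = 51, qend = 100, sstart = 51, send = 100)
  ch <- chain_hsps(list(h1, h2))
  expect_equal(ch$bridged_subject_gap, 0)
  db <- reference_db(c(L = strrep("A", 120)))
  rec <- reconstitute_allele(ch, db, strrep("A", 100))
  expect_equal(nchar(rec$q_aln), 100)
  expect_false(grepl("-", rec$q_aln, fixed = TRUE))
  expect_equal(classify_allele(rec, 100)$allele_class, "wild-type")
})

test_that("queries without a credible hit report no_hits or multiple_hits", {
  fx <- fix_locus()
  none <- local_align(strrep("ACGT", 10), fx$db)
  expect_true(none$no_hits)
  expect_length(none$hsps, 0)

  # two loci sharing the query sequence trigger the multiple-hits flag
  db2 <- reference_db(c(l1 = fx$seq, l2 = fx$seq))
  h <- local_align(substr(fx$seq, 20, 160), db2)
  expect_true(h$multiple_hits)
  expect_error(local_align("ACGTACGTACGTACG", fx$db), "shorter than 20")
})
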