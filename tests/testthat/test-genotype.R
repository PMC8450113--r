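# hand-built gapped alignments for classification tests
mk_aln <- function(q_aln, s_aln, locus = "L") {
  qlen <- nchar(gsub("-", "", q_aln))
  slen <- nchar(gsub("-", "", s_aln))
  structure(list(locus_name = locus, qstart = 1, qend = qlen,
                 sstart = 1, send = slen, strand = "+", score = 0,
                 q_aln = q_aln, s_aln = s_aln,
                 midline = ampliclone:::midline_of(q_aln, s_aln)),
            class = "hsp")
}

test_that("allele classes and sizes follow the mutation taxonomy", {
  wt <- classify_allele(mk_aln("ACGTACGT", "ACGTACGT"))
  expect_equal(wt$allele_class, "wild-type")
  expect_equal(wt$size_bp, 0)

  del <- classify_allele(mk_aln("ACGT--------ACGT", "ACGTACGTACGTACGT"))
  expect_equal(del$label, "likely deletion 8 bp")

  ins <- classify_allele(mk_aln("ACGTTTACGT", "ACGT--ACGT"))
  expect_equal(ins$label, "likely insertion 2 bp")

  sub <- classify_allele(mk_aln("ACGTACGT", "ACGAACGT"))
  expect_equal(sub$allele_class, "substitution")
  expect_equal(sub$size_bp, 1)

  # one gap column in subject plus two mismatches: complex, 3 bp
  cpx <- classify_allele(mk_aln("AAGTACGTT", "A-GTACGAA"))
  expect_equal(cpx$allele_class, "complex indel")
  expect_equal(cpx$size_bp, 3)
})

test_that("partial-coverage alignments are deprecated, not classified", {
  aln <- mk_aln("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT")
  ok <- classify_allele(aln, query_len = 21)
  expect_true(is.na(ok$deprecated_reason))
  short <- classify_allele(aln, query_len = 40)
  expect_equal(short$deprecated_reason, "partial_coverage")
  expect_true(is.na(short$allele_class))
})

# ranked table + calls for inference tests
mk_ranked <- function(adj) {
  data.frame(rank = seq_along(adj), sequence = strrep("A", 30 + seq_along(adj)),
             count = round(adj * 10), raw_freq = adj, pct_top10 = adj,
             adj_gt1 = adj, adj_gt10 = adj, scarce_flag = adj < 10)
}
mk_call <- function(class, size = 2L) {
  structure(list(allele_class = class, size_bp = size,
                 label = paste("likely", class, size, "bp"),
                 locus_name = "L", alignment = NULL,
                 deprecated_reason = NA_character_),
            class = "allele_call")
}

test_that("genotype inference applies the prominence rule", {
  hom <- infer_genotype("s", mk_ranked(c(96, 4)),
                        list(mk_call("deletion", 8L), mk_call("wild-type", 0L)))
  expect_equal(hom$cohort, "homozygous deletion")
  expect_equal(hom$ploidy_note, "diploid-consistent")

  het <- infer_genotype("s", mk_ranked(c(52, 45, 3)),
                        list(mk_call("wild-type", 0L), mk_call("deletion", 3L),
                             mk_call("insertion", 1L)))
  expect_equal(het$cohort, "heterozygous wt+mutant")

  mm <- infer_genotype("s", mk_ranked(c(55, 45)),
                       list(mk_call("deletion", 3L), mk_call("insertion", 1L)))
  expect_equal(mm$cohort, "heterozygous mutant+mutant")

  multi <- infer_genotype("s", mk_ranked(c(40, 35, 20, 5)),
                          list(mk_call("insertion", 1L), mk_call("deletion", 2L),
                               mk_call("substitution", 1L), mk_call("wild-type", 0L)))
  expect_equal(multi$cohort, "unclear/multi-allelic")
  expect_equal(multi$ploidy_note, "multiploid")

  nothing <- infer_genotype("s", mk_ranked(c(6, 5, 4)),
                            list(mk_call("deletion", 1L), mk_call("deletion", 2L),
                                 mk_call("deletion", 3L)))
  expect_equal(nothing$cohort, "unclear/multi-allelic")
  expect_match(nothing$note, "insufficient representation")

  # the threshold is tunable: at 0.30 only one allele of the het is prominent
  strict <- infer_genotype("s", mk_ranked(c(60, 25, 15)),
                           list(mk_call("wild-type", 0L), mk_call("deletion", 3L),
                                mk_call("insertion", 1L)),
                           prominence_threshold = 0.30)
  expect_equal(strict$cohort, "homozygous wild-type")
})

test_that("deprecated alleles never enter the genotype", {
  dep <- structure(list(allele_class = NA_character_, size_bp = NA_integer_,
                        label = "deprecated: no hits", locus_name = NA_character_,
                        alignment = NULL, deprecated_reason = "no_hits"),
                   class = "allele_call")
  g <- infer_genotype("s", mk_ranked(c(55, 45)),
                      list(mk_call("deletion", 4L), dep))
  expect_equal(g$cohort, "homozygous deletion")
})

test_that("guide and test sub-sequences annotate presence and ablation", {
  fx <- fix_locus()
  guide <- substr(fx$seq, 81, 100)
  # deletion removing most of the guide target
  q <- paste0(substr(fx$seq, 1, 85), substr(fx$seq, 101, 240))
  h <- local_align(q, fx$db)
  anns <- annotate_subsequences(h$hsps[[1]], fx$db, h$query_oriented,
                                guide = guide,
                                test = reverse_complement(substr(fx$seq, 30, 45)))
  expect_length(anns, 2)
  g <- anns[[1]]
  expect_equal(g$role, "guide")
  expect_true(g$found_ref)
  expect_equal(g$ref_positions$pos, 81)
  expect_false(g$found_allele)   # ablated by the deletion
  t <- anns[[2]]
  expect_equal(t$role, "test")
  expect_true(t$found_ref)
  expect_equal(t$ref_positions$strand, "-")  # planted as revcomp
  expect_true(t$found_allele)
  expect_error(annotate_subsequences(h$hsps[[1]], fx$db, q, guide = "ACGT"),
               "shorter than 6")
  expect_length(annotate_subsequences(h$hsps[[1]], fx$db, q), 0)
})

test_that("population summaries aggregate cohorts and lost reads", {
  mk_res <- function(id, cohort, classes, adj, dep = NULL) {
    calls <- lapply(classes, mk_call)
    if (!is.null(dep)) {
      calls[[length(calls) + 1L]] <- structure(
        list(allele_class = NA_character_, size_bp = NA_integer_,
             label = "dep", locus_name = NA_character_, alignment = NULL,
             deprecated_reason = dep), class = "allele_call")
      adj <- c(adj, 2)
    }
    ranked <- mk_ranked(adj)
    g <- infer_genotype(id, ranked, calls)
    g$cohort <- cohort
    list(sample_id = id, ranked = ranked, calls = calls, genotype = g)
  }
  res <- list(
    mk_res("a", "homozygous deletion", list("deletion"), 100),
    mk_res("b", "heterozygous wt+mutant", list("wild-type", "insertion"),
           c(52, 48)),
    mk_res("c", "homozygous wild-type", list("wild-type"), 100),
    mk_res("d", "unclear/multi-allelic", list("deletion"), 5, dep = "no_hits"))
  ps <- summarize_population(res)
  expect_equal(ps$n_samples, 4)
  expect_equal(ps$fraction_genotyped, 0.75)
  expect_equal(sum(ps$pct_cohort), 100)
  expect_equal(as.integer(ps$cohort_counts["homozygous deletion"]), 1)
  expect_equal(unname(ps$reads_lost["no_hits"]), 20)

  zero <- summarize_population(list())
  expect_equal(zero$n_samples, 0)
  expect_equal(zero$fraction_genotyped, 0)
})

test_that("reports group cohorts in fixed order with the scarce divider", {
  plan <- standard_plate_plan()
  # one clone of each flavour, deliberately shuffled
  pick <- plan[c(93, 1, 41, 15, 35, 60, 80, 50)]
  sim <- simulate_clonal_plate(seed = 5, depth = 40, error_rate = 0.01,
                               plan = pick)
  results <- lapply(names(sim$samples), function(sid) {
    s <- sim$samples[[sid]]
    genotype_sample(sid, tally_reads(s$r1, s$r2), sim$db)
  })
  outdir <- withr::local_tempdir()
  paths <- render_reports(results, sim$db, outdir)
  expect_true(all(file.exists(paths)))

  gl <- readLines(paths["genotypes_txt"])
  heads <- grep("^== ", gl, value = TRUE)
  lev <- sub("^== (.*) \\(.*$", "\\1", heads)
  expect_equal(lev, intersect(ampliclone:::COHORT_LEVELS, lev))

  al <- readLines(paths["allele_definitions_txt"])
  div <- grep("remaining alleles occur at frequency <10%", al)
  expect_gt(length(div), 0)
  # the divider precedes scarce entries within a sample block: the ranked
  # allele right after a divider line is rendered after it
  expect_match(al[div[1]], ">>>>>.*<<<<<")

  csv <- read.csv(paths["allele_definitions_csv"])
  expect_equal(nrow(csv), sum(vapply(results, function(r) nrow(r$ranked), 0L)))
  expect_true(all(c("sample_id", "rank", "allele_class", "size_bp", "locus",
                    "count", "raw_freq", "pct_top10", "adj_gt1", "adj_gt10",
                    "genotype_cohort") %in% names(csv)))
})

test_that("genotype_run processes a fastq directory end to end", {
  plan <- standard_plate_plan()[c(1, 20, 45)]
  sim <- simulate_clonal_plate(seed = 3, depth = 20, error_rate = 0,
                               plan = plan)
  fq <- withr::local_tempdir()
  for (sid in names(sim$samples)) {
    write_fastq(sim$samples[[sid]]$r1, file.path(fq, paste0(sid, "_R1.fastq")))
    write_fastq(sim$samples[[sid]]$r2, file.path(fq, paste0(sid, "_R2.fastq")))
  }
  reff <- file.path(fq, "ref.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$reference), reff)
  out <- file.path(fq, "reports")
  run <- genotype_run(fq, reff, out, guide = sim$guide)
  expect_length(run$results, 3)
  called <- vapply(run$results, function(r) r$genotype$cohort, character(1))
  expect_equal(unname(called), sim$truth$cohort)
  expect_true(file.exists(file.path(out, "run_metrics.txt")))
})
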