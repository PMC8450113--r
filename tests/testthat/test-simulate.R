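test_that("locus simulation is deterministic and respects plant bounds", {
  l1 <- simulate_locus(100, list(list(seq = "ACGGTTCC", at = 40)), seed = 3)
  l2 <- simulate_locus(100, list(list(seq = "ACGGTTCC", at = 40)), seed = 3)
  expect_identical(as.character(l1), as.character(l2))
  expect_equal(substr(as.character(l1), 40, 47), "ACGGTTCC")
  expect_equal(nchar(l1), 100)
  expect_false(identical(as.character(l1),
                         as.character(simulate_locus(100, seed = 4))))
  expect_error(simulate_locus(50, list(list(seq = "ACGT", at = 49)), seed = 1),
               "exceeds locus bounds")
  expect_error(simulate_locus(50, list(list(seq = "ACGTACGT", at = 10),
                                       list(seq = "GGGG", at = 12)), seed = 1),
               "overlapping plants")
})

test_that("edits apply at the blunt cut 3 bp from the PAM-proximal end", {
  guide <- ampliclone:::SIM_GUIDE
  locus <- as.character(simulate_locus(120, list(list(seq = guide, at = 41)),
                                       seed = 8))
  # protospacer at 41..60: cut between positions 57 and 58
  del <- simulate_edit(locus, guide, "deletion", size = 8)
  expect_equal(nchar(as.character(del)), 112)
  expect_equal(as.character(del),
               paste0(substr(locus, 1, 57), substr(locus, 66, 120)))
  expect_equal(attr(del, "truth_class"), "deletion")
  expect_equal(attr(del, "cut"), 57)

  ins <- simulate_edit(locus, guide, "insertion", ins_seq = "T")
  expect_equal(nchar(as.character(ins)), 121)
  expect_equal(substr(as.character(ins), 58, 58), "T")

  sub <- simulate_edit(locus, guide, "substitution", size = 3)
  expect_equal(nchar(as.character(sub)), 120)
  changed <- which(strsplit(as.character(sub), "")[[1]] !=
                     strsplit(locus, "")[[1]])
  expect_equal(changed, 58:60)

  cpx <- simulate_edit(locus, guide, "complex", size = 3, ins_len = 1)
  expect_equal(attr(cpx, "truth_class"), "complex indel")
  expect_equal(attr(cpx, "truth_size"), 4)

  expect_error(simulate_edit(strrep("ACGT", 30), guide, "deletion", 5),
               "not found")
  two <- paste0(locus, locus)
  expect_error(simulate_edit(two, guide, "deletion", 5), "more than once")
})

test_that("complex edits are never reducible to pure indels", {
  expect_true(ampliclone:::is_subseq("ACG", "AACCGG"))
  expect_false(ampliclone:::is_subseq("ACG", "GCA"))
  guide <- ampliclone:::SIM_GUIDE
  locus <- as.character(simulate_locus(140, list(list(seq = guide, at = 41)),
                                       seed = 10))
  for (spec in list(c(2, 1), c(3, 2), c(2, 3), c(4, 3), c(6, 3))) {
    a <- simulate_edit(locus, guide, "complex", size = spec[1],
                       ins_len = spec[2])
    expect_false(ampliclone:::is_subseq_either_way(locus, as.character(a)))
  }
})

test_that("read simulation is deterministic with a recorded allele split", {
  set.seed(1)
  a1 <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
              collapse = "")
  a2 <- paste0(substr(a1, 1, 90), substr(a1, 101, 200))
  r <- simulate_reads(c(a1, a2), c(0.5, 0.5), 1000, error_rate = 0,
                      read_len = 150, seed = 6)
  expect_equal(sum(r$allele_counts), 1000)
  merged <- mapply(function(s1, s2, q1, q2)
    merge_read_pair(s1, s2, q1, q2), r$r1$seq, r$r2$seq, r$r1$qual,
    r$r2$qual)
  tl <- table(unlist(merged))
  expect_equal(length(tl), 2)
  expect_equal(sort(as.integer(tl)), sort(r$allele_counts))
  # realized split is binomial around 500
  expect_true(all(r$allele_counts > 400 & r$allele_counts < 600))

  r2 <- simulate_reads(c(a1, a2), c(0.5, 0.5), 1000, error_rate = 0,
                       read_len = 150, seed = 6)
  expect_identical(r, r2)

  single <- simulate_reads(a1, 1, 50, 0, read_len = 150, seed = 2)
  tls <- ampliclone:::tally_from_sequences(
    mapply(merge_read_pair, single$r1$seq, single$r2$seq))
  expect_equal(length(tls$counts), 1)

  expect_error(simulate_reads(a2, 1, 10, 0, read_len = 500, seed = 1),
               "exceeds amplicon")
  expect_error(simulate_reads(c(a1, a2), c(0.7, 0.6), 10, 0, 100, 1),
               "sum to 1")
})

test_that("errored bases carry low quality so consensus can repair them", {
  set.seed(2)
  amp <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
               collapse = "")
  r <- simulate_reads(amp, 1, 200, error_rate = 0.05, read_len = 80, seed = 9)
  sv <- strsplit(r$r1$seq, ""); qv <- strsplit(r$r1$qual, "")
  tv <- strsplit(amp, "")[[1]]
  for (i in seq_len(50)) {
    wrong <- which(sv[[i]] != tv)
    expect_true(all(qv[[i]][wrong] == "#"))
    expect_true(all(qv[[i]][setdiff(seq_len(80), wrong)] == "I"))
  }
})

test_that("the standard plate covers all cohorts with consistent truth", {
  plan <- standard_plate_plan()
  expect_length(plan, 96)
  expect_equal(anyDuplicated(vapply(plan, `[[`, "", "well")), 0)
  sim <- simulate_clonal_plate(seed = 2, depth = 4, error_rate = 0)
  expect_equal(nrow(sim$truth), 96)
  expect_setequal(unique(sim$truth$cohort),
                  c("homozygous wild-type", "homozygous deletion",
                    "homozygous insertion", "homozygous substitution",
                    "homozygous complex", "heterozygous wt+mutant",
                    "heterozygous mutant+mutant", "unclear/multi-allelic"))
  # long-deletion clones live on their own loci sized to the deletion
  long <- sim$truth[sim$truth$locus != "locusA", ]
  expect_equal(nrow(long), 4)
  expect_equal(sort(as.integer(long$sizes)), c(100, 200, 500, 900))
  # per-sample read length never exceeds the shortest allele amplicon
  for (sid in names(sim$samples)) {
    amps <- nchar(strsplit(sim$truth$alleles[sim$truth$sample_id == sid],
                           ";")[[1]])
    expect_lte(sim$samples[[sid]]$read_len, min(amps))
  }
  # determinism across builds
  sim2 <- simulate_clonal_plate(seed = 2, depth = 4, error_rate = 0)
  expect_identical(sim$samples[["SIM1-A01"]]$r1, sim2$samples[["SIM1-A01"]]$r1)
  expect_identical(sim$reference, sim2$reference)
})

test_that("the use-case fixture encodes its documented truth", {
  uc <- fix_use_case()
  ref <- uc$reference[[1]]
  expect_equal(substr(ref, uc$site_start, uc$site_start + 14),
               "ACCACAGGGTGTTCT")
  expect_equal(nchar(uc$allele_ins), nchar(ref) + 1)
  expect_equal(nchar(uc$allele_del), nchar(ref) - 5)
  # reference carries exactly one motif hit: the planted GBS, plus strand
  expect_equal(nrow(uc$ref_hits), 1)
  expect_equal(uc$ref_hits$motif_id, "GBS1")
  expect_equal(uc$ref_hits$start, uc$site_start)
  expect_equal(uc$ref_hits$strand, "+")
  # balanced background: uniform marginal
  expect_equal(unname(uc$bg$marginal), rep(0.25, 4), tolerance = 1e-12)
})

test_that("pooled reads demultiplex back to their source samples", {
  plan <- standard_plate_plan()[c(1, 20, 45)]
  sim <- simulate_clonal_plate(seed = 6, depth = 10, error_rate = 0,
                               plan = plan)
  lib <- fix_lib()
  sheet <- build_sample_sheet("A", "I", "P", c(130, 130),
                              parse_plate_lines("SIM1,1-96,1"), lib)
  pool <- pool_samples(sim$samples, sheet)
  expect_equal(nrow(pool$r1), 30)
  res <- demultiplex(pool$r1, pool$r2, sheet)
  expect_equal(sum(res$counts), 30)
  expect_equal(unname(res$counts["unassigned"]), 0)
  for (sid in names(sim$samples)) {
    expect_equal(unname(res$counts[sid]), 10)
  }
})

test_that("simulations write a complete file bundle", {
  plan <- standard_plate_plan()[c(1, 30)]
  sim <- simulate_clonal_plate(seed = 4, depth = 5, error_rate = 0,
                               plan = plan)
  out <- withr::local_tempdir()
  write_simulation(sim, out)
  expect_true(all(file.exists(file.path(out,
    c("reference.fasta", "truth.tsv", "plates.txt", "barcodes.fasta")))))
  fq <- list.files(out, "_R[12]\\.fastq$")
  expect_length(fq, 4)
  tr <- read.delim(file.path(out, "truth.tsv"))
  expect_equal(nrow(tr), 2)
})
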