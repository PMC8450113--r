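# Shared fixtures, computed lazily once per test run.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

fix_lib <- function() fixture("lib", function() generate_barcode_library(1))

fix_use_case <- function() fixture("uc", function() {
  uc <- use_case_fixture()
  uc$bg <- estimate_markov_background(uc$background_seq, order = 0)
  uc$ref_hits <- scan_sequence(uc$reference, uc$motifs, uc$bg, 1e-4)
  uc
})

# a genotyped simulated plate, keyed by error rate (seed fixed: these are
# the study conditions, identical across the suite)
fix_plate <- function(error_rate) {
  key <- paste0("plate_", error_rate)
  fixture(key, function() {
    sim <- simulate_clonal_plate(seed = 1, depth = 30, error_rate = error_rate)
    t0 <- Sys.time()
    results <- lapply(names(sim$samples), function(sid) {
      s <- sim$samples[[sid]]
      genotype_sample(sid, tally_reads(s$r1, s$r2), sim$db)
    })
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    called <- vapply(results, function(r) r$genotype$cohort, character(1))
    list(sim = sim, results = results, called = called,
         truth = sim$truth$cohort, elapsed = elapsed)
  })
}

# reference locus + db reused across alignment tests
fix_locus <- function() fixture("locus", function() {
  set.seed(421)
  locus <- paste(sample(c("A", "C", "G", "T"), 240, replace = TRUE),
                 collapse = "")
  list(seq = locus, db = reference_db(c(locus1 = locus)))
})

fix_big_locus <- function() fixture("big_locus", function() {
  set.seed(422)
  big <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
  list(seq = big, db = reference_db(c(big = big)))
})

# hand-built HSP for chain tests
make_hsp <- function(locus = "L", qstart, qend, sstart, send, strand = "+",
                     score = 100) {
  structure(list(locus_name = locus, qstart = qstart, qend = qend,
                 sstart = sstart, send = send, strand = strand,
                 score = score, q_aln = strrep("A", qend - qstart + 1),
                 s_aln = strrep("A", qend - qstart + 1),
                 midline = strrep("|", qend - qstart + 1)),
            class = "hsp")
}

# enumeration oracle for exact motif p-values: weights every w-mer by its
# order-0 background probability and accumulates P(int score >= t)
enumerate_pvalues <- function(lo) {
  w <- lo$width
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  ints <- integer(nrow(grid))
  probs <- rep(1, nrow(grid))
  for (j in seq_len(w)) {
    ints <- ints + lo$int[cbind(grid[, j], j)]
    probs <- probs * lo$bg[grid[, j]]
  }
  list(ints = ints, probs = probs)
}
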