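# Synthetic data generation: reference loci with planted motif instances
# and guide targets, Cas9 edit alleles, paired-end reads with substitution
# errors, pooled/demultiplexable FASTQ, and truth tables for the whole
# pipeline.

#' Assemble a locus with planted elements
#'
#' Builds a random sequence of the requested length and overwrites planted
#' elements (motif consensus instances, guide protospacers) at fixed
#' 1-based positions.  Overlapping or out-of-bounds plants are an error.
#'
#' @param len Locus length (nt).
#' @param plants list of `list(seq=, at=)` elements.
#' @param seed Integer seed (deterministic output).
#' @return Character scalar; attribute `manifest` records the plants.
#' @export
simulate_locus <- function(len, plants = list(), seed) {
  base <- local_seed(seed, random_dna(len))
  v <- strsplit(base, "")[[1]]
  occupied <- rep(FALSE, len)
  manifest <- list()
  for (p in plants) {
    s <- strsplit(toupper(p$seq), "")[[1]]
    at <- p$at
    if (at < 1 || at + length(s) - 1 > len) {
      stop("plant at ", at, " exceeds locus bounds")
    }
    span <- at:(at + length(s) - 1)
    if (any(occupied[span])) stop("overlapping plants at position ", at)
    occupied[span] <- TRUE
    v[span] <- s
    manifest[[length(manifest) + 1L]] <-
      data.frame(at = at, width = length(s), seq = p$seq)
  }
  out <- paste(v, collapse = "")
  attr(out, "manifest") <- if (length(manifest))
    do.call(rbind, manifest) else NULL
  out
}

#' Simulate one Cas9 edit allele
#'
#' Locates the 20-nt guide protospacer (must occur exactly once on either
#' strand) and applies the edit at the blunt cut site 3 bp 5' of the
#' PAM-proximal end (between protospacer positions 17 and 18).  Deletions
#' remove `size` bases immediately 3' of the cut; insertions add `ins_seq`
#' at the cut; substitutions rewrite `size` bases 3' of the cut; complex
#' edits delete then insert at the cut.
#'
#' @param locus Reference locus sequence.
#' @param guide 20-nt protospacer sequence.
#' @param type One of `"wild-type"`, `"deletion"`, `"insertion"`,
#'   `"substitution"`, `"complex"`.
#' @param size Bases deleted/substituted (ignored for insertion).
#' @param ins_seq Inserted bases (insertion/complex).
#' @param ins_len For complex edits without an explicit `ins_seq`: number of
#'   inserted bases, chosen automatically so the edit cannot re-align as a
#'   pure indel (letters disjoint from the edited context, verified by a
#'   subsequence check).
#' @return Allele sequence; attributes `truth_class`, `truth_size`, `cut`.
#' @export
simulate_edit <- function(locus, guide, type = "wild-type", size = 0,
                          ins_seq = "", ins_len = NULL) {
  guide <- toupper(guide)
  if (nchar(guide) != 20) stop("guide must be 20 nt")
  fwd <- gregexpr(guide, locus, fixed = TRUE)[[1]]
  rev_ <- gregexpr(reverse_complement(guide), locus, fixed = TRUE)[[1]]
  nf <- sum(fwd > 0); nr <- sum(rev_ > 0)
  if (nf + nr == 0) stop("guide not found in locus")
  if (nf + nr > 1) stop("guide occurs more than once in locus")
  cut <- if (nf == 1) fwd[1] + 16L else rev_[1] + 2L
  L <- nchar(locus)
  left <- substr(locus, 1, cut)
  if (type == "wild-type") {
    allele <- locus
    cls <- "wild-type"; sz <- 0L
  } else if (type == "deletion") {
    if (cut + size > L) stop("deletion exceeds locus")
    allele <- paste0(left, substr(locus, cut + size + 1, L))
    cls <- "deletion"; sz <- as.integer(size)
  } else if (type == "insertion") {
    if (!nzchar(ins_seq)) stop("insertion requires ins_seq")
    allele <- paste0(left, toupper(ins_seq), substr(locus, cut + 1, L))
    cls <- "insertion"; sz <- nchar(ins_seq)
  } else if (type == "substitution") {
    if (cut + size > L) stop("substitution exceeds locus")
    orig <- strsplit(substr(locus, cut + 1, cut + size), "")[[1]]
    repl <- vapply(orig, function(b) setdiff(DNA_BASES, b)[1], "")
    allele <- paste0(left, paste(repl, collapse = ""),
                     substr(locus, cut + size + 1, L))
    cls <- "substitution"; sz <- as.integer(size)
  } else if (type == "complex") {
    if (cut + size > L) stop("deletion part exceeds locus")
    if (!nzchar(ins_seq)) {
      if (is.null(ins_len) || ins_len < 1) {
        stop("complex edit requires ins_seq or ins_len")
      }
      ins_seq <- pick_complex_insert(locus, cut, size, ins_len)
    }
    allele <- paste0(left, toupper(ins_seq), substr(locus, cut + size + 1, L))
    if (is_subseq_either_way(locus, allele)) {
      stop("complex edit degenerates to a pure indel; choose other ins_seq")
    }
    cls <- "complex indel"; sz <- as.integer(size) + nchar(ins_seq)
  } else stop("unknown edit type: ", type)
  attr(allele, "truth_class") <- cls
  attr(allele, "truth_size") <- sz
  attr(allele, "cut") <- cut
  allele
}

#' Simulate paired-end reads from a mix of alleles
#'
#' Reads the two amplicon ends (R1 from the 5' end, R2 from the 3' end,
#' reverse-complemented) with independent per-base substitution errors at
#' `error_rate`.  Correct bases carry Phred 40 ('I'); substituted bases
#' carry Phred 2 ('#'), so overlap consensus can favor the accurate mate.
#' Allele read counts are multinomial in `fractions`; the realized split is
#' returned for the truth table.
#'
#' @param alleles Character vector of allele sequences.
#' @param fractions Allele fractions (sum to 1).
#' @param depth Total read pairs.
#' @param error_rate Per-base substitution probability.
#' @param read_len Read length; must not exceed the shortest allele.
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @return list with `r1`, `r2` (data.frames id/seq/qual) and
#'   `allele_counts`.
#' @export
simulate_reads <- function(alleles, fractions, depth, error_rate = 0,
                           read_len = 130, seed = NULL) {
  stopifnot(length(alleles) == length(fractions), depth >= 1)
  if (abs(sum(fractions) - 1) > 1e-8) stop("allele fractions must sum to 1")
  if (any(read_len > nchar(alleles))) {
    stop("read_len (", read_len, ") exceeds amplicon length (",
         min(nchar(alleles)), ")")
  }
  gen <- function() {
    counts <- as.integer(rmultinom(1, depth, fractions))
    r1s <- r2s <- q1s <- q2s <- character(depth)
    k <- 0L
    for (a in seq_along(alleles)) {
      if (counts[a] == 0) next
      fwd <- substr(alleles[a], 1, read_len)
      rev_ <- substr(reverse_complement(alleles[a]), 1, read_len)
      for (r in seq_len(counts[a])) {
        k <- k + 1L
        e1 <- add_errors(fwd, error_rate)
        e2 <- add_errors(rev_, error_rate)
        r1s[k] <- e1$seq; q1s[k] <- e1$qual
        r2s[k] <- e2$seq; q2s[k] <- e2$qual
      }
    }
    ids <- sprintf("read%05d", seq_len(depth))
    list(r1 = data.frame(id = ids, seq = r1s, qual = q1s,
                         stringsAsFactors = FALSE),
         r2 = data.frame(id = ids, seq = r2s, qual = q2s,
                         stringsAsFactors = FALSE),
         allele_counts = counts)
  }
  if (!is.null(seed)) local_seed(seed, gen()) else gen()
}

# a true complex indel must not be expressible as a pure deletion or pure
# insertion: neither sequence may be a subsequence of the other
is_subseq <- function(short, long) {
  a <- strsplit(short, "")[[1]]
  b <- strsplit(long, "")[[1]]
  j <- 1L
  for (i in seq_along(b)) {
    if (j <= length(a) && a[j] == b[i]) j <- j + 1L
  }
  j > length(a)
}

is_subseq_either_way <- function(ref, allele) {
  if (nchar(ref) == nchar(allele)) return(FALSE)  # substitution handled upstream
  if (nchar(allele) < nchar(ref)) is_subseq(allele, ref)
  else is_subseq(ref, allele)
}

# inserted bases for a complex edit: prefer letters absent from the deleted
# bases and the immediate flanks, and verify the allele is not reducible to
# a pure indel
pick_complex_insert <- function(locus, cut, size, ins_len) {
  L <- nchar(locus)
  context <- strsplit(substr(locus, max(1, cut - 3),
                             min(L, cut + size + 3)), "")[[1]]
  cand <- unique(c(setdiff(DNA_BASES, context), DNA_BASES))
  pairs <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  for (p in c(cand, pairs)) {
    ins <- substr(strrep(p, ins_len), 1, ins_len)
    allele <- paste0(substr(locus, 1, cut), ins,
                     substr(locus, cut + size + 1, L))
    if (!is_subseq_either_way(locus, allele)) return(ins)
  }
  stop("could not construct an irreducible complex edit at cut ", cut)
}

add_errors <- function(seq, error_rate) {
  if (error_rate <= 0) {
    return(list(seq = seq, qual = strrep("I", nchar(seq))))
  }
  v <- strsplit(seq, "")[[1]]
  q <- rep("I", length(v))
  err <- which(runif(length(v)) < error_rate)
  if (length(err)) {
    v[err] <- vapply(v[err], function(b)
      sample(setdiff(DNA_BASES, b), 1), "")
    q[err] <- "#"
  }
  list(seq = paste(v, collapse = ""), qual = paste(q, collapse = ""))
}

# guide planted in every simulated locus: arbitrary fixed 20-mer, unique by
# construction (flanks are checked at build time)
SIM_GUIDE <- "GACGTTACCGGATAACTGTC"

#' Clone plan for a simulated 96-clone plate
#'
#' The default study condition: a full 96-well plate of clonal isolates
#' spanning every genotype cohort -- homozygous wild-type, homozygous
#' deletions (1-40 bp), insertions (1-10 bp), substitutions, complex
#' indels, heterozygous wt+mutant and mutant+mutant clones, four homozygous
#' long-deletion clones (100/200/500/900 bp, each on its own locus so the
#' edited amplicon stays sequenceable), and multi-allelic clones.
#'
#' @return list of per-clone specs (`well`, `cohort`, `locus`, `alleles` =
#'   list of edit specs, `fractions`).
#' @export
standard_plate_plan <- function() {
  wt <- list(type = "wild-type")
  del <- function(k) list(type = "deletion", size = k)
  ins <- function(k) list(type = "insertion",
                          ins_seq = substr("TTAGGCATCC", 1, k))
  sub <- function(k) list(type = "substitution", size = k)
  cpx <- function(d, i) list(type = "complex", size = d, ins_len = i)
  clones <- list()
  add <- function(cohort, alleles, fractions, locus = "locusA") {
    clones[[length(clones) + 1L]] <<- list(
      cohort = cohort, alleles = alleles, fractions = fractions,
      locus = locus)
  }
  for (i in 1:14) add("homozygous wild-type", list(wt), 1)
  for (k in c(1, 2, 3, 5, 7, 8, 10, 12, 15, 18, 21, 24, 28, 32, 36, 40)) {
    add("homozygous deletion", list(del(k)), 1)
  }
  for (k in 1:10) add("homozygous insertion", list(ins(k)), 1)
  for (k in c(1, 2, 3, 4, 1, 2, 3, 4)) add("homozygous substitution",
                                           list(sub(k)), 1)
  cpx_specs <- list(cpx(2, 1), cpx(3, 1), cpx(4, 2), cpx(5, 2), cpx(6, 3),
                    cpx(3, 2), cpx(2, 3), cpx(4, 3))
  for (s in cpx_specs) add("homozygous complex", list(s), 1)
  het_muts <- list(del(2), del(6), del(11), del(17), del(23), del(29),
                   del(35), del(40), del(4), del(9), ins(1), ins(3), ins(5),
                   ins(8), ins(10), sub(2), sub(3), sub(1), cpx(3, 1),
                   cpx(5, 2))
  for (m in het_muts) add("heterozygous wt+mutant", list(wt, m), c(0.5, 0.5))
  mm_pairs <- list(list(del(3), ins(2)), list(del(8), del(14)),
                   list(ins(4), sub(2)), list(del(5), cpx(2, 1)),
                   list(del(12), ins(6)), list(sub(3), del(20)),
                   list(ins(2), ins(7)), list(del(26), sub(1)),
                   list(cpx(4, 2), del(7)), list(del(33), ins(9)))
  for (p in mm_pairs) add("heterozygous mutant+mutant", p, c(0.5, 0.5))
  for (k in c(100, 200, 500, 900)) {
    add("homozygous deletion", list(del(k)), 1,
        locus = paste0("locusDel", k))
  }
  multi <- list(list(wt, del(10), ins(2)), list(wt, del(16), sub(2)),
                list(del(3), ins(1), del(22)), list(wt, del(30), ins(4)),
                list(wt, del(13), del(27)), list(del(6), ins(7), sub(3)))
  for (m in multi) add("unclear/multi-allelic", m, rep(1 / 3, 3))
  wells <- paste0(rep(LETTERS[1:8], each = 12), sprintf("%02d", 1:12))
  for (i in seq_along(clones)) clones[[i]]$well <- wells[i]
  clones
}

#' Simulate a clonal 96-well plate end to end
#'
#' Builds the reference loci (a 170-nt standard locus plus one locus per
#' long-deletion size), applies each clone's edits, and simulates reads at
#' the requested depth and error rate.  Per clone the read length is capped
#' at its shortest allele amplicon.  Everything is deterministic for a
#' fixed seed.
#'
#' @param seed Integer seed.
#' @param depth Read pairs per clone (default 30).
#' @param error_rate Per-base substitution error (default 0).
#' @param read_len Nominal read length (default 130).
#' @param plan Clone plan (default [standard_plate_plan()]).
#' @param plate_name Prefix for sample ids.
#' @return list with `reference` (named character), `db` (`reference_db`),
#'   `samples` (per clone: `r1`, `r2`, `read_len`), `truth` (data.frame),
#'   `guide`.
#' @export
simulate_clonal_plate <- function(seed, depth = 30, error_rate = 0,
                                  read_len = 130,
                                  plan = standard_plate_plan(),
                                  plate_name = "SIM1") {
  loci <- c(
    locusA = as.character(
      simulate_locus(170, list(list(seq = SIM_GUIDE, at = 61)),
                     seed = seed + 101L)),
    locusDel100 = as.character(
      simulate_locus(190, list(list(seq = SIM_GUIDE, at = 21)),
                     seed = seed + 102L)),
    locusDel200 = as.character(
      simulate_locus(290, list(list(seq = SIM_GUIDE, at = 21)),
                     seed = seed + 103L)),
    locusDel500 = as.character(
      simulate_locus(590, list(list(seq = SIM_GUIDE, at = 21)),
                     seed = seed + 104L)),
    locusDel900 = as.character(
      simulate_locus(990, list(list(seq = SIM_GUIDE, at = 21)),
                     seed = seed + 105L)))
  db <- reference_db(loci)
  samples <- list()
  truth <- list()
  local_seed(seed, {
    for (cl in plan) {
      sid <- paste0(plate_name, "-", cl$well)
      locus <- loci[[cl$locus]]
      edited <- lapply(cl$alleles, function(sp) {
        simulate_edit(locus, SIM_GUIDE, type = sp$type,
                      size = sp$size %||% 0, ins_seq = sp$ins_seq %||% "",
                      ins_len = sp$ins_len)
      })
      alleles <- vapply(edited, as.character, character(1))
      meta <- lapply(edited, function(a) {
        list(class = attr(a, "truth_class"), size = attr(a, "truth_size"))
      })
      rl <- min(read_len, nchar(alleles))
      reads <- simulate_reads(alleles, cl$fractions, depth,
                              error_rate = error_rate, read_len = rl)
      samples[[sid]] <- list(r1 = reads$r1, r2 = reads$r2, read_len = rl,
                             allele_counts = reads$allele_counts)
      truth[[sid]] <- data.frame(
        sample_id = sid, well = cl$well, locus = cl$locus,
        cohort = cl$cohort, n_alleles = length(alleles),
        classes = paste(vapply(meta, `[[`, "", "class"), collapse = ";"),
        sizes = paste(vapply(meta, function(m) m$size, 0L), collapse = ";"),
        alleles = paste(alleles, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  })
  list(reference = loci, db = db, samples = samples,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       guide = SIM_GUIDE)
}

#' Write a simulated plate to disk
#'
#' Emits `reference.fasta`, per-sample `<sample>_R1/_R2.fastq`,
#' `truth.tsv`, `plates.txt` (one plate line covering the 96 wells) and a
#' generated barcode library (`barcodes.fasta`).
#'
#' @param sim Result of [simulate_clonal_plate()].
#' @param outdir Output directory.
#' @param seed Seed for the barcode library.
#' @return Invisibly, the output directory.
#' @export
write_simulation <- function(sim, outdir, seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$reference),
                              file.path(outdir, "reference.fasta"))
  for (sid in names(sim$samples)) {
    write_fastq(sim$samples[[sid]]$r1,
                file.path(outdir, paste0(sid, "_R1.fastq")))
    write_fastq(sim$samples[[sid]]$r2,
                file.path(outdir, paste0(sid, "_R2.fastq")))
  }
  utils::write.table(sim$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines("SIM1,1-96,1", file.path(outdir, "plates.txt"))
  lib <- generate_barcode_library(seed)
  write_barcode_library(lib, file.path(outdir, "barcodes.fasta"))
  invisible(outdir)
}

#' Pool per-sample reads with index-carrying deflines
#'
#' Concatenates per-sample read pairs into one pooled R1/R2 pair whose
#' deflines carry the sample's dual index as `...<i7>+<i5>`, the fixture
#' convention consumed by [demultiplex()].
#'
#' @param samples Named list of `list(r1=, r2=)` keyed by sample id.
#' @param sheet A `sample_sheet` covering the sample ids.
#' @return list with pooled `r1` and `r2` data.frames.
#' @export
pool_samples <- function(samples, sheet) {
  rows <- sheet$data
  r1 <- list(); r2 <- list()
  for (sid in names(samples)) {
    i <- match(sid, rows$sample_id)
    if (is.na(i)) stop("sample ", sid, " not in sheet")
    tag <- paste0(" 1:N:0:", rows$i7_seq[i], "+", rows$i5_seq[i])
    a <- samples[[sid]]$r1; b <- samples[[sid]]$r2
    a$id <- paste0(sid, ".", seq_len(nrow(a)), tag)
    b$id <- a$id
    r1[[sid]] <- a; r2[[sid]] <- b
  }
  list(r1 = do.call(rbind, c(r1, list(make.row.names = FALSE))),
       r2 = do.call(rbind, c(r2, list(make.row.names = FALSE))))
}

#' The motif-collation use case fixture
#'
#' A synthetic analog of a glucocorticoid-receptor binding-sequence (GBS)
#' editing experiment: a 200-nt locus carries one planted GBS instance
#' (`ACCACAGGGTGTTCT`, matching a 15-wide GBS matrix with a free 3-bp
#' spacer; the half-sites are deliberately asymmetric so the site does not
#' also match on the minus strand).  Two engineered alleles accompany it: a
#' +1 insertion of `A` after the first site base, which destroys the
#' planted GBS while creating both a shifted GBS match and a novel
#' SOX-family-like match (`AACCACAG`), and a 5-bp deletion that simply
#' ablates the GBS.  A
#' compositionally balanced 2-kb background sequence is included for
#' Markov estimation.
#'
#' @param seed Seed for flank and background generation.
#' @return list with `reference` (named character), `db`, `motifs`,
#'   `background_seq`, `site_start`, `allele_ins`, `allele_del`, `truth`.
#' @export
use_case_fixture <- function(seed = 7) {
  site <- "ACCACAGGGTGTTCT"
  flank_l <- local_seed(seed + 1L, random_dna(80))
  substr(flank_l, 80, 80) <- "C"   # forbid an accidental SOX match in ref
  flank_r <- local_seed(seed + 2L, random_dna(105))
  ref <- paste0(flank_l, site, flank_r)
  site_start <- 81L
  allele_ins <- paste0(substr(ref, 1, site_start), "A",
                       substr(ref, site_start + 1, nchar(ref)))
  allele_del <- paste0(substr(ref, 1, site_start + 1),
                       substr(ref, site_start + 7, nchar(ref)))
  motifs <- list(
    consensus_pwm("ACCACANNNTGTTCT", "GBS1", "GR", dominance = 0.95),
    consensus_pwm("AACCACAG", "SOX1", "SOX2", dominance = 0.95))
  background_seq <- local_seed(seed + 3L,
    paste(sample(rep(DNA_BASES, 500)), collapse = ""))
  list(reference = c(gor_locus = ref),
       db = reference_db(c(gor_locus = ref)),
       motifs = motifs, background_seq = background_seq,
       site_start = site_start,
       allele_ins = allele_ins, allele_del = allele_del,
       truth = list(
         ref_hits = data.frame(motif_id = "GBS1", start = site_start,
                               strand = "+"),
         ins_lost = "GBS1", ins_gained = c("GBS1", "SOX1"),
         del_lost = "GBS1", del_gained = character(0)))
}
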