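# Allele classification, genotype inference, sub-sequence annotation,
# population summaries and report rendering.

COHORT_LEVELS <- c("homozygous deletion", "homozygous insertion",
                   "homozygous substitution", "homozygous complex",
                   "heterozygous wt+mutant", "heterozygous mutant+mutant",
                   "homozygous wild-type", "unclear/multi-allelic")

DEPRECATION_REASONS <- c("no_hits", "multiple_hits", "chain_overlap_or_span",
                         "partial_coverage")

#' Classify one allele alignment
#'
#' Classification relative to the reference hit: wild-type (no gaps, no
#' mismatches), deletion (gaps only in the query), insertion (gaps only in
#' the subject), substitution (no gaps, >= 1 mismatch), or complex indel
#' (gaps on both sides, or gaps plus mismatches).  `size_bp` is the total
#' number of inserted plus deleted bases; for substitutions it counts the
#' substituted bases.  Alignments covering less than `min_coverage` of the
#' query are deprecated as unreliable rather than classified.
#'
#' @param aln An `hsp` (possibly reconstituted).
#' @param query_len Length of the query the alignment came from.
#' @param min_coverage Minimum aligned query fraction (default 0.9).
#' @return An `allele_call`: list with `allele_class`, `size_bp`, `label`
#'   (e.g. "likely deletion 8 bp"), `locus_name`, `alignment`,
#'   `deprecated_reason` (NA when classified).
#' @export
classify_allele <- function(aln, query_len = NULL, min_coverage = 0.9) {
  stopifnot(inherits(aln, "hsp"))
  call <- function(cls, size, label, deprecated = NA_character_) {
    structure(list(allele_class = cls, size_bp = size, label = label,
                   locus_name = aln$locus_name, alignment = aln,
                   deprecated_reason = deprecated),
              class = "allele_call")
  }
  if (!is.null(query_len)) {
    cov <- (aln$qend - aln$qstart + 1) / query_len
    if (cov < min_coverage) {
      return(call(NA_character_, NA_integer_, "deprecated: partial coverage",
                  "partial_coverage"))
    }
  }
  q <- strsplit(aln$q_aln, "")[[1]]
  s <- strsplit(aln$s_aln, "")[[1]]
  del <- sum(q == "-")
  ins <- sum(s == "-")
  mism <- sum(q != "-" & s != "-" & q != s)
  if (del == 0 && ins == 0 && mism == 0) {
    return(call("wild-type", 0L, "wild-type"))
  }
  if (del > 0 && ins == 0 && mism == 0) {
    return(call("deletion", del, sprintf("likely deletion %d bp", del)))
  }
  if (ins > 0 && del == 0 && mism == 0) {
    return(call("insertion", ins, sprintf("likely insertion %d bp", ins)))
  }
  if (del == 0 && ins == 0) {
    return(call("substitution", mism, sprintf("likely substitution %d bp", mism)))
  }
  size <- del + ins + mism
  call("complex indel", size, sprintf("likely complex indel %d bp", size))
}

#' Infer a genotype from ranked allele calls
#'
#' Prominent alleles are those whose adjusted (>1% rendition) frequency is
#' at least `prominence_threshold` (default 10%).  One prominent allele
#' gives a homozygous cohort of its class; two give a heterozygous cohort
#' (wt+mutant when one is wild-type, else mutant+mutant); more than two give
#' "unclear/multi-allelic" with a multiploid note; none gives
#' "unclear/multi-allelic" (insufficient representation).  Homozygosity here
#' means one prominent sequence: a clone carrying two identical alleles is
#' indistinguishable from amplicon data and reported the same way.
#'
#' @param sample_id Sample identifier.
#' @param ranked data.frame from [rank_and_filter()].
#' @param calls list of `allele_call`, parallel to `ranked` rows.
#' @param prominence_threshold Adjusted-frequency cutoff, as a fraction
#'   (default 0.10).
#' @return A `genotype_call`: list with `sample_id`, `cohort`,
#'   `prominent` (indices into `ranked`), `ploidy_note`, `note`.
#' @export
infer_genotype <- function(sample_id, ranked, calls,
                           prominence_threshold = 0.10) {
  stopifnot(nrow(ranked) == length(calls))
  adj <- ranked$adj_gt1
  usable <- vapply(calls, function(cl) is.na(cl$deprecated_reason), logical(1))
  prominent <- which(!is.na(adj) & adj >= 100 * prominence_threshold & usable)
  n <- length(prominent)
  classes <- vapply(calls, function(cl) cl$allele_class %||% NA_character_,
                    character(1))[prominent]
  ploidy <- if (n >= 1 && n <= 2) "diploid-consistent" else "multiploid"
  if (n == 0) {
    cohort <- "unclear/multi-allelic"
    note <- "insufficient representation of allele(s)"
    ploidy <- NA_character_
  } else if (n == 1) {
    cohort <- switch(classes[1],
                     "wild-type" = "homozygous wild-type",
                     "deletion" = "homozygous deletion",
                     "insertion" = "homozygous insertion",
                     "substitution" = "homozygous substitution",
                     "complex indel" = "homozygous complex")
    note <- "single prominent allele (true homozygote or identical alleles)"
  } else if (n == 2) {
    cohort <- if (any(classes == "wild-type")) "heterozygous wt+mutant"
              else "heterozygous mutant+mutant"
    note <- ""
  } else {
    cohort <- "unclear/multi-allelic"
    note <- sprintf("%d prominent alleles", n)
  }
  structure(list(sample_id = sample_id, cohort = cohort,
                 prominent = prominent, ploidy_note = ploidy, note = note),
            class = "genotype_call")
}

#' Annotate short sub-sequences on an alignment
#'
#' Exact-match search of a guide RNA (rendered above alignments) or a test
#' sub-sequence (rendered below) on both strands of the reference locus and
#' of the allele, so that indels can be interpreted as consequences of
#' nuclease targeting and test sequences assessed for presence versus
#' ablation.
#'
#' @param aln An `hsp` alignment (query = allele, subject = reference).
#' @param db `reference_db` for the subject side.
#' @param query_oriented Full allele sequence in aligned orientation.
#' @param guide,test Optional sub-sequences (length >= 6).
#' @return list of `subseq_annotation`: `query_seq`, `role`, `found_ref`,
#'   `found_allele`, `ref_positions` (data.frame pos/strand),
#'   `allele_positions`.
#' @export
annotate_subsequences <- function(aln, db, query_oriented,
                                  guide = NULL, test = NULL) {
  mk <- function(seqs, role) {
    if (is.null(seqs)) return(NULL)
    seqs <- toupper(seqs)
    if (nchar(seqs) < 6) stop(role, " sub-sequence shorter than 6 nt")
    ref_seq <- db$seq[match(aln$locus_name, db$name)]
    find <- function(subj) {
      hitsp <- gregexpr(seqs, subj, fixed = TRUE)[[1]]
      hitsm <- gregexpr(reverse_complement(seqs), subj, fixed = TRUE)[[1]]
      pos <- c(if (hitsp[1] > 0) hitsp else integer(0),
               if (hitsm[1] > 0) hitsm else integer(0))
      strand <- c(if (hitsp[1] > 0) rep("+", length(hitsp)) else character(0),
                  if (hitsm[1] > 0) rep("-", length(hitsm)) else character(0))
      data.frame(pos = as.integer(pos), strand = strand,
                 stringsAsFactors = FALSE)
    }
    rp <- find(ref_seq)
    ap <- find(query_oriented)
    structure(list(query_seq = seqs, role = role,
                   found_ref = nrow(rp) > 0, found_allele = nrow(ap) > 0,
                   ref_positions = rp, allele_positions = ap),
              class = "subseq_annotation")
  }
  out <- list()
  g <- mk(guide, "guide"); if (!is.null(g)) out <- c(out, list(g))
  t <- mk(test, "test"); if (!is.null(t)) out <- c(out, list(t))
  out
}

#' Summarize a genotyped population
#'
#' Aggregates per-sample genotype calls into cohort percentages, diploid
#' versus multiploid fractions, wild-type versus mutant allele-class
#' percentages over prominent alleles, and a synopsis of reads lost to
#' analysis by deprecation reason.
#'
#' @param results list of per-sample results as produced by
#'   [genotype_sample()] (each with `genotype`, `ranked`, `calls`).
#' @return A `population_summary` list.
#' @export
summarize_population <- function(results) {
  n <- length(results)
  cohorts <- vapply(results, function(r) r$genotype$cohort, character(1))
  genotyped <- cohorts != "unclear/multi-allelic"
  cohort_tab <- table(factor(cohorts, levels = COHORT_LEVELS))
  ploidy <- vapply(results, function(r) r$genotype$ploidy_note %||% NA_character_,
                   character(1))
  classes <- unlist(lapply(results, function(r) {
    idx <- r$genotype$prominent
    vapply(r$calls[idx], function(cl) cl$allele_class, character(1))
  }))
  lost <- unlist(lapply(results, function(r) {
    vapply(r$calls, function(cl) cl$deprecated_reason, character(1))
  }))
  lost_counts <- lapply(results, function(r) {
    reasons <- vapply(r$calls, function(cl) cl$deprecated_reason, character(1))
    counts <- r$ranked$count
    vapply(DEPRECATION_REASONS, function(rs) {
      sum(counts[!is.na(reasons) & reasons == rs])
    }, numeric(1))
  })
  reads_lost <- Reduce(`+`, lost_counts,
                       accumulate = FALSE) %||% setNames(rep(0, 4), DEPRECATION_REASONS)
  structure(list(
    n_samples = n,
    fraction_genotyped = if (n) mean(genotyped) else 0,
    pct_diploid = if (n) 100 * mean(!is.na(ploidy) & ploidy == "diploid-consistent") else 0,
    pct_multiploid = if (n) 100 * mean(!is.na(ploidy) & ploidy == "multiploid") else 0,
    pct_cohort = if (n) 100 * as.numeric(cohort_tab) / max(sum(cohort_tab), 1) else
      rep(0, length(COHORT_LEVELS)),
    cohort_counts = cohort_tab,
    pct_wildtype_alleles = if (length(classes)) 100 * mean(classes == "wild-type") else 0,
    pct_mutant_alleles = if (length(classes)) 100 * mean(classes != "wild-type") else 0,
    allele_class_counts = table(factor(classes,
      levels = c("wild-type", "deletion", "insertion", "substitution",
                 "complex indel"))),
    reads_lost = reads_lost
  ), class = "population_summary")
}

#' Genotype one sample from its merged-read tally
#'
#' Ranks the sample's merged sequences, aligns each ranked sequence to the
#' reference database (chaining and reconstituting multi-HSP alignments),
#' classifies alleles, and infers the genotype cohort.
#'
#' @param sample_id Sample identifier.
#' @param tally A `read_tally`.
#' @param db `reference_db`.
#' @param params [align_params()].
#' @param prominence_threshold Fraction for [infer_genotype()].
#' @param guide,test Optional annotation sub-sequences.
#' @param top_n Ranked sequences to analyze (default 10).
#' @param max_span_bp Chain span limit (default 1000).
#' @return list with `sample_id`, `ranked`, `calls`, `genotype`,
#'   `annotations`.
#' @export
genotype_sample <- function(sample_id, tally, db, params = align_params(),
                            prominence_threshold = 0.10, guide = NULL,
                            test = NULL, top_n = 10, max_span_bp = 1000) {
  ranked <- rank_and_filter(tally, top_n = top_n)
  calls <- vector("list", nrow(ranked))
  annotations <- vector("list", nrow(ranked))
  for (i in seq_len(nrow(ranked))) {
    calls[[i]] <- call_one_allele(ranked$sequence[i], db, params, max_span_bp)
    if ((!is.null(guide) || !is.null(test)) &&
        is.na(calls[[i]]$deprecated_reason)) {
      annotations[[i]] <- annotate_subsequences(
        calls[[i]]$alignment, db, attr(calls[[i]], "query_oriented"),
        guide = guide, test = test)
    }
  }
  genotype <- infer_genotype(sample_id, ranked, calls, prominence_threshold)
  list(sample_id = sample_id, ranked = ranked, calls = calls,
       genotype = genotype, annotations = annotations)
}

# align + (chain + reconstitute) + classify one candidate allele sequence
call_one_allele <- function(seq, db, params = align_params(),
                            max_span_bp = 1000, min_coverage = 0.9) {
  dep <- function(reason, label) {
    structure(list(allele_class = NA_character_, size_bp = NA_integer_,
                   label = label, locus_name = NA_character_,
                   alignment = NULL, deprecated_reason = reason),
              class = "allele_call")
  }
  hits <- local_align(seq, db, params)
  if (hits$no_hits) return(dep("no_hits", "deprecated: no hits"))
  if (hits$multiple_hits) return(dep("multiple_hits", "deprecated: multiple hits"))
  if (length(hits$hsps) == 1) {
    aln <- hits$hsps[[1]]
  } else {
    chain <- chain_hsps(hits$hsps, max_span_bp = max_span_bp)
    if (inherits(chain, "deprecated_chain")) {
      return(dep("chain_overlap_or_span",
                 paste0("deprecated: hsp chain ", chain$reason)))
    }
    aln <- reconstitute_allele(chain, db, hits$query_oriented)
  }
  out <- classify_allele(aln, query_len = nchar(seq),
                         min_coverage = min_coverage)
  attr(out, "query_oriented") <- hits$query_oriented
  attr(out, "n_hsps") <- length(hits$hsps)
  out
}

SCARCE_DIVIDER <- ">>>>> remaining alleles occur at frequency <10% <<<<<"

fmt_pct <- function(x) ifelse(is.na(x), "-", sprintf("%.1f%%", x))

format_sample_block <- function(res, db) {
  g <- res$genotype
  lines <- c(sprintf("Sample: %s", res$sample_id),
             sprintf("Inferred genotype: %s%s", g$cohort,
                     if (nzchar(g$note %||% "")) paste0(" (", g$note, ")") else ""))
  divider_done <- FALSE
  for (i in seq_len(nrow(res$ranked))) {
    r <- res$ranked[i, ]
    if (isTRUE(r$scarce_flag) && !divider_done) {
      lines <- c(lines, SCARCE_DIVIDER)
      divider_done <- TRUE
    }
    cl <- res$calls[[i]]
    lines <- c(lines,
      sprintf("  Allele: rank %d | reads %d | raw %s | top10 %s | >1%% %s | >10%% %s",
              r$rank, r$count, fmt_pct(r$raw_freq), fmt_pct(r$pct_top10),
              fmt_pct(r$adj_gt1), fmt_pct(r$adj_gt10)),
      sprintf("  Allele definition: %s", cl$label))
    if (!is.null(cl$alignment)) {
      loc <- cl$alignment$locus_name
      coords <- db$coords[match(loc, db$name)]
      lines <- c(lines,
        sprintf("  Locus: %s %s | strand %s | subject %d-%d",
                loc, coords, cl$alignment$strand,
                cl$alignment$sstart, cl$alignment$send),
        "  Alignment:",
        format_alignment_block(cl$alignment))
      anns <- res$annotations[[i]]
      for (a in anns %||% list()) {
        place <- if (a$role == "guide") "above" else "below"
        lines <- c(lines, sprintf(
          "  %s sequence %s (%s): reference %s, allele %s", a$role,
          a$query_seq, place,
          if (a$found_ref) "present" else "absent",
          if (a$found_allele) "present" else "absent (ablated)"))
      }
    }
    lines <- c(lines, "")
  }
  c(lines, "")
}

#' Render genotype reports
#'
#' Writes `allele_definitions.txt` (per-sample Allele/Locus/Alignment blocks
#' with the scarce divider), `allele_definitions.csv` (one row per ranked
#' allele with all four frequency renditions), `genotypes.txt` (samples
#' grouped by cohort in the fixed reporting order: deletions before
#' insertions before substitutions/complex, then heterozygous, wild-type,
#' unclear), `population_summary.txt` and `run_metrics.txt`.
#'
#' @param results list of per-sample results ([genotype_sample()]).
#' @param db `reference_db`.
#' @param outdir Output directory (created if needed).
#' @param metrics Optional named list appended to `run_metrics.txt`.
#' @return Invisibly, the named vector of file paths.
#' @export
render_reports <- function(results, db, outdir, metrics = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    allele_definitions_txt = file.path(outdir, "allele_definitions.txt"),
    allele_definitions_csv = file.path(outdir, "allele_definitions.csv"),
    genotypes_txt = file.path(outdir, "genotypes.txt"),
    population_summary_txt = file.path(outdir, "population_summary.txt"),
    run_metrics_txt = file.path(outdir, "run_metrics.txt"))

  writeLines(unlist(lapply(results, format_sample_block, db = db)),
             paths["allele_definitions_txt"])

  csv <- do.call(rbind, lapply(results, function(res) {
    if (nrow(res$ranked) == 0) return(NULL)
    data.frame(
      sample_id = res$sample_id,
      rank = res$ranked$rank,
      allele_class = vapply(res$calls, function(cl)
        cl$allele_class %||% NA_character_, character(1)),
      size_bp = vapply(res$calls, function(cl)
        as.integer(cl$size_bp %||% NA_integer_), integer(1)),
      locus = vapply(res$calls, function(cl)
        cl$locus_name %||% NA_character_, character(1)),
      count = res$ranked$count,
      raw_freq = res$ranked$raw_freq,
      pct_top10 = res$ranked$pct_top10,
      adj_gt1 = res$ranked$adj_gt1,
      adj_gt10 = res$ranked$adj_gt10,
      genotype_cohort = res$genotype$cohort,
      stringsAsFactors = FALSE)
  }))
  utils::write.table(csv, paths["allele_definitions_csv"], sep = ",",
                     row.names = FALSE, quote = FALSE)

  cohorts <- vapply(results, function(r) r$genotype$cohort, character(1))
  glines <- character(0)
  for (lev in COHORT_LEVELS) {
    idx <- which(cohorts == lev)
    if (!length(idx)) next
    glines <- c(glines, sprintf("== %s (%d samples) ==", lev, length(idx)),
                vapply(results[idx], function(r) {
                  labs <- vapply(r$calls[r$genotype$prominent],
                                 function(cl) cl$label, character(1))
                  sprintf("  %s: %s", r$sample_id,
                          if (length(labs)) paste(labs, collapse = " / ")
                          else "(no prominent alleles)")
                }, character(1)), "")
  }
  writeLines(glines, paths["genotypes_txt"])

  ps <- summarize_population(results)
  writeLines(format_population_summary(ps), paths["population_summary_txt"])

  mt <- c(sprintf("samples: %d", length(results)),
          sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
          vapply(names(metrics), function(k)
            sprintf("%s: %s", k, paste(metrics[[k]], collapse = ",")),
            character(1)))
  writeLines(mt, paths["run_metrics_txt"])
  invisible(paths)
}

format_population_summary <- function(ps) {
  c("Synopsis of Interpretations: Allele Definitions & Genotype Inferences",
    sprintf("  samples: %d", ps$n_samples),
    sprintf("  fraction genotyped: %.1f%%", 100 * ps$fraction_genotyped),
    sprintf("  %% diploid (1-2 prominent alleles): %.1f%%", ps$pct_diploid),
    sprintf("  %% multiploid (>2 prominent alleles): %.1f%%", ps$pct_multiploid),
    sprintf("  cohort %s: %.1f%% (%d)", COHORT_LEVELS, ps$pct_cohort,
            as.integer(ps$cohort_counts)),
    sprintf("  %% wild-type alleles: %.1f%%", ps$pct_wildtype_alleles),
    sprintf("  %% mutant alleles: %.1f%%", ps$pct_mutant_alleles),
    "Synopsis of Reads Lost to Analysis",
    sprintf("  %s: %d", names(ps$reads_lost), as.integer(ps$reads_lost)))
}

#' @export
print.population_summary <- function(x, ...) {
  writeLines(format_population_summary(x))
  invisible(x)
}

#' Run the genotyping pipeline over a directory of FASTQ pairs
#'
#' Discovers `<sample>_R1.fastq[.gz]` / `<sample>_R2.fastq[.gz]` pairs,
#' merges and tallies reads, genotypes every sample and renders the report
#' files.
#'
#' @param fastq_dir Directory of per-sample FASTQ pairs.
#' @param reference Reference FASTA path (or `reference_db`).
#' @param outdir Report directory.
#' @inheritParams genotype_sample
#' @param min_overlap,max_mismatch_rate Merge parameters.
#' @return list with `results`, `summary`, `paths`, `elapsed_sec`.
#' @export
genotype_run <- function(fastq_dir, reference, outdir,
                         prominence_threshold = 0.10, guide = NULL,
                         test = NULL, top_n = 10, params = align_params(),
                         min_overlap = 10, max_mismatch_rate = 0.1) {
  t0 <- Sys.time()
  db <- if (inherits(reference, "reference_db")) reference else reference_db(reference)
  r1_files <- sort(list.files(fastq_dir, "_R1\\.fastq(\\.gz)?$", full.names = TRUE))
  if (!length(r1_files)) stop("no *_R1.fastq files in ", fastq_dir)
  results <- lapply(r1_files, function(f1) {
    f2 <- sub("_R1\\.fastq", "_R2.fastq", f1)
    if (!file.exists(f2)) stop("missing mate file for ", f1)
    sid <- sub("_R1\\.fastq(\\.gz)?$", "", basename(f1))
    tl <- tally_reads(read_fastq(f1), read_fastq(f2),
                      min_overlap = min_overlap,
                      max_mismatch_rate = max_mismatch_rate)
    genotype_sample(sid, tl, db, params = params,
                    prominence_threshold = prominence_threshold,
                    guide = guide, test = test, top_n = top_n)
  })
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  paths <- render_reports(results, db, outdir, metrics = list(
    prominence_threshold = prominence_threshold,
    top_n = top_n, elapsed_sec = sprintf("%.1f", elapsed)))
  list(results = results, summary = summarize_population(results),
       paths = paths, elapsed_sec = elapsed)
}
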