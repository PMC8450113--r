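# Collation of TFBS losses and gains per allele, with gap-aware mapping of
# allele hit coordinates onto the reference through the alignment.

# coordinate machinery for one gapped alignment (query = allele,
# subject = reference): position -> column maps for both sides, the
# allele -> reference position map, and the set of gap columns
alignment_maps <- function(aln) {
  q <- strsplit(aln$q_aln, "")[[1]]
  s <- strsplit(aln$s_aln, "")[[1]]
  qpos <- spos <- rep(NA_integer_, length(q))
  qc <- aln$qstart - 1L
  sc <- aln$sstart - 1L
  for (i in seq_along(q)) {
    if (q[i] != "-") { qc <- qc + 1L; qpos[i] <- qc }
    if (s[i] != "-") { sc <- sc + 1L; spos[i] <- sc }
  }
  qcol <- rep(NA_integer_, qc)
  okq <- !is.na(qpos)
  qcol[qpos[okq]] <- which(okq)
  scol <- rep(NA_integer_, sc)
  oks <- !is.na(spos)
  scol[spos[oks]] <- which(oks)
  q2s <- rep(NA_integer_, qc)
  q2s[qpos[okq]] <- spos[okq]
  list(q2s = q2s, qcol = qcol, scol = scol,
       gapcols = which(q == "-" | s == "-"),
       qspan = c(aln$qstart, aln$qend), sspan = c(aln$sstart, aln$send))
}

# does the hit window [start, stop], whose positions map to alignment
# columns via `poscol`, touch an alignment gap?  Windows reaching outside
# the aligned span count as touching; so do windows whose column span
# (padded by one column either side) contains a gap column.  The rule is
# the same for both alignment sides, which keeps the diff antisymmetric.
window_touches_gap <- function(start, stop, poscol, gapcols) {
  wpos <- start:stop
  inside <- wpos >= 1 & wpos <= length(poscol)
  if (!all(inside)) return(TRUE)
  cols <- poscol[wpos]
  if (anyNA(cols)) return(TRUE)
  any(gapcols >= min(cols) - 1L & gapcols <= max(cols) + 1L)
}

#' Collate lost and gained TFBS hits for one allele
#'
#' Allele hit coordinates are mapped onto the reference through the
#' alignment.  A hit present with identical (motif, strand, mapped start) on
#' both sides is unchanged and appears in neither list.  Unmatched reference
#' hits are lost; unmatched allele hits are gained.  Hits whose window
#' touches an alignment gap -- it contains inserted or deleted columns, or
#' directly abuts one -- cannot be placed exactly: they are reported with an
#' approximate-position flag and are never cancelled against the other
#' side, so that sites interrupted or reconstituted around an indel are
#' always surfaced.  The touch rule is identical on both sides, keeping the
#' diff antisymmetric under role reversal.
#'
#' @param ref_hits,allele_hits Hit data.frames from [scan_sequence()] (one
#'   reference sequence, one allele sequence).
#' @param aln `hsp` alignment of the allele (query) to the reference
#'   (subject).
#' @return A `tfbs_diff`: data.frame with `side` ("lost"/"gained"),
#'   `motif_id`, `tf_name`, `start`, `stop`, `strand`, `score`, `p_value`,
#'   `matched_seq`, `ref_start` (mapped reference start; exact for lost,
#'   possibly approximate for gained), `approx`.
#' @export
collate <- function(ref_hits, allele_hits, aln) {
  if (is.null(aln)) stop("alignment absent for allele")
  maps <- alignment_maps(aln)

  a <- allele_hits
  n_a <- nrow(a)
  mapped_start <- rep(NA_integer_, n_a)
  approx_a <- rep(FALSE, n_a)
  for (i in seq_len(n_a)) {
    approx_a[i] <- window_touches_gap(a$start[i], a$stop[i], maps$qcol,
                                      maps$gapcols)
    wpos <- a$start[i]:a$stop[i]
    inside <- wpos[wpos >= 1 & wpos <= length(maps$q2s)]
    m <- maps$q2s[inside]
    known <- m[!is.na(m)]
    mapped_start[i] <- if (length(inside) && !is.na(maps$q2s[inside[1]]))
      maps$q2s[inside[1]] else if (length(known)) known[1] else NA_integer_
  }

  r <- ref_hits
  n_r <- nrow(r)
  approx_r <- rep(FALSE, n_r)
  for (i in seq_len(n_r)) {
    approx_r[i] <- window_touches_gap(r$start[i], r$stop[i], maps$scol,
                                      maps$gapcols)
  }

  matched_a <- rep(FALSE, n_a)
  matched_r <- rep(FALSE, n_r)
  if (n_a && n_r) {
    key_a <- paste(a$motif_id, a$strand, mapped_start)
    key_r <- paste(r$motif_id, r$strand, r$start)
    for (i in which(!approx_a)) {
      j <- which(!matched_r & !approx_r & key_r == key_a[i])
      if (length(j)) {
        matched_a[i] <- TRUE
        matched_r[j[1]] <- TRUE
      }
    }
  }

  lost <- if (n_r) r[!matched_r, , drop = FALSE] else r
  gained <- if (n_a) a[!matched_a, , drop = FALSE] else a
  mk <- function(df, side, ref_start, approx) {
    if (!nrow(df)) {
      df$side <- character(0); df$ref_start <- integer(0); df$approx <- logical(0)
      return(df)
    }
    df$side <- side
    df$ref_start <- ref_start
    df$approx <- approx
    df
  }
  out <- rbind(
    mk(lost, "lost", if (n_r) r$start[!matched_r] else integer(0),
       if (n_r) approx_r[!matched_r] else logical(0)),
    mk(gained, "gained", if (n_a) mapped_start[!matched_a] else integer(0),
       if (n_a) approx_a[!matched_a] else logical(0)))
  rownames(out) <- NULL
  class(out) <- c("tfbs_diff", "data.frame")
  out
}

#' Partition alleles by TF-of-interest loss/regain status
#'
#' Given per-allele diffs, builds three views for one transcription factor:
#' alleles that lost a TFBS for the TF without regaining one for the same
#' TF; alleles that lost one and regained an alternative TFBS for the same
#' TF; and alleles that lost one and gained a TFBS for a distinct TF.  The
#' first two views are mutually exclusive; the third is independent.
#'
#' @param diffs data.frame of pooled `tfbs_diff` rows carrying `sample_id`
#'   and `rank` columns.
#' @param tf_name TF of interest (matched against `tf_name`).
#' @return list of three data.frames (`lost_no_regain`,
#'   `lost_regain_same_tf`, `lost_gain_distinct_tf`) of sample_id/rank
#'   pairs.
#' @export
tf_of_interest_views <- function(diffs, tf_name) {
  empty <- data.frame(sample_id = character(0), rank = integer(0))
  if (!nrow(diffs) || !tf_name %in% diffs$tf_name) {
    if (nrow(diffs) && !tf_name %in% diffs$tf_name) {
      warning("TF of interest '", tf_name, "' not present in any hit")
    }
    return(list(lost_no_regain = empty, lost_regain_same_tf = empty,
                lost_gain_distinct_tf = empty))
  }
  keys <- unique(diffs[, c("sample_id", "rank")])
  flags <- lapply(seq_len(nrow(keys)), function(i) {
    d <- diffs[diffs$sample_id == keys$sample_id[i] & diffs$rank == keys$rank[i], ]
    lost_tf <- any(d$side == "lost" & d$tf_name == tf_name)
    gained_same <- any(d$side == "gained" & d$tf_name == tf_name)
    gained_dist <- any(d$side == "gained" & d$tf_name != tf_name)
    c(lost_tf & !gained_same, lost_tf & gained_same, lost_tf & gained_dist)
  })
  fl <- do.call(rbind, flags)
  list(lost_no_regain = keys[fl[, 1], , drop = FALSE],
       lost_regain_same_tf = keys[fl[, 2], , drop = FALSE],
       lost_gain_distinct_tf = keys[fl[, 3], , drop = FALSE])
}

fmt_pval <- function(p, approx) {
  paste0(sprintf("%.3g", p), ifelse(approx, " (note, approx. position)", ""))
}

# track line: matched_seq placed at its alignment columns
hit_track <- function(hit, aln, side) {
  q <- strsplit(aln$q_aln, "")[[1]]
  s <- strsplit(aln$s_aln, "")[[1]]
  ncol_ <- length(q)
  track <- rep(" ", ncol_)
  pos <- if (side == "gained") cumsum(q != "-") else cumsum(s != "-")
  offset <- if (side == "gained") aln$qstart - 1L else aln$sstart - 1L
  cols <- which(pos + offset >= hit$start & pos + offset <= hit$stop &
                  (if (side == "gained") q != "-" else s != "-"))
  if (length(cols)) {
    chars <- strsplit(hit$matched_seq, "")[[1]]
    track[cols] <- chars[seq_along(cols)]
  }
  paste(track, collapse = "")
}

#' Render the TFBS collation report and workbook
#'
#' `collated_TFBS.txt` shows, per allele, the allele-versus-reference
#' alignment with TFBSs new to the allele rendered above it and TFBSs lost
#' from the allele below it; approximate-position hits carry the literal
#' annotation "note, approx. position" next to their p-value.  The workbook
#' is a directory of tab-separated worksheets (at most eight): all hits,
#' lost, gained, lost+gained, the three TF-of-interest views (when a TF is
#' given), and a summary.
#'
#' @param diffs Pooled diff data.frame (`sample_id`, `rank` + `tfbs_diff`
#'   columns).
#' @param alignments Named list (`<sample_id>|<rank>`) of `hsp` alignments.
#' @param outdir Output directory.
#' @param tf_name Optional TF of interest.
#' @return Invisibly, list with `txt` path and `workbook` directory.
#' @export
render_collation <- function(diffs, alignments, outdir, tf_name = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  txt <- file.path(outdir, "collated_TFBS.txt")
  lines <- character(0)
  for (key in names(alignments)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    sid <- parts[1]; rk <- as.integer(parts[2])
    aln <- alignments[[key]]
    d <- diffs[diffs$sample_id == sid & diffs$rank == rk, , drop = FALSE]
    lines <- c(lines, sprintf("Sample %s | allele rank %d | locus %s",
                              sid, rk, aln$locus_name))
    gained <- d[d$side == "gained", , drop = FALSE]
    lost <- d[d$side == "lost", , drop = FALSE]
    for (i in seq_len(nrow(gained))) {
      lines <- c(lines,
        sprintf("  new TFBS  %s", hit_track(gained[i, ], aln, "gained")),
        sprintf("            ^ %s (%s) %s-%s (%s) pval %s",
                gained$motif_id[i], gained$tf_name[i], gained$start[i],
                gained$stop[i], gained$strand[i],
                fmt_pval(gained$p_value[i], gained$approx[i])))
    }
    lines <- c(lines,
               sprintf("  allele    %s", aln$q_aln),
               sprintf("            %s", aln$midline),
               sprintf("  reference %s", aln$s_aln))
    for (i in seq_len(nrow(lost))) {
      lines <- c(lines,
        sprintf("  lost TFBS %s", hit_track(lost[i, ], aln, "lost")),
        sprintf("            v %s (%s) %s-%s (%s) pval %s",
                lost$motif_id[i], lost$tf_name[i], lost$start[i],
                lost$stop[i], lost$strand[i],
                fmt_pval(lost$p_value[i], lost$approx[i])))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, txt)

  wb <- file.path(outdir, "collated_TFBS_workbook")
  dir.create(wb, showWarnings = FALSE)
  sheet <- function(name, df) {
    utils::write.table(df, file.path(wb, paste0(name, ".tsv")), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  sheet("01_all_hits", diffs)
  sheet("02_lost", diffs[diffs$side == "lost", , drop = FALSE])
  sheet("03_gained", diffs[diffs$side == "gained", , drop = FALSE])
  both_keys <- intersect(
    unique(paste(diffs$sample_id, diffs$rank)[diffs$side == "lost"]),
    unique(paste(diffs$sample_id, diffs$rank)[diffs$side == "gained"]))
  sheet("04_lost_and_gained",
        diffs[paste(diffs$sample_id, diffs$rank) %in% both_keys, , drop = FALSE])
  if (!is.null(tf_name)) {
    views <- tf_of_interest_views(diffs, tf_name)
    sheet("05_tf_lost_no_regain", views$lost_no_regain)
    sheet("06_tf_lost_regain_same_tf", views$lost_regain_same_tf)
    sheet("07_tf_lost_gain_distinct_tf", views$lost_gain_distinct_tf)
  }
  summary_df <- data.frame(
    alleles = length(alignments),
    hits_lost = sum(diffs$side == "lost"),
    hits_gained = sum(diffs$side == "gained"),
    approx_hits = sum(diffs$approx))
  sheet("08_summary", summary_df)
  invisible(list(txt = txt, workbook = wb))
}

#' Run the TFBS collation pipeline over a directory of FASTQ pairs
#'
#' For each sample the top `top_n` (default 5) most abundant merged read
#' types are aligned to the reference, scanned for motif hits alongside the
#' reference, and diffed.  Writes `collated_TFBS.txt` and the workbook
#' directory plus `run_metrics.txt`.
#'
#' @param fastq_dir Directory of `<sample>_R1/_R2.fastq` pairs.
#' @param reference Reference FASTA (or `reference_db`).
#' @param motifs MEME-minimal motif file path, or list of `pwm`.
#' @param background_fasta FASTA for Markov background estimation (or a
#'   `markov_background`).
#' @param outdir Output directory.
#' @param p_threshold FIMO-style reporting threshold (default 1e-4).
#' @param tf_name Optional TF of interest.
#' @param top_n Candidate alleles per sample (default 5).
#' @param markov_order Background order (default 0).
#' @param params [align_params()].
#' @return list with `diffs`, `views`, `paths`, `per_sample`.
#' @export
collate_run <- function(fastq_dir, reference, motifs, background_fasta,
                        outdir, p_threshold = 1e-4, tf_name = NULL,
                        top_n = 5, markov_order = 0,
                        params = align_params()) {
  t0 <- Sys.time()
  db <- if (inherits(reference, "reference_db")) reference else reference_db(reference)
  motif_list <- if (is.character(motifs)) parse_meme_motifs(motifs) else motifs
  bg <- if (inherits(background_fasta, "markov_background")) background_fasta
        else estimate_markov_background(background_fasta, order = markov_order)
  los <- lapply(motif_list, build_log_odds, background = bg)
  ref_seqs <- setNames(db$seq, db$name)
  ref_hits_all <- scan_sequence(ref_seqs, los, bg, p_threshold)

  r1_files <- sort(list.files(fastq_dir, "_R1\\.fastq(\\.gz)?$", full.names = TRUE))
  if (!length(r1_files)) stop("no *_R1.fastq files in ", fastq_dir)
  all_diffs <- list()
  alignments <- list()
  per_sample <- list()
  for (f1 in r1_files) {
    f2 <- sub("_R1\\.fastq", "_R2.fastq", f1)
    sid <- sub("_R1\\.fastq(\\.gz)?$", "", basename(f1))
    tl <- tally_reads(read_fastq(f1), read_fastq(f2))
    ranked <- rank_and_filter(tl, top_n = top_n)
    per_sample[[sid]] <- list(n_candidates = nrow(ranked))
    for (i in seq_len(nrow(ranked))) {
      hits <- local_align(ranked$sequence[i], db, params)
      if (hits$no_hits || hits$multiple_hits) next
      aln <- if (length(hits$hsps) == 1) hits$hsps[[1]] else {
        chain <- chain_hsps(hits$hsps)
        if (inherits(chain, "deprecated_chain")) next
        reconstitute_allele(chain, db, hits$query_oriented)
      }
      allele_seq <- setNames(hits$query_oriented, "allele")
      a_hits <- scan_sequence(allele_seq, los, bg, p_threshold)
      r_hits <- ref_hits_all[ref_hits_all$sequence_name == aln$locus_name, ,
                             drop = FALSE]
      d <- collate(r_hits, a_hits, aln)
      if (nrow(d)) {
        d$sample_id <- sid
        d$rank <- ranked$rank[i]
        all_diffs[[length(all_diffs) + 1L]] <- d
      }
      alignments[[paste(sid, ranked$rank[i], sep = "|")]] <- aln
    }
  }
  diffs <- if (length(all_diffs)) do.call(rbind, all_diffs) else
    data.frame(motif_id = character(0), tf_name = character(0),
               sequence_name = character(0), start = integer(0),
               stop = integer(0), strand = character(0), score = numeric(0),
               p_value = numeric(0), matched_seq = character(0),
               side = character(0), ref_start = integer(0),
               approx = logical(0), sample_id = character(0),
               rank = integer(0))
  paths <- render_collation(diffs, alignments, outdir, tf_name)
  views <- if (!is.null(tf_name)) tf_of_interest_views(diffs, tf_name) else NULL
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  writeLines(c(sprintf("samples: %d", length(r1_files)),
               sprintf("candidate alleles per sample (top_n): %d", top_n),
               sprintf("p-value threshold: %g", p_threshold),
               sprintf("markov order: %d", markov_order),
               sprintf("tf of interest: %s", tf_name %||% "(none)"),
               sprintf("elapsed_sec: %.1f", elapsed)),
             file.path(outdir, "run_metrics.txt"))
  list(diffs = diffs, views = views, paths = paths, per_sample = per_sample,
       elapsed_sec = elapsed)
}
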