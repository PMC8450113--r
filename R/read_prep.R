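# Read preparation: demultiplexing by dual index, overlap merging of
# paired-end reads, tallying of distinct merged sequences, and the four
# abundance renditions used to rank candidate alleles.

#' Read / write FASTQ
#'
#' Thin wrappers around Biostrings FASTQ support returning plain character
#' data (`id`, `seq`, `qual` with Sanger-scaled Phred qualities).  Gzipped
#' input is handled transparently.
#'
#' @param path FASTQ file.
#' @return `read_fastq`: data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping (empty) metadata columns on conversion
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fastq
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

# index pair "ACGTACGT+TTGGCCAA" from an Illumina-style defline
index_from_defline <- function(id) {
  m <- regexpr("[ACGTN]{4,}\\+[ACGTN]{4,}$", id)
  out <- rep(NA_character_, length(id))
  out[m > 0] <- regmatches(id, m)
  out
}

#' Demultiplex pooled reads by dual index
#'
#' Assigns each read pair to the Sample Sheet row whose (i7, i5) barcode pair
#' matches the indices carried in the read defline (convention
#' `... <i7>+<i5>`), allowing up to `max_mismatch` substitutions per index.
#' A pair is assigned only when exactly one row is within tolerance for both
#' indices; ambiguous or unmatched pairs go to the unassigned bin.  Read
#' counts are conserved: assigned + unassigned equals the input count.
#'
#' @param r1,r2 data.frames from [read_fastq()] (mate order preserved).
#' @param sheet A `sample_sheet`.
#' @param max_mismatch Per-index substitution tolerance (default 1).
#' @param outdir Optional directory; when given, per-sample
#'   `<sample_id>_R1.fastq` / `_R2.fastq` files and `unassigned_R*.fastq`
#'   are written.
#' @return list with `assignments` (per-read sample id or NA), `counts`
#'   (table per sample incl. `"unassigned"`), `n_ambiguous`, and (if
#'   `outdir` given) `files`.
#' @export
demultiplex <- function(r1, r2, sheet, max_mismatch = 1, outdir = NULL) {
  stopifnot(inherits(sheet, "sample_sheet"), nrow(r1) == nrow(r2))
  idx <- index_from_defline(r1$id)
  if (anyNA(idx)) stop("reads without an index pair in the defline: ",
                       sum(is.na(idx)), " (expected '...<i7>+<i5>')")
  parts <- strsplit(idx, "+", fixed = TRUE)
  obs_i7 <- vapply(parts, `[`, "", 1)
  obs_i5 <- vapply(parts, `[`, "", 2)
  rows_i7 <- sheet$data$i7_seq
  rows_i5 <- sheet$data$i5_seq
  assign_one <- function(o7, o5) {
    d7 <- hamming(o7, rows_i7)
    d5 <- hamming(o5, rows_i5)
    hit <- which(d7 <= max_mismatch & d5 <= max_mismatch)
    if (length(hit) == 1) hit else if (length(hit) > 1) -1L else NA_integer_
  }
  key <- paste(obs_i7, obs_i5)
  ukey <- !duplicated(key)
  lookup <- setNames(mapply(assign_one, obs_i7[ukey], obs_i5[ukey]), key[ukey])
  rowidx <- lookup[key]
  ambiguous <- !is.na(rowidx) & rowidx == -1L
  rowidx[ambiguous] <- NA_integer_
  assignments <- sheet$data$sample_id[rowidx]
  counts <- table(factor(ifelse(is.na(assignments), "unassigned", assignments),
                         levels = c(sheet$data$sample_id, "unassigned")))
  out <- list(assignments = assignments, counts = counts,
              n_ambiguous = sum(ambiguous))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    groups <- split(seq_along(assignments),
                    ifelse(is.na(assignments), "unassigned", assignments))
    for (g in names(groups)) {
      ii <- groups[[g]]
      f1 <- file.path(outdir, paste0(g, "_R1.fastq"))
      f2 <- file.path(outdir, paste0(g, "_R2.fastq"))
      write_fastq(r1[ii, ], f1)
      write_fastq(r2[ii, ], f2)
      files <- c(files, f1, f2)
    }
    out$files <- files
  }
  out
}

#' Merge one read pair by 3' overlap
#'
#' Finds the maximal-length overlap between the 3' end of R1 and the 5' end
#' of the reverse-complemented R2 whose mismatch rate is at most
#' `max_mismatch_rate` and whose length is at least `min_overlap`.  At
#' overlap mismatches the consensus takes the base with the higher Phred
#' quality (R1 wins ties).  Merged length is `len(r1) + len(r2) - overlap`.
#'
#' @param r1_seq,r2_seq Mate sequences (R2 in sequencing orientation).
#' @param r1_qual,r2_qual Sanger-scaled quality strings (optional; equal
#'   qualities assumed when absent).
#' @param min_overlap Minimum qualifying overlap (default 10).
#' @param max_mismatch_rate Maximum fraction of mismatched overlap positions
#'   (default 0.1).
#' @return The merged sequence, or `NULL` when no overlap qualifies (a merge
#'   failure; counted, not fatal).
#' @export
merge_read_pair <- function(r1_seq, r2_seq, r1_qual = NULL, r2_qual = NULL,
                            min_overlap = 10, max_mismatch_rate = 0.1) {
  if (!nzchar(r1_seq) || !nzchar(r2_seq)) stop("empty read")
  rc2 <- reverse_complement(r2_seq)
  a <- strsplit(r1_seq, "")[[1]]
  b <- strsplit(rc2, "")[[1]]
  qa <- if (is.null(r1_qual)) rep(30L, length(a)) else utf8ToInt(r1_qual) - 33L
  qb <- if (is.null(r2_qual)) rep(30L, length(b)) else rev(utf8ToInt(r2_qual) - 33L)
  n1 <- length(a); n2 <- length(b)
  hi <- min(n1, n2); lo <- max(min_overlap, 1)
  if (hi < lo) return(NULL)
  for (ov in seq(hi, lo, by = -1)) {
    sa <- (n1 - ov + 1):n1
    sb <- 1:ov
    mism <- which(a[sa] != b[sb])
    if (length(mism) / ov <= max_mismatch_rate) {
      cons <- a[sa]
      if (length(mism)) {
        useb <- qb[sb][mism] > qa[sa][mism]
        cons[mism[useb]] <- b[sb][mism[useb]]
      }
      return(paste(c(a[seq_len(n1 - ov)], cons, b[seq_len(n2 - ov) + ov]),
                   collapse = ""))
    }
  }
  NULL
}

#' Tally merged read sequences for one sample
#'
#' Merges every read pair and counts the distinct merged sequences.  The
#' conservation invariant `sum(counts) + merge_failures == n_pairs` always
#' holds.
#'
#' @param r1,r2 data.frames from [read_fastq()].
#' @inheritParams merge_read_pair
#' @return A `read_tally`: list with `counts` (named integer vector,
#'   sequence -> count), `total_reads` (merged pair count) and
#'   `merge_failures`.
#' @export
tally_reads <- function(r1, r2, min_overlap = 10, max_mismatch_rate = 0.1) {
  stopifnot(nrow(r1) == nrow(r2))
  counts <- new.env(parent = emptyenv())
  fails <- 0L
  for (i in seq_len(nrow(r1))) {
    m <- merge_read_pair(r1$seq[i], r2$seq[i], r1$qual[i], r2$qual[i],
                         min_overlap, max_mismatch_rate)
    if (is.null(m)) {
      fails <- fails + 1L
    } else {
      counts[[m]] <- (counts[[m]] %||% 0L) + 1L
    }
  }
  keys <- ls(counts)
  cv <- setNames(vapply(keys, function(k) counts[[k]], integer(1)), keys)
  structure(list(counts = cv, total_reads = sum(cv), merge_failures = fails,
                 n_pairs = nrow(r1)),
            class = "read_tally")
}

# tally directly from already-merged sequences (simulator / test shortcut)
tally_from_sequences <- function(seqs) {
  tb <- table(seqs)
  structure(list(counts = setNames(as.integer(tb), names(tb)),
                 total_reads = length(seqs), merge_failures = 0L,
                 n_pairs = length(seqs)),
            class = "read_tally")
}

#' Rank merged sequences and compute the four frequency renditions
#'
#' The most abundant merged sequences (at most `top_n`, default 10) are
#' ranked by count, ties broken lexicographically by sequence for
#' determinism.  For each ranked sequence four abundance renditions are
#' reported: raw frequency (% of all merged reads); % of the top-`top_n`
#' mass; % after excluding reads at <= 1% raw frequency; and % after
#' excluding reads at <= 10% raw frequency.  The two filtered renditions are
#' renormalized to 100% over the retained reads; sequences excluded by a
#' filter carry `NA` in that rendition.  Sequences whose adjusted (>1%)
#' frequency falls below 10% are flagged scarce (likely artefacts in clonal
#' material).
#'
#' @param tally A `read_tally`.
#' @param top_n Number of ranked sequences to report (default 10).
#' @return data.frame with columns `rank`, `sequence`, `count`, `raw_freq`,
#'   `pct_top10`, `adj_gt1`, `adj_gt10`, `scarce_flag` (frequencies in
#'   percent).
#' @export
rank_and_filter <- function(tally, top_n = 10) {
  stopifnot(inherits(tally, "read_tally"))
  cv <- tally$counts
  if (length(cv) == 0) {
    return(data.frame(rank = integer(0), sequence = character(0),
                      count = integer(0), raw_freq = numeric(0),
                      pct_top10 = numeric(0), adj_gt1 = numeric(0),
                      adj_gt10 = numeric(0), scarce_flag = logical(0)))
  }
  ord <- order(-cv, names(cv))
  cv <- cv[ord]
  total <- tally$total_reads
  raw_all <- 100 * cv / total
  keep1 <- raw_all > 1
  keep10 <- raw_all > 10
  denom1 <- sum(cv[keep1])
  denom10 <- sum(cv[keep10])
  top <- utils::head(seq_along(cv), top_n)
  denom_top <- sum(cv[top])
  adj1 <- ifelse(keep1[top], 100 * cv[top] / denom1, NA_real_)
  adj10 <- ifelse(keep10[top], 100 * cv[top] / denom10, NA_real_)
  data.frame(
    rank = seq_along(top),
    sequence = names(cv)[top],
    count = as.integer(cv[top]),
    raw_freq = raw_all[top],
    pct_top10 = 100 * cv[top] / denom_top,
    adj_gt1 = adj1,
    adj_gt10 = adj10,
    scarce_flag = is.na(adj1) | adj1 < 10,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
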