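# Local alignment of candidate allele sequences against reference loci.
# Single alignment fragments (HSPs) hold indels of at most `max_gap` bp
# (BLASTN-like behaviour); longer indels split the alignment into colinear
# fragments that are chained, within a 1 kb subject span, and reconstituted
# into one allele-versus-reference alignment.

#' Build a reference database from FASTA
#'
#' Deflines are parsed as `name [coordinates ...]`: the first whitespace
#' token is the unique locus name, the remainder (typically genome
#' coordinates) is kept as a description string.
#'
#' @param fasta Path to a reference FASTA, or a named character vector of
#'   sequences.
#' @return A `reference_db`: data.frame with columns `name`, `coords`,
#'   `seq`.
#' @export
reference_db <- function(fasta) {
  if (length(fasta) == 1 && file.exists(fasta)) {
    x <- Biostrings::readDNAStringSet(fasta)
    deflines <- names(x)
    seqs <- toupper(as.character(x))
  } else {
    deflines <- names(fasta)
    if (is.null(deflines)) stop("reference sequences must be named")
    seqs <- toupper(unname(fasta))
  }
  name <- sub("\\s.*$", "", deflines)
  coords <- ifelse(grepl("\\s", deflines), sub("^\\S+\\s+", "", deflines), "")
  if (anyDuplicated(name)) stop("duplicate locus names in reference")
  if (any(grepl("[^ACGTN]", seqs))) stop("reference sequences must be A/C/G/T/N")
  db <- data.frame(name = name, coords = coords, seq = seqs,
                   stringsAsFactors = FALSE)
  class(db) <- c("reference_db", "data.frame")
  db
}

#' Fetch a reference subsequence
#'
#' 1-based inclusive coordinates, mirroring BLAST reporting conventions.
#'
#' @param db A `reference_db`.
#' @param locus Locus name.
#' @param start,end 1-based inclusive span.
#' @return The subsequence as a character scalar.
#' @export
fetch_reference_span <- function(db, locus, start, end) {
  i <- match(locus, db$name)
  if (is.na(i)) stop("unknown locus: ", locus)
  L <- nchar(db$seq[i])
  if (start < 1 || end > L || start > end) {
    stop("span ", start, "-", end, " out of range for locus ", locus,
         " (length ", L, ")")
  }
  substr(db$seq[i], start, end)
}

#' Alignment scoring parameters
#'
#' BLASTN-like defaults: match +2, mismatch -3, gap open -5, gap extend -2
#' (a gap of length g costs 5 + 2g).  `max_gap` caps the indel length a
#' single alignment fragment may hold (default 60 bp); longer indels split
#' into multiple fragments.  `min_score` discards trivial fragments;
#' `multi_hit_ratio` flags queries whose second-best locus scores within
#' this fraction of the best.
#'
#' @param match,mismatch,gap_open,gap_extend Scoring terms (penalties
#'   negative).
#' @param max_gap Maximum gap-run length inside one fragment (bp).
#' @param min_score Minimum fragment score to report.
#' @param max_hsps Maximum fragments collected per locus/strand.
#' @param multi_hit_ratio Second-best/best score ratio that triggers the
#'   multiple-hits flag.
#' @return list of parameters.
#' @export
align_params <- function(match = 2, mismatch = -3, gap_open = -5,
                         gap_extend = -2, max_gap = 60, min_score = 40,
                         max_hsps = 4, multi_hit_ratio = 0.9) {
  list(match = match, mismatch = mismatch, gap_open = abs(gap_open),
       gap_extend = abs(gap_extend), max_gap = max_gap,
       min_score = min_score, max_hsps = max_hsps,
       multi_hit_ratio = multi_hit_ratio)
}

midline_of <- function(qa, sa) {
  q <- strsplit(qa, "")[[1]]
  s <- strsplit(sa, "")[[1]]
  paste(ifelse(q != "-" & s != "-" & q == s, "|", " "), collapse = "")
}

new_hsp <- function(locus_name, strand, raw, qa, sa) {
  structure(list(locus_name = locus_name,
                 qstart = raw$qstart, qend = raw$qend,
                 sstart = raw$sstart, send = raw$send,
                 strand = strand, score = raw$score,
                 q_aln = qa, s_aln = sa, midline = midline_of(qa, sa)),
            class = "hsp")
}

# Trim gap runs lying within `max_tail` columns of either alignment end.
# A micro-extension that jumps a gap just before the end of a local
# alignment is more plausibly part of the adjacent indel than a separate
# event; trimming it keeps chained long-indel sizes exact.  Edits at the
# extreme ends of an amplicon (within `max_tail` bp) are outside the
# trustworthy window anyway.
trim_hsp_ends <- function(raw, params, max_tail = 10) {
  q <- raw$q_aln; s <- raw$s_aln
  n <- length(q)
  gap <- q == 0L | s == 0L
  if (!any(gap)) return(raw)
  lo <- 1L; hi <- n
  repeat {
    inwin <- which(gap & seq_len(n) >= lo & seq_len(n) <= hi)
    if (!length(inwin)) break
    runs <- rle(gap[lo:hi])
    ends <- lo - 1L + cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    gi <- which(runs$values)
    first <- gi[1]; last <- gi[length(gi)]
    if (hi - ends[last] <= max_tail && starts[last] > lo) {
      hi <- starts[last] - 1L
    } else if (starts[first] - lo <= max_tail && ends[first] < hi) {
      lo <- ends[first] + 1L
    } else break
  }
  if (lo == 1L && hi == n) return(raw)
  qa <- q[lo:hi]; sa <- s[lo:hi]
  qhead <- sum(q[seq_len(lo - 1L)] != 0L)
  shead <- sum(s[seq_len(lo - 1L)] != 0L)
  n_open <- sum(rle(qa == 0L | sa == 0L)$values)
  list(score = sum(qa != 0L & sa != 0L & qa == sa) * params$match +
         sum(qa != 0L & sa != 0L & qa != sa) * params$mismatch -
         n_open * params$gap_open -
         (sum(qa == 0L) + sum(sa == 0L)) * params$gap_extend,
       qstart = raw$qstart + qhead,
       qend = raw$qstart + qhead + sum(qa != 0L) - 1L,
       sstart = raw$sstart + shead,
       send = raw$sstart + shead + sum(sa != 0L) - 1L,
       q_aln = qa, s_aln = sa)
}

# all qualifying HSPs for one oriented query vs one subject, by iterative
# masking of the aligned query span
hsps_one_strand <- function(qcode, scode, locus_name, strand, params) {
  out <- list()
  qwork <- qcode
  for (k in seq_len(params$max_hsps)) {
    raw <- .sw_align_cpp(qwork, scode, params$match, params$mismatch,
                         params$gap_open, params$gap_extend, params$max_gap)
    if (raw$score < params$min_score) break
    trimmed <- trim_hsp_ends(raw, params)
    qa <- int_to_dna(trimmed$q_aln)
    sa <- int_to_dna(trimmed$s_aln)
    out[[length(out) + 1L]] <- new_hsp(locus_name, strand, trimmed, qa, sa)
    # mask the untrimmed span so trimmed tails are not re-found
    qwork[raw$qstart:raw$qend] <- 9L
    # not enough unmasked query left to reach min_score
    if (sum(qwork != 9L, na.rm = TRUE) * params$match < params$min_score) break
  }
  out
}

#' Local alignment of a query against the reference database
#'
#' Aligns the query (both strands) to every locus.  Indels of up to
#' `max_gap` bp (default 60) between matching flanks are reported within a
#' single HSP; longer indels yield two or more HSPs recovered by masking and
#' re-alignment.  The best locus is chosen by total HSP score on its better
#' strand; a second locus scoring within `multi_hit_ratio` of the best is
#' flagged as a multiple hit.
#'
#' @param query DNA string (length >= 20).
#' @param db A `reference_db`.
#' @param params [align_params()].
#' @return A `blast_hits` object: list with `hsps` (best locus/strand, by
#'   query start), `locus`, `strand`, `query_oriented` (the query in the
#'   aligned orientation), `no_hits`, `multiple_hits`, `locus_scores`.
#' @export
local_align <- function(query, db, params = align_params()) {
  query <- toupper(query)
  if (nchar(query) < 20) stop("query shorter than 20 nt")
  qplus <- dna_to_int(query)
  qminus <- rev(5L - qplus)  # revcomp in integer coding (NA stays NA)
  per_locus <- lapply(seq_len(nrow(db)), function(i) {
    scode <- dna_to_int(db$seq[i])
    hp <- hsps_one_strand(qplus, scode, db$name[i], "+", params)
    hm <- hsps_one_strand(qminus, scode, db$name[i], "-", params)
    sp <- sum(vapply(hp, `[[`, 0, "score"))
    sm <- sum(vapply(hm, `[[`, 0, "score"))
    if (sm > sp) list(hsps = hm, strand = "-", score = sm)
    else list(hsps = hp, strand = "+", score = sp)
  })
  scores <- vapply(per_locus, `[[`, 0, "score")
  names(scores) <- db$name
  if (all(scores <= 0)) {
    return(structure(list(hsps = list(), locus = NA_character_,
                          strand = NA_character_, query_oriented = query,
                          no_hits = TRUE, multiple_hits = FALSE,
                          locus_scores = scores),
                     class = "blast_hits"))
  }
  best <- which.max(scores)
  multiple <- sum(scores >= params$multi_hit_ratio * scores[best]) > 1
  sel <- per_locus[[best]]
  hsps <- sel$hsps[order(vapply(sel$hsps, `[[`, 0L, "qstart"))]
  oriented <- if (sel$strand == "-") reverse_complement(query) else query
  structure(list(hsps = hsps, locus = db$name[best], strand = sel$strand,
                 query_oriented = oriented, no_hits = FALSE,
                 multiple_hits = multiple, locus_scores = scores),
            class = "blast_hits")
}

#' Chain colinear HSPs spanning a long indel
#'
#' Accepts two or more HSPs on one locus and strand only when they are
#' colinear (query and subject order agree), non-overlapping in both query
#' and subject, and their combined subject span does not exceed
#' `max_span_bp` (default 1000, the 1 kb rule).  Otherwise a deprecation
#' value is returned with reason `"overlap"`, `"span_exceeded"` or
#' `"discordant"` -- never an error.
#'
#' @param hsps list of `hsp` objects (or a `blast_hits`).
#' @param max_span_bp Maximum combined subject span (bp).
#' @return A `chained_alignment` (fields `hsps`, `bridged_subject_gap`,
#'   `bridged_query_gap`, `subject_span`) or a `deprecated_chain` with a
#'   `reason`.
#' @export
chain_hsps <- function(hsps, max_span_bp = 1000) {
  if (inherits(hsps, "blast_hits")) hsps <- hsps$hsps
  stopifnot(length(hsps) >= 2)
  deprecate <- function(reason) structure(list(reason = reason),
                                          class = "deprecated_chain")
  loci <- vapply(hsps, `[[`, "", "locus_name")
  strands <- vapply(hsps, `[[`, "", "strand")
  if (length(unique(loci)) > 1 || length(unique(strands)) > 1) {
    return(deprecate("discordant"))
  }
  ord <- order(vapply(hsps, `[[`, 0, "qstart"))
  hsps <- hsps[ord]
  qs <- vapply(hsps, `[[`, 0, "qstart"); qe <- vapply(hsps, `[[`, 0, "qend")
  ss <- vapply(hsps, `[[`, 0, "sstart"); se <- vapply(hsps, `[[`, 0, "send")
  n <- length(hsps)
  if (any(qs[-1] <= qe[-n])) return(deprecate("overlap"))
  if (any(ss[-1] < ss[-n])) return(deprecate("discordant"))
  if (any(ss[-1] <= se[-n])) return(deprecate("overlap"))
  span <- max(se) - min(ss) + 1
  if (span > max_span_bp) return(deprecate("span_exceeded"))
  structure(list(hsps = hsps,
                 bridged_subject_gap = sum(ss[-1] - se[-n] - 1L),
                 bridged_query_gap = sum(qs[-1] - qe[-n] - 1L),
                 subject_span = span),
            class = "chained_alignment")
}

# Junction refinement for chained HSPs.  A fragment can "steal" a few bases
# of its neighbour's flank through a lucky extension across the indel
# boundary (net-positive despite a mismatch); the stolen bases then corrupt
# the bridged gap length.  Refinement trims non-match columns within
# `max_tail` columns of the inner-facing ends and re-extends the opposite
# fragment diagonally over exact matches, restoring the exact indel size.
trim_hsp_side <- function(hsp, side, max_tail = 10, min_keep = 5) {
  q <- strsplit(hsp$q_aln, "")[[1]]
  s <- strsplit(hsp$s_aln, "")[[1]]
  repeat {
    n <- length(q)
    nonmatch <- which(q == "-" | s == "-" | q != s)
    if (!length(nonmatch)) break
    if (side == "tail") {
      cand <- nonmatch[n - nonmatch < max_tail]
      if (!length(cand)) break
      cut <- max(cand)
      if (cut - 1L < min_keep) break
      keep <- seq_len(cut - 1L)
    } else {
      cand <- nonmatch[nonmatch <= max_tail]
      if (!length(cand)) break
      cut <- min(cand)
      if (n - cut < min_keep) break
      keep <- (cut + 1L):n
    }
    dq <- sum(q[-keep] != "-")
    ds <- sum(s[-keep] != "-")
    if (side == "tail") {
      hsp$qend <- hsp$qend - dq
      hsp$send <- hsp$send - ds
    } else {
      hsp$qstart <- hsp$qstart + dq
      hsp$sstart <- hsp$sstart + ds
    }
    q <- q[keep]; s <- s[keep]
  }
  hsp$q_aln <- paste(q, collapse = "")
  hsp$s_aln <- paste(s, collapse = "")
  hsp$midline <- midline_of(hsp$q_aln, hsp$s_aln)
  hsp
}

refine_junction <- function(prev, cur, query_oriented, sseq, max_tail = 10) {
  prev <- trim_hsp_side(prev, "tail", max_tail)
  cur <- trim_hsp_side(cur, "head", max_tail)
  qv <- strsplit(query_oriented, "")[[1]]
  sv <- strsplit(sseq, "")[[1]]
  # grow prev rightward over exact diagonal matches
  while (prev$qend + 1L < cur$qstart && prev$send + 1L < cur$sstart &&
         qv[prev$qend + 1L] == sv[prev$send + 1L]) {
    prev$qend <- prev$qend + 1L
    prev$send <- prev$send + 1L
    b <- qv[prev$qend]
    prev$q_aln <- paste0(prev$q_aln, b)
    prev$s_aln <- paste0(prev$s_aln, b)
  }
  # grow cur leftward over exact diagonal matches
  while (cur$qstart - 1L > prev$qend && cur$sstart - 1L > prev$send &&
         qv[cur$qstart - 1L] == sv[cur$sstart - 1L]) {
    cur$qstart <- cur$qstart - 1L
    cur$sstart <- cur$sstart - 1L
    b <- qv[cur$qstart]
    cur$q_aln <- paste0(b, cur$q_aln)
    cur$s_aln <- paste0(b, cur$s_aln)
  }
  prev$midline <- midline_of(prev$q_aln, prev$s_aln)
  cur$midline <- midline_of(cur$q_aln, cur$s_aln)
  list(prev = prev, cur = cur)
}

#' Reconstitute a single alignment from a chain
#'
#' Joins the chained HSPs into one contiguous query-versus-subject alignment
#' over the full subject span: reference bases between consecutive HSPs are
#' fetched from the database and rendered as deletion columns, unaligned
#' query bases between HSPs as insertion columns.
#'
#' @param chain A `chained_alignment`.
#' @param db The `reference_db` the HSPs refer to.
#' @param query_oriented The query sequence in aligned orientation.
#' @return A single `hsp`-like alignment covering the whole chain.
#' @export
reconstitute_allele <- function(chain, db, query_oriented) {
  stopifnot(inherits(chain, "chained_alignment"))
  hsps <- chain$hsps
  locus <- hsps[[1]]$locus_name
  sseq <- db$seq[match(locus, db$name)]
  for (k in seq_along(hsps)[-1]) {
    r <- refine_junction(hsps[[k - 1]], hsps[[k]], query_oriented, sseq)
    hsps[[k - 1]] <- r$prev
    hsps[[k]] <- r$cur
  }
  qa <- hsps[[1]]$q_aln
  sa <- hsps[[1]]$s_aln
  bridged <- 0L
  for (k in seq_along(hsps)[-1]) {
    prev <- hsps[[k - 1]]; cur <- hsps[[k]]
    bridged <- bridged + (cur$sstart - prev$send - 1L)
    qgap <- cur$qstart - prev$qend - 1L
    sgap <- cur$sstart - prev$send - 1L
    if (qgap < 0 || sgap < 0) stop("inconsistent chain")
    if (qgap > 0) {
      ins <- substr(query_oriented, prev$qend + 1L, cur$qstart - 1L)
      qa <- paste0(qa, ins)
      sa <- paste0(sa, strrep("-", qgap))
    }
    if (sgap > 0) {
      del <- fetch_reference_span(db, locus, prev$send + 1L, cur$sstart - 1L)
      qa <- paste0(qa, strrep("-", sgap))
      sa <- paste0(sa, del)
    }
    qa <- paste0(qa, cur$q_aln)
    sa <- paste0(sa, cur$s_aln)
  }
  last <- hsps[[length(hsps)]]
  structure(list(locus_name = locus,
                 qstart = hsps[[1]]$qstart, qend = last$qend,
                 sstart = hsps[[1]]$sstart, send = last$send,
                 strand = hsps[[1]]$strand,
                 score = sum(vapply(hsps, `[[`, 0, "score")),
                 q_aln = qa, s_aln = sa, midline = midline_of(qa, sa),
                 reconstituted = TRUE,
                 bridged_subject_gap = bridged),
            class = "hsp")
}

#' @export
print.hsp <- function(x, ...) {
  cat(sprintf("HSP %s strand %s score %d | query %d-%d subject %d-%d\n",
              x$locus_name, x$strand, as.integer(x$score),
              x$qstart, x$qend, x$sstart, x$send))
  invisible(x)
}

# render one alignment in the three-line gapped layout, wrapped
format_alignment_block <- function(aln, width = 60, indent = "    ") {
  n <- nchar(aln$q_aln)
  qpos <- aln$qstart; spos <- aln$sstart
  qch <- strsplit(aln$q_aln, "")[[1]]
  sch <- strsplit(aln$s_aln, "")[[1]]
  lines <- character(0)
  for (off in seq(1, n, by = width)) {
    hi <- min(off + width - 1, n)
    qseg <- substr(aln$q_aln, off, hi)
    mseg <- substr(aln$midline, off, hi)
    sseg <- substr(aln$s_aln, off, hi)
    nq <- sum(qch[off:hi] != "-")
    ns <- sum(sch[off:hi] != "-")
    lines <- c(lines,
               sprintf("%squery %6d %s %d", indent, qpos, qseg,
                       qpos + max(nq - 1, 0)),
               sprintf("%s             %s", indent, mseg),
               sprintf("%ssbjct %6d %s %d", indent, spos, sseg,
                       spos + max(ns - 1, 0)))
    qpos <- qpos + nq; spos <- spos + ns
  }
  lines
}
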