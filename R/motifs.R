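# Position weight matrices: MEME-minimal parsing, Markov background
# estimation, background-normalized log-odds with exact p-values by dynamic
# programming, and both-strand scanning at a p-value threshold.

#' Construct a PWM object
#'
#' @param mat 4 x w probability matrix (rows A, C, G, T; columns sum to 1).
#' @param motif_id,tf_name Identifiers.
#' @param nsites Optional source-site count.
#' @return A `pwm` object.
#' @export
pwm <- function(mat, motif_id, tf_name = motif_id, nsites = 20) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("PWM must have 4 rows (A,C,G,T)")
  rownames(mat) <- DNA_BASES
  if (any(mat < 0)) stop("motif ", motif_id, ": negative probabilities")
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-6)) {
    stop("motif ", motif_id, ": column(s) ",
         paste(which(abs(cs - 1) > 1e-6), collapse = ","), " do not sum to 1")
  }
  structure(list(motif_id = motif_id, tf_name = tf_name,
                 width = ncol(mat), mat = mat, nsites = nsites),
            class = "pwm")
}

# PWM whose consensus is `consensus`; `dominance` at the consensus base,
# remainder spread evenly; positions given in `uniform` are fully uniform
# (used for flexible spacers, e.g. the GRE 3-bp spacer)
consensus_pwm <- function(consensus, motif_id, tf_name = motif_id,
                          dominance = 0.95, uniform = integer(0)) {
  b <- strsplit(toupper(consensus), "")[[1]]
  w <- length(b)
  mat <- matrix((1 - dominance) / 3, 4, w, dimnames = list(DNA_BASES, NULL))
  for (j in seq_len(w)) {
    if (j %in% uniform || b[j] == "N") mat[, j] <- 0.25
    else mat[b[j], j] <- dominance
  }
  pwm(mat, motif_id, tf_name)
}

#' Parse / write MEME-minimal motif files
#'
#' Reads the MEME minimal text format (version line, optional ALPHABET /
#' strands / background lines, then `MOTIF` blocks each with a
#' `letter-probability matrix` header).  Matrix rows are per-position
#' probabilities over A, C, G, T; malformed matrices raise an error naming
#' the motif.
#'
#' @param file Path to a MEME-minimal text file.
#' @return list of `pwm` objects.
#' @export
parse_meme_motifs <- function(file) {
  lines <- readLines(file)
  if (!any(grepl("^MEME version", lines))) {
    stop("not a MEME-minimal file (no 'MEME version' line): ", file)
  }
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MOTIF blocks in ", file)
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    hdr <- strsplit(trimws(lines[starts[k]]), "\\s+")[[1]]
    motif_id <- hdr[2]
    tf_name <- if (length(hdr) >= 3) hdr[3] else motif_id
    body_end <- if (k < length(starts)) starts[k + 1] - 1 else length(lines)
    block <- lines[starts[k]:body_end]
    lp <- grep("^letter-probability matrix", block)
    if (!length(lp)) stop("motif ", motif_id, ": missing letter-probability matrix")
    hdr2 <- block[lp[1]]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr2))
    nsites <- suppressWarnings(
      as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", hdr2)))
    rows <- block[-seq_len(lp[1])]
    rows <- rows[grepl("^\\s*[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}\\s*$", rows)]
    if (length(rows) != w) {
      stop("motif ", motif_id, ": expected ", w, " matrix rows, found ",
           length(rows))
    }
    vals <- t(vapply(strsplit(trimws(rows), "\\s+"),
                     function(x) as.numeric(x[1:4]), numeric(4)))
    out[[k]] <- pwm(t(vals), motif_id, tf_name,
                    nsites = if (is.na(nsites)) 20L else nsites)
  }
  out
}

#' @rdname parse_meme_motifs
#' @param motifs list of `pwm` objects.
#' @param path Output file.
#' @param background Optional length-4 background written to the header.
#' @export
write_meme_motifs <- function(motifs, path, background = rep(0.25, 4)) {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
             "Background letter frequencies",
             paste(sprintf("%s %.5f", DNA_BASES, background), collapse = " "),
             "")
  for (m in motifs) {
    lines <- c(lines,
               paste("MOTIF", m$motif_id, m$tf_name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       m$width, m$nsites %||% 20L),
               apply(m$mat, 2, function(col)
                 paste(sprintf("%.6f", col), collapse = " ")),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Estimate a Markov background model from sequences
#'
#' Counts (k+1)-mers over both strands of the supplied sequences, adds a
#' pseudocount of 0.1 per cell, and normalizes to conditional probabilities
#' of each base given its k-mer context.  The order-0 marginal (used for
#' log-odds scoring and exact p-value tables) is always computed alongside.
#'
#' @param x FASTA path or character vector of sequences.
#' @param order Markov order k >= 0 (default 0).
#' @param pseudocount Added to every (k+1)-mer count cell (default 0.1).
#' @return A `markov_background`: list with `order`, `cond` (contexts x 4
#'   matrix of conditionals), `marginal` (named length-4 vector).
#' @export
estimate_markov_background <- function(x, order = 0, pseudocount = 0.1) {
  seqs <- if (length(x) == 1 && file.exists(x)) {
    as.character(Biostrings::readDNAStringSet(x))
  } else x
  seqs <- toupper(seqs)
  seqs <- seqs[nzchar(seqs)]
  if (!length(seqs)) stop("no sequences for background estimation")
  both <- c(seqs, reverse_complement(seqs))
  total_len <- sum(nchar(seqs))
  if (total_len <= 4^(order + 1)) {
    warning("background training length (", total_len,
            ") small for order ", order)
  }
  count_kmers <- function(k) {
    ctxs <- if (k == 0) "" else
      apply(expand.grid(rep(list(DNA_BASES), k))[, k:1, drop = FALSE], 1,
            paste, collapse = "")
    counts <- matrix(0, length(ctxs), 4, dimnames = list(ctxs, DNA_BASES))
    for (s in both) {
      v <- strsplit(s, "")[[1]]
      n <- length(v)
      if (n < k + 1) next
      ctx <- if (k == 0) rep("", n) else {
        substring(s, seq_len(n - k), seq_len(n - k) + k - 1)
      }
      nxt <- v[(k + 1):n]
      ctx_use <- if (k == 0) ctx[(k + 1):n] else ctx
      ok <- !grepl("[^ACGT]", ctx_use) & nxt %in% DNA_BASES
      if (!any(ok)) next
      tb <- table(factor(ctx_use[ok], levels = ctxs),
                  factor(nxt[ok], levels = DNA_BASES))
      counts <- counts + as.matrix(tb)
    }
    counts
  }
  counts <- count_kmers(order) + pseudocount
  cond <- counts / rowSums(counts)
  marg_counts <- if (order == 0) counts else count_kmers(0) + pseudocount
  marginal <- as.numeric(marg_counts[1, ] / sum(marg_counts[1, ]))
  names(marginal) <- DNA_BASES
  structure(list(order = order, cond = cond, marginal = marginal,
                 pseudocount = pseudocount, training_length = total_len),
            class = "markov_background")
}

#' Uniform order-0 background
#' @return A `markov_background` with marginal 0.25 per base.
#' @export
uniform_background <- function() {
  cond <- matrix(0.25, 1, 4, dimnames = list("", DNA_BASES))
  structure(list(order = 0, cond = cond,
                 marginal = setNames(rep(0.25, 4), DNA_BASES),
                 pseudocount = 0, training_length = Inf),
            class = "markov_background")
}

#' Background-normalized log-odds with an exact p-value table
#'
#' Converts a PWM into integer-discretized log2 odds against an order-0
#' background: `score(j, b) = log2(((p_jb + pc * bg_b) / (1 + pc)) / bg_b)`
#' with a background-proportional pseudocount `pc` (default 0.1).  Scores
#' are discretized per column to a shared integer scale (`nbins` bins,
#' default 1000) and the exact null distribution of the total integer score
#' of a random w-mer drawn from the background is computed by dynamic
#' programming, giving an exact p-value for every achievable score.
#'
#' @param x A `pwm`.
#' @param background `markov_background` (its order-0 marginal is used; the
#'   exact p-value table is defined under an order-0 null).
#' @param pseudocount Background-proportional pseudocount (default 0.1).
#' @param nbins Discretization bins (default 1000).
#' @return A `log_odds` object: `real` (4 x w log2-odds), `int` (4 x w
#'   integer scores), `offset`, `scale`, `survival` (P(S >= t) indexed by
#'   integer score t = 0..w*(nbins-1)), `bg`.
#' @export
build_log_odds <- function(x, background, pseudocount = 0.1, nbins = 1000) {
  stopifnot(inherits(x, "pwm"), inherits(background, "markov_background"))
  bg <- background$marginal
  if (any(bg <= 0)) stop("zero background probability")
  p <- x$mat
  s <- log2(sweep(sweep(p, 1, pseudocount * bg, "+") / (1 + pseudocount),
                  1, bg, "/"))
  off <- apply(s, 2, min)
  delta <- max(sweep(s, 2, off, "-"))
  scale <- if (delta > 0) (nbins - 1) / delta else 1
  int_mat <- round(sweep(s, 2, off, "-") * scale)
  storage.mode(int_mat) <- "integer"
  w <- x$width
  maxint <- max(int_mat)
  pdf <- numeric(w * maxint + 1)
  pdf[1] <- 1
  cur_max <- 0L
  for (j in seq_len(w)) {
    new <- numeric(length(pdf))
    for (b in 1:4) {
      sh <- int_mat[b, j]
      idx <- seq_len(cur_max + 1L)
      new[idx + sh] <- new[idx + sh] + pdf[idx] * bg[b]
    }
    pdf <- new
    cur_max <- cur_max + max(int_mat[, j])
  }
  survival <- rev(cumsum(rev(pdf)))
  survival <- pmin(survival, 1)
  structure(list(motif_id = x$motif_id, tf_name = x$tf_name, width = w,
                 real = s, int = int_mat, offset = off, scale = scale,
                 survival = survival, bg = bg, nbins = nbins),
            class = "log_odds")
}

# exact p-value of integer score t (P(S_int >= t) under the background)
pvalue_from_int <- function(lo, t) {
  t <- pmax(pmin(t, length(lo$survival) - 1L), 0L)
  lo$survival[t + 1L]
}

# integer and real window scores for every window start of an int-coded seq
window_scores <- function(code, lo) {
  w <- lo$width
  L <- length(code)
  nwin <- L - w + 1L
  if (nwin < 1) return(list(int = integer(0), real = numeric(0)))
  S <- integer(nwin)
  R <- numeric(nwin)
  bad <- logical(nwin)
  for (j in seq_len(w)) {
    cj <- code[j:(j + nwin - 1L)]
    nab <- is.na(cj)
    bad <- bad | nab
    cj[nab] <- 1L
    S <- S + lo$int[cbind(cj, j)]
    R <- R + lo$real[cbind(cj, j)]
  }
  S[bad] <- NA_integer_
  R[bad] <- NA_real_
  list(int = S, real = R)
}

#' Scan sequences for motif hits at an exact p-value threshold
#'
#' Scores every window of every sequence on both strands against each motif
#' and reports hits whose exact p-value is at or below the threshold
#' (default 1e-4; adjustable, with the hit set at a stricter threshold
#' always nested inside that of a looser one).  Minus-strand hits report
#' the plus-strand coordinate span and the hit-strand matched sequence.
#'
#' @param seqs Named character vector of sequences.
#' @param motifs list of `pwm` objects (or prebuilt `log_odds`).
#' @param background `markov_background` used for log-odds and p-values.
#' @param p_threshold Reporting threshold on the exact p-value.
#' @param pseudocount,nbins Passed to [build_log_odds()] when `motifs`
#'   contains `pwm`s.
#' @return data.frame of hits: `motif_id`, `tf_name`, `sequence_name`,
#'   `start`, `stop`, `strand`, `score`, `p_value`, `matched_seq`, sorted
#'   by sequence and position.  Attribute `windows_scored` counts scored
#'   windows per motif x sequence (both strands).
#' @export
scan_sequence <- function(seqs, motifs, background = uniform_background(),
                          p_threshold = 1e-4, pseudocount = 0.1,
                          nbins = 1000) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named")
  }
  los <- lapply(motifs, function(m) {
    if (inherits(m, "log_odds")) m
    else build_log_odds(m, background, pseudocount, nbins)
  })
  hits <- list()
  nwin_tab <- list()
  for (sn in names(seqs)) {
    seq_up <- toupper(seqs[[sn]])
    code <- dna_to_int(seq_up)
    rc_code <- rev(5L - code)
    L <- length(code)
    for (lo in los) {
      w <- lo$width
      if (L < w) {
        nwin_tab[[length(nwin_tab) + 1L]] <-
          data.frame(motif_id = lo$motif_id, sequence_name = sn, windows = 0L)
        next
      }
      sp <- window_scores(code, lo)
      sm <- window_scores(rc_code, lo)
      nwin_tab[[length(nwin_tab) + 1L]] <-
        data.frame(motif_id = lo$motif_id, sequence_name = sn,
                   windows = 2L * (L - w + 1L))
      pv_p <- pvalue_from_int(lo, sp$int)
      pv_m <- pvalue_from_int(lo, sm$int)
      ip <- which(!is.na(sp$int) & pv_p <= p_threshold)
      im <- which(!is.na(sm$int) & pv_m <= p_threshold)
      if (length(ip)) {
        hits[[length(hits) + 1L]] <- data.frame(
          motif_id = lo$motif_id, tf_name = lo$tf_name, sequence_name = sn,
          start = ip, stop = ip + w - 1L, strand = "+",
          score = sp$real[ip], p_value = pv_p[ip],
          matched_seq = substring(seq_up, ip, ip + w - 1L),
          stringsAsFactors = FALSE)
      }
      if (length(im)) {
        # minus-strand window i (on revcomp) covers plus coords
        # [L - i - w + 2, L - i + 1]
        st <- L - im - w + 2L
        hits[[length(hits) + 1L]] <- data.frame(
          motif_id = lo$motif_id, tf_name = lo$tf_name, sequence_name = sn,
          start = st, stop = st + w - 1L, strand = "-",
          score = sm$real[im], p_value = pv_m[im],
          matched_seq = substring(paste(int_to_dna(rc_code), collapse = ""),
                                  im, im + w - 1L),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else data.frame(
    motif_id = character(0), tf_name = character(0),
    sequence_name = character(0), start = integer(0), stop = integer(0),
    strand = character(0), score = numeric(0), p_value = numeric(0),
    matched_seq = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$sequence_name, out$start, out$motif_id, out$strand), ]
  rownames(out) <- NULL
  attr(out, "windows_scored") <- do.call(rbind, nwin_tab)
  out
}
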