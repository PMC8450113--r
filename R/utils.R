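#' @useDynLib ampliclone, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames rbinom rmultinom runif
#' @importFrom utils write.table read.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Run code under a fixed RNG state, restoring the caller's state afterwards.
local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Reverse complement of a DNA string
#'
#' Strict reverse complementation over the alphabet `A,C,G,T,N`.  Used for
#' index handling on the i5 side of dual-indexed libraries and for
#' strand-aware searches.
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector of the same length with each element
#'   reverse-complemented.
#' @examples
#' reverse_complement("AAACCC")  # "GGGTTT"
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0) return(character(0))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("non-DNA character in sequence(s): ",
         paste(utils::head(seq[bad], 3), collapse = ", "))
  }
  vapply(seq, function(x) {
    if (nchar(x) == 0) return("")
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# integer coding A=1 C=2 G=3 T=4, NA otherwise
dna_to_int <- function(seq) {
  x <- match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
  x
}

int_to_dna <- function(code) {
  out <- rep("N", length(code))
  ok <- !is.na(code) & code >= 1 & code <= 4
  out[ok] <- DNA_BASES[code[ok]]
  out[!is.na(code) & code == 0] <- "-"
  paste(out, collapse = "")
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Hamming distance between equal-length strings (vectorised over y)
hamming <- function(x, y) {
  xs <- strsplit(x, "")[[1]]
  vapply(strsplit(y, ""), function(ys) sum(xs != ys), integer(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
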