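# Dual-index barcode planning: a 96 + 96 library of 8-nt i7/i5 barcode
# primers and its expansion, via short plate:barcode specification lines,
# into an Illumina-style Sample Sheet of up to 9,216 sample rows.

WELLS_96 <- paste0(rep(LETTERS[1:8], each = 12), sprintf("%02d", 1:12))

#' Generate a dual-index barcode library
#'
#' Builds a seeded random library of 8-nt barcode primers, 96 for the i7
#' (well-identifying) role and 96 for the i5 (plate-identifying) role, under
#' a minimum pairwise Hamming-distance constraint so that single sequencing
#' errors in an index cannot convert one barcode into another.  Candidates
#' are drawn as a seeded permutation of all 4^length words and accepted
#' greedily; the search fails loudly (it is never silently relaxed) if the
#' distance constraint cannot be met.
#'
#' @param seed Integer seed; the library is deterministic given the seed.
#' @param min_distance Minimum pairwise Hamming distance among accepted
#'   barcodes (default 3, i.e. any two barcodes differ at >= 3 positions).
#' @param n_per_role Barcodes per role (default 96).
#' @param width Barcode length in nucleotides (default 8).
#' @return A `barcode_library`: data.frame with columns `id` ("i7-01" ...
#'   "i5-96"), `role` and `barcode`.
#' @examples
#' lib <- generate_barcode_library(seed = 1)
#' nrow(lib)  # 192
#' @export
generate_barcode_library <- function(seed, min_distance = 3, n_per_role = 96,
                                     width = 8) {
  stopifnot(length(min_distance) == 1, min_distance >= 1, min_distance <= width)
  n_total <- 2L * n_per_role
  n_words <- 4L^width
  # all words as an n_words x width matrix of base indices 1..4
  digits <- matrix(0L, n_words, width)
  idx <- 0:(n_words - 1)
  for (j in seq_len(width)) {
    digits[, j] <- (idx %% 4L) + 1L
    idx <- idx %/% 4L
  }
  ord <- local_seed(seed, sample.int(n_words))
  accepted <- matrix(0L, n_total, width)
  n_acc <- 0L
  for (k in ord) {
    cand <- digits[k, ]
    if (n_acc > 0L) {
      d <- rowSums(accepted[seq_len(n_acc), , drop = FALSE] !=
                     matrix(cand, n_acc, width, byrow = TRUE))
      if (min(d) < min_distance) next
    }
    n_acc <- n_acc + 1L
    accepted[n_acc, ] <- cand
    if (n_acc == n_total) break
  }
  if (n_acc < n_total) {
    stop("barcode search failed: only ", n_acc, " of ", n_total,
         " barcodes of width ", width, " satisfy pairwise Hamming distance >= ",
         min_distance)
  }
  codes <- apply(accepted, 1, function(r) paste(DNA_BASES[r], collapse = ""))
  lib <- data.frame(
    id = c(sprintf("i7-%02d", seq_len(n_per_role)),
           sprintf("i5-%02d", seq_len(n_per_role))),
    role = rep(c("i7", "i5"), each = n_per_role),
    barcode = codes,
    stringsAsFactors = FALSE
  )
  class(lib) <- c("barcode_library", "data.frame")
  lib
}

#' Write / read a barcode library
#'
#' The library is serialized either as FASTA (defline = primer id, sequence
#' = barcode) or as a two-column TSV (`id`, `barcode`; the role is recovered
#' from the id prefix).
#'
#' @param lib A `barcode_library`.
#' @param path Output file.
#' @param format `"fasta"` or `"tsv"`.
#' @return `write_barcode_library` returns `path` invisibly;
#'   `read_barcode_library` returns a `barcode_library`.
#' @export
write_barcode_library <- function(lib, path, format = c("fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "fasta") {
    x <- Biostrings::DNAStringSet(setNames(lib$barcode, lib$id))
    Biostrings::writeXStringSet(x, path)
  } else {
    utils::write.table(lib[, c("id", "barcode")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_barcode_library
#' @export
read_barcode_library <- function(path, format = c("fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "fasta") {
    x <- Biostrings::readDNAStringSet(path)
    lib <- data.frame(id = names(x), barcode = as.character(x),
                      stringsAsFactors = FALSE)
  } else {
    lib <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  }
  lib$role <- sub("-.*$", "", lib$id)
  if (!all(lib$role %in% c("i5", "i7"))) {
    stop("barcode ids must look like 'i7-01' / 'i5-01'")
  }
  lib <- lib[, c("id", "role", "barcode")]
  rownames(lib) <- NULL
  class(lib) <- c("barcode_library", "data.frame")
  lib
}

validate_barcode_library <- function(lib) {
  stopifnot(is.data.frame(lib), all(c("id", "role", "barcode") %in% names(lib)))
  if (anyDuplicated(lib$id)) stop("duplicate barcode ids")
  for (r in unique(lib$role)) {
    b <- lib$barcode[lib$role == r]
    if (anyDuplicated(b)) stop("duplicate barcodes within role ", r)
  }
  if (any(nchar(lib$barcode) != nchar(lib$barcode[1]))) {
    stop("barcodes must share one length")
  }
  if (any(grepl("[^ACGT]", lib$barcode))) stop("barcodes must be A/C/G/T only")
  invisible(lib)
}

# minimum pairwise Hamming distance within a set of equal-length strings
min_pairwise_hamming <- function(codes) {
  n <- length(codes)
  if (n < 2) return(Inf)
  mat <- do.call(rbind, strsplit(codes, ""))
  best <- Inf
  for (i in seq_len(n - 1)) {
    d <- rowSums(mat[(i + 1):n, , drop = FALSE] !=
                   matrix(mat[i, ], n - i, ncol(mat), byrow = TRUE))
    best <- min(best, d)
  }
  best
}

#' Parse plate specification lines
#'
#' One line of three comma-separated values describes a whole 96-well plate:
#' `plate name, i7 barcode id range, i5 barcode id` (e.g. `"PlateA,1-96,7"`).
#' The i7 range may be a single id (`"5"`) or an inclusive range (`"1-12"`).
#'
#' @param lines Character vector of specification lines (blank lines and
#'   lines starting with `#` are ignored), or a file path via `file`.
#' @param file Optional path to a plain-text plate list.
#' @return data.frame with columns `plate_name`, `i7_from`, `i7_to`, `i5_id`.
#' @export
parse_plate_lines <- function(lines = NULL, file = NULL) {
  if (!is.null(file)) lines <- readLines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("no plate lines supplied")
  out <- lapply(seq_along(lines), function(i) {
    parts <- trimws(strsplit(lines[[i]], ",")[[1]])
    if (length(parts) != 3) {
      stop("plate line ", i, " must have 3 comma-separated fields: ", lines[[i]])
    }
    rng <- strsplit(parts[2], "-")[[1]]
    from <- suppressWarnings(as.integer(rng[1]))
    to <- if (length(rng) > 1) suppressWarnings(as.integer(rng[2])) else from
    if (is.na(from) || is.na(to)) stop("plate line ", i, ": bad i7 range '", parts[2], "'")
    i5 <- suppressWarnings(as.integer(parts[3]))
    if (is.na(i5)) stop("plate line ", i, ": bad i5 id '", parts[3], "'")
    data.frame(plate_name = parts[1], i7_from = from, i7_to = to, i5_id = i5,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# map i7 index 1..96 to well "A01".."H12", row-major across the plate
i7_to_well <- function(i) WELLS_96[i]

#' Expand one plate line into Sample Sheet data rows
#'
#' Each i7 id in the plate's range becomes one row; i7 ids act as well ids in
#' row-major plate order (i7-01 -> A01, ..., i7-12 -> A12, i7-13 -> B01, ...,
#' i7-96 -> H12) and the plate's single i5 id is shared by every row.  The
#' sample id is `<plate name>-<well>`.
#'
#' @param line One-row data.frame as produced by [parse_plate_lines()] (or a
#'   list with fields `plate_name`, `i7_from`, `i7_to`, `i5_id`).
#' @param lib A `barcode_library`.
#' @return data.frame of Sample Sheet data rows.
#' @export
expand_plate_line <- function(line, lib) {
  validate_barcode_library(lib)
  if (grepl(",", line$plate_name)) stop("plate name may not contain commas")
  if (line$i7_from > line$i7_to) stop("empty or reversed i7 range")
  if (line$i7_from < 1 || line$i7_to > 96) stop("i7 range outside 1..96")
  if (line$i5_id < 1 || line$i5_id > 96) stop("i5 id outside 1..96")
  i7_ids <- sprintf("i7-%02d", line$i7_from:line$i7_to)
  i5_id <- sprintf("i5-%02d", line$i5_id)
  i7_seq <- lib$barcode[match(i7_ids, lib$id)]
  i5_seq <- lib$barcode[match(i5_id, lib$id)]
  if (anyNA(i7_seq) || is.na(i5_seq)) stop("unknown barcode id for plate ", line$plate_name)
  wells <- i7_to_well(line$i7_from:line$i7_to)
  data.frame(
    sample_id = paste0(line$plate_name, "-", wells),
    plate_name = line$plate_name,
    well = wells,
    i7_id = i7_ids,
    i7_seq = i7_seq,
    i5_id = i5_id,
    i5_seq = i5_seq,
    stringsAsFactors = FALSE
  )
}

#' Build a Sample Sheet from plate lines
#'
#' Expands up to 96 plate specification lines into a full Sample Sheet
#' document with `[Header]`, `[Reads]` and `[Data]` sections.  Workflow "A"
#' writes i5 barcodes as entered; workflow "B" writes the reverse complement
#' of each i5 barcode, mirroring the two Illumina index-2 chemistry
#' conventions.
#'
#' @param workflow `"A"` or `"B"`.
#' @param investigator,project `[Header]` values (no commas).
#' @param reads Integer vector of cycle counts; one entry = single-end, two =
#'   paired-end.
#' @param lines data.frame of plate lines ([parse_plate_lines()]).
#' @param lib A `barcode_library`.
#' @return A `sample_sheet` object: list with `workflow`, `header`, `reads`
#'   and `data` (the expanded rows, with `i5_seq` as written for the chosen
#'   workflow).
#' @export
build_sample_sheet <- function(workflow = c("A", "B"), investigator, project,
                               reads, lines, lib) {
  workflow <- match.arg(workflow)
  if (nrow(lines) < 1) stop("at least one plate line is required")
  if (nrow(lines) > 96) stop("at most 96 plate lines are supported")
  if (anyDuplicated(lines$plate_name)) stop("duplicate plate names")
  if (any(grepl(",", c(investigator, project)))) stop("header values may not contain commas")
  if (!length(reads) %in% c(1L, 2L) || any(reads < 1)) {
    stop("reads must be one or two positive cycle counts")
  }
  rows <- do.call(rbind, lapply(seq_len(nrow(lines)), function(i) {
    expand_plate_line(lines[i, ], lib)
  }))
  if (anyDuplicated(rows[, c("i7_seq", "i5_seq")])) {
    stop("duplicate (i7, i5) barcode pair across rows")
  }
  if (anyDuplicated(rows$sample_id)) stop("duplicate sample ids")
  if (workflow == "B") rows$i5_seq <- reverse_complement(rows$i5_seq)
  doc <- list(
    workflow = workflow,
    header = list(investigator_name = investigator, project_name = project),
    reads = as.integer(reads),
    data = rows
  )
  class(doc) <- "sample_sheet"
  doc
}

SHEET_DATA_COLS <- c("sample_id", "plate_name", "well", "i7_id", "i7_seq",
                     "i5_id", "i5_seq")

#' Serialize / parse / write a Sample Sheet
#'
#' The sheet is a three-section CSV (`[Header]`, `[Reads]`, `[Data]`);
#' serialize -> parse -> serialize is byte-identical.
#'
#' @param doc A `sample_sheet`.
#' @return `format_sample_sheet` returns a character vector of lines;
#'   `write_sample_sheet` writes them and returns the path invisibly;
#'   `parse_sample_sheet` returns a `sample_sheet`.
#' @export
format_sample_sheet <- function(doc) {
  stopifnot(inherits(doc, "sample_sheet"))
  c("[Header]",
    paste0("Workflow,", doc$workflow),
    paste0("InvestigatorName,", doc$header$investigator_name),
    paste0("ProjectName,", doc$header$project_name),
    "[Reads]",
    as.character(doc$reads),
    "[Data]",
    paste(SHEET_DATA_COLS, collapse = ","),
    do.call(paste, c(unname(as.list(doc$data[, SHEET_DATA_COLS])), sep = ",")))
}

#' @rdname format_sample_sheet
#' @param path Output CSV path.
#' @export
write_sample_sheet <- function(doc, path) {
  writeLines(format_sample_sheet(doc), path)
  invisible(path)
}

#' @rdname format_sample_sheet
#' @param text Character vector of sheet lines, or a file path via `file`.
#' @param file Optional path to read.
#' @export
parse_sample_sheet <- function(text = NULL, file = NULL) {
  if (!is.null(file)) text <- readLines(file)
  secs <- which(grepl("^\\[", text))
  need <- c("[Header]", "[Reads]", "[Data]")
  if (!all(need %in% text[secs])) {
    stop("missing section(s): ", paste(setdiff(need, text[secs]), collapse = ", "))
  }
  sec_of <- function(name) {
    at <- which(text == name)
    nxt <- c(secs[secs > at], length(text) + 1L)[1]
    if (at + 1 > nxt - 1) return(integer(0))
    (at + 1):(nxt - 1)
  }
  hdr <- text[sec_of("[Header]")]
  kv <- strsplit(hdr, ",")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ","), "")
  get_hdr <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop("[Header] is missing '", k, "'")
    vals[i]
  }
  workflow <- get_hdr("Workflow")
  if (!workflow %in% c("A", "B")) stop("Workflow must be A or B")
  reads_lines <- sec_of("[Reads]")
  reads <- suppressWarnings(as.integer(text[reads_lines]))
  if (length(reads) < 1 || anyNA(reads)) {
    stop("malformed [Reads] section near line ", reads_lines[1])
  }
  data_lines <- sec_of("[Data]")
  if (length(data_lines) < 2) stop("[Data] section has no rows")
  header_row <- strsplit(text[data_lines[1]], ",")[[1]]
  if (!identical(header_row, SHEET_DATA_COLS)) {
    stop("malformed [Data] header at line ", data_lines[1])
  }
  body <- data_lines[-1]
  parts <- strsplit(text[body], ",")
  bad <- which(lengths(parts) != length(SHEET_DATA_COLS))
  if (length(bad)) stop("malformed [Data] row at line ", body[bad[1]])
  rows <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(rows) <- SHEET_DATA_COLS
  if (anyDuplicated(rows$sample_id)) {
    stop("duplicated sample_id in [Data] (line ",
         body[which(duplicated(rows$sample_id))[1]], ")")
  }
  doc <- list(
    workflow = workflow,
    header = list(investigator_name = get_hdr("InvestigatorName"),
                  project_name = get_hdr("ProjectName")),
    reads = reads,
    data = rows
  )
  class(doc) <- "sample_sheet"
  doc
}

#' Validate a Sample Sheet
#'
#' Content checks never throw; each check is reported with a pass/fail flag
#' and the offending rows.  Checks: (i7, i5) barcode-pair uniqueness, well
#' legality (A01..H12), sample-id format (`<plate>-<well>`), and row count
#' <= 9216.
#'
#' @param doc A `sample_sheet`.
#' @return data.frame with columns `check`, `pass`, `n_offending`,
#'   `offending` (comma-separated row numbers, possibly truncated).
#' @export
validate_sample_sheet <- function(doc) {
  stopifnot(inherits(doc, "sample_sheet"))
  d <- doc$data
  res <- list()
  add <- function(check, offending) {
    off <- sort(unique(offending))
    res[[length(res) + 1L]] <<- data.frame(
      check = check, pass = length(off) == 0, n_offending = length(off),
      offending = paste(utils::head(off, 20), collapse = ","),
      stringsAsFactors = FALSE)
  }
  pair <- paste(d$i7_seq, d$i5_seq)
  add("barcode_pair_unique", which(pair %in% pair[duplicated(pair)]))
  add("well_legal", which(!d$well %in% WELLS_96))
  add("sample_id_format", which(d$sample_id != paste0(d$plate_name, "-", d$well)))
  add("row_count_le_9216", if (nrow(d) > 9216) seq_len(nrow(d)) else integer(0))
  do.call(rbind, res)
}

#' @export
print.sample_sheet <- function(x, ...) {
  cat("Sample Sheet (workflow ", x$workflow, "): ", nrow(x$data),
      " data rows, ", length(unique(x$data$plate_name)), " plate(s), reads ",
      paste(x$reads, collapse = "x"), "\n", sep = "")
  invisible(x)
}
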