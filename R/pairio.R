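# Input/output layer: the input-list file, paired FASTQ loading, and the
# three output modes. All readers and writers are byte-faithful: headers,
# sequences and qualities pass through unmodified.

#' Parse an input-list file of paired FASTQ paths
#'
#' The input-list file is a plain-text file naming FASTQ files, one path
#' per line; two adjacent lines name the two mate files of one library,
#' with reads in the same order. Blank lines and surrounding whitespace
#' are ignored.
#'
#' @param path Path to the input-list file.
#' @return An object of class `input_list`: a list with `file_paths`
#'   (character vector, in file order) and `pairs_of_files` (list of
#'   length-2 character vectors taking adjacent entries).
#' @examples
#' lst <- tempfile()
#' writeLines(c("a_1.fq", "a_2.fq"), lst)
#' parse_input_list(lst)$pairs_of_files
#' @seealso [load_pairs()]
#' @export
parse_input_list <- function(path) {
  if (!file.exists(path)) {
    stop("input list not found: ", path)
  }
  lines <- trimws(readLines(path, warn = FALSE))
  files <- lines[nzchar(lines)]
  if (length(files) == 0L) {
    stop("empty input list: ", path)
  }
  if (length(files) %% 2L != 0L) {
    stop("unpaired file list: ", length(files), " file(s) listed in ",
         path, "; mate files must come in adjacent pairs")
  }
  structure(
    list(
      file_paths = files,
      pairs_of_files = unname(split(
        files, rep(seq_len(length(files) / 2L), each = 2L)))
    ),
    class = "input_list"
  )
}

# Strict 4-line-record FASTQ reader. Multi-line (wrapped) FASTQ is
# rejected; '+' line content is ignored; gzip input is detected by the
# .gz suffix. Returns parallel character vectors.
read_fastq_file <- function(path) {
  if (!file.exists(path)) {
    stop("FASTQ file not found: ", path)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  if (n == 0L) {
    stop("empty FASTQ file: ", path)
  }
  if (n %% 4L != 0L) {
    stop("malformed FASTQ in ", path, ": ", n,
         " lines is not a multiple of 4 (wrapped records are not supported)")
  }
  first <- seq.int(1L, n, by = 4L)
  hdr <- lines[first]
  sq <- lines[first + 1L]
  plus <- lines[first + 2L]
  qual <- lines[first + 3L]

  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1L], " in ", path,
         ": header line does not start with '@'")
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1L], " in ", path,
         ": missing '+' separator line")
  }
  bad <- which(!nzchar(sq))
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1L], " in ", path,
         ": empty sequence")
  }
  bad <- grep("[[:space:]]", sq)
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1L], " in ", path,
         ": whitespace inside sequence")
  }
  bad <- which(nchar(sq, type = "bytes") != nchar(qual, type = "bytes"))
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1L], " in ", path,
         ": sequence and quality lengths differ")
  }
  list(header = substring(hdr, 2L), sequence = sq, quality = qual)
}

#' Construct an in-memory store of read pairs
#'
#' A `pair_store` holds one row per read pair: header, sequence and
#' quality for each mate, plus the pair's 0-based input ordinal. It is a
#' plain `data.frame` subclass, so the usual subsetting and inspection
#' tools apply; ordinals index pairs for O(1) retrieval and serve as the
#' deterministic tie-break during sorting.
#'
#' @param seq1,seq2 Character vectors of mate-1 / mate-2 sequences.
#' @param header1,header2 Read headers (without the leading `@`).
#' @param qual1,qual2 Quality strings, same length as the sequences.
#'   Default is a constant maximum-quality placeholder.
#' @param ordinal Integer vector of unique 0-based input positions.
#' @return A `pair_store` data frame.
#' @examples
#' pair_store(c("ACGT", "ACG"), c("TTTT", "TTT"))
#' @export
pair_store <- function(seq1, seq2,
                       header1 = sprintf("pair%d/1", seq_along(seq1)),
                       header2 = sprintf("pair%d/2", seq_along(seq2)),
                       qual1 = strrep("I", nchar(seq1)),
                       qual2 = strrep("I", nchar(seq2)),
                       ordinal = seq_along(seq1) - 1L) {
  df <- data.frame(
    header1 = as.character(header1), seq1 = as.character(seq1),
    qual1 = as.character(qual1),
    header2 = as.character(header2), seq2 = as.character(seq2),
    qual2 = as.character(qual2),
    ordinal = as.integer(ordinal),
    stringsAsFactors = FALSE
  )
  validate_pair_store(structure(df, class = c("pair_store", "data.frame")))
}

validate_pair_store <- function(store) {
  stopifnot(is.data.frame(store))
  needed <- c("header1", "seq1", "qual1", "header2", "seq2", "qual2",
              "ordinal")
  missing <- setdiff(needed, names(store))
  if (length(missing)) {
    stop("pair_store is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(store$ordinal)) {
    stop("pair_store ordinals must be unique")
  }
  if (any(!nzchar(store$seq1)) || any(!nzchar(store$seq2))) {
    stop("pair_store sequences must be non-empty")
  }
  bad <- nzchar(store$qual1) &
    nchar(store$qual1, type = "bytes") != nchar(store$seq1, type = "bytes")
  bad2 <- nzchar(store$qual2) &
    nchar(store$qual2, type = "bytes") != nchar(store$seq2, type = "bytes")
  if (any(bad) || any(bad2)) {
    stop("pair_store quality strings must match sequence lengths")
  }
  store
}

#' @export
print.pair_store <- function(x, ...) {
  cat("pair_store with", nrow(x), "read pair(s)\n")
  NextMethod()
}

#' Load read pairs from the FASTQ files named in an input list
#'
#' Reads every file pair of the input list and assembles one `pair_store`:
#' record i of the first file and record i of the second file of each pair
#' form one read pair, file pairs are concatenated in list order, and
#' ordinals 0..n-1 are assigned in read order. Headers are stored without
#' the leading `@`. Files ending in `.gz` are decompressed on the fly.
#'
#' @param input_list An `input_list` from [parse_input_list()], or a path
#'   to an input-list file.
#' @param normalize_case If `TRUE`, sequences are uppercased on load.
#'   Off by default: comparison is byte-wise and case is preserved.
#' @return A `pair_store` with one row per read pair.
#' @export
load_pairs <- function(input_list, normalize_case = FALSE) {
  if (is.character(input_list)) {
    input_list <- parse_input_list(input_list)
  }
  stopifnot(inherits(input_list, "input_list"))
  parts <- lapply(input_list$pairs_of_files, function(fp) {
    a <- read_fastq_file(fp[1L])
    b <- read_fastq_file(fp[2L])
    if (length(a$sequence) != length(b$sequence)) {
      stop("mate file length mismatch: ", fp[1L], " has ",
           length(a$sequence), " records but ", fp[2L], " has ",
           length(b$sequence))
    }
    data.frame(
      header1 = a$header, seq1 = a$sequence, qual1 = a$quality,
      header2 = b$header, seq2 = b$sequence, qual2 = b$quality,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, parts)
  rownames(df) <- NULL
  if (normalize_case) {
    df$seq1 <- toupper(df$seq1)
    df$seq2 <- toupper(df$seq2)
  }
  df$ordinal <- seq_len(nrow(df)) - 1L
  validate_pair_store(structure(df, class = c("pair_store", "data.frame")))
}

write_fastq <- function(header, sequence, quality, path) {
  if (length(sequence) == 0L) {
    writeLines(character(0), path)
    return(invisible(NULL))
  }
  writeLines(as.vector(rbind(paste0("@", header), sequence, "+", quality)),
             path)
}

write_fasta <- function(header, sequence, path) {
  writeLines(as.vector(rbind(paste0(">", header), sequence)), path)
}

#' Write retained read pairs to disk
#'
#' Three output modes are supported: `fastq-pair` (two FASTQ files, record
#' i of each file are mates), `fasta-pair` (likewise in FASTA), and
#' `fasta-interleaved` (one FASTA file in which records 2i-1 and 2i are
#' the two mates of pair i). Sequences and qualities are emitted exactly
#' as read; FASTA sequences are written on a single unwrapped line.
#'
#' @param result A `dedup_result` (its retained pairs are written) or a
#'   `pair_store`.
#' @param out1 Path of the first (or only) output file.
#' @param out2 Path of the second output file; required for the two-file
#'   modes and must be absent for `fasta-interleaved`.
#' @param mode Output mode, one of `"fastq-pair"`, `"fasta-pair"`,
#'   `"fasta-interleaved"`.
#' @return Invisibly, the number of pairs written.
#' @export
write_output <- function(result, out1, out2 = NULL,
                         mode = c("fastq-pair", "fasta-pair",
                                  "fasta-interleaved")) {
  mode <- match.arg(mode)
  store <- if (inherits(result, "dedup_result")) result$retained else result
  store <- validate_pair_store(store)
  n <- nrow(store)

  if (mode == "fasta-interleaved") {
    if (!is.null(out2)) {
      stop("fasta-interleaved mode writes a single file; out2 must be absent")
    }
    writeLines(as.vector(rbind(
      paste0(">", store$header1), store$seq1,
      paste0(">", store$header2), store$seq2
    )), out1)
    return(invisible(n))
  }

  if (is.null(out2)) {
    stop("mode '", mode, "' writes two files; out2 is required")
  }
  if (mode == "fastq-pair") {
    if (any(!nzchar(store$qual1)) || any(!nzchar(store$qual2))) {
      stop("quality unavailable for FASTQ output; use a FASTA mode")
    }
    write_fastq(store$header1, store$seq1, store$qual1, out1)
    write_fastq(store$header2, store$seq2, store$qual2, out2)
  } else {
    write_fasta(store$header1, store$seq1, out1)
    write_fasta(store$header2, store$seq2, out2)
  }
  invisible(n)
}
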