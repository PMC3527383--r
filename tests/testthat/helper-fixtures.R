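# Fixture builders. FASTQ files written here are assembled line by line,
# independently of the package writers.

raw_fastq_lines <- function(header, sequence, quality) {
  unlist(Map(function(h, s, q) c(paste0("@", h), s, "+", q),
             header, sequence, quality), use.names = FALSE)
}

write_raw_fastq <- function(path, header, sequence,
                            quality = strrep("I", nchar(sequence))) {
  writeLines(raw_fastq_lines(header, sequence, quality), path)
}

# Write a paired library plus its input-list file; returns the list path.
make_library_files <- function(seq1, seq2,
                               dir = withr::local_tempdir(
                                 .local_envir = parent.frame()),
                               gz = FALSE) {
  ext <- if (gz) ".fq.gz" else ".fq"
  f1 <- file.path(dir, paste0("lib_1", ext))
  f2 <- file.path(dir, paste0("lib_2", ext))
  h <- sprintf("read%d", seq_along(seq1))
  con1 <- if (gz) gzfile(f1, "wt") else file(f1, "wt")
  writeLines(raw_fastq_lines(paste0(h, "/1"), seq1, strrep("I", nchar(seq1))),
             con1)
  close(con1)
  con2 <- if (gz) gzfile(f2, "wt") else file(f2, "wt")
  writeLines(raw_fastq_lines(paste0(h, "/2"), seq2, strrep("I", nchar(seq2))),
             con2)
  close(con2)
  lst <- file.path(dir, "input_list.txt")
  writeLines(c(f1, f2), lst)
  lst
}

# Random pairs with rich duplicate/prefix structure: templates drawn from
# a small pool, emitted with random 3'-truncations of each mate.
rand_prefix_pairs <- function(n, n_templates, len = 10L, max_trunc = 3L) {
  rand_seq <- function(k, l) {
    vapply(seq_len(k),
           function(i) paste(sample(c("A", "C", "G", "T"), l, TRUE),
                             collapse = ""),
           character(1))
  }
  t1 <- rand_seq(n_templates, len)
  t2 <- rand_seq(n_templates, len)
  cl <- sample.int(n_templates, n, replace = TRUE)
  d1 <- sample.int(max_trunc + 1L, n, replace = TRUE) - 1L
  d2 <- sample.int(max_trunc + 1L, n, replace = TRUE) - 1L
  list(seq1 = substr(t1[cl], 1L, len - d1),
       seq2 = substr(t2[cl], 1L, len - d2))
}
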