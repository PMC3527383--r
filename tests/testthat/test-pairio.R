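test_that("input-list parsing pairs adjacent lines and rejects bad lists", {
  d <- withr::local_tempdir()
  lst <- file.path(d, "list.txt")

  writeLines(c("a_1.fq", "a_2.fq"), lst)
  il <- parse_input_list(lst)
  expect_length(il$pairs_of_files, 1L)
  expect_equal(il$pairs_of_files[[1]], c("a_1.fq", "a_2.fq"))

  # blank lines and surrounding whitespace ignored; order preserved
  writeLines(c("  a_1.fq ", "", "a_2.fq", "b_1.fq", "b_2.fq", " "), lst)
  il <- parse_input_list(lst)
  expect_length(il$pairs_of_files, 2L)
  expect_equal(il$pairs_of_files[[2]], c("b_1.fq", "b_2.fq"))

  writeLines("a_1.fq", lst)
  expect_error(parse_input_list(lst), "unpaired file list")
  writeLines(character(0), lst)
  expect_error(parse_input_list(lst), "empty input list")
})

test_that("loading assembles pairs across file pairs with 0-based ordinals", {
  withr::local_seed(11)
  d <- withr::local_tempdir()
  a1 <- c("ACGT", "TTTT", "GGCA")
  a2 <- c("CCCC", "AAAA", "TGCA")
  lst <- make_library_files(a1, a2, dir = d)
  st <- load_pairs(parse_input_list(lst))
  expect_s3_class(st, "pair_store")
  expect_equal(nrow(st), 3L)
  expect_equal(st$ordinal, 0:2)
  expect_equal(st$seq1, a1)
  expect_equal(st$seq2, a2)
  expect_false(any(startsWith(st$header1, "@")))

  # two file pairs of sizes 2 and 3 concatenate in list order
  d2 <- withr::local_tempdir()
  lst_a <- make_library_files(c("AAAA", "CCCC"), c("GGGG", "TTTT"), dir = d2)
  b1 <- file.path(d2, "b_1.fq")
  b2 <- file.path(d2, "b_2.fq")
  write_raw_fastq(b1, paste0("b", 1:3, "/1"), c("ACAC", "GTGT", "CACA"))
  write_raw_fastq(b2, paste0("b", 1:3, "/2"), c("TGTG", "ACCA", "GTTG"))
  lst_all <- file.path(d2, "all.txt")
  writeLines(c(readLines(lst_a), b1, b2), lst_all)
  st <- load_pairs(lst_all)
  expect_equal(nrow(st), 5L)
  expect_equal(st$ordinal, 0:4)
  expect_equal(st$seq1[3:5], c("ACAC", "GTGT", "CACA"))
})

test_that("unequal mate files and malformed records are hard errors", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "x_1.fq")
  f2 <- file.path(d, "x_2.fq")
  lst <- file.path(d, "list.txt")
  writeLines(c(f1, f2), lst)

  write_raw_fastq(f1, c("r1/1", "r2/1", "r3/1"), c("AAAA", "CCCC", "GGGG"))
  write_raw_fastq(f2, c("r1/2", "r2/2"), c("TTTT", "ACGT"))
  expect_error(load_pairs(lst), "mate file length mismatch")

  write_raw_fastq(f2, c("r1/2", "r2/2", "r3/2"), c("TTTT", "ACGT", "CCAA"))
  expect_silent(st <- load_pairs(lst))

  # missing '+' line
  writeLines(c("@r1/1", "ACGT", "IIII"), f1)
  expect_error(load_pairs(lst), "not a multiple of 4")
  writeLines(c("@r1/1", "ACGT", "x", "IIII"), f1)
  expect_error(load_pairs(lst), "missing '\\+' separator")
  # sequence/quality length mismatch, with record index
  writeLines(c("@r1/1", "ACGT", "+", "IIII",
               "@r2/1", "ACGT", "+", "III"), f1)
  expect_error(load_pairs(lst), "record 2 .*quality lengths differ")
  # empty sequence rejected
  writeLines(c("@r1/1", "", "+", ""), f1)
  expect_error(load_pairs(lst), "empty sequence")
})

test_that("gzip input is read transparently and case handling is opt-in", {
  withr::local_seed(3)
  s1 <- c("acgt", "ACGT")
  s2 <- c("TTTT", "tttt")
  lst <- make_library_files(s1, s2, gz = TRUE)
  st <- load_pairs(lst)
  expect_equal(st$seq1, s1)  # bytes preserved by default
  st_up <- load_pairs(lst, normalize_case = TRUE)
  expect_equal(st_up$seq1, c("ACGT", "ACGT"))
  expect_equal(st_up$qual1, st$qual1)
})

test_that("FASTQ writing agrees with an independent parser", {
  withr::local_seed(42)
  p <- rand_prefix_pairs(30, 10)
  st <- pair_store(p$seq1, p$seq2)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "out_1.fq")
  f2 <- file.path(d, "out_2.fq")
  write_output(st, f1, f2, mode = "fastq-pair")
  bs <- Biostrings::readDNAStringSet(f1, format = "fastq")
  expect_equal(as.character(unname(bs)), st$seq1)
  expect_equal(names(bs), st$header1)
  bs2 <- Biostrings::readDNAStringSet(f2, format = "fastq")
  expect_equal(as.character(unname(bs2)), st$seq2)
})

test_that("all output modes keep mates synchronized and bytes intact", {
  withr::local_seed(7)
  p <- rand_prefix_pairs(20, 6)
  st <- pair_store(p$seq1, p$seq2)
  d <- withr::local_tempdir()

  # fastq-pair: round-trip is byte-faithful
  f1 <- file.path(d, "u_1.fq")
  f2 <- file.path(d, "u_2.fq")
  n <- write_output(st, f1, f2, mode = "fastq-pair")
  expect_equal(n, nrow(st))
  lst <- file.path(d, "roundtrip.txt")
  writeLines(c(f1, f2), lst)
  back <- load_pairs(lst)
  expect_equal(back$header1, st$header1)
  expect_equal(back$seq1, st$seq1)
  expect_equal(back$qual1, st$qual1)
  expect_equal(back$header2, st$header2)
  expect_equal(back$seq2, st$seq2)
  expect_equal(back$qual2, st$qual2)

  # one retained pair in fastq-pair mode -> exactly 4 lines per file
  one <- st[1, , drop = FALSE]
  write_output(one, f1, f2, mode = "fastq-pair")
  expect_length(readLines(f1), 4L)
  expect_length(readLines(f2), 4L)

  # fasta-pair: record i of each file are mates
  fa1 <- file.path(d, "u_1.fa")
  fa2 <- file.path(d, "u_2.fa")
  write_output(st, fa1, fa2, mode = "fasta-pair")
  l1 <- readLines(fa1)
  l2 <- readLines(fa2)
  expect_equal(l1[seq(2, length(l1), by = 2)], st$seq1)
  expect_equal(l2[seq(2, length(l2), by = 2)], st$seq2)
  expect_equal(sub("^>", "", l1[seq(1, length(l1), by = 2)]), st$header1)

  # fasta-interleaved: records 2i-1 and 2i are mates of pair i
  fa <- file.path(d, "u.fa")
  write_output(st[1:2, ], fa, mode = "fasta-interleaved")
  l <- readLines(fa)
  expect_length(l, 8L)
  expect_equal(l[c(2, 4, 6, 8)],
               c(st$seq1[1], st$seq2[1], st$seq1[2], st$seq2[2]))
})

test_that("writer preconditions are enforced", {
  st <- pair_store("ACGT", "TTTT")
  d <- withr::local_tempdir()
  expect_error(write_output(st, file.path(d, "a.fa"), file.path(d, "b.fa"),
                            mode = "fasta-interleaved"),
               "out2 must be absent")
  expect_error(write_output(st, file.path(d, "a.fq"), mode = "fastq-pair"),
               "out2 is required")
  st$qual1 <- ""
  st$qual2 <- ""
  expect_error(write_output(st, file.path(d, "a.fq"), file.path(d, "b.fq"),
                            mode = "fastq-pair"),
               "quality unavailable for FASTQ output")
})
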