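test_that("diff_aligned recovers the fixture replacements from sequences", {
  p <- sage1_aligned_pair()
  rl <- diff_aligned(p$seq_a, p$seq_b, labels = c("Pan", "Homo"))
  expect_s3_class(rl, "replacement_list")
  expect_identical(nrow(rl), 15L)
  expect_identical(unlist(rl[1, ], use.names = FALSE), c("82", "C", "R"))
  expect_identical(rl$site, sage1_replacements()$site)
  f <- attr(rl, "filter")
  expect_identical(sum(f), 805L)  # matches+mismatches+gap+nonstandard
})

test_that("diff_aligned filters gaps and non-standard codes with counts", {
  rl <- diff_aligned("AC-DXWK", "ACWDAAR")
  # col3 gap, col5 nonstandard X, col6 W->A replacement, col7 K->R replacement
  expect_identical(rl$site, c(6L, 7L))
  expect_identical(rl$from, c("W", "K"))
  f <- attr(rl, "filter")
  expect_identical(f[["gap"]], 1L)
  expect_identical(f[["nonstandard"]], 1L)
  expect_identical(sum(f), 7L)
  expect_identical(nrow(diff_aligned("ACDK", "ACDK")), 0L)
  expect_error(diff_aligned("ACD", "AC"), "length")
})

test_that("diff_aligned is swap-symmetric and bounded by alignment length", {
  set.seed(42)
  aas <- dirsel:::AAINDEX_ORDER
  for (i in 1:20) {
    n <- sample(10:120, 1)
    a <- sample(c(aas, "-"), n, replace = TRUE, prob = c(rep(1, 20), 2))
    b <- sample(c(aas, "-"), n, replace = TRUE, prob = c(rep(1, 20), 2))
    ab <- diff_aligned(paste(a, collapse = ""), paste(b, collapse = ""))
    ba <- diff_aligned(paste(b, collapse = ""), paste(a, collapse = ""))
    expect_identical(ab$site, ba$site)
    expect_identical(ab$from, ba$to)
    expect_identical(ab$to, ba$from)
    expect_lte(nrow(ab), n)
    expect_identical(sum(attr(ab, "filter")), n)
  }
})

test_that("replacement_list enforces its invariants", {
  expect_error(replacement_list(c(5, 5), c("A", "C"), c("V", "G"), 10),
               "duplicated site")
  expect_error(replacement_list(3, "A", "A", 10), "identical residues")
  expect_error(replacement_list(3, "A", "X", 10), "non-standard")
  expect_error(replacement_list(11, "A", "V", 10), "beyond sequence_length")
  expect_error(replacement_list(0, "A", "V", 10), ">= 1")
  # unsorted input is sorted by site
  rl <- replacement_list(c(9, 2), c("A", "C"), c("V", "G"), 10)
  expect_identical(rl$site, c(2L, 9L))
})

test_that("translation handles codes, trailing bases, ambiguity, stops", {
  expect_identical(translate_cds("ATG"), "M")
  expect_identical(translate_cds("atgaaa"), "MK")
  # invertebrate mitochondrial code: AGA = Ser, TGA = Trp
  expect_identical(translate_cds("AGATGA", 5), "SW")
  expect_warning(p <- translate_cds(strrep("ATG", 215) %+% "A"), "trailing")
  expect_identical(nchar(p), 215L)
  expect_warning(translate_cds("ATGNNNAAA"), "ambiguous")
  expect_warning(translate_cds("TAAATG"), "internal stop")
  expect_error(translate_cds("ATO"), "non-IUPAC")
  expect_error(translate_cds("AT"), "shorter")
  # a 645-nt coding fragment translates to 215 residues
  set.seed(7)
  cds <- paste(sample(c("A", "C", "G", "T"), 645, replace = TRUE),
               collapse = "")
  expect_identical(nchar(suppressWarnings(translate_cds(cds, 5))), 215L)
})

test_that("replacement tables round-trip and validate", {
  path <- tempfile(fileext = ".tsv")
  write_replacement_table(sage1_replacements(), path)
  back <- read_replacement_table(path)
  expect_identical(nrow(back), 15L)
  expect_identical(strip_df(back), strip_df(sage1_replacements()))
  # canonical round-trip is byte-identical
  path2 <- tempfile(fileext = ".tsv")
  write_replacement_table(back, path2)
  expect_identical(readLines(path2), readLines(path))

  writeLines("site\tfrom\tto", path)
  expect_identical(nrow(read_replacement_table(path)), 0L)
  writeLines(c("site\tfrom\tto", "82\tC\tR", "82\tV\tA"), path)
  expect_error(read_replacement_table(path), "duplicated site")
  writeLines(c("site\tfrom\tto", "82\tC\tC"), path)
  expect_error(read_replacement_table(path), "identical residues")
  writeLines(c("site\tfrom\tto", "82\tC\tX"), path)
  expect_error(read_replacement_table(path), "non-standard")
  writeLines(c("site\tresidue", "82\tC"), path)
  expect_error(read_replacement_table(path), "lacks column")
})

test_that("BLAST tabular pairs parse and map to query coordinates", {
  path <- write_blast_fixture(c(
    blast_row("q1", "s1", 10, 15, "CVKDAQ", "RVKDAQ"),
    blast_row("q1", "s2", 3, 8, "AC-DEFG", "ACWD-FG")))
  pairs <- parse_blast_pairs(path)
  expect_length(pairs, 2)
  rls <- blast_replacements(pairs)
  expect_identical(rls[[1]]$site, 10L)        # qstart offset applied
  expect_identical(rls[[1]]$from, "C")
  expect_identical(attr(rls[[1]], "labels"), c("q1", "s1"))
  # gapped HSP: gap columns excluded by the downstream diff filter
  expect_identical(attr(rls[[2]], "filter")[["gap"]], 2L)

  expect_length(parse_blast_pairs(write_blast_fixture(character())), 0)
  expect_error(parse_blast_pairs(path, columns = c("qseqid", "sseqid")),
               "qstart.*qseq.*sseq|required")
  writeLines("q1\ts1\tonly\tfour", path)
  expect_error(parse_blast_pairs(path), "field")
})

test_that("fetch_or_load_fasta resolves files, caches, and ambiguity", {
  path <- write_fasta(list(rec1 = "MKTV"))
  rec <- fetch_or_load_fasta(path)
  expect_identical(rec$id, "rec1")
  expect_identical(rec$seq, "MKTV")

  multi <- write_fasta(list(a = "MK", b = "MV"))
  expect_error(fetch_or_load_fasta(multi), "a, b")
  expect_identical(fetch_or_load_fasta(multi, record = "b")$seq, "MV")

  cache <- tempfile(); dir.create(cache)
  write_fasta(list(`ACC123 test` = "MKV"),
              file.path(cache, "ACC123.fasta"))
  expect_identical(fetch_or_load_fasta("ACC123", cache_dir = cache)$seq,
                   "MKV")
  expect_error(fetch_or_load_fasta("NOPE999", cache_dir = cache),
               "allow_fetch")
})
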