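test_that("whole-sequence partition pools every replacement", {
  rl <- sage1_replacements()
  ps <- partition_whole(rl)
  expect_length(ps, 1)
  expect_identical(ps[[1]]$partition$start, 1L)
  expect_identical(ps[[1]]$partition$end, 805L)
  expect_identical(nrow(ps[[1]]$replacements), 15L)

  empty <- replacement_list(integer(), character(), character(), 100)
  expect_identical(nrow(partition_whole(empty)[[1]]$replacements), 0L)

  # definitional equivalence with a single full-span region
  rg <- partition_regions(rl, data.frame(name = "all", start = 1, end = 805))
  expect_identical(as.data.frame(rg[[1]]$replacements),
                   as.data.frame(ps[[1]]$replacements))
})

test_that("sliding windows enumerate starts and truncate the last window", {
  rl <- replacement_list(c(10, 82, 210), c("C", "C", "C"),
                         c("R", "R", "R"), 215)
  ws <- partition_windows(rl, 50, 50)
  expect_length(ws, 5)
  starts <- vapply(unclass(ws), function(e) e$partition$start, 0L)
  expect_identical(starts, c(1L, 51L, 101L, 151L, 201L))
  last <- ws[[5]]$partition
  expect_identical(c(last$start, last$end), c(201L, 215L))
  expect_true(last$truncated)

  # window == sequence length: one window equal to whole()
  w1 <- partition_windows(rl, 215, 10)
  expect_length(w1, 1)
  expect_identical(nrow(w1[[1]]$replacements), 3L)

  # replacement at site 82 with window 50 / step 25 -> windows [51,100], [76,125]
  w2 <- partition_windows(rl, 50, 25)
  hit <- vapply(unclass(w2), function(e) 82 %in% e$replacements$site, TRUE)
  names(hit) <- vapply(unclass(w2), function(e) e$partition$name, "")
  expect_identical(names(hit)[hit], c("[51-100]", "[76-125]"))

  expect_warning(big <- partition_windows(rl, 500, 50), "single whole-sequence")
  expect_length(big, 1)
  expect_error(partition_windows(rl, 0, 5), ">= 1")
  expect_error(partition_windows(rl, 10, 0), ">= 1")
})

test_that("window assignment matches a brute-force containment oracle", {
  set.seed(99)
  for (i in 1:100) {
    L <- sample(30:300, 1)
    window <- sample(1:L, 1)
    step <- sample(1:window, 1)  # step <= window: full coverage regime
    n <- sample(0:min(20, L), 1)
    rl <- sample_null_replacements(n, sequence_length = L)
    ws <- partition_windows(rl, window, step)
    assigned <- sum(vapply(unclass(ws), function(e) nrow(e$replacements), 0L))
    # oracle: enumerate window intervals directly (window >= L collapses
    # to the single whole-sequence window by contract)
    starts <- if (window >= L) 1L else seq.int(1L, L, by = step)
    oracle <- sum(vapply(rl$site, function(s)
      sum(starts <= s & pmin(starts + window - 1L, L) >= s), 0L))
    expect_identical(assigned, oracle)
    if (n > 0) {
      covered <- unique(unlist(lapply(unclass(ws),
                                      function(e) e$replacements$site)))
      expect_setequal(covered, rl$site)  # every replacement in >= 1 window
    }
  }
})

test_that("partitioning never alters a replacement record", {
  rl <- sage1_replacements()
  for (ps in list(partition_whole(rl), partition_windows(rl, 100, 25),
                  partition_regions(rl, data.frame(name = c("a", "b"),
                                                   start = c(1, 400),
                                                   end = c(500, 805))))) {
    for (e in unclass(ps)) {
      sub <- as.data.frame(e$replacements)
      orig <- as.data.frame(rl)[rl$site %in% sub$site, ]
      rownames(orig) <- NULL
      expect_identical(sub, orig)
    }
  }
})

test_that("regions overlap, clip, and validate", {
  rl <- sage1_replacements()
  rg <- partition_regions(rl, data.frame(name = c("input", "output"),
                                         start = c(1, 50), end = c(100, 200)))
  # overlapping regions both receive the shared replacement at site 82
  expect_true(all(vapply(unclass(rg),
                         function(e) 82 %in% e$replacements$site, TRUE)))

  expect_length(partition_regions(rl, data.frame(name = character(),
                                                 start = integer(),
                                                 end = integer())), 0)
  expect_warning(cl <- partition_regions(
    rl, data.frame(name = "far", start = 800, end = 900)), "clipped")
  expect_identical(cl[[1]]$partition$end, 805L)
  expect_error(partition_regions(rl, data.frame(name = "bad", start = 10,
                                                end = 5)),
               "start <= end")
})

test_that("region files and BED intervals convert to 1-based inclusive", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("name\tstart\tend", "input\t1\t215"), path)
  rg <- read_regions(path)
  expect_identical(rg$start, 1L)
  writeLines("name\tfrom\tto", path)
  expect_error(read_regions(path), "lacks column")

  bed <- tempfile(fileext = ".bed")
  writeLines(c("# comment", "prot\t0\t215\tinput", "prot\t215\t430"), bed)
  conv <- bed_to_regions(bed)
  expect_identical(conv$start, c(1L, 216L))
  expect_identical(conv$end, c(215L, 430L))
  expect_identical(conv$name[1], "input")
})

test_that("partition panels stack in long form with empty partitions kept", {
  rl <- sage1_replacements()
  res <- run_partition_panels(partition_windows(rl, 400, 400),
                              builtin_scales()["h"],
                              convention = "from_minus_to")
  expect_identical(nrow(res), 3L)  # windows [1-400], [401-800], [801-805]
  expect_identical(res$partition, c("[1-400]", "[401-800]", "[801-805]"))
  expect_identical(res$n, c(3L, 10L, 2L))
  expect_equal(sum(res$net_change), 27.1)
})
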