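# shared fixture builders; everything is generated in code at test time

table1_deltas <- c(7.0, 2.4, -1.3, 1.0, -7.7, -0.1, 2.4, 7.7, -1.0,
                   2.5, 2.7, -2.5, 7.0, 2.4, 4.6)

h_scale <- function() builtin_scales()[["h"]]

# a tiny AAindex flat file: `values` is a named list accession -> 20 values
write_aaindex_fixture <- function(values, path = tempfile(fileext = ".txt")) {
  con <- file(path, "w")
  on.exit(close(con))
  for (acc in names(values)) {
    v <- values[[acc]]
    writeLines(c(
      paste("H", acc),
      paste("D description of", acc),
      "R PMID:0000000",
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      paste(" ", paste(v[1:10], collapse = "  ")),
      paste(" ", paste(v[11:20], collapse = "  ")),
      "//"), con)
  }
  path
}

write_blast_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("# blastp tabular with qseq/sseq", rows), path)
  path
}

blast_row <- function(qid, sid, qstart, qend, qseq, sseq) {
  paste(qid, sid, "90.0", nchar(qseq), "1", "0", qstart, qend, "1",
        nchar(gsub("-", "", sseq)), "1e-50", "200", qseq, sseq, sep = "\t")
}

write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), path)
  path
}

`%+%` <- function(a, b) paste0(a, b)

# plain data-frame content, custom attributes stripped
strip_df <- function(d) {
  d <- as.data.frame(d)
  attributes(d) <- attributes(d)[c("names", "row.names")]
  class(d) <- "data.frame"
  d
}

# random delta vectors for oracle-equivalence checks
random_delta_vectors <- function(k, seed) {
  set.seed(seed)
  lapply(seq_len(k), function(i) {
    n <- sample(2:50, 1)
    stats::rnorm(n)
  })
}
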