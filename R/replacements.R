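# Replacement lists: the per-comparison record of inferred amino-acid
# differences, and every route that produces one (aligned protein pairs,
# coding-sequence pairs, BLAST tabular output, external tables).

#' Construct a replacement list
#'
#' A replacement list records the inferred amino-acid differences of one
#' pairwise comparison: one row per residue site where the two sequences
#' carry different standard amino acids. Sites are 1-based in the frame
#' of the first/query sequence and strictly increasing (at most one
#' replacement per site per comparison).
#'
#' @param site integer vector of 1-based residue coordinates.
#' @param from,to residue codes (one- or three-letter); `from != to`
#'   rowwise, both standard.
#' @param sequence_length total number of residue sites in the
#'   comparison frame; every `site` must be `<= sequence_length`.
#' @param labels character pair naming the two sequences.
#' @param filter named integer vector of exclusion counts accumulated
#'   during extraction (`matches`, `mismatches`, `gap`, `nonstandard`).
#' @return object of class `replacement_list` (a data frame with
#'   columns `site`, `from`, `to` and attributes `sequence_length`,
#'   `labels`, `filter`).
#' @examples
#' replacement_list(c(82, 754), c("Cys", "Cys"), c("Arg", "Arg"), 805)
#' @export
replacement_list <- function(site, from, to, sequence_length,
                             labels = c("seq_a", "seq_b"),
                             filter = c(matches = NA_integer_,
                                        mismatches = NA_integer_,
                                        gap = 0L, nonstandard = 0L)) {
  site <- as.integer(site)
  from <- aa_one(from)
  to <- aa_one(to)
  stopifnot(length(from) == length(site), length(to) == length(site))
  if (length(site)) {
    stop_nonstandard(c(from, to), "replacement_list()")
    if (any(from == to))
      stop(sprintf("replacement with identical residues at site(s) %s",
                   paste(site[from == to], collapse = ", ")), call. = FALSE)
    if (any(site < 1L)) stop("sites must be >= 1", call. = FALSE)
    o <- order(site)
    site <- site[o]; from <- from[o]; to <- to[o]
    if (anyDuplicated(site))
      stop(sprintf("duplicated site(s): %s",
                   paste(unique(site[duplicated(site)]), collapse = ", ")),
           call. = FALSE)
    if (any(site > sequence_length))
      stop(sprintf("site(s) beyond sequence_length (%d): %s", sequence_length,
                   paste(site[site > sequence_length], collapse = ", ")),
           call. = FALSE)
  }
  structure(
    data.frame(site = site, from = from, to = to, stringsAsFactors = FALSE),
    sequence_length = as.integer(sequence_length),
    labels = as.character(labels),
    filter = filter,
    class = c("replacement_list", "data.frame"))
}

# subset rows while preserving replacement_list attributes
rl_subset <- function(rl, idx) {
  out <- as.data.frame(rl)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            sequence_length = attr(rl, "sequence_length"),
            labels = attr(rl, "labels"),
            filter = attr(rl, "filter"),
            class = c("replacement_list", "data.frame"))
}

#' @export
print.replacement_list <- function(x, ...) {
  lab <- attr(x, "labels")
  cat(sprintf("<replacement_list> %s vs %s: %d replacement(s) over %d site(s)\n",
              lab[1], lab[2], nrow(x), attr(x, "sequence_length")))
  f <- attr(x, "filter")
  if (!all(is.na(f)))
    cat("  filter counts:",
        paste(names(f), f, sep = "=", collapse = ", "), "\n")
  if (nrow(x)) print(as.data.frame(x))
  invisible(x)
}

#' Extract replacements from an aligned protein pair
#'
#' Walks two equal-length aligned protein sequences and emits one
#' replacement per site where both carry different standard amino
#' acids. Sites with a gap or non-standard code (`X`, `B`, `Z`, `*`,
#' ...) in either sequence are excluded, never imputed, and tallied in
#' the result's `filter` attribute so that
#' `matches + mismatches + gap + nonstandard == alignment length`.
#'
#' @param seq_a,seq_b aligned sequences (single strings); `from` is
#'   taken from `seq_a`, `to` from `seq_b`.
#' @param labels character pair naming the sequences.
#' @param frame `"alignment"` (sites are alignment columns, the default)
#'   or `"first"` (sites count only non-gap positions of `seq_a`, as
#'   needed for BLAST HSPs reported in query coordinates).
#' @param offset added to every site (e.g. `qstart - 1` for an HSP).
#' @return a [replacement_list()].
#' @examples
#' diff_aligned("CVK", "RVK")  # one replacement: site 1, C -> R
#' @export
diff_aligned <- function(seq_a, seq_b, labels = c("seq_a", "seq_b"),
                         frame = c("alignment", "first"), offset = 0L) {
  stopifnot(is.character(seq_a), length(seq_a) == 1,
            is.character(seq_b), length(seq_b) == 1)
  frame <- match.arg(frame)
  a <- toupper(strsplit(seq_a, "")[[1]])
  b <- toupper(strsplit(seq_b, "")[[1]])
  if (length(a) != length(b))
    stop(sprintf("aligned sequences differ in length (%d vs %d)",
                 length(a), length(b)), call. = FALSE)
  gap_chars <- c("-", ".")
  is_gap <- a %in% gap_chars | b %in% gap_chars
  nonstd <- !is_gap & (!is_standard_aa(a) | !is_standard_aa(b))
  usable <- !is_gap & !nonstd
  differ <- usable & a != b
  sites <- if (frame == "alignment") seq_along(a) else cumsum(!(a %in% gap_chars))
  seq_len_out <- if (frame == "alignment") length(a) else sum(!(a %in% gap_chars)) + offset
  replacement_list(
    site = sites[differ] + as.integer(offset),
    from = a[differ], to = b[differ],
    sequence_length = seq_len_out,
    labels = labels,
    filter = c(matches = sum(usable & a == b), mismatches = sum(differ),
               gap = sum(is_gap), nonstandard = sum(nonstd)))
}

#' Translate a protein-coding nucleotide sequence
#'
#' Translates complete codons only; 1--2 trailing nucleotides are
#' dropped with a warning. IUPAC ambiguity codes are accepted: a codon
#' whose expansions all give one amino acid is solved, otherwise it
#' yields `X` with a warning. Internal stop codons are translated as
#' `*` and flagged with a warning. Uses the standard NCBI translation
#' tables via Biostrings.
#'
#' @param nt nucleotide sequence (single string, DNA or RNA alphabet).
#' @param genetic_code_id NCBI translation table number; `1` (standard,
#'   default) or e.g. `5` (invertebrate mitochondrial, used for copepod
#'   COI barcodes).
#' @return single protein string.
#' @examples
#' translate_cds("ATGAAATAG")       # "MK*"
#' translate_cds("ATTTGA", 5)       # invertebrate mito: TGA = Trp
#' @export
translate_cds <- function(nt, genetic_code_id = 1) {
  stopifnot(is.character(nt), length(nt) == 1)
  nt <- chartr("u", "t", gsub("\\s", "", nt))
  nt <- toupper(chartr("U", "T", nt))
  chars <- unique(strsplit(nt, "")[[1]])
  bad <- setdiff(chars, names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad))
    stop(sprintf("non-IUPAC nucleotide character(s): %s",
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  if (nchar(nt) < 3) stop("sequence shorter than one codon", call. = FALSE)
  extra <- nchar(nt) %% 3
  if (extra) {
    warning(sprintf("dropping %d trailing nucleotide(s) (incomplete codon)",
                    extra), call. = FALSE)
    nt <- substr(nt, 1, nchar(nt) - extra)
  }
  code <- Biostrings::getGeneticCode(as.character(genetic_code_id))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(nt), genetic.code = code, if.fuzzy.codon = "solve",
    no.init.codon = TRUE))
  if (grepl("X", aa))
    warning(sprintf("%d ambiguous codon(s) translated as 'X'",
                    lengths(regmatches(aa, gregexpr("X", aa)))), call. = FALSE)
  internal_stop <- gregexpr("\\*", substr(aa, 1, nchar(aa) - 1))[[1]]
  if (internal_stop[1] != -1)
    warning(sprintf("internal stop codon(s) at residue position(s) %s translated as '*'",
                    paste(internal_stop, collapse = ", ")), call. = FALSE)
  aa
}

#' Parse BLAST tabular output carrying aligned sequences
#'
#' Reads BLAST tabular output (`-outfmt 6`-style, comment lines starting
#' with `#` are skipped) that includes the aligned query and subject
#' sequence columns `qseq` and `sseq`; each HSP row yields one aligned
#' pair. Gaps are retained in the pair -- the downstream
#' [diff_aligned()] gap filter applies.
#'
#' @param path path to the tabular file.
#' @param columns character vector naming the columns in order. The
#'   default is the standard 12-column format extended with
#'   `qseq`/`sseq` (i.e. produced by
#'   `-outfmt "6 std qseq sseq"`). `qseqid`, `sseqid`, `qstart`,
#'   `qseq` and `sseq` are required.
#' @return object of class `blast_pairs`: a list of HSP records, each
#'   `list(query_id, subject_id, qstart, qseq, sseq)`.
#' @seealso [blast_replacements()] to turn each pair into a
#'   [replacement_list()] in query coordinates.
#' @export
parse_blast_pairs <- function(path,
                              columns = c("qseqid", "sseqid", "pident",
                                          "length", "mismatch", "gapopen",
                                          "qstart", "qend", "sstart", "send",
                                          "evalue", "bitscore",
                                          "qseq", "sseq")) {
  need <- c("qseqid", "sseqid", "qstart", "qseq", "sseq")
  missing <- setdiff(need, columns)
  if (length(missing))
    stop(sprintf("BLAST column spec lacks required field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines)) return(structure(list(), class = "blast_pairs"))
  rows <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != length(columns)))
    stop(sprintf("BLAST row %d has %d field(s); %d expected from the column spec (required fields: %s)",
                 which(nf != length(columns))[1], nf[nf != length(columns)][1],
                 length(columns), paste(need, collapse = ", ")), call. = FALSE)
  pairs <- lapply(rows, function(r) {
    names(r) <- columns
    qs <- r[["qseq"]]; ss <- r[["sseq"]]
    if (nchar(qs) != nchar(ss))
      stop("HSP qseq/sseq lengths differ", call. = FALSE)
    list(query_id = r[["qseqid"]], subject_id = r[["sseqid"]],
         qstart = as.integer(r[["qstart"]]), qseq = qs, sseq = ss)
  })
  structure(pairs, class = "blast_pairs")
}

#' @rdname parse_blast_pairs
#' @param pairs a `blast_pairs` object (or one element of it).
#' @return `blast_replacements()` returns a list of
#'   [replacement_list()], one per HSP, sites in query coordinates.
#' @export
blast_replacements <- function(pairs) {
  if (!inherits(pairs, "blast_pairs")) pairs <- structure(list(pairs),
                                                          class = "blast_pairs")
  lapply(unclass(pairs), function(p) {
    diff_aligned(p$qseq, p$sseq, labels = c(p$query_id, p$subject_id),
                 frame = "first", offset = p$qstart - 1L)
  })
}

#' Read / write plain replacement tables
#'
#' The interchange format for externally generated replacement lists
#' (e.g. exported from ancestral character-state reconstruction tools):
#' a TSV with header `site`, `from`, `to` and 1-based sites. Validation
#' is strict -- duplicate sites, `from == to` rows, and non-standard
#' residues are errors.
#'
#' @param path file path.
#' @param sequence_length total residue sites; defaults to the maximum
#'   site in the table.
#' @param labels sequence-pair labels.
#' @return `read_replacement_table()` returns a [replacement_list()].
#' @export
read_replacement_table <- function(path, sequence_length = NULL,
                                   labels = c("seq_a", "seq_b")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  need <- c("site", "from", "to")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("replacement table %s lacks column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (is.null(sequence_length))
    sequence_length <- if (nrow(df)) max(as.integer(df$site)) else 0L
  replacement_list(df$site, df$from, df$to, sequence_length, labels = labels)
}

#' @rdname read_replacement_table
#' @param replacements a [replacement_list()].
#' @export
write_replacement_table <- function(replacements, path) {
  stopifnot(inherits(replacements, "replacement_list"))
  utils::write.table(as.data.frame(replacements), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a FASTA record from a file or accession cache
#'
#' Local files are always accepted. A bare accession is resolved against
#' `cache_dir/<accession>.fasta`; network fetching (NCBI efetch) is off
#' by default and only attempted when `allow_fetch = TRUE`, so that all
#' core workflows run offline.
#'
#' @param x path to a FASTA file or a sequence accession.
#' @param cache_dir directory searched for `<accession>.fasta`.
#' @param record id of the record to select when the file holds several;
#'   with multiple records and no selector, the error lists the ids.
#' @param allow_fetch set `TRUE` to permit a network download of an
#'   accession missing from the cache (written to `cache_dir`).
#' @return `list(id, desc, seq)` with `seq` a single character string.
#' @export
fetch_or_load_fasta <- function(x, cache_dir = NULL, record = NULL,
                                allow_fetch = FALSE) {
  path <- NULL
  if (file.exists(x)) {
    path <- x
  } else if (!is.null(cache_dir) &&
             file.exists(file.path(cache_dir, paste0(x, ".fasta")))) {
    path <- file.path(cache_dir, paste0(x, ".fasta"))
  } else if (allow_fetch) {
    if (is.null(cache_dir)) cache_dir <- tempdir()
    path <- file.path(cache_dir, paste0(x, ".fasta"))
    url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                  "?db=nuccore&id=", x, "&rettype=fasta&retmode=text")
    status <- tryCatch(utils::download.file(url, path, quiet = TRUE),
                       error = function(e) 1L, warning = function(w) 1L)
    if (!identical(status, 0L) || !file.size(path) > 0)
      stop(sprintf("failed to fetch accession '%s' from NCBI", x),
           call. = FALSE)
  } else {
    stop(sprintf(paste0(
      "no local file or cached copy for '%s'. Supply a FASTA file, place ",
      "'%s.fasta' in the cache directory, or re-run with allow_fetch = TRUE ",
      "on a machine with network access."), x, x), call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop(sprintf("no records in %s", path), call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (length(set) > 1) {
    if (is.null(record))
      stop(sprintf("%s holds %d records; pass 'record' to select one of: %s",
                   path, length(set), paste(ids, collapse = ", ")),
           call. = FALSE)
    idx <- match(record, ids)
    if (is.na(idx))
      stop(sprintf("record '%s' not found in %s (ids: %s)", record, path,
                   paste(ids, collapse = ", ")), call. = FALSE)
  } else idx <- 1L
  list(id = ids[idx],
       desc = sub("^\\S+\\s*", "", names(set)[idx]),
       seq = as.character(set[[idx]]))
}
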