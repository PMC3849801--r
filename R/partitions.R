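# Partitioning: pool replacements by whole sequence, sliding windows,
# or named residue regions before testing.  Partitions live in 1-based
# inclusive residue coordinates so they stay comparable to structural
# annotations; pooling never alters a replacement record.

new_partition <- function(name, start, end, truncated = FALSE) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start)
    stop(sprintf("invalid partition '%s': need 1 <= start <= end (got %s..%s)",
                 name, start, end), call. = FALSE)
  structure(list(name = as.character(name), start = start, end = end,
                 truncated = isTRUE(truncated)),
            class = "seq_partition")
}

#' @export
print.seq_partition <- function(x, ...) {
  cat(sprintf("<partition> %s [%d, %d]%s\n", x$name, x$start, x$end,
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

partition_set <- function(entries) {
  structure(entries, class = "partition_set")
}

#' @export
print.partition_set <- function(x, ...) {
  cat(sprintf("<partition_set> %d partition(s)\n", length(x)))
  for (e in unclass(x))
    cat(sprintf("  %-12s [%4d, %4d]  %d replacement(s)\n",
                e$partition$name, e$partition$start, e$partition$end,
                nrow(e$replacements)))
  invisible(x)
}

pool_into <- function(replacements, partition) {
  rl_subset(replacements,
            replacements$site >= partition$start &
              replacements$site <= partition$end)
}

#' Whole-sequence partition
#'
#' Pools all replacements into a single partition spanning residue 1 to
#' the sequence length -- the "entire alignment" analysis.
#'
#' @param replacements a [replacement_list()].
#' @return a `partition_set` of one entry, each entry a
#'   `list(partition, replacements)`.
#' @export
partition_whole <- function(replacements) {
  stopifnot(inherits(replacements, "replacement_list"))
  p <- new_partition("whole", 1L, max(attr(replacements, "sequence_length"), 1L))
  partition_set(list(list(partition = p,
                          replacements = pool_into(replacements, p))))
}

#' Sliding-window partitions
#'
#' Windows of `window` residues start at 1, 1 + `step`, ... while the
#' start lies within the sequence; the final window is truncated at the
#' sequence end (and flagged). Each replacement is assigned to every
#' window containing its site, so with `step <= window` coverage is
#' complete. Used to localize clusters of unidirectional change.
#'
#' @inheritParams partition_whole
#' @param window window width in residues (>= 1).
#' @param step start-to-start distance in residues (>= 1); defaults to
#'   `window` (non-overlapping tiling).
#' @return a `partition_set`, one entry per window, named
#'   `"[start-end]"`.
#' @examples
#' rl <- sage1_replacements()
#' length(partition_windows(rl, 100, 100))  # 9 windows over 805 sites
#' @export
partition_windows <- function(replacements, window, step = window) {
  stopifnot(inherits(replacements, "replacement_list"))
  window <- as.integer(window); step <- as.integer(step)
  if (is.na(window) || window < 1L) stop("window must be >= 1", call. = FALSE)
  if (is.na(step) || step < 1L) stop("step must be >= 1", call. = FALSE)
  L <- attr(replacements, "sequence_length")
  if (window >= L) {
    if (window > L)
      warning(sprintf("window (%d) exceeds sequence length (%d); using a single whole-sequence window",
                      window, L), call. = FALSE)
    ws <- partition_whole(replacements)
    ws[[1]]$partition$truncated <- window > L
    return(partition_set(unclass(ws)))
  }
  starts <- seq.int(1L, L, by = step)
  partition_set(lapply(starts, function(s) {
    e <- min(s + window - 1L, L)
    p <- new_partition(sprintf("[%d-%d]", s, e), s, e,
                       truncated = e - s + 1L < window)
    list(partition = p, replacements = pool_into(replacements, p))
  }))
}

#' Named-region partitions
#'
#' Pools replacements into user-defined residue intervals, e.g.
#' functional domains or structurally annotated regions (proton input /
#' output regions of a membrane pump, secondary-structure elements).
#' Regions may overlap; a replacement falls in every region containing
#' its site. Regions running past the sequence end are clipped with a
#' warning; `end < start` is an error.
#'
#' @inheritParams partition_whole
#' @param regions data frame with columns `name`, `start`, `end`
#'   (1-based inclusive), e.g. from [read_regions()].
#' @return a `partition_set`, one entry per region row.
#' @export
partition_regions <- function(replacements, regions) {
  stopifnot(inherits(replacements, "replacement_list"))
  if (!all(c("name", "start", "end") %in% names(regions)))
    stop("regions need columns: name, start, end", call. = FALSE)
  L <- attr(replacements, "sequence_length")
  partition_set(lapply(seq_len(nrow(regions)), function(i) {
    s <- as.integer(regions$start[i]); e <- as.integer(regions$end[i])
    if (e > L) {
      warning(sprintf("region '%s' [%d, %d] exceeds sequence length %d; clipped",
                      regions$name[i], s, e, L), call. = FALSE)
      e <- L
    }
    p <- new_partition(regions$name[i], s, e)
    list(partition = p, replacements = pool_into(replacements, p))
  }))
}

#' Read a region table
#'
#' `read_regions()` expects a TSV with header `name`, `start`, `end` in
#' 1-based inclusive residue coordinates. `bed_to_regions()` converts
#' BED intervals (0-based, half-open; columns chrom/start/end and
#' optionally name) to the same 1-based inclusive convention by adding 1
#' to the start.
#'
#' @param path file path.
#' @return data frame with columns `name`, `start`, `end`.
#' @export
read_regions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  missing <- setdiff(c("name", "start", "end"), names(df))
  if (length(missing))
    stop(sprintf("region file %s lacks column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df[c("name", "start", "end")]
}

#' @rdname read_regions
#' @export
bed_to_regions <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "#")
  if (ncol(df) < 3) stop("BED input needs at least 3 columns", call. = FALSE)
  data.frame(
    name = if (ncol(df) >= 4) as.character(df[[4]]) else
      sprintf("%s:%d-%d", df[[1]], df[[2]] + 1L, df[[3]]),
    start = as.integer(df[[2]]) + 1L,
    end = as.integer(df[[3]]),
    stringsAsFactors = FALSE)
}

#' Run the property panel over every partition
#'
#' Convenience wrapper: applies [run_property_panel()] to each entry of
#' a `partition_set` and stacks the results in long form. Partitions
#' with no replacements yield rows with `n = 0` and `NA` statistics
#' (rather than an error), since empty windows are routine.
#'
#' @param partitions a `partition_set`.
#' @inheritParams run_property_panel
#' @return data frame: `partition`, `start`, `end`, then the
#'   [run_property_panel()] columns.
#' @export
run_partition_panels <- function(partitions, library = builtin_scales(),
                                 convention = c("to_minus_from",
                                                "from_minus_to"),
                                 adjust = FALSE, alpha = 0.05, min_n = 5L) {
  stopifnot(inherits(partitions, "partition_set"))
  convention <- match.arg(convention)
  blocks <- lapply(unclass(partitions), function(e) {
    panel <- if (nrow(e$replacements)) {
      suppressWarnings(
        run_property_panel(e$replacements, library, convention,
                           adjust = adjust, alpha = alpha, min_n = min_n))
    } else {
      empty <- run_property_panel(
        replacement_list(1, "A", "V", 1), library, convention,
        adjust = adjust, alpha = alpha, min_n = min_n)
      empty$n <- 0L
      for (col in c("mean", "sd", "se", "t", "p", "net_change"))
        empty[[col]] <- NA_real_
      empty$df <- NA_integer_
      empty$direction <- "none"
      empty$degenerate <- TRUE
      empty$low_n <- TRUE
      empty
    }
    cbind(data.frame(partition = e$partition$name,
                     start = e$partition$start, end = e$partition$end,
                     stringsAsFactors = FALSE),
          as.data.frame(panel))
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  structure(out, convention = convention,
            class = c("directional_panel", "data.frame"))
}
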