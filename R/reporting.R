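# Reporting: signed significance symbols, property-by-partition result
# matrices (TSV / JSON / text grid), and the Table-1-style pairwise
# single-property report.  Rendering is pure: a result set maps to one
# byte sequence (fixed column order, fixed "%.12g" numeric formatting,
# no timestamps).

DEFAULT_TIERS <- c(0.1, 0.05, 0.01)

num_fmt <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 12))
}

#' Signed significance symbol for one result
#'
#' Maps a two-tailed p-value and a direction of mean change onto the
#' signed symbol notation used in directional-selection summary tables:
#' `k` repetitions of `+` (mean increase) or `-` (mean decrease), where
#' `k` is the number of significance tiers met; empty when no tier is
#' met or the mean is zero. The default tiers p < 0.1 / 0.05 / 0.01 map
#' to one / two / three symbols -- a monotone interpretation of the
#' one-to-three-symbol notation (see the methods vignette), and fully
#' configurable.
#'
#' @param p two-tailed p-value.
#' @param mean mean delta (its sign picks the symbol).
#' @param tiers strictly decreasing p thresholds.
#' @param degenerate if `TRUE` (or `p` is `NA`) renders `"NA"`.
#' @return a single string.
#' @examples
#' significance_symbol(0.04, 1.2)    # "++"
#' significance_symbol(0.2, -1)     # ""
#' significance_symbol(0.005, -1)   # "---"
#' @export
significance_symbol <- function(p, mean, tiers = DEFAULT_TIERS,
                                degenerate = FALSE) {
  if (any(diff(tiers) >= 0)) stop("tiers must be strictly decreasing",
                                  call. = FALSE)
  if (isTRUE(degenerate) || is.na(p)) return("NA")
  k <- sum(p < tiers)
  if (k == 0 || mean == 0) return("")
  strrep(if (mean > 0) "+" else "-", k)
}

#' @rdname significance_symbol
#' @param result a `directional_test` object or one row of a
#'   `directional_panel`.
#' @export
symbolize <- function(result, tiers = DEFAULT_TIERS) {
  if (inherits(result, "directional_test"))
    return(significance_symbol(result$p_two_tailed, result$mean, tiers,
                               result$degenerate))
  significance_symbol(result$p, result$mean, tiers,
                      isTRUE(result$degenerate))
}

panel_long <- function(results) {
  df <- as.data.frame(results)
  attributes(df) <- attributes(df)[c("names", "row.names", "class")]
  class(df) <- "data.frame"
  if (!"partition" %in% names(df)) {
    df <- data.frame(partition = rep("whole", nrow(df)), df,
                     check.names = FALSE, stringsAsFactors = FALSE)
  }
  df
}

#' Render a property-by-partition result matrix
#'
#' Formats the stacked results of [run_partition_panels()] (or a single
#' [run_property_panel()], treated as one "whole" partition).
#'
#' * `"tsv"`: full numeric fields (`n`, `mean`, `sd`, `se`, `t`, `df`,
#'   `p`, `net_change`, ...) in long form, one row per (partition,
#'   scale), numbers at 12 significant digits.
#' * `"json"`: the same records as a JSON array.
#' * `"grid"`: the compact signed-symbol matrix -- properties as rows
#'   grouped under their category headings, partitions as columns --
#'   reproducible cell-by-cell from the TSV via [significance_symbol()].
#'
#' @param results a `directional_panel` data frame.
#' @param format `"tsv"`, `"json"` or `"grid"`.
#' @param tiers significance tiers for the grid (see
#'   [significance_symbol()]).
#' @return a single character string (the document).
#' @export
report_matrix <- function(results, format = c("tsv", "json", "grid"),
                          tiers = DEFAULT_TIERS) {
  format <- match.arg(format)
  df <- panel_long(results)
  num_cols <- intersect(c("mean", "sd", "se", "t", "p", "net_change", "p_adj"),
                        names(df))
  switch(format,
    tsv = {
      out <- df
      for (col in num_cols) out[[col]] <- num_fmt(out[[col]])
      lines <- c(paste(names(out), collapse = "\t"),
                 if (nrow(out)) apply(out, 1, function(r)
                   paste(ifelse(is.na(r), "NA", r), collapse = "\t")))
      paste0(paste(lines, collapse = "\n"), "\n")
    },
    json = {
      out <- df
      paste0(jsonlite::toJSON(out, dataframe = "rows", digits = NA,
                              na = "null", pretty = TRUE), "\n")
    },
    grid = {
      parts <- unique(df$partition)
      scales <- unique(df[c("scale", "category")])
      width <- max(nchar(c("Property", scales$scale)))
      pw <- pmax(nchar(parts), 4L)
      hdr <- paste(c(formatC("Property", width = width, flag = "-"),
                     mapply(formatC, parts, width = pw,
                            MoreArgs = list(flag = "-"))),
                   collapse = "  ")
      lines <- hdr
      for (cat_name in unique(scales$category)) {
        lines <- c(lines, paste0("## ", cat_name))
        for (sym in scales$scale[scales$category == cat_name]) {
          cells <- vapply(seq_along(parts), function(j) {
            row <- df[df$scale == sym & df$partition == parts[j], ]
            cell <- if (nrow(row)) symbolize(row[1, ], tiers) else ""
            formatC(cell, width = pw[j], flag = "-")
          }, "")
          lines <- c(lines,
                     paste(c(formatC(sym, width = width, flag = "-"), cells),
                           collapse = "  "))
        }
      }
      paste0(paste(lines, collapse = "\n"), "\n")
    })
}

#' Table-style pairwise single-property report
#'
#' Mirrors the classic worked-example layout: one row per replacement
#' (site, from, to, signed delta) and a net-change footer, for one
#' property scale.
#'
#' @inheritParams replacement_deltas
#' @return a single character string.
#' @examples
#' cat(pairwise_report(sage1_replacements(), builtin_scales()[["h"]],
#'                     "from_minus_to"))
#' @export
pairwise_report <- function(replacements, scale,
                            convention = c("to_minus_from",
                                           "from_minus_to")) {
  convention <- match.arg(convention)
  dv <- replacement_deltas(replacements, scale, convention)
  lab <- attr(replacements, "labels")
  lines <- c(
    sprintf("Directional analysis: %s vs %s, property %s (%s)",
            lab[1], lab[2], scale$symbol, convention),
    sprintf("%-8s%-6s%-6s%s", "Site", "From", "To",
            paste("Delta", scale$symbol)),
    sprintf("%-8d%-6s%-6s%+g", replacements$site, replacements$from,
            replacements$to, dv$values),
    sprintf("%-20s%+g", "Net Change =", sum(dv$values)))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write a rendered report
#'
#' @param doc document string from [report_matrix()] or
#'   [pairwise_report()].
#' @param path output file, or `""` for standard output.
#' @export
write_report <- function(doc, path = "") {
  cat(doc, file = path)
  invisible(path)
}
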