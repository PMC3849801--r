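# The directional-selection test: score a replacement set through one
# property scale and test H0: mu = 0 on the signed deltas.
#
# The statistic is computed from the method's two defining equations,
#     t = Xbar / s_Xbar,   s_Xbar^2 = (Sum Xi^2 - (Sum Xi)^2 / N) / (N - 1) / N,
# with df = N - 1 and the two-tailed tail probability taken from the
# exact Student-t distribution (not a normal approximation: N is small
# in practice).  The implementation is deliberately independent of
# stats::t.test, which the test suite uses as the oracle.

#' Score a replacement set through one property scale
#'
#' Produces the delta vector `X_i`: one signed property change per
#' replacement, in replacement order.
#'
#' @param replacements a [replacement_list()]; must be non-empty.
#' @param scale a [prop_scale()].
#' @inheritParams property_delta
#' @return object of class `delta_vector`:
#'   `list(values, sites, scale_symbol, convention)`.
#' @examples
#' dv <- replacement_deltas(sage1_replacements(),
#'                          builtin_scales()[["h"]], "from_minus_to")
#' sum(dv$values)  # +27.1
#' @export
replacement_deltas <- function(replacements, scale,
                               convention = c("to_minus_from",
                                              "from_minus_to")) {
  stopifnot(inherits(replacements, "replacement_list"))
  convention <- match.arg(convention)
  if (!nrow(replacements))
    stop("empty replacement list: no deltas to compute (report NA upstream if desired)",
         call. = FALSE)
  structure(
    list(values = property_delta(scale, replacements$from, replacements$to,
                                 convention),
         sites = replacements$site,
         scale_symbol = scale$symbol,
         convention = convention),
    class = "delta_vector")
}

#' @export
print.delta_vector <- function(x, ...) {
  cat(sprintf("<delta_vector> scale %s (%s), n = %d\n",
              x$scale_symbol, x$convention, length(x$values)))
  print(stats::setNames(x$values, x$sites))
  invisible(x)
}

# Core one-sample t computation on a bare numeric vector.
# Degenerate handling:
#   n == 1            -> t, p undefined (NA), flagged
#   sd == 0, mean == 0 -> t = 0, p = 1, flagged
#   sd == 0, mean != 0 -> t = +/-Inf, p = 0, flagged
t_core <- function(x) {
  n <- length(x)
  if (n == 0) stop("empty delta vector", call. = FALSE)
  s1 <- sum(x)
  s2 <- sum(x^2)
  m <- s1 / n
  if (n == 1) {
    return(list(n = n, mean = m, sd = NA_real_, se = NA_real_,
                t = NA_real_, df = 0L, p = NA_real_, net = s1,
                degenerate = TRUE))
  }
  ss <- max(s2 - s1^2 / n, 0)  # guard tiny negative from roundoff
  sdv <- sqrt(ss / (n - 1))
  se <- sdv / sqrt(n)
  if (se == 0) {
    degenerate <- TRUE
    if (m == 0) { t <- 0; p <- 1 } else { t <- sign(m) * Inf; p <- 0 }
  } else {
    degenerate <- FALSE
    t <- m / se
    p <- 2 * stats::pt(-abs(t), df = n - 1)
  }
  list(n = n, mean = m, sd = sdv, se = se, t = t, df = n - 1L, p = p,
       net = s1, degenerate = degenerate)
}

#' Two-tailed one-sample t-test on property deltas
#'
#' Tests whether the mean signed property change over a replacement set
#' differs from zero (H0: mu = 0, i.e. no net directional change). A
#' significant positive (negative) mean indicates replacements
#' accumulating in the same physicochemical direction -- the method's
#' signature of directional selection on that property.
#'
#' Degenerate inputs are flagged rather than dropped: with a single
#' replacement the statistic is undefined (`p = NA`); with zero
#' variance, `p` is 1 (mean 0) or 0 (mean nonzero). Results with fewer
#' than `min_n` replacements carry a low-power advisory flag.
#'
#' @param deltas a [replacement_deltas()] result, or a bare numeric
#'   vector of deltas.
#' @param alpha reporting threshold used only to set the `direction`
#'   label (`"none"` when `p >= alpha` or the mean is zero).
#' @param min_n minimum replacement count below which `low_n` is set.
#' @return object of class `directional_test` with fields
#'   `scale_symbol`, `convention`, `n`, `mean`, `sd`, `se`, `t`, `df`,
#'   `p_two_tailed`, `net_change`, `direction`, `degenerate`, `low_n`.
#' @examples
#' dv <- replacement_deltas(sage1_replacements(),
#'                          builtin_scales()[["h"]], "from_minus_to")
#' directional_t_test(dv)  # t = 1.728, df = 14, p = 0.106
#' @export
directional_t_test <- function(deltas, alpha = 0.05, min_n = 5L) {
  if (inherits(deltas, "delta_vector")) {
    x <- deltas$values
    sym <- deltas$scale_symbol
    conv <- deltas$convention
  } else {
    x <- as.numeric(deltas)
    sym <- NA_character_
    conv <- NA_character_
  }
  if (!all(is.finite(x))) stop("deltas must be finite", call. = FALSE)
  core <- t_core(x)
  direction <- if (is.na(core$p) || core$p >= alpha || core$mean == 0) "none"
               else if (core$mean > 0) "increase" else "decrease"
  structure(
    list(scale_symbol = sym, convention = conv, n = core$n,
         mean = core$mean, sd = core$sd, se = core$se, t = core$t,
         df = core$df, p_two_tailed = core$p, net_change = core$net,
         direction = direction, degenerate = core$degenerate,
         low_n = core$n < min_n),
    class = "directional_test")
}

#' @export
print.directional_test <- function(x, ...) {
  cat(sprintf("<directional_test>%s n = %d\n",
              if (is.na(x$scale_symbol)) "" else
                sprintf(" scale %s (%s),", x$scale_symbol, x$convention),
              x$n))
  cat(sprintf("  mean = %.6g  se = %.6g  net change = %+.6g\n",
              x$mean, x$se, x$net_change))
  cat(sprintf("  t = %.6g on %d df, two-tailed p = %.6g  [%s]%s%s\n",
              x$t, x$df, x$p_two_tailed, x$direction,
              if (x$degenerate) "  (degenerate)" else "",
              if (x$low_n) "  (low n)" else ""))
  invisible(x)
}

#' Run the directional test across a property library
#'
#' One two-tailed test per scale, in library order. Per-scale failures
#' are trapped and reported in the `error` column without aborting the
#' remaining panel.
#'
#' @inheritParams replacement_deltas
#' @param library a [prop_library()]; defaults to the built-in 25-scale
#'   panel.
#' @param adjust if `TRUE`, append a Benjamini--Hochberg adjusted
#'   p-value column `p_adj` across the panel's scales. Raw p-values stay
#'   primary; the adjustment is additive and changes no other field.
#' @inheritParams directional_t_test
#' @return data frame of class `directional_panel`, one row per scale:
#'   `scale`, `category`, `n`, `mean`, `sd`, `se`, `t`, `df`, `p`,
#'   `net_change`, `direction`, `degenerate`, `low_n`, `error`
#'   (and `p_adj` when requested).
#' @examples
#' run_property_panel(sage1_replacements(), convention = "from_minus_to")
#' @export
run_property_panel <- function(replacements, library = builtin_scales(),
                               convention = c("to_minus_from",
                                              "from_minus_to"),
                               adjust = FALSE, alpha = 0.05, min_n = 5L) {
  convention <- match.arg(convention)
  rows <- lapply(unclass(library), function(scale) {
    res <- tryCatch(
      directional_t_test(replacement_deltas(replacements, scale, convention),
                         alpha = alpha, min_n = min_n),
      error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(scale = scale$symbol, category = scale$category,
                 n = NA_integer_, mean = NA_real_, sd = NA_real_,
                 se = NA_real_, t = NA_real_, df = NA_integer_, p = NA_real_,
                 net_change = NA_real_, direction = NA_character_,
                 degenerate = NA, low_n = NA,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(scale = scale$symbol, category = scale$category,
                 n = res$n, mean = res$mean, sd = res$sd, se = res$se,
                 t = res$t, df = res$df, p = res$p_two_tailed,
                 net_change = res$net_change, direction = res$direction,
                 degenerate = res$degenerate, low_n = res$low_n,
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scale = character(), category = character(), n = integer(),
               mean = numeric(), sd = numeric(), se = numeric(),
               t = numeric(), df = integer(), p = numeric(),
               net_change = numeric(), direction = character(),
               degenerate = logical(), low_n = logical(),
               error = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  failed <- out$scale[!is.na(out$error)]
  if (length(failed))
    warning(sprintf("panel failed for scale(s): %s",
                    paste(failed, collapse = ", ")), call. = FALSE)
  structure(out, convention = convention,
            labels = attr(replacements, "labels"),
            class = c("directional_panel", "data.frame"))
}
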