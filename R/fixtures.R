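# Bundled worked-example fixture and synthetic replacement generators.
#
# The SAGE1 fixture is the published 15-replacement Pan/Homo comparison
# used throughout the test suite as the single source of truth for the
# hydropathy worked example.  The generators draw replacements from the
# 380 ordered pairs of distinct standard residues: uniformly (the null
# of "no net change") or exponentially tilted toward positive deltas of
# a chosen scale (the biased model used for power checks).

# evaluate code under a temporary RNG state seeded with `seed`;
# NULL seed means: use (and advance) the caller's RNG stream
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' The SAGE1 Pan/Homo replacement fixture
#'
#' The bundled worked example: the 15 amino-acid differences between the
#' chimpanzee and human SAGE1 proteins, at residue sites 82 through 805.
#' Under the hydropathy scale `"h"` with the `from_minus_to` convention
#' these reproduce the published delta column exactly (net change
#' +27.1).
#'
#' @return a [replacement_list()] of 15 replacements
#'   (`sequence_length = 805`).
#' @examples
#' nrow(sage1_replacements())  # 15
#' @export
sage1_replacements <- function() {
  replacement_list(
    site = c(82L, 92L, 160L, 450L, 507L, 523L, 563L, 582L, 605L, 672L,
             675L, 694L, 754L, 802L, 805L),
    from = c("Cys", "Val", "Arg", "Gln", "Asp", "Ser", "Val", "Val", "Phe",
             "Ala", "Ser", "Thr", "Cys", "Val", "Leu"),
    to = c("Arg", "Ala", "His", "Arg", "Val", "Thr", "Ala", "Asp", "Leu",
           "Thr", "Asn", "Ala", "Arg", "Ala", "Ser"),
    sequence_length = 805L,
    labels = c("Pan_SAGE1", "Homo_SAGE1"),
    filter = c(matches = 790L, mismatches = 15L, gap = 0L, nonstandard = 0L))
}

#' Synthetic aligned pair carrying the SAGE1 differences
#'
#' Builds two synthetic 805-residue aligned protein sequences that
#' differ exactly at the 15 fixture sites (identical pseudo-random
#' background elsewhere, deterministic). Useful for exercising the
#' alignment-diff and FASTA ingestion paths end-to-end; these are not
#' the real SAGE1 sequences.
#'
#' @return `list(seq_a, seq_b)` of single strings, 805 residues each.
#' @export
sage1_aligned_pair <- function() {
  rl <- sage1_replacements()
  bg <- with_local_seed(19821005, sample(AAINDEX_ORDER, 805, replace = TRUE))
  a <- b <- bg
  a[rl$site] <- rl$from
  b[rl$site] <- rl$to
  list(seq_a = paste(a, collapse = ""), seq_b = paste(b, collapse = ""))
}

#' Enumerate the 380 ordered residue pairs and their deltas
#'
#' Exact enumeration over all ordered pairs of distinct standard amino
#' acids -- the support of the null replacement model. By antisymmetry
#' the enumeration mean of any scale's deltas is exactly zero, which is
#' what makes the uniform pair law a null for "no net change".
#'
#' @return `enumerate_pairs()`: data frame of 380 rows (`from`, `to`).
#' @export
enumerate_pairs <- function() {
  g <- expand.grid(from = AAINDEX_ORDER, to = AAINDEX_ORDER,
                   stringsAsFactors = FALSE)
  g <- g[g$from != g$to, c("from", "to")]
  rownames(g) <- NULL
  g
}

#' @rdname enumerate_pairs
#' @inheritParams property_delta
#' @param scale a [prop_scale()].
#' @return `enumerate_deltas()`: numeric vector of the 380 deltas.
#' @export
enumerate_deltas <- function(scale,
                             convention = c("to_minus_from",
                                            "from_minus_to")) {
  pairs <- enumerate_pairs()
  property_delta(scale, pairs$from, pairs$to, match.arg(convention))
}

#' Sample replacements from the null model
#'
#' Draws `n` replacements at distinct random sites, each an ordered
#' residue pair drawn uniformly from the 380 distinct-pair support --
#' no codon or mutational-bias structure, matching the property-level
#' null hypothesis of no net change. Reproducible for a fixed seed.
#'
#' @param n number of replacements.
#' @param sequence_length number of residue sites (must be `>= n`).
#' @param seed optional integer seed; the caller's RNG state is left
#'   untouched when a seed is given.
#' @return a [replacement_list()].
#' @examples
#' sample_null_replacements(15, seed = 1)
#' @export
sample_null_replacements <- function(n, sequence_length = 805L, seed = NULL) {
  n <- as.integer(n)
  if (n > sequence_length)
    stop(sprintf("n (%d) exceeds sequence length (%d)", n, sequence_length),
         call. = FALSE)
  pairs <- enumerate_pairs()
  with_local_seed(seed, {
    sites <- if (n) sort(sample.int(sequence_length, n)) else integer()
    idx <- if (n) sample.int(nrow(pairs), n, replace = TRUE) else integer()
    replacement_list(sites, pairs$from[idx], pairs$to[idx], sequence_length,
                     labels = c("null_a", "null_b"),
                     filter = c(matches = sequence_length - n,
                                mismatches = n, gap = 0L, nonstandard = 0L))
  })
}

# pair-sampling weights of the biased model: exponential tilt of the
# uniform law, exp(bias * delta / sd(deltas)); bias = 0 is exactly null
biased_weights <- function(scale, bias,
                           convention = c("to_minus_from", "from_minus_to")) {
  if (bias < 0) stop("bias must be >= 0", call. = FALSE)
  z <- enumerate_deltas(scale, match.arg(convention))
  w <- exp(bias * z / stats::sd(z))
  w / sum(w)
}

#' Sample replacements from the biased (directional) model
#'
#' Like [sample_null_replacements()] but residue pairs are drawn with
#' probability proportional to `exp(bias * delta / sd(delta))` under
#' `scale` -- an exponential tilt whose acceptance weight increases with
#' the delta. `bias = 0` reduces exactly to the null; the expected mean
#' delta is strictly increasing in `bias`. Used to check the power of
#' the directional test.
#'
#' @inheritParams sample_null_replacements
#' @param scale a [prop_scale()] defining the biased direction.
#' @param bias non-negative tilt strength.
#' @inheritParams property_delta
#' @return a [replacement_list()].
#' @export
sample_biased_replacements <- function(n, scale, bias = 0,
                                       sequence_length = 805L, seed = NULL,
                                       convention = c("to_minus_from",
                                                      "from_minus_to")) {
  n <- as.integer(n)
  convention <- match.arg(convention)
  if (n > sequence_length)
    stop(sprintf("n (%d) exceeds sequence length (%d)", n, sequence_length),
         call. = FALSE)
  pairs <- enumerate_pairs()
  w <- biased_weights(scale, bias, convention)
  with_local_seed(seed, {
    sites <- if (n) sort(sample.int(sequence_length, n)) else integer()
    idx <- if (n) sample.int(nrow(pairs), n, replace = TRUE, prob = w)
           else integer()
    replacement_list(sites, pairs$from[idx], pairs$to[idx], sequence_length,
                     labels = c("biased_a", "biased_b"),
                     filter = c(matches = sequence_length - n,
                                mismatches = n, gap = 0L, nonstandard = 0L))
  })
}
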