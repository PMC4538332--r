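# Seeded synthetic protein corpora.
#
# Generates random protein sequences over the 20 standard amino acids with a
# configurable length law, so search and load-balance behaviour can be
# studied without any external database.  The log-normal default (median
# around 300 residues, dispersion 0.45 on the log scale) mimics the
# right-skewed length distribution of curated protein databases; residue
# composition is uniform, which real proteomes are not — see the package
# vignette for what that does and does not exercise.

#' Generate a synthetic protein database
#'
#' @param n Number of sequences (>= 1).
#' @param law Length distribution: `"lognormal"` (default) or `"uniform"`.
#' @param min_len,max_len Inclusive length bounds; log-normal draws are
#'   clamped into them, uniform draws are taken over them.
#' @param meanlog,sdlog Log-normal parameters (log residues).
#' @param seed Optional integer seed for reproducibility.
#' @param prefix Identifier prefix; sequences are named
#'   `<prefix>_000001`, ...
#' @return A [sequence_db()].
#' @export
#' @examples
#' db <- synth_protein_db(10, law = "uniform", min_len = 50, max_len = 60,
#'                        seed = 1)
#' range(db$lengths)
synth_protein_db <- function(n, law = c("lognormal", "uniform"),
                             min_len = 25L, max_len = 2000L,
                             meanlog = log(300), sdlog = 0.45,
                             seed = NULL, prefix = "synth") {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("'n' must be a single integer >= 1")
  }
  law <- match.arg(law)
  if (min_len < 1 || max_len < min_len) stop("invalid length bounds")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- as.integer(n)
  lengths <- switch(law,
    uniform = sample(seq.int(min_len, max_len), n, replace = TRUE),
    lognormal = pmin(pmax(as.integer(round(stats::rlnorm(n, meanlog, sdlog))),
                          as.integer(min_len)), as.integer(max_len))
  )
  aa <- canonical_residues()
  residues <- vapply(lengths, function(L) {
    paste(sample(aa, L, replace = TRUE), collapse = "")
  }, "")
  ids <- sprintf("%s_%06d", prefix, seq_len(n))
  sequence_db(ids, residues)
}
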