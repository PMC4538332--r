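# Independent desk-scale oracle: enumerates local alignments recursively,
# with no dynamic-programming matrix shared with the engines under test.

# Best *global* affine-gap alignment score of q vs s, by recursion over
# alignment columns.  state: 0 = start/after match, 1 = inside gap in query
# (consuming subject), 2 = inside gap in subject (consuming query).
brute_global_affine <- function(q, s, score_fn, rho, sigma) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    if (i > length(qc) && j > length(sc)) return(0)
    best <- -1e9
    if (i <= length(qc) && j <= length(sc)) {
      best <- max(best, score_fn(qc[i], sc[j]) + rec(i + 1L, j + 1L, 0L))
    }
    if (j <= length(sc)) {
      cost <- if (state == 1L) sigma else rho + sigma
      best <- max(best, -cost + rec(i, j + 1L, 1L))
    }
    if (i <= length(qc)) {
      cost <- if (state == 2L) sigma else rho + sigma
      best <- max(best, -cost + rec(i + 1L, j, 2L))
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, 0L)
}

# Best local score: max over all substring pairs of their global score,
# floored at zero.
brute_local_sw <- function(q, s, score_fn, rho, sigma) {
  best <- 0
  nq <- nchar(q); ns <- nchar(s)
  for (i1 in seq_len(nq)) for (i2 in i1:nq) {
    for (j1 in seq_len(ns)) for (j2 in j1:ns) {
      best <- max(best, brute_global_affine(substr(q, i1, i2),
                                            substr(s, j1, j2),
                                            score_fn, rho, sigma))
    }
  }
  best
}

# Toy match/mismatch matrix over a small alphabet, as a sub_matrix object.
toy_matrix <- function(letters = c("A", "C", "G", "T"), match = 3L,
                       mismatch = -3L, name = "toy") {
  n <- length(letters)
  m <- matrix(mismatch, n, n, dimnames = list(letters, letters))
  diag(m) <- match
  substitution_matrix(m, name = name)
}

random_protein <- function(len) {
  paste(sample(canonical_residues(), len, replace = TRUE), collapse = "")
}
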