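# Smith-Waterman local alignment: reference engine, tiled engine, and the
# batched database driver.
#
# Affine gaps: a gap of length g costs rho + g * sigma (open penalty rho,
# per-residue extension sigma).  Both engines compute the optimal local
# alignment score only; no traceback.

#' Affine gap penalty model
#'
#' @param rho Gap-open penalty (non-negative integer); a gap of length g
#'   costs `rho + g * sigma`.
#' @param sigma Gap-extension penalty per gap residue (integer >= 1).
#' @return Object of class `gap_model`.
#' @export
gap_model <- function(rho = 10L, sigma = 2L) {
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho != round(rho)) {
    stop("'rho' must be a single non-negative integer")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 1 ||
      sigma != round(sigma)) {
    stop("'sigma' must be a single integer >= 1")
  }
  structure(list(rho = as.integer(rho), sigma = as.integer(sigma)),
            class = "gap_model")
}

#' Tile geometry for the tiled engine
#'
#' A tile covers `K` subject residues by `P` query residues.  `P` must be a
#' multiple of 4 because the packed query profile delivers 4 scores per
#' fetch; both default to 4 to keep the register carry model small.
#'
#' @param K Subject-axis tile width (>= 1).
#' @param P Query-axis tile height (positive multiple of 4).
#' @return Object of class `tile_config`.
#' @export
tile_config <- function(K = 4L, P = 4L) {
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K != round(K)) {
    stop("'K' must be a single integer >= 1")
  }
  if (!is.numeric(P) || length(P) != 1L || P < 4 || P %% 4 != 0) {
    stop("'P' must be a positive multiple of 4")
  }
  structure(list(K = as.integer(K), P = as.integer(P)), class = "tile_config")
}

#' Reference Smith-Waterman score (naive full-matrix Gotoh)
#'
#' Computes the optimal local alignment score by the three-matrix Gotoh
#' recurrences over the full L1 x L2 grid.  This is the oracle the tiled
#' engine is checked against, and the fallback path for queries that exceed
#' the shared-memory budget and for subjects beyond the length threshold.
#'
#' @param query,subject Residue strings (or single-record databases).
#'   `subject` may be empty (`""`), giving score 0.
#' @param matrix A [substitution_matrix()].
#' @param gaps A [gap_model()].
#' @return Non-negative integer score.
#' @export
#' @examples
#' b62 <- load_matrix("blosum62")
#' sw_reference("A", "A", b62, gap_model(10, 2))  # 4
sw_reference <- function(query, subject, matrix, gaps = gap_model()) {
  stopifnot(inherits(matrix, "sub_matrix"), inherits(gaps, "gap_model"))
  q <- as_residue_string(query)
  s <- as_residue_string(subject)
  if (nchar(q) == 0L) stop("empty query")
  if (nchar(s) == 0L) return(0L)
  c_sw_reference(residues_to_idx(q, matrix), residues_to_idx(s, matrix),
                 matrix$scores, gaps$rho, gaps$sigma)
}

# Residue indices of one interleaved lane, pad symbol mapped to the extra
# profile column (n_letters + 1).
layout_to_idx <- function(layout, matrix) {
  idx <- matrix$alphabet$index[layout$flat]
  pad_idx <- length(matrix$alphabet$letters) + 1L
  idx[layout$flat == matrix$alphabet$pad_symbol] <- pad_idx
  if (anyNA(idx)) {
    if ("X" %in% matrix$alphabet$letters) {
      idx[is.na(idx)] <- matrix$alphabet$index[["X"]]
    } else {
      stop("layout contains residues outside the matrix alphabet")
    }
  }
  as.integer(idx)
}

#' Tiled Smith-Waterman score with explicit memory modeling
#'
#' Scores one query/subject pair by the tiled engine: the DP matrix is cut
#' into `K x P` tiles traversed in column-major order (tiles sharing the
#' same K subject residues are processed top to bottom before moving
#' right).  Within a tile each of the P query residues is aligned against
#' the K subject residues left to right.  Row-boundary values of H and F
#' are carried in a K-register model; column-boundary values of H and E
#' cross tile columns only through a per-lane column buffer that stands for
#' per-thread shared memory (2 bytes per cell, matrices H and E).  The
#' score is bit-identical to [sw_reference()] on every input.
#'
#' @param query Residue string (or single-record database).
#' @param subject Residue string; ignored when `layout`/`lane` are given.
#' @param matrix A [substitution_matrix()].
#' @param gaps A [gap_model()].
#' @param tiles A [tile_config()].
#' @param budget Optional [memory_budget()]; when supplied, queries longer
#'   than `budget$q_max` are rejected (the batch driver dispatches those to
#'   [sw_reference()] instead).
#' @param profile Optional precomputed [build_query_profile()] for `query`
#'   (must use `P = tiles$P` and the same matrix).
#' @param layout,lane Optional: score lane `lane` (1-based) of an
#'   [interleave_group()] layout instead of `subject`.
#' @return List of class `sw_tiled_result`: `score` and `stats`
#'   (`buffer_reads`, `buffer_writes`, `peak_buffer_bytes`, `cells`,
#'   `tile_cols`, `overflow` — an advisory flag raised when a buffered
#'   value leaves the signed 16-bit range implied by 2-byte cells).
#' @export
#' @examples
#' b62 <- load_matrix("blosum62")
#' sw_tiled("A", "A", b62, gap_model(10, 2))$score  # 4
sw_tiled <- function(query, subject = NULL, matrix, gaps = gap_model(),
                     tiles = tile_config(), budget = NULL, profile = NULL,
                     layout = NULL, lane = NULL) {
  stopifnot(inherits(matrix, "sub_matrix"), inherits(gaps, "gap_model"),
            inherits(tiles, "tile_config"))
  q <- as_residue_string(query)
  if (nchar(q) == 0L) stop("empty query")
  if (!is.null(budget)) {
    stopifnot(inherits(budget, "memory_budget"))
    if (nchar(q) > budget$q_max) {
      stop("query length ", nchar(q), " exceeds the tiled-path budget Q_max = ",
           budget$q_max, "; use sw_reference()")
    }
  }
  if (is.null(profile)) {
    profile <- build_query_profile(q, matrix, P = tiles$P)
  } else {
    stopifnot(inherits(profile, "query_profile"))
    if (profile$P != tiles$P) stop("profile P does not match tile config")
    if (profile$matrix_name != matrix$name) {
      stop("profile was built from a different matrix")
    }
  }
  if (is.null(layout)) {
    s <- as_residue_string(subject)
    layout <- interleave_group(s, K = tiles$K, group_size = 1L)
    lane <- 1L
  } else {
    stopifnot(inherits(layout, "interleaved_layout"),
              is.numeric(lane), length(lane) == 1L,
              lane >= 1L, lane <= layout$group_size)
    if (layout$padded_length %% tiles$K != 0L) {
      stop("layout was padded for a different tile width K")
    }
  }
  res <- c_sw_tiled(profile$scores, layout_to_idx(layout, matrix),
                    as.integer(lane) - 1L, layout$group_size,
                    layout$padded_length, tiles$K, tiles$P,
                    gaps$rho, gaps$sigma)
  structure(
    list(score = res$score,
         stats = res[c("buffer_reads", "buffer_writes", "peak_buffer_bytes",
                       "cells", "tile_cols", "overflow")]),
    class = "sw_tiled_result"
  )
}

#' @export
print.sw_tiled_result <- function(x, ...) {
  cat(sprintf(
    "<sw_tiled_result> score=%d (cells=%g, buffer r/w=%g/%g, peak=%g B%s)\n",
    x$score, x$stats$cells, x$stats$buffer_reads, x$stats$buffer_writes,
    x$stats$peak_buffer_bytes,
    if (isTRUE(x$stats$overflow)) ", 16-bit overflow" else ""))
  invisible(x)
}

#' Search a database with one query
#'
#' The intertask driver: the database is sorted ascending by length,
#' partitioned into consecutive 32-lane groups, and each group is
#' interleaved so lock-step lanes read coalesced memory.  When the query
#' fits the shared-memory budget (`query length <= Q_max = floor(S / (4 T))`)
#' each lane is scored by the tiled engine over the interleaved layout;
#' otherwise, and for subjects longer than `length_threshold`, the
#' reference engine is used.  Results are ranked by descending score, ties
#' broken by subject id ascending.
#'
#' @param query Residue string (or single-record database).
#' @param db A [sequence_db()].
#' @param matrix A [substitution_matrix()].
#' @param gaps A [gap_model()].
#' @param exec_cfg An [exec_config()] (shared memory, threads per block,
#'   warp size, length threshold).
#' @param tiles A [tile_config()].
#' @param verbose Log the dispatch decision and budget arithmetic.
#' @return `data.frame` with columns `rank`, `subject_id`,
#'   `subject_length`, `score`, plus attribute `"path"`
#'   (`"tiled_short_query"` or `"reference_fallback"`).
#' @export
sw_batch <- function(query, db, matrix, gaps = gap_model(),
                     exec_cfg = exec_config(), tiles = tile_config(),
                     verbose = FALSE) {
  stopifnot(inherits(db, "sequence_db"), inherits(matrix, "sub_matrix"),
            inherits(exec_cfg, "exec_config"))
  q <- as_residue_string(query)
  budget <- memory_budget(exec_cfg$shared_bytes, exec_cfg$threads_per_block)
  path <- dispatch(nchar(q), budget, verbose = verbose)

  sorted <- sort_by_length(db)
  scores <- integer(sorted$n)

  if (path == "tiled_short_query") {
    profile <- build_query_profile(q, matrix, P = tiles$P)
    long <- sorted$lengths > exec_cfg$length_threshold
    groups <- consecutive_groups(sorted$n, exec_cfg$warp_size)
    for (grp in groups) {
      short_in_grp <- grp[!long[grp]]
      if (length(short_in_grp) > 0L) {
        layout <- interleave_group(sorted$residues[short_in_grp],
                                   K = tiles$K,
                                   group_size = exec_cfg$warp_size)
        idx <- layout_to_idx(layout, matrix)
        for (k in seq_along(short_in_grp)) {
          res <- c_sw_tiled(profile$scores, idx, k - 1L, layout$group_size,
                            layout$padded_length, tiles$K, tiles$P,
                            gaps$rho, gaps$sigma)
          scores[short_in_grp[[k]]] <- res$score
        }
      }
    }
    # intratask-size subjects: serial reference path
    for (i in which(long)) {
      scores[i] <- sw_reference(q, sorted$residues[[i]], matrix, gaps)
    }
  } else {
    for (i in seq_len(sorted$n)) {
      scores[i] <- sw_reference(q, sorted$residues[[i]], matrix, gaps)
    }
  }

  ord <- order(-scores, sorted$ids)
  out <- data.frame(
    rank = seq_len(sorted$n),
    subject_id = sorted$ids[ord],
    subject_length = sorted$lengths[ord],
    score = scores[ord],
    stringsAsFactors = FALSE
  )
  attr(out, "path") <- path
  attr(out, "q_max") <- budget$q_max
  out
}
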