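# Execution-model accounting: shared-memory budget, path dispatch, warp
# load-balance cost, and cell-update throughput.
#
# The tiled engine buffers, per thread, the H and E values of one tile-column
# boundary for every query position — 2 matrices x 2 bytes per cell = 4 bytes
# per query residue.  With S bytes of shared memory per multiprocessor split
# across T threads, the longest query the tiled path can serve is therefore
# Q_max = floor(S / (4 T)).  Cost is counted in DP cell updates, the portable
# surrogate for wall-clock time on lock-step hardware.

#' Shared memory available to one thread
#'
#' @param shared_bytes Shared memory per multiprocessor, in bytes (S > 0).
#' @param threads_per_block Threads sharing it (T > 0).
#' @return `floor(shared_bytes / threads_per_block)` bytes.  At the classic
#'   16 KiB / 256-thread configuration this is 64 bytes, i.e. 16 words.
#' @export
per_thread_shared_bytes <- function(shared_bytes, threads_per_block) {
  check_positive(shared_bytes, "shared_bytes")
  check_positive(threads_per_block, "threads_per_block")
  as.integer(shared_bytes %/% threads_per_block)
}

#' Longest query the tiled path supports
#'
#' Buffering matrices H and E at 2 bytes per cell costs 4 bytes of shared
#' memory per query residue per thread, so the budget admits queries up to
#' `floor(shared_bytes / (4 * threads_per_block))` residues.
#'
#' @inheritParams per_thread_shared_bytes
#' @return Integer Q_max (0 means the tiled path is unavailable).
#' @export
#' @examples
#' max_query_length(16384, 256)  # 16
max_query_length <- function(shared_bytes, threads_per_block) {
  check_positive(shared_bytes, "shared_bytes")
  check_positive(threads_per_block, "threads_per_block")
  as.integer(shared_bytes %/% (4 * threads_per_block))
}

check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("'", what, "' must be a single positive number")
  }
  invisible(x)
}

#' Shared-memory budget
#'
#' @inheritParams per_thread_shared_bytes
#' @return Object of class `memory_budget`: `shared_bytes`,
#'   `threads_per_block`, `bytes_per_cell` (2), `buffered_matrices` (2,
#'   H and E), and the derived `q_max`.
#' @export
memory_budget <- function(shared_bytes = 16384L, threads_per_block = 256L) {
  structure(
    list(
      shared_bytes = as.integer(shared_bytes),
      threads_per_block = as.integer(check_positive(threads_per_block,
                                                    "threads_per_block")),
      bytes_per_cell = 2L,
      buffered_matrices = 2L,
      q_max = max_query_length(shared_bytes, threads_per_block)
    ),
    class = "memory_budget"
  )
}

#' @export
print.memory_budget <- function(x, ...) {
  cat(sprintf("<memory_budget> S=%d B, T=%d threads -> Q_max=%d residues\n",
              x$shared_bytes, x$threads_per_block, x$q_max))
  invisible(x)
}

#' Execution configuration for the batch driver
#'
#' Defaults mirror a 16 KiB shared-memory multiprocessor with 256-thread
#' blocks and 32-lane warps; `length_threshold` is the intertask/intratask
#' cutoff above which subjects are scored serially by the reference engine.
#'
#' @param blocks Grid size (> 0).
#' @param threads_per_block Threads per block (> 0).
#' @param warp_size Lanes per lock-step group (fixed 32 in production use;
#'   exposed for desk-scale tests).
#' @param length_threshold Subject-length cutoff for the intertask path.
#' @param shared_bytes Shared memory per multiprocessor, bytes.
#' @return Object of class `exec_config`.
#' @export
exec_config <- function(blocks = 64L, threads_per_block = 256L,
                        warp_size = WARP_SIZE, length_threshold = 3072L,
                        shared_bytes = 16384L) {
  for (v in c(blocks = blocks, threads_per_block = threads_per_block,
              warp_size = warp_size, length_threshold = length_threshold,
              shared_bytes = shared_bytes)) {
    if (!is.numeric(v) || v <= 0) stop("all exec_config parameters must be positive")
  }
  structure(
    list(blocks = as.integer(blocks),
         threads_per_block = as.integer(threads_per_block),
         warp_size = as.integer(warp_size),
         length_threshold = as.integer(length_threshold),
         shared_bytes = as.integer(shared_bytes)),
    class = "exec_config"
  )
}

#' Choose the scoring path for a query
#'
#' The tiled short-query path is used iff the query fits the shared-memory
#' budget (`query_length <= Q_max`); otherwise the full-matrix reference
#' engine serves the query.
#'
#' @param query_length Query length in residues (>= 1).
#' @param budget A [memory_budget()].
#' @param verbose Log the decision with both numbers.
#' @return `"tiled_short_query"` or `"reference_fallback"`.
#' @export
dispatch <- function(query_length, budget, verbose = FALSE) {
  stopifnot(inherits(budget, "memory_budget"))
  if (!is.numeric(query_length) || length(query_length) != 1L ||
      query_length < 1) {
    stop("'query_length' must be a single integer >= 1")
  }
  path <- if (query_length <= budget$q_max) "tiled_short_query"
          else "reference_fallback"
  if (verbose) {
    message(sprintf(
      "dispatch: query_length=%d, S=%d, T=%d, Q_max=%d -> %s",
      as.integer(query_length), budget$shared_bytes,
      budget$threads_per_block, budget$q_max, path))
  }
  path
}

#' Warp load-balance cost report
#'
#' Models the intertask cost of a database ordering: lanes are filled with
#' consecutive subject lengths in runs of `warp_size` (the last warp padded
#' with zero-length lanes), each lane costs `query_length * subject_length`
#' cell updates, and a warp is busy until its slowest lane finishes.
#' `paid_cells` is the lock-step cost actually spent
#' (`warp_size * sum(makespans)`); `efficiency` compares it with the useful
#' work `total_cells`.
#'
#' @param lengths Subject lengths in warp order (non-negative integers,
#'   non-empty).
#' @param query_length Query length in residues (> 0).
#' @param warp_size Lanes per warp.
#' @return Object of class `warp_cost_report`: `per_warp_makespan`,
#'   `total_cells`, `paid_cells`, `efficiency`, `n_warps`, `warp_size`,
#'   `query_length`.
#' @export
#' @examples
#' warp_makespan(c(10, 30), query_length = 5, warp_size = 2)$efficiency  # 2/3
warp_makespan <- function(lengths, query_length, warp_size = WARP_SIZE) {
  if (length(lengths) == 0L) stop("'lengths' must be non-empty")
  if (any(lengths < 0)) stop("'lengths' must be non-negative")
  check_positive(query_length, "query_length")
  check_positive(warp_size, "warp_size")
  warp_size <- as.integer(warp_size)
  n_warps <- ceiling(length(lengths) / warp_size)
  padded <- c(as.numeric(lengths),
              numeric(n_warps * warp_size - length(lengths)))
  lane_cost <- query_length * matrix(padded, nrow = warp_size)
  makespan <- apply(lane_cost, 2L, max)
  total <- query_length * sum(as.numeric(lengths))
  paid <- warp_size * sum(makespan)
  structure(
    list(per_warp_makespan = makespan,
         total_cells = total,
         paid_cells = paid,
         efficiency = if (paid > 0) total / paid else NA_real_,
         n_warps = as.integer(n_warps),
         warp_size = warp_size,
         query_length = query_length),
    class = "warp_cost_report"
  )
}

#' @export
print.warp_cost_report <- function(x, ...) {
  cat(sprintf(
    "<warp_cost_report> %d warp(s) of %d: total=%g, paid=%g cells, efficiency=%.3f\n",
    x$n_warps, x$warp_size, x$total_cells, x$paid_cells, x$efficiency))
  invisible(x)
}

#' Giga cell updates per second
#'
#' @param total_cells DP cells computed.
#' @param seconds Elapsed seconds (> 0).
#' @return `total_cells / seconds / 1e9`.
#' @export
gcups <- function(total_cells, seconds) {
  if (!is.numeric(seconds) || length(seconds) != 1L || seconds <= 0) {
    stop("'seconds' must be a single positive number")
  }
  if (!is.numeric(total_cells) || length(total_cells) != 1L ||
      total_cells < 0) {
    stop("'total_cells' must be a single non-negative number")
  }
  total_cells / seconds / 1e9
}
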