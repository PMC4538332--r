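# FASTA I/O, ascending length sort, and the 32-lane interleaved layout.
#
# Lock-step lanes (a GPU warp, or SIMD lanes generally) read the i-th residue
# of 32 different subject sequences in one transaction only if those residues
# are adjacent in memory.  The layout below stores residue i of lane k at flat
# position 32*i + k, after sorting the database ascending by length so that
# the 32 sequences sharing a warp are of similar length.

#' Construct a sequence database
#'
#' @param ids Character vector of sequence identifiers (first header token).
#' @param residues Character vector of residue strings (upper-cased).
#' @param headers Optional full FASTA headers (defaults to `ids`).
#' @return Object of class `sequence_db`: a list with `ids`, `residues`,
#'   `headers`, `lengths`, `original_index` (0-based position in the input),
#'   `n`, and `sorted_flag`.
#' @export
sequence_db <- function(ids, residues, headers = ids) {
  stopifnot(is.character(ids), is.character(residues),
            length(ids) == length(residues), length(headers) == length(ids))
  if (length(ids) == 0L) stop("empty database")
  residues <- toupper(residues)
  lengths <- nchar(residues)
  if (any(lengths == 0L)) {
    stop("record(s) with empty sequence: ",
         paste(ids[lengths == 0L], collapse = ", "))
  }
  structure(
    list(
      ids = ids,
      residues = residues,
      headers = headers,
      lengths = as.integer(lengths),
      original_index = seq_along(ids) - 1L,
      n = length(ids),
      sorted_flag = !is.unsorted(lengths)
    ),
    class = "sequence_db"
  )
}

#' @export
print.sequence_db <- function(x, ...) {
  cat(sprintf("<sequence_db> %d sequence(s), lengths %d..%d%s\n",
              x$n, min(x$lengths), max(x$lengths),
              if (x$sorted_flag) ", sorted by length" else ""))
  invisible(x)
}

# Accept a residue string, a sequence_db of size one, or (db, i) extraction.
as_residue_string <- function(x) {
  if (inherits(x, "sequence_db")) {
    if (x$n != 1L) stop("expected a single sequence, got a database of ", x$n)
    return(x$residues[[1L]])
  }
  stopifnot(is.character(x), length(x) == 1L)
  toupper(x)
}

#' Read a FASTA file into a sequence database
#'
#' @param path Path to a FASTA file with at least one record.
#' @return A [sequence_db()] in file order, with `original_index` assigned.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA file has no records: ", path)
  headers <- names(set)
  if (is.null(headers) || any(!nzchar(trimws(headers)))) {
    stop("malformed FASTA header in ", path)
  }
  ids <- vapply(strsplit(trimws(headers), "\\s+"), `[[`, "", 1L)
  sequence_db(ids, as.character(set), headers = headers)
}

#' Write a sequence database to FASTA
#'
#' Sequences are wrapped at 60 columns; full headers are retained.
#'
#' @param db A [sequence_db()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path) {
  stopifnot(inherits(db, "sequence_db"))
  set <- Biostrings::BStringSet(db$residues)
  names(set) <- db$headers
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Sort a database ascending by sequence length
#'
#' Stable sort: ties keep input order.  Sorting puts sequences of similar
#' length into the same 32-lane group, which minimises the idle time of
#' lock-step lanes waiting for the longest sequence in their group.
#'
#' @param db A [sequence_db()].
#' @return The database reordered with non-decreasing lengths;
#'   `original_index` retains each record's position in the input file.
#' @export
sort_by_length <- function(db) {
  stopifnot(inherits(db, "sequence_db"))
  ord <- order(db$lengths)  # stable in R
  out <- db
  for (f in c("ids", "residues", "headers", "lengths", "original_index")) {
    out[[f]] <- db[[f]][ord]
  }
  out$sorted_flag <- TRUE
  out
}

# Lanes per interleaved group; mirrors the 32-thread warp.  Tests may pass
# smaller group sizes explicitly.
WARP_SIZE <- 32L

#' Interleave up to 32 sequences into a flat lane-major layout
#'
#' Residue i (0-based) of lane k is stored at flat position
#' `group_size * i + k` (0-based), so that lock-step lanes reading their
#' i-th residues touch `group_size` consecutive memory locations.  Groups
#' with fewer than `group_size` sequences are completed with empty lanes;
#' all lanes are padded with the pad sentinel to the group maximum length
#' rounded up to a multiple of the tile width `K`.
#'
#' @param seqs Character vector of residue strings (1 to `group_size`), or a
#'   [sequence_db()].
#' @param K Tile width used to round up the padded length.
#' @param group_size Number of lanes (default 32).
#' @return Object of class `interleaved_layout`: `group_size`, `flat`
#'   (character vector of single letters, length
#'   `padded_length * group_size`), `lane_lengths`, `padded_length`,
#'   `n_seqs`.
#' @export
interleave_group <- function(seqs, K = 4L, group_size = WARP_SIZE) {
  if (inherits(seqs, "sequence_db")) seqs <- seqs$residues
  stopifnot(is.character(seqs))
  if (length(seqs) < 1L) stop("empty group")
  if (length(seqs) > group_size) {
    stop("group of ", length(seqs), " exceeds group size ", group_size)
  }
  K <- as.integer(K)
  stopifnot(K >= 1L)
  group_size <- as.integer(group_size)
  n_seqs <- length(seqs)
  lane_lengths <- integer(group_size)
  lane_lengths[seq_len(n_seqs)] <- nchar(seqs)
  padded_length <- as.integer(ceiling(max(lane_lengths) / K) * K)
  flat <- rep(PAD_SYMBOL, padded_length * group_size)
  for (k in seq_len(n_seqs)) {
    chars <- strsplit(toupper(seqs[[k]]), "", fixed = TRUE)[[1L]]
    if (length(chars) > 0L) {
      # residue i (0-based) of lane k-1 (0-based) -> flat[group_size*i + (k-1)]
      flat[group_size * (seq_along(chars) - 1L) + k] <- chars
    }
  }
  structure(
    list(
      group_size = group_size,
      flat = flat,
      lane_lengths = lane_lengths,
      padded_length = padded_length,
      n_seqs = n_seqs
    ),
    class = "interleaved_layout"
  )
}

#' @export
print.interleaved_layout <- function(x, ...) {
  cat(sprintf("<interleaved_layout> %d lane(s) of %d, padded length %d\n",
              x$n_seqs, x$group_size, x$padded_length))
  invisible(x)
}

#' Recover the original sequences from an interleaved layout
#'
#' Inverse of [interleave_group()]: reads lane k's residues at flat
#' positions `group_size * i + k` up to the lane's true length.
#'
#' @param layout An [interleave_group()] layout.
#' @return Character vector of the `n_seqs` original residue strings.
#' @export
deinterleave <- function(layout) {
  stopifnot(inherits(layout, "interleaved_layout"))
  expected <- layout$padded_length * layout$group_size
  if (length(layout$flat) != expected) {
    stop("corrupted layout: flat has ", length(layout$flat),
         " symbols, expected ", expected)
  }
  vapply(seq_len(layout$n_seqs), function(k) {
    len <- layout$lane_lengths[[k]]
    if (len == 0L) return("")
    paste(layout$flat[layout$group_size * (seq_len(len) - 1L) + k],
          collapse = "")
  }, "")
}

# Split indices 1..n into consecutive runs of `group_size`.
consecutive_groups <- function(n, group_size = WARP_SIZE) {
  split(seq_len(n), (seq_len(n) - 1L) %/% group_size)
}
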