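# Substitution matrices and the packed query profile.
#
# A substitution matrix is the symmetric integer table sbt(a, b) scoring one
# residue pair; BLOSUM62 scores the 210 unordered pairs of the 20 standard
# amino acids (plus ambiguity letters B, Z, X and the stop '*').  The query
# profile precomputes sbt(query[i], a) for every query position i and alphabet
# letter a, packed in groups of P consecutive positions so the scoring engine
# fetches P scores per access instead of doing a matrix lookup per cell.

#' The 20 standard amino-acid letters
#'
#' One-letter codes of the 20 canonical amino acids, in alphabetical order.
#'
#' @return Character vector of length 20.
#' @export
canonical_residues <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Reserved sentinel for dummy/padding residues; never a matrix letter.
PAD_SYMBOL <- "?"

#' Construct a substitution matrix object
#'
#' Wraps a named, symmetric integer matrix of residue-pair scores together
#' with its alphabet.  Most users will call [load_matrix()] instead; this
#' constructor exists for custom (e.g. toy match/mismatch) matrices.
#'
#' @param scores Square integer matrix with identical row and column names
#'   (single residue letters); must be symmetric.
#' @param name Label for the matrix.
#' @return An object of class `sub_matrix` with fields `name`, `scores`
#'   (integer matrix), and `alphabet` (list with `canonical`, `extras`,
#'   `letters`, `pad_symbol`, `index` — a named integer vector mapping each
#'   letter, and the pad symbol, to a dense 1-based index).
#' @export
#' @examples
#' m <- substitution_matrix(matrix(c(3L, -3L, -3L, 3L), 2, 2,
#'                                 dimnames = list(c("A", "G"), c("A", "G"))),
#'                          name = "toy")
#' sbt_score(m, "A", "A")
substitution_matrix <- function(scores, name = "custom") {
  if (!is.matrix(scores) || nrow(scores) != ncol(scores)) {
    stop("'scores' must be a square matrix")
  }
  letters <- rownames(scores)
  if (is.null(letters) || !identical(letters, colnames(scores))) {
    stop("'scores' must have identical row and column names")
  }
  if (anyDuplicated(letters)) stop("duplicate letters in matrix alphabet")
  if (PAD_SYMBOL %in% letters) {
    stop("the pad symbol '", PAD_SYMBOL, "' cannot be a matrix letter")
  }
  if (any(scores != round(scores))) stop("non-integer entry in matrix")
  storage.mode(scores) <- "integer"
  if (!isTRUE(all.equal(scores, t(scores)))) {
    stop("substitution matrix is not symmetric")
  }
  canonical <- intersect(canonical_residues(), letters)
  extras <- setdiff(letters, canonical)
  index <- seq_along(letters)
  names(index) <- letters
  index[PAD_SYMBOL] <- length(letters) + 1L
  structure(
    list(
      name = name,
      scores = scores,
      alphabet = list(
        canonical = canonical,
        extras = extras,
        letters = letters,
        pad_symbol = PAD_SYMBOL,
        index = index
      )
    ),
    class = "sub_matrix"
  )
}

#' @export
print.sub_matrix <- function(x, ...) {
  cat(sprintf("<sub_matrix> %s: %d letters (%d canonical, %d extra)\n",
              x$name, length(x$alphabet$letters),
              length(x$alphabet$canonical), length(x$alphabet$extras)))
  invisible(x)
}

#' Load a substitution matrix
#'
#' Reads a substitution matrix either from a bundled name (`"blosum62"`,
#' `"blosum50"`) or from a file in NCBI text format: lines starting with `#`
#' are comments, the first non-comment line is the header row of alphabet
#' letters, and each following line is a letter followed by its integer score
#' row.  The table must be square and symmetric.
#'
#' @param source Bundled matrix name (case-insensitive) or path to an
#'   NCBI-format matrix file.
#' @return A [substitution_matrix()] object.
#' @export
#' @examples
#' b62 <- load_matrix("blosum62")
#' sbt_score(b62, "W", "W")  # 11
load_matrix <- function(source = "blosum62") {
  stopifnot(is.character(source), length(source) == 1L)
  bundled <- c(blosum62 = "BLOSUM62.txt", blosum50 = "BLOSUM50.txt")
  key <- tolower(source)
  if (key %in% names(bundled)) {
    path <- system.file("extdata", bundled[[key]], package = "tilesw",
                        mustWork = TRUE)
    name <- toupper(key)
  } else if (file.exists(source)) {
    path <- source
    name <- basename(source)
  } else {
    stop("unknown builtin matrix name and no such file: '", source, "'")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("matrix file has no table: ", path)
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  n <- length(header)
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  if (length(rows) != n) {
    stop("matrix file is not square: ", n, " header letters but ",
         length(rows), " rows")
  }
  scores <- matrix(NA_integer_, n, n, dimnames = list(header, header))
  for (r in rows) {
    if (length(r) != n + 1L) stop("malformed matrix row: ", paste(r, collapse = " "))
    dbl <- suppressWarnings(as.numeric(r[-1L]))
    if (anyNA(dbl) || any(dbl != round(dbl))) {
      stop("non-integer entry in matrix row '", r[[1L]], "'")
    }
    vals <- as.integer(dbl)
    if (!(r[[1L]] %in% header)) stop("row letter '", r[[1L]], "' not in header")
    scores[r[[1L]], ] <- vals
  }
  substitution_matrix(scores, name = name)
}

#' Score one residue pair
#'
#' @param matrix A [substitution_matrix()] object.
#' @param a,b Single residue letters.
#' @return Integer score sbt(a, b).
#' @export
sbt_score <- function(matrix, a, b) {
  stopifnot(inherits(matrix, "sub_matrix"))
  if (!(a %in% matrix$alphabet$letters)) stop("unknown letter '", a, "'")
  if (!(b %in% matrix$alphabet$letters)) stop("unknown letter '", b, "'")
  matrix$scores[a, b]
}

#' Count unordered residue pairs
#'
#' Number of unordered letter pairs, including identical pairs, for an
#' alphabet of `n` letters: n(n+1)/2.  For the 20 standard amino acids this
#' is the familiar 210 substitution pairs a protein scoring table records.
#'
#' @param n Alphabet size (>= 1).
#' @return Integer pair count.
#' @export
#' @examples
#' count_unordered_pairs(20)  # 210
count_unordered_pairs <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("'n' must be a single integer >= 1")
  }
  as.integer(n * (n + 1) / 2)
}

# Map a residue string to dense alphabet indices, remapping unknown letters
# to 'X' when the matrix provides it (standard ambiguity letter), else error.
residues_to_idx <- function(residues, matrix) {
  chars <- strsplit(toupper(residues), "", fixed = TRUE)[[1L]]
  idx <- matrix$alphabet$index[chars]
  if (anyNA(idx)) {
    if ("X" %in% matrix$alphabet$letters) {
      idx[is.na(idx)] <- matrix$alphabet$index[["X"]]
    } else {
      bad <- unique(chars[is.na(idx)])
      stop("residue(s) not in matrix alphabet and no 'X' to remap to: ",
           paste(bad, collapse = ", "))
    }
  }
  unname(idx)
}

# Score assigned to any cell involving a pad/dummy residue: large negative so
# a padded cell can never lift H above 0, small enough to never wrap 32-bit
# arithmetic.
PAD_SCORE <- -1048576L

#' Build a packed query profile
#'
#' Precomputes, for every query position i, the score row
#' `sbt(query[i], a)` over all alphabet letters a, and packs the rows in
#' groups of `P` consecutive positions (the final group padded with dummy
#' positions).  The profile also carries one extra column for the pad
#' sentinel so padded subject residues score `PAD_SCORE` everywhere.
#'
#' @param query Query residue string, or a single-record object from
#'   [read_fasta()].
#' @param matrix A [substitution_matrix()] object.
#' @param P Group size (query positions per packed group); must be a
#'   positive multiple of 4.
#' @return An object of class `query_profile`: `query` (index vector),
#'   `query_length`, `P`, `n_groups`, `padded_length`
#'   (`n_groups * P`), `scores` (integer matrix `padded_length` x
#'   `(n_letters + 1)`; last column is the pad-residue column; padded rows
#'   hold the padding score), `pad_score`, and `matrix_name`.
#' @export
#' @examples
#' b62 <- load_matrix("blosum62")
#' prof <- build_query_profile("AW", b62)
#' prof$scores[2, "W"]  # 11
build_query_profile <- function(query, matrix, P = 4L) {
  stopifnot(inherits(matrix, "sub_matrix"))
  if (!is.numeric(P) || length(P) != 1L || P < 4 || P %% 4 != 0) {
    stop("'P' must be a positive multiple of 4")
  }
  P <- as.integer(P)
  residues <- as_residue_string(query)
  if (nchar(residues) == 0L) stop("empty query")
  qidx <- residues_to_idx(residues, matrix)
  L1 <- length(qidx)
  n_groups <- as.integer(ceiling(L1 / P))
  padded <- n_groups * P
  letters <- matrix$alphabet$letters
  prof <- matrix(PAD_SCORE, nrow = padded, ncol = length(letters) + 1L,
                 dimnames = list(NULL, c(letters, matrix$alphabet$pad_symbol)))
  prof[seq_len(L1), seq_along(letters)] <- matrix$scores[qidx, , drop = FALSE]
  structure(
    list(
      query = qidx,
      query_length = L1,
      P = P,
      n_groups = n_groups,
      padded_length = padded,
      scores = prof,
      pad_score = PAD_SCORE,
      matrix_name = matrix$name
    ),
    class = "query_profile"
  )
}

#' @export
print.query_profile <- function(x, ...) {
  cat(sprintf("<query_profile> L1=%d, P=%d, %d group(s), matrix %s\n",
              x$query_length, x$P, x$n_groups, x$matrix_name))
  invisible(x)
}

#' Fetch the packed scores of one profile group
#'
#' Returns the `P` consecutive query-position scores of group `group_index`
#' against one alphabet letter, in query order — the vectorised access the
#' scoring engine performs once per subject residue per tile instead of `P`
#' separate matrix lookups.
#'
#' @param profile A [build_query_profile()] object.
#' @param group_index 1-based group index (`1 .. n_groups`).
#' @param letter Single alphabet letter (or the pad symbol).
#' @return Integer vector of length `P`; positions past the true query
#'   length carry the padding score.
#' @export
fetch_packed_scores <- function(profile, group_index, letter) {
  stopifnot(inherits(profile, "query_profile"))
  if (!is.numeric(group_index) || length(group_index) != 1L ||
      group_index < 1 || group_index > profile$n_groups) {
    stop("'group_index' out of range 1..", profile$n_groups)
  }
  if (!(letter %in% colnames(profile$scores))) {
    stop("unknown letter '", letter, "'")
  }
  g <- as.integer(group_index)
  rows <- ((g - 1L) * profile$P + 1L):(g * profile$P)
  unname(profile$scores[rows, letter])
}
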