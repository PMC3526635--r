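#' RNA sequences
#'
#' Construct a validated RNA sequence.  DNA-style `T` is normalized to `U`
#' and lowercase letters are upper-cased; any other character is an error.
#'
#' @param x A single string over the alphabet `A`, `C`, `G`, `U` (or `T`).
#'   An existing `rna_sequence` is passed through (with `id` updated when
#'   supplied).
#' @param id Text label for the sequence.
#' @return An object of class `rna_sequence`: a list with elements `id`,
#'   `seq` (the normalized residue string) and `n` (its length).
#' @examples
#' rna_sequence("gauTacc", id = "toy")
#' @export
rna_sequence <- function(x, id = NULL) {
  if (inherits(x, "rna_sequence")) {
    if (!is.null(id)) x$id <- id
    return(x)
  }
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort("`x` must be a single string.")
  }
  s <- chartr("tT", "uU", x)
  s <- toupper(gsub("[[:space:]]", "", s))
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "U"))
  if (length(bad)) {
    abort(sprintf("invalid residue '%s' at position %d (alphabet is A/C/G/U, T accepted)",
                  chars[bad[1L]], bad[1L]))
  }
  if (length(chars) < 1L) abort("sequence must contain at least one residue")
  structure(list(id = if (is.null(id)) "seq" else id, seq = s, n = length(chars)),
            class = "rna_sequence")
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("<rna_sequence> %s (%d nt)\n%s\n", x$id, x$n, x$seq))
  invisible(x)
}

# residue characters as a vector
seq_chars <- function(seq) strsplit(seq$seq, "", fixed = TRUE)[[1L]]

# residues coded A=1 C=2 G=3 U=4
seq_codes <- function(seq) {
  match(seq_chars(seq), c("A", "C", "G", "U"))
}

#' Base-pairing rule
#'
#' The set of admissible nucleotide pairs.  The default is the six
#' Watson-Crick and wobble pairs: A-U, C-G and G-U in either orientation.
#'
#' @param allowed Character vector of unordered pairs, e.g. `c("AU","CG","GU")`.
#' @return An object of class `base_pair_rule`.
#' @export
base_pair_rule <- function(allowed = c("AU", "CG", "GU")) {
  allowed <- toupper(allowed)
  if (!all(nchar(allowed) == 2L)) abort("each entry must name two nucleotides, e.g. \"AU\"")
  both <- unique(c(allowed, vapply(allowed, function(p) {
    paste0(substr(p, 2, 2), substr(p, 1, 1))
  }, character(1L))))
  structure(list(ordered = both), class = "base_pair_rule")
}

# n x n logical matrix: can positions (l, j) pair under rule? (no theta here)
pairing_matrix <- function(seq, rule = base_pair_rule()) {
  chars <- seq_chars(seq)
  n <- seq$n
  key <- outer(chars, chars, paste0)
  matrix(key %in% rule$ordered, n, n)
}

#' Secondary structures
#'
#' A pseudoknot-free set of base pairs on a sequence of length `n`, each pair
#' `(i, j)` separated by more than `theta` positions (`j - i > theta`, i.e. at
#' least `theta` unpaired nucleotides in a hairpin loop).
#'
#' @param pairs A two-column integer matrix of 1-based pairs (i < j), or an
#'   empty matrix / NULL for the empty structure.
#' @param n Sequence length the structure annotates.
#' @param theta Minimum number of unpaired nucleotides enclosed by a hairpin
#'   pair; default 3.
#' @return An object of class `secondary_structure` with elements `pairs`
#'   (ordered two-column matrix), `partner` (integer vector, `NA` when
#'   unpaired), `n` and `theta`.
#' @examples
#' secondary_structure(rbind(c(1, 5)), n = 5)
#' @export
secondary_structure <- function(pairs = NULL, n, theta = 3L) {
  n <- as.integer(n)
  theta <- as.integer(theta)
  if (n < 1L) abort("`n` must be positive")
  if (is.null(pairs) || length(pairs) == 0L) {
    pairs <- matrix(integer(0), 0L, 2L)
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs)) {
    swap <- pairs[, 1L] > pairs[, 2L]
    pairs[swap, ] <- pairs[swap, 2:1]
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
    if (any(pairs < 1L | pairs > n)) abort("pair index out of range 1..n")
    if (any(pairs[, 2L] - pairs[, 1L] <= theta)) {
      bad <- which(pairs[, 2L] - pairs[, 1L] <= theta)[1L]
      abort(sprintf("pair (%d,%d) violates the minimum hairpin size theta=%d",
                    pairs[bad, 1L], pairs[bad, 2L], theta))
    }
    idx <- c(pairs)
    if (anyDuplicated(idx)) {
      abort(sprintf("position %d occurs in more than one pair", idx[duplicated(idx)][1L]))
    }
    if (nrow(pairs) > 1L) {
      for (a in seq_len(nrow(pairs) - 1L)) {
        i <- pairs[a, 1L]; j <- pairs[a, 2L]
        b <- (a + 1L):nrow(pairs)
        cross <- pairs[b, 1L, drop = TRUE] < j & pairs[b, 2L, drop = TRUE] > j  # sorted: k > i
        if (any(cross)) {
          w <- b[which(cross)[1L]]
          abort(sprintf("pairs (%d,%d) and (%d,%d) cross (pseudoknots are not allowed)",
                        i, j, pairs[w, 1L], pairs[w, 2L]))
        }
      }
    }
  }
  partner <- rep(NA_integer_, n)
  if (nrow(pairs)) {
    partner[pairs[, 1L]] <- pairs[, 2L]
    partner[pairs[, 2L]] <- pairs[, 1L]
  }
  structure(list(pairs = pairs, partner = partner, n = n, theta = theta),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> n=%d, %d pairs, theta=%d\n%s\n",
              x$n, nrow(x$pairs), x$theta, format_dot_bracket(x)))
  invisible(x)
}

#' Parse and render dot-bracket notation
#'
#' `parse_dot_bracket()` converts a string of `.`, `(` and `)` into a
#' [secondary_structure()]; `format_dot_bracket()` is its inverse.
#'
#' @param text Dot-bracket string.
#' @param theta Minimum hairpin size enforced on the parsed pairs.
#' @return A `secondary_structure` (resp. a string).
#' @examples
#' parse_dot_bracket("((...))")
#' format_dot_bracket(parse_dot_bracket("(...)"))
#' @export
parse_dot_bracket <- function(text, theta = 3L) {
  if (inherits(text, "secondary_structure")) return(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c(".", "(", ")"))
  if (length(bad)) {
    abort(sprintf("invalid character '%s' at position %d (expected '.', '(' or ')')",
                  chars[bad[1L]], bad[1L]))
  }
  stack <- integer(0)
  pairs <- matrix(integer(0), 0L, 2L)
  for (pos in seq_along(chars)) {
    if (chars[pos] == "(") {
      stack <- c(stack, pos)
    } else if (chars[pos] == ")") {
      if (!length(stack)) abort(sprintf("unmatched ')' at position %d", pos))
      pairs <- rbind(pairs, c(stack[length(stack)], pos))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) abort(sprintf("unmatched '(' at position %d", stack[length(stack)]))
  secondary_structure(pairs, n = length(chars), theta = theta)
}

#' @rdname parse_dot_bracket
#' @param S A `secondary_structure`.
#' @export
format_dot_bracket <- function(S) {
  out <- rep(".", S$n)
  if (nrow(S$pairs)) {
    out[S$pairs[, 1L]] <- "("
    out[S$pairs[, 2L]] <- ")"
  }
  paste(out, collapse = "")
}

# fast symmetric-difference size between two pair matrices on length n
pair_sets_distance <- function(p1, p2, n) {
  k1 <- (p1[, 1L] - 1) * n + p1[, 2L]
  k2 <- (p2[, 1L] - 1) * n + p2[, 2L]
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Base-pair distance between two structures
#'
#' The number of base pairs present in exactly one of the two structures
#' (the size of the symmetric difference of their pair sets).
#'
#' @param S,T `secondary_structure` objects annotating the same length.
#' @return A non-negative integer; zero iff the structures are equal.
#' @examples
#' bp_distance(parse_dot_bracket("(...)"), parse_dot_bracket("....."))
#' @export
bp_distance <- function(S, T) {
  if (S$n != T$n) abort(sprintf("structures annotate different lengths (%d vs %d)", S$n, T$n))
  pair_sets_distance(S$pairs, T$pairs, S$n)
}

#' Restrict a structure to an interval
#'
#' Keeps exactly the pairs `(x, y)` with `i <= x < y <= j`.  The result is
#' re-indexed on the same coordinate system (length `n` unchanged).
#'
#' @param S A `secondary_structure`.
#' @param i,j 1-based closed interval bounds.
#' @export
restrict_structure <- function(S, i, j) {
  if (i < 1L || j > S$n || i > j) abort(sprintf("interval [%d,%d] out of range 1..%d", i, j, S$n))
  keep <- S$pairs[, 1L] >= i & S$pairs[, 2L] <= j
  secondary_structure(S$pairs[keep, , drop = FALSE], n = S$n, theta = S$theta)
}

#' Upper bound on the reachable base-pair distance
#'
#' No structure on `n` nucleotides can lie further from the reference than
#' `|S*| + floor((n - theta) / 2)`: every reference pair can be absent and at
#' most `floor((n - theta)/2)` novel pairs can be formed under the minimum
#' hairpin size.
#'
#' @param Sstar Reference `secondary_structure` (or a pair count).
#' @param n Sequence length; defaults to `Sstar$n`.
#' @param theta Minimum hairpin size; defaults to `Sstar$theta`.
#' @return Integer bound, always `< n`.
#' @export
max_distance_bound <- function(Sstar, n = NULL, theta = NULL) {
  if (inherits(Sstar, "secondary_structure")) {
    npairs <- nrow(Sstar$pairs)
    if (is.null(n)) n <- Sstar$n
    if (is.null(theta)) theta <- Sstar$theta
  } else {
    npairs <- as.integer(Sstar)
    if (is.null(n) || is.null(theta)) abort("`n` and `theta` are required when `Sstar` is a count")
  }
  npairs + max(0L, (n - theta) %/% 2L)
}

#' Check sequence/structure compatibility
#'
#' Lists every pair of `S` whose nucleotides are not admissible under the
#' pairing rule.  An empty result means the structure is compatible.
#'
#' @param seq An [rna_sequence()] (or string).
#' @param S A `secondary_structure` of the same length.
#' @param rule A [base_pair_rule()].
#' @return A tibble with columns `i`, `j`, `nt_i`, `nt_j`, one row per
#'   incompatible pair.
#' @export
validate_compatibility <- function(seq, S, rule = base_pair_rule()) {
  seq <- rna_sequence(seq)
  if (S$n != seq$n) abort(sprintf("structure length %d does not match sequence length %d", S$n, seq$n))
  chars <- seq_chars(seq)
  if (!nrow(S$pairs)) {
    return(tibble::tibble(i = integer(0), j = integer(0),
                          nt_i = character(0), nt_j = character(0)))
  }
  key <- paste0(chars[S$pairs[, 1L]], chars[S$pairs[, 2L]])
  bad <- !key %in% rule$ordered
  tibble::tibble(i = S$pairs[bad, 1L], j = S$pairs[bad, 2L],
                 nt_i = chars[S$pairs[bad, 1L]], nt_j = chars[S$pairs[bad, 2L]])
}
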