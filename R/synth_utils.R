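# ---------------------------------------------------------------------------
# Seeded sequence generators and the dinucleotide-shuffle control
# ---------------------------------------------------------------------------

#' Random RNA sequence
#'
#' Residues drawn i.i.d. from `composition` (uniform by default), using an
#' explicit integer seed; the global random state is untouched.
#'
#' @param length Sequence length.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param composition Named probabilities for A, C, G, U; must sum to 1.
#' @param id Sequence label.
#' @return An [rna_sequence()].
#' @examples
#' random_rna(10, seed = 1)
#' @export
random_rna <- function(length, seed,
                       composition = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                       id = NULL) {
  length <- as.integer(length)
  if (length < 1L) abort("`length` must be >= 1")
  if (abs(sum(composition) - 1) > 1e-8) abort("`composition` must sum to 1")
  chars <- withr::with_seed(seed, {
    sample(c("A", "C", "G", "U"), length, replace = TRUE, prob = composition)
  })
  rna_sequence(paste(chars, collapse = ""),
               id = if (is.null(id)) sprintf("random_n%d_s%d", length, seed) else id)
}

#' Altschul-Erikson dinucleotide shuffle
#'
#' Permutes the sequence while preserving its exact dinucleotide multiset
#' (hence also mononucleotide counts) and its first and last nucleotides.
#' The shuffle samples a uniformly random last-edge arborescence of the
#' dinucleotide multigraph toward the final nucleotide, randomizes the
#' remaining edge orders, and walks the resulting Eulerian path.  Degenerate
#' inputs (single-nucleotide alphabet, `n = 2`) are returned unchanged.
#'
#' @param seq An [rna_sequence()] or string.
#' @param seed Integer seed.
#' @return An [rna_sequence()] with the shuffled residues.
#' @export
dinucleotide_shuffle <- function(seq, seed) {
  seq <- rna_sequence(seq)
  chars <- seq_chars(seq)
  n <- seq$n
  if (n < 2L) abort("need at least 2 nucleotides")
  verts <- unique(chars)
  out_id <- paste0(seq$id, "_shuf", seed)
  if (length(verts) == 1L || n == 2L) {
    return(rna_sequence(seq$seq, id = out_id))
  }
  first <- chars[1L]; last <- chars[n]
  edges <- split(chars[-1L], chars[-n])  # out-edge targets per source vertex
  shuffled <- withr::with_seed(seed, {
    srcs <- names(edges)
    need_last <- setdiff(srcs, last)
    repeat {
      last_edge <- vapply(need_last, function(v) {
        tg <- edges[[v]]
        tg[sample.int(length(tg), 1L)]
      }, character(1L))
      # last-edge graph must reach `last` from every vertex (arborescence)
      ok <- all(vapply(need_last, function(v) {
        seen <- character(0)
        while (v != last) {
          if (v %in% seen || !v %in% need_last) return(FALSE)
          seen <- c(seen, v)
          v <- last_edge[[v]]
        }
        TRUE
      }, logical(1L)))
      if (ok) break
    }
    adj <- lapply(srcs, function(v) {
      tg <- edges[[v]]
      if (v %in% need_last) {
        drop <- match(last_edge[[v]], tg)
        rest <- tg[-drop]
        c(rest[sample.int(length(rest))], last_edge[[v]])
      } else {
        tg[sample.int(length(tg))]
      }
    })
    names(adj) <- srcs
    ptr <- setNames(rep(1L, length(srcs)), srcs)
    walk <- character(n)
    walk[1L] <- first
    cur <- first
    for (i in 2:n) {
      nxt <- adj[[cur]][ptr[[cur]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      walk[i] <- nxt
      cur <- nxt
    }
    walk
  })
  rna_sequence(paste(shuffled, collapse = ""), id = out_id)
}

# dinucleotide count table of a sequence, as a named vector
dinucleotide_counts <- function(seq) {
  chars <- seq_chars(rna_sequence(seq))
  if (length(chars) < 2L) return(integer(0))
  tab <- table(paste0(chars[-length(chars)], chars[-1L]))
  setNames(as.integer(tab), names(tab))
}

#' Embed a perfect hairpin in a random background
#'
#' Builds a random background sequence and splices in a complementary
#' stem-loop at a known offset; the matching dot-bracket target makes a
#' synthetic positive control for [window_scan()].
#'
#' @param length Total sequence length.
#' @param seed Integer seed.
#' @param stem Stem length in base pairs.
#' @param loop Hairpin loop length (must be >= `theta`).
#' @param offset 1-based position of the first stem nucleotide.
#' @param composition Background nucleotide probabilities.
#' @param theta Minimum hairpin size.
#' @return A list with `seq` (the full [rna_sequence()]), `target` (the
#'   window-sized `secondary_structure`), `offset` and `window` (its length).
#' @export
embed_hairpin <- function(length, seed, stem = 5L, loop = 4L, offset = 1L,
                          composition = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                          theta = 3L) {
  stem <- as.integer(stem); loop <- as.integer(loop); offset <- as.integer(offset)
  window <- 2L * stem + loop
  if (loop < theta) abort(sprintf("loop length %d is below theta = %d", loop, theta))
  if (stem < 1L) abort("`stem` must be >= 1")
  if (offset < 1L || offset + window - 1L > length) {
    abort(sprintf("hairpin [%d, %d] does not fit in length %d", offset, offset + window - 1L, length))
  }
  comp_rc <- c(A = "U", C = "G", G = "C", U = "A")
  parts <- withr::with_seed(seed, {
    bg <- sample(c("A", "C", "G", "U"), length, replace = TRUE, prob = composition)
    arm <- sample(c("A", "C", "G", "U"), stem, replace = TRUE)
    lp <- sample(c("A", "C", "G", "U"), loop, replace = TRUE)
    list(bg = bg, arm = arm, lp = lp)
  })
  hairpin <- c(parts$arm, parts$lp, rev(unname(comp_rc[parts$arm])))
  chars <- parts$bg
  chars[offset:(offset + window - 1L)] <- hairpin
  target <- parse_dot_bracket(
    paste0(strrep("(", stem), strrep(".", loop), strrep(")", stem)),
    theta = theta)
  list(seq = rna_sequence(paste(chars, collapse = ""),
                          id = sprintf("embed_s%d_o%d", seed, offset)),
       target = target, offset = offset, window = window)
}

#' Pearson product-moment correlation
#'
#' A validated wrapper around [stats::cor()]: requires equal lengths of at
#' least 3 and non-degenerate variances.
#'
#' @param xs,ys Numeric vectors.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(xs, ys) {
  if (length(xs) != length(ys)) abort("`xs` and `ys` must have equal length")
  if (length(xs) < 3L) abort("need at least 3 observations")
  if (sd(xs) == 0 || sd(ys) == 0) abort("degenerate variance")
  cor(xs, ys, method = "pearson")
}

#' Example thiamine-pyrophosphate riboswitch aptamers
#'
#' Two TPP riboswitch aptamer sequences from the Rfam RF00059 seed alignment
#' (EMBL accessions BX842649.1/277414-277318, 97 nt, and
#' AACY022101973.1/389-487, 99 nt), used as realistic inputs for profiles
#' and shuffle controls.
#'
#' @return A named list of two [rna_sequence()] objects.
#' @export
tpp_aptamers <- function() {
  list(
    BX842649 = rna_sequence(paste0(
      "ACCUGACGCUAGGGGUGUUGGUGAAUUCACCGACUGAGAAUAACCCUUUG",
      "AACCUGAUAGAGAUAAUGCUCGCGCAGGGAAGCAAGAAUAGAAAGAU"),
      id = "BX842649.1/277414-277318"),
    AACY022101973 = rna_sequence(paste0(
      "UAUAAGUCCAAGGGGUGCCAAUUGGCUGAGAUGGUUUUAACCAAUCCCUU",
      "UGAACCUGAUCCGGUUAAUACCGGCGUAGGAAUGGAUUUUCUCUACAGC"),
      id = "AACY022101973.1/389-487")
  )
}
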