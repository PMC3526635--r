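# ---------------------------------------------------------------------------
# Distance-indexed partition-function polynomial
#
# For a sequence s and reference structure S*, the polynomial
#   Z(x) = sum_S exp(-E(S)/RT) * x^d(S, S*)
# has non-negative real coefficients Z_k (the distance-class partition
# functions) and degree bounded by |S*| + floor((n - theta)/2) < n.  It is
# evaluated at fixed complex points by an interval dynamic program that keeps
# base-pair-distance bookkeeping relative to S* through prefix pair counts.
# ---------------------------------------------------------------------------

# Distance bookkeeping tables for a reference structure:
#   Cx[i, j + 1] = |S* restricted to [i, j]|   (column 'i' is the empty
#   interval [i, i-1] and holds 0), and the partner vector of S*.
distance_bookkeeping <- function(Sstar) {
  n <- Sstar$n
  partner <- Sstar$partner
  Cx <- matrix(0L, n, n + 1L)
  for (i in seq_len(n)) {
    acc <- 0L
    for (j in i:n) {
      q <- partner[j]
      if (!is.na(q) && q >= i && q < j) acc <- acc + 1L
      Cx[i, j + 1L] <- acc
    }
  }
  list(Cx = Cx, partner = partner, nref = nrow(Sstar$pairs))
}

#' Distance increment when introducing a base pair
#'
#' When the interval `[i, j]` is decomposed by pairing `(l, j)` into
#' `[i, l-1]` and `[l+1, j-1]`, the base-pair distance to the restricted
#' reference grows by
#' `|S*[i,j]| - |S*[i,l-1]| - |S*[l+1,j-1]| + 1 - 2 * [(l,j) in S*]`:
#' the reference pairs made unrepresentable by the split, plus one for a
#' novel pair (zero net for re-introducing a reference pair).
#'
#' @param Sstar Reference `secondary_structure`.
#' @param i,l,j Indices with `i <= l < j`.
#' @return A non-negative integer.
#' @export
pair_distance_increment <- function(Sstar, i, l, j) {
  if (i > l || l >= j || i < 1L || j > Sstar$n) abort("need 1 <= i <= l < j <= n")
  bk <- distance_bookkeeping(Sstar)
  inref <- !is.na(bk$partner[j]) && bk$partner[j] == l
  bk$Cx[i, j + 1L] - bk$Cx[i, l] - bk$Cx[l + 1L, j] + 1L - 2L * inref
}

#' Distance increment when position j stays unpaired
#'
#' One reference pair `(l, j)` with `i <= l < j` becomes unrepresentable when
#' `j` is left unpaired in the interval `[i, j]`.
#'
#' @inheritParams pair_distance_increment
#' @return 0 or 1.
#' @export
unpaired_increment <- function(Sstar, i, j) {
  if (i > j || i < 1L || j > Sstar$n) abort("need 1 <= i <= j <= n")
  q <- Sstar$partner[j]
  as.integer(!is.na(q) && q >= i && q < j)
}

# ---------------------------------------------------------------------------
# precomputation shared across evaluation points
# ---------------------------------------------------------------------------

dp_precompute <- function(seq, Sstar, model, rule = base_pair_rule()) {
  seq <- rna_sequence(seq)
  if (Sstar$n != seq$n) {
    abort(sprintf("reference length %d does not match sequence length %d", Sstar$n, seq$n))
  }
  n <- seq$n
  theta <- Sstar$theta
  bk <- distance_bookkeeping(Sstar)
  can <- pairing_matrix(seq, rule)
  pairable <- can & outer(seq_len(n), seq_len(n), function(l, j) j - l > theta)
  # l-candidates per closing index j, and h-candidates per opening index i
  by_j <- lapply(seq_len(n), function(j) which(pairable[, j]))
  by_i <- lapply(seq_len(n), function(i) which(pairable[i, ]))
  pc <- list(seq = seq, n = n, theta = theta, Cx = bk$Cx, partner = bk$partner,
             nref = bk$nref, pairable = pairable, by_j = by_j, by_i = by_i,
             RT = model$RT, model = model, maxe = bk$nref + 1L)
  if (inherits(model, "turner_model")) {
    pc <- c(pc, turner_precompute(pc, model))
  } else {
    pc$w_pair <- exp(-model$epsilon / model$RT)
  }
  pc
}

# Turner-specific tables: hairpin weights per closing pair and, per closing
# pair (i,j), the admissible interior pairs (k,l) with their Boltzmann
# weights and reference pair counts.
turner_precompute <- function(pc, model) {
  n <- pc$n
  par <- model$params
  RT <- model$RT
  chars <- seq_chars(pc$seq)
  ptype <- matrix(NA_integer_, n, n)
  idx <- which(pc$pairable, arr.ind = TRUE)
  if (nrow(idx)) {
    ptype[idx] <- pair_type_index(chars[idx[, 1L]], chars[idx[, 2L]])
  }
  WH <- matrix(0, n, n)
  if (nrow(idx)) {
    WH[idx] <- exp(-loop_init_energy(par$hairpin, idx[, 2L] - idx[, 1L] - 1L) / RT)
  }
  # global list of admissible pairs ordered by span (inner pairs first)
  pl <- idx[order(idx[, 2L] - idx[, 1L]), , drop = FALSE]
  cand <- vector("list", n * n)
  if (nrow(pl)) {
    pk <- pl[, 1L]; plr <- pl[, 2L]
    for (a in seq_len(nrow(idx))) {
      i <- idx[a, 1L]; j <- idx[a, 2L]
      sel <- which(pk > i & plr < j & (pk - i - 1L) + (j - plr - 1L) <= par$max_internal)
      if (!length(sel)) next
      k <- pk[sel]; l <- plr[sel]
      E <- interior_energy(par, ptype[i, j], ptype[cbind(k, l)], k - i - 1L, j - l - 1L)
      keep <- is.finite(E)
      if (!any(keep)) next
      cand[[(j - 1L) * n + i]] <- list(k = k[keep], l = l[keep],
                                       w = exp(-E[keep] / RT),
                                       cnt = pc$Cx[cbind(k[keep], l[keep] + 1L)])
    }
  }
  list(WH = WH, cand = cand,
       w_ml_close = exp(-(par$multiloop_init + par$multiloop_branch) / RT),
       w_branch = exp(-par$multiloop_branch / RT),
       w_unpaired = exp(-par$multiloop_unpaired / RT))
}

# ---------------------------------------------------------------------------
# single-point evaluation
# ---------------------------------------------------------------------------

# Nussinov model: single interval matrix.
#   Zhat(i,j) = x^{b0} Zhat(i,j-1)
#             + sum_l w * x^{b(l,j)} * Zhat(i,l-1) * Zhat(l+1,j-1)
zhat_point_nussinov <- function(pc, x) {
  n <- pc$n; theta <- pc$theta; Cx <- pc$Cx
  xp <- x^(0:pc$maxe)
  Mx <- matrix(as.complex(1), n, n + 1L)  # Mx[i, j+1] = Zhat(i, j); base cases 1
  if (n - 1L >= theta + 1L) {
    for (d in (theta + 1L):(n - 1L)) {
      for (i in seq_len(n - d)) {
        j <- i + d
        b0 <- Cx[i, j + 1L] - Cx[i, j]
        val <- xp[b0 + 1L] * Mx[i, j]
        ls <- pc$by_j[[j]]
        ls <- ls[ls >= i]
        if (length(ls)) {
          b <- Cx[i, j + 1L] - Cx[i, ls] - Cx[cbind(ls + 1L, j)] + 1L -
               2L * (!is.na(pc$partner[j]) & ls == pc$partner[j])
          val <- val + pc$w_pair * sum(xp[b + 1L] * Mx[i, ls] * Mx[cbind(ls + 1L, j)])
        }
        Mx[i, j + 1L] <- val
      }
    }
  }
  Mx[1L, n + 1L]
}

# Turner-style model: McCaskill decomposition with distance factors.
#   ZB(i,j): (i,j) paired; hairpin, interior loop, or multiloop closing.
#   ZM1(i,j): exactly one multiloop helix starting at i, tail unpaired.
#   ZM(i,j): one or more multiloop helices.
#   E(j): exterior segment [1, j].
# Each decomposition step carries x^Delta, Delta = reference pairs made
# unrepresentable + 1 per introduced non-reference pair (0 if the introduced
# pair is in S*).
zhat_point_turner <- function(pc, x) {
  n <- pc$n; theta <- pc$theta; Cx <- pc$Cx
  xp <- x^(0:pc$maxe)
  ZB <- matrix(as.complex(0), n, n)
  ZM1 <- matrix(as.complex(0), n, n)
  ZM <- matrix(as.complex(0), n, n + 1L)  # ZM[i, j+1]; column i = empty = 0
  if (n - 1L >= theta + 1L) {
    for (d in (theta + 1L):(n - 1L)) {
      for (i in seq_len(n - d)) {
        j <- i + d
        if (pc$pairable[i, j]) {
          base_exp <- Cx[i, j + 1L] + 1L -
                      2L * (!is.na(pc$partner[j]) && pc$partner[j] == i)
          v <- pc$WH[i, j] * xp[base_exp + 1L]
          cd <- pc$cand[[(j - 1L) * n + i]]
          if (!is.null(cd)) {
            v <- v + sum(cd$w * ZB[cbind(cd$k, cd$l)] * xp[base_exp - cd$cnt + 1L])
          }
          ls <- seq2(i + theta + 3L, j - theta - 2L)
          if (length(ls)) {
            v <- v + pc$w_ml_close *
              sum(ZM[i + 1L, ls] * ZM1[cbind(ls, j - 1L)] *
                  xp[base_exp - Cx[i + 1L, ls] - Cx[cbind(ls, j)] + 1L])
          }
          ZB[i, j] <- v
        }
        # ZM1: helix (i,h), tail (h, j] unpaired
        hs <- pc$by_i[[i]]
        hs <- hs[hs <= j]
        if (length(hs)) {
          ZM1[i, j] <- pc$w_branch *
            sum(ZB[cbind(i, hs)] * pc$w_unpaired^(j - hs) *
                xp[Cx[i, j + 1L] - Cx[cbind(i, hs + 1L)] + 1L])
        }
        # ZM: last ZM1 block starts at l
        ls2 <- seq2(i, j - theta - 1L)
        if (length(ls2)) {
          z1 <- ZM1[cbind(ls2, j)]
          cnt_lj <- Cx[cbind(ls2, j + 1L)]
          ZM[i, j + 1L] <-
            sum(pc$w_unpaired^(ls2 - i) * z1 * xp[Cx[i, j + 1L] - cnt_lj + 1L]) +
            sum(ZM[i, ls2] * z1 * xp[Cx[i, j + 1L] - Cx[i, ls2] - cnt_lj + 1L])
        }
      }
    }
  }
  # exterior
  E <- complex(n + 1L); E[1L] <- as.complex(1)
  for (j in seq_len(n)) {
    u <- Cx[1L, j + 1L] - Cx[1L, j]
    v <- E[j] * xp[u + 1L]
    ls <- pc$by_j[[j]]
    if (length(ls)) {
      v <- v + sum(E[ls] * ZB[cbind(ls, j)] *
                   xp[Cx[1L, j + 1L] - Cx[1L, ls] - Cx[cbind(ls, j + 1L)] + 1L])
    }
    E[j + 1L] <- v
  }
  E[n + 1L]
}

# increasing integer sequence, empty when from > to
seq2 <- function(from, to) if (from > to) integer(0) else from:to

zhat_point <- function(pc, x) {
  if (inherits(pc$model, "turner_model")) zhat_point_turner(pc, x)
  else zhat_point_nussinov(pc, x)
}

#' Evaluate the distance polynomial at a complex point
#'
#' Computes `Z(x) = sum_S exp(-E(S)/RT) * x^d(S, S*)` over all secondary
#' structures of `seq` by dynamic programming over intervals (cubic time,
#' quadratic space per point).  At `x = 1` this is the ordinary partition
#' function.
#'
#' @param seq An [rna_sequence()] or string.
#' @param Sstar Reference `secondary_structure` (dot-bracket strings are
#'   parsed).
#' @param x A complex (or real) scalar.
#' @param model An `energy_model`; default [nussinov_model()].
#' @param rule A [base_pair_rule()].
#' @return A complex scalar.
#' @examples
#' evaluate_at("GAAAC", ".....", x = 1, model = nussinov_model(RT = 1))
#' @export
evaluate_at <- function(seq, Sstar, x, model = nussinov_model(), rule = base_pair_rule()) {
  Sstar <- parse_dot_bracket(Sstar)
  pc <- dp_precompute(seq, Sstar, model, rule)
  zhat_point(pc, as.complex(x))
}

#' Evaluate the distance polynomial at the m-th roots of unity
#'
#' Evaluates `Z(x)` at `x = exp(2 pi i j / m)` for `j = 0..m-1`.  Because the
#' coefficients are real, values at conjugate roots are complex conjugates,
#' so only `j = 0..floor(m/2)` are computed by the dynamic program and the
#' remainder is filled by conjugation (`half_evaluation = FALSE` forces the
#' full computation, for validation).
#'
#' @inheritParams evaluate_at
#' @param m Number of evaluation points; must exceed the distance bound of
#'   [max_distance_bound()].  Defaults to the sequence length `n` (the
#'   polynomial has degree `< n`).
#' @param half_evaluation Use the conjugate-symmetry shortcut (default TRUE).
#' @return An object of class `complex_evaluation`: list with `m`, `values`
#'   (complex vector), `Z` (the real partition function, entry 0), the
#'   distance `bound`, and input metadata.
#' @examples
#' ev <- evaluate_on_roots("GAAAC", ".....", model = nussinov_model(RT = 1), m = 4)
#' ev$values
#' @export
evaluate_on_roots <- function(seq, Sstar, model = nussinov_model(), m = NULL,
                              rule = base_pair_rule(), half_evaluation = TRUE) {
  seq <- rna_sequence(seq)
  Sstar <- parse_dot_bracket(Sstar)
  bound <- max_distance_bound(Sstar)
  if (is.null(m)) m <- max(seq$n, bound + 1L)
  m <- as.integer(m)
  if (m < bound + 1L) {
    abort(sprintf("m = %d is too small: the polynomial degree can reach %d, need m >= %d",
                  m, bound, bound + 1L))
  }
  pc <- dp_precompute(seq, Sstar, model, rule)
  om <- roots_of_unity(m)
  values <- complex(m)
  top <- if (half_evaluation) m %/% 2L else m - 1L
  for (j in 0:top) values[j + 1L] <- zhat_point(pc, om[j + 1L])
  if (half_evaluation && m > 1L) {
    for (j in seq2(m %/% 2L + 1L, m - 1L)) values[j + 1L] <- Conj(values[m - j + 1L])
  }
  Z <- Re(values[1L])
  if (Z <= 0) abort("partition function is not positive; check the energy model")
  structure(list(m = m, values = values, Z = Z, bound = bound,
                 seq_id = seq$id, n = seq$n, theta = Sstar$theta,
                 reference = format_dot_bracket(Sstar), model = pc$model$name,
                 RT = pc$model$RT),
            class = "complex_evaluation")
}

#' @export
print.complex_evaluation <- function(x, ...) {
  cat(sprintf("<complex_evaluation> m=%d points, Z=%.6g, bound=%d (%s model)\n",
              x$m, x$Z, x$bound, x$model))
  invisible(x)
}

#' Partition function without distance bookkeeping
#'
#' An independent McCaskill-style computation of the plain partition function
#' `Z = sum_S exp(-E(S)/RT)`, used to cross-check the polynomial evaluation
#' at `x = 1`.  It shares no code with the complex-point recursion.
#'
#' @inheritParams evaluate_at
#' @param theta Minimum hairpin size.
#' @return A positive real number.
#' @export
partition_function <- function(seq, model = nussinov_model(), rule = base_pair_rule(),
                               theta = 3L) {
  seq <- rna_sequence(seq)
  n <- seq$n
  theta <- as.integer(theta)
  can <- pairing_matrix(seq, rule)
  if (inherits(model, "turner_model")) {
    return(partition_function_turner(seq, model, can, theta))
  }
  w <- exp(-model$epsilon / model$RT)
  Zm <- matrix(1, n, n + 1L)  # Zm[i, j+1] = Z(i, j)
  if (n - 1L >= theta + 1L) {
    for (d in (theta + 1L):(n - 1L)) {
      for (i in seq_len(n - d)) {
        j <- i + d
        val <- Zm[i, j]
        ls <- which(can[seq2(i, j - theta - 1L), j]) + i - 1L
        if (length(ls)) val <- val + w * sum(Zm[i, ls] * Zm[cbind(ls + 1L, j)])
        Zm[i, j + 1L] <- val
      }
    }
  }
  Zm[1L, n + 1L]
}

partition_function_turner <- function(seq, model, can, theta) {
  n <- seq$n
  par <- model$params
  RT <- model$RT
  chars <- seq_chars(seq)
  pairable <- can & outer(seq_len(n), seq_len(n), function(l, j) j - l > theta)
  ZB <- matrix(0, n, n); ZM1 <- matrix(0, n, n); ZM <- matrix(0, n, n + 1L)
  wmlc <- exp(-(par$multiloop_init + par$multiloop_branch) / RT)
  wb <- exp(-par$multiloop_branch / RT)
  wu <- exp(-par$multiloop_unpaired / RT)
  if (n - 1L >= theta + 1L) {
    for (d in (theta + 1L):(n - 1L)) {
      for (i in seq_len(n - d)) {
        j <- i + d
        if (pairable[i, j]) {
          v <- exp(-loop_init_energy(par$hairpin, j - i - 1L) / RT)
          ks <- seq2(i + 1L, j - theta - 2L)
          for (k in ks) {
            lmin <- max(k + theta + 1L, j - 1L - (par$max_internal - (k - i - 1L)))
            for (l in seq2(lmin, j - 1L)) {
              if (!pairable[k, l]) next
              E <- interior_energy(par, pair_type_index(chars[i], chars[j]),
                                   pair_type_index(chars[k], chars[l]),
                                   k - i - 1L, j - l - 1L)
              if (is.finite(E)) v <- v + exp(-E / RT) * ZB[k, l]
            }
          }
          ls <- seq2(i + theta + 3L, j - theta - 2L)
          if (length(ls)) v <- v + wmlc * sum(ZM[i + 1L, ls] * ZM1[cbind(ls, j - 1L)])
          ZB[i, j] <- v
        }
        hs <- which(pairable[i, seq2(i + theta + 1L, j)]) + i + theta
        if (length(hs)) ZM1[i, j] <- wb * sum(ZB[cbind(i, hs)] * wu^(j - hs))
        ls2 <- seq2(i, j - theta - 1L)
        if (length(ls2)) {
          z1 <- ZM1[cbind(ls2, j)]
          ZM[i, j + 1L] <- sum(wu^(ls2 - i) * z1) + sum(ZM[i, ls2] * z1)
        }
      }
    }
  }
  E <- numeric(n + 1L); E[1L] <- 1
  for (j in seq_len(n)) {
    v <- E[j]
    ls <- which(pairable[seq2(1L, j - theta - 1L), j])
    if (length(ls)) v <- v + sum(E[ls] * ZB[cbind(ls, j)])
    E[j + 1L] <- v
  }
  E[n + 1L]
}
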