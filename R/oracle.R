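# ---------------------------------------------------------------------------
# Ground truth at desk scale: exhaustive enumeration of the ensemble and the
# integer-distance dynamic program.
# ---------------------------------------------------------------------------

#' Exhaustively enumerate all secondary structures
#'
#' Generates every pseudoknot-free, pairing-rule-respecting structure of the
#' sequence by recursive interval decomposition.  Intended as a test oracle;
#' refuses sequences longer than `cap`.
#'
#' @inheritParams evaluate_at
#' @param theta Minimum hairpin size.
#' @param cap Maximum sequence length accepted (default 30).
#' @return An object of class `ensemble_enumeration`: list with the sequence,
#'   `theta`, and `structures`, a list of two-column pair matrices.
#' @examples
#' length(enumerate_structures("GAAAC")$structures)  # empty + (1,5)
#' @export
enumerate_structures <- function(seq, theta = 3L, rule = base_pair_rule(), cap = 30L) {
  seq <- rna_sequence(seq)
  if (seq$n > cap) {
    abort(sprintf("n = %d exceeds the enumeration cap (%d); use the dynamic program instead",
                  seq$n, cap))
  }
  n <- seq$n
  can <- pairing_matrix(seq, rule)
  empty <- matrix(integer(0), 0L, 2L)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i <= theta) return(list(empty))
    key <- paste0(i, ",", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- rec(i, j - 1L)  # j unpaired
    for (l in i:(j - theta - 1L)) {
      if (!can[l, j]) next
      left <- if (l - 1L < i) list(empty) else rec(i, l - 1L)
      right <- rec(l + 1L, j - 1L)
      for (L in left) for (R in right) {
        out[[length(out) + 1L]] <- rbind(c(l, j), L, R)
      }
    }
    memo[[key]] <- out
    out
  }
  structure(list(seq = seq, theta = as.integer(theta), structures = rec(1L, n)),
            class = "ensemble_enumeration")
}

#' @export
print.ensemble_enumeration <- function(x, ...) {
  cat(sprintf("<ensemble_enumeration> %s (n=%d): %d structures (theta=%d)\n",
              x$seq$id, x$seq$n, length(x$structures), x$theta))
  invisible(x)
}

#' Count secondary structures by recursion
#'
#' The standard counting recursion
#' `N(i,j) = N(i,j-1) + sum_l N(i,l-1) * N(l+1,j-1)`, used as an independent
#' check on [enumerate_structures()].
#'
#' @inheritParams enumerate_structures
#' @return The number of structures (double).
#' @export
count_structures <- function(seq, theta = 3L, rule = base_pair_rule()) {
  seq <- rna_sequence(seq)
  n <- seq$n
  can <- pairing_matrix(seq, rule)
  N <- matrix(1, n, n + 1L)  # N[i, j+1]; empty/short intervals count 1
  if (n - 1L >= theta + 1L) {
    for (d in (theta + 1L):(n - 1L)) {
      for (i in seq_len(n - d)) {
        j <- i + d
        val <- N[i, j]
        for (l in i:(j - theta - 1L)) {
          if (can[l, j]) val <- val + N[i, l] * N[l + 1L, j]
        }
        N[i, j + 1L] <- val
      }
    }
  }
  N[1L, n + 1L]
}

# lightweight structure construction for enumerated pair matrices
pairs_to_structure <- function(pairs, n, theta) {
  partner <- rep(NA_integer_, n)
  if (nrow(pairs)) {
    partner[pairs[, 1L]] <- pairs[, 2L]
    partner[pairs[, 2L]] <- pairs[, 1L]
  }
  structure(list(pairs = pairs, partner = partner, n = n, theta = theta),
            class = "secondary_structure")
}

#' Exact profile by exhaustive enumeration
#'
#' Computes `p(k) = sum_{d(S,S*) = k} exp(-E(S)/RT) / Z` exactly (up to
#' floating-point summation) from the complete list of structures.
#'
#' @inheritParams evaluate_at
#' @param cap Enumeration size cap, passed to [enumerate_structures()].
#' @return A `structural_profile` (untruncated; `method = "enumeration"`).
#' @export
exact_profile <- function(seq, Sstar, model = nussinov_model(),
                          rule = base_pair_rule(), cap = 30L) {
  seq <- rna_sequence(seq)
  Sstar <- parse_dot_bracket(Sstar)
  en <- enumerate_structures(seq, theta = Sstar$theta, rule = rule, cap = cap)
  K <- max_distance_bound(Sstar)
  Zk <- numeric(K + 1L)
  n <- seq$n
  chars <- seq_chars(seq)
  nussinov <- inherits(model, "nussinov_model")
  nstar <- nrow(Sstar$pairs)
  starkeys <- (Sstar$pairs[, 1L] - 1L) * n + Sstar$pairs[, 2L]
  for (pairs in en$structures) {
    np <- nrow(pairs)
    inter <- if (np && nstar) sum(((pairs[, 1L] - 1L) * n + pairs[, 2L]) %in% starkeys) else 0L
    d <- np + nstar - 2L * inter
    E <- if (nussinov) model$epsilon * np
         else turner_energy_fast(chars, pairs_to_structure(pairs, n, Sstar$theta), model$params)
    if (!is.finite(E)) next
    Zk[d + 1L] <- Zk[d + 1L] + exp(-E / model$RT)
  }
  Z <- sum(Zk)
  p <- Zk / Z
  new_structural_profile(p, p_full = p, digits = NA_integer_,
                         meta = list(seq_id = seq$id, n = seq$n,
                                     reference = format_dot_bracket(Sstar),
                                     model = model$name, theta = Sstar$theta,
                                     RT = model$RT, Z = Z, bound = K,
                                     method = "enumeration",
                                     imag_residual = 0,
                                     pre_truncation_mass = sum(p)))
}

#' Integer-distance dynamic program (Nussinov model)
#'
#' Computes the distance-class partition functions `Z_k` directly with an
#' integer-indexed recursion: the interval table holds truncated coefficient
#' vectors and each split convolves the sub-interval vectors, shifted by the
#' distance increment of [pair_distance_increment()].  This is the
#' polynomial-expansion route that the complex-evaluation algorithm avoids;
#' at desk scale it is an exact cross-check.
#'
#' @inheritParams evaluate_at
#' @return Numeric vector `Z_0..Z_K` with `K = max_distance_bound(Sstar)`;
#'   `sum(Z_k)` is the partition function and `Z_0 = exp(-E(S*)/RT)` when the
#'   reference is a compatible structure.
#' @export
rnabor_integer_dp <- function(seq, Sstar, model = nussinov_model(),
                              rule = base_pair_rule()) {
  if (!inherits(model, "nussinov_model")) {
    abort("the integer-distance DP is implemented for the Nussinov model; use exact_profile() for other models")
  }
  seq <- rna_sequence(seq)
  Sstar <- parse_dot_bracket(Sstar)
  if (Sstar$n != seq$n) abort("reference length does not match sequence length")
  n <- seq$n
  theta <- Sstar$theta
  bk <- distance_bookkeeping(Sstar)
  Cx <- bk$Cx
  K <- max_distance_bound(Sstar)
  w <- exp(-model$epsilon / model$RT)
  can <- pairing_matrix(seq, rule)
  shift <- function(v, by) if (by == 0L) v else c(numeric(by), v)
  padd <- function(a, b) {
    len <- max(length(a), length(b))
    c(a, numeric(len - length(a))) + c(b, numeric(len - length(b)))
  }
  pmul <- function(a, b) {
    r <- numeric(length(a) + length(b) - 1L)
    for (ii in seq_along(a)) {
      idx <- ii:(ii + length(b) - 1L)
      r[idx] <- r[idx] + a[ii] * b
    }
    r
  }
  LL <- lapply(seq_len(n), function(i) rep(list(1), n + 1L))  # LL[[i]][[j+1]] = Zk(i,j)
  if (n - 1L >= theta + 1L) {
    for (d in (theta + 1L):(n - 1L)) {
      for (i in seq_len(n - d)) {
        j <- i + d
        b0 <- Cx[i, j + 1L] - Cx[i, j]
        acc <- shift(LL[[i]][[j]], b0)
        for (l in i:(j - theta - 1L)) {
          if (!can[l, j]) next
          b <- Cx[i, j + 1L] - Cx[i, l] - Cx[l + 1L, j] + 1L -
               2L * (!is.na(bk$partner[j]) && bk$partner[j] == l)
          acc <- padd(acc, shift(w * pmul(LL[[i]][[l]], LL[[l + 1L]][[j]]), b))
        }
        LL[[i]][[j + 1L]] <- head(acc, K + 1L)
      }
    }
  }
  Zk <- LL[[1L]][[n + 1L]]
  c(Zk, numeric(K + 1L - length(Zk)))
}

#' Compare the three computation routes
#'
#' Runs the FFT recovery, the integer-distance DP and (when feasible) the
#' exhaustive enumeration on the same instance and reports pairwise total
#' variation distances.
#'
#' @inheritParams exact_profile
#' @return A tibble with columns `method_a`, `method_b`, `tv`.
#' @export
oracle_compare <- function(seq, Sstar, model = nussinov_model(),
                           rule = base_pair_rule(), cap = 30L) {
  seq <- rna_sequence(seq)
  Sstar <- parse_dot_bracket(Sstar)
  ev <- evaluate_on_roots(seq, Sstar, model = model, rule = rule)
  p_fft <- profile_probabilities(recover_profile(ev))
  routes <- list(fft = p_fft)
  if (inherits(model, "nussinov_model")) {
    Zk <- rnabor_integer_dp(seq, Sstar, model, rule)
    routes$integer_dp <- Zk / sum(Zk)
  }
  if (seq$n <= cap) {
    routes$enumeration <- profile_probabilities(exact_profile(seq, Sstar, model, rule, cap))
  }
  nm <- names(routes)
  cmb <- utils::combn(length(nm), 2L)
  tibble::tibble(
    method_a = nm[cmb[1L, ]],
    method_b = nm[cmb[2L, ]],
    tv = purrr::map_dbl(seq_len(ncol(cmb)), function(a) {
      total_variation(routes[[cmb[1L, a]]], routes[[cmb[2L, a]]])
    })
  )
}
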