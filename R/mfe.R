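# ---------------------------------------------------------------------------
# Minimum free energy folding: maximum-pairs DP for the Nussinov model and a
# Zuker-style loop-based DP for the Turner model.  Ties are broken toward
# the smaller 5' pairing index (candidates scanned in ascending order).
# ---------------------------------------------------------------------------

#' Minimum free energy structure
#'
#' Folds the sequence under the given energy model.  For the Nussinov model
#' this maximizes the number of base pairs (for `epsilon < 0`); for the
#' Turner-style model it runs a Zuker-type dynamic program over the same
#' loop decomposition used by [turner_energy()].
#'
#' @inheritParams evaluate_at
#' @param theta Minimum hairpin size.
#' @return A `secondary_structure`.
#' @examples
#' format_dot_bracket(mfe_structure("GGGGAAAACCCC", nussinov_model()))
#' @export
mfe_structure <- function(seq, model = turner_model(), theta = 3L,
                          rule = base_pair_rule()) {
  seq <- rna_sequence(seq)
  if (inherits(model, "turner_model")) {
    mfe_turner(seq, model, theta, rule)
  } else {
    mfe_nussinov(seq, model, theta, rule)
  }
}

mfe_nussinov <- function(seq, model, theta, rule) {
  n <- seq$n
  if (model$epsilon >= 0) return(secondary_structure(NULL, n = n, theta = theta))
  can <- pairing_matrix(seq, rule)
  M <- matrix(0L, n, n + 1L)  # M[i, j+1] = max pairs on [i, j]
  if (n - 1L >= theta + 1L) {
    for (d in (theta + 1L):(n - 1L)) {
      for (i in seq_len(n - d)) {
        j <- i + d
        best <- M[i, j]
        for (l in i:(j - theta - 1L)) {
          if (can[l, j]) best <- max(best, M[i, l] + M[l + 1L, j] + 1L)
        }
        M[i, j + 1L] <- best
      }
    }
  }
  pairs <- matrix(integer(0), 0L, 2L)
  stack <- list(c(1L, n))
  while (length(stack)) {
    iv <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- iv[1L]; j <- iv[2L]
    if (j - i <= theta) next
    placed <- FALSE
    for (l in i:(j - theta - 1L)) {  # smallest 5' pairing index first
      if (can[l, j] && M[i, l] + M[l + 1L, j] + 1L == M[i, j + 1L]) {
        pairs <- rbind(pairs, c(l, j))
        if (l - 1L >= i) stack[[length(stack) + 1L]] <- c(i, l - 1L)
        stack[[length(stack) + 1L]] <- c(l + 1L, j - 1L)
        placed <- TRUE
        break
      }
    }
    if (!placed) stack[[length(stack) + 1L]] <- c(i, j - 1L)
  }
  secondary_structure(pairs, n = n, theta = theta)
}

mfe_turner <- function(seq, model, theta, rule) {
  n <- seq$n
  par <- model$params
  chars <- seq_chars(seq)
  can <- pairing_matrix(seq, rule)
  pairable <- can & outer(seq_len(n), seq_len(n), function(l, j) j - l > theta)
  b <- par$multiloop_branch; a <- par$multiloop_init; cc <- par$multiloop_unpaired
  WB <- matrix(Inf, n, n); WM1 <- matrix(Inf, n, n); WM <- matrix(Inf, n, n + 1L)
  interior_E <- function(i, j, k, l) {
    interior_energy(par, pair_type_index(chars[i], chars[j]),
                    pair_type_index(chars[k], chars[l]),
                    k - i - 1L, j - l - 1L)
  }
  if (n - 1L >= theta + 1L) {
    for (d in (theta + 1L):(n - 1L)) {
      for (i in seq_len(n - d)) {
        j <- i + d
        if (pairable[i, j]) {
          best <- loop_init_energy(par$hairpin, j - i - 1L)
          for (k in seq2(i + 1L, j - theta - 2L)) {
            if (k - i - 1L > par$max_internal) break
            for (l in seq2(max(k + theta + 1L, j - 1L - (par$max_internal - (k - i - 1L))), j - 1L)) {
              if (!pairable[k, l]) next
              best <- min(best, interior_E(i, j, k, l) + WB[k, l])
            }
          }
          for (l in seq2(i + theta + 3L, j - theta - 2L)) {
            best <- min(best, a + b + WM[i + 1L, l] + WM1[l, j - 1L])
          }
          WB[i, j] <- best
        }
        hs <- which(pairable[i, seq2(i + theta + 1L, j)]) + i + theta
        if (length(hs)) WM1[i, j] <- min(WB[cbind(i, hs)] + b + cc * (j - hs))
        ls2 <- seq2(i, j - theta - 1L)
        if (length(ls2)) {
          w1 <- WM1[cbind(ls2, j)]
          WM[i, j + 1L] <- min(cc * (ls2 - i) + w1, WM[i, ls2] + w1)
        }
      }
    }
  }
  W <- numeric(n + 1L)
  for (j in seq_len(n)) {
    best <- W[j]
    for (l in seq2(1L, j - theta - 1L)) {
      if (pairable[l, j]) best <- min(best, W[l] + WB[l, j])
    }
    W[j + 1L] <- best
  }
  # traceback
  pairs <- matrix(integer(0), 0L, 2L)
  eq <- function(x, y) is.finite(x) && abs(x - y) <= 1e-9
  tb_WB <- function(i, j) {
    pairs <<- rbind(pairs, c(i, j))
    val <- WB[i, j]
    if (eq(loop_init_energy(par$hairpin, j - i - 1L), val)) return(invisible())
    for (k in seq2(i + 1L, j - theta - 2L)) {
      if (k - i - 1L > par$max_internal) break
      for (l in seq2(max(k + theta + 1L, j - 1L - (par$max_internal - (k - i - 1L))), j - 1L)) {
        if (pairable[k, l] && eq(interior_E(i, j, k, l) + WB[k, l], val)) {
          tb_WB(k, l); return(invisible())
        }
      }
    }
    for (l in seq2(i + theta + 3L, j - theta - 2L)) {
      if (eq(a + b + WM[i + 1L, l] + WM1[l, j - 1L], val)) {
        tb_WM(i + 1L, l - 1L); tb_WM1(l, j - 1L); return(invisible())
      }
    }
    abort("internal error: MFE traceback failed in WB")
  }
  tb_WM1 <- function(i, j) {
    val <- WM1[i, j]
    hs <- which(pairable[i, seq2(i + theta + 1L, j)]) + i + theta
    for (h in hs) {
      if (eq(WB[i, h] + b + cc * (j - h), val)) { tb_WB(i, h); return(invisible()) }
    }
    abort("internal error: MFE traceback failed in WM1")
  }
  tb_WM <- function(i, j) {
    val <- WM[i, j + 1L]
    for (l in seq2(i, j - theta - 1L)) {
      if (eq(cc * (l - i) + WM1[l, j], val)) { tb_WM1(l, j); return(invisible()) }
      if (eq(WM[i, l] + WM1[l, j], val)) { tb_WM(i, l - 1L); tb_WM1(l, j); return(invisible()) }
    }
    abort("internal error: MFE traceback failed in WM")
  }
  tb_W <- function(j) {
    while (j >= 1L) {
      if (eq(W[j], W[j + 1L])) { j <- j - 1L; next }
      advanced <- FALSE
      for (l in seq2(1L, j - theta - 1L)) {
        if (pairable[l, j] && eq(W[l] + WB[l, j], W[j + 1L])) {
          tb_WB(l, j); j <- l - 1L; advanced <- TRUE; break
        }
      }
      if (!advanced) abort("internal error: MFE traceback failed in W")
    }
  }
  tb_W(n)
  secondary_structure(pairs, n = n, theta = theta)
}
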