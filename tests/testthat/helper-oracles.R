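# Test helpers: independent oracles and seeded instance generators.
# Everything here is deliberately naive and written independently of the
# package's own dynamic programs.

# symmetric difference of pair sets, counted directly on "i:j" strings
bf_bp_distance <- function(p1, p2) {
  k1 <- if (nrow(p1)) paste(p1[, 1], p1[, 2], sep = ":") else character(0)
  k2 <- if (nrow(p2)) paste(p2[, 1], p2[, 2], sep = ":") else character(0)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# restriction by direct filtering (independent of restrict_structure)
bf_restrict_pairs <- function(pairs, i, j) {
  keep <- pairs[, 1] >= i & pairs[, 2] <= j
  pairs[keep, , drop = FALSE]
}

# naive polynomial evaluation: sum over the enumerated ensemble
bf_evaluate <- function(seq, Sstar, x, model) {
  seq <- rna_sequence(seq)
  en <- enumerate_structures(seq, theta = Sstar$theta)
  tot <- 0 + 0i
  for (pairs in en$structures) {
    S <- secondary_structure(pairs, n = seq$n, theta = Sstar$theta)
    E <- structure_energy(seq, S, model)
    if (!is.finite(E)) next
    d <- bf_bp_distance(pairs, Sstar$pairs)
    tot <- tot + exp(-E / model$RT) * x^d
  }
  tot
}

# independent loop decomposition: children of each pair found by filtering,
# not by partner-vector walking
bf_turner_energy <- function(seq, S, model) {
  seq <- rna_sequence(seq)
  chars <- strsplit(seq$seq, "")[[1]]
  par <- model$params
  pairs <- S$pairs
  if (!nrow(pairs)) return(0)
  E <- 0
  for (a in seq_len(nrow(pairs))) {
    i <- pairs[a, 1]; j <- pairs[a, 2]
    inside <- pairs[pairs[, 1] > i & pairs[, 2] < j, , drop = FALSE]
    # children = inside pairs not enclosed by another inside pair
    is_child <- vapply(seq_len(nrow(inside)), function(b) {
      k <- inside[b, 1]; l <- inside[b, 2]
      !any(inside[, 1] < k & inside[, 2] > l)
    }, logical(1))
    children <- inside[is_child, , drop = FALSE]
    nc <- nrow(children)
    if (nc == 0) {
      E <- E + rnaprof:::loop_init_energy(par$hairpin, j - i - 1)
    } else if (nc == 1) {
      k <- children[1, 1]; l <- children[1, 2]
      E <- E + rnaprof:::interior_energy(
        par, rnaprof:::pair_type_index(chars[i], chars[j]),
        rnaprof:::pair_type_index(chars[k], chars[l]), k - i - 1, j - l - 1)
    } else {
      covered <- sum(children[, 2] - children[, 1] + 1)
      unpaired <- (j - i - 1) - covered
      E <- E + par$multiloop_init + par$multiloop_branch * (nc + 1) +
           par$multiloop_unpaired * unpaired
    }
  }
  E
}

# seeded random instance: sequence of length n and a reference drawn
# uniformly from the enumerated ensemble
rand_instance <- function(seed, nmin = 8L, nmax = 25L, theta = 3L) {
  n <- nmin + withr::with_seed(seed, sample.int(nmax - nmin + 1L, 1L)) - 1L
  seq <- random_rna(n, seed = seed + 1L)
  en <- enumerate_structures(seq, theta = theta)
  idx <- withr::with_seed(seed + 2L, sample.int(length(en$structures), 1L))
  Sstar <- secondary_structure(en$structures[[idx]], n = n, theta = theta)
  list(seq = seq, Sstar = Sstar, n = n, structures = en$structures)
}

# random non-crossing structure for property tests (via the ensemble of a
# random sequence)
rand_structure <- function(seed, n = 20L) {
  inst <- rand_instance(seed, nmin = n, nmax = n)
  inst$Sstar
}

# ---------------------------------------------------------------------------
# lazily-built shared suite for the acceptance tests: 100 seeded Nussinov
# instances, n in [8, 25], each with the FFT profile, the enumeration
# profile, the integer-distance DP and the raw evaluations
# ---------------------------------------------------------------------------
.suite_cache <- new.env(parent = emptyenv())

nussinov_suite <- function() {
  if (!is.null(.suite_cache$nussinov)) return(.suite_cache$nussinov)
  mod <- nussinov_model()
  suite <- lapply(1:100, function(r) {
    inst <- rand_instance(seed = 31000L + 7L * r, nmin = 8L, nmax = 25L)
    ev <- evaluate_on_roots(inst$seq, inst$Sstar, model = mod)
    list(seq = inst$seq, Sstar = inst$Sstar, n = inst$n, ev = ev,
         fft = recover_profile(ev),
         enum = exact_profile(inst$seq, inst$Sstar, mod),
         Zk = rnabor_integer_dp(inst$seq, inst$Sstar, mod))
  })
  .suite_cache$nussinov <- suite
  suite
}

turner_suite <- function() {
  if (!is.null(.suite_cache$turner)) return(.suite_cache$turner)
  mod <- turner_model()
  suite <- lapply(1:50, function(r) {
    inst <- rand_instance(seed = 57000L + 11L * r, nmin = 8L, nmax = 20L)
    list(seq = inst$seq, Sstar = inst$Sstar, n = inst$n,
         fft = structure_profile(inst$seq, inst$Sstar, model = mod),
         enum = exact_profile(inst$seq, inst$Sstar, mod))
  })
  .suite_cache$turner <- suite
  suite
}
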