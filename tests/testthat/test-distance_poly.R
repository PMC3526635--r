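test_that("pair and unpaired distance increments match their definitions", {
  # introducing the reference pair itself costs 0
  Sref <- secondary_structure(rbind(c(2, 8)), n = 10)
  expect_equal(pair_distance_increment(Sref, 1, 2, 8), 0L)
  # a novel pair against the empty reference costs 1
  expect_equal(pair_distance_increment(secondary_structure(NULL, n = 10), 1, 2, 8), 1L)
  # nested reference pair survives in the subinterval: only the new pair differs
  Snest <- secondary_structure(rbind(c(3, 7)), n = 10)
  expect_equal(pair_distance_increment(Snest, 1, 2, 8), 1L)

  S29 <- secondary_structure(rbind(c(2, 9)), n = 9)
  expect_equal(unpaired_increment(S29, 1, 9), 1L)
  expect_equal(unpaired_increment(S29, 3, 9), 0L)
  expect_equal(unpaired_increment(secondary_structure(NULL, n = 9), 1, 9), 0L)
})

test_that("pair increment equals the brute-force restricted-distance count", {
  for (seed in 1:10) {
    inst <- rand_instance(seed + 600L, nmin = 10L, nmax = 14L)
    Sstar <- inst$Sstar
    n <- inst$n
    combos <- withr::with_seed(seed, {
      cbind(i = sample(1:3, 6, TRUE), l = sample(4:7, 6, TRUE), j = sample(9:n, 6, TRUE))
    })
    for (r in seq_len(nrow(combos))) {
      i <- combos[r, 1]; l <- combos[r, 2]; j <- combos[r, 3]
      if (!(i <= l && l < j)) next
      # d({(l,j)}, S*[i,j]) - d({}, S*[i,l-1]) - d({}, S*[l+1,j-1])
      ref_ij <- bf_restrict_pairs(Sstar$pairs, i, j)
      ref_left <- bf_restrict_pairs(Sstar$pairs, i, l - 1)
      ref_mid <- bf_restrict_pairs(Sstar$pairs, l + 1, j - 1)
      bf <- bf_bp_distance(rbind(c(l, j)), ref_ij) - nrow(ref_left) - nrow(ref_mid)
      expect_equal(pair_distance_increment(Sstar, i, l, j), bf)
    }
  }
})

test_that("evaluation matches hand-enumerable micro-cases", {
  mod <- nussinov_model(epsilon = -1, RT = 1)
  expect_equal(Re(evaluate_at("AAAAA", ".....", 1, mod)), 1)
  expect_equal(evaluate_at("GAAAC", ".....", 1, mod), as.complex(1 + exp(1)))
  expect_equal(evaluate_at("GAAAC", ".....", -1, mod), as.complex(1 - exp(1)))
})

test_that("the DP equals naive ensemble summation at random unit-circle points", {
  for (seed in 1:6) {
    inst <- rand_instance(seed + 800L, nmin = 8L, nmax = 14L)
    xs <- withr::with_seed(seed, exp(2i * pi * runif(4)))
    for (mod in list(nussinov_model(), turner_model())) {
      for (x in xs) {
        got <- evaluate_at(inst$seq, inst$Sstar, x, mod)
        want <- bf_evaluate(inst$seq, inst$Sstar, x, mod)
        expect_lt(Mod(got - want) / Mod(want), 1e-10)
      }
    }
  }
})

test_that("evaluation at x = 1 reproduces the independent partition function", {
  for (seed in 1:8) {
    sq <- random_rna(10 + 3 * seed, seed = 900L + seed)
    for (mod in list(nussinov_model(), turner_model())) {
      z_poly <- Re(evaluate_at(sq, strrep(".", sq$n), 1, mod))
      z_ind <- partition_function(sq, mod)
      expect_lt(abs(z_poly - z_ind) / z_ind, 1e-10)
    }
  }
})

test_that("roots-of-unity evaluation has the documented shape and symmetry", {
  mod <- nussinov_model(epsilon = -1, RT = 1)
  ev <- evaluate_on_roots("GAAAC", ".....", mod, m = 4)
  e <- exp(1)
  expect_equal(ev$values, complex(real = c(1 + e, 1, 1 - e, 1), imaginary = c(0, e, 0, -e)))
  expect_equal(ev$Z, 1 + e)
  # conjugate symmetry and a real positive leading entry on a bigger instance
  inst <- rand_instance(1234L, nmin = 18L, nmax = 18L)
  ev2 <- evaluate_on_roots(inst$seq, inst$Sstar, nussinov_model())
  m <- ev2$m
  for (j in 1:(m - 1)) {
    expect_lt(Mod(ev2$values[m - j + 1] - Conj(ev2$values[j + 1])), 1e-8 * ev2$Z)
  }
  expect_gt(Re(ev2$values[1]), 0)
  expect_lt(abs(Im(ev2$values[1])), 1e-12 * ev2$Z)
  expect_error(evaluate_on_roots(inst$seq, inst$Sstar, nussinov_model(), m = 2),
               "too small")
})

test_that("half-evaluation equals full evaluation", {
  inst <- rand_instance(77L, nmin = 15L, nmax = 15L)
  full <- evaluate_on_roots(inst$seq, inst$Sstar, nussinov_model(), half_evaluation = FALSE)
  half <- evaluate_on_roots(inst$seq, inst$Sstar, nussinov_model(), half_evaluation = TRUE)
  expect_lt(max(Mod(full$values - half$values)), 1e-9 * full$Z)
})
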