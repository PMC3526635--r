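test_that("roots of unity are exact at the anchor points", {
  expect_equal(roots_of_unity(1), as.complex(1))
  expect_equal(roots_of_unity(2), as.complex(c(1, -1)))
  expect_equal(roots_of_unity(4), complex(real = c(1, 0, -1, 0), imaginary = c(0, 1, 0, -1)))
  expect_identical(roots_of_unity(7)[1], 1 + 0i)
  expect_error(roots_of_unity(0), "positive")
})

test_that("the inverse DFT inverts evaluation at roots of unity", {
  expect_equal(inverse_dft(c(1, 1, 1, 1)), as.complex(c(1, 0, 0, 0)))
  expect_equal(inverse_dft(c(2, 0, 2, 0)), as.complex(c(1, 0, 1, 0)))  # 1 + x^2
  expect_equal(Re(inverse_dft(c(1, 0))), c(0.5, 0.5))
  # round trip on random real coefficient vectors
  for (seed in 1:8) {
    coefs <- withr::with_seed(seed, runif(seed + 3))
    m <- length(coefs)
    om <- roots_of_unity(m)
    vals <- vapply(om, function(x) sum(coefs * x^(seq_len(m) - 1)), complex(1))
    back <- inverse_dft(vals)
    expect_equal(Re(back), coefs, tolerance = 1e-12)
    expect_lt(max(abs(Im(back))), 1e-12)
  }
})

test_that("profile recovery reproduces the two-structure micro-case", {
  mod <- nussinov_model(epsilon = -1, RT = 1)
  e <- exp(1)
  p1 <- structure_profile("GAAAC", ".....", model = mod, m = 4, digits = 4)
  expect_equal(p1$p, c(0.2689, 0.7311, 0, 0))
  expect_equal(profile_probabilities(p1), c(1, e, 0, 0) / (1 + e), tolerance = 1e-12)
  p2 <- structure_profile("GAAAC", "(...)", model = mod, m = 4, digits = 4)
  expect_equal(p2$p, c(0.7311, 0.2689, 0, 0))
  p3 <- structure_profile("AAAAA", ".....", model = mod)
  expect_equal(profile_probabilities(p3)[1], 1, tolerance = 1e-12)
  expect_true(all(abs(profile_probabilities(p3)[-1]) < 1e-12))
})

test_that("profiles are normalized with support inside the distance bound", {
  for (seed in c(5, 21, 33)) {
    inst <- rand_instance(seed + 1500L, nmin = 12L, nmax = 22L)
    prof <- structure_profile(inst$seq, inst$Sstar, model = nussinov_model())
    p <- profile_probabilities(prof)
    expect_lt(abs(profile_meta(prof)$pre_truncation_mass - 1), 1e-9)
    expect_true(all(p >= 0 | p > -1e-9))
    K <- max_distance_bound(inst$Sstar)
    if (length(p) > K + 1) expect_lt(max(abs(p[(K + 2):length(p)])), 1e-9)
  }
})

test_that("p(0) * Z recovers the Boltzmann factor of the reference", {
  for (seed in c(2, 8)) {
    inst <- rand_instance(seed + 1700L, nmin = 10L, nmax = 20L)
    for (mod in list(nussinov_model(), turner_model())) {
      prof <- structure_profile(inst$seq, inst$Sstar, model = mod)
      Z <- profile_meta(prof)$Z
      lhs <- profile_probabilities(prof)[1] * Z
      rhs <- exp(-structure_energy(inst$seq, inst$Sstar, mod) / mod$RT)
      # relative when p(0) is well-scaled, Z-relative at the precision floor
      expect_lt(min(abs(lhs - rhs) / rhs, abs(lhs - rhs) / Z), 1e-9)
    }
  }
})

test_that("digit rounding moves total variation by less than 5e-6 per point", {
  inst <- rand_instance(4242L, nmin = 20L, nmax = 20L)
  prof <- structure_profile(inst$seq, inst$Sstar, model = nussinov_model(), digits = 6L)
  tv <- total_variation(profile_probabilities(prof), prof$p)
  expect_lt(tv, 5e-6 * length(prof$p))
})

test_that("TSV output carries metadata and the k/p table", {
  prof <- structure_profile("GAAAC", ".....", model = nussinov_model(RT = 1), digits = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(prof, f)
  lines <- readLines(f)
  expect_true(any(grepl("^# model: nussinov", lines)))
  expect_true(any(grepl("^# reference: \\.\\.\\.\\.\\.$", lines)))
  body <- lines[!grepl("^#", lines)][-1]
  expect_equal(length(body), 2L)  # rows up to the last nonzero k
  expect_equal(strsplit(body[2], "\t")[[1]][2], "0.7311")
})
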