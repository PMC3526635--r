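# ---------------------------------------------------------------------------
# Coefficient recovery: inverse DFT of the evaluations at roots of unity
# ---------------------------------------------------------------------------

#' Complex roots of unity
#'
#' @param m A positive integer.
#' @return The vector `exp(2 pi i j / m)` for `j = 0..m-1`; the first element
#'   is exactly 1.
#' @export
roots_of_unity <- function(m) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) abort("`m` must be a positive integer")
  om <- exp(2i * pi * (seq_len(m) - 1L) / m)
  om[1L] <- 1 + 0i
  om
}

#' Inverse discrete Fourier transform
#'
#' Recovers polynomial coefficients from values at the m-th roots of unity:
#' `a_k = (1/m) * sum_j values[j] * omega^{-kj}` (the Vandermonde inverse).
#' Composing with forward evaluation is the identity to machine precision.
#'
#' @param values Complex vector of length `m`.
#' @return Complex coefficient vector of length `m`.
#' @examples
#' inverse_dft(c(2, 0, 2, 0))  # 1 + x^2
#' @export
inverse_dft <- function(values) {
  if (!length(values)) abort("`values` must be non-empty")
  stats::fft(as.complex(values)) / length(values)
}

#' Recover the structural profile from polynomial evaluations
#'
#' Normalizes the evaluations by the partition function `Z` (the value at
#' `x = 1`), applies the inverse DFT, takes real parts as the probabilities
#' `p(k)` and reports them to `digits` decimal places.  Negative round-off
#' coefficients in `(-10^-digits, 0)` are clamped to zero; the vector is
#' renormalized only if the clamped mass exceeds `10^-digits`.  A large
#' imaginary residual or a pre-truncation mass away from 1 signals a dynamic
#' programming or symmetry bug and raises a hard error.
#'
#' @param ev A `complex_evaluation` from [evaluate_on_roots()].
#' @param digits Truncation precision, default 6 decimal places.
#' @return A `structural_profile`: a tibble with columns `k` and `p`
#'   (truncated probabilities), carrying the full-precision vector and run
#'   metadata as attributes (see [profile_probabilities()]).
#' @export
recover_profile <- function(ev, digits = 6L) {
  stopifnot(inherits(ev, "complex_evaluation"))
  m <- ev$m
  coef <- inverse_dft(ev$values / ev$Z)
  imag_res <- max(abs(Im(coef)))
  if (imag_res > 1e-6) {
    abort(sprintf("imaginary residual %.3g exceeds 1e-6: distance-polynomial evaluation is inconsistent", imag_res),
          class = "rnaprof_numerical_error")
  }
  p <- Re(coef)
  mass <- sum(p)
  if (abs(mass - 1) > 1e-6) {
    abort(sprintf("probabilities sum to %.8f before truncation (|sum - 1| > 1e-6)", mass),
          class = "rnaprof_numerical_error")
  }
  tol <- 10^(-digits)
  clamped <- p < 0 & p > -tol
  clamped_mass <- -sum(p[clamped])
  p[clamped] <- 0
  if (clamped_mass > tol) p <- p / sum(p)
  p_trunc <- round(p, digits)
  new_structural_profile(p_trunc, p_full = p, digits = digits,
                         meta = list(seq_id = ev$seq_id, n = ev$n,
                                     reference = ev$reference, model = ev$model,
                                     theta = ev$theta, RT = ev$RT, Z = ev$Z,
                                     bound = ev$bound, method = "fft",
                                     imag_residual = imag_res,
                                     pre_truncation_mass = mass))
}

new_structural_profile <- function(p, p_full, digits, meta) {
  out <- tibble::new_tibble(
    list(k = seq_along(p) - 1L, p = p),
    nrow = length(p),
    class = "structural_profile"
  )
  attr(out, "p_full") <- p_full
  attr(out, "digits") <- digits
  attr(out, "meta") <- meta
  out
}

#' Access profile probabilities and metadata
#'
#' `profile_probabilities()` returns the probability vector `p(0..m-1)`,
#' either as printed (truncated to the profile's `digits`) or at full double
#' precision.  `profile_meta()` returns the run metadata (sequence id,
#' reference, model, theta, RT, Z, distance bound, imaginary residual).
#'
#' @param profile A `structural_profile`.
#' @param truncated Return the truncated (printed) values? Default FALSE.
#' @export
profile_probabilities <- function(profile, truncated = FALSE) {
  if (truncated) profile$p else attr(profile, "p_full")
}

#' @rdname profile_probabilities
#' @export
profile_meta <- function(profile) attr(profile, "meta")

#' @export
print.structural_profile <- function(x, ...) {
  meta <- profile_meta(x)
  cat(sprintf("# structural profile: %s (n=%d), reference %s\n# model %s, Z = %.6g\n",
              meta$seq_id, meta$n, meta$reference, meta$model, meta$Z))
  NextMethod()
}

#' Compute a structural-neighbor profile
#'
#' The main pipeline: validates the inputs, evaluates the distance-indexed
#' partition-function polynomial at roots of unity and recovers `p(k)`, the
#' Boltzmann probability that a structure of `seq` lies at base-pair distance
#' `k` from the reference.
#'
#' @param seq An [rna_sequence()] or string.
#' @param reference Reference structure: a `secondary_structure`, a
#'   dot-bracket string, or `"mfe"` to fold the sequence first (see
#'   [mfe_structure()]).  The empty structure (all dots) yields the
#'   distribution of the number of base pairs per structure.
#' @param model An `energy_model`; default [turner_model()].
#' @param m Number of evaluation points (default: sequence length).
#' @param digits Truncation precision of the printed probabilities.
#' @param theta Minimum hairpin size used when parsing `reference`.
#' @param rule A [base_pair_rule()].
#' @param validate Reject references with inadmissible pairs (default TRUE);
#'   when FALSE such pairs only trigger a warning (the distance bookkeeping
#'   is still exact).
#' @return A `structural_profile` tibble (columns `k`, `p`).
#' @examples
#' structure_profile("GAAAC", ".....", model = nussinov_model(RT = 1), digits = 4)
#' @export
structure_profile <- function(seq, reference, model = turner_model(), m = NULL,
                              digits = 6L, theta = 3L, rule = base_pair_rule(),
                              validate = TRUE) {
  seq <- rna_sequence(seq)
  if (is.character(reference) && length(reference) == 1L && identical(reference, "mfe")) {
    reference <- mfe_structure(seq, model, theta = theta, rule = rule)
  } else {
    reference <- parse_dot_bracket(reference, theta = theta)
  }
  bad <- validate_compatibility(seq, reference, rule)
  if (nrow(bad)) {
    msg <- sprintf("reference contains %d pair(s) not admissible under the pairing rule (first: (%d,%d)=%s-%s)",
                   nrow(bad), bad$i[1L], bad$j[1L], bad$nt_i[1L], bad$nt_j[1L])
    if (validate) abort(msg) else warn(msg)
  }
  ev <- evaluate_on_roots(seq, reference, model = model, m = m, rule = rule)
  recover_profile(ev, digits = digits)
}

#' Total variation distance between two profiles
#'
#' Half the L1 distance between two probability vectors; profiles (or bare
#' vectors) of different lengths are compared after zero-padding.
#'
#' @param p,q `structural_profile` objects or numeric vectors.
#' @param truncated Compare truncated (printed) values instead of
#'   full-precision ones.
#' @return A number in `[0, 1]`.
#' @export
total_variation <- function(p, q, truncated = FALSE) {
  pv <- if (inherits(p, "structural_profile")) profile_probabilities(p, truncated) else as.numeric(p)
  qv <- if (inherits(q, "structural_profile")) profile_probabilities(q, truncated) else as.numeric(q)
  len <- max(length(pv), length(qv))
  sum(abs(c(pv, numeric(len - length(pv))) - c(qv, numeric(len - length(qv))))) / 2
}

#' Write a profile as TSV
#'
#' Writes `#`-prefixed metadata lines followed by a two-column table `k`,
#' `p(k)` up to the last nonzero index.
#'
#' @param profile A `structural_profile`.
#' @param path Output file path (or connection); `""` prints to stdout.
#' @export
write_profile_tsv <- function(profile, path = "") {
  meta <- profile_meta(profile)
  hdr <- c(sprintf("# id: %s", meta$seq_id),
           sprintf("# reference: %s", meta$reference),
           sprintf("# model: %s", meta$model),
           sprintf("# theta: %d", meta$theta),
           sprintf("# RT: %.6g", meta$RT),
           sprintf("# Z: %.10g", meta$Z),
           sprintf("# digits: %d", attr(profile, "digits")))
  last <- max(c(1L, which(profile$p > 0)))
  body <- sprintf("%d\t%s", profile$k[seq_len(last)],
                  format(profile$p[seq_len(last)], scientific = FALSE, trim = TRUE))
  writeLines(c(hdr, "k\tp", body), con = if (identical(path, "")) stdout() else path)
  invisible(profile)
}
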