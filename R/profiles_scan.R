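# ---------------------------------------------------------------------------
# Profile statistics and moving-window / prefix-scan applications
# ---------------------------------------------------------------------------

#' Summary statistics of a structural profile
#'
#' The mean `mu = sum k p(k)` is the expected base-pair distance to the
#' reference; with the empty reference it is the expected number of base
#' pairs per structure.  `sigma` is the standard deviation and `cv = sigma /
#' mu` the coefficient of variation (a landscape-ruggedness descriptor;
#' undefined when `mu = 0`).  Statistics use the full-precision
#' probabilities, not the truncated printed values.
#'
#' @param profile A `structural_profile`.
#' @return A one-row tibble with columns `mean`, `sd`, `cv`, `support`.
#' @export
profile_stats <- function(profile) {
  p <- profile_probabilities(profile)
  k <- seq_along(p) - 1
  mu <- sum(k * p)
  sigma <- sqrt(max(0, sum(k^2 * p) - mu^2))
  digits <- attr(profile, "digits")
  tol <- if (is.null(digits) || is.na(digits)) 0 else 10^(-digits - 3L)
  tibble::tibble(
    mean = mu,
    sd = sigma,
    cv = if (mu > 0) sigma / mu else NA_real_,
    support = max(c(0L, k[p > tol]))
  )
}

#' Expected base-pair distance to a target structure
#'
#' Runs the full profile pipeline with the target as reference and returns
#' the profile mean.
#'
#' @inheritParams structure_profile
#' @param target Target structure (dot-bracket string or
#'   `secondary_structure`).
#' @return A single number (base pairs).
#' @export
expected_distance_to <- function(seq, target, model = turner_model(), m = NULL,
                                 theta = 3L, rule = base_pair_rule()) {
  p <- structure_profile(seq, target, model = model, m = m, theta = theta,
                         rule = rule, validate = FALSE)
  profile_stats(p)$mean
}

#' Moving-window scan against a target structure
#'
#' Slides a window of length `|target|` along the sequence and computes, for
#' each offset, the expected base-pair distance of the window's Boltzmann
#' ensemble to the target.  A well-defined minimum localizes where the
#' target structure (e.g. a riboswitch expression platform) can form.
#'
#' @inheritParams expected_distance_to
#' @param step Offset step size (default 1).
#' @return A tibble of class `scan_track` with columns `offset` (1-based
#'   window start) and `expected_distance`.
#' @export
window_scan <- function(seq, target, step = 1L, model = turner_model(),
                        theta = 3L, rule = base_pair_rule()) {
  seq <- rna_sequence(seq)
  target <- parse_dot_bracket(target, theta = theta)
  w <- target$n
  if (w > seq$n) abort(sprintf("target length %d exceeds sequence length %d", w, seq$n))
  offsets <- seq.int(1L, seq$n - w + 1L, by = as.integer(step))
  vals <- purrr::map_dbl(offsets, function(o) {
    sub <- rna_sequence(substr(seq$seq, o, o + w - 1L),
                        id = sprintf("%s[%d-%d]", seq$id, o, o + w - 1L))
    # most windows cannot realize the target's pairs; that is the signal, so
    # pairing-rule warnings are silenced here
    suppressWarnings(
      expected_distance_to(sub, target, model = model, theta = theta, rule = rule))
  })
  out <- tibble::new_tibble(list(offset = offsets, expected_distance = vals),
                            nrow = length(offsets), class = "scan_track")
  attr(out, "window") <- w
  attr(out, "step") <- as.integer(step)
  attr(out, "target") <- format_dot_bracket(target)
  attr(out, "seq_id") <- seq$id
  out
}

#' Profiles of all prefixes of a sequence
#'
#' For each prefix length `L` in `from:to`, computes the structural profile
#' of the prefix with the reference taken as its own MFE structure
#' (`ref = "mfe"`) or the empty structure (`ref = "empty"`).  Co-transcriptional
#' emergence of competing conformations shows up as multimodal prefix
#' profiles.
#'
#' @inheritParams structure_profile
#' @param from,to Prefix length range (`from <= to <= n`).
#' @param ref `"mfe"` or `"empty"`.
#' @return A tibble of class `prefix_scan` in long format (columns
#'   `prefix_length`, `k`, `p`), with the individual `structural_profile`
#'   objects in `attr(, "profiles")`.
#' @export
prefix_scan <- function(seq, from, to, model = turner_model(),
                        ref = c("mfe", "empty"), theta = 3L,
                        rule = base_pair_rule(), digits = 6L) {
  seq <- rna_sequence(seq)
  ref <- match.arg(ref)
  from <- as.integer(from); to <- as.integer(to)
  if (from > to || to > seq$n || from < 1L) {
    abort(sprintf("need 1 <= from <= to <= n (got from=%d, to=%d, n=%d)", from, to, seq$n))
  }
  profiles <- purrr::map(from:to, function(L) {
    pre <- rna_sequence(substr(seq$seq, 1L, L), id = sprintf("%s[1-%d]", seq$id, L))
    reference <- if (ref == "mfe") mfe_structure(pre, model, theta = theta, rule = rule)
                 else secondary_structure(NULL, n = L, theta = theta)
    structure_profile(pre, reference, model = model, theta = theta,
                      rule = rule, digits = digits)
  })
  names(profiles) <- as.character(from:to)
  long <- dplyr::bind_rows(purrr::map2(profiles, from:to, function(pr, L) {
    tibble::tibble(prefix_length = L, k = pr$k, p = profile_probabilities(pr))
  }))
  out <- tibble::new_tibble(long, nrow = nrow(long), class = "prefix_scan")
  attr(out, "profiles") <- profiles
  attr(out, "ref") <- ref
  out
}
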