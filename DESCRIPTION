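Package: rnaprof
Title: Boltzmann Structural-Neighbor Profiles for RNA Secondary Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes, for an RNA sequence and a fixed reference secondary
    structure, the Boltzmann probability p(k) that a structure drawn from the
    thermodynamic ensemble lies at base-pair distance k from the reference.
    The distance-indexed partition-function polynomial is evaluated at complex
    roots of unity by an interval dynamic program and its coefficients are
    recovered with the inverse discrete Fourier transform, which is numerically
    stable where direct polynomial expansion and Lagrange interpolation are
    not.  Includes Nussinov-Jacobson and nearest-neighbor (Turner-style) energy
    models, an exhaustive enumeration oracle and an integer-distance dynamic
    program for validation, profile summary statistics, moving-window and
    prefix scans for conformational-switch localization, and seeded sequence
    generators including the Altschul-Erikson dinucleotide shuffle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    rlang,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Biostrings
Config/testthat/edition: 3
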