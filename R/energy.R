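#' Thermodynamic constants
#'
#' @param R Gas constant in kcal/(mol K).
#' @param T Absolute temperature in K (default 310.15 K = 37 C).
#' @return A list with `R`, `T` and their product `RT` (kcal/mol).
#' @export
thermo_constants <- function(R = 0.0019872, T = 310.15) {
  if (R <= 0 || T <= 0) abort("R and T must be positive")
  list(R = R, T = T, RT = R * T)
}

#' Boltzmann factor of an energy
#'
#' @param E Free energy in kcal/mol (may be `Inf` for forbidden states).
#' @param RT Thermal energy kcal/mol; defaults to 37 C.
#' @return `exp(-E / RT)`.
#' @export
boltzmann_factor <- function(E, RT = thermo_constants()$RT) {
  exp(-E / RT)
}

#' Energy models
#'
#' `nussinov_model()` scores a structure as `epsilon` times its number of
#' base pairs (the Nussinov-Jacobson model).  `turner_model()` scores the
#' unique loop decomposition with a bundled nearest-neighbor table: stacks,
#' hairpin/bulge/internal initiation with Jacobson-Stockmayer extrapolation,
#' and an affine multiloop `a + b * branches + c * unpaired`.  Dangles,
#' coaxial stacking and special hairpin bonuses are not modelled.
#'
#' @param epsilon Energy per base pair, kcal/mol (default -1).
#' @param RT Thermal energy kcal/mol.
#' @param param_file Path to a plain-text key/value parameter table; defaults
#'   to the table shipped with the package.
#' @param params Named list of overrides applied on top of the loaded table
#'   (e.g. `list(multiloop_unpaired = 0.1)`).
#' @return An object of class `energy_model`.
#' @examples
#' nussinov_model(epsilon = -1, RT = 1)
#' @export
nussinov_model <- function(epsilon = -1, RT = thermo_constants()$RT) {
  structure(list(name = "nussinov", epsilon = epsilon, RT = RT),
            class = c("nussinov_model", "energy_model"))
}

#' @rdname nussinov_model
#' @export
turner_model <- function(param_file = NULL, RT = thermo_constants()$RT, params = NULL) {
  if (is.null(param_file)) {
    param_file <- system.file("extdata", "turner_params.txt", package = "rnaprof")
  }
  tab <- read_turner_params(param_file)
  if (!is.null(params)) tab <- modifyList(tab, params)
  structure(list(name = "turner", params = tab, RT = RT),
            class = c("turner_model", "energy_model"))
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("<energy_model> %s (RT = %.4f kcal/mol)\n", x$name, x$RT))
  invisible(x)
}

# pair type order used throughout: AU UA CG GC GU UG
PAIR_TYPES <- c("AU", "UA", "CG", "GC", "GU", "UG")

read_turner_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  toks <- strsplit(trimws(lines), "\\s+")
  stack <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  hairpin <- numeric(0); bulge <- numeric(0); internal <- numeric(0)
  scalars <- list()
  for (tk in toks) {
    switch(tk[1L],
      stack = { stack[tk[2L], tk[3L]] <- as.numeric(tk[4L]) },
      hairpin = { hairpin[as.integer(tk[2L])] <- as.numeric(tk[3L]) },
      bulge = { bulge[as.integer(tk[2L])] <- as.numeric(tk[3L]) },
      internal = { internal[as.integer(tk[2L])] <- as.numeric(tk[3L]) },
      { scalars[[tk[1L]]] <- as.numeric(tk[2L]) }
    )
  }
  c(list(stack = stack, hairpin = hairpin, bulge = bulge, internal = internal), scalars)
}

# loop-initiation energy with Jacobson-Stockmayer extrapolation; sizes below
# the table start are forbidden (Inf)
loop_init_energy <- function(tab, size) {
  known <- which(!is.na(tab))
  smin <- min(known); smax <- max(known)
  js <- 1.75 * 0.0019872 * 310.15
  ifelse(size < smin, Inf,
         ifelse(size <= smax, tab[pmin(size, smax)],
                tab[smax] + js * log(size / smax)))
}

pair_type_index <- function(a, b) match(paste0(a, b), PAIR_TYPES)

# interior-loop (incl. stack, bulge) energy between outer pair (i,j) and
# inner pair (k,l); vectorized over k,l
interior_energy <- function(par, ptype_out, ptype_in, n1, n2) {
  size <- n1 + n2
  E <- ifelse(size == 0L,
              par$stack[cbind(ptype_out, ptype_in)],
              ifelse(n1 == 0L | n2 == 0L,
                     loop_init_energy(par$bulge, pmax(size, 1L)),
                     loop_init_energy(par$internal, pmax(size, 2L)) +
                       pmin(par$internal_asym * abs(n1 - n2), par$internal_asym_max)))
  E[size > par$max_internal] <- Inf
  E
}

#' Nussinov-Jacobson energy of a structure
#'
#' @param S A `secondary_structure`.
#' @param epsilon Energy per base pair (kcal/mol).
#' @return `epsilon * |pairs|`; zero for the empty structure.
#' @export
nussinov_energy <- function(S, epsilon = -1) {
  epsilon * nrow(S$pairs)
}

# loop decomposition of a structure: returns a list of loops, each a list
# with type in {hairpin, stack, bulge, internal, multiloop} and fields
decompose_loops <- function(S) {
  np <- nrow(S$pairs)
  if (!np) return(list())
  pairs <- S$pairs
  partner <- S$partner
  loops <- vector("list", np)
  for (a in seq_len(np)) {
    i <- pairs[a, 1L]; j <- pairs[a, 2L]
    # children: maximal pairs strictly inside (i,j)
    children <- matrix(integer(0), 0L, 2L)
    unpaired <- 0L
    pos <- i + 1L
    while (pos < j) {
      q <- partner[pos]
      if (!is.na(q) && q > pos) {
        children <- rbind(children, c(pos, q))
        pos <- q + 1L
      } else {
        unpaired <- unpaired + 1L
        pos <- pos + 1L
      }
    }
    nc <- nrow(children)
    if (nc == 0L) {
      loops[[a]] <- list(type = "hairpin", i = i, j = j, size = j - i - 1L)
    } else if (nc == 1L) {
      k <- children[1L, 1L]; l <- children[1L, 2L]
      n1 <- k - i - 1L; n2 <- j - l - 1L
      type <- if (n1 + n2 == 0L) "stack" else if (n1 == 0L || n2 == 0L) "bulge" else "internal"
      loops[[a]] <- list(type = type, i = i, j = j, k = k, l = l, n1 = n1, n2 = n2)
    } else {
      loops[[a]] <- list(type = "multiloop", i = i, j = j,
                         branches = nc + 1L, unpaired = unpaired)
    }
  }
  loops
}

#' Nearest-neighbor (Turner-style) energy of a structure
#'
#' Sums loop free energies over the unique loop decomposition of `S`:
#' hairpins, stacks, bulges, internal loops and affine multiloops.  The
#' exterior loop contributes zero.  Loops outside the tabulated/extrapolated
#' range (hairpins smaller than the table minimum, interior loops larger than
#' `max_internal`) are assigned `Inf`, i.e. zero Boltzmann weight.
#'
#' @param seq An [rna_sequence()] (or string).
#' @param S A compatible `secondary_structure`.
#' @param model A [turner_model()].
#' @return Free energy in kcal/mol.
#' @export
turner_energy <- function(seq, S, model = turner_model()) {
  seq <- rna_sequence(seq)
  bad <- validate_compatibility(seq, S)
  if (nrow(bad)) {
    abort(sprintf("pair (%d,%d) = %s-%s is not admissible", bad$i[1L], bad$j[1L],
                  bad$nt_i[1L], bad$nt_j[1L]))
  }
  turner_energy_fast(seq_chars(seq), S, model$params)
}

# validation-free kernel shared with the enumeration oracle
turner_energy_fast <- function(chars, S, par) {
  loops <- decompose_loops(S)
  E <- 0
  for (lp in loops) {
    E <- E + switch(lp$type,
      hairpin = loop_init_energy(par$hairpin, lp$size),
      stack = ,
      bulge = ,
      internal = interior_energy(par,
                                 pair_type_index(chars[lp$i], chars[lp$j]),
                                 pair_type_index(chars[lp$k], chars[lp$l]),
                                 lp$n1, lp$n2),
      multiloop = par$multiloop_init + par$multiloop_branch * lp$branches +
                  par$multiloop_unpaired * lp$unpaired)
  }
  E
}

#' Energy of a structure under a model
#'
#' Generic dispatcher used by the oracle: Nussinov-Jacobson or Turner-style.
#'
#' @inheritParams turner_energy
#' @param model An `energy_model`.
#' @export
structure_energy <- function(seq, S, model) {
  UseMethod("structure_energy", model)
}

#' @export
structure_energy.nussinov_model <- function(seq, S, model) {
  nussinov_energy(S, model$epsilon)
}

#' @export
structure_energy.turner_model <- function(seq, S, model) {
  turner_energy(seq, S, model)
}
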