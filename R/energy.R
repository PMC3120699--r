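# Nearest-neighbor thermodynamic model (intrinsic information source).
#
# The model is deliberately simplified relative to full rule sets used by
# mature folding engines: Watson-Crick + GU wobble stacking energies,
# length-tabulated hairpin/bulge/internal penalties with log extrapolation,
# a linear multibranch term, and a terminal AU/GU penalty charged in every
# non-stacking context. Parameters live in a versioned YAML file and are
# pluggable, so a richer table can be dropped in without code changes.

PAIR_TYPES <- c("AU", "UA", "GC", "CG", "GU", "UG")
GAS_CONSTANT <- 0.0019872  # kcal / (mol K)

.coinfold_env <- new.env(parent = emptyenv())

#' Load nearest-neighbor energy parameters
#'
#' Reads the versioned YAML parameter file (the built-in file
#' `energy_params_v1.yaml` by default), validates it, and returns the
#' internal parameter list. The gas constant times temperature, `RT`, is
#' recomputed from `temperature_kelvin`, so overriding the temperature in a
#' parameter file consistently rescales every Boltzmann weight.
#'
#' @param path Path to a YAML parameter file, or `NULL` for the built-in
#'   defaults (cached after the first load).
#' @return List of class `energy_params` with fields `RT`, `min_hairpin`,
#'   `stack` (6 x 6 matrix over pair types AU, UA, GC, CG, GU, UG),
#'   `hairpin`, `bulge`, `internal` (each a list with `first_length` and
#'   `energies`), `multibranch` (`offset`, `per_branch`, `per_unpaired`),
#'   `terminal_au_penalty` and `loop_extrapolation_coeff`.
#' @export
load_energy_params <- function(path = NULL) {
  if (is.null(path)) {
    cached <- .coinfold_env$default_energy
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "energy_params_v1.yaml", package = "coinfold")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  raw <- yaml::read_yaml(path)
  tK <- as.numeric(raw$temperature_kelvin)
  if (!is.finite(tK) || tK <= 0) stop("energy params: temperature_kelvin must be positive", call. = FALSE)
  stack <- matrix(NA_real_, 6L, 6L, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  for (p in PAIR_TYPES) {
    for (q in PAIR_TYPES) {
      v <- raw$stack[[p]][[q]]
      if (is.null(v)) stop(sprintf("energy params: missing stack entry %s/%s", p, q), call. = FALSE)
      stack[p, q] <- as.numeric(v)
    }
  }
  check_table <- function(tab, what, min_needed) {
    fl <- as.integer(tab$first_length)
    en <- as.numeric(tab$energies)
    if (length(en) < 1L || anyNA(en)) stop(sprintf("energy params: bad %s table", what), call. = FALSE)
    if (fl > min_needed) {
      stop(sprintf("energy params: %s table must start at length %d or below", what, min_needed), call. = FALSE)
    }
    list(first_length = fl, energies = en)
  }
  mh <- as.integer(raw$min_hairpin)
  if (is.na(mh) || mh < 0L) stop("energy params: min_hairpin must be >= 0", call. = FALSE)
  params <- structure(list(
    version = raw$version,
    temperature_kelvin = tK,
    RT = GAS_CONSTANT * tK,
    min_hairpin = mh,
    terminal_au_penalty = as.numeric(raw$terminal_au_penalty),
    loop_extrapolation_coeff = as.numeric(raw$loop_extrapolation_coeff),
    stack = stack,
    hairpin = check_table(raw$hairpin, "hairpin", max(mh, 1L)),
    bulge = check_table(raw$bulge, "bulge", 1L),
    internal = check_table(raw$internal, "internal", 2L),
    multibranch = list(offset = as.numeric(raw$multibranch$offset),
                       per_branch = as.numeric(raw$multibranch$per_branch),
                       per_unpaired = as.numeric(raw$multibranch$per_unpaired)),
    source = path
  ), class = "energy_params")
  if (cache) .coinfold_env$default_energy <- params
  params
}

#' Canonical base-pair test
#'
#' `TRUE` exactly for the canonical pairs AU, UA, GC, CG and the GU/UG
#' wobble pairs.
#'
#' @param a,b Single residues in A, C, G, U (vectorized).
#' @return Logical vector.
#' @examples
#' can_pair("G", "U")  # TRUE: wobble is canonical
#' can_pair("A", "C")  # FALSE
#' @export
can_pair <- function(a, b) {
  paste0(a, b) %in% PAIR_TYPES
}

pair_type <- function(a, b) {
  pt <- paste0(a, b)
  pt[!pt %in% PAIR_TYPES] <- NA_character_
  pt
}

# Loop penalty with Jacobson-Stockmayer extrapolation beyond the table.
loop_energy <- function(n, tab, params) {
  fl <- tab$first_length
  en <- tab$energies
  nmax <- fl + length(en) - 1L
  ifelse(n <= nmax,
         en[pmax(n - fl + 1L, 1L)],
         en[length(en)] + params$loop_extrapolation_coeff * params$RT * log(n / nmax))
}

hairpin_energy <- function(n, params) loop_energy(n, params$hairpin, params)
bulge_energy <- function(n, params) loop_energy(n, params$bulge, params)
internal_energy <- function(n, params) loop_energy(n, params$internal, params)

# Terminal AU/GU penalty for one pair, by residues.
au_penalty <- function(a, b, params) {
  ifelse(paste0(a, b) %in% c("AU", "UA", "GU", "UG"), params$terminal_au_penalty, 0)
}

#' Free energy change of a secondary structure
#'
#' Evaluates the Gibbs free energy change of folding under the shipped
#' simplified nearest-neighbor model by decomposing the structure into its
#' loops: stacked pairs, hairpin loops, bulge and internal loops, multibranch
#' loops (linear model: offset + per-branch + per-unpaired, the closing pair
#' counting as a branch) and the exterior loop (zero per unpaired base).
#' The terminal AU/GU penalty is charged for every AU/UA/GU/UG pair that
#' closes a hairpin, bulge, internal or multibranch loop, and for every such
#' pair that starts a branch in a multibranch or exterior loop; stacked pair
#' interfaces carry no penalty.
#'
#' @param seq An [rna_sequence].
#' @param st A valid [secondary_structure] on the sequence; every pair must
#'   be canonical and enclose at least `params$min_hairpin` nucleotides.
#' @param params Parameters from [load_energy_params].
#' @return Free energy change in kcal/mol; exactly 0 for the empty structure.
#' @examples
#' s <- rna_sequence("hp", "GGGAAACCC")
#' st <- secondary_structure(rbind(c(1, 9), c(2, 8), c(3, 7)), 9)
#' structure_free_energy(s, st, load_energy_params())
#' @export
structure_free_energy <- function(seq, st, params = load_energy_params()) {
  if (st$length != seq$length) stop("structure and sequence lengths differ", call. = FALSE)
  ok <- is_valid_structure(st)
  if (!isTRUE(ok)) stop(attr(ok, "why"), call. = FALSE)
  p <- st$pairs
  if (nrow(p) == 0L) return(0)
  r <- seq$residues
  for (row in seq_len(nrow(p))) {
    i <- p[row, 1L]; j <- p[row, 2L]
    if (!can_pair(r[i], r[j])) {
      stop(sprintf("non-canonical pair (%d,%d): %s-%s", i, j, r[i], r[j]), call. = FALSE)
    }
    if (j - i - 1L < params$min_hairpin) {
      stop(sprintf("pair (%d,%d) encloses fewer than %d nucleotides", i, j, params$min_hairpin),
           call. = FALSE)
    }
  }
  v <- partner_vector(st)
  aup <- function(i, j) au_penalty(r[i], r[j], params)
  # children and unpaired count of the region strictly between a and b
  scan_region <- function(a, b) {
    children <- matrix(integer(0), ncol = 2L)
    unpaired <- 0L
    k <- a
    while (k <= b) {
      if (v[k] == 0L) {
        unpaired <- unpaired + 1L
        k <- k + 1L
      } else {
        children <- rbind(children, c(k, v[k]))
        k <- v[k] + 1L
      }
    }
    list(children = children, unpaired = unpaired)
  }
  mb <- params$multibranch
  total <- 0
  # loop closed by each pair
  for (row in seq_len(nrow(p))) {
    i <- p[row, 1L]; j <- p[row, 2L]
    reg <- scan_region(i + 1L, j - 1L)
    ch <- reg$children
    nb <- nrow(ch)
    if (nb == 0L) {
      total <- total + hairpin_energy(j - i - 1L, params) + aup(i, j)
    } else if (nb == 1L) {
      k <- ch[1L, 1L]; l <- ch[1L, 2L]
      n1 <- k - i - 1L; n2 <- j - l - 1L
      if (n1 == 0L && n2 == 0L) {
        total <- total + params$stack[pair_type(r[i], r[j]), pair_type(r[k], r[l])]
      } else if (n1 == 0L || n2 == 0L) {
        total <- total + bulge_energy(n1 + n2, params) + aup(i, j) + aup(k, l)
      } else {
        total <- total + internal_energy(n1 + n2, params) + aup(i, j) + aup(k, l)
      }
    } else {
      total <- total + mb$offset + mb$per_branch * (nb + 1L) +
        mb$per_unpaired * reg$unpaired + aup(i, j)
      for (cc in seq_len(nb)) total <- total + aup(ch[cc, 1L], ch[cc, 2L])
    }
  }
  # exterior loop: per-branch terminal penalties only
  ext <- scan_region(1L, st$length)
  if (nrow(ext$children) > 0L) {
    for (cc in seq_len(nrow(ext$children))) {
      total <- total + aup(ext$children[cc, 1L], ext$children[cc, 2L])
    }
  }
  total
}
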