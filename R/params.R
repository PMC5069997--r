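#' Load nearest-neighbour energy parameters
#'
#' Reads one or more plain-text parameter files in the package's table
#' grammar and returns a fully populated parameter set for the Turner
#' nearest-neighbour loop model.  All energies are free energies in
#' kcal/mol at the table temperature.
#'
#' @details
#' The file format is line based.  A line starting with `#` is a comment.
#' A line consisting of a single upper-case word opens a named block; all
#' whitespace-separated tokens up to the next block header belong to that
#' block.  The token `INF` denotes an infinite (forbidden) energy.
#' Pair-indexed tables always use the pair order AU, CG, GC, UA, GU, UG and
#' the nucleotide order A, C, G, U.  Recognised blocks:
#'
#' \describe{
#'   \item{MISC}{`key value` lines: `au_penalty`, `asym`, `max_asym`,
#'     `temperature` (Kelvin), `gas_constant` (kcal/(mol K)).}
#'   \item{ML_PARAMS}{`a`, `b`, `c`: multiloop closure, per-branch and
#'     per-unpaired-nucleotide penalties.}
#'   \item{STACK}{6x6 values, row = outer pair, column = inner pair.}
#'   \item{HAIRPIN, BULGE, INTERNAL}{30 loop initiation values for sizes
#'     1..30.}
#'   \item{MISMATCH_HAIRPIN, MISMATCH_INTERNAL}{6 blocks of 4x4 values:
#'     closing pair, then nucleotide at the 5' interior flank (rows) and at
#'     the 3' interior flank (columns).}
#'   \item{DANGLE5, DANGLE3}{6x4 values: pair, dangling nucleotide.}
#'   \item{TRILOOPS, TETRALOOPS, HEXALOOPS}{`sequence value` lines; the
#'     sequence includes the closing nucleotides; the value is the bonus
#'     added on top of the generic hairpin term of that size.}
#'   \item{INT11}{36 blocks of 4x4: outer pair, reversed inner pair, then
#'     5' and 3' loop nucleotides; 1x1 interior-loop lookup.}
#'   \item{INT21}{outer pair, reversed inner pair, 5' loop nucleotide, then
#'     4x4 over the two 3' loop nucleotides; 1x2 lookup.}
#'   \item{INT22}{outer pair, reversed inner pair, then the four loop
#'     nucleotides; 2x2 lookup.}
#' }
#'
#' The `INT*` and special hairpin blocks are optional; the remaining blocks
#' are mandatory.
#'
#' @param paths character vector of file paths, read in order; later files
#'   may add or override blocks.
#' @param temperature formal temperature in Kelvin used to form `RT`.
#'   Defaults to the `temperature` entry of the MISC block (the table
#'   temperature).
#' @return an object of class `dual_energy_params`.
#' @seealso [turner_params()], [zero_params()], [hairpin_energy()]
#' @export
load_parameters <- function(paths, temperature = NULL) {
  blocks <- list()
  for (path in paths) {
    if (!file.exists(path)) stop("parameter file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    cur <- NULL
    for (ln in lines) {
      ln <- trimws(ln)
      if (!nzchar(ln)) next
      if (grepl("^[A-Z][A-Z0-9_]*$", ln)) {
        cur <- ln
        blocks[[cur]] <- character(0)
      } else {
        if (is.null(cur)) stop("parameter file ", path,
                               ": values before any block header")
        blocks[[cur]] <- c(blocks[[cur]], strsplit(ln, "[[:space:]]+")[[1L]])
      }
    }
  }

  num <- function(tok, block) {
    v <- suppressWarnings(ifelse(toupper(tok) == "INF", Inf, as.numeric(tok)))
    if (anyNA(v)) stop("malformed value in block ", block, ": ",
                       paste(tok[is.na(v)], collapse = " "))
    v
  }
  need <- function(name, n = NULL) {
    tok <- blocks[[name]]
    if (is.null(tok)) stop("missing mandatory table: ", name)
    v <- num(tok, name)
    if (!is.null(n) && length(v) != n)
      stop("block ", name, ": expected ", n, " values, found ", length(v))
    v
  }
  kv <- function(name) {
    tok <- blocks[[name]]
    if (is.null(tok)) stop("missing mandatory table: ", name)
    if (length(tok) %% 2L != 0L) stop("block ", name, ": odd token count")
    keys <- tok[seq(1L, length(tok), 2L)]
    vals <- num(tok[seq(2L, length(tok), 2L)], name)
    stats::setNames(vals, keys)
  }
  loop_table <- function(name) {
    tok <- blocks[[name]]
    if (is.null(tok)) return(stats::setNames(numeric(0), character(0)))
    if (length(tok) %% 2L != 0L) stop("block ", name, ": odd token count")
    seqs <- toupper(tok[seq(1L, length(tok), 2L)])
    stats::setNames(num(tok[seq(2L, length(tok), 2L)], name), seqs)
  }
  int_table <- function(name, extra_dims) {
    tok <- blocks[[name]]
    if (is.null(tok)) return(NULL)
    dims <- c(rev(extra_dims), 6L, 6L)     # fill fastest index first
    v <- num(tok, name)
    if (length(v) != prod(dims))
      stop("block ", name, ": expected ", prod(dims), " values")
    aperm(array(v, dims), rev(seq_along(dims)))
  }

  misc <- kv("MISC")
  ml <- kv("ML_PARAMS")
  for (k in c("au_penalty", "asym", "max_asym", "temperature"))
    if (is.na(misc[k])) stop("MISC block lacks entry: ", k)
  gas_constant <- if (!is.na(misc["gas_constant"])) unname(misc["gas_constant"])
                  else 1.98717e-3
  t0 <- unname(misc["temperature"])
  temperature <- if (is.null(temperature)) t0 else temperature
  if (temperature <= 0) stop("temperature must be positive (Kelvin)")

  p <- list(
    stack = matrix(need("STACK", 36L), 6L, 6L, byrow = TRUE,
                   dimnames = list(PAIR_NAMES, PAIR_NAMES)),
    hairpin_init = need("HAIRPIN", 30L),
    bulge_init = need("BULGE", 30L),
    internal_init = need("INTERNAL", 30L),
    mm_hairpin = aperm(array(need("MISMATCH_HAIRPIN", 96L), c(4L, 4L, 6L)),
                       c(3L, 2L, 1L)),
    mm_internal = aperm(array(need("MISMATCH_INTERNAL", 96L), c(4L, 4L, 6L)),
                        c(3L, 2L, 1L)),
    dangle5 = matrix(need("DANGLE5", 24L), 6L, 4L, byrow = TRUE,
                     dimnames = list(PAIR_NAMES, NT_LETTERS)),
    dangle3 = matrix(need("DANGLE3", 24L), 6L, 4L, byrow = TRUE,
                     dimnames = list(PAIR_NAMES, NT_LETTERS)),
    triloop = loop_table("TRILOOPS"),
    tetraloop = loop_table("TETRALOOPS"),
    hexaloop = loop_table("HEXALOOPS"),
    int11 = int_table("INT11", c(4L, 4L)),
    int21 = int_table("INT21", c(4L, 4L, 4L)),
    int22 = int_table("INT22", c(4L, 4L, 4L, 4L)),
    ml_a = unname(ml["a"]), ml_b = unname(ml["b"]), ml_c = unname(ml["c"]),
    au_penalty = unname(misc["au_penalty"]),
    asym = unname(misc["asym"]),
    max_asym = unname(misc["max_asym"]),
    table_temperature = t0,
    temperature = temperature,
    gas_constant = gas_constant,
    RT = gas_constant * temperature
  )
  if (anyNA(c(p$ml_a, p$ml_b, p$ml_c)))
    stop("ML_PARAMS block must define a, b and c")
  if (p$au_penalty < 0) stop("au_penalty must be non-negative")
  class(p) <- "dual_energy_params"
  p
}

#' Packaged Turner 2004 parameter tables
#'
#' Loads the Turner 2004 free-energy tables shipped with the package
#' (37 degrees C, i.e. 310.15 K), including the 1x1, 1x2 and 2x2
#' interior-loop lookup tables.
#'
#' @param temperature formal temperature in Kelvin (default: the table
#'   temperature, 310.15 K).  Energies are always the 310.15 K table
#'   values; the formal temperature only changes `RT` in the Boltzmann
#'   exponent (see [dual_expected_energy()]).
#' @return a `dual_energy_params` object.
#' @export
turner_params <- function(temperature = NULL) {
  key <- if (is.null(temperature)) "default" else format(temperature, digits = 12)
  cached <- .param_cache[[key]]
  if (!is.null(cached)) return(cached)
  files <- c(system.file("extdata", "turner2004.txt", package = "dualpf"),
             system.file("extdata", "turner2004_int22.txt", package = "dualpf"))
  p <- load_parameters(files, temperature = temperature)
  .param_cache[[key]] <- p
  p
}

.param_cache <- new.env(parent = emptyenv())

#' All-zero energy model
#'
#' A parameter set in which every energy term is exactly zero, so that every
#' Boltzmann factor is 1 and partition functions reduce to compatible
#' sequence counts.  Useful for counting identities and tests.
#'
#' @param temperature Kelvin.
#' @return a `dual_energy_params` object.
#' @export
zero_params <- function(temperature = 310.15) {
  p <- list(
    stack = matrix(0, 6L, 6L, dimnames = list(PAIR_NAMES, PAIR_NAMES)),
    hairpin_init = numeric(30L),
    bulge_init = numeric(30L),
    internal_init = numeric(30L),
    mm_hairpin = array(0, c(6L, 4L, 4L)),
    mm_internal = array(0, c(6L, 4L, 4L)),
    dangle5 = matrix(0, 6L, 4L, dimnames = list(PAIR_NAMES, NT_LETTERS)),
    dangle3 = matrix(0, 6L, 4L, dimnames = list(PAIR_NAMES, NT_LETTERS)),
    triloop = stats::setNames(numeric(0), character(0)),
    tetraloop = stats::setNames(numeric(0), character(0)),
    hexaloop = stats::setNames(numeric(0), character(0)),
    int11 = NULL, int21 = NULL, int22 = NULL,
    ml_a = 0, ml_b = 0, ml_c = 0,
    au_penalty = 0, asym = 0, max_asym = 0,
    table_temperature = temperature,
    temperature = temperature,
    gas_constant = 1.98717e-3,
    RT = 1.98717e-3 * temperature
  )
  class(p) <- "dual_energy_params"
  p
}

#' @export
print.dual_energy_params <- function(x, ...) {
  cat("Nearest-neighbour energy parameters (kcal/mol)\n")
  cat(sprintf("  table temperature: %.2f K, RT = %.5f kcal/mol\n",
              x$table_temperature, x$RT))
  cat(sprintf("  multiloop a = %.2f, b = %.2f, c = %.2f; AU penalty = %.2f\n",
              x$ml_a, x$ml_b, x$ml_c, x$au_penalty))
  cat(sprintf("  special loops: %d tri, %d tetra, %d hexa; int11/int21/int22: %s/%s/%s\n",
              length(x$triloop), length(x$tetraloop), length(x$hexaloop),
              !is.null(x$int11), !is.null(x$int21), !is.null(x$int22)))
  invisible(x)
}

# Jacobson-Stockmayer length extrapolation shared by the loop accessors
.loop_extrapolate <- function(table, size, params) {
  ifelse(size <= 30L, table[pmax(size, 1L)],
         table[30L] + 1.75 * params$RT * log(size / 30))
}

#' Loop initiation energies
#'
#' Table lookup for loop sizes up to 30, with the logarithmic
#' Jacobson-Stockmayer extrapolation `E(30) + 1.75 RT ln(size/30)` beyond.
#'
#' @param params a `dual_energy_params` object.
#' @param size loop size in unpaired nucleotides (hairpin: at least 3;
#'   bulge: at least 1; internal: at least 2).  Vectorised.
#' @return energy in kcal/mol.
#' @export
hairpin_energy <- function(params, size) {
  if (any(size < 3L)) stop("hairpin size below the steric floor of 3")
  .loop_extrapolate(params$hairpin_init, size, params)
}

#' @rdname hairpin_energy
#' @export
bulge_energy <- function(params, size) {
  if (any(size < 1L)) stop("bulge size must be at least 1")
  .loop_extrapolate(params$bulge_init, size, params)
}

#' @rdname hairpin_energy
#' @export
internal_energy <- function(params, size) {
  if (any(size < 2L)) stop("internal loop size must be at least 2")
  .loop_extrapolate(params$internal_init, size, params)
}

#' Terminal AU/GU penalty of a pair
#'
#' @param params a `dual_energy_params` object.
#' @param pair pair name ("AU", "UA", "GC", "CG", "GU", "UG") or pair index
#'   1..6 in that order.  Vectorised.
#' @return the penalty in kcal/mol: `au_penalty` for AU, UA, GU and UG,
#'   0 for GC and CG.
#' @export
au_penalty_of <- function(params, pair) {
  idx <- if (is.character(pair)) match(toupper(pair), PAIR_NAMES) else as.integer(pair)
  if (anyNA(idx) || any(idx < 1L) || any(idx > 6L))
    stop("not a canonical base pair: ", paste(pair, collapse = ", "))
  ifelse(idx %in% c(2L, 3L), 0, params$au_penalty)
}

# vectorised helper used by the recursions: penalty by pair index
.au_vec <- function(params) c(params$au_penalty, 0, 0, params$au_penalty,
                              params$au_penalty, params$au_penalty)
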