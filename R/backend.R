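# Pluggable folding backends supplying MFE structures and base-pair
# probability matrices for the ensemble metrics.
#
# The reference backend enumerates the complete secondary structure space
# of a sequence (theta = 3) and scores it with this package's own loop
# model, so MFE structures and pairing probabilities are exact; it is
# restricted to short sequences.  An adapter to the ViennaRNA command-line
# tools is provided for realistic lengths, and a stub backend wraps
# user-supplied functions (useful for testing the metric formulas with
# hand-built matrices).

#' Fold a sequence with a backend
#'
#' @param backend a folding backend object.
#' @param sequence RNA sequence string.
#' @return `mfe_fold`: a list with `structure` (dot-bracket) and `energy`
#'   (kcal/mol).  `basepair_probs`: a [bpp_matrix()].
#' @export
mfe_fold <- function(backend, sequence) UseMethod("mfe_fold")

#' @rdname mfe_fold
#' @export
basepair_probs <- function(backend, sequence) UseMethod("basepair_probs")

#' Exact enumeration folding backend
#'
#' Enumerates every secondary structure of a sequence (canonical pairs,
#' hairpins of at least 3 unpaired nucleotides), evaluates each with
#' [energy_of_structure()], and derives the MFE structure (ties broken
#' deterministically by enumeration order) and the exact Boltzmann
#' base-pair probabilities.  Exponential in the sequence length; intended
#' for short sequences and as the reference implementation the metric
#' pipeline is validated against.
#'
#' @inheritParams dual_pf
#' @param max_structures refuse sequences whose structure count exceeds
#'   this guard.
#' @return a folding backend object.
#' @export
fold_backend_exhaustive <- function(params = turner_params(),
                                    mode = c("d2", "d0"),
                                    bulge_convention = c("stack", "literal"),
                                    small_internal = c("tables", "generic"),
                                    max_structures = 2e5) {
  structure(list(params = params, mode = match.arg(mode),
                 bulge = match.arg(bulge_convention),
                 small_internal = match.arg(small_internal),
                 max_structures = max_structures),
            class = c("fold_backend_exhaustive", "fold_backend"))
}

# all well-nested structures over positions i..j as lists of pair rows
.enum_structures <- function(v, guard = 2e5) {
  n <- length(v)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j) return(list(list()))
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- rec(i + 1L, j)                            # i unpaired
    if (j >= i + THETA + 1L) for (k in (i + THETA + 1L):j) {
      if (PAIR_CODE[v[i], v[k]] == 0L) next
      left <- rec(i + 1L, k - 1L)
      right <- rec(k + 1L, j)
      for (ls in left) for (rs in right)
        out[[length(out) + 1L]] <- c(list(c(i, k)), ls, rs)
    }
    if (length(out) > guard)
      stop("structure enumeration exceeds the guard of ", guard)
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

.structs_energies <- function(backend, sequence) {
  v <- nt_to_int(sequence)
  n <- length(v)
  structs <- .enum_structures(v, backend$max_structures)
  dbs <- vapply(structs, function(ps) {
    ch <- rep(".", n)
    for (pr in ps) { ch[pr[1L]] <- "("; ch[pr[2L]] <- ")" }
    paste(ch, collapse = "")
  }, "")
  E <- vapply(dbs, function(db)
    energy_of_structure(sequence, db, backend$params, backend$mode,
                        backend$bulge, backend$small_internal), 0,
    USE.NAMES = FALSE)
  list(structs = structs, dbs = dbs, E = E, n = n)
}

#' @export
mfe_fold.fold_backend_exhaustive <- function(backend, sequence) {
  se <- .structs_energies(backend, sequence)
  best <- which.min(se$E)
  list(structure = se$dbs[best], energy = se$E[best])
}

#' @export
basepair_probs.fold_backend_exhaustive <- function(backend, sequence) {
  se <- .structs_energies(backend, sequence)
  w <- exp(-(se$E - min(se$E)) / backend$params$RT)
  w <- w / sum(w)
  p <- matrix(0, se$n, se$n)
  for (q in seq_along(se$structs))
    for (pr in se$structs[[q]])
      p[pr[1L], pr[2L]] <- p[pr[1L], pr[2L]] + w[q]
  bpp_matrix(p)
}

#' ViennaRNA command-line folding backend
#'
#' Adapter to the `RNAfold` executable (if installed and on the PATH) for
#' MFE structures and base-pair probabilities at realistic sequence
#' lengths.  Pairing probabilities are read from the postscript dot plot
#' emitted by `RNAfold -p`.
#'
#' @param dangles dangle option passed to RNAfold (`"2"` or `"0"`).
#' @param rnafold path to the RNAfold executable.
#' @return a folding backend object.
#' @export
fold_backend_vienna <- function(dangles = c("2", "0"),
                                rnafold = Sys.which("RNAfold")) {
  if (!nzchar(rnafold))
    stop("RNAfold executable not found on PATH")
  structure(list(rnafold = rnafold, dangles = match.arg(dangles)),
            class = c("fold_backend_vienna", "fold_backend"))
}

#' @export
mfe_fold.fold_backend_vienna <- function(backend, sequence) {
  out <- system2(backend$rnafold,
                 c("--noPS", paste0("-d", backend$dangles)),
                 input = sequence, stdout = TRUE)
  line <- out[2L]
  db <- sub("^([().]+).*$", "\\1", line)
  en <- as.numeric(sub("^.*\\((\\s*-?[0-9.]+)\\)\\s*$", "\\1", line))
  list(structure = db, energy = en)
}

#' @export
basepair_probs.fold_backend_vienna <- function(backend, sequence) {
  wd <- tempfile("vrna")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE))
  owd <- setwd(wd)
  on.exit(setwd(owd), add = TRUE, after = FALSE)
  system2(backend$rnafold, c("-p", "--noPS", paste0("-d", backend$dangles)),
          input = c(">q", sequence), stdout = NULL)
  ps <- readLines(file.path(wd, "q_dp.ps"), warn = FALSE)
  ub <- grep("ubox$", ps, value = TRUE)
  ub <- ub[grepl("^[0-9]", ub)]
  n <- nchar(sequence)
  p <- matrix(0, n, n)
  for (ln in ub) {
    f <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    i <- as.integer(f[1L]); j <- as.integer(f[2L])
    p[i, j] <- as.numeric(f[3L])^2
  }
  bpp_matrix(p)
}

#' Stub folding backend from user functions
#'
#' Wraps arbitrary `mfe` and `bpp` functions of a sequence; used to test
#' the metric layer with prescribed structures/matrices.
#'
#' @param mfe function(sequence) returning `list(structure=, energy=)`.
#' @param bpp function(sequence) returning a [bpp_matrix()] (or a plain
#'   matrix, which is wrapped).
#' @return a folding backend object.
#' @export
fold_backend_stub <- function(mfe, bpp) {
  structure(list(mfe = mfe, bpp = bpp),
            class = c("fold_backend_stub", "fold_backend"))
}

#' @export
mfe_fold.fold_backend_stub <- function(backend, sequence)
  backend$mfe(sequence)

#' @export
basepair_probs.fold_backend_stub <- function(backend, sequence) {
  out <- backend$bpp(sequence)
  if (!inherits(out, "bpp_matrix")) out <- bpp_matrix(out)
  out
}
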