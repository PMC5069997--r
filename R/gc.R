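#' GC count of a sequence fragment
#'
#' @param x character string over the RNA alphabet (IUPAC letters other
#'   than A/C/G/U are rejected).
#' @return the number of G and C symbols.
#' @export
gc_count <- function(x) {
  sum(NT_GC[nt_to_int(x)])
}

#' Count constrained assignments with exact GC content
#'
#' Number of joint nucleotide assignments of a set of positions, each with
#' its own allowed subset of \{A,C,G,U\}, such that exactly `k` positions
#' carry G or C.  Computed by a position-by-position convolution; with all
#' positions unconstrained this collapses to `choose(m, k) * 2^m`.
#'
#' @param positions list of allowed nucleotide sets: integer codes 1..4
#'   (A, C, G, U) or IUPAC letters.
#' @param k required number of G/C positions.
#' @return a count (0 when infeasible, e.g. `k` larger than the number of
#'   positions that can carry G or C).
#' @export
count_constrained_assignments <- function(positions, k) {
  if (k < 0) return(0)
  v <- .gc_count_vector(positions)
  if (k + 1L > length(v)) return(0)
  v[k + 1L]
}

# full distribution: element k+1 = number of assignments with GC-count k
.gc_count_vector <- function(positions) {
  positions <- lapply(positions, function(s) {
    if (is.character(s)) s <- IUPAC_SETS[[toupper(s)]]
    as.integer(s)
  })
  f <- 1
  for (s in positions) {
    gc <- sum(NT_GC[s] == 1L)
    at <- length(s) - gc
    f <- .gc_shift_mix(f, at, gc)
  }
  f
}

# multiply a GC-count polynomial by (at + gc * z)
.gc_shift_mix <- function(f, at, gc) {
  out <- numeric(length(f) + 1L)
  out[seq_along(f)] <- at * f
  out[seq_along(f) + 1L] <- out[seq_along(f) + 1L] + gc * f
  out
}

# convolution of two GC-count polynomials (index = GC count + 1)
.gc_conv <- function(a, b) {
  if (length(a) == 1L) return(a * b)
  if (length(b) == 1L) return(b * a)
  out <- numeric(length(a) + length(b) - 1L)
  for (k in seq_along(a)) {
    if (a[k] != 0) {
      idx <- k + seq_along(b) - 1L
      out[idx] <- out[idx] + a[k] * b
    }
  }
  out
}

# shift a polynomial by g GC units (multiply by z^g)
.gc_shiftpoly <- function(f, g) {
  if (g == 0L) return(f)
  c(numeric(g), f)
}
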