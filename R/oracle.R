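#' Brute-force dual partition function (enumeration oracle)
#'
#' Enumerates every sequence compatible with the target (respecting its
#' IUPAC constraints), evaluates each energy with
#' [energy_of_structure()]'s loop model, and sums the Boltzmann factors
#' directly.  Exact but exponential; intended as the independent oracle
#' the dynamic programming is tested against.
#'
#' @inheritParams dual_pf
#' @param max_sequences refuse enumeration beyond this many compatible
#'   sequences.
#' @return the dual partition function `Z*(s0)` (unscaled).
#' @export
brute_force_dual_pf <- function(target, params = turner_params(),
                                mode = c("d2", "d0"),
                                bulge_convention = c("stack", "literal"),
                                small_internal = c("tables", "generic"),
                                max_sequences = 2e6) {
  if (is.character(target)) target <- parse_target(target)
  mode <- match.arg(mode)
  opts <- .resolve_opts(bulge_convention, small_internal)
  M <- .enumerate_compatible(target, max_sequences)
  E <- .seq_energies(M, target, params, mode, opts)
  sum(exp(-E / params$RT))
}

# matrix of all compatible sequences (rows) under the target's constraints
.enumerate_compatible <- function(target, max_sequences = 2e6) {
  npairs <- nrow(target$pairs)
  unpaired <- which(target$pair_table == 0L)
  counts <- c(vapply(target$allowed_pairs, length, 0L),
              lengths(target$allowed[unpaired]))
  total <- prod(counts)
  if (total > max_sequences)
    stop("enumeration too large: ", format(total, big.mark = ","),
         " compatible sequences exceed the guard of ",
         format(max_sequences, big.mark = ","))
  if (total == 0)
    return(matrix(integer(0), 0L, target$n))
  cols <- c(target$allowed_pairs, target$allowed[unpaired])
  grid <- as.matrix(do.call(expand.grid, c(cols, KEEP.OUT.ATTRS = FALSE)))
  storage.mode(grid) <- "integer"
  M <- matrix(0L, nrow(grid), target$n)
  for (r in seq_len(npairs)) {
    M[, target$pairs[r, 1L]] <- PAIR_NT[grid[, r], 1L]
    M[, target$pairs[r, 2L]] <- PAIR_NT[grid[, r], 2L]
  }
  for (q in seq_along(unpaired))
    M[, unpaired[q]] <- grid[, npairs + q]
  M
}
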