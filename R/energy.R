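#' Free energy of a sequence on a fixed secondary structure
#'
#' Evaluates the additive Turner loop-model energy `E(a, s)` of a sequence
#' threaded onto a structure, using exactly the loop conventions of the
#' dual partition function recursions (same AU-penalty placement, mismatch,
#' dangle, multiloop and bulge/interior-loop switches), so that
#' `sum(exp(-E/RT))` over all compatible sequences equals [dual_pf()].
#'
#' @param sequence RNA sequence (string over A/C/G/U).
#' @param structure dot-bracket string or [rna_target][parse_target];
#'   constraints attached to a target are ignored here, compatibility means
#'   canonical (Watson-Crick or GU) pairing at every base pair.
#' @param params,mode,bulge_convention,small_internal as in [dual_pf()].
#' @return energy in kcal/mol; `+Inf` if the sequence is incompatible with
#'   the structure (with the first offending pair as attribute `where`).
#' @examples
#' energy_of_structure("GGGGAAACCCC", "((((...))))", mode = "d0")
#' @export
energy_of_structure <- function(sequence, structure,
                                params = turner_params(),
                                mode = c("d2", "d0"),
                                bulge_convention = c("stack", "literal"),
                                small_internal = c("tables", "generic")) {
  mode <- match.arg(mode)
  opts <- .resolve_opts(bulge_convention, small_internal)
  if (is.character(structure)) structure <- parse_target(structure)
  M <- matrix(nt_to_int(sequence), nrow = 1L)
  if (ncol(M) != structure$n)
    stop("sequence length ", ncol(M), " does not match structure length ",
         structure$n)
  E <- .seq_energies(M, structure, params, mode, opts)
  if (is.infinite(E)) {
    bad <- which(PAIR_CODE[cbind(M[1L, structure$pairs[, 1L]],
                                 M[1L, structure$pairs[, 2L]])] == 0L)[1L]
    attr(E, "where") <- structure$pairs[bad, ]
  }
  E
}

# vectorised evaluator: M is an N x n integer matrix of nucleotide codes
.seq_energies <- function(M, target, params, mode, opts) {
  N <- nrow(M)
  npairs <- nrow(target$pairs)
  auv <- .au_vec(params)
  E <- numeric(N)

  P <- matrix(0L, N, max(npairs, 1L))
  incomp <- logical(N)
  for (r in seq_len(npairs)) {
    pi <- PAIR_CODE[cbind(M[, target$pairs[r, 1L]], M[, target$pairs[r, 2L]])]
    incomp <- incomp | pi == 0L
    P[, r] <- pmax(pi, 1L)      # placeholder index for incompatible rows
  }

  for (r in which(target$bp_close_el_ml)) E <- E + auv[P[, r]]

  special_lookup <- function(xy, interior_cols, size, table) {
    if (!length(table)) return(numeric(N))
    keys <- (xy - 1)
    for (q in seq_len(size)) keys <- keys * 4 + (M[, interior_cols[q]] - 1)
    tk <- vapply(names(table), function(s) {
      v <- nt_to_int(s)
      k <- match(paste0(NT_LETTERS[v[1L]], NT_LETTERS[v[length(v)]]),
                 PAIR_NAMES) - 1
      for (q in 2:(length(v) - 1L)) k <- k * 4 + (v[q] - 1)
      k
    }, 0)
    hit <- match(keys, tk)
    ifelse(is.na(hit), 0, table[ifelse(is.na(hit), 1L, hit)])
  }

  for (lp in target$loops) {
    if (lp$kind == "external") {
      if (mode == "d2") E <- E + .dangle_energies(M, target, lp, P, params, mode)
      next
    }
    r <- lp$closing
    i <- target$pairs[r, 1L]; j <- target$pairs[r, 2L]
    xy <- P[, r]
    if (lp$kind == "hairpin") {
      s <- lp$size
      E <- E + hairpin_energy(params, s)
      if (s == 3L) E <- E + auv[xy]
      else E <- E + params$mm_hairpin[cbind(xy, M[, i + 1L], M[, j - 1L])]
      if (s %in% c(3L, 4L, 6L)) {
        tab <- switch(as.character(s), "3" = params$triloop,
                      "4" = params$tetraloop, "6" = params$hexaloop)
        E <- E + special_lookup(xy, (i + 1L):(j - 1L), s, tab)
      }
    } else if (lp$kind == "stack") {
      E <- E + params$stack[cbind(xy, P[, lp$inner])]
    } else if (lp$kind %in% c("bulge_left", "bulge_right")) {
      rs <- max(lp$r1, lp$r2)
      uv <- P[, lp$inner]
      if (opts$bulge == "stack" && rs == 1L)
        E <- E + bulge_energy(params, 1L) + params$stack[cbind(xy, uv)]
      else if (opts$bulge == "stack")
        E <- E + bulge_energy(params, rs) + auv[xy] + auv[uv]
      else
        E <- E + bulge_energy(params, rs) + auv[xy]
    } else if (lp$kind == "internal") {
      k <- target$pairs[lp$inner, 1L]; l <- target$pairs[lp$inner, 2L]
      uv <- P[, lp$inner]
      r1 <- lp$r1; r2 <- lp$r2
      if (.internal_uses_tables(lp, params, opts)) {
        E <- E + if (r1 == 1L && r2 == 1L)
          params$int11[cbind(xy, PAIR_REV[uv], M[, i + 1L], M[, j - 1L])]
        else if (r1 == 1L && r2 == 2L)
          params$int21[cbind(xy, PAIR_REV[uv], M[, i + 1L], M[, l + 1L],
                             M[, j - 1L])]
        else if (r1 == 2L && r2 == 1L)
          params$int21[cbind(PAIR_REV[uv], xy, M[, l + 1L], M[, i + 1L],
                             M[, k - 1L])]
        else
          params$int22[cbind(xy, PAIR_REV[uv], M[, i + 1L], M[, k - 1L],
                             M[, l + 1L], M[, j - 1L])]
      } else {
        E <- E + internal_energy(params, r1 + r2) +
          min(params$asym * abs(r1 - r2), params$max_asym) + auv[xy] +
          params$mm_internal[cbind(xy, M[, i + 1L], M[, j - 1L])] +
          params$mm_internal[cbind(PAIR_REV[uv], M[, l + 1L], M[, k - 1L])]
      }
    } else {                      # multiloop
      E <- E + params$ml_a + params$ml_b * (lp$k + 1L) +
        params$ml_c * lp$ell + auv[xy]
      if (mode == "d2") E <- E + .dangle_energies(M, target, lp, P, params, mode)
    }
  }
  E[incomp] <- Inf
  E
}

# d2 dangle terms of one multiloop/external loop, per sequence row
.dangle_energies <- function(M, target, lp, P, params, mode) {
  E <- numeric(nrow(M))
  groups <- build_groups(target, lp, "d2")
  for (g in groups) {
    dg <- g$dangles
    if (is.null(dg)) next
    for (q in seq_len(nrow(dg))) {
      role <- dg[q, ]
      nt <- M[, role$pos]
      pr <- P[, role$pair]
      E <- E + switch(role$side,
        d5 = params$dangle5[cbind(pr, nt)],
        d3 = params$dangle3[cbind(pr, nt)],
        in3 = params$dangle3[cbind(PAIR_REV[pr], nt)],
        in5 = params$dangle5[cbind(PAIR_REV[pr], nt)])
    }
  }
  E
}
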