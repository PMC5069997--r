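# Dual partition function engine.
#
# Every loop of the target is compiled into a "loop model": a per-pair
# prefactor, a list of group tables, and a set of energy-free positions.
# A group table enumerates the joint instantiations of the positions whose
# energy contributions are interdependent (inner base pairs, terminal
# mismatch positions, dangle positions), with one Boltzmann weight per
# instantiation, conditioned on the closing pair where required.  The same
# tables drive the forward computation of Z*(i,j;X,Y), its GC-resolved
# variant, and the stochastic backtracking sampler, which guarantees that
# sampling probabilities are exactly the conditional partition function
# ratios.

.resolve_opts <- function(bulge_convention = c("stack", "literal"),
                          small_internal = c("tables", "generic")) {
  list(bulge = match.arg(bulge_convention),
       small_internal = match.arg(small_internal))
}

# weight table of one adjacency group of a multiloop/external loop (d2),
# or a degenerate one-helix group (d0)
.group_table <- function(target, params, RT, C, loop, group) {
  pairs <- target$pairs
  closing <- loop$closing
  gp <- setdiff(group$pairs, closing)      # pairs summed inside the group
  vars <- group$vars
  cols <- c(lapply(gp, function(r) target$allowed_pairs[[r]]),
            target$allowed[vars])
  nrows <- prod(vapply(cols, length, 0L))
  if (nrows == 0L)
    return(list(pairs = gp, vars = vars,
                choice = matrix(0L, 0L, length(gp)),
                varnt = matrix(0L, 0L, length(vars)),
                W = matrix(0, 0L, 6L), gamma = integer(0)))
  if (nrows > 1e7)
    stop("group table too large (", nrows, " instantiations); ",
         "a multiloop/external-loop group exceeds the memory guard")
  grid <- as.matrix(do.call(expand.grid, c(cols, KEEP.OUT.ATTRS = FALSE)))
  storage.mode(grid) <- "integer"
  choice <- grid[, seq_along(gp), drop = FALSE]
  varnt <- grid[, length(gp) + seq_along(vars), drop = FALSE]

  # nucleotide at a position, per row; xy-dependent slots return a 6-list
  resolve_nt <- function(pos) {
    if (target$pair_table[pos] == 0L)
      return(list(dep = FALSE, nt = varnt[, match(pos, vars)]))
    prow <- target$bp_at[if (target$pair_table[pos] > pos) pos
                         else target$pair_table[pos]]
    side <- if (pairs[prow, 1L] == pos) 1L else 2L
    if (!is.na(closing) && prow == closing)
      return(list(dep = TRUE, side = side))
    k <- match(prow, gp)
    list(dep = FALSE, nt = PAIR_NT[cbind(choice[, k], side)])
  }

  W <- matrix(rep(C^(-length(vars)), nrows), nrows, 6L)
  dg <- group$dangles
  if (!is.null(dg)) {
    for (q in seq_len(nrow(dg))) {
      role <- dg[q, ]
      ntinfo <- resolve_nt(role$pos)
      if (role$side %in% c("d5", "d3")) {
        k <- match(role$pair, gp)
        tab <- if (role$side == "d5") params$dangle5 else params$dangle3
        if (!ntinfo$dep) {
          W <- W * exp(-tab[cbind(choice[, k], ntinfo$nt)] / RT)
        } else {
          for (xy in 1:6) {
            nt <- PAIR_NT[xy, ntinfo$side]
            W[, xy] <- W[, xy] * exp(-tab[cbind(choice[, k], nt)] / RT)
          }
        }
      } else {
        # closing pair viewed from inside: reversed pair indexes the tables
        tab <- if (role$side == "in3") params$dangle3 else params$dangle5
        if (!ntinfo$dep) {
          for (xy in 1:6)
            W[, xy] <- W[, xy] * exp(-tab[cbind(PAIR_REV[xy], ntinfo$nt)] / RT)
        } else {
          for (xy in 1:6) {
            nt <- PAIR_NT[xy, ntinfo$side]
            W[, xy] <- W[, xy] * exp(-tab[PAIR_REV[xy], nt] / RT)
          }
        }
      }
    }
  }
  gamma <- if (length(vars)) as.integer(rowSums(matrix(NT_GC[varnt],
                                                       nrows))) else
           integer(nrows)
  list(pairs = gp, vars = vars, choice = choice, varnt = varnt,
       W = W, gamma = gamma)
}

# single-group table for hairpin / stack / bulge / internal loops
.one_loop_table <- function(target, params, RT, C, loop, opts) {
  pairs <- target$pairs
  r <- loop$closing
  i <- unname(pairs[r, 1L]); j <- unname(pairs[r, 2L])
  mk <- function(gp, vars, wfun) {
    cols <- c(lapply(gp, function(rr) target$allowed_pairs[[rr]]),
              target$allowed[vars])
    nrows <- prod(vapply(cols, length, 0L))
    if (nrows == 0L)
      return(list(pairs = gp, vars = vars,
                  choice = matrix(0L, 0L, length(gp)),
                  varnt = matrix(0L, 0L, length(vars)),
                  W = matrix(0, 0L, 6L), gamma = integer(0)))
    grid <- as.matrix(do.call(expand.grid, c(cols, KEEP.OUT.ATTRS = FALSE)))
    storage.mode(grid) <- "integer"
    choice <- grid[, seq_along(gp), drop = FALSE]
    varnt <- grid[, length(gp) + seq_along(vars), drop = FALSE]
    W <- wfun(choice, varnt) * C^(-length(vars))
    gamma <- if (length(vars))
      as.integer(rowSums(matrix(NT_GC[varnt], nrows))) else
      rep(0L, nrows)
    list(pairs = gp, vars = vars, choice = choice, varnt = varnt,
         W = W, gamma = gamma)
  }

  if (loop$kind == "hairpin") {
    s <- loop$size
    special <- switch(as.character(s), "3" = params$triloop,
                      "4" = params$tetraloop, "6" = params$hexaloop,
                      stats::setNames(numeric(0), character(0)))
    # small loops (and hexaloops with special entries) enumerate the whole
    # interior so that special-loop bonuses condition the sampler exactly
    vars <- if (s <= 4L || (s == 6L && length(special)))
      (i + 1L):(j - 1L) else c(i + 1L, j - 1L)
    wfun <- function(choice, varnt) {
      nr <- nrow(varnt)
      W <- matrix(1, nr, 6L)
      if (s > 3L) {
        n1 <- varnt[, 1L]; n2 <- varnt[, ncol(varnt)]
        for (xy in 1:6)
          W[, xy] <- exp(-params$mm_hairpin[cbind(xy, n1, n2)] / RT)
      }
      if (length(special)) {
        mid <- apply(varnt, 1L, function(v) paste(NT_LETTERS[v], collapse = ""))
        for (xy in 1:6) {
          key <- paste0(NT_LETTERS[PAIR_NT[xy, 1L]], mid,
                        NT_LETTERS[PAIR_NT[xy, 2L]])
          hit <- match(key, names(special))
          bonus <- ifelse(is.na(hit), 0, special[ifelse(is.na(hit), 1L, hit)])
          W[, xy] <- W[, xy] * exp(-bonus / RT)
        }
      }
      W
    }
    return(mk(integer(0), vars, wfun))
  }

  inner <- loop$inner
  if (loop$kind == "stack") {
    wfun <- function(choice, varnt) {
      W <- matrix(0, nrow(choice), 6L)
      for (xy in 1:6) W[, xy] <- exp(-params$stack[xy, choice[, 1L]] / RT)
      W
    }
    return(mk(inner, integer(0), wfun))
  }

  if (loop$kind %in% c("bulge_left", "bulge_right")) {
    rsize <- max(loop$r1, loop$r2)
    binit <- bulge_energy(params, rsize)
    auv <- .au_vec(params)
    wfun <- function(choice, varnt) {
      W <- matrix(0, nrow(choice), 6L)
      if (opts$bulge == "stack" && rsize == 1L) {
        for (xy in 1:6)
          W[, xy] <- exp(-(binit + params$stack[xy, choice[, 1L]]) / RT)
      } else if (opts$bulge == "stack") {
        # both closing pairs pay the terminal penalty; no cross-bulge stack
        inner_au <- auv[choice[, 1L]]
        for (xy in 1:6)
          W[, xy] <- exp(-(binit + auv[xy] + inner_au) / RT)
      } else {
        # literal convention: initiation plus outer terminal penalty only
        for (xy in 1:6) W[, xy] <- exp(-(binit + auv[xy]) / RT)
      }
      W
    }
    return(mk(inner, integer(0), wfun))
  }

  # internal loop
  k <- unname(pairs[inner, 1L]); l <- unname(pairs[inner, 2L])
  r1 <- loop$r1; r2 <- loop$r2
  use_tables <- opts$small_internal == "tables" &&
    ((r1 == 1L && r2 == 1L && !is.null(params$int11)) ||
     (r1 + r2 == 3L && min(r1, r2) == 1L && !is.null(params$int21)) ||
     (r1 == 2L && r2 == 2L && !is.null(params$int22)))
  if (use_tables) {
    vars <- c((i + 1L):(k - 1L), (l + 1L):(j - 1L))
    wfun <- function(choice, varnt) {
      W <- matrix(0, nrow(choice), 6L)
      uv <- PAIR_REV[choice[, 1L]]
      for (xy in 1:6) {
        E <- if (r1 == 1L && r2 == 1L)
          params$int11[cbind(xy, uv, varnt[, 1L], varnt[, 2L])]
        else if (r1 == 1L && r2 == 2L)
          params$int21[cbind(xy, uv, varnt[, 1L], varnt[, 2L], varnt[, 3L])]
        else if (r1 == 2L && r2 == 1L)
          params$int21[cbind(uv, xy, varnt[, 3L], varnt[, 1L], varnt[, 2L])]
        else
          params$int22[cbind(xy, uv, varnt[, 1L], varnt[, 2L],
                             varnt[, 3L], varnt[, 4L])]
        W[, xy] <- exp(-E / RT)
      }
      W
    }
    return(mk(inner, vars, wfun))
  }
  mmpos <- unique(c(i + 1L, j - 1L, k - 1L, l + 1L))
  p1 <- match(i + 1L, mmpos); p2 <- match(j - 1L, mmpos)
  p3 <- match(k - 1L, mmpos); p4 <- match(l + 1L, mmpos)
  wfun <- function(choice, varnt) {
    W <- matrix(0, nrow(choice), 6L)
    rev_uv <- PAIR_REV[choice[, 1L]]
    inner_mm <- exp(-params$mm_internal[cbind(rev_uv, varnt[, p4],
                                              varnt[, p3])] / RT)
    for (xy in 1:6)
      W[, xy] <- exp(-params$mm_internal[cbind(xy, varnt[, p1],
                                               varnt[, p2])] / RT) * inner_mm
    W
  }
  mk(inner, mmpos, wfun)
}

# compile all loop models for a target / parameter set / mode
.loop_models <- function(target, params, mode, C, opts) {
  RT <- params$RT
  auv <- .au_vec(params)
  lapply(target$loops, function(loop) {
    if (loop$kind %in% c("multiloop", "external")) {
      groups <- build_groups(target, loop, mode)
      tables <- lapply(groups, function(g)
        c(.group_table(target, params, RT, C, loop, g),
          list(closing_member = g$closing_member)))
      allvars <- unlist(lapply(tables, `[[`, "vars"))
      if (loop$kind == "external") {
        unpaired <- which(target$pair_table == 0L)
        inside <- unlist(lapply(loop$inner, function(r)
          target$pairs[r, 1L]:target$pairs[r, 2L]))
        unpaired <- setdiff(unpaired, inside)
        free <- setdiff(unpaired, allvars)
        pref <- rep(C^(-length(free)), 6L)
        return(list(kind = loop$kind, closing = NA_integer_, span = target$n,
                    groups = tables, free = free, pref = pref))
      }
      r <- loop$closing
      i <- unname(target$pairs[r, 1L]); j <- unname(target$pairs[r, 2L])
      interior <- setdiff(which(target$pair_table == 0L), integer(0))
      interior <- interior[interior > i & interior < j]
      inside <- unlist(lapply(loop$inner, function(rr)
        target$pairs[rr, 1L]:target$pairs[rr, 2L]))
      unpaired <- setdiff(interior, inside)
      free <- setdiff(unpaired, allvars)
      mlE <- params$ml_a + params$ml_b * (loop$k + 1L) + params$ml_c * loop$ell
      pref <- exp(-(mlE + auv) / RT) * C^(-(2L + length(free)))
      if (target$bp_close_el_ml[r]) pref <- pref * exp(-auv / RT)
      return(list(kind = loop$kind, closing = r, span = j - i + 1L,
                  groups = tables, free = free, pref = pref))
    }
    r <- loop$closing
    i <- unname(target$pairs[r, 1L]); j <- unname(target$pairs[r, 2L])
    tab <- .one_loop_table(target, params, RT, C, loop, opts)
    allpos <- if (j - i > 1L) (i + 1L):(j - 1L) else integer(0)
    inside <- unlist(lapply(loop$inner, function(rr)
      target$pairs[rr, 1L]:target$pairs[rr, 2L]))
    free <- setdiff(setdiff(allpos, inside), tab$vars)
    pref <- rep(C^(-(2L + length(free))), 6L)
    if (loop$kind == "hairpin") {
      pref <- pref * exp(-hairpin_energy(params, loop$size) / RT)
      if (loop$size == 3L) pref <- pref * exp(-auv / RT)
    } else if (loop$kind == "internal") {
      # table pathway encodes the full loop energy in W; generic adds terms
      if (!.internal_uses_tables(loop, params, opts)) {
        asymE <- min(params$asym * abs(loop$r1 - loop$r2), params$max_asym)
        pref <- pref * exp(-(internal_energy(params, loop$r1 + loop$r2) +
                               asymE + auv) / RT)
      }
    }
    if (target$bp_close_el_ml[r]) pref <- pref * exp(-auv / RT)
    list(kind = loop$kind, closing = r, span = j - i + 1L,
         groups = list(c(tab, list(closing_member = TRUE))),
         free = free, pref = pref)
  })
}

.internal_uses_tables <- function(loop, params, opts) {
  r1 <- loop$r1; r2 <- loop$r2
  opts$small_internal == "tables" &&
    ((r1 == 1L && r2 == 1L && !is.null(params$int11)) ||
     (r1 + r2 == 3L && min(r1, r2) == 1L && !is.null(params$int21)) ||
     (r1 == 2L && r2 == 2L && !is.null(params$int22)))
}

#' Compute the dual partition function of a target structure
#'
#' Computes `Z*(i,j;X,Y)` for every base pair of the target in
#' inner-to-outer order and assembles the total dual partition function
#' `Z*(s0)`: the sum of Boltzmann factors `exp(-E(a, s0)/RT)` over all
#' sequences `a` compatible with the target structure and its IUPAC
#' constraints.  Optionally the computation is resolved by exact
#' GC-content, yielding `Z*(s0, k)` for every `k` simultaneously.
#'
#' @param target an [rna_target][parse_target] (or a dot-bracket string,
#'   parsed with no constraints).
#' @param params energy parameters; default [turner_params()].
#' @param mode dangle model: `"d0"` ignores single-stranded stacking terms,
#'   `"d2"` adds 5' and 3' dangle energies on both flanks of every
#'   multiloop/external-loop helix.
#' @param scale positive scaling constant `C`; internally the scaled values
#'   `Z(i,j;X,Y)/C^(j-i+1)` are propagated so that long targets do not
#'   overflow, and `ln Z*` is recovered exactly.  The default is derived
#'   from the geometric mean of the stacking Boltzmann weights.
#' @param gc_resolved if `TRUE`, every value is resolved by GC content.
#' @param bulge_convention size-1 bulge handling: `"stack"` (default)
#'   retains the stacking term across the bulge and applies terminal
#'   penalties only for larger bulges; `"literal"` uses initiation plus the
#'   outer terminal penalty at every size.
#' @param small_internal `"tables"` (default) scores 1x1, 1x2, 2x1 and 2x2
#'   interior loops from the dedicated lookup tables when present;
#'   `"generic"` uses the size-based initiation + mismatch formula for all
#'   interior loops.
#' @return an object of class `dual_pf` holding the per-pair tables, the
#'   group/conditional tables used by [sample_sequences()], and the total
#'   `Z*` (per GC-content class when `gc_resolved`).  With infeasible
#'   constraints the result has `feasible = FALSE`, `Z* = 0`, and a
#'   diagnostic naming the first empty allowed-pair set.
#' @examples
#' st <- dual_pf("((((....))))", mode = "d0")
#' log_dual_partition(st)
#' @export
dual_pf <- function(target, params = turner_params(), mode = c("d2", "d0"),
                    scale = NULL, gc_resolved = FALSE,
                    bulge_convention = c("stack", "literal"),
                    small_internal = c("tables", "generic")) {
  if (is.character(target)) target <- parse_target(target)
  stopifnot(inherits(target, "rna_target"),
            inherits(params, "dual_energy_params"))
  mode <- match.arg(mode)
  opts <- .resolve_opts(bulge_convention, small_internal)
  if (is.null(scale)) scale <- .default_scale(params)
  if (scale <= 0) stop("scaling constant must be positive")
  n <- target$n
  npairs <- nrow(target$pairs)

  empty <- which(vapply(target$allowed_pairs, length, 0L) == 0L)
  if (length(empty)) {
    r <- empty[1L]
    out <- list(target = target, params = params, mode = mode, scale = scale,
                gc_resolved = gc_resolved, opts = opts, models = NULL,
                Z = NULL, Zsum = NULL, Z_total = if (gc_resolved)
                  numeric(n + 1L) else 0,
                feasible = FALSE,
                diagnostic = sprintf(
                  "constraints leave no allowed pair at base pair (%d,%d)",
                  target$pairs[r, 1L], target$pairs[r, 2L]))
    class(out) <- "dual_pf"
    return(out)
  }

  models <- .loop_models(target, params, mode, scale, opts)

  if (!gc_resolved) {
    Z <- matrix(0, max(npairs, 1L), 6L)
    for (r in seq_len(npairs)) {
      md <- models[[r]]
      fc <- prod(lengths(target$allowed[md$free]))
      for (xy in target$allowed_pairs[[r]]) {
        tot <- md$pref[xy] * fc
        for (g in md$groups) {
          prodZ <- rep(1, nrow(g$W))
          for (q in seq_along(g$pairs))
            prodZ <- prodZ * Z[g$pairs[q], ][g$choice[, q]]
          tot <- tot * sum(g$W[, xy] * prodZ)
        }
        Z[r, xy] <- tot
      }
      if (!all(is.finite(Z[r, ])))
        stop("numeric overflow at base pair (", target$pairs[r, 1L], ",",
             target$pairs[r, 2L], "); increase the scaling constant")
    }
    md <- models[[npairs + 1L]]
    fc <- prod(lengths(target$allowed[md$free]))
    tot <- md$pref[1L] * fc
    for (g in md$groups) {
      prodZ <- rep(1, nrow(g$W))
      for (q in seq_along(g$pairs))
        prodZ <- prodZ * Z[g$pairs[q], ][g$choice[, q]]
      tot <- tot * sum(g$W[, 1L] * prodZ)
    }
    Z_total <- tot
    Zsum <- if (npairs) rowSums(Z) else numeric(0)
  } else {
    Z <- vector("list", npairs)
    for (r in seq_len(npairs)) {
      md <- models[[r]]
      span <- md$span
      fvec <- .gc_count_vector(target$allowed[md$free])
      Zr <- vector("list", 6L)
      for (xy in target$allowed_pairs[[r]]) {
        acc <- .gc_groups_conv(md, Z, xy)
        acc <- .gc_conv(acc, fvec) * md$pref[xy]
        acc <- .gc_shiftpoly(acc, PAIR_GC[xy])
        length(acc) <- span + 1L
        acc[is.na(acc)] <- 0
        Zr[[xy]] <- acc
      }
      for (xy in setdiff(1:6, target$allowed_pairs[[r]]))
        Zr[[xy]] <- numeric(span + 1L)
      Z[[r]] <- Zr
    }
    md <- models[[npairs + 1L]]
    fvec <- .gc_count_vector(target$allowed[md$free])
    acc <- .gc_groups_conv(md, Z, 1L)
    acc <- .gc_conv(acc, fvec) * md$pref[1L]
    length(acc) <- n + 1L
    acc[is.na(acc)] <- 0
    Z_total <- acc
    Zsum <- lapply(Z, function(Zr) Reduce(`+`, Zr))
  }

  out <- list(target = target, params = params, mode = mode, scale = scale,
              gc_resolved = gc_resolved, opts = opts, models = models,
              Z = Z, Zsum = Zsum, Z_total = Z_total, feasible =
                sum(if (gc_resolved) sum(Z_total) else Z_total) > 0,
              diagnostic = NULL)
  class(out) <- "dual_pf"
  out
}

# convolution over the groups of one loop model, conditioned on xy
.gc_groups_conv <- function(md, Z, xy) {
  acc <- 1
  for (g in md$groups) {
    if (nrow(g$W) == 0L) return(numeric(1L))
    if (length(g$pairs) == 0L) {
      gv <- numeric(max(g$gamma) + 1L)
      for (row in seq_len(nrow(g$W)))
        gv[g$gamma[row] + 1L] <- gv[g$gamma[row] + 1L] + g$W[row, xy]
    } else {
      key <- apply(g$choice, 1L, paste, collapse = ",")
      gv <- 0
      for (tk in unique(key)) {
        rows <- which(key == tk)
        conv <- 1
        for (q in seq_along(g$pairs))
          conv <- .gc_conv(conv, Z[[g$pairs[q]]][[g$choice[rows[1L], q]]])
        wsum <- numeric(max(g$gamma[rows]) + 1L)
        for (row in rows)
          wsum[g$gamma[row] + 1L] <- wsum[g$gamma[row] + 1L] + g$W[row, xy]
        term <- .gc_conv(wsum, conv)
        if (length(term) > length(gv)) {
          term[seq_along(gv)] <- term[seq_along(gv)] + gv
          gv <- term
        } else {
          gv[seq_along(term)] <- gv[seq_along(term)] + term
        }
      }
    }
    acc <- .gc_conv(acc, gv)
  }
  acc
}

.default_scale <- function(params) {
  st <- params$stack[is.finite(params$stack)]
  if (!length(st) || all(st == 0)) return(1)
  max(1, exp(-mean(st) / (2 * params$RT)))
}

#' Natural logarithm of the dual partition function
#'
#' @param state a `dual_pf` object.
#' @return `ln Z*(s0)`, independent of the scaling constant; `-Inf` (with
#'   the infeasibility diagnostic as an attribute) when the constraints
#'   admit no sequence.
#' @export
log_dual_partition <- function(state) {
  stopifnot(inherits(state, "dual_pf"))
  tot <- if (state$gc_resolved) sum(state$Z_total) else state$Z_total
  if (tot <= 0)
    return(structure(-Inf, infeasible = TRUE, diagnostic = state$diagnostic))
  log(tot) + state$target$n * log(state$scale)
}

#' Per-base-pair dual partition function table
#'
#' The per-pair values `Z*(i,j;X,Y)` and their row sums `Z*(i,j)`, on the
#' unscaled scale, ordered by base-pair index (inner to outer).  The six
#' pair columns are in the order AU, CG, GC, UA, GU, UG.
#'
#' @param state a `dual_pf` object.
#' @return a data frame with columns `index`, `i`, `j`, `type`, the six
#'   pair columns, and `Z`.
#' @export
bp_table <- function(state) {
  stopifnot(inherits(state, "dual_pf"))
  tg <- state$target
  npairs <- nrow(tg$pairs)
  vals <- matrix(0, npairs, 6L)
  for (r in seq_len(npairs)) {
    span <- tg$pairs[r, 2L] - tg$pairs[r, 1L] + 1L
    row <- if (state$gc_resolved)
      vapply(state$Z[[r]], sum, 0) else state$Z[r, ]
    vals[r, ] <- row * state$scale^span
  }
  kinds <- vapply(seq_len(npairs), function(r) {
    lp <- tg$loops[[r]]
    switch(lp$kind, hairpin = switch(as.character(lp$size),
                                     "3" = "triloop", "4" = "tetraloop",
                                     "6" = "hexaloop", "hairpin"),
           bulge_left = "l.bulge", bulge_right = "r.bulge",
           internal = "int.loop", lp$kind)
  }, "")
  out <- data.frame(index = seq_len(npairs), i = tg$pairs[, 1L],
                    j = tg$pairs[, 2L], type = kinds)
  colnames(vals) <- PAIR_NAMES
  out <- cbind(out, as.data.frame(vals))
  out$Z <- rowSums(vals)
  out
}

#' GC-content profile of the dual partition function
#'
#' @param state a `dual_pf` object computed with `gc_resolved = TRUE`.
#' @return a data frame with columns `k` (GC count 0..n), `Z` (the dual
#'   partition function restricted to GC-content `k`, unscaled) and `p`
#'   (the normalised profile `Z*(s0,k)/Z*(s0)`).
#' @export
gc_profile <- function(state) {
  stopifnot(inherits(state, "dual_pf"))
  if (!state$gc_resolved)
    stop("state was not computed with gc_resolved = TRUE")
  n <- state$target$n
  z <- state$Z_total * state$scale^n
  data.frame(k = 0:n, Z = z, p = if (sum(z) > 0) z / sum(z) else z)
}

#' @export
print.dual_pf <- function(x, ...) {
  cat(sprintf("Dual partition function state (%s%s), n = %d, C = %.4g\n",
              x$mode, if (x$gc_resolved) ", GC-resolved" else "",
              x$target$n, x$scale))
  if (!x$feasible) {
    cat("  INFEASIBLE:", x$diagnostic, "\n")
  } else {
    cat(sprintf("  ln Z* = %.6f\n", log_dual_partition(x)))
  }
  invisible(x)
}
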