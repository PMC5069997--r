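# Stochastic backtracking over the stored conditional tables.
#
# Sampling visits the external loop first, then base pairs in descending
# base-pair index (outer to inner).  At every decision the roulette wheel
# uses the stored group-table masses, so each sequence is drawn i.i.d. with
# probability exactly exp(-E(a,s0)/RT) / Z*(s0) (or its GC-conditioned
# analogue).  Tables are scanned in a fixed canonical order (pairs AU, CG,
# GC, UA, GU, UG; nucleotides A, C, G, U; GC budgets ascending), so runs
# are reproducible from the seed.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample sequences from the dual Boltzmann distribution
#'
#' Draws sequences compatible with the target structure, each with
#' probability proportional to `exp(-E(a, s0)/RT)`, by stochastic
#' backtracking over the conditional tables stored by [dual_pf()].  With
#' `gc` set, sampling is conditioned on an exact GC count: loop-level GC
#' budgets are drawn by roulette over the GC-resolved masses before
#' nucleotides are instantiated, and every returned sequence has exactly
#' the requested number of G+C positions.
#'
#' @param state a `dual_pf` object (computed with `gc_resolved = TRUE`
#'   when `gc` is used).
#' @param n number of sequences to draw.
#' @param seed integer seed; the same seed and configuration reproduce the
#'   identical sample list.
#' @param gc optional exact GC target: an integer count, or a fraction in
#'   (0,1) rounded half-up to a count.
#' @param filter_mfe if `TRUE`, repeatedly sample and keep only sequences
#'   whose minimum free energy structure (per `backend`) equals the
#'   target, until `n` sequences are accepted or `max_attempts` draws per
#'   accepted sequence are exhausted (then a partial result is returned
#'   with a warning).
#' @param backend a folding backend (see [fold_backend_exhaustive()]);
#'   required when `filter_mfe = TRUE`.
#' @param max_attempts attempt budget per accepted sequence when filtering.
#' @return a data frame with one row per sequence: `sequence`, `energy`
#'   (kcal/mol on the target), `gc` (GC count), `ln_p` (log dual Boltzmann
#'   probability; GC-conditioned when `gc` is set), and `attempts` when
#'   filtering.
#' @export
sample_sequences <- function(state, n, seed = NULL, gc = NULL,
                             filter_mfe = FALSE, backend = NULL,
                             max_attempts = 1000L) {
  stopifnot(inherits(state, "dual_pf"), n >= 1)
  if (!state$feasible)
    stop("cannot sample: ", state$diagnostic %||% "Z* is zero")
  if (!is.null(gc)) {
    if (!state$gc_resolved)
      stop("GC-conditioned sampling needs a state computed with gc_resolved = TRUE")
    if (gc > 0 && gc < 1) gc <- floor(gc * state$target$n + 0.5)
    gc <- as.integer(gc)
    if (gc < 0L || gc > state$target$n || state$Z_total[gc + 1L] <= 0)
      stop("requested GC content ", gc, " is infeasible for this target")
  }
  if (filter_mfe && is.null(backend))
    stop("filter_mfe requires a folding backend")

  .with_seed(seed, {
    if (!filter_mfe) return(.sample_block(state, n, gc))
    out <- NULL
    attempts_total <- 0L
    budget <- max_attempts * n
    db <- state$target$db
    while ((is.null(out) || nrow(out) < n) && attempts_total < budget) {
      chunk <- max(16L, n - if (is.null(out)) 0L else nrow(out))
      rec <- .sample_block(state, chunk, gc)
      attempts_total <- attempts_total + chunk
      keep <- vapply(rec$sequence,
                     function(s) identical(mfe_fold(backend, s)$structure, db),
                     TRUE)
      out <- rbind(out, rec[keep, , drop = FALSE])
    }
    if (is.null(out) || nrow(out) < n)
      warning("filter_mfe: accepted ", if (is.null(out)) 0L else nrow(out),
              " of ", n, " requested sequences within ",
              attempts_total, " attempts")
    out <- utils::head(out, n)
    if (nrow(out)) {
      rownames(out) <- NULL
      out$attempts <- attempts_total
    }
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# inverse-CDF roulette in the canonical outcome order.  Unlike
# sample(prob = ...), which sorts the probabilities internally, this keeps
# the outcome order fixed, so a perturbation of the weights at floating
# point level (e.g. a different scaling constant) cannot permute outcomes;
# zero-weight outcomes are never drawn.
.roulette <- function(size, prob) {
  cs <- cumsum(prob)
  tot <- cs[length(cs)]
  findInterval(stats::runif(size) * tot, cs) + 1L
}

.sample_block <- function(state, N, gc) {
  M <- if (is.null(gc)) .sample_plain(state, N) else .sample_gc(state, N, gc)
  E <- .seq_energies(M, state$target, state$params, state$mode, state$opts)
  lnZ <- log_dual_partition(state)
  if (!is.null(gc)) {
    n <- state$target$n
    lnZ <- log(state$Z_total[gc + 1L]) + n * log(state$scale)
  }
  data.frame(sequence = apply(M, 1L, function(v) int_to_nt(v)),
             energy = E,
             gc = as.integer(rowSums(matrix(NT_GC[M], N))),
             ln_p = -E / state$params$RT - lnZ)
}

# vectorised sampler, no GC conditioning
.sample_plain <- function(state, N) {
  tg <- state$target
  n <- tg$n
  npairs <- nrow(tg$pairs)
  Z <- state$Z
  if (state$gc_resolved) {      # marginalise the GC-resolved tables
    Z <- matrix(0, max(npairs, 1L), 6L)
    for (r in seq_len(npairs))
      Z[r, ] <- vapply(state$Z[[r]], sum, 0)
  }
  M <- matrix(0L, N, n)
  PC <- matrix(0L, N, max(npairs, 1L))

  draw_group <- function(g, rows, xy) {
    mass <- g$W[, xy]
    for (q in seq_along(g$pairs))
      mass <- mass * Z[g$pairs[q], ][g$choice[, q]]
    idx <- if (length(mass) == 1L) rep(1L, length(rows))
           else .roulette(length(rows), mass)
    for (q in seq_along(g$vars))
      M[rows, g$vars[q]] <<- g$varnt[idx, q]
    for (q in seq_along(g$pairs)) {
      pr <- g$pairs[q]
      ch <- g$choice[idx, q]
      PC[rows, pr] <<- ch
      M[rows, tg$pairs[pr, 1L]] <<- PAIR_NT[ch, 1L]
      M[rows, tg$pairs[pr, 2L]] <<- PAIR_NT[ch, 2L]
    }
  }
  fill_free <- function(free, rows) {
    for (pos in free) {
      al <- tg$allowed[[pos]]
      M[rows, pos] <<- al[sample.int(length(al), length(rows), TRUE)]
    }
  }

  md <- state$models[[npairs + 1L]]
  for (g in md$groups) draw_group(g, seq_len(N), 1L)
  fill_free(md$free, seq_len(N))

  for (r in rev(seq_len(npairs))) {
    md <- state$models[[r]]
    for (xy in sort(unique(PC[, r]))) {
      rows <- which(PC[, r] == xy)
      for (g in md$groups) draw_group(g, rows, xy)
      fill_free(md$free, rows)
    }
  }
  M
}

# per-loop sampling structures for GC-conditioned backtracking; everything
# that does not depend on the running budget is precomputed here
.gc_samp_tables <- function(state) {
  Z <- state$Z
  tg <- state$target
  lapply(state$models, function(md) {
    groups <- lapply(md$groups, function(g) {
      nr <- nrow(g$W)
      base <- vector("list", nr)
      zs <- vector("list", nr)
      zsuff <- vector("list", nr)
      for (t in seq_len(nr)) {
        zst <- lapply(seq_along(g$pairs), function(q)
          Z[[g$pairs[q]]][[g$choice[t, q]]])
        conv <- 1
        h <- length(zst)
        suf <- vector("list", h + 1L)
        suf[[h + 1L]] <- 1
        for (q in rev(seq_len(h))) suf[[q]] <- .gc_conv(zst[[q]], suf[[q + 1L]])
        conv <- if (h) suf[[1L]] else 1
        base[[t]] <- .gc_shiftpoly(conv, g$gamma[t])
        zs[[t]] <- zst
        zsuff[[t]] <- suf
      }
      U <- lapply(1:6, function(xy)
        lapply(seq_len(nr), function(t) g$W[t, xy] * base[[t]]))
      V <- lapply(U, function(u) {
        len <- max(vapply(u, length, 0L), 1L)
        acc <- numeric(len)
        for (x in u) acc[seq_along(x)] <- acc[seq_along(x)] + x
        acc
      })
      list(U = U, V = V, zs = zs, zsuff = zsuff)
    })
    fvec <- .gc_count_vector(tg$allowed[md$free])
    G <- length(groups)
    suff <- lapply(1:6, function(xy) {
      s <- vector("list", G + 1L)
      s[[G + 1L]] <- fvec
      for (g in rev(seq_len(G)))
        s[[g]] <- .gc_conv(groups[[g]]$V[[xy]], s[[g + 1L]])
      s
    })
    # free-position placement helpers
    m <- length(md$free)
    fsets <- tg$allowed[md$free]
    fsuff <- vector("list", m + 1L)
    if (m) {
      fsuff[[m + 1L]] <- 1
      for (q in rev(seq_len(m))) fsuff[[q]] <- .gc_count_vector(fsets[q:m])
    }
    fgc <- lapply(fsets, function(al) al[NT_GC[al] == 1L])
    fat <- lapply(fsets, function(al) al[NT_GC[al] == 0L])
    list(groups = groups, fvec = fvec, suff = suff,
         fsuff = fsuff, fgc = fgc, fat = fat)
  })
}

.sample_gc <- function(state, N, gc) {
  tg <- state$target
  n <- tg$n
  npairs <- nrow(tg$pairs)
  Z <- state$Z
  st <- .gc_samp_tables(state)
  M <- matrix(0L, N, n)
  PC <- matrix(0L, N, max(npairs, 1L))
  AB <- matrix(0L, N, max(npairs, 1L))   # GC budget per pair (incl. its nts)
  cand_cache <- new.env(parent = emptyenv())

  pick <- function(mass) {
    if (length(mass) == 1L) return(1L)
    .roulette(1L, mass)
  }

  # place `beta` G/C among free positions, uniformly over arrangements
  place_free <- function(s, free, beta, tb) {
    m <- length(free)
    if (!m) return(invisible())
    for (q in seq_len(m)) {
      gcs <- tb$fgc[[q]]
      ats <- tb$fat[[q]]
      nxt <- tb$fsuff[[q + 1L]]
      wgc <- if (beta >= 1L && beta <= length(nxt)) length(gcs) * nxt[beta] else 0
      wat <- if (beta + 1L <= length(nxt)) length(ats) * nxt[beta + 1L] else 0
      use_gc <- (wgc + wat) * stats::runif(1L) < wgc
      if (use_gc) {
        M[s, free[q]] <<- gcs[pick(rep(1, length(gcs)))]
        beta <- beta - 1L
      } else {
        M[s, free[q]] <<- ats[pick(rep(1, length(ats)))]
      }
    }
  }

  # sample one loop for sample s: closing pair r (NA = external), xy of the
  # closing pair, `budget` = GC count of the loop's own interior
  samp_loop <- function(s, r, xy, budget) {
    md <- state$models[[if (is.na(r)) npairs + 1L else r]]
    tb <- st[[if (is.na(r)) npairs + 1L else r]]
    G <- length(md$groups)
    suff <- tb$suff[[xy]]
    li <- if (is.na(r)) npairs + 1L else r
    for (g in seq_len(G)) {
      gt <- md$groups[[g]]
      key <- paste(li, g, xy, budget, sep = ":")
      cand <- cand_cache[[key]]
      if (is.null(cand)) {
        U <- tb$groups[[g]]$U[[xy]]
        S <- suff[[g + 1L]]
        cand_t <- integer(0); cand_a <- integer(0); cand_w <- numeric(0)
        for (t in seq_along(U)) {
          u <- U[[t]]
          amax <- min(length(u) - 1L, budget)
          if (amax < 0L) next
          a <- 0:amax
          w <- u[a + 1L] * ifelse(budget - a + 1L <= length(S),
                                  S[budget - a + 1L], 0)
          keep <- w > 0
          cand_t <- c(cand_t, rep(t, sum(keep)))
          cand_a <- c(cand_a, a[keep])
          cand_w <- c(cand_w, w[keep])
        }
        cand <- list(t = cand_t, a = cand_a, w = cand_w)
        cand_cache[[key]] <- cand
      }
      if (!length(cand$w))
        stop("internal error: no feasible GC split in sampling")
      kidx <- pick(cand$w)
      t <- cand$t[kidx]; a <- cand$a[kidx]
      for (q in seq_along(gt$vars)) M[s, gt$vars[q]] <<- gt$varnt[t, q]
      rem <- a - gt$gamma[t]
      # distribute `rem` among the inner components of row t
      h <- length(gt$pairs)
      if (h) {
        zs <- tb$groups[[g]]$zs[[t]]
        zsuff <- tb$groups[[g]]$zsuff[[t]]
        for (q in seq_len(h)) {
          zq <- zs[[q]]; Sq <- zsuff[[q + 1L]]
          amax <- min(length(zq) - 1L, rem)
          aa <- 0:amax
          w <- zq[aa + 1L] * ifelse(rem - aa + 1L <= length(Sq),
                                    Sq[rem - aa + 1L], 0)
          aq <- aa[pick(w)]
          pr <- gt$pairs[q]; ch <- gt$choice[t, q]
          PC[s, pr] <<- ch
          AB[s, pr] <<- aq
          M[s, tg$pairs[pr, 1L]] <<- PAIR_NT[ch, 1L]
          M[s, tg$pairs[pr, 2L]] <<- PAIR_NT[ch, 2L]
          rem <- rem - aq
        }
        if (rem != 0L) stop("internal error: GC budget not exhausted in group")
      }
      budget <- budget - a
    }
    place_free(s, md$free, budget, tb)
  }

  for (s in seq_len(N)) {
    samp_loop(s, NA_integer_, 1L, gc)
    for (r in rev(seq_len(npairs)))
      samp_loop(s, r, PC[s, r], AB[s, r] - PAIR_GC[PC[s, r]])
  }
  M
}

#' Keep sequences whose MFE structure equals the target
#'
#' @param sequences character vector of sequences, or a record data frame
#'   from [sample_sequences()].
#' @param target an [rna_target][parse_target] or dot-bracket string.
#' @param backend a folding backend providing `mfe_fold`.
#' @return the subset (same type as the input, order preserved) whose
#'   minimum free energy structure is identical to the target.  Sequences
#'   on which the backend fails are dropped with a warning naming them.
#' @export
filter_mfe <- function(sequences, target, backend) {
  if (is.character(target)) target <- parse_target(target)
  seqs <- if (is.data.frame(sequences)) sequences$sequence else sequences
  status <- vapply(seqs, function(s) {
    res <- tryCatch(mfe_fold(backend, s), error = function(e) NULL)
    if (is.null(res)) NA else identical(res$structure, target$db)
  }, TRUE)
  if (anyNA(status)) {
    warning("folding backend failed on: ",
            paste(utils::head(seqs[is.na(status)], 5L), collapse = ", "))
    status[is.na(status)] <- FALSE
  }
  if (is.data.frame(sequences)) sequences[status, , drop = FALSE]
  else sequences[status]
}
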