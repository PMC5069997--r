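# Shared fixtures: parameters are loaded once; the worked 28-nt example
# (a two-stem multiloop with a triloop and a constrained tetraloop) is the
# reference instance with externally known per-pair values.

TP <- turner_params()
ZP <- zero_params()

worked_example <- function() {
  db <- "(((.((...)).)).(((....)).))."
  iu <- paste(replace(replace(rep("N", 28), 18, "G"), 23, "C"), collapse = "")
  parse_target(db, iu)
}

# exact dual Boltzmann distribution over all compatible sequences
exact_distribution <- function(target, params, mode, gc = NULL) {
  M <- dualpf:::.enumerate_compatible(target)
  E <- dualpf:::.seq_energies(M, target, params, mode,
                              dualpf:::.resolve_opts())
  gcv <- rowSums(matrix(dualpf:::NT_GC[M], nrow(M)))
  keep <- if (is.null(gc)) rep(TRUE, nrow(M)) else gcv == gc
  pr <- exp(-E[keep] / params$RT)
  key <- apply(M[keep, , drop = FALSE], 1L,
               function(v) dualpf:::int_to_nt(v))
  list(key = key, p = pr / sum(pr), E = E[keep], gc = gcv[keep])
}

# chi-square GOF p-value with pooling of cells expected below 5
chisq_pvalue <- function(seqs, exact) {
  N <- length(seqs)
  obs <- as.numeric(table(factor(seqs, levels = exact$key)))
  expd <- N * exact$p
  pool <- expd < 5
  obs2 <- c(obs[!pool], sum(obs[pool]))
  exp2 <- c(expd[!pool], sum(expd[pool]))
  chi <- sum((obs2 - exp2)^2 / exp2)
  stats::pchisq(chi, length(obs2) - 1L, lower.tail = FALSE)
}

# random constrained instances with a bounded enumeration size
random_small_instance <- function(seed, n = 14L, max_count = 1e5) {
  repeat {
    db <- generate_random_structure(n, pair_density = 0.6, seed = seed)
    iu <- random_constraints(db, p_constrained = 0.6, seed = seed + 7919L)
    tgt <- parse_target(db, iu)
    cnt <- prod(c(vapply(tgt$allowed_pairs, length, 0L),
                  lengths(tgt$allowed[tgt$pair_table == 0L])))
    if (cnt > 0 && cnt <= max_count) return(tgt)
    seed <- seed + 104729L
  }
}

# toy ensembles: explicit structure distributions over a fixed length
toy_ensemble <- function(structs, probs) {
  n <- nchar(structs[1L])
  p <- matrix(0, n, n)
  plist <- lapply(structs, function(db) dualpf:::parse_target_lenient(db)$pairs)
  for (q in seq_along(structs))
    for (r in seq_len(nrow(plist[[q]])))
      p[plist[[q]][r, 1L], plist[[q]][r, 2L]] <-
        p[plist[[q]][r, 1L], plist[[q]][r, 2L]] + probs[q]
  list(pm = bpp_matrix(p), structs = structs, probs = probs)
}

cross_expected_distance <- function(a, b) {
  tot <- 0
  for (q in seq_along(a$structs)) for (r in seq_along(b$structs))
    tot <- tot + a$probs[q] * b$probs[r] *
      base_pair_distance(a$structs[q], b$structs[r])
  tot
}
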