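# Structure-ensemble metrics over base-pair probability matrices, plus the
# robustness/neutrality measures defined on single-point mutant
# neighbourhoods.

#' Base-pair probability matrix
#'
#' Container for the Boltzmann pairing probabilities `p_ij` of one
#' sequence.  Rows/columns are positions; only `i < j` entries are used.
#'
#' @param p an n x n matrix with `p[i,j]` the probability that positions
#'   `i < j` pair; entries must lie in `[0,1]` and every position's total
#'   pairing probability must not exceed 1.
#' @return an object of class `bpp_matrix` with the unpaired
#'   probabilities `q_i = 1 - sum_j p_ij` attached.
#' @export
bpp_matrix <- function(p) {
  stopifnot(is.matrix(p), nrow(p) == ncol(p))
  n <- nrow(p)
  up <- p
  up[lower.tri(up, diag = TRUE)] <- 0
  if (any(up < -1e-9) || any(up > 1 + 1e-9))
    stop("pairing probabilities must lie in [0,1]")
  tot <- rowSums(up) + colSums(up)
  if (any(tot > 1 + 1e-9))
    stop("total pairing probability exceeds 1 at position ",
         which.max(tot))
  structure(list(n = n, p = up, q = pmax(0, 1 - tot)), class = "bpp_matrix")
}

#' @export
print.bpp_matrix <- function(x, ...) {
  cat("Base-pair probability matrix, n =", x$n, "\n")
  cat(sprintf("  expected pairs: %.3f; ensemble diversity: %.3f\n",
              sum(x$p), ensemble_diversity(x)))
  invisible(x)
}

#' Base pair distance between two structures
#'
#' The size of the symmetric difference of the two base-pair sets.
#'
#' @param s,t dot-bracket strings or [rna_target][parse_target] objects of
#'   equal length.
#' @return an integer distance.
#' @export
base_pair_distance <- function(s, t) {
  ps <- .pairs_of(s); pt <- .pairs_of(t)
  if (attr(ps, "n") != attr(pt, "n"))
    stop("structures have different lengths")
  length(setdiff(ps, pt)) + length(setdiff(pt, ps))
}

.pairs_of <- function(s) {
  if (is.character(s)) s <- parse_target_lenient(s)
  out <- if (nrow(s$pairs)) paste(s$pairs[, 1L], s$pairs[, 2L]) else character(0)
  attr(out, "n") <- s$n
  out
}

# structure parser without the hairpin-size floor, for comparing arbitrary
# (e.g. externally folded) structures
parse_target_lenient <- function(db) {
  chars <- strsplit(gsub("[[:space:]]", "", db), "")[[1L]]
  n <- length(chars)
  pair_table <- integer(n)
  stack <- integer(0)
  for (k in seq_len(n)) {
    if (chars[k] == "(") stack <- c(stack, k)
    else if (chars[k] == ")") {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      pair_table[i] <- k; pair_table[k] <- i
    }
  }
  opens <- which(chars == "(")
  list(n = n, pairs = cbind(i = opens, j = pair_table[opens]))
}

#' Ensemble diversity (intrinsic distance)
#'
#' The expected base pair distance between two structures drawn
#' independently from the Boltzmann ensemble:
#' `d0 = 2 * sum_{i<j} p_ij (1 - p_ij)`.
#'
#' @param pm a [bpp_matrix()].
#' @return `d0` in base pairs.
#' @export
ensemble_diversity <- function(pm) {
  stopifnot(inherits(pm, "bpp_matrix"))
  2 * sum(pm$p * (1 - pm$p))
}

#' Plasticity (normalised ensemble diversity)
#'
#' `P = d0 / (n/2)`, the ensemble diversity normalised by the maximum
#' possible number of base pairs; lies in `[0,1]`.
#'
#' @param pm a [bpp_matrix()].
#' @param n sequence length (default: taken from the matrix).
#' @return the plasticity.
#' @export
plasticity <- function(pm, n = pm$n) {
  ensemble_diversity(pm) / (n / 2)
}

#' Ensemble distance between two sequences
#'
#' The Euclidean distance between base-pair probability matrices,
#' `D_V(a,b) = sqrt(sum_{i<j} (p_ij(a) - p_ij(b))^2)`; a true metric,
#' equal to the square root of the expected cross base-pair distance minus
#' the mean of the two ensemble diversities.
#'
#' @param pm_a,pm_b [bpp_matrix()] objects of equal size.
#' @return `D_V`.
#' @export
ensemble_distance <- function(pm_a, pm_b) {
  stopifnot(inherits(pm_a, "bpp_matrix"), inherits(pm_b, "bpp_matrix"),
            pm_a$n == pm_b$n)
  sqrt(sum((pm_a$p - pm_b$p)^2))
}

#' Asymmetric ensemble distance d1
#'
#' The expected base pair distance between the ensembles of `a` and `b`
#' minus the ensemble diversity of `a`:
#' `d1(a,b) = sum_{i<j} [p_ij(a)(1-p_ij(b)) + p_ij(b)(1-p_ij(a))] - d0(a)`.
#' Not symmetric, hence not a metric.
#'
#' @param pm_a,pm_b [bpp_matrix()] objects of equal size.
#' @return `d1(a, b)`.
#' @export
d1_distance <- function(pm_a, pm_b) {
  stopifnot(pm_a$n == pm_b$n)
  cross <- sum(pm_a$p * (1 - pm_b$p) + pm_b$p * (1 - pm_a$p))
  cross - ensemble_diversity(pm_a)
}

.mutants_of <- function(sequence) {
  v <- nt_to_int(sequence)
  out <- character(0)
  for (q in seq_along(v)) for (nt in setdiff(1:4, v[q])) {
    w <- v; w[q] <- nt
    out <- c(out, int_to_nt(w))
  }
  out
}

#' Mutational robustness of a sequence
#'
#' One minus the length-normalised average ensemble distance from the
#' sequence to its `3n` single-point mutants.  The default `"dv"` variant
#' uses the metric `D_V`: `R = 1 - <D_V>/n`; the `"d1"` variant uses the
#' asymmetric `d1` with the historical normalisation `R = 1 - <d1>/(n/2)`.
#'
#' @param sequence RNA sequence string.
#' @param backend a folding backend (see [fold_backend_exhaustive()]).
#' @param variant `"dv"` (default) or `"d1"`.
#' @return the robustness value.
#' @export
mutational_robustness <- function(sequence, backend, variant = c("dv", "d1")) {
  variant <- match.arg(variant)
  n <- nchar(sequence)
  pm0 <- basepair_probs(backend, sequence)
  ds <- vapply(.mutants_of(sequence), function(mut) {
    pm <- basepair_probs(backend, mut)
    if (variant == "dv") ensemble_distance(pm0, pm)
    else d1_distance(pm0, pm)
  }, 0)
  if (variant == "dv") 1 - mean(ds) / n else 1 - mean(ds) / (n / 2)
}

#' Neutrality of a sequence
#'
#' `eta = 1 - <d_BP>/n`, where `<d_BP>` is the mean base pair distance
#' between the MFE structures of the `3n` single-point mutants and the
#' wild-type MFE structure.
#'
#' @inheritParams mutational_robustness
#' @return the neutrality in `[0, 1]`.
#' @export
neutrality <- function(sequence, backend) {
  n <- nchar(sequence)
  s0 <- mfe_fold(backend, sequence)$structure
  ds <- vapply(.mutants_of(sequence), function(mut)
    base_pair_distance(s0, mfe_fold(backend, mut)$structure), 0)
  1 - mean(ds) / n
}

#' Ensemble quality measures of a sequence against a target
#'
#' Computes, from the base-pair probability matrix and MFE structure of
#' the sequence: the ensemble defect (length-normalised expected Hamming
#' distance to the target pairing vector), the length-normalised expected
#' base pair distance to the target, the proportion of target base pairs
#' present in the MFE structure (native contacts), the average positional
#' entropy (natural log over the pairing states of each position), and the
#' length-normalised ensemble diversity.
#'
#' @param sequence RNA sequence string.
#' @param target dot-bracket string or [rna_target][parse_target].
#' @param backend a folding backend.
#' @return a named list: `ensemble_defect`, `expected_bp_distance`,
#'   `native_contacts`, `positional_entropy`, `diversity`.
#' @export
measure_battery <- function(sequence, target, backend) {
  if (is.character(target)) target <- parse_target(target)
  n <- target$n
  pm <- basepair_probs(backend, sequence)
  stopifnot(pm$n == n)
  mfe <- mfe_fold(backend, sequence)$structure

  partner <- target$pair_table
  # ensemble defect: per position, probability of not being in the target
  # pairing state
  pfull <- pm$p + t(pm$p)
  defect <- 0
  for (q in seq_len(n))
    defect <- defect + if (partner[q] > 0L) 1 - pfull[q, partner[q]] else
      1 - pm$q[q]
  # expected base-pair distance to the target
  in_target <- matrix(FALSE, n, n)
  if (nrow(target$pairs))
    in_target[target$pairs] <- TRUE
  ebp <- sum(1 - pm$p[in_target]) + sum(pm$p[!in_target & upper.tri(pm$p)])

  mfe_pairs <- parse_target_lenient(mfe)$pairs
  tgt_keys <- paste(target$pairs[, 1L], target$pairs[, 2L])
  mfe_keys <- paste(mfe_pairs[, 1L], mfe_pairs[, 2L])
  natc <- if (length(tgt_keys)) mean(tgt_keys %in% mfe_keys) else NA_real_

  ent <- 0
  for (q in seq_len(n)) {
    ps <- c(pfull[q, ], pm$q[q])
    ps <- ps[ps > 0]
    ent <- ent - sum(ps * log(ps))
  }

  list(ensemble_defect = defect / n,
       expected_bp_distance = ebp / n,
       native_contacts = natc,
       positional_entropy = ent / n,
       diversity = ensemble_diversity(pm) / n)
}

#' Z-score of a wild-type value against control values
#'
#' `(wt - mean(controls)) / sd(controls)` with the sample (n-1) standard
#' deviation.
#'
#' @param wild_type_value scalar.
#' @param control_values numeric vector of at least 2 values with non-zero
#'   spread.
#' @return the Z-score.
#' @export
zscore_report <- function(wild_type_value, control_values) {
  if (length(control_values) < 2L)
    stop("need at least 2 control values")
  s <- stats::sd(control_values)
  if (s == 0) stop("Z-score undefined: controls have zero standard deviation")
  (wild_type_value - mean(control_values)) / s
}
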