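#' Generate a random well-nested target structure
#'
#' Draws a random secondary structure of length `n` by repeatedly
#' proposing base pairs at uniformly random positions and accepting those
#' that keep the structure well nested with hairpins of at least 3
#' unpaired nucleotides.  Reproducible from the seed; used as a fixture
#' generator for property tests.
#'
#' @param n structure length.
#' @param pair_density target fraction of paired positions (0..1).
#' @param seed integer seed.
#' @return a dot-bracket string.
#' @export
generate_random_structure <- function(n, pair_density = 0.5, seed = NULL) {
  stopifnot(n >= 1)
  .with_seed(seed, {
    pt <- integer(n)
    target_pairs <- floor(n * pair_density / 2)
    attempts <- 0L
    npair <- 0L
    ok_nested <- function(i, j) {
      # every position between i and j must have its partner inside (i,j)
      inside <- (i + 1L):(j - 1L)
      all(pt[inside] == 0L | (pt[inside] > i & pt[inside] < j))
    }
    enclosing_ok <- function(i, j) {
      # no existing pair (a,b) with a < i < b < j or i < a < j < b
      prs <- which(pt > seq_len(n))
      for (a in prs) {
        b <- pt[a]
        if ((a < i && i <= b && b < j) || (i < a && a <= j && j < b))
          return(FALSE)
      }
      TRUE
    }
    while (npair < target_pairs && attempts < 50L * n) {
      attempts <- attempts + 1L
      i <- sample.int(n, 1L)
      j <- sample.int(n, 1L)
      if (i > j) { tmp <- i; i <- j; j <- tmp }
      if (j - i <= THETA) next
      if (pt[i] != 0L || pt[j] != 0L) next
      if (!ok_nested(i, j) || !enclosing_ok(i, j)) next
      # adding (i,j) must not strangle an unpaired stretch below theta+1
      pt[i] <- j; pt[j] <- i
      db <- .pt_to_db(pt)
      parsed <- tryCatch(parse_target(db), error = function(e) NULL)
      if (is.null(parsed)) { pt[i] <- 0L; pt[j] <- 0L; next }
      npair <- npair + 1L
    }
    .pt_to_db(pt)
  })
}

.pt_to_db <- function(pt) {
  ch <- rep(".", length(pt))
  ch[pt > seq_along(pt)] <- "("
  ch[pt != 0L & pt < seq_along(pt)] <- ")"
  paste(ch, collapse = "")
}

#' Random IUPAC constraint string for a target
#'
#' Draws per-position IUPAC codes (biased towards mild constraints) such
#' that every base pair keeps at least one allowed pair; used by the
#' property-test suites.
#'
#' @param target an [rna_target][parse_target] or dot-bracket string.
#' @param p_constrained probability that a position receives a
#'   non-`N` code.
#' @param seed integer seed.
#' @return an IUPAC string of the target's length.
#' @export
random_constraints <- function(target, p_constrained = 0.3, seed = NULL) {
  if (is.character(target)) target <- parse_target(target)
  codes <- c("A", "C", "G", "U", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V")
  .with_seed(seed, {
    repeat {
      iu <- rep("N", target$n)
      pick <- stats::runif(target$n) < p_constrained
      iu[pick] <- sample(codes, sum(pick), replace = TRUE)
      ok <- tryCatch({
        tg <- parse_target(target$db, paste(iu, collapse = ""))
        all(vapply(tg$allowed_pairs, length, 0L) > 0L)
      }, error = function(e) FALSE)
      if (ok) return(paste(iu, collapse = ""))
    }
  })
}
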