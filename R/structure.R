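#' Parse a target secondary structure and sequence constraints
#'
#' Parses a dot-bracket string into a target-structure object: the base-pair
#' set, its loop decomposition (hairpins, stacks, bulges, internal loops,
#' multiloops and the external loop), the inner-to-outer total order on base
#' pairs used by the dual partition function recursions, and the
#' per-position/per-pair allowed sets induced by an optional IUPAC
#' constraint string.
#'
#' @details
#' Positions are numbered 1..n inclusive.  The structure must be well
#' nested (pseudoknots are rejected) and every hairpin must enclose at
#' least 3 unpaired nucleotides (`j - i > 3`).  The base-pair order ranks
#' `(i,j)` before `(x,y)` iff `x < i < j < y` or `i < j < x < y`, so every
#' pair ranks after all pairs it encloses and left subtrees precede right
#' subtrees.
#'
#' IUPAC constraints restrict the allowed nucleotide set at each position;
#' at a base pair the allowed pair set is the subset of the six canonical
#' pairs (AU, CG, GC, UA, GU, UG) whose nucleotides are allowed at the two
#' positions.  An empty allowed-pair set makes the target infeasible; this
#' is detected and reported by [dual_pf()], not silently zeroed here.
#'
#' @param dotbracket a string over `(`, `)` and `.`.
#' @param iupac optional IUPAC constraint string of the same length
#'   (default: unconstrained, i.e. `N` everywhere).
#' @return an object of class `rna_target` with components `n`, `db`,
#'   `pairs` (matrix, rows in base-pair order), `pair_table`, `loops`,
#'   `bp_close_el_ml`, `allowed` (list of allowed nucleotide codes per
#'   position) and `allowed_pairs` (list per base-pair row).
#' @examples
#' tgt <- parse_target("((((...))))", "NNNNGNNNNNN")
#' tgt$pairs
#' @export
parse_target <- function(dotbracket, iupac = NULL) {
  db <- gsub("[[:space:]]", "", dotbracket)
  chars <- strsplit(db, "")[[1L]]
  n <- length(chars)
  if (n == 0L) stop("empty structure")
  bad <- setdiff(unique(chars), c("(", ")", "."))
  if (length(bad)) stop("structure contains characters outside '().': ",
                        paste(bad, collapse = " "))

  pair_table <- integer(n)
  stack <- integer(0)
  for (k in seq_len(n)) {
    if (chars[k] == "(") stack <- c(stack, k)
    else if (chars[k] == ")") {
      if (!length(stack)) stop("unbalanced brackets: unmatched ')' at position ", k)
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (k - i <= THETA)
        stop("hairpin at (", i, ",", k, ") violates the steric floor: ",
             "pairs need j - i > ", THETA)
      pair_table[i] <- k
      pair_table[k] <- i
    }
  }
  if (length(stack)) stop("unbalanced brackets: unmatched '(' at position ",
                          stack[length(stack)])

  opens <- which(chars == "(")
  pairs <- cbind(i = opens, j = pair_table[opens])
  if (nrow(pairs)) {
    # base-pair order: DFS, children (left to right) before their parent
    rank <- .bp_order_rank(pairs, pair_table, n)
    pairs <- pairs[order(rank), , drop = FALSE]
  }
  bp_at <- integer(n)                 # position -> base-pair row (opens only)
  if (nrow(pairs)) bp_at[pairs[, 1L]] <- seq_len(nrow(pairs))

  loops <- .decompose_loops(pairs, pair_table, bp_at, n)
  bp_close_el_ml <- logical(nrow(pairs))
  for (lp in loops)
    if (lp$kind %in% c("multiloop", "external"))
      bp_close_el_ml[lp$inner] <- TRUE

  # constraints
  if (is.null(iupac)) iupac <- strrep("N", n)
  iup <- strsplit(toupper(gsub("[[:space:]]", "", iupac)), "")[[1L]]
  if (length(iup) != n)
    stop("constraint string length ", length(iup),
         " does not match structure length ", n)
  allowed <- IUPAC_SETS[iup]
  if (any(vapply(allowed, is.null, TRUE)))
    stop("invalid IUPAC letter(s): ",
         paste(unique(iup[vapply(allowed, is.null, TRUE)]), collapse = " "))
  allowed <- unname(allowed)
  allowed_pairs <- lapply(seq_len(nrow(pairs)), function(r) {
    ai <- allowed[[pairs[r, 1L]]]
    aj <- allowed[[pairs[r, 2L]]]
    which(PAIR_NT[, 1L] %in% ai & PAIR_NT[, 2L] %in% aj)
  })

  structure(list(n = n, db = db, pairs = pairs, pair_table = pair_table,
                 bp_at = bp_at, loops = loops,
                 bp_close_el_ml = bp_close_el_ml,
                 iupac = paste(iup, collapse = ""),
                 allowed = allowed, allowed_pairs = allowed_pairs),
            class = "rna_target")
}

# rank of each pair row under the order: (i,j) < (x,y) iff x<i<j<y or i<j<x<y.
# Equivalent to a DFS of the structure tree emitting children before parents.
.bp_order_rank <- function(pairs, pair_table, n) {
  out <- integer(nrow(pairs))
  counter <- 0L
  rowof <- integer(n)
  rowof[pairs[, 1L]] <- seq_len(nrow(pairs))
  visit <- function(i, j) {                 # interval, exclusive of a closing pair
    k <- i
    while (k <= j) {
      if (pair_table[k] > k) {
        visit(k + 1L, pair_table[k] - 1L)
        counter <<- counter + 1L
        out[rowof[k]] <<- counter
        k <- pair_table[k] + 1L
      } else k <- k + 1L
    }
  }
  visit(1L, n)
  out
}

# loop records: one per closing pair, plus the external loop (kind "external")
.decompose_loops <- function(pairs, pair_table, bp_at, n) {
  children_of <- function(i, j) {         # direct inner pairs of interval (i,j)
    res <- integer(0)
    k <- i
    while (k <= j) {
      if (pair_table[k] > k) {
        res <- c(res, bp_at[k])
        k <- pair_table[k] + 1L
      } else k <- k + 1L
    }
    res
  }
  loops <- vector("list", nrow(pairs) + 1L)
  for (r in seq_len(nrow(pairs))) {
    i <- unname(pairs[r, 1L]); j <- unname(pairs[r, 2L])
    inner <- children_of(i + 1L, j - 1L)
    if (length(inner) == 0L) {
      loops[[r]] <- list(kind = "hairpin", closing = r, inner = integer(0),
                         size = j - i - 1L)
    } else if (length(inner) == 1L) {
      k <- unname(pairs[inner, 1L]); l <- unname(pairs[inner, 2L])
      r1 <- k - i - 1L; r2 <- j - l - 1L
      kind <- if (r1 == 0L && r2 == 0L) "stack"
              else if (r2 == 0L) "bulge_left"
              else if (r1 == 0L) "bulge_right"
              else "internal"
      loops[[r]] <- list(kind = kind, closing = r, inner = inner,
                         r1 = r1, r2 = r2)
    } else {
      spans <- pairs[inner, 2L] - pairs[inner, 1L] + 1L
      loops[[r]] <- list(kind = "multiloop", closing = r, inner = inner,
                         k = length(inner),
                         ell = (j - i - 1L) - sum(spans))
    }
  }
  ext_inner <- children_of(1L, n)
  spans <- if (length(ext_inner)) pairs[ext_inner, 2L] - pairs[ext_inner, 1L] + 1L else integer(0)
  loops[[nrow(pairs) + 1L]] <- list(kind = "external", closing = NA_integer_,
                                    inner = ext_inner, ell = n - sum(spans))
  loops
}

#' Base pairs in recursion order
#'
#' @param target an `rna_target`.
#' @return the base-pair matrix ordered so that every pair follows all pairs
#'   it encloses (ascending base-pair index).
#' @export
order_base_pairs <- function(target) {
  stopifnot(inherits(target, "rna_target"))
  target$pairs
}

#' Dangle-adjacency groups of a multiloop or external loop
#'
#' Partitions the helices of a multiloop or external loop (plus, for a
#' multiloop, its closing pair) into maximal groups of mutually adjacent
#' helices whose dangling positions overlap, as used by the d2 dangle
#' model.  Two sibling helices `(x,y)` and `(x',y')` are adjacent when
#' `x' - y <= 2`; the closing pair `(i,j)` of a multiloop is adjacent to an
#' inner helix `(x,y)` when `x <= i + 2` or `y >= j - 2`.  Adjacency is
#' closed transitively, so groups are maximal.
#'
#' @param target an `rna_target`.
#' @param loop a loop record of `target$loops` with kind `multiloop` or
#'   `external`.
#' @param mode `"d0"` (no dangles: one degenerate group per helix, no
#'   dangle positions) or `"d2"` (both flanks of every helix contribute).
#' @return a list of groups; each group has `pairs` (base-pair rows, the
#'   multiloop closing pair marked by `closing = TRUE`), `dangles` (a data
#'   frame of dangle roles: pair row, side, position, and how the position
#'   is bound: a free variable, another dangle variable, or a paired
#'   position), and `vars` (the distinct free dangle positions).
#' @export
build_groups <- function(target, loop, mode = c("d2", "d0")) {
  mode <- match.arg(mode)
  stopifnot(loop$kind %in% c("multiloop", "external"))
  pairs <- target$pairs
  n <- target$n
  inner <- loop$inner[order(pairs[loop$inner, 1L])]
  is_ml <- loop$kind == "multiloop"
  cp <- if (is_ml) loop$closing else NA_integer_

  if (mode == "d0") {
    gs <- lapply(inner, function(r)
      list(pairs = r, closing_member = FALSE,
           dangles = NULL, vars = integer(0)))
    if (is_ml) gs <- c(gs, list(list(pairs = cp, closing_member = TRUE,
                                     dangles = NULL, vars = integer(0))))
    return(gs)
  }

  # adjacency components over the member list (inner helices [+ closing])
  members <- c(inner, if (is_ml) cp)
  m <- length(members)
  adj <- matrix(FALSE, m, m)
  ii <- if (is_ml) pairs[cp, 1L] else 0L
  jj <- if (is_ml) pairs[cp, 2L] else 0L
  for (a in seq_along(inner)) {
    for (b in seq_along(inner)) {
      if (a >= b) next
      xa <- pairs[inner[a], ]; xb <- pairs[inner[b], ]
      if (xa[1L] > xb[1L]) { tmp <- xa; xa <- xb; xb <- tmp }
      if (xb[1L] - xa[2L] <= 2L) adj[a, b] <- adj[b, a] <- TRUE
    }
    if (is_ml) {
      x <- pairs[inner[a], ]
      if (x[1L] <= ii + 2L || x[2L] >= jj - 2L)
        adj[a, m] <- adj[m, a] <- TRUE
    }
  }
  comp <- seq_len(m)
  repeat {
    changed <- FALSE
    for (a in seq_len(m)) for (b in seq_len(m))
      if (adj[a, b] && comp[b] > comp[a]) { comp[b] <- comp[a]; changed <- TRUE }
    if (!changed) break
  }

  lapply(unique(comp), function(cid) {
    mem <- members[comp == cid]
    closing_member <- is_ml && cp %in% mem
    # dangle roles: for inner helices 5' at x-1, 3' at y+1;
    # for the closing pair (viewed from inside) 3' at i+1, 5' at j-1.
    roles <- list()
    for (r in mem) {
      x <- pairs[r, 1L]; y <- pairs[r, 2L]
      if (is_ml && r == cp) {
        roles[[length(roles) + 1L]] <- list(pair = r, side = "in3", pos = x + 1L)
        roles[[length(roles) + 1L]] <- list(pair = r, side = "in5", pos = y - 1L)
      } else {
        if (x > 1L) roles[[length(roles) + 1L]] <- list(pair = r, side = "d5", pos = x - 1L)
        if (y < n) roles[[length(roles) + 1L]] <- list(pair = r, side = "d3", pos = y + 1L)
      }
    }
    pos <- vapply(roles, `[[`, 0L, "pos")
    paired_here <- target$pair_table[pos] != 0L
    vars <- sort(unique(pos[!paired_here]))
    dangles <- data.frame(
      pair = vapply(roles, `[[`, 0L, "pair"),
      side = vapply(roles, `[[`, "", "side"),
      pos = pos,
      bound_paired = paired_here,
      var = ifelse(paired_here, NA_integer_, match(pos, vars))
    )
    list(pairs = mem, closing_member = closing_member,
         dangles = dangles, vars = vars)
  })
}

#' Render a target structure back to dot-bracket notation
#'
#' @param target an `rna_target`.
#' @return the dot-bracket string.
#' @export
format_dotbracket <- function(target) {
  stopifnot(inherits(target, "rna_target"))
  ch <- rep(".", target$n)
  ch[target$pairs[, 1L]] <- "("
  ch[target$pairs[, 2L]] <- ")"
  paste(ch, collapse = "")
}

#' @export
print.rna_target <- function(x, ...) {
  cat("RNA target structure, n =", x$n, "\n")
  cat(" ", x$db, "\n")
  if (x$iupac != strrep("N", x$n)) cat(" ", x$iupac, "\n")
  kinds <- vapply(x$loops, `[[`, "", "kind")
  cat(sprintf("  %d base pairs; loops: %s\n", nrow(x$pairs),
              paste(sprintf("%s=%d", names(table(kinds)), table(kinds)),
                    collapse = ", ")))
  invisible(x)
}

#' Read a target record from a file
#'
#' Accepts either a bare dot-bracket line or a FASTA-like record: a `>name`
#' header, the structure line, and an optional IUPAC constraint line.
#'
#' @param path file path.
#' @return an `rna_target`.
#' @export
read_target <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty target file: ", path)
  if (startsWith(lines[1L], ">")) lines <- lines[-1L]
  parse_target(lines[1L], if (length(lines) >= 2L) lines[2L] else NULL)
}
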