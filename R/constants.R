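# Nucleotide and base-pair codings shared across the package.
# Nucleotides are coded 1..4 = A, C, G, U.  Canonical pairs are listed in the
# fixed order AU, CG, GC, UA, GU, UG; this order is used for every
# pair-indexed table, for printed per-pair columns, and for the roulette
# scan order of the sampler.

NT_LETTERS <- c("A", "C", "G", "U")

PAIR_NAMES <- c("AU", "CG", "GC", "UA", "GU", "UG")

# row r = (5' nucleotide, 3' nucleotide) of pair r
PAIR_NT <- matrix(c(1L, 4L,   # AU
                    2L, 3L,   # CG
                    3L, 2L,   # GC
                    4L, 1L,   # UA
                    3L, 4L,   # GU
                    4L, 3L),  # UG
                  ncol = 2L, byrow = TRUE,
                  dimnames = list(PAIR_NAMES, c("i", "j")))

# PAIR_CODE[x, y] = pair index of nucleotides (x, y), 0 if non-canonical
PAIR_CODE <- matrix(0L, 4L, 4L, dimnames = list(NT_LETTERS, NT_LETTERS))
for (r in seq_len(6L)) PAIR_CODE[PAIR_NT[r, 1L], PAIR_NT[r, 2L]] <- r

# index of the reversed pair: AU<->UA, CG<->GC, GU<->UG
PAIR_REV <- c(4L, 3L, 2L, 1L, 6L, 5L)

# GC-count contributed by a single nucleotide / by a pair
NT_GC <- c(0L, 1L, 1L, 0L)
PAIR_GC <- NT_GC[PAIR_NT[, 1L]] + NT_GC[PAIR_NT[, 2L]]

# IUPAC ambiguity codes -> allowed nucleotide subsets of {A,C,G,U}
IUPAC_SETS <- list(
  A = 1L, C = 2L, G = 3L, U = 4L, T = 4L,
  R = c(1L, 3L), Y = c(2L, 4L), S = c(2L, 3L), W = c(1L, 4L),
  K = c(3L, 4L), M = c(1L, 2L),
  B = c(2L, 3L, 4L), D = c(1L, 3L, 4L), H = c(1L, 2L, 4L),
  V = c(1L, 2L, 3L), N = c(1L, 2L, 3L, 4L)
)

# minimum number of unpaired nucleotides in a hairpin (steric floor)
THETA <- 3L

nt_to_int <- function(x) {
  v <- match(strsplit(toupper(x), "")[[1L]], NT_LETTERS)
  if (anyNA(v)) stop("sequence contains letters outside {A,C,G,U}: ", x)
  v
}

int_to_nt <- function(v) paste(NT_LETTERS[v], collapse = "")
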