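# Independent oracles and small generators used across the suite.

AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Free amino-acid formulas, frozen from the standard table (verified against
# an independent cheminformatics formula routine before freezing).
FREE_AA_FORMULA <- list(
  A = c(C = 3L, H = 7L, N = 1L, O = 2L),
  R = c(C = 6L, H = 14L, N = 4L, O = 2L),
  N = c(C = 4L, H = 8L, N = 2L, O = 3L),
  D = c(C = 4L, H = 7L, N = 1L, O = 4L),
  C = c(C = 3L, H = 7L, N = 1L, O = 2L, S = 1L),
  E = c(C = 5L, H = 9L, N = 1L, O = 4L),
  Q = c(C = 5L, H = 10L, N = 2L, O = 3L),
  G = c(C = 2L, H = 5L, N = 1L, O = 2L),
  H = c(C = 6L, H = 9L, N = 3L, O = 2L),
  I = c(C = 6L, H = 13L, N = 1L, O = 2L),
  L = c(C = 6L, H = 13L, N = 1L, O = 2L),
  K = c(C = 6L, H = 14L, N = 2L, O = 2L),
  M = c(C = 5L, H = 11L, N = 1L, O = 2L, S = 1L),
  F = c(C = 9L, H = 11L, N = 1L, O = 2L),
  P = c(C = 5L, H = 9L, N = 1L, O = 2L),
  S = c(C = 3L, H = 7L, N = 1L, O = 3L),
  T = c(C = 4L, H = 9L, N = 1L, O = 3L),
  W = c(C = 11L, H = 12L, N = 2L, O = 2L),
  Y = c(C = 9L, H = 11L, N = 1L, O = 3L),
  V = c(C = 5L, H = 11L, N = 1L, O = 2L)
)

# Residue-arithmetic oracle: sum of free formulas minus (L - 1) waters.
oracle_peptide_formula <- function(sequence) {
  codes <- strsplit(sequence, "")[[1]]
  total <- c(C = 0L, H = 0L, N = 0L, O = 0L, S = 0L)
  for (code in codes) {
    f <- FREE_AA_FORMULA[[code]]
    total[names(f)] <- total[names(f)] + f
  }
  L <- length(codes)
  total[["H"]] <- total[["H"]] - 2L * (L - 1L)
  total[["O"]] <- total[["O"]] - (L - 1L)
  total[total > 0L]
}

expect_formula_equal <- function(got, want) {
  got <- got[order(names(got))]
  want <- want[order(names(want))]
  expect_identical(as.integer(got), as.integer(want),
                   label = paste(names(got), got, collapse = " "))
  expect_identical(names(got), names(want))
}

# Exhaustive sliding-window motif oracle.
oracle_scan <- function(sequence, pattern) {
  sc <- strsplit(sequence, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  L <- length(sc)
  k <- length(pc)
  if (k > L) return(integer(0))
  hits <- integer(0)
  for (o in seq_len(L - k + 1L)) {
    window <- sc[o:(o + k - 1L)]
    if (all(pc == "X" | pc == window)) hits <- c(hits, o)
  }
  hits
}

random_sequence <- function(length = 12L) {
  paste(sample(AA20, length, replace = TRUE), collapse = "")
}

random_cx10c <- function() {
  paste0("C", paste(sample(AA20, 10L, replace = TRUE), collapse = ""), "C")
}
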