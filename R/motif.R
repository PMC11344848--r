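# Motif scanning and sequence-logo analytics for selection outputs. Motif
# patterns are strings over the 20 residue letters plus the wildcard X;
# match offsets are 1-based inclusive (peptide-literature convention).

#' Built-in motif patterns
#'
#' `motif_hpq()` returns the two canonical linear streptavidin-binding
#' tripeptide motifs, HPQ and HPM, scanned separately and reported jointly.
#' `motif_cyclic_consensus()` is the 12-position consensus of the cyclized
#' binders: C and P fixed at positions 1-2, N at 4, P at 8, C at 12,
#' wildcards elsewhere (CPXNXXXPXXXC).
#'
#' @return Character vector of pattern strings.
#' @export
motif_hpq <- function() c("HPQ", "HPM")

#' @rdname motif_hpq
#' @export
motif_cyclic_consensus <- function() "CPXNXXXPXXXC"

check_pattern <- function(pattern) {
  if (length(pattern) != 1L || is.na(pattern) || !nzchar(pattern)) {
    abort("`pattern` must be a single non-empty string")
  }
  pattern <- toupper(pattern)
  bad <- setdiff(strsplit(pattern, "")[[1]], c(AA_CODES, "X"))
  if (length(bad)) {
    abort(sprintf("invalid pattern symbol(s): %s (use residue letters or X)",
                  paste(unique(bad), collapse = ", ")))
  }
  pattern
}

#' Scan a sequence for a motif pattern
#'
#' Reports every offset (1-based) where the pattern matches: fixed letters
#' must equal the sequence residue, `X` matches any residue, and overlapping
#' matches are all reported. A pattern longer than the sequence yields an
#' empty result.
#'
#' @param sequence One-letter residue string.
#' @param pattern Motif string over residue letters and `X`.
#' @return Integer vector of match offsets (possibly empty).
#' @examples
#' scan_motif("AHPQA", "HPQ")
#' scan_motif("CPANAAAPAAAC", motif_cyclic_consensus())
#' @export
scan_motif <- function(sequence, pattern) {
  sequence <- check_sequence(sequence)
  pattern <- check_pattern(pattern)
  if (nchar(pattern) > nchar(sequence)) return(integer(0))
  rx <- paste0("(?=", gsub("X", ".", pattern, fixed = TRUE), ")")
  hits <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits)
}

#' Does a sequence carry the cyclic-binder consensus?
#'
#' `TRUE` iff the sequence is a 12-mer matching CPXNXXXPXXXC from position 1
#' (C1, P2, N4, P8, C12 fixed).
#'
#' @param sequence One-letter residue string.
#' @return Logical flag.
#' @export
matches_consensus <- function(sequence) {
  sequence <- check_sequence(sequence)
  nchar(sequence) == 12L && 1L %in% scan_motif(sequence, motif_cyclic_consensus())
}

#' Deduplicate a peptide panel
#'
#' Keeps the first occurrence of each distinct residue string, preserving
#' order. The number of unique sequences is `nrow()` of the result (also
#' attached as attribute `n_unique`).
#'
#' @param panel A panel (see [as_panel()]).
#' @return The deduplicated panel tibble.
#' @export
unique_sequences <- function(panel) {
  panel <- as_panel(panel)
  out <- panel[!duplicated(panel$sequence), ]
  attr(out, "n_unique") <- nrow(out)
  out
}

#' Position frequency matrix of an aligned panel
#'
#' @param panel A nonempty panel of equal-length sequences.
#' @return A `pfm`: 20 x L integer matrix of residue counts (rows = residue
#'   letters, columns = positions), with attribute `n_sequences`. Every
#'   column sums to the panel size.
#' @export
build_pfm <- function(panel) {
  panel <- as_panel(panel)
  if (nrow(panel) == 0L) abort("cannot build a PFM from an empty panel")
  lens <- nchar(panel$sequence)
  if (length(unique(lens)) != 1L) {
    off <- panel$id[lens != lens[1]]
    abort(sprintf("sequences must share one length; offending ids: %s",
                  paste(off, collapse = ", ")))
  }
  L <- lens[1]
  chars <- do.call(rbind, strsplit(panel$sequence, ""))
  counts <- vapply(seq_len(L), function(p) {
    as.integer(table(factor(chars[, p], levels = AA_CODES)))
  }, integer(length(AA_CODES)))
  dimnames(counts) <- list(AA_CODES, seq_len(L))
  structure(counts, class = c("pfm", "matrix"), n_sequences = nrow(panel))
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> %d positions, %d sequences\n",
              ncol(x), attr(x, "n_sequences")))
  print(unclass(x)[rowSums(x) > 0, , drop = FALSE])
  invisible(x)
}

#' @rdname build_pfm
#' @param x A `pfm`.
#' @param ... Unused.
#' @return `tidy()` returns a long tibble (`position`, `residue`, `count`,
#'   `frequency`).
#' @export
tidy.pfm <- function(x, ...) {
  n <- attr(x, "n_sequences")
  df <- as_tibble(as.table(unclass(x)), .name_repair = "minimal")
  names(df) <- c("residue", "position", "count")
  df$position <- as.integer(as.character(df$position))
  df$count <- as.integer(df$count)
  df$frequency <- df$count / n
  dplyr::arrange(df[c("position", "residue", "count", "frequency")],
                 .data$position, .data$residue)
}

#' Information content per logo column
#'
#' `IC(p) = log2(20) - H(p)` with `H` the Shannon entropy (bits) of the
#' column's residue frequencies. The WebLogo-style small-sample correction
#' `e_n = 19 / (2 ln(2) n)` is off by default.
#'
#' @param pfm A `pfm`.
#' @param small_sample_correction Subtract the small-sample correction
#'   (results are floored at 0).
#' @return A tibble (`position`, `entropy`, `ic`) with `ic` in
#'   \[0, log2(20)\] bits.
#' @export
information_content <- function(pfm, small_sample_correction = FALSE) {
  stopifnot(inherits(pfm, "pfm"))
  n <- attr(pfm, "n_sequences")
  ent <- apply(unclass(pfm), 2, function(col) {
    p <- col / n
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  ic <- log2(20) - ent
  if (small_sample_correction) {
    ic <- pmax(0, ic - 19 / (2 * log(2) * n))
  }
  tibble(position = seq_len(ncol(pfm)), entropy = unname(ent), ic = unname(ic))
}

#' Consensus pattern from a position frequency matrix
#'
#' Position p emits residue r if `freq(r, p) >= threshold`, else the
#' wildcard `X`. Thresholds at or below 0.5 are rejected because two
#' residues could then tie.
#'
#' @param pfm A `pfm`.
#' @param threshold Fraction in (0.5, 1].
#' @return Consensus pattern string (residue letters and `X`).
#' @export
consensus_string <- function(pfm, threshold = 0.9) {
  stopifnot(inherits(pfm, "pfm"))
  if (threshold <= 0.5 || threshold > 1) {
    abort("`threshold` must be in (0.5, 1] so the winning residue is unique")
  }
  n <- attr(pfm, "n_sequences")
  out <- apply(unclass(pfm), 2, function(col) {
    w <- which(col / n >= threshold)
    if (length(w) == 1L) rownames(pfm)[w] else "X"
  })
  paste(out, collapse = "")
}

#' @rdname build_pfm
#' @param object A `pfm`.
#' @export
autoplot.pfm <- function(object, ...) {
  freq <- tidy(object)
  ic <- information_content(object)
  df <- dplyr::left_join(freq, ic, by = "position")
  df$height <- df$frequency * df$ic
  df <- df[df$height > 0, ]
  df <- dplyr::arrange(df, .data$position, .data$height)
  df <- dplyr::mutate(dplyr::group_by(df, .data$position),
                      ymax = cumsum(.data$height),
                      ymin = .data$ymax - .data$height)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = (.data$ymin + .data$ymax) / 2,
                                   label = .data$residue,
                                   size = .data$height)) +
    ggplot2::geom_text(ggplot2::aes(colour = .data$residue),
                       show.legend = FALSE) +
    ggplot2::scale_size_continuous(range = c(1, 8), guide = "none") +
    ggplot2::scale_x_continuous(breaks = unique(df$position)) +
    ggplot2::labs(x = "position", y = "information (bits)") +
    ggplot2::theme_minimal()
}
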