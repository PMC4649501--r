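AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a degenerate residue-class motif
#'
#' A motif is an ordered list of allowed-residue sets, one per position;
#' `"*"` (or `NULL`) denotes a wildcard position matching any amino acid.
#'
#' @param positions A list of character vectors of one-letter codes (or
#'   `"*"` for a wildcard).
#' @param name Motif name.
#' @return A `pef_motif` object.
#' @export
motif_pattern <- function(positions, name = "motif") {
  positions <- lapply(positions, function(p) {
    if (is.null(p) || identical(p, "*")) return(AA_ALPHABET)
    p <- toupper(p)
    bad <- setdiff(p, AA_ALPHABET)
    if (length(bad) > 0) {
      abort(paste0("invalid residue code(s) in motif: ", paste(bad, collapse = ", ")))
    }
    if (length(p) == 0) abort("motif position has empty residue set")
    p
  })
  structure(list(positions = positions, name = name), class = "pef_motif")
}

#' @export
print.pef_motif <- function(x, ...) {
  cat(sprintf("# pef_motif '%s', %d positions\n", x$name, length(x$positions)))
  for (i in seq_along(x$positions)) {
    p <- x$positions[[i]]
    cat(sprintf("  %d: %s\n", i,
                if (length(p) == length(AA_ALPHABET)) "x (any)"
                else paste(p, collapse = "")))
  }
  invisible(x)
}

#' Built-in Sorcin-binding consensus motifs
#'
#' Two degenerate motifs recovered from phage-display selections against
#' Sorcin:
#' \describe{
#'   \item{`phi_gm_x_p`}{The relaxed Phi/Gly/Met-Phi/Gly/Met-x-P motif:
#'     positions 1-2 an aromatic residue (Trp, Tyr, Phe) or Gly or Met,
#'     position 3 any residue, position 4 proline. This matches the GYYP of
#'     Sorcin's own N-terminal GYYPGG peptide.}
#'   \item{`acidic_phi`}{An acidic residue (Asp/Glu) followed by an
#'     aromatic (Trp/Tyr/Phe); the aromatic set is configurable via
#'     [motif_pattern()] if a wider Phi definition is wanted.}
#' }
#'
#' @return A named list of two `pef_motif` objects.
#' @export
builtin_patterns <- function() {
  list(
    phi_gm_x_p = motif_pattern(
      list(c("W", "Y", "F", "G", "M"), c("W", "Y", "F", "G", "M"),
           "*", "P"),
      name = "Phi/Gly/Met-Phi/Gly/Met-x-P"),
    acidic_phi = motif_pattern(
      list(c("D", "E"), c("W", "Y", "F")),
      name = "acidic-Phi"))
}

#' Scan a sequence for motif matches
#'
#' All (overlapping) window matches, left to right, 1-based start positions.
#'
#' @param seq An amino-acid string (uppercase one-letter codes).
#' @param pattern A `pef_motif`.
#' @return A tibble: `start`, `match`. Zero rows when the sequence is
#'   shorter than the pattern or carries no hit.
#' @export
scan_motif <- function(seq, pattern) {
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0) {
    abort(sprintf("invalid residue '%s' at position %d", chars[bad[1]], bad[1]))
  }
  L <- length(pattern$positions)
  n <- length(chars)
  if (n < L || L == 0) return(tibble(start = integer(), match = character()))
  ok <- vapply(seq_len(n - L + 1), function(s) {
    all(vapply(seq_len(L), function(k) {
      chars[s + k - 1] %in% pattern$positions[[k]]
    }, logical(1)))
  }, logical(1))
  starts <- which(ok)
  tibble(start = starts,
         match = vapply(starts, function(s) {
           paste(chars[s:(s + L - 1)], collapse = "")
         }, character(1)))
}

#' Strip phage-display vector linkers from peptide sequences
#'
#' Removes the library's vector-derived flanking linkers (N-terminal
#' `SSSG`, C-terminal `GGGSGG` by default) when present; they are not part
#' of the selected peptide.
#'
#' @param sequences Character vector of peptide sequences.
#' @param five,three Linker sequences to strip.
#' @return Character vector of stripped sequences.
#' @export
strip_linkers <- function(sequences, five = "SSSG", three = "GGGSGG") {
  out <- sub(paste0("^", five), "", toupper(sequences))
  sub(paste0(three, "$"), "", out)
}

#' Position frequency matrix of a peptide set
#'
#' In `anchor = NULL` mode, sequences must share one length and are counted
#' column-wise. In motif-anchored mode each sequence is aligned on its first
#' hit of the anchor motif and counts are taken over the motif window;
#' sequences without a hit are dropped (and reported via the `dropped`
#' attribute).
#'
#' @param sequences Character vector of peptide sequences.
#' @param anchor Optional `pef_motif` to align on.
#' @param unique_only Deduplicate identical sequences before counting
#'   (default `TRUE`, matching the convention of counting unique clones).
#' @param pseudocount Added to every cell (default 0).
#'
#' @return A `pef_pfm`: list with `counts` (20 x L matrix, rows the amino
#'   acids), `n_sequences`, `pseudocount`.
#' @export
build_pfm <- function(sequences, anchor = NULL, unique_only = TRUE,
                      pseudocount = 0) {
  if (length(sequences) == 0) abort("no sequences")
  sequences <- toupper(sequences)
  if (unique_only) sequences <- unique(sequences)
  dropped <- character(0)
  if (!is.null(anchor)) {
    L <- length(anchor$positions)
    windows <- vapply(sequences, function(s) {
      hits <- scan_motif(s, anchor)
      if (nrow(hits) == 0) return(NA_character_)
      hits$match[1]
    }, character(1))
    dropped <- sequences[is.na(windows)]
    aligned <- windows[!is.na(windows)]
    if (length(aligned) == 0) abort("no sequence contains the anchor motif")
  } else {
    lens <- nchar(sequences)
    if (length(unique(lens)) > 1) {
      abort("sequences of unequal length; supply an anchor motif")
    }
    aligned <- sequences
    L <- lens[1]
  }
  counts <- matrix(pseudocount, nrow = length(AA_ALPHABET), ncol = L,
                   dimnames = list(AA_ALPHABET, NULL))
  for (s in aligned) {
    ch <- strsplit(s, "")[[1]]
    for (k in seq_len(L)) counts[ch[k], k] <- counts[ch[k], k] + 1
  }
  structure(list(counts = counts, n_sequences = length(aligned),
                 pseudocount = pseudocount, dropped = dropped),
            class = "pef_pfm")
}

#' @export
print.pef_pfm <- function(x, ...) {
  cat(sprintf("# pef_pfm: %d positions, %d sequences\n",
              ncol(x$counts), x$n_sequences))
  print(pfm_consensus(x))
  invisible(x)
}

#' Per-position consensus (argmax) of a PFM
#'
#' @param pfm A `pef_pfm`.
#' @return Character vector of the most frequent residue per position.
#' @export
pfm_consensus <- function(pfm) {
  rownames(pfm$counts)[apply(pfm$counts, 2, which.max)]
}

#' Tidy a PFM into long form
#'
#' @param x A `pef_pfm`.
#' @param ... Unused.
#' @return A tibble: `position`, `residue`, `count`, `frequency`.
#' @export
tidy.pef_pfm <- function(x, ...) {
  cs <- colSums(x$counts)
  tibble(position = rep(seq_len(ncol(x$counts)), each = nrow(x$counts)),
         residue = rep(rownames(x$counts), ncol(x$counts)),
         count = as.numeric(x$counts),
         frequency = as.numeric(sweep(x$counts, 2, pmax(cs, 1e-12), `/`)))
}

#' Per-condition motif prevalence
#'
#' The fraction of sequences in each condition carrying at least one motif
#' hit -- the quantity used to ask whether a binding mode is
#' calcium-dependent in phage-display selections run in parallel under
#' calcium and EDTA.
#'
#' @param peptides A tibble with columns `sequence` and `condition`.
#' @param pattern A `pef_motif`.
#' @param unique_only Deduplicate sequences within each condition first.
#' @return A tibble: `condition`, `n`, `n_hits`, `fraction`.
#' @export
condition_enrichment <- function(peptides, pattern, unique_only = TRUE) {
  peptides <- as_tibble(peptides)
  if (nrow(peptides) == 0) abort("empty peptide table")
  peptides |>
    group_by(.data$condition) |>
    summarise(n = if (unique_only) dplyr::n_distinct(.data$sequence) else n(),
              n_hits = sum(vapply(
                if (unique_only) unique(.data$sequence) else .data$sequence,
                function(s) nrow(scan_motif(s, pattern)) > 0, logical(1))),
              .groups = "drop") |>
    mutate(fraction = .data$n_hits / .data$n)
}

#' Information-content sequence logo of a PFM
#'
#' WebLogo-convention stack heights: each column carries
#' `log2(20) - H(column)` bits shared among residues by frequency.
#'
#' @param pfm A `pef_pfm`.
#' @return A ggplot object.
#' @export
plot_logo <- function(pfm) {
  td <- tidy(pfm)
  td <- td[td$frequency > 0, ]
  ic <- td |>
    group_by(.data$position) |>
    summarise(h = -sum(.data$frequency * log2(.data$frequency)),
              .groups = "drop") |>
    mutate(ic = log2(20) - .data$h)
  td <- left_join(td, ic, by = "position") |>
    mutate(bits = .data$frequency * .data$ic) |>
    group_by(.data$position) |>
    arrange(.data$bits, .by_group = TRUE) |>
    mutate(ytop = cumsum(.data$bits), ymid = .data$ytop - .data$bits / 2) |>
    ungroup()
  ggplot2::ggplot(td, ggplot2::aes(x = .data$position, y = .data$ymid)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$residue,
                                    size = .data$bits,
                                    colour = .data$residue),
                       show.legend = FALSE) +
    ggplot2::scale_size_continuous(range = c(1, 10)) +
    ggplot2::scale_x_continuous(breaks = unique(td$position)) +
    ggplot2::labs(x = "position", y = "bits") +
    ggplot2::theme_minimal()
}
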