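# Kinase consensus-motif scanning of phosphosite flanking windows.
# Motifs are degenerate patterns over positions -6..+6 around the
# phosphosite (13 tokens: a residue, a bracketed residue set, or the '.'
# wildcard); matching is per-position set membership, with terminal '-'
# padding matching nothing except the wildcard.

.MOTIF_K <- 6L  # half-width; window length 2k + 1 = 13

.parse_motif_pattern <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  tokens <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1]
      if (is.na(j) || j == i + 1L) stop("malformed pattern: ", pattern)
      tokens[[length(tokens) + 1L]] <- chars[(i + 1L):(j - 1L)]
      i <- j + 1L
    } else if (ch == ".") {
      tokens[[length(tokens) + 1L]] <- NULL_TOKEN
      i <- i + 1L
    } else if (ch %in% names(.AA_MONO)) {
      tokens[[length(tokens) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("malformed pattern character '", ch, "' in: ", pattern)
    }
  }
  if (length(tokens) != 2L * .MOTIF_K + 1L) {
    stop("pattern must have exactly ", 2L * .MOTIF_K + 1L,
         " positions (-6..+6): ", pattern)
  }
  center <- tokens[[.MOTIF_K + 1L]]
  if (identical(center, NULL_TOKEN) || !all(center %in% c("S", "T", "Y"))) {
    stop("pattern anchor (position 0) must be restricted to S/T/Y: ", pattern)
  }
  tokens
}

NULL_TOKEN <- "."  # wildcard marker inside parsed token lists

#' Read a kinase consensus-motif library
#'
#' One motif per line, `KINASE<TAB>pattern`, where the pattern spells 13
#' positions (-6..+6 around the phosphosite) as single residues, bracketed
#' residue sets like `[ST]`, or `.` wildcards. Lines starting with `#` are
#' comments. The packaged default library
#' (`system.file("extdata", "kinase_motifs.tsv", package = "triplexquant")`)
#' carries literature consensus patterns for CK2, CK1, PKA, GSK3 and the
#' proline-directed p38 MAPK / JNK / CDK class.
#'
#' @param path Library file (default: the packaged library).
#' @return List of motifs, each a list with `kinase` and `tokens` (13
#'   parsed position tokens).
#' @export
read_kinase_motifs <- function(path = system.file("extdata", "kinase_motifs.tsv",
                                                  package = "triplexquant")) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed motif line: ", ln)
    list(kinase = parts[1], pattern = parts[2],
         tokens = .parse_motif_pattern(parts[2]))
  })
}

#' Extract the flanking window around a phosphosite
#'
#' @param sequence Protein sequence.
#' @param position 1-based residue number of the phosphosite (must be
#'   S, T or Y).
#' @param k Half-width of the window (default 6, giving 13 residues).
#' @return Character window of length `2k + 1` with position 0 at the
#'   center; positions beyond the protein termini are padded with `-`.
#' @examples
#' extract_flank("MSAP", 2, k = 2)  # "-MSAP"
#' @export
extract_flank <- function(sequence, position, k = .MOTIF_K) {
  chars <- .check_sequence(sequence, "protein sequence")
  if (position < 1 || position > length(chars)) {
    stop("position outside protein")
  }
  if (!chars[position] %in% c("S", "T", "Y")) {
    stop("site error: residue at position ", position, " is '",
         chars[position], "', not S/T/Y")
  }
  idx <- (position - k):(position + k)
  win <- ifelse(idx >= 1L & idx <= length(chars), chars[pmax(pmin(idx, length(chars)), 1L)], "-")
  paste(win, collapse = "")
}

#' Scan flanking windows against a kinase motif library
#'
#' A kinase hits a window iff at every non-wildcard pattern position the
#' window residue belongs to the pattern's residue set; `-` padding never
#' matches a non-wildcard position. Several kinases may hit one window.
#'
#' @param windows Character vector of 13-residue flanking windows.
#' @param library Motif library from [read_kinase_motifs()].
#' @return Data frame with columns `window_index`, `window`, `kinase`,
#'   one row per (window, kinase) hit.
#' @export
scan_kinase_motifs <- function(windows, library = read_kinase_motifs()) {
  if (!length(library)) stop("motif library is empty")
  wlen <- 2L * .MOTIF_K + 1L
  if (any(nchar(windows) != wlen)) {
    stop("all windows must have length ", wlen)
  }
  wmat <- do.call(rbind, strsplit(windows, "", fixed = TRUE))
  hits <- list()
  for (m in library) {
    ok <- rep(TRUE, length(windows))
    for (p in seq_len(wlen)) {
      tok <- m$tokens[[p]]
      if (identical(tok, NULL_TOKEN)) next
      ok <- ok & wmat[, p] %in% tok
    }
    if (any(ok)) {
      hits[[length(hits) + 1L]] <- data.frame(
        window_index = which(ok),
        window = windows[ok],
        kinase = m$kinase
      )
    }
  }
  if (!length(hits)) {
    return(data.frame(window_index = integer(), window = character(),
                      kinase = character()))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$window_index, out$kinase), ]
  rownames(out) <- NULL
  out
}

#' Summarize kinase hits over all accepted sites
#'
#' @param hits Hit table from [scan_kinase_motifs()].
#' @param n_sites Total number of scanned sites (denominator of the
#'   fractions; one site may be hit by several kinases, so fractions may
#'   sum above one).
#' @param library Motif library (kinases with zero hits are still listed).
#' @return Data frame `kinase`, `n_sites_hit`, `fraction`, ordered by
#'   descending count then kinase name.
#' @export
kinase_summary <- function(hits, n_sites, library = read_kinase_motifs()) {
  kinases <- vapply(library, `[[`, character(1), "kinase")
  counts <- stats::setNames(integer(length(kinases)), kinases)
  if (nrow(hits)) {
    tab <- table(hits$kinase[!duplicated(paste(hits$window_index, hits$kinase))])
    counts[names(tab)] <- as.integer(tab)
  }
  out <- data.frame(
    kinase = names(counts),
    n_sites_hit = as.integer(counts),
    fraction = if (n_sites > 0) as.numeric(counts) / n_sites else 0
  )
  out <- out[order(-out$n_sites_hit, out$kinase), ]
  rownames(out) <- NULL
  out
}
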