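# Mass constants (monoisotopic, Da). Residue masses are the standard
# amino-acid residue table; water/proton/HPO3 from elemental composition.

.AA_MONO <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

.MASS_WATER <- 18.010565
.MASS_PROTON <- 1.007276
.MASS_PHOSPHO <- 79.966331   # HPO3
.MASS_CAM <- 57.021464       # carbamidomethyl (iodoacetamide), fixed on Cys

.check_sequence <- function(sequence, what = "sequence") {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    stop("empty ", what, ": a non-empty amino-acid string is required")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(.AA_MONO))
  if (length(bad)) {
    stop("unknown residue(s) in ", what, ": ", paste(unique(bad), collapse = ", "))
  }
  invisible(chars)
}

#' Triplex dimethyl label channels
#'
#' The three isotopic dimethyl channels used in triplex labeling. Reductive
#' amination converts every peptide primary amine (the alpha-amine of the
#' N-terminus and each lysine epsilon-amine) into a dimethylamine. With
#' CH2O/NaBH3CN the added composition per amine is C2H4 (light, nominally
#' +28 Da); with CD2O/NaBH3CN it is C2D4 (intermediate, +32 Da); with
#' 13CD2O/NaBD3CN it is 13C2D6 - H2 (heavy, +36 Da). Adjacent channels
#' therefore differ by a nominal 4 Da per labeled amine.
#'
#' @return A data frame with one row per channel and columns `name`
#'   (`light`, `intermediate`, `heavy`), `per_site_delta` (exact
#'   monoisotopic mass added per labeled amine, Da) and `nominal_delta`
#'   (integer Da).
#' @examples
#' label_channels()
#' @export
label_channels <- function() {
  data.frame(
    name = c("light", "intermediate", "heavy"),
    per_site_delta = c(28.031300, 32.056407, 36.075670),
    nominal_delta = c(28L, 32L, 36L)
  )
}

.channel_row <- function(channel) {
  ch <- label_channels()
  i <- match(channel, ch$name)
  if (is.na(i)) {
    stop("unknown label channel '", channel,
         "'; expected one of: ", paste(ch$name, collapse = ", "))
  }
  ch[i, ]
}

#' In silico tryptic digestion of a protein
#'
#' Cleaves after lysine (K) or arginine (R), suppressing cleavage when the
#' following residue is proline (the usual Mascot-style trypsin rule), and
#' emits every contiguous run of at most `max_missed + 1` fragments, so each
#' peptide carries its missed-cleavage count.
#'
#' @param sequence Protein amino-acid sequence (single string, canonical
#'   20-letter alphabet).
#' @param protein_id Identifier copied into the output rows.
#' @param max_missed Maximum number of missed cleavages (default 2).
#' @return A data frame with columns `protein_id`, `sequence`, `start`
#'   (0-based offset of the peptide within the protein) and
#'   `missed_cleavages`.
#' @examples
#' digest_protein("AKGR", max_missed = 1)
#' @export
digest_protein <- function(sequence, protein_id = "", max_missed = 2L) {
  chars <- .check_sequence(sequence, "protein sequence")
  if (max_missed < 0) stop("max_missed must be >= 0")
  n <- length(chars)
  # cleavage after position i when chars[i] in {K,R} and chars[i+1] != P
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | chars[pmin(cut_after + 1L, n)] != "P"]
  starts <- c(1L, cut_after[cut_after < n] + 1L)
  ends <- c(cut_after[cut_after < n], n)
  nfrag <- length(starts)
  out <- vector("list", nfrag)
  for (i in seq_len(nfrag)) {
    jmax <- min(nfrag, i + max_missed)
    js <- i:jmax
    out[[i]] <- data.frame(
      protein_id = protein_id,
      sequence = vapply(js, function(j) {
        paste(chars[starts[i]:ends[j]], collapse = "")
      }, character(1)),
      start = starts[i] - 1L,
      missed_cleavages = js - i
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Digest every protein of a proteome
#'
#' @param proteome Data frame with columns `id` and `sequence` (e.g. from
#'   [read_fasta()] or [generate_proteome()]).
#' @inheritParams digest_protein
#' @return Row-bound [digest_protein()] results for all proteins.
#' @export
digest_proteome <- function(proteome, max_missed = 2L) {
  stopifnot(is.data.frame(proteome), all(c("id", "sequence") %in% names(proteome)))
  res <- lapply(seq_len(nrow(proteome)), function(i) {
    digest_protein(proteome$sequence[i], proteome$id[i], max_missed)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Number of dimethyl-labelable sites of a peptide
#'
#' One site for the peptide N-terminal alpha-amine plus one per lysine
#' epsilon-amine.
#'
#' @param sequence Peptide sequence(s); vectorized.
#' @return Integer vector of label-site counts.
#' @examples
#' count_label_sites(c("SAMTLER", "AKTK"))
#' @export
count_label_sites <- function(sequence) {
  vapply(sequence, function(s) {
    .check_sequence(s, "peptide sequence")
    1L + sum(strsplit(s, "", fixed = TRUE)[[1]] == "K")
  }, integer(1), USE.NAMES = FALSE)
}

#' Total label mass shift for a channel
#'
#' @param channel One of `"light"`, `"intermediate"`, `"heavy"`.
#' @param n_sites Number of labeled amines (>= 1).
#' @param nominal If `TRUE`, use the integer nominal per-site shifts
#'   (28/32/36 Da) instead of the exact monoisotopic ones.
#' @return Mass shift in Da (`n_sites * per_site_delta`).
#' @examples
#' channel_shift("light", 1, nominal = TRUE)   # 28
#' channel_shift("heavy", 2)                   # 72.15134
#' @export
channel_shift <- function(channel, n_sites, nominal = FALSE) {
  if (any(n_sites < 1)) stop("n_sites must be >= 1")
  row <- .channel_row(channel)
  delta <- if (nominal) as.numeric(row$nominal_delta) else row$per_site_delta
  n_sites * delta
}

#' Monoisotopic mass of a (modified, labeled) peptide
#'
#' Sum of residue monoisotopic masses plus water, fixed modifications
#' (default: carbamidomethyl on every cysteine), +79.966331 Da per
#' phosphosite, and the dimethyl channel shift over all labelable amines.
#'
#' @param sequence Peptide sequence.
#' @param channel Label channel name, or `NULL` for an unlabeled peptide.
#' @param n_phospho Number of phospho groups carried (default 0).
#' @param fixed_mods Named numeric vector of per-residue fixed-modification
#'   mass deltas (default `c(C = 57.021464)`).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mono_mass("G")                      # 75.032029
#' peptide_mono_mass("SAMTLER", "light")
#' @export
peptide_mono_mass <- function(sequence, channel = NULL, n_phospho = 0L,
                              fixed_mods = c(C = .MASS_CAM)) {
  chars <- .check_sequence(sequence, "peptide sequence")
  if (n_phospho < 0) stop("n_phospho must be >= 0")
  m <- sum(.AA_MONO[chars]) + .MASS_WATER + n_phospho * .MASS_PHOSPHO
  if (length(fixed_mods)) {
    for (res in names(fixed_mods)) {
      m <- m + sum(chars == res) * fixed_mods[[res]]
    }
  }
  if (!is.null(channel)) {
    m <- m + channel_shift(channel, count_label_sites(sequence))
  }
  unname(m)
}

#' m/z of a neutral mass at a given charge
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge state.
#' @return `(mass + charge * proton) / charge`.
#' @examples
#' mz_of(1000, 2)
#' @export
mz_of <- function(mass, charge) {
  if (any(charge < 1)) stop("charge must be >= 1")
  (mass + charge * .MASS_PROTON) / charge
}

#' Read a protein or DNA FASTA file into a data frame
#'
#' @param path FASTA file path.
#' @param type `"AA"` (default) or `"DNA"`.
#' @return Data frame with columns `id` (first whitespace-delimited token of
#'   the header) and `sequence`.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") {
    Biostrings::readAAStringSet(path)
  } else {
    Biostrings::readDNAStringSet(path)
  }
  data.frame(
    id = unname(vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)),
    sequence = unname(as.character(set))
  )
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param records Data frame with columns `id` and `sequence`.
#' @param path Output file path.
#' @param type `"AA"` (default) or `"DNA"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  stopifnot(all(c("id", "sequence") %in% names(records)))
  set <- if (type == "AA") {
    Biostrings::AAStringSet(records$sequence)
  } else {
    Biostrings::DNAStringSet(records$sequence)
  }
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
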