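# JASPAR-format position frequency matrices, log-odds PWM construction,
# and double-stranded promoter scanning with a relative-score threshold.

.DNA_BASES <- c("A", "C", "G", "T")

.check_pfm <- function(counts, tf_name = "") {
  if (!is.matrix(counts) || nrow(counts) != 4L || ncol(counts) < 1L) {
    stop("PFM must be a 4 x L matrix (", tf_name, ")")
  }
  if (any(counts < 0)) stop("negative count in PFM ", tf_name)
  if (any(colSums(counts) <= 0)) stop("zero column sum in PFM ", tf_name)
  invisible(counts)
}

#' Read position frequency matrices in JASPAR text format
#'
#' Parses the four-row JASPAR count format: a header `>ID NAME` followed by
#' rows `A [ 1 2 ... ]`, `C [ ... ]`, `G [ ... ]`, `T [ ... ]` (the
#' brackets are optional). Several records per file are supported.
#'
#' @param path File path, or a character vector of lines via `text`.
#' @param text Optional character vector of lines (overrides `path`).
#' @return Named list of PFM objects (class `pfm`): lists with `tf_name`,
#'   `id` and `counts` (4 x L matrix, rows A/C/G/T).
#' @export
read_pfm <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  heads <- which(startsWith(lines, ">"))
  if (!length(heads)) stop("no JASPAR records found")
  ends <- c(heads[-1L] - 1L, length(lines))
  pfms <- lapply(seq_along(heads), function(i) {
    hdr <- sub("^>\\s*", "", lines[heads[i]])
    toks <- strsplit(hdr, "\\s+")[[1]]
    id <- toks[1]
    name <- if (length(toks) > 1L) paste(toks[-1L], collapse = " ") else toks[1]
    body <- lines[(heads[i] + 1L):ends[i]]
    rows <- lapply(body, function(ln) {
      base <- sub("^([ACGT]).*", "\\1", ln)
      nums <- gsub("[^0-9eE+.\\-]", " ", sub("^[ACGT]", "", ln))
      vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
      if (anyNA(vals)) stop("format error: unparseable PFM row: ", ln)
      list(base = base, vals = vals)
    })
    bases <- vapply(rows, `[[`, character(1), "base")
    if (!setequal(bases, .DNA_BASES)) {
      stop("format error: PFM record ", id, " must have rows A, C, G, T")
    }
    lens <- lengths(lapply(rows, `[[`, "vals"))
    if (length(unique(lens)) != 1L) {
      stop("format error: row-length mismatch in PFM record ", id)
    }
    counts <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(counts) <- bases
    counts <- counts[.DNA_BASES, , drop = FALSE]
    .check_pfm(counts, name)
    structure(list(tf_name = name, id = id, counts = counts), class = "pfm")
  })
  names(pfms) <- vapply(pfms, `[[`, character(1), "tf_name")
  pfms
}

#' Write PFMs in canonical JASPAR text format
#'
#' @param pfms List of `pfm` objects (or a single one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfms, path) {
  if (inherits(pfms, "pfm")) pfms <- list(pfms)
  lines <- unlist(lapply(pfms, function(p) {
    c(paste0(">", p$id, " ", p$tf_name),
      vapply(.DNA_BASES, function(b) {
        sprintf("%s [ %s ]", b, paste(format(p$counts[b, ], trim = TRUE),
                                      collapse = " "))
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Convert a position frequency matrix to a log-odds PWM
#'
#' Per column, `p = (count + pseudocount) / (colsum + 4 * pseudocount)` and
#' `log_odds = log2(p / background)`. The maximum attainable score is the
#' sum of the column maxima (the score of the consensus sequence).
#'
#' @param pfm A `pfm` object.
#' @param pseudocount Pseudocount added per cell (default 0.25, i.e. one
#'   pseudo-observation per column).
#' @param background Named background probabilities over A/C/G/T (must sum
#'   to 1; default uniform).
#' @return Object of class `pwm`: `tf_name`, `log_odds` (4 x L),
#'   `background`, `max_score`.
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 0.25,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(inherits(pfm, "pfm"))
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  background <- background[.DNA_BASES]
  if (anyNA(background) || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8) {
    stop("background must be positive A/C/G/T probabilities summing to 1")
  }
  counts <- pfm$counts
  p <- sweep(counts + pseudocount, 2L, colSums(counts) + 4 * pseudocount, "/")
  lo <- log2(p / background)
  structure(list(
    tf_name = pfm$tf_name,
    log_odds = lo,
    background = background,
    max_score = sum(apply(lo, 2L, max))
  ), class = "pwm")
}

.revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# score every window of length L on one strand; returns numeric vector
# (NA where the window contains a non-ACGT base)
.score_windows <- function(seq, log_odds) {
  L <- ncol(log_odds)
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1]], .DNA_BASES)
  n <- length(idx) - L + 1L
  if (n < 1L) return(numeric())
  scores <- rep(0, n)
  for (j in seq_len(L)) {
    scores <- scores + log_odds[cbind(idx[j:(j + n - 1L)], j)]
  }
  scores
}

#' Scan a DNA sequence with a PWM on both strands
#'
#' Every window of the matrix length is scored on the forward strand and
#' on the reverse complement; windows containing `N` are skipped. Hits are
#' windows with `score >= min_relative_score * max_score`; coordinates are
#' always reported on the forward strand (0-based start).
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param pwm A `pwm` object from [pfm_to_pwm()].
#' @param min_relative_score Relative score threshold in `[0, 1]`
#'   (default 0.8).
#' @return Data frame `tf_name`, `start` (0-based, forward strand),
#'   `strand`, `score`, `relative_score`, ordered by `start`.
#' @export
scan_sequence <- function(seq, pwm, min_relative_score = 0.8) {
  stopifnot(inherits(pwm, "pwm"))
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("sequence must be over A, C, G, T, N")
  L <- ncol(pwm$log_odds)
  n <- nchar(seq)
  cut <- min_relative_score * pwm$max_score
  fwd <- .score_windows(seq, pwm$log_odds)
  rev <- .score_windows(.revcomp(seq), pwm$log_odds)
  rows <- list()
  if (length(fwd)) {
    hit <- which(!is.na(fwd) & fwd >= cut)
    if (length(hit)) {
      rows[[1]] <- data.frame(tf_name = pwm$tf_name, start = hit - 1L,
                              strand = "+", score = fwd[hit])
    }
  }
  if (length(rev)) {
    hit <- which(!is.na(rev) & rev >= cut)
    if (length(hit)) {
      # position p (1-based) on the reverse complement maps to forward
      # start n - L - p + 1 (0-based)
      rows[[length(rows) + 1L]] <- data.frame(
        tf_name = pwm$tf_name, start = n - L - hit + 1L,
        strand = "-", score = rev[hit])
    }
  }
  if (!length(rows)) {
    return(data.frame(tf_name = character(), start = integer(),
                      strand = character(), score = numeric(),
                      relative_score = numeric()))
  }
  out <- do.call(rbind, rows)
  out$relative_score <- out$score / pwm$max_score
  out <- out[order(out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Fraction of genes whose promoter carries at least one PWM hit
#'
#' @param promoters Data frame with columns `gene_id` and `sequence`.
#' @param pwms List of `pwm` objects (or a single one).
#' @param min_relative_score Relative score threshold (default 0.8).
#' @return List with `fractions` (per TF: `tf_name`, `n_genes_hit`,
#'   `fraction`) and `per_gene` (`gene_id`, `tf_name`, `n_hits`).
#' @export
gene_hit_fraction <- function(promoters, pwms, min_relative_score = 0.8) {
  stopifnot(is.data.frame(promoters), nrow(promoters) >= 1L)
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  per_gene <- do.call(rbind, lapply(pwms, function(pw) {
    data.frame(
      gene_id = promoters$gene_id,
      tf_name = pw$tf_name,
      n_hits = vapply(promoters$sequence, function(s) {
        nrow(scan_sequence(s, pw, min_relative_score))
      }, integer(1), USE.NAMES = FALSE)
    )
  }))
  rownames(per_gene) <- NULL
  agg <- stats::aggregate(n_hits ~ tf_name, per_gene,
                          function(x) sum(x > 0))
  fractions <- data.frame(
    tf_name = agg$tf_name,
    n_genes_hit = agg$n_hits,
    fraction = agg$n_hits / nrow(promoters)
  )
  list(fractions = fractions, per_gene = per_gene)
}
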