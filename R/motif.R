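# B-box position-weight-matrix scanning and region-set over-representation

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position-weight matrix
#'
#' @param mat Numeric matrix, 4 rows (A, C, G, T) by L columns, of
#'   per-position base probabilities or counts; columns are renormalized
#'   after adding `pseudocount`.
#' @param name Motif name.
#' @param background Background base frequencies (default uniform).
#' @param pseudocount Added to every cell before normalization.
#' @return Object of class `pwm`: probabilities `prob`, log-odds score
#'   matrix `score` in bits (with an all-zero `N` row so ambiguous bases
#'   are background-neutral), `name`, `background`.
#' @export
pwm <- function(mat, name = "motif", background = rep(0.25, 4),
                pseudocount = 0) {
  stopifnot(is.matrix(mat), nrow(mat) == 4, ncol(mat) >= 1,
            all(mat >= 0), length(background) == 4,
            abs(sum(background) - 1) < 1e-8)
  dimnames(mat) <- list(DNA_BASES, NULL)
  mat <- mat + pseudocount
  prob <- sweep(mat, 2, colSums(mat), "/")
  score <- log2(sweep(prob, 1, background, "/"))
  score <- rbind(score, N = 0)
  structure(list(name = name, prob = prob, score = score,
                 background = setNames(background, DNA_BASES),
                 length = ncol(prob)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$name, ": ", x$length, " bp, max score ",
      round(pwm_max_score(x), 2), " bits\n", sep = "")
  invisible(x)
}

#' @export
tidy.pwm <- function(x, ...) {
  as_tibble(as.data.frame(x$prob)) |>
    dplyr::mutate(base = DNA_BASES) |>
    pivot_longer(-"base", names_to = "position", values_to = "prob") |>
    dplyr::mutate(position = as.integer(sub("^V", "", .data$position)))
}

#' Build a PWM from an IUPAC consensus
#'
#' Each consensus letter distributes one count uniformly over its IUPAC
#' bases (N over all four), then a uniform pseudocount is added and
#' columns renormalized.
#'
#' @param consensus IUPAC string.
#' @param name Motif name.
#' @param pseudocount Per-cell pseudocount (default 0.25).
#' @param background Background base frequencies.
#' @return A [pwm()].
#' @export
pwm_from_consensus <- function(consensus, name = consensus, pseudocount = 0.25,
                               background = rep(0.25, 4)) {
  letters <- strsplit(toupper(consensus), "")[[1]]
  iupac <- Biostrings::IUPAC_CODE_MAP
  cols <- vapply(letters, function(ch) {
    if (!ch %in% names(iupac)) abort(paste0("not an IUPAC code: ", ch))
    bases <- strsplit(iupac[[ch]], "")[[1]]
    col <- setNames(numeric(4), DNA_BASES)
    col[bases] <- 1 / length(bases)
    col
  }, numeric(4))
  pwm(cols, name = name, background = background, pseudocount = pseudocount)
}

#' Default B-box position-weight matrix
#'
#' A synthetic stand-in for the B-box-like TFIIIC recognition matrix
#' (which is not redistributable here): the canonical RNA polymerase III
#' B-box internal-promoter consensus `GTTCGAANNC` centered in 16 columns
#' whose flanks are uninformative (`N`, scoring 0 bits), built with
#' [pwm_from_consensus()] at pseudocount 0.25. Replace with a measured
#' matrix via [read_pwm()] for real scans.
#'
#' @return A 16-column [pwm()].
#' @export
bbox_pwm <- function() {
  pwm_from_consensus("NNNGTTCGAANNCNNN", name = "Bbox_consensus_standin")
}

#' Maximal achievable PWM score
#'
#' @param x A [pwm()].
#' @return Bits.
#' @export
pwm_max_score <- function(x) {
  stopifnot(inherits(x, "pwm"))
  sum(apply(x$score[DNA_BASES, , drop = FALSE], 2, max))
}

#' Read / write a PWM as a plain-text matrix
#'
#' Whitespace-delimited file: one header line (motif name), then L rows of
#' 4 probabilities (A C G T).
#'
#' @param path File path.
#' @param background,pseudocount Passed to [pwm()].
#' @return A [pwm()] (for `read_pwm`); `path` invisibly (for `write_pwm`).
#' @export
read_pwm <- function(path, background = rep(0.25, 4), pseudocount = 0) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  name <- trimws(lines[1])
  rows <- lapply(lines[-1], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (any(lengths(rows) != 4)) abort("each PWM row must have 4 values (A C G T)")
  pwm(t(do.call(rbind, rows)), name = name, background = background,
      pseudocount = pseudocount)
}

#' @rdname read_pwm
#' @param x A [pwm()].
#' @export
write_pwm <- function(x, path) {
  stopifnot(inherits(x, "pwm"))
  rows <- apply(x$prob, 2, function(col) paste(formatC(col, format = "g", digits = 10),
                                               collapse = " "))
  readr::write_lines(c(x$name, rows), path)
  invisible(path)
}

seq_to_codes <- function(s) {
  chars <- strsplit(toupper(s), "")[[1]]
  codes <- match(chars, c(DNA_BASES, "N"))
  if (anyNA(codes)) {
    abort(paste0("invalid character '", chars[which(is.na(codes))[1]],
                 "' at position ", which(is.na(codes))[1]))
  }
  codes
}

#' Score one window against a PWM
#'
#' Log-odds score in bits, summed per column; `N` contributes 0 bits
#' (background-neutral).
#'
#' @param x A [pwm()].
#' @param subseq Character string of exactly `x$length` bases (ACGTN).
#' @return Score in bits.
#' @export
score_window <- function(x, subseq) {
  stopifnot(inherits(x, "pwm"))
  codes <- seq_to_codes(subseq)
  if (length(codes) != x$length) {
    abort(paste0("subsequence length ", length(codes),
                 " != PWM length ", x$length))
  }
  sum(x$score[cbind(codes, seq_along(codes))])
}

scan_codes <- function(score_mat, codes) {
  L <- ncol(score_mat); n <- length(codes)
  if (n < L) return(numeric(0))
  out <- numeric(n - L + 1)
  for (j in seq_len(L)) {
    out <- out + unname(score_mat[, j])[codes[j:(n - L + j)]]
  }
  out
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Scan a sequence for PWM hits on both strands
#'
#' All offsets scoring at least `threshold` bits are reported; reverse
#' strand hits are scored on the reverse complement, with the offset
#' mapped back to the forward-strand coordinate of the hit's left edge.
#'
#' @param x A [pwm()].
#' @param seq Character string (ACGTN) or named character vector of
#'   sequences.
#' @param threshold Minimum score in bits; default 80% of the maximal
#'   score.
#' @param seq_id Identifier used when `seq` is a single unnamed string.
#' @return Tibble of hits: `seq_id`, `offset` (0-based), `strand`,
#'   `score`.
#' @export
scan_sequence <- function(x, seq, threshold = 0.8 * pwm_max_score(x),
                          seq_id = "seq") {
  stopifnot(inherits(x, "pwm"))
  if (length(seq) > 1 || !is.null(names(seq))) {
    ids <- names(seq) %||% paste0(seq_id, seq_along(seq))
    return(purrr::map2(unname(seq), ids,
                       ~ scan_sequence(x, .x, threshold, .y)) |> list_rbind())
  }
  n <- nchar(seq)
  hit0 <- tibble(seq_id = character(), offset = integer(),
                 strand = character(), score = double())
  if (n < x$length) return(hit0)
  fwd <- scan_codes(x$score, seq_to_codes(seq))
  rev <- scan_codes(x$score, seq_to_codes(revcomp(seq)))
  hits <- dplyr::bind_rows(
    tibble(seq_id = seq_id, offset = which(fwd >= threshold) - 1L,
           strand = "+", score = fwd[fwd >= threshold]),
    tibble(seq_id = seq_id,
           offset = n - x$length - (which(rev >= threshold) - 1L),
           strand = "-", score = rev[rev >= threshold])
  )
  dplyr::arrange(hits, .data$offset, .data$strand)
}

#' Ordinal B-box category of a score
#'
#' Bins the best hit score of an element into the ordinal categories used
#' for tabulating B-box predictions (`+` to `++++`). Four cut points
#' delimit the four ordinal bins; edges are right-closed upward: a score
#' exactly on an edge takes the higher bin; scores below the lowest edge
#' give `"no call"`, and a perfect consensus lands in `++++`.
#'
#' @param score Numeric score(s) in bits.
#' @param edges Four strictly increasing cut points; default 80, 87.5, 95
#'   and 99% of `max_score`.
#' @param max_score Maximal PWM score used for the default edges.
#' @return Ordered factor with levels `no call`, `+`, `++`, `+++`,
#'   `++++`.
#' @export
bbox_category <- function(score, edges = max_score * c(0.80, 0.875, 0.95, 0.99),
                          max_score = pwm_max_score(bbox_pwm())) {
  stopifnot(length(edges) == 4, all(diff(edges) > 0))
  lab <- c("no call", "+", "++", "+++", "++++")
  idx <- findInterval(score, edges) + 1L
  factor(lab[idx], levels = lab, ordered = TRUE)
}

#' Motif over-representation of a region set versus background
#'
#' Each sequence is scored as containing (>= 1 hit at `threshold`) or not;
#' the resulting 2x2 table of target versus background sequences is tested
#' with a two-sided Fisher's exact test.
#'
#' @param x A [pwm()].
#' @param target_seqs,background_seqs Named character vectors of sequences
#'   (or `Biostrings::DNAStringSet`).
#' @param threshold Hit threshold in bits (default 80% of max).
#' @return One-row tibble: hit fractions, counts, odds ratio, Fisher p.
#' @export
motif_overrepresentation <- function(x, target_seqs, background_seqs,
                                     threshold = 0.8 * pwm_max_score(x)) {
  as_chr <- function(s) {
    if (is(s, "DNAStringSet")) setNames(as.character(s), names(s)) else s
  }
  t <- as_chr(target_seqs); b <- as_chr(background_seqs)
  if (length(t) == 0 || length(b) == 0) abort("both sequence sets must be non-empty")
  has_hit <- function(s) {
    vapply(s, function(one) nrow(scan_sequence(x, one, threshold)) > 0, logical(1))
  }
  kt <- sum(has_hit(t)); kb <- sum(has_hit(b))
  tab <- matrix(c(kt, length(t) - kt, kb, length(b) - kb), nrow = 2)
  ft <- fisher.test(tab)
  tibble(n_target = length(t), n_background = length(b),
         target_hit_frac = kt / length(t),
         background_hit_frac = kb / length(b),
         odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Seeded 50/50 split of a sequence or region set
#'
#' Utility reproducing a test-versus-validation split: elements are
#' randomly divided into two halves of (near-)equal size.
#'
#' @param x Vector or data frame (split by row).
#' @param seed Integer seed.
#' @return List with elements `test` and `validation`.
#' @export
split_half <- function(x, seed = 1) {
  n <- if (is.data.frame(x)) nrow(x) else length(x)
  idx <- withr::with_seed(seed, sample(n, floor(n / 2)))
  if (is.data.frame(x)) {
    list(test = x[sort(idx), , drop = FALSE], validation = x[-sort(idx), , drop = FALSE])
  } else {
    list(test = x[sort(idx)], validation = x[-sort(idx)])
  }
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), names(s))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(unname(seqs), names(seqs))), path)
  invisible(path)
}
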