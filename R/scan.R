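#' Binomial test for one differential window
#'
#' Under the null of no differential enrichment, the `k_a` tags observed in
#' library A among the `n = k_a + k_b` tags falling in a window are
#' distributed Binomial(n, p0) with `p0 = N_a / (N_a + N_b)` set by the
#' total library sizes. Both one-sided tail probabilities include the
#' observed count. The optional two-sided p-value is the doubled smaller
#' tail, capped at 1.
#'
#' @param k_a,k_b Tag counts in the window for libraries A and B.
#' @param n_a,n_b Total library sizes (after filtering/deduplication).
#' @param alpha Significance threshold used to assign a direction
#'   (default 1e-3).
#'
#' @return A one-row tibble per input element: `k_a`, `k_b`, `n`, `p0`,
#'   `p_inc` (upper tail), `p_dec` (lower tail), `p_two`, `direction`
#'   (`"increase"`, `"decrease"` or `"none"`). Vectorized over `k_a`/`k_b`.
#' @export
#' @examples
#' binomial_window_test(15, 5, 1e6, 1e6)
binomial_window_test <- function(k_a, k_b, n_a, n_b, alpha = 1e-3) {
  stopifnot(n_a >= 0, n_b >= 0, all(k_a >= 0), all(k_b >= 0),
            length(k_a) == length(k_b))
  # two empty libraries: no information, every window is a null window
  p0 <- if (n_a + n_b == 0) 0.5 else n_a / (n_a + n_b)
  n <- k_a + k_b
  p_inc <- pbinom(k_a - 1, n, p0, lower.tail = FALSE)
  p_dec <- pbinom(k_a, n, p0)
  # -log10 p via log-space tails: avoids 0/Inf for strong windows
  mlog10_inc <- -pbinom(k_a - 1, n, p0, lower.tail = FALSE, log.p = TRUE) / log(10)
  mlog10_dec <- -pbinom(k_a, n, p0, log.p = TRUE) / log(10)
  direction <- dplyr::case_when(
    p_inc < alpha & p_dec >= alpha ~ "increase",
    p_dec < alpha & p_inc >= alpha ~ "decrease",
    .default = "none"
  )
  tibble(
    k_a = as.integer(k_a), k_b = as.integer(k_b), n = as.integer(n), p0 = p0,
    p_inc = p_inc, p_dec = p_dec,
    p_two = pmin(1, 2 * pmin(p_inc, p_dec)),
    mlog10_inc = mlog10_inc, mlog10_dec = mlog10_dec,
    direction = direction
  )
}

#' Scan two tag libraries with sliding windows
#'
#' Slides windows of `window` bp at `step` bp stride across every
#' chromosome shared by the two libraries, counts tags from each library
#' per window and applies [binomial_window_test()]. The final window of a
#' chromosome that does not fit entirely is emitted truncated and flagged;
#' truncated windows are excluded from region calling by default.
#'
#' @param lib_a,lib_b [tag_library()] objects on identical `chrom_sizes`.
#'   `lib_a` is the "condition" library: `direction == "increase"` means
#'   enrichment in `lib_a`.
#' @param window Window width in bp (default 2000).
#' @param step Stride in bp (default 500); must satisfy `0 < step <= window`.
#' @param alpha Per-window significance threshold (default 1e-3).
#'
#' @return A tibble of class `acet_windows`, ordered by (chrom, start),
#'   with columns `chrom`, `start`, `end`, `truncated`, the
#'   [binomial_window_test()] columns, and attributes `window`, `step`,
#'   `alpha`, `n_a`, `n_b`.
#' @export
scan_windows <- function(lib_a, lib_b, window = 2000, step = 500, alpha = 1e-3) {
  stopifnot(inherits(lib_a, "tag_library"), inherits(lib_b, "tag_library"),
            window > 0, step > 0, step <= window, alpha > 0, alpha < 1)
  if (!identical(lib_a$chrom_sizes[sort(names(lib_a$chrom_sizes))],
                 lib_b$chrom_sizes[sort(names(lib_b$chrom_sizes))])) {
    abort("libraries have mismatched `chrom_sizes`")
  }
  chroms <- sort(names(lib_a$chrom_sizes))
  per_chrom <- lapply(chroms, function(ch) {
    L <- lib_a$chrom_sizes[[ch]]
    if (L >= window) {
      starts <- seq(0L, as.integer(L - window), by = as.integer(step))
      # one flagged partial window if the tiling leaves a 3' remainder
      if (max(starts) + window < L) starts <- c(starts, max(starts) + as.integer(step))
    } else {
      starts <- 0L
    }
    ends <- pmin(starts + as.integer(window), as.integer(L))
    pa <- lib_a$tags$pos[lib_a$tags$chrom == ch]
    pb <- lib_b$tags$pos[lib_b$tags$chrom == ch]
    count_in <- function(p, s, e) {
      if (length(p) == 0) return(integer(length(s)))
      findInterval(e - 0.5, p) - findInterval(s - 0.5, p)
    }
    tibble(
      chrom = ch, start = starts, end = ends,
      truncated = (starts + window) > L,
      k_a = count_in(pa, starts, ends),
      k_b = count_in(pb, starts, ends)
    )
  })
  win <- dplyr::bind_rows(per_chrom)
  res <- dplyr::bind_cols(
    win[, c("chrom", "start", "end", "truncated")],
    binomial_window_test(win$k_a, win$k_b, lib_a$n, lib_b$n, alpha = alpha)
  )
  structure(res, class = c("acet_windows", class(res)),
            window = window, step = step, alpha = alpha,
            n_a = lib_a$n, n_b = lib_b$n,
            chrom_sizes = lib_a$chrom_sizes)
}

#' @export
tidy.acet_windows <- function(x, ...) as_tibble(x)

#' @export
glance.acet_windows <- function(x, ...) {
  alpha <- attr(x, "alpha")
  keep <- !x$truncated
  tibble(
    n_windows = nrow(x),
    n_increase = sum(x$p_inc[keep] < alpha),
    n_decrease = sum(x$p_dec[keep] < alpha),
    alpha = alpha, window = attr(x, "window"), step = attr(x, "step"),
    fdr = estimate_fdr(x, alpha = alpha)
  )
}

#' Merge significant windows into differential regions
#'
#' Windows with a one-sided p-value below `alpha` are merged, per
#' direction, into maximal unions of overlapping-or-abutting windows.
#' Truncated chromosome-edge windows are excluded by default. A region's
#' `peak_score` is the maximum -log10(p) over its member windows.
#'
#' @param windows An `acet_windows` tibble from [scan_windows()].
#' @param alpha Significance threshold; defaults to the scan's.
#' @param include_truncated Include flagged partial edge windows?
#'
#' @return Tibble of class `acet_regions`: `chrom`, `start`, `end`,
#'   `direction` (`"increase"`/`"decrease"`), `peak_score`, `n_windows`,
#'   `width`.
#' @export
merge_significant <- function(windows, alpha = attr(windows, "alpha") %||% 1e-3,
                              include_truncated = FALSE) {
  stopifnot(is.data.frame(windows))
  w <- as_tibble(windows)
  if (!include_truncated && "truncated" %in% names(w)) w <- w[!w$truncated, ]
  out <- list()
  for (dir in c("increase", "decrease")) {
    p <- if (dir == "increase") w$p_inc else w$p_dec
    score <- if (dir == "increase") w$mlog10_inc else w$mlog10_dec
    sig <- which(p < alpha)
    if (length(sig) == 0) next
    gr <- GenomicRanges::GRanges(
      w$chrom[sig], IRanges::IRanges(w$start[sig] + 1L, w$end[sig])
    )
    red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    out[[dir]] <- tibble(
      chrom = as.character(GenomeInfoDb::seqnames(red)),
      start = GenomicRanges::start(red) - 1L,
      end = GenomicRanges::end(red),
      direction = dir,
      peak_score = map_dbl(revmap, ~ max(score[sig][.x])),
      n_windows = lengths(revmap)
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(chrom = character(), start = integer(), end = integer(),
                  direction = character(), peak_score = double(),
                  n_windows = integer())
  }
  res <- dplyr::arrange(res, .data$chrom, .data$start, .data$direction)
  res$width <- res$end - res$start
  structure(res, class = c("acet_regions", class(res)), alpha = alpha)
}

#' @export
tidy.acet_regions <- function(x, ...) as_tibble(x)

#' Per-direction region summary
#'
#' @param x An `acet_regions` tibble.
#' @param ... Unused.
#' @return One row per direction: count, min/median/max width, top score.
#' @export
glance.acet_regions <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble(direction = character(), n_regions = integer(),
                  min_width = double(), median_width = double(),
                  max_width = double(), max_score = double()))
  }
  as_tibble(x) |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(
      n_regions = dplyr::n(),
      min_width = min(.data$width), median_width = median(.data$width),
      max_width = max(.data$width), max_score = max(.data$peak_score),
      .groups = "drop"
    )
}

#' Discreteness-aware FDR estimate for the window scan
#'
#' For each tested window the probability, under the binomial null with the
#' window's total count `n` and the library-size ratio `p0`, that either
#' one-sided p-value falls below `alpha` is accumulated exactly over the
#' discrete outcome space. The estimate is this expected number of false
#' discoveries divided by the number of windows actually called. Windows
#' with `n = 0` can never be significant and are skipped.
#'
#' The ratio is capped at 1 (a fraction of discoveries cannot exceed
#' 100%), which is where null data land.
#'
#' @param windows `acet_windows` tibble.
#' @param alpha Threshold (defaults to the scan's).
#' @return Estimated FDR in `[0, 1]`, or `NA` (with attribute `reason`)
#'   when nothing is called.
#' @export
estimate_fdr <- function(windows, alpha = attr(windows, "alpha") %||% 1e-3) {
  w <- as_tibble(windows)
  if ("truncated" %in% names(w)) w <- w[!w$truncated, ]
  w <- w[w$n > 0, ]
  n_called <- sum(w$p_inc < alpha | w$p_dec < alpha)
  if (n_called == 0) {
    return(structure(NA_real_, reason = "no window called at alpha"))
  }
  p0 <- w$p0[1]
  mass_for_n <- function(n) {
    k <- 0:n
    p_inc <- pbinom(k - 1, n, p0, lower.tail = FALSE)
    p_dec <- pbinom(k, n, p0)
    sum(dbinom(k[p_inc < alpha | p_dec < alpha], n, p0))
  }
  tab <- table(w$n)
  masses <- vapply(as.integer(names(tab)), mass_for_n, numeric(1))
  expected_fp <- sum(masses * as.integer(tab))
  min(1, expected_fp / n_called)
}
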