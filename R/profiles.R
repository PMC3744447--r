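# TSS-relative metaprofiles: per-bin tag density and acetylated-SINE
# density, with Mann-Whitney group comparisons

#' Two-tailed Mann-Whitney p-value
#'
#' Thin wrapper around [stats::wilcox.test()]: exact enumeration for small
#' untied samples, normal approximation with tie correction otherwise
#' (warnings from the tie path are suppressed).
#'
#' @param x,y Numeric samples.
#' @return Two-sided p-value, or `NA` if either sample has < 1 value.
#' @export
mann_whitney_p <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1) return(NA_real_)
  if (all(x %in% y[1]) && all(y %in% y[1]) && length(unique(c(x, y))) == 1) return(1)
  suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
}

# per-gene x per-bin count matrix on TSS-relative, strand-oriented
# coordinates (downstream positive). Bins of `bin` bp covering
# [-range, +range). Bins extending past a chromosome end are NA.
tss_bin_matrix <- function(lib, genes, bin, range) {
  stopifnot(inherits(lib, "tag_library"), range %% bin == 0)
  g <- genes_as_tibble(genes)
  edges <- seq(-range, range, by = bin)
  nb <- length(edges) - 1
  mat <- matrix(NA_real_, nrow = nrow(g), ncol = nb,
                dimnames = list(g$gene_id, NULL))
  tags_by_chrom <- split(lib$tags$pos, lib$tags$chrom)
  for (i in seq_len(nrow(g))) {
    L <- lib$chrom_sizes[[g$chrom[i]]]
    if (is.null(L)) abort(paste0("gene on unknown chromosome: ", g$chrom[i]))
    p <- tags_by_chrom[[g$chrom[i]]]
    rel_lo <- edges[-length(edges)]; rel_hi <- edges[-1]
    if (g$strand[i] == "+") {
      glo <- g$tss[i] + rel_lo; ghi <- g$tss[i] + rel_hi
    } else {
      # flip: relative offset r covers genomic (tss - hi, tss - lo]
      glo <- g$tss[i] - rel_hi + 1; ghi <- g$tss[i] - rel_lo + 1
    }
    ok <- glo >= 0 & ghi <= L
    cnt <- rep(NA_real_, nb)
    if (any(ok)) {
      if (is.null(p) || length(p) == 0) {
        cnt[ok] <- 0
      } else {
        cnt[ok] <- findInterval(ghi[ok] - 0.5, p) - findInterval(glo[ok] - 0.5, p)
      }
    }
    mat[i, ] <- cnt
  }
  attr(mat, "bin_start") <- edges[-length(edges)]
  mat
}

#' TSS-relative tag-density metaprofile
#'
#' Bins tags on TSS-relative coordinates (minus-strand genes flipped so
#' downstream is positive), averages per bin across the genes of each
#' group, and reports the mean read count per bin. Bins truncated by a
#' chromosome end are masked from the average.
#'
#' @param lib A [tag_library()].
#' @param genes Gene tibble; a `group` column, if present, stratifies the
#'   profile.
#' @param bin Bin width in bp (default 100).
#' @param range Half-range around the TSS in bp (default 2000; must be a
#'   multiple of `bin`).
#' @return Tibble of class `tss_profile`: `offset` (bin start, bp relative
#'   to TSS), `group`, `mean_density` (mean tags per bin), `n_genes`.
#' @export
tss_tag_density_profile <- function(lib, genes, bin = 100, range = 2000) {
  g <- genes_as_tibble(genes)
  if (!"group" %in% names(g)) g$group <- "all"
  mat <- tss_bin_matrix(lib, g, bin, range)
  offs <- attr(mat, "bin_start")
  res <- purrr::map(sort(unique(g$group)), function(grp) {
    m <- mat[g$group == grp, , drop = FALSE]
    tibble(offset = offs, group = grp,
           mean_density = colMeans(m, na.rm = TRUE),
           n_genes = colSums(!is.na(m)))
  }) |> list_rbind()
  structure(res, class = c("tss_profile", class(res)), bin = bin)
}

#' Promoter-window tag-density statistics per gene group
#'
#' Summarizes the per-gene mean tag count per `bin`-bp bin inside a fixed
#' TSS-relative window (default the first 500 bp downstream) as a
#' five-number summary per group, and compares groups pairwise with
#' two-tailed Mann-Whitney tests.
#'
#' @param lib A [tag_library()].
#' @param genes Gene tibble with a `group` column.
#' @param window Length-2 vector, TSS-relative window `[lo, hi)` in bp.
#' @param bin Bin width used for the per-gene statistic (default 100).
#' @param pairs Two-column matrix/list of group pairs to test; default all
#'   pairs with >= 2 genes each.
#' @return List with `summary` (min, q1, median, q3, max, n per group) and
#'   `tests` (group_a, group_b, p).
#' @export
tss_window_stats <- function(lib, genes, window = c(0, 500), bin = 100,
                             pairs = NULL) {
  g <- genes_as_tibble(genes)
  stopifnot("group" %in% names(g), length(window) == 2,
            (window[2] - window[1]) %% bin == 0)
  range <- max(abs(window))
  mat <- tss_bin_matrix(lib, g, bin, range)
  offs <- attr(mat, "bin_start")
  sel <- offs >= window[1] & offs < window[2]
  stat <- rowMeans(mat[, sel, drop = FALSE], na.rm = FALSE)
  vals <- split(stat, g$group)
  summ <- imap(vals, function(v, grp) {
    v <- v[!is.na(v)]
    q <- quantile(v, c(0, .25, .5, .75, 1), names = FALSE)
    tibble(group = grp, min = q[1], q1 = q[2], median = q[3], q3 = q[4],
           max = q[5], n = length(v))
  }) |> list_rbind()
  groups <- summ$group[summ$n >= 2]
  if (is.null(pairs)) {
    pairs <- if (length(groups) >= 2) t(utils::combn(groups, 2)) else
      matrix(character(0), ncol = 2)
  }
  tests <- purrr::map(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    tibble(group_a = a, group_b = b,
           p = mann_whitney_p(vals[[a]], vals[[b]]))
  }) |> list_rbind()
  if (nrow(tests) == 0) tests <- tibble(group_a = character(), group_b = character(),
                                        p = double())
  list(summary = summ, tests = tests, per_gene = tibble(gene_id = g$gene_id,
                                                        group = g$group,
                                                        density = stat))
}

# per-gene x per-offset count of acetylated-SINE midpoints in centered
# windows; offsets -range..range step `step`, window of `window` bp
sine_offset_matrix <- function(ac_sines, genes, chrom_sizes,
                               window, step, range, centered = TRUE) {
  g <- genes_as_tibble(genes)
  s <- as_tibble(ac_sines)
  offsets <- seq(-range, range, by = step)
  half <- window / 2
  mids_by_chrom <- if (nrow(s) > 0) {
    split(floor((s$start + s$end) / 2), s$chrom)
  } else list()
  mat <- matrix(NA_real_, nrow = nrow(g), ncol = length(offsets),
                dimnames = list(g$gene_id, NULL))
  for (i in seq_len(nrow(g))) {
    L <- chrom_sizes[[g$chrom[i]]]
    mids <- mids_by_chrom[[g$chrom[i]]]
    # closed window [lo, hi]: an element midpoint exactly on a window
    # edge counts for both flanking offsets
    lo <- if (centered) offsets - half else offsets
    hi <- lo + window
    if (g$strand[i] == "+") {
      glo <- g$tss[i] + lo; ghi <- g$tss[i] + hi
    } else {
      glo <- g$tss[i] - hi; ghi <- g$tss[i] - lo
    }
    ok <- glo >= 0 & ghi < L
    cnt <- rep(NA_real_, length(offsets))
    if (any(ok)) {
      if (is.null(mids) || length(mids) == 0) {
        cnt[ok] <- 0
      } else {
        mids <- sort(mids)
        cnt[ok] <- findInterval(ghi[ok] + 0.5, mids) - findInterval(glo[ok] - 0.5, mids)
      }
    }
    mat[i, ] <- cnt
  }
  attr(mat, "offsets") <- offsets
  mat
}

#' Acetylated-SINE density profile around TSSs
#'
#' For each TSS-relative offset (default -100 to +100 kbp every 5 kbp),
#' counts per gene the de novo acetylated SINEs whose midpoint falls in a
#' `window`-bp window centered on the offset, closed at both edges
#' (minus-strand genes flipped),
#' averages within each gene group, and tests NI against CE at every
#' offset with a two-tailed Mann-Whitney test. Windows truncated by a
#' chromosome end are masked.
#'
#' @param ac_sines Acetylated SINE tibble (e.g. from
#'   [acetylated_sines()]).
#' @param genes Gene tibble with `group` column.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param window Window width in bp (default 50000).
#' @param step Offset spacing in bp (default 5000).
#' @param range Maximum absolute offset in bp (default 100000).
#' @param test_pair Groups compared per offset (default NI vs CE).
#' @param centered Center windows on the offset (default) or left-align.
#' @return Tibble of class `sine_profile`: `offset`, `group`,
#'   `mean_density` (mean SINEs per window), `n_genes`; per-offset test
#'   p-values in `attr(, "tests")` and merged into the rows of
#'   `test_pair[1]` as column `p_vs`.
#' @export
sine_density_profile <- function(ac_sines, genes, chrom_sizes,
                                 window = 50000, step = 5000, range = 100000,
                                 test_pair = c("NI", "CE"), centered = TRUE) {
  g <- genes_as_tibble(genes)
  stopifnot("group" %in% names(g))
  mat <- sine_offset_matrix(ac_sines, g, chrom_sizes, window, step, range,
                            centered = centered)
  offsets <- attr(mat, "offsets")
  res <- purrr::map(sort(unique(g$group)), function(grp) {
    m <- mat[g$group == grp, , drop = FALSE]
    tibble(offset = offsets, group = grp,
           mean_density = colMeans(m, na.rm = TRUE),
           n_genes = colSums(!is.na(m)))
  }) |> list_rbind()
  tests <- NULL
  if (all(test_pair %in% g$group)) {
    a <- mat[g$group == test_pair[1], , drop = FALSE]
    b <- mat[g$group == test_pair[2], , drop = FALSE]
    tests <- tibble(
      offset = offsets,
      p = vapply(seq_along(offsets),
                 function(j) mann_whitney_p(a[, j], b[, j]), numeric(1)),
      higher_in = vapply(seq_along(offsets), function(j) {
        ma <- mean(a[, j], na.rm = TRUE); mb <- mean(b[, j], na.rm = TRUE)
        if (isTRUE(ma > mb)) test_pair[1] else test_pair[2]
      }, character(1))
    )
  }
  structure(res, class = c("sine_profile", class(res)),
            tests = tests, test_pair = test_pair, window = window)
}

#' Per-offset test table of a SINE density profile
#'
#' @param x A `sine_profile`.
#' @param ... Unused.
#' @return Tibble `offset`, `p`, `higher_in`, or `NULL` if the test pair
#'   was not present.
#' @export
profile_tests <- function(x, ...) attr(x, "tests")
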