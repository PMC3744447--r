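# genomic-context module: gene grouping, region classification, repeat
# enrichment and background sampling

# sample odds ratio, Haldane-Anscombe corrected when a margin cell is 0
# (keeps degenerate tables finite: identical sets give exactly 1)
sample_odds_ratio <- function(tab) {
  if (any(tab == 0)) tab <- tab + 0.5
  (tab[1, 1] * tab[2, 2]) / (tab[2, 1] * tab[1, 2])
}

genes_as_tibble <- function(genes) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  g <- as_tibble(genes)
  if (!"tss" %in% names(g)) {
    g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  }
  g
}

ranges_of <- function(df, start = "start", end = "end") {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df[[start]] + 1L, df[[end]]))
}

#' Read a gene annotation from BED6
#'
#' @param path BED6: chrom, start, end, gene_id, score, strand (0-based
#'   half-open gene bodies). The TSS is the strand-appropriate body end.
#' @return Tibble: gene_id, chrom, start, end, strand, tss.
#' @export
read_genes <- function(path) {
  df <- readr::read_tsv(path,
                        col_names = c("chrom", "start", "end", "gene_id", "score", "strand"),
                        col_types = "ciicdc", progress = FALSE)
  genes_as_tibble(df[, c("gene_id", "chrom", "start", "end", "strand")])
}

#' Read a repeat annotation
#'
#' @param path TSV with header columns chrom, start, end, strand, name,
#'   family, class (RepeatMasker-style, 0-based half-open).
#' @return Tibble of repeat elements.
#' @export
read_repeats <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", start = "i", end = "i", strand = "c",
    name = "c", family = "c", class = "c"
  ), progress = FALSE)
}

#' Read an expression table
#'
#' @param path TSV with header: gene_id, detected_ctrl, detected_stim
#'   (logical), fold_change, adj_p.
#' @return Tibble.
#' @export
read_expression <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", detected_ctrl = "l", detected_stim = "l",
    fold_change = "d", adj_p = "d"
  ), progress = FALSE)
}

#' Assign genes to expression-response groups
#'
#' Groups genes by their transcriptional response to stimulation:
#' stimulus-induced (`NI`) if the fold change is at least `fold_threshold`
#' (inclusive) with adjusted p below `p_threshold`; repressed (`NR`) if
#' reduced at least as strongly (fold change `<= 1/fold_threshold`);
#' constitutively expressed (`CE`) if detected in both conditions without
#' qualifying as NI/NR; constitutively silent (`CS`) if detected in
#' neither. Genes detected in exactly one condition that pass no
#' differential threshold are left `unassigned` with a warning.
#'
#' @param expr Tibble with columns gene_id, detected_ctrl, detected_stim,
#'   fold_change (> 0, stimulated / control), adj_p.
#' @param fold_threshold Minimum induction fold (default 1.24).
#' @param p_threshold Adjusted-p cutoff (default 0.05).
#' @return `expr` with a `group` column
#'   (`"CS"`, `"CE"`, `"NI"`, `"NR"`, `"unassigned"`).
#' @export
classify_genes <- function(expr, fold_threshold = 1.24, p_threshold = 0.05) {
  stopifnot(is.data.frame(expr), all(expr$fold_change > 0),
            all(expr$adj_p >= 0 & expr$adj_p <= 1))
  if (anyDuplicated(expr$gene_id)) abort("one record per gene required")
  e <- as_tibble(expr)
  de <- e$adj_p < p_threshold
  e$group <- dplyr::case_when(
    de & e$fold_change >= fold_threshold ~ "NI",
    de & e$fold_change <= 1 / fold_threshold ~ "NR",
    e$detected_ctrl & e$detected_stim ~ "CE",
    !e$detected_ctrl & !e$detected_stim ~ "CS",
    .default = "unassigned"
  )
  if (any(e$group == "unassigned")) {
    warn(paste0(sum(e$group == "unassigned"),
                " gene(s) detected in one condition only; left unassigned"))
  }
  e
}

#' Classify differential regions by genomic context
#'
#' Each region is assigned one exclusive category: `tss` if it overlaps at
#' least one transcription start site (precedence), else `gene_body` if it
#' overlaps a gene body, else `extragenic`.
#'
#' @param regions `acet_regions` tibble (chrom, start, end).
#' @param genes Gene tibble as from [read_genes()].
#' @return `regions` with a `context` column.
#' @export
classify_region_context <- function(regions, genes) {
  g <- genes_as_tibble(genes)
  r <- as_tibble(regions)
  if (nrow(r) == 0) return(dplyr::mutate(r, context = character(0)))
  rr <- ranges_of(r)
  tss <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$tss + 1L, g$tss + 1L))
  body <- ranges_of(g)
  r$context <- dplyr::case_when(
    IRanges::overlapsAny(rr, tss) ~ "tss",
    IRanges::overlapsAny(rr, body) ~ "gene_body",
    .default = "extragenic"
  )
  r
}

#' Sample random background intervals
#'
#' Draws `n` intervals whose widths reproduce the `widths` multiset,
#' placed uniformly over chromosomes (weighted by the number of valid
#' placements). With `constraint = "tss_overlapping"` every interval is
#' anchored on a randomly chosen TSS so that it contains at least one.
#'
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param widths Integer vector of interval widths to reproduce.
#' @param n Number of intervals (default `length(widths)`; widths are
#'   recycled/sampled to `n`).
#' @param constraint `"none"` or `"tss_overlapping"`.
#' @param genes Gene tibble (required for the TSS constraint).
#' @param seed Integer seed; the draw is reproducible per seed.
#' @return Tibble: chrom, start, end, width.
#' @export
sample_background <- function(chrom_sizes, widths, n = length(widths),
                              constraint = c("none", "tss_overlapping"),
                              genes = NULL, seed = 1) {
  constraint <- match.arg(constraint)
  stopifnot(length(widths) > 0, all(widths > 0))
  withr::with_seed(seed, {
    w <- if (n == length(widths)) as.integer(widths) else
      as.integer(sample(widths, n, replace = TRUE))
    if (constraint == "none") {
      avail <- pmax(chrom_sizes[chrom_sizes >= max(w)] , 0)
      if (length(avail) == 0) abort("no chromosome can hold the widest interval")
      chrom <- sample(names(avail), n, replace = TRUE, prob = avail)
      start <- vapply(seq_len(n), function(i) {
        as.integer(floor(runif(1, 0, chrom_sizes[[chrom[i]]] - w[i] + 1)))
      }, integer(1))
    } else {
      if (is.null(genes) || nrow(genes) == 0) {
        abort("tss_overlapping background requires `genes`")
      }
      g <- genes_as_tibble(genes)
      idx <- sample(nrow(g), n, replace = TRUE)
      chrom <- g$chrom[idx]
      start <- vapply(seq_len(n), function(i) {
        L <- chrom_sizes[[chrom[i]]]
        tss <- g$tss[idx[i]]
        lo <- max(0, tss - w[i] + 1); hi <- min(tss, L - w[i])
        if (hi < lo) abort("tss_overlapping constraint unsatisfiable for a width")
        as.integer(floor(runif(1, lo, hi + 1)))
      }, integer(1))
    }
    tibble(chrom = chrom, start = start, end = start + w, width = w)
  })
}

#' Repeat-family enrichment of regions versus background
#'
#' For each repeat family (or any grouping column), counts how many query
#' regions and how many background intervals contain at least one element,
#' tests the 2x2 table with a two-sided Fisher's exact test, and reports
#' frequencies as elements per 1000 regions.
#'
#' @param regions Region tibble (chrom, start, end).
#' @param repeats Repeat tibble as from [read_repeats()].
#' @param background Size-matched random intervals, e.g. from
#'   [sample_background()].
#' @param by Grouping column of `repeats`: `"family"`, `"class"` or
#'   `"name"`.
#' @return Tibble per group: element frequencies per 1000 regions in each
#'   set, region counts containing >= 1 element, odds ratio and Fisher p.
#' @export
repeat_enrichment <- function(regions, repeats, background, by = "family") {
  r <- as_tibble(regions); b <- as_tibble(background); rep <- as_tibble(repeats)
  if (nrow(r) == 0) abort("empty region set")
  stopifnot(by %in% names(rep))
  rr <- ranges_of(r); br <- ranges_of(b)
  groups <- sort(unique(rep[[by]]))
  purrr::map(groups, function(g) {
    el <- ranges_of(rep[rep[[by]] == g, ])
    a_contains <- sum(IRanges::overlapsAny(rr, el))
    b_contains <- sum(IRanges::overlapsAny(br, el))
    n_el_a <- sum(IRanges::countOverlaps(rr, el))
    n_el_b <- sum(IRanges::countOverlaps(br, el))
    tab <- matrix(c(a_contains, nrow(r) - a_contains,
                    b_contains, nrow(b) - b_contains), nrow = 2)
    ft <- fisher.test(tab)
    tibble(
      group = g,
      freq_per_1000_regions = 1000 * n_el_a / nrow(r),
      freq_per_1000_background = 1000 * n_el_b / nrow(b),
      n_regions_with = a_contains, n_background_with = b_contains,
      odds_ratio = sample_odds_ratio(tab), p = ft$p.value
    )
  }) |> list_rbind()
}

#' Flag de novo acetylated SINEs
#'
#' SINE-class repeat elements overlapping (by at least 1 bp, half-open
#' adjacency excluded) any region of increased acetylation.
#'
#' @param plus_regions Regions of increased acetylation (chrom, start,
#'   end); rows with a `direction` column are filtered to `"increase"`.
#' @param repeats Repeat tibble; only `class == "SINE"` elements are
#'   considered.
#' @return The flagged SINE rows of `repeats`.
#' @export
acetylated_sines <- function(plus_regions, repeats) {
  r <- as_tibble(plus_regions)
  if ("direction" %in% names(r)) r <- r[r$direction == "increase", ]
  s <- as_tibble(repeats)
  s <- s[s$class == "SINE", ]
  if (nrow(s) == 0 || nrow(r) == 0) return(s[integer(0), ])
  s[IRanges::overlapsAny(ranges_of(s), ranges_of(r)), ]
}
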