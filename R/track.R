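#' Write the signed -log10(p) changes track
#'
#' Serializes differential regions as a browser-loadable wiggle track of
#' column bars: one BED-style data line per region whose height is
#' `-log10(p)` at the region peak for increases and `log10(p)` (negative)
#' for decreases. Only regions called below `alpha` are written.
#' Coordinates in the data lines are 0-based half-open, as in bedGraph.
#'
#' @param regions `acet_regions` tibble from [merge_significant()].
#' @param path Output file.
#' @param name Track name written in the `track type=wiggle_0` header.
#' @param alpha Regions with peak p-value >= `alpha` are excluded
#'   (defaults to the calling threshold stored on `regions`).
#' @return `path`, invisibly.
#' @export
write_changes_track <- function(regions, path, name = "H3K9K14ac_changes",
                                alpha = attr(regions, "alpha") %||% 1e-3) {
  stopifnot(is.data.frame(regions))
  r <- as_tibble(regions)
  header <- paste0('track type=wiggle_0 name="', name,
                   '" description="signed -log10(p) of differential acetylation"')
  if (nrow(r) == 0) {
    readr::write_lines(header, path)
    return(invisible(path))
  }
  r <- r[r$peak_score > -log10(alpha), ]
  height <- ifelse(r$direction == "increase", r$peak_score, -r$peak_score)
  lines <- paste(r$chrom, r$start, r$end, formatC(height, format = "g", digits = 12),
                 sep = "\t")
  readr::write_lines(c(header, lines), path)
  invisible(path)
}

#' Read a changes track back into regions
#'
#' Parses a wiggle/bedGraph track (bedGraph data lines, fixedStep or
#' variableStep blocks) of signed heights, merges overlapping-or-abutting
#' spans of the same sign into regions, and summarizes each direction.
#' Overlapping spans of opposite sign make the track ill-formed and raise
#' an error.
#'
#' @param path Track file.
#' @return List with `regions` (an `acet_regions` tibble whose
#'   `peak_score` is the maximum absolute height per region) and `summary`
#'   (per-direction count and width range).
#' @export
read_changes_track <- function(path) {
  gr <- rtracklayer::import(path)
  df <- tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    height = as.numeric(S4Vectors::mcols(gr)$score)
  )
  df <- df[df$height != 0, ]
  df$direction <- ifelse(df$height > 0, "increase", "decrease")
  # ill-formed if a position carries both signs
  if (nrow(df) > 1) {
    pos <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
    hits <- GenomicRanges::findOverlaps(pos, pos)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    clash <- q < s & df$direction[q] != df$direction[s]
    if (any(clash)) abort("ill-formed track: overlapping spans of opposite sign")
  }
  out <- list()
  for (dir in c("increase", "decrease")) {
    d <- df[df$direction == dir, ]
    if (nrow(d) == 0) next
    gr1 <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1L, d$end))
    red <- GenomicRanges::reduce(gr1, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    out[[dir]] <- tibble(
      chrom = as.character(GenomeInfoDb::seqnames(red)),
      start = GenomicRanges::start(red) - 1L,
      end = GenomicRanges::end(red),
      direction = dir,
      peak_score = map_dbl(revmap, ~ max(abs(d$height[.x]))),
      n_windows = lengths(revmap)
    )
  }
  regions <- dplyr::bind_rows(out)
  if (nrow(regions) == 0) {
    regions <- tibble(chrom = character(), start = integer(), end = integer(),
                      direction = character(), peak_score = double(),
                      n_windows = integer())
  }
  regions <- dplyr::arrange(regions, .data$chrom, .data$start, .data$direction)
  regions$width <- regions$end - regions$start
  regions <- structure(regions, class = c("acet_regions", class(regions)))
  list(regions = regions, summary = glance(regions))
}

#' Write regions as BED6
#'
#' @param regions `acet_regions` tibble.
#' @param path Output path. The name field carries the direction and the
#'   score field `round(100 * peak_score)`.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  r <- as_tibble(regions)
  lines <- paste(r$chrom, r$start, r$end,
                 ifelse(r$direction == "increase", "+dAc", "-dAc"),
                 round(100 * pmin(r$peak_score, 100)), ".", sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}
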