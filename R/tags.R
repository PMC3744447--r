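#' Construct a tag library
#'
#' A tag library holds the deduplicated, quality-filtered 5' mapping
#' positions of one ChIP-seq library, together with the chromosome sizes of
#' the assembly. Positions are 0-based base-pair offsets of the mapped 5'
#' end of each read.
#'
#' @param tags Tibble/data frame with columns `chrom` (character),
#'   `pos` (integer, 0-based 5' position) and `strand` (`"+"`/`"-"`).
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param name Library label used in reports.
#' @param dedup Collapse tags sharing (chrom, pos, strand) to one molecule?
#'   Clonal duplicates at the same position are treated as PCR artifacts.
#'
#' @return An object of class `tag_library`: a list with elements `name`,
#'   `chrom_sizes`, `tags` (tibble sorted by chrom, pos) and `n` (tag count
#'   after filtering).
#' @export
tag_library <- function(tags, chrom_sizes, name = "library", dedup = TRUE) {
  stopifnot(is.data.frame(tags), all(c("chrom", "pos", "strand") %in% names(tags)))
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    abort("`chrom_sizes` must be a named vector of chromosome lengths")
  }
  tags <- as_tibble(tags)[, c("chrom", "pos", "strand")]
  tags$chrom <- as.character(tags$chrom)
  tags$pos <- as.integer(tags$pos)
  unknown <- setdiff(unique(tags$chrom), names(chrom_sizes))
  if (length(unknown) > 0) {
    abort(paste0("tags on chromosomes absent from `chrom_sizes`: ",
                 paste(unknown, collapse = ", ")))
  }
  bad <- tags$pos < 0 | tags$pos >= chrom_sizes[tags$chrom]
  if (any(bad)) {
    abort(paste0(sum(bad), " tag position(s) outside [0, chromosome length)"))
  }
  if (dedup) tags <- dplyr::distinct(tags, .data$chrom, .data$pos, .data$strand)
  tags <- dplyr::arrange(tags, .data$chrom, .data$pos)
  structure(
    list(name = name, chrom_sizes = chrom_sizes, tags = tags, n = nrow(tags)),
    class = "tag_library"
  )
}

#' @export
print.tag_library <- function(x, ...) {
  cat("<tag_library> ", x$name, ": ", format(x$n, big.mark = ","), " tags on ",
      length(x$chrom_sizes), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' @export
tidy.tag_library <- function(x, ...) x$tags

#' @export
glance.tag_library <- function(x, ...) {
  tibble(name = x$name, n_tags = x$n, n_chrom = length(x$chrom_sizes),
         genome_bp = sum(x$chrom_sizes))
}

#' Read a chromosome-sizes table
#'
#' @param path Two-column TSV (chromosome, length in bp), no header.
#' @return Named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "size"),
                        col_types = "cd", progress = FALSE)
  setNames(df$size, df$chrom)
}

#' Load mapped tags from a BED-like file
#'
#' Reads a 6-column BED file of mapped reads (the score column carrying the
#' mapping quality), applies the mapping-quality filter, reduces each read
#' to its 5' genomic position (interval start for `+` reads, `end - 1` for
#' `-` reads) and collapses clonal duplicates so that every retained tag
#' derives from an independent molecule.
#'
#' @param path BED6 file: chrom, start, end, name, score (mapping quality),
#'   strand. 0-based half-open intervals.
#' @param chrom_sizes Named vector of chromosome lengths (see
#'   [read_chrom_sizes()]).
#' @param mapq_min Minimum mapping quality retained (default 10).
#' @param dedup Collapse duplicates at identical (chrom, position, strand)?
#' @param on_unknown_chrom `"skip"` (drop with a warning) or `"error"` for
#'   records on chromosomes absent from `chrom_sizes`.
#' @param name Library label.
#'
#' @return A [tag_library()].
#' @export
read_tags <- function(path, chrom_sizes, mapq_min = 10, dedup = TRUE,
                      on_unknown_chrom = c("skip", "error"),
                      name = basename(path)) {
  on_unknown_chrom <- match.arg(on_unknown_chrom)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    empty <- tibble(chrom = character(), pos = integer(), strand = character())
    return(tag_library(empty, chrom_sizes, name = name, dedup = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    abort(paste0("malformed BED line ", which(nf < 6)[1], " in ", path,
                 ": expected >= 6 tab-separated fields, got ", nf[nf < 6][1]))
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  mapq <- suppressWarnings(as.numeric(m[, 5]))
  bad <- which(is.na(start) | is.na(end) | is.na(mapq) | !m[, 6] %in% c("+", "-"))
  if (length(bad) > 0) {
    abort(paste0("malformed BED line ", bad[1], " in ", path))
  }
  df <- tibble(
    chrom = m[, 1],
    pos = ifelse(m[, 6] == "+", start, end - 1L),
    strand = m[, 6],
    mapq = mapq
  )
  df <- df[df$mapq >= mapq_min, ]
  unknown <- !df$chrom %in% names(chrom_sizes)
  if (any(unknown)) {
    if (on_unknown_chrom == "error") {
      abort(paste0("records on unknown chromosome(s): ",
                   paste(unique(df$chrom[unknown]), collapse = ", ")))
    }
    warn(paste0("skipping ", sum(unknown), " record(s) on unknown chromosome(s)"))
    df <- df[!unknown, ]
  }
  tag_library(df[, c("chrom", "pos", "strand")], chrom_sizes,
              name = name, dedup = dedup)
}

#' Write a tag library as BED6
#'
#' Inverse of [read_tags()]: each tag becomes a 1-bp interval at its 5'
#' position with score 60.
#'
#' @param lib A [tag_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tags <- function(lib, path) {
  stopifnot(inherits(lib, "tag_library"))
  t <- lib$tags
  lines <- paste(t$chrom, t$pos, t$pos + 1L, "tag", 60L, t$strand, sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Count tags falling in one genomic window
#'
#' Counts tags whose 5' position lies in the half-open interval
#' `[start, start + width)`. A window running past the chromosome end is
#' truncated and flagged.
#'
#' @param lib A [tag_library()].
#' @param chrom Chromosome name.
#' @param start 0-based window start.
#' @param width Window width in bp.
#' @return Integer count with attribute `truncated` (logical).
#' @export
count_window <- function(lib, chrom, start, width) {
  stopifnot(inherits(lib, "tag_library"))
  L <- lib$chrom_sizes[[chrom]]
  if (is.null(L)) abort(paste0("unknown chromosome: ", chrom))
  if (start < 0 || start >= L) abort("window start outside chromosome")
  end <- min(start + width, L)
  p <- lib$tags$pos[lib$tags$chrom == chrom]
  k <- sum(p >= start & p < end)
  structure(as.integer(k), truncated = (start + width > L))
}
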