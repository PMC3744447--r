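# ggplot2 views of the main result types

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_rect geom_col
#'   geom_segment geom_histogram facet_wrap labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a TSS tag-density metaprofile
#'
#' @param object A `tss_profile` from [tss_tag_density_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tss_profile <- function(object, ...) {
  bin <- attr(object, "bin")
  ggplot(as_tibble(object),
         aes(x = .data$offset + bin / 2, y = .data$mean_density,
             colour = .data$group)) +
    geom_line() +
    labs(x = "position relative to TSS (bp)",
         y = sprintf("mean tags per %d-bp bin", bin), colour = "group") +
    theme_minimal()
}

#' Plot an acetylated-SINE density profile
#'
#' Group means per offset, with horizontal bars marking offsets where the
#' tested pair differs at P < 0.05 (two-tailed Mann-Whitney).
#'
#' @param object A `sine_profile` from [sine_density_profile()].
#' @param sig_level Significance level for the bars (default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sine_profile <- function(object, sig_level = 0.05, ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(x = .data$offset / 1000, y = .data$mean_density,
                      colour = .data$group)) +
    geom_line() +
    labs(x = "position relative to TSS (kbp)",
         y = sprintf("mean SINEs per %g-kbp window", attr(object, "window") / 1000),
         colour = "group") +
    theme_minimal()
  tests <- profile_tests(object)
  if (!is.null(tests)) {
    sig <- tests[!is.na(tests$p) & tests$p < sig_level &
                   tests$higher_in == attr(object, "test_pair")[1], ]
    if (nrow(sig) > 0) {
      step <- diff(sort(unique(df$offset)))[1]
      p <- p + geom_segment(
        data = sig,
        aes(x = (.data$offset - step / 2) / 1000,
            xend = (.data$offset + step / 2) / 1000),
        y = -0.02 * max(df$mean_density), yend = -0.02 * max(df$mean_density),
        colour = "red", linewidth = 2, inherit.aes = FALSE)
    }
  }
  p
}

#' Plot the width distribution of differential regions
#'
#' @param object An `acet_regions` tibble.
#' @param binwidth Histogram bin width in bp (default 500).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.acet_regions <- function(object, binwidth = 500, ...) {
  ggplot(as_tibble(object), aes(x = .data$width)) +
    geom_histogram(binwidth = binwidth, boundary = 0) +
    facet_wrap(~direction) +
    labs(x = "region width (bp)", y = "regions") +
    theme_minimal()
}

#' Column-bar view of a changes track
#'
#' Draws the signed -log10(p) region bars of one chromosome window, the
#' browser-style rendering of the changes track.
#'
#' @param regions `acet_regions` tibble.
#' @param chrom Chromosome to draw.
#' @param from,to Optional bp limits.
#' @return A ggplot.
#' @export
plot_changes_track <- function(regions, chrom, from = NULL, to = NULL) {
  r <- as_tibble(regions)
  r <- r[r$chrom == chrom, ]
  if (!is.null(from)) r <- r[r$end > from, ]
  if (!is.null(to)) r <- r[r$start < to, ]
  r$height <- ifelse(r$direction == "increase", r$peak_score, -r$peak_score)
  ggplot(r) +
    geom_rect(aes(xmin = .data$start / 1000, xmax = .data$end / 1000,
                  ymin = pmin(0, .data$height), ymax = pmax(0, .data$height),
                  fill = .data$direction)) +
    labs(x = sprintf("%s position (kbp)", chrom), y = "signed -log10(p)") +
    theme_minimal()
}
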