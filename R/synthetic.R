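# Seeded generators for every input the pipeline consumes, each returning
# ground truth alongside the data. All randomness is routed through an
# explicit integer seed (withr::with_seed), so outputs are byte-identical
# per seed.

#' Simulate a pair of ChIP-seq tag libraries with spiked windows
#'
#' Background tags are placed uniformly at `background_rate` tags per bp
#' in both libraries; each spiked interval receives `ratio`-fold the
#' background rate in library A only. Counts are Poisson; positions are
#' uniform; clonal duplicates at identical (chromosome, position, strand)
#' are collapsed, as in real libraries.
#'
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param background_rate Tags per bp per library (default 0.0075, i.e. a
#'   mean of 15 tags per 2-kb window).
#' @param spikes Tibble `chrom`, `start`, `end`, `ratio` of enriched
#'   intervals (ratio > 0; 1 = null), or `NULL`.
#' @param seed Integer seed.
#' @param names Labels of the two libraries.
#' @return List: `lib_a`, `lib_b` ([tag_library()]s) and `truth` (the
#'   spike table with exact spiked tag counts).
#' @export
sim_tag_libraries <- function(chrom_sizes, background_rate = 0.0075,
                              spikes = NULL, seed = 1,
                              names = c("condition", "control")) {
  stopifnot(background_rate > 0)
  if (!is.null(spikes)) {
    stopifnot(all(c("chrom", "start", "end", "ratio") %in% colnames(spikes)),
              all(spikes$ratio > 0),
              all(spikes$chrom %in% base::names(chrom_sizes)),
              all(spikes$start >= 0),
              all(spikes$end <= chrom_sizes[spikes$chrom]))
  }
  withr::with_seed(seed, {
    draw_uniform <- function(rate) {
      purrr::imap(as.list(chrom_sizes), function(L, ch) {
        n <- rpois(1, rate * L)
        tibble(chrom = ch,
               pos = as.integer(floor(runif(n, 0, L))),
               strand = sample(c("+", "-"), n, replace = TRUE))
      }) |> list_rbind()
    }
    a <- draw_uniform(background_rate)
    b <- draw_uniform(background_rate)
    spiked_counts <- integer(0)
    if (!is.null(spikes) && nrow(spikes) > 0) {
      extra <- purrr::pmap(as.list(as_tibble(spikes)[, c("chrom", "start", "end", "ratio")]),
                           function(chrom, start, end, ratio) {
        n <- rpois(1, (ratio - 1) * background_rate * (end - start))
        n <- max(n, 0)
        tibble(chrom = chrom,
               pos = as.integer(floor(runif(n, start, end))),
               strand = sample(c("+", "-"), n, replace = TRUE))
      })
      spiked_counts <- vapply(extra, nrow, integer(1))
      a <- dplyr::bind_rows(a, list_rbind(extra))
    }
    truth <- if (is.null(spikes)) NULL else
      dplyr::mutate(as_tibble(spikes), n_spiked_tags = spiked_counts)
    list(
      lib_a = tag_library(a, chrom_sizes, name = names[1]),
      lib_b = tag_library(b, chrom_sizes, name = names[2]),
      truth = truth
    )
  })
}

#' Simulate a gene annotation with group-specific SINE placement
#'
#' Genes of the four expression-response groups (CS, CE, NI, NR) are laid
#' out on a regular pitch with random strands, far enough apart that
#' their +/-125-kb neighborhoods never interleave. Acetylated SINEs are
#' planted in two layers: a uniform genome-wide background common to all
#' groups, and a Poisson-distributed surplus per NI gene placed uniformly
#' inside a TSS-relative band (strand-oriented). The expression table is
#' generated consistently with the labels (NI fold >= `fold_threshold`
#' with adjusted p < 0.05, etc.).
#'
#' @param n_genes Named counts per group, e.g. `c(CS = 50, CE = 100, NI =
#'   100, NR = 20)`.
#' @param sine_band TSS-relative band (bp, downstream positive) of the NI
#'   surplus (default `c(20000, 75000)`).
#' @param sine_surplus Mean surplus SINEs per NI gene (Poisson; default 2).
#' @param background_sine_rate Acetylated SINEs per bp genome-wide
#'   (default 6e-6, about 0.3 per 50-kb window).
#' @param gene_pitch Spacing between consecutive TSSs (default 300 kb).
#' @param gene_length Gene body length (default 10 kb).
#' @param sine_width SINE element width (default 150 bp).
#' @param fold_threshold Induction threshold reproduced in the expression
#'   table (default 1.24).
#' @param seed Integer seed.
#' @return List: `genes` (with `group`), `repeats` (acetylated SINE
#'   table), `expression`, `chrom_sizes`, `truth` (per-gene planted
#'   surplus offsets).
#' @export
sim_annotation <- function(n_genes = c(CS = 50, CE = 100, NI = 100, NR = 20),
                           sine_band = c(20000, 75000), sine_surplus = 2,
                           background_sine_rate = 6e-6,
                           gene_pitch = 3e5, gene_length = 1e4,
                           sine_width = 150, fold_threshold = 1.24, seed = 1) {
  stopifnot(all(c("CS", "CE", "NI", "NR") %in% names(n_genes)),
            gene_pitch >= 2.6e5)
  n_tot <- sum(n_genes)
  L <- (n_tot + 1) * gene_pitch
  chrom_sizes <- c(chrS = L)
  withr::with_seed(seed, {
    group <- sample(rep(names(n_genes), n_genes))
    tss <- as.integer(seq_len(n_tot) * gene_pitch)
    strand <- sample(c("+", "-"), n_tot, replace = TRUE)
    genes <- tibble(
      gene_id = sprintf("g%04d", seq_len(n_tot)),
      chrom = "chrS",
      start = ifelse(strand == "+", tss, tss - gene_length + 1L),
      end = ifelse(strand == "+", tss + gene_length, tss + 1L),
      strand = strand, tss = tss, group = group
    )
    # background acetylated SINEs, uniform genome-wide
    n_bg <- rpois(1, background_sine_rate * L)
    bg_start <- sort(as.integer(floor(runif(n_bg, 0, L - sine_width))))
    # NI surplus inside the strand-oriented band
    ni <- genes[genes$group == "NI", ]
    n_extra <- rpois(nrow(ni), sine_surplus)
    extra <- purrr::map(seq_len(nrow(ni)), function(i) {
      if (n_extra[i] == 0) return(NULL)
      off <- floor(runif(n_extra[i], sine_band[1], sine_band[2]))
      pos <- if (ni$strand[i] == "+") ni$tss[i] + off else
        ni$tss[i] - off - sine_width
      tibble(gene_id = ni$gene_id[i], offset = as.integer(off),
             start = as.integer(pos))
    }) |> list_rbind()
    all_start <- c(bg_start, if (!is.null(extra) && nrow(extra)) extra$start)
    fam <- sample(c("B1", "B2", "B4", "MIR", "ID"), length(all_start),
                  replace = TRUE, prob = c(.4, .25, .2, .1, .05))
    repeats <- tibble(
      chrom = "chrS", start = as.integer(all_start),
      end = as.integer(all_start + sine_width),
      strand = sample(c("+", "-"), length(all_start), replace = TRUE),
      name = paste0(fam, "_el"), family = fam, class = "SINE"
    ) |> dplyr::arrange(.data$start)
    expression <- genes |>
      dplyr::transmute(
        gene_id = .data$gene_id,
        detected_ctrl = .data$group %in% c("CE", "NI", "NR"),
        detected_stim = .data$group %in% c("CE", "NI", "NR"),
        fold_change = dplyr::case_when(
          group == "NI" ~ runif(n_tot, fold_threshold, 3),
          group == "NR" ~ runif(n_tot, 1 / 3, 1 / fold_threshold),
          .default = runif(n_tot, 0.95, 1.05)
        ),
        adj_p = ifelse(.data$group %in% c("NI", "NR"),
                       runif(n_tot, 0, 0.049), runif(n_tot, 0.2, 1))
      )
    list(genes = genes, repeats = repeats, expression = expression,
         chrom_sizes = chrom_sizes,
         truth = list(surplus = extra, band = sine_band,
                      n_background = n_bg))
  })
}

#' Simulate sequences with planted motif instances
#'
#' Background sequences are i.i.d. uniform ACGT; a designated fraction
#' receives one maximal-scoring realization of the PWM consensus at a
#' recorded offset (ties at uninformative columns resolved randomly).
#'
#' @param n Number of sequences.
#' @param len Sequence length (bp).
#' @param plant_frac Fraction of sequences carrying a planted instance.
#' @param motif A [pwm()] (default [bbox_pwm()]).
#' @param seed Integer seed.
#' @return List: `seqs` (named character vector) and `truth`
#'   (seq_id, planted, offset, instance).
#' @export
sim_sequences <- function(n, len, plant_frac = 0.5, motif = bbox_pwm(),
                          seed = 1) {
  stopifnot(plant_frac >= 0, plant_frac <= 1, len >= motif$length)
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- sprintf("s%04d", seq_len(n))
    planted <- seq_len(n) <= round(plant_frac * n)
    planted <- sample(planted)
    offsets <- rep(NA_integer_, n)
    instances <- rep(NA_character_, n)
    sc <- motif$score[DNA_BASES, , drop = FALSE]
    for (i in which(planted)) {
      inst <- paste(vapply(seq_len(motif$length), function(j) {
        best <- which(sc[, j] == max(sc[, j]))
        DNA_BASES[if (length(best) == 1) best else sample(best, 1)]
      }, character(1)), collapse = "")
      off <- sample.int(len - motif$length + 1, 1) - 1L
      substr(seqs[i], off + 1, off + motif$length) <- inst
      offsets[i] <- off; instances[i] <- inst
    }
    list(seqs = seqs,
         truth = tibble(seq_id = names(seqs), planted = planted,
                        offset = offsets, instance = instances))
  })
}

# add an anisotropic Gaussian of peak `amp` at physical center `c_nm`
# (x,y,z) to a [y,x,z] array, evaluated within a 3-sigma box
add_gaussian <- function(arr, c_nm, sigma_nm, amp, voxel) {
  d <- dim(arr)
  cx <- c_nm[1] / voxel[1]; cy <- c_nm[2] / voxel[2]; cz <- c_nm[3] / voxel[3]
  sx <- sigma_nm[1] / voxel[1]; sy <- sigma_nm[2] / voxel[2]
  sz <- sigma_nm[3] / voxel[3]
  xr <- max(1, floor(cx - 3 * sx)):min(d[2], ceiling(cx + 3 * sx + 1))
  yr <- max(1, floor(cy - 3 * sy)):min(d[1], ceiling(cy + 3 * sy + 1))
  zr <- max(1, floor(cz - 3 * sz)):min(d[3], ceiling(cz + 3 * sz + 1))
  gx <- exp(-((xr - 0.5) - cx)^2 / (2 * sx^2))
  gy <- exp(-((yr - 0.5) - cy)^2 / (2 * sy^2))
  gz <- exp(-((zr - 0.5) - cz)^2 / (2 * sz^2))
  arr[yr, xr, zr] <- arr[yr, xr, zr] +
    amp * (gy %o% gx %o% gz)
  arr
}

#' Simulate a 3-channel confocal stack of one nucleus
#'
#' Builds an ellipsoidal DAPI-stained nucleus, `n_foci` Gaussian RNAPII
#' foci at grid-jittered voxel centers inside the nucleus with a minimum
#' pairwise separation, and one FISH spot per requested distance, placed
#' at exactly that physical distance from its nearest focus. Gaussian
#' read noise is added to every channel.
#'
#' @param dim Stack dimensions `c(ny, nx, nz)` in voxels (default 64, 64,
#'   24).
#' @param voxel Voxel sizes `c(dx, dy, dz)` in nm (default 100, 100, 200).
#' @param n_foci Number of RNAPII foci.
#' @param spot_distances_nm Numeric vector: one FISH spot per element,
#'   planted at that distance from its nearest focus. May be empty.
#' @param focus_amp,focus_sigma_nm Focus peak amplitude and isotropic
#'   in-plane sigma (default 0.7, `c(80, 80, 110)` nm).
#' @param spot_amp,spot_sigma_nm FISH spot shape (default 0.8, `c(110,
#'   110, 160)` nm).
#' @param nucleus_frac Ellipsoid semi-axes as a fraction of the half-size
#'   of the stack (default 0.85).
#' @param baseline_rnap RNAPII background inside the nucleus (default
#'   0.06).
#' @param noise_sd Gaussian read-noise SD (default 0.004).
#' @param min_sep_vox Minimum focus separation in voxels `c(y, x, z)`
#'   (default 6, 6, 4), chosen so that supra-threshold focus voxels of
#'   neighbouring foci can never touch.
#' @param seed Integer seed.
#' @return List: `stack` ([image_stack()]) and `truth` (foci centers,
#'   spot centers and exact planted distances, all in nm).
#' @export
sim_image_stack <- function(dim = c(64, 64, 24),
                            voxel = c(dx = 100, dy = 100, dz = 200),
                            n_foci = 12, spot_distances_nm = numeric(0),
                            focus_amp = 0.7, focus_sigma_nm = c(80, 80, 110),
                            spot_amp = 0.8, spot_sigma_nm = c(110, 110, 160),
                            nucleus_frac = 0.85, baseline_rnap = 0.06,
                            noise_sd = 0.004, min_sep_vox = c(6, 6, 4),
                            seed = 1) {
  stopifnot(n_foci >= 1)
  withr::with_seed(seed, {
    ny <- dim[1]; nx <- dim[2]; nz <- dim[3]
    ctr <- c(x = nx / 2 * voxel[[1]], y = ny / 2 * voxel[[2]],
             z = nz / 2 * voxel[[3]])
    semi <- c(x = nucleus_frac * nx / 2 * voxel[[1]],
              y = nucleus_frac * ny / 2 * voxel[[2]],
              z = nucleus_frac * nz / 2 * voxel[[3]])
    xs <- (seq_len(nx) - 0.5) * voxel[[1]]
    ys <- (seq_len(ny) - 0.5) * voxel[[2]]
    zs <- (seq_len(nz) - 0.5) * voxel[[3]]
    ell <- function(margin = 0) {
      ex <- ((xs - ctr["x"]) / (semi["x"] - margin))^2
      ey <- ((ys - ctr["y"]) / (semi["y"] - margin))^2
      ez <- ((zs - ctr["z"]) / (semi["z"] - margin))^2
      outer(outer(ey, ex, "+"), ez, "+") < 1  # [y,x,z]
    }
    inside <- ell(0)
    # candidate focus sites: voxel centers on a coarse grid, well inside
    core <- ell(3 * max(focus_sigma_nm))
    gy <- seq(2, ny - 1, by = min_sep_vox[1])
    gx <- seq(2, nx - 1, by = min_sep_vox[2])
    gz <- seq(2, nz - 1, by = min_sep_vox[3])
    cand <- expand.grid(y = gy, x = gx, z = gz)
    ok <- core[cbind(cand$y, cand$x, cand$z)]
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) < n_foci) {
      abort(paste0("cannot place ", n_foci, " foci: only ", nrow(cand),
                   " grid sites inside the nucleus core"))
    }
    pick <- cand[sample(nrow(cand), n_foci), , drop = FALSE]
    foci <- tibble(
      x_nm = (pick$x - 0.5) * voxel[[1]],
      y_nm = (pick$y - 0.5) * voxel[[2]],
      z_nm = (pick$z - 0.5) * voxel[[3]]
    )
    fm <- as.matrix(foci)
    rnap <- array(0, c(ny, nx, nz))
    rnap[inside] <- baseline_rnap
    for (i in seq_len(nrow(foci))) {
      rnap <- add_gaussian(rnap, fm[i, ], focus_sigma_nm, focus_amp, voxel)
    }
    fish <- array(0, c(ny, nx, nz))
    spots <- NULL
    for (d0 in spot_distances_nm) {
      placed <- FALSE
      for (try in 1:200) {
        anchor <- sample(nrow(foci), 1)
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        s <- fm[anchor, ] + d0 * u
        dists <- sqrt(colSums((t(fm) - s)^2))
        in_core <- all(s > 0) &&
          sum(((s[1] - ctr["x"]) / (semi["x"] - 3 * max(spot_sigma_nm)))^2 +
                ((s[2] - ctr["y"]) / (semi["y"] - 3 * max(spot_sigma_nm)))^2 +
                ((s[3] - ctr["z"]) / (semi["z"] - 3 * max(spot_sigma_nm)))^2) < 1
        # spots must stay resolvable from each other
        clear <- is.null(spots) ||
          all(sqrt((spots$x_nm - s[1])^2 + (spots$y_nm - s[2])^2 +
                     (spots$z_nm - s[3])^2) > 6 * max(spot_sigma_nm))
        if (in_core && clear && abs(min(dists) - d0) < 1e-6) {
          fish <- add_gaussian(fish, s, spot_sigma_nm, spot_amp, voxel)
          spots <- dplyr::bind_rows(spots, tibble(
            x_nm = s[1], y_nm = s[2], z_nm = s[3],
            planted_nm = d0, nearest_focus_nm = min(dists)))
          placed <- TRUE
          break
        }
      }
      if (!placed) abort("could not place a FISH spot at the requested distance")
    }
    dapi <- array(0, c(ny, nx, nz))
    dapi[inside] <- 0.75
    noisy <- function(a) {
      if (noise_sd > 0) a <- a + array(rnorm(length(a), 0, noise_sd), dim(a))
      pmin(pmax(a, 0), 1)
    }
    stack <- image_stack(
      list(dapi = noisy(dapi), rnap = noisy(rnap), fish = noisy(fish)),
      voxel = voxel
    )
    list(stack = stack,
         truth = list(foci = foci,
                      spots = spots %||% tibble(x_nm = double(), y_nm = double(),
                                                z_nm = double(),
                                                planted_nm = double(),
                                                nearest_focus_nm = double()),
                      nucleus = inside))
  })
}

#' Simulate a colocalization experiment over many cells
#'
#' Each synthetic cell carries one FISH spot which, with probability
#' `f_coloc`, is planted `near_nm` from its nearest RNAPII focus
#' (colocalized at the 225-nm rule) and otherwise `far_nm` away.
#'
#' @param n_cells Number of cells (default 50).
#' @param f_coloc True colocalized fraction.
#' @param near_nm,far_nm Planted near/far distances (default 100 and
#'   700 nm).
#' @param seed Integer seed.
#' @param ... Passed to [sim_image_stack()].
#' @return List: `cells` (list of per-cell stacks + truth) and `truth`
#'   (tibble cell, colocalized, planted_nm).
#' @export
sim_cells <- function(n_cells = 50, f_coloc = 0.6, near_nm = 100,
                      far_nm = 700, seed = 1, ...) {
  flags <- withr::with_seed(seed, runif(n_cells) < f_coloc)
  cells <- purrr::map(seq_len(n_cells), function(i) {
    d <- if (flags[i]) near_nm else far_nm
    sim_image_stack(spot_distances_nm = d, seed = seed + 1000L + i, ...)
  })
  list(cells = cells,
       truth = tibble(cell = seq_len(n_cells), colocalized = flags,
                      planted_nm = ifelse(flags, near_nm, far_nm)))
}
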