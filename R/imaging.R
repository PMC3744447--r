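# 3D immuno-DNA FISH analysis: nucleus masking, positive-voxel calling,
# object detection with intensity-weighted centroids, anisotropic
# nearest-positive-voxel distances and colocalization calls.
#
# Stacks are stored as [y, x, z] arrays; physical coordinates are voxel
# centers: x = (col - 0.5) * dx, y = (row - 0.5) * dy, z = (slice - 0.5) * dz,
# all in nm.

#' Construct a multi-channel 3D image stack
#'
#' @param channels Named list of 3D numeric arrays of identical dimension
#'   `[y, x, z]`, intensities in `[0, 1]`.
#' @param voxel Physical voxel size in nm, named `c(dx, dy, dz)`
#'   (default 100 x 100 x 200 nm; the 200-nm axial spacing matches a
#'   0.2-um confocal z-distance).
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel = c(dx = 100, dy = 100, dz = 200)) {
  stopifnot(is.list(channels), length(channels) > 0,
            !is.null(names(channels)), all(nzchar(names(channels))),
            length(voxel) == 3, all(voxel > 0))
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, integer(1)) != 3)) abort("channels must be 3D arrays")
  if (length(unique(lapply(dims, identity))) != 1) {
    abort("all channels must share the same dimensions")
  }
  names(voxel) <- c("dx", "dy", "dz")
  structure(list(channels = channels, voxel = voxel, dim = dims[[1]]),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat("<image_stack> ", paste(x$dim, collapse = " x "), " voxels [y,x,z], ",
      length(x$channels), " channel(s): ", paste(names(x$channels), collapse = ", "),
      "; voxel ", paste(x$voxel, collapse = "/"), " nm\n", sep = "")
  invisible(x)
}

#' Write / read an image stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are stored channel-major (all z slices of channel 1, then
#' channel 2, ...) as 32-bit float; the sidecar records channel names,
#' slice count and voxel sizes.
#'
#' @param stack An [image_stack()].
#' @param path TIFF path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path` invisibly (write) or an [image_stack()] (read).
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- list()
  for (ch in names(stack$channels)) {
    a <- pmin(pmax(stack$channels[[ch]], 0), 1)
    for (z in seq_len(stack$dim[3])) pages[[length(pages) + 1]] <- a[, , z]
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(channels = names(stack$channels), nz = stack$dim[3],
         voxel_nm = as.list(stack$voxel)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- meta$nz
  chans <- setNames(vector("list", length(meta$channels)), meta$channels)
  for (i in seq_along(meta$channels)) {
    sl <- pages[((i - 1) * nz + 1):(i * nz)]
    chans[[i]] <- array(unlist(sl), dim = c(dim(sl[[1]]), nz))
  }
  image_stack(chans, voxel = unlist(meta$voxel_nm))
}

# single global Otsu threshold of a 3D channel (EBImage's otsu is
# per-frame, so the stack is flattened into one frame first)
otsu_threshold <- function(v) {
  hi <- max(v)
  if (hi <= 0) abort("no nucleus found: channel is empty")
  img <- EBImage::Image(as.numeric(v) / hi, dim = c(length(v), 1))
  EBImage::otsu(img, range = c(0, 1), levels = 256) * hi
}

#' Label 26-connected components of a 3D mask
#'
#' @param mask Logical 3D array.
#' @return Integer array of the same dimension; 0 = background, components
#'   numbered from 1.
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3)
  lab <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  pos <- integer(prod(d))
  pos[idx] <- seq_along(idx)
  ai <- arrayInd(idx, d)
  offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  # half of the 26 neighbors: each undirected adjacency counted once
  offs <- offs[offs[, 3] > 0 |
                 (offs[, 3] == 0 & (offs[, 2] > 0 |
                                      (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]
  edges <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    nb <- sweep(ai, 2, offs[i, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nlin <- (nb[ok, 3] - 1) * d[1] * d[2] + (nb[ok, 2] - 1) * d[1] + nb[ok, 1]
    nid <- pos[nlin]
    hit <- nid > 0
    if (any(hit)) edges[[i]] <- cbind(which(ok)[hit], nid[hit])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(el) && nrow(el) > 0) g <- igraph::add_edges(g, t(el))
  lab[idx] <- as.integer(igraph::components(g)$membership)
  lab
}

#' Segment the cell nucleus from the DAPI channel
#'
#' Otsu threshold on the DAPI channel (single global threshold over the
#' stack), retention of the largest 26-connected component, and per-slice
#' hole filling. Fields containing several nuclei return only the largest
#' (single-cell contract; crop multi-cell fields upstream).
#'
#' @param stack An [image_stack()].
#' @param channel DAPI channel name (default `"dapi"`).
#' @return Logical 3D mask with attributes `n_voxels`.
#' @export
segment_nucleus <- function(stack, channel = "dapi") {
  stopifnot(inherits(stack, "image_stack"), channel %in% names(stack$channels))
  v <- stack$channels[[channel]]
  thr <- otsu_threshold(v)
  m <- v > thr
  if (!any(m)) abort("no nucleus found")
  lab <- label_components(m)
  sizes <- tabulate(lab[lab > 0])
  m <- lab == which.max(sizes)
  filled <- EBImage::fillHull(EBImage::Image(m * 1, dim = dim(m)))
  m <- as.array(filled) > 0
  structure(m, n_voxels = sum(m))
}

channel_stats <- function(v, mask) {
  x <- v[mask]
  m <- mean(x)
  list(mean = m, sd = sqrt(mean((x - m)^2)))  # population SD
}

#' Call positive voxels at mean + k SD within the nucleus
#'
#' A voxel is positive when it lies inside the mask and its intensity
#' strictly exceeds the nuclear mean plus `k` standard deviations
#' (population SD over the masked voxels). This per-cell adaptive
#' threshold absorbs staining-intensity differences between cells.
#'
#' @param stack An [image_stack()].
#' @param channel Channel name (e.g. the RNAPII-ser5P channel).
#' @param mask Logical nucleus mask from [segment_nucleus()].
#' @param k SD multiplier (default 1).
#' @return Logical 3D array of positive voxels.
#' @export
positive_voxels <- function(stack, channel, mask, k = 1) {
  stopifnot(inherits(stack, "image_stack"), channel %in% names(stack$channels),
            any(mask))
  v <- stack$channels[[channel]]
  st <- channel_stats(v, mask)
  if (st$sd == 0) {
    warn("constant channel inside mask: no positive voxels")
    return(array(FALSE, dim(v)))
  }
  mask & (v > st$mean + k * st$sd)
}

#' Detect 3D objects with intensity-weighted centroids
#'
#' Thresholds a channel inside a mask (mean + `k` SD by default, or an
#' absolute `threshold`), labels 26-connected components, drops components
#' below `min_volume` voxels, and reports each object's voxel volume,
#' integrated intensity and intensity-weighted center of mass in physical
#' nm.
#'
#' @param stack An [image_stack()].
#' @param channel Channel name.
#' @param mask Logical 3D mask restricting the search.
#' @param k SD multiplier of the default threshold rule (default 2).
#' @param threshold Absolute intensity threshold overriding the rule.
#' @param min_volume Minimum component size in voxels (default 2).
#' @return Tibble: `label`, `volume`, `total_intensity`, `x_nm`, `y_nm`,
#'   `z_nm`; the label array is attached as attribute `labels`.
#' @export
detect_objects <- function(stack, channel, mask = NULL, k = 2,
                           threshold = NULL, min_volume = 2) {
  stopifnot(inherits(stack, "image_stack"), channel %in% names(stack$channels))
  v <- stack$channels[[channel]]
  if (is.null(mask)) mask <- array(TRUE, dim(v))
  if (is.null(threshold)) {
    st <- channel_stats(v, mask)
    threshold <- st$mean + k * st$sd
  }
  pos <- mask & (v > threshold)
  lab <- label_components(pos)
  empty <- tibble(label = integer(), volume = integer(),
                  total_intensity = double(), x_nm = double(),
                  y_nm = double(), z_nm = double())
  if (!any(pos)) return(structure(empty, labels = lab))
  idx <- which(lab > 0)
  l <- lab[idx]
  keep_lab <- which(tabulate(l) >= min_volume)
  if (length(keep_lab) == 0) return(structure(empty, labels = lab))
  sel <- l %in% keep_lab
  idx <- idx[sel]; l <- l[sel]
  ai <- arrayInd(idx, dim(v))
  vox <- stack$voxel
  w <- v[idx]
  x <- (ai[, 2] - 0.5) * vox[["dx"]]
  y <- (ai[, 1] - 0.5) * vox[["dy"]]
  z <- (ai[, 3] - 0.5) * vox[["dz"]]
  tot <- rowsum(w, l)
  res <- tibble(
    label = seq_along(keep_lab),
    volume = as.integer(tabulate(l)[keep_lab]),
    total_intensity = as.numeric(tot),
    x_nm = as.numeric(rowsum(w * x, l) / tot),
    y_nm = as.numeric(rowsum(w * y, l) / tot),
    z_nm = as.numeric(rowsum(w * z, l) / tot)
  )
  relab <- array(0L, dim(v))
  relab[idx] <- match(l, keep_lab)
  structure(res, labels = relab)
}

#' Count transcription factories
#'
#' Number of 26-connected components of RNAPII-positive voxels (mean + k
#' SD rule of [positive_voxels()]) of at least `min_volume` voxels inside
#' the nucleus.
#'
#' @param stack An [image_stack()].
#' @param channel RNAPII channel name (default `"rnap"`).
#' @param mask Nucleus mask.
#' @param k SD multiplier (default 1).
#' @param min_volume Minimum focus size in voxels (default 2).
#' @return Integer count.
#' @export
count_factories <- function(stack, channel = "rnap", mask, k = 1, min_volume = 2) {
  pos <- positive_voxels(stack, channel, mask, k = k)
  lab <- label_components(pos)
  if (!any(pos)) return(0L)
  sum(tabulate(lab[lab > 0]) >= min_volume)
}

#' Distance from a point to the nearest positive voxel
#'
#' Minimum Euclidean distance, under anisotropic voxel scaling, from a
#' physical-coordinate point (e.g. a FISH-signal centroid) to the center
#' of any positive voxel — in all directions, not only within one
#' confocal plane.
#'
#' @param point_nm Numeric length-3 vector `c(x, y, z)` in nm.
#' @param positive Logical 3D array of positive voxels.
#' @param voxel Voxel sizes `c(dx, dy, dz)` in nm.
#' @return Distance in nm; `Inf` with a warning when no voxel is positive.
#' @export
nearest_positive_distance <- function(point_nm, positive, voxel) {
  stopifnot(length(point_nm) == 3, length(voxel) == 3)
  idx <- which(positive)
  if (length(idx) == 0) {
    warn("no positive voxel: distance is Inf")
    return(Inf)
  }
  ai <- arrayInd(idx, dim(positive))
  dx2 <- ((ai[, 2] - 0.5) * voxel[[1]] - point_nm[1])^2
  dy2 <- ((ai[, 1] - 0.5) * voxel[[2]] - point_nm[2])^2
  dz2 <- ((ai[, 3] - 0.5) * voxel[[3]] - point_nm[3])^2
  sqrt(min(dx2 + dy2 + dz2))
}

#' Score locus-to-factory colocalization
#'
#' A locus is scored as factory-associated when its distance to the
#' nearest RNAPII-positive voxel is at most `threshold_nm` (inclusive;
#' 225 nm by default, the distance at which the two smallest detectable
#' objects overlap).
#'
#' @param records Tibble with a `distance_nm` column.
#' @param threshold_nm Colocalization threshold in nm (default 225).
#' @return `records` with a logical `colocalized` column.
#' @export
colocalize <- function(records, threshold_nm = 225) {
  stopifnot(is.data.frame(records), "distance_nm" %in% names(records))
  dplyr::mutate(as_tibble(records),
                colocalized = .data$distance_nm <= threshold_nm)
}

#' Compare colocalization frequencies between two conditions
#'
#' Two-sided Fisher's exact test on the 2x2 table of colocalized versus
#' not across two groups of cells/loci.
#'
#' @param group_a,group_b Length-2 vectors `c(n_colocalized, n_total)`.
#' @return One-row tibble: per-group fractions, odds ratio, p.
#' @export
compare_colocalization <- function(group_a, group_b) {
  stopifnot(length(group_a) == 2, length(group_b) == 2,
            group_a[2] > 0, group_b[2] > 0,
            group_a[1] <= group_a[2], group_b[1] <= group_b[2])
  tab <- matrix(c(group_a[1], group_a[2] - group_a[1],
                  group_b[1], group_b[2] - group_b[1]), nrow = 2)
  ft <- fisher.test(tab)
  tibble(frac_a = group_a[1] / group_a[2], frac_b = group_b[1] / group_b[2],
         odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' RNA-FISH particle intensities
#'
#' Detects mRNA ribonucleoparticles on the FISH channel within a cell
#' mask ([detect_objects()] with the mean + k SD rule) and reports the
#' per-particle table together with the per-cell total fluorescence
#' intensity.
#'
#' @param stack An [image_stack()].
#' @param channel FISH channel name (default `"fish"`).
#' @param cell_mask Logical mask of the cell (e.g. a transfection-marker
#'   mask).
#' @param k SD multiplier (default 2).
#' @param min_volume Minimum particle size in voxels (default 2).
#' @return List: `particles` (tibble) and `total_intensity` (sum of
#'   integrated particle intensities; 0 when none detected).
#' @export
particle_intensities <- function(stack, channel = "fish", cell_mask, k = 2,
                                 min_volume = 2) {
  obj <- detect_objects(stack, channel, mask = cell_mask, k = k,
                        min_volume = min_volume)
  list(particles = obj, total_intensity = sum(obj$total_intensity))
}

#' Single-cell immuno-DNA FISH analysis
#'
#' Convenience wrapper running the full per-cell chain: nucleus
#' segmentation, RNAPII positive-voxel calling, FISH object detection,
#' nearest-positive-voxel distance and colocalization call for every
#' detected locus, plus the transcription-factory count.
#'
#' @param stack An [image_stack()] with DAPI, RNAPII and FISH channels.
#' @param dapi,rnap,fish Channel names.
#' @param k_rnap SD multiplier for RNAPII-positive voxels (default 1).
#' @param k_fish SD multiplier for FISH object detection (default 2).
#' @param min_volume Minimum object size in voxels (default 2).
#' @param threshold_nm Colocalization threshold (default 225).
#' @return Tibble, one row per detected FISH locus: object geometry,
#'   `distance_nm`, `colocalized`, `n_factories`.
#' @export
analyze_cell <- function(stack, dapi = "dapi", rnap = "rnap", fish = "fish",
                         k_rnap = 1, k_fish = 2, min_volume = 2,
                         threshold_nm = 225) {
  mask <- segment_nucleus(stack, dapi)
  pos <- positive_voxels(stack, rnap, mask, k = k_rnap)
  nf <- {
    lab <- label_components(pos)
    if (any(pos)) sum(tabulate(lab[lab > 0]) >= min_volume) else 0L
  }
  obj <- detect_objects(stack, fish, mask = mask, k = k_fish,
                        min_volume = min_volume)
  if (nrow(obj) == 0) {
    return(tibble(label = integer(), volume = integer(),
                  total_intensity = double(), x_nm = double(), y_nm = double(),
                  z_nm = double(), distance_nm = double(),
                  colocalized = logical(), n_factories = integer()))
  }
  obj$distance_nm <- vapply(seq_len(nrow(obj)), function(i) {
    nearest_positive_distance(c(obj$x_nm[i], obj$y_nm[i], obj$z_nm[i]),
                              pos, stack$voxel)
  }, numeric(1))
  obj <- colocalize(obj, threshold_nm)
  obj$n_factories <- nf
  obj
}
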