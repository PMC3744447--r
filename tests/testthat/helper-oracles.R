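# Independent brute-force oracles used to freeze expected values.
# Each is deliberately naive (enumeration / linear scan) and shares no
# code with the implementation it checks.

# exact one-sided binomial tails by pmf summation
oracle_binom_tails <- function(k_a, n, p0) {
  pmf <- vapply(0:n, function(k) choose(n, k) * p0^k * (1 - p0)^(n - k),
                numeric(1))
  list(p_inc = sum(pmf[(k_a:n) + 1]), p_dec = sum(pmf[(0:k_a) + 1]))
}

# two-sided Fisher p by full hypergeometric enumeration of tables with
# the observed margins; two-sided rule: sum of all table probabilities
# not exceeding the observed one (R's convention)
oracle_fisher_two_sided <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  lo <- max(0, n1 - m2); hi <- min(m1, n1)
  prob <- function(x) {
    choose(m1, x) * choose(m2, n1 - x) / choose(m1 + m2, n1)
  }
  ps <- vapply(lo:hi, prob, numeric(1))
  sum(ps[ps <= prob(a) * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
# (requires no ties across the pooled sample for exactness)
oracle_mw_two_sided <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(n, nx)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * (n - nx) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# linear-scan window count
oracle_count_tags <- function(pos, start, end) sum(pos >= start & pos < end)

# exhaustive nearest-positive-voxel distance by triple loop
oracle_nearest_distance <- function(point_nm, positive, voxel) {
  voxel <- unname(voxel); point_nm <- unname(point_nm)
  d <- dim(positive)
  best <- Inf
  for (z in seq_len(d[3])) for (x in seq_len(d[2])) for (y in seq_len(d[1])) {
    if (positive[y, x, z]) {
      dd <- sqrt(((x - 0.5) * voxel[1] - point_nm[1])^2 +
                   ((y - 0.5) * voxel[2] - point_nm[2])^2 +
                   ((z - 0.5) * voxel[3] - point_nm[3])^2)
      if (dd < best) best <- dd
    }
  }
  best
}

# tiny tag library straight from vectors
make_lib <- function(pos, chrom_sizes = c(chr1 = 1e4), strand = "+",
                     chrom = "chr1", name = "lib", dedup = FALSE) {
  tag_library(tibble::tibble(chrom = chrom, pos = as.integer(pos),
                             strand = strand),
              chrom_sizes, name = name, dedup = dedup)
}

# write a BED6 tag file from vectors
write_bed6 <- function(path, chrom, start, end, mapq, strand) {
  writeLines(paste(chrom, start, end, "r", mapq, strand, sep = "\t"), path)
}
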