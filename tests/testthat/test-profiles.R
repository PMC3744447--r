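test_that("Mann-Whitney backend matches enumeration and handles ties", {
  # worked value: complete separation of {1,2,3} vs {11,12,13}
  expect_equal(mann_whitney_p(1:3, 11:13), 0.1)
  expect_equal(oracle_mw_two_sided(1:3, 11:13), 0.1)
  expect_equal(mann_whitney_p(c(2, 2, 2), c(2, 2, 2)), 1)
  expect_equal(mann_whitney_p(rep(0, 5), rep(0, 4)), 1)
  # untied random samples, combined n <= 12: exact enumeration oracle
  set.seed(8)
  for (rep in 1:20) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    v <- sample(1:100, nx + ny)
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    expect_equal(mann_whitney_p(x, y), oracle_mw_two_sided(x, y),
                 tolerance = 1e-9)
  }
})

test_that("TSS tag profiles bin on strand-oriented coordinates", {
  cs <- c(chr1 = 100000)
  genes <- tibble::tibble(
    gene_id = c("plus", "minus"), chrom = "chr1",
    start = c(50000L, 20000L), end = c(55000L, 30000L),
    strand = c("+", "-"), group = c("A", "B")
  )
  # plus TSS = 50000; minus TSS = 29999
  lib <- make_lib(c(50150, 29999 - 150), chrom_sizes = cs)
  prof <- tss_tag_density_profile(lib, genes, bin = 100, range = 500)
  a <- prof[prof$group == "A", ]
  expect_equal(a$mean_density[a$offset == 100], 1)
  expect_equal(sum(a$mean_density), 1)
  b <- prof[prof$group == "B", ]
  expect_equal(b$mean_density[b$offset == 100], 1)
  expect_equal(sum(b$mean_density), 1)
  # no tags: all-zero profile
  prof0 <- tss_tag_density_profile(make_lib(integer(0), chrom_sizes = cs),
                                   genes, bin = 100, range = 500)
  expect_true(all(prof0$mean_density == 0))
})

test_that("bins past the chromosome edge are masked from the average", {
  cs <- c(chr1 = 10000)
  genes <- tibble::tibble(gene_id = "edge", chrom = "chr1", start = 300L,
                          end = 2000L, strand = "+")
  lib <- make_lib(c(50, 350), chrom_sizes = cs)
  prof <- tss_tag_density_profile(lib, genes, bin = 100, range = 500)
  # upstream bins beyond position 0 are NA-masked (n_genes drops to 0)
  expect_equal(prof$n_genes[prof$offset == -500], 0)
  expect_true(is.nan(prof$mean_density[prof$offset == -500]))
  expect_equal(prof$mean_density[prof$offset == -300], 1)
  expect_equal(prof$mean_density[prof$offset == 0], 1)
})

test_that("profiles are invariant under genome reflection", {
  cs <- c(chr1 = 200000); L <- cs[[1]]
  set.seed(5)
  pos <- sample(0:(L - 1), 400)
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:4), chrom = "chr1",
    start = c(40000L, 80000L, 120000L, 160000L),
    end = c(45000L, 85000L, 125000L, 165000L),
    strand = c("+", "-", "+", "-"), group = "all"
  )
  lib <- make_lib(pos, chrom_sizes = cs)
  flip_strand <- c(`+` = "-", `-` = "+")
  genes_r <- dplyr::mutate(genes,
                           start2 = L - end, end2 = L - start,
                           start = as.integer(start2), end = as.integer(end2),
                           strand = unname(flip_strand[strand])
  )[, names(genes)]
  lib_r <- make_lib(L - 1 - pos, chrom_sizes = cs)
  p1 <- tss_tag_density_profile(lib, genes, bin = 100, range = 2000)
  p2 <- tss_tag_density_profile(lib_r, genes_r, bin = 100, range = 2000)
  expect_equal(p1$mean_density, p2$mean_density)
})

test_that("promoter-window stats summarize groups and test pairs", {
  cs <- c(chr1 = 100000)
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:5), chrom = "chr1",
    start = seq(10000L, 50000L, 10000L), end = seq(12000L, 52000L, 10000L),
    strand = "+", group = c("hi", "hi", "lo", "lo", "solo")
  )
  # 10 tags in [tss, tss+500) for "hi" genes, none for "lo"
  pos <- as.vector(outer(seq(0, 450, 50), genes$start[1:2], "+"))
  lib <- make_lib(pos, chrom_sizes = cs)
  st <- tss_window_stats(lib, genes, window = c(0, 500), bin = 100)
  expect_equal(st$summary$median[st$summary$group == "hi"], 2)  # 10 tags / 5 bins
  expect_equal(st$summary$median[st$summary$group == "lo"], 0)
  # singleton group is summarized but never tested
  expect_false("solo" %in% c(st$tests$group_a, st$tests$group_b))
  expect_true(all(c("hi", "lo") %in% c(st$tests$group_a, st$tests$group_b)))
})

test_that("a SINE midpoint spans the inclusive window band of offsets", {
  cs <- c(chr1 = 1e6)
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 500000L,
                          end = 510000L, strand = "+", group = "NI")
  # element midpoint at TSS + 30000
  sines <- tibble::tibble(chrom = "chr1", start = 529925L, end = 530075L,
                          strand = "+", name = "B1_el", family = "B1",
                          class = "SINE")
  prof <- sine_density_profile(sines, genes, cs, test_pair = c("NI", "NI"))
  hit <- prof$offset[prof$mean_density > 0]
  expect_equal(hit, seq(5000, 55000, 5000))
  # no acetylated SINE within reach: zero profile
  far <- dplyr::mutate(sines, start = 900000L, end = 900150L)
  prof0 <- sine_density_profile(far, genes, cs, test_pair = c("NI", "NI"))
  expect_true(all(prof0$mean_density == 0))
})

test_that("group SINE density equals the mean of per-gene profiles", {
  ann <- sim_annotation(n_genes = c(CS = 5, CE = 10, NI = 10, NR = 5),
                        seed = 31)
  prof <- sine_density_profile(ann$repeats, ann$genes, ann$chrom_sizes)
  for (grp in c("NI", "CE")) {
    per_gene <- lapply(which(ann$genes$group == grp), function(i) {
      one <- ann$genes[i, ]
      p1 <- sine_density_profile(ann$repeats, one, ann$chrom_sizes,
                                 test_pair = c("x", "y"))
      p1$mean_density
    })
    manual <- colMeans(do.call(rbind, per_gene), na.rm = TRUE)
    expect_equal(prof$mean_density[prof$group == grp], manual)
  }
})
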