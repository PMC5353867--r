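test_that("genotype_panel validates its pieces", {
  g <- matrix(c(0, 1, 2, 1), nrow = 2)
  expect_s3_class(toy_panel(g), "genotype_panel")
  expect_error(toy_panel(matrix(c(0, 3), 1)), "0/1/2")
  expect_error(toy_panel(matrix(c(0, NA), 1)), "missing")
  bad_map <- data.frame(marker_id = c("a", "b"), chromosome = c(1L, 1L),
                        position = c(200L, 100L))
  expect_error(genotype_panel(g, bad_map), "ordered")
  dup_map <- data.frame(marker_id = c("a", "a"), chromosome = 1L,
                        position = c(100L, 200L))
  expect_error(genotype_panel(g, dup_map), "unique")
})

test_that("filter_maf applies the threshold and is idempotent", {
  # frequencies {0.005, 0.01, 0.2, 0.5, 0.009} via explicit genotype columns
  n <- 1000
  p <- c(0.005, 0.01, 0.2, 0.5, 0.009)
  geno <- sapply(p, function(pk) {
    cnt <- round(2 * n * pk)
    c(rep(1, cnt), rep(0, n - cnt))  # exact allele counts
  })
  panel <- toy_panel(geno)
  expect_equal(maf(panel), p)
  kept <- filter_maf(panel, 0.01)
  expect_equal(kept$map$marker_id, c("m002", "m003", "m004"))
  # threshold 0 keeps everything polymorphic
  expect_equal(ncol(filter_maf(panel, 0)$genotypes), 5L)
  # idempotence
  expect_identical(filter_maf(kept, 0.01)$genotypes, kept$genotypes)
  # empty result names the threshold
  rare <- toy_panel(sapply(c(0.01, 0.02), function(pk)
    c(rep(1, round(2 * 100 * pk)), rep(0, 100 - round(2 * 100 * pk)))))
  expect_error(filter_maf(rare, 0.1), "0.1")
})

test_that("filter_maf matches a brute-force per-column scan on a random panel", {
  panel <- random_panel(80, 200, seed = 5)
  keep_oracle <- logical(200)
  for (k in 1:200) {                       # independent per-column loop
    pk <- sum(panel$genotypes[, k]) / (2 * 80)
    keep_oracle[k] <- min(pk, 1 - pk) >= 0.05
  }
  kept <- filter_maf(panel, 0.05)
  expect_identical(kept$map$marker_id, panel$map$marker_id[keep_oracle])
})

test_that("center_genotypes matches the definition and column sums vanish", {
  panel <- toy_panel(cbind(c(0, 1, 2), c(1, 1, 1)))
  W <- center_genotypes(panel)
  expect_equal(W[, 1], c(-1, 0, 1), ignore_attr = TRUE)   # p = 0.5
  expect_equal(W[, 2], c(0, 0, 0), ignore_attr = TRUE)    # degenerate column
  panel <- random_panel(50, 20, seed = 9)
  expect_lt(max(abs(colSums(center_genotypes(panel)))), 1e-9)
  # explicit frequency override
  W <- center_genotypes(panel, freq = rep(0.25, 20))
  expect_equal(W, panel$genotypes - 0.5, ignore_attr = TRUE)
})

test_that("partition_regions implements the window-and-merge rule", {
  map250 <- data.frame(marker_id = sprintf("a%03d", 1:250), chromosome = 1L,
                       position = 1:250 * 10L)
  p <- partition_regions(map250, "fixed_size", window = 100, merge_threshold = 50)
  expect_equal(p$n_snp, c(100L, 100L, 50L))   # remainder 50 stands alone
  map249 <- map250[1:249, ]
  p <- partition_regions(map249, "fixed_size", window = 100, merge_threshold = 50)
  expect_equal(p$n_snp, c(100L, 149L))        # remainder 49 merges
  # modes
  map2 <- rbind(map250, transform(map250, marker_id = sprintf("b%03d", 1:250),
                                  chromosome = 2L))
  expect_equal(nrow(partition_regions(map2, "all_snp")), 1L)
  pc <- partition_regions(map2, "per_chromosome")
  expect_equal(pc$chromosome, c(1L, 2L))
  expect_equal(pc$n_snp, c(250L, 250L))
  # tiny chromosome: one small region plus a warning
  map_small <- data.frame(marker_id = c(map250$marker_id, "z1", "z2"),
                          chromosome = c(map250$chromosome, 2L, 2L),
                          position = c(map250$position, 5L, 6L))
  expect_warning(ps <- partition_regions(map_small, "fixed_size", 100, 50),
                 "small region")
  expect_equal(ps$n_snp[nrow(ps)], 2L)
})

test_that("fixed-size partition of a 29-autosome 43,008-marker map lands near 430 regions", {
  set.seed(11)
  map <- bovine_like_map(43008L)
  p <- partition_regions(map, "fixed_size", window = 100, merge_threshold = 50)
  expect_gte(nrow(p), 415L)
  expect_lte(nrow(p), 431L)
  expect_true(all(p$n_snp >= 50L))
})

test_that("partitions cover every marker exactly once on random maps", {
  set.seed(21)
  for (rep in 1:20) {
    nchr <- sample(1:5, 1)
    counts <- sample(30:300, nchr, replace = TRUE)
    m <- sum(counts)
    map <- data.frame(marker_id = sprintf("s%05d", 1:m),
                      chromosome = rep(seq_len(nchr), counts),
                      position = as.integer(unlist(lapply(counts, function(n)
                        sort(sample.int(n * 50, n))))))
    mode <- sample(c("all_snp", "per_chromosome", "fixed_size"), 1)
    p <- suppressWarnings(partition_regions(map, mode, window = 70,
                                            merge_threshold = 35))
    idx <- unlist(Map(seq.int, p$first, p$last))
    expect_identical(sort(idx), 1:m)
    expect_identical(anyDuplicated(idx), 0L)
    expect_identical(region_labels(p),
                     rep.int(p$region_index, p$n_snp))
    # no region spans a chromosome boundary (except the whole-genome mode)
    if (mode != "all_snp")
      expect_true(all(map$chromosome[p$first] == map$chromosome[p$last]))
  }
})

test_that("drp_weights is (1-r2)/r2 by default and rejects the endpoints", {
  expect_equal(drp_weights(0.5), 1)
  expect_equal(drp_weights(0.8), 0.25)
  expect_equal(drp_weights(c(0.9, 0.5, 0.2)), c(1/9, 1, 4))
  expect_true(all(diff(drp_weights(c(0.2, 0.5, 0.9))) < 0))
  expect_error(drp_weights(1), "strictly inside")
  expect_error(drp_weights(0), "strictly inside")
  # pluggable alternative
  expect_equal(drp_weights(0.5, formula = function(r) 1 / r), 2)
})

test_that("drp_table and align_drp enforce the one-record-per-animal contract", {
  panel <- random_panel(5, 4, seed = 3)
  ids <- rownames(panel$genotypes)
  d <- drp_table(ids, rnorm(5), rep(0.6, 5))
  expect_equal(d$weight, rep(2/3, 5))
  expect_error(drp_table(c("a", "a"), 1:2, c(0.5, 0.5)), "duplicated")
  expect_error(align_drp(drp_table("ghost", 1, 0.5), panel), "no genotype")
  shuffled <- d[c(3, 1, 5, 2, 4), ]
  expect_equal(align_drp(shuffled, panel)$animal_id, ids)
})

test_that("harmonize_panels intersects maps and applies the joint MAF rule", {
  p1 <- random_panel(300, 40, seed = 31, pop = "A")
  p2 <- random_panel(300, 40, seed = 32, pop = "B")
  # make marker 5 rare in panel 2 only
  p2$genotypes[, 5] <- c(1, rep(0, 299))
  p2 <- genotype_panel(p2$genotypes, p2$map, "B")
  h <- harmonize_panels(p1, p2, maf_threshold = 0.01)
  expect_false("m005" %in% h[[1]]$map$marker_id)
  expect_identical(h[[1]]$map$marker_id, h[[2]]$map$marker_id)
  disjoint <- random_panel(10, 3, 1)
  disjoint$map$marker_id <- paste0("other_", disjoint$map$marker_id)
  colnames(disjoint$genotypes) <- disjoint$map$marker_id
  expect_error(harmonize_panels(p1, disjoint), "no markers")
})

test_that("genotype and phenotype files round-trip through the readers", {
  sim <- tiny_world(41, n = c(15L, 12L), chr = 2L, mpc = 10L)
  dir <- withr::local_tempdir()
  paths <- write_simulated_dataset(sim, dir)
  p1 <- read_plink_raw(paths["raw1"], paths["map1"], "pop1")
  expect_equal(p1$genotypes, sim$panels[[1]]$genotypes, ignore_attr = FALSE)
  expect_equal(p1$map, sim$panels[[1]]$map)
  d1 <- read_drp_tsv(paths["pheno"], population = "pop1")
  expect_equal(d1$drp, sim$drp1$drp, tolerance = 1e-10)
  expect_error(read_drp_tsv(paths["pheno"]), "population")
  bed <- file.path(dir, "regions.tsv")
  write_region_bed(sim$partition, sim$panels[[1]]$map, bed)
  reg <- read.table(bed, header = TRUE)
  expect_equal(reg$n_snp, sim$partition$n_snp)
  expect_equal(reg$start_bp,
               sim$panels[[1]]$map$position[sim$partition$first])
})

test_that("the VCF dosage reader agrees with hand-coded genotypes", {
  vcf <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
           "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
           "1\t200\tv2\tC\tT\t.\tPASS\t.\tGT\t0|1\t1|1\t0|0")
  f <- withr::local_tempfile(lines = vcf, fileext = ".vcf")
  panel <- read_vcf_dosage(f)
  expect_equal(unname(panel$genotypes),
               matrix(c(0, 1, 2, 1, 2, 0), nrow = 3))
  expect_equal(panel$map$position, c(100L, 200L))
  multi <- sub("\tG\t", "\tG,T\t", vcf[3], fixed = TRUE)
  f2 <- withr::local_tempfile(lines = c(vcf[1:2], multi), fileext = ".vcf")
  expect_error(read_vcf_dosage(f2), "multi-allelic")
})
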