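# Compact builders used across test files. All fixtures are generated in
# code under fixed seeds; nothing is read from disk.

# a small valid panel with given genotype columns
toy_panel <- function(geno, chromosome = NULL, pop = "pop") {
  geno <- as.matrix(geno)
  m <- ncol(geno)
  if (is.null(chromosome)) chromosome <- rep(1L, m)
  map <- data.frame(marker_id = sprintf("m%03d", seq_len(m)),
                    chromosome = chromosome,
                    position = as.integer(seq_len(m) * 1000 +
                                            1e7 * (chromosome - 1L)))
  genotype_panel(geno, map, population_id = pop)
}

# random panel with frequencies bounded away from 0/1
random_panel <- function(n, m, seed, pop = "pop") {
  set.seed(seed)
  p <- runif(m, 0.08, 0.5)
  geno <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
  toy_panel(geno, pop = pop)
}

# a marker map shaped like the 29-autosome 50K panel: chromosome marker
# counts proportional to approximate autosome physical lengths, scaled to a
# requested total
bovine_like_map <- function(total_markers = 43008L) {
  len <- c(158, 137, 121, 120, 120, 119, 112, 113, 105, 104, 107, 91, 84,
           84, 85, 81, 75, 66, 64, 72, 71, 61, 52, 62, 42, 51, 45, 46, 51)
  counts <- floor(total_markers * len / sum(len))
  counts[1] <- counts[1] + (total_markers - sum(counts))
  data.frame(marker_id = sprintf("snp%05d", seq_len(total_markers)),
             chromosome = rep(seq_along(counts), counts),
             position = as.integer(unlist(lapply(counts, function(n)
               sort(sample.int(n * 60000L, n))))))
}

# tiny two-population world for fast sampler tests
tiny_world <- function(seed, n = c(200L, 200L), chr = 2L, mpc = 100L, ...) {
  simulate_dataset(simulation_config(n_animals = n, n_chromosomes = chr,
                                     markers_per_chr = mpc, seed = seed,
                                     ...))
}

fast_mcmc <- function(seed, n_cycles = 2000L, burn_in = 800L, thin = 4L) {
  mcmc_config(n_cycles, burn_in, thin, seed = seed)
}
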