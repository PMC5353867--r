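#' MCMC settings for the Gibbs samplers
#'
#' The reference protocol for genome-scale analyses is 50,000 cycles with the
#' first 20,000 discarded as burn-in and every 20th of the remaining cycles
#' retained, giving 1,500 posterior samples. Desk-scale tests use shorter
#' chains.
#'
#' @param n_cycles total Gibbs cycles.
#' @param burn_in cycles discarded before storage starts.
#' @param thin store every \code{thin}-th post-burn-in cycle.
#' @param seed integer seed for the single R random stream driving the chain.
#' @param var_ceiling divergence guard: the sampler aborts with diagnostics
#'   if any variance draw exceeds this multiple of the pooled phenotypic
#'   variance.
#' @param start optional named list of start values (\code{sigma2_e},
#'   \code{sigma2_a}, \code{r}, \code{sigma2_r}; each length 2).
#' @return list of class \code{mcmc_config}.
#' @export
mcmc_config <- function(n_cycles = 50000L, burn_in = 20000L, thin = 20L,
                        seed = 1L, var_ceiling = 1e6, start = NULL) {
  stopifnot(burn_in < n_cycles, thin >= 1)
  structure(list(n_cycles = as.integer(n_cycles),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), var_ceiling = var_ceiling,
                 start = start),
            class = "mcmc_config")
}

#' Number of retained posterior samples under an MCMC configuration
#'
#' \code{(n_cycles - burn_in) \%/\% thin}; e.g. the reference protocol
#' (50,000 / 20,000 / 20) retains exactly 1,500 samples.
#'
#' @param mcmc an \code{\link{mcmc_config}}.
#' @return integer sample count.
#' @export
retained_samples <- function(mcmc) {
  (mcmc$n_cycles - mcmc$burn_in) %/% mcmc$thin
}

# shared front-end for both samplers
run_gibbs <- function(panels, drp_tables, partition, mcmc,
                      heterogeneous, update_shared = TRUE,
                      update_variances = TRUE) {
  stopifnot(length(panels) == 2, length(drp_tables) == 2,
            inherits(mcmc, "mcmc_config"))
  map1 <- panels[[1]]$map
  if (!identical(map1$marker_id, panels[[2]]$map$marker_id))
    stop("panels must share one harmonized map (see harmonize_panels)")
  if (is.null(partition))
    partition <- partition_regions(map1, mode = "all_snp")
  if (attr(partition, "n_markers") != nrow(map1))
    stop("partition does not index this map")
  if (any(partition$n_snp < 1)) stop("empty region in partition")
  reg <- region_labels(partition)
  J <- nrow(partition)

  drp <- list(align_drp(drp_tables[[1]], panels[[1]]),
              align_drp(drp_tables[[2]], panels[[2]]))
  keep1 <- match(drp[[1]]$animal_id, rownames(panels[[1]]$genotypes))
  keep2 <- match(drp[[2]]$animal_id, rownames(panels[[2]]$genotypes))
  W1 <- center_genotypes(panels[[1]])[keep1, , drop = FALSE]
  W2 <- center_genotypes(panels[[2]])[keep2, , drop = FALSE]
  y1 <- drp[[1]]$drp; y2 <- drp[[2]]$drp
  d1 <- drp[[1]]$weight; d2 <- drp[[2]]$weight

  p1 <- panels[[1]]$allele_freq; p2 <- panels[[2]]$allele_freq
  wv1 <- wv2 <- wc <- numeric(J)
  for (j in seq_len(J)) {
    idx <- partition$first[j]:partition$last[j]
    wv1[j] <- sum(2 * p1[idx] * (1 - p1[idx]))
    wv2[j] <- sum(2 * p2[idx] * (1 - p2[idx]))
    wc[j] <- sum(2 * sqrt(p1[idx] * (1 - p1[idx]) * p2[idx] * (1 - p2[idx])))
  }

  vary <- c(var(y1), var(y2))
  start <- list(sigma2_e = 0.5 * vary,
                sigma2_a = 0.5 * vary / c(sum(wv1), sum(wv2)),
                r = sqrt(0.25 * vary / c(sum(wv1), sum(wv2))),
                sigma2_r = 0.25 * vary / c(sum(wv1), sum(wv2)))
  if (!is.null(mcmc$start)) start <- modifyList(start, mcmc$start)
  ceiling_abs <- mcmc$var_ceiling * max(vary)

  set.seed(mcmc$seed)
  core <- .gibbs_core(W1, W2, y1, y2, d1, d2, as.integer(reg), J,
                      wv1, wv2, wc,
                      mcmc$n_cycles, mcmc$burn_in, mcmc$thin,
                      heterogeneous, update_shared, update_variances,
                      start$sigma2_e, start$sigma2_a, start$r,
                      start$sigma2_r, ceiling_abs)
  if (core$n_saved < 1) stop("no samples retained; check mcmc settings")

  # deviance at the posterior-mean parameters (for DIC)
  res1 <- y1 - core$post_mean_u[1] - drop(W1 %*% core$post_mean_a1)
  res2 <- y2 - core$post_mean_u[2] - drop(W2 %*% core$post_mean_a2)
  dev_mean <- sample_deviance(list(res1, res2), list(d1, d2),
                              core$post_mean_sigma2_e)

  structure(list(samples = core$samples,
                 n_regions = J,
                 partition = partition,
                 model = if (heterogeneous) "heterogeneous" else "homogeneous",
                 mcmc = mcmc,
                 post_mean_a = list(core$post_mean_a1, core$post_mean_a2),
                 post_mean_u = core$post_mean_u,
                 post_mean_sigma2_e = core$post_mean_sigma2_e,
                 deviance_at_mean = dev_mean,
                 freq_weights = list(wv1 = wv1, wv2 = wv2, wc = wc)),
            class = "posterior_chain")
}

#' Gibbs sampler: homogeneous multi-trait Bayesian rrBLUP
#'
#' SNP effects of the two populations are linked through one shared latent
#' vector s scaled by population scalars r_i, so every SNP carries the same
#' effect variance r_i^2 + sigma2_a*_i and cross-population covariance
#' r_1 r_2. Per retained draw the chain stores these per-SNP quantities, the
#' frequency-weighted genomic variances/covariances (per region of
#' \code{partition}, if given, and totals), residual variances and the
#' model deviance.
#'
#' @param panels list of two harmonized \code{\link{genotype_panel}}s.
#' @param drp_tables list of the two matching \code{\link{drp_table}}s.
#' @param mcmc an \code{\link{mcmc_config}}.
#' @param partition optional \code{region_partition} used only to report
#'   region-level sums (the model itself is homogeneous); default: whole
#'   genome as one region.
#' @return a \code{posterior_chain} object.
#' @export
gibbs_homogeneous <- function(panels, drp_tables, mcmc, partition = NULL) {
  run_gibbs(panels, drp_tables, partition, mcmc, heterogeneous = FALSE)
}

#' Gibbs sampler: heterogeneous (region-specific) multi-trait Bayesian rrBLUP
#'
#' Extends the homogeneous model with a second genome-length latent vector s1
#' whose region-j segment is scaled by region-by-population scalars r_ij (with
#' N(0, sigma2_r_i) priors), so region j carries SNP-effect variance
#' r_i^2 + r_ij^2 + sigma2_a*_i and cross-population covariance
#' r_1 r_2 + r_1j r_2j. With a single region the model reduces to the
#' homogeneous sampler plus one redundant channel.
#'
#' @inheritParams gibbs_homogeneous
#' @param partition a \code{region_partition} from
#'   \code{\link{partition_regions}} (required).
#' @return a \code{posterior_chain} object.
#' @export
gibbs_heterogeneous <- function(panels, drp_tables, partition, mcmc) {
  if (is.null(partition)) stop("heterogeneous model requires a partition")
  run_gibbs(panels, drp_tables, partition, mcmc, heterogeneous = TRUE)
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat(sprintf("posterior_chain (%s model): %d retained samples, %d region(s)\n",
              x$model, nrow(x$samples), x$n_regions))
  tot <- totals_and_h2(x)
  print(tot)
  invisible(x)
}

#' Posterior-mean genomic values from a Bayesian fit
#'
#' Returns, for each animal in each panel, the posterior-mean genomic value
#' under both populations' SNP effects: W_i \%*\% post-mean a_t for t = 1, 2.
#' The own-trait column is the Bayesian analogue of a GEBV.
#'
#' @param chain a \code{posterior_chain}.
#' @param panels the panels the chain was fitted on.
#' @return list of two matrices (animals x 2 traits), one per panel.
#' @export
genomic_values <- function(chain, panels) {
  stopifnot(inherits(chain, "posterior_chain"))
  lapply(1:2, function(i) {
    W <- center_genotypes(panels[[i]])
    out <- cbind(trait1 = drop(W %*% chain$post_mean_a[[1]]),
                 trait2 = drop(W %*% chain$post_mean_a[[2]]))
    rownames(out) <- rownames(panels[[i]]$genotypes)
    out
  })
}
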