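#' Configuration for the two-population synthetic generator
#'
#' The generator emulates the data structure the multi-trait models assume:
#' two populations genotyped on one shared marker map with population-specific
#' allele frequencies, SNP effects drawn per region from a 2x2
#' cross-population (co)variance matrix, and deregressed-proof phenotypes with
#' record-specific residual weights.
#'
#' Defaults describe a 50K-chip-like desk-scale world: 500 animals per
#' population on 5 chromosomes x 200 markers, base frequencies uniform
#' between 0.05 and 0.5 with a small cross-population perturbation, one region per
#' chromosome with per-SNP effect variance 0.2 and cross-population effect
#' correlation 0.6, population-1 reliabilities cow-like (mean 0.45) and
#' population-2 bull-like (mean 0.85), and residual variances giving
#' genomic-to-total variance ratios near 0.4 and 0.85 (mirroring the
#' magnitude classes reported for cow-dominated vs progeny-tested-bull DRP).
#'
#' @param n_animals length-2 integer, animals per population.
#' @param n_chromosomes number of autosomes.
#' @param markers_per_chr markers per chromosome (recycled).
#' @param freq_law function(m) returning m base allele frequencies.
#' @param freq_perturb_sd SD of the logit-scale perturbation that makes the
#'   two populations' frequencies differ (0 = identical frequencies).
#' @param region_mode,region_window,region_merge how truth regions are laid
#'   out (passed to \code{\link{partition_regions}}).
#' @param effect_var matrix (n_regions x 2) or length-2 vector of per-SNP
#'   effect variances per population (vector = same for every region).
#' @param effect_cor vector (length n_regions or 1) of cross-population
#'   per-SNP effect correlations.
#' @param reliability list of two functions(n) drawing reliabilities, or a
#'   length-2 numeric of constant reliabilities.
#' @param sigma2_e length-2 residual variances.
#' @param mean_drp length-2 overall means.
#' @param drp_scale length-2 multipliers applied to population DRP (and hence
#'   effects), emulating populations whose DRP are on different scales.
#' @param seed integer seed (consumed by the simulate_* functions).
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_animals = c(500L, 500L),
                              n_chromosomes = 5L,
                              markers_per_chr = 200L,
                              freq_law = function(m) runif(m, 0.05, 0.5),
                              freq_perturb_sd = 0.1,
                              region_mode = "per_chromosome",
                              region_window = 100L,
                              region_merge = 50L,
                              effect_var = c(0.2, 0.2),
                              effect_cor = 0.6,
                              reliability = c(0.45, 0.85),
                              sigma2_e = c(110, 13),
                              mean_drp = c(0, 0),
                              drp_scale = c(1, 1),
                              seed = 1L) {
  cfg <- list(n_animals = as.integer(n_animals),
              n_chromosomes = as.integer(n_chromosomes),
              markers_per_chr = rep_len(as.integer(markers_per_chr),
                                        n_chromosomes),
              freq_law = freq_law, freq_perturb_sd = freq_perturb_sd,
              region_mode = region_mode, region_window = region_window,
              region_merge = region_merge,
              effect_var = effect_var, effect_cor = effect_cor,
              reliability = reliability, sigma2_e = as.numeric(sigma2_e),
              mean_drp = as.numeric(mean_drp),
              drp_scale = as.numeric(drp_scale), seed = as.integer(seed))
  stopifnot(length(cfg$n_animals) == 2, all(cfg$n_animals > 0),
            length(cfg$sigma2_e) == 2, all(cfg$sigma2_e >= 0),
            all(abs(unlist(cfg["effect_cor"])) <= 1))
  if (is.numeric(cfg$reliability))
    stopifnot(all(cfg$reliability > 0 & cfg$reliability < 1))
  class(cfg) <- "simulation_config"
  cfg
}

sim_map <- function(config) {
  m <- sum(config$markers_per_chr)
  data.frame(
    marker_id = sprintf("snp%05d", seq_len(m)),
    chromosome = rep(seq_len(config$n_chromosomes), config$markers_per_chr),
    position = unlist(lapply(config$markers_per_chr, function(n)
      sort(sample.int(n * 60000L, n)))))
}

#' Simulate two genotype panels on a shared map
#'
#' Genotypes are independent binomial(2, p_ik) draws per marker and
#' population (no LD), where population frequencies derive from a common base
#' frequency with an optional logit-normal cross-population perturbation.
#' Markers whose realized MAF falls below 0.01 in either population are
#' redrawn with a fresh base frequency, so the returned panels need no further
#' MAF filtering.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list of two \code{\link{genotype_panel}} objects sharing one map.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  map <- sim_map(config)
  m <- nrow(map)
  n <- config$n_animals
  draw_freqs <- function(m) {
    p0 <- config$freq_law(m)
    if (any(p0 <= 0 | p0 >= 1)) stop("freq_law produced values outside (0,1)")
    perturb <- function(p) {
      if (config$freq_perturb_sd == 0) return(p)
      plogis(qlogis(p) + rnorm(length(p), 0, config$freq_perturb_sd))
    }
    cbind(perturb(p0), perturb(p0))
  }
  pmat <- draw_freqs(m)
  g1 <- matrix(rbinom(n[1] * m, 2L, rep(pmat[, 1], each = n[1])), nrow = n[1])
  g2 <- matrix(rbinom(n[2] * m, 2L, rep(pmat[, 2], each = n[2])), nrow = n[2])
  # redraw markers that fail MAF 0.01 in either population
  for (iter in 1:50) {
    maf1 <- pmin(colMeans(g1) / 2, 1 - colMeans(g1) / 2)
    maf2 <- pmin(colMeans(g2) / 2, 1 - colMeans(g2) / 2)
    bad <- which(maf1 < 0.01 | maf2 < 0.01)
    if (!length(bad)) break
    if (iter == 50)
      stop("frequency law infeasible: cannot reach MAF >= 0.01 in 50 redraws")
    pmat[bad, ] <- draw_freqs(length(bad))
    g1[, bad] <- rbinom(n[1] * length(bad), 2L,
                        rep(pmat[bad, 1], each = n[1]))
    g2[, bad] <- rbinom(n[2] * length(bad), 2L,
                        rep(pmat[bad, 2], each = n[2]))
  }
  rownames(g1) <- sprintf("p1_%05d", seq_len(n[1]))
  rownames(g2) <- sprintf("p2_%05d", seq_len(n[2]))
  list(genotype_panel(g1, map, "pop1"), genotype_panel(g2, map, "pop2"))
}

#' Simulate SNP effects, breeding values and DRP with known truth
#'
#' For each region j the per-SNP effect pairs (a_1k, a_2k) are i.i.d.
#' bivariate normal with the region's configured 2x2 (co)variance matrix --
#' the marginal distribution implied by the latent-scaling hierarchy, so the
#' Bayesian model is correctly specified for these data. True breeding values
#' are TBV_i = W_i a_i with W centered at the panel's own frequencies, and
#' DRP_n = mean_i + TBV_n + e_n with var(e_n) = d_n * sigma2_e_i, d_n the
#' reliability-derived weight.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param panels list of two panels from \code{\link{simulate_genotypes}}.
#' @return list with elements \code{drp1}, \code{drp2}
#'   (\code{\link{drp_table}}s), \code{truth} (a \code{simulation_truth}
#'   list: effects, TBV, per-region true V_g / covariance / correlation
#'   computed from the generating parameters and realized frequencies, plus
#'   the realized-effect versions), and \code{partition}.
#' @export
simulate_effects_and_drp <- function(config, panels) {
  stopifnot(inherits(config, "simulation_config"), length(panels) == 2)
  set.seed(config$seed + 104729L)  # separate stream from genotype draw
  map <- panels[[1]]$map
  part <- partition_regions(map, mode = config$region_mode,
                            window = config$region_window,
                            merge_threshold = config$region_merge)
  J <- nrow(part)
  ev <- config$effect_var
  if (is.null(dim(ev))) ev <- matrix(rep(ev, each = J), nrow = J)
  stopifnot(nrow(ev) == J, ncol(ev) == 2, all(ev >= 0))
  ec <- rep_len(config$effect_cor, J)
  m <- nrow(map)
  a1 <- numeric(m); a2 <- numeric(m)
  for (j in seq_len(J)) {
    idx <- part$first[j]:part$last[j]
    cv <- ec[j] * sqrt(ev[j, 1] * ev[j, 2])
    Sig <- matrix(c(ev[j, 1], cv, cv, ev[j, 2]), 2)
    eig <- eigen(Sig, symmetric = TRUE)
    if (any(eig$values < -1e-10))
      stop(sprintf("region %d effect (co)variance matrix is not PSD", j))
    L <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0))) %*% t(eig$vectors)
    z <- matrix(rnorm(2 * length(idx)), nrow = 2)
    aa <- L %*% z
    a1[idx] <- aa[1, ]; a2[idx] <- aa[2, ]
  }
  a1 <- a1 * config$drp_scale[1]
  a2 <- a2 * config$drp_scale[2]
  W1 <- center_genotypes(panels[[1]])
  W2 <- center_genotypes(panels[[2]])
  tbv1 <- drop(W1 %*% a1)
  tbv2 <- drop(W2 %*% a2)
  rel <- config$reliability
  draw_rel <- function(i, n) {
    if (is.numeric(rel)) rep(rel[i], n) else rel[[i]](n)
  }
  n <- config$n_animals
  r2_1 <- draw_rel(1, n[1]); r2_2 <- draw_rel(2, n[2])
  d1 <- drp_weights(r2_1); d2 <- drp_weights(r2_2)
  s2e <- config$sigma2_e * config$drp_scale^2
  y1 <- config$mean_drp[1] + tbv1 + rnorm(n[1], 0, sqrt(d1 * s2e[1]))
  y2 <- config$mean_drp[2] + tbv2 + rnorm(n[2], 0, sqrt(d2 * s2e[2]))
  drp1 <- drp_table(rownames(panels[[1]]$genotypes), y1, r2_1, "pop1")
  drp2 <- drp_table(rownames(panels[[2]]$genotypes), y2, r2_2, "pop2")
  truth <- sim_truth(panels, part, a1, a2, ev * rep(config$drp_scale^2,
                                                   each = J), ec,
                     tbv1, tbv2, s2e)
  list(drp1 = drp1, drp2 = drp2, truth = truth, partition = part)
}

# per-region truth, both from the generating parameters (formula route) and
# from the realized effect draws (empirical route)
sim_truth <- function(panels, part, a1, a2, ev, ec, tbv1, tbv2, sigma2_e) {
  J <- nrow(part)
  p1 <- panels[[1]]$allele_freq; p2 <- panels[[2]]$allele_freq
  out <- data.frame(region_index = part$region_index,
                    vg1 = NA_real_, vg2 = NA_real_, cov = NA_real_,
                    corr = NA_real_, vg1_realized = NA_real_,
                    vg2_realized = NA_real_, cov_realized = NA_real_)
  W1 <- center_genotypes(panels[[1]]); W2 <- center_genotypes(panels[[2]])
  for (j in seq_len(J)) {
    idx <- part$first[j]:part$last[j]
    cv <- ec[j] * sqrt(ev[j, 1] * ev[j, 2])
    out$vg1[j] <- region_variance_sum(p1[idx], ev[j, 1])
    out$vg2[j] <- region_variance_sum(p2[idx], ev[j, 2])
    out$cov[j] <- region_covariance_sum(p1[idx], p2[idx], cv)
    # realized: plug the empirical (co)variance of the drawn effects into the
    # same frequency-weighted sums
    emp <- stats::cov(cbind(a1[idx], a2[idx]))
    out$vg1_realized[j] <- region_variance_sum(p1[idx], emp[1, 1])
    out$vg2_realized[j] <- region_variance_sum(p2[idx], emp[2, 2])
    out$cov_realized[j] <- region_covariance_sum(p1[idx], p2[idx], emp[1, 2])
  }
  out$corr <- region_correlation(out$vg1, out$vg2, out$cov)
  totals <- list(vg1 = sum(out$vg1), vg2 = sum(out$vg2), cov = sum(out$cov))
  totals$corr <- totals$cov / sqrt(totals$vg1 * totals$vg2)
  structure(list(regions = out, totals = totals,
                 effects = cbind(a1 = a1, a2 = a2),
                 tbv = list(tbv1, tbv2), sigma2_e = sigma2_e),
            class = "simulation_truth")
}

#' Simulate a complete two-population dataset
#'
#' Convenience wrapper running \code{\link{simulate_genotypes}} then
#' \code{\link{simulate_effects_and_drp}}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with \code{panels}, \code{drp1}, \code{drp2}, \code{truth},
#'   \code{partition}.
#' @export
simulate_dataset <- function(config) {
  panels <- simulate_genotypes(config)
  out <- simulate_effects_and_drp(config, panels)
  out$panels <- panels
  out
}

#' Simulate records directly from the multi-trait GBLUP model
#'
#' Draws additive values for all animals from N(0, G0 kron G) given a
#' genomic relationship matrix, then records y_i = mean_i + a_i + e_i for
#' each population's own trait with var(e_n) = d_n * sigma2_e_i. This is the
#' exact generative model of the REML comparator, so its variance components
#' are recovered free of the SNP-effect-sampling noise the marker-based
#' generator carries.
#'
#' @param grm a \code{\link{build_grm}} result over the two populations.
#' @param G0 2x2 additive (co)variance matrix (PSD).
#' @param sigma2_e length-2 residual variances.
#' @param reliability length-2 reliabilities in (0,1) (constant per
#'   population).
#' @param mean_y length-2 overall means.
#' @param seed integer seed.
#' @return list with \code{drp1}, \code{drp2} and \code{truth} (list: G0,
#'   sigma2_e, a = the drawn additive values, animals x 2).
#' @export
simulate_gblup_dataset <- function(grm, G0, sigma2_e,
                                   reliability = c(0.45, 0.85),
                                   mean_y = c(0, 0), seed = 1L) {
  stopifnot(inherits(grm, "grm"), all(dim(G0) == c(2, 2)))
  if (min(eigen(G0, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("G0 is not positive semi-definite")
  set.seed(seed)
  N <- nrow(grm$G)
  eg <- eigen(grm$G, symmetric = TRUE)
  Lg <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
  e0 <- eigen(G0, symmetric = TRUE)
  L0 <- e0$vectors %*% diag(sqrt(pmax(e0$values, 0)))
  # a (N x 2) with cov G0 kron G:  a = Lg Z L0'
  a <- Lg %*% matrix(rnorm(2 * N), N, 2) %*% t(L0)
  i1 <- which(grm$pop_index == 1); i2 <- which(grm$pop_index == 2)
  d1 <- drp_weights(rep(reliability[1], length(i1)))
  d2 <- drp_weights(rep(reliability[2], length(i2)))
  y1 <- mean_y[1] + a[i1, 1] + rnorm(length(i1), 0, sqrt(d1 * sigma2_e[1]))
  y2 <- mean_y[2] + a[i2, 2] + rnorm(length(i2), 0, sqrt(d2 * sigma2_e[2]))
  ids <- rownames(grm$G)
  if (is.null(ids)) ids <- sprintf("animal_%05d", seq_len(N))
  list(drp1 = drp_table(ids[i1], y1, rep(reliability[1], length(i1)), "pop1"),
       drp2 = drp_table(ids[i2], y2, rep(reliability[2], length(i2)), "pop2"),
       truth = list(G0 = G0, sigma2_e = sigma2_e, a = a))
}

#' Write a simulated dataset to disk in the formats the readers accept
#'
#' Genotypes as PLINK-raw + map per population, phenotypes as one TSV, truth
#' as a structured TSV plus JSON sidecar of the totals.
#'
#' @param sim result of \code{\link{simulate_dataset}}.
#' @param dir output directory (created).
#' @return invisibly, the vector of written paths.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(raw1 = file.path(dir, "pop1.raw"),
             map1 = file.path(dir, "pop1.map"),
             raw2 = file.path(dir, "pop2.raw"),
             map2 = file.path(dir, "pop2.map"),
             pheno = file.path(dir, "drp.tsv"),
             truth = file.path(dir, "truth_regions.tsv"),
             truth_json = file.path(dir, "truth_totals.json"))
  write_plink_raw(sim$panels[[1]], paths["raw1"], paths["map1"])
  write_plink_raw(sim$panels[[2]], paths["raw2"], paths["map2"])
  write_drp_tsv(list(sim$drp1, sim$drp2), paths["pheno"])
  write.table(sim$truth$regions, paths["truth"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth$totals, paths["truth_json"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
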