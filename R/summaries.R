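#' Regional genomic variance from per-SNP effect variance
#'
#' The additive genomic variance contributed by a region is the sum over its
#' markers of 2 p (1 - p) times the per-SNP effect variance, with p the
#' coded-allele frequency in that population.
#'
#' @param freq coded-allele frequencies of the region's markers in the
#'   population.
#' @param var_a per-SNP effect variance for the region: either one scalar
#'   (the model's within-region assumption) or one value per marker.
#' @return scalar V_g for the region (trait units squared).
#' @export
region_variance_sum <- function(freq, var_a) {
  stopifnot(length(var_a) == 1L || length(var_a) == length(freq))
  sum(2 * freq * (1 - freq) * var_a)
}

#' Regional genomic covariance between two populations
#'
#' Sum over the region's markers of 2 sqrt(p1 (1-p1) p2 (1-p2)) times the
#' per-SNP cross-population effect covariance (geometric-mean frequency
#' weight). Reduces to \code{\link{region_variance_sum}} weighting when the
#' two populations share frequencies.
#'
#' @param freq1,freq2 coded-allele frequencies of the region's markers in
#'   populations 1 and 2.
#' @param cov_a per-SNP effect covariance (scalar or per marker).
#' @return scalar cross-population V_g for the region.
#' @export
region_covariance_sum <- function(freq1, freq2, cov_a) {
  stopifnot(length(freq1) == length(freq2),
            length(cov_a) == 1L || length(cov_a) == length(freq1))
  sum(2 * sqrt(freq1 * (1 - freq1) * freq2 * (1 - freq2)) * cov_a)
}

#' Regional genomic correlation
#'
#' R = C / sqrt(V1 * V2). Draws in which either variance is at or below the
#' numerical floor are flagged undefined (NA) rather than silently dropped;
#' callers report the excluded count.
#'
#' @param v1,v2 region genomic variances (vectors over draws allowed).
#' @param cv region genomic covariance.
#' @param floor numerical floor for the variances (default 1e-12 x the larger
#'   variance scale).
#' @return correlation(s); NA where undefined.
#' @export
region_correlation <- function(v1, v2, cv,
                               floor = 1e-12 * max(abs(v1), abs(v2), 1e-300)) {
  ok <- v1 > floor & v2 > floor
  out <- rep(NA_real_, length(cv))
  out[ok] <- cv[ok] / sqrt(v1[ok] * v2[ok])
  out
}

#' Deviance information criterion from a deviance trace
#'
#' Spiegelhalter form: DIC = mean(D) + pD with pD = mean(D) - D(theta_bar),
#' where D(theta_bar) is the deviance at the posterior mean of the model
#' parameters.
#'
#' @param deviance_trace post-burn-in deviance samples.
#' @param deviance_at_mean deviance evaluated at the posterior-mean
#'   parameters.
#' @return list with \code{dic}, \code{p_d}, \code{mean_deviance}.
#' @export
compute_dic <- function(deviance_trace, deviance_at_mean) {
  if (length(deviance_trace) < 30)
    stop("need at least 30 retained deviance samples for DIC")
  dbar <- mean(deviance_trace)
  p_d <- dbar - deviance_at_mean
  list(dic = dbar + p_d, p_d = p_d, mean_deviance = dbar)
}

#' Gaussian deviance of DRP records given a model state
#'
#' -2 x log likelihood of the records under the model's weighted Gaussian
#' residual, summed over both populations: for record n in population i with
#' residual e_n = y_n - u_i - (W a_i)_n,
#' contribution log(2 pi d_n sigma2_e_i) + e_n^2 / (d_n sigma2_e_i).
#'
#' @param residuals list of two residual vectors (one per population),
#'   already net of mean and genomic values.
#' @param weights list of the two residual-weight vectors d.
#' @param sigma2_e numeric length-2 vector of residual variances.
#' @return scalar deviance.
#' @export
sample_deviance <- function(residuals, weights, sigma2_e) {
  stopifnot(length(residuals) == 2, length(weights) == 2,
            length(sigma2_e) == 2)
  dev <- 0
  for (i in 1:2) {
    v <- weights[[i]] * sigma2_e[i]
    dev <- dev + sum(log(2 * pi * v) + residuals[[i]]^2 / v)
  }
  dev
}

#' Summarize a posterior chain into per-region genomic parameters
#'
#' Posterior median is the point estimate and the posterior standard
#' deviation over thinned samples is the standard error, for each region's
#' genomic variance in each population, the cross-population covariance and
#' the correlation. Proportions are the median variances (covariances)
#' divided by their sum over regions, so they sum to one exactly.
#'
#' @param chain a \code{posterior_chain} from \code{\link{gibbs_homogeneous}}
#'   or \code{\link{gibbs_heterogeneous}}.
#' @return data.frame (one row per region) of class
#'   \code{region_genomic_params} with estimates, SEs, proportions, and the
#'   count of draws where the correlation was undefined.
#' @export
summarize_regions <- function(chain) {
  stopifnot(inherits(chain, "posterior_chain"))
  J <- chain$n_regions
  S <- chain$samples
  get <- function(stub) S[, sprintf("%s_%d", stub, seq_len(J)), drop = FALSE]
  vg1 <- get("vg1"); vg2 <- get("vg2"); cv <- get("cov")
  corr <- matrix(NA_real_, nrow = nrow(S), ncol = J)
  floor_v <- 1e-12 * max(vg1, vg2)
  for (j in seq_len(J))
    corr[, j] <- region_correlation(vg1[, j], vg2[, j], cv[, j],
                                    floor = floor_v)
  med <- function(m) apply(m, 2, median)
  sdev <- function(m) apply(m, 2, sd)
  vg1_m <- med(vg1); vg2_m <- med(vg2); cv_m <- med(cv)
  out <- data.frame(
    region_index = seq_len(J),
    chromosome = chain$partition$chromosome,
    n_snp = chain$partition$n_snp,
    vg1 = vg1_m, vg1_se = sdev(vg1),
    vg2 = vg2_m, vg2_se = sdev(vg2),
    cov = cv_m, cov_se = sdev(cv),
    corr = apply(corr, 2, median, na.rm = TRUE),
    corr_se = apply(corr, 2, sd, na.rm = TRUE),
    n_undefined_corr = colSums(is.na(corr)),
    prop_vg1 = vg1_m / sum(vg1_m),
    prop_vg2 = vg2_m / sum(vg2_m),
    prop_cov = cv_m / sum(cv_m))
  class(out) <- c("region_genomic_params", "data.frame")
  out
}

#' Totals, heritabilities and DIC for a fitted model
#'
#' Totals are plain sums of the per-region genomic variances and covariances
#' (between-region covariances are ignored, by construction of the regional
#' decomposition). h2_i = Va_i / (Va_i + Ve_i) is the proportion of record
#' variance that is genomic, i.e. the reliability-like statistic reported
#' alongside DRP analyses.
#'
#' For a \code{posterior_chain} the totals/correlation are posterior medians
#' of the per-draw totals with posterior-SD standard errors, and DIC is
#' computed from the stored deviance trace. For REML
#' \code{variance_components} the asymptotic estimates are reported and DIC
#' is NA.
#'
#' @param fit a \code{posterior_chain} or \code{variance_components} object.
#' @return list of class \code{model_fit_report} with elements \code{va1},
#'   \code{va2}, \code{cov}, \code{corr} (each with \code{*_se}), \code{ve1},
#'   \code{ve2}, \code{h2_1}, \code{h2_2}, \code{dic}, \code{method}.
#' @export
totals_and_h2 <- function(fit) {
  if (inherits(fit, "posterior_chain")) {
    S <- fit$samples
    tot1 <- S[, "vg1_total"]; tot2 <- S[, "vg2_total"]
    ctot <- S[, "cov_total"]
    corr <- region_correlation(tot1, tot2, ctot)
    ve1 <- median(S[, "sigma2_e1"]); ve2 <- median(S[, "sigma2_e2"])
    dic <- compute_dic(S[, "deviance"], fit$deviance_at_mean)$dic
    rep_ <- list(va1 = median(tot1), va1_se = sd(tot1),
                 va2 = median(tot2), va2_se = sd(tot2),
                 cov = median(ctot), cov_se = sd(ctot),
                 corr = median(corr, na.rm = TRUE),
                 corr_se = sd(corr, na.rm = TRUE),
                 ve1 = ve1, ve2 = ve2,
                 dic = dic, method = paste0("mt_bayes_", fit$model))
  } else if (inherits(fit, "variance_components")) {
    rep_ <- list(va1 = fit$G0[1, 1], va1_se = fit$se["va1"],
                 va2 = fit$G0[2, 2], va2_se = fit$se["va2"],
                 cov = fit$G0[1, 2], cov_se = fit$se["cov12"],
                 corr = fit$correlation, corr_se = fit$se["corr"],
                 ve1 = fit$sigma2_e[1], ve2 = fit$sigma2_e[2],
                 dic = NA_real_, method = "mt_gblup")
  } else stop("unsupported fit object")
  rep_$h2_1 <- rep_$va1 / (rep_$va1 + rep_$ve1)
  rep_$h2_2 <- rep_$va2 / (rep_$va2 + rep_$ve2)
  class(rep_) <- "model_fit_report"
  rep_
}

#' @export
print.model_fit_report <- function(x, ...) {
  cat(sprintf("model fit report (%s)\n", x$method))
  cat(sprintf("  Va_1  %10.3f (%.3f)    Va_2 %10.3f (%.3f)\n",
              x$va1, x$va1_se, x$va2, x$va2_se))
  cat(sprintf("  Cov   %10.3f (%.3f)    Corr %9.3f (%.3f)\n",
              x$cov, x$cov_se, x$corr, x$corr_se))
  cat(sprintf("  Ve_1  %10.3f    Ve_2 %10.3f\n", x$ve1, x$ve2))
  cat(sprintf("  h2_1  %10.3f    h2_2 %10.3f    DIC %s\n", x$h2_1, x$h2_2,
              ifelse(is.na(x$dic), "NA", sprintf("%.1f", x$dic))))
  invisible(x)
}

#' Write per-region results as TSV
#'
#' Schema: region_index, chromosome, start_bp, end_bp, n_snp, Va_pop1,
#' Va_pop2, cov, corr, proportions, with SEs.
#'
#' @param params a \code{\link{summarize_regions}} result.
#' @param map marker map (for bp ranges); the partition used for the chain.
#' @param partition the \code{region_partition}.
#' @param file output path.
#' @export
write_region_results <- function(params, map, partition, file) {
  if (inherits(map, "genotype_panel")) map <- map$map
  out <- cbind(params[, "region_index", drop = FALSE],
               chromosome = map$chromosome[partition$first],
               start_bp = map$position[partition$first],
               end_bp = map$position[partition$last],
               params[, setdiff(names(params),
                                c("region_index", "chromosome"))])
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
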