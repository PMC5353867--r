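#' VanRaden method-1 genomic relationship matrix
#'
#' G = Z Z' / (2 sum p_k (1 - p_k)), with Z the allele-frequency-centered
#' genotype matrix of the combined set of animals from both populations and
#' p_k, by default, the coded-allele frequency observed in that combined set.
#'
#' @param panels a single \code{\link{genotype_panel}} or a list of two
#'   harmonized panels (rows are stacked population 1 then population 2).
#' @param freq_base \code{"combined"} (default) computes p_k from the stacked
#'   genotypes; \code{"given"} uses \code{freq}.
#' @param freq optional frequency vector when \code{freq_base = "given"}.
#' @param stabilize if TRUE, add 1e-6 to the diagonal only when a Cholesky
#'   factorization of G fails (off by default).
#' @return list of class \code{grm} with elements \code{G} (symmetric, with
#'   animal-id dimnames), \code{freq}, \code{scaling} (2 sum p(1-p)) and
#'   \code{pop_index} (1/2 label per row).
#' @export
build_grm <- function(panels, freq_base = c("combined", "given"),
                      freq = NULL, stabilize = FALSE) {
  freq_base <- match.arg(freq_base)
  if (inherits(panels, "genotype_panel")) panels <- list(panels)
  if (length(panels) == 2 &&
      !identical(panels[[1]]$map$marker_id, panels[[2]]$map$marker_id))
    stop("panels must be harmonized to one map before building G")
  M <- do.call(rbind, lapply(panels, function(p) p$genotypes))
  pop_index <- rep(seq_along(panels),
                   vapply(panels, function(p) nrow(p$genotypes), integer(1)))
  if (freq_base == "combined") {
    freq <- colMeans(M) / 2
  } else {
    stopifnot(!is.null(freq), length(freq) == ncol(M))
  }
  scaling <- 2 * sum(freq * (1 - freq))
  if (scaling <= 0)
    stop("all markers monomorphic at the chosen frequencies: scaling constant <= 0")
  Z <- sweep(M, 2, 2 * freq, "-")
  G <- tcrossprod(Z) / scaling
  if (stabilize && inherits(try(chol(G), silent = TRUE), "try-error"))
    G <- G + diag(1e-6, nrow(G))
  structure(list(G = G, freq = unname(freq), scaling = scaling,
                 pop_index = pop_index),
            class = "grm")
}

# V, its derivative structure and the projected quantities for model 5:
# y = (y1; y2), V = [va1 G11 + ve1 D1, c12 G12; c12 G21, va2 G22 + ve2 D2]
reml_build_V <- function(theta, Gb, D1, D2, n1, n2) {
  V <- matrix(0, n1 + n2, n1 + n2)
  i1 <- seq_len(n1); i2 <- n1 + seq_len(n2)
  V[i1, i1] <- theta[1] * Gb$G11 + diag(theta[4] * D1, n1)
  V[i2, i2] <- theta[3] * Gb$G22 + diag(theta[5] * D2, n2)
  V[i1, i2] <- theta[2] * Gb$G12
  V[i2, i1] <- t(V[i1, i2])
  V
}

#' Bivariate REML for the multi-trait GBLUP model
#'
#' Fits the two-trait mixed model in which each animal carries a record for
#' exactly one trait (its population's DRP), the additive effects have
#' covariance G0 kron G, and the residuals are heteroscedastic with
#' per-record weights d and zero covariance between traits (no animal has
#' both records). Maximization is by average-information (AI) updates of
#' theta = (va1, cov12, va2, ve1, ve2) with step halving whenever an AI step
#' leaves the parameter space or decreases the restricted likelihood;
#' convergence requires both a small gradient norm and a small relative
#' parameter change. Asymptotic standard errors come from the inverse AI
#' matrix at convergence; the SE of the derived correlation is obtained by
#' the delta method.
#'
#' @param grm a \code{\link{build_grm}} result over both populations' animals.
#' @param drp_tables list of the two \code{\link{drp_table}}s (orders must
#'   match the G rows of their population blocks).
#' @param max_iter maximum AI iterations (default 100).
#' @param tol convergence tolerance (default 1e-6) on the scaled gradient
#'   norm and relative parameter change.
#' @param verbose print the likelihood trajectory.
#' @return list of class \code{variance_components}: \code{G0} (2x2),
#'   \code{sigma2_e} (length 2), \code{correlation}, \code{se} (named:
#'   va1, cov12, va2, ve1, ve2, corr), \code{loglik}, \code{trajectory},
#'   \code{iterations}, \code{boundary} flag, plus the data pieces needed by
#'   \code{\link{gebv_from_components}}.
#' @export
reml_bivariate <- function(grm, drp_tables, max_iter = 100L, tol = 1e-6,
                           verbose = FALSE) {
  stopifnot(inherits(grm, "grm"), length(drp_tables) == 2)
  i1 <- which(grm$pop_index == 1); i2 <- which(grm$pop_index == 2)
  n1 <- length(i1); n2 <- length(i2)
  if (nrow(drp_tables[[1]]) != n1 || nrow(drp_tables[[2]]) != n2)
    stop("each animal must carry exactly one record; table sizes disagree with G blocks")
  ids <- rownames(grm$G)
  if (!is.null(ids)) {
    if (!identical(drp_tables[[1]]$animal_id, ids[i1]) ||
        !identical(drp_tables[[2]]$animal_id, ids[i2]))
      stop("DRP record order must match the G-matrix animal order")
  }
  y <- c(drp_tables[[1]]$drp, drp_tables[[2]]$drp)
  D1 <- drp_tables[[1]]$weight; D2 <- drp_tables[[2]]$weight
  Gb <- list(G11 = grm$G[i1, i1], G22 = grm$G[i2, i2], G12 = grm$G[i1, i2])
  N <- n1 + n2
  X <- cbind(c(rep(1, n1), rep(0, n2)), c(rep(0, n1), rep(1, n2)))

  j1 <- seq_len(n1); j2 <- n1 + seq_len(n2)
  dV <- function(t) {       # derivative of V wrt theta[t], as a function
    M <- matrix(0, N, N)
    switch(t,
           { M[j1, j1] <- Gb$G11 },
           { M[j1, j2] <- Gb$G12; M[j2, j1] <- t(Gb$G12) },
           { M[j2, j2] <- Gb$G22 },
           { diag(M)[j1] <- D1 },
           { diag(M)[j2] <- D2 })
    M
  }

  restricted_ll <- function(theta) {
    V <- reml_build_V(theta, Gb, D1, D2, n1, n2)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    Vinv <- chol2inv(ch)
    XtVX <- crossprod(X, Vinv %*% X)
    chx <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(chx)) return(list(ll = -Inf))
    P <- Vinv - Vinv %*% X %*% chol2inv(chx) %*% crossprod(X, Vinv)
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                    sum(y * Py))
    list(ll = ll, P = P, Py = Py)
  }

  inside <- function(theta) {
    theta[1] > 0 && theta[3] > 0 && theta[4] > 0 && theta[5] > 0 &&
      abs(theta[2]) < 0.999 * sqrt(theta[1] * theta[3])
  }

  v1 <- var(drp_tables[[1]]$drp); v2 <- var(drp_tables[[2]]$drp)
  theta <- c(v1 / 2, 0, v2 / 2, v1 / 2, v2 / 2)
  names(theta) <- c("va1", "cov12", "va2", "ve1", "ve2")
  cur <- restricted_ll(theta)
  trajectory <- cur$ll
  AI <- NULL
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    dVs <- lapply(1:5, dV)
    grad <- numeric(5)
    PdPy <- vector("list", 5)
    for (t in 1:5) {
      dVt <- dVs[[t]]
      dPy <- drop(dVt %*% cur$Py)
      PdPy[[t]] <- drop(cur$P %*% dPy)
      grad[t] <- -0.5 * (sum(cur$P * dVt) - sum(cur$Py * dPy))
    }
    AI <- matrix(0, 5, 5)
    for (t in 1:5) for (u in t:5) {
      AI[t, u] <- 0.5 * sum((dVs[[t]] %*% cur$Py) * PdPy[[u]])
      AI[u, t] <- AI[t, u]
    }
    step <- tryCatch(solve(AI, grad), error = function(e) grad / max(diag(AI)))
    # step halving: stay inside the parameter space and never decrease ll
    accepted <- FALSE
    for (h in 0:24) {
      cand <- theta + step / 2^h
      if (!inside(cand)) next
      nxt <- restricted_ll(cand)
      if (nxt$ll >= cur$ll - 1e-10) {
        rel_change <- max(abs(cand - theta) / (abs(theta) + 1e-8))
        theta <- cand; cur <- nxt
        trajectory <- c(trajectory, cur$ll)
        accepted <- TRUE
        if (verbose)
          message(sprintf("iter %d  ll %.6f  |grad| %.3g", iter, cur$ll,
                          sqrt(sum(grad^2))))
        if (sqrt(sum(grad^2)) < tol * (1 + abs(cur$ll)) &&
            rel_change < 100 * tol) converged <- TRUE
        break
      }
    }
    if (!accepted) { converged <- sqrt(sum(grad^2)) < 1e-3 * (1 + abs(cur$ll)); break }
    if (converged) break
  }
  if (!converged) {
    err <- simpleError("REML did not converge")
    err$trajectory <- trajectory
    stop(err)
  }
  se <- sqrt(pmax(diag(solve(AI)), 0))
  names(se) <- names(theta)
  corr <- theta[2] / sqrt(theta[1] * theta[3])
  # delta method for the correlation
  gr <- c(-0.5 * corr / theta[1], 1 / sqrt(theta[1] * theta[3]),
          -0.5 * corr / theta[3], 0, 0)
  se <- c(se, corr = sqrt(max(drop(t(gr) %*% solve(AI) %*% gr), 0)))
  G0 <- matrix(c(theta[1], theta[2], theta[2], theta[3]), 2)
  boundary <- min(eigen(G0, symmetric = TRUE, only.values = TRUE)$values) <
    1e-8 * max(theta[1], theta[3])
  structure(list(G0 = G0, sigma2_e = unname(theta[4:5]),
                 correlation = unname(corr), se = se,
                 loglik = cur$ll, trajectory = trajectory,
                 iterations = length(trajectory) - 1L,
                 boundary = boundary,
                 n = c(n1, n2)),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("bivariate REML components (%d + %d records, %d iterations)\n",
              x$n[1], x$n[2], x$iterations))
  cat(sprintf("  G0: va1 %.4g  cov %.4g  va2 %.4g   corr %.3f (SE %.3f)\n",
              x$G0[1, 1], x$G0[1, 2], x$G0[2, 2], x$correlation,
              x$se["corr"]))
  cat(sprintf("  ve1 %.4g  ve2 %.4g   logL %.4f%s\n", x$sigma2_e[1],
              x$sigma2_e[2], x$loglik,
              if (x$boundary) "   [G0 at PSD boundary]" else ""))
  invisible(x)
}

#' GEBV for both traits from converged REML components
#'
#' BLUP solutions of the multi-trait GBLUP at the REML estimates: for every
#' genotyped animal, the predicted additive merit for both traits (including
#' the trait the animal has no record for), via a-hat = C V^{-1} (y - X b),
#' where C = Cov(a, y) under G0 kron G.
#'
#' @param grm the \code{\link{build_grm}} result used in the fit.
#' @param components a \code{\link{reml_bivariate}} result.
#' @param drp_tables the same DRP tables used in the fit.
#' @return data.frame: animal_id, population, gebv_trait1, gebv_trait2.
#' @export
gebv_from_components <- function(grm, components, drp_tables) {
  i1 <- which(grm$pop_index == 1); i2 <- which(grm$pop_index == 2)
  n1 <- length(i1); n2 <- length(i2); N <- n1 + n2
  y <- c(drp_tables[[1]]$drp, drp_tables[[2]]$drp)
  D1 <- drp_tables[[1]]$weight; D2 <- drp_tables[[2]]$weight
  G0 <- components$G0; ve <- components$sigma2_e
  Gb <- list(G11 = grm$G[i1, i1], G22 = grm$G[i2, i2], G12 = grm$G[i1, i2])
  theta <- c(G0[1, 1], G0[1, 2], G0[2, 2], ve[1], ve[2])
  V <- reml_build_V(theta, Gb, D1, D2, n1, n2)
  ch <- tryCatch(chol(V), error = function(e)
    stop("singular coefficient matrix at the REML estimates"))
  Vinv <- chol2inv(ch)
  X <- cbind(c(rep(1, n1), rep(0, n2)), c(rep(0, n1), rep(1, n2)))
  XtVX <- crossprod(X, Vinv %*% X)
  b <- solve(XtVX, crossprod(X, Vinv %*% y))
  resid <- drop(Vinv %*% (y - X %*% b))
  # Cov(a_t, y'): records of trait 1 sit on animals i1, trait 2 on i2
  C1 <- cbind(G0[1, 1] * grm$G[, i1], G0[1, 2] * grm$G[, i2])
  C2 <- cbind(G0[1, 2] * grm$G[, i1], G0[2, 2] * grm$G[, i2])
  gebv1 <- drop(C1 %*% resid)
  gebv2 <- drop(C2 %*% resid)
  data.frame(animal_id = if (!is.null(rownames(grm$G))) rownames(grm$G)
             else sprintf("animal_%d", seq_len(N)),
             population = grm$pop_index,
             gebv_trait1 = gebv1, gebv_trait2 = gebv2,
             stringsAsFactors = FALSE)
}
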