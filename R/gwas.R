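#' Frequency-based genotype imputation within subpopulations
#'
#' Each missing code is drawn Binomial(2, p) with p the counted-allele
#' frequency among non-missing members of the sample's subpopulation
#' (a documented stand-in for haplotype-cluster imputation, adequate for
#' unlinked loci). A locus entirely missing within a subpopulation falls
#' back to the global frequency, with a warning.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param subpopulations character vector assigning every sample to an
#'   imputation group (e.g. the three gene pools of the emulated system);
#'   defaults to the population labels.
#' @param seed integer seed (deterministic imputation).
#' @return the genotype object with no missing codes.
#' @export
imputeGenotypes <- function(ge, subpopulations = populations(ge),
                            seed = 1L) {
  codes <- genoCodes(ge)
  if (!anyNA(codes)) return(ge)
  pglob <- .alleleFreq(codes)
  withSeed(seed, {
    for (sp in unique(subpopulations)) {
      rows <- subpopulations == sp
      sub <- codes[rows, , drop = FALSE]
      p <- .alleleFreq(sub)
      bad <- !is.finite(p)
      if (any(bad & colSums(is.na(sub)) > 0)) {
        warning("locus entirely missing in subpopulation '", sp,
                "': global frequency used")
        p[bad] <- pglob[bad]
      }
      p[!is.finite(p)] <- 0.5          # all-missing everywhere: last resort
      miss <- which(is.na(sub), arr.ind = TRUE)
      if (nrow(miss))
        sub[miss] <- rbinom(nrow(miss), 2L, p[miss[, 2]])
      codes[rows, ] <- sub
    }
  })
  out <- ge
  SummarizedExperiment::assay(out, "codes") <- t(codes)
  out
}

#' VanRaden genomic relationship matrix
#'
#' K = Z Z' / (2 * sum(p(1-p))) with Z the genotype codes centered by
#' twice the allele frequency. Requires complete genotypes (impute
#' first) and at least two polymorphic loci.
#'
#' @param ge a complete [GenotypeExperiment-class] (or codes matrix).
#' @return n x n symmetric kinship matrix with sample ids as dimnames.
#' @export
vanRadenKinship <- function(ge) {
  codes <- if (is(ge, "GenotypeExperiment")) genoCodes(ge) else ge
  if (anyNA(codes)) stop("genotypes must be complete; impute first")
  p <- colMeans(codes) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all loci monomorphic: kinship undefined")
  Z <- sweep(codes, 2, 2 * p)
  K <- tcrossprod(Z) / denom
  dimnames(K) <- list(rownames(codes), rownames(codes))
  K
}

# ---- single-kinship mixed model machinery (EMMA-style) ----------------

# Precompute the spectral pieces shared by every response under the same
# fixed effects X and kinship K: the eigen system of S K S (S projecting
# off X) for the REML profile, and the eigen system of K for fast
# V^{-1} v products.
.mixedPrep <- function(X, K, ridge = 1e-6) {
  n <- nrow(X); q <- ncol(X)
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  M <- S %*% K %*% S
  ee <- eigen((M + t(M)) / 2, symmetric = TRUE)
  keep <- seq_len(n - q)
  lam <- ee$values[keep]
  if (any(lam < 1e-10)) lam <- lam + ridge
  eK <- eigen((K + t(K)) / 2, symmetric = TRUE)
  list(X = X, n = n, q = q, lam = lam,
       W = ee$vectors[, keep, drop = FALSE],
       U = eK$vectors, eps = pmax(eK$values, 0))
}

# REML profile over delta = sigma2_e / sigma2_g for one response, using
# a precomputed .mixedPrep. Returns variance components, GLS beta and a
# function vinvMult(v) computing V^{-1} v.
.remlFit <- function(prep, y) {
  n <- prep$n; q <- prep$q
  eta <- crossprod(prep$W, y)[, 1]
  obj <- function(logd) {
    d <- exp(logd)
    (n - q) * log(sum(eta^2 / (prep$lam + d))) + sum(log(prep$lam + d))
  }
  grid <- seq(-10, 10, length.out = 41)
  vals <- vapply(grid, obj, 0)
  i0 <- which.min(vals)
  opt <- optimize(obj, c(grid[max(1, i0 - 1)],
                         grid[min(length(grid), i0 + 1)]), tol = 1e-8)
  delta <- exp(opt$minimum)
  sigma_g <- sum(eta^2 / (prep$lam + delta)) / (n - q)
  sigma_e <- delta * sigma_g
  if (!is.finite(sigma_g) || sigma_g <= 0) {
    sigma_g <- 0; sigma_e <- var(y)
    if (!is.finite(sigma_e) || sigma_e <= 0) sigma_e <- 1
  }
  w <- 1 / (sigma_g * prep$eps + sigma_e)
  vinvMult <- function(v) {
    vt <- crossprod(prep$U, v)
    prep$U %*% (vt * w)
  }
  X <- prep$X
  ViX <- vinvMult(X)
  beta <- solve(crossprod(X, ViX), crossprod(ViX, y))
  list(delta = delta, sigma_g = sigma_g, sigma_e = sigma_e,
       beta = beta, vinvMult = vinvMult, vinv_w = w,
       reml_obj = -0.5 * opt$objective)
}

# ML log-likelihood of the same model (for BIC model selection across
# different fixed-effect sets, where REML values are not comparable).
.mlLogLik <- function(y, X, K) {
  n <- length(y)
  ee <- eigen((K + t(K)) / 2, symmetric = TRUE)
  U <- ee$vectors; eps <- pmax(ee$values, 0)
  yt <- crossprod(U, y)[, 1]
  Xt <- crossprod(U, X)
  nll <- function(logd) {
    d <- exp(logd)
    w <- 1 / (eps + d)
    XtWX <- crossprod(Xt, Xt * w)
    beta <- solve(XtWX, crossprod(Xt, yt * w))
    r <- yt - Xt %*% beta
    rss <- sum(w * r^2)
    s2 <- max(rss / n, 1e-12)     # a perfect candidate fit stays finite
    0.5 * (n * log(2 * pi * s2) + sum(log(eps + d)) + n)
  }
  grid <- seq(-10, 10, length.out = 41)
  vals <- vapply(grid, nll, 0)
  i0 <- which.min(vals)
  opt <- optimize(nll, c(grid[max(1, i0 - 1)],
                         grid[min(length(grid), i0 + 1)]), tol = 1e-8)
  -opt$objective
}

#' Forward BIC selection of fixed-effect covariates under the null MLM
#'
#' Candidates are tried in a fixed order (sex first, then principal
#' components in index order); a candidate enters the model if it lowers
#' the BIC of the no-marker mixed model (ML likelihood, k = fixed effects
#' + 2 variance components) by more than 2.
#'
#' @param phenotype numeric 0/1 life-history vector.
#' @param candidates named list of candidate covariate vectors, e.g.
#'   \code{list(sex = ..., PC1 = ..., PC2 = ..., PC3 = ...)}. Constant
#'   candidates are skipped.
#' @param kinship n x n kinship matrix.
#' @return character vector of selected candidate names (possibly empty),
#'   with attribute \code{"bic_trace"}.
#' @export
selectCovariates <- function(phenotype, candidates, kinship) {
  n <- length(phenotype)
  X <- matrix(1, n, 1)
  bic <- function(Xm) {
    ll <- .mlLogLik(phenotype, Xm, kinship)
    -2 * ll + (ncol(Xm) + 2) * log(n)
  }
  cur <- bic(X)
  trace <- data.frame(candidate = "(intercept)", bic = cur,
                      entered = TRUE)
  selected <- character(0)
  for (nm in names(candidates)) {
    v <- candidates[[nm]]
    if (length(unique(v[!is.na(v)])) < 2L) next
    v <- as.numeric(if (is.character(v) || is.factor(v))
      as.integer(factor(v)) else v)
    cand <- cbind(X, v)
    b <- bic(cand)
    entered <- (cur - b) > 2
    trace <- rbind(trace, data.frame(candidate = nm, bic = b,
                                     entered = entered))
    if (entered) { X <- cand; cur <- b; selected <- c(selected, nm) }
  }
  attr(selected, "bic_trace") <- trace
  selected
}

#' Kinship-corrected single-marker association tests
#'
#' Gaussian mixed model y = X beta + g + e with g ~ N(0, sigma2_g K):
#' variance components are estimated once by REML under the no-marker
#' null and reused for every marker (P3D), each marker entering as one
#' additional fixed effect tested by a Wald t-test. The binary phenotype
#' is modelled as Gaussian 0/1, as the emulated GWAS framework does.
#'
#' @param phenotype numeric 0/1 vector.
#' @param ge complete [GenotypeExperiment-class] (or codes matrix).
#' @param fixed matrix (or data.frame) of fixed-effect covariates, one
#'   row per sample, or NULL for intercept only.
#' @param kinship n x n kinship matrix; a non-positive-definite matrix is
#'   ridged by 1e-6.
#' @param q FDR level for the significance flag.
#' @return list of class \code{"MlmFit"}: \code{tests} (data.frame:
#'   locus, effect, se, p, significant), \code{sigma_g}, \code{sigma_e},
#'   \code{delta}, \code{by_threshold}, \code{lambda} (genomic
#'   inflation).
#' @export
fitMlmMarkerTests <- function(phenotype, ge, fixed = NULL, kinship,
                              q = 0.05) {
  codes <- if (is(ge, "GenotypeExperiment")) genoCodes(ge) else ge
  y <- as.numeric(phenotype)
  n <- length(y)
  stopifnot(nrow(codes) == n, nrow(kinship) == n)
  X0 <- cbind(`(Intercept)` = rep(1, n),
              if (!is.null(fixed)) as.matrix(fixed))
  ev <- min(eigen(kinship, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 1e-8) kinship <- kinship + 1e-6 * diag(n)
  prep <- .mixedPrep(X0, kinship)
  fit0 <- .remlFit(prep, y)
  Vinv <- prep$U %*% (t(prep$U) * fit0$vinv_w)
  Vy <- Vinv %*% y
  VX0 <- Vinv %*% X0
  ViG <- Vinv %*% codes                # n x m, one pass
  q0 <- ncol(X0)
  eff <- se <- pv <- rep(NA_real_, ncol(codes))
  for (j in seq_len(ncol(codes))) {
    gj <- codes[, j]
    if (sd(gj) == 0) next
    XtVX <- cbind(rbind(crossprod(X0, VX0), crossprod(gj, VX0)),
                  c(crossprod(X0, ViG[, j]), crossprod(gj, ViG[, j])))
    XtVy <- c(crossprod(X0, Vy), crossprod(gj, Vy))
    C <- tryCatch(solve(XtVX), error = function(e) NULL)
    if (is.null(C)) next
    beta <- C %*% XtVy
    k <- q0 + 1L
    eff[j] <- beta[k]
    se[j] <- sqrt(C[k, k])
    tval <- eff[j] / se[j]
    pv[j] <- 2 * pt(-abs(tval), df = n - k)
  }
  m <- sum(is.finite(pv))
  thr <- if (m >= 1) byFdrThreshold(m, q) else NA_real_
  tests <- data.frame(locus = colnames(codes), effect = eff, se = se,
                      p = pv, significant = is.finite(pv) & pv < thr,
                      row.names = NULL)
  structure(list(tests = tests, sigma_g = fit0$sigma_g,
                 sigma_e = fit0$sigma_e, delta = fit0$delta,
                 beta = fit0$beta, by_threshold = thr,
                 lambda = genomicInflation(pv)),
            class = "MlmFit")
}

#' @export
print.MlmFit <- function(x, ...) {
  cat(sprintf("MLM marker scan: %d loci, sigma_g = %.4f, sigma_e = %.4f\n",
              nrow(x$tests), x$sigma_g, x$sigma_e))
  cat(sprintf("  BY threshold %.3g; %d significant; lambda = %.3f\n",
              x$by_threshold, sum(x$tests$significant, na.rm = TRUE),
              x$lambda))
  invisible(x)
}

#' Residualize phenotype and genotypes for random-forest analysis
#'
#' Fits the no-marker mixed model to the phenotype and, with the same
#' model form (same fixed effects and kinship random effect, variance
#' components re-estimated per response), to every marker column as a
#' 0/1/2 response. Residuals are response minus fixed-effect fit minus
#' the kinship BLUP: r = y - X beta - g_hat, with
#' g_hat = sigma2_g K V^{-1} (y - X beta), i.e. r = sigma2_e V^{-1}
#' (y - X beta).
#'
#' @param phenotype numeric 0/1 vector.
#' @param ge complete [GenotypeExperiment-class] (or codes matrix).
#' @param fixed covariate matrix or NULL.
#' @param kinship n x n kinship matrix.
#' @return list of class \code{"ResidualData"}: \code{phenotype}
#'   (residual vector), \code{genotypes} (residual matrix, samples x
#'   loci).
#' @export
residualize <- function(phenotype, ge, fixed = NULL, kinship) {
  codes <- if (is(ge, "GenotypeExperiment")) genoCodes(ge) else ge
  y <- as.numeric(phenotype)
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(fixed)) as.matrix(fixed))
  ev <- min(eigen(kinship, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 1e-8) kinship <- kinship + 1e-6 * diag(n)
  prep <- .mixedPrep(X, kinship)
  residOf <- function(v) {
    if (sd(v) == 0) return(rep(0, n))
    f <- .remlFit(prep, v)
    r0 <- v - X %*% f$beta
    as.vector(f$sigma_e * f$vinvMult(r0))
  }
  G <- apply(codes, 2, residOf)
  dimnames(G) <- dimnames(codes)
  structure(list(phenotype = residOf(y), genotypes = G),
            class = "ResidualData")
}
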