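#' REML variance components for the kinship mixed model
#'
#' Fits `y = X beta + u + e` with `u ~ N(0, sigma2_g K)` and
#' `e ~ N(0, sigma2_e I)` by profiling the (restricted) likelihood over
#' `delta = sigma2_e / sigma2_g`. A single eigendecomposition of K
#' rotates the model so the covariance is diagonal; the profile
#' likelihood is then maximized by golden-section search on log(delta)
#' over [1e-5, 1e5]. The pseudo-heritability is
#' `sigma2_g / (sigma2_g + sigma2_e) = 1 / (1 + delta)`.
#'
#' @param y phenotype vector (complete cases).
#' @param X fixed-effect design matrix (full column rank, including the
#'   intercept).
#' @param K kinship matrix (symmetric PSD), or NULL when `eigen_K` is
#'   supplied.
#' @param eigen_K optional precomputed `eigen(K, symmetric = TRUE)`;
#'   pass it when fitting many phenotypes against one kinship.
#' @param method `"reml"` (default) or `"ml"` (used for information
#'   criteria).
#' @return A list of class `varcomp`: `sigma2_g`, `sigma2_e`,
#'   `pseudo_h2`, `delta`, `loglik` (at the chosen criterion), `method`.
#' @export
reml_variance_components <- function(y, X, K = NULL, eigen_K = NULL,
                                     method = c("reml", "ml")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop(
      "design matrix is rank deficient; collinear column(s): ",
      paste(bad, collapse = ", ")
    )
  }
  if (is.null(eigen_K)) eigen_K <- eigen(K, symmetric = TRUE)
  d <- pmax(eigen_K$values, 0)
  U <- eigen_K$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  p <- ncol(X)
  ldet_xx <- determinant(crossprod(Xt), logarithm = TRUE)$modulus

  crit <- function(logdelta) {
    delta <- exp(logdelta)
    w <- 1 / (d + delta)
    sw <- sqrt(w)
    Xs <- Xt * sw
    ys <- yt * sw
    fit <- stats::lm.fit(Xs, ys)
    rss <- sum(fit$residuals^2)
    if (method == "reml") {
      s2 <- rss / (n - p)
      ldet_xwx <- determinant(crossprod(Xs), logarithm = TRUE)$modulus
      -0.5 * ((n - p) * log(2 * pi * s2) + (n - p) -
        sum(log(w)) + ldet_xwx - ldet_xx)
    } else {
      s2 <- rss / n
      -0.5 * (n * log(2 * pi * s2) + n - sum(log(w)))
    }
  }
  opt <- stats::optimize(crit,
    interval = log(c(1e-5, 1e5)),
    maximum = TRUE, tol = 1e-8
  )
  # guard against a maximum at the boundary of the search interval
  cand <- c(opt$maximum, log(1e-5), log(1e5))
  vals <- c(opt$objective, crit(log(1e-5)), crit(log(1e5)))
  best <- which.max(vals)
  delta <- exp(cand[best])
  w <- 1 / (d + delta)
  sw <- sqrt(w)
  fit <- stats::lm.fit(Xt * sw, yt * sw)
  rss <- sum(fit$residuals^2)
  s2g <- rss / if (method == "reml") (n - p) else n
  structure(
    list(
      sigma2_g = s2g, sigma2_e = delta * s2g,
      pseudo_h2 = 1 / (1 + delta), delta = delta,
      loglik = vals[best], method = method
    ),
    class = "varcomp"
  )
}

# rotate y, X and markers into the eigenbasis of K and whiten with the
# current variance ratio; everything downstream is then plain OLS
whiten <- function(y, X, M, eigen_K, delta) {
  d <- pmax(eigen_K$values, 0)
  U <- eigen_K$vectors
  sw <- sqrt(1 / (d + delta))
  list(
    y = drop(crossprod(U, y)) * sw,
    X = crossprod(U, X) * sw,
    M = if (is.null(M)) NULL else crossprod(U, M) * sw
  )
}

#' Single-marker association scan under the mixed model
#'
#' Generalized-least-squares test of each candidate marker added to the
#' fixed effects, with the variance components held fixed at the supplied
#' values (the approximate scan used within each step of the multi-locus
#' search: components are re-estimated between steps, not per marker).
#' P-values come from the 1-df F-test of the marker coefficient. Markers
#' collinear with the covariates are reported with p = 1 and flagged.
#'
#' @param y phenotype vector.
#' @param X covariate matrix (intercept, structure covariates, cofactor
#'   markers).
#' @param K kinship matrix or NULL when `eigen_K` given.
#' @param varcomp a `varcomp` object fixing `delta`.
#' @param markers accessions x markers dosage matrix of candidates.
#' @param eigen_K optional precomputed eigendecomposition of K.
#' @param exact if TRUE, re-estimate REML variance components for every
#'   marker model (slow; intended for small oracle checks).
#' @return data.frame of class `scan_result`: `marker`, `beta`, `se`,
#'   `p`, `collinear`.
#' @export
scan_markers <- function(y, X, K = NULL, varcomp, markers,
                         eigen_K = NULL, exact = FALSE) {
  X <- as.matrix(X)
  if (is.null(eigen_K)) eigen_K <- eigen(K, symmetric = TRUE)
  n <- length(y)
  p <- ncol(X)
  if (exact) {
    res <- lapply(seq_len(ncol(markers)), function(j) {
      Xj <- cbind(X, markers[, j])
      if (qr(Xj)$rank < ncol(Xj)) {
        return(data.frame(beta = 0, se = NA_real_, p = 1, collinear = TRUE))
      }
      vc <- reml_variance_components(y, Xj, eigen_K = eigen_K)
      wj <- whiten(y, Xj, NULL, eigen_K, vc$delta)
      fit <- stats::lm.fit(wj$X, wj$y)
      rss <- sum(fit$residuals^2)
      s2 <- rss / (n - p - 1)
      xtx_inv <- chol2inv(chol(crossprod(wj$X)))
      se <- sqrt(s2 * xtx_inv[p + 1, p + 1])
      beta <- fit$coefficients[p + 1]
      pv <- stats::pf((beta / se)^2, 1, n - p - 1, lower.tail = FALSE)
      data.frame(beta = beta, se = se, p = pv, collinear = FALSE)
    })
    out <- do.call(rbind, res)
  } else {
    wt <- whiten(y, X, markers, eigen_K, varcomp$delta)
    fit0 <- stats::lm.fit(wt$X, wt$y)
    ey <- fit0$residuals
    rss0 <- sum(ey^2)
    B <- qr.coef(qr(wt$X), wt$M)
    E <- wt$M - wt$X %*% B
    den <- colSums(E^2)
    num <- colSums(E * ey)
    tot <- colSums(wt$M^2)
    collinear <- den <= 1e-10 * pmax(tot, 1)
    beta <- ifelse(collinear, 0, num / den)
    rss1 <- pmax(rss0 - num^2 / ifelse(collinear, Inf, den), 0)
    df <- n - p - 1
    s2 <- rss1 / df
    se <- sqrt(s2 / den)
    fstat <- (rss0 - rss1) / s2
    pv <- stats::pf(fstat, 1, df, lower.tail = FALSE)
    pv[collinear] <- 1
    se[collinear] <- NA_real_
    out <- data.frame(beta = beta, se = se, p = pv, collinear = collinear)
  }
  out <- cbind(marker = colnames(markers), out)
  rownames(out) <- NULL
  class(out) <- c("scan_result", "data.frame")
  out
}

# p-values of each covariate column (GLS t-tests) under fixed delta
covariate_pvalues <- function(y, X, eigen_K, delta) {
  wt <- whiten(y, X, NULL, eigen_K, delta)
  fit <- stats::lm.fit(wt$X, wt$y)
  n <- length(y)
  p <- ncol(wt$X)
  s2 <- sum(fit$residuals^2) / (n - p)
  xtx_inv <- chol2inv(chol(crossprod(wt$X)))
  se <- sqrt(s2 * diag(xtx_inv))
  tval <- fit$coefficients / se
  stats::setNames(
    stats::pf(tval^2, 1, n - p, lower.tail = FALSE),
    colnames(X)
  )
}

#' Multi-locus mixed-model forward search
#'
#' Stepwise forward selection: starting from the base covariates
#' (intercept plus structure covariates, typically three genotype PCs),
#' each step re-estimates the variance components, scans all remaining
#' markers with [scan_markers()], and adds the most significant marker as
#' a fixed cofactor. The search stops when the pseudo-heritability falls
#' to (effectively) zero, when `max_steps` is reached, or when no marker
#' can be added. Within every step the p-values of all current cofactors
#' are re-computed under that step's model, which is what the model
#' selection criteria consume.
#'
#' @param y phenotype vector.
#' @param X0 base covariate matrix (include the intercept).
#' @param K kinship matrix, or NULL with `eigen_K` supplied.
#' @param markers accessions x markers dosage matrix.
#' @param map optional marker map (`marker`, `chrom`, `pos`) used to
#'   break p-value ties by genome order.
#' @param max_steps maximum cofactors to add (default 20).
#' @param h2_stop pseudo-heritability value treated as zero
#'   (default 0.01).
#' @param eigen_K optional precomputed eigendecomposition of K.
#' @param keep_scans if TRUE, keep the full per-step scan tables (the
#'   step-0 scan is always kept).
#' @return A list of class `mlmm_fit`: `cofactors` (ordered marker ids),
#'   `steps` (per step: cofactors, varcomp, cofactor p-values),
#'   `pseudo_h2_path`, `scan0` (null-model scan), `n`, `m`.
#' @export
mlmm_forward <- function(y, X0, K = NULL, markers, map = NULL,
                         max_steps = 20, h2_stop = 0.01,
                         eigen_K = NULL, keep_scans = FALSE) {
  X0 <- as.matrix(X0)
  if (is.null(colnames(markers))) {
    colnames(markers) <- paste0("m", seq_len(ncol(markers)))
  }
  if (is.null(eigen_K)) eigen_K <- eigen(K, symmetric = TRUE)
  tie_rank <- if (!is.null(map)) {
    stats::setNames(
      rank(order(order(map$chrom, map$pos))),
      map$marker
    )[colnames(markers)]
  } else {
    stats::setNames(seq_len(ncol(markers)), colnames(markers))
  }

  cof <- character(0)
  steps <- list()
  vc <- reml_variance_components(y, X0, eigen_K = eigen_K)
  h2_path <- vc$pseudo_h2
  scan0 <- scan_markers(y, X0,
    varcomp = vc, markers = markers,
    eigen_K = eigen_K
  )
  steps[[1]] <- list(
    cofactors = character(0), varcomp = vc,
    cofactor_p = stats::setNames(numeric(0), character(0)),
    scan = if (keep_scans) scan0 else NULL
  )
  scan <- scan0

  repeat {
    if (length(cof) >= max_steps) break
    # the stopping statistic is the heritable variance remaining under the
    # current cofactor model; it only becomes meaningful once the search
    # has started (a mono/oligogenic signal is invisible to the kinship
    # term at the null model), so the first step is always attempted
    if (length(cof) >= 1L && vc$pseudo_h2 <= h2_stop) break
    cand <- scan[!scan$collinear, ]
    if (!nrow(cand) || all(cand$p >= 1)) break
    o <- order(cand$p, tie_rank[cand$marker])
    best <- cand$marker[o[1]]
    cof <- c(cof, best)
    X <- cbind(X0, markers[, cof, drop = FALSE])
    vc <- reml_variance_components(y, X, eigen_K = eigen_K)
    cof_p <- covariate_pvalues(y, X, eigen_K, vc$delta)[cof]
    h2_path <- c(h2_path, vc$pseudo_h2)
    remaining <- setdiff(colnames(markers), cof)
    scan <- if (length(remaining) && vc$pseudo_h2 > h2_stop &&
      length(cof) < max_steps) {
      scan_markers(y, X,
        varcomp = vc,
        markers = markers[, remaining, drop = FALSE], eigen_K = eigen_K
      )
    } else {
      scan[0, ]
    }
    steps[[length(steps) + 1]] <- list(
      cofactors = cof, varcomp = vc, cofactor_p = cof_p,
      scan = if (keep_scans) scan else NULL
    )
  }
  structure(
    list(
      cofactors = cof, steps = steps, pseudo_h2_path = h2_path,
      scan0 = scan0, n = length(y), m = ncol(markers),
      X0 = X0, markers_used = colnames(markers), eigen_K = eigen_K,
      y = y, markers = markers
    ),
    class = "mlmm_fit"
  )
}

#' Select the multiple-Bonferroni and extended-BIC models from a forward
#' path
#'
#' The multiple-Bonferroni (mBonf) model is the largest model on the
#' forward path whose every cofactor has a p-value at or below
#' `alpha / m_effective`; it is the more stringent criterion. The
#' extended-BIC model minimizes `-2 logLik(ML) + k log(n) +
#' 2 gamma log C(m_effective, k)` over path models with k cofactors. The
#' high-confidence set is the union of the two selected models; each SNP
#' is tiered `"stringent"` (in the mBonf model) or `"lower"` (extended-BIC
#' model only).
#'
#' @param fit an `mlmm_fit`.
#' @param m_effective number of markers tested (Bonferroni denominator).
#' @param alpha familywise significance level (default 0.05).
#' @param gamma extended-BIC complexity weight (default 1).
#' @return A list of class `mlmm_selection`: `mbonf`, `extbic` (marker
#'   id vectors), `high_confidence` (data.frame marker/tier), `threshold`,
#'   `extbic_values`.
#' @export
select_models <- function(fit, m_effective = fit$m, alpha = 0.05,
                          gamma = 1.0) {
  thr <- alpha / m_effective
  n_models <- length(fit$steps)
  mbonf <- character(0)
  for (k in seq_len(n_models)) {
    cp <- fit$steps[[k]]$cofactor_p
    if (length(cp) && all(cp <= thr)) mbonf <- fit$steps[[k]]$cofactors
  }
  ebic <- numeric(n_models)
  for (k in seq_len(n_models)) {
    cof <- fit$steps[[k]]$cofactors
    X <- cbind(fit$X0, fit$markers[, cof, drop = FALSE])
    ml <- reml_variance_components(fit$y, X,
      eigen_K = fit$eigen_K,
      method = "ml"
    )
    nk <- length(cof)
    ebic[k] <- -2 * ml$loglik + nk * log(fit$n) +
      2 * gamma * lchoose(m_effective, nk)
  }
  extbic <- fit$steps[[which.min(ebic)]]$cofactors
  hc <- union(mbonf, extbic)
  high_confidence <- data.frame(
    marker = hc,
    tier = ifelse(hc %in% mbonf, "stringent", "lower"),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      mbonf = mbonf, extbic = extbic,
      high_confidence = high_confidence, threshold = thr,
      extbic_values = ebic
    ),
    class = "mlmm_selection"
  )
}

#' Run the full MLMM analysis for one phenotype
#'
#' Convenience wrapper: forward search followed by model selection.
#'
#' @inheritParams mlmm_forward
#' @inheritParams select_models
#' @return The `mlmm_fit` with an added `selection` element.
#' @export
mlmm <- function(y, X0, K = NULL, markers, map = NULL, alpha = 0.05,
                 max_steps = 20, h2_stop = 0.01, gamma = 1.0,
                 eigen_K = NULL) {
  fit <- mlmm_forward(y, X0, K,
    markers = markers, map = map,
    max_steps = max_steps, h2_stop = h2_stop, eigen_K = eigen_K
  )
  fit$selection <- select_models(fit,
    m_effective = ncol(markers),
    alpha = alpha, gamma = gamma
  )
  fit
}

#' @export
print.mlmm_fit <- function(x, ...) {
  cat(sprintf(
    "mlmm_fit: n=%d, m=%d, %d cofactor step(s); pseudo-h2 %.3f -> %.3f\n",
    x$n, x$m, length(x$cofactors),
    x$pseudo_h2_path[1], x$pseudo_h2_path[length(x$pseudo_h2_path)]
  ))
  if (!is.null(x$selection)) {
    cat(sprintf(
      "  mBonf: {%s}; extBIC: {%s}\n",
      paste(x$selection$mbonf, collapse = ", "),
      paste(x$selection$extbic, collapse = ", ")
    ))
  }
  invisible(x)
}
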