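# Restricted log-likelihood profiled over gamma = sigma_q^2 / sigma_e^2, in
# the eigenbasis of D. With H = I + gamma D and p = rank(X) the value at the
# profiled residual variance is
# -(1/2) [ (n-p) log sigma_e2(gamma) + log|H| + log|X' H^{-1} X| + (n-p) ].
# Constant terms follow this one convention throughout the package so they
# cancel in likelihood-ratio differences. Computation in C++ (reml.cpp).
.reml_profile <- function(gamma, lam, ty, tX) {
  v <- reml_profile_grid(lam, ty, as.matrix(tX), gamma)
  list(loglik = v[1L, 1L], sigma_e2 = v[1L, 2L])
}

#' REML fit of the one-variance-component mixed model
#'
#' Fits `y = X beta + q + e` with `q ~ N(0, D sigma_q^2)` and
#' `e ~ N(0, I sigma_e^2)` by maximizing the restricted log-likelihood over
#' `gamma = sigma_q^2 / sigma_e^2 >= 0`, profiling out `sigma_e^2`.
#' Optimization evaluates the boundary `gamma = 0` and a log-spaced grid on
#' `[1e-6, 1e3]`, then refines the best grid point by golden-section search to
#' a relative tolerance of 1e-6.
#'
#' @param y Numeric phenotype vector.
#' @param X Fixed-effects design matrix (full column rank; include the
#'   intercept column).
#' @param D Diplotype (or other) relationship matrix, n x n.
#' @param eig Optional precomputed `eigen(D, symmetric = TRUE)`.
#' @return List of class `reml_fit`: `sigma_q2`, `sigma_e2`, `gamma`,
#'   `loglik`, `converged`.
#' @export
reml_fit <- function(y, X, D = NULL, eig = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (qr(X)$rank < ncol(X)) stop("X is singular: drop collinear covariates")
  if (n <= ncol(X)) stop("need more records than fixed effects")
  if (is.null(eig)) {
    stopifnot(is.matrix(D), nrow(D) == n, ncol(D) == n)
    eig <- sym_eigen((D + t(D)) / 2)
  }
  .reml_core(y, X, eig)
}

# optimizer core shared by reml_fit and lrt_scan (which validates X once)
.reml_core <- function(y, X, eig) {
  lam <- eig$values
  ty <- drop(crossprod(eig$vectors, y))
  tX <- crossprod(eig$vectors, X)

  gammas <- c(0, 10^seq(-6, 3, length.out = 16))
  prof <- reml_profile_grid(lam, ty, tX, gammas)
  lls <- prof[, 1L]
  if (all(!is.finite(lls))) stop("non-finite restricted likelihood")
  best <- which.max(lls)
  gamma_hat <- gammas[best]
  if (best > 1L) {
    lo <- gammas[max(best - 1L, 2L)] # stay on the log grid
    hi <- gammas[min(best + 1L, length(gammas))]
    if (best == 2L) lo <- gammas[2L] * 1e-2
    f <- function(lg) reml_profile_grid(lam, ty, tX, 10^lg)[1L, 1L]
    opt <- stats::optimize(f, interval = log10(c(lo, hi)), maximum = TRUE,
                           tol = 1e-7)
    gamma_hat <- 10^opt$maximum
    if (.reml_profile(0, lam, ty, tX)$loglik >= opt$objective)
      gamma_hat <- 0
  }
  fit <- .reml_profile(gamma_hat, lam, ty, tX)
  structure(list(sigma_q2 = gamma_hat * fit$sigma_e2, sigma_e2 = fit$sigma_e2,
                 gamma = gamma_hat, loglik = fit$loglik, converged = TRUE),
            class = "reml_fit")
}

#' Null-model REML fit (no locus effect)
#'
#' Closed form: `sigma_e2 = RSS / (n - p)` from ordinary least squares, with
#' the restricted log-likelihood under the same constant convention as
#' [reml_fit()] (it equals `reml_fit` at `gamma = 0`).
#'
#' @inheritParams reml_fit
#' @return A `reml_fit` with `sigma_q2 = 0`.
#' @export
null_fit <- function(y, X) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p) stop("X is singular: drop collinear covariates")
  if (n <= p) stop("need more records than fixed effects")
  qx <- qr(X)
  r <- stats::resid(lm.fit(X, y))
  rss <- sum(r * r)
  if (rss <= max(1e-12 * sum(y * y), .Machine$double.eps))
    stop("y lies in the span of X: zero residual variance")
  s2 <- rss / (n - p)
  ch <- chol(crossprod(X))
  ll <- -0.5 * ((n - p) * log(s2) + 2 * sum(log(diag(ch))) + (n - p))
  structure(list(sigma_q2 = 0, sigma_e2 = s2, gamma = 0, loglik = ll,
                 converged = TRUE),
            class = "reml_fit")
}

#' Likelihood-ratio-test scan over sliding-window diplotype matrices
#'
#' For each window, builds the locus-IBD matrix ([locibd_matrix()]), converts
#' it to a diplotype relationship matrix ([drm_from_locibd()]), fits the
#' mixed model by REML and computes
#' `LRT = max(0, 2 (loglik_H1 - loglik_H0))`. The null model is fitted once:
#' it has no window-specific terms. Windows whose fit fails are recorded with
#' `LRT = NA` and the scan continues.
#'
#' @param panel Phased, complete [haplotype_panel()] (run [impute_panel()]
#'   first if needed).
#' @param map Marker map matching the panel columns.
#' @param y Phenotype vector (one per panel animal) or a matrix with one
#'   column per phenotype replicate (e.g. permutations); all columns share
#'   the window DRMs.
#' @param X Fixed-effects design; defaults to an intercept column.
#' @param params [ibd_params()].
#' @param window_size,step Window geometry in SNPs.
#' @param freqs Optional per-SNP allele-1 frequencies.
#' @param method Locus-IBD estimator passed to [locibd_matrix()].
#' @return For vector `y`: data frame of class `scan_result` with columns
#'   `window`, `midpoint_bp`, `lrt`, `sigma_q2`, `sigma_e2`, `loglik_h1`,
#'   `loglik_h0`. For matrix `y`: the same frame with one `lrt_<k>` column
#'   per phenotype column.
#' @export
lrt_scan <- function(panel, map, y, X = NULL, params = ibd_params(),
                     window_size = 40L, step = 1L, freqs = NULL,
                     method = c("multipoint", "runs")) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "haplotype_panel"))
  n <- length(panel$animals)
  ymat <- if (is.matrix(y)) y else matrix(y, ncol = 1L)
  stopifnot(nrow(ymat) == n)
  if (is.null(X)) X <- matrix(1, n, 1L)
  if (is.null(freqs)) freqs <- panel_freqs(panel)
  windows <- make_windows(map, size = window_size, step = step)
  r <- ncol(ymat)
  h0 <- lapply(seq_len(r), function(k) null_fit(ymat[, k], X))
  lrt <- matrix(NA_real_, nrow(windows), r)
  s_q <- s_e <- ll1 <- rep(NA_real_, nrow(windows))
  for (w in seq_len(nrow(windows))) {
    res <- tryCatch({
      M <- locibd_matrix(panel, windows[w, ], map, freqs, params, method)
      D <- drm_from_locibd(M)
      eig <- attr(D, "eigen")
      fits <- lapply(seq_len(r), function(k) .reml_core(ymat[, k], X, eig))
      list(fits = fits)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("window %d failed: %s", w, conditionMessage(res)))
      next
    }
    for (k in seq_len(r))
      lrt[w, k] <- max(0, 2 * (res$fits[[k]]$loglik - h0[[k]]$loglik))
    s_q[w] <- res$fits[[1L]]$sigma_q2
    s_e[w] <- res$fits[[1L]]$sigma_e2
    ll1[w] <- res$fits[[1L]]$loglik
  }
  out <- data.frame(window = windows$index, midpoint_bp = windows$midpoint_bp)
  if (r == 1L) {
    out$lrt <- lrt[, 1L]
    out$sigma_q2 <- s_q; out$sigma_e2 <- s_e
    out$loglik_h1 <- ll1; out$loglik_h0 <- h0[[1L]]$loglik
  } else {
    for (k in seq_len(r)) out[[sprintf("lrt_%d", k)]] <- lrt[, k]
  }
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Bonferroni chi-square significance threshold for an LRT scan
#'
#' Upper-tail quantile of the chi-square distribution with one degree of
#' freedom at probability `alpha_total / n_tests`. (The LRT null is in truth
#' a 50:50 mixture of chi-square 0 and 1 because the variance component is
#' boundary-constrained; the plain chi-square-1 convention is conservative.)
#'
#' @param alpha_total Total type-I error rate (0 < alpha < 1).
#' @param n_tests Number of tests (windows) for the Bonferroni correction.
#' @return The LRT threshold.
#' @export
significance_threshold <- function(alpha_total, n_tests) {
  stopifnot(alpha_total > 0, alpha_total < 1, n_tests >= 1)
  stats::qchisq(alpha_total / n_tests, df = 1, lower.tail = FALSE)
}

#' LRT units per LOD
#'
#' One LOD (log10 odds) equals `2 ln 10 ~ 4.605` on the LRT scale.
#' @return The constant `2 * log(10)`.
#' @export
lod_unit <- function() 2 * log(10)

#' 2-LOD drop-off support intervals around scan peaks
#'
#' Peaks are windows above `threshold`; for each, the support interval extends
#' outward through all consecutive windows with
#' `LRT > peak_LRT - drop_lod * 2 ln 10`, with boundaries at the midpoints of
#' the outermost windows still above the drop line. All above-threshold
#' windows inside an interval are merged around its highest peak; remaining
#' peaks outside every primary interval are reported separately.
#'
#' @param scan A `scan_result` from [lrt_scan()] (columns `midpoint_bp`,
#'   `lrt`).
#' @param threshold Significance threshold on the LRT scale (e.g.
#'   [significance_threshold()]).
#' @param drop_lod LOD units of drop (default 2).
#' @return Data frame with `peak_bp`, `peak_lrt`, `lower_bp`, `upper_bp`,
#'   one row per reported peak, ordered by descending peak LRT. Empty when no
#'   window exceeds the threshold.
#' @export
lod_ci <- function(scan, threshold, drop_lod = 2) {
  stopifnot(is.data.frame(scan), all(c("midpoint_bp", "lrt") %in% names(scan)))
  if (nrow(scan) == 0L) stop("empty scan")
  lrt <- scan$lrt
  m <- length(lrt)
  above <- which(!is.na(lrt) & lrt > threshold)
  empty <- data.frame(peak_bp = numeric(0), peak_lrt = numeric(0),
                      lower_bp = numeric(0), upper_bp = numeric(0))
  if (!length(above)) return(empty)
  is_locmax <- vapply(above, function(w) {
    (w == 1L || is.na(lrt[w - 1L]) || lrt[w] >= lrt[w - 1L]) &&
      (w == m || is.na(lrt[w + 1L]) || lrt[w] >= lrt[w + 1L])
  }, logical(1))
  peaks <- above[is_locmax]
  iv <- t(vapply(peaks, function(pk) {
    dropline <- lrt[pk] - drop_lod * lod_unit()
    lo <- pk
    while (lo > 1L && !is.na(lrt[lo - 1L]) && lrt[lo - 1L] > dropline)
      lo <- lo - 1L
    hi <- pk
    while (hi < m && !is.na(lrt[hi + 1L]) && lrt[hi + 1L] > dropline)
      hi <- hi + 1L
    c(lo, hi, pk)
  }, numeric(3)))
  # merge overlapping per-peak intervals around their highest peak
  ord <- order(iv[, 1L])
  iv <- iv[ord, , drop = FALSE]
  merged <- list()
  cur <- iv[1L, ]
  for (r in seq_len(nrow(iv))[-1L]) {
    if (iv[r, 1L] <= cur[2L]) {
      cur[2L] <- max(cur[2L], iv[r, 2L])
      if (lrt[iv[r, 3L]] > lrt[cur[3L]]) cur[3L] <- iv[r, 3L]
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- iv[r, ]
    }
  }
  merged[[length(merged) + 1L]] <- cur
  out <- do.call(rbind, lapply(merged, function(v) {
    data.frame(peak_bp = scan$midpoint_bp[v[3L]], peak_lrt = lrt[v[3L]],
               lower_bp = scan$midpoint_bp[v[1L]],
               upper_bp = scan$midpoint_bp[v[2L]])
  }))
  out[order(-out$peak_lrt), , drop = FALSE]
}
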