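# brute-force restricted log-likelihood via explicit matrix inverses,
# independent of the eigenbasis implementation
reml_brute <- function(gamma, y, X, D) {
  n <- length(y); p <- ncol(X)
  H <- diag(n) + gamma * D
  Hi <- solve(H)
  XtHiX <- t(X) %*% Hi %*% X
  beta <- solve(XtHiX, t(X) %*% Hi %*% y)
  r <- y - X %*% beta
  s2 <- drop(t(r) %*% Hi %*% r) / (n - p)
  as.numeric(-0.5 * ((n - p) * log(s2) + determinant(H)$modulus +
                       determinant(XtHiX)$modulus + (n - p)))
}

toy_fit_data <- function(n = 12, seed = 5) {
  set.seed(seed)
  B <- matrix(runif(4 * n^2, 0, 1), 2 * n)
  B <- (B + t(B)) / 2; diag(B) <- 1
  D <- drm_from_locibd(B)
  X <- cbind(1, rnorm(n))
  q <- drop(crossprod(chol(D + diag(1e-8, n)), rnorm(n)))
  y <- drop(X %*% c(1, 0.5)) + q + rnorm(n, sd = 0.5)
  list(y = y, X = X, D = unclass(D))
}

test_that("restricted likelihood matches the brute-force evaluation", {
  td <- toy_fit_data()
  fit <- reml_fit(td$y, td$X, td$D)
  expect_equal(fit$loglik, drop(reml_brute(fit$gamma, td$y, td$X, td$D)),
               tolerance = 1e-8)
  # at arbitrary fixed ratios too
  eig <- cldla:::sym_eigen(td$D)
  for (g in c(0.1, 1, 7)) {
    ll <- cldla:::.reml_profile(g, eig$values,
                                drop(crossprod(eig$vectors, td$y)),
                                crossprod(eig$vectors, td$X))$loglik
    expect_equal(ll, drop(reml_brute(g, td$y, td$X, td$D)), tolerance = 1e-8)
  }
})

test_that("an identity relationship matrix carries no signal", {
  td <- toy_fit_data(n = 30, seed = 6)
  fit <- reml_fit(td$y, td$X, diag(30))
  h0 <- null_fit(td$y, td$X)
  expect_equal(fit$loglik, h0$loglik, tolerance = 1e-4)
})

test_that("null fit is ordinary least squares under the shared constant convention", {
  y <- c(1, 2, 3, 4)
  X <- matrix(1, 4, 1)
  h0 <- null_fit(y, X)
  expect_equal(h0$sigma_e2, 5 / 3)
  expect_equal(h0$sigma_q2, 0)
  # zero relationship matrix reduces the mixed model to the null
  fit0 <- reml_fit(y, X, matrix(0, 4, 4))
  expect_equal(fit0$loglik, h0$loglik, tolerance = 1e-8)
  expect_error(null_fit(X %*% 2, X), "span")
  expect_error(null_fit(y, cbind(X, X)), "singular")
})

test_that("variance components are recovered in simulation", {
  set.seed(21)
  n <- 120
  # structured relationship matrix (random diplotype sharing), well away from
  # a constant matrix so the genetic effect is separable from the intercept
  Z <- matrix(rbinom(n * 40, 1L, 0.3), n)
  D <- tcrossprod(scale(Z)) / 40 + diag(0.2, n)
  ch <- chol(D)
  X <- cbind(1, rnorm(n))
  ratios <- replicate(40, {
    y <- drop(X %*% c(2, 1)) + sqrt(4) * drop(crossprod(ch, rnorm(n))) + rnorm(n)
    f <- reml_fit(y, X, D)
    f$sigma_q2 / f$sigma_e2
  })
  expect_gte(median(ratios), 2)
  expect_lte(median(ratios), 8)
})

test_that("scan wiring: single window, invariances, failure tolerance", {
  sim <- small_sim(seed = 7)
  panel <- impute_panel(sim$haplotypes)
  panel$alleles <- panel$alleles[, seq_len(sim$n_target_snps), drop = FALSE]
  map <- sim$target_map
  y <- encode_phenotypes(sim$status_records)
  one <- lrt_scan(panel, map[1:40, ], y,
                  freqs = panel_freqs(panel)[1:40])
  expect_equal(nrow(one), 1L)
  expect_gte(one$lrt, 0)
  expect_equal(one$lrt, max(0, 2 * (one$loglik_h1 - one$loglik_h0)),
               tolerance = 1e-8)

  # LRT is invariant to phenotype location shifts and X-column additions
  sub <- map[30:100, ]
  f <- panel_freqs(panel)[30:100]
  p2 <- panel; p2$alleles <- p2$alleles[, 30:100]
  X <- cbind(1, rnorm(length(y)))
  s1 <- lrt_scan(p2, sub, y, X, freqs = f)
  s2 <- lrt_scan(p2, sub, y + 11 + 3 * X[, 2], X, freqs = f)
  expect_equal(s2$lrt, s1$lrt, tolerance = 1e-6)
})

test_that("the chi-square threshold reproduces standard quantiles", {
  expect_equal(significance_threshold(0.05, 1), qchisq(0.95, 1),
               tolerance = 1e-12)
  expect_equal(significance_threshold(0.05, 1), 3.841, tolerance = 5e-4)
  expect_equal(significance_threshold(0.2, 1),
               qchisq(0.2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(significance_threshold(0, 10))
  expect_error(significance_threshold(0.05, 0))
})

test_that("drop-off intervals follow the hand-evaluated rule", {
  scan <- data.frame(midpoint_bp = (1:5) * 1e6,
                     lrt = c(10, 21, 30, 22, 10))
  ci <- lod_ci(scan, threshold = 25.223, drop_lod = 2)
  expect_equal(nrow(ci), 1L)
  expect_equal(ci$peak_bp, 3e6)
  expect_equal(ci$lower_bp, 2e6)
  expect_equal(ci$upper_bp, 4e6)
  # flat profile below threshold
  flat <- data.frame(midpoint_bp = (1:5) * 1e6, lrt = rep(11, 5))
  expect_equal(nrow(lod_ci(flat, 25.223)), 0L)
  # single exceeding window: degenerate interval
  spike <- data.frame(midpoint_bp = (1:5) * 1e6, lrt = c(1, 1, 30, 1, 1))
  cs <- lod_ci(spike, 25.223)
  expect_equal(cs$lower_bp, cs$peak_bp)
  expect_equal(cs$upper_bp, cs$peak_bp)
  # two distinct peaks with a deep valley are reported separately
  two <- data.frame(midpoint_bp = (1:9) * 1e6,
                    lrt = c(5, 28, 30, 5, 5, 5, 40, 42, 5))
  c2 <- lod_ci(two, 25.223)
  expect_equal(nrow(c2), 2L)
  expect_equal(c2$peak_bp, c(8e6, 3e6))
  # overlapping per-peak intervals merge around the highest peak
  plateau <- data.frame(midpoint_bp = (1:7) * 1e6,
                        lrt = c(5, 30, 26, 31, 27, 29, 5))
  cp <- lod_ci(plateau, 25.223)
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$peak_bp, 4e6)
  expect_equal(cp$lower_bp, 2e6)
  expect_equal(cp$upper_bp, 6e6)
})
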