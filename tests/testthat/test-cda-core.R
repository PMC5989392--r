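test_that("the Hamiltonian evaluates the phenotype-linear energy", {
  p <- newCdaParams(2, "dominant")
  expect_equal(cdaHamiltonian(p, c(1, 1), 0.7), 0)
  # h_1^(0)(1) = 0.5, h_1^(1)(1) = 1.0, J_12^(1)(1,1) = 0.2
  p@h[1, 1] <- 0.5
  p@h[1, 2] <- 1.0
  p@J[1, 2, 2] <- 0.2
  p@J[2, 1, 2] <- 0.2
  expect_equal(cdaHamiltonian(p, c(1, 1), 1), 1.7)
  pr <- randomParams(4, "genotypic", seed = 8)
  expect_equal(cdaHamiltonian(pr, rep(0, 4), 1.3), 0)
})

test_that("site conditionals are normalized softmax probabilities", {
  pg <- newCdaParams(3, "genotypic")
  expect_equal(unname(siteConditional(pg, 2, c(1, 0, 2), 0.4)), rep(1 / 3, 3))
  pd <- newCdaParams(3, "dominant")
  expect_equal(unname(siteConditional(pd, 1, c(0, 1, 1), -2)), rep(1 / 2, 2))
  p1 <- newCdaParams(1, "dominant")
  p1@h[1, 1] <- log(2)
  expect_equal(unname(siteConditional(p1, 1, 0, 5)), c(1 / 3, 2 / 3))
  pr <- randomParams(4, "genotypic", seed = 2)
  expect_equal(sum(siteConditional(pr, 3, c(2, 1, 0, 1), 0.9)), 1)
})

test_that("pseudo-log-likelihood matches closed forms and penalty sign", {
  co <- randomCohort(20, 3, "genotypic", seed = 5)
  p0 <- newCdaParams(3, "genotypic")
  expect_equal(pseudoLogLik(co, p0, 0.5, 0.5), 20 * 3 * log(1 / 3))
  # single sample, m = 1: ln Pr(a=1) = ln(2/3) minus the field penalty
  p1 <- newCdaParams(1, "dominant")
  p1@h[1, 1] <- log(2)
  co1 <- cdaCohort(matrix(1, 1, 1), phenotype = 0.3, encoding = "dominant")
  lam1 <- 0.4
  expect_equal(pseudoLogLik(co1, p1, lam1, Inf),
               log(2 / 3) - 0.5 * lam1 * log(2)^2)
  # adding the penalty with nonzero parameters strictly decreases the value
  pr <- randomParams(3, "genotypic", seed = 6)
  expect_lt(pseudoLogLik(co, pr, 1, 1), pseudoLogLik(co, pr, 1e-12, 1e-12))
})

test_that("analytic gradients match finite differences of the objective", {
  for (enc in c("dominant", "genotypic")) {
    co <- randomCohort(15, 3, enc, seed = 31)
    pr <- randomParams(3, enc, sd = 0.4, seed = 32)
    gr <- pseudoGrad(co, pr, 0.7, 0.3)
    n <- nSamples(co)
    eps <- 1e-5
    # probe a field and a coupling entry
    for (probe in list(list(slot = "h", idx = c(2, 2)),
                       list(slot = "J", idx = c(1, 3, 2)))) {
      pp <- pr; pm <- pr
      if (probe$slot == "h") {
        pp@h[probe$idx[1], probe$idx[2]] <- pp@h[probe$idx[1], probe$idx[2]] + eps
        pm@h[probe$idx[1], probe$idx[2]] <- pm@h[probe$idx[1], probe$idx[2]] - eps
        g <- gr$h[probe$idx[1], probe$idx[2]]
      } else {
        i <- probe$idx[1]; j <- probe$idx[2]; l <- probe$idx[3]
        pp@J[i, j, l] <- pp@J[i, j, l] + eps; pp@J[j, i, l] <- pp@J[i, j, l]
        pm@J[i, j, l] <- pm@J[i, j, l] - eps; pm@J[j, i, l] <- pm@J[i, j, l]
        g <- gr$J[probe$idx[1], probe$idx[2], probe$idx[3]]
      }
      fd <- (pseudoLogLik(co, pp, 0.7, 0.3) -
             pseudoLogLik(co, pm, 0.7, 0.3)) / (2 * eps * n)
      expect_equal(g, fd, tolerance = 1e-6)
    }
  }
})

test_that("gradient at zero parameters is sample frequency minus uniform", {
  co <- randomCohort(40, 3, "genotypic", seed = 9)
  G <- genotypes(co)
  gr <- pseudoGrad(co, newCdaParams(3, "genotypic"), 0.2, 0.2)
  for (i in 1:3) for (a in 1:2)
    expect_equal(gr$h[(i - 1) * 2 + a, 1], mean(G[, i] == a) - 1 / 3,
                 tolerance = 1e-12)
})

test_that("couplings stay frozen at zero when lambda2 is infinite", {
  co <- randomCohort(30, 4, seed = 12)
  gr <- pseudoGrad(co, newCdaParams(4, "dominant"), 0.1, Inf)
  expect_true(all(gr$J == 0))
  fit <- fitCda(co, 0.1, Inf)
  expect_true(all(fit$params@J == 0))
  expect_false(fit$params@interactions)
})

test_that("strong penalization drives phenotype-dependent parameters to zero", {
  sim <- sampleCohort(simPreset("null", m = 5, n = 300, seed = 21))
  fit <- fitCda(sim$cohort, 10, 10)
  expect_true(fit$converged)
  theta1 <- c(fit$params@h[, 2], fit$params@J[, , 2])
  expect_lt(max(abs(theta1)), 0.05)
})

test_that("fitting is deterministic and preserves the zero reference", {
  co <- randomCohort(50, 4, "genotypic", seed = 13)
  f1 <- fitCda(co, 0.3, 0.3)
  f2 <- fitCda(co, 0.3, 0.3)
  expect_identical(f1$params@h, f2$params@h)
  expect_identical(f1$params@J, f2$params@J)
  expect_true(validObject(f1$params))
  expect_equal(cdaHamiltonian(f1$params, rep(0, 4), 1.7), 0)
})

test_that("Bayes prediction returns the prior mean for null models", {
  p <- newCdaParams(3, "dominant")
  p@h[, 1] <- c(0.4, -0.2, 1)  # phenotype-independent only
  G <- matrix(rbinom(30, 1, 0.5), 10, 3)
  expect_equal(bayesPredict(p, G, mu = 2.5, sigma2 = 4), rep(2.5, 10),
               tolerance = 1e-10)
})

test_that("Bayes prediction matches a fine-grid quadrature oracle", {
  p <- newCdaParams(1, "dominant")
  p@h[1, 1] <- 0.3
  p@h[1, 2] <- 0.8
  mu <- 0.5; s2 <- 1.44
  oracle <- function(a) {
    f <- function(y) {
      eta <- 0.3 + 0.8 * y
      pr <- if (a == 1) exp(eta) / (1 + exp(eta)) else 1 / (1 + exp(eta))
      pr * dnorm(y, mu, sqrt(s2))
    }
    num <- integrate(function(y) y * f(y), mu - 9, mu + 9,
                     rel.tol = 1e-12)$value
    num / integrate(f, mu - 9, mu + 9, rel.tol = 1e-12)$value
  }
  fine <- yGrid(mu, s2, n = 4001, span = 6)
  pred <- bayesPredict(p, matrix(c(0, 1), 2, 1), mu, s2, grid = fine)
  expect_equal(pred, c(oracle(0), oracle(1)), tolerance = 1e-6)
  # default grid is converged: doubling the density moves predictions < 1e-4
  d1 <- bayesPredict(p, matrix(c(0, 1), 2, 1), mu, s2)
  d2 <- bayesPredict(p, matrix(c(0, 1), 2, 1), mu, s2,
                     grid = yGrid(mu, s2, n = 201))
  expect_lt(max(abs(d1 - d2)), 1e-4)
})

test_that("site conditionals equal exact conditionals for factorized models", {
  # with J = 0 the joint factorizes, so PL conditionals are exact
  sp <- simSpec(4, 2, "dominant", h0 = c(-0.2, 0.3), h1 = c(0.2, 0.3),
                seed = 14)
  p <- drawCdaParams(sp)
  genos <- enumerateGenotypes(4, "dominant")
  for (y in c(-1.5, 0, 2)) {
    tab <- enumerateConditional(p, y, genos)
    ctx <- c(1, 0, 1, 1)
    for (i in 1:4) {
      sel0 <- genos[, i] == 0 &
        rowSums(genos[, -i, drop = FALSE] ==
                  matrix(ctx[-i], nrow(genos), 3, byrow = TRUE)) == 3
      sel1 <- genos[, i] == 1 &
        rowSums(genos[, -i, drop = FALSE] ==
                  matrix(ctx[-i], nrow(genos), 3, byrow = TRUE)) == 3
      exact <- c(sum(tab[sel0]), sum(tab[sel1]))
      exact <- exact / sum(exact)
      expect_equal(unname(siteConditional(p, i, ctx, y)), exact,
                   tolerance = 1e-12)
    }
  }
})

test_that("cross-validation predicts every sample once with seeded folds", {
  co <- randomCohort(100, 3, seed = 17)
  cv <- crossValidateCda(co, 1, 1, folds = 5, seed = 7, refit = FALSE)
  expect_equal(as.integer(table(cv@foldId)), rep(20L, 5))
  expect_true(all(is.finite(cv@predictions)))
  expect_lt(abs(cv@R), 3 / sqrt(100))  # no signal
  cv2 <- crossValidateCda(co, 1, 1, folds = 5, seed = 7, refit = FALSE)
  expect_identical(cv@predictions, cv2@predictions)
})

test_that("penalizer grid search reduces to plain CV and prefers larger ties", {
  sim <- sampleCohort(simPreset("recovery", m = 3, n = 80, seed = 19))
  one <- optimizePenalizers(sim$cohort, lambda1Grid = 0.5, lambda2Grid = 2,
                            seed = 3, refit = FALSE)
  cv <- crossValidateCda(sim$cohort, 0.5, 2, seed = 3, refit = FALSE)
  expect_equal(one@R, cv@R)
  expect_identical(one@predictions, cv@predictions)
  # selection oracle: best candidate by CV score, ties to larger penalizers
  l1 <- c(0.1, 10); l2 <- c(1, Inf)
  best <- NULL
  for (a in l1) for (b in l2) {
    R <- crossValidateCda(sim$cohort, a, b, seed = 3, refit = FALSE)@R
    if (is.null(best) || R >= best$R) best <- list(R = R, l1 = a, l2 = b)
  }
  opt <- optimizePenalizers(sim$cohort, lambda1Grid = l1, lambda2Grid = l2,
                            seed = 3, refit = FALSE)
  expect_equal(opt@R, best$R)
  expect_equal(opt@lambda1, best$l1)
  expect_identical(opt@lambda2, best$l2)
})

test_that("parameter tables round-trip through the text serialization", {
  for (enc in c("dominant", "genotypic")) {
    p <- randomParams(3, enc, seed = 23)
    tb <- paramTable(p)
    L <- if (enc == "dominant") 1 else 2
    expect_equal(sum(is.na(tb$j)), 2 * 3 * L)        # field rows
    expect_equal(sum(!is.na(tb$j)), 2 * 3 * L * L)   # coupling rows
    path <- tempfile(fileext = ".tsv")
    writeCdaParams(p, path)
    q <- readCdaParams(path)
    expect_equal(q@h, p@h, tolerance = 1e-12)
    expect_equal(q@J, p@J, tolerance = 1e-12)
    expect_equal(q@encoding, enc)
  }
})
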