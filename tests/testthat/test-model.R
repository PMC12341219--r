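# helper: assemble a minimal hmsc_fit by hand from given draw arrays
fake_fit <- function(B_chains, X, taxa, Lambda_chains = NULL,
                     eta_chains = NULL, levels = list(), component = "presence") {
  chains <- lapply(seq_along(B_chains), function(i) {
    list(B = B_chains[[i]],
         Lambda = if (!is.null(Lambda_chains)) Lambda_chains[[i]] else list(),
         eta = if (!is.null(eta_chains)) eta_chains[[i]] else list(),
         sigma2 = matrix(1, dim(B_chains[[i]])[1], length(taxa)))
  })
  structure(list(
    component = component, chains = chains, X = X,
    levels = levels, group_levels = lapply(levels, unique), taxa = taxa,
    n_factors = stats::setNames(rep(2L, length(levels)), names(levels)),
    mcmc = list(chains = length(chains), retained = dim(B_chains[[1]])[1],
                thin = 1L, n_iter = 0L, burn = 0L),
    seed = 1L
  ), class = "hmsc_fit")
}

test_that("hurdle_split standardises present cells and excludes sparse taxa", {
  copies <- rbind(t1 = c(0, 10, 100, 1000),
                  t2 = c(5, 5, 5, 5),
                  t3 = c(0, 0, 0, 42))
  colnames(copies) <- paste0("s", 1:4)
  expect_warning(h <- hurdle_split(copies), "excluded")
  expect_equal(unname(h$P[, "t1"]), c(0, 1, 1, 1))
  expect_equal(h$excluded, "t3")
  # standardisation oracle: mean 0, sd 1 over present cells
  a <- h$A[, "t1"]
  expect_equal(mean(a, na.rm = TRUE), 0)
  expect_equal(stats::sd(a, na.rm = TRUE), 1)
  expect_equal(sum(is.na(a)), 1L)
  obs <- log(copies["t1", copies["t1", ] > 0])
  expect_equal(unname(a[!is.na(a)]), unname((obs - mean(obs)) / stats::sd(obs)))
  # all-present taxon has no missing cells
  expect_false(anyNA(h$A[, "t2"]))
})

test_that("split-chain PSRF matches the textbook formula and flags divergence", {
  set.seed(3)
  # identical stationary chains: PSRF ~ 1 for every parameter (split-chain
  # R-hat also compares chain halves, so white noise sits near 1, not at it)
  m <- matrix(rnorm(200), 100, 2)
  expect_equal(unname(psrf(list(m, m))), c(1, 1), tolerance = 0.05)
  # chains centred at 0 vs 10: PSRF >> 1.05
  far <- psrf(list(matrix(rnorm(100), 100, 1),
                   matrix(rnorm(100, 10), 100, 1)))
  expect_gt(far, 3)
  # formula oracle computed step by step on stored toy chains
  c1 <- matrix(seq(0, 1, length.out = 40) + rnorm(40, 0, 0.1), 40, 1)
  c2 <- matrix(rnorm(40, 0.3, 0.4), 40, 1)
  got <- psrf(list(c1, c2))
  segs <- list(c1[1:20, 1], c1[21:40, 1], c2[1:20, 1], c2[21:40, 1])
  n <- 20
  W <- mean(sapply(segs, var))
  B <- n * var(sapply(segs, mean))
  expect_equal(unname(got), sqrt(((n - 1) / n * W + B / n) / W))
  expect_error(psrf(list(m)), "2 chains")
})

test_that("AUC and Tjur R2 match brute-force oracles", {
  set.seed(7)
  y <- rbinom(40, 1, 0.4)
  p <- runif(40)
  fitX <- cbind(intercept = 1)
  # brute force over all concordant/discordant pairs
  pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
  brute <- mean(ifelse(p[pairs$i] > p[pairs$j], 1,
                       ifelse(p[pairs$i] == p[pairs$j], 0.5, 0)))
  expect_equal(darkamp:::auc_rank(p, y), brute)
  expect_equal(darkamp:::tjur_r2(p, y),
               mean(p[y == 1]) - mean(p[y == 0]))
  # perfect separation
  expect_equal(darkamp:::auc_rank(y + 0.0, y), 1)
  expect_equal(darkamp:::tjur_r2(y + 0.0, y), 1)
  # predictions independent of outcomes at large n: AUC ~ 0.5
  set.seed(8)
  y2 <- rbinom(5000, 1, 0.5); p2 <- runif(5000)
  expect_equal(darkamp:::auc_rank(p2, y2), 0.5, tolerance = 0.03)
})

test_that("fixed-effect support calls follow pooled posterior sign fractions", {
  X <- cbind(intercept = 1, season = c(0, 1), sex = c(0, 1))
  B1 <- array(0, c(100, 3, 2))
  B1[, 2, 1] <- abs(rnorm(100)) + 0.1       # taxon 1: all-positive season draws
  B1[, 2, 2] <- rnorm(100)                  # taxon 2: symmetric about zero
  B1[, 3, ] <- rnorm(200)
  fit <- fake_fit(list(B1, B1), X, taxa = c("tA", "tB"))
  supp <- fixed_effect_support(fit, prob = 0.95)
  expect_equal(supp$season$taxa$call, c("positive", "none"))
  expect_equal(supp$season$prop_positive, 0.5)
})

test_that("residual associations recover constructed loading structure", {
  J <- 4
  lam_draw <- function(noise = 0.02) {
    l <- matrix(rnorm(2 * J, 0, noise), 2, J)
    l[1, 1] <- l[1, 2] <- 1      # taxa 1,2 load identically
    l[1, 3] <- -1                # taxon 3 opposite
    l
  }
  mk <- function() {
    arr <- array(0, c(50, 2, J))
    for (i in 1:50) arr[i, , ] <- lam_draw()
    arr
  }
  X <- cbind(intercept = 1, season = 0:1, sex = c(0, 1))
  B <- array(0, c(50, 3, J))
  fit <- fake_fit(list(B, B), X, taxa = paste0("t", 1:J),
                  Lambda_chains = list(list(site = mk()), list(site = mk())),
                  eta_chains = list(list(site = array(0, c(50, 2, 2))),
                                    list(site = array(0, c(50, 2, 2)))),
                  levels = list(site = c("a", "b")))
  ra <- residual_associations(fit, "site", prob = 0.90)
  expect_equal(unname(ra$sign["t1", "t2"]), 1)
  expect_gte(ra$support["t1", "t2"], 0.9)
  expect_equal(unname(ra$sign["t1", "t3"]), -1)
  expect_gte(ra$support["t1", "t3"], 0.9)
  expect_equal(unname(diag(ra$mean_corr)), rep(1, J))
  # taxon 4 is independent noise: no supported association with taxon 1
  expect_lt(ra$support["t1", "t4"], 0.9)
  expect_error(residual_associations(fit, "species"), "level")
})

test_that("independent taxa rarely reach 0.90 association support", {
  set.seed(9)
  J <- 10
  mk <- function() {
    arr <- array(rnorm(200 * 2 * J, 0, 0.1), c(200, 2, J))
    arr
  }
  X <- cbind(intercept = 1, season = 0:1, sex = c(0, 1))
  B <- array(0, c(200, 3, J))
  fit <- fake_fit(list(B, B), X, taxa = paste0("t", 1:J),
                  Lambda_chains = list(list(site = mk()), list(site = mk())),
                  eta_chains = list(list(site = array(0, c(200, 2, 2))),
                                    list(site = array(0, c(200, 2, 2)))),
                  levels = list(site = c("a", "b")))
  ra <- residual_associations(fit, "site", prob = 0.90)
  off <- ra$support[upper.tri(ra$support)]
  expect_gte(mean(off < 0.90), 0.95)
})

test_that("variance partitioning attributes pure fixed effects entirely", {
  set.seed(10)
  X <- cbind(intercept = 1, season = rep(0:1, 10), sex = rep(c(0, 1), each = 10))
  B <- array(0, c(30, 3, 2))
  B[, 2, 1] <- 2                             # taxon 1: season only
  B[, 2, 2] <- 1; B[, 3, 2] <- 1             # taxon 2: equal season and sex
  lam0 <- array(0, c(30, 2, 2))
  eta0 <- array(rnorm(30 * 4 * 2), c(30, 4, 2))
  fit <- fake_fit(list(B, B), X, taxa = c("tA", "tB"),
                  Lambda_chains = list(list(site = lam0), list(site = lam0)),
                  eta_chains = list(list(site = eta0), list(site = eta0)),
                  levels = list(site = rep(c("a", "b", "c", "d"), 5)))
  vp <- variance_partition(fit)
  expect_equal(unname(vp["season", "tA"]), 1)
  expect_equal(unname(vp["site", "tA"]), 0)
  # symmetric construction: equal season and sex variance -> 0.5 / 0.5
  expect_equal(unname(vp["season", "tB"]), 0.5)
  expect_equal(unname(vp["sex", "tB"]), 0.5)
  # fractions sum to one per taxon
  expect_equal(unname(colSums(vp)), c(1, 1), tolerance = 1e-8)
})

test_that("probit likelihood is invariant to factor sign flips", {
  set.seed(11)
  n <- 50; J <- 4; K <- 2
  X <- cbind(intercept = 1, season = rbinom(n, 1, 0.5), sex = rbinom(n, 1, 0.5))
  B <- matrix(rnorm(3 * J), 3, J)
  eta <- matrix(rnorm(10 * K), 10, K)
  lam <- matrix(rnorm(K * J), K, J)
  g <- sample(10, n, replace = TRUE)
  M1 <- X %*% B + eta[g, ] %*% lam
  M2 <- X %*% B + (-eta[g, ]) %*% (-lam)
  Y <- (M1 + rnorm(n * J) > 0) * 1
  ll <- function(M) sum(Y * pnorm(M, log.p = TRUE) +
                          (1 - Y) * pnorm(-M, log.p = TRUE))
  expect_equal(ll(M1), ll(M2))
})

test_that("the sampler recovers fixed effects and planted sex bias", {
  sim <- simulate_hmsc(n = 200, J = 10, component = "presence", seed = 3,
                       b_sd = 1.2)
  fit <- fit_community(sim$Y, sim$covariates, sim$levels, "presence",
                       n_factors = 2, chains = 2, retained = 100, thin = 1,
                       seed = 5)
  expect_s3_class(fit, "hmsc_fit")
  bhat <- coef(fit)
  expect_gt(stats::cor(as.vector(bhat), as.vector(sim$truth$B)), 0.8)
  # strong planted sex effects are called with the right sign
  strong <- which(abs(sim$truth$B["sex", ]) > 1)
  if (length(strong) >= 2) {
    supp <- fixed_effect_support(fit, prob = 0.95)
    calls <- supp$sex$taxa$call[strong]
    want <- ifelse(sim$truth$B["sex", strong] > 0, "positive", "negative")
    expect_gte(mean(calls == want), 0.75)
  }
  # printing and summarising work
  expect_output(print(fit), "presence")
})

test_that("fixed-effect RMSE shrinks with sample size", {
  rmse_at <- function(n, seed) {
    sim <- simulate_hmsc(n = n, J = 8, component = "presence", seed = seed)
    fit <- fit_community(sim$Y, sim$covariates, sim$levels, "presence",
                         n_factors = 2, chains = 2, retained = 100, thin = 1,
                         seed = seed + 1)
    sqrt(mean((coef(fit) - sim$truth$B)^2))
  }
  expect_lt(rmse_at(400, 21), rmse_at(100, 21))
})

test_that("the abundance component fits observed cells only and is evaluated", {
  sim <- simulate_hmsc(n = 200, J = 8, component = "abundance", seed = 6,
                       missing_frac = 0.3)
  fit <- fit_community(sim$Y, sim$covariates, sim$levels, "abundance",
                       n_factors = 2, chains = 2, retained = 100, thin = 1,
                       seed = 2)
  expect_gt(stats::cor(as.vector(coef(fit)), as.vector(sim$truth$B)), 0.8)
  ev <- evaluate(fit, cv = FALSE)
  expect_true(all(ev$explanatory$r2 >= 0 & ev$explanatory$r2 <= 1, na.rm = TRUE))
})

test_that("explanatory metrics exceed predictive metrics on average", {
  sim <- simulate_hmsc(n = 120, J = 6, component = "presence", seed = 13)
  fit <- fit_community(sim$Y, sim$covariates, sim$levels, "presence",
                       n_factors = 2, chains = 2, retained = 80, thin = 1,
                       seed = 3)
  ev <- evaluate(fit, folds = 2, seed = 4, cv = TRUE)
  expect_gte(mean(ev$explanatory$auc, na.rm = TRUE),
             mean(ev$predictive$auc, na.rm = TRUE))
})

test_that("degenerate inputs are refused", {
  sim <- simulate_hmsc(n = 40, J = 3, component = "presence", seed = 2)
  Y <- sim$Y
  Y[, 1] <- 0   # all-absent taxon
  expect_error(fit_community(Y, sim$covariates, sim$levels, "presence",
                             chains = 2, retained = 10),
               "constant")
  X <- cbind(intercept = 1, season = 1, sex = rep(0:1, 20))  # rank deficient
  expect_error(fit_community(sim$Y, levels = sim$levels, component = "presence",
                             X = X, chains = 2, retained = 10),
               "full rank")
  expect_error(psrf_check(structure(list(mcmc = list(chains = 1)),
                                    class = "hmsc_fit")),
               "2 chains")
})
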