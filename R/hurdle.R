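# Hierarchical hurdle community model: probit presence-absence and Gaussian
# conditional abundance with season/sex fixed effects and latent-factor
# random effects (site, host species, host genotype, individual).
#
# The sampler is a blocked Gibbs scheme. Presence uses probit data
# augmentation with truncated-normal latents; conditional abundance uses a
# Gaussian likelihood with missing (non-present) cells imputed each sweep,
# which keeps every conditional update a balanced matrix operation while
# leaving the observed-data posterior untouched. Factor loadings carry a
# multiplicative-gamma shrinkage prior; fixed effects a standard-normal
# prior; residual variances (abundance only) an inverse-gamma(0.5, 0.5)
# prior.

#' Split an abundance table into hurdle responses
#'
#' Presence is `copies > 0`; the conditional-abundance response is the
#' natural log of copies, standardised per taxon (mean 0, sd 1) over
#' present cells only, with non-presences missing. Taxa present in fewer
#' than two samples are excluded from the abundance response.
#'
#' @param copies Taxa x sample matrix of copy numbers (or read counts).
#' @return list: `P` (samples x taxa 0/1 matrix), `A` (samples x taxa with
#'   NA at absences; columns standardised), `excluded` (taxa dropped from
#'   `A`).
#' @export
hurdle_split <- function(copies) {
  P <- t(copies > 0) * 1L
  A <- t(copies)
  A[A <= 0] <- NA
  A <- log(A)
  n_pres <- colSums(!is.na(A))
  excluded <- colnames(A)[n_pres < 2]
  if (length(excluded)) {
    warning("taxa present in < 2 samples excluded from abundance response: ",
            paste(excluded, collapse = ", "))
  }
  A <- A[, n_pres >= 2, drop = FALSE]
  for (j in seq_len(ncol(A))) {
    mu <- mean(A[, j], na.rm = TRUE)
    sdv <- stats::sd(A[, j], na.rm = TRUE)
    # constant present values carry no abundance signal: centred to zero
    A[, j] <- if (is.na(sdv) || sdv == 0) (A[, j] - mu) else (A[, j] - mu) / sdv
  }
  list(P = P, A = A, excluded = excluded)
}

#' Build the fixed-effect design matrix
#'
#' Intercept plus indicator contrasts for season (summer vs spring) and sex
#' (male vs female).
#'
#' @param covariates data.frame with factors/characters `season`
#'   (`"spring"`/`"summer"`) and `sex` (`"F"`/`"M"`).
#' @return Numeric matrix with columns `intercept`, `season`, `sex`.
#' @export
build_design <- function(covariates) {
  X <- cbind(
    intercept = 1,
    season = as.numeric(covariates$season == "summer"),
    sex = as.numeric(covariates$sex == "M")
  )
  rownames(X) <- rownames(covariates)
  X
}

# truncated-normal latents for the probit layer: draw z ~ N(m, 1) subject to
# sign(z) matching y, numerically stable deep in the tails
rtnorm_probit <- function(M, Y) {
  s <- ifelse(Y == 1, 1, -1)
  mm <- pmax(s * M, -37)
  u <- matrix(stats::runif(length(M)), nrow(M))
  q <- stats::qnorm(pmax((1 - u) * stats::pnorm(mm), 1e-300),
                    lower.tail = FALSE)
  s * (mm + q)
}

# one-chain Gibbs run; returns retained draws
run_chain <- function(Y, X, groups, K, component, n_iter, burn, thin,
                      priors, seed) {
  set.seed(seed)
  n <- nrow(Y); J <- ncol(Y); p <- ncol(X)
  L <- length(groups)
  lev_names <- names(groups)
  G <- vapply(groups, nlevels, integer(1))
  gidx <- lapply(groups, as.integer)
  gsize <- lapply(gidx, tabulate)
  presence <- component == "presence"
  obs <- !is.na(Y)
  miss <- !obs

  # state
  B <- matrix(0, p, J)
  sigma2 <- rep(1, J)
  Lam <- lapply(seq_len(L), function(l) matrix(stats::rnorm(K[l] * J, 0, 0.1), K[l], J))
  eta <- lapply(seq_len(L), function(l) matrix(stats::rnorm(G[l] * K[l]), G[l], K[l]))
  phi <- lapply(seq_len(L), function(l) matrix(1, K[l], J))
  delta <- lapply(seq_len(L), function(l) rep(1, K[l]))
  Fl <- lapply(seq_len(L), function(l) eta[[l]][gidx[[l]], , drop = FALSE] %*% Lam[[l]])
  Ftot <- Reduce(`+`, Fl, matrix(0, n, J))
  Z <- Y
  if (presence) Z <- ifelse(Y == 1, 0.5, -0.5) else Z[miss] <- 0
  XtX <- crossprod(X)
  Ip <- diag(p)

  n_keep <- (n_iter - burn) %/% thin
  out <- list(
    B = array(NA_real_, c(n_keep, p, J)),
    Lambda = lapply(seq_len(L), function(l) array(NA_real_, c(n_keep, K[l], J))),
    eta = lapply(seq_len(L), function(l) array(NA_real_, c(n_keep, G[l], K[l]))),
    sigma2 = matrix(NA_real_, n_keep, J)
  )
  keep_i <- 0L

  for (it in seq_len(n_iter)) {
    M <- X %*% B + Ftot
    # -- latent/missing response
    if (presence) {
      Z <- rtnorm_probit(M, Y)
    } else if (any(miss)) {
      Z[miss] <- M[miss] +
        stats::rnorm(sum(miss)) * sqrt(sigma2)[col(Z)[miss]]
    }
    # -- fixed effects
    R <- Z - Ftot
    XtR <- crossprod(X, R)
    if (presence) {
      V <- solve(XtX + Ip)
      Rv <- chol(V)
      B <- V %*% XtR + t(Rv) %*% matrix(stats::rnorm(p * J), p, J)
    } else {
      for (j in seq_len(J)) {
        V <- solve(XtX / sigma2[j] + Ip)
        B[, j] <- V %*% (XtR[, j] / sigma2[j]) +
          t(chol(V)) %*% stats::rnorm(p)
      }
    }
    XB <- X %*% B
    # -- latent factors per level
    for (l in seq_len(L)) {
      Kl <- K[l]
      Rl <- Z - XB - (Ftot - Fl[[l]])
      # eta given Lambda
      Lw <- t(Lam[[l]]) / sigma2           # J x K
      A <- Lam[[l]] %*% Lw                 # K x K
      S <- rowsum(Rl, gidx[[l]], reorder = TRUE)  # G x J (group order 1..G)
      rhs <- S %*% Lw                      # G x K
      neweta <- matrix(0, G[l], Kl)
      for (m in unique(gsize[[l]])) {
        sel <- which(gsize[[l]] == m)
        V <- solve(diag(Kl) + m * A)
        Rv <- chol((V + t(V)) / 2)
        mean_sel <- rhs[sel, , drop = FALSE] %*% V
        neweta[sel, ] <- mean_sel +
          matrix(stats::rnorm(length(sel) * Kl), ncol = Kl) %*% Rv
      }
      eta[[l]] <- neweta
      # Lambda given eta, with multiplicative-gamma shrinkage
      H <- neweta[gidx[[l]], , drop = FALSE]
      HtH <- crossprod(H)
      HtR <- crossprod(H, Rl)
      tau <- cumprod(delta[[l]])
      for (j in seq_len(J)) {
        P <- HtH / sigma2[j] + diag(phi[[l]][, j] * tau, Kl)
        V <- solve(P)
        Lam[[l]][, j] <- V %*% (HtR[, j] / sigma2[j]) +
          t(chol((V + t(V)) / 2)) %*% stats::rnorm(Kl)
      }
      # shrinkage hyperparameters
      nu <- priors$nu
      lam2 <- Lam[[l]]^2
      phi[[l]] <- matrix(
        stats::rgamma(Kl * J, (nu + 1) / 2, rate = (nu + lam2 * tau) / 2),
        Kl, J)
      pl2 <- phi[[l]] * lam2               # K x J
      for (h in seq_len(Kl)) {
        tau_wo <- cumprod(delta[[l]])
        tau_wo[h:Kl] <- tau_wo[h:Kl] / delta[[l]][h]
        shape <- (if (h == 1) priors$a1 else priors$a2) + J * (Kl - h + 1) / 2
        rate <- 1 + 0.5 * sum(tau_wo[h:Kl] * rowSums(pl2)[h:Kl])
        delta[[l]][h] <- stats::rgamma(1, shape, rate = rate)
      }
      Ftot <- Ftot - Fl[[l]]
      Fl[[l]] <- H %*% Lam[[l]]
      Ftot <- Ftot + Fl[[l]]
    }
    # -- residual variances (abundance only)
    if (!presence) {
      E <- Z - XB - Ftot
      sigma2 <- 1 / stats::rgamma(
        J, priors$sigma_a + n / 2,
        rate = priors$sigma_b + colSums(E^2) / 2)
    }
    # -- retain
    if (it > burn && (it - burn) %% thin == 0) {
      keep_i <- keep_i + 1L
      out$B[keep_i, , ] <- B
      for (l in seq_len(L)) {
        out$Lambda[[l]][keep_i, , ] <- Lam[[l]]
        out$eta[[l]][keep_i, , ] <- eta[[l]]
      }
      out$sigma2[keep_i, ] <- sigma2
    }
  }
  names(out$Lambda) <- lev_names
  names(out$eta) <- lev_names
  out
}

#' Fit a hierarchical latent-factor community model
#'
#' Fits one hurdle component: `"presence"` (Bernoulli-probit via data
#' augmentation) or `"abundance"` (Gaussian on log-scaled abundance with
#' non-present cells missing). Season and sex enter as fixed effects; each
#' random level (e.g. site, species, genotype, sample unit) contributes
#' latent factors with taxon loadings under a multiplicative-gamma
#' shrinkage prior. Each chain runs `375 * thin` iterations, discards the
#' first `125 * thin` as burn-in and retains every `thin`-th draw, giving
#' `retained` draws per chain.
#'
#' @param Y Samples x taxa response matrix: 0/1 for presence, real with NA
#'   for conditional abundance (see [hurdle_split()]).
#' @param covariates data.frame with `season` and `sex` (see
#'   [build_design()]), or a pre-built design via `X`.
#' @param levels Named list of character/factor vectors (length n): random
#'   levels, e.g. `list(site=, species=, genotype=, unit=)`.
#' @param component `"presence"` or `"abundance"`.
#' @param n_factors Latent factors per level (scalar or named vector).
#' @param chains Number of MCMC chains.
#' @param retained Retained draws per chain.
#' @param thin Thinning interval; total iterations are `1.5 * retained *
#'   thin` per chain with the first third as burn-in.
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @param X Optional design matrix overriding `covariates`.
#' @param priors Prior hyperparameters (see defaults).
#' @return An object of class `"hmsc_fit"`.
#' @export
fit_community <- function(Y, covariates = NULL, levels, component = c("presence", "abundance"),
                          n_factors = 2L, chains = 4L, retained = 250L, thin = 1L,
                          seed = 1L, X = NULL,
                          priors = list(a1 = 2, a2 = 3, nu = 3,
                                        sigma_a = 0.5, sigma_b = 0.5)) {
  component <- match.arg(component)
  if (is.null(X)) X <- build_design(covariates)
  stopifnot(nrow(X) == nrow(Y))
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is not full rank")
  if (component == "presence") {
    const <- apply(Y, 2, function(y) all(y == y[1]))
    if (any(const)) {
      stop("taxa with constant presence must be excluded before fitting: ",
           paste(colnames(Y)[const], collapse = ", "))
    }
  }
  groups <- lapply(levels, function(g) factor(as.character(g)))
  K <- if (length(n_factors) == 1) {
    stats::setNames(rep(as.integer(n_factors), length(groups)), names(groups))
  } else {
    vapply(names(groups), function(l) as.integer(n_factors[[l]]), integer(1))
  }
  burn <- (retained %/% 2L) * thin
  n_iter <- burn + retained * thin
  chain_draws <- lapply(seq_len(chains), function(cc) {
    run_chain(Y, X, groups, K, component, n_iter, burn, thin,
              priors, seed = seed + cc - 1L)
  })
  structure(list(
    component = component, chains = chain_draws, X = X,
    levels = lapply(groups, as.character),
    group_levels = lapply(groups, levels),
    taxa = colnames(Y) %||% paste0("taxon", seq_len(ncol(Y))),
    Y = Y, n_factors = K,
    mcmc = list(chains = chains, retained = retained, thin = thin,
                n_iter = n_iter, burn = burn),
    seed = seed
  ), class = "hmsc_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hmsc_fit <- function(x, ...) {
  cat("Hierarchical latent-factor community model (", x$component, " component)\n",
      sep = "")
  cat(sprintf("  taxa: %d  samples: %d\n", length(x$taxa), nrow(x$X)))
  cat(sprintf("  random levels: %s\n",
              paste(sprintf("%s (%d groups, %d factors)", names(x$levels),
                            vapply(x$group_levels, length, integer(1)),
                            x$n_factors), collapse = ", ")))
  cat(sprintf("  MCMC: %d chains x %d retained (thin %d, burn-in %d)\n",
              x$mcmc$chains, x$mcmc$retained, x$mcmc$thin, x$mcmc$burn))
  invisible(x)
}

#' Posterior mean fixed effects
#' @param object An `hmsc_fit`.
#' @param ... Unused.
#' @return Covariate x taxon matrix of posterior means.
#' @export
coef.hmsc_fit <- function(object, ...) {
  draws <- do.call(abind1, lapply(object$chains, `[[`, "B"))
  out <- apply(draws, c(2, 3), mean)
  dimnames(out) <- list(colnames(object$X), object$taxa)
  out
}

# bind draw arrays along iteration margin
abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  d[1] <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  out <- array(NA_real_, d)
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

# pooled draws of one fixed-effect covariate: (chains*retained) x taxa
pooled_B <- function(fit, covariate) {
  ci <- match(covariate, colnames(fit$X))
  do.call(rbind, lapply(fit$chains, function(ch) ch$B[, ci, ]))
}

#' Split-chain potential scale reduction factors
#'
#' Standard split-R-hat: each chain is halved, and for each parameter
#' \eqn{\hat R = \sqrt{((n-1)/n \, W + B/n) / W}} with within-segment
#' variance W and between-segment variance B of the segment means.
#'
#' @param chains List of iteration x parameter matrices, one per chain.
#' @return Numeric vector of PSRF per parameter.
#' @export
psrf <- function(chains) {
  if (length(chains) < 2) stop("need at least 2 chains")
  segs <- list()
  for (m in chains) {
    n <- nrow(m); h <- n %/% 2L
    segs <- c(segs, list(m[seq_len(h), , drop = FALSE],
                         m[(n - h + 1L):n, , drop = FALSE]))
  }
  n <- nrow(segs[[1]])
  means <- vapply(segs, colMeans, numeric(ncol(chains[[1]])))
  vars <- vapply(segs, function(m) apply(m, 2, stats::var),
                 numeric(ncol(chains[[1]])))
  if (is.null(dim(means))) {
    means <- matrix(means, 1); vars <- matrix(vars, 1)
  }
  W <- rowMeans(vars)
  B <- n * apply(means, 1, stats::var)
  sqrt(((n - 1) / n * W + B / n) / pmax(W, .Machine$double.eps))
}

#' Convergence check on season and sex responses
#'
#' Computes split-chain PSRF over the per-taxon season and sex
#' coefficients and passes when the chosen quantile (third quartile by
#' default) is at most `threshold`.
#'
#' @param fit An `hmsc_fit`.
#' @param params Covariate names checked.
#' @param quantile Quantile of the PSRF distribution compared.
#' @param threshold Pass threshold.
#' @return list: `pass`, `q` (the quantile value), `psrf` (per parameter).
#' @export
psrf_check <- function(fit, params = c("season", "sex"), quantile = 0.75,
                       threshold = 1.05) {
  if (fit$mcmc$chains < 2) stop("need at least 2 chains")
  per_chain <- lapply(fit$chains, function(ch) {
    ci <- match(params, colnames(fit$X))
    do.call(cbind, lapply(ci, function(i) ch$B[, i, ]))
  })
  r <- psrf(per_chain)
  q <- stats::quantile(r, quantile, names = FALSE)
  list(pass = q <= threshold, q = q, psrf = r)
}

#' Fit with automatic thinning escalation
#'
#' Fits at `thin = 1` and escalates thin by factors of 10 until the PSRF
#' check passes or the ladder is exhausted, mirroring the usual
#' convergence protocol.
#'
#' @inheritParams fit_community
#' @param thin_ladder Increasing thinning values tried.
#' @param threshold PSRF pass threshold.
#' @return An `hmsc_fit` with elements `converged` and `psrf_q3` added.
#' @export
fit_community_auto <- function(Y, covariates = NULL, levels, component = "presence",
                               thin_ladder = c(1L, 10L, 100L, 1000L),
                               threshold = 1.05, ...) {
  fit <- NULL
  for (th in thin_ladder) {
    fit <- fit_community(Y, covariates, levels, component, thin = th, ...)
    chk <- psrf_check(fit, threshold = threshold)
    fit$converged <- chk$pass
    fit$psrf_q3 <- chk$q
    if (chk$pass) break
  }
  fit
}

#' Variance partitioning over fixed covariates and random levels
#'
#' Per taxon and posterior draw, each component's share is the variance
#' over samples of its fitted contribution to the linear predictor: for a
#' covariate `var(x_c b_cj)`, for a random level `var(eta[g(i)] lambda_j)`.
#' Using the realised contribution (the identified product of factors and
#' loadings) rather than loading norms keeps the attribution invariant to
#' the arbitrary relative scaling of factors versus loadings. Shares are
#' normalised to sum to one per draw and averaged over draws.
#'
#' @param fit An `hmsc_fit`.
#' @return Matrix (components x taxa) of mean variance fractions.
#' @export
variance_partition <- function(fit) {
  covars <- setdiff(colnames(fit$X), "intercept")
  lev_names <- names(fit$levels)
  J <- length(fit$taxa)
  comps <- c(covars, lev_names)
  acc <- matrix(0, length(comps), J, dimnames = list(comps, fit$taxa))
  n_draws <- 0L
  xvar <- apply(fit$X[, covars, drop = FALSE], 2, stats::var)
  gidx <- lapply(lev_names, function(l) {
    match(fit$levels[[l]], fit$group_levels[[l]])
  })
  names(gidx) <- lev_names
  col_vars <- function(M) colMeans(M^2) - colMeans(M)^2
  for (ch in fit$chains) {
    nit <- dim(ch$B)[1]
    for (it in seq_len(nit)) {
      V <- matrix(0, length(comps), J)
      for (ci in seq_along(covars)) {
        V[ci, ] <- xvar[ci] * ch$B[it, match(covars[ci], colnames(fit$X)), ]^2
      }
      for (li in seq_along(lev_names)) {
        l <- lev_names[li]
        eta <- matrix(ch$eta[[l]][it, , ], dim(ch$eta[[l]])[2])
        lam <- matrix(ch$Lambda[[l]][it, , ], dim(ch$Lambda[[l]])[2])
        V[length(covars) + li, ] <- col_vars(eta[gidx[[l]], , drop = FALSE] %*% lam)
      }
      tot <- colSums(V)
      ok <- tot > 0
      V[, ok] <- sweep(V[, ok, drop = FALSE], 2, tot[ok], "/")
      acc <- acc + V
      n_draws <- n_draws + 1L
    }
  }
  acc / n_draws
}

# posterior-mean predictions on the response scale, optionally for new data
predict_hmsc <- function(fit, X = fit$X, levels = fit$levels) {
  n <- nrow(X); J <- length(fit$taxa)
  pred <- matrix(0, n, J)
  n_draws <- 0L
  gmaps <- lapply(names(fit$levels), function(l) {
    match(as.character(levels[[l]]), fit$group_levels[[l]])
  })
  names(gmaps) <- names(fit$levels)
  for (ch in fit$chains) {
    nit <- dim(ch$B)[1]
    for (it in seq_len(nit)) {
      M <- X %*% ch$B[it, , ]
      for (l in names(fit$levels)) {
        eta <- matrix(ch$eta[[l]][it, , ], dim(ch$eta[[l]])[2])
        lam <- matrix(ch$Lambda[[l]][it, , ], dim(ch$Lambda[[l]])[2])
        gi <- gmaps[[l]]
        contrib <- matrix(0, n, J)
        seen <- !is.na(gi)
        contrib[seen, ] <- eta[gi[seen], , drop = FALSE] %*% lam
        M <- M + contrib
      }
      pred <- pred + if (fit$component == "presence") stats::pnorm(M) else M
      n_draws <- n_draws + 1L
    }
  }
  pred / n_draws
}

# rank-based AUC
auc_rank <- function(p, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

tjur_r2 <- function(p, y) {
  if (!any(y == 1) || !any(y == 0)) return(NA_real_)
  mean(p[y == 1]) - mean(p[y == 0])
}

#' Explanatory and predictive fit metrics
#'
#' Explanatory metrics come from posterior-mean predictions on the fitting
#' data; predictive metrics from two-fold cross-validation with folds
#' stratified by a grouping level (species by default) so both folds carry
#' every retained group. Presence models report AUC and Tjur R-squared;
#' abundance models report squared Pearson correlation on observed cells.
#'
#' @param fit An `hmsc_fit`.
#' @param folds Number of CV folds.
#' @param seed Seed for the fold assignment.
#' @param cv Set `FALSE` to skip the (costly) cross-validation refits.
#' @param stratify_by Level name used to stratify folds.
#' @return list with `explanatory` and (if `cv`) `predictive`, each a
#'   data.frame per taxon.
#' @export
evaluate <- function(fit, folds = 2L, seed = 1L, cv = TRUE,
                     stratify_by = intersect("species", names(fit$levels))[1]) {
  Y <- fit$Y
  expl <- metric_frame(fit, predict_hmsc(fit), Y)
  out <- list(explanatory = expl)
  if (cv) {
    n <- nrow(Y)
    fold <- with_seed(seed, {
      f <- integer(n)
      strat <- if (!is.na(stratify_by) && !is.null(stratify_by)) {
        fit$levels[[stratify_by]]
      } else rep("all", n)
      for (s in unique(strat)) {
        idx <- which(strat == s)
        f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      f
    })
    pred <- matrix(NA_real_, n, length(fit$taxa))
    for (k in seq_len(folds)) {
      tr <- fold != k
      fit_k <- fit_community(
        Y[tr, , drop = FALSE], levels = lapply(fit$levels, `[`, tr),
        component = fit$component, n_factors = fit$n_factors,
        chains = fit$mcmc$chains, retained = fit$mcmc$retained,
        thin = fit$mcmc$thin, seed = fit$seed + 100L * k,
        X = fit$X[tr, , drop = FALSE]
      )
      pred[!tr, ] <- predict_hmsc(fit_k, X = fit$X[!tr, , drop = FALSE],
                                  levels = lapply(fit$levels, `[`, !tr))
    }
    out$predictive <- metric_frame(fit, pred, Y)
  }
  out
}

metric_frame <- function(fit, pred, Y) {
  if (fit$component == "presence") {
    data.frame(
      taxon = fit$taxa,
      auc = vapply(seq_along(fit$taxa), function(j) auc_rank(pred[, j], Y[, j]),
                   numeric(1)),
      tjur_r2 = vapply(seq_along(fit$taxa), function(j) tjur_r2(pred[, j], Y[, j]),
                       numeric(1)),
      row.names = NULL
    )
  } else {
    data.frame(
      taxon = fit$taxa,
      r2 = vapply(seq_along(fit$taxa), function(j) {
        obs <- !is.na(Y[, j]) & !is.na(pred[, j])
        if (sum(obs) < 3 || stats::sd(pred[obs, j]) == 0) return(NA_real_)
        stats::cor(pred[obs, j], Y[obs, j])^2
      }, numeric(1)),
      row.names = NULL
    )
  }
}

#' Posterior support for season and sex responses
#'
#' A taxon is called positive (negative) for a covariate when at least
#' `prob` of pooled posterior draws of its coefficient are above (below)
#' zero. Community-level proportions are reported alongside per-taxon
#' calls.
#'
#' @param fit An `hmsc_fit`.
#' @param prob Posterior probability required for a call.
#' @param params Covariates examined.
#' @return list per covariate: data.frame of per-taxon `p_pos` and `call`
#'   plus `prop_positive`/`prop_negative`.
#' @export
fixed_effect_support <- function(fit, prob = 0.95, params = c("season", "sex")) {
  out <- list()
  for (cv in params) {
    draws <- pooled_B(fit, cv)
    p_pos <- colMeans(draws > 0)
    call <- ifelse(p_pos >= prob, "positive",
                   ifelse(1 - p_pos >= prob, "negative", "none"))
    out[[cv]] <- list(
      taxa = data.frame(taxon = fit$taxa, p_pos = p_pos, call = call,
                        row.names = NULL),
      prop_positive = mean(call == "positive"),
      prop_negative = mean(call == "negative")
    )
  }
  out
}

#' Residual taxon-taxon associations at a random level
#'
#' For each posterior draw the level's association matrix is
#' \eqn{\Omega = \Lambda^\top \Lambda}; a pair's support is the larger of
#' the fractions of draws with positive or negative \eqn{\Omega_{ij}}.
#' Pairs at or above `prob` are reported with their sign.
#'
#' @param fit An `hmsc_fit`.
#' @param level Random-level name.
#' @param prob Posterior support threshold.
#' @return list: `support` (taxa x taxa), `sign` (+1/-1/0), `pairs`
#'   (data.frame of supported pairs), `mean_corr` (correlation-scaled mean
#'   association matrix with unit diagonal).
#' @export
residual_associations <- function(fit, level, prob = 0.90) {
  if (!level %in% names(fit$levels)) stop("level not in model: ", level)
  J <- length(fit$taxa)
  pos <- neg <- matrix(0, J, J)
  omega_sum <- matrix(0, J, J)
  n_draws <- 0L
  for (ch in fit$chains) {
    nit <- dim(ch$Lambda[[level]])[1]
    for (it in seq_len(nit)) {
      lam <- matrix(ch$Lambda[[level]][it, , ], dim(ch$Lambda[[level]])[2])
      om <- crossprod(lam)
      pos <- pos + (om > 0)
      neg <- neg + (om < 0)
      omega_sum <- omega_sum + om
      n_draws <- n_draws + 1L
    }
  }
  pos <- pos / n_draws; neg <- neg / n_draws
  support <- pmax(pos, neg)
  sgn <- sign(pos - neg)
  dimnames(support) <- dimnames(sgn) <- list(fit$taxa, fit$taxa)
  om <- omega_sum / n_draws
  d <- sqrt(pmax(diag(om), .Machine$double.eps))
  corr <- om / outer(d, d)
  diag(corr) <- 1
  dimnames(corr) <- dimnames(support)
  ut <- which(upper.tri(support) & support >= prob, arr.ind = TRUE)
  pairs <- data.frame(
    taxon_a = fit$taxa[ut[, 1]], taxon_b = fit$taxa[ut[, 2]],
    sign = sgn[ut], support = support[ut], row.names = NULL
  )
  list(support = support, sign = sgn, pairs = pairs, mean_corr = corr)
}

#' @export
summary.hmsc_fit <- function(object, ...) {
  chk <- psrf_check(object)
  supp <- fixed_effect_support(object)
  vp <- variance_partition(object)
  out <- list(component = object$component, psrf_q3 = chk$q,
              converged = chk$pass, support = supp,
              variance_partition_mean = rowMeans(vp))
  class(out) <- "summary.hmsc_fit"
  out
}

#' @export
print.summary.hmsc_fit <- function(x, ...) {
  cat("Component:", x$component, "\n")
  cat(sprintf("PSRF Q3 (season & sex): %.3f (%s)\n", x$psrf_q3,
              if (x$converged) "converged" else "not converged"))
  cat("Mean variance fractions:\n")
  print(round(x$variance_partition_mean, 3))
  for (cv in names(x$support)) {
    cat(sprintf("%s: %.0f%% positive, %.0f%% negative taxa at 95%% support\n",
                cv, 100 * x$support[[cv]]$prop_positive,
                100 * x$support[[cv]]$prop_negative))
  }
  invisible(x)
}

#' @export
plot.hmsc_fit <- function(x, ...) {
  vp <- variance_partition(x)
  graphics::barplot(vp, col = seq_len(nrow(vp)) + 1, border = NA,
                    las = 2, cex.names = 0.6,
                    ylab = "variance fraction",
                    legend.text = rownames(vp),
                    args.legend = list(x = "topright", bty = "n", cex = 0.7), ...)
  invisible(vp)
}

#' Simulate data from the latent-factor hurdle model
#'
#' Generates a balanced season x sex design, random-level maps, true fixed
#' effects and loadings, and a response from the model's own generative
#' process; used for parameter-recovery checks.
#'
#' @param n Samples.
#' @param J Taxa.
#' @param n_site,n_species Group counts for the site and species levels.
#' @param n_factors True factors per level.
#' @param b_sd Standard deviation of true season/sex effects.
#' @param load_sd Named numeric: loading scale per level (levels absent
#'   from the model get 0).
#' @param component `"presence"` or `"abundance"`.
#' @param missing_frac For abundance: fraction of cells set missing at
#'   random (emulating the hurdle).
#' @param seed Seed.
#' @return list: `Y`, `covariates`, `levels`, `truth` (list with `B`,
#'   `Lambda`, `eta`, `X`).
#' @export
simulate_hmsc <- function(n = 200L, J = 20L, n_site = 6L, n_species = 8L,
                          n_factors = 2L,
                          b_sd = 1, load_sd = c(site = 0.3, species = 1,
                                                genotype = 0.3, unit = 0.3),
                          component = "presence", missing_frac = 0.3,
                          seed = 1L) {
  with_seed(seed, {
    covariates <- data.frame(
      season = sample(c("spring", "summer"), n, replace = TRUE),
      sex = sample(c("F", "M"), n, replace = TRUE)
    )
    X <- build_design(covariates)
    levels <- list(
      site = paste0("S", sample.int(n_site, n, replace = TRUE)),
      species = paste0("sp", sample.int(n_species, n, replace = TRUE)),
      genotype = NULL, unit = paste0("u", seq_len(n))
    )
    levels$genotype <- paste0(levels$species, "g",
                              sample.int(3, n, replace = TRUE))
    B <- rbind(intercept = stats::rnorm(J, 0, 0.5),
               season = stats::rnorm(J, 0, b_sd),
               sex = stats::rnorm(J, 0, b_sd))
    M <- X %*% B
    Lambda <- list(); eta <- list()
    for (l in names(levels)) {
      gl <- factor(levels[[l]])
      lam <- matrix(stats::rnorm(n_factors * J, 0, load_sd[[l]]), n_factors, J)
      et <- matrix(stats::rnorm(nlevels(gl) * n_factors), nlevels(gl), n_factors)
      Lambda[[l]] <- lam; eta[[l]] <- et
      M <- M + et[as.integer(gl), , drop = FALSE] %*% lam
    }
    if (component == "presence") {
      Y <- (M + matrix(stats::rnorm(n * J), n, J) > 0) * 1L
    } else {
      Y <- M + matrix(stats::rnorm(n * J), n, J)
      Y[matrix(stats::runif(n * J) < missing_frac, n, J)] <- NA
    }
    colnames(Y) <- paste0("taxon", seq_len(J))
    list(Y = Y, covariates = covariates, levels = levels,
         truth = list(B = B, Lambda = Lambda, eta = eta, X = X))
  })
}
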