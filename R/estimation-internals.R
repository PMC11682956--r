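# Internal machinery for mixed-effects estimation.
#
# The conditional model is linear given the individual parameters except for
# ke0, which enters through the effect-site concentration Ce. Plasma
# kinetics carry no random effects (PK is fixed, scaled by weight), so for
# each subject everything about the plasma side can be precomputed once and
# Ce(ke0) at the observation times becomes a cheap analytic function of ke0.
# That "Ce basis" is what makes SAEM and Laplace affordable in plain R.

# Per-subject Ce basis at fixed observation times.
# For a completed zero-order input (elapsed time u past the end of the
# absorption window) the contribution of one event of amount A is
#   A * [ ceD1u(k) e^{-k u} + sum_j g_j k/(k-lambda_j)(e^{-lambda_j u} - e^{-k u}) ]
# with per-subject constants q_j, F_j, g_j; summing over events needs only
# sum_e A_e e^{-k u_e} (k-dependent) and sum_e A_e e^{-lambda_j u_e}
# (precomputed). Events still inside their absorption window at an
# observation time are kept aside and evaluated exactly.
.ce_subject_basis <- function(pk_i, reg, times) {
  macro <- .pk_macro(pk_i)
  O <- length(times)
  if (nrow(reg) == 0L) {
    return(list(O = O, n_rows = 0L, u = numeric(), A = numeric(),
                obs = integer(), P = matrix(0, O, 2),
                lambda = macro$lambda, q = c(0, 0), F = c(1, 1), g = c(0, 0),
                d1 = pk_i$d1, partial = NULL))
  }
  d1 <- reg$duration[1]
  if (any(reg$duration != d1)) {
    stop("ce basis: all events of one regimen must share one duration",
         call. = FALSE)
  }
  rho <- 1000 / d1 # ug per day per mg of dose
  lambda <- macro$lambda
  q <- (rho / macro$v1) * macro$coef / lambda
  F_ <- exp(-lambda * d1)
  g <- q * (1 - F_)
  tau <- outer(times, reg$start, "-") # O x E
  complete <- which(tau >= d1)
  part <- which(tau > 0 & tau < d1)
  Amt <- matrix(reg$amount_mg, O, nrow(reg), byrow = TRUE)
  u <- tau[complete] - d1
  A <- Amt[complete]
  obs <- row(tau)[complete]
  P <- matrix(0, O, 2)
  for (j in 1:2) {
    pj <- A * exp(-lambda[j] * u)
    if (length(pj)) {
      rs <- rowsum(pj, obs)
      P[as.integer(rownames(rs)), j] <- rs
    }
  }
  partial <- NULL
  if (length(part)) {
    partial <- list(obs = row(tau)[part], A = Amt[part], tau = tau[part])
  }
  list(O = O, n_rows = length(u), u = u, A = A, obs = obs, P = P,
       lambda = lambda, q = q, F = F_, g = g, d1 = d1, partial = partial)
}

# Ce at the basis' observation times for one ke0 value
.ce_subject_eval <- function(b, ke0) {
  ce <- numeric(b$O)
  if (b$n_rows == 0L && is.null(b$partial)) return(ce)
  k <- ke0
  r <- k / (k - b$lambda)
  ekd1 <- exp(-k * b$d1)
  ceD1u <- sum(b$q * ((1 - ekd1) - r * (b$F - ekd1)))
  if (b$n_rows > 0L) {
    w <- b$A * exp(-k * b$u)
    W <- numeric(b$O)
    rs <- rowsum(w, b$obs)
    W[as.integer(rownames(rs))] <- rs
    ce <- ceD1u * W + b$g[1] * r[1] * (b$P[, 1] - W) +
      b$g[2] * r[2] * (b$P[, 2] - W)
  }
  if (!is.null(b$partial)) {
    p <- b$partial
    for (m in seq_along(p$obs)) {
      acc <- 0
      for (j in 1:2) {
        acc <- acc + b$q[j] * ((1 - exp(-k * p$tau[m])) -
                                 r[j] * (exp(-b$lambda[j] * p$tau[m]) -
                                           exp(-k * p$tau[m])))
      }
      ce[p$obs[m]] <- ce[p$obs[m]] + p$A[m] * acc
    }
  }
  ce
}

# Stack per-subject bases into flat arrays so Ce for all subjects at once is
# a handful of vectorised operations over all (observation, event) pairs.
.ce_stack <- function(bases) {
  n <- length(bases)
  O_i <- vapply(bases, `[[`, integer(1) + 0L, "O")
  obs_offset <- c(0L, cumsum(O_i))[seq_len(n)]
  N <- sum(O_i)
  u <- unlist(lapply(bases, `[[`, "u"), use.names = FALSE)
  A <- unlist(lapply(bases, `[[`, "A"), use.names = FALSE)
  row_obs <- unlist(lapply(seq_len(n), function(i) {
    bases[[i]]$obs + obs_offset[i]
  }), use.names = FALSE)
  row_subj <- rep.int(seq_len(n),
                      vapply(bases, `[[`, integer(1) + 0L, "n_rows"))
  P <- do.call(rbind, lapply(bases, `[[`, "P"))
  subj_obs <- rep.int(seq_len(n), O_i)
  lambda <- t(vapply(bases, `[[`, numeric(2), "lambda"))
  q <- t(vapply(bases, `[[`, numeric(2), "q"))
  F_ <- t(vapply(bases, `[[`, numeric(2), "F"))
  g <- t(vapply(bases, `[[`, numeric(2), "g"))
  d1 <- vapply(bases, `[[`, numeric(1), "d1")
  has_partial <- which(!vapply(bases, function(b) is.null(b$partial),
                               logical(1)))
  list(n = n, N = N, u = u, A = A, row_obs = row_obs, row_subj = row_subj,
       P = P, subj_obs = subj_obs, lambda = lambda, q = q, F = F_, g = g,
       d1 = d1, obs_offset = obs_offset, bases = bases,
       has_partial = has_partial)
}

# Ce for every observation row given one ke0 per subject
.ce_stack_eval <- function(st, ke0) {
  k_obs <- ke0[st$subj_obs]
  r1 <- k_obs / (k_obs - st$lambda[st$subj_obs, 1])
  r2 <- k_obs / (k_obs - st$lambda[st$subj_obs, 2])
  ekd1 <- exp(-k_obs * st$d1[st$subj_obs])
  q1 <- st$q[st$subj_obs, 1]; q2 <- st$q[st$subj_obs, 2]
  F1 <- st$F[st$subj_obs, 1]; F2 <- st$F[st$subj_obs, 2]
  ceD1u <- q1 * ((1 - ekd1) - r1 * (F1 - ekd1)) +
    q2 * ((1 - ekd1) - r2 * (F2 - ekd1))
  W <- numeric(st$N)
  if (length(st$u)) {
    w <- st$A * exp(-ke0[st$row_subj] * st$u)
    rs <- rowsum(w, st$row_obs)
    W[as.integer(rownames(rs))] <- rs
  }
  g1 <- st$g[st$subj_obs, 1]; g2 <- st$g[st$subj_obs, 2]
  ce <- ceD1u * W + g1 * r1 * (st$P[, 1] - W) + g2 * r2 * (st$P[, 2] - W)
  for (i in st$has_partial) {
    b <- st$bases[[i]]
    p <- b$partial
    k <- ke0[i]
    r <- k / (k - b$lambda)
    for (m in seq_along(p$obs)) {
      acc <- sum(b$q * ((1 - exp(-k * p$tau[m])) -
                          r * (exp(-b$lambda * p$tau[m]) - exp(-k * p$tau[m]))))
      idx <- st$obs_offset[i] + p$obs[m]
      ce[idx] <- ce[idx] + p$A[m] * acc
    }
  }
  ce
}

# ---- covariate / design-matrix layer -------------------------------------

.dim_names <- c("ke0", "e0", "deff", "kprog")

# covariate model: tibble(param, covariate, ref) where ref is the
# normalisation constant for continuous covariates (NA for sex)
.default_covmodel <- function(age_ref = 5) {
  tibble::tibble(param = "e0", covariate = "age", ref = age_ref)
}

.term_name <- function(param, covariate) {
  ifelse(param == "e0" & covariate == "age", "beta_age",
         paste0("beta_", param, "_", covariate))
}

# per-subject 4 x p design matrices mapping theta to the mean of
# phi = (log ke0, log e0, log deff, kprog)
.build_design <- function(demog, covmodel) {
  n <- nrow(demog)
  nterm <- if (is.null(covmodel)) 0L else nrow(covmodel)
  p <- 4L + nterm
  theta_names <- c("log_ke0", "log_e0", "log_deff", "kprog")
  M <- array(0, dim = c(n, 4, p))
  for (d in 1:4) M[, d, d] <- 1
  if (nterm > 0) {
    for (k in seq_len(nterm)) {
      cv <- covmodel$covariate[k]
      val <- demog[[cv]]
      if (is.null(val)) {
        stop("covariate `", cv, "` not found in demographics", call. = FALSE)
      }
      x <- if (cv == "sex") as.numeric(val == "female") else {
        log(val / covmodel$ref[k])
      }
      d <- match(covmodel$param[k], .dim_names)
      M[, d, 4L + k] <- x
      theta_names <- c(theta_names, .term_name(covmodel$param[k], cv))
    }
  }
  list(M = M, p = p, theta_names = theta_names)
}

# mean matrix mu (n x 4) for a theta vector
.mu_matrix <- function(design, theta) {
  n <- dim(design$M)[1]
  mu <- matrix(0, n, 4)
  for (d in 1:4) mu[, d] <- design$M[, d, , drop = TRUE] %*% theta
  mu
}

# ---- problem container ----------------------------------------------------

# Assemble everything estimation needs from a trial dataset: observed rows,
# per-subject Ce bases (PK fixed, allometrically scaled to weight), design
# matrices for the covariate model.
.prepare_problem <- function(dataset, fixed_pk, covmodel) {
  stopifnot(inherits(dataset, "trial_dataset"))
  dm <- dataset$demographics
  n <- nrow(dm)
  obs <- dataset$observations
  obs <- obs[!obs$missing & !is.na(obs$score), ]
  sid <- match(obs$id, dm$id)
  if (anyNA(sid)) stop("observations refer to unknown subjects", call. = FALSE)
  ord <- order(sid, obs$time)
  obs <- obs[ord, ]
  sid <- sid[ord]
  bases <- vector("list", n)
  for (i in seq_len(n)) {
    pk_i <- scale_pk(fixed_pk, dm$weight[i])
    reg_i <- dataset$dosing[dataset$dosing$id == dm$id[i], ]
    reg_i <- regimen(start = reg_i$start, amount_mg = reg_i$amount_mg,
                     duration = if (nrow(reg_i)) reg_i$duration else 0.0625)
    bases[[i]] <- .ce_subject_basis(pk_i, reg_i, obs$time[sid == i])
  }
  st <- .ce_stack(bases)
  design <- .build_design(dm, covmodel)
  obs_index <- split(seq_len(nrow(obs)), sid)
  list(y = obs$score, t = obs$time, subj = sid, n = n, N = nrow(obs),
       n_i = tabulate(sid, n), stack = st, bases = bases, design = design,
       demog = dm, covmodel = covmodel, fixed_pk = fixed_pk,
       obs_index = obs_index)
}

# predictions for all observation rows given phi (n x 4); ce may be passed
# in when ke0 has not changed
.predict_rows <- function(prob, phi, ce = NULL) {
  if (is.null(ce)) ce <- .ce_stack_eval(prob$stack, exp(phi[, 1]))
  list(f = exp(phi[prob$subj, 2]) + phi[prob$subj, 4] * prob$t +
         exp(phi[prob$subj, 3]) * ce,
       ce = ce)
}

.rss_by_subject <- function(prob, f) {
  as.vector(rowsum((prob$y - f)^2, prob$subj))
}

# Omega as a 4x4 from (omega vector of 4 SDs, corr between e0 and kprog)
.omega_matrix <- function(om, corr) {
  S <- diag(om^2)
  S[2, 4] <- S[4, 2] <- corr * om[2] * om[4]
  S
}

# pseudo-inverse restricted to active dims (positive SDs); inactive etas are
# pinned at zero
.omega_inverse <- function(om, corr) {
  act <- which(om > 0)
  Oi <- matrix(0, 4, 4)
  if (length(act)) {
    Oi[act, act] <- solve(.omega_matrix(om, corr)[act, act, drop = FALSE])
  }
  list(inv = Oi, active = act)
}

# ---- SAEM -----------------------------------------------------------------

#' SAEM control settings
#'
#' @param n_burn Exploration-phase iterations (step size 1).
#' @param n_iter Smoothing-phase iterations (decreasing step size).
#' @param n_chains Number of parallel MCMC chains.
#' @param mcmc_sweeps Componentwise random-walk sweeps per iteration.
#' @param gamma_burn Stochastic-approximation step size during the
#'   exploration phase. Values below 1 average the sufficient statistics
#'   over roughly `1/gamma_burn` iterations, damping single-draw noise.
#' @param gamma_power Exponent of the smoothing-phase step size
#'   `1/k^gamma_power`; must lie in (0.5, 1] for convergence, smaller
#'   values forget the exploration state faster.
#' @param refresh_every How often (iterations) the joint-kernel proposal
#'   geometry (per-subject Laplace covariances) is recomputed.
#' @return A list of class `saem_control`.
#' @export
saem_control <- function(n_burn = 300, n_iter = 400, n_chains = 2,
                         mcmc_sweeps = 2, gamma_burn = 0.25,
                         gamma_power = 0.7, refresh_every = 25) {
  structure(list(n_burn = n_burn, n_iter = n_iter, n_chains = n_chains,
                 mcmc_sweeps = mcmc_sweeps, gamma_burn = gamma_burn,
                 gamma_power = gamma_power, refresh_every = refresh_every),
            class = "saem_control")
}

# per-subject proposal geometry for the joint MH kernel: Cholesky factors of
# the local posterior covariance (inverse Hessian at a warm-started mode).
# The per-subject posteriors couple the etas strongly (baseline with slope,
# ke0 with deff), so componentwise walks alone mix far too slowly.
.refresh_jprop <- function(prob, theta, om, corr, sigma2, eta) {
  act <- which(om > 0)
  Oact <- .omega_matrix(om, corr)[act, act, drop = FALSE]
  Oinv <- solve(Oact)
  Lfall <- chol(Oact)
  mu <- .mu_matrix(prob$design, theta)
  L <- vector("list", prob$n)
  modes <- matrix(0, prob$n, length(act))
  gmode <- rep(Inf, prob$n)
  for (i in seq_len(prob$n)) {
    g <- function(e) .subject_g(prob, i, mu[i, ], Oinv, act, sigma2, e)
    opt <- tryCatch(stats::nlminb(eta[i, act], g,
                                  control = list(iter.max = 30)),
                    error = function(e) NULL)
    L[[i]] <- Lfall
    if (is.null(opt)) next
    modes[i, ] <- opt$par
    gmode[i] <- opt$objective
    H <- tryCatch(stats::optimHess(opt$par, g), error = function(e) NULL)
    if (is.null(H)) next
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(V) || any(!is.finite(V)) || any(diag(V) <= 0)) next
    Lc <- tryCatch(chol((V + t(V)) / 2), error = function(e) NULL)
    if (!is.null(Lc)) L[[i]] <- Lc
  }
  list(L = L, act = act, modes = modes, gmode = gmode)
}

# one MH refresh of a chain's eta matrix; returns updated state
.mh_update <- function(prob, state, theta, om, corr, sigma2, prop_scale,
                       jprop = NULL, jscale = 1) {
  mu <- state$mu
  oi <- .omega_inverse(om, corr)
  act <- oi$active
  eta <- state$eta
  phi <- mu + eta
  ce <- state$ce
  f <- state$f
  rss <- state$rss
  qform <- function(e) {
    rowSums((e %*% oi$inv) * e)
  }
  qcur <- qform(eta)
  acc_count <- numeric(4)
  # kernel 1: independence proposal from the prior N(0, Omega)
  if (length(act)) {
    eta_star <- matrix(0, prob$n, 4)
    Sact <- .omega_matrix(om, corr)[act, act, drop = FALSE]
    z <- matrix(stats::rnorm(prob$n * length(act)), prob$n)
    eta_star[, act] <- z %*% chol(Sact)
    phi_star <- mu + eta_star
    pr <- .predict_rows(prob, phi_star)
    rss_star <- .rss_by_subject(prob, pr$f)
    lacc <- -0.5 * (rss_star - rss) / sigma2
    take <- log(stats::runif(prob$n)) < lacc
    if (any(take)) {
      eta[take, ] <- eta_star[take, ]
      rows <- unlist(prob$obs_index[take], use.names = FALSE)
      ce[rows] <- pr$ce[rows]
      f[rows] <- pr$f[rows]
      rss[take] <- rss_star[take]
      qcur[take] <- qform(eta)[take]
      phi <- mu + eta
    }
  }
  # kernel 2: joint random walk along the local posterior geometry
  acc_joint <- 0
  if (!is.null(jprop) && length(act)) {
    for (rep in 1:2) {
      z <- matrix(stats::rnorm(prob$n * length(act)), prob$n)
      eta_star <- eta
      for (i in seq_len(prob$n)) {
        eta_star[i, act] <- eta[i, act] +
          jscale * as.vector(z[i, ] %*% jprop$L[[i]])
      }
      phi_star <- mu + eta_star
      pr <- .predict_rows(prob, phi_star)
      rss_star <- .rss_by_subject(prob, pr$f)
      qstar <- qform(eta_star)
      lacc <- -0.5 * (rss_star - rss) / sigma2 - 0.5 * (qstar - qcur)
      take <- log(stats::runif(prob$n)) < lacc
      if (any(take)) {
        eta[take, ] <- eta_star[take, ]
        rows <- unlist(prob$obs_index[take], use.names = FALSE)
        ce[rows] <- pr$ce[rows]
        f[rows] <- pr$f[rows]
        rss[take] <- rss_star[take]
        qcur[take] <- qstar[take]
      }
      acc_joint <- acc_joint + mean(take) / 2
    }
  }
  # kernel 3: componentwise random walks
  for (sweep in seq_len(state$sweeps)) {
    for (d in act) {
      eta_star <- eta
      eta_star[, d] <- eta[, d] +
        prop_scale[d] * stats::rnorm(prob$n)
      phi_star <- mu + eta_star
      if (d == 1L) {
        pr <- .predict_rows(prob, phi_star)
      } else {
        pr <- .predict_rows(prob, phi_star, ce = ce)
      }
      rss_star <- .rss_by_subject(prob, pr$f)
      qstar <- qform(eta_star)
      lacc <- -0.5 * (rss_star - rss) / sigma2 - 0.5 * (qstar - qcur)
      take <- log(stats::runif(prob$n)) < lacc
      if (any(take)) {
        eta[take, d] <- eta_star[take, d]
        rows <- unlist(prob$obs_index[take], use.names = FALSE)
        ce[rows] <- pr$ce[rows]
        f[rows] <- pr$f[rows]
        rss[take] <- rss_star[take]
        qcur[take] <- qstar[take]
      }
      acc_count[d] <- acc_count[d] + mean(take)
    }
  }
  state$eta <- eta
  state$ce <- ce
  state$f <- f
  state$rss <- rss
  state$acc <- acc_count / max(1, state$sweeps)
  state$acc_joint <- acc_joint
  state
}

# M-step: GLS for theta given Omega, moment update for Omega, closed-form
# sigma; two alternating passes
.m_step <- function(prob, mphi, Sphi, rss_sa, theta, om, corr, sigma2,
                    estimate_corr) {
  act0 <- which(om > 0)
  for (pass in 1:2) {
    oi <- .omega_inverse(om, corr)
    Oi <- oi$inv
    # dims with zero variance still constrain theta: their phi is
    # deterministic, so fit them by least squares with a large weight
    for (d in setdiff(1:4, act0)) Oi[d, d] <- 1e6
    p <- prob$design$p
    A <- matrix(0, p, p)
    b <- numeric(p)
    for (i in seq_len(prob$n)) {
      Mi <- matrix(prob$design$M[i, , ], nrow = 4)
      A <- A + t(Mi) %*% Oi %*% Mi
      b <- b + t(Mi) %*% Oi %*% mphi[i, ]
    }
    theta <- as.vector(solve(A, b))
    mu <- .mu_matrix(prob$design, theta)
    # unstructured moment matrix, then projection onto the omega structure
    Om_hat <- matrix(0, 4, 4)
    for (i in seq_len(prob$n)) {
      Om_hat <- Om_hat + Sphi[i, , ] - tcrossprod(mphi[i, ], mu[i, ]) -
        tcrossprod(mu[i, ], mphi[i, ]) + tcrossprod(mu[i, ])
    }
    Om_hat <- Om_hat / prob$n
    om_new <- om
    om_new[act0] <- sqrt(pmax(diag(Om_hat)[act0], 1e-12))
    if (estimate_corr && all(c(2, 4) %in% act0)) {
      corr <- Om_hat[2, 4] / (om_new[2] * om_new[4])
      corr <- max(min(corr, 0.98), -0.98)
    }
    om <- om_new
  }
  sigma2 <- max(rss_sa / prob$N, 1e-12)
  list(theta = theta, om = om, corr = corr, sigma2 = sigma2)
}

.saem <- function(prob, theta0, om0, corr0, sigma0, control,
                  estimate_corr = TRUE) {
  n_burn <- control$n_burn
  n_iter <- control$n_iter
  n_total <- n_burn + n_iter
  theta <- theta0
  om <- om0 # om0/sigma0 also anchor the annealing floor below
  corr <- corr0
  sigma2 <- sigma0^2
  act <- which(om > 0)
  if (!length(act)) {
    stop("SAEM requires at least one positive omega; use method = 'laplace'",
         call. = FALSE)
  }
  mu <- .mu_matrix(prob$design, theta)
  # start every chain at the empirical-Bayes modes of the initial model:
  # starting from eta = 0 leaves the first sufficient statistics dominated
  # by unexplained between-subject spread, which inflates sigma and can
  # trap the run at a spurious stationary point
  eta0 <- .eb_modes(prob, theta, om, corr, sqrt(sigma2))
  chains <- lapply(seq_len(control$n_chains), function(c) {
    pr <- .predict_rows(prob, mu + eta0)
    list(eta = eta0, mu = mu, ce = pr$ce, f = pr$f,
         rss = .rss_by_subject(prob, pr$f), sweeps = control$mcmc_sweeps)
  })
  mphi <- .mu_matrix(prob$design, theta)
  Sphi <- array(0, dim = c(prob$n, 4, 4))
  for (i in seq_len(prob$n)) Sphi[i, , ] <- tcrossprod(mphi[i, ])
  rss_sa <- sum(chains[[1]]$rss)
  prop_scale <- 0.5 * pmax(om, 1e-3)
  jprop <- .refresh_jprop(prob, theta, om, corr, sigma2, eta0)
  jscale <- 1
  trace <- vector("list", n_total)
  for (k in seq_len(n_total)) {
    # a damped constant step during exploration keeps single-draw spikes in
    # the sufficient statistics (stale etas right after a fixed-effect
    # move) from destabilising the variance updates; polynomial smoothing
    # afterwards (exponent < 1 forgets the exploration state faster than
    # 1/k while still averaging out the chain noise)
    gamma <- if (k <= n_burn) control$gamma_burn else
      1 / (k - n_burn)^control$gamma_power
    mu <- .mu_matrix(prob$design, theta)
    if (k %% control$refresh_every == 0 || k == n_burn + 1) {
      jprop <- .refresh_jprop(prob, theta, om, corr, sigma2,
                              chains[[1]]$eta)
      if (k <= n_burn) {
        # re-anchor chains that got stranded far from their conditional
        # mode during an early variance spike; stuck subjects otherwise
        # keep the residual variance inflated indefinitely
        oi <- .omega_inverse(om, corr)
        for (c in seq_along(chains)) {
          eta_c <- chains[[c]]$eta
          qc <- rowSums((eta_c %*% oi$inv) * eta_c)
          g_cur <- 0.5 * chains[[c]]$rss / sigma2 + 0.5 * qc
          stuck <- which(is.finite(jprop$gmode) &
                           g_cur - jprop$gmode > 10)
          if (length(stuck)) {
            eta_c[stuck, jprop$act] <- jprop$modes[stuck, , drop = FALSE]
            pr <- .predict_rows(prob, mu + eta_c)
            chains[[c]]$eta <- eta_c
            chains[[c]]$ce <- pr$ce
            chains[[c]]$f <- pr$f
            chains[[c]]$rss <- .rss_by_subject(prob, pr$f)
          }
        }
      }
    }
    mphi_new <- matrix(0, prob$n, 4)
    Sphi_new <- array(0, dim = c(prob$n, 4, 4))
    rss_new <- 0
    acc <- numeric(4)
    acc_joint <- 0
    for (c in seq_along(chains)) {
      chains[[c]]$mu <- mu
      pr <- .predict_rows(prob, mu + chains[[c]]$eta)
      chains[[c]]$ce <- pr$ce
      chains[[c]]$f <- pr$f
      chains[[c]]$rss <- .rss_by_subject(prob, pr$f)
      chains[[c]] <- .mh_update(prob, chains[[c]], theta, om, corr, sigma2,
                                prop_scale, jprop = jprop, jscale = jscale)
      phi_c <- mu + chains[[c]]$eta
      mphi_new <- mphi_new + phi_c
      for (i in seq_len(prob$n)) {
        Sphi_new[i, , ] <- Sphi_new[i, , ] + tcrossprod(phi_c[i, ])
      }
      rss_new <- rss_new + sum(chains[[c]]$rss)
      acc <- acc + chains[[c]]$acc
      acc_joint <- acc_joint + chains[[c]]$acc_joint
    }
    nc <- length(chains)
    mphi_new <- mphi_new / nc
    Sphi_new <- Sphi_new / nc
    rss_new <- rss_new / nc
    acc <- acc / nc
    acc_joint <- acc_joint / nc
    if (k <= n_burn) { # adapt proposal scales toward target acceptance
      prop_scale[act] <- prop_scale[act] *
        exp(0.6 * (acc[act] - 0.4) / sqrt(k))
      jscale <- jscale * exp(0.6 * (acc_joint - 0.35) / sqrt(k))
    }
    mphi <- (1 - gamma) * mphi + gamma * mphi_new
    Sphi <- (1 - gamma) * Sphi + gamma * Sphi_new
    rss_sa <- (1 - gamma) * rss_sa + gamma * rss_new
    upd <- .m_step(prob, mphi, Sphi, rss_sa, theta, om, corr, sigma2,
                   estimate_corr)
    theta <- upd$theta
    om <- upd$om
    corr <- upd$corr
    sigma2 <- upd$sigma2
    trace[[k]] <- c(iter = k, stats::setNames(theta, prob$design$theta_names),
                    omega_ke0 = om[1], omega_e0 = om[2], omega_deff = om[3],
                    omega_kprog = om[4], corr_e0_kprog = corr,
                    sigma_add = sqrt(sigma2))
  }
  eta_last <- chains[[1]]$eta
  list(theta = theta, om = om, corr = corr, sigma = sqrt(sigma2),
       trace = tibble::as_tibble(do.call(rbind, trace)),
       eta = eta_last,
       converged = all(is.finite(c(theta, om, corr, sigma2))))
}

# ---- Laplace --------------------------------------------------------------

# joint negative log density (up to additive constants handled by caller)
# as a function of the active etas of one subject
.subject_g <- function(prob, i, mu_i, Oinv_act, act, sigma2, eta_act) {
  eta <- numeric(4)
  eta[act] <- eta_act
  phi <- mu_i + eta
  ce <- .ce_subject_eval(prob$bases[[i]], exp(phi[1]))
  rows <- prob$obs_index[[i]]
  f <- exp(phi[2]) + phi[4] * prob$t[rows] + exp(phi[3]) * ce
  rss <- sum((prob$y[rows] - f)^2)
  0.5 * rss / sigma2 + 0.5 * sum((eta_act %*% Oinv_act) * eta_act)
}

# Laplace -2 log marginal likelihood; optionally warm-started at `modes`
.laplace_ofv <- function(prob, theta, om, corr, sigma, modes = NULL,
                         return_modes = FALSE) {
  sigma2 <- sigma^2
  mu <- .mu_matrix(prob$design, theta)
  act <- which(om > 0)
  d <- length(act)
  ofv <- 0
  new_modes <- if (d) matrix(0, prob$n, d) else NULL
  if (d) {
    Oact <- .omega_matrix(om, corr)[act, act, drop = FALSE]
    Oinv <- solve(Oact)
    ldet_O <- determinant(Oact, logarithm = TRUE)$modulus
  }
  for (i in seq_len(prob$n)) {
    rows <- prob$obs_index[[i]]
    n_i <- length(rows)
    if (d == 0L) {
      phi <- mu[i, ]
      ce <- .ce_subject_eval(prob$bases[[i]], exp(phi[1]))
      f <- exp(phi[2]) + phi[4] * prob$t[rows] + exp(phi[3]) * ce
      ofv <- ofv + n_i * log(2 * pi * sigma2) +
        sum((prob$y[rows] - f)^2) / sigma2
      next
    }
    g <- function(e) .subject_g(prob, i, mu[i, ], Oinv, act, sigma2, e)
    start <- if (is.null(modes)) rep(0, d) else modes[i, ]
    opt <- stats::nlminb(start, g)
    H <- stats::optimHess(opt$par, g)
    ldet_H <- determinant(H, logarithm = TRUE)$modulus
    ofv <- ofv + n_i * log(2 * pi * sigma2) + as.numeric(ldet_O) +
      2 * opt$objective + as.numeric(ldet_H)
    if (return_modes) new_modes[i, ] <- opt$par
  }
  if (return_modes) list(ofv = ofv, modes = new_modes, active = act) else ofv
}

# empirical-Bayes eta modes (n x 4, inactive dims zero)
.eb_modes <- function(prob, theta, om, corr, sigma) {
  act <- which(om > 0)
  eta <- matrix(0, prob$n, 4,
                dimnames = list(NULL, paste0("eta_", .dim_names)))
  if (!length(act)) return(eta)
  res <- .laplace_ofv(prob, theta, om, corr, sigma, return_modes = TRUE)
  eta[, act] <- res$modes
  eta
}

# ---- parameter packing ----------------------------------------------------

# theta vector <-> natural-scale named estimates
.theta_to_estimates <- function(theta, theta_names) {
  est <- theta
  names(est) <- theta_names
  est[["log_ke0"]] <- exp(theta[1]); names(est)[1] <- "ke0"
  est[["log_e0"]] <- exp(theta[2]); names(est)[2] <- "e0"
  est[["log_deff"]] <- exp(theta[3]); names(est)[3] <- "deff"
  est
}

.estimates_to_theta <- function(pd, covmodel) {
  theta <- c(log(pd$ke0), log(pd$e0), log(pd$deff), pd$kprog)
  if (!is.null(covmodel) && nrow(covmodel)) {
    betas <- rep(0, nrow(covmodel))
    sel <- covmodel$param == "e0" & covmodel$covariate == "age"
    betas[sel] <- pd$beta_age
    theta <- c(theta, betas)
  }
  theta
}
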