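# Marginal-likelihood machinery.
#
# The model for arm-mean decrease y at time t in study s is
#   y ~ Normal( m(t; p_s), sigma^2 / n )          (inverse_sqrt_n weighting)
# where the study parameters p_s deviate from the typical values via random
# effects eta_s ~ N(0, diag(omega^2)), proportional (p*exp(eta)) or additive
# (p+eta) per parameter. The per-study likelihood integrates eta out by a
# Laplace approximation (default) or adaptive Gauss-Hermite quadrature; the
# inner mode is found by quasi-Newton with an analytic gradient.

# ---- parameter vector <-> spec -------------------------------------------

.theta_names <- function(spec) {
  onset <- .onset_par(spec)
  c("log_emax", paste0("log_", onset),
    vapply(spec$covariates, function(ce) paste0("slope_", ce$covariate),
           character(1)),
    if (length(spec$iiv)) paste0("log_omega_", names(spec$iiv)),
    "log_sigma")
}

.natural_names <- function(spec) {
  onset <- .onset_par(spec)
  c("emax", onset,
    vapply(spec$covariates, function(ce) paste0("slope_", ce$covariate),
           character(1)),
    if (length(spec$iiv)) paste0("omega_", names(spec$iiv)),
    "sigma")
}

.theta_from_spec <- function(spec) {
  th <- c(log(spec$emax), log(.onset_val(spec)),
          vapply(spec$covariates, `[[`, numeric(1), "slope"),
          if (length(spec$iiv))
            log(pmax(vapply(spec$iiv, `[[`, numeric(1), "sd"), 1e-6)),
          log(spec$residual_sd))
  names(th) <- .theta_names(spec)
  th
}

.spec_from_theta <- function(spec, theta) {
  spec$emax <- exp(theta[[1L]])
  if (spec$form == "emax_et50") {
    spec$et50 <- exp(theta[[2L]])
  } else {
    spec$k <- exp(theta[[2L]])
  }
  nb <- length(spec$covariates)
  if (nb) {
    for (j in seq_len(nb)) {
      spec$covariates[[j]]$slope <- unname(theta[[2L + j]])
    }
  }
  for (j in seq_along(spec$iiv)) {
    spec$iiv[[j]]$sd <- exp(theta[[2L + nb + j]])
  }
  spec$residual_sd <- exp(theta[[length(theta)]])
  spec
}

# unconstrained -> natural scale, with the same ordering as .natural_names
.natural_from_theta <- function(spec, theta) {
  nb <- length(spec$covariates)
  nat <- theta
  logs <- setdiff(seq_along(theta), 2L + seq_len(nb))
  nat[logs] <- exp(theta[logs])
  names(nat) <- .natural_names(spec)
  nat
}

# ---- data preparation -----------------------------------------------------

# Flatten a dataset into per-study records: observation vectors plus the
# centered covariate design matrix X (one column per covariate effect).
# Arms missing a required covariate are excluded and counted.
.prep_studies <- function(data, spec, quiet = FALSE) {
  studies <- .mbma_studies(data, quiet = quiet)
  cov_names <- vapply(spec$covariates, `[[`, character(1), "covariate")
  refs <- vapply(spec$covariates, `[[`, numeric(1), "reference")
  excluded <- 0L
  recs <- list()
  for (sid in names(studies)) {
    t <- y <- w <- numeric(0)
    X <- matrix(0, 0L, length(cov_names))
    arm_ids <- character(0)
    arm_of <- integer(0)
    for (arm in studies[[sid]]) {
      xv <- numeric(length(cov_names))
      ok <- TRUE
      for (j in seq_along(cov_names)) {
        v <- arm$covariates[[cov_names[j]]]
        if (is.null(v) || is.na(v)) {
          ok <- FALSE
          break
        }
        xv[j] <- v - refs[j]
      }
      if (!ok) {
        excluded <- excluded + 1L
        next
      }
      k <- length(arm$t_months)
      t <- c(t, arm$t_months)
      y <- c(y, arm$decrease)
      w <- c(w, rep(if (spec$residual_weighting == "inverse_sqrt_n") arm$n
                    else 1, k))
      X <- rbind(X, matrix(xv, k, length(cov_names), byrow = TRUE))
      arm_ids <- c(arm_ids, arm$arm_id)
      arm_of <- c(arm_of, rep(length(arm_ids), k))
    }
    if (length(y)) {
      recs[[sid]] <- list(study_id = sid, t = t, y = y, w = w, X = X,
                          n_obs = length(y), arm_ids = arm_ids,
                          arm_of = arm_of, sum_log_w = sum(log(w)))
    }
  }
  if (excluded && !quiet) {
    message(excluded, " arm(s) excluded: missing a covariate required by ",
            "the model")
  }
  structure(recs, excluded_arms = excluded)
}

# iiv bookkeeping: index of eta acting on emax / onset (0 = none), scales
.iiv_info <- function(spec) {
  nms <- names(spec$iiv)
  onset <- .onset_par(spec)
  list(
    q = length(nms),
    j_emax = match("emax", nms, nomatch = 0L),
    j_onset = match(onset, nms, nomatch = 0L),
    scale_emax = if ("emax" %in% nms) spec$iiv$emax$scale else NA_character_,
    scale_onset = if (onset %in% nms) spec$iiv[[onset]]$scale else NA_character_
  )
}

# Structural mean and its derivatives with respect to eta, one study.
# pars: list(emax, onset, beta); returns list(m, dm [n_obs x q]).
.study_mean <- function(rec, form, pars, eta, info) {
  E0 <- pars$emax
  if (length(pars$beta)) E0 <- E0 + drop(rec$X %*% pars$beta)
  if (info$j_emax) {
    Es <- if (info$scale_emax == "proportional") {
      E0 * exp(eta[info$j_emax])
    } else {
      E0 + eta[info$j_emax]
    }
  } else {
    Es <- E0
  }
  onset_s <- pars$onset
  if (info$j_onset) {
    onset_s <- if (info$scale_onset == "proportional") {
      onset_s * exp(eta[info$j_onset])
    } else {
      onset_s + eta[info$j_onset]
    }
  }
  t <- rec$t
  if (form == "emax_et50") {
    denom <- onset_s + t
    f <- t / denom
    m <- Es * f
    dm <- if (info$q) matrix(0, rec$n_obs, info$q) else NULL
    if (info$j_emax) {
      dm[, info$j_emax] <- if (info$scale_emax == "proportional") m else f
    }
    if (info$j_onset) {
      dm[, info$j_onset] <- if (info$scale_onset == "proportional") {
        -m * onset_s / denom
      } else {
        -m / denom
      }
    }
  } else {
    ex <- exp(-onset_s * t)
    f <- 1 - ex
    m <- Es * f
    dm <- if (info$q) matrix(0, rec$n_obs, info$q) else NULL
    if (info$j_emax) {
      dm[, info$j_emax] <- if (info$scale_emax == "proportional") m else f
    }
    if (info$j_onset) {
      dm[, info$j_onset] <- if (info$scale_onset == "proportional") {
        Es * t * onset_s * ex
      } else {
        Es * t * ex
      }
    }
  }
  list(m = m, dm = dm)
}

# Joint negative log density h(eta) and gradient for one study.
.make_h <- function(rec, form, pars, info, om2, sig2) {
  const <- 0.5 * (rec$n_obs * log(2 * pi * sig2) - rec$sum_log_w) +
    if (info$q) 0.5 * sum(log(2 * pi * om2)) else 0
  h <- function(eta) {
    me <- .study_mean(rec, form, pars, eta, info)
    r <- rec$y - me$m
    0.5 * sum(rec$w * r * r) / sig2 + const +
      if (info$q) 0.5 * sum(eta * eta / om2) else 0
  }
  grad <- function(eta) {
    me <- .study_mean(rec, form, pars, eta, info)
    r <- rec$y - me$m
    drop(-crossprod(me$dm, rec$w * r)) / sig2 + eta / om2
  }
  list(h = h, grad = grad)
}

# Central finite-difference Jacobian of the analytic gradient = Hessian of h.
.inner_hessian <- function(grad, eta, step = 1e-4) {
  q <- length(eta)
  H <- matrix(0, q, q)
  for (j in seq_len(q)) {
    hj <- step * (1 + abs(eta[j]))
    ej <- numeric(q)
    ej[j] <- hj
    H[, j] <- (grad(eta + ej) - grad(eta - ej)) / (2 * hj)
  }
  (H + t(H)) / 2
}

# Laplace (or AGQ) log-likelihood contribution of one study.
# `cache` is an environment holding warm-start modes keyed by study id.
.loglik_study <- function(rec, form, pars, info, om2, sig2, cache,
                          method = "laplace", gh = NULL) {
  fns <- .make_h(rec, form, pars, info, om2, sig2)
  q <- info$q
  if (q == 0L) {
    return(-fns$h(numeric(0)))
  }
  eta0 <- cache[[rec$study_id]]
  if (is.null(eta0) || length(eta0) != q) eta0 <- numeric(q)
  opt <- stats::nlminb(eta0, fns$h, gradient = fns$grad,
                       control = list(rel.tol = 1e-12, iter.max = 200))
  eta_hat <- opt$par
  cache[[rec$study_id]] <- eta_hat
  H <- .inner_hessian(fns$grad, eta_hat)
  detH <- if (q == 1L) H[1L, 1L] else det(H)
  if (!is.finite(detH) || detH <= 0) {
    # mode Hessian not positive definite (flat/ill-conditioned corner of the
    # outer search); fall back to the prior curvature so the objective stays
    # finite and the optimizer can move away
    H <- diag(1 / om2, q)
    detH <- prod(1 / om2)
  }
  if (identical(method, "laplace")) {
    return(-opt$objective + 0.5 * q * log(2 * pi) - 0.5 * log(detH))
  }
  # adaptive Gauss-Hermite centered at the mode, scaled by chol(H^-1)
  A <- solve(H)
  L <- t(chol(A))
  z <- gh$x
  wgt <- gh$w
  if (q == 1L) {
    nodes <- matrix(eta_hat + sqrt(2) * L[1L, 1L] * z, ncol = 1L)
    W <- wgt
    zz <- z * z
  } else {
    g <- expand.grid(i = seq_along(z), j = seq_along(z))
    U <- cbind(z[g$i], z[g$j])
    nodes <- t(eta_hat + sqrt(2) * L %*% t(U))
    W <- wgt[g$i] * wgt[g$j]
    zz <- rowSums(U * U)
  }
  hv <- vapply(seq_len(nrow(nodes)), function(i) fns$h(nodes[i, ]),
               numeric(1))
  shift <- opt$objective
  s <- sum(W * exp(zz - (hv - shift)))
  0.5 * q * log(2) + sum(log(diag(L))) + log(s) - shift
}

# Objective-function value (-2 log marginal likelihood) for a parameter
# vector theta, given prepared study records.
.ofv <- function(theta, spec, recs, cache,
                 method = "laplace", gh = NULL) {
  nb <- length(spec$covariates)
  pars <- list(
    emax = exp(theta[[1L]]),
    onset = exp(theta[[2L]]),
    beta = if (nb) unname(theta[2L + seq_len(nb)]) else numeric(0)
  )
  info <- .iiv_info(spec)
  om2 <- if (info$q) exp(2 * theta[2L + nb + seq_len(info$q)]) else numeric(0)
  sig2 <- exp(2 * theta[[length(theta)]])
  ll <- 0
  for (rec in recs) {
    ll <- ll + .loglik_study(rec, spec$form, pars, info, om2, sig2, cache,
                             method = method, gh = gh)
  }
  if (!is.finite(ll)) ll <- -1e10
  -2 * ll
}

# Central finite-difference Hessian of a scalar function (used for the
# observed information of the outer objective).
.fd_hessian <- function(f, x, step = 1e-4) {
  p <- length(x)
  hs <- step * (1 + abs(x))
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- numeric(p)
    ei[i] <- hs[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / hs[i]^2
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        ej <- numeric(p)
        ej[j] <- hs[j]
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
             f(x - ei - ej)) / (4 * hs[i] * hs[j])
      }
    }
  }
  H
}
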