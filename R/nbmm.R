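# Mixed-effects negative binomial regression (NB2, log link) with a
# Gaussian random intercept per patient, fitted by maximum likelihood with
# adaptive Gauss-Hermite quadrature over the random effect.

#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for \eqn{\int e^{-x^2} f(x) dx}, computed by the
#' Golub-Welsch eigenvalue method.
#'
#' @param n number of nodes.
#' @return list with `nodes` and `weights`.
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Marginal log-likelihood of the NB random-intercept model
#'
#' For each cluster (patient) the likelihood integrates the NB2 likelihood
#' of its observations over a Gaussian random intercept:
#' \deqn{\ell_i = \log \int \prod_j NB(y_{ij}; \mu_{ij} e^{b}, \theta)\,
#'   \phi(b; 0, \sigma^2)\, db}
#' with \eqn{\mu_{ij} = \exp(x_{ij}^\top \beta)}. The integral is evaluated
#' by adaptive Gauss-Hermite quadrature centered at the per-cluster
#' posterior mode (found by Newton's method; the integrand is log-concave
#' in `b`). With `sigma = 0` the model reduces to an ordinary NB GLM.
#'
#' @param beta fixed-effect coefficients (matching columns of `X`).
#' @param theta NB2 dispersion (variance `mu + mu^2/theta`).
#' @param sigma random-intercept standard deviation (>= 0).
#' @param y integer response vector.
#' @param X model matrix.
#' @param cluster cluster (patient) identifier vector.
#' @param nodes quadrature nodes (default 25).
#' @return total marginal log-likelihood (scalar).
#' @export
nb_mixed_loglik <- function(beta, theta, sigma, y, X, cluster, nodes = 25) {
  eta <- drop(X %*% beta)
  idx <- split(seq_along(y), cluster)
  gh <- gauss_hermite(nodes)
  sum(vapply(idx, function(ii) {
    nb_cluster_loglik(y[ii], eta[ii], theta, sigma, gh)
  }, numeric(1)))
}

nb_cluster_loglik <- function(y, eta, theta, sigma, gh) {
  if (sigma < 1e-8) {
    return(sum(dnbinom(y, size = theta, mu = exp(eta), log = TRUE)))
  }
  if (any(!is.finite(exp(eta)))) return(-Inf)
  # Newton for the mode of h(b) = log f(y|b) + log phi(b; 0, sigma);
  # the integrand is log-concave in b, steps are capped for safety
  b <- 0
  for (it in 1:100) {
    mu <- exp(pmin(eta + b, 700))
    d1 <- sum(y - (y + theta) * mu / (mu + theta)) - b / sigma^2
    d2 <- -sum((y + theta) * theta * mu / (mu + theta)^2) - 1 / sigma^2
    if (!is.finite(d1) || !is.finite(d2) || d2 >= 0) return(-Inf)
    step <- d1 / d2
    step <- sign(step) * min(abs(step), 5)
    b <- b - step
    if (abs(step) < 1e-10) break
  }
  mu <- exp(pmin(eta + b, 700))
  d2 <- -sum((y + theta) * theta * mu / (mu + theta)^2) - 1 / sigma^2
  if (!is.finite(d2) || d2 >= 0) return(-Inf)
  shat <- sqrt(-1 / d2)
  bk <- b + sqrt(2) * shat * gh$nodes
  h <- vapply(bk, function(bb) {
    sum(dnbinom(y, size = theta, mu = exp(eta + bb), log = TRUE)) +
      dnorm(bb, 0, sigma, log = TRUE)
  }, numeric(1))
  log(sqrt(2) * shat) + logsumexp(log(gh$weights) + gh$nodes^2 + h)
}

# Shared model-frame construction for both mixed models. Returns the model
# matrix, the interaction column indices, and the prediction scaffolding.
trend_model_frame <- function(data, time_coding, covariates = NULL,
                              interaction = TRUE) {
  stopifnot(all(c("group", "patient_id") %in% names(data)))
  data$group <- factor(data$group,
                       levels = unique(c(intersect("placebo", data$group),
                                         unique(data$group))))
  if (nlevels(data$group) < 1) stop("no groups")
  if (time_coding == "categorical") {
    stopifnot(all(c("timepoint_label", "timepoint_years") %in% names(data)))
    ord <- order(tapply(data$timepoint_years, data$timepoint_label, min))
    lev <- names(sort(tapply(data$timepoint_years, data$timepoint_label,
                             min)))
    data$.time <- factor(data$timepoint_label, levels = lev)
  } else {
    stopifnot("timepoint_years" %in% names(data))
    data$.time <- data$timepoint_years
  }
  rhs <- if (interaction) "group * .time" else "group + .time"
  if (length(covariates)) {
    rhs <- paste(rhs, "+", paste(covariates, collapse = " + "))
  }
  f <- stats::as.formula(paste("~", rhs))
  X <- stats::model.matrix(f, data = data)
  list(X = X, data = data, formula = f,
       interaction = grep(":", colnames(X)))
}

# Linear combinations giving per-group cell means (categorical coding) or
# per-group slopes (continuous coding), as rows of a matrix L.
trend_contrasts <- function(mf, time_coding) {
  data <- mf$data
  groups <- levels(data$group)
  cov_means <- NULL
  if (time_coding == "categorical") {
    tlev <- levels(data$.time)
    grid <- expand.grid(group = groups, .time = tlev,
                        stringsAsFactors = FALSE)
    grid$group <- factor(grid$group, levels = groups)
    grid$.time <- factor(grid$.time, levels = tlev)
  } else {
    grid <- NULL  # slopes handled directly below
  }
  if (time_coding == "categorical") {
    newd <- grid
    # extra covariates enter at their sample mean
    extra <- setdiff(all.vars(mf$formula), c("group", ".time"))
    for (v in extra) newd[[v]] <- mean(data[[v]])
    L <- stats::model.matrix(mf$formula, data = newd)
    yrs <- tapply(data$timepoint_years, data$.time, min)[as.character(grid$.time)]
    list(L = L, labels = data.frame(group = as.character(grid$group),
                                    timepoint_label = as.character(grid$.time),
                                    timepoint_years = as.numeric(yrs)))
  } else {
    # slope for group g = d(linear predictor)/d(years)
    p <- ncol(mf$X)
    L <- matrix(0, nrow = length(groups), ncol = p,
                dimnames = list(groups, colnames(mf$X)))
    L[, ".time"] <- 1
    for (g in groups[-1]) {
      cn <- paste0("group", g, ":.time")
      if (cn %in% colnames(mf$X)) L[g, cn] <- 1
    }
    list(L = L, labels = data.frame(group = groups))
  }
}

#' Fit the mixed-effects negative binomial trend model
#'
#' Crypt-level pattern counts are modeled as NB2 with log link, fixed
#' effects treatment, time and their interaction, and a Gaussian random
#' intercept per patient. Estimation is by maximum likelihood with adaptive
#' Gauss-Hermite quadrature ([nb_mixed_loglik()]), optimizing jointly over
#' the fixed effects, `log(theta)` and `log(sigma)` by quasi-Newton (BFGS)
#' from Poisson GLM starting values. Wald tests and confidence intervals
#' are computed on the log scale and exponentiated for reporting.
#'
#' With `time_coding = "categorical"` the fit reports per-group conditional
#' mean counts per timepoint (at random intercept 0); with `"continuous"`
#' (time in years, 4 months = 1/3) it reports the per-group multiplicative
#' rate of change per year, `exp(slope)`.
#'
#' If the random-intercept variance collapses to the boundary the model is
#' refitted with `sigma = 0` (an ordinary NB GLM) and a warning is issued.
#'
#' @param data crypt-level data.frame with columns `group`, `patient_id`,
#'   `timepoint_label`, `timepoint_years` and the outcome.
#' @param outcome name of the count outcome column (default `"diversity"`).
#' @param time_coding `"continuous"` or `"categorical"`.
#' @param nodes quadrature nodes (default 25).
#' @param covariates optional extra fixed-effect column names (e.g. `"age"`).
#' @param interaction include the treatment-by-time interaction (default
#'   TRUE; FALSE gives the reduced model for likelihood-ratio testing).
#' @return object of class `trend_fit`.
#' @export
fit_nb_mixed <- function(data, outcome = "diversity",
                         time_coding = c("continuous", "categorical"),
                         nodes = 25, covariates = NULL, interaction = TRUE) {
  time_coding <- match.arg(time_coding)
  y <- data[[outcome]]
  stopifnot(!is.null(y), all(y >= 0), all(is.finite(y)))
  n_per_group <- tapply(data$patient_id, data$group,
                        function(p) length(unique(p)))
  if (any(n_per_group < 2)) {
    stop("need >= 2 patients per group for a mixed fit")
  }
  mf <- trend_model_frame(data, time_coding, covariates, interaction)
  X <- mf$X
  cluster <- as.character(data$patient_id)
  p <- ncol(X)
  gh <- gauss_hermite(nodes)
  idx <- split(seq_along(y), cluster)

  negll <- function(par) {
    beta <- par[1:p]
    theta <- exp(par[p + 1])
    sigma <- exp(par[p + 2])
    eta <- drop(X %*% beta)
    ll <- sum(vapply(idx, function(ii) {
      nb_cluster_loglik(y[ii], eta[ii], theta, sigma, gh)
    }, numeric(1)))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  start <- c(coef(glm(y ~ X - 1, family = poisson())), log(10), log(0.3))
  names(start) <- c(colnames(X), "log_theta", "log_sigma")
  opt <- optim(start, negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12), hessian = TRUE)
  if (opt$convergence != 0) {
    stop(sprintf("NB mixed fit did not converge (code %d): %s",
                 opt$convergence, opt$message %||% ""))
  }
  sigma <- unname(exp(opt$par[p + 2]))
  boundary <- sigma < 1e-4
  if (boundary) {
    warning("random-intercept variance at boundary (~0); ",
            "reporting the GLM-equivalent fit", call. = FALSE)
    negll0 <- function(par) {
      beta <- par[1:p]
      theta <- exp(par[p + 1])
      ll <- sum(dnbinom(y, size = theta, mu = exp(drop(X %*% beta)),
                        log = TRUE))
      if (!is.finite(ll)) return(1e10)
      -ll
    }
    opt0 <- optim(opt$par[1:(p + 1)], negll0, method = "BFGS",
                  control = list(maxit = 500, reltol = 1e-12),
                  hessian = TRUE)
    vc <- solve(opt0$hessian)
    est <- opt0$par
    loglik <- -opt0$value
    theta <- unname(exp(est[p + 1]))
    sigma <- 0
    npar <- p + 2  # variance parameter still counted (boundary estimate)
    vcov_beta <- vc[1:p, 1:p, drop = FALSE]
  } else {
    vc <- tryCatch(solve(opt$hessian), error = function(e) {
      MASS::ginv(opt$hessian)
    })
    est <- opt$par
    loglik <- -opt$value
    theta <- unname(exp(est[p + 1]))
    npar <- p + 2
    vcov_beta <- vc[1:p, 1:p, drop = FALSE]
  }
  beta <- est[1:p]

  fit <- new_trend_fit(
    model_kind = "nb_mixed", time_coding = time_coding, outcome = outcome,
    beta = beta, vcov_beta = vcov_beta, theta = theta, sigma = sigma,
    loglik = loglik, npar = npar, n = length(y), mf = mf,
    boundary = boundary, link = "log")
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Assemble the common trend_fit structure: coefficient table, per-group
# means or rates, interaction bookkeeping.
new_trend_fit <- function(model_kind, time_coding, outcome, beta, vcov_beta,
                          theta = NA_real_, sigma, loglik, npar, n, mf,
                          boundary = FALSE, link = c("log", "identity"),
                          sigma_resid = NA_real_) {
  link <- match.arg(link)
  se <- sqrt(pmax(diag(vcov_beta), 0))
  z <- beta / se
  coefs <- data.frame(
    term = colnames(mf$X), estimate = unname(beta), se = unname(se),
    z = unname(z), p = 2 * pnorm(-abs(z)),
    ci_lo = unname(beta - qnorm(0.975) * se),
    ci_hi = unname(beta + qnorm(0.975) * se),
    stringsAsFactors = FALSE)

  ct <- trend_contrasts(mf, time_coding)
  est <- drop(ct$L %*% beta)
  vse <- sqrt(pmax(rowSums((ct$L %*% vcov_beta) * ct$L), 0))
  lo <- est - qnorm(0.975) * vse
  hi <- est + qnorm(0.975) * vse
  derived <- ct$labels
  if (link == "log") {
    derived$estimate <- exp(est)
    derived$ci_lo <- exp(lo)
    derived$ci_hi <- exp(hi)
  } else {
    derived$estimate <- est
    derived$ci_lo <- lo
    derived$ci_hi <- hi
  }
  names(derived)[names(derived) == "estimate"] <-
    if (time_coding == "categorical") "mean" else
      if (link == "log") "rate_per_year" else "change_per_year"

  structure(list(
    model_kind = model_kind, time_coding = time_coding, outcome = outcome,
    coefficients = coefs, vcov = vcov_beta, theta = theta, sigma = sigma,
    sigma_resid = sigma_resid, loglik = loglik, npar = npar, n = n,
    interaction_terms = colnames(mf$X)[mf$interaction],
    derived = derived, boundary = boundary, link = link,
    terms = colnames(mf$X)
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<trend_fit> %s, %s time, outcome = %s (n = %d, logLik = %.2f)\n",
              x$model_kind, x$time_coding, x$outcome, x$n, x$loglik))
  if (x$model_kind == "nb_mixed") {
    cat(sprintf("  dispersion theta = %.3g, random-intercept sd = %.3g\n",
                x$theta, x$sigma))
  } else {
    cat(sprintf("  residual sd = %.3g, random-intercept sd = %.3g\n",
                x$sigma_resid, x$sigma))
  }
  print(x$derived, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Interaction test between nested trend fits
#'
#' Tests whether the time trend differs between treatment groups. The
#' default report is a Wald chi-square test on the treatment-by-time
#' interaction coefficients of the full fit; a likelihood-ratio test
#' against the reduced (no-interaction) fit is reported alongside when a
#' reduced fit is supplied.
#'
#' @param full a `trend_fit` including the interaction.
#' @param reduced optional nested `trend_fit` without the interaction
#'   (same data, same outcome).
#' @return list with `wald_stat`, `df`, `p_wald`, and (if `reduced` given)
#'   `lrt_stat`, `df_lrt`, `p_lrt`.
#' @export
test_interaction <- function(full, reduced = NULL) {
  stopifnot(inherits(full, "trend_fit"))
  it <- full$interaction_terms
  out <- list()
  if (!length(it)) {
    out$wald_stat <- 0
    out$df <- 0L
    out$p_wald <- 1
  } else {
    ii <- match(it, full$coefficients$term)
    b <- full$coefficients$estimate[ii]
    V <- full$vcov[ii, ii, drop = FALSE]
    W <- drop(t(b) %*% solve(V, b))
    out$wald_stat <- W
    out$df <- length(ii)
    out$p_wald <- pchisq(W, df = length(ii), lower.tail = FALSE)
  }
  if (!is.null(reduced)) {
    stopifnot(inherits(reduced, "trend_fit"))
    if (reduced$model_kind != full$model_kind ||
        reduced$outcome != full$outcome || reduced$n != full$n) {
      stop("fits are not nested on the same data")
    }
    if (!all(reduced$terms %in% full$terms)) {
      stop("reduced model terms are not a subset of the full model")
    }
    df <- full$npar - reduced$npar
    if (df == 0L && isTRUE(all.equal(sort(reduced$terms),
                                     sort(full$terms)))) {
      out$lrt_stat <- 0
      out$df_lrt <- 0L
      out$p_lrt <- 1
      out$wald_stat <- 0
      out$p_wald <- 1
    } else {
      if (df <= 0L) stop("full model must have more parameters")
      stat <- max(0, 2 * (full$loglik - reduced$loglik))
      out$lrt_stat <- stat
      out$df_lrt <- df
      out$p_lrt <- pchisq(stat, df = df, lower.tail = FALSE)
    }
  }
  out
}

#' Fit the no-interaction (reduced) companion model
#'
#' Same structure as [fit_nb_mixed()] / [fit_lmm()] but with treatment and
#' time main effects only, for likelihood-ratio interaction testing.
#'
#' @inheritParams fit_nb_mixed
#' @param model `"nb_mixed"` or `"linear_mixed"`.
#' @return a `trend_fit`.
#' @export
fit_reduced <- function(data, outcome, model = c("nb_mixed", "linear_mixed"),
                        time_coding = c("continuous", "categorical"),
                        nodes = 25) {
  model <- match.arg(model)
  time_coding <- match.arg(time_coding)
  if (model == "nb_mixed") {
    fit_nb_mixed(data, outcome, time_coding, nodes, interaction = FALSE)
  } else {
    fit_lmm(data, outcome, time_coding, interaction = FALSE)
  }
}
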