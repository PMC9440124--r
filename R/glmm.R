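#' Settings for the crossed random-effects logistic fit
#'
#' @param outer_tol Convergence tolerance of the outer variance-component
#'   optimisation, on the log-likelihood scale.
#' @param inner_tol Convergence tolerance of the inner penalized IRLS solve,
#'   on the penalized deviance scale.
#' @param max_outer Maximum outer iterations (simplex evaluations are
#'   bounded at a small multiple of this).
#' @param max_inner Maximum Newton steps per inner solve.
#' @param log_sd_floor Floor of the log-SD parameterisation; an estimate at
#'   the floor is reported as sigma = 0 with a boundary flag.
#' @param fix_sigma Optional named numeric, e.g. `c(rater = 0, lesion = 0)`,
#'   fixing either variance component instead of estimating it.
#' @return A list of settings.
#' @export
glmm_settings <- function(outer_tol = 1e-6, inner_tol = 1e-8, max_outer = 200L,
                          max_inner = 50L, log_sd_floor = -12, fix_sigma = NULL) {
  list(outer_tol = outer_tol, inner_tol = inner_tol,
       max_outer = as.integer(max_outer), max_inner = as.integer(max_inner),
       log_sd_floor = log_sd_floor, fix_sigma = fix_sigma)
}

log1pexp <- function(x) {
  # numerically stable log(1 + exp(x))
  out <- x
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  big <- x > 18 & x <= 33.3
  out[big] <- x[big] + exp(-x[big])
  out
}

#' Logistic regression with crossed rater and lesion random intercepts
#'
#' Fits `logit P(y = 1) = beta0 + beta1 * session + u[rater] + v[lesion]`
#' with independent normal random intercepts `u ~ N(0, sigma_rater^2)` and
#' `v ~ N(0, sigma_lesion^2)` by Laplace-approximated maximum likelihood.
#' An inner penalized IRLS solve finds the joint mode of `(beta, u, v)` for
#' given variance components; because the lesion block of the penalized
#' Hessian is diagonal, every Newton step and the Laplace log-determinant
#' correction are computed by block elimination of the lesion effects,
#' which reduces each solve to a dense system of size `2 + n_raters`. A
#' bounded Nelder-Mead search over the two log-SDs drives the outer
#' optimisation, followed by a refinement of `(beta, log-SDs)` against the
#' Laplace objective itself (the penalized solve profiles `beta` at a
#' slightly different criterion). The fit is deterministic given data and
#' settings; boundary estimates (sigma = 0) are allowed and flagged, and
#' with both SDs at zero the fit reduces exactly to plain logistic IRLS.
#'
#' @param rows A data.frame with columns `y` (0/1), `session` (0/1),
#'   `rater_id`, `lesion_id`. An `endpoint_rows` object is accepted.
#' @param settings A [glmm_settings()] list.
#' @return An object of class `"glmm_fit"` with elements `beta`
#'   (`(Intercept)`, `session`), `se_beta`, `sigma_rater`, `sigma_lesion`,
#'   `loglik`, `converged`, `boundary`, `n_obs`, `n_raters`, `n_lesions`,
#'   `vcov_beta`, `ranef` (modes of the random effects).
#' @export
fit_crossed_logistic <- function(rows, settings = glmm_settings()) {
  if (inherits(rows, "endpoint_rows")) rows <- rows$rows
  rows <- as.data.frame(rows)
  stopifnot(all(c("y", "session", "rater_id", "lesion_id") %in% names(rows)))
  y <- as.numeric(rows$y)
  if (!all(y %in% c(0, 1))) stop("y must be 0/1", call. = FALSE)
  ses <- as.numeric(rows$session)
  if (!all(ses %in% c(0, 1))) stop("session must be coded 0/1", call. = FALSE)
  if (length(unique(ses)) < 2L) stop("both session levels must be present", call. = FALSE)
  rater <- factor(rows$rater_id)
  lesion <- factor(rows$lesion_id)
  nr <- nlevels(rater); nl <- nlevels(lesion)
  if (nr < 2L || nl < 2L) stop("need at least 2 raters and 2 lesions", call. = FALSE)
  if (all(y == 0) || all(y == 1)) {
    stop("complete separation: all responses are ", y[1],
         "; the session effect is not identified", call. = FALSE)
  }

  n <- length(y)
  ri <- as.integer(rater); li <- as.integer(lesion)
  # rater x lesion cell bookkeeping for the Hessian cross block
  cell <- (li - 1L) * nr + ri
  cell_levels <- sort(unique(cell))
  cell_r <- ((cell_levels - 1L) %% nr) + 1L
  cell_l <- ((cell_levels - 1L) %/% nr) + 1L
  p <- 2L

  eta_of <- function(beta, ur, ul) beta[1] + beta[2] * ses + ur[ri] + ul[li]

  # fast fixed-layout group sums: precompute the sort order once, then each
  # aggregation is a gather + cumsum + segment difference
  make_agg <- function(g, ng) {
    o <- order(g)
    ends <- cumsum(tabulate(g, ng)) + 1L
    function(x) {
      cs <- c(0, cumsum(x[o]))[ends]
      cs - c(0, cs[-ng])
    }
  }
  agg_r <- make_agg(ri, nr)
  agg_l <- make_agg(li, nl)
  agg_cell <- make_agg(match(cell, cell_levels), length(cell_levels))
  cross_block <- function(w) {
    C <- matrix(0, nr, nl)
    C[cbind(cell_r, cell_l)] <- agg_cell(w)
    C
  }

  # Newton direction for (top, lesion) blocks where the lesion block of the
  # Hessian is diagonal; `top` is (beta, u_rater) in the joint solve and
  # u_rater alone in the u-only solve. Returns the step and the Cholesky
  # pieces needed for log-determinants.
  block_solve <- function(A, B, dl, g_top, g_l) {
    Binv <- B / rep(dl, each = nrow(B))
    S <- A - Binv %*% t(B)
    R <- chol(S)
    top <- backsolve(R, backsolve(R, g_top - Binv %*% g_l, transpose = TRUE))
    lst <- (g_l - as.numeric(crossprod(B, top))) / dl
    list(top = as.numeric(top), lesion = lst, chol_S = R)
  }

  state <- new.env(parent = emptyenv())
  state$beta <- c(stats::qlogis(mean(pmin(pmax(y, 0.01), 0.99))), 0)
  state$ur <- numeric(nr)
  state$ul <- numeric(nl)

  penalized_dev <- function(beta, ur, ul, prec_r, prec_l) {
    eta <- eta_of(beta, ur, ul)
    -2 * sum(y * eta - log1pexp(eta)) + prec_r * sum(ur^2) + prec_l * sum(ul^2)
  }

  # Laplace marginal log-likelihood at the current mode; needs the u-block
  # log-determinant, computed by eliminating the diagonal lesion block
  laplace_loglik <- function(beta, ur, ul, log_sd, prec_r, prec_l) {
    eta <- eta_of(beta, ur, ul)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    swr <- agg_r(w); swl <- agg_l(w)
    C <- cross_block(w)
    dl <- swl + prec_l
    S <- diag(swr + prec_r, nr) - (C / rep(dl, each = nr)) %*% t(C)
    ldet <- sum(log(dl)) + 2 * sum(log(diag(chol(S))))
    sum(y * eta - log1pexp(eta)) - 0.5 * (prec_r * sum(ur^2) + prec_l * sum(ul^2)) -
      nr * log_sd[1] - nl * log_sd[2] - 0.5 * ldet
  }

  # penalized IRLS over (beta, u) or over u alone (beta fixed)
  pirls <- function(log_sd, beta = NULL) {
    prec_r <- exp(-2 * log_sd[1]); prec_l <- exp(-2 * log_sd[2])
    profile_beta <- is.null(beta)
    b <- if (profile_beta) state$beta else beta
    ur <- state$ur; ul <- state$ul
    dev <- penalized_dev(b, ur, ul, prec_r, prec_l)
    for (it in seq_len(settings$max_inner)) {
      eta <- eta_of(b, ur, ul)
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      res <- y - mu
      swr <- agg_r(w); swl <- agg_l(w)
      C <- cross_block(w)
      dl <- swl + prec_l
      g_r <- agg_r(res) - prec_r * ur
      g_l <- agg_l(res) - prec_l * ul
      if (profile_beta) {
        ws <- w * ses
        sws_r <- agg_r(ws); sws_l <- agg_l(ws)
        A <- matrix(0, p + nr, p + nr)
        A[1, 1] <- sum(w); A[1, 2] <- A[2, 1] <- sum(ws); A[2, 2] <- sum(ws)
        A[1, p + seq_len(nr)] <- A[p + seq_len(nr), 1] <- swr
        A[2, p + seq_len(nr)] <- A[p + seq_len(nr), 2] <- sws_r
        diag(A)[p + seq_len(nr)] <- swr + prec_r
        B <- rbind(swl, sws_l, C)
        g_top <- c(sum(res), sum(res * ses), g_r)
        sol <- block_solve(A, B, dl, g_top, g_l)
        step_b <- sol$top[seq_len(p)]
        step_r <- sol$top[-seq_len(p)]
      } else {
        sol <- block_solve(diag(swr + prec_r, nr), C, dl, g_r, g_l)
        step_b <- c(0, 0)
        step_r <- sol$top
      }
      step_l <- sol$lesion
      t_ <- 1
      repeat {
        nb <- b + t_ * step_b; nur <- ur + t_ * step_r; nul <- ul + t_ * step_l
        new_dev <- penalized_dev(nb, nur, nul, prec_r, prec_l)
        if (is.finite(new_dev) && new_dev <= dev + 1e-12) break
        t_ <- t_ / 2
        if (t_ < 2^-30) break
      }
      done <- abs(dev - new_dev) < settings$inner_tol * (abs(dev) + 1)
      b <- nb; ur <- nur; ul <- nul; dev <- new_dev
      if (done) break
    }
    state$beta <- b; state$ur <- ur; state$ul <- ul
    list(loglik = laplace_loglik(b, ur, ul, log_sd, prec_r, prec_l),
         beta = b, ur = ur, ul = ul)
  }

  floor_ <- settings$log_sd_floor
  fix <- settings$fix_sigma
  fixed_rater <- !is.null(fix) && "rater" %in% names(fix)
  fixed_lesion <- !is.null(fix) && "lesion" %in% names(fix)
  to_log_sd <- function(sigma) max(log(max(sigma, 0)), floor_)
  full_theta <- function(free) {
    th <- numeric(2)
    th[1] <- if (fixed_rater) to_log_sd(fix[["rater"]]) else free[1]
    th[2] <- if (fixed_lesion) to_log_sd(fix[["lesion"]]) else free[[length(free)]]
    th
  }
  n_free <- 2L - fixed_rater - fixed_lesion
  clamp <- function(x) pmin(pmax(x, floor_), 5)

  neg <- function(free) -pirls(full_theta(clamp(free)))$loglik

  outer_conv <- TRUE
  if (n_free == 0L) {
    theta <- full_theta(numeric(0))
  } else if (n_free == 1L) {
    opt <- stats::optimize(neg, interval = c(floor_, 3), tol = 1e-6)
    theta <- full_theta(opt$minimum)
  } else {
    opt <- stats::optim(c(-0.5, -0.5), neg, method = "Nelder-Mead",
                        control = list(reltol = settings$outer_tol,
                                       maxit = 4L * settings$max_outer))
    outer_conv <- opt$convergence == 0L
    theta <- full_theta(clamp(opt$par))
  }

  stage1 <- pirls(theta)
  beta_hat <- stage1$beta

  # refinement: re-optimize (beta, free log-SDs) against the Laplace
  # objective itself, unless the model degenerates to plain logistic
  # regression (both SDs at zero), where stage 1 already is exact ML
  at_zero <- theta <= floor_ + 1e-6
  if (!all(at_zero)) {
    pack <- function(par) {
      th <- numeric(2); i <- 3L
      if (fixed_rater) th[1] <- theta[1] else { th[1] <- par[i]; i <- i + 1L }
      th[2] <- if (fixed_lesion) theta[2] else par[i]
      list(beta = par[1:2], theta = clamp(th))
    }
    par0 <- c(beta_hat, theta[!c(fixed_rater, fixed_lesion)])
    neg2 <- function(par) {
      pp <- pack(par)
      -pirls(pp$theta, beta = pp$beta)$loglik
    }
    opt2 <- stats::optim(par0, neg2, method = "Nelder-Mead",
                         control = list(reltol = settings$outer_tol * 1e-2,
                                        maxit = 8L * settings$max_outer))
    outer_conv <- outer_conv && opt2$convergence == 0L
    pp <- pack(opt2$par)
    beta_hat <- pp$beta; theta <- pp$theta
  }

  final <- pirls(theta, beta = beta_hat)
  prec_r <- exp(-2 * theta[1]); prec_l <- exp(-2 * theta[2])
  eta <- eta_of(final$beta, final$ur, final$ul)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)

  # cov(beta) from the Schur complement of the joint penalized Hessian:
  # invert the u-block against X'WZ by the same lesion-block elimination
  ws <- w * ses
  swr <- agg_r(w); swl <- agg_l(w)
  sws_r <- agg_r(ws); sws_l <- agg_l(ws)
  C <- cross_block(w)
  dl <- swl + prec_l
  A_u <- diag(swr + prec_r, nr)
  ZWX <- rbind(cbind(swr, sws_r), cbind(swl, sws_l))  # (nr+nl) x 2
  Y <- matrix(0, nr + nl, p)
  for (j in seq_len(p)) {
    sol <- block_solve(A_u, C, dl, ZWX[seq_len(nr), j], ZWX[nr + seq_len(nl), j])
    Y[, j] <- c(sol$top, sol$lesion)
  }
  XWX <- matrix(c(sum(w), sum(ws), sum(ws), sum(ws)), 2L)
  vcov_beta <- solve(XWX - crossprod(ZWX, Y))
  se_beta <- sqrt(pmax(diag(vcov_beta), 0))

  boundary <- theta <= floor_ + 1e-6
  sigma <- exp(theta)
  sigma[boundary] <- 0
  beta <- final$beta
  names(beta) <- names(se_beta) <- c("(Intercept)", "session")
  structure(list(
    beta = beta, se_beta = se_beta, vcov_beta = vcov_beta,
    sigma_rater = sigma[1], sigma_lesion = sigma[2],
    loglik = final$loglik, converged = outer_conv, boundary = any(boundary),
    n_obs = n, n_raters = nr, n_lesions = nl,
    ranef = list(rater = stats::setNames(final$ur, levels(rater)),
                 lesion = stats::setNames(final$ul, levels(lesion))),
    theta = theta, settings = settings), class = "glmm_fit")
}

#' Summarise a fit as a JSON-ready list
#'
#' Scalar fields of the fit (coefficients, SEs, variance components,
#' log-likelihood, convergence flags, dimensions), suitable for
#' `jsonlite::write_json(..., auto_unbox = TRUE)`.
#'
#' @param x A `glmm_fit`.
#' @param ... Unused.
#' @return A named list.
#' @export
as.list.glmm_fit <- function(x, ...) {
  list(beta = as.list(x$beta), se_beta = as.list(x$se_beta),
       sigma_rater = x$sigma_rater, sigma_lesion = x$sigma_lesion,
       loglik = x$loglik, converged = x$converged, boundary = x$boundary,
       n_obs = x$n_obs, n_raters = x$n_raters, n_lesions = x$n_lesions)
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Crossed random-intercept logistic fit (Laplace ML)\n")
  cat(sprintf("  n = %d obs, %d raters, %d lesions; logLik = %.3f%s\n",
              x$n_obs, x$n_raters, x$n_lesions, x$loglik,
              if (!x$converged) " (NOT converged)" else ""))
  est <- cbind(Estimate = x$beta, `Std. Error` = x$se_beta,
               `OR` = exp(x$beta))
  print(round(est, 4))
  cat(sprintf("  sigma_rater = %.4f, sigma_lesion = %.4f%s\n",
              x$sigma_rater, x$sigma_lesion,
              if (x$boundary) " (boundary)" else ""))
  invisible(x)
}

#' Wald confidence interval on the odds-ratio scale
#'
#' @param fit A converged [fit_crossed_logistic()] fit.
#' @param level Confidence level in (0, 1).
#' @param term Coefficient name, default `"session"`.
#' @return Numeric `c(ci_low, ci_high)` on the OR scale.
#' @export
wald_interval <- function(fit, level = 0.95, term = "session") {
  stopifnot(inherits(fit, "glmm_fit"))
  if (!isTRUE(fit$converged)) stop("refusing to compute an interval from a non-converged fit",
                                   call. = FALSE)
  stopifnot(level > 0, level < 1)
  z <- stats::qnorm((1 + level) / 2)
  b <- fit$beta[[term]]; se <- fit$se_beta[[term]]
  stats::setNames(exp(c(b - z * se, b + z * se)), c("ci_low", "ci_high"))
}

#' One-sided Wald test of an odds-ratio bound
#'
#' Tests H0: OR = `bound` against OR `>` or `<` `bound` with the Wald
#' statistic `z = (beta - log(bound)) / se`.
#'
#' @param fit A converged [fit_crossed_logistic()] fit.
#' @param bound Positive odds-ratio bound.
#' @param direction `"greater"` (default) or `"less"`.
#' @param term Coefficient name, default `"session"`.
#' @return A list with `z`, `p`, `bound`, `direction`.
#' @export
test_one_sided <- function(fit, bound, direction = c("greater", "less"),
                           term = "session") {
  stopifnot(inherits(fit, "glmm_fit"))
  if (!isTRUE(fit$converged)) stop("refusing to test a non-converged fit", call. = FALSE)
  stopifnot(bound > 0)
  direction <- match.arg(direction)
  z <- (fit$beta[[term]] - log(bound)) / fit$se_beta[[term]]
  p <- if (direction == "greater") stats::pnorm(z, lower.tail = FALSE) else stats::pnorm(z)
  list(z = z, p = p, bound = bound, direction = direction)
}
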