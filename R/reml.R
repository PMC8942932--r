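# Dense average-information REML with EM fallback, for linear mixed models
# y = X b + sum_i u_i + e,  u_i ~ N(0, theta_i * M_i),  e ~ N(0, theta_e I),
# where each M_i = Z_i K_i Z_i' is supplied as an n x n covariance kernel.
# Sizes here are a few thousand observations, so the n x n algebra (one
# Cholesky and one inverse per iteration) is the cheapest reliable route.

# One REML evaluation at theta; returns loglik and the pieces reused by
# the AI/EM updates and by the caller (beta, betaCov, Py).
.remlEval <- function(theta, y, X, Mlist, needP = FALSE) {
  n <- length(y)
  k <- length(Mlist)
  V <- diag(rep(theta[k + 1L], n))
  for (i in seq_len(k)) V <- V + theta[i] * Mlist[[i]]
  cholV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cholV)) return(NULL)
  Vinv <- chol2inv(cholV)
  A <- Vinv %*% X                       # V^-1 X
  XtVX <- crossprod(X, A)
  cXtVX <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(cXtVX)) return(NULL)
  Cinv <- chol2inv(cXtVX)               # (X' V^-1 X)^-1
  Vy <- Vinv %*% y
  beta <- Cinv %*% crossprod(X, Vy)
  Py <- as.numeric(Vy - A %*% beta)
  ytPy <- sum(y * Py)
  p <- ncol(X)
  ll <- -0.5 * (2 * sum(log(diag(cholV))) + 2 * sum(log(diag(cXtVX))) +
                  ytPy + (n - p) * log(2 * pi))
  out <- list(ll = ll, beta = as.numeric(beta), betaCov = Cinv, Py = Py,
              Vinv = if (needP) Vinv else NULL,
              A = if (needP) A else NULL, Cinv = Cinv)
  out
}

# tr(P M) with P = Vinv - A Cinv A' ; M symmetric
.trPM <- function(ev, M) {
  sum(ev$Vinv * M) - sum(ev$Cinv * crossprod(ev$A, M %*% ev$A))
}

.applyP <- function(ev, w, X) {
  as.numeric(ev$Vinv %*% w - ev$A %*% (ev$Cinv %*% crossprod(X, ev$Vinv %*% w)))
}

#' @keywords internal
.aiReml <- function(y, X, Mlist, init = NULL, fixedTheta = NULL,
                    maxit = 60L, tolLl = 1e-9, tolGrad = 1e-6) {
  n <- length(y)
  k <- length(Mlist)
  # drop aliased fixed-effect columns
  qrX <- qr(X)
  X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]

  if (!is.null(fixedTheta)) {
    ev <- .remlEval(fixedTheta, y, X, Mlist)
    if (is.null(ev)) stop("REML evaluation failed at the supplied components")
    return(list(theta = fixedTheta, ll = ev$ll, beta = ev$beta,
                betaCov = ev$betaCov, Py = ev$Py, X = X,
                converged = TRUE, niter = 0L, llTrace = ev$ll))
  }

  vy <- stats::var(y)
  lb <- 1e-8 * vy
  theta <- if (is.null(init)) rep(vy / (k + 1L), k + 1L) else pmax(init, lb)
  # effective number of levels per term, for the EM step
  qlev <- c(vapply(Mlist, function(M) {
    sum(diag(M)) / max(mean(diag(M)), .Machine$double.eps)
  }, numeric(1)), n)

  ev <- .remlEval(theta, y, X, Mlist, needP = TRUE)
  if (is.null(ev)) stop("REML evaluation failed at the starting values")
  llTrace <- ev$ll
  converged <- FALSE
  iter <- 0L
  while (iter < maxit) {
    iter <- iter + 1L
    # gradient and AI matrix
    grad <- numeric(k + 1L)
    W <- matrix(0, n, k + 1L)
    for (i in seq_len(k)) {
      Wi <- as.numeric(Mlist[[i]] %*% ev$Py)
      W[, i] <- Wi
      grad[i] <- -0.5 * (.trPM(ev, Mlist[[i]]) - sum(ev$Py * Wi))
    }
    W[, k + 1L] <- ev$Py
    trP <- sum(diag(ev$Vinv)) - sum(ev$Cinv * crossprod(ev$A))
    grad[k + 1L] <- -0.5 * (trP - sum(ev$Py^2))
    PW <- vapply(seq_len(ncol(W)), function(j) .applyP(ev, W[, j], X),
                 numeric(n))
    AI <- 0.5 * crossprod(W, PW)

    atLb <- theta <= lb * 1.0001
    free <- which(!(atLb & grad < 0))     # keep boundary zeros pinned
    if (!length(free)) { converged <- TRUE; break }
    step <- numeric(k + 1L)
    AIf <- AI[free, free, drop = FALSE]
    sol <- tryCatch(solve(AIf + diag(1e-10 * max(diag(AIf)) + 1e-300,
                                     length(free)), grad[free]),
                    error = function(e) NULL)
    if (is.null(sol)) sol <- grad[free] / pmax(diag(AIf), 1e-12)
    step[free] <- sol

    improved <- FALSE
    fac <- 1
    for (h in seq_len(9L)) {
      cand <- pmax(theta + fac * step, lb)
      evC <- .remlEval(cand, y, X, Mlist, needP = TRUE)
      if (!is.null(evC) && evC$ll >= ev$ll - 1e-12) {
        improved <- TRUE; break
      }
      fac <- fac / 2
    }
    if (!improved) {
      # EM fallback: guaranteed-ascent update
      cand <- pmax(theta + (2 * theta^2 / qlev) * grad, lb)
      evC <- .remlEval(cand, y, X, Mlist, needP = TRUE)
      if (is.null(evC) || evC$ll < ev$ll - 1e-8) { converged <- TRUE; break }
    }
    dll <- evC$ll - ev$ll
    theta <- cand
    ev <- evC
    llTrace <- c(llTrace, ev$ll)
    gOK <- all(abs(grad[free]) * pmax(theta[free], lb) <
                 tolGrad * (1 + abs(ev$ll)))
    if (dll < tolLl * (1 + abs(ev$ll)) && (gOK || iter > 3L)) {
      converged <- TRUE
      break
    }
  }
  list(theta = theta, ll = ev$ll, beta = ev$beta, betaCov = ev$betaCov,
       Py = ev$Py, X = X, converged = converged, niter = iter,
       llTrace = llTrace)
}
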