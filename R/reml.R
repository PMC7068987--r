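# Average-information REML for linear variance structures
#
# V(theta) = sum_p theta_p * B_p with known symmetric B_p (the last usually
# the identity for the residual). Scores and average-information matrix in
# the standard P-matrix form:
#   score_p = -0.5 * (tr(P B_p) - y' P B_p P y)
#   AI_pq   =  0.5 * y' P B_p P B_q P y
# AI (Fisher-scoring on the average information) steps are halved when they
# leave the feasible region or decrease the REML log-likelihood; if no
# feasible AI step exists, variance-type parameters fall back to the
# positive multiplicative fixed-point update
#   theta_p <- theta_p * (y' P B_p P y) / tr(P B_p)
# (the expectation-maximization-flavoured update used by classic REML
# programs) and covariance blocks are projected to the nearest PSD matrix.

reml_engine <- function(y, X, Bmats, init = NULL, lower = NULL,
                        psd_groups = NULL, max_iter = 200, tol = 1e-8) {
  n <- length(y)
  np <- length(Bmats)
  vy <- var(y)
  if (!is.finite(vy) || vy <= 0) abort("Response has no variance.")
  lb_default <- 1e-8 * vy
  if (is.null(lower)) lower <- rep(lb_default, np)
  theta <- init %||% rep(vy / np, np)
  names(theta) <- names(Bmats)

  feasible <- function(th) {
    if (any(th < lower - 1e-12)) return(FALSE)
    for (g in psd_groups) {
      m <- matrix(c(th[g[1]], th[g[2]], th[g[2]], th[g[3]]), 2)
      if (m[1, 1] < 0 || m[2, 2] < 0 || det(m) < -1e-10 * max(1, m[1, 1] * m[2, 2])) {
        return(FALSE)
      }
    }
    TRUE
  }
  project_feasible <- function(th) {
    th <- pmax(th, lower)
    for (g in psd_groups) {
      m <- matrix(c(th[g[1]], th[g[2]], th[g[2]], th[g[3]]), 2)
      e <- eigen(m, symmetric = TRUE)
      if (min(e$values) < 0) {
        m <- e$vectors %*% diag(pmax(e$values, 1e-10 * max(abs(e$values)))) %*% t(e$vectors)
        th[g[1]] <- m[1, 1]; th[g[2]] <- m[1, 2]; th[g[3]] <- m[2, 2]
      }
    }
    th
  }

  eval_point <- function(th) {
    V <- matrix(0, n, n)
    for (p in seq_len(np)) V <- V + th[p] * Bmats[[p]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {
      ch <- tryCatch(chol(V + diag(1e-8 * vy, n)), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
    }
    Vinv <- chol2inv(ch)
    XtVinvX <- crossprod(X, Vinv %*% X)
    chx <- tryCatch(chol(XtVinvX), error = function(e) NULL)
    if (is.null(chx)) return(NULL)
    XtVinvX_inv <- chol2inv(chx)
    VinvX <- Vinv %*% X
    P <- Vinv - VinvX %*% XtVinvX_inv %*% t(VinvX)
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) + sum(y * Py))
    list(ll = ll, P = P, Py = Py, Vinv = Vinv,
         XtVinvX_inv = XtVinvX_inv, VinvX = VinvX)
  }

  st <- eval_point(theta)
  if (is.null(st)) abort("Initial variance structure is singular.")
  converged <- FALSE
  used_fallback <- FALSE
  trace <- numeric(0)
  stall <- 0L
  patience <- 0L
  best_overall <- list(theta = theta, st = st, ll = st$ll)
  AI <- NULL

  for (iter in seq_len(max_iter)) {
    BPy <- lapply(Bmats, function(B) drop(B %*% st$Py))
    yPBPy <- vapply(BPy, function(v) sum(st$Py * v), numeric(1))
    trPB <- vapply(Bmats, function(B) sum(st$P * B), numeric(1))
    score <- -0.5 * (trPB - yPBPy)
    PBPy <- lapply(BPy, function(v) drop(st$P %*% v))
    AI <- matrix(0, np, np)
    for (p in seq_len(np)) {
      for (q in p:np) {
        AI[p, q] <- AI[q, p] <- 0.5 * sum(BPy[[p]] * PBPy[[q]])
      }
    }
    # active set: a variance pinned at its bound whose gradient points
    # outward stays frozen this iteration (keeps AI well conditioned)
    at_lb <- is.finite(lower) & (theta <= lower * (1 + 1e-6) + 1e-300)
    active <- !(at_lb & score < 0)
    if (!any(active)) {
      converged <- TRUE
      break
    }
    step <- numeric(np)
    sol <- tryCatch(solve(AI[active, active, drop = FALSE], score[active]),
                    error = function(e) NULL)
    if (is.null(sol)) {
      sol <- solve(AI[active, active, drop = FALSE] +
                     diag(1e-6 * max(diag(AI)[active]), sum(active)),
                   score[active])
    }
    step[active] <- sol

    # EM-flavoured multiplicative candidate: always feasible, preserves the
    # correlation of covariance blocks while rescaling their variances
    em_candidate <- function() {
      cand <- theta
      em_ratio <- yPBPy / pmax(trPB, 1e-300)
      is_var <- rep(TRUE, np)
      for (g in psd_groups) is_var[g[2]] <- FALSE
      cand[is_var] <- pmax(theta[is_var] * em_ratio[is_var], lower[is_var])
      for (g in psd_groups) {
        denom <- sqrt(theta[g[1]] * theta[g[3]])
        r <- if (denom > 0) theta[g[2]] / denom else 0
        cand[g[2]] <- r * sqrt(cand[g[1]] * cand[g[3]])
      }
      project_feasible(cand)
    }

    accepted <- FALSE
    best <- NULL
    h <- 1
    for (k in 1:12) {
      cand <- theta + h * step
      if (!feasible(cand)) cand <- project_feasible(cand)
      st_cand <- eval_point(cand)
      if (!is.null(st_cand)) {
        if (is.null(best) || st_cand$ll > best$st$ll) {
          best <- list(theta = cand, st = st_cand)
        }
        if (st_cand$ll >= st$ll - 1e-4 * abs(st$ll)) {
          theta_new <- cand; st_new <- st_cand; accepted <- TRUE
          break
        }
      }
      h <- h / 2
    }
    if (!accepted) {
      used_fallback <- TRUE
      cand <- em_candidate()
      st_cand <- eval_point(cand)
      if (!is.null(st_cand) &&
          (is.null(best) || st_cand$ll > best$st$ll)) {
        best <- list(theta = cand, st = st_cand)
      }
      if (is.null(best)) break
      theta_new <- best$theta; st_new <- best$st
    }

    dll <- abs(st_new$ll - st$ll)
    dth <- max(abs(theta_new - theta) / pmax(abs(theta), vy * 1e-4))
    theta <- theta_new
    st <- st_new
    trace <- c(trace, st$ll)
    if (st$ll > best_overall$ll + 1e-6 * (1 + abs(st$ll))) {
      best_overall <- list(theta = theta, st = st, ll = st$ll)
      patience <- 0L
    } else {
      patience <- patience + 1L
    }
    stall <- if (dll < tol * (1 + abs(st$ll))) stall + 1L else 0L
    # converged when the log-likelihood has stopped moving; parameter
    # stability ends it immediately, a persistent stall or boundary chatter
    # (no real improvement over ten iterations) after a grace period
    if ((stall >= 1L && dth < 1e-4) || stall >= 3L || patience >= 10L) {
      converged <- TRUE
      if (patience >= 10L && best_overall$ll > st$ll) {
        theta <- best_overall$theta
        st <- best_overall$st
      }
      break
    }
  }

  vcov_theta <- tryCatch(solve(AI), error = function(e) {
    solve(AI + diag(1e-6 * max(diag(AI)), np))
  })
  dimnames(vcov_theta) <- list(names(theta), names(theta))
  beta <- drop(st$XtVinvX_inv %*% crossprod(st$VinvX, y))
  names(beta) <- colnames(X)
  at_boundary <- theta <= lower * 1.5 + 1e-300

  list(
    theta = theta, vcov = vcov_theta, loglik = st$ll,
    beta = beta, beta_vcov = st$XtVinvX_inv,
    converged = converged, iterations = length(trace), trace = trace,
    at_boundary = at_boundary, used_fallback = used_fallback
  )
}
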