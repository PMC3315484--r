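#' Canonical transformation of variance components
#'
#' Finds the linear trait recoding `Q` that maps the residual covariance to
#' the identity and the genetic covariance to a diagonal matrix:
#' `Q R Q' = I` and `Q G Q' = D`. `Q` is built from the Cholesky factor of
#' `R` and the eigenvectors of the whitened genetic covariance, which is
#' the left-eigenvector decomposition of `G R^-1`. Under this recoding the
#' multivariate mixed model decouples into independent univariate models.
#'
#' @param comps A [variance_components()] (R must be positive definite).
#' @return List with `Q`, `D` (diagonal genetic variances, decreasing),
#'   and `Qinv`.
#' @export
canonical_transform <- function(comps) {
  stopifnot(inherits(comps, "variance_components"))
  U <- tryCatch(chol(comps$R), error = function(e) {
    abort("R is not positive definite; re-initialize the components.")
  })
  Q0 <- solve(t(U)) # Q0 R Q0' = I
  M <- Q0 %*% comps$G %*% t(Q0)
  M <- (M + t(M)) / 2
  es <- eigen(M, symmetric = TRUE)
  Q <- t(es$vectors) %*% Q0
  list(Q = Q, D = es$values, Qinv = solve(Q))
}

# Core projection computation. Everything lives in the doubly transformed
# basis: the GRM eigenbasis (A -> diag(lambda)) and the canonical trait
# basis (R -> I, G -> diag(d)), in which V is diagonal with entries
# lambda_k * d_a + 1 (times R's scale) and the REML problem decouples into
# t independent univariate problems sharing the design X. The fast path
# computes the likelihood, P y, and the diagonal projection profiles
# needed by the gradient and EM updates in O(m t s^2); `need_W = TRUE`
# additionally builds the V^-1 X blocks used by the Fisher information.
reml_project <- function(model, comps, need_W = FALSE) {
  m <- model$m
  t <- model$t
  s <- model$s
  ct <- canonical_transform(comps)
  Q <- ct$Q
  d <- ct$D
  lambda <- model$lambda

  Delta <- outer(lambda, d) + 1 # m x t (columns: canonical traits)
  if (min(Delta) <= 1e-12) {
    i_bad <- which(Delta == min(Delta), arr.ind = TRUE)[1, ]
    abort(sprintf(
      paste(
        "V is numerically singular: canonical genetic variance d[%d] = %.4g",
        "with GRM eigenvalue %.4g gives a non-positive variance block."
      ),
      i_bad[2], d[i_bad[2]], lambda[i_bad[1]]
    ))
  }
  iDelta <- 1 / Delta

  Ytil <- model$Ytil
  Xtil <- model$Xtil
  Yc <- Ytil %*% t(Q) # canonical-trait, GRM-eigenbasis data

  logdetR <- as.numeric(determinant(comps$R, logarithm = TRUE)$modulus)
  logdetV <- sum(log(Delta)) + m * logdetR

  # per canonical trait: univariate GLS with diagonal variance Delta[, a]
  pyc <- matrix(0, m, t) # P~ y per canonical trait
  diagP <- matrix(0, m, t) # diag(P~_a)
  logdetC0 <- -s * logdetR
  yPy <- 0
  for (a in seq_len(t)) {
    w <- iDelta[, a]
    Wv <- Xtil * w
    C0a <- crossprod(Xtil, Wv)
    cha <- tryCatch(chol(C0a), error = function(e) {
      abort("X' V^-1 X is singular; check the fixed-effect design.")
    })
    Ca <- chol2inv(cha)
    logdetC0 <- logdetC0 + 2 * sum(log(diag(cha)))
    beta_a <- Ca %*% crossprod(Wv, Yc[, a])
    pyc[, a] <- (Yc[, a] - Xtil %*% beta_a) * w
    diagP[, a] <- w - rowSums((Wv %*% Ca) * Wv)
    yPy <- yPy + sum(Yc[, a] * pyc[, a])
  }
  pyt <- pyc %*% Q # P y in original trait coordinates (GRM eigenbasis)
  loglik <- -0.5 * (logdetV + logdetC0 + yPy)

  out <- list(
    loglik = loglik, pyt = pyt, pyc = pyc, diagP = diagP,
    lambda = lambda, Delta = Delta, Q = Q, d = d,
    comps = comps, m = m, t = t, s = s,
    logdetV = logdetV, logdetC0 = logdetC0, yPy = yPy,
    BB = NULL, W = NULL, C = NULL
  )
  if (need_W) out <- c_proj_full(out, model)
  structure(out, class = "reml_projection")
}

# augment a projection with the Binv-entry vectors, the V^-1 X block array,
# and (X' V^-1 X)^-1 over the full design, for the Fisher information
c_proj_full <- function(proj, model) {
  m <- proj$m
  t <- proj$t
  s <- model$s
  Q <- proj$Q
  iDelta <- 1 / proj$Delta
  Xtil <- model$Xtil

  QQ <- Q[, rep(seq_len(t), each = t), drop = FALSE] *
    Q[, rep(seq_len(t), times = t), drop = FALSE]
  BB <- iDelta %*% QQ # m x t^2; column (i-1)*t+j holds (B_k^-1)[i,j]

  p <- t * s
  W <- array(0, c(m, t, p))
  for (j in seq_len(t)) {
    Bj <- BB[, (seq_len(t) - 1L) * t + j, drop = FALSE]
    for (b in seq_len(s)) {
      W[, , (j - 1L) * s + b] <- Bj * Xtil[, b]
    }
  }
  C0 <- matrix(0, p, p)
  for (i in seq_len(t)) {
    C0[((i - 1L) * s + 1L):(i * s), ] <- crossprod(Xtil, matrix(W[, i, ], m, p))
  }
  C0 <- (C0 + t(C0)) / 2
  proj$BB <- BB
  proj$W <- W
  proj$C <- chol2inv(chol(C0))
  proj
}

#' Restricted log-likelihood of the mixed model
#'
#' Evaluates the REML log-likelihood
#' `L = -1/2 (log det V + log det(X' V^-1 X) + y' P y)` (additive constants
#' dropped), where `V` has `m x m` blocks `cov_g(i,j) A + cov_e(i,j) I` and
#' `P = V^-1 - V^-1 X (X' V^-1 X)^-1 X' V^-1` is the REML projection.
#'
#' @param model A [reml_model()].
#' @param comps A [variance_components()].
#' @return List with `loglik` (scalar) and `proj`, an opaque projection
#'   object reused by [reml_gradient()], the EM steps, and
#'   [fisher_information()].
#' @export
restricted_loglik <- function(model, comps) {
  proj <- reml_project(model, comps)
  list(loglik = proj$loglik, proj = proj)
}

# index into the BB matrix for entry (i, j)
bb_col <- function(t, i, j) (i - 1L) * t + j

#' Gradient of the restricted log-likelihood
#'
#' Analytic REML gradient, `dL/dtheta_a = -1/2 (tr(P V_a) - y' P V_a P y)`,
#' where `V_a` is `E_ij (x) A` for genetic parameters and `E_ij (x) I` for
#' residual parameters, with `E_ij` the symmetric basis matrix. Parameters
#' follow the fixed ordering: genetic block then residual block, pairs
#' `(i, j)` with `i <= j`.
#'
#' @inheritParams restricted_loglik
#' @param proj Optional projection from [restricted_loglik()] at the same
#'   `comps`.
#' @return Named numeric vector of length `t (t + 1)`.
#' @export
reml_gradient <- function(model, comps, proj = NULL) {
  if (is.null(proj)) proj <- reml_project(model, comps)
  t <- proj$t
  px <- param_index(t)
  pyt <- proj$pyt

  TG <- proj_block_sum(proj, proj$lambda) # tr(P_ij A) for all blocks
  TE <- proj_block_sum(proj, rep(1, proj$m)) # tr(P_ij)
  QG <- crossprod(pyt, proj$lambda * pyt) # (Py)_i' A (Py)_j
  QE <- crossprod(pyt, pyt)

  grad <- numeric(nrow(px))
  for (a in seq_len(nrow(px))) {
    i <- px$i[a]
    j <- px$j[a]
    mult <- if (i == j) 1 else 2
    if (px$block[a] == "g") {
      grad[a] <- -0.5 * mult * (TG[i, j] - QG[i, j])
    } else {
      grad[a] <- -0.5 * mult * (TE[i, j] - QE[i, j])
    }
  }
  names(grad) <- param_names(t, model$traits)
  grad
}

# S[i,j] = sum_k w_k [P_k]_{ij} = tr(diag(w) P_ij) over the t x t diagonal
# blocks of the projection in the GRM eigenbasis; P_ij = sum_a Q[a,i] Q[a,j]
# P~_a with P~_a the decoupled canonical-trait projections
proj_block_sum <- function(proj, w) {
  trv <- colSums(w * proj$diagP) # per canonical trait
  crossprod(proj$Q, trv * proj$Q)
}

#' One univariate EM-REML step
#'
#' Standard EM update for a single trait:
#' `sg2 <- sg2 + sg2^2 (y' P A P y - tr(P A)) / m` and
#' `se2 <- se2 + se2^2 (y' P P y - tr(P)) / m`. The restricted
#' log-likelihood never decreases, and a zero-gradient point is a fixed
#' point. Updates that would go non-positive are floored at
#' `1e-8 x` the phenotypic variance, with a warning.
#'
#' @inheritParams reml_gradient
#' @return Updated [variance_components()].
#' @export
em_step_univariate <- function(model, comps, proj = NULL) {
  if (model$t != 1) abort("em_step_univariate() requires a single trait.")
  upd <- em1_core(
    model$Ytil[, 1], model$Xtil, model$lambda,
    comps$G[1, 1], comps$R[1, 1],
    floor_val = 1e-8 * var(model$Y[, 1])
  )
  variance_components(upd[1], upd[2])
}

# scalar EM-REML step in the GRM eigenbasis; returns c(sg2', se2')
em1_core <- function(ytil, Xtil, lambda, sg2, se2, floor_val) {
  m <- length(ytil)
  v <- sg2 * lambda + se2
  if (min(v) <= 0) {
    abort(sprintf(
      "V is numerically singular: variance block %.4g at GRM eigenvalue %.4g.",
      min(v), lambda[which.min(v)]
    ))
  }
  Wv <- Xtil / v
  C0 <- crossprod(Xtil, Wv)
  C <- solve(C0)
  beta <- C %*% crossprod(Wv, ytil)
  py <- (ytil - Xtil %*% beta)[, 1] / v
  trAP <- sum(lambda / v) - sum(C * crossprod(Wv, lambda * Wv))
  trP <- sum(1 / v) - sum(C * crossprod(Wv, Wv))
  sg2_new <- sg2 + sg2^2 * (sum(lambda * py^2) - trAP) / m
  se2_new <- se2 + se2^2 * (sum(py^2) - trP) / m
  if (sg2_new <= 0 || se2_new <= 0) {
    warn("EM update went non-positive; flooring at a small positive value.")
    sg2_new <- max(sg2_new, floor_val)
    se2_new <- max(se2_new, floor_val)
  }
  c(sg2_new, se2_new)
}

#' One multivariate EM-REML step (direct algorithm)
#'
#' E-step/M-step update of the full genetic and residual covariance
#' matrices. With `py_j` the trait-`j` component of `P y`, the genetic
#' update is
#' `G <- (1/m) (Ug + m G - G Sg G)` where
#' `Ug[i,j] = sum_k lambda_k (G py)_ki (G py)_kj` in the GRM eigenbasis and
#' `Sg = sum_k lambda_k P_k` collects the diagonal blocks of the projection;
#' the residual update replaces `A` by the identity. For one trait the step
#' reduces exactly to [em_step_univariate()].
#'
#' @inheritParams reml_gradient
#' @return Updated [variance_components()].
#' @export
em_step_multivariate <- function(model, comps, proj = NULL) {
  if (is.null(proj)) proj <- reml_project(model, comps)
  m <- proj$m
  G <- comps$G
  R <- comps$R
  pyt <- proj$pyt
  lambda <- proj$lambda

  Gpy <- pyt %*% G
  Rpy <- pyt %*% R
  Ug <- crossprod(Gpy, lambda * Gpy)
  Ur <- crossprod(Rpy, Rpy)
  Sg <- proj_block_sum(proj, lambda)
  Sr <- proj_block_sum(proj, rep(1, m))

  G_new <- (Ug + m * G - G %*% Sg %*% G) / m
  R_new <- (Ur + m * R - R %*% Sr %*% R) / m
  variance_components((G_new + t(G_new)) / 2, (R_new + t(R_new)) / 2)
}

#' Fisher information of the variance-component estimates
#'
#' Information matrix at the fit, `t(t+1) x t(t+1)`, ordered
#' genetic-then-residual with pairs `(i, j)`, `i <= j`, within each block.
#' `type = "observed"` (default) evaluates the negative Hessian of the
#' restricted log-likelihood,
#' `F[a,b] = y' P V_a P V_b P y - 1/2 tr(P V_a P V_b)`; `type = "expected"`
#' evaluates its expectation `F[a,b] = 1/2 tr(P V_a P V_b)`. The two agree
#' in expectation and closely at the optimum for well-behaved fits.
#' Standard errors are square roots of the diagonal of `F^-1`; a singular
#' `F` falls back to the Moore-Penrose pseudo-inverse with a warning.
#'
#' @inheritParams reml_gradient
#' @param type `"observed"` (negative Hessian) or `"expected"`.
#' @return List with `F`, `vcov` (`F^-1`), and `se` (named vector).
#' @export
fisher_information <- function(model, comps, proj = NULL,
                               type = c("observed", "expected")) {
  type <- match.arg(type)
  if (is.null(proj)) proj <- reml_project(model, comps, need_W = TRUE)
  if (is.null(proj$BB)) proj <- c_proj_full(proj, model)
  t <- proj$t
  m <- proj$m
  p <- t * proj$s
  px <- param_index(t)
  np <- nrow(px)
  lambda <- proj$lambda
  BB <- proj$BB
  C <- proj$C

  Wmat <- lapply(seq_len(t), function(i) matrix(proj$W[, i, ], m, p))
  ck_of <- function(a) if (px$block[a] == "g") lambda else rep(1, m)

  # per-parameter S_a = W' V_a W and C S_a
  S_list <- vector("list", np)
  for (a in seq_len(np)) {
    i <- px$i[a]
    j <- px$j[a]
    ck <- ck_of(a)
    Sa <- crossprod(Wmat[[i]], ck * Wmat[[j]])
    if (i != j) Sa <- Sa + t(Sa) else Sa <- (Sa + t(Sa)) / 2
    S_list[[a]] <- Sa
  }
  CS <- lapply(S_list, function(S) C %*% S)

  pairs_of <- function(a) {
    if (px$i[a] == px$j[a]) {
      list(c(px$i[a], px$i[a]))
    } else {
      list(c(px$i[a], px$j[a]), c(px$j[a], px$i[a]))
    }
  }

  # trace part tr(P V_a P V_b) for every parameter pair
  Tr <- matrix(0, np, np)
  for (a in seq_len(np)) {
    ia <- px$i[a]
    ja <- px$j[a]
    ca <- ck_of(a)
    for (b in a:np) {
      ib <- px$i[b]
      jb <- px$j[b]
      cb <- ck_of(b)
      cab <- ca * cb
      wab <- (2 - (ia == ja)) * (2 - (ib == jb)) / 2
      term1 <- wab * sum(cab * (
        BB[, bb_col(t, ja, ib)] * BB[, bb_col(t, ia, jb)] +
          BB[, bb_col(t, ja, jb)] * BB[, bb_col(t, ia, ib)]
      ))
      # middle term: tr(C W' V_a V^-1 V_b W)
      term2 <- 0
      for (uv in pairs_of(a)) {
        for (wx in pairs_of(b)) {
          weight <- cab * BB[, bb_col(t, uv[2], wx[1])]
          H <- crossprod(Wmat[[uv[1]]], weight * Wmat[[wx[2]]])
          term2 <- term2 + sum(C * t(H))
        }
      }
      term3 <- sum(t(CS[[a]]) * CS[[b]])
      Tr[a, b] <- Tr[b, a] <- term1 - 2 * term2 + term3
    }
  }

  if (type == "expected") {
    Fmat <- Tr / 2
  } else {
    # data part: (V_a P y)' P (V_b P y)
    pyt <- proj$pyt
    u_list <- vector("list", np)
    Pu_list <- vector("list", np)
    for (a in seq_len(np)) {
      ck <- ck_of(a)
      u <- matrix(0, m, t)
      for (uv in pairs_of(a)) {
        u[, uv[1]] <- u[, uv[1]] + ck * pyt[, uv[2]]
      }
      u_list[[a]] <- u
      Pu_list[[a]] <- apply_projection(proj, u)
    }
    Fmat <- matrix(0, np, np)
    for (a in seq_len(np)) {
      for (b in a:np) {
        Fmat[a, b] <- Fmat[b, a] <-
          sum(u_list[[a]] * Pu_list[[b]]) - Tr[a, b] / 2
      }
    }
  }
  nm <- param_names(t, model$traits)
  dimnames(Fmat) <- list(nm, nm)

  vc <- tryCatch(solve(Fmat), error = function(e) {
    warn("Fisher information is singular; using a pseudo-inverse.")
    pseudo_inverse(Fmat)
  })
  dimnames(vc) <- dimnames(Fmat)
  se <- sqrt(pmax(diag(vc), 0))
  list(F = Fmat, vcov = vc, se = se)
}

# One EM step of the canonical-transformation algorithm. The current
# components are recoded so the residual covariance is the identity and the
# genetic covariance is diagonal; under that guess the projection is
# block-diagonal across transformed traits, so a univariate EM step per
# transformed trait ([em1_core()]) updates the diagonal components, the
# cross moments of the decoupled projections supply the covariance
# updates, and the result is transformed back. Returns the updated
# components, the restricted log-likelihood at the *input* components, and
# a minimal projection usable by [reml_gradient()].
canonical_em_step <- function(model, comps) {
  m <- model$m
  t <- model$t
  s <- model$s
  lambda <- model$lambda
  Xtil <- model$Xtil
  ct <- canonical_transform(comps)
  Q <- ct$Q
  D <- ct$D
  Yq <- model$Ytil %*% t(Q)

  Delta <- outer(lambda, D) + 1
  if (min(Delta) <= 1e-12) {
    abort("V is numerically singular in the canonical basis; re-initialize.")
  }
  pyc <- matrix(0, m, t)
  diagP <- matrix(0, m, t)
  logdetC0 <- 0
  yPy <- 0
  dnew <- numeric(t)
  rnew <- numeric(t)
  for (a in seq_len(t)) {
    w <- 1 / Delta[, a]
    Wv <- Xtil * w
    cha <- chol(crossprod(Xtil, Wv))
    Ca <- chol2inv(cha)
    logdetC0 <- logdetC0 + 2 * sum(log(diag(cha)))
    beta_a <- Ca %*% crossprod(Wv, Yq[, a])
    pyc[, a] <- (Yq[, a] - Xtil %*% beta_a) * w
    diagP[, a] <- w - rowSums((Wv %*% Ca) * Wv)
    yPy <- yPy + sum(Yq[, a] * pyc[, a])
    upd <- em1_core(Yq[, a], Xtil, lambda, D[a], 1, floor_val = 1e-8)
    dnew[a] <- upd[1]
    rnew[a] <- upd[2]
  }
  logdetR <- as.numeric(determinant(comps$R, logarithm = TRUE)$modulus)
  loglik <- -0.5 * (sum(log(Delta)) + m * logdetR + logdetC0 - s * logdetR + yPy)

  # covariance updates from the cross moments of the decoupled projections
  Gp <- pyc * rep(D, each = m)
  Gt <- crossprod(Gp, lambda * Gp) / m
  Rt <- crossprod(pyc, pyc) / m
  diag(Gt) <- dnew
  diag(Rt) <- rnew
  Qi <- ct$Qinv
  comps_new <- variance_components(
    Qi %*% Gt %*% t(Qi),
    Qi %*% Rt %*% t(Qi)
  )
  proj_min <- structure(
    list(
      loglik = loglik, pyt = pyc %*% Q, pyc = pyc, diagP = diagP,
      lambda = lambda, Delta = Delta, Q = Q, d = D, comps = comps,
      m = m, t = t, s = s, BB = NULL, W = NULL, C = NULL
    ),
    class = "reml_projection"
  )
  list(comps = comps_new, loglik = loglik, proj = proj_min)
}

# apply the REML projection P = V^-1 - V^-1 X C X' V^-1 to an m x t matrix
# of rotated (GRM eigenbasis) trait values
apply_projection <- function(proj, w) {
  t <- proj$t
  m <- proj$m
  p <- t * proj$s
  Viw <- ((w %*% t(proj$Q)) * (1 / proj$Delta)) %*% proj$Q
  Wtw <- numeric(p)
  for (i in seq_len(t)) {
    Wtw <- Wtw + as.vector(crossprod(matrix(proj$W[, i, ], m, p), w[, i]))
  }
  z <- proj$C %*% Wtw
  out <- Viw
  for (i in seq_len(t)) {
    out[, i] <- out[, i] - matrix(proj$W[, i, ], m, p) %*% z
  }
  out
}

pseudo_inverse <- function(M, tol = 1e-10) {
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  pos <- abs(es$values) > tol * max(abs(es$values))
  es$vectors[, pos, drop = FALSE] %*%
    ((1 / es$values[pos]) * t(es$vectors[, pos, drop = FALSE]))
}
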