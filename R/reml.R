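# Henderson's mixed-model equations and REML for the animal model
#
#   y = HY + BM + PN + gamma*LW + pen + a + e,
#
# univariate or bivariate, with additive effects covarying proportionally to
# the pedigree numerator relationship matrix. Variance components are
# estimated by EM-REML (monotone reference implementation) with
# average-information acceleration; the restricted likelihood is evaluated
# through the sparse-inverse identities of the MME, and all trace identities
# used by the updates are validated against dense-matrix oracles in the
# test suite.

#' Specify the trait model
#'
#' @param response response column name.
#' @param fixed fixed-effect factor columns (first level dropped for
#'   identifiability).
#' @param covariate numeric covariate column (the live-weight slope), or
#'   `NULL` to omit it (traits defined without the weight adjustment).
#' @param pen pen (shared environment) factor column.
#' @return a `model_spec`.
#' @export
model_spec <- function(response,
                       fixed = c("herd_year", "birth_month", "parity"),
                       covariate = "live_weight_kg",
                       pen = "pen") {
  structure(list(response = response, fixed = fixed, covariate = covariate,
                 pen = pen),
            class = "model_spec")
}

# Build incidence structures shared by REML and BLUP.
mm_prepare <- function(models, data, ped, groups = NULL) {
  if (inherits(models, "model_spec")) models <- list(models)
  n_tr <- length(models)
  stopifnot(n_tr %in% c(1L, 2L))
  ped <- as_pedigree(ped)
  q <- nrow(ped)
  Ainv <- build_a_inverse(ped, groups)
  qa <- nrow(Ainv)
  data <- as.data.frame(data)
  stopifnot("animal" %in% names(data), all(data$animal %in% ped$animal))
  arow <- match(data$animal, ped$animal)
  pen_col <- models[[1]]$pen
  stopifnot(pen_col %in% names(data))
  pens <- sort(unique(as.character(data[[pen_col]])))
  npen <- length(pens)
  pen_idx <- match(as.character(data[[pen_col]]), pens)

  obs_rows <- vector("list", n_tr)
  Xs <- vector("list", n_tr)
  xnames <- vector("list", n_tr)
  for (t in seq_len(n_tr)) {
    m <- models[[t]]
    stopifnot(m$response %in% names(data))
    rows <- which(!is.na(data[[m$response]]))
    if (!length(rows)) stop("no observations for ", m$response, call. = FALSE)
    df <- data[rows, , drop = FALSE]
    terms <- character(0)
    for (fx in m$fixed) {
      stopifnot(fx %in% names(df))
      df[[fx]] <- factor(df[[fx]])
      if (nlevels(df[[fx]]) > 1L) terms <- c(terms, fx)
    }
    if (!is.null(m$covariate)) terms <- c(terms, m$covariate)
    form <- if (length(terms)) stats::reformulate(terms) else ~1
    X <- stats::model.matrix(form, df)
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) {
      keep <- qrx$pivot[seq_len(qrx$rank)]
      warning("dropping ", ncol(X) - qrx$rank,
              " aliased fixed-effect column(s) for ", m$response,
              call. = FALSE)
      X <- X[, keep, drop = FALSE]
    }
    obs_rows[[t]] <- rows
    Xs[[t]] <- X
    xnames[[t]] <- paste0(m$response, ":", colnames(X))
  }
  n_obs_t <- lengths(obs_rows)
  offs <- cumsum(c(0L, n_obs_t))[seq_len(n_tr)]
  n_obs <- sum(n_obs_t)

  # obs position of (data row, trait); NA when unobserved
  pos <- matrix(NA_integer_, nrow(data), n_tr)
  for (t in seq_len(n_tr)) {
    pos[obs_rows[[t]], t] <- offs[t] + seq_along(obs_rows[[t]])
  }
  pat_key <- apply(!is.na(pos), 1L, function(z) paste(which(z), collapse = ","))
  patterns <- list()
  for (key in unique(pat_key[pat_key != ""])) {
    rows <- which(pat_key == key)
    S <- as.integer(strsplit(key, ",")[[1]])
    patterns[[key]] <- list(S = S, rows = rows,
                            pos = pos[rows, S, drop = FALSE])
  }

  p_t <- vapply(Xs, ncol, integer(1))
  Xbig <- Matrix::.bdiag(lapply(Xs, function(x) methods::as(x, "CsparseMatrix")))
  Wi <- unlist(lapply(seq_len(n_tr), function(t) offs[t] + seq_along(obs_rows[[t]])))
  Wj <- unlist(lapply(seq_len(n_tr), function(t) {
    (t - 1L) * npen + pen_idx[obs_rows[[t]]]
  }))
  Wbig <- Matrix::sparseMatrix(i = Wi, j = Wj, x = 1,
                               dims = c(n_obs, n_tr * npen))
  Zj <- unlist(lapply(seq_len(n_tr), function(t) {
    (t - 1L) * qa + arow[obs_rows[[t]]]
  }))
  Zbig <- Matrix::sparseMatrix(i = Wi, j = Zj, x = 1,
                               dims = c(n_obs, n_tr * qa))
  y <- unlist(lapply(seq_len(n_tr), function(t) {
    data[[models[[t]]$response]][obs_rows[[t]]]
  }))
  Tmat <- cbind(Xbig, Wbig, Zbig)
  p <- ncol(Xbig)
  sec <- list(
    fixed = seq_len(p),
    pen = lapply(seq_len(n_tr), function(t) p + (t - 1L) * npen + seq_len(npen)),
    animal = lapply(seq_len(n_tr), function(t) {
      p + n_tr * npen + (t - 1L) * qa + seq_len(q)
    }),
    group = if (qa > q) lapply(seq_len(n_tr), function(t) {
      p + n_tr * npen + (t - 1L) * qa + (q + 1L):qa
    }),
    animal_full = lapply(seq_len(n_tr), function(t) {
      p + n_tr * npen + (t - 1L) * qa + seq_len(qa)
    })
  )
  Atrip <- Matrix::mat2triplet(Ainv)
  obs_animal <- unlist(lapply(seq_len(n_tr), function(t) arow[obs_rows[[t]]]))
  obs_trait <- rep(seq_len(n_tr), times = n_obs_t)
  list(models = models, n_traits = n_tr, ped = ped, q = q, qa = qa,
       Ainv = Ainv, log_det_a = attr(Ainv, "log_det_a"),
       Atrip = Atrip, npen = npen, pens = pens,
       Tmat = Tmat, y = y, n_obs = n_obs, n_obs_t = n_obs_t, p = p,
       p_t = p_t, sec = sec, patterns = patterns, offs = offs,
       obs_animal = obs_animal, obs_trait = obs_trait,
       n_datarows = nrow(data),
       xnames = unlist(xnames), groups = groups,
       resp = vapply(models, function(m) m$response, character(1)))
}

# sparse block-diagonal (over observations) matrix whose per-row block is
# matfun(S) for the row's missingness pattern S
row_block_sparse <- function(prep, matfun) {
  ii <- list(); jj <- list(); xx <- list(); k <- 0L
  for (pat in prep$patterns) {
    B <- matfun(pat$S)
    nS <- length(pat$S)
    for (a in seq_len(nS)) {
      for (b in seq_len(nS)) {
        if (B[a, b] == 0) next
        k <- k + 1L
        ii[[k]] <- pat$pos[, a]
        jj[[k]] <- pat$pos[, b]
        xx[[k]] <- rep(B[a, b], nrow(pat$pos))
      }
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(prep$n_obs, prep$n_obs))
}

theta_valid <- function(th) {
  ok <- function(m) all(is.finite(m)) && min(eigen(m, symmetric = TRUE,
                                                  only.values = TRUE)$values) > 0
  ok(th$G) && ok(th$R) && all(is.finite(th$P)) && all(th$P > 0)
}

theta_pack <- function(th) {
  n_tr <- nrow(th$G)
  lt <- which(lower.tri(th$G, diag = TRUE))
  c(th$G[lt], th$P, th$R[lt])
}

theta_unpack <- function(v, n_tr) {
  nl <- n_tr * (n_tr + 1) / 2
  G <- matrix(0, n_tr, n_tr); lt <- which(lower.tri(G, diag = TRUE))
  G[lt] <- v[seq_len(nl)]; G <- G + t(G) - diag(diag(G), n_tr)
  P <- v[nl + seq_len(n_tr)]
  R <- matrix(0, n_tr, n_tr)
  R[lt] <- v[nl + n_tr + seq_len(nl)]; R <- R + t(R) - diag(diag(R), n_tr)
  list(G = G, P = P, R = R)
}

# Assemble and solve the MME for components theta; returns everything the
# updates need.
mm_solve <- function(prep, th, want_inverse = TRUE) {
  n_tr <- prep$n_traits
  Rinv_star <- row_block_sparse(prep, function(S) {
    solve(th$R[S, S, drop = FALSE])
  })
  TrT <- Matrix::t(prep$Tmat)
  TR <- TrT %*% Rinv_star
  M <- TR %*% prep$Tmat
  Ginv <- solve(th$G)
  pen_prec <- rep(1 / th$P, each = prep$npen)
  gblock <- Matrix::.bdiag(list(
    Matrix::Diagonal(prep$p, 0),
    Matrix::Diagonal(length(pen_prec), pen_prec),
    Matrix::kronecker(Ginv, prep$Ainv)
  ))
  M <- M + gblock
  rhs <- as.numeric(TR %*% prep$y)
  Md <- as.matrix(Matrix::forceSymmetric(M))
  ch <- tryCatch(chol(Md), error = function(e) {
    chol(Md + diag(1e-8 * mean(diag(Md)), nrow(Md)))
  })
  sol <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
  Cinv <- if (want_inverse) chol2inv(ch) else NULL
  yRy <- as.numeric(prep$y %*% (Rinv_star %*% prep$y))
  resid <- prep$y - as.numeric(prep$Tmat %*% sol)
  r <- as.numeric(Rinv_star %*% resid)
  logdet_rstar <- sum(vapply(prep$patterns, function(pat) {
    length(pat$rows) * determinant(th$R[pat$S, pat$S, drop = FALSE],
                                   logarithm = TRUE)$modulus
  }, numeric(1)))
  logdet_g <- prep$npen * sum(log(th$P)) +
    prep$q * determinant(th$G, logarithm = TRUE)$modulus +
    n_tr * prep$log_det_a
  logdetM <- 2 * sum(log(diag(ch)))
  yPy <- yRy - sum(sol * rhs)
  m2lr <- as.numeric(logdet_rstar + logdet_g + logdetM + yPy)
  list(M = M, ch = ch, sol = sol, Cinv = Cinv, r = r, resid = resid,
       Rinv_star = Rinv_star, TR = TR, yPy = yPy, loglik = -0.5 * m2lr)
}

# trace of Cinv * B for sparse B given as triplet list
tr_cinv <- function(Cinv, Bi, Bj, Bx, ioff = 0L, joff = 0L) {
  sum(Cinv[cbind(Bj + joff, Bi + ioff)] * Bx)
}

# U' Ainv V for q-vectors via triplets
quad_ainv <- function(prep, u, v) {
  sum(prep$Atrip$x * u[prep$Atrip$i] * v[prep$Atrip$j])
}

mm_em_update <- function(prep, th, fit) {
  if (any(vapply(prep$patterns, function(p) length(p$S), integer(1)) <
          prep$n_traits)) {
    stop("EM updates require complete multi-trait records", call. = FALSE)
  }
  n_tr <- prep$n_traits
  q <- prep$q; npen <- prep$npen
  sol <- fit$sol; Cinv <- fit$Cinv
  U <- vapply(seq_len(n_tr), function(t) sol[prep$sec$animal[[t]]],
              numeric(q))
  Pv <- vapply(seq_len(n_tr), function(t) sol[prep$sec$pen[[t]]],
               numeric(npen))
  if (npen == 1L) Pv <- matrix(Pv, nrow = 1L)
  G <- matrix(0, n_tr, n_tr)
  for (j in seq_len(n_tr)) {
    for (k in j:n_tr) {
      tra <- tr_cinv(Cinv, prep$Atrip$i, prep$Atrip$j, prep$Atrip$x,
                     ioff = prep$sec$animal[[j]][1] - 1L,
                     joff = prep$sec$animal[[k]][1] - 1L)
      G[j, k] <- G[k, j] <- (quad_ainv(prep, U[, j], U[, k]) + tra) / q
    }
  }
  P <- vapply(seq_len(n_tr), function(t) {
    (sum(Pv[, t]^2) + sum(diag(Cinv)[prep$sec$pen[[t]]])) / npen
  }, numeric(1))
  R <- matrix(0, n_tr, n_tr)
  e <- fit$resid
  for (j in seq_len(n_tr)) {
    rows_j <- prep$offs[j] + seq_len(prep$n_obs_t[j])
    Tj <- prep$Tmat[rows_j, , drop = FALSE]
    for (k in j:n_tr) {
      rows_k <- prep$offs[k] + seq_len(prep$n_obs_t[k])
      Tk <- prep$Tmat[rows_k, , drop = FALSE]
      B <- Matrix::mat2triplet(Matrix::t(Tk) %*% Tj)
      trc <- tr_cinv(Cinv, B$i, B$j, B$x)
      R[j, k] <- R[k, j] <- (sum(e[rows_j] * e[rows_k]) + trc) /
        prep$n_obs_t[j]
    }
  }
  list(G = G, P = P, R = R)
}

# Score vector and average-information matrix at theta, given a solved MME.
mm_score_ai <- function(prep, th, fit) {
  n_tr <- prep$n_traits
  q <- prep$q; npen <- prep$npen
  sol <- fit$sol; Cinv <- fit$Cinv; r <- fit$r
  Ginv <- solve(th$G)
  U <- vapply(seq_len(n_tr), function(t) sol[prep$sec$animal[[t]]], numeric(q))
  if (q == 1L) U <- matrix(U, nrow = 1L)
  Pv <- vapply(seq_len(n_tr), function(t) sol[prep$sec$pen[[t]]], numeric(npen))
  if (npen == 1L) Pv <- matrix(Pv, nrow = 1L)
  # r arranged per data row/trait
  rmat <- matrix(0, prep$n_datarows, n_tr)
  for (pat in prep$patterns) {
    for (a in seq_along(pat$S)) rmat[pat$rows, pat$S[a]] <- r[pat$pos[, a]]
  }
  QA <- matrix(0, n_tr, n_tr) # U_t' Ainv U_t'
  SA <- matrix(0, n_tr, n_tr) # sum Ainv o Cinv block
  for (t1 in seq_len(n_tr)) {
    for (t2 in seq_len(n_tr)) {
      QA[t1, t2] <- quad_ainv(prep, U[, t1], U[, t2])
      SA[t1, t2] <- tr_cinv(Cinv, prep$Atrip$i, prep$Atrip$j, prep$Atrip$x,
                            ioff = prep$sec$animal[[t1]][1] - 1L,
                            joff = prep$sec$animal[[t2]][1] - 1L)
    }
  }
  lt <- which(lower.tri(diag(n_tr), diag = TRUE), arr.ind = TRUE)
  params <- list()
  for (m in seq_len(nrow(lt))) {
    params[[length(params) + 1L]] <- list(type = "G", j = lt[m, 1], k = lt[m, 2])
  }
  for (t in seq_len(n_tr)) {
    params[[length(params) + 1L]] <- list(type = "P", t = t)
  }
  for (m in seq_len(nrow(lt))) {
    params[[length(params) + 1L]] <- list(type = "R", j = lt[m, 1], k = lt[m, 2])
  }
  np <- length(params)
  score <- numeric(np)
  uvecs <- vector("list", np)
  esym <- function(j, k, n) {
    E <- matrix(0, n, n); E[j, k] <- E[j, k] + 1; E[k, j] <- E[k, j] + 1
    if (j == k) E[j, k] <- 1
    E
  }
  for (i in seq_len(np)) {
    pm <- params[[i]]
    if (pm$type == "G") {
      E <- esym(pm$j, pm$k, n_tr)
      B2 <- Ginv %*% E %*% Ginv
      quad <- sum(B2 * QA)
      trc <- q * sum(diag(Ginv %*% E)) - sum(B2 * SA)
      EG <- E %*% Ginv
      Wt <- U %*% t(EG) # q x n_tr: w_t = sum_t' EG[t,t'] U_t'
      # observation-level expansion of Z*(E G^-1 x I) u_hat
      uvecs[[i]] <- Wt[cbind(prep$obs_animal, prep$obs_trait)]
    } else if (pm$type == "P") {
      quad <- sum(Pv[, pm$t]^2) / th$P[pm$t]^2
      trc <- npen / th$P[pm$t] -
        sum(diag(Cinv)[prep$sec$pen[[pm$t]]]) / th$P[pm$t]^2
      u <- numeric(prep$n_obs)
      rows_t <- prep$offs[pm$t] + seq_len(prep$n_obs_t[pm$t])
      Wsub <- prep$Tmat[rows_t, prep$sec$pen[[pm$t]], drop = FALSE]
      u[rows_t] <- as.numeric(Wsub %*% Pv[, pm$t]) / th$P[pm$t]
      uvecs[[i]] <- u
    } else {
      E <- esym(pm$j, pm$k, n_tr)
      quad <- if (pm$j == pm$k) sum(rmat[, pm$j]^2) else
        2 * sum(rmat[, pm$j] * rmat[, pm$k])
      tr1 <- sum(vapply(prep$patterns, function(pat) {
        RS <- solve(th$R[pat$S, pat$S, drop = FALSE])
        length(pat$rows) * sum(diag(RS %*% E[pat$S, pat$S, drop = FALSE]))
      }, numeric(1)))
      Wstar <- row_block_sparse(prep, function(S) {
        RS <- solve(th$R[S, S, drop = FALSE])
        RS %*% E[S, S, drop = FALSE] %*% RS
      })
      Dm <- Matrix::mat2triplet(Matrix::t(prep$Tmat) %*% Wstar %*% prep$Tmat)
      trc <- tr1 - tr_cinv(fit$Cinv, Dm$i, Dm$j, Dm$x)
      u <- numeric(prep$n_obs)
      for (pat in prep$patterns) {
        ES <- E[pat$S, pat$S, drop = FALSE]
        for (a in seq_along(pat$S)) {
          acc <- numeric(length(pat$rows))
          for (b in seq_along(pat$S)) {
            acc <- acc + ES[a, b] * r[pat$pos[, b]]
          }
          u[pat$pos[, a]] <- acc
        }
      }
      uvecs[[i]] <- u
    }
    score[i] <- -0.5 * (trc - quad)
  }
  # AI matrix via one extra MME solve per parameter
  Pu <- vector("list", np)
  for (i in seq_len(np)) {
    rhs_u <- as.numeric(fit$TR %*% uvecs[[i]])
    s_u <- backsolve(fit$ch, backsolve(fit$ch, rhs_u, transpose = TRUE))
    Pu[[i]] <- as.numeric(fit$Rinv_star %*%
                            (uvecs[[i]] - as.numeric(prep$Tmat %*% s_u)))
  }
  AI <- matrix(0, np, np)
  for (i in seq_len(np)) {
    for (j in i:np) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(uvecs[[i]] * Pu[[j]])
    }
  }
  list(score = score, AI = AI, params = params)
}

reml_engine <- function(prep, start = NULL, method = c("ai", "em"),
                        max_iter = 50L, tol = 1e-5, n_em_start = 2L,
                        verbose = FALSE) {
  method <- match.arg(method)
  n_tr <- prep$n_traits
  if (!is.null(prep$groups)) {
    stop("REML fitting uses a pedigree without unknown-parent groups; ",
         "fit groups in solve_blup()", call. = FALSE)
  }
  if (is.null(start)) {
    vy <- vapply(seq_len(n_tr), function(t) {
      stats::var(prep$y[prep$offs[t] + seq_len(prep$n_obs_t[t])])
    }, numeric(1))
    s <- sqrt(vy)
    G <- diag(0.3 * vy, n_tr); R <- diag(0.6 * vy, n_tr)
    if (n_tr == 2L) {
      G[1, 2] <- G[2, 1] <- 0.1 * 0.3 * s[1] * s[2]
      R[1, 2] <- R[2, 1] <- 0.1 * 0.6 * s[1] * s[2]
    }
    start <- list(G = G, P = 0.1 * vy, R = R)
  }
  th <- start
  stopifnot(theta_valid(th))
  complete <- all(vapply(prep$patterns, function(p) length(p$S),
                         integer(1)) == n_tr)
  fit <- mm_solve(prep, th)
  lik_trace <- fit$loglik
  converged <- FALSE
  ai_cov <- NULL
  for (it in seq_len(max_iter)) {
    use_em <- method == "em" || (it <= n_em_start && complete)
    if (use_em) {
      th_new <- mm_em_update(prep, th, fit)
      fit_new <- mm_solve(prep, th_new)
    } else {
      sa <- mm_score_ai(prep, th, fit)
      AI <- sa$AI
      # guard: ridge if AI nearly singular
      ev <- eigen(AI, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < 1e-10 * max(ev)) AI <- AI + diag(1e-8 * max(ev), nrow(AI))
      delta <- solve(AI, sa$score)
      step <- 1
      repeat {
        th_new <- theta_unpack(theta_pack(th) + step * delta, n_tr)
        if (theta_valid(th_new)) {
          fit_new <- mm_solve(prep, th_new)
          if (fit_new$loglik >= fit$loglik - 1e-6) break
        }
        step <- step / 2
        if (step < 1 / 2^12) {
          if (complete) {
            th_new <- mm_em_update(prep, th, fit)
            fit_new <- mm_solve(prep, th_new)
          } else {
            th_new <- th; fit_new <- fit
          }
          break
        }
      }
      ai_cov <- tryCatch(solve(AI), error = function(e) NULL)
    }
    rel <- max(abs(theta_pack(th_new) - theta_pack(th)) /
                 pmax(abs(theta_pack(th)), 1e-8))
    th <- th_new; fit <- fit_new
    lik_trace <- c(lik_trace, fit$loglik)
    if (verbose) {
      message(sprintf("iter %2d  logL %.4f  max rel change %.2e", it,
                      fit$loglik, rel))
    }
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("REML did not converge in ", max_iter,
            " iterations; last iterate returned", call. = FALSE)
  }
  list(theta = th, fit = fit, loglik_trace = lik_trace,
       converged = converged, n_iter = length(lik_trace) - 1L,
       ai_cov = ai_cov)
}

reml_result <- function(prep, eng, method) {
  th <- eng$theta
  n_tr <- prep$n_traits
  h2 <- diag(th$G) / (diag(th$G) + th$P + diag(th$R))
  h2_no_pen <- diag(th$G) / (diag(th$G) + diag(th$R))
  r_g <- if (n_tr == 2L) th$G[1, 2] / sqrt(th$G[1, 1] * th$G[2, 2]) else NULL
  se <- NULL
  if (!is.null(eng$ai_cov)) {
    # delta-method SEs for h2 (and r_g) from the AI covariance
    pack0 <- theta_pack(th)
    fn_list <- lapply(seq_len(n_tr), function(t) {
      function(v) {
        t2 <- theta_unpack(v, n_tr)
        t2$G[t, t] / (t2$G[t, t] + t2$P[t] + t2$R[t, t])
      }
    })
    if (n_tr == 2L) {
      fn_list <- c(fn_list, list(function(v) {
        t2 <- theta_unpack(v, n_tr)
        t2$G[1, 2] / sqrt(t2$G[1, 1] * t2$G[2, 2])
      }))
    }
    num_grad <- function(f, v) {
      h <- pmax(abs(v), 1e-4) * 1e-5
      vapply(seq_along(v), function(i) {
        vp <- v; vm <- v; vp[i] <- v[i] + h[i]; vm[i] <- v[i] - h[i]
        (f(vp) - f(vm)) / (2 * h[i])
      }, numeric(1))
    }
    ses <- vapply(fn_list, function(f) {
      g <- num_grad(f, pack0)
      sqrt(max(drop(t(g) %*% eng$ai_cov %*% g), 0))
    }, numeric(1))
    se <- list(h2 = ses[seq_len(n_tr)],
               r_g = if (n_tr == 2L) ses[n_tr + 1L],
               components = sqrt(pmax(diag(eng$ai_cov), 0)))
  }
  structure(
    list(G = th$G, pen = th$P, R = th$R,
         traits = prep$resp,
         h2 = stats::setNames(h2, prep$resp),
         h2_no_pen = stats::setNames(h2_no_pen, prep$resp),
         r_g = r_g, sigma_g = stats::setNames(sqrt(diag(th$G)), prep$resp),
         se = se, loglik_trace = eng$loglik_trace,
         converged = eng$converged, n_iter = eng$n_iter,
         n_obs = prep$n_obs, q = prep$q, npen = prep$npen, method = method),
    class = "reml_fit"
  )
}

#' Univariate REML for the animal model
#'
#' Estimates additive, pen and residual variances for one trait by
#' restricted maximum likelihood on Henderson's mixed-model equations.
#' `method = "em"` runs pure EM-REML (monotone in the restricted
#' likelihood); the default `"ai"` starts with EM steps and switches to
#' average-information updates guarded by likelihood step-halving.
#'
#' @param model a [model_spec()].
#' @param data phenotype data frame with an `animal` column.
#' @param ped pedigree (see [as_pedigree()]).
#' @param start optional list with `G`, `P`, `R` start values.
#' @param max_iter,tol convergence control (relative component change).
#' @param method `"ai"` or `"em"`.
#' @param verbose print the iteration trace.
#' @return a `reml_fit` with components, heritability (pen variance included
#'   in the phenotypic denominator; `h2_no_pen` reported alongside),
#'   likelihood trace and asymptotic SEs from the AI matrix.
#' @export
reml_univariate <- function(model, data, ped, start = NULL, max_iter = 50L,
                            tol = 1e-5, method = c("ai", "em"),
                            verbose = FALSE) {
  method <- match.arg(method)
  prep <- mm_prepare(model, data, ped)
  eng <- reml_engine(prep, start, method, max_iter, tol, verbose = verbose)
  reml_result(prep, eng, method)
}

#' Bivariate REML with pen covariance constrained to zero
#'
#' Estimates 2x2 additive-genetic and residual covariance matrices and
#' per-trait pen variances; the pen effect is uncorrelated across traits by
#' construction (its cross-trait covariance is fixed at zero). The genetic
#' correlation is `G12 / sqrt(G11 G22)`.
#'
#' @param models list of two [model_spec()] objects (the two traits may use
#'   different fixed structures, e.g. omit the live-weight covariate).
#' @inheritParams reml_univariate
#' @return a `reml_fit` with `r_g` filled in.
#' @export
reml_bivariate <- function(models, data, ped, start = NULL, max_iter = 60L,
                           tol = 1e-5, method = c("ai", "em"),
                           verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(length(models) == 2L)
  prep <- mm_prepare(models, data, ped)
  eng <- reml_engine(prep, start, method, max_iter, tol, verbose = verbose)
  reml_result(prep, eng, method)
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("<reml_fit> %s; %d observations, %d animals, %s\n",
              paste(x$traits, collapse = " + "), x$n_obs, x$q,
              if (x$converged) sprintf("converged in %d iterations", x$n_iter)
              else "NOT converged"))
  for (t in seq_along(x$traits)) {
    cat(sprintf("  %s: sigma2_a %.4f, sigma2_pen %.4f, sigma2_e %.4f, h2 %.3f%s\n",
                x$traits[t], x$G[t, t], x$pen[t], x$R[t, t], x$h2[t],
                if (!is.null(x$se)) sprintf(" (SE %.3f)", x$se$h2[t]) else ""))
  }
  if (!is.null(x$r_g)) {
    cat(sprintf("  genetic correlation r_g %.3f%s\n", x$r_g,
                if (!is.null(x$se) && !is.null(x$se$r_g))
                  sprintf(" (SE %.3f)", x$se$r_g) else ""))
  }
  invisible(x)
}

#' @export
tidy.reml_fit <- function(x, ...) {
  out <- list()
  for (t in seq_along(x$traits)) {
    out[[length(out) + 1L]] <- tibble::tibble(
      trait = x$traits[t],
      term = c("sigma2_a", "sigma2_pen", "sigma2_e", "h2"),
      estimate = c(x$G[t, t], x$pen[t], x$R[t, t], x$h2[t]))
  }
  if (length(x$traits) == 2L) {
    out[[length(out) + 1L]] <- tibble::tibble(
      trait = paste(x$traits, collapse = ":"),
      term = c("cov_a", "cov_e", "r_g"),
      estimate = c(x$G[1, 2], x$R[1, 2], x$r_g))
  }
  dplyr::bind_rows(out)
}

#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, n_animals = x$q, n_iter = x$n_iter,
    converged = x$converged,
    loglik = utils::tail(x$loglik_trace, 1),
    r_g = if (is.null(x$r_g)) NA_real_ else x$r_g
  )
}

#' Heritability from variance components
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_pen + sigma2_e)`. The pen variance is
#' part of the phenotypic denominator by default; set `include_pen = FALSE`
#' for the narrow denominator without it (both conventions are reported by
#' [reml_univariate()]).
#'
#' @param vc a `reml_fit`, or a numeric vector
#'   `c(sigma2_a, sigma2_pen, sigma2_e)`.
#' @param include_pen include the pen variance in the denominator.
#' @return heritability (vector for multi-trait fits).
#' @export
heritability <- function(vc, include_pen = TRUE) {
  if (inherits(vc, "reml_fit")) {
    if (include_pen) return(vc$h2) else return(vc$h2_no_pen)
  }
  stopifnot(length(vc) == 3L)
  tot <- vc[1] + include_pen * vc[2] + vc[3]
  if (tot <= 0) stop("total variance must be positive", call. = FALSE)
  unname(vc[1] / tot)
}

#' Henderson's mixed-model equations
#'
#' Assembles the MME coefficient matrix and right-hand side for the trait
#' model at fixed variance components (fixed herd-year, birth-month and
#' parity effects with first levels dropped, the live-weight covariate,
#' random pen and additive-animal blocks; with `groups`, unknown parents are
#' replaced by genetic groups, augmenting the animal block).
#'
#' @inheritParams reml_univariate
#' @param groups optional [assign_genetic_groups()] result.
#' @param vc variance components: a `reml_fit` or a list with `G`
#'   (matrix), `P` (pen variances) and `R` (residual matrix).
#' @return a list with sparse `M`, `rhs`, the solution `sol`, column labels
#'   and section indices.
#' @export
build_mme <- function(model, data, ped, groups = NULL, vc) {
  prep <- mm_prepare(model, data, ped, groups)
  th <- if (inherits(vc, "reml_fit")) {
    list(G = vc$G, P = vc$pen, R = vc$R)
  } else {
    list(G = as.matrix(vc$G), P = vc$P, R = as.matrix(vc$R))
  }
  n_tr <- prep$n_traits
  Rinv_star <- row_block_sparse(prep, function(S) {
    solve(th$R[S, S, drop = FALSE])
  })
  TR <- Matrix::t(prep$Tmat) %*% Rinv_star
  M <- TR %*% prep$Tmat
  Ginv <- solve(th$G)
  pen_prec <- rep(1 / th$P, each = prep$npen)
  ridge <- if (prep$qa > prep$q) {
    # group equations are confounded with the intercept; regularise weakly
    d <- numeric(prep$qa) ; d[(prep$q + 1L):prep$qa] <- 1e-6
    Matrix::kronecker(Ginv, Matrix::Diagonal(prep$qa, d))
  } else {
    NULL
  }
  gblock <- Matrix::.bdiag(list(
    Matrix::Diagonal(prep$p, 0),
    Matrix::Diagonal(length(pen_prec), pen_prec),
    Matrix::kronecker(Ginv, prep$Ainv)
  ))
  M <- M + gblock
  if (!is.null(ridge)) {
    ng <- prep$qa
    ioff <- prep$p + n_tr * prep$npen
    M[ioff + seq_len(n_tr * ng), ioff + seq_len(n_tr * ng)] <-
      M[ioff + seq_len(n_tr * ng), ioff + seq_len(n_tr * ng)] + ridge
  }
  rhs <- as.numeric(TR %*% prep$y)
  sol <- tryCatch(
    as.numeric(Matrix::solve(M, rhs)),
    error = function(e) {
      stop("singular mixed-model equations after constraints; confounded ",
           "terms among: ", paste(utils::head(prep$xnames, 8), collapse = ", "),
           call. = FALSE)
    })
  list(M = M, rhs = rhs, sol = sol, prep = prep,
       labels = list(fixed = prep$xnames, pens = prep$pens,
                     animals = prep$ped$animal),
       sections = prep$sec)
}

#' BLUP breeding values for all pedigree animals
#'
#' Solves the MME at the given variance components and returns estimated
#' breeding values for every animal in the pedigree (phenotyped or not).
#' With `groups`, unknown parents enter through the unknown-parent-group
#' augmentation and founder EBVs shrink toward their group means.
#'
#' @inheritParams build_mme
#' @return an EBV tibble: `animal`, `birth_year` (if present in `ped`), one
#'   `ebv_<trait>` column per trait; group-effect estimates are attached as
#'   attribute `"group_effects"`.
#' @export
solve_blup <- function(model, data, ped, groups = NULL, vc) {
  mme <- build_mme(model, data, ped, groups, vc)
  prep <- mme$prep
  out <- tibble::tibble(animal = prep$ped$animal)
  if ("birth_year" %in% names(prep$ped)) out$birth_year <- prep$ped$birth_year
  for (t in seq_len(prep$n_traits)) {
    out[[paste0("ebv_", prep$resp[t])]] <- mme$sol[prep$sec$animal[[t]]]
  }
  if (!is.null(prep$sec$group)) {
    ge <- lapply(seq_len(prep$n_traits), function(t) mme$sol[prep$sec$group[[t]]])
    attr(out, "group_effects") <- ge
  }
  out
}

#' Genetic trend from estimated breeding values
#'
#' Mean EBV by birth year, expressed in genetic standard deviations and
#' anchored so the trend is zero at the reference year.
#'
#' @param ebvs EBV tibble from [solve_blup()] (needs `birth_year`).
#' @param sigma_g genetic standard deviation used for scaling.
#' @param ref_year anchor year whose mean EBV defines zero.
#' @param trait EBV column; defaults to the first `ebv_` column.
#' @return tibble with `birth_year`, `n`, `mean_ebv` and `trend` (in
#'   sigma_g units, zero at `ref_year`).
#' @export
genetic_trend <- function(ebvs, sigma_g, ref_year = 2010L, trait = NULL) {
  stopifnot(sigma_g > 0, "birth_year" %in% names(ebvs))
  if (is.null(trait)) trait <- grep("^ebv_", names(ebvs), value = TRUE)[1]
  stopifnot(trait %in% names(ebvs))
  tb <- dplyr::summarise(
    dplyr::group_by(ebvs, .data$birth_year),
    n = dplyr::n(),
    mean_ebv = mean(.data[[trait]]),
    .groups = "drop")
  if (!ref_year %in% tb$birth_year) {
    stop("no animals born in reference year ", ref_year, call. = FALSE)
  }
  ref <- tb$mean_ebv[tb$birth_year == ref_year]
  tb$trend <- (tb$mean_ebv - ref) / sigma_g
  tb
}

#' @export
autoplot.reml_fit <- function(object, ...) {
  d <- tibble::tibble(iteration = seq_along(object$loglik_trace) - 1L,
                      loglik = object$loglik_trace)
  ggplot2::ggplot(d, ggplot2::aes(.data$iteration, .data$loglik)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "iteration", y = "restricted log-likelihood")
}

#' Plot a genetic trend
#'
#' @param trend tibble from [genetic_trend()].
#' @return a ggplot.
#' @export
plot_genetic_trend <- function(trend) {
  ggplot2::ggplot(trend, ggplot2::aes(.data$birth_year, .data$trend)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "birth year",
                  y = expression("mean EBV (" * sigma[G] * " units)"))
}
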