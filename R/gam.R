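#' Covariate panel
#'
#' A named covariate that is spatial-only (n x 1), temporal-only (1 x T) or
#' spatio-temporal (n x T); broadcastable to the full n x T layout of the
#' count panel.
#'
#' @param name covariate label, e.g. "upc", "cam", "cc", "par", "hos", "pob".
#' @param values numeric matrix (n x T, n x 1 or 1 x T) or vector.
#' @param kind one of "spatial", "temporal", "spatiotemporal"; inferred from
#'   the shape when missing.
#' @return object of class `covariate_panel`.
#' @export
covariate_panel <- function(name, values, kind = NULL) {
  if (!is.matrix(values)) values <- matrix(values, ncol = 1L)
  if (!all(is.finite(values))) stop("covariate values must be finite")
  if (is.null(kind)) {
    kind <- if (ncol(values) == 1L) "spatial"
            else if (nrow(values) == 1L) "temporal" else "spatiotemporal"
  }
  kind <- match.arg(kind, c("spatial", "temporal", "spatiotemporal"))
  structure(list(name = name, values = values, kind = kind),
            class = "covariate_panel")
}

# broadcast a covariate panel to n x T
broadcast_covariate <- function(cov, n, T_len) {
  v <- cov$values
  if (nrow(v) == n && ncol(v) == T_len) return(v)
  if (ncol(v) == 1L && nrow(v) == n) return(matrix(v, n, T_len))
  if (nrow(v) == 1L && ncol(v) == T_len) return(matrix(v, n, T_len, byrow = TRUE))
  stop(sprintf("covariate '%s' (%d x %d) not broadcastable to %d x %d",
               cov$name, nrow(v), ncol(v), n, T_len))
}

#' Cubic (or other degree) B-spline basis with quantile knots
#'
#' Cox-de Boor evaluation via [splines::splineDesign()]. Interior knots are
#' placed at quantiles of `x`; boundary knots just outside the data range so
#' the basis is a partition of unity on the whole observed range.
#'
#' @param x numeric vector of evaluation points.
#' @param num_basis number of basis functions k (>= degree + 1).
#' @param degree polynomial degree (default cubic).
#' @return object of class `spline_basis`: list with `B` (length(x) x k
#'   matrix), `knots` (full knot vector), `degree`, `range` (boundary).
#' @export
bspline_basis <- function(x, num_basis = 10L, degree = 3L) {
  stopifnot(all(is.finite(x)))
  if (num_basis < degree + 1L) stop("num_basis must be >= degree + 1")
  rng <- range(x)
  if (rng[1] == rng[2]) stop("constant covariate: degenerate knots")
  pad <- 1e-8 * diff(rng)
  n_int <- num_basis - degree - 1L
  interior <- if (n_int > 0L) {
    q <- stats::quantile(x, probs = seq_len(n_int) / (n_int + 1L), names = FALSE)
    # ties in x can collapse quantile knots; fall back to equal spacing
    if (anyDuplicated(q)) q <- rng[1] + diff(rng) * seq_len(n_int) / (n_int + 1L)
    q
  } else numeric(0)
  knots <- c(rep(rng[1] - pad, degree + 1L), interior, rep(rng[2] + pad, degree + 1L))
  B <- splines::splineDesign(knots, x, ord = degree + 1L)
  structure(list(B = B, knots = knots, degree = degree, range = rng),
            class = "spline_basis")
}

# evaluate an existing basis at new x, clamping out-of-range values
eval_basis <- function(basis, x) {
  lo <- basis$knots[1] + 1e-12
  hi <- basis$knots[length(basis$knots)] - 1e-12
  if (any(x < lo | x > hi))
    warning("covariate values outside the training range; clamped to boundary knots")
  x <- pmin(pmax(x, lo), hi)
  splines::splineDesign(basis$knots, x, ord = basis$degree + 1L)
}

#' Row-wise Kronecker product of two bases
#'
#' Builds the tensor-product surface basis: row i of the result is the
#' Kronecker product of row i of `B1` with row i of `B2`, giving an
#' I x (k1*k2) design for a smooth bivariate surface.
#'
#' @param B1,B2 matrices with the same number of rows.
#' @return I x (k1*k2) matrix.
#' @export
tensor_row_kronecker <- function(B1, B2) {
  B1 <- as.matrix(B1); B2 <- as.matrix(B2)
  if (nrow(B1) != nrow(B2)) stop("row-count mismatch")
  k1 <- ncol(B1); k2 <- ncol(B2)
  out <- matrix(0, nrow(B1), k1 * k2)
  for (j in seq_len(k1))
    out[, ((j - 1L) * k2 + 1L):(j * k2)] <- B1[, j] * B2
  out
}

#' Generalized cross-validation score
#'
#' GCV = n * RSS / (n - edf)^2, the leave-one-out surrogate used to select
#' smoothing parameters.
#'
#' @param rss residual sum of squares (>= 0).
#' @param n_obs number of observations.
#' @param edf effective degrees of freedom of the fit (0 <= edf < n_obs).
#' @return scalar score.
#' @export
gcv_score <- function(rss, n_obs, edf) {
  stopifnot(rss >= 0, edf >= 0)
  if (edf >= n_obs) stop("edf must be smaller than n_obs")
  n_obs * rss / (n_obs - edf)^2
}

# second-order difference penalty matrix D2'D2 for k coefficients
diff_penalty <- function(k, order = 2L) {
  D <- diag(k)
  for (i in seq_len(order)) D <- diff(D)
  crossprod(D)
}

# penalized IRLS for a Poisson/log-link additive model.
# Xd: design (first column intercept), P: penalty (already lambda-scaled),
# blocks: list of column index vectors per smooth term.
pirls <- function(y, Xd, P, maxit = 60L, tol = 1e-10) {
  n <- length(y)
  eta <- rep(log(mean(y) + 0.1), n)
  mu <- exp(eta)
  dev_old <- Inf
  beta <- NULL
  for (it in seq_len(maxit)) {
    w <- mu                       # Poisson working weights
    z <- eta + (y - mu) / mu      # working response
    XtW <- t(Xd * w)
    H <- XtW %*% Xd + P
    beta <- tryCatch(solve(H, XtW %*% z),
                     error = function(e) stop("rank-deficient penalized design: ", conditionMessage(e)))
    eta <- drop(Xd %*% beta)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
    if (is.finite(dev_old) && abs(dev_old - dev) < tol * (abs(dev) + 0.1)) break
    dev_old <- dev
  }
  XtWX <- t(Xd * mu) %*% Xd
  A <- solve(XtWX + P, XtWX)      # hat-like matrix in coefficient space
  edf_total <- sum(diag(A))
  # Pearson chi-square as the RSS entering GCV (weighted working residuals)
  rss <- sum((y - mu)^2 / mu)
  list(beta = drop(beta), eta = eta, mu = mu, edf_total = edf_total,
       edf_diag = diag(A), rss = rss, H_inv = solve(XtWX + P), XtWX = XtWX)
}

#' Fit the baseline log-intensity as a penalized additive model
#'
#' Fits g(E[Y]) = beta0 + sum_i f_i(x_i) with a log link, cubic B-spline
#' smooths (second-order difference penalty, P-spline style) and smoothing
#' parameters selected by minimizing GCV over a log-spaced grid via
#' coordinate descent. The fitted values on the log scale become the
#' covariate-driven baseline alpha_t of the count model (two-stage pipeline:
#' alpha first, then theta by MCMC conditional on alpha).
#'
#' With `smooth = FALSE` every covariate enters linearly (a single straight
#' line term), the comparison variant used to isolate the effect of spline
#' smoothing. With `select = TRUE`, terms whose approximate Wald p-value
#' exceeds `select_threshold` are dropped and the model refit (a mechanism
#' for covariate selection, not a claim about any particular dataset).
#'
#' @param response n x T matrix of counts (or positive reals).
#' @param covariates list of [covariate_panel()] objects (>= 1).
#' @param num_basis basis functions per smooth term.
#' @param degree spline degree (3 = cubic).
#' @param lambda_grid log-spaced candidate smoothing parameters.
#' @param smooth logical: spline smooths (TRUE) or linear terms (FALSE).
#' @param select logical: drop non-significant terms and refit.
#' @param select_threshold p-value threshold for dropping a term.
#' @return object of class `spingarch_gam`: `beta0`, `terms` (per-covariate
#'   basis, coefficients, lambda, edf, p-value), `fitted_alpha` (n x T, log
#'   scale), `gcv`, `edf`, `link = "log"`.
#' @export
fit_alpha_gam <- function(response, covariates, num_basis = 10L, degree = 3L,
                          lambda_grid = 10^seq(-4, 6, length.out = 11),
                          smooth = TRUE, select = FALSE,
                          select_threshold = 0.05) {
  stopifnot(is.matrix(response), length(covariates) >= 1L)
  n <- nrow(response); T_len <- ncol(response)
  y <- as.vector(response)
  if (any(!is.finite(y)) || any(y < 0)) stop("response must be finite and non-negative")

  build_design <- function(covs) {
    bases <- list(); blocks <- list()
    cols <- list(rep(1, length(y)))
    pen_blocks <- list()
    pos <- 2L
    for (cv in covs) {
      xv <- as.vector(broadcast_covariate(cv, n, T_len))
      if (!all(is.finite(xv))) stop("non-finite covariate: ", cv$name)
      if (smooth) {
        bs <- bspline_basis(xv, num_basis = num_basis, degree = degree)
        Bc <- sweep(bs$B, 2L, colMeans(bs$B))   # center for identifiability
        k <- ncol(Bc)
        bases[[cv$name]] <- list(basis = bs, centers = colMeans(bs$B),
                                 type = "spline")
        cols[[length(cols) + 1L]] <- Bc
        blocks[[cv$name]] <- pos:(pos + k - 1L)
        pen_blocks[[cv$name]] <- diff_penalty(k)
        pos <- pos + k
      } else {
        xc <- xv - mean(xv)
        bases[[cv$name]] <- list(center = mean(xv), type = "linear")
        cols[[length(cols) + 1L]] <- matrix(xc, ncol = 1L)
        blocks[[cv$name]] <- pos
        pen_blocks[[cv$name]] <- matrix(0, 1, 1)
        pos <- pos + 1L
      }
    }
    Xd <- do.call(cbind, cols)
    list(Xd = Xd, blocks = blocks, pen = pen_blocks, bases = bases)
  }

  fit_once <- function(covs) {
    d <- build_design(covs)
    p <- ncol(d$Xd)
    nm <- names(d$blocks)
    lam <- stats::setNames(rep(1, length(nm)), nm)
    assemble_P <- function(lam) {
      P <- matrix(0, p, p)
      for (nmi in nm) {
        idx <- d$blocks[[nmi]]
        P[idx, idx] <- lam[[nmi]] * d$pen[[nmi]]
        # fixed small ridge: centering makes the constant coefficient
        # vector a null direction of both the design and the difference
        # penalty, so the system is singular without it
        if (length(idx) > 1L)
          P[idx, idx] <- P[idx, idx] + diag(1e-6, length(idx))
      }
      P
    }
    best <- NULL
    if (smooth && length(lambda_grid) > 1L) {
      for (pass in 1:2) {
        for (nmi in nm) {
          scores <- vapply(lambda_grid, function(lv) {
            lam2 <- lam; lam2[[nmi]] <- lv
            f <- pirls(y, d$Xd, assemble_P(lam2))
            gcv_score(f$rss, length(y), f$edf_total)
          }, numeric(1))
          lam[[nmi]] <- lambda_grid[which.min(scores)]
        }
      }
    }
    f <- pirls(y, d$Xd, assemble_P(lam))
    gcv <- gcv_score(f$rss, length(y), f$edf_total)
    # per-term edf and approximate Wald significance
    terms <- list()
    Vb <- f$H_inv %*% f$XtWX %*% f$H_inv   # sandwich-style approx covariance
    for (nmi in nm) {
      idx <- d$blocks[[nmi]]
      bt <- f$beta[idx]
      edf_t <- sum(f$edf_diag[idx])
      Vt <- Vb[idx, idx, drop = FALSE]
      stat <- tryCatch(
        drop(t(bt) %*% solve(Vt + diag(1e-10, length(idx)), bt)),
        error = function(e) NA_real_)
      df_t <- max(edf_t, 1)
      pval <- if (is.na(stat)) NA_real_ else stats::pchisq(stat, df = df_t, lower.tail = FALSE)
      terms[[nmi]] <- list(coef = bt, lambda = unname(lam[[nmi]]), edf = edf_t,
                           p_value = pval, info = d$bases[[nmi]])
    }
    structure(list(beta0 = f$beta[1], terms = terms,
                   fitted_alpha = matrix(f$eta, n, T_len),
                   gcv = gcv, edf = f$edf_total, link = "log",
                   smooth = smooth, n = n, T_len = T_len),
              class = "spingarch_gam")
  }

  fit <- fit_once(covariates)
  if (select) {
    repeat {
      pv <- vapply(fit$terms, function(tr) tr$p_value, numeric(1))
      drop_nm <- names(which.max(pv))
      if (length(fit$terms) <= 1L || all(pv <= select_threshold, na.rm = TRUE)) break
      covariates <- Filter(function(cv) cv$name != drop_nm, covariates)
      fit <- fit_once(covariates)
    }
  }
  fit
}

#' @export
print.spingarch_gam <- function(x, ...) {
  cat(sprintf("Penalized additive baseline fit (log link): beta0=%.3f, total edf=%.2f, GCV=%.4g\n",
              x$beta0, x$edf, x$gcv))
  for (nm in names(x$terms)) {
    tr <- x$terms[[nm]]
    cat(sprintf("  %-6s lambda=%-8.3g edf=%5.2f p=%.3g\n",
                nm, tr$lambda, tr$edf, tr$p_value))
  }
  invisible(x)
}

#' Evaluate a fitted additive baseline on covariates
#'
#' Reconstructs beta0 + sum_i f_i(x_i) on new (or the training) covariate
#' panels. Values outside the training range are clamped to the boundary
#' knots with a warning.
#'
#' @param fit a [fit_alpha_gam()] object.
#' @param covariates list of [covariate_panel()] with names matching the fit.
#' @param n,T_len output layout; defaults to the training layout.
#' @return n x T baseline panel on the log scale.
#' @export
predict_alpha <- function(fit, covariates, n = fit$n, T_len = fit$T_len) {
  names(covariates) <- vapply(covariates, function(cv) cv$name, character(1))
  eta <- matrix(fit$beta0, n, T_len)
  for (nm in names(fit$terms)) {
    if (!nm %in% names(covariates)) stop("missing covariate: ", nm)
    xv <- as.vector(broadcast_covariate(covariates[[nm]], n, T_len))
    tr <- fit$terms[[nm]]
    contrib <- if (tr$info$type == "spline") {
      Bn <- eval_basis(tr$info$basis, xv)
      Bn <- sweep(Bn, 2L, tr$info$centers)
      drop(Bn %*% tr$coef)
    } else {
      (xv - tr$info$center) * tr$coef
    }
    eta <- eta + matrix(contrib, n, T_len)
  }
  eta
}
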