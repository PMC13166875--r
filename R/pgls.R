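#' Phylogenetic generalized least squares
#'
#' Regression of gene-family counts on a species trait accounting for
#' phylogenetic non-independence through the Brownian covariance
#' `V[i, j] =` shared root-to-LCA path length between species i and j.
#' Off-diagonal entries can be scaled by Pagel's lambda, either fixed or
#' estimated by maximizing the restricted (REML) log-likelihood on
#' `[0, 1]`. Estimates are the GLS closed form
#' `(X' V^-1 X)^-1 X' V^-1 y` with a t-test on the slope at `n - 2`
#' degrees of freedom. With `lambda = 0` on an ultrametric tree (or a
#' star phylogeny) the fit reduces to ordinary least squares.
#'
#' @param tree species `ortree`; leaves not present in both `x` and `y`
#'   are pruned.
#' @param x named trait vector (species labels as names).
#' @param y named response vector (e.g. gene counts per species).
#' @param lambda_mode `"fixed"` or `"ML"`.
#' @param lambda the fixed lambda value (default 1 = pure Brownian);
#'   ignored under ML.
#' @return a `pgls_fit`: list with `coefficients` (intercept, slope),
#'   `se`, `t`, `p_value`, `df`, `sigma2`, `lambda`, `logLik_reml`, `n`.
#' @export
pgls_fit <- function(tree, x, y, lambda_mode = c("fixed", "ML"), lambda = 1) {
  lambda_mode <- match.arg(lambda_mode)
  sp <- intersect(names(x)[!is.na(x)], names(y)[!is.na(y)])
  sp <- intersect(sp, tree$label[tree$is_leaf])
  n <- length(sp)
  if (n < 4) stop("PGLS needs >= 4 species shared by tree, x and y")
  if (any(tree$length < 0)) stop("negative branch lengths")
  phy <- as_phylo(tree)
  drop <- setdiff(phy$tip.label, sp)
  if (length(drop) > 0) phy <- ape::drop.tip(phy, drop)
  V0 <- ape::vcv(phy)[sp, sp]
  X <- cbind(`(Intercept)` = 1, slope = as.numeric(x[sp]))
  yv <- as.numeric(y[sp])
  V_of <- function(lam) {
    V <- lam * V0
    diag(V) <- diag(V0)
    V
  }
  gls_core <- function(lam) {
    V <- V_of(lam)
    L <- tryCatch(chol(V), error = function(e)
      stop("rank error: singular phylogenetic covariance"))
    Xs <- backsolve(L, X, transpose = TRUE)
    ys <- backsolve(L, yv, transpose = TRUE)
    XtX <- crossprod(Xs)
    if (rcond(XtX) < 1e-12) stop("rank error: singular design matrix")
    beta <- solve(XtX, crossprod(Xs, ys))
    r <- ys - Xs %*% beta
    list(beta = beta, rss = sum(r^2), XtX = XtX, logdetV = 2 * sum(log(diag(L))))
  }
  reml_ll <- function(lam) {
    g <- gls_core(lam)
    p <- ncol(X)
    s2 <- g$rss / (n - p)
    -0.5 * ((n - p) * log(2 * pi * s2) + g$logdetV +
              determinant(g$XtX, logarithm = TRUE)$modulus[1] + (n - p))
  }
  if (lambda_mode == "ML") {
    opt <- stats::optimize(reml_ll, c(0, 1), maximum = TRUE, tol = 1e-8)
    # compare against the boundaries, optimize() can miss them
    cand <- c(0, opt$maximum, 1)
    ll <- vapply(cand, reml_ll, numeric(1))
    lambda <- cand[which.max(ll)]
  }
  g <- gls_core(lambda)
  df <- n - ncol(X)
  sigma2 <- g$rss / df
  vcov_beta <- sigma2 * solve(g$XtX)
  se <- sqrt(diag(vcov_beta))
  tstat <- as.numeric(g$beta) / se
  pv <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  structure(list(coefficients = stats::setNames(as.numeric(g$beta),
                                                colnames(X)),
                 se = se, t = tstat, p_value = pv, df = df,
                 sigma2 = sigma2, lambda = lambda,
                 logLik_reml = reml_ll(lambda), n = n),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("<pgls> n=%d lambda=%.3f slope=%.4g (se %.3g) t=%.3f p=%.4g\n",
              x$n, x$lambda, x$coefficients[2], x$se[2], x$t[2],
              x$p_value[2]))
  invisible(x)
}

#' PGLS screen of every gene family against one trait
#'
#' Fits [pgls_fit()] per family column, then corrects slope p-values
#' across families with Benjamini-Hochberg. Mostly-single-copy families
#' should be removed first with [filter_families()].
#'
#' @param tree species `ortree`.
#' @param trait named trait vector.
#' @param counts species x family count matrix (rownames = species).
#' @param ... passed to [pgls_fit()].
#' @return data.frame: family, slope, se, t, p_value, lambda, q_value.
#' @export
pgls_screen <- function(tree, trait, counts, ...) {
  m <- as.matrix(counts)
  fams <- colnames(m)
  rows <- lapply(fams, function(f) {
    y <- stats::setNames(m[, f], rownames(m))
    fit <- pgls_fit(tree, trait, y, ...)
    data.frame(family = f, slope = fit$coefficients[2], se = fit$se[2],
               t = fit$t[2], p_value = fit$p_value[2], lambda = fit$lambda,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q_value <- bh_correct(out$p_value)
  out
}
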