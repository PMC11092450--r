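#' Dirichlet-multinomial log-likelihood
#'
#' For a cells-by-isoforms count matrix X with per-cell totals n_c, the
#' model is X_c ~ Multinomial(n_c, pi_c) with pi_c ~ Dirichlet(alpha). The
#' marginal log-likelihood is
#' sum_c \[ lgamma(S) - lgamma(n_c + S) + sum_k (lgamma(X_ck + alpha_k) -
#' lgamma(alpha_k)) \] with S = sum(alpha). The multinomial coefficient is
#' constant in alpha and omitted.
#'
#' @param X Numeric matrix, cells x isoforms, non-negative counts.
#' @param alpha Positive concentration vector of length `ncol(X)`.
#' @return Scalar log-likelihood.
#' @export
dm_loglik <- function(X, alpha) {
  X <- as.matrix(X)
  stopifnot(length(alpha) == ncol(X))
  if (any(!is.finite(alpha)) || any(alpha <= 0)) return(-Inf)
  n <- rowSums(X)
  S <- sum(alpha)
  sum(lgamma(S) - lgamma(n + S)) +
    sum(sweep(lgamma(sweep(X, 2, alpha, "+")), 2, lgamma(alpha), "-"))
}

#' Fit the Dirichlet-multinomial model for one gene
#'
#' Maximum-likelihood estimation of the concentration vector alpha by
#' quasi-Newton optimization in log-alpha space (which keeps alpha
#' positive and the likelihood smooth), started from a moment-based
#' initialization. Reported alongside alpha are the population-average
#' transcript usage pi_bar_k = alpha_k / sum(alpha) and the mean-invariant
#' over-dispersion phi = 1 / (1 + sum(alpha)): small phi means cells
#' co-express isoforms at similar proportions, large phi means each cell
#' tends to commit to one isoform.
#'
#' @param X Cells x isoforms count matrix (at least 2 isoform columns and
#'   2 cells with positive totals).
#' @param maxit Maximum optimizer iterations (default 500).
#' @param reltol Relative convergence tolerance (default 1e-10).
#' @param init Optional starting alpha (defaults to a moment-based start).
#' @return A `dm_fit` object: list with `alpha`, `pi_bar`, `phi`, `loglik`,
#'   `converged`, `boundary` (TRUE when some alpha hit the lower clip of
#'   1e-8) and `n_cells`.
#' @examples
#' X <- t(rmultinom(50, 20, c(0.6, 0.4)))
#' fit <- fit_dm(X)
#' tidy(fit)
#' glance(fit)
#' @export
fit_dm <- function(X, maxit = 500L, reltol = 1e-10, init = NULL) {
  X <- as.matrix(X)
  X <- X[rowSums(X) > 0, , drop = FALSE]
  if (ncol(X) < 2L) abort("need at least 2 isoform columns")
  if (nrow(X) < 2L) abort("need at least 2 cells with nonzero counts")
  if (all(X == 0)) abort("degenerate all-zero data")

  alpha0 <- init %||% dm_moment_init(X)
  obj <- function(la) safe_negll(dm_loglik(X, exp(la)))
  opt <- stats::optim(log(pmin(pmax(alpha0, 1e-6), 1e4)), obj,
                      method = "L-BFGS-B",
                      lower = log(1e-8), upper = log(1e4),
                      control = list(maxit = maxit, factr = 1e3))
  # polish with a second pass in case the first stopped early
  opt2 <- stats::optim(opt$par, obj, method = "L-BFGS-B",
                       lower = log(1e-8), upper = log(1e4),
                       control = list(maxit = maxit, factr = 1e3))
  if (opt2$value < opt$value) opt <- opt2
  alpha <- pmax(exp(opt$par), 1e-8)
  new_dm_fit(alpha, loglik = -opt$value, converged = opt$convergence == 0L,
             boundary = any(exp(opt$par) < 1e-8), n_cells = nrow(X),
             names = colnames(X))
}

new_dm_fit <- function(alpha, loglik, converged, boundary, n_cells,
                       names = NULL) {
  if (!is.null(names)) names(alpha) <- names
  structure(
    list(alpha = alpha, pi_bar = alpha / sum(alpha),
         phi = 1 / (1 + sum(alpha)), loglik = loglik,
         converged = converged, boundary = boundary, n_cells = n_cells),
    class = "dm_fit")
}

# moment-based starting point: pi_hat from pooled proportions, scale from
# the method-of-moments over-dispersion of per-cell proportions
dm_moment_init <- function(X) {
  n <- rowSums(X)
  p_pool <- pmax(colSums(X) / sum(X), 1e-6)
  p_pool <- p_pool / sum(p_pool)
  P <- X / n
  v <- apply(P, 2, stats::var)
  ev <- p_pool * (1 - p_pool)
  # var(p_ck) ~ pi(1-pi) * (1/n + phi) roughly; solve for S = 1/phi - 1
  phi_hat <- stats::median(pmax(v / pmax(ev, 1e-8) - mean(1 / pmax(n, 1)), 1e-3),
                           na.rm = TRUE)
  phi_hat <- min(max(phi_hat, 1e-3), 0.9)
  S <- 1 / phi_hat - 1
  pmax(p_pool * S, 1e-4)
}

#' @export
print.dm_fit <- function(x, ...) {
  cat(sprintf("<dm_fit> K = %d, cells = %d, phi = %.4f, loglik = %.2f%s\n",
              length(x$alpha), x$n_cells, x$phi, x$loglik,
              if (!x$converged) " (not converged)" else ""))
  print(round(x$pi_bar, 4))
  invisible(x)
}

#' Tidy a Dirichlet-multinomial fit
#'
#' @param x A `dm_fit`.
#' @param ... Unused.
#' @return Tibble with one row per isoform: `isoform`, `alpha`, `pi_bar`.
#' @export
tidy.dm_fit <- function(x, ...) {
  tibble::tibble(
    isoform = names(x$alpha) %||% as.character(seq_along(x$alpha)),
    alpha = unname(x$alpha), pi_bar = unname(x$pi_bar))
}

#' One-row summary of a Dirichlet-multinomial fit
#'
#' @param x A `dm_fit`.
#' @param ... Unused.
#' @return Tibble with `phi`, `loglik`, `n_cells`, `K`, `converged`.
#' @export
glance.dm_fit <- function(x, ...) {
  tibble::tibble(phi = x$phi, loglik = x$loglik, n_cells = x$n_cells,
                 K = length(x$alpha), converged = x$converged)
}

# finite, bounded negative log-likelihood for the optimizer
safe_negll <- function(ll) {
  if (!is.finite(ll)) return(1e10)
  min(-ll, 1e10)
}

# box bounds for the constrained fits: logits within +/-25, total
# concentration S within [1e-4, 1e4]. Above ~1e4 the lgamma(S) -
# lgamma(n + S) difference loses precision, and such fits are
# indistinguishable from a plain multinomial anyway.
shared_bounds <- function(n_logit) {
  list(lower = c(rep(-25, n_logit), log(1e-4), log(1e-4)),
       upper = c(rep(25, n_logit), log(1e4), log(1e4)))
}

# --- constrained fits used by the likelihood-ratio tests ---------------------

# H0 of the gene-level test: both groups share pi_bar, each keeps its own
# over-dispersion phi_g (alpha_g = pi_bar * (1/phi_g - 1)).
fit_dm_shared_pi <- function(XA, XB, maxit = 500L, reltol = 1e-10) {
  K <- ncol(XA)
  stopifnot(ncol(XB) == K, K >= 2)
  XA <- XA[rowSums(XA) > 0, , drop = FALSE]
  XB <- XB[rowSums(XB) > 0, , drop = FALSE]
  p0 <- pmax(colSums(XA) + colSums(XB), 0.5)
  p0 <- p0 / sum(p0)
  par0 <- c(log(p0[-K] / p0[K]), 0, 0)  # K-1 logits + log S_A + log S_B
  unpack <- function(par) {
    z <- c(par[seq_len(K - 1)], 0)
    p <- exp(z - max(z)); p <- p / sum(p)
    list(p = p, SA = exp(par[K]), SB = exp(par[K + 1]))
  }
  obj <- function(par) {
    u <- unpack(par)
    safe_negll(dm_loglik(XA, pmax(u$p * u$SA, 1e-10)) +
                 dm_loglik(XB, pmax(u$p * u$SB, 1e-10)))
  }
  bounds <- shared_bounds(K - 1L)
  opt <- stats::optim(par0, obj, method = "L-BFGS-B",
                      lower = bounds$lower, upper = bounds$upper,
                      control = list(maxit = maxit, factr = 1e3))
  opt2 <- stats::optim(opt$par, obj, method = "L-BFGS-B",
                       lower = bounds$lower, upper = bounds$upper,
                       control = list(maxit = maxit, factr = 1e3))
  if (opt2$value < opt$value) opt <- opt2
  u <- unpack(opt$par)
  list(pi_bar = u$p, phi_A = 1 / (1 + u$SA), phi_B = 1 / (1 + u$SB),
       loglik = -opt$value, converged = opt$convergence == 0L)
}

# H0 of the transcript-level test for isoform k: pi_bar_k equal across
# groups; the composition of the remaining isoforms stays free per group,
# as does each group's over-dispersion.
fit_dm_shared_component <- function(XA, XB, k, maxit = 500L, reltol = 1e-10) {
  K <- ncol(XA)
  stopifnot(ncol(XB) == K, K >= 2, k >= 1, k <= K)
  XA <- XA[rowSums(XA) > 0, , drop = FALSE]
  XB <- XB[rowSums(XB) > 0, , drop = FALSE]
  rest <- setdiff(seq_len(K), k)
  pool <- pmax(colSums(XA) + colSums(XB), 0.5)
  pk0 <- pool[k] / sum(pool)
  restA <- pmax(colSums(XA)[rest], 0.5); restA <- restA / sum(restA)
  restB <- pmax(colSums(XB)[rest], 0.5); restB <- restB / sum(restB)
  r <- K - 1L  # size of the free composition per group
  par0 <- c(stats::qlogis(min(max(pk0, 1e-4), 1 - 1e-4)),
            if (r > 1) log(restA[-r] / restA[r]) else numeric(0),
            if (r > 1) log(restB[-r] / restB[r]) else numeric(0),
            0, 0)
  softmax <- function(z) { z <- c(z, 0); e <- exp(z - max(z)); e / sum(e) }
  unpack <- function(par) {
    pk <- stats::plogis(par[1])
    i <- 2L
    qA <- if (r > 1) softmax(par[i:(i + r - 2L)]) else 1
    i <- i + max(r - 1L, 0L)
    qB <- if (r > 1) softmax(par[i:(i + r - 2L)]) else 1
    i <- i + max(r - 1L, 0L)
    pA <- pB <- numeric(K)
    pA[k] <- pB[k] <- pk
    pA[rest] <- (1 - pk) * qA
    pB[rest] <- (1 - pk) * qB
    list(pA = pA, pB = pB, SA = exp(par[i]), SB = exp(par[i + 1L]))
  }
  obj <- function(par) {
    u <- unpack(par)
    safe_negll(dm_loglik(XA, pmax(u$pA * u$SA, 1e-10)) +
                 dm_loglik(XB, pmax(u$pB * u$SB, 1e-10)))
  }
  n_logit <- 1L + 2L * max(r - 1L, 0L)
  bounds <- shared_bounds(n_logit)
  opt <- stats::optim(par0, obj, method = "L-BFGS-B",
                      lower = bounds$lower, upper = bounds$upper,
                      control = list(maxit = maxit, factr = 1e3))
  opt2 <- stats::optim(opt$par, obj, method = "L-BFGS-B",
                       lower = bounds$lower, upper = bounds$upper,
                       control = list(maxit = maxit, factr = 1e3))
  if (opt2$value < opt$value) opt <- opt2
  u <- unpack(opt$par)
  list(pi_A = u$pA, pi_B = u$pB, phi_A = 1 / (1 + u$SA),
       phi_B = 1 / (1 + u$SB), loglik = -opt$value,
       converged = opt$convergence == 0L)
}
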