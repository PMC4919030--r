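#' The LG+Gamma amino-acid rate model
#'
#' Builds the Le-Gascuel (LG) general time-reversible rate matrix from the
#' packaged plain-text exchangeabilities and equilibrium frequencies, scaled
#' so that the expected substitution rate at equilibrium is 1, together with
#' a discrete-gamma model of among-site rate variation.
#'
#' The eigendecomposition of the symmetrized generator is precomputed so
#' that transition matrices `P(t) = exp(Qt)` are exact (to floating point)
#' for any branch length.
#'
#' @param gamma_shape gamma shape parameter alpha (> 0); the survey's trees
#'   used 1.224 and 1.151.
#' @param n_categories number of equal-probability rate categories
#'   (default 6, the survey's setting).
#' @param frequencies optional length-20 replacement for the LG equilibrium
#'   frequencies (e.g. empirical "+F" frequencies); must sum to 1.
#' @return object of class `rate_model`: list with `name`, `Q` (20 x 20, rows
#'   sum to 0), `frequencies`, `gamma_shape`, `n_categories`,
#'   `category_rates`, `category_weights`, and the eigensystem used by
#'   [transition_matrix()].
#' @examples
#' m <- lg_model(gamma_shape = 1.151)
#' rowSums(transition_matrix(m, 0.5)) # all 1
#' @export
lg_model <- function(gamma_shape = 1.0, n_categories = 6L,
                     frequencies = NULL) {
  path <- system.file("extdata", "lg_model.txt", package = "hrsurvey")
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  iex <- which(lines == "EXCHANGEABILITIES")
  ifr <- which(lines == "FREQUENCIES")
  ex <- as.numeric(lines[(iex + 1):(ifr - 1)])
  bf <- as.numeric(lines[(ifr + 1):length(lines)])
  stopifnot(length(ex) == 190L, length(bf) == 20L)
  if (!is.null(frequencies)) {
    stopifnot(length(frequencies) == 20L,
              isTRUE(all.equal(sum(frequencies), 1)))
    bf <- as.numeric(frequencies)
  }
  bf <- bf / sum(bf)
  S <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  S[lower.tri(S)] <- ex  # column-major lower-triangle order
  S <- S + t(S)
  Q <- S * rep(bf, each = 20)     # q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  scale <- -sum(bf * diag(Q))     # mean rate at equilibrium
  Q <- Q / scale
  # symmetric eigendecomposition of B = diag(sqrt(pi)) Q diag(1/sqrt(pi))
  sp <- sqrt(bf)
  B <- (sp %o% (1 / sp)) * Q
  B <- (B + t(B)) / 2             # symmetrize against rounding
  eig <- eigen(B, symmetric = TRUE)
  gm <- discretize_gamma(gamma_shape, n_categories)
  structure(list(name = "LG", Q = Q, frequencies = setNames(bf, AA20),
                 gamma_shape = gamma_shape,
                 n_categories = as.integer(n_categories),
                 category_rates = gm$rates, category_weights = gm$weights,
                 eig_values = eig$values,
                 eig_right = (1 / sp) * eig$vectors,     # diag(1/sp) %*% V
                 eig_left = t(sp * eig$vectors)),        # t(V) %*% diag(sp)
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("%s+G rate model: alpha %.4g, %d categories\n",
              x$name, x$gamma_shape, x$n_categories))
  invisible(x)
}

#' Transition probability matrix under a rate model
#'
#' `P(t) = exp(Q t r)` computed from the precomputed eigendecomposition.
#'
#' @param model a [lg_model()].
#' @param t branch length (expected substitutions per site, >= 0).
#' @param rate site-rate multiplier (e.g. a gamma category rate).
#' @return 20 x 20 stochastic matrix.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  if (t < 0) stop("negative branch length", call. = FALSE)
  P <- model$eig_right %*% (exp(model$eig_values * t * rate) * model$eig_left)
  P[P < 0] <- 0                       # clip tiny negative round-off
  P <- P / rowSums(P)
  dimnames(P) <- list(AA20, AA20)
  P
}

#' Discrete-gamma rate categories
#'
#' Equal-probability categories with the category rate equal to the mean of
#' its quantile slice of a Gamma(shape = alpha, rate = alpha) distribution
#' (mean 1), computed in closed form via the incomplete-gamma identity, so
#' the weighted mean rate is exactly 1.
#'
#' @param alpha gamma shape parameter (> 0).
#' @param n_categories number of categories (>= 1).
#' @return list with `rates` and `weights` (each length `n_categories`).
#' @export
discretize_gamma <- function(alpha, n_categories = 6L) {
  if (!is.finite(alpha) || alpha <= 0)
    stop("gamma shape alpha must be > 0", call. = FALSE)
  k <- as.integer(n_categories)
  if (k < 1L) stop("n_categories must be >= 1", call. = FALSE)
  if (k == 1L) return(list(rates = 1, weights = 1))
  q <- qgamma((0:k) / k, shape = alpha, rate = alpha)
  # E[X; X in (l, u)] = F_{alpha+1}(u) - F_{alpha+1}(l) for X ~ Gamma(a, a)
  m <- pgamma(q, shape = alpha + 1, rate = alpha)
  rates <- k * diff(m)
  rates <- rates / sum(rates / k)     # exact mean 1 against tail rounding
  list(rates = rates, weights = rep(1 / k, k))
}
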