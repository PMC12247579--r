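#' Matern (order 3/2) covariance matrix over weight positions
#'
#' Builds the fixed within-group correlation matrix used to encourage smooth
#' weight profiles: entry (k, i) is \code{(1 + sqrt(3) d / h) exp(-sqrt(3) d / h)}
#' with \code{d = |k - i|}. Large length scales \code{h} couple neighbouring
#' weights strongly (approaching an all-ones matrix); \code{h -> 0} recovers
#' the identity, i.e. no smoothness assumption.
#'
#' @param size Number of weights in the group (matrix dimension).
#' @param h Positive length scale, in units of weight index spacing.
#' @return A \code{size} x \code{size} symmetric matrix with unit diagonal.
#' @examples
#' matern_covariance(4, h = 2)
#' @export
matern_covariance <- function(size, h) {
  size <- as.integer(size)
  if (size < 1L) stop("'size' must be >= 1", call. = FALSE)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("'h' must be a positive finite scalar", call. = FALSE)
  d <- abs(outer(seq_len(size), seq_len(size), "-"))
  r <- sqrt(3) * d / h
  (1 + r) * exp(-r)
}

# Cholesky with escalating jitter: near-singular smoothness matrices (large h)
# need a small diagonal boost before factorization. Jitter starts at
# 1e-10 * mean(diag) and escalates tenfold up to 1e-6 * mean(diag).
chol_jitter <- function(A, label = "matrix") {
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(R)) return(list(R = R, jitter = 0))
  base <- mean(diag(A))
  for (eps in base * 10^seq(-10, -6)) {
    R <- tryCatch(chol(A + diag(eps, nrow(A))), error = function(e) NULL)
    if (!is.null(R)) return(list(R = R, jitter = eps))
  }
  stop(sprintf("%s is not positive-definite even after jitter", label),
       call. = FALSE)
}

#' Inverse-Gamma hyperprior settings
#'
#' The group shrinkage scales lambda_j and the residual variance nu carry
#' Inverse-Gamma hyperpriors: shape \code{eta} and scale \code{tau} for each
#' lambda_j, shape \code{phi} and scale \code{kappa} for nu. Passing
#' \code{gamma} sets all four to one value — the usual simplification; small
#' gamma (for example 1e-4) gives broad hyperpriors that permit aggressive
#' shrinkage of irrelevant groups.
#'
#' @param eta,tau Shape and scale of the lambda prior.
#' @param phi,kappa Shape and scale of the nu prior.
#' @param gamma Optional convenience scalar; when supplied it overrides the
#'   other four.
#' @return An object of class \code{hyperpriors}.
#' @examples
#' hyperpriors(gamma = 1e-4)
#' hyperpriors(eta = 1, tau = 2, phi = 1, kappa = 1)
#' @export
hyperpriors <- function(eta = 1e-4, tau = 1e-4, phi = 1e-4, kappa = 1e-4,
                        gamma = NULL) {
  if (!is.null(gamma)) {
    stopifnot(is.numeric(gamma), length(gamma) == 1L)
    eta <- tau <- phi <- kappa <- gamma
  }
  vals <- c(eta = eta, tau = tau, phi = phi, kappa = kappa)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("hyperprior parameters must be strictly positive", call. = FALSE)
  structure(as.list(vals), class = "hyperpriors")
}

#' @export
print.hyperpriors <- function(x, ...) {
  cat(sprintf("hyperpriors: eta=%g tau=%g phi=%g kappa=%g\n",
              x$eta, x$tau, x$phi, x$kappa))
  invisible(x)
}

# log-density of Inverse-Gamma(shape a, scale b) at x
dinvgamma_log <- function(x, a, b) a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x

#' Group-wise prior state
#'
#' Packages the per-group shrinkage scales lambda_j together with the fixed
#' within-group smoothness matrices Omega_j, forming the block-diagonal weight
#' prior covariance Lambda with blocks \code{lambda_j * Omega_j}. Groups
#' without a length scale in \code{h} use the identity for Omega_j.
#'
#' @param design A \code{grouped_design}.
#' @param lambdas Positive scalar (recycled) or length-J vector of scales.
#' @param h Optional named numeric vector of Matern length scales; names must
#'   match group names. Unnamed scalar applies to every group.
#' @return An object of class \code{prior_state} holding \code{lambdas},
#'   \code{omegas}, their inverses and log-determinants.
#' @export
prior_state <- function(design, lambdas = 1, h = NULL) {
  stopifnot(inherits(design, "grouped_design"))
  J <- nrow(design$groups)
  lambdas <- as.numeric(lambdas)
  if (length(lambdas) == 1L) lambdas <- rep(lambdas, J)
  if (length(lambdas) != J || any(!is.finite(lambdas)) || any(lambdas <= 0))
    stop("'lambdas' must be J positive scalars", call. = FALSE)
  omegas <- build_omegas(design, h)
  pre <- precompute_omegas(omegas)
  structure(list(lambdas = stats::setNames(lambdas, design$groups$name),
                 omegas = omegas, omega_inv = pre$inv,
                 omega_logdet = pre$logdet, identity = pre$identity),
            class = "prior_state")
}

# Per-group Omega matrices from a smoothness spec (NULL / scalar / named vector)
build_omegas <- function(design, h = NULL) {
  J <- nrow(design$groups)
  sizes <- design$groups$size
  nms <- design$groups$name
  hs <- rep(NA_real_, J)
  if (!is.null(h)) {
    h <- unlist(h)
    if (is.null(names(h)) || all(names(h) == "")) {
      if (length(h) == 1L) hs[] <- h
      else if (length(h) == J) hs <- as.numeric(h)
      else stop("'h' must be a scalar, length-J, or named vector", call. = FALSE)
    } else {
      idx <- match(names(h), nms)
      if (anyNA(idx))
        stop(sprintf("unknown group in smoothness spec: %s",
                     paste(names(h)[is.na(idx)], collapse = ", ")), call. = FALSE)
      hs[idx] <- as.numeric(h)
    }
    if (any(!is.na(hs) & hs <= 0))
      stop("Matern length scales must be positive", call. = FALSE)
  }
  omegas <- vector("list", J)
  for (j in seq_len(J)) {
    omegas[[j]] <- if (is.na(hs[j])) diag(1, sizes[j])
                   else matern_covariance(sizes[j], hs[j])
  }
  names(omegas) <- nms
  omegas
}

precompute_omegas <- function(omegas) {
  J <- length(omegas)
  inv <- vector("list", J); logdet <- numeric(J); ident <- logical(J)
  for (j in seq_len(J)) {
    Om <- omegas[[j]]
    if (all(Om == diag(1, nrow(Om)))) {
      inv[[j]] <- Om; logdet[j] <- 0; ident[j] <- TRUE
    } else {
      f <- chol_jitter(Om, label = sprintf("Omega[%d]", j))
      inv[[j]] <- chol2inv(f$R)
      logdet[j] <- 2 * sum(log(diag(f$R)))
      ident[j] <- FALSE
    }
  }
  list(inv = inv, logdet = logdet, identity = ident)
}

# Dense D x D Lambda (block-diagonal lambda_j Omega_j); small problems only.
lambda_matrix <- function(design, prior) {
  D <- design$D
  Lam <- matrix(0, D, D)
  for (j in seq_len(nrow(design$groups))) {
    idx <- group_columns(design, j)
    Lam[idx, idx] <- prior$lambdas[j] * prior$omegas[[j]]
  }
  Lam
}
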