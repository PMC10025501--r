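#' Item parameter container for the three-node MPP model
#'
#' Bundles per-node, per-item 2PL parameters: discriminations \code{alpha},
#' difficulties \code{b} on the trait scale, and intercepts \code{d} on the
#' log-odds scale. The intercept is defined as \code{d = alpha * b}, and node
#' response probabilities are \code{plogis(alpha * theta + d)}.
#'
#' @param alpha numeric 3 x J matrix (rows: midpoint, agreement, extreme) of
#'   discriminations; all entries must be strictly positive.
#' @param b numeric 3 x J matrix of difficulties on the trait scale.
#' @return An object of class \code{mpp_item_params}: a list with elements
#'   \code{alpha}, \code{b}, \code{d} (all 3 x J, rownames = node labels) and
#'   \code{J}.
#' @examples
#' p <- item_params(alpha = matrix(1, 3, 2), b = matrix(0, 3, 2))
#' p$d  # all zero
#' @export
item_params <- function(alpha, b) {
  alpha <- as.matrix(alpha)
  b <- as.matrix(b)
  if (nrow(alpha) != 3L || nrow(b) != 3L)
    stop("'alpha' and 'b' must have 3 rows (midpoint, agreement, extreme)")
  if (!identical(dim(alpha), dim(b)))
    stop("'alpha' and 'b' must have identical dimensions")
  if (ncol(alpha) < 1L) stop("at least one item is required")
  if (!all(is.finite(alpha)) || !all(is.finite(b)))
    stop("item parameters must be finite")
  if (any(alpha <= 0))
    stop("all discriminations must be strictly positive")
  rownames(alpha) <- rownames(b) <- MPP_NODES
  colnames(alpha) <- colnames(b) <- paste0("item", seq_len(ncol(alpha)))
  d <- alpha * b
  structure(list(alpha = alpha, b = b, d = d, J = ncol(alpha)),
            class = "mpp_item_params")
}

#' @export
print.mpp_item_params <- function(x, ...) {
  cat(sprintf("MPP item parameters: %d items x 3 nodes (d = alpha * b)\n", x$J))
  cat("mean alpha by node:",
      paste(sprintf("%s %.2f", MPP_NODES, rowMeans(x$alpha)), collapse = ", "),
      "\n")
  cat("mean d by node:    ",
      paste(sprintf("%s %.2f", MPP_NODES, rowMeans(x$d)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Latent trait container
#'
#' Person-by-node latent trait values for the three MPP decision processes,
#' together with the correlation matrix they were (or are assumed to be)
#' drawn under. Traits are on the standard-normal scale.
#'
#' @param theta numeric n x 3 matrix of trait values (columns: midpoint,
#'   agreement, extreme).
#' @param R 3 x 3 correlation matrix (symmetric, unit diagonal, positive
#'   semi-definite).
#' @return An object of class \code{mpp_latent_traits}: list with \code{theta}
#'   (n x 3, colnames = node labels) and \code{R}.
#' @export
latent_traits <- function(theta, R = diag(3)) {
  theta <- as.matrix(theta)
  if (ncol(theta) != 3L)
    stop("'theta' must have 3 columns (midpoint, agreement, extreme)")
  validate_cor_matrix(R)
  colnames(theta) <- MPP_NODES
  structure(list(theta = theta, R = R, n = nrow(theta)),
            class = "mpp_latent_traits")
}

#' @export
print.mpp_latent_traits <- function(x, ...) {
  cat(sprintf("MPP latent traits: %d persons x 3 nodes\n", x$n))
  cat("assumed correlations: r(M,A) =", format(x$R[1, 2]),
      " r(A,E) =", format(x$R[2, 3]), " r(M,E) =", format(x$R[1, 3]), "\n")
  invisible(x)
}

# Validates a correlation matrix; reports the offending eigenvalue when the
# matrix is not positive semi-definite.
validate_cor_matrix <- function(R, tol = 1e-8) {
  R <- as.matrix(R)
  if (nrow(R) != 3L || ncol(R) != 3L) stop("'R' must be 3 x 3")
  if (!isSymmetric(unname(R), tol = 1e-8)) stop("'R' must be symmetric")
  if (any(abs(diag(R) - 1) > 1e-8)) stop("'R' must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol)
    stop(sprintf("'R' is not positive semi-definite (smallest eigenvalue %.3g)",
                 min(ev)))
  invisible(R)
}

#' Single-node 2PL response probability
#'
#' Probability of taking the "1" branch at a node, in the intercept
#' parameterization: \code{plogis(alpha * theta + d)}.
#'
#' @param alpha discrimination(s), strictly positive.
#' @param d intercept(s) on the log-odds scale.
#' @param theta trait value(s).
#' @return Probabilities in (0, 1); vectorized over the inputs.
#' @examples
#' node_probability(1, 0, 0)        # 0.5
#' node_probability(2, -1, 1)       # plogis(1)
#' @export
node_probability <- function(alpha, d, theta) {
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("'alpha' must be strictly positive and finite")
  plogis(alpha * theta + d)
}

# Category probabilities from the three node probabilities. The midpoint
# branch alone determines category 3; categories 1/2/4/5 require a directed
# response and combine the agreement and extreme branches.
cat_probs_from_nodes <- function(pM, pA, pE) {
  cbind(`1` = (1 - pM) * (1 - pA) * pE,
        `2` = (1 - pM) * (1 - pA) * (1 - pE),
        `3` = pM,
        `4` = (1 - pM) * pA * (1 - pE),
        `5` = (1 - pM) * pA * pE)
}

#' Five-category response probabilities under the MPP model
#'
#' Combines the three node probabilities into the distribution over Likert
#' categories 1--5 for one item. Category 3 is reached if and only if the
#' midpoint branch is taken; the remaining categories split the directed
#' responses by agreement and extremity.
#'
#' @param params an \code{\link{item_params}} object.
#' @param theta length-3 trait vector (midpoint, agreement, extreme) or an
#'   n x 3 matrix of trait vectors.
#' @param item item index (column of \code{params}).
#' @return A length-5 probability vector (or n x 5 matrix), columns named
#'   "1".."5"; rows sum to 1.
#' @examples
#' p <- item_params(matrix(1, 3, 1), matrix(0, 3, 1))
#' category_probabilities(p, c(0, 0, 0))  # (0.125, 0.125, 0.5, 0.125, 0.125)
#' @export
category_probabilities <- function(params, theta, item = 1L) {
  stopifnot(inherits(params, "mpp_item_params"))
  if (item < 1L || item > params$J) stop("'item' out of range")
  th <- if (is.matrix(theta)) theta else matrix(theta, nrow = 1L)
  if (ncol(th) != 3L) stop("'theta' must have 3 components per person")
  if (any(!is.finite(th))) stop("'theta' must be finite")
  a <- params$alpha[, item]
  d <- params$d[, item]
  pM <- node_probability(a[1L], d[1L], th[, 1L])
  pA <- node_probability(a[2L], d[2L], th[, 2L])
  pE <- node_probability(a[3L], d[3L], th[, 3L])
  out <- cat_probs_from_nodes(pM, pA, pE)
  if (!is.matrix(theta)) out <- drop(out)
  out
}

# Pseudo-item coding of the five categories (rows: categories 1..5; columns:
# midpoint, agreement, extreme). NA marks structural missingness: once the
# midpoint branch is taken the later decisions never happen.
PSEUDO_CODES <- matrix(
  c(0L, 0L, 1L,   # 1: directed, disagree, extreme
    0L, 0L, 0L,   # 2: directed, disagree, not extreme
    1L, NA, NA,   # 3: midpoint -- tree terminates
    0L, 1L, 0L,   # 4: directed, agree, not extreme
    0L, 1L, 1L),  # 5: directed, agree, extreme
  nrow = 5L, byrow = TRUE,
  dimnames = list(category = 1:5, node = MPP_NODES)
)

#' Decompose Likert responses into binary pseudo-items
#'
#' Recodes each 1--5 response into the three binary node decisions of the MPP
#' tree. The agreement and extreme codes are structurally missing (\code{NA})
#' exactly when the response is the midpoint (category 3).
#'
#' @param responses integer matrix (persons x items) with entries in 1..5.
#' @return An object of class \code{mpp_pseudo_items}: a persons x items x 3
#'   array of 0/1/NA codes, third dimension named by node.
#' @examples
#' x <- matrix(c(1, 3, 5, 2), 2, 2)
#' decompose_responses(x)
#' @export
decompose_responses <- function(responses) {
  x <- as.matrix(responses)
  bad <- which(!(x %in% 1:5) | is.na(x))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(x)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(x)) + 1L
    stop(sprintf(
      "response out of range {1..5} at person %d, item %d (value %s)",
      i, j, format(x[bad[1L]])))
  }
  codes <- array(NA_integer_, dim = c(nrow(x), ncol(x), 3L),
                 dimnames = list(rownames(x), colnames(x), MPP_NODES))
  for (k in 1:3) codes[, , k] <- PSEUDO_CODES[x, k]
  structure(codes, class = "mpp_pseudo_items")
}

#' Recompose pseudo-items into Likert responses
#'
#' Exact inverse of \code{\link{decompose_responses}}. Each (midpoint,
#' agreement, extreme) pattern must be one of the five legal rows of the
#' pseudo-item coding; in particular the agreement/extreme codes must be
#' missing if and only if the midpoint code is 1.
#'
#' @param codes an \code{mpp_pseudo_items} array (persons x items x 3).
#' @return Integer persons x items matrix with entries in 1..5.
#' @export
recompose_responses <- function(codes) {
  codes <- unclass(codes)
  if (length(dim(codes)) != 3L || dim(codes)[3L] != 3L)
    stop("'codes' must be a persons x items x 3 array")
  dd <- dim(codes)[1:2]
  m <- codes[, , 1L, drop = FALSE]; dim(m) <- dd
  a <- codes[, , 2L, drop = FALSE]; dim(a) <- dd
  e <- codes[, , 3L, drop = FALSE]; dim(e) <- dd
  # key = M*100 + A*10 + E with NA -> legal only alongside M = 1
  out <- matrix(NA_integer_, nrow(m), ncol(m),
                dimnames = dimnames(codes)[1:2])
  mid <- !is.na(m) & m == 1L
  dir <- !is.na(m) & m == 0L
  legal_mid <- mid & is.na(a) & is.na(e)
  legal_dir <- dir & !is.na(a) & !is.na(e) & a %in% 0:1 & e %in% 0:1
  illegal <- which(!(legal_mid | legal_dir))
  if (length(illegal)) {
    i <- ((illegal[1L] - 1L) %% nrow(m)) + 1L
    j <- ((illegal[1L] - 1L) %/% nrow(m)) + 1L
    stop(sprintf("illegal pseudo-item pattern at person %d, item %d", i, j))
  }
  out[legal_mid] <- 3L
  # directed responses: category from (A, E)
  out[dir & a == 0L & e == 1L] <- 1L
  out[dir & a == 0L & e == 0L] <- 2L
  out[dir & a == 1L & e == 0L] <- 4L
  out[dir & a == 1L & e == 1L] <- 5L
  out
}

# Numerically safe Bernoulli log-probability on the log-odds scale:
# y * eta - log(1 + exp(eta)), computed through log1p to stay finite for
# |eta| well beyond 35.
bernoulli_loglik <- function(y, eta) {
  lp <- ifelse(eta > 0, -log1p(exp(-eta)), eta - log1p(exp(eta)))   # log p
  lq <- ifelse(eta > 0, -eta - log1p(exp(-eta)), -log1p(exp(eta)))  # log(1-p)
  ifelse(y == 1L, lp, lq)
}

#' Log-likelihood of decomposed MPP data
#'
#' Sum over all observed pseudo-item cells of the Bernoulli log-probability
#' under each node's 2PL sub-model. Structurally missing cells contribute
#' nothing, so this equals the log of the product-of-nodes category
#' likelihood on the original Likert data.
#'
#' @param params an \code{\link{item_params}} object.
#' @param traits an \code{\link{latent_traits}} object (or n x 3 matrix).
#' @param codes an \code{mpp_pseudo_items} array from
#'   \code{\link{decompose_responses}}.
#' @return The scalar log-likelihood.
#' @export
mpp_loglik <- function(params, traits, codes) {
  stopifnot(inherits(params, "mpp_item_params"))
  th <- if (inherits(traits, "mpp_latent_traits")) traits$theta else as.matrix(traits)
  codes <- unclass(codes)
  if (length(dim(codes)) != 3L || dim(codes)[3L] != 3L)
    stop("'codes' must be a persons x items x 3 array")
  if (dim(codes)[1L] != nrow(th))
    stop("person count mismatch between 'traits' and 'codes'")
  if (dim(codes)[2L] != params$J)
    stop("item count mismatch between 'params' and 'codes'")
  ll <- 0
  for (k in 1:3) {
    y <- codes[, , k, drop = FALSE]
    dim(y) <- dim(codes)[1:2]
    eta <- outer(th[, k], params$alpha[k, ]) +
      matrix(params$d[k, ], nrow(th), params$J, byrow = TRUE)
    obs <- !is.na(y)
    if (any(obs)) ll <- ll + sum(bernoulli_loglik(y[obs], eta[obs]))
  }
  ll
}
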