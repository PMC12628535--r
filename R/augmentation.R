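#' Stochastic augmentation configuration
#'
#' Defaults are the grid-search optimum for this task: masking probability
#' `p_mask = 0.15` on the token-embedding view and Gaussian noise scale
#' `eta = 0.01` on the CGR state view (grids searched:
#' `p_mask` in 0.05..0.25, `eta` in 0.005..0.04).
#'
#' @param p_mask probability that a feature entry is zeroed, in \[0, 1\].
#' @param eta standard deviation of the additive Gaussian noise, >= 0.
#' @param granularity `"element"` masks individual entries of the feature
#'   matrix; `"token"` masks whole token rows.
#' @return an `augmentation_config` list.
#' @export
augmentation_config <- function(p_mask = 0.15, eta = 0.01,
                                granularity = c("element", "token")) {
  granularity <- match.arg(granularity)
  if (!is.numeric(p_mask) || p_mask < 0 || p_mask > 1) {
    stop("p_mask must lie in [0, 1]")
  }
  if (!is.numeric(eta) || eta < 0) stop("eta must be non-negative")
  structure(list(p_mask = p_mask, eta = eta, granularity = granularity),
            class = "augmentation_config")
}

#' Sample a binary feature mask
#'
#' Entries are independent: `M_ij = 1` if `U(0,1) > p_mask`, else 0, so the
#' expected masked (zero) fraction is `p_mask`. Draws come from the global
#' R random stream; seed with [set.seed()] for reproducibility.
#'
#' @param dims integer vector of matrix dimensions (rows, cols).
#' @param p_mask masking probability in \[0, 1\].
#' @return binary (0/1) matrix of the requested shape.
#' @export
sample_mask <- function(dims, p_mask) {
  if (!is.numeric(p_mask) || p_mask < 0 || p_mask > 1) {
    stop("p_mask must lie in [0, 1]")
  }
  dims <- as.integer(dims)
  matrix(as.numeric(stats::runif(prod(dims)) > p_mask), dims[1], dims[2])
}

#' Apply a binary mask to a feature matrix (Hadamard product)
#'
#' Unmasked entries pass through bit-exactly; masked entries become exactly
#' zero. A single-column mask broadcasts across the feature dimension
#' (whole-token masking).
#'
#' @param X numeric feature matrix.
#' @param M binary mask, same shape as `X` or one column with `nrow(X)`
#'   rows.
#' @return masked matrix, same shape as `X`.
#' @export
mask_features <- function(X, M) {
  if (is.null(dim(M))) M <- matrix(M, ncol = 1)
  if (nrow(M) != nrow(X)) stop("mask row count does not match feature matrix")
  if (ncol(M) == ncol(X)) {
    X * M
  } else if (ncol(M) == 1L) {
    X * M[, 1]
  } else {
    stop("mask must match the feature matrix shape or be a single column")
  }
}

#' Add scaled Gaussian noise to a continuous feature matrix
#'
#' `X + eta * N(0, 1)`, element-wise independent draws. `eta = 0` is a
#' bit-exact identity.
#'
#' @param X numeric matrix (CGR state features).
#' @param eta noise scale, >= 0.
#' @return matrix of the same shape.
#' @export
add_noise <- function(X, eta) {
  if (!is.numeric(eta) || eta < 0) stop("eta must be non-negative")
  if (eta == 0) return(X)
  X + matrix(stats::rnorm(length(X)), nrow(X), ncol(X)) * eta
}

# One stochastic view: element (or token-row) masking on the embedding
# features, additive noise on the CGR state features.
augment_view <- function(X, X_extra, config) {
  M <- if (config$granularity == "token") {
    sample_mask(c(nrow(X), 1L), config$p_mask)
  } else {
    sample_mask(dim(X), config$p_mask)
  }
  list(X = mask_features(X, M),
       X_extra = add_noise(X_extra, config$eta),
       M = M)
}

#' Generate a correlated pair of augmented multi-view copies of one sample
#'
#' Two augmentation operators are sampled independently and each applied to
#' the full multi-view feature set, using a distinct strategy per feature
#' type: random masking for the token-embedding matrix `X`, additive
#' Gaussian noise for the CGR state matrix `X_extra`. The two resulting
#' views form the positive pair for the contrastive objective.
#'
#' @param sample list with `X` (tokens x d embedding matrix) and `X_extra`
#'   (positions x 1 CGR state matrix).
#' @param config an [augmentation_config()].
#' @return an `augmented_pair`: list with `view_q` and `view_k`, each
#'   holding `X`, `X_extra` and the mask `M` used.
#' @export
make_views <- function(sample, config = augmentation_config()) {
  if (is.null(sample$X) || is.null(sample$X_extra)) {
    stop("sample must carry both X and X_extra feature matrices")
  }
  X <- sample$X
  Xe <- as.matrix(sample$X_extra)
  structure(list(view_q = augment_view(X, Xe, config),
                 view_k = augment_view(X, Xe, config)),
            class = "augmented_pair")
}
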