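# Domain-adversarial alignment. A binary discriminator d(.) is trained to
# tell source-subject features from target-subject features; a gradient
# reversal layer (GRL) between the feature extractor and the discriminator
# flips (and scales by lambda) the gradient flowing back into the extractor,
# so the extractor learns subject-invariant features while the discriminator
# learns to separate them:
#
#   min_{theta_f} max_{theta_d}  L_classifier + L_gcn - lambda * L_disc
#
# realized as: the discriminator minimizes L_disc; the extractor side
# minimizes L_classifier + L_gcn - lambda * L_disc via the GRL.

#' Adversarial-weight schedule
#'
#' Two variants of the epoch-dependent balance weight `lambda(p)`, where
#' `p` is the ratio of the current epoch to the maximum epochs:
#' \describe{
#'   \item{`decreasing`}{`lambda = 2 / (1 - exp(-p)) - 1`: starts
#'     large (emphasizing domain alignment early) and decreases toward 1.
#'     Undefined at `p = 0`; schedule starts at epoch 1.}
#'   \item{`dann_increasing`}{`lambda = 2 / (1 + exp(-gamma * p)) - 1`: the
#'     standard DANN warm-up from 0 toward 1 (`gamma` defaults to 10).}
#' }
#'
#' @param p training progress in `(0, 1]` (`[0, 1]` for `dann_increasing`).
#' @param variant schedule variant.
#' @param gamma growth rate of the `dann_increasing` variant.
#' @return Non-negative scalar `lambda`.
#' @export
lambda_schedule <- function(p, variant = c("decreasing", "dann_increasing"),
                            gamma = 10) {
  variant <- match.arg(variant)
  if (variant == "decreasing") {
    if (any(p <= 0)) {
      stop("decreasing schedule has a pole at p = 0; start at epoch 1",
           call. = FALSE)
    }
    2 / (1 - exp(-p)) - 1
  } else {
    if (any(p < 0)) stop("p must be >= 0", call. = FALSE)
    2 / (1 + exp(-gamma * p)) - 1
  }
}

#' Domain discriminator loss
#'
#' `L_disc = -sum_i log d(source_i) - sum_j log(1 - d(target_j))`, where
#' `d(.)` is the discriminator's source-probability output. Probabilities
#' are clamped at `eps` before the logs.
#'
#' @param d_source numeric vector of source-probabilities on source windows.
#' @param d_target numeric vector of source-probabilities on target windows.
#' @param reduce `"sum"` (as defined) or `"mean"` (per-sample average, used
#'   by the training loop for batch-size invariance).
#' @param eps probability clamp.
#' @return Scalar loss.
#' @export
discriminator_loss <- function(d_source, d_target, reduce = c("sum", "mean"),
                               eps = 1e-7) {
  reduce <- match.arg(reduce)
  if (length(d_source) == 0L || length(d_target) == 0L) {
    stop("both source and target batches must be non-empty", call. = FALSE)
  }
  ps <- pmin(pmax(d_source, eps), 1 - eps)
  pt <- pmin(pmax(d_target, eps), 1 - eps)
  total <- -sum(log(ps)) - sum(log(1 - pt))
  if (reduce == "mean") total / (length(ps) + length(pt)) else total
}

#' Gradient reversal layer (forward pass)
#'
#' Identity in the forward direction. The backward contract — the gradient
#' flowing to the input is multiplied by `-lambda` — is realized by
#' [grl_backward()] inside the training loop (there is no autodiff tape).
#'
#' @param x any numeric input.
#' @return `x`, unchanged.
#' @export
gradient_reversal <- function(x) x

#' Gradient reversal layer (backward contract)
#'
#' @param grad gradient arriving from the discriminator side.
#' @param lambda adversarial weight.
#' @return `-lambda * grad`.
#' @export
grl_backward <- function(grad, lambda) -lambda * grad

#' Extractor-side total loss
#'
#' `L_classifier + L_gcn - lambda * L_disc`: the quantity the feature
#' extractor and classifier minimize (the discriminator separately
#' minimizes `L_disc`).
#'
#' @param L_classifier source-window classification cross-entropy.
#' @param L_gcn graph regularization loss.
#' @param L_disc discriminator loss.
#' @param lambda adversarial weight.
#' @return Scalar.
#' @export
total_loss <- function(L_classifier, L_gcn, L_disc, lambda) {
  stopifnot(is.finite(L_classifier), is.finite(L_gcn), is.finite(L_disc))
  L_classifier + L_gcn - lambda * L_disc
}
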