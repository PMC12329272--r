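#' Effective affine form of batch normalization
#'
#' Folds per-channel batch normalization into an equivalent scale and shift
#' applied to the convolution output: with learnable scale \eqn{\gamma} and
#' shift \eqn{\beta}, batch statistics \eqn{E[x]} and \eqn{Var[x]}, and
#' stabilizer \eqn{\epsilon},
#' \deqn{w_{bn} = \gamma / \sqrt{Var[x] + \epsilon}, \qquad
#'       b_{bn} = \beta - \gamma E[x] / \sqrt{Var[x] + \epsilon},}
#' so that a normalized block computes
#' \eqn{\sigma(w_{bn} (w_{conv} x + b_{conv}) + b_{bn})}. When batch
#' normalization is disabled the block reduces to
#' \eqn{\sigma(w_{conv} x + b_{conv})}.
#'
#' @param gamma,beta learnable per-channel scale and shift.
#' @param mean,var per-channel statistics; `var` must be non-negative.
#' @param epsilon positive stabilizer (default `1e-5`).
#' @return list with per-channel `w_bn` and `b_bn`.
#' @export
bn_effective_affine <- function(gamma, beta, mean, var, epsilon = 1e-5) {
  if (any(var < 0)) stop("batch variance must be non-negative", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  inv_sd <- 1 / sqrt(var + epsilon)
  list(w_bn = gamma * inv_sd, b_bn = beta - gamma * mean * inv_sd)
}
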