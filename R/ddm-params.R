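#' @useDynLib rewardDDM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef cor.test dbeta dgamma dnorm lm median optim
#'   optimHess p.adjust pchisq plogis pnorm predict pt qlogis qnorm quantile
#'   rbinom rnorm rpois runif sd setNames t.test var vcov chisq.test glm
#'   binomial rgamma rbeta complete.cases
#' @importFrom utils head read.csv tail write.csv
NULL

# The two reward contexts: the reference choice (upper bound) paired with the
# large or the small reward.
DDM_CONTEXTS <- c("ref-large", "ref-small")

#' Collapsing-bound DDM parameters
#'
#' Container for the parameters of a drift-diffusion model with logistically
#' collapsing bounds and reward-context-dependent biases. Momentary evidence is
#' `E ~ N(coherence + me, 1)` and the decision variable integrates `k * E`
#' with unit diffusion. The total bound separation decays as
#' `B(t) = a / (1 + exp(beta_alpha * t - beta_d))`; the relative bound height
#' `z` places the accumulation start point a fraction `z` of the way up from
#' the lower bound, so `z > 0.5` puts the upper bound closer to the start.
#'
#' The drift offset `me` ("fictive evidence", in coherence units) and `z` take
#' one value per reward context: `"ref-large"` (reference choice paired with
#' the large reward) and `"ref-small"`.
#'
#' @param k drift scaling (per unit coherence per second); `k > 0`.
#' @param me_by_context named numeric of length 2 (`ref-large`, `ref-small`):
#'   additive evidence offset per context, in coherence units. An unnamed
#'   length-2 vector is taken in that order; a scalar is recycled.
#' @param z_by_context named numeric of length 2: relative bound height per
#'   context, each in (0, 1). Same recycling rules as `me_by_context`.
#' @param a maximal bound separation (evidence units); `a > 0`.
#' @param beta_alpha bound-collapse rate (1/s); `beta_alpha >= 0`.
#' @param beta_d bound-collapse onset parameter (unitless).
#' @param t0 non-decision time (s); `t0 >= 0`. RT = decision time + `t0`.
#' @return An object of class `ddm_params`.
#' @examples
#' p <- ddm_params(k = 6, me_by_context = c(0.05, -0.03),
#'                 z_by_context = c(0.48, 0.55), a = 2,
#'                 beta_alpha = 3, beta_d = 5, t0 = 0.3)
#' p
#' @export
ddm_params <- function(k, me_by_context = 0, z_by_context = 0.5, a = 2,
                       beta_alpha = 3, beta_d = 5, t0 = 0.3) {
  me <- expand_context(me_by_context, "me_by_context")
  z <- expand_context(z_by_context, "z_by_context")
  stopifnot(is.numeric(k), length(k) == 1L, is.numeric(a), length(a) == 1L)
  if (!(k > 0)) stop("k must be > 0")
  if (!(a > 0)) stop("a must be > 0")
  if (beta_alpha < 0) stop("beta_alpha must be >= 0")
  if (t0 < 0) stop("t0 must be >= 0")
  if (any(z <= 0 | z >= 1)) stop("z_by_context values must lie in (0, 1)")
  structure(list(k = k, me_by_context = me, z_by_context = z, a = a,
                 beta_alpha = beta_alpha, beta_d = beta_d, t0 = t0),
            class = "ddm_params")
}

expand_context <- function(x, what) {
  if (length(x) == 1L) x <- rep(x, 2L)
  if (length(x) != 2L) stop(what, " must have length 1 or 2")
  if (is.null(names(x))) names(x) <- DDM_CONTEXTS
  if (!setequal(names(x), DDM_CONTEXTS))
    stop(what, " must be keyed by contexts ", paste(DDM_CONTEXTS, collapse = ", "))
  x[DDM_CONTEXTS]
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("Collapsing-bound DDM parameters\n")
  cat(sprintf("  k = %.4g, a = %.4g, beta_alpha = %.4g, beta_d = %.4g, t0 = %.4g s\n",
              x$k, x$a, x$beta_alpha, x$beta_d, x$t0))
  for (ctx in DDM_CONTEXTS)
    cat(sprintf("  [%s]  me = %+.4g, z = %.4g\n", ctx,
                x$me_by_context[[ctx]], x$z_by_context[[ctx]]))
  invisible(x)
}

#' Serialize / restore DDM parameters as YAML
#'
#' Flat key-value text representation with the same field names as
#' [ddm_params()].
#'
#' @param params a `ddm_params` object.
#' @param path file path.
#' @return `write_ddm_params` returns `path` invisibly; `read_ddm_params`
#'   returns a `ddm_params` object.
#' @export
write_ddm_params <- function(params, path) {
  stopifnot(inherits(params, "ddm_params"))
  yaml::write_yaml(lapply(unclass(params), function(v)
    if (is.null(names(v))) v else as.list(v)), path)
  invisible(path)
}

#' @rdname write_ddm_params
#' @export
read_ddm_params <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(ddm_params, lapply(x, function(v) unlist(v)))
}

context_label <- function(code) {
  # numeric coding +1 = ref-large, -1 = ref-small
  ifelse(code > 0, "ref-large", "ref-small")
}
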