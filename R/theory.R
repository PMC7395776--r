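#' Multiplicative polygenic model
#'
#' Parameterises the model in which the log odds of disease are linear in a
#' normally distributed PRS. \code{gamma} is the \emph{log} odds ratio per
#' control SD of the analysed population. When the PRS has been
#' standardised to a different reference population's control SD,
#' \code{control_sd} and \code{reference_sd} convert a per-reference-SD
#' effect into a per-control-SD \code{gamma}:
#' \code{gamma = log(or_per_reference_sd) * control_sd / reference_sd}.
#'
#' Note: although an effect per SD is often quoted as an OR, all
#' closed-form consequences here (\eqn{\lambda_P}, predicted bin ORs,
#' theoretical AUC) require the log OR; supplying \code{or_per_sd} converts
#' internally.
#'
#' @param gamma log OR per control SD (mutually exclusive with
#'   \code{or_per_sd}).
#' @param or_per_sd OR per \code{reference_sd} unit; converted to
#'   \code{gamma} via the SD ratio.
#' @param control_sd control PRS SD of the analysed population.
#' @param reference_sd control PRS SD of the standardising population.
#' @param prevalence disease prevalence for finite-prevalence computations.
#' @return classed list \code{polygenic_model}.
#' @export
polygenic_model <- function(gamma = NULL, or_per_sd = NULL,
                            control_sd = 1, reference_sd = 1,
                            prevalence = 0.05) {
  stopifnot(control_sd > 0, reference_sd > 0,
            prevalence > 0, prevalence < 1)
  if (is.null(gamma) == is.null(or_per_sd))
    stop("supply exactly one of gamma or or_per_sd")
  if (is.null(gamma)) {
    stopifnot(or_per_sd > 0)
    gamma <- log(or_per_sd) * control_sd / reference_sd
  }
  stopifnot(is.finite(gamma))
  structure(list(gamma = gamma, control_sd = control_sd,
                 reference_sd = reference_sd, prevalence = prevalence),
            class = "polygenic_model")
}

#' @export
print.polygenic_model <- function(x, ...) {
  cat(sprintf("Multiplicative polygenic model: gamma = %.4f per control SD",
              x$gamma),
      sprintf("(OR %.3f); control SD %.3f, reference SD %.3f, prevalence %.3f\n",
              exp(x$gamma), x$control_sd, x$reference_sd, x$prevalence))
  invisible(x)
}

#' Familial relative risk attributable to the PRS
#'
#' Under the multiplicative polygenic model the relative risk to
#' first-degree relatives of affected women due to the PRS alone is
#' \eqn{\lambda_P = \exp(\gamma^2 / 2)}.
#'
#' @param model a [polygenic_model()].
#' @return \eqn{\lambda_P \ge 1}.
#' @export
lambda_p <- function(model) {
  exp(model$gamma^2 / 2)
}

#' Fraction of familial relative risk explained by the PRS
#'
#' \eqn{\ln(\lambda_P)/\ln(\lambda) = \gamma^2 / (2 \ln \lambda)}, the
#' log-scale share of an assumed familial relative risk \eqn{\lambda}
#' (default 2 for breast cancer) accounted for by the score.
#'
#' @param model a [polygenic_model()].
#' @param lambda_fam assumed familial relative risk, > 1.
#' @return list with \code{lambda_p}, \code{lambda_fam} and
#'   \code{fraction_explained}.
#' @export
frr_explained <- function(model, lambda_fam = 2) {
  if (lambda_fam <= 1) stop("lambda_fam must exceed 1")
  lp <- lambda_p(model)
  list(lambda_p = lp, lambda_fam = lambda_fam,
       fraction_explained = model$gamma^2 / (2 * log(lambda_fam)))
}

# Expected case and control bin masses under the model. In the rare-disease
# limit cases are N(gamma, 1) when controls are N(0, 1); the exact mode
# integrates the logistic model at the stated prevalence.
.bin_masses <- function(model, breaks, mode = c("rare", "exact")) {
  mode <- match.arg(mode)
  g <- model$gamma
  if (mode == "rare") {
    ctrl <- diff(stats::pnorm(breaks))
    case <- diff(stats::pnorm(breaks - g))
  } else {
    # P(case | z) = expit(b0 + g z) with b0 set to the stated prevalence
    b0 <- .solve_intercept(g, 0, 1, model$prevalence)
    f_case <- function(z) stats::dnorm(z) * expit(b0 + g * z)
    f_ctrl <- function(z) stats::dnorm(z) * (1 - expit(b0 + g * z))
    nb <- length(breaks) - 1L
    case <- ctrl <- numeric(nb)
    for (i in seq_len(nb)) {
      lo <- max(breaks[i], -10); hi <- min(breaks[i + 1], 10)
      case[i] <- stats::integrate(f_case, lo, hi)$value
      ctrl[i] <- stats::integrate(f_ctrl, lo, hi)$value
    }
    case <- case / sum(case)
    ctrl <- ctrl / sum(ctrl)
  }
  list(case = case, control = ctrl)
}

#' Predicted percentile-bin odds ratios under the polygenic model
#'
#' With control PRS standard normal and the log OR linear in the PRS, the
#' case distribution is (in the rare-disease limit) the control
#' distribution shifted by \eqn{\gamma}. The predicted OR of bin
#' \eqn{[a,b]} versus the reference bin \eqn{[c,d]} (cut points =
#' standard-normal quantiles of the scheme boundaries) is
#' \deqn{\frac{[\Phi(b-\gamma)-\Phi(a-\gamma)]/[\Phi(b)-\Phi(a)]}
#'            {[\Phi(d-\gamma)-\Phi(c-\gamma)]/[\Phi(d)-\Phi(c)]}.}
#' \code{mode = "exact"} instead integrates case/control densities under
#' the model's stated finite prevalence.
#'
#' @param model a [polygenic_model()].
#' @param scheme a [bin_scheme()].
#' @param mode \code{"rare"} (normal-shift approximation, default) or
#'   \code{"exact"} (finite prevalence).
#' @return data frame with bin labels, boundaries and predicted OR
#'   (reference bin = 1).
#' @export
predicted_bin_or <- function(model, scheme = bin_scheme(),
                             mode = c("rare", "exact")) {
  mode <- match.arg(mode)
  breaks <- stats::qnorm(scheme$boundaries)
  if (any(diff(breaks) <= 0)) stop("degenerate bin in scheme")
  m <- .bin_masses(model, breaks, mode)
  enr <- m$case / m$control
  or <- enr / enr[scheme$reference]
  data.frame(bin = scheme$labels,
             lower = scheme$boundaries[-length(scheme$boundaries)],
             upper = scheme$boundaries[-1],
             or = or,
             reference = seq_along(or) == scheme$reference,
             stringsAsFactors = FALSE)
}

#' Theoretical AUC of the polygenic model
#'
#' Under the normal-shift model (cases N(\eqn{\gamma}, 1), controls
#' N(0, 1)) the probability that a random case outscores a random control
#' is \eqn{\Phi(\gamma/\sqrt 2)}.
#'
#' @param model a [polygenic_model()].
#' @return AUC in \[0.5, 1\] for \eqn{\gamma \ge 0}.
#' @export
theoretical_auc <- function(model) {
  stats::pnorm(model$gamma / sqrt(2))
}
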