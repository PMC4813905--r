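# Safety factor and the logistic mapping from safety factor to empirical
# insertion probability. The safety factor is the ratio of predicted buckling
# force to predicted insertion force: a design with safety factor 1 is
# predicted to buckle exactly when it starts to penetrate.

#' Safety factor
#'
#' @param buckling_force,insertion_force Forces in consistent units, both > 0.
#' @return Dimensionless ratio.
#' @export
safety_factor <- function(buckling_force, insertion_force) {
  if (any(buckling_force <= 0) || any(insertion_force <= 0))
    pf_stop("pf_domain_error", "forces must be positive")
  buckling_force / insertion_force
}

#' Predict buckling force, insertion force and safety factor for a design
#'
#' @param assembly A [coated_assembly()].
#' @param tissue A [tissue_model()].
#' @param backend `"surrogate"` (default) or `"fem"` for the insertion force.
#' @param bc Buckling boundary condition.
#' @param logistic Optional fitted [fit_logistic()] model; if given, the
#'   predicted insertion probability is attached.
#' @param ... Passed to [simulate_insertion()] for the FEM backend.
#' @return A `pf_prediction` with forces in N and the safety factor.
#' @export
predict_insertion <- function(assembly, tissue = tissue_preset("brain"),
                              backend = c("surrogate", "fem"),
                              bc = "fixed_pinned", logistic = NULL, ...) {
  backend <- match.arg(backend)
  Fb <- buckling_force(assembly, bc = bc)
  Fi <- if (backend == "surrogate") surrogate_insertion_force(assembly, tissue)
        else simulate_insertion(assembly, tissue, ...)$insertion_force
  sf <- safety_factor(Fb, Fi)
  structure(list(buckling_force = Fb, insertion_force = Fi,
                 safety_factor = sf, backend = backend, bc = bc,
                 predicted_probability =
                   if (!is.null(logistic)) predict_probability(logistic, sf)),
            class = "pf_prediction")
}

#' @export
print.pf_prediction <- function(x, ...) {
  cat(sprintf("F_buckle = %.4g mN, F_insert = %.4g mN, safety factor = %.3g",
              mN(x$buckling_force), mN(x$insertion_force), x$safety_factor))
  if (!is.null(x$predicted_probability))
    cat(sprintf(", p(insert) = %.3f", x$predicted_probability))
  cat("\n"); invisible(x)
}

#' Safety factors for the packaged cohorts
#'
#' Runs the package mechanics (composite Euler buckling, surrogate insertion
#' force) over every cohort record and returns a table ready for
#' [fit_logistic()].
#'
#' @param cohorts List of cohort records, default all 22.
#' @param tissue Tissue model used for insertion forces (one preset for all
#'   cohorts, as the outcomes were pooled in the source experiments).
#' @param bc Buckling boundary condition.
#' @return Data frame: id, buckling/insertion force (mN), safety_factor,
#'   n_pass, n_total, success_rate.
#' @export
cohort_safety_factors <- function(cohorts = load_all_cohorts(),
                                  tissue = tissue_preset("brain"),
                                  bc = "fixed_pinned") {
  do.call(rbind, lapply(cohorts, function(co) {
    pr <- predict_insertion(co$assembly, tissue, backend = "surrogate", bc = bc)
    data.frame(id = co$id,
               buckling_force_mN = mN(pr$buckling_force),
               insertion_force_mN = mN(pr$insertion_force),
               safety_factor = pr$safety_factor,
               n_pass = co$n_pass, n_total = co$n_total,
               success_rate = co$success_rate)
  }))
}

#' Fit the logistic safety-factor / success-probability relationship
#'
#' Two-parameter symmetric logistic `p(SF) = 1 / (1 + exp(-k (SF - SF50)))`
#' fitted by maximizing the binomial likelihood of the pass counts
#' (count-weighted, since cohorts have unequal sizes). The fit is
#' deterministic (iteratively reweighted least squares from a fixed start;
#' no randomness).
#'
#' @param points Data frame with columns `safety_factor`, `n_pass`, `n_total`.
#' @param ridge Non-negative ridge penalty on the slope/intercept; needed when
#'   the outcomes are completely separated in safety factor.
#' @return A `pf_logistic` with `midpoint` (SF at p = 0.5), `slope` (k) and
#'   `fit_meta`.
#' @export
fit_logistic <- function(points, ridge = 0) {
  need <- c("safety_factor", "n_pass", "n_total")
  if (!all(need %in% names(points)))
    pf_stop("pf_config_error", "points needs columns %s", paste(need, collapse = ", "))
  if (length(unique(points$safety_factor)) < 3)
    pf_stop("pf_insufficient_data", "need >= 3 distinct safety-factor values")
  rate <- points$n_pass / points$n_total
  mixed <- any(rate > 0 & rate < 1)
  sep <- !mixed && length(unique(rate)) > 1 &&
    max(points$safety_factor[rate == 0]) < min(points$safety_factor[rate == 1])
  if (sep && ridge <= 0)
    pf_stop("pf_separation_error",
            "outcomes completely separated in safety factor; refit with ridge > 0")
  if (ridge > 0) {
    nll <- function(b) {
      eta <- b[1] + b[2] * points$safety_factor
      -sum(points$n_pass * eta - points$n_total * log1p(exp(eta))) +
        ridge * sum(b^2)
    }
    # deterministic start from a linear probit-style regression on rates
    z <- qlogis(pmin(pmax(rate, 0.02), 0.98))
    st <- coef(lm(z ~ points$safety_factor))
    op <- optim(st, nll, method = "BFGS", control = list(maxit = 500))
    b <- op$par; conv <- op$convergence == 0; loss <- op$value
  } else {
    fit <- suppressWarnings(
      glm(cbind(n_pass, n_total - n_pass) ~ safety_factor,
          family = binomial(), data = points))
    b <- coef(fit); conv <- fit$converged; loss <- fit$deviance
  }
  if (!is.finite(b[2]) || b[2] <= 0)
    pf_stop("pf_separation_error", "non-positive fitted slope; data degenerate")
  structure(list(midpoint = unname(-b[1] / b[2]), slope = unname(b[2]),
                 fit_meta = list(n_points = nrow(points), loss = loss,
                                 converged = conv, ridge = ridge,
                                 form = "two-parameter symmetric logistic, binomial likelihood")),
            class = "pf_logistic")
}

#' @export
print.pf_logistic <- function(x, ...) {
  cat(sprintf("<logistic> SF50 = %.3f, slope = %.3f (n = %d, converged = %s)\n",
              x$midpoint, x$slope, x$fit_meta$n_points, x$fit_meta$converged))
  invisible(x)
}

#' Predicted insertion probability at a safety factor
#'
#' @param model A fitted `pf_logistic`.
#' @param safety_factor Scalar or vector.
#' @return Probability in (0, 1). Designs with `p >= 0.99` are reported as
#'   operational "100% success" by [sf_at_probability()] conventions.
#' @export
predict_probability <- function(model, safety_factor) {
  stopifnot(inherits(model, "pf_logistic"))
  plogis(model$slope * (safety_factor - model$midpoint))
}

#' Safety factor at which a target probability is reached
#'
#' @param model A fitted `pf_logistic`.
#' @param p Target probability (default 0.99, the operational "100% success"
#'   level — a logistic never reaches 1 exactly).
#' @export
sf_at_probability <- function(model, p = 0.99) {
  stopifnot(inherits(model, "pf_logistic"))
  model$midpoint + qlogis(p) / model$slope
}
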