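# Design-space exploration: sweeps over the eight probe/coating/tissue design
# parameters, probability color maps for parameter pairs, bivariate map
# statistics, and multi-variable regression of safety factor on the
# parameters.

.ds_params <- list(
  coating_thickness   = list(range = c(0, 200),     unit = "um (per side)"),
  probe_length        = list(range = c(0.01, 10),   unit = "mm"),
  coating_stiffness   = list(range = c(0.001, 100), unit = "GPa"),
  coating_aspect_ratio = list(range = c(0.1, 10),   unit = "-"),
  probe_width         = list(range = c(5, 350),     unit = "um"),
  bevel_angle         = list(range = c(0, 75),      unit = "deg"),
  probe_stiffness     = list(range = c(1, 5000),    unit = "MPa"),
  brain_stiffness     = list(range = c(0.5, 5),     unit = "kPa"))

.ds_defaults <- c(coating_thickness = 50, probe_length = 3.5,
                  coating_stiffness = 1.9, coating_aspect_ratio = 1,
                  probe_width = 20, bevel_angle = 45,
                  probe_stiffness = 5.6, brain_stiffness = 2.5)

#' The eight-parameter design space
#'
#' Parameter ranges of the design study: per-side coating thickness, probe
#' length, coating stiffness, coating aspect ratio (width/thickness), probe
#' width, coating tip bevel angle, probe stiffness and brain stiffness.
#' Grids are strictly increasing and default to `n_grid` evenly spaced points
#' over each range.
#'
#' @param n_grid Points per parameter grid (default 10).
#' @param ranges Optional named list overriding `[min, max]` ranges (must stay
#'   within the modeled ranges).
#' @return A `pf_design_space`.
#' @export
design_space <- function(n_grid = 10, ranges = NULL) {
  ps <- .ds_params
  if (!is.null(ranges)) for (nm in names(ranges)) {
    if (!nm %in% names(ps)) pf_stop("pf_config_error", "unknown parameter '%s'", nm)
    ps[[nm]]$range <- ranges[[nm]]
  }
  for (nm in names(ps)) {
    g <- seq(ps[[nm]]$range[1], ps[[nm]]$range[2], length.out = n_grid)
    if (any(diff(g) <= 0)) pf_stop("pf_config_error", "grid for '%s' not increasing", nm)
    ps[[nm]]$grid <- g
  }
  structure(list(parameters = ps, defaults = .ds_defaults),
            class = "pf_design_space")
}

# Build assembly + tissue for one parameter assignment (design units).
# Probe: Parylene-class rectangular shank, thickness 5 um, swept width/length
# and stiffness; coating applied per side when coating_thickness > 0, overall
# width following the aspect ratio but never narrower than the probe.
design_point <- function(par) {
  p <- as.list(par)
  probe_mat <- material("probe_sweep", p$probe_stiffness * 1e6, 1289, 0.45)
  # stub-length corner of the space: keep the shank at least as long as wide
  w_p <- min(p$probe_width, p$probe_length * 1e3)
  probe <- probe_spec(w_p, 5, p$probe_length * 1e3, probe_mat)
  cthk <- p$coating_thickness
  if (cthk > 1e-9) {
    coat_mat <- material("coating_sweep", p$coating_stiffness * 1e9, 1290, 0.42)
    t_c <- 5 + 2 * cthk
    w_c <- max(p$coating_aspect_ratio * t_c, w_p)
    coating <- coating_spec(t_c, w_c, p$probe_length * 1e3 + 500,
                            bevel_angle = p$bevel_angle, material = coat_mat)
    asm <- coated_assembly(probe, coating)
  } else asm <- coated_assembly(probe)
  tissue <- tissue_preset("brain", small_strain_stiffness = p$brain_stiffness * 1e3)
  list(assembly = asm, tissue = tissue)
}

#' Sweep the design space
#'
#' Evaluates buckling force, insertion force and safety factor at every point
#' of a factorial grid over the free parameters (all others held at `fixed`
#' or at the package defaults), or at a deterministic Latin-hypercube sample
#' of all parameters when `sample_n` is given (used for the regression).
#'
#' @param ds A [design_space()].
#' @param free Character vector of parameters swept on their grids (ignored
#'   when `sample_n` is given).
#' @param fixed Named overrides for the remaining parameters (design units).
#' @param backend `"surrogate"` (default) or `"fem"`.
#' @param sample_n Latin-hypercube sample size over all 8 parameters.
#' @param seed Seed for the hypercube sample (deterministic given seed).
#' @param max_fail_frac Error if more than this fraction of points fail.
#' @return Data frame with one row per design point: the parameter values,
#'   `F_buckle_mN`, `F_insert_mN`, `safety_factor`, `ok`.
#' @export
sweep_design <- function(ds = design_space(), free = NULL, fixed = list(),
                         backend = c("surrogate", "fem"),
                         sample_n = NULL, seed = 1, max_fail_frac = 0.1) {
  backend <- match.arg(backend)
  pnames <- names(ds$parameters)
  base <- ds$defaults
  for (nm in names(fixed)) base[[nm]] <- fixed[[nm]]
  if (!is.null(sample_n)) {
    set.seed(seed)
    pts <- sapply(pnames, function(nm) {
      r <- ds$parameters[[nm]]$range
      u <- (sample.int(sample_n) - runif(sample_n)) / sample_n
      r[1] + u * (r[2] - r[1])
    })
    grid <- as.data.frame(pts)
  } else {
    if (is.null(free) || !length(free))
      pf_stop("pf_config_error", "supply `free` parameters or `sample_n`")
    gl <- lapply(free, function(nm) ds$parameters[[nm]]$grid)
    names(gl) <- free
    grid <- expand.grid(gl, KEEP.OUT.ATTRS = FALSE)
    for (nm in setdiff(pnames, free)) grid[[nm]] <- base[[nm]]
    grid <- grid[pnames]
  }
  res <- lapply(seq_len(nrow(grid)), function(i) {
    out <- tryCatch({
      dp <- design_point(grid[i, ])
      Fb <- buckling_force(dp$assembly)
      Fi <- if (backend == "surrogate")
        surrogate_insertion_force(dp$assembly, dp$tissue)
      else simulate_insertion(dp$assembly, dp$tissue,
                              mesh = "coarse")$insertion_force
      c(Fb = Fb, Fi = Fi)
    }, error = function(e) c(Fb = NA_real_, Fi = NA_real_))
    out
  })
  m <- do.call(rbind, res)
  grid$F_buckle_mN <- mN(m[, "Fb"])
  grid$F_insert_mN <- mN(m[, "Fi"])
  grid$safety_factor <- m[, "Fb"] / m[, "Fi"]
  grid$ok <- is.finite(grid$safety_factor)
  if (mean(!grid$ok) > max_fail_frac)
    pf_stop("pf_sweep_error", "%.0f%% of sweep points failed",
            100 * mean(!grid$ok))
  attr(grid, "backend") <- backend
  grid
}

#' Probability color map for a parameter pair
#'
#' Converts a sweep table into a 2-D grid of predicted insertion
#' probabilities via a fitted logistic; missing cells are bilinearly
#' interpolated (along rows then columns) and flagged.
#'
#' @param sweep_tbl Output of [sweep_design()] covering the pair's grid.
#' @param logistic A fitted [fit_logistic()].
#' @param pair Character vector of two parameter names `(rho1, rho2)`.
#' @return A `pf_probability_map`: `values` matrix (`rho1` along rows),
#'   `grid1`, `grid2`, `interpolated` logical matrix, provenance.
#' @export
probability_map <- function(sweep_tbl, logistic, pair) {
  stopifnot(length(pair) == 2, all(pair %in% names(sweep_tbl)))
  g1 <- sort(unique(sweep_tbl[[pair[1]]]))
  g2 <- sort(unique(sweep_tbl[[pair[2]]]))
  vals <- matrix(NA_real_, length(g1), length(g2))
  i <- match(sweep_tbl[[pair[1]]], g1)
  j <- match(sweep_tbl[[pair[2]]], g2)
  ok <- sweep_tbl$ok
  vals[cbind(i[ok], j[ok])] <-
    predict_probability(logistic, sweep_tbl$safety_factor[ok])
  miss <- is.na(vals)
  if (mean(miss) > 0.5)
    pf_stop("pf_coverage_error", "more than 50%% of map cells missing")
  if (any(miss)) {
    fill1 <- function(v, g) {
      if (all(is.na(v)) || !any(is.na(v))) return(v)
      approx(g[!is.na(v)], v[!is.na(v)], xout = g, rule = 2)$y
    }
    for (jj in seq_along(g2)) vals[, jj] <- fill1(vals[, jj], g1)
    for (ii in seq_along(g1)) vals[ii, ] <- fill1(vals[ii, ], g2)
  }
  vals <- pmin(pmax(vals, 0), 1)
  structure(list(param1 = list(name = pair[1], grid = g1),
                 param2 = list(name = pair[2], grid = g2),
                 values = vals, interpolated = miss,
                 provenance = list(backend = attr(sweep_tbl, "backend"),
                                   interp_frac = mean(miss))),
            class = "pf_probability_map")
}

sample_moments <- function(p) {
  m <- mean(p); d <- p - m
  v <- mean(d^2)
  list(var = v,
       skew = if (v > 0) mean(d^3) / v^1.5 else NA_real_,
       kurt = if (v > 0) mean(d^4) / v^2 else NA_real_)
}

density_moments <- function(p, x) {
  w <- p / sum(p)
  m <- sum(w * x); d <- x - m
  v <- sum(w * d^2)
  list(var = v,
       skew = if (v > 0) sum(w * d^3) / v^1.5 else NA_real_,
       kurt = if (v > 0) sum(w * d^4) / v^2 else NA_real_)
}

#' Bivariate statistics of a probability map
#'
#' For each fixed value of the second parameter, the probability profile
#' along the first parameter is summarised by its variance, skewness and
#' kurtosis, and the row statistics are averaged into a single triple for the
#' map. Two row conventions are available: `"values"` (default) takes
#' unweighted sample moments of the probability values along the row — a
#' mostly-successful row with a few failures is then strongly left-skewed and
#' leptokurtic; `"density"` normalizes the profile to unit mass and takes
#' positional moments of the resulting distribution over the parameter axis.
#' Zero-variance rows contribute variance 0 and are excluded from the
#' skewness/kurtosis averages (count reported).
#'
#' @param map A [probability_map()].
#' @param convention `"values"` or `"density"`.
#' @return A `pf_map_stats`: `kurtosis`, `variance`, `skewness`,
#'   `n_degenerate_rows`.
#' @export
map_statistics <- function(map, convention = c("values", "density")) {
  convention <- match.arg(convention)
  v <- map$values
  rows <- lapply(seq_along(map$param2$grid), function(j) {
    p <- v[, j]
    if (convention == "values") sample_moments(p)
    else if (sum(p) > 0) density_moments(p, map$param1$grid)
    else list(var = 0, skew = NA_real_, kurt = NA_real_)
  })
  vars <- vapply(rows, `[[`, 0, "var")
  sk <- vapply(rows, `[[`, 0, "skew")
  ku <- vapply(rows, `[[`, 0, "kurt")
  degen <- !is.finite(sk)
  if (all(degen))
    pf_stop("pf_degenerate_map", "all rows have zero variance")
  structure(list(kurtosis = mean(ku[!degen]), variance = mean(vars),
                 skewness = mean(sk[!degen]),
                 n_degenerate_rows = sum(degen), convention = convention),
            class = "pf_map_stats")
}

#' Multi-variable regression of safety factor on the design parameters
#'
#' Ordinary least squares of the safety factor on the eight parameters in
#' their design units, reporting coefficients, 95% confidence intervals and
#' p-values sorted by ascending p (ties broken by |t|). Standardized
#' coefficients are also attached.
#'
#' @param sweep_tbl A sweep covering all eight parameters (e.g. a
#'   Latin-hypercube [sweep_design()]), with at least 10x more points than
#'   parameters.
#' @return A `pf_regression` with a `table` data frame.
#' @export
regress_safety_factor <- function(sweep_tbl) {
  pnames <- names(.ds_params)
  stopifnot(all(pnames %in% names(sweep_tbl)))
  tbl <- sweep_tbl[sweep_tbl$ok, ]
  if (nrow(tbl) < 10 * length(pnames))
    pf_stop("pf_insufficient_data", "need >= %d points", 10 * length(pnames))
  nvar <- vapply(tbl[pnames], function(x) var(x) > 0, TRUE)
  if (any(!nvar))
    pf_stop("pf_collinearity_error", "constant predictors: %s",
            paste(pnames[!nvar], collapse = ", "))
  X <- scale(as.matrix(tbl[pnames]))
  cn <- kappa(cbind(1, X), exact = TRUE)
  if (cn > 1e8) {
    cm <- abs(cor(tbl[pnames])); diag(cm) <- 0
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pf_stop("pf_collinearity_error", "collinear design (condition %g): %s",
            cn, paste(pnames[worst], collapse = " vs "))
  }
  f <- stats::as.formula(paste("safety_factor ~", paste(pnames, collapse = " + ")))
  fit <- lm(f, data = tbl)
  sm <- summary(fit)$coefficients
  ci <- confint(fit)
  rows <- data.frame(parameter = pnames,
                     coefficient = sm[pnames, "Estimate"],
                     ci_lo = ci[pnames, 1], ci_hi = ci[pnames, 2],
                     t = sm[pnames, "t value"],
                     p_value = sm[pnames, "Pr(>|t|)"],
                     unit = vapply(.ds_params[pnames], `[[`, "", "unit"))
  rows <- rows[order(rows$p_value, -abs(rows$t)), ]
  rownames(rows) <- NULL
  sdX <- apply(as.matrix(tbl[pnames]), 2, sd)
  rows$std_coefficient <- rows$coefficient * sdX[rows$parameter] /
    sd(tbl$safety_factor)
  structure(list(table = rows, fit = fit, n = nrow(tbl)),
            class = "pf_regression")
}

#' @export
print.pf_regression <- function(x, ...) {
  cat(sprintf("Safety-factor regression on %d design points\n", x$n))
  print(format(x$table, digits = 3), row.names = FALSE)
  invisible(x)
}
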