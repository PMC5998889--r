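#' Settings of the leave-one-out intensity estimator
#'
#' @param lambda_offset Positive offset `lambda` (default 2): the intensity
#'   of a point that the parent model explains perfectly. With a
#'   well-calibrated fit the squared studentized leave-one-out residual has
#'   mean about 1, so `lambda = 2` makes well-explained points score about
#'   +1 and poorly explained points negative.
#' @param sigma_floor Lower bound on every estimated scale (default 1e-8),
#'   keeping exactly-fit genes finite.
#' @param fit Regression used for the leave-one-out fits: `"mm"` (default,
#'   high-breakdown MM-estimation via [MASS::rlm()], robust to time points
#'   where the regulation is switched off), `"huber"` (Huber M-estimation)
#'   or `"ols"` (ordinary least squares via [fit_parent_model()]).
#' @param rho_cap Cap on the absolute studentized residual (default 5): a
#'   single aberrant point can depress an intensity to at most
#'   `lambda - rho_cap^2`, so one outlier cannot veto a whole period.
#' @return An `IntensityConfig` list.
#' @export
intensity_config <- function(lambda_offset = 2, sigma_floor = 1e-8,
                             fit = c("mm", "huber", "ols"), rho_cap = 5) {
  if (lambda_offset <= 0) stop("lambda_offset must be > 0", call. = FALSE)
  if (sigma_floor <= 0) stop("sigma_floor must be > 0", call. = FALSE)
  if (rho_cap <= 0) stop("rho_cap must be > 0", call. = FALSE)
  structure(list(lambda_offset = lambda_offset, sigma_floor = sigma_floor,
                 fit = match.arg(fit), rho_cap = rho_cap),
            class = "IntensityConfig")
}

#' Ordinary least-squares fit of a child gene on its parents
#'
#' Fits `child ~ intercept + parents` by OLS. A rank-deficient design is
#' fitted through pivoting (aliased coefficients set to zero) and flagged
#' degenerate, so a constant parent leaves the intercept at the child mean.
#'
#' @param child_values Numeric response vector over a subset of time points.
#' @param parent_values Numeric matrix (same rows) of parent expressions.
#' @param config An [intensity_config()]; supplies the scale floor.
#' @return List with `coefficients` (intercept first), `residual_scale`
#'   (`sqrt(RSS / (n - p - 1))`, floored at `sigma_floor`) and a
#'   `degenerate` flag.
#' @export
fit_parent_model <- function(child_values, parent_values,
                             config = intensity_config()) {
  y <- as.numeric(child_values)
  X <- as.matrix(parent_values)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("child and parent values differ in length", call. = FALSE)
  if (n < p + 2L) {
    stop("too few points: need at least ", p + 2L, " for ", p, " parent(s)",
         call. = FALSE)
  }
  D <- cbind("(Intercept)" = 1, X)
  fit <- stats::lm.fit(D, y)
  coefs <- fit$coefficients
  degenerate <- anyNA(coefs)
  coefs[is.na(coefs)] <- 0
  rss <- sum((y - drop(D %*% coefs))^2)
  scale <- max(sqrt(rss / (n - p - 1L)), config$sigma_floor)
  list(coefficients = coefs, residual_scale = scale, degenerate = degenerate)
}

# One leave-one-out pass over a child gene: robust (or OLS) fit on all
# points but j, then the intensity
#   M_j = lambda * max(0, 1 - (s_model / s_null)^2) - min(rho_j^2, cap^2)
# where rho_j is the prediction-error-scaled (studentized) residual of the
# held-out point. The first term is the robust fraction of the child's
# variation that the parents explain; the second the held-out surprise.
loo_gene_intensity <- function(y, X, config) {
  n <- length(y)
  p <- ncol(X)
  cap2 <- config$rho_cap^2
  out <- numeric(n)
  for (j in seq_len(n)) {
    yt <- y[-j]
    Dt <- cbind(1, X[-j, , drop = FALSE])
    cf <- switch(config$fit,
      ols = fit_parent_model(yt, X[-j, , drop = FALSE], config)$coefficients,
      tryCatch(
        suppressWarnings(stats::coef(MASS::rlm(
          Dt, yt, intercept = FALSE, maxit = 60,
          method = if (config$fit == "mm") "MM" else "M"))),
        error = function(e) fit_parent_model(yt, X[-j, , drop = FALSE],
                                             config)$coefficients))
    res <- yt - drop(Dt %*% cf)
    if (config$fit == "ols") {
      s_model <- sqrt(sum(res^2) / (n - 1L - p - 1L))
      s_null <- stats::sd(yt)
    } else {
      s_model <- stats::mad(res, center = 0)
      s_null <- stats::mad(yt)
    }
    s_model <- max(s_model, config$sigma_floor)
    s_null <- max(s_null, config$sigma_floor)
    xj <- c(1, X[j, ])
    lev <- tryCatch(sqrt(1 + drop(crossprod(xj, solve(crossprod(Dt), xj)))),
                    error = function(e) sqrt(2))
    rho2 <- min(((y[j] - sum(cf * xj)) / (s_model * lev))^2, cap2)
    out[j] <- config$lambda_offset * max(0, 1 - (s_model / s_null)^2) - rho2
  }
  out
}

#' Leave-one-out regulation intensities
#'
#' For every regulated gene, each time point is held out in turn, the gene
#' is regressed on its parents over the remaining points, and the held-out
#' point is scored by how well the parent model predicts it relative to the
#' model's residual scale and to the gene's own variability. Genes without
#' parents get no row. The result is invariant to affine rescaling of a
#' child gene and carries no temporal smoothing: permuting time points
#' permutes the columns identically.
#'
#' @param profile An `ExpressionProfile`.
#' @param network A `RegulatoryNetwork`; every regulated gene and all its
#'   parents must be present in the profile.
#' @param config An [intensity_config()].
#' @return An `IntensityMatrix` over the regulated genes.
#' @export
loo_intensity <- function(profile, network, config = intensity_config()) {
  stopifnot(inherits(profile, "ExpressionProfile"),
            inherits(network, "RegulatoryNetwork"))
  genes <- regulated_genes(network)
  if (length(genes) == 0L) stop("network has no regulated genes", call. = FALSE)
  n_time <- ncol(profile$values)
  rows <- matrix(NA_real_, length(genes), n_time,
                 dimnames = list(genes, NULL))
  for (g in genes) {
    if (!g %in% rownames(profile$values)) {
      stop("regulated gene ", shQuote(g), " missing from the expression profile",
           call. = FALSE)
    }
    pa <- parents(network, g)
    missing <- setdiff(pa, rownames(profile$values))
    if (length(missing) > 0L) {
      stop("parent(s) of ", shQuote(g), " missing from the profile: ",
           paste(shQuote(missing), collapse = ", "), call. = FALSE)
    }
    if (n_time < length(pa) + 3L) {
      stop("too few time points for gene ", shQuote(g), ": need at least ",
           length(pa) + 3L, call. = FALSE)
    }
    X <- t(profile$values[pa, , drop = FALSE])
    rows[g, ] <- loo_gene_intensity(profile$values[g, ], X, config)
  }
  intensity_matrix(rows, profile$time_points)
}
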