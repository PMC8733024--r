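#' Build design matrices for the marker-based model
#'
#' Assembles the response and incidence structures of the Bayesian ridge
#' marker model `y = X b + Z W m + e`: `X` holds an intercept plus
#' reference-coded year contrasts (the first year is the reference, so `X`
#' is full rank with one column per additional year), `Z` maps phenotype
#' records to lines (kept as an index vector since each record belongs to
#' exactly one line) and `W` is the line-by-marker dosage matrix, used
#' uncentred (the intercept absorbs the mean).
#'
#' @param phenotypes Tibble with `id`, `year` and `value` columns; repeated
#'   records of a line share its `W` row.
#' @param genotypes Numeric/integer marker dosage matrix with line ids as
#'   rownames; every phenotyped line must be present.
#' @return A `design_matrices` list: `y`, `X`, `line` (record -> row of `W`),
#'   `W`, `line_ids`, `marker_ids`, `years`.
#' @export
build_design <- function(phenotypes, genotypes) {
  miss <- setdiff(unique(phenotypes$id), rownames(genotypes))
  if (length(miss) > 0L)
    stopf("phenotyped lines without genotypes: %s%s",
          paste(head(miss, 5L), collapse = ", "),
          if (length(miss) > 5L) sprintf(" (+%d more)", length(miss) - 5L) else "")
  line_ids <- rownames(genotypes)
  years <- sort(unique(phenotypes$year))
  X <- matrix(1, nrow(phenotypes), 1L, dimnames = list(NULL, "(Intercept)"))
  if (length(years) > 1L) {
    yr <- factor(phenotypes$year, levels = years)
    contrasts <- stats::model.matrix(~yr)[, -1L, drop = FALSE]
    colnames(contrasts) <- paste0("year", years[-1L])
    X <- cbind(X, contrasts)
  }
  structure(list(y = phenotypes$value, X = X,
                 line = match(phenotypes$id, line_ids),
                 W = as.matrix(genotypes),
                 line_ids = line_ids,
                 marker_ids = colnames(genotypes),
                 years = years),
            class = "design_matrices")
}

#' @export
print.design_matrices <- function(x, ...) {
  cat(sprintf("<design_matrices> n_y = %d, n_b = %d, n_i = %d, n_m = %d\n",
              length(x$y), ncol(x$X), nrow(x$W), ncol(x$W)))
  invisible(x)
}

# Record-level marker matrix M = Z W and the mixed-model coefficient matrix
#   C = [X'X, X'M; M'X, M'M + I * lambda],  lambda = s2e / s2m,
# plus the right-hand side [X'y; M'y].
mme_system <- function(design, varcomp) {
  if (varcomp$sigma2_m <= 0 || varcomp$sigma2_e <= 0)
    stopf("variance components must be strictly positive")
  lambda <- varcomp$sigma2_e / varcomp$sigma2_m
  M <- design$W[design$line, , drop = FALSE]
  X <- design$X
  n_m <- ncol(M)
  C <- rbind(cbind(crossprod(X), crossprod(X, M)),
             cbind(crossprod(M, X), crossprod(M) + diag(lambda, n_m)))
  list(C = C, rhs = c(crossprod(X, design$y), crossprod(M, design$y)),
       n_b = ncol(X), n_m = n_m, lambda = lambda)
}

#' Solve Henderson's mixed model equations
#'
#' Returns the conditional expectation `E(b, m | y, s2m, s2e)` of the fixed
#' and marker effects given the variance components, i.e. the
#' generalised-ridge solution with shrinkage `lambda = s2e / s2m` on the
#' marker block.
#'
#' @param design A `design_matrices` object.
#' @param varcomp List/vector with `sigma2_m` and `sigma2_e` (positive).
#' @return List with `b` (fixed-effect estimates) and `m` (marker BLUPs).
#' @export
solve_mme <- function(design, varcomp) {
  sys <- mme_system(design, as.list(varcomp))
  R <- tryCatch(chol(sys$C), error = function(e)
    stopf("mixed-model coefficient matrix not positive definite (collinear fixed effects?): %s",
          conditionMessage(e)))
  sol <- backsolve(R, forwardsolve(R, sys$rhs, upper.tri = TRUE,
                                   transpose = TRUE))
  list(b = setNames(sol[seq_len(sys$n_b)], colnames(design$X)),
       m = setNames(sol[-seq_len(sys$n_b)], design$marker_ids))
}

#' Chain settings for posterior sampling
#'
#' Defaults follow the reference analysis scale: 100,000 iterations, 10,000
#' burn-in, every 100th draw kept, giving 900 retained samples. Tests and
#' examples use reduced profiles.
#'
#' @param n_iter,burnin,thin MCMC settings; `(n_iter - burnin) / thin` must
#'   be a positive integer (the retained sample count).
#' @return A `chain_control` list with the derived `n_samples`.
#' @export
chain_control <- function(n_iter = 100000L, burnin = 10000L, thin = 100L) {
  n_iter <- as.integer(n_iter); burnin <- as.integer(burnin)
  thin <- as.integer(thin)
  if (burnin >= n_iter || thin < 1L)
    stopf("need burnin < n_iter and thin >= 1")
  if ((n_iter - burnin) %% thin != 0L)
    stopf("(n_iter - burnin) must be a multiple of thin")
  structure(list(n_iter = n_iter, burnin = burnin, thin = thin,
                 n_samples = (n_iter - burnin) %/% thin),
            class = "chain_control")
}

new_effect_samples <- function(b, m, varcomp, approach, chain, seed,
                               marker_ids) {
  colnames(m) <- marker_ids
  structure(list(b = b, m = m, varcomp = varcomp, approach = approach,
                 chain = chain, seed = seed, marker_ids = marker_ids),
            class = "effect_samples")
}

#' @export
print.effect_samples <- function(x, ...) {
  cat(sprintf("<effect_samples> %d draws x %d markers (%s)\n", nrow(x$m),
              ncol(x$m), x$approach))
  invisible(x)
}

#' Sample effects from their conditional posterior (empirical Bayes)
#'
#' Draws from the multivariate normal `N(E(b, m | y), Var(b, m | y))` with
#' the variance components plugged in: the mean is the mixed-model solution
#' and the covariance is the inverse coefficient matrix times `s2e`. One
#' Cholesky factorisation of the coefficient matrix serves both the mean and
#' all perturbation back-solves. With zero phenotype records the marker draws
#' fall back to the prior `N(0, s2m)`.
#'
#' @param design A `design_matrices` object.
#' @param varcomp List/vector with positive `sigma2_m`, `sigma2_e`.
#' @param n_samples Number of posterior draws (default 900).
#' @param seed Integer seed.
#' @return An `effect_samples` object with fixed plug-in variances.
#' @export
sample_effects_conditional <- function(design, varcomp, n_samples = 900L,
                                       seed = 1L) {
  varcomp <- as.list(varcomp)
  if (n_samples < 1L) stopf("n_samples must be >= 1")
  set.seed(sub_seed(seed, "conditional"))
  n_m <- ncol(design$W)
  vc_tbl <- tibble::tibble(draw = seq_len(n_samples),
                           sigma2_m = varcomp$sigma2_m,
                           sigma2_e = varcomp$sigma2_e)
  if (length(design$y) == 0L) {
    m <- matrix(rnorm(n_samples * n_m, sd = sqrt(varcomp$sigma2_m)),
                n_samples, n_m)
    b <- matrix(0, n_samples, ncol(design$X))
    return(new_effect_samples(b, m, vc_tbl, "empirical", NULL, seed,
                              design$marker_ids))
  }
  sys <- mme_system(design, varcomp)
  R <- chol(sys$C)
  mean_vec <- backsolve(R, forwardsolve(R, sys$rhs, upper.tri = TRUE,
                                        transpose = TRUE))
  p <- sys$n_b + sys$n_m
  Zs <- matrix(rnorm(p * n_samples), p, n_samples)
  draws <- mean_vec + sqrt(varcomp$sigma2_e) * backsolve(R, Zs)
  b <- t(draws[seq_len(sys$n_b), , drop = FALSE])
  m <- t(draws[-seq_len(sys$n_b), , drop = FALSE])
  colnames(b) <- colnames(design$X)
  new_effect_samples(b, m, vc_tbl, "empirical", NULL, seed,
                     design$marker_ids)
}

#' Full-Bayes Gibbs sampler for the marker model
#'
#' Single-site Gibbs sampling with residual updating over fixed effects
#' (flat prior) and marker effects (common normal prior), and
#' scaled-inverse-chi-square updates for the marker-effect and residual
#' variances. Default hyperpriors use 4 degrees of freedom with scales from
#' an even split of the phenotypic variance: the residual scale is half of
#' `var(y)` and the marker scale is the other half divided by the summed
#' marker-dosage variances.
#'
#' @param design A `design_matrices` object.
#' @param chain A [chain_control()] object.
#' @param priors Optional list overriding `nu_m`, `scale_m`, `nu_e`,
#'   `scale_e` (all positive).
#' @param update_variances Set `FALSE` to hold the variances fixed at their
#'   initial values (the chain then samples the conditional MVN of the
#'   effects).
#' @param varcomp_init Optional starting values for `sigma2_m`, `sigma2_e`.
#' @param seed Integer seed.
#' @return An `effect_samples` object with per-draw variance components.
#' @export
gibbs_fit <- function(design, chain = chain_control(), priors = NULL,
                      update_variances = TRUE, varcomp_init = NULL,
                      seed = 1L) {
  y <- design$y
  vy <- var_1n(y)
  sum_wvar <- sum(apply(design$W, 2L, var_1n))
  default <- list(nu_m = 4, scale_m = 0.5 * vy / max(sum_wvar, 1e-12),
                  nu_e = 4, scale_e = 0.5 * vy)
  pr <- utils::modifyList(default, priors %||% list())
  if (any(unlist(pr) <= 0)) stopf("hyperparameters must be positive")
  init <- utils::modifyList(list(sigma2_m = pr$scale_m, sigma2_e = pr$scale_e),
                            varcomp_init %||% list())
  set.seed(sub_seed(seed, "gibbs"))
  M <- design$W[design$line, , drop = FALSE]
  res <- gibbs_ridge_cpp(y, design$X, M, chain$n_iter, chain$burnin,
                         chain$thin, pr$nu_m, pr$scale_m, pr$nu_e, pr$scale_e,
                         init$sigma2_m, init$sigma2_e, update_variances)
  colnames(res$b) <- colnames(design$X)
  vc <- tibble::tibble(draw = seq_len(nrow(res$m)),
                       sigma2_m = res$sigma2_m, sigma2_e = res$sigma2_e)
  new_effect_samples(res$b, res$m, vc, "full", chain, seed,
                     design$marker_ids)
}

#' Truncated SVD of a marker matrix
#'
#' Column-centres `W` and returns the leading principal-component structure:
#' scores `T = U S`, orthonormal loadings `V` and the cumulative fraction of
#' marker-genotype variation explained (leading squared singular values over
#' the total). Requests beyond `min(dim(W))` are capped there, where the
#' explained fraction is exactly 1; components beyond the numerical rank get
#' zero scores and loadings.
#'
#' @param W Line-by-marker dosage matrix.
#' @param n_components Number of leading components to keep.
#' @return A `reduced_design` list: `T`, `V`, `d` (singular values),
#'   `explained` (cumulative fractions), `center`, `n_components`.
#' @export
svd_reduce <- function(W, n_components) {
  W <- as.matrix(W)
  k_max <- min(dim(W))
  if (n_components < 1L) stopf("n_components must be >= 1")
  k <- min(as.integer(n_components), k_max)
  ctr <- colMeans(W)
  Wc <- sweep(W, 2L, ctr)
  if (nrow(Wc) <= ncol(Wc)) {
    ee <- eigen(tcrossprod(Wc), symmetric = TRUE)
    total <- sum(pmax(ee$values, 0))
    d <- sqrt(pmax(ee$values[seq_len(k)], 0))
    U <- ee$vectors[, seq_len(k), drop = FALSE]
    pos <- d > max(d[1], 1) * 1e-9
    V <- matrix(0, ncol(Wc), k)
    if (any(pos))
      V[, pos] <- sweep(crossprod(Wc, U[, pos, drop = FALSE]), 2L, d[pos], "/")
    U[, !pos] <- 0
  } else {
    sv <- svd(Wc, nu = k, nv = k)
    total <- sum(sv$d^2)
    d <- sv$d[seq_len(k)]
    pos <- d > max(d[1], 1) * 1e-9
    U <- sv$u; V <- sv$v
    U[, !pos] <- 0; V[, !pos] <- 0; d[!pos] <- 0
  }
  d[!pos] <- 0
  scores <- sweep(U, 2L, d, "*")
  rownames(scores) <- rownames(W)
  rownames(V) <- colnames(W)
  structure(list(T = scores, V = V, d = d,
                 explained = cumsum(d^2) / total, center = ctr,
                 n_components = k),
            class = "reduced_design")
}

#' @export
print.reduced_design <- function(x, ...) {
  cat(sprintf("<reduced_design> %d components, %.1f%% of marker variation\n",
              x$n_components, 100 * x$explained[x$n_components]))
  invisible(x)
}

#' Back-transform component-effect samples to marker effects
#'
#' Maps principal-component effect draws back to the marker scale through
#' the SVD loadings: `m = V s` per draw.
#'
#' @param component_samples Draws-by-components matrix of component effects.
#' @param V Loading matrix (markers x components) from [svd_reduce()].
#' @return Draws-by-markers matrix of approximated marker-effect samples.
#' @export
backtransform_effects <- function(component_samples, V) {
  if (ncol(component_samples) != ncol(V))
    stopf("component dimension mismatch: %d draws columns vs %d loadings",
          ncol(component_samples), ncol(V))
  out <- component_samples %*% t(V)
  colnames(out) <- rownames(V)
  out
}

#' Fit the marker-based model
#'
#' End-to-end fit of the Bayesian ridge marker model on a phenotype table and
#' marker dosage matrix. `approach = "full"` runs the Gibbs sampler over all
#' parameters; `approach = "empirical"` first estimates the variance
#' components as posterior means of a full-Bayes run (unless supplied) and
#' then draws effect samples from the conditional multivariate normal.
#' Setting `n_components` fits the reduced model on truncated-SVD scores and
#' back-transforms the component draws to marker effects.
#'
#' @param phenotypes Tibble with `id`, `year`, `value`.
#' @param genotypes Line-by-marker dosage matrix with rownames.
#' @param approach `"full"` or `"empirical"`.
#' @param n_components Optional number of leading principal components.
#' @param chain A [chain_control()].
#' @param priors Optional hyperprior overrides, see [gibbs_fit()].
#' @param varcomp Optional plug-in variance components for the empirical
#'   approach (list with `sigma2_m`, `sigma2_e`).
#' @param seed Integer seed.
#' @return A `marker_fit` object: the `effect_samples`, the design, and for
#'   reduced fits the `reduced_design`.
#' @export
fit_marker_model <- function(phenotypes, genotypes,
                             approach = c("full", "empirical"),
                             n_components = NULL, chain = chain_control(),
                             priors = NULL, varcomp = NULL, seed = 1L) {
  approach <- match.arg(approach)
  design <- build_design(phenotypes, genotypes)
  reduced <- NULL
  fit_design <- design
  if (!is.null(n_components)) {
    reduced <- svd_reduce(design$W, n_components)
    fit_design <- design
    fit_design$W <- reduced$T
    fit_design$marker_ids <- sprintf("PC%04d", seq_len(reduced$n_components))
  }
  if (approach == "full") {
    samples <- gibbs_fit(fit_design, chain = chain, priors = priors,
                         seed = seed)
  } else {
    if (is.null(varcomp)) {
      pre <- gibbs_fit(fit_design, chain = chain, priors = priors,
                       seed = sub_seed(seed, "varcomp"))
      varcomp <- list(sigma2_m = mean(pre$varcomp$sigma2_m),
                      sigma2_e = mean(pre$varcomp$sigma2_e))
    }
    samples <- sample_effects_conditional(fit_design, varcomp,
                                          n_samples = chain$n_samples,
                                          seed = seed)
    samples$chain <- chain
  }
  if (!is.null(reduced)) {
    samples$component_samples <- samples$m
    samples$m <- backtransform_effects(samples$m, reduced$V)
    samples$marker_ids <- design$marker_ids
  }
  structure(list(samples = samples, design = design, reduced = reduced,
                 approach = approach, seed = seed),
            class = "marker_fit")
}

#' @export
print.marker_fit <- function(x, ...) {
  cat(sprintf("<marker_fit> %s Bayes%s: %d draws, %d markers, %d records\n",
              x$approach,
              if (is.null(x$reduced)) ""
              else sprintf(" (reduced, %d components)",
                           x$reduced$n_components),
              nrow(x$samples$m), ncol(x$design$W), length(x$design$y)))
  invisible(x)
}

#' @describeIn fit_marker_model Posterior summaries per model term (fixed
#'   effects and, optionally, markers).
#' @param x A `marker_fit`.
#' @param markers Include per-marker rows (default `FALSE`; there are many).
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.marker_fit <- function(x, markers = FALSE, ...) {
  b <- x$samples$b
  out <- tibble::tibble(term = colnames(b), type = "fixed",
                        estimate = colMeans(b),
                        std.error = apply(b, 2L, stats::sd))
  if (markers) {
    m <- x$samples$m
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = x$samples$marker_ids, type = "marker",
      estimate = colMeans(m), std.error = apply(m, 2L, stats::sd)))
  }
  out
}

#' @describeIn fit_marker_model One-row model overview with posterior-mean
#'   variance components.
#' @exportS3Method generics::glance
#' @export
glance.marker_fit <- function(x, ...) {
  tibble::tibble(approach = x$approach,
                 n_records = length(x$design$y),
                 n_lines = nrow(x$design$W),
                 n_markers = ncol(x$design$W),
                 n_components = if (is.null(x$reduced)) NA_integer_
                                else x$reduced$n_components,
                 n_draws = nrow(x$samples$m),
                 sigma2_m = mean(x$samples$varcomp$sigma2_m),
                 sigma2_e = mean(x$samples$varcomp$sigma2_e))
}
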