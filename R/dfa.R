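## Linear discriminant classification of calls to individuals, per-variable
## contributions (partial Wilks' lambda), and the label-permutation chance
## level. Classification uses Fisher linear classification functions built
## from the pooled within-group covariance and group means; the default
## accuracy is resubstitution (training calls classified by the fitted
## functions), whose overfitting inflation above 1/k is exactly what the
## permutation null measures.

.dfa_matrix <- function(data, group, vars) {
  if (!group %in% names(data)) stop("grouping column `", group, "` not found")
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("feature table lacks variables: ", paste(miss, collapse = ", "))
  X <- as.matrix(data[, vars, drop = FALSE])
  if (!is.numeric(X)) stop("selected variables must be numeric")
  if (anyNA(X)) stop("missing values among selected variables")
  g <- factor(data[[group]])
  list(X = X, g = g)
}

## fast core: classification-function fit + resubstitution accuracy (%)
.dfa_resub_accuracy <- function(X, g) {
  n <- nrow(X)
  ng <- as.vector(table(g))
  M <- rowsum(X, g) / ng
  Xc <- X - M[as.integer(g), , drop = FALSE]
  W <- crossprod(Xc) / (n - nlevels(g))
  A <- M %*% solve(W)
  c0 <- -0.5 * rowSums(A * M)
  S <- X %*% t(A) + rep(c0, each = n)
  100 * mean(max.col(S, ties.method = "first") == as.integer(g))
}

#' Fit discriminant classification functions
#'
#' Computes group means, the pooled within-group covariance, and one linear
#' classification function per group (coefficients `W^-1 mu_g`, constant
#' `-mu_g' W^-1 mu_g / 2 + log prior_g`). Priors are equal by default (the
#' design is near-balanced); proportional priors are available.
#'
#' @param data Feature table: one row per call, containing `group` and `vars`.
#' @param group Name of the grouping column (default `"individual_id"`).
#' @param vars Variables to use; default the 11 of [dfa_default_vars()].
#' @param prior `"equal"` or `"proportional"`.
#' @param ridge If `TRUE`, add `1e-8 * trace(W)/p` to the diagonal of the
#'   pooled covariance (explicit opt-in for near-singular tables).
#' @return A `dfa_model`.
#' @export
fit_dfa <- function(data, group = "individual_id", vars = dfa_default_vars(),
                    prior = c("equal", "proportional"), ridge = FALSE) {
  prior <- match.arg(prior)
  dm <- .dfa_matrix(data, group, vars)
  X <- dm$X; g <- dm$g
  n <- nrow(X); p <- ncol(X); k <- nlevels(g)
  if (k < 2L) stop("need at least two groups")
  ng <- as.vector(table(g))
  if (any(ng < 2L))
    stop("every group needs at least 2 rows; offending: ",
         paste(levels(g)[ng < 2L], collapse = ", "))
  if (n <= p + k)
    stop("too few rows (", n, ") for ", p, " variables and ", k,
         " groups; pooled covariance would be singular or near-singular")
  M <- rowsum(X, g) / ng
  Xc <- X - M[as.integer(g), , drop = FALSE]
  W <- crossprod(Xc) / (n - k)
  if (ridge) W <- W + diag(1e-8 * sum(diag(W)) / p, p)
  ## rank test on the correlation-scaled matrix so heterogeneous variable
  ## units (seconds vs hertz) cannot masquerade as rank deficiency
  dw <- sqrt(diag(W))
  if (any(dw <= 0))
    stop("pooled within-group covariance is singular; collinear variable(s): ",
         paste(vars[dw <= 0], collapse = ", "))
  qrW <- qr(W / tcrossprod(dw))
  if (qrW$rank < p) {
    bad <- vars[qrW$pivot[(qrW$rank + 1L):p]]
    stop("pooled within-group covariance is singular; collinear variable(s): ",
         paste(bad, collapse = ", "))
  }
  Winv <- tryCatch(chol2inv(chol(W)), error = function(e)
    stop("pooled within-group covariance is not positive definite: ",
         conditionMessage(e), call. = FALSE))
  A <- M %*% Winv
  c0 <- -0.5 * rowSums(A * M)
  pri <- if (prior == "equal") rep(1 / k, k) else ng / n
  structure(list(
    levels = levels(g), counts = ng, means = M, pooled_cov = W,
    coef = A, const = c0 + log(pri), prior = prior, priors = pri,
    vars = vars, group_col = group, n = n
  ), class = "dfa_model")
}

#' @export
print.dfa_model <- function(x, ...) {
  cat(sprintf("<dfa_model: %d groups, %d variables, n = %d, %s priors>\n",
              length(x$levels), length(x$vars), x$n, x$prior))
  invisible(x)
}

#' Classify calls with fitted discriminant functions
#'
#' Each call is assigned to the group with the highest classification score;
#' ties (astronomically rare with continuous features) go to the lowest group
#' index. Classifying the training table itself gives resubstitution
#' accuracy — the conventional "percent correct assignment".
#'
#' @param model A `dfa_model` from [fit_dfa()].
#' @param data Feature table with the model's variables and grouping column.
#' @return A `dfa_classification`: confusion matrix (true x assigned),
#'   per-group percent correct, average percent correct (total correct /
#'   total calls), `n_calls`, `n_groups` and the assigned labels.
#' @export
classify <- function(model, data) {
  stopifnot(inherits(model, "dfa_model"))
  miss <- setdiff(model$vars, names(data))
  if (length(miss))
    stop("table lacks model variables: ", paste(miss, collapse = ", "))
  X <- as.matrix(data[, model$vars, drop = FALSE])
  if (anyNA(X)) stop("missing values among model variables")
  truth <- factor(data[[model$group_col]], levels = model$levels)
  if (anyNA(truth))
    stop("table contains groups unknown to the model: ",
         paste(setdiff(unique(data[[model$group_col]]), model$levels),
               collapse = ", "))
  S <- X %*% t(model$coef) + rep(model$const, each = nrow(X))
  assigned <- factor(model$levels[max.col(S, ties.method = "first")],
                     levels = model$levels)
  confusion <- table(true = truth, assigned = assigned)
  correct <- diag(confusion)
  sizes <- rowSums(confusion)
  structure(list(
    confusion = confusion,
    per_group_pct = 100 * correct / sizes,
    average_pct = 100 * sum(correct) / nrow(X),
    n_calls = nrow(X), n_groups = length(model$levels),
    assigned = assigned
  ), class = "dfa_classification")
}

#' @export
print.dfa_classification <- function(x, ...) {
  cat(sprintf("<dfa_classification: %.1f%% correct (%d calls, %d groups)>\n",
              x$average_pct, x$n_calls, x$n_groups))
  invisible(x)
}

#' Leave-one-out discriminant classification
#'
#' Refits the model without each call in turn and classifies the held-out
#' call — the cross-validated counterpart of resubstitution accuracy.
#'
#' @inheritParams fit_dfa
#' @return A `dfa_classification`.
#' @export
classify_loo <- function(data, group = "individual_id",
                         vars = dfa_default_vars(),
                         prior = c("equal", "proportional")) {
  prior <- match.arg(prior)
  dm <- .dfa_matrix(data, group, vars)
  g <- dm$g
  n <- nrow(dm$X)
  assigned <- character(n)
  for (i in seq_len(n)) {
    m <- fit_dfa(data[-i, , drop = FALSE], group, vars, prior)
    S <- dm$X[i, , drop = FALSE] %*% t(m$coef) + m$const
    assigned[i] <- m$levels[which.max(S)]
  }
  assigned <- factor(assigned, levels = levels(g))
  confusion <- table(true = g, assigned = assigned)
  correct <- diag(confusion)
  structure(list(
    confusion = confusion,
    per_group_pct = 100 * correct / rowSums(confusion),
    average_pct = 100 * sum(correct) / n,
    n_calls = n, n_groups = nlevels(g),
    assigned = assigned
  ), class = "dfa_classification")
}

#' Per-variable contribution to discrimination (partial Wilks' lambda)
#'
#' For each variable, the partial Wilks' lambda of the full model relative to
#' the model without that variable, and the corresponding F-to-remove with
#' `(k - 1, n - k - p + 1)` degrees of freedom. Smaller lambda means greater
#' unique contribution to group separation.
#'
#' @inheritParams fit_dfa
#' @return Data frame with columns `variable`, `lambda`, `F`.
#' @export
wilks_contributions <- function(data, group = "individual_id",
                                vars = dfa_default_vars()) {
  dm <- .dfa_matrix(data, group, vars)
  X <- dm$X; g <- dm$g
  n <- nrow(X); p <- ncol(X); k <- nlevels(g)
  if (k < 2L) stop("need at least two groups")
  if (n - k - p + 1 < 1)
    stop("too few rows for the F-to-remove denominator df")
  Xc_tot <- scale(X, center = TRUE, scale = FALSE)
  Tm <- crossprod(Xc_tot)
  dt <- sqrt(diag(Tm))
  if (any(dt <= 0) || qr(Tm / tcrossprod(dt))$rank < p)
    stop("variables are collinear; cannot compute partial Wilks' lambda")
  M <- rowsum(X, g) / as.vector(table(g))
  Xc_w <- X - M[as.integer(g), , drop = FALSE]
  Wm <- crossprod(Xc_w)
  ldet <- function(A) {
    d <- determinant(A, logarithm = TRUE)
    if (d$sign <= 0) stop("singular cross-product matrix: variables are collinear")
    as.numeric(d$modulus)
  }
  lam_full <- exp(ldet(Wm) - ldet(Tm))
  lambda <- numeric(p)
  for (j in seq_len(p)) {
    keep <- setdiff(seq_len(p), j)
    lam_red <- exp(ldet(Wm[keep, keep, drop = FALSE]) -
                   ldet(Tm[keep, keep, drop = FALSE]))
    lambda[j] <- lam_full / lam_red
  }
  lambda <- pmin(lambda, 1)
  Fval <- ((n - k - p + 1) / (k - 1)) * (1 - lambda) / lambda
  data.frame(variable = vars, lambda = lambda, F = Fval,
             stringsAsFactors = FALSE)
}

#' Permutation null distribution of classification accuracy
#'
#' For each permutation, call rows are randomly reassigned to groups
#' (preserving the original group sizes), the discriminant functions are
#' refitted and the average percent correct recorded. The resulting
#' distribution is the chance level against which observed accuracy is
#' judged; with resubstitution it sits well above 100/k because of
#' overfitting.
#'
#' @inheritParams fit_dfa
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @param mode `"resubstitution"` (default) or `"loo"`.
#' @return A `permutation_null`: accuracy samples (%), their mean, sd and
#'   95/99/99.9 percentiles.
#' @export
permutation_null <- function(data, group = "individual_id",
                             vars = dfa_default_vars(), n_perm = 1000,
                             seed = NULL,
                             mode = c("resubstitution", "loo")) {
  mode <- match.arg(mode)
  if (!is.numeric(n_perm) || n_perm < 1) stop("`n_perm` must be at least 1")
  dm <- .dfa_matrix(data, group, vars)
  X <- dm$X; g <- dm$g
  if (nlevels(g) < 2L) stop("need at least two groups")
  if (!is.null(seed)) set.seed(seed)
  samples <- numeric(n_perm)
  perm_data <- data
  for (b in seq_len(n_perm)) {
    gp <- sample(g)
    if (mode == "resubstitution") {
      samples[b] <- .dfa_resub_accuracy(X, gp)
    } else {
      perm_data[[group]] <- gp
      samples[b] <- classify_loo(perm_data, group, vars)$average_pct
    }
  }
  structure(list(
    samples = samples, n_perm = as.integer(n_perm),
    mean = mean(samples), sd = stats::sd(samples),
    q95 = unname(stats::quantile(samples, 0.95)),
    q99 = unname(stats::quantile(samples, 0.99)),
    q999 = unname(stats::quantile(samples, 0.999)),
    mode = mode, seed = seed
  ), class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null: %.1f +/- %.1f%% (%d permutations, %s)>\n",
              x$mean, x$sd, x$n_perm, x$mode))
  invisible(x)
}

#' Significance of an observed accuracy against the permutation null
#'
#' One-sided percentile comparison: the observed value is significant at
#' p < 0.05 / 0.01 / 0.001 when it exceeds 95% / 99% / 99.9% of the
#' permuted-accuracy samples.
#'
#' @param observed_pct Observed average percent correct.
#' @param null A `permutation_null`.
#' @return One of `"p < 0.001"`, `"p < 0.01"`, `"p < 0.05"`, `"n.s."`.
#' @export
significance <- function(observed_pct, null) {
  stopifnot(inherits(null, "permutation_null"))
  prop <- mean(observed_pct > null$samples)
  if (prop >= 0.999) "p < 0.001"
  else if (prop >= 0.99) "p < 0.01"
  else if (prop >= 0.95) "p < 0.05"
  else "n.s."
}
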