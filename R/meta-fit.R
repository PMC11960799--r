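#' Control parameters for the multilevel REML fit
#'
#' @param starts number of optimizer starts (default 3: method-of-moments,
#'   near-zero, perturbed method-of-moments).
#' @param reltol relative log-likelihood convergence tolerance.
#' @param maxit maximum optimizer iterations per start.
#' @param seed seed used for the perturbed start.
#' @param zero_tol variance components below this are reported as exactly
#'   0 (boundary solutions; on the unitless squared-SMD scale 1e-6 is far
#'   below any interpretable heterogeneity).
#' @return A list of class `meta_control`.
#' @export
meta_control <- function(starts = 3, reltol = 1e-8, maxit = 500, seed = 1L,
                         zero_tol = 1e-6) {
  structure(list(starts = starts, reltol = reltol, maxit = maxit,
                 seed = seed, zero_tol = zero_tol), class = "meta_control")
}

#' Multilevel random-effects meta-analysis with phylogenetic correlation
#'
#' Fits the marginal model `y ~ N(X beta, V)` with
#' `V = sum_l sigma2_l Z_l Z_l' + diag(vi)`, where the random-effect levels
#' are study identity, effect-size identity (one effect per record), species
#' identity, and species phylogeny (whose `Z A Z'` term uses the
#' phylogenetic correlation matrix `A`). Variance components are estimated
#' by REML with a log-variance parameterization, analytic gradients and
#' multi-start optimization; fixed effects follow by generalized least
#' squares at the REML solution. Confidence intervals are normal-based
#' (t-based available); prediction intervals add all variance components.
#'
#' For moderator models, the omnibus moderator test `Q_M` is a Wald
#' chi-square on contrasts chosen so that it tests differences among
#' moderator levels (for no-intercept level-means parameterizations) or all
#' non-intercept coefficients (for intercept models). Marginal R-squared is
#' the percentage of total variance attributable to the fixed effects:
#' `100 * var(X beta) / (var(X beta) + sum(sigma2))`.
#'
#' @param formula model formula, e.g. `yi ~ 1` (null model) or
#'   `yi ~ 0 + event_type` (level-means meta-regression).
#' @param vi sampling variances: a numeric vector or the (quoted or bare)
#'   name of a column of `data`.
#' @param data data frame holding the model variables.
#' @param study,species grouping vectors or column names for the study and
#'   species random effects.
#' @param A phylogenetic correlation matrix (or a
#'   [tree_to_correlation] result) with dimnames covering every species;
#'   required when `"phylo"` is in `random`. Species present in the data
#'   but absent from `A` abort the fit.
#' @param random character subset of `c("study", "es", "species", "phylo")`.
#' @param sigma2_fixed optional named numeric fixing some components (e.g.
#'   `c(phylo = 0)`); fixed components are not optimized.
#' @param method `"REML"` (default) or `"ML"`.
#' @param test `"z"` (default) or `"t"` critical values for CIs/PIs.
#' @param level confidence level (default 0.95).
#' @param control a [meta_control] list.
#' @return An object of class `meta_fit`; see [summary.meta_fit].
#' @export
meta_fit <- function(formula, vi, data, study = NULL, species = NULL,
                     A = NULL, random = c("study", "es", "species", "phylo"),
                     sigma2_fixed = NULL, method = c("REML", "ML"),
                     test = c("z", "t"), level = 0.95,
                     control = meta_control()) {
  method <- match.arg(method); test <- match.arg(test)
  cl <- match.call()
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  k <- length(y)
  pull <- function(arg) {
    v <- eval(arg, data, parent.frame(2))
    if (is.character(v) && length(v) == 1 && v %in% names(data))
      v <- data[[v]]
    v
  }
  vi <- pull(cl$vi)
  if (!is.numeric(vi) || length(vi) != k)
    stop("'vi' must give one sampling variance per record", call. = FALSE)
  if (any(vi <= 0)) stop("sampling variances must be > 0", call. = FALSE)
  study_v <- if (!is.null(cl$study)) pull(cl$study) else NULL
  species_v <- if (!is.null(cl$species)) pull(cl$species) else NULL

  random <- intersect(c("study", "es", "species", "phylo"), random)
  if (is.null(study_v)) random <- setdiff(random, "study")
  if (is.null(species_v)) random <- setdiff(random, c("species", "phylo"))
  if ("phylo" %in% random && is.null(A)) random <- setdiff(random, "phylo")
  if (!length(random)) stop("no random-effect levels specified",
                            call. = FALSE)
  if ("study" %in% random && length(unique(study_v)) < 2)
    stop("need at least 2 studies", call. = FALSE)

  ind <- function(g) {
    g <- factor(g)
    Z <- stats::model.matrix(~ 0 + g)
    tcrossprod(Z)
  }
  M <- list()
  if ("study" %in% random) M$study <- ind(study_v)
  if ("es" %in% random) M$es <- diag(k)
  if ("species" %in% random) M$species <- ind(species_v)
  if ("phylo" %in% random) {
    if (inherits(A, "phylo_correlation")) A <- A$A
    sp <- as.character(species_v)
    missA <- setdiff(unique(sp), rownames(A))
    if (length(missA))
      stop("species absent from the correlation matrix: ",
           paste(missA, collapse = ", "), call. = FALSE)
    Zs <- A[sp, sp, drop = FALSE]
    M$phylo <- (Zs + t(Zs)) / 2
  }
  L <- length(M)

  fixed <- rep(NA_real_, L); names(fixed) <- names(M)
  if (!is.null(sigma2_fixed)) {
    bad <- setdiff(names(sigma2_fixed), names(M))
    if (length(bad)) stop("unknown fixed components: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    fixed[names(sigma2_fixed)] <- sigma2_fixed
  }
  free <- which(is.na(fixed))

  p <- ncol(X)
  reml <- method == "REML"
  # constant terms of the (restricted) log-likelihood, metafor convention
  ll_const <- if (reml)
    0.5 * ((k - p) * log(2 * pi) - determinant(crossprod(X))$modulus[1])
  else 0.5 * k * log(2 * pi)

  # negative (restricted) log-likelihood and its pieces at sigma2
  nll_pieces <- function(sigma2) {
    V <- diag(vi, k)
    for (l in seq_len(L)) if (sigma2[l] > 0) V <- V + sigma2[l] * M[[l]]
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(NULL)
    Vinv <- chol2inv(cV)
    U <- Vinv %*% X
    XtViX <- crossprod(X, U)
    cXX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(cXX)) return(NULL)
    XtViX_inv <- chol2inv(cXX)
    beta <- XtViX_inv %*% crossprod(U, y)
    r <- y - X %*% beta
    Vir <- Vinv %*% r
    q <- sum(r * Vir)
    ld_V <- 2 * sum(log(diag(cV)))
    ld_XX <- 2 * sum(log(diag(cXX)))
    nll <- ll_const + 0.5 * (ld_V + q + if (reml) ld_XX else 0)
    list(nll = nll, Vinv = Vinv, U = U, XtViX_inv = XtViX_inv,
         beta = beta, Vir = Vir)
  }
  obj <- function(theta) {
    sigma2 <- fixed; sigma2[free] <- exp(theta)
    pc <- nll_pieces(sigma2)
    if (is.null(pc)) return(1e10)
    pc$nll
  }
  grad <- function(theta) {
    sigma2 <- fixed; sigma2[free] <- exp(theta)
    pc <- nll_pieces(sigma2)
    if (is.null(pc)) return(rep(0, length(free)))
    P <- if (reml)
      pc$Vinv - pc$U %*% pc$XtViX_inv %*% t(pc$U)
    else pc$Vinv
    Py <- pc$Vir                            # P y = V^-1 (y - X beta_hat)
    vapply(free, function(l) {
      g <- 0.5 * (sum(P * M[[l]]) - sum(Py * (M[[l]] %*% Py)))
      g * sigma2[l]                         # chain rule, log scale
    }, 0)
  }

  vbar0 <- mean(vi)
  # method-of-moments-flavoured start: excess dispersion split over levels
  fe <- stats::lm.fit(X, y)
  mom <- max(stats::var(fe$residuals) - vbar0, vbar0 / 10) /
    max(length(free), 1)
  starts <- list(rep(log(mom), length(free)),
                 rep(log(vbar0 * 1e-3), length(free)))
  if (control$starts >= 3) {
    set.seed(control$seed)
    starts <- c(starts, list(log(mom * 3) +
                               stats::rnorm(length(free), sd = 0.5)))
  }
  starts <- starts[seq_len(min(control$starts, length(starts)))]

  best <- NULL; conv <- FALSE
  if (length(free)) {
    for (s in starts) {
      op <- tryCatch(
        stats::nlminb(s, obj, grad,
                      lower = rep(log(1e-12), length(free)),
                      upper = rep(log(1e6), length(free)),
                      control = list(rel.tol = control$reltol,
                                     iter.max = control$maxit)),
        error = function(e) NULL)
      if (is.null(op)) next
      if (is.null(best) || op$objective < best$objective - 1e-12) best <- op
      if (op$convergence == 0) conv <- TRUE
    }
    if (is.null(best))
      stop("REML optimization failed from every start", call. = FALSE)
  } else {
    best <- list(par = numeric(), objective = obj(numeric()),
                 convergence = 0L)
    conv <- TRUE
  }
  sigma2 <- fixed; sigma2[free] <- exp(best$par)
  sigma2[sigma2 < control$zero_tol] <- 0

  pc <- nll_pieces(sigma2)
  beta <- drop(pc$beta); names(beta) <- colnames(X)
  Vb <- pc$XtViX_inv; dimnames(Vb) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(Vb))
  crit <- if (test == "z") stats::qnorm(1 - (1 - level) / 2)
  else stats::qt(1 - (1 - level) / 2, df = k - p)
  zval <- beta / se
  pval <- if (test == "z") 2 * stats::pnorm(-abs(zval))
  else 2 * stats::pt(-abs(zval), df = k - p)
  tau2_sum <- sum(sigma2)
  pi_se <- sqrt(se^2 + tau2_sum)

  fit <- structure(list(
    coefficients = beta, se = se, zval = zval, pval = pval,
    ci.lb = beta - crit * se, ci.ub = beta + crit * se,
    pi.lb = beta - crit * pi_se, pi.ub = beta + crit * pi_se,
    sigma2 = sigma2, k = k, p = p, yi = y, vi = vi, X = X,
    terms = attr(mf, "terms"), xlevels = stats::.getXlevels(
      attr(mf, "terms"), mf),
    vb = Vb, M = M, method = method, test = test, level = level,
    logLik = -pc$nll, convergence = conv,
    random = names(M), fixed_sigma2 = sigma2_fixed,
    call = cl), class = "meta_fit")

  qm <- meta_qm(fit)
  fit$QM <- qm$QM; fit$QM_df <- qm$df; fit$QM_p <- qm$p
  fit$R2_marginal <- meta_r2(fit)
  fit$I2 <- heterogeneity(fit)
  fit
}

# Omnibus moderator Wald test. In intercept models all non-intercept
# coefficients are tested against zero. In no-intercept (level-means)
# models, a term coded as a full set of level indicators is tested through
# level-difference contrasts (so Q_M asks whether levels differ, not
# whether they are zero); contrast-coded or continuous terms are tested
# against zero.
meta_qm <- function(fit) {
  X <- fit$X
  asgn <- attr(X, "assign")
  has_int <- any(asgn == 0)
  p <- ncol(X)
  rows <- list()
  if (has_int) {
    for (j in which(asgn != 0)) {
      e <- rep(0, p); e[j] <- 1; rows[[length(rows) + 1]] <- e
    }
  } else if (p >= 1) {
    groups <- split(seq_len(p), asgn)
    for (g in groups) {
      sub <- X[, g, drop = FALSE]
      full_dummies <- length(g) > 1 && all(sub %in% c(0, 1)) &&
        all(abs(rowSums(sub) - 1) < 1e-12)
      if (length(g) == 1 && all(sub == 1)) next  # single-level moderator:
                                                 # intercept-like, no contrast
      if (full_dummies) {
        for (j in g[-1]) {                 # differences among level means
          e <- rep(0, p); e[g[1]] <- -1; e[j] <- 1
          rows[[length(rows) + 1]] <- e
        }
      } else {
        for (j in g) {
          e <- rep(0, p); e[j] <- 1; rows[[length(rows) + 1]] <- e
        }
      }
    }
  }
  if (!length(rows)) return(list(QM = NA_real_, df = 0L, p = NA_real_))
  Lm <- do.call(rbind, rows)
  lb <- Lm %*% fit$coefficients
  lv <- Lm %*% fit$vb %*% t(Lm)
  QM <- drop(t(lb) %*% solve(lv, lb))
  df <- nrow(Lm)
  list(QM = QM, df = df, p = stats::pchisq(QM, df, lower.tail = FALSE))
}

# Marginal R-squared (%): fixed-effect variance over fixed + random.
meta_r2 <- function(fit) {
  fv <- drop(fit$X %*% fit$coefficients)
  sf <- stats::var(fv)
  tot <- sf + sum(fit$sigma2)
  if (tot <= 0) return(0)
  100 * sf / tot
}

#' Multilevel heterogeneity (I-squared) decomposition
#'
#' Total I-squared is the share of total effect-size variance attributable
#' to the random-effect components rather than sampling error:
#' `100 * sum(sigma2) / (sum(sigma2) + v_bar)`, with per-level shares
#' `100 * sigma2_l / (sum(sigma2) + v_bar)`, which sum to the total by
#' construction. The typical sampling variance `v_bar` uses the standard
#' multilevel formulation `(k - 1) sum(w) / ((sum(w))^2 - sum(w^2))` with
#' `w = 1/vi`; a simple mean of the `vi` is switchable. The choice is
#' recorded in the result.
#'
#' @param fit a [meta_fit] object.
#' @param vbar `"weighted"` (default) or `"mean"`.
#' @return A list of class `heterogeneity`: `total` (%), `by_level` (named
#'   %, summing to `total`), `vbar`, `vbar_method`.
#' @export
heterogeneity <- function(fit, vbar = c("weighted", "mean")) {
  vbar <- match.arg(vbar)
  w <- 1 / fit$vi
  vb <- if (vbar == "weighted")
    (fit$k - 1) * sum(w) / (sum(w)^2 - sum(w^2))
  else mean(fit$vi)
  denom <- sum(fit$sigma2) + vb
  structure(list(total = 100 * sum(fit$sigma2) / denom,
                 by_level = 100 * fit$sigma2 / denom,
                 vbar = vb, vbar_method = vbar), class = "heterogeneity")
}

#' @export
print.heterogeneity <- function(x, ...) {
  cat(sprintf("Total I2 = %.1f%% (typical sampling variance %.4g, %s)\n",
              x$total, x$vbar, x$vbar_method))
  for (nm in names(x$by_level))
    cat(sprintf("  %-8s %.1f%%\n", nm, x$by_level[nm]))
  invisible(x)
}

#' Evaluate the (restricted) log-likelihood at given variance components
#'
#' Profile tool for diagnostics and for verifying that the fitted solution
#' is a local optimum: returns the REML (or ML) log-likelihood of a fitted
#' model evaluated at an arbitrary vector of variance components.
#'
#' @param fit a [meta_fit] object.
#' @param sigma2 named or positional numeric vector of components (defaults
#'   to the fitted values).
#' @return The log-likelihood (numeric scalar).
#' @export
reml_logLik <- function(fit, sigma2 = fit$sigma2) {
  if (!is.null(names(sigma2))) sigma2 <- sigma2[fit$random]
  k <- fit$k; X <- fit$X; y <- fit$yi; vi <- fit$vi
  V <- diag(vi, k)
  for (l in seq_along(fit$M)) if (sigma2[l] > 0)
    V <- V + sigma2[l] * fit$M[[l]]
  cV <- chol(V); Vinv <- chol2inv(cV)
  U <- Vinv %*% X; XtViX <- crossprod(X, U)
  cXX <- chol(XtViX)
  beta <- chol2inv(cXX) %*% crossprod(U, y)
  r <- y - X %*% beta
  q <- sum(r * (Vinv %*% r))
  reml <- fit$method == "REML"
  ll_const <- if (reml)
    0.5 * ((k - ncol(X)) * log(2 * pi) -
             determinant(crossprod(X))$modulus[1])
  else 0.5 * k * log(2 * pi)
  -(ll_const + 0.5 * (2 * sum(log(diag(cV))) + q +
                        if (reml) 2 * sum(log(diag(cXX))) else 0))
}

#' @export
print.meta_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Multilevel meta-analysis (%s), k = %d\n", x$method, x$k))
  cat("Random components (sigma2):",
      paste(sprintf("%s = %.4g", names(x$sigma2), x$sigma2),
            collapse = ", "), "\n")
  tab <- data.frame(estimate = x$coefficients, se = x$se, z = x$zval,
                    p = x$pval, ci.lb = x$ci.lb, ci.ub = x$ci.ub)
  print(round(tab, digits))
  invisible(x)
}

#' Summary of a multilevel meta-analytic fit
#'
#' @param object a [meta_fit] object.
#' @param ... unused.
#' @return The object augmented for printing: coefficient table, variance
#'   components, I-squared decomposition, `Q_M` and marginal R-squared.
#' @export
summary.meta_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.meta_fit")
}

#' @export
print.summary.meta_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  print(f$I2)
  if (!is.na(f$QM))
    cat(sprintf("Q_M(df = %d) = %.4g, p = %.4g; marginal R2 = %.2f%%\n",
                f$QM_df, f$QM, f$QM_p, f$R2_marginal))
  cat(sprintf("log %s likelihood: %.4f (converged: %s)\n", f$method,
              f$logLik, f$convergence))
  invisible(x)
}

#' @export
coef.meta_fit <- function(object, ...) object$coefficients

#' @export
vcov.meta_fit <- function(object, ...) object$vb

#' @export
logLik.meta_fit <- function(object, ...) {
  structure(object$logLik, df = object$p + sum(object$sigma2 > 0),
            class = "logLik")
}

#' Predicted pooled effects with confidence and prediction intervals
#'
#' @param object a [meta_fit] object.
#' @param newdata optional data frame of moderator values; defaults to the
#'   distinct rows of the fitted design.
#' @param ... unused.
#' @return Data frame with `pred`, `se`, `ci.lb`, `ci.ub`, `pi.lb`,
#'   `pi.ub`.
#' @export
predict.meta_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    Xn <- unique(object$X)
  } else {
    tt <- stats::delete.response(object$terms)
    mfn <- stats::model.frame(tt, newdata, xlev = object$xlevels)
    Xn <- stats::model.matrix(tt, mfn)
  }
  pred <- drop(Xn %*% object$coefficients)
  se <- sqrt(rowSums((Xn %*% object$vb) * Xn))
  crit <- if (object$test == "z")
    stats::qnorm(1 - (1 - object$level) / 2)
  else stats::qt(1 - (1 - object$level) / 2, df = object$k - object$p)
  pi_se <- sqrt(se^2 + sum(object$sigma2))
  data.frame(pred = pred, se = se,
             ci.lb = pred - crit * se, ci.ub = pred + crit * se,
             pi.lb = pred - crit * pi_se, pi.ub = pred + crit * pi_se)
}

#' @export
residuals.meta_fit <- function(object,
                               type = c("response", "standardized"), ...) {
  type <- match.arg(type)
  r <- object$yi - drop(object$X %*% object$coefficients)
  if (type == "standardized")
    r <- r / sqrt(object$vi + sum(object$sigma2))
  r
}

#' Forest-style plot of a meta-analytic fit
#'
#' Effect sizes against precision with the pooled estimate(s), confidence
#' interval and prediction interval overlaid. Base graphics.
#'
#' @param x a [meta_fit] object.
#' @param ... passed to [graphics::plot].
#' @export
plot.meta_fit <- function(x, ...) {
  ord <- order(x$yi)
  yi <- x$yi[ord]; se <- sqrt(x$vi[ord])
  graphics::plot(yi, seq_along(yi), pch = 16,
                 cex = 0.4 + 0.6 * (1 / se) / max(1 / se),
                 xlab = "Effect size (SMDH)", ylab = "Record",
                 panel.first = graphics::abline(v = 0, lty = 3), ...)
  graphics::segments(yi - 1.96 * se, seq_along(yi), yi + 1.96 * se,
                     seq_along(yi), col = "grey70")
  graphics::abline(v = x$coefficients[1], col = "red3", lwd = 2)
  graphics::abline(v = c(x$ci.lb[1], x$ci.ub[1]), col = "red3", lty = 2)
  invisible(x)
}

#' Meta-regression on one or more moderators (no-intercept level means)
#'
#' Convenience wrapper fitting `yi ~ 0 + moderator_1 + ...` with the full
#' random-effect structure, returning the fit with the omnibus `Q_M`
#' (testing differences among moderator levels) and marginal R-squared.
#'
#' @param records data frame with `yi`, `vi`, `study`, `species` and the
#'   moderator columns.
#' @param moderators character vector of moderator column names.
#' @param A optional phylogenetic correlation matrix.
#' @param ... passed to [meta_fit].
#' @return A [meta_fit] object.
#' @export
moderator_test <- function(records, moderators, A = NULL, ...) {
  for (m in moderators) {
    if (!m %in% names(records)) stop("unknown moderator: ", m,
                                     call. = FALSE)
    records[[m]] <- factor(records[[m]])
  }
  # single-level moderators carry no contrast: drop them from the design
  # (Q_M is then reported as NA and marginal R2 is 0 for a pure-constant
  # moderator set)
  multi <- moderators[vapply(moderators,
                             function(m) nlevels(records[[m]]) > 1, TRUE)]
  fml <- if (length(multi))
    stats::as.formula(paste("yi ~ 0 +", paste(multi, collapse = " + ")))
  else yi ~ 1
  args <- list(fml, vi = records$vi, data = records, A = A, ...)
  if ("study" %in% names(records)) args$study <- records$study
  if ("species" %in% names(records)) args$species <- records$species
  do.call(meta_fit, args)
}

#' Authorship-group publication-bias check
#'
#' Fits the level-means model on a two-level first-author grouping and
#' reports the per-group pooled estimates plus the Wald p-value of the
#' between-group difference.
#'
#' @param records data frame with `yi`, `vi`, `study`, `species` and the
#'   grouping column.
#' @param group name of the grouping column (default `"author_group"`).
#' @param A optional phylogenetic correlation matrix.
#' @param ... passed to [meta_fit].
#' @return A list: `fit` (the [meta_fit]), `groups` (per-group estimates
#'   with CIs), `diff_p` (difference p-value).
#' @export
publication_bias_check <- function(records, group = "author_group",
                                   A = NULL, ...) {
  g <- factor(records[[group]])
  if (any(table(g) == 0) || nlevels(g) < 2)
    stop("both authorship groups must be non-empty", call. = FALSE)
  fit <- moderator_test(records, group, A = A, ...)
  est <- data.frame(group = levels(g), estimate = stats::coef(fit),
                    ci.lb = fit$ci.lb, ci.ub = fit$ci.ub, p = fit$pval,
                    row.names = NULL)
  list(fit = fit, groups = est, diff_p = fit$QM_p)
}
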