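# Two-part (hurdle) expression model for log-normalized single-nucleus data.
#
# Each gene is modelled in two parts: a logistic "detection" component for
# whether the gene is observed (value > 0), and a Gaussian "expression"
# component for the positive values. Significance of a two-level predictor
# comes from a likelihood-ratio test that sums the two components'
# chi-square statistics (df = 2, one parameter dropped per component).
# Both components may carry a Gaussian random intercept for donor.
# No empirical-Bayes shrinkage is applied across genes.

#' Per-nucleus gene detection rate
#'
#' Fraction of genes with nonzero normalized expression in each nucleus.
#' Used (centered) as the \code{cngeneson} covariate of the hurdle model.
#'
#' @param m a \code{\link{normalized_matrix}} or a plain numeric matrix
#'   (nuclei x genes).
#' @param center subtract the across-nuclei mean (default FALSE).
#' @return Numeric vector, one value per nucleus.
#' @export
detection_rate <- function(m, center = FALSE) {
  vals <- if (inherits(m, "normalized_matrix")) m$values else m
  r <- rowMeans(vals > 0)
  if (center) r <- r - mean(r)
  r
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p vector of p-values in [0, 1]; NAs propagate.
#' @return BH step-up adjusted values (monotone in p-rank, capped at 1).
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Firth bias-reduced logistic regression; used when ordinary ML separates.
# Returns coefficients and the penalized log-likelihood.
firth_logistic <- function(X, z, maxit = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XW <- X * sqrt(w)
    XtWX <- crossprod(XW)
    R <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(R)) break
    H <- XW %*% chol2inv(R) %*% t(XW)
    h <- diag(H)
    U <- drop(t(X) %*% (z - p + h * (0.5 - p)))
    delta <- drop(chol2inv(R) %*% U)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  ll <- sum(z * log(pmax(p, 1e-12)) + (1 - z) * log(pmax(1 - p, 1e-12)))
  w <- p * (1 - p)
  XtWX <- crossprod(X * sqrt(w))
  pll <- ll + 0.5 * determinant(XtWX, logarithm = TRUE)$modulus
  list(coef = beta, pll = as.numeric(pll))
}

# Fixed-effects hurdle fit for one gene. group: 2-level factor. covs: numeric
# matrix (may have 0 columns). Returns the pieces of a HurdleResult row.
hurdle_fit_fixed <- function(y, group, covs) {
  z <- as.numeric(y > 0)
  n <- length(y)
  g1 <- as.numeric(group == levels(group)[2])
  X_full <- cbind(`(Intercept)` = rep(1, n), group = g1)
  if (!is.null(covs)) X_full <- cbind(X_full, covs)
  X_red <- X_full[, -2, drop = FALSE]
  converged <- TRUE
  fallback <- "none"

  lrt_d <- 0; b_d <- NULL
  if (stats::var(z) > 0) {
    fit_f <- suppressWarnings(
      stats::glm.fit(X_full, z, family = stats::binomial()))
    fit_r <- suppressWarnings(
      stats::glm.fit(X_red, z, family = stats::binomial()))
    sep <- any(fit_f$fitted.values > 1 - 1e-8) ||
      any(fit_f$fitted.values < 1e-8) || !fit_f$converged
    if (sep) {
      ff <- firth_logistic(X_full, z)
      fr <- firth_logistic(X_red, z)
      lrt_d <- max(0, 2 * (ff$pll - fr$pll))
      b_d <- ff$coef
      fallback <- "firth"
    } else {
      lrt_d <- max(0, fit_r$deviance - fit_f$deviance)
      b_d <- fit_f$coefficients
    }
  } else {
    b_d <- c(stats::qlogis(min(max(mean(z), 1e-8), 1 - 1e-8)),
             rep(0, ncol(X_full) - 1))
  }
  b_d[is.na(b_d)] <- 0

  pos <- y > 0
  n_pos_lvl <- tapply(pos, group, sum)
  df <- 2; lrt_c <- 0
  b_c <- NULL
  if (all(n_pos_lvl >= 3)) {
    yp <- y[pos]
    qf <- stats::lm.fit(X_full[pos, , drop = FALSE], yp)
    qr_ <- stats::lm.fit(X_red[pos, , drop = FALSE], yp)
    rss_f <- sum(qf$residuals^2); rss_r <- sum(qr_$residuals^2)
    lrt_c <- if (rss_f > 0) max(0, sum(pos) * log(rss_r / rss_f)) else 0
    b_c <- qf$coefficients
    b_c[is.na(b_c)] <- 0
  } else {
    # too few positive nuclei in a level: discrete-only test
    df <- 1
    fallback <- if (fallback == "none") "discrete_only" else
      paste(fallback, "discrete_only", sep = "+")
    qr_ <- stats::lm.fit(X_red[pos, , drop = FALSE], y[pos])
    b_c <- c(qr_$coefficients[1], 0, qr_$coefficients[-1])
    b_c[is.na(b_c)] <- 0
  }

  lrt <- lrt_d + if (df == 2) lrt_c else 0
  cm <- if (is.null(covs) || ncol(covs) == 0) numeric(0) else colMeans(covs)
  x0 <- c(1, 0, cm); x1 <- c(1, 1, cm)
  E0 <- stats::plogis(sum(x0 * b_d)) * sum(x0 * b_c)
  E1 <- stats::plogis(sum(x1 * b_d)) * sum(x1 * b_c)
  list(lrt_stat = lrt, df = df,
       p_value = stats::pchisq(lrt, df, lower.tail = FALSE),
       log2fc = E1 - E0, discrete_coef = unname(b_d[2]),
       continuous_coef = unname(b_c[2]), converged = converged,
       fallback = fallback)
}

# Mixed-effects hurdle fit for one gene: Gaussian random intercept per
# group_var level in both components, ML fitting, LRT for dropping the
# predictor's fixed effect from both components (df = 2).
# theta_zero constrains the random-intercept variance to zero (used to
# check the reduction to the fixed-effects fit).
hurdle_fit_mixed <- function(y, dat, predictor, covariates, group_var,
                             theta_zero = FALSE) {
  z <- as.numeric(y > 0)
  dat$..z <- z
  dat$..y <- y
  covs_part <- if (length(covariates) > 0)
    paste(covariates, collapse = " + ") else NULL
  rhs_full <- paste(c(predictor, covs_part), collapse = " + ")
  rhs_red <- if (is.null(covs_part)) "1" else covs_part
  re <- sprintf("(1 | %s)", group_var)
  f_full_d <- stats::as.formula(paste("..z ~", rhs_full, "+", re))
  f_red_d <- stats::as.formula(paste("..z ~", rhs_red, "+", re))
  converged <- TRUE

  # GLM evaluation of the model with the random-intercept variance at 0;
  # used both for the theta_zero diagnostic and as a flagged fallback when
  # the mixed fit fails numerically
  glm_zero_d <- function(f, d) {
    gf <- lme4::glFormula(f, data = d, family = stats::binomial())
    fit <- suppressWarnings(
      stats::glm.fit(gf$X, d$..z, family = stats::binomial()))
    # Bernoulli saturated log-likelihood is 0, so ll = -deviance/2
    list(ll = -fit$deviance / 2, beta = fit$coefficients,
         Xnames = colnames(gf$X))
  }
  lm_zero_c <- function(f, d) {
    lf <- lme4::lFormula(f, data = d, REML = FALSE)
    fit <- stats::lm.fit(lf$X, d$..y)
    n <- length(d$..y)
    rss <- sum(fit$residuals^2)
    list(ll = -n / 2 * (log(2 * pi) + log(rss / n) + 1),
         beta = fit$coefficients, Xnames = colnames(lf$X))
  }
  glmer_ll <- function(f, d) {
    if (theta_zero) return(glm_zero_d(f, d))
    fit <- tryCatch(
      withCallingHandlers(
        lme4::glmer(f, data = d, family = stats::binomial(),
                    control = lme4::glmerControl(calc.derivs = FALSE,
                                                 check.conv.singular =
                                                   lme4::.makeCC(action = "ignore",
                                                                 tol = 1e-4))),
        warning = function(w) {
          converged <<- FALSE
          invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (is.null(fit)) {
      converged <<- FALSE
      return(glm_zero_d(f, d))
    }
    list(ll = as.numeric(stats::logLik(fit)), beta = lme4::fixef(fit),
         Xnames = names(lme4::fixef(fit)))
  }
  lmer_ll <- function(f, d) {
    if (theta_zero) return(lm_zero_c(f, d))
    fit <- tryCatch(
      withCallingHandlers(
        lme4::lmer(f, data = d, REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular =
                                                 lme4::.makeCC(action = "ignore",
                                                               tol = 1e-4))),
        warning = function(w) {
          converged <<- FALSE
          invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (is.null(fit)) {
      converged <<- FALSE
      return(lm_zero_c(f, d))
    }
    list(ll = as.numeric(stats::logLik(fit)), beta = lme4::fixef(fit),
         Xnames = names(lme4::fixef(fit)))
  }

  lrt_d <- 0
  beta_d <- NULL; names_d <- NULL
  if (stats::var(z) > 0) {
    fd <- glmer_ll(f_full_d, dat)
    rd <- glmer_ll(f_red_d, dat)
    lrt_d <- max(0, 2 * (fd$ll - rd$ll))
    beta_d <- fd$beta; names_d <- fd$Xnames
  }

  pos <- y > 0
  lvl <- dat[[predictor]]
  n_pos_lvl <- tapply(pos, lvl, sum)
  df <- 2; lrt_c <- 0
  beta_c <- NULL; names_c <- NULL
  fallback <- "none"
  if (all(n_pos_lvl >= 3)) {
    dpos <- dat[pos, , drop = FALSE]
    f_full_c <- stats::as.formula(paste("..y ~", rhs_full, "+", re))
    f_red_c <- stats::as.formula(paste("..y ~", rhs_red, "+", re))
    fc <- lmer_ll(f_full_c, dpos)
    rc <- lmer_ll(f_red_c, dpos)
    lrt_c <- max(0, 2 * (fc$ll - rc$ll))
    beta_c <- fc$beta; names_c <- fc$Xnames
  } else {
    df <- 1
    fallback <- "discrete_only"
  }

  lrt <- lrt_d + if (df == 2) lrt_c else 0
  # composite log2FC from the fixed-effect parts at covariate means
  lvls <- levels(factor(dat[[predictor]]))
  pred_at <- function(beta, nms, level_on) {
    if (is.null(beta)) return(0)
    x <- numeric(length(beta)); names(x) <- nms
    x["(Intercept)"] <- 1
    coef_name <- paste0(predictor, lvls[2])
    if (coef_name %in% nms) x[coef_name] <- as.numeric(level_on)
    for (cv in covariates) {
      v <- dat[[cv]]
      if (is.numeric(v) && cv %in% nms) x[cv] <- mean(v)
      if (is.factor(v) || is.character(v)) {
        fl <- levels(factor(v))[-1]
        for (l2 in fl) {
          nm <- paste0(cv, l2)
          if (nm %in% nms) x[nm] <- mean(v == l2)
        }
      }
    }
    sum(x * beta)
  }
  E_at <- function(on) {
    pdet <- if (is.null(beta_d)) mean(z) else
      stats::plogis(pred_at(beta_d, names_d, on))
    mu <- if (is.null(beta_c)) mean(y[pos]) else pred_at(beta_c, names_c, on)
    pdet * mu
  }
  log2fc <- E_at(TRUE) - E_at(FALSE)
  coef_name <- paste0(predictor, lvls[2])
  list(lrt_stat = lrt, df = df,
       p_value = stats::pchisq(lrt, df, lower.tail = FALSE),
       log2fc = log2fc,
       discrete_coef = if (!is.null(beta_d) && coef_name %in% names_d)
         unname(beta_d[coef_name]) else 0,
       continuous_coef = if (!is.null(beta_c) && coef_name %in% names_c)
         unname(beta_c[coef_name]) else 0,
       converged = converged, fallback = fallback)
}

#' Fit the two-part hurdle model for one gene
#'
#' Logistic regression of detection (value > 0) plus Gaussian regression of
#' the positive values, with an optional donor random intercept in both
#' components. The likelihood-ratio statistic for the predictor of interest
#' sums the two components (df = 2; df = 1 when a level has fewer than 3
#' positive nuclei and the test falls back to the discrete part). The
#' composite log2 fold change is the difference in predicted mean
#' expression, P(detected) x E[value | detected], between the predictor's
#' two levels at covariate means.
#'
#' @param y numeric vector of log2-normalized expression for one gene.
#' @param data data.frame of nucleus-level variables.
#' @param predictor name of the two-level factor of interest.
#' @param covariates character vector of covariate column names (e.g.
#'   \code{cngeneson}, \code{age}, \code{sex}, \code{RIN}, \code{PMI}).
#' @param random_intercept optional grouping column name (e.g. donor) for a
#'   Gaussian random intercept in both components.
#' @param theta_zero constrain the random-intercept variance to zero
#'   (diagnostic; reduces to the fixed-effects fit).
#' @return A one-row data.frame with \code{lrt_stat}, \code{df},
#'   \code{p_value}, \code{log2fc}, \code{discrete_coef},
#'   \code{continuous_coef}, \code{converged}, \code{fallback}.
#' @export
fit_hurdle <- function(y, data, predictor, covariates = character(),
                       random_intercept = NULL, theta_zero = FALSE) {
  stopifnot(is.numeric(y), nrow(data) == length(y))
  lvl <- factor(data[[predictor]])
  if (nlevels(lvl) != 2)
    stop("predictor_of_interest must have exactly 2 levels")
  if (predictor %in% covariates)
    stop("predictor must not appear among covariates")
  if (sum(y > 0) < 3) {
    return(data.frame(lrt_stat = NA_real_, df = NA_integer_,
                      p_value = NA_real_, log2fc = NA_real_,
                      discrete_coef = NA_real_, continuous_coef = NA_real_,
                      converged = FALSE, fallback = "not_tested"))
  }
  res <- if (is.null(random_intercept)) {
    covs <- build_covariate_matrix(data, covariates)
    d2 <- data; d2[[predictor]] <- lvl
    hurdle_fit_fixed(y, lvl, covs)
  } else {
    d2 <- data; d2[[predictor]] <- lvl
    hurdle_fit_mixed(y, d2, predictor, covariates, random_intercept,
                     theta_zero = theta_zero)
  }
  as.data.frame(res)
}

# numeric design columns for the fixed-effects fast path; factors expanded
# to treatment-coded dummies
build_covariate_matrix <- function(data, covariates) {
  if (length(covariates) == 0) return(NULL)
  mats <- lapply(covariates, function(cv) {
    v <- data[[cv]]
    if (is.numeric(v)) {
      m <- matrix(v, ncol = 1); colnames(m) <- cv; m
    } else {
      f <- factor(v)
      m <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(m) <- paste0(cv, levels(f)[-1]); m
    }
  })
  do.call(cbind, mats)
}

#' Fixed-effects hurdle test for every gene
#'
#' Applies the two-part hurdle LRT of a two-level factor to each column of
#' an expression matrix; the fast path behind marker detection and
#' platform-gene flagging. Genes with fewer than \code{min_positive}
#' expressing nuclei are returned untested (NA row).
#'
#' @param vals numeric nuclei x genes matrix of log2-normalized expression.
#' @param group two-level factor over nuclei.
#' @param covariates data.frame (or numeric matrix) of nucleus-level
#'   covariates, e.g. centered detection rate.
#' @param min_positive minimum expressing nuclei for a gene to be tested.
#' @return data.frame with one row per gene: \code{gene, lrt_stat, df,
#'   p_value, log2fc, discrete_coef, continuous_coef, converged, fallback}.
#' @export
hurdle_test_all <- function(vals, group, covariates = NULL,
                            min_positive = 3) {
  stopifnot(nlevels(group) == 2)
  covs <- if (is.data.frame(covariates))
    build_covariate_matrix(covariates, names(covariates)) else covariates
  g <- ncol(vals)
  out <- vector("list", g)
  genes <- colnames(vals)
  if (is.null(genes)) genes <- paste0("g", seq_len(g))
  for (j in seq_len(g)) {
    y <- vals[, j]
    if (sum(y > 0) < min_positive) {
      out[[j]] <- data.frame(lrt_stat = NA_real_, df = NA_integer_,
                             p_value = NA_real_, log2fc = NA_real_,
                             discrete_coef = NA_real_,
                             continuous_coef = NA_real_,
                             converged = FALSE, fallback = "not_tested")
    } else {
      out[[j]] <- as.data.frame(hurdle_fit_fixed(y, group, covs))
    }
  }
  res <- do.call(rbind, out)
  res <- cbind(gene = genes, res)
  rownames(res) <- NULL
  res
}
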