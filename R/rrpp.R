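# hat matrix of a design-matrix column subset (projection onto its span)
hat_matrix <- function(X) {
  if (is.null(X) || ncol(X) == 0L) return(matrix(0, nrow(X), nrow(X)))
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

# permutation matrix generator: n_perm rows, each a permutation of 1..n,
# optionally restricted within blocks
make_perms <- function(n, n_perm, blocks = NULL) {
  if (is.null(blocks)) {
    t(replicate(n_perm, sample.int(n)))
  } else {
    blocks <- as.factor(blocks)
    idx <- split(seq_len(n), blocks)
    t(replicate(n_perm, {
      p <- seq_len(n)
      for (ii in idx) if (length(ii) > 1L) p[ii] <- ii[sample.int(length(ii))]
      p
    }))
  }
}

# term containment (for Type II SS): does term u contain term t?
term_contains <- function(fac, t, u) {
  if (t == u) return(FALSE)
  vt <- rownames(fac)[fac[, t] > 0]
  vu <- rownames(fac)[fac[, u] > 0]
  all(vt %in% vu)
}

#' Residual-randomization linear model on multivariate shape data
#'
#' Fits a (multivariate) linear model of a shape matrix on continuous and/or
#' categorical predictors and assesses each term by randomizing
#' reduced-model residuals (RRPP).  For every term the appropriate
#' reduced-vs-full comparison is taken according to the sum-of-squares type:
#' Type I (sequential), Type II (each term against the model holding all
#' terms that do not contain it) or Type III (each term dropped from the
#' full model, with sum-to-zero contrasts).  Significance comes from the
#' permutation distribution of the F statistic; the effect size Z is the
#' standardized position of the observed F in that distribution.
#'
#' When a positive-definite `covariance` is supplied the model is estimated
#' by generalized least squares: data and design are whitened by the inverse
#' square root of the covariance, so an identity covariance reproduces
#' ordinary least squares exactly.
#'
#' @param formula one-sided or two-sided formula; the right-hand side names
#'   columns of `data` (e.g. `~ size * group`).  The response is supplied
#'   separately as `Y`.
#' @param data data.frame of predictors (n rows).
#' @param Y numeric n x p response matrix (e.g. tangent coordinates).
#' @param ss_type `"I"`, `"II"` or `"III"`.
#' @param n_perm number of random permutations (default 999).
#' @param blocks optional factor restricting permutations to shuffle within
#'   its levels (e.g. species, for within-group exchangeability).
#' @param covariance optional n x n positive-definite covariance (GLS).
#' @param seed optional integer seed for the permutations.
#' @param z_transform `"none"` (Z computed on the raw permuted F values,
#'   the default) or `"log"` (on log F).
#' @return object of class `rrpp_fit`; element `aov_table` is a data.frame
#'   with Df, SS, MS, Rsq, F, Z and p for every term plus Residuals and
#'   Total rows.  Coefficients, fitted values, residuals and the permutation
#'   F distributions are retained for downstream use.
#' @references Collyer, M.L. & Adams, D.C. (2018) RRPP: An R package for
#'   fitting linear models to high-dimensional data using residual
#'   randomization. Methods in Ecology and Evolution 9, 1772-1779.
#' @export
rrpp_lm <- function(formula, data, Y, ss_type = c("II", "I", "III"),
                    n_perm = 999L, blocks = NULL, covariance = NULL,
                    seed = NULL, z_transform = c("none", "log")) {
  ss_type <- match.arg(as.character(ss_type), c("II", "I", "III"))
  z_transform <- match.arg(z_transform)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (nrow(data) != n) stop("nrow(data) != nrow(Y)")
  if (!is.null(seed)) set.seed(seed)
  data <- as.data.frame(data)
  for (j in seq_along(data))
    if (is.character(data[[j]])) data[[j]] <- factor(data[[j]])

  tf <- stats::delete.response(stats::terms(formula, data = data))
  labels <- attr(tf, "term.labels")
  fac <- attr(tf, "factors")
  contrasts_arg <- NULL
  if (ss_type == "III") {
    fvars <- names(Filter(function(v) is.factor(v) || is.character(v), data))
    fvars <- intersect(fvars, all.vars(tf))
    contrasts_arg <- stats::setNames(
      replicate(length(fvars), "contr.sum", simplify = FALSE), fvars)
    if (length(contrasts_arg) == 0L) contrasts_arg <- NULL
  }
  mf <- stats::model.frame(tf, data)
  X <- stats::model.matrix(tf, mf, contrasts.arg = contrasts_arg)
  assign <- attr(X, "assign")
  if (qr(X)$rank < ncol(X)) stop("singular design matrix")

  W <- NULL
  if (!is.null(covariance)) {
    covariance <- as.matrix(covariance)
    ev <- eigen((covariance + t(covariance)) / 2, symmetric = TRUE)
    if (min(ev$values) <= 0)
      stop("covariance matrix is not positive-definite")
    W <- ev$vectors %*% diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
    Y <- W %*% Y
    X <- W %*% X
    attr(X, "assign") <- assign
  }

  H_full <- hat_matrix(X)
  df_resid <- n - qr(X)$rank
  R_full <- Y - H_full %*% Y
  ss_resid <- sum(R_full^2)
  # total SS about the (GLS-transformed) intercept fit
  X0 <- X[, assign == 0L, drop = FALSE]
  H0 <- hat_matrix(X0)
  ss_total <- sum(((diag(n) - H0) %*% Y)^2)

  nt <- length(labels)
  comparisons <- vector("list", nt)
  for (ti in seq_len(nt)) {
    if (ss_type == "I") {
      red_terms <- if (ti > 1L) seq_len(ti - 1L) else integer(0)
      full_terms <- seq_len(ti)
    } else if (ss_type == "II") {
      # reduced model: every other term that does not contain this one
      red_terms <- setdiff(seq_len(nt), ti)
      red_terms <- red_terms[!vapply(labels[red_terms], function(lu)
        term_contains(fac, labels[ti], lu), TRUE)]
      full_terms <- sort(c(red_terms, ti))
    } else {
      red_terms <- setdiff(seq_len(nt), ti)
      full_terms <- seq_len(nt)
    }
    comparisons[[ti]] <- list(reduced = red_terms, full = full_terms)
  }

  perms <- make_perms(n, n_perm, blocks)
  obs_perm <- matrix(seq_len(n), 1L)
  aov <- data.frame(Df = integer(0), SS = double(0), MS = double(0),
                    Rsq = double(0), F = double(0), Z = double(0),
                    p = double(0))
  Fperm_list <- list()
  for (ti in seq_len(nt)) {
    cmp <- comparisons[[ti]]
    Xr <- X[, assign %in% c(0L, cmp$reduced), drop = FALSE]
    Xf <- X[, assign %in% c(0L, cmp$full), drop = FALSE]
    Hr <- hat_matrix(Xr)
    Hf <- hat_matrix(Xf)
    dfn <- qr(Xf)$rank - qr(Xr)$rank
    Dn <- Hf - Hr
    Dd <- diag(n) - H_full
    Er <- Y - Hr %*% Y
    G <- tcrossprod(Er)
    ssn_obs <- sum(perm_quadform(Dn, G, obs_perm))
    ssd_obs <- sum(perm_quadform(Dd, G, obs_perm))
    F_obs <- if (ssd_obs <= 1e-12 * max(1, ssn_obs))
      Inf else (ssn_obs / dfn) / (ssd_obs / df_resid)
    ssn_p <- perm_quadform(Dn, G, perms)
    ssd_p <- perm_quadform(Dd, G, perms)
    Fp <- (ssn_p / dfn) / pmax(ssd_p, 1e-300) * df_resid
    pval <- (sum(Fp >= F_obs - 1e-12) + 1) / (n_perm + 1)
    if (z_transform == "log") {
      lf <- log(pmax(Fp, 1e-300))
      Z <- (log(max(F_obs, 1e-300)) - mean(lf)) / stats::sd(lf)
    } else {
      Z <- (min(F_obs, .Machine$double.xmax) - mean(Fp)) / stats::sd(Fp)
    }
    aov <- rbind(aov, data.frame(Df = dfn, SS = ssn_obs, MS = ssn_obs / dfn,
                                 Rsq = ssn_obs / ss_total, F = F_obs, Z = Z,
                                 p = pval))
    Fperm_list[[labels[ti]]] <- Fp
  }
  rownames(aov) <- labels
  aov <- rbind(aov,
               Residuals = data.frame(Df = df_resid, SS = ss_resid,
                                      MS = ss_resid / max(df_resid, 1L),
                                      Rsq = ss_resid / ss_total, F = NA,
                                      Z = NA, p = NA),
               Total = data.frame(Df = n - qr(X0)$rank, SS = ss_total,
                                  MS = NA, Rsq = 1, F = NA, Z = NA, p = NA))
  coef_full <- qr.coef(qr(X), Y)
  fitted <- H_full %*% Y
  structure(list(aov_table = aov,
                 coefficients = coef_full,
                 fitted = fitted,
                 residuals = R_full,
                 Y = Y, X = X, assign = assign, terms = tf,
                 contrasts_arg = contrasts_arg,
                 ss_type = ss_type, n_perm = n_perm,
                 perm_F = Fperm_list,
                 data = data,
                 gls = !is.null(covariance), whitener = W),
            class = "rrpp_fit")
}

#' @export
print.rrpp_fit <- function(x, digits = 4L, ...) {
  cat(sprintf("Residual-randomization linear model (Type %s SS, %d permutations%s)\n",
              x$ss_type, x$n_perm, if (x$gls) ", GLS" else ""))
  tab <- x$aov_table
  tab$SS <- signif(tab$SS, digits); tab$MS <- signif(tab$MS, digits)
  tab$Rsq <- round(tab$Rsq, 3L); tab$F <- signif(tab$F, digits)
  tab$Z <- round(tab$Z, 2L)
  print(tab)
  invisible(x)
}
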