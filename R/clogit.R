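# Conditional logistic regression on 1:M matched sets, fitted from scratch.
#
# For matched set s with members j (covariate rows x_j) and case row c(s),
# the exact conditional log-likelihood is
#
#   l(beta) = sum_s [ x_{c(s)} . beta  -  log sum_{j in s} exp(x_j . beta) ],
#
# i.e. the probability that the case is the member it is, conditional on the
# set's covariates. Gradient and Hessian are analytic:
#
#   grad = sum_s [ x_{c(s)} - sum_j p_j x_j ],        p_j = softmax(x_j.beta)
#   hess = -sum_s [ sum_j p_j x_j x_j' - (sum_j p_j x_j)(sum_j p_j x_j)' ].
#
# Maximization is Newton-Raphson from beta = 0 with step halving; Wald 95%
# intervals come from the inverse observed information at the optimum.

prep_clogit_data <- function(x, is_case, set_id) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  set <- factor(set_id)
  n_case <- tapply(is_case, set, sum)
  bad <- names(n_case)[is.na(n_case) | n_case != 1L]
  if (length(bad)) {
    stopf("each matched set must contain exactly one case; offending set(s): %s",
          paste(utils::head(bad, 5L), collapse = ", "))
  }
  # Identifiability: a column constant within every set carries no
  # conditional information.
  si <- as.integer(set)
  for (j in seq_len(ncol(x))) {
    rng <- tapply(x[, j], si, function(v) max(v) - min(v))
    if (all(rng == 0)) {
      stopf("column '%s' is constant within every set (no within-set variation); drop it or merge categories",
            colnames(x)[j])
    }
  }
  list(x = x, is_case = as.logical(is_case), set = si,
       n_sets = nlevels(set))
}

clogit_core <- function(beta, x, is_case, set, n_sets) {
  eta <- drop(x %*% beta)
  mx <- vapply(split(eta, set), max, numeric(1))
  w <- exp(eta - mx[set])
  denom <- rowsum(w, set, reorder = TRUE)[, 1]
  ll <- sum(eta[is_case]) - sum(log(denom) + mx)
  p <- w / denom[set]
  s1 <- rowsum(x * p, set, reorder = TRUE)          # n_sets x k
  grad <- colSums(x[is_case, , drop = FALSE]) - colSums(s1)
  info <- crossprod(x * sqrt(p)) - crossprod(s1)    # observed information
  list(loglik = ll, grad = grad, info = info)
}

#' Exact conditional log-likelihood
#'
#' Evaluates the conditional log-likelihood of 1:M matched sets at `beta`,
#' with the analytic gradient and Hessian attached as attributes
#' `"gradient"` and `"hessian"`.
#'
#' @param beta Coefficient vector.
#' @param x Design matrix (one row per set member).
#' @param is_case Logical vector, exactly one `TRUE` per set.
#' @param set_id Set identifier vector.
#' @return The log-likelihood value with `gradient` and `hessian` attributes.
#' @export
conditional_loglik <- function(beta, x, is_case, set_id) {
  d <- prep_clogit_data(x, is_case, set_id)
  stopifnot(length(beta) == ncol(d$x))
  core <- clogit_core(as.numeric(beta), d$x, d$is_case, d$set, d$n_sets)
  structure(core$loglik, gradient = core$grad, hessian = -core$info)
}

#' Fit conditional logistic regression by Newton-Raphson
#'
#' Maximizes the exact conditional likelihood from `beta = 0` with step
#' halving, declaring convergence when the gradient sup-norm drops below
#' `tol`. The covariance of the estimates is the inverse observed information
#' at the optimum; odds ratios carry 95% Wald intervals
#' `exp(beta +/- 1.96 se)`.
#'
#' @inheritParams conditional_loglik
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on `max(abs(gradient))`.
#' @return Object of class `clogit_fit`: `beta`, `cov`, `or_table` (term, OR,
#'   95% CI, se of log-OR), `loglik`, `n_sets`, `converged`, `iterations`.
#' @export
clogit_fit <- function(x, is_case, set_id, max_iter = 50L, tol = 1e-8) {
  d <- prep_clogit_data(x, is_case, set_id)
  k <- ncol(d$x)
  beta <- rep(0, k)
  core <- clogit_core(beta, d$x, d$is_case, d$set, d$n_sets)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(core$grad)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(core$info, core$grad), error = function(e) {
      stopf("singular Hessian at iteration %d: %s", iter, conditionMessage(e))
    })
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      cand_core <- clogit_core(cand, d$x, d$is_case, d$set, d$n_sets)
      if (is.finite(cand_core$loglik) && cand_core$loglik > core$loglik) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break   # step-halving floor: no improving step left
    }
    if (lambda < 1e-10) { converged <- max(abs(core$grad)) < 1e-5; break }
    beta <- cand
    core <- cand_core
    if (max(abs(beta)) > 15) {
      bad <- colnames(d$x)[abs(beta) > 15]
      stop(structure(
        class = c("clogit_separation", "error", "condition"),
        list(message = sprintf(
          "estimates diverging (|beta| > 15) for term(s) %s: likely complete separation; merge sparse exposure categories",
          paste(bad, collapse = ", ")),
          call = NULL, terms = bad)))
    }
  }
  if (!converged && max(abs(core$grad)) < tol) converged <- TRUE
  if (!converged) {
    stopf("conditional logistic fit failed to converge in %d iterations (max |gradient| = %.3g); possible separation - consider merging categories",
          iter, max(abs(core$grad)))
  }
  cov <- tryCatch(solve(core$info), error = function(e) {
    stopf("singular Hessian at the optimum: %s", conditionMessage(e))
  })
  cov <- (cov + t(cov)) / 2
  se <- sqrt(diag(cov))
  z <- qnorm(0.975)
  or_table <- data.frame(
    term = colnames(d$x), beta = beta, se = se,
    or = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
    stringsAsFactors = FALSE)
  rownames(or_table) <- NULL
  structure(list(beta = setNames(beta, colnames(d$x)), cov = cov,
                 or_table = or_table, loglik = core$loglik,
                 n_sets = d$n_sets, converged = converged,
                 iterations = iter),
            class = "clogit_fit")
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat(sprintf("Conditional logistic fit: %d sets, loglik %.3f, %d iterations\n",
              x$n_sets, x$loglik, x$iterations))
  tab <- x$or_table
  tab$or <- format_or(tab$or)
  tab$ci <- paste0("(", format_or(tab$ci_low), "-", format_or(tab$ci_high), ")")
  print(tab[, c("term", "or", "ci")], row.names = FALSE)
  invisible(x)
}

# Display rounding used in report tables: >= 10 to 2 significant figures,
# otherwise 1 decimal.
format_or <- function(or) {
  ifelse(or >= 10, signif(or, 2), round(or, 1))
}

exposure_design <- function(tab, covariates = character()) {
  lev <- exposure_levels()
  x <- vapply(lev[-1], function(l) as.numeric(tab$category == l),
              numeric(nrow(tab)))
  if (length(covariates)) {
    xc <- vapply(covariates, function(cv) as.numeric(tab[[cv]]),
                 numeric(nrow(tab)))
    x <- cbind(x, xc)
  }
  colnames(x) <- c(lev[-1], covariates)
  x
}

# Drop design columns that cannot be estimated: never observed among cases
# (reported "not estimable", as in subgroup tables), never among controls, or
# without within-set variation.
prunable_columns <- function(x, is_case, set_id) {
  notes <- setNames(rep(NA_character_, ncol(x)), colnames(x))
  case_tot <- colSums(x[is_case, , drop = FALSE])
  ctl_tot <- colSums(x[!is_case, , drop = FALSE])
  si <- as.integer(factor(set_id))
  for (j in seq_len(ncol(x))) {
    rng <- tapply(x[, j], si, function(v) max(v) - min(v))
    if (case_tot[j] == 0) {
      notes[j] <- "not estimable (no exposed case)"
    } else if (ctl_tot[j] == 0) {
      notes[j] <- "not estimable (no exposed control)"
    } else if (all(rng == 0)) {
      notes[j] <- "not estimable (no within-set variation)"
    }
  }
  notes
}

fit_association <- function(tab, covariates = character(),
                            drop_inestimable = FALSE) {
  x <- exposure_design(tab, covariates)
  if (!drop_inestimable) return(clogit_fit(x, tab$is_case, tab$set_id))
  notes <- prunable_columns(x, tab$is_case, tab$set_id)
  repeat {
    keep <- is.na(notes)
    if (!any(keep)) stopf("no estimable column remains")
    fit <- tryCatch(
      clogit_fit(x[, keep, drop = FALSE], tab$is_case, tab$set_id),
      clogit_separation = function(e) e)
    if (!inherits(fit, "condition")) break
    notes[fit$terms] <- "not estimable (separation)"
  }
  fit$dropped <- notes[!is.na(notes)]
  fit
}

#' Univariable exposure model
#'
#' Conditional logistic regression of case status on the eight exposure
#' category indicators only; matching variables are adjusted for implicitly
#' by the conditioning on sets.
#'
#' @param tab An analysis table from [build_analysis_table()].
#' @param drop_inestimable Drop categories with no exposed case/control
#'   rather than failing.
#' @return A `clogit_fit`.
#' @export
univariable_exposure_fit <- function(tab, drop_inestimable = FALSE) {
  fit_association(tab, character(), drop_inestimable)
}

#' Multivariable model
#'
#' As [univariable_exposure_fit()] plus the three adjustment covariates:
#' 5-year carditis history, 30-day SARS-CoV-2 infection, and the deprivation
#' indicator (coded `least_deprived` so that "most deprived" is the
#' reference).
#'
#' @inheritParams univariable_exposure_fit
#' @return A `clogit_fit`.
#' @export
multivariable_fit <- function(tab, drop_inestimable = FALSE) {
  tab$least_deprived <- !tab$deprived
  fit_association(tab,
                  c("history_carditis_5y", "infection_30d", "least_deprived"),
                  drop_inestimable)
}
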