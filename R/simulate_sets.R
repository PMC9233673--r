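# Direct simulation of matched sets with a known conditional odds ratio,
# used for calibration studies of the conditional-logistic fitter without
# going through a full registry.

#' Simulate 1:M matched sets with a binary exposure
#'
#' Draws every member's exposure as Bernoulli(`exposure_prev`) and selects
#' the case within each set with probability proportional to
#' `exp(log(true_or) * x)` — exactly the conditional logistic model, so
#' `true_or` is the true conditional odds ratio the fitter should recover.
#'
#' @param n_sets Number of matched sets.
#' @param ratio Controls per case.
#' @param exposure_prev Exposure prevalence.
#' @param true_or True conditional odds ratio.
#' @return Data frame: `set_id`, `is_case`, `x`.
#' @export
simulate_matched_binary <- function(n_sets, ratio = 10L,
                                    exposure_prev = 0.1, true_or = 2) {
  m <- ratio + 1L
  x <- matrix(runif(n_sets * m) < exposure_prev, nrow = n_sets)
  w <- exp(log(true_or) * x)
  u <- runif(n_sets) * rowSums(w)
  cw <- apply(w, 1, cumsum)                  # m x n_sets
  case_idx <- vapply(seq_len(n_sets),
                     function(i) which(cw[, i] >= u[i])[1], integer(1))
  is_case <- matrix(FALSE, nrow = n_sets, ncol = m)
  is_case[cbind(seq_len(n_sets), case_idx)] <- TRUE
  data.frame(set_id = rep(seq_len(n_sets), each = m),
             is_case = as.vector(t(is_case)),
             x = as.numeric(as.vector(t(x))))
}
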