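# Multi-start bounded least squares on top of minpack.lm::nls.lm.
#
# starts: list of named numeric start vectors (same names/order as bounds).
# resid_fn: function(par) -> residual vector.
# prefer: optional parameter name; among fits whose SSE is within `tie_tol`
#   (relative) of the best, the fit with the lowest value of that parameter
#   wins. This is the tie-break rule for near-degenerate optima (e.g. a c50
#   pushed to its bound fitting no better than an interior one).
# Returns list(par, sse, r2, converged); r2 against `y` (1 - SSE/SStot).
fit_bounded_ls <- function(starts, resid_fn, lower, upper, y,
                           prefer = NULL, tie_tol = 0.01) {
  fits <- list()
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    fits[[length(fits) + 1]] <- list(par = fit$par, sse = sum(fit$fvec^2),
                                     converged = fit$info %in% 1:4)
  }
  if (length(fits) == 0) {
    return(list(par = NULL, sse = NA_real_, r2 = NA_real_, converged = FALSE))
  }
  sses <- vapply(fits, `[[`, numeric(1), "sse")
  best_sse <- min(sses)
  cand <- fits[sses <= best_sse * (1 + tie_tol) + 1e-12]
  best <- if (!is.null(prefer) && length(cand) > 1) {
    cand[[which.min(vapply(cand, function(f) f$par[[prefer]], numeric(1)))]]
  } else {
    fits[[which.min(sses)]]
  }
  sst <- sum((y - mean(y))^2)
  best$r2 <- if (sst > 0) 1 - best$sse / sst else NA_real_
  best
}
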