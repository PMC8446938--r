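#' Log posterior density of the hierarchical model
#'
#' Evaluates `log p(state | data)` up to an additive constant for a fully
#' specified parameter state: Gaussian likelihood
#' `y_i ~ N(eta_i, v_i + tau^2)`, Gaussian priors on all location parameters
#' (fixed effects N(0, `fixed_sd`^2); nested random intercepts/slopes;
#' RW2 walk coefficients with spectral prior variances `sd_rw^2 / lambda`;
#' study effects with coverage-specific `kappa`), and half-Cauchy hyperpriors
#' on all standard deviations. Used both in testing (term-by-term oracle
#' equivalence) and as the reference density the sampler targets.
#'
#' @param state list with elements `params` (named vector matching the
#'   layout returned in `fit$layout$par$name`, or any subset; missing
#'   entries are zero) and `sds` (named vector of the standard-deviation
#'   parameters, all required).
#' @param cells transformed cells for one outcome x sex (see
#'   [logit_transform()]).
#' @param hierarchy an [as_hierarchy()] table.
#' @param spec a [model_spec()].
#' @return scalar log density (`-Inf` allowed); non-finite component errors
#'   name the offending term.
#' @export
log_posterior <- function(state, cells, hierarchy, spec = model_spec()) {
  d <- build_design(cells, hierarchy, spec)
  log_posterior_design(state, d)
}

log_posterior_design <- function(state, d) {
  par <- d$layout$par
  x <- rep(0, nrow(par))
  if (!is.null(state$params)) {
    m <- match(names(state$params), par$name)
    if (anyNA(m))
      stop("unknown parameters in state: ",
           paste(names(state$params)[is.na(m)], collapse = ", "))
    x[m] <- state$params
  }
  sds <- state$sds
  need <- c(names(d$vblocks), "tau")
  if (!all(need %in% names(sds)))
    stop("state$sds missing: ", paste(setdiff(need, names(sds)), collapse = ", "))
  if (any(sds[need] <= 0)) return(-Inf)

  terms <- c()
  r <- d$y - as.vector(d$A %*% x)
  terms["likelihood"] <- sum(stats::dnorm(r, 0, sqrt(d$v + sds[["tau"]]^2),
                                          log = TRUE))
  fixed_idx <- block_idx(d$layout, "fixed")
  terms["prior_fixed"] <- sum(stats::dnorm(x[fixed_idx], 0, d$spec$fixed_sd,
                                           log = TRUE))
  for (nm in names(d$vblocks)) {
    vb <- d$vblocks[[nm]]
    if (length(vb$idx))
      terms[paste0("prior_", nm)] <- sum(stats::dnorm(
        x[vb$idx], 0, sds[[nm]] / sqrt(vb$wt), log = TRUE))
    terms[paste0("hyper_", nm)] <- half_cauchy_logpdf(sds[[nm]], vb$scale)
  }
  terms["hyper_tau"] <- half_cauchy_logpdf(sds[["tau"]], d$spec$tau_scale)
  bad <- names(terms)[is.nan(terms) | is.na(terms)]
  if (length(bad))
    stop("non-finite log-posterior term(s): ", paste(bad, collapse = ", "))
  sum(terms)
}
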