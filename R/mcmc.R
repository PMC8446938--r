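#' Fit the hierarchical model by MCMC
#'
#' Gibbs sampler for the model of [model_spec()]. Given the variance
#' parameters, all location parameters (fixed effects, nested random
#' intercepts and slopes, RW2 walk coefficients, study effects) are jointly
#' Gaussian and are drawn exactly in one block through a sparse Cholesky
#' factorisation, so their mixing is immediate. The standard-deviation
#' parameters are updated by univariate slice sampling on the log scale,
#' each with an additional non-centered (ancillarity) rescaling move that
#' interweaves the two parameterisations and removes the usual funnel
#' pathology of variance components; the shared non-sampling SD `tau` is
#' slice-sampled against the full residual likelihood.
#'
#' Runs are bit-reproducible given `config$seed`. Chains run sequentially.
#' After sampling, split-R-hat and effective sample sizes are computed for
#' all variance parameters and fixed effects; R-hat above 1.1 triggers a
#' warning (never silently ignored).
#'
#' @param cells transformed cells (see [logit_transform()]) for a single
#'   outcome x sex; may have zero rows, in which case the sampler explores
#'   the prior.
#' @param hierarchy an [as_hierarchy()] table.
#' @param spec a [model_spec()].
#' @param config an [mcmc_config()].
#' @return object of class `cascade_fit`: retained draws of all parameters,
#'   the parameter layout, diagnostics, and everything needed by
#'   [predict_surface()].
#' @export
run_mcmc <- function(cells, hierarchy, spec = model_spec(),
                     config = mcmc_config()) {
  stopifnot(inherits(config, "mcmc_config"))
  d <- build_design(cells, hierarchy, spec)
  n_obs <- length(d$y)
  npar <- nrow(d$layout$par)
  vb <- d$vblocks
  sd_names <- c(names(vb), "tau")
  scales <- c(vapply(vb, `[[`, numeric(1), "scale"), tau = spec$tau_scale)

  have_obs <- n_obs > 0
  if (have_obs) {
    qm <- build_q_mapping(d$A, npar)
    Q <- qm$Qpat
    Ablk <- lapply(vb, function(b)
      if (length(b$idx)) d$A[, b$idx, drop = FALSE] else NULL)
    touched <- vapply(Ablk, function(M) !is.null(M) && length(M@x) > 0,
                      logical(1))
  }
  fixed_idx <- block_idx(d$layout, "fixed")
  base_prec <- rep(0, npar)
  base_prec[fixed_idx] <- 1 / spec$fixed_sd^2

  n_keep <- config$samples %/% config$thin
  total_keep <- n_keep * config$chains
  draws <- matrix(NA_real_, total_keep, npar,
                  dimnames = list(NULL, d$layout$par$name))
  sd_draws <- matrix(NA_real_, total_keep, length(sd_names),
                     dimnames = list(NULL, sd_names))
  chain_id <- rep(seq_len(config$chains), each = n_keep)

  set.seed(config$seed)
  ch <- NULL
  row0 <- 0L
  for (chain in seq_len(config$chains)) {
    sds <- scales
    x <- rep(0, npar)
    tau2 <- sds[["tau"]]^2
    r <- if (have_obs) d$y else numeric(0)

    for (it in seq_len(config$burn_in + config$samples)) {
      # --- joint Gaussian draw of all location parameters -----------------
      prec <- base_prec
      for (nm in names(vb)) {
        b <- vb[[nm]]
        if (length(b$idx)) prec[b$idx] <- b$wt / sds[[nm]]^2
      }
      if (have_obs) {
        w <- 1 / (d$v + tau2)
        qx <- as.vector(qm$S %*% w)
        qx[qm$diagpos] <- qx[qm$diagpos] + prec
        Q@x <- qx
        ch <- if (is.null(ch)) Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE)
              else Matrix::update(ch, Q)
        b_vec <- as.vector(Matrix::crossprod(d$A, w * d$y))
        mu <- as.vector(Matrix::solve(ch, b_vec, system = "A"))
        z <- stats::rnorm(npar)
        x <- mu + as.vector(Matrix::solve(
          ch, Matrix::solve(ch, z, system = "Lt"), system = "Pt"))
        r <- d$y - as.vector(d$A %*% x)
      } else {
        x <- stats::rnorm(npar, 0, sqrt(1 / prec))
      }

      # --- tau: slice on log scale ---------------------------------------
      lt <- slice_sample1(log(sds[["tau"]]), function(l) {
        tt2 <- exp(2 * l)
        ll <- if (have_obs)
          -0.5 * sum(log(d$v + tt2) + r^2 / (d$v + tt2)) else 0
        ll + half_cauchy_logpdf(exp(l), spec$tau_scale) + l
      }, w = 0.5)
      sds[["tau"]] <- exp(lt)
      tau2 <- sds[["tau"]]^2
      if (have_obs) w <- 1 / (d$v + tau2)

      # --- structural SDs: centered slice + non-centered rescaling -------
      for (nm in names(vb)) {
        b <- vb[[nm]]
        nblk <- length(b$idx)
        if (nblk == 0L) { sds[[nm]] <- rhalf_cauchy(1, b$scale); next }
        ss <- sum(b$wt * x[b$idx]^2)
        ls <- slice_sample1(log(sds[[nm]]), function(l) {
          s2 <- exp(2 * l)
          -(nblk - 1) * l - ss / (2 * s2) - log1p(s2 / b$scale^2)
        }, w = 0.7)
        sds[[nm]] <- exp(ls)
        # ancillarity move: rescale the block, keep x/sd fixed
        if (have_obs && touched[[nm]]) {
          g <- as.vector(Ablk[[nm]] %*% x[b$idx])
          u <- r + g
          c1 <- sum(w * u * g); c2 <- sum(w * g^2)
          s_old <- sds[[nm]]
          ls2 <- slice_sample1(log(s_old), function(l) {
            rho <- exp(l) / s_old
            -0.5 * (c2 * rho^2 - 2 * c1 * rho) - log1p(exp(2 * l) / b$scale^2) + l
          }, w = 0.7)
          rho <- exp(ls2) / s_old
          sds[[nm]] <- exp(ls2)
          x[b$idx] <- x[b$idx] * rho
          r <- u - rho * g
        } else if (!have_obs) {
          # no data: the non-centered conditional is the prior itself
          rho_sd <- rhalf_cauchy(1, b$scale)
          x[b$idx] <- x[b$idx] * (rho_sd / sds[[nm]])
          sds[[nm]] <- rho_sd
        }
      }

      if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L) {
        row0 <- row0 + 1L
        draws[row0, ] <- x
        sd_draws[row0, ] <- sds
      }
    }
  }

  monitored <- cbind(sd_draws, draws[, fixed_idx, drop = FALSE])
  diag <- mcmc_diagnostics(monitored, chain_id)
  if (any(diag$rhat > 1.1, na.rm = TRUE))
    warning("MCMC convergence: split-R-hat > 1.1 for ",
            paste(diag$parameter[which(diag$rhat > 1.1)], collapse = ", "))

  structure(list(draws = draws, sd_draws = sd_draws, chain = chain_id,
                 layout = d$layout, spec = spec, hierarchy = d$hierarchy,
                 vblocks = vb, config = config, diagnostics = diag,
                 n_obs = n_obs,
                 cells = d$cells,
                 outcome = unique(as.character(d$cells$outcome)) %||% NA,
                 sex = unique(as.character(d$cells$sex)) %||% NA),
            class = "cascade_fit")
}

#' @export
print.cascade_fit <- function(x, ...) {
  cat("<cascade_fit> ", nrow(x$draws), " draws x ", ncol(x$draws),
      " parameters (", x$config$chains, " chain(s), ", x$n_obs,
      " observations)\n", sep = "")
  cat("  max split-R-hat: ",
      round(suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)), 3),
      "; min ESS: ",
      round(suppressWarnings(min(x$diagnostics$ess, na.rm = TRUE)), 1),
      "\n", sep = "")
  invisible(x)
}

#' Fit one outcome and sex from crude cells
#'
#' Convenience wrapper: filters crude cells to `outcome` and `sex`, applies
#' [logit_transform()] with the spec's centering, and runs [run_mcmc()].
#'
#' @param cells crude-cell data.frame.
#' @param hierarchy an [as_hierarchy()] table.
#' @param outcome,sex the fit's outcome and sex.
#' @param spec a [model_spec()].
#' @param config an [mcmc_config()].
#' @param var_floor passed to [logit_transform()].
#' @return a `cascade_fit`.
#' @export
fit_cascade_model <- function(cells, hierarchy, outcome, sex,
                              spec = model_spec(), config = mcmc_config(),
                              var_floor = 1e-6) {
  outcome <- match.arg(outcome, cascade_outcomes())
  sex <- match.arg(sex, cascade_sexes())
  sub <- cells[cells$outcome == outcome & cells$sex == sex, , drop = FALSE]
  if (!nrow(sub))
    stop("no cells for outcome '", outcome, "', sex '", sex, "'")
  tc <- logit_transform(sub, var_floor = var_floor,
                        center_year = spec$center_year,
                        center_age = spec$center_age)
  run_mcmc(tc, hierarchy, spec, config)
}

# split-R-hat and effective sample size (Gelman et al. split-chain form;
# ESS from pairwise-summed autocorrelations with Geyer truncation)
mcmc_diagnostics <- function(draw_mat, chain_id) {
  split_chains <- function(v, id) {
    out <- list()
    for (c_ in unique(id)) {
      vc <- v[id == c_]
      h <- length(vc) %/% 2L
      out[[length(out) + 1L]] <- vc[seq_len(h)]
      out[[length(out) + 1L]] <- vc[h + seq_len(h)]
    }
    out
  }
  one <- function(v) {
    chains <- split_chains(v, chain_id)
    m <- length(chains); n <- length(chains[[1]])
    if (n < 4 || stats::sd(v) == 0) return(c(rhat = NA, ess = NA))
    means <- vapply(chains, mean, numeric(1))
    vars <- vapply(chains, stats::var, numeric(1))
    W <- mean(vars); B <- n * stats::var(means)
    var_plus <- (n - 1) / n * W + B / n
    rhat <- sqrt(var_plus / W)
    # ESS
    rho_sum <- 0
    for (ch_ in chains) {
      ac <- stats::acf(ch_, lag.max = min(n - 2L, 50L), plot = FALSE,
                       demean = TRUE)$acf[-1]
      s <- 0
      k <- 1
      while (k < length(ac)) {
        pair <- ac[k] + ifelse(k + 1 <= length(ac), ac[k + 1], 0)
        if (pair < 0) break
        s <- s + pair
        k <- k + 2
      }
      rho_sum <- rho_sum + s
    }
    ess <- m * n / (1 + 2 * rho_sum / m)
    c(rhat = rhat, ess = min(ess, m * n))
  }
  res <- t(apply(draw_mat, 2, one))
  data.frame(parameter = colnames(draw_mat), rhat = res[, 1], ess = res[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}
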