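test_that("retained draw counts follow samples / thin x chains", {
  h <- tiny_hierarchy()
  cells <- logit_transform(make_cells("s1", "AAA", 2005, p = 0.3, n = 200),
                           center_year = 2004.5)
  fit <- suppressWarnings(run_mcmc(cells, h, tiny_spec(),
                                   mcmc_config(burn_in = 20, samples = 60,
                                               thin = 3, chains = 2, seed = 1)))
  expect_equal(nrow(fit$draws), 40L)       # 60/3 per chain x 2
  expect_equal(table(fit$chain)[[1]], 20L)
  # publication-scale preset: 50 000 post-burn-in kept every 10th = 5000
  pcfg <- mcmc_config_publication()
  expect_equal(pcfg$samples %/% pcfg$thin, 5000L)
})

test_that("identical seed, config and data give bit-identical draws", {
  h <- tiny_hierarchy()
  cells <- logit_transform(
    make_cells(c("s1", "s1", "s2"), c("AAA", "AAA", "ABA"),
               c(2003, 2006, 2004), p = c(0.3, 0.35, 0.5),
               n = 300, age = c(45, 60, 50)))
  cfg <- mcmc_config(burn_in = 50, samples = 100, thin = 2, chains = 2,
                     seed = 123)
  f1 <- suppressWarnings(run_mcmc(cells, h, tiny_spec(), cfg))
  f2 <- suppressWarnings(run_mcmc(cells, h, tiny_spec(), cfg))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$sd_draws, f2$sd_draws)
  f3 <- suppressWarnings(run_mcmc(cells, h, tiny_spec(),
                                  mcmc_config(burn_in = 50, samples = 100,
                                              thin = 2, chains = 2, seed = 4)))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("precision-rich constant data pins the predicted logit", {
  # single country, no trend, true constant logit -1; n_eff = 2000 per cell
  h <- tiny_hierarchy()
  p0 <- expit(-1)
  cells <- do.call(rbind, lapply(2000:2009, function(yr)
    make_cells(paste0("s", yr), "AAA", yr, p = p0, n = 2000,
               age = rep(age_bands(), each = 1))))
  fit <- suppressWarnings(run_mcmc(logit_transform(cells), h, tiny_spec(),
                                   fast_mcmc(seed = 5)))
  surf <- predict_surface(fit, countries = "AAA")
  mean_logit <- mean(logit(surf$arr))
  expect_lt(abs(mean_logit - (-1)), 0.1)
})

test_that("posterior country means shrink between own data and region mean", {
  h <- tiny_hierarchy()
  # AAA's data sit at logit -0.5; sibling AAB (same region) at -1.0
  cells <- rbind(
    make_cells("sA", "AAA", rep(c(2002, 2007), each = 5), p = expit(-0.5),
               n = 800, age = rep(seq(30, 70, 10), 2)),
    make_cells("sB", "AAB", rep(c(2002, 2007), each = 5), p = expit(-1.0),
               n = 800, age = rep(seq(30, 70, 10), 2)))
  fit <- suppressWarnings(run_mcmc(logit_transform(cells), h, tiny_spec(),
                                   fast_mcmc(seed = 6)))
  surf <- predict_surface(fit, countries = c("AAA", "AAB"),
                          years = c(2002, 2007), ages = seq(32.5, 72.5, 10))
  eta_a <- mean(logit(surf$arr["AAA", , , ]))
  expect_gt(eta_a, -1.0)
  expect_lt(eta_a, -0.45)
})

test_that("duplicated national data pull harder than added community data", {
  h <- tiny_hierarchy()
  base <- rbind(
    make_cells("sA", "AAA", 2005, p = expit(-0.3), n = 500, age = 50),
    make_cells("sB", "AAB", 2005, p = expit(-1.2), n = 500, age = 50),
    make_cells("sC", "ABA", 2005, p = expit(-1.2), n = 500, age = 50))
  dup_nat <- rbind(base, transform(base[1, ], study_id = "sA2"))
  add_com <- rbind(base, transform(base[1, ], study_id = "sA3",
                                   coverage = "community"))
  target <- -0.3
  wins <- 0
  for (seed in 1:3) {
    eta <- function(cells) {
      fit <- suppressWarnings(run_mcmc(logit_transform(cells), h, tiny_spec(),
                                       fast_mcmc(seed = seed)))
      mean(logit(predict_surface(fit, countries = "AAA", years = 2005,
                                 ages = 52.5)$arr))
    }
    if (abs(eta(dup_nat) - target) < abs(eta(add_com) - target))
      wins <- wins + 1
  }
  expect_gte(wins, 2)
})

test_that("convergence problems raise a warning, never pass silently", {
  h <- tiny_hierarchy()
  cells <- logit_transform(make_cells("s1", "AAA", 2005, p = 0.3, n = 100))
  # absurdly short run on sparse data: R-hat cannot be clean
  expect_warning(
    run_mcmc(cells, h, tiny_spec(), mcmc_config(burn_in = 2, samples = 8,
                                                thin = 1, chains = 2,
                                                seed = 2)),
    "R-hat")
})

test_that("the sparse joint Gaussian block samples the exact conditional", {
  # fix the variance parameters by making their slice targets razor sharp:
  # compare mean/cov of the location draw against the closed form on a
  # small instance with a single iteration repeated many times
  h <- as_hierarchy(tiny_hierarchy()[1:2, ])
  spec <- tiny_spec()
  cells <- logit_transform(
    make_cells(c("s1", "s2"), c("AAA", "AAB"), c(2003, 2006),
               p = c(0.3, 0.6), n = c(150, 250), age = c(45, 65)))
  d <- htncascade:::build_design(cells, h, spec)
  qm <- htncascade:::build_q_mapping(d$A, nrow(d$layout$par))
  sds <- default_sds()
  prec <- rep(1 / spec$fixed_sd^2, nrow(d$layout$par))
  for (nm in names(d$vblocks)) {
    b <- d$vblocks[[nm]]
    if (length(b$idx)) prec[b$idx] <- b$wt / sds[[nm]]^2
  }
  w <- 1 / (d$v + sds[["tau"]]^2)
  qx <- as.vector(qm$S %*% w)
  qx[qm$diagpos] <- qx[qm$diagpos] + prec
  Q <- qm$Qpat; Q@x <- qx
  # closed form via dense algebra
  Ad <- as.matrix(d$A)
  Qd <- t(Ad) %*% diag(w, length(w)) %*% Ad + diag(prec)
  expect_equal(as.matrix(Q), Qd, tolerance = 1e-10, ignore_attr = TRUE)
  bb <- as.vector(t(Ad) %*% (w * d$y))
  mu_dense <- solve(Qd, bb)
  ch <- Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE)
  mu_sparse <- as.vector(Matrix::solve(ch, bb, system = "A"))
  expect_equal(mu_sparse, mu_dense, tolerance = 1e-8)
  # sampling path: empirical covariance of the permuted-solve draws
  set.seed(9)
  n_rep <- 4000
  sel <- 1:3
  zs <- matrix(rnorm(n_rep * nrow(Qd)), nrow(Qd))
  xs <- apply(zs, 2, function(z)
    (mu_sparse + as.vector(Matrix::solve(ch, Matrix::solve(ch, z, system = "Lt"),
                                         system = "Pt")))[sel])
  emp_cov <- stats::cov(t(xs))
  expect_equal(emp_cov, solve(Qd)[sel, sel], tolerance = 0.15,
               ignore_attr = TRUE)
  expect_equal(rowMeans(xs), mu_dense[sel], tolerance = 0.3)
})
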