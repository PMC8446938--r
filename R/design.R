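# Internal design machinery: parameter layout, sparse design matrices, and
# the precomputed mapping that lets the Gibbs sampler refresh the posterior
# precision matrix with a single sparse matrix-vector product per iteration.

FIXED_OFFSETS <- c("beta_subnational", "beta_community", "beta_urban", "beta_rural")

# Parameter layout for one outcome x sex fit. All hierarchy units get
# parameters whether or not they have data; unobserved units are then drawn
# from their conditional prior, which is exactly how countries without data
# inherit their region's distribution.
param_layout <- function(hmaps, spec, study_ids = character()) {
  n_years <- length(spec$years)
  kw <- min(spec$rw_dim, n_years - 2L)
  rw <- rw2_basis(n_years, kw)
  ages_all <- age_band_midpoints()
  AB <- age_spline_basis(ages_all, spec$knots, spec$boundary)
  n_age <- ncol(AB)

  fixed <- c("a_global", "b_global", paste0("age", seq_len(n_age)), "theta",
             FIXED_OFFSETS)
  par <- data.frame(name = fixed, block = "fixed", level = "global",
                    unit = "", stringsAsFactors = FALSE)
  add <- function(prefix, block, level, units) {
    data.frame(name = paste0(prefix, "[", units, "]"), block = block,
               level = level, unit = units, stringsAsFactors = FALSE)
  }
  for (lv in c("super", "region", "country")) {
    units <- switch(lv, super = hmaps$supers, region = hmaps$regions,
                    country = hmaps$countries)
    par <- rbind(par,
                 add(paste0("a_", lv), "dev_a", lv, units),
                 add(paste0("b_", lv), "dev_b", lv, units))
  }
  wunits <- list(global = "world", super = hmaps$supers,
                 region = hmaps$regions, country = hmaps$countries)
  for (lv in names(wunits)) {
    for (u in wunits[[lv]]) {
      par <- rbind(par, data.frame(
        name = paste0("w_", lv, "[", u, ",", seq_len(kw), "]"),
        block = paste0("walk_", lv), level = lv, unit = u,
        stringsAsFactors = FALSE))
    }
  }
  if (length(study_ids))
    par <- rbind(par, add("e", "study", "study", study_ids))
  par$idx <- seq_len(nrow(par))

  list(par = par, rw = rw, kw = kw, age_basis = AB, n_age = n_age,
       hmaps = hmaps, study_ids = study_ids)
}

# indices of a block, by name prefix
block_idx <- function(layout, block) layout$par$idx[layout$par$block == block]

# evaluate the layout's age basis at new midpoints (the basis structure is
# fixed at layout time; evaluation never changes it)
eval_age_basis <- function(layout, spec, ages) {
  if (layout$n_age == 1L)
    return(matrix(ages - mean(spec$boundary), ncol = 1))
  m <- splines::ns(ages, knots = spec$knots, Boundary.knots = spec$boundary)
  matrix(as.numeric(m), nrow = length(ages))
}

# Variance-parameter bookkeeping: for each scalar SD parameter, the location
# parameters it governs and the penalty weight entering the prior precision
# (eigenvalue lambda_k for walk coefficients, 1 otherwise).
variance_blocks <- function(layout, spec, study_cov = NULL) {
  par <- layout$par
  lam <- layout$rw$lambda
  vb <- list()
  for (lv in c("super", "region", "country")) {
    vb[[paste0("sd_a_", lv)]] <- list(
      idx = par$idx[par$block == "dev_a" & par$level == lv],
      wt = NULL, scale = spec$sd_scale_intercept[[lv]])
    vb[[paste0("sd_b_", lv)]] <- list(
      idx = par$idx[par$block == "dev_b" & par$level == lv],
      wt = NULL, scale = spec$sd_scale_slope[[lv]])
  }
  for (lv in c("global", "super", "region", "country")) {
    idx <- par$idx[par$block == paste0("walk_", lv)]
    vb[[paste0("sd_rw_", lv)]] <- list(
      idx = idx, wt = rep(lam, length(idx) / layout$kw),
      scale = spec$sd_scale_rw[[lv]])
  }
  if (length(layout$study_ids)) {
    for (cv in coverage_levels()) {
      idx <- par$idx[par$block == "study"][study_cov == cv]
      vb[[paste0("kappa_", cv)]] <- list(
        idx = idx, wt = NULL, scale = spec$kappa_scale[[cv]])
    }
  } else {
    for (cv in coverage_levels())
      vb[[paste0("kappa_", cv)]] <- list(idx = integer(0), wt = NULL,
                                         scale = spec$kappa_scale[[cv]])
  }
  for (nm in names(vb))
    if (is.null(vb[[nm]]$wt)) vb[[nm]]$wt <- rep(1, length(vb[[nm]]$idx))
  vb
}

# triplets for one "structural" design row (everything except offsets and
# study effects), given country, year index and age midpoint
structural_cols <- function(layout, spec, country, year_idx, age_mid) {
  par <- layout$par
  hm <- layout$hmaps
  n <- length(country)
  stopifnot(length(year_idx) == n, length(age_mid) == n)
  if (n == 0L)
    return(list(rows = integer(0), cols = integer(0), xs = numeric(0), n = 0L))
  t_c <- spec$years[year_idx] - spec$center_year
  z_c <- age_mid - spec$center_age
  AB <- eval_age_basis(layout, spec, age_mid)
  kw <- layout$kw
  B <- layout$rw$B

  name_idx <- setNames(par$idx, par$name)
  reg <- hm$regions[hm$reg_of_cty[country]]
  sup <- hm$supers[hm$sup_of_cty[country]]

  rows <- integer(0); cols <- integer(0); xs <- numeric(0)
  push <- function(j, x) {
    rows <<- c(rows, seq_len(n)); cols <<- c(cols, rep_len(j, n)); xs <<- c(xs, x)
  }
  push(name_idx[["a_global"]], rep(1, n))
  push(name_idx[["b_global"]], t_c)
  for (k in seq_len(layout$n_age))
    push(name_idx[[paste0("age", k)]], AB[, k])
  push(name_idx[["theta"]], z_c * t_c)
  # deviations
  pushu <- function(prefix, units, x) {
    rows <<- c(rows, seq_len(n))
    cols <<- c(cols, name_idx[paste0(prefix, "[", units, "]")])
    xs <<- c(xs, x)
  }
  pushu("a_super", sup, rep(1, n));   pushu("b_super", sup, t_c)
  pushu("a_region", reg, rep(1, n));  pushu("b_region", reg, t_c)
  pushu("a_country", country, rep(1, n)); pushu("b_country", country, t_c)
  # walks: kw basis columns per level
  wpush <- function(lv, units) {
    for (k in seq_len(kw)) {
      rows <<- c(rows, seq_len(n))
      cols <<- c(cols, name_idx[paste0("w_", lv, "[", units, ",", k, "]")])
      xs <<- c(xs, B[year_idx, k])
    }
  }
  wpush("global", rep("world", n))
  wpush("super", sup); wpush("region", reg); wpush("country", country)
  list(rows = rows, cols = cols, xs = xs, n = n)
}

# Full design for observed cells of one outcome x sex.
build_design <- function(cells, hierarchy, spec) {
  stopifnot(inherits(spec, "cascade_model_spec"))
  hierarchy <- as_hierarchy(hierarchy)
  hm <- hierarchy_maps(hierarchy)
  cells <- as.data.frame(cells)
  stopifnot(all(c("y", "v", "country", "year", "age_group_lower",
                  "coverage", "scope", "study_id") %in% names(cells)))
  if (!all(cells$country %in% hm$countries))
    stop("cells reference countries missing from the hierarchy: ",
         paste(setdiff(unique(cells$country), hm$countries), collapse = ", "))
  if (!all(cells$year %in% spec$years))
    stop("cells outside the estimation window ",
         min(spec$years), "-", max(spec$years))

  study_ids <- sort(unique(as.character(cells$study_id)))
  layout <- param_layout(hm, spec, study_ids)
  study_cov <- vapply(study_ids, function(s)
    as.character(cells$coverage[match(s, cells$study_id)]), character(1))

  n <- nrow(cells)
  year_idx <- match(cells$year, spec$years)
  sc <- structural_cols(layout, spec, as.character(cells$country), year_idx,
                        cells$age_group_lower + 2.5)
  rows <- sc$rows; cols <- sc$cols; xs <- sc$xs
  name_idx <- setNames(layout$par$idx, layout$par$name)
  # coverage / scope offsets
  off <- list(beta_subnational = cells$coverage == "subnational",
              beta_community = cells$coverage == "community",
              beta_urban = cells$scope == "urban_only",
              beta_rural = cells$scope == "rural_only")
  for (nm in names(off)) {
    w <- which(off[[nm]])
    if (length(w)) {
      rows <- c(rows, w); cols <- c(cols, rep(name_idx[[nm]], length(w)))
      xs <- c(xs, rep(1, length(w)))
    }
  }
  if (n > 0) {
    sidx <- name_idx[paste0("e[", as.character(cells$study_id), "]")]
    rows <- c(rows, seq_len(n)); cols <- c(cols, sidx); xs <- c(xs, rep(1, n))
  }

  npar <- nrow(layout$par)
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = xs, dims = c(n, npar))
  list(A = A, y = cells$y, v = cells$v, layout = layout, spec = spec,
       hierarchy = hierarchy,
       vblocks = variance_blocks(layout, spec, study_cov),
       study_cov = study_cov, cells = cells)
}

# Precompute the sparse map S with Q@x = S %*% w (+ prior diagonal), where
# w are the per-observation likelihood precisions. Pattern of Q is fixed, so
# the Cholesky factorisation can be updated symbolically-in-place.
build_q_mapping <- function(A, npar) {
  Apat <- A
  Apat@x[] <- 1
  Qpat <- as(Matrix::forceSymmetric(Matrix::crossprod(Apat) +
                                      Matrix::Diagonal(npar), "U"),
             "CsparseMatrix")
  ptr <- Qpat@p
  qcol <- rep.int(seq_len(npar) - 1L, diff(ptr))
  qkey <- Qpat@i + qcol * as.double(npar)
  At <- as(A, "TsparseMatrix")
  o <- order(At@i, At@j)
  ri <- At@i[o]; rj <- At@j[o]; rx <- At@x[o]
  splits <- split(seq_along(ri), ri)
  Si <- Sj <- Sx <- vector("list", length(splits))
  for (ii in seq_along(splits)) {
    idx <- splits[[ii]]
    cc <- rj[idx]; vv <- rx[idx]
    m <- length(cc)
    rep1 <- rep.int(seq_len(m), rev(seq_len(m)))
    rep2 <- unlist(lapply(seq_len(m), function(k) k:m), use.names = FALSE)
    key <- cc[rep1] + cc[rep2] * as.double(npar)
    Si[[ii]] <- match(key, qkey)
    Sj[[ii]] <- rep.int(ri[idx[1]] + 1L, length(key))
    Sx[[ii]] <- vv[rep1] * vv[rep2]
  }
  S <- Matrix::sparseMatrix(i = unlist(Si), j = unlist(Sj), x = unlist(Sx),
                            dims = c(length(qkey), nrow(A)))
  diagpos <- match((seq_len(npar) - 1L) * (as.double(npar) + 1), qkey)
  list(Qpat = Qpat, S = S, diagpos = diagpos)
}

# Prediction design matrix over a (country, year, age) grid with offsets and
# study effects at their national reference (zero). Row order matches an
# array [country, year, age] in R's column-major layout.
build_prediction_matrix <- function(layout, spec, countries, years, ages) {
  grid <- expand.grid(country = countries, year = years, age = ages,
                      stringsAsFactors = FALSE)
  stopifnot(all(years %in% spec$years))
  sc <- structural_cols(layout, spec, as.character(grid$country),
                        match(grid$year, spec$years), grid$age)
  npar <- nrow(layout$par)
  Matrix::sparseMatrix(i = sc$rows, j = sc$cols, x = sc$xs,
                       dims = c(nrow(grid), npar))
}
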