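# Shared fixtures and small oracles, all built in code at test time.

tiny_hierarchy <- function() {
  as_hierarchy(data.frame(
    country = c("AAA", "AAB", "ABA", "BAA"),
    region = c("rA1", "rA1", "rA2", "rB1"),
    super_region = c("sA", "sA", "sA", "sB")))
}

tiny_spec <- function(...) model_spec(years = 2000:2009, rw_dim = 6, ...)

# hand-rolled crude cells on the observation scale
make_cells <- function(study_id, country, year, p, n, outcome = "prevalence",
                       sex = "female", age = 50, coverage = "national",
                       scope = "both") {
  df <- data.frame(study_id = study_id, country = country, year = year,
                   coverage = coverage, scope = scope, sex = sex,
                   age_group_lower = age, outcome = outcome, p_hat = p,
                   n_eff = n, se = sqrt(p * (1 - p) / n), n_raw = n,
                   stringsAsFactors = FALSE)
  df
}

# microdata builder with explicit blood pressures
make_records <- function(sbp, dbp, meds, diagnosed = NA, age = 50,
                         sex = "female", weight = 1) {
  data.frame(age = age, sex = sex, sbp = sbp, dbp = dbp,
             on_medication = meds, diagnosed = diagnosed, weight = weight,
             stringsAsFactors = FALSE)
}

default_sds <- function() {
  c(sd_a_super = 1, sd_a_region = 0.5, sd_a_country = 0.4,
    sd_b_super = 0.02, sd_b_region = 0.02, sd_b_country = 0.02,
    sd_rw_global = 0.01, sd_rw_super = 0.01, sd_rw_region = 0.01,
    sd_rw_country = 0.01, kappa_national = 0.05, kappa_subnational = 0.1,
    kappa_community = 0.15, tau = 0.05)
}

# batch-means standard error of a statistic of a (possibly autocorrelated)
# draw sequence
batch_se <- function(v, stat = median, n_batch = 20L) {
  n <- length(v)
  bs <- floor(n / n_batch)
  vals <- vapply(seq_len(n_batch), function(b)
    stat(v[((b - 1) * bs + 1):(b * bs)]), numeric(1))
  stats::sd(vals) / sqrt(n_batch)
}

# small synthetic world used by several suites (fast: 8 countries, 10 years)
small_world_config <- function(...) {
  world_config(n_countries = 8L, n_regions = 4L, n_super_regions = 2L,
               years = 2000:2009, rw_dim = 6L, ...)
}

fast_mcmc <- function(seed = 1L, chains = 1L) {
  mcmc_config(burn_in = 200L, samples = 600L, thin = 3L, chains = chains,
              seed = seed)
}
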